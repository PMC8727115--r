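# Plug-in (maximum-likelihood, frequency-count) information estimators on
# discrete variables. All quantities are in bits (log base 2). Zero cells
# follow the 0*log(0) := 0 convention; no smoothing is applied. Tiny negative
# values caused by floating point are clamped to zero.

.NEG_TOL <- 1e-9

# Encode an arbitrary atomic vector as integer codes 1..L.
as_codes <- function(x) {
  if (is.factor(x)) return(as.integer(x))
  as.integer(factor(x, levels = sort(unique(x))))
}

check_equal_length <- function(...) {
  ns <- lengths(list(...))
  if (any(ns == 0L)) stop("columns must be non-empty", call. = FALSE)
  if (length(unique(ns)) != 1L) {
    stop("columns must have identical length (got ",
         paste(ns, collapse = ", "), ")", call. = FALSE)
  }
  invisible(ns[[1L]])
}

#' Contingency counts over one to three discrete columns
#'
#' Counts joint occurrences over the cross-product of the columns' category
#' alphabets. This is the count basis for every estimator in the package.
#'
#' @param ... One to three atomic vectors of equal length (factors, integers,
#'   characters, or logicals), interpreted as discrete columns.
#' @return An array of integer counts with one dimension per column (a plain
#'   vector for one column), whose entries sum to the number of samples.
#' @examples
#' tabulate_counts(c(0, 1, 0, 1), c(0, 1, 0, 1))
#' @export
tabulate_counts <- function(...) {
  cols <- list(...)
  if (length(cols) < 1L || length(cols) > 3L)
    stop("tabulate_counts() takes 1 to 3 columns", call. = FALSE)
  check_equal_length(...)
  tab <- table(lapply(cols, as_codes))
  array(as.integer(tab), dim = dim(tab))
}

# Shannon entropy in bits from a vector/array of counts.
entropy_from_counts <- function(counts) {
  n <- sum(counts)
  counts <- counts[counts > 0]
  p <- counts / n
  -sum(p * log2(p))
}

clamp0 <- function(v) {
  if (v < 0 && v > -.NEG_TOL) 0 else v
}

#' Shannon entropy of a discrete column
#'
#' \eqn{H(X) = -\sum_x p(x) \log_2 p(x)} with maximum-likelihood cell
#' probabilities; \eqn{0 \log 0 := 0}.
#'
#' @param x An atomic vector interpreted as a discrete column.
#' @return Entropy in bits, in \code{[0, log2(alphabet size)]}.
#' @examples
#' entropy(c(0, 0, 0, 1))  # about 0.811 bits
#' @export
entropy <- function(x) {
  if (length(x) == 0L) stop("columns must be non-empty", call. = FALSE)
  entropy_from_counts(tabulate(as_codes(x)))
}

#' Conditional entropy H(X | Y)
#'
#' \eqn{H(X\mid Y) = \sum_y p(y) H(X \mid Y = y) = H(X,Y) - H(Y)}.
#'
#' @param x,given Equal-length discrete columns.
#' @return Conditional entropy in bits, in \code{[0, H(x)]}.
#' @export
conditional_entropy <- function(x, given) {
  check_equal_length(x, given)
  jointly <- entropy_from_counts(tabulate_counts(x, given))
  clamp0(jointly - entropy(given))
}

#' Mutual information I(X; Y)
#'
#' Plug-in estimate of
#' \eqn{I(X;Y)=\sum_{x,y} p(x,y)\log_2 \frac{p(x,y)}{p(x)p(y)}},
#' computed as \eqn{H(X)+H(Y)-H(X,Y)}. Symmetric and non-negative.
#'
#' @param x,y Equal-length discrete columns.
#' @return Mutual information in bits.
#' @examples
#' mutual_information(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1 bit
#' @export
mutual_information <- function(x, y) {
  check_equal_length(x, y)
  v <- entropy(x) + entropy(y) - entropy_from_counts(tabulate_counts(x, y))
  clamp0(v)
}

#' Conditional mutual information I(X; Y | Z)
#'
#' \eqn{I(X;Y\mid Z)=\sum_z p(z) I(X;Y \mid Z=z)}, computed via the joint
#' entropy identity \eqn{H(X,Z)+H(Y,Z)-H(Z)-H(X,Y,Z)}.
#'
#' @param x,y,z Equal-length discrete columns.
#' @return Conditional mutual information in bits (non-negative).
#' @export
conditional_mutual_information <- function(x, y, z) {
  check_equal_length(x, y, z)
  v <- entropy_from_counts(tabulate_counts(x, z)) +
    entropy_from_counts(tabulate_counts(y, z)) -
    entropy(z) -
    entropy_from_counts(tabulate_counts(x, y, z))
  clamp0(v)
}

#' Interaction information I(X; Y) - I(X; Y | C)
#'
#' Positive values indicate redundancy of \code{x} and \code{y} with respect
#' to the class \code{c}; negative values indicate synergy (the pair carries
#' class information that neither member carries alone, as in a parity/XOR
#' relation).
#'
#' @param x,y,c Equal-length discrete columns; \code{c} is the class.
#' @return Interaction information in bits; may be negative.
#' @export
interaction_information <- function(x, y, c) {
  mutual_information(x, y) - conditional_mutual_information(x, y, c)
}

#' Information gain factor CU used by the NDCRFS criterion
#'
#' \eqn{CU(f_{sel}, f_k) = 2 / (H(f_{sel}\mid C) + H(f_k\mid C))}. When both
#' features are deterministic functions of the class the denominator vanishes
#' and CU is defined as 0, so the redundancy penalty disappears and such
#' candidates are ranked by relevance alone.
#'
#' @param f_sel,f_cand,c Equal-length discrete columns: a selected feature, a
#'   candidate feature, and the class.
#' @return Dimensionless gain factor (1/bits).
#' @export
cu_factor <- function(f_sel, f_cand, c) {
  check_equal_length(f_sel, f_cand, c)
  denom <- conditional_entropy(f_sel, c) + conditional_entropy(f_cand, c)
  if (denom < 1e-12) return(0)
  2 / denom
}
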