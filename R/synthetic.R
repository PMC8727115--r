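# Generator of discrete classification tables with planted feature roles, so
# every criterion and the full pipeline are testable without external data.
# Roles mirror the three relevance/redundancy regimes the criteria are built
# to discriminate: features marginally relevant to the class, noisy copies of
# relevant features (redundancy), parity-coupled pairs that are marginally
# class-independent but jointly informative (interaction), and uniform noise.

#' Describe a planted synthetic dataset design
#'
#' @param n_samples Number of rows.
#' @param n_classes Number of class categories (class drawn uniformly); all
#'   planted features use the same alphabet size.
#' @param n_relevant Features that copy the class, each value independently
#'   re-sampled uniformly from the alphabet with probability
#'   \code{relevance_noise}.
#' @param n_redundant Noisy copies of planted relevant features (cycling
#'   through them), re-sampled with probability \code{redundancy_noise};
#'   requires \code{n_relevant >= 1} when positive.
#' @param n_interacting_pairs Pairs \code{(X, (class - X) mod n_classes)}
#'   (XOR for a binary alphabet) with partner values re-sampled with
#'   probability \code{interaction_noise}: each member is marginally
#'   independent of the class, the pair jointly determines it.
#' @param n_irrelevant Uniform-noise features.
#' @param relevance_noise,redundancy_noise,interaction_noise Re-sampling
#'   probabilities; \code{relevance_noise} must lie in \code{[0, 0.5)}.
#' @return An object of class \code{planted_design}.
#' @examples
#' d <- planted_design(n_samples = 200, n_relevant = 2, n_irrelevant = 5)
#' @export
planted_design <- function(n_samples = 500L, n_classes = 2L,
                           n_relevant = 5L, n_redundant = 5L,
                           n_interacting_pairs = 1L, n_irrelevant = 20L,
                           relevance_noise = 0.1, redundancy_noise = 0.1,
                           interaction_noise = 0) {
  counts <- c(n_relevant, n_redundant, n_interacting_pairs, n_irrelevant)
  if (any(counts < 0) || sum(counts) < 1L)
    stop("feature counts must be non-negative with at least one feature",
         call. = FALSE)
  if (n_redundant > 0L && n_relevant < 1L)
    stop("redundant copies require at least one relevant feature",
         call. = FALSE)
  if (relevance_noise < 0 || relevance_noise >= 0.5)
    stop("relevance_noise must be in [0, 0.5)", call. = FALSE)
  for (r in c(redundancy_noise, interaction_noise))
    if (r < 0 || r > 1) stop("noise rates must be in [0, 1]", call. = FALSE)
  if (n_samples < 2L || n_classes < 2L)
    stop("need at least 2 samples and 2 classes", call. = FALSE)
  structure(list(
    n_samples = as.integer(n_samples), n_classes = as.integer(n_classes),
    n_relevant = as.integer(n_relevant),
    n_redundant = as.integer(n_redundant),
    n_interacting_pairs = as.integer(n_interacting_pairs),
    n_irrelevant = as.integer(n_irrelevant),
    relevance_noise = relevance_noise, redundancy_noise = redundancy_noise,
    interaction_noise = interaction_noise
  ), class = "planted_design")
}

#' @export
print.planted_design <- function(x, ...) {
  cat("Planted design: ", x$n_samples, " samples, ", x$n_classes,
      " classes\n  relevant ", x$n_relevant, " (noise ", x$relevance_noise,
      "), redundant ", x$n_redundant, " (noise ", x$redundancy_noise,
      "), interacting pairs ", x$n_interacting_pairs, " (noise ",
      x$interaction_noise, "), irrelevant ", x$n_irrelevant, "\n", sep = "")
  invisible(x)
}

resample_uniform <- function(values, rate, n_classes) {
  if (rate <= 0) return(values)
  hit <- stats::runif(length(values)) < rate
  values[hit] <- sample.int(n_classes, sum(hit), replace = TRUE) - 1L
  values
}

#' Generate a synthetic classification table with planted roles
#'
#' Column order is relevant, redundant, interacting (pairs adjacent),
#' irrelevant; all values are 0-based integer codes, the class column is
#' named \code{class}. Fully reproducible from \code{seed}.
#'
#' @param design A \code{\link{planted_design}}.
#' @param seed Integer seed controlling all randomness.
#' @return A list of class \code{planted_dataset}: \code{data} (data frame
#'   with the class column), \code{roles} (data frame with columns
#'   \code{feature}, \code{role}, \code{source}: the copied relevant feature
#'   for redundant columns, the partner for interacting columns), the
#'   \code{design} and the \code{seed}.
#' @examples
#' ds <- generate_dataset(planted_design(n_samples = 100), seed = 1)
#' table(ds$roles$role)
#' @export
generate_dataset <- function(design, seed = 1L) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(as.integer(seed))
  n <- design$n_samples
  m <- design$n_classes
  cl <- sample.int(m, n, replace = TRUE) - 1L

  cols <- list()
  roles <- character(0)
  source <- character(0)
  add <- function(values, role, src = NA_character_) {
    i <- length(cols) + 1L
    cols[[i]] <<- as.integer(values)
    roles[i] <<- role
    source[i] <<- src
  }

  for (i in seq_len(design$n_relevant))
    add(resample_uniform(cl, design$relevance_noise, m), "relevant")
  rel_idx <- which(roles == "relevant")
  for (i in seq_len(design$n_redundant)) {
    src <- rel_idx[(i - 1L) %% length(rel_idx) + 1L]
    add(resample_uniform(cols[[src]], design$redundancy_noise, m),
        "redundant", paste0("f", src))
  }
  for (i in seq_len(design$n_interacting_pairs)) {
    x <- sample.int(m, n, replace = TRUE) - 1L
    partner <- resample_uniform((cl - x) %% m, design$interaction_noise, m)
    j <- length(cols) + 1L
    add(x, "interacting", paste0("f", j + 1L))
    add(partner, "interacting", paste0("f", j))
  }
  for (i in seq_len(design$n_irrelevant))
    add(sample.int(m, n, replace = TRUE) - 1L, "irrelevant")

  names(cols) <- paste0("f", seq_along(cols))
  data <- as.data.frame(cols)
  data$class <- cl
  structure(list(
    data = data,
    roles = data.frame(feature = names(cols), role = roles, source = source,
                       stringsAsFactors = FALSE),
    design = design, seed = as.integer(seed)
  ), class = "planted_dataset")
}

#' @export
print.planted_dataset <- function(x, ...) {
  cat("Planted dataset (seed ", x$seed, "): ", nrow(x$data), " x ",
      ncol(x$data) - 1L, " + class\n", sep = "")
  print(table(x$roles$role))
  invisible(x)
}

#' Analytic mutual information of a planted role with the class
#'
#' Closed-form \eqn{I(f; C)} implied by the design's noise mixture, for a
#' binary class and binary features. A relevant feature is the class passed
#' through uniform re-sampling at rate \eqn{\rho}, i.e. a binary symmetric
#' channel with flip probability \eqn{\rho/2}, giving
#' \eqn{I = 1 - H_b(\rho/2)} bits. Redundant copies chain a second channel;
#' interacting and irrelevant features are marginally independent of the
#' class (0 bits).
#'
#' @param design A \code{\link{planted_design}} with \code{n_classes = 2}.
#' @param role One of \code{"relevant"}, \code{"redundant"},
#'   \code{"interacting"}, \code{"irrelevant"}.
#' @return Expected mutual information in bits.
#' @export
expected_mi <- function(design, role = c("relevant", "redundant",
                                         "interacting", "irrelevant")) {
  stopifnot(inherits(design, "planted_design"))
  role <- match.arg(role)
  if (design$n_classes != 2L)
    stop("expected_mi is implemented for binary alphabets only",
         call. = FALSE)
  hb <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  flip_rel <- design$relevance_noise / 2
  switch(role,
    relevant = 1 - hb(flip_rel),
    redundant = {
      f2 <- design$redundancy_noise / 2
      flip <- flip_rel * (1 - f2) + (1 - flip_rel) * f2
      1 - hb(flip)
    },
    interacting = 0,
    irrelevant = 0
  )
}

#' Small worked fixture: a duplicated feature next to a balanced one
#'
#' Eight samples, binary class; \code{f1} is a noisy copy of the class,
#' \code{f2} duplicates \code{f1} exactly, and \code{f3} is class-balanced
#' (zero marginal relevance). Useful for seeing how the criteria treat exact
#' duplicates versus genuinely new columns.
#'
#' @return Data frame with columns \code{f1}, \code{f2}, \code{f3},
#'   \code{class}.
#' @examples
#' toy_duplicate_data()
#' @export
toy_duplicate_data <- function() {
  data.frame(
    f1 = c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L),
    f2 = c(0L, 0L, 0L, 1L, 0L, 1L, 1L, 1L),
    f3 = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 1L),
    class = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  )
}
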