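# Per-candidate scoring for the eight selection criteria, over a shared
# selection state that memoizes pairwise statistics. Scores for mim, cife,
# jmi, cmim, drjmim and ndcrfs are in bits; dwfs and dwur produce
# dimensionless dynamic weights. The two kinds are never compared across
# criteria.

CRITERIA <- c("mim", "cife", "jmi", "cmim", "dwfs", "drjmim", "dwur", "ndcrfs")

#' Names of the available selection criteria
#'
#' @return Character vector of criterion names accepted by
#'   \code{\link{select_features}} and the command-line tool.
#' @export
list_criteria <- function() CRITERIA

match_criterion <- function(criterion) {
  if (!is.character(criterion) || length(criterion) != 1L ||
      !(criterion %in% CRITERIA)) {
    stop("unknown criterion ", deparse(criterion), "; available: ",
         paste(CRITERIA, collapse = ", "), call. = FALSE)
  }
  criterion
}

# Build the shared selection state: integer-coded feature matrix, class
# codes, per-feature relevance I(f;C), entropies H(f) and H(f|C), H(C), a
# pairwise-statistics cache, and an instrumentation counter of how many
# pairwise (feature, feature) statistic evaluations were performed.
new_selection_state <- function(x, y, beta = 0.5) {
  x <- as.data.frame(x)
  if (ncol(x) < 1L) stop("no features", call. = FALSE)
  check_equal_length(x[[1L]], y)
  yc <- as_codes(y)
  if (max(yc) < 2L)
    stop("constant class column: nothing to discriminate", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1)
    stop("beta must be a single value in [0, 1]", call. = FALSE)
  Xc <- vapply(x, as_codes, integer(nrow(x)))
  if (is.null(colnames(Xc))) colnames(Xc) <- paste0("f", seq_len(ncol(Xc)))
  st <- new.env(parent = emptyenv())
  st$X <- Xc
  st$y <- yc
  st$n <- nrow(Xc)
  st$p <- ncol(Xc)
  st$feature_names <- colnames(Xc)
  st$beta <- beta
  st$HC <- entropy(yc)
  st$Hf <- apply(Xc, 2L, entropy)
  st$HfC <- apply(Xc, 2L, conditional_entropy, given = yc)
  st$rel <- apply(Xc, 2L, mutual_information, y = yc)
  st$pair_cache <- new.env(parent = emptyenv())
  st$n_pair_stats <- 0L
  st
}

# All pairwise statistics between features i and j needed by any criterion,
# computed from one pass over the joint tables and memoized:
#   mi        = I(f_i; f_j)
#   cmi_ff_C  = I(f_i; f_j | C)
#   cmi_iC_j  = I(f_i; C | f_j)   (asymmetric; i is the candidate)
pair_stats <- function(st, i, j) {
  key <- paste0(i, ":", j)
  hit <- st$pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  fi <- st$X[, i]; fj <- st$X[, j]; yc <- st$y
  Hij  <- entropy_from_counts(tabulate_counts(fi, fj))
  HiC  <- st$HfC[i] + st$HC
  HjC  <- st$HfC[j] + st$HC
  HijC <- entropy_from_counts(tabulate_counts(fi, fj, yc))
  out <- list(
    mi       = clamp0(st$Hf[i] + st$Hf[j] - Hij),
    cmi_ff_C = clamp0(HiC + HjC - st$HC - HijC),
    cmi_iC_j = clamp0(Hij + HjC - st$Hf[j] - HijC)
  )
  st$pair_cache[[key]] <- out
  # the mirrored key shares the symmetric parts; cmi_jC_i differs
  st$pair_cache[[paste0(j, ":", i)]] <- list(
    mi = out$mi, cmi_ff_C = out$cmi_ff_C,
    cmi_iC_j = clamp0(Hij + HiC - st$Hf[i] - HijC)
  )
  st$n_pair_stats <- st$n_pair_stats + 1L
  out
}

# Dynamic-relevance ratio: 2 * (I(f_k; C | f_sel) - I(f_k; C)) / (H(f_k) + H(C)).
# Positive values flag interaction relevance, negative values redundancy.
c_ratio_state <- function(st, k, sel) {
  denom <- st$Hf[k] + st$HC
  if (denom < 1e-12)
    stop("degenerate input: constant feature and constant class", call. = FALSE)
  ps <- pair_stats(st, k, sel)
  2 * (ps$cmi_iC_j - st$rel[k]) / denom
}

cu_state <- function(st, sel, k) {
  denom <- st$HfC[sel] + st$HfC[k]
  if (denom < 1e-12) return(0)
  2 / denom
}

# From-scratch score of candidate f_k given the ordered selected set S.
# This path never uses the incremental aggregates kept by the greedy driver,
# so it doubles as the no-cache correctness route in the tests.
score_one <- function(st, S, k, criterion) {
  rel_k <- st$rel[[k]]
  if (criterion == "mim") return(rel_k)
  if (length(S) == 0L) return(rel_k)  # empty-sum/max convention: MIM seeding
  switch(criterion,
    cife = {
      pen <- vapply(S, function(s) {
        ps <- pair_stats(st, k, s); ps$mi - ps$cmi_ff_C
      }, numeric(1))
      rel_k - sum(pen)
    },
    jmi = {
      pen <- vapply(S, function(s) {
        ps <- pair_stats(st, k, s); ps$mi - ps$cmi_ff_C
      }, numeric(1))
      rel_k - mean(pen)
    },
    cmim = {
      pen <- vapply(S, function(s) {
        ps <- pair_stats(st, k, s); ps$mi - ps$cmi_ff_C
      }, numeric(1))
      rel_k - max(pen)
    },
    ndcrfs = {
      pen <- vapply(S, function(s) {
        ps <- pair_stats(st, k, s)
        cu_state(st, s, k) * (ps$cmi_ff_C - st$rel[[s]])
      }, numeric(1))
      rel_k - max(pen)
    },
    drjmim = {
      terms <- vapply(S, function(s) {
        ps <- pair_stats(st, k, s)
        ii <- ps$mi - ps$cmi_ff_C  # interaction information I(f_k; s; C)
        ii * (rel_k + c_ratio_state(st, k, s) * st$rel[[s]])
      }, numeric(1))
      min(terms)
    },
    dwfs = {
      w <- 1
      for (s in S) {
        denom <- st$Hf[[k]] + st$HC
        if (denom < 1e-12)
          stop("degenerate input: constant feature and constant class",
               call. = FALSE)
        ps <- pair_stats(st, k, s)
        w <- w * (2 * (ps$cmi_iC_j - rel_k) / denom + 1)
      }
      w * rel_k
    },
    dwur = {
      w <- 1
      for (s in S) {
        ps <- pair_stats(st, k, s)
        w <- w * (1 - st$beta * ps$mi) *
          (rel_k + c_ratio_state(st, k, s) * st$rel[[s]])
      }
      w
    },
    stop("unknown criterion ", criterion, call. = FALSE)
  )
}

#' Score candidate features under a selection criterion
#'
#' Computes the criterion value of each candidate feature given an ordered,
#' already-selected feature set, from scratch (no incremental caching). With
#' an empty selected set every criterion reduces to the relevance
#' \eqn{I(f_k; C)}, so all criteria agree on the first feature to select.
#'
#' @param x Data frame or matrix of discrete features.
#' @param y Class column (vector of length \code{nrow(x)}).
#' @param criterion One of \code{list_criteria()}.
#' @param selected Character vector (or integer indices) of already-selected
#'   features, in selection order. May be empty.
#' @param candidates Features to score; defaults to all non-selected columns.
#' @param beta Redundancy coefficient in \code{[0, 1]} used by \code{dwur}.
#' @return Named numeric vector of scores (bits for \code{mim}, \code{cife},
#'   \code{jmi}, \code{cmim}, \code{drjmim}, \code{ndcrfs}; dimensionless
#'   weights for \code{dwfs} and \code{dwur}).
#' @examples
#' d <- toy_duplicate_data()
#' score_candidates(d[c("f1", "f2", "f3")], d$class, "ndcrfs", selected = "f1")
#' @export
score_candidates <- function(x, y, criterion, selected = character(),
                             candidates = NULL, beta = 0.5) {
  criterion <- match_criterion(criterion)
  st <- new_selection_state(x, y, beta)
  resolve <- function(ids) {
    if (is.numeric(ids)) ids <- st$feature_names[ids]
    bad <- setdiff(ids, st$feature_names)
    if (length(bad))
      stop("unknown feature id(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    ids
  }
  selected <- resolve(selected)
  if (is.null(candidates)) candidates <- setdiff(st$feature_names, selected)
  candidates <- resolve(candidates)
  if (length(intersect(selected, candidates)))
    stop("selected and candidate sets must be disjoint", call. = FALSE)
  Sidx <- match(selected, st$feature_names)
  vapply(candidates, function(f)
    score_one(st, Sidx, match(f, st$feature_names), criterion), numeric(1))
}
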