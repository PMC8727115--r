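# Greedy forward search: at each step the argmax-scoring candidate moves
# from the candidate set to the selected set, until K features are chosen or
# the candidates are exhausted. Ties break to the lowest feature index;
# non-finite scores rank last. Pairwise statistics are evaluated only against
# the newly selected feature, so a run costs at most T * n_features pairwise
# evaluations (the O(Tmn) bound, with m the per-statistic cost in samples).

greedy_rank <- function(st, criterion, k) {
  p <- st$p
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k <- min(as.integer(k), p)

  selected <- integer(0)
  step_scores <- numeric(0)
  cand <- seq_len(p)

  # per-candidate incremental aggregates
  pen_sum <- numeric(p)            # cife/jmi: sum over S of I - CMI
  pen_max <- rep(-Inf, p)          # cmim: running max of I - CMI
  pen_max_cu <- rep(-Inf, p)       # ndcrfs: running max of CU * (CMI - rel_s)
  run_min <- rep(Inf, p)           # drjmim: running min of the product
  W <- rep(1, p)                   # dwfs/dwur dynamic weights

  current_scores <- function() {
    nS <- length(selected)
    if (nS == 0L) return(st$rel[cand])  # every criterion seeds by relevance
    switch(criterion,
      mim    = st$rel[cand],
      cife   = st$rel[cand] - pen_sum[cand],
      jmi    = st$rel[cand] - pen_sum[cand] / nS,
      cmim   = st$rel[cand] - pen_max[cand],
      ndcrfs = st$rel[cand] - pen_max_cu[cand],
      drjmim = run_min[cand],
      dwfs   = W[cand] * st$rel[cand],
      dwur   = W[cand]
    )
  }

  while (length(selected) < k && length(cand) > 0L) {
    sc <- current_scores()
    sc_rank <- sc
    sc_rank[!is.finite(sc_rank)] <- -Inf   # undefined penalties never win
    pick <- cand[which.max(sc_rank)]       # first max = lowest feature index
    step_scores <- c(step_scores, sc[match(pick, cand)])
    selected <- c(selected, pick)
    cand <- setdiff(cand, pick)

    if (length(cand) > 0L && criterion != "mim") {
      rel_new <- st$rel[[pick]]
      for (f in cand) {
        ps <- pair_stats(st, f, pick)
        ii <- ps$mi - ps$cmi_ff_C
        switch(criterion,
          cife = ,
          jmi  = pen_sum[f] <- pen_sum[f] + ii,
          cmim = pen_max[f] <- max(pen_max[f], ii),
          ndcrfs = pen_max_cu[f] <- max(
            pen_max_cu[f], cu_state(st, pick, f) * (ps$cmi_ff_C - rel_new)),
          drjmim = run_min[f] <- min(
            run_min[f],
            ii * (st$rel[[f]] + c_ratio_state(st, f, pick) * rel_new)),
          dwfs = {
            denom <- st$Hf[[f]] + st$HC
            if (denom < 1e-12)
              stop("degenerate input: constant feature and constant class",
                   call. = FALSE)
            W[f] <- W[f] * (2 * (ps$cmi_iC_j - st$rel[[f]]) / denom + 1)
          },
          dwur = W[f] <- W[f] * (1 - st$beta * ps$mi) *
            (st$rel[[f]] + c_ratio_state(st, f, pick) * rel_new)
        )
      }
    }
  }
  list(order = selected, scores = step_scores, n_pair_stats = st$n_pair_stats)
}

validate_discrete_features <- function(x) {
  for (nm in names(x)) {
    col <- x[[nm]]
    if (is.numeric(col) && any(col != round(col)))
      stop("feature '", nm, "' has non-integer values; discretize it first ",
           "(see discretize())", call. = FALSE)
  }
  invisible(x)
}

#' Greedy information-theoretic feature selection
#'
#' Ranks features of a discrete (or discretized) classification table by
#' greedy forward search under one of eight information-theoretic criteria.
#' The default criterion, \code{"ndcrfs"}, scores a candidate \eqn{f_k} as
#' \deqn{J(f_k) = I(f_k;C) - \max_{s \in S} CU(s, f_k)\,
#'   (I(f_k; s \mid C) - I(s; C)),}
#' where \eqn{CU(s,f_k) = 2/(H(s\mid C)+H(f_k\mid C))} is an information gain
#' factor that normalises the conditional interaction penalty. The first
#' selected feature always maximises the relevance \eqn{I(f;C)}; ties break
#' to the lowest column index.
#'
#' @param x A formula (\code{class ~ .}), a data frame / matrix of discrete
#'   features, or a dataset returned by \code{\link{read_dataset}}.
#' @param ... Passed on to methods.
#' @return An object of class \code{feature_ranking}: the selection
#'   \code{order} (feature names), the criterion \code{scores} at each step,
#'   the criterion name, and bookkeeping fields. See
#'   \code{\link{as.data.frame.feature_ranking}}.
#' @examples
#' d <- toy_duplicate_data()
#' select_features(class ~ ., d, criterion = "ndcrfs", k = 3)
#' @seealso \code{\link{score_candidates}}, \code{\link{list_criteria}},
#'   \code{\link{discretize}}, \code{\link{benchmark}}
#' @export
select_features <- function(x, ...) UseMethod("select_features")

#' @rdname select_features
#' @param formula A model formula whose response is the class column, e.g.
#'   \code{class ~ .}.
#' @param data Data frame holding the features and the class column.
#' @export
select_features.formula <- function(formula, data, ...) {
  x <- formula  # first-arg name fixed by the generic
  mf <- stats::model.frame(x, data = data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  feats <- mf[, -1L, drop = FALSE]
  out <- select_features.default(feats, y, ...)
  out$call <- match.call()
  out
}

#' @rdname select_features
#' @export
select_features.fs_dataset <- function(x, ...) {
  if (any(x$kinds == "continuous"))
    stop("dataset has continuous columns; discretize it first ",
         "(see discretize())", call. = FALSE)
  d <- x$data
  out <- select_features.default(d[setdiff(names(d), x$class_column)],
                                 d[[x$class_column]], ...)
  out$call <- match.call()
  out
}

#' @rdname select_features
#' @param y Class column (required for the default method).
#' @param criterion One of \code{list_criteria()}; default \code{"ndcrfs"}.
#' @param k Number of features to select; \code{NULL} (default) ranks all
#'   features.
#' @param beta Redundancy coefficient in \code{[0, 1]} for \code{dwur}.
#' @export
select_features.default <- function(x, y, criterion = "ndcrfs", k = NULL,
                                    beta = 0.5, ...) {
  criterion <- match_criterion(criterion)
  x <- as.data.frame(x)
  if (anyNA(x) || anyNA(y))
    stop("missing values present; drop incomplete rows first ",
         "(read_dataset() does this at load time)", call. = FALSE)
  validate_discrete_features(x)
  st <- new_selection_state(x, y, beta)
  if (is.null(k)) k <- st$p
  res <- greedy_rank(st, criterion, k)
  structure(list(
    order = st$feature_names[res$order],
    scores = unname(res$scores),
    criterion = criterion,
    k_requested = as.integer(min(k, st$p)),
    n_samples = st$n,
    n_features = st$p,
    beta = if (criterion == "dwur") beta else NULL,
    n_pair_stats = res$n_pair_stats,
    call = match.call()
  ), class = "feature_ranking")
}

#' Rank every feature of a dataset
#'
#' Convenience wrapper equal to \code{select_features} with \code{k} set to
#' the number of features, producing a full ranking (a permutation of all
#' feature names).
#'
#' @inheritParams select_features.default
#' @param ... Passed to \code{\link{select_features}}.
#' @return A \code{feature_ranking} covering all features.
#' @export
rank_all <- function(x, ...) select_features(x, ..., k = NULL)

#' @export
print.feature_ranking <- function(x, ...) {
  cat("Greedy feature ranking (criterion: ", x$criterion, ")\n", sep = "")
  cat("  ", x$n_samples, " samples, ", x$n_features, " features, ",
      length(x$order), " selected\n", sep = "")
  df <- as.data.frame(x)
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ... ", nrow(df) - 10L, " more rows\n", sep = "")
  invisible(x)
}

#' @export
summary.feature_ranking <- function(object, ...) {
  print(object)
  cat("Pairwise statistic evaluations:", object$n_pair_stats, "\n")
  if (!is.null(object$beta)) cat("beta:", object$beta, "\n")
  invisible(object)
}

#' Coerce a feature ranking to a data frame
#'
#' @param x A \code{feature_ranking}.
#' @param ... Unused.
#' @return Data frame with columns \code{rank}, \code{feature}, \code{score},
#'   \code{criterion} (the ranking TSV layout).
#' @export
as.data.frame.feature_ranking <- function(x, ...) {
  data.frame(rank = seq_along(x$order), feature = x$order, score = x$scores,
             criterion = x$criterion, stringsAsFactors = FALSE)
}

#' @export
plot.feature_ranking <- function(x, ...) {
  graphics::plot(seq_along(x$scores), x$scores, type = "b", pch = 19,
                 xlab = "selection step", ylab = "criterion score",
                 main = paste0("Greedy selection path (", x$criterion, ")"),
                 ...)
  invisible(x)
}

#' Write / read a feature ranking as TSV
#'
#' The TSV has columns \code{rank}, \code{feature}, \code{score},
#' \code{criterion}, one row per selected feature, preceded by comment lines
#' (\code{#}) recording how the ranking was produced.
#'
#' @param ranking A \code{feature_ranking}.
#' @param path Output file path.
#' @param metadata Optional named character vector of extra provenance lines.
#' @return \code{path}, invisibly.
#' @export
write_ranking <- function(ranking, path, metadata = NULL) {
  stopifnot(inherits(ranking, "feature_ranking"))
  hdr <- c(
    paste0("# criterion: ", ranking$criterion),
    paste0("# n_samples: ", ranking$n_samples),
    paste0("# n_features: ", ranking$n_features),
    paste0("# package: ndcrfs ",
           as.character(utils::packageVersion("ndcrfs"))),
    if (!is.null(metadata)) paste0("# ", names(metadata), ": ", metadata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(ranking), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking
#' @param path Path of a ranking TSV written by \code{write_ranking}.
#' @return For \code{read_ranking}: the ranking data frame.
#' @export
read_ranking <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
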