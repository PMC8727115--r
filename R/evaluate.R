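# Benchmarking harness: Jaccard comparison of selected subsets, stratified
# k-fold cross-validated accuracy over nested subset sizes, wins/ties/losses
# summaries, and a one-call benchmark report across criteria.

#' Jaccard index of two feature subsets
#'
#' \eqn{|S_1 \cap S_2| / |S_1 \cup S_2|}: 1 for identical subsets, 0 for
#' disjoint ones. For equal-size subsets of size K the attainable values lie
#' on the grid \eqn{i/(2K-i)}, \eqn{i = 0..K}.
#'
#' @param s1,s2 Feature identifier vectors (duplicates ignored); at least one
#'   must be non-empty.
#' @return Ratio in \code{[0, 1]}.
#' @examples
#' jaccard_index(1:10, 8:17)  # overlap 3 of size-10 sets: 3/17
#' @export
jaccard_index <- function(s1, s2) {
  u <- union(s1, s2)
  if (length(u) == 0L)
    stop("both subsets are empty", call. = FALSE)
  length(intersect(s1, s2)) / length(u)
}

#' Wins/ties/losses of a reference method against a competitor
#'
#' Compares paired per-dataset values (e.g. accuracies) at a fixed printed
#' precision and counts how often the reference is higher, equal, or lower.
#'
#' @param reference,competitor Equal-length numeric vectors.
#' @param digits Decimal precision at which values are compared (default 3,
#'   the usual table precision).
#' @return Named integer vector \code{c(wins, ties, losses)}.
#' @export
wins_ties_losses <- function(reference, competitor, digits = 3L) {
  if (length(reference) != length(competitor))
    stop("reference and competitor must have equal length", call. = FALSE)
  r <- round(reference, digits)
  s <- round(competitor, digits)
  c(wins = sum(r > s), ties = sum(r == s), losses = sum(r < s))
}

#' Column mean at table precision
#'
#' Arithmetic mean of per-dataset values rounded to the stated precision
#' (the "Average" row of a comparison table).
#'
#' @param values Non-empty numeric vector.
#' @param digits Rounding precision (default 3).
#' @return The rounded mean.
#' @export
summarize_table <- function(values, digits = 3L) {
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  round(mean(values), digits)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so fold sizes differ by at most one per class and the
# assignment is reproducible from the seed.
stratified_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed))
  assignment <- integer(length(y))
  for (lev in unique(y)) {
    idx <- which(y == lev)
    if (length(idx) < 2L)
      stop("class '", lev, "' has fewer than 2 samples; it would be absent ",
           "from a training fold", call. = FALSE)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

classifier_registry <- function() {
  list(
    knn = function(train_x, train_y, test_x, params) {
      k <- if (!is.null(params$knn_k)) params$knn_k else 3L
      as.character(class::knn(train_x, test_x, factor(train_y), k = k))
    },
    tree = function(train_x, train_y, test_x, params) {
      df <- data.frame(train_x)
      df$.class <- factor(train_y)
      fit <- rpart::rpart(.class ~ ., data = df, method = "class")
      as.character(predict(fit, data.frame(test_x), type = "class"))
    },
    svm = function(train_x, train_y, test_x, params) {
      fit <- e1071::svm(train_x, factor(train_y),
                        type = "C-classification",
                        kernel = if (!is.null(params$svm_kernel))
                          params$svm_kernel else "radial")
      as.character(predict(fit, test_x))
    }
  )
}

#' Stratified cross-validated accuracy over nested subset sizes
#'
#' For each subset size K, trains the classifier on the first K features of
#' the ranking within each training fold and averages test-fold accuracy.
#' Folds are stratified by class and reproducible from \code{seed}.
#'
#' @param data Data frame with the class column.
#' @param ranking A \code{feature_ranking} (or a character vector of feature
#'   names in rank order) derived from the same feature names.
#' @param class_column Name of the class column.
#' @param classifier \code{"knn"}, \code{"tree"}, or \code{"svm"}.
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed (default 42, recorded in the result).
#' @param k_values Subset sizes to evaluate; default \code{1:length(order)}.
#' @param params Optional classifier hyperparameters
#'   (\code{knn_k}, \code{svm_kernel}).
#' @param discretize_folds How continuous feature columns are discretized for
#'   the classifier: \code{"per_fold"} (default; schemes fitted on the
#'   training fold only and applied to the test fold, so no information leaks
#'   from test rows), \code{"once"} (fitted on the full data before CV, for
#'   strict mimicry of protocols that discretize up front), or \code{"none"}
#'   (classifiers consume the raw values).
#' @return Data frame with columns \code{k} and \code{accuracy} (percent),
#'   with the seed, classifier, and any per-fold discretization schemes
#'   stored as attributes.
#' @export
cross_validated_accuracy <- function(data, ranking, class_column = "class",
                                     classifier = c("knn", "tree", "svm"),
                                     folds = 5L, seed = 42L, k_values = NULL,
                                     params = list(),
                                     discretize_folds = c("per_fold", "once",
                                                          "none")) {
  classifier <- match.arg(classifier)
  discretize_folds <- match.arg(discretize_folds)
  order <- if (inherits(ranking, "feature_ranking")) ranking$order
           else as.character(ranking)
  if (!class_column %in% names(data))
    stop("class column '", class_column, "' not found", call. = FALSE)
  missing_feats <- setdiff(order, names(data))
  if (length(missing_feats))
    stop("ranking names features absent from the data: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  if (is.null(k_values)) k_values <- seq_along(order)
  y <- data[[class_column]]
  fold_of <- stratified_folds(y, folds, seed)
  predict_fn <- classifier_registry()[[classifier]]

  is_cont <- vapply(data[order], function(col)
    is.numeric(col) && any(col != round(col)), logical(1))
  fold_schemes <- vector("list", folds)
  x_all <- as.matrix(data.matrix(data[order]))
  if (discretize_folds == "once" && any(is_cont)) {
    for (j in which(is_cont)) {
      sc <- discretize_fit(x_all[, j], y)
      x_all[, j] <- discretize_apply(sc, x_all[, j])
    }
  }

  fold_matrices <- lapply(seq_len(folds), function(fd) {
    test <- fold_of == fd
    train_x <- x_all[!test, , drop = FALSE]
    test_x <- x_all[test, , drop = FALSE]
    if (discretize_folds == "per_fold" && any(is_cont)) {
      schemes <- list()
      for (j in which(is_cont)) {
        sc <- discretize_fit(train_x[, j], y[!test])  # training rows only
        train_x[, j] <- discretize_apply(sc, train_x[, j])
        test_x[, j] <- discretize_apply(sc, test_x[, j])
        schemes[[order[j]]] <- sc
      }
      fold_schemes[[fd]] <<- schemes
    }
    list(train_x = train_x, test_x = test_x, test = test)
  })

  acc <- vapply(k_values, function(K) {
    cols <- seq_len(K)
    fold_acc <- vapply(seq_len(folds), function(fd) {
      fm <- fold_matrices[[fd]]
      if (!any(fm$test)) return(NA_real_)
      pred <- predict_fn(fm$train_x[, cols, drop = FALSE], y[!fm$test],
                         fm$test_x[, cols, drop = FALSE], params)
      mean(pred == as.character(y[fm$test])) * 100
    }, numeric(1))
    mean(fold_acc, na.rm = TRUE)
  }, numeric(1))

  out <- data.frame(k = k_values, accuracy = acc)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "classifier") <- classifier
  attr(out, "folds") <- as.integer(folds)
  attr(out, "fold_schemes") <- fold_schemes
  out
}

#' Benchmark several criteria on one dataset
#'
#' Ranks the features once per criterion, evaluates the cross-validated
#' accuracy curve of each ranking, and summarises: best accuracy and the
#' smallest subset size attaining it, the Jaccard matrix between the
#' top-\code{k_max} subsets, and per-K wins/ties/losses of the reference
#' criterion against each competitor.
#'
#' @param data Data frame of discrete features plus the class column.
#' @param class_column Name of the class column.
#' @param criteria Criteria to compare (default: all eight).
#' @param k_max Largest subset size (default: all features).
#' @param reference Criterion used for wins/ties/losses (default
#'   \code{"ndcrfs"}; must be among \code{criteria}).
#' @inheritParams cross_validated_accuracy
#' @param beta DWUR redundancy coefficient.
#' @return An object of class \code{benchmark_report}: accuracy curves
#'   (matrix K x criteria, percent), best accuracy and its K per criterion,
#'   Jaccard matrix, wins/ties/losses, rankings, classifier, folds and seed.
#' @export
benchmark <- function(data, class_column = "class",
                      criteria = list_criteria(), k_max = NULL,
                      classifier = c("knn", "tree", "svm"), folds = 5L,
                      seed = 42L, reference = "ndcrfs", beta = 0.5,
                      params = list()) {
  classifier <- match.arg(classifier)
  criteria <- vapply(criteria, match_criterion, character(1))
  if (!reference %in% criteria)
    stop("reference criterion must be among the benchmarked criteria",
         call. = FALSE)
  feats <- setdiff(names(data), class_column)
  if (is.null(k_max)) k_max <- length(feats)
  k_max <- min(k_max, length(feats))

  rankings <- lapply(criteria, function(cr)
    select_features.default(data[feats], data[[class_column]],
                            criterion = cr, k = k_max, beta = beta))
  names(rankings) <- criteria

  curves <- sapply(criteria, function(cr)
    cross_validated_accuracy(data, rankings[[cr]], class_column, classifier,
                             folds, seed, k_values = seq_len(k_max),
                             params = params)$accuracy)
  rownames(curves) <- seq_len(k_max)

  best <- apply(curves, 2L, max)
  best_k <- apply(curves, 2L, which.max)  # smallest argmax

  jac <- outer(criteria, criteria, Vectorize(function(a, b)
    jaccard_index(rankings[[a]]$order, rankings[[b]]$order)))
  dimnames(jac) <- list(criteria, criteria)

  wtl <- sapply(setdiff(criteria, reference), function(cr)
    wins_ties_losses(curves[, reference], curves[, cr]))

  structure(list(
    curves = curves, best_accuracy = best, best_k = best_k,
    jaccard = jac, wins_ties_losses = wtl, rankings = rankings,
    classifier = classifier, folds = as.integer(folds),
    seed = as.integer(seed), reference = reference
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark report (", x$classifier, ", ", x$folds, "-fold CV, seed ",
      x$seed, ")\n", sep = "")
  tab <- data.frame(criterion = colnames(x$curves),
                    best_accuracy = round(x$best_accuracy, 3),
                    at_k = x$best_k)
  print(tab, row.names = FALSE)
  cat("Jaccard matrix at final K:\n")
  print(round(x$jaccard, 3))
  cat("Per-K wins/ties/losses of ", x$reference, " vs competitors:\n",
      sep = "")
  print(x$wins_ties_losses)
  invisible(x)
}

#' Write a benchmark report to JSON and Markdown
#'
#' The JSON file carries the full machine-readable report (curves, best
#' accuracies, Jaccard matrix, wins/ties/losses, seed, classifier); the
#' optional Markdown file holds a human-readable summary table.
#'
#' @param report A \code{benchmark_report}.
#' @param json_path Output JSON path.
#' @param markdown_path Optional Markdown path.
#' @param csv_path Optional CSV of the accuracy curves (columns \code{k},
#'   \code{criterion}, \code{accuracy_percent}).
#' @return \code{json_path}, invisibly.
#' @export
write_benchmark <- function(report, json_path, markdown_path = NULL,
                            csv_path = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  payload <- list(
    classifier = report$classifier, folds = report$folds,
    seed = report$seed, reference = report$reference,
    best_accuracy = as.list(report$best_accuracy),
    best_k = as.list(report$best_k),
    curves = as.data.frame(report$curves),
    jaccard = report$jaccard,
    wins_ties_losses = report$wins_ties_losses,
    package_version = as.character(utils::packageVersion("ndcrfs"))
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(markdown_path)) {
    lines <- c(
      paste0("# Benchmark (", report$classifier, ", ", report$folds,
             "-fold CV, seed ", report$seed, ")"),
      "",
      "| criterion | best accuracy (%) | at K |",
      "|---|---|---|",
      sprintf("| %s | %.3f | %d |", colnames(report$curves),
              report$best_accuracy, report$best_k))
    writeLines(lines, markdown_path)
  }
  if (!is.null(csv_path)) {
    long <- expand.grid(k = as.integer(rownames(report$curves)),
                        criterion = colnames(report$curves),
                        stringsAsFactors = FALSE)
    long$accuracy_percent <- as.vector(report$curves)
    utils::write.csv(long, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}
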