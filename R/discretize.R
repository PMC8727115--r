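# Class-aware discretization of continuous columns so the plug-in
# information estimators apply. The default method is class-attribute
# interdependence maximisation (CAIM): starting from a single interval,
# boundaries are added greedily from the midpoints between sorted distinct
# values, each time picking the boundary that maximises
#   caim = (1/r) * sum_over_intervals (max class count)^2 / interval total,
# and stopping once the criterion no longer improves and the number of
# intervals has reached the number of classes. Equal-width and
# equal-frequency binning are provided as explicitly labelled fallbacks.

caim_value <- function(cuts, values, labels_int, n_classes) {
  bins <- findInterval(values, cuts) + 1L
  r <- length(cuts) + 1L
  tot <- 0
  for (b in seq_len(r)) {
    inb <- labels_int[bins == b]
    if (length(inb) == 0L) next
    cnt <- tabulate(inb, nbins = n_classes)
    tot <- tot + max(cnt)^2 / length(inb)
  }
  tot / r
}

fit_caim <- function(values, labels) {
  labels_int <- as_codes(labels)
  n_classes <- max(labels_int)
  distinct <- sort(unique(values))
  if (length(distinct) < 2L) {
    return(list(cut_points = numeric(0), bins = 1L))
  }
  if (length(values) < n_classes)
    stop("fewer samples than classes; cannot fit CAIM", call. = FALSE)
  midpoints <- (distinct[-1L] + distinct[-length(distinct)]) / 2
  cuts <- numeric(0)
  best <- caim_value(cuts, values, labels_int, n_classes)
  repeat {
    remaining <- setdiff(midpoints, cuts)
    if (length(remaining) == 0L) break
    cand_vals <- vapply(remaining, function(m)
      caim_value(sort(c(cuts, m)), values, labels_int, n_classes), numeric(1))
    i <- which.max(cand_vals)  # deterministic: first max, midpoints ascending
    if (cand_vals[i] > best || length(cuts) + 1L < n_classes) {
      cuts <- sort(c(cuts, remaining[i]))
      best <- cand_vals[i]
    } else break
  }
  list(cut_points = cuts, bins = length(cuts) + 1L)
}

fit_equal_width <- function(values, bins) {
  rng <- range(values)
  if (diff(rng) == 0) return(list(cut_points = numeric(0), bins = 1L))
  cuts <- seq(rng[1L], rng[2L], length.out = bins + 1L)[-c(1L, bins + 1L)]
  list(cut_points = cuts, bins = length(cuts) + 1L)
}

fit_equal_frequency <- function(values, bins) {
  qs <- stats::quantile(values, probs = seq_len(bins - 1L) / bins,
                        names = FALSE, type = 7)
  cuts <- sort(unique(qs))
  cuts <- cuts[cuts > min(values) & cuts < max(values)]
  list(cut_points = cuts, bins = length(cuts) + 1L)
}

#' Fit a discretization scheme to one continuous column
#'
#' @param values Numeric vector (the continuous column).
#' @param labels Class column of equal length (required for \code{"caim"}).
#' @param method \code{"caim"} (class-aware, default), \code{"equal_width"},
#'   or \code{"equal_frequency"}.
#' @param bins Bin count for the two unsupervised fallbacks (default 5;
#'   ignored by CAIM, which chooses its own interval count).
#' @return An object of class \code{discretization_scheme} with fields
#'   \code{method}, \code{cut_points} (strictly increasing boundaries) and
#'   \code{bins} (\code{= length(cut_points) + 1}).
#' @examples
#' sc <- discretize_fit(c(1, 2, 3, 4), labels = c(0, 0, 1, 1))
#' sc$cut_points  # single cut between 2 and 3
#' @export
discretize_fit <- function(values, labels = NULL,
                           method = c("caim", "equal_width",
                                      "equal_frequency"),
                           bins = 5L) {
  method <- match.arg(method)
  if (!is.numeric(values) || length(values) == 0L)
    stop("values must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(values)) stop("values contain missing entries", call. = FALSE)
  fit <- switch(method,
    caim = {
      if (is.null(labels)) stop("CAIM requires class labels", call. = FALSE)
      check_equal_length(values, labels)
      fit_caim(values, labels)
    },
    equal_width = fit_equal_width(values, bins),
    equal_frequency = fit_equal_frequency(values, bins)
  )
  structure(list(method = method, cut_points = fit$cut_points,
                 bins = fit$bins),
            class = "discretization_scheme")
}

#' Apply a fitted discretization scheme
#'
#' Codes each value as the number of cut points strictly below it, so codes
#' lie in \code{0:(bins - 1)} and larger values never receive smaller codes.
#' Out-of-range values clamp to the edge bins.
#'
#' @param scheme A \code{discretization_scheme}.
#' @param values Numeric vector to code.
#' @return Integer vector of category codes in \code{[0, bins)}.
#' @export
discretize_apply <- function(scheme, values) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  findInterval(values, scheme$cut_points)
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("Discretization scheme (", x$method, "): ", x$bins, " bin(s)\n",
      sep = "")
  if (length(x$cut_points))
    cat("  cut points:", paste(signif(x$cut_points, 6), collapse = ", "),
        "\n")
  invisible(x)
}

#' Discretize every continuous column of a classification table
#'
#' Columns already discrete (factors, characters, logicals, or integer-valued
#' numerics with at most \code{discrete_threshold} distinct values) pass
#' through unchanged; the rest are fitted per column with
#' \code{\link{discretize_fit}} and recoded.
#'
#' @param data Data frame including the class column.
#' @param class_column Name of the class column (default \code{"class"}).
#' @inheritParams discretize_fit
#' @param discrete_threshold Maximum number of distinct integer values for a
#'   numeric column to count as already discrete (default 10).
#' @return List with \code{data} (the discretized data frame) and
#'   \code{schemes} (named list of fitted \code{discretization_scheme}s, one
#'   per converted column).
#' @export
discretize <- function(data, class_column = "class",
                       method = c("caim", "equal_width", "equal_frequency"),
                       bins = 5L, discrete_threshold = 10L) {
  method <- match.arg(method)
  if (!class_column %in% names(data))
    stop("class column '", class_column, "' not found", call. = FALSE)
  labels <- data[[class_column]]
  schemes <- list()
  for (nm in setdiff(names(data), class_column)) {
    col <- data[[nm]]
    if (!is.numeric(col)) next
    if (all(col == round(col)) &&
        length(unique(col)) <= discrete_threshold) next
    sc <- discretize_fit(col, labels, method = method, bins = bins)
    schemes[[nm]] <- sc
    data[[nm]] <- discretize_apply(sc, col)
  }
  list(data = data, schemes = schemes)
}

#' Serialize discretization schemes to JSON
#'
#' Writes a JSON object mapping column name to
#' \code{\{method, cut_points, bins\}}; \code{read_schemes} restores it.
#'
#' @param schemes Named list of \code{discretization_scheme}s (as returned in
#'   \code{discretize()$schemes}).
#' @param path JSON file path.
#' @return \code{path} invisibly; for \code{read_schemes}, the named list of
#'   schemes.
#' @export
write_schemes <- function(schemes, path) {
  payload <- lapply(schemes, function(s)
    list(method = s$method, cut_points = s$cut_points, bins = s$bins))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schemes
#' @export
read_schemes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(s)
    structure(list(method = s$method,
                   cut_points = as.numeric(s$cut_points),
                   bins = as.integer(s$bins)),
              class = "discretization_scheme"))
}
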