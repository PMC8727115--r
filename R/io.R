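# File I/O for classification tables. CSV: comma-separated, header row, one
# sample per row, UTF-8, `NA` or an empty cell marking a missing value.
# ARFF files are read through foreign::read.arff, with declared nominal
# attributes marked discrete. Rows with any missing cell are deleted at load
# time, with the count reported.

infer_kinds <- function(data, class_column, discrete_threshold = 10L) {
  vapply(names(data), function(nm) {
    col <- data[[nm]]
    if (nm == class_column) return("discrete")
    if (!is.numeric(col)) return("discrete")
    if (all(col == round(col)) &&
        length(unique(col)) <= discrete_threshold) "discrete"
    else "continuous"
  }, character(1))
}

#' Load a classification table from CSV or ARFF
#'
#' Drops incomplete rows (reporting the count), checks that the class column
#' exists and is not constant, and infers per-column kinds: non-numeric
#' columns and integer-valued numerics with at most \code{discrete_threshold}
#' distinct values count as discrete, everything else as continuous (and
#' must be discretized before selection).
#'
#' @param path Path to a \code{.csv} or \code{.arff} file.
#' @param format \code{"auto"} (by extension), \code{"csv"}, or
#'   \code{"arff"}.
#' @param class_column Name of the class column (default \code{"class"}).
#' @param discrete_threshold Distinct-value cutoff for treating an
#'   integer-valued numeric column as discrete (default 10).
#' @param kinds Optional named character vector overriding inferred kinds
#'   (\code{"discrete"} or \code{"continuous"}).
#' @return An object of class \code{fs_dataset}: \code{data} (the cleaned
#'   data frame), \code{class_column}, \code{kinds}, and \code{provenance}
#'   (source path and number of dropped rows).
#' @export
read_dataset <- function(path, format = c("auto", "csv", "arff"),
                         class_column = "class", discrete_threshold = 10L,
                         kinds = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.arff$", path, ignore.case = TRUE)) "arff"
              else "csv"
  }
  data <- switch(format,
    csv = utils::read.csv(path, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE),
    arff = foreign::read.arff(path)
  )
  if (!class_column %in% names(data))
    stop("class column '", class_column, "' not found; available columns: ",
         paste(names(data), collapse = ", "), call. = FALSE)
  if (anyDuplicated(names(data)))
    stop("feature names are not unique", call. = FALSE)
  complete <- stats::complete.cases(data)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("read_dataset: dropped ", n_dropped, " incomplete row(s)")
    data <- data[complete, , drop = FALSE]
    rownames(data) <- NULL
  }
  if (nrow(data) == 0L)
    stop("no complete rows left after deletion", call. = FALSE)
  inferred <- infer_kinds(data, class_column, discrete_threshold)
  if (!is.null(kinds)) {
    bad <- setdiff(names(kinds), names(data))
    if (length(bad))
      stop("kind override for unknown column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    inferred[names(kinds)] <- kinds
  }
  structure(list(
    data = data, class_column = class_column, kinds = inferred,
    provenance = list(path = path, format = format, n_dropped = n_dropped)
  ), class = "fs_dataset")
}

#' @export
print.fs_dataset <- function(x, ...) {
  cat("Dataset: ", nrow(x$data), " samples, ",
      ncol(x$data) - 1L, " features + class ('", x$class_column, "')\n",
      sep = "")
  kinds <- x$kinds[names(x$kinds) != x$class_column]
  cat("  discrete ", sum(kinds == "discrete"), ", continuous ",
      sum(kinds == "continuous"), "; dropped rows: ",
      x$provenance$n_dropped, "\n", sep = "")
  invisible(x)
}

#' Write a classification table (and optional role sidecar) to CSV
#'
#' For a \code{planted_dataset} the feature-role metadata and design
#' parameters go to a JSON sidecar next to the CSV (never into the CSV
#' itself), so downstream selection cannot accidentally read the roles.
#'
#' @param x A data frame, \code{fs_dataset}, or \code{planted_dataset}.
#' @param path Output CSV path.
#' @param sidecar_path Path of the JSON sidecar for planted datasets
#'   (default: \code{path} with \code{.roles.json} appended).
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(x, path, sidecar_path = NULL) {
  if (inherits(x, "planted_dataset")) {
    utils::write.csv(x$data, path, row.names = FALSE)
    if (is.null(sidecar_path))
      sidecar_path <- paste0(sub("\\.csv$", "", path), ".roles.json")
    jsonlite::write_json(
      list(roles = x$roles, design = unclass(x$design), seed = x$seed,
           package_version =
             as.character(utils::packageVersion("ndcrfs"))),
      sidecar_path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "fs_dataset")) {
    utils::write.csv(x$data, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
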