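#' Feature matrix with mixed-type columns and explicit missingness
#'
#' The central container of the pipeline: one row per subject (or hospital
#' stay), one column per aggregated clinical variable.  Continuous variables
#' are numeric in their clinical units; categorical variables are factors.
#' Missing cells are `NA`; [missing_mask()] exposes the mask explicitly.
#'
#' @param data data.frame of variables (numeric or factor columns).
#' @param meta data.frame of per-variable metadata with columns `name`,
#'   `type` (`"continuous"` or `"categorical"`), `unit` (may be `NA`) and
#'   `levels` (pipe-separated level string for categoricals, `NA` otherwise).
#'   If omitted it is inferred from `data`.
#' @param subject_id optional vector of subject identifiers (stored as
#'   attribute, default `seq_len(nrow(data))`).
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(data, meta = NULL, subject_id = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(meta)) {
    meta <- data.frame(
      name = names(data),
      type = ifelse(vapply(data, is.numeric, logical(1)),
                    "continuous", "categorical"),
      unit = NA_character_,
      levels = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(identical(meta$name, names(data)),
            all(meta$type %in% c("continuous", "categorical")))
  for (j in which(meta$type == "categorical")) {
    lv <- meta$levels[j]
    if (!is.na(lv) && nzchar(lv)) {
      data[[j]] <- factor(as.character(data[[j]]),
                          levels = strsplit(lv, "|", fixed = TRUE)[[1]])
    } else {
      data[[j]] <- as.factor(data[[j]])
      meta$levels[j] <- paste(levels(data[[j]]), collapse = "|")
    }
  }
  structure(list(data = data, meta = meta,
                 subject_id = subject_id %||% seq_len(nrow(data))),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  mm <- missing_mask(x)
  cat(sprintf("<feature_matrix> %d subjects x %d variables (%d continuous, %d categorical), %.2f%% missing\n",
              nrow(x$data), ncol(x$data),
              sum(x$meta$type == "continuous"),
              sum(x$meta$type == "categorical"),
              100 * mean(mm)))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$data)

#' Missingness mask of a feature matrix
#'
#' @param fm a [feature_matrix()].
#' @return logical matrix, `TRUE` where the cell is missing.
#' @export
missing_mask <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  m <- vapply(fm$data, is.na, logical(nrow(fm$data)))
  if (nrow(fm$data) == 1L) m <- matrix(m, nrow = 1,
                                       dimnames = list(NULL, names(fm$data)))
  m
}

#' Subset a feature matrix by rows and/or variables
#' @param fm a [feature_matrix()].
#' @param rows integer/logical row index (default all).
#' @param vars character vector of variable names (default all).
#' @return a [feature_matrix()].
#' @export
fm_subset <- function(fm, rows = NULL, vars = NULL) {
  stopifnot(inherits(fm, "feature_matrix"))
  rows <- rows %||% seq_len(nrow(fm$data))
  vars <- vars %||% fm$meta$name
  stopifnot(all(vars %in% fm$meta$name))
  j <- match(vars, fm$meta$name)
  feature_matrix(fm$data[rows, j, drop = FALSE],
                 fm$meta[j, , drop = FALSE],
                 subject_id = fm$subject_id[rows])
}

#' Write / read a feature matrix as CSV plus a metadata sidecar
#'
#' The values go to `<path>` and the column metadata (variable name, type,
#' unit, levels) to `<path>` with a `.meta.csv` suffix replacing `.csv`.
#'
#' @param fm a [feature_matrix()].
#' @param path CSV file path.
#' @return `path`, invisibly (writer) or a [feature_matrix()] (reader).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- data.frame(subject_id = fm$subject_id, fm$data,
                    check.names = FALSE)
  data.table::fwrite(out, path, na = "")
  data.table::fwrite(fm$meta, meta_path(path), na = "")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dat <- data.table::fread(path, na.strings = "", data.table = FALSE,
                           colClasses = list(character = "subject_id"))
  meta <- data.table::fread(meta_path(path), na.strings = "",
                            data.table = FALSE)
  sid <- dat$subject_id
  dat$subject_id <- NULL
  for (j in which(meta$type == "continuous")) dat[[j]] <- as.numeric(dat[[j]])
  feature_matrix(dat, meta, subject_id = sid)
}

meta_path <- function(path) sub("\\.csv$", ".meta.csv", path)
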