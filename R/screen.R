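#' Assemble a dose-response table
#'
#' Normalises a long-format data frame of replicate-level viability
#' measurements into the canonical screen table used throughout the package.
#' Accepts either a `concentration_uM` column (converted to
#' `x = log10(concentration)`) or a ready-made `x` column, and either
#' `viability_pct` or `response`.
#'
#' @param df Data frame with columns `cell_line`, `drug`,
#'   `concentration_uM` (or `x`), `replicate`, `viability_pct` (or
#'   `response`).
#' @return A data frame of class `"dose_response_table"` with columns
#'   `cell_line`, `drug`, `concentration_uM`, `x`, `replicate`, `response`,
#'   row order preserved.
#' @export
dose_response_table <- function(df) {
  df <- as.data.frame(df)
  if (!"response" %in% names(df) && "viability_pct" %in% names(df))
    df$response <- df$viability_pct
  if (!"x" %in% names(df)) {
    if (!"concentration_uM" %in% names(df))
      stop("need a 'concentration_uM' or 'x' column", call. = FALSE)
    conc <- df$concentration_uM
    if (!is.numeric(conc) || any(!is.finite(conc)))
      stop("concentration_uM must be finite numeric", call. = FALSE)
    bad <- which(conc <= 0)
    if (length(bad))
      stop("non-positive concentration (log10 undefined) in rows: ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    df$x <- log10(conc)
  }
  if (!"concentration_uM" %in% names(df)) df$concentration_uM <- 10^df$x
  need <- c("cell_line", "drug", "replicate", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$response) || any(!is.finite(df$response)))
    stop("response must be finite numeric", call. = FALSE)
  if (any(!is.finite(df$replicate)) || any(df$replicate < 1))
    stop("replicate indices must be positive integers starting at 1",
         call. = FALSE)
  out <- df[, c("cell_line", "drug", "concentration_uM", "x",
                "replicate", "response")]
  out$cell_line <- as.character(out$cell_line)
  out$drug <- as.character(out$drug)
  class(out) <- c("dose_response_table", "data.frame")
  out
}

delim_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") "," else "\t"
}

#' Read a screen table from delimited text
#'
#' Reads a long-format screen export with header columns `cell_line`,
#' `drug`, `concentration_uM`, `replicate`, `viability_pct` (CSV or TSV,
#' chosen by file extension) and validates it.  Concentrations are converted
#' to log10 uM in the returned table; row order is preserved.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A [dose_response_table()].
#' @export
read_screen <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  need <- c("cell_line", "drug", "concentration_uM", "replicate",
            "viability_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("screen file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("concentration_uM", "replicate", "viability_pct")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric values in column '", col, "' near line(s): ",
           paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
    }
  }
  bad <- which(df$concentration_uM <= 0)
  if (length(bad))
    stop("non-positive concentration_uM (log10 undefined) at line(s): ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "), call. = FALSE)
  dose_response_table(df)
}

#' Write a screen table to delimited text
#'
#' Inverse of [read_screen()]: writes the canonical columns `cell_line`,
#' `drug`, `concentration_uM`, `replicate`, `viability_pct`.
#'
#' @param screen A [dose_response_table()].
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_screen <- function(screen, path) {
  out <- data.frame(cell_line = screen$cell_line, drug = screen$drug,
                    concentration_uM = screen$concentration_uM,
                    replicate = screen$replicate,
                    viability_pct = screen$response)
  utils::write.table(out, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-cell-line feature vector
#'
#' Reads a delimited table keyed by cell line and returns a named vector of
#' one feature (expression intensity, mutation indicator, ...).
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @param key_column Name of the cell-line key column (default
#'   `"cell_line"`).
#' @param value_column Feature column; defaults to the first non-key column.
#' @return Named vector (numeric or character) keyed by cell line.
#' @export
read_features <- function(path, key_column = "cell_line",
                          value_column = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE)
  if (!key_column %in% names(df))
    stop("feature file lacks key column '", key_column, "'", call. = FALSE)
  keys <- as.character(df[[key_column]])
  if (anyDuplicated(keys))
    stop("duplicate cell-line keys in feature file: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  value_column <- value_column %||% setdiff(names(df), key_column)[1]
  if (is.na(value_column) || !value_column %in% names(df))
    stop("no feature value column found", call. = FALSE)
  setNames(df[[value_column]], keys)
}

#' Split cell lines at the median of a feature
#'
#' Labels each cell line `"plus"` (over-expressed) when its value is
#' strictly greater than the panel median, and `"minus"` otherwise; ties at
#' the median go to `"minus"`.
#'
#' @param values Named numeric vector keyed by cell line.
#' @return Named character vector of `"plus"`/`"minus"` labels — a group
#'   assignment usable by [llr_statistic()] and [omnibus_perm_test()].
#' @export
median_split <- function(values) {
  if (is.null(names(values)) || !is.numeric(values))
    stop("values must be a named numeric vector", call. = FALSE)
  med <- median(values, na.rm = TRUE)
  setNames(ifelse(values > med, "plus", "minus"), names(values))
}

subset_drug <- function(screen, drug = NULL) {
  drugs <- unique(screen$drug)
  if (is.null(drug)) {
    if (length(drugs) > 1L)
      stop("screen contains several drugs; pass `drug`", call. = FALSE)
    return(screen)
  }
  if (!drug %in% drugs)
    stop("drug '", drug, "' not present in screen", call. = FALSE)
  screen[screen$drug == drug, , drop = FALSE]
}
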