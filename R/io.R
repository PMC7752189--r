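#' Read and write the package's tabular artifacts
#'
#' All tabular inputs and outputs are plain CSV (UTF-8, header row, one
#' record per line, empty field for missing). The readers validate the
#' schema and coerce item columns to integer.
#'
#' @param path file path.
#' @name sdm_io
NULL

#' @rdname sdm_io
#' @export
read_patient_ratings <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("physician_id", "patient_id")
  if (!all(need %in% names(tab))) {
    stop("patient-rating table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cols <- grep("^item_", names(tab), value = TRUE)
  if (length(cols) == 0) stop("patient-rating table has no item_* columns")
  tab[cols] <- lapply(tab[cols], as.integer)
  tab
}

#' @rdname sdm_io
#' @export
read_observer_ratings <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("physician_id", "consultation_id", "rater_id", "instrument")
  if (!all(need %in% names(tab))) {
    stop("observer-rating table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  cols <- grep("^item_", names(tab), value = TRUE)
  if (length(cols) == 0) stop("observer-rating table has no item_* columns")
  tab[cols] <- lapply(tab[cols], as.integer)
  tab
}

#' @rdname sdm_io
#' @param x table to write.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
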