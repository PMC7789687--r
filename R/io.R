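# Delimited-text I/O. The file contract: CSV with a header row, one row per
# participant per wave, missing cells written as empty fields (the only
# missingness sentinel -- ordinal code 0 is a legal response and is never
# overloaded). Factor columns are restored from the canonical level registry.

#' Write a cohort table to CSV
#'
#' @param table a `cohort_table` (long) or wide data.frame.
#' @param path output file path.
#' @param params optional [generator_params()] written alongside as
#'   `<path>.params.json` so the cohort is reproducible from its sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path, params = NULL) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  if (!is.null(params)) {
    pj <- unclass(params)
    jsonlite::write_json(pj, paste0(path, ".params.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Empty fields become `NA`; factor columns (`smoking`, `sleep_cat`, the
#' demographics) are restored with their canonical level order.
#'
#' @param path CSV written by [write_cohort()].
#' @return a `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (v in names(cohort_factor_levels()))
    if (v %in% names(d))
      d[[v]] <- factor(d[[v]], levels = cohort_factor_levels()[[v]])
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Serialize / restore a mask record
#'
#' JSON round trip so masking and evaluation can run in separate processes.
#'
#' @param mask_record a `mask_record` from [mask_wave_item()].
#' @param path JSON file path.
#' @return `write_mask_record`: `path`, invisibly. `read_mask_record`: the
#'   restored `mask_record`.
#' @export
write_mask_record <- function(mask_record, path) {
  stopifnot(inherits(mask_record, "mask_record"))
  jsonlite::write_json(unclass(mask_record), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mask_record
#' @export
read_mask_record <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- list(variable = x$variable, wave = x$wave,
              participant_id = as.character(x$participant_id),
              truth = x$truth)
  structure(rec, class = "mask_record")
}
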