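#' Convert a wide cohort table to long format
#'
#' Wide input has one row per participant, time-varying variables carrying a
#' `_W1` / `_W2` suffix, and time-constant variables unsuffixed. Long output
#' has exactly two rows per participant, one per wave, enabling cross-wave
#' information sharing inside a single imputation model.
#'
#' Column order is canonical: `participant_id`, `wave`, constants in their
#' wide order, then time-varying variables in their wide order; [to_wide()]
#' uses the matching canonical wide order, so the two functions round-trip
#' bit-exactly.
#'
#' @param wide data.frame with a `participant_id` column.
#' @return long `data.frame` of class `cohort_table`.
#' @export
to_long <- function(wide) {
  stopifnot("participant_id" %in% names(wide))
  if (anyDuplicated(wide$participant_id))
    stop("participant_id must be unique in a wide table")
  nm <- setdiff(names(wide), "participant_id")
  sufx <- sub(".*_(W[12])$", "\\1", nm)
  is_tv <- grepl("_W[12]$", nm)
  base <- unique(sub("_W[12]$", "", nm[is_tv]))
  for (b in base) for (w in WAVES)
    if (!paste0(b, "_", w) %in% nm)
      stop(sprintf("time-varying variable '%s' is missing wave %s", b, w))
  const <- nm[!is_tv]
  bad <- grepl("_W", const, fixed = TRUE)
  if (any(bad)) stop("unparseable wave suffix on: ", paste(const[bad], collapse = ", "))
  rows <- lapply(seq_along(WAVES), function(w) {
    d <- wide[c("participant_id", const)]
    d$wave <- WAVES[w]
    for (b in base) d[[b]] <- wide[[paste0(b, "_", WAVES[w])]]
    d[c("participant_id", "wave", const, base)]
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$wave), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Convert a long cohort table to wide format
#'
#' Inverse of [to_long()]: time-constant variables (identical at both waves)
#' stay single columns; all others become `var_W1`, `var_W2` pairs.
#'
#' @param long a long-format `data.frame` with `participant_id` and `wave`.
#' @return wide `data.frame`, one row per participant.
#' @export
to_wide <- function(long) {
  stopifnot(all(c("participant_id", "wave") %in% names(long)))
  check_two_waves(long)
  long <- long[order(long$participant_id, long$wave), , drop = FALSE]
  w1 <- long[long$wave == "W1", , drop = FALSE]
  w2 <- long[long$wave == "W2", , drop = FALSE]
  vars <- setdiff(names(long), c("participant_id", "wave"))
  is_const <- vapply(vars, function(v) identical(w1[[v]], w2[[v]]), logical(1))
  out <- data.frame(participant_id = w1$participant_id, stringsAsFactors = FALSE)
  for (v in vars[is_const]) out[[v]] <- w1[[v]]
  for (v in vars[!is_const]) {
    out[[paste0(v, "_W1")]] <- w1[[v]]
    out[[paste0(v, "_W2")]] <- w2[[v]]
  }
  rownames(out) <- NULL
  out
}

check_two_waves <- function(long) {
  if (anyDuplicated(long[c("participant_id", "wave")]))
    stop("(participant_id, wave) must be unique")
  tab <- table(long$participant_id)
  if (any(tab != 2) || !all(long$wave %in% WAVES))
    stop("every participant must appear at exactly waves W1 and W2")
  invisible(long)
}

#' Mask one variable at one wave, keeping held-out truth
#'
#' Sets every target-wave cell of `variable` to missing and records the
#' original values so evaluation can score imputations against truth and
#' [unmask()] can restore the input exactly. All other cells are untouched;
#' no rows are reordered or dropped.
#'
#' @param table long `cohort_table`.
#' @param variable column name to mask.
#' @param wave wave label (`"W1"` or `"W2"`).
#' @return list with `table` (masked copy) and `mask_record` (class
#'   `mask_record`: `variable`, `wave`, `participant_id`, `truth`).
#' @export
mask_wave_item <- function(table, variable, wave) {
  if (!variable %in% names(table)) stop("variable not found: ", variable)
  if (!wave %in% table$wave) stop("wave not found: ", wave)
  idx <- which(table$wave == wave)
  if (anyNA(table[[variable]][idx]))
    stop("variable already has missing values at the target wave")
  rec <- structure(list(variable = variable, wave = wave,
                        participant_id = table$participant_id[idx],
                        truth = table[[variable]][idx]),
                   class = "mask_record")
  table[[variable]][idx] <- NA
  list(table = table, mask_record = rec)
}

#' Restore masked values from a mask record
#'
#' @param table masked long table.
#' @param mask_record record produced by [mask_wave_item()].
#' @return table with the held-out truth written back.
#' @export
unmask <- function(table, mask_record) {
  stopifnot(inherits(mask_record, "mask_record"))
  idx <- which(table$wave == mask_record$wave)
  if (!identical(table$participant_id[idx], mask_record$participant_id))
    stop("mask record does not match this table")
  table[[mask_record$variable]][idx] <- mask_record$truth
  table
}

#' Exclude participants with a fully missing wave
#'
#' Participants for whom every one of `vars` is missing at some wave cannot
#' contribute cross-wave information and are removed before masking (the
#' analysis cohort excludes such respondents explicitly rather than silently).
#'
#' @param table long `cohort_table`.
#' @param vars variables defining "fully missing" (default: the 9 depression
#'   items).
#' @return list with `table` (filtered) and `excluded` (participant ids).
#' @export
exclude_empty_waves <- function(table, vars = PHQ_ITEMS) {
  vars <- intersect(vars, names(table))
  all_missing <- rowSums(!is.na(table[vars])) == 0
  bad <- unique(table$participant_id[all_missing])
  if (length(bad))
    message(sprintf("excluding %d participant(s) with a fully missing wave", length(bad)))
  keep <- !(table$participant_id %in% bad)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(table = out, excluded = bad)
}
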