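#' Read a long-form measurement table
#'
#' Comma-delimited text with a header row and columns `label`, `density`,
#' `replicate`, `rank`, `organ`, `value_cm`. Rows with an unknown organ
#' code, nonpositive density, rank below 1 or a negative/missing value are
#' rejected; all rejections are collected and reported together with their
#' row numbers.
#'
#' @param path CSV path.
#' @return Validated measurement table (data frame).
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "density", "replicate", "rank", "organ", "value_cm")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort_domain(sprintf("measurement table lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  raw$density <- suppressWarnings(as.numeric(raw$density))
  raw$rank <- suppressWarnings(as.integer(raw$rank))
  raw$value_cm <- suppressWarnings(as.numeric(raw$value_cm))
  problems <- character(0)
  flag <- function(bad, why) {
    if (any(bad)) problems <<- c(problems,
      sprintf("row %d: %s", which(bad) + 1L, why))  # +1 for the header line
  }
  flag(!(raw$organ %in% organ_codes()),
       sprintf("unknown organ code '%s'", raw$organ))
  flag(is.na(raw$density) | raw$density <= 0, "density must be positive")
  flag(is.na(raw$rank) | raw$rank < 1, "rank must be a positive integer")
  flag(is.na(raw$value_cm) | raw$value_cm < 0, "value_cm must be >= 0")
  if (length(problems)) {
    stop(errorCondition(
      paste0("invalid measurement record(s):\n  ", paste(problems, collapse = "\n  ")),
      class = c("maizecanopy_validation_error", "maizecanopy_error")))
  }
  raw[, need]
}

#' Write a measurement table
#'
#' Inverse of [read_measurements()]; write-then-read is the identity on
#' valid tables.
#'
#' @param table Measurement table data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  need <- c("label", "density", "replicate", "rank", "organ", "value_cm")
  stopifnot(all(need %in% names(table)))
  utils::write.csv(table[, need], path, row.names = FALSE)
  invisible(path)
}

#' Profile I/O in the measurement-table format
#'
#' A profile is stored as a single-replicate measurement table so the same
#' readers serve both kinds of file.
#'
#' @param profile A [base_profile].
#' @param path CSV path.
#' @param label Label column value.
#' @return `write_profile`: `path` invisibly; `read_profile`: a
#'   [base_profile].
#' @export
write_profile <- function(profile, path, label = "profile") {
  stopifnot(inherits(profile, "base_profile"))
  tab <- data.frame(label = label, density = profile$density, replicate = 1L,
                    rank = profile$data$rank, organ = profile$data$organ,
                    value_cm = profile$data$size_cm)
  write_measurements(tab, path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  tab <- read_measurements(path)
  dens <- unique(tab$density)
  if (length(dens) != 1) abort_domain("profile file must hold exactly one density")
  base_profile(data.frame(rank = tab$rank, organ = tab$organ, size_cm = tab$value_cm),
               density = dens)
}
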