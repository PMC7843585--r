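#' Organ dimension codes
#'
#' The six final-size organ dimensions modeled per phytomer, all in cm:
#' \describe{
#'   \item{LL}{lamina (leaf blade) length}
#'   \item{LW}{lamina maximum width}
#'   \item{SL}{sheath length}
#'   \item{SW}{sheath average width}
#'   \item{IL}{internode length}
#'   \item{ID}{internode diameter}
#' }
#'
#' @return Character vector of the six organ codes.
#' @export
organ_codes <- function() c("LL", "LW", "SL", "SW", "IL", "ID")

#' Modeled phytomer ranks
#'
#' Ranks are counted acropetally (1 = basal). Ranks 1-5 senesce early and
#' carry no modeled morphology; ranks 6-18 are modeled.
#'
#' @return Integer vector 6:18.
#' @export
modeled_ranks <- function() 6:18

# reference plant density, plants m^-2
REFERENCE_DENSITY <- 4.5

# field trial density treatments, plants m^-2
TRIAL_DENSITIES <- c(4.5, 6, 7.5, 9, 15)

check_organ <- function(organ) {
  organ <- as.character(organ)
  bad <- setdiff(unique(organ), organ_codes())
  if (length(bad)) {
    stop(errorCondition(
      sprintf("unknown organ code(s): %s", paste(bad, collapse = ", ")),
      class = c("maizecanopy_organ_error", "maizecanopy_error")
    ))
  }
  organ
}

check_rank <- function(rank) {
  rank <- as.integer(rank)
  if (any(is.na(rank)) || any(!(rank %in% modeled_ranks()))) {
    stop(errorCondition(
      sprintf("phytomer rank must be in %d-%d (got: %s)",
              min(modeled_ranks()), max(modeled_ranks()),
              paste(rank, collapse = ", ")),
      class = c("maizecanopy_rank_error", "maizecanopy_error")
    ))
  }
  rank
}

abort_domain <- function(msg) {
  stop(errorCondition(msg,
    class = c("maizecanopy_domain_error", "maizecanopy_error")))
}

abort_missing_entry <- function(msg) {
  stop(errorCondition(msg,
    class = c("maizecanopy_missing_entry_error", "maizecanopy_error")))
}
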