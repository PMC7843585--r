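#' Per-phytomer organ-size profile
#'
#' Holds the final size (cm) of each of the six organ dimensions for the
#' modeled phytomer ranks 6-18 at a given plant density. The profile at the
#' reference density (4.5 plants m^-2) is the base from which density
#' responses are applied.
#'
#' @param data Data frame with columns `rank`, `organ`, `size_cm`; must
#'   cover all 13 modeled ranks x 6 organs, sizes >= 0.
#' @param density Plant density of the profile, plants m^-2.
#' @param total_leaf_number Total number of initiated leaves (default 18).
#' @param senesced_ranks Basal ranks dropped before full expansion
#'   (default 1-5); they carry no modeled morphology.
#' @return An object of class `base_profile`.
#' @export
base_profile <- function(data, density = REFERENCE_DENSITY,
                         total_leaf_number = 18L, senesced_ranks = 1:5) {
  stopifnot(is.data.frame(data),
            all(c("rank", "organ", "size_cm") %in% names(data)))
  data$rank <- as.integer(data$rank)
  data$organ <- check_organ(data$organ)
  if (density <= 0) abort_domain("density must be positive")
  want <- expand.grid(rank = modeled_ranks(), organ = organ_codes(),
                      stringsAsFactors = FALSE)
  key <- paste(data$rank, data$organ)
  missing <- setdiff(paste(want$rank, want$organ), key)
  if (length(missing)) {
    abort_missing_entry(sprintf("profile missing %d (rank, organ) entr%s: %s",
                                length(missing),
                                if (length(missing) == 1) "y" else "ies",
                                paste(head(missing, 8), collapse = "; ")))
  }
  if (anyDuplicated(key)) abort_domain("duplicated (rank, organ) entries in profile")
  if (any(!is.finite(data$size_cm)) || any(data$size_cm < 0)) {
    abort_domain("profile sizes must be finite and >= 0")
  }
  if (total_leaf_number < max(modeled_ranks())) {
    abort_domain("total_leaf_number must be >= the highest modeled rank")
  }
  data <- data[order(data$rank, match(data$organ, organ_codes())),
               c("rank", "organ", "size_cm")]
  rownames(data) <- NULL
  structure(list(density = density, data = data,
                 total_leaf_number = as.integer(total_leaf_number),
                 senesced_ranks = as.integer(senesced_ranks)),
            class = "base_profile")
}

#' Look up organ sizes in a profile
#'
#' @param profile A [base_profile].
#' @param organ One organ code.
#' @param rank Ranks to extract (default all modeled ranks, ordered).
#' @return Numeric vector of sizes in cm, named by rank.
#' @export
profile_sizes <- function(profile, organ, rank = modeled_ranks()) {
  stopifnot(inherits(profile, "base_profile"))
  organ <- check_organ(organ)
  rank <- check_rank(rank)
  d <- profile$data[profile$data$organ == organ, ]
  stats::setNames(d$size_cm[match(rank, d$rank)], rank)
}

#' @export
print.base_profile <- function(x, ...) {
  cat(sprintf("Organ-size profile at %.2f plants/m2 (%d leaves, ranks %d-%d modeled)\n",
              x$density, x$total_leaf_number, min(x$data$rank), max(x$data$rank)))
  wide <- as.data.frame.base_profile(x)
  print(wide, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.base_profile <- function(x, ...) {
  wide <- stats::reshape(x$data, idvar = "rank", timevar = "organ",
                         direction = "wide")
  names(wide) <- sub("^size_cm\\.", "", names(wide))
  wide[order(wide$rank), c("rank", organ_codes())]
}
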