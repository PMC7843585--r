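#' Normalized root mean square error
#'
#' Agreement statistic between simulated and observed values:
#' NRMSE = 100 * sqrt(mean((sim - obs)^2)) / mean(obs), in percent.
#' The mean-square term sits under a square root, per the "root mean
#' square" semantics of the statistic.
#'
#' @param sim Simulated values.
#' @param obs Observed values; same length, nonzero mean.
#' @return NRMSE in percent (>= 0).
#' @examples
#' nrmse(c(3, 3, 3), c(1, 2, 3))  # 100 * sqrt(5/3) / 2 = 64.55
#' @export
nrmse <- function(sim, obs) {
  if (length(sim) != length(obs)) {
    stop(errorCondition("sim and obs must have equal length",
      class = c("maizecanopy_shape_error", "maizecanopy_error")))
  }
  if (!length(obs)) abort_domain("need at least one observation")
  m <- mean(obs)
  if (m == 0) {
    stop(errorCondition("observed mean is zero; NRMSE undefined",
      class = c("maizecanopy_degenerate_normalization_error", "maizecanopy_error")))
  }
  100 * sqrt(mean((sim - obs)^2)) / m
}

#' Quality class of an NRMSE value
#'
#' Simulation quality bands: excellent (NRMSE <= 10%), good (10-20%],
#' fair (20-30%], poor (> 30%). Band edges belong to the lower band.
#'
#' @param value NRMSE in percent, >= 0.
#' @return Factor level among excellent/good/fair/poor (vectorized).
#' @export
classify_nrmse <- function(value) {
  if (any(value < 0)) abort_domain("NRMSE cannot be negative")
  cut(value, breaks = c(-Inf, 10, 20, 30, Inf),
      labels = c("excellent", "good", "fair", "poor"), right = TRUE)
}

#' Validate a simulated profile against observed measurements
#'
#' Pairs simulated organ sizes with per-rank observed means (replicates
#' averaged first) at one density and computes NRMSE and its quality class
#' per organ. Derived quantities are validated too when their ingredients
#' are present: leaf area (LA, needs LL and LW) and leaf insertion height
#' (LIH, needs IL); otherwise they are skipped with a message.
#'
#' @param simulated A [base_profile] at the target density.
#' @param observed A measurement table (see [read_measurements()]).
#' @param density Density at which to compare, plants m^-2; defaults to
#'   the simulated profile's density.
#' @param shape_factor Blade shape factor for derived LA.
#' @return Data frame of class `validation_report` with columns
#'   `quantity`, `density`, `nrmse`, `n`, `mean_observed`, `quality`.
#' @export
validate_profiles <- function(simulated, observed, density = simulated$density,
                              shape_factor = 0.75) {
  stopifnot(inherits(simulated, "base_profile"), is.data.frame(observed))
  obs <- observed[observed$density == density & observed$rank %in% modeled_ranks(), ]
  if (!nrow(obs)) {
    stop(errorCondition(
      sprintf("no observations at density %.3g overlap the modeled ranks", density),
      class = c("maizecanopy_empty_comparison_error", "maizecanopy_error")))
  }
  means <- stats::aggregate(value_cm ~ rank + organ, data = obs, FUN = mean)
  rows <- list()
  obs_by_organ <- function(code) {
    d <- means[means$organ == code, ]
    stats::setNames(d$value_cm, d$rank)
  }
  compare <- function(quantity, sim_vec, obs_vec) {
    ranks <- intersect(names(sim_vec), names(obs_vec))
    if (!length(ranks)) return(NULL)
    v <- nrmse(unname(sim_vec[ranks]), unname(obs_vec[ranks]))
    data.frame(quantity = quantity, density = density, nrmse = v,
               n = length(ranks), mean_observed = mean(obs_vec[ranks]),
               quality = as.character(classify_nrmse(v)))
  }
  for (code in intersect(organ_codes(), unique(means$organ))) {
    rows[[code]] <- compare(code, profile_sizes(simulated, code), obs_by_organ(code))
  }
  oLL <- obs_by_organ("LL"); oLW <- obs_by_organ("LW"); oIL <- obs_by_organ("IL")
  la_ranks <- intersect(names(oLL), names(oLW))
  if (length(la_ranks)) {
    sim_la <- leaf_area(profile_sizes(simulated, "LL"), profile_sizes(simulated, "LW"), shape_factor)
    obs_la <- leaf_area(oLL[la_ranks], oLW[la_ranks], shape_factor)
    rows$LA <- compare("LA", sim_la, obs_la)
  } else message("LA validation skipped: LL and LW not both observed")
  if (length(oIL) == length(modeled_ranks())) {
    sim_lih <- leaf_insertion_heights(simulated)
    obs_lih <- cumsum(oIL[as.character(modeled_ranks())])
    rows$LIH <- compare("LIH", sim_lih, obs_lih)
  } else message("LIH validation skipped: IL not observed at every modeled rank")
  report <- do.call(rbind, rows)
  if (is.null(report)) {
    stop(errorCondition("no comparable quantities at this density",
      class = c("maizecanopy_empty_comparison_error", "maizecanopy_error")))
  }
  rownames(report) <- NULL
  class(report) <- c("validation_report", class(report))
  report
}

#' Write a validation report as delimited text
#'
#' Lays the report out like a results table: one row per quantity, one
#' NRMSE column per density.
#'
#' @param report One or more `validation_report` data frames (rbind-ed).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  wide <- stats::reshape(as.data.frame(report)[, c("quantity", "density", "nrmse")],
                         idvar = "quantity", timevar = "density", direction = "wide")
  names(wide) <- sub("^nrmse\\.", "PD", names(wide))
  ord <- match(wide$quantity, c(organ_codes(), "LA", "LIH"))
  utils::write.csv(wide[order(ord), ], path, row.names = FALSE)
  invisible(path)
}
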