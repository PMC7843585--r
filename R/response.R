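#' Density regressor
#'
#' Under the default `"increment"` convention the regressor is the density
#' increase above the reference (x = PD - 4.5); under `"absolute"` it is the
#' density itself.
#'
#' @param density Plant density, plants m^-2.
#' @param params A [response_params] object.
#' @return Numeric regressor value x.
#' @keywords internal
density_regressor <- function(density, params) {
  switch(params$regressor_mode,
         increment = density - params$reference_density,
         absolute = density)
}

#' Percent change of an organ size under increased plant density
#'
#' Evaluates the density-response equations for one organ dimension at one
#' or more phytomer ranks. Grouped phytomers (6-11 and 13-18) follow
#' Y = A*ln(x) + B*rank + C; the ear phytomer (rank 12) follows
#' Y = D*x + E, with Y the percent change relative to the reference-density
#' size. At the reference density exactly, the equations are bypassed and
#' 0 is returned (the log term is undefined at x = 0 under the increment
#' convention).
#'
#' Densities above the highest field treatment (15 plants m^-2) are
#' extrapolation; a warning is emitted.
#'
#' @param organ One organ code (see [organ_codes()]).
#' @param rank Phytomer rank(s), 6-18.
#' @param density Plant density, plants m^-2; must be >= the reference.
#' @param params A [response_params] object; default [default_params()].
#' @return Numeric vector of signed percent changes, one per rank.
#' @examples
#' relative_change("LL", 12, 15)       # 0.11*10.5 + 1.70 = 2.855
#' relative_change("LL", 8, 6)         # 2.99*log(1.5) + 0.12*8 + 0.32
#' relative_change("SW", 6:18, 4.5)    # all zero at the reference density
#' @export
relative_change <- function(organ, rank, density, params = default_params()) {
  stopifnot(inherits(params, "response_params"), length(density) == 1)
  organ <- check_organ(organ)
  stopifnot(length(organ) == 1)
  rank <- check_rank(rank)
  if (density < params$reference_density) {
    abort_domain(sprintf(
      "density %.3g below the reference %.3g; the response is defined for increased density only",
      density, params$reference_density))
  }
  if (density == params$reference_density) return(rep(0, length(rank)))
  if (density > max(TRIAL_DENSITIES)) {
    warning(sprintf("density %.3g plants/m2 is above the highest calibrated treatment (%.3g); extrapolating",
                    density, max(TRIAL_DENSITIES)), call. = FALSE)
  }
  x <- density_regressor(density, params)
  o <- params$organs[[organ]]
  y <- numeric(length(rank))
  is_ear <- rank == params$ear_rank
  y[is_ear] <- o$ear$D * x + o$ear$E
  grouped <- !is_ear
  if (any(grouped)) {
    if (x <= 0) {
      abort_domain("nonpositive density regressor with a grouped rank: the logarithmic term requires x > 0")
    }
    lower <- grouped & rank < params$ear_rank
    upper <- grouped & rank > params$ear_rank
    y[lower] <- o$lower$A * log(x) + o$lower$B * rank[lower] + o$lower$C
    y[upper] <- o$upper$A * log(x) + o$upper$B * rank[upper] + o$upper$C
  }
  y
}

#' Predict an organ-size profile at an elevated plant density
#'
#' Applies the percent-change response multiplicatively to every (rank,
#' organ) entry of a reference-density profile:
#' predicted = base * (1 + Y/100), floored at zero. At the reference
#' density the output equals the base profile exactly.
#'
#' @param base A complete [base_profile] at the reference density.
#' @param density Target plant density, plants m^-2.
#' @param params A [response_params]; default [default_params()].
#' @return A [base_profile] flagged with the target density.
#' @export
apply_response <- function(base, density, params = default_params()) {
  stopifnot(inherits(base, "base_profile"), inherits(params, "response_params"))
  if (base$density != params$reference_density) {
    abort_domain(sprintf("base profile density %.3g is not the reference density %.3g",
                         base$density, params$reference_density))
  }
  d <- base$data
  y <- numeric(nrow(d))
  for (code in organ_codes()) {
    sel <- d$organ == code
    y[sel] <- relative_change(code, d$rank[sel], density, params)
  }
  d$size_cm <- pmax(0, d$size_cm * (1 + y / 100))
  base_profile(d, density = density,
               total_leaf_number = base$total_leaf_number,
               senesced_ranks = base$senesced_ranks)
}
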