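#' Fit density-response coefficients by ordinary least squares
#'
#' Refits either the grouped model Y = A*ln(x) + B*rank + C or the
#' ear-phytomer model Y = D*x + E to observed percent changes. Fitting is
#' plain unweighted OLS (via [stats::lm()]); R^2 = 1 - SSE/SST.
#'
#' @param observations Data frame with columns `x` (density regressor),
#'   `rank` (phytomer rank; ignored by the ear model) and `y` (percent
#'   change).
#' @param model `"grouped"` or `"ear"`.
#' @return A `fit_result` list: `params` (a [group_params] or
#'   [ear_params]), `r_squared`, `n_points`, `residual_sse`, and `se`
#'   (coefficient standard errors, NA when the fit is saturated).
#' @examples
#' x <- rep(c(1.5, 3, 4.5, 10.5), each = 6)
#' rk <- rep(6:11, times = 4)
#' y <- 2.99 * log(x) + 0.12 * rk + 0.32
#' fit_group(data.frame(x = x, rank = rk, y = y), "grouped")$params
#' @export
fit_group <- function(observations, model = c("grouped", "ear")) {
  model <- match.arg(model)
  stopifnot(is.data.frame(observations), all(c("x", "y") %in% names(observations)))
  obs <- observations
  if (model == "grouped") {
    if (!"rank" %in% names(obs)) abort_domain("grouped model needs a rank column")
    if (any(obs$x <= 0)) {
      abort_domain("grouped model requires positive density regressor values (logarithm)")
    }
    if (nrow(obs) < 3 || length(unique(obs$x)) < 2 || length(unique(obs$rank)) < 2) {
      stop(errorCondition(
        "singular design: grouped fit needs >= 3 points spanning >= 2 regressor values and >= 2 ranks",
        class = c("maizecanopy_singular_design_error", "maizecanopy_error")))
    }
    fit <- stats::lm(y ~ log(x) + rank, data = obs)
    co <- stats::coef(fit)
    params <- group_params(A = unname(co[["log(x)"]]), B = unname(co[["rank"]]),
                           C = unname(co[["(Intercept)"]]))
  } else {
    if (length(unique(obs$x)) < 2) {
      stop(errorCondition(
        "singular design: ear fit needs >= 2 distinct regressor values",
        class = c("maizecanopy_singular_design_error", "maizecanopy_error")))
    }
    fit <- stats::lm(y ~ x, data = obs)
    co <- stats::coef(fit)
    params <- ear_params(D = unname(co[["x"]]), E = unname(co[["(Intercept)"]]))
  }
  if (anyNA(co)) {
    stop(errorCondition("singular design: coefficients not estimable",
      class = c("maizecanopy_singular_design_error", "maizecanopy_error")))
  }
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((obs$y - mean(obs$y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  # noise-free designs fit exactly; lm warns that its summary is unreliable
  # there, but the (near-zero) SEs are not used in that regime
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, length(co)))
  structure(list(params = params, r_squared = r2,
                 n_points = nrow(obs), residual_sse = sse,
                 se = stats::setNames(unname(se), names(co))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("OLS fit:", paste(sprintf("%s=%.4g", names(x$params), unlist(x$params)),
                        collapse = " "),
      sprintf(" R2=%.4f n=%d SSE=%.4g\n", x$r_squared, x$n_points, x$residual_sse))
  invisible(x)
}

#' Observed percent change relative to the reference density
#'
#' Converts a long-form measurement table into the percent-change scale the
#' response equations are expressed in: replicates are averaged per
#' (density, rank, organ), and each elevated-density mean is expressed as
#' percent change relative to the reference-density mean at the same rank
#' and organ.
#'
#' @param table A measurement table (see [read_measurements()]).
#' @param params A [response_params] supplying the reference density and
#'   regressor convention.
#' @param reference Optional [base_profile] supplying known
#'   reference-density sizes. By default the reference sizes are the
#'   table's own reference-density means; when the true base profile is
#'   known (simulation studies), passing it here avoids the correlated
#'   errors a shared noisy denominator would inject into the regression.
#' @return Data frame with columns `organ`, `rank`, `density`, `x`
#'   (regressor), `y` (percent change).
#' @export
observed_relative_change <- function(table, params = default_params(),
                                     reference = NULL) {
  stopifnot(is.data.frame(table))
  means <- stats::aggregate(value_cm ~ density + rank + organ, data = table, FUN = mean)
  ref <- if (is.null(reference)) {
    means[means$density == params$reference_density, ]
  } else {
    stopifnot(inherits(reference, "base_profile"))
    data.frame(rank = reference$data$rank, organ = reference$data$organ,
               value_cm = reference$data$size_cm)
  }
  if (!nrow(ref)) {
    abort_missing_entry(sprintf("table has no observations at the reference density %.3g",
                                params$reference_density))
  }
  elev <- means[means$density > params$reference_density, ]
  key <- paste(elev$rank, elev$organ)
  ref_key <- paste(ref$rank, ref$organ)
  ref_val <- ref$value_cm[match(key, ref_key)]
  keep <- !is.na(ref_val) & ref_val > 0
  elev <- elev[keep, ]
  data.frame(organ = elev$organ, rank = elev$rank, density = elev$density,
             x = vapply(elev$density, density_regressor, numeric(1), params = params),
             y = 100 * (elev$value_cm / ref_val[keep] - 1),
             row.names = NULL)
}

#' Refit the full parameterization from a measurement table
#'
#' Runs [observed_relative_change()] and fits, per organ, the lower group
#' (ranks 6 to ear-1), the ear phytomer and the upper group (ear+1 to 18).
#'
#' @inheritParams observed_relative_change
#' @return Named list per organ code of lists `lower`, `ear`, `upper`,
#'   each a `fit_result`.
#' @export
fit_all_groups <- function(table, params = default_params()) {
  changes <- observed_relative_change(table, params)
  lapply(stats::setNames(organ_codes(), organ_codes()), function(code) {
    d <- changes[changes$organ == code, ]
    list(
      lower = fit_group(d[d$rank < params$ear_rank, ], "grouped"),
      ear   = fit_group(d[d$rank == params$ear_rank, ], "ear"),
      upper = fit_group(d[d$rank > params$ear_rank, ], "grouped")
    )
  })
}
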