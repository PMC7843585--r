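#' Synthetic field-trial configuration
#'
#' Parameters of the synthetic base-profile and observation generator. The
#' defaults mirror the field trial the response equations were derived
#' from: 5 densities (4.5, 6, 7.5, 9, 15 plants m^-2), 3 replicates, and
#' bell-shaped rank profiles with realistic maize organ magnitudes.
#'
#' @param peaks Data frame with columns `organ`, `peak_cm`, `peak_rank`,
#'   `width` defining each organ's Gaussian-in-rank size profile.
#' @param noise_sd_percent Multiplicative noise standard deviation, percent
#'   of the true size. Default 2.
#' @param replicates Replicates per density. Default 3.
#' @param densities Density treatments, plants m^-2.
#' @param seed Master seed; per-density streams derive from it
#'   deterministically.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(peaks = default_synth_peaks(),
                         noise_sd_percent = 2, replicates = 3L,
                         densities = TRIAL_DENSITIES, seed = 1L) {
  stopifnot(is.data.frame(peaks),
            all(c("organ", "peak_cm", "peak_rank", "width") %in% names(peaks)))
  peaks$organ <- check_organ(peaks$organ)
  if (!setequal(peaks$organ, organ_codes())) {
    abort_missing_entry("peaks must cover all six organ codes exactly once")
  }
  if (any(peaks$peak_cm <= 0)) abort_domain("peak sizes must be positive")
  if (any(!(peaks$peak_rank %in% modeled_ranks()))) {
    abort_domain("peak ranks must lie in the modeled range 6-18")
  }
  if (any(peaks$width <= 0)) abort_domain("profile widths must be positive")
  if (noise_sd_percent < 0) abort_domain("noise_sd_percent must be >= 0")
  if (replicates < 1) abort_domain("need at least one replicate")
  if (any(densities <= 0)) abort_domain("densities must be positive")
  structure(list(peaks = peaks, noise_sd_percent = noise_sd_percent,
                 replicates = as.integer(replicates),
                 densities = sort(densities), seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_synth_peaks <- function() {
  data.frame(
    organ     = c("LL", "LW", "SL", "SW", "IL", "ID"),
    peak_cm   = c(80,   10,   18,   3,    14,   2.2),
    peak_rank = c(12L,  13L,  10L,  10L,  14L,  8L),
    width     = c(4,    4,    5,    6,    4,    6)
  )
}

#' Generate a synthetic reference-density base profile
#'
#' Each organ's size over ranks 6-18 follows a Gaussian-in-rank bump,
#' size(rank) = peak * exp(-(rank - peak_rank)^2 / (2 * width^2)),
#' emulating the bell-shaped rank profiles of fully expanded maize canopies
#' (largest laminae mid-canopy, longest internodes above the ear).
#' Deterministic for a fixed config.
#'
#' @param config A [synth_config].
#' @return A [base_profile] at the reference density 4.5 plants m^-2 with
#'   18 initiated leaves.
#' @export
generate_base_profile <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  grid <- expand.grid(rank = modeled_ranks(), organ = organ_codes(),
                      stringsAsFactors = FALSE)
  i <- match(grid$organ, config$peaks$organ)
  grid$size_cm <- config$peaks$peak_cm[i] *
    exp(-(grid$rank - config$peaks$peak_rank[i])^2 / (2 * config$peaks$width[i]^2))
  base_profile(grid, density = REFERENCE_DENSITY, total_leaf_number = 18L)
}

# deterministic per-density stream seed below 2^31
stream_seed <- function(master, k) {
  (as.numeric(master) * 2654435761 + 97 * k) %% 2147483647
}

#' Generate a synthetic multi-density observation table
#'
#' Emulates destructive-sampling measurements: for every density,
#' replicate, rank and organ, the model prediction
#' (via [apply_response()]) is perturbed by multiplicative Gaussian noise,
#' value = predicted * (1 + e), e ~ N(0, noise_sd_percent / 100), and
#' truncated at zero (truncation is logged). Seeded per density from the
#' master seed, so tables are identical across runs for a fixed config.
#'
#' @param base A reference-density [base_profile].
#' @param params A [response_params]; default [default_params()].
#' @param config A [synth_config] (densities, replicates, noise, seed).
#' @param label Year-like label column value. Default "synth".
#' @return A long-form measurement table: `label`, `density`,
#'   `replicate`, `rank`, `organ`, `value_cm`.
#' @export
generate_observations <- function(base, params = default_params(),
                                  config = synth_config(), label = "synth") {
  stopifnot(inherits(base, "base_profile"), inherits(config, "synth_config"))
  out <- vector("list", length(config$densities))
  for (k in seq_along(config$densities)) {
    dens <- config$densities[k]
    pred <- if (dens == params$reference_density) base else
      apply_response(base, dens, params)
    d <- pred$data
    n <- nrow(d) * config$replicates
    set.seed(stream_seed(config$seed, k))
    eps <- stats::rnorm(n, 0, config$noise_sd_percent / 100)
    block <- data.frame(
      label = label, density = dens,
      replicate = rep(seq_len(config$replicates), each = nrow(d)),
      rank = rep(d$rank, config$replicates),
      organ = rep(d$organ, config$replicates),
      value_cm = rep(d$size_cm, config$replicates) * (1 + eps)
    )
    n_trunc <- sum(block$value_cm < 0)
    if (n_trunc) {
      message(sprintf("truncated %d negative synthetic value(s) to 0 at density %.3g",
                      n_trunc, dens))
      block$value_cm <- pmax(0, block$value_cm)
    }
    out[[k]] <- block
  }
  do.call(rbind, out)
}
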