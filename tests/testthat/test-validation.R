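test_that("nrmse matches hand arithmetic and its contracts", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(3, 3, 3), c(1, 2, 3)), 100 * sqrt(5 / 3) / 2)
  # joint rescaling leaves the statistic unchanged
  s <- c(4, 7, 1); o <- c(5, 6, 2)
  expect_equal(nrmse(3.7 * s, 3.7 * o), nrmse(s, o))
  # constant additive simulation bias e with observed mean m gives 100*|e|/m
  o <- c(2, 4, 6)
  expect_equal(nrmse(o + 0.5, o), 100 * 0.5 / mean(o))
  expect_equal(nrmse(o - 0.5, o), 100 * 0.5 / mean(o))
  expect_error(nrmse(1:3, 1:4), class = "maizecanopy_shape_error")
  expect_error(nrmse(c(1, -1), c(1, -1)),
               class = "maizecanopy_degenerate_normalization_error")
})

test_that("quality bands use closed upper edges", {
  expect_equal(as.character(classify_nrmse(c(0, 10, 10.01, 20, 20.01, 30, 30.01, 64.55))),
               c("excellent", "excellent", "good", "good", "fair", "fair",
                 "poor", "poor"))
  expect_error(classify_nrmse(-1), class = "maizecanopy_domain_error")
})

test_that("validate_profiles reports zero NRMSE when observations equal the simulation", {
  base <- generate_base_profile()
  sim <- apply_response(base, 7.5)
  obs <- data.frame(label = "t", density = 7.5,
                    replicate = rep(1:2, each = nrow(sim$data)),
                    rank = rep(sim$data$rank, 2), organ = rep(sim$data$organ, 2),
                    value_cm = rep(sim$data$size_cm, 2))
  report <- validate_profiles(sim, obs)
  expect_setequal(report$quantity, c(organ_codes(), "LA", "LIH"))
  expect_equal(report$nrmse, rep(0, nrow(report)))
  expect_true(all(report$quality == "excellent"))
  expect_true(all(report$n == 13))
})

test_that("a uniform +10% observation shift gives the closed-form NRMSE", {
  # closed form 100*0.1/1.1 = 9.09: exact when sizes are constant in rank
  # (rms equals mean); a lower bound otherwise
  sim <- flat_profile()
  obs <- data.frame(label = "t", density = 4.5, replicate = 1,
                    rank = sim$data$rank, organ = sim$data$organ,
                    value_cm = sim$data$size_cm * 1.1)
  report <- validate_profiles(sim, obs)
  organ_rows <- report[report$quantity %in% organ_codes(), ]
  expect_equal(organ_rows$nrmse, rep(100 * 0.1 / 1.1, nrow(organ_rows)),
               tolerance = 1e-10)

  varied <- apply_response(generate_base_profile(), 6)
  obs2 <- data.frame(label = "t", density = 6, replicate = 1,
                     rank = varied$data$rank, organ = varied$data$organ,
                     value_cm = varied$data$size_cm * 1.1)
  report2 <- validate_profiles(varied, obs2)
  expect_true(all(report2$nrmse >= 100 * 0.1 / 1.1 - 1e-9))
})

test_that("sparse observations degrade gracefully", {
  base <- generate_base_profile()
  sim <- apply_response(base, 9)
  one <- data.frame(label = "t", density = 9, replicate = 1,
                    rank = 10, organ = "LL",
                    value_cm = unname(profile_sizes(sim, "LL", 10)))
  report <- suppressMessages(validate_profiles(sim, one))
  expect_equal(nrow(report[report$quantity == "LL", ]), 1)
  expect_equal(report$n[report$quantity == "LL"], 1)
  expect_error(validate_profiles(sim, one, density = 15),
               class = "maizecanopy_empty_comparison_error")
})

test_that("organ NRMSE rises with the noise level of synthetic observations", {
  base <- generate_base_profile()
  sim <- apply_response(base, 7.5)
  med_nrmse <- function(sd) {
    cfg <- synth_config(noise_sd_percent = sd, replicates = 3, seed = 11)
    obs <- suppressWarnings(generate_observations(base, config = cfg))
    stats::median(validate_profiles(sim, obs, 7.5)$nrmse)
  }
  levels <- vapply(c(1, 4, 12), med_nrmse, numeric(1))
  expect_true(all(diff(levels) > 0))
})

test_that("validation reports serialize to a results-style table", {
  base <- generate_base_profile()
  reports <- do.call(rbind, lapply(c(4.5, 7.5), function(d) {
    sim <- apply_response(base, d)
    obs <- data.frame(label = "t", density = d, replicate = 1,
                      rank = sim$data$rank, organ = sim$data$organ,
                      value_cm = sim$data$size_cm)
    validate_profiles(sim, obs)
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(reports, path)
  wide <- utils::read.csv(path)
  expect_equal(wide$quantity, c(organ_codes(), "LA", "LIH"))
  expect_named(wide, c("quantity", "PD4.5", "PD7.5"))
})
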