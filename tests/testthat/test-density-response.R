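test_that("relative_change evaluates the printed coefficients by hand", {
  # ear phytomer: linear in the density increment
  expect_equal(relative_change("LL", 12, 15), 0.11 * 10.5 + 1.70)
  # grouped phytomer: log + linear
  expect_equal(relative_change("LL", 8, 6), 2.99 * log(1.5) + 0.12 * 8 + 0.32)
  # upper group uses its own coefficients
  expect_equal(relative_change("IL", 14, 9), 2.91 * log(4.5) - 2.06 * 14 + 32.08)
})

test_that("the reference density is an identity for every organ and rank", {
  for (code in organ_codes()) {
    expect_equal(relative_change(code, modeled_ranks(), 4.5),
                 rep(0, length(modeled_ranks())))
  }
})

test_that("rank and regressor domains are enforced", {
  expect_error(relative_change("LL", 5, 6), class = "maizecanopy_rank_error")
  expect_error(relative_change("LL", 19, 6), class = "maizecanopy_rank_error")
  expect_error(relative_change("XX", 8, 6), class = "maizecanopy_organ_error")
  expect_error(relative_change("LL", 8, 4), class = "maizecanopy_domain_error")
  expect_warning(relative_change("LL", 8, 20), "extrapolating")
})

test_that("relative_change is continuous and monotone in x per the log coefficient sign", {
  # away from the log singularity at x = 0, the response is smooth
  xs <- seq(5.5, 15, length.out = 200)
  for (case in list(list(organ = "LL", rank = 8, sign = +1),   # A = 2.99 > 0
                    list(organ = "SW", rank = 8, sign = -1))) { # A = -8.99 < 0
    y <- vapply(xs, function(d) relative_change(case$organ, case$rank, d), numeric(1))
    expect_true(all(case$sign * diff(y) >= 0))
    expect_lt(max(abs(diff(y))), 1)  # no jumps on a fine grid
  }
})

test_that("apply_response scales sizes multiplicatively and floors at zero", {
  base <- flat_profile(c(LL = 100, LW = 10, SL = 18, SW = 3, IL = 10, ID = 2))
  pred <- apply_response(base, 6)
  expect_equal(unname(profile_sizes(pred, "LL", 8)),
               100 * (1 + (2.99 * log(1.5) + 0.12 * 8 + 0.32) / 100))
  expect_equal(pred$density, 6)

  # identity at the reference density
  same <- apply_response(base, 4.5)
  expect_identical(same$data, base$data)

  # a -100% (or worse) response cannot produce negative sizes
  crash <- response_params(modifyList(default_params()$organs, list(
    LL = list(lower = group_params(0, 0, -150), ear = ear_params(0, -150),
              upper = group_params(0, 0, -150)))))
  floored <- apply_response(base, 6, crash)
  expect_true(all(profile_sizes(floored, "LL") == 0))
  expect_true(all(floored$data$size_cm >= 0))
})

test_that("default_params carries the full printed parameterization", {
  p <- default_params()
  expect_setequal(names(p$organs), organ_codes())
  expect_equal(unlist(p$organs$SW$lower), c(A = -8.99, B = -0.24, C = 4.92))
  expect_equal(unlist(p$organs$ID$ear), c(D = -1.63, E = -9.53))
  expect_equal(unlist(p$organs$IL$upper), c(A = 2.91, B = -2.06, C = 32.08))
  expect_equal(p$ear_rank, 12L)
  expect_equal(p$regressor_mode, "increment")
})

test_that("absolute regressor mode uses density itself", {
  p <- default_params()
  p_abs <- response_params(p$organs, regressor_mode = "absolute")
  expect_equal(relative_change("LL", 12, 15, p_abs), 0.11 * 15 + 1.70)
  expect_equal(relative_change("LL", 8, 6, p_abs), 2.99 * log(6) + 0.12 * 8 + 0.32)
})

test_that("incomplete parameterizations and profiles are rejected with named gaps", {
  organs <- default_params()$organs
  organs$ID <- NULL
  expect_error(response_params(organs), class = "maizecanopy_missing_entry_error")

  grid <- expand.grid(rank = modeled_ranks(), organ = organ_codes(),
                      stringsAsFactors = FALSE)
  grid$size_cm <- 1
  holes <- grid[-which(grid$rank == 9 & grid$organ == "SL"), ]
  err <- tryCatch(base_profile(holes), error = identity)
  expect_s3_class(err, "maizecanopy_missing_entry_error")
  expect_match(conditionMessage(err), "9 SL")
})
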