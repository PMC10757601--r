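test_that("beta moment matching solves the two moment equations", {
  mm <- moment_match_beta(0.186, 0.0186)
  expect_equal(mm$alpha, 81.214, tolerance = 1e-4)
  expect_equal(mm$beta, 355.4204, tolerance = 1e-4)
  # analytic mean and variance of the matched distribution round-trip
  for (case in list(c(0.186, 0.0186), c(0.89, 0.13), c(0.0007, 0.0001),
                    c(0.5, 0.2), c(0.0069, 0.0612))) {
    mm <- moment_match_beta(case[1], case[2])
    s <- mm$alpha + mm$beta
    expect_equal(mm$alpha / s, case[1], tolerance = 1e-10)
    expect_equal(sqrt(mm$alpha * mm$beta / (s^2 * (s + 1))), case[2], tolerance = 1e-10)
  }
  # shrinking se drives both shapes up while preserving the mean
  big <- moment_match_beta(0.5, 1e-6)
  expect_gt(big$alpha, 1e10)
  expect_equal(big$alpha / (big$alpha + big$beta), 0.5, tolerance = 1e-12)
})

test_that("beta matching rejects infeasible variances and boundary means", {
  expect_error(moment_match_beta(0.5, 0.5), "invalid variance")
  expect_error(moment_match_beta(0.5, 0.6, name = "p_bad"), "p_bad")
  expect_error(moment_match_beta(0, 0.1), "inside")
  expect_error(moment_match_beta(1, 0.1), "inside")
})

test_that("gamma moment matching is exact, including shape below 1", {
  mm <- moment_match_gamma(666.88, 133.375)
  expect_equal(mm$shape, 25.0, tolerance = 1e-4)
  expect_equal(mm$scale, 26.6748, tolerance = 1e-4)
  heavy <- moment_match_gamma(902.31, 2310.5)
  expect_equal(heavy$shape, 0.15251, tolerance = 1e-4)
  expect_lt(heavy$shape, 1)
  for (case in list(c(666.88, 133.375), c(902.31, 2310.5), c(3.22, 21.97))) {
    mm <- moment_match_gamma(case[1], case[2])
    expect_equal(mm$shape * mm$scale, case[1], tolerance = 1e-10)
    expect_equal(sqrt(mm$shape) * mm$scale, case[2], tolerance = 1e-10)
  }
  expect_error(moment_match_gamma(0, 1), "mean > 0")
  expect_error(moment_match_gamma(-5, 1), "mean > 0")
})

test_that("sampled distributions reproduce their published moments", {
  set.seed(101)
  mm <- moment_match_beta(0.89, 0.13)
  x <- rbeta(1e6, mm$alpha, mm$beta)
  expect_equal(mean(x), 0.89, tolerance = 5e-4)
  expect_equal(sd(x), 0.13, tolerance = 5e-3)
  mg <- moment_match_gamma(666.88, 133.375)
  y <- rgamma(1e6, shape = mg$shape, scale = mg$scale)
  expect_lt(abs(mean(y) - 666.88), 3 * 133.375 / sqrt(1e6) * 1.5)
})

test_that("parameter-set sampling is seed-deterministic and domain-respecting", {
  a <- suppressWarnings(sample_parameter_set(base_ps, seed = 11))
  b <- suppressWarnings(sample_parameter_set(base_ps, seed = 11))
  expect_identical(a, b)
  # degenerate rows come back as their means
  fixed <- base_ps$specs$name[base_ps$specs$se == 0]
  expect_equal(a[fixed], base_values[fixed])
  # domains hold across many draws
  set.seed(3)
  sp <- base_ps$specs
  for (i in 1:200) {
    v <- suppressWarnings(sample_parameter_set(base_ps))
    expect_true(all(v[sp$name[sp$role != "cost"]] >= 0 &
                      v[sp$name[sp$role != "cost"]] <= 1))
    expect_true(all(v[sp$name[sp$role == "cost"]] >= 0))
  }
})

test_that("detection-rate draws average to the published mean", {
  set.seed(5)
  mm <- moment_match_beta(0.186, 0.0186)
  x <- rbeta(1e4, mm$alpha, mm$beta)
  expect_equal(mean(x), 0.186, tolerance = 1e-3)
})

test_that("infeasible beta rows fall back to their mean with a warning", {
  ps <- parameter_set(rbind(
    param_spec("p_ok", 0.5, 0.1, "beta", "probability"),
    param_spec("u_bad", 0.5, 0.6, "beta", "utility")))
  expect_warning(v <- sample_parameter_set(ps, seed = 1), "u_bad")
  expect_equal(v[["u_bad"]], 0.5)
})

test_that("surgery uptake triples are renormalised when a draw exceeds 1", {
  ps <- parameter_set(rbind(
    param_spec("p_uptake_both", 0.6, 0.15, "beta", "probability"),
    param_spec("p_uptake_rrm", 0.6, 0.15, "beta", "probability"),
    param_spec("p_uptake_rrso", 0.6, 0.15, "beta", "probability")))
  set.seed(2)
  saw <- FALSE
  for (i in 1:50) {
    v <- withCallingHandlers(sample_parameter_set(ps),
                             warning = function(w) {
                               saw <<- TRUE
                               invokeRestart("muffleWarning")
                             })
    expect_lte(v[["p_uptake_both"]] + v[["p_uptake_rrm"]] + v[["p_uptake_rrso"]], 1 + 1e-12)
  }
  expect_true(saw)
})

test_that("config round-trips and the shipped default fixture pins the inputs", {
  tmp <- tempfile(fileext = ".yaml")
  save_parameters(base_ps, tmp)
  ps2 <- load_parameters(tmp)
  expect_equal(ps2$specs$mean, base_ps$specs$mean)
  expect_equal(ps2$specs$se, base_ps$specs$se)
  expect_identical(ps2$settings$entry_age, base_ps$settings$entry_age)

  fixture <- system.file("extdata", "table1_default.yaml", package = "brcacea")
  expect_true(nzchar(fixture))
  psf <- load_parameters(fixture)
  expect_identical(nrow(psf$specs), 83L)
  # checksum over the full value table
  expect_equal(sum(psf$specs$mean), 39752.4528, tolerance = 1e-8)
  spot <- c(p_detect = 0.1860, p_vus = 0.0631, cost_test_ngs = 666.88,
            cost_test_targeted = 78.13, u_well = 0.89, u_metoc = 0.71,
            rec_1_5 = 0.2432, mort_bc_1 = 0.15, oc_dev_rrso = 0.0027,
            cost_ip_brov = 3533.81)
  expect_equal(param_values(psf)[names(spot)], spot)
  expect_identical(psf$settings$wtp, 5000)
  expect_identical(psf$settings$currency_conversion, 32.0)
})

test_that("schema violations are reported with the offending keys", {
  tmp <- tempfile(fileext = ".yaml")
  save_parameters(base_ps, tmp)
  cfg <- yaml::read_yaml(tmp)
  cfg$bogus_section <- list(a = 1)
  yaml::write_yaml(cfg, tmp)
  expect_error(load_parameters(tmp), "bogus_section")

  cfg$bogus_section <- NULL
  cfg$parameters <- cfg$parameters[-1]  # drop p_detect
  yaml::write_yaml(cfg, tmp)
  expect_error(load_parameters(tmp), "p_detect")

  expect_error(load_parameters(tempfile()), "not found")
  expect_error(param_spec("c_neg", -1, 1, "gamma", "cost"), ">= 0")
  expect_error(param_spec("p_big", 1.2, 0.1, "beta", "probability"), "\\[0, 1\\]")
  expect_error(param_spec("c_beta", 10, 1, "beta", "cost"), "only valid")
})

test_that("one-way ranges respect domains and explicit overrides", {
  expect_equal(owsa_range(base_ps, "p_detect"), c(0.186 - 1.96 * 0.0186, 0.186 + 1.96 * 0.0186))
  expect_equal(owsa_range(base_ps, "cost_test_ngs"), c(0.75, 1.25) * 666.88)
  expect_equal(owsa_range(base_ps, "p_family_positive"), c(0.5, 0.5))
  # utilities clip at 1
  expect_equal(owsa_range(base_ps, "u_postbc")[2], 1)
  ps <- base_ps
  ps$specs[ps$specs$name == "p_detect", c("low", "high")] <- c(0.1, 0.3)
  expect_equal(owsa_range(ps, "p_detect"), c(0.1, 0.3))
  expect_error(owsa_range(base_ps, "nope"), "unknown parameter")
})
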