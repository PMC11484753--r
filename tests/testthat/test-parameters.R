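test_that("defaults match the reference parameter set", {
  p <- default_parameters()
  expect_s3_class(p, "per2_params")
  expect_equal(p$n, 3)
  expect_equal(p$mu_S, log(2) / 2)
  expect_equal(p$K_S, 0.3684)
  expect_equal(p$v_A, 1)
  expect_equal(p$mu_A, 1)
  expect_equal(p$K_A, 4.0)
  expect_equal(p$g_S, 14 / (log(2) / 2))
  expect_equal(p$eta_S, 1)
  expect_equal(p$tau, 6.2)
  expect_equal(p$alpha, 0)
  expect_equal(p$f_S, 0)
  expect_equal(p$f_A, 0)
})

test_that("g_S default stays coupled to the effective mu_S", {
  expect_equal(default_parameters(mu_S = log(2) / 2)$g_S, 28 / log(2),
               tolerance = 1e-12)
  expect_equal(default_parameters(mu_S = 0.1)$g_S, 140)
  # explicit g_S override wins over the coupling
  expect_equal(default_parameters(mu_S = 0.1, g_S = 5)$g_S, 5)
  expect_equal(round(default_parameters()$g_S, 1), 40.4)
})

test_that("unknown fields and domain violations are strict errors", {
  expect_error(default_parameters(bogus = 1), class = "per2as_config_error")
  expect_error(default_parameters(f_S = 1.5),
               class = "per2as_validation_error")
  expect_error(default_parameters(f_A = -0.1),
               class = "per2as_validation_error")
  expect_error(default_parameters(mu_S = 0),
               class = "per2as_validation_error")
  expect_error(default_parameters(K_A = -1),
               class = "per2as_validation_error")
  expect_error(default_parameters(tau = -2),
               class = "per2as_validation_error")
  expect_error(default_parameters(n = 0.5),
               class = "per2as_validation_error")
  # the error message names the offending field
  expect_error(default_parameters(eta_S = -1), "eta_S")
})

test_that("parameter sets round-trip through flat YAML mappings", {
  p <- default_parameters(f_S = 0.8, f_A = 0.8, K_A = 0.67, alpha = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  q <- read_parameters(path)
  expect_equal(unclass(q), unclass(p))
  # unknown keys in a file are rejected
  writeLines(c("K_A: 4.0", "weird_key: 1"), path)
  expect_error(read_parameters(path), class = "per2as_config_error")
})

test_that("knock-down half-life follows log(2)/(mu_S (1 + alpha))", {
  expect_equal(knockdown_half_life(default_parameters()), 2.0)
  expect_equal(knockdown_half_life(default_parameters(alpha = 4)), 0.4)
  expect_equal(knockdown_half_life(default_parameters(alpha = 1)), 1.0)
  expect_equal(knockdown_half_life(default_parameters(mu_S = log(2))), 1.0)
})

test_that("translation rate truncates speed * 3600 / length", {
  expect_identical(translation_rate_per_hour(5, 1257), 14L)
  expect_identical(translation_rate_per_hour(1, 3600), 1L)
  expect_identical(translation_rate_per_hour(10, 1257), 28L)
  expect_error(translation_rate_per_hour(0, 1257),
               class = "per2as_domain_error")
  expect_error(translation_rate_per_hour(5, -1),
               class = "per2as_domain_error")
})

test_that("explicit kinetics keep the quasi-steady-state ratios", {
  p <- default_parameters()
  kin <- full_kinetics(p, rate_scale = 250)
  expect_equal(kin$k_off_S / kin$k_on_S, p$K_S^p$n)
  expect_equal(kin$k_off_A / kin$k_on_A, p$K_A)
  expect_silent(validate_kinetics(kin, p))
  bad <- kin
  bad$k_off_A <- bad$k_off_A * 1.5
  expect_error(validate_kinetics(bad, p), class = "per2as_validation_error")
  expect_error(full_kinetics(p, rate_scale = -1),
               class = "per2as_validation_error")
})

test_that("nondimensionalization forms the four rate ratios", {
  mu <- log(2) / 2
  dp <- dimensional_params(v_SD = 3, mu_SD = mu, v_AD = 3, mu_AD = mu,
                           g_SD = 14, eta_SD = mu)
  p <- nondimensionalize(dp)
  expect_equal(p$v_A, 1)
  expect_equal(p$mu_A, 1)
  expect_equal(p$eta_S, 1)
  expect_equal(p$g_S, 28 / log(2), tolerance = 1e-12)
  expect_equal(p$mu_S, mu)
  expect_equal(attr(p, "concentration_scale"), 3 / mu)
  expect_error(dimensional_params(v_SD = 0, mu_SD = mu, v_AD = 1,
                                  mu_AD = mu, g_SD = 14, eta_SD = mu),
               class = "per2as_validation_error")
})

test_that("rescaling the concentration unit leaves dimensionless params alone", {
  mu <- log(2) / 2
  dp1 <- dimensional_params(v_SD = 2, mu_SD = mu, v_AD = 2, mu_AD = mu,
                            g_SD = 14, eta_SD = mu)
  dp2 <- dimensional_params(v_SD = 6, mu_SD = mu, v_AD = 6, mu_AD = mu,
                            g_SD = 14, eta_SD = mu)
  p1 <- nondimensionalize(dp1)
  p2 <- nondimensionalize(dp2)
  fields <- names(default_parameters())
  expect_equal(unclass(p1)[fields], unclass(p2)[fields])
  expect_equal(attr(p2, "concentration_scale"),
               3 * attr(p1, "concentration_scale"))
})
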