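test_that("sense activity follows the autoinhibition Hill form", {
  p <- default_parameters()
  expect_equal(qss_activity_sense(0, p), 1.0)
  expect_equal(qss_activity_sense(1 / p$K_S, p), 0.5)
  expect_equal(qss_activity_sense(2 / p$K_S, p), 1 / 9)
  # strictly decreasing in p_S
  grid <- qss_activity_sense(seq(0, 10, by = 0.25), p)
  expect_true(all(diff(grid) < 0))
  expect_error(qss_activity_sense(-0.1, p), class = "per2as_domain_error")
})

test_that("antisense activity is the constant 1/(1 + K_A)", {
  expect_equal(qss_activity_antisense(default_parameters()), 0.2)
  expect_equal(qss_activity_antisense(default_parameters(K_A = 0)), 1.0)
  expect_equal(qss_activity_antisense(default_parameters(K_A = 0.67)),
               1 / 1.67)
  # strictly decreasing in K_A
  acts <- vapply(c(0, 0.5, 1, 2, 4, 8),
                 function(k) qss_activity_antisense(default_parameters(K_A = k)),
                 numeric(1))
  expect_true(all(diff(acts) < 0))
})

test_that("switching equilibrium reproduces the closed-form activities", {
  # set dX/dt = 0 in the explicit kinetics and solve numerically
  set.seed(42)
  for (i in 1:20) {
    p <- default_parameters(K_S = runif(1, 0.1, 2), K_A = runif(1, 0, 6),
                            n = sample(1:4, 1))
    kin <- full_kinetics(p, rate_scale = runif(1, 10, 1000))
    pS <- runif(1, 0, 5)
    rootS <- uniroot(function(X) kin$k_on_S * (1 - X) -
                       kin$k_off_S * pS^p$n * X,
                     c(0, 1), tol = 1e-12)$root
    rootA <- uniroot(function(X) kin$k_on_A * (1 - X) - kin$k_off_A * X,
                     c(0, 1), tol = 1e-12)$root
    expect_equal(rootS, qss_activity_sense(pS, p), tolerance = 1e-8)
    expect_equal(rootA, qss_activity_antisense(p), tolerance = 1e-8)
  }
})

test_that("reduced derivatives equal mu_S times the production/decay balance", {
  set.seed(7)
  for (i in 1:25) {
    p <- default_parameters(f_S = runif(1), f_A = runif(1),
                            K_A = runif(1, 0, 6), alpha = runif(1, 0, 4))
    st <- c(m_S = runif(1, 0, 1), m_A = runif(1, 0, 1), p_S = runif(1, 0, 30))
    del <- runif(1, 0, 1)
    d <- rhs_reduced(0, st, del, p)
    XS <- 1 / (1 + (p$K_S * st[["p_S"]])^p$n)
    XA <- 1 / (1 + p$K_A)
    expect_equal(d[["m_S"]],
                 p$mu_S * (XS * (1 - p$f_S * XA) -
                             (1 + p$alpha) * st[["m_S"]]))
    expect_equal(d[["m_A"]],
                 p$mu_S * (p$v_A * XA * (1 - p$f_A * XS) -
                             p$mu_A * st[["m_A"]]))
    expect_equal(d[["p_S"]],
                 p$mu_S * (p$g_S * del - p$eta_S * st[["p_S"]]))
  }
})

test_that("reduced system has the expected degenerate limits", {
  p <- default_parameters()
  # m_A balance is zero exactly at the decoupled fixed point v_A/(mu_A(1+K_A))
  d <- rhs_reduced(0, c(m_S = 0.3, m_A = 0.2, p_S = 1), 0.3, p)
  expect_equal(d[["m_A"]], p$mu_S * (0.2 - 0.2))
  # no delayed mRNA and no protein: no protein flux
  expect_equal(rhs_reduced(0, c(0, 0, 0), 0, p)[["p_S"]], 0)
  # f_A = 1 and p_S = 0: sense promoter fully on, all antisense RNAP collides
  p2 <- default_parameters(f_A = 1)
  d2 <- rhs_reduced(0, c(m_S = 0, m_A = 0.5, p_S = 0), 0, p2)
  expect_equal(d2[["m_A"]], -p2$mu_S * p2$mu_A * 0.5)
  expect_error(rhs_reduced(0, c(-0.1, 0, 0), 0, p),
               class = "per2as_domain_error")
  expect_error(rhs_reduced(0, c(0.1, 0, 0), -1, p),
               class = "per2as_domain_error")
})

test_that("full-system collision terms behave at the corners", {
  p <- default_parameters(f_S = 1, f_A = 1)
  kin <- full_kinetics(p)
  # total collision (f_S = 1, both promoters on) kills sense production
  d <- rhs_full(0, c(X_S = 1, X_A = 1, m_S = 0.4, m_A = 0.1, p_S = 0), 0,
                kin, p)
  expect_equal(d[["m_S"]], -p$mu_S * 0.4)
  # silent sense promoter: pure decay of m_S
  d2 <- rhs_full(0, c(X_S = 0, X_A = 0.2, m_S = 0.4, m_A = 0.1, p_S = 0), 0,
                 kin, default_parameters(alpha = 4))
  expect_equal(d2[["m_S"]], -default_parameters(alpha = 4)$mu_S * 5 * 0.4)
  # no repressor: recruitment only, dX_S/dt >= 0
  d3 <- rhs_full(0, c(X_S = 0.5, X_A = 0.2, m_S = 0, m_A = 0, p_S = 0), 0,
                 kin, p)
  expect_equal(d3[["X_S"]], kin$k_on_S * 0.5)
  expect_gte(d3[["X_S"]], 0)
  expect_error(rhs_full(0, c(1.2, 0.2, 0, 0, 0), 0, kin, p),
               class = "per2as_domain_error")
})

test_that("full-system trajectories stay in the invariant region", {
  p <- default_parameters(f_S = 0.8, f_A = 0.8)
  traj <- simulate_model(p, system = "full", t_end = 300)
  tol <- 1e-9
  expect_true(all(traj$X_S >= -tol & traj$X_S <= 1 + tol))
  expect_true(all(traj$X_A >= -tol & traj$X_A <= 1 + tol))
  expect_true(all(traj$m_S >= -tol))
  expect_true(all(traj$m_A >= -tol))
  expect_true(all(traj$p_S >= -tol))
})
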