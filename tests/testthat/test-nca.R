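test_that("cmax/tmax take the maximum quantifiable sample, earliest on ties", {
  p <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5),
                         concentrations = c(300, 150, 80))
  expect_equal(find_cmax_tmax(p), list(cmax = 300, tmax = 1))
  p2 <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5),
                          concentrations = c(100, 100, 50))
  expect_equal(find_cmax_tmax(p2), list(cmax = 100, tmax = 1))
  # BLQ maximum is ignored
  p3 <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5),
                          concentrations = c(300, 150, 80),
                          blq = c(TRUE, FALSE, FALSE))
  expect_equal(find_cmax_tmax(p3)$cmax, 150)
  p4 <- conc_time_profile("a", "g", dose = 30, times = c(1, 3),
                          concentrations = c(1, 1), blq = c(TRUE, TRUE))
  expect_error(find_cmax_tmax(p4), class = "gadnca_not_evaluable")
})

test_that("time-zero back-extrapolation is log-linear through the first two points", {
  p <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5),
                         concentrations = c(100, 25, 10))
  # hand arithmetic: slope = ln(25/100)/2, C0 = 100 * exp(ln 4 / 2) = 200
  expect_equal(back_extrapolate_c0(p)$c0, 200, tolerance = 1e-12)
  expect_false(back_extrapolate_c0(p)$fallback)

  flat <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5),
                            concentrations = c(50, 50, 10))
  expect_equal(back_extrapolate_c0(flat), list(c0 = 50, fallback = TRUE))

  # exact mono-exponential: recovers the true C(0) to 1e-9 relative
  lam <- 0.21; C0 <- 123.4
  t <- c(1, 3, 5, 10)
  pm <- conc_time_profile("a", "g", dose = 30, times = t,
                          concentrations = C0 * exp(-lam * t))
  expect_lt(rel_err(back_extrapolate_c0(pm)$c0, C0), 1e-9)
})

test_that("trapezoid rules match their closed forms and reject bad segments", {
  expect_equal(trapezoid_linear(10, 10, 1), 10)
  expect_equal(trapezoid_linear(0, 10, 2), 10)
  expect_equal(trapezoid_linear(238.1, 100, 2), 338.1)
  expect_error(trapezoid_linear(1, 1, 0), "dt")

  expect_equal(trapezoid_log(10, 5, 1), 5 / log(2), tolerance = 1e-12)
  # oracle: adaptive quadrature of the exponential through (0,10) and (1,5)
  f <- function(t) 10 * exp(log(0.5) * t)
  expect_equal(trapezoid_log(10, 5, 1),
               integrate(f, 0, 1, rel.tol = 1e-12)$value, tolerance = 1e-10)
  expect_error(trapezoid_log(10, 10, 1), "unequal")
  expect_error(trapezoid_log(0, 5, 1), "positive")

  # log rule is exact on any exponential segment
  lam <- 0.037; C0 <- 87
  t1 <- 12; t2 <- 31
  seg <- trapezoid_log(C0 * exp(-lam * t1), C0 * exp(-lam * t2), t2 - t1)
  expect_equal(seg, C0 * (exp(-lam * t1) - exp(-lam * t2)) / lam,
               tolerance = 1e-12)
})

test_that("linear-up/log-down integration matches analytic areas on dense biexponentials", {
  A <- 200; alpha <- 0.35; B <- 50; beta <- 0.02
  p <- biexp_profile(A, alpha, B, beta)
  Tlast <- max(p$times)
  res <- integrate_auc_aumc(p, c0 = A + B)
  expect_lt(rel_err(res$auc_last, biexp_auc_to(A, alpha, B, beta, Tlast)), 1e-6)
  expect_lt(rel_err(res$aumc_last, biexp_aumc_to(A, alpha, B, beta, Tlast)), 1e-5)
  # degenerate two-point rectangle via the public segment rules
  expect_equal(trapezoid_linear(10, 10, 1), 10)
})

test_that("terminal regression recovers exact log-linear data and selects sane windows", {
  t <- c(30, 60, 90)
  p <- conc_time_profile("a", "g", dose = 30, times = c(1, 5, t),
                         concentrations = c(500, 300, 100 * exp(-0.05 * t)))
  fit <- fit_lambda_z(p)
  expect_equal(fit$lambda_z, 0.05, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_gte(fit$n_points, 3)
  expect_equal(fit$c_last_pred, 100 * exp(-0.05 * 90), tolerance = 1e-8)

  # t1/2 identity via run_nca downstream: lambda = ln 2 -> half-life 1 min
  expect_equal(log(2) / fit$lambda_z, log(2) / 0.05)

  # noiseless biexponential with alpha >> beta: lambda_z within 1% of beta
  pb <- biexp_profile(400, 1.0, 50, 0.02, times = schedule_times)
  expect_lt(rel_err(fit_lambda_z(pb)$lambda_z, 0.02), 0.01)

  # rising profile has no terminal decline
  up <- conc_time_profile("a", "g", dose = 30, times = c(1, 3, 5, 10, 20),
                          concentrations = c(1, 2, 3, 4, 5))
  expect_error(fit_lambda_z(up), class = "gadnca_not_evaluable")

  # fixed window override is honoured
  fw <- fit_lambda_z(pb, window = c(30, 90))
  expect_equal(fw$n_points, 3)
  expect_equal(fw$time_range, c(30, 90))
})

test_that("extrapolation to infinity is exact for exponentials and flags heavy tails", {
  # exact mono-exponential, C0 = 100, lambda = 0.05, samples to 90 min:
  # auc_inf must equal C0/lambda = 2000 exactly
  lam <- 0.05; C0 <- 100
  t <- c(1, 3, 5, 10, 20, 30, 60, 90)
  p <- conc_time_profile("a", "g", dose = 30, times = t,
                         concentrations = C0 * exp(-lam * t))
  r <- run_nca(p)
  expect_equal(r$auc_inf, C0 / lam, tolerance = 1e-9)
  expect_equal(r$auc_extrapolated_pct,
               100 * (1 - r$auc_last / r$auc_inf), tolerance = 1e-12)
  # sampled to 40 half-lives the extrapolated share vanishes
  long <- mono_profile(C0 = 100, lambda = 0.05)
  expect_lt(run_nca(long)$auc_extrapolated_pct, 1e-10)
  # a short window leaves a large flagged tail
  slow <- conc_time_profile("a", "g", dose = 30, times = t,
                            concentrations = 300 * exp(-0.004 * t))
  rs <- run_nca(slow)
  expect_gt(rs$auc_extrapolated_pct, 20)
  expect_true("extrapolation_gt_20pct" %in% rs$quality_flags)
})

test_that("derived parameters follow the standard NCA identities", {
  fit <- structure(list(lambda_z = 0.05, c_last_pred = 1), class = "lambda_z_fit")
  par <- derive_parameters(auc_inf = 3000, aumc_inf = 60000, fit, dose = 30)
  expect_equal(par$cl, 10)               # 30 umol / 3000 umol*min/L = 10 mL/min
  expect_equal(par$v_z, 10 / 0.05)
  expect_equal(par$mrt, 20)
  expect_equal(par$v_ss, 10 * 20)
  expect_equal(par$t_half_beta, log(2) / 0.05)
  expect_equal(par$t_half_eff, 0.693 * 20)
  expect_error(derive_parameters(3000, 60000, fit, dose = 0), "dose")
})

test_that("noncompartmental closure on exact mono-exponential input", {
  set.seed(31)
  for (i in 1:5) {
    lam <- runif(1, 0.01, 0.2); C0 <- runif(1, 50, 500); dose <- runif(1, 5, 60)
    p <- mono_profile(C0 = C0, lambda = lam, dose = dose)
    r <- run_nca(p)
    V <- 1000 * dose / C0
    expect_lt(rel_err(r$cl, lam * V), 1e-6)
    expect_lt(rel_err(r$v_ss, V), 1e-6)
    expect_lt(rel_err(r$v_z, V), 1e-6)
    expect_lt(rel_err(r$mrt, 1 / lam), 1e-6)
    expect_lt(rel_err(r$t_half_beta, log(2) / lam), 1e-6)
  }
})

test_that("scaling laws: concentrations scale CL, doses scale volumes", {
  t <- schedule_times
  conc <- 300 * exp(-0.05 * t) + 40 * exp(-0.01 * t)
  p1 <- conc_time_profile("a", "g", dose = 30, times = t, concentrations = conc)
  p2 <- conc_time_profile("a", "g", dose = 30, times = t,
                          concentrations = 2 * conc)
  r1 <- run_nca(p1); r2 <- run_nca(p2)
  expect_equal(r2$cl, r1$cl / 2, tolerance = 1e-10)
  expect_equal(r2$t_half_beta, r1$t_half_beta, tolerance = 1e-10)
  expect_equal(r2$t_half_eff, r1$t_half_eff, tolerance = 1e-10)
  r3 <- run_nca(p1, dose = 60)
  expect_equal(r3$cl, 2 * r1$cl, tolerance = 1e-10)
  expect_equal(r3$v_ss, 2 * r1$v_ss, tolerance = 1e-10)
  expect_equal(r3$v_z, 2 * r1$v_z, tolerance = 1e-10)
})

test_that("definitional identities hold on simulated subjects", {
  cfg <- cohort_config(group_sizes = c(4L, 3L, 3L), seed = 21)
  for (p in simulate_cohort(cfg)) {
    r <- run_nca(p)
    expect_equal(r$auc_extrapolated_pct,
                 100 * (1 - r$auc_last / r$auc_inf), tolerance = 1e-10)
    expect_equal(r$v_ss, r$cl * r$mrt, tolerance = 1e-10)
    expect_equal(r$t_half_eff, 0.693 * r$mrt, tolerance = 1e-10)
    expect_gte(r$auc_inf, r$auc_last)
    expect_gte(r$aumc_inf, r$aumc_last)
    expect_true(all(c(r$cl, r$v_z, r$v_ss, r$mrt, r$t_half_beta) > 0))
  }
})

test_that("BLQ samples are excluded and all-BLQ profiles fail structurally", {
  t <- schedule_times
  conc <- 300 * exp(-0.05 * t)
  full <- conc_time_profile("a", "g", dose = 30, times = t,
                            concentrations = conc)
  # flagging the last sample BLQ truncates the profile at 60 min
  trunc <- conc_time_profile("a", "g", dose = 30, times = t,
                             concentrations = conc,
                             blq = c(rep(FALSE, 7), TRUE))
  r <- run_nca(trunc)
  expect_equal(r$t_last, 60)
  expect_lt(r$auc_last, run_nca(full)$auc_last)

  allblq <- conc_time_profile("a", "g", dose = 30, times = t,
                              concentrations = conc,
                              blq = rep(TRUE, 8))
  err <- tryCatch(run_nca(allblq), gadnca_not_evaluable = function(e) e)
  expect_s3_class(err, "gadnca_not_evaluable")
  expect_match(conditionMessage(err), "quantifiable")
})

test_that("starred moment tails work where defined and fall back where not", {
  t <- schedule_times
  # slow elimination: C*t rising through 90 min -> no starred rate constant,
  # requested star mode falls back to the standard tail with a flag
  slow <- conc_time_profile("a", "g", dose = 30, times = t,
                            concentrations = 200 * exp(-0.008 * t))
  rs <- run_nca(slow, aumc_tail = "star")
  expect_true("aumc_tail_standard_fallback" %in% rs$quality_flags)
  expect_true(is.na(rs$lambda_z_star))
  expect_gt(rs$aumc_inf, rs$aumc_last)
  expect_equal(rs$aumc_inf, run_nca(slow)$aumc_inf)
  # the default standard tail needs no fallback
  expect_false("aumc_tail_standard_fallback" %in%
                 run_nca(slow)$quality_flags)

  # fast elimination: starred fit exists; star and lambda_z modes differ from
  # standard only in the tail term
  fast <- mono_profile(C0 = 300, lambda = 0.1, dose = 30)
  rf <- run_nca(fast, aumc_tail = "star")
  expect_false("aumc_tail_standard_fallback" %in% rf$quality_flags)
  expect_gt(rf$lambda_z_star, 0)
  r_std <- run_nca(fast)
  r_lz <- run_nca(fast, aumc_tail = "lambda_z")
  expect_equal(rf$auc_inf, r_std$auc_inf)
  expect_equal(rf$aumc_last, r_std$aumc_last)
  # on a 40-half-life window all three tails are negligible and agree
  expect_equal(rf$aumc_inf, r_std$aumc_inf, tolerance = 1e-6)
  expect_equal(r_lz$aumc_inf, r_std$aumc_inf, tolerance = 1e-6)
})
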