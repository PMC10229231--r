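test_that("fixation probability has the correct degenerate limits", {
  # critical lineage: constant environment at wild-type equilibrium with
  # b_M = b_WF, d_M = d_W gives beta = d exactly -> certain eventual loss
  p_crit <- model_params(b_WH = 1, mu = 0, validate = FALSE)
  d <- duration_dist(10)
  expect_equal(pfix(p_crit, d, 0), 0, tolerance = 1e-6)
  # subcritical mutant
  p_sub <- model_params(b_M = 0.05)
  expect_equal(pfix(p_sub, d, 0), 0)
  # supercritical in the fluctuating baseline: strictly between 0 and 1,
  # and periodic in t0 by construction
  p <- baseline_params()
  d2 <- duration_dist(22.5)
  v <- pfix(p, d2, c(0, 10, 30, 44.9))
  expect_true(all(v > 0 & v < 1))
})

test_that("fixation probability tracks the phase structure of the cycle", {
  # a mutant appearing late in the favourable phase (just before the harsh
  # phase, where the declining wild type frees resources) is better off than
  # one appearing early in the favourable phase at high wild-type density
  p <- baseline_params()
  tau <- 1.5 * baseline_tau0H()
  d <- duration_dist(tau)
  early_F <- pfix(p, d, tau + 0.25 * tau)
  late_F <- pfix(p, d, tau + 0.95 * tau)
  expect_gt(late_F, early_F)
})

test_that("branching-formula pfix matches the lineage-simulation oracle", {
  p <- baseline_params()
  tau <- 0.5 * baseline_tau0H()
  d <- duration_dist(tau)
  for (frac in c(0, 0.5, 1.2, 1.8)) {
    t0 <- frac * tau
    pf <- pfix(p, d, t0)
    mc <- simulate_lineage_establishment(p, d, t0, n_reps = 4000, seed = 19)
    expect_lt(abs(pf - mc$p_hat), 3 * max(mc$se, 1e-3))
  }
})

test_that("mutant-supply integrals vanish appropriately and converge", {
  d <- duration_dist(22.5)
  s0 <- mutant_supply(model_params(mu = 0), d)
  expect_equal(s0$Sigma_H, 0)
  expect_equal(s0$Sigma_F, 0)
  # perfectly harsh environment: no harsh-phase births at all
  s1 <- mutant_supply(baseline_params(), d)
  expect_equal(s1$Sigma_H, 0)
  expect_gt(s1$Sigma_F, 0)
  # imperfect harshness contributes a small harsh supply
  s2 <- mutant_supply(model_params(b_WH = 0.01), d)
  expect_gt(s2$Sigma_H, 0)
  expect_lt(s2$Sigma_H, s2$Sigma_F)
  # grid refinement: default resolution is converged to ~1e-6 relative
  fine <- mutant_supply(baseline_params(), d, n_grid = 16384)
  expect_equal(s1$Sigma_F, fine$Sigma_F, tolerance = 1e-5)
})

test_that("de novo rescue probability composes supply and cycle counts", {
  d <- duration_dist(22.5)
  expect_equal(p_rescue_dn(model_params(mu = 0), d), 0)
  # only realizations with at least one favourable phase can be rescued when
  # Sigma_H = 0 and Sigma_F -> Inf: the limit is 1 - P(q_F = 0)
  pH <- 0.4; pF <- 0.2
  expect_equal(p_rescue_dn_from(pH, pF, 0, 50),
               1 - qF_pmf(pH, pF, 0), tolerance = 1e-10)
  # certain single-phase death: no favourable phase, no rescue without
  # harsh-phase supply
  expect_equal(p_rescue_dn_from(1, 0, 0, 5), 0)
  # with harsh supply the first (k+1 exponent) phase still contributes
  expect_equal(p_rescue_dn_from(1, 0, 0.3, 5), 1 - exp(-0.3), tolerance = 1e-12)
  # monotone decreasing in tau at baseline (sigma = 0)
  p <- baseline_params()
  t0h <- baseline_tau0H()
  pr <- vapply(c(0.4, 0.8, 1.2, 2) * t0h,
               function(tt) p_rescue_dn(p, duration_dist(tt)), numeric(1))
  expect_true(all(diff(pr) < 0))
})

test_that("environmental stochasticity lowers the rescue probability below tau0H", {
  p <- baseline_params()
  tau <- 0.5 * baseline_tau0H()
  pr0 <- p_rescue_dn(p, duration_dist(tau))
  pr_small <- p_rescue_dn(p, duration_dist(tau, 0.1 * tau))
  pr_big <- p_rescue_dn(p, duration_dist(tau, tau))
  expect_gt(pr0, pr_small)
  expect_gt(pr_small, pr_big)
})

test_that("total rescue probability composes standing variation and de novo", {
  expect_equal(p_rescue_total_from(0, 0.37), 0.37)
  expect_equal(p_rescue_total_from(1, 0.0), 1)
  expect_equal(p_rescue_total_from(0.25, 0.4), 0.25 + 0.75 * 0.4)
  p <- baseline_params()
  d <- duration_dist(2 * baseline_tau0H())
  pred <- rescue_prediction(p, d)
  expect_equal(pred$p_r, pred$p_r_SGV + (1 - pred$p_r_SGV) * pred$p_r_DN)
  expect_true(pred$p_r >= pred$p_r_SGV && pred$p_r <= 1)
})

test_that("standing-variation rescue matches simulation in the slow regime", {
  # at tau = 2 tau0H the de novo contribution is tiny, isolating p_r_SGV
  p <- baseline_params()
  d <- duration_dist(2 * baseline_tau0H())
  pred <- rescue_prediction(p, d)
  expect_lt(pred$p_r_DN, 0.01)
  ens <- run_ensemble(p, d, init_mutants = 1, n_reps = 800, seed = 23)
  phat <- ens$p_rescue_hat[["est"]]
  se <- sqrt(phat * (1 - phat) / 800)
  expect_lt(abs(pred$p_r - phat), 3 * se)
})

test_that("appearance time follows the cycle algebra", {
  p <- baseline_params()
  t0h <- baseline_tau0H()
  d <- duration_dist(0.5 * t0h)
  app <- appearance_time(p, d)
  expect_true(app$t_af > 0 && app$t_af < d$mean_tau)
  expect_equal(app$tau_af, (2 * app$q_af_F - 1) * d$mean_tau + app$t_af)
  # frequent mutation (K mu = 10): the rescuing mutant appears during the
  # first favourable environment for any tau
  p_freq <- model_params(mu = 1e-1)
  for (mult in c(0.3, 1, 2)) {
    qa <- appearance_time(p_freq, duration_dist(mult * t0h))$q_af_F
    expect_equal(qa, 1, tolerance = 1e-3)
  }
  # rare mutation: the phase count before success falls with tau and
  # converges to unity once extinction outruns mutant supply
  qas <- vapply(c(0.3, 0.5, 1, 2), function(mult)
    appearance_time(p, duration_dist(mult * t0h))$q_af_F, numeric(1))
  expect_true(all(diff(qas) < 0))
  expect_equal(qas[4], 1, tolerance = 0.02)
  expect_error(appearance_time(model_params(mu = 0), d),
               "conditioning on null event|no absorption")
})

test_that("fast-fluctuation limit evaluates the averaged-environment formulas", {
  p <- baseline_params()
  fl <- fast_limit(p)
  expect_equal(fl$b_tilde, 0.5)
  expect_equal(fl$N_tilde_star, 100 * (1 - 0.1 / 0.5))
  expect_equal(fl$s_tilde, 1)   # b_M d_W / (b_tilde d_M) - 1
  expect_equal(fl$tau_af_tilde, 1 / (1e-3 * 80 * 0.1 * 1))
  expect_gt(fl$T0_tilde, 1e10)  # effectively immortal healthy population
  # no fluctuation: averaged quantities reduce to the favourable ones (the
  # neutral mutant, s_tilde = 0, has no finite appearance time and warns)
  pc <- model_params(b_WH = 1, validate = FALSE)
  flc <- suppressWarnings(fast_limit(pc))
  expect_equal(flc$b_tilde, 1)
  expect_equal(flc$N_tilde_star, 90)
  expect_equal(flc$s_tilde, 0)
  # non-beneficial mutant in the averaged environment is signalled
  expect_warning(fast_limit(model_params(b_M = 0.4, d_M = 0.4, validate = FALSE)),
                 "s_tilde")
})

test_that("harsh-phase mutant supply evaluates the printed approximations", {
  expect_equal(unlist(harsh_mutant_supply(baseline_params())),
               c(N_birth = 0, p_at_least_one_mutant = 0))
  p <- model_params(b_WH = 0.01)
  hs <- harsh_mutant_supply(p)
  expect_equal(hs$N_birth, 0.01 * 90 * (200 - 90) / (2 * 0.1 * 100))  # 4.95
  expect_equal(hs$N_birth, 4.95)
  expect_equal(hs$p_at_least_one_mutant, 1 - 0.999^4.95, tolerance = 1e-12)
})

test_that("imperfect harshness barely changes extinction and rescue", {
  # d_W / b_WH = 10. In the extinction-dominated regime the mean extinction
  # time is set by the shared harsh-survival scale, so the shorthand T0
  # (whose harsh-time term log(N*)/d_W ignores b_WH) agrees within 5%; a few
  # residual births only shift the rescue probability by less than the
  # 0-to-1-scale differences that environmental stochasticity produces.
  t0h <- baseline_tau0H()
  for (mult in c(2, 3)) {
    d <- duration_dist(mult * t0h)
    T0p <- extinction_prediction(model_params(mu = 0), d)$T0_approx
    T0i <- extinction_prediction(model_params(b_WH = 0.01, mu = 0), d)$T0_approx
    expect_lt(abs(T0i - T0p) / T0p, 0.05)
  }
  d <- duration_dist(0.5 * t0h)
  prp <- p_rescue_dn(baseline_params(), d)
  pri <- p_rescue_dn(model_params(b_WH = 0.01), d)
  sigma_effect <- abs(prp - p_rescue_dn(baseline_params(),
                                        duration_dist(0.5 * t0h, 0.05 * t0h)))
  expect_lt(abs(pri - prp), sigma_effect)
})

test_that("growth types order extinction time and rescue probability", {
  # Gompertz >= Richards(beta = 2) >= logistic >= Richards(beta = 0.5) at a
  # mid-range environment duration: larger equilibria and faster growth
  # favour persistence and rescue
  laws <- list(growth_law("gompertz"), growth_law("richards", beta = 2),
               growth_law("logistic"), growth_law("richards", beta = 0.5))
  tau <- 0.5 * baseline_tau0H()
  d <- duration_dist(tau)
  T0s <- vapply(laws, function(gl)
    extinction_prediction(model_params(mu = 0, growth = gl), d)$T0, numeric(1))
  prs <- vapply(laws, function(gl)
    p_rescue_dn(model_params(growth = gl), d), numeric(1))
  expect_true(all(diff(T0s) <= 0))
  expect_true(all(diff(prs) <= 0))
})
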