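test_that("master equation reproduces the pure-death closed forms", {
  p <- model_params(mu = 0)           # b_WH = 0
  N0 <- 90
  tt <- c(0.5, 2, 10, 25, 60, 100)
  sol <- harsh_phase_solution(p, N0, tt)
  for (i in seq_along(tt)) {
    probs <- sol$P[i, ]
    expect_equal(sum(probs), 1, tolerance = 1e-8)
    # extinction mass (1 - e^{-d t})^N0 and binomial size marginal
    expect_equal(probs[1], pure_death_extinction_cdf(tt[i], N0, 0.1),
                 tolerance = 1e-8)
    expect_equal(probs[1 + 0:N0][-1],
                 stats::dbinom(1:N0, N0, exp(-0.1 * tt[i]))[],
                 tolerance = 1e-8)
  }
  # extinction mass is non-decreasing in time
  expect_true(all(diff(sol$P[, 1]) >= -1e-12))
  # t = 0 is a point mass at N0
  sol0 <- harsh_phase_solution(p, N0, 0)
  expect_equal(sol0$P[1, N0 + 1], 1, tolerance = 1e-12)
})

test_that("imperfectly harsh master equation matches a matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  p <- model_params(b_WH = 0.01, mu = 0)
  K <- p$K
  n <- 0:K
  lam <- n * p$b_WH * density_factor(p$growth, n, K)
  lam[K + 1] <- 0
  mu_ <- n * p$d_W
  Q <- matrix(0, K + 1, K + 1)
  for (i in seq_len(K + 1)) {
    if (i < K + 1) Q[i, i + 1] <- lam[i]
    if (i > 1) Q[i, i - 1] <- mu_[i]
    Q[i, i] <- -(lam[i] + mu_[i])
  }
  t <- 60
  P_oracle <- as.numeric(Matrix::expm(Matrix::Matrix(t(Q) * t)) %*%
                           replace(numeric(K + 1), 91, 1))
  sol <- harsh_phase_solution(p, 90, t)
  expect_equal(sol$P[1, ], P_oracle, tolerance = 1e-7)
})

test_that("harsh-phase extinction probability behaves across tau", {
  p <- baseline_params()
  t0h <- baseline_tau0H()
  expect_lt(p0_harsh(p, duration_dist(1e-3)), 1e-10)
  expect_gte(p0_harsh(p, duration_dist(10 * t0h)), 0.999)
  # non-decreasing in tau (sigma = 0)
  taus <- c(0.3, 0.7, 1, 1.6, 3) * t0h
  ph <- vapply(taus, function(tt) p0_harsh(p, duration_dist(tt)), numeric(1))
  expect_true(all(diff(ph) >= -1e-12))

  # sigma > 0 quadrature vs Monte-Carlo over sampled durations with the
  # pure-death closed-form CDF (1e5 draws)
  d <- duration_dist(45, 4.5)
  quad <- p0_harsh(p, d)
  set.seed(4)
  draws <- sample_duration(d, 1e5)
  mc <- pure_death_extinction_cdf(draws, 90, 0.1)
  se <- stats::sd(mc) / sqrt(length(mc))
  expect_lt(abs(quad - mean(mc)), 3 * se)
})

test_that("end-of-harsh distribution is the conditioned binomial for b_WH = 0", {
  p <- baseline_params()
  tau <- 22.5
  w <- end_of_harsh_distribution(p, duration_dist(tau))
  expect_equal(sum(w), 1, tolerance = 1e-9)
  q <- exp(-0.1 * tau)
  ref <- stats::dbinom(1:100, 90, q) / (1 - (1 - q)^90)
  expect_equal(w, ref, tolerance = 1e-7)
  # tau -> 0: mass concentrates near N0
  w0 <- end_of_harsh_distribution(p, duration_dist(0.05))
  expect_gt(sum(w0[85:95]), 0.999)
  expect_error(end_of_harsh_distribution(p, duration_dist(60 * baseline_tau0H())),
               "conditioning on null event")
})

test_that("rapid extinction probability matches theory and simulation", {
  p <- baseline_params()
  expect_equal(rapid_extinction_prob(p, 0), 1)
  # low-n approximation (d_W/b_WF)^n within 10% at baseline
  for (n in 1:3) {
    expect_equal(rapid_extinction_prob(p, n), 0.1^n, tolerance = 0.1)
  }
  # gompertz low-n approximation (d_W / (b_WF log K))^n
  pg <- model_params(growth = growth_law("gompertz"))
  expect_equal(rapid_extinction_prob(pg, 1), 0.1 / log(100), tolerance = 0.1)
  # strictly decreasing in n
  u <- rapid_extinction_prob(p, 0:89)
  expect_true(all(diff(u) < 0))
  # exact independent oracle: direct linear solve of the hitting system
  K <- p$K; M <- 90
  lam <- (1:(M - 1)) * p$b_WF * density_factor(p$growth, 1:(M - 1), K)
  mu_ <- (1:(M - 1)) * p$d_W
  A <- matrix(0, M - 1, M - 1); rhs <- numeric(M - 1)
  for (i in 1:(M - 1)) {
    tot <- lam[i] + mu_[i]
    A[i, i] <- 1
    if (i > 1) A[i, i - 1] <- -mu_[i] / tot else rhs[i] <- mu_[i] / tot
    if (i < M - 1) A[i, i + 1] <- -lam[i] / tot
  }
  expect_equal(rapid_extinction_prob(p, 1:(M - 1)), solve(A, rhs),
               tolerance = 1e-10)
  # SSA first-passage sanity check at n = 2
  mc <- simulate_rapid_extinction(p, n0 = 2, n_reps = 1e4, seed = 12)
  expect_lt(abs(rapid_extinction_prob(p, 2) - mc$p_hat), 4 * mc$se)
})

test_that("favourable-phase extinction probability is consistent with simulation", {
  p <- model_params(mu = 0)
  tau <- 45
  d <- duration_dist(tau)
  pF <- p0_fav(p, d)
  expect_true(pF >= 0 && pF <= 1)
  # bounded by the single-individual rapid-extinction scale
  expect_lt(pF, 0.1 * 1.2)
  # tau -> 0 leaves the population near N*, rapid extinction negligible
  expect_lt(p0_fav(p, duration_dist(0.1)), 1e-10)

  # empirical: among realizations surviving the first harsh phase (T0 > tau),
  # the fraction that die during the first favourable phase (T0 <= 2 tau)
  set.seed(21)
  res <- run_ensemble(p, d, n_reps = 1e4, seed = 21)
  t0 <- res$reps$T0
  surv <- t0 > tau
  cond <- mean(t0[surv] <= 2 * tau & res$reps$extinct_phase[surv] == "F")
  se <- sqrt(cond * (1 - cond) / sum(surv))
  expect_lt(abs(pF - cond), 3 * se)
})

test_that("cycle-count law is geometric with the composed survival probability", {
  expect_equal(qF_pmf(1, 0.3, 0), 1)
  expect_equal(mean_qF(1, 0.3), 0)
  expect_equal(mean_qF(0.5, 0), 1)
  expect_error(mean_qF(0, 0), "no absorption")

  pH <- 0.23; pF <- 0.08
  k <- 0:300
  pmf <- qF_pmf(pH, pF, k)
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  # factored printed form (1-pH)^k (1-pF)^k (pH + (1-pH) pF)
  expect_equal(pmf, (1 - pH)^k * (1 - pF)^k * (pH + (1 - pH) * pF),
               tolerance = 1e-14)
  # mean of the truncated pmf equals the closed form s/(1-s)
  expect_equal(mean_qF(pH, pF), sum(k * pmf), tolerance = 1e-12)
  # printed ratio form: (1 - pH - pF + pH pF) / (pH + pF - pH pF)
  s <- (1 - pH) * (1 - pF)
  expect_equal(mean_qF(pH, pF), s / (1 - s), tolerance = 1e-14)
  expect_equal(s / (1 - s),
               (1 - pH - pF + pH * pF) / (pH + pF - pH * pF),
               tolerance = 1e-14)

  # Bernoulli-cycle Monte-Carlo oracle: geometric draws with the same
  # per-cycle death probability
  set.seed(13)
  dies <- 1 - (1 - pH) * (1 - pF)
  draws <- stats::rgeom(1e5, dies)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean_qF(pH, pF) - mean(draws)), 3 * se)
})

test_that("extinction-time prediction has the right limits and structure", {
  p <- model_params(mu = 0)
  t0h <- baseline_tau0H()
  # very slow fluctuations: T0 -> mean harsh survival time (~ H_90 / d)
  slow <- extinction_prediction(p, duration_dist(20 * t0h))
  expect_equal(slow$T0, pure_death_mean_absorption(90, 0.1), tolerance = 0.03)
  expect_equal(slow$tau_0H_approx, log(90) / 0.1, tolerance = 1e-10)
  # stochastic durations shorten persistence below the harsh-survival scale
  tau <- 0.5 * t0h
  det <- extinction_prediction(p, duration_dist(tau))
  sto <- extinction_prediction(p, duration_dist(tau, 0.1 * tau))
  expect_lt(sto$T0, det$T0)
  # probabilities and times are coherent
  for (x in list(det, sto)) {
    expect_true(x$p0_H >= 0 && x$p0_H <= 1)
    expect_true(x$p0_F >= 0 && x$p0_F <= 1)
    expect_true(x$omega_F >= 0 && x$omega_F <= 1)
    expect_gt(x$T0, 0)
  }
})
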