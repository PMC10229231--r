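#' Periodic mean-field cycle background
#'
#' Precomputes, on a uniform grid over one full environmental cycle
#' `[0, 2 tau]` (harsh on `[0, tau)`, favourable on `[tau, 2 tau)`), the
#' mean-field wild-type trajectory (harsh phase started at the favourable
#' equilibrium `N*`, favourable phase started at the end-of-harsh size), the
#' mutant birth-rate profile `beta(s) = b_M g(<N_W>(s)/K)`, and the cumulative
#' integrals needed for fixation probabilities. The orbit is continued
#' periodically: environmental stochasticity enters the rescue theory only
#' through the per-phase extinction probabilities, so fixation is always
#' assessed against the mean-duration periodic background.
#'
#' @param params A [model_params()].
#' @param dist A [duration_dist()] (only `mean_tau` is used here).
#' @param n_grid Panels per phase for the trapezoidal integrals.
#' @return An internal list used by [pfix()] and [mutant_supply()].
#' @keywords internal
rescue_cycle <- function(params, dist, n_grid = 4096) {
  tau <- dist$mean_tau
  K <- params$K
  nstar <- equilibrium_size(params$growth, params$b_WF, params$d_W, K)
  tH <- seq(0, tau, length.out = n_grid + 1)
  NH <- mean_trajectory(params, "H", N0 = nstar, t = tH)
  NF <- mean_trajectory(params, "F", N0 = NH[n_grid + 1], t = tH)
  s <- c(tH, tau + tH[-1])
  NW <- c(NH, NF[-1])
  beta <- params$b_M * density_factor(params$growth, NW, K)
  R <- as.numeric(pracma::cumtrapz(s, params$d_M - beta))
  Delta <- R[length(R)]
  # A_i = int_{s_i}^{2 tau} exp(R(u) - R_i) du by backward recursion with
  # per-step rescaling: exp(R) spans many e-folds over a cycle, so the naive
  # difference of cumulative integrals cancels catastrophically
  n <- length(s)
  h <- diff(s)
  edR <- exp(diff(R))
  A <- numeric(n)
  for (i in (n - 1):1) A[i] <- edR[i] * A[i + 1] + h[i] / 2 * (1 + edR[i])
  C <- A[1]  # full-cycle integral int_0^{2 tau} exp(R) du (R(0) = 0)
  list(params = params, tau = tau, s = s, tH = tH, NH = NH, NF = NF,
       NW = NW, beta = beta, R = R, A = A, C = C, Delta = Delta)
}

# pfix evaluated at arbitrary cycle positions using a precomputed cycle:
# J(t0) = d_M * (A(t0) + C exp(Delta - R(t0)) / (1 - exp(Delta))), where the
# second term sums the geometric contributions of all later periods
# (Delta - R(t0) <= 0, so the factor never overflows).
pfix_from_cycle <- function(cycle, t0) {
  d_M <- cycle$params$d_M
  if (cycle$Delta >= 0) return(rep(0, length(t0)))
  R0 <- stats::approx(cycle$s, cycle$R, xout = t0)$y
  A0 <- stats::approx(cycle$s, cycle$A, xout = t0)$y
  J <- d_M * (A0 + cycle$C * exp(cycle$Delta - R0) / (1 - exp(cycle$Delta)))
  pmin(pmax(1 / (1 + J), 0), 1)
}

#' Fixation probability of a single mutant appearing at cycle time t0
#'
#' Survival probability of a time-inhomogeneous linear birth-death lineage
#' started from one mutant at cycle position `t0` (harsh phase occupies
#' `[0, tau)`, favourable `[tau, 2 tau)`), with birth rate
#' `beta(s) = b_M g(<N_W>(s)/K)` along the periodic mean-field wild-type
#' orbit and death rate `d_M`:
#' `pfix(t0) = 1 / (1 + integral_{t0}^{Inf} d_M exp(rho(u)) du)` with
#' `rho(u) = integral_{t0}^{u} (d_M - beta(s)) ds`. The infinite integral is
#' evaluated exactly over periods by geometric summation (the per-period
#' increment of `rho` is constant by periodicity). Returns 0 when the
#' per-period net lineage growth is non-positive.
#'
#' @inheritParams rescue_cycle
#' @param t0 Cycle position(s) in `[0, 2 tau)`. `t0 = 0` is the start of the
#'   first harsh phase, so `pfix(0)` is the fixation probability of a single
#'   pre-existing mutant (standing genetic variation).
#' @return Probability vector, one per element of `t0`.
#' @export
pfix <- function(params, dist, t0, n_grid = 4096) {
  if (any(t0 < 0 | t0 >= 2 * dist$mean_tau))
    stop("`t0` must lie in [0, 2*tau)")
  cycle <- rescue_cycle(params, dist, n_grid)
  pfix_from_cycle(cycle, t0)
}

#' Mutant-supply integrals over one environmental cycle
#'
#' Expected numbers of mutants that appear *and fix*, per cycle, in the harsh
#' and favourable phases:
#' `Sigma_H = mu b_WH integral_0^tau <N_W>_H(t) g(<N_W>_H(t)/K) pfix(t) dt`
#' and
#' `Sigma_F = mu b_WF integral_0^tau <N_W>_F(t) g(<N_W>_F(t)/K) pfix(t+tau) dt`,
#' with the mean-field approximation `<N_W g(N_W/K)> ~ <N_W> g(<N_W>/K)`. For
#' the logistic law the density factor is `1 - <N_W>/K`; other laws use their
#' own factor `g`.
#'
#' @inheritParams rescue_cycle
#' @return List with `Sigma_H`, `Sigma_F` (dimensionless, `>= 0`).
#' @export
mutant_supply <- function(params, dist, n_grid = 4096) {
  cycle <- rescue_cycle(params, dist, n_grid)
  mutant_supply_from_cycle(cycle)
}

mutant_supply_from_cycle <- function(cycle) {
  params <- cycle$params
  K <- params$K
  tH <- cycle$tH
  SH <- if (params$mu == 0 || params$b_WH == 0) 0 else {
    wH <- cycle$NH * density_factor(params$growth, cycle$NH, K) *
      pfix_from_cycle(cycle, tH)
    params$mu * params$b_WH * pracma::trapz(tH, wH)
  }
  SF <- if (params$mu == 0) 0 else {
    tF <- pmin(cycle$tau + tH, 2 * cycle$tau * (1 - 1e-12))
    wF <- cycle$NF * density_factor(params$growth, cycle$NF, K) *
      pfix_from_cycle(cycle, tF)
    params$mu * params$b_WF * pracma::trapz(tH, wF)
  }
  list(Sigma_H = max(SH, 0), Sigma_F = max(SF, 0))
}

# number of cycle-count terms needed for tail mass < tol; capped (the cap
# switches callers to closed-form summation)
qF_kmax <- function(s, tol = 1e-12) {
  if (s <= 0) return(0L)
  if (s >= 1 - 1e-14) return(5000001L)
  as.integer(min(ceiling(log(tol) / log(s)), 5e6)) + 1L
}

#' Rescue probability by de novo mutations
#'
#' The probability that a de novo mutant appears and fixes before extinction:
#' `p_r_DN = sum_k P(q_F = k) (1 - exp(-(k+1) Sigma_H - k Sigma_F))` — a
#' realization that undergoes `k` favourable phases experiences `k+1` harsh
#' phases, and rescue requires at least one fixing mutant among those phases.
#' The geometric series is truncated at tail mass `< 1e-12` (a closed form is
#' used when the per-cycle survival is so close to 1 that the series would be
#' excessively long).
#'
#' `p_rescue_dn_from()` composes the same quantity from precomputed parts.
#'
#' @inheritParams rescue_cycle
#' @param p0_H,p0_F Per-phase extinction probabilities.
#' @param Sigma_H,Sigma_F Mutant-supply integrals (see [mutant_supply()]).
#' @return Probability in `[0, 1]`.
#' @export
p_rescue_dn <- function(params, dist, n_grid = 4096) {
  sup <- mutant_supply(params, dist, n_grid)
  pH <- p0_harsh(params, dist)
  p_rescue_dn_from(pH, p0_fav_or_zero(params, dist, pH),
                   sup$Sigma_H, sup$Sigma_F)
}

#' @rdname p_rescue_dn
#' @export
p_rescue_dn_from <- function(p0_H, p0_F, Sigma_H, Sigma_F) {
  s <- cycle_survival(p0_H, p0_F)
  if (Sigma_H <= 0 && Sigma_F <= 0) return(0)
  kmax <- qF_kmax(s)
  if (kmax > 5e6) {
    # geometric closed form of the same series
    return(min(max(1 - (1 - s) * exp(-Sigma_H) /
                     (1 - s * exp(-(Sigma_H + Sigma_F))), 0), 1))
  }
  k <- 0:kmax
  val <- sum(s^k * (1 - s) * (1 - exp(-(k + 1) * Sigma_H - k * Sigma_F)))
  min(max(val, 0), 1)
}

#' Total rescue probability (standing variation + de novo)
#'
#' With a single pre-existing mutant, `p_r_SGV = pfix(0)` and
#' `p_r = p_r_SGV + (1 - p_r_SGV) p_r_DN`: the population is rescued either by
#' the pre-existing lineage or, failing that, by a de novo mutant.
#'
#' @inheritParams rescue_cycle
#' @param p_r_SGV,p_r_DN Component probabilities, for direct composition.
#' @return Probability in `[p_r_SGV, 1]`.
#' @export
p_rescue_total <- function(params, dist, n_grid = 4096) {
  p_rescue_total_from(pfix(params, dist, 0, n_grid),
                      p_rescue_dn(params, dist, n_grid))
}

#' @rdname p_rescue_total
#' @export
p_rescue_total_from <- function(p_r_SGV, p_r_DN) {
  p_r_SGV + (1 - p_r_SGV) * p_r_DN
}

#' Mean appearance time of the de novo mutant that rescues the population
#'
#' Conditional on rescue by a de novo mutation, the rescuing mutant appears on
#' average at `tau_af = (2 <q_af_F> - 1) tau + t_af`, where `<q_af_F>` is the
#' mean number of favourable environments that occur before a mutant appears
#' and fixes,
#' `<q_af_F> = sum_k P(q_F = k) sum_{q=0}^{k} q exp(-(q-1) Sigma_F)`
#' `(1 - exp(-Sigma_F)) / p_r`,
#' and `t_af` is the fixation-weighted mean appearance position within a
#' favourable phase:
#' `t_af = integral_0^tau t w(t) dt / integral_0^tau w(t) dt` with
#' `w(t) = mu b_WF <N_W>_F(t) g(<N_W>_F(t)/K) pfix(t + tau)`. Harsh-phase
#' mutants are neglected (their supply is zero for `b_WH = 0` and negligible
#' when `d_W/b_WH >> 1`).
#'
#' @inheritParams rescue_cycle
#' @param normalization `"dn"` (default) normalizes by the de novo rescue
#'   probability — the exact conditioning when rescue is by de novo mutation —
#'   or `"total"` by the combined probability including a pre-existing mutant.
#' @return List with `q_af_F`, `t_af`, `tau_af`.
#' @export
appearance_time <- function(params, dist, n_grid = 4096,
                            normalization = c("dn", "total")) {
  normalization <- match.arg(normalization)
  cycle <- rescue_cycle(params, dist, n_grid)
  sup <- mutant_supply_from_cycle(cycle)
  pH <- p0_harsh(params, dist)
  pF <- p0_fav_or_zero(params, dist, pH)
  p_dn <- p_rescue_dn_from(pH, pF, sup$Sigma_H, sup$Sigma_F)
  if (p_dn <= 0) stop("conditioning on null event: p_r_DN = 0")
  norm <- switch(normalization,
    dn = p_dn,
    total = p_rescue_total_from(pfix_from_cycle(cycle, 0), p_dn))
  s <- cycle_survival(pH, pF)
  kmax <- min(qF_kmax(s), 2e5)
  SF <- sup$Sigma_F
  # inner sum T(k) = sum_{q=0}^{k} q e^{-(q-1) SF} (1 - e^{-SF}), built
  # incrementally across k; it saturates once q >> 1/Sigma_F, so the
  # geometric cycle-count tail beyond kmax contributes T(kmax) * s^(kmax+1)
  k <- 0:kmax
  qv <- 0:kmax
  inner_terms <- qv * exp(-(qv - 1) * SF) * (1 - exp(-SF))
  Tk <- cumsum(inner_terms)
  q_af <- (sum(qF_pmf(pH, pF, k) * Tk) +
             Tk[kmax + 1] * s^(kmax + 1)) / norm

  tH <- cycle$tH
  tF <- pmin(cycle$tau + tH, 2 * cycle$tau * (1 - 1e-12))
  w <- params$mu * params$b_WF * cycle$NF *
    density_factor(params$growth, cycle$NF, params$K) *
    pfix_from_cycle(cycle, tF)
  wtot <- pracma::trapz(tH, w)
  t_af <- if (wtot > 0) pracma::trapz(tH, tH * w) / wtot else NA_real_
  list(q_af_F = q_af, t_af = t_af,
       tau_af = (2 * q_af - 1) * dist$mean_tau + t_af)
}

#' Fast-fluctuation (self-averaged) limit
#'
#' For environment durations much shorter than all demographic time scales the
#' dynamics reduce to a constant environment with averaged birth rate
#' `b_tilde = (b_WF + b_WH)/2`, effective equilibrium size
#' `N_tilde* = equilibrium_size(growth, b_tilde, d_W, K)`, mutant selection
#' coefficient `s_tilde = b_M d_W / (b_tilde d_M) - 1`, mean
#' appearance-and-fixation time `tau_af_tilde = 1/(mu N_tilde* d_W s_tilde)`
#' (for `s_tilde > 0`), and mean extinction time `T0_tilde` of the effective
#' constant-environment chain (first-passage recursion on the birth-death
#' generator; astronomically large for healthy populations).
#'
#' @param params A [model_params()].
#' @return A list of class `fast_limit` with `b_tilde`, `N_tilde_star`,
#'   `s_tilde`, `tau_af_tilde` (`NA` with a warning when `s_tilde <= 0`),
#'   `T0_tilde`.
#' @export
fast_limit <- function(params) {
  b_t <- (params$b_WF + params$b_WH) / 2
  if (!(b_t > params$d_W))
    stop("averaged birth rate does not exceed the death rate; no effective equilibrium")
  n_t <- equilibrium_size(params$growth, b_t, params$d_W, params$K)
  s_t <- params$b_M * params$d_W / (b_t * params$d_M) - 1
  tau_af_t <- if (s_t > 0) {
    1 / (params$mu * n_t * params$d_W * s_t)
  } else {
    warning("s_tilde <= 0: mutant not beneficial in the averaged environment")
    NA_real_
  }
  # mean extinction time from round(N~*): h_m = mean time m -> m-1 satisfies
  # h_m = 1/mu_m + (lambda_m/mu_m) h_{m+1}, backward from m = K
  K <- params$K
  n <- 1:K
  lam <- n * b_t * density_factor(params$growth, n, K)
  mu_ <- n * params$d_W
  h <- numeric(K)
  h[K] <- 1 / mu_[K]
  if (K > 1) for (m in (K - 1):1) h[m] <- 1 / mu_[m] + (lam[m] / mu_[m]) * h[m + 1]
  T0_t <- sum(h[seq_len(round(n_t))])
  structure(list(b_tilde = b_t, N_tilde_star = n_t, s_tilde = s_t,
                 tau_af_tilde = tau_af_t, T0_tilde = T0_t),
            class = "fast_limit")
}

#' Mutant supply in an imperfectly harsh environment
#'
#' An imperfectly harsh environment (`0 < b_WH << d_W`) allows some births:
#' approximately `N_birth = b_WH N* (2K - N*) / (2 d_W K)` births occur per
#' harsh phase (the declining population integrates to `N*/d_W` individuals x
#' time, each giving birth at the mean density-regulated rate), and the
#' probability that at least one of them is a mutant is
#' `1 - (1 - mu)^N_birth`.
#'
#' @param params A [model_params()].
#' @return List with `N_birth` and `p_at_least_one_mutant`.
#' @export
harsh_mutant_supply <- function(params) {
  if (params$b_WH == 0) return(list(N_birth = 0, p_at_least_one_mutant = 0))
  nstar <- equilibrium_size(params$growth, params$b_WF, params$d_W, params$K)
  nb <- params$b_WH * nstar * (2 * params$K - nstar) / (2 * params$d_W * params$K)
  list(N_birth = nb, p_at_least_one_mutant = 1 - (1 - params$mu)^nb)
}

#' Bundled analytical rescue prediction
#'
#' Computes all rescue-side quantities in one pass (sharing the cycle
#' background and master-equation solves): the mutant-supply integrals, the
#' standing-variation and de novo rescue probabilities, their combination,
#' and the appearance-time decomposition.
#'
#' @inheritParams appearance_time
#' @return A list of class `rescue_prediction` with `Sigma_H`, `Sigma_F`,
#'   `p_r_SGV`, `p_r_DN`, `p_r`, `q_af_F`, `t_af`, `tau_af`.
#' @export
rescue_prediction <- function(params, dist, n_grid = 4096) {
  cycle <- rescue_cycle(params, dist, n_grid)
  sup <- mutant_supply_from_cycle(cycle)
  pH <- p0_harsh(params, dist)
  pF <- p0_fav_or_zero(params, dist, pH)
  p_sgv <- pfix_from_cycle(cycle, 0)
  p_dn <- p_rescue_dn_from(pH, pF, sup$Sigma_H, sup$Sigma_F)
  app <- if (p_dn > 0) {
    appearance_time(params, dist, n_grid)
  } else {
    list(q_af_F = NA_real_, t_af = NA_real_, tau_af = NA_real_)
  }
  structure(list(Sigma_H = sup$Sigma_H, Sigma_F = sup$Sigma_F,
                 p_r_SGV = p_sgv, p_r_DN = p_dn,
                 p_r = p_rescue_total_from(p_sgv, p_dn),
                 q_af_F = app$q_af_F, t_af = app$t_af, tau_af = app$tau_af),
            class = "rescue_prediction")
}

#' @export
print.rescue_prediction <- function(x, ...) {
  cat("<rescue_prediction>\n")
  cat(sprintf("  Sigma_H = %.5g   Sigma_F = %.5g\n", x$Sigma_H, x$Sigma_F))
  cat(sprintf("  p_r_SGV = %.5f  p_r_DN = %.5f  p_r = %.5f\n",
              x$p_r_SGV, x$p_r_DN, x$p_r))
  if (!is.na(x$tau_af))
    cat(sprintf("  q_af_F = %.4f   t_af = %.3f   tau_af = %.3f\n",
                x$q_af_F, x$t_af, x$tau_af))
  invisible(x)
}
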