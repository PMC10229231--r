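#' Rescue-declaration threshold
#'
#' A realization is declared "rescued" once the mutant count reaches
#' `ceil(frac * N_M*)`, with `N_M*` the mutant equilibrium size. From that
#' size the residual extinction probability of the mutant population is
#' astronomically small (of order `(d_M/b_M)^threshold`), so the declaration
#' is effectively exact at the default `frac = 0.9`.
#'
#' @param params A [model_params()].
#' @param frac Fraction of the mutant equilibrium size, in `(0, 1]`.
#' @return Integer threshold `>= 1`.
#' @export
rescue_threshold <- function(params, frac = 0.9) {
  if (!(params$b_M > params$d_M))
    stop("mutant must be viable (b_M > d_M) to define a rescue threshold")
  nm <- equilibrium_size(params$growth, params$b_M, params$d_M, params$K)
  max(1L, as.integer(ceiling(frac * nm)))
}

#' Simulate one realization of the eco-evolutionary process
#'
#' Exact event-driven (Gillespie) simulation of the two-genotype
#' density-regulated birth-death process over an alternating harsh/favourable
#' environment (harsh phase first). Event rates in environment `a` are:
#' wild-type birth `N_W b_W,a g(N_tot/K)`, wild-type death `N_W d_W`, mutant
#' birth `N_M b_M g(N_tot/K)`, mutant death `N_M d_M`, with
#' `N_tot = N_W + N_M` (both genotypes compete for the same resource). Each
#' wild-type birth yields a mutant offspring with probability `mu`; mutant
#' births never mutate back. Time-inhomogeneity is handled by capping each
#' exponential waiting time at the next environmental switch and redrawing,
#' which is exact because rates are constant within a phase. The realization
#' absorbs either at total extinction (`fate = "extinct"`) or when the mutant
#' count reaches [rescue_threshold()] (`fate = "rescued"`).
#'
#' Uses R's global RNG stream; call `set.seed()` for reproducibility.
#'
#' @param params A [model_params()].
#' @param dist A [duration_dist()].
#' @param init_mutants Number of pre-existing mutants at time 0 (0 or 1:
#'   standing genetic variation).
#' @param init_wt Initial wild-type count; defaults to the favourable
#'   equilibrium size rounded to the nearest integer.
#' @param rescue_frac Passed to [rescue_threshold()].
#' @param max_events Guard against non-absorbing parameterizations.
#' @param trajectory Record the full `(t, N_W, N_M, phase)` trajectory?
#' @param t_max Optional censoring horizon: the realization stops with
#'   `fate = "censored"` if neither absorption occurred by this time (useful
#'   for trajectory studies and non-absorbing parameter sets).
#' @return A list of class `sim_outcome` with elements `fate`, `T0`
#'   (extinction time, extinct only), `rescue_time` (rescued only), `q_F`
#'   (completed favourable phases before absorption), `extinct_phase`,
#'   `first_success_mutant_time` (appearance time of the oldest surviving
#'   mutant lineage at rescue declaration), `n_mutation_events`, `n_events`
#'   and optionally `trajectory`.
#' @examples
#' set.seed(1)
#' simulate_realization(model_params(), duration_dist(22.5))
#' @export
simulate_realization <- function(params, dist, init_mutants = 0,
                                 init_wt = NULL, rescue_frac = 0.9,
                                 max_events = 1e9, trajectory = FALSE,
                                 t_max = Inf) {
  if (!init_mutants %in% c(0L, 1L))
    stop("`init_mutants` must be 0 or 1 (a single pre-existing mutant)")
  if (is.null(init_wt)) {
    init_wt <- as.integer(round(
      equilibrium_size(params$growth, params$b_WF, params$d_W, params$K)))
  }
  thr <- rescue_threshold(params, rescue_frac)
  out <- ssa_realization_cpp(
    params$b_WF, params$b_WH, params$d_W, params$b_M, params$d_M, params$mu,
    params$K, growth_kind_code(params$growth), params$growth$beta,
    dist$mean_tau, dist$sigma, as.integer(init_wt), as.integer(init_mutants),
    thr, max_events, trajectory, t_max)
  class(out) <- "sim_outcome"
  out
}

#' @export
print.sim_outcome <- function(x, ...) {
  if (x$fate == "censored") {
    cat(sprintf("<sim_outcome: censored (no absorption by horizon), N_W = %d, N_M = %d>\n",
                x$N_W_final, x$N_M_final))
    return(invisible(x))
  }
  if (x$fate == "extinct") {
    cat(sprintf("<sim_outcome: extinct at t = %.3f (phase %s), q_F = %d, %d mutation events>\n",
                x$T0, x$extinct_phase, x$q_F, x$n_mutation_events))
  } else {
    cat(sprintf("<sim_outcome: rescued at t = %.3f, lineage appeared at t = %.3f, q_F = %d>\n",
                x$rescue_time, x$first_success_mutant_time, x$q_F))
  }
  invisible(x)
}

#' Run an ensemble of independent realizations
#'
#' Replicates [simulate_realization()] with independent per-replicate RNG
#' streams derived from a single root seed (sub-seeds drawn once via
#' `sample.int`, then `set.seed` per replicate), so the output is bit-identical
#' for identical inputs and any replicate can be reproduced in isolation.
#'
#' @inheritParams simulate_realization
#' @param n_reps Number of replicates, `>= 1`.
#' @param seed Root integer seed.
#' @return A list of class `ensemble_summary`: `n_reps`, `p_rescue_hat` (with
#'   95% binomial CI), `mean_T0_given_extinct`, `mean_qF`,
#'   `mean_appearance_time_given_rescue` (each with 95% t-based CIs),
#'   `omega_F_hat` (proportion of extinctions in favourable phases), `seed`,
#'   `rng` metadata, and the per-replicate data frame `reps`.
#' @export
run_ensemble <- function(params, dist, init_mutants = 0, n_reps, seed,
                         init_wt = NULL, rescue_frac = 0.9, max_events = 1e9) {
  if (!is.numeric(n_reps) || n_reps < 1) stop("`n_reps` must be >= 1")
  n_reps <- as.integer(n_reps)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    set.seed(sub_seeds[i])
    o <- simulate_realization(params, dist, init_mutants = init_mutants,
                              init_wt = init_wt, rescue_frac = rescue_frac,
                              max_events = max_events)
    rows[[i]] <- data.frame(
      rep = i, fate = o$fate, T0 = o$T0, rescue_time = o$rescue_time,
      q_F = o$q_F,
      extinct_phase = ifelse(is.na(o$extinct_phase), NA_character_, o$extinct_phase),
      first_success_mutant_time = o$first_success_mutant_time,
      n_mutation_events = o$n_mutation_events, stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  rescued <- reps$fate == "rescued"

  binom_ci <- function(k, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    ci <- stats::binom.test(k, n)$conf.int
    c(ci[1], ci[2])
  }
  mean_ci <- function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    if (length(x) < 2 || stats::sd(x) == 0) return(c(m, m, m))
    half <- stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
    c(m, m - half, m + half)
  }
  pr <- mean(rescued)
  pci <- binom_ci(sum(rescued), n_reps)
  t0 <- mean_ci(reps$T0[!rescued])
  qf <- mean_ci(reps$q_F)
  ta <- mean_ci(reps$first_success_mutant_time[rescued])
  ext_F <- sum(reps$extinct_phase == "F", na.rm = TRUE)
  n_ext <- sum(!rescued)
  structure(list(
    n_reps = n_reps,
    p_rescue_hat = c(est = pr, lo = min(pci[1], pr), hi = max(pci[2], pr)),
    mean_T0_given_extinct = c(est = t0[1], lo = t0[2], hi = t0[3]),
    mean_qF = c(est = qf[1], lo = qf[2], hi = qf[3]),
    mean_appearance_time_given_rescue = c(est = ta[1], lo = ta[2], hi = ta[3]),
    omega_F_hat = if (n_ext > 0) ext_F / n_ext else NA_real_,
    seed = seed,
    rng = list(kind = RNGkind()[1], stream = "per-replicate sub-seeds via sample.int"),
    reps = reps), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary: %d replicates (seed %s)>\n", x$n_reps,
              format(x$seed)))
  cat(sprintf("  P(rescue)        : %.4f  [%.4f, %.4f]\n",
              x$p_rescue_hat["est"], x$p_rescue_hat["lo"], x$p_rescue_hat["hi"]))
  cat(sprintf("  E[T0 | extinct]  : %.3f  [%.3f, %.3f]\n",
              x$mean_T0_given_extinct["est"], x$mean_T0_given_extinct["lo"],
              x$mean_T0_given_extinct["hi"]))
  cat(sprintf("  E[q_F]           : %.3f\n", x$mean_qF["est"]))
  if (!is.na(x$mean_appearance_time_given_rescue["est"]))
    cat(sprintf("  E[t_app | rescue]: %.3f  [%.3f, %.3f]\n",
                x$mean_appearance_time_given_rescue["est"],
                x$mean_appearance_time_given_rescue["lo"],
                x$mean_appearance_time_given_rescue["hi"]))
  if (!is.na(x$omega_F_hat))
    cat(sprintf("  omega_F (empir.) : %.4f\n", x$omega_F_hat))
  invisible(x)
}

#' Write per-replicate ensemble results to CSV
#'
#' @param ensemble An `ensemble_summary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, path) {
  utils::write.csv(ensemble$reps, path, row.names = FALSE, na = "")
  invisible(path)
}
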