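#' Sweep configuration
#'
#' Describes a grid experiment: for each combination of growth law,
#' environment duration and duration standard deviation, the sweep computes
#' the analytical extinction and rescue predictions and a simulated ensemble
#' summary. Durations may be given in multiples of the harsh-survival time
#' `tau0_H` (the default, which makes grids transfer across carrying
#' capacities) or in absolute time.
#'
#' @param base_params A [model_params()].
#' @param tau_grid Environment durations (non-empty).
#' @param tau_units `"tau0H"` (multiples of [tau0_harsh()]) or `"absolute"`.
#' @param sigma_values Duration standard deviations; entries may be given as
#'   fractions of tau via `sigma_units = "tau"` or absolute.
#' @param sigma_units `"tau"` (sigma = value * tau) or `"absolute"`.
#' @param growth_laws List of [growth_law()] objects; defaults to the base
#'   parameters' law.
#' @param init_mutants 0 or 1 pre-existing mutants.
#' @param n_reps Replicates per grid point, `>= 1`.
#' @param seed Root seed.
#' @param label Free-text experiment id.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(base_params = model_params(), tau_grid,
                         tau_units = c("tau0H", "absolute"),
                         sigma_values = 0, sigma_units = c("tau", "absolute"),
                         growth_laws = NULL, init_mutants = 0,
                         n_reps = 1000, seed = 1, label = "sweep") {
  tau_units <- match.arg(tau_units)
  sigma_units <- match.arg(sigma_units)
  if (length(tau_grid) < 1) stop("`tau_grid` must be non-empty")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  if (is.null(growth_laws)) growth_laws <- list(base_params$growth)
  structure(list(base_params = base_params, tau_grid = tau_grid,
                 tau_units = tau_units, sigma_values = sigma_values,
                 sigma_units = sigma_units, growth_laws = growth_laws,
                 init_mutants = init_mutants, n_reps = as.integer(n_reps),
                 seed = seed, label = label),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config '%s': %d tau x %d sigma x %d growth laws, %d reps>\n",
              x$label, length(x$tau_grid), length(x$sigma_values),
              length(x$growth_laws), x$n_reps))
  invisible(x)
}

#' Run a sweep: analytical curves plus simulated points
#'
#' For every grid point the analytical predictions
#' ([extinction_prediction()], [rescue_prediction()]) and an ensemble of
#' stochastic realizations ([run_ensemble()]) are computed. Per-point seeds
#' are derived deterministically from the config seed, so results are
#' bit-identical across reruns. A grid point whose parameter combination is
#' invalid is reported in the `error` column without aborting the sweep.
#'
#' @param config A [sweep_config()].
#' @return Data frame (one row per growth law x tau x sigma) with analytic
#'   columns (`p0_H`, `p0_F`, `omega_F`, `mean_qF`, `T0`, `Sigma_H`,
#'   `Sigma_F`, `p_r_SGV`, `p_r_DN`, `p_r`, `tau_af`) and simulated columns
#'   with 95% CIs (`sim_p_rescue*`, `sim_T0*`, `sim_qF`, `sim_tau_af`,
#'   `sim_omega_F`), plus `n_reps`, `point_seed` and `error`.
#' @export
run_sweep <- function(config) {
  bp <- config$base_params
  grid <- expand.grid(gi = seq_along(config$growth_laws),
                      tau_in = config$tau_grid,
                      sigma_in = config$sigma_values,
                      KEEP.OUT.ATTRS = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  point_seeds <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    gl <- config$growth_laws[[grid$gi[i]]]
    params <- tryCatch(
      model_params(bp$b_WF, bp$b_WH, bp$d_W, bp$b_M, bp$d_M, bp$mu, bp$K,
                   growth = gl),
      error = function(e) e)
    base_row <- data.frame(
      experiment = config$label, growth = gl$kind, beta = gl$beta,
      tau = NA_real_, sigma = NA_real_, n_reps = config$n_reps,
      point_seed = point_seeds[i], stringsAsFactors = FALSE)
    if (inherits(params, "error")) {
      base_row$error <- conditionMessage(params)
      return(base_row)
    }
    tau <- if (config$tau_units == "tau0H") {
      grid$tau_in[i] * tau0_harsh(params)
    } else grid$tau_in[i]
    sigma <- if (config$sigma_units == "tau") grid$sigma_in[i] * tau
             else grid$sigma_in[i]
    base_row$tau <- tau
    base_row$sigma <- sigma
    res <- tryCatch({
      dist <- duration_dist(tau, sigma)
      ext <- extinction_prediction(params, dist)
      resc <- rescue_prediction(params, dist)
      ens <- run_ensemble(params, dist, init_mutants = config$init_mutants,
                          n_reps = config$n_reps, seed = point_seeds[i])
      cbind(base_row, data.frame(
        p0_H = ext$p0_H, p0_F = ext$p0_F, omega_F = ext$omega_F,
        mean_qF = ext$mean_qF, T0 = ext$T0,
        Sigma_H = resc$Sigma_H, Sigma_F = resc$Sigma_F,
        p_r_SGV = resc$p_r_SGV, p_r_DN = resc$p_r_DN, p_r = resc$p_r,
        tau_af = resc$tau_af,
        sim_p_rescue = ens$p_rescue_hat["est"],
        sim_p_rescue_lo = ens$p_rescue_hat["lo"],
        sim_p_rescue_hi = ens$p_rescue_hat["hi"],
        sim_T0 = ens$mean_T0_given_extinct["est"],
        sim_T0_lo = ens$mean_T0_given_extinct["lo"],
        sim_T0_hi = ens$mean_T0_given_extinct["hi"],
        sim_qF = ens$mean_qF["est"],
        sim_tau_af = ens$mean_appearance_time_given_rescue["est"],
        sim_omega_F = ens$omega_F_hat,
        error = NA_character_, stringsAsFactors = FALSE))
    }, error = function(e) {
      base_row$error <- conditionMessage(e)
      base_row
    })
    res
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows missing result columns
    all_cols <- c("experiment", "growth", "beta", "tau", "sigma", "n_reps",
                  "point_seed", "p0_H", "p0_F", "omega_F", "mean_qF", "T0",
                  "Sigma_H", "Sigma_F", "p_r_SGV", "p_r_DN", "p_r", "tau_af",
                  "sim_p_rescue", "sim_p_rescue_lo", "sim_p_rescue_hi",
                  "sim_T0", "sim_T0_lo", "sim_T0_hi", "sim_qF", "sim_tau_af",
                  "sim_omega_F", "error")
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  }))
  rownames(out) <- NULL
  out
}

#' Figure-style experiment presets
#'
#' Named [sweep_config()]s matching the baseline study conditions (wild-type
#' birth rates 1 favourable / 0 harsh unless stated, death rate 0.1, mutant
#' rates 1 and 0.1, carrying capacity 100, mutation probability `1e-3`,
#' equilibrium size 90), at a default 1000 replicates per grid point.
#' `fig2*` presets target extinction times (mutation switched off),
#' `fig3*` rescue probabilities, `fig4*` appearance times, and `fig1c`
#' carries all four growth laws for trajectory comparisons. Tau grids are
#' log-spaced over `[0.1, 4] tau0_H`, except the extinction-time presets,
#' which span `[0.45, 4] tau0_H`: without mutation the mean persistence grows
#' like the inverse per-cycle extinction probability (of order `e^{90}` cycles
#' at `0.1 tau0_H`), so simulated extinction times are only measurable once
#' `tau` is an appreciable fraction of the harsh-survival scale.
#'
#' @param name Preset name; omit to list available names.
#' @param n_reps Override the replicate count.
#' @param seed Root seed.
#' @return A `sweep_config` (or a character vector of names).
#' @export
presets <- function(name = NULL, n_reps = 1000, seed = 1) {
  tau_default <- exp(seq(log(0.1), log(4), length.out = 7))
  tau_extinct <- exp(seq(log(0.45), log(4), length.out = 7))
  base <- model_params()
  base_mu0 <- model_params(mu = 0)
  all_laws <- list(growth_law("logistic"), growth_law("gompertz"),
                   growth_law("richards", beta = 2),
                   growth_law("richards", beta = 0.5))
  defs <- list(
    fig1c = function() sweep_config(base, tau_grid = 1,
      growth_laws = all_laws, n_reps = n_reps, seed = seed, label = "fig1c"),
    fig2a = function() sweep_config(base_mu0, tau_grid = tau_extinct,
      sigma_values = c(0, 0.1, 1), n_reps = n_reps, seed = seed, label = "fig2a"),
    fig2b = function() sweep_config(base_mu0, tau_grid = tau_extinct,
      growth_laws = all_laws, n_reps = n_reps, seed = seed, label = "fig2b"),
    fig2c = function() sweep_config(model_params(b_WH = 0.01, mu = 0),
      tau_grid = tau_extinct, n_reps = n_reps, seed = seed, label = "fig2c"),
    fig3a = function() sweep_config(base, tau_grid = tau_default,
      n_reps = n_reps, seed = seed, label = "fig3a"),
    fig3b = function() sweep_config(base, tau_grid = tau_default,
      sigma_values = c(0, 0.1, 1), n_reps = n_reps, seed = seed, label = "fig3b"),
    fig3c = function() sweep_config(base, tau_grid = tau_default,
      growth_laws = all_laws, n_reps = n_reps, seed = seed, label = "fig3c"),
    fig3d = function() sweep_config(model_params(b_WH = 0.01),
      tau_grid = tau_default, n_reps = n_reps, seed = seed, label = "fig3d"),
    fig4a = function() sweep_config(base, tau_grid = tau_default,
      n_reps = n_reps, seed = seed, label = "fig4a"),
    fig4b = function() sweep_config(base, tau_grid = tau_default,
      sigma_values = c(0, 0.1, 1), n_reps = n_reps, seed = seed, label = "fig4b")
  )
  if (is.null(name)) return(names(defs))
  if (!name %in% names(defs))
    stop("unknown preset '", name, "'; available: ",
         paste(names(defs), collapse = ", "))
  defs[[name]]()
}
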