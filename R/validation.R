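#' Monte-Carlo establishment probability of a single mutant lineage
#'
#' Direct stochastic simulation of a single mutant lineage embedded in the
#' periodic mean-field wild-type background (the same background the
#' analytical [pfix()] uses): a linear birth-death process with
#' time-dependent birth rate `b_M g(<N_W>(t)/K)` and death rate `d_M`,
#' simulated exactly by thinning, absorbed at 0 (loss) or at `threshold`
#' copies (establishment). Serves as an independent cross-check of the
#' branching-process formula.
#'
#' @inheritParams pfix
#' @param t0 Single cycle position in `[0, 2 tau)`.
#' @param n_reps Number of lineage replicates.
#' @param seed Integer seed.
#' @param threshold Establishment size (default: the [rescue_threshold()]).
#' @return List with `p_hat`, `se` (binomial standard error) and `n_reps`.
#' @export
simulate_lineage_establishment <- function(params, dist, t0, n_reps, seed,
                                           threshold = NULL, n_grid = 2048) {
  if (length(t0) != 1L || t0 < 0 || t0 >= 2 * dist$mean_tau)
    stop("`t0` must be a single position in [0, 2*tau)")
  if (is.null(threshold)) threshold <- rescue_threshold(params)
  cycle <- rescue_cycle(params, dist, n_grid)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_reps)) {
    o <- ssa_lineage_cpp(params$b_M, params$d_M, params$K,
                         growth_kind_code(params$growth), params$growth$beta,
                         dist$mean_tau, t0, cycle$NW, as.integer(threshold), 1e8)
    if (o$established) hits <- hits + 1L
  }
  p <- hits / n_reps
  list(p_hat = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}

#' Monte-Carlo first-passage probability in a favourable environment
#'
#' Fraction of exact wild-type-only realizations, in a constant favourable
#' environment, that hit 0 before first reaching `barrier` (default
#' `ceil(N*)`). Independent cross-check of the gambler's-ruin computation in
#' [rapid_extinction_prob()].
#'
#' @inheritParams rapid_extinction_prob
#' @param n0 Initial size.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return List with `p_hat`, `se`, `n_reps`.
#' @export
simulate_rapid_extinction <- function(params, n0, n_reps, seed, barrier = NULL) {
  if (is.null(barrier))
    barrier <- ceiling(equilibrium_size(params$growth, params$b_WF, params$d_W,
                                        params$K))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_reps)) {
    o <- ssa_first_passage_cpp(params$b_WF, params$d_W, params$K,
                               growth_kind_code(params$growth),
                               params$growth$beta,
                               as.integer(n0), as.integer(barrier), 1e8)
    if (o$hit_zero) hits <- hits + 1L
  }
  p <- hits / n_reps
  list(p_hat = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}
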