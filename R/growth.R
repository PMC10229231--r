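#' Density-regulated growth laws
#'
#' Constructs a growth-law descriptor. The per capita birth rate of an
#' individual is `b * g(N/K)` where the density factor `g` depends on the law:
#' `1 - N/K` (logistic), `log(K/N)` (Gompertz) or `1 - (N/K)^beta` (Richards,
#' also known as theta-logistic). All three factors vanish at the carrying
#' capacity `K`, so the population size never exceeds `K`.
#'
#' @param kind One of `"logistic"`, `"gompertz"`, `"richards"`.
#' @param beta Positive shape exponent; used only by the Richards law
#'   (`beta = 1` recovers the logistic law).
#' @return An object of class `growth_law`.
#' @examples
#' growth_law("richards", beta = 2)
#' @export
growth_law <- function(kind = c("logistic", "gompertz", "richards"), beta = 1) {
  kind <- match.arg(kind)
  if (kind == "richards") {
    if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
      stop("`beta` must be a single positive number for the Richards law")
  } else {
    beta <- 1
  }
  structure(list(kind = kind, beta = beta), class = "growth_law")
}

#' @export
print.growth_law <- function(x, ...) {
  if (x$kind == "richards") {
    cat(sprintf("<growth_law: richards, beta = %g>\n", x$beta))
  } else {
    cat(sprintf("<growth_law: %s>\n", x$kind))
  }
  invisible(x)
}

growth_kind_code <- function(growth) {
  switch(growth$kind, logistic = 1L, gompertz = 2L, richards = 3L)
}

#' Density factor of a growth law
#'
#' Evaluates the dimensionless density factor `g(N/K)` that multiplies the
#' intrinsic birth rate. For the Gompertz law the factor diverges as `N -> 0`;
#' in deterministic (real-valued) trajectories it is capped at its value for
#' `N = 1`, i.e. `log(K)`, which is the low-density per capita factor of the
#' stochastic process (where a birth requires `N >= 1`).
#'
#' @param growth A [growth_law()].
#' @param N Population size(s), `0 <= N <= K` (real-valued allowed).
#' @param K Carrying capacity.
#' @return Numeric vector of non-negative factors, `0` at `N = K`.
#' @export
density_factor <- function(growth, N, K) {
  if (any(N < 0 | N > K)) stop("`N` must satisfy 0 <= N <= K")
  x <- N / K
  g <- switch(growth$kind,
    logistic = 1 - x,
    gompertz = {
      out <- numeric(length(x))
      low <- N < 1
      out[low] <- log(K)
      out[!low] <- log(1 / x[!low])
      out
    },
    richards = 1 - x^growth$beta
  )
  pmax(g, 0)
}

#' Per capita birth rate under density regulation
#'
#' @inheritParams density_factor
#' @param b Intrinsic (density-free) birth rate, `b >= 0`.
#' @return `b * g(N/K)`; zero at `N = K` for all laws.
#' @examples
#' per_capita_birth_rate(growth_law("richards", beta = 2), b = 1, N = 50, K = 100)
#' @export
per_capita_birth_rate <- function(growth, b, N, K) {
  if (any(b < 0)) stop("`b` must be non-negative")
  b * density_factor(growth, N, K)
}

#' Equilibrium population size
#'
#' The positive fixed point `N*` where density-regulated births balance deaths,
#' `b g(N*/K) = d`. Closed forms: `K (1 - d/b)` (logistic),
#' `K (1 - d/b)^(1/beta)` (Richards) and `K exp(-d/b)` (Gompertz). Only defined
#' for `b > d`.
#'
#' @inheritParams density_factor
#' @param b Intrinsic birth rate.
#' @param d Death rate.
#' @return Real equilibrium size in `(0, K)`.
#' @examples
#' equilibrium_size(growth_law("logistic"), b = 1, d = 0.1, K = 100)  # 90
#' @export
equilibrium_size <- function(growth, b, d, K) {
  if (!(b > d)) stop("no positive equilibrium: requires b > d")
  switch(growth$kind,
    logistic = K * (1 - d / b),
    gompertz = K * exp(-d / b),
    richards = K * (1 - d / b)^(1 / growth$beta)
  )
}

#' Model parameters for the two-genotype birth-death process
#'
#' Bundles the demographic and mutational rate constants. The wild type has
#' environment-dependent birth rate (`b_WF` in the favourable state, `b_WH` in
#' the harsh state) and environment-independent death rate `d_W`; the
#' generalist mutant has constant birth rate `b_M` and death rate `d_M` in both
#' states. A mutant offspring is produced at each wild-type birth event with
#' probability `mu`.
#'
#' By default the parameterization is validated to describe growth in the
#' favourable environment (`b_WF > d_W`) and decline in the harsh one
#' (`b_WH < d_W`); set `validate = FALSE` for exploratory parameter sets
#' (e.g. a constant environment).
#'
#' @param b_WF,b_WH Wild-type birth rates in favourable / harsh environments.
#' @param d_W Wild-type death rate.
#' @param b_M,d_M Mutant birth and death rates (environment-independent).
#' @param mu Mutation probability per wild-type birth event, in `[0, 1]`.
#' @param K Carrying capacity (positive integer).
#' @param growth A [growth_law()].
#' @param validate Enforce `b_WF > d_W` and `b_WH < d_W`?
#' @return An object of class `model_params`.
#' @examples
#' model_params()  # the baseline parameter set
#' @export
model_params <- function(b_WF = 1, b_WH = 0, d_W = 0.1, b_M = 1, d_M = 0.1,
                         mu = 1e-3, K = 100, growth = growth_law("logistic"),
                         validate = TRUE) {
  rates <- c(b_WF = b_WF, b_WH = b_WH, d_W = d_W, b_M = b_M, d_M = d_M)
  if (any(!is.finite(rates)) || any(rates < 0)) stop("all rates must be finite and >= 0")
  if (!is.finite(mu) || mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  if (!is.finite(K) || K < 1 || K != round(K)) stop("`K` must be a positive integer")
  if (!inherits(growth, "growth_law")) stop("`growth` must be a growth_law object")
  if (validate) {
    if (!(b_WF > d_W)) stop("favourable growth requires b_WF > d_W (or validate = FALSE)")
    if (!(b_WH < d_W)) stop("harsh decline requires b_WH < d_W (or validate = FALSE)")
  }
  structure(list(b_WF = b_WF, b_WH = b_WH, d_W = d_W, b_M = b_M, d_M = d_M,
                 mu = mu, K = as.integer(K), growth = growth),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  wild type : b_WF = %g, b_WH = %g, d_W = %g\n", x$b_WF, x$b_WH, x$d_W))
  cat(sprintf("  mutant    : b_M = %g, d_M = %g\n", x$b_M, x$d_M))
  cat(sprintf("  mutation  : mu = %g   carrying capacity: K = %d\n", x$mu, x$K))
  cat(sprintf("  growth    : %s%s\n", x$growth$kind,
              if (x$growth$kind == "richards") sprintf(" (beta = %g)", x$growth$beta) else ""))
  invisible(x)
}

#' Serialize / deserialize model parameters
#'
#' `params_to_list()` flattens a [model_params()] object into a named list with
#' keys `b_WF, b_WH, d_W, b_M, d_M, mu, K, growth, beta` suitable for YAML or
#' JSON configs; `params_from_list()` is its inverse.
#'
#' @param params A `model_params` object.
#' @param x A named list (e.g. from `yaml::read_yaml()`).
#' @param validate Passed to [model_params()].
#' @return A named list / a `model_params` object.
#' @export
params_to_list <- function(params) {
  list(b_WF = params$b_WF, b_WH = params$b_WH, d_W = params$d_W,
       b_M = params$b_M, d_M = params$d_M, mu = params$mu, K = params$K,
       growth = params$growth$kind, beta = params$growth$beta)
}

#' @rdname params_to_list
#' @export
params_from_list <- function(x, validate = TRUE) {
  defaults <- params_to_list(model_params())
  miss <- setdiff(names(x), names(defaults))
  if (length(miss)) stop("unknown parameter keys: ", paste(miss, collapse = ", "))
  x <- utils::modifyList(defaults, x)
  model_params(b_WF = x$b_WF, b_WH = x$b_WH, d_W = x$d_W, b_M = x$b_M,
               d_M = x$d_M, mu = x$mu, K = x$K,
               growth = growth_law(x$growth, beta = x$beta), validate = validate)
}

#' Mean survival time in an uninterrupted harsh environment
#'
#' The reference time scale `tau0H ~ log(N*) / d_W`, with `N*` the favourable
#' equilibrium size: the time a wild-type population of size `N*` takes, on
#' average, to decline to extinction when births are (almost) fully prevented.
#' Environment durations are naturally expressed in multiples of this scale.
#'
#' @param params A [model_params()].
#' @return Time.
#' @export
tau0_harsh <- function(params) {
  nstar <- equilibrium_size(params$growth, params$b_WF, params$d_W, params$K)
  log(nstar) / params$d_W
}

#' Deterministic mean-field trajectory
#'
#' Solves `dN/dt = (b g(N/K) - d_W) N` from `N(0) = N0`, with `b` the
#' wild-type birth rate of the requested environmental phase. Exact closed
#' forms exist for all three laws and are used by default: the logistic ODE is
#' a Riccati equation, the Richards ODE becomes linear in `N^(-beta)` and the
#' Gompertz ODE is linear in `log N`. `method = "ode"` integrates numerically
#' (adaptive `deSolve::lsoda`, rtol `1e-8`) with the low-density Gompertz cap
#' of [density_factor()] applied; the two routes agree to high accuracy and
#' the numerical one is kept as an independent cross-check.
#'
#' @param params A [model_params()].
#' @param phase `"F"` (favourable) or `"H"` (harsh).
#' @param N0 Initial size, `0 <= N0 <= K`.
#' @param t Time(s) `>= 0` at which to evaluate.
#' @param method `"closed"` (default) or `"ode"`.
#' @return Numeric vector of sizes, one per element of `t`.
#' @examples
#' p <- model_params()
#' mean_trajectory(p, "H", N0 = 90, t = 10)  # 90 * exp(-1)
#' @export
mean_trajectory <- function(params, phase = c("F", "H"), N0, t,
                            method = c("closed", "ode")) {
  phase <- match.arg(phase)
  method <- match.arg(method)
  if (N0 < 0 || N0 > params$K) stop("`N0` must satisfy 0 <= N0 <= K")
  if (any(t < 0)) stop("`t` must be non-negative")
  b <- if (phase == "F") params$b_WF else params$b_WH
  d <- params$d_W
  K <- params$K
  if (N0 == 0) return(rep(0, length(t)))
  if (b == 0) return(N0 * exp(-d * t))
  if (method == "ode") return(trajectory_ode(params$growth, b, d, K, N0, t))
  gl <- params$growth
  out <- switch(gl$kind,
    logistic = closed_richards(1, b, d, K, N0, t),
    richards = closed_richards(gl$beta, b, d, K, N0, t),
    gompertz = {
      if (N0 < 1) {
        # below the capped-density region the closed form does not apply
        trajectory_ode(gl, b, d, K, N0, t)
      } else {
        zinf <- log(K) - d / b
        exp(zinf + (log(N0) - zinf) * exp(-b * t))
      }
    }
  )
  pmin(out, K)
}

# dN/dt = rN - (b/K^beta) N^(beta+1) is Bernoulli: y = N^-beta is linear.
closed_richards <- function(beta, b, d, K, N0, t) {
  r <- b - d
  if (abs(r) < 1e-14) {
    # y' = beta * b / K^beta, pure drift
    y <- N0^(-beta) + beta * (b / K^beta) * t
    return(y^(-1 / beta))
  }
  yinf <- b / (r * K^beta)
  y <- yinf + (N0^(-beta) - yinf) * exp(-beta * r * t)
  # for r < 0 (declining phase) y stays positive and N decays towards 0
  y^(-1 / beta)
}

trajectory_ode <- function(growth, b, d, K, N0, t) {
  times <- sort(unique(c(0, t)))
  deriv <- function(tt, y, parms) {
    N <- min(max(y[1], 0), K)
    list((b * density_factor(growth, N, K) - d) * N)
  }
  sol <- deSolve::lsoda(c(N = N0), times = times, func = deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  vals <- stats::approx(sol[, 1], sol[, 2], xout = t)$y
  pmin(pmax(vals, 0), K)
}
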