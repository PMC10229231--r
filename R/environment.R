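#' Phase-duration distribution
#'
#' The law of a single environmental phase duration. `sigma = 0` is the
#' deterministic (Dirac-delta) case: every phase lasts exactly `mean_tau`,
#' producing periodic environmental changes. `sigma > 0` gives a normal
#' distribution of mean `mean_tau` and standard deviation `sigma` truncated to
#' exclude negative durations, producing quasi-periodic changes.
#'
#' @param mean_tau Mean duration (before truncation), `> 0`.
#' @param sigma Standard deviation (before truncation), `>= 0`.
#' @return An object of class `duration_dist`.
#' @examples
#' duration_dist(45, sigma = 4.5)
#' @export
duration_dist <- function(mean_tau, sigma = 0) {
  if (!is.numeric(mean_tau) || length(mean_tau) != 1L || !(mean_tau > 0))
    stop("`mean_tau` must be a single positive time")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative time")
  structure(list(mean_tau = mean_tau, sigma = sigma), class = "duration_dist")
}

#' @export
print.duration_dist <- function(x, ...) {
  if (x$sigma == 0) {
    cat(sprintf("<duration_dist: deterministic, tau = %g>\n", x$mean_tau))
  } else {
    cat(sprintf("<duration_dist: zero-truncated normal, tau = %g, sigma = %g>\n",
                x$mean_tau, x$sigma))
  }
  invisible(x)
}

#' Density of the phase-duration distribution
#'
#' For `sigma > 0`, the normal density renormalized to `[0, Inf)`:
#' `phi((t - tau)/sigma) / (sigma * Z)` with `Z = Phi(tau/sigma)`
#' `= (1/2)(1 + erf(tau / (sigma sqrt(2))))`. Zero for `t < 0`.
#'
#' @param dist A [duration_dist()] with `sigma > 0`.
#' @param t Time(s).
#' @return Density values.
#' @export
duration_pdf <- function(dist, t) {
  if (dist$sigma == 0) stop("degenerate distribution has no density")
  Z <- stats::pnorm(dist$mean_tau / dist$sigma)
  ifelse(t < 0, 0, stats::dnorm(t, dist$mean_tau, dist$sigma) / Z)
}

# mean of the zero-truncated normal, tau + sigma*phi(tau/sigma)/Phi(tau/sigma)
truncated_mean <- function(dist) {
  if (dist$sigma == 0) return(dist$mean_tau)
  a <- dist$mean_tau / dist$sigma
  dist$mean_tau + dist$sigma * stats::dnorm(a) / stats::pnorm(a)
}

#' Sample phase durations
#'
#' `sigma = 0` returns `mean_tau` exactly; `sigma > 0` draws from the
#' zero-truncated normal by rejection from the untruncated normal (exact for
#' this truncation; acceptance probability `Phi(tau/sigma) >= 1/2` since
#' `tau > 0`). Uses R's global RNG stream.
#'
#' @param dist A [duration_dist()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative durations.
#' @export
sample_duration <- function(dist, n = 1) {
  if (dist$sigma == 0) return(rep(dist$mean_tau, n))
  out <- numeric(0)
  need <- n
  while (need > 0) {
    # over-draw to amortize rejection
    m <- ceiling(need / stats::pnorm(dist$mean_tau / dist$sigma)) + 8L
    draw <- stats::rnorm(m, dist$mean_tau, dist$sigma)
    draw <- draw[draw > 0]
    out <- c(out, draw)
    need <- n - length(out)
  }
  out[seq_len(n)]
}

#' Generate an alternating harsh/favourable schedule
#'
#' Phases strictly alternate starting with a HARSH phase (the population starts
#' at its favourable-environment equilibrium, so the first environmental change
#' it experiences is the onset of harshness). Durations are sampled
#' independently per phase from `dist`; phases are appended until their
#' cumulative duration first exceeds `horizon`.
#'
#' @param dist A [duration_dist()].
#' @param horizon Positive time span to cover.
#' @return A data frame of class `env_schedule` with columns `phase`
#'   (`"H"`/`"F"`) and `duration`.
#' @export
generate_schedule <- function(dist, horizon) {
  if (!(horizon > 0)) stop("`horizon` must be positive")
  phases <- character(0)
  durations <- numeric(0)
  total <- 0
  ph <- "H"
  while (total <= horizon) {
    d <- sample_duration(dist, 1)
    if (d <= 0) next
    phases <- c(phases, ph)
    durations <- c(durations, d)
    total <- total + d
    ph <- if (ph == "H") "F" else "H"
  }
  structure(data.frame(phase = phases, duration = durations,
                       stringsAsFactors = FALSE),
            class = c("env_schedule", "data.frame"))
}

#' Write a schedule as two-column TSV
#'
#' @param schedule An `env_schedule` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
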