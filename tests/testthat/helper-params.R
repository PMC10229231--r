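# Baseline study conditions: favourable birth 1, harsh birth 0, death 0.1,
# mutant rates 1 / 0.1, carrying capacity 100, mutation probability 1e-3,
# equilibrium size 90, harsh survival scale tau0H = log(90)/0.1 ~ 45.
baseline_params <- function(...) model_params(...)

baseline_tau0H <- function(params = baseline_params()) tau0_harsh(params)

all_growth_laws <- function() {
  list(logistic = growth_law("logistic"),
       gompertz = growth_law("gompertz"),
       richards2 = growth_law("richards", beta = 2),
       richards05 = growth_law("richards", beta = 0.5))
}

# pure-death closed forms (independent oracles for b_WH = 0)
pure_death_extinction_cdf <- function(t, N0, d) (1 - exp(-d * t))^N0

pure_death_mean_absorption <- function(N0, d) sum(1 / (1:N0)) / d
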