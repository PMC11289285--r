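# Shared fixtures, built once per test run. Sessions are small so the whole
# suite stays fast; heavier simulations live in the tests that need them.

.fx <- new.env()

fx_cfg <- function() synthetic_config(n_neurons = 30, n_laps = 10, seed = 101)

fx_sim <- function() {
  if (is.null(.fx$sim)) .fx$sim <- simulate_session(fx_cfg())
  .fx$sim
}

fx_session <- function() fx_sim()$session

# A high-SNR fully tuned session for recovery-style checks.
fx_sim_tuned <- function() {
  if (is.null(.fx$tuned)) {
    cfg <- synthetic_config(n_neurons = 20, n_laps = 50, seed = 21,
                            fraction_tuned = 1,
                            amplitude_range = c(1.5, 2.5))
    .fx$tuned <- simulate_session(cfg)
  }
  .fx$tuned
}

# Circular angular distance in degrees.
circ_err_deg <- function(a, b) {
  abs(((a - b + pi) %% (2 * pi)) - pi) * 180 / pi
}

# Bessel-ratio I1(k)/I0(k) by direct series summation in log space; the
# independent oracle for tuning-index and peak-width checks.
bessel_ratio_series <- function(k, n_terms = 400) {
  if (k == 0) return(0)
  m <- 0:(n_terms - 1)
  log_terms_0 <- 2 * m * log(k / 2) - 2 * lgamma(m + 1)
  log_terms_1 <- (2 * m + 1) * log(k / 2) - lgamma(m + 1) - lgamma(m + 2)
  lse <- function(lt) {
    mx <- max(lt)
    mx + log(sum(exp(lt - mx)))
  }
  exp(lse(log_terms_1) - lse(log_terms_0))
}
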