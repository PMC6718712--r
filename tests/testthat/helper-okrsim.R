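# Shared helpers: calibrated protocol cache and an independent fixed-step
# Euler integrator used as numerical oracle. The oracle reimplements the
# reduced plasticity equations directly from their mathematical form and
# never calls the package's derivative or integration code.

.okr_cache <- new.env(parent = emptyenv())

calibrated_d <- function() {
  if (is.null(.okr_cache$d))
    .okr_cache$d <- calibrate_d_train()
  .okr_cache$d
}

std_protocol <- function(n_sessions = 5, ...) {
  okr_protocol(n_sessions = n_sessions, d_train = calibrated_d(), ...)
}

cached_sim <- function(scenario, key = scenario) {
  if (is.null(.okr_cache[[key]]))
    .okr_cache[[key]] <- simulate_okr(scenario, std_protocol())
  .okr_cache[[key]]
}

# Independent explicit-Euler oracle. Returns per-session matrices of the
# three weights at post-training and end-of-rest.
euler_oracle <- function(params, protocol, dt_train = 1e-4, dt_rest = 1e-3) {
  l1 <- 1 / params$tau1
  l3 <- if (is.infinite(params$tau3)) 0 else 1 / params$tau3
  l4 <- 1 / params$tau4
  l6 <- 1 / params$tau6
  w0 <- c(params$w0_pf_pc, params$w0_pf_mli, params$w0_mf_dn)
  a <- params$alpha
  f <- params$f_mf
  deriv <- function(w, d, r, training) {
    wc <- pmax(w, 0)
    f_pc <- (wc[1L] - wc[2L]) * a * f
    e <- d * f - (wc[3L] * f - f_pc)
    d_pc <- (if (training) -l1 * params$beta1 * r * a * f * e else 0) -
      l3 * (wc[1L] - w0[1L])
    rm <- if (params$ramp_on_mli) r else 1
    d_ml <- (if (training) l1 * params$beta3 * rm * a * f * e else 0) -
      l3 * (wc[2L] - w0[2L])
    d_dn <- l4 * params$gamma * (wc[2L] - wc[1L] + w0[1L] - w0[2L]) * a * f^2 +
      l6 * (w0[3L] - wc[3L])
    if (params$freeze_pf_mli) d_ml <- 0
    dd <- c(d_pc, d_ml, d_dn)
    dd[w <= 0 & dd < 0] <- 0
    dd
  }
  w <- w0
  post <- end <- matrix(NA_real_, protocol$n_sessions, 3L)
  for (s in seq_len(protocol$n_sessions)) {
    for (k in seq_len(round(protocol$train_hours / dt_train)))
      w <- pmax(w + dt_train * deriv(w, protocol$d_train, protocol$ramp[s],
                                     TRUE), 0)
    post[s, ] <- w
    for (k in seq_len(round(protocol$rest_hours / dt_rest)))
      w <- pmax(w + dt_rest * deriv(w, params$d0, 1, FALSE), 0)
    end[s, ] <- w
  }
  list(post = post, end = end)
}

full_comparison <- function() {
  if (is.null(.okr_cache$comparison))
    .okr_cache$comparison <- compare_scenarios(list_scenarios(),
                                               std_protocol())
  .okr_cache$comparison
}
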