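#' Run a full training protocol
#'
#' Integrates the circuit through every training and rest phase of a
#' protocol, applying scheduled events at phase boundaries, and returns the
#' complete simulation: dense weight and gain trajectories plus per-session
#' marks (pre-training, post-training, end-of-rest).
#'
#' State is continuous across phase boundaries; the only discontinuities are
#' documented parameter overrides (events). The OKR gain column is the
#' read-out of [okr_gain()] applied to the weights at every sample, using
#' the parameters in force at that time.
#'
#' @param params An [okr_params()] object (possibly from [get_scenario()]).
#' @param protocol An [okr_protocol()] object.
#' @param state Initial state; defaults to the configured baseline.
#' @param check_balance If \code{TRUE} (default), stop when the initial
#'   configuration violates the baseline balance beyond \code{1e-10} unless
#'   the initial state was supplied explicitly.
#' @param rtol,atol Solver tolerances, passed to [integrate_phase()].
#' @return An object of class \code{"okr_sim"}: a list with
#'   \describe{
#'     \item{trajectory}{data.frame with \code{t_hours}, the three weights,
#'       \code{gain}, \code{phase} ("train"/"rest") and \code{session}.}
#'     \item{sessions}{data.frame of per-session marks: gains and weights at
#'       pre-train, post-train and end-of-rest.}
#'     \item{params, protocol, scenario}{the inputs (scenario name if known).}
#'   }
#' @examples
#' sim <- run_protocol(okr_params(), okr_protocol(n_sessions = 2))
#' sim
#' @export
run_protocol <- function(params, protocol = okr_protocol(),
                         state = NULL, check_balance = TRUE,
                         rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "okr_params"), inherits(protocol, "okr_protocol"))
  explicit_state <- !is.null(state)
  if (is.null(state)) state <- baseline_state(params)
  if (check_balance && !explicit_state)
    check_baseline_balance(params, state, tol = 1e-10)

  pend <- length(protocol$events)
  next_event <- if (pend) 1L else 0L
  t0 <- 0
  w <- pmax(as.numeric(state), 0)
  traj <- vector("list", 2L * protocol$n_sessions)
  marks <- vector("list", protocol$n_sessions)

  apply_events <- function(params, now) {
    while (next_event > 0L && next_event <= pend &&
           protocol$events[[next_event]]$time <= now + 1e-9) {
      ov <- protocol$events[[next_event]]$set
      bad <- setdiff(names(ov), names(params))
      if (length(bad))
        stop("unknown parameter(s) in event override: ",
             paste(bad, collapse = ", "), call. = FALSE)
      params[names(ov)] <- ov
      validate_okr_params(params)
      next_event <<- next_event + 1L
      # assignment in enclosure: params is returned, next_event advanced
    }
    params
  }

  for (s in seq_len(protocol$n_sessions)) {
    params <- apply_events(params, t0)
    pre <- w
    g_pre <- okr_gain(pre, params)
    tr <- integrate_phase(pre, params, d = protocol$d_train,
                          ramp = protocol$ramp[s], training = TRUE,
                          duration = protocol$train_hours,
                          rtol = rtol, atol = atol)
    w <- tr[nrow(tr), 2L:4L]
    post <- w
    g_post <- okr_gain(post, params)
    traj[[2L * s - 1L]] <- data.frame(
      t_hours = t0 + tr[, "t"], w_pf_pc = tr[, "w_pf_pc"],
      w_pf_mli = tr[, "w_pf_mli"], w_mf_dn = tr[, "w_mf_dn"],
      gain = apply(tr[, 2L:4L, drop = FALSE], 1L, okr_gain, params = params),
      phase = "train", session = s)
    t0 <- t0 + protocol$train_hours

    params <- apply_events(params, t0)
    if (protocol$rest_hours > 0) {
      re <- integrate_phase(w, params, d = params$d0,
                            ramp = protocol$ramp[s], training = FALSE,
                            duration = protocol$rest_hours,
                            rtol = rtol, atol = atol)
      w <- re[nrow(re), 2L:4L]
      traj[[2L * s]] <- data.frame(
        t_hours = t0 + re[, "t"], w_pf_pc = re[, "w_pf_pc"],
        w_pf_mli = re[, "w_pf_mli"], w_mf_dn = re[, "w_mf_dn"],
        gain = apply(re[, 2L:4L, drop = FALSE], 1L, okr_gain, params = params),
        phase = "rest", session = s)
      t0 <- t0 + protocol$rest_hours
    }
    g_end <- okr_gain(w, params)
    marks[[s]] <- data.frame(
      session = s,
      gain_pre = g_pre, gain_post = g_post, gain_end_rest = g_end,
      w_pf_pc_pre = pre[1L], w_pf_pc_post = post[1L], w_pf_pc_end = w[1L],
      w_pf_mli_pre = pre[2L], w_pf_mli_post = post[2L], w_pf_mli_end = w[2L],
      w_mf_dn_pre = pre[3L], w_mf_dn_post = post[3L], w_mf_dn_end = w[3L])
  }

  res <- list(trajectory = do.call(rbind, traj),
              sessions = do.call(rbind, marks),
              params = params, protocol = protocol,
              scenario = attr(params, "scenario") %||% NA_character_)
  rownames(res$trajectory) <- NULL
  rownames(res$sessions) <- NULL
  class(res) <- "okr_sim"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a named lesion scenario
#'
#' Convenience front end: resolves a registered scenario (see
#' [list_scenarios()]), merges its events into the protocol, and runs it.
#'
#' @param scenario Scenario name (default \code{"normal"}).
#' @param protocol An [okr_protocol()]; scenario events are appended to it.
#' @param ... Passed to [run_protocol()].
#' @return An \code{"okr_sim"} object.
#' @examples
#' sim <- simulate_okr("mf_gc_attenuation", okr_protocol(n_sessions = 2))
#' summary(sim)
#' @export
simulate_okr <- function(scenario = "normal", protocol = okr_protocol(), ...) {
  sc <- get_scenario(scenario)
  params <- scenario_params(sc)
  if (length(sc$events)) {
    ev <- lapply(sc$events, resolve_event_time, protocol = protocol)
    protocol <- okr_protocol(n_sessions = protocol$n_sessions,
                             train_hours = protocol$train_hours,
                             rest_hours = protocol$rest_hours,
                             d_train = protocol$d_train,
                             ramp = protocol$ramp,
                             events = c(protocol$events, ev))
  }
  sim <- run_protocol(params, protocol, ...)
  sim$scenario <- sc$name
  sim
}

# scenario events are declared relative to sessions ("after training of
# session k"); convert to absolute protocol time
resolve_event_time <- function(ev, protocol) {
  if (!is.null(ev$after_training_of_session)) {
    k <- ev$after_training_of_session
    if (k > protocol$n_sessions)
      stop(sprintf("event after session %d lies outside a %d-session protocol",
                   k, protocol$n_sessions), call. = FALSE)
    list(time = (k - 1) * (protocol$train_hours + protocol$rest_hours) +
           protocol$train_hours,
         set = ev$set)
  } else {
    ev
  }
}

#' Calibrate the training desired gain against the normal-scenario anchor
#'
#' The desired gain during training, \code{d_train}, is the one free
#' behavioural parameter of the model. It is pinned once by a single scalar
#' root search on the normal scenario: find \code{d_train} such that the OKR
#' gain at the end of the last training phase equals \code{target}
#' (0.56 after five sessions, against a pre-training gain of 0.30). The
#' equilibrium read-out satisfies \eqn{G \to g_{OKR0}\, d} under sustained
#' training, so the calibrated value lies near \code{target / g_okr0}.
#'
#' @param target Anchor gain at the final post-training mark.
#' @param protocol Protocol used for calibration (the standard 5-session
#'   paradigm); its \code{d_train} field is ignored.
#' @param params Parameters of the reference scenario (normal defaults).
#' @param interval Search interval for the root.
#' @param tol Root-finding tolerance on \code{d_train}.
#' @return The calibrated \code{d_train} (scalar).
#' @examples
#' \donttest{
#' d <- calibrate_d_train()
#' round(d, 3)  # close to 2
#' }
#' @export
calibrate_d_train <- function(target = 0.56, protocol = okr_protocol(),
                              params = okr_params(),
                              interval = c(1.2, 4), tol = 1e-8) {
  f <- function(d) {
    pr <- okr_protocol(n_sessions = protocol$n_sessions,
                       train_hours = protocol$train_hours,
                       rest_hours = protocol$rest_hours,
                       d_train = d, ramp = protocol$ramp,
                       events = protocol$events)
    sim <- run_protocol(params, pr)
    sim$sessions$gain_post[protocol$n_sessions] - target
  }
  stats::uniroot(f, interval, tol = tol)$root
}
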