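#' Training protocol
#'
#' Describes the session schedule of a gain-up adaptation experiment: each
#' session is one training phase under the training desired gain followed by
#' an off-task (rest/darkness) phase, repeated daily. The standard paradigm
#' is 1 h of training and 23 h of rest per session.
#'
#' The early-session ramp emulates the S-shaped rise of long-term gain over
#' the first days: the error-driven PF-PC induction is scaled by
#' \code{ramp[s]} during session \code{s}. The default schedule is
#' \eqn{r(s) = \min(1, s/3)}, i.e. one third, two thirds, then full strength
#' from the third session onward.
#'
#' Events are parameter overrides applied at a phase boundary: an event
#' \code{list(time = 73, set = list(gamma = 0))} switches the corticonuclear
#' coefficient off at the first phase boundary at or after hour 73 (the end
#' of session-4 training under the default schedule). Each event fires
#' exactly once.
#'
#' @param n_sessions Number of daily sessions.
#' @param train_hours Duration of the training phase (hours).
#' @param rest_hours Duration of the off-task phase (hours).
#' @param d_train Desired gain (cerebellar space) during training. The
#'   package default is the anchor-calibrated value for the normal scenario
#'   (see [calibrate_d_train()]); it is a plain number and can be set freely.
#' @param ramp Either a function of the session index or a numeric vector
#'   (recycled to \code{n_sessions}) of ramp factors in \eqn{[0, 1]}.
#' @param events List of events, each \code{list(time = <hours>, set =
#'   <named list of parameter overrides>)}.
#' @return Object of class \code{"okr_protocol"}.
#' @examples
#' okr_protocol()                     # 5 x (1 h train + 23 h rest)
#' okr_protocol(n_sessions = 8)
#' @export
okr_protocol <- function(n_sessions = 5,
                         train_hours = 1,
                         rest_hours = 23,
                         d_train = 1.87,
                         ramp = function(s) pmin(1, s / 3),
                         events = list()) {
  stopifnot(n_sessions >= 1, train_hours > 0, rest_hours >= 0,
            is.numeric(d_train), length(d_train) == 1L, d_train >= 0)
  n_sessions <- as.integer(n_sessions)
  r <- if (is.function(ramp)) vapply(seq_len(n_sessions), ramp, numeric(1))
       else rep_len(as.numeric(ramp), n_sessions)
  if (any(r < 0 | r > 1))
    stop("ramp factors must lie in [0, 1]", call. = FALSE)
  total <- n_sessions * (train_hours + rest_hours)
  for (ev in events) {
    if (!is.list(ev) || is.null(ev$time) || !is.list(ev$set))
      stop("each event must be list(time = <hours>, set = <named list>)",
           call. = FALSE)
    if (ev$time < 0 || ev$time > total)
      stop(sprintf("event time %g h lies outside the simulated range [0, %g]",
                   ev$time, total), call. = FALSE)
  }
  if (length(events) > 1L)
    events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  structure(list(n_sessions = n_sessions, train_hours = train_hours,
                 rest_hours = rest_hours, d_train = d_train,
                 ramp = r, events = events),
            class = "okr_protocol")
}

#' @export
print.okr_protocol <- function(x, ...) {
  cat(sprintf("OKR training protocol: %d session(s) of %g h training + %g h rest\n",
              x$n_sessions, x$train_hours, x$rest_hours))
  cat(sprintf("  d_train = %g, ramp = [%s]\n", x$d_train,
              paste(format(x$ramp, digits = 3), collapse = ", ")))
  if (length(x$events))
    for (ev in x$events)
      cat(sprintf("  event at %g h: %s\n", ev$time,
                  paste(names(ev$set), unlist(ev$set), sep = " = ",
                        collapse = ", ")))
  invisible(x)
}

#' Integrate one protocol phase
#'
#' Integrates the three coupled plasticity equations over a single phase
#' (training or rest) with an adaptive explicit Runge-Kutta scheme
#' (Dormand-Prince 4(5) via \pkg{deSolve}), recording the trajectory on a
#' fixed grid plus the exact phase end point. Weights are clamped at zero:
#' the derivative field projects at the floor and recorded samples are
#' non-negative.
#'
#' @inheritParams dw_pf_pc
#' @param duration Phase duration in hours (> 0).
#' @param dt_record Recording resolution in hours.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @return A numeric matrix with columns \code{t}, \code{w_pf_pc},
#'   \code{w_pf_mli}, \code{w_mf_dn}; \code{t} is phase-local (starts at 0).
#' @examples
#' p <- okr_params()
#' tr <- integrate_phase(baseline_state(p), p, d = 2, duration = 1)
#' tail(tr, 1)
#' @export
integrate_phase <- function(state, params, d, ramp = 1, training = TRUE,
                            duration, dt_record = if (training) 0.01 else 0.1,
                            rtol = 1e-6, atol = 1e-8) {
  stopifnot(duration > 0, dt_record > 0)
  times <- unique(c(seq(0, duration, by = dt_record), duration))
  rhs <- function(t, y, parms) list(circuit_derivs(y, params, d, ramp, training))
  out <- deSolve::ode(y = pmax(as.numeric(state), 0), times = times,
                      func = rhs, parms = NULL, method = "ode45",
                      rtol = rtol, atol = atol)
  diagn <- attr(out, "istate")
  if (!is.null(diagn) && diagn[1L] < 0)
    stop("phase integration failed (solver state ", diagn[1L], ")",
         call. = FALSE)
  m <- unname(cbind(out[, 1L], pmax(out[, 2L:4L], 0)))
  colnames(m) <- c("t", "w_pf_pc", "w_pf_mli", "w_mf_dn")
  m
}
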