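#' Plasticity rate of the PF-PC synaptic weight
#'
#' Reduced rate equation for the parallel fiber-Purkinje cell weight. During
#' training the climbing-fiber error signal drives depression (LTD for
#' \eqn{e > 0}):
#' \deqn{\dot W_{PF-PC} = -\frac{\beta_1 r}{\tau_1}\,\alpha f_{MF}\, e
#'   \;-\; \frac{1}{\tau_3}\,(W_{PF-PC} - W^0_{PF-PC}),}
#' where \eqn{r} is the early-session ramp factor. Off task (darkness) the
#' error-driven term is gated off and only the relaxation toward baseline
#' remains. The spontaneous LTD/LTP balance is already substituted away:
#' at the baseline state with \code{d = d0} the rate is exactly zero.
#'
#' @inheritParams layer_rates
#' @param ramp Ramp factor in \eqn{[0, 1]} multiplying the error-driven term
#'   (1 after the early sessions).
#' @param training Logical; \code{TRUE} during the training phase.
#' @return Rate of weight change, per hour.
#' @examples
#' p <- okr_params()
#' dw_pf_pc(baseline_state(p), p, d = 1)                  # 0 (fixed point)
#' dw_pf_pc(baseline_state(p), p, d = 2)                  # -1/0.33
#' @export
dw_pf_pc <- function(state, params, d, ramp = 1, training = TRUE) {
  w <- as.numeric(state)
  r <- okr_rates(params)
  drive <- 0
  if (training) {
    e <- layer_rates(w, params, d)$e
    drive <- -r$lambda1 * params$beta1 * ramp * params$alpha * params$f_mf * e
  }
  drive - r$lambda3 * (w[1L] - params$w0_pf_pc)
}

#' Plasticity rate of the PF-MLI synaptic weight
#'
#' Mirror rule of [dw_pf_pc()] with opposite sign of the error-driven term
#' (coherent PF and climbing-fiber activity potentiates the PF-MLI synapse):
#' \deqn{\dot W_{PF-MLI} = +\frac{\beta_3}{\tau_1}\,\alpha f_{MF}\, e
#'   \;-\; \frac{1}{\tau_3}\,(W_{PF-MLI} - W^0_{PF-MLI}).}
#' The ramp factor applies only if \code{params$ramp_on_mli} is set (by
#' default the ramp shapes the PF-PC rule alone). When
#' \code{params$freeze_pf_mli} is set the rate is identically zero.
#'
#' @inheritParams dw_pf_pc
#' @return Rate of weight change, per hour.
#' @export
dw_pf_mli <- function(state, params, d, ramp = 1, training = TRUE) {
  if (params$freeze_pf_mli) return(0)
  w <- as.numeric(state)
  r <- okr_rates(params)
  drive <- 0
  if (training) {
    e <- layer_rates(w, params, d)$e
    rm <- if (params$ramp_on_mli) ramp else 1
    drive <- r$lambda1 * params$beta3 * rm * params$alpha * params$f_mf * e
  }
  drive - r$lambda3 * (w[2L] - params$w0_pf_mli)
}

#' Plasticity rate of the MF-DN synaptic weight
#'
#' Hebbian-like consolidation rule at the mossy fiber-deep nuclei synapse,
#' driven by the disinhibition of the nuclei relative to baseline (the
#' corticonuclear channel through which cortical memory is transferred):
#' \deqn{\dot W_{MF-DN} = \frac{\gamma}{\tau_4}\,
#'   (W_{PF-MLI} - W_{PF-PC} + W^0_{PF-PC} - W^0_{PF-MLI})\,\alpha f_{MF}^2
#'   \;+\; \frac{1}{\tau_6}\,(W^0_{MF-DN} - W_{MF-DN}).}
#' This rule is active during both training and rest: most of the transfer
#' occurs during the slow cortical recovery after each session. With
#' \eqn{\gamma = 0} (corticonuclear block) only the decay toward baseline
#' remains.
#'
#' @inheritParams layer_rates
#' @return Rate of weight change, per hour.
#' @examples
#' p <- okr_params()
#' dw_mf_dn(baseline_state(p), p)  # 0 (fixed point)
#' @export
dw_mf_dn <- function(state, params) {
  w <- as.numeric(state)
  r <- okr_rates(params)
  r$lambda4 * params$gamma *
    (w[2L] - w[1L] + params$w0_pf_pc - params$w0_pf_mli) *
    params$alpha * params$f_mf^2 +
    r$lambda6 * (params$w0_mf_dn - w[3L])
}

#' Combined derivative field with non-negativity projection
#'
#' Evaluates the three plasticity rates at once, applying the weight floor:
#' weights are clamped at zero, and a weight sitting at (or numerically
#' below) zero with a negative rate gets rate zero, which also inactivates
#' its error-driven induction while clamped.
#'
#' @inheritParams dw_pf_pc
#' @return Numeric length-3 vector of rates (PF-PC, PF-MLI, MF-DN), per hour.
#' @keywords internal
circuit_derivs <- function(state, params, d, ramp = 1, training = TRUE) {
  w <- pmax(as.numeric(state), 0)
  dw <- c(dw_pf_pc(w, params, d, ramp, training),
          dw_pf_mli(w, params, d, ramp, training),
          dw_mf_dn(w, params))
  at_floor <- as.numeric(state) <= 0 & dw < 0
  dw[at_floor] <- 0
  dw
}

#' Baseline-balance residuals of a configuration
#'
#' The reduced plasticity rules are constructed so that the spontaneous
#' LTD/LTP balance holds exactly at the configured baseline weights: the
#' relaxation residuals of the PF-PC and MF-DN rules vanish there. This
#' function evaluates those residuals at a given state (by default the
#' configured baseline), i.e. the off-task rates
#' \eqn{-\lambda_3 (W_{PF-PC} - W^0_{PF-PC})} and the full MF-DN rate. A
#' consistent configuration returns \code{c(0, 0)}; a corrupted baseline
#' (initial state inconsistent with the configured \eqn{W^0}) shows up as a
#' nonzero residual.
#'
#' @param params An [okr_params()] object.
#' @param state State at which to evaluate; defaults to the configured
#'   baseline.
#' @param tol If not \code{NULL}, residuals larger than \code{tol} in
#'   absolute value raise a configuration-inconsistency error.
#' @return Named numeric vector \code{c(pf_pc = ..., mf_dn = ...)} of
#'   residual rates (per hour).
#' @examples
#' check_baseline_balance(okr_params())             # c(0, 0)
#' @export
check_baseline_balance <- function(params, state = baseline_state(params),
                                   tol = NULL) {
  res <- c(pf_pc = dw_pf_pc(state, params, d = params$d0, training = FALSE),
           mf_dn = dw_mf_dn(state, params))
  if (!is.null(tol) && any(abs(res) > tol))
    stop("configuration inconsistency: baseline-balance residuals (",
         paste(sprintf("%s = %.3g", names(res), res), collapse = ", "),
         ") exceed tolerance ", tol, call. = FALSE)
  res
}
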