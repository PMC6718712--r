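#' Model parameters for the cerebellar OKR circuit
#'
#' Builds and validates the full parameter set of the firing-rate model:
#' layer transmission coefficients, plasticity regulatory coefficients,
#' baseline synaptic weights, time constants and the gain read-out scaling.
#'
#' The circuit has three plastic synapse populations: parallel fiber to
#' Purkinje cell (PF-PC, the fast learning site), parallel fiber to
#' molecular-layer interneuron (PF-MLI, plasticity of opposite sign), and
#' mossy fiber to deep nuclei (MF-DN, the slow consolidation site). Each
#' learning rate is the inverse of a time constant, \eqn{\lambda_i = 1/\tau_i}.
#'
#' Time constants are expressed in hours. \code{tau1} (default 0.33 h, about
#' 20 min) governs error-driven induction at the cortical synapses, on the
#' scale over which PF-PC depression is induced electrophysiologically.
#' \code{tau3} (default 60 h, i.e. 2.5 days) governs cortical recovery in
#' darkness, matching the observation that recovery from training takes more
#' than one day. \code{tau4} and \code{tau6} (default 132 h, i.e. 5.5 days,
#' and equal by construction) govern nuclear transfer and decay; the slow
#' nuclear dynamics is what accumulates long-term memory across daily
#' sessions. See the package vignette for the full rationale.
#'
#' \code{lambda2}, \code{lambda5}, \code{ltd_spon}, \code{f_pc_max} and
#' \code{cf_bar}/\code{dn_bar} are carried as documentation fields only: the
#' baseline-balance substitution eliminates them from the reduced plasticity
#' rules, and no evaluated code path reads them.
#'
#' @param f_mf Mossy-fiber population rate (dimensionless, normalised; 1).
#' @param alpha Granular-layer transmission coefficient, in \eqn{[0, 1]}.
#'   Normally set directly; see [transmission_coefficient()] to derive it
#'   from Golgi-cell weights.
#' @param beta1 Regulatory coefficient for train-induced PF-PC LTD.
#' @param beta2 Regulatory coefficient substituted for both \code{beta1} and
#'   \code{beta3} under climbing-fiber (inferior olive) blockade, or
#'   \code{NA} when unused.
#' @param beta3 Regulatory coefficient for train-induced PF-MLI LTP.
#' @param gamma Corticonuclear transmission coefficient (PC to DN).
#' @param w0_pf_pc,w0_pf_mli,w0_mf_dn Baseline synaptic weights.
#' @param tau1,tau3,tau4,tau6 Time constants in hours (see Details);
#'   \code{tau3 = Inf} represents a vanishing recovery rate.
#' @param d0 Baseline desired gain in cerebellar space.
#' @param g_okr0 Read-out scaling from cerebellar space to OKR gain.
#' @param freeze_pf_mli If \code{TRUE}, the PF-MLI weight is held fixed at
#'   its baseline (hard constraint; its derivative is forced to zero).
#' @param ramp_on_mli If \code{TRUE}, the first-sessions ramp factor also
#'   multiplies the PF-MLI error term; by default it applies to the PF-PC
#'   rule only.
#' @param lambda2,lambda5,ltd_spon,f_pc_max,dn_bar,cf_bar Documentation-only
#'   symbols of the unreduced plasticity rules (never evaluated).
#'
#' @return An object of class \code{"okr_params"} (a validated list).
#' @seealso [get_scenario()] for the registered lesion configurations,
#'   [check_baseline_balance()] for configuration consistency.
#' @examples
#' p <- okr_params()
#' p$alpha
#' okr_params(alpha = 0.3)  # attenuated granular-layer transmission
#' @export
okr_params <- function(f_mf = 1,
                       alpha = 1,
                       beta1 = 1,
                       beta2 = NA_real_,
                       beta3 = 0.5,
                       gamma = 1,
                       w0_pf_pc = 1,
                       w0_pf_mli = 1,
                       w0_mf_dn = 1,
                       tau1 = 0.33,
                       tau3 = 60,
                       tau4 = 132,
                       tau6 = tau4,
                       d0 = 1,
                       g_okr0 = 0.3,
                       freeze_pf_mli = FALSE,
                       ramp_on_mli = FALSE,
                       lambda2 = NA_real_,
                       lambda5 = NA_real_,
                       ltd_spon = NA_real_,
                       f_pc_max = NA_real_,
                       dn_bar = NA_real_,
                       cf_bar = NA_real_) {
  p <- list(f_mf = f_mf, alpha = alpha, beta1 = beta1, beta2 = beta2,
            beta3 = beta3, gamma = gamma,
            w0_pf_pc = w0_pf_pc, w0_pf_mli = w0_pf_mli, w0_mf_dn = w0_mf_dn,
            tau1 = tau1, tau3 = tau3, tau4 = tau4, tau6 = tau6,
            d0 = d0, g_okr0 = g_okr0,
            freeze_pf_mli = isTRUE(freeze_pf_mli),
            ramp_on_mli = isTRUE(ramp_on_mli),
            lambda2 = lambda2, lambda5 = lambda5, ltd_spon = ltd_spon,
            f_pc_max = f_pc_max, dn_bar = dn_bar, cf_bar = cf_bar)
  validate_okr_params(p)
  class(p) <- "okr_params"
  p
}

validate_okr_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num1(p$f_mf), p$f_mf >= 0)
  if (!num1(p$alpha) || p$alpha < 0 || p$alpha > 1)
    stop("'alpha' must be a single number in [0, 1]", call. = FALSE)
  for (nm in c("beta1", "beta3", "gamma", "w0_pf_pc", "w0_pf_mli",
               "w0_mf_dn", "g_okr0")) {
    if (!num1(p[[nm]]) || p[[nm]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", nm),
           call. = FALSE)
  }
  for (nm in c("tau1", "tau4", "tau6")) {
    if (!num1(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("'%s' must be a single positive number (hours)", nm),
           call. = FALSE)
  }
  # tau3 = Inf encodes lambda3 = 0 (no cortical recovery)
  if (!(is.numeric(p$tau3) && length(p$tau3) == 1L &&
        (is.infinite(p$tau3) || p$tau3 > 0)))
    stop("'tau3' must be a positive number or Inf (hours)", call. = FALSE)
  if (!num1(p$d0) || p$d0 < 0)
    stop("'d0' must be a single non-negative number", call. = FALSE)
  invisible(p)
}

#' Learning rates from time constants
#'
#' @param params An [okr_params()] object.
#' @return Named list with \code{lambda1}, \code{lambda3}, \code{lambda4},
#'   \code{lambda6} in per-hour units; \code{lambda3} is 0 when
#'   \code{tau3 = Inf}.
#' @keywords internal
okr_rates <- function(params) {
  list(lambda1 = 1 / params$tau1,
       lambda3 = if (is.infinite(params$tau3)) 0 else 1 / params$tau3,
       lambda4 = 1 / params$tau4,
       lambda6 = 1 / params$tau6)
}

#' Granular-layer transmission coefficient from Golgi-cell weights
#'
#' The granule-cell population output is shaped by feedforward (MF-GO) and
#' feedback (PF-GO) Golgi inhibition; solving the granular-layer balance for
#' the effective input-layer gain gives
#' \deqn{\alpha = (1 - W_{PF\mbox{-}GO}) / (1 + W_{MF\mbox{-}GO}).}
#' With no Golgi inhibition \eqn{\alpha = 1}; total feedback inhibition gives
#' \eqn{\alpha = 0}. This is an optional derivation: scenarios normally set
#' \eqn{\alpha} directly.
#'
#' @param w_pf_go Parallel fiber to Golgi-cell weight (must not exceed 1).
#' @param w_mf_go Mossy fiber to Golgi-cell weight (non-negative).
#' @return The transmission coefficient, guaranteed to lie in \eqn{[0, 1]}.
#' @examples
#' transmission_coefficient(0, 0)      # 1: no inhibition
#' transmission_coefficient(0.4, 1.0)  # 0.3
#' @export
transmission_coefficient <- function(w_pf_go, w_mf_go) {
  stopifnot(is.numeric(w_pf_go), is.numeric(w_mf_go),
            length(w_pf_go) == 1L, length(w_mf_go) == 1L)
  if (w_mf_go < 0)
    stop("'w_mf_go' must be non-negative", call. = FALSE)
  if (w_pf_go > 1)
    stop("'w_pf_go' must not exceed 1", call. = FALSE)
  a <- (1 - w_pf_go) / (1 + w_mf_go)
  if (is.na(a) || a < 0 || a > 1)
    stop("inputs produce a transmission coefficient outside [0, 1]",
         call. = FALSE)
  a
}

#' Circuit state (synaptic weights at a time point)
#'
#' @param w_pf_pc,w_pf_mli,w_mf_dn Synaptic weights (non-negative).
#' @param t Time in hours.
#' @return Object of class \code{"okr_state"}: a named numeric weight vector
#'   with a \code{t} attribute.
#' @examples
#' okr_state(1, 1, 1)
#' @export
okr_state <- function(w_pf_pc, w_pf_mli, w_mf_dn, t = 0) {
  w <- c(w_pf_pc = w_pf_pc, w_pf_mli = w_pf_mli, w_mf_dn = w_mf_dn)
  stopifnot(is.numeric(w), length(w) == 3L, all(is.finite(w)))
  if (any(w < 0))
    stop("synaptic weights must be non-negative", call. = FALSE)
  structure(w, t = t, class = "okr_state")
}

#' Baseline circuit state of a parameter set
#'
#' @param params An [okr_params()] object.
#' @return The [okr_state()] at the configured baseline weights.
#' @export
baseline_state <- function(params) {
  okr_state(params$w0_pf_pc, params$w0_pf_mli, params$w0_mf_dn)
}

#' Layer population rates and error signal
#'
#' Computes the instantaneous feedforward quantities of the circuit:
#' \itemize{
#'   \item \eqn{f_{PF} = \alpha f_{MF}} (granular-layer output),
#'   \item \eqn{f_{PC} = (W_{PF-PC} - W_{PF-MLI}) f_{PF}} (Purkinje output,
#'     net of interneuron inhibition),
#'   \item \eqn{f_{DN} = W_{MF-DN} f_{MF} - f_{PC}} (deep-nuclei output;
#'     the minus sign reflects the GABAergic nature of PCs),
#'   \item \eqn{e = d\, f_{MF} - f_{DN}} (the learning error conveyed by
#'     climbing fibers, for desired gain \code{d}).
#' }
#'
#' @param state An [okr_state()] (or plain length-3 weight vector in the
#'   order PF-PC, PF-MLI, MF-DN).
#' @param params An [okr_params()] object.
#' @param d Desired gain in cerebellar space.
#' @return Named list with \code{f_pf}, \code{f_pc}, \code{f_dn}, \code{e}.
#' @examples
#' p <- okr_params()
#' layer_rates(baseline_state(p), p, d = 1)  # e = 0 at baseline
#' @export
layer_rates <- function(state, params, d) {
  w <- as.numeric(state)
  f_pf <- params$alpha * params$f_mf
  f_pc <- (w[1L] - w[2L]) * f_pf
  f_dn <- w[3L] * params$f_mf - f_pc
  list(f_pf = f_pf, f_pc = f_pc, f_dn = f_dn, e = d * params$f_mf - f_dn)
}

#' OKR gain read-out
#'
#' Maps the synaptic state to the behavioural optokinetic-reflex gain:
#' \deqn{G_{OKR} = g_{OKR0}\,(W_{MF-DN} - \alpha W_{PF-PC} + \alpha W_{PF-MLI}).}
#' The read-out is linear in each weight and in \code{g_okr0}; at the normal
#' baseline (all weights 1, \eqn{\alpha = 1}) it equals \code{g_okr0}.
#'
#' @inheritParams layer_rates
#' @return The OKR gain (dimensionless scalar).
#' @examples
#' p <- okr_params()
#' okr_gain(baseline_state(p), p)  # 0.3
#' @export
okr_gain <- function(state, params) {
  w <- as.numeric(state)
  params$g_okr0 *
    (w[3L] - w[1L] * params$alpha + w[2L] * params$alpha)
}

#' @export
print.okr_params <- function(x, ...) {
  cat("Cerebellar OKR model parameters\n")
  cat(sprintf("  transmission: alpha = %g, gamma = %g, f_MF = %g\n",
              x$alpha, x$gamma, x$f_mf))
  b2 <- if (is.na(x$beta2)) "-" else format(x$beta2)
  cat(sprintf("  regulatory:   beta1 = %g, beta2 = %s, beta3 = %g\n",
              x$beta1, b2, x$beta3))
  cat(sprintf("  baselines:    W0[PF-PC] = %g, W0[PF-MLI] = %g, W0[MF-DN] = %g\n",
              x$w0_pf_pc, x$w0_pf_mli, x$w0_mf_dn))
  cat(sprintf("  time const.:  tau1 = %g h, tau3 = %g h, tau4 = tau6 = %g h\n",
              x$tau1, x$tau3, x$tau4))
  cat(sprintf("  read-out:     d0 = %g, g_OKR0 = %g\n", x$d0, x$g_okr0))
  if (x$freeze_pf_mli) cat("  PF-MLI weight frozen at baseline\n")
  invisible(x)
}
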