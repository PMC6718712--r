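#' @name scenarios
#' @title Registered lesion scenarios
#'
#' @description
#' Each scenario is an immutable named configuration: parameter overrides on
#' the normal defaults, baseline weight overrides, optional event triggers,
#' and a provenance note. The registry covers the normal condition and the
#' classic cerebellar lesion manipulations:
#'
#' \describe{
#'   \item{normal}{wild-type defaults (no overrides).}
#'   \item{mf_gc_attenuation}{granular-layer transmission attenuated,
#'     \eqn{\alpha = 0.3}.}
#'   \item{pf_pc_train_ltd_partial / _complete}{train-induced PF-PC LTD
#'     blocked, \eqn{\beta_1 = 0.3} / \eqn{0}.}
#'   \item{pf_pc_spont_ltd_block}{spontaneous PF-PC LTD blocked; the
#'     disturbed spontaneous balance shifts the baselines to
#'     \eqn{W^0 = (1.1, 1.1, 0)}.}
#'   \item{pf_pc_spont_ltp_block}{spontaneous PF-PC LTP blocked; the PF-PC
#'     weight collapses to its floor, giving \eqn{W^0_{PF-PC} = 0},
#'     \eqn{\beta_1 = 0}, \eqn{\lambda_3 = 0} (\code{tau3 = Inf}),
#'     \eqn{\beta_3 = 0.48}, \eqn{W^0_{PF-MLI} = W^0_{MF-DN} = 0.5}.}
#'   \item{pf_pc_rate_alteration}{altered induction/recovery rates,
#'     \code{tau1 = 2} h and \code{tau3 = 36} h (1.5 days); exposed as a
#'     parameterised family via the \code{tau1}/\code{tau3} arguments of
#'     [get_scenario()].}
#'   \item{cf_block_partial / _complete}{climbing-fiber signalling to the
#'     cortex blocked: \eqn{\beta_1} and \eqn{\beta_3} both replaced by
#'     \eqn{\beta_2 = 0.3} / \eqn{0}.}
#'   \item{pf_mli_no_plasticity}{PF-MLI plasticity blocked: \eqn{\beta_3 = 0}
#'     and the weight held fixed at baseline (hard freeze).}
#'   \item{pf_mli_no_baseline}{PF-MLI baseline activity eliminated:
#'     \eqn{W^0_{PF-MLI} = W^0_{MF-DN} = 0}, \eqn{W^0_{PF-PC} = 0.4},
#'     \eqn{\beta_1 = 0.1}, \eqn{\beta_3 = 0.2}.}
#'   \item{pc_dn_block}{corticonuclear transmission cut during learning:
#'     event \eqn{\gamma \to 0} immediately after training on the fourth
#'     session.}
#' }
NULL

scenario_registry <- function(tau1_alt = 2, tau3_alt = 36) {
  list(
    normal = list(
      overrides = list(),
      notes = "wild-type configuration; all coefficients at defaults"),
    mf_gc_attenuation = list(
      overrides = list(alpha = 0.3),
      notes = "granular-layer (MF-GC) transmission reduced from 1 to 0.3"),
    pf_pc_train_ltd_partial = list(
      overrides = list(beta1 = 0.3),
      notes = "partial blockade of train-induced PF-PC LTD"),
    pf_pc_train_ltd_complete = list(
      overrides = list(beta1 = 0),
      notes = "complete blockade of train-induced PF-PC LTD"),
    pf_pc_spont_ltd_block = list(
      overrides = list(w0_pf_pc = 1.1, w0_pf_mli = 1.1, w0_mf_dn = 0),
      notes = "spontaneous PF-PC LTD blocked; baselines shifted to 1.1/1.1/0"),
    pf_pc_spont_ltp_block = list(
      overrides = list(w0_pf_pc = 0, beta1 = 0, tau3 = Inf, beta3 = 0.48,
                       w0_pf_mli = 0.5, w0_mf_dn = 0.5),
      notes = "spontaneous PF-PC LTP blocked; PF-PC weight clamped at 0"),
    pf_pc_rate_alteration = list(
      overrides = list(tau1 = tau1_alt, tau3 = tau3_alt),
      notes = "altered learning/recovery rates at the PF-PC synapse"),
    cf_block_partial = list(
      overrides = list(beta1 = 0.3, beta3 = 0.3, beta2 = 0.3),
      notes = "partial blockade of CF signal: beta1 and beta3 replaced by beta2 = 0.3"),
    cf_block_complete = list(
      overrides = list(beta1 = 0, beta3 = 0, beta2 = 0),
      notes = "complete blockade of CF signal: beta1 and beta3 replaced by beta2 = 0"),
    pf_mli_no_plasticity = list(
      overrides = list(beta3 = 0, freeze_pf_mli = TRUE),
      notes = "PF-MLI weight fixed at its baseline for all t"),
    pf_mli_no_baseline = list(
      overrides = list(w0_pf_mli = 0, w0_mf_dn = 0, w0_pf_pc = 0.4,
                       beta1 = 0.1, beta3 = 0.2),
      notes = "PF-MLI baseline activity eliminated; compensatory baseline shifts"),
    pc_dn_block = list(
      overrides = list(),
      events = list(list(after_training_of_session = 4,
                         set = list(gamma = 0))),
      notes = "corticonuclear transmission cut (gamma -> 0) after session-4 training")
  )
}

#' List the registered scenario names
#'
#' @return Character vector of the registered scenario identifiers.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  names(scenario_registry())
}

#' Retrieve a registered scenario configuration
#'
#' @param name One of [list_scenarios()].
#' @param tau1,tau3 For \code{"pf_pc_rate_alteration"} only: the altered
#'   induction and recovery time constants in hours (defaults 2 and 36,
#'   i.e. 1.5 days), exposing the scenario as a parameterised family.
#' @return Object of class \code{"okr_scenario"}: list with \code{name},
#'   \code{overrides}, \code{events} and \code{notes}.
#' @examples
#' get_scenario("mf_gc_attenuation")$overrides
#' @export
get_scenario <- function(name, tau1 = 2, tau3 = 36) {
  reg <- scenario_registry(tau1_alt = tau1, tau3_alt = tau3)
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg))
    stop("unknown scenario '", paste(name, collapse = ","),
         "'; registered scenarios: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  sc <- reg[[name]]
  structure(list(name = name, overrides = sc$overrides,
                 events = sc$events %||% list(), notes = sc$notes),
            class = "okr_scenario")
}

#' Resolve a scenario into a full parameter set
#'
#' Applies the scenario's overrides on the normal defaults. Applying a
#' scenario is idempotent: the overrides replace, never accumulate.
#'
#' @param scenario An \code{"okr_scenario"} (or scenario name).
#' @param base Baseline parameter set to override (normal defaults).
#' @return An [okr_params()] object with a \code{"scenario"} attribute.
#' @examples
#' scenario_params("cf_block_complete")$beta1
#' @export
scenario_params <- function(scenario, base = okr_params()) {
  if (is.character(scenario)) scenario <- get_scenario(scenario)
  stopifnot(inherits(scenario, "okr_scenario"))
  p <- base
  ov <- scenario$overrides
  if (length(ov)) p[names(ov)] <- ov
  validate_okr_params(p)
  attr(p, "scenario") <- scenario$name
  p
}

#' @export
print.okr_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n ", x$notes, "\n")
  if (length(x$overrides))
    cat("  overrides:",
        paste(names(x$overrides), unlist(x$overrides), sep = " = ",
              collapse = ", "), "\n")
  if (length(x$events)) cat("  events:", length(x$events), "\n")
  invisible(x)
}
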