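#' Per-session behavioural metrics
#'
#' Short-term (fast) adaptation is the gain change across one training hour
#' (post-training minus pre-training of the same session); long-term (slow)
#' adaptation is the gain after training on a given day relative to the
#' pre-training gain of the first day.
#'
#' @param sim An \code{"okr_sim"} object from [run_protocol()].
#' @param session Session index (default: all sessions).
#' @return data.frame with one row per requested session: the three gain
#'   marks, \code{stm_increment}, \code{ltm_increment} and the net
#'   percentage weight change of each synapse (see [weight_change_pct()]).
#' @examples
#' sim <- simulate_okr(protocol = okr_protocol(n_sessions = 2))
#' session_metrics(sim)
#' @export
session_metrics <- function(sim, session = NULL) {
  stopifnot(inherits(sim, "okr_sim"))
  sm <- sim$sessions
  if (is.null(sm) || !nrow(sm))
    stop("simulation has no session marks", call. = FALSE)
  if (is.null(session)) session <- sm$session
  if (any(!session %in% sm$session))
    stop("session index out of range", call. = FALSE)
  rows <- sm[match(session, sm$session), ]
  out <- data.frame(
    session = rows$session,
    gain_pre = rows$gain_pre,
    gain_post = rows$gain_post,
    gain_end_rest = rows$gain_end_rest,
    stm_increment = rows$gain_post - rows$gain_pre,
    ltm_increment = rows$gain_post - sm$gain_pre[sm$session == 1L])
  for (syn in c("pf_pc", "pf_mli", "mf_dn"))
    out[[paste0("pct_", syn)]] <-
      vapply(out$session, function(s)
        tryCatch(weight_change_pct(sim, s, toupper(gsub("_", "-", syn))),
                 error = function(e) NA_real_),
        numeric(1))
  rownames(out) <- NULL
  out
}

synapse_key <- function(synapse) {
  key <- tolower(gsub("-", "_", synapse))
  if (!key %in% c("pf_pc", "pf_mli", "mf_dn"))
    stop("'synapse' must be one of PF-PC, PF-MLI, MF-DN", call. = FALSE)
  key
}

#' Percentage synaptic weight change at a session
#'
#' Two conventions are provided, matching the two quantities of interest in
#' lesion comparisons:
#' \describe{
#'   \item{\code{type = "net"} (default)}{the net change of the weight at
#'     the end of the session (after its rest phase) relative to the
#'     scenario's own baseline \eqn{W^0}:
#'     \eqn{100\,(W_{end}(s) - W^0)/W^0}. This is the cumulative state
#'     change the lesion comparisons report.}
#'   \item{\code{type = "training"}}{the train-induced component within the
#'     session: \eqn{100\,(W_{post}(s) - W_{pre}(s))/W^0}. This isolates
#'     the error-driven induction of that day's training hour.}
#' }
#' Signed; negative values are depression. Percentages are referenced to
#' the scenario's own baseline (lesions shift baselines).
#'
#' @param sim An \code{"okr_sim"} object.
#' @param session Session index.
#' @param synapse One of \code{"PF-PC"}, \code{"PF-MLI"}, \code{"MF-DN"}.
#' @param type \code{"net"} or \code{"training"} (see Details).
#' @return Signed percentage (scalar).
#' @examples
#' sim <- simulate_okr(protocol = okr_protocol(n_sessions = 2))
#' weight_change_pct(sim, 2, "PF-PC")
#' @export
weight_change_pct <- function(sim, session, synapse,
                              type = c("net", "training")) {
  stopifnot(inherits(sim, "okr_sim"))
  type <- match.arg(type)
  key <- synapse_key(synapse)
  sm <- sim$sessions
  if (!session %in% sm$session)
    stop("session index out of range", call. = FALSE)
  row <- sm[sm$session == session, ]
  w0 <- sim$params[[paste0("w0_", key)]]
  if (w0 == 0)
    stop("percentage change is undefined: baseline weight of ", synapse,
         " is 0 in this scenario", call. = FALSE)
  num <- switch(type,
                net = row[[paste0("w_", key, "_end")]] - w0,
                training = row[[paste0("w_", key, "_post")]] -
                  row[[paste0("w_", key, "_pre")]])
  100 * num / w0
}

#' Compare scenarios on the standard protocol
#'
#' Runs each named scenario through the same protocol and tabulates the
#' final-session behaviour: short- and long-term gain increments and the
#' net percentage weight change of each synapse. Rows keep the input order.
#' Percentage entries are \code{NA} where the scenario's baseline weight is
#' zero (undefined percentage).
#'
#' @param names Character vector of scenario names (default: all registered).
#' @param protocol An [okr_protocol()].
#' @param session Session at which to measure (default: last).
#' @return data.frame with columns \code{scenario}, \code{stm}, \code{ltm},
#'   \code{pct_pf_pc}, \code{pct_pf_mli}, \code{pct_mf_dn}.
#' @examples
#' \donttest{
#' compare_scenarios(c("normal", "cf_block_complete"))
#' }
#' @export
compare_scenarios <- function(names = list_scenarios(),
                              protocol = okr_protocol(),
                              session = protocol$n_sessions) {
  rows <- lapply(names, function(nm) {
    sim <- simulate_okr(nm, protocol)
    m <- session_metrics_core(sim, session)
    pct <- vapply(c("PF-PC", "PF-MLI", "MF-DN"), function(s)
      tryCatch(weight_change_pct(sim, session, s),
               error = function(e) NA_real_), numeric(1))
    data.frame(scenario = nm, stm = m$stm, ltm = m$ltm,
               pct_pf_pc = pct[[1L]], pct_pf_mli = pct[[2L]],
               pct_mf_dn = pct[[3L]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# stm/ltm without the pct columns (avoids undefined-percentage errors)
session_metrics_core <- function(sim, session) {
  sm <- sim$sessions
  row <- sm[sm$session == session, ]
  list(stm = row$gain_post - row$gain_pre,
       ltm = row$gain_post - sm$gain_pre[sm$session == 1L])
}
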