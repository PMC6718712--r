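#' @export
print.okr_sim <- function(x, ...) {
  n <- x$protocol$n_sessions
  cat("Cerebellar OKR adaptation simulation\n")
  if (!is.na(x$scenario)) cat("  scenario:", x$scenario, "\n")
  cat(sprintf("  protocol: %d session(s), %g h train + %g h rest, d_train = %g\n",
              n, x$protocol$train_hours, x$protocol$rest_hours,
              x$protocol$d_train))
  sm <- x$sessions
  cat(sprintf("  gain: %.3f (pre-training) -> %.3f (post-training, session %d)\n",
              sm$gain_pre[1L], sm$gain_post[n], n))
  cat(sprintf("  samples: %d over %.0f h\n", nrow(x$trajectory),
              max(x$trajectory$t_hours)))
  invisible(x)
}

#' Summarise a simulation: per-session adaptation metrics
#'
#' @param object An \code{"okr_sim"} object.
#' @param ... Unused.
#' @return An object of class \code{"summary.okr_sim"} wrapping the
#'   [session_metrics()] table.
#' @export
summary.okr_sim <- function(object, ...) {
  out <- list(scenario = object$scenario,
              metrics = session_metrics(object),
              final = coef(object))
  class(out) <- "summary.okr_sim"
  out
}

#' @export
print.summary.okr_sim <- function(x, digits = 4, ...) {
  if (!is.na(x$scenario)) cat("Scenario:", x$scenario, "\n")
  cat("Per-session adaptation metrics:\n")
  print(format(x$metrics, digits = digits), row.names = FALSE)
  cat("Final synaptic weights:\n")
  print(round(x$final, digits))
  invisible(x)
}

#' Final synaptic weights of a simulation
#'
#' @param object An \code{"okr_sim"} object.
#' @param ... Unused.
#' @return Named numeric vector of the three weights at the end of the run.
#' @export
coef.okr_sim <- function(object, ...) {
  tr <- object$trajectory
  last <- tr[nrow(tr), ]
  c(w_pf_pc = last$w_pf_pc, w_pf_mli = last$w_pf_mli, w_mf_dn = last$w_mf_dn)
}

#' @export
as.data.frame.okr_sim <- function(x, ...) {
  x$trajectory
}

#' Plot gain and synaptic-weight trajectories
#'
#' Two stacked panels in the style of the classic adaptation figures: OKR
#' gain over time on top (with the pre-training level dashed), the three
#' synaptic weights below.
#'
#' @param x An \code{"okr_sim"} object.
#' @param ... Additional graphical parameters passed to
#'   \code{\link[graphics]{matplot}}.
#' @return \code{x}, invisibly.
#' @export
plot.okr_sim <- function(x, ...) {
  tr <- x$trajectory
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  days <- tr$t_hours / 24
  graphics::plot(days, tr$gain, type = "l", col = "black",
                 xlab = "", ylab = "OKR gain",
                 main = if (!is.na(x$scenario)) x$scenario else "OKR adaptation")
  graphics::abline(h = x$sessions$gain_pre[1L], lty = 2, col = "grey40")
  graphics::matplot(days, as.matrix(tr[, c("w_pf_pc", "w_pf_mli", "w_mf_dn")]),
                    type = "l", lty = 1,
                    col = c("firebrick", "forestgreen", "steelblue"),
                    xlab = "time (days)", ylab = "synaptic weight", ...)
  graphics::legend("topleft", bty = "n", lty = 1, cex = 0.8,
                   col = c("firebrick", "forestgreen", "steelblue"),
                   legend = c("PF-PC", "PF-MLI", "MF-DN"))
  invisible(x)
}
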