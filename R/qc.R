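#' Quality-control filter for a control/treated fit pair
#'
#' A protein enters the melting-point shift analysis only if both the
#' vehicle-control and the treated fits are trustworthy: converged, good
#' fit (r-squared at least \code{r2_min}), plateau below
#' \code{plateau_max} (high plateaus make the 50% crossing poorly
#' determined), and a defined melting point lying inside the observed
#' temperature window extended by \code{tm_window_margin} degrees. Every
#' violated condition contributes a named reason code, suffixed
#' \code{_control} or \code{_treated}.
#'
#' @param fit_control,fit_treated \code{unfolding_fit} objects for the two
#'   conditions of one protein.
#' @param settings a [fit_settings()] list (thresholds \code{r2_min},
#'   \code{plateau_max}, \code{tm_window_margin}).
#' @return list with \code{pass} (logical) and \code{reasons} (character
#'   vector, empty when passing).
#' @export
qc_filter <- function(fit_control, fit_treated, settings = fit_settings()) {
  reasons <- character()
  for (side in c("control", "treated")) {
    fit <- if (side == "control") fit_control else fit_treated
    if (!fit$converged) {
      reasons <- c(reasons, paste0("not_converged_", side))
      next
    }
    r2 <- fit$r_squared
    if (is.na(r2) || r2 < settings$r2_min) {
      reasons <- c(reasons, paste0("low_r2_", side))
    }
    p <- fit$coefficients[["p"]]
    if (p >= settings$plateau_max) {
      reasons <- c(reasons, paste0("high_plateau_", side))
    }
    if (is.na(fit$tm)) {
      reasons <- c(reasons, paste0("no_tm_", side))
    } else {
      tw <- range(fit$data$temperature_c)
      m <- settings$tm_window_margin
      if (fit$tm < tw[1] - m || fit$tm > tw[2] + m) {
        reasons <- c(reasons, paste0("tm_out_of_window_", side))
      }
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
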