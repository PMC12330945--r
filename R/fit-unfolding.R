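#' Fit settings for melting-curve regression
#'
#' Collects the tunable knobs of [fit_unfolding()] and the downstream QC
#' filter in one validated list, so a pipeline configuration can carry them
#' around explicitly.
#'
#' @param min_points minimum number of distinct temperatures with data
#'   required to attempt a fit.
#' @param r2_min minimum r-squared (per condition) to pass QC.
#' @param plateau_max maximum fitted plateau to pass QC.
#' @param tm_window_margin Tm must fall within the observed temperature
#'   window extended by this many degrees on each side to pass QC.
#' @param a_bounds,p_bounds box constraints for the slope and plateau.
#'   Bounds for the inflection \code{b} are data-driven:
#'   \code{[min(T) - b_margin, max(T) + b_margin]}.
#' @param b_margin margin (degrees Celsius) added to the temperature window
#'   for the \code{b} bounds.
#' @param multistart_a,multistart_b multiplicative perturbations of the
#'   initial slope and additive perturbations (degrees Celsius) of the
#'   initial inflection tried, as a grid, when the first fit fails.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return a list of class \code{"fit_settings"}.
#' @export
fit_settings <- function(min_points = 5,
                         r2_min = 0.8,
                         plateau_max = 0.4,
                         tm_window_margin = 5,
                         a_bounds = c(-10, -1e-3),
                         p_bounds = c(0, 0.999),
                         b_margin = 10,
                         multistart_a = c(0.5, 1, 2),
                         multistart_b = c(-3, 0, 3),
                         max_iter = 500) {
  stopifnot(min_points >= 4, r2_min >= 0, r2_min <= 1,
            length(a_bounds) == 2, a_bounds[1] < a_bounds[2], a_bounds[2] < 0,
            length(p_bounds) == 2, p_bounds[1] >= 0, p_bounds[2] < 1,
            b_margin >= 0, max_iter >= 1)
  structure(list(min_points = min_points, r2_min = r2_min,
                 plateau_max = plateau_max,
                 tm_window_margin = tm_window_margin,
                 a_bounds = a_bounds, p_bounds = p_bounds,
                 b_margin = b_margin,
                 multistart_a = multistart_a, multistart_b = multistart_b,
                 max_iter = max_iter),
            class = "fit_settings")
}

#' Fit the equilibrium unfolding model to a melting curve
#'
#' Estimates the parameters (a, b, p) of the unfolding curve
#' (see [eval_unfolding()]) from reference-normalized abundance
#' measurements by bounded nonlinear least squares, pooling all replicate
#' points jointly. Because each replicate is normalized to its
#' lowest-temperature intensity, the observable is the \emph{relative}
#' curve \eqn{f(T)/f(T_{ref})}, which equals 1 at the reference by
#' construction; the fit uses exactly that model, and the melting point is
#' then read off the absolute curve via [melting_point()].
#'
#' Initialization: the plateau starts at the smallest observed relative
#' abundance (clipped to \code{[0, 0.3]}), the inflection at the
#' temperature whose mean abundance is closest to \eqn{(1+p_0)/2}, and the
#' slope from the finite-difference slope of the mean curve around that
#' temperature (a logistic has derivative \eqn{a(1-p)/4} at its midpoint).
#' If the first bounded Levenberg-Marquardt run fails, a 3x3 grid of
#' perturbed starting values is tried; \code{converged} is \code{FALSE}
#' only if all fail.
#'
#' @param object a melting curve: either a data frame with columns
#'   \code{temperature_c} and \code{rel_abundance} (plus optionally
#'   \code{replicate}), e.g. one element of [normalize_to_reference()]
#'   output, or a formula \code{rel_abundance ~ temperature_c} with
#'   \code{data}.
#' @param settings a [fit_settings()] list.
#' @param data for the formula method, a data frame in which to evaluate
#'   the formula.
#' @param ... unused.
#' @return an object of class \code{"unfolding_fit"} with components
#'   \code{coefficients} (named \code{a}, \code{b}, \code{p}), \code{tm},
#'   \code{r_squared}, \code{rmse}, \code{n_points} (distinct
#'   temperatures), \code{converged}, \code{reference_temperature},
#'   \code{data}, \code{fitted.values}, \code{residuals} and
#'   \code{reason} (\code{NA} or a skip/failure code such as
#'   \code{"insufficient_points"}). Methods: \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}, \code{simulate}.
#' @examples
#' tt <- seq(43, 60, length.out = 6)
#' y  <- unfolding_rel(tt, a = -0.8, b = 51, p = 0.1, t_ref = 43)
#' fit <- fit_unfolding(data.frame(temperature_c = tt, rel_abundance = y))
#' coef(fit)
#' fit$tm
#' @export
fit_unfolding <- function(object, ...) UseMethod("fit_unfolding")

#' @rdname fit_unfolding
#' @export
fit_unfolding.data.frame <- function(object, settings = fit_settings(), ...) {
  stopifnot(all(c("temperature_c", "rel_abundance") %in% names(object)))
  fit_unfolding_impl(object$temperature_c, object$rel_abundance, settings,
                     protein_id = attr(object, "protein_id"),
                     condition = attr(object, "condition"),
                     call = match.call())
}

#' @rdname fit_unfolding
#' @export
fit_unfolding.formula <- function(object, data, settings = fit_settings(),
                                  ...) {
  mf <- stats::model.frame(object, data)
  fit_unfolding_impl(mf[[2L]], mf[[1L]], settings, call = match.call())
}

fit_unfolding_impl <- function(temperature, y, settings,
                               protein_id = NULL, condition = NULL,
                               call = NULL) {
  keep <- is.finite(temperature) & is.finite(y)
  temperature <- temperature[keep]
  y <- y[keep]
  n_temps <- length(unique(temperature))

  skeleton <- structure(
    list(coefficients = c(a = NA_real_, b = NA_real_, p = NA_real_),
         tm = NA_real_, r_squared = NA_real_, rmse = NA_real_,
         n_points = n_temps, converged = FALSE, reason = NA_character_,
         reference_temperature = if (length(temperature)) min(temperature) else NA_real_,
         data = data.frame(temperature_c = temperature, rel_abundance = y),
         fitted.values = NULL, residuals = NULL,
         protein_id = protein_id, condition = condition,
         settings = settings, call = call),
    class = "unfolding_fit")

  if (n_temps < settings$min_points) {
    skeleton$reason <- "insufficient_points"
    return(skeleton)
  }

  t_ref <- min(temperature)
  t_min <- min(temperature)
  t_max <- max(temperature)
  lower <- c(settings$a_bounds[1], t_min - settings$b_margin,
             settings$p_bounds[1])
  upper <- c(settings$a_bounds[2], t_max + settings$b_margin,
             settings$p_bounds[2])

  start <- unfolding_start(temperature, y, settings)
  grid <- expand.grid(fa = settings$multistart_a, fb = settings$multistart_b)
  # first attempt is the unperturbed start; perturbations only on failure
  ord <- order(grid$fa != 1 | grid$fb != 0)
  grid <- grid[ord, , drop = FALSE]

  resid_fn <- function(par) {
    y - unfolding_rel(temperature, par[1], par[2], par[3], t_ref)
  }
  # analytic Jacobian of the residuals wrt (a, b, p); r = -f(T)/f(t_ref)
  jac_fn <- function(par) {
    a <- par[1]; b <- par[2]; p <- par[3]
    grad <- function(tt) {
      s <- stats::plogis(a * (tt - b))
      f <- (1 - p) * s + p
      d <- (1 - p) * s * (1 - s)
      cbind(f = f, da = d * (tt - b), db = -d * a, dp = 1 - s)
    }
    gT <- grad(temperature)
    gR <- grad(t_ref)
    f <- gT[, "f"]; g <- gR[, "f"]
    -cbind((gT[, "da"] * g - f * gR[, "da"]) / g^2,
           (gT[, "db"] * g - f * gR[, "db"]) / g^2,
           (gT[, "dp"] * g - f * gR[, "dp"]) / g^2)
  }

  best <- NULL
  for (k in seq_len(nrow(grid))) {
    a0 <- min(max(start["a"] * grid$fa[k], lower[1]), upper[1])
    b0 <- min(max(start["b"] + grid$fb[k], lower[2]), upper[2])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(a0, b0, start[["p"]]), fn = resid_fn, jac = jac_fn,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = settings$max_iter, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    ok <- !is.null(fit) && fit$info %in% 1:4 && all(is.finite(fit$par))
    if (ok && (is.null(best) || fit$deviance < best$deviance)) best <- fit
    # first (unperturbed) start accepted outright; perturbations compete
    if (ok && k == 1L) break
  }

  if (is.null(best)) {
    skeleton$reason <- "fit_failed"
    return(skeleton)
  }

  cf <- stats::setNames(best$par, c("a", "b", "p"))
  fitted <- unfolding_rel(temperature, cf[["a"]], cf[["b"]], cf[["p"]], t_ref)
  res <- y - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)

  out <- skeleton
  out$coefficients <- c(a = cf[["a"]], b = cf[["b"]], p = cf[["p"]])
  out$tm <- if (cf[["p"]] < 0.5) melting_point(cf[["a"]], cf[["b"]], cf[["p"]]) else NA_real_
  out$r_squared <- if (ss_tot > 1e-12) 1 - ss_res / ss_tot else NA_real_
  out$rmse <- sqrt(mean(res^2))
  out$converged <- TRUE
  out$fitted.values <- fitted
  out$residuals <- res
  out
}

# Heuristic starting values; see fit_unfolding() docs.
unfolding_start <- function(temperature, y, settings) {
  p0 <- min(max(min(y), 0), 0.3)
  mu <- tapply(y, temperature, mean)
  tt <- as.numeric(names(mu))
  o <- order(tt)
  tt <- tt[o]; mu <- as.numeric(mu)[o]
  target <- (1 + p0) / 2
  i <- which.min(abs(mu - target))
  b0 <- tt[i]
  lo <- max(i - 1L, 1L)
  hi <- min(i + 1L, length(tt))
  slope <- if (hi > lo) (mu[hi] - mu[lo]) / (tt[hi] - tt[lo]) else 0
  a0 <- if (slope < 0) 4 * slope / (1 - p0) else -0.5
  a0 <- min(max(a0, settings$a_bounds[1]), settings$a_bounds[2])
  c(a = a0, b = b0, p = p0)
}

#' @export
print.unfolding_fit <- function(x, digits = 4, ...) {
  hdr <- "Equilibrium unfolding fit"
  if (!is.null(x$protein_id)) {
    hdr <- paste0(hdr, " [", x$protein_id,
                  if (!is.null(x$condition)) paste0(", ", x$condition), "]")
  }
  cat(hdr, "\n")
  if (!x$converged) {
    cat("  not converged (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  a = %.*g /degC, b = %.*g degC, p = %.*g\n",
              digits, cf[["a"]], digits, cf[["b"]], digits, cf[["p"]]))
  cat(sprintf("  Tm = %s degC, r-squared = %s, rmse = %.*g, n = %d temperatures\n",
              if (is.na(x$tm)) "undefined" else formatC(x$tm, digits = digits, format = "g"),
              if (is.na(x$r_squared)) "NA" else formatC(x$r_squared, digits = digits, format = "g"),
              digits, x$rmse, x$n_points))
  invisible(x)
}

#' @export
summary.unfolding_fit <- function(object, ...) {
  out <- list(
    protein_id = object$protein_id, condition = object$condition,
    coefficients = object$coefficients, tm = object$tm,
    r_squared = object$r_squared, rmse = object$rmse,
    n_points = object$n_points, n_obs = nrow(object$data),
    converged = object$converged, reason = object$reason,
    reference_temperature = object$reference_temperature)
  class(out) <- "summary.unfolding_fit"
  out
}

#' @export
print.summary.unfolding_fit <- function(x, ...) {
  print(structure(x, class = "unfolding_fit"))
  cat(sprintf("  %d observations, reference temperature %g degC\n",
              x$n_obs, x$reference_temperature))
  invisible(x)
}

#' @export
coef.unfolding_fit <- function(object, ...) object$coefficients

#' Predict from an unfolding fit
#'
#' @param object an \code{unfolding_fit}.
#' @param newdata data frame with a \code{temperature_c} column, or a bare
#'   numeric temperature vector. Defaults to the fitted temperatures.
#' @param type \code{"relative"}: the modeled normalized curve
#'   \eqn{f(T)/f(T_{ref})} the data were fit on; \code{"folded"}: the
#'   absolute fraction folded \eqn{f(T)}.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.unfolding_fit <- function(object, newdata = NULL,
                                  type = c("relative", "folded"), ...) {
  type <- match.arg(type)
  if (!object$converged) stop("cannot predict from a non-converged fit",
                              call. = FALSE)
  tt <- if (is.null(newdata)) {
    object$data$temperature_c
  } else if (is.data.frame(newdata)) {
    newdata$temperature_c
  } else {
    as.numeric(newdata)
  }
  cf <- object$coefficients
  if (type == "folded") {
    eval_unfolding(tt, cf[["a"]], cf[["b"]], cf[["p"]])
  } else {
    unfolding_rel(tt, cf[["a"]], cf[["b"]], cf[["p"]],
                  object$reference_temperature)
  }
}

#' @export
fitted.unfolding_fit <- function(object, ...) object$fitted.values

#' @export
residuals.unfolding_fit <- function(object, ...) object$residuals

#' Plot an unfolding fit
#'
#' Observed normalized abundances with the fitted melting curve and, when
#' defined, the melting point marked at the 50% denaturation level.
#'
#' @param x an \code{unfolding_fit}.
#' @param ... passed to \code{plot.default} for the data points.
#' @export
plot.unfolding_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$temperature_c, d$rel_abundance,
                 xlab = "Temperature (degC)",
                 ylab = "Relative abundance",
                 main = paste(c(x$protein_id, x$condition), collapse = " / "),
                 ...)
  if (x$converged) {
    tt <- seq(min(d$temperature_c), max(d$temperature_c), length.out = 200)
    graphics::lines(tt, predict(x, tt))
    if (!is.na(x$tm)) {
      graphics::abline(v = x$tm, lty = 2)
      graphics::abline(h = 0.5, lty = 3)
    }
  }
  invisible(x)
}

#' Simulate noisy curves from a fitted model
#'
#' Draws replicate melting curves from the fitted parameters under the
#' package's multiplicative log-normal noise model, on the fitted
#' temperature grid.
#'
#' @param object a converged \code{unfolding_fit}.
#' @param nsim number of replicate curves.
#' @param seed optional integer seed.
#' @param noise_cv linear-scale coefficient of variation of the noise.
#' @param ... unused.
#' @return data frame with columns \code{replicate}, \code{temperature_c},
#'   \code{rel_abundance}.
#' @export
simulate.unfolding_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_cv = 0.1, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit",
                              call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tt <- sort(unique(object$data$temperature_c))
  mu <- predict(object, tt)
  sigma <- sqrt(log(1 + noise_cv^2))
  do.call(rbind, lapply(seq_len(nsim), function(r) {
    data.frame(replicate = r, temperature_c = tt,
               rel_abundance = mu * exp(stats::rnorm(length(tt), 0, sigma)))
  }))
}
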