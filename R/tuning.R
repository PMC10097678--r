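## Directional-tuning statistics: Gaussian tuning fits on circularly
## re-centered direction axes, selectivity criteria, population circular
## statistics, forward/return angular-shift analysis, peripersonal
## delta-ratio statistics and kinematic (amplitude/velocity) sensitivity.

#' Gaussian direction-tuning fit
#'
#' Fits f(x) = b0 * exp(-((x - b1) / b2)^2) to per-direction mean peak
#' responses. The direction axis is first shifted circularly so the direction
#' with the maximum response sits at the center (wrap-around is handled by
#' re-centering, not by a periodic model); the fitted preferred direction b1
#' is mapped back to absolute degrees in [0, 360). 95% confidence intervals
#' come from the linearized covariance at the optimum (t-based).
#'
#' @param directions_deg stimulus directions in degrees (>= 5 distinct).
#' @param responses mean peak response per direction (same length).
#' @return object of class `tuning_fit` with `b0`, `b1`, `b2`, `ci95`
#'   (3 x 2 matrix), `converged`, `sigma`, `directions_deg`, `responses`,
#'   `center_deg` and, when not converged, `reason`.
#' @export
fit_direction_tuning <- function(directions_deg, responses) {
  stopifnot(length(directions_deg) == length(responses),
            all(is.finite(directions_deg)))
  ok <- is.finite(responses)
  if (length(unique(wrap360(directions_deg[ok]))) < 5)
    stop("need at least 5 distinct directions with finite responses")
  d <- wrap360(directions_deg[ok]); r <- responses[ok]
  center <- d[which.max(r)]
  x <- circ_diff_deg(d, center)               # re-centered axis, peak near 0
  failed <- function(reason) {
    structure(list(b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                   ci95 = matrix(NA_real_, 3, 2,
                                 dimnames = list(c("b0", "b1", "b2"), NULL)),
                   converged = FALSE, reason = reason, sigma = NA_real_,
                   directions_deg = d, responses = r, center_deg = center),
              class = "tuning_fit")
  }
  dat <- data.frame(x = x, y = r)
  one_fit <- function(b2_start) tryCatch(
    suppressWarnings(
      nls(y ~ b0 * exp(-((x - b1) / b2)^2), data = dat,
          start = list(b0 = max(r), b1 = 0, b2 = b2_start),
          lower = c(-Inf, -180, 1e-6), upper = c(Inf, 180, 1e6),
          algorithm = "port",
          control = stats::nls.control(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  fits <- Filter(Negate(is.null), lapply(c(40, 70, 110), one_fit))
  if (length(fits) == 0) return(failed("optimizer failure"))
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]
  est <- coef(fit)
  ## covariance from the analytic Jacobian at the optimum; a singular
  ## Jacobian (flat tuning: b1, b2 unidentified) yields unbounded CIs
  ee <- exp(-((x - est["b1"]) / est["b2"])^2)
  J <- cbind(ee,
             est["b0"] * 2 * (x - est["b1"]) / est["b2"]^2 * ee,
             est["b0"] * 2 * (x - est["b1"])^2 / est["b2"]^3 * ee)
  df_res <- max(length(r) - 3, 1)
  sigma2 <- sum(residuals(fit)^2) / df_res
  V <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) < 0))
    rep(Inf, 3) else sqrt(diag(V))
  tq <- qt(0.975, df = df_res)
  ci <- cbind(est - tq * se, est + tq * se)
  rownames(ci) <- c("b0", "b1", "b2")
  structure(list(b0 = unname(est["b0"]),
                 b1 = wrap360(unname(est["b1"]) + center),
                 b2 = unname(est["b2"]),
                 ci95 = ci, converged = TRUE, reason = NULL,
                 sigma = summary(fit)$sigma,
                 directions_deg = d, responses = r, center_deg = center),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  if (!x$converged) {
    cat("tuning fit: not converged (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("tuning fit: b0=%.4g, preferred direction b1=%.4g deg, width b2=%.4g deg\n",
                x$b0, x$b1, x$b2))
  }
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) {
  c(b0 = object$b0, b1 = object$b1, b2 = object$b2)
}

#' @export
plot.tuning_fit <- function(x, ...) {
  ord <- order(x$directions_deg)
  plot(x$directions_deg[ord], x$responses[ord], pch = 19,
       xlab = "movement direction (deg)", ylab = "peak response", ...)
  if (isTRUE(x$converged)) {
    dd <- seq(0, 360, length.out = 361)
    lines(dd, x$b0 * exp(-(circ_diff_deg(dd, x$b1) / x$b2)^2), lty = 2)
  }
  invisible(x)
}

#' Directional-selectivity criterion
#'
#' A neuron counts as directionally selective when the 95% confidence
#' intervals of both the fitted amplitude b0 and width b2 exclude zero, and
#' the fitted width stays within the half-circle (`max_width_deg`, default
#' 180 degrees): on a re-centered +-180 degree axis a Gaussian wider than the
#' domain is indistinguishable from flat tuning, so such fits are treated as
#' non-selective. Non-converged fits are never selective.
#'
#' @param fit a [fit_direction_tuning()] result.
#' @param max_width_deg largest tuning width still counted as directional.
#' @return logical flag, with attribute `reason` when `FALSE`.
#' @export
is_directionally_selective <- function(fit, max_width_deg = 180) {
  stopifnot(inherits(fit, "tuning_fit"))
  if (!isTRUE(fit$converged))
    return(structure(FALSE, reason = fit$reason %||% "not converged"))
  excl0 <- function(ci) all(is.finite(ci)) && (ci[1] > 0 || ci[2] < 0)
  if (!(excl0(fit$ci95["b0", ]) && excl0(fit$ci95["b2", ])))
    return(structure(FALSE, reason = "b0 or b2 CI includes zero"))
  if (fit$b2 > max_width_deg)
    return(structure(FALSE, reason = "tuning wider than the half-circle"))
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Population distribution of preferred directions
#'
#' Bins the preferred directions of selective fits at the tested directions
#' and tests circular uniformity with the Rayleigh test.
#'
#' @param fits list of `tuning_fit` objects (>= 10 converged fits needed).
#' @param bin_directions_deg bin centers (default the 8 cardinal/ordinal
#'   directions).
#' @return list with `preferred_deg`, `counts` (named by bin center),
#'   `rayleigh_z`, `rayleigh_p`.
#' @export
preferred_direction_distribution <- function(fits,
                                             bin_directions_deg = seq(0, 315, by = 45)) {
  prefs <- vapply(fits, function(f) if (isTRUE(f$converged)) f$b1 else NA_real_,
                  numeric(1))
  prefs <- prefs[is.finite(prefs)]
  if (length(prefs) < 10)
    stop("need at least 10 preferred directions for a stable Rayleigh test")
  ## assign each angle to the nearest bin center (circularly)
  bin <- vapply(prefs, function(a)
    bin_directions_deg[which.min(abs(circ_diff_deg(a, bin_directions_deg)))],
    numeric(1))
  counts <- table(factor(bin, levels = bin_directions_deg))
  rt <- rayleigh_test(prefs)
  list(preferred_deg = prefs,
       counts = setNames(as.integer(counts), names(counts)),
       rayleigh_z = rt$z, rayleigh_p = rt$p)
}

#' Angular shift of preferred spatial position between movement phases
#'
#' Converts per-phase preferred movement directions to preferred
#' spatial-position angles -- for home-to-target movements the position angle
#' is the movement direction itself (target seen from the start point); for
#' target-to-home movements it is the movement direction + 180 degrees (the
#' start point seen from home) -- and reports the per-neuron circular
#' difference (return minus forward) in [0, 360) plus its circular mean. A
#' population tuned to movement direction lands at 180 degrees; a population
#' tuned to spatial position lands at 0.
#'
#' @param fits_forward,fits_return matched lists of `tuning_fit` objects for
#'   home-to-target and target-to-home movements of the same neurons.
#' @return list with `shift_deg` (per neuron, `NA` for pairs that are not
#'   both selective), `circular_mean_deg`, `resultant_R`, `n`.
#' @export
angular_shift_analysis <- function(fits_forward, fits_return) {
  if (length(fits_forward) != length(fits_return))
    stop("forward and return fit lists must be matched per neuron")
  shift <- rep(NA_real_, length(fits_forward))
  for (i in seq_along(fits_forward)) {
    ff <- fits_forward[[i]]; fr <- fits_return[[i]]
    if (!isTRUE(is_directionally_selective(ff)) ||
        !isTRUE(is_directionally_selective(fr))) next
    pos_fwd <- ff$b1
    pos_ret <- wrap360(fr$b1 + 180)
    shift[i] <- wrap360(pos_ret - pos_fwd)
  }
  ok <- is.finite(shift)
  if (!any(ok)) stop("no neuron pair is selective in both phases")
  cm <- circular_mean_deg(shift[ok])
  list(shift_deg = shift, circular_mean_deg = cm$mean_deg,
       resultant_R = cm$R, n = sum(ok))
}

#' Peripersonal delta ratio between matched movement conditions
#'
#' For per-trial peak responses x (home-to-target) and y (target-to-home),
#' the delta ratio is (mean(x) - mean(y)) / max(mean(x), mean(y)); values in
#' [-1, 1] for non-negative means, negative when the second condition drives
#' the neuron more. Per-neuron significance is a two-sided Welch t-test on
#' the trial values.
#'
#' @param per_trial_x,per_trial_y numeric vectors of per-trial peak responses.
#' @param alpha per-neuron significance level (default 0.01).
#' @return list with `value`, `xbar`, `ybar`, `p`, `significant`.
#' @export
delta_ratio <- function(per_trial_x, per_trial_y, alpha = 0.01) {
  stopifnot(length(per_trial_x) > 0, length(per_trial_y) > 0)
  xbar <- mean(per_trial_x); ybar <- mean(per_trial_y)
  if (max(xbar, ybar) <= 0) stop("delta ratio undefined: both means are <= 0")
  value <- (xbar - ybar) / max(xbar, ybar)
  p <- if (length(per_trial_x) > 1 && length(per_trial_y) > 1 &&
           (var(per_trial_x) + var(per_trial_y)) > 0)
    t.test(per_trial_x, per_trial_y)$p.value else NA_real_
  list(value = value, xbar = xbar, ybar = ybar, p = p,
       significant = is.finite(p) && p < alpha)
}

#' Population test of delta ratios against zero
#'
#' @param values per-neuron delta-ratio values.
#' @return two-sided one-sample t-test result (`htest`).
#' @export
delta_ratio_population_test <- function(values) {
  stopifnot(length(values) >= 2)
  t.test(values, mu = 0)
}

#' Sensitivity of peak responses to movement amplitude or velocity
#'
#' Linear regression of per-trial peak responses on a kinematic variable,
#' with the Pearson correlation over trials and the percent change in the
#' fitted response for a doubling of the variable, evaluated at the midpoint
#' of the tested range.
#'
#' @param values per-trial peak responses.
#' @param kinematic per-trial amplitude (mm) or velocity (cm/s).
#' @param kind label, `"amplitude"` or `"velocity"`.
#' @return object of class `kinematic_sensitivity`: `slope`, `intercept`,
#'   `r`, `p`, `pct_per_doubling` (NA when the fitted response at the
#'   reference value is not positive), `v_ref`, `kind`.
#' @export
kinematic_sensitivity <- function(values, kinematic,
                                  kind = c("amplitude", "velocity")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(kinematic))
  lv <- unique(kinematic)
  if (length(lv) < 3) stop("need at least 3 distinct kinematic levels")
  if (min(table(kinematic)) < 5)
    warning("fewer than 5 repetitions at some kinematic level")
  fit <- lm(values ~ kinematic)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  ct <- if (var(values) > 0) cor.test(values, kinematic)
        else list(estimate = 0, p.value = 1)
  v_ref <- (min(kinematic) + max(kinematic)) / 2
  f_ref <- intercept + slope * v_ref
  pct <- if (f_ref > 0) 100 * (intercept + slope * 2 * v_ref - f_ref) / f_ref
         else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 r = unname(ct$estimate), p = ct$p.value,
                 pct_per_doubling = pct, v_ref = v_ref, kind = kind),
            class = "kinematic_sensitivity")
}

#' @export
print.kinematic_sensitivity <- function(x, ...) {
  cat(sprintf("%s sensitivity: slope %.4g, r=%.3f (p=%.3g), %% change per doubling %s\n",
              x$kind, x$slope, x$r, x$p,
              if (is.finite(x$pct_per_doubling))
                sprintf("%.4g%%", x$pct_per_doubling) else "undefined"))
  invisible(x)
}
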