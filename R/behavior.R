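## Behavioral statistics for the two-alternative forced-choice forelimb
## discrimination task: the adaptive side-bias controller, cumulative-
## Gaussian psychometric fitting with guess/lapse rates, probe-trial answer
## summaries and inactivation delta-%-correct statistics.

#' Side-bias state of the adaptive stimulus controller
#'
#' Tracks the last `window_size` non-aborted trials and the resulting bias,
#' defined as the fraction of correct responses on medial trials minus the
#' fraction correct on lateral trials (a side with no trials in the window
#' contributes 0). The double-sigmoid parameters default to tau1 = -0.5,
#' tau2 = 0.5, s1 = 30, s2 = 12.
#'
#' @param window_size number of trials in the running window (default 10).
#' @param tau1,tau2,s1,s2 double-sigmoid inflection points and slopes.
#' @return object of class `bias_state`.
#' @export
bias_state <- function(window_size = 10, tau1 = -0.5, tau2 = 0.5,
                       s1 = 30, s2 = 12) {
  structure(list(window = data.frame(side = character(0),
                                     correct = logical(0)),
                 window_size = window_size, bias = 0,
                 tau1 = tau1, tau2 = tau2, s1 = s1, s2 = s2),
            class = "bias_state")
}

compute_bias <- function(window) {
  frac <- function(side) {
    k <- window$side == side
    if (!any(k)) 0 else mean(window$correct[k])
  }
  frac("medial") - frac("lateral")
}

#' Update the bias state with one trial
#'
#' Aborted trials leave the state unchanged; otherwise the trial enters the
#' FIFO window and the bias is recomputed.
#'
#' @param state a [bias_state()].
#' @param side `"medial"` or `"lateral"`.
#' @param outcome `"correct"`, `"incorrect"` or `"abort"`.
#' @return the updated `bias_state`.
#' @export
update_bias <- function(state, side, outcome) {
  stopifnot(inherits(state, "bias_state"),
            side %in% c("medial", "lateral"),
            outcome %in% c("correct", "incorrect", "abort"))
  if (outcome == "abort") return(state)
  w <- rbind(state$window,
             data.frame(side = side, correct = outcome == "correct"))
  if (nrow(w) > state$window_size)
    w <- w[(nrow(w) - state$window_size + 1):nrow(w), , drop = FALSE]
  state$window <- w
  state$bias <- compute_bias(w)
  state
}

#' Probability of a medial trial from the bias controller
#'
#' Evaluates the double-sigmoid
#' P_med = 1 - 0.5 / (1 + ((bias + 1)/tau1)^s1) - 0.5 / (1 + ((bias + 1)/tau2)^s2)
#' exactly as specified (tau1 is negative; the even integer exponents keep
#' the first term well-defined), clamped to [0, 1]. Note the resulting curve
#' is asymmetric in the bias: it drops to 0 only for strongly negative bias.
#'
#' @param state a [bias_state()], or a numeric bias value in [-1, 1] when the
#'   default parameters are wanted.
#' @return probability in [0, 1].
#' @export
p_medial <- function(state) {
  if (is.numeric(state)) {
    bias <- state
    tau1 <- -0.5; tau2 <- 0.5; s1 <- 30; s2 <- 12
  } else {
    stopifnot(inherits(state, "bias_state"))
    bias <- state$bias
    tau1 <- state$tau1; tau2 <- state$tau2; s1 <- state$s1; s2 <- state$s2
  }
  stopifnot(all(bias >= -1 & bias <= 1))
  p <- 1 - 0.5 / (1 + ((bias + 1) / tau1)^s1) -
           0.5 / (1 + ((bias + 1) / tau2)^s2)
  pmin(pmax(p, 0), 1)
}

## psychometric model: P(right answer) for signed displacement x (mm;
## lateral positive, medial negative)
psychometric_prob <- function(x, pse, sigma, guess, lapse) {
  guess + (1 - guess - lapse) * pnorm((x - pse) / sigma)
}

#' Maximum-likelihood psychometric fit (cumulative Gaussian + guess/lapse)
#'
#' Fits P(right) = guess + (1 - guess - lapse) * Phi((x - pse) / sigma) to
#' right-answer counts by signed displacement (medial negative, lateral
#' positive), with profile-likelihood 95% confidence intervals.
#'
#' @param displacement_mm per-trial signed displacement.
#' @param answered_right per-trial logical (or 0/1) right answers.
#' @param ci compute profile-likelihood CIs (default TRUE).
#' @return object of class `psychometric_fit`: `pse`, `sigma`, `guess`,
#'   `lapse`, `ci95` (4 x 2), `logLik`, `levels` (the aggregated table),
#'   `boundary` flag (perfect separation pushes sigma to its lower bound).
#' @export
fit_psychometric <- function(displacement_mm, answered_right, ci = TRUE) {
  x <- as.numeric(displacement_mm)
  y <- as.logical(answered_right)
  stopifnot(length(x) == length(y), all(is.finite(x)))
  lv <- sort(unique(x))
  if (length(lv) < 2) stop("need at least 2 displacement levels")
  agg <- data.frame(x = lv,
                    n = vapply(lv, function(v) sum(x == v), numeric(1)),
                    k = vapply(lv, function(v) sum(y[x == v]), numeric(1)))
  lo <- c(min(lv) - diff(range(lv)), 1e-3, 0, 0)
  hi <- c(max(lv) + diff(range(lv)), 10 * diff(range(lv)), 0.499, 0.499)
  nll <- function(par) {
    p <- psychometric_prob(agg$x, par[1], par[2], par[3], par[4])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  start <- c(pse = 0, sigma = diff(range(lv)) / 4, guess = 0.02, lapse = 0.02)
  opt <- optim(start, nll, method = "L-BFGS-B", lower = lo, upper = hi)
  ## refine from a second start to avoid local optima
  opt2 <- optim(c(median(lv), diff(range(lv)) / 2, 0.1, 0.1), nll,
                method = "L-BFGS-B", lower = lo, upper = hi)
  if (opt2$value < opt$value) opt <- opt2
  est <- opt$par
  names(est) <- c("pse", "sigma", "guess", "lapse")
  boundary <- est["sigma"] <= lo[2] * (1 + 1e-6)
  ci95 <- matrix(NA_real_, 4, 2, dimnames = list(names(est), NULL))
  if (ci) {
    crit <- opt$value + qchisq(0.95, 1) / 2
    for (j in 1:4) {
      prof <- function(v) {
        par0 <- est; par0[j] <- v
        o <- optim(par0[-j], function(q) {
          p <- par0; p[-j] <- q; nll(p)
        }, method = "L-BFGS-B", lower = lo[-j], upper = hi[-j])
        o$value
      }
      lim <- function(side) {
        bound <- if (side < 0) lo[j] else hi[j]
        f_bound <- prof(bound)
        if (f_bound <= crit) return(bound)       # CI touches the box bound
        tryCatch(
          uniroot(function(v) prof(v) - crit, interval =
                    sort(c(est[j], bound)), tol = 1e-4)$root,
          error = function(e) bound)
      }
      ci95[j, ] <- c(lim(-1), lim(+1))
    }
  }
  structure(list(pse = unname(est["pse"]), sigma = unname(est["sigma"]),
                 guess = unname(est["guess"]), lapse = unname(est["lapse"]),
                 ci95 = ci95, logLik = -opt$value, levels = agg,
                 boundary = boundary),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit: PSE %.4g mm, sigma %.4g mm, guess %.3g, lapse %.3g%s\n",
              x$pse, x$sigma, x$guess, x$lapse,
              if (x$boundary) " (boundary fit: near-perfect separation)" else ""))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(pse = object$pse, sigma = object$sigma,
    guess = object$guess, lapse = object$lapse)
}

#' @export
predict.psychometric_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$levels$x else newdata
  psychometric_prob(x, object$pse, object$sigma, object$guess, object$lapse)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  with(x$levels, plot(x, k / n, ylim = c(0, 1), pch = 19,
                      xlab = "signed displacement (mm)",
                      ylab = "P(right answer)", ...))
  xs <- seq(min(x$levels$x), max(x$levels$x), length.out = 200)
  lines(xs, predict(x, xs), lty = 2)
  invisible(x)
}

#' Per-class probe-trial answer analysis
#'
#' Computes the percentage of right-spout answers per stimulus class (medial,
#' lateral, anterior, posterior) and session, and compares the anterior vs
#' posterior probe classes with a two-sided t-test over sessions.
#'
#' @param trials data.frame with columns `session`, `class` and
#'   `answer` (`"left"`/`"right"`/`"none"`); aborted trials (answer
#'   `"none"`) are dropped.
#' @return list with `per_session` (session x class %-right matrix),
#'   `mean_pct` (per class), `anterior_vs_posterior` (`htest` or `NULL`).
#' @export
probe_answer_analysis <- function(trials) {
  stopifnot(all(c("session", "class", "answer") %in% names(trials)))
  t2 <- trials[trials$answer %in% c("left", "right"), ]
  classes <- intersect(c("medial", "lateral", "anterior", "posterior"),
                       unique(t2$class))
  missing <- setdiff(unique(t2$class), classes)
  if (length(setdiff(c("medial", "lateral", "anterior", "posterior"),
                     classes)) > 0)
    warning("classes with zero trials excluded: ",
            paste(setdiff(c("medial", "lateral", "anterior", "posterior"),
                          classes), collapse = ", "))
  sessions <- sort(unique(t2$session))
  per <- matrix(NA_real_, length(sessions), length(classes),
                dimnames = list(as.character(sessions), classes))
  for (s in seq_along(sessions)) for (cl in classes) {
    k <- t2$session == sessions[s] & t2$class == cl
    if (any(k)) per[s, cl] <- 100 * mean(t2$answer[k] == "right")
  }
  avp <- NULL
  if (all(c("anterior", "posterior") %in% classes)) {
    a <- per[, "anterior"]; p <- per[, "posterior"]
    ok <- is.finite(a) & is.finite(p)
    if (sum(ok) >= 2) {
      d <- a[ok] - p[ok]
      avp <- if (sd(d) > 0) t.test(a[ok], p[ok], paired = TRUE)
      else list(p.value = if (mean(d) == 0) 1 else 0,
                estimate = mean(d), method = "degenerate paired comparison")
    }
  }
  list(per_session = per, mean_pct = colMeans(per, na.rm = TRUE),
       anterior_vs_posterior = avp)
}

#' Inactivation delta-%-correct summaries
#'
#' For each inactivation site, computes the per-session change in % correct
#' relative to the control site (site minus control, so performance drops are
#' negative), tests the session-level deltas against zero with a two-sided
#' t-test, and Bonferroni-corrects across sites. Sessions lacking control
#' trials are dropped with a message.
#'
#' @param trials data.frame with columns `session`, `site` (control trials
#'   labelled `control_label`) and `outcome` (`"correct"`/`"incorrect"`/
#'   `"abort"`; aborts are excluded).
#' @param control_label label of the control site (default `"control"`).
#' @return data.frame with one row per site: `site`, `n_sessions`,
#'   `delta_pct_correct` (mean over sessions), `p`, `p_bonferroni`.
#' @export
inactivation_delta <- function(trials, control_label = "control") {
  stopifnot(all(c("session", "site", "outcome") %in% names(trials)))
  t2 <- trials[trials$outcome != "abort", ]
  sites <- setdiff(unique(t2$site), control_label)
  if (length(sites) == 0) stop("no inactivation sites in the trial table")
  pct <- function(k) 100 * mean(t2$outcome[k] == "correct")
  res <- lapply(sites, function(site) {
    sess <- unique(t2$session[t2$site == site])
    deltas <- vapply(sess, function(s) {
      kc <- t2$session == s & t2$site == control_label
      ks <- t2$session == s & t2$site == site
      if (!any(kc)) return(NA_real_)
      pct(ks) - pct(kc)
    }, numeric(1))
    dropped <- sum(!is.finite(deltas))
    if (dropped > 0)
      message(dropped, " session(s) without control trials dropped for site ",
              site)
    deltas <- deltas[is.finite(deltas)]
    p <- if (length(deltas) >= 2 && var(deltas) > 0)
      t.test(deltas, mu = 0)$p.value else NA_real_
    data.frame(site = site, n_sessions = length(deltas),
               delta_pct_correct = mean(deltas), p = p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * length(sites), 1)
  out
}
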