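# Piecewise linear-quadratic MSD fitting and derived ecological parameters.

PIECEWISE_PAR <- c("a11", "a10", "ts", "a22", "a21", "a20")

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i - p_i)^2 / \sum_i (y_i - \bar y)^2}.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 2);
#'   the observations must not all be equal.
#' @return The coefficient of determination (1 for a perfect fit).
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L)
    stop("'observed' and 'predicted' must have equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observations have zero variance")
  1 - sum((observed - predicted)^2) / ss_tot
}

phase_fits <- function(curve, ts, weights) {
  d1 <- curve[curve$t <= ts, ]
  d2 <- curve[curve$t > ts, ]
  if (nrow(d1) < 3L || nrow(d2) < 3L)
    stop("need >= 3 MSD points in each phase (breakpoint ts = ", ts, ")")
  w1 <- if (weights) 1 / pmax(d1$se, 1e-12)^2 else NULL
  w2 <- if (weights) 1 / pmax(d2$se, 1e-12)^2 else NULL
  f1 <- lm(msd ~ t, data = d1, weights = w1)
  f2 <- lm(msd ~ t + I(t^2), data = d2, weights = w2)
  list(f1 = f1, f2 = f2, d1 = d1, d2 = d2)
}

piecewise_sse <- function(curve, ts, weights) {
  pf <- phase_fits(curve, ts, weights)
  sum(residuals(pf$f1)^2) + sum(residuals(pf$f2)^2)
}

#' Fit the piecewise linear-quadratic MSD model
#'
#' Phase 1 (`t <= ts`) is fitted with a straight line
#' `msd = a11 * t + a10`; phase 2 (`t > ts`) with a quadratic
#' `msd = a22 * t^2 + a21 * t + a20`. The two phases are fitted
#' independently (no continuity constraint); the jump at the breakpoint is
#' reported as a diagnostic. With `ts = "free"` the breakpoint is chosen by
#' least squares over the interior grid times, with an F-test profile
#' interval (the objective is piecewise constant between grid times, so a
#' linearised interval for `ts` is unavailable).
#'
#' @param curve an `msd_curve` data frame spanning both phases.
#' @param ts breakpoint time in seconds (default 5400 s = 1.5 h), or
#'   `"free"` to fit it.
#' @param level confidence level for parameter intervals (default 0.95).
#' @param weights if `TRUE`, weight each point by `1/se^2` (off by
#'   default; the points are used unweighted).
#' @return An object of class `piecewise_fit`: coefficients
#'   `a11, a10, ts, a22, a21, a20`, a CI matrix, per-phase and overall
#'   R-squared, and the jump diagnostic at `ts`.
#' @export
fit_piecewise_msd <- function(curve, ts = 5400, level = 0.95,
                              weights = FALSE) {
  stopifnot(is.data.frame(curve), all(c("t", "msd") %in% names(curve)))
  ts_fixed <- !identical(ts, "free")
  ts_ci <- c(NA_real_, NA_real_)
  if (!ts_fixed) {
    cand <- sort(unique(curve$t))
    cand <- cand[cand > cand[3] & cand < cand[length(cand) - 3L]]
    if (!length(cand)) stop("free-ts fit: breakpoint left the data span")
    sse <- vapply(cand, function(s)
      tryCatch(piecewise_sse(curve, s, weights), error = function(e) Inf),
      numeric(1))
    if (!any(is.finite(sse)))
      stop("free-ts fit: no admissible breakpoint in the data span")
    ts <- cand[which.min(sse)]
    # F-test profile interval for the breakpoint
    n <- nrow(curve)
    s2 <- min(sse) / (n - 6)
    thresh <- min(sse) + s2 * qf(level, 1, n - 6)
    inside <- cand[sse <= thresh]
    ts_ci <- range(inside)
  }
  pf <- phase_fits(curve, ts, weights)
  c1 <- coef(pf$f1)
  c2 <- coef(pf$f2)
  est <- c(a11 = unname(c1["t"]), a10 = unname(c1["(Intercept)"]),
           ts = ts,
           a22 = unname(c2["I(t^2)"]), a21 = unname(c2["t"]),
           a20 = unname(c2["(Intercept)"]))
  ci1 <- confint(pf$f1, level = level)
  ci2 <- confint(pf$f2, level = level)
  ci <- rbind(a11 = ci1["t", ], a10 = ci1["(Intercept)", ],
              ts = if (ts_fixed) c(ts, ts) else ts_ci,
              a22 = ci2["I(t^2)", ], a21 = ci2["t", ],
              a20 = ci2["(Intercept)", ])
  colnames(ci) <- c("lo", "hi")
  r2_1 <- goodness_of_fit(pf$d1$msd, fitted(pf$f1))
  r2_2 <- goodness_of_fit(pf$d2$msd, fitted(pf$f2))
  pred_all <- predict_piecewise_coef(est, curve$t)
  fit <- structure(list(
    coef = est, ci = ci, ts_fixed = ts_fixed, level = level,
    r2 = list(phase1 = r2_1, phase2 = r2_2,
              overall = goodness_of_fit(curve$msd, pred_all)),
    jump = unname((est["a22"] * ts^2 + est["a21"] * ts + est["a20"]) -
                    (est["a11"] * ts + est["a10"])),
    physical = unname(est["a11"] > 0 && est["a22"] < 0),
    curve = curve
  ), class = "piecewise_fit")
  if (!fit$physical)
    warning("fit is not physically sensible (needs a11 > 0 and a22 < 0)")
  fit
}

predict_piecewise_coef <- function(a, t) {
  ifelse(t <= a["ts"],
         a["a11"] * t + a["a10"],
         a["a22"] * t^2 + a["a21"] * t + a["a20"])
}

#' Evaluate a piecewise MSD fit
#'
#' @param fit a `piecewise_fit` (or a named coefficient vector with
#'   elements `a11, a10, ts, a22, a21, a20`).
#' @param t times (s).
#' @return Predicted MSD (m^2).
#' @export
predict_piecewise <- function(fit, t) {
  a <- if (inherits(fit, "piecewise_fit")) fit$coef else fit
  unname(predict_piecewise_coef(a, t))
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat("Piecewise linear-quadratic MSD fit",
      if (x$ts_fixed) "(fixed breakpoint)" else "(fitted breakpoint)", "\n")
  tab <- cbind(estimate = x$coef, x$ci)
  print(signif(tab, 4))
  cat(sprintf("R2: phase 1 %.3f, phase 2 %.3f, overall %.3f; jump at ts %.3g m2\n",
              x$r2$phase1, x$r2$phase2, x$r2$overall, x$jump))
  invisible(x)
}

#' Ecological parameters derived from a piecewise MSD fit
#'
#' From the phase-1 slope and intercept and the phase-2 quadratic:
#' diffusion rate `D = a11/4`; straight-line flight speed
#' \eqn{v = \sqrt{D/(\pi t_{ref})}} at the reference timescale `t_ref`
#' (default 1 s); departure delay `t_d = -a10/a11`; core sustenance zone
#' radius `R0 = sqrt(2 * a20)`; and the shrinking-domain radius schedule
#' \eqn{R(t) = \sqrt{2(a_{22}t^2 + a_{21}t + a_{20})}} with its collapse
#' time (dawn). Intervals are propagated by evaluating at the endpoints of
#' each coefficient's confidence interval.
#'
#' @param fit a `piecewise_fit`.
#' @param t_ref reference timescale in seconds for the speed conversion.
#' @return An object of class `derived_params`.
#' @export
derived_parameters <- function(fit, t_ref = 1) {
  stopifnot(inherits(fit, "piecewise_fit"))
  a <- fit$coef
  ci <- fit$ci
  if (a["a11"] <= 0) stop("a11 <= 0: no positive diffusion rate")
  D <- unname(a["a11"] / 4)
  D_ci <- ci["a11", ] / 4
  v <- sqrt(D / (pi * t_ref))
  v_ci <- sqrt(D_ci / (pi * t_ref))
  td_combo <- c(outer(-ci["a10", ], 1 / ci["a11", ]))
  t_d <- unname(-a["a10"] / a["a11"])
  R0 <- unname(sqrt(2 * a["a20"]))
  R0_ci <- sqrt(2 * pmax(ci["a20", ], 0))
  a22 <- unname(a["a22"]); a21 <- unname(a["a21"]); a20 <- unname(a["a20"])
  Rt <- function(t) sqrt(pmax(2 * (a22 * t^2 + a21 * t + a20), 0))
  # collapse time: larger root of the phase-2 quadratic (a22 < 0)
  disc <- a21^2 - 4 * a22 * a20
  dawn <- if (a22 < 0 && disc > 0)
    (-a21 - sqrt(disc)) / (2 * a22) else NA_real_
  structure(list(
    D = D, D_ci = unname(D_ci),
    v = v, v_ci = unname(v_ci), t_ref = t_ref,
    t_d = t_d, t_d_ci = unname(range(td_combo)),
    R0 = R0, R0_ci = unname(R0_ci),
    Rt = Rt, dawn = dawn, fit = fit
  ), class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf("D   = %.3g m2/s   [%.3g, %.3g]\n", x$D, x$D_ci[1], x$D_ci[2]))
  cat(sprintf("v   = %.3g m/s    [%.3g, %.3g]  (t_ref = %g s)\n",
              x$v, x$v_ci[1], x$v_ci[2], x$t_ref))
  cat(sprintf("t_d = %.3g s      [%.3g, %.3g]\n",
              x$t_d, x$t_d_ci[1], x$t_d_ci[2]))
  cat(sprintf("R0  = %.3g m      [%.3g, %.3g]\n",
              x$R0, x$R0_ci[1], x$R0_ci[2]))
  if (is.finite(x$dawn))
    cat(sprintf("R(t) collapses at t = %.3g s (%.2f h)\n",
                x$dawn, x$dawn / 3600))
  invisible(x)
}

#' Pointwise confidence band of a model curve from parameter intervals
#'
#' Evaluates the model at every combination of confidence-interval endpoint
#' values and takes the pointwise minimum and maximum, mirroring the
#' dashed-envelope convention used for simulated MSD bands.
#'
#' @param ci matrix with one row per parameter and columns `lo`, `hi`.
#' @param evaluator function taking a parameter vector (in the row order of
#'   `ci`) and returning the model curve at `times`.
#' @param times evaluation times (s).
#' @return List with `times`, `lower` and `upper` curves.
#' @export
confidence_band <- function(ci, evaluator, times) {
  k <- nrow(ci)
  if (k > 8L) stop("too many parameters for endpoint enumeration")
  combos <- as.matrix(expand.grid(rep(list(1:2), k)))
  curves <- apply(combos, 1L, function(ix)
    evaluator(ci[cbind(seq_len(k), ix)], times))
  curves <- matrix(curves, nrow = length(times))
  list(times = times,
       lower = apply(curves, 1L, min),
       upper = apply(curves, 1L, max))
}
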