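#' Symmetric sigmoid RH length model
#'
#' The four-parameter logistic curve used to model RH length as a function of
#' distance from the root tip:
#' \deqn{f(d) = L_{noise} + \frac{L_{max} - L_{noise}}{1 + e^{(d_{50} - d)/\delta}}}
#' `L_noise` is the lower asymptote (measurement noise in the hairless zone),
#' `L_max` the upper asymptote (mature hair length), `d50` the inflection
#' point and `delta` the slope factor. The tangent at `d50` meets the two
#' asymptotes at `d50 - 2*delta` and `d50 + 2*delta`, delimiting the
#' approximately linear growth region of width `4*delta`.
#'
#' @param d distance from the root tip (micrometres).
#' @param L_noise,L_max,d50,delta model parameters (micrometres).
#' @return Model value(s) at `d`.
#' @export
rh_sigmoid <- function(d, L_noise, L_max, d50, delta) {
  L_noise + (L_max - L_noise) / (1 + exp((d50 - d) / delta))
}

#' Fitted sigmoid parameters
#'
#' @param L_noise,L_max,d50,delta fitted parameters (micrometres); `delta`
#'   must be positive.
#' @param r2 goodness of fit, 1 - SS_res/SS_tot.
#' @param fit_range_um numeric length-2, the distance range actually fitted.
#' @param n_points number of points used.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(L_noise, L_max, d50, delta, r2, fit_range_um,
                           n_points) {
  if (delta <= 0) stop("delta must be > 0")
  if (fit_range_um[1] >= fit_range_um[2]) stop("fit range start must precede end")
  if (L_max < L_noise)
    warning("fitted L_max below L_noise: profile is not sigmoid-increasing")
  structure(list(L_noise = L_noise, L_max = L_max, d50 = d50, delta = delta,
                 r2 = r2, fit_range_um = as.numeric(fit_range_um),
                 n_points = as.integer(n_points)),
            class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf(paste0("<sigmoid_params> L_noise = %.3g um, L_max = %.4g um, ",
                     "d50 = %.4g um, delta = %.4g um, r2 = %.4f ",
                     "(%d points in [%.0f, %.0f] um)\n"),
              x$L_noise, x$L_max, x$d50, x$delta, x$r2,
              x$n_points, x$fit_range_um[1], x$fit_range_um[2]))
  invisible(x)
}

# select usable points: side, range (closed), unflagged for excluded labels
.fit_points <- function(profile, range_um, exclude_flags, sides) {
  pts <- profile$points
  pts <- pts[pts$side %in% sides, , drop = FALSE]
  if (!is.null(range_um))
    pts <- pts[pts$distance_um >= range_um[1] &
                 pts$distance_um <= range_um[2], , drop = FALSE]
  for (lab in exclude_flags) {
    cn <- paste0("flag_", lab)
    if (cn %in% names(pts)) pts <- pts[pts[[cn]] == 0, , drop = FALSE]
  }
  pts[order(pts$distance_um), , drop = FALSE]
}

#' Least-squares sigmoid fit of an RH length profile
#'
#' Unweighted least-squares fit of [rh_sigmoid] by damped least squares
#' (Levenberg-Marquardt), with initial values derived from the data:
#' `L_noise0` = minimal measured length in range, `L_max0` = maximal length,
#' `d50_0` = the distance of the first point (in increasing distance) whose
#' length reaches `L_max0 / 2`, and `delta0` = the distance of the first
#' point whose length reaches `0.1 * L_max0 / 2` (falling back to a tenth of
#' the range width when no point qualifies). `L_noise` is bounded below by 0
#' and `delta` kept positive.
#'
#' @param profile an [rh_profile].
#' @param range_um numeric length-2 fit range (micrometres, closed); `NULL`
#'   fits the whole profile.
#' @param exclude_flags character vector of annotation labels; points flagged
#'   with any of them are dropped before fitting.
#' @param sides which root sides to use (default both).
#' @return A [sigmoid_params].
#' @export
fit_sigmoid <- function(profile, range_um = NULL, exclude_flags = character(),
                        sides = c("left", "right")) {
  stopifnot(inherits(profile, "rh_profile"))
  pts <- .fit_points(profile, range_um, exclude_flags, sides)
  if (nrow(pts) < 8)
    stop("need >= 8 unflagged points in range; got ", nrow(pts))
  if (length(unique(pts$distance_um)) < 4)
    stop("distances must span >= 4 distinct values")
  d <- pts$distance_um; L <- pts$length_um
  if (max(L) == min(L)) stop("degenerate data: all lengths equal")

  L_noise0 <- min(L)
  L_max0 <- max(L)
  d50_0 <- d[which(L >= L_max0 / 2)[1]]
  width <- diff(range(d))
  i_delta <- which(L >= 0.05 * L_max0)[1]
  delta0 <- if (is.na(i_delta) || d[i_delta] <= 0) width / 10 else d[i_delta]

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, maxiter = 1000)
  dat <- data.frame(d = d, L = L)
  run_lm <- function(delta_start) {
    minpack.lm::nlsLM(
      L ~ L_noise + (L_max - L_noise) / (1 + exp((d50 - d) / delta)),
      data = dat,
      start = list(L_noise = L_noise0, L_max = L_max0, d50 = d50_0,
                   delta = delta_start),
      control = ctrl)
  }
  fail <- function(e) {
    stop("sigmoid fit did not converge (initial values: L_noise0=",
         signif(L_noise0, 6), ", L_max0=", signif(L_max0, 6), ", d50_0=",
         signif(d50_0, 6), ", delta0=", signif(delta0, 6), "): ",
         conditionMessage(e))
  }
  # a delta0 far beyond the data range makes the model locally linear and
  # the start singular; fall back to a tenth of the range once
  fit <- tryCatch(run_lm(delta0),
                  error = function(e1) tryCatch(run_lm(width / 10), error = fail))
  cf <- stats::coef(fit)
  # bounds by clipping: delta must end up positive, L_noise non-negative
  if (cf[["delta"]] < 0)
    fit <- tryCatch(run_lm(abs(cf[["delta"]])), error = fail)
  cf <- stats::coef(fit)
  if (cf[["delta"]] <= 0)
    fail(simpleError("fitted slope factor delta is not positive"))
  if (cf[["L_noise"]] < 0) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        L ~ (L_max) / (1 + exp((d50 - d) / delta)), data = dat,
        start = list(L_max = cf[["L_max"]], d50 = cf[["d50"]],
                     delta = max(cf[["delta"]], 1e-9)),
        control = ctrl),
      error = fail)
    cf <- c(L_noise = 0, stats::coef(fit))
    if (cf[["delta"]] <= 0)
      fail(simpleError("fitted slope factor delta is not positive"))
  }
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((L - mean(L))^2)
  sigmoid_params(cf[["L_noise"]], cf[["L_max"]], cf[["d50"]], cf[["delta"]],
                r2 = 1 - ss_res / ss_tot,
                fit_range_um = if (is.null(range_um)) range(d) else range_um,
                n_points = length(d))
}

#' Two-step sigmoid fit
#'
#' The definitive fit of the workflow: a first sigmoid fit over a user-chosen
#' range (typically 0 to 6000 um from the tip) provides `d50_1` and
#' `delta_1`; the second fit is computed over `d50_1 +/- 5*delta_1`,
#' intersected with the data extent, and is the reported result.
#'
#' @inheritParams fit_sigmoid
#' @param first_range_um range for the first fit (micrometres).
#' @return A list of class `rh_two_step_fit` with elements `fit1`, `fit2`
#'   (both [sigmoid_params]), `second_range_requested_um` (before clipping)
#'   and `second_range_um` (after clipping to the data extent).
#' @export
two_step_fit <- function(profile, first_range_um = c(0, 6000),
                         exclude_flags = character(),
                         sides = c("left", "right")) {
  fit1 <- tryCatch(
    fit_sigmoid(profile, first_range_um, exclude_flags, sides),
    error = function(e) stop("first fit failed: ", conditionMessage(e)))
  req <- c(fit1$d50 - 5 * fit1$delta, fit1$d50 + 5 * fit1$delta)
  all_pts <- .fit_points(profile, NULL, exclude_flags, sides)
  ext <- range(all_pts$distance_um)
  clipped <- c(max(req[1], ext[1]), min(req[2], ext[2]))
  fit2 <- tryCatch(
    fit_sigmoid(profile, clipped, exclude_flags, sides),
    error = function(e) stop("second fit failed: ", conditionMessage(e)))
  structure(list(fit1 = fit1, fit2 = fit2,
                 second_range_requested_um = req,
                 second_range_um = clipped),
            class = "rh_two_step_fit")
}

#' @export
print.rh_two_step_fit <- function(x, ...) {
  cat("Two-step sigmoid fit\n first :"); print(x$fit1)
  cat(sprintf(" second fit range: requested [%.0f, %.0f] um, used [%.0f, %.0f] um\n",
              x$second_range_requested_um[1], x$second_range_requested_um[2],
              x$second_range_um[1], x$second_range_um[2]))
  cat(" second:"); print(x$fit2)
  invisible(x)
}

#' Biological parameters derived from a sigmoid fit
#'
#' From fitted parameters: RH initiation position `d50 - 2*delta`, growth
#' arrest position `d50 + 2*delta`, growth-region width `4*delta`, the
#' division+elongation zone (tip to initiation), and, when a root growth rate
#' is supplied, the estimated RH growth rate
#' `(L_max - L_noise) / (4*delta) * root rate`.
#'
#' @param p a [sigmoid_params].
#' @param root_growth_rate_um_h optional root growth rate (micrometres/hour).
#' @return A list of class `derived_params`; `rh_growth_rate_um_h` is absent
#'   when no root rate is supplied.
#' @export
derive_parameters <- function(p, root_growth_rate_um_h = NULL) {
  stopifnot(inherits(p, "sigmoid_params"))
  out <- list(initiation_um = p$d50 - 2 * p$delta,
              arrest_um = p$d50 + 2 * p$delta,
              growth_region_um = 4 * p$delta,
              div_elong_zone_um = p$d50 - 2 * p$delta)
  if (!is.null(root_growth_rate_um_h))
    out$rh_growth_rate_um_h <-
      (p$L_max - p$L_noise) / (4 * p$delta) * root_growth_rate_um_h
  structure(out, class = "derived_params")
}

#' @export
print.derived_params <- function(x, ...) {
  cat(sprintf(paste0("<derived_params> initiation %.0f um, arrest %.0f um, ",
                     "growth region %.0f um"),
              x$initiation_um, x$arrest_um, x$growth_region_um))
  if (!is.null(x$rh_growth_rate_um_h))
    cat(sprintf(", RH growth rate %.1f um/h", x$rh_growth_rate_um_h))
  cat("\n")
  invisible(x)
}

#' Plot profile data with the two-step fit
#'
#' Profile points, the first fit (black), the second fit (red), the second
#' fit's data range (grey band) and dashed vertical lines at
#' `d50 +/- 2*delta` of the second fit.
#'
#' @param profile an [rh_profile].
#' @param tsf an `rh_two_step_fit` from [two_step_fit].
#' @param file optional PNG path; when `NULL`, draws on the current device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_fit <- function(profile, tsf, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 700, res = 120)
    on.exit(grDevices::dev.off())
  }
  pts <- profile$points
  graphics::plot(pts$distance_um, pts$length_um,
                 col = ifelse(pts$side == "left", "steelblue", "darkorange"),
                 pch = 16, cex = 0.6, xlab = "distance from root tip (um)",
                 ylab = "RH length (um)")
  graphics::rect(tsf$second_range_um[1], graphics::par("usr")[3],
                 tsf$second_range_um[2], graphics::par("usr")[4],
                 col = grDevices::adjustcolor("grey", 0.25), border = NA)
  dd <- seq(min(pts$distance_um), max(pts$distance_um), length.out = 400)
  graphics::lines(dd, rh_sigmoid(dd, tsf$fit1$L_noise, tsf$fit1$L_max,
                                 tsf$fit1$d50, tsf$fit1$delta), lwd = 2)
  graphics::lines(dd, rh_sigmoid(dd, tsf$fit2$L_noise, tsf$fit2$L_max,
                                 tsf$fit2$d50, tsf$fit2$delta),
                  col = "red", lwd = 2)
  graphics::abline(v = tsf$fit2$d50 + c(-2, 2) * tsf$fit2$delta, lty = 2)
  invisible(file)
}
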