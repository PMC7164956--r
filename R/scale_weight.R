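#' @title Scaling and q-weighted difference structure factors
#' @description Light and dark amplitude sets are brought to a common absolute
#'   scale with an isotropic model k.exp(-B_rel s^2), then combined into
#'   per-reflection weighted difference structure factors dF = w (|F_light| -
#'   |F_dark|) with phases borrowed from the dark model. The q-weight
#'   down-weights reflections with large sigma or outlying |dF|.
#' @name scale_weight
NULL

#' Scale a reflection set onto a reference
#'
#' Finds (k, B_rel) minimising sum (k exp(-B_rel s^2) F_target - F_ref)^2 over
#' the common indices, excluding reflections with d larger than
#' `low_res_cutoff`, and returns the target with amplitudes (and sigmas)
#' multiplied by k exp(-B_rel s^2).
#'
#' @param target,reference `refl_set`s sharing a cell.
#' @param low_res_cutoff Low-resolution cutoff in angstrom; reflections with
#'   d > cutoff are excluded from the fit (default 18).
#' @return List with `scaled` (the scaled target) and `result` (a
#'   `scale_result`: `k`, `b_rel`, `n_common`, `residual` = mean absolute
#'   relative deviation from the reference after scaling).
#' @export
scale_to_reference <- function(target, reference, low_res_cutoff = 18) {
  m <- match_hkl(target, reference)
  if (length(m$a) < 2) stop("fewer than 2 common reflections")
  d <- refl_d(target)[m$a]
  dr <- refl_d(reference)[m$b]
  if (min(d) > max(dr) || min(dr) > max(d)) {
    stop("non-overlapping resolution ranges")
  }
  use <- d <= low_res_cutoff
  if (sum(use) < 2) stop("fewer than 2 common reflections inside the low-resolution cutoff")
  ft <- abs(target$f[m$a][use])
  fr <- abs(reference$f[m$b][use])
  s2 <- (1 / (2 * d[use]))^2

  k_for_b <- function(b) {
    e <- exp(-b * s2)
    sum(e * ft * fr) / sum((e * ft)^2)
  }
  obj <- function(b) {
    e <- exp(-b * s2)
    k <- k_for_b(b)
    sum((k * e * ft - fr)^2)
  }
  opt <- stats::optimize(obj, interval = c(-200, 200), tol = 1e-10)
  b_rel <- opt$minimum
  k <- k_for_b(b_rel)
  if (!is.finite(k) || k <= 0) stop("scaling produced a non-positive scale factor")

  fac_all <- k * exp(-b_rel * (1 / (2 * refl_d(target)))^2)
  scaled <- target
  scaled$f <- target$f * fac_all
  scaled$sigf <- target$sigf * fac_all
  res <- mean(abs(k * exp(-b_rel * s2) * ft - fr) / pmax(fr, .Machine$double.eps))
  result <- structure(list(k = k, b_rel = b_rel, n_common = sum(use),
                           residual = res),
                      class = "scale_result")
  list(scaled = scaled, result = result)
}

#' @export
print.scale_result <- function(x, ...) {
  cat(sprintf("scale: k=%.6g  B_rel=%.4g A^2  n=%d  residual=%.3g\n",
              x$k, x$b_rel, x$n_common, x$residual))
  invisible(x)
}

#' Per-reflection q-weights for difference amplitudes
#'
#' w_h = \[1 + sigma^2(dF_h)/<sigma^2(dF)> + |dF_h|^2/<|dF|^2>\]^-1, with the
#' means taken over the working set. Reflections with noisy or outlying
#' differences are down-weighted; all weights lie in (0, 1). When every sigma
#' is zero (noiseless synthetic data) the sigma term drops out.
#'
#' @param delta_f Signed difference amplitudes.
#' @param sigmas Combined sigma(dF) values, >= 0 (NA treated as 0).
#' @return Numeric weights in (0, 1).
#' @export
q_weights <- function(delta_f, sigmas = 0) {
  sigmas <- ifelse(is.na(sigmas), 0, sigmas)
  if (length(delta_f) < 1) stop("need at least one reflection")
  if (any(sigmas < 0)) stop("sigmas must be >= 0")
  mean_s2 <- mean(sigmas^2)
  mean_d2 <- mean(delta_f^2)
  if (mean_s2 == 0 && mean_d2 == 0) {
    stop("degenerate weighting: all dF and sigma are zero")
  }
  s_term <- if (mean_s2 > 0) sigmas^2 / mean_s2 else 0
  d_term <- if (mean_d2 > 0) delta_f^2 / mean_d2 else 0
  1 / (1 + s_term + d_term)
}

#' Weighted isomorphous difference structure factors
#'
#' Per common (h,k,l): signed amplitude w (|F_light| - |F_dark|), phase copied
#' from the dark model's calculated phases, sigma(dF) propagated as
#' sqrt(sig_light^2 + sig_dark^2). Reflections missing in any input are
#' dropped (count reported via a message). Inputs must already be on a common
#' scale (see [scale_to_reference()]).
#'
#' @param light,dark `refl_set`s of observed amplitudes on a common scale.
#' @param dark_phases `refl_set` carrying the dark model's phases (e.g. from
#'   [calc_structure_factors()]).
#' @param weighting Apply q-weights (default `TRUE`); with `FALSE` all
#'   weights are 1.
#' @return A `refl_set` of signed, weighted difference amplitudes with phases;
#'   the `weight` column holds the weights applied.
#' @export
weighted_difference <- function(light, dark, dark_phases, weighting = TRUE) {
  m <- match_hkl(light, dark)
  if (!length(m$a)) stop("light and dark share no reflections")
  common <- data.frame(h = dark$h[m$b], k = dark$k[m$b], l = dark$l[m$b])
  mp <- match_hkl(dark_phases, common)
  if (length(mp$a) < length(m$a)) {
    common <- common[mp$b, , drop = FALSE]
    m$a <- m$a[mp$b]; m$b <- m$b[mp$b]
  }
  n_dropped <- (max(nrow(light), nrow(dark)) - nrow(common))
  if (n_dropped > 0) message(n_dropped, " reflection(s) dropped (not in all inputs)")
  if (!nrow(common)) stop("no reflections common to light, dark and phase sets")

  dF <- abs(light$f[m$a]) - abs(dark$f[m$b])
  sl <- ifelse(is.na(light$sigf[m$a]), 0, light$sigf[m$a])
  sd_ <- ifelse(is.na(dark$sigf[m$b]), 0, dark$sigf[m$b])
  sig <- sqrt(sl^2 + sd_^2)
  w <- if (weighting && (any(dF != 0) || any(sig != 0))) {
    q_weights(dF, sig)
  } else {
    rep(1, length(dF))   # null experiment: nothing to down-weight
  }
  reflection_set(common$h, common$k, common$l,
                 f = w * dF, sigf = sig, phi = dark_phases$phi[mp$a],
                 weight = w, cell = refl_cell(dark), label = "dFo")
}
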