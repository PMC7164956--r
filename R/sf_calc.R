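#' @title Structure factors by direct summation
#' @description Complex structure factors are computed from an atomic model by
#'   direct summation over atoms, F(h) = sum_j occ_j f_j(s) exp(-B_j s^2)
#'   exp(2 pi i h.x_j), with s = sin(theta)/lambda = 1/(2d) and four-Gaussian
#'   Cromer-Mann atomic form factors. Direct summation is exact at toy scale
#'   and serves as the oracle for the FFT map synthesis.
#' @name sf_calc
NULL

# Cromer-Mann coefficients (a1..a4, b1..b4, c); f(s) = sum a_i exp(-b_i s^2) + c
CROMER_MANN <- list(
  H  = list(a = c(0.489918, 0.262003, 0.196767, 0.049879),
            b = c(20.6593, 7.74039, 49.5519, 2.20159), c = 0.001305),
  C  = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
            b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N  = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
            b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.529),
  O  = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
            b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  P  = list(a = c(6.43450, 4.17910, 1.78000, 1.49080),
            b = c(1.90670, 27.1570, 0.526000, 68.1645), c = 1.11490),
  S  = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
            b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900),
  FE = list(a = c(11.7695, 7.35730, 3.52220, 2.30450),
            b = c(4.76110, 0.307200, 15.3535, 76.8805), c = 1.03690)
)

#' Atomic form factor
#'
#' Four-Gaussian Cromer-Mann scattering factor for a neutral atom,
#' f(s) = sum a_i exp(-b_i s^2) + c with s = sin(theta)/lambda in 1/angstrom.
#' At s = 0 the value equals the element's electron count.
#'
#' @param element Element symbol (H, C, N, O, P, S, Fe).
#' @param s sin(theta)/lambda in 1/angstrom (vectorised), >= 0.
#' @return Form factor in electrons.
#' @export
form_factor <- function(element, s) {
  cm <- CROMER_MANN[[toupper(element)]]
  if (is.null(cm)) stop("no tabulated form factor for element '", element, "'")
  if (any(s < 0)) stop("s must be >= 0")
  vapply(s, function(si) sum(cm$a * exp(-cm$b * si^2)) + cm$c, numeric(1))
}

#' Generate unique Miller indices in a resolution range
#'
#' Enumerates one representative per Friedel pair (the h > 0 hemisphere; on
#' the h = 0 plane k > 0; on the h = k = 0 line l > 0), excluding (0,0,0),
#' keeping reflections with d_min <= d <= d_max.
#'
#' @param cell A [unit_cell()].
#' @param d_min,d_max Resolution limits in angstrom, 0 < d_min < d_max.
#' @return data.frame with integer columns `h`, `k`, `l` and the resolution `d`.
#' @export
generate_hkl <- function(cell, d_min, d_max = Inf) {
  if (d_min <= 0 || d_min >= d_max) stop("require 0 < d_min < d_max")
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min) + 1L
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2], l = -hmax[3]:hmax[3])
  d <- d_spacing(cell, g$h, g$k, g$l)
  hemi <- (g$h > 0) | (g$h == 0 & g$k > 0) | (g$h == 0 & g$k == 0 & g$l > 0)
  keep <- hemi & is.finite(d) & d >= d_min & d <= d_max
  out <- g[keep, , drop = FALSE]
  out$d <- d[keep]
  out <- out[order(out$h, out$k, out$l), , drop = FALSE]
  rownames(out) <- NULL
  out
}

P212121_OPS <- list(
  list(R = diag(3), t = c(0, 0, 0)),
  list(R = diag(c(-1, -1, 1)), t = c(1 / 2, 0, 1 / 2)),
  list(R = diag(c(-1, 1, -1)), t = c(0, 1 / 2, 1 / 2)),
  list(R = diag(c(1, -1, -1)), t = c(1 / 2, 1 / 2, 0))
)

#' Expand a model to space group P 1
#'
#' Applies the symmetry operators of the model's space group to every atom and
#' returns the resulting model with space group "P 1". Supported groups:
#' P 1 (identity) and P 21 21 21.
#'
#' @param model An `xtal_model`.
#' @return An `xtal_model` in P 1.
#' @export
expand_to_p1 <- function(model) {
  sg <- gsub(" ", "", toupper(model$spacegroup))
  if (sg == "P1") return(model)
  if (sg != "P212121") stop("unsupported space group: ", model$spacegroup)
  fr <- frac_coords(model$cell, coords(model))
  pieces <- lapply(P212121_OPS, function(op) {
    a <- model$atoms
    a[c("x", "y", "z")] <- orth_coords(model$cell,
                                       sweep(fr %*% t(op$R), 2, -op$t))
    a
  })
  atomic_model(do.call(rbind, pieces), model$cell, "P 1")
}

#' Structure factors of an atomic model by direct summation
#'
#' @param model An `xtal_model` in P 1 or P 21 21 21 (expanded internally).
#' @param hkl data.frame with columns `h`, `k`, `l` (e.g. from
#'   [generate_hkl()]); (0,0,0) is allowed and returns the total electron
#'   count.
#' @param label Label for the returned set (default `"Fc"`).
#' @return A [reflection_set()] with amplitudes and phases (degrees).
#' @export
calc_structure_factors <- function(model, hkl, label = "Fc") {
  model <- expand_to_p1(model)
  a <- model$atoms
  d <- d_spacing(model$cell, hkl$h, hkl$k, hkl$l)
  s <- ifelse(is.finite(d), 1 / (2 * d), 0)
  fr <- frac_coords(model$cell, coords(model))

  # per-element form factors at every s, then per-atom scattering weight
  fs <- matrix(0, nrow = length(s), ncol = nrow(a))
  for (el in unique(a$element)) {
    idx <- which(a$element == el)
    fs[, idx] <- form_factor(el, s)
  }
  w <- fs * exp(-outer(s^2, a$b)) * rep(a$occ, each = length(s))

  phase <- as.matrix(hkl[c("h", "k", "l")]) %*% t(fr)
  fcomplex <- rowSums(w * exp(2i * pi * phase))
  reflection_set(hkl$h, hkl$k, hkl$l,
                 f = Mod(fcomplex),
                 phi = Arg(fcomplex) * 180 / pi,
                 cell = model$cell, label = label)
}
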