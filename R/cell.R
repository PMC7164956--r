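#' Unit cell
#'
#' Construct a crystallographic unit cell from lengths (angstrom) and angles
#' (degrees). The orthogonalisation matrix follows the PDB convention (a along
#' x, b in the xy plane), so fractional and Cartesian coordinates interconvert
#' for any triclinic cell.
#'
#' @param a,b,c Cell edge lengths in angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return An object of class `unit_cell` with elements `a,b,c,alpha,beta,gamma`,
#'   the 3x3 orthogonalisation matrix `orth` (columns are the cell vectors),
#'   its inverse `frac`, and the cell `volume` in cubic angstrom.
#' @examples
#' cl <- unit_cell(54.98, 116.69, 117.86)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(!is.finite(c(a, b, c, alpha, beta, gamma)))) {
    stop("unit cell parameters must be finite")
  }
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(alpha <= 0 | alpha >= 180) || any(beta <= 0 | beta >= 180) ||
      any(gamma <= 0 | gamma >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  sg <- sinpi(gamma / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("degenerate unit cell (non-positive volume)")
  vol <- a * b * c * sqrt(vfac)
  orth <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, vol / (a * b * sg)
  ), nrow = 3)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         orth = orth, frac = solve(orth), volume = vol),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

#' Convert Cartesian coordinates (angstrom) to fractional
#'
#' @param cell A [unit_cell()].
#' @param xyz Numeric matrix (n x 3) or length-3 vector of Cartesian coordinates.
#' @return Matrix of the same shape with fractional coordinates.
#' @export
frac_coords <- function(cell, xyz) {
  xyz <- rbind_coords(xyz)
  t(cell$frac %*% t(xyz))
}

#' Convert fractional coordinates to Cartesian (angstrom)
#'
#' @inheritParams frac_coords
#' @param frac Numeric matrix (n x 3) or length-3 vector of fractional coordinates.
#' @export
orth_coords <- function(cell, frac) {
  frac <- rbind_coords(frac)
  t(cell$orth %*% t(frac))
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3)
    matrix(x, ncol = 3)
  } else {
    stopifnot(ncol(x) == 3)
    as.matrix(x)
  }
}

#' Resolution of reflections
#'
#' d-spacing of Miller indices in a given cell, via the reciprocal metric
#' tensor, valid for any triclinic cell.
#'
#' @param cell A [unit_cell()].
#' @param h,k,l Integer vectors of Miller indices (recycled together).
#' @return d-spacings in angstrom (`Inf` for (0,0,0)).
#' @export
d_spacing <- function(cell, h, k, l) {
  hkl <- cbind(h, k, l)
  gstar <- solve(crossprod(cell$orth))   # reciprocal metric tensor
  inv_d2 <- rowSums((hkl %*% gstar) * hkl)
  ifelse(inv_d2 <= 0, Inf, 1 / sqrt(inv_d2))
}

# minimum-image Cartesian distances between one point and a set of points,
# both given in Cartesian angstrom; correct for small (possibly triclinic)
# cells where features sit near cell edges
min_image_dist <- function(cell, from, to) {
  from <- as.numeric(from)
  to <- rbind_coords(to)
  df <- sweep(frac_coords(cell, to), 2, as.numeric(cell$frac %*% from))
  df <- df - round(df)
  sqrt(rowSums(orth_coords(cell, df)^2))
}
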