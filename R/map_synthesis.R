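#' @title Fourier synthesis of density maps
#' @description Real-space density maps are synthesised from phased (possibly
#'   signed) coefficients by inverse Fourier transform on a regular grid over
#'   the unit cell: rho(x) = (1/V) sum_h F_h exp(-2 pi i h.x), with the
#'   Friedel mates added automatically so the map is real. F(000) is omitted,
#'   so every map has zero mean. Difference maps synthesised from signed
#'   weighted dF coefficients sit at half the absolute density scale (the
#'   difference Fourier approximation).
#' @name map_synthesis
NULL

#' Construct a density map object
#'
#' @param values 3-D numeric array of density samples (x fastest convention is
#'   `values[ix, iy, iz]` at fractional coordinates ((ix-1)/nx, ...)).
#' @param cell A [unit_cell()].
#' @param scale_tag `"absolute"` (e/A^3) or `"sigma"` (rms units).
#' @param label Free-text label.
#' @return Object of class `density_map`.
#' @export
density_map <- function(values, cell, scale_tag = "absolute", label = "") {
  dm <- dim(values)
  if (length(dm) != 3 || any(dm < 4)) stop("map grid must be 3-D with every dimension >= 4")
  if (any(!is.finite(values))) stop("map contains non-finite values")
  structure(list(values = values, cell = cell, scale_tag = scale_tag,
                 label = label),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  dm <- dim(x$values)
  cat(sprintf("density map %dx%dx%d (%s scale)  min=%.3g max=%.3g rms=%.3g\n",
              dm[1], dm[2], dm[3], x$scale_tag, min(x$values), max(x$values),
              map_rms(x)))
  invisible(x)
}

#' Root-mean-square density about the map mean
#'
#' @param map A [density_map()].
#' @return The rms in the map's units (1 for a sigma-scaled map).
#' @export
map_rms <- function(map) {
  v <- map$values
  sqrt(mean((v - mean(v))^2))
}

#' Default map grid for a coefficient set
#'
#' Grid dimensions chosen so the spacing along every cell edge is at most
#' `d_min/oversample` (default oversampling 3, the conventional choice).
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution limit of the coefficients, angstrom.
#' @param oversample Spacing divisor (default 3).
#' @return Integer vector `c(nx, ny, nz)`.
#' @export
default_grid <- function(cell, d_min, oversample = 3) {
  n <- ceiling(c(cell$a, cell$b, cell$c) * oversample / d_min)
  pmax(as.integer(n), 4L)
}

#' Fourier synthesis of a density map
#'
#' rho(x) = (1/V) sum_h F_h exp(-2 pi i h.x) over the Friedel-completed set
#' (conjugate mates added automatically), evaluated on a regular grid by FFT.
#' F(000) is never included, so the map mean is zero.
#'
#' @param coeffs A `refl_set` whose every reflection has a phase; signed
#'   amplitudes allowed (difference coefficients).
#' @param grid Integer `c(nx, ny, nz)`; defaults to [default_grid()] at the
#'   set's d_min.
#' @param label Label for the map.
#' @return A [density_map()] on the absolute scale.
#' @export
synthesize_map <- function(coeffs, grid = NULL, label = refl_label(coeffs)) {
  n_nophase <- sum(is.na(coeffs$phi))
  if (n_nophase > 0) stop(n_nophase, " coefficient(s) lack a phase")
  cell <- refl_cell(coeffs)
  d <- refl_d(coeffs)
  d_min <- min(d)
  if (is.null(grid)) grid <- default_grid(cell, d_min)
  grid <- as.integer(grid)
  spacing <- c(cell$a, cell$b, cell$c) / grid
  if (any(spacing > d_min / 2 + 1e-9)) {
    stop("grid too coarse: spacing must be <= d_min/2 (d_min = ",
         signif(d_min, 4), " A)")
  }
  keep <- !(coeffs$h == 0 & coeffs$k == 0 & coeffs$l == 0)
  fc <- refl_complex(coeffs)[keep]
  h <- coeffs$h[keep]; k <- coeffs$k[keep]; l <- coeffs$l[keep]

  lin <- function(hh, kk, ll) {
    1 + (hh %% grid[1]) + grid[1] * ((kk %% grid[2]) + grid[2] * (ll %% grid[3]))
  }
  # accumulate both Friedel mates; rowsum handles any aliased indices
  vals <- c(fc, Conj(fc))
  at <- c(lin(h, k, l), lin(-h, -k, -l))
  agg <- rowsum(cbind(Re(vals), Im(vals)), group = at)
  A <- array(0i, dim = grid)
  A[as.integer(rownames(agg))] <- complex(real = agg[, 1], imaginary = agg[, 2])

  rho_c <- stats::fft(A) / cell$volume
  rho <- Re(rho_c)
  imag_rel <- max(abs(Im(rho_c))) / max(max(abs(rho)), .Machine$double.eps)
  if (imag_rel > 1e-6) {
    warning("synthesised map has relative imaginary part ", signif(imag_rel, 3))
  }
  density_map(rho, cell, "absolute", label)
}

#' Normalise a map to sigma units
#'
#' Divides the density values by the map's rms about its mean, so peak
#' heights read directly in sigma. Idempotent on an already-normalised map.
#'
#' @param map A [density_map()] with non-zero rms.
#' @return The map with `scale_tag = "sigma"` and rms 1.
#' @export
sigma_scale <- function(map) {
  r <- map_rms(map)
  if (r <= 0) stop("cannot sigma-scale a constant map")
  map$values <- map$values / r
  map$scale_tag <- "sigma"
  map
}

#' Cartesian coordinates of every grid point
#'
#' @param map A [density_map()].
#' @return Matrix (nx*ny*nz x 3) of Cartesian positions in angstrom, in the
#'   array's storage order (first index fastest).
#' @export
grid_coords <- function(map) {
  dm <- dim(map$values)
  fr <- cbind(
    rep((seq_len(dm[1]) - 1) / dm[1], times = dm[2] * dm[3]),
    rep(rep((seq_len(dm[2]) - 1) / dm[2], each = dm[1]), times = dm[3]),
    rep((seq_len(dm[3]) - 1) / dm[3], each = dm[1] * dm[2])
  )
  orth_coords(map$cell, fr)
}

#' Write a density map in CCP4/MRC format (mode 2)
#'
#' Minimal single-volume writer: 1024-byte header, float32 data, axis order
#' x fastest, full unit cell, space group 1.
#'
#' @param map A [density_map()].
#' @param path Output path.
#' @export
write_ccp4_map <- function(map, path) {
  dm <- dim(map$values)
  cl <- map$cell
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  v <- map$values
  wi(dm)                      # NC NR NS
  wi(2)                       # MODE 2 = float32
  wi(c(0, 0, 0))              # start
  wi(dm)                      # intervals per cell edge
  wf(c(cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma))
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))
  wi(1)                       # ISPG
  wi(0)                       # NSYMBT
  wi(rep(0, 25))              # extra
  wf(c(0, 0, 0))              # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map_rms(map))
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  wf(as.numeric(v))
  invisible(path)
}

#' Read a CCP4/MRC map written by [write_ccp4_map()]
#'
#' @param path Input path.
#' @param scale_tag Scale tag to attach (the format does not record it).
#' @return A [density_map()].
#' @export
read_ccp4_map <- function(path, scale_tag = "absolute") {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n = n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n = n, size = 4, endian = "little")
  dm <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) maps supported")
  ri(3); nxyz <- ri(3)
  cpar <- rf(6)
  axes <- ri(3)
  if (!identical(axes, c(1L, 2L, 3L))) stop("only MAPC,MAPR,MAPS = 1,2,3 supported")
  rf(3); ri(1)
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  v <- rf(prod(dm))
  density_map(array(v, dim = dm),
              unit_cell(cpar[1], cpar[2], cpar[3], cpar[4], cpar[5], cpar[6]),
              scale_tag = scale_tag)
}
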