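#' @title Map comparison: local correlation, difference-difference maps, peaks
#' @description Tools for judging agreement between observed and calculated
#'   difference maps: Pearson correlation over spherical regions
#'   (minimum-image convention), affine-rescaled difference-difference maps,
#'   and signed peak detection with nearest-atom attribution.
#' @name map_compare
NULL

# logical mask of grid points within `radius` angstrom (minimum image) of any
# of the given Cartesian centers
sphere_mask <- function(map, centers, radius) {
  centers <- rbind_coords(centers)
  dm <- dim(map$values)
  gc <- grid_coords(map)
  inside <- rep(FALSE, nrow(gc))
  for (i in seq_len(nrow(centers))) {
    inside <- inside | (min_image_dist(map$cell, centers[i, ], gc) <= radius)
  }
  array(inside, dim = dm)
}

check_same_grid <- function(map_a, map_b) {
  if (!identical(dim(map_a$values), dim(map_b$values))) {
    stop("maps are on different grids")
  }
  ca <- map_a$cell; cb <- map_b$cell
  if (max(abs(c(ca$a - cb$a, ca$b - cb$b, ca$c - cb$c,
                ca$alpha - cb$alpha, ca$beta - cb$beta,
                ca$gamma - cb$gamma))) > 1e-6) {
    stop("maps have different unit cells")
  }
}

#' Local Pearson correlation between two maps
#'
#' Pearson correlation of the two maps over all grid points whose
#' minimum-image distance to `center` is at most `radius` — the statistic used
#' to judge local agreement between observed and calculated difference
#' density (spheres of 3.5 or 10 angstrom radius in practice).
#'
#' @param map_a,map_b [density_map()]s on identical grids and cells.
#' @param center Cartesian center (angstrom); a matrix of centers gives the
#'   union of the spheres.
#' @param radius Sphere radius in angstrom (> grid spacing).
#' @return Correlation in \[-1, 1\].
#' @export
local_pcc <- function(map_a, map_b, center, radius) {
  check_same_grid(map_a, map_b)
  spacing <- min(c(map_a$cell$a, map_a$cell$b, map_a$cell$c) / dim(map_a$values))
  if (radius <= spacing) stop("radius must exceed the grid spacing")
  mask <- sphere_mask(map_a, center, radius)
  if (sum(mask) < 10) stop("sphere covers fewer than 10 grid points")
  stats::cor(map_a$values[mask], map_b$values[mask])
}

#' Difference-difference map
#'
#' Linearly rescales the observed map so its global maximum and minimum equal
#' those of the calculated map, then subtracts: out = (a obs + b) - calc.
#' Residual features locate regions where the model's predicted difference
#' density disagrees with observation.
#'
#' @param obs,calc Non-constant [density_map()]s on identical grids.
#' @return A [density_map()] of the residual.
#' @export
diff_diff_map <- function(obs, calc) {
  check_same_grid(obs, calc)
  o_max <- max(obs$values); o_min <- min(obs$values)
  c_max <- max(calc$values); c_min <- min(calc$values)
  if (o_max == o_min || c_max == c_min) stop("constant map: cannot rescale")
  a <- (c_max - c_min) / (o_max - o_min)
  b <- c_max - a * o_max
  out <- obs
  out$values <- (a * obs$values + b) - calc$values
  out$label <- "ddmap"
  out
}

#' Signed peak search with nearest-atom attribution
#'
#' Finds local extrema (26-neighbour definition on the periodic grid) with
#' |value| at or above `threshold` sigma, suppresses any peak within
#' `min_separation` of a stronger one of the same sign (greedy, by |height|;
#' opposite signs never suppress each other, since paired +/- features a
#' bond-length apart are the signature difference maps exist to show), and
#' annotates
#' each survivor with the nearest model atom within `attribution_cutoff`
#' (minimum-image distance). Both signs are reported, mirroring the
#' per-feature sigma tables of difference-map analyses.
#'
#' @param map A sigma-scaled [density_map()].
#' @param threshold Detection threshold in sigma units (> 0), default 3.
#' @param min_separation Minimum peak separation in angstrom (default 2).
#' @param model Optional `xtal_model` used for attribution.
#' @param attribution_cutoff Maximum atom-peak distance for attribution
#'   (default 2.5 angstrom).
#' @return data.frame of class `peak_list`, sorted by |height| descending,
#'   with columns `x,y,z` (angstrom), `height` (signed sigma), `atom`
#'   (label or NA) and `atom_dist`.
#' @export
find_peaks <- function(map, threshold = 3, min_separation = 2, model = NULL,
                       attribution_cutoff = 2.5) {
  if (map$scale_tag != "sigma") stop("find_peaks expects a sigma-scaled map")
  if (threshold <= 0) stop("threshold must be > 0")
  v <- map$values
  dm <- dim(v)
  shift <- function(arr, s) {
    ix <- ((seq_len(dm[1]) - 1 + s[1]) %% dm[1]) + 1
    iy <- ((seq_len(dm[2]) - 1 + s[2]) %% dm[2]) + 1
    iz <- ((seq_len(dm[3]) - 1 + s[3]) %% dm[3]) + 1
    arr[ix, iy, iz]
  }
  is_max <- array(TRUE, dm); is_min <- array(TRUE, dm)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- shift(v, c(dx, dy, dz))
    is_max <- is_max & (v > nb)
    is_min <- is_min & (v < nb)
  }
  cand <- which((is_max & v >= threshold) | (is_min & v <= -threshold))
  gc <- grid_coords(map)
  pk <- data.frame(x = gc[cand, 1], y = gc[cand, 2], z = gc[cand, 3],
                   height = v[cand])
  pk <- pk[order(-abs(pk$height)), , drop = FALSE]

  keep <- logical(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    p <- c(pk$x[i], pk$y[i], pk$z[i])
    sel <- which(keep & sign(pk$height) == sign(pk$height[i]))
    ok <- TRUE
    if (length(sel)) {
      dmin <- min(min_image_dist(map$cell, p,
                                 as.matrix(pk[sel, c("x", "y", "z")])))
      ok <- dmin >= min_separation
    }
    keep[i] <- ok
  }
  pk <- pk[keep, , drop = FALSE]
  rownames(pk) <- NULL

  pk$atom <- rep(NA_character_, nrow(pk))
  pk$atom_dist <- rep(NA_real_, nrow(pk))
  if (!is.null(model) && nrow(pk) && n_atoms(model)) {
    xyz <- coords(model)
    lab <- sprintf("%s/%s %d %s", model$atoms$chain, model$atoms$resname,
                   model$atoms$resno, model$atoms$name)
    for (i in seq_len(nrow(pk))) {
      dd <- min_image_dist(map$cell, c(pk$x[i], pk$y[i], pk$z[i]), xyz)
      j <- which.min(dd)
      if (dd[j] <= attribution_cutoff) {
        pk$atom[i] <- lab[j]
        pk$atom_dist[i] <- dd[j]
      }
    }
  }
  attr(pk, "threshold") <- threshold
  attr(pk, "map_label") <- map$label
  class(pk) <- c("peak_list", "data.frame")
  pk
}

empty_peak_list <- function(threshold, map_label = "") {
  pk <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                   height = numeric(0), atom = character(0),
                   atom_dist = numeric(0))
  attr(pk, "threshold") <- threshold
  attr(pk, "map_label") <- map_label
  class(pk) <- c("peak_list", "data.frame")
  pk
}

#' Write a peak list as tab-separated text
#'
#' Columns mirror the per-feature tables of difference-map reports: label,
#' sign, height in sigma, attributed atom and distance.
#'
#' @param peaks A `peak_list` from [find_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  hdr <- paste(c("label", "sign", "height_sigma", "atom", "dist_A",
                 "x", "y", "z"), collapse = "\t")
  body <- sprintf("peak%02d\t%s\t%.2f\t%s\t%s\t%.3f\t%.3f\t%.3f",
                  seq_len(nrow(peaks)),
                  ifelse(peaks$height >= 0, "+", "-"),
                  peaks$height,
                  ifelse(is.na(peaks$atom), "", peaks$atom),
                  ifelse(is.na(peaks$atom_dist), "",
                         sprintf("%.2f", peaks$atom_dist)),
                  peaks$x, peaks$y, peaks$z)
  writeLines(c(hdr, body), path)
}
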