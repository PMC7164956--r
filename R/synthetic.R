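#' @title Synthetic toy crystals with known ground truth
#' @description A small P1 crystal that mimics the statistical structure of a
#'   pump-probe experiment: a chromophore-like cluster with a planar four-atom
#'   ring arm that can twist about a bond (the D-ring analogue), an anchor
#'   triad of nitrogens (the A/B/C-ring analogue), and a pyrrole-water-like
#'   oxygen hydrogen-bond distance from the arm. The photoproduct is the dark
#'   model with a known dihedral twist and water displacement; observations
#'   are two-state complex mixtures of dark and photoproduct structure
#'   factors at a known population, with optional multiplicative Gaussian
#'   amplitude noise. Every pipeline stage can thus be validated against
#'   ground truth with no experimental data.
#' @name synthetic_data
NULL

# run expr with a local RNG state (seeded), restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

unit_vec <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation of points (rows) about the axis through `origin` along
# unit vector `axis` by `theta` degrees (right-handed about `axis`)
rotate_about_axis <- function(pts, origin, axis, theta_deg) {
  u <- unit_vec(axis)
  th <- theta_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), nrow = 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(rbind_coords(pts), 2, origin) %*% t(R), 2, -origin)
}

# NeRF-style placement: position of a fourth atom given three predecessors,
# a bond length, a bond angle (deg) and a torsion (deg, IUPAC)
place_atom <- function(p1, p2, p3, bond, angle_deg, torsion_deg) {
  bc <- unit_vec(p3 - p2)
  n <- unit_vec(vcross(p2 - p1, bc))
  m <- vcross(n, bc)
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  p3 + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build the toy dark-state crystal
#'
#' Twenty non-hydrogen atoms in a 22 angstrom cubic P1 cell: a planar ring
#' arm C14-C15-C16-ND (+C17) with a dark-state torsion of 20 degrees, an
#' anchor triad of nitrogens with carbon scaffold, a water oxygen 2.8
#' angstrom from the arm, and a ring of scaffold atoms around the cluster.
#' The scaffold matters: in a real crystal the photoproduct perturbs only a
#' tiny fraction of the scattering matter, and the difference-Fourier
#' treatment relies on that dilution. A 20-atom model cannot reach
#' protein-like dilution with light atoms alone, so the scaffold ring carries
#' heavier elements (Fe, S) that stand in for the scattering weight of the
#' unmoved bulk, keeping the moved atoms (ND, C17, water) near 6 percent of
#' the squared scattering power. Coordinates carry a small seeded jitter (at most 0.1
#' angstrom displacement), so different seeds give the same topology with
#' slightly different geometry; the same seed is bit-reproducible.
#'
#' @param seed Integer seed.
#' @return An `xtal_model`.
#' @export
make_toy_dark <- function(seed = 1) {
  cell <- unit_cell(22, 22, 22)
  c14 <- c(9.0, 10.0, 10.0)
  c15 <- c(10.45, 10.0, 10.0)
  c16 <- c15 + 1.43 * c(cos(pi / 3), sin(pi / 3), 0)
  nd <- place_atom(c14, c15, c16, 1.40, 120, 20)   # dark-state torsion 20 deg
  c17 <- place_atom(c15, c16, nd, 1.40, 120, 180)
  w <- c14 + 2.8 * unit_vec(c(-0.4, 0.9, 1.1))
  n1 <- w + 2.9 * unit_vec(c(-1.0, 0.3, 0.2))
  n2 <- w + 2.9 * unit_vec(c(0.2, 1.0, 0.4))
  n3 <- w + 2.9 * unit_vec(c(0.1, -0.4, 1.0))
  ctr <- (n1 + n2 + n3) / 3
  c1 <- n1 + 1.4 * unit_vec(n1 - ctr)
  c2 <- n2 + 1.4 * unit_vec(n2 - ctr)
  c3 <- n3 + 1.4 * unit_vec(n3 - ctr)
  # scaffold ring around the cluster, in a tilted plane
  ring_ctr <- c(9.5, 11.5, 11.5)
  e1 <- unit_vec(c(1, -1, 0)); e2 <- unit_vec(vcross(c(1, 1, 1), e1))
  ang <- (0:7) * pi / 4
  scaf <- t(vapply(ang, function(a) {
    ring_ctr + 6.0 * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
  xyz <- rbind(c14, c15, c16, nd, c17, n1, n2, n3, c1, c2, c3, w, scaf)
  jit <- with_local_seed(seed, matrix(stats::runif(length(xyz), -0.05, 0.05),
                                      ncol = 3))
  xyz <- xyz + jit
  atoms <- data.frame(
    element = c("C", "C", "C", "N", "C", "N", "N", "N", "C", "C", "C", "O",
                "FE", "S", "O", "S", "FE", "N", "C", "O"),
    name = c("C14", "C15", "C16", "ND", "C17", "N1", "N2", "N3",
             "C1", "C2", "C3", "O",
             "FE1", "S1", "OB1", "S2", "FE2", "NB1", "CB1", "OB2"),
    resname = c(rep("BLN", 5), rep("ANC", 6), "HOH", rep("SCF", 8)),
    resno = c(rep(1L, 5), rep(2L, 6), 3L, rep(4L, 8)),
    chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = 15, occ = 1
  )
  atomic_model(atoms, cell, "P 1")
}

#' Build the photoproduct model from the dark model
#'
#' Rotates the terminal arm atoms (ND and C17) about the C15-C16 bond axis by
#' `twist_deg` — so the realised change of the C14-C15-C16-ND torsion equals
#' `twist_deg` — and translates the water oxygen by `water_shift`. All other
#' atoms are untouched.
#'
#' @param dark Model from [make_toy_dark()].
#' @param twist_deg Torsion change in degrees.
#' @param water_shift Cartesian displacement of the water, angstrom 3-vector.
#' @return An `xtal_model` of the photoproduct.
#' @export
perturb_light <- function(dark, twist_deg, water_shift = c(0, 0, 0)) {
  a <- dark$atoms
  i15 <- which(a$name == "C15"); i16 <- which(a$name == "C16")
  p15 <- as.numeric(a[i15, c("x", "y", "z")])
  p16 <- as.numeric(a[i16, c("x", "y", "z")])
  axis <- p16 - p15
  if (sqrt(sum(axis^2)) < 1e-6) stop("degenerate twist axis (C15 == C16)")
  move <- which(a$name %in% c("ND", "C17"))
  a[move, c("x", "y", "z")] <- rotate_about_axis(
    as.matrix(a[move, c("x", "y", "z")]), p15, axis, twist_deg)
  iw <- which(a$name == "O" & a$resname == "HOH")
  a[iw, c("x", "y", "z")] <- a[iw, c("x", "y", "z")] + rbind(water_shift)
  atomic_model(a, dark$cell, dark$spacegroup)
}

#' Simulate observed amplitude sets from a two-state crystal
#'
#' The light-state observation is the amplitude of the coherent two-state
#' mixture (1-p) Fc_dark + p Fc_light (complex sum, as unit cells average
#' coherently), so the standard difference-Fourier treatment is an
#' approximation exactly as for real data. Multiplicative Gaussian noise with
#' relative standard deviation `noise_rel` is applied independently to both
#' sets and the sigma column is populated as `noise_rel * amplitude`.
#'
#' @param dark,light `xtal_model`s of the two states.
#' @param population Photoactivated fraction p in \[0, 1\].
#' @param noise_rel Relative amplitude noise (0 = noiseless).
#' @param d_min High-resolution limit in angstrom.
#' @param seed Integer seed for the noise draws.
#' @param d_max Low-resolution limit (default 100 angstrom).
#' @return List with observed `fo_dark`, `fo_light` and pure `fc_dark`,
#'   `fc_light` reflection sets.
#' @export
simulate_observations <- function(dark, light, population, noise_rel = 0,
                                  d_min = 1.5, seed = 1, d_max = 100) {
  if (population < 0 || population > 1) stop("population must lie in [0, 1]")
  if (d_min <= 0) stop("d_min must be > 0")
  hkl <- generate_hkl(dark$cell, d_min, d_max)
  fc_dark <- calc_structure_factors(dark, hkl, label = "Fc_dark")
  fc_light <- calc_structure_factors(light, hkl, label = "Fc_light")
  mix <- (1 - population) * refl_complex(fc_dark) +
    population * refl_complex(fc_light)
  n <- nrow(hkl)
  eps <- with_local_seed(seed, list(stats::rnorm(n, 0, max(noise_rel, 0)),
                                    stats::rnorm(n, 0, max(noise_rel, 0))))
  amp_dark <- pmax(fc_dark$f * (1 + eps[[1]]), 0)
  amp_light <- pmax(Mod(mix) * (1 + eps[[2]]), 0)
  sig <- function(a) if (noise_rel > 0) noise_rel * a else 0
  list(
    fo_dark = reflection_set(hkl$h, hkl$k, hkl$l, amp_dark,
                             sigf = sig(amp_dark), cell = dark$cell,
                             label = "Fo_dark"),
    fo_light = reflection_set(hkl$h, hkl$k, hkl$l, amp_light,
                              sigf = sig(amp_light), cell = dark$cell,
                              label = "Fo_light"),
    fc_dark = fc_dark,
    fc_light = fc_light
  )
}

#' Full synthetic fixture
#'
#' Convenience wrapper tying the generator together: dark model, photoproduct
#' (default 70 degree twist and 1.5 angstrom water shift), and observed
#' amplitude sets at the given population and noise level. The defaults are
#' the study conditions used throughout the tests: population 0.08,
#' d_min 1.5 angstrom, 22 angstrom P1 cell.
#'
#' @param seed Integer seed (model jitter and noise draws).
#' @param population Photoactivated fraction (default 0.08).
#' @param twist_deg Arm torsion change, degrees (default 70).
#' @param water_shift Water displacement, angstrom (default (1.5, 0, 0)).
#' @param noise_rel Relative amplitude noise (default 0).
#' @param d_min Resolution limit (default 1.5 angstrom).
#' @return List of class `synthetic_truth`: models, reflection sets and the
#'   generating parameters.
#' @export
synthetic_truth <- function(seed = 1, population = 0.08, twist_deg = 70,
                            water_shift = c(1.5, 0, 0), noise_rel = 0,
                            d_min = 1.5) {
  dark <- make_toy_dark(seed)
  light <- perturb_light(dark, twist_deg, water_shift)
  obs <- simulate_observations(dark, light, population, noise_rel, d_min,
                               seed = seed + 1000L)
  structure(c(list(dark_model = dark, light_model = light,
                   population = population, twist_deg = twist_deg,
                   water_shift = water_shift, noise_rel = noise_rel,
                   d_min = d_min, seed = seed), obs),
            class = "synthetic_truth")
}
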