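# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# canonical noiseless study-condition fixture (p = 0.08, 70 deg twist,
# 1.5 A water shift, d_min 1.5 A)
study_truth <- function() cached("truth_1", synthetic_truth(seed = 1))

# a tiny 3-atom model in a 10 A cubic P1 cell
tiny_model <- function() {
  atoms <- data.frame(
    element = c("C", "N", "O"),
    name = c("C1", "N1", "O1"),
    resname = "LIG", resno = 1L, chain = "A",
    x = c(1.0, 3.2, 5.1), y = c(2.0, 4.4, 1.3), z = c(3.0, 2.2, 6.0),
    b = c(5, 10, 15), occ = c(1, 1, 0.5)
  )
  atomic_model(atoms, unit_cell(10, 10, 10))
}

# independent direct-summation structure-factor oracle (scalar loops; no code
# shared with the vectorised implementation)
oracle_structure_factors <- function(model, hkl) {
  cm <- list(
    C = list(a = c(2.31, 1.02, 1.5886, 0.865),
             b = c(20.8439, 10.2075, 0.5687, 51.6512), c = 0.2156),
    N = list(a = c(12.2126, 3.1322, 2.0125, 1.1663),
             b = c(0.0057, 9.8933, 28.9975, 0.5826), c = -11.529),
    O = list(a = c(3.0485, 2.2868, 1.5463, 0.867),
             b = c(13.2771, 5.7011, 0.3239, 32.9089), c = 0.2508)
  )
  cellmat <- model$cell$orth
  out <- complex(nrow(hkl))
  for (r in seq_len(nrow(hkl))) {
    hv <- c(hkl$h[r], hkl$k[r], hkl$l[r])
    gstar <- solve(t(cellmat) %*% cellmat)
    inv_d2 <- as.numeric(t(hv) %*% gstar %*% hv)
    s <- sqrt(inv_d2) / 2
    acc <- 0 + 0i
    for (j in seq_len(nrow(model$atoms))) {
      at <- model$atoms[j, ]
      co <- cm[[at$element]]
      f <- sum(co$a * exp(-co$b * s^2)) + co$c
      xf <- solve(cellmat, c(at$x, at$y, at$z))
      acc <- acc + at$occ * f * exp(-at$b * s^2) *
        exp(2i * pi * sum(hv * xf))
    }
    out[r] <- acc
  }
  out
}

# independent double-loop Fourier synthesis oracle: rho(x) = (1/V) sum over
# the Friedel-completed set of F exp(-2 pi i h.x), evaluated per grid point
oracle_synthesize <- function(coeffs, grid) {
  cell <- attr(coeffs, "cell")
  vol <- cell$volume
  rho <- array(0, dim = grid)
  fc <- coeffs$f * exp(1i * pi * coeffs$phi / 180)
  for (ix in seq_len(grid[1])) for (iy in seq_len(grid[2])) {
    for (iz in seq_len(grid[3])) {
      x <- c((ix - 1) / grid[1], (iy - 1) / grid[2], (iz - 1) / grid[3])
      acc <- 0 + 0i
      for (r in seq_len(nrow(coeffs))) {
        ph <- sum(c(coeffs$h[r], coeffs$k[r], coeffs$l[r]) * x)
        acc <- acc + fc[r] * exp(-2i * pi * ph) +
          Conj(fc[r]) * exp(2i * pi * ph)
      }
      rho[ix, iy, iz] <- Re(acc) / vol
    }
  }
  rho
}

# small phased coefficient set for map tests (20 reflections, 10 A cube)
toy_coeffs <- function(seed = 7) {
  cell <- unit_cell(10, 10, 10)
  hkl <- generate_hkl(cell, 3.2, 11)
  set.seed(seed)
  idx <- sample(nrow(hkl), 20)
  reflection_set(hkl$h[idx], hkl$k[idx], hkl$l[idx],
                 f = round(stats::runif(20, 1, 10), 3),
                 phi = round(stats::runif(20, -179, 179), 2),
                 cell = cell, label = "toy")
}
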