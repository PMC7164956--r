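random_map <- function(seed, n = 16, cell = unit_cell(16, 16, 16)) {
  set.seed(seed)
  density_map(array(stats::rnorm(n^3), c(n, n, n)), cell)
}

test_that("local correlation is 1 against itself, -1 against its negation, symmetric", {
  m <- random_map(1)
  ctr <- c(8, 8, 8)
  expect_equal(local_pcc(m, m, ctr, 4), 1)
  neg <- m; neg$values <- -neg$values
  expect_equal(local_pcc(m, neg, ctr, 4), -1)
  m2 <- random_map(2)
  expect_equal(local_pcc(m, m2, ctr, 4), local_pcc(m2, m, ctr, 4))
})

test_that("local correlation equals a hand-rolled covariance over the same sphere", {
  m1 <- random_map(3); m2 <- random_map(4)
  ctr <- c(5, 5, 5); r <- 3.2
  # oracle mask: explicit minimum-image distances per grid point
  n <- 16; a <- 16
  vals1 <- c(); vals2 <- c()
  for (ix in 0:(n - 1)) for (iy in 0:(n - 1)) for (iz in 0:(n - 1)) {
    d <- (c(ix, iy, iz) / n * a) - ctr
    d <- d - round(d / a) * a
    if (sqrt(sum(d^2)) <= r) {
      vals1 <- c(vals1, m1$values[ix + 1, iy + 1, iz + 1])
      vals2 <- c(vals2, m2$values[ix + 1, iy + 1, iz + 1])
    }
  }
  expect_gte(length(vals1), 100)
  oracle <- sum((vals1 - mean(vals1)) * (vals2 - mean(vals2))) /
    sqrt(sum((vals1 - mean(vals1))^2) * sum((vals2 - mean(vals2))^2))
  expect_equal(local_pcc(m1, m2, ctr, r), oracle, tolerance = 1e-12)
})

test_that("local correlation validates its inputs", {
  m <- random_map(5)
  small <- random_map(5, n = 8, cell = unit_cell(16, 16, 16))
  expect_error(local_pcc(m, small, c(8, 8, 8), 4), "different grids")
  expect_error(local_pcc(m, m, c(8, 8, 8), 0.5), "radius")
})

test_that("difference-difference maps pin the observed extremes to the calculated ones", {
  calc <- random_map(6)
  expect_equal(max(abs(diff_diff_map(calc, calc)$values)), 0)
  obs2 <- calc; obs2$values <- 2 * calc$values
  expect_equal(max(abs(diff_diff_map(obs2, calc)$values)), 0, tolerance = 1e-12)
  # affine coefficients for obs range [-2, 4] against calc range [-1, 1]:
  # a = 1/3, b = -1/3, checked on a hand-evaluated 3-value set
  cell <- unit_cell(8, 8, 8)
  ov <- array(0, c(4, 4, 4)); cv <- array(0, c(4, 4, 4))
  ov[1:3] <- c(4, -2, 1); cv[1:3] <- c(1, -1, 0.2)
  obs <- density_map(ov, cell); cal <- density_map(cv, cell)
  dd <- diff_diff_map(obs, cal)
  a <- 1 / 3; b <- -1 / 3
  expect_equal(dd$values, (a * ov + b) - cv, tolerance = 1e-12)
  # scaled observed extremes equal calc extremes exactly
  scaled <- a * ov + b
  expect_equal(max(scaled), max(cv))
  expect_equal(min(scaled), min(cv))
  expect_error(diff_diff_map(density_map(array(1, c(4, 4, 4)), cell), cal),
               "constant")
})

planted_blob_map <- function(centers_frac, heights, n = 24, a = 24,
                             width = 1.0, noise_sd = 1, seed = 9) {
  set.seed(seed)
  v <- array(stats::rnorm(n^3, sd = noise_sd), c(n, n, n))
  blob <- array(0, c(n, n, n))
  for (b in seq_along(heights)) {
    ctr <- centers_frac[[b]] * a
    for (ix in 0:(n - 1)) for (iy in 0:(n - 1)) for (iz in 0:(n - 1)) {
      d <- (c(ix, iy, iz) / n * a) - ctr
      d <- d - round(d / a) * a
      r2 <- sum(d^2)
      if (r2 < 16) {
        blob[ix + 1, iy + 1, iz + 1] <-
          max(blob[ix + 1, iy + 1, iz + 1], heights[b] * exp(-r2 / (2 * width^2)))
      }
    }
  }
  # planted features replace (not add to) the background so their heights are
  # known exactly
  v[blob > 0] <- blob[blob > 0]
  sigma_scale(density_map(v, unit_cell(a, a, a)))
}

test_that("a planted +5 sigma blob is found as a single positive peak at its center", {
  m <- planted_blob_map(list(c(0.5, 0.5, 0.5)), 5)
  pk <- find_peaks(m, threshold = 4.4, min_separation = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$height, 5, tolerance = 0.2 / 5)
  expect_lt(max(abs(c(pk$x, pk$y, pk$z) - 12)), 1.01)  # within one grid step
})

test_that("thresholds, suppression and sign behave as specified", {
  m <- planted_blob_map(list(c(0.5, 0.5, 0.5)), 5)
  expect_equal(nrow(find_peaks(m, threshold = max(m$values) + 1)), 0)
  # two same-sign blobs closer than min_separation collapse to the stronger
  m2 <- planted_blob_map(list(c(0.5, 0.5, 0.5), c(0.56, 0.5, 0.5)), c(6, 4.5))
  pk2 <- find_peaks(m2, threshold = 4, min_separation = 2.5)
  pos <- pk2[pk2$height > 0, ]
  expect_equal(nrow(pos), 1)
  expect_equal(pos$height, max(m2$values))
  # the negated map returns the same peaks with flipped signs
  mneg <- m; mneg$values <- -mneg$values
  pk <- find_peaks(m, threshold = 4.4)
  pkn <- find_peaks(mneg, threshold = 4.4)
  expect_equal(pkn$height, -pk$height)
  expect_equal(pkn[c("x", "y", "z")], pk[c("x", "y", "z")])
})

test_that("peaks are attributed to the nearest atom within the cutoff", {
  m <- planted_blob_map(list(c(0.5, 0.5, 0.5), c(0.2, 0.2, 0.2)), c(6, 5))
  atoms <- data.frame(element = "O", name = "O", resname = "HOH", resno = 1L,
                      chain = "A", x = 12.4, y = 12.2, z = 11.8, b = 10, occ = 1)
  model <- atomic_model(atoms, m$cell)
  pk <- find_peaks(m, threshold = 4.4, model = model)
  near <- pk[which.max(pk$height), ]
  expect_match(near$atom, "HOH 1 O")
  expect_lt(near$atom_dist, 2.5)
  far <- pk[order(-pk$height), ][2, ]   # blob at (4.8, 4.8, 4.8): no atom close
  expect_true(is.na(far$atom))
})

test_that("find_peaks requires a sigma-scaled map and a positive threshold", {
  m <- random_map(10)
  expect_error(find_peaks(m, 3), "sigma-scaled")
  expect_error(find_peaks(sigma_scale(m), -1), "threshold")
})
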