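make_refl <- function(f, cell = unit_cell(20, 20, 20), sig = NA_real_,
                      phi = NA_real_) {
  hkl <- generate_hkl(cell, 2.5, 100)[seq_along(f), ]
  reflection_set(hkl$h, hkl$k, hkl$l, f, sigf = sig, phi = phi, cell = cell)
}

test_that("pure scalar and identity scalings are recovered exactly", {
  cell <- unit_cell(20, 20, 20)
  hkl <- generate_hkl(cell, 2.5, 100)
  set.seed(11)
  fref <- stats::runif(nrow(hkl), 5, 50)
  ref <- reflection_set(hkl$h, hkl$k, hkl$l, fref, cell = cell)
  tgt <- reflection_set(hkl$h, hkl$k, hkl$l, 2 * fref, cell = cell)
  out <- scale_to_reference(tgt, ref)
  expect_equal(out$result$k, 0.5, tolerance = 1e-6)
  expect_equal(out$result$b_rel, 0, tolerance = 1e-5)
  expect_lt(out$result$residual, 1e-9)
  ident <- scale_to_reference(ref, ref)
  expect_equal(ident$result$k, 1, tolerance = 1e-8)
  expect_equal(ident$result$b_rel, 0, tolerance = 1e-5)
})

test_that("synthetic (k, B) distortions are recovered and scaling is idempotent", {
  cell <- unit_cell(20, 20, 20)
  hkl <- generate_hkl(cell, 2.0, 100)
  set.seed(12)
  fref <- stats::runif(nrow(hkl), 5, 50)
  s2 <- (1 / (2 * d_spacing(cell, hkl$h, hkl$k, hkl$l)))^2
  ref <- reflection_set(hkl$h, hkl$k, hkl$l, fref, sigf = 0.1 * fref, cell = cell)
  tgt <- reflection_set(hkl$h, hkl$k, hkl$l, fref / (0.8 * exp(-5 * s2)),
                        cell = cell)
  out <- scale_to_reference(tgt, ref)
  expect_equal(out$result$k, 0.8, tolerance = 1e-4)
  expect_equal(out$result$b_rel, 5, tolerance = 1e-3)
  expect_equal(out$scaled$f, fref, tolerance = 1e-6)
  again <- scale_to_reference(out$scaled, ref)
  expect_equal(again$result$k, 1, tolerance = 1e-6)
  expect_equal(again$result$b_rel, 0, tolerance = 1e-4)
  # sigmas are scaled by the same per-reflection factor
  tgt2 <- reflection_set(hkl$h, hkl$k, hkl$l, 2 * fref, sigf = 0.2 * fref,
                         cell = cell)
  out2 <- scale_to_reference(tgt2, ref)
  expect_equal(out2$scaled$sigf, 0.1 * fref, tolerance = 1e-6)
})

test_that("scaling errors on insufficient overlap", {
  cell <- unit_cell(20, 20, 20)
  a <- reflection_set(1, 0, 0, 10, cell = cell)
  b <- reflection_set(1, 0, 0, 10, cell = cell)
  expect_error(scale_to_reference(a, b), "fewer than 2")
})

test_that("q-weights follow the closed form and its symmetries", {
  # uniform sigma and uniform |dF|: every term is 1, so w = 1/3
  expect_equal(q_weights(rep(2, 8), rep(0.5, 8)), rep(1 / 3, 8))
  # an outlier 10x the rms of the rest is down-weighted hardest
  df <- c(rep(1, 9), 10)
  w <- q_weights(df, rep(0.2, 10))
  expect_equal(which.min(w), 10)
  expect_true(all(w > 0 & w < 1))
  # frozen 5-reflection oracle: direct spreadsheet-style evaluation
  dF <- c(1.0, -2.0, 0.5, 3.0, -1.5)
  sg <- c(0.2, 0.4, 0.1, 0.8, 0.3)
  expected <- 1 / (1 + sg^2 / mean(sg^2) + dF^2 / mean(dF^2))
  expect_equal(q_weights(dF, sg), expected, tolerance = 1e-12)
  # invariance under a common positive rescaling of dF and sigma
  expect_equal(q_weights(3.7 * dF, 3.7 * sg), expected, tolerance = 1e-12)
  expect_error(q_weights(rep(0, 4), rep(0, 4)), "degenerate")
})

test_that("weighted differences carry dark phases, signs and propagated sigmas", {
  cell <- unit_cell(20, 20, 20)
  light <- make_refl(c(110, 50, 30), cell, sig = c(3, 1, 1))
  dark <- make_refl(c(100, 55, 30), cell, sig = c(4, 1, 1))
  phases <- make_refl(c(1, 1, 1), cell, phi = c(45, -120, 10))
  dF <- weighted_difference(light, dark, phases, weighting = FALSE)
  expect_equal(dF$f, c(10, -5, 0))
  expect_equal(dF$phi, c(45, -120, 10))
  expect_equal(dF$sigf, c(5, sqrt(2), sqrt(2)))
  # light == dark: all signed amplitudes zero (and no degenerate-weight error)
  expect_equal(weighted_difference(dark, dark, phases)$f, c(0, 0, 0))
  # antisymmetry under swapping light and dark
  rev <- weighted_difference(dark, light, phases, weighting = FALSE)
  expect_equal(rev$f, -dF$f)
  expect_error(weighted_difference(make_refl(1), make_refl(1)[0, ], phases),
               "no reflections|share no")
})

test_that("reflections absent from any input are dropped with a message", {
  cell <- unit_cell(20, 20, 20)
  light <- make_refl(c(10, 20, 30, 40), cell)
  dark <- make_refl(c(10, 20, 30), cell)
  phases <- make_refl(c(1, 1, 1), cell, phi = c(0, 0, 0))
  expect_message(dF <- weighted_difference(light, dark, phases,
                                           weighting = FALSE), "dropped")
  expect_equal(nrow(dF), 3)
})

test_that("generator oracle: differences track p(|F_light|-|F_dark|) in the linear regime", {
  # small perturbation, where the difference-Fourier linearisation is good
  tr <- synthetic_truth(seed = 1, twist_deg = 5, water_shift = c(0.2, 0, 0))
  dF <- abs(tr$fo_light$f) - abs(tr$fo_dark$f)
  lin <- tr$population * (abs(tr$fc_light$f) - abs(tr$fc_dark$f))
  expect_lt(sqrt(mean((dF - lin)^2)) / sqrt(mean(lin^2)), 0.15)
  expect_gt(stats::cor(dF, lin), 0.99)
  # at the full study conditions the approximation degrades but stays strongly
  # correlated with the two-state signal
  tr2 <- study_truth()
  dF2 <- abs(tr2$fo_light$f) - abs(tr2$fo_dark$f)
  lin2 <- tr2$population * (abs(tr2$fc_light$f) - abs(tr2$fc_dark$f))
  expect_gt(stats::cor(dF2, lin2), 0.85)
})
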