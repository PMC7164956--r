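test_that("generate_hkl matches exhaustive enumeration on a cubic cell", {
  cell <- unit_cell(10, 10, 10)
  got <- generate_hkl(cell, 5, 100)
  # brute-force oracle: loop the -3..3 cube, compute d, keep the hemisphere
  keep <- list()
  for (h in -3:3) for (k in -3:3) for (l in -3:3) {
    if (h == 0 && k == 0 && l == 0) next
    d <- 10 / sqrt(h^2 + k^2 + l^2)
    hemi <- h > 0 || (h == 0 && k > 0) || (h == 0 && k == 0 && l > 0)
    if (hemi && d >= 5 && d <= 100) keep[[length(keep) + 1]] <- c(h, k, l)
  }
  oracle <- do.call(rbind, keep)
  oracle <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ]
  expect_equal(as.matrix(got[c("h", "k", "l")]), oracle,
               ignore_attr = TRUE)
})

test_that("a narrow d window around the cell edge returns only axial reflections", {
  cell <- unit_cell(10, 10, 10)
  got <- generate_hkl(cell, 9.9, 10.1)
  expect_equal(nrow(got), 3)
  expect_setequal(paste(got$h, got$k, got$l),
                  c("1 0 0", "0 1 0", "0 0 1"))
  expect_error(generate_hkl(cell, 5, 5), "d_min < d_max")
})

test_that("form factors give the electron count at s = 0 and decay monotonically", {
  expect_equal(form_factor("C", 0), 6, tolerance = 0.01 / 6)
  expect_equal(form_factor("O", 0), 8, tolerance = 0.01 / 8)
  expect_equal(form_factor("FE", 0), 26, tolerance = 0.01)
  # frozen from an independent evaluation of the tabulated sum at s = 0.5
  f_c_half <- 2.31 * exp(-20.8439 * 0.25) + 1.02 * exp(-10.2075 * 0.25) +
    1.5886 * exp(-0.5687 * 0.25) + 0.865 * exp(-51.6512 * 0.25) + 0.2156
  expect_equal(form_factor("C", 0.5), f_c_half, tolerance = 1e-12)
  s <- seq(0, 1.5, by = 0.01)
  for (el in c("H", "C", "N", "O", "S", "FE")) {
    v <- form_factor(el, s)
    expect_true(all(v > 0))
    expect_true(all(diff(v) <= 1e-12))
  }
  expect_error(form_factor("ZZ", 0.1), "no tabulated")
})

test_that("a single origin atom gives real positive structure factors", {
  atoms <- data.frame(element = "C", name = "C1", resname = "LIG", resno = 1L,
                      chain = "A", x = 0, y = 0, z = 0, b = 0, occ = 1)
  m <- atomic_model(atoms, unit_cell(10, 10, 10))
  hkl <- generate_hkl(m$cell, 2, 100)
  fc <- calc_structure_factors(m, hkl)
  expect_equal(fc$phi, rep(0, nrow(fc)), tolerance = 1e-9)
  s <- 1 / (2 * refl_d(fc))
  expect_equal(fc$f, form_factor("C", s), tolerance = 1e-12)
  # F(000) equals the total electron count
  f000 <- calc_structure_factors(m, data.frame(h = 0, k = 0, l = 0))
  expect_equal(f000$f, 6, tolerance = 0.01)
})

test_that("structure factors match an independent direct-summation oracle", {
  m <- tiny_model()
  hkl <- generate_hkl(m$cell, 2.5, 100)[1:20, ]
  fc <- calc_structure_factors(m, hkl)
  oracle <- oracle_structure_factors(m, hkl)
  expect_equal(fc$f, Mod(oracle), tolerance = 1e-8)
  # compare phases through the complex values to avoid wrap-around issues
  expect_equal(fc$f * exp(1i * pi * fc$phi / 180), oracle, tolerance = 1e-8)
})

test_that("Friedel symmetry holds: |F(h)| = |F(-h)|, phase(-h) = -phase(h)", {
  m <- tiny_model()
  hkl <- generate_hkl(m$cell, 3, 100)
  fp <- calc_structure_factors(m, hkl)
  fm <- calc_structure_factors(m, data.frame(h = -hkl$h, k = -hkl$k, l = -hkl$l))
  expect_equal(fm$f, fp$f, tolerance = 1e-10)
  expect_equal(exp(1i * pi * fm$phi / 180), exp(-1i * pi * fp$phi / 180),
               tolerance = 1e-10)
})

test_that("raising B damps amplitudes beyond s = 0 and translation keeps them", {
  m <- tiny_model()
  hkl <- generate_hkl(m$cell, 3, 9)   # exclude s = 0 region edge cases
  f1 <- calc_structure_factors(m, hkl)
  m2 <- m; m2$atoms$b <- m2$atoms$b + 10
  f2 <- calc_structure_factors(m2, hkl)
  expect_true(all(f2$f < f1$f))
  m3 <- m; m3$atoms[c("x", "y", "z")] <- m3$atoms[c("x", "y", "z")] +
    matrix(rep(c(1.3, -0.7, 2.9), each = 3), ncol = 3)
  f3 <- calc_structure_factors(m3, hkl)
  expect_equal(f3$f, f1$f, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(f3$phi, f1$phi, tolerance = 1e-4)))
})

test_that("P212121 models equal the explicitly expanded P1 calculation", {
  atoms <- tiny_model()$atoms
  m_sym <- atomic_model(atoms, unit_cell(10, 12, 14), "P 21 21 21")
  hkl <- generate_hkl(m_sym$cell, 3, 100)
  f_sym <- calc_structure_factors(m_sym, hkl)
  # expand by hand with the four screw operators
  ops <- list(
    list(R = diag(3), t = c(0, 0, 0)),
    list(R = diag(c(-1, -1, 1)), t = c(0.5, 0, 0.5)),
    list(R = diag(c(-1, 1, -1)), t = c(0, 0.5, 0.5)),
    list(R = diag(c(1, -1, -1)), t = c(0.5, 0.5, 0))
  )
  fr <- frac_coords(m_sym$cell, coords(m_sym))
  all_atoms <- do.call(rbind, lapply(ops, function(op) {
    a <- atoms
    a[c("x", "y", "z")] <- orth_coords(m_sym$cell,
                                       sweep(fr %*% op$R, 2, -op$t))
    a
  }))
  m_p1 <- atomic_model(all_atoms, m_sym$cell, "P 1")
  f_p1 <- calc_structure_factors(m_p1, hkl)
  expect_equal(f_sym$f, f_p1$f, tolerance = 1e-10)
  expect_error(calc_structure_factors(
    atomic_model(atoms, unit_cell(10, 10, 10), "C 2"), hkl), "C 2")
})
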