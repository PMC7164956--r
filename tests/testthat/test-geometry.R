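test_that("torsion angles reproduce planar references and constructed rotations", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180)
  # rotate the cis fourth point by 35 degrees about the p2-p3 axis
  # (independent Rodrigues construction)
  p1 <- c(0, 0, 0); p2 <- c(1, 0, 0); p3 <- c(1, 1, 0); p4 <- c(0, 1, 0)
  u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  th <- 35 * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  p4r <- as.numeric(R %*% (p4 - p3)) + p3
  expect_equal(abs(dihedral(p1, p2, p3, p4r)), 35, tolerance = 1e-6)
  # reversal symmetry and output range
  set.seed(31)
  for (i in 1:20) {
    p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
    d1 <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    d2 <- dihedral(p[4, ], p[3, ], p[2, ], p[1, ])
    expect_equal(d1, d2, tolerance = 1e-9)
    expect_true(d1 > -180 && d1 <= 180)
  }
  expect_error(dihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "degenerate")
})

test_that("torsions agree with an independent reference implementation", {
  set.seed(32)
  for (i in 1:10) {
    p <- matrix(stats::rnorm(12, sd = 3), 4, 3)
    expect_equal(dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(p))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("torsions are invariant under rigid rotation plus translation", {
  set.seed(33)
  p <- matrix(stats::rnorm(12, sd = 2), 4, 3)
  ref <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
  th <- 0.7; axis <- c(1, 2, -1) / sqrt(6)
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  q <- p %*% t(R) + matrix(rep(c(5, -3, 2), each = 4), 4)
  expect_equal(dihedral(q[1, ], q[2, ], q[3, ], q[4, ]), ref,
               tolerance = 1e-9)
})

test_that("model_dihedral resolves atom specs uniquely", {
  m <- make_toy_dark(1)
  spec <- list(list(name = "C14"), list(name = "C15"),
               list(name = "C16"), list(name = "ND"))
  d <- model_dihedral(m, spec)
  expect_true(abs(d - 20) < 8)   # dark-state torsion 20 deg up to jitter
  expect_error(model_dihedral(m, list(list(name = "C14"), list(name = "C15"),
                                      list(name = "C16"),
                                      list(name = "NOPE"))), "0 atoms")
})

test_that("Kabsch superposition removes rigid motion and is symmetric", {
  set.seed(34)
  a <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  expect_equal(kabsch_rmsd(a, a)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_rmsd(a, sweep(a, 2, c(-5, -5, -5)))$rmsd, 0,
               tolerance = 1e-10)
  th <- 1.1; u <- c(0, 0, 1)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  b <- a %*% t(R) + matrix(rep(c(1, 2, 3), each = 10), 10)
  expect_equal(kabsch_rmsd(a, b)$rmsd, 0, tolerance = 1e-10)
  b2 <- b; b2[4, ] <- b2[4, ] + c(1, 0, 0)
  fit <- kabsch_rmsd(a, b2)
  expect_equal(fit$rmsd, kabsch_rmsd(b2, a)$rmsd, tolerance = 1e-9)
  # applying the returned transform reproduces the rmsd
  moved <- a %*% t(fit$rotation) +
    matrix(rep(fit$translation, each = 10), 10)
  expect_equal(sqrt(mean(rowSums((moved - b2)^2))), fit$rmsd,
               tolerance = 1e-10)
  expect_error(kabsch_rmsd(a[1:2, ], b2[1:2, ]), "at least 3")
})

test_that("Kabsch rmsd matches an independent superposition implementation", {
  set.seed(35)
  a <- matrix(stats::rnorm(30, sd = 3), 10, 3)
  b <- a
  b[4, ] <- b[4, ] + c(1, 0, 0)     # one atom displaced by 1 angstrom
  fit <- kabsch_rmsd(a, b)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(b)), mobile = as.numeric(t(a))))
  rmsd_ref <- sqrt(mean(colSums(matrix((ref - as.numeric(t(b)))^2, nrow = 3))))
  expect_equal(fit$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("mean displacement reports signed radial motion relative to a reference", {
  m <- make_toy_dark(1)
  ref <- list(chain = "A", resno = 3, name = "O")
  same <- mean_displacement(m, m, residues = c(1, 2), reference = ref)
  expect_equal(same$mean, 0)
  # move every selected atom radially away from the reference by 0.5 A
  refpos <- as.numeric(coords(select_atoms(m, residues = c(3, 3)))[1, ])
  m2 <- m
  sel <- m2$atoms$resno %in% 1:2
  dirs <- sweep(coords(m2)[sel, ], 2, refpos)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  m2$atoms[sel, c("x", "y", "z")] <- coords(m2)[sel, ] + 0.5 * dirs
  out <- mean_displacement(m, m2, residues = c(1, 2), reference = ref)
  expect_equal(out$mean, 0.5, tolerance = 1e-9)
  expect_equal(out$per_atom$delta, rep(0.5, sum(sel)), tolerance = 1e-9)
  # graded displacements average as expected
  steps <- seq(0.1, by = 0.1, length.out = sum(sel))
  m3 <- m
  m3$atoms[sel, c("x", "y", "z")] <- coords(m3)[sel, ] + steps * dirs
  out3 <- mean_displacement(m, m3, residues = c(1, 2), reference = ref)
  expect_equal(out3$mean, mean(steps), tolerance = 1e-9)
  # antisymmetry under swapping the models (same reference position)
  swap <- mean_displacement(m2, m, residues = c(1, 2), reference = ref)
  expect_equal(swap$mean, -out$mean, tolerance = 1e-9)
  # mismatched selections are reported
  m4 <- m2
  m4$atoms <- m4$atoms[-1, ]
  expect_error(mean_displacement(m, m4, residues = c(1, 2), reference = ref),
               "missing")
})
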