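test_that("kabsch recovers identity, planted rotations and translations", {
  X <- coords(toy40())
  k0 <- kabsch(X, X)
  expect_equal(k0$rmsd, 0, tolerance = 1e-10)
  expect_equal(k0$transform$rotation, diag(3), tolerance = 1e-8)
  # planted 30 degree rotation + translation
  Y <- sweep(X %*% t(rot_z(30)), 2, c(1, 2, 3), "+")
  k <- kabsch(X, Y)
  expect_equal(rotation_angle(k$transform$rotation), 30, tolerance = 1e-6)
  expect_lt(k$rmsd, 1e-8)
  expect_equal(det(k$transform$rotation), 1, tolerance = 1e-8)
  # 4-point square translated by (1,2,3): translation recovered exactly
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  kt <- kabsch(sq, sweep(sq, 2, c(1, 2, 3), "+"))
  expect_equal(apply_transform(sweep(sq, 2, c(1, 2, 3), "+"), kt$transform),
               sq, tolerance = 1e-10)
})

test_that("kabsch agrees with an independent least-squares fit", {
  set.seed(42)
  X <- matrix(rnorm(30), ncol = 3)
  Y <- sweep(X %*% t(rot_z(53)), 2, c(-2, 5, 1), "+") +
    matrix(rnorm(30, 0, 0.2), ncol = 3)
  k <- kabsch(X, Y)
  ref <- bio3d::fit.xyz(as.numeric(t(X)), as.numeric(t(Y)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  rmsd_ref <- sqrt(mean(colSums(matrix((ref - as.numeric(t(X)))^2,
                                       nrow = 3))))
  expect_equal(k$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("kabsch rejects degenerate input", {
  expect_error(kabsch(matrix(0, 2, 3), matrix(0, 2, 3)), "N >= 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("trimmed superposition reproduces planted noise levels", {
  d <- toy40()
  s0 <- match_and_superpose(d, d)
  expect_equal(s0$rmsd_core, 0, tolerance = 1e-10)
  expect_equal(s0$n_matched, 40)
  expect_equal(s0$n_initial, 40)
  # noisy copy: core rmsd ~ sigma * sqrt(3), and within 10% of the
  # brute-force full-set Kabsch rmsd (nothing should be trimmed below floor)
  nz <- jitter_model(d, 0.5, seed = 11)
  s <- match_and_superpose(d, nz)
  full <- kabsch(coords(d)[d$atoms$elety == "CA", ],
                 coords(nz)[nz$atoms$elety == "CA", ])
  expect_lt(abs(s$rmsd_core - full$rmsd) / full$rmsd, 0.10)
  expect_equal(s$rmsd_core, 0.5 * sqrt(3), tolerance = 0.25)
  # symmetry under argument swap
  s_rev <- match_and_superpose(nz, d)
  expect_lt(abs(s$rmsd_core - s_rev$rmsd_core), 0.05)
  expect_true(s$n_matched <= s$n_initial)
})

test_that("trimming discards genuinely displaced residues", {
  d <- toy40()
  m <- d
  far <- m$atoms$resno %in% 1:4
  m$atoms$x[far] <- m$atoms$x[far] + 25
  s <- match_and_superpose(d, m)
  expect_equal(s$n_matched, 36)
  expect_lt(s$rmsd_core, 0.5)
  expect_equal(s$n_initial, 40)
})

test_that("hinge angle recovers planted domain rotations", {
  d <- toy40()
  expect_equal(hinge_angle(d, d, "resi 1-20", "resi 21-40"), 0,
               tolerance = 1e-6)
  # rotate the second half by 30 degrees about a hinge point
  d2 <- d
  half <- d2$atoms$resno > 20
  piv <- colMeans(coords(d2)[d2$atoms$resno == 20, , drop = FALSE])
  hx <- sweep(sweep(coords(d2)[half, ], 2, piv) %*% t(rot_z(30)), 2, piv,
              "+")
  d2$atoms$x[half] <- hx[, 1]
  d2$atoms$y[half] <- hx[, 2]
  d2$atoms$z[half] <- hx[, 3]
  ang <- hinge_angle(d, d2, "resi 1-20", "resi 21-40")
  expect_lt(abs(ang - 30), 0.1)
  # invariant to a global rigid motion applied to either model
  g <- rigid(rot_z(77), c(10, -4, 3))
  expect_equal(hinge_angle(apply_transform(d, g), d2, "resi 1-20",
                           "resi 21-40"), ang, tolerance = 1e-6)
  expect_equal(hinge_angle(d, apply_transform(d2, g), "resi 1-20",
                           "resi 21-40"), ang, tolerance = 1e-6)
  expect_error(hinge_angle(d, d2, "resi 1-2", "resi 21-40"), "3 CA")
})

test_that("ensemble RMSF matches planted fluctuation statistics", {
  d <- toy40()
  # identical frames: all zero
  es0 <- ensemble_rmsf(list(d, d, d))
  expect_true(all(es0$rmsf < 1e-10))
  # isotropic Gaussian noise: RMSF -> sigma * sqrt(3) (the rigid-body fit
  # absorbs 6 of the 3N degrees of freedom, a ~2.5% deflation at N = 40)
  frames <- lapply(1:500, function(i) jitter_model(d, 0.3, seed = 1000 + i))
  es <- ensemble_rmsf(frames)
  expect_equal(mean(es$rmsf), 0.3 * sqrt(3), tolerance = 0.05)
  expect_true(all(es$rmsf >= 0))
  # nm units are A / 10
  es_nm <- ensemble_rmsf(frames[1:10], units = "nm")
  es_A <- ensemble_rmsf(frames[1:10], units = "A")
  expect_equal(es_nm$rmsf, es_A$rmsf / 10)
  # two frames, one atom displaced by d: RMSF = d/2 (fit on the fixed part)
  f2 <- d
  ca1 <- which(f2$atoms$resno == 1 & f2$atoms$elety == "CA")
  f2$atoms$x[ca1] <- f2$atoms$x[ca1] + 2.4
  es2 <- ensemble_rmsf(list(d, f2), fit_selection = "resi 5-20")
  expect_equal(unname(es2$rmsf[1]), 1.2, tolerance = 1e-8)
  # mismatched residue sets are reported
  short <- select_atoms(d, "resi 1-15")
  expect_error(ensemble_rmsf(list(d, short)), "mismatch")
})
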