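single_atom <- function(elesy = "C") {
  structure_model(atom_row("A", 1, "ALA", "CA", elesy, 0, 0, 0))
}

test_that("SASA matches the analytic sphere and two-sphere formulas", {
  s <- sasa(single_atom(), probe = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * (1.87 + 1.4)^2, tolerance = 0.01)
  # two overlapping solvent-expanded spheres: closed-form cap loss
  two <- structure_model(rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                               atom_row("A", 2, "ALA", "O", "O", 2.5, 0, 0)))
  s2 <- sasa(two, probe = 1.4, n_points = 960)
  R1 <- 1.87 + 1.4
  R2 <- 1.40 + 1.4
  d <- 2.5
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  analytic <- 4 * pi * (R1^2 + R2^2) - 2 * pi * (R1 * h1 + R2 * h2)
  expect_equal(s2$total, analytic, tolerance = 0.02)
  expect_equal(s2$total, sum(s2$per_atom_area), tolerance = 1e-9)
  expect_true(all(s2$per_atom_area >= 0))
})

test_that("SASA matches a Monte-Carlo rejection oracle within 2%", {
  set.seed(101)
  cl <- make_toy_domain(10, seed = 13)
  keep <- select_atoms(cl, "resi 1-2")          # small heavy-atom cluster
  s <- sasa(keep, n_points = 960)
  radii <- default_radii()
  a <- keep$atoms
  xyz <- coords(keep)
  R <- radii[a$elesy] + 1.4
  mc_area <- vapply(seq_len(nrow(a)), function(i) {
    n <- 1e5
    u <- matrix(rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n)
    for (j in seq_len(nrow(a))[-i]) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 >= R[j]^2
    }
    4 * pi * R[i]^2 * mean(free)
  }, numeric(1))
  expect_equal(s$total, sum(mc_area), tolerance = 0.02)
})

test_that("SASA is invariant when the point lattice co-rotates", {
  d <- make_toy_domain(25, seed = 4)
  Rz <- rot_z(40)
  d_rot <- apply_transform(d, rigid(Rz, c(5, -3, 2)))
  s0 <- sasa(d, n_points = 480)
  s1 <- sasa(d_rot, n_points = 480, orientation = Rz)
  expect_equal(s1$per_atom_area, s0$per_atom_area, tolerance = 1e-12)
  # with the lattice fixed in the laboratory frame the drift stays tiny
  s2 <- sasa(d_rot, n_points = 960)
  s3 <- sasa(d, n_points = 960)
  expect_lt(abs(s2$total - s3$total) / s3$total, 0.005)
})

test_that("unknown elements without a radius are reported", {
  expect_error(sasa(single_atom("XX")), "no radius")
})

test_that("buried surface obeys its invariants", {
  m <- dimer_full()
  rep1 <- buried_surface(m, "chain A", "chain B", n_points = 240)
  rep2 <- buried_surface(m, "chain B", "chain A", n_points = 240)
  expect_gt(rep1$bsa_total, 0)
  expect_equal(rep1$bsa_total, rep2$bsa_total)        # exact symmetry
  # partition: the two groups sum to 100%
  expect_equal(component_contribution(rep1, "chain A") +
                 component_contribution(rep1, "chain B"), 100,
               tolerance = 0.5)
  expect_equal(component_contribution(rep1, "all"), 100, tolerance = 1e-9)
  # doubling the sampling changes the total by < 1%
  rep480 <- buried_surface(m, "chain A", "chain B", n_points = 480)
  expect_lt(abs(rep480$bsa_total - rep1$bsa_total) / rep1$bsa_total, 0.01)
  expect_error(buried_surface(m, "chain A", "all"), "overlap")
  expect_error(buried_surface(m, "chain A", "none"), "non-empty")
})

test_that("separated groups bury nothing", {
  far <- structure_model(rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                               atom_row("B", 1, "ALA", "CA", "C", 50, 0, 0)))
  rep <- buried_surface(far, "chain A", "chain B", n_points = 240)
  expect_equal(rep$bsa_total, 0)
  expect_error(component_contribution(rep, "chain A"), "zero")
})

test_that("two touching spheres bury the analytic cap area", {
  pair <- structure_model(rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                                atom_row("B", 1, "ALA", "CA", "C", 4, 0, 0)))
  rep <- buried_surface(pair, "chain A", "chain B", n_points = 3840)
  R <- 1.87 + 1.4
  d <- 4
  h <- R - d / 2
  expect_equal(rep$bsa_total, 2 * 2 * pi * R * h, tolerance = 0.02)
})

test_that("glycans travel with their parent chain's group", {
  m <- dimer_full()
  rep <- buried_surface(m, "chain A", "chain B", n_points = 240)
  gly_contrib <- component_contribution(rep, "kind glycan")
  expect_gt(gly_contrib, 0)
  # per-residue table includes sugar residues on both sides
  sugars <- rep$per_residue[rep$per_residue$resid %in% sugar_codes(), ]
  expect_setequal(unique(sugars$group), c("A", "B"))
})

test_that("typed contacts classify planted geometries", {
  expect_equal(nrow(find_contacts(dimer_plain(), "resi 1-3 and chain A",
                                  "resi 1-3 and chain B",
                                  nb_cutoff = 0.1, hb_cutoff = 0.1,
                                  sb_cutoff = 0.1, ss_cutoff = 0.1)), 0)
  atoms <- rbind(
    atom_row("A", 1, "SER", "OG", "O", 0, 0, 0),
    atom_row("B", 1, "ASN", "ND2", "N", 2.9, 0, 0),
    atom_row("A", 2, "ASP", "OD1", "O", 0, 10, 0),
    atom_row("B", 2, "ARG", "NH1", "N", 3.8, 10, 0),
    atom_row("A", 3, "CYS", "SG", "S", 0, 20, 0),
    atom_row("B", 3, "CYS", "SG", "S", 2.05, 20, 0),
    atom_row("A", 4, "ALA", "CB", "C", 0, 30, 0),
    atom_row("B", 4, "ALA", "CB", "C", 3.9, 30, 0))
  ct <- find_contacts(structure_model(atoms), "chain A", "chain B")
  expect_equal(sort(ct$kind),
               sort(c("hydrogen_bond", "salt_bridge", "disulfide",
                      "nonbonded")))
  expect_equal(ct$distance[ct$kind == "hydrogen_bond"], 2.9)
  # the salt-bridge N-O pair is not double-reported as a hydrogen bond
  expect_equal(sum(ct$resno_a == 2), 1)
  # planted dimer carries its disulfide in the contact list
  ct2 <- find_contacts(dimer_full(), "chain A", "chain B")
  expect_true("disulfide" %in% ct2$kind)
})
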