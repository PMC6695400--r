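test_that("generators are pure functions of their seed", {
  expect_identical(coords(make_toy_domain(20, seed = 3)),
                   coords(make_toy_domain(20, seed = 3)))
  expect_false(identical(coords(make_toy_domain(20, seed = 3)),
                         coords(make_toy_domain(20, seed = 4))))
  d <- make_toy_domain(25, seed = 8)
  expect_identical(coords(make_c2_dimer(d, TRUE, TRUE, seed = 2)),
                   coords(make_c2_dimer(d, TRUE, TRUE, seed = 2)))
  expect_identical(make_sequence_family(30, c(a = 2, b = 2), seed = 5),
                   make_sequence_family(30, c(a = 2, b = 2), seed = 5))
  t1 <- make_titration(1e-8, seed = 9)
  t2 <- make_titration(1e-8, seed = 9)
  expect_identical(t1$signal, t2$signal)
  # generators do not disturb the caller's RNG stream
  set.seed(123)
  before <- .Random.seed
  invisible(make_toy_domain(15, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("toy domains are clash-free and compact", {
  d <- make_toy_domain(50, seed = 2)
  a <- d$atoms
  expect_equal(nrow(a[a$elety == "CA", ]), 50)
  expect_gte(semadimer:::.min_nonbonded(a), 2.4)
  # radius of gyration grows sublinearly with chain length
  rg <- function(n, seed) {
    x <- coords(make_toy_domain(n, seed))
    sqrt(mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  }
  sizes <- c(20, 40, 80)
  rgs <- vapply(sizes, function(n)
    mean(vapply(1:3, function(s) rg(n, s), numeric(1))), numeric(1))
  slope <- coef(lm(log(rgs) ~ log(sizes)))[2]
  expect_lt(slope, 0.8)
  expect_error(make_toy_domain(5), ">= 10")
})

test_that("C2 dimers satisfy contact and planted-feature contracts", {
  m <- dimer_full()
  a <- m$atoms
  xa <- as.matrix(a[a$chain == "A" & a$kind == "amino_acid",
                    c("x", "y", "z")])
  xb <- as.matrix(a[a$chain == "B" & a$kind == "amino_acid",
                    c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  expect_gte(sum(d2 <= 4.5^2), 20)
  # planted disulfide: exactly one interchain bond
  ss <- find_disulfides(m)
  expect_equal(nrow(ss[ss$scope == "interchain" & !ss$near_contact, ]), 1)
  # planted glycan: >= 5 atoms within 4 A of the partner chain
  gl_a <- as.matrix(a[a$kind == "glycan" & a$chain == "A",
                      c("x", "y", "z")])
  other <- as.matrix(a[a$chain == "B" & a$kind != "glycan",
                       c("x", "y", "z")])
  dg <- outer(rowSums(gl_a^2), rowSums(other^2), "+") - 2 * gl_a %*% t(other)
  expect_gte(sum(sqrt(pmax(dg, 0)) <= 4), 5)
  expect_gte(min(sqrt(pmax(dg, 0))), 2.4)
  # glycans contribute buried surface
  rep <- buried_surface(m, "chain A", "chain B", n_points = 240)
  expect_gt(component_contribution(rep, "kind glycan"), 0)
  # unplanted dimer: non-covalent
  expect_equal(covalent_dimer_call(dimer_plain())$verdict,
               "no_covalent_link")
})

test_that("structure families carry their planted class structure", {
  base <- toy40()
  fam0 <- make_structure_family(
    base, list(only = list(n_members = 2, rigid_shift = 0,
                           noise_sigma = 0)), seed = 1)
  expect_equal(coords(fam0[[1]]), coords(base))
  expect_equal(coords(fam0[[2]]), coords(base))
  fam <- make_structure_family(
    base, list(c1 = list(n_members = 2, rigid_shift = 0, noise_sigma = 0.2),
               c2 = list(n_members = 2, rigid_shift = 4, noise_sigma = 0.2)),
    seed = 2)
  expect_equal(unname(attr(fam, "class_labels")),
               c("c1", "c1", "c2", "c2"))
  expect_identical(coords(make_structure_family(
    base, list(c1 = list(n_members = 1, rigid_shift = 0,
                         noise_sigma = 0.2)), seed = 2)[[1]]),
    coords(fam[[1]]))
})

test_that("sequence families plant exactly what was asked", {
  plain <- make_sequence_family(30, c(a = 2, b = 3), seed = 4)
  expect_equal(length(unique(plain)), 1)    # no plants, no background
  pp <- list(`7` = c(a = "negatively_charged", b = "positively_charged"))
  fam <- make_sequence_family(30, c(a = 2, b = 3), pp, seed = 4)
  l7 <- substr(fam, 7, 7)
  expect_true(all(residue_chemistry(l7[1:2]) == "negatively_charged"))
  expect_true(all(residue_chemistry(l7[3:5]) == "positively_charged"))
  # everything else identical
  expect_equal(length(unique(paste0(substr(fam, 1, 6),
                                    substr(fam, 8, 30)))), 1)
  expect_error(make_sequence_family(10, c(a = 1, b = 1),
                                    list(`40` = c(a = "polar", b = "polar"))),
               "outside")
})

test_that("synthetic titrations hit their presets", {
  t0 <- make_titration(kd = 1e-8, noise_cv = 0, seed = 1)
  expect_equal(fit_kd(t0, n_bootstrap = 0)$kd, 1e-8, tolerance = 1e-6)
  expect_gte(min(t0$ligand_conc), 1e-8 / 100)
  expect_lte(max(t0$ligand_conc), 1e-8 * 1000)
  expect_equal(nrow(t0), 16)
  # 2-fold dilution
  expect_equal(t0$ligand_conc[-16] / t0$ligand_conc[-1], rep(2, 15))
})
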