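test_that("a minimal single-ATOM PDB record parses to one chain/residue/atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 1)
  expect_equal(chain_ids(m), "A")
  expect_equal(m$atoms$resno, 1)
  expect_equal(unname(coords(m)[1, ]), c(1, 2, 3))
  expect_equal(m$atoms$kind, "amino_acid")
})

test_that("PDB and mmCIF round-trips preserve the model to 3 decimals", {
  m <- dimer_full()
  for (fmt in c("pdb", "mmcif")) {
    f <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb" else ".cif")
    write_structure(m, f, format = fmt)
    m2 <- suppressWarnings(read_structure(f))
    expect_equal(n_atoms(m2), n_atoms(m))
    expect_lt(max(abs(coords(m2) - coords(m))), 1e-3)
    expect_equal(m2$atoms$resid, m$atoms$resid)
    expect_equal(m2$atoms$chain, m$atoms$chain)
    # idempotence: a second round-trip reproduces the first exactly
    f2 <- withr::local_tempfile(fileext = if (fmt == "pdb") ".pdb"
                                else ".cif")
    write_structure(m2, f2, format = fmt)
    m3 <- suppressWarnings(read_structure(f2))
    expect_identical(coords(m3), coords(m2))
  }
})

test_that("alternate locations resolve to highest occupancy, first on ties", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       8.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(n_atoms(m), 2)
  expect_equal(m$atoms$x[m$atoms$elety == "CA"], 9)  # higher occupancy
  expect_equal(m$atoms$x[m$atoms$elety == "CB"], 1)  # tie: first wins
})

test_that("write_structure handles empty models and rejects long chain ids", {
  empty <- select_atoms(toy40(), "none")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(empty, f)
  expect_true(file.exists(f))
  bad <- toy40()
  bad$atoms$chain <- "AB"
  expect_error(write_structure(bad, withr::local_tempfile(fileext = ".pdb")),
               "single-character")
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
  expect_error(write_structure(toy40(), "x.xyz"), "format")
})

test_that("selection language selects chains, ranges, kinds and composes", {
  m <- dimer_full()
  a_only <- select_atoms(m, "chain A")
  expect_setequal(unique(a_only$atoms$parent_chain), "A")
  rng <- select_atoms(m, "authchain A and resi 10-20")
  expect_equal(sort(unique(rng$atoms$resno)), 10:20)
  expect_equal(length(unique(.subset2(rng$atoms, "resno"))), 11)
  gly <- select_atoms(m, "kind glycan")
  expect_true(all(gly$atoms$resid %in% sugar_codes()))
  expect_equal(n_atoms(select_atoms(m, "none")), 0)
  comb <- select_atoms(m, "(chain A or chain B) and not kind glycan")
  expect_false(any(comb$atoms$kind == "glycan"))
  expect_equal(n_atoms(select_atoms(m, "all")), n_atoms(m))
  # atoms partition across chain selections
  expect_equal(n_atoms(select_atoms(m, "chain A")) +
                 n_atoms(select_atoms(m, "chain B")), n_atoms(m))
})

test_that("malformed selections raise syntax errors with a position", {
  m <- toy40()
  expect_error(select_atoms(m, "chain"), "expected chain id")
  expect_error(select_atoms(m, "frobnicate A"), "unknown term")
  expect_error(select_atoms(m, "resi 1-x"), "bad range")
  expect_error(select_atoms(m, "kind wet"), "unknown kind")
  expect_error(select_atoms(m, "(chain A"), "expected ')'")
  expect_error(select_atoms(m, "chain A chain B"), "unexpected")
})

test_that("glycan assignment walks Asn-ND2 then sugar-sugar links", {
  # no sugars: unchanged
  m0 <- toy40()
  expect_identical(assign_glycans(m0)$atoms, m0$atoms)
  # constructed Asn + NAG at 1.45 A C1-ND2
  atoms <- rbind(
    atom_row("A", 10, "ASN", "CB", "C", 0, 0, 0),
    atom_row("A", 10, "ASN", "ND2", "N", 1.3, 0, 0),
    atom_row("B", 901, "NAG", "C1", "C", 2.75, 0, 0, hetero = TRUE),
    atom_row("B", 901, "NAG", "O4", "O", 3.45, 0, 0, hetero = TRUE),
    atom_row("B", 902, "BMA", "C1", "C", 4.85, 0, 0, hetero = TRUE))
  m <- assign_glycans(structure_model(atoms))
  gl <- m$atoms[m$atoms$kind == "glycan", ]
  expect_equal(unique(gl$parent_chain), "A")
  expect_equal(unique(gl$glycan_root), 10)
  expect_identical(coords(m), coords(structure_model(atoms)))
  # sugar reachable from two Asn roots is an error
  atoms2 <- rbind(
    atom_row("A", 10, "ASN", "ND2", "N", 0, 0, 0),
    atom_row("B", 20, "ASN", "ND2", "N", 2.8, 0, 0),
    atom_row("A", 901, "NAG", "C1", "C", 1.4, 0, 0, hetero = TRUE))
  expect_error(assign_glycans(structure_model(atoms2)), "two Asn roots")
  # unattached sugar flagged as free ligand
  atoms3 <- atom_row("A", 901, "NAG", "C1", "C", 50, 50, 50, hetero = TRUE)
  m3 <- assign_glycans(structure_model(atoms3))
  expect_equal(m3$atoms$kind, "ligand")
})

test_that("generated dimer glycans attach to their own chain's Asn", {
  m <- dimer_full()
  gl <- m$atoms[m$atoms$kind == "glycan", ]
  expect_gt(nrow(gl), 0)
  expect_equal(unique(gl$parent_chain[gl$chain == "A"]), "A")
  expect_equal(unique(gl$parent_chain[gl$chain == "B"]), "B")
  expect_equal(unique(gl$glycan_root), attr(m, "planted")$glycan_resno)
})
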