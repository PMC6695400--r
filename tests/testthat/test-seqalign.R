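test_that("global alignment handles identity, symmetry and errors", {
  a <- global_align("MKTAYIAK", "MKTAYIAK")
  expect_equal(a$identity, 100)
  expect_equal(a$members[["a"]], "MKTAYIAK")
  # score and identity are symmetric under argument swap
  x <- "HEAGAWGHEE"
  y <- "PAWHEAE"
  f <- global_align(x, y)
  r <- global_align(y, x)
  expect_equal(f$score, r$score)
  expect_equal(f$identity, r$identity)
  # degap round-trip restores the inputs
  expect_equal(degap(f, "a"), x)
  expect_equal(degap(f, "b"), y)
  expect_error(global_align("", "ACD"), "empty")
  expect_error(global_align("ACD", "AB1"), "outside")
})

test_that("alignment DP matches the exhaustive enumeration oracle", {
  submat <- .default_submat()
  set.seed(21)
  alpha <- c("A", "C", "D", "E")
  for (i in 1:25) {
    la <- sample(1:6, 1)
    lb <- sample(1:6, 1)
    sa <- paste(sample(alpha, la, replace = TRUE), collapse = "")
    sb <- paste(sample(alpha, lb, replace = TRUE), collapse = "")
    got <- global_align(sa, sb, gap_open = 10, gap_extend = 0.5)$score
    want <- enumerate_best_score(sa, sb, submat, 10, 0.5)
    expect_equal(got, want, info = paste(sa, sb))
  }
})

test_that("alignment scores agree with an independent implementation", {
  set.seed(33)
  aa <- unname(semadimer:::.AA3[1:20])
  for (i in 1:5) {
    sa <- paste(sample(aa, 60, replace = TRUE), collapse = "")
    sb <- paste(sample(aa, 50, replace = TRUE), collapse = "")
    mine <- global_align(sa, sb, gap_open = 10, gap_extend = 0.5)$score
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    # Biostrings charges opening + extension on the first gap position
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      sa, sb, substitutionMatrix = e$BLOSUM62, gapOpening = 9.5,
      gapExtension = 0.5, type = "global"))
    expect_equal(mine, ref)
  }
})

test_that("progressive MSA reduces to pairwise and keeps copies gap-free", {
  two <- progressive_msa(c(p = "HEAGAWGHEE", q = "PAWHEAE"))
  pw <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(unname(two$members), unname(pw$members))
  three <- progressive_msa(c(a = "MKTAYIAKQR", b = "MKTAYIAKQR",
                             c = "MKTAYIQR"))
  # the copy aligns gap-for-gap with its twin
  expect_equal(three$members[["a"]], three$members[["b"]])
  expect_equal(gsub("-", "", three$members[["c"]]), "MKTAYIQR")
  # single sequence passes through
  one <- progressive_msa(c(z = "ACDEF"))
  expect_equal(one$members[["z"]], "ACDEF")
  # column structure stable under input reordering
  reord <- progressive_msa(c(c = "MKTAYIQR", b = "MKTAYIAKQR",
                             a = "MKTAYIAKQR"))
  expect_equal(reord$members[sort(names(reord$members))],
               three$members[sort(names(three$members))])
})

test_that("planted MSA columns are recovered across seeded families", {
  hits <- 0L
  total <- 0L
  for (seed in 1:20) {
    pp <- list(`10` = c(c1 = "hydrophobic", c2 = "negatively_charged"),
               `25` = c(c1 = "polar", c2 = "positively_charged"))
    seqs <- make_sequence_family(40, c(c1 = 2, c2 = 2), pp,
                                 background_rate = 0.01, seed = seed)
    msa <- progressive_msa(seqs)
    for (p in c(10, 25)) {
      total <- total + 1L
      cols <- vapply(msa$members, function(s)
        substr(s, p, p), character(1))   # gap-free family: column = position
      chem <- residue_chemistry(cols)
      ok <- length(unique(chem[1:2])) == 1 &&
        length(unique(chem[3:4])) == 1 && chem[1] != chem[3]
      hits <- hits + as.integer(ok)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("sequon scanning matches a regular-expression oracle", {
  expect_equal(nrow(sequon_scan("NPT")), 0)       # proline blocks the site
  one <- sequon_scan("ANCSA")
  expect_equal(one$position, 2)
  expect_equal(one$triplet, "NCS")
  # overlapping sites are all reported
  expect_equal(sequon_scan("NNSS")$position, c(1, 2))
  # author-style numbering and ranges
  sc <- sequon_scan("ANCSAANGTA", numbering_start = 310)
  expect_equal(sc$position, c(311, 316))
  expect_equal(sequon_scan("ANCSAANGTA", range = c(310, 313),
                           numbering_start = 310)$position, 311)
  set.seed(8)
  aa <- unname(semadimer:::.AA3[1:20])
  for (i in 1:200) {
    s <- paste(sample(aa, sample(3:60, 1), replace = TRUE), collapse = "")
    oracle <- gregexpr("N(?=[^P][ST])", s, perl = TRUE)[[1]]
    oracle <- oracle[oracle > 0]
    expect_equal(sequon_scan(s)$position, as.integer(oracle), info = s)
  }
})

test_that("residue chemistry partitions the 20-letter alphabet", {
  aa <- unname(semadimer:::.AA3[1:20])
  chem <- residue_chemistry(aa)
  expect_equal(sort(unique(chem)),
               c("hydrophobic", "negatively_charged", "polar",
                 "positively_charged", "special"))
  expect_equal(length(chem), 20)
  expect_equal(residue_chemistry("D"), "negatively_charged")
  expect_equal(residue_chemistry("F"), "hydrophobic")
  expect_equal(residue_chemistry("H"), "polar")
  expect_equal(residue_chemistry("H",
                                 reclassify = c(H = "positively_charged")),
               "positively_charged")
  expect_error(residue_chemistry("B"), "unknown")
})
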