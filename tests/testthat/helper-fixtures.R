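# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; no binary fixtures are stored.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

toy40 <- function() fixture("toy40", function() make_toy_domain(40, seed = 7))

dimer_plain <- function() fixture("dimer_plain", function()
  make_c2_dimer(toy40(), plant_ss = FALSE, plant_glycan = FALSE, seed = 3))

dimer_full <- function() fixture("dimer_full", function()
  make_c2_dimer(toy40(), plant_ss = TRUE, plant_glycan = TRUE, seed = 3))

# atom-table shorthand for hand-built micro structures
atom_row <- function(chain, resno, resid, elety, elesy, x, y, z,
                     o = 1, hetero = FALSE, insert = "") {
  data.frame(chain = chain, resno = resno, insert = insert, resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z, o = o,
             hetero = hetero, stringsAsFactors = FALSE)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
}

rigid <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

jitter_model <- function(model, sigma, seed) {
  set.seed(seed)
  xyz <- coords(model) + matrix(rnorm(3 * n_atoms(model), 0, sigma),
                                ncol = 3)
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# independent affine-gap alignment oracle: enumerate every global alignment
# recursively (no DP-style memoisation) and return the best score under the
# gap_open + gap_extend * (L - 1) convention
enumerate_best_score <- function(a, b, submat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, submat[ca[i], cb[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(ca)) {
      pen <- if (last == "x") gap_extend else gap_open
      best <- max(best, -pen + rec(i + 1, j, "x"))
    }
    if (j <= length(cb)) {
      pen <- if (last == "y") gap_extend else gap_open
      best <- max(best, -pen + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# planted hot-spot scenario shared by specificity and report tests
hotspot_scenario <- function() fixture("hotspot_scenario", function() {
  d0 <- toy40()
  ref0 <- dimer_plain()
  bs <- buried_surface(ref0, "chain A", "chain B", n_points = 240)
  ir <- bs$per_residue[bs$per_residue$group == "A" &
                         bs$per_residue$delta_asa > 1, ]
  planted <- sort(ir$resno)[1:5]
  pp <- lapply(seq_along(planted), function(i)
    if (i %% 2) c(c1 = "hydrophobic", c2 = "positively_charged")
    else c(c1 = "hydrophobic", c2 = "polar"))
  names(pp) <- planted
  seqs <- make_sequence_family(40, c(c1 = 2, c2 = 2), pp, seed = 5)
  ref <- set_model_sequence(ref0, seqs[["c1_1"]])
  fam <- make_structure_family(
    d0, list(c1 = list(n_members = 2, rigid_shift = 0, noise_sigma = 0.2),
             c2 = list(n_members = 2, rigid_shift = 0, noise_sigma = 0.2)),
    seed = 9)
  fam <- Map(set_model_sequence, fam, seqs[names(fam)])
  list(reference = ref, queries = fam, seqs = seqs, planted = planted,
       class_labels = attr(seqs, "class_labels"))
})
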