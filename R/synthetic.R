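# Seed-controlled synthetic generators. They produce structures, families,
# titrations and molar-mass observations carrying exactly the features the
# analysis stages assume (planted interchain disulfide, glycan contacting
# the partner chain, class-specific substitutions, known Kd), so the whole
# pipeline is testable without external downloads. Toy structures carry
# ideal-geometry backbone stubs rather than physically folded chains:
# sufficient for area/contact/superposition math, which is geometry-only.

.unit <- function(v) v / sqrt(sum(v^2))

.any_perp <- function(u) {
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(.cross3(u, w))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# self-avoiding compact CA trace: step 3.8 A, backbone bend 100-150 deg,
# CA pairs |i-j| >= 3 kept >= 6.0 A apart
.ca_trace <- function(n_res, max_restarts = 30) {
  step <- 3.8
  min_sep <- 6.0
  for (attempt in seq_len(max_restarts)) {
    ca <- matrix(NA_real_, n_res, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- .unit(stats::rnorm(3))
    ca[2, ] <- ca[1, ] + step * dir
    ok <- TRUE
    for (i in 3:n_res) {
      placed <- FALSE
      centroid <- colMeans(ca[1:(i - 1), , drop = FALSE])
      for (try in 1:100) {
        cand <- .unit(stats::rnorm(3) +
                        0.35 * .unit(centroid - ca[i - 1, ]))
        d <- sum(cand * dir)
        if (d < 0.17 || d > 0.87) next      # backbone bend 100-150 deg
        pos <- ca[i - 1, ] + step * cand
        if (i > 3) {
          prev <- ca[1:(i - 3), , drop = FALSE]
          if (min(sqrt(rowSums(sweep(prev, 2, pos)^2))) < min_sep) next
        }
        ca[i, ] <- pos
        dir <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(ca)
  }
  stop("could not place a self-avoiding CA trace after ", max_restarts,
       " restarts")
}

.toy_atoms <- function(ca, seq_letters) {
  n <- nrow(ca)
  aa3 <- names(.AA3)[match(seq_letters, .AA3)]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    prev_u <- if (i > 1) .unit(ca[i - 1, ] - ca[i, ])
              else .unit(ca[i, ] - ca[i + 1, ])
    next_u <- if (i < n) .unit(ca[i + 1, ] - ca[i, ])
              else .unit(ca[i, ] - ca[i - 1, ])
    axis <- .unit(next_u - prev_u)
    out_v <- -(prev_u + next_u)
    out_v <- out_v - sum(out_v * axis) * axis
    out_u <- if (sqrt(sum(out_v^2)) < 1e-6) .any_perp(axis) else .unit(out_v)
    pos <- rbind(N = ca[i, ] + 1.46 * prev_u,
                 CA = ca[i, ],
                 C = ca[i, ] + 1.52 * next_u,
                 O = ca[i, ] + 1.52 * next_u + 1.23 * out_u,
                 CB = ca[i, ] + 1.53 * out_u)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, insert = "", resid = aa3[i],
      elety = rownames(pos), elesy = c("N", "C", "C", "O", "C"),
      x = pos[, 1], y = pos[, 2], z = pos[, 3], o = 1, hetero = FALSE)
  }
  do.call(rbind, rows)
}

# heavy-atom pairs from residues separated by >= 2 in sequence (or different
# chains); used for the generator's clash guarantee
.min_nonbonded <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  same_chain <- outer(atoms$chain, atoms$chain, "==")
  near_seq <- abs(outer(atoms$resno, atoms$resno, "-")) <= 1
  excl <- same_chain & near_seq
  diag(excl) <- TRUE
  min(d[!excl])
}

#' Generate a compact toy protein domain
#'
#' Builds a self-avoiding compact CA trace with ideal backbone stubs
#' (N, CA, C, O, CB) and a seed-deterministic random sequence (cysteine-free,
#' so covalent features are only ever planted explicitly). The result is
#' clash-free: no heavy-atom pair from non-adjacent residues is closer than
#' 2.4 A.
#'
#' @param n_res Residue count (>= 10).
#' @param seed Integer seed; same seed, same coordinates.
#' @return A single-chain `structure_model`.
#' @export
make_toy_domain <- function(n_res, seed = 1) {
  if (n_res < 10) stop("n_res must be >= 10")
  atoms <- .with_seed(seed, {
    res <- NULL
    for (round in 1:10) {
      ca <- .ca_trace(n_res)
      letters1 <- sample(setdiff(unname(.AA3[1:20]), "C"), n_res,
                         replace = TRUE)
      cand <- .toy_atoms(ca, letters1)
      if (.min_nonbonded(cand) >= 2.4) {
        res <- cand
        break
      }
    }
    if (is.null(res)) stop("could not build a clash-free toy domain")
    res
  })
  structure_model(atoms, id = sprintf("toy_%d_%d", n_res, seed))
}

# C2 image about the axis {x = px, y = 0} parallel to z
.c2_image <- function(xyz, px) {
  cbind(2 * px - xyz[, 1], -xyz[, 2], xyz[, 3])
}

.interchain_stats <- function(xyz_a, xyz_b, contact_cutoff = 4.5) {
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), "+") -
    2 * xyz_a %*% t(xyz_b)
  d2 <- pmax(d2, 0)
  list(min = sqrt(min(d2)), n_contacts = sum(d2 <= contact_cutoff^2))
}

.sugar_residue <- function(center, u_in, u_out, resname, resno, chain) {
  ring_ax <- .any_perp(u_in)
  ring_ax2 <- .cross3(u_in, ring_ax)
  ang <- seq(0, 2 * pi, length.out = 6)[1:5]
  ring <- t(vapply(ang, function(a)
    center + 0.75 * (cos(a) * ring_ax + sin(a) * ring_ax2), numeric(3)))
  pos <- rbind(C1 = center - 0.7 * u_in,
               ring,
               O4 = center + 0.7 * u_out)
  rownames(pos) <- c("C1", "C2", "C3", "C4", "C5", "O5", "O4")
  data.frame(chain = chain, resno = resno, insert = "", resid = resname,
             elety = rownames(pos),
             elesy = c("C", "C", "C", "C", "C", "O", "O"),
             x = pos[, 1], y = pos[, 2], z = pos[, 3], o = 1, hetero = TRUE)
}

# build a 3-sugar chain (NAG-NAG-BMA) from an anchor toward the partner
# chain, with centre clearance to the partner tuned into [3.2, 3.4] A
.build_glycan <- function(nd2, partner_xyz, chain) {
  target <- partner_xyz[which.min(sqrt(rowSums(sweep(partner_xyz, 2,
                                                     nd2)^2))), ]
  u <- .unit(target - nd2)
  centers <- matrix(NA_real_, 3, 3)
  dirs <- matrix(NA_real_, 4, 3)
  dirs[1, ] <- u
  cur <- nd2 + 2.15 * u
  centers[1, ] <- cur
  side <- .any_perp(u)
  for (k in 2:3) {
    step_dir <- dirs[k - 1, ]
    cand <- cur + 2.8 * step_dir
    clear <- min(sqrt(rowSums(sweep(partner_xyz, 2, cand)^2)))
    if (clear < 3.2) step_dir <- .unit(0.2 * step_dir + side)
    cur <- cur + 2.8 * step_dir
    centers[k, ] <- cur
    dirs[k, ] <- step_dir
  }
  dirs[4, ] <- dirs[3, ]
  # slide the whole chain along u so the closest centre sits 3.2-3.4 A away
  for (it in 1:200) {
    clear <- min(apply(centers, 1, function(cc)
      min(sqrt(rowSums(sweep(partner_xyz, 2, cc)^2)))))
    if (clear < 3.2) centers <- sweep(centers, 2, 0.05 * u)
    else if (clear > 3.4) centers <- sweep(centers, 2, -0.05 * u)
    else break
  }
  resn <- c("NAG", "NAG", "BMA")
  out <- do.call(rbind, lapply(1:3, function(k)
    .sugar_residue(centers[k, ], dirs[k, ], dirs[k + 1, ], resn[k],
                   900 + k, chain)))
  out
}

#' Generate a C2-symmetric homodimer with plantable covalent features
#'
#' Duplicates a toy domain by a 180 degree rotation about a two-fold axis and
#' slides the copy in until the chains make at least `min_contacts`
#' heavy-atom contacts within 4.5 A without clashing. Optionally plants an
#' interchain disulfide (one surface residue per chain mutated to Cys, SG
#' atoms 2.05 A apart across the interface) and/or a three-sugar
#' NAG-NAG-BMA glycan on a surface Asn of each chain that contacts the
#' partner chain (>= 5 atoms within 4 A).
#'
#' @param domain A single-chain `structure_model` (e.g. [make_toy_domain()]).
#' @param plant_ss Plant the interchain disulfide?
#' @param plant_glycan Plant the partner-contacting glycans?
#' @param seed Integer seed.
#' @param min_contacts Required interchain heavy-atom contacts within 4.5 A.
#' @return A two-chain `structure_model` (chains A and B) with attribute
#'   `planted` recording the planted residue numbers.
#' @export
make_c2_dimer <- function(domain, plant_ss = FALSE, plant_glycan = FALSE,
                          seed = 1, min_contacts = 20) {
  .with_seed(seed, {
    a <- domain$atoms[, c("chain", "resno", "insert", "resid", "elety",
                          "elesy", "x", "y", "z", "o", "hetero")]
    base_xyz <- as.matrix(a[, c("x", "y", "z")])
    base_xyz <- sweep(base_xyz, 2, colMeans(base_xyz))
    # search orientations until a face broad enough for the required contact
    # count meets the partner before any clash
    px <- NA
    for (rot_try in 1:80) {
      Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(Q) < 0) Q[, 1] <- -Q[, 1]
      xyz <- base_xyz %*% Q
      px_grid <- seq(max(xyz[, 1]) + 8, mean(xyz[, 1]), by = -0.1)
      for (p in px_grid) {
        st <- .interchain_stats(xyz, .c2_image(xyz, p))
        if (st$min < 2.6) break
        if (st$n_contacts >= min_contacts) {
          px <- p
          break
        }
      }
      if (!is.na(px)) break
    }
    if (is.na(px))
      stop("could not satisfy the interchain contact constraint")
    a$x <- xyz[, 1]
    a$y <- xyz[, 2]
    a$z <- xyz[, 3]
    planted <- list()
    cb <- which(a$elety == "CB")
    img_cb <- .c2_image(xyz[cb, , drop = FALSE], px)
    self_pair_d <- sqrt(rowSums((xyz[cb, , drop = FALSE] - img_cb)^2))
    ord <- order(self_pair_d)
    if (plant_ss) {
      r_ss <- a$resno[cb[ord[1]]]
      a$resid[a$resno == r_ss] <- "CYS"
      cb_a <- xyz[cb[ord[1]], ]
      cb_b <- img_cb[ord[1], ]
      u <- .unit(cb_b - cb_a)
      m <- (cb_a + cb_b) / 2
      sg_a <- m - 1.025 * u
      a <- rbind(a, data.frame(chain = "A", resno = r_ss, insert = "",
                               resid = "CYS", elety = "SG", elesy = "S",
                               x = sg_a[1], y = sg_a[2], z = sg_a[3],
                               o = 1, hetero = FALSE))
      planted$ss_resno <- r_ss
    }
    # image chain B (including any SG; its image lands 2.05 A away)
    xyz_a_full <- as.matrix(a[, c("x", "y", "z")])
    b <- a
    b$chain <- "B"
    bxyz <- .c2_image(xyz_a_full, px)
    b$x <- bxyz[, 1]
    b$y <- bxyz[, 2]
    b$z <- bxyz[, 3]
    if (plant_glycan) {
      # surface residue near (but not at) the closest-approach point
      cand <- ord[2:min(8, length(ord))]
      if (plant_ss) cand <- cand[a$resno[cb[cand]] != planted$ss_resno]
      done <- FALSE
      for (ci in cand) {
        r_gly <- a$resno[cb[ci]]
        cb_pos <- xyz[cb[ci], ]
        partner <- as.matrix(b[, c("x", "y", "z")])
        u0 <- .unit(partner[which.min(sqrt(rowSums(sweep(partner, 2,
                                                         cb_pos)^2))), ] -
                      cb_pos)
        nd2 <- cb_pos + 1.3 * u0
        gly <- .build_glycan(nd2, partner, "A")
        gxyz <- as.matrix(gly[, c("x", "y", "z")])
        own <- as.matrix(a[a$resno != r_gly, c("x", "y", "z")])
        min_own <- min(sqrt(pmax(0, outer(rowSums(gxyz^2), rowSums(own^2),
                                          "+") - 2 * gxyz %*% t(own))))
        st <- .interchain_stats(gxyz, partner, contact_cutoff = 4.0)
        if (min_own >= 2.4 && st$min >= 2.4 && st$n_contacts >= 5) {
          a$resid[a$resno == r_gly] <- "ASN"
          b$resid[b$resno == r_gly] <- "ASN"
          nd2_row <- data.frame(chain = "A", resno = r_gly, insert = "",
                                resid = "ASN", elety = "ND2", elesy = "N",
                                x = nd2[1], y = nd2[2], z = nd2[3],
                                o = 1, hetero = FALSE)
          a <- rbind(a, nd2_row, gly)
          # mirror to chain B
          extra <- rbind(nd2_row, gly)
          exyz <- .c2_image(as.matrix(extra[, c("x", "y", "z")]), px)
          extra$chain <- "B"
          extra$x <- exyz[, 1]
          extra$y <- exyz[, 2]
          extra$z <- exyz[, 3]
          b <- rbind(b, extra)
          planted$glycan_resno <- r_gly
          done <- TRUE
          break
        }
      }
      if (!done) stop("could not place a partner-contacting glycan")
    }
    out <- structure_model(rbind(a, b), id = paste0(domain$id, "_c2"))
    out <- assign_glycans(out)
    attr(out, "planted") <- planted
    out
  })
}

#' Generate a structure family with planted class structure
#'
#' Each member is the base model with a class-specific rigid shift applied to
#' the C-terminal half of the chain (a synthetic inter-class sub-domain
#' rearrangement) plus isotropic Gaussian coordinate noise.
#'
#' @param base A `structure_model`.
#' @param classes Named list: class -> `list(n_members, rigid_shift,
#'   noise_sigma)` (angstrom).
#' @param seed Integer seed.
#' @return Named list of `structure_model`s with attribute `class_labels`.
#' @export
make_structure_family <- function(base, classes, seed = 1) {
  .with_seed(seed, {
    half <- stats::median(base$atoms$resno)
    out <- list()
    labels <- character()
    for (cl in names(classes)) {
      spec <- classes[[cl]]
      for (m in seq_len(spec$n_members)) {
        mod <- base
        shift_mask <- mod$atoms$resno > half
        mod$atoms$x[shift_mask] <- mod$atoms$x[shift_mask] + spec$rigid_shift
        n <- nrow(mod$atoms)
        mod$atoms$x <- mod$atoms$x + stats::rnorm(n, 0, spec$noise_sigma)
        mod$atoms$y <- mod$atoms$y + stats::rnorm(n, 0, spec$noise_sigma)
        mod$atoms$z <- mod$atoms$z + stats::rnorm(n, 0, spec$noise_sigma)
        id <- paste0(cl, "_", m)
        mod$id <- id
        out[[id]] <- mod
        labels[id] <- cl
      }
    }
    attr(out, "class_labels") <- labels
    out
  })
}

.CHEM_LETTERS <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
  polar = c("S", "T", "N", "Q", "C", "H"),
  positively_charged = c("K", "R"),
  negatively_charged = c("D", "E"),
  special = c("G", "P"))

#' Generate a sequence family with planted class-specific substitutions
#'
#' Members share one random base sequence; at each planted position every
#' member of a class carries a residue of that class's prescribed chemistry
#' (one representative letter per class per position, so chemistry is
#' uniform within class). Background mutations are applied independently at
#' non-planted positions.
#'
#' @param length Sequence length.
#' @param classes Named integer vector: class -> member count.
#' @param planted_positions Named list: position (as character) -> named
#'   vector class -> chemistry class (see [residue_chemistry()]).
#' @param background_rate Per-position substitution probability away from
#'   planted positions (default 0).
#' @param seed Integer seed.
#' @return Named character vector of sequences with attribute `class_labels`.
#' @export
make_sequence_family <- function(length, classes, planted_positions = list(),
                                 background_rate = 0, seed = 1) {
  pos <- as.integer(names(planted_positions))
  if (length(pos) && (any(pos < 1) || any(pos > length)))
    stop("planted position outside sequence range")
  .with_seed(seed, {
    alphabet <- unname(.AA3[1:20])
    base <- sample(alphabet, length, replace = TRUE)
    plant_letter <- list()
    for (p in names(planted_positions)) {
      plant_letter[[p]] <- vapply(planted_positions[[p]], function(chem) {
        pool <- .CHEM_LETTERS[[chem]]
        if (is.null(pool)) stop("unknown chemistry class '", chem, "'")
        sample(pool, 1)
      }, character(1))
    }
    out <- character()
    labels <- character()
    for (cl in names(classes)) {
      for (m in seq_len(classes[[cl]])) {
        s <- base
        for (p in names(plant_letter)) s[as.integer(p)] <- plant_letter[[p]][cl]
        if (background_rate > 0) {
          mut <- which(stats::runif(length) < background_rate)
          mut <- setdiff(mut, pos)
          if (length(mut)) s[mut] <- sample(alphabet, length(mut),
                                            replace = TRUE)
        }
        id <- paste0(cl, "_", m)
        out[id] <- paste(s, collapse = "")
        labels[id] <- cl
      }
    }
    attr(out, "class_labels") <- labels
    out
  })
}

#' Generate a synthetic titration with known Kd
#'
#' Two-fold dilution series from `kd * 1000` downwards (clipped to
#' `n_points`, never below `kd / 100`); the signal follows the exact 1:1
#' depletion model with multiplicative Gaussian noise of coefficient
#' `noise_cv`.
#'
#' @param kd True dissociation constant (molar).
#' @param R Labelled-species concentration (molar, default 5e-9).
#' @param n_points Number of titration points (default 16).
#' @param noise_cv Multiplicative noise coefficient of variation.
#' @param seed Integer seed.
#' @param s_free,s_bound Signal endpoints.
#' @return A [titration()] with attributes `true_kd`, `s_free`, `s_bound`.
#' @export
make_titration <- function(kd, R = 5e-9, n_points = 16, noise_cv = 0.02,
                           seed = 1, s_free = 1, s_bound = 2) {
  full <- kd * 1000 / 2^(0:ceiling(log2(1e5)))
  full <- full[full >= kd / 100]
  L <- full[seq_len(min(n_points, length(full)))]
  .with_seed(seed, {
    mu <- s_free + (s_bound - s_free) * fraction_bound(R, L, kd)
    sig <- mu * (1 + stats::rnorm(length(L), 0, noise_cv))
    out <- titration(L, sig, R)
    attr(out, "true_kd") <- kd
    attr(out, "s_free") <- s_free
    attr(out, "s_bound") <- s_bound
    out
  })
}

#' Imprint an amino-acid sequence onto a model
#'
#' Renames the amino-acid residues of every protein chain to match
#' `sequence` (position 1 = first residue of the chain in author order).
#' Atom names and coordinates are untouched, so a generated family can carry
#' the sequences of a matching [make_sequence_family()].
#'
#' @param model A `structure_model`.
#' @param sequence Sequence string, at least as long as the longest chain.
#' @return The relabelled model.
#' @export
set_model_sequence <- function(model, sequence) {
  ch <- .check_seq(sequence)
  if (any(ch == "X")) stop("cannot imprint unknown residue 'X'")
  aa3 <- names(.AA3)[match(ch, .AA3)]
  a <- model$atoms
  for (cid in chain_ids(model)) {
    rows <- which(a$chain == cid & a$kind == "amino_acid")
    if (!length(rows)) next
    keys <- .residue_key(a[rows, , drop = FALSE])
    idx <- match(keys, unique(keys))
    if (max(idx) > length(aa3))
      stop("sequence shorter than chain ", cid)
    a$resid[rows] <- aa3[idx]
  }
  model$atoms <- a
  model
}

#' Generate molar-mass observations around oligomer peaks
#'
#' Draws observed masses near integer multiples of a monomer mass, emulating
#' light-scattering peak masses for a mixture of oligomeric states.
#'
#' @param m_monomer Monomer mass (kDa).
#' @param copy_numbers Integer copy number per observation.
#' @param rel_sd Relative measurement noise (default 0.02).
#' @param seed Integer seed.
#' @return data.frame with `sample`, `n_true`, `m_obs_kda`, `sd_kda`.
#' @export
make_molar_mass_obs <- function(m_monomer, copy_numbers, rel_sd = 0.02,
                                seed = 1) {
  .with_seed(seed, {
    mu <- m_monomer * copy_numbers
    m <- mu * (1 + stats::rnorm(length(mu), 0, rel_sd))
    data.frame(sample = paste0("obs_", seq_along(mu)),
               n_true = as.integer(copy_numbers),
               m_obs_kda = m, sd_kda = mu * rel_sd)
  })
}
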