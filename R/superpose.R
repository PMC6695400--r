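# Rigid-body superposition: Kabsch fitting, sequence-guided equivalencing
# with iterative core trimming, inter-domain hinge angles, ensemble RMSF.

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the
#' (optionally weighted) rmsd between `R %*% mov + t` and `ref`. Reflections
#' are corrected so `det(R) = +1`.
#'
#' @param coords_ref,coords_mov N x 3 coordinate matrices (angstrom), N >= 3.
#' @param weights Optional non-negative weights of length N.
#' @return List with `transform` (class `rigid_transform`: `rotation` 3x3,
#'   `translation` length-3) and `rmsd` (angstrom).
#' @export
kabsch <- function(coords_ref, coords_mov, weights = NULL) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  n <- nrow(coords_ref)
  if (n < 3 || nrow(coords_mov) != n)
    stop("kabsch needs two equal-length coordinate sets with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("bad weights")
  w <- weights / sum(weights)
  cr <- colSums(coords_ref * w)
  cm <- colSums(coords_mov * w)
  Rc <- sweep(coords_ref, 2, cr)
  Mc <- sweep(coords_mov, 2, cm)
  sv_ref <- svd(Rc * sqrt(w))$d
  if (sv_ref[2] < 1e-8)
    stop("degenerate (collinear) reference geometry")
  H <- t(Mc * w) %*% Rc          # 3 x 3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(cr - R %*% cm)
  fitted <- Mc %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Rc)^2)))
  transform <- structure(list(rotation = R, translation = t_vec),
                         class = "rigid_transform")
  list(transform = transform, rmsd = rmsd)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: rotation angle",
      sprintf("%.2f deg,", rotation_angle(x$rotation)),
      "translation", sprintf("[%.2f %.2f %.2f] A\n", x$translation[1],
                             x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation angle of a 3x3 rotation matrix
#' @param R Orthonormal rotation matrix.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Apply a rigid transform
#' @param x A `structure_model` or an N x 3 coordinate matrix.
#' @param transform A `rigid_transform`.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  if (inherits(x, "structure_model")) {
    xyz <- coords(x)
    xyz <- sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
    coords(x) <- xyz
    return(x)
  }
  sweep(as.matrix(x) %*% t(transform$rotation), 2, transform$translation, "+")
}

# CA atoms of amino-acid residues, in author order, with sequence
.ca_table <- function(model) {
  a <- model$atoms
  ca <- a[a$kind == "amino_acid" & a$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(.residue_key(ca)), , drop = FALSE]
  ca$letter <- unname(.AA3[ca$resid])
  ca$letter[is.na(ca$letter)] <- "X"
  ca
}

# Equivalence CA pairs between two models by global sequence alignment.
.matched_ca <- function(model_a, model_b, gap_open = 10, gap_extend = 0.5) {
  ca_a <- .ca_table(model_a)
  ca_b <- .ca_table(model_b)
  if (nrow(ca_a) < 3 || nrow(ca_b) < 3)
    stop("need at least 3 CA atoms per model")
  aln <- global_align(paste(ca_a$letter, collapse = ""),
                      paste(ca_b$letter, collapse = ""),
                      gap_open = gap_open, gap_extend = gap_extend)
  ij <- aln$pairs                      # matrix of 1-based indices, 0 = gap
  both <- ij[, 1] > 0 & ij[, 2] > 0
  list(ca_a = ca_a, ca_b = ca_b,
       ia = ij[both, 1], ib = ij[both, 2])
}

#' Superpose two structures with iterative core trimming
#'
#' Initial residue equivalences come from a global sequence alignment of the
#' amino-acid content; the Kabsch fit is then refined by discarding pairs
#' deviating more than `max(trim_factor * rmsd, floor_A)` and refitting until
#' no pair is discarded or `max_cycles` is reached. The surviving pairs
#' define the core rmsd, the convention behind trimmed counts such as
#' "rmsd over N CA atoms".
#'
#' @param model_a,model_b `structure_model`s containing amino-acid CA atoms.
#' @param trim_factor Deviation multiplier for trimming (default 2).
#' @param max_cycles Maximum refit cycles (default 10).
#' @param floor_A Trimming floor in angstrom (default 3.5).
#' @return Object of class `superposition`: `transform` (maps b onto a),
#'   `rmsd_core`, `n_matched`, `n_initial`, `pairs` (data.frame of matched
#'   author residue numbers and deviations).
#' @export
match_and_superpose <- function(model_a, model_b, trim_factor = 2,
                                max_cycles = 10, floor_A = 3.5) {
  m <- .matched_ca(model_a, model_b)
  if (length(m$ia) < 3) stop("fewer than 3 initial residue equivalences")
  A <- as.matrix(m$ca_a[m$ia, c("x", "y", "z")])
  B <- as.matrix(m$ca_b[m$ib, c("x", "y", "z")])
  keep <- rep(TRUE, nrow(A))
  fit <- NULL
  for (cycle in seq_len(max_cycles)) {
    fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    dev <- sqrt(rowSums((apply_transform(B, fit$transform) - A)^2))
    cutoff <- max(trim_factor * fit$rmsd, floor_A)
    new_keep <- keep & (dev <= cutoff)
    if (sum(new_keep) < 3 || identical(new_keep, keep)) break
    keep <- new_keep
  }
  fit <- kabsch(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
  dev <- sqrt(rowSums((apply_transform(B, fit$transform) - A)^2))
  pairs <- data.frame(
    chain_a = m$ca_a$chain[m$ia], resno_a = m$ca_a$resno[m$ia],
    chain_b = m$ca_b$chain[m$ib], resno_b = m$ca_b$resno[m$ib],
    deviation = dev, core = keep)
  structure(list(transform = fit$transform, rmsd_core = fit$rmsd,
                 n_matched = sum(keep), n_initial = nrow(A), pairs = pairs),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d CA atoms (%d initial)\n",
              x$rmsd_core, x$n_matched, x$n_initial))
  invisible(x)
}

#' Inter-domain hinge angle between two conformers
#'
#' Superposes `model_mov` onto `model_ref` using the anchor selection, then
#' Kabsch-fits the mobile selection; the residual rotation angle is the hinge
#' reorientation of the mobile domain relative to the anchor.
#'
#' @param model_ref,model_mov `structure_model`s.
#' @param anchor_selection,mobile_selection Selection expressions resolving
#'   to >= 3 CA atoms in both models.
#' @return Hinge angle in degrees, in `[0, 180]`.
#' @export
hinge_angle <- function(model_ref, model_mov, anchor_selection,
                        mobile_selection) {
  fit_part <- function(sel) {
    a <- select_atoms(model_ref, sel)
    b <- select_atoms(model_mov, sel)
    m <- .matched_ca(a, b)
    if (length(m$ia) < 3) stop("selection '", sel, "' gives < 3 CA pairs")
    list(A = as.matrix(m$ca_a[m$ia, c("x", "y", "z")]),
         B = as.matrix(m$ca_b[m$ib, c("x", "y", "z")]))
  }
  anc <- fit_part(anchor_selection)
  mob <- fit_part(mobile_selection)
  anchor_fit <- kabsch(anc$A, anc$B)
  B_mob <- apply_transform(mob$B, anchor_fit$transform)
  resid_fit <- kabsch(mob$A, B_mob)
  rotation_angle(resid_fit$transform$rotation)
}

#' Per-residue RMSF over an ensemble of conformations
#'
#' Frames are superposed onto their mean structure (fit recomputed against
#' the updated mean twice) using CA atoms of `fit_selection`; the RMSF of
#' residue i is `sqrt(mean_frames |x_i - <x_i>|^2)` over its CA position.
#'
#' @param frames List of `structure_model`s sharing residue identity.
#' @param fit_selection Selection used for the superposition fit
#'   (default `"all"`).
#' @param units `"A"` or `"nm"`.
#' @return Object of class `ensemble_stats`: `rmsf` (named per residue),
#'   `n_frames`, `units`.
#' @export
ensemble_rmsf <- function(frames, fit_selection = "all", units = "A") {
  if (length(frames) < 2) stop("need at least 2 frames")
  tabs <- lapply(frames, .ca_table)
  keys <- lapply(tabs, .residue_key)
  ref_keys <- keys[[1]]
  for (k in seq_along(keys)) {
    if (!identical(keys[[k]], ref_keys)) {
      off <- union(setdiff(keys[[k]], ref_keys), setdiff(ref_keys, keys[[k]]))
      stop("frame ", k, " residue set mismatch: ",
           paste(utils::head(off, 5), collapse = ", "))
    }
  }
  fit_mask <- selection_mask(
    structure_model(tabs[[1]][, setdiff(names(tabs[[1]]), "letter")]),
    fit_selection)
  if (sum(fit_mask) < 3) stop("fit selection gives < 3 CA atoms")
  X <- lapply(tabs, function(tt) as.matrix(tt[, c("x", "y", "z")]))
  mean_x <- X[[1]]
  for (it in 1:2) {
    X <- lapply(X, function(xi) {
      fit <- kabsch(mean_x[fit_mask, , drop = FALSE],
                    xi[fit_mask, , drop = FALSE])
      apply_transform(xi, fit$transform)
    })
    mean_x <- Reduce(`+`, X) / length(X)
  }
  dev2 <- Reduce(`+`, lapply(X, function(xi) rowSums((xi - mean_x)^2))) /
    length(X)
  rmsf <- sqrt(dev2)
  if (units == "nm") rmsf <- rmsf / 10
  names(rmsf) <- ref_keys
  structure(list(rmsf = rmsf, n_frames = length(frames), units = units),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble_stats: %d residues over %d frames, median RMSF %.3f %s\n",
              length(x$rmsf), x$n_frames, stats::median(x$rmsf), x$units))
  invisible(x)
}
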