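# Solvent-accessible surface area (Shrake-Rupley, deterministic Fibonacci
# sphere), buried-surface partition at an interface, typed contacts.

#' Default van der Waals radii (angstrom)
#'
#' Chothia-style heavy-atom radii used for surface-area work: C 1.87,
#' N 1.65, O 1.40, S 1.85, plus P and common halogens/ions for robustness.
#'
#' @return Named numeric vector keyed by element symbol.
#' @export
default_radii <- function() {
  c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, SE = 1.90)
}

# Deterministic Fibonacci unit-sphere lattice.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- pi * (3 - sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

.sasa_atoms_mask <- function(model) {
  a <- model$atoms
  a$kind != "water" & a$elesy != "H" & a$elesy != "D"
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area with a rolling probe, computed on a shared
#' deterministic Fibonacci point lattice. Waters and hydrogens are excluded;
#' glycan and ligand heavy atoms are included. The point lattice is fixed in
#' the laboratory frame by default; pass `orientation` (a rotation matrix)
#' to co-rotate it with the molecule, which makes SASA exactly invariant
#' under that rotation.
#'
#' @param model A `structure_model`.
#' @param probe Probe radius (angstrom, default 1.4).
#' @param n_points Test points per atom (default 960).
#' @param radii Named per-element radii; see [default_radii()].
#' @param orientation Optional 3x3 rotation applied to the point lattice.
#' @return Object of class `area_set`: `per_atom_area` (NA for excluded
#'   atoms), `total`, `probe_radius`, `n_points`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960, radii = default_radii(),
                 orientation = NULL) {
  if (n_atoms(model) == 0) stop("empty model")
  mask <- .sasa_atoms_mask(model)
  a <- model$atoms[mask, , drop = FALSE]
  unknown <- setdiff(unique(a$elesy), names(radii))
  if (length(unknown))
    stop("no radius configured for element(s): ",
         paste(unknown, collapse = ", "))
  pts <- .fibonacci_sphere(n_points)
  if (!is.null(orientation)) pts <- pts %*% t(orientation)
  per <- rep(NA_real_, n_atoms(model))
  if (nrow(a)) {
    per[mask] <- .sasa_cpp(as.matrix(a[, c("x", "y", "z")]),
                           radii[a$elesy], probe, pts)
  }
  structure(list(per_atom_area = per, total = sum(per, na.rm = TRUE),
                 probe_radius = probe, n_points = n_points),
            class = "area_set")
}

#' @export
print.area_set <- function(x, ...) {
  cat(sprintf("area_set: total SASA %.1f A^2 (probe %.1f A, %d points)\n",
              x$total, x$probe_radius, x$n_points))
  invisible(x)
}

#' Buried surface area between two groups of a complex
#'
#' Buried surface is the loss of solvent-accessible area on complexation,
#' summed over BOTH groups: `SASA(A) + SASA(B) - SASA(A+B)`. Glycans travel
#' with their parent chain's group (selection `chain` follows
#' [assign_glycans()] attachment). Only atoms belonging to one of the two
#' groups enter the calculation, so per-component contributions partition
#' the total.
#'
#' @param complex A `structure_model` holding both groups.
#' @param group_a,group_b Disjoint, non-empty selection expressions.
#' @param probe,n_points,radii,orientation See [sasa()].
#' @param threshold Per-residue delta-ASA above which a residue is listed as
#'   an interface residue (angstrom^2, default 0.1).
#' @return Object of class `interface_report`: `bsa_total`, `per_residue`
#'   (delta-ASA per residue per group), `interface_residues`, plus the union
#'   model and per-atom deltas used by [component_contribution()].
#' @export
buried_surface <- function(complex, group_a, group_b, probe = 1.4,
                           n_points = 960, radii = default_radii(),
                           orientation = NULL, threshold = 0.1) {
  mask_a <- selection_mask(complex, group_a)
  mask_b <- selection_mask(complex, group_b)
  if (any(mask_a & mask_b))
    stop("groups overlap: ", sum(mask_a & mask_b), " shared atoms")
  if (!any(mask_a) || !any(mask_b)) stop("both groups must be non-empty")
  model_a <- select_atoms(complex, mask_a)
  model_b <- select_atoms(complex, mask_b)
  union_model <- select_atoms(complex, mask_a | mask_b)
  in_a <- mask_a[mask_a | mask_b]
  s_a <- sasa(model_a, probe, n_points, radii, orientation)
  s_b <- sasa(model_b, probe, n_points, radii, orientation)
  s_ab <- sasa(union_model, probe, n_points, radii, orientation)
  alone <- numeric(n_atoms(union_model))
  alone[in_a] <- s_a$per_atom_area
  alone[!in_a] <- s_b$per_atom_area
  delta <- alone - s_ab$per_atom_area
  delta[is.na(delta)] <- 0
  bsa_total <- sum(delta)
  u <- union_model$atoms
  key <- .residue_key(u)
  per_res <- stats::aggregate(delta,
                              by = list(group = ifelse(in_a, "A", "B"),
                                        chain = u$chain, resno = u$resno,
                                        insert = u$insert, resid = u$resid),
                              FUN = sum)
  names(per_res)[names(per_res) == "x"] <- "delta_asa"
  per_res <- per_res[order(per_res$group, per_res$chain, per_res$resno), ]
  rownames(per_res) <- NULL
  structure(list(group_a = if (is.character(group_a)) group_a else "<mask>",
                 group_b = if (is.character(group_b)) group_b else "<mask>",
                 bsa_total = bsa_total,
                 per_residue = per_res,
                 interface_residues =
                   per_res[per_res$delta_asa > threshold, , drop = FALSE],
                 model = union_model, per_atom_delta = delta,
                 in_group_a = in_a, probe = probe, n_points = n_points),
            class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("interface_report: %s vs %s\n", x$group_a, x$group_b))
  cat(sprintf("  buried surface (both groups): %.1f A^2\n", x$bsa_total))
  cat(sprintf("  interface residues: %d\n", nrow(x$interface_residues)))
  invisible(x)
}

#' Percent contribution of a component to the buried surface
#'
#' `100 * sum(delta-ASA over component atoms) / bsa_total`. Components that
#' partition the complex have contributions summing to 100.
#'
#' @param report An `interface_report` from [buried_surface()].
#' @param component Selection expression over the union model (subset of the
#'   two groups).
#' @return Percent of total buried surface.
#' @export
component_contribution <- function(report, component) {
  if (report$bsa_total <= 0)
    stop("undefined contribution: total buried surface is zero")
  mask <- selection_mask(report$model, component)
  100 * sum(report$per_atom_delta[mask]) / report$bsa_total
}

#' Typed inter-group atomic contacts
#'
#' Detects, between two disjoint groups: disulfides (CYS SG--SG <= 2.3 A),
#' salt bridges (Asp/Glu carboxylate O vs Lys NZ / Arg NE,NH1,NH2 / His
#' ND1,NE2 <= 4.0 A), hydrogen bonds (N/O donor-acceptor pairs <= 3.5 A;
#' distance-only, crystal structures lack hydrogens) and remaining nonbonded
#' heavy-atom pairs <= 4.0 A. Each pair is reported once with its most
#' specific kind.
#'
#' @param complex A `structure_model`.
#' @param group_a,group_b Disjoint selection expressions.
#' @param hb_cutoff,sb_cutoff,nb_cutoff,ss_cutoff Distance cutoffs (angstrom).
#' @return data.frame with kind, atom descriptors and distance.
#' @export
find_contacts <- function(complex, group_a, group_b, hb_cutoff = 3.5,
                          sb_cutoff = 4.0, nb_cutoff = 4.0,
                          ss_cutoff = 2.3) {
  mask_a <- selection_mask(complex, group_a)
  mask_b <- selection_mask(complex, group_b)
  if (any(mask_a & mask_b)) stop("groups overlap")
  heavy <- .sasa_atoms_mask(complex)
  ia <- which(mask_a & heavy)
  ib <- which(mask_b & heavy)
  empty <- data.frame(kind = character(), chain_a = character(),
                      resno_a = integer(), resid_a = character(),
                      name_a = character(), chain_b = character(),
                      resno_b = integer(), resid_b = character(),
                      name_b = character(), distance = numeric())
  if (!length(ia) || !length(ib)) return(empty)
  at <- complex$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  maxcut <- max(hb_cutoff, sb_cutoff, nb_cutoff, ss_cutoff)
  d2 <- outer(rowSums(xyz[ia, , drop = FALSE]^2),
              rowSums(xyz[ib, , drop = FALSE]^2), "+") -
    2 * xyz[ia, , drop = FALSE] %*% t(xyz[ib, , drop = FALSE])
  hits <- which(d2 <= maxcut^2, arr.ind = TRUE)
  if (!nrow(hits)) return(empty)
  i <- ia[hits[, 1]]
  j <- ib[hits[, 2]]
  dist <- sqrt(pmax(0, d2[hits]))
  is_sg <- function(k) at$resid[k] == "CYS" & at$elety[k] == "SG"
  acidic_o <- function(k) at$resid[k] %in% c("ASP", "GLU") &
    at$elety[k] %in% c("OD1", "OD2", "OE1", "OE2")
  basic_n <- function(k)
    (at$resid[k] == "LYS" & at$elety[k] == "NZ") |
    (at$resid[k] == "ARG" & at$elety[k] %in% c("NE", "NH1", "NH2")) |
    (at$resid[k] == "HIS" & at$elety[k] %in% c("ND1", "NE2"))
  no <- function(k) at$elesy[k] %in% c("N", "O")
  kind <- rep(NA_character_, length(i))
  kind[dist <= ss_cutoff & is_sg(i) & is_sg(j)] <- "disulfide"
  sb <- is.na(kind) & dist <= sb_cutoff &
    ((acidic_o(i) & basic_n(j)) | (basic_n(i) & acidic_o(j)))
  kind[sb] <- "salt_bridge"
  hb <- is.na(kind) & dist <= hb_cutoff & no(i) & no(j)
  kind[hb] <- "hydrogen_bond"
  kind[is.na(kind) & dist <= nb_cutoff] <- "nonbonded"
  keep <- !is.na(kind)
  out <- data.frame(kind = kind[keep],
                    chain_a = at$chain[i][keep], resno_a = at$resno[i][keep],
                    resid_a = at$resid[i][keep], name_a = at$elety[i][keep],
                    chain_b = at$chain[j][keep], resno_b = at$resno[j][keep],
                    resid_b = at$resid[j][keep], name_b = at$elety[j][keep],
                    distance = dist[keep])
  out[order(out$kind, out$distance), ]
}
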