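# Transfer of a receptor-binding interface from a reference ligand-receptor
# complex onto query structures, and calling of class-specific substitution
# positions ("hot-spots") at the transferred site.

#' Transfer a receptor-binding interface onto a query structure
#'
#' Interface residues of the reference ligand (delta-ASA against the receptor
#' above `delta_threshold`) are mapped onto the query through the residue
#' pairing of a trimmed superposition of the reference ligand onto the query.
#'
#' @param reference_complex `structure_model` holding ligand and receptor.
#' @param ligand_sel,receptor_sel Selections for the two partners.
#' @param query Query `structure_model` (its sema-domain content should be
#'   superposable on the reference ligand).
#' @param delta_threshold Interface membership threshold on delta-ASA
#'   (angstrom^2, default 1).
#' @param n_points Sphere sampling for the interface calculation.
#' @return Object of class `transferred_interface`: `query_id`, `source`,
#'   `residues` (query residues mapped from the reference interface),
#'   `mapping` (reference residue -> query residue), `unmapped` (reference
#'   interface residues without a query equivalent).
#' @export
transfer_interface <- function(reference_complex, ligand_sel, receptor_sel,
                               query, delta_threshold = 1, n_points = 240) {
  rep_if <- buried_surface(reference_complex, ligand_sel, receptor_sel,
                           n_points = n_points)
  lig_res <- rep_if$per_residue[rep_if$per_residue$group == "A" &
                                  rep_if$per_residue$delta_asa >
                                    delta_threshold, , drop = FALSE]
  ligand <- select_atoms(reference_complex, ligand_sel)
  sup <- match_and_superpose(query, ligand)
  pr <- sup$pairs  # resno_a: query, resno_b: reference ligand
  ref_key <- paste(lig_res$chain, lig_res$resno)
  pair_key <- paste(pr$chain_b, pr$resno_b)
  hit <- match(ref_key, pair_key)
  mapping <- data.frame(
    ref_chain = lig_res$chain, ref_resno = lig_res$resno,
    ref_resid = lig_res$resid, delta_asa = lig_res$delta_asa,
    query_chain = pr$chain_a[hit], query_resno = pr$resno_a[hit])
  mapped <- !is.na(hit)
  structure(list(query_id = query$id, source = reference_complex$id,
                 residues = mapping[mapped, c("query_chain", "query_resno")],
                 mapping = mapping[mapped, , drop = FALSE],
                 unmapped = mapping[!mapped,
                                    c("ref_chain", "ref_resno", "ref_resid")],
                 superposition = sup),
            class = "transferred_interface")
}

#' @export
print.transferred_interface <- function(x, ...) {
  cat(sprintf("transferred_interface: %s -> %s, %d residues mapped, %d unmapped\n",
              x$source, x$query_id, nrow(x$residues), nrow(x$unmapped)))
  invisible(x)
}

#' Call class-specific substitution positions at a transferred interface
#'
#' For every alignment column holding a transferred-interface residue of at
#' least one member, the residue chemistry (see [residue_chemistry()]) is
#' compared across members: a hot-spot is called when chemistry is uniform
#' within each class but differs between classes. Within-class uniformity
#' means identical chemistry class, not identical residue. The substitution
#' kind distinguishes hydrophobic/polar swaps from swaps involving a charge
#' change.
#'
#' @param interfaces Named list of `transferred_interface` objects, one per
#'   member (names are member ids).
#' @param msa Alignment containing all members.
#' @param class_labels Named character vector member -> class.
#' @param numbering_start Named vector of each member's first residue number
#'   (default 1).
#' @param reference_member Member whose own numbering is used for reported
#'   positions (default: lexicographically first id).
#' @param reclassify Passed to [residue_chemistry()].
#' @return data.frame (class `hotspot_calls`): `column`, `position`
#'   (reference-member numbering, NA where the reference is gapped), one
#'   chemistry column per class, and `kind`.
#' @export
call_hotspots <- function(interfaces, msa, class_labels,
                          numbering_start = NULL, reference_member = NULL,
                          reclassify = NULL) {
  ids <- sort(names(interfaces))
  if (!all(ids %in% names(msa$members)))
    stop("member(s) missing from msa: ",
         paste(setdiff(ids, names(msa$members)), collapse = ", "))
  if (!all(ids %in% names(class_labels)))
    stop("member(s) missing class label")
  classes <- sort(unique(class_labels[ids]))
  if (is.null(reference_member)) reference_member <- ids[1]
  start_of <- function(id) {
    if (is.null(numbering_start) || is.null(numbering_start[[id]])) 1L
    else as.integer(numbering_start[[id]])
  }
  gapped <- lapply(msa$members[ids], function(s) strsplit(s, "")[[1]])
  # member position -> alignment column
  col_of <- lapply(gapped, function(g) which(g != "-"))
  # columns touched by any member's transferred interface
  iface_cols <- integer(0)
  for (id in ids) {
    pos <- interfaces[[id]]$residues$query_resno
    idx <- pos - start_of(id) + 1L
    idx <- idx[idx >= 1 & idx <= length(col_of[[id]])]
    iface_cols <- union(iface_cols, col_of[[id]][idx])
  }
  iface_cols <- sort(iface_cols)
  out <- NULL
  for (cc in iface_cols) {
    letters_cc <- vapply(gapped, function(g) g[cc], character(1))
    if (any(letters_cc == "-")) next
    chem <- residue_chemistry(letters_cc, reclassify = reclassify)
    names(chem) <- ids
    class_chem <- vapply(classes, function(cl) {
      u <- unique(chem[ids[class_labels[ids] == cl]])
      if (length(u) == 1) u else NA_character_
    }, character(1))
    if (any(is.na(class_chem))) next                 # not uniform within class
    if (length(unique(class_chem)) < length(classes)) next  # no between-class difference
    charged <- class_chem %in% c("positively_charged", "negatively_charged")
    kind <- if (any(charged)) "charge_swap"
            else if (setequal(unique(class_chem), c("hydrophobic", "polar")))
              "hydrophobic_polar_swap"
            else "other"
    gref <- gapped[[reference_member]]
    pos_ref <- if (gref[cc] == "-") NA_integer_
               else sum(gref[seq_len(cc)] != "-") + start_of(reference_member) - 1L
    row <- data.frame(column = cc, position = pos_ref, kind = kind)
    for (cl in classes) row[[paste0("chem_", cl)]] <- class_chem[[cl]]
    out <- rbind(out, row)
  }
  if (is.null(out))
    out <- data.frame(column = integer(), position = integer(),
                      kind = character())
  class(out) <- c("hotspot_calls", "data.frame")
  attr(out, "reference_member") <- reference_member
  out
}
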