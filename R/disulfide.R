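# Disulfide detection, covalent-dimer verdicts, and cross-family residue
# equivalencing through a multiple sequence alignment.

#' Find disulfide bonds in a structure
#'
#' All cysteine SG--SG pairs within `cutoff` are reported as bonds; pairs in
#' `(cutoff, near_cutoff]` are reported separately as near-contacts. Scope is
#' classified by chain identity (author chain, not glycan-parent grouping).
#'
#' @param model A `structure_model`.
#' @param cutoff SG--SG bond cutoff (angstrom, default 2.3; a typical S--S
#'   bond is about 2.05 A).
#' @param near_cutoff Upper limit for near-contact reporting (default 3.0).
#' @return data.frame with one row per pair: chains, residue numbers,
#'   `sg_distance`, `scope` (`intrachain`/`interchain`), `near_contact`.
#' @export
find_disulfides <- function(model, cutoff = 2.3, near_cutoff = 3.0) {
  a <- model$atoms
  sg <- which(a$resid == "CYS" & a$elety == "SG")
  empty <- data.frame(chain_a = character(), resno_a = integer(),
                      chain_b = character(), resno_b = integer(),
                      sg_distance = numeric(), scope = character(),
                      near_contact = logical())
  if (length(sg) < 2) return(empty)
  xyz <- as.matrix(a[sg, c("x", "y", "z")])
  out <- empty
  for (p in seq_len(length(sg) - 1)) {
    for (q in (p + 1):length(sg)) {
      d <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
      if (d > near_cutoff) next
      same_res <- .residue_key(a[sg[c(p, q)], ])[1] ==
        .residue_key(a[sg[c(p, q)], ])[2]
      if (same_res) next
      out <- rbind(out, data.frame(
        chain_a = a$chain[sg[p]], resno_a = a$resno[sg[p]],
        chain_b = a$chain[sg[q]], resno_b = a$resno[sg[q]],
        sg_distance = d,
        scope = if (a$chain[sg[p]] == a$chain[sg[q]]) "intrachain"
                else "interchain",
        near_contact = d > cutoff))
    }
  }
  rownames(out) <- NULL
  out
}

#' Covalent-dimer verdict from interchain disulfides
#'
#' The verdict considers covalent linkage only: a structure is called a
#' covalent dimer iff it contains at least one interchain disulfide bond
#' (near-contacts do not count). Non-covalent association is out of scope
#' here.
#'
#' @param model A `structure_model`.
#' @param cutoff SG--SG bond cutoff passed to [find_disulfides()].
#' @return Object of class `covalent_dimer_call`: `structure_id`,
#'   `interchain_bonds` (data.frame), `verdict` (`"covalent_dimer"` or
#'   `"no_covalent_link"`).
#' @export
covalent_dimer_call <- function(model, cutoff = 2.3) {
  if (length(chain_ids(model)) < 1) stop("model has no chains")
  ss <- find_disulfides(model, cutoff = cutoff)
  inter <- ss[ss$scope == "interchain" & !ss$near_contact, , drop = FALSE]
  structure(list(structure_id = model$id, interchain_bonds = inter,
                 verdict = if (nrow(inter)) "covalent_dimer"
                           else "no_covalent_link"),
            class = "covalent_dimer_call")
}

#' @export
print.covalent_dimer_call <- function(x, ...) {
  cat("covalent_dimer_call [", x$structure_id, "]: ", x$verdict, sep = "")
  if (nrow(x$interchain_bonds))
    cat(" (", nrow(x$interchain_bonds), " interchain S-S)", sep = "")
  cat("\n")
  invisible(x)
}

#' Map a residue position across family members through an MSA
#'
#' Finds the alignment column holding `position_from` of `member_from` and
#' returns the letter and own-numbering position of `member_to` in that
#' column (or a gap indicator). This is how a cysteine position in one family
#' member is compared with its equivalent in another.
#'
#' @param msa An alignment object (see [progressive_msa()]).
#' @param member_from,member_to Member ids.
#' @param position_from Position in `member_from`'s own numbering.
#' @param numbering_start Named vector: first-residue number of each member's
#'   sequence (default 1 for all).
#' @return List with `letter` (`"-"` if gapped), `position` (NA if gapped)
#'   and `column`.
#' @export
equivalent_residue <- function(msa, member_from, position_from, member_to,
                               numbering_start = NULL) {
  ids <- names(msa$members)
  if (!member_from %in% ids || !member_to %in% ids)
    stop("member not present in alignment")
  start_of <- function(id) {
    if (is.null(numbering_start) || is.null(numbering_start[[id]])) 1L
    else as.integer(numbering_start[[id]])
  }
  gfrom <- strsplit(msa$members[[member_from]], "")[[1]]
  idx_from <- position_from - start_of(member_from) + 1L
  nongap <- which(gfrom != "-")
  if (idx_from < 1 || idx_from > length(nongap))
    stop("position ", position_from, " outside sequence of ", member_from)
  col <- nongap[idx_from]
  gto <- strsplit(msa$members[[member_to]], "")[[1]]
  if (gto[col] == "-")
    return(list(letter = "-", position = NA_integer_, column = col))
  pos_to <- sum(gto[seq_len(col)] != "-") + start_of(member_to) - 1L
  list(letter = gto[col], position = pos_to, column = col)
}
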