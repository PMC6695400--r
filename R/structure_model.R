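#' @useDynLib semadimer, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Recognised residue codes ---------------------------------------------------

.AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V", MSE = "M")

.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")

#' Default sugar residue codes recognised as N-glycan components
#'
#' Three-letter codes treated as glycan residues when classifying atoms.
#' Covers the common N-glycan building blocks seen in crystal structures
#' (N-acetylglucosamine, mannose, fucose, galactose).
#'
#' @return Character vector of residue codes.
#' @export
sugar_codes <- function() c("NAG", "NDG", "BMA", "MAN", "FUC", "GAL")

.classify_kind <- function(resid, extra_sugars = character()) {
  kind <- rep("other", length(resid))
  kind[resid %in% names(.AA3)] <- "amino_acid"
  kind[resid %in% c(sugar_codes(), extra_sugars)] <- "glycan"
  kind[resid %in% .WATER_CODES] <- "water"
  kind[kind == "other"] <- "ligand"
  kind
}

# Constructor ----------------------------------------------------------------

#' Construct a structure model from an atom table
#'
#' The atom table is the single source of truth: one row per atom, author
#' chain/residue numbering preserved. Glycan residues carry a `parent_chain`
#' (set by [assign_glycans()]) so that chain selections keep covalently
#' attached sugars with their protein chain.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`, `resid`
#'   (3-letter residue code), `elety` (atom name), `elesy` (element symbol),
#'   `x`, `y`, `z` (angstrom), `o` (occupancy), `hetero` (logical).
#' @param id Model identifier.
#' @param source_format One of `"pdb"`, `"mmcif"`, `"r"`.
#' @param extra_sugars Additional residue codes to classify as glycan.
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, id = "model", source_format = "r",
                            extra_sugars = character()) {
  required <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  atoms$chain <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$resno <- as.integer(atoms$resno)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(is.na(atoms$elesy) | atoms$elesy == ""))
    stop("empty element symbol in atom table")
  if (is.null(atoms$kind))
    atoms$kind <- .classify_kind(atoms$resid, extra_sugars)
  if (is.null(atoms$parent_chain))
    atoms$parent_chain <- atoms$chain
  if (is.null(atoms$glycan_root))
    atoms$glycan_root <- NA_integer_
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, source_format = source_format),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model '", x$id, "' (", x$source_format, ")\n", sep = "")
  cat("  atoms:", nrow(a), " chains:", paste(unique(a$chain), collapse = " "),
      "\n")
  kinds <- table(a$kind[!duplicated(.residue_key(a))])
  cat("  residues:", sum(kinds), "(",
      paste(names(kinds), kinds, sep = ":", collapse = " "), ")\n")
  invisible(x)
}

.residue_key <- function(a) paste(a$chain, a$resno, a$insert, sep = "|")

#' Number of atoms in a model
#' @param model A `structure_model`.
#' @return Integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of author chain ids, in order of appearance.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Coordinate matrix of a model
#' @param model A `structure_model`.
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

`coords<-` <- function(model, value) {
  stopifnot(nrow(value) == nrow(model$atoms), ncol(value) == 3)
  model$atoms$x <- value[, 1]
  model$atoms$y <- value[, 2]
  model$atoms$z <- value[, 3]
  model
}

#' One-letter amino-acid sequence of a chain
#'
#' @param model A `structure_model`.
#' @param chain Chain id; default first protein chain.
#' @return Named character vector, one letter per amino-acid residue in
#'   author order; names are author residue numbers (with insertion codes).
#' @export
chain_sequence <- function(model, chain = NULL) {
  a <- model$atoms[model$atoms$kind == "amino_acid", , drop = FALSE]
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  if (!nrow(a)) return(character())
  keep <- !duplicated(.residue_key(a))
  r <- a[keep, , drop = FALSE]
  out <- unname(.AA3[r$resid])
  out[is.na(out)] <- "X"
  names(out) <- paste0(r$resno, r$insert)
  out
}

# Selection mini-language ----------------------------------------------------
#
# Grammar:  expr   := and_expr ( "or" and_expr )*
#           and_expr := not_expr ( "and" not_expr )*
#           not_expr := "not" not_expr | primary
#           primary  := "(" expr ")" | term
#           term     := "chain" ids | "authchain" ids | "resi" ranges |
#                       "kind" word | "elem" word | "name" word |
#                       "all" | "none"
# ids and ranges are comma separated without spaces (e.g. resi 120-130,200).
# "chain" follows glycan attachment (parent_chain); "authchain" is the raw
# author chain id.

.tokenize_selection <- function(s) {
  s <- gsub("([()])", " \\1 ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[toks != ""]
}

.parse_ranges <- function(tok, pos) {
  parts <- strsplit(tok, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", p))[[1]]
    if (!length(m))
      stop("selection syntax error at token ", pos, ": bad range '", p, "'")
    lo <- as.integer(m[2])
    hi <- if (m[3] == "") lo else as.integer(m[3])
    c(lo, hi)
  })
  do.call(rbind, out)
}

.selection_eval <- function(atoms, tokens) {
  pos <- 0L
  n <- length(tokens)
  peek <- function() if (pos < n) tokens[pos + 1L] else NA_character_
  advance <- function() {
    pos <<- pos + 1L
    tokens[pos]
  }
  need <- function(what) {
    if (pos >= n)
      stop("selection syntax error at token ", pos + 1L,
           ": expected ", what, " but input ended")
    advance()
  }
  parse_term <- function() {
    tok <- need("a term")
    switch(tok,
      all = rep(TRUE, nrow(atoms)),
      none = rep(FALSE, nrow(atoms)),
      chain = {
        ids <- strsplit(need("chain id(s)"), ",", fixed = TRUE)[[1]]
        atoms$parent_chain %in% ids
      },
      authchain = {
        ids <- strsplit(need("chain id(s)"), ",", fixed = TRUE)[[1]]
        atoms$chain %in% ids
      },
      resi = {
        rng <- .parse_ranges(need("residue range(s)"), pos + 1L)
        hit <- rep(FALSE, nrow(atoms))
        for (k in seq_len(nrow(rng)))
          hit <- hit | (atoms$resno >= rng[k, 1] & atoms$resno <= rng[k, 2])
        hit
      },
      kind = {
        k <- need("a residue kind")
        ok <- c("amino_acid", "glycan", "water", "ligand", "other")
        if (!k %in% ok)
          stop("selection syntax error at token ", pos,
               ": unknown kind '", k, "'")
        atoms$kind == k
      },
      elem = atoms$elesy %in% strsplit(need("element(s)"), ",")[[1]],
      name = atoms$elety %in% strsplit(need("atom name(s)"), ",")[[1]],
      "(" = {
        v <- parse_expr()
        tok2 <- need("')'")
        if (tok2 != ")")
          stop("selection syntax error at token ", pos, ": expected ')'")
        v
      },
      stop("selection syntax error at token ", pos,
           ": unknown term '", tok, "'")
    )
  }
  parse_not <- function() {
    if (identical(peek(), "not")) {
      advance()
      !parse_not()
    } else parse_term()
  }
  parse_and <- function() {
    v <- parse_not()
    while (identical(peek(), "and")) {
      advance()
      v <- v & parse_not()
    }
    v
  }
  parse_expr <- function() {
    v <- parse_and()
    while (identical(peek(), "or")) {
      advance()
      v <- v | parse_and()
    }
    v
  }
  v <- parse_expr()
  if (pos < n)
    stop("selection syntax error at token ", pos + 1L,
         ": unexpected '", tokens[pos + 1L], "'")
  v
}

#' Select atoms from a model by expression
#'
#' Selection expressions combine `chain`, `authchain`, `resi` (inclusive
#' author-numbered ranges), `kind`, `elem`, `name`, `all`, `none` with
#' `and`, `or`, `not` and parentheses, e.g.
#' `"chain A and resi 120-130"`. `chain` follows glycan attachment so that a
#' chain's covalently linked sugars travel with it; use `authchain` for the
#' raw deposited chain id.
#'
#' @param model A `structure_model`.
#' @param selection Selection expression string, or a logical vector over
#'   atoms.
#' @return A new `structure_model` containing exactly the matching atoms
#'   (possibly empty).
#' @export
select_atoms <- function(model, selection) {
  mask <- selection_mask(model, selection)
  out <- model
  out$atoms <- model$atoms[mask, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Logical atom mask for a selection expression
#' @inheritParams select_atoms
#' @return Logical vector, one entry per atom.
#' @export
selection_mask <- function(model, selection) {
  if (is.logical(selection)) {
    stopifnot(length(selection) == nrow(model$atoms))
    return(selection)
  }
  .selection_eval(model$atoms, .tokenize_selection(selection))
}
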