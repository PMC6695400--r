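# Reading/writing PDB and mmCIF files behind the structure_model container.
# Parsing is delegated to bio3d; altloc resolution and residue-kind
# classification happen here so every downstream module sees one convention.

.guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  stop("cannot guess structure format from extension '.", ext,
       "'; pass format explicitly")
}

.element_from_name <- function(elety) {
  # strip digits/primes, take leading letter(s); good enough as a fallback
  s <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(s, 1, 2))
  one <- toupper(substr(s, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA"),
         two, one)
}

#' Read a macromolecular structure
#'
#' Reads PDB (fixed-column) or mmCIF files into a [structure_model()].
#' Alternate locations are resolved to the highest-occupancy conformer
#' (first on ties); waters, sugars, amino acids and other ligands are
#' classified by residue code.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param extra_sugars Additional residue codes recognised as glycans.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = "auto", extra_sugars = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .guess_format(path)
  if (!format %in% c("pdb", "mmcif"))
    stop("unknown structure format '", format, "'")
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE,
                                         rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  a <- pdb$atom
  elesy <- a$elesy
  bad <- is.na(elesy) | elesy == ""
  if (any(bad)) elesy[bad] <- .element_from_name(a$elety[bad])
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain) | a$chain == "", "_", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid,
    elety = a$elety,
    elesy = toupper(elesy),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE)
  # altloc resolution: highest occupancy wins, first on ties
  alt <- ifelse(is.na(a$alt), "", a$alt)
  if (any(alt != "")) {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 sep = "|")
    ord <- order(key, -atoms$o, seq_len(nrow(atoms)))
    keep_sorted <- !duplicated(key[ord])
    keep <- sort(ord[keep_sorted])
    atoms <- atoms[keep, , drop = FALSE]
  }
  structure_model(atoms, id = sub("\\.[^.]*$", "", basename(path)),
                  source_format = format, extra_sugars = extra_sugars)
}

#' Write a structure model to disk
#'
#' PDB output goes through bio3d's fixed-column writer; mmCIF output is a
#' minimal `atom_site` loop. Coordinates survive a round-trip to 3 decimals.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = "auto") {
  if (format == "auto") format <- .guess_format(path)
  a <- model$atoms
  if (format == "pdb") {
    if (nrow(a) == 0) {
      writeLines("END", path)
      return(invisible(path))
    }
    if (any(nchar(a$chain) > 1))
      stop("PDB dialect permits single-character chain ids; offending: ",
           paste(unique(a$chain[nchar(a$chain) > 1]), collapse = ", "))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     type = ifelse(a$hetero, "HETATM", "ATOM"),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, insert = ifelse(a$insert == "", NA,
                                                      a$insert),
                     o = a$o, b = rep(0, nrow(a)), elesy = a$elesy)
  } else if (format == "mmcif") {
    # canonical wwPDB atom_site field order, which positional readers expect
    hdr <- c(paste0("data_", gsub("[^A-Za-z0-9_]", "_", model$id)),
             "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "type_symbol", "label_atom_id",
                      "label_alt_id", "label_comp_id", "label_asym_id",
                      "label_entity_id", "label_seq_id",
                      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                      "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                      "auth_seq_id", "auth_comp_id", "auth_asym_id",
                      "auth_atom_id", "pdbx_PDB_model_num")))
    if (nrow(a) == 0) {
      writeLines(c(hdr[1], "#"), path)
      return(invisible(path))
    }
    ins <- ifelse(a$insert == "", "?", a$insert)
    rows <- sprintf(
      "%-6s %d %s %-4s . %-3s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 ? %d %-3s %s %-4s 1",
      ifelse(a$hetero, "HETATM", "ATOM"), seq_len(nrow(a)), a$elesy,
      a$elety, a$resid, a$chain, a$resno, ins, a$x, a$y, a$z, a$o,
      a$resno, a$resid, a$chain, a$elety)
    writeLines(c(hdr, rows, "#"), path)
  } else stop("unknown structure format '", format, "'")
  invisible(path)
}

# Glycan attachment ------------------------------------------------------------

#' Attach covalently linked glycans to their parent protein chain
#'
#' Walks covalent linkage geometry: a sugar residue is rooted at an Asn when
#' one of its carbon atoms lies within `link_cutoff` of the Asn side-chain
#' ND2; further sugars are chained through O--C links within `sugar_cutoff`.
#' Attached sugars inherit the Asn's chain as `parent_chain` and record the
#' root Asn residue number; sugars reachable from no Asn are reclassified as
#' free ligands. Coordinates are never modified.
#'
#' @param model A `structure_model`.
#' @param link_cutoff Asn ND2 to sugar C bond-length cutoff (angstrom).
#' @param sugar_cutoff Sugar-to-sugar O--C link cutoff (angstrom).
#' @return The model with glycan grouping annotated.
#' @export
assign_glycans <- function(model, link_cutoff = 2.0, sugar_cutoff = 1.8) {
  a <- model$atoms
  sug <- which(a$kind == "glycan")
  if (!length(sug)) return(model)
  skey <- .residue_key(a)
  sres <- unique(skey[sug])
  # candidate Asn root atoms
  nd2 <- which(a$kind == "amino_acid" & a$resid == "ASN" & a$elety == "ND2")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d2 <- function(i, j) {
    dx <- outer(xyz[i, 1], xyz[j, 1], "-")
    dy <- outer(xyz[i, 2], xyz[j, 2], "-")
    dz <- outer(xyz[i, 3], xyz[j, 3], "-")
    dx * dx + dy * dy + dz * dz
  }
  root_of <- setNames(rep(NA_character_, length(sres)), sres)  # residue key of Asn
  # direct Asn -> sugar links
  if (length(nd2)) {
    sc <- sug[a$elesy[sug] == "C"]
    if (length(sc)) {
      dm <- d2(nd2, sc)
      hits <- which(dm <= link_cutoff^2, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        s_res <- skey[sc[hits[h, 2]]]
        asn_key <- skey[nd2[hits[h, 1]]]
        prev <- root_of[[s_res]]
        if (!is.na(prev) && prev != asn_key)
          stop("glycan residue ", s_res,
               " is linked to two Asn roots: ", prev, " and ", asn_key)
        root_of[[s_res]] <- asn_key
      }
    }
  }
  # sugar-sugar adjacency via O--C links
  adj <- matrix(FALSE, length(sres), length(sres),
                dimnames = list(sres, sres))
  so <- sug[a$elesy[sug] == "O"]
  sc <- sug[a$elesy[sug] == "C"]
  if (length(so) && length(sc)) {
    dm <- d2(so, sc)
    hits <- which(dm <= sugar_cutoff^2, arr.ind = TRUE)
    for (h in seq_len(nrow(hits))) {
      r1 <- skey[so[hits[h, 1]]]
      r2 <- skey[sc[hits[h, 2]]]
      if (r1 != r2) adj[r1, r2] <- adj[r2, r1] <- TRUE
    }
  }
  # propagate roots through the sugar graph (BFS)
  repeat {
    changed <- FALSE
    for (r in sres) {
      if (is.na(root_of[[r]])) next
      nb <- sres[adj[r, ]]
      for (b in nb) {
        if (is.na(root_of[[b]])) {
          root_of[[b]] <- root_of[[r]]
          changed <- TRUE
        } else if (root_of[[b]] != root_of[[r]]) {
          stop("glycan residue ", b, " is linked to two Asn roots: ",
               root_of[[b]], " and ", root_of[[r]])
        }
      }
    }
    if (!changed) break
  }
  asn_chain <- setNames(a$chain, skey)
  asn_resno <- setNames(a$resno, skey)
  for (r in sres) {
    rows <- which(skey == r)
    if (!is.na(root_of[[r]])) {
      model$atoms$parent_chain[rows] <- asn_chain[[root_of[[r]]]]
      model$atoms$glycan_root[rows] <- asn_resno[[root_of[[r]]]]
    } else {
      model$atoms$kind[rows] <- "ligand"
    }
  }
  model
}
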