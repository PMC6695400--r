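# End-to-end reports: dimer interface accounting, specificity hot-spots,
# structure-based tree. Every report embeds its fully resolved configuration
# so a run is reproducible from the report alone.

.report_config <- function(...) {
  cfg <- list(...)
  cfg$package_version <- as.character(utils::packageVersion("semadimer"))
  cfg
}

.write_report_json <- function(report, path) {
  if (!is.null(path)) {
    slim <- report
    slim$model <- NULL
    jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Dimer interface report
#'
#' Buried-surface total, optional per-component contributions (e.g. domains,
#' glycans), disulfide inventory with a covalent-dimer verdict, and typed
#' contacts for one complex.
#'
#' @param model A `structure_model` (run [assign_glycans()] beforehand if
#'   glycan grouping matters).
#' @param group_a,group_b Selection expressions for the two partners.
#' @param components Named list of selection expressions whose percent
#'   contributions to the buried surface are reported.
#' @param probe,n_points See [sasa()].
#' @param json_path Optional path for a JSON copy of the report.
#' @return List (class `dimer_report`) with `bsa_total`, `contributions`,
#'   `disulfides`, `verdict`, `contacts`, `interface_residues`, `config`.
#'   If either group is empty the report carries `note = "no interface"`
#'   instead of interface numbers.
#' @export
run_dimer_report <- function(model, group_a = "chain A", group_b = "chain B",
                             components = list(), probe = 1.4,
                             n_points = 960, json_path = NULL) {
  cfg <- .report_config(structure_id = model$id, group_a = group_a,
                        group_b = group_b,
                        components = lapply(components, identity),
                        probe = probe, n_points = n_points)
  ss <- find_disulfides(model)
  call <- covalent_dimer_call(model)
  ok_a <- any(selection_mask(model, group_a))
  ok_b <- any(selection_mask(model, group_b))
  if (!ok_a || !ok_b) {
    rep <- list(note = "no interface: a grouping selects no atoms",
                bsa_total = NA_real_, contributions = list(),
                disulfides = ss, verdict = call$verdict, contacts = NULL,
                config = cfg)
    class(rep) <- "dimer_report"
    .write_report_json(rep, json_path)
    return(rep)
  }
  iface <- buried_surface(model, group_a, group_b, probe = probe,
                          n_points = n_points)
  contrib <- lapply(components, function(sel)
    component_contribution(iface, sel))
  contacts <- find_contacts(model, group_a, group_b)
  rep <- list(bsa_total = iface$bsa_total, contributions = contrib,
              interface_residues = iface$interface_residues,
              disulfides = ss, verdict = call$verdict, contacts = contacts,
              config = cfg)
  class(rep) <- "dimer_report"
  .write_report_json(rep, json_path)
  rep
}

#' @export
print.dimer_report <- function(x, ...) {
  cat("dimer_report [", x$config$structure_id, "]\n", sep = "")
  if (!is.null(x$note)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf("  buried surface: %.1f A^2\n", x$bsa_total))
    for (nm in names(x$contributions))
      cat(sprintf("  %s contribution: %.1f%%\n", nm, x$contributions[[nm]]))
    cat(sprintf("  contacts: %d typed pairs\n",
                if (is.null(x$contacts)) 0L else nrow(x$contacts)))
  }
  cat("  covalent-dimer verdict:", x$verdict, "\n")
  invisible(x)
}

#' Specificity report: transferred interfaces and hot-spot calls
#'
#' Transfers the receptor-binding interface of a reference complex onto each
#' query, aligns the query sequences, and calls class-specific substitution
#' positions at the transferred site.
#'
#' @param reference_complex Reference ligand-receptor `structure_model`.
#' @param ligand_sel,receptor_sel Selections in the reference complex.
#' @param queries Named list of query `structure_model`s.
#' @param class_labels Named vector query id -> class.
#' @param delta_threshold Interface membership threshold (angstrom^2).
#' @param json_path Optional JSON output path.
#' @param ... Passed to [call_hotspots()].
#' @return List (class `specificity_report`) with `interfaces`, `msa`,
#'   `hotspots`, `config`. With a single class the hot-spot table is empty
#'   and a warning is issued.
#' @export
run_specificity_report <- function(reference_complex, ligand_sel,
                                   receptor_sel, queries, class_labels,
                                   delta_threshold = 1, json_path = NULL,
                                   ...) {
  cfg <- .report_config(reference = reference_complex$id,
                        ligand_sel = ligand_sel,
                        receptor_sel = receptor_sel,
                        queries = names(queries),
                        class_labels = as.list(class_labels),
                        delta_threshold = delta_threshold)
  interfaces <- lapply(queries, function(q)
    transfer_interface(reference_complex, ligand_sel, receptor_sel, q,
                       delta_threshold = delta_threshold))
  seqs <- vapply(queries, function(q)
    paste(chain_sequence(q), collapse = ""), character(1))
  msa <- progressive_msa(seqs)
  if (length(unique(class_labels[names(queries)])) < 2) {
    warning("single-class input: no between-class hot-spots can be called")
    hs <- data.frame(column = integer(), position = integer(),
                     kind = character())
    class(hs) <- c("hotspot_calls", "data.frame")
  } else {
    hs <- call_hotspots(interfaces, msa, class_labels, ...)
  }
  rep <- list(interfaces = interfaces, msa = msa, hotspots = hs,
              config = cfg)
  class(rep) <- "specificity_report"
  if (!is.null(json_path)) {
    jsonlite::write_json(list(hotspots = as.data.frame(hs), config = cfg),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("specificity_report:", length(x$interfaces), "queries,",
      nrow(x$hotspots), "hot-spot position(s)\n")
  if (nrow(x$hotspots)) print(as.data.frame(x$hotspots))
  invisible(x)
}

#' Structure-based tree report
#'
#' Pairwise superposition distances over a selection (e.g. the sema domain),
#' a tree (NJ or UPGMA) and its Newick string; the selection used is logged
#' in the config.
#'
#' @param models Named list of `structure_model`s (>= 3).
#' @param selection Domain selection applied to every model.
#' @param method `"nj"` or `"upgma"`.
#' @param newick_path,matrix_path Optional output paths (Newick text, TSV).
#' @return List (class `tree_report`) with `distance_matrix`, `tree`,
#'   `newick`, `config`.
#' @export
run_tree_report <- function(models, selection = "all", method = "nj",
                            newick_path = NULL, matrix_path = NULL) {
  cfg <- .report_config(models = names(models), selection = selection,
                        method = method)
  D <- build_distance_matrix(models, selection = selection)
  tree <- if (method == "nj") nj_tree(D) else upgma_tree(D)
  nwk <- newick(tree)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(matrix_path))
    utils::write.table(D, matrix_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  rep <- list(distance_matrix = D, tree = tree, newick = nwk, config = cfg)
  class(rep) <- "tree_report"
  rep
}

#' @export
print.tree_report <- function(x, ...) {
  cat("tree_report:", length(x$config$models), "structures,",
      x$config$method, "tree\n")
  cat("  ", x$newick, "\n")
  invisible(x)
}
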