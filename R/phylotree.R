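# Structure-based phylogeny: coverage-penalised superposition distances,
# distance matrices, NJ/UPGMA trees (via ape/phangorn), Newick output.

#' Coverage-penalised structural distance
#'
#' `D = rmsd_core / f` with coverage `f = n_matched / min(len_a, len_b)`.
#' Low-coverage superpositions are penalised so that a small, tight common
#' core does not masquerade as global similarity. Self-comparison gives 0;
#' full coverage reduces to the core rmsd.
#'
#' @param sup A `superposition` from [match_and_superpose()].
#' @param len_a,len_b Amino-acid residue counts of the two models.
#' @return Distance (angstrom-scaled, >= rmsd_core).
#' @export
structural_distance <- function(sup, len_a, len_b) {
  if (sup$n_matched < 3) stop("superposition has fewer than 3 matched pairs")
  f <- sup$n_matched / min(len_a, len_b)
  if (f <= 0) stop("zero coverage")
  sup$rmsd_core / f
}

#' Pairwise structural distance matrix
#'
#' Runs [match_and_superpose()] on every ordered pair of models (optionally
#' restricted to a selection, e.g. the sema domain) and symmetrises by
#' averaging `D(i,j)` and `D(j,i)`.
#'
#' @param models Named list of `structure_model`s (>= 3).
#' @param selection Selection applied to every model before superposition.
#' @param ... Passed to [match_and_superpose()].
#' @return Symmetric numeric matrix with zero diagonal, labels = model names.
#' @export
build_distance_matrix <- function(models, selection = "all", ...) {
  if (length(models) < 3) stop("need at least 3 models")
  ids <- names(models)
  if (is.null(ids)) stop("models must be named")
  sub <- lapply(models, select_atoms, selection = selection)
  lens <- vapply(sub, function(m) nrow(.ca_table(m)), integer(1))
  k <- length(ids)
  D <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      dij <- tryCatch({
        s1 <- match_and_superpose(sub[[i]], sub[[j]], ...)
        s2 <- match_and_superpose(sub[[j]], sub[[i]], ...)
        (structural_distance(s1, lens[i], lens[j]) +
           structural_distance(s2, lens[j], lens[i])) / 2
      }, error = function(e)
        stop("superposition failed for pair ", ids[i], " / ", ids[j], ": ",
             conditionMessage(e)))
      D[i, j] <- D[j, i] <- dij
    }
  }
  D
}

.check_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3)
    stop("need a square distance matrix with >= 3 labels")
  if (any(!is.finite(d))) stop("non-finite entries in distance matrix")
  d
}

#' Neighbor-joining tree from a distance matrix
#' @param d Symmetric distance matrix with labels.
#' @return An `ape` `phylo` tree (unrooted), branch lengths clamped at 0.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(stats::as.dist(.check_matrix(d)))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' UPGMA tree from a distance matrix
#' @param d Symmetric distance matrix with labels.
#' @return A rooted ultrametric `phylo` tree.
#' @export
upgma_tree <- function(d) {
  phangorn::upgma(stats::as.dist(.check_matrix(d)))
}

#' Newick string for a tree
#' @param tree A `phylo` object.
#' @param digits Branch-length precision.
#' @return Newick string (also writable with [ape::write.tree()]).
#' @export
newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Are the members of each class monophyletic in a tree?
#'
#' Utility for planted-class recovery checks: tests whether every class's
#' members form a clade (checked on the unrooted topology via
#' [ape::is.monophyletic()]).
#'
#' @param tree A `phylo` object.
#' @param class_labels Named vector label -> class for every tip.
#' @return Named logical vector, one entry per class.
#' @export
classes_monophyletic <- function(tree, class_labels) {
  classes <- unique(class_labels[tree$tip.label])
  vapply(classes, function(cl) {
    tips <- names(class_labels)[class_labels == cl]
    ape::is.monophyletic(tree, tips)
  }, logical(1))
}
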