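# Global pairwise alignment (Gotoh affine-gap DP), small progressive MSA,
# percent identity, N-glycosylation sequon scanning, residue chemistry.

.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                  "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.check_seq <- function(s, what = "sequence") {
  if (length(s) != 1 || is.na(s) || nchar(s) == 0)
    stop("empty ", what)
  ch <- strsplit(toupper(s), "")[[1]]
  bad <- setdiff(unique(ch), .AA_ALPHABET)
  if (length(bad))
    stop(what, " contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  ch
}

.default_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# percent identity between two gapped strings: identical aligned pairs over
# gap-free aligned pairs (the package convention); denominator = "columns"
# uses full alignment length instead.
.pair_identity <- function(ga, gb, denominator = "pairs") {
  a <- strsplit(ga, "")[[1]]
  b <- strsplit(gb, "")[[1]]
  both <- a != "-" & b != "-"
  denom <- if (denominator == "columns") length(a) else sum(both)
  if (denom == 0) return(NA_real_)
  100 * sum(a == b & both) / denom
}

.new_alignment <- function(members, denominator = "pairs") {
  lens <- nchar(members)
  stopifnot(length(unique(lens)) == 1)
  ids <- names(members)
  k <- length(members)
  pid <- matrix(100, k, k, dimnames = list(ids, ids))
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      pid[i, j] <- pid[j, i] <- .pair_identity(members[i], members[j],
                                               denominator)
  }
  structure(list(members = members, columns = unname(lens[1]),
                 pairwise_identity = pid),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat("alignment of", length(x$members), "sequence(s),", x$columns,
      "columns\n")
  if (length(x$members) == 2)
    cat(sprintf("  identity: %.1f%%\n", x$pairwise_identity[1, 2]))
  invisible(x)
}

#' Remove gaps from an alignment member
#' @param alignment An alignment object.
#' @param id Member id.
#' @return Ungapped sequence string.
#' @export
degap <- function(alignment, id) gsub("-", "", alignment$members[[id]])

#' Global pairwise alignment with affine gaps (Gotoh)
#'
#' Optimal global alignment under BLOSUM62 (default) with gap cost
#' `gap_open + gap_extend * (L - 1)` for a gap of length L. Identity is
#' counted over gap-free aligned pairs by default.
#'
#' @param seq_a,seq_b Amino-acid sequences (strings, 20 letters plus X).
#' @param substitution_matrix Square scoring matrix with amino-acid
#'   dimnames; default BLOSUM62.
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @param identity_denominator `"pairs"` (gap-free aligned pairs, default)
#'   or `"columns"` (alignment length).
#' @return An alignment object with members `a` and `b`, plus `score`,
#'   `identity` (percent) and `pairs` (2-column matrix of 1-based aligned
#'   positions, 0 = gap).
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = NULL,
                         gap_open = 10, gap_extend = 0.5,
                         identity_denominator = "pairs") {
  ca <- .check_seq(seq_a, "seq_a")
  cb <- .check_seq(seq_b, "seq_b")
  if (is.null(substitution_matrix)) substitution_matrix <- .default_submat()
  if (!all(c(ca, cb) %in% rownames(substitution_matrix)))
    stop("substitution matrix does not cover all sequence letters")
  S <- substitution_matrix[ca, cb, drop = FALSE]
  res <- .gotoh_cpp(S, gap_open, gap_extend)
  ga <- ifelse(res$ai > 0, ca[pmax(res$ai, 1)], "-")
  gb <- ifelse(res$bi > 0, cb[pmax(res$bi, 1)], "-")
  aln <- .new_alignment(c(a = paste(ga, collapse = ""),
                          b = paste(gb, collapse = "")),
                        denominator = identity_denominator)
  aln$score <- res$score
  aln$identity <- aln$pairwise_identity["a", "b"]
  aln$pairs <- cbind(res$ai, res$bi)
  aln
}

#' Progressive multiple sequence alignment
#'
#' Small profile-based progressive MSA: the guide order starts from the most
#' similar pair and grows by descending best identity to the profile, ties
#' broken by lexicographic id; each sequence is added by affine-gap
#' profile-sequence dynamic programming (profile column scored as the mean
#' substitution score over its non-gap letters).
#'
#' @param seqs Named character vector or list of sequences (>= 1).
#' @inheritParams global_align
#' @return An alignment object over all input ids.
#' @export
progressive_msa <- function(seqs, substitution_matrix = NULL,
                            gap_open = 10, gap_extend = 0.5) {
  seqs <- unlist(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(ids == "")) stop("sequences must be named")
  if (length(seqs) == 1) return(.new_alignment(seqs))
  if (is.null(substitution_matrix)) substitution_matrix <- .default_submat()
  if (length(seqs) == 2) {
    aln <- global_align(seqs[1], seqs[2], substitution_matrix,
                        gap_open, gap_extend)
    return(.new_alignment(stats::setNames(aln$members, ids)))
  }
  k <- length(seqs)
  pid <- matrix(0, k, k, dimnames = list(ids, ids))
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    pid[i, j] <- pid[j, i] <-
      global_align(seqs[i], seqs[j], substitution_matrix,
                   gap_open, gap_extend)$identity
  # seed pair: highest identity, id-lexicographic tie-break
  best <- -Inf
  seed <- c(ids[1], ids[2])
  for (i in order(ids)) for (j in order(ids)) {
    if (ids[i] >= ids[j]) next
    if (pid[i, j] > best + 1e-12) {
      best <- pid[i, j]
      seed <- c(ids[i], ids[j])
    }
  }
  aln0 <- global_align(seqs[seed[1]], seqs[seed[2]], substitution_matrix,
                       gap_open, gap_extend)
  profile <- stats::setNames(aln0$members, seed)
  remaining <- setdiff(ids, seed)
  while (length(remaining)) {
    sc <- vapply(remaining,
                 function(id) max(pid[id, names(profile)]), numeric(1))
    nxt <- remaining[order(-sc, remaining)][1]
    profile <- .profile_add(profile, seqs[[nxt]], nxt, substitution_matrix,
                            gap_open, gap_extend)
    remaining <- setdiff(remaining, nxt)
  }
  .new_alignment(profile[ids])
}

# Align one sequence to a gapped profile and return the grown profile.
.profile_add <- function(profile, seq, id, submat, gap_open, gap_extend) {
  cols <- do.call(rbind, strsplit(unname(profile), ""))  # members x columns
  ch <- .check_seq(seq)
  nc <- ncol(cols)
  # expected substitution score of each profile column against each letter
  letters_used <- unique(ch)
  colscore <- matrix(0, nc, length(letters_used),
                     dimnames = list(NULL, letters_used))
  for (a in letters_used) {
    s <- submat[, a]
    colscore[, a] <- apply(cols, 2, function(cc) {
      ng <- cc[cc != "-"]
      if (!length(ng)) 0 else sum(s[ng]) / nrow(cols)
    })
  }
  S <- colscore[, ch, drop = FALSE]   # columns x seq positions
  res <- .gotoh_cpp(S, gap_open, gap_extend)
  grown <- matrix("-", nrow(cols) + 1, length(res$ai))
  for (t in seq_along(res$ai)) {
    if (res$ai[t] > 0) grown[seq_len(nrow(cols)), t] <- cols[, res$ai[t]]
    if (res$bi[t] > 0) grown[nrow(cols) + 1, t] <- ch[res$bi[t]]
  }
  out <- apply(grown, 1, paste, collapse = "")
  stats::setNames(out, c(names(profile), id))
}

#' Scan a sequence for N-glycosylation sequons
#'
#' Finds every N-X-S/T motif with X != P (the sequon marking a potential
#' N-linked glycosylation site), including overlapping occurrences.
#'
#' @param seq Amino-acid sequence string.
#' @param range Optional inclusive `c(lo, hi)` positions (in the protein's
#'   own numbering) restricting where the Asn may sit.
#' @param numbering_start Number of the first residue of `seq` (author /
#'   construct numbering; default 1).
#' @return data.frame with `position` (Asn position) and `triplet`.
#' @export
sequon_scan <- function(seq, range = NULL, numbering_start = 1) {
  ch <- .check_seq(seq)
  n <- length(ch)
  pos <- integer(0)
  if (n >= 3) {
    i <- 1:(n - 2)
    hit <- ch[i] == "N" & ch[i + 1] != "P" & ch[i + 2] %in% c("S", "T")
    pos <- i[hit]
  }
  out_pos <- pos + numbering_start - 1L
  if (!is.null(range)) {
    keep <- out_pos >= range[1] & out_pos <= range[2]
    pos <- pos[keep]
    out_pos <- out_pos[keep]
  }
  data.frame(position = out_pos,
             triplet = vapply(pos, function(p)
               paste(ch[p:(p + 2)], collapse = ""), character(1)))
}

#' Chemistry class of an amino acid
#'
#' Fixed five-class partition of the 20-letter alphabet used for hot-spot
#' chemistry comparisons: hydrophobic `AVLIMFWY`, polar `STNQCH`,
#' positively charged `KR`, negatively charged `DE`, special `GP`.
#' Histidine sits in the polar class (near-neutral at physiological pH);
#' override via `reclassify`.
#'
#' @param aa One-letter amino-acid code (vectorised).
#' @param reclassify Optional named character vector of overrides,
#'   e.g. `c(H = "positively_charged")`.
#' @return Character vector of chemistry classes.
#' @export
residue_chemistry <- function(aa, reclassify = NULL) {
  tab <- c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
           I = "hydrophobic", M = "hydrophobic", F = "hydrophobic",
           W = "hydrophobic", Y = "hydrophobic",
           S = "polar", T = "polar", N = "polar", Q = "polar",
           C = "polar", H = "polar",
           K = "positively_charged", R = "positively_charged",
           D = "negatively_charged", E = "negatively_charged",
           G = "special", P = "special")
  if (!is.null(reclassify)) tab[names(reclassify)] <- reclassify
  aa <- toupper(aa)
  if (any(!aa %in% names(tab)))
    stop("unknown amino-acid letter: ",
         paste(setdiff(aa, names(tab)), collapse = ", "))
  unname(tab[aa])
}

# FASTA I/O --------------------------------------------------------------------

#' Read sequences from a FASTA file
#' @param path FASTA file path.
#' @return Named character vector of (upper-case) sequences.
#' @export
read_fasta <- function(path) {
  xs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  stats::setNames(toupper(unlist(xs)), names(xs))
}

#' Write sequences (or an alignment) to FASTA
#' @param seqs Named character vector, or an alignment object (members are
#'   written gapped, i.e. aligned FASTA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "msa_alignment")) seqs <- seqs$members
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path)
  invisible(path)
}
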