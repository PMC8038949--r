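AA_AMBIGUOUS <- c("X", "B", "Z")

split_seq <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Pairwise percent sequence identity
#'
#' In `"aligned"` mode the two sequences must be the same length (rows of
#' an alignment): identity is the number of identical residue pairs over
#' the columns where both sequences are non-gap, as a percentage.
#' Ambiguous residues (X/B/Z) are excluded from the denominator. In
#' `"global_align"` mode the sequences are first globally aligned
#' (Needleman-Wunsch via Biostrings, match +1, mismatch 0, linear gap -1
#' by default) and identity is computed the same way on the alignment.
#'
#' @param seq_a,seq_b Protein sequences (single strings;
#'   case-insensitive, `-` is the gap character).
#' @param mode `"aligned"` or `"global_align"`.
#' @param match,mismatch,gap Alignment scores for `"global_align"`.
#' @return Percent identity in `[0, 100]`; symmetric in its arguments.
#' @examples
#' percent_identity("ACDEF", "ACDFF")  # 80
#' @export
percent_identity <- function(seq_a, seq_b,
                             mode = c("aligned", "global_align"),
                             match = 1, mismatch = 0, gap = -1) {
  mode <- match.arg(mode)
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("Empty sequence.")
  if (mode == "global_align") {
    alphabet <- unique(c(AA20, AA_AMBIGUOUS, "U", "O", "*"))
    mat <- matrix(mismatch, length(alphabet), length(alphabet),
                  dimnames = list(alphabet, alphabet))
    diag(mat) <- match
    al <- Biostrings::pairwiseAlignment(
      toupper(seq_a), toupper(seq_b), type = "global",
      substitutionMatrix = mat, gapOpening = 0, gapExtension = -gap)
    seq_a <- as.character(Biostrings::alignedPattern(al))
    seq_b <- as.character(Biostrings::alignedSubject(al))
  }
  a <- split_seq(seq_a); b <- split_seq(seq_b)
  if (length(a) != length(b)) {
    abort("Aligned mode requires equal-length sequences.")
  }
  both <- a != "-" & b != "-" &
    !(a %in% AA_AMBIGUOUS) & !(b %in% AA_AMBIGUOUS)
  if (!any(both)) abort("No comparable (both non-gap) columns.")
  100 * sum(a[both] == b[both]) / sum(both)
}

as_alignment_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (is.matrix(alignment)) {
    m <- toupper(alignment)
  } else {
    if (is.null(names(alignment))) {
      names(alignment) <- paste0("seq", seq_along(alignment))
    }
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) {
      abort("Alignment rows must all have the same length.")
    }
    m <- do.call(rbind, lapply(alignment, split_seq))
    rownames(m) <- names(alignment)
  }
  if (anyDuplicated(rownames(m))) abort("Sequence ids must be unique.")
  m
}

#' Pairwise p-distance matrix from a protein alignment
#'
#' The p-distance between two rows is the fraction of differing sites
#' over the columns where both are non-gap and unambiguous (pairwise
#' deletion). Errors if a pair shares no comparable column.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, a character matrix, or an `AAStringSet`.
#' @return A symmetric matrix with zero diagonal, entries in `[0, 1]`,
#'   dimnames = sequence ids.
#' @export
p_distance <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) abort("Need at least two sequences.")
  ok <- m != "-" & !(m %in% AA_AMBIGUOUS)
  dim(ok) <- dim(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        abort(sprintf("No comparable columns between %s and %s.",
                      rownames(m)[i], rownames(m)[j]))
      }
      d[i, j] <- d[j, i] <- sum(m[i, comp] != m[j, comp]) / sum(comp)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' The Saitou-Nei agglomerative algorithm with the standard Q-criterion.
#' Determinism rules: ties in Q (within 1e-12) are broken by the lowest
#' index pair in the current working matrix; a negative branch length at a
#' join is clamped to zero with the deficit transferred to the sister
#' branch created at the same join (and, at the final three-way join, to
#' the longest of the other two branches), preserving path lengths.
#'
#' @param dm Symmetric distance matrix with dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree with branch lengths in the units
#'   of `dm`. On an additive matrix the generating topology and branch
#'   lengths are recovered exactly.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    abort("`dm` must be a square matrix.")
  }
  if (max(abs(dm - t(dm))) > 1e-8) abort("`dm` must be symmetric.")
  n <- nrow(dm)
  if (n < 3L) abort("Need at least 3 taxa.")
  labs <- rownames(dm) %||% paste0("t", seq_len(n))
  # each working taxon is a newick fragment (no trailing length)
  frag <- labs
  d <- (dm + t(dm)) / 2
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  while (length(frag) > 3L) {
    nn <- length(frag)
    rs <- rowSums(d)
    q <- (nn - 2) * d - outer(rs, rs, `+`)
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (nn - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0; li <- max(li, 0) }
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(nn), c(i, j))
    d_new <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                   c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d_new
  }
  # final three-way join
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ln <- c(a, b, c3)
  for (k in which(ln < 0)) {
    others <- setdiff(1:3, k)
    tgt <- others[which.max(ln[others])]
    ln[tgt] <- ln[tgt] + ln[k]
    ln[k] <- 0
  }
  ln <- pmax(ln, 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(ln[1]), frag[2], fmt(ln[2]),
                 frag[3], fmt(ln[3]))
  ape::read.tree(text = nwk)
}

#' Bootstrap supports for the neighbor-joining tree of an alignment
#'
#' Builds the full-data NJ tree on p-distances, then resamples alignment
#' columns with replacement `replicates` times, rebuilds the NJ tree for
#' each replicate, and scores every internal branch of the full tree by
#' the percentage of replicate trees containing the same bipartition.
#' Supports are stored in `node.label`. If the alignment carries no
#' resolved signal (all pairwise distances zero) the tree is returned with
#' `NA` supports and a warning.
#'
#' @param alignment As in [p_distance()].
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (column resampling is seed-deterministic).
#' @return The full-data `phylo` tree with `node.label` percentages and
#'   attribute `replicates`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000, seed = 1L) {
  m <- as_alignment_matrix(alignment)
  check_number(replicates, "replicates", lower = 1)
  full <- neighbor_joining(p_distance(m))
  if (all(p_distance(m) == 0)) {
    warn("All sequences identical: no resolved bipartitions.")
    full$node.label <- rep(NA_character_, full$Nnode)
    attr(full, "replicates") <- replicates
    return(full)
  }
  reps <- with_seed(seed, {
    lapply(seq_len(replicates), function(b) {
      cols <- sample.int(ncol(m), replace = TRUE)
      tryCatch(neighbor_joining(p_distance(m[, cols, drop = FALSE])),
               error = function(e) {
                 abort(sprintf("Replicate %d failed: %s", b,
                               conditionMessage(e)))
               })
    })
  })
  counts <- ape::prop.clades(full, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.character(round(100 * counts / replicates))
  attr(full, "replicates") <- replicates
  full
}

#' Write a tree as Newick text
#'
#' Branch lengths are written in full precision; internal-node bootstrap
#' supports (when present in `node.label`) appear as internal labels, the
#' convention read back by `ape::read.tree()`.
#'
#' @param tree An `ape::phylo`.
#' @param path Optional file; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around `Biostrings::readAAStringSet()` returning a named
#' character vector (the alignment container used across the package).
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
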