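## Marker-gene phylogeny stage: protein p-distances from a curated multiple
## alignment (pairwise gap deletion), neighbor-joining, and bootstrap support
## with a 50% display threshold. The alignment itself is an input (the
## curation/MSA step is upstream of this pipeline).

#' Coerce an alignment to a character matrix
#'
#' Accepts a named character vector of equal-length aligned sequences, an
#' `AAStringSet`, or an already-split character matrix.
#' @keywords internal
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (methods::is(alignment, "XStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  stopifnot(is.character(alignment))
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have equal length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment) %||% paste0("t", seq_len(nrow(m)))
  m
}

#' Read an aligned protein FASTA
#'
#' @param path Aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}

#' Pairwise p-distance matrix with pairwise gap deletion
#'
#' `D[i, j]` is the proportion of mismatching positions among columns where
#' neither sequence has a gap (`-` or `.`). A pair with zero comparable
#' columns is an error.
#'
#' @param alignment Aligned sequences (see [alignment_matrix()]).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  gap <- m == "-" | m == "."
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop(sprintf("no comparable columns between %s and %s",
                     rownames(m)[i], rownames(m)[j]), call. = FALSE)
      }
      d <- mean(m[i, ok] != m[j, ok])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero and flagged in the `clamped` attribute.
#'
#' @param D Symmetric distance matrix, >= 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-12) || any(diag(D) != 0) || any(D < 0)) {
    stop("D must be symmetric and nonnegative with zero diagonal",
         call. = FALSE)
  }
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_reps` times, recomputes
#' the p-distance + NJ tree per replicate, and counts how often each
#' internal split of the reference tree recurs. Supports below
#' `display_threshold` percent are blanked in the display newick but kept in
#' the support table. Reproducible given `seed`.
#'
#' @param alignment Aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Optional RNG seed.
#' @param display_threshold Percent threshold for showing supports
#'   (default 50).
#' @param outgroup Optional taxon label used to root the display tree.
#' @return List: `tree` (reference NJ tree with `node.label` = support %),
#'   `supports` (tibble: node, support_pct, shown), `newick` (display
#'   string with sub-threshold supports suppressed).
#' @export
bootstrap_support <- function(alignment, n_reps = 100L, seed = NULL,
                              display_threshold = 50,
                              outgroup = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  m <- alignment_matrix(alignment)
  if (!is.null(seed)) set.seed(seed)
  ref <- nj_tree(pdistance_matrix(m))
  reps <- lapply(seq_len(n_reps), function(r) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    nj_tree(pdistance_matrix(m[, cols, drop = FALSE]))
  })
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  shown <- support >= display_threshold
  disp <- ref
  disp$node.label <- ifelse(shown, format(round_half_up(support), trim = TRUE),
                            "")
  if (!is.null(outgroup)) {
    disp <- ape::root(disp, outgroup = outgroup, resolve.root = TRUE)
  }
  ref$node.label <- format(round_half_up(support), trim = TRUE)
  list(
    tree = ref,
    supports = tibble::tibble(node = ape::Ntip(ref) + seq_along(support),
                              support_pct = support, shown = shown),
    newick = ape::write.tree(disp)
  )
}
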