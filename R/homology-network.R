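## Prophage-prophage homology network from all-vs-all ORF alignments,
## annotation confidence tiers, remnant classification, lifecycle/structural
## keyword census, and k-word dotplot synteny.

#' Map an ORF identifier to its prophage
#'
#' ORF ids follow the `prophage_id:orf_index` convention; everything before
#' the last `:` is the prophage.
#'
#' @param orf_id Character vector of ORF ids.
#' @return Character vector of prophage ids.
#' @export
orf_prophage <- function(orf_id) {
  bad <- !grepl(":", orf_id, fixed = TRUE)
  if (any(bad)) {
    stop("ORF id(s) not in prophage:orf form: ",
         paste(head(orf_id[bad], 5L), collapse = ", "), call. = FALSE)
  }
  sub(":[^:]*$", "", orf_id)
}

#' Define homolog pairs from raw alignment hits
#'
#' A hit qualifies as a homolog when percent identity >= `min_identity`
#' (inclusive), e-value <= `max_evalue` (inclusive) and alignment length
#' strictly exceeds 20 residues (i.e. >= `min_alen` = 21). Self-hits are
#' dropped, reciprocal duplicates are collapsed to one undirected pair, and
#' pairs whose two ORFs sit on the same prophage are retained but flagged
#' `internal` (they never contribute graph edges).
#'
#' @param hits Tibble from [read_homology_hits()].
#' @param min_identity Inclusive percent-identity threshold (default 30).
#' @param max_evalue Inclusive e-value threshold (default 1e-4).
#' @param min_alen Minimum alignment length kept (default 21, i.e. > 20).
#' @param known_prophages Optional character vector; ORFs mapping elsewhere
#'   raise an error.
#' @return Tibble of undirected homolog pairs: `orf1, orf2, prophage1,
#'   prophage2, internal`, with `orf1 < orf2` lexicographically.
#' @export
filter_homologs <- function(hits, min_identity = 30, max_evalue = 1e-4,
                            min_alen = 21L, known_prophages = NULL) {
  keep <- hits$pct_identity >= min_identity & hits$evalue <= max_evalue &
    hits$aln_length >= min_alen & hits$query_orf != hits$subject_orf
  h <- hits[keep, , drop = FALSE]
  orf1 <- pmin(h$query_orf, h$subject_orf)
  orf2 <- pmax(h$query_orf, h$subject_orf)
  dup <- duplicated(paste(orf1, orf2, sep = "\r"))
  out <- tibble::tibble(orf1 = orf1[!dup], orf2 = orf2[!dup])
  out$prophage1 <- orf_prophage(out$orf1)
  out$prophage2 <- orf_prophage(out$orf2)
  if (!is.null(known_prophages)) {
    unknown <- setdiff(unique(c(out$prophage1, out$prophage2)),
                       known_prophages)
    if (length(unknown) > 0L) {
      stop("ORF maps to unknown prophage(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out$internal <- out$prophage1 == out$prophage2
  out
}

#' Annotation confidence tier for a hit
#'
#' High confidence requires both e-value < 1e-4 and alignment length > 100;
#' everything else is low (the complement).
#'
#' @param evalue,aln_length Numeric vectors.
#' @return Character vector, `"high"` or `"low"`.
#' @export
annotate_confidence <- function(evalue, aln_length) {
  ifelse(evalue < 1e-4 & aln_length > 100, "high", "low")
}

#' Build the prophage homology graph
#'
#' Nodes are prophages; an undirected edge's weight is the number of distinct
#' homologous ORF pairs between the two prophages. Edges with weight >= 10
#' are `significant`, the rest `weak`. Per-node homolog counts (total pairs
#' summed over partners, and distinct ORFs with >= 1 external partner) are
#' attached as vertex attributes.
#'
#' @param pairs Homolog pairs from [filter_homologs()]; internal pairs are
#'   excluded from edges.
#' @param nodes Optional tibble with `prophage_id` and extra attributes
#'   (e.g. `strain_id`, `virfam_label`) to seed isolated nodes too.
#' @return An igraph graph with vertex attributes `homolog_pairs` and
#'   `homolog_orfs`, edge attributes `weight` and `edge_class`.
#' @export
build_prophage_graph <- function(pairs, nodes = NULL) {
  ext <- pairs[!pairs$internal, , drop = FALSE]
  p1 <- pmin(ext$prophage1, ext$prophage2)
  p2 <- pmax(ext$prophage1, ext$prophage2)
  key <- paste(p1, p2, sep = "\r")
  w <- as.integer(table(key))
  uk <- names(table(key))
  edges <- tibble::tibble(
    from = sub("\r.*$", "", uk),
    to = sub("^.*\r", "", uk),
    weight = w,
    edge_class = ifelse(w >= 10L, "significant", "weak")
  )
  ids <- unique(c(pairs$prophage1, pairs$prophage2, edges$from, edges$to))
  if (!is.null(nodes)) ids <- unique(c(nodes$prophage_id, ids))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  # per-node totals over external pairs
  pair_count <- setNames(integer(length(ids)), ids)
  orf_count <- setNames(integer(length(ids)), ids)
  if (nrow(ext) > 0L) {
    tp <- table(c(ext$prophage1, ext$prophage2))
    pair_count[names(tp)] <- as.integer(tp)
    orfs <- unique(rbind(data.frame(p = ext$prophage1, o = ext$orf1),
                         data.frame(p = ext$prophage2, o = ext$orf2)))
    to <- table(orfs$p)
    orf_count[names(to)] <- as.integer(to)
  }
  igraph::V(g)$homolog_pairs <- unname(pair_count[igraph::V(g)$name])
  igraph::V(g)$homolog_orfs <- unname(orf_count[igraph::V(g)$name])
  if (!is.null(nodes)) {
    for (col in setdiff(names(nodes), "prophage_id")) {
      v <- setNames(nodes[[col]], nodes$prophage_id)
      igraph::vertex_attr(g, col) <- unname(v[igraph::V(g)$name])
    }
  }
  g
}

#' Per-node summary table of the homology graph
#'
#' @param graph From [build_prophage_graph()].
#' @return Tibble: `prophage_id, homolog_pairs, homolog_orfs` plus any extra
#'   vertex attributes.
#' @export
graph_node_table <- function(graph) {
  at <- igraph::vertex_attr(graph)
  out <- tibble::as_tibble(at)
  names(out)[names(out) == "name"] <- "prophage_id"
  out
}

#' Flag prophage-remnant candidates
#'
#' A candidate is a prophage left unclassified by the structural-module
#' classifier that also shares fewer than 10 homologous protein pairs with
#' the rest of the community - the signature of remnants, satellite viruses
#' or isolated phage genes. A missing taxonomic label counts as
#' `"unassigned"`, not `"unclassified"`.
#'
#' @param virfam_label Character vector of taxonomic labels.
#' @param homolog_count Total homolog pairs per prophage.
#' @return Logical vector.
#' @export
classify_remnant <- function(virfam_label, homolog_count) {
  lab <- ifelse(is.na(virfam_label), "unassigned", virfam_label)
  lab == "unclassified" & homolog_count < 10L
}

#' Lifecycle and structural keyword census of ORF annotations
#'
#' Case-insensitive whole-word matching of the lifecycle markers (terminase,
#' integrase, nuclease, transposase, DNA primase, lysin) and structural
#' markers (portal, head, capsid, tail, coat, baseplate) in free-text
#' annotations; one annotation may hit several keywords. Whole-word
#' boundaries prevent collisions like "overhead" matching "head".
#'
#' @param annotations Character vector of product annotations (possibly
#'   `"hypothetical protein"`).
#' @return List with `lifecycle` and `structural` named count vectors and
#'   `hypothetical_fraction`.
#' @export
keyword_census <- function(annotations) {
  lifecycle_kw <- c("terminase", "integrase", "nuclease", "transposase",
                    "DNA primase", "lysin")
  structural_kw <- c("portal", "head", "capsid", "tail", "coat", "baseplate")
  count_kw <- function(kws) {
    vapply(kws, function(k) {
      pat <- paste0("\\b", gsub(" ", "[ ]", k), "\\b")
      sum(grepl(pat, annotations, ignore.case = TRUE, perl = TRUE))
    }, integer(1))
  }
  list(
    lifecycle = count_kw(lifecycle_kw),
    structural = count_kw(structural_kw),
    hypothetical_fraction = if (length(annotations) == 0L) 0 else
      mean(grepl("\\bhypothetical\\b", annotations, ignore.case = TRUE,
                 perl = TRUE))
  )
}

#' k-word dotplot between two DNA sequences
#'
#' Exact word matching of all `word_size`-mers; positions are 0-based.
#' Words containing `N` never match. Reverse-complement matches are computed
#' against the reverse complement of `seq2` and reported in `seq2` forward
#' coordinates (the position of the leftmost base of the matched window on
#' the forward strand).
#'
#' @param seq1,seq2 DNA strings over `{A,C,G,T,N}` (case-insensitive).
#' @param word_size Word length k, 4 <= k <= min sequence length.
#' @param strand `"forward"`, `"revcomp"` or `"both"`.
#' @return Tibble of matches: `i` (position in seq1), `j` (position in seq2),
#'   `strand`.
#' @export
dotplot <- function(seq1, seq2, word_size = 10L,
                    strand = c("both", "forward", "revcomp")) {
  strand <- match.arg(strand)
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (word_size < 4L || word_size > min(n1, n2)) {
    stop("word_size must be in [4, min(|seq1|, |seq2|)]", call. = FALSE)
  }
  words_of <- function(s) {
    n <- nchar(s)
    substring(s, 1:(n - word_size + 1L), word_size:n)
  }
  match_words <- function(w1, w2) {
    ok1 <- !grepl("N", w1, fixed = TRUE)
    ok2 <- !grepl("N", w2, fixed = TRUE)
    shared <- intersect(w1[ok1], w2[ok2])
    if (length(shared) == 0L) {
      return(tibble::tibble(i = integer(), j = integer()))
    }
    idx1 <- split(which(ok1), w1[ok1])
    idx2 <- split(which(ok2), w2[ok2])
    dplyr::bind_rows(lapply(shared, function(w) {
      expand.grid(i = idx1[[w]] - 1L, j = idx2[[w]] - 1L)  # 0-based
    }))
  }
  w1 <- words_of(seq1)
  out <- list()
  if (strand %in% c("both", "forward")) {
    m <- match_words(w1, words_of(seq2))
    if (nrow(m) > 0L) m$strand <- "forward"
    out$fwd <- m
  }
  if (strand %in% c("both", "revcomp")) {
    rc2 <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gsub("[^ACGTN]", "N", seq2))))
    m <- match_words(w1, words_of(rc2))
    if (nrow(m) > 0L) {
      # position j on the rc strand starts at forward coordinate
      # n2 - word_size - j (leftmost base of the window, 0-based)
      m$j <- n2 - word_size - m$j
      m$strand <- "revcomp"
    }
    out$rev <- m
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(i = integer(), j = integer(), strand = character())
  }
  res[order(res$i, res$j), , drop = FALSE]
}

#' Export graph edges as a Circos-style link table
#'
#' @param graph From [build_prophage_graph()].
#' @param calls Prophage calls providing `start`/`end` per prophage.
#' @return Tibble: `prophage_id, start, end, partner, weight, edge_class`.
#' @export
link_table <- function(graph, calls) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(ed) == 0L) {
    return(tibble::tibble(prophage_id = character(), start = integer(),
                          end = integer(), partner = character(),
                          weight = integer(), edge_class = character()))
  }
  pos <- calls[match(ed$from, calls$prophage_id), c("start", "end")]
  tibble::tibble(prophage_id = ed$from, start = pos$start, end = pos$end,
                 partner = ed$to, weight = ed$weight,
                 edge_class = ed$edge_class)
}
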