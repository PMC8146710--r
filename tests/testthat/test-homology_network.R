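mk_hit <- function(q, s, ident = 50, alen = 100L, ev = 1e-20) {
  tibble::tibble(query_orf = q, subject_orf = s, pct_identity = ident,
                 aln_length = as.integer(alen), evalue = ev, bitscore = 100)
}

test_that("homolog filter applies inclusive identity/e-value and alen > 20", {
  hits <- dplyr::bind_rows(
    mk_hit("p1:1", "p2:1", ident = 30.0, alen = 25, ev = 1e-4),  # kept
    mk_hit("p1:2", "p2:2", ident = 45, alen = 20, ev = 1e-30),   # alen
    mk_hit("p1:3", "p2:3", ident = 29.9, alen = 100),            # identity
    mk_hit("p1:4", "p2:4", ident = 45, alen = 100, ev = 2e-4),   # e-value
    mk_hit("p1:5", "p1:5"),                                      # self
    mk_hit("p1:6", "p1:7")                                       # internal
  )
  f <- filter_homologs(hits)
  expect_equal(nrow(f), 2L)
  expect_equal(sort(f$orf1), c("p1:1", "p1:6"))
  expect_true(f$internal[f$orf1 == "p1:6"])
  expect_false(f$internal[f$orf1 == "p1:1"])
})

test_that("homolog pairs are invariant to row order and hit orientation", {
  set.seed(3)
  fwd <- dplyr::bind_rows(lapply(1:15, function(i) {
    mk_hit(sprintf("p1:%d", i), sprintf("p2:%d", i))
  }))
  rev <- fwd
  rev$query_orf <- fwd$subject_orf
  rev$subject_orf <- fwd$query_orf
  both <- dplyr::bind_rows(fwd, rev)[sample(30), ]
  f1 <- filter_homologs(fwd)
  f2 <- filter_homologs(both)
  key <- function(f) sort(paste(f$orf1, f$orf2))
  expect_equal(key(f1), key(f2))
  expect_equal(nrow(f2), 15L)  # reciprocal duplicates collapsed
})

test_that("unmapped ORFs raise an error", {
  expect_error(filter_homologs(mk_hit("plain_orf", "p2:1")), "prophage:orf")
  expect_error(filter_homologs(mk_hit("p9:1", "p2:1"),
                               known_prophages = c("p1", "p2")),
               "unknown prophage")
})

test_that("annotation confidence needs both a strong e-value and a long alignment", {
  expect_equal(annotate_confidence(c(1e-5, 1e-3, 1e-5, 1e-4),
                                   c(150, 150, 50, 150)),
               c("high", "low", "low", "low"))
})

test_that("graph edges weight distinct pairs and threshold at 10", {
  pairs10 <- filter_homologs(dplyr::bind_rows(lapply(1:10, function(i) {
    mk_hit(sprintf("pA:%d", i), sprintf("pB:%d", i))
  })))
  g <- build_prophage_graph(pairs10)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$weight, 10L)
  expect_equal(ed$edge_class, "significant")

  pairs1 <- filter_homologs(mk_hit("pA:1", "pB:1"))
  g1 <- build_prophage_graph(pairs1)
  expect_equal(igraph::E(g1)$edge_class, "weak")

  # internal pairs contribute no edges
  internal <- filter_homologs(mk_hit("pA:1", "pA:2"))
  g0 <- build_prophage_graph(internal)
  expect_equal(igraph::ecount(g0), 0L)

  nt <- graph_node_table(g)
  expect_equal(sort(nt$homolog_pairs), c(10L, 10L))
  expect_equal(sort(nt$homolog_orfs), c(10L, 10L))
})

test_that("significant components recover planted clusters", {
  cfg <- sim_config(n_clusters = 2L, within_pairs = 12L, between_pairs = 2L)
  ids <- paste0("p", 1:8)
  sim <- simulate_homology_hits(ids, cfg, seed = 21)
  pairs <- filter_homologs(sim$hits)
  g <- build_prophage_graph(pairs)
  sig <- igraph::subgraph_from_edges(
    g, igraph::E(g)[igraph::E(g)$edge_class == "significant"],
    delete.vertices = FALSE)
  comp <- igraph::components(sig)$membership
  split_got <- split(names(comp), comp)
  split_want <- split(names(sim$clusters), sim$clusters)
  norm <- function(l) unname(lapply(l, sort))[order(vapply(lapply(l, sort),
                                                           `[`, "", 1L))]
  expect_equal(norm(split_got), norm(split_want))

  # below-threshold cluster spec yields no significant edges
  sim9 <- simulate_homology_hits(ids, sim_config(within_pairs = 9L), seed = 2)
  g9 <- build_prophage_graph(filter_homologs(sim9$hits))
  expect_true(all(igraph::E(g9)$edge_class == "weak"))
})

test_that("remnant candidates are unclassified with < 10 homologs", {
  expect_equal(
    classify_remnant(c("unclassified", "Myoviridae", "unclassified", NA),
                     c(3, 3, 15, 2)),
    c(TRUE, FALSE, FALSE, FALSE))
})

test_that("keyword census counts whole words case-insensitively", {
  ann <- c("phage Terminase large subunit", "hypothetical protein",
           "tail fiber protein", "overhead crane protein",
           "DNA primase/helicase")
  kc <- keyword_census(ann)
  expect_equal(kc$lifecycle[["terminase"]], 1L)
  expect_equal(kc$lifecycle[["DNA primase"]], 1L)
  expect_equal(kc$structural[["tail"]], 1L)
  expect_equal(kc$structural[["head"]], 0L)  # 'overhead' must not match
  expect_equal(kc$hypothetical_fraction, 1 / 5)
  k0 <- keyword_census(character())
  expect_true(all(k0$lifecycle == 0L))
  expect_equal(k0$hypothetical_fraction, 0)
})

test_that("dotplot finds diagonals, antidiagonals, and nothing in noise", {
  set.seed(8)
  s1 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  d <- dotplot(s1, s1, word_size = 10, strand = "forward")
  expect_true(all(d$i == d$j | d$i != d$j))      # contains the diagonal:
  expect_true(all(seq(0, 290) %in% d$i[d$i == d$j]))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s1)))
  dr <- dotplot(s1, rc, word_size = 10, strand = "revcomp")
  # antidiagonal in forward coordinates: j = n - k - i
  anti <- dr[dr$j == 300 - 10 - dr$i, ]
  expect_true(all(seq(0, 290) %in% anti$i))

  s2 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  s3 <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  expect_equal(nrow(dotplot(s2, s3, word_size = 12, strand = "forward")), 0L)

  # words containing N never match
  expect_equal(nrow(dotplot("AAAANAAAAA", "AAAANAAAAA", word_size = 10)), 0L)
  expect_error(dotplot(s2, s3, word_size = 3), "word_size")
  expect_error(dotplot("ACGT", "ACGT", word_size = 5), "word_size")
})
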