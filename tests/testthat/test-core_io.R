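test_that("interval dialects normalize to 0-based half-open coordinates", {
  tmp <- withr::local_tempdir()
  bed <- file.path(tmp, "a.bed")
  writeLines("repA\t0\t100", bed)
  rec <- read_intervals(bed, "bed", detector = "A", strain_id = "s1")
  expect_equal(rec$start, 0L)
  expect_equal(rec$end, 100L)
  expect_equal(rec$end - rec$start, 100L)

  gff <- file.path(tmp, "a.gff3")
  writeLines(c("##gff-version 3",
               "repA\tdet\tprophage\t1\t100\t.\t+\t.\tID=p1"), gff)
  rec2 <- read_intervals(gff, "gff3", detector = "B", strain_id = "s1")
  expect_equal(rec2$start, 0L)
  expect_equal(rec2$end, 100L)

  tsv <- file.path(tmp, "a.tsv")
  writeLines(c("strain_id\treplicon_id\tstart\tend", "s1\trepA\t1\t100"), tsv)
  rec3 <- read_intervals(tsv, "tsv1based", detector = "A")
  expect_equal(rec3$start, 0L)
  expect_equal(rec3$end, 100L)
})

test_that("invalid intervals are rejected with a validation error", {
  tmp <- withr::local_tempdir()
  tsv <- file.path(tmp, "bad.tsv")
  writeLines(c("strain_id\treplicon_id\tstart\tend", "s1\trepA\t500\t400"),
             tsv)
  expect_error(read_intervals(tsv, "tsv1based", detector = "A"),
               "start < end")
})

test_that("tsv round-trip is identity and 1-based conversion is an involution", {
  tmp <- withr::local_tempdir()
  set.seed(11)
  x <- tibble::tibble(
    strain_id = sample(c("s1", "s2"), 20, TRUE),
    replicon_id = sample(c("chr", "p1"), 20, TRUE),
    detector = "A",
    start = sample.int(1e6, 20),
    end = NA_integer_)
  x$end <- x$start + sample.int(5e4, 20)
  x <- x[order(x$strain_id, x$replicon_id, x$start), ]
  p <- file.path(tmp, "rt.tsv")
  write_intervals_tsv1based(x, p)
  y <- read_intervals(p, "tsv1based", detector = "A")
  expect_equal(y[, c("strain_id", "replicon_id", "start", "end")],
               x[, c("strain_id", "replicon_id", "start", "end")])
  # involution on raw integers
  s1 <- 12345L
  expect_identical(((s1 - 1L) + 1L), s1)
})

test_that("bed round-trip preserves intervals", {
  tmp <- withr::local_tempdir()
  x <- tibble::tibble(strain_id = "s1", replicon_id = "chr", detector = "A",
                      start = c(0L, 5000L), end = c(100L, 9000L))
  p <- file.path(tmp, "rt.bed")
  write_intervals_bed(x, p)
  y <- read_intervals(p, "bed", detector = "A", strain_id = "s1")
  expect_equal(y$start, x$start)
  expect_equal(y$end, x$end)
})

test_that("homology hit reader maps the 12-column tabular layout", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "hits.tsv")
  writeLines(paste("p1:3", "p2:7", "45.2", "210", "5", "1", "1", "210",
                   "3", "212", "1e-30", "150", sep = "\t"), p)
  h <- read_homology_hits(p)
  expect_equal(h$query_orf, "p1:3")
  expect_equal(h$pct_identity, 45.2)
  expect_equal(h$aln_length, 210L)
  expect_equal(h$evalue, 1e-30)

  bad <- file.path(tmp, "bad.tsv")
  writeLines(paste("p1:3", "p2:7", "101.0", "210", "5", "1", "1", "210",
                   "3", "212", "1e-30", "150", sep = "\t"), bad)
  expect_error(read_homology_hits(bad), "pident")

  empty <- file.path(tmp, "empty.tsv")
  file.create(empty)
  expect_warning(h0 <- read_homology_hits(empty), "empty")
  expect_equal(nrow(h0), 0L)
})

test_that("trait reader derives growth class and validates vocabulary", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "traits.tsv")
  writeLines(c(
    "strain_id\tfamily\thabitat\tgenome_bp\tgc_pct\tdoubling_h\tgrowth_class",
    "s1\tDesulfovibrionaceae\tfreshwater\t3600000\t55\t6\t",
    "s2\tDesulfovibrionaceae\tmarine\t4100000\t48\t12\t",
    "s3\tPeptococcaceae\tsoil\t3900000\t45\t30\t"), p)
  tr <- read_trait_table(p)
  expect_equal(tr$growth_class, c("fast", "fast", "slow"))  # <=12 h is fast

  bad <- file.path(tmp, "bad.tsv")
  writeLines(c("strain_id\tfamily\thabitat\tgenome_bp\tgc_pct",
               "s1\tX\tocean\t3600000\t55"), bad)
  expect_error(read_trait_table(bad), "freshwater, brackish, marine")
})

test_that("crispr table reader validates evidence levels and coordinates", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "cr.tsv")
  writeLines(c(
    "strain_id\treplicon_id\tstart\tend\tn_spacers\tevidence_level\ton_plasmid",
    "s1\tchr\t100\t2000\t28\t3\tFALSE"), p)
  cr <- read_crispr_table(p)
  expect_equal(cr$n_spacers, 28L)
  bad <- file.path(tmp, "bad.tsv")
  writeLines(c(
    "strain_id\treplicon_id\tstart\tend\tn_spacers\tevidence_level\ton_plasmid",
    "s1\tchr\t100\t2000\t28\t5\tFALSE"), bad)
  expect_error(read_crispr_table(bad), "evidence_level")
})

test_that("replicon concatenation tracks junctions", {
  iv <- tibble::tibble(strain_id = "s1", replicon_id = c("chr", "p1"),
                       detector = "A", start = c(100L, 10L),
                       end = c(500L, 60L))
  cc <- concatenate_replicons(iv, c(chr = 1000L, p1 = 200L))
  expect_equal(cc$junctions, 1000)
  expect_equal(cc$intervals$start, c(100L, 1010L))
  expect_equal(cc$intervals$end, c(500L, 1060L))
  expect_error(concatenate_replicons(iv, c(chr = 1000L)), "unknown replicon")
})

test_that("packaged example files read and call consensus end to end", {
  bed <- system.file("extdata", "example_detector_A.bed",
                     package = "srpcensus")
  gff <- system.file("extdata", "example_detector_B.gff3",
                     package = "srpcensus")
  a <- read_intervals(bed, "bed", detector = "A", strain_id = "demo1")
  b <- read_intervals(gff, "gff3", detector = "B", strain_id = "demo1")
  cc <- consensus_calls(a, b)
  expect_equal(nrow(cc), 1L)           # only one region is doubly supported
  expect_equal(cc$start, 50099L)       # intersection of the two reports
  expect_equal(cc$end, 105800L)

  tr <- read_trait_table(system.file("extdata", "example_traits.tsv",
                                     package = "srpcensus"))
  expect_equal(tr$growth_class, c("fast", "slow", "fast"))
  geo <- add_geometry(tr)
  expect_true(all(is.finite(geo$volume_um3)))
})
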