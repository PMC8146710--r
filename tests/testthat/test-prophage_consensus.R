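mk_set <- function(starts, ends, detector = "A", strain = "s1",
                   replicon = "chr") {
  tibble::tibble(strain_id = strain, replicon_id = replicon,
                 detector = detector, start = as.integer(starts),
                 end = as.integer(ends))
}

test_that("pairwise consensus matches the set-operation definitions", {
  # identical inputs
  cc <- consensus_calls(mk_set(10000, 50000), mk_set(10000, 50000, "B"))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$start, 10000L)
  expect_equal(cc$end, 50000L)
  expect_equal(cc$length, 40000L)

  # disjoint inputs: single-detector regions are discarded
  expect_equal(nrow(consensus_calls(mk_set(10000, 50000),
                                    mk_set(60000, 80000, "B"))), 0L)

  # partial overlap: intersection vs union span
  a <- mk_set(10000, 50000); b <- mk_set(30000, 80000, "B")
  ci <- consensus_calls(a, b, mode = "intersection")
  expect_equal(c(ci$start, ci$end, ci$length), c(30000L, 50000L, 20000L))
  cu <- consensus_calls(a, b, mode = "union")
  expect_equal(c(cu$start, cu$end, cu$length), c(10000L, 80000L, 70000L))

  # one B interval bridging two A intervals yields two separated calls
  a2 <- mk_set(c(0, 20000), c(10000, 30000))
  b2 <- mk_set(5000, 25000, "B")
  c2 <- consensus_calls(a2, b2)
  expect_equal(c2$start, c(5000L, 20000L))
  expect_equal(c2$end, c(10000L, 25000L))
})

test_that("consensus ids number calls serially per strain", {
  a <- dplyr::bind_rows(mk_set(c(100, 5000), c(1000, 9000), strain = "sA"),
                        mk_set(200, 900, strain = "sB"))
  b <- dplyr::bind_rows(mk_set(c(100, 5000), c(1000, 9000), "B", "sA"),
                        mk_set(200, 900, "B", "sB"))
  cc <- consensus_calls(a, b)
  expect_equal(cc$prophage_id, c("1R1", "1R2", "2R1"))
})

test_that("consensus is symmetric and intersection is nested in union", {
  set.seed(42)
  for (rep in 1:25) {
    a <- random_interval_set(8, 2000, detector = "A")
    b <- random_interval_set(8, 2000, detector = "B")
    for (mode in c("intersection", "union")) {
      ab <- consensus_calls(a, b, mode = mode)
      ba <- consensus_calls(b, a, mode = mode)
      expect_equal(ab[, c("start", "end")], ba[, c("start", "end")])
    }
    ci <- consensus_calls(a, b, "intersection")
    cu <- consensus_calls(a, b, "union")
    if (nrow(ci) > 0) {
      contained <- vapply(seq_len(nrow(ci)), function(i) {
        any(cu$start <= ci$start[i] & cu$end >= ci$end[i])
      }, logical(1))
      expect_true(all(contained))
    }
  }
})

test_that("intersection-mode consensus equals the per-base voting oracle", {
  set.seed(7)
  for (rep in 1:120) {
    a <- random_interval_set(10, 500)
    b <- random_interval_set(10, 500, detector = "B")
    got <- consensus_calls(a, b, "intersection")
    want <- oracle_consensus_intersection(a, b, 500L)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$start, as.integer(want$start))
      expect_equal(got$end, as.integer(want$end))
    }
  }
})

test_that("min_overlap and unknown strains are enforced", {
  a <- mk_set(0, 100); b <- mk_set(99, 200, "B")
  expect_equal(nrow(consensus_calls(a, b, min_overlap = 1)), 1L)
  expect_equal(nrow(consensus_calls(a, b, min_overlap = 2)), 0L)
  expect_error(consensus_calls(a, b, min_overlap = 0), "min_overlap")
  expect_error(consensus_calls(a, b, strains = "other"), "unknown strain")
})

test_that("junction-spanning calls are rejected under concatenation", {
  a <- mk_set(900, 1100, replicon = "concat")
  b <- mk_set(950, 1200, "B", replicon = "concat")
  cc <- consensus_calls(a, b, junctions = list(s1 = 1000))
  expect_equal(nrow(cc), 0L)
  cc2 <- consensus_calls(a, b, junctions = list(s1 = 5000))
  expect_equal(nrow(cc2), 1L)
})

test_that("size classification is strict at 30 kb", {
  expect_equal(classify_size(c(13123, 29999, 30000, 169593)),
               c("small", "small", "standard", "standard"))
})

test_that("genome burden arithmetic and rounding", {
  calls <- tibble::tibble(start = c(0L, 200000L), end = c(50000L, 225000L))
  gb <- genome_burden(calls, 3e6)
  expect_equal(gb$total_prophage_bp, 75000L)
  expect_equal(gb$prophage_pct, 2.5)
  gb1 <- genome_burden(tibble::tibble(start = 0L, end = 100000L), 1e6)
  expect_equal(gb1$prophage_pct, 10)
  gb0 <- genome_burden(calls[0, ], 1e6)
  expect_equal(gb0$total_prophage_bp, 0L)
  expect_equal(gb0$prophage_pct, 0)
  expect_error(genome_burden(calls, 0), "genome_bp")
})

test_that("census summary reproduces half-up prevalence percentages", {
  census <- tibble::tibble(strain_id = paste0("s", 1:91),
                           n_prophages = rep(c(1L, 0L), c(51L, 40L)),
                           total_prophage_bp = 0L, genome_bp = 4e6,
                           prophage_fraction = 0, prophage_pct = 0,
                           n_crispr = 0L)
  s <- census_summary(census)
  expect_equal(s$lysogen_pct, 56)
  expect_equal(s$n_lysogens, 51L)
  s0 <- census_summary(dplyr::mutate(census, n_prophages = 0L))
  expect_equal(s0$lysogen_pct, 0)
  expect_error(census_summary(census[0, ]), "empty")

  strata <- rep(c("freshwater", "other"), c(22, 69))
  census2 <- census
  census2$n_prophages <- 0L
  census2$n_prophages[1:15] <- 1L       # 15 of 22 freshwater
  census2$n_prophages[23:40] <- 1L
  s2 <- census_summary(census2, strata)
  expect_equal(s2$lysogen_pct[s2$stratum == "freshwater"], 68)
})
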