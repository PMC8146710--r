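test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(n_strains = 30L)
  s1 <- simulate_strain_census(cfg, seed = 5)
  s2 <- simulate_strain_census(cfg, seed = 5)
  expect_identical(s1, s2)
  d1 <- simulate_detector_outputs(s1$truth, s1$strains, cfg, seed = 6)
  d2 <- simulate_detector_outputs(s2$truth, s2$strains, cfg, seed = 6)
  expect_identical(d1, d2)
})

test_that("lysogen fraction extremes are respected", {
  all_lys <- simulate_strain_census(
    sim_config(n_strains = 20L, lysogen_fraction = 1, prophage_rate = 1),
    seed = 2)
  expect_equal(nrow(all_lys$truth), 20L)   # exactly one prophage each
  none <- simulate_strain_census(
    sim_config(n_strains = 20L, lysogen_fraction = 0), seed = 2)
  expect_equal(nrow(none$truth), 0L)
})

test_that("implanted prophages never overlap within a strain", {
  sim <- simulate_strain_census(sim_config(n_strains = 40L), seed = 9)
  by_strain <- split(sim$truth, sim$truth$strain_id)
  for (tr in by_strain) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1) {
      expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
    }
  }
})

test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(lysogen_fraction = 1.2), "probabilities")
  expect_error(sim_config(trait_rho = 1.5), "trait_rho")
  expect_error(sim_config(detector_fpr_per_Mb = -1), "fpr")
  expect_error(sim_config(evidence_probs = c(0.5, 0.5)), "evidence_probs")
})

test_that("perfect detectors reproduce the implanted truth through the pipeline", {
  cfg <- sim_config(n_strains = 25L, detector_sensitivity_A = 1,
                    detector_sensitivity_B = 1, detector_fpr_per_Mb = 0,
                    boundary_jitter_sd = 0)
  sim <- simulate_strain_census(cfg, seed = 11)
  det <- simulate_detector_outputs(sim$truth, sim$strains, cfg, seed = 12)
  calls <- consensus_calls(det$A, det$B,
                           strains = sim$strains$strain_id)
  truth <- sim$truth[order(sim$truth$strain_id, sim$truth$start), ]
  expect_equal(calls$start, truth$start)
  expect_equal(calls$end, truth$end)
  expect_equal(calls$strain_id, truth$strain_id)
})

test_that("trait copula hits the comonotone and independent extremes", {
  cfg1 <- sim_config(n_strains = 60L, trait_rho = 1)
  sim <- simulate_strain_census(cfg1, seed = 14)
  counts <- as.integer(table(factor(sim$truth$strain_id,
                                    levels = sim$strains$strain_id)))
  tr1 <- simulate_traits(sim$strains, sim$truth, cfg1, seed = 15)
  # comonotone coupling: every lysogen's volume exceeds what ties allow to
  # invert; check rank agreement on the untied count values
  rho <- suppressWarnings(cor(tr1$volume_um3, counts, method = "spearman"))
  expect_gt(rho, 0.8)

  cfg0 <- sim_config(n_strains = 60L, trait_rho = 0)
  reps <- vapply(1:40, function(i) {
    s <- simulate_strain_census(cfg0, seed = 100 + i)
    cts <- as.integer(table(factor(s$truth$strain_id,
                                   levels = s$strains$strain_id)))
    tr <- simulate_traits(s$strains, s$truth, cfg0, seed = 200 + i)
    suppressWarnings(cor(tr$volume_um3, cts, method = "spearman"))
  }, numeric(1))
  expect_lt(abs(mean(reps)), 0.05)
})

test_that("generated files validate under the package readers", {
  tmp <- withr::local_tempdir()
  cfg <- sim_config(n_strains = 15L)
  sim <- simulate_strain_census(cfg, seed = 31)
  det <- simulate_detector_outputs(sim$truth, sim$strains, cfg, seed = 32)
  traits <- simulate_traits(sim$strains, sim$truth, cfg, seed = 33)
  paths <- write_simulated_inputs(sim, det, traits, tmp)
  a <- read_intervals(paths[["detector_a"]], "tsv1based", detector = "A")
  b <- read_intervals(paths[["detector_b"]], "tsv1based", detector = "B")
  expect_equal(nrow(a), nrow(det$A))
  expect_equal(a$start, det$A$start)
  cr <- read_crispr_table(paths[["crispr"]])
  expect_equal(nrow(cr), nrow(sim$arrays))
  tr <- read_trait_table(paths[["traits"]])
  expect_equal(nrow(tr), 15L)

  hits <- simulate_homology_hits(paste0("p", 1:4), cfg, seed = 34)
  hp <- file.path(tmp, "hits.tsv")
  blast12 <- data.frame(hits$hits$query_orf, hits$hits$subject_orf,
                        hits$hits$pct_identity, hits$hits$aln_length,
                        0L, 0L, 1L, hits$hits$aln_length, 1L,
                        hits$hits$aln_length, hits$hits$evalue,
                        hits$hits$bitscore)
  write.table(blast12, hp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  rh <- read_homology_hits(hp)
  expect_equal(nrow(rh), nrow(hits$hits))
})

test_that("realized lysogen fraction matches the binomial expectation", {
  cfg <- sim_config(n_strains = 91L)
  reps <- vapply(1:60, function(i) {
    s <- simulate_strain_census(cfg, seed = 1000 + i)
    length(unique(s$truth$strain_id)) / 91
  }, numeric(1))
  se <- sqrt(0.56 * 0.44 / (60 * 91))
  expect_lt(abs(mean(reps) - 0.56), 4 * se + 0.01)
})

test_that("decoy hits never pass the homolog filter", {
  sim <- simulate_homology_hits(paste0("p", 1:6), sim_config(), seed = 77)
  decoys <- sim$hits[grepl(":d", sim$hits$query_orf, fixed = TRUE), ]
  expect_gt(nrow(decoys), 0)
  expect_equal(nrow(filter_homologs(decoys)), 0L)
})
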