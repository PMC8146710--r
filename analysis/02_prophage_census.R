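#!/usr/bin/env Rscript
# Step 2: call consensus prophages from the two detectors' reports, classify
# them by size, and build the per-strain census with genome burden.
# Intersection-mode consensus is the conservative default: a region counts
# only where both detectors agree, and its coordinates are the overlap.

suppressPackageStartupMessages(library(srpcensus))

detA <- read_intervals("results/inputs/detector_A.tsv", "tsv1based",
                       detector = "A")
detB <- read_intervals("results/inputs/detector_B.tsv", "tsv1based",
                       detector = "B")
strains <- read_trait_table("results/inputs/strain_traits.tsv")

calls <- consensus_calls(detA, detB, mode = "intersection",
                         strains = strains$strain_id)
census <- strain_census(calls, strains)

dir.create("results", showWarnings = FALSE)
write_tsv_plain(calls, "results/prophage_calls.tsv")
write_intervals_bed(calls, "results/prophage_calls.bed")
write_tsv_plain(census, "results/strain_census.tsv")

s <- census_summary(census, strata = strains$habitat)
write_tsv_plain(s, "results/census_summary.tsv")

overall <- s[s$stratum == "overall", ]
message(sprintf("%d consensus prophages in %d/%d strains (%d%% lysogens; %d poly-lysogens)",
                overall$total_prophages, overall$n_lysogens,
                overall$n_strains, overall$lysogen_pct,
                overall$n_polylysogens))
message(sprintf("size classes: %d small (<30 kb), %d standard; mean length %.1f kb",
                sum(calls$size_class == "small"),
                sum(calls$size_class == "standard"),
                mean(calls$length) / 1000))
message(sprintf("genome burden among lysogens: %.2f%%-%.2f%%",
                min(census$prophage_pct[census$n_prophages > 0]),
                max(census$prophage_pct[census$n_prophages > 0])))
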