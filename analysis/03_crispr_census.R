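#!/usr/bin/env Rscript
# Step 3: filter CRISPR arrays to evidence levels 2-4 (the stringent
# criterion separating real arrays from spurious repeats), compute
# prevalence, spacer statistics by lysogeny, and localize arrays relative
# to the consensus prophages.

suppressPackageStartupMessages(library(srpcensus))

arrays_raw <- read_crispr_table("results/inputs/crispr_arrays.tsv")
strains <- read_trait_table("results/inputs/strain_traits.tsv")
calls <- utils::read.delim("results/prophage_calls.tsv")

arrays <- filter_arrays(arrays_raw, min_evidence = 2L)
message(sprintf("%d of %d detected arrays pass the evidence filter",
                nrow(arrays), nrow(arrays_raw)))

prev <- crispr_prevalence(arrays, strains, strata = strains$habitat)
write_tsv_plain(prev, "results/crispr_prevalence.tsv")
overall <- prev[prev$stratum == "overall", ]
message(sprintf("CRISPR: %d arrays in %d/%d strains (%d%%); per-strain range %d-%d",
                overall$total_arrays, overall$n_with_crispr,
                overall$n_strains, overall$crispr_pct,
                overall$min_arrays, overall$max_arrays))

census <- utils::read.delim("results/strain_census.tsv")
lysogen <- setNames(ifelse(census$n_prophages > 0, "lysogen", "non_lysogen"),
                    census$strain_id)
sp <- spacer_summary(arrays, lysogen)
write_tsv_plain(sp, "results/spacer_summary.tsv")
message(paste(sprintf("median spacers (%s): %s", sp$group,
                      sp$median_spacers), collapse = " | "))

emb <- arrays_in_prophages(arrays, calls)
write_tsv_plain(emb$arrays, "results/crispr_localized.tsv")
message(sprintf("%d arrays embedded in prophages (%s%% of prophages carry one)",
                sum(emb$arrays$in_prophage), emb$pct))
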