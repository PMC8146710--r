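#!/usr/bin/env Rscript
# Step 7: the association battery relating carriage to ecophysiology:
# volume-prophage Spearman, lysogen/non-lysogen spacer comparison
# (Wilcoxon), lysogeny x CRISPR contingency (odds ratio + Fisher),
# correlation-matrix PCA of the eight trait variables, and family-level
# aggregation.

suppressPackageStartupMessages(library(srpcensus))

census <- utils::read.delim("results/strain_census.tsv")
traits <- read_trait_table("results/traits_with_geometry.tsv")
arrays <- filter_arrays(read_crispr_table("results/inputs/crispr_arrays.tsv"))
census$n_crispr <- as.integer(table(factor(arrays$strain_id,
                                           levels = census$strain_id)))

stats_out <- list()

rc <- rank_correlation(traits$volume_um3[match(census$strain_id,
                                               traits$strain_id)],
                       census$n_prophages)
stats_out$volume_vs_prophages <- c(rho = rc$estimate, p = rc$p_value,
                                   n = rc$n)
message(sprintf("cell volume vs prophage count: Spearman %.4f (p = %.4g, n = %d)",
                rc$estimate, rc$p_value, rc$n))

lys <- census$n_prophages > 0
spacers_by <- split(arrays$n_spacers, lys[match(arrays$strain_id,
                                                census$strain_id)])
if (length(spacers_by) == 2L) {
  w <- wilcoxon_ranksum(spacers_by[["TRUE"]], spacers_by[["FALSE"]])
  stats_out$spacers_lys_vs_non <- c(W = w$statistic, p = w$p_value)
  message(sprintf("spacer counts, lysogens vs non-lysogens: W = %.0f, p = %.4f",
                  w$statistic, w$p_value))
}

tab <- table(lysogen = lys, crispr = census$n_crispr > 0)[2:1, 2:1]
f <- fisher_or(tab)
stats_out$lysogeny_x_crispr <- c(OR = f$odds_ratio, lo = f$ci95[1],
                                 hi = f$ci95[2], p = f$p_value)
message(sprintf("lysogeny x CRISPR: OR = %.2f (95%% CI %.3f-%.2f), Fisher p = %.4f",
                f$odds_ratio, f$ci95[1], f$ci95[2], f$p_value))

m <- trait_matrix(census, traits, lysogens_only = TRUE)
p <- pca_traits(m)
write_tsv_plain(as.data.frame(p$loadings), "results/pca_loadings.tsv")
message(sprintf("PCA over %d lysogens: PC1 %.1f%%, PC2 %.1f%% of variance",
                p$n, p$percent_variance[1], p$percent_variance[2]))

fa <- family_aggregate(census, traits)
write_tsv_plain(fa$table, "results/family_table.tsv")
message(sprintf("family-level prophage vs CRISPR totals: Spearman %.3f (p = %.4f, %d families)",
                fa$correlation$estimate, fa$correlation$p_value,
                fa$correlation$n))

st <- data.frame(statistic = names(unlist(stats_out)),
                 value = unlist(stats_out))
write_tsv_plain(st, "results/association_stats.tsv")
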