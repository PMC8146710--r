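#!/usr/bin/env Rscript
# Step 4: estimate cell volume and surface area from cell dimensions,
# classify cell sizes, and compute the two burden measures per strain:
# prophage bp per um^3 of cell and prophage bp per genome bp (density).
# Small cells can rank low on the first and high on the second.

suppressPackageStartupMessages(library(srpcensus))

traits <- read_trait_table("results/inputs/strain_traits.tsv")
census <- utils::read.delim("results/strain_census.tsv")

traits <- add_geometry(traits)
write_tsv_plain(traits, "results/traits_with_geometry.tsv")
message(sprintf("volume classes: %s",
                paste(names(table(traits$volume_class)),
                      table(traits$volume_class), collapse = ", ")))

burden <- do.call(rbind, lapply(seq_len(nrow(census)), function(i) {
  v <- traits$volume_um3[match(census$strain_id[i], traits$strain_id)]
  b <- burden_per_cell(census[i, ], ifelse(is.na(v), NA_real_, v))
  cbind(strain_id = census$strain_id[i], b)
}))
write_tsv_plain(burden, "results/burden_per_cell.tsv")

lys <- burden[burden$n_prophages_per_cell > 0, ]
message(sprintf("prophage DNA per cell volume (lysogens): %.0f-%.0f bp/um^3",
                min(lys$prophage_bp_per_um3, na.rm = TRUE),
                max(lys$prophage_bp_per_um3, na.rm = TRUE)))
message(sprintf("prophage density (lysogens): %.4f-%.4f",
                min(lys$prophage_density), max(lys$prophage_density)))
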