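## Worked-example dataset: a synthetic reconstruction of the SRP survey's
## headline count structure (91 strains; 81 prophages in 51 lysogens; 160
## CRISPR arrays in 71 strains, 30 of them single-array; 15/22 freshwater
## and 17/40 marine/brackish lysogens; 12 small prophages; 4 prophages with
## an embedded CRISPR array; spacer medians 30/25 for arrays in lysogens vs
## non-lysogens; 6 Peptococcaceae strains carrying 13 prophages). Interval
## coordinates and spacer values are synthetic; only the count structure is
## faithful. Used by the worked examples, the acceptance script and the
## tests.

symmetric_spacers <- function(n, center, spread = 20L) {
  k <- n %/% 2L
  off <- ((seq_len(k) - 1L) %% spread) + 1L
  sort(c(rep(center, n - 2L * k), center - off, center + off))
}

#' Synthetic worked-example survey dataset
#'
#' Builds, entirely in code, a census-shaped dataset whose marginal counts
#' match the published SRP survey structure, so that the summary operations
#' reproduce the survey's printed percentages. Coordinates, spacer values
#' and identifiers are synthetic.
#'
#' @return List: `strains` (91 rows: strain_id, family, habitat, genome_bp),
#'   `calls` (81 prophage calls with lengths and size classes),
#'   `arrays` (160 CRISPR arrays, evidence 2-4), `census`
#'   ([strain_census()] output), `lysogen` (named logical).
#' @export
example_survey <- function() {
  n <- 91L
  strain_id <- sprintf("srp%02d", seq_len(n))
  habitat <- c(rep("freshwater", 22), rep("marine", 30), rep("brackish", 10),
               rep("soil", 10), rep("engineered", 10),
               rep("host_associated", 9))
  # lysogens: 15/22 freshwater, 13/30 marine, 4/10 brackish, rest 19 of 29
  lysogen <- c(rep(c(TRUE, FALSE), c(15, 7)),    # freshwater
               rep(c(TRUE, FALSE), c(13, 17)),   # marine
               rep(c(TRUE, FALSE), c(4, 6)),     # brackish
               rep(c(TRUE, FALSE), c(7, 3)),     # soil
               rep(c(TRUE, FALSE), c(7, 3)),     # engineered
               rep(c(TRUE, FALSE), c(5, 4)))     # host-associated
  stopifnot(sum(lysogen) == 51L)
  # prophages per lysogen: one strain with 6, nine with 3, seven with 2,
  # thirty-four with 1 (total 81); the first six lysogens are the
  # Peptococcaceae block (13 prophages across 6 strains)
  per_lysogen <- c(3L, 2L, 2L, 2L, 2L, 2L,            # Peptococcaceae
                   6L, rep(3L, 8L), rep(2L, 2L), rep(1L, 34L))
  stopifnot(length(per_lysogen) == 51L, sum(per_lysogen) == 81L)
  n_proph <- integer(n)
  n_proph[lysogen] <- per_lysogen
  family <- rep("Desulfovibrionaceae", n)
  family[which(lysogen)[1:6]] <- "Peptococcaceae"
  family[!lysogen][1:20] <- rep(c("Desulfobacteraceae", "Desulfobulbaceae",
                                  "Desulfohalobiaceae", "Archaeoglobaceae"),
                                each = 5)

  # prophage lengths per lysogen: 12 calls below 30 kb overall; the
  # six-prophage strain's lengths sum to the survey's per-strain maximum
  # 360,426 bp; the minimum length 13,123 bp sits in a single-prophage
  # strain
  lengths_per <- c(
    list(c(56000L, 56000L, 56000L)),                     # L1 Peptococcaceae
    rep(list(c(56000L, 56000L)), 5L),                    # L2-L6
    list(c(169593L, 56000L, 56000L, 33000L, 26000L, 19833L)),  # L7, six
    list(c(18000L, 18000L, 56000L), c(18000L, 18000L, 56000L),
         c(22000L, 22000L, 56000L), c(22000L, 26000L, 56000L),
         c(26000L, 56000L, 56000L), c(56000L, 56000L, 56000L),
         c(56000L, 56000L, 56000L), c(56000L, 56000L, 56000L)),  # L8-L15
    rep(list(c(56000L, 56000L)), 2L),                    # L16-L17
    list(13123L),                                        # L18, the minimum
    rep(list(56000L), 33L)                               # L19-L51 singles
  )
  stopifnot(length(lengths_per) == 51L,
            identical(lengths(lengths_per), as.integer(per_lysogen)),
            sum(unlist(lengths_per) < 30000L) == 12L,
            sum(lengths_per[[7L]]) == 360426L)
  lys_idx <- which(n_proph > 0L)
  calls <- dplyr::bind_rows(lapply(seq_along(lys_idx), function(j) {
    len <- lengths_per[[j]]
    gap <- 100000L
    start <- cumsum(c(50000L, head(len, -1L) + gap))
    tibble::tibble(strain_id = strain_id[lys_idx[j]], replicon_id = "chr",
                   start = start, end = start + len)
  }))
  serial <- stats::ave(seq_len(nrow(calls)), calls$strain_id, FUN = seq_along)
  calls$prophage_id <- paste0(match(calls$strain_id, strain_id), "R", serial)
  calls$length <- calls$end - calls$start
  calls$size_class <- classify_size(calls$length)
  calls$virfam_label <- "unassigned"

  # genome sizes pin the burden extremes: 360,426 prophage bp / 9.55% for
  # the six-prophage strain, 13,123 bp / 0.22% for the minimum strain
  genome_bp <- rep(3900000L, n)
  genome_bp[lys_idx[7L]] <- as.integer(round(360426 / 0.0955))
  genome_bp[lys_idx[18L]] <- as.integer(round(13123 / 0.0022))

  # CRISPR arrays: 71 carriers (42 lysogens, 29 non-lysogens); 30 strains
  # with one array, 41 with more (11 + 10 + 31x3 + 8x2 = 130); total 160
  carriers_lys <- which(lysogen)[1:42]
  carriers_non <- which(!lysogen)[1:29]
  carriers <- c(carriers_lys, carriers_non)
  arrays_per <- integer(n)
  arrays_per[carriers[1L]] <- 11L
  arrays_per[carriers[2L]] <- 10L
  arrays_per[carriers[3:33]] <- 3L
  arrays_per[carriers[34:41]] <- 2L
  arrays_per[carriers[42:71]] <- 1L
  stopifnot(sum(arrays_per) == 160L, sum(arrays_per == 1L) == 30L)
  arr_strain <- rep(strain_id, arrays_per)
  arr_lys <- rep(lysogen, arrays_per)
  spacers <- integer(length(arr_strain))
  spacers[arr_lys] <- symmetric_spacers(sum(arr_lys), 30L)
  spacers[!arr_lys] <- symmetric_spacers(sum(!arr_lys), 25L)
  arrays <- tibble::tibble(
    strain_id = arr_strain,
    replicon_id = "chr",
    start = 10000L + 2000L * (stats::ave(seq_along(arr_strain), arr_strain,
                                         FUN = seq_along) - 1L),
    end = NA_integer_,
    n_spacers = spacers,
    evidence_level = rep_len(c(2L, 3L, 4L), length(arr_strain)),
    on_plasmid = FALSE
  )
  arrays$end <- arrays$start + arrays$n_spacers * 65L
  arrays$on_plasmid[1:2] <- TRUE
  arrays$replicon_id[1:2] <- "plasmid1"
  # embed 4 arrays inside 4 distinct prophage calls (4/81 = 5%)
  host_calls <- calls[match(unique(calls$strain_id)[1:4],
                            calls$strain_id), ]
  for (j in 1:4) {
    slot <- which(arrays$strain_id == host_calls$strain_id[j] &
                    !arrays$on_plasmid)[1L]
    if (is.na(slot)) {
      arrays <- dplyr::bind_rows(arrays, tibble::tibble(
        strain_id = host_calls$strain_id[j], replicon_id = "chr",
        start = 0L, end = 0L, n_spacers = 30L, evidence_level = 2L,
        on_plasmid = FALSE))
      slot <- nrow(arrays)
    }
    arrays$start[slot] <- host_calls$start[j] + 1000L
    arrays$end[slot] <- arrays$start[slot] + arrays$n_spacers[slot] * 65L
  }
  arrays <- validate_crispr(arrays, "example survey arrays")

  strains <- tibble::tibble(strain_id = strain_id, family = family,
                            habitat = habitat, genome_bp = genome_bp)
  census <- strain_census(calls, strains, arrays = arrays)
  list(strains = strains, calls = calls, arrays = arrays, census = census,
       lysogen = setNames(lysogen, strain_id))
}
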