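## Synthetic-data generator: emulates every input the census pipeline
## consumes (detector intervals, CRISPR tables, trait tables, homology hits,
## alignments) with the statistical structure the analysis assumes, so all
## stages are testable without external detector software.
##
## Defaults encode the study conditions of the SRP survey: 91 strains, 56%
## lysogens with ~1.6 prophages each, mean prophage length ~56.12 kb, 78% of
## strains carrying 1-11 CRISPR arrays, and a volume-prophage Spearman
## correlation of ~0.32.

#' Simulation configuration
#'
#' Builds a validated configuration list for the generators. All
#' probabilities must lie in `[0, 1]`; seeded runs are reproducible.
#'
#' @param n_strains Number of strains (default 91).
#' @param lysogen_fraction Probability a strain carries >= 1 prophage
#'   (default 0.56).
#' @param prophage_rate Success probability of the zero-truncated geometric
#'   for prophages per lysogen; the mean is `1/prophage_rate` (default
#'   51/81, mean ~1.59).
#' @param length_meanlog,length_sdlog Lognormal prophage length (bp); the
#'   defaults target a mean of 56,120 bp.
#' @param length_min Lower clamp on prophage length (bp).
#' @param genome_mean,genome_sd Normal genome length (bp), truncated above
#'   `1e6`.
#' @param gc_mean,gc_sd GC percent, clamped to `[25, 75]`.
#' @param crispr_carrier_fraction Probability a strain carries >= 1 CRISPR
#'   array (default 0.78); implemented as a zero-inflated Poisson whose
#'   total zero mass is `1 - crispr_carrier_fraction`.
#' @param crispr_lambda Poisson mean of the non-inflated array count
#'   component (default 2.5; observed counts range ~1-11).
#' @param spacer_mu,spacer_size Negative-binomial spacers per array
#'   (`1 + NB(mu, size)`; defaults give a median near 27).
#' @param plasmid_array_prob Probability an array sits on a plasmid
#'   (default 2/160).
#' @param evidence_probs Probabilities of evidence levels 2-4 for genuine
#'   arrays (length 3).
#' @param spurious_array_rate Mean number of spurious level-1 CRISPR-like
#'   detections per strain (removed by the evidence filter; default 0.4).
#' @param detector_sensitivity_A,detector_sensitivity_B Per-prophage
#'   detection probabilities (defaults 0.98).
#' @param detector_fpr_per_Mb Expected false-positive detections per Mb
#'   (default 0.05).
#' @param boundary_jitter_sd SD (bp) of the rounded normal jitter applied to
#'   reported boundaries (default 150).
#' @param trait_rho Target Spearman correlation between cell volume and
#'   prophage count (default 0.32).
#' @param volume_meanlog,volume_sdlog Lognormal cell volume (um^3).
#' @param n_clusters,within_pairs,between_pairs,decoys_per_pair Homology
#'   cluster specification: prophages are split into `n_clusters` families
#'   sharing `within_pairs` qualifying ORF pairs inside a cluster and
#'   `between_pairs` across clusters, plus sub-threshold decoy hits.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 91L,
                       lysogen_fraction = 0.56,
                       prophage_rate = 51 / 81,
                       length_meanlog = log(56120) - 0.55^2 / 2,
                       length_sdlog = 0.55,
                       length_min = 5000,
                       genome_mean = 3.9e6,
                       genome_sd = 7e5,
                       gc_mean = 50,
                       gc_sd = 8,
                       crispr_carrier_fraction = 0.78,
                       crispr_lambda = 2.5,
                       spacer_mu = 28,
                       spacer_size = 4,
                       plasmid_array_prob = 2 / 160,
                       evidence_probs = c(0.30, 0.35, 0.35),
                       spurious_array_rate = 0.4,
                       detector_sensitivity_A = 0.98,
                       detector_sensitivity_B = 0.98,
                       detector_fpr_per_Mb = 0.05,
                       boundary_jitter_sd = 150,
                       trait_rho = 0.32,
                       volume_meanlog = log(1.3),
                       volume_sdlog = 0.8,
                       n_clusters = 3L,
                       within_pairs = 12L,
                       between_pairs = 2L,
                       decoys_per_pair = 1L) {
  cfg <- as.list(environment())
  probs <- c(lysogen_fraction, prophage_rate, crispr_carrier_fraction,
             detector_sensitivity_A, detector_sensitivity_B,
             plasmid_array_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must be in [0, 1]", call. = FALSE)
  }
  if (abs(trait_rho) > 1) stop("|trait_rho| must be <= 1", call. = FALSE)
  if (detector_fpr_per_Mb < 0) stop("detector_fpr_per_Mb < 0", call. = FALSE)
  if (abs(sum(evidence_probs) - 1) > 1e-8 || length(evidence_probs) != 3L) {
    stop("evidence_probs must be 3 probabilities (levels 2-4) summing to 1",
         call. = FALSE)
  }
  if (spurious_array_rate < 0) {
    stop("spurious_array_rate must be >= 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

rlength <- function(n, cfg) {
  pmax(cfg$length_min,
       round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)))
}

place_nonoverlapping <- function(lengths, genome_bp, max_attempts = 100L) {
  if (length(lengths) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  if (sum(lengths) > genome_bp) {
    stop("infeasible packing: prophage bp exceed genome", call. = FALSE)
  }
  for (attempt in seq_len(max_attempts)) {
    starts <- sort(sample.int(genome_bp - max(lengths), length(lengths)))
    lens <- if (length(lengths) > 1L) sample(lengths) else lengths
    ends <- starts + lens
    if (all(ends <= genome_bp) &&
        (length(starts) == 1L || all(starts[-1L] >= ends[-length(ends)]))) {
      return(tibble::tibble(start = as.integer(starts),
                            end = as.integer(ends)))
    }
  }
  stop("failed to place non-overlapping prophages after ", max_attempts,
       " attempts", call. = FALSE)
}

srp_families <- c("Desulfovibrionaceae", "Peptococcaceae",
                  "Desulfobacteraceae", "Desulfobulbaceae",
                  "Desulfohalobiaceae", "Desulfomicrobiaceae",
                  "Syntrophobacteraceae", "Archaeoglobaceae",
                  "Nitrospiraceae")
srp_family_probs <- c(0.40, 0.07, 0.14, 0.09, 0.07, 0.06, 0.06, 0.06, 0.05)

#' Simulate the strain census truth
#'
#' Generates per-strain genome metadata, implanted non-overlapping prophage
#' intervals (the ground truth the detectors will report around), and CRISPR
#' arrays with spacer counts.
#'
#' @param config From [sim_config()].
#' @param seed Optional RNG seed.
#' @return List: `strains` (strain_id, family, habitat, genome_bp, gc_pct),
#'   `truth` (implanted prophage intervals, 0-based half-open),
#'   `arrays` (CRISPR arrays in the pipeline schema).
#' @export
simulate_strain_census <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_strains
  strains <- tibble::tibble(
    strain_id = sprintf("s%03d", seq_len(n)),
    family = sample(srp_families, n, replace = TRUE,
                    prob = srp_family_probs),
    habitat = sample(trait_vocab$habitat, n, replace = TRUE,
                     prob = c(0.24, 0.11, 0.33, 0.10, 0.12, 0.10)),
    genome_bp = as.integer(pmax(1e6 + 1,
                                round(rnorm(n, config$genome_mean,
                                            config$genome_sd)))),
    gc_pct = pmin(75, pmax(25, rnorm(n, config$gc_mean, config$gc_sd)))
  )
  lysogen <- runif(n) < config$lysogen_fraction
  n_proph <- integer(n)
  n_proph[lysogen] <- rgeom(sum(lysogen), config$prophage_rate) + 1L
  truth <- dplyr::bind_rows(lapply(which(n_proph > 0L), function(i) {
    iv <- place_nonoverlapping(rlength(n_proph[i], config),
                               strains$genome_bp[i])
    tibble::tibble(strain_id = strains$strain_id[i], replicon_id = "chr",
                   start = iv$start, end = iv$end)
  }))
  if (nrow(truth) == 0L) {
    truth <- tibble::tibble(strain_id = character(), replicon_id = character(),
                            start = integer(), end = integer())
  }
  # zero-inflated Poisson array counts with total zero mass 1 - carrier frac
  p0_pois <- exp(-config$crispr_lambda)
  pi0 <- max(0, (1 - config$crispr_carrier_fraction - p0_pois) /
               (1 - p0_pois))
  n_real <- ifelse(runif(n) < pi0, 0L, rpois(n, config$crispr_lambda))
  n_spur <- rpois(n, config$spurious_array_rate)
  n_arr <- n_real + n_spur
  arrays <- dplyr::bind_rows(lapply(which(n_arr > 0L), function(i) {
    k <- n_arr[i]
    spacers <- 1L + rnbinom(k, size = config$spacer_size,
                            mu = config$spacer_mu)
    len <- as.integer(spacers * 65L)  # ~30 bp repeat + ~35 bp spacer
    on_pl <- runif(k) < config$plasmid_array_prob
    start <- vapply(len, function(l) {
      sample.int(strains$genome_bp[i] - l, 1L)
    }, integer(1))
    ev <- c(1L + sample(1:3, n_real[i], replace = TRUE,
                        prob = config$evidence_probs),
            rep(1L, n_spur[i]))
    tibble::tibble(strain_id = strains$strain_id[i],
                   replicon_id = ifelse(on_pl, "plasmid1", "chr"),
                   start = start, end = start + len,
                   n_spacers = spacers,
                   evidence_level = ev,
                   on_plasmid = on_pl)
  }))
  if (nrow(arrays) == 0L) {
    arrays <- tibble::tibble(strain_id = character(),
                             replicon_id = character(), start = integer(),
                             end = integer(), n_spacers = integer(),
                             evidence_level = integer(),
                             on_plasmid = logical())
  }
  list(strains = strains, truth = truth, arrays = arrays)
}

#' Simulate two detectors' outputs around the truth
#'
#' Each detector reports each true prophage independently with its
#' sensitivity; reported boundaries are perturbed by rounded normal jitter
#' (clamped inside the genome). Poisson false positives are added at
#' `detector_fpr_per_Mb`, with lengths from the prophage length distribution
#' and uniform placement.
#'
#' @param truth Truth intervals from [simulate_strain_census()].
#' @param strains Strain table from the same call.
#' @param config From [sim_config()].
#' @param seed Optional RNG seed.
#' @return List of two detection-record tibbles, `A` and `B`.
#' @export
simulate_detector_outputs <- function(truth, strains,
                                      config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genome <- setNames(strains$genome_bp, strains$strain_id)
  one_detector <- function(label, sens) {
    det <- if (nrow(truth) == 0L) truth[0, ] else {
      keep <- runif(nrow(truth)) < sens
      truth[keep, , drop = FALSE]
    }
    if (nrow(det) > 0L && config$boundary_jitter_sd > 0) {
      g <- genome[det$strain_id]
      det$start <- pmax(0L, as.integer(det$start +
        round(rnorm(nrow(det), 0, config$boundary_jitter_sd))))
      det$end <- pmin(as.integer(g), as.integer(det$end +
        round(rnorm(nrow(det), 0, config$boundary_jitter_sd))))
      det <- det[det$start < det$end, , drop = FALSE]
    }
    fps <- dplyr::bind_rows(lapply(seq_len(nrow(strains)), function(i) {
      nf <- rpois(1L, config$detector_fpr_per_Mb *
                    strains$genome_bp[i] / 1e6)
      if (nf == 0L) return(NULL)
      len <- rlength(nf, config)
      len <- pmin(len, strains$genome_bp[i] - 1L)
      st <- vapply(len, function(l) {
        sample.int(strains$genome_bp[i] - l, 1L)
      }, integer(1))
      tibble::tibble(strain_id = strains$strain_id[i], replicon_id = "chr",
                     start = st, end = st + len)
    }))
    out <- dplyr::bind_rows(det, fps)
    if (nrow(out) == 0L) {
      out <- tibble::tibble(strain_id = character(),
                            replicon_id = character(),
                            start = integer(), end = integer())
    }
    out$detector <- label
    out$source_dialect <- "tsv1based"
    tibble::as_tibble(sort_intervals(
      out[, c("strain_id", "replicon_id", "detector", "start", "end",
              "source_dialect")]))
  }
  list(A = one_detector("A", config$detector_sensitivity_A),
       B = one_detector("B", config$detector_sensitivity_B))
}

#' Simulate a strain trait table coupled to the census truth
#'
#' Cell volumes are lognormal and coupled to the prophage-count rank through
#' a Gaussian copula targeting Spearman `trait_rho`: the count's average
#' rank (tie-block midpoint) is mapped to a standardized latent normal
#' score, the latent Pearson correlation is `2 sin(pi rho / 6)`, and the
#' volume is the lognormal quantile of the correlated score. Rod dimensions
#' consistent with the volume (aspect ratio 3) are back-computed. Remaining
#' traits are drawn independently of the census.
#'
#' @param strains Strain table from [simulate_strain_census()].
#' @param truth Truth intervals from the same call (defines prophage counts).
#' @param config From [sim_config()].
#' @param seed Optional RNG seed.
#' @return Trait tibble accepted by [validate_traits()].
#' @export
simulate_traits <- function(strains, truth, config = sim_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(strains)
  counts <- as.integer(table(factor(truth$strain_id,
                                    levels = strains$strain_id)))
  # average-rank (tie-block midpoint) transform: coupling to the midpoint
  # rather than a within-block uniform avoids wasting correlation on
  # orderings the tied Spearman cannot see, so the realized average-rank
  # Spearman stays calibrated to trait_rho despite integer-count ties
  m_count <- (rank(counts, ties.method = "average") - 0.5) / n
  z_count <- qnorm(pmin(1 - 1e-12, pmax(1e-12, m_count)))
  z_count <- if (sd(z_count) > 0) {
    (z_count - mean(z_count)) / sd(z_count)
  } else rnorm(n)  # all counts tied: no rank signal to couple to
  r_latent <- 2 * sin(pi * config$trait_rho / 6)
  z_vol <- r_latent * z_count + sqrt(1 - r_latent^2) * rnorm(n)
  volume <- qlnorm(pnorm(z_vol), config$volume_meanlog, config$volume_sdlog)
  # rod of aspect ratio 3: V = pi r^2 L, L = 6 r  =>  r = (V / (6 pi))^(1/3)
  r_cell <- (volume / (6 * pi))^(1 / 3)
  doubling <- rlnorm(n, log(14), 0.6)
  thermo <- runif(n) < 0.11
  opt_T <- ifelse(thermo, runif(n, 50, 70), runif(n, 25, 38))
  traits <- tibble::tibble(
    strain_id = strains$strain_id,
    family = strains$family,
    gram = sample(c("negative", "positive"), n, TRUE, prob = c(0.85, 0.15)),
    motile = sample(c(TRUE, FALSE, NA), n, TRUE, prob = c(0.6, 0.3, 0.1)),
    shape = "rod",
    length_um = 6 * r_cell,
    width_um = 2 * r_cell,
    volume_um3 = volume,
    habitat = strains$habitat,
    opt_pH = rnorm(n, 7.1, 0.5),
    opt_T = opt_T,
    temp_class = ifelse(thermo, "thermophile", "mesophile"),
    doubling_h = doubling,
    genome_bp = strains$genome_bp,
    gc_pct = strains$gc_pct,
    oxidizer = sample(c("incomplete", "complete", "unknown"), n, TRUE,
                      prob = c(0.6, 0.3, 0.1))
  )
  validate_traits(traits, where = "simulated traits")
}

#' Simulate an all-vs-all homology hit table with planted clusters
#'
#' Prophages are assigned to `n_clusters` families; each within-cluster pair
#' of prophages receives `within_pairs` distinct qualifying ORF-pair hits and
#' each between-cluster pair `between_pairs`, so that with the >= 10 edge
#' rule the significant-edge components recover the planted clusters.
#' Sub-threshold decoy hits (short alignments, weak e-values, low identity)
#' are interleaved.
#'
#' @param prophage_ids Character vector of prophage ids.
#' @param config From [sim_config()] (cluster spec fields).
#' @param seed Optional RNG seed.
#' @return List: `hits` (BLAST-style columns as in [read_homology_hits()]),
#'   `clusters` (named cluster assignment).
#' @export
simulate_homology_hits <- function(prophage_ids, config = sim_config(),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- max(1L, min(config$n_clusters, length(prophage_ids)))
  cluster <- setNames(rep_len(seq_len(k), length(prophage_ids)),
                      prophage_ids)
  mk_hits <- function(p1, p2, n, qualifying) {
    if (n == 0L) return(NULL)
    idx <- seq_len(n)
    if (qualifying) {
      tibble::tibble(
        query_orf = paste0(p1, ":", idx),
        subject_orf = paste0(p2, ":", idx),
        pct_identity = runif(n, 35, 90),
        aln_length = as.integer(round(runif(n, 80, 300))),
        evalue = 10^(-runif(n, 6, 40)),
        bitscore = runif(n, 60, 400))
    } else {
      # decoys fail exactly one criterion each, cycling through the three
      why <- (idx %% 3L)
      tibble::tibble(
        query_orf = paste0(p1, ":d", idx),
        subject_orf = paste0(p2, ":d", idx),
        pct_identity = ifelse(why == 0L, runif(n, 5, 25), runif(n, 35, 90)),
        aln_length = as.integer(ifelse(why == 1L, round(runif(n, 5, 20)),
                                       round(runif(n, 80, 300)))),
        evalue = ifelse(why == 2L, 10^(-runif(n, 0, 3.9)),
                        10^(-runif(n, 6, 40))),
        bitscore = runif(n, 20, 60))
    }
  }
  prs <- if (length(prophage_ids) >= 2L) {
    combn(prophage_ids, 2L, simplify = FALSE)
  } else list()
  hits <- dplyr::bind_rows(lapply(prs, function(pp) {
    same <- cluster[pp[1L]] == cluster[pp[2L]]
    n_q <- if (same) config$within_pairs else config$between_pairs
    dplyr::bind_rows(
      mk_hits(pp[1L], pp[2L], n_q, qualifying = TRUE),
      mk_hits(pp[1L], pp[2L], config$decoys_per_pair, qualifying = FALSE))
  }))
  list(hits = hits, clusters = cluster)
}

#' Simulate a protein alignment down a random tree (synthetic marker gene)
#'
#' A stand-in for a curated marker alignment: an ancestral sequence is
#' evolved along a random rooted tree, substituting each site on each edge
#' with probability `min(0.75, edge length)` to a uniformly random different
#' residue. Suitable for exercising the distance/NJ/bootstrap stage offline.
#'
#' @param n_taxa Number of taxa (>= 3).
#' @param n_sites Alignment length (default 523).
#' @param seed Optional RNG seed.
#' @param scale Multiplier on the random tree's edge lengths (default 0.5).
#' @return List: `alignment` (named character vector) and `tree` (the
#'   generating `phylo`).
#' @export
simulate_protein_alignment <- function(n_taxa, n_sites = 523L, seed = NULL,
                                       scale = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  tree <- ape::rtree(n_taxa)
  tree$edge.length <- tree$edge.length * scale
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  seqs <- vector("list", n_nodes)
  root <- ape::Ntip(tree) + 1L
  seqs[[root]] <- sample(aa, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {  # ape edges are in preorder
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    p_sub <- min(0.75, tree$edge.length[e])
    s <- seqs[[parent]]
    hit <- runif(n_sites) < p_sub
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(old) {
        sample(setdiff(aa, old), 1L)
      }, character(1))
    }
    seqs[[child]] <- s
  }
  aln <- vapply(seq_len(ape::Ntip(tree)), function(i) {
    paste(seqs[[i]], collapse = "")
  }, character(1))
  names(aln) <- tree$tip.label
  list(alignment = aln, tree = tree)
}

#' Write a full set of simulated pipeline inputs to a directory
#'
#' Emits every external file format the readers consume: the two detectors'
#' outputs in the 1-based TSV dialect (plus per-strain BED for detector A),
#' the CRISPR table, the trait table, the truth intervals, and a 12-column
#' homology hit table.
#'
#' @param sim Output of [simulate_strain_census()].
#' @param detectors Output of [simulate_detector_outputs()].
#' @param traits Output of [simulate_traits()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulated_inputs <- function(sim, detectors, traits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    detector_a = file.path(dir, "detector_A.tsv"),
    detector_b = file.path(dir, "detector_B.tsv"),
    crispr = file.path(dir, "crispr_arrays.tsv"),
    traits = file.path(dir, "strain_traits.tsv"),
    truth = file.path(dir, "truth_intervals.tsv"),
    strains = file.path(dir, "strains.tsv")
  )
  write_intervals_tsv1based(detectors$A, paths[["detector_a"]])
  write_intervals_tsv1based(detectors$B, paths[["detector_b"]])
  write_tsv_plain(sim$arrays, paths[["crispr"]])
  write_tsv_plain(traits, paths[["traits"]])
  write_tsv_plain(sim$truth, paths[["truth"]])
  write_tsv_plain(sim$strains, paths[["strains"]])
  invisible(paths)
}
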