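## Consensus prophage calling from two independent detectors.
##
## A region counts as a prophage only when both detectors support it: every
## A-interval/B-interval pair overlapping by >= min_overlap bp contributes
## either its intersection (default) or its union span, and the emitted
## regions are then merged (book-ended regions included) per replicon.

#' Consensus prophage calls from two detectors' interval sets
#'
#' Regions supported by only one detector are discarded. For each overlapping
#' A/B interval pair the pairwise intersection (`mode = "intersection"`,
#' default, the conservative coordinate choice) or the pairwise union span
#' (`mode = "union"`) is emitted; emitted regions that overlap or are
#' book-ended on the same replicon are merged into a single call. Calls are
#' numbered serially per strain by start coordinate as
#' `<strainIndex>R<serial>` (e.g. `1R5`).
#'
#' @param setA,setB Detection records (see [read_intervals()]) from the two
#'   detectors; internal 0-based half-open coordinates.
#' @param mode `"intersection"` or `"union"`.
#' @param min_overlap Minimum overlap in bp for a pair to count (default 1;
#'   no reciprocal-fraction requirement).
#' @param strains Optional character vector of known strain ids; records from
#'   other strains raise an error, and the strain index used in prophage ids
#'   follows this ordering. Defaults to the sorted strains present.
#' @param junctions Optional named list (per strain) of junction positions
#'   from [concatenate_replicons()]; calls spanning a junction are dropped.
#' @return Tibble of prophage calls: `prophage_id, strain_id, replicon_id,
#'   start, end, length, size_class, virfam_label`.
#' @export
consensus_calls <- function(setA, setB, mode = c("intersection", "union"),
                            min_overlap = 1L, strains = NULL,
                            junctions = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(min_overlap) || min_overlap < 1) {
    stop("min_overlap must be >= 1", call. = FALSE)
  }
  validate_intervals(setA, "detector A")
  validate_intervals(setB, "detector B")
  seen <- union(unique(setA$strain_id), unique(setB$strain_id))
  if (is.null(strains)) {
    strains <- sort(seen)
  } else {
    unknown <- setdiff(seen, strains)
    if (length(unknown) > 0L) {
      stop("records from unknown strain(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  empty <- tibble::tibble(prophage_id = character(), strain_id = character(),
                          replicon_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          size_class = character(), virfam_label = character())
  keyA <- paste(setA$strain_id, setA$replicon_id, sep = "\r")
  keyB <- paste(setB$strain_id, setB$replicon_id, sep = "\r")
  out <- list()
  for (key in intersect(unique(keyA), unique(keyB))) {
    a <- setA[keyA == key, , drop = FALSE]
    b <- setB[keyB == key, , drop = FALSE]
    ira <- IRanges::IRanges(start = a$start + 1L, end = a$end)
    irb <- IRanges::IRanges(start = b$start + 1L, end = b$end)
    hits <- IRanges::findOverlaps(ira, irb, minoverlap = min_overlap)
    if (length(hits) == 0L) next
    qa <- ira[S4Vectors::queryHits(hits)]
    qb <- irb[S4Vectors::subjectHits(hits)]
    emitted <- if (mode == "intersection") {
      IRanges::pintersect(qa, qb)
    } else {
      IRanges::punion(qa, qb, fill.gap = TRUE)
    }
    merged <- IRanges::reduce(emitted)  # merges overlapping and book-ended
    out[[key]] <- tibble::tibble(
      strain_id   = a$strain_id[1L],
      replicon_id = a$replicon_id[1L],
      start       = IRanges::start(merged) - 1L,
      end         = IRanges::end(merged)
    )
  }
  if (length(out) == 0L) return(empty)
  calls <- dplyr::bind_rows(out)
  calls <- calls[order(match(calls$strain_id, strains), calls$replicon_id,
                       calls$start), , drop = FALSE]
  if (!is.null(junctions)) {
    keep <- vapply(seq_len(nrow(calls)), function(i) {
      j <- junctions[[calls$strain_id[i]]]
      is.null(j) || !any(j > calls$start[i] & j < calls$end[i])
    }, logical(1))
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls) == 0L) return(empty)
  serial <- stats::ave(seq_len(nrow(calls)), calls$strain_id,
                       FUN = seq_along)
  calls$prophage_id <- paste0(match(calls$strain_id, strains), "R", serial)
  calls$length <- calls$end - calls$start
  calls$size_class <- classify_size(calls$length)
  calls$virfam_label <- "unassigned"
  calls[, c("prophage_id", "strain_id", "replicon_id", "start", "end",
            "length", "size_class", "virfam_label")]
}

#' Prophage size class
#'
#' Small prophages are those shorter than 30 kb (strict inequality); such
#' elements are enriched in remnants and mobile elements.
#'
#' @param length_bp Integer vector of call lengths (bp), all >= 1.
#' @return Character vector, `"small"` or `"standard"`.
#' @export
classify_size <- function(length_bp) {
  stopifnot(all(length_bp >= 1))
  ifelse(length_bp < 30000L, "small", "standard")
}

#' Per-strain prophage genome burden
#'
#' @param calls Prophage calls for one strain (post-merge, non-overlapping).
#' @param genome_bp Total genome size in bp (> 0).
#' @return One-row tibble: `n_prophages, total_prophage_bp, genome_bp,
#'   prophage_fraction, prophage_pct` (percent, 2 decimals, half-up).
#' @export
genome_burden <- function(calls, genome_bp) {
  if (!is.numeric(genome_bp) || genome_bp <= 0) {
    stop("genome_bp must be > 0", call. = FALSE)
  }
  total <- if (nrow(calls) == 0L) 0L else sum(calls$end - calls$start)
  frac <- total / genome_bp
  tibble::tibble(
    n_prophages = nrow(calls),
    total_prophage_bp = as.integer(total),
    genome_bp = as.numeric(genome_bp),
    prophage_fraction = frac,
    prophage_pct = round_half_up(100 * frac, 2)
  )
}

#' Build the per-strain census table
#'
#' @param calls All prophage calls (as from [consensus_calls()]).
#' @param strains Tibble with `strain_id` and `genome_bp` (one row/strain).
#' @param arrays Optional filtered CRISPR arrays, for the `n_crispr` column.
#' @return Tibble with one row per strain: `strain_id, n_prophages,
#'   total_prophage_bp, genome_bp, prophage_fraction, prophage_pct, n_crispr`.
#' @export
strain_census <- function(calls, strains, arrays = NULL) {
  stopifnot(all(c("strain_id", "genome_bp") %in% names(strains)))
  rows <- lapply(seq_len(nrow(strains)), function(i) {
    sid <- strains$strain_id[i]
    b <- genome_burden(calls[calls$strain_id == sid, , drop = FALSE],
                       strains$genome_bp[i])
    b$strain_id <- sid
    b
  })
  out <- dplyr::bind_rows(rows)
  out$n_crispr <- if (is.null(arrays)) 0L else
    as.integer(table(factor(arrays$strain_id,
                            levels = strains$strain_id))[out$strain_id])
  out[, c("strain_id", "n_prophages", "total_prophage_bp", "genome_bp",
          "prophage_fraction", "prophage_pct", "n_crispr")]
}

#' Census summary: lysogeny prevalence overall and by stratum
#'
#' A lysogen carries >= 1 prophage; a poly-lysogen >= 2. Prevalence
#' percentages are rounded half-up to the nearest integer.
#'
#' @param census Per-strain census rows ([strain_census()]).
#' @param strata Optional vector (length nrow(census)) or the name of a
#'   column in `census` giving a stratum label per strain.
#' @return Tibble with one row per stratum plus an `"overall"` row:
#'   `stratum, n_strains, n_lysogens, lysogen_pct, total_prophages,
#'   n_polylysogens`.
#' @export
census_summary <- function(census, strata = NULL) {
  if (nrow(census) == 0L) stop("empty census", call. = FALSE)
  if (is.character(strata) && length(strata) == 1L &&
      strata %in% names(census)) {
    strata <- census[[strata]]
  }
  one <- function(rows, label) {
    tibble::tibble(
      stratum = label,
      n_strains = nrow(rows),
      n_lysogens = sum(rows$n_prophages >= 1L),
      lysogen_pct = round_half_up(100 * sum(rows$n_prophages >= 1L) /
                                    nrow(rows)),
      total_prophages = sum(rows$n_prophages),
      n_polylysogens = sum(rows$n_prophages >= 2L)
    )
  }
  out <- one(census, "overall")
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(census))
    per <- lapply(sort(unique(strata)), function(s) {
      one(census[strata == s, , drop = FALSE], s)
    })
    out <- dplyr::bind_rows(out, per)
  }
  out
}
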