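#' srpcensus: prophage and CRISPR census for sulfate-reducing prokaryotes
#'
#' Internal genomic coordinates are 0-based, half-open everywhere
#' (BED-native): an interval `[start, end)` has length `end - start`.
#' 1-based inclusive inputs (GFF3, the legacy 1-based TSV dialect) are
#' converted on read with `start <- start - 1`.
#'
#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats median rnorm rlnorm rpois rgeom rnbinom runif rbinom
#'   qnorm pnorm qlnorm setNames complete.cases cor prcomp pt phyper
#'   fisher.test wilcox.test sd quantile cophenetic
#' @importFrom utils read.delim write.table head combn
"_PACKAGE"

## Controlled vocabularies ----------------------------------------------------

#' Controlled vocabularies for strain trait tables
#'
#' Fixed token sets for the categorical trait columns. Habitat follows the
#' six-way classification used for SRP isolation sources; growth class is
#' derived from the minimum doubling time at optimum conditions (fast iff
#' doubling time <= 12 h).
#'
#' @format A named list of character vectors.
#' @export
trait_vocab <- list(
  habitat      = c("freshwater", "brackish", "marine", "soil", "engineered",
                   "host_associated"),
  gram         = c("positive", "negative", "unknown"),
  shape        = c("rod", "coccus", "ovoid", "other"),
  temp_class   = c("mesophile", "thermophile", "psychrotroph"),
  growth_class = c("fast", "slow"),
  oxidizer     = c("complete", "incomplete", "unknown"),
  detector     = c("A", "B"),
  virfam_label = c("Myoviridae", "Siphoviridae", "Podoviridae",
                   "unclassified", "unassigned")
)

#' Doubling-time boundary (hours) separating fast from slow growers
#' @keywords internal
FAST_DOUBLING_H <- 12

#' Round half away from zero
#'
#' Base `round()` uses banker's rounding; census prevalences are reported
#' half-up (0.5 always rounds up), which is the convention that reproduces
#' every printed survey percentage.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Interval reading -----------------------------------------------------------

validate_intervals <- function(x, where = "intervals") {
  stopifnot(is.data.frame(x))
  need <- c("strain_id", "replicon_id", "detector", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing columns: %s", where, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0L) {
    stop(sprintf(
      "%s: invalid interval (need 0 <= start < end) in row(s) %s",
      where, paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

sort_intervals <- function(x) {
  x[order(x$strain_id, x$replicon_id, x$start), , drop = FALSE]
}

#' Read detector interval output into normalized detection records
#'
#' Reads one prophage detector's reported regions and normalizes them to the
#' internal 0-based half-open convention. BED input is already 0-based
#' half-open; GFF3 and the legacy 1-based-inclusive TSV dialect are converted
#' with `start <- start - 1`.
#'
#' BED and GFF3 files describe one strain's replicons, so `strain_id` must be
#' supplied; the TSV dialect carries a `strain_id` column
#' (`strain_id, replicon_id, start, end`, 1-based inclusive).
#'
#' @param path File to read.
#' @param format One of `"bed"`, `"gff3"`, `"tsv1based"`.
#' @param detector Detector label, `"A"` or `"B"`.
#' @param strain_id Strain identifier (required for bed/gff3).
#' @return A tibble of detection records, sorted by (strain, replicon, start),
#'   with columns `strain_id, replicon_id, detector, start, end,
#'   source_dialect`.
#' @export
read_intervals <- function(path, format = c("bed", "gff3", "tsv1based"),
                           detector = c("A", "B"), strain_id = NULL) {
  format <- match.arg(format)
  detector <- match.arg(detector)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format %in% c("bed", "gff3")) {
    if (is.null(strain_id)) {
      stop("strain_id is required for bed/gff3 input", call. = FALSE)
    }
    gr <- tryCatch(
      rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
      error = function(e) {
        stop(sprintf("parse error in %s (%s): %s", path, format,
                     conditionMessage(e)), call. = FALSE)
      })
    out <- tibble::tibble(
      strain_id   = strain_id,
      replicon_id = as.character(GenomicRanges::seqnames(gr)),
      detector    = detector,
      # GRanges is 1-based inclusive internally regardless of source format
      start       = GenomicRanges::start(gr) - 1L,
      end         = GenomicRanges::end(gr)
    )
  } else {
    tab <- read_tsv_checked(path, c("strain_id", "replicon_id", "start", "end"),
                            numeric_cols = c("start", "end"))
    out <- tibble::tibble(
      strain_id   = as.character(tab$strain_id),
      replicon_id = as.character(tab$replicon_id),
      detector    = detector,
      start       = as.integer(tab$start) - 1L,  # 1-based inclusive on disk
      end         = as.integer(tab$end)
    )
  }
  out$source_dialect <- format
  validate_intervals(out, where = path)
  tibble::as_tibble(sort_intervals(out))
}

#' Write detection records or prophage calls as BED
#'
#' Internal coordinates are already BED's 0-based half-open convention, so the
#' interval columns are written unchanged; the name column carries the
#' detector label or the prophage id.
#'
#' @param x Tibble with `replicon_id`, `start`, `end` and either `detector`
#'   or `prophage_id`.
#' @param path Output file.
#' @export
write_intervals_bed <- function(x, path) {
  name <- if ("prophage_id" %in% names(x)) x$prophage_id else x$detector
  gr <- GenomicRanges::GRanges(
    seqnames = x$replicon_id,
    ranges   = IRanges::IRanges(start = x$start + 1L, end = x$end),
    name     = name
  )
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# Hand parser only for the pipeline's own TSV dialects (no installed package
# owns these); reports 1-based file line numbers on failure.
read_tsv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("parse error in %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "")
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                   path, col, bad[1L] + 1L), call. = FALSE)  # +1 for header
    }
    tab[[col]] <- v
  }
  tab
}

## Homology hits --------------------------------------------------------------

#' Read BLAST-style 12-column tabular protein hits
#'
#' Consumes all-vs-all ORF alignment output in the standard 12-column tabular
#' layout (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`, no header). Columns 1, 2, 3, 4, 11 and 12 map to the
#' homology-hit fields; extra columns are ignored. ORF identifiers follow the
#' `prophage_id:orf_index` convention.
#'
#' @param path Tabular hits file.
#' @return Tibble with `query_orf, subject_orf, pct_identity, aln_length,
#'   evalue, bitscore`; empty (with a warning) for an empty file.
#' @export
read_homology_hits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(query_orf = character(), subject_orf = character(),
                          pct_identity = numeric(), aln_length = integer(),
                          evalue = numeric(), bitscore = numeric())
  if (file.size(path) == 0L) {
    warning("empty homology hit file: ", path, call. = FALSE)
    return(empty)
  }
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) {
    stop(sprintf("%s: expected >= 12 tab-separated columns, found %d",
                 path, ncol(tab)), call. = FALSE)
  }
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric %s at line %d", path, name, bad[1L]),
           call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    query_orf    = as.character(tab[[1L]]),
    subject_orf  = as.character(tab[[2L]]),
    pct_identity = num(3L, "pident"),
    aln_length   = as.integer(num(4L, "length")),
    evalue       = num(11L, "evalue"),
    bitscore     = num(12L, "bitscore")
  )
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop(path, ": pident outside [0, 100]", call. = FALSE)
  }
  if (any(out$aln_length < 1L)) stop(path, ": aln_length < 1", call. = FALSE)
  if (any(out$evalue < 0)) stop(path, ": negative e-value", call. = FALSE)
  out
}

## Trait table ----------------------------------------------------------------

#' Read a strain trait table
#'
#' Reads the ecophysiological trait TSV (one row per strain). Categorical
#' columns are validated against [trait_vocab]; missing optional values stay
#' `NA` (never imputed). `growth_class` is derived from `doubling_h` when
#' absent: fast iff doubling time at optimum conditions is <= 12 h.
#'
#' @param path TSV with header. Required columns: `strain_id`, `family`,
#'   `habitat`, `genome_bp`, `gc_pct`. Optional: `gram, motile, shape,
#'   length_um, width_um, volume_um3, area_um2, opt_pH, opt_T, temp_class,
#'   doubling_h, growth_class, oxidizer`.
#' @return Tibble of strain traits.
#' @export
read_trait_table <- function(path) {
  tab <- read_tsv_checked(
    path, c("strain_id", "family", "habitat", "genome_bp", "gc_pct"),
    numeric_cols = intersect(
      c("length_um", "width_um", "volume_um3", "area_um2", "opt_pH", "opt_T",
        "doubling_h", "genome_bp", "gc_pct"), names(
          read.delim(path, nrows = 1, sep = "\t", check.names = FALSE))))
  validate_traits(tibble::as_tibble(tab), where = path)
}

#' Validate (and complete) a strain trait table
#'
#' @param traits Data frame of strain traits.
#' @param where Label used in error messages.
#' @return The validated tibble with `growth_class` filled in from
#'   `doubling_h` where absent.
#' @export
validate_traits <- function(traits, where = "traits") {
  traits <- tibble::as_tibble(traits)
  for (col in c("habitat", "gram", "shape", "temp_class", "growth_class",
                "oxidizer")) {
    if (!col %in% names(traits)) next
    v <- traits[[col]]
    bad <- !is.na(v) & v != "" & !(v %in% trait_vocab[[col]])
    if (any(bad)) {
      stop(sprintf("%s: unknown %s token(s) %s; allowed: {%s}", where, col,
                   paste(unique(v[bad]), collapse = ", "),
                   paste(trait_vocab[[col]], collapse = ", ")), call. = FALSE)
    }
    v[!is.na(v) & v == ""] <- NA_character_
    traits[[col]] <- v
  }
  if (any(!is.na(traits$gc_pct) & (traits$gc_pct < 0 | traits$gc_pct > 100))) {
    stop(where, ": gc_pct outside [0, 100]", call. = FALSE)
  }
  if (!"growth_class" %in% names(traits)) traits$growth_class <- NA_character_
  if ("doubling_h" %in% names(traits)) {
    derived <- ifelse(traits$doubling_h <= FAST_DOUBLING_H, "fast", "slow")
    fill <- is.na(traits$growth_class) & !is.na(traits$doubling_h)
    traits$growth_class[fill] <- derived[fill]
    clash <- !is.na(traits$growth_class) & !is.na(traits$doubling_h) &
      traits$growth_class != derived
    if (any(clash)) {
      stop(sprintf(
        "%s: growth_class inconsistent with doubling_h (fast iff <= %d h) for strain(s) %s",
        where, FAST_DOUBLING_H,
        paste(traits$strain_id[clash], collapse = ", ")), call. = FALSE)
    }
  }
  traits
}

## CRISPR table ---------------------------------------------------------------

#' Read a CRISPR array table
#'
#' Input TSV schema: `strain_id, replicon_id, start, end, n_spacers,
#' evidence_level, on_plasmid` with 0-based half-open coordinates (the
#' pipeline's own export dialect). Evidence level is the detector confidence
#' grade 1-4.
#'
#' @param path TSV file.
#' @return Tibble of CRISPR arrays.
#' @export
read_crispr_table <- function(path) {
  tab <- read_tsv_checked(
    path,
    c("strain_id", "replicon_id", "start", "end", "n_spacers",
      "evidence_level", "on_plasmid"),
    numeric_cols = c("start", "end", "n_spacers", "evidence_level"))
  out <- tibble::tibble(
    strain_id      = as.character(tab$strain_id),
    replicon_id    = as.character(tab$replicon_id),
    start          = as.integer(tab$start),
    end            = as.integer(tab$end),
    n_spacers      = as.integer(tab$n_spacers),
    evidence_level = as.integer(tab$evidence_level),
    on_plasmid     = as.logical(tab$on_plasmid)
  )
  validate_crispr(out, where = path)
}

#' @rdname read_crispr_table
#' @param arrays Data frame of CRISPR arrays.
#' @param where Label used in error messages.
#' @export
validate_crispr <- function(arrays, where = "crispr") {
  arrays <- tibble::as_tibble(arrays)
  if (any(arrays$start >= arrays$end)) {
    stop(where, ": CRISPR array with start >= end", call. = FALSE)
  }
  if (any(!arrays$evidence_level %in% 1:4)) {
    stop(where, ": evidence_level outside {1,2,3,4}", call. = FALSE)
  }
  if (any(arrays$n_spacers < 1L)) {
    stop(where, ": n_spacers must be >= 1", call. = FALSE)
  }
  arrays
}

#' Write a tibble as a plain TSV (the pipeline dialect)
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv_plain <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write detection records in the 1-based inclusive TSV dialect
#'
#' Round-trip companion of `read_intervals(format = "tsv1based")`.
#' @param x Detection records (internal 0-based half-open).
#' @param path Output path.
#' @export
write_intervals_tsv1based <- function(x, path) {
  out <- data.frame(strain_id = x$strain_id, replicon_id = x$replicon_id,
                    start = x$start + 1L, end = x$end)
  write_tsv_plain(out, path)
}

#' Concatenate a strain's replicons into one coordinate system
#'
#' Compatibility helper reproducing the workaround of analysing short plasmids
#' concatenated to the chromosome: replicons are laid end-to-end with
#' 0-length junctions, and the junction positions are returned so that calls
#' spanning a junction can be rejected downstream.
#'
#' @param intervals Detection records for one strain.
#' @param replicon_lengths Named integer vector of replicon lengths (bp); the
#'   concatenation order.
#' @return List with `intervals` (remapped to replicon `"concat"`) and
#'   `junctions` (0-based positions between adjacent replicons).
#' @export
concatenate_replicons <- function(intervals, replicon_lengths) {
  stopifnot(!is.null(names(replicon_lengths)))
  offs <- cumsum(c(0, unname(replicon_lengths)))
  offset <- setNames(offs[seq_along(replicon_lengths)], names(replicon_lengths))
  unknown <- setdiff(unique(intervals$replicon_id), names(replicon_lengths))
  if (length(unknown) > 0L) {
    stop("unknown replicon(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- intervals
  out$start <- unname(intervals$start + offset[intervals$replicon_id])
  out$end <- unname(intervals$end + offset[intervals$replicon_id])
  out$replicon_id <- "concat"
  list(intervals = tibble::as_tibble(out),
       junctions = offs[-c(1L, length(offs))])
}
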