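## CRISPR array census: evidence-level filtering, prevalence, spacer
## statistics, and localization relative to prophages.

#' Filter CRISPR arrays by detection evidence level
#'
#' An array is accepted when its evidence level (detector confidence grade,
#' 1-4) is at least `min_evidence`; the default 2 is the stringent criterion
#' that discriminates real arrays from spurious CRISPR-like elements.
#' Idempotent.
#'
#' @param arrays CRISPR array tibble (see [read_crispr_table()]).
#' @param min_evidence Integer in 1-4.
#' @return The retained arrays.
#' @export
filter_arrays <- function(arrays, min_evidence = 2L) {
  if (!is.numeric(min_evidence) || length(min_evidence) != 1L ||
      min_evidence < 1 || min_evidence > 4) {
    stop("min_evidence must be in 1..4", call. = FALSE)
  }
  validate_crispr(arrays)
  arrays[arrays$evidence_level >= min_evidence &
           arrays$evidence_level <= 4L, , drop = FALSE]
}

#' CRISPR prevalence overall and by stratum
#'
#' @param arrays Filtered arrays.
#' @param strains Tibble with `strain_id` (every strain surveyed, including
#'   array-free ones).
#' @param strata Optional stratum label per strain (vector aligned with
#'   `strains`, or a column name in `strains`).
#' @return Tibble per stratum plus `"overall"`: `stratum, n_strains,
#'   n_with_crispr, crispr_pct` (half-up integer), `total_arrays,
#'   min_arrays, max_arrays` (range over strains that carry >= 1 array;
#'   NA when none do).
#' @export
crispr_prevalence <- function(arrays, strains, strata = NULL) {
  if (nrow(strains) == 0L) stop("empty strain table", call. = FALSE)
  orphan <- setdiff(unique(arrays$strain_id), strains$strain_id)
  if (length(orphan) > 0L) {
    stop("array references unknown strain(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (is.character(strata) && length(strata) == 1L &&
      strata %in% names(strains)) {
    strata <- strains[[strata]]
  }
  counts <- as.integer(table(factor(arrays$strain_id,
                                    levels = strains$strain_id)))
  one <- function(idx, label) {
    n <- counts[idx]
    carriers <- n[n >= 1L]
    tibble::tibble(
      stratum = label,
      n_strains = length(idx),
      n_with_crispr = sum(n >= 1L),
      crispr_pct = round_half_up(100 * sum(n >= 1L) / length(idx)),
      total_arrays = sum(n),
      min_arrays = if (length(carriers)) min(carriers) else NA_integer_,
      max_arrays = if (length(carriers)) max(carriers) else NA_integer_
    )
  }
  out <- one(seq_len(nrow(strains)), "overall")
  if (!is.null(strata)) {
    stopifnot(length(strata) == nrow(strains))
    out <- dplyr::bind_rows(out, lapply(sort(unique(strata)), function(s) {
      one(which(strata == s), s)
    }))
  }
  out
}

#' Median spacer count per strain-level group
#'
#' The median is taken over array-level spacer counts (each array one
#' observation); an even count of arrays yields the mean of the two central
#' values.
#'
#' @param arrays Filtered arrays.
#' @param grouping Named vector mapping `strain_id` to a group label (e.g.
#'   lysogen / non-lysogen).
#' @return Tibble: `group, n_arrays, median_spacers`.
#' @export
spacer_summary <- function(arrays, grouping) {
  stopifnot(!is.null(names(grouping)))
  unknown <- setdiff(unique(arrays$strain_id), names(grouping))
  if (length(unknown) > 0L) {
    stop("no group label for strain(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  g <- unname(grouping[arrays$strain_id])
  dplyr::bind_rows(lapply(sort(unique(g)), function(lev) {
    sp <- arrays$n_spacers[g == lev]
    tibble::tibble(group = lev, n_arrays = length(sp),
                   median_spacers = median(sp))
  }))
}

#' Localize CRISPR arrays relative to prophage calls
#'
#' An array is prophage-embedded iff it is fully contained in a call
#' (`[a_start, a_end) subset of [p_start, p_end)` on the same strain and
#' replicon); partial overlap does not count.
#'
#' @param arrays Filtered arrays.
#' @param calls Prophage calls ([consensus_calls()]).
#' @return List with `arrays` (input plus logical `in_prophage` and the
#'   containing `prophage_id` or NA), `per_prophage` (embedded-array count
#'   per call) and `frac_prophages_with_array` (fraction of calls carrying
#'   >= 1 embedded array; `pct` half-up).
#' @export
arrays_in_prophages <- function(arrays, calls) {
  host <- rep(NA_character_, nrow(arrays))
  if (nrow(arrays) > 0L && nrow(calls) > 0L) {
    for (i in seq_len(nrow(arrays))) {
      hit <- which(calls$strain_id == arrays$strain_id[i] &
                     calls$replicon_id == arrays$replicon_id[i] &
                     calls$start <= arrays$start[i] &
                     calls$end >= arrays$end[i])
      if (length(hit) > 0L) host[i] <- calls$prophage_id[hit[1L]]
    }
  }
  arrays$in_prophage <- !is.na(host)
  arrays$prophage_id <- host
  per <- tibble::tibble(
    prophage_id = calls$prophage_id,
    n_embedded_arrays = as.integer(table(factor(host,
      levels = calls$prophage_id)))
  )
  frac <- if (nrow(calls) > 0L) mean(per$n_embedded_arrays >= 1L) else NA_real_
  list(arrays = arrays, per_prophage = per,
       frac_prophages_with_array = frac,
       pct = if (is.na(frac)) NA_real_ else round_half_up(100 * frac))
}
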