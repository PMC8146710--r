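## Association statistics relating prophage/CRISPR carriage to host traits:
## rank correlation with exact small-n permutation p-values, rank-sum tests,
## 2x2 contingency analysis with odds ratio, correlation-matrix PCA, and
## family-level aggregation. All statistics use complete-case deletion.

#' All permutations of 1..n (lexicographic)
#' @keywords internal
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Rank correlation with exact small-sample p-value
#'
#' Spearman uses average ranks for ties. The two-sided p-value is computed by
#' exact permutation enumeration (all `n!` orderings of one variable's ranks)
#' when `n <= 9`, and the t approximation
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n - 2` df otherwise. Pearson uses the
#' standard t test throughout.
#'
#' @param x,y Paired numeric vectors; incomplete pairs are dropped.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List: `estimate, p_value, n, method, exact`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs, have ", n, call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  if (method == "spearman") {
    rx <- rank(x); ry <- rank(y)
    r <- cor(rx, ry)
    if (n <= 9L) {
      perms <- all_permutations(n)
      # permute y's ranks; correlation of rx with each permuted ry
      rr <- apply(perms, 1L, function(p) cor(rx, ry[p]))
      p_val <- mean(abs(rr) >= abs(r) - 1e-12)
      exact <- TRUE
    } else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      p_val <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
      exact <- FALSE
    }
  } else {
    r <- cor(x, y)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p_val <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tt), df = n - 2)
    exact <- FALSE
  }
  list(estimate = r, p_value = min(1, p_val), n = n, method = method,
       exact = exact)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact null enumeration when the combined sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. Thin convention wrapper over
#' [stats::wilcox.test()].
#'
#' @param sample_a,sample_b Nonempty numeric vectors.
#' @return List: `statistic` (Mann-Whitney U of the first sample),
#'   `p_value`, `exact`, `n_a`, `n_b`.
#' @export
wilcoxon_ranksum <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0L
  exact <- (length(sample_a) + length(sample_b) <= 12L) && !ties
  wt <- suppressWarnings(
    wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = exact, n_a = length(sample_a), n_b = length(sample_b))
}

#' Odds ratio, Woolf confidence interval, and Fisher's exact test
#'
#' The sample odds ratio `OR = (a d) / (b c)` with the Woolf (logit) 95% CI
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction (+0.5 to every cell) is applied to
#' the estimate and CI and flagged. The two-sided p-value is Fisher's exact
#' test (sum of hypergeometric probabilities not exceeding the observed
#' table's), computed on the uncorrected table.
#'
#' @param tab 2x2 matrix of nonnegative counts; rows = factor 1 (e.g.
#'   lysogen yes/no), columns = factor 2 (e.g. CRISPR yes/no).
#' @return List: `odds_ratio, ci95` (length-2), `p_value`,
#'   `haldane_corrected`.
#' @export
fisher_or <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: odds ratio not estimable", call. = FALSE)
  }
  corrected <- any(tab == 0)
  ct <- if (corrected) tab + 0.5 else tab
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se <- sqrt(sum(1 / ct))
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  p <- fisher.test(tab)$p.value
  list(odds_ratio = or, ci95 = ci, p_value = p,
       haldane_corrected = corrected)
}

#' Correlation-matrix PCA of the trait matrix
#'
#' Complete-case rows only; columns standardized to mean 0, sd 1 (PCA on the
#' correlation matrix). Components are ordered by decreasing eigenvalue;
#' percent variance is `100 * eigenvalue / sum(eigenvalues)`. Each loading
#' vector is oriented so that its largest-magnitude entry is positive (sign
#' convention only).
#'
#' @param mat Numeric matrix or data frame, rows = strains, columns =
#'   variables.
#' @param exclude Optional row names (strain ids) dropped before the
#'   analysis (e.g. volume outliers).
#' @return List: `loadings` (variables x components), `percent_variance`,
#'   `scores` (complete-case rows x components), `n` (rows used).
#' @export
pca_traits <- function(mat, exclude = NULL) {
  m <- as.matrix(mat)
  if (!is.null(exclude) && !is.null(rownames(m))) {
    m <- m[!rownames(m) %in% exclude, , drop = FALSE]
  }
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L) {
    stop("need at least 3 complete-case rows, have ", nrow(m), call. = FALSE)
  }
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  if (any(apply(m, 2L, sd) == 0)) {
    stop("zero-variance column cannot be standardized", call. = FALSE)
  }
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ev <- pc$sdev^2
  list(loadings = rot, percent_variance = 100 * ev / sum(ev),
       scores = scores, n = nrow(m))
}

#' Assemble the eight-variable trait matrix for PCA
#'
#' Columns: `nproph, ncrispr, pH, T, gc_pct, doubling_h, volume, genome_bp`.
#'
#' @param census Per-strain census ([strain_census()]).
#' @param traits Trait table with geometry columns ([add_geometry()]).
#' @param lysogens_only Restrict to strains with >= 1 prophage (the PCA of
#'   the survey is over lysogens).
#' @return Numeric matrix with strain ids as row names.
#' @export
trait_matrix <- function(census, traits, lysogens_only = TRUE) {
  merged <- dplyr::left_join(census, traits, by = "strain_id")
  if (lysogens_only) merged <- merged[merged$n_prophages >= 1L, , drop = FALSE]
  m <- cbind(nproph = merged$n_prophages, ncrispr = merged$n_crispr,
             pH = merged$opt_pH, T = merged$opt_T, gc_pct = merged$gc_pct,
             doubling_h = merged$doubling_h, volume = merged$volume_um3,
             genome_bp = merged$genome_bp.x %||% merged$genome_bp)
  rownames(m) <- merged$strain_id
  m
}

#' Family-level aggregation and cross-family carriage correlation
#'
#' Aggregates the census per host family and tests whether families rank
#' similarly for total prophages and total CRISPR arrays (Spearman).
#'
#' @param census Per-strain census with `n_crispr`.
#' @param traits Trait table with `family` (and optionally `volume_um3`,
#'   `genome_bp`).
#' @return List: `table` (per family: `family, n_strains, total_prophages,
#'   total_crispr, mean_prophages, median_volume, median_genome_bp`) and
#'   `correlation` ([rank_correlation()] of total prophages vs total CRISPR
#'   across families; errors with a clear message when < 4 families).
#' @export
family_aggregate <- function(census, traits) {
  merged <- dplyr::left_join(census, traits[, intersect(
    c("strain_id", "family", "volume_um3", "genome_bp"), names(traits))],
    by = "strain_id")
  if (any(is.na(merged$family))) {
    stop("every strain needs a family label", call. = FALSE)
  }
  gb <- if ("genome_bp.x" %in% names(merged)) merged$genome_bp.x else
    merged$genome_bp
  fam <- sort(unique(merged$family))
  tab <- dplyr::bind_rows(lapply(fam, function(f) {
    rows <- merged[merged$family == f, , drop = FALSE]
    tibble::tibble(
      family = f,
      n_strains = nrow(rows),
      total_prophages = sum(rows$n_prophages),
      total_crispr = sum(rows$n_crispr),
      mean_prophages = mean(rows$n_prophages),
      median_volume = if ("volume_um3" %in% names(rows))
        median(rows$volume_um3, na.rm = TRUE) else NA_real_,
      median_genome_bp = median(gb[merged$family == f], na.rm = TRUE)
    )
  }))
  corr <- tryCatch(
    rank_correlation(tab$total_prophages, tab$total_crispr),
    error = function(e) {
      stop("cross-family correlation needs >= 4 families with variation: ",
           conditionMessage(e), call. = FALSE)
    })
  list(table = tab, correlation = corr)
}
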