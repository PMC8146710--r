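# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Per-base voting consensus: a base belongs to a call iff it is covered by
# >= 1 interval of each detector (intersection mode) or by >= 1 interval of
# either detector in a run that contains at least one doubly-covered base
# (union mode is not oracled; intersection is). Returns 0-based half-open
# intervals for a single replicon.
oracle_consensus_intersection <- function(a, b, genome_len) {
  cov <- function(iv) {
    x <- logical(genome_len)
    for (k in seq_len(nrow(iv))) {
      if (iv$end[k] > iv$start[k]) {
        x[(iv$start[k] + 1L):iv$end[k]] <- TRUE  # 1-based base index
      }
    }
    x
  }
  both <- cov(a) & cov(b)
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# C(n_a + n_b, n_a) group labelings (valid without ties).
oracle_wilcoxon_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  labelings <- combn(n, na)
  sums <- apply(labelings, 2L, function(idx) sum(r[idx]))
  mu <- na * (n + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Exact two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins and summing probabilities <= the observed table's.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Exact two-sided Spearman permutation p for tie-free data by enumerating
# all n! permutations (uses package-independent recursion).
oracle_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perm_rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  rr <- vapply(perm_rec(ry), function(p) abs(cor(rx, p)), numeric(1))
  mean(rr >= obs - 1e-12)
}

# Random single-replicon interval sets for consensus property tests
random_interval_set <- function(n_max, genome_len, strain = "s1",
                                replicon = "chr", detector = "A") {
  n <- sample.int(n_max, 1L)
  start <- sample.int(genome_len - 1L, n, replace = TRUE) - 1L
  len <- sample.int(max(2L, genome_len %/% 5L), n, replace = TRUE)
  end <- pmin(genome_len, start + len)
  ok <- end > start
  tibble::tibble(strain_id = strain, replicon_id = replicon,
                 detector = detector, start = start[ok], end = end[ok])
}
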