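# Independent oracles used across the test files. Each one re-derives the
# quantity it checks through a different route than the package code.

# Exhaustive single-effect Bayesian regression: per-column log Bayes factor
# from the marginal likelihood N(y; 0, sigma2 I + V x x') via
# Sherman-Morrison, plus the conjugate posterior moments.
oracle_single_effect <- function(X, y, V, sigma2) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lbf <- vapply(seq_len(ncol(Xc)), function(j) {
    x <- Xc[, j]
    xtx <- sum(x^2)
    xty <- sum(x * yc)
    -0.5 * log(1 + V * xtx / sigma2) +
      0.5 * V * xty^2 / (sigma2 * (sigma2 + V * xtx))
  }, numeric(1))
  w <- exp(lbf - max(lbf))
  alpha <- w / sum(w)
  post_var <- 1 / (1 / V + colSums(Xc^2) / sigma2)
  post_mean <- post_var * drop(crossprod(Xc, yc)) / sigma2
  list(lbf = lbf, alpha = alpha, mu = post_mean)
}

# Brute-force overlapping motif count by sliding a window over the string.
oracle_motif_count <- function(sequence, motif) {
  k <- nchar(motif)
  n <- nchar(sequence)
  if (n < k) return(0L)
  sum(vapply(seq_len(n - k + 1L),
             function(i) substr(sequence, i, i + k - 1L) == motif,
             logical(1)))
}

# Per-base coverage counting over explicit positions (0-based half-open).
oracle_consensus <- function(sample_beds, k, lo, hi) {
  pos <- lo:(hi - 1L)
  cover <- vapply(pos, function(p)
    sum(vapply(sample_beds, function(bed)
      any(bed$start <= p & p < bed$end), logical(1))), integer(1))
  ok <- cover >= k
  if (!any(ok)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = pos[starts[r$values]],
             end = pos[ends[r$values]] + 1L)
}

# Monte-Carlo Hardy-Weinberg oracle: permute the observed alleles into
# random genotype pairs and estimate P(het count as or less probable than
# observed) from the permutation distribution of the het count.
oracle_hwe_mc <- function(n_hom_ref, n_het, n_hom_alt, reps = 20000L,
                          seed = 1L) {
  set.seed(seed)
  n <- n_hom_ref + n_het + n_hom_alt
  alleles <- c(rep(0L, 2L * n_hom_ref + n_het),
               rep(1L, 2L * n_hom_alt + n_het))
  hets <- vapply(seq_len(reps), function(i) {
    a <- sample(alleles)
    sum(a[seq(1L, 2L * n, 2L)] != a[seq(2L, 2L * n, 2L)])
  }, integer(1))
  tab <- table(hets) / reps
  p_obs <- tab[as.character(n_het)]
  if (is.na(p_obs)) p_obs <- 0
  sum(tab[tab <= p_obs + 1e-12])
}

# Two-sided Fisher p by direct hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); nn <- sum(tab[2, ]); k <- sum(tab[, 1])
  probs <- stats::dhyper(0:k, m, nn, k)
  obs <- stats::dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Deterministic small HFS matrix used by several association tests.
toy_hfs <- function(n = 200L, m = 12L, seed = 7L) {
  set.seed(seed)
  x <- matrix(round(rnorm(n * m, 0, 0.1), 2), n, m)
  colnames(x) <- sprintf("chr1:%d-%d", (seq_len(m) - 1L) * 4096L,
                         seq_len(m) * 4096L)
  x
}
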