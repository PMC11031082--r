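#' Synthetic HFS data and the fine-mapping evaluation study
#'
#' The generator emulates the statistical shape of cohort-scale HFS data
#' without genotypes: per locus, a pool of haplotype scores with a
#' Beta-distributed frequency spectrum (so rare haplotypes exist), two
#' haplotype draws per individual coupled weakly along each block to match a
#' target adjacent-locus R^2, and centered, two-decimal HFS values. The
#' evaluation study plants causal loci with standard-normal effects, adds
#' noise to a target heritability, fine-maps every block, and scores
#' discrimination (AUC of PIP) and calibration (FDR of PIP > 0.95 calls).
#'
#' @name simulate
NULL

# comonotone correlation between two discrete score pools: the correlation
# of (s_a(U), s_b(U)) for one shared uniform U, used to calibrate coupling
.comonotone_cor <- function(freq_a, score_a, freq_b, score_b) {
  cum_a <- cumsum(freq_a); cum_b <- cumsum(freq_b)
  br <- sort(unique(c(0, cum_a, cum_b)))
  br[length(br)] <- 1
  len <- diff(br)
  midpoints <- (br[-1] + br[-length(br)]) / 2
  ia <- pmin(findInterval(midpoints, cum_a, left.open = TRUE) + 1L,
             length(score_a))
  ib <- pmin(findInterval(midpoints, cum_b, left.open = TRUE) + 1L,
             length(score_b))
  sa <- score_a[ia]
  sb <- score_b[ib]
  mu_a <- sum(len * sa); mu_b <- sum(len * sb)
  va <- sum(len * (sa - mu_a)^2); vb <- sum(len * (sb - mu_b)^2)
  if (va <= 0 || vb <= 0) return(NA_real_)
  sum(len * (sa - mu_a) * (sb - mu_b)) / sqrt(va * vb)
}

#' Generate a synthetic HFS matrix
#'
#' Each locus gets a haplotype score pool: a reference score, additional
#' haplotype scores scattered around it, and haplotype frequencies drawn
#' from Beta(0.2, 2) and renormalized, which guarantees a heavy tail of rare
#' haplotypes. Each individual draws two haplotypes per locus; along a block
#' the draw of one chromosome copy reuses the previous locus's quantile with
#' a coupling probability calibrated (from the pools' comonotone
#' correlations) so the median adjacent-locus HFS R^2 matches
#' \code{target_r2}. Values are centered on the reference score and rounded
#' to two decimals. Fully reproducible from \code{seed}.
#'
#' @param n individuals (>= 2).
#' @param m loci (>= 2).
#' @param n_blocks number of independent blocks; loci are split evenly and
#'   each block is placed on its own chromosome. Default 1.
#' @param target_r2 target median adjacent-locus R^2 in [0, 1); default
#'   0.013.
#' @param max_haplotypes haplotype pool size upper bound per locus (pool
#'   sizes are drawn in 4..max_haplotypes); default 16.
#' @param score_sd spread of non-reference haplotype scores around the
#'   reference at functionally variable loci; default 0.2.
#' @param prop_functional fraction of loci whose haplotypes carry real
#'   functional score differences; at the remaining loci haplotype scores
#'   differ from the reference only at scorer-noise level (\code{noise_sd}),
#'   so after two-decimal rounding those columns are typically constant and
#'   drop out of fine-mapping, as rounding is designed to do. Default 0.5.
#' @param noise_sd scorer-noise spread at non-functional loci; default 0.002
#'   (below half the rounding quantum).
#' @param seed integer seed.
#' @return list: \code{hfs} (n x m matrix, columns locus_id), \code{loci}
#'   (locus_id, chrom, start, end), \code{block_of} (block id per locus),
#'   \code{pools} (per-locus freq/score vectors), \code{coupling} (the
#'   calibrated reuse probability), \code{seed}.
#' @export
generate_synthetic_hfs <- function(n, m, n_blocks = 1L, target_r2 = 0.013,
                                   max_haplotypes = 16L, score_sd = 0.2,
                                   prop_functional = 0.5, noise_sd = 0.002,
                                   seed = 1L) {
  stopifnot(n >= 2L, m >= 2L, target_r2 >= 0, target_r2 < 1)
  set.seed(seed)
  block_of <- rep(seq_len(n_blocks), length.out = m)
  block_of <- sort(block_of)
  chrom <- paste0("chr", block_of)
  start <- unlist(lapply(split(seq_len(m), block_of), function(jj)
    (seq_along(jj) - 1L) * 4096L), use.names = FALSE)
  loci <- data.frame(
    locus_id = sprintf("%s:%d-%d", chrom, start, start + 4096L),
    chrom = chrom, start = start, end = start + 4096L,
    stringsAsFactors = FALSE)

  pools <- vector("list", m)
  functional <- stats::runif(m) < prop_functional
  for (j in seq_len(m)) {
    h <- sample(4:max_haplotypes, 1L)
    raw <- stats::rbeta(h, 0.2, 2)
    freq <- raw / sum(raw)
    ref <- stats::runif(1, 0.2, 0.8)
    sd_j <- if (functional[j]) score_sd else noise_sd
    scores <- c(ref, ref + stats::rnorm(h - 1L, 0, sd_j))
    pools[[j]] <- list(freq = freq, scores = scores, ref = ref,
                       functional = functional[j])
  }

  # calibrate the quantile-reuse probability from the pools themselves
  # (functional pairs: the others are mostly constant after rounding and
  # are excluded from the adjacent-R^2 median anyway)
  cpl <- 0
  if (target_r2 > 0 && m > 1L) {
    jj <- which(block_of[-m] == block_of[-1L])
    jj_f <- jj[functional[jj] & functional[jj + 1L]]
    if (length(jj_f) >= 2L) jj <- jj_f
    rq <- vapply(jj, function(j) .comonotone_cor(
      pools[[j]]$freq, pools[[j]]$scores,
      pools[[j + 1L]]$freq, pools[[j + 1L]]$scores), numeric(1))
    med_rq <- stats::median(abs(rq), na.rm = TRUE)
    if (!is.finite(med_rq) || med_rq <= 0)
      stop("infeasible correlation target: pools carry no usable signal")
    cpl <- min(sqrt(target_r2) / med_rq, 0.95)
  }

  hfs <- matrix(NA_real_, n, m,
                dimnames = list(sprintf("ind%04d", seq_len(n)),
                                loci$locus_id))
  for (copy in 1:2) {
    u_prev <- NULL
    for (j in seq_len(m)) {
      new_block <- j == 1L || block_of[j] != block_of[j - 1L]
      u <- stats::runif(n)
      if (!new_block && cpl > 0) {
        reuse <- stats::runif(n) < cpl
        u[reuse] <- u_prev[reuse]
      }
      pool <- pools[[j]]
      idx <- findInterval(u, cumsum(pool$freq), left.open = TRUE) + 1L
      idx[idx > length(pool$scores)] <- length(pool$scores)
      s <- pool$scores[idx]
      hfs[, j] <- if (copy == 1L) s else hfs[, j] + s
      u_prev <- u
    }
  }
  for (j in seq_len(m))
    hfs[, j] <- round_half_away(hfs[, j] / 2 - pools[[j]]$ref, 2L)

  list(hfs = hfs, loci = loci, block_of = block_of, pools = pools,
       coupling = cpl, seed = seed)
}

#' Simulate a quantitative trait from an HFS matrix
#'
#' A fraction of loci is causal with standard-normal effects; Gaussian noise
#' is added (orthogonalized and rescaled) so the in-sample genetic variance
#' fraction equals \code{h2} exactly.
#'
#' @param hfs individuals x loci HFS matrix.
#' @param prop_causal fraction of causal loci; default 0.01
#'   (\code{round(prop_causal * m)} must be >= 1).
#' @param h2 target heritability in (0, 1]; default 0.1.
#' @param seed integer seed.
#' @return list: \code{trait} (length-n vector), \code{truth} (causal ids,
#'   effects, h2, seed).
#' @export
simulate_trait <- function(hfs, prop_causal = 0.01, h2 = 0.1, seed = 1L) {
  m <- ncol(hfs)
  n_causal <- round(prop_causal * m)
  if (n_causal < 1L) stop("prop_causal * m must be at least 1")
  stopifnot(h2 > 0, h2 <= 1)
  set.seed(seed)
  for (attempt in 1:2) {
    causal <- sort(sample.int(m, n_causal))
    beta <- stats::rnorm(n_causal)
    g <- drop(hfs[, causal, drop = FALSE] %*% beta)
    if (stats::var(g) > 0) break
    if (attempt == 2L) stop("all causal columns constant; cannot simulate")
  }
  if (h2 < 1) {
    e <- stats::rnorm(length(g))
    e <- stats::residuals(stats::lm(e ~ g))          # exact orthogonality
    e <- e * sqrt(stats::var(g) * (1 - h2) / h2 / stats::var(e))
  } else e <- 0
  trait <- g + e
  list(trait = trait,
       truth = list(causal_ids = colnames(hfs)[causal], beta = beta,
                    h2 = h2, seed = seed))
}

#' Score fine-mapping output against the simulation truth
#'
#' AUC is the rank-based probability that a causal locus outranks a
#' non-causal one by PIP (ties mid-ranked); FDR is the false fraction of
#' loci called at \code{pip > pip_threshold} (0 when nothing is called,
#' flagged by \code{no_calls}). Loci without a PIP (NA: constant HFS columns
#' never enter the fine-mapping model) are not evaluable and are excluded,
#' on both the causal and the non-causal side.
#'
#' @param pip named per-locus PIP vector.
#' @param truth truth list from [simulate_trait()] (or a character vector of
#'   causal locus ids).
#' @param pip_threshold call threshold (strict); default 0.95.
#' @return list: auc, fdr, n_calls, tp, fp, no_calls.
#' @export
evaluate_finemap <- function(pip, truth, pip_threshold = 0.95) {
  causal_ids <- if (is.list(truth)) truth$causal_ids else truth
  if (!length(causal_ids)) stop("no causal loci in truth")
  pip <- pip[is.finite(pip)]       # loci without a PIP are not evaluable
  is_causal <- names(pip) %in% causal_ids
  n_c <- sum(is_causal); n_nc <- sum(!is_causal)
  if (n_c == 0L || n_nc == 0L)
    return(list(auc = NA_real_, fdr = NA_real_, n_calls = 0L, tp = 0L,
                fp = 0L, no_calls = TRUE))
  r <- rank(pip, ties.method = "average")
  auc <- (sum(r[is_causal]) - n_c * (n_c + 1) / 2) / (n_c * n_nc)
  called <- pip > pip_threshold
  tp <- sum(called & is_causal); fp <- sum(called & !is_causal)
  list(auc = auc,
       fdr = if (tp + fp == 0L) 0 else fp / (tp + fp),
       n_calls = tp + fp, tp = tp, fp = fp, no_calls = tp + fp == 0L)
}

#' Run the seeded fine-mapping simulation study
#'
#' Per replicate: generate a synthetic HFS matrix, simulate a trait, scale
#' it, fine-map every block with [susie_fit()], and evaluate AUC and FDR of
#' the PIPs against the planted truth. All replicate seeds derive from
#' \code{seed}.
#'
#' @param n,m,n_blocks,target_r2 generator settings (see
#'   [generate_synthetic_hfs()]); defaults 5000, 5000, 50, 0.013.
#' @param prop_causal,h2 trait settings; defaults 0.01 and 0.1 (with the
#'   defaults the per-causal-locus non-centrality n * h2 / m_causal is 10).
#' @param reps replicates; default 5.
#' @param seed master seed; default 1.
#' @param L,pip_threshold fine-mapping settings; defaults 10 and 0.95.
#' @return list: \code{replicates} (data.frame rep, auc, fdr, n_calls, tp,
#'   fp), \code{median_auc}, \code{median_fdr}, \code{seed}.
#' @export
run_simulation_study <- function(n = 5000L, m = 5000L, n_blocks = 50L,
                                 target_r2 = 0.013, prop_causal = 0.01,
                                 h2 = 0.1, reps = 5L, seed = 1L, L = 10L,
                                 pip_threshold = 0.95) {
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    gen <- generate_synthetic_hfs(n, m, n_blocks = n_blocks,
                                  target_r2 = target_r2,
                                  seed = .subseed(seed, 2L * r))
    sim <- simulate_trait(gen$hfs, prop_causal = prop_causal, h2 = h2,
                          seed = .subseed(seed, 2L * r + 1L))
    y <- drop(scale(sim$trait))
    fm <- finemap_blocks(gen$hfs, y, gen$block_of, L = L)
    pip <- stats::setNames(fm$pip, fm$locus_id)
    ev <- evaluate_finemap(pip, sim$truth, pip_threshold)
    rows[[r]] <- data.frame(rep = r, auc = ev$auc, fdr = ev$fdr,
                            n_calls = ev$n_calls, tp = ev$tp, fp = ev$fp)
  }
  reps_df <- do.call(rbind, rows)
  list(replicates = reps_df,
       median_auc = stats::median(reps_df$auc, na.rm = TRUE),
       median_fdr = stats::median(reps_df$fdr, na.rm = TRUE),
       seed = seed)
}
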