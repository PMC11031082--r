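#' Sum-of-single-effects fine-mapping of HFS blocks
#'
#' The regression model is y = sum_l X b_l + e with each b_l having exactly
#' one nonzero coordinate ("single effect"); fitting is by iterative Bayesian
#' stepwise selection (IBSS): each effect is updated in turn against the
#' residual excluding it, giving per-locus inclusion weights (alpha), from
#' which per-locus posterior inclusion probabilities (PIP) and coverage-level
#' credible sets are derived. Per-effect prior variances are optimized by
#' marginal-likelihood maximization and effects whose optimum is ~0 are
#' pruned; the residual variance is updated from the expected residual sum of
#' squares.
#'
#' @name finemap
NULL

# log Bayes factor of a single-effect regression per column, given
# bhat (OLS estimate), shat2 (its sampling variance) and prior variance V
.lbf_single <- function(bhat, shat2, V) {
  if (V <= 0) return(rep(0, length(bhat)))
  0.5 * log(shat2 / (V + shat2)) +
    0.5 * (bhat^2 / shat2) * (V / (V + shat2))
}

# log(sum(pi * BF)) for the single-effect model, used to optimize V
.loglik_single <- function(V, bhat, shat2, log_pi) {
  lbf <- .lbf_single(bhat, shat2, V) + log_pi
  m <- max(lbf)
  m + log(sum(exp(lbf - m)))
}

.softmax <- function(lx) {
  m <- max(lx)
  w <- exp(lx - m)
  w / sum(w)
}

#' Fit the sum-of-single-effects model to one block of HFS columns
#'
#' @param X n x p matrix of centered, rounded HFS values (one column per
#'   locus). Constant columns are removed and reported.
#' @param y length-n prepared trait vector.
#' @param L maximum number of single effects; default 10.
#' @param coverage credible-set coverage level; default 0.95.
#' @param tol convergence tolerance on the maximum absolute PIP change
#'   between iterations; default 1e-4.
#' @param max_iter iteration cap; default 200 (non-convergence returns a
#'   result with \code{converged = FALSE} and a warning).
#' @param prior_variance scaled prior variance of a single effect: the prior
#'   effect variance is \code{prior_variance * var(y)} on standardized
#'   columns (the reference-implementation convention); default 0.2.
#' @param estimate_prior_variance optimize the prior variance per effect by
#'   bounded 1-D marginal-likelihood maximization instead of keeping it
#'   fixed (effects with optimum ~0 are then pruned from the PIP); default
#'   FALSE.
#' @param standardize scale columns to unit variance for fitting (posterior
#'   effects are returned on the original scale); default TRUE.
#' @param residual_variance initial (or fixed) residual variance; default
#'   \code{var(y)}.
#' @param estimate_residual_variance update the residual variance from the
#'   expected residual sum of squares each iteration; default TRUE.
#' @param min_purity smallest absolute within-set correlation a credible set
#'   must attain; default 0.5.
#' @param prior_weights per-column prior inclusion probabilities; default
#'   uniform 1/p.
#' @return object of class \code{susie_fit}: \code{pip} (named per-locus),
#'   \code{alpha}, \code{mu}, \code{mu2} (L x p), \code{posterior_effect}
#'   (p-vector sum_l alpha * mu), \code{credible_sets} (list with members,
#'   attained coverage, purity, effect index), \code{sigma2},
#'   \code{prior_variances}, \code{lbf_effect}, \code{niter},
#'   \code{converged}, \code{removed_columns}.
#' @export
susie_fit <- function(X, y, L = 10L, coverage = 0.95, tol = 1e-4,
                      max_iter = 200L, prior_variance = 0.2,
                      estimate_prior_variance = FALSE,
                      residual_variance = NULL,
                      estimate_residual_variance = TRUE,
                      min_purity = 0.5, prior_weights = NULL,
                      standardize = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10L) stop("need at least 10 individuals")
  if (length(y) != n) stop("X and y disagree in length")
  if (!all(is.finite(X))) stop("X must be finite")
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2L, function(v) stats::sd(v) > 0)
  removed <- cn[!keep]
  X <- X[, keep, drop = FALSE]; cn <- cn[keep]
  p <- ncol(X)
  if (p == 0L) stop("no variable columns left after constant-column removal")
  L <- min(L, p)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  csd <- rep(1, p)
  if (standardize) {
    csd <- apply(Xc, 2L, stats::sd)
    Xc <- sweep(Xc, 2L, csd, `/`)
  }
  yc <- y - mean(y)
  d <- colSums(Xc^2)
  sigma2 <- if (is.null(residual_variance)) stats::var(yc) else
    residual_variance
  pi0 <- if (is.null(prior_weights)) rep(1 / p, p) else
    prior_weights[keep] / sum(prior_weights[keep])
  log_pi <- log(pi0)

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  V <- rep(prior_variance * stats::var(yc), L)
  lbf_eff <- rep(0, L)
  B <- colSums(alpha * mu)
  r_full <- yc - drop(Xc %*% B)
  pip_old <- rep(0, p)
  converged <- FALSE
  it <- 0L

  while (it < max_iter) {
    it <- it + 1L
    for (l in seq_len(L)) {
      b_l <- alpha[l, ] * mu[l, ]
      r_l <- r_full + drop(Xc %*% b_l)
      Xty <- drop(crossprod(Xc, r_l))
      bhat <- Xty / d
      shat2 <- sigma2 / d
      if (estimate_prior_variance) {
        opt <- stats::optimize(function(lv)
          .loglik_single(exp(lv), bhat, shat2, log_pi),
          interval = c(-30, 10), maximum = TRUE, tol = 1e-8)
        V[l] <- if (opt$objective >
                    .loglik_single(0, bhat, shat2, log_pi)) exp(opt$maximum)
        else 0
        if (V[l] < 1e-9) V[l] <- 0
      }
      if (V[l] > 0) {
        lbf <- .lbf_single(bhat, shat2, V[l]) + log_pi
        alpha[l, ] <- .softmax(lbf)
        post_var <- 1 / (1 / V[l] + d / sigma2)
        mu[l, ] <- post_var * Xty / sigma2
        mu2[l, ] <- post_var + mu[l, ]^2
        m <- max(lbf)
        lbf_eff[l] <- m + log(sum(exp(lbf - m)))
      } else {                       # pruned effect: no contribution
        alpha[l, ] <- pi0
        mu[l, ] <- 0
        mu2[l, ] <- 0
        lbf_eff[l] <- 0
      }
      b_new <- alpha[l, ] * mu[l, ]
      r_full <- r_l - drop(Xc %*% b_new)
    }
    if (estimate_residual_variance) {
      erss <- sum(r_full^2)
      for (l in seq_len(L)) {
        b_l <- alpha[l, ] * mu[l, ]
        erss <- erss + sum(d * alpha[l, ] * mu2[l, ]) -
          sum(drop(Xc %*% b_l)^2)
      }
      sigma2 <- max(erss / n, .Machine$double.eps)
    }
    live <- V > 1e-9
    pip <- if (any(live))
      1 - apply(1 - alpha[live, , drop = FALSE], 2L, prod)
    else rep(0, p)
    if (max(abs(pip - pip_old)) < tol) { converged <- TRUE; break }
    pip_old <- pip
  }
  if (!converged)
    warning("IBSS did not converge in ", max_iter, " iterations")

  names(pip) <- cn
  if (standardize) {                 # back to the original column scale
    mu <- sweep(mu, 2L, csd, `/`)
    mu2 <- sweep(mu2, 2L, csd^2, `/`)
  }
  colnames(alpha) <- colnames(mu) <- colnames(mu2) <- cn
  cs <- .credible_sets(alpha, V, Xc, cn, coverage, min_purity)
  structure(list(
    pip = pip, alpha = alpha, mu = mu, mu2 = mu2,
    posterior_effect = stats::setNames(colSums(alpha * mu), cn),
    credible_sets = cs, sigma2 = sigma2, prior_variances = V,
    lbf_effect = lbf_eff, niter = it, converged = converged,
    removed_columns = removed), class = "susie_fit")
}

# smallest alpha-mass sets reaching `coverage`, filtered by purity
.credible_sets <- function(alpha, V, Xc, cn, coverage, min_purity) {
  out <- list()
  seen <- character(0)
  for (l in which(V > 1e-9)) {
    ord <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, ord])
    k <- which(csum >= coverage)[1L]
    if (is.na(k)) next
    idx <- sort(ord[seq_len(k)])
    purity <- if (length(idx) == 1L) 1 else {
      cm <- abs(stats::cor(Xc[, idx, drop = FALSE]))
      min(cm[lower.tri(cm)])
    }
    if (is.na(purity) || purity < min_purity) next
    key <- paste(idx, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- list(
      loci = cn[idx], coverage = csum[k], purity = purity, effect = l)
  }
  out
}

#' Fine-map every block of an HFS matrix
#'
#' @param hfs individuals x loci matrix (columns named by locus_id).
#' @param y prepared trait vector aligned to rows.
#' @param block_of vector (or factor) of block ids, one per column of
#'   \code{hfs}.
#' @param ... further arguments to [susie_fit()].
#' @return data.frame: locus_id, block_id, pip, posterior_effect, cs (id of
#'   the credible set containing the locus, NA otherwise). Constant columns
#'   get pip 0.
#' @export
finemap_blocks <- function(hfs, y, block_of, ...) {
  stopifnot(length(block_of) == ncol(hfs))
  res <- list()
  for (b in unique(block_of)) {
    jj <- which(block_of == b)
    Xb <- hfs[, jj, drop = FALSE]
    df <- data.frame(locus_id = colnames(Xb),
                     block_id = b,
                     pip = NA_real_,       # stays NA for constant columns
                     posterior_effect = 0, cs = NA_character_,
                     stringsAsFactors = FALSE)
    if (any(apply(Xb, 2L, stats::sd) > 0)) {
      fit <- susie_fit(Xb, y, ...)
      m <- match(names(fit$pip), df$locus_id)
      df$pip[m] <- fit$pip
      df$posterior_effect[m] <- fit$posterior_effect
      for (k in seq_along(fit$credible_sets))
        df$cs[df$locus_id %in% fit$credible_sets[[k]]$loci] <-
          paste0(b, "_CS", k)
    }
    res[[length(res) + 1L]] <- df
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call causal loci from PIPs
#'
#' @param pip named PIP vector (or data.frame with locus_id and pip).
#' @param threshold strict lower bound; a locus is causal iff
#'   \code{pip > threshold}. Default 0.95.
#' @return character vector of causal locus ids.
#' @export
call_causal <- function(pip, threshold = 0.95) {
  if (is.data.frame(pip)) pip <- stats::setNames(pip$pip, pip$locus_id)
  names(pip)[!is.na(pip) & pip > threshold]
}

#' Loci causal for two or more traits
#'
#' @param causal_by_trait named list of per-trait causal locus-id vectors.
#' @return character vector of pleiotropic locus ids.
#' @export
pleiotropic_loci <- function(causal_by_trait) {
  tab <- table(unlist(lapply(causal_by_trait, unique)))
  names(tab)[tab >= 2L]
}

#' Match a p-value- and distance-matched control locus to each causal locus
#'
#' Controls are non-causal loci whose association p-value is within
#' \code{log10_tol} of the causal locus's on the log10 scale; among those the
#' genomically nearest (same chromosome) is chosen. Without an eligible
#' candidate the globally nearest in log10 p is used and flagged. Matching
#' is greedy without replacement in order of increasing causal p.
#'
#' @param causal_ids causal locus ids.
#' @param assoc association data.frame (locus_id, chrom, start, end, p).
#' @param log10_tol p-value match tolerance on the log10 scale; default 0.5.
#' @return data.frame: causal_id, control_id (NA if skipped), fallback flag.
#' @export
match_controls <- function(causal_ids, assoc, log10_tol = 0.5) {
  assoc <- assoc[!is.na(assoc$p), , drop = FALSE]
  assoc$lp <- log10(assoc$p)
  assoc$mid <- (assoc$start + assoc$end) / 2
  causal <- assoc[assoc$locus_id %in% causal_ids, , drop = FALSE]
  causal <- causal[order(causal$p), , drop = FALSE]
  pool <- assoc[!assoc$locus_id %in% causal_ids, , drop = FALSE]
  used <- character(0)
  out <- lapply(seq_len(nrow(causal)), function(i) {
    cand <- pool[!pool$locus_id %in% used, , drop = FALSE]
    if (!nrow(cand))
      return(data.frame(causal_id = causal$locus_id[i],
                        control_id = NA_character_, fallback = NA))
    ok <- abs(cand$lp - causal$lp[i]) <= log10_tol
    fallback <- !any(ok)
    if (fallback) {
      pick <- cand$locus_id[which.min(abs(cand$lp - causal$lp[i]))]
    } else {
      cand <- cand[ok, , drop = FALSE]
      dist <- ifelse(cand$chrom == causal$chrom[i],
                     abs(cand$mid - causal$mid[i]), Inf)
      pick <- if (all(is.infinite(dist)))
        cand$locus_id[which.min(abs(cand$lp - causal$lp[i]))]
      else cand$locus_id[which.min(dist)]
    }
    used <<- c(used, pick)
    data.frame(causal_id = causal$locus_id[i], control_id = pick,
               fallback = fallback)
  })
  do.call(rbind, out)
}

#' Fisher enrichment of an annotation in causal vs control loci
#'
#' @param causal_flags logical annotation values of the causal loci, or a
#'   2 x 2 count matrix (rows = causal/control, cols = annotated/not).
#' @param control_flags logical annotation values of the control (or
#'   background) loci; ignored when a matrix is given.
#' @return list: \code{or} (sample cross-product odds ratio; Haldane 0.5
#'   correction with \code{haldane = TRUE} when a margin is zero), \code{p}
#'   (two-sided Fisher exact), \code{table}.
#' @export
fisher_enrichment <- function(causal_flags, control_flags = NULL) {
  tab <- if (is.matrix(causal_flags)) causal_flags else
    matrix(c(sum(causal_flags), sum(!causal_flags),
             sum(control_flags), sum(!control_flags)),
           nrow = 2L, byrow = TRUE,
           dimnames = list(c("causal", "control"), c("yes", "no")))
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L) || all(tab == 0L))
    stop("degenerate 2x2 table")
  haldane <- any(tab == 0L)
  tt <- if (haldane) tab + 0.5 else tab
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(or = or, p = p, table = tab, haldane = haldane)
}

#' Trait variance tagged by a locus set in held-out individuals
#'
#' Multivariate OLS of the held-out trait on the HFS of the given loci;
#' reports the regression R^2 and the Gaussian-likelihood AIC (p + 2
#' parameters: slopes, intercept, residual variance).
#'
#' @param X_test held-out individuals x loci HFS matrix.
#' @param y_test held-out trait values.
#' @return list: \code{r2}, \code{aic}, \code{n}, \code{p},
#'   \code{rank_deficient} flag (aliased columns dropped by the QR fit).
#' @export
tagged_variance <- function(X_test, y_test) {
  X_test <- as.matrix(X_test)
  n <- nrow(X_test); p <- ncol(X_test)
  if (n <= p + 2L) stop("need n_test > p + 2")
  fit <- stats::lm(y_test ~ X_test)
  rank_def <- fit$rank < p + 1L
  if (rank_def)
    warning("rank-deficient design: aliased columns dropped from the fit")
  r2 <- summary(fit)$r.squared
  list(r2 = r2, aic = stats::AIC(fit), n = n, p = p,
       rank_deficient = rank_def)
}
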