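#' HFS-trait association
#'
#' Phenotypes are adjusted for covariates and inverse-normal transformed
#' once; each locus's HFS column is then tested by simple linear regression
#' without covariates. Genome-wide significance uses the conventional
#' 5e-8 threshold, and inflation is monitored with the genomic-control
#' lambda.
#'
#' @name association
NULL

#' Adjust and inverse-normal transform a phenotype
#'
#' Quantitative traits: OLS residuals on the covariates. Binary traits:
#' deviance residuals from a logistic model. Residuals are then rank-based
#' inverse-normal transformed with the Blom offset,
#' \code{qnorm((rank - 3/8) / (n + 1/4))}.
#'
#' @param y numeric phenotype (0/1 for binary).
#' @param covariates optional data.frame/matrix of covariates (complete
#'   cases required).
#' @param binary logical; default FALSE.
#' @return list: \code{value} (transformed phenotype), \code{binary},
#'   \code{covariates} (names used).
#' @export
prepare_phenotype <- function(y, covariates = NULL, binary = FALSE) {
  if (length(unique(y[!is.na(y)])) < 2L) stop("constant phenotype")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (anyNA(covariates)) stop("covariates must be complete")
    X <- stats::model.matrix(~ ., data = covariates)
    if (qr(X)$rank < ncol(X)) stop("singular covariate design")
    df <- data.frame(.y = y, covariates)
    res <- if (binary)
      stats::residuals(stats::glm(.y ~ ., data = df,
                                  family = stats::binomial()),
                       type = "deviance")
    else stats::residuals(stats::lm(.y ~ ., data = df))
  } else {
    res <- if (binary) {
      p <- mean(y)
      sign(y - p) * sqrt(-2 * (y * log(p) + (1 - y) * log(1 - p)))
    } else y - mean(y)
  }
  r <- rank(res, ties.method = "average")
  n <- length(res)
  list(value = stats::qnorm((r - 3 / 8) / (n + 1 / 4)),
       binary = binary,
       covariates = if (is.null(covariates)) character(0)
       else colnames(covariates))
}

#' Simple linear regression of a prepared trait on one HFS column
#'
#' @param x HFS values at one locus.
#' @param y prepared (adjusted, normalized) trait values.
#' @return list with \code{beta}, \code{se}, \code{p} (two-sided),
#'   \code{chisq} (Wald, 1 df), \code{n}, and \code{excluded} with a
#'   \code{reason} when the column is unusable (constant HFS).
#' @export
associate <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 non-missing pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0)
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                chisq = NA_real_, n = n, excluded = TRUE,
                reason = "constant_hfs"))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  rss <- sum((y - mean(y) - beta * (x - mean(x)))^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df = n - 2L)
  list(beta = beta, se = se, p = max(p, .Machine$double.xmin),
       chisq = tval^2, n = n, excluded = FALSE, reason = NA_character_)
}

#' Associate every locus of an HFS matrix with a prepared trait
#'
#' @param hfs individuals x loci matrix.
#' @param y prepared trait values aligned to rows.
#' @param loci optional locus data.frame supplying chrom/start/end.
#' @return data.frame (one row per locus): locus_id, beta, se, p, chisq, n,
#'   excluded, reason, plus coordinates when \code{loci} is given.
#' @export
associate_all <- function(hfs, y, loci = NULL) {
  res <- lapply(seq_len(ncol(hfs)), function(j) {
    a <- associate(hfs[, j], y)
    data.frame(locus_id = colnames(hfs)[j], beta = a$beta, se = a$se,
               p = a$p, chisq = a$chisq, n = a$n, excluded = a$excluded,
               reason = a$reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(loci))
    out <- cbind(out,
                 loci[match(out$locus_id, loci$locus_id),
                      c("chrom", "start", "end")])
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation factor
#'
#' Median of the association chi-square statistics divided by the median of
#' the 1-df chi-square distribution (0.4549364), so a well-calibrated test
#' has lambda near 1.
#'
#' @param chisq vector of 1-df chi-square statistics (NAs dropped).
#' @return lambda (scalar).
#' @export
lambda_gc <- function(chisq) {
  chisq <- chisq[is.finite(chisq)]
  if (!length(chisq)) stop("no finite chi-square statistics")
  stats::median(chisq) / stats::qchisq(0.5, df = 1L)
}

#' Greedy selection of independent association hits
#'
#' Repeatedly takes the most significant remaining locus below \code{alpha}
#' and suppresses all significant loci whose midpoints lie within
#' \code{window} bp of its midpoint (same chromosome).
#'
#' @param results association data.frame with \code{p}, \code{chrom},
#'   \code{start}, \code{end}.
#' @param window suppression half-width in bp; default 200000.
#' @param alpha significance threshold; default 5e-8.
#' @return subset of \code{results}: the independent hits, ordered by p.
#' @export
independent_hits <- function(results, window = 2e5, alpha = 5e-8) {
  sig <- results[!is.na(results$p) & results$p < alpha, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  sig$mid <- (sig$start + sig$end) / 2
  sig <- sig[order(sig$p), , drop = FALSE]
  taken <- logical(nrow(sig)); alive <- rep(TRUE, nrow(sig))
  for (i in seq_len(nrow(sig))) {
    if (!alive[i]) next
    taken[i] <- TRUE
    near <- alive & sig$chrom == sig$chrom[i] &
      abs(sig$mid - sig$mid[i]) <= window
    alive[near] <- FALSE
  }
  out <- sig[taken, , drop = FALSE]
  out$mid <- NULL
  rownames(out) <- NULL
  out
}
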