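#' HFS-weighted polygenic scores and SNP-PRS integration
#'
#' The HFS polygenic score of an individual is the weighted sum of its HFS
#' values, with the per-locus posterior effects from fine-mapping as weights.
#' Summing within independent blocks instead gives per-block scores, which
#' are integrated with an externally trained SNP-based PRS by LASSO in a
#' tuning sample and evaluated by simple-regression R^2 in a disjoint test
#' sample.
#'
#' @name prediction
NULL

#' HFS polygenic score
#'
#' @param hfs individuals x loci matrix (columns named by locus_id).
#' @param effects named per-locus weight vector (posterior effects); must be
#'   a subset of the HFS columns.
#' @param pip optional named PIP vector; with \code{pip_threshold}, loci at
#'   or below the threshold get weight 0.
#' @param pip_threshold strict PIP restriction threshold (default NULL: use
#'   all loci).
#' @return named per-individual score vector, zero for all-reference rows.
#' @export
hfs_prs <- function(hfs, effects, pip = NULL, pip_threshold = NULL) {
  if (is.null(names(effects)) || !all(names(effects) %in% colnames(hfs)))
    stop("effects must be named by locus ids present in the HFS matrix")
  w <- stats::setNames(numeric(ncol(hfs)), colnames(hfs))
  w[names(effects)] <- effects
  if (!is.null(pip_threshold)) {
    if (is.null(pip)) stop("pip_threshold needs a pip vector")
    low <- names(pip)[pip <= pip_threshold]
    w[intersect(low, names(w))] <- 0
  }
  drop(hfs %*% w)
}

#' Per-block HFS prediction scores
#'
#' @param hfs individuals x loci matrix.
#' @param effects named per-locus weight vector.
#' @param block_of block id per column of \code{hfs}.
#' @return individuals x blocks matrix; rows sum to [hfs_prs()] exactly.
#' @export
block_scores <- function(hfs, effects, block_of) {
  stopifnot(length(block_of) == ncol(hfs))
  if (anyNA(block_of)) stop("every locus must be assigned a block")
  w <- stats::setNames(numeric(ncol(hfs)), colnames(hfs))
  w[names(effects)] <- effects
  blocks <- unique(block_of)
  out <- vapply(blocks, function(b) {
    jj <- which(block_of == b)
    drop(hfs[, jj, drop = FALSE] %*% w[jj])
  }, numeric(nrow(hfs)))
  colnames(out) <- as.character(blocks)
  rownames(out) <- rownames(hfs)
  out
}

#' Integrate block scores with an external SNP PRS by LASSO
#'
#' L1-penalized least squares of the trait on [snp_prs | block scores] in the
#' tuning sample, with the penalty chosen by seeded 5-fold cross-validation.
#' Predictors are standardized internally; weights are returned on the
#' original scale.
#'
#' @param blocks tuning-sample individuals x blocks score matrix.
#' @param snp_prs tuning-sample SNP-PRS vector.
#' @param trait tuning-sample (prepared) trait vector.
#' @param seed integer seed for the cross-validation fold split.
#' @param alpha elastic-net mixing parameter (1 = LASSO, the default;
#'   0 = ridge).
#' @param nfolds cross-validation folds; default 5.
#' @return list of class \code{hfs_integration}: \code{intercept},
#'   \code{weight_snp_prs}, \code{weights_blocks} (named), \code{lambda},
#'   \code{alpha}, \code{seed}.
#' @export
integrate_lasso <- function(blocks, snp_prs, trait, seed = 1L, alpha = 1,
                            nfolds = 5L) {
  n <- length(trait)
  if (n < 50L) stop("tuning sample too small (need at least 50 individuals)")
  if (stats::sd(trait) == 0) stop("constant trait")
  X <- cbind(snp_prs = snp_prs, as.matrix(blocks))
  stopifnot(nrow(X) == n)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(X, trait, alpha = alpha, nfolds = nfolds,
                          standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  structure(list(
    intercept = co[1L, 1L],
    weight_snp_prs = co["snp_prs", 1L],
    weights_blocks = stats::setNames(co[-(1:2), 1L],
                                     rownames(co)[-(1:2)]),
    lambda = cv$lambda.min, alpha = alpha, seed = seed),
    class = "hfs_integration")
}

#' Predict with an integration model
#'
#' @param model [integrate_lasso()] fit.
#' @param blocks individuals x blocks score matrix.
#' @param snp_prs SNP-PRS vector.
#' @return per-individual integrated prediction score.
#' @export
predict_integrated <- function(model, blocks, snp_prs) {
  blocks <- as.matrix(blocks)
  w <- model$weights_blocks[colnames(blocks)]
  w[is.na(w)] <- 0
  model$intercept + model$weight_snp_prs * snp_prs + drop(blocks %*% w)
}

#' Prediction R^2 in an evaluation sample
#'
#' Squared Pearson correlation between score and trait, identical to the R^2
#' of the simple linear regression of trait on score.
#'
#' @param score per-individual prediction score.
#' @param trait trait values.
#' @param eval_ids optional names/indices restricting the evaluation sample.
#' @return R^2 scalar; NA with a warning when the score is constant.
#' @export
evaluate_r2 <- function(score, trait, eval_ids = NULL) {
  if (!is.null(eval_ids)) {
    score <- score[eval_ids]; trait <- trait[eval_ids]
  }
  if (stats::sd(score) == 0) {
    warning("constant score: R^2 undefined")
    return(NA_real_)
  }
  stats::cor(score, trait)^2
}
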