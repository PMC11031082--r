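#' Annotation construction and PIP-enrichment regression
#'
#' Follows the stratified-regression idea: per-locus posterior inclusion
#' probabilities are regressed on a baseline annotation matrix plus one
#' functional annotation at a time; an annotation is significant when its
#' coefficient is positive and its Bonferroni-adjusted p-value is below 0.05,
#' and terms significant in more than half of the traits are removed as
#' likely confounders.
#'
#' @name enrichment
NULL

#' Flag loci overlapping a feature set by at least a fraction of their length
#'
#' Mirrors \code{bedtools intersect -f}: a locus is annotated 1 when the
#' total number of its bases covered by the feature intervals is at least
#' \code{min_fraction} of the locus length.
#'
#' @param loci locus data.frame (\code{chrom}, \code{start}, \code{end}).
#' @param features BED data.frame of feature intervals.
#' @param min_fraction minimum covered fraction of the locus; default 0.1.
#' @return integer 0/1 vector along \code{loci}.
#' @export
annotate_overlap <- function(loci, features, min_fraction = 0.1) {
  if (!nrow(loci)) return(integer(0))
  if (is.null(features) || !nrow(features))
    return(integer(nrow(loci)))
  .check_bed_df(features)
  lgr <- .loci_gr(loci)
  fgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(start = features$start + 1L, end = features$end)))
  hits <- GenomicRanges::findOverlaps(lgr, fgr)
  ov <- IRanges::pintersect(lgr[S4Vectors::queryHits(hits)],
                            fgr[S4Vectors::subjectHits(hits)])
  cov <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
  total <- integer(nrow(loci))
  total[as.integer(names(cov))] <- as.integer(cov)
  as.integer(total >= min_fraction * (loci$end - loci$start))
}

#' Size-filter and de-duplicate gene sets
#'
#' Keeps sets with more than 5 and fewer than 500 genes, orders them by
#' average-linkage hierarchical clustering on Jaccard distance, and walks the
#' leaf order removing the smaller of any adjacent pair sharing more than
#' \code{max_overlap} of the smaller set's genes. The scan is iterated to a
#' fixed point so the result is idempotent.
#'
#' @param gene_sets named list of character vectors of gene ids.
#' @param min_genes,max_genes strict size bounds; defaults 5 and 500.
#' @param max_overlap overlap threshold |A int B| / min(|A|, |B|);
#'   default 0.3.
#' @return named list: the retained gene sets, in input order.
#' @export
prune_pathways <- function(gene_sets, min_genes = 5L, max_genes = 500L,
                           max_overlap = 0.3) {
  if (!length(gene_sets)) stop("empty gene-set list")
  sizes <- lengths(gene_sets)
  keep <- gene_sets[sizes > min_genes & sizes < max_genes]
  repeat {
    if (length(keep) < 2L) break
    ord <- .cluster_order(keep)
    removed <- character(0)
    i <- 1L
    while (i < length(ord)) {
      a <- keep[[ord[i]]]; b <- keep[[ord[i + 1L]]]
      frac <- length(intersect(a, b)) / min(length(a), length(b))
      if (frac > max_overlap) {
        # drop the smaller member; ties drop the later one in leaf order
        drop_j <- if (length(a) < length(b)) i else i + 1L
        removed <- c(removed, ord[drop_j])
        ord <- ord[-drop_j]
      } else i <- i + 1L
    }
    if (!length(removed)) break
    keep <- keep[setdiff(names(keep), removed)]
  }
  keep[order(match(names(keep), names(gene_sets)))]
}

# average-linkage hierarchical clustering on Jaccard distance; leaf order
.cluster_order <- function(sets) {
  nm <- names(sets)
  n <- length(sets)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    inter <- length(intersect(sets[[i]], sets[[j]]))
    uni <- length(union(sets[[i]], sets[[j]]))
    d[i, j] <- d[j, i] <- 1 - inter / max(uni, 1L)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  nm[hc$order]
}

#' Link loci to a gene set through SNP-to-gene scores
#'
#' A locus is annotated 1 for a gene set iff it contains a SNP linked to a
#' member gene with score strictly greater than \code{min_score}.
#'
#' @param loci locus data.frame.
#' @param links data.frame with \code{chrom}, \code{pos} (1-based SNP
#'   position), \code{gene}, \code{score}.
#' @param gene_set character vector of gene ids.
#' @param min_score strict link-score threshold; default 0.5.
#' @return integer 0/1 vector along \code{loci}.
#' @export
link_pathway <- function(loci, links, gene_set, min_score = 0.5) {
  good <- links[links$gene %in% gene_set & links$score > min_score, ,
                drop = FALSE]
  if (!nrow(good)) return(integer(nrow(loci)))
  out <- integer(nrow(loci))
  for (i in seq_len(nrow(loci)))
    out[i] <- as.integer(any(
      good$chrom == loci$chrom[i] &
        good$pos > loci$start[i] & good$pos <= loci$end[i]))
  out
}

#' Regress PIP on baseline annotations plus one functional annotation
#'
#' @param pip per-locus PIP vector.
#' @param baseline loci x k baseline annotation matrix/data.frame.
#' @param annotation per-locus binary (or numeric) functional annotation.
#' @return list: \code{coef}, \code{t}, \code{p} for the annotation term, or
#'   \code{skipped = TRUE} with a \code{reason} when the annotation is
#'   collinear with the baseline (aliased in the OLS fit).
#' @export
pip_regression <- function(pip, baseline, annotation) {
  baseline <- as.matrix(baseline)
  if (length(pip) <= ncol(baseline) + 2L)
    stop("need more loci than baseline columns + 2")
  X <- cbind(baseline, .annot = annotation)
  fit <- stats::lm(pip ~ X)
  cf <- summary(fit)$coefficients
  row <- grep("\\.annot$", rownames(cf))
  aliased <- is.na(fit$coefficients[grep("\\.annot$",
                                         names(fit$coefficients))])
  if (length(aliased) && aliased)
    return(list(skipped = TRUE, reason = "collinear_with_baseline",
                coef = NA_real_, t = NA_real_, p = NA_real_))
  list(skipped = FALSE, reason = NA_character_,
       coef = cf[row, 1L], t = cf[row, 3L], p = cf[row, 4L])
}

#' Test a family of functional annotations against one trait's PIPs
#'
#' Runs [pip_regression()] per annotation and applies the Bonferroni rule
#' over the family: significant iff \code{coef > 0} and
#' \code{p * n_tested < 0.05}.
#'
#' @param pip per-locus PIP vector.
#' @param baseline baseline annotation matrix.
#' @param annotations loci x m matrix/data.frame of functional annotations
#'   (columns named).
#' @param alpha familywise threshold; default 0.05.
#' @return data.frame: annotation, coef, t, p, p_adj, significant, skipped.
#' @export
enrichment_scan <- function(pip, baseline, annotations, alpha = 0.05) {
  annotations <- as.data.frame(annotations)
  res <- lapply(names(annotations), function(nm) {
    r <- pip_regression(pip, baseline, annotations[[nm]])
    data.frame(annotation = nm, coef = r$coef, t = r$t, p = r$p,
               skipped = r$skipped, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  n_tested <- sum(!out$skipped)
  out$p_adj <- pmin(out$p * n_tested, 1)
  out$significant <- !out$skipped & !is.na(out$coef) &
    out$coef > 0 & out$p_adj < alpha
  out
}

#' Remove terms significant in more than half of the traits
#'
#' Recurrently significant pathways or cell types across unrelated traits
#' usually reflect unrecognized confounders; they are removed from every
#' trait's result.
#'
#' @param sig_by_trait named list of per-trait character vectors of
#'   significant term names.
#' @param n_traits total number of traits tested (default: the list length).
#' @return list: \code{kept} (filtered per-trait lists), \code{removed}
#'   (term names significant in more than \code{n_traits / 2} traits).
#' @export
filter_recurrent <- function(sig_by_trait, n_traits = length(sig_by_trait)) {
  tab <- table(unlist(lapply(sig_by_trait, unique)))
  recurrent <- names(tab)[tab > n_traits / 2]
  list(kept = lapply(sig_by_trait, setdiff, y = recurrent),
       removed = recurrent)
}

#' Baseline annotation matrix for enrichment regression
#'
#' Assembles the per-locus baseline: number of haplotypes, HFS range scaled
#' by the absolute reference score, the 39 reference sequence-class scores,
#' any supplied binary genomic-region flags, and optional per-position
#' statistics aggregated per locus (max background-selection B, min allele
#' age, mean coalescent rate).
#'
#' @param meta per-locus metadata from [hfs_from_vcf()] (needs
#'   \code{n_haplotypes}, \code{hfs_range}).
#' @param ref_scores loci x 39 matrix of reference haplotype scores.
#' @param region_flags optional loci x k 0/1 matrix (exon, intron, UTRs,
#'   TSS flank, conservation classes, ...).
#' @param position_stats optional named list of data.frames
#'   (\code{chrom}, \code{pos}, \code{value}) aggregated by
#'   \code{max}/\code{min}/\code{mean} according to \code{aggregate}.
#' @param loci locus data.frame (required with \code{position_stats}).
#' @param aggregate named character vector mapping each element of
#'   \code{position_stats} to "max", "min" or "mean".
#' @return numeric matrix, one row per locus.
#' @export
baseline_annotations <- function(meta, ref_scores, region_flags = NULL,
                                 position_stats = NULL, loci = NULL,
                                 aggregate = NULL) {
  out <- cbind(n_haplotypes = meta$n_haplotypes,
               hfs_range = meta$hfs_range,
               ref_scores)
  if (!is.null(region_flags)) out <- cbind(out, as.matrix(region_flags))
  if (!is.null(position_stats)) {
    stopifnot(!is.null(loci), !is.null(aggregate))
    for (nm in names(position_stats)) {
      ps <- position_stats[[nm]]
      f <- switch(aggregate[[nm]], max = max, min = min, mean = mean,
                  stop("aggregate must be max, min or mean"))
      v <- vapply(seq_len(nrow(loci)), function(i) {
        sel <- ps$chrom == loci$chrom[i] &
          ps$pos > loci$start[i] & ps$pos <= loci$end[i]
        if (!any(sel)) NA_real_ else f(ps$value[sel])
      }, numeric(1))
      out <- cbind(out, v)
      colnames(out)[ncol(out)] <- nm
    }
  }
  out
}
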