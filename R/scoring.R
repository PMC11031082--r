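#' Sequence-class scoring and haplotype function scores
#'
#' Each 4096-bp haplotype sequence is mapped to 39 sequence-class scores by a
#' pluggable scorer (the packaged surrogate, or an external deep-learning
#' model behind the same contract). The per-individual HFS at a locus is the
#' mean of its two haplotypes' scores in the locus's reference sequence
#' class, centered on the reference haplotype's score and rounded to two
#' decimals (so an individual homozygous for the reference haplotype has
#' HFS = 0 exactly, and scorer noise below 0.005 is zeroed out).
#'
#' @name scoring
NULL

.hfs_env <- new.env(parent = emptyenv())

#' The packaged surrogate scorer manifest
#'
#' Fixed 6-mer motif sets and weights defining the deterministic surrogate
#' scorer: each of the 39 sequence classes scores
#' \code{plogis(sum(weight * motif count))}, so a poly-N sequence scores 0.5
#' in every class.
#'
#' @return data.frame with \code{class_index}, \code{class_name},
#'   \code{motif}, \code{weight}.
#' @export
surrogate_manifest <- function() {
  if (is.null(.hfs_env$manifest)) {
    path <- system.file("extdata", "surrogate_manifest.tsv",
                        package = "hfstools", mustWork = TRUE)
    .hfs_env$manifest <- utils::read.table(path, sep = "\t", header = TRUE,
                                           stringsAsFactors = FALSE)
  }
  .hfs_env$manifest
}

#' The 39 sequence-class names
#' @return character vector of length 39.
#' @export
sequence_class_names <- function() {
  man <- surrogate_manifest()
  man$class_name[!duplicated(man$class_index)]
}

.check_seq <- function(sequence, locus_size = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("sequence must be a single string")
  if (!is.null(locus_size) && nchar(sequence) != locus_size)
    stop("sequence has length ", nchar(sequence), ", expected ", locus_size)
  if (grepl("[^ACGTNacgtn]", sequence))
    stop("sequence alphabet must be {A,C,G,T,N}")
  invisible(TRUE)
}

#' Score one sequence with the surrogate scorer
#'
#' Deterministic stand-in scorer with the same I/O contract as an external
#' sequence-class model: class score = logistic of the weighted count of that
#' class's fixed 6-mer motifs (overlapping occurrences counted). Edits
#' outside every motif match window of a class leave that class's score
#' unchanged.
#'
#' @param sequence a single DNA string over \{A,C,G,T,N\}.
#' @param locus_size expected sequence length (default 4096); pass NULL to
#'   skip the length check.
#' @return named numeric vector of 39 finite scores in (0, 1).
#' @export
surrogate_score <- function(sequence, locus_size = 4096L) {
  .check_seq(sequence, locus_size)
  man <- surrogate_manifest()
  subject <- Biostrings::DNAString(toupper(sequence))
  counts <- vapply(man$motif, function(m)
    Biostrings::countPattern(m, subject), integer(1), USE.NAMES = FALSE)
  raw <- tapply(man$weight * counts, man$class_index, sum)
  out <- stats::plogis(as.numeric(raw))
  names(out) <- sequence_class_names()
  out
}

#' Make a vectorized scorer from a per-sequence scoring function
#'
#' @param fun function mapping one sequence string to a finite numeric
#'   39-vector; default the packaged [surrogate_score()].
#' @return function mapping a character vector of sequences to an n x 39
#'   matrix (identical sequences are scored once and reuse the same row).
#' @export
make_scorer <- function(fun = surrogate_score) {
  function(sequences) {
    uniq <- unique(sequences)
    rows <- t(vapply(uniq, fun, numeric(39L)))
    m <- rows[match(sequences, uniq), , drop = FALSE]
    rownames(m) <- NULL
    colnames(m) <- sequence_class_names()
    m
  }
}

#' Score a set of haplotype sequences
#'
#' @param scorer vectorized scorer from [make_scorer()] (or any function with
#'   that contract).
#' @param sequences character vector of equal-length sequences; element 1 is
#'   the reference haplotype by convention.
#' @return list: \code{scores} (haplotypes x 39 matrix), \code{class_names}.
#' @export
score_sequences <- function(scorer, sequences) {
  if (!length(sequences)) stop("no sequences to score")
  for (s in sequences) .check_seq(s, nchar(sequences[[1L]]))
  scores <- scorer(sequences)
  if (!is.matrix(scores) || ncol(scores) != 39L || !all(is.finite(scores)))
    stop("scorer must return a finite n x 39 matrix")
  list(scores = scores, class_names = sequence_class_names())
}

#' Sequence class of a locus (argmax of the reference haplotype's scores)
#'
#' @param reference_scores numeric 39-vector.
#' @return integer class index in 1..39; ties broken toward the lowest index.
#' @export
reference_class <- function(reference_scores) {
  if (all(is.na(reference_scores))) stop("all scores are NA")
  which.max(reference_scores)   # which.max already takes the first maximum
}

#' Per-individual HFS at one locus
#'
#' HFS = mean of the two haplotypes' scores in the reference sequence class,
#' minus the reference haplotype's score, rounded to two decimals (half away
#' from zero). Symmetric in the two haplotypes; homozygous-reference
#' individuals get exactly 0.
#'
#' @param score_matrix haplotypes x 39 matrix, row 1 = reference haplotype.
#' @param individual_map n x 2 matrix of haplotype row indices.
#' @param class_index reference sequence class (default: argmax of row 1).
#' @return numeric vector of HFS values, named by the map's rownames.
#' @export
compute_hfs <- function(score_matrix, individual_map,
                        class_index = reference_class(score_matrix[1L, ])) {
  if (any(individual_map < 1L | individual_map > nrow(score_matrix)))
    stop("individual_map refers to a missing haplotype index")
  col <- score_matrix[, class_index]
  ref <- col[1L]
  raw <- (col[individual_map[, 1L]] + col[individual_map[, 2L]]) / 2 - ref
  out <- round_half_away(raw, 2L)
  names(out) <- rownames(individual_map)
  out
}

#' Squared correlation between adjacent loci's HFS columns
#'
#' The HFS analogue of linkage disequilibrium: for each pair of consecutive
#' loci on the same chromosome, the squared Pearson correlation of their HFS
#' columns. Constant columns give an undefined R^2 and are excluded from the
#' median.
#'
#' @param hfs individuals x loci HFS matrix, columns ordered like
#'   \code{loci}.
#' @param loci locus data.frame with \code{chrom} (and the column order of
#'   \code{hfs}).
#' @return list: \code{r2} per adjacent same-chromosome pair (NA where
#'   undefined), \code{median} over defined values.
#' @export
adjacent_ld <- function(hfs, loci) {
  if (ncol(hfs) < 2L) stop("need at least 2 loci")
  if (nrow(hfs) < 3L) stop("need at least 3 individuals")
  j <- seq_len(ncol(hfs) - 1L)
  same <- loci$chrom[j] == loci$chrom[j + 1L]
  r2 <- rep(NA_real_, ncol(hfs) - 1L)
  for (k in j[same]) {
    x <- hfs[, k]; y <- hfs[, k + 1L]
    if (stats::sd(x) > 0 && stats::sd(y) > 0)
      r2[k] <- stats::cor(x, y)^2
  }
  r2 <- r2[same]
  if (!any(is.finite(r2))) stop("fewer than 2 usable loci")
  list(r2 = r2, median = stats::median(r2, na.rm = TRUE))
}

#' End-to-end HFS matrix from FASTA + phased VCF + loci
#'
#' Per-locus driver: subset variants, QC, enumerate haplotypes, build
#' sequences, score, and assemble the individuals x loci HFS matrix.
#' Individuals dropped by QC at a locus get NA there.
#'
#' @param fasta [Biostrings::DNAStringSet] of the reference genome.
#' @param vcf parsed phased VCF from [read_phased_vcf()].
#' @param loci locus data.frame from [tile_genome()].
#' @param scorer vectorized scorer; default the surrogate.
#' @param locus_size locus width (default 4096).
#' @return list: \code{hfs} (individuals x loci matrix, columns =
#'   \code{locus_id}), \code{meta} (per-locus reference_class,
#'   reference_score, n_haplotypes, hfs_range), \code{loci}.
#' @export
hfs_from_vcf <- function(fasta, vcf, loci, scorer = make_scorer(),
                         locus_size = 4096L) {
  samples <- vcf$samples
  hfs <- matrix(NA_real_, nrow = length(samples), ncol = nrow(loci),
                dimnames = list(samples, loci$locus_id))
  meta <- data.frame(locus_id = loci$locus_id,
                     reference_class = NA_integer_,
                     reference_score = NA_real_,
                     n_haplotypes = NA_integer_,
                     hfs_range = NA_real_)
  for (i in seq_len(nrow(loci))) {
    sel <- vcf$variants$chrom == loci$chrom[i] &
      vcf$variants$pos > loci$start[i] & vcf$variants$pos <= loci$end[i]
    lg <- list(variants = vcf$variants[sel, , drop = FALSE],
               hapA = vcf$hapA[sel, , drop = FALSE],
               hapB = vcf$hapB[sel, , drop = FALSE],
               samples = samples)
    qc <- qc_filter(lg)
    haps <- enumerate_haplotypes(qc$lg)
    refseq <- get_locus_sequence(fasta, loci[i, ], locus_size)
    seqs <- haplotype_sequences(haps, refseq, qc$lg$variants, loci$start[i])
    sc <- score_sequences(scorer, seqs)
    cls <- reference_class(sc$scores[1L, ])
    vals <- compute_hfs(sc$scores, haps$individual_map, cls)
    hfs[names(vals), i] <- vals
    ref_score <- sc$scores[1L, cls]
    meta$reference_class[i] <- cls
    meta$reference_score[i] <- ref_score
    meta$n_haplotypes[i] <- nrow(sc$scores)
    meta$hfs_range[i] <- diff(range(sc$scores[, cls])) /
      max(abs(ref_score), .Machine$double.eps)
  }
  list(hfs = hfs, meta = meta, loci = loci)
}
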