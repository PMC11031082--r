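#' Per-locus haplotypes from phased genotypes
#'
#' A locus's genotypes are reduced to the set of distinct haplotypes observed
#' in the cohort, each haplotype is turned into a fixed-length DNA sequence
#' against the reference, and every individual is mapped to its two haplotype
#' ids. Variant QC (imputation INFO, Hardy-Weinberg, minor allele count,
#' missingness) runs before enumeration.
#'
#' @name haplotypes
NULL

#' Read a phased VCF into per-haplotype allele matrices
#'
#' Multi-allelic records are split into biallelic records. Genotypes must be
#' phased (\code{a|b}); an unphased heterozygote raises an error naming the
#' individual. Missing calls (\code{.}) become \code{NA}.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param info_field name of the INFO key holding imputation quality in
#'   [0, 1]; default \code{"INFO"}. Records without the key get \code{NA}
#'   (treated as passing by [qc_filter()]).
#' @return list with \code{variants} (data.frame: chrom, pos, ref, alt,
#'   info_score), \code{hapA}/\code{hapB} (variants x individuals integer
#'   matrices of 0 = REF / 1 = ALT / NA) and \code{samples}.
#' @export
read_phased_vcf <- function(path, info_field = "INFO") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  info_raw <- fix[, "INFO"]
  info_score <- vapply(info_raw, function(s) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", info_field, "=([^;]+)"), s))[[1]]
    if (length(m) == 2L) suppressWarnings(as.numeric(m[2L])) else NA_real_
  }, numeric(1), USE.NAMES = FALSE)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    g <- gt[i, ]
    unph <- grepl("/", g, fixed = TRUE) & !grepl("\\|", g) &
      !g %in% c(".", "./.", paste0(0:9, "/", 0:9))
    if (any(unph, na.rm = TRUE))
      stop("unphased genotype for individual ",
           samples[which(unph)[1L]], " at ", fix[i, "CHROM"], ":",
           fix[i, "POS"])
    parts <- strsplit(sub("/", "|", g, fixed = TRUE), "|", fixed = TRUE)
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    for (k in seq_along(alts)) {         # split multi-allelics
      rows[[length(rows) + 1L]] <- list(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], info_score = info_score[i],
        hapA = ifelse(is.na(a1), NA_integer_, as.integer(a1 == k)),
        hapB = ifelse(is.na(a2), NA_integer_, as.integer(a2 == k)))
    }
  }
  variants <- data.frame(
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, function(r) r$pos, integer(1)),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    info_score = vapply(rows, function(r) r$info_score, numeric(1)),
    stringsAsFactors = FALSE)
  hapA <- do.call(rbind, lapply(rows, `[[`, "hapA"))
  hapB <- do.call(rbind, lapply(rows, `[[`, "hapB"))
  colnames(hapA) <- colnames(hapB) <- samples
  list(variants = variants, hapA = hapA, hapB = hapB, samples = samples)
}

#' Hardy-Weinberg exact test p-value
#'
#' Exact (non mid-p) two-sided test of Hardy-Weinberg proportions from
#' genotype counts, summing the probabilities of all heterozygote
#' configurations no more likely than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  n_a <- 2L * n_hom_alt + n_het              # minor-allele side handled below
  n_A <- 2L * n_hom_ref + n_het
  rare <- min(n_a, n_A)
  hets <- seq.int(rare %% 2L, rare, by = 2L)  # parity-feasible het counts
  # probability of (AA, Aa, aa) under HWE conditional on the allele counts:
  # P(h) = n! / (AA! h! aa!) * 2^h * rare! (2n-rare)! / (2n)!
  logp <- vapply(hets, function(h) {
    aa <- (rare - h) %/% 2L
    AA <- n - aa - h
    lgamma(n + 1) - lgamma(AA + 1) - lgamma(h + 1) - lgamma(aa + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2L * n - rare + 1) -
      lgamma(2L * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- which(hets == n_het)
  if (!length(obs)) return(1)   # inconsistent counts; be permissive
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Variant and individual QC within one locus
#'
#' A variant is retained iff its imputation quality is at least
#' \code{min_info} (or absent), its Hardy-Weinberg exact p-value is at least
#' \code{min_hwe_p}, its minor allele count (over non-missing haplotypes of
#' retained individuals) is at least \code{min_mac}, and its genotype missing
#' rate is at most \code{max_missing}. Individuals missing more than
#' \code{max_ind_missing} of the retained variants are dropped.
#'
#' @param lg locus genotypes from [read_phased_vcf()] (possibly subset to a
#'   locus).
#' @param min_info,min_hwe_p,min_mac,max_missing,max_ind_missing thresholds;
#'   defaults 0.8, 1e-6, 10, 0.10, 0.10.
#' @return list: \code{lg} (retained variants, retained individuals),
#'   \code{dropped_individuals}, \code{removed_variants} (data.frame with a
#'   \code{reason} column).
#' @export
qc_filter <- function(lg, min_info = 0.8, min_hwe_p = 1e-6, min_mac = 10L,
                      max_missing = 0.10, max_ind_missing = 0.10) {
  n_ind <- length(lg$samples)
  if (n_ind == 0L) stop("no individuals in locus genotypes")
  nv <- nrow(lg$variants)
  if (is.null(nv) || nv == 0L)
    return(list(lg = lg, dropped_individuals = character(0),
                removed_variants = cbind(lg$variants,
                                         reason = character(0))))
  reason <- rep(NA_character_, nv)
  for (i in seq_len(nv)) {
    a <- lg$hapA[i, ]; b <- lg$hapB[i, ]
    miss <- is.na(a) | is.na(b)
    inf <- lg$variants$info_score[i]
    ac <- sum(a[!miss]) + sum(b[!miss])
    an <- 2L * sum(!miss)
    mac <- min(ac, an - ac)
    g <- a[!miss] + b[!miss]
    hwe <- hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
    if (!is.na(inf) && inf < min_info) reason[i] <- "info"
    else if (hwe < min_hwe_p) reason[i] <- "hwe"
    else if (mac < min_mac) reason[i] <- "mac"
    else if (mean(miss) > max_missing) reason[i] <- "missing"
  }
  keep <- is.na(reason)
  removed <- cbind(lg$variants[!keep, , drop = FALSE],
                   reason = reason[!keep])
  lg$variants <- lg$variants[keep, , drop = FALSE]
  lg$hapA <- lg$hapA[keep, , drop = FALSE]
  lg$hapB <- lg$hapB[keep, , drop = FALSE]

  dropped <- character(0)
  if (nrow(lg$variants)) {
    ind_miss <- colMeans(is.na(lg$hapA) | is.na(lg$hapB))
    dropped <- lg$samples[ind_miss > max_ind_missing]
    keep_ind <- !(lg$samples %in% dropped)
    lg$hapA <- lg$hapA[, keep_ind, drop = FALSE]
    lg$hapB <- lg$hapB[, keep_ind, drop = FALSE]
    lg$samples <- lg$samples[keep_ind]
  }
  list(lg = lg, dropped_individuals = dropped, removed_variants = removed)
}

#' Enumerate distinct haplotypes over retained variants
#'
#' Haplotypes are defined by their allele vectors. Missing haplotype calls
#' that survived QC are filled with the reference allele (counted in
#' \code{n_ref_filled}). The all-reference haplotype is always present at
#' index 1, even when absent from the cohort.
#'
#' @param lg QC'd locus genotypes (see [qc_filter()]).
#' @return list: \code{alleles} (distinct haplotypes x variants 0/1 matrix,
#'   row 1 = reference), \code{individual_map} (n x 2 matrix of haplotype
#'   indices), \code{hap_counts} (occurrences per haplotype, summing to 2n),
#'   \code{samples}, \code{n_ref_filled}.
#' @export
enumerate_haplotypes <- function(lg) {
  n_ind <- length(lg$samples)
  nv <- nrow(lg$variants)
  if (nv == 0L) {
    return(list(alleles = matrix(integer(0), nrow = 1, ncol = 0),
                individual_map = matrix(1L, nrow = n_ind, ncol = 2,
                                        dimnames = list(lg$samples, NULL)),
                hap_counts = 2L * n_ind, samples = lg$samples,
                n_ref_filled = 0L))
  }
  hapA <- lg$hapA; hapB <- lg$hapB
  n_fill <- sum(is.na(hapA)) + sum(is.na(hapB))
  hapA[is.na(hapA)] <- 0L
  hapB[is.na(hapB)] <- 0L
  all_haps <- cbind(hapA, hapB)            # variants x 2n
  keys <- apply(all_haps, 2L, paste, collapse = "")
  ref_key <- paste(rep("0", nv), collapse = "")
  uniq <- unique(c(ref_key, keys))
  idx <- match(keys, uniq)
  alleles <- do.call(rbind, lapply(strsplit(uniq, ""), as.integer))
  map <- cbind(idx[seq_len(n_ind)], idx[n_ind + seq_len(n_ind)])
  rownames(map) <- lg$samples
  counts <- tabulate(idx, nbins = length(uniq))
  list(alleles = alleles, individual_map = map, hap_counts = counts,
       samples = lg$samples, n_ref_filled = n_fill)
}

#' Build the fixed-length DNA sequence of one haplotype
#'
#' Alternate alleles are spliced into the reference sequence left to right.
#' The sequence start stays anchored on the locus start: a net insertion of
#' k bp discards the last k bases, a net deletion appends k \code{N}s, so the
#' result always has \code{nchar(reference_seq)} bases.
#'
#' @param reference_seq locus reference sequence (single string, typically
#'   4096 bp; short terminal loci should be N-padded before calling).
#' @param alleles integer vector (0 = REF, 1 = ALT) over the locus variants.
#' @param variants data.frame with \code{pos} (1-based genomic), \code{ref},
#'   \code{alt}, sorted by position.
#' @param locus_start 0-based locus start used to convert positions to
#'   offsets.
#' @return DNA string of length \code{nchar(reference_seq)}.
#' @export
build_sequence <- function(reference_seq, alleles, variants, locus_start) {
  L <- nchar(reference_seq)
  if (length(alleles) != nrow(variants))
    stop("allele vector and variant table disagree in length")
  apply_idx <- which(alleles == 1L)
  if (!length(apply_idx)) return(reference_seq)
  v <- variants[apply_idx, , drop = FALSE]
  off <- v$pos - locus_start          # 1-based offset within the locus
  ord <- order(off)
  v <- v[ord, , drop = FALSE]; off <- off[ord]
  if (any(off < 1L | off > L))
    stop("variant position outside the locus")
  # truncate REF spans crossing the 3' locus boundary
  ref_len <- pmin(nchar(v$ref), L - off + 1L)
  ends <- off + ref_len - 1L
  if (any(off[-1L] <= ends[-length(ends)]))
    stop("overlapping variants on one haplotype")
  pieces <- character(2L * nrow(v) + 1L)
  cursor <- 1L
  for (i in seq_len(nrow(v))) {
    obs <- substr(reference_seq, off[i], ends[i])
    exp_ref <- substr(v$ref[i], 1L, ref_len[i])
    if (toupper(obs) != toupper(exp_ref))
      stop("allele inconsistent with reference at offset ", off[i],
           " (expected ", exp_ref, ", found ", obs, ")")
    pieces[2L * i - 1L] <- substr(reference_seq, cursor, off[i] - 1L)
    pieces[2L * i] <- v$alt[i]
    cursor <- ends[i] + 1L
  }
  pieces[2L * nrow(v) + 1L] <- substr(reference_seq, cursor, L)
  seq <- paste(pieces, collapse = "")
  if (nchar(seq) > L) seq <- substr(seq, 1L, L)            # 3' truncation
  if (nchar(seq) < L)
    seq <- paste0(seq, strrep("N", L - nchar(seq)))         # 3' N-padding
  seq
}

#' Distinct haplotype sequences for one locus
#'
#' @param haps haplotype enumeration from [enumerate_haplotypes()].
#' @param reference_seq locus reference sequence (string).
#' @param variants retained variant data.frame (see [build_sequence()]).
#' @param locus_start 0-based locus start.
#' @return character vector of sequences, element 1 the reference.
#' @export
haplotype_sequences <- function(haps, reference_seq, variants, locus_start) {
  vapply(seq_len(nrow(haps$alleles)), function(i)
    build_sequence(reference_seq, haps$alleles[i, ], variants, locus_start),
    character(1))
}

#' Fetch (and N-pad) the reference sequence of a locus
#'
#' @param fasta a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @param locus one-row locus data.frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @param locus_size target length; shorter terminal loci are N-padded at the
#'   3' end. Default 4096.
#' @return upper-case sequence string of length \code{locus_size}.
#' @export
get_locus_sequence <- function(fasta, locus, locus_size = 4096L) {
  chrom <- locus$chrom[1L]
  if (!chrom %in% names(fasta)) stop("chromosome ", chrom, " not in FASTA")
  s <- as.character(Biostrings::subseq(fasta[[chrom]],
                                       start = locus$start[1L] + 1L,
                                       end = locus$end[1L]))
  s <- toupper(s)
  if (nchar(s) < locus_size)
    s <- paste0(s, strrep("N", locus_size - nchar(s)))
  s
}
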