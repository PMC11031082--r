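#' Generate an end-to-end synthetic test cohort
#'
#' Writes a toy reference FASTA, a phased VCF, per-sample chromatin-state
#' BEDs, an assembly-gap BED and a phenotype/covariate TSV, plus a JSON
#' manifest of every planted truth (variant positions, the causal locus,
#' expected distinct-haplotype counts). The causal variant is a 6-bp
#' insertion, so it shifts the downstream frame and is guaranteed to move
#' sequence-class scores; the phenotype is its dosage effect plus noise.
#'
#' @param dir output directory (created if needed).
#' @param n_individuals cohort size; default 60.
#' @param chrom_sizes named integer vector; default
#'   \code{c(chr1 = 40960, chr2 = 24576)}.
#' @param n_snps_per_locus SNP count planted in each variable locus;
#'   default 2.
#' @param effect causal dosage effect on the phenotype; default 1.5.
#' @param seed integer seed.
#' @return (invisibly) list of file paths plus the manifest.
#' @export
generate_fixture_cohort <- function(dir, n_individuals = 60L,
                                    chrom_sizes = c(chr1 = 40960L,
                                                    chr2 = 24576L),
                                    n_snps_per_locus = 2L, effect = 1.5,
                                    seed = 1L) {
  stopifnot(sum(chrom_sizes) <= 5e6)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  genome <- lapply(chrom_sizes, function(sz)
    paste(sample(bases, sz, replace = TRUE), collapse = ""))

  fasta <- file.path(dir, "genome.fa")
  writeLines(unlist(lapply(names(genome), function(ch)
    c(paste0(">", ch),
      substring(genome[[ch]],
                seq(1, nchar(genome[[ch]]), 80),
                pmin(seq(1, nchar(genome[[ch]]), 80) + 79,
                     nchar(genome[[ch]])))))), fasta)

  # chromatin states: two tissues x two samples; one shared active region
  # per chromosome plus private noise intervals
  active <- data.frame(chrom = names(chrom_sizes),
                       start = c(10000L, 8000L),
                       end = c(11000L, 9500L))
  states_dir <- file.path(dir, "states")
  dir.create(states_dir, showWarnings = FALSE)
  state_files <- character(0)
  for (tissue in c("tissueA", "tissueB")) for (samp in 1:2) {
    noise_start <- sample.int(3000L, 2L) + c(20000L, 2000L)
    bed <- rbind(
      data.frame(chrom = active$chrom, start = active$start,
                 end = active$end, name = "TSS"),
      data.frame(chrom = names(chrom_sizes), start = noise_start,
                 end = noise_start + 400L,
                 name = if (samp == 1L) "EnhA" else "Quies"))
    f <- file.path(states_dir, paste0(tissue, "_s", samp, ".bed"))
    write_bed(bed[order(bed$chrom, bed$start), ], f)
    state_files <- c(state_files, f)
  }
  gaps <- data.frame(chrom = "chr2", start = 20000L, end = 21000L)
  gaps_file <- file.path(dir, "gaps.bed")
  write_bed(gaps, gaps_file)

  # variants: SNPs in three loci per chromosome plus one causal 6-bp
  # insertion inside the chr1 active-region locus
  vrows <- list()
  plant_snps <- function(chrom, lo, hi) {
    pos <- sort(sample(seq.int(lo, hi), n_snps_per_locus))
    for (p in pos) {
      ref <- substr(genome[[chrom]], p, p)
      alt <- sample(setdiff(bases, ref), 1L)
      f <- stats::runif(1, 0.2, 0.4)
      vrows[[length(vrows) + 1L]] <<- list(
        chrom = chrom, pos = p, ref = ref, alt = alt, af = f,
        causal = FALSE)
    }
  }
  plant_snps("chr1", 10050L, 10950L)   # inside the active locus
  plant_snps("chr1", 25000L, 26000L)
  plant_snps("chr2", 8100L, 9400L)
  plant_snps("chr2", 12500L, 13500L)
  ins_pos <- 10500L
  ins_ref <- substr(genome$chr1, ins_pos, ins_pos)
  man <- surrogate_manifest()
  # payload of motifs from the locus's own reference class (the class whose
  # score defines the HFS), so the insertion reliably moves that score; the
  # centered locus on the chr1 active region is [center-2048, center+2048)
  ctr <- floor((10000L + 11000L) / 2)
  win <- substr(genome$chr1, ctr - 2048L + 1L, ctr + 2048L)
  ref_cls <- reference_class(surrogate_score(win))
  payload <- paste(rep(man$motif[man$class_index == ref_cls][1:2], 3L),
                   collapse = "")
  ins_alt <- paste0(ins_ref, payload)
  vrows[[length(vrows) + 1L]] <- list(chrom = "chr1", pos = ins_pos,
                                      ref = ins_ref, alt = ins_alt,
                                      af = 0.3, causal = TRUE)
  variants <- do.call(rbind, lapply(vrows, as.data.frame))
  variants <- variants[order(variants$chrom, variants$pos), ]
  dup <- duplicated(variants[, c("chrom", "pos")])
  variants <- variants[!dup, ]

  ids <- sprintf("ind%03d", seq_len(n_individuals))
  hapA <- matrix(0L, nrow(variants), n_individuals)
  hapB <- matrix(0L, nrow(variants), n_individuals)
  for (i in seq_len(nrow(variants))) {
    repeat {
      a <- stats::rbinom(n_individuals, 1L, variants$af[i])
      b <- stats::rbinom(n_individuals, 1L, variants$af[i])
      mac <- min(sum(a + b), 2L * n_individuals - sum(a + b))
      if (mac >= 10L) break
    }
    hapA[i, ] <- a; hapB[i, ] <- b
  }

  vcf_file <- file.path(dir, "cohort.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- vapply(seq_len(nrow(variants)), function(i) {
    gt <- paste0(hapA[i, ], "|", hapB[i, ])
    paste(c(variants$chrom[i], variants$pos[i], ".", variants$ref[i],
            variants$alt[i], ".", "PASS", "INFO=0.99", "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf_file)

  dosage <- hapA[which(variants$causal), ] + hapB[which(variants$causal), ]
  pheno <- effect * dosage + stats::rnorm(n_individuals)
  pheno_file <- file.path(dir, "phenotype.tsv")
  utils::write.table(
    data.frame(id = ids, trait = round(pheno, 6),
               age = sample(40:70, n_individuals, replace = TRUE),
               sex = stats::rbinom(n_individuals, 1L, 0.5)),
    pheno_file, sep = "\t", quote = FALSE, row.names = FALSE)

  # expected distinct haplotypes per planted window (all-REF haplotype
  # included even when unobserved), recomputed from the raw allele matrices
  windows <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = c(10000L, 25000L, 8100L, 12500L),
    end = c(11000L, 26001L, 9401L, 13501L))
  hap_counts <- lapply(seq_len(nrow(windows)), function(w) {
    ii <- which(variants$chrom == windows$chrom[w] &
                  variants$pos >= windows$start[w] &
                  variants$pos <= windows$end[w])
    keys <- apply(cbind(hapA[ii, , drop = FALSE],
                        hapB[ii, , drop = FALSE]), 2L, paste, collapse = "")
    list(chrom = windows$chrom[w], start = windows$start[w],
         end = windows$end[w],
         n_haplotypes = length(unique(c(
           paste(rep("0", length(ii)), collapse = ""), keys))))
  })
  manifest <- list(
    seed = seed, n_individuals = n_individuals,
    chrom_sizes = as.list(chrom_sizes),
    active_regions = active,
    variants = variants,
    causal = list(chrom = "chr1", pos = ins_pos, alt = ins_alt,
                  effect = effect),
    expected_haplotypes = hap_counts)
  manifest_file <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(fasta = fasta, vcf = vcf_file, states = state_files,
                 gaps = gaps_file, phenotype = pheno_file,
                 manifest_file = manifest_file, manifest = manifest))
}
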