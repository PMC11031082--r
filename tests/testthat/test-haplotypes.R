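# build a locus-genotype object by hand: alleles as variants x individuals
make_lg <- function(hapA, hapB, info = NULL, pos = NULL) {
  nv <- nrow(hapA)
  list(variants = data.frame(
    chrom = "chr1",
    pos = if (is.null(pos)) seq(100L, by = 50L, length.out = nv) else pos,
    ref = rep("A", nv), alt = rep("G", nv),
    info_score = if (is.null(info)) rep(NA_real_, nv) else info),
    hapA = hapA, hapB = hapB,
    samples = sprintf("s%02d", seq_len(ncol(hapA))))
}

test_that("QC removes variants failing INFO, HWE, MAC and missingness rules", {
  n <- 100L
  set.seed(1)
  # common well-behaved variant (HWE proportions, MAC >> 10)
  good <- rbinom(n, 1L, 0.3)
  goodB <- rbinom(n, 1L, 0.3)
  # allele count 9 < 10 -> removed
  rare <- c(rep(1L, 9L), rep(0L, n - 9L))
  # extreme heterozygote deficit -> HWE exact p far below 1e-6
  defA <- c(rep(1L, 50L), rep(0L, 50L))
  hapA <- rbind(good, rare, defA)
  hapB <- rbind(goodB, integer(n), defA)
  lg <- make_lg(hapA, hapB, info = c(NA, NA, NA))
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)

  qc <- qc_filter(lg)
  expect_equal(nrow(qc$lg$variants), 1L)
  expect_setequal(qc$removed_variants$reason, c("mac", "hwe"))
  expect_length(qc$dropped_individuals, 0L)

  # low imputation quality -> removed even if genotypes are fine
  lg2 <- make_lg(rbind(good), rbind(goodB), info = 0.79)
  expect_equal(qc_filter(lg2)$removed_variants$reason, "info")
  lg3 <- make_lg(rbind(good), rbind(goodB), info = 0.8)
  expect_equal(nrow(qc_filter(lg3)$lg$variants), 1L)

  # all thresholds satisfied -> identity
  lg4 <- make_lg(rbind(good, goodB), rbind(goodB, good))
  qc4 <- qc_filter(lg4)
  expect_equal(qc4$lg$variants, lg4$variants)
  expect_length(qc4$dropped_individuals, 0L)

  # an individual missing > 10% of retained variants is dropped
  hapA5 <- rbind(good, goodB, rbinom(n, 1, .3), rbinom(n, 1, .3),
                 rbinom(n, 1, .3))
  hapB5 <- rbind(goodB, good, rbinom(n, 1, .3), rbinom(n, 1, .3),
                 rbinom(n, 1, .3))
  hapA5[1:2, 1L] <- NA            # individual 1 misses 2/5 = 40%
  lg5 <- make_lg(hapA5, hapB5)
  qc5 <- qc_filter(lg5)
  expect_equal(qc5$dropped_individuals, "s01")
  expect_equal(length(qc5$lg$samples), n - 1L)

  expect_error(qc_filter(list(variants = data.frame(), samples = character(0))),
               "no individuals")
})

test_that("HWE exact test agrees with a permutation oracle", {
  cases <- list(c(21, 18, 11), c(40, 8, 2), c(5, 20, 25))
  for (cs in cases) {
    p_exact <- hwe_exact_p(cs[1], cs[2], cs[3])
    p_mc <- oracle_hwe_mc(cs[1], cs[2], cs[3], reps = 40000L, seed = 42L)
    expect_lt(abs(p_exact - p_mc), 0.02)
  }
  expect_equal(hwe_exact_p(25, 50, 25), 1)
})

test_that("haplotype enumeration yields distinct allele vectors with reference first", {
  # all homozygous reference: a single haplotype, everyone maps to (1,1)
  lg <- make_lg(matrix(0L, 1, 3), matrix(0L, 1, 3))
  h <- enumerate_haplotypes(lg)
  expect_equal(nrow(h$alleles), 1L)
  expect_true(all(h$individual_map == 1L))
  expect_equal(sum(h$hap_counts), 6L)

  # one phased heterozygote 0|1: two haplotypes, map (1, 2)
  lg2 <- make_lg(matrix(c(0L, 0L, 0L), 1), matrix(c(1L, 0L, 0L), 1))
  h2 <- enumerate_haplotypes(lg2)
  expect_equal(nrow(h2$alleles), 2L)
  expect_equal(unname(h2$individual_map[1L, ]), c(1L, 2L))

  # two SNPs, pairs 0|0 1|1 and 1|0 0|1 -> haplotypes {00, 11, 10, 01}
  hapA <- matrix(c(0L, 0L, 1L, 0L), 2)
  hapB <- matrix(c(1L, 1L, 0L, 1L), 2)
  h3 <- enumerate_haplotypes(make_lg(hapA, hapB))
  expect_equal(nrow(h3$alleles), 4L)
  expect_equal(sum(h3$hap_counts), 4L)

  # counts invariant under reordering individuals
  perm <- c(2L, 1L)
  h3p <- enumerate_haplotypes(make_lg(hapA[, perm], hapB[, perm]))
  expect_setequal(h3$hap_counts, h3p$hap_counts)

  # reference haplotype present even when absent from the sample
  h4 <- enumerate_haplotypes(make_lg(matrix(1L, 1, 2), matrix(1L, 1, 2)))
  expect_equal(nrow(h4$alleles), 2L)
  expect_equal(h4$alleles[1L, ], 0L)
  expect_equal(h4$hap_counts[1L], 0L)
})

test_that("sequence construction anchors the 5' end and fixes length at 4096", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 4096, replace = TRUE),
               collapse = "")
  v_snp <- data.frame(pos = 101L, ref = substr(ref, 101, 101), alt = "X")
  out <- build_sequence(ref, 1L, v_snp, 0L)
  expect_equal(nchar(out), 4096L)
  diffs <- which(strsplit(out, "")[[1]] != strsplit(ref, "")[[1]])
  expect_equal(diffs, 101L)

  # 5-bp deletion: edited 4091-bp string plus NNNNN
  v_del <- data.frame(pos = 201L, ref = substr(ref, 201, 206),
                      alt = substr(ref, 201, 201))
  del <- build_sequence(ref, 1L, v_del, 0L)
  expect_equal(nchar(del), 4096L)
  expect_equal(substr(del, 4092, 4096), "NNNNN")
  expect_equal(substr(del, 1, 200), substr(ref, 1, 200))
  expect_equal(substr(del, 201, 4091), paste0(substr(ref, 201, 201),
                                              substr(ref, 207, 4096)))

  # 3-bp insertion: first 4096 bp of the 4099-bp edited string
  v_ins <- data.frame(pos = 301L, ref = substr(ref, 301, 301),
                      alt = paste0(substr(ref, 301, 301), "TAG"))
  ins <- build_sequence(ref, 1L, v_ins, 0L)
  expect_equal(nchar(ins), 4096L)
  expect_equal(substr(ins, 302, 304), "TAG")
  expect_equal(substr(ins, 305, 4096), substr(ref, 302, 4093))

  # reference allele vector returns the reference exactly
  expect_identical(build_sequence(ref, 0L, v_ins, 0L), ref)

  expect_error(build_sequence(ref, 1L,
                              data.frame(pos = 101L, ref = "T", alt = "G"),
                              0L), "inconsistent")
  v_overlap <- data.frame(pos = c(401L, 403L),
                          ref = c(substr(ref, 401, 405), substr(ref, 403, 403)),
                          alt = c("A", "C"))
  expect_error(build_sequence(ref, c(1L, 1L), v_overlap, 0L), "overlap")

  # property: random indel/SNP mixes always give 4096 bases
  set.seed(11)
  for (k in 1:20) {
    pos <- sort(sample(seq(10L, 4000L, by = 60L), 5L))
    vv <- do.call(rbind, lapply(pos, function(p) {
      type <- sample(c("snp", "ins", "del"), 1L)
      r <- switch(type, snp = substr(ref, p, p),
                  ins = substr(ref, p, p),
                  del = substr(ref, p, p + sample(1:5, 1L)))
      a <- switch(type,
                  snp = sample(setdiff(c("A", "C", "G", "T"),
                                       substr(ref, p, p)), 1L),
                  ins = paste0(substr(ref, p, p),
                               paste(sample(c("A", "C", "G", "T"),
                                            sample(1:6, 1L), replace = TRUE),
                                     collapse = "")),
                  del = substr(ref, p, p))
      data.frame(pos = p, ref = r, alt = a)
    }))
    out <- build_sequence(ref, rep(1L, nrow(vv)), vv, 0L)
    expect_equal(nchar(out), 4096L)
    expect_false(grepl("[^ACGTN]", out))
  }
})

test_that("phased VCF parsing splits multi-allelics and rejects unphased calls", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"q\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\tINFO=0.95\tGT\t0|1\t1|1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\tINFO=0.90\tGT\t0|2\t1|0",
    "chr1\t300\t.\tT\tA\t.\tPASS\t.\tGT\t.|.\t0|0"), tmp)
  v <- read_phased_vcf(tmp)
  expect_equal(nrow(v$variants), 4L)   # multi-allelic split into 2 records
  expect_equal(v$variants$alt[2:3], c("T", "G"))
  expect_equal(v$variants$info_score, c(0.95, 0.90, 0.90, NA))
  expect_equal(unname(v$hapA[, "s1"]), c(0L, 0L, 0L, NA))
  expect_equal(unname(v$hapB[, "s1"]), c(1L, 0L, 1L, NA))
  expect_equal(unname(v$hapA[, "s2"]), c(1L, 1L, 0L, 0L))

  bad <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), bad)
  expect_error(read_phased_vcf(bad), "unphased.*s1")
})
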