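test_that("overlap annotation applies the 10% locus-fraction rule exactly", {
  loci <- data.frame(chrom = "chr1", start = c(0L, 8192L, 16384L),
                     end = c(4096L, 12288L, 20480L))
  feat <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
  # 410 of 4096 bp: flagged; 409: not; zero overlap: not
  expect_equal(annotate_overlap(loci, feat(0L, 410L)), c(1L, 0L, 0L))
  expect_equal(annotate_overlap(loci, feat(0L, 409L)), c(0L, 0L, 0L))
  expect_equal(annotate_overlap(loci, feat(30000L, 31000L)), c(0L, 0L, 0L))
  # split features accumulate per-base coverage
  two <- rbind(feat(0L, 205L), feat(1000L, 1205L))
  expect_equal(annotate_overlap(loci, two)[1L], 1L)

  # monotonicity: enlarging the feature never flips 1 -> 0
  set.seed(41)
  for (k in 1:20) {
    s <- sample.int(20000L, 1L); w <- sample.int(2000L, 1L)
    f1 <- feat(s, s + w)
    f2 <- feat(max(0L, s - 500L), s + w + 500L)
    expect_true(all(annotate_overlap(loci, f2) >=
                      annotate_overlap(loci, f1)))
  }
})

test_that("pathway pruning filters by size and removes overlapping neighbors", {
  gs <- list(tiny = letters[1:4],
             huge = paste0("g", 1:600),
             a = paste0("g", 1:10),
             b = c(paste0("g", 1:4), paste0("h", 1:46)),
             c = paste0("x", 1:20))
  pruned <- prune_pathways(gs)
  expect_false("tiny" %in% names(pruned))   # 4 genes, needs > 5
  expect_false("huge" %in% names(pruned))   # 600 genes, needs < 500
  # a (10 genes) shares 4 with b (50): 4/10 = 0.4 > 0.3 -> smaller removed
  expect_false("a" %in% names(pruned))
  expect_true(all(c("b", "c") %in% names(pruned)))

  disjoint <- list(p1 = paste0("a", 1:10), p2 = paste0("b", 1:10),
                   p3 = paste0("c", 1:10))
  expect_equal(names(prune_pathways(disjoint)), names(disjoint))

  # idempotency on random collections
  set.seed(42)
  pool <- paste0("g", 1:150)
  rand <- lapply(1:15, function(i) sample(pool, sample(6:60, 1L)))
  names(rand) <- paste0("s", 1:15)
  once <- prune_pathways(rand)
  expect_identical(prune_pathways(once), once)
  expect_error(prune_pathways(list()), "empty")
})

test_that("pathway linking needs one SNP with link score strictly above 0.5", {
  loci <- data.frame(chrom = "chr1", start = c(0L, 4096L),
                     end = c(4096L, 8192L))
  links <- data.frame(chrom = "chr1", pos = c(100L, 5000L, 6000L),
                      gene = c("G1", "G2", "G3"),
                      score = c(0.6, 0.5, 0.9))
  expect_equal(link_pathway(loci, links, c("G1")), c(1L, 0L))
  expect_equal(link_pathway(loci, links, c("G2")), c(0L, 0L))  # exactly 0.5
  expect_equal(link_pathway(loci, links, c("G3")), c(0L, 1L))
  expect_equal(link_pathway(loci, links, c("NOPE")), c(0L, 0L))
})

test_that("PIP regression recovers planted coefficients and skips collinear annotations", {
  set.seed(43)
  n <- 400L
  baseline <- cbind(b1 = rnorm(n), b2 = rnorm(n))
  annot <- rbinom(n, 1L, 0.3)
  pip <- 0.3 * annot + rnorm(n, 0, 0.05)
  r <- pip_regression(pip, baseline, annot)
  expect_false(r$skipped)
  expect_equal(r$coef, 0.3, tolerance = 0.05)
  expect_lt(r$p, 1e-10)

  dup <- pip_regression(pip, cbind(baseline, annot), annot)
  expect_true(dup$skipped)
  expect_equal(dup$reason, "collinear_with_baseline")

  # permuted annotations keep the nominal type-I rate
  set.seed(44)
  null_p <- vapply(1:200, function(i)
    pip_regression(rnorm(n, 0, 0.05), baseline, sample(annot))$p,
    numeric(1))
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.03)
})

test_that("the Bonferroni family rule and sign requirement decide significance", {
  set.seed(45)
  n <- 300L
  baseline <- cbind(b1 = rnorm(n))
  good <- rbinom(n, 1L, 0.4)
  neg <- rbinom(n, 1L, 0.4)
  weak <- rbinom(n, 1L, 0.4)
  pip <- 0.4 * good - 0.4 * neg + 0.02 * weak + rnorm(n, 0, 0.05)
  scan <- enrichment_scan(pip, baseline,
                          data.frame(good = good, neg = neg, weak = weak))
  expect_equal(scan$p_adj, pmin(scan$p * 3, 1))
  expect_true(scan$significant[scan$annotation == "good"])
  # strongly associated but negative coefficient: not significant
  expect_lt(scan$p[scan$annotation == "neg"], 0.05)
  expect_false(scan$significant[scan$annotation == "neg"])
  # Bonferroni arithmetic: raw 0.04 with 2 tests -> adjusted 0.08, not sig
  fake <- enrichment_scan(rnorm(100, 0, 0.05), cbind(b = rnorm(100)),
                          data.frame(x = rbinom(100, 1, .5),
                                     y = rbinom(100, 1, .5)))
  expect_equal(fake$p_adj, pmin(fake$p * 2, 1))
  expect_true(all(!fake$significant[fake$p_adj >= 0.05 |
                                      fake$coef <= 0]))
})

test_that("recurrently significant terms are removed from every trait", {
  traits <- paste0("t", 1:14)
  sig <- setNames(vector("list", 14L), traits)
  for (t in traits) sig[[t]] <- character(0)
  for (t in traits[1:8]) sig[[t]] <- c(sig[[t]], "confounder")  # 8/14 > 7
  for (t in traits[1:7]) sig[[t]] <- c(sig[[t]], "borderline")  # 7/14 = 7
  sig$t1 <- c(sig$t1, "specific")
  out <- filter_recurrent(sig)
  expect_equal(out$removed, "confounder")
  expect_false("confounder" %in% unlist(out$kept))
  expect_true("borderline" %in% out$kept$t1)
  expect_true("specific" %in% out$kept$t1)
})

test_that("baseline assembly aggregates per-position statistics by max/min/mean", {
  meta <- data.frame(n_haplotypes = c(3L, 5L), hfs_range = c(0.1, 0.4))
  rs <- matrix(runif(2 * 39), 2, 39,
               dimnames = list(NULL, sequence_class_names()))
  loci <- data.frame(chrom = "chr1", start = c(0L, 4096L),
                     end = c(4096L, 8192L))
  ps <- list(max_B = data.frame(chrom = "chr1", pos = c(10L, 20L, 5000L),
                                value = c(1, 7, 2)))
  bl <- baseline_annotations(meta, rs, position_stats = ps, loci = loci,
                             aggregate = c(max_B = "max"))
  expect_equal(ncol(bl), 2L + 39L + 1L)
  expect_equal(unname(bl[, "max_B"]), c(7, 2))
})
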