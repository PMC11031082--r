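# one-off generator for inst/extdata/surrogate_manifest.tsv (fixed seed)
set.seed(390604)
classes <- c(
  "P Promoter",
  "E1 Stem cell enhancer", "E2 Multi-tissue enhancer",
  "E3 Brain / muscle enhancer", "E4 Multi-tissue enhancer",
  "E5 B-cell-like enhancer", "E6 Weak epithelial enhancer",
  "E7 Monocyte enhancer", "E8 Weak multi-tissue enhancer",
  "E9 Liver / intestine enhancer", "E10 Brain enhancer",
  "E11 T-cell enhancer", "E12 Erythroblast-like enhancer",
  "TN1 Transcribed region 1", "TN2 Transcribed region 2",
  "TN3 Transcribed region 3", "TN4 Transcribed region 4",
  "L1 Low signal 1", "L2 Low signal 2", "L3 Low signal 3",
  "L4 Low signal 4", "L5 Low signal 5", "L6 Low signal 6",
  "L7 Low signal 7", "L8 Low signal 8",
  "HET1 Heterochromatin 1", "HET2 Heterochromatin 2",
  "HET3 Heterochromatin 3", "HET4 Heterochromatin 4",
  "HET5 Heterochromatin 5",
  "PC1 Polycomb heterochromatin", "PC2 Weak polycomb", "PC3 Polycomb",
  "PC4 Bivalent stem cell enhancer",
  "TF1 NANOG / FOXA1 binding", "TF2 CEBPB binding",
  "TF3 FOXA1 / AR / ESR1 binding", "TF4 OTX2 binding", "TF5 AR binding")
stopifnot(length(classes) == 39)
k <- 6L; n_motif <- 4L
seen <- character(0)
rows <- list()
for (ci in seq_along(classes)) {
  motifs <- character(0)
  while (length(motifs) < n_motif) {
    m <- paste(sample(c("A","C","G","T"), k, replace = TRUE), collapse = "")
    if (!(m %in% seen)) { motifs <- c(motifs, m); seen <- c(seen, m) }
  }
  w <- round(runif(n_motif, 0.05, 0.25), 3)
  rows[[ci]] <- data.frame(class_index = ci, class_name = classes[ci],
                           motif = motifs, weight = w)
}
man <- do.call(rbind, rows)
write.table(man, "inst/extdata/surrogate_manifest.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
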