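#' Round half away from zero
#'
#' Base R's \code{round()} rounds half to even; HFS values are instead rounded
#' half away from zero so that, e.g., a centered score of 0.505 becomes 0.51
#' and -0.505 becomes -0.51.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2, the HFS convention).
#' @return numeric vector rounded to \code{digits} decimals.
#' @export
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  # nudge by a relative epsilon so values stored as 0.505-1e-17 still round up
  sign(x) * floor(abs(x) * m + 0.5 + .Machine$double.eps * abs(x) * m) / m
}

#' Read a BED3+ file
#'
#' @param path path to a tab-separated BED file (no header). Columns beyond
#'   the third are kept and named \code{name}, \code{score}, \code{strand}
#'   then \code{V7}, ... in order.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) and any extra columns.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#",
                          quote = "")
  if (ncol(df) < 3L)
    stop("malformed BED file (fewer than 3 columns): ", path)
  extra <- c("name", "score", "strand")
  nm <- c("chrom", "start", "end",
          extra[seq_len(max(0L, min(ncol(df) - 3L, 3L)))])
  if (ncol(df) > 6L) nm <- c(nm, paste0("V", 7:ncol(df)))
  names(df) <- nm
  bad <- which(!is.finite(df$start) | !is.finite(df$end) | df$end <= df$start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], " in ", path,
         ": end must exceed start")
  df
}

#' Write intervals as BED
#'
#' @param df data.frame whose first three columns are chrom/start/end;
#'   remaining columns are appended as-is.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path: one set per line, fields \code{name}, \code{desc},
#'   then gene symbols, tab-separated.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) character(0) else unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

# internal: data.frame of loci -> GRanges
.loci_gr <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(start = loci$start + 1L,
                                          end = loci$end))
}

# internal: derive a fresh 32-bit sub-seed from a base seed and an index
.subseed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}
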