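#' Genome segmentation into fixed-size loci
#'
#' The unit of analysis is a 4096-bp locus. Loci are anchored on chromatin
#' "active regions" (TSS / transcribed / enhancer / promoter states shared by
#' at least half of the samples of a tissue): short regions get one locus
#' centered on them, long regions are tiled outward from their midpoint, and
#' the remaining genome is covered by non-overlapping gap-fill tiles.
#'
#' @name segmentation
NULL

#' Derive consensus active regions from per-sample chromatin-state intervals
#'
#' For each tissue, a base is called active when at least
#' \code{ceil(min_fraction * n_samples)} of that tissue's samples annotate it
#' with one of \code{active_states} (per-base counting, not interval
#' identity). The per-tissue consensus intervals are then unioned across
#' tissues and merged; intervals overlapping an assembly gap are removed.
#'
#' @param state_beds either a list of per-sample BED data.frames (a single
#'   tissue) or a named list of such lists (one element per tissue). Each
#'   data.frame needs columns \code{chrom}, \code{start}, \code{end} and
#'   \code{name} (the chromatin-state label), as returned by [read_bed()].
#' @param active_states character vector of state labels counted as active.
#' @param min_fraction minimum supporting-sample fraction within a tissue,
#'   in (0, 1]; default 0.5.
#' @param gaps optional BED data.frame of assembly gaps; consensus intervals
#'   overlapping any gap are dropped.
#' @return data.frame of merged active regions: \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{n_supporting}, the maximum
#'   per-base supporting-sample count inside the region (maximized over
#'   tissues).
#' @export
derive_active_regions <- function(state_beds, active_states,
                                  min_fraction = 0.5, gaps = NULL) {
  if (is.data.frame(state_beds)) state_beds <- list(state_beds)
  if (length(state_beds) == 0L)
    stop("empty sample set: each tissue needs at least one sample BED")
  if (is.data.frame(state_beds[[1L]])) state_beds <- list(state_beds)
  if (any(lengths(state_beds) == 0L))
    stop("empty sample set: each tissue needs at least one sample BED")
  stopifnot(min_fraction > 0, min_fraction <= 1)

  per_tissue <- lapply(state_beds, function(samples) {
    grl <- lapply(samples, function(bed) {
      .check_bed_df(bed)
      act <- bed[bed$name %in% active_states, , drop = FALSE]
      GenomicRanges::reduce(GenomicRanges::GRanges(
        act$chrom, IRanges::IRanges(start = act$start + 1L, end = act$end)))
    })
    k <- as.integer(ceiling(min_fraction * length(samples)))
    # align the per-sample coverage vectors on shared chromosome lengths
    chroms <- sort(unique(unlist(lapply(grl, function(g)
      as.character(GenomicRanges::seqnames(g))))))
    if (!length(chroms))
      return(list(consensus = GenomicRanges::GRanges(),
                  coverage = NULL))
    maxend <- vapply(chroms, function(ch) max(0L, unlist(lapply(
      grl, function(g) {
        gg <- g[as.character(GenomicRanges::seqnames(g)) == ch]
        if (length(gg)) max(GenomicRanges::end(gg)) else integer(0)
      }))), numeric(1))
    grl <- lapply(grl, function(g) {
      GenomeInfoDb::seqlevels(g) <- chroms
      GenomeInfoDb::seqlengths(g) <- maxend
      g
    })
    cov <- Reduce(`+`, lapply(grl, GenomicRanges::coverage))
    hit <- IRanges::slice(cov, lower = k, rangesOnly = TRUE)
    consensus <- GenomicRanges::GRanges(
      rep(names(hit), lengths(hit)), unlist(hit, use.names = FALSE))
    list(consensus = consensus, coverage = cov)
  })

  consensus <- GenomicRanges::reduce(
    do.call(c, unname(lapply(per_tissue, `[[`, "consensus"))))
  if (!is.null(gaps) && nrow(gaps)) {
    gap_gr <- GenomicRanges::GRanges(
      gaps$chrom, IRanges::IRanges(start = gaps$start + 1L, end = gaps$end))
    consensus <- consensus[!IRanges::overlapsAny(consensus, gap_gr)]
  }
  if (length(consensus) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_supporting = integer(0)))

  # support = per-base max over tissues of the supporting-sample count
  support <- vapply(seq_along(consensus), function(i) {
    reg <- consensus[i]
    max(vapply(per_tissue, function(tt) {
      cv <- tt$coverage
      if (is.null(cv)) return(0L)
      ch <- as.character(GenomicRanges::seqnames(reg))
      if (!ch %in% names(cv)) return(0L)
      st <- GenomicRanges::start(reg)
      en <- min(GenomicRanges::end(reg), length(cv[[ch]]))
      if (en < st) return(0L)
      v <- IRanges::Views(cv[[ch]], start = st, end = en)
      as.integer(max(max(v), 0L))
    }, integer(1)))
  }, integer(1))

  data.frame(chrom = as.character(GenomicRanges::seqnames(consensus)),
             start = GenomicRanges::start(consensus) - 1L,
             end = GenomicRanges::end(consensus),
             n_supporting = support,
             stringsAsFactors = FALSE)
}

.check_bed_df <- function(bed) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(bed)))
    stop("BED data.frame must carry columns chrom/start/end")
  bad <- which(bed$end <= bed$start)
  if (length(bad))
    stop("malformed BED line ", bad[1L], ": end must exceed start")
  invisible(TRUE)
}

#' Tile a genome into loci anchored on active regions
#'
#' Active regions shorter than \code{locus_size} receive a single locus
#' centered on the region (center = \code{floor((start+end)/2)}); longer
#' regions are tiled with \code{locus_size} windows outward from their
#' midpoint (the midpoint is a tile boundary; tiles are emitted alternately
#' rightward then leftward and only tiles overlapping the region are kept).
#' Candidate loci are processed in coordinate order; a candidate overlapping
#' an already-emitted locus is shifted right to abut it and dropped if it
#' then reaches into the next active region. The complement of the
#' active-derived loci (minus assembly gaps) is covered with gap-fill tiles;
#' complement remainders shorter than \code{locus_size} are emitted with
#' their true length and flagged \code{short} (the scoring step N-pads them).
#'
#' @param regions data.frame of active regions (\code{chrom}, \code{start},
#'   \code{end}), sorted and non-overlapping, e.g. from
#'   [derive_active_regions()]. May have zero rows.
#' @param chrom_sizes data.frame with columns \code{chrom} and \code{size}.
#' @param gaps optional BED data.frame of assembly gaps excluded from
#'   gap-fill tiling.
#' @param locus_size locus width in bp; positive even integer, default 4096.
#' @return data.frame of loci: \code{locus_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{length}, \code{origin} (\code{centered},
#'   \code{midpoint_tile} or \code{gap_fill}) and \code{short} flag, sorted
#'   by (chrom, start) and pairwise non-overlapping.
#' @export
tile_genome <- function(regions, chrom_sizes, gaps = NULL,
                        locus_size = 4096L) {
  if (!is.numeric(locus_size) || locus_size <= 0 || locus_size %% 2 != 0)
    stop("locus_size must be a positive even integer")
  locus_size <- as.integer(locus_size)
  half <- locus_size %/% 2L
  stopifnot(all(c("chrom", "size") %in% names(chrom_sizes)))
  if (is.null(regions))
    regions <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  if (nrow(regions)) {
    if (!all(regions$chrom %in% chrom_sizes$chrom))
      stop("region chromosome absent from chrom_sizes")
    sz <- chrom_sizes$size[match(regions$chrom, chrom_sizes$chrom)]
    if (any(regions$start < 0 | regions$end > sz))
      stop("region outside chromosome bounds")
  }

  out <- list()
  for (ch in chrom_sizes$chrom) {
    size <- chrom_sizes$size[chrom_sizes$chrom == ch][1L]
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    reg <- reg[order(reg$start), , drop = FALSE]

    cand <- .candidate_loci(reg, size, locus_size, half)
    kept <- .resolve_overlaps(cand, reg, size, locus_size)
    fills <- .gap_fill(kept, ch, size,
                       if (is.null(gaps)) NULL
                       else gaps[gaps$chrom == ch, , drop = FALSE],
                       locus_size)
    if (nrow(kept))
      kept <- data.frame(chrom = ch, kept, stringsAsFactors = FALSE)
    out[[ch]] <- rbind(
      if (nrow(kept)) kept else NULL,
      if (nrow(fills)) fills else NULL)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || !nrow(res))
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), origin = character(0),
                      short = logical(0)))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  data.frame(locus_id = sprintf("%s:%d-%d", res$chrom, res$start, res$end),
             res[, c("chrom", "start", "end")],
             length = res$end - res$start,
             origin = res$origin, short = res$short,
             stringsAsFactors = FALSE)
}

# candidate active-derived loci for one chromosome, coordinate-sorted
.candidate_loci <- function(reg, size, locus_size, half) {
  if (!nrow(reg))
    return(data.frame(start = integer(0), end = integer(0),
                      origin = character(0), region = integer(0)))
  rows <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    s <- reg$start[i]; e <- reg$end[i]
    if (e - s < locus_size) {
      ctr <- floor((s + e) / 2)
      st <- ctr - half
      rows[[i]] <- data.frame(start = st, end = st + locus_size,
                              origin = "centered", region = i)
    } else {
      m <- floor((s + e) / 2)
      n_right <- ceiling((e - m) / locus_size)
      n_left <- ceiling((m - s) / locus_size)
      st_r <- m + (seq_len(n_right) - 1L) * locus_size
      st_l <- m - seq_len(n_left) * locus_size
      st <- sort(c(st_r, st_l))
      rows[[i]] <- data.frame(start = st, end = st + locus_size,
                              origin = "midpoint_tile", region = i)
    }
  }
  cand <- do.call(rbind, rows)
  # clamp into the chromosome, preserving width where possible
  cand$start <- pmax(cand$start, 0L)
  over <- cand$end > size
  cand$start[over] <- pmax(size - locus_size, 0L)
  cand$end <- pmin(cand$start + locus_size, size)
  cand[order(cand$start, cand$end), , drop = FALSE]
}

# greedy left-to-right overlap resolution between candidate loci
.resolve_overlaps <- function(cand, reg, size, locus_size) {
  kept <- list(); prev_end <- -1L
  for (i in seq_len(nrow(cand))) {
    st <- cand$start[i]; en <- cand$end[i]
    if (st < prev_end) {            # shift right to abut the previous locus
      st <- prev_end
      en <- st + (cand$end[i] - cand$start[i])
      if (en > size) next
      ri <- cand$region[i]
      if (ri < nrow(reg) && en > reg$start[ri + 1L]) next  # next region's turf
    }
    kept[[length(kept) + 1L]] <- data.frame(
      start = st, end = en, origin = cand$origin[i],
      short = (en - st) < locus_size)
    prev_end <- en
  }
  if (!length(kept))
    return(data.frame(start = integer(0), end = integer(0),
                      origin = character(0), short = logical(0)))
  do.call(rbind, kept)
}

# tile the complement of emitted loci (minus gaps) with gap_fill loci
.gap_fill <- function(kept, ch, size, gaps, locus_size) {
  chrom_gr <- GenomicRanges::GRanges(ch, IRanges::IRanges(1L, size))
  used <- if (nrow(kept))
    GenomicRanges::GRanges(ch, IRanges::IRanges(kept$start + 1L, kept$end))
  else GenomicRanges::GRanges()
  if (!is.null(gaps) && nrow(gaps))
    used <- c(used, GenomicRanges::GRanges(
      ch, IRanges::IRanges(gaps$start + 1L, gaps$end)))
  comp <- GenomicRanges::setdiff(chrom_gr, used)
  rows <- list()
  for (i in seq_along(comp)) {
    s <- GenomicRanges::start(comp[i]) - 1L
    e <- GenomicRanges::end(comp[i])
    n_full <- (e - s) %/% locus_size
    if (n_full > 0) {
      st <- s + (seq_len(n_full) - 1L) * locus_size
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = st, end = st + locus_size,
        origin = "gap_fill", short = FALSE)
    }
    rem <- s + n_full * locus_size
    if (rem < e)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = rem, end = e,
        origin = "gap_fill", short = TRUE)
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), origin = character(0),
                      short = logical(0)))
  do.call(rbind, rows)
}

#' Shift loci toward the 5' end for sliding-window analysis
#'
#' Each locus keeps its length and moves \code{shift} bp upstream; loci that
#' would cross the chromosome start are clipped to start at 0 and flagged.
#'
#' @param loci locus data.frame from [tile_genome()].
#' @param shift shift in bp, must be smaller than the locus size; default
#'   2048.
#' @return data.frame like \code{loci} with updated coordinates, refreshed
#'   \code{locus_id} and a logical \code{clipped} column.
#' @export
sliding_shift <- function(loci, shift = 2048L) {
  if (nrow(loci) == 0L) {
    loci$clipped <- logical(0)
    return(loci)
  }
  if (any(shift >= loci$length))
    stop("shift must be smaller than the locus size")
  len <- loci$end - loci$start
  new_start <- pmax(loci$start - as.integer(shift), 0L)
  out <- loci
  out$start <- new_start
  out$end <- new_start + len
  out$clipped <- loci$start < shift
  out$locus_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}
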