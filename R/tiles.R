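# Genome-tile quantification of uniquely mapping piRNA-sized reads:
# exclusion mask (tRNA/snRNA/snoRNA +-100 nt plus the aubergine-like
# locus), fixed-width tiling with 5'-end assignment, hpRNA normalization,
# aggregation to piRNA-cluster abundances and ratios to a reference
# library.  Interval arithmetic goes through IRanges.

#' Build the tile-analysis exclusion mask
#'
#' Pads every tRNA, snRNA and snoRNA feature by `pad` nt on both sides,
#' clips to contig bounds, adds the aubergine-locus intervals unpadded, and
#' stores the result merged and sorted per contig.
#'
#' @param annotation feature annotation data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param pad padding in nt (default 100).
#' @return data.frame: contig, start, end (0-based half-open, merged).
#' @export
build_mask <- function(annotation, contig_lengths, pad = 100L) {
  pad_classes <- c("tRNA", "snRNA", "snoRNA")
  padded <- annotation[annotation$class %in% pad_classes, , drop = FALSE]
  aub <- annotation[annotation$class == "aub_locus", , drop = FALSE]
  iv <- rbind(
    if (nrow(padded)) data.frame(contig = padded$contig,
                                 start = pmax(0L, padded$start - pad),
                                 end = pmin(contig_lengths[padded$contig],
                                            padded$end + pad)),
    if (nrow(aub)) data.frame(contig = aub$contig, start = aub$start,
                              end = aub$end))
  if (is.null(iv) || nrow(iv) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(iv, iv$contig), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(contig = d$contig[1L], start = IRanges::start(r) - 1L,
               end = IRanges::end(r), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$contig, out$start), , drop = FALSE]
}

#' Tile counts of unique genome mappers
#'
#' Restricts to unique genome mappers of reads longer than 22 nt, removes
#' every alignment overlapping the exclusion mask by at least 1 nt, assigns
#' each surviving alignment to the tile containing its 5' end, and
#' normalizes counts per million hpRNA reads.  Tiles partition each contig
#' without overlap (the last tile of a contig may be shorter).
#'
#' @param unique_alignments output of [unique_genome_mappers()].
#' @param mask exclusion mask from [build_mask()].
#' @param contig_lengths named integer vector.
#' @param tile_width tile width in nt (default 1000); must be positive.
#' @param hpRNA_total normalization denominator; 0 gives `NA` per-million
#'   values.
#' @param min_len minimum read length (default 23).
#' @return data.frame: contig, start, end, count, per_million; attributes
#'   `masked_out` (weight removed by the mask) and `total_weight` (weight
#'   entering the tiles).
#' @export
tile_counts <- function(unique_alignments, mask, contig_lengths,
                        tile_width = 1000L, hpRNA_total = 0,
                        min_len = 23L) {
  if (tile_width <= 0L) stop("tile_width must be positive")
  a <- unique_alignments[unique_alignments$length >= min_len, , drop = FALSE]
  masked_out <- 0
  if (nrow(a) > 0L && nrow(mask) > 0L) {
    hit <- rep(FALSE, nrow(a))
    for (ctg in unique(mask$contig)) {
      ai <- which(a$target == ctg)
      if (!length(ai)) next
      q <- IRanges::IRanges(start = a$start[ai] + 1L,
                            end = a$start[ai] + a$length[ai])
      m <- mask[mask$contig == ctg, , drop = FALSE]
      s <- IRanges::IRanges(start = m$start + 1L, end = m$end)
      hit[ai] <- IRanges::overlapsAny(q, s)
    }
    masked_out <- sum(a$weight[hit])
    a <- a[!hit, , drop = FALSE]
  }
  tiles <- do.call(rbind, lapply(names(contig_lengths), function(ctg) {
    starts <- seq(0L, contig_lengths[[ctg]] - 1L, by = tile_width)
    data.frame(contig = ctg, start = starts,
               end = pmin(starts + tile_width, contig_lengths[[ctg]]),
               stringsAsFactors = FALSE)
  }))
  tiles$count <- 0
  if (nrow(a) > 0L) {
    p5 <- ifelse(a$strand == "+", a$start, a$start + a$length - 1L)
    key <- paste(a$target, (p5 %/% tile_width) * tile_width)
    tot <- tapply(a$weight, key, sum)
    tkey <- paste(tiles$contig, tiles$start)
    idx <- match(names(tot), tkey)
    tiles$count[idx] <- as.numeric(tot)
  }
  tiles$per_million <- if (hpRNA_total > 0) tiles$count * 1e6 / hpRNA_total
                       else NA_real_
  attr(tiles, "masked_out") <- masked_out
  attr(tiles, "total_weight") <- sum(a$weight)
  tiles
}

#' Aggregate tile values to piRNA-cluster abundances
#'
#' Sums normalized tile values over the tiles whose midpoint lies inside
#' each annotated piRNA cluster.  A cluster covering no tile midpoint gets
#' abundance 0 with a warning.
#'
#' @param tile_table from [tile_counts()].
#' @param annotation feature annotation (uses `piRNA_cluster` records).
#' @param value column of `tile_table` to aggregate (default
#'   `"per_million"`).
#' @return data.frame: cluster, contig, abundance.
#' @export
cluster_abundance <- function(tile_table, annotation,
                              value = "per_million") {
  cl <- annotation[annotation$class == "piRNA_cluster", , drop = FALSE]
  mid <- (tile_table$start + tile_table$end) / 2
  out <- do.call(rbind, lapply(seq_len(nrow(cl)), function(i) {
    sel <- tile_table$contig == cl$contig[i] &
      mid >= cl$start[i] & mid < cl$end[i]
    if (!any(sel))
      warning("cluster ", cl$name[i], " covers no tile midpoint")
    data.frame(cluster = cl$name[i], contig = cl$contig[i],
               abundance = sum(tile_table[[value]][sel]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(cluster = character(),
                                      contig = character(),
                                      abundance = numeric())
  out
}

#' Cluster abundance relative to a reference library
#'
#' Per-cluster ratio of sample abundance to reference abundance (e.g.
#' progenitor-cell libraries relative to a control ovary library).  A zero
#' or missing reference abundance flags the ratio as `NA`.
#'
#' @param sample_abundance,reference_abundance data.frames from
#'   [cluster_abundance()] over the same cluster set.
#' @return data.frame: cluster, sample, reference, ratio.
#' @export
relative_to_reference <- function(sample_abundance, reference_abundance) {
  if (!setequal(sample_abundance$cluster, reference_abundance$cluster))
    stop("sample and reference must cover the same cluster set")
  m <- match(sample_abundance$cluster, reference_abundance$cluster)
  ref <- reference_abundance$abundance[m]
  data.frame(cluster = sample_abundance$cluster,
             sample = sample_abundance$abundance,
             reference = ref,
             ratio = ifelse(is.na(ref) | ref <= 0, NA_real_,
                            sample_abundance$abundance / ref),
             stringsAsFactors = FALSE)
}
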