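# piRNA signature statistics: size distributions, positional nucleotide
# frequency matrices around the ping-pong anchor positions, 1U/10A
# z-scores, phased-biogenesis downstream-U frequency and the TE-mapping
# fraction, all normalized per million hpRNA reads where applicable.
#
# "piRNA-sized" means longer than 22 nt (length >= 23); the upper bound is
# the global 18-40 nt size selection.

#' Size distribution of TE-mapping reads
#'
#' Weighted read counts per insert length (18-40 nt) and orientation
#' (sense/antisense relative to the TE consensus), with values normalized
#' per million hpRNA reads.  A read placed in both orientations contributes
#' its split alignment weight to each.
#'
#' @param te_alignments TE alignment data.frame (from [map_reads()]); an
#'   `orientation` column is added via [classify_te_orientation()] if
#'   absent.
#' @param hpRNA_total hpRNA-mapping read count used as the normalization
#'   denominator; when 0 the `per_million` column is `NA` and raw counts
#'   are still returned.
#' @param min_len,max_len length window of the table.
#' @return data.frame: length, orientation, count, per_million.
#' @export
size_distribution <- function(te_alignments, hpRNA_total,
                              min_len = 18L, max_len = 40L) {
  if (is.null(te_alignments$orientation))
    te_alignments <- classify_te_orientation(te_alignments)
  grid <- expand.grid(length = min_len:max_len,
                      orientation = c("sense", "antisense"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$length, grid$orientation)
  cnt <- setNames(numeric(length(key)), key)
  if (nrow(te_alignments) > 0L) {
    a <- te_alignments[te_alignments$length >= min_len &
                         te_alignments$length <= max_len, , drop = FALSE]
    if (nrow(a) > 0L) {
      tt <- tapply(a$weight, paste(a$length, a$orientation), sum)
      cnt[names(tt)] <- tt
    }
  }
  grid$count <- unname(cnt)
  grid$per_million <- if (hpRNA_total > 0) grid$count * 1e6 / hpRNA_total
                      else NA_real_
  grid
}

#' Positional nucleotide frequencies around a ping-pong anchor
#'
#' Builds the 11-position frequency matrix around the first nucleotide of
#' antisense reads (`anchor = "antisense_pos1"`) or the tenth nucleotide of
#' sense reads (`anchor = "sense_pos10"`), for alignments of reads longer
#' than 22 nt.  The anchor sits at the centre (position index 5, 0-based);
#' window positions inside the read are taken from the read sequence and
#' positions upstream of the read's 5' end from the alignment target on the
#' read strand.  Alignments whose window exceeds the target bounds are
#' dropped and counted.  Columns are weighted by alignment weight and each
#' position normalizes to 1.
#'
#' @param alignments alignment data.frame (TE alignments with `seq`,
#'   `target`, `start`, `strand`, `length`, `weight`).
#' @param targets named character vector of target sequences (e.g. the TE
#'   consensus library).
#' @param anchor `"antisense_pos1"` or `"sense_pos10"`.
#' @param min_len minimum read length (default 23, i.e. "> 22 nt").
#' @return object of class `freq_matrix`: list with `freq` (11 x 4 matrix,
#'   columns A/C/G/U), `anchor`, `n_alignments`, `n_weight`, `dropped`,
#'   `empty`.
#' @export
positional_frequencies <- function(alignments, targets,
                                   anchor = c("antisense_pos1", "sense_pos10"),
                                   min_len = 23L) {
  anchor <- match.arg(anchor)
  want_strand <- if (anchor == "antisense_pos1") "-" else "+"
  a <- alignments[alignments$length >= min_len &
                    alignments$strand == want_strand, , drop = FALSE]
  dropped <- 0L
  windows <- character(0)
  weights <- numeric(0)
  if (nrow(a) > 0L) {
    if (anchor == "sense_pos10") {
      # window = read positions 5..15 (1-based), all inside the read
      windows <- substring(a$seq, 5L, 15L)
      weights <- a$weight
    } else {
      # anchor at read position 1; upstream context (window indices 0..4)
      # comes from the target, 3' of the placement on the minus strand
      tlen <- nchar(targets)[a$target]
      e <- a$start + a$length
      ok <- e + 5L <= tlen
      dropped <- sum(!ok)
      a <- a[ok, , drop = FALSE]
      e <- e[ok]
      ctx <- revcomp(substring(unname(targets[a$target]), e + 1L, e + 5L))
      windows <- paste0(ctx, substring(a$seq, 1L, 6L))
      weights <- a$weight
    }
  }
  bases <- c("A", "C", "G", "U")
  freq <- matrix(NA_real_, nrow = 11L, ncol = 4L,
                 dimnames = list(position = as.character(-5:5), base = bases))
  empty <- length(windows) == 0L
  if (!empty) {
    mat <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  ncol = 11L, byrow = TRUE)
    mat <- chartr("T", "U", mat)
    tot <- sum(weights)
    for (b in bases)
      freq[, b] <- colSums((mat == b) * weights) / tot
  }
  structure(list(freq = freq, anchor = anchor,
                 n_alignments = length(windows), n_weight = sum(weights),
                 dropped = dropped, empty = empty),
            class = "freq_matrix")
}

#' @export
print.freq_matrix <- function(x, ...) {
  cat(sprintf("Positional frequency matrix (%s), %d alignments%s\n",
              x$anchor, x$n_alignments,
              if (x$dropped > 0L) sprintf(", %d dropped at target edge",
                                          x$dropped) else ""))
  if (!x$empty) print(round(x$freq, 3)) else cat("  <empty>\n")
  invisible(x)
}

#' Ping-pong z-score of an anchor-position base frequency
#'
#' The z-score is the deviation of the frequency at the anchor position
#' from the mean frequency over the 11 window positions, divided by the
#' population standard deviation (divisor n) of those 11 values.  A window
#' with a single outlying value therefore yields |z| = sqrt(10), and
#' sqrt(10) is the attainable maximum.  A zero-SD (degenerate) window
#' returns z = 0 with `degenerate = TRUE`.
#'
#' @param matrix `freq_matrix` from [positional_frequencies()].
#' @param base one of "A", "C", "G", "U".
#' @param anchor_index 0-based window index of the anchor (default 5, the
#'   centre).
#' @return list with `z` and `degenerate`.
#' @export
pingpong_zscore <- function(matrix, base = c("U", "A", "C", "G"),
                            anchor_index = 5L) {
  base <- match.arg(base)
  if (isTRUE(matrix$empty))
    return(list(z = NA_real_, degenerate = TRUE))
  f <- matrix$freq[, base]
  stopifnot(length(f) == 11L)
  sdev <- sqrt(mean((f - mean(f))^2))
  if (sdev == 0)
    return(list(z = 0, degenerate = TRUE))
  list(z = (f[[anchor_index + 1L]] - mean(f)) / sdev, degenerate = FALSE)
}

#' Downstream-uridine (phasing) frequency
#'
#' For each genome alignment of a read longer than 22 nt, inspects the
#' genomic base immediately 3' of the read on the read strand: for a plus
#' strand placement `[start, end)` that is the base at `end`; for a minus
#' strand placement the complement of the base at `start - 1`.  Alignments
#' at target edges are dropped and counted.  Returns the weighted U
#' frequency per category: TE-mapping reads, non-TE genome-mapping reads
#' and all reads.
#'
#' @param alignments genome alignment data.frame.
#' @param bundle `ref_bundle` supplying genomic context.
#' @param te_read_ids read ids that also map to TE consensus sequences
#'   (defines the TE-mapping category); `NULL` leaves the TE categories
#'   empty.
#' @param min_len minimum read length (default 23).
#' @return data.frame: category, frequency (NA when no alignments), n
#'   (total weight); attribute `dropped` counts edge drops.
#' @export
downstream_u_frequency <- function(alignments, bundle, te_read_ids = NULL,
                                   min_len = 23L) {
  a <- alignments[alignments$length >= min_len, , drop = FALSE]
  clen <- nchar(bundle$genome)
  pos <- ifelse(a$strand == "+", a$start + a$length, a$start - 1L)
  ok <- pos >= 0L & pos < clen[a$target]
  dropped <- sum(!ok)
  a <- a[ok, , drop = FALSE]; pos <- pos[ok]
  if (nrow(a) > 0L) {
    b <- base_at(bundle$genome, a$target, pos)
    downU <- ifelse(a$strand == "+", b == "T", b == "A")
  } else downU <- logical(0)
  cats <- list(
    `TE-mapping` = if (is.null(te_read_ids)) rep(FALSE, nrow(a))
                   else a$read_id %in% te_read_ids,
    `non-TE genome-mapping` = if (is.null(te_read_ids)) rep(TRUE, nrow(a))
                              else !a$read_id %in% te_read_ids,
    all = rep(TRUE, nrow(a)))
  out <- do.call(rbind, lapply(names(cats), function(nm) {
    sel <- cats[[nm]]
    n <- sum(a$weight[sel])
    data.frame(category = nm,
               frequency = if (n > 0) sum(a$weight[sel & downU]) / n
                           else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  attr(out, "dropped") <- dropped
  out
}

#' Fraction of piRNA-sized reads mapping to TE sequences
#'
#' The fraction of clean reads longer than 22 nt that have at least one TE
#' consensus alignment.
#'
#' @param clean_reads clean-read data.frame (`read_id`, `seq`).
#' @param te_alignments TE alignment data.frame.
#' @param min_len minimum read length (default 23).
#' @return list with `fraction` (NA when no piRNA-sized reads), `n_reads`,
#'   `n_te_mapped`.
#' @export
te_mapping_fraction <- function(clean_reads, te_alignments, min_len = 23L) {
  big <- clean_reads[nchar(clean_reads$seq) >= min_len, , drop = FALSE]
  n <- nrow(big)
  if (n == 0L)
    return(list(fraction = NA_real_, n_reads = 0L, n_te_mapped = 0L))
  mapped <- sum(big$read_id %in% te_alignments$read_id)
  list(fraction = mapped / n, n_reads = n, n_te_mapped = mapped)
}
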