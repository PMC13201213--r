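# Raw FASTQ -> clean, size-selected inserts: exact 3' adapter trimming,
# removal of the 4 randomized nucleotides at either end, and 18-40 nt size
# selection.  No quality filtering is applied to small-RNA reads.

#' Trim the 3' adapter from read sequences
#'
#' A read is truncated at the leftmost exact occurrence of either the full
#' adapter anywhere in the read or an adapter prefix of length at least
#' `min_overlap` anchored at the read's 3' end.  Matching is exact (zero
#' mismatches).  Reads with no match are returned as `NA` (untrimmed) and
#' are excluded downstream.
#'
#' @param seqs character vector of raw read sequences.
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum anchored prefix length (default 6).
#' @return character vector: trimmed sequences, `NA` where untrimmed.
#' @examples
#' trim_adapter(paste0("ACGT", "AGATCGGAAGAGCACACGTCT"))
#' @export
trim_adapter <- function(seqs, adapter = "AGATCGGAAGAGCACACGTCT",
                         min_overlap = 6L) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  n <- nchar(seqs)
  alen <- nchar(adapter)
  # leftmost internal occurrence of the full adapter (1-based; -1 if none)
  pos_full <- regexpr(adapter, seqs, fixed = TRUE)
  cut <- ifelse(pos_full > 0L, as.integer(pos_full), NA_integer_)
  # adapter prefixes (>= min_overlap, < full length) anchored at the 3' end;
  # the full adapter anchored at the end is already an internal occurrence
  ks <- if (alen - 1L >= min_overlap) seq(min_overlap, alen - 1L) else integer(0)
  for (k in ks) {
    hit <- !is.na(seqs) & n >= k &
      substring(seqs, n - k + 1L, n) == substring(adapter, 1L, k)
    anchored <- ifelse(hit, n - k + 1L, NA_integer_)
    cut <- pmin(cut, anchored, na.rm = TRUE)
  }
  out <- substring(seqs, 1L, ifelse(is.na(cut), 0L, cut - 1L))
  out[is.na(cut)] <- NA_character_
  out
}

#' Strip the randomized UMI nucleotides from trimmed inserts
#'
#' Removes the first and last `umi_len` nucleotides.  Inserts shorter than
#' `2 * umi_len + 1` cannot contain an insert base and are discarded
#' (returned as `NA`).
#'
#' @param seqs trimmed sequences (NA entries pass through as NA).
#' @param umi_len randomized-nucleotide length at each end (default 4).
#' @return character vector of inserts, `NA` where discarded.
#' @export
strip_umis <- function(seqs, umi_len = 4L) {
  n <- nchar(seqs)
  ok <- !is.na(seqs) & n >= 2L * umi_len + 1L
  out <- rep(NA_character_, length(seqs))
  out[ok] <- substring(seqs[ok], umi_len + 1L, n[ok] - umi_len)
  out
}

#' Size-select inserts to the analysis window
#'
#' Keeps reads with `min_len <= length <= max_len` (inclusive) and reports
#' per-boundary discard counts.
#'
#' @param reads data.frame with columns `read_id`, `seq`.
#' @param min_len,max_len inclusive bounds (default 18 and 40).
#' @return list with `kept` (data.frame) and `discarded`
#'   (c(below, above)).
#' @export
size_select <- function(reads, min_len = 18L, max_len = 40L) {
  len <- nchar(reads$seq)
  below <- len < min_len
  above <- len > max_len
  kept <- reads[!below & !above, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, discarded = c(below = sum(below), above = sum(above)))
}

#' Preprocess a raw small-RNA FASTQ into clean inserts
#'
#' Runs adapter trimming, UMI stripping and size selection in order, and
#' returns the clean reads together with a discard report whose categories
#' partition the input (`input = kept + untrimmed + short_after_umi +
#' size_below + size_above`).
#'
#' @param fastq path to a FASTQ file, or a data.frame with `read_id`,
#'   `seq` columns (raw sequences).
#' @param adapter,min_overlap see [trim_adapter()].
#' @param umi_len see [strip_umis()].
#' @param min_len,max_len see [size_select()].
#' @return list with `clean` (data.frame read_id, seq, length) and
#'   `report` (named integer vector).
#' @export
preprocess_reads <- function(fastq, adapter = "AGATCGGAAGAGCACACGTCT",
                             min_overlap = 6L, umi_len = 4L,
                             min_len = 18L, max_len = 40L) {
  if (is.character(fastq) && length(fastq) == 1L) {
    if (!file.exists(fastq)) stop("FASTQ not found: ", fastq)
    ss <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    raw <- data.frame(read_id = sub("\\s.*$", "", names(ss)),
                      seq = as.character(ss), stringsAsFactors = FALSE)
  } else {
    raw <- as.data.frame(fastq, stringsAsFactors = FALSE)
    stopifnot(all(c("read_id", "seq") %in% names(raw)))
  }
  n_input <- nrow(raw)
  trimmed <- trim_adapter(raw$seq, adapter, min_overlap)
  n_untrimmed <- sum(is.na(trimmed))
  insert <- strip_umis(trimmed, umi_len)
  n_short <- sum(is.na(insert)) - n_untrimmed
  ok <- !is.na(insert)
  kept_df <- data.frame(read_id = raw$read_id[ok], seq = insert[ok],
                        stringsAsFactors = FALSE)
  sel <- size_select(kept_df, min_len, max_len)
  clean <- sel$kept
  clean$length <- nchar(clean$seq)
  report <- c(input = n_input, untrimmed = n_untrimmed,
              short_after_umi = n_short,
              size_below = unname(sel$discarded["below"]),
              size_above = unname(sel$discarded["above"]),
              kept = nrow(clean))
  list(clean = clean, report = report)
}
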