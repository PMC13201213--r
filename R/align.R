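# Read placement: exhaustive k-mismatch mapping with all-best-strata
# reporting (the behavioural contract of Bowtie-1 style --all --best
# --strata mapping, re-specified as an internal operation at toy scale),
# infrastructural-RNA annotation, unique-mapper selection and TE sense /
# antisense classification.

#' Map reads against a set of targets
#'
#' Exhaustive placement of each read on every target, both strands, keeping
#' placements with at most `max_mismatches` mismatches.  Under
#' `report = "all_best_strata"` only the placements tied at the per-read
#' minimal mismatch count are returned (a read with no placement at or under
#' the maximum is simply absent).  `N` never matches any base, including
#' `N`.  Each read carries total weight 1, split evenly over its reported
#' placements, so downstream weighted counts conserve read totals.
#'
#' Identical read sequences are mapped once and the placements replicated,
#' so heavily duplicated small-RNA libraries map quickly.
#'
#' @param reads data.frame with columns `read_id`, `seq` (clean inserts), or
#'   a named character vector of sequences.
#' @param targets named character vector of target sequences.
#' @param max_mismatches integer in 0..3.
#' @param report `"all_best_strata"` (default) or `"all"`.
#' @param target_class label stored in the `class` column (e.g. "genome",
#'   "TE", "infrastructural").
#' @return data.frame with columns read_id, seq, length, target, class,
#'   start (0-based), strand, mismatches, weight.
#' @examples
#' map_reads(c(r1 = "ACGT"), c(t1 = "TTACGTTT"), max_mismatches = 1)
#' @export
map_reads <- function(reads, targets, max_mismatches = 1L,
                      report = c("all_best_strata", "all"),
                      target_class = "genome") {
  report <- match.arg(report)
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    reads <- data.frame(read_id = ids, seq = unname(reads),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if (length(targets) == 0L) stop("targets must be nonempty")
  if (is.null(names(targets))) stop("targets must be named")
  if (!max_mismatches %in% 0:3) stop("max_mismatches must be in 0..3")

  empty <- data.frame(read_id = character(), seq = character(),
                      length = integer(), target = character(),
                      class = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)

  useq <- unique(reads$seq)
  hits <- cpp_map_reads(useq, revcomp(useq), unname(targets),
                        as.integer(max_mismatches),
                        report == "all_best_strata")
  if (nrow(hits) == 0L) return(empty)

  # expand unique-sequence hits back to reads
  idx <- match(reads$seq, useq)
  per_seq <- split(seq_len(nrow(hits)), hits$read)
  hit_rows <- per_seq[as.character(idx)]
  n_hits <- lengths(hit_rows)
  keep <- n_hits > 0L
  if (!any(keep)) return(empty)
  read_rep <- rep(which(keep), n_hits[keep])
  hrow <- unlist(hit_rows[keep], use.names = FALSE)

  out <- data.frame(
    read_id = reads$read_id[read_rep],
    seq = reads$seq[read_rep],
    length = nchar(reads$seq[read_rep]),
    target = names(targets)[hits$target[hrow]],
    class = target_class,
    start = hits$start[hrow],
    strand = ifelse(hits$strand[hrow] == 1L, "+", "-"),
    mismatches = hits$mismatches[hrow],
    weight = rep(1 / n_hits[keep], n_hits[keep]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

INFRA_CLASSES <- c("rRNA", "snRNA", "snoRNA", "miRNA", "tRNA", "hpRNA")

#' Annotate reads against infrastructural RNAs
#'
#' Maps reads with at most one mismatch to the sense-strand sequences of the
#' annotated infrastructural features (rRNA, snRNA, snoRNA, miRNA, tRNA and
#' the hairpin-RNA locus) and flags each read by the classes it hits.  The
#' hpRNA-flagged read total is the normalisation denominator used by the
#' signature and tile stages.  Annotation does not remove reads from
#' genome/TE mapping; exclusion happens only in tile masking.
#'
#' @param reads clean-read data.frame (`read_id`, `seq`).
#' @param bundle `ref_bundle`.
#' @param max_mismatches default 1.
#' @return list with `flags` (data.frame read_id, class — one row per read
#'   x class hit), `class_counts` (named read counts per class) and
#'   `hpRNA_total` (count of hpRNA-flagged reads).
#' @export
annotate_infrastructural <- function(reads, bundle, max_mismatches = 1L) {
  stopifnot(inherits(bundle, "ref_bundle"))
  ann <- bundle$annotation
  infra <- ann[ann$class %in% INFRA_CLASSES, , drop = FALSE]
  if (nrow(infra) == 0L || nrow(reads) == 0L) {
    return(list(flags = data.frame(read_id = character(), class = character(),
                                   stringsAsFactors = FALSE),
                class_counts = setNames(integer(length(INFRA_CLASSES)),
                                        INFRA_CLASSES),
                hpRNA_total = 0L))
  }
  seqs <- vapply(seq_len(nrow(infra)), function(i)
    fetch_sequence(bundle, infra$contig[i], infra$start[i], infra$end[i],
                   infra$strand[i]), "")
  names(seqs) <- paste0(infra$class, ":", infra$name)
  aln <- map_reads(reads, seqs, max_mismatches = max_mismatches,
                   report = "all", target_class = "infrastructural")
  aln$feature_class <- sub(":.*$", "", aln$target)
  flags <- unique(aln[, c("read_id", "feature_class")])
  names(flags)[2L] <- "class"
  counts <- vapply(INFRA_CLASSES, function(cl)
    length(unique(flags$read_id[flags$class == cl])), 0L)
  list(flags = flags, class_counts = counts,
       hpRNA_total = counts[["hpRNA"]])
}

#' Select reads mapping uniquely to the genome
#'
#' Keeps reads whose best-stratum genome alignment set has size exactly one;
#' multi-mappers and unaligned reads are dropped.  Input must come from
#' [map_reads()] with `report = "all_best_strata"`.
#'
#' @param alignments genome alignment data.frame.
#' @return subset of `alignments` (one row per retained read).
#' @export
unique_genome_mappers <- function(alignments) {
  if (nrow(alignments) == 0L) return(alignments)
  n <- table(alignments$read_id)
  keep <- alignments$read_id %in% names(n)[n == 1L]
  out <- alignments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify TE alignments as sense or antisense
#'
#' The stored TE consensus is the element's sense (mRNA-like) strand, so a
#' plus-strand alignment is sense and a minus-strand alignment antisense.
#' A read placed in both orientations under all-best-strata reporting
#' contributes its split weight to each orientation.
#'
#' @param alignments TE alignment data.frame.
#' @return `alignments` with an added `orientation` column.
#' @export
classify_te_orientation <- function(alignments) {
  alignments$orientation <- ifelse(alignments$strand == "+",
                                   "sense", "antisense")
  alignments
}
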