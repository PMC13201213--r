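# Length-normalized TE mRNA abundance per million transcripts (host and TE
# transcripts share the denominator).  Counts are taken as given; the
# upstream read-level quantifier is out of scope.

#' Length-normalized abundance per million transcripts
#'
#' For each transcript, `rate = count / length`; abundances are
#' `rate * 1e6 / sum(rate)` over host and TE transcripts together, so the
#' table sums to one million and is invariant to rescaling all counts.
#'
#' @param table data.frame with columns `transcript_id`, `class`
#'   ("host"/"TE"), `length` (> 0), `count` (>= 0).
#' @return `table` with an added `abundance` column.
#' @export
tpm <- function(table) {
  stopifnot(all(c("transcript_id", "class", "length", "count") %in%
                  names(table)))
  if (anyDuplicated(table$transcript_id))
    stop("transcript ids must be unique")
  if (any(table$length <= 0)) stop("transcript lengths must be positive")
  if (any(table$count < 0)) stop("counts must be nonnegative")
  rate <- table$count / table$length
  tot <- sum(rate)
  if (tot == 0) stop("all counts are zero; abundance undefined")
  table$abundance <- rate * 1e6 / tot
  table
}

#' Per-TE abundance summary and between-library log-ratios
#'
#' Sums TE-class abundances per element and computes log2 ratios between
#' two libraries, guarding zeros with a pseudo-abundance (default 1
#' per-million unit, recorded in the output).
#'
#' @param tpm_a,tpm_b abundance tables from [tpm()] for the two libraries.
#' @param pseudo pseudo-abundance added to both sides of each ratio.
#' @return list with `per_te` (data.frame: transcript_id, abundance_a,
#'   abundance_b, log2_ratio), `total_te` (named numeric: total TE
#'   abundance per library) and `pseudo`.
#' @export
te_summary <- function(tpm_a, tpm_b, pseudo = 1) {
  ta <- tpm_a[tpm_a$class == "TE", , drop = FALSE]
  tb <- tpm_b[tpm_b$class == "TE", , drop = FALSE]
  ids <- union(ta$transcript_id, tb$transcript_id)
  a <- setNames(numeric(length(ids)), ids)
  b <- a
  a[ta$transcript_id] <- ta$abundance
  b[tb$transcript_id] <- tb$abundance
  per_te <- data.frame(transcript_id = ids,
                       abundance_a = unname(a), abundance_b = unname(b),
                       log2_ratio = log2((a + pseudo) / (b + pseudo)),
                       stringsAsFactors = FALSE)
  rownames(per_te) <- NULL
  list(per_te = per_te,
       total_te = c(a = sum(a), b = sum(b)),
       pseudo = pseudo)
}
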