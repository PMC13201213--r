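# Independent brute-force k-mismatch scanner used as the mapping oracle.
# Enumerates every (target, offset, strand) by raw byte comparison, with N
# forced to mismatch on either side (distinct sentinel bytes).  Kept
# deliberately separate from the package's mapper implementation.

oracle_scan <- function(read, targets, max_mm) {
  out <- list()
  rc <- pirnasig::revcomp(read)
  for (t in seq_along(targets)) {
    tseq <- targets[[t]]
    tl <- nchar(tseq)
    ql <- nchar(read)
    if (ql > tl) next
    tr <- charToRaw(tseq)
    tr[tr == charToRaw("N")] <- as.raw(255L)
    for (strand in c("+", "-")) {
      q <- charToRaw(if (strand == "+") read else rc)
      q[q == charToRaw("N")] <- as.raw(254L)
      for (s in 0:(tl - ql)) {
        mm <- sum(tr[(s + 1):(s + ql)] != q)
        if (mm <= max_mm)
          out[[length(out) + 1L]] <- data.frame(
            target = names(targets)[t], start = s, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target = character(), start = integer(),
                      strand = character(), mismatches = integer()))
  do.call(rbind, out)
}

oracle_best_strata <- function(read, targets, max_mm) {
  all <- oracle_scan(read, targets, max_mm)
  if (nrow(all) == 0L) return(all)
  all[all$mismatches == min(all$mismatches), , drop = FALSE]
}

# canonical key of an alignment set for equality checks
align_key <- function(d) {
  if (is.null(d) || nrow(d) == 0L) return("<empty>")
  paste(sort(paste(d$target, d$start, d$strand, d$mismatches)),
        collapse = ";")
}

random_read <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}
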