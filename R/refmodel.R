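# Reference model: genome contigs, BED6 feature annotation, TE consensus
# library.  Coordinates are 0-based half-open (BED-native) everywhere in the
# package; strand is "+" or "-"; sequences use the DNA alphabet {A,C,G,T,N}.

FEATURE_CLASSES <- c("rRNA", "snRNA", "snoRNA", "miRNA", "tRNA", "hpRNA",
                     "piRNA_cluster", "TE_insertion", "aub_locus")

#' Feature classes understood by the annotation model
#'
#' The nine feature classes used in the filtering, masking and tiling rules:
#' infrastructural RNAs (rRNA, snRNA, snoRNA, miRNA, tRNA), the hairpin-RNA
#' (hpRNA) siRNA locus used for normalisation, piRNA clusters, transposon
#' insertions and the aubergine-like locus excluded from tile analysis.
#'
#' @return character vector of class names.
#' @export
feature_classes <- function() FEATURE_CLASSES

validate_seqs <- function(seqs, what) {
  if (length(seqs) == 0L) stop(what, ": no sequences found")
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop(what, ": every sequence needs a name")
  if (anyDuplicated(nm)) stop(what, ": duplicate sequence ids: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(nchar(seqs) == 0L)) stop(what, ": empty sequence present")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop(what, ": sequence characters outside {A,C,G,T,N} in: ",
         paste(nm[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  seqs
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and validated against the {A,C,G,T,N} alphabet.
#'
#' @param path FASTA file.
#' @param what label used in error messages.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, what = path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e) stop("malformed FASTA '", path, "': ",
                                      conditionMessage(e))),
    warning = function(w) stop("malformed FASTA '", path, "': ",
                               conditionMessage(w)))
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_seqs(seqs, what)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file; lines wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Read a BED6 feature annotation
#'
#' The name column carries `feature-class:name`; start/end are 0-based
#' half-open as in BED.  Records are validated against the known feature
#' classes (and, when `contig_lengths` is given, against contig bounds).
#'
#' @param path BED6 file (may be empty or absent header-less TSV).
#' @param contig_lengths optional named integer vector for bounds checking.
#' @return data.frame with columns contig, start, end, strand, class, name.
#' @export
read_bed <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    ann <- data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), class = character(),
                      name = character(), stringsAsFactors = FALSE)
    return(ann)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop("malformed BED at line ", which(nf < 6L)[1L], ": expected 6 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  cls_name <- strsplit(m[, 4L], ":", fixed = TRUE)
  bad <- lengths(cls_name) < 2L
  if (any(bad))
    stop("malformed BED name column at line ", which(bad)[1L],
         ": expected feature-class:name")
  ann <- data.frame(
    contig = m[, 1L],
    start  = suppressWarnings(as.integer(m[, 2L])),
    end    = suppressWarnings(as.integer(m[, 3L])),
    strand = m[, 6L],
    class  = vapply(cls_name, `[`, "", 1L),
    name   = vapply(cls_name, function(x) paste(x[-1L], collapse = ":"), ""),
    stringsAsFactors = FALSE)
  validate_annotation(ann, contig_lengths)
}

validate_annotation <- function(ann, contig_lengths = NULL) {
  if (nrow(ann) == 0L) return(ann)
  if (anyNA(ann$start) || anyNA(ann$end)) stop("non-integer BED coordinates")
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'")
  if (!all(ann$class %in% FEATURE_CLASSES))
    stop("unknown feature class: ",
         paste(setdiff(unique(ann$class), FEATURE_CLASSES), collapse = ", "))
  if (any(ann$start < 0L) || any(ann$start >= ann$end))
    stop("annotation requires 0 <= start < end")
  if (!is.null(contig_lengths)) {
    if (!all(ann$contig %in% names(contig_lengths)))
      stop("annotation contig absent from genome: ",
           paste(setdiff(unique(ann$contig), names(contig_lengths)),
                 collapse = ", "))
    if (any(ann$end > contig_lengths[ann$contig]))
      stop("annotation record extends past contig end: ",
           ann$name[which(ann$end > contig_lengths[ann$contig])[1L]])
  }
  ann
}

#' Write a feature annotation as BED6
#'
#' Inverse of [read_bed()]: the name column is written as
#' `feature-class:name`, score 0.  Round-trips coordinates bit-exactly.
#'
#' @param ann annotation data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ann, path) {
  lines <- if (nrow(ann) == 0L) character(0) else
    paste(ann$contig, ann$start, ann$end,
          paste0(ann$class, ":", ann$name), 0L, ann$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Load and validate a reference bundle
#'
#' Reads the genome FASTA, BED6 annotation and TE consensus FASTA and
#' returns the validated bundle used by all downstream stages.  The stored
#' strand of each TE consensus is its sense (mRNA-like) strand.
#'
#' @param genome_path genome FASTA.
#' @param annotation_path BED6 annotation (`feature-class:name` names).
#' @param te_path TE consensus FASTA.
#' @return an object of class `ref_bundle`: list with `genome` (named
#'   character), `annotation` (data.frame), `te` (named character).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_fasta(c(chr1 = "ACGTACGTACGT"), file.path(dir, "genome.fa"))
#' writeLines(character(0), file.path(dir, "ann.bed"))
#' write_fasta(c(gypsy = "ACGT"), file.path(dir, "te.fa"))
#' b <- load_reference(file.path(dir, "genome.fa"),
#'                     file.path(dir, "ann.bed"), file.path(dir, "te.fa"))
#' @export
load_reference <- function(genome_path, annotation_path, te_path) {
  genome <- read_fasta(genome_path, "genome")
  te <- read_fasta(te_path, "TE library")
  ann <- read_bed(annotation_path, contig_lengths = nchar(genome))
  structure(list(genome = genome, annotation = ann, te = te),
            class = "ref_bundle")
}

#' Write a reference bundle to disk
#'
#' @param bundle `ref_bundle`.
#' @param dir output directory (created if needed); writes `genome.fa`,
#'   `annotation.bed`, `te.fa`.
#' @return named character vector of paths, invisibly.
#' @export
write_reference <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ref_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             annotation = file.path(dir, "annotation.bed"),
             te = file.path(dir, "te.fa"))
  write_fasta(bundle$genome, paths["genome"])
  write_bed(bundle$annotation, paths["annotation"])
  write_fasta(bundle$te, paths["te"])
  invisible(paths)
}

#' @export
print.ref_bundle <- function(x, ...) {
  cat("Reference bundle\n")
  cat(sprintf("  genome:     %d contig(s), %s nt total\n",
              length(x$genome), format(sum(nchar(x$genome)), big.mark = ",")))
  cat(sprintf("  annotation: %d feature(s) in %d class(es)\n",
              nrow(x$annotation), length(unique(x$annotation$class))))
  cat(sprintf("  TE library: %d consensus element(s)\n", length(x$te)))
  invisible(x)
}

#' Fetch a reference subsequence
#'
#' Plus strand returns the genome substring over the 0-based half-open
#' interval; minus strand returns its reverse complement; an empty interval
#' returns the empty string.
#'
#' @param bundle `ref_bundle` (or any list with a `genome` element).
#' @param contig contig id.
#' @param start,end 0-based half-open interval, `0 <= start <= end <= length`.
#' @param strand "+" or "-".
#' @return character scalar.
#' @export
fetch_sequence <- function(bundle, contig, start, end, strand = "+") {
  genome <- if (is.list(bundle)) bundle$genome else bundle
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end < start || end > len)
    stop("interval [", start, ",", end, ") out of bounds for ", contig,
         " (length ", len, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (start == end) return("")
  s <- substring(genome[[contig]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}
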