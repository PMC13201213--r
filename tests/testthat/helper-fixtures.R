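# Shared fixtures, built once per test run.  The default toy reference and
# a mid-sized oxidized library are reused by several test files.

.fixtures <- new.env(parent = emptyenv())

fixture_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- build_toy_reference(seed = 42)
  .fixtures$bundle
}

# simulated library of 8000 primary reads under default (piRNA-rich,
# oxidized) conditions, with rendered FASTQ and truth table
fixture_library <- function() {
  if (is.null(.fixtures$lib)) {
    bundle <- fixture_bundle()
    cfg <- sim_config(seed = 42, n_reads = 8000)
    reads <- simulate_small_rna(bundle, cfg)
    ox <- apply_oxidation(reads, cfg)
    fq <- tempfile(fileext = ".fastq")
    truth <- tempfile(fileext = ".tsv")
    render_fastq(ox, cfg, fq, truth)
    .fixtures$lib <- list(bundle = bundle, config = cfg, reads = reads,
                          oxidized = ox, fastq = fq, truth = truth)
  }
  .fixtures$lib
}

# assemble a freq_matrix object from a bare 11 x 4 frequency matrix
manual_freq_matrix <- function(freq, anchor = "antisense_pos1") {
  dimnames(freq) <- list(position = as.character(-5:5),
                         base = c("A", "C", "G", "U"))
  structure(list(freq = freq, anchor = anchor, n_alignments = 1L,
                 n_weight = 1, dropped = 0L, empty = FALSE),
            class = "freq_matrix")
}
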