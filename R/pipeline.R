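# Pipeline driver: configuration, stage sequencing, TSV report assembly.
# Stage order mirrors the read-processing protocol: preprocess ->
# infrastructural annotation -> genome mapping (unique mappers) -> TE
# mapping -> signatures -> tiles -> (optional) TE mRNA abundance.

#' Pipeline configuration
#'
#' Every tunable of the analysis stages, with its default.  Unknown keys
#' are rejected.  The configuration (plus a hash of it) is written into
#' every output file header so re-running with the same configuration
#' byte-reproduces all outputs.
#'
#' @param adapter 3' adapter sequence.
#' @param min_overlap minimum anchored adapter overlap (nt).
#' @param umi_len randomized nucleotides stripped from each end.
#' @param min_len,max_len size-selection window (nt, inclusive).
#' @param infra_max_mm,genome_max_mm,te_max_mm per-stage mismatch maxima.
#' @param report alignment reporting mode.
#' @param min_pirna_len "piRNA-sized" threshold (length >= this; default
#'   23, i.e. longer than 22 nt).
#' @param window_len,anchor_offset signature window geometry (11 positions,
#'   anchor at 0-based index 5).
#' @param tile_width tile width (nt).
#' @param mask_pad exclusion-mask padding around tRNA/snRNA/snoRNA (nt).
#' @param tpm_pseudo pseudo-abundance for TE expression log-ratios.
#' @param seed seed recorded in output headers.
#' @return classed list `pipeline_config`.
#' @export
pipeline_config <- function(adapter = "AGATCGGAAGAGCACACGTCT",
                            min_overlap = 6L, umi_len = 4L,
                            min_len = 18L, max_len = 40L,
                            infra_max_mm = 1L, genome_max_mm = 1L,
                            te_max_mm = 3L,
                            report = "all_best_strata",
                            min_pirna_len = 23L,
                            window_len = 11L, anchor_offset = 5L,
                            tile_width = 1000L, mask_pad = 100L,
                            tpm_pseudo = 1, seed = 1L) {
  cfg <- list(adapter = adapter, min_overlap = as.integer(min_overlap),
              umi_len = as.integer(umi_len), min_len = as.integer(min_len),
              max_len = as.integer(max_len),
              infra_max_mm = as.integer(infra_max_mm),
              genome_max_mm = as.integer(genome_max_mm),
              te_max_mm = as.integer(te_max_mm), report = report,
              min_pirna_len = as.integer(min_pirna_len),
              window_len = as.integer(window_len),
              anchor_offset = as.integer(anchor_offset),
              tile_width = as.integer(tile_width),
              mask_pad = as.integer(mask_pad),
              tpm_pseudo = tpm_pseudo, seed = as.integer(seed))
  if (cfg$window_len != 11L || cfg$anchor_offset != 5L)
    stop("signature window is defined as 11 positions, anchor index 5")
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config), vapply(config, paste, "", collapse = ","),
                   sep = "="), f)
  unname(tools::md5sum(f))
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pirnasig config_hash=%s seed=%d",
                     config_hash(config), config$seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full piRNA-signature pipeline
#'
#' Executes preprocess, infrastructural annotation, genome and TE mapping,
#' signature statistics and (optionally) tile quantification and TE mRNA
#' abundance on a raw FASTQ plus reference bundle, and assembles a report
#' object.  When `outdir` is given, every table is written as TSV with a
#' config-hash/seed header plus a `summary.tsv` of headline statistics;
#' outputs written before a failing stage are retained.
#'
#' @param fastq raw FASTQ path (or data.frame of raw reads).
#' @param bundle `ref_bundle` from [load_reference()] or
#'   [build_toy_reference()].
#' @param config [pipeline_config()].
#' @param te_counts optional transcript count table (single library or
#'   `condition` column with two levels) for the TE-expression stage.
#' @param reference_cluster_abundance optional [cluster_abundance()] table
#'   of a reference library; adds per-cluster ratios.
#' @param outdir optional output directory.
#' @param skip_tiles skip the tile stage.
#' @return object of class `pirnasig_report`.
#' @export
run_pipeline <- function(fastq, bundle, config = pipeline_config(),
                         te_counts = NULL,
                         reference_cluster_abundance = NULL,
                         outdir = NULL, skip_tiles = FALSE) {
  stopifnot(inherits(bundle, "ref_bundle"),
            inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(outdir))
      write_report_tsv(df, file.path(outdir, paste0(name, ".tsv")), config)
  }

  pre <- run_stage("preprocess", preprocess_reads(
    fastq, adapter = config$adapter, min_overlap = config$min_overlap,
    umi_len = config$umi_len, min_len = config$min_len,
    max_len = config$max_len))
  clean <- pre$clean
  emit(data.frame(category = names(pre$report), reads = unname(pre$report)),
       "preprocess_report")

  infra <- run_stage("infrastructural", annotate_infrastructural(
    clean, bundle, max_mismatches = config$infra_max_mm))
  hp <- infra$hpRNA_total
  emit(data.frame(class = names(infra$class_counts),
                  reads = unname(infra$class_counts)), "infrastructural")

  genome_aln <- run_stage("genome_mapping", map_reads(
    clean, bundle$genome, max_mismatches = config$genome_max_mm,
    report = config$report, target_class = "genome"))
  uniq <- unique_genome_mappers(genome_aln)

  te_aln <- run_stage("te_mapping", classify_te_orientation(map_reads(
    clean, bundle$te, max_mismatches = config$te_max_mm,
    report = config$report, target_class = "TE")))
  emit(te_aln, "te_alignments")

  sizes <- run_stage("signatures", size_distribution(
    te_aln, hp, min_len = config$min_len, max_len = config$max_len))
  fm_anti <- positional_frequencies(te_aln, bundle$te, "antisense_pos1",
                                    min_len = config$min_pirna_len)
  fm_sense <- positional_frequencies(te_aln, bundle$te, "sense_pos10",
                                     min_len = config$min_pirna_len)
  z1u <- pingpong_zscore(fm_anti, "U", config$anchor_offset)
  z10a <- pingpong_zscore(fm_sense, "A", config$anchor_offset)
  phasing <- downstream_u_frequency(genome_aln, bundle,
                                    te_read_ids = unique(te_aln$read_id),
                                    min_len = config$min_pirna_len)
  tefrac <- te_mapping_fraction(clean, te_aln,
                                min_len = config$min_pirna_len)
  emit(sizes, "size_distribution")
  emit(cbind(position = rownames(fm_anti$freq),
             as.data.frame(fm_anti$freq)), "freq_antisense_pos1")
  emit(cbind(position = rownames(fm_sense$freq),
             as.data.frame(fm_sense$freq)), "freq_sense_pos10")
  emit(phasing, "phasing")

  tiles <- clusters <- ratios <- NULL
  if (!skip_tiles) {
    tiles <- run_stage("tiles", {
      mask <- build_mask(bundle$annotation, nchar(bundle$genome),
                         pad = config$mask_pad)
      tile_counts(uniq, mask, nchar(bundle$genome),
                  tile_width = config$tile_width, hpRNA_total = hp,
                  min_len = config$min_pirna_len)
    })
    clusters <- cluster_abundance(tiles, bundle$annotation)
    emit(tiles, "tiles")
    emit(clusters, "cluster_abundance")
    if (!is.null(reference_cluster_abundance)) {
      ratios <- relative_to_reference(clusters, reference_cluster_abundance)
      emit(ratios, "cluster_ratios")
    }
  }

  te_expr <- NULL
  if (!is.null(te_counts)) {
    te_expr <- run_stage("te_expression", {
      if (!is.null(te_counts$condition) &&
          length(unique(te_counts$condition)) == 2L) {
        conds <- sort(unique(te_counts$condition))
        ta <- tpm(te_counts[te_counts$condition == conds[1L],
                            setdiff(names(te_counts), "condition")])
        tb <- tpm(te_counts[te_counts$condition == conds[2L],
                            setdiff(names(te_counts), "condition")])
        te_summary(ta, tb, pseudo = config$tpm_pseudo)
      } else {
        list(per_te = NULL, abundance = tpm(te_counts))
      }
    })
    if (!is.null(te_expr$per_te)) emit(te_expr$per_te, "te_expression")
  }

  summary_df <- data.frame(
    statistic = c("reads_in", "reads_clean", "hpRNA_total",
                  "z_1U_antisense", "z_10A_sense",
                  "downstream_U_all", "downstream_U_TE",
                  "te_mapping_fraction"),
    value = c(pre$report[["input"]], pre$report[["kept"]], hp,
              z1u$z, z10a$z,
              phasing$frequency[phasing$category == "all"],
              phasing$frequency[phasing$category == "TE-mapping"],
              tefrac$fraction),
    stringsAsFactors = FALSE)
  emit(summary_df, "summary")

  structure(list(config = config, preprocess = pre, infra = infra,
                 hpRNA_total = hp, genome_alignments = genome_aln,
                 unique_genome = uniq, te_alignments = te_aln,
                 size_distribution = sizes,
                 freq_antisense = fm_anti, freq_sense = fm_sense,
                 z_1U_antisense = z1u, z_10A_sense = z10a,
                 phasing = phasing, te_fraction = tefrac,
                 tiles = tiles, cluster_abundance = clusters,
                 cluster_ratios = ratios, te_expression = te_expr,
                 summary = summary_df),
            class = "pirnasig_report")
}

#' @export
print.pirnasig_report <- function(x, ...) {
  cat("piRNA signature report\n")
  cat(sprintf("  reads: %d in -> %d clean (hpRNA normalizer: %d)\n",
              x$preprocess$report[["input"]],
              x$preprocess$report[["kept"]], x$hpRNA_total))
  cat(sprintf("  ping-pong z-scores: 1U antisense = %.3f, 10A sense = %.3f\n",
              x$z_1U_antisense$z, x$z_10A_sense$z))
  dU <- x$phasing$frequency[x$phasing$category == "all"]
  cat(sprintf("  downstream-U frequency (all genome mappers): %.3f\n", dU))
  cat(sprintf("  TE-mapping fraction of piRNA-sized reads: %.3f\n",
              x$te_fraction$fraction))
  if (!is.null(x$cluster_abundance)) {
    cat("  piRNA-cluster abundance (per million hpRNA reads):\n")
    for (i in seq_len(nrow(x$cluster_abundance)))
      cat(sprintf("    %-12s %.1f\n", x$cluster_abundance$cluster[i],
                  x$cluster_abundance$abundance[i]))
  }
  invisible(x)
}
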