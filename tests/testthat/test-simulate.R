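test_that("reference and library generation are byte-deterministic", {
  b1 <- build_toy_reference(seed = 7)
  b2 <- build_toy_reference(seed = 7)
  expect_identical(b1$genome, b2$genome)
  expect_identical(b1$annotation, b2$annotation)
  expect_identical(b1$te, b2$te)

  cfg <- sim_config(seed = 7, n_reads = 500)
  r1 <- simulate_small_rna(b1, cfg)
  r2 <- simulate_small_rna(b2, cfg)
  expect_identical(r1, r2)

  f1 <- tempfile(); t1 <- tempfile(); f2 <- tempfile(); t2 <- tempfile()
  render_fastq(apply_oxidation(r1, cfg), cfg, f1, t1)
  render_fastq(apply_oxidation(r2, cfg), cfg, f2, t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("reference construction validates its parameters", {
  expect_error(build_toy_reference(1, list(n_clusters = 0L)),
               "at least one piRNA cluster")
  expect_error(build_toy_reference(1, list(bogus = 3)), "unknown reference")
  # requested feature counts drive annotation contents exactly
  b <- build_toy_reference(3, list(n_te = 2L, te_length = 2000L,
                                   n_te_insertions = 4L,
                                   n_clusters = 1L, cluster_length = 1500L,
                                   fragment_len_range = c(300L, 450L)))
  expect_equal(sum(b$annotation$class == "TE_insertion"), 4L)
  expect_length(b$te, 2L)
  # every feature class appears at least once
  expect_setequal(unique(b$annotation$class), feature_classes())
})

test_that("cluster fragments carry genuine TE consensus sequence", {
  b <- fixture_bundle()
  f <- b$fragments
  for (i in seq_len(min(nrow(f), 8L))) {
    genome_piece <- fetch_sequence(b, f$contig[i], f$start[i], f$end[i], "+")
    te_piece <- substring(b$te[[f$te[i]]], f$te_start[i] + 1L, f$te_end[i])
    expect_identical(genome_piece,
                     if (f$orientation[i] == "antisense") revcomp(te_piece)
                     else te_piece)
  }
})

test_that("simulated reads match their genome placement and class bounds", {
  lib <- fixture_library()
  r <- lib$reads
  b <- lib$bundle
  idx <- sample(nrow(r), 200)
  for (i in idx)
    expect_identical(r$seq[i], fetch_sequence(b, r$contig[i], r$start[i],
                                              r$end[i], r$strand[i]))
  expect_true(all(nchar(r$seq[r$class == "piRNA"]) %in% 23:32))
  expect_true(all(nchar(r$seq[r$class == "hpRNA_siRNA"]) == 21L))
  expect_true(all(nchar(r$seq[r$class == "miRNA"]) == 22L))
  expect_true(all(nchar(r$seq[r$class == "degradation"]) %in% 18:40))
})

test_that("ping-pong pairs obey the 10-nt 5' overlap geometry exactly", {
  lib <- fixture_library()
  r <- lib$reads
  partners <- r[r$role == "partner", ]
  expect_gt(nrow(partners), 100L)
  mates <- r[match(partners$partner_id, r$read_id), ]
  # partner 10th base is the complement of the mate's 1st base, for all pairs
  p10 <- substring(partners$seq, 10L, 10L)
  m1 <- substring(mates$seq, 1L, 1L)
  expect_true(all(p10 == chartr("ACGT", "TGCA", m1)))
  # and the partner's 5' end sits 10 nt into the antisense mate
  expect_true(all(partners$end - 1L == mates$start + 9L))
  expect_true(all(partners$strand == "-" & mates$strand == "+"))
})

test_that("pingpong_fraction = 0 emits no partners", {
  cfg <- sim_config(seed = 5, n_reads = 800, pingpong_fraction = 0)
  r <- simulate_small_rna(fixture_bundle(), cfg)
  expect_true(all(is.na(r$partner_id)))
  expect_false(any(r$role == "partner"))
})

test_that("configured u1 bias is recovered from the truth table", {
  cfg <- sim_config(seed = 7, n_reads = 10000, u1_bias = 0.9)
  r <- simulate_small_rna(fixture_bundle(), cfg)
  prim <- r[r$class == "piRNA" & r$role == "primary", ]
  frac <- mean(substring(prim$seq, 1L, 1L) == "T")
  expect_gte(frac, 0.87)
  expect_lte(frac, 0.93)
})

test_that("class fractions are recovered within binomial error", {
  lib <- fixture_library()
  prim <- lib$reads[lib$reads$role == "primary", ]
  emp <- table(prim$class) / nrow(prim)
  cfg <- lib$config
  for (cl in names(cfg$class_fractions)) {
    p <- cfg$class_fractions[[cl]]
    tol <- 3 * sqrt(p * (1 - p) / nrow(prim))
    expect_lt(abs(emp[[cl]] - p), tol + 1e-12)
  }
})

test_that("oxidation retains methylated reads and thins unmethylated ones", {
  cfg <- sim_config(seed = 3)
  all_meth <- data.frame(read_id = paste0("r", 1:100),
                         methylated = rep(TRUE, 100))
  expect_identical(apply_oxidation(all_meth, cfg), all_meth)

  unmeth <- data.frame(read_id = paste0("r", 1:10000),
                       methylated = rep(FALSE, 10000))
  kept <- apply_oxidation(unmeth, cfg, seed = 3)
  expect_gte(nrow(kept), 150)  # binomial 99% band at p = 0.02
  expect_lte(nrow(kept), 250)
  expect_true(all(kept$read_id %in% unmeth$read_id))  # subset, never creates

  cfg0 <- sim_config(seed = 3, oxidation_survival_unmethylated = 0)
  mixed <- data.frame(read_id = paste0("r", 1:200),
                      methylated = rep(c(TRUE, FALSE), 100))
  expect_true(all(apply_oxidation(mixed, cfg0)$methylated))
})

test_that("rendered FASTQ embeds the insert between UMIs and the adapter", {
  cfg <- sim_config(seed = 9)
  reads <- data.frame(read_id = "r1", seq = random_read(25),
                      class = "piRNA", methylated = TRUE)
  fq <- tempfile(); tr <- tempfile()
  render_fastq(reads, cfg, fq, tr)
  rec <- readLines(fq)
  expect_length(rec, 4L)
  expect_identical(rec[1], "@r1")
  expect_identical(nchar(rec[2]), 75L)
  expect_identical(substring(rec[2], 5L, 29L), reads$seq)  # insert after UMI
  expect_identical(substring(rec[2], 34L, 54L), cfg$adapter3)
  expect_identical(rec[4], strrep("I", 75))
  truth <- read.delim(tr)
  expect_true(truth$adapter_present)

  # insert too long for the cycle count: adapter absent, flagged
  cfg30 <- sim_config(seed = 9, read_cycles = 30L)
  long <- data.frame(read_id = "r2", seq = random_read(25),
                     class = "piRNA", methylated = TRUE)
  render_fastq(long, cfg30, fq, tr)
  expect_false(read.delim(tr)$adapter_present)
  expect_false(grepl(cfg30$adapter3, readLines(fq)[2], fixed = TRUE))
})

test_that("sim_config validates fractions, probabilities and the seed", {
  expect_error(sim_config(), "seed is mandatory")
  expect_error(sim_config(1, class_fractions = c(piRNA = 0.9,
                                                 hpRNA_siRNA = 0.2,
                                                 miRNA = 0, degradation = 0)),
               "sum to 1")
  expect_error(sim_config(1, u1_bias = 1.2), "probabilities")
})

test_that("simulated TE count tables behave under null fold changes", {
  tc <- simulate_te_counts(seed = 21, mean_count = 1e4, dispersion = 1e4)
  ta <- tpm(tc[tc$condition == "A", -1])
  tb <- tpm(tc[tc$condition == "B", -1])
  s <- te_summary(ta, tb)
  expect_true(all(abs(s$per_te$log2_ratio) <= 0.1))

  # a configured fold change shows up in the counts
  tc2 <- simulate_te_counts(seed = 21, mean_count = 1e4, dispersion = 1e4,
                            fold_changes = c(TE1 = 4))
  a <- tc2[tc2$condition == "A" & tc2$transcript_id == "TE1", "count"]
  b <- tc2[tc2$condition == "B" & tc2$transcript_id == "TE1", "count"]
  expect_gt(b / a, 2)
})
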