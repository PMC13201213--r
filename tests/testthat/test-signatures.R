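make_aln <- function(read_id, seq, target, start, strand, weight = 1) {
  data.frame(read_id = read_id, seq = seq, length = nchar(seq),
             target = target, class = "TE", start = start, strand = strand,
             mismatches = 0L, weight = weight, stringsAsFactors = FALSE)
}

test_that("size distribution arithmetic and hpRNA normalization", {
  a <- classify_te_orientation(rbind(
    make_aln("r1", random_read(25), "TE1", 0, "-"),
    make_aln("r2", random_read(25), "TE1", 5, "-"),
    make_aln("r3", random_read(26), "TE1", 9, "-")))
  sd <- size_distribution(a, hpRNA_total = 1000)
  expect_equal(sd$per_million[sd$length == 25 & sd$orientation == "antisense"],
               2000)
  expect_equal(sd$per_million[sd$length == 26 & sd$orientation == "antisense"],
               1000)
  expect_equal(sum(sd$count), 3)

  # doubling weights doubles every normalized value (linearity)
  a2 <- a; a2$weight <- 2
  sd2 <- size_distribution(a2, hpRNA_total = 1000)
  expect_equal(sd2$per_million, 2 * sd$per_million)

  # no alignments: all-zero table; zero denominator: NA per-million
  z <- size_distribution(a[0, ], hpRNA_total = 1000)
  expect_true(all(z$count == 0))
  expect_true(all(is.na(size_distribution(a, hpRNA_total = 0)$per_million)))
})

test_that("positional frequency windows match a direct tally", {
  te <- c(TOY = random_read(60))
  # four plus-strand (sense) alignments of 24-nt reads
  starts <- c(0, 7, 13, 20)
  reads <- substring(te[[1]], starts + 1, starts + 24)
  a <- make_aln(paste0("r", 1:4), reads, "TOY", starts, "+")
  fm <- positional_frequencies(a, te, "sense_pos10")
  expect_false(fm$empty)
  # independent tally: window = read positions 5..15, anchor index 6
  for (w in 1:11) {
    col <- substring(reads, 4 + w, 4 + w)
    col <- chartr("T", "U", col)
    for (b in c("A", "C", "G", "U"))
      expect_equal(fm$freq[w, b], mean(col == b))
  }
  # single alignment: point mass at the anchor on the read's 10th base
  one <- positional_frequencies(a[1, ], te, "sense_pos10")
  b10 <- chartr("T", "U", substring(reads[1], 10, 10))
  expect_equal(one$freq["0", b10], 1)
  expect_equal(sum(one$freq["0", ]), 1)

  # every column normalizes to 1
  expect_true(all(abs(rowSums(fm$freq) - 1) < 1e-9))
})

test_that("antisense windows draw upstream context from the target", {
  te <- c(TOY = random_read(80))
  # minus-strand read covering [30, 54); its 5' end is at target coord 53
  rseq <- revcomp(substring(te[[1]], 31, 54))
  a <- make_aln("r1", rseq, "TOY", 30, "-")
  fm <- positional_frequencies(a, te, "antisense_pos1")
  # window indices -5..-1 are complements of target coords 58..54
  ctx <- chartr("ACGT", "UGCA", # complement, displayed as RNA
                strsplit(substring(te[[1]], 55, 59), "")[[1]])
  for (i in 1:5)
    expect_equal(unname(fm$freq[i, rev(ctx)[i]]), 1)
  # window indices 0..5 are the read's first six bases
  rb <- chartr("T", "U", strsplit(substring(rseq, 1, 6), "")[[1]])
  for (i in 1:6)
    expect_equal(unname(fm$freq[5 + i, rb[i]]), 1)

  # an alignment too close to the target end is dropped and counted
  edge <- make_aln("r2", revcomp(substring(te[[1]], 55, 78)), "TOY", 54, "-")
  fme <- positional_frequencies(edge, te, "antisense_pos1")
  expect_true(fme$empty)
  expect_equal(fme$dropped, 1L)
})

test_that("ping-pong z-score follows the population-SD window convention", {
  fm <- manual_freq_matrix(matrix(0.25, 11, 4))
  # anchor (index 5, row 6) equal to the window mean gives z = 0
  u <- c(0.1, 0.5, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3)
  expect_equal(mean(u), u[6])
  fm$freq[, "U"] <- u
  expect_equal(pingpong_zscore(fm, "U")$z, 0)

  # single outlier at the anchor: |z| = sqrt(10), whatever the values
  for (base in c(0.05, 0.25, 0.8)) for (out in c(0.9, 0.0001)) {
    u <- rep(base, 11); u[6] <- out
    fm$freq[, "U"] <- u
    expect_equal(abs(pingpong_zscore(fm, "U")$z), sqrt(10), tolerance = 1e-12)
  }

  # degenerate (constant) window: z = 0 with the flag set
  fm$freq[, "U"] <- rep(0.25, 11)
  z <- pingpong_zscore(fm, "U")
  expect_equal(z$z, 0)
  expect_true(z$degenerate)
})

test_that("downstream-U inspects the genomic base 3' of the read", {
  g <- c(chr1 = paste0(strrep("A", 9), "C", random_read(15),
                       "T", random_read(14)))
  # plus-strand read over [0, 25): next base (coord 25) is T
  bun <- structure(list(genome = g), class = "ref_bundle")
  plus <- make_aln("p", substring(g[[1]], 1, 25), "chr1", 0, "+")
  resp <- downstream_u_frequency(plus, bun)
  expect_equal(resp$frequency[resp$category == "all"], 1)
  # minus-strand read over [10, 35): base at coord 9 is C, complement G -> no U
  minus <- make_aln("m", revcomp(substring(g[[1]], 11, 35)), "chr1", 10, "-")
  resm <- downstream_u_frequency(minus, bun)
  expect_equal(resm$frequency[resm$category == "all"], 0)
  # minus-strand read whose upstream base is A: complement T -> downstream U
  g2 <- c(chr1 = paste0(strrep("A", 10), random_read(30)))
  bun2 <- structure(list(genome = g2), class = "ref_bundle")
  minus2 <- make_aln("m2", revcomp(substring(g2[[1]], 11, 35)), "chr1", 10, "-")
  resm2 <- downstream_u_frequency(minus2, bun2)
  expect_equal(resm2$frequency[resm2$category == "all"], 1)
  # read at the contig edge is dropped and counted
  edge <- make_aln("e", substring(g[[1]], 16, 40), "chr1", 15, "+")
  rese <- downstream_u_frequency(edge, bun)
  expect_true(is.na(rese$frequency[rese$category == "all"]))
  expect_equal(attr(rese, "dropped"), 1L)
  # TE vs non-TE categorisation
  both <- rbind(plus, minus)
  res <- downstream_u_frequency(both, bun, te_read_ids = "p")
  expect_equal(res$frequency[res$category == "TE-mapping"], 1)
  expect_equal(res$frequency[res$category == "non-TE genome-mapping"], 0)
})

test_that("TE-mapping fraction counts piRNA-sized reads with TE placements", {
  reads <- data.frame(read_id = paste0("r", 1:10),
                      seq = vapply(rep(25L, 10), random_read, ""))
  aln <- make_aln(paste0("r", 1:9), "x", "TE1", 0, "+")
  tf <- te_mapping_fraction(reads, aln)
  expect_equal(tf$fraction, 0.9)
  expect_equal(tf$n_reads, 10L)
  short <- data.frame(read_id = "s", seq = random_read(20))
  expect_true(is.na(te_mapping_fraction(short, aln)$fraction))
})
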