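mk_uniq <- function(read_id, contig, start, len, strand = "+", weight = 1) {
  data.frame(read_id = read_id, seq = strrep("A", len), length = len,
             target = contig, class = "genome", start = start,
             strand = strand, mismatches = 0L, weight = weight,
             stringsAsFactors = FALSE)
}

ann_row <- function(contig, start, end, class, name, strand = "+") {
  data.frame(contig = contig, start = start, end = end, strand = strand,
             class = class, name = name, stringsAsFactors = FALSE)
}

test_that("exclusion mask pads, clips and merges intervals", {
  lens <- c(chr1 = 10000L)
  m <- build_mask(ann_row("chr1", 500, 600, "tRNA", "t1"), lens)
  expect_equal(m[, c("start", "end")], data.frame(start = 400L, end = 700L))

  clipped <- build_mask(ann_row("chr1", 50, 120, "tRNA", "t1"), lens)
  expect_equal(clipped$start, 0L)
  expect_equal(clipped$end, 220L)

  # two tRNAs 50 nt apart merge into one padded interval
  two <- rbind(ann_row("chr1", 500, 600, "tRNA", "t1"),
               ann_row("chr1", 650, 700, "tRNA", "t2"))
  merged <- build_mask(two, lens)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(400L, 800L))

  # aubergine locus enters unpadded; miRNA loci do not enter at all
  with_aub <- rbind(ann_row("chr1", 2000, 2500, "aub_locus", "aub"),
                    ann_row("chr1", 4000, 4100, "miRNA", "m1"))
  ma <- build_mask(with_aub, lens)
  expect_equal(nrow(ma), 1L)
  expect_equal(c(ma$start, ma$end), c(2000L, 2500L))
})

test_that("tile counting assigns by 5' end, masks overlaps, normalizes", {
  lens <- c(chr1 = 5000L)
  mask <- build_mask(ann_row("chr1", 3000, 3100, "tRNA", "t1"), lens)
  a <- rbind(mk_uniq("r1", "chr1", 1500, 25),
             mk_uniq("r2", "chr1", 1600, 25),
             mk_uniq("r3", "chr1", 1980, 25),         # 5' in [1000,2000)
             mk_uniq("r4", "chr1", 2875, 26),         # overlaps mask by 1 nt
             mk_uniq("r5", "chr1", 2500, 25))
  tt <- tile_counts(a, mask, lens, tile_width = 1000L, hpRNA_total = 3000)
  expect_equal(tt$count[tt$start == 1000], 3)
  expect_equal(tt$per_million[tt$start == 1000], 1000)
  expect_equal(tt$count[tt$start == 2000], 1)  # r4 removed by the mask
  expect_equal(attr(tt, "masked_out"), 1)
  # minus-strand 5' end assignment: start + len - 1
  b <- mk_uniq("m1", "chr1", 995, 25, strand = "-")  # 5' end at 1019
  tb <- tile_counts(b, mask[0, ], lens, 1000L, 1000)
  expect_equal(tb$count[tb$start == 1000], 1)
  expect_error(tile_counts(a, mask, lens, tile_width = 0L), "tile_width")
})

test_that("tile counts conserve unmasked unique-mapper weight", {
  set.seed(31)
  lens <- c(chr1 = 20000L, chr2 = 15000L)
  ann <- rbind(ann_row("chr1", 5000, 5100, "tRNA", "t1"),
               ann_row("chr2", 1000, 1500, "aub_locus", "aub"))
  a <- do.call(rbind, lapply(1:300, function(i) {
    ctg <- sample(names(lens), 1)
    len <- sample(23:32, 1)
    mk_uniq(paste0("r", i), ctg, sample(0:(lens[[ctg]] - len), 1), len,
            sample(c("+", "-"), 1))
  }))
  for (pad in c(0L, 100L, 400L)) {
    mask <- build_mask(ann, lens, pad = pad)
    tt <- tile_counts(a, mask, lens, 1000L, hpRNA_total = 100)
    expect_equal(sum(tt$count) + attr(tt, "masked_out"), sum(a$weight))
  }
  # mask monotonicity: larger pads never increase any tile count
  t0 <- tile_counts(a, build_mask(ann, lens, pad = 0L), lens, 1000L, 100)
  t4 <- tile_counts(a, build_mask(ann, lens, pad = 400L), lens, 1000L, 100)
  expect_true(all(t4$count <= t0$count))
  # tiles partition each contig without overlap
  tt <- tile_counts(a, build_mask(ann, lens), lens, 1000L, 100)
  for (ctg in names(lens)) {
    d <- tt[tt$contig == ctg, ]
    expect_equal(d$start, seq(0L, lens[[ctg]] - 1L, by = 1000L))
    expect_true(all(d$end[-nrow(d)] == d$start[-1]))
  }
})

test_that("cluster abundance sums tiles by midpoint and handles degenerates", {
  tt <- data.frame(contig = "chr1", start = seq(0L, 4000L, 1000L),
                   end = seq(1000L, 5000L, 1000L),
                   count = c(1, 10, 0, 5, 2),
                   per_million = c(100, 10, 0, 5, 200) * 1)
  tt$per_million <- c(1, 10, 0, 5, 2) * 1000
  ann <- ann_row("chr1", 900, 4100, "piRNA_cluster", "cl1")
  ca <- cluster_abundance(tt, ann)
  expect_equal(ca$abundance, (10 + 0 + 5) * 1000)
  # cluster shorter than a tile with no midpoint inside: 0 with warning
  tiny <- ann_row("chr1", 100, 300, "piRNA_cluster", "tiny")
  expect_warning(ca2 <- cluster_abundance(tt, tiny), "no tile midpoint")
  expect_equal(ca2$abundance, 0)
  # disjoint clusters are independent of each other's tiles
  two <- rbind(ann_row("chr1", 900, 2100, "piRNA_cluster", "a"),
               ann_row("chr1", 2900, 4100, "piRNA_cluster", "b"))
  ca3 <- cluster_abundance(tt, two)
  # only the tile [1000,2000) has its midpoint inside [900,2100)
  expect_equal(ca3$abundance[ca3$cluster == "a"], 10000)
  expect_equal(ca3$abundance[ca3$cluster == "b"], 5000)
})

test_that("relative abundance flags zero references and scales linearly", {
  s <- data.frame(cluster = c("a", "b"), contig = "chr1",
                  abundance = c(30, 10))
  r <- data.frame(cluster = c("a", "b"), contig = "chr1",
                  abundance = c(10, 0))
  rr <- relative_to_reference(s, r)
  expect_equal(rr$ratio[rr$cluster == "a"], 3)
  expect_true(is.na(rr$ratio[rr$cluster == "b"]))
  ident <- relative_to_reference(s, s)
  expect_true(all(ident$ratio == 1))
  expect_error(relative_to_reference(s, r[1, , drop = FALSE]),
               "same cluster set")
})

test_that("simulated cluster piRNAs land in tiles of their source cluster", {
  lib <- fixture_library()
  b <- lib$bundle
  clean <- data.frame(read_id = lib$oxidized$read_id,
                      seq = lib$oxidized$seq)
  aln <- map_reads(clean, b$genome, max_mismatches = 1)
  uniq <- unique_genome_mappers(aln)
  mask <- build_mask(b$annotation, nchar(b$genome))
  tt <- tile_counts(uniq, mask, nchar(b$genome), 1000L, hpRNA_total = 100)
  ca <- cluster_abundance(tt, b$annotation, value = "count")
  truth_pi <- lib$oxidized$read_id[lib$oxidized$class == "piRNA"]
  in_clusters <- sum(ca$abundance)
  n_pi_unique <- sum(uniq$read_id %in% truth_pi)
  expect_gte(in_clusters / n_pi_unique, 0.90)
})
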