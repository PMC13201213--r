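# Synthetic small-RNA library generator.  Builds a toy reference (genome +
# annotation + TE consensus library) and emits seeded read populations with
# the biogenesis structure the analysis detects: 5' uridine bias, ping-pong
# sense partners with the 10-nt 5' overlap geometry, phased 3' ends
# (downstream uridine), 2'-O-methylation and periodate oxidation, plus
# hpRNA-derived siRNA, miRNA and degradation-fragment backgrounds.
#
# The toy reference uses a uniform base composition (25% each): the
# generative biases are imposed by rejection sampling of (position, length)
# pairs, so a configured probability (e.g. u1_bias = 0.25) corresponds
# exactly to "no bias" against the background.

#' Simulation configuration
#'
#' All knobs of the library simulator, with defaults reflecting an oxidized
#' piRNA-rich library: piRNA-sized inserts (23-32 nt) with a strong 5'-U
#' bias, mostly TE-antisense, half of them with a ping-pong sense partner,
#' phased 3' ends at 50% downstream-U, piRNA/siRNA 3' ends 2'-O-methylated
#' (so they survive periodate oxidation) over unmethylated miRNA and
#' degradation backgrounds.  Class fractions must sum to 1 and the seed is
#' mandatory.
#'
#' @param seed integer seed (mandatory; drives every random choice).
#' @param n_reads number of primary reads (ping-pong partners are emitted in
#'   addition, linked through `partner_id`).
#' @param class_fractions named probabilities over
#'   piRNA / hpRNA_siRNA / miRNA / degradation, summing to 1.
#' @param piRNA_len_range inclusive insert length range for piRNA reads.
#' @param piRNA_antisense_fraction probability a primary piRNA is
#'   TE-antisense.
#' @param u1_bias probability a primary piRNA 5' nucleotide is U.
#' @param pingpong_fraction probability an antisense piRNA has a sense
#'   partner.
#' @param phasing_downstream_u probability the genomic base immediately 3'
#'   of a piRNA is U on the read strand.
#' @param methylation_prob per-class probability of 3' 2'-O-methylation.
#' @param oxidation_survival_unmethylated survival probability of an
#'   unmethylated read under periodate oxidation.
#' @param adapter3 3' adapter sequence ligated after the randomized UMI.
#' @param umi_len randomized-nucleotide (UMI) length at each end of the
#'   insert.
#' @param read_cycles sequencing read length in cycles.
#' @return classed list `sim_config`.
#' @export
sim_config <- function(seed,
                       n_reads = 10000L,
                       class_fractions = c(piRNA = 0.5, hpRNA_siRNA = 0.2,
                                           miRNA = 0.1, degradation = 0.2),
                       piRNA_len_range = c(23L, 32L),
                       piRNA_antisense_fraction = 0.8,
                       u1_bias = 0.9,
                       pingpong_fraction = 0.5,
                       phasing_downstream_u = 0.5,
                       methylation_prob = c(piRNA = 1, hpRNA_siRNA = 1,
                                            miRNA = 0, degradation = 0),
                       oxidation_survival_unmethylated = 0.02,
                       adapter3 = "AGATCGGAAGAGCACACGTCT",
                       umi_len = 4L,
                       read_cycles = 75L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  need <- c("piRNA", "hpRNA_siRNA", "miRNA", "degradation")
  if (!setequal(names(class_fractions), need))
    stop("class_fractions must name exactly: ", paste(need, collapse = ", "))
  class_fractions <- class_fractions[need]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop("class_fractions must sum to 1")
  probs <- c(class_fractions, piRNA_antisense_fraction, u1_bias,
             pingpong_fraction, phasing_downstream_u, methylation_prob,
             oxidation_survival_unmethylated)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!setequal(names(methylation_prob), need))
    stop("methylation_prob must name exactly: ", paste(need, collapse = ", "))
  stopifnot(length(piRNA_len_range) == 2L,
            piRNA_len_range[1] <= piRNA_len_range[2], n_reads >= 1)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 class_fractions = class_fractions,
                 piRNA_len_range = as.integer(piRNA_len_range),
                 piRNA_antisense_fraction = piRNA_antisense_fraction,
                 u1_bias = u1_bias, pingpong_fraction = pingpong_fraction,
                 phasing_downstream_u = phasing_downstream_u,
                 methylation_prob = methylation_prob[need],
                 oxidation_survival_unmethylated =
                   oxidation_survival_unmethylated,
                 adapter3 = adapter3, umi_len = as.integer(umi_len),
                 read_cycles = as.integer(read_cycles)),
            class = "sim_config")
}

#' Default toy-reference parameters
#'
#' Contig count and length, TE consensus library size, piRNA cluster
#' number/length and fragment geometry, dispersed-insertion count and
#' divergence, and the per-class counts and lengths of the
#' infrastructural, hpRNA and aubergine-like loci.  Any entry can be
#' overridden through the `params` argument of [build_toy_reference()].
#'
#' @return named list of parameters.
#' @export
default_ref_params <- function() {
  list(n_contigs = 3L, contig_length = 50000L,
       n_te = 6L, te_length = 3000L,
       n_clusters = 2L, cluster_length = 8000L,
       fragment_len_range = c(500L, 900L),
       fragment_antisense_fraction = 0.8,
       n_te_insertions = 4L, insertion_divergence = 0.2,
       n_trna = 2L, n_snrna = 1L, n_snorna = 1L, n_mirna = 2L, n_rrna = 1L,
       trna_length = 75L, snrna_length = 150L, snorna_length = 130L,
       mirna_length = 70L, rrna_length = 120L,
       hprna_length = 400L, aub_length = 2000L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    alt <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")
    ch[hit] <- vapply(ch[hit], function(b)
      substring(alt[[b]], s <- sample.int(3L, 1L), s), "")
  }
  paste(ch, collapse = "")
}

splice_into <- function(contig, start0, piece) {
  # replace contig bases [start0, start0 + nchar(piece)) with piece
  paste0(substring(contig, 1L, start0),
         piece,
         substring(contig, start0 + nchar(piece) + 1L, nchar(contig)))
}

#' Build a toy reference bundle
#'
#' Deterministically (for a fixed seed) generates random contigs, a TE
#' consensus library, piRNA clusters filled with TE fragments inserted
#' predominantly antisense, dispersed diverged TE insertions, and one or
#' more loci of every infrastructural class plus an hpRNA locus and an
#' aubergine-like locus.  Cluster fragments are carved from disjoint
#' regions of the consensus elements so that piRNA-sized reads map the
#' genome uniquely; dispersed insertions are diverged so they do not
#' cross-map within one mismatch.
#'
#' @param seed integer seed.
#' @param params named list overriding [default_ref_params()] entries;
#'   unknown names are rejected.
#' @return `ref_bundle` with extra elements `fragments` (cluster TE
#'   fragment table used by the read simulator), `params` and `seed`.
#' @export
build_toy_reference <- function(seed, params = list()) {
  p <- default_ref_params()
  unknown <- setdiff(names(params), names(p))
  if (length(unknown)) stop("unknown reference params: ",
                            paste(unknown, collapse = ", "))
  p[names(params)] <- params
  if (p$n_clusters < 1L) stop("at least one piRNA cluster is required")
  if (p$n_te < 1L || p$te_length < 100L) stop("need n_te >= 1, te_length >= 100")
  set.seed(as.integer(seed))

  te <- setNames(vapply(seq_len(p$n_te), function(i) random_dna(p$te_length),
                        ""), paste0("TE", seq_len(p$n_te)))
  contig_names <- paste0("chr", seq_len(p$n_contigs))
  genome <- setNames(vapply(contig_names, function(x)
    random_dna(p$contig_length), ""), contig_names)

  ann <- list()
  add_feat <- function(contig, start, end, strand, class, name) {
    ann[[length(ann) + 1L]] <<- data.frame(
      contig = contig, start = as.integer(start), end = as.integer(end),
      strand = strand, class = class, name = name, stringsAsFactors = FALSE)
  }

  # --- piRNA clusters with TE fragments (contig 1) ------------------------
  gap_between_clusters <- 2000L
  need <- p$n_clusters * (p$cluster_length + gap_between_clusters)
  if (need > p$contig_length)
    stop("clusters exceed contig length; enlarge contig_length")
  te_cursor <- setNames(integer(p$n_te), names(te)) # next free consensus base
  alloc_te_region <- function(len) {
    free <- names(te)[p$te_length - te_cursor >= len]
    if (!length(free)) return(NULL)
    nm <- if (length(free) == 1L) free else sample(free, 1L)
    s <- te_cursor[[nm]]
    te_cursor[[nm]] <<- s + len
    list(te = nm, start = s, end = s + len)
  }
  frags <- list()
  for (ci in seq_len(p$n_clusters)) {
    cstart <- (ci - 1L) * (p$cluster_length + gap_between_clusters) + 1000L
    cend <- cstart + p$cluster_length
    if (cend > p$contig_length) stop("clusters exceed contig length")
    add_feat("chr1", cstart, cend, "+", "piRNA_cluster", paste0("cluster", ci))
    pos <- cstart
    repeat {
      flen <- sample(seq(p$fragment_len_range[1], p$fragment_len_range[2]), 1L)
      gap <- sample(30:80, 1L)
      if (pos + flen + gap > cend) break
      reg <- alloc_te_region(flen)
      if (is.null(reg))
        stop("TE consensus library exhausted; increase n_te or te_length")
      piece <- substring(te[[reg$te]], reg$start + 1L, reg$end)
      orient <- if (runif(1) < p$fragment_antisense_fraction)
        "antisense" else "sense"
      if (orient == "antisense") piece <- revcomp(piece)
      genome[["chr1"]] <- splice_into(genome[["chr1"]], pos, piece)
      frags[[length(frags) + 1L]] <- data.frame(
        contig = "chr1", start = pos, end = pos + flen,
        te = reg$te, te_start = reg$start, te_end = reg$end,
        orientation = orient, cluster = paste0("cluster", ci),
        stringsAsFactors = FALSE)
      pos <- pos + flen + gap
    }
  }
  fragments <- do.call(rbind, frags)
  if (sum(fragments$orientation == "antisense") == 0L ||
      (p$fragment_antisense_fraction < 1 &&
       sum(fragments$orientation == "sense") == 0L)) {
    # guarantee both orientations exist when both are requested
    flip <- which(fragments$orientation ==
                    names(which.max(table(fragments$orientation))))[1L]
    f <- fragments[flip, ]
    piece <- substring(te[[f$te]], f$te_start + 1L, f$te_end)
    neworient <- if (f$orientation == "antisense") "sense" else "antisense"
    if (neworient == "antisense") piece <- revcomp(piece)
    genome[[f$contig]] <- splice_into(genome[[f$contig]], f$start, piece)
    fragments$orientation[flip] <- neworient
  }

  # --- infrastructural loci, hpRNA, aubergine-like locus (contig 2) -------
  c2 <- contig_names[min(2L, p$n_contigs)]
  cursor <- 500L
  place <- function(len, strand, class, name) {
    gap <- sample(300:800, 1L)
    s <- cursor + gap
    if (s + len > p$contig_length - 500L)
      stop("infrastructural loci exceed contig length")
    add_feat(c2, s, s + len, strand, class, name)
    cursor <<- s + len
    c(s, s + len)
  }
  for (i in seq_len(p$n_rrna))  place(p$rrna_length, "+", "rRNA", paste0("rRNA", i))
  for (i in seq_len(p$n_snrna)) place(p$snrna_length, "+", "snRNA", paste0("snRNA", i))
  for (i in seq_len(p$n_snorna)) place(p$snorna_length, "+", "snoRNA", paste0("snoRNA", i))
  for (i in seq_len(p$n_trna))  place(p$trna_length, sample(c("+", "-"), 1L),
                                      "tRNA", paste0("tRNA", i))
  for (i in seq_len(p$n_mirna)) place(p$mirna_length, sample(c("+", "-"), 1L),
                                      "miRNA", paste0("miR", i))
  place(p$hprna_length, "+", "hpRNA", "hpRNA1")
  place(p$aub_length, "+", "aub_locus", "aub")

  # --- dispersed, diverged TE insertions (contig 3 / tail of contig 2) ----
  c3 <- contig_names[min(3L, p$n_contigs)]
  ins_cursor <- 1000L
  for (i in seq_len(p$n_te_insertions)) {
    nm <- names(te)[(i - 1L) %% p$n_te + 1L]
    ilen <- min(1200L, p$te_length)
    istart <- sample.int(p$te_length - ilen + 1L, 1L) - 1L
    piece <- mutate_seq(substring(te[[nm]], istart + 1L, istart + ilen),
                        p$insertion_divergence)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") piece <- revcomp(piece)
    s <- ins_cursor + sample(200:600, 1L)
    if (s + ilen > p$contig_length - 200L)
      stop("TE insertions exceed contig length")
    genome[[c3]] <- splice_into(genome[[c3]], s, piece)
    add_feat(c3, s, s + ilen, strand, "TE_insertion", paste0(nm, "_ins", i))
    ins_cursor <- s + ilen
  }

  annotation <- do.call(rbind, ann)
  rownames(annotation) <- NULL
  validate_annotation(annotation, nchar(genome))
  structure(list(genome = genome, annotation = annotation, te = te,
                 fragments = fragments, params = p, seed = as.integer(seed)),
            class = "ref_bundle")
}

# base at 0-based position pos of each read's contig (vectorised)
base_at <- function(genome, contig, pos) {
  substring(genome[contig], pos + 1L, pos + 1L)
}

# pick, per row, one TRUE column of `allowed` uniformly at random;
# returns NA for rows with no TRUE entry
pick_allowed_col <- function(allowed) {
  if (!is.matrix(allowed)) allowed <- matrix(allowed, nrow = 1L)
  r <- matrix(runif(length(allowed)), nrow = nrow(allowed))
  r[!allowed] <- -1
  ok <- rowSums(allowed) > 0L
  out <- max.col(r, ties.method = "first")
  out[!ok] <- NA_integer_
  out
}

#' Simulate a small-RNA read population
#'
#' Draws reads according to the class fractions of `config`.  Primary piRNA
#' 5' ends are chosen inside the cluster TE fragments so that the 5' base is
#' U with probability `u1_bias`; insert lengths are chosen so that the
#' genomic base immediately 3' of the read (on the read strand) is U with
#' probability `phasing_downstream_u` (rejection sampling over positions
#' and lengths).  With probability `pingpong_fraction` an antisense piRNA
#' receives a sense partner on the opposite genome strand whose 5' end lies
#' 10 nt into the antisense read, so the partner's 10th base is the
#' complement of the mate's 1st.  hpRNA-derived siRNAs are 21 nt, miRNAs
#' 22 nt from fixed mature positions, degradation fragments uniform
#' 18-40 nt from random loci.  Methylation flags are drawn per class.
#'
#' @param bundle reference from [build_toy_reference()] (must carry the
#'   `fragments` table).
#' @param config [sim_config()].
#' @return data.frame of simulated reads: read_id, seq, class, source,
#'   contig, start, end, strand, methylated, role (primary/partner),
#'   partner_id.
#' @export
simulate_small_rna <- function(bundle, config) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(config, "sim_config"))
  if (is.null(bundle$fragments))
    stop("bundle lacks the cluster fragment table; use build_toy_reference()")
  set.seed(config$seed)
  genome <- bundle$genome
  ann <- bundle$annotation
  frags <- bundle$fragments
  lmin <- config$piRNA_len_range[1]; lmax <- config$piRNA_len_range[2]
  lens <- lmin:lmax

  n <- config$n_reads
  cls <- sample(names(config$class_fractions), n, replace = TRUE,
                prob = config$class_fractions)
  n_pi <- sum(cls == "piRNA"); n_si <- sum(cls == "hpRNA_siRNA")
  n_mi <- sum(cls == "miRNA"); n_dg <- sum(cls == "degradation")

  # candidate 5' positions per fragment orientation, with margins so that
  # the read and a potential ping-pong partner stay inside the fragment
  cand_for <- function(orient) {
    f <- frags[frags$orientation == orient, , drop = FALSE]
    if (nrow(f) == 0L) return(NULL)
    lo <- f$start + lmax - 10L   # partner span margin
    hi <- f$end - lmax
    keep <- lo <= hi
    f <- f[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
    if (nrow(f) == 0L) return(NULL)
    pos <- unlist(mapply(seq, lo, hi, SIMPLIFY = FALSE), use.names = FALSE)
    idx <- rep(seq_len(nrow(f)), hi - lo + 1L)
    data.frame(contig = f$contig[idx], pos = pos, te = f$te[idx],
               cluster = f$cluster[idx],
               base = base_at(genome, f$contig[idx], pos),
               stringsAsFactors = FALSE)
  }

  draw_pirna <- function(m, cand) {
    if (m == 0L) return(NULL)
    if (is.null(cand)) stop("no cluster fragments in required orientation; ",
                            "regenerate the reference")
    isT <- runif(m) < config$u1_bias
    tpool <- which(cand$base == "T"); npool <- which(cand$base != "T")
    if ((any(isT) && !length(tpool)) || (any(!isT) && !length(npool)))
      stop("cluster too T-poor (or T-rich) to satisfy u1_bias; ",
           "regenerate the reference")
    draw_pos <- function(k, fromT) {
      pool <- if (fromT) tpool else npool
      pool[sample.int(length(pool), k, replace = TRUE)]
    }
    ci <- integer(m)
    ci[isT] <- draw_pos(sum(isT), TRUE)
    ci[!isT] <- draw_pos(sum(!isT), FALSE)
    wantT <- runif(m) < config$phasing_downstream_u
    L <- integer(m)
    todo <- seq_len(m)
    for (iter in 1:50) {
      if (!length(todo)) break
      ctg <- cand$contig[ci[todo]]; p0 <- cand$pos[ci[todo]]
      nb <- vapply(lens, function(l) base_at(genome, ctg, p0 + l) == "T",
                   logical(length(todo)))
      if (length(todo) == 1L) nb <- matrix(nb, nrow = 1L)
      allowed <- nb
      allowed[!wantT[todo], ] <- !nb[!wantT[todo], ]
      pick <- pick_allowed_col(allowed)
      ok <- !is.na(pick)
      L[todo[ok]] <- lens[pick[ok]]
      bad <- todo[!ok]
      if (length(bad)) {
        # redraw failed positions from the same T/non-T pool, preserving
        # the already-drawn u1 category
        bT <- bad[isT[bad]]; bN <- bad[!isT[bad]]
        if (length(bT)) ci[bT] <- draw_pos(length(bT), TRUE)
        if (length(bN)) ci[bN] <- draw_pos(length(bN), FALSE)
      }
      todo <- bad
    }
    if (length(todo))
      stop("cluster too T-poor to satisfy phasing bias; ",
           "regenerate the reference")
    ctg <- cand$contig[ci]; p0 <- cand$pos[ci]
    data.frame(contig = ctg, start = p0, end = p0 + L, strand = "+",
               seq = substring(genome[ctg], p0 + 1L, p0 + L),
               source = cand$te[ci], stringsAsFactors = FALSE)
  }

  n_anti <- sum(runif(n_pi) < config$piRNA_antisense_fraction)
  n_sense <- n_pi - n_anti
  anti <- draw_pirna(n_anti, cand_for("antisense"))
  sens <- if (n_sense > 0L) draw_pirna(n_sense, cand_for("sense")) else NULL
  if (!is.null(anti)) anti$orientation <- "antisense"
  if (!is.null(sens)) sens$orientation <- "sense"
  primaries <- rbind(anti, sens)

  # ping-pong partners for antisense primaries
  partners <- NULL
  if (n_anti > 0L && config$pingpong_fraction > 0) {
    mate <- which(runif(n_anti) < config$pingpong_fraction)
    if (length(mate)) {
      ctg <- anti$contig[mate]; g <- anti$start[mate] + 9L
      wantT <- runif(length(mate)) < config$phasing_downstream_u
      nb <- vapply(lens, function(l) base_at(genome, ctg, g - l) == "A",
                   logical(length(mate)))
      if (length(mate) == 1L) nb <- matrix(nb, nrow = 1L)
      allowed <- nb
      allowed[!wantT, ] <- !nb[!wantT, ]
      pick <- pick_allowed_col(allowed)
      pick[is.na(pick)] <- sample.int(length(lens), sum(is.na(pick)),
                                      replace = TRUE)
      Lp <- lens[pick]
      partners <- data.frame(
        contig = ctg, start = g - Lp + 1L, end = g + 1L, strand = "-",
        seq = revcomp(substring(genome[ctg], g - Lp + 2L, g + 1L)),
        source = anti$source[mate], orientation = "sense",
        stringsAsFactors = FALSE)
      partners$mate_index <- mate
    }
  }

  # hpRNA-derived siRNAs (21 nt)
  sirna <- NULL
  if (n_si > 0L) {
    hp <- ann[ann$class == "hpRNA", , drop = FALSE]
    if (nrow(hp) == 0L) stop("no hpRNA locus in annotation")
    hp <- hp[1L, ]
    u <- hp$start + sample.int(hp$end - hp$start - 21L + 1L, n_si,
                               replace = TRUE) - 1L
    st <- sample(c("+", "-"), n_si, replace = TRUE)
    sq <- substring(genome[hp$contig], u + 1L, u + 21L)
    sq[st == "-"] <- revcomp(sq[st == "-"])
    sirna <- data.frame(contig = hp$contig, start = u, end = u + 21L,
                        strand = st, seq = sq, source = hp$name,
                        orientation = NA_character_, stringsAsFactors = FALSE)
  }

  # miRNAs: fixed 22-nt mature sequence per locus
  mirna <- NULL
  if (n_mi > 0L) {
    ml <- ann[ann$class == "miRNA", , drop = FALSE]
    if (nrow(ml) == 0L) stop("no miRNA locus in annotation")
    li <- sample.int(nrow(ml), n_mi, replace = TRUE)
    s <- ifelse(ml$strand[li] == "+", ml$start[li], ml$end[li] - 22L)
    sq <- substring(genome[ml$contig[li]], s + 1L, s + 22L)
    neg <- ml$strand[li] == "-"
    sq[neg] <- revcomp(sq[neg])
    mirna <- data.frame(contig = ml$contig[li], start = s, end = s + 22L,
                        strand = ml$strand[li], seq = sq,
                        source = ml$name[li], orientation = NA_character_,
                        stringsAsFactors = FALSE)
  }

  # degradation fragments: uniform 18-40 nt anywhere
  degr <- NULL
  if (n_dg > 0L) {
    ctg <- sample(names(genome), n_dg, replace = TRUE, prob = nchar(genome))
    L <- sample(18:40, n_dg, replace = TRUE)
    s <- floor(runif(n_dg) * (nchar(genome)[ctg] - L)) # 0-based start
    st <- sample(c("+", "-"), n_dg, replace = TRUE)
    sq <- substring(genome[ctg], s + 1L, s + L)
    sq[st == "-"] <- revcomp(sq[st == "-"])
    degr <- data.frame(contig = ctg, start = s, end = s + L, strand = st,
                       seq = sq, source = "random",
                       orientation = NA_character_, stringsAsFactors = FALSE)
  }

  assemble <- function(df, class, role) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    data.frame(seq = df$seq, class = class, source = df$source,
               contig = df$contig, start = df$start, end = df$end,
               strand = df$strand, orientation = df$orientation,
               role = role, stringsAsFactors = FALSE)
  }
  out <- rbind(assemble(primaries, "piRNA", "primary"),
               assemble(partners, "piRNA", "partner"),
               assemble(sirna, "hpRNA_siRNA", "primary"),
               assemble(mirna, "miRNA", "primary"),
               assemble(degr, "degradation", "primary"))
  out$read_id <- sprintf("sr%07d", seq_len(nrow(out)))
  out$methylated <- runif(nrow(out)) < config$methylation_prob[out$class]
  out$partner_id <- NA_character_
  if (!is.null(partners) && nrow(partners) > 0L) {
    prow <- which(out$role == "partner")
    mrow <- partners$mate_index  # row index within antisense primaries block
    out$partner_id[prow] <- out$read_id[mrow]
    out$partner_id[mrow] <- out$read_id[prow]
  }
  rownames(out) <- NULL
  out[, c("read_id", "seq", "class", "source", "contig", "start", "end",
          "strand", "orientation", "role", "methylated", "partner_id")]
}

#' Apply periodate oxidation to a simulated population
#'
#' Methylated reads are retained with probability 1; unmethylated reads
#' survive with probability `oxidation_survival_unmethylated`.  Oxidation
#' never creates reads: the output is a subset of the input.
#'
#' @param reads data.frame from [simulate_small_rna()].
#' @param config [sim_config()].
#' @param seed RNG seed for the survival draws (default derived from the
#'   config seed so the whole simulation is reproducible end to end).
#' @return surviving subset of `reads`.
#' @export
apply_oxidation <- function(reads, config, seed = config$seed + 1L) {
  stopifnot(is.logical(reads$methylated))
  set.seed(as.integer(seed))
  keep <- reads$methylated |
    runif(nrow(reads)) < config$oxidation_survival_unmethylated
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render a simulated population as raw FASTQ plus truth table
#'
#' Each record is `UMI(4) + insert + UMI(4) + 3' adapter`, padded with
#' random bases and truncated to the configured cycle count, with constant
#' quality "I".  The sidecar truth TSV preserves the ground-truth linkage
#' (class, placement, methylation, ping-pong partner, adapter presence).
#'
#' @param reads simulated read data.frame.
#' @param config [sim_config()].
#' @param fastq_path,truth_path output files.
#' @param seed RNG seed for UMI/pad bases.
#' @return invisible list with the two paths.
#' @export
render_fastq <- function(reads, config, fastq_path, truth_path,
                         seed = config$seed + 2L) {
  set.seed(as.integer(seed))
  n <- nrow(reads)
  cycles <- config$read_cycles
  k <- config$umi_len
  rand_block <- function(m, len) {
    if (m == 0L || len == 0L) return(character(m))
    apply(matrix(sample(c("A", "C", "G", "T"), m * len, replace = TRUE),
                 nrow = m), 1L, paste, collapse = "")
  }
  umi5 <- rand_block(n, k)
  umi3 <- rand_block(n, k)
  full <- paste0(umi5, reads$seq, umi3, config$adapter3)
  pad_needed <- pmax(0L, cycles - nchar(full))
  maxpad <- max(pad_needed)
  if (maxpad > 0L) {
    pads <- rand_block(n, maxpad)
    full <- paste0(full, substring(pads, 1L, pad_needed))
  }
  sequence <- substring(full, 1L, cycles)
  adapter_present <- (2L * k + nchar(reads$seq)) < cycles
  qual <- strrep("I", cycles)
  fq <- character(4L * n)
  fq[seq(1L, by = 4L, length.out = n)] <- paste0("@", reads$read_id)
  fq[seq(2L, by = 4L, length.out = n)] <- sequence
  fq[seq(3L, by = 4L, length.out = n)] <- "+"
  fq[seq(4L, by = 4L, length.out = n)] <- qual
  writeLines(fq, fastq_path)
  truth <- reads
  truth$adapter_present <- adapter_present
  write.table(truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(fastq = fastq_path, truth = truth_path))
}

#' Simulate a two-condition TE/host transcript count table
#'
#' Negative-binomial counts for host transcripts and TE elements across two
#' conditions ("A", "B"), with configurable per-TE fold changes applied to
#' condition B.  Feeds the TPM-style abundance arithmetic of
#' [tpm()] / [te_summary()].
#'
#' @param seed integer seed.
#' @param n_host number of host transcripts.
#' @param te_names TE element names.
#' @param host_length_range host transcript length range (nt).
#' @param te_length TE consensus length (nt).
#' @param mean_count expected count per transcript (before length and
#'   expression-level scaling).
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param fold_changes named per-TE fold change (condition B vs A); default
#'   1 for every element.
#' @return long data.frame: condition, transcript_id, class, length, count.
#' @export
simulate_te_counts <- function(seed, n_host = 200L,
                               te_names = paste0("TE", 1:6),
                               host_length_range = c(500L, 5000L),
                               te_length = 2500L,
                               mean_count = 500,
                               dispersion = 50,
                               fold_changes = NULL) {
  set.seed(as.integer(seed))
  ids <- c(paste0("host", seq_len(n_host)), te_names)
  class <- c(rep("host", n_host), rep("TE", length(te_names)))
  len <- c(sample(seq(host_length_range[1], host_length_range[2]), n_host,
                  replace = TRUE),
           rep(te_length, length(te_names)))
  expr <- stats::rgamma(length(ids), shape = 2, rate = 2) # relative level
  fc <- setNames(rep(1, length(te_names)), te_names)
  if (!is.null(fold_changes)) {
    unknown <- setdiff(names(fold_changes), te_names)
    if (length(unknown)) stop("fold change for unknown TE: ",
                              paste(unknown, collapse = ", "))
    fc[names(fold_changes)] <- fold_changes
  }
  mu_a <- mean_count * expr * len / mean(len)
  mu_b <- mu_a * c(rep(1, n_host), fc)
  rbind(
    data.frame(condition = "A", transcript_id = ids, class = class,
               length = len,
               count = rnbinom(length(ids), mu = mu_a, size = dispersion),
               stringsAsFactors = FALSE),
    data.frame(condition = "B", transcript_id = ids, class = class,
               length = len,
               count = rnbinom(length(ids), mu = mu_b, size = dispersion),
               stringsAsFactors = FALSE))
}
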