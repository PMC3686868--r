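mk_genome_hit <- function(read_id, chrom, pos0, width = 43L, sp = "sp") {
  data.table::data.table(read_id = read_id, reference_kind = "genome",
                         species_label = sp, target = chrom,
                         position = pos0, strand = "+", mismatches = 0L,
                         qwidth = width)
}

three_tx <- function() {
  # t1: exon (100, 300); t2 overlaps t1: exon (250, 500); t3 far: (1000, 1200)
  xenopartition:::transcript_set(data.table::data.table(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g1", "g2"),
    chromosome = "chr1", strand = "+",
    start0 = c(100L, 250L, 1000L), end0 = c(300L, 500L, 1200L),
    biotype = NA), "sp")
}

test_that("genome hits count once per overlapping transcript", {
  tr <- three_tx()
  # read inside t1 only
  h1 <- mk_genome_hit("r1", "chr1", 150L)
  n1 <- count_reads_per_transcript(h1, tr)
  expect_equal(setNames(n1$N, n1$transcript_id),
               c(t1 = 1L, t2 = 0L, t3 = 0L))
  # read overlapping both t1 and t2 (interval [260, 303))
  h2 <- mk_genome_hit("r2", "chr1", 260L)
  n2 <- count_reads_per_transcript(h2, tr)
  expect_equal(setNames(n2$N, n2$transcript_id),
               c(t1 = 1L, t2 = 1L, t3 = 0L))
  # single-base overlap still counts (ends at 300, t2 starts at 250)
  h3 <- mk_genome_hit("r3", "chr1", 299L)   # [299, 342) hits t1 by 1 base
  n3 <- count_reads_per_transcript(h3, tr)
  expect_equal(n3[n3$transcript_id == "t1", ]$N, 1L)
  # oracle: brute-force interval scan over all transcripts
  set.seed(301)
  for (rep in 1:50) {
    p <- sample(0:1250, 1)
    h <- mk_genome_hit("rx", "chr1", p)
    n <- count_reads_per_transcript(h, tr)
    manual <- vapply(seq_len(nrow(tr)), function(i) {
      s <- tr$exon_starts[[i]]; e <- tr$exon_ends[[i]]
      as.integer(any(pmax(s, p) < pmin(e, p + 43L)))
    }, integer(1))
    expect_equal(n$N, manual)
  }
  expect_equal(attr(n2, "T_total"), 1L)
})

test_that("junction hits increment every transcript sharing the breakpoint", {
  fx <- make_two_exon_fixture(seed = 302)
  tr2 <- data.table::copy(fx$transcripts)
  tr2$transcript_id <- "tx2"
  tr3 <- data.table::copy(fx$transcripts)   # different, non-sharing transcript
  tr3$transcript_id <- "tx3"
  tr3$exon_starts <- list(c(fx$coords$s1, fx$coords$s2 + 10L))
  tr3$exon_ends <- list(c(fx$coords$e1e - 10L, fx$coords$e2e))
  tr <- rbind(fx$transcripts, tr2, tr3)
  j <- build_junction_db(tr, fx$genome)
  shared <- paste("spX", "chr1", "+", fx$coords$e1e, fx$coords$s2, sep = "|")
  expect_true(shared %in% j$junction_id)
  jh <- data.table::data.table(read_id = "r1", reference_kind = "junction",
                               species_label = "spX", target = shared,
                               position = 21L, strand = "+",
                               mismatches = 0L, qwidth = 43L)
  n <- count_reads_per_transcript(jh, tr, j)
  expect_equal(setNames(n$N, n$transcript_id),
               c(tx1 = 1L, tx2 = 1L, tx3 = 0L))
  # unknown junction id errors
  jh_bad <- data.table::copy(jh)
  jh_bad$target <- "sp|chrZ|+|1|2"
  expect_error(count_reads_per_transcript(jh_bad, tr, j), "unknown junction")
})

test_that("adjusted RPKM arithmetic, sentinels and invariances", {
  # pseudocount only
  expect_equal(rpkm(0, 1000, 0, 1e6), 0.001)
  # direct arithmetic of the adopted form
  expect_equal(rpkm(10, 1000, 0, 1e6), 10.001)
  # U shrinks the mappable length: rpkm strictly increases
  r_u <- vapply(c(0, 100, 500, 900, 999), function(u)
    rpkm(10, 1000, u, 1e6), numeric(1))
  expect_true(all(diff(r_u) > 0))
  # linearity in N (above the pseudocount)
  expect_equal(rpkm(20, 1000, 0, 1e6) - 0.001,
               2 * (rpkm(10, 1000, 0, 1e6) - 0.001))
  # depth invariance: scaling N and T together leaves rpkm unchanged
  expect_equal(rpkm(10, 1000, 50, 1e6), rpkm(30, 1000, 50, 3e6))
  # sentinel when no mappable length remains
  expect_true(is.na(rpkm(5, 100, 100, 1e6)))
  expect_true(is.na(rpkm(5, 100, 150, 1e6)))
  expect_error(rpkm(5, 100, 0, 0), "uniquely mappable")
})

test_that("gene level picks the max-read transcript with deterministic ties", {
  tq <- data.table::data.table(
    transcript_id = c("tA", "tB", "tC", "tD", "tE"),
    gene_id = c("g1", "g1", "g2", "g2", "g3"),
    N = c(3L, 7L, 5L, 5L, 0L), L = 100L, U = 0L,
    rpkm = c(1, 2, 3, 4, 0.001))
  g <- gene_level(tq)
  expect_equal(g[g$gene_id == "g1", ]$representative_transcript_id, "tB")
  # tie at N = 5: lexicographically smallest id wins
  expect_equal(g[g$gene_id == "g2", ]$representative_transcript_id, "tC")
  expect_equal(g[g$gene_id == "g3", ]$detected, FALSE)
  expect_equal(g[g$gene_id == "g1", ]$detected, TRUE)
  expect_equal(g[g$gene_id == "g1", ]$read_count, 7L)
  # detection monotone in the threshold
  prev <- NULL
  for (t in 1:8) {
    det <- gene_level(tq, detection_threshold = t)
    det <- det$gene_id[det$detected]
    if (!is.null(prev)) expect_true(all(det %in% prev))
    prev <- det
  }
})

test_that("species mixture estimate is the unique-B read share", {
  cls_a <- list(classes = data.table::data.table(
    read_id = sprintf("r%d", 1:1000),
    class = c(rep("unique", 850), rep("unmapped", 150))),
    unique_hits = data.table::data.table())
  cls_b <- list(classes = data.table::data.table(
    read_id = sprintf("r%d", 1:1000),
    class = c(rep("unmapped", 850), rep("unique", 150))),
    unique_hits = data.table::data.table())
  part <- partition_by_species(cls_a, cls_b)
  mix <- estimate_species_mix(part)
  expect_equal(mix$fraction_B, 0.15)
  expect_equal(mix$fraction_A, 0.85)
  # unique_B = 0 -> 0
  cls_b0 <- list(classes = data.table::data.table(
    read_id = sprintf("r%d", 1:1000), class = "unmapped"),
    unique_hits = data.table::data.table())
  expect_equal(estimate_species_mix(
    partition_by_species(cls_a, cls_b0))$fraction_B, 0)
  # nothing retained -> error
  cls_none <- list(classes = data.table::data.table(
    read_id = sprintf("r%d", 1:10), class = "unmapped"),
    unique_hits = data.table::data.table())
  expect_error(estimate_species_mix(
    partition_by_species(cls_none, cls_none)), "no retained")
})

test_that("five-column count export round-trips and validates", {
  counts <- data.table::data.table(
    gene_id = c("g1", "g2"),
    Control_1 = c(10L, 0L), Control_2 = c(12L, 1L),
    Treated_1 = c(5L, 2L), Treated_2 = c(7L, 3L))
  tf <- tempfile(fileext = ".tsv")
  export_counts_table(counts, tf)
  back <- read_counts_table(tf)
  expect_equal(ncol(back), 5L)
  expect_equal(nrow(back), 2L)
  expect_equal(as.data.frame(back), as.data.frame(counts))
  # empty gene set -> header-only file
  export_counts_table(counts[0], tf)
  expect_equal(nrow(read_counts_table(tf)), 0L)
  expect_equal(length(readLines(tf)), 1L)
  # non-integer counts rejected
  bad <- data.table::copy(counts)
  bad$Control_1 <- c(1.5, 2)
  expect_error(export_counts_table(bad, tf), "non-integer")
})

test_that("size factors divide library sizes by their median", {
  expect_equal(size_factors(c(10, 20, 30, 40)),
               c(0.4, 0.8, 1.2, 1.6))
  expect_equal(size_factors(c(5, 5, 5)), c(1, 1, 1))
  expect_equal(size_factors(7), 1)
  expect_error(size_factors(c(10, 0)), "library size")
  # from a count table: column sums
  counts <- data.frame(id = c("a", "b"), s1 = c(5L, 5L), s2 = c(10L, 10L),
                       s3 = c(15L, 15L), s4 = c(20L, 20L))
  expect_equal(unname(size_factors(counts)), c(0.4, 0.8, 1.2, 1.6))
})

test_that("transcript_quant composes counts, U and rpkm", {
  g <- species_genome("sp", c(chr1 = strrep("A", 400)))
  mask <- build_uniqueome(g, k = 50)
  tr <- xenopartition:::transcript_set(
    data.table::data.table(transcript_id = "t1", gene_id = "g1",
                           chromosome = "chr1", strand = "+",
                           start0 = 100L, end0 = 300L, biotype = NA), "sp")
  h <- mk_genome_hit(c("r1", "r2"), "chr1", c(120L, 150L))
  tq <- transcript_quant(h, tr, mask = mask)
  expect_equal(tq$N, 2L)
  expect_equal(tq$L, 200L)
  expect_equal(tq$U, 200L - 50L + 1L)   # every window in the exon is marked
  expect_equal(tq$rpkm, 2 / (((200 - 151) / 1000) * (2 / 1e6)) + 0.001)
})
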