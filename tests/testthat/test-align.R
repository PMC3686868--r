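test_that("trimming arithmetic follows the policy", {
  pol <- alignment_policy()
  expect_equal(nchar(trim_read(rand_seq(50), pol)), 43L)
  # interior subsequence: first base and last six bases removed
  r <- paste0("G", strrep("A", 43), "CCCCCC")
  expect_equal(trim_read(r, pol), strrep("A", 43))
  pol_any <- alignment_policy(min_read_length = 1L)
  expect_equal(nchar(trim_read(rand_seq(36), pol_any)), 29L)
  expect_true(is.na(trim_read(rand_seq(7), pol_any)))
  expect_true(is.na(trim_read(rand_seq(29), pol)))  # below min_read_length
})

test_that("planted reads are found at their unique loci", {
  set.seed(200)
  repeat {
    chrom <- rand_seq(2000)
    if (!anyDuplicated(substring(chrom, 1:(2000 - 42), 43:2000))) break
  }
  g <- species_genome("sp", c(chr1 = chrom))
  pol <- alignment_policy()
  # read whose trimmed 43-mer sits at 0-based offset 7
  read50 <- paste0("G", substr(chrom, 8, 50), "AAAAAA")
  hits <- align_reads(c(r1 = read50), g, policy = pol)
  genome_hits <- hits[hits$strand == "+" | hits$strand == "-", ]
  expect_equal(nrow(hits[hits$mismatches == 0L]), 1L)
  h <- hits[hits$mismatches == 0L]
  expect_equal(h$target, "chr1")
  expect_equal(h$position, 7L)
  expect_equal(h$strand, "+")

  # reverse-complement read maps on the minus strand at the same locus
  rc50 <- paste0("G", oracle_revcomp(substr(chrom, 8, 50)), "AAAAAA")
  hits_rc <- align_reads(c(r2 = rc50), g, policy = pol)
  h <- hits_rc[hits_rc$mismatches == 0L]
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$position, 7L)
})

test_that("seed budget rejects 3 seed mismatches; total budget rejects 4", {
  set.seed(201)
  repeat {
    chrom <- rand_seq(1500)
    if (!anyDuplicated(substring(chrom, 1:(1500 - 42), 43:1500))) break
  }
  g <- species_genome("sp", c(chr1 = chrom))
  pol <- alignment_policy()
  core <- substr(chrom, 101, 143)
  flip <- function(s, pos) {
    for (p in pos) {
      old <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1L]
    }
    s
  }
  mk_read <- function(core43) paste0("G", core43, "AAAAAA")
  ora <- function(r) oracle_align_one(trim_read(r, pol),
                                      list(chr1 = chrom), pol)
  # 2 mismatches in the 25-base seed: accepted
  r2 <- mk_read(flip(core, c(3, 20)))
  h2 <- align_reads(c(x = r2), g, policy = pol)
  expect_true(any(h2$position == 100L & h2$mismatches == 2L))
  # 3 mismatches inside the seed: rejected at that locus
  r3 <- mk_read(flip(core, c(3, 12, 20)))
  h3 <- align_reads(c(x = r3), g, policy = pol)
  expect_false(any(h3$position == 100L & h3$strand == "+"))
  expect_equal(nrow(h3), nrow(ora(r3)))
  # 3 mismatches total with only 2 in seed: accepted
  r3b <- mk_read(flip(core, c(3, 20, 40)))
  h3b <- align_reads(c(x = r3b), g, policy = pol)
  expect_true(any(h3b$position == 100L & h3b$mismatches == 3L))
  # 4 mismatches total: rejected
  r4 <- mk_read(flip(core, c(3, 20, 33, 40)))
  h4 <- align_reads(c(x = r4), g, policy = pol)
  expect_false(any(h4$position == 100L & h4$strand == "+"))
})

test_that("junction-straddling reads hit the junction, not the genome", {
  fx <- make_two_exon_fixture(seed = 202, exon_len = c(100L, 100L))
  j <- build_junction_db(fx$transcripts, fx$genome)
  pol <- alignment_policy()
  chrom <- fx$genome$chromosomes[["chr1"]]
  # spliced read: last 21 bases of exon1 + first 22 of exon2 (43 effective)
  part1 <- substr(chrom, fx$coords$e1e - 20, fx$coords$e1e)
  part2 <- substr(chrom, fx$coords$s2 + 1, fx$coords$s2 + 22)
  read50 <- paste0("G", part1, part2, "AAAAAA")
  hits <- align_reads(c(jr = read50), fx$genome, j, policy = pol)
  # verify the straddler is unique to the junction via the oracle
  refs <- c(list(chr1 = chrom), setNames(j$sequence, j$junction_id))
  ora <- oracle_align_one(trim_read(read50, pol), refs, pol)
  got_key <- paste(hits$target, hits$position, hits$strand, hits$mismatches)
  ora_key <- paste(ora$target, ora$position, ora$strand, ora$mismatches)
  expect_equal(length(got_key), length(ora_key))
  expect_setequal(got_key, ora_key)
  expect_true(all(hits$reference_kind == "junction"))
  expect_equal(hits[hits$mismatches == 0L]$position, 21L)  # 42 - 21
})

test_that("aligner equals the sliding-window oracle on random and repeat-laden reads", {
  set.seed(203)
  # repeat-laden reference: a repeated cassette plus random sequence
  cassette <- rand_seq(60)
  chrom1 <- paste0(rand_seq(4000), cassette, rand_seq(500), cassette,
                   rand_seq(400))
  chrom2 <- paste0(rand_seq(1500), substr(cassette, 1, 50), rand_seq(1000))
  g <- species_genome("sp", c(c1 = chrom1, c2 = chrom2))
  fx <- make_two_exon_fixture(seed = 204)
  jx <- build_junction_db(fx$transcripts, fx$genome)
  jx$species_label <- "sp"
  pol <- alignment_policy()
  index <- build_align_index(g, jx)
  refs <- c(list(c1 = chrom1, c2 = chrom2),
            setNames(jx$sequence, jx$junction_id))

  mk_reads <- function(n, src) {
    vapply(seq_len(n), function(i) {
      s <- src[[sample(length(src), 1)]]
      start <- sample(nchar(s) - 49, 1)
      r <- substr(s, start, start + 49)
      # sprinkle 0-4 errors anywhere
      k <- sample(0:4, 1)
      if (k > 0) for (p in sample(50, k)) {
        old <- substr(r, p, p)
        substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
      if (runif(1) < 0.5) r else oracle_revcomp(r)
    }, character(1))
  }
  reads <- c(mk_reads(60, list(chrom1, chrom2)),
             mk_reads(25, list(paste0(cassette, cassette, cassette))),
             vapply(1:15, function(i) rand_seq(50), character(1)))
  ids <- sprintf("r%03d", seq_along(reads))
  hits <- align_reads(data.frame(read_id = ids, sequence = reads),
                      policy = pol, index = index)
  n_mismatched <- 0L
  for (i in seq_along(reads)) {
    ora <- oracle_align_one(trim_read(reads[i], pol), refs, pol)
    got <- hits[hits$read_id == ids[i], ]
    got_key <- paste(got$target, got$position, got$strand, got$mismatches)
    ora_key <- paste(ora$target, ora$position, ora$strand, ora$mismatches)
    if (!setequal(got_key, ora_key) || length(got_key) != length(ora_key))
      n_mismatched <- n_mismatched + 1L
  }
  expect_equal(n_mismatched, 0L)
})

test_that("short trimmed reads fall back to the exhaustive scan", {
  set.seed(208)
  chrom <- rand_seq(1200)
  g <- species_genome("sp", c(chr1 = chrom))
  pol <- alignment_policy(min_read_length = 20L)
  # 25-base reads trim to 18 < 24, below the seeded path's minimum width
  reads <- vapply(1:10, function(i) {
    st <- sample(1100, 1)
    substr(chrom, st, st + 24)
  }, character(1))
  ids <- sprintf("s%02d", 1:10)
  hits <- align_reads(data.frame(read_id = ids, sequence = reads),
                      g, policy = pol)
  for (i in 1:10) {
    ora <- oracle_align_one(trim_read(reads[i], pol), list(chr1 = chrom), pol)
    got <- hits[hits$read_id == ids[i], ]
    expect_setequal(paste(got$target, got$position, got$strand,
                          got$mismatches),
                    paste(ora$target, ora$position, ora$strand,
                          ora$mismatches))
  }
})

test_that("reads with N beyond the budget fail to match", {
  set.seed(205)
  chrom <- rand_seq(800)
  g <- species_genome("sp", c(chr1 = chrom))
  pol <- alignment_policy()
  core <- substr(chrom, 101, 143)
  rn <- paste0("G", core, "AAAAAA")
  for (p in c(3, 9, 17, 30)) substr(rn, p + 1, p + 1) <- "N"  # 4 Ns
  hits <- align_reads(c(x = rn), g, policy = pol)
  expect_equal(nrow(hits), 0L)
})

test_that("alignment output is deterministic and byte-identical", {
  set.seed(206)
  chrom <- rand_seq(3000)
  g <- species_genome("sp", c(chr1 = chrom))
  reads <- data.frame(read_id = sprintf("r%d", 1:50),
                      sequence = vapply(1:50, function(i) {
                        st <- sample(2950, 1)
                        substr(chrom, st, st + 49)
                      }, character(1)))
  h1 <- align_reads(reads, g)
  h2 <- align_reads(reads, g)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
})

test_that("SAM round-trip: written hits read back identically", {
  set.seed(207)
  chrom <- rand_seq(1000)
  g <- species_genome("sp", c(chr1 = chrom))
  reads <- data.frame(read_id = c("a", "b"),
                      sequence = c(substr(chrom, 11, 60),
                                   substr(chrom, 501, 550)))
  index <- build_align_index(g)
  hits <- align_reads(reads, index = index)
  tf <- tempfile(fileext = ".sam")
  write_hits_sam(hits, index, tf)
  back <- read_sam_hits(tf, "sp")
  data.table::setorder(back, read_id)
  expect_equal(back$read_id, hits$read_id)
  expect_equal(back$position, hits$position)
  expect_equal(back$strand, hits$strand)
  expect_equal(back$mismatches, hits$mismatches)
  expect_equal(back$reference_kind, c("genome", "genome"))
})
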