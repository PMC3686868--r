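# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no Biostrings, no seed index, no data.table grouping): they
# are the reference against which the implementation is checked.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         vapply(s, function(x)
           paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""),
           character(1), USE.NAMES = FALSE))
}

# Exhaustive k-mer multiset mask: named list of 0/1 vectors per qualified
# chromosome. Windows containing N are marked 1 and excluded from counting.
oracle_kmer_mask <- function(genomes, k, both_strands = FALSE) {
  if (inherits(genomes, "species_genome")) genomes <- list(genomes)
  seqs <- list()
  for (g in genomes)
    for (nm in names(g$chromosomes))
      seqs[[paste(g$species_label, nm, sep = "|")]] <- g$chromosomes[[nm]]
  wins <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    st <- seq_len(n - k + 1L)
    substring(s, st, st + k - 1L)
  })
  all_k <- unlist(wins, use.names = FALSE)
  clean <- all_k[!grepl("N", all_k, fixed = TRUE)]
  tab <- table(clean)
  count_of <- function(w) {
    cnt <- tab[w]
    cnt[is.na(cnt)] <- 0L
    as.integer(cnt)
  }
  lapply(wins, function(w) {
    if (length(w) == 0L) return(integer(0))
    marked <- grepl("N", w, fixed = TRUE)
    idx <- which(!marked)
    if (length(idx)) {
      total <- count_of(w[idx])
      if (both_strands) total <- total + count_of(oracle_revcomp(w[idx]))
      marked[idx] <- total >= 2L
    }
    as.integer(marked)
  })
}

# Hamming distance profile of query against every offset of ref, N counted
# as mismatch. Returns integer vector over starts 1..(n-m+1).
hamming_profile <- function(query, ref) {
  m <- nchar(query)
  n <- nchar(ref)
  if (n < m) return(integer(0))
  n_off <- n - m + 1L
  mm <- integer(n_off)
  qc <- strsplit(query, "", fixed = TRUE)[[1L]]
  rc <- strsplit(ref, "", fixed = TRUE)[[1L]]
  for (j in seq_len(m)) {
    rj <- rc[j:(j + n_off - 1L)]
    mm <- mm + as.integer(rj != qc[j] | rj == "N" | qc[j] == "N")
  }
  mm
}

# Sliding-window alignment oracle: all loci on both strands of all refs
# where the trimmed query matches within the policy budgets. refs is a
# named character vector/list; kinds names which refs are junctions.
oracle_align_one <- function(trimmed, refs, policy) {
  m <- nchar(trimmed)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") trimmed else oracle_revcomp(trimmed)
    s <- min(policy$seed_length, m)
    seed_pos <- if (strand == "+") 1:s else (m - s + 1L):m
    for (nm in names(refs)) {
      mm <- hamming_profile(q, refs[[nm]])
      if (length(mm) == 0L) next
      # seed-only profile: mismatches restricted to seed positions
      seed_q <- substr(q, seed_pos[1L], seed_pos[length(seed_pos)])
      mm_seed_part <- hamming_profile(seed_q, refs[[nm]])
      # seed window within an alignment starting at offset i sits at
      # i + seed_pos[1] - 1 in the reference
      idx <- seq_along(mm) + seed_pos[1L] - 1L
      mm_seed <- mm_seed_part[idx]
      ok <- which(mm <= policy$total_mismatch_budget &
                    mm_seed <= policy$seed_mismatch_budget)
      if (length(ok))
        out[[length(out) + 1L]] <- data.frame(
          target = nm, position = ok - 1L, strand = strand,
          mismatches = mm[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(target = character(), position = integer(),
                  strand = character(), mismatches = integer())
}

# Faster exhaustive sliding-window oracle for larger batches (ACGT only).
# Total-mismatch profile at every offset is computed by tabulating, for each
# query position j, the reference positions carrying the query's j-th base
# (shifted to alignment starts); seed mismatches are then counted directly
# at the offsets within the total budget. Equivalent to oracle_align_one on
# N-free inputs.
oracle_prep_refs <- function(refs) {
  lapply(refs, function(s) {
    rc <- strsplit(s, "", fixed = TRUE)[[1L]]
    list(n = length(rc), seq = s,
         pos = lapply(c(A = "A", C = "C", G = "G", T = "T"),
                      function(b) which(rc == b)))
  })
}

oracle_align_fast <- function(trimmed, prep, policy) {
  m <- nchar(trimmed)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") trimmed else oracle_revcomp(trimmed)
    qc <- strsplit(q, "", fixed = TRUE)[[1L]]
    s <- min(policy$seed_length, m)
    seed_pos <- if (strand == "+") 1:s else (m - s + 1L):m
    for (nm in names(prep)) {
      p <- prep[[nm]]
      n_off <- p$n - m + 1L
      if (n_off < 1L) next
      offs <- unlist(lapply(seq_len(m), function(j)
        p$pos[[qc[j]]] - (j - 1L)), use.names = FALSE)
      offs <- offs[offs >= 1L & offs <= n_off]
      mm <- m - tabulate(offs, n_off)
      cand <- which(mm <= policy$total_mismatch_budget)
      if (!length(cand)) next
      keep <- vapply(cand, function(i) {
        tw <- substr(p$seq, i + seed_pos[1L] - 1L,
                     i + seed_pos[length(seed_pos)] - 1L)
        qw <- substr(q, seed_pos[1L], seed_pos[length(seed_pos)])
        sum(strsplit(tw, "", fixed = TRUE)[[1L]] !=
              strsplit(qw, "", fixed = TRUE)[[1L]]) <=
          policy$seed_mismatch_budget
      }, logical(1))
      cand <- cand[keep]
      if (length(cand))
        out[[length(out) + 1L]] <- data.frame(
          target = nm, position = cand - 1L, strand = strand,
          mismatches = mm[cand], stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(target = character(), position = integer(),
                  strand = character(), mismatches = integer())
}

# Independent set-logic repartition from per-species class vectors.
oracle_partition_classes <- function(class_a, class_b) {
  mapply(function(ca, cb) {
    mapped_a <- ca %in% c("unique", "multimapped")
    mapped_b <- cb %in% c("unique", "multimapped")
    if (mapped_a && mapped_b) "cross_species_discard"
    else if (ca == "unique") "unique_A"
    else if (cb == "unique") "unique_B"
    else if (ca == "multimapped" || cb == "multimapped") "multimapped_discard"
    else if (ca == "antisense_junction" || cb == "antisense_junction")
      "antisense_junction_discard"
    else "unmapped"
  }, class_a, class_b, USE.NAMES = FALSE)
}

# Minimum Hamming distance of a probe to any same-length substring of any
# transcript (both strands unless forward_only).
oracle_min_hamming <- function(probe, transcriptome, forward_only = FALSE) {
  best <- Inf
  queries <- if (forward_only) probe else c(probe, oracle_revcomp(probe))
  for (tx in transcriptome)
    for (q in queries) {
      mm <- hamming_profile(q, tx)
      if (length(mm)) best <- min(best, mm)
    }
  best
}

# Direct MCC on a 2x2 table (no boundary conventions).
oracle_mcc <- function(A, B, C, D) {
  (A * B - C * D) / sqrt((A + C) * (A + D) * (B + C) * (B + D))
}

# small two-exon genome fixture used by several files
make_two_exon_fixture <- function(seed = 42, exon_len = c(100L, 100L),
                                  intron_len = 60L, strand = "+",
                                  label = "spX") {
  set.seed(seed)
  lead <- rand_seq(30)
  e1 <- rand_seq(exon_len[1])
  intr <- rand_seq(intron_len)
  e2 <- rand_seq(exon_len[2])
  tailseq <- rand_seq(30)
  chrom <- paste0(lead, e1, intr, e2, tailseq)
  s1 <- 30L
  e1e <- s1 + exon_len[1]
  s2 <- e1e + intron_len
  e2e <- s2 + exon_len[2]
  genome <- species_genome(label, c(chr1 = chrom))
  exons <- data.table::data.table(
    transcript_id = "tx1", gene_id = "g1", chromosome = "chr1",
    strand = strand, start0 = c(s1, s2), end0 = c(e1e, e2e),
    biotype = "test")
  transcripts <- xenopartition:::transcript_set(exons, label)
  list(genome = genome, transcripts = transcripts,
       coords = list(s1 = s1, e1e = e1e, s2 = s2, e2e = e2e))
}
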