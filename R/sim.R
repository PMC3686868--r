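#' Configuration for the two-species simulator
#'
#' Defaults describe the xenograft setting the pipeline targets: two
#' genomes whose orthologous exons share ~85% nucleotide identity, a host
#' (species B) RNA fraction of 15% (within the ~8-17% range typical of
#' xenograft samples), 50-base reads, and log-normal per-transcript
#' expression rates.
#'
#' @param seed integer seed; every output is byte-reproducible under it.
#' @param n_genes genes per species.
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_length inclusive range of exon lengths (bases).
#' @param intron_length inclusive range of intron lengths.
#' @param intergenic_gap inclusive range of gaps between genes.
#' @param ortholog_fraction share of species-A genes with a species-B
#'   counterpart.
#' @param ortholog_identity per-base match probability between counterpart
#'   exons (default 0.85).
#' @param mixture_fraction_B fraction of reads drawn from species B
#'   (default 0.15).
#' @param n_reads total reads to simulate.
#' @param read_length read length in bases (default 50).
#' @param error_rate per-base sequencing substitution rate (default 0.005).
#' @param expr_meanlog,expr_sdlog log-normal parameters of per-transcript
#'   rates.
#' @param species_labels labels for the two species.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 40L, exons_per_gene = c(2L, 5L),
                       exon_length = c(120L, 300L),
                       intron_length = c(100L, 300L),
                       intergenic_gap = c(200L, 500L),
                       ortholog_fraction = 0.8, ortholog_identity = 0.85,
                       mixture_fraction_B = 0.15, n_reads = 20000L,
                       read_length = 50L, error_rate = 0.005,
                       expr_meanlog = 1, expr_sdlog = 1,
                       species_labels = c("speciesA", "speciesB")) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              intergenic_gap = as.integer(intergenic_gap),
              ortholog_fraction = ortholog_fraction,
              ortholog_identity = ortholog_identity,
              mixture_fraction_B = mixture_fraction_B,
              n_reads = as.integer(n_reads),
              read_length = as.integer(read_length),
              error_rate = error_rate,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              species_labels = species_labels)
  probs <- c(cfg$ortholog_fraction, cfg$ortholog_identity,
             cfg$mixture_fraction_B, cfg$error_rate)
  stopifnot(all(probs >= 0 & probs <= 1), cfg$n_genes >= 1L,
            cfg$n_reads >= 0L, cfg$read_length >= 1L,
            length(cfg$species_labels) == 2L,
            cfg$species_labels[1L] != cfg$species_labels[2L])
  structure(cfg, class = "sim_config")
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each base with probability p, uniformly among the other three
mutate_seq <- function(s, p) {
  if (p <= 0) return(s)
  b <- strsplit(s, "", fixed = TRUE)[[1L]]
  hit <- runif(length(b)) < p
  if (any(hit)) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    idx <- which(hit)
    b[idx] <- vapply(b[idx], function(x)
      sample(alt[[x]], 1L), character(1))
  }
  paste(b, collapse = "")
}

runif_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq(range[1L], range[2L]), n, replace = TRUE)
}

# lay out genes on one chromosome; ortholog rows reuse donor exon sequences
# (mutated at 1 - identity); returns chromosome string + exon table
build_chromosome <- function(cfg, prefix, donor_exons = NULL) {
  n <- cfg$n_genes
  pieces <- character(0)
  cursor <- 0L
  rows <- list()
  for (g in seq_len(n)) {
    gap <- runif_int(1L, cfg$intergenic_gap)
    pieces <- c(pieces, rand_bases(gap))
    cursor <- cursor + gap
    donor <- if (!is.null(donor_exons) && g <= length(donor_exons))
      donor_exons[[g]] else NULL
    n_ex <- if (!is.null(donor)) length(donor)
            else runif_int(1L, cfg$exons_per_gene)
    strand <- sample(c("+", "-"), 1L)
    for (e in seq_len(n_ex)) {
      if (e > 1L) {
        ilen <- runif_int(1L, cfg$intron_length)
        pieces <- c(pieces, rand_bases(ilen))
        cursor <- cursor + ilen
      }
      ex_seq <- if (!is.null(donor))
        mutate_seq(donor[[e]], 1 - cfg$ortholog_identity)
      else rand_bases(runif_int(1L, cfg$exon_length))
      elen <- nchar(ex_seq)
      pieces <- c(pieces, ex_seq)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = g, exon = e, start0 = cursor, end0 = cursor + elen,
        strand = strand, seq = ex_seq)
      cursor <- cursor + elen
    }
  }
  tail_gap <- runif_int(1L, cfg$intergenic_gap)
  pieces <- c(pieces, rand_bases(tail_gap))
  exons <- data.table::rbindlist(rows)
  exons[, `:=`(transcript_id = sprintf("%s_T%04d", prefix, gene),
               gene_id = sprintf("%s_G%04d", prefix, gene))]
  list(sequence = paste(pieces, collapse = ""), exons = exons)
}

#' Simulate a two-species genome pair with orthologous genes
#'
#' Species A genes are generated de novo (one transcript per gene, random
#' strand); for `ortholog_fraction` of them a species B counterpart is
#' created by substituting exon bases at rate `1 - ortholog_identity`
#' (intronic and intergenic sequence is drawn fresh — exon similarity is
#' what drives cross-species read ambiguity). Remaining species B genes are
#' de novo. Deterministic under `config$seed`.
#'
#' @param config `sim_config`.
#' @param out_dir optional directory; when given, FASTA, GTF and an ortholog
#'   map TSV are written there.
#' @return list: `genomes` (named list of two `species_genome`),
#'   `transcripts` (combined transcript table), `ortholog_map`
#'   (`data.table` of `gene_a`, `gene_b`).
#' @export
simulate_genome_pair <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  la <- config$species_labels[1L]
  lb <- config$species_labels[2L]

  a <- build_chromosome(config, prefix = la)
  n_orth <- round(config$ortholog_fraction * config$n_genes)
  donor <- if (n_orth > 0L)
    lapply(split(a$exons$seq, a$exons$gene)[as.character(seq_len(n_orth))],
           as.list)
  else NULL
  b <- build_chromosome(config, prefix = lb, donor_exons = donor)

  a$exons[, seq := NULL]
  b$exons[, seq := NULL]
  mk_tr <- function(ch, label) {
    ex <- data.table::copy(ch$exons)
    ex[, chromosome := "chr1"]
    transcript_set(ex[, list(transcript_id, gene_id, chromosome, strand,
                             start0, end0,
                             biotype = "protein_coding")], label)
  }
  tr_a <- mk_tr(a, la)
  tr_b <- mk_tr(b, lb)
  genomes <- list(
    species_genome(la, c(chr1 = a$sequence)),
    species_genome(lb, c(chr1 = b$sequence)))
  names(genomes) <- c(la, lb)
  orth <- data.table::data.table(
    gene_a = sprintf("%s_G%04d", la, seq_len(n_orth)),
    gene_b = sprintf("%s_G%04d", lb, seq_len(n_orth)))
  out <- list(genomes = genomes,
              transcripts = rbind(tr_a, tr_b),
              ortholog_map = orth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genome_fasta(genomes[[la]], file.path(out_dir,
                                                paste0(la, ".fa")))
    write_genome_fasta(genomes[[lb]], file.path(out_dir,
                                                paste0(lb, ".fa")))
    write_gtf(tr_a, file.path(out_dir, paste0(la, ".gtf")))
    write_gtf(tr_b, file.path(out_dir, paste0(lb, ".gtf")))
    write_tsv(orth, file.path(out_dir, "orthologs.tsv"))
  }
  out
}

# spliced (sense-strand) sequence of one transcript row
spliced_sequence <- function(transcript, genome) {
  s0 <- transcript$exon_starts[[1L]]
  e0 <- transcript$exon_ends[[1L]]
  chrom <- genome$chromosomes[[transcript$chromosome]]
  parts <- substring(chrom, s0 + 1L, e0)
  s <- paste(parts, collapse = "")
  if (transcript$strand == "-") revcomp(s) else s
}

#' Simulate truth-labelled mixed-species reads
#'
#' Per-transcript rates `lambda` are drawn log-normal; each read picks its
#' species by `mixture_fraction_B`, a transcript proportional to
#' `lambda * L`, a start uniform along the spliced transcript (so reads
#' straddle splice junctions), and suffers per-base substitution errors at
#' `error_rate`. Reads are emitted as the transcript's sense sequence
#' (strand-agnostic generation matching unstranded genome mapping).
#' Transcripts shorter than the read length are excluded with a warning.
#'
#' @param sim result of [simulate_genome_pair()].
#' @param config `sim_config`.
#' @return list: `reads` (`data.table` of `read_id`, `sequence`), `truth`
#'   (`read_id`, `species_label`, `transcript_id`, `offset` — 0-based
#'   spliced start), `expression` (`transcript_id`, `species_label`,
#'   `lambda`).
#' @export
simulate_reads <- function(sim, config = sim_config()) {
  set.seed(config$seed + 1L)
  tr <- sim$transcripts
  spliced <- vapply(seq_len(nrow(tr)), function(i)
    spliced_sequence(tr[i], sim$genomes[[tr$species_label[i]]]),
    character(1))
  lens <- nchar(spliced)
  lambda <- stats::rlnorm(nrow(tr), config$expr_meanlog, config$expr_sdlog)
  expression <- data.table::data.table(
    transcript_id = tr$transcript_id, species_label = tr$species_label,
    lambda = lambda, spliced_length = lens)
  usable <- lens >= config$read_length
  if (any(!usable))
    warning(sum(!usable), " transcript(s) shorter than the read length ",
            "excluded from read generation")

  la <- config$species_labels[1L]
  lb <- config$species_labels[2L]
  n <- config$n_reads
  is_b <- runif(n) < config$mixture_fraction_B
  pick <- integer(n)
  for (sp in c(la, lb)) {
    sel <- if (sp == lb) which(is_b) else which(!is_b)
    cand <- which(usable & tr$species_label == sp)
    if (length(sel) && length(cand) == 0L)
      stop("no usable transcripts for species ", sp)
    if (length(sel))
      pick[sel] <- sample(cand, length(sel), replace = TRUE,
                          prob = (lambda * lens)[cand])
  }
  offset <- integer(n)
  seqs <- character(n)
  if (n > 0L) {
    max_start <- lens[pick] - config$read_length
    offset <- floor(runif(n) * (max_start + 1L))
    seqs <- substring(spliced[pick], offset + 1L,
                      offset + config$read_length)
    if (config$error_rate > 0) {
      n_err <- rbinom(n, config$read_length, config$error_rate)
      for (i in which(n_err > 0L)) {
        b <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
        posn <- sample(config$read_length, n_err[i])
        alt <- c("A", "C", "G", "T")
        for (p in posn) b[p] <- sample(setdiff(alt, b[p]), 1L)
        seqs[i] <- paste(b, collapse = "")
      }
    }
  }
  ids <- sprintf("read_%06d", seq_len(n))
  list(
    reads = data.table::data.table(read_id = ids, sequence = seqs),
    truth = data.table::data.table(read_id = ids,
                                   species_label = tr$species_label[pick],
                                   transcript_id = tr$transcript_id[pick],
                                   offset = as.integer(offset)),
    expression = expression)
}

#' Evaluate a partition against simulation truth
#'
#' Precision and recall of the species-unique classes against the true
#' species of origin, plus the species-mixture estimation error.
#'
#' @param partition `partition_result`.
#' @param truth truth table from [simulate_reads()].
#' @return list with per-species `precision` and `recall` (named by species
#'   label; `NA` when undefined), `mixture_estimate`, `mixture_truth` and
#'   `mixture_error`.
#' @export
evaluate_partition <- function(partition, truth) {
  if (is.null(truth) || nrow(truth) == 0L) stop("missing truth labels")
  m <- merge(partition$classes, truth, by = "read_id")
  if (nrow(m) != nrow(partition$classes))
    stop("truth labels missing for ",
         nrow(partition$classes) - nrow(m), " read(s)")
  la <- partition$species_a
  lb <- partition$species_b
  pr <- function(pred_class, sp) {
    pred <- m$class == pred_class
    truth_sp <- m$species_label == sp
    precision <- if (sum(pred) == 0L) NA_real_
                 else sum(pred & truth_sp) / sum(pred)
    recall <- if (sum(truth_sp) == 0L) NA_real_
              else sum(pred & truth_sp) / sum(truth_sp)
    c(precision = precision, recall = recall)
  }
  a <- pr("unique_A", la)
  b <- pr("unique_B", lb)
  mix <- tryCatch(estimate_species_mix(partition)$fraction_B,
                  error = function(e) NA_real_)
  mix_truth <- mean(m$species_label == lb)
  list(precision = setNames(c(a["precision"], b["precision"]), c(la, lb)),
       recall = setNames(c(a["recall"], b["recall"]), c(la, lb)),
       mixture_estimate = mix, mixture_truth = mix_truth,
       mixture_error = if (is.na(mix)) NA_real_ else abs(mix - mix_truth))
}

#' Run the whole pipeline on one read set
#'
#' Convenience wrapper: align against both species (genome + junction
#' library), partition, and return the partition plus per-species
#' classifications.
#'
#' @param reads read table (`read_id`, `sequence`).
#' @param index_a,index_b prebuilt [build_align_index()] per species.
#' @param policy `alignment_policy`.
#' @return `partition_result`.
#' @export
align_and_partition <- function(reads, index_a, index_b,
                                policy = alignment_policy()) {
  hits_a <- align_reads(reads, policy = policy, index = index_a)
  hits_b <- align_reads(reads, policy = policy, index = index_b)
  too_short <- attr(hits_a, "too_short")
  kept <- setdiff(reads$read_id, too_short)
  cls_a <- classify_within_species(hits_a, kept)
  cls_b <- classify_within_species(hits_b, kept)
  partition_by_species(cls_a, cls_b,
                       species_a = index_a$species_label,
                       species_b = index_b$species_label,
                       too_short = too_short)
}
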