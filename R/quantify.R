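#' Count retained unique reads per transcript
#'
#' Intersect semantics: a genome hit increments N of every transcript whose
#' exon union overlaps the hit interval by at least one base (a read may
#' count towards several overlapping transcripts; no fractional assignment);
#' a junction hit increments N of every transcript containing that
#' junction's breakpoint between adjacent exons. T, the per-species total of
#' uniquely mappable reads, is attached as an attribute.
#'
#' @param hits unique retained hits for one species (e.g.
#'   `partition$unique_hits_a`).
#' @param transcripts transcript table for the same species.
#' @param junctions junction table the hits were aligned against (needed to
#'   resolve junction hits; may be `NULL` if there are none).
#' @return `data.table` (`transcript_id`, `gene_id`, `N`, `L`) covering all
#'   transcripts, with attribute `T_total`.
#' @export
count_reads_per_transcript <- function(hits, transcripts, junctions = NULL) {
  hits <- data.table::as.data.table(hits)
  counts <- data.table::data.table(transcript_id = transcripts$transcript_id,
                                   gene_id = transcripts$gene_id,
                                   L = transcripts$L, N = 0L)
  t_total <- length(unique(hits$read_id))

  gh <- hits[hits$reference_kind == "genome"]
  if (nrow(gh)) {
    ex <- exon_granges(transcripts)
    rd <- GenomicRanges::GRanges(
      gh$target, IRanges::IRanges(start = gh$position + 1L,
                                  width = gh$qwidth))
    ov <- GenomicRanges::findOverlaps(rd, ex, minoverlap = 1L)
    if (length(ov)) {
      # one increment per (read, transcript) even if several exons overlap
      inc <- unique(data.table::data.table(
        read = S4Vectors::queryHits(ov),
        transcript_id = ex$transcript_id[S4Vectors::subjectHits(ov)]))
      add <- inc[, list(n = .N), by = transcript_id]
      counts[add, N := N + n, on = "transcript_id"]
    }
  }

  jh <- hits[hits$reference_kind == "junction"]
  if (nrow(jh)) {
    if (is.null(junctions)) stop("junction hits present but no junction table")
    unknown <- setdiff(unique(jh$target), junctions$junction_id)
    if (length(unknown))
      stop("hit references unknown junction_id: ",
           paste(head(unknown, 3L), collapse = ", "))
    jmap <- junction_transcript_map(transcripts,
                                    junctions$species_label[1L])
    add <- merge(jh[, list(n_reads = .N), by = target],
                 jmap, by.x = "target", by.y = "junction_id",
                 allow.cartesian = TRUE)
    if (nrow(add)) {
      add <- add[, list(n = sum(n_reads)), by = transcript_id]
      counts[add, N := N + n, on = "transcript_id"]
    }
  }
  data.table::setattr(counts, "T_total", t_total)
  counts[]
}

# junction_id -> transcript_id membership: a transcript contains a junction
# iff it has an adjacent exon pair with matching breakpoint coordinates.
junction_transcript_map <- function(transcripts, species_label) {
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    s0 <- transcripts$exon_starts[[i]]
    e0 <- transcripts$exon_ends[[i]]
    n <- length(s0)
    if (n < 2L) next
    rows[[length(rows) + 1L]] <- data.table::data.table(
      junction_id = paste(species_label, transcripts$chromosome[i],
                          transcripts$strand[i], e0[-n], s0[-1L], sep = "|"),
      transcript_id = transcripts$transcript_id[i])
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L)
    out <- data.table::data.table(junction_id = character(),
                                  transcript_id = character())
  unique(out)
}

#' Mappability-adjusted RPKM
#'
#' `rpkm = N / (((L - U) / 1000) * (T / C)) + pseudocount`: reads per
#' kilobase of *mappable* transcript length per `C` (default one million)
#' uniquely mapped reads — standard RPKM with the transcript length
#' replaced by the effective mappable length `L - U` (exonic length minus
#' non-unique loci), plus a small constant so logs of undetected
#' transcripts are finite. Returns `NA` where `L - U <= 0` (no mappable
#' length; such transcripts are excluded downstream).
#'
#' @param N reads mapped to the transcript (vectorised).
#' @param L transcript exonic length in bases.
#' @param U non-unique loci within the transcript ([count_nonunique_loci()]).
#' @param T_total total uniquely mappable reads for the species/sample.
#' @param C scaling constant (default 1e6).
#' @param pseudocount constant added to the RPKM itself (default 0.001).
#' @return numeric vector of adjusted RPKM values.
#' @export
rpkm <- function(N, L, U = 0L, T_total, C = 1e6, pseudocount = 0.001) {
  if (any(T_total <= 0)) stop("no uniquely mappable reads (T = 0)")
  eff <- L - U
  out <- N / ((eff / 1000) * (T_total / C)) + pseudocount
  out[eff <= 0] <- NA_real_
  out
}

#' Full transcript-level quantification
#'
#' Combines read counting, the non-unique loci count U and the adjusted
#' RPKM into one table.
#'
#' @inheritParams count_reads_per_transcript
#' @param mask optional `uniqueome_mask`; without it U = 0 everywhere.
#' @param C,pseudocount passed to [rpkm()].
#' @return `data.table`: `transcript_id`, `gene_id`, `N`, `L`, `U`, `rpkm`;
#'   attribute `T_total`.
#' @export
transcript_quant <- function(hits, transcripts, junctions = NULL,
                             mask = NULL, C = 1e6, pseudocount = 0.001) {
  counts <- count_reads_per_transcript(hits, transcripts, junctions)
  t_total <- attr(counts, "T_total")
  u <- integer(nrow(counts))
  if (!is.null(mask)) {
    for (i in seq_len(nrow(counts))) {
      tr <- transcripts[transcripts$transcript_id == counts$transcript_id[i], ]
      u[i] <- count_nonunique_loci(mask, tr)
    }
  }
  counts[, U := u]
  counts[, rpkm := rpkm(N, L, U, t_total, C = C, pseudocount = pseudocount)]
  data.table::setattr(counts, "T_total", t_total)
  counts[]
}

#' Summarise transcript quantifications to gene level
#'
#' The transcript mapped by the highest number of reads represents its
#' parent gene (ties broken by lexicographically smallest transcript_id, so
#' output is deterministic); a gene is detected iff its representative has
#' at least `detection_threshold` reads (default 1).
#'
#' @param tq transcript quantification table ([transcript_quant()]).
#' @param detection_threshold minimum read count for a detection call.
#' @return `data.table`: `gene_id`, `representative_transcript_id`, `rpkm`,
#'   `read_count`, `detected`.
#' @export
gene_level <- function(tq, detection_threshold = 1L) {
  tq <- data.table::as.data.table(tq)
  if (!"rpkm" %in% names(tq)) tq$rpkm <- NA_real_
  data.table::setorder(tq, gene_id, -N, transcript_id)
  g <- tq[, list(representative_transcript_id = transcript_id[1L],
                 rpkm = rpkm[1L], read_count = N[1L]), by = gene_id]
  g[, detected := read_count >= detection_threshold]
  g[]
}

#' Estimate the species mixture from a partition
#'
#' The fraction of sample B (e.g. mouse host) RNA is estimated as the
#' proportion of retained reads mapping uniquely to species B.
#'
#' @param partition `partition_result`.
#' @return list: `fraction_A`, `fraction_B`, `n_unique_A`, `n_unique_B`.
#' @export
estimate_species_mix <- function(partition) {
  na <- as.integer(partition$counts[["unique_A"]])
  nb <- as.integer(partition$counts[["unique_B"]])
  if (na + nb == 0L) stop("no retained species-unique reads")
  list(fraction_A = na / (na + nb), fraction_B = nb / (na + nb),
       n_unique_A = na, n_unique_B = nb)
}

#' Export a five-column count table
#'
#' First column is the gene (or transcript) identifier, the remaining four
#' the integer read counts of the two control and two treated samples.
#'
#' @param counts data.frame: identifier column plus one integer count column
#'   per sample.
#' @param path output TSV.
#' @param sample_order column order for the four samples (default
#'   `Control_1, Control_2, Treated_1, Treated_2` when present).
#' @return `path`, invisibly.
#' @export
export_counts_table <- function(counts, path,
                                sample_order = NULL) {
  counts <- data.table::as.data.table(counts)
  id_col <- names(counts)[1L]
  samp <- setdiff(names(counts), id_col)
  if (is.null(sample_order)) {
    dflt <- c("Control_1", "Control_2", "Treated_1", "Treated_2")
    sample_order <- if (all(dflt %in% samp)) dflt else samp
  }
  stopifnot(all(sample_order %in% samp))
  vals <- as.matrix(counts[, sample_order, with = FALSE])
  if (any(vals != round(vals)))
    stop("non-integer counts in count table")
  out <- counts[, c(id_col, sample_order), with = FALSE]
  if (length(sample_order) != 4L)
    warning("count table has ", length(sample_order) + 1L,
            " columns (expected 5)")
  write_tsv(out, path)
  invisible(path)
}

#' Read back a count table written by [export_counts_table()]
#'
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_counts_table <- function(path) read_tsv(path)

#' Per-sample size factors
#'
#' Effective library sizes: each sample's library size divided by the
#' median library size over all samples. (This deliberately follows the
#' stated rule rather than the DESeq median-of-ratios default.)
#'
#' @param x either a numeric vector of library sizes or a count table whose
#'   first column is the identifier (library sizes are column sums).
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(x) {
  if (is.data.frame(x)) {
    libs <- vapply(x[, -1L, drop = FALSE], sum, numeric(1))
  } else {
    libs <- x
  }
  if (any(libs <= 0)) stop("zero or negative library size")
  libs / median(libs)
}
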