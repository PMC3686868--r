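#' Construct a species genome
#'
#' A genome is a set of named chromosome sequences tagged with a species
#' label. Sequences are uppercased and any character outside `{A,C,G,T}` is
#' folded to `N`. Masks and alignment indexes are built over this unit.
#'
#' @param species_label free-text species tag (e.g. `"human"`); must be
#'   unique within a workspace of genomes.
#' @param chromosomes named character vector of nucleotide sequences.
#' @return object of class `species_genome`.
#' @export
species_genome <- function(species_label, chromosomes) {
  stopifnot(is.character(species_label), length(species_label) == 1L,
            nzchar(species_label))
  if (length(chromosomes) == 0L)
    stop("genome '", species_label, "' has no chromosomes")
  nm <- names(chromosomes)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (any(nchar(chromosomes) == 0L))
    stop("empty chromosome sequence: ",
         paste(nm[nchar(chromosomes) == 0L], collapse = ", "))
  chromosomes <- setNames(normalize_seq(chromosomes), nm)
  structure(list(species_label = species_label, chromosomes = chromosomes),
            class = "species_genome")
}

#' @export
print.species_genome <- function(x, ...) {
  cat("species_genome:", x$species_label, "-", length(x$chromosomes),
      "chromosome(s),", sum(nchar(x$chromosomes)), "bases\n")
  invisible(x)
}

#' Read a genome from FASTA
#'
#' Record names are taken from the first whitespace-delimited token of the
#' header. Lowercase is folded to uppercase and non-ACGT characters to `N`.
#'
#' @param path FASTA file.
#' @param species_label species tag for the resulting genome.
#' @return `species_genome`.
#' @export
read_genome_fasta <- function(path, species_label) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  species_genome(species_label, setNames(as.character(ss), nm))
}

#' Write a genome (or any named sequence set) to FASTA
#'
#' @param x `species_genome`, or a named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(x, path) {
  seqs <- if (inherits(x, "species_genome")) x$chromosomes else x
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read transcript models from an Ensembl-dialect GTF
#'
#' Only `exon` features are used; they must carry `gene_id` and
#' `transcript_id` attributes. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention, and exons are
#' grouped per transcript and sorted by genomic coordinate.
#'
#' @param path GTF file.
#' @param species_label species tag attached to every transcript.
#' @return a `data.table` with one row per transcript: `transcript_id`,
#'   `gene_id`, `species_label`, `chromosome`, `strand`, `biotype`,
#'   list-columns `exon_starts`/`exon_ends` (0-based half-open, sorted), and
#'   exonic length `L`.
#' @export
read_gtf <- function(path, species_label) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid) || any(!nzchar(tid))) {
    bad <- if (is.null(tid)) seq_along(gr) else which(is.na(tid) | !nzchar(tid))
    stop("exon feature(s) missing transcript_id (exon record ",
         paste(head(bad, 5L), collapse = ", "), ")")
  }
  gid <- gr$gene_id
  if (is.null(gid)) gid <- rep(NA_character_, length(gr))
  bt <- gr$gene_biotype
  if (is.null(bt)) bt <- rep(NA_character_, length(gr))
  ex <- data.table::data.table(
    transcript_id = tid,
    gene_id = gid,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    biotype = bt
  )
  transcript_set(ex, species_label)
}

# Assemble a transcript table from a per-exon data.table with columns
# transcript_id, gene_id, chromosome, strand, start0, end0[, biotype].
transcript_set <- function(exons, species_label) {
  stopifnot(all(c("transcript_id", "gene_id", "chromosome", "strand",
                  "start0", "end0") %in% names(exons)))
  if (!"biotype" %in% names(exons)) exons$biotype <- NA_character_
  if (any(exons$start0 >= exons$end0))
    stop("exon with start >= end")
  data.table::setorder(exons, transcript_id, start0)
  tr <- exons[, {
    if (.N > 1L && any(start0[-1L] < end0[-.N]))
      stop("overlapping exons within transcript ", transcript_id[1L])
    list(gene_id = gene_id[1L], chromosome = chromosome[1L],
         strand = strand[1L], biotype = biotype[1L],
         exon_starts = list(start0), exon_ends = list(end0),
         L = sum(end0 - start0))
  }, by = transcript_id]
  tr[, species_label := species_label]
  data.table::setcolorder(tr, c("transcript_id", "gene_id", "species_label",
                                "chromosome", "strand", "biotype"))
  tr[]
}

#' Write transcript models as an Ensembl-dialect GTF
#'
#' Emits one `exon` feature line per exon with `gene_id` and `transcript_id`
#' attributes, converting internal 0-based half-open coordinates back to GTF
#' 1-based inclusive.
#'
#' @param transcripts transcript table as returned by [read_gtf()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- character(0)
  for (i in seq_len(nrow(transcripts))) {
    s0 <- transcripts$exon_starts[[i]]
    e0 <- transcripts$exon_ends[[i]]
    bt <- transcripts$biotype[i]
    attr_str <- sprintf(
      'gene_id "%s"; transcript_id "%s";%s',
      transcripts$gene_id[i], transcripts$transcript_id[i],
      if (is.na(bt)) "" else sprintf(' gene_biotype "%s";', bt))
    lines <- c(lines, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                              transcripts$chromosome[i], s0 + 1L, e0,
                              transcripts$strand[i], attr_str))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build the splice-junction library from an annotation
#'
#' One record per distinct genomic breakpoint
#' `(species, chromosome, strand, donor_end, acceptor_start)` over all
#' adjacent exon pairs of all transcripts — junctions shared between
#' transcripts appear once. The sequence is the last `flank` bases of the
#' upstream exon joined to the first `flank` bases of the downstream exon
#' (whole exon if shorter than `flank`), emitted in transcription
#' orientation: minus-strand junctions are reverse-complemented.
#'
#' The default `flank = 42` is the effective read length minus one for
#' 43-base effective reads, so any read overlapping the breakpoint by at
#' least one base on each side can align.
#'
#' @param transcripts transcript table (see [read_gtf()]).
#' @param genome `species_genome` containing every referenced chromosome.
#' @param flank maximum bases taken from each side of the breakpoint.
#' @return `data.table` with one row per junction: `junction_id`,
#'   `species_label`, `chromosome`, `strand`, `donor_end`, `acceptor_start`,
#'   slice coordinates and `sequence`.
#' @export
build_junction_db <- function(transcripts, genome, flank = 42L) {
  if (!is.numeric(flank) || flank < 1L) stop("flank must be >= 1")
  flank <- as.integer(flank)
  missing_chr <- setdiff(unique(transcripts$chromosome),
                         names(genome$chromosomes))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  recs <- vector("list", nrow(transcripts))
  for (i in seq_len(nrow(transcripts))) {
    s0 <- transcripts$exon_starts[[i]]
    e0 <- transcripts$exon_ends[[i]]
    n <- length(s0)
    if (n < 2L) next
    recs[[i]] <- data.table::data.table(
      chromosome = transcripts$chromosome[i],
      strand = transcripts$strand[i],
      donor_end = e0[-n],            # half-open end of upstream exon
      acceptor_start = s0[-1L],      # start of downstream exon
      up_len = e0[-n] - s0[-n],
      down_len = e0[-1L] - s0[-1L]
    )
  }
  recs <- data.table::rbindlist(recs)
  if (nrow(recs) == 0L) {
    return(data.table::data.table(
      junction_id = character(), species_label = character(),
      chromosome = character(), strand = character(),
      donor_end = integer(), acceptor_start = integer(),
      donor_start = integer(), acceptor_end = integer(),
      sequence = character()))
  }
  # non-redundancy key: the genomic breakpoint (widest flank wins when
  # transcripts disagree on exon extent, which cannot happen for the same
  # breakpoint coordinates except via exon length -> take max)
  recs <- recs[, list(up_len = max(up_len), down_len = max(down_len)),
               by = list(chromosome, strand, donor_end, acceptor_start)]
  f1 <- pmin(flank, recs$up_len)
  f2 <- pmin(flank, recs$down_len)
  recs[, `:=`(donor_start = donor_end - f1, acceptor_end = acceptor_start + f2)]
  lens <- nchar(genome$chromosomes)[recs$chromosome]
  if (any(recs$donor_start < 0L) || any(recs$acceptor_end > lens)) {
    bad <- which(recs$donor_start < 0L | recs$acceptor_end > lens)[1L]
    stop("junction slice outside chromosome bounds at ",
         recs$chromosome[bad], ":", recs$donor_end[bad], "-",
         recs$acceptor_start[bad])
  }
  chrom_seq <- genome$chromosomes[recs$chromosome]
  donor <- substring(chrom_seq, recs$donor_start + 1L, recs$donor_end)
  acceptor <- substring(chrom_seq, recs$acceptor_start + 1L, recs$acceptor_end)
  seq_plus <- paste0(donor, acceptor)
  seq_out <- ifelse(recs$strand == "-", revcomp(seq_plus), seq_plus)
  recs[, `:=`(
    species_label = genome$species_label,
    junction_id = paste(genome$species_label, chromosome, strand,
                        donor_end, acceptor_start, sep = "|"),
    sequence = seq_out
  )]
  stopifnot(!anyDuplicated(recs$junction_id))
  data.table::setcolorder(recs, c("junction_id", "species_label",
                                  "chromosome", "strand", "donor_end",
                                  "acceptor_start", "donor_start",
                                  "acceptor_end", "sequence"))
  recs[]
}

#' Write a junction library to FASTA
#'
#' Record headers are the deterministic `junction_id`s.
#'
#' @param junctions table from [build_junction_db()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_junction_fasta <- function(junctions, path) {
  write_genome_fasta(setNames(junctions$sequence, junctions$junction_id), path)
}

#' Export junction breakpoints as BED6
#'
#' Rows are `(chrom, donor_end - 1, acceptor_start, junction_id, 0, strand)`:
#' the two exonic bases flanking the intron in half-open coordinates.
#'
#' @param junctions table from [build_junction_db()].
#' @param path optional output file; if `NULL`, the BED table is returned.
#' @return `data.table` of BED6 fields (invisibly if written to file).
#' @export
junction_bed <- function(junctions, path = NULL) {
  bed <- data.table::data.table(
    chrom = junctions$chromosome,
    start = junctions$donor_end - 1L,
    end = junctions$acceptor_start,
    name = junctions$junction_id,
    score = 0L,
    strand = junctions$strand
  )
  if (!is.null(path)) {
    data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
    return(invisible(bed))
  }
  bed
}
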