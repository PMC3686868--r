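#' Build the non-unique k-mer mask over a set of genomes
#'
#' For every window start position on every chromosome of every genome, the
#' k-mer beginning there is looked up in the multiset of all k-mers of the
#' concatenated genome collection; positions whose k-mer occurs at two or
#' more start positions anywhere (any chromosome, any species) are marked 1
#' (non-unique), all others 0. Reads cannot map uniquely at marked loci, so
#' the mask feeds the mappability correction of the adjusted RPKM.
#'
#' Windows containing `N` are marked 1: reads are never mapped across `N`,
#' so such loci cannot contribute uniquely mapped reads. Only plus-strand
#' k-mers are compared by default; with `both_strands = TRUE` a k-mer is
#' also non-unique when its reverse complement occurs anywhere (a
#' palindromic k-mer then marks itself).
#'
#' @param genomes a `species_genome` or list of them; species labels must be
#'   unique.
#' @param k window length in bases (default 50).
#' @param both_strands also match reverse complements (default `FALSE`).
#' @return object of class `uniqueome_mask`: `k`, `both_strands`, `species`
#'   (qualified chromosome name `species|chrom` -> species label),
#'   `chrom_lengths`, and `masks` — a named list of integer 0/1 vectors of
#'   length `max(0, chrom_length - k + 1)` per qualified chromosome.
#' @export
build_uniqueome <- function(genomes, k = 50L, both_strands = FALSE) {
  if (inherits(genomes, "species_genome")) genomes <- list(genomes)
  stopifnot(length(genomes) >= 1L, is.numeric(k), k >= 1L)
  k <- as.integer(k)
  labels <- vapply(genomes, function(g) g$species_label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate species labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))

  chroms <- list()   # qualified name -> sequence
  species <- character(0)
  for (g in genomes) {
    qn <- paste(g$species_label, names(g$chromosomes), sep = "|")
    chroms[qn] <- as.list(unname(g$chromosomes))
    species[qn] <- g$species_label
  }
  chrom_lengths <- vapply(chroms, nchar, integer(1))
  if (all(chrom_lengths < k))
    warning("k = ", k, " exceeds every chromosome length; mask is empty")

  # k-mer multiset over all chromosomes; N windows excluded from matching
  # (they are marked non-unique by policy regardless)
  win <- lapply(chroms, substr_windows, k = k)
  all_kmers <- unlist(win, use.names = FALSE)
  has_n <- grepl("N", all_kmers, fixed = TRUE)
  counts <- data.table::data.table(gram = all_kmers[!has_n])[
    , list(n = .N), by = gram]
  if (isTRUE(both_strands)) {
    rc <- data.table::data.table(gram = revcomp(counts$gram), n_rc = counts$n)
    rc <- rc[, list(n_rc = sum(n_rc)), by = gram]
    counts <- merge(counts, rc, by = "gram", all.x = TRUE)
    counts[is.na(counts$n_rc), "n_rc"] <- 0L
    counts$n <- counts$n + counts$n_rc
  }
  dup_kmers <- counts$gram[counts$n >= 2L]

  masks <- lapply(win, function(w) {
    if (length(w) == 0L) return(integer(0))
    nw <- grepl("N", w, fixed = TRUE)
    marked <- nw
    idx <- which(!nw)
    if (length(idx))
      marked[idx] <- data.table::`%chin%`(w[idx], dup_kmers)
    as.integer(marked)
  })
  structure(list(k = k, both_strands = isTRUE(both_strands),
                 species = species, chrom_lengths = chrom_lengths,
                 masks = masks),
            class = "uniqueome_mask")
}

#' @export
print.uniqueome_mask <- function(x, ...) {
  nw <- sum(lengths(x$masks))
  nm <- sum(vapply(x$masks, sum, numeric(1)))
  cat("uniqueome_mask: k =", x$k, "-", length(x$masks), "chromosome(s),",
      nw, "windows,", nm, "marked non-unique\n")
  invisible(x)
}

#' Count non-unique loci within a transcript (U)
#'
#' U is the number of marked window starts whose whole k-mer window lies
#' inside one of the transcript's exon-union intervals — the same support
#' as the exonic length L, so the adjusted RPKM denominator L - U is
#' well-defined and `0 <= U <= L`. With `span = TRUE` the genomic span
#' (introns included) is used instead.
#'
#' @param mask `uniqueome_mask`.
#' @param transcript one-row transcript table (see [read_gtf()]).
#' @param span count over the genomic span rather than the exon union.
#' @return integer U with `0 <= U <= L` (exon-union mode).
#' @export
count_nonunique_loci <- function(mask, transcript, span = FALSE) {
  stopifnot(inherits(mask, "uniqueome_mask"), nrow(transcript) == 1L)
  qn <- paste(transcript$species_label, transcript$chromosome, sep = "|")
  if (!qn %in% names(mask$masks))
    stop("chromosome absent from mask: ", qn)
  m <- mask$masks[[qn]]
  s0 <- transcript$exon_starts[[1L]]
  e0 <- transcript$exon_ends[[1L]]
  if (isTRUE(span)) {
    s0 <- min(s0)
    e0 <- max(e0)
  }
  u <- 0L
  for (i in seq_along(s0)) {
    lo <- s0[i] + 1L                        # mask index of window start s0[i]
    hi <- min(e0[i] - mask$k + 1L, length(m))  # window must fit in the exon
    if (hi >= lo) u <- u + sum(m[lo:hi])
  }
  u
}

#' Fraction of non-unique loci per species
#'
#' @param mask `uniqueome_mask`.
#' @return list with `per_species` (named numeric, marked / window starts)
#'   and `overall`.
#' @export
genome_nonunique_fraction <- function(mask) {
  stopifnot(inherits(mask, "uniqueome_mask"))
  nw <- lengths(mask$masks)
  if (sum(nw) == 0L) stop("empty mask (no windows)")
  nm <- vapply(mask$masks, sum, numeric(1))
  sp <- mask$species[names(mask$masks)]
  per <- vapply(split(seq_along(nw), sp), function(i)
    sum(nm[i]) / sum(nw[i]), numeric(1))
  list(per_species = per, overall = sum(nm) / sum(nw))
}

#' Serialise a mask as run-length BED plus a JSON sidecar
#'
#' Marked windows are written as half-open intervals of window starts
#' (chrom = qualified `species|chrom` name); `<path>.json` records `k`,
#' strand mode, species map and chromosome lengths so the mask is
#' reconstructable and inspectable with standard tools.
#'
#' @param mask `uniqueome_mask`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_uniqueome_bed <- function(mask, path) {
  rows <- list()
  for (qn in names(mask$masks)) {
    m <- mask$masks[[qn]]
    if (length(m) == 0L || sum(m) == 0L) next
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values == 1L
    rows[[qn]] <- data.table::data.table(chrom = qn, start = starts[keep],
                                         end = ends[keep])
  }
  bed <- data.table::rbindlist(rows)
  if (nrow(bed) == 0L)
    bed <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer())
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  jsonlite::write_json(
    list(k = mask$k, both_strands = mask$both_strands,
         species = as.list(mask$species),
         chrom_lengths = as.list(mask$chrom_lengths)),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a mask serialised by [write_uniqueome_bed()]
#'
#' @param path BED path (sidecar `<path>.json` must exist).
#' @return `uniqueome_mask`.
#' @export
read_uniqueome_bed <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"))
  chrom_lengths <- unlist(side$chrom_lengths)
  k <- as.integer(side$k)
  masks <- lapply(chrom_lengths, function(n) integer(max(0L, n - k + 1L)))
  bed <- tryCatch(
    data.table::fread(path, sep = "\t",
                      col.names = c("chrom", "start", "end")),
    error = function(e) NULL)
  if (!is.null(bed) && nrow(bed)) {
    for (i in seq_len(nrow(bed))) {
      qn <- bed$chrom[i]
      masks[[qn]][(bed$start[i] + 1L):bed$end[i]] <- 1L
    }
  }
  structure(list(k = k, both_strands = isTRUE(side$both_strands),
                 species = unlist(side$species),
                 chrom_lengths = chrom_lengths, masks = masks),
            class = "uniqueome_mask")
}
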