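#' Alignment policy
#'
#' The mapping policy: reads lose their first and last base and five 3'-end
#' bases (50-base reads become 43-base effective reads), at most
#' `seed_mismatch_budget` mismatches are allowed in the first `seed_length`
#' bases of the trimmed read, and at most `total_mismatch_budget` mismatches
#' overall. The seed is anchored at the 5' end of the read as sequenced, so
#' on the minus strand it sits at the 3' end of the reverse-complemented
#' query.
#'
#' @param seed_length seed window length (default 25).
#' @param seed_mismatch_budget max mismatches within the seed (default 2).
#' @param trim_first,trim_last,trim_3prime bases removed from the read
#'   (defaults 1, 1, 5).
#' @param total_mismatch_budget max mismatches over the whole trimmed read
#'   (default 3).
#' @param min_read_length reads shorter than this are routed to unmapped
#'   with reason `too_short` (default 30).
#' @return object of class `alignment_policy`.
#' @export
alignment_policy <- function(seed_length = 25L, seed_mismatch_budget = 2L,
                             trim_first = 1L, trim_last = 1L,
                             trim_3prime = 5L, total_mismatch_budget = 3L,
                             min_read_length = 30L) {
  p <- list(seed_length = as.integer(seed_length),
            seed_mismatch_budget = as.integer(seed_mismatch_budget),
            trim_first = as.integer(trim_first),
            trim_last = as.integer(trim_last),
            trim_3prime = as.integer(trim_3prime),
            total_mismatch_budget = as.integer(total_mismatch_budget),
            min_read_length = as.integer(min_read_length),
            report_unique_only = TRUE)
  stopifnot(p$seed_length >= 1L, p$seed_mismatch_budget >= 0L,
            p$trim_first >= 0L, p$trim_last >= 0L, p$trim_3prime >= 0L,
            p$total_mismatch_budget >= 0L)
  structure(p, class = "alignment_policy")
}

#' Trim reads to their effective sequence
#'
#' Removes `trim_first` leading bases, then `trim_last + trim_3prime`
#' trailing bases; a 50-base read under the default policy yields a 43-base
#' effective sequence. Reads too short to trim return `NA` (callers route
#' them to the unmapped class with reason `too_short`).
#'
#' @param sequence character vector of read sequences.
#' @param policy `alignment_policy`.
#' @return character vector of trimmed sequences (`NA` where too short).
#' @export
trim_read <- function(sequence, policy = alignment_policy()) {
  n <- nchar(sequence)
  lost <- policy$trim_first + policy$trim_last + policy$trim_3prime
  out <- ifelse(n > lost,
                substr(sequence, policy$trim_first + 1L,
                       n - policy$trim_last - policy$trim_3prime),
                NA_character_)
  out[n < policy$min_read_length] <- NA_character_
  out
}

#' Build a seed index over a genome plus junction library
#'
#' Every 8-mer of every reference sequence is recorded with its position.
#' Lookups split the 25-base seed into three disjoint 8-mers: with at most
#' two seed mismatches at least one part matches exactly (pigeonhole), so
#' candidate verification is fully sensitive within the policy budgets.
#'
#' @param genome `species_genome`.
#' @param junctions optional junction table from [build_junction_db()].
#' @param q seed part length (default 8; change only with cause).
#' @return object of class `align_index`.
#' @export
build_align_index <- function(genome, junctions = NULL, q = 8L) {
  stopifnot(inherits(genome, "species_genome"))
  q <- as.integer(q)
  refs <- list()
  kinds <- character(0)
  for (nm in names(genome$chromosomes)) {
    refs[[nm]] <- genome$chromosomes[[nm]]
    kinds[nm] <- "genome"
  }
  if (!is.null(junctions) && nrow(junctions)) {
    if (anyDuplicated(junctions$junction_id))
      stop("duplicate junction_ids")
    for (i in seq_len(nrow(junctions))) {
      refs[[junctions$junction_id[i]]] <- junctions$sequence[i]
      kinds[junctions$junction_id[i]] <- "junction"
    }
  }
  if (length(refs) == 0L) stop("empty index")
  tabs <- lapply(names(refs), function(nm) {
    w <- substr_windows(refs[[nm]], q)
    if (length(w) == 0L) return(NULL)
    keep <- !grepl("N", w, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(gram = w[keep], target = nm,
                           pos = which(keep))   # 1-based
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, gram)
  structure(list(species_label = genome$species_label, q = q,
                 refs = refs, kinds = kinds,
                 ref_lengths = vapply(refs, nchar, integer(1)),
                 grams = idx),
            class = "align_index")
}

# Seed-region query positions for one orientation.
# Plus strand: seed occupies query positions 1..s (5' end of the read).
# Minus strand: query is the reverse complement, so the read's 5' seed sits
# at the last s query positions.
seed_positions <- function(width, seed_length, strand) {
  s <- min(seed_length, width)
  if (strand == "+") seq_len(s) else (width - s + 1L):width
}

# Fully sensitive scan of queries of one width against all references:
# every offset, one strand (queries already oriented). Used as fallback for
# short queries; the main path is the seed index.
scan_all_offsets <- function(queries, read_ids, index, policy, strand) {
  width <- nchar(queries[1L])
  out <- list()
  for (nm in names(index$refs)) {
    rl <- index$ref_lengths[[nm]]
    if (rl < width) next
    starts <- seq_len(rl - width + 1L)
    tw <- substring(index$refs[[nm]], starts, starts + width - 1L)
    sp <- seed_positions(width, policy$seed_length, strand)
    for (i in seq_along(queries)) {
      mm <- string_mismatches(rep(queries[i], length(tw)), tw, width)
      mm_seed <- string_mismatches(rep(queries[i], length(tw)), tw, width, sp)
      ok <- which(mm <= policy$total_mismatch_budget &
                    mm_seed <= policy$seed_mismatch_budget)
      if (length(ok))
        out[[length(out) + 1L]] <- data.table::data.table(
          read_id = read_ids[i], target = nm, position = ok - 1L,
          strand = strand, mismatches = mm[ok], qwidth = width)
    }
  }
  data.table::rbindlist(out)
}

# Seed-and-verify for queries of a single width (>= 24 + needed), one strand.
seed_hits_one_width <- function(queries, read_ids, index, policy, strand) {
  width <- nchar(queries[1L])
  q <- index$q
  sp <- seed_positions(width, policy$seed_length, strand)
  # three disjoint q-grams inside the first 3q bases of the seed region
  part_off <- sp[1L] + q * (0:2)
  cand <- list()
  for (po in part_off) {
    g <- substr(queries, po, po + q - 1L)
    dt <- data.table::data.table(gram = g, read_idx = seq_along(queries),
                                 qstart = po)
    hit <- index$grams[dt, on = "gram", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hit))
      cand[[length(cand) + 1L]] <- hit[, list(
        read_idx, target, start = pos - qstart + 1L)]
  }
  cand <- data.table::rbindlist(cand)
  if (nrow(cand) == 0L) return(data.table::data.table())
  cand <- unique(cand)
  cand <- cand[start >= 1L &
                 start + width - 1L <= index$ref_lengths[target]]
  if (nrow(cand) == 0L) return(data.table::data.table())
  # verify candidates: mismatch counts with N counted as mismatch
  qs <- queries[cand$read_idx]
  chrom_seq <- unlist(index$refs[cand$target], use.names = FALSE)
  ts <- substring(chrom_seq, cand$start, cand$start + width - 1L)
  mm <- string_mismatches(qs, ts, width)
  mm_seed <- string_mismatches(qs, ts, width, sp)
  keep <- mm <= policy$total_mismatch_budget &
    mm_seed <= policy$seed_mismatch_budget
  if (!any(keep)) return(data.table::data.table())
  data.table::data.table(read_id = read_ids[cand$read_idx[keep]],
                         target = cand$target[keep],
                         position = cand$start[keep] - 1L,
                         strand = strand,
                         mismatches = mm[keep],
                         qwidth = width)
}

#' Align reads against one species' genome + junction index
#'
#' Reports all loci, on both strands, where the trimmed read matches with at
#' most `seed_mismatch_budget` mismatches in its seed and
#' `total_mismatch_budget` mismatches overall ("try hard": exhaustive within
#' budget, fully sensitive on desk-scale references). `N` in read or
#' reference never matches.
#'
#' @param reads data.frame with columns `read_id`, `sequence` (or a named
#'   character vector).
#' @param genome `species_genome` (ignored when `index` is given).
#' @param junctions optional junction table (ignored when `index` is given).
#' @param policy `alignment_policy`.
#' @param index optional prebuilt [build_align_index()] result.
#' @return `data.table` of hits: `read_id`, `reference_kind`,
#'   `species_label`, `target`, `position` (0-based), `strand`,
#'   `mismatches`, `qwidth`; attribute `too_short` lists reads dropped
#'   before alignment.
#' @export
align_reads <- function(reads, genome = NULL, junctions = NULL,
                        policy = alignment_policy(), index = NULL) {
  if (is.character(reads))
    reads <- data.table::data.table(read_id = names(reads),
                                    sequence = unname(reads))
  reads <- data.table::as.data.table(reads)
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  if (anyDuplicated(reads$read_id))
    stop("duplicate read_ids")
  if (is.null(index)) index <- build_align_index(genome, junctions)

  trimmed <- trim_read(normalize_seq(reads$sequence), policy)
  too_short <- reads$read_id[is.na(trimmed)]
  ok <- !is.na(trimmed)
  ids <- reads$read_id[ok]
  trimmed <- trimmed[ok]

  hits <- list()
  if (length(trimmed)) {
    widths <- nchar(trimmed)
    for (w in unique(widths)) {
      sel <- widths == w
      qs_plus <- trimmed[sel]
      qs_minus <- revcomp(qs_plus)
      # pigeonhole over three disjoint q-grams needs the seed region to
      # hold all three parts and the seed budget to leave one part clean
      seeded_ok <- policy$seed_mismatch_budget <= 2L &&
        min(policy$seed_length, w) >= 3L * index$q
      if (seeded_ok) {
        hits[[length(hits) + 1L]] <-
          seed_hits_one_width(qs_plus, ids[sel], index, policy, "+")
        hits[[length(hits) + 1L]] <-
          seed_hits_one_width(qs_minus, ids[sel], index, policy, "-")
      } else {
        hits[[length(hits) + 1L]] <-
          scan_all_offsets(qs_plus, ids[sel], index, policy, "+")
        hits[[length(hits) + 1L]] <-
          scan_all_offsets(qs_minus, ids[sel], index, policy, "-")
      }
    }
  }
  hits <- data.table::rbindlist(hits[lengths(lapply(hits, names)) > 0])
  if (nrow(hits) == 0L)
    hits <- data.table::data.table(read_id = character(), target = character(),
                                   position = integer(), strand = character(),
                                   mismatches = integer(), qwidth = integer())
  hits[, `:=`(reference_kind = unname(index$kinds[target]),
              species_label = index$species_label)]
  data.table::setcolorder(hits, c("read_id", "reference_kind",
                                  "species_label", "target", "position",
                                  "strand", "mismatches", "qwidth"))
  data.table::setorder(hits, read_id, target, position, strand)
  data.table::setattr(hits, "too_short", too_short)
  hits[]
}

#' Ingest alignment hits from a SAM file
#'
#' Alternative hit source for real data: records with mapping quality > 0
#' are converted to the internal hit table (secondary-alignment records are
#' kept as additional hits for their read). The internal aligner remains the
#' reference implementation.
#'
#' @param path SAM file.
#' @param species_label species the alignments belong to.
#' @param junction_ids reference names to classify as junction hits.
#' @return hit `data.table` as from [align_reads()].
#' @export
read_sam_hits <- function(path, species_label, junction_ids = character(0)) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq", "qwidth"),
    tag = "NM")
  b <- Rsamtools::scanBam(bam, param = prm)[[1L]]
  keep <- !is.na(b$pos) & (is.na(b$mapq) | b$mapq > 0L)
  nm <- b$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(b$pos))
  hits <- data.table::data.table(
    read_id = b$qname[keep],
    target = as.character(b$rname[keep]),
    position = b$pos[keep] - 1L,
    strand = as.character(b$strand[keep]),
    mismatches = nm[keep],
    qwidth = b$qwidth[keep])
  hits[, `:=`(reference_kind = ifelse(target %in% junction_ids,
                                      "junction", "genome"),
              species_label = species_label)]
  data.table::setcolorder(hits, c("read_id", "reference_kind",
                                  "species_label", "target", "position",
                                  "strand", "mismatches", "qwidth"))
  hits[]
}

#' Write retained hits as SAM
#'
#' Minimal SAM export (one `@SQ` line per reference of the species' genome +
#' junction library); sequence and quality columns are `*`.
#'
#' @param hits hit table.
#' @param index the `align_index` the hits were produced against.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_sam <- function(hits, index, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(index$ref_lengths),
                   index$ref_lengths))
  flag <- ifelse(hits$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                  hits$read_id, flag, hits$target, hits$position + 1L,
                  hits$qwidth, hits$mismatches)
  writeLines(c(hdr, body), path)
  invisible(path)
}
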