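#' Classify each read's hits within one species
#'
#' Order of operations: junction hits on the minus strand of the junction
#' sequence are removed first (antisense hits are treated as false
#' positives), then the surviving hit count decides the class: exactly one
#' hit is `unique`, two or more (including a genome hit plus a junction hit,
#' the pseudogene-versus-splice-junction ambiguity) is `multimapped`. A read
#' whose only hits were antisense junction hits is `antisense_junction`;
#' reads with no hits are `unmapped`. Genome minus-strand hits are kept: the
#' library is unstranded at the genome level.
#'
#' @param hits hit table for one species (from [align_reads()] or
#'   [read_sam_hits()]).
#' @param read_ids all read ids of the run (so unmapped reads are classed).
#' @return list: `classes` (`data.table` of `read_id`, `class`) and
#'   `unique_hits` (the single surviving hit per `unique` read).
#' @export
classify_within_species <- function(hits, read_ids) {
  stopifnot(!anyDuplicated(read_ids))
  hits <- data.table::as.data.table(hits)
  antisense <- hits$reference_kind == "junction" & hits$strand == "-"
  surv <- hits[!antisense]
  n_surv <- surv[, list(n_hits = .N), by = read_id]
  had_hits <- unique(hits$read_id)

  cls <- data.table::data.table(read_id = read_ids, class = "unmapped")
  if (length(had_hits))
    cls[read_id %in% had_hits, class := "antisense_junction"]
  if (nrow(n_surv)) {
    uni <- n_surv$read_id[n_surv$n_hits == 1L]
    mult <- n_surv$read_id[n_surv$n_hits >= 2L]
    if (length(uni)) cls[read_id %in% uni, class := "unique"]
    if (length(mult)) cls[read_id %in% mult, class := "multimapped"]
  }
  unique_hits <- surv[read_id %in% cls$read_id[cls$class == "unique"]]
  list(classes = cls, unique_hits = unique_hits)
}

#' Partition reads between two species
#'
#' Set logic over the per-species classifications of the same read set:
#' a read is `unique_A` iff unique in A and not mapped in B (symmetrically
#' `unique_B`); mapped (unique or multimapped) in both species is
#' `cross_species_discard`; multimapped in exactly one species is
#' `multimapped_discard`; a read whose only alignments anywhere were
#' antisense junction hits is `antisense_junction_discard`; everything else
#' is `unmapped`. Classes are disjoint and exhaustive, so class counts sum
#' to the number of input reads.
#'
#' @param cls_a,cls_b results of [classify_within_species()] for species A
#'   and B over the same reads.
#' @param species_a,species_b species labels.
#' @param too_short read ids dropped at trimming (classed `unmapped`).
#' @return object of class `partition_result`: `classes` (`read_id`,
#'   `class`), `counts`, species labels, per-species unique hit tables and
#'   per-species mapped flags.
#' @export
partition_by_species <- function(cls_a, cls_b, species_a = "A",
                                 species_b = "B",
                                 too_short = character(0)) {
  a <- cls_a$classes
  b <- cls_b$classes
  if (!setequal(a$read_id, b$read_id)) {
    miss <- c(setdiff(a$read_id, b$read_id), setdiff(b$read_id, a$read_id))
    stop("read sets differ between species; e.g. ",
         paste(head(miss, 5L), collapse = ", "))
  }
  m <- merge(a, b, by = "read_id", suffixes = c("_a", "_b"))
  mapped_a <- m$class_a %in% c("unique", "multimapped")
  mapped_b <- m$class_b %in% c("unique", "multimapped")
  cls <- rep("unmapped", nrow(m))
  cls[m$class_a == "antisense_junction" | m$class_b == "antisense_junction"] <-
    "antisense_junction_discard"
  cls[(m$class_a == "multimapped" & !mapped_b) |
        (m$class_b == "multimapped" & !mapped_a)] <- "multimapped_discard"
  cls[m$class_a == "unique" & !mapped_b] <- "unique_A"
  cls[m$class_b == "unique" & !mapped_a] <- "unique_B"
  cls[mapped_a & mapped_b] <- "cross_species_discard"
  classes <- data.table::data.table(read_id = m$read_id, class = cls)
  if (length(too_short))
    classes <- rbind(classes,
                     data.table::data.table(read_id = too_short,
                                            class = "unmapped"))
  lev <- c("unique_A", "unique_B", "cross_species_discard",
           "multimapped_discard", "antisense_junction_discard", "unmapped")
  counts <- table(factor(classes$class, levels = lev))
  stopifnot(sum(counts) == nrow(classes))
  ids_a <- m$read_id[cls == "unique_A"]
  ids_b <- m$read_id[cls == "unique_B"]
  structure(list(
    classes = classes,
    counts = counts,
    species_a = species_a, species_b = species_b,
    unique_hits_a = cls_a$unique_hits[cls_a$unique_hits$read_id %in% ids_a],
    unique_hits_b = cls_b$unique_hits[cls_b$unique_hits$read_id %in% ids_b],
    mapped_a = data.table::data.table(read_id = m$read_id, mapped = mapped_a),
    mapped_b = data.table::data.table(read_id = m$read_id, mapped = mapped_b)
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result (", x$species_a, " vs ", x$species_b, "):\n",
      sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-class and per-species mapping statistics
#'
#' Yield loss for a species is the fraction of its mapped reads (any
#' surviving hit) that also mapped to the other species and were therefore
#' discarded by the cross-species rule.
#'
#' @param partition `partition_result`.
#' @param transcripts optional transcript table; when given, the fraction of
#'   retained unique reads overlapping any exon is reported per species.
#' @param path optional TSV output path.
#' @return `data.table` of statistics (`metric`, `value`).
#' @export
mapping_stats <- function(partition, transcripts = NULL, path = NULL) {
  cnt <- as.list(partition$counts)
  n_mapped_a <- sum(partition$mapped_a$mapped)
  n_mapped_b <- sum(partition$mapped_b$mapped)
  both <- merge(partition$mapped_a, partition$mapped_b, by = "read_id",
                suffixes = c("_a", "_b"))
  n_both <- sum(both$mapped_a & both$mapped_b)
  stats <- data.table::data.table(
    metric = c(paste0("n_", names(cnt)), "n_reads",
               paste0("yield_loss_", partition$species_a),
               paste0("yield_loss_", partition$species_b)),
    value = c(unlist(cnt), nrow(partition$classes),
              if (n_mapped_a > 0) n_both / n_mapped_a else NA_real_,
              if (n_mapped_b > 0) n_both / n_mapped_b else NA_real_))
  if (!is.null(transcripts)) {
    for (side in c("a", "b")) {
      uh <- partition[[paste0("unique_hits_", side)]]
      sp <- partition[[paste0("species_", side)]]
      tr <- transcripts[transcripts$species_label == sp, ]
      frac <- if (nrow(uh) == 0L) NA_real_ else {
        gh <- uh[uh$reference_kind == "genome"]
        n_tx <- sum(uh$reference_kind == "junction")
        if (nrow(gh)) {
          ex <- exon_granges(tr)
          rd <- GenomicRanges::GRanges(
            gh$target, IRanges::IRanges(start = gh$position + 1L,
                                        width = gh$qwidth))
          n_tx <- n_tx +
            sum(IRanges::overlapsAny(rd, ex))
        }
        n_tx / nrow(uh)
      }
      stats <- rbind(stats, data.table::data.table(
        metric = paste0("frac_in_transcripts_", sp), value = frac))
    }
  }
  if (!is.null(path)) write_tsv(stats, path)
  stats
}

# GRanges of all exons of a transcript table, names = transcript_id.
exon_granges <- function(transcripts) {
  n_ex <- lengths(transcripts$exon_starts)
  GenomicRanges::GRanges(
    rep(transcripts$chromosome, n_ex),
    IRanges::IRanges(
      start = unlist(transcripts$exon_starts) + 1L,
      end = unlist(transcripts$exon_ends)),
    transcript_id = rep(transcripts$transcript_id, n_ex),
    gene_id = rep(transcripts$gene_id, n_ex))
}
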