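#' Two-platform detection contingency table
#'
#' Counts over a common gene universe: `A` detected on both platforms, `B`
#' undetected on both, `C` detected by platform 1 only, `D` detected by
#' platform 2 only. Also reports the two directional agreement percentages
#' `A/(A+C)` (platform-1 detections confirmed by platform 2) and `A/(A+D)`,
#' rounded half-up to integer percent for display (raw ratios retained).
#'
#' @param detected_1,detected_2 character vectors of detected gene ids.
#' @param universe all gene ids compared.
#' @return object of class `detection_contingency` with fields `A`, `B`,
#'   `C`, `D`, `ratio_1_in_2`, `ratio_2_in_1`, `pct_1_in_2`, `pct_2_in_1`.
#' @export
detection_contingency <- function(detected_1, detected_2, universe) {
  out1 <- setdiff(detected_1, universe)
  out2 <- setdiff(detected_2, universe)
  if (length(out1) || length(out2))
    stop("detected gene(s) outside universe: ",
         paste(head(c(out1, out2), 5L), collapse = ", "))
  detected_1 <- unique(detected_1)
  detected_2 <- unique(detected_2)
  universe <- unique(universe)
  A <- length(intersect(detected_1, detected_2))
  C <- length(setdiff(detected_1, detected_2))
  D <- length(setdiff(detected_2, detected_1))
  B <- length(universe) - A - C - D
  r12 <- if (A + C > 0) A / (A + C) else NA_real_
  r21 <- if (A + D > 0) A / (A + D) else NA_real_
  structure(list(A = A, B = B, C = C, D = D,
                 ratio_1_in_2 = r12, ratio_2_in_1 = r21,
                 pct_1_in_2 = if (is.na(r12)) NA_real_
                              else round_half_up(100 * r12),
                 pct_2_in_1 = if (is.na(r21)) NA_real_
                              else round_half_up(100 * r21)),
            class = "detection_contingency")
}

#' @export
print.detection_contingency <- function(x, ...) {
  cat(sprintf(
    "detection contingency: A=%d B=%d C=%d D=%d | %s%% (%d/%d), %s%% (%d/%d)\n",
    x$A, x$B, x$C, x$D, x$pct_1_in_2, x$A, x$A + x$C,
    x$pct_2_in_1, x$A, x$A + x$D))
  invisible(x)
}

#' Correspondence score between two detection platforms
#'
#' A Matthews-correlation-style score over the detected/undetected 2x2
#' table with `(A, B, C, D)` in the roles of `(TP, TN, FP, FN)`:
#' `CS = (A*B - C*D) / sqrt((A+C)(A+D)(B+C)(B+D))`. CS is 1 for perfect
#' correspondence, 0 when agreement is no better than random, and -1 when
#' every gene detected on one platform is undetected on the other.
#' Boundary conventions where the formula is undefined: `C = D = 0` (with
#' `A`, `B` not both zero) returns 1 — perfect correspondence; `A = B = 0`
#' returns -1; any other zero denominator factor returns 0.
#'
#' @param ct `detection_contingency`, or `A` as a numeric when all four
#'   counts are given separately.
#' @param B,C,D optional counts when `ct` is numeric `A`.
#' @return CS in `[-1, 1]`.
#' @export
correspondence_score <- function(ct, B = NULL, C = NULL, D = NULL) {
  if (inherits(ct, "detection_contingency")) {
    A <- ct$A; B <- ct$B; C <- ct$C; D <- ct$D
  } else {
    A <- ct
  }
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  stopifnot(A >= 0, B >= 0, C >= 0, D >= 0)
  if (A + B + C + D == 0) stop("all-zero contingency table")
  if (C == 0 && D == 0) return(1)
  if (A == 0 && B == 0) return(-1)
  denom <- sqrt((A + C) * (A + D) * (B + C) * (B + D))
  if (denom == 0) return(0)
  (A * B - C * D) / denom
}

#' Squared Pearson correlation over co-detected genes
#'
#' Computed only from genes detected on both platforms, on each platform's
#' native comparable scale (e.g. log2 RPKM versus -dCT).
#'
#' @param values_1,values_2 named numeric vectors of expression values.
#' @param detected_1,detected_2 detected gene ids per platform.
#' @return squared Pearson correlation.
#' @export
codetected_r2 <- function(values_1, values_2, detected_1, detected_2) {
  co <- intersect(intersect(detected_1, detected_2),
                  intersect(names(values_1), names(values_2)))
  if (length(co) < 3L)
    stop("fewer than 3 co-detected genes (", length(co), ")")
  cor(values_1[co], values_2[co])^2
}

#' Sweep the read-count detection threshold against a fixed platform
#'
#' For each threshold `t`, platform-1 detection becomes
#' `{gene : count >= t}` and the contingency and correspondence score are
#' recomputed against the fixed platform-2 calls.
#'
#' @param counts named numeric vector: gene -> read count.
#' @param detected_2 platform-2 detected gene ids.
#' @param universe gene universe (default: names of `counts`).
#' @param thresholds integer thresholds (default 1:101).
#' @param path optional TSV output.
#' @return `data.table`: `threshold`, `n_detected_1`, `A`, `B`, `C`, `D`,
#'   `cs`.
#' @export
threshold_sweep <- function(counts, detected_2, universe = names(counts),
                            thresholds = 1:101, path = NULL) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  rows <- lapply(thresholds, function(t) {
    det1 <- names(counts)[counts >= t]
    ct <- detection_contingency(det1, detected_2, universe)
    data.table::data.table(threshold = t, n_detected_1 = length(det1),
                           A = ct$A, B = ct$B, C = ct$C, D = ct$D,
                           cs = correspondence_score(ct))
  })
  out <- data.table::rbindlist(rows)
  if (!is.null(path)) write_tsv(out, path)
  out
}

#' Screen microarray probes for cross-species hybridisation risk
#'
#' For each probe the minimum Hamming distance to any same-length substring
#' of any transcript of the alternative species is found (both strands by
#' default, since probes may be antisense to the mRNA depending on platform
#' chemistry); a probe is high-risk iff that distance is at most `max_mm`.
#' A probeset is high-risk iff it contains a high-risk probe, and a gene iff
#' any of its probesets is. `N` never matches. The scan is fully sensitive
#' within `max_mm`.
#'
#' @param probes data.frame with `probe_id`, `probeset_id`, `gene_id`,
#'   `sequence` (uniform length, default 25-mers).
#' @param transcriptome named character vector (or `DNAStringSet`) of the
#'   alternative species' transcript sequences.
#' @param max_mm mismatch tolerance (default 3).
#' @param forward_only scan only the forward strand.
#' @return list: `probes` (`data.table` with `best_mismatch_count` — `NA`
#'   when no match within `max_mm` — and `high_risk`), `probesets`,
#'   `genes` (aggregated flags).
#' @export
probe_cross_species_risk <- function(probes, transcriptome, max_mm = 3L,
                                     forward_only = FALSE) {
  probes <- data.table::as.data.table(probes)
  stopifnot(all(c("probe_id", "probeset_id", "gene_id", "sequence")
                %in% names(probes)))
  if (inherits(transcriptome, "XStringSet"))
    transcriptome <- as.character(transcriptome)
  if (length(transcriptome) == 0L) stop("empty transcriptome")
  plen <- unique(nchar(probes$sequence))
  if (length(plen) != 1L)
    stop("probe lengths not uniform: ", paste(plen, collapse = ", "))
  if (plen < 1L) stop("empty probe sequence")
  subject <- Biostrings::DNAStringSet(normalize_seq(transcriptome))
  pseq <- normalize_seq(probes$sequence)
  best <- rep(NA_integer_, nrow(probes))
  strands <- if (forward_only) "+" else c("+", "-")
  for (i in seq_len(nrow(probes))) {
    for (st in strands) {
      qs <- if (st == "+") pseq[i] else revcomp(pseq[i])
      m <- Biostrings::vmatchPattern(qs, subject, max.mismatch = max_mm,
                                     fixed = TRUE)
      for (si in which(S4Vectors::elementNROWS(m) > 0L)) {
        starts <- IRanges::start(m[[si]])
        widths <- IRanges::width(m[[si]])
        keep <- widths == plen &
          starts >= 1L & starts + plen - 1L <= nchar(transcriptome[[si]])
        if (!any(keep)) next
        tw <- substring(as.character(subject[[si]]),
                        starts[keep], starts[keep] + plen - 1L)
        # recount with N-as-mismatch semantics and refilter
        mm <- string_mismatches(rep(qs, length(tw)), tw, plen)
        mm <- mm[mm <= max_mm]
        if (length(mm))
          best[i] <- min(best[i], mm, na.rm = TRUE)
      }
    }
  }
  probes <- probes[, list(probe_id, probeset_id, gene_id)]
  probes[, `:=`(best_mismatch_count = best, high_risk = !is.na(best))]
  probesets <- probes[, list(high_risk = any(high_risk)),
                      by = list(probeset_id, gene_id)]
  genes <- probesets[, list(high_risk = any(high_risk)), by = gene_id]
  list(probes = probes[], probesets = probesets[], genes = genes[])
}
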