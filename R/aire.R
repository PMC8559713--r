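# Aire-centred transcript analyses: differential transcript usage between
# Aire-knockout and Aire-positive samples, structural classification of
# transcripts (classical = coding with both UTRs), and the transcript
# length / UTR / CDS shift statistics.

#' Differential transcript usage test
#'
#' Per-transcript NB conditional exact test of summed Aire-knockout versus
#' Aire-positive counts (library-size normalized), with BH adjustment and
#' the `padj < p_threshold`, `fc >= fc_threshold` gates. "Aire-regulated"
#' transcripts are those significantly higher in the Aire-positive samples.
#' The returned table doubles as MA-plot input (mean vs fold-change).
#'
#' @param counts Transcript count matrix (transcripts x samples).
#' @param ko_samples,pos_samples Column names (>= 2 replicates each).
#' @param dispersion NB dispersion (default 0.1).
#' @param fc_threshold,p_threshold Significance gates (defaults 2, 0.05;
#'   fc gate is `>=`).
#' @return Data frame with `transcript_id`, `mean_expr`, `fc`, `log2fc`
#'   (positive = higher in Aire-positive), `p`, `padj`, `aire_regulated`.
#' @export
transcript_usage_test <- function(counts, ko_samples, pos_samples,
                                  dispersion = 0.1, fc_threshold = 2,
                                  p_threshold = 0.05) {
  if (length(ko_samples) < 2 || length(pos_samples) < 2) {
    stop("need >= 2 replicates per condition")
  }
  tab <- aire_differential(counts, ko_samples, pos_samples,
                           dispersion = dispersion)
  log2fc <- ifelse(tab$direction == "down_in_ko", log2(tab$fc),
                   ifelse(tab$direction == "up_in_ko", -log2(tab$fc), 0))
  data.frame(transcript_id = tab$feature_id,
             mean_expr = (tab$mean_ko + tab$mean_pos) / 2,
             fc = tab$fc, log2fc = log2fc, p = tab$p, padj = tab$padj,
             aire_regulated = tab$direction == "down_in_ko" &
               tab$fc >= fc_threshold & !is.na(tab$padj) &
               tab$padj < p_threshold,
             stringsAsFactors = FALSE)
}

#' Structural class of a transcript
#'
#' `classical` = coding with both a 5' and a 3' UTR; `nonclassical` = coding
#' but missing at least one UTR; `unannotated` = no CDS.
#'
#' @param t A `transcript_model`.
#' @return List with `transcript_id`, `class`, `utr5`, `cds`, `utr3`.
#' @export
classify_structure <- function(t) {
  p <- transcript_parts(t)
  cls <- if (!p$coding) "unannotated"
         else if (p$utr5 > 0 && p$utr3 > 0) "classical"
         else "nonclassical"
  list(transcript_id = t$transcript_id, class = cls,
       utr5 = p$utr5, cds = p$cds, utr3 = p$utr3, total = p$total)
}

#' Structural classification table for an annotation
#' @param ann An [annotation()].
#' @return Data frame with one row per transcript.
#' @export
classify_structures <- function(ann) {
  rows <- lapply(ann$transcripts, function(t) {
    as.data.frame(classify_structure(t), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length-distribution shift tests between two transcript groups
#'
#' Kolmogorov-Smirnov test on the full length distributions, two-sided
#' rank-sum (Wilcoxon / Mann-Whitney, normal approximation with tie
#' correction), and mean / percent differences, computed for the total
#' length and optionally per part (5'UTR, CDS, 3'UTR).
#'
#' @param a,b Numeric vectors of lengths (group A e.g. Aire-regulated,
#'   group B the comparison group).
#' @param parts_a,parts_b Optional data frames with `utr5`, `cds`, `utr3`
#'   columns for the per-part comparisons.
#' @return List with `ks` (statistic, p), `wilcox_p`, `mean_diff`
#'   (mean(a) - mean(b)), `pct_diff`, and `parts` (data frame) when part
#'   tables are given.
#' @export
length_shift_tests <- function(a, b, parts_a = NULL, parts_b = NULL) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 lengths per group")
  ks <- suppressWarnings(stats::ks.test(a, b))
  wx <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  out <- list(ks = list(statistic = unname(ks$statistic),
                        p = ks$p.value),
              wilcox_p = wx$p.value,
              mean_diff = mean(a) - mean(b),
              pct_diff = 100 * (mean(a) - mean(b)) / mean(b))
  if (!is.null(parts_a) && !is.null(parts_b)) {
    out$parts <- do.call(rbind, lapply(c("utr5", "cds", "utr3"),
                                       function(pt) {
      pa <- parts_a[[pt]]; pb <- parts_b[[pt]]
      data.frame(part = pt, mean_a = mean(pa), mean_b = mean(pb),
                 mean_diff = mean(pa) - mean(pb),
                 pct_diff = 100 * (mean(pa) - mean(pb)) / mean(pb),
                 wilcox_p = suppressWarnings(
                   stats::wilcox.test(pa, pb, exact = FALSE)$p.value),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
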