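# Local alternative-splicing events: enumeration from transcript models
# (skipped exon SE, retained intron RI, mutually exclusive exons MX,
# alternative 3'/5' splice sites A3/A5, alternative first/last exons AF/AL),
# PSI computation from TPM ratios or inclusion/skipping counts, differential
# splicing calls, and the exon-inclusion-pattern and microexon analyses.
#
# Event coordinates are 0-based half-open genomic positions. Event ids are
# deterministic strings "TYPE:gene;chrom:coords:strand" so that repeated runs
# and different machines produce identical tables.

.intron_key <- function(introns) {
  if (nrow(introns) == 0) return(character(0))
  paste(introns[, 1], introns[, 2], sep = "-")
}

.exon_key <- function(exons) paste(exons[, 1], exons[, 2], sep = "-")

#' Enumerate local alternative-splicing events in an annotation
#'
#' Events are found per gene by comparing the intron/exon structures of its
#' transcripts. Naming of alternative splice sites is strand-aware (the
#' alternative site at the genomic-left intron boundary is the donor on `+`,
#' hence A5, and the acceptor on `-`, hence A3). For SE the inclusion form
#' carries the cassette exon; for RI the inclusion form retains the intron;
#' for A5/A3 the inclusion form uses the shorter intron (more exonic
#' sequence); for MX and AF/AL the inclusion form uses the genomic-left
#' alternative exon.
#'
#' @param ann An [annotation()].
#' @return Data frame with one row per event: `event_id`, `gene_id`,
#'   `chrom`, `strand`, `type`, `coords` (semicolon-joined), `inclusion`
#'   and `exclusion` (comma-joined transcript ids), `cassette_length`
#'   (SE only, `NA` otherwise).
#' @export
enumerate_events <- function(ann) {
  rows <- list()
  for (g in names(ann$genes)) {
    tids <- ann$genes[[g]]
    if (length(tids) < 2) next
    txs <- ann$transcripts[tids]
    chrom <- txs[[1]]$chrom
    strand <- txs[[1]]$strand
    introns <- lapply(txs, transcript_introns)
    ikeys <- lapply(introns, .intron_key)
    exons <- lapply(txs, function(t) t$exons)
    ekeys <- lapply(exons, .exon_key)
    has_intron <- function(key) tids[vapply(ikeys, function(k) key %in% k,
                                            TRUE)]
    has_exon <- function(key) tids[vapply(ekeys, function(k) key %in% k,
                                          TRUE)]
    all_introns <- unique(do.call(rbind, introns))
    emit <- function(type, coords, inc, exc, cassette = NA_real_) {
      if (length(inc) == 0 || length(exc) == 0) return()
      if (length(intersect(inc, exc)) > 0) return()
      id <- paste0(type, ":", g, ";", chrom, ":",
                   paste(coords, collapse = ":"), ":", strand)
      rows[[id]] <<- data.frame(
        event_id = id, gene_id = g, chrom = chrom, strand = strand,
        type = type, coords = paste(coords, collapse = ";"),
        inclusion = paste(sort(inc), collapse = ","),
        exclusion = paste(sort(exc), collapse = ","),
        cassette_length = cassette, stringsAsFactors = FALSE)
    }

    # --- cassette candidates: (donor, exon_start, exon_end, acceptor) where
    # some transcript splices donor->exon and exon->acceptor around one exon
    cass <- list()
    for (ti in seq_along(tids)) {
      ex <- exons[[ti]]
      if (nrow(ex) < 3) next
      for (j in 2:(nrow(ex) - 1)) {
        cass[[paste(ex[j - 1, 2], ex[j, 1], ex[j, 2], ex[j + 1, 1])]] <-
          c(ex[j - 1, 2], ex[j, 1], ex[j, 2], ex[j + 1, 1])
      }
    }
    # SE: a skip intron (donor, acceptor) matches a cassette's outer bounds
    for (cc in cass) {
      skip_key <- paste(cc[1], cc[4], sep = "-")
      exc <- has_intron(skip_key)
      inc <- intersect(has_intron(paste(cc[1], cc[2], sep = "-")),
                       has_intron(paste(cc[3], cc[4], sep = "-")))
      if (length(exc) > 0) {
        emit("SE", c(cc[1], cc[2], cc[3], cc[4]), setdiff(inc, exc), exc,
             cassette = cc[3] - cc[2])
      }
    }
    # MX: two cassettes sharing outer bounds, non-overlapping exons, never
    # co-occurring in one transcript
    if (length(cass) >= 2) {
      cm <- do.call(rbind, cass)
      for (i in seq_len(nrow(cm) - 1)) {
        for (j in (i + 1):nrow(cm)) {
          a <- cm[i, ]; b <- cm[j, ]
          if (a[1] != b[1] || a[4] != b[4]) next
          if (a[3] > b[2] && b[3] > a[2]) next  # overlapping exons
          if (a[2] > b[2]) { tmp <- a; a <- b; b <- tmp }
          use_a <- intersect(has_intron(paste(a[1], a[2], sep = "-")),
                             has_intron(paste(a[3], a[4], sep = "-")))
          use_b <- intersect(has_intron(paste(b[1], b[2], sep = "-")),
                             has_intron(paste(b[3], b[4], sep = "-")))
          if (length(intersect(use_a, use_b)) > 0) next
          emit("MX", c(a[1], a[2], a[3], a[4], b[2], b[3]), use_a, use_b)
        }
      }
    }
    # RI: intron of one transcript exactly spanned by an exon of another
    # with shared outer exon boundaries
    for (ti in seq_along(tids)) {
      ex <- exons[[ti]]
      if (nrow(ex) < 2) next
      for (j in seq_len(nrow(ex) - 1)) {
        x1 <- ex[j, 1]; x2 <- ex[j, 2]; x3 <- ex[j + 1, 1]; x4 <- ex[j + 1, 2]
        retained <- has_exon(paste(x1, x4, sep = "-"))
        spliced <- intersect(has_exon(paste(x1, x2, sep = "-")),
                             has_exon(paste(x3, x4, sep = "-")))
        if (length(retained) > 0) {
          emit("RI", c(x1, x2, x3, x4), retained, setdiff(spliced, retained))
        }
      }
    }
    # Alternative splice sites / first / last exons: introns sharing one
    # boundary
    if (nrow(all_introns) >= 2) {
      .alt_site_events(all_introns, tids, txs, introns, strand, emit)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(event_id = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      type = character(0), coords = character(0),
                      inclusion = character(0), exclusion = character(0),
                      cassette_length = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$event_id), , drop = FALSE]
}

# classify pairs of introns sharing exactly one boundary into A5/A3 (the
# neighboring exons overlap) or AF/AL (distinct terminal exons)
.alt_site_events <- function(all_introns, tids, txs, introns, strand, emit) {
  ikey_list <- lapply(introns, .intron_key)
  has_intron <- function(key) tids[vapply(ikey_list, function(k) key %in% k,
                                          TRUE)]
  # for each transcript/intron: the exon upstream (ending at intron start)
  # and downstream (starting at intron end), and whether they are terminal
  neighbor <- function(tid, d, a) {
    ex <- txs[[tid]]$exons
    ups <- which(ex[, 2] == d)
    dns <- which(ex[, 1] == a)
    list(up = ex[ups[1], ], up_first = ups[1] == 1,
         dn = ex[dns[1], ], dn_last = dns[1] == nrow(ex))
  }
  n <- nrow(all_introns)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d1 <- all_introns[i, 1]; a1 <- all_introns[i, 2]
      d2 <- all_introns[j, 1]; a2 <- all_introns[j, 2]
      t1 <- has_intron(paste(d1, a1, sep = "-"))
      t2 <- has_intron(paste(d2, a2, sep = "-"))
      t1x <- setdiff(t1, t2); t2x <- setdiff(t2, t1)
      if (length(t1x) == 0 || length(t2x) == 0) next
      if (a1 == a2 && d1 != d2) {
        # shared genomic-right boundary; alternative genomic-left site
        dlo <- min(d1, d2); dhi <- max(d1, d2)
        tlo <- if (d1 < d2) t1x else t2x
        thi <- if (d1 < d2) t2x else t1x
        nlo <- neighbor(tlo[1], dlo, a1)
        nhi <- neighbor(thi[1], dhi, a1)
        if (max(nlo$up[1], nhi$up[1]) < dlo) {
          # flanking exons overlap -> alternative site at the intron's
          # genomic-left boundary: donor on +, acceptor on -
          type <- if (strand == "+") "A5" else "A3"
          # inclusion = shorter intron = more exonic sequence
          emit(type, c(dlo, dhi, a1), thi, tlo)
        } else if (nlo$up_first && nhi$up_first && nhi$up[1] >= dlo) {
          type <- if (strand == "+") "AF" else "AL"
          emit(type, c(nlo$up[1], dlo, nhi$up[1], dhi, a1), tlo, thi)
        }
      } else if (d1 == d2 && a1 != a2) {
        alo <- min(a1, a2); ahi <- max(a1, a2)
        tlo <- if (a1 < a2) t1x else t2x
        thi <- if (a1 < a2) t2x else t1x
        nlo <- neighbor(tlo[1], d1, alo)
        nhi <- neighbor(thi[1], d1, ahi)
        if (min(nlo$dn[2], nhi$dn[2]) > ahi) {
          type <- if (strand == "+") "A3" else "A5"
          emit(type, c(d1, alo, ahi), tlo, thi)
        } else if (nlo$dn_last && nhi$dn_last && nlo$dn[2] <= ahi) {
          type <- if (strand == "+") "AL" else "AF"
          emit(type, c(d1, alo, nlo$dn[2], ahi, nhi$dn[2]), tlo, thi)
        }
      }
    }
  }
}

#' PSI from transcript TPMs
#'
#' Transcript-ratio PSI for one event in one sample:
#' `sum TPM(inclusion) / sum TPM(inclusion + exclusion)`; missing when the
#' denominator is below `min_total`.
#'
#' @param inclusion_tpm,exclusion_tpm Numeric vectors of isoform TPMs.
#' @param min_total Minimum denominator (default 1 TPM).
#' @return PSI in \[0, 1\] or `NA`.
#' @export
psi_from_tpm <- function(inclusion_tpm, exclusion_tpm, min_total = 1) {
  denom <- sum(inclusion_tpm) + sum(exclusion_tpm)
  if (denom < min_total) return(NA_real_)
  sum(inclusion_tpm) / denom
}

#' Length-normalized PSI from inclusion/skipping counts
#'
#' `psi = (I/len_i) / (I/len_i + S/len_s)`; missing when `I + S` is below
#' `min_reads`.
#'
#' @param inclusion,skipping Non-negative counts.
#' @param len_inclusion,len_skipping Effective form lengths (> 0).
#' @param min_reads Minimum total reads (default 10).
#' @return PSI in \[0, 1\] or `NA`.
#' @export
psi_from_counts <- function(inclusion, skipping, len_inclusion = 1,
                            len_skipping = 1, min_reads = 10) {
  if (inclusion < 0 || skipping < 0) stop("counts must be non-negative")
  if (len_inclusion <= 0 || len_skipping <= 0) stop("lengths must be > 0")
  if (inclusion + skipping < min_reads) return(NA_real_)
  ni <- inclusion / len_inclusion
  ns <- skipping / len_skipping
  if (ni + ns == 0) return(NA_real_)
  ni / (ni + ns)
}

#' Differential splicing across two conditions
#'
#' Per event, a binomial GLM likelihood-ratio test of condition on the
#' (length-normalized) inclusion proportion across replicates, BH-adjusted
#' across events. An event is significant when `padj < fdr_threshold` and
#' `|delta PSI| > delta_threshold`.
#'
#' @param inclusion,skipping Integer matrices (events x samples).
#' @param conditions Factor/character vector of condition labels per sample
#'   (exactly two levels, >= 2 replicates each).
#' @param len_inclusion,len_skipping Effective form lengths per event
#'   (default 1: no length adjustment).
#' @param delta_threshold Minimum |delta PSI| gate (default 0.2; use 0 to
#'   gate on FDR only).
#' @param fdr_threshold BH FDR gate (default 0.05).
#' @param min_reads Events with fewer total reads in any sample are dropped.
#' @return Data frame with `event_id`, `psi_1`, `psi_2` (condition means in
#'   level order), `delta_psi` (level2 - level1), `p`, `padj`, `significant`.
#' @export
differential_events <- function(inclusion, skipping, conditions,
                                len_inclusion = 1, len_skipping = 1,
                                delta_threshold = 0.2, fdr_threshold = 0.05,
                                min_reads = 10) {
  conditions <- factor(conditions)
  if (nlevels(conditions) < 2) stop("two conditions required")
  if (nlevels(conditions) > 2) stop("exactly two conditions supported")
  if (any(table(conditions) < 2)) stop("need >= 2 replicates per condition")
  inclusion <- as.matrix(inclusion)
  skipping <- as.matrix(skipping)
  li <- rep_len(len_inclusion, nrow(inclusion))
  ls <- rep_len(len_skipping, nrow(inclusion))
  ev <- rownames(inclusion)
  res <- lapply(seq_len(nrow(inclusion)), function(k) {
    i <- inclusion[k, ]; s <- skipping[k, ]
    if (any(i + s < min_reads)) {
      return(data.frame(event_id = ev[k], psi_1 = NA_real_, psi_2 = NA_real_,
                        delta_psi = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    # length normalization: rescale to preserve per-sample totals so the
    # binomial model keeps the observed information content
    ia <- i / li[k]; sa <- s / ls[k]
    tot <- i + s
    f <- tot / (ia + sa)
    in_ <- round(ia * f); sn <- round(sa * f)
    psi <- ia / (ia + sa)
    m <- tapply(psi, conditions, mean)
    fit <- stats::glm(cbind(in_, sn) ~ conditions, family = stats::binomial())
    null <- stats::glm(cbind(in_, sn) ~ 1, family = stats::binomial())
    p <- stats::pchisq(null$deviance - fit$deviance,
                       df = 1, lower.tail = FALSE)
    data.frame(event_id = ev[k], psi_1 = m[[1]], psi_2 = m[[2]],
               delta_psi = m[[2]] - m[[1]], p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out$significant <- !is.na(out$padj) & out$padj < fdr_threshold &
    abs(out$delta_psi) > delta_threshold
  out
}

#' Tally differential events by type and gene category
#'
#' @param diff Result of [differential_events()].
#' @param events Event table from [enumerate_events()] (for `type` and
#'   `gene_id`).
#' @param categories Optional gene classification from [categorize_genes()].
#' @return Data frame of counts of significant events by `type` (and
#'   `category`), plus the number of distinct genes involved.
#' @export
tally_events <- function(diff, events, categories = NULL) {
  sig <- diff[!is.na(diff$significant) & diff$significant, , drop = FALSE]
  m <- match(sig$event_id, events$event_id)
  tab <- data.frame(event_id = sig$event_id, type = events$type[m],
                    gene_id = events$gene_id[m], stringsAsFactors = FALSE)
  if (!is.null(categories)) {
    tab$category <- categories$category[match(tab$gene_id,
                                              categories$gene_id)]
    counts <- as.data.frame(table(type = tab$type, category = tab$category))
  } else {
    counts <- as.data.frame(table(type = tab$type))
  }
  names(counts)[names(counts) == "Freq"] <- "n_events"
  list(counts = counts, n_events = nrow(tab),
       n_genes = length(unique(tab$gene_id)))
}

#' Exon-inclusion pattern filter
#'
#' Retains exons with a low inclusion rate in the TEC-like samples
#' (mean PSI < `mean_max` and max PSI < `max_max`) that are included in at
#' least one peripheral tissue (PSI > `tissue_min`), restricted to exons
#' longer than `length_floor`.
#'
#' @param psi Numeric matrix (exon events x samples).
#' @param tec_samples,tissue_samples Column names.
#' @param exon_lengths Numeric vector per row (cassette lengths).
#' @param length_floor Minimum exon length (default 50, strict >).
#' @param mean_max,max_max,tissue_min PSI gates (defaults 0.1, 0.2, 0.5).
#' @return The retained rows of `psi` restricted to the tissue columns,
#'   with attribute `"retained"` (row names kept).
#' @export
exon_inclusion_patterns <- function(psi, tec_samples, tissue_samples,
                                    exon_lengths, length_floor = 50,
                                    mean_max = 0.1, max_max = 0.2,
                                    tissue_min = 0.5) {
  psi <- as.matrix(psi)
  tec <- psi[, tec_samples, drop = FALSE]
  tis <- psi[, tissue_samples, drop = FALSE]
  keep <- exon_lengths > length_floor &
    rowMeans(tec, na.rm = TRUE) < mean_max &
    apply(tec, 1, function(v) all(is.na(v)) || max(v, na.rm = TRUE) <
            max_max) &
    apply(tis, 1, function(v) any(v > tissue_min, na.rm = TRUE))
  keep[is.na(keep)] <- FALSE
  tis[keep, , drop = FALSE]
}

#' Microexon PSI summary
#'
#' Microexons are SE cassette exons of length <= `cutoff` (boundary
#' inclusive). Returns per-sample PSI distribution summaries and the full
#' per-event PSI table.
#'
#' @param events Event table from [enumerate_events()].
#' @param psi Numeric PSI matrix (rownames = event ids).
#' @param cutoff Microexon length cutoff (default 30).
#' @return List with `summary` (per-sample quantiles and mean) and `psi`
#'   (microexon rows of the PSI matrix).
#' @export
microexon_summary <- function(events, psi, cutoff = 30) {
  se <- events[events$type == "SE" & !is.na(events$cassette_length) &
                 events$cassette_length <= cutoff, , drop = FALSE]
  ids <- intersect(se$event_id, rownames(psi))
  sub <- psi[ids, , drop = FALSE]
  summ <- do.call(rbind, lapply(colnames(sub), function(s) {
    v <- sub[, s]
    q <- stats::quantile(v, probs = c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(sample_id = s, n = sum(!is.na(v)), q25 = q[[1]],
               median = q[[2]], q75 = q[[3]], mean = mean(v, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(summary = summ, psi = sub)
}
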