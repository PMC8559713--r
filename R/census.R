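# Detection-based transcriptome census: detection calls and fraction curves,
# per-gene isoform fractions by gene category, gene-vs-transcript ANCOVA,
# isoform-usage entropy, the multi-isoform alternative-splicing fraction by
# expression quartile, and peripheral-isoform representation.

#' Detection matrix from an expression matrix
#'
#' A feature is detected in a sample when its abundance is strictly greater
#' than the threshold (detection at `TPM > 0` corresponds to
#' `threshold = 0`).
#'
#' @param expr An `expression_matrix` in TPM.
#' @param threshold Detection threshold (TPM, >= 0).
#' @return Logical matrix with a `"threshold"` attribute.
#' @export
detect <- function(expr, threshold = 0) {
  if (threshold < 0) stop("threshold must be >= 0")
  det <- expr$values > threshold
  attr(det, "threshold") <- threshold
  det
}

#' Per-sample detection-fraction curve over a threshold grid
#'
#' @param expr An `expression_matrix` in TPM.
#' @param universe Character vector of feature ids defining the denominator
#'   (e.g. annotated protein-coding transcripts).
#' @param thresholds Numeric vector of TPM thresholds.
#' @return Data frame with `sample_id`, `threshold`, `detected`, `fraction`.
#' @export
detection_fraction_curve <- function(expr, universe,
                                     thresholds = c(0, 0.1, 0.5, 1, 2, 5)) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty feature universe")
  present <- intersect(universe, rownames(expr$values))
  vals <- expr$values[present, , drop = FALSE]
  out <- lapply(thresholds, function(th) {
    d <- colSums(vals > th)
    data.frame(sample_id = colnames(vals), threshold = th,
               detected = as.integer(d), fraction = d / length(universe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-gene isoform detection fraction by gene category
#'
#' For every multi-isoform gene and sample, the fraction of its annotated
#' isoforms detected; single-isoform genes are excluded (their number is
#' reported via a message).
#'
#' @param det Detection matrix from [detect()] at the transcript level.
#' @param ann An [annotation()].
#' @param categories Optional gene classification from [categorize_genes()];
#'   when given, a `category` column is attached.
#' @return Data frame with `gene_id`, `sample_id`, `n_isoforms`,
#'   `n_detected`, `fraction` (and `category`).
#' @export
isoform_fraction <- function(det, ann, categories = NULL) {
  n_iso <- lengths(ann$genes)
  multi <- names(n_iso)[n_iso >= 2]
  if (length(multi) < length(n_iso)) {
    message(length(n_iso) - length(multi),
            " single-isoform genes excluded from isoform-fraction census")
  }
  rows <- lapply(multi, function(g) {
    tids <- intersect(ann$genes[[g]], rownames(det))
    nd <- colSums(det[tids, , drop = FALSE])
    data.frame(gene_id = g, sample_id = colnames(det),
               n_isoforms = length(ann$genes[[g]]),
               n_detected = as.integer(nd),
               fraction = nd / length(ann$genes[[g]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(categories)) {
    out$category <- categories$category[match(out$gene_id,
                                              categories$gene_id)]
  }
  out
}

#' ANCOVA on detected transcript versus gene counts
#'
#' Ordinary least squares `transcripts ~ genes * group` on per-sample
#' detected counts, testing whether the transcripts-per-gene trend differs
#' between groups (e.g. TEC versus peripheral tissues). Samples named in
#' `exclude` are dropped before fitting.
#'
#' @param counts Data frame with `sample_id`, `genes`, `transcripts`,
#'   `group` (two levels).
#' @param exclude Character vector of sample ids to drop (e.g. testis).
#' @return List with `slopes` (named per group), `interaction_p`, and the
#'   fitted `model`.
#' @export
gene_transcript_ancova <- function(counts, exclude = character(0)) {
  d <- counts[!counts$sample_id %in% exclude, , drop = FALSE]
  d$group <- factor(d$group)
  if (nlevels(d$group) != 2) stop("exactly two groups required")
  if (any(table(d$group) < 3)) {
    stop("need >= 3 samples per group for the slope comparison")
  }
  fit <- stats::lm(transcripts ~ genes * group, data = d)
  an <- stats::anova(fit)
  co <- stats::coef(fit)
  g2 <- levels(d$group)[2]
  slopes <- c(co[["genes"]], co[["genes"]] + co[[paste0("genes:group", g2)]])
  names(slopes) <- levels(d$group)
  list(slopes = slopes,
       interaction_p = an["genes:group", "Pr(>F)"],
       model = fit)
}

#' Shannon entropy of isoform usage
#'
#' `H = -sum p_i log2 p_i` (bits) over the isoform TPM shares of one gene in
#' one sample, with `0 log 0 = 0`.
#'
#' @param tpm Numeric vector of isoform TPMs for one gene in one sample.
#' @return Entropy in bits, or `NA` when the total is 0.
#' @export
splice_entropy <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  s <- sum(tpm)
  if (s == 0) return(NA_real_)
  p <- tpm / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mean isoform-usage entropy per gene set and sample
#'
#' @param expr Transcript-level `expression_matrix` (TPM).
#' @param ann An [annotation()].
#' @param gene_sets Named list of gene-id vectors (e.g. per-tissue iTRA
#'   sets); restricted to multi-isoform genes.
#' @return Data frame with `set_id`, `sample_id`, `n_genes`, `mean_entropy`.
#' @export
entropy_census <- function(expr, ann, gene_sets) {
  n_iso <- lengths(ann$genes)
  out <- lapply(names(gene_sets), function(nm) {
    genes <- intersect(gene_sets[[nm]], names(n_iso)[n_iso >= 2])
    h <- sapply(colnames(expr$values), function(s) {
      hs <- vapply(genes, function(g) {
        tids <- intersect(ann$genes[[g]], rownames(expr$values))
        splice_entropy(expr$values[tids, s])
      }, 0)
      mean(hs, na.rm = TRUE)
    })
    data.frame(set_id = nm, sample_id = colnames(expr$values),
               n_genes = length(genes), mean_entropy = unname(h),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fraction of alternatively spliced multi-isoform genes by expression
#' quartile
#'
#' Within each sample, genes under test are split into quartiles of
#' gene-level TPM (ties to the lower quartile) and the fraction of genes
#' with more than one isoform detected is reported per quartile.
#'
#' @param det Transcript-level detection matrix.
#' @param gene_expr Gene-level `expression_matrix` (TPM).
#' @param ann An [annotation()].
#' @param gene_sets Named list of gene-id vectors (iTRA sets, or the full TRA
#'   set for the TEC-like sample).
#' @param samples Optional sample ids to restrict to.
#' @param min_genes Quartiles with fewer genes are flagged `low_n`.
#' @return Data frame with `set_id`, `sample_id`, `quartile`, `n_genes`,
#'   `fraction_as`, `low_n`.
#' @export
multi_isoform_as_fraction <- function(det, gene_expr, ann, gene_sets,
                                      samples = NULL, min_genes = 5) {
  if (is.null(samples)) samples <- colnames(det)
  n_iso <- lengths(ann$genes)
  out <- list()
  for (nm in names(gene_sets)) {
    genes <- intersect(gene_sets[[nm]], names(n_iso)[n_iso >= 2])
    genes <- intersect(genes, rownames(gene_expr$values))
    for (s in samples) {
      gx <- gene_expr$values[genes, s]
      expressed <- genes[gx > 0]
      if (length(expressed) == 0) next
      q <- stats::quantile(gx[gx > 0], probs = c(0.25, 0.5, 0.75))
      qi <- findInterval(gx[gx > 0], q, left.open = TRUE) + 1L
      n_det <- vapply(expressed, function(g) {
        sum(det[intersect(ann$genes[[g]], rownames(det)), s])
      }, 0L)
      for (k in 1:4) {
        in_q <- qi == k
        if (!any(in_q)) next
        out[[length(out) + 1]] <- data.frame(
          set_id = nm, sample_id = s, quartile = k,
          n_genes = sum(in_q),
          fraction_as = mean(n_det[in_q] > 1),
          low_n = sum(in_q) < min_genes, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Representation of tissue-restricted transcript sets in a target sample
#'
#' For each tissue's set of restricted transcripts, the fraction detected in
#' the target sample. Optionally also reports, per sample of a representative
#' panel, the novel transcripts detected in exactly one panel sample
#' ("uniquely detected").
#'
#' @param restricted_sets Named list (tissue -> transcript ids).
#' @param det Transcript-level detection matrix.
#' @param target Sample id of the target (e.g. the TEC-like sample).
#' @param panel Optional character vector of representative sample ids over
#'   which unique detection is computed.
#' @param novel_ids Optional ids of novel transcripts (required with
#'   `panel`).
#' @return List with `representation` data frame (`tissue`, `n_restricted`,
#'   `n_detected`, `fraction`) and, when `panel` is given, `unique_novel`
#'   (`sample_id`, `n_unique_novel`).
#' @export
peripheral_representation <- function(restricted_sets, det, target,
                                      panel = NULL, novel_ids = NULL) {
  rep_rows <- lapply(names(restricted_sets), function(ts) {
    ids <- intersect(restricted_sets[[ts]], rownames(det))
    n <- length(restricted_sets[[ts]])
    if (n == 0) {
      return(data.frame(tissue = ts, n_restricted = 0L, n_detected = NA,
                        fraction = NA_real_, stringsAsFactors = FALSE))
    }
    nd <- sum(det[ids, target])
    data.frame(tissue = ts, n_restricted = n, n_detected = nd,
               fraction = nd / n, stringsAsFactors = FALSE)
  })
  out <- list(representation = do.call(rbind, rep_rows))
  if (!is.null(panel)) {
    if (is.null(novel_ids)) stop("novel_ids required with a panel")
    ids <- intersect(novel_ids, rownames(det))
    sub <- det[ids, panel, drop = FALSE]
    unique_mask <- rowSums(sub) == 1
    out$unique_novel <- data.frame(
      sample_id = panel,
      n_unique_novel = as.integer(colSums(sub[unique_mask, , drop = FALSE])),
      stringsAsFactors = FALSE)
  }
  out
}
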