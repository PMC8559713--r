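# Count-based statistics shared across the pipeline: library-size
# normalization, a negative-binomial conditional exact test (a deliberately
# simple stand-in for moderated count tests, applying the same decision
# thresholds), BH adjustment, Fisher's exact test wrappers, the junction
# differential census and generic set-overlap enrichment.

#' Library-size normalization
#'
#' Size factor for each column is its total divided by the geometric mean of
#' all column totals; normalized counts are counts divided by their column's
#' factor.
#'
#' @param counts Numeric matrix of non-negative counts (features x samples).
#' @return List with `size_factors` (named numeric) and `normalized` matrix.
#' @export
normalize_libsize <- function(counts) {
  counts <- as.matrix(counts)
  totals <- colSums(counts)
  if (any(totals <= 0)) stop("zero-total column in count matrix")
  geo <- exp(mean(log(totals)))
  sf <- totals / geo
  list(size_factors = sf, normalized = sweep(counts, 2, sf, "/"))
}

#' Negative-binomial conditional exact test for two counts
#'
#' Tests whether two (summed) counts are consistent with equal underlying
#' expression, conditioning on their total. Under the null the first count,
#' given the total `n`, follows the conditional distribution of
#' `NB(mu_a, size = 1/dispersion)` against `NB(mu_b, size = 1/dispersion)`
#' where the means are proportional to the size factors. At `dispersion = 0`
#' this reduces to the exact binomial test with success probability
#' `sf_a / (sf_a + sf_b)`. The two-sided p-value doubles the smaller tail,
#' capped at 1. The fold-change is computed from size-factor-normalized
#' counts with a pseudo-count of 0.5 and reported as a positive ratio plus a
#' direction.
#'
#' @param a,b Non-negative integer counts (sums over replicates).
#' @param dispersion NB dispersion (>= 0); 0 gives the binomial limit.
#' @param size_factors Length-2 numeric vector of library size factors.
#' @return List with `p`, `fc` (>= 1), `log2fc` (signed, a vs b),
#'   `direction` (`"a>b"`, `"b>a"` or `"none"`) and `mean_a`, `mean_b`
#'   (normalized means).
#' @export
nb_exact_test <- function(a, b, dispersion = 0, size_factors = c(1, 1)) {
  if (a < 0 || b < 0 || a != round(a) || b != round(b)) {
    stop("counts must be non-negative integers")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  n <- a + b
  na <- (a + 0.5) / size_factors[1]
  nb <- (b + 0.5) / size_factors[2]
  log2fc <- log2(na / nb)
  direction <- if (a / size_factors[1] > b / size_factors[2]) "a>b"
               else if (a / size_factors[1] < b / size_factors[2]) "b>a"
               else "none"
  if (n == 0) {
    return(list(p = 1, fc = 1, log2fc = 0, direction = "none",
                mean_a = na, mean_b = nb))
  }
  if (dispersion == 0) {
    pi_a <- size_factors[1] / sum(size_factors)
    lower <- stats::pbinom(a, n, pi_a)
    upper <- stats::pbinom(a - 1, n, pi_a, lower.tail = FALSE)
  } else {
    k <- 0:n
    size <- 1 / dispersion
    mu_a <- n * size_factors[1] / sum(size_factors)
    mu_b <- n - mu_a
    logp <- stats::dnbinom(k, size = size, mu = mu_a, log = TRUE) +
      stats::dnbinom(n - k, size = size, mu = mu_b, log = TRUE)
    pr <- exp(logp - max(logp))
    pr <- pr / sum(pr)
    lower <- sum(pr[k <= a])
    upper <- sum(pr[k >= a])
  }
  p <- min(1, 2 * min(lower, upper))
  list(p = p, fc = 2^abs(log2fc), log2fc = log2fc, direction = direction,
       mean_a = na, mean_b = nb)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps [stats::p.adjust()] after validating the
#' input range). Order-invariant and idempotent.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fisher's exact test on a 2x2 table
#'
#' P-value from the hypergeometric distribution (via [stats::fisher.test()]);
#' the reported odds ratio is the sample odds ratio `ad/bc` (the convention
#' used for enrichment reporting), with `Inf` when `bc = 0` and `ad > 0` and
#' `NA` for the 0/0 case.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `table`, `odds_ratio`, `p`, `alternative`.
#' @export
fisher_exact <- function(tab, alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table cells must be non-negative integers")
  }
  ad <- tab[1, 1] * tab[2, 2]
  bc <- tab[1, 2] * tab[2, 1]
  or <- if (bc == 0 && ad == 0) NA_real_
        else if (bc == 0) Inf
        else ad / bc
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(table = tab, odds_ratio = or, p = p, alternative = alternative)
}

#' Set-overlap enrichment against a collection of annotation sets
#'
#' One Fisher test per annotation set (each first intersected with the
#' universe), BH adjustment across sets. Covers GO-style overrepresentation
#' and target-list overlap tests uniformly.
#'
#' @param target Character vector of feature ids (must lie in `universe`).
#' @param sets Named list of character vectors.
#' @param universe Character vector defining the test universe.
#' @param alternative Passed to [fisher_exact()] (one-sided `"greater"` for
#'   classical overrepresentation, `"two.sided"` for overlap tests).
#' @return Data frame with one row per set: overlap counts, `odds_ratio`
#'   (`Inf` rendered as the string `"inf"` when written to TSV), `p`, `padj`.
#' @export
set_enrichment <- function(target, sets, universe,
                           alternative = "greater") {
  target <- unique(target)
  universe <- unique(universe)
  extra <- setdiff(target, universe)
  if (length(extra) > 0) {
    stop("target ids outside universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  res <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    a <- length(intersect(target, s))
    b <- length(setdiff(target, s))
    c_ <- length(setdiff(s, target))
    d <- length(universe) - a - b - c_
    ft <- fisher_exact(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                       alternative = alternative)
    data.frame(set_id = nm, n_set = length(s), n_target = length(target),
               overlap = a, odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- bh_adjust(out$p)
  out
}

#' Differential splice-junction census
#'
#' Compares per-gene numbers of distinct supported splice junctions between
#' two samples with the NB conditional exact test (single high-depth sample
#' per side, fixed dispersion), applies the BH p < `p_threshold` and
#' |fc| > `fc_threshold` gates, then tests each tissue's iTRA gene set for
#' enrichment among the genes with significantly more junctions in sample B
#' (one-sided Fisher).
#'
#' @param jc A [junction_counts()] object.
#' @param sample_a,sample_b Column names: the TEC-like sample (A) and the
#'   peripheral sample (B).
#' @param classification Gene classification table from
#'   [categorize_genes()] (needs `gene_id`, `is_tra`, `itra_tissue`).
#' @param min_reads Minimum reads for a junction to count as present
#'   (default 1).
#' @param dispersion NB dispersion used in no-replicate mode (default 0.1).
#' @param fc_threshold,p_threshold Significance gates (defaults 2 and 0.05).
#' @return List with `gene_table` (per-gene test results) and `enrichment`
#'   (per-tissue Fisher results with BH adjustment).
#' @export
differential_junction_census <- function(jc, sample_a, sample_b,
                                         classification, min_reads = 1,
                                         dispersion = 0.1,
                                         fc_threshold = 2,
                                         p_threshold = 0.05) {
  cnt <- jc$counts
  if (!all(c(sample_a, sample_b) %in% colnames(cnt))) {
    stop("samples not found in junction counts")
  }
  gid <- jc$junctions$gene_id
  na_ <- tapply(cnt[, sample_a] >= min_reads, gid, sum)
  nb_ <- tapply(cnt[, sample_b] >= min_reads, gid, sum)
  genes <- names(na_)
  res <- mapply(function(a, b) {
    r <- nb_exact_test(as.integer(a), as.integer(b),
                       dispersion = dispersion)
    c(r$p, r$log2fc)
  }, na_, nb_)
  gene_table <- data.frame(gene_id = genes,
                           junctions_a = as.integer(na_),
                           junctions_b = as.integer(nb_),
                           log2fc = res[2, ], p = res[1, ],
                           stringsAsFactors = FALSE)
  gene_table$padj <- bh_adjust(gene_table$p)
  gene_table$sig_higher_b <- gene_table$padj < p_threshold &
    gene_table$log2fc < -log2(fc_threshold)
  gene_table$sig_higher_a <- gene_table$padj < p_threshold &
    gene_table$log2fc > log2(fc_threshold)

  cls <- classification[match(gene_table$gene_id, classification$gene_id), ]
  tissues <- sort(unique(stats::na.omit(cls$itra_tissue)))
  if (length(tissues) == 0) stop("no iTRA tissues in classification")
  enr <- lapply(tissues, function(ts) {
    is_itra <- !is.na(cls$itra_tissue) & cls$itra_tissue == ts
    hi <- gene_table$sig_higher_b
    ft <- fisher_exact(matrix(c(sum(hi & is_itra), sum(hi & !is_itra),
                                sum(!hi & is_itra), sum(!hi & !is_itra)),
                              2, byrow = TRUE), alternative = "greater")
    data.frame(tissue = ts, n_sig_higher = sum(hi),
               n_itra = sum(is_itra), overlap = sum(hi & is_itra),
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  enrichment <- do.call(rbind, enr)
  enrichment$padj <- bh_adjust(enrichment$p)
  list(gene_table = gene_table, enrichment = enrichment)
}
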