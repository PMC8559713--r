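# Tissue-specificity (tau) scoring and gene classification: tissue-restricted
# antigen (TRA) genes, Aire-regulated genes, the three-way category and the
# per-tissue iTRA assignment.

#' Tissue-specificity index tau
#'
#' `tau = sum_i (1 - x_i / x_max) / (N - 1)` on per-tissue expression
#' summaries; 0 for uniform expression, 1 for single-tissue expression.
#' By default values are log2(TPM + 1) transformed first (common practice
#' for tau); set `log_transform = FALSE` to score the raw scale.
#'
#' @param x Numeric vector of per-tissue expression summaries (>= 0).
#' @param log_transform Apply log2(x + 1) before scoring (default TRUE).
#' @return tau in \[0, 1\], or `NA` (with a warning) for an all-zero vector.
#' @export
compute_tau <- function(x, log_transform = TRUE) {
  if (length(x) < 2) stop("tau requires >= 2 tissues")
  if (any(x < 0)) stop("expression must be non-negative")
  if (all(x == 0)) {
    warning("all-zero expression vector: tau undefined")
    return(NA_real_)
  }
  if (log_transform) x <- log2(x + 1)
  sum(1 - x / max(x)) / (length(x) - 1)
}

#' Classify tissue-restricted features
#'
#' Computes tau per feature over a per-tissue expression panel (one column
#' per tissue; TEC-like samples must not be in the panel) and flags features
#' with `tau >= tau_threshold` as tissue-restricted, assigning each to its
#' maximal-expression ("home") tissue. Argmax ties are broken by the
#' lexicographically smallest tissue name.
#'
#' @param tissue_expr Numeric matrix, features x tissues (colnames = tissue
#'   names, one column per tissue).
#' @param tau_threshold Restriction threshold (default 0.9; use 0.5 with a
#'   splicing-factor gene list to derive tissue-restricted splicing factors).
#' @param log_transform Passed to [compute_tau()].
#' @return Data frame with `feature_id`, `tau`, `restricted`, `home_tissue`,
#'   `max_tissue_expression`.
#' @export
classify_restricted <- function(tissue_expr, tau_threshold = 0.9,
                                log_transform = TRUE) {
  tissue_expr <- as.matrix(tissue_expr)
  if (anyDuplicated(colnames(tissue_expr))) {
    stop("duplicate tissue columns")
  }
  if (ncol(tissue_expr) < 2) stop("need >= 2 tissue columns")
  tau <- apply(tissue_expr, 1, function(v) {
    if (all(v == 0)) NA_real_ else compute_tau(v, log_transform)
  })
  ord <- order(colnames(tissue_expr))
  home <- colnames(tissue_expr)[ord][apply(
    tissue_expr[, ord, drop = FALSE], 1, which.max)]
  data.frame(feature_id = rownames(tissue_expr), tau = tau,
             restricted = !is.na(tau) & tau >= tau_threshold,
             home_tissue = home,
             max_tissue_expression = apply(tissue_expr, 1, max),
             stringsAsFactors = FALSE)
}

#' Flag Aire-regulated genes
#'
#' A gene is Aire-regulated when it is down-regulated in the Aire-knockout
#' sample by more than `fc_threshold`-fold with BH-adjusted p below
#' `p_threshold`.
#'
#' @param stats Data frame with columns `feature_id`, `fc` (positive ratio),
#'   `direction` (`"down_in_ko"` / `"up_in_ko"` / `"none"`), `padj`.
#' @param fc_threshold,p_threshold Gates (defaults 2 and 0.05; fc strict >).
#' @return Logical vector named by `feature_id`.
#' @export
classify_aire <- function(stats, fc_threshold = 2, p_threshold = 0.05) {
  req <- c("feature_id", "fc", "direction", "padj")
  if (!all(req %in% names(stats))) {
    stop("stats table must have columns: ", paste(req, collapse = ", "))
  }
  flag <- stats$direction == "down_in_ko" & stats$fc > fc_threshold &
    !is.na(stats$padj) & stats$padj < p_threshold
  stats::setNames(flag, stats$feature_id)
}

#' Aire-regulation differential test from gene counts
#'
#' Per-gene NB conditional exact test of summed Aire-knockout versus
#' Aire-positive counts, with library-size normalization and BH adjustment,
#' producing the table [classify_aire()] consumes.
#'
#' @param counts Count matrix (genes x samples).
#' @param ko_samples,pos_samples Column names of the knockout and
#'   Aire-positive samples.
#' @param dispersion Per-replicate NB dispersion (default 0.1). The test is
#'   run on replicate sums, whose dispersion is `dispersion / r` for `r`
#'   replicates (the smaller group size is used when the design is
#'   unbalanced).
#' @return Data frame with `feature_id`, `mean_ko`, `mean_pos`, `fc`,
#'   `direction`, `p`, `padj`.
#' @export
aire_differential <- function(counts, ko_samples, pos_samples,
                              dispersion = 0.1) {
  counts <- as.matrix(counts)
  norm <- normalize_libsize(counts[, c(ko_samples, pos_samples),
                                   drop = FALSE])
  sf <- norm$size_factors
  dispersion <- dispersion / min(length(ko_samples), length(pos_samples))
  ko <- rowSums(counts[, ko_samples, drop = FALSE])
  pos <- rowSums(counts[, pos_samples, drop = FALSE])
  sf_ko <- sum(sf[ko_samples])
  sf_pos <- sum(sf[pos_samples])
  res <- t(mapply(function(a, b) {
    r <- nb_exact_test(a, b, dispersion = dispersion,
                       size_factors = c(sf_ko, sf_pos))
    c(p = r$p, fc = r$fc, dirn = match(r$direction, c("a>b", "b>a", "none")))
  }, ko, pos))
  out <- data.frame(feature_id = rownames(counts),
                    mean_ko = ko / sf_ko, mean_pos = pos / sf_pos,
                    fc = res[, "fc"],
                    direction = c("up_in_ko", "down_in_ko",
                                  "none")[res[, "dirn"]],
                    p = res[, "p"], stringsAsFactors = FALSE)
  out$padj <- bh_adjust(out$p)
  out
}

#' Three-way gene categorization with iTRA assignment
#'
#' Combines tau-based restriction with the Aire-regulation flag:
#' `Aire-TRA` = TRA and Aire-regulated; `non-Aire-TRA` = TRA and not
#' Aire-regulated; `non-TRA` otherwise. Every TRA gene is assigned to the
#' tissue in which it is most highly expressed (its iTRA tissue).
#'
#' @param restricted Output of [classify_restricted()] at the gene level.
#' @param aire_flags Named logical vector from [classify_aire()] (genes
#'   absent from it are treated as not Aire-regulated).
#' @return Data frame with `gene_id`, `tau`, `is_tra`, `is_aire_regulated`,
#'   `category`, `itra_tissue`, `max_tissue_expression`.
#' @export
categorize_genes <- function(restricted, aire_flags = logical(0)) {
  aire <- !is.na(aire_flags[restricted$feature_id]) &
    aire_flags[restricted$feature_id]
  aire[is.na(aire)] <- FALSE
  is_tra <- restricted$restricted
  category <- ifelse(is_tra & aire, "Aire-TRA",
                     ifelse(is_tra, "non-Aire-TRA", "non-TRA"))
  data.frame(gene_id = restricted$feature_id, tau = restricted$tau,
             is_tra = is_tra, is_aire_regulated = unname(aire),
             category = category,
             itra_tissue = ifelse(is_tra, restricted$home_tissue,
                                  NA_character_),
             max_tissue_expression = restricted$max_tissue_expression,
             stringsAsFactors = FALSE)
}
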