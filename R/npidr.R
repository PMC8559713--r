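# Nonparametric irreproducible discovery rate (npIDR) filtering of transcript
# detections across two replicate pools: expression-binned irreproducibility
# fractions, isotonic (non-increasing in expression) smoothing, and the
# acceptance filter used to retain reproducibly detected transcripts.

#' Expression-binned npIDR curve from two detection replicates
#'
#' Transcripts detected in either replicate are binned by expression
#' (equal-occupancy bins on log10(TPM + eps), left-closed edges) and the raw
#' npIDR per bin is the fraction detected in exactly one replicate. The
#' curve is then smoothed by isotonic regression constrained to be
#' non-increasing with expression (weighted by bin occupancy); empty bins
#' inherit the smoothed value of their neighbors.
#'
#' @param rep1,rep2 Character vectors of detected transcript ids.
#' @param expression Named numeric vector: TPM for every transcript detected
#'   in either replicate.
#' @param n_bins Number of equal-occupancy expression bins (default 20).
#' @param eps Pseudo-TPM added before the log (default 0.01).
#' @return Object of class `npidr_curve`: data frame of bins with
#'   `log_tpm_lo`, `log_tpm_hi`, `n`, `n_irreproducible`, `npidr_raw`,
#'   `npidr_smooth`.
#' @export
compute_npidr <- function(rep1, rep2, expression, n_bins = 20, eps = 0.01) {
  union_ids <- union(rep1, rep2)
  if (length(union_ids) == 0) stop("empty detection union")
  missing_expr <- setdiff(union_ids, names(expression))
  if (length(missing_expr) > 0) {
    stop("expression missing for detected transcripts: ",
         paste(utils::head(missing_expr, 5), collapse = ", "))
  }
  x <- log10(expression[union_ids] + eps)
  irre <- xor(union_ids %in% rep1, union_ids %in% rep2)
  n_bins <- min(n_bins, max(1, length(union_ids)))
  edges <- unique(stats::quantile(x, probs = seq(0, 1, length.out =
                                                   n_bins + 1), names = FALSE))
  if (length(edges) < 2) edges <- c(min(x), max(x) + 1e-9)
  # left-closed bins; widen the last edge so the maximum falls inside
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  bin <- findInterval(x, edges, rightmost.closed = FALSE, left.open = FALSE)
  bin[bin > length(edges) - 1] <- length(edges) - 1
  nb <- length(edges) - 1
  n <- tabulate(bin, nbins = nb)
  n_irr <- vapply(seq_len(nb), function(k) sum(irre[bin == k]), 0L)
  raw <- ifelse(n > 0, n_irr / n, NA_real_)
  # isotonic fit, non-increasing in expression: fit non-decreasing on the
  # reversed occupied bins (weighted least squares via PAVA)
  occ <- which(n > 0)
  sm <- rep(NA_real_, nb)
  sm[occ] <- rev(.pava(rev(raw[occ]), rev(n[occ])))
  # empty bins inherit from the nearest occupied neighbor below (or above
  # for leading empties)
  for (k in seq_len(nb)) {
    if (is.na(sm[k])) {
      below <- occ[occ < k]
      above <- occ[occ > k]
      sm[k] <- if (length(below) > 0) sm[max(below)] else sm[min(above)]
    }
  }
  curve <- data.frame(log_tpm_lo = edges[-length(edges)],
                      log_tpm_hi = edges[-1], n = n,
                      n_irreproducible = n_irr, npidr_raw = raw,
                      npidr_smooth = sm)
  structure(list(bins = curve, eps = eps), class = "npidr_curve")
}

# pool-adjacent-violators: weighted non-decreasing least-squares fit
.pava <- function(y, w) {
  n <- length(y)
  if (n == 0) return(y)
  # blocks kept on a stack: value, weight, number of elements
  val <- numeric(n); wt <- numeric(n); len <- integer(n)
  top <- 0
  for (i in seq_len(n)) {
    top <- top + 1
    val[top] <- y[i]; wt[top] <- w[i]; len[top] <- 1L
    while (top > 1 && val[top - 1] > val[top] + 1e-15) {
      val[top - 1] <- (val[top - 1] * wt[top - 1] + val[top] * wt[top]) /
        (wt[top - 1] + wt[top])
      wt[top - 1] <- wt[top - 1] + wt[top]
      len[top - 1] <- len[top - 1] + len[top]
      top <- top - 1
    }
  }
  rep(val[seq_len(top)], len[seq_len(top)])
}

#' Look up smoothed npIDR at given expression values
#'
#' @param curve An `npidr_curve`.
#' @param tpm Numeric vector of TPM values.
#' @return Smoothed npIDR per value (values outside the binned range take
#'   the nearest bin's value).
#' @export
npidr_at <- function(curve, tpm) {
  b <- curve$bins
  x <- log10(tpm + curve$eps)
  k <- findInterval(x, c(b$log_tpm_lo, b$log_tpm_hi[nrow(b)]))
  k[k < 1] <- 1
  k[k > nrow(b)] <- nrow(b)
  b$npidr_smooth[k]
}

#' Filter transcripts by reproducibility
#'
#' A transcript in the detection union is accepted when the smoothed npIDR
#' at its expression is at most `threshold`.
#'
#' @param curve An `npidr_curve` computed on the same data.
#' @param union_ids Transcript ids detected in either replicate.
#' @param expression Named numeric TPM vector covering `union_ids`.
#' @param threshold Acceptance threshold in \[0, 1\] (default 0.1).
#' @return Character vector of accepted transcript ids.
#' @export
filter_reproducible <- function(curve, union_ids, expression,
                                threshold = 0.1) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- npidr_at(curve, expression[union_ids]) <= threshold
  union_ids[keep]
}
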