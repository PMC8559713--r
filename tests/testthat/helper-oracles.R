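# Independent brute-force oracles used to validate the package's statistics,
# plus small fixture builders. These deliberately avoid the code paths they
# check.

# Fisher's exact p by full hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher_p <- function(a, b, c_, d, alternative = "two.sided") {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  pr <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- pr[xs == a]
  if (alternative == "two.sided") {
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  } else if (alternative == "greater") {
    sum(pr[xs >= a])
  } else {
    sum(pr[xs <= a])
  }
}

# Two-sided exact binomial p by tail doubling, from raw density sums.
oracle_binom_two_sided <- function(a, n, p) {
  lower <- sum(stats::dbinom(0:a, n, p))
  upper <- sum(stats::dbinom(a:n, n, p))
  min(1, 2 * min(lower, upper))
}

# KS statistic as the brute-force maximum ECDF difference over all points.
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(vapply(pts, function(x) {
    abs(mean(a <= x) - mean(b <= x))
  }, 0))
}

# Raw npIDR per bin by direct set arithmetic, given explicit bin membership.
oracle_npidr_fraction <- function(ids, rep1, rep2) {
  if (length(ids) == 0) return(NA_real_)
  one <- sum(xor(ids %in% rep1, ids %in% rep2))
  one / length(ids)
}

# Skipped-exon events by naive enumeration: for every transcript triple of
# consecutive exons, look for any transcript with the direct skip junction.
oracle_se_events <- function(ann) {
  found <- character(0)
  for (g in names(ann$genes)) {
    tids <- ann$genes[[g]]
    introns <- lapply(ann$transcripts[tids], transcript_introns)
    for (t1 in tids) {
      ex <- ann$transcripts[[t1]]$exons
      if (nrow(ex) < 3) next
      for (j in 2:(nrow(ex) - 1)) {
        d <- ex[j - 1, 2]; a <- ex[j + 1, 1]
        skip <- vapply(introns, function(ii) {
          any(ii[, 1] == d & ii[, 2] == a)
        }, TRUE)
        inc <- vapply(introns, function(ii) {
          any(ii[, 1] == d & ii[, 2] == ex[j, 1]) &&
            any(ii[, 1] == ex[j, 2] & ii[, 2] == a)
        }, TRUE)
        if (any(skip) && any(inc & !skip)) {
          found <- c(found, paste("SE", g, d, ex[j, 1], ex[j, 2], a))
        }
      }
    }
  }
  sort(unique(found))
}

# A small hand-built annotation: one plus-strand gene with an SE and an A5
# event, one minus-strand two-exon gene.
toy_annotation <- function() {
  annotation(list(
    transcript_model("tA.1", "gA", "chr1", "+",
                     rbind(c(100, 200), c(300, 400), c(500, 600)),
                     cds = c(150, 550)),
    transcript_model("tA.2", "gA", "chr1", "+",
                     rbind(c(100, 200), c(500, 600)), cds = c(150, 550)),
    transcript_model("tA.3", "gA", "chr1", "+",
                     rbind(c(100, 250), c(300, 400), c(500, 600)),
                     cds = c(150, 550)),
    transcript_model("tB.1", "gB", "chr1", "-",
                     rbind(c(1000, 1100), c(1200, 1300)),
                     cds = c(1050, 1250))
  ))
}
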