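# IUPAC motif scanning and positional enrichment of the RBFOX recognition
# motif (WGCAUGM) around regulated exons, with permutation-based FDR.
#
# Coverage profiles follow the motif-map convention: a fixed window of
# intronic and exonic sequence at each exon boundary, a sliding smoothing
# window, and per-offset coverage = fraction of exons with >= 1 motif match
# overlapping the smoothing window centered at that offset. Significance of
# the target profile over a background exon pool is assessed by resampling
# same-size exon sets from the pool.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a sequence for exact IUPAC motif matches
#'
#' All (including overlapping) matches of an IUPAC consensus on the given
#' sequence; `U` and `T` are equivalent in both motif and sequence.
#'
#' @param sequence Character scalar (DNA/RNA alphabet) or
#'   [Biostrings::DNAString].
#' @param motif IUPAC consensus string (e.g. `"WGCAUGM"`).
#' @return Integer vector of 0-based match start positions.
#' @export
scan_iupac <- function(sequence, motif) {
  motif <- toupper(motif)
  codes <- strsplit(motif, "")[[1]]
  if (!all(codes %in% names(.IUPAC))) {
    stop("invalid IUPAC code in motif: ",
         paste(setdiff(codes, names(.IUPAC)), collapse = ", "))
  }
  seq_chr <- toupper(as.character(sequence))
  seq_chr <- chartr("U", "T", seq_chr)
  motif_dna <- chartr("U", "T", motif)
  hits <- Biostrings::matchPattern(motif_dna,
                                   Biostrings::DNAString(seq_chr),
                                   fixed = FALSE)
  as.integer(IRanges::start(hits)) - 1L
}

#' Extract strand-aware flanking windows for a set of exons
#'
#' For each exon, four sequence segments in transcript orientation:
#' upstream intron (`up_len` nt ending at the exon's 5' boundary), exon
#' start (`exon_len` nt), exon end (`exon_len` nt), downstream intron
#' (`down_len` nt). Segments truncated at the chromosome end are padded
#' with `N` (excluded from coverage denominators downstream).
#'
#' @param exons Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`.
#' @param genome Named [Biostrings::DNAStringSet] (or named character) of
#'   chromosome sequences.
#' @param up_len,down_len Intronic window lengths (default 250).
#' @param exon_len Exonic window length (default 50).
#' @return List of per-exon lists with `upstream`, `exon_start`, `exon_end`,
#'   `downstream` character sequences (sense strand of the gene).
#' @export
exon_flanks <- function(exons, genome, up_len = 250, down_len = 250,
                        exon_len = 50) {
  if (is.character(genome)) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  get_seq <- function(chrom, lo, hi) {
    # 0-based half-open; pad out-of-range with N
    chr <- genome[[chrom]]
    n <- length(chr)
    lo2 <- max(lo, 0); hi2 <- min(hi, n)
    if (hi2 <= lo2) return(strrep("N", hi - lo))
    s <- as.character(Biostrings::subseq(chr, lo2 + 1, hi2))
    paste0(strrep("N", lo2 - lo), s, strrep("N", hi - hi2))
  }
  lapply(seq_len(nrow(exons)), function(i) {
    ch <- exons$chrom[i]; s <- exons$start[i]; e <- exons$end[i]
    st <- exons$strand[i]
    left <- get_seq(ch, s - up_len, s)
    right <- get_seq(ch, e, e + down_len)
    ex_l <- get_seq(ch, s, min(e, s + exon_len))
    ex_r <- get_seq(ch, max(s, e - exon_len), e)
    # exons shorter than the window are padded with N on their inner side so
    # every exon contributes fixed-length segments
    pad <- strrep("N", max(0, exon_len - (e - s)))
    ex_l <- paste0(ex_l, pad)
    ex_r <- paste0(pad, ex_r)
    if (st == "+") {
      list(upstream = left, exon_start = ex_l, exon_end = ex_r,
           downstream = right)
    } else {
      rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
      list(upstream = rc(right), exon_start = rc(ex_r),
           exon_end = rc(ex_l), downstream = rc(left))
    }
  })
}

# per-exon logical coverage vector over the concatenated window axis
.flank_hits <- function(flank, motif, exon_len) {
  segs <- c(flank$upstream, flank$exon_start, flank$exon_end,
            flank$downstream)
  lapply(segs, function(s) {
    hit <- rep(FALSE, nchar(s))
    valid <- strsplit(s, "")[[1]] != "N"
    for (p in scan_iupac(s, motif)) {
      hit[(p + 1):min(nchar(s), p + nchar(motif))] <- TRUE
    }
    list(hit = hit, valid = valid)
  })
}

#' Positional motif coverage profile for an exon set
#'
#' @param flanks Output of [exon_flanks()] for the exon set.
#' @param motif IUPAC consensus.
#' @param smooth Smoothing window width in nt (odd, default 31): coverage at
#'   an offset is the fraction of exons with >= 1 motif base overlapping the
#'   window centered there (exons whose sequence at that offset is padding
#'   are excluded from the denominator).
#' @return Data frame with `segment` (upstream/exon_start/exon_end/
#'   downstream), `offset` (0-based within segment), `coverage`, `n`.
#' @export
positional_coverage <- function(flanks, motif, smooth = 31) {
  if (length(flanks) == 0) stop("empty exon set")
  half <- smooth %/% 2
  per_exon <- lapply(flanks, .flank_hits, motif = motif,
                     exon_len = nchar(flanks[[1]]$exon_start))
  seg_names <- c("upstream", "exon_start", "exon_end", "downstream")
  out <- list()
  for (si in seq_along(seg_names)) {
    len <- nchar(flanks[[1]][[seg_names[si]]])
    cov_num <- numeric(len); cov_den <- numeric(len)
    for (pe in per_exon) {
      hit <- pe[[si]]$hit; valid <- pe[[si]]$valid
      # windowed "any hit" via cumulative sums
      cs <- cumsum(c(0, hit))
      for (off in seq_len(len)) {
        lo <- max(1, off - half); hi <- min(len, off + half)
        if (!valid[off]) next
        cov_den[off] <- cov_den[off] + 1
        if (cs[hi + 1] - cs[lo] > 0) cov_num[off] <- cov_num[off] + 1
      }
    }
    out[[si]] <- data.frame(segment = seg_names[si],
                            offset = seq_len(len) - 1L,
                            coverage = ifelse(cov_den > 0,
                                              cov_num / cov_den, NA_real_),
                            n = cov_den, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Permutation-based positional motif enrichment
#'
#' Compares the coverage profile of a target exon set against a null built
#' from `n_perm` random same-size draws from a background exon pool.
#' Per-offset empirical p-values `(1 + #{null >= observed}) / (n_perm + 1)`
#' are BH-adjusted across the offsets of each window segment (upstream
#' intron, exon edges, downstream intron) separately, so that strong
#' enrichment in one window does not relax the false-discovery control in
#' the others; the significance mask is `padj <= fdr`.
#'
#' @param target_flanks,background_flanks Outputs of [exon_flanks()].
#' @param motif IUPAC consensus (default `"WGCAUGM"`, the RBFOX motif).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param fdr FDR threshold for the mask (default 0.05).
#' @param smooth Smoothing width (default 31).
#' @return Data frame: `segment`, `offset`, `coverage`, `null_mean`,
#'   `null_q95`, `p`, `padj`, `significant`.
#' @export
permutation_enrichment <- function(target_flanks, background_flanks,
                                   motif = "WGCAUGM", n_perm = 1000,
                                   fdr = 0.05, smooth = 31) {
  if (length(background_flanks) < length(target_flanks)) {
    stop("background pool smaller than target set")
  }
  if (n_perm < 100) warning("fewer than 100 permutations")
  obs <- positional_coverage(target_flanks, motif, smooth = smooth)
  m <- length(target_flanks)
  # precompute background per-exon profiles once; a permutation is then a
  # mean over a random subset of rows
  bg_prof <- .exon_profiles(background_flanks, motif, smooth)
  null <- matrix(NA_real_, nrow = n_perm, ncol = nrow(obs))
  for (b in seq_len(n_perm)) {
    pick <- sample.int(length(background_flanks), m)
    num <- colSums(bg_prof$hit[pick, , drop = FALSE] &
                     bg_prof$valid[pick, , drop = FALSE])
    den <- colSums(bg_prof$valid[pick, , drop = FALSE])
    null[b, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  p <- vapply(seq_len(nrow(obs)), function(k) {
    if (is.na(obs$coverage[k])) return(NA_real_)
    (1 + sum(null[, k] >= obs$coverage[k], na.rm = TRUE)) / (n_perm + 1)
  }, 0)
  obs$null_mean <- colMeans(null, na.rm = TRUE)
  obs$null_q95 <- apply(null, 2, stats::quantile, probs = 0.95,
                        na.rm = TRUE)
  obs$p <- p
  obs$padj <- stats::ave(p, obs$segment,
                         FUN = function(v) bh_adjust(v))
  obs$significant <- !is.na(obs$padj) & obs$padj <= fdr
  obs
}

# matrix form of per-exon windowed hit/valid indicators over the
# concatenated window axis (rows = exons)
.exon_profiles <- function(flanks, motif, smooth) {
  half <- smooth %/% 2
  lens <- vapply(c("upstream", "exon_start", "exon_end", "downstream"),
                 function(s) nchar(flanks[[1]][[s]]), 0)
  total <- sum(lens)
  hit_m <- matrix(FALSE, nrow = length(flanks), ncol = total)
  val_m <- matrix(FALSE, nrow = length(flanks), ncol = total)
  for (i in seq_along(flanks)) {
    pe <- .flank_hits(flanks[[i]], motif, lens[2])
    col0 <- 0
    for (si in 1:4) {
      len <- lens[si]
      hit <- pe[[si]]$hit; valid <- pe[[si]]$valid
      cs <- cumsum(c(0, hit))
      for (off in seq_len(len)) {
        lo <- max(1, off - half); hi <- min(len, off + half)
        hit_m[i, col0 + off] <- (cs[hi + 1] - cs[lo]) > 0
      }
      val_m[i, col0 + seq_len(len)] <- valid
      col0 <- col0 + len
    }
  }
  list(hit = hit_m, valid = val_m)
}
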