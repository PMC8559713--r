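# Transcript models and annotation container.
#
# Internal coordinates are 0-based half-open throughout the package; the
# 1-based inclusive GTF convention is converted exactly once, at I/O time.

#' Construct a transcript model
#'
#' A transcript model holds the exon (and optionally CDS) structure of one
#' transcript on a genome. Exons are stored as 0-based half-open intervals,
#' sorted ascending by start regardless of strand.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix (start, end), 0-based half-open.
#' @param cds Optional length-2 numeric vector `(start, end)` giving the
#'   genomic CDS span (0-based half-open), or `NULL` for non-coding models.
#' @param biotype Gene biotype string (e.g. `"protein_coding"`).
#' @param novel Logical: is this transcript absent from the reference
#'   annotation?
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, biotype = "protein_coding",
                             novel = FALSE) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  if (any(exons[, 2] <= exons[, 1])) {
    stop("transcript ", transcript_id, ": exon with end <= start")
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] < exons[-nrow(exons), 2])) {
    stop("transcript ", transcript_id, ": overlapping exons")
  }
  if (!is.null(cds)) {
    cds <- as.numeric(cds)
    if (length(cds) != 2 || cds[2] <= cds[1]) {
      stop("transcript ", transcript_id, ": invalid cds span")
    }
    if (!.span_in_exons(cds, exons)) {
      stop("transcript ", transcript_id, ": cds outside exon union")
    }
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 biotype = biotype, novel = isTRUE(novel)),
            class = "transcript_model")
}

# every exonic base of span must be covered by the exon set; introns strictly
# inside the span are allowed (a genomic CDS span usually crosses introns)
.span_in_exons <- function(span, exons) {
  span[1] >= exons[1, 1] && span[2] <= exons[nrow(exons), 2] &&
    .exonic_overlap(span, exons) > 0
}

.exonic_overlap <- function(span, exons) {
  sum(pmax(0, pmin(exons[, 2], span[2]) - pmax(exons[, 1], span[1])))
}

#' Mature transcript length (sum of exon lengths)
#' @param t A `transcript_model`.
#' @return Length in nucleotides.
#' @export
transcript_length <- function(t) {
  sum(t$exons[, 2] - t$exons[, 1])
}

#' Introns of a transcript
#' @param t A `transcript_model`.
#' @return Two-column matrix of 0-based half-open intron intervals
#'   (donor = intron start, acceptor = intron end in genomic coordinates);
#'   zero rows for single-exon transcripts.
#' @export
transcript_introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = t$exons[-n, 2], end = t$exons[-1, 1])
}

#' Construct an annotation (collection of transcript models)
#'
#' @param transcripts List of `transcript_model` objects.
#' @return An object of class `annotation` with fields `transcripts`
#'   (named list), `genes` (gene_id -> character vector of transcript ids)
#'   and `gene_biotype` (named character).
#' @export
annotation <- function(transcripts) {
  ids <- vapply(transcripts, `[[`, "", "transcript_id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(transcripts) <- ids
  gene_ids <- vapply(transcripts, `[[`, "", "gene_id")
  genes <- split(ids, gene_ids)
  gene_biotype <- vapply(split(
    vapply(transcripts, `[[`, "", "biotype"), gene_ids),
    function(x) x[[1]], "")
  structure(list(transcripts = transcripts, genes = genes,
                 gene_biotype = gene_biotype),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat("annotation:", length(x$transcripts), "transcripts in",
      length(x$genes), "genes\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# GTF I/O (Ensembl dialect: gene_id / transcript_id / gene_biotype attributes)

.gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, ' "([^"]*)"'), attrs))
  if (length(m) == 0 || m == "") return(NA_character_)
  sub(paste0(key, ' "([^"]*)"'), "\\1", m)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` and `CDS` feature lines are used. GTF 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention.
#' Transcripts must carry `gene_id` and `transcript_id` attributes; a
#' transcript spanning multiple chromosomes is rejected.
#'
#' @param path Path to a GTF file.
#' @return An [annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) return(annotation(list()))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF line ", idx[which(nf < 9)[1]], " in ", path,
         ": expected 9 tab-separated fields")
  }
  tab <- do.call(rbind, lapply(fields, `[`, 1:9))
  feat <- tab[, 3]
  sel <- feat %in% c("exon", "CDS")
  tab <- tab[sel, , drop = FALSE]
  lineno <- idx[sel]
  start <- suppressWarnings(as.numeric(tab[, 4]))
  end <- suppressWarnings(as.numeric(tab[, 5]))
  bad <- which(is.na(start) | is.na(end) | end < start)
  if (length(bad) > 0) {
    stop("malformed GTF line ", lineno[bad[1]], " in ", path,
         ": bad coordinates")
  }
  tid <- vapply(tab[, 9], .gtf_attr, "", key = "transcript_id",
                USE.NAMES = FALSE)
  gid <- vapply(tab[, 9], .gtf_attr, "", key = "gene_id", USE.NAMES = FALSE)
  bt <- vapply(tab[, 9], .gtf_attr, "", key = "gene_biotype",
               USE.NAMES = FALSE)
  if (anyNA(tid) || anyNA(gid)) {
    miss <- which(is.na(tid) | is.na(gid))[1]
    stop("malformed GTF line ", lineno[miss], " in ", path,
         ": missing gene_id/transcript_id attribute")
  }
  rows <- data.frame(tid = tid, gid = gid, chrom = tab[, 1],
                     strand = tab[, 7], feat = tab[, 3],
                     start = start - 1, end = end, biotype = bt,
                     stringsAsFactors = FALSE)
  tx <- lapply(split(rows, rows$tid), function(d) {
    if (length(unique(d$chrom)) > 1) {
      stop("transcript ", d$tid[1], " spans multiple chromosomes")
    }
    ex <- d[d$feat == "exon", , drop = FALSE]
    if (nrow(ex) == 0) {
      stop("transcript ", d$tid[1], " has no exon lines")
    }
    cds_rows <- d[d$feat == "CDS", , drop = FALSE]
    cds <- if (nrow(cds_rows) > 0) c(min(cds_rows$start), max(cds_rows$end))
    biotype <- ex$biotype[1]
    if (is.na(biotype)) biotype <- "protein_coding"
    transcript_model(d$tid[1], d$gid[1], d$chrom[1], d$strand[1],
                     cbind(ex$start, ex$end), cds = cds, biotype = biotype,
                     novel = grepl("_N$", d$tid[1]))
  })
  annotation(unname(tx))
}

#' Write an annotation to a GTF file
#'
#' Emits `transcript`, `exon` and `CDS` lines in 1-based inclusive
#' coordinates, ordered deterministically by (gene_id, transcript_id,
#' start) so repeated runs are byte-identical.
#'
#' @param ann An [annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#!isocensus GTF export", con)
  gene_ids <- sort(names(ann$genes))
  for (g in gene_ids) {
    for (tid in sort(ann$genes[[g]])) {
      t <- ann$transcripts[[tid]]
      attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                       g, tid, t$biotype)
      span <- c(t$exons[1, 1], t$exons[nrow(t$exons), 2])
      writeLines(sprintf("%s\tisocensus\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         t$chrom, span[1] + 1, span[2], t$strand, attrs), con)
      for (i in seq_len(nrow(t$exons))) {
        writeLines(sprintf("%s\tisocensus\texon\t%d\t%d\t.\t%s\t.\t%s",
                           t$chrom, t$exons[i, 1] + 1, t$exons[i, 2],
                           t$strand, attrs), con)
      }
      if (!is.null(t$cds)) {
        # emit one CDS line per exon overlapping the genomic CDS span
        for (i in seq_len(nrow(t$exons))) {
          lo <- max(t$exons[i, 1], t$cds[1])
          hi <- min(t$exons[i, 2], t$cds[2])
          if (hi > lo) {
            writeLines(sprintf("%s\tisocensus\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                               t$chrom, lo + 1, hi, t$strand, attrs), con)
          }
        }
      }
    }
  }
  invisible(path)
}

#' Split a coding transcript into 5'UTR / CDS / 3'UTR lengths
#'
#' Lengths are in mature-transcript nucleotides (introns excluded) and are
#' strand-aware: the 5' end is the leftmost exonic base on `+` and the
#' rightmost on `-`. Non-coding transcripts are flagged and return zero part
#' lengths.
#'
#' @param t A `transcript_model`.
#' @return List with `utr5`, `cds`, `utr3` (nucleotides), `total`
#'   (transcript length) and `coding` (logical).
#' @export
transcript_parts <- function(t) {
  total <- transcript_length(t)
  if (is.null(t$cds)) {
    return(list(utr5 = 0, cds = 0, utr3 = 0, total = total, coding = FALSE))
  }
  cds_len <- .exonic_overlap(t$cds, t$exons)
  left <- .exonic_overlap(c(t$exons[1, 1], t$cds[1]), t$exons)
  right <- .exonic_overlap(c(t$cds[2], t$exons[nrow(t$exons), 2]), t$exons)
  if (t$strand == "+") {
    utr5 <- left; utr3 <- right
  } else {
    utr5 <- right; utr3 <- left
  }
  stopifnot(utr5 + cds_len + utr3 == total)
  list(utr5 = utr5, cds = cds_len, utr3 = utr3, total = total, coding = TRUE)
}
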