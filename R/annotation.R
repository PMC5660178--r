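#' Exon-structured transcript collections
#'
#' An `AnnotationSet` is the package's universal transcript container: a
#' strand-aware, indexed collection of exon-structured transcript models.
#' Internally it keeps a transcript-level table (id, gene, span, biotype,
#' expression, exon count, exonic length) and an exon-level
#' [GenomicRanges::GRanges] carrying `transcript_id`, which together support
#' the strand-aware interval queries every downstream step relies on.
#' All coordinates are 1-based inclusive (GTF convention).
#'
#' @param exons a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   (one of `+`, `-`, `.`), `transcript_id`, `gene_id`, and optionally
#'   `biotype`, `expression`, `source_sample`. One row per exon.
#' @return an object of class `AnnotationSet`.
#' @examples
#' ex <- data.frame(chrom = "chr1", start = c(100, 300), end = c(200, 400),
#'                  strand = "+", transcript_id = "t1", gene_id = "g1",
#'                  biotype = "lincRNA")
#' ann <- annotation_set(ex)
#' n_transcripts(ann)
#' @export
annotation_set <- function(exons) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "strand", "transcript_id", "gene_id")
  missing_cols <- setdiff(needed, names(exons))
  if (length(missing_cols)) {
    stop("exon table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"biotype" %in% names(exons)) exons$biotype <- rep("unknown", nrow(exons))
  if (!"expression" %in% names(exons)) {
    exons$expression <- rep(NA_real_, nrow(exons))
  }
  if (!"source_sample" %in% names(exons)) {
    exons$source_sample <- rep(NA_character_, nrow(exons))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(is.na(exons$start)) || any(is.na(exons$end))) {
      stop("non-numeric exon coordinates")
    }
    if (any(exons$start < 1L) || any(exons$end < exons$start)) {
      stop("invalid exon coordinates: need start >= 1 and end >= start")
    }
    if (!all(exons$strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'")
    }
  }

  dt <- data.table::as.data.table(exons)
  data.table::setorder(dt, transcript_id, start)
  # per-transcript consistency: single chrom and strand
  chk <- dt[, list(nchrom = length(unique(chrom)),
                   nstrand = length(unique(strand)),
                   ngene = length(unique(gene_id))), by = "transcript_id"]
  bad <- chk[chk$nchrom > 1L | chk$nstrand > 1L]
  if (nrow(bad)) {
    stop("transcript(s) with exons on conflicting chrom/strand: ",
         paste(utils::head(bad$transcript_id, 5L), collapse = ", "))
  }
  ov <- dt[, list(bad = any(start[-1L] <= end[-length(end)])), by = "transcript_id"]
  if (any(ov$bad)) {
    stop("transcript(s) with overlapping exons: ",
         paste(utils::head(ov$transcript_id[ov$bad], 5L), collapse = ", "))
  }

  if (nrow(dt)) {
    tx <- dt[, list(
      gene_id = gene_id[1L],
      chrom = chrom[1L],
      start = min(start),
      end = max(end),
      strand = strand[1L],
      biotype = biotype[1L],
      expression = expression[1L],
      source_sample = source_sample[1L],
      n_exons = .N,
      exonic_length = sum(end - start + 1L)
    ), by = "transcript_id"]
    data.table::setorder(tx, chrom, start, transcript_id)
  } else {
    tx <- data.table::data.table(
      transcript_id = character(), gene_id = character(),
      chrom = character(), start = integer(), end = integer(),
      strand = character(), biotype = character(),
      expression = numeric(), source_sample = character(),
      n_exons = integer(), exonic_length = integer())
  }

  exon_gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start, end = dt$end),
    strand = ifelse(dt$strand == ".", "*", dt$strand)
  )
  S4Vectors::mcols(exon_gr)$transcript_id <- dt$transcript_id

  genes <- tx[, list(biotype = biotype[1L], n_transcripts = .N), by = "gene_id"]

  structure(
    list(tx = as.data.frame(tx), exons = exon_gr,
         genes = as.data.frame(genes)),
    class = "AnnotationSet"
  )
}

#' @export
print.AnnotationSet <- function(x, ...) {
  cat(sprintf("AnnotationSet: %d transcripts, %d genes, %d exons\n",
              nrow(x$tx), nrow(x$genes), length(x$exons)))
  if (nrow(x$tx)) {
    bt <- sort(table(x$tx$biotype), decreasing = TRUE)
    cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of transcripts in an AnnotationSet
#' @param ann an `AnnotationSet`.
#' @return integer count.
#' @export
n_transcripts <- function(ann) nrow(ann$tx)

#' Transcript-level table of an AnnotationSet
#' @param ann an `AnnotationSet`.
#' @return a `data.frame` with one row per transcript (id, gene, span,
#'   strand, biotype, expression, exon count, exonic length).
#' @export
tx_table <- function(ann) ann$tx

#' Exon-level GRanges of an AnnotationSet
#' @param ann an `AnnotationSet`.
#' @return a [GenomicRanges::GRanges] with a `transcript_id` metadata column;
#'   strand `.` is represented as `*`.
#' @export
exon_ranges <- function(ann) ann$exons

#' Transcript-span GRanges of an AnnotationSet
#' @param ann an `AnnotationSet`.
#' @return a [GenomicRanges::GRanges] of transcript spans with
#'   `transcript_id` metadata.
#' @export
span_ranges <- function(ann) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$tx$chrom,
    ranges = IRanges::IRanges(ann$tx$start, ann$tx$end),
    strand = ifelse(ann$tx$strand == ".", "*", ann$tx$strand)
  )
  S4Vectors::mcols(gr)$transcript_id <- ann$tx$transcript_id
  gr
}

#' Subset an AnnotationSet by transcript ids
#' @param ann an `AnnotationSet`.
#' @param ids character vector of transcript ids to keep.
#' @return the reduced `AnnotationSet`.
#' @export
subset_transcripts <- function(ann, ids) {
  keep <- S4Vectors::mcols(ann$exons)$transcript_id %in% ids
  ex <- ann$exons[keep]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(ex))),
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    stringsAsFactors = FALSE
  )
  meta <- ann$tx[match(df$transcript_id, ann$tx$transcript_id),
                 c("gene_id", "biotype", "expression", "source_sample")]
  annotation_set(cbind(df, meta))
}

#' Combine AnnotationSets
#' @param ... `AnnotationSet` objects. Transcript ids must be unique across
#'   the inputs.
#' @return a single combined `AnnotationSet`.
#' @export
bind_annotation_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "AnnotationSet")) {
    sets <- sets[[1]]
  }
  ids <- unlist(lapply(sets, function(s) s$tx$transcript_id))
  if (anyDuplicated(ids)) {
    stop("transcript ids are not unique across the combined sets")
  }
  annotation_set(do.call(rbind, lapply(sets, exon_table)))
}

#' Exon table of an AnnotationSet
#'
#' The inverse of [annotation_set()]: a plain exon-level `data.frame`
#' (1-based inclusive, strand `.` for unstranded).
#' @param ann an `AnnotationSet`.
#' @return a `data.frame`, one row per exon.
#' @export
exon_table <- function(ann) {
  ex <- ann$exons
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(ex))),
    transcript_id = S4Vectors::mcols(ex)$transcript_id,
    stringsAsFactors = FALSE
  )
  meta <- ann$tx[match(df$transcript_id, ann$tx$transcript_id),
                 c("gene_id", "biotype", "expression", "source_sample")]
  rownames(meta) <- NULL
  cbind(df, meta)
}

#' Intron-chain keys
#'
#' A transcript-structure fingerprint: `chrom:strand:` followed by the
#' ordered intron coordinates. Two multi-exon transcripts share a key iff
#' they have the identical intron chain on the same chromosome and strand.
#' Single-exon transcripts get `NA` (they have no introns).
#' @param ann an `AnnotationSet`.
#' @return named character vector, one entry per transcript.
#' @export
intron_chain_keys <- function(ann) {
  ex <- exon_table(ann)
  dt <- data.table::as.data.table(ex)
  data.table::setorder(dt, transcript_id, start)
  keys <- dt[, list(key = {
    if (.N < 2L) NA_character_
    else {
      istart <- end[-.N] + 1L
      iend <- start[-1L] - 1L
      paste0(chrom[1L], ":", strand[1L], ":",
             paste(istart, iend, sep = "-", collapse = ";"))
    }
  }), by = "transcript_id"]
  out <- keys$key
  names(out) <- keys$transcript_id
  out[ann$tx$transcript_id]
}

#' Gene-level exon unions
#'
#' Flattens the exons of all transcripts of each gene into a non-redundant
#' set of exonic intervals (the counting footprint used for quantification).
#' @param ann an `AnnotationSet`.
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column.
#' @export
gene_exon_union <- function(ann) {
  ex <- ann$exons
  gid <- ann$tx$gene_id[match(S4Vectors::mcols(ex)$transcript_id,
                              ann$tx$transcript_id)]
  parts <- S4Vectors::split(ex, gid)
  red <- GenomicRanges::reduce(parts)
  flat <- unlist(red, use.names = TRUE)
  S4Vectors::mcols(flat)$gene_id <- names(flat)
  names(flat) <- NULL
  flat
}

#' Transcription start sites
#'
#' The 5' end of each transcript on its coding strand: span start for `+`,
#' span end for `-`. Unstranded transcripts use the span start.
#' @param ann an `AnnotationSet`.
#' @return named integer vector of TSS positions keyed by transcript id.
#' @export
transcript_tss <- function(ann) {
  tss <- ifelse(ann$tx$strand == "-", ann$tx$end, ann$tx$start)
  names(tss) <- ann$tx$transcript_id
  tss
}

# findOverlaps with the seqlevel-mismatch chatter silenced: queries against
# chromosomes absent from the subject are a legitimate, handled case here
find_overlaps_quiet <- function(...) {
  suppressWarnings(GenomicRanges::findOverlaps(...))
}
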