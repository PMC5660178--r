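#' Count fragments over gene-level exon unions
#'
#' featureCounts-style fragment assignment: a fragment is assigned to a
#' gene when it overlaps that gene's exon union by at least 1 bp (and the
#' strands match, in stranded mode). Fragments overlapping the exon unions
#' of more than one gene are discarded as ambiguous; fragments on
#' chromosomes absent from the feature space are tallied as
#' `unmapped_feature_space`. The library size is the total number of
#' fragments seen, so per sample
#' `assigned + ambiguous + unassigned = library_size`.
#'
#' @param fragments a fragment `data.frame` (see [read_fragments()]); may
#'   contain several samples.
#' @param features an `AnnotationSet` whose genes define the counting
#'   footprint.
#' @param mode `"stranded"` or `"unstranded"` (strand-blind assignment).
#' @return a list: `counts` (gene x sample integer matrix),
#'   `library_sizes`, `feature_lengths` (exon-union bp per gene), and
#'   `tallies` (per sample: assigned, ambiguous, unassigned,
#'   unmapped_feature_space).
#' @export
count_fragments <- function(fragments, features,
                            mode = c("stranded", "unstranded")) {
  mode <- match.arg(mode)
  union_gr <- gene_exon_union(features)
  gene_ids <- sort(unique(S4Vectors::mcols(union_gr)$gene_id))
  flen <- vapply(split(IRanges::width(IRanges::ranges(union_gr)),
                       S4Vectors::mcols(union_gr)$gene_id), sum, 1L)
  samples <- sort(unique(fragments$sample_id))
  if (!length(samples)) samples <- character(0)
  counts <- matrix(0L, nrow = length(gene_ids), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  lib <- stats::setNames(integer(length(samples)), samples)
  tallies <- matrix(0L, nrow = length(samples), ncol = 4L,
                    dimnames = list(samples, c("assigned", "ambiguous",
                                               "unassigned",
                                               "unmapped_feature_space")))
  if (!nrow(fragments)) {
    return(list(counts = counts, library_sizes = lib,
                feature_lengths = flen, tallies = tallies))
  }
  gene_strand <- features$tx$strand[match(S4Vectors::mcols(union_gr)$gene_id,
                                          features$tx$gene_id)]
  frag_gr <- GenomicRanges::GRanges(fragments$chrom,
                                    IRanges::IRanges(fragments$start,
                                                     fragments$end))
  known_chrom <- fragments$chrom %in%
    as.character(unique(GenomicRanges::seqnames(union_gr)))
  hits <- find_overlaps_quiet(frag_gr, union_gr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (mode == "stranded" && length(qh)) {
    fs <- fragments$strand[qh]; gs <- gene_strand[sh]
    ok <- fs == gs | fs == "." | gs == "."
    qh <- qh[ok]; sh <- sh[ok]
  }
  gene_hit <- S4Vectors::mcols(union_gr)$gene_id[sh]
  # unique genes per fragment
  key <- !duplicated(paste(qh, gene_hit, sep = "\r"))
  qh <- qh[key]; gene_hit <- gene_hit[key]
  ngenes <- tabulate(qh, nbins = nrow(fragments))
  assigned <- ngenes == 1L
  ambiguous <- ngenes > 1L

  for (s in samples) {
    in_s <- fragments$sample_id == s
    lib[s] <- sum(in_s)
    a_idx <- which(in_s & assigned)
    if (length(a_idx)) {
      g <- gene_hit[match(a_idx, qh)]
      tb <- table(g)
      counts[names(tb), s] <- counts[names(tb), s] + as.integer(tb)
    }
    tallies[s, "assigned"] <- length(a_idx)
    tallies[s, "ambiguous"] <- sum(in_s & ambiguous)
    tallies[s, "unassigned"] <- sum(in_s & !assigned & !ambiguous)
    tallies[s, "unmapped_feature_space"] <- sum(in_s & !known_chrom)
  }
  list(counts = counts, library_sizes = lib, feature_lengths = flen,
       tallies = tallies)
}

#' RPKM normalization
#'
#' Reads (fragments) per kilobase of feature per million mapped reads:
#' `rpkm = count / ((length/1000) * (library_size/1e6))`.
#' @param counts gene x sample count matrix.
#' @param feature_lengths named vector of exon-union lengths in bp
#'   (row order of `counts`).
#' @param library_sizes named vector of total mapped fragments per sample
#'   (column order of `counts`).
#' @return a matrix of RPKM values with the dimensions of `counts`.
#' @export
rpkm <- function(counts, feature_lengths, library_sizes) {
  counts <- as.matrix(counts)
  if (any(library_sizes <= 0)) {
    bad <- names(library_sizes)[library_sizes <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  if (any(feature_lengths <= 0)) stop("feature lengths must be positive")
  fl <- as.numeric(feature_lengths[rownames(counts)])
  ls <- as.numeric(library_sizes[colnames(counts)])
  sweep(sweep(counts, 1, fl / 1000, "/"), 2, ls / 1e6, "/")
}

#' Build a quantification matrix for known + novel lncRNAs
#'
#' Convenience wrapper: counts fragments over the combined known-lncRNA
#' and merged-novel feature space and attaches RPKM. The known lncRNA set
#' is selected by biotype: `lincRNA` only in unstranded mode, all lncRNA
#' biotypes (`lincRNA`, `antisense`, ...) in stranded mode, where
#' opposite-strand transcription is separable.
#'
#' @param known the reference `AnnotationSet`.
#' @param novels merged novel `AnnotationSet` (may be empty/NULL).
#' @param fragments a fragment `data.frame` covering all samples.
#' @param mode `"stranded"` or `"unstranded"`.
#' @param lncrna_biotypes biotypes treated as known lncRNAs; default
#'   depends on `mode`.
#' @return a `QuantMatrix`: list with `counts`, `rpkm`, `library_sizes`,
#'   `feature_lengths`, `tallies`, and `features` (the combined
#'   `AnnotationSet`).
#' @export
quantify_lncrnas <- function(known, novels, fragments,
                             mode = c("stranded", "unstranded"),
                             lncrna_biotypes = NULL) {
  mode <- match.arg(mode)
  if (is.null(lncrna_biotypes)) {
    lncrna_biotypes <- if (mode == "stranded") {
      c("lincRNA", "antisense", "sense_intronic", "sense_overlapping",
        "processed_transcript", "lncRNA")
    } else "lincRNA"
  }
  keep <- known$tx$transcript_id[known$tx$biotype %in% lncrna_biotypes]
  sets <- list()
  if (length(keep)) sets <- c(sets, list(subset_transcripts(known, keep)))
  if (!is.null(novels) && n_transcripts(novels) > 0) {
    sets <- c(sets, list(novels))
  }
  if (!length(sets)) stop("no known lncRNAs and no novel candidates to quantify")
  feats <- if (length(sets) == 1L) sets[[1]] else bind_annotation_sets(sets)
  q <- count_fragments(fragments, feats, mode)
  q$rpkm <- rpkm(q$counts, q$feature_lengths, q$library_sizes)
  q$features <- feats
  structure(q, class = "QuantMatrix")
}

#' @export
print.QuantMatrix <- function(x, ...) {
  cat(sprintf("QuantMatrix: %d features x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}
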