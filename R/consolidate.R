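#' Merge predicted candidates across samples
#'
#' Consolidates per-sample candidate sets into one unified novel-lncRNA
#' annotation. Multi-exon candidates with the identical intron chain (same
#' chromosome and strand, identical intron coordinate lists) are merged
#' into a single transcript whose span is the union of the member spans;
#' single-exon candidates on the same strand are clustered by transitive
#' overlap (at least 1 bp) and merged to the union span. Merged transcripts get
#' deterministic ids `NOVEL.<gene>.<tx>` assigned after coordinate
#' sorting, so the result is independent of sample order. With a single
#' sample the merge is a pass-through (renaming only).
#'
#' @param per_sample a list of `CandidateSet`s (only `PASSED` candidates
#'   are used) or `AnnotationSet`s of candidates. Names are used as sample
#'   ids when the sets carry none.
#' @return a `MergedAnnotation`: list with `ann` (the merged
#'   `AnnotationSet`, biotype `novel`, with a `classification` column on
#'   the transcript table), `provenance` (named list: merged id ->
#'   data.frame of sample_id/transcript_id members), and `n_samples`.
#' @export
merge_candidates <- function(per_sample) {
  stopifnot(length(per_sample) >= 1L)
  single_sample <- length(per_sample) == 1L

  member_tabs <- lapply(seq_along(per_sample), function(i) {
    x <- per_sample[[i]]
    if (inherits(x, "CandidateSet")) {
      keep <- names(x$status)[x$status == "PASSED"]
      ann <- subset_transcripts(x$ann, keep)
      cls <- x$class[keep]
    } else if (inherits(x, "AnnotationSet")) {
      ann <- x
      cls <- if ("classification" %in% names(x$tx)) {
        stats::setNames(x$tx$classification, x$tx$transcript_id)
      } else {
        stats::setNames(rep(NA_character_, nrow(x$tx)), x$tx$transcript_id)
      }
    } else stop("per_sample entries must be CandidateSet or AnnotationSet")
    sid <- ann$tx$source_sample
    if (all(is.na(sid))) {
      sid <- rep(if (!is.null(names(per_sample)) && nzchar(names(per_sample)[i]))
        names(per_sample)[i] else paste0("sample", i), nrow(ann$tx))
    }
    tt <- ann$tx
    tt$sample_id <- sid
    tt$classification <- unname(cls[tt$transcript_id])
    tt$chain <- unname(intron_chain_keys(ann))
    list(tx = tt, exons = exon_table(ann))
  })
  tx <- do.call(rbind, lapply(member_tabs, `[[`, "tx"))
  exons <- do.call(rbind, lapply(member_tabs, `[[`, "exons"))
  if (!nrow(tx)) {
    return(structure(list(ann = annotation_set(exons[0, c("chrom", "start", "end",
                                                          "strand", "transcript_id",
                                                          "gene_id")]),
                          provenance = list(), n_samples = length(per_sample)),
                     class = "MergedAnnotation"))
  }
  unstranded <- tapply(tx$strand == ".", tx$sample_id, any)
  if (length(unique(unstranded)) > 1L) {
    stop("cannot merge stranded and unstranded candidate sets together")
  }

  # group key: intron chain for multi-exon; overlap cluster for single-exon
  tx$member <- paste(tx$sample_id, tx$transcript_id, sep = "\r")
  group <- character(nrow(tx))
  multi <- !is.na(tx$chain)
  group[multi] <- paste0("chain:", tx$chain[multi])
  se <- which(!multi)
  if (length(se)) {
    gr <- GenomicRanges::GRanges(tx$chrom[se],
                                 IRanges::IRanges(tx$start[se], tx$end[se]),
                                 strand = ifelse(tx$strand[se] == ".", "*",
                                                 tx$strand[se]))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
    rev <- S4Vectors::mcols(red)$revmap
    for (k in seq_along(red)) {
      group[se[rev[[k]]]] <- sprintf("se:%s:%s:%d", tx$chrom[se[rev[[k]][1]]],
                                     tx$strand[se[rev[[k]][1]]],
                                     min(tx$start[se[rev[[k]]]]))
    }
  }
  if (single_sample) group <- tx$member  # pass-through: no structural merging

  groups <- split(seq_len(nrow(tx)), group)
  merged <- lapply(groups, function(idx) {
    g <- tx[idx, , drop = FALSE]
    span_start <- min(g$start); span_end <- max(g$end)
    chain <- g$chain[1L]
    if (!is.na(chain)) {
      # rebuild exons from the shared intron chain and the union span
      coords <- strsplit(sub("^[^:]+:[^:]+:", "", chain), ";")[[1]]
      im <- do.call(rbind, lapply(strsplit(coords, "-"), as.integer))
      ex_start <- c(span_start, im[, 2L] + 1L)
      ex_end <- c(im[, 1L] - 1L, span_end)
    } else {
      ex_start <- span_start; ex_end <- span_end
    }
    list(chrom = g$chrom[1L], strand = g$strand[1L],
         ex_start = ex_start, ex_end = ex_end,
         start = span_start, end = span_end,
         classification = g$classification[1L],
         members = data.frame(sample_id = g$sample_id,
                              transcript_id = g$transcript_id,
                              stringsAsFactors = FALSE))
  })
  ord <- order(vapply(merged, `[[`, "", "chrom"),
               vapply(merged, function(m) m$start, 1L),
               vapply(merged, function(m) m$end, 1L),
               vapply(merged, `[[`, "", "strand"))
  merged <- merged[ord]

  # gene grouping: strand-aware transitive span overlap among merged models
  mg <- GenomicRanges::GRanges(
    vapply(merged, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(merged, function(m) m$start, 1L),
                     vapply(merged, function(m) m$end, 1L)),
    strand = ifelse(vapply(merged, `[[`, "", "strand") == ".", "*",
                    vapply(merged, `[[`, "", "strand")))
  red <- GenomicRanges::reduce(mg, min.gapwidth = 0L, with.revmap = TRUE)
  gene_of <- integer(length(merged))
  for (k in seq_along(red)) gene_of[S4Vectors::mcols(red)$revmap[[k]]] <- k
  gene_rank <- match(gene_of, unique(gene_of))

  ex_rows <- list(); prov <- list()
  tx_in_gene <- integer(max(gene_rank))
  for (i in seq_along(merged)) {
    m <- merged[[i]]
    g <- gene_rank[i]
    tx_in_gene[g] <- tx_in_gene[g] + 1L
    tid <- sprintf("NOVEL.%d.%d", g, tx_in_gene[g])
    ex_rows[[i]] <- data.frame(
      chrom = m$chrom, start = m$ex_start, end = m$ex_end, strand = m$strand,
      transcript_id = tid, gene_id = sprintf("NOVEL.%d", g),
      biotype = "novel", stringsAsFactors = FALSE)
    prov[[tid]] <- m$members
  }
  ann <- annotation_set(do.call(rbind, ex_rows))
  ann$tx$classification <- vapply(ann$tx$transcript_id, function(id) {
    merged[[which(names(prov) == id)]]$classification
  }, "")
  structure(list(ann = ann, provenance = prov,
                 n_samples = length(per_sample)),
            class = "MergedAnnotation")
}

#' @export
print.MergedAnnotation <- function(x, ...) {
  cat(sprintf("MergedAnnotation: %d merged transcripts from %d sample(s)\n",
              n_transcripts(x$ann), x$n_samples))
  invisible(x)
}

#' Annotate lncRNAs with their nearest protein-coding gene
#'
#' For every lncRNA, finds the protein-coding gene on the same chromosome
#' minimizing the TSS-to-TSS distance (default) or the span gap. The
#' signed distance is `gene TSS - lncRNA TSS` on the plus axis and is 0
#' exactly when the genomic spans overlap. Ties are broken toward the
#' lexicographically smaller gene id. lncRNAs on chromosomes without any
#' coding gene get an empty annotation with distance `NA`.
#'
#' @param lncrnas an `AnnotationSet` of known + novel lncRNAs.
#' @param known the reference `AnnotationSet` (its `protein_coding` genes
#'   are the annotation universe).
#' @param method `"tss_to_tss"` (default) or `"span_gap"`.
#' @return a `data.frame`: `lncrna_id`, `nearest_gene_id`,
#'   `nearest_gene_name`, `distance_bp` (signed; 0 on overlap; `NA` when
#'   no coding gene shares the chromosome), `orientation` (`same_strand`,
#'   `antisense` or `lncrna_unstranded`).
#' @export
annotate_nearest_gene <- function(lncrnas, known,
                                  method = c("tss_to_tss", "span_gap")) {
  method <- match.arg(method)
  ktx <- known$tx[known$tx$biotype == "protein_coding", , drop = FALSE]
  genes <- data.table::as.data.table(ktx)[, list(
    chrom = chrom[1L], start = min(start), end = max(end),
    strand = strand[1L]), by = "gene_id"]
  genes <- as.data.frame(genes)
  genes$tss <- ifelse(genes$strand == "-", genes$end, genes$start)

  ltx <- lncrnas$tx
  out <- data.frame(lncrna_id = ltx$transcript_id,
                    nearest_gene_id = NA_character_,
                    nearest_gene_name = NA_character_,
                    distance_bp = NA_real_,
                    orientation = NA_character_,
                    stringsAsFactors = FALSE)
  if (!nrow(ltx) || !nrow(genes)) return(out)
  ltss <- ifelse(ltx$strand == "-", ltx$end, ltx$start)
  for (i in seq_len(nrow(ltx))) {
    g <- genes[genes$chrom == ltx$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    overlap <- g$start <= ltx$end[i] & g$end >= ltx$start[i]
    if (method == "tss_to_tss") {
      dist <- g$tss - ltss[i]
    } else {
      dist <- ifelse(g$start > ltx$end[i], g$start - ltx$end[i],
              ifelse(g$end < ltx$start[i], g$end - ltx$start[i], 0))
    }
    dist[overlap] <- 0
    ord <- order(abs(dist), g$gene_id)
    best <- ord[1L]
    out$nearest_gene_id[i] <- g$gene_id[best]
    out$nearest_gene_name[i] <- g$gene_id[best]
    out$distance_bp[i] <- dist[best]
    out$orientation[i] <- if (ltx$strand[i] == ".") "lncrna_unstranded"
      else if (ltx$strand[i] == g$strand[best]) "same_strand" else "antisense"
  }
  out
}
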