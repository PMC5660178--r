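#' Read a GTF file into an AnnotationSet
#'
#' Parses tab-separated GTF (1-based inclusive coordinates), grouping exon
#' features into transcripts by `transcript_id`. The transcript biotype is
#' taken from the first attribute present among `biotype_keys`; the
#' expression value from the first present among `expression_keys`
#' (StringTie emits `FPKM`, `TPM` and `cov`; FPKM is preferred by default).
#' Non-exon feature lines are ignored, except `transcript` lines which are
#' only used to validate that exons fall inside the declared span.
#' Transcripts that have a `transcript` line but no exon lines are dropped
#' with a warning.
#'
#' @param path path to a GTF file.
#' @param biotype_keys attribute keys searched, in order, for the biotype.
#' @param expression_keys attribute keys searched, in order, for the
#'   expression value.
#' @param source_sample optional sample label attached to every transcript.
#' @return an [annotation_set()].
#' @export
read_gtf <- function(path,
                     biotype_keys = c("transcript_type", "transcript_biotype",
                                      "gene_type", "gene_biotype"),
                     expression_keys = c("FPKM", "TPM", "cov"),
                     source_sample = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(annotation_set(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), transcript_id = character(),
      gene_id = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GTF line ", lineno[which(nf < 9L)[1L]],
         ": expected 9 tab-separated fields")
  }
  m <- matrix(unlist(lapply(fields, `[`, 1:9)), ncol = 9L, byrow = TRUE)
  feature <- m[, 3L]
  use <- feature %in% c("exon", "transcript")
  m <- m[use, , drop = FALSE]
  lineno <- lineno[use]
  feature <- feature[use]
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed GTF line ", lineno[which(is.na(start) | is.na(end))[1L]],
         ": non-numeric coordinates")
  }
  attrs <- m[, 9L]
  pull_attr <- function(key) {
    pat <- paste0('(^|; ?)', key, ' "([^"]*)"')
    mm <- regmatches(attrs, regexec(pat, attrs))
    vapply(mm, function(x) if (length(x) >= 3L) x[3L] else NA_character_, "")
  }
  gene_id <- pull_attr("gene_id")
  transcript_id <- pull_attr("transcript_id")
  if (anyNA(gene_id) || anyNA(transcript_id)) {
    stop("GTF line ", lineno[which(is.na(gene_id) | is.na(transcript_id))[1L]],
         ": missing gene_id or transcript_id attribute")
  }
  biotype <- rep(NA_character_, length(attrs))
  for (key in biotype_keys) {
    v <- pull_attr(key)
    biotype <- ifelse(is.na(biotype), v, biotype)
  }
  biotype[is.na(biotype)] <- "unknown"
  expression <- rep(NA_real_, length(attrs))
  for (key in expression_keys) {
    v <- suppressWarnings(as.numeric(pull_attr(key)))
    expression <- ifelse(is.na(expression), v, expression)
  }

  is_exon <- feature == "exon"
  ex <- data.frame(
    chrom = m[is_exon, 1L], start = start[is_exon], end = end[is_exon],
    strand = m[is_exon, 7L], transcript_id = transcript_id[is_exon],
    gene_id = gene_id[is_exon], biotype = biotype[is_exon],
    expression = expression[is_exon],
    source_sample = source_sample, stringsAsFactors = FALSE
  )
  declared <- unique(transcript_id[!is_exon])
  orphan <- setdiff(declared, ex$transcript_id)
  if (length(orphan)) {
    warning("dropping ", length(orphan),
            " transcript(s) with no exon lines: ",
            paste(utils::head(orphan, 5L), collapse = ", "))
  }
  # prefer transcript-line attributes for biotype/expression when present
  if (any(!is_exon)) {
    tl <- data.frame(transcript_id = transcript_id[!is_exon],
                     biotype = biotype[!is_exon],
                     expression = expression[!is_exon],
                     stringsAsFactors = FALSE)
    tl <- tl[!duplicated(tl$transcript_id), ]
    i <- match(ex$transcript_id, tl$transcript_id)
    hit <- !is.na(i)
    ex$biotype[hit] <- ifelse(is.na(tl$biotype[i[hit]]) | tl$biotype[i[hit]] == "unknown",
                              ex$biotype[hit], tl$biotype[i[hit]])
    ex$expression[hit] <- ifelse(is.na(tl$expression[i[hit]]),
                                 ex$expression[hit], tl$expression[i[hit]])
  }
  annotation_set(ex)
}

#' Write an AnnotationSet as GTF
#'
#' Emits one `transcript` line plus one `exon` line per exon for every
#' transcript, 1-based inclusive. Attributes carry `gene_id`,
#' `transcript_id`, `transcript_type`, `FPKM` (when expression is present)
#' and `classification` (when a `classification` column was attached to the
#' transcript table, as for candidate sets).
#'
#' @param ann an `AnnotationSet`.
#' @param path output path.
#' @param source value for the GTF source column.
#' @return invisibly, the path.
#' @export
write_gtf <- function(ann, path, source = "lncscout") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#gtf produced by lncscout", con)
  tx <- ann$tx
  if (!nrow(tx)) return(invisible(path))
  ex <- exon_table(ann)
  cls <- if ("classification" %in% names(tx)) tx$classification else NULL
  fmt_attr <- function(gene, txid, biotype, expr, class) {
    a <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
                 gene, txid, biotype)
    if (!is.na(expr)) a <- paste0(a, sprintf(' FPKM "%s";', format(expr, digits = 10)))
    if (!is.null(class) && !is.na(class)) a <- paste0(a, sprintf(' classification "%s";', class))
    a
  }
  out <- character(0)
  for (i in seq_len(nrow(tx))) {
    class_i <- if (is.null(cls)) NULL else cls[i]
    attr_i <- fmt_attr(tx$gene_id[i], tx$transcript_id[i], tx$biotype[i],
                       tx$expression[i], class_i)
    out <- c(out, paste(tx$chrom[i], source, "transcript", tx$start[i],
                        tx$end[i], ".", tx$strand[i], ".", attr_i, sep = "\t"))
    exi <- ex[ex$transcript_id == tx$transcript_id[i], , drop = FALSE]
    exi <- exi[order(exi$start), , drop = FALSE]
    out <- c(out, paste(exi$chrom, source, "exon", exi$start, exi$end, ".",
                        exi$strand, ".", attr_i, sep = "\t"))
  }
  writeLines(out, con)
  invisible(path)
}

#' Read a BED file of repeat/low-complexity regions
#'
#' BED coordinates are 0-based half-open; they are converted to the internal
#' 1-based inclusive convention (`start + 1`, `end`). Queries against the
#' resulting track are strand-blind.
#'
#' @param path path to a BED3+ file.
#' @return a `RepeatTrack`: a list with an unstranded
#'   [GenomicRanges::GRanges] in `$intervals`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(repeat_track(GenomicRanges::GRanges()))
  fields <- strsplit(lines, "[\t ]+")
  if (any(lengths(fields) < 3L)) {
    stop("malformed BED line ", lineno[which(lengths(fields) < 3L)[1L]],
         ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  bstart <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  bend <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(bstart) || anyNA(bend)) {
    stop("malformed BED line ", lineno[which(is.na(bstart) | is.na(bend))[1L]],
         ": non-numeric coordinates")
  }
  if (any(bend <= bstart)) {
    stop("malformed BED line ", lineno[which(bend <= bstart)[1L]],
         ": end <= start")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(bstart + 1L, bend),
                               strand = "*")
  repeat_track(gr)
}

#' Construct a RepeatTrack
#' @param intervals an unstranded [GenomicRanges::GRanges].
#' @return a `RepeatTrack` object.
#' @export
repeat_track <- function(intervals) {
  GenomicRanges::strand(intervals) <- "*"
  structure(list(intervals = intervals), class = "RepeatTrack")
}

#' @export
print.RepeatTrack <- function(x, ...) {
  cat(sprintf("RepeatTrack: %d intervals\n", length(x$intervals)))
  invisible(x)
}

#' Write a RepeatTrack as BED3
#'
#' Converts internal 1-based inclusive coordinates back to BED 0-based
#' half-open (`start - 1`, `end`); the round trip with [read_bed()] is the
#' identity.
#' @param track a `RepeatTrack`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_bed <- function(track, path) {
  gr <- track$intervals
  df <- data.frame(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read fragment records
#'
#' Fragments are the simplified alignment currency used for quantification:
#' one genomic span per sequenced fragment. Two input dialects are
#' supported: a TSV with header `chrom, start, end, strand, sample_id`
#' (1-based inclusive), and SAM, where each properly-paired template (flag
#' 0x2, TLEN > 0) defines one fragment spanning `POS .. POS + TLEN - 1`.
#'
#' @param path path to a fragment TSV or SAM file.
#' @param format `"tsv"`, `"sam"`, or `"auto"` (by file extension).
#' @param sample_id sample label for SAM input (TSV carries its own column).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `sample_id`, in file order.
#' @export
read_fragments <- function(path, format = c("auto", "tsv", "sam"),
                           sample_id = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "sam") return(read_fragments_sam(path, sample_id))
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("chrom", "strand", "sample_id")))
  if (!nrow(dt)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sample_id = character()))
  }
  needed <- c("chrom", "start", "end", "strand", "sample_id")
  if (!all(needed %in% names(dt))) {
    stop("fragment table must have columns: ", paste(needed, collapse = ", "))
  }
  if (!is.numeric(dt$start) || !is.numeric(dt$end)) {
    stop("non-numeric coordinates in fragment table")
  }
  if (any(dt$end < dt$start)) stop("fragment with end < start")
  data.frame(chrom = dt$chrom, start = as.integer(dt$start),
             end = as.integer(dt$end), strand = dt$strand,
             sample_id = dt$sample_id, stringsAsFactors = FALSE)
}

read_fragments_sam <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), sample_id = character())
  if (!length(lines)) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- as.integer(vapply(f, `[`, "", 2L))
  pos <- suppressWarnings(as.integer(vapply(f, `[`, "", 4L)))
  tlen <- suppressWarnings(as.integer(vapply(f, `[`, "", 9L)))
  if (anyNA(pos) || anyNA(tlen)) stop("non-numeric coordinates in SAM record")
  chrom <- vapply(f, `[`, "", 3L)
  # one fragment per properly-paired template: take the leftmost mate (TLEN > 0)
  use <- bitwAnd(flag, 2L) != 0L & tlen > 0L & chrom != "*"
  if (!any(use)) return(empty)
  strand <- ifelse(bitwAnd(flag[use], 16L) != 0L, "-", "+")
  data.frame(chrom = chrom[use], start = pos[use],
             end = pos[use] + tlen[use] - 1L, strand = strand,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

#' Write fragment records as TSV
#' @param fragments a fragment `data.frame` as returned by
#'   [read_fragments()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments[c("chrom", "start", "end", "strand", "sample_id")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Warn when two inputs share no chromosome names
#'
#' Chromosome naming is taken verbatim (no `chr` prefix harmonization);
#' this validation pass catches the classic hg19 `chr1` vs `1` mismatch
#' before it silently produces zero overlaps.
#' @param a,b character vectors of chromosome names (or objects with
#'   seqnames).
#' @param what label used in the warning message.
#' @return invisibly TRUE if the name sets intersect, FALSE otherwise.
#' @export
check_chromosome_names <- function(a, b, what = "inputs") {
  na <- unique(as.character(a)); nb <- unique(as.character(b))
  ok <- length(intersect(na, nb)) > 0L || !length(na) || !length(nb)
  if (!ok) {
    warning("the ", what, " share zero chromosome names (e.g. ",
            na[1L], " vs ", nb[1L], "); overlaps will be empty")
  }
  invisible(ok)
}
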