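#' Withhold a fraction of known lincRNAs
#'
#' Implements the withhold-and-recover validation setup: known lincRNAs
#' are first screened for eligibility (length bounds, repeat overlap,
#' coding potential when a genome and scorers are supplied, and no overlap
#' with any other known transcript — not every annotated lincRNA passes
#' the pipeline's own criteria), then a seeded uniform sample of
#' `round(fraction * n_eligible)` transcripts is removed from the
#' annotation for the pipeline to re-predict.
#'
#' @param known the reference `AnnotationSet`.
#' @param fraction fraction of the eligible lincRNAs to withhold, in (0,1).
#' @param seed integer seed for the uniform draw.
#' @param cfg a [filter_config()] used for the eligibility screen.
#' @param repeats optional `RepeatTrack` for the repeat screen.
#' @param genome,scorer_a,scorer_b optional genome and scorers for the
#'   coding-potential screen.
#' @param coding_threshold,coding_mode combination settings for the screen.
#' @param lincrna_biotype biotype labels treated as lincRNA.
#' @return a list: `reduced` (known minus withheld), `withheld`
#'   (`AnnotationSet`), `eligible_ids`.
#' @export
withhold <- function(known, fraction = 1 / 3, seed = 1L,
                     cfg = filter_config(), repeats = NULL,
                     genome = NULL, scorer_a = NULL, scorer_b = NULL,
                     coding_threshold = 0.9, coding_mode = "union",
                     lincrna_biotype = "lincRNA") {
  stopifnot(fraction > 0, fraction < 1)
  tx <- known$tx
  linc <- tx[tx$biotype %in% lincrna_biotype, , drop = FALSE]
  if (!nrow(linc)) stop("annotation contains no lincRNA-biotype transcripts")

  ok <- linc$exonic_length >= cfg$min_length_bp &
    !(linc$n_exons == 1L & linc$exonic_length > cfg$max_single_exon_length_bp)
  if (!is.null(repeats)) {
    sub <- subset_transcripts(known, linc$transcript_id)
    frac_rep <- repeat_overlap_fraction(sub, repeats)[linc$transcript_id]
    ok <- ok & !(linc$n_exons == 1L & frac_rep > cfg$repeat_overlap_max_fraction)
  }
  # no overlap with any known transcript of another gene
  spans <- GenomicRanges::GRanges(linc$chrom,
                                  IRanges::IRanges(linc$start, linc$end))
  all_spans <- GenomicRanges::GRanges(tx$chrom,
                                      IRanges::IRanges(tx$start, tx$end))
  hits <- find_overlaps_quiet(spans, all_spans, ignore.strand = TRUE)
  other <- tx$gene_id[S4Vectors::subjectHits(hits)] !=
    linc$gene_id[S4Vectors::queryHits(hits)]
  ok[unique(S4Vectors::queryHits(hits)[other])] <- FALSE
  if (!is.null(genome) && !is.null(scorer_a) && !is.null(scorer_b)) {
    sub <- subset_transcripts(known, linc$transcript_id)
    seqs <- spliced_sequences(sub, genome)[linc$transcript_id]
    call <- combine_calls(predict_noncoding(scorer_a, seqs),
                          predict_noncoding(scorer_b, seqs),
                          coding_threshold, coding_mode)
    ok <- ok & call
  }
  eligible <- linc$transcript_id[ok]
  if (!length(eligible)) stop("no known lincRNAs pass the eligibility screen")
  set.seed(seed)
  n_out <- max(1L, round(fraction * length(eligible)))
  withheld_ids <- sort(sample(eligible, n_out))
  list(
    reduced = subset_transcripts(known,
                                 setdiff(tx$transcript_id, withheld_ids)),
    withheld = subset_transcripts(known, withheld_ids),
    eligible_ids = eligible
  )
}

# fraction of each withheld transcript's exonic bases covered by the exons
# of each overlapping candidate, same strand ('.' matches any)
exonic_overlap_fractions <- function(withheld, cand_ann) {
  wex <- exon_ranges(withheld)
  cex <- exon_ranges(cand_ann)
  hits <- find_overlaps_quiet(wex, cex, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(withheld_id = character(), candidate_id = character(),
                      fraction = numeric()))
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ws <- as.character(GenomicRanges::strand(wex))[qh]
  cs <- as.character(GenomicRanges::strand(cex))[sh]
  ok <- ws == cs | ws == "*" | cs == "*"
  qh <- qh[ok]; sh <- sh[ok]
  if (!length(qh)) {
    return(data.frame(withheld_id = character(), candidate_id = character(),
                      fraction = numeric()))
  }
  w <- IRanges::width(IRanges::pintersect(IRanges::ranges(wex)[qh],
                                          IRanges::ranges(cex)[sh]))
  dt <- data.table::data.table(
    withheld_id = S4Vectors::mcols(wex)$transcript_id[qh],
    candidate_id = S4Vectors::mcols(cex)$transcript_id[sh],
    bases = w)
  agg <- dt[, list(bases = sum(bases)), by = c("withheld_id", "candidate_id")]
  agg$fraction <- agg$bases /
    withheld$tx$exonic_length[match(agg$withheld_id,
                                    withheld$tx$transcript_id)]
  as.data.frame(agg[, c("withheld_id", "candidate_id", "fraction")])
}

#' Match withheld transcripts against predicted candidates
#'
#' A withheld transcript is `RECOVERED` when some `PASSED` candidate
#' covers at least `min_overlap` of its exonic bases on the same strand
#' (default rule), or shares its exact intron chain
#' (`rule = "intron_chain"`; single-exon transcripts then require
#' reciprocal span overlap of `min_overlap`). Otherwise the status is the
#' first filter that removed its best-overlapping candidate, or
#' `NOT_ASSEMBLED` when no candidate overlaps it at all. When fragment
#' records are supplied, withheld transcripts without any exonic fragment
#' coverage are `NOT_COVERED` (they could never have been assembled).
#'
#' @param withheld an `AnnotationSet` of withheld transcripts.
#' @param cands a `CandidateSet` after the cascade and coding scoring.
#' @param rule `"exon_overlap"` (default) or `"intron_chain"`.
#' @param min_overlap minimum covered fraction of withheld exonic bases.
#' @param fragments optional fragment `data.frame` for the coverage check.
#' @return named character vector of statuses (one per withheld
#'   transcript): `RECOVERED_LINCRNA`, `RECOVERED_OVERLAP`,
#'   `FILTERED_LENGTH`, `FILTERED_REPEAT`, `FILTERED_EXPRESSION`,
#'   `FILTERED_CODING`, `NOT_ASSEMBLED`, `NOT_COVERED`.
#' @export
match_recovered <- function(withheld, cands,
                            rule = c("exon_overlap", "intron_chain"),
                            min_overlap = 0.5, fragments = NULL) {
  rule <- match.arg(rule)
  wtx <- withheld$tx
  status <- stats::setNames(rep("NOT_ASSEMBLED", nrow(wtx)),
                            wtx$transcript_id)
  if (!nrow(wtx)) return(status)

  ov <- exonic_overlap_fractions(withheld, cands$ann)
  passed_ids <- names(cands$status)[cands$status == "PASSED"]

  if (rule == "intron_chain") {
    wchain <- intron_chain_keys(withheld)
    cchain <- intron_chain_keys(cands$ann)
    chain_ok <- ov$candidate_id %in% passed_ids &
      !is.na(wchain[ov$withheld_id]) &
      !is.na(cchain[ov$candidate_id]) &
      wchain[ov$withheld_id] == cchain[ov$candidate_id]
    recip <- ov$fraction >= min_overlap &
      is.na(wchain[ov$withheld_id])  # single-exon fallback
    rec <- ov[ (chain_ok | (recip & ov$candidate_id %in% passed_ids)), ,
               drop = FALSE]
  } else {
    rec <- ov[ov$candidate_id %in% passed_ids &
                ov$fraction >= min_overlap, , drop = FALSE]
  }
  if (nrow(rec)) {
    rec <- rec[order(-rec$fraction), , drop = FALSE]
    rec <- rec[!duplicated(rec$withheld_id), , drop = FALSE]
    cls <- cands$class[rec$candidate_id]
    status[rec$withheld_id] <- ifelse(cls == "OVERLAP_ANTISENSE",
                                      "RECOVERED_OVERLAP",
                                      "RECOVERED_LINCRNA")
  }

  # attribute the rest to the first failing filter of their
  # best-overlapping candidate
  first_fail <- first_failed_filter(cands)
  rest <- ov[!(ov$withheld_id %in% names(status)[grepl("^RECOVERED",
                                                       status)]), ,
             drop = FALSE]
  if (nrow(rest)) {
    rest <- rest[order(-rest$fraction), , drop = FALSE]
    rest <- rest[!duplicated(rest$withheld_id), , drop = FALSE]
    ff <- first_fail[rest$candidate_id]
    lab <- c(length = "FILTERED_LENGTH", `repeat` = "FILTERED_REPEAT",
             expression = "FILTERED_EXPRESSION",
             coding_potential = "FILTERED_CODING")
    has_fail <- !is.na(ff)
    status[rest$withheld_id[has_fail]] <- lab[ff[has_fail]]
    # overlapping a candidate that itself passed but under min_overlap:
    # still effectively not assembled to sufficient completeness
  }

  if (!is.null(fragments) && nrow(wtx)) {
    wex <- exon_ranges(withheld)
    fgr <- GenomicRanges::GRanges(fragments$chrom,
                                  IRanges::IRanges(fragments$start,
                                                   fragments$end))
    h <- find_overlaps_quiet(wex, fgr, ignore.strand = TRUE)
    covered <- unique(S4Vectors::mcols(wex)$transcript_id[
      S4Vectors::queryHits(h)])
    status[setdiff(wtx$transcript_id, covered)] <- "NOT_COVERED"
  }
  status
}

# first failed filter per candidate, in cascade order, from the trace
first_failed_filter <- function(cands) {
  ids <- cands$ann$tx$transcript_id
  out <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (f in c("length", "repeat", "expression", "coding_potential")) {
    tr <- cands$trace[cands$trace$filter == f & !cands$trace$passed, ]
    sel <- tr$transcript_id[is.na(out[tr$transcript_id])]
    out[sel] <- f
  }
  out
}

#' Recovery funnel report
#'
#' Aggregates per-withheld-transcript statuses into the recovery funnel:
#' withheld -> covered -> assembled -> recovered / filtered. The recall is
#' `100 * (recovered lincRNA + recovered overlapping) / assembled`,
#' rounded to one decimal; with nothing assembled it is reported as `NA`.
#' Length- and coding-filtered transcripts are pooled into
#' `n_filtered_other`. The funnel always conserves:
#' `n_assembled = recovered + sum(per-filter losses)`.
#'
#' @param statuses character vector of statuses from [match_recovered()]
#'   (counts of `NOT_COVERED` reduce `n_covered`; `NOT_ASSEMBLED` reduces
#'   `n_assembled`).
#' @param n_withheld,n_covered optional explicit funnel heads; by default
#'   derived from `statuses`.
#' @return an `EvalReport` list with the funnel counts and `recall_pct`.
#' @export
recall_report <- function(statuses, n_withheld = NULL, n_covered = NULL) {
  tab <- function(x) sum(statuses == x)
  rep_ <- list(
    n_withheld = if (is.null(n_withheld)) length(statuses) else n_withheld,
    n_covered = if (is.null(n_covered)) sum(statuses != "NOT_COVERED")
                else n_covered,
    n_recovered_lincrna = tab("RECOVERED_LINCRNA"),
    n_recovered_overlap = tab("RECOVERED_OVERLAP"),
    n_filtered_repeat = tab("FILTERED_REPEAT"),
    n_filtered_expression = tab("FILTERED_EXPRESSION"),
    n_filtered_other = tab("FILTERED_LENGTH") + tab("FILTERED_CODING")
  )
  rep_$n_assembled <- rep_$n_recovered_lincrna + rep_$n_recovered_overlap +
    rep_$n_filtered_repeat + rep_$n_filtered_expression +
    rep_$n_filtered_other
  rep_$recall_pct <- if (rep_$n_assembled > 0) {
    round(100 * (rep_$n_recovered_lincrna + rep_$n_recovered_overlap) /
            rep_$n_assembled, 1)
  } else NA_real_
  structure(rep_, class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat("Withhold-and-recover funnel\n")
  cat(sprintf("  withheld:   %d\n", x$n_withheld))
  cat(sprintf("  covered:    %d\n", x$n_covered))
  cat(sprintf("  assembled:  %d\n", x$n_assembled))
  cat(sprintf("  recovered:  %d lincRNA + %d overlapping\n",
              x$n_recovered_lincrna, x$n_recovered_overlap))
  cat(sprintf("  filtered:   %d repeat, %d expression, %d other\n",
              x$n_filtered_repeat, x$n_filtered_expression,
              x$n_filtered_other))
  cat(sprintf("  recall:     %s%%\n",
              ifelse(is.na(x$recall_pct), "NA", x$recall_pct)))
  invisible(x)
}
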