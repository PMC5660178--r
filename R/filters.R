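#' Filter cascade configuration
#'
#' Tunable thresholds for the candidate filter cascade. Defaults follow the
#' discovery rules: candidates shorter than 200 bp are removed (strict
#' `<`), single-exon candidates longer than 10,000 bp are removed (strict
#' `>`), single-exon candidates with more than half of their exonic bases
#' inside repeat/low-complexity regions are removed (multi-exon candidates
#' are exempt from the repeat rule), and expression bounds are derived per
#' sample from the expressed known transcripts: the (0.05, 0.95) quantiles
#' for single-exon candidates (both tails are noise-prone) and the 0.05
#' quantile as a lower bound only for multi-exon candidates (incompletely
#' constructed models sit at low expression; there is no upper bound).
#'
#' @param min_length_bp minimum exonic length in bp.
#' @param max_single_exon_length_bp maximum exonic length for single-exon
#'   candidates.
#' @param repeat_overlap_max_fraction maximum tolerated fraction of a
#'   single-exon candidate's exonic bases overlapping repeats; `0` means
#'   any overlap fails.
#' @param single_exon_expr_quantiles length-2 numeric `(q_low, q_high)` on
#'   the known single-exon expression distribution.
#' @param multi_exon_expr_quantile `q_low` on the known multi-exon
#'   expression distribution.
#' @param min_reference_n minimum number of expressed known transcripts per
#'   exon class before the cutoffs fall back to the pooled distribution.
#' @return a `FilterConfig` list.
#' @export
filter_config <- function(min_length_bp = 200L,
                          max_single_exon_length_bp = 10000L,
                          repeat_overlap_max_fraction = 0.5,
                          single_exon_expr_quantiles = c(0.05, 0.95),
                          multi_exon_expr_quantile = 0.05,
                          min_reference_n = 20L) {
  stopifnot(min_length_bp > 0L, max_single_exon_length_bp > 0L,
            repeat_overlap_max_fraction >= 0, repeat_overlap_max_fraction <= 1,
            length(single_exon_expr_quantiles) == 2L,
            single_exon_expr_quantiles[1] >= 0,
            single_exon_expr_quantiles[1] < single_exon_expr_quantiles[2],
            single_exon_expr_quantiles[2] <= 1,
            multi_exon_expr_quantile >= 0, multi_exon_expr_quantile < 1)
  structure(list(min_length_bp = as.integer(min_length_bp),
                 max_single_exon_length_bp = as.integer(max_single_exon_length_bp),
                 repeat_overlap_max_fraction = repeat_overlap_max_fraction,
                 single_exon_expr_quantiles = single_exon_expr_quantiles,
                 multi_exon_expr_quantile = multi_exon_expr_quantile,
                 min_reference_n = as.integer(min_reference_n)),
            class = "FilterConfig")
}

#' Length filter
#'
#' Fails candidates whose exonic length is below `min_length_bp`
#' (strictly), and single-exon candidates whose length exceeds
#' `max_single_exon_length_bp` (strictly). Boundary values 200 and 10,000
#' pass.
#'
#' @param cands a `CandidateSet`.
#' @param cfg a [filter_config()].
#' @return the `CandidateSet` with a `"length"` entry appended to every
#'   candidate's filter trace.
#' @export
length_filter <- function(cands, cfg = filter_config()) {
  tx <- cands$ann$tx
  if (!nrow(tx)) return(cands)
  len <- tx$exonic_length
  single <- tx$n_exons == 1L
  too_short <- len < cfg$min_length_bp
  too_long <- single & len > cfg$max_single_exon_length_bp
  passed <- !(too_short | too_long)
  detail <- ifelse(too_short,
                   sprintf("exonic length %d < %d", len, cfg$min_length_bp),
            ifelse(too_long,
                   sprintf("single-exon length %d > %d", len,
                           cfg$max_single_exon_length_bp),
                   sprintf("exonic length %d", len)))
  append_trace(cands, tx$transcript_id, "length", passed, detail)
}

#' Repeat-overlap fraction of candidate exonic bases
#'
#' Computes, strand-blind, the fraction of each candidate's exonic bases
#' covered by the repeat track. Overlapping repeat intervals are flattened
#' first so no base is counted twice.
#' @param ann an `AnnotationSet`.
#' @param repeats a `RepeatTrack`.
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
repeat_overlap_fraction <- function(ann, repeats) {
  ids <- ann$tx$transcript_id
  out <- stats::setNames(rep(0, length(ids)), ids)
  if (!length(ids) || !length(repeats$intervals)) return(out)
  ex <- exon_ranges(ann)
  GenomicRanges::strand(ex) <- "*"
  rep_flat <- GenomicRanges::reduce(repeats$intervals, ignore.strand = TRUE)
  hits <- find_overlaps_quiet(ex, rep_flat, ignore.strand = TRUE)
  if (length(hits)) {
    inter_w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(ex)[S4Vectors::queryHits(hits)],
      IRanges::ranges(rep_flat)[S4Vectors::subjectHits(hits)]))
    txid <- S4Vectors::mcols(ex)$transcript_id[S4Vectors::queryHits(hits)]
    cov <- tapply(inter_w, txid, sum)
    out[names(cov)] <- as.numeric(cov) /
      ann$tx$exonic_length[match(names(cov), ids)]
  }
  out
}

#' Repeat filter
#'
#' Single-exon candidates fail when more than
#' `repeat_overlap_max_fraction` of their exonic bases overlap the repeat
#' track (strand-blind). Multi-exon candidates are exempt: their spliced
#' structure is itself evidence against a repeat artifact.
#'
#' @inheritParams length_filter
#' @param repeats a `RepeatTrack`.
#' @return the `CandidateSet` with a `"repeat"` trace entry per candidate.
#' @export
repeat_filter <- function(cands, repeats, cfg = filter_config()) {
  tx <- cands$ann$tx
  if (!nrow(tx)) return(cands)
  frac <- repeat_overlap_fraction(cands$ann, repeats)[tx$transcript_id]
  single <- tx$n_exons == 1L
  passed <- !single | frac <= cfg$repeat_overlap_max_fraction
  detail <- ifelse(!single, "exempt (multi-exon)",
                   sprintf("repeat overlap fraction %.3f (max %.3f)",
                           frac, cfg$repeat_overlap_max_fraction))
  append_trace(cands, tx$transcript_id, "repeat", passed, detail)
}

#' Derive sample-specific expression cutoffs
#'
#' Computes empirical quantile bounds on the expression of the known
#' transcripts observed in one sample, separately for single-exon and
#' multi-exon reference classes (restricted to expression > 0). Quantiles
#' use the linear-interpolation (type-7) convention for reproducibility.
#' When a class has fewer than `min_reference_n` expressed reference
#' transcripts, its quantiles are computed on the pooled expressed
#' reference set instead; with no expressed reference transcripts at all
#' the function errors and absolute fallback cutoffs must be supplied by
#' the caller.
#'
#' Because the cutoffs are quantiles of what was actually observed,
#' samples sequenced at lower depth get lower absolute cutoffs — the
#' sample-specific behavior the cascade depends on.
#'
#' @param known the reference `AnnotationSet` (used for exon counts).
#' @param sample_expression named numeric vector, known transcript id to
#'   expression in this sample.
#' @param cfg a [filter_config()].
#' @param sample_id label recorded in the result.
#' @return an `ExpressionCutoffs` list: `single_exon_low`,
#'   `single_exon_high`, `multi_exon_low`, reference set sizes, and the
#'   sample id.
#' @export
derive_expression_cutoffs <- function(known, sample_expression,
                                      cfg = filter_config(),
                                      sample_id = NA_character_) {
  expr <- sample_expression[!is.na(sample_expression) & sample_expression > 0]
  if (!length(expr)) {
    stop("no expressed known transcripts in this sample; ",
         "supply absolute fallback cutoffs via expression_cutoffs()")
  }
  nex <- known$tx$n_exons[match(names(expr), known$tx$transcript_id)]
  single <- expr[!is.na(nex) & nex == 1L]
  multi <- expr[!is.na(nex) & nex > 1L]
  q <- cfg$single_exon_expr_quantiles
  ref_single <- if (length(single) >= cfg$min_reference_n) single else expr
  ref_multi <- if (length(multi) >= cfg$min_reference_n) multi else expr
  se <- stats::quantile(ref_single, probs = q, type = 7, names = FALSE)
  me <- stats::quantile(ref_multi, probs = cfg$multi_exon_expr_quantile,
                        type = 7, names = FALSE)
  expression_cutoffs(single_exon_low = se[1], single_exon_high = se[2],
                     multi_exon_low = me, n_known_single = length(single),
                     n_known_multi = length(multi), sample_id = sample_id)
}

#' Construct expression cutoffs directly
#' @param single_exon_low,single_exon_high bounds applied to single-exon
#'   candidates (inclusive).
#' @param multi_exon_low lower bound applied to multi-exon candidates.
#' @param n_known_single,n_known_multi reference set sizes (bookkeeping).
#' @param sample_id sample label.
#' @return an `ExpressionCutoffs` list.
#' @export
expression_cutoffs <- function(single_exon_low, single_exon_high,
                               multi_exon_low, n_known_single = NA_integer_,
                               n_known_multi = NA_integer_,
                               sample_id = NA_character_) {
  stopifnot(single_exon_low <= single_exon_high,
            single_exon_low >= 0, multi_exon_low >= 0)
  structure(list(sample_id = sample_id,
                 single_exon_low = unname(single_exon_low),
                 single_exon_high = unname(single_exon_high),
                 multi_exon_low = unname(multi_exon_low),
                 n_known_single = n_known_single,
                 n_known_multi = n_known_multi),
            class = "ExpressionCutoffs")
}

#' Expression filter
#'
#' Single-exon candidates must fall inside
#' `[single_exon_low, single_exon_high]` (both tails are removed as likely
#' technical noise); multi-exon candidates must reach `multi_exon_low`
#' (no upper bound). Candidates without an expression value fail.
#'
#' @inheritParams length_filter
#' @param cutoffs an [expression_cutoffs()] /
#'   [derive_expression_cutoffs()] result.
#' @return the `CandidateSet` with an `"expression"` trace entry per
#'   candidate.
#' @export
expression_filter <- function(cands, cutoffs) {
  tx <- cands$ann$tx
  if (!nrow(tx)) return(cands)
  expr <- tx$expression
  single <- tx$n_exons == 1L
  no_expr <- is.na(expr)
  passed <- ifelse(no_expr, FALSE,
            ifelse(single,
                   expr >= cutoffs$single_exon_low & expr <= cutoffs$single_exon_high,
                   expr >= cutoffs$multi_exon_low))
  detail <- ifelse(no_expr, "no expression value",
            ifelse(single,
                   sprintf("FPKM %.4g vs single-exon bounds [%.4g, %.4g]",
                           expr, cutoffs$single_exon_low, cutoffs$single_exon_high),
                   sprintf("FPKM %.4g vs multi-exon lower bound %.4g",
                           expr, cutoffs$multi_exon_low)))
  append_trace(cands, tx$transcript_id, "expression", passed, detail)
}

#' Run the filter cascade
#'
#' Applies length, repeat and expression filters in that fixed order.
#' Every candidate is traced through all three filters, but the per-filter
#' failure counts attribute each failing candidate to the FIRST filter it
#' failed, so the counts always conserve:
#' `input = survivors + sum(per-filter failures)`.
#'
#' @param cands a `CandidateSet` (status `PENDING`).
#' @param repeats a `RepeatTrack`.
#' @param known the reference `AnnotationSet`.
#' @param sample_expression named expression vector of known transcripts in
#'   this sample (see [derive_expression_cutoffs()]); alternatively pass
#'   precomputed `cutoffs`.
#' @param cfg a [filter_config()].
#' @param cutoffs optional precomputed [expression_cutoffs()].
#' @return a list: `candidates` (the traced `CandidateSet`; failing
#'   candidates have status `FILTERED`, survivors keep `PENDING` until
#'   coding-potential scoring), `counts` (named: input, passed,
#'   failed_length, failed_repeat, failed_expression), `cutoffs`, and
#'   `first_failure` (named vector: first failing filter per candidate or
#'   `NA`).
#' @export
run_cascade <- function(cands, repeats, known, sample_expression = NULL,
                        cfg = filter_config(), cutoffs = NULL) {
  if (is.null(cutoffs)) {
    cutoffs <- derive_expression_cutoffs(known, sample_expression, cfg,
                                         sample_id = cands$ann$tx$source_sample[1])
  }
  cands <- length_filter(cands, cfg)
  cands <- repeat_filter(cands, repeats, cfg)
  cands <- expression_filter(cands, cutoffs)

  ids <- cands$ann$tx$transcript_id
  first_fail <- rep(NA_character_, length(ids))
  names(first_fail) <- ids
  for (f in c("length", "repeat", "expression")) {
    tr <- cands$trace[cands$trace$filter == f, ]
    failed <- tr$transcript_id[!tr$passed]
    sel <- is.na(first_fail[failed])
    first_fail[failed[sel]] <- f
  }
  cands$status[ids] <- ifelse(is.na(first_fail), "PENDING", "FILTERED")
  counts <- c(input = length(ids),
              passed = sum(is.na(first_fail)),
              failed_length = sum(first_fail == "length", na.rm = TRUE),
              failed_repeat = sum(first_fail == "repeat", na.rm = TRUE),
              failed_expression = sum(first_fail == "expression", na.rm = TRUE))
  list(candidates = cands, counts = counts, cutoffs = cutoffs,
       first_failure = first_fail)
}
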