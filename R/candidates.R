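#' Candidate classes
#'
#' Every assembled transcript falls into exactly one of four classes when
#' compared against the reference annotation:
#' `KNOWN` (matches an annotated transcript by id or structure),
#' `LINCRNA` (no overlap with any known transcript on either strand),
#' `OVERLAP_ANTISENSE` (stranded data only: every overlap is with
#' opposite-strand known transcripts), and
#' `REJECTED_SENSE_OVERLAP` (any same-strand overlap; in unstranded mode,
#' any overlap at all, since only intergenic lncRNAs are callable without
#' strand information).
#' @name candidate-classes
NULL

CANDIDATE_CLASSES <- c("LINCRNA", "OVERLAP_ANTISENSE", "KNOWN",
                       "REJECTED_SENSE_OVERLAP")

# Structure-level KNOWN matching: assembler ids are arbitrary, so a
# transcript is treated as known when its id exists in the reference, when
# its intron chain exactly matches a known transcript on the same
# chrom/strand, or (single-exon) when its span lies within a known
# single-exon transcript's span on the same strand. Returns the matched
# known transcript id or NA per assembled transcript.
match_known_structure <- function(assembled, known) {
  atx <- assembled$tx
  ktx <- known$tx
  out <- rep(NA_character_, nrow(atx))
  if (!nrow(atx) || !nrow(ktx)) return(stats::setNames(out, atx$transcript_id))

  # 1. identity passthrough by transcript id
  i <- match(atx$transcript_id, ktx$transcript_id)
  out[!is.na(i)] <- ktx$transcript_id[i[!is.na(i)]]

  # 2. exact intron-chain match (multi-exon)
  akeys <- intron_chain_keys(assembled)
  kkeys <- intron_chain_keys(known)
  j <- match(akeys, kkeys)
  hit <- is.na(out) & !is.na(akeys) & !is.na(j)
  out[hit] <- ktx$transcript_id[j[hit]]

  # 3. single-exon containment within a known single-exon span, same strand
  se_a <- which(is.na(out) & atx$n_exons == 1L)
  se_k <- which(ktx$n_exons == 1L)
  if (length(se_a) && length(se_k)) {
    qa <- GenomicRanges::GRanges(atx$chrom[se_a],
                                 IRanges::IRanges(atx$start[se_a], atx$end[se_a]))
    sk <- GenomicRanges::GRanges(ktx$chrom[se_k],
                                 IRanges::IRanges(ktx$start[se_k], ktx$end[se_k]))
    ov <- find_overlaps_quiet(qa, sk, type = "within")
    if (length(ov)) {
      qs <- atx$strand[se_a][S4Vectors::queryHits(ov)]
      ss <- ktx$strand[se_k][S4Vectors::subjectHits(ov)]
      ok <- qs == ss | qs == "." | ss == "."
      ov <- ov[ok]
      if (length(ov)) {
        first <- !duplicated(S4Vectors::queryHits(ov))
        out[se_a[S4Vectors::queryHits(ov)[first]]] <-
          ktx$transcript_id[se_k[S4Vectors::subjectHits(ov)[first]]]
      }
    }
  }
  stats::setNames(out, atx$transcript_id)
}

#' Classify assembled transcripts against a reference annotation
#'
#' Strand-aware classification of every transcript in `assembled` into one
#' of the four [candidate classes][candidate-classes]. The overlap test
#' defaults to transcript-span overlap of at least 1 bp; `overlap_level =
#' "exon"` restricts it to exon-vs-exon overlap. In `unstranded` mode any
#' overlap rejects the transcript because antisense transcription cannot be
#' separated from its host gene without strand information.
#'
#' Transcripts on a chromosome absent from the reference are classified
#' `LINCRNA` with a warning (no overlap is determinable there).
#'
#' @param assembled an `AnnotationSet` of assembled transcripts.
#' @param known the reference `AnnotationSet`.
#' @param mode `"stranded"` or `"unstranded"`.
#' @param overlap_level `"span"` (default) or `"exon"`.
#' @return named character vector of classes, one per assembled transcript.
#' @export
classify_transcripts <- function(assembled, known,
                                 mode = c("stranded", "unstranded"),
                                 overlap_level = c("span", "exon")) {
  mode <- match.arg(mode)
  overlap_level <- match.arg(overlap_level)
  atx <- assembled$tx
  cls <- rep(NA_character_, nrow(atx))
  names(cls) <- atx$transcript_id
  if (!nrow(atx)) return(cls)

  known_match <- match_known_structure(assembled, known)
  cls[!is.na(known_match)] <- "KNOWN"

  off_chrom <- !(atx$chrom %in% known$tx$chrom)
  if (any(off_chrom & is.na(cls))) {
    warning(sum(off_chrom & is.na(cls)),
            " transcript(s) on chromosome(s) absent from the reference; ",
            "classified LINCRNA (no overlap determinable)")
  }

  todo <- which(is.na(cls))
  if (!length(todo)) return(cls)

  if (overlap_level == "span") {
    q <- GenomicRanges::GRanges(atx$chrom[todo],
                                IRanges::IRanges(atx$start[todo], atx$end[todo]))
    s <- GenomicRanges::GRanges(known$tx$chrom,
                                IRanges::IRanges(known$tx$start, known$tx$end))
    s_tx <- known$tx$transcript_id
    ov <- find_overlaps_quiet(q, s, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  } else {
    aex <- exon_ranges(assembled)
    a_id <- S4Vectors::mcols(aex)$transcript_id
    sel <- a_id %in% atx$transcript_id[todo]
    q <- aex[sel]
    s <- exon_ranges(known)
    ov <- find_overlaps_quiet(q, s, ignore.strand = TRUE)
    qh <- match(a_id[sel][S4Vectors::queryHits(ov)], atx$transcript_id[todo])
    s_tx <- S4Vectors::mcols(s)$transcript_id[S4Vectors::subjectHits(ov)]
    sh <- match(s_tx, known$tx$transcript_id)
    sh_dup <- duplicated(paste(qh, sh))
    qh <- qh[!sh_dup]; sh <- sh[!sh_dup]
  }

  a_strand <- atx$strand[todo]
  k_strand <- known$tx$strand
  same <- logical(length(todo))
  anyov <- logical(length(todo))
  if (length(qh)) {
    ss <- k_strand[sh]
    qs <- a_strand[qh]
    is_same <- qs == ss | qs == "." | ss == "."
    anyov[unique(qh)] <- TRUE
    same[unique(qh[is_same])] <- TRUE
  }
  cls[todo[!anyov]] <- "LINCRNA"
  if (mode == "stranded") {
    cls[todo[anyov & !same]] <- "OVERLAP_ANTISENSE"
    cls[todo[anyov & same]] <- "REJECTED_SENSE_OVERLAP"
  } else {
    cls[todo[anyov]] <- "REJECTED_SENSE_OVERLAP"
  }
  cls
}

#' Classify a single transcript
#'
#' Convenience wrapper around [classify_transcripts()] for one transcript.
#' @param t an `AnnotationSet` containing exactly one transcript.
#' @inheritParams classify_transcripts
#' @return a single class string.
#' @export
classify_transcript <- function(t, known, mode = c("stranded", "unstranded"),
                                overlap_level = c("span", "exon")) {
  stopifnot(n_transcripts(t) == 1L)
  unname(classify_transcripts(t, known, mode, overlap_level))
}

#' Candidate sets
#'
#' A `CandidateSet` is the per-candidate ledger carried through the filter
#' cascade and coding-potential scoring: the candidate transcripts
#' themselves, their classification, an ordered filter trace
#' (filter name, pass/fail, detail), coding scores, and a final status in
#' `{PENDING, PASSED, FILTERED}`.
#'
#' @param ann `AnnotationSet` of the candidate transcripts.
#' @param class named class vector (values `LINCRNA` /
#'   `OVERLAP_ANTISENSE`).
#' @return a `CandidateSet` object.
#' @export
candidate_set <- function(ann, class) {
  ids <- ann$tx$transcript_id
  stopifnot(all(ids %in% names(class)))
  structure(list(
    ann = ann,
    class = class[ids],
    trace = data.frame(transcript_id = character(), filter = character(),
                       passed = logical(), detail = character(),
                       stringsAsFactors = FALSE),
    scores = data.frame(transcript_id = ids,
                        score_a = rep(NA_real_, length(ids)),
                        score_b = rep(NA_real_, length(ids)),
                        noncoding = rep(NA, length(ids)),
                        stringsAsFactors = FALSE),
    status = stats::setNames(rep("PENDING", length(ids)), ids)
  ), class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet: %d candidates (%s)\n", length(x$status),
              paste(sprintf("%s=%d", names(table(x$class)), table(x$class)),
                    collapse = ", ")))
  st <- table(x$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  invisible(x)
}

append_trace <- function(cands, ids, filter, passed, detail) {
  cands$trace <- rbind(cands$trace, data.frame(
    transcript_id = ids, filter = filter, passed = passed,
    detail = detail, stringsAsFactors = FALSE))
  cands
}

#' Extract novel transcript candidates
#'
#' Runs [classify_transcripts()] over an assembled sample and returns the
#' `LINCRNA` / `OVERLAP_ANTISENSE` transcripts as a [candidate_set()] with
#' status `PENDING`, plus a summary of the partition
#' (`assembled_total = known_matched + rejected + candidates`) and the
#' expression of the known-matched transcripts (keyed by the *known*
#' transcript id), which downstream feeds the sample-specific expression
#' cutoffs.
#'
#' @inheritParams classify_transcripts
#' @return a list with elements `candidates` (a `CandidateSet`), `summary`
#'   (counts), and `known_expression` (named numeric vector).
#' @export
extract_candidates <- function(assembled, known,
                               mode = c("stranded", "unstranded"),
                               overlap_level = c("span", "exon")) {
  mode <- match.arg(mode)
  overlap_level <- match.arg(overlap_level)
  cls <- classify_transcripts(assembled, known, mode, overlap_level)
  keep <- names(cls)[cls %in% c("LINCRNA", "OVERLAP_ANTISENSE")]
  summary <- list(
    assembled_total = length(cls),
    known_matched = sum(cls == "KNOWN"),
    rejected = sum(cls == "REJECTED_SENSE_OVERLAP"),
    candidates = length(keep)
  )
  known_match <- match_known_structure(assembled, known)
  km <- known_match[!is.na(known_match)]
  expr <- assembled$tx$expression[match(names(km), assembled$tx$transcript_id)]
  known_expression <- stats::setNames(expr, unname(km))
  known_expression <- known_expression[!is.na(known_expression)]

  cand_ann <- subset_transcripts(assembled, keep)
  list(candidates = candidate_set(cand_ann, cls[keep]),
       summary = summary,
       known_expression = known_expression)
}
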