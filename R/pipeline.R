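#' Pipeline configuration
#'
#' Assembles and validates the declarative configuration the end-to-end
#' runner consumes. Inputs may be file paths (GTF/BED/FASTA/fragment TSV)
#' or in-memory objects (`AnnotationSet`, `RepeatTrack`,
#' [Biostrings::DNAStringSet], fragment `data.frame`), so the same surface
#' serves scripted runs and programmatic use.
#'
#' @param mode `"stranded"` or `"unstranded"`.
#' @param known reference annotation: GTF path or `AnnotationSet`.
#' @param repeats repeat track: BED path or `RepeatTrack`.
#' @param genome genome: FASTA path or [Biostrings::DNAStringSet]
#'   (`NULL` disables coding-potential scoring).
#' @param samples named list; each element a list with `assembled` (GTF
#'   path or `AnnotationSet`) and optional `fragments` (TSV/SAM path or
#'   fragment `data.frame`).
#' @param filter a [filter_config()].
#' @param coding_threshold,coding_mode combination settings for the two
#'   noncoding scorers.
#' @param overlap_level `"span"` or `"exon"` classification overlap.
#' @param nearest_method `"tss_to_tss"` or `"span_gap"`.
#' @param out_dir optional output directory for reports.
#' @param seed integer seed (scorer training and any sampling).
#' @return a validated `PipelineConfig` list.
#' @export
pipeline_config <- function(mode = c("stranded", "unstranded"),
                            known, repeats, genome = NULL, samples,
                            filter = filter_config(),
                            coding_threshold = 0.9,
                            coding_mode = c("union", "intersection"),
                            overlap_level = c("span", "exon"),
                            nearest_method = c("tss_to_tss", "span_gap"),
                            out_dir = NULL, seed = 1L) {
  mode <- match.arg(mode)
  coding_mode <- match.arg(coding_mode)
  overlap_level <- match.arg(overlap_level)
  nearest_method <- match.arg(nearest_method)
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  for (x in list(known, repeats)) {
    if (is.character(x) && !file.exists(x)) stop("no such file: ", x)
  }
  if (is.character(genome) && !file.exists(genome)) {
    stop("no such file: ", genome)
  }
  for (s in samples) {
    if (is.character(s$assembled) && !file.exists(s$assembled)) {
      stop("no such file: ", s$assembled)
    }
  }
  structure(list(mode = mode, known = known, repeats = repeats,
                 genome = genome, samples = samples, filter = filter,
                 coding_threshold = coding_threshold,
                 coding_mode = coding_mode, overlap_level = overlap_level,
                 nearest_method = nearest_method, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' File-based equivalent of [pipeline_config()]: keys mirror its
#' arguments; `samples` is a map of sample id to `{assembled, fragments}`
#' paths (relative paths resolve against the YAML file's directory).
#' @param path YAML file.
#' @param overrides named list of keys overriding the file values.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  y <- yaml::read_yaml(path)
  y[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  rp <- function(f) {
    if (is.null(f) || !is.character(f)) return(f)
    if (grepl("^(/|~|[A-Za-z]:)", f)) f else file.path(base, f)
  }
  samples <- lapply(y$samples, function(s) {
    list(assembled = rp(s$assembled), fragments = rp(s$fragments))
  })
  fc_args <- y$filter
  fc <- if (is.null(fc_args)) filter_config() else do.call(filter_config, fc_args)
  pipeline_config(
    mode = y$mode %||% "stranded",
    known = rp(y$known), repeats = rp(y$repeats), genome = rp(y$genome),
    samples = samples, filter = fc,
    coding_threshold = y$coding_threshold %||% 0.9,
    coding_mode = y$coding_mode %||% "union",
    overlap_level = y$overlap_level %||% "span",
    nearest_method = y$nearest_method %||% "tss_to_tss",
    out_dir = rp(y$out_dir), seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_known <- function(x) if (inherits(x, "AnnotationSet")) x else read_gtf(x)
load_repeats <- function(x) if (inherits(x, "RepeatTrack")) x else read_bed(x)
load_genome <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) {
    g <- Biostrings::readDNAStringSet(x)
    names(g) <- sub("\\s.*$", "", names(g))
    g
  } else x
}
load_assembled <- function(x, sid) {
  if (inherits(x, "AnnotationSet")) x else read_gtf(x, source_sample = sid)
}
load_fragments <- function(x, sid) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x else read_fragments(x, sample_id = sid)
}

.scorer_cache <- new.env(parent = emptyenv())

#' Default noncoding scorer pair
#'
#' Trains scorer A (ORF-based features) and scorer B (composition
#' features) on the synthetic codon-biased training set; deterministic
#' given the seed, and cached per seed within the session.
#' @param seed integer seed.
#' @return list with `scorer_a` and `scorer_b`.
#' @export
default_scorers <- function(seed = 1L) {
  key <- as.character(seed)
  if (!is.null(.scorer_cache[[key]])) return(.scorer_cache[[key]])
  tr <- synth_training_sequences(seed = seed)
  out <- list(
    scorer_a = train_scorer(tr$coding, tr$noncoding, "orf", seed = seed),
    scorer_b = train_scorer(tr$coding, tr$noncoding, "composition",
                            seed = seed))
  .scorer_cache[[key]] <- out
  out
}

#' Run a single sample through extraction, filtering and scoring
#'
#' The per-sample stage of the pipeline: classify the assembled
#' transcripts against the reference, run the filter cascade with
#' sample-specific expression cutoffs, and (when a genome is available)
#' finalize with coding-potential scoring.
#'
#' @param assembled the sample's assembled `AnnotationSet`.
#' @param known reference `AnnotationSet`.
#' @param repeats `RepeatTrack`.
#' @param genome [Biostrings::DNAStringSet] or `NULL`.
#' @param scorers a [default_scorers()]-shaped list, required with a
#'   genome.
#' @param mode,overlap_level,cfg,coding_threshold,coding_mode see
#'   [pipeline_config()].
#' @return list: `candidates` (finalized `CandidateSet`), `extraction`
#'   (partition summary), `cascade_counts`, `cutoffs`.
#' @export
predict_sample <- function(assembled, known, repeats, genome = NULL,
                           scorers = NULL,
                           mode = c("stranded", "unstranded"),
                           overlap_level = "span", cfg = filter_config(),
                           coding_threshold = 0.9, coding_mode = "union") {
  mode <- match.arg(mode)
  if (mode == "stranded" && nrow(assembled$tx) &&
      all(assembled$tx$strand == ".")) {
    stop("stranded mode but every assembled transcript is unstranded ('.');",
         " check the assembly/aligner strandedness settings")
  }
  check_chromosome_names(assembled$tx$chrom, known$tx$chrom,
                         "assembled transcripts and reference annotation")
  ext <- extract_candidates(assembled, known, mode, overlap_level)
  casc <- run_cascade(ext$candidates, repeats, known,
                      sample_expression = ext$known_expression, cfg = cfg)
  cands <- casc$candidates
  if (!is.null(genome)) {
    if (is.null(scorers)) stop("coding-potential scoring needs scorers")
    cands <- score_candidates(cands, genome, scorers$scorer_a,
                              scorers$scorer_b, coding_threshold,
                              coding_mode)
  } else {
    # without a genome the cascade survivors are final
    ids <- names(cands$status)[cands$status == "PENDING"]
    cands$status[ids] <- "PASSED"
  }
  list(candidates = cands, extraction = ext$summary,
       cascade_counts = casc$counts, cutoffs = casc$cutoffs)
}

#' Run the full multi-sample pipeline
#'
#' Per sample: candidate extraction, filter cascade, coding-potential
#' scoring. Across samples: merge of passed candidates into a unified
#' novel annotation (a pass-through when only one sample is provided),
#' fragment quantification of known + novel lncRNAs (raw counts and
#' RPKM), and nearest-coding-gene annotation. When `out_dir` is set,
#' writes `novel_merged.gtf`, `lncrna_annotation.tsv`, `counts.tsv`,
#' `rpkm.tsv`, per-sample `filter_report_<s>.tsv` and a JSON
#' `run_summary.json`.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @return a `PipelineRun` list: `per_sample` stage results, `merged`,
#'   `quant`, `annotation`, `summary`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  known <- load_known(config$known)
  repeats <- load_repeats(config$repeats)
  genome <- load_genome(config$genome)
  scorers <- if (!is.null(genome)) default_scorers(config$seed) else NULL

  per_sample <- list()
  for (sid in names(config$samples)) {
    s <- config$samples[[sid]]
    assembled <- load_assembled(s$assembled, sid)
    res <- tryCatch(
      predict_sample(assembled, known, repeats, genome, scorers,
                     mode = config$mode,
                     overlap_level = config$overlap_level,
                     cfg = config$filter,
                     coding_threshold = config$coding_threshold,
                     coding_mode = config$coding_mode),
      error = function(e) stop("sample '", sid, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    per_sample[[sid]] <- res
    message(sprintf(
      "[%s] assembled=%d known=%d rejected=%d candidates=%d passed=%d",
      sid, res$extraction$assembled_total, res$extraction$known_matched,
      res$extraction$rejected, res$extraction$candidates,
      sum(res$candidates$status == "PASSED")))
  }

  merged <- merge_candidates(lapply(per_sample, `[[`, "candidates"))
  merge_skipped <- length(per_sample) == 1L
  message(sprintf("merge: %d novel transcript(s)%s",
                  n_transcripts(merged$ann),
                  if (merge_skipped) " (merging skipped: single sample)" else ""))

  fragments <- do.call(rbind, Filter(Negate(is.null),
    lapply(names(config$samples), function(sid) {
      load_fragments(config$samples[[sid]]$fragments, sid)
    })))
  quant <- NULL
  if (!is.null(fragments) && nrow(fragments)) {
    quant <- quantify_lncrnas(known, merged$ann, fragments, config$mode)
    message(sprintf("quantified %d features over %d sample(s)",
                    nrow(quant$counts), ncol(quant$counts)))
  }

  lnc_bt <- if (config$mode == "stranded") {
    c("lincRNA", "antisense", "sense_intronic", "sense_overlapping",
      "processed_transcript", "lncRNA")
  } else "lincRNA"
  known_lnc_ids <- known$tx$transcript_id[known$tx$biotype %in% lnc_bt]
  ann_sets <- list()
  if (length(known_lnc_ids)) {
    ann_sets <- c(ann_sets, list(subset_transcripts(known, known_lnc_ids)))
  }
  if (n_transcripts(merged$ann)) ann_sets <- c(ann_sets, list(merged$ann))
  annotation <- if (length(ann_sets)) {
    all_lnc <- if (length(ann_sets) == 1L) ann_sets[[1]] else
      bind_annotation_sets(ann_sets)
    annotate_nearest_gene(all_lnc, known, config$nearest_method)
  } else NULL

  summary <- list(
    mode = config$mode, seed = config$seed,
    n_samples = length(per_sample),
    merge_skipped = merge_skipped,
    per_sample = lapply(per_sample, function(r) {
      c(r$extraction, as.list(r$cascade_counts),
        list(passed = sum(r$candidates$status == "PASSED")))
    }),
    n_novel_merged = n_transcripts(merged$ann),
    n_known_lncrna = length(known_lnc_ids)
  )
  run <- structure(list(per_sample = per_sample, merged = merged,
                        quant = quant, annotation = annotation,
                        summary = summary, known = known,
                        scorers = scorers),
                   class = "PipelineRun")
  if (!is.null(config$out_dir)) write_run_reports(run, config)
  run
}

#' @export
print.PipelineRun <- function(x, ...) {
  cat(sprintf("PipelineRun: %d sample(s), %d merged novel lncRNA(s)\n",
              x$summary$n_samples, x$summary$n_novel_merged))
  invisible(x)
}

write_run_reports <- function(run, config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  ann <- run$merged$ann
  write_gtf(ann, file.path(out, "novel_merged.gtf"))
  if (!is.null(run$annotation)) {
    meta <- rbind_fill_tx(run)
    utils::write.table(meta, file.path(out, "lncrna_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$quant)) {
    wr <- function(m, f) {
      df <- data.frame(feature = rownames(m), m, check.names = FALSE)
      utils::write.table(df, file.path(out, f), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    wr(run$quant$counts, "counts.tsv")
    wr(run$quant$rpkm, "rpkm.tsv")
  }
  for (sid in names(run$per_sample)) {
    r <- run$per_sample[[sid]]
    tr <- r$candidates$trace
    st <- data.frame(transcript_id = names(r$candidates$status),
                     class = unname(r$candidates$class),
                     final_status = unname(r$candidates$status))
    utils::write.table(merge(st, tr, by = "transcript_id", all.x = TRUE),
                       file.path(out, sprintf("filter_report_%s.tsv", sid)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

# Fig-2-style feature table: location, length, exon count, nearest gene
rbind_fill_tx <- function(run) {
  feats <- if (!is.null(run$quant)) run$quant$features else run$merged$ann
  tx <- feats$tx
  loc <- sprintf("%s:%d-%d(%s)", tx$chrom, tx$start, tx$end, tx$strand)
  df <- data.frame(transcript_id = tx$transcript_id, location = loc,
                   exonic_length = tx$exonic_length, n_exons = tx$n_exons,
                   biotype = tx$biotype, stringsAsFactors = FALSE)
  ann <- run$annotation
  i <- match(df$transcript_id, ann$lncrna_id)
  df$nearest_gene <- ann$nearest_gene_id[i]
  df$tss_distance_bp <- ann$distance_bp[i]
  df$orientation <- ann$orientation[i]
  df
}

# combine per-sample candidate sets under sample-prefixed ids so recovery
# matching can consider every sample's evidence at once
combine_candidate_sets <- function(cand_list) {
  exs <- list(); classes <- character(); statuses <- character()
  traces <- list(); scores <- list()
  for (sid in names(cand_list)) {
    cs <- cand_list[[sid]]
    ex <- exon_table(cs$ann)
    pre <- function(id) paste(sid, id, sep = "|")
    ex$transcript_id <- pre(ex$transcript_id)
    ex$gene_id <- pre(ex$gene_id)
    exs[[sid]] <- ex
    classes <- c(classes, stats::setNames(unname(cs$class),
                                          pre(names(cs$class))))
    statuses <- c(statuses, stats::setNames(unname(cs$status),
                                            pre(names(cs$status))))
    tr <- cs$trace; tr$transcript_id <- pre(tr$transcript_id)
    traces[[sid]] <- tr
    sc <- cs$scores; sc$transcript_id <- pre(sc$transcript_id)
    scores[[sid]] <- sc
  }
  ann <- annotation_set(do.call(rbind, exs))
  out <- candidate_set(ann, classes)
  out$trace <- do.call(rbind, traces)
  out$scores <- do.call(rbind, scores)
  out$status <- statuses[ann$tx$transcript_id]
  out
}

#' Withhold-and-recover evaluation run
#'
#' Wires the evaluation end to end: screen and withhold a fraction of the
#' known lincRNAs, run the discovery pipeline against the reduced
#' annotation, match every withheld transcript against the predicted
#' candidates from all samples, and aggregate the recovery funnel.
#'
#' @param config a [pipeline_config()] (or YAML path).
#' @param fraction fraction of eligible known lincRNAs to withhold.
#' @param seed seed for the withholding draw (defaults to the config
#'   seed).
#' @param match_rule,min_overlap see [match_recovered()].
#' @return list: `report` (an `EvalReport`), `statuses`, `withheld_ids`,
#'   `run` (the underlying `PipelineRun`).
#' @export
run_eval <- function(config, fraction = 1 / 3, seed = NULL,
                     match_rule = "exon_overlap", min_overlap = 0.5) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(seed)) seed <- config$seed
  known <- load_known(config$known)
  repeats <- load_repeats(config$repeats)
  genome <- load_genome(config$genome)
  scorers <- if (!is.null(genome)) default_scorers(config$seed) else NULL

  wh <- withhold(known, fraction, seed, cfg = config$filter,
                 repeats = repeats, genome = genome,
                 scorer_a = scorers$scorer_a, scorer_b = scorers$scorer_b,
                 coding_threshold = config$coding_threshold,
                 coding_mode = config$coding_mode)

  cfg2 <- config
  cfg2$known <- wh$reduced
  cfg2$out_dir <- NULL
  run <- run_pipeline(cfg2)

  combo <- combine_candidate_sets(lapply(run$per_sample, `[[`,
                                         "candidates"))
  fragments <- do.call(rbind, Filter(Negate(is.null),
    lapply(names(config$samples), function(sid) {
      load_fragments(config$samples[[sid]]$fragments, sid)
    })))
  statuses <- match_recovered(wh$withheld, combo, rule = match_rule,
                              min_overlap = min_overlap,
                              fragments = fragments)
  report <- recall_report(statuses)
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    utils::write.table(
      data.frame(transcript_id = names(statuses), status = unname(statuses)),
      file.path(config$out_dir, "eval_statuses.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "eval_funnel.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(report = report, statuses = statuses,
       withheld_ids = wh$withheld$tx$transcript_id, run = run)
}
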