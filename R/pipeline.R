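#' Pipeline configuration
#'
#' Validated bundle of input paths, thresholds and options for
#' [run_pipeline()]. All thresholds default to the method's published
#' values: DEG/IR/AS significance p < 0.01 with a 2-fold gate, alignment
#' identity > 0.95 with >= 4 nt terminal exact matches, blocks < 8 nt
#' removed, ratio pseudocount 1, logCPM prior 0.5.
#'
#' @param annotation Path to the GFF3 annotation.
#' @param sam_wt,sam_mut Character vectors of SAM paths, one per biological
#'   replicate of each condition.
#' @param exclude Optional exclusion list (second-site splice-site loci to
#'   drop): a character vector of gene ids, a `data.frame` with `chrom`,
#'   `start`, `end`, or a path to a TSV with those columns (or a single
#'   `gene_id` column).
#' @param outdir Output directory for TSV reports (`NULL`: in-memory only).
#' @param reporter Optional reporter-locus description for variant
#'   quantification: a `reporter_locus` or a list with `chrom`,
#'   `canonical = c(start, end)`, `non_canonical = c(start, end)`.
#' @param p_cutoff,fold,identity,end_match,min_block,pseudocount,prior,anchor
#'   Thresholds (see above).
#' @param deg_on_log,ir_on_log Run the DEG / IR t-tests on log2 values.
#' @param seed Seed recorded in the run manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, sam_wt, sam_mut, exclude = NULL,
                            outdir = NULL, reporter = NULL,
                            p_cutoff = 0.01, fold = 2, identity = 0.95,
                            end_match = 4L, min_block = 8L, pseudocount = 1,
                            prior = 0.5, anchor = 8L,
                            deg_on_log = FALSE, ir_on_log = FALSE,
                            seed = 1L) {
  cfg <- as.list(environment())
  if (!length(sam_wt) || !length(sam_mut))
    stop("config validation error: replicate lists must be non-empty")
  if (length(sam_wt) != length(sam_mut))
    warning("unbalanced design: ", length(sam_wt), " wt vs ",
            length(sam_mut), " mut replicates")
  for (p in c(annotation, sam_wt, sam_mut))
    if (!file.exists(p)) stop("config validation error: missing input ", p)
  thr <- c(p_cutoff, fold, identity, end_match, min_block, prior, anchor)
  if (any(thr <= 0)) stop("config validation error: thresholds must be positive")
  if (is.character(exclude) && length(exclude) == 1L && file.exists(exclude)) {
    ex <- utils::read.delim(exclude)
    cfg$exclude <- if (all(c("chrom", "start", "end") %in% names(ex))) ex
                   else ex$gene_id
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(startsWith(p, "/"), p, file.path(base, p))
  for (k in c("annotation", "exclude"))
    if (is.character(y[[k]])) y[[k]] <- rel(y[[k]])
  for (k in c("sam_wt", "sam_mut"))
    y[[k]] <- rel(unlist(y[[k]]))
  if (!is.null(y$outdir)) y$outdir <- rel(y$outdir)
  if (!is.null(y$reporter)) {
    y$reporter <- list(chrom = y$reporter$chrom,
                       canonical = unlist(y$reporter$canonical),
                       non_canonical = unlist(y$reporter$non_canonical))
  }
  do.call(pipeline_config, y)
}

#' Run the full detection pipeline
#'
#' Executes ingest (SAM reading and acceptance filters) -> evidence layers
#' (depth, junctions, gene counts) -> TMM/logCPM/RPKM differential
#' expression -> intron-retention and AS-event testing -> optional reporter
#' quantification -> summary table. Identical config and inputs give
#' byte-identical outputs (stable sort orders, no RNG). When `outdir` is
#' set, deterministic TSV reports are written, each headed by a comment line
#' carrying the package version, a config hash, and the seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return List of class `pipeline_result`: `samples`, `groups`,
#'   `attrition` (per-sample filter drop counts), `deg`, `ir` (results +
#'   skipped), `as_events`, `reporter` (or `NULL`), `summary`, `counts`,
#'   `normalization`, and `paths` of written reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[splicegauge] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("reading annotation ", config$annotation)
  genes <- stage("annotation", read_gff3(config$annotation))

  sams <- c(setNames(config$sam_wt, paste0("wt_", seq_along(config$sam_wt))),
            setNames(config$sam_mut, paste0("mut_", seq_along(config$sam_mut))))
  groups <- sub("_[0-9]+$", "", names(sams))

  records <- list(); attrition <- list()
  for (s in names(sams)) {
    rec <- stage("ingest", read_sam(sams[s]))
    pass1 <- filter_transcriptome_pass(rec, config$identity, config$end_match)
    pass2 <- filter_short_blocks(rec, config$min_block)
    records[[s]] <- apply_filters(rec, pass1 & pass2)
    attrition[[s]] <- c(input = nrow(rec$reads), rec$skipped,
                        fail_identity_endmatch = sum(!pass1),
                        fail_short_block = sum(!pass2),
                        accepted = sum(pass1 & pass2))
    say(s, ": ", attrition[[s]]["accepted"], "/", nrow(rec$reads),
        " records accepted")
  }

  say("computing evidence layers")
  depths <- stage("depth", lapply(records, compute_depth))
  juncs <- stage("junctions", lapply(records, extract_junctions))
  jmat <- junction_matrix(juncs)
  gcounts <- stage("gene counts", gene_count_matrix(records, genes))

  say("differential expression (TMM -> logCPM -> RPKM -> t-tests)")
  counts <- gcounts$unique
  norm <- stage("normalization", {
    f <- tmm_factors(counts)
    lc <- logcpm(counts, f, prior = config$prior)
    rp <- rpkm_from_logcpm(lc, gene_lengths(genes))
    list(factors = f, logcpm = lc, rpkm = rp)
  })
  deg <- stage("DEG", call_degs(norm$rpkm, groups,
                                p_cutoff = config$p_cutoff,
                                fold = config$fold,
                                on_log = config$deg_on_log))

  say("intron retention testing")
  ir_tab <- stage("IR ratios", ir_ratio_table(depths, genes))
  ir <- stage("IR classification",
              classify_introns(ir_tab, groups, p_cutoff = config$p_cutoff,
                               fold = config$fold, on_log = config$ir_on_log,
                               exclude = config$exclude))

  say("alternative-splicing events")
  cand <- stage("AS enumeration", enumerate_as_events(jmat, genes))
  if (!is.null(config$exclude) && nrow(cand)) {
    drop <- if (is.character(config$exclude))
      cand$gene_id %in% config$exclude
    else excluded_introns(
      data.frame(gene_id = cand$gene_id, chrom = cand$chrom,
                 start = cand$donor, end = cand$acceptor),
      config$exclude)
    cand <- cand[!drop, , drop = FALSE]
  }
  as_events <- stage("AS classification",
                     classify_as_events(cand, jmat, gcounts$unique, groups,
                                        p_cutoff = config$p_cutoff,
                                        fold = config$fold,
                                        pseudocount = config$pseudocount))

  reporter <- NULL
  if (!is.null(config$reporter)) {
    say("reporter variant quantification")
    reporter <- stage("reporter",
                      quantify_variants(records, config$reporter, groups,
                                        anchor = config$anchor))
  }

  summary <- summarize_events(deg, ir$results, as_events, genes)

  res <- structure(
    list(samples = names(sams), groups = groups,
         attrition = do.call(rbind, attrition), deg = deg, ir = ir,
         as_events = as_events, reporter = reporter, summary = summary,
         counts = counts, normalization = norm, paths = character()),
    class = "pipeline_result")
  if (!is.null(config$outdir)) res$paths <- write_reports(res, config)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

write_reports <- function(res, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(unclass(config))
  hdr <- sprintf("# splicegauge %s\tconfig=%s\tseed=%d",
                 as.character(utils::packageVersion("splicegauge")),
                 hash, config$seed)
  emit <- function(df, name, order_cols = NULL) {
    if (!is.null(order_cols) && nrow(df))
      df <- df[do.call(order, df[order_cols]), , drop = FALSE]
    p <- file.path(config$outdir, name)
    writeLines(hdr, p)
    suppressWarnings(write.table(df, p, append = TRUE, sep = "\t",
                                 quote = FALSE, row.names = FALSE))
    p
  }
  paths <- c(
    deg = emit(res$deg, "deg.tsv", "gene_id"),
    ir = emit(res$ir$results, "ir.tsv", c("chrom", "start", "gene_id")),
    ir_skipped = emit(res$ir$skipped, "ir_skipped.tsv",
                      c("chrom", "start", "gene_id")),
    as_events = emit(res$as_events, "as_events.tsv",
                     c("chrom", "donor", "acceptor", "type", "gene_id")),
    summary = emit(res$summary, "summary.tsv"),
    attrition = emit(data.frame(sample_id = rownames(res$attrition),
                                res$attrition, row.names = NULL),
                     "attrition.tsv"))
  if (!is.null(res$reporter))
    paths["reporter"] <- emit(res$reporter$per_replicate, "reporter.tsv")
  manifest <- file.path(config$outdir, "manifest.yaml")
  yaml::write_yaml(list(package = "splicegauge",
                        version = as.character(utils::packageVersion("splicegauge")),
                        config_hash = hash, seed = config$seed,
                        outputs = as.list(paths)), manifest)
  c(paths, manifest = manifest)
}

#' Write a full synthetic cohort to disk
#'
#' Generates the annotation, per-replicate SAM files for both conditions,
#' and ground-truth TSV logs for a scenario; the companion of
#' [run_pipeline()] for end-to-end testing and demos. Deterministic given
#' the scenario seed.
#'
#' @param scenario A [splice_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list: `annotation` (GFF3 path), `sam_wt`, `sam_mut`
#'   (paths), `ann` (the in-memory [generate_annotation()] result),
#'   `junction_logs` (generator junction tables per sample),
#'   `fragment_counts` (genes x samples), `reporter_counts`, and `truth_paths`.
#' @export
simulate_cohort <- function(scenario, dir) {
  stopifnot(inherits(scenario, "splice_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(scenario)
  gff <- file.path(dir, "annotation.gff3")
  write_gff3(ann$genes, gff)

  sam_paths <- list(wt = character(), mut = character())
  jlogs <- list(); fcounts <- list(); rcounts <- list()
  for (cond in c("wt", "mut")) {
    for (r in seq_len(scenario$replicates)) {
      sid <- paste0(cond, "_", r)
      p <- file.path(dir, paste0(sid, ".sam"))
      sim <- simulate_alignments(scenario, ann, cond, r, path = p)
      sam_paths[[cond]] <- c(sam_paths[[cond]], p)
      jlogs[[sid]] <- sim$junctions
      fcounts[[sid]] <- sim$n_fragments
      if (!is.null(sim$reporter_counts)) rcounts[[sid]] <- sim$reporter_counts
    }
  }
  fragment_counts <- do.call(cbind, fcounts)

  tpaths <- c(
    introns = file.path(dir, "truth_introns.tsv"),
    genes = file.path(dir, "truth_genes.tsv"),
    skips = file.path(dir, "truth_skips.tsv"),
    alts = file.path(dir, "truth_alts.tsv"))
  write.table(ann$truth$introns, tpaths["introns"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ann$truth$genes, tpaths["genes"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ann$truth$skips, tpaths["skips"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ann$truth$alts, tpaths["alts"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jl <- data.table::rbindlist(lapply(names(jlogs), function(s) {
    j <- data.table::as.data.table(jlogs[[s]]); j[, sample_id := s]; j
  }), fill = TRUE)
  jpath <- file.path(dir, "truth_junctions.tsv")
  write.table(as.data.frame(jl), jpath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(annotation = gff, sam_wt = sam_paths$wt,
                 sam_mut = sam_paths$mut, ann = ann,
                 junction_logs = jlogs, fragment_counts = fragment_counts,
                 reporter_counts = rcounts,
                 truth_paths = c(tpaths, junctions = jpath)))
}

#' Compare pipeline calls against a scenario's ground truth
#'
#' Labels each planted event as detected or missed and counts false calls
#' among unplanted introns/genes, giving per-category sensitivity and
#' false-call rates.
#'
#' @param result A `pipeline_result`.
#' @param ann The matching [generate_annotation()] result.
#' @return `data.frame`: `category`, `planted`, `detected`, `sensitivity`,
#'   `false_calls`, `n_unplanted`, `false_call_rate`.
#' @export
evaluate_against_truth <- function(result, ann) {
  tr <- ann$truth
  key <- function(df) paste(df$gene_id, df$start, df$end)

  ir_res <- result$ir$results
  rows <- list()
  for (cls in c("IR", "MES")) {
    planted <- tr$introns[!is.na(tr$introns$planted) &
                            tr$introns$planted == cls, , drop = FALSE]
    called <- ir_res[ir_res$class == cls, , drop = FALSE]
    det <- sum(key(planted) %in% key(called))
    unplanted <- tr$introns[is.na(tr$introns$planted), , drop = FALSE]
    fc <- sum(key(called) %in% key(unplanted))
    rows[[cls]] <- data.frame(category = cls, planted = nrow(planted),
                              detected = det,
                              false_calls = fc,
                              n_unplanted = nrow(unplanted))
  }

  deg <- result$deg
  for (cls in c("up", "down")) {
    planted <- tr$genes$gene_id[!is.na(tr$genes$planted) &
                                  tr$genes$planted == cls]
    called <- deg$gene_id[deg$call == cls]
    unplanted <- tr$genes$gene_id[is.na(tr$genes$planted)]
    rows[[paste0("DEG_", cls)]] <-
      data.frame(category = paste0("DEG_", cls), planted = length(planted),
                 detected = sum(planted %in% called),
                 false_calls = sum(called %in% unplanted),
                 n_unplanted = length(unplanted))
  }

  ev <- result$as_events[result$as_events$reported, , drop = FALSE]
  jkey <- function(df) paste(df$chrom, df$donor, df$acceptor)
  alt_planted <- tr$alts
  rows[["alt"]] <- data.frame(
    category = "alt_site", planted = nrow(alt_planted),
    detected = sum(jkey(alt_planted) %in% jkey(ev)),
    false_calls = NA_integer_, n_unplanted = NA_integer_)
  if (nrow(tr$skips)) {
    sk_j <- paste(tr$skips$chrom, tr$skips$prev_end, tr$skips$next_start)
    rows[["skip"]] <- data.frame(
      category = "exon_skip", planted = nrow(tr$skips),
      detected = sum(sk_j %in% jkey(ev[ev$type == "exon_skip", ])),
      false_calls = NA_integer_, n_unplanted = NA_integer_)
  }

  out <- do.call(rbind, rows)
  out$sensitivity <- ifelse(out$planted > 0, out$detected / out$planted, NA)
  out$false_call_rate <- ifelse(!is.na(out$n_unplanted) & out$n_unplanted > 0,
                                out$false_calls / out$n_unplanted, NA)
  rownames(out) <- NULL
  out[, c("category", "planted", "detected", "sensitivity", "false_calls",
          "n_unplanted", "false_call_rate")]
}
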