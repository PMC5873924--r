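#' Combine per-sample junction tables into a count matrix
#'
#' @param junction_list Named list of per-sample junction tables as returned
#'   by [extract_junctions()].
#' @return `data.frame` with `chrom`, `donor`, `acceptor` and one count
#'   column per sample (zero-filled).
#' @export
junction_matrix <- function(junction_list) {
  stopifnot(length(junction_list) >= 1L, !is.null(names(junction_list)))
  tabs <- lapply(names(junction_list), function(nm) {
    j <- data.table::as.data.table(junction_list[[nm]])
    j[, sample_id := nm]
    j
  })
  long <- data.table::rbindlist(tabs)
  if (!nrow(long)) {
    out <- data.frame(chrom = character(), donor = integer(),
                      acceptor = integer())
    out[names(junction_list)] <- integer(0)
    return(out)
  }
  wide <- data.table::dcast(long, chrom + donor + acceptor ~ sample_id,
                            value.var = "count", fill = 0L)
  miss <- setdiff(names(junction_list), names(wide))
  for (m in miss) wide[[m]] <- 0L
  data.table::setcolorder(wide, c("chrom", "donor", "acceptor",
                                  names(junction_list)))
  data.table::setorder(wide, chrom, donor, acceptor)
  as.data.frame(wide)
}

#' Per-gene count matrices across samples
#'
#' @param records_list Named list of `alignment_records` (one per sample).
#' @param genes A `gene_model_set`.
#' @return List of two integer matrices (`total`, `unique`), genes x samples.
#' @export
gene_count_matrix <- function(records_list, genes) {
  stopifnot(!is.null(names(records_list)))
  tabs <- lapply(records_list, count_gene_reads, genes = genes)
  gene_id <- tabs[[1L]]$gene_id
  tot <- vapply(tabs, function(t) t$total, integer(length(gene_id)))
  uni <- vapply(tabs, function(t) t$unique, integer(length(gene_id)))
  tot <- matrix(tot, ncol = length(tabs),
                dimnames = list(gene_id, names(records_list)))
  uni <- matrix(uni, ncol = length(tabs),
                dimnames = list(gene_id, names(records_list)))
  list(total = tot, unique = uni)
}

# mean per-base depth over intervals of one chromosome's coverage vector
region_mean_depth <- function(cov_chrom, start, end) {
  if (!length(start)) return(numeric())
  v <- IRanges::Views(cov_chrom, start = start, end = end)
  IRanges::viewSums(v) / (end - start + 1)
}

#' Intron-retention ratio of one intron in one replicate
#'
#' The intron-retention ratio is the average per-base read depth over the
#' intron divided by the average per-base read depth over its two
#' neighboring exons, pooled base-wise (one average over all flanking exonic
#' bases, not the mean of two exon means). A ratio of 0 means fully spliced;
#' values near 1 mean the intron is covered like its flanks, i.e. retained.
#' When the flanking-exon depth is zero the ratio is undefined and `NA` is
#' returned (never coerced to 0 or Inf).
#'
#' @param depth An `RleList` coverage profile from [compute_depth()].
#' @param gene A `gene_model`.
#' @param intron_index 1-based index into `gene$introns`.
#' @return A single numeric ratio, or `NA` if undefined.
#' @export
intron_retention_ratio <- function(depth, gene, intron_index) {
  intr <- gene$introns[intron_index, ]
  fl <- neighboring_exons(gene, intron_index)
  cv <- depth[[gene$chrom]]
  isum <- sum(IRanges::viewSums(IRanges::Views(cv, intr$start, intr$end)))
  esum <- sum(IRanges::viewSums(IRanges::Views(
    cv,
    c(fl$upstream$start, fl$downstream$start),
    c(fl$upstream$end, fl$downstream$end))))
  ew <- (fl$upstream$end - fl$upstream$start + 1) +
    (fl$downstream$end - fl$downstream$start + 1)
  imean <- isum / (intr$end - intr$start + 1)
  emean <- esum / ew
  if (emean == 0) return(NA_real_)
  imean / emean
}

#' Intron-retention ratios for all introns across samples
#'
#' Vectorized [intron_retention_ratio()] over every pooled intron of a gene
#' set and every sample.
#'
#' @param depth_list Named list of `RleList` coverage profiles (one per
#'   sample).
#' @param genes A `gene_model_set`.
#' @return List with `introns` (the [all_introns()] table) and `ratios`
#'   (numeric matrix, introns x samples; `NA` marks undefined ratios).
#' @export
ir_ratio_table <- function(depth_list, genes) {
  introns <- all_introns(genes)
  ratios <- matrix(NA_real_, nrow(introns), length(depth_list),
                   dimnames = list(NULL, names(depth_list)))
  if (!nrow(introns)) return(list(introns = introns, ratios = ratios))
  iw <- introns$end - introns$start + 1
  ew <- (introns$up_end - introns$up_start + 1) +
    (introns$down_end - introns$down_start + 1)
  for (s in names(depth_list)) {
    cov <- depth_list[[s]]
    for (ch in unique(introns$chrom)) {
      k <- which(introns$chrom == ch)
      cv <- cov[[ch]]
      isum <- IRanges::viewSums(IRanges::Views(cv, introns$start[k],
                                               introns$end[k]))
      esum <- IRanges::viewSums(IRanges::Views(cv, introns$up_start[k],
                                               introns$up_end[k])) +
        IRanges::viewSums(IRanges::Views(cv, introns$down_start[k],
                                         introns$down_end[k]))
      r <- (isum / iw[k]) / (esum / ew[k])
      r[esum == 0] <- NA_real_
      ratios[k, s] <- r
    }
  }
  list(introns = introns, ratios = ratios)
}

#' Classify introns as retained (IR) or more efficiently spliced (MES)
#'
#' Per intron, a two-sided Welch t-test compares the per-replicate retention
#' ratios between conditions. An intron is classified `IR` when p <
#' `p_cutoff` and the mean mutant ratio is at least `fold` times the mean
#' wild-type ratio, `MES` when p < `p_cutoff` and the mean mutant ratio is at
#' most 1/`fold` of the wild type, else `none`. Introns with any undefined
#' replicate ratio, with fewer than 2 defined ratios in a group, or on the
#' exclusion list are not tested; they are tallied in the `skipped` report.
#'
#' @param ir_tab Result of [ir_ratio_table()].
#' @param groups Condition label per sample column of `ir_tab$ratios`.
#' @param reference,treatment Condition labels (defaults `"wt"`, `"mut"`).
#' @param p_cutoff,fold Significance and fold gates (defaults 0.01, 2).
#' @param on_log Test log2(ratio + `log_eps`) instead of raw ratios.
#' @param log_eps Offset for the optional log transform (default 1e-3).
#' @param exclude Optional exclusion list: either a character vector of gene
#'   ids or a `data.frame` with `chrom`, `start`, `end`; introns of listed
#'   genes or overlapping listed intervals are dropped before testing.
#' @return List with `results` (tested introns: coordinates, group mean
#'   ratios, `fc`, `p`, `class`) and `skipped` (`data.frame` of intron
#'   coordinates and reasons).
#' @export
classify_introns <- function(ir_tab, groups, reference = "wt",
                             treatment = "mut", p_cutoff = 0.01, fold = 2,
                             on_log = FALSE, log_eps = 1e-3, exclude = NULL) {
  introns <- ir_tab$introns
  ratios <- ir_tab$ratios
  stopifnot(length(groups) == ncol(ratios))
  ref_i <- which(groups == reference); trt_i <- which(groups == treatment)
  if (length(ref_i) < 2L || length(trt_i) < 2L)
    stop("need >= 2 replicates per condition")

  skip_reason <- rep(NA_character_, nrow(introns))
  if (!is.null(exclude)) {
    skip_reason[excluded_introns(introns, exclude)] <- "excluded locus"
  }
  nref <- rowSums(!is.na(ratios[, ref_i, drop = FALSE]))
  ntrt <- rowSums(!is.na(ratios[, trt_i, drop = FALSE]))
  und <- is.na(skip_reason) & (nref < length(ref_i) | ntrt < length(trt_i))
  skip_reason[und & (nref >= 2L & ntrt >= 2L)] <- "undefined ratio in a replicate"
  skip_reason[und & (nref < 2L | ntrt < 2L)] <- "fewer than 2 defined ratios in a group"

  test_i <- which(is.na(skip_reason))
  res <- introns[test_i, c("gene_id", "chrom", "strand", "start", "end"),
                 drop = FALSE]
  if (length(test_i)) {
    x <- ratios[test_i, trt_i, drop = FALSE]
    y <- ratios[test_i, ref_i, drop = FALSE]
    tin_x <- if (on_log) log2(x + log_eps) else x
    tin_y <- if (on_log) log2(y + log_eps) else y
    wt <- welch_t_rows(tin_x, tin_y)
    res$mean_ref <- rowMeans(y)
    res$mean_trt <- rowMeans(x)
    res$fc <- res$mean_trt / res$mean_ref
    res$p <- wt$p_value
    res$class <- "none"
    sig <- res$p < p_cutoff & !is.na(res$p)
    res$class[sig & res$mean_trt >= fold * res$mean_ref] <- "IR"
    res$class[sig & res$mean_trt <= res$mean_ref / fold] <- "MES"
  } else {
    res$mean_ref <- res$mean_trt <- res$fc <- res$p <- numeric(0)
    res$class <- character(0)
  }
  rownames(res) <- NULL
  skipped <- cbind(introns[!is.na(skip_reason),
                           c("gene_id", "chrom", "start", "end"), drop = FALSE],
                   reason = skip_reason[!is.na(skip_reason)])
  rownames(skipped) <- NULL
  list(results = res, skipped = skipped)
}

excluded_introns <- function(introns, exclude) {
  if (is.character(exclude)) return(introns$gene_id %in% exclude)
  stopifnot(all(c("chrom", "start", "end") %in% names(exclude)))
  if (!nrow(exclude)) return(rep(FALSE, nrow(introns)))
  igr <- GenomicRanges::GRanges(introns$chrom,
                                IRanges::IRanges(introns$start, introns$end))
  xgr <- GenomicRanges::GRanges(exclude$chrom,
                                IRanges::IRanges(exclude$start, exclude$end))
  GenomicRanges::countOverlaps(igr, xgr) > 0L
}

#' Alternative-splicing ratio
#'
#' Supporting over non-supporting junction-read counts for a candidate
#' event, with a symmetric pseudocount so zero denominators stay testable:
#' `(supporting + pseudocount) / (non_supporting + pseudocount)`.
#'
#' @param supporting,non_supporting Nonnegative counts (vectorized).
#' @param pseudocount Added to both counts before the ratio (default 1; use
#'   0 for the bare ratio).
#' @param log2 Return the log2 ratio.
#' @return Numeric vector.
#' @export
as_ratio <- function(supporting, non_supporting, pseudocount = 1,
                     log2 = FALSE) {
  r <- (supporting + pseudocount) / (non_supporting + pseudocount)
  if (log2) base::log2(r) else r
}

#' Expression ratio of an AS event
#'
#' Event-supporting junction reads over reads uniquely assignable to the
#' event's gene — a second, gene-level-normalized evidence channel:
#' `(supporting + pseudocount) / (unique_gene_reads + pseudocount)`.
#'
#' @param supporting Supporting junction-read counts.
#' @param unique_gene_reads Unique read counts of the event's gene.
#' @param pseudocount Added to both counts (default 1; 0 for the bare ratio).
#' @param log2 Return the log2 ratio.
#' @return Numeric vector.
#' @export
expression_ratio <- function(supporting, unique_gene_reads, pseudocount = 1,
                             log2 = FALSE) {
  r <- (supporting + pseudocount) / (unique_gene_reads + pseudocount)
  if (log2) base::log2(r) else r
}

#' Enumerate candidate alternative-splicing events
#'
#' From observed junctions and the annotation, candidates are:
#'
#' * `exon_skip` — for every internal exon, when a junction joining its two
#'   flanking exons (`prev_exon.end` -> `next_exon.start`) was observed.
#'   Supporting reads are that skip junction; non-supporting reads are the
#'   two annotated junctions linking the skipped exon to either flank.
#' * `alt_donor` / `alt_acceptor` / `alt_both` — for every observed junction
#'   that differs from an annotated intron's boundaries while both endpoints
#'   fall within that intron's neighboring-exon pair and the removed region
#'   overlaps the intron (the junction spans the same exon pair). The side
#'   label is strand-aware: the donor is the intron boundary at the
#'   transcription-upstream (5') end. Supporting reads are the novel
#'   junction; non-supporting reads are the annotated junction.
#'
#' @param junctions Junction table with `chrom`, `donor`, `acceptor`
#'   (e.g. [junction_matrix()] output or a single [extract_junctions()]
#'   table); each row is one observed junction.
#' @param genes A `gene_model_set`.
#' @return `data.frame` of candidates: `gene_id`, `chrom`, `strand`, `type`,
#'   `donor`, `acceptor` (the defining junction), reference coordinates, and
#'   non-supporting junctions `ns1_donor`, `ns1_acceptor`, `ns2_donor`,
#'   `ns2_acceptor` (the second pair is `NA` for alt events).
#' @export
enumerate_as_events <- function(junctions, genes) {
  obs <- data.table::as.data.table(junctions[, c("chrom", "donor", "acceptor")])
  obs <- unique(obs)
  ann <- data.table::as.data.table(all_introns(genes))
  empty <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), type = character(),
                      donor = integer(), acceptor = integer(),
                      ref_start = integer(), ref_end = integer(),
                      ns1_donor = integer(), ns1_acceptor = integer(),
                      ns2_donor = integer(), ns2_acceptor = integer())
  if (!nrow(obs)) return(empty)

  # exon skipping: observed junction joining the two flanks of an internal exon
  iex <- data.table::as.data.table(internal_exons(genes))
  skip <- NULL
  if (nrow(iex)) {
    iex[, `:=`(donor = prev_end, acceptor = next_start)]
    skip <- merge(iex, obs, by = c("chrom", "donor", "acceptor"))
    skip <- if (nrow(skip))
      skip[, .(gene_id, chrom, strand, type = "exon_skip",
               donor, acceptor, ref_start = start, ref_end = end,
               ns1_donor = prev_end, ns1_acceptor = start,
               ns2_donor = end, ns2_acceptor = next_start)]
    else NULL
  }

  # alternative donor/acceptor: novel junction over an annotated exon pair
  annj <- ann[, .(chrom, donor = start - 1L, acceptor = end + 1L)]
  novel <- obs[!annj, on = c("chrom", "donor", "acceptor")]
  alt <- NULL
  if (nrow(novel) && nrow(ann)) {
    ann2 <- ann[, .(gene_id, chrom, strand, start, end, up_start, down_end)]
    alt <- ann2[novel,
                on = .(chrom, up_start <= donor, down_end >= acceptor,
                       start <= acceptor, end >= donor),
                nomatch = NULL,
                .(gene_id, chrom, strand, start = x.start, end = x.end,
                  donor = i.donor, acceptor = i.acceptor)]
    if (nrow(alt)) {
      # removed region must genuinely overlap the intron
      alt <- alt[donor + 1L <= end & acceptor - 1L >= start]
    }
    if (nrow(alt)) {
      left_diff <- alt$donor != alt$start - 1L
      right_diff <- alt$acceptor != alt$end + 1L
      plus <- alt$strand == "+"
      type <- ifelse(left_diff & right_diff, "alt_both",
              ifelse(left_diff,
                     ifelse(plus, "alt_donor", "alt_acceptor"),
                     ifelse(plus, "alt_acceptor", "alt_donor")))
      alt <- alt[, .(gene_id, chrom, strand, type = type, donor, acceptor,
                     ref_start = start, ref_end = end,
                     ns1_donor = start - 1L, ns1_acceptor = end + 1L,
                     ns2_donor = NA_integer_, ns2_acceptor = NA_integer_)]
    } else alt <- NULL
  }
  out <- data.table::rbindlist(list(skip, alt), use.names = TRUE)
  if (!nrow(out)) return(empty)
  out <- unique(out)
  data.table::setorder(out, chrom, donor, acceptor, type, gene_id)
  as.data.frame(out)
}

#' Test and classify candidate AS events
#'
#' For each candidate, per-replicate log2 AS ratios (supporting over
#' non-supporting junction reads) and log2 expression ratios (supporting
#' over unique gene reads) are compared between conditions with two-sided
#' Welch t-tests. An event is *reported* only when both p-values are below
#' `p_cutoff`; a reported event is classified `enhanced` when the mean
#' mutant expression ratio is at least `fold` times the wild-type mean, and
#' `reduced` when at most 1/`fold` of it, else `none`. Candidates with zero
#' supporting reads in every replicate of both groups are dropped.
#'
#' @param candidates Output of [enumerate_as_events()].
#' @param jmat Junction count matrix from [junction_matrix()].
#' @param unique_counts Integer matrix of unique per-gene read counts
#'   (genes x samples, rownames = gene ids) — see [gene_count_matrix()].
#' @param groups Condition label per sample (matching `jmat` count columns
#'   and `unique_counts` columns).
#' @param reference,treatment Condition labels (defaults `"wt"`, `"mut"`).
#' @param p_cutoff,fold Significance and fold gates (defaults 0.01, 2).
#' @param pseudocount Pseudocount for both ratios (default 1).
#' @return `data.frame`: the candidate columns plus per-group mean
#'   expression ratios, `p_as`, `p_expr`, `reported`, `class`.
#' @export
classify_as_events <- function(candidates, jmat, unique_counts, groups,
                               reference = "wt", treatment = "mut",
                               p_cutoff = 0.01, fold = 2, pseudocount = 1) {
  samples <- setdiff(names(jmat), c("chrom", "donor", "acceptor"))
  stopifnot(length(groups) == length(samples),
            all(samples %in% colnames(unique_counts)))
  n <- nrow(candidates)
  if (!n) {
    out <- candidates
    out$mean_expr_ref <- out$mean_expr_trt <- out$p_as <- out$p_expr <- numeric(0)
    out$reported <- logical(0); out$class <- character(0)
    return(out)
  }
  jdt <- data.table::as.data.table(jmat)
  lookup <- function(d, a) {
    q <- data.table::data.table(chrom = candidates$chrom, donor = d,
                                acceptor = a)
    m <- jdt[q, on = c("chrom", "donor", "acceptor")]
    cnt <- as.matrix(m[, samples, with = FALSE])
    cnt[is.na(cnt)] <- 0L
    cnt
  }
  S <- lookup(candidates$donor, candidates$acceptor)
  NS <- lookup(candidates$ns1_donor, candidates$ns1_acceptor)
  has2 <- !is.na(candidates$ns2_donor)
  if (any(has2)) {
    NS2 <- lookup(candidates$ns2_donor, candidates$ns2_acceptor)
    NS[has2, ] <- NS[has2, , drop = FALSE] + NS2[has2, , drop = FALSE]
  }
  U <- unique_counts[candidates$gene_id, samples, drop = FALSE]

  keep <- rowSums(S) > 0L
  candidates <- candidates[keep, , drop = FALSE]
  S <- S[keep, , drop = FALSE]; NS <- NS[keep, , drop = FALSE]
  U <- U[keep, , drop = FALSE]

  ref_i <- which(groups == reference); trt_i <- which(groups == treatment)
  if (length(ref_i) < 2L || length(trt_i) < 2L)
    stop("need >= 2 replicates per condition")
  las <- as_ratio(S, NS, pseudocount, log2 = TRUE)
  lex <- expression_ratio(S, U, pseudocount, log2 = TRUE)
  rex <- expression_ratio(S, U, pseudocount)
  p_as <- welch_t_rows(las[, trt_i, drop = FALSE],
                       las[, ref_i, drop = FALSE])$p_value
  p_expr <- welch_t_rows(lex[, trt_i, drop = FALSE],
                         lex[, ref_i, drop = FALSE])$p_value
  mean_ref <- rowMeans(rex[, ref_i, drop = FALSE])
  mean_trt <- rowMeans(rex[, trt_i, drop = FALSE])
  reported <- p_as < p_cutoff & p_expr < p_cutoff &
    !is.na(p_as) & !is.na(p_expr)
  class <- rep("none", nrow(candidates))
  class[reported & mean_trt >= fold * mean_ref] <- "enhanced"
  class[reported & mean_trt <= mean_ref / fold] <- "reduced"
  out <- candidates
  out$mean_expr_ref <- mean_ref
  out$mean_expr_trt <- mean_trt
  out$p_as <- p_as
  out$p_expr <- p_expr
  out$reported <- reported
  out$class <- class
  rownames(out) <- NULL
  out
}

#' Summary table of expression and splicing changes
#'
#' Tallies DEG calls, intron classifications and reported AS events, with
#' the percentage of total annotated introns (or genes for DEGs, internal
#' exons for exon skipping) affected.
#'
#' @param deg Output of [call_degs()] (or `NULL`).
#' @param ir `results` element of [classify_introns()] (or `NULL`).
#' @param as_events Output of [classify_as_events()] (or `NULL`).
#' @param genes A `gene_model_set` (supplies the denominators).
#' @return `data.frame`: `category`, `count`, `denominator`, `percent`.
#' @export
summarize_events <- function(deg, ir, as_events, genes) {
  n_genes <- length(genes)
  n_introns <- nrow(all_introns(genes))
  n_internal <- nrow(internal_exons(genes))
  cnt <- function(x) if (is.null(x)) 0L else as.integer(x)
  rep_ev <- if (!is.null(as_events))
    as_events[as_events$reported, , drop = FALSE] else NULL
  rows <- data.frame(
    category = c("DEG_up", "DEG_down", "IR", "MES", "exon_skip",
                 "alt_5ss", "alt_3ss", "alt_both"),
    count = c(cnt(sum(deg$call == "up")), cnt(sum(deg$call == "down")),
              cnt(sum(ir$class == "IR")), cnt(sum(ir$class == "MES")),
              cnt(sum(rep_ev$type == "exon_skip")),
              cnt(sum(rep_ev$type == "alt_donor")),
              cnt(sum(rep_ev$type == "alt_acceptor")),
              cnt(sum(rep_ev$type == "alt_both"))),
    denominator = c(n_genes, n_genes, n_introns, n_introns, n_internal,
                    n_introns, n_introns, n_introns))
  rows$percent <- ifelse(rows$denominator > 0,
                         100 * rows$count / rows$denominator, NA_real_)
  rows
}
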