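#' Generative scenario for a synthetic splicing cohort
#'
#' A `splice_scenario` fully parameterizes a desk-scale two-condition RNA-seq
#' cohort with known ground truth: multi-exon gene structures, per-gene
#' expression, per-intron retention probabilities, planted differential
#' events (retention changes, exon skipping, alternative donor/acceptor
#' usage, expression changes), replicate structure and the RNG seed. Given
#' the same scenario and seed, every output (annotation, SAM files, truth
#' logs) is byte-identical.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range `c(lo, hi)` of exons per gene.
#' @param exon_len,intron_len Integer ranges (nt) for exon/intron widths.
#' @param expression Mean fragment count per gene per replicate (Poisson
#'   mean before per-replicate noise).
#' @param retention Baseline per-intron probability that a fragment retains
#'   the intron (both conditions).
#' @param ir_introns,ir_fold Number of introns planted with `ir_fold`-times
#'   higher retention in the mutant.
#' @param mes_introns,mes_fold Number of introns planted with
#'   `mes_fold`-times higher retention in the wild type (more efficient
#'   splicing in the mutant).
#' @param skip_exons Number of internal exons planted with differential
#'   skipping.
#' @param skip_usage Named probabilities `c(wt=, mut=)` that a fragment skips
#'   a planted exon.
#' @param alt_acceptor_introns,alt_donor_introns Numbers of introns planted
#'   with an alternative 3' (acceptor) or 5' (donor) splice site.
#' @param alt_offset Offset in nt between the annotated and alternative
#'   splice-site boundary (default 3, the reporter geometry).
#' @param alt_usage Named probabilities `c(wt=, mut=)` that a spliced
#'   fragment uses the alternative junction.
#' @param deg_up,deg_down,deg_fold Numbers of genes planted with
#'   `deg_fold`-times higher/lower expression in the mutant.
#' @param replicates Biological replicates per condition (default 3).
#' @param read_len Read length in nt.
#' @param noise_sd Per-gene per-replicate log2-normal expression noise sd.
#' @param min_anchor Minimum alignment-block overhang in nt; fragment starts
#'   that would create a block shorter than this are not drawn (default 8,
#'   matching the block-credibility filter).
#' @param reporter Optional [reporter_locus_spec()] mixed into the cohort.
#' @param seed Integer RNG seed.
#' @return A validated list of class `splice_scenario`.
#' @export
splice_scenario <- function(n_genes = 50L,
                            exons_per_gene = c(2L, 5L),
                            exon_len = c(150L, 400L),
                            intron_len = c(250L, 450L),
                            expression = 200,
                            retention = 0.12,
                            ir_introns = 0L, ir_fold = 5,
                            mes_introns = 0L, mes_fold = 5,
                            skip_exons = 0L,
                            skip_usage = c(wt = 0.05, mut = 0.40),
                            alt_acceptor_introns = 0L,
                            alt_donor_introns = 0L,
                            alt_offset = 3L,
                            alt_usage = c(wt = 0.05, mut = 0.50),
                            deg_up = 0L, deg_down = 0L, deg_fold = 4,
                            replicates = 3L,
                            read_len = 50L,
                            noise_sd = 0.1,
                            min_anchor = 8L,
                            reporter = NULL,
                            seed = 1L) {
  sc <- as.list(environment())
  fracs <- c(retention, skip_usage, alt_usage)
  if (any(fracs < 0) || any(fracs > 1))
    stop("configuration error: all fractions must lie in [0, 1]")
  if (ir_fold < 1 || mes_fold < 1)
    stop("configuration error: retention folds must be >= 1")
  if (alt_offset < 1L) stop("configuration error: alt_offset must be >= 1")
  if (replicates < 2L)
    stop("configuration error: t-tests need >= 2 replicates per condition")
  if (exon_len[1L] < min_anchor)
    stop("configuration error: exons shorter than the anchor overlap")
  if (read_len > 2L * exon_len[1L])
    stop("configuration error: read_len too large for the shortest exon pair")
  if (intron_len[1L] <= alt_offset + 1L)
    stop("configuration error: intron_len must exceed alt_offset + 1")
  if (!is.null(reporter)) stopifnot(inherits(reporter, "reporter_locus_spec"))
  structure(sc, class = "splice_scenario")
}

#' @export
print.splice_scenario <- function(x, ...) {
  cat(sprintf(paste0("<splice_scenario> %d gene(s), %d+%d replicates, ",
                     "read_len %d, seed %d\n"),
              x$n_genes, x$replicates, x$replicates, x$read_len, x$seed))
  invisible(x)
}

#' Generate annotation and ground truth for a scenario
#'
#' Lays the scenario's genes out along one synthetic chromosome (well
#' separated, so every read is assignable to a single gene), draws gene
#' structures, and plants the scenario's differential events. Deterministic
#' given the scenario seed.
#'
#' @param scenario A [splice_scenario()].
#' @return List of class `splice_annotation`: `genes` (a `gene_model_set`,
#'   including the reporter gene when configured), `seqlengths`, and `truth`
#'   — a list of data frames (`introns` with per-condition retention and
#'   planted class; `skips`; `alts` with the novel junction; `genes` with
#'   per-condition expression; `reporter` proportions when configured).
#' @export
generate_annotation <- function(scenario) {
  stopifnot(inherits(scenario, "splice_scenario"))
  with_seed(scenario$seed, generate_annotation_impl(scenario))
}

generate_annotation_impl <- function(sc) {
  rint <- function(n, rng) {   # safe for degenerate ranges (lo == hi)
    v <- seq.int(rng[1L], rng[2L])
    v[sample.int(length(v), n, replace = TRUE)]
  }
  gap <- 500L
  cursor <- 1000L
  genes <- vector("list", sc$n_genes)
  ids <- sprintf("g%04d", seq_len(sc$n_genes))
  for (i in seq_len(sc$n_genes)) {
    n_ex <- rint(1L, sc$exons_per_gene)
    ew <- rint(n_ex, sc$exon_len)
    iw <- if (n_ex > 1L) rint(n_ex - 1L, sc$intron_len) else integer()
    starts <- ends <- integer(n_ex)
    pos <- cursor
    for (k in seq_len(n_ex)) {
      starts[k] <- pos
      ends[k] <- pos + ew[k] - 1L
      pos <- ends[k] + 1L + if (k < n_ex) iw[k] else 0L
    }
    strand <- sample(c("+", "-"), 1L)
    tx <- setNames(list(data.frame(start = starts, end = ends)),
                   paste0(ids[i], ".1"))
    genes[[i]] <- gene_model(ids[i], "chrS", strand, tx)
    cursor <- max(ends) + gap
  }
  names(genes) <- ids
  genes <- structure(genes, class = "gene_model_set",
                     rejected = data.frame(gene_id = character(),
                                           reason = character()))
  seqlengths <- c(chrS = as.integer(cursor + 1000L))

  introns <- all_introns(genes)
  introns$ret_wt <- sc$retention
  introns$ret_mut <- sc$retention
  introns$planted <- NA_character_

  # exon-skip plants first; their genes are kept free of intron plants
  iex <- internal_exons(genes)
  skips <- iex[0, ]
  if (sc$skip_exons > 0L) {
    if (nrow(iex) < sc$skip_exons)
      stop("configuration error: not enough internal exons to plant skips")
    skips <- iex[sample.int(nrow(iex), sc$skip_exons), , drop = FALSE]
  }
  if (nrow(skips)) {
    skips$usage_wt <- unname(sc$skip_usage["wt"])
    skips$usage_mut <- unname(sc$skip_usage["mut"])
  } else {
    skips$usage_wt <- skips$usage_mut <- numeric(0)
  }

  pool <- which(!(introns$gene_id %in% skips$gene_id))
  need <- sc$ir_introns + sc$mes_introns + sc$alt_acceptor_introns +
    sc$alt_donor_introns
  if (length(pool) < need)
    stop("configuration error: not enough introns to plant all events")
  picked <- if (need) sample(pool, need) else integer()
  take <- function(n) {
    out <- picked[seq_len(n)]
    picked <<- picked[-seq_len(n)]
    out
  }
  ir_idx <- take(sc$ir_introns)
  mes_idx <- take(sc$mes_introns)
  alt3_idx <- take(sc$alt_acceptor_introns)
  alt5_idx <- take(sc$alt_donor_introns)
  introns$ret_mut[ir_idx] <- pmin(sc$retention * sc$ir_fold, 0.95)
  introns$planted[ir_idx] <- "IR"
  introns$ret_wt[mes_idx] <- pmin(sc$retention * sc$mes_fold, 0.95)
  introns$planted[mes_idx] <- "MES"

  alts <- alt_junctions(introns, c(alt3_idx, alt5_idx),
                        rep(c("acceptor", "donor"),
                            c(length(alt3_idx), length(alt5_idx))),
                        sc$alt_offset)
  if (nrow(alts)) {
    alts$usage_wt <- unname(sc$alt_usage["wt"])
    alts$usage_mut <- unname(sc$alt_usage["mut"])
    introns$planted[alts$intron_row] <- paste0("alt_", alts$side)
  }

  gtruth <- data.frame(gene_id = ids,
                       expr_wt = sc$expression, expr_mut = sc$expression,
                       planted = NA_character_)
  deg_pick <- sample.int(sc$n_genes, sc$deg_up + sc$deg_down)
  up <- deg_pick[seq_len(sc$deg_up)]
  down <- setdiff(deg_pick, up)
  gtruth$expr_mut[up] <- sc$expression * sc$deg_fold
  gtruth$planted[up] <- "up"
  gtruth$expr_mut[down] <- sc$expression / sc$deg_fold
  gtruth$planted[down] <- "down"

  truth <- list(introns = introns, skips = skips, alts = alts,
                genes = gtruth)
  if (!is.null(sc$reporter)) {
    loc <- make_reporter_locus(sc$reporter)
    genes[[loc$gene$gene_id]] <- loc$gene
    class(genes) <- "gene_model_set"
    seqlengths <- c(seqlengths,
                    setNames(as.integer(loc$gene_end + 1000L),
                             sc$reporter$chrom))
    truth$reporter <- loc
  }
  structure(list(genes = genes, seqlengths = seqlengths, truth = truth),
            class = "splice_annotation")
}

# novel junction coordinates for planted alternative splice sites;
# `side` is strand-aware (donor = 5' end of the intron in transcription
# direction), the stored donor/acceptor columns are genomic-left/right
alt_junctions <- function(introns, rows, side, offset) {
  if (!length(rows))
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), intron_row = integer(),
                      side = character(), donor = integer(),
                      acceptor = integer()))
  it <- introns[rows, ]
  left_moves <- (it$strand == "+" & side == "donor") |
    (it$strand == "-" & side == "acceptor")
  donor <- ifelse(left_moves, it$start - 1L + offset, it$start - 1L)
  acceptor <- ifelse(left_moves, it$end + 1L, it$end + 1L - offset)
  data.frame(gene_id = it$gene_id, chrom = it$chrom, strand = it$strand,
             intron_row = rows, side = side,
             donor = as.integer(donor), acceptor = as.integer(acceptor))
}

#' Simulate one replicate's alignments as a SAM file
#'
#' Fragment counts per gene are Poisson with a per-gene per-replicate
#' log-normal expression perturbation; each fragment independently realizes
#' intron retention, exon skipping and alternative-junction usage per the
#' scenario's ground truth; read start positions are uniform over the
#' realized transcript, excluding starts that would create an alignment
#' block shorter than the anchor. Spliced reads get `N`-gapped CIGARs
#' matching the realized junctions; retained-intron reads are contiguous.
#' Records carry `NM`/`MD` tags consistent with the acceptance filters.
#' Reporter reads (when configured) are appended; they span the diagnostic
#' donor boundary with uniform anchored offsets, so variant class counts are
#' exactly multinomial in the generative proportions.
#'
#' @param scenario A [splice_scenario()].
#' @param ann Result of [generate_annotation()] for the same scenario.
#' @param condition `"wt"` or `"mut"`.
#' @param replicate Replicate index (1-based).
#' @param path Output SAM path; `NULL` keeps the records in memory only.
#' @return Invisibly, a list: `sam` (character lines, header included),
#'   `junctions` (the generator's junction log: `chrom`, `donor`,
#'   `acceptor`, `count`), `n_fragments` per gene, and `reporter_counts`
#'   (named class counts, when configured).
#' @export
simulate_alignments <- function(scenario, ann, condition, replicate,
                                path = NULL) {
  stopifnot(inherits(scenario, "splice_scenario"),
            inherits(ann, "splice_annotation"),
            condition %in% c("wt", "mut"))
  out <- with_seed(derive_seed(scenario$seed, condition, replicate),
                   simulate_replicate_impl(scenario, ann, condition))
  hdr <- sam_header(ann$seqlengths)
  out$sam <- c(hdr, out$sam)
  if (!is.null(path)) writeLines(out$sam, path)
  invisible(out)
}

sam_header <- function(seqlengths) {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), unname(seqlengths)),
    paste0("@PG\tID:splicegauge\tPN:splicegauge\tVN:",
           as.character(utils::packageVersion("splicegauge"))))
}

rand_bases <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

simulate_replicate_impl <- function(sc, ann, condition) {
  rl <- sc$read_len
  anchor <- sc$min_anchor
  truth <- ann$truth
  ret_col <- if (condition == "wt") "ret_wt" else "ret_mut"
  usage_col <- if (condition == "wt") "usage_wt" else "usage_mut"
  expr_col <- if (condition == "wt") "expr_wt" else "expr_mut"

  sam <- vector("list", length(ann$genes))
  jlogs <- vector("list", length(ann$genes))
  nfrag <- setNames(integer(nrow(truth$genes)), truth$genes$gene_id)
  qual <- strrep("I", rl)

  for (gi in seq_len(nrow(truth$genes))) {
    gid <- truth$genes$gene_id[gi]
    g <- ann$genes[[gid]]
    lam <- truth$genes[[expr_col]][gi] * 2^rnorm(1L, 0, sc$noise_sd)
    n <- rpois(1L, lam)
    nfrag[gid] <- n
    if (n == 0L) next
    ex <- g$transcripts[[1L]]
    n_ex <- nrow(ex)
    g_introns <- truth$introns[truth$introns$gene_id == gid, , drop = FALSE]
    g_skips <- truth$skips[truth$skips$gene_id == gid, , drop = FALSE]
    g_alts <- truth$alts[truth$alts$gene_id == gid, , drop = FALSE]

    # per-fragment realizations -> pattern key
    n_int <- nrow(g_introns)
    istate <- matrix(0L, n, max(n_int, 1L))  # 0 spliced, 1 retained, 2 alt
    if (n_int) {
      for (k in seq_len(n_int)) {
        ret <- runif(n) < g_introns[[ret_col]][k]
        istate[ret, k] <- 1L
        arow <- which(g_alts$intron_row == as.integer(
          rownames(g_introns)[k]))
        if (length(arow) == 1L) {
          use_alt <- !ret & runif(n) < g_alts[[usage_col]][arow]
          istate[use_alt, k] <- 2L
        }
      }
    }
    skstate <- matrix(FALSE, n, max(nrow(g_skips), 1L))
    if (nrow(g_skips)) {
      for (k in seq_len(nrow(g_skips)))
        skstate[, k] <- runif(n) < g_skips[[usage_col]][k]
    }
    key <- paste(apply(istate, 1L, paste, collapse = ""),
                 apply(skstate, 1L, paste, collapse = ""), sep = "|")

    # isoform segment structures per realized pattern
    ukey <- unique(key)
    segs_by_key <- lapply(ukey, function(ky) {
      i1 <- match(ky, key)
      realize_segments(ex, g_introns, g_skips, g_alts, istate[i1, ],
                       skstate[i1, ])
    })
    names(segs_by_key) <- ukey
    # fragment counts are proportional to transcript length (shearing):
    # resample realized patterns with length weights so per-base coverage
    # is isoform-balanced and depth ratios estimate the event fractions
    wlen <- vapply(segs_by_key, function(s)
      max(sum(s$end - s$start + 1L) - rl + 1L, 1L), numeric(1L))
    key <- sample(key, n, replace = TRUE, prob = wlen[key] / mean(wlen[key]))

    gsam <- list(); gjun <- list()
    ctr <- 0L
    for (ky in unique(key)) {
      idx <- which(key == ky)
      segs <- segs_by_key[[ky]]
      reads <- draw_reads(segs, length(idx), rl, anchor, gid, g$chrom)
      if (is.null(reads)) next
      ctr <- ctr + 1L
      gsam[[ctr]] <- reads$fields
      gjun[[ctr]] <- reads$junctions
    }
    fields <- data.table::rbindlist(gsam)
    seqs <- rand_bases(nrow(fields), rl)
    sam[[gi]] <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:0\tMD:Z:%d",
                         paste0(gid, ":", condition, ":", seq_len(nrow(fields))),
                         g$chrom, fields$pos, fields$cigar, seqs, qual, rl)
    jl <- data.table::rbindlist(gjun)
    if (nrow(jl)) jlogs[[gi]] <- jl
  }

  jun <- data.table::rbindlist(jlogs)
  rep_counts <- NULL
  if (!is.null(sc$reporter)) {
    rr <- simulate_reporter_reads(sc, truth$reporter, condition)
    sam <- c(sam, list(rr$sam))
    jun <- data.table::rbindlist(list(jun, rr$junctions), use.names = TRUE)
    rep_counts <- rr$counts
  }
  if (nrow(jun)) {
    jun <- jun[, .(count = .N), by = .(chrom, donor, acceptor)]
    data.table::setorder(jun, chrom, donor, acceptor)
  } else {
    jun <- data.table::data.table(chrom = character(), donor = integer(),
                                  acceptor = integer(), count = integer())
  }
  list(sam = unlist(sam), junctions = as.data.frame(jun),
       n_fragments = nfrag, reporter_counts = rep_counts)
}

# genomic segments of one realized isoform
realize_segments <- function(ex, g_introns, g_skips, g_alts, istate, sk) {
  n_ex <- nrow(ex)
  skipped <- rep(FALSE, n_ex)
  if (nrow(g_skips)) skipped[g_skips$exon_index[sk]] <- TRUE
  keep <- which(!skipped)
  cs <- ex$start[keep[1L]]; ce <- ex$end[keep[1L]]
  segs_s <- integer(); segs_e <- integer()
  for (j in seq_along(keep)[-1L]) {
    prev <- keep[j - 1L]; cur <- keep[j]
    if (cur - prev > 1L) {                      # skipped exon(s) in between
      segs_s <- c(segs_s, cs); segs_e <- c(segs_e, ce)
      cs <- ex$start[cur]; ce <- ex$end[cur]
      next
    }
    st <- istate[prev]                           # intron index == prev exon
    if (st == 1L) {                              # retained: contiguous
      ce <- ex$end[cur]
    } else if (st == 2L) {                       # alternative junction
      arow <- which(g_alts$intron_row ==
                      as.integer(rownames(g_introns)[prev]))
      segs_s <- c(segs_s, cs); segs_e <- c(segs_e, g_alts$donor[arow])
      cs <- g_alts$acceptor[arow]; ce <- ex$end[cur]
    } else {                                     # annotated splice
      segs_s <- c(segs_s, cs); segs_e <- c(segs_e, ce)
      cs <- ex$start[cur]; ce <- ex$end[cur]
    }
  }
  data.frame(start = c(segs_s, cs), end = c(segs_e, ce))
}

# uniform fragment starts on a realized transcript, excluding starts that
# would create an alignment block shorter than `anchor`
draw_reads <- function(segs, n, rl, anchor, gid, chrom_name) {
  w <- segs$end - segs$start + 1L
  L <- sum(w)
  if (L < rl)
    stop("configuration error: read length ", rl,
         " exceeds realized transcript of gene ", gid, " (", L, " nt)")
  npos <- L - rl + 1L
  ok <- rep(TRUE, npos)
  cumw <- cumsum(w)
  bounds <- cumw[-length(cumw)]
  for (b in bounds) {
    lo1 <- max(1L, b - rl + 2L); hi1 <- min(npos, b + anchor - rl)
    if (lo1 <= hi1) ok[lo1:hi1] <- FALSE
    lo2 <- max(1L, b - anchor + 2L); hi2 <- min(npos, b)
    if (lo2 <= hi2) ok[lo2:hi2] <- FALSE
  }
  allowed <- which(ok)
  if (!length(allowed))
    stop("configuration error: no anchored read placement on gene ", gid)
  p <- allowed[sample.int(length(allowed), n, replace = TRUE)]

  cum0 <- c(0L, cumw)
  j1 <- findInterval(p - 1L, cum0, rightmost.closed = FALSE)
  q <- p + rl - 1L
  j2 <- findInterval(q - 1L, cum0)
  pos <- segs$start[j1] + (p - cum0[j1] - 1L)
  gend <- segs$start[j2] + (q - cum0[j2] - 1L)

  cigars <- character(n)
  jun <- vector("list", n)
  single <- j1 == j2
  cigars[single] <- paste0(rl, "M")
  for (i in which(!single)) {
    js <- j1[i]:j2[i]
    bs <- c(pos[i], segs$start[js[-1L]])
    be <- c(segs$end[js[-length(js)]], gend[i])
    gaps <- bs[-1L] - be[-length(be)] - 1L
    cigars[i] <- paste0(paste0(be - bs + 1L, "M",
                               c(paste0(gaps, "N"), ""), collapse = ""))
    jun[[i]] <- data.table::data.table(chrom = chrom_name,
                                       donor = be[-length(be)],
                                       acceptor = bs[-1L])
  }
  jun <- data.table::rbindlist(jun)
  list(fields = data.table::data.table(pos = pos, cigar = cigars),
       junctions = jun)
}
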