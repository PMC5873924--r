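#' Specification of the dual-intron reporter locus
#'
#' Generative parameterization of a reporter gene whose pre-mRNA yields
#' three splice variants: a long unspliced transcript, a transcript spliced
#' at a canonical intron, and a transcript spliced at a non-canonical intron
#' whose 3' splice site lies only `acceptor_offset` nt away (default 3, the
#' non-canonical acceptor on the outside). Default per-condition proportions
#' follow the reporter shift this pipeline is built to resolve: in the wild
#' type roughly 55% unspliced / 22% canonical / 23% non-canonical, in the
#' mutant roughly 50% / 47% / 3%.
#'
#' @param proportions_wt,proportions_mut Numeric triples
#'   `(unspliced, canonical, non_canonical)` summing to 1.
#' @param acceptor_offset Offset in nt between the two introns' 3' splice
#'   sites (>= 1).
#' @param donor_offset Offset in nt between the two introns' 5' splice
#'   sites (default 0: shared donor).
#' @param exon_len,intron_len Exon and canonical-intron lengths in nt.
#' @param n_fragments Reporter fragments per replicate.
#' @param chrom,gene_id Reporter chromosome and gene id.
#' @return A validated list of class `reporter_locus_spec`.
#' @export
reporter_locus_spec <- function(proportions_wt = c(unspliced = 0.55,
                                                   canonical = 0.22,
                                                   non_canonical = 0.23),
                                proportions_mut = c(unspliced = 0.50,
                                                    canonical = 0.47,
                                                    non_canonical = 0.03),
                                acceptor_offset = 3L,
                                donor_offset = 0L,
                                exon_len = 300L,
                                intron_len = 150L,
                                n_fragments = 2000L,
                                chrom = "chrR",
                                gene_id = "reporterGFP") {
  sp <- as.list(environment())
  for (p in list(proportions_wt, proportions_mut)) {
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop("configuration error: proportions must be 3 nonnegative values summing to 1")
  }
  if (acceptor_offset < 1L)
    stop("configuration error: acceptor_offset must be >= 1")
  if (acceptor_offset >= exon_len || donor_offset >= intron_len)
    stop("configuration error: offset larger than the flanking exon/intron")
  structure(sp, class = "reporter_locus_spec")
}

#' Build the reporter gene model and its two intron definitions
#'
#' The annotated transcript carries the canonical intron; the non-canonical
#' intron shares its region but starts `donor_offset` nt earlier and ends
#' `acceptor_offset` nt later (removing the first bases of the downstream
#' exon), so the two junctions are distinguishable by exact boundary
#' matching.
#'
#' @param spec A [reporter_locus_spec()].
#' @return List of class `reporter_locus`: `gene` (a [gene_model()]),
#'   `canonical` and `non_canonical` intron coordinates (`c(start, end)`),
#'   `spec`, and `gene_end`.
#' @export
make_reporter_locus <- function(spec) {
  stopifnot(inherits(spec, "reporter_locus_spec"))
  e1s <- 1001L
  e1e <- e1s + spec$exon_len - 1L
  cis <- e1e + 1L
  cie <- cis + spec$intron_len - 1L
  e2s <- cie + 1L
  e2e <- e2s + spec$exon_len - 1L
  canonical <- c(start = cis, end = cie)
  non_canonical <- c(start = cis - spec$donor_offset,
                     end = cie + spec$acceptor_offset)
  if (identical(unname(canonical), unname(non_canonical)))
    stop("configuration error: indistinguishable intron definitions")
  gene <- gene_model(spec$gene_id, spec$chrom, "+",
                     setNames(list(data.frame(start = c(e1s, e2s),
                                              end = c(e1e, e2e))),
                              paste0(spec$gene_id, ".1")))
  structure(list(gene = gene, canonical = canonical,
                 non_canonical = non_canonical, spec = spec,
                 gene_end = e2e),
            class = "reporter_locus")
}

# boundary geometry shared by the generator and the quantifier
reporter_geometry <- function(locus) {
  ca <- locus$canonical; nc <- locus$non_canonical
  list(chrom = locus$gene$chrom,
       b_c = unname(ca["start"]) - 1L,          # canonical donor boundary
       b_n = unname(nc["start"]) - 1L,
       a_c = unname(ca["end"]) + 1L,            # acceptor boundaries
       a_n = unname(nc["end"]) + 1L)
}

# anchored reporter reads: every fragment spans its variant's donor boundary
# with >= anchor overhang on each side, uniform offset; class counts are
# therefore exactly multinomial in the generative proportions
simulate_reporter_reads <- function(sc, locus, condition) {
  spec <- locus$spec
  geo <- reporter_geometry(locus)
  rl <- sc$read_len; anchor <- sc$min_anchor
  if (rl - anchor > spec$exon_len - spec$acceptor_offset)
    stop("configuration error: read overhang exceeds the downstream exon")
  p <- if (condition == "wt") spec$proportions_wt else spec$proportions_mut
  n <- spec$n_fragments
  cls <- sample.int(3L, n, replace = TRUE, prob = p)
  l <- sample(seq.int(anchor, rl - anchor), n, replace = TRUE)

  b <- ifelse(cls == 3L, geo$b_n, geo$b_c)
  a <- ifelse(cls == 3L, geo$a_n, geo$a_c)
  pos <- b - l + 1L
  cigar <- ifelse(cls == 1L, paste0(rl, "M"),
                  paste0(l, "M", a - b - 1L, "N", rl - l, "M"))
  seqs <- rand_bases(n, rl)
  sam <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tNM:i:0\tMD:Z:%d",
                 paste0(spec$gene_id, ":", condition, ":", seq_len(n)),
                 geo$chrom, pos, cigar, seqs, strrep("I", rl), rl)
  spliced <- cls != 1L
  jun <- data.table::data.table(chrom = geo$chrom, donor = b[spliced],
                                acceptor = a[spliced])
  counts <- c(unspliced = sum(cls == 1L), canonical = sum(cls == 2L),
              non_canonical = sum(cls == 3L))
  list(sam = sam, junctions = jun, counts = counts)
}

#' Quantify the three reporter splice variants
#'
#' Per replicate: the canonical and non-canonical variants are counted from
#' junction reads matching the respective intron boundaries *exactly* (both
#' donor and acceptor; no fuzzy matching, so an acceptor 3 nt away is never
#' confused); the unspliced variant is counted from contiguous reads
#' spanning the canonical donor boundary by at least `anchor` nt on each
#' side. Percentages are over the three-class total, computed per replicate
#' and then averaged within condition. Junction reads in the locus matching
#' neither intron are tallied as `other`, never merged into a class.
#'
#' @param records_list Named list of `alignment_records`, one per sample.
#' @param locus A `reporter_locus` (from [make_reporter_locus()]), or a list
#'   with `chrom`, `canonical = c(start, end)`,
#'   `non_canonical = c(start, end)`.
#' @param groups Optional condition label per sample; adds per-condition
#'   mean percentages.
#' @param anchor Minimum overhang for unspliced evidence (default 8 nt,
#'   mirroring the block-credibility filter).
#' @return List of class `reporter_quant`: `per_replicate` (counts and
#'   percentages per sample) and `means` (per-condition mean percentages;
#'   `NULL` without `groups`).
#' @export
quantify_variants <- function(records_list, locus, groups = NULL,
                              anchor = 8L) {
  if (!inherits(locus, "reporter_locus")) {
    stopifnot(all(c("chrom", "canonical", "non_canonical") %in% names(locus)))
    locus <- list(gene = list(chrom = locus$chrom),
                  canonical = locus$canonical,
                  non_canonical = locus$non_canonical)
    class(locus) <- "reporter_locus"
  }
  geo <- reporter_geometry(locus)
  if (geo$b_c == geo$b_n && geo$a_c == geo$a_n)
    stop("configuration error: indistinguishable intron definitions")
  span <- range(geo$b_n - 1L, geo$b_c - 1L, geo$a_c + 1L, geo$a_n + 1L)

  one <- function(rec) {
    j <- extract_junctions(rec)
    j <- j[j$chrom == geo$chrom &
             j$donor >= span[1L] - anchor & j$acceptor <= span[2L] + anchor, ,
           drop = FALSE]
    canonical <- sum(j$count[j$donor == geo$b_c & j$acceptor == geo$a_c])
    non_canonical <- sum(j$count[j$donor == geo$b_n & j$acceptor == geo$a_n])
    other <- sum(j$count) - canonical - non_canonical
    b <- rec$blocks
    unspliced <- sum(b$chrom == geo$chrom & b$start <= geo$b_c - anchor + 1L &
                       b$end >= geo$b_c + anchor)
    c(unspliced = unspliced, canonical = canonical,
      non_canonical = non_canonical, other = other)
  }
  counts <- t(vapply(records_list, one, numeric(4L)))
  tot <- rowSums(counts[, 1:3, drop = FALSE])
  pct <- 100 * counts[, 1:3, drop = FALSE] / tot
  colnames(pct) <- paste0("pct_", colnames(pct))
  per_rep <- data.frame(sample_id = names(records_list), counts, pct,
                        row.names = NULL)
  means <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(records_list))
    means <- do.call(rbind, lapply(unique(groups), function(gp) {
      data.frame(condition = gp,
                 t(colMeans(pct[groups == gp, , drop = FALSE])))
    }))
  }
  structure(list(per_replicate = per_rep, means = means),
            class = "reporter_quant")
}

#' @export
print.reporter_quant <- function(x, ...) {
  cat("<reporter_quant>\n")
  print(x$per_replicate, digits = 4)
  if (!is.null(x$means)) {
    cat("condition means:\n")
    print(x$means, digits = 4)
  }
  invisible(x)
}
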