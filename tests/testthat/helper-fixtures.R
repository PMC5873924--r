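# fixture builders and independent brute-force oracles shared across tests

# write a small SAM file from explicit records
# records: list of lists with qname, flag, chrom, pos, cigar, and optional
# `tags` character vector (e.g. c("NM:i:0", "MD:Z:100"))
sam_fixture <- function(records, seqlengths = c(chr1 = 100000L)) {
  path <- withr::local_tempfile(fileext = ".sam",
                                .local_envir = parent.frame())
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   unname(seqlengths)))
  body <- vapply(records, function(r) {
    tags <- if (is.null(r$tags)) "" else paste0("\t", paste(r$tags, collapse = "\t"))
    rl <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar, perl = TRUE))[[1]]))
    paste0(r$qname, "\t", r$flag %||% 0L, "\t", r$chrom, "\t", r$pos,
           "\t255\t", r$cigar, "\t*\t0\t0\t", strrep("A", max(rl, 1L)),
           "\t", strrep("I", max(rl, 1L)), tags)
  }, character(1L))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-gene GFF3 text fixture
gff_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

gff_row <- function(chrom, type, s, e, strand, attrs)
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s, e, strand, attrs)

# two-exon plus-strand gene as GFF3 rows
simple_gene_rows <- function(id = "gA", chrom = "chr1",
                             exons = list(c(101L, 200L), c(301L, 400L)),
                             strand = "+") {
  s <- min(vapply(exons, `[`, integer(1L), 1L))
  e <- max(vapply(exons, `[`, integer(1L), 2L))
  tx <- paste0(id, ".1")
  c(gff_row(chrom, "gene", s, e, strand, paste0("ID=", id)),
    gff_row(chrom, "mRNA", s, e, strand, paste0("ID=", tx, ";Parent=", id)),
    unlist(lapply(seq_along(exons), function(k)
      gff_row(chrom, "exon", exons[[k]][1L], exons[[k]][2L], strand,
              paste0("ID=", tx, ".e", k, ";Parent=", tx)))))
}

# brute-force per-base depth over an interval from a blocks data.frame
oracle_region_depth <- function(blocks, chrom, start, end) {
  vapply(start:end, function(p)
    sum(blocks$chrom == chrom & blocks$start <= p & blocks$end >= p),
    numeric(1L))
}

# brute-force intron retention ratio straight from the definition
oracle_ir_ratio <- function(blocks, chrom, intron, up, down) {
  di <- mean(oracle_region_depth(blocks, chrom, intron[1L], intron[2L]))
  fl <- c(oracle_region_depth(blocks, chrom, up[1L], up[2L]),
          oracle_region_depth(blocks, chrom, down[1L], down[2L]))
  if (mean(fl) == 0) return(NA_real_)
  di / mean(fl)
}

# brute-force logCPM / RPKM straight from the formulas, one cell at a time
oracle_logcpm <- function(counts, factors, prior = 0.5,
                          lib_size = colSums(counts)) {
  out <- counts * 0
  for (j in seq_len(ncol(counts))) {
    eff <- lib_size[j] * factors[j]
    for (i in seq_len(nrow(counts)))
      out[i, j] <- log2((counts[i, j] + prior) / (eff + 2 * prior) * 1e6)
  }
  out
}

oracle_rpkm <- function(lc, lengths) {
  out <- lc * 0
  for (j in seq_len(ncol(lc)))
    for (i in seq_len(nrow(lc)))
      out[i, j] <- 2^lc[i, j] / (lengths[i] / 1000)
  out
}

# small two-condition cohort read into filtered records + evidence layers
ingest_cohort <- function(coh, identity = 0.95, end_match = 4L,
                          min_block = 8L) {
  samples <- c(coh$sam_wt, coh$sam_mut)
  names(samples) <- c(paste0("wt_", seq_along(coh$sam_wt)),
                      paste0("mut_", seq_along(coh$sam_mut)))
  recs <- lapply(samples, function(p) {
    r <- read_sam(p)
    apply_filters(r, filter_transcriptome_pass(r, identity, end_match) &
                    filter_short_blocks(r, min_block))
  })
  groups <- sub("_[0-9]+$", "", names(recs))
  list(records = recs, groups = groups,
       depths = lapply(recs, compute_depth))
}
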