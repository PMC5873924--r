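#' Read a SAM file into block-level alignment records
#'
#' Parses a text SAM file into one record per primary mapped alignment, with
#' the alignment split into genomic blocks at `N` CIGAR operations (introns),
#' plus the metadata the acceptance filters need:
#'
#' * `identity`: fraction of aligned bases matching the reference,
#'   `1 - NM / (M + I + D)` from the `NM` tag when present, otherwise
#'   reconstructed from the `MD` tag (mismatch letters plus CIGAR indels);
#'   `NA` when neither tag is available.
#' * `em_left`, `em_right`: lengths (nt) of the terminal exact-match runs,
#'   taken from the leading/trailing match counts of the `MD` tag (a
#'   soft-clipped end has run 0). With no `MD` but `NM:i:0`, both ends equal
#'   the full aligned-reference length.
#'
#' Unmapped, secondary and supplementary records, and records without a
#' CIGAR, are skipped and counted in the `skipped` element.
#'
#' @param path Path to a SAM file with an `@SQ` header.
#' @return An object of class `alignment_records`: a list with
#'   `reads` (`data.frame`: `read_id`, `chrom`, `pos`, `cigar`, `identity`,
#'   `em_left`, `em_right`, `n_blocks`), `blocks` (`data.frame`: `read`
#'   (row index into `reads`), `chrom`, `start`, `end`), `seqlengths`
#'   (named integer), and `skipped` (named integer counts).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  hdr <- lines[is_hdr]
  if (!length(hdr)) stop("SAM file ", path, " has no header")
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  seqlengths <- setNames(ln, sn)

  body <- lines[!is_hdr]
  if (!length(body))
    return(empty_records(seqlengths))
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, names = FALSE)
  read_id <- f[[1L]]
  flag <- as.integer(f[[2L]])
  chrom <- f[[3L]]
  pos <- as.integer(f[[4L]])
  cigar <- f[[6L]]

  unmapped <- bitwAnd(flag, 0x4L) != 0L
  secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
  no_cigar <- cigar == "*" & !unmapped
  if (any(no_cigar))
    warning(sum(no_cigar), " mapped record(s) without CIGAR skipped")
  keep <- !unmapped & !secondary & !no_cigar
  skipped <- c(unmapped = sum(unmapped), secondary = sum(secondary),
               no_cigar = sum(no_cigar))

  body <- body[keep]
  read_id <- read_id[keep]; chrom <- chrom[keep]
  pos <- pos[keep]; cigar <- cigar[keep]
  if (!length(body)) {
    out <- empty_records(seqlengths); out$skipped <- skipped; return(out)
  }

  nm <- extract_tag(body, "NM:i:([0-9]+)")
  md <- extract_tag(body, "MD:Z:([^\t]+)")
  nm <- suppressWarnings(as.numeric(nm))

  # per-record CIGAR op tallies (reference/query consumption)
  ops_rng <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)
  toks <- regmatches(cigar, ops_rng)
  ntok <- lengths(toks)
  tk <- data.table::data.table(read = rep(seq_along(cigar), ntok),
                               tok = unlist(toks))
  tk[, len := as.integer(sub(".$", "", tok))]
  tk[, op := substring(tok, nchar(tok))]
  tal <- tk[, .(m = sum(len[op %in% c("M", "=", "X")]),
                ins = sum(len[op == "I"]),
                del = sum(len[op == "D"]),
                lclip = op[1L] %in% c("S", "H"),
                rclip = op[.N] %in% c("S", "H")), by = read]
  aligned <- tal$m + tal$ins + tal$del

  # identity: NM tag preferred, else mismatches counted from MD + indels
  errs <- nm
  need_md <- is.na(nm) & !is.na(md)
  if (any(need_md))
    errs[need_md] <- md_mismatches(md[need_md]) +
      tal$ins[need_md] + tal$del[need_md]
  identity <- 1 - errs / aligned

  # terminal exact-match runs
  lead <- suppressWarnings(as.integer(sub("^([0-9]+).*", "\\1", md)))
  trail <- suppressWarnings(as.integer(sub(".*?([0-9]+)$", "\\1", md)))
  lead[!grepl("^[0-9]", md) & !is.na(md)] <- 0L
  trail[!grepl("[0-9]$", md) & !is.na(md)] <- 0L
  perfect <- !is.na(nm) & nm == 0
  em_left <- ifelse(!is.na(md), lead, ifelse(perfect, tal$m + tal$del, NA_integer_))
  em_right <- ifelse(!is.na(md), trail, ifelse(perfect, tal$m + tal$del, NA_integer_))
  em_left[tal$lclip] <- 0L
  em_right[tal$rclip] <- 0L

  # genomic blocks: alignment split at N gaps (established CIGAR machinery)
  blk <- GenomicAlignments::extractAlignmentRangesOnReference(cigar, pos = pos)
  nblk <- lengths(blk)
  ublk <- unlist(blk, use.names = FALSE)
  blocks <- data.frame(read = rep(seq_along(cigar), nblk),
                       chrom = rep(chrom, nblk),
                       start = IRanges::start(ublk),
                       end = IRanges::end(ublk))

  reads <- data.frame(read_id = read_id, chrom = chrom, pos = pos,
                      cigar = cigar, identity = identity,
                      em_left = as.integer(em_left),
                      em_right = as.integer(em_right),
                      n_blocks = as.integer(nblk))
  structure(list(reads = reads, blocks = blocks, seqlengths = seqlengths,
                 skipped = skipped),
            class = "alignment_records")
}

empty_records <- function(seqlengths) {
  structure(list(
    reads = data.frame(read_id = character(), chrom = character(),
                       pos = integer(), cigar = character(),
                       identity = numeric(), em_left = integer(),
                       em_right = integer(), n_blocks = integer()),
    blocks = data.frame(read = integer(), chrom = character(),
                        start = integer(), end = integer()),
    seqlengths = seqlengths,
    skipped = c(unmapped = 0L, secondary = 0L, no_cigar = 0L)),
    class = "alignment_records")
}

extract_tag <- function(lines, pattern) {
  m <- regexpr(paste0("\t", pattern), lines)
  out <- rep(NA_character_, length(lines))
  hit <- m > 0L
  out[hit] <- sub(paste0(".*\t", pattern, ".*"), "\\1", lines[hit])
  out
}

# mismatch count from an MD tag: substituted-base letters outside ^-deletions
md_mismatches <- function(md) {
  nchar(gsub("[0-9]+", "", gsub("\\^[A-Z]+", "", md)))
}

#' @export
print.alignment_records <- function(x, ...) {
  cat(sprintf("<alignment_records> %d read(s), %d block(s) on %d sequence(s)\n",
              nrow(x$reads), nrow(x$blocks), length(x$seqlengths)))
  invisible(x)
}

#' Transcriptome-stage acceptance filter
#'
#' Accepts a record iff its identity is strictly greater than `min_identity`
#' (default 0.95, i.e. ">95%") and both terminal exact-match runs are at
#' least `min_end_match` nt (default 4). Records with unknown identity or
#' end-match metadata are rejected. Pure predicate; applied per record (for
#' paired data the rule is enforced on each mate).
#'
#' @param records An `alignment_records` object.
#' @param min_identity Exclusive identity threshold (default 0.95).
#' @param min_end_match Inclusive terminal exact-match threshold in nt
#'   (default 4).
#' @return Logical vector over `records$reads`.
#' @export
filter_transcriptome_pass <- function(records, min_identity = 0.95,
                                      min_end_match = 4L) {
  r <- records$reads
  ok <- r$identity > min_identity & r$em_left >= min_end_match &
    r$em_right >= min_end_match
  ok & !is.na(ok)
}

#' Minimum block-length acceptance filter
#'
#' Rejects a record iff any of its alignment blocks is shorter than
#' `min_block` nt (default 8; a block of exactly 8 nt is accepted).
#'
#' @param records An `alignment_records` object.
#' @param min_block Minimum block length in nt.
#' @return Logical vector over `records$reads`.
#' @export
filter_short_blocks <- function(records, min_block = 8L) {
  b <- data.table::as.data.table(records$blocks)
  minw <- b[, .(w = min(end - start + 1L)), by = read]
  out <- rep(TRUE, nrow(records$reads))
  out[minw$read] <- minw$w >= min_block
  out
}

#' Subset alignment records by a logical filter
#'
#' @param records An `alignment_records` object.
#' @param keep Logical vector over records (e.g. the conjunction of
#'   [filter_transcriptome_pass()] and [filter_short_blocks()]).
#' @return A filtered `alignment_records`; the `skipped` element gains a
#'   `filtered` count.
#' @export
apply_filters <- function(records, keep) {
  stopifnot(length(keep) == nrow(records$reads))
  idx <- which(keep)
  remap <- integer(nrow(records$reads)); remap[idx] <- seq_along(idx)
  blocks <- records$blocks[records$blocks$read %in% idx, , drop = FALSE]
  blocks$read <- remap[blocks$read]
  rownames(blocks) <- NULL
  reads <- records$reads[idx, , drop = FALSE]
  rownames(reads) <- NULL
  structure(list(reads = reads, blocks = blocks,
                 seqlengths = records$seqlengths,
                 skipped = c(records$skipped, filtered = sum(!keep))),
            class = "alignment_records")
}

#' Per-base depth profile of one replicate
#'
#' Every base covered by an alignment block increments depth by 1; the total
#' over the genome equals the summed block lengths (conservation invariant).
#'
#' @param records An `alignment_records` object (typically after filtering).
#' @return An `RleList` of per-base coverage, one run-length vector per
#'   sequence in the SAM header.
#' @export
compute_depth <- function(records) {
  sl <- records$seqlengths
  b <- records$blocks
  if (nrow(b) && any(b$end > sl[b$chrom]))
    stop("alignment block beyond declared sequence length")
  gr <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end),
                               seqlengths = sl)
  GenomicRanges::coverage(gr)
}

#' Extract splice-junction observations
#'
#' Every adjacent block pair of every record yields one junction observation
#' (`donor` = last base of the upstream block, `acceptor` = first base of the
#' downstream block); a read with three blocks contributes two junctions.
#'
#' @param records An `alignment_records` object.
#' @return `data.frame` sorted by (`chrom`, `donor`, `acceptor`) with a
#'   `count` column.
#' @export
extract_junctions <- function(records) {
  b <- data.table::as.data.table(records$blocks)
  if (!nrow(b))
    return(data.frame(chrom = character(), donor = integer(),
                      acceptor = integer(), count = integer()))
  data.table::setorder(b, read, start)
  b[, `:=`(nxt_start = data.table::shift(start, -1L),
           nxt_read = data.table::shift(read, -1L))]
  j <- b[nxt_read == read, .(chrom, donor = end, acceptor = nxt_start)]
  out <- j[, .(count = .N), by = .(chrom, donor, acceptor)]
  data.table::setorder(out, chrom, donor, acceptor)
  as.data.frame(out)
}

#' Per-gene total and unique read counts
#'
#' A read counts toward a gene's `total` if its span overlaps the gene span;
#' it is `unique` to the gene iff all its blocks fall within that gene's
#' span and it overlaps no other annotated gene. Ambiguous reads contribute
#' to totals only.
#'
#' @param records An `alignment_records` object.
#' @param genes A `gene_model_set`.
#' @return `data.frame` with `gene_id`, `total`, `unique` (one row per gene,
#'   in `genes` order).
#' @export
count_gene_reads <- function(records, genes) {
  ggr <- gene_ranges(genes)
  b <- data.table::as.data.table(records$blocks)
  gene_id <- S4Vectors::mcols(ggr)$gene_id
  if (!nrow(b))
    return(data.frame(gene_id = gene_id, total = 0L, unique = 0L))
  sp <- b[, .(chrom = chrom[1L], start = min(start), end = max(end)), by = read]
  rgr <- GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start, sp$end))
  ov <- GenomicRanges::findOverlaps(rgr, ggr, ignore.strand = TRUE)
  n_genes_hit <- GenomicRanges::countOverlaps(rgr, ggr, ignore.strand = TRUE)
  within <- GenomicRanges::findOverlaps(rgr, ggr, type = "within",
                                        ignore.strand = TRUE)
  total <- tabulate(S4Vectors::subjectHits(ov), nbins = length(ggr))
  uniq_hits <- within[n_genes_hit[S4Vectors::queryHits(within)] == 1L]
  unique_n <- tabulate(S4Vectors::subjectHits(uniq_hits), nbins = length(ggr))
  data.frame(gene_id = gene_id, total = total, unique = unique_n)
}
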