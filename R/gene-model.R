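#' Gene models: exon chains and derived introns
#'
#' A `gene_model` holds one gene: its chromosome, strand, and one or more
#' transcripts, each an ordered chain of exons. Introns are not read from the
#' annotation; they are *derived* as the gaps between consecutive exons
#' (`intron.start = exon_i.end + 1`, `intron.end = exon_{i+1}.start - 1`), so
#' a transcript with n exons contributes n - 1 introns. Introns are pooled
#' over transcripts and deduplicated by (start, end); each deduplicated
#' intron remembers the transcript that contributed it, which is where its
#' neighboring exons are looked up. All coordinates are 1-based inclusive
#' (GFF3/SAM convention).
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts Named list; each element a `data.frame` with integer
#'   columns `start`, `end` giving exons sorted by `start`.
#' @return An object of class `gene_model` with elements `gene_id`, `chrom`,
#'   `strand`, `transcripts`, and `introns` (a `data.frame` with columns
#'   `start`, `end`, `transcript`, `index`, where `index` is the 1-based
#'   intron position within the contributing transcript).
#' @examples
#' g <- gene_model("g1", "chr1", "+",
#'                 list(t1 = data.frame(start = c(101, 301), end = c(200, 400))))
#' g$introns  # one intron, 201..300
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L,
            strand %in% c("+", "-"), is.list(transcripts),
            length(transcripts) >= 1L)
  if (is.null(names(transcripts)) || any(!nzchar(names(transcripts))))
    names(transcripts) <- paste0(gene_id, ".", seq_along(transcripts))
  transcripts <- lapply(transcripts, function(ex) {
    ex <- as.data.frame(ex)[, c("start", "end")]
    ex$start <- as.integer(ex$start); ex$end <- as.integer(ex$end)
    if (any(ex$end < ex$start)) stop("exon with end < start in gene ", gene_id)
    ex <- ex[order(ex$start), , drop = FALSE]
    rownames(ex) <- NULL
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping or abutting-without-gap exons in gene ", gene_id)
    ex
  })
  introns <- derive_introns(transcripts)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = transcripts, introns = introns),
            class = "gene_model")
}

derive_introns <- function(transcripts) {
  out <- lapply(names(transcripts), function(tx) {
    ex <- transcripts[[tx]]
    n <- nrow(ex)
    if (n < 2L)
      return(data.frame(start = integer(), end = integer(),
                        transcript = character(), index = integer()))
    istart <- ex$end[-n] + 1L
    iend   <- ex$start[-1L] - 1L
    if (any(iend < istart))
      stop("consecutive exons without an intervening gap in transcript ", tx)
    data.frame(start = istart, end = iend, transcript = tx,
               index = seq_len(n - 1L))
  })
  out <- do.call(rbind, out)
  out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d transcript(s), %d intron(s)\n",
              x$gene_id, x$chrom, gene_span(x)[1L], gene_span(x)[2L], x$strand,
              length(x$transcripts), nrow(x$introns)))
  invisible(x)
}

#' Genomic span of a gene model
#' @param gene A `gene_model`.
#' @return Integer vector `c(start, end)` over all exons of all transcripts.
#' @export
gene_span <- function(gene) {
  s <- vapply(gene$transcripts, function(ex) min(ex$start), integer(1L))
  e <- vapply(gene$transcripts, function(ex) max(ex$end), integer(1L))
  c(min(s), max(e))
}

#' Exons immediately flanking an intron
#'
#' Returns the exon immediately upstream and immediately downstream (in
#' genomic order) of the pooled intron with 1-based index `intron_index`,
#' taken from the transcript that contributed the intron.
#'
#' @param gene A `gene_model`.
#' @param intron_index 1-based index into `gene$introns`.
#' @return A list with `upstream` and `downstream`, each a one-row
#'   `data.frame` with `start`, `end`.
#' @export
neighboring_exons <- function(gene, intron_index) {
  introns <- gene$introns
  if (!is.numeric(intron_index) || intron_index < 1L ||
      intron_index > nrow(introns))
    stop("intron_index ", intron_index, " out of range for gene ",
         gene$gene_id, " (", nrow(introns), " introns)")
  intr <- introns[intron_index, ]
  ex <- gene$transcripts[[intr$transcript]]
  up   <- ex[ex$end == intr$start - 1L, , drop = FALSE]
  down <- ex[ex$start == intr$end + 1L, , drop = FALSE]
  stopifnot(nrow(up) == 1L, nrow(down) == 1L)
  list(upstream = up[, c("start", "end")], downstream = down[, c("start", "end")])
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene`/`mRNA` (or `transcript`)/`exon` features into
#' [gene_model()] objects. Exons are attached to their `Parent` transcript,
#' transcripts to their `Parent` gene. Genes whose exon chains violate the
#' model invariants (overlapping exons, gap-less neighbours) are rejected and
#' reported through a warning and the `"rejected"` attribute, never silently
#' dropped.
#'
#' @param path Path to a GFF3 file.
#' @return A named list of `gene_model` objects (class `gene_model_set`),
#'   with attribute `rejected`: a `data.frame` of gene ids and reasons.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L))
    stop("malformed GFF3 line ", body[which(nf != 9L)[1L]],
         ": expected 9 tab-separated fields, found ", nf[nf != 9L][1L])
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1L))

  genes <- g[g$type == "gene", ]
  txs   <- g[g$type %in% c("mRNA", "transcript"), ]
  exons <- g[g$type == "exon", ]
  if (nrow(exons) && anyNA(exons$Parent))
    stop("structural error: exon without Parent attribute (feature ",
         which(is.na(exons$Parent))[1L], " of exon set)")
  if (nrow(exons) && !all(exons$Parent %in% txs$ID))
    stop("structural error: exon Parent '",
         setdiff(exons$Parent, txs$ID)[1L], "' is not an mRNA/transcript ID")

  rejected <- data.frame(gene_id = character(), reason = character())
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx_ids <- txs$ID[txs$Parent == gid]
    trs <- lapply(tx_ids, function(tid) {
      ex <- exons[exons$Parent == tid, c("start", "end")]
      ex[order(ex$start), , drop = FALSE]
    })
    names(trs) <- tx_ids
    trs <- trs[vapply(trs, nrow, integer(1L)) > 0L]
    if (!length(trs)) {
      rejected <- rbind(rejected, data.frame(gene_id = gid,
                                             reason = "no exons"))
      next
    }
    gm <- tryCatch(
      gene_model(gid, as.character(genes$seqid[i]),
                 as.character(genes$strand[i]), trs),
      error = function(e) conditionMessage(e))
    if (is.character(gm)) {
      rejected <- rbind(rejected, data.frame(gene_id = gid, reason = gm))
    } else out[[gid]] <- gm
  }
  if (nrow(rejected))
    warning(nrow(rejected), " gene(s) rejected; see attr(x, 'rejected')")
  structure(out, class = "gene_model_set", rejected = rejected)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d gene(s), %d intron(s)\n",
              length(x), nrow(all_introns(x))))
  invisible(x)
}

#' @export
`[.gene_model_set` <- function(x, i) {
  structure(NextMethod(), class = "gene_model_set",
            rejected = attr(x, "rejected"))
}

#' Write gene models to a GFF3 file
#'
#' Deterministic serializer for [gene_model()] collections: identical models
#' always produce byte-identical files (genes in list order, exons by start).
#'
#' @param genes A `gene_model_set` or list of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  rows <- character()
  fmt <- function(chrom, type, s, e, strand, attrs)
    sprintf("%s\tsplicegauge\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, s, e, strand, attrs)
  for (g in genes) {
    sp <- gene_span(g)
    rows <- c(rows, fmt(g$chrom, "gene", sp[1L], sp[2L], g$strand,
                        paste0("ID=", g$gene_id)))
    for (tx in names(g$transcripts)) {
      ex <- g$transcripts[[tx]]
      rows <- c(rows,
                fmt(g$chrom, "mRNA", min(ex$start), max(ex$end), g$strand,
                    paste0("ID=", tx, ";Parent=", g$gene_id)),
                vapply(seq_len(nrow(ex)), function(k)
                  fmt(g$chrom, "exon", ex$start[k], ex$end[k], g$strand,
                      paste0("ID=", tx, ".exon", k, ";Parent=", tx)),
                  character(1L)))
    }
  }
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Table of all pooled introns across a gene set
#' @param genes A `gene_model_set`.
#' @return `data.frame`: `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `transcript`, `index`, plus flanking-exon bounds `up_start`, `up_end`,
#'   `down_start`, `down_end`.
#' @export
all_introns <- function(genes) {
  out <- lapply(genes, function(g) {
    n <- nrow(g$introns)
    if (!n) return(NULL)
    fl <- lapply(seq_len(n), function(i) neighboring_exons(g, i))
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               g$introns,
               up_start   = vapply(fl, function(f) f$upstream$start,  integer(1L)),
               up_end     = vapply(fl, function(f) f$upstream$end,    integer(1L)),
               down_start = vapply(fl, function(f) f$downstream$start, integer(1L)),
               down_end   = vapply(fl, function(f) f$downstream$end,  integer(1L)))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = integer(), end = integer(),
                      transcript = character(), index = integer(),
                      up_start = integer(), up_end = integer(),
                      down_start = integer(), down_end = integer())
  rownames(out) <- NULL
  out
}

#' Table of internal exons (exon-skipping candidates)
#' @param genes A `gene_model_set`.
#' @return `data.frame` with one row per internal exon of each transcript:
#'   `gene_id`, `chrom`, `strand`, `transcript`, `exon_index`, `start`,
#'   `end`, and flanking-exon boundaries `prev_end`, `next_start`.
#' @export
internal_exons <- function(genes) {
  out <- lapply(genes, function(g) {
    rows <- lapply(names(g$transcripts), function(tx) {
      ex <- g$transcripts[[tx]]
      n <- nrow(ex)
      if (n < 3L) return(NULL)
      i <- 2:(n - 1L)
      data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
                 transcript = tx, exon_index = i,
                 start = ex$start[i], end = ex$end[i],
                 prev_end = ex$end[i - 1L], next_start = ex$start[i + 1L])
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      strand = character(), transcript = character(),
                      exon_index = integer(), start = integer(),
                      end = integer(), prev_end = integer(),
                      next_start = integer())
  rownames(out) <- NULL
  out
}

#' Gene spans as a GRanges
#' @param genes A `gene_model_set`.
#' @return A `GRanges` with one range per gene (`gene_id` metadata column).
#' @export
gene_ranges <- function(genes) {
  sp <- vapply(genes, gene_span, integer(2L))
  GenomicRanges::GRanges(
    vapply(genes, function(g) g$chrom, character(1L)),
    IRanges::IRanges(sp[1L, ], sp[2L, ]),
    strand = vapply(genes, function(g) g$strand, character(1L)),
    gene_id = vapply(genes, function(g) g$gene_id, character(1L)))
}

#' Exonic gene length (union of exonic bases)
#' @param genes A `gene_model_set`.
#' @return Named integer vector of union-exon lengths in nt.
#' @export
gene_lengths <- function(genes) {
  vapply(genes, function(g) {
    ex <- do.call(rbind, g$transcripts)
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ex$start, ex$end))))
  }, integer(1L))
}
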