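test_that("CIGAR N operations split alignments into genomic blocks", {
  path <- sam_fixture(list(
    list(qname = "r1", chrom = "chr1", pos = 101L, cigar = "50M100N50M",
         tags = c("NM:i:0", "MD:Z:100")),
    list(qname = "r2", chrom = "chr1", pos = 11L, cigar = "30M20N30M20N30M",
         tags = c("NM:i:0", "MD:Z:90"))))
  rec <- read_sam(path)
  b1 <- rec$blocks[rec$blocks$read == 1L, ]
  expect_equal(b1$start, c(101L, 251L))
  expect_equal(b1$end, c(150L, 300L))
  expect_equal(rec$reads$n_blocks, c(2L, 3L))
})

test_that("identity and end matches derive from NM/MD tags", {
  path <- sam_fixture(list(
    list(qname = "perfect", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = "NM:i:0"),                                 # no MD at all
    list(qname = "mism", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = c("NM:i:4", "MD:Z:4A40C30G20T2")),
    list(qname = "mdonly", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = "MD:Z:50A49"),
    list(qname = "clip", chrom = "chr1", pos = 1L, cigar = "5S95M",
         tags = c("NM:i:0", "MD:Z:95"))))
  rec <- read_sam(path)
  r <- rec$reads
  expect_equal(r$identity[1L], 1.0)
  expect_equal(r$em_left[1L], 100L)
  expect_equal(r$em_right[1L], 100L)
  expect_equal(r$identity[2L], 1 - 4 / 100)
  expect_equal(r$em_left[2L], 4L)
  expect_equal(r$em_right[2L], 2L)
  expect_equal(r$identity[3L], 1 - 1 / 100)   # mismatch reconstructed from MD
  expect_equal(r$em_left[4L], 0L)             # soft-clipped end
})

test_that("unmapped and secondary records are skipped with counts", {
  path <- sam_fixture(list(
    list(qname = "ok", chrom = "chr1", pos = 1L, cigar = "50M",
         tags = c("NM:i:0", "MD:Z:50")),
    list(qname = "un", flag = 4L, chrom = "*", pos = 0L, cigar = "*"),
    list(qname = "sec", flag = 256L, chrom = "chr1", pos = 5L, cigar = "50M")))
  rec <- read_sam(path)
  expect_equal(nrow(rec$reads), 1L)
  expect_equal(unname(rec$skipped[c("unmapped", "secondary")]), c(1L, 1L))
})

test_that("acceptance filters honor their exact boundaries", {
  recs <- list(
    list(qname = "id95", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = c("NM:i:5", "MD:Z:10A10C10G10T10A10C10G10T14")),  # identity .95
    list(qname = "id96_e44", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = c("NM:i:4", "MD:Z:4A20C40G28T4")),
    list(qname = "e3", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = c("NM:i:1", "MD:Z:3A96")),
    list(qname = "b7", chrom = "chr1", pos = 1L, cigar = "50M100N7M",
         tags = c("NM:i:0", "MD:Z:57")),
    list(qname = "b8", chrom = "chr1", pos = 1L, cigar = "8M100N92M",
         tags = c("NM:i:0", "MD:Z:100")),
    list(qname = "single", chrom = "chr1", pos = 1L, cigar = "100M",
         tags = c("NM:i:0", "MD:Z:100")))
  rec <- read_sam(sam_fixture(recs))
  tp <- filter_transcriptome_pass(rec)
  expect_false(tp[1L])  # identity exactly 0.95 fails the strict > threshold
  expect_equal(rec$reads$identity[2L], 0.96)
  expect_true(tp[2L])   # end matches of exactly 4 are accepted
  expect_false(tp[3L])  # a 3 nt terminal run fails
  sb <- filter_short_blocks(rec)
  expect_false(sb[4L])  # block of 7 < 8 removed
  expect_true(sb[5L])   # block of exactly 8 kept
  expect_true(sb[6L])

  # pure predicates: application order cannot matter
  expect_equal(
    apply_filters(apply_filters(rec, tp), filter_short_blocks(apply_filters(rec, tp)))$reads$read_id,
    apply_filters(apply_filters(rec, sb), filter_transcriptome_pass(apply_filters(rec, sb)))$reads$read_id)
})

test_that("depth counts every block base once and conserves totals", {
  path <- sam_fixture(list(
    list(qname = "a", chrom = "chr1", pos = 1L, cigar = "10M",
         tags = c("NM:i:0", "MD:Z:10")),
    list(qname = "b", chrom = "chr1", pos = 1L, cigar = "10M",
         tags = c("NM:i:0", "MD:Z:10")),
    list(qname = "c", chrom = "chr1", pos = 101L, cigar = "20M30N20M",
         tags = c("NM:i:0", "MD:Z:40"))))
  rec <- read_sam(path)
  depth <- compute_depth(rec)
  expect_equal(as.numeric(depth$chr1[1:10]), rep(2, 10))
  expect_equal(as.numeric(depth$chr1[11]), 0)
  expect_equal(sum(sum(depth)),
               sum(rec$blocks$end - rec$blocks$start + 1L))
})

test_that("every adjacent block pair yields one junction count", {
  path <- sam_fixture(list(
    list(qname = "j1", chrom = "chr1", pos = 101L, cigar = "50M100N50M",
         tags = c("NM:i:0", "MD:Z:100")),
    list(qname = "j1b", chrom = "chr1", pos = 121L, cigar = "30M100N70M",
         tags = c("NM:i:0", "MD:Z:100")),
    list(qname = "j2", chrom = "chr1", pos = 11L, cigar = "30M20N30M20N30M",
         tags = c("NM:i:0", "MD:Z:90"))))
  rec <- read_sam(path)
  j <- extract_junctions(rec)
  expect_equal(sum(j$count), 4L)  # 1 + 1 (same junction) + 2 (triple read)
  expect_equal(j$count[j$donor == 150L & j$acceptor == 251L], 2L)
  expect_equal(nrow(j[j$donor %in% c(40L, 90L), ]), 2L)
})

test_that("unique gene reads require containment in exactly one gene", {
  rows <- c(simple_gene_rows(id = "gA", exons = list(c(101L, 400L))),
            simple_gene_rows(id = "gB", exons = list(c(350L, 700L))),
            simple_gene_rows(id = "gC", exons = list(c(1001L, 1300L))))
  genes <- read_gff3(gff_fixture(rows))
  path <- sam_fixture(list(
    list(qname = "inA", chrom = "chr1", pos = 110L, cigar = "50M",
         tags = c("NM:i:0", "MD:Z:50")),
    list(qname = "ambig", chrom = "chr1", pos = 340L, cigar = "50M",
         tags = c("NM:i:0", "MD:Z:50")),
    list(qname = "inC", chrom = "chr1", pos = 1100L, cigar = "50M",
         tags = c("NM:i:0", "MD:Z:50"))))
  rec <- read_sam(path)
  cnt <- count_gene_reads(rec, genes)
  expect_equal(cnt$total, c(2L, 1L, 1L))   # ambiguous read in both totals
  expect_equal(cnt$unique, c(1L, 0L, 1L))  # but in neither unique count
})

test_that("unique counts on simulated non-overlapping genes equal fragments", {
  sc <- splice_scenario(n_genes = 8, expression = 60, seed = 21)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_wt[1L])
  cnt <- count_gene_reads(rec, coh$ann$genes)
  expect_equal(setNames(cnt$unique, cnt$gene_id),
               coh$fragment_counts[, "wt_1"])
  expect_equal(nrow(rec$reads), sum(coh$fragment_counts[, "wt_1"]))
})
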