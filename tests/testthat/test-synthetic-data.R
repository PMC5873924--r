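test_that("scenario validation rejects infeasible parameterizations", {
  expect_error(splice_scenario(retention = 1.2), "fractions")
  expect_error(splice_scenario(replicates = 1L), "replicates")
  expect_error(splice_scenario(alt_offset = 0L), "alt_offset")
  expect_error(splice_scenario(read_len = 1000L), "read_len")
})

test_that("same scenario and seed give byte-identical outputs", {
  sc <- splice_scenario(n_genes = 6, expression = 40,
                        ir_introns = 1, alt_acceptor_introns = 1, seed = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_cohort(sc, d1)
  simulate_cohort(sc, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # a different seed changes the reads
  sc2 <- splice_scenario(n_genes = 6, expression = 40,
                         ir_introns = 1, alt_acceptor_introns = 1, seed = 4)
  d3 <- withr::local_tempdir()
  simulate_cohort(sc2, d3)
  expect_false(identical(readLines(file.path(d1, "wt_1.sam")),
                         readLines(file.path(d3, "wt_1.sam"))))
})

test_that("one SAM record is emitted per generated fragment", {
  sc <- splice_scenario(n_genes = 10, expression = 50, seed = 8)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  for (s in seq_len(3)) {
    n_rec <- sum(!startsWith(readLines(coh$sam_wt[s]), "@"))
    expect_equal(n_rec, sum(coh$fragment_counts[, paste0("wt_", s)]))
  }
})

test_that("zero retention leaves intron interiors uncovered", {
  sc <- splice_scenario(n_genes = 10, expression = 80, retention = 0, seed = 6)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_mut[1L])
  depth <- compute_depth(rec)
  introns <- all_introns(coh$ann$genes)
  for (i in seq_len(nrow(introns))) {
    expect_equal(sum(IRanges::viewSums(IRanges::Views(
      depth[[introns$chrom[i]]], introns$start[i], introns$end[i]))), 0)
  }
  expect_gt(nrow(extract_junctions(rec)), 0L)
})

test_that("full retention yields contiguous coverage and no junctions", {
  sc <- splice_scenario(n_genes = 6, expression = 60, retention = 1, seed = 6)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_wt[1L])
  expect_equal(nrow(extract_junctions(rec)), 0L)
  expect_true(all(rec$reads$n_blocks == 1L))
})

test_that("measured retention tracks the generative fraction (binomial oracle)", {
  # introns whose flanks are both internal exons, away from the coverage
  # ramps at transcript termini that depress terminal-exon mean depth
  sc <- splice_scenario(n_genes = 40, exons_per_gene = c(4L, 4L),
                        expression = 700, retention = 0.3, seed = 14)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  ing <- ingest_cohort(coh)
  tab <- ir_ratio_table(ing$depths, coh$ann$genes)
  mid <- tab$introns$index == 2L
  est <- rowMeans(tab$ratios[mid, , drop = FALSE])  # mean over 6 replicates
  # per-intron binomial SE on the scale of fragments overlapping the intron
  iw <- (tab$introns$end - tab$introns$start + 1L)[mid]
  n_frag <- 6 * 50 * (iw + sc$read_len) / sc$read_len
  se <- sqrt(0.3 * 0.7 / n_frag)
  within3 <- abs(est - 0.3) <= 3 * se + 0.015  # anchored-placement slack
  expect_gt(mean(within3), 0.9)
  expect_lt(abs(mean(est) - 0.3), 0.02)
})

test_that("reporter reads are exact for their variant", {
  mk <- function(p_wt) {
    reporter_locus_spec(proportions_wt = p_wt,
                        proportions_mut = p_wt, n_fragments = 200L)
  }
  sc <- splice_scenario(n_genes = 2, expression = 20,
                        reporter = mk(c(1, 0, 0)), seed = 5)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_wt[1L])
  rep_reads <- rec$reads[rec$reads$chrom == "chrR", ]
  expect_equal(nrow(rep_reads), 200L)
  expect_true(all(rep_reads$n_blocks == 1L))   # all unspliced -> contiguous

  sc2 <- splice_scenario(n_genes = 2, expression = 20,
                         reporter = mk(c(0, 1, 0)), seed = 5)
  coh2 <- simulate_cohort(sc2, withr::local_tempdir())
  rec2 <- read_sam(coh2$sam_wt[1L])
  j <- extract_junctions(rec2)
  j <- j[j$chrom == "chrR", ]
  loc <- coh2$ann$truth$reporter
  expect_equal(nrow(j), 1L)                    # single canonical junction
  expect_equal(j$donor, unname(loc$canonical["start"]) - 1L)
  expect_equal(j$acceptor, unname(loc$canonical["end"]) + 1L)
  expect_equal(j$count, 200L)
})

test_that("generator ground truth labels planted events", {
  sc <- splice_scenario(n_genes = 40, exons_per_gene = c(3L, 4L),
                        ir_introns = 4, mes_introns = 3, skip_exons = 2,
                        alt_acceptor_introns = 2, alt_donor_introns = 1,
                        deg_up = 3, deg_down = 2, expression = 30, seed = 2)
  ann <- generate_annotation(sc)
  expect_equal(sum(ann$truth$introns$planted == "IR", na.rm = TRUE), 4L)
  expect_equal(sum(ann$truth$introns$planted == "MES", na.rm = TRUE), 3L)
  expect_equal(nrow(ann$truth$skips), 2L)
  expect_equal(nrow(ann$truth$alts), 3L)
  expect_equal(sum(ann$truth$genes$planted == "up", na.rm = TRUE), 3L)
  # planted retention folds are encoded in the truth table
  ir <- ann$truth$introns[!is.na(ann$truth$introns$planted) &
                            ann$truth$introns$planted == "IR", ]
  expect_equal(ir$ret_mut / ir$ret_wt, rep(sc$ir_fold, 4L))
  # alt junctions differ from the annotated boundaries on the planted side
  for (k in seq_len(nrow(ann$truth$alts))) {
    a <- ann$truth$alts[k, ]
    intr <- ann$truth$introns[a$intron_row, ]
    expect_true(a$donor != intr$start - 1L || a$acceptor != intr$end + 1L)
  }
})
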