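ratio_gene <- function() {
  gene_model("gR", "chr1", "+", list(
    t1 = data.frame(start = c(101L, 301L), end = c(200L, 400L))))
}

depth_from_runs <- function(vals, len = 1000L) {
  v <- numeric(len)
  for (r in vals) v[r$at[1L]:r$at[2L]] <- r$depth
  IRanges::RleList(chr1 = S4Vectors::Rle(v))
}

test_that("intron retention ratio is intron depth over pooled flank depth", {
  g <- ratio_gene()
  d <- depth_from_runs(list(list(at = c(101L, 200L), depth = 40),
                            list(at = c(201L, 300L), depth = 10),
                            list(at = c(301L, 400L), depth = 40)))
  expect_equal(intron_retention_ratio(d, g, 1L), 0.25)

  d0 <- depth_from_runs(list(list(at = c(101L, 200L), depth = 40),
                             list(at = c(301L, 400L), depth = 40)))
  expect_equal(intron_retention_ratio(d0, g, 1L), 0)

  # zero flank depth -> undefined, flagged as NA, never 0 or Inf
  dz <- depth_from_runs(list(list(at = c(201L, 300L), depth = 5)))
  expect_true(is.na(intron_retention_ratio(dz, g, 1L)))

  # asymmetric flanks pool base-wise: one average over all flank bases
  da <- depth_from_runs(list(list(at = c(101L, 200L), depth = 10),
                             list(at = c(201L, 300L), depth = 15),
                             list(at = c(301L, 400L), depth = 50)))
  expect_equal(intron_retention_ratio(da, g, 1L), 15 / 30)
})

test_that("intron ratios match a brute-force recomputation from blocks", {
  sc <- splice_scenario(n_genes = 6, expression = 60, retention = 0.3,
                        seed = 17)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_wt[1L])
  depth <- compute_depth(rec)
  tab <- ir_ratio_table(list(wt_1 = depth), coh$ann$genes)
  for (i in seq_len(nrow(tab$introns))) {
    it <- tab$introns[i, ]
    expect_equal(unname(tab$ratios[i, 1L]),
                 oracle_ir_ratio(rec$blocks, it$chrom,
                                 c(it$start, it$end),
                                 c(it$up_start, it$up_end),
                                 c(it$down_start, it$down_end)),
                 tolerance = 1e-12)
  }
})

test_that("intron classification applies the dual p and fold gates", {
  introns <- data.frame(gene_id = paste0("g", 1:4), chrom = "chr1",
                        strand = "+", start = c(201L, 601L, 1001L, 1401L),
                        end = c(300L, 700L, 1100L, 1500L),
                        transcript = "t", index = 1L,
                        up_start = 1L, up_end = 2L,
                        down_start = 3L, down_end = 4L)
  ratios <- rbind(c(0.10, 0.11, 0.09, 0.30, 0.31, 0.29),  # clear IR
                  c(0.10, 0.11, 0.09, 0.10, 0.11, 0.09),  # identical
                  c(0.100, 0.101, 0.099, 0.190, 0.191, 0.189),  # fold 1.9
                  c(0.30, 0.31, 0.29, 0.10, 0.11, 0.09))  # clear MES
  colnames(ratios) <- c(paste0("wt_", 1:3), paste0("mut_", 1:3))
  cl <- classify_introns(list(introns = introns, ratios = ratios),
                         rep(c("wt", "mut"), each = 3))
  res <- cl$results
  expect_equal(res$class, c("IR", "none", "none", "MES"))
  expect_equal(res$p[1],
               t.test(ratios[1, 4:6], ratios[1, 1:3])$p.value,
               tolerance = 1e-12)
  expect_equal(res$p[2], 1)
  expect_lt(res$p[3], 0.01)  # significant, but the 2x fold gate fails
})

test_that("undefined and excluded introns are skipped with reasons", {
  introns <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                        strand = "+", start = c(201L, 601L),
                        end = c(300L, 700L), transcript = "t", index = 1L,
                        up_start = 1L, up_end = 2L, down_start = 3L,
                        down_end = 4L)
  ratios <- rbind(c(0.1, NA, 0.1, 0.3, 0.3, 0.3),
                  c(0.1, 0.1, 0.1, 0.5, 0.5, 0.5))
  cl <- classify_introns(list(introns = introns, ratios = ratios),
                         rep(c("wt", "mut"), each = 3), exclude = "gB")
  expect_equal(nrow(cl$results), 0L)
  expect_setequal(cl$skipped$reason,
                  c("undefined ratio in a replicate", "excluded locus"))
})

test_that("AS and expression ratios follow the pseudocounted formulas", {
  expect_equal(as_ratio(20, 5, pseudocount = 0), 4)
  expect_equal(as_ratio(0, 0), 1)
  expect_equal(as_ratio(0, 0, log2 = TRUE), 0)
  expect_equal(expression_ratio(20, 200, pseudocount = 0), 0.1)
  expect_equal(expression_ratio(0, 9), (0 + 1) / (9 + 1))
  expect_equal(as_ratio(c(3, 7), c(1, 0)), c(2, 8))
})

test_that("candidate enumeration classifies junction geometry strand-aware", {
  rows <- c(simple_gene_rows(id = "gP",
                             exons = list(c(101L, 200L), c(301L, 400L))),
            simple_gene_rows(id = "gM", chrom = "chr2",
                             exons = list(c(101L, 200L), c(301L, 400L)),
                             strand = "-"),
            simple_gene_rows(id = "gE", chrom = "chr3",
                             exons = list(c(101L, 200L), c(301L, 400L),
                                          c(501L, 600L))))
  genes <- read_gff3(gff_fixture(rows))
  obs <- data.frame(
    chrom = c("chr1", "chr1", "chr2", "chr3", "chr3", "chr3"),
    donor = c(200L, 200L, 200L, 200L, 400L, 200L),
    acceptor = c(298L, 301L, 298L, 501L, 501L, 301L))
  cand <- enumerate_as_events(obs, genes)

  # acceptor moved 3 nt on the plus strand: alternative 3' splice site
  p <- cand[cand$gene_id == "gP", ]
  expect_equal(nrow(p), 1L)
  expect_equal(p$type, "alt_acceptor")
  expect_equal(p$acceptor, 298L)
  # the annotated junction itself is never a candidate
  expect_false(any(cand$donor == 200L & cand$acceptor == 301L))
  # same geometry on the minus strand is an alternative donor (5' site)
  m <- cand[cand$gene_id == "gM", ]
  expect_equal(m$type, "alt_donor")
  # junction joining exon 1 to exon 3 skips exon 2
  e <- cand[cand$gene_id == "gE" & cand$type == "exon_skip", ]
  expect_equal(nrow(e), 1L)
  expect_equal(c(e$donor, e$acceptor), c(200L, 501L))
  expect_equal(c(e$ns1_donor, e$ns1_acceptor), c(200L, 301L))
  expect_equal(c(e$ns2_donor, e$ns2_acceptor), c(400L, 501L))
  # the skip junction is not double-counted as an alt event
  expect_false(any(cand$type != "exon_skip" & cand$gene_id == "gE" &
                     cand$acceptor == 501L))
})

test_that("AS events are reported only when both t-tests pass", {
  cand <- data.frame(gene_id = "gP", chrom = "chr1", strand = "+",
                     type = "alt_acceptor", donor = 200L, acceptor = 298L,
                     ref_start = 201L, ref_end = 300L,
                     ns1_donor = 200L, ns1_acceptor = 301L,
                     ns2_donor = NA_integer_, ns2_acceptor = NA_integer_)
  samples <- c(paste0("wt_", 1:3), paste0("mut_", 1:3))
  groups <- rep(c("wt", "mut"), each = 3)
  jmat <- data.frame(chrom = "chr1", donor = c(200L, 200L),
                     acceptor = c(298L, 301L))
  jmat[samples] <- 0L
  jmat[1, samples] <- c(2L, 3L, 2L, 60L, 55L, 58L)    # novel junction
  jmat[2, samples] <- c(80L, 75L, 82L, 30L, 31L, 29L) # annotated junction
  ucounts <- matrix(rep(c(200L, 210L, 190L, 205L, 195L, 200L), 1),
                    nrow = 1, dimnames = list("gP", samples))
  res <- classify_as_events(cand, jmat, ucounts, groups)
  expect_true(res$reported)
  expect_equal(res$class, "enhanced")
  expect_lt(res$p_as, 0.01)
  expect_lt(res$p_expr, 0.01)
  # identical groups: both p = 1, unreported
  jmat2 <- jmat
  jmat2[1, samples] <- 10L
  jmat2[2, samples] <- 40L
  u2 <- matrix(200L, 1, 6, dimnames = list("gP", samples))
  res2 <- classify_as_events(cand, jmat2, u2, groups)
  expect_equal(res2$p_as, 1)
  expect_false(res2$reported)
  # AS ratio shifts but gene-level expression ratio does not: unreported
  jmat3 <- jmat
  jmat3[1, samples] <- c(10L, 11L, 9L, 30L, 31L, 29L)
  jmat3[2, samples] <- c(90L, 89L, 91L, 28L, 30L, 29L)
  u3 <- matrix(c(300L, 310L, 290L, 840L, 860L, 815L), 1,
               dimnames = list("gP", samples))
  res3 <- classify_as_events(cand, jmat3, u3, groups)
  expect_lt(res3$p_as, 0.01)
  expect_gt(res3$p_expr, 0.01)
  expect_false(res3$reported)
})

test_that("events with zero support everywhere are never candidates", {
  cand <- data.frame(gene_id = "gX", chrom = "chr1", strand = "+",
                     type = "alt_donor", donor = 150L, acceptor = 301L,
                     ref_start = 201L, ref_end = 300L,
                     ns1_donor = 200L, ns1_acceptor = 301L,
                     ns2_donor = NA_integer_, ns2_acceptor = NA_integer_)
  samples <- c(paste0("wt_", 1:3), paste0("mut_", 1:3))
  jmat <- data.frame(chrom = "chr1", donor = 200L, acceptor = 301L)
  jmat[samples] <- 50L
  u <- matrix(100L, 1, 6, dimnames = list("gX", samples))
  res <- classify_as_events(cand, jmat, u, rep(c("wt", "mut"), each = 3))
  expect_equal(nrow(res), 0L)
})

test_that("depth rescaling of one replicate leaves its ratios unchanged", {
  sc <- splice_scenario(n_genes = 5, expression = 80, retention = 0.2,
                        seed = 23)
  coh <- simulate_cohort(sc, withr::local_tempdir())
  rec <- read_sam(coh$sam_wt[1L])
  d1 <- compute_depth(rec)
  d2 <- d1 * 3L
  t1 <- ir_ratio_table(list(s = d1), coh$ann$genes)
  t2 <- ir_ratio_table(list(s = d2), coh$ann$genes)
  expect_equal(t1$ratios, t2$ratios)
})

test_that("summary tallies events with the right denominators", {
  rows <- c(simple_gene_rows(id = "g1",
                             exons = list(c(101L, 200L), c(301L, 400L),
                                          c(501L, 600L))),
            simple_gene_rows(id = "g2", chrom = "chr2",
                             exons = list(c(101L, 200L), c(301L, 400L))))
  genes <- read_gff3(gff_fixture(rows))
  empty <- summarize_events(NULL, NULL, NULL, genes)
  expect_true(all(empty$count == 0L))
  expect_equal(empty$denominator[empty$category == "IR"], 3L)
  expect_equal(empty$denominator[empty$category == "exon_skip"], 1L)

  ir <- data.frame(class = c("IR", "IR", "MES", "none"))
  deg <- data.frame(call = c("up", "down", "none"))
  as_ev <- data.frame(type = c("alt_acceptor", "alt_acceptor", "alt_donor",
                               "exon_skip"),
                      reported = c(TRUE, TRUE, TRUE, FALSE))
  s <- summarize_events(deg, ir, as_ev, genes)
  expect_equal(s$count[s$category == "IR"], 2L)
  expect_equal(s$percent[s$category == "IR"], 100 * 2 / 3)
  expect_equal(s$count[s$category == "alt_3ss"], 2L)
  expect_equal(s$count[s$category == "exon_skip"], 0L)  # unreported
})
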