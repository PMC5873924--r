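#' TMM normalization factors
#'
#' Weighted trimmed mean of M-values between-sample normalization for count
#' libraries. For each sample against a reference column, per-gene log2
#' expression ratios (M) and average log2 abundances (A) are computed on
#' library-size-scaled counts; genes with a zero count in either sample are
#' excluded; the M values are trimmed 30% on each side by M and 5% on each
#' side by A; the surviving M values are averaged with inverse
#' asymptotic-variance weights and exponentiated. The reference column is the
#' sample whose 75th count percentile (scaled by library size) is closest to
#' the mean across samples. Factors are rescaled to geometric mean 1. A
#' sample whose trimmed M values are all within 1e-6 of zero gets factor
#' exactly 1, so identical or globally rescaled columns are left untouched.
#'
#' @param counts Nonnegative numeric matrix, genes x samples.
#' @param lib_size Library sizes; defaults to column sums.
#' @param trim_m,trim_a Two-sided trim fractions on M and A (defaults 0.30
#'   and 0.05).
#' @return Numeric vector of positive per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts),
                        trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(lib_size <= 0)) stop("normalization error: sample with all-zero counts")
  uq <- apply(counts, 2L, quantile, probs = 0.75) / lib_size
  ref <- if (stats::median(uq) < 1e-20) which.max(colSums(sqrt(counts)))
         else which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i)
    tmm_pair(counts[, i], counts[, ref], lib_size[i], lib_size[ref],
             trim_m, trim_a), numeric(1L))
  f / exp(mean(log(f)))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  m <- log2(p_obs / p_ref)
  a <- (log2(p_obs) + log2(p_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  ok <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[ok]; a <- a[ok]; w <- w[ok]
  if (!length(m) || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(m[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' log2 counts per million
#'
#' `logCPM = log2((count + prior) / (effective library size + 2 * prior) * 1e6)`
#' with effective library size = library size x TMM factor.
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Per-sample normalization factors (default all 1).
#' @param prior Pseudocount added to each count (default 0.5).
#' @param lib_size Library sizes; defaults to column sums.
#' @return Matrix of logCPM values, same shape as `counts`.
#' @export
logcpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5,
                   lib_size = colSums(counts)) {
  counts <- as.matrix(counts)
  eff <- lib_size * factors
  lc <- log2(sweep(counts + prior, 2L, eff + 2 * prior, "/") * 1e6)
  dimnames(lc) <- dimnames(counts)
  lc
}

#' RPKM from logCPM
#'
#' `RPKM = 2^logCPM / (length / 1000)` with `length` the exonic gene length
#' in nt (union of exonic bases across transcripts).
#'
#' @param lc logCPM matrix, genes x samples.
#' @param lengths Per-gene exonic lengths in nt (recycled across columns).
#' @return Matrix of RPKM values.
#' @export
rpkm_from_logcpm <- function(lc, lengths) {
  if (any(lengths < 1)) stop("configuration error: gene length < 1")
  2^lc / (lengths / 1000)
}

#' Welch two-sample t-test (textbook form)
#'
#' Two-sided unequal-variance t-test with Welch-Satterthwaite degrees of
#' freedom. Degenerate inputs are resolved explicitly: when both groups have
#' zero variance, p is 1 if the means are equal (no evidence of difference)
#' and 0 otherwise.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  r <- welch_t_rows(matrix(x, nrow = 1L), matrix(y, nrow = 1L))
  list(statistic = r$statistic[1L], df = r$df[1L], p_value = r$p_value[1L])
}

#' Row-wise Welch t-tests
#'
#' Vectorized [welch_t()] over the rows of two matrices (groups in columns).
#'
#' @param x,y Numeric matrices with equal row counts and >= 2 columns each.
#' @return List of vectors `statistic`, `df`, `p_value` (one per row).
#' @export
welch_t_rows <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) >= 2L, ncol(y) >= 2L)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1L) + (vy / ny)^2 / (ny - 1L))
  p <- 2 * pt(-abs(tt), df)
  zero <- se2 == 0 & !is.na(se2)
  if (any(zero)) {
    eq <- zero & mx == my
    p[eq] <- 1; tt[eq] <- 0; df[eq] <- nx + ny - 2L
    ne <- zero & mx != my
    p[ne] <- 0; tt[ne] <- sign(mx[ne] - my[ne]) * Inf; df[ne] <- nx + ny - 2L
  }
  list(statistic = tt, df = df, p_value = p)
}

#' Call differentially expressed genes
#'
#' Welch two-sided t-test per gene on per-sample RPKM (or log2 RPKM) values;
#' fold change is mean(treatment RPKM) / mean(reference RPKM). A gene is
#' `up` if FC >= `fold` and p < `p_cutoff`, `down` if FC <= 1/`fold` and
#' p < `p_cutoff`, else `none`. No multiple-testing correction is applied
#' (raw p-value thresholds throughout; see the methods vignette for the
#' caveat).
#'
#' @param rpkm RPKM matrix, genes x samples (rownames = gene ids).
#' @param groups Character/factor vector over columns naming each sample's
#'   condition.
#' @param reference,treatment The two condition labels (defaults `"wt"`,
#'   `"mut"`); fold change is treatment over reference.
#' @param p_cutoff,fold Significance and fold-change gates (defaults 0.01, 2).
#' @param on_log If `TRUE`, the t-test runs on `log2(rpkm + log_eps)` values
#'   (fold change is still computed on the raw scale).
#' @param log_eps Offset for the log transform (default 1e-4 RPKM).
#' @return `data.frame`: `gene_id`, `mean_ref`, `mean_trt`, `fc`, `p`,
#'   `call`.
#' @export
call_degs <- function(rpkm, groups, reference = "wt", treatment = "mut",
                      p_cutoff = 0.01, fold = 2, on_log = FALSE,
                      log_eps = 1e-4) {
  rpkm <- as.matrix(rpkm)
  stopifnot(length(groups) == ncol(rpkm))
  ref_i <- which(groups == reference); trt_i <- which(groups == treatment)
  if (length(ref_i) < 2L || length(trt_i) < 2L)
    stop("need >= 2 replicates per condition")
  xin <- if (on_log) log2(rpkm + log_eps) else rpkm
  wt <- welch_t_rows(xin[, trt_i, drop = FALSE], xin[, ref_i, drop = FALSE])
  mean_ref <- rowMeans(rpkm[, ref_i, drop = FALSE])
  mean_trt <- rowMeans(rpkm[, trt_i, drop = FALSE])
  fc <- mean_trt / mean_ref
  call <- rep("none", nrow(rpkm))
  sig <- wt$p_value < p_cutoff & !is.na(wt$p_value)
  call[sig & !is.na(fc) & fc >= fold] <- "up"
  call[sig & !is.na(fc) & fc <= 1 / fold] <- "down"
  data.frame(gene_id = rownames(rpkm) %||% as.character(seq_len(nrow(rpkm))),
             mean_ref = mean_ref, mean_trt = mean_trt, fc = fc,
             p = wt$p_value, call = call, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
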