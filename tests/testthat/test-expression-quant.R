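test_that("read normalization follows the six-step procedure", {
  cal <- bin_calibration(bin_areas = c(25, 25, 25, 25))
  counts <- rbind(v1 = c(10, 0, 0, 0))
  nr <- normalize_reads(counts, cal, bin_totals = c(100, 200, 300, 400))
  expect_equal(unname(nr$normalized[1, ]), c(1, 0, 0, 0))

  # per-bin depth invariance: scaling bin-3 counts and its total cancels
  counts2 <- rbind(v1 = c(5, 10, 20, 5), v2 = c(2, 8, 30, 10))
  t0 <- c(50, 80, 100, 40)
  a <- normalize_reads(counts2, cal, bin_totals = t0)
  counts3 <- counts2; counts3[, 3] <- counts3[, 3] * 10
  b <- normalize_reads(counts3, cal, bin_totals = t0 * c(1, 1, 10, 1))
  expect_equal(a$normalized, b$normalized)

  # equal adjusted reads in all bins -> uniform vector
  eq <- normalize_reads(rbind(v = c(10, 10, 10, 10)), cal,
                        bin_totals = c(100, 100, 100, 100))
  expect_equal(unname(eq$normalized[1, ]), rep(0.25, 4))

  # with uniform %Bin and equal totals, normalization is a plain proportion
  set.seed(1)
  cc <- matrix(rpois(20, 30), nrow = 5)
  rownames(cc) <- paste0("v", 1:5)
  pr <- normalize_reads(cc, cal, bin_totals = rep(1000, 4))$normalized
  expect_equal(pr, cc / rowSums(cc), ignore_attr = TRUE)

  # non-uniform areas re-weight the bins
  cal2 <- bin_calibration(bin_areas = c(10, 20, 30, 40))
  nr2 <- normalize_reads(rbind(v = c(10, 10, 10, 10)), cal2,
                         bin_totals = rep(100, 4))
  expect_equal(unname(nr2$normalized[1, ]), c(0.1, 0.2, 0.3, 0.4))

  # zero-read variants are flagged and excluded from expression
  nr3 <- normalize_reads(rbind(v1 = c(1, 0, 0, 0), v0 = c(0, 0, 0, 0)), cal)
  expect_equal(nr3$flagged, "v0")
  expect_true(all(is.na(nr3$normalized["v0", ])))
})

test_that("bin-weighted expression hits the calibration endpoints and mean", {
  cal <- bin_calibration()
  expect_equal(compute_expression(c(0, 0, 0, 1), cal), 7541)
  expect_equal(compute_expression(c(1, 0, 0, 0), cal), 607)
  expect_equal(compute_expression(rep(0.25, 4), cal), 3027)
  expect_error(compute_expression(c(0.5, 0.2, 0.1, 0.1), cal), "sum to 1")
  # bounded by the extreme bin means; moving mass upward strictly increases it
  set.seed(2)
  for (i in 1:20) {
    p <- as.vector(stats::rmultinom(1, 50, rep(0.25, 4))) / 50
    e <- compute_expression(p, cal)
    expect_gte(e, 607); expect_lte(e, 7541)
    if (p[1] > 0) {
      q <- p + c(-1, 0, 0, 1) / 50
      expect_gt(compute_expression(q, cal), e)
    }
  }
})

test_that("quality groups split on read support and top-bin saturation", {
  norm <- rbind(c(0.25, 0.25, 0.25, 0.25),
                c(0.02, 0.01, 0.02, 0.95),
                c(0.25, 0.25, 0.25, 0.25),
                c(0.05, 0.05, 0.10, 0.80))
  expect_equal(classify_group(norm, c(100, 100, 39, 40)), c(1L, 2L, 3L, 1L))
  # the boundary read count of exactly 40 is not group 3
  expect_equal(classify_group(norm[1, , drop = FALSE], 40), 1L)
})

test_that("the quantification wrapper produces consistent records", {
  set.seed(4)
  counts <- matrix(rpois(40, 30), nrow = 10)
  rownames(counts) <- sprintf("v%02d", 1:10)
  counts[10, ] <- 0
  rec <- quantify_expression(counts)
  expect_s3_class(rec, "expression_records")
  expect_equal(nrow(rec), 10)
  ok <- !is.na(rec$expression)
  expect_equal(rowSums(as.matrix(rec[ok, c("x", "y", "z", "w")])),
               rep(1, sum(ok)), ignore_attr = TRUE)
  expect_true(all(is.na(rec$expression[10])))
  expect_equal(rec$group[10], 3L)
})

test_that("barcode aggregation pools read-weighted information", {
  counts <- rbind(b1 = c(8, 2, 0, 0), b2 = c(4, 1, 0, 0), b3 = c(0, 0, 5, 5))
  rec <- quantify_expression(counts, min_reads = 1)
  agg <- aggregate_barcodes(rec, c("vA", "vA", "vB"), counts = counts,
                            min_reads = 1)
  expect_equal(agg$variant_id, c("vA", "vB"))
  expect_equal(agg$total_reads, c(15, 10))
  # b1 and b2 have identical proportions, so the weighted mean preserves them
  expect_equal(unname(unlist(agg[1, c("x", "y", "z", "w")])),
               unname(unlist(rec[1, c("x", "y", "z", "w")])))
  # pooled mode agrees when barcodes share the bin totals
  pooled <- aggregate_barcodes(rec, c("vA", "vA", "vB"), counts = counts,
                               mode = "pooled", min_reads = 1)
  expect_equal(pooled$total_reads, agg$total_reads)
})

test_that("per-motif distributions use at-least-once membership", {
  variants <- data.frame(variant_id = c("d", "s1", "s2", "rep"),
                         arity = c(0, 1, 1, 2),
                         motifs = c("", "mA", "mB", "mA,mA"),
                         starts = c("", "46", "46", "28,66"))
  catalog <- motif_catalog(data.frame(motif_id = c("mA", "mB"),
                                      sequence = c("ACGTACGTAC", "TGCATGCATG"),
                                      known_function = "unknown",
                                      source_organism = "synthetic"))
  rec <- data.frame(variant_id = variants$variant_id,
                    expression = c(1000, 2000, 3000, 4000),
                    total_reads = 100, group = 1L)
  dist <- per_motif_distributions(rec, variants, catalog)
  # the double-mA variant contributes once to mA's group
  expect_equal(sort(dist$values$mA), c(2000, 4000))
  expect_equal(dist$values$mB, 3000)
  # desert group: variants with an unfilled slot (arity < max observed)
  expect_equal(sort(dist$values$desert), c(1000, 2000, 3000))
  expect_equal(dist$summary$n[dist$summary$motif_id == "mA"], 2L)
})

test_that("rank-shift testing flags separated motif groups", {
  set.seed(8)
  vals <- c(lapply(1:6, function(i) rnorm(40, mean = i * 4)),
            lapply(7:12, function(i) rnorm(40, mean = 24)))
  names(vals) <- sprintf("g%02d", 1:12)
  dist <- list(values = vals)
  res <- rank_shift_test(dist, rank_offset = 5, fdr = 0.10)
  expect_equal(nrow(res), 12)
  # the extreme low group differs strongly from groups >= 5 ranks away
  expect_true(res$significant[res$motif_id == "g01"])
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
  # identical groups far apart are not called shifted
  same <- list(values = stats::setNames(
    lapply(1:7, function(i) c(rnorm(30))), paste0("s", 1:7)))
  same$values <- lapply(same$values, function(x) same$values[[1]])
  res2 <- rank_shift_test(same, rank_offset = 5, fdr = 0.10)
  expect_true(all(res2$p > 0.5, na.rm = TRUE))
})

test_that("barcode-pair correlations behave on constructed vectors", {
  rec <- data.frame(variant_id = NA,
                    x = c(0.7, 0.7, 0.4, 0.1, 0.25, 0.25),
                    y = c(0.2, 0.2, 0.3, 0.2, 0.25, 0.25),
                    z = c(0.1, 0.1, 0.2, 0.3, 0.25, 0.25),
                    w = c(0.0, 0.0, 0.1, 0.4, 0.25, 0.25),
                    expression = 1000, total_reads = 50)
  out <- barcode_pair_correlation(rec, c("vsame", "vsame", "vrev", "vrev",
                                         "vflat", "vflat"))
  expect_equal(out$r[out$variant_id == "vsame"], 1)
  expect_equal(out$r[out$variant_id == "vrev"], -1)
  expect_true(out$flagged[out$variant_id == "vflat"])
  expect_true(is.na(out$r[out$variant_id == "vflat"]))
})

test_that("median-vs-count correlation detects ordered and anti-ordered groups", {
  mk <- function(medians, ns) {
    list(summary = data.frame(motif_id = seq_along(medians), n = ns,
                              median = medians, q1 = NA, q3 = NA))
  }
  expect_equal(median_vs_count_correlation(mk(c(1, 2, 3, 4), c(10, 20, 30, 40)))$r, 1)
  expect_equal(median_vs_count_correlation(mk(c(4, 3, 2, 1), c(10, 20, 30, 40)))$r, -1)
  expect_true(median_vs_count_correlation(mk(c(2, 2, 2), c(5, 5, 5)))$flagged)
  expect_error(median_vs_count_correlation(mk(c(1, 2), c(1, 2))), "at least 3")
})
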