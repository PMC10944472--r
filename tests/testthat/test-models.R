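test_that("the motif-additive model composes boost, attenuation and core level", {
  m <- mam(boost_weights = c(act1 = 2, act2 = 4), repressors = "rep1",
           core_levels = c(weak = 100, strong = 800),
           calibration = c(intercept = 1, slope = 0.5))
  # motif-free cassette: fold 1, expression = core level
  p0 <- predict(m, list(character(0)))
  expect_equal(p0$fold, 1)
  expect_equal(p0$expression, 100)
  # one repressor, no activators: fold = attenuation factor
  expect_equal(predict(m, list("rep1"))$fold, 0.5)
  # attenuation is applied once regardless of repressor count
  expect_equal(predict(m, list(c("rep1", "rep1", "rep1")))$fold, 0.5)
  # boost is additive and linear under linear calibration
  f1 <- predict(m, list("act1"))$fold
  f2 <- predict(m, list(c("act1", "act1")))$fold
  expect_equal(f1, 1 + 0.5 * 2)
  expect_equal(f2 - f1, f1 - 1)  # doubling the summed weight adds linearly
  # adding an activator never decreases the fold
  expect_gte(predict(m, list(c("rep1", "act1")))$fold,
             predict(m, list("rep1"))$fold)
  # multiplicative in core level
  expect_equal(predict(m, list("act2"), core = "strong")$expression,
               8 * predict(m, list("act2"), core = "weak")$expression)
  # unknown promoter / neutral motifs
  expect_error(predict(m, list("act1"), core = "nope"), "unknown core")
  expect_equal(predict(m, list("never_seen"))$fold, 1)
})

test_that("MAM calibration recovers a known line", {
  x <- c(1, 2, 3, 4, 6)
  y <- 0.8 + 0.6 * x
  fit <- fit_mam_calibration(y, x)
  expect_equal(fit$intercept, 0.8)
  expect_equal(fit$slope, 0.6)
  expect_equal(fit$r, 1)
  # noisy line recovered within a loose interval
  set.seed(13)
  xs <- runif(30, 0, 8)
  ys <- 1 + 0.5 * xs + rnorm(30, 0, 0.1)
  fit2 <- fit_mam_calibration(ys, xs)
  expect_lt(abs(fit2$slope - 0.5), 0.1)
  expect_equal(fit_mam_calibration(c(2, 2, 2), c(1, 2, 3))$slope, 0)
  expect_error(fit_mam_calibration(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("MAM built from mHG results uses -log10 p boosts", {
  cls <- data.frame(motif_id = c("a", "b", "r"),
                    p_up = c(1e-6, 1e-2, 0.9), p_down = c(0.5, 0.6, 1e-8),
                    class = c("activating", "undetermined", "repressing"),
                    conflict = FALSE)
  m <- mam_from_mhg(cls, calibration = c(intercept = 1, slope = 1))
  expect_equal(unname(coef(m)["a"]), 6)
  expect_false("b" %in% names(coef(m)))
  expect_equal(predict(m, list("r"))$fold, 0.5)
})

test_that("one-hot encoding is exact and uniform-padded", {
  m <- one_hot_encode("ACGT", 4)
  expect_equal(m, diag(4), ignore_attr = TRUE)
  p <- one_hot_encode(strrep("A", 101), 186)
  expect_equal(dim(p), c(4, 186))
  expect_equal(unname(p[, 102]), rep(0.25, 4))
  expect_equal(sum(p[, 102:186] != 0.25), 0)  # 85 padded columns
  expect_equal(colSums(p), rep(1, 186), ignore_attr = TRUE)
  expect_error(one_hot_encode("ACGN", 4), "illegal")
  expect_error(one_hot_encode("ACGTA", 4), "exceeds")
})

test_that("evaluation bootstraps follow the configured schemes", {
  set.seed(14)
  x <- rnorm(11); y <- x
  ev <- evaluate_predictions(x, y, scheme = "all_subsets")
  expect_equal(ev$r, 1)
  expect_equal(ev$bootstrap_mean, 1)
  expect_equal(ev$bootstrap_sd, 0)
  expect_equal(ev$n_subsets, choose(11, 9))  # 55 subsets of 9 out of 11
  ev2 <- evaluate_predictions(rnorm(50), rnorm(50), scheme = "random_subsets",
                              subset_size = 30, n_boot = 100, seed = 2)
  expect_equal(ev2$n_subsets, 100)
  expect_true(abs(ev2$bootstrap_mean) < 0.5)
  expect_equal(evaluate_predictions(x, -x)$r, -1)
  expect_true(evaluate_predictions(rep(1, 5), rnorm(5))$flagged)
})

test_that("training-set selection honors the three cohort definitions", {
  set.seed(15)
  rec <- data.frame(variant_id = sprintf("v%03d", 1:100),
                    expression = rnorm(100, 2000, 300),
                    total_reads = rpois(100, 100),
                    deep = rep(c(TRUE, FALSE), c(20, 80)),
                    has_mixed = rep(c(TRUE, FALSE, TRUE, FALSE), 25))
  adm <- select_training_set(rec, "adm", n_top = 30)
  expect_equal(nrow(adm), 30)
  expect_gte(min(adm$total_reads), sort(rec$total_reads, decreasing = TRUE)[30])
  amm <- select_training_set(rec, "amm")
  mbo <- select_training_set(rec, "mbo")
  expect_true(all(amm$deep))
  expect_true(all(mbo$variant_id %in% amm$variant_id))  # MBO subset of AMM
  expect_error(select_training_set(rec, "adm", read_cutoff = 1e9),
               "empty training-set")
  split <- select_training_set(rec, "amm", holdout = 0.2, seed = 1)
  expect_equal(nrow(split$train) + nrow(split$test), nrow(amm))
  expect_equal(nrow(split$test), 4)
})

test_that("the CNN trains deterministically and respects output modes", {
  set.seed(16)
  n <- 60
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = ""),
    character(1))
  y <- rnorm(n, 1000, 200)
  cfg <- cnn_config(n_kernels = 8, dense_units = 4, epochs = 2,
                    ensemble_size = 2, seed = 3)
  m1 <- surs_cnn(seqs, y, config = cfg)
  m2 <- surs_cnn(seqs, y, config = cfg)
  p1 <- predict(m1, seqs)
  p2 <- predict(m2, seqs)
  expect_identical(p1, p2)  # seeded determinism
  expect_length(p1, n)

  # bins mode returns probability vectors
  bins <- t(apply(matrix(runif(n * 4), n), 1, function(r) r / sum(r)))
  cfgb <- cnn_config(n_kernels = 8, dense_units = 4, epochs = 2,
                     ensemble_size = 2, output_mode = "bins", seed = 3)
  mb <- surs_cnn(seqs, bins, config = cfgb)
  pb <- predict(mb, seqs)
  expect_equal(dim(pb), c(n, 4))
  expect_equal(rowSums(pb), rep(1, n), tolerance = 1e-8)

  # hybrid mode requires motif counts at prediction time
  counts <- matrix(rpois(n * 3, 1), n, 3)
  cfgh <- cnn_config(n_kernels = 8, dense_units = 4, epochs = 2,
                     ensemble_size = 1, include_motif_counts = TRUE, seed = 4)
  mh <- surs_cnn(seqs, y, motif_counts = counts, config = cfgh)
  expect_error(predict(mh, seqs), "requires motif_counts")
  expect_length(predict(mh, seqs, motif_counts = counts), n)
  # shorter sequences are padded up to the model input length
  short <- substr(seqs[1:3], 1, 25)
  expect_length(predict(mh, short, motif_counts = counts[1:3, , drop = FALSE]), 3)
})

test_that("motif-count inputs are derived from designs or sequences", {
  des <- make_design(m = 2, max_arity = 2)
  mc <- motif_count_matrix(des$variants, des$catalog)
  expect_equal(dim(mc), c(nrow(des$variants), 2))
  expect_equal(unname(rowSums(mc)), des$variants$arity)
  # repeated motifs count twice
  double <- des$variants$motifs == paste(rep(des$catalog$motif_id[1], 2),
                                         collapse = ",")
  expect_equal(unname(mc[double, 1]), 2L)
  # sequence scanning finds embedded motifs
  mc2 <- motif_count_matrix(variable_region(des$catalog$motif_id[1],
                                            des$catalog, des$chassis),
                            des$catalog)
  expect_equal(unname(mc2[1, 1]), 1L)
})
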