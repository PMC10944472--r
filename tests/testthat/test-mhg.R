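test_that("hypergeometric tails match direct combinatorial counting", {
  expect_equal(hypergeometric_tail(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeometric_tail(0, 3, 2, 6), 1)
  for (N in 2:10) for (B in 0:N) for (n in 1:N) for (b in 0:min(n, B)) {
    expect_equal(hypergeometric_tail(b, n, B, N), hgt_oracle(b, n, B, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeometric_tail(3, 2, 2, 4), "invalid")
})

test_that("the mHG score is the minimal prefix tail", {
  s <- mhg_score(c(1, 1, 0, 0))
  expect_equal(s$score, 1 / 6)
  expect_equal(s$n_star, 2)
  expect_equal(mhg_score(c(0, 0, 0, 0))$score, 1)
  expect_equal(mhg_score(c(0, 0, 1, 1))$score, 1)
  # random lists agree with the independent oracle
  set.seed(5)
  for (i in 1:50) {
    N <- sample(3:14, 1)
    lab <- rbinom(N, 1, 0.4)
    expect_equal(mhg_score(lab)$score, mhg_score_oracle(lab), tolerance = 1e-10)
  }
})

test_that("the exact p-value equals exhaustive arrangement enumeration", {
  # spot value: N = 4, B = 2, score 1/6 is attained by a single arrangement
  expect_equal(mhg_exact_pvalue(1 / 6, 4, 2), 1 / 6)
  expect_equal(mhg_exact_pvalue(1, 10, 0), 1)
  # full enumeration for all N <= 9 and all B (the acceptance suite extends
  # this to N <= 12)
  for (N in 2:9) for (B in 0:N) {
    arr <- all_arrangements(N, B)
    scores <- apply(arr, 1, mhg_score_oracle)
    for (s in unique(scores)) {
      p_dp <- mhg_exact_pvalue(s, N, B)
      p_enum <- mean(scores <= s + 1e-12)
      expect_equal(p_dp, p_enum, tolerance = 1e-10)
    }
  }
})

test_that("score and p-value obey the lower and union bounds", {
  set.seed(6)
  for (i in 1:300) {
    N <- sample(5:60, 1)
    lab <- rbinom(N, 1, runif(1, 0.1, 0.6))
    s <- mhg_score(lab)
    p <- mhg_exact_pvalue(s$score, N, sum(lab), log_score = s$log_score)
    expect_gte(p + 1e-12, s$score)
    expect_lte(p, min(1, N * s$score) + 1e-9)
  }
})

test_that("reversing the ranked list swaps the up and down results", {
  set.seed(7)
  expr <- rnorm(40)
  lab <- rbinom(40, 1, 0.3)
  ids <- sprintf("v%02d", 1:40)
  up <- mhg_test(lab, expr, "up", ids = ids)
  down_rev <- mhg_test(lab, -expr, "down", ids = ids)
  expect_equal(up$score, down_rev$score)
  expect_equal(up$p_exact, down_rev$p_exact)
  expect_equal(up$n_star, down_rev$n_star)
})

test_that("prepending labeled items never worsens the up-direction score", {
  set.seed(9)
  for (i in 1:20) {
    lab <- rbinom(15, 1, 0.3)
    s0 <- mhg_score(lab)$score
    s1 <- mhg_score(c(1, lab))$score
    expect_lte(s1, s0 + 1e-12)
  }
})

test_that("motif enrichment labels variants by content and honors ties", {
  variants <- data.frame(variant_id = sprintf("v%02d", 1:20),
                         arity = rep(c(1, 1, 2, 0), 5),
                         motifs = rep(c("mA", "mB", "mA,mB", ""), 5))
  catalog <- motif_catalog(data.frame(motif_id = c("mA", "mB", "mC"),
                                      sequence = c("ACGTACGTAC", "TGCATGCATG",
                                                   "GGATCCGGAT"),
                                      known_function = "unknown",
                                      source_organism = "synthetic"))
  set.seed(10)
  rec <- data.frame(variant_id = variants$variant_id,
                    expression = 1000 + 2000 * grepl("mA", variants$motifs) +
                      rnorm(20, 0, 10),
                    total_reads = 100, group = 1L)
  class(rec) <- c("expression_records", "data.frame")
  res <- enrich_motifs(rec, variants, catalog, alpha = 1e-2)
  up <- res[res$direction == "up", ]
  expect_lt(up$p_exact[up$motif_id == "mA"], 1e-2)
  # a motif absent from every variant scores 1
  expect_equal(up$mhg_score[up$motif_id == "mC"], 1)
  expect_equal(up$p_exact[up$motif_id == "mC"], 1)
  # label counts recorded
  expect_equal(up$B[up$motif_id == "mA"], 10)
  expect_equal(up$N[up$motif_id == "mA"], 20)
})

test_that("sub-motif enrichment splits signal between realizations", {
  # one mixed motif (K at position 3); only the 'G' realization is active
  catalog <- make_catalog(2, n_mixed = 1, seed = 21)
  chassis <- design_desert(101, exclusion = catalog$sequence, seed = 2100)
  variants <- enumerate_variants(catalog, max_arity = 1)
  mixed_id <- catalog$motif_id[catalog$n_mixed > 0][1]
  v_mix <- variants$variant_id[variants$motifs == mixed_id]
  sub <- expand_mixed_motif(mixed_base_motif(mixed_id,
                                             catalog$sequence[catalog$motif_id == mixed_id]))
  set.seed(11)
  assigns <- expand.grid(a1 = c("G", "T"), a2 = c("A", "C"),
                         stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(assigns)), function(i) {
    data.frame(variant_id = rep(v_mix, 10),
               subvariant = paste0(assigns$a1[i], assigns$a2[i]),
               expression = rnorm(10, ifelse(assigns$a1[i] == "G", 4000, 1500), 50),
               total_reads = 60)
  }))
  base <- data.frame(variant_id = rep(variants$variant_id[variants$arity == 0], 40),
                     subvariant = "", expression = rnorm(40, 1500, 50),
                     total_reads = 60)
  res <- enrich_submotifs(rbind(recs, base), variants, catalog, chassis,
                          alpha = 1e-3)
  up <- res[res$direction == "up" & res$parent_id == mixed_id, ]
  g_rows <- up[substr(up$assignment, 1, 1) == "G", ]
  t_rows <- up[substr(up$assignment, 1, 1) == "T", ]
  expect_true(all(g_rows$p_exact < 1e-3))
  expect_true(all(t_rows$p_exact > 1e-3))
})

test_that("motif classification follows the two-direction rule", {
  mk <- function(pu, pd) {
    up <- data.frame(motif_id = "m", direction = "up", p_exact = pu)
    down <- data.frame(motif_id = "m", direction = "down", p_exact = pd)
    classify_motifs(up, down, alpha = 1e-4)
  }
  expect_equal(mk(1e-6, 0.3)$class, "activating")
  expect_equal(mk(0.3, 1e-6)$class, "repressing")
  expect_equal(mk(0.3, 0.2)$class, "undetermined")
  both <- mk(1e-6, 1e-7)
  expect_equal(both$class, "undetermined")
  expect_true(both$conflict)
})
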