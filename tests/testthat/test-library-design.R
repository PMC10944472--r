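test_that("exclusion-database filtering applies the retention rules", {
  expect_equal(filter_exclusion_database(c("ACGT", "ACGTA")), "ACGTA")
  expect_equal(filter_exclusion_database("acgtacgt"), character(0))
  expect_equal(filter_exclusion_database("ACGTAcccccc"), character(0))
  # lower-case positions in retained motifs become wildcards
  expect_equal(filter_exclusion_database("ACGTAGttCC"), "ACGTAGNNCC")
  expect_equal(filter_exclusion_database(character(0)), character(0))
})

test_that("desert design excludes all motifs on both strands and is seeded", {
  d <- design_desert(30, exclusion = "AAAAA", seed = 11)
  expect_equal(nchar(d$sequence), 30)
  expect_equal(count_hits_regex(d$sequence, "AAAAA"), 0)

  excl <- c("AAAAA", "GGGGG", "ACGTAC", "TTATTTA", "CCWWGG")
  d2 <- design_desert(101, exclusion = excl, seed = 5)
  expect_equal(count_hits_regex(d2$sequence, excl), 0)
  expect_equal(sum(scan_iupac(d2$sequence, excl)), 0)
  # deterministic given the seed
  expect_identical(design_desert(101, exclusion = excl, seed = 5)$sequence,
                   d2$sequence)
  # infeasible: every 5-mer excluded
  expect_error(design_desert(10, exclusion = "NNNNN", seed = 1,
                             max_attempts = 20), "infeasible")
})

test_that("variant enumeration matches brute-force ordered-tuple counts", {
  # closed form and explicit oracle for small catalogs
  for (m in 1:3) {
    catalog <- make_catalog(m)
    v <- enumerate_variants(catalog, max_arity = 3)
    expect_equal(nrow(v), sum(m^(0:3)))
    # brute-force tuples
    ids <- catalog$motif_id
    tuples <- c("", ids)
    for (a in ids) for (b in ids) tuples <- c(tuples, paste(a, b, sep = ","))
    for (a in ids) for (b in ids) for (c in ids)
      tuples <- c(tuples, paste(a, b, c, sep = ","))
    expect_setequal(v$motifs, tuples)
  }
  v1 <- enumerate_variants(make_catalog(1), max_arity = 1)
  expect_equal(nrow(v1), 2)  # desert + one single
  expect_equal(v1$starts, c("", "46"))
  v3 <- enumerate_variants(make_catalog(2), max_arity = 3)
  expect_equal(nrow(v3), 15)
  expect_equal(unique(v3$starts[v3$arity == 3]), "18,46,74")
  # a motif longer than the slot spacing is a placement error
  long <- motif_catalog(data.frame(motif_id = "big",
                                   sequence = paste(rep("ACGTA", 6), collapse = ""),
                                   known_function = "unknown",
                                   source_organism = "synthetic"))
  expect_error(enumerate_variants(long, max_arity = 3), "does not fit")
})

test_that("barcode sets satisfy all design constraints and are seeded", {
  bc <- generate_barcodes(40, seed = 3)
  b <- bc$barcodes
  expect_equal(length(b), 40)
  expect_true(all(nchar(b) == 15))
  d <- utils::adist(b)
  expect_true(min(d[upper.tri(d)]) >= 3)
  expect_true(all(gc_content(b) >= 0.35 & gc_content(b) <= 0.65))
  expect_true(all(max_homopolymer(b) <= 3))
  expect_false(any(grepl("ACTAGT", b) | grepl("CGGCCG", b)))
  expect_identical(generate_barcodes(40, seed = 3)$barcodes, b)
  expect_equal(length(generate_barcodes(1, seed = 1)$barcodes), 1)
  expect_error(generate_barcodes(1e6, length = 4, max_attempts = 500),
               "infeasible")
})

test_that("barcode allocation conserves variants and row counts", {
  des <- make_design(m = 3, max_arity = 2, deep_count = 2)
  man <- des$manifest
  n_var <- nrow(des$variants)  # 13 variants
  expect_equal(nrow(man), 2 * n_var + (22 - 2) * 2)
  tab <- table(man$variant_id)
  expect_true(all(tab >= 2))
  expect_equal(sort(unique(as.integer(tab))), c(2, 22))
  expect_equal(sum(tab == 22), 2)
  expect_false(any(duplicated(man$barcode)))  # barcode identifies its variant
  expect_false(any(duplicated(man$oligo_id)))
  # deep_count = 0 gives everyone the default
  man0 <- make_design(m = 2, max_arity = 1, deep_count = 0)$manifest
  expect_true(all(table(man0$variant_id) == 2))
})

test_that("oligo assembly places motifs at the fixed positions", {
  des <- make_design(m = 2, max_arity = 3)
  man <- des$manifest
  chassis <- des$chassis$sequence
  expect_true(all(nchar(man$variable_region) == 101))
  # desert variant equals the chassis exactly
  expect_equal(unique(man$variable_region[man$arity == 0]), chassis)
  # single-motif variants carry the motif at base 46
  one <- man[man$arity == 1, ][1, ]
  mseq <- des$catalog$sequence[des$catalog$motif_id == one$motifs]
  expect_equal(substr(one$variable_region, 46, 45 + nchar(mseq)), mseq)
  # triple-motif variants place motif 3 at base 74
  three <- man[man$arity == 3, ][1, ]
  m3 <- strsplit(three$motifs, ",")[[1]][3]
  mseq3 <- des$catalog$sequence[des$catalog$motif_id == m3]
  expect_equal(substr(three$variable_region, 74, 73 + nchar(mseq3)), mseq3)
  # bases outside motif footprints equal the chassis
  starts <- c(18, 46, 74)
  lens <- nchar(des$catalog$sequence[match(strsplit(three$motifs, ",")[[1]],
                                           des$catalog$motif_id)])
  covered <- unlist(mapply(seq, starts, starts + lens - 1))
  outside <- setdiff(1:101, covered)
  expect_equal(strsplit(three$variable_region, "")[[1]][outside],
               strsplit(chassis, "")[[1]][outside])
  # full oligo layout
  expect_equal(three$full_oligo,
               paste0(attr(man, "flanks")$primer5, "ACTAGT", three$barcode,
                      three$variable_region, "CGGCCG",
                      attr(man, "flanks")$primer3))
})

test_that("restriction sites inside barcode or variable region are design errors", {
  expect_error(assemble_oligo(strrep("A", 101), "AAACTAGTAAAAAAA"),
               "inside barcode")
  region <- paste0(strrep("A", 40), "CGGCCG", strrep("A", 55))
  expect_error(assemble_oligo(region, "CATCATCATCATCAT"), "variable region")
  # a K that could realize a site is caught too (ACTAGK covers ACTAGT)
  region_k <- paste0(strrep("A", 40), "ACTAGK", strrep("A", 55))
  expect_error(assemble_oligo(region_k, "CATCATCATCATCAT"), "variable region")
})

test_that("manifests round-trip through TSV", {
  des <- make_design(m = 2, max_arity = 1)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_manifest(des$manifest, tmp)
  man2 <- read_manifest(tmp)
  expect_equal(man2$full_oligo, des$manifest$full_oligo)
  expect_equal(man2$variant_id, des$manifest$variant_id)
})
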