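# Shared fixtures: small synthetic catalogs and designs built in code, plus
# independent oracles used to cross-check the package implementations.

# Deterministic small catalog of length-10 motifs; n_mixed of them carry one
# K and one M. Sequences avoid SpeI/EagI sites under every mixed-base
# realization so they can be embedded in oligos.
make_catalog <- function(m, n_mixed = 0, seed = 42) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- character(0)
  while (length(seqs) < m) {
    s <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    i <- length(seqs) + 1
    if (i <= n_mixed) {
      ch <- strsplit(s, "")[[1]]
      ch[3] <- "K"; ch[8] <- "M"
      s <- paste(ch, collapse = "")
    }
    bad <- any(vapply(expand_mixed_motif(s)$sequence, function(x)
      grepl("ACTAGT", x) || grepl("CGGCCG", x), logical(1)))
    if (!bad && !(s %in% seqs)) seqs <- c(seqs, s)
  }
  motif_catalog(data.frame(motif_id = sprintf("m%02d", seq_len(m)),
                           sequence = seqs,
                           known_function = "unknown",
                           source_organism = "synthetic",
                           stringsAsFactors = FALSE))
}

# Small complete design: chassis + variants + manifest.
make_design <- function(m = 2, n_mixed = 0, max_arity = 2, deep_count = 0,
                        seed = 7) {
  catalog <- make_catalog(m, n_mixed = n_mixed, seed = seed)
  variants <- enumerate_variants(catalog, max_arity = max_arity)
  # a motif/chassis junction can create a restriction site (a design error);
  # redraw the chassis until the whole manifest assembles cleanly
  for (try in 1:25) {
    chassis <- design_desert(101, exclusion = catalog$sequence,
                             seed = seed + 1000 + try)
    manifest <- tryCatch(
      allocate_barcodes(variants, catalog, chassis,
                        deep_count = deep_count, seed = seed),
      error = function(e) NULL)
    if (!is.null(manifest)) break
  }
  if (is.null(manifest)) stop("no clean design found for the fixture")
  list(catalog = catalog, chassis = chassis, variants = variants,
       manifest = manifest)
}

# Independent IUPAC scanner built on regular expressions (no Biostrings),
# used as the oracle for desert-chassis verification.
IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
                 S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
                 D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(motif) {
  paste(IUPAC_CLASS[strsplit(toupper(motif), "")[[1]]], collapse = "")
}

regex_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  vapply(x, function(s)
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

count_hits_regex <- function(subject, motifs) {
  total <- 0L
  for (m in c(motifs, regex_revcomp(motifs))) {
    hits <- gregexpr(sprintf("(?=%s)", iupac_regex(m)), subject, perl = TRUE)[[1]]
    total <- total + sum(hits > 0)
  }
  total
}

# Independent hypergeometric upper tail by direct combinatorial summation.
hgt_oracle <- function(b, n, B, N) {
  j <- b:min(n, B)
  sum(choose(B, j) * choose(N - B, n - j)) / choose(N, n)
}

# Independent minimum over prefixes using the combinatorial tail.
mhg_score_oracle <- function(labels) {
  N <- length(labels); B <- sum(labels)
  if (B == 0 || B == N || N == 1) return(1)
  min(vapply(seq_len(N - 1), function(n)
    hgt_oracle(sum(labels[seq_len(n)]), n, B, N), numeric(1)))
}

# All distinct arrangements of B ones among N positions.
all_arrangements <- function(N, B) {
  if (B == 0) return(matrix(0L, nrow = 1, ncol = N))
  pos <- utils::combn(N, B)
  t(apply(pos, 2, function(p) { v <- integer(N); v[p] <- 1L; v }))
}
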