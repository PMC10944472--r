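# Internal sequence utilities shared across modules.

BASES <- c("A", "C", "G", "T")
MIXED_CODES <- c(K = "GT", M = "AC")  # K = G/T, M = A/C

#' Reverse complement of character sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors. IUPAC ambiguity codes are handled.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Split equal-length sequences into a character matrix (one row per sequence).
seq_char_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(character(0), nrow = 0))
  n <- unique(nchar(x))
  if (length(n) != 1L) stop("sequences must have equal length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

#' GC content of sequences
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(x) {
  gc <- nchar(gsub("[^GCgc]", "", x))
  gc / nchar(x)
}

#' Longest homopolymer run
#' @param x Character vector of DNA sequences.
#' @return Integer vector: length of the longest run of one base in each sequence.
#' @export
max_homopolymer <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) if (length(ch) == 0L) 0L else max(rle(ch)$lengths),
         integer(1))
}

# Hamming distance from one string to a set of equal-length strings.
# Any character mismatch (including 'N') counts as one error.
hamming_to_set <- function(x, set_mat) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  rowSums(set_mat != matrix(xs, nrow = nrow(set_mat), ncol = length(xs), byrow = TRUE))
}

#' Scan a sequence for IUPAC motif matches on both strands
#'
#' Counts occurrences of each (possibly degenerate) motif in `subject`,
#' on the forward strand and on the reverse complement. Used to verify that a
#' desert chassis is free of known binding sites.
#'
#' @param subject A single DNA sequence (character).
#' @param motifs Character vector of IUPAC motifs (upper case; `N` = wildcard).
#' @param both_strands Scan the reverse-complement strand as well (default TRUE).
#' @return Integer vector of per-motif hit counts (forward + reverse).
#' @export
scan_iupac <- function(subject, motifs, both_strands = TRUE) {
  subj <- Biostrings::DNAString(subject)
  vapply(motifs, function(m) {
    pat <- Biostrings::DNAString(m)
    hits <- Biostrings::countPattern(pat, subj, fixed = FALSE)
    if (both_strands) {
      hits <- hits + Biostrings::countPattern(Biostrings::reverseComplement(pat),
                                              subj, fixed = FALSE)
    }
    as.integer(hits)
  }, integer(1))
}

# Locate footprints (IRanges-style start/end data.frame) of IUPAC motif hits on
# both strands of a sequence; used by the desert designer to resample bases.
iupac_hit_ranges <- function(subject, motifs) {
  subj <- Biostrings::DNAString(subject)
  out <- list()
  for (m in motifs) {
    pat <- Biostrings::DNAString(m)
    for (p in list(pat, Biostrings::reverseComplement(pat))) {
      hits <- Biostrings::matchPattern(p, subj, fixed = FALSE)
      if (length(hits) > 0L) {
        out[[length(out) + 1L]] <- data.frame(start = Biostrings::start(hits),
                                              end = Biostrings::end(hits))
      }
    }
  }
  if (length(out) == 0L) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# Fixed mixed-base chars at positions of a {A,C,G,T,K,M} sequence.
find_mixed_positions <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  which(chars %in% names(MIXED_CODES))
}

# Does a concrete base agree with a design character (K/M treated as pairs)?
base_matches_design <- function(base, design_char) {
  if (design_char %in% BASES) return(base == design_char)
  allowed <- strsplit(MIXED_CODES[[design_char]], "", fixed = TRUE)[[1]]
  base %in% allowed
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
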