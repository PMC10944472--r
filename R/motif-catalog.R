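# Motif catalog: PWMs, mixed-base (K/M) motifs and their concrete sub-motifs.
#
# The library encodes transcription-factor binding motifs with the two
# degenerate synthesis bases K (G/T) and M (A/C), so one designed motif is
# physically a mixture of 2^k concrete "sub-motifs" for k mixed positions.

KNOWN_FUNCTIONS <- c("activating", "repressing", "dual", "unknown")

#' Construct a position weight matrix
#'
#' @param motif_id Identifier.
#' @param mat Numeric 4 x L matrix of base frequencies, rows `A`, `C`, `G`, `T`.
#'   Each column must be a probability vector (sums to 1 within 1e-6) and the
#'   motif must be at least 5 columns long.
#' @param source_organism Free-text organism label.
#' @return An object of class `pwm_matrix`.
#' @export
pwm_matrix <- function(motif_id, mat, source_organism = "unknown") {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stopf("PWM '%s': matrix must have 4 rows (A,C,G,T)", motif_id)
  rownames(mat) <- BASES
  if (ncol(mat) < 5L) stopf("PWM '%s': length %d < 5", motif_id, ncol(mat))
  if (any(mat < 0 | mat > 1)) stopf("PWM '%s': frequencies must lie in [0,1]", motif_id)
  bad <- which(abs(colSums(mat) - 1) > 1e-6)
  if (length(bad) > 0L)
    stopf("PWM '%s': column %d does not sum to 1", motif_id, bad[1])
  structure(list(motif_id = motif_id, mat = mat, source_organism = source_organism),
            class = "pwm_matrix")
}

#' @export
print.pwm_matrix <- function(x, ...) {
  cat(sprintf("PWM '%s' (%s), length %d\n", x$motif_id, x$source_organism, ncol(x$mat)))
  print(round(x$mat, 3))
  invisible(x)
}

#' Construct a mixed-base motif
#'
#' A motif over the alphabet `{A,C,G,T,K,M}` where `K` stands for G/T and `M`
#' for A/C. At most 4 mixed positions are allowed (the synthesis chemistry
#' realizes up to 16 concrete sub-motifs per designed motif).
#'
#' @param motif_id Identifier.
#' @param sequence Motif sequence over `{A,C,G,T,K,M}`.
#' @param known_function One of `"activating"`, `"repressing"`, `"dual"`,
#'   `"unknown"`.
#' @param source_organism Free-text organism label.
#' @return An object of class `mixed_base_motif`.
#' @export
mixed_base_motif <- function(motif_id, sequence,
                             known_function = "unknown",
                             source_organism = "unknown") {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), c(BASES, names(MIXED_CODES)))
  if (length(bad) > 0L)
    stopf("motif '%s': illegal character(s) %s (only A,C,G,T,K,M supported)",
          motif_id, paste(bad, collapse = ","))
  mixed <- which(chars %in% names(MIXED_CODES))
  if (length(mixed) > 4L)
    stopf("motif '%s': %d mixed positions exceed the maximum of 4",
          motif_id, length(mixed))
  known_function <- match.arg(known_function, KNOWN_FUNCTIONS)
  structure(list(motif_id = motif_id, sequence = sequence,
                 mixed_positions = mixed, known_function = known_function,
                 source_organism = source_organism),
            class = "mixed_base_motif")
}

#' @export
print.mixed_base_motif <- function(x, ...) {
  cat(sprintf("Mixed-base motif '%s': %s (%s, %s; %d mixed position%s)\n",
              x$motif_id, x$sequence, x$known_function, x$source_organism,
              length(x$mixed_positions),
              if (length(x$mixed_positions) == 1L) "" else "s"))
  invisible(x)
}

#' Encode a PWM as a mixed-base motif
#'
#' Each PWM column is collapsed to one synthesis character. If a single base
#' reaches `pair_threshold` the consensus base is emitted (single-base
#' dominance takes precedence over the pair rules). Otherwise, if the combined
#' G+T frequency reaches the threshold a `K` is emitted; else if A+C reaches it
#' an `M`; else the single most probable base. Ties are broken K before M, and
#' alphabetically among single bases. The encoding is deterministic.
#'
#' @param pwm A [pwm_matrix()].
#' @param pair_threshold Fraction in (0.5, 1]; default 0.70.
#' @param known_function,source_organism Annotation carried to the motif
#'   (organism defaults to the PWM's).
#' @return A [mixed_base_motif()] of the same length as the PWM.
#' @export
encode_pwm_to_mixed <- function(pwm, pair_threshold = 0.70,
                                known_function = "unknown",
                                source_organism = NULL) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  if (!(pair_threshold > 0.5 && pair_threshold <= 1))
    stopf("pair_threshold must lie in (0.5, 1]")
  mat <- pwm$mat
  enc <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (max(col) >= pair_threshold) return(BASES[which.max(col)])
    if (col["G"] + col["T"] >= pair_threshold) return("K")
    if (col["A"] + col["C"] >= pair_threshold) return("M")
    BASES[which.max(col)]
  }, character(1))
  mixed_base_motif(pwm$motif_id, paste(enc, collapse = ""),
                   known_function = known_function,
                   source_organism = source_organism %||% pwm$source_organism)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a mixed-base motif into its concrete sub-motifs
#'
#' A motif with k mixed positions expands into exactly 2^k concrete
#' `{A,C,G,T}` sub-motifs, listed in lexicographic order of the assignment
#' string (the concrete bases chosen at the mixed positions, in order).
#' A motif without mixed bases returns itself as its single sub-motif.
#'
#' @param motif A [mixed_base_motif()] or a plain sequence string.
#' @return A data.frame with columns `parent_id`, `sequence`, `assignment`.
#' @export
expand_mixed_motif <- function(motif) {
  if (is.character(motif)) motif <- mixed_base_motif("motif", motif)
  chars <- strsplit(motif$sequence, "", fixed = TRUE)[[1]]
  mixed <- motif$mixed_positions
  if (length(mixed) == 0L) {
    return(data.frame(parent_id = motif$motif_id, sequence = motif$sequence,
                      assignment = "", stringsAsFactors = FALSE))
  }
  opts <- lapply(chars[mixed], function(ch)
    strsplit(MIXED_CODES[[ch]], "", fixed = TRUE)[[1]])
  grid <- do.call(expand.grid, c(opts, stringsAsFactors = FALSE))
  assignment <- do.call(paste0, grid)
  seqs <- vapply(seq_len(nrow(grid)), function(i) {
    ch <- chars
    ch[mixed] <- unlist(grid[i, ], use.names = FALSE)
    paste(ch, collapse = "")
  }, character(1))
  ord <- order(assignment)
  data.frame(parent_id = motif$motif_id, sequence = seqs[ord],
             assignment = assignment[ord], stringsAsFactors = FALSE)
}

#' Assemble a motif catalog
#'
#' @param motifs A list of [mixed_base_motif()] objects, or a data.frame with
#'   columns `motif_id`, `sequence`, `known_function`, `source_organism`.
#' @param desert_id Identifier of the sentinel "no motif" entry (not one of
#'   the catalog motifs).
#' @return An object of class `motif_catalog`: a data.frame with one row per
#'   motif (`motif_id`, `sequence`, `known_function`, `source_organism`,
#'   `n_mixed`) and attribute `desert_id`.
#' @export
motif_catalog <- function(motifs, desert_id = "desert") {
  if (is.data.frame(motifs)) {
    motifs <- lapply(seq_len(nrow(motifs)), function(i)
      mixed_base_motif(motifs$motif_id[i], motifs$sequence[i],
                       motifs$known_function[i], motifs$source_organism[i]))
  }
  if (length(motifs) == 0L) stopf("empty motif catalog")
  df <- do.call(rbind, lapply(motifs, function(m)
    data.frame(motif_id = m$motif_id, sequence = m$sequence,
               known_function = m$known_function,
               source_organism = m$source_organism,
               n_mixed = length(m$mixed_positions),
               stringsAsFactors = FALSE)))
  dup <- df$motif_id[duplicated(df$motif_id)]
  if (length(dup) > 0L)
    stopf("duplicate motif id(s): %s", paste(unique(dup), collapse = ","))
  if (desert_id %in% df$motif_id)
    stopf("desert id '%s' collides with a catalog motif", desert_id)
  structure(df, class = c("motif_catalog", "data.frame"), desert_id = desert_id)
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat(sprintf("Motif catalog: %d motifs (%d mixed-base, %d plain); desert id '%s'\n",
              nrow(x), sum(x$n_mixed > 0), sum(x$n_mixed == 0),
              attr(x, "desert_id")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Load a motif catalog from a TSV file
#'
#' Expects tab-separated columns `motif_id`, `sequence`, `source_organism`
#' (or `organism`) and `known_function`. Rows with characters outside
#' `{A,C,G,T,K,M}` or duplicate ids are rejected with an error naming the row.
#'
#' @param path Path to the TSV file.
#' @return A [motif_catalog()].
#' @export
load_motif_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stopf("motif catalog file '%s' is empty", path)
  if ("organism" %in% names(df) && !"source_organism" %in% names(df))
    names(df)[names(df) == "organism"] <- "source_organism"
  need <- c("motif_id", "sequence", "source_organism", "known_function")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stopf("motif catalog '%s' lacks column(s): %s", path, paste(miss, collapse = ","))
  motifs <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(mixed_base_motif(df$motif_id[i], df$sequence[i],
                              df$known_function[i], df$source_organism[i]),
             error = function(e) stopf("row %d of '%s': %s", i, path, conditionMessage(e)))
  })
  motif_catalog(motifs)
}

#' Example 41-motif catalog
#'
#' Loads the catalog shipped with the package: 41 eukaryotic TFBS motifs of
#' length 10-13, of which 20 carry K/M mixed bases and 21 are plain. A subset
#' are published yeast/mouse/fly/fission-yeast consensus motifs; the remainder
#' are synthetic fillers (marked `synthetic` in the organism column) so that
#' the full catalog geometry can be exercised without redistributing the
#' original PWM collection.
#'
#' @return A [motif_catalog()] with 41 rows.
#' @export
example_motif_catalog <- function() {
  load_motif_catalog(system.file("extdata", "motif_catalog_41.tsv",
                                 package = "surs", mustWork = TRUE))
}

#' Export all sub-motifs of a catalog to FASTA
#'
#' @param catalog A [motif_catalog()].
#' @param path Output FASTA path.
#' @return Invisibly, the expansion data.frame.
#' @export
export_submotifs_fasta <- function(catalog, path) {
  exp <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i)
    expand_mixed_motif(mixed_base_motif(catalog$motif_id[i], catalog$sequence[i],
                                        catalog$known_function[i],
                                        catalog$source_organism[i]))))
  ss <- Biostrings::DNAStringSet(exp$sequence)
  names(ss) <- ifelse(exp$assignment == "", exp$parent_id,
                      paste0(exp$parent_id, "_", exp$assignment))
  Biostrings::writeXStringSet(ss, path)
  invisible(exp)
}
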