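# Library design: desert chassis, variant enumeration, barcodes, manifest.
#
# Variants place 0-3 motifs at fixed 1-based positions inside a 101-base
# "desert" chassis scrubbed of known binding sites: position 46 for single
# motifs, 28/66 for doubles, 18/46/74 for triples. Each oligo is
# primer + SpeI + 15-nt barcode + variable region + EagI + primer.

SPEI_SITE <- "ACTAGT"
EAGI_SITE <- "CGGCCG"

# Default PCR handles; chosen free of SpeI/EagI sites on both strands.
DEFAULT_FLANKS <- list(primer5 = "ACACGACGCTCTTCCGATCTACCTA",
                       primer3 = "AGATCGGAAGAGCACACGTCTGAAC")

#' Filter a TFBS exclusion database
#'
#' Applies the retention rules used to build the desert-design screen:
#' motifs shorter than 5 nt are dropped; motifs written entirely in lower case
#' (low-information positions) are dropped; motifs that contain lower-case
#' characters and have 5 or fewer upper-case characters are dropped. Retained
#' motifs are upper-cased with their lower-case positions replaced by the `N`
#' wildcard.
#'
#' @param iupac_motifs Character vector of IUPAC motifs, possibly mixed case.
#' @return Character vector of retained motifs (upper case, `N` wildcards).
#' @export
filter_exclusion_database <- function(iupac_motifs) {
  if (length(iupac_motifs) == 0L) return(character(0))
  n_upper <- nchar(gsub("[^A-Z]", "", iupac_motifs))
  has_lower <- grepl("[a-z]", iupac_motifs)
  keep <- nchar(iupac_motifs) >= 5L & n_upper > 0L & !(has_lower & n_upper <= 5L)
  kept <- iupac_motifs[keep]
  toupper(gsub("[a-z]", "N", kept))
}

#' Design a desert chassis sequence
#'
#' Generates a sequence of the requested length containing no occurrence of
#' any exclusion motif on either strand. Bases are proposed uniformly at
#' random; after each proposal the sequence is scanned with IUPAC-aware
#' matching and the bases under any hit footprint are resampled, up to
#' `max_attempts` repair rounds.
#'
#' @param length Chassis length in bases (default 101; a longer 186-base
#'   variant is used for extended validation designs).
#' @param exclusion Character vector of retained IUPAC exclusion motifs
#'   (see [filter_exclusion_database()]); may be empty.
#' @param seed Integer RNG seed; the result is deterministic given the seed.
#' @param max_attempts Repair-round budget before declaring infeasibility.
#' @param avoid_sites Restriction sites additionally excluded from the
#'   chassis (default SpeI/EagI, required for cloning-faithful designs).
#' @return An object of class `desert_chassis` with fields `sequence`,
#'   `length`, `exclusion`, `seed`, `attempts`.
#' @export
design_desert <- function(length = 101, exclusion = character(0), seed = 1,
                          max_attempts = 5000,
                          avoid_sites = c(SPEI_SITE, EAGI_SITE)) {
  exclusion <- unique(c(toupper(exclusion), avoid_sites))
  if (length(exclusion) > 0L && length < max(nchar(exclusion)))
    stopf("chassis length %d shorter than the longest exclusion motif", length)
  set.seed(seed)
  chars <- sample(BASES, length, replace = TRUE)
  attempts <- 0L
  repeat {
    hits <- if (length(exclusion) > 0L)
      iupac_hit_ranges(paste(chars, collapse = ""), exclusion)
    else data.frame(start = integer(0), end = integer(0))
    if (nrow(hits) == 0L) break
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      blockers <- exclusion[scan_iupac(paste(chars, collapse = ""), exclusion) > 0]
      stopf("desert design infeasible after %d attempts; blocking motif(s): %s",
            max_attempts, paste(blockers, collapse = ","))
    }
    pos <- unique(unlist(mapply(seq, hits$start, hits$end, SIMPLIFY = FALSE)))
    chars[pos] <- sample(BASES, length(pos), replace = TRUE)
  }
  structure(list(sequence = paste(chars, collapse = ""), length = length,
                 exclusion = exclusion, seed = seed, attempts = attempts),
            class = "desert_chassis")
}

#' @export
print.desert_chassis <- function(x, ...) {
  cat(sprintf("Desert chassis: %d bp, %d exclusion motifs screened (seed %d)\n%s\n",
              x$length, length(x$exclusion), x$seed, x$sequence))
  invisible(x)
}

#' Fixed motif start positions for a given arity
#'
#' @param arity Number of motifs placed (0-3).
#' @return Integer vector of 1-based start positions in the variable region.
#' @export
motif_starts <- function(arity) {
  switch(as.character(arity),
         "0" = integer(0), "1" = 46L, "2" = c(28L, 66L), "3" = c(18L, 46L, 74L),
         stopf("unsupported arity %s (0-3 motifs per variant)", arity))
}

#' Enumerate all 0..max_arity ordered motif arrangements
#'
#' Enumerates every ordered tuple of catalog motifs (repetition allowed) of
#' length 0 to `max_arity`, each placed at the fixed positions for its arity.
#' For m motifs the count is the closed form sum over k of m^k, e.g. the
#' 41-motif catalog with `max_arity = 3` yields 70,644 variants including the
#' motif-free desert variant.
#'
#' @param catalog A [motif_catalog()].
#' @param max_arity Maximum number of motifs per variant (default 3).
#' @param region_length Variable-region length the motifs must fit (default 101).
#' @return A data.frame with columns `variant_id`, `arity`, `motifs`
#'   (comma-separated motif ids; `""` for the desert variant) and `starts`
#'   (comma-separated 1-based starts).
#' @export
enumerate_variants <- function(catalog, max_arity = 3, region_length = 101) {
  stopifnot(inherits(catalog, "motif_catalog"), max_arity >= 0)
  ids <- catalog$motif_id
  len <- stats::setNames(nchar(catalog$sequence), ids)
  rows <- list(data.frame(arity = 0L, motifs = "", stringsAsFactors = FALSE))
  for (k in seq_len(max_arity)) {
    starts <- motif_starts(k)
    # placement feasibility: motif i must end before the next slot starts,
    # and the last motif must fit inside the region
    max_len <- max(len)
    bounds <- c(diff(starts), region_length - starts[k] + 1L)
    if (any(max_len > bounds)) {
      offender <- ids[which.max(len)]
      stopf("motif '%s' (length %d) does not fit the arity-%d slot spacing",
            offender, max(len), k)
    }
    grid <- do.call(expand.grid,
                    c(rep(list(ids), k), stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
    rows[[k + 1L]] <- data.frame(arity = k,
                                 motifs = do.call(paste, c(rev(grid), sep = ",")),
                                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$variant_id <- sprintf("v%06d", seq_len(nrow(out)))
  out$starts <- vapply(out$arity, function(a)
    paste(motif_starts(a), collapse = ","), character(1))
  out[, c("variant_id", "arity", "motifs", "starts")]
}

# Split the comma-joined motifs column back into a list of id vectors.
variant_motif_list <- function(variants) {
  lapply(strsplit(variants$motifs, ",", fixed = TRUE), function(x) x[x != ""])
}

#' Build the variable region of a variant
#'
#' Embeds the variant's motif sequences into the desert chassis at the fixed
#' positions for its arity; all bases outside the motif footprints equal the
#' chassis. Mixed-base motifs keep their K/M characters (the synthesized oligo
#' is a mixture).
#'
#' @param motif_ids Character vector of 0-3 catalog motif ids.
#' @param catalog A [motif_catalog()].
#' @param chassis A [design_desert()] result or a chassis sequence string.
#' @return The variable-region sequence (same length as the chassis).
#' @export
variable_region <- function(motif_ids, catalog, chassis) {
  seq <- if (inherits(chassis, "desert_chassis")) chassis$sequence else chassis
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  starts <- motif_starts(length(motif_ids))
  for (i in seq_along(motif_ids)) {
    m <- catalog$sequence[match(motif_ids[i], catalog$motif_id)]
    if (is.na(m)) stopf("motif '%s' not in catalog", motif_ids[i])
    idx <- starts[i]:(starts[i] + nchar(m) - 1L)
    if (max(idx) > length(chars))
      stopf("motif '%s' overruns the variable region", motif_ids[i])
    chars[idx] <- strsplit(m, "", fixed = TRUE)[[1]]
  }
  paste(chars, collapse = "")
}

#' Generate a constrained barcode set
#'
#' Rejection-samples barcodes satisfying all design constraints: pairwise
#' Levenshtein edit distance at least `min_edit` (enforced greedily against
#' all accepted barcodes), GC content within `gc_bounds`, no homopolymer run
#' longer than `max_run`, and no restriction site from `avoid` inside the
#' barcode. Deterministic given the seed.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in nt (default 15).
#' @param min_edit Minimum pairwise edit distance (default 3).
#' @param gc_bounds GC-fraction bounds (default 0.35-0.65).
#' @param max_run Maximum homopolymer run (default 3).
#' @param seed Integer RNG seed.
#' @param avoid Sequences that must not occur inside a barcode
#'   (default: SpeI and EagI sites).
#' @param max_attempts Proposal budget; exceeded -> infeasibility error
#'   reporting the count achieved.
#' @return An object of class `barcode_set`; `$barcodes` holds the sequences.
#' @export
generate_barcodes <- function(n, length = 15, min_edit = 3,
                              gc_bounds = c(0.35, 0.65), max_run = 3, seed = 1,
                              avoid = c(SPEI_SITE, EAGI_SITE),
                              max_attempts = max(1000L, 200L * n)) {
  stopifnot(n >= 1)
  set.seed(seed)
  accepted <- character(0)
  attempts <- 0L
  while (length(accepted) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stopf("barcode generation infeasible: %d of %d found within the budget",
            length(accepted), n)
    cand <- paste(sample(BASES, length, replace = TRUE), collapse = "")
    gc <- gc_content(cand)
    if (gc < gc_bounds[1] || gc > gc_bounds[2]) next
    if (max_homopolymer(cand) > max_run) next
    if (any(vapply(avoid, function(s) grepl(s, cand, fixed = TRUE), logical(1))))
      next
    if (length(accepted) > 0L &&
        min(utils::adist(cand, accepted)) < min_edit) next
    accepted <- c(accepted, cand)
  }
  structure(list(barcodes = accepted, length = length, min_pairwise_edit = min_edit,
                 gc_bounds = gc_bounds, max_homopolymer = max_run, seed = seed),
            class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("Barcode set: %d x %d nt (edit >= %d, GC %.0f-%.0f%%, runs <= %d)\n",
              length(x$barcodes), x$length, x$min_pairwise_edit,
              100 * x$gc_bounds[1], 100 * x$gc_bounds[2], x$max_homopolymer))
  invisible(x)
}

#' Allocate barcodes to variants and assemble the design manifest
#'
#' A randomly chosen subset of `deep_count` variants receives `n_deep`
#' barcodes each ("deep" variants, used downstream for the high-confidence
#' analysis set); every other variant receives `n_default` barcodes. The total
#' row count is `n_default * |variants| + (n_deep - n_default) * deep_count`.
#'
#' @param variants Variant table from [enumerate_variants()].
#' @param catalog A [motif_catalog()].
#' @param chassis A [design_desert()] result.
#' @param n_default Barcodes per ordinary variant (default 2).
#' @param n_deep Barcodes per deep variant (default 22).
#' @param deep_count Number of deep variants (default 0).
#' @param barcodes Optional pre-generated [generate_barcodes()] set; generated
#'   on the fly (same seed) when `NULL`.
#' @param flanks List with `primer5`, `primer3` (defaults shipped with the
#'   package); SpeI/EagI sites are inserted automatically.
#' @param seed Integer RNG seed for the deep-variant draw (and barcode
#'   generation when needed).
#' @return A `design_manifest` data.frame: one row per oligo with columns
#'   `oligo_id`, `variant_id`, `barcode`, `arity`, `motifs`, `starts`,
#'   `variable_region`, `full_oligo`, `deep`.
#' @export
allocate_barcodes <- function(variants, catalog, chassis, n_default = 2,
                              n_deep = 22, deep_count = 0, barcodes = NULL,
                              flanks = DEFAULT_FLANKS, seed = 1) {
  stopifnot(deep_count <= nrow(variants))
  n_rows <- n_default * nrow(variants) + (n_deep - n_default) * deep_count
  if (is.null(barcodes)) barcodes <- generate_barcodes(n_rows, seed = seed)
  if (length(barcodes$barcodes) < n_rows)
    stopf("need %d barcodes but only %d supplied", n_rows, length(barcodes$barcodes))
  set.seed(seed)
  deep_ids <- if (deep_count > 0)
    sample(variants$variant_id, deep_count) else character(0)
  per_variant <- ifelse(variants$variant_id %in% deep_ids, n_deep, n_default)
  idx <- rep(seq_len(nrow(variants)), per_variant)
  motif_lists <- variant_motif_list(variants)
  regions <- vapply(motif_lists, variable_region, character(1),
                    catalog = catalog, chassis = chassis)
  man <- data.frame(oligo_id = sprintf("o%07d", seq_along(idx)),
                    variant_id = variants$variant_id[idx],
                    barcode = barcodes$barcodes[seq_along(idx)],
                    arity = variants$arity[idx],
                    motifs = variants$motifs[idx],
                    starts = variants$starts[idx],
                    variable_region = regions[idx],
                    deep = variants$variant_id[idx] %in% deep_ids,
                    stringsAsFactors = FALSE)
  man$full_oligo <- vapply(seq_len(nrow(man)), function(i)
    assemble_oligo(man$variable_region[i], man$barcode[i], flanks), character(1))
  attr(man, "flanks") <- flanks
  attr(man, "chassis") <- if (inherits(chassis, "desert_chassis"))
    chassis$sequence else chassis
  class(man) <- c("design_manifest", "data.frame")
  man
}

#' Assemble a full oligo sequence
#'
#' Layout: 5' primer + SpeI site + barcode + variable region + EagI site +
#' 3' primer. A restriction site occurring inside the barcode or the variable
#' region (with K/M positions treated as ambiguity codes) is a design error,
#' since it would be cut during library cloning.
#'
#' @param variable_region Variable-region sequence (may contain K/M).
#' @param barcode Barcode sequence.
#' @param flanks List with `primer5` and `primer3`.
#' @return The full oligo sequence.
#' @export
assemble_oligo <- function(variable_region, barcode, flanks = DEFAULT_FLANKS) {
  for (site in c(SPEI_SITE, EAGI_SITE)) {
    if (grepl(site, barcode, fixed = TRUE))
      stopf("restriction site %s inside barcode %s", site, barcode)
    if (Biostrings::countPattern(Biostrings::DNAString(site),
                                 Biostrings::DNAString(variable_region),
                                 fixed = FALSE) > 0)
      stopf("restriction site %s inside variable region", site)
  }
  paste0(flanks$primer5, SPEI_SITE, barcode, variable_region, EAGI_SITE,
         flanks$primer3)
}

#' Write / read a design manifest as TSV
#'
#' @param manifest A `design_manifest`.
#' @param path Output (input) TSV path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(man) <- c("design_manifest", "data.frame")
  man
}

#' @export
print.design_manifest <- function(x, ...) {
  cat(sprintf("Design manifest: %d oligos, %d variants (%d deep)\n",
              nrow(x), length(unique(x$variant_id)),
              length(unique(x$variant_id[x$deep]))))
  invisible(x)
}
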