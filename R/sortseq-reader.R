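# SORT-seq read parsing: demultiplex bin/variant barcodes, verify the sURS
# body, annotate mixed-base sub-variants, and tally counts.

REJECT_REASONS <- c("too-short", "no-primer", "no-bin-barcode",
                    "no-variant-barcode", "ambiguous-barcode", "body-mismatch")

#' Demultiplexing configuration
#'
#' @param forward_primer The 5' amplification primer located in every valid
#'   read (default: the package's design flank).
#' @param bin_barcodes Named character vector mapping bin id to the bin
#'   barcode sequence prepended by the per-bin PCR, or `NULL` when reads
#'   arrive in one file per bin (simulator mode).
#' @param min_read_length Reads shorter than this are rejected (default 200).
#' @param barcode_max_errors Maximum mismatches plus undetermined (`N`) bases
#'   tolerated in a barcode (default 2; must stay below the designed minimum
#'   barcode distance).
#' @param body_max_mismatch Mismatches tolerated in the variable region
#'   outside mixed positions (default 0: exact matching).
#' @return An object of class `demux_config`.
#' @export
demux_config <- function(forward_primer = DEFAULT_FLANKS$primer5,
                         bin_barcodes = NULL, min_read_length = 200,
                         barcode_max_errors = 2, body_max_mismatch = 0) {
  if (!is.null(bin_barcodes) && is.null(names(bin_barcodes)))
    stopf("bin_barcodes must be a named vector (bin id -> sequence)")
  structure(list(forward_primer = forward_primer, bin_barcodes = bin_barcodes,
                 min_read_length = min_read_length,
                 barcode_max_errors = barcode_max_errors,
                 body_max_mismatch = body_max_mismatch),
            class = "demux_config")
}

#' Read per-bin FASTQ files
#'
#' @param paths Character vector of FASTQ paths, one per bin, in bin order.
#' @param bin_ids Bin identifiers (default `bin1..binN` by position).
#' @return Named list of character vectors of read sequences.
#' @export
read_bin_fastq <- function(paths, bin_ids = paste0("bin", seq_along(paths))) {
  out <- lapply(paths, function(p)
    as.character(Biostrings::readDNAStringSet(p, format = "fastq")))
  names(out) <- bin_ids
  out
}

# Match one observed barcode against the designed set.
# Returns the index of the unique best match within tolerance, or NA
# (reason attribute distinguishes no-match from ambiguity).
match_barcode <- function(obs, design_mat, design_seqs, max_errors) {
  hit <- match(obs, design_seqs)
  if (!is.na(hit)) return(hit)
  d <- hamming_to_set(obs, design_mat)
  dmin <- min(d)
  if (dmin > max_errors) return(structure(NA_integer_, reason = "no-match"))
  best <- which(d == dmin)
  if (length(best) > 1L) return(structure(NA_integer_, reason = "ambiguous"))
  best
}

#' Assign merged reads to (bin, variant)
#'
#' Pipeline per read, first failure recorded as the rejection reason:
#' length filter, forward-primer location, bin-barcode demultiplexing (only
#' when `config$bin_barcodes` is set; otherwise `bin_id` labels the whole
#' file), variant-barcode matching within `barcode_max_errors` mismatches+Ns,
#' and full variable-region verification with mixed (K/M) positions
#' wildcarded to their allowed base pair. For assigned reads from mixed-base
#' designs the concrete bases observed at the mixed positions are recorded as
#' the sub-variant assignment.
#'
#' @param reads Character vector of merged read sequences.
#' @param manifest A `design_manifest`.
#' @param config A [demux_config()].
#' @param bin_id Bin label for per-bin-file input (ignored when bin barcodes
#'   are configured).
#' @return A data.frame with one row per read: `bin`, `variant_id`, `reason`
#'   (`"assigned"` or a rejection reason), `subvariant`.
#' @export
assign_reads <- function(reads, manifest, config = demux_config(),
                         bin_id = "bin1") {
  n <- length(reads)
  res <- data.frame(bin = rep(NA_character_, n),
                    variant_id = rep(NA_character_, n),
                    reason = rep(NA_character_, n),
                    subvariant = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(res)
  reads <- toupper(reads)
  bc_len <- unique(nchar(manifest$barcode))
  stopifnot(length(bc_len) == 1L)
  design_mat <- seq_char_matrix(manifest$barcode)
  region_chars <- strsplit(manifest$variable_region, "", fixed = TRUE)
  region_len <- nchar(manifest$variable_region[1])

  too_short <- nchar(reads) < config$min_read_length
  res$reason[too_short] <- "too-short"

  ppos <- rep(-1L, n)
  ppos[!too_short] <- regexpr(config$forward_primer, reads[!too_short],
                              fixed = TRUE)
  res$reason[!too_short & ppos < 0] <- "no-primer"
  todo <- which(is.na(res$reason))

  if (!is.null(config$bin_barcodes)) {
    bb_len <- unique(nchar(config$bin_barcodes))
    bb_mat <- seq_char_matrix(unname(config$bin_barcodes))
    for (i in todo) {
      s <- ppos[i] - bb_len
      if (s < 1L) { res$reason[i] <- "no-bin-barcode"; next }
      obs <- substr(reads[i], s, ppos[i] - 1L)
      hit <- match_barcode(obs, bb_mat, unname(config$bin_barcodes),
                           config$barcode_max_errors)
      if (is.na(hit)) res$reason[i] <- "no-bin-barcode"
      else res$bin[i] <- names(config$bin_barcodes)[hit]
    }
    todo <- which(is.na(res$reason))
  } else {
    res$bin[todo] <- bin_id
  }

  for (i in todo) {
    bstart <- ppos[i] + nchar(config$forward_primer) + nchar(SPEI_SITE)
    obs_bc <- substr(reads[i], bstart, bstart + bc_len - 1L)
    hit <- match_barcode(obs_bc, design_mat, manifest$barcode,
                         config$barcode_max_errors)
    if (is.na(hit)) {
      res$reason[i] <- if (identical(attr(hit, "reason"), "ambiguous"))
        "ambiguous-barcode" else "no-variant-barcode"
      next
    }
    vstart <- bstart + bc_len
    obs_region <- substr(reads[i], vstart, vstart + region_len - 1L)
    if (nchar(obs_region) < region_len) { res$reason[i] <- "body-mismatch"; next }
    ver <- verify_body(obs_region, region_chars[[hit]])
    if (ver$mismatches > config$body_max_mismatch) {
      res$reason[i] <- "body-mismatch"
    } else {
      res$reason[i] <- "assigned"
      res$variant_id[i] <- manifest$variant_id[hit]
      res$subvariant[i] <- ver$subvariant
    }
  }
  res
}

# Compare an observed region against the design characters; K/M design
# positions accept their base pair and contribute the sub-variant assignment.
verify_body <- function(obs, design_chars) {
  obs_chars <- strsplit(obs, "", fixed = TRUE)[[1]]
  plain <- design_chars %in% BASES
  mism <- sum(obs_chars[plain] != design_chars[plain])
  mixed <- which(!plain)
  sub <- ""
  if (length(mixed) > 0L) {
    ok <- mapply(base_matches_design, obs_chars[mixed], design_chars[mixed])
    mism <- mism + sum(!ok)
    sub <- paste(obs_chars[mixed], collapse = "")
  }
  list(mismatches = mism, subvariant = sub)
}

#' Annotate the sub-variant of a body-verified read
#'
#' Returns the concrete base observed at each mixed (K/M) position of the
#' variant's design, in design order. A base outside the allowed pair makes
#' the read a body mismatch (`NA` returned).
#'
#' @param read_region Observed variable-region sequence.
#' @param design_region The variant's designed variable region (with K/M).
#' @return Assignment string (e.g. `"TC"`), `""` for plain variants, `NA` on
#'   a disallowed base.
#' @export
annotate_subvariant <- function(read_region, design_region) {
  ver <- verify_body(read_region, strsplit(design_region, "", fixed = TRUE)[[1]])
  if (ver$mismatches > 0) return(NA_character_)
  ver$subvariant
}

#' Tally read assignments into bin count tables
#'
#' @param assignments One assignment data.frame (or an rbind of several) from
#'   [assign_reads()].
#' @param variant_ids Variants to report rows for (default: those observed).
#' @param bins Bin labels in column order (default `bin1..bin4`).
#' @return A list with `counts` (variant x bin integer matrix),
#'   `sub_counts` (data.frame variant_id, subvariant, one column per bin) and
#'   `rejections` (named counts by reason, including `assigned`).
#' @export
tally_assignments <- function(assignments, variant_ids = NULL,
                              bins = paste0("bin", 1:4)) {
  ok <- assignments$reason == "assigned"
  if (is.null(variant_ids))
    variant_ids <- sort(unique(assignments$variant_id[ok]))
  counts <- matrix(0L, nrow = length(variant_ids), ncol = length(bins),
                   dimnames = list(variant_ids, bins))
  if (any(ok)) {
    tab <- table(factor(assignments$variant_id[ok], levels = variant_ids),
                 factor(assignments$bin[ok], levels = bins))
    counts[] <- as.integer(tab)
  }
  sub <- assignments[ok, c("variant_id", "subvariant", "bin")]
  if (nrow(sub) > 0L) {
    key <- interaction(sub$variant_id, sub$subvariant, drop = TRUE, sep = "\r")
    tab <- table(key, factor(sub$bin, levels = bins))
    parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
    sub_counts <- data.frame(variant_id = vapply(parts, `[`, "", 1),
                             subvariant = vapply(parts, function(p)
                               if (length(p) > 1) p[2] else "", character(1)),
                             stringsAsFactors = FALSE)
    sub_counts <- cbind(sub_counts,
                        as.data.frame.matrix(unclass(tab)))
  } else {
    sub_counts <- data.frame(variant_id = character(0), subvariant = character(0))
    for (b in bins) sub_counts[[b]] <- integer(0)
  }
  rejections <- table(factor(assignments$reason,
                             levels = c("assigned", REJECT_REASONS)))
  list(counts = counts, sub_counts = sub_counts,
       rejections = stats::setNames(as.integer(rejections), names(rejections)))
}

#' Parse a full per-bin SORT-seq experiment
#'
#' Convenience wrapper: runs [assign_reads()] on each bin's reads and tallies
#' the union into a single count table.
#'
#' @param reads_by_bin Named list of read vectors (see [read_bin_fastq()]).
#' @param manifest A `design_manifest`.
#' @param config A [demux_config()].
#' @return As [tally_assignments()], plus `assignments` (the per-read table).
#' @export
parse_sortseq <- function(reads_by_bin, manifest, config = demux_config()) {
  all_assign <- do.call(rbind, lapply(names(reads_by_bin), function(b)
    assign_reads(reads_by_bin[[b]], manifest, config, bin_id = b)))
  tal <- tally_assignments(all_assign,
                           variant_ids = sort(unique(manifest$variant_id)),
                           bins = names(reads_by_bin))
  tal$assignments <- all_assign
  tal
}
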