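# SORT-seq simulator with known ground truth.
#
# Generative model: each variant has a latent log-fluorescence
# mu0 + sum(beta_motif * count) + variant noise; single cells fluoresce
# log-normally around the latent value (cell noise sigma_c); cells are
# gated into 4 bins at fixed boundaries (default: quartiles of the pooled
# distribution, emulating FACS gate placement); per-bin reads are
# multinomial across variants with probability proportional to
# abundance x bin-membership probability.

#' Simulation configuration
#'
#' @param motif_effects Named numeric vector: motif id -> additive effect on
#'   latent log-expression (unnamed catalog motifs default to 0). Effects are
#'   additive on the log scale, i.e. multiplicative on fluorescence.
#' @param mu0 Core (desert) latent log-expression (default `log(1500)`,
#'   centering the fluorescence range of a four-bin sort).
#' @param sigma_v Variant-level noise SD on the latent log scale (default 0.05).
#' @param sigma_c Cell-level log-fluorescence spread (default 0.4).
#' @param bin_boundaries Three increasing gate thresholds on the log scale;
#'   `NULL` (default) places them at the pooled 25/50/75% quantiles.
#' @param per_bin_depth Reads per bin (scalar or length-4).
#' @param bin_means Bin calibration means used for true/estimated expression
#'   (default the measured four-bin values 607/1364/2596/7541 A.U.).
#' @param barcode_error_rate Per-base substitution rate for simulated reads.
#' @param abundance Per-variant relative abundance (default uniform: one
#'   integrated locus per cell).
#' @param seed Integer RNG seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(motif_effects = numeric(0), mu0 = log(1500),
                       sigma_v = 0.05, sigma_c = 0.4, bin_boundaries = NULL,
                       per_bin_depth = 1e4, bin_means = c(607, 1364, 2596, 7541),
                       barcode_error_rate = 0, abundance = NULL, seed = 1) {
  stopifnot(sigma_v >= 0, sigma_c >= 0, all(per_bin_depth >= 0))
  if (!is.null(bin_boundaries) && any(diff(bin_boundaries) <= 0))
    stopf("bin boundaries must be strictly increasing")
  structure(list(motif_effects = motif_effects, mu0 = mu0, sigma_v = sigma_v,
                 sigma_c = sigma_c, bin_boundaries = bin_boundaries,
                 per_bin_depth = per_bin_depth, bin_means = bin_means,
                 barcode_error_rate = barcode_error_rate,
                 abundance = abundance, seed = seed),
            class = "sim_config")
}

#' Simulate per-variant ground truth
#'
#' Computes each variant's latent log-expression (additive motif effects +
#' variant noise), its 4-bin membership probabilities under the log-normal
#' cell model, and its true expression in calibration units
#' (`sum(bin_prob * bin_mean)`).
#'
#' @param variants Variant table from [enumerate_variants()].
#' @param config A [sim_config()].
#' @return Object of class `sim_truth`: data.frame `variant_id`, `latent`,
#'   `p1..p4`, `true_expression`, with attributes `boundaries`, `bin_areas`
#'   (pooled percentage area per bin) and `config`.
#' @export
simulate_truth <- function(variants, config = sim_config()) {
  set.seed(config$seed)
  motif_lists <- variant_motif_list(variants)
  eff <- vapply(motif_lists, function(ms) {
    ms <- ms[ms %in% names(config$motif_effects)]  # repetition multiplies the effect
    sum(config$motif_effects[ms])
  }, numeric(1))
  n <- nrow(variants)
  latent <- config$mu0 + eff +
    if (config$sigma_v > 0) stats::rnorm(n, 0, config$sigma_v) else 0
  boundaries <- config$bin_boundaries
  if (is.null(boundaries)) {
    # pooled fluorescence quantiles (FACS-style gate placement)
    pool <- stats::rnorm(5e4, mean = sample(latent, 5e4, replace = TRUE),
                         sd = config$sigma_c)
    boundaries <- unname(stats::quantile(pool, c(0.25, 0.5, 0.75)))
  }
  cdf <- vapply(boundaries, function(t)
    stats::pnorm(t, mean = latent, sd = config$sigma_c), numeric(n))
  if (is.null(dim(cdf))) cdf <- matrix(cdf, nrow = n)
  probs <- cbind(cdf[, 1], cdf[, 2] - cdf[, 1], cdf[, 3] - cdf[, 2],
                 1 - cdf[, 3])
  probs[probs < 0] <- 0
  colnames(probs) <- paste0("p", 1:4)
  abundance <- config$abundance %||% rep(1, n)
  areas <- 100 * colSums(probs * abundance) / sum(abundance)
  out <- cbind(data.frame(variant_id = variants$variant_id,
                          latent = latent, stringsAsFactors = FALSE),
               as.data.frame(probs),
               data.frame(true_expression = as.vector(probs %*% config$bin_means)))
  structure(out, class = c("sim_truth", "data.frame"),
            boundaries = boundaries, bin_areas = unname(areas), config = config)
}

#' Simulate a bin read-count table
#'
#' For each bin, reads are drawn multinomially across variants with
#' probability proportional to `abundance x bin-membership probability`;
#' per-bin totals equal the configured depths exactly.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The same [sim_config()] (defaults to the truth's).
#' @return Integer matrix (variants x 4 bins) with variant ids as row names.
#' @export
simulate_counts <- function(truth, config = attr(truth, "config")) {
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  abundance <- config$abundance %||% rep(1, n)
  depth <- rep(config$per_bin_depth, length.out = 4L)
  counts <- matrix(0L, nrow = n, ncol = 4L,
                   dimnames = list(truth$variant_id, paste0("bin", 1:4)))
  probs <- as.matrix(truth[, paste0("p", 1:4)])
  for (b in 1:4) {
    w <- abundance * probs[, b]
    if (sum(w) == 0 || depth[b] == 0) next
    counts[, b] <- as.integer(stats::rmultinom(1, depth[b], w))
  }
  counts
}

#' Bin calibration implied by a simulation
#'
#' Closes the loop with the quantifier: the percentage bin areas come from
#' the simulated pooled bin distribution and the bin means from the
#' configuration.
#'
#' @param truth A [simulate_truth()] result.
#' @return A [bin_calibration()].
#' @export
sim_calibration <- function(truth) {
  cfg <- attr(truth, "config")
  bin_calibration(bin_means = cfg$bin_means, bin_areas = attr(truth, "bin_areas"))
}

#' Simulate per-bin reads
#'
#' Expands a simulated count table into full oligo reads. Each read of a
#' variant picks one of its barcodes uniformly, realizes every K/M mixed
#' position by sampling the allowed base pair uniformly, is embedded in
#' fixed amplicon pads (so standard designs always exceed the 200-base
#' length filter), and receives independent per-base substitution errors at
#' `barcode_error_rate`.
#'
#' @param counts Count matrix from [simulate_counts()].
#' @param manifest A `design_manifest`.
#' @param config A [sim_config()].
#' @param fastq_dir Optional directory: writes `bin1.fastq` ... `bin4.fastq`.
#' @param pad5,pad3 Amplicon context added around the oligo.
#' @return Named list of character vectors of reads (one per bin); written
#'   to FASTQ as a side effect when `fastq_dir` is given.
#' @export
simulate_reads <- function(counts, manifest, config = sim_config(),
                           fastq_dir = NULL,
                           pad5 = "TATAGCCTTGACGGTCAGGATCAA",
                           pad3 = "GGATTCTCAAGCGGACTTGCCATA") {
  set.seed(config$seed + 2L)
  by_variant <- split(seq_len(nrow(manifest)), manifest$variant_id)
  bins <- colnames(counts) %||% paste0("bin", seq_len(ncol(counts)))
  out <- stats::setNames(vector("list", length(bins)), bins)
  for (b in seq_along(bins)) {
    nb <- counts[, b]
    variants <- rep(rownames(counts), nb)
    if (length(variants) == 0L) { out[[b]] <- character(0); next }
    rows <- vapply(variants, function(v) {
      ix <- by_variant[[v]]
      if (length(ix) == 1L) ix else sample(ix, 1L)
    }, integer(1))
    reads <- vapply(rows, function(i) {
      oligo <- realize_mixed(manifest$full_oligo[i])
      paste0(pad5, oligo, pad3)
    }, character(1))
    if (config$barcode_error_rate > 0)
      reads <- add_substitutions(reads, config$barcode_error_rate)
    out[[b]] <- unname(reads)
  }
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    for (b in names(out)) {
      ss <- Biostrings::DNAStringSet(out[[b]])
      if (length(ss) > 0) names(ss) <- sprintf("%s_read%06d", b, seq_along(ss))
      Biostrings::writeXStringSet(ss, file.path(fastq_dir, paste0(b, ".fastq")),
                                  format = "fastq")
    }
  }
  out
}

# Realize K/M positions of an oligo by sampling the allowed pair uniformly.
realize_mixed <- function(oligo) {
  chars <- strsplit(oligo, "", fixed = TRUE)[[1]]
  mixed <- which(chars %in% names(MIXED_CODES))
  if (length(mixed) > 0L) {
    chars[mixed] <- vapply(chars[mixed], function(ch)
      sample(strsplit(MIXED_CODES[[ch]], "", fixed = TRUE)[[1]], 1L),
      character(1))
  }
  paste(chars, collapse = "")
}

add_substitutions <- function(reads, rate) {
  vapply(reads, function(r) {
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < rate)
    if (length(hit) > 0L) {
      chars[hit] <- vapply(chars[hit], function(ch)
        sample(setdiff(BASES, ch), 1L), character(1))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Recovery metrics for a simulated pipeline run
#'
#' Compares pipeline outputs against the simulation ground truth:
#' (i) Pearson correlation of estimated expression with the true expression,
#' (ii) sensitivity and specificity of the mHG activating/repressing
#' classification against the planted effect signs at the given alpha, and
#' optionally (iii) the correlation of model predictions with truth.
#'
#' @param records Variant-level `expression_records` from the pipeline.
#' @param truth The [simulate_truth()] object.
#' @param classification Result of [classify_motifs()] (optional).
#' @param effects The planted `motif_effects` (defaults to the config's).
#' @param predictions Optional named or truth-ordered model predictions.
#' @return List with `expression_r`, and when available `sensitivity`,
#'   `specificity`, `n_planted`, `false_positives`, `prediction_r`.
#' @export
recovery_report <- function(records, truth, classification = NULL,
                            effects = attr(truth, "config")$motif_effects,
                            predictions = NULL) {
  m <- merge(records[, c("variant_id", "expression")],
             truth[, c("variant_id", "true_expression")], by = "variant_id")
  m <- m[!is.na(m$expression), ]
  out <- list(expression_r = stats::cor(m$expression, m$true_expression),
              n_variants = nrow(m))
  if (!is.null(classification)) {
    cl <- classification[classification$motif_id %in%
                           union(names(effects), classification$motif_id), ]
    cl <- cl[cl$motif_id != "desert", ]
    planted_sign <- sign(effects[cl$motif_id])
    planted_sign[is.na(planted_sign)] <- 0
    called <- ifelse(cl$class == "activating", 1,
                     ifelse(cl$class == "repressing", -1, 0))
    pos <- planted_sign != 0
    out$n_planted <- sum(pos)
    out$sensitivity <- if (any(pos)) mean(called[pos] == planted_sign[pos]) else NA
    out$specificity <- if (any(!pos)) mean(called[!pos] == 0) else NA
    out$false_positives <- sum(called[!pos] != 0)
  }
  if (!is.null(predictions)) {
    stopifnot(length(predictions) == nrow(truth))
    out$prediction_r <- stats::cor(predictions, truth$true_expression)
  }
  out
}
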