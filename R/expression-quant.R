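# Expression quantification: normalized bin vectors, bin-weighted mean
# fluorescent expression, quality groups, and cohort statistics.

#' Bin calibration for expression estimation
#'
#' Holds the mean fluorescence of each FACS bin and the percentage area each
#' bin occupies in the pooled sort histogram. The default bin means are the
#' values measured for the four-bin yeast sort (607, 1364, 2596, 7541 A.U.);
#' the default areas are uniform, appropriate for simulated data where gates
#' are placed at pooled quartiles.
#'
#' @param bin_means Strictly increasing fluorescence means, one per bin (A.U.).
#' @param bin_areas Non-negative percentage areas, one per bin.
#' @return An object of class `bin_calibration`.
#' @export
bin_calibration <- function(bin_means = c(607, 1364, 2596, 7541),
                            bin_areas = rep(25, length(bin_means))) {
  if (any(diff(bin_means) <= 0)) stopf("bin_means must be strictly increasing")
  if (any(bin_areas < 0)) stopf("bin_areas must be non-negative")
  if (length(bin_means) != length(bin_areas))
    stopf("bin_means and bin_areas must have equal length")
  structure(list(bin_means = bin_means, bin_areas = bin_areas),
            class = "bin_calibration")
}

#' Normalize raw bin read counts
#'
#' Implements the bin normalization procedure: (1) the total reads per bin,
#' (2) each variant's count divided by its bin total, (3-4) scaled by the
#' bin's percentage histogram area giving adjusted reads `a_vb`, (5) summed
#' over bins to `S_v`, (6) divided by `S_v` to give the normalized bin vector
#' which sums to 1. Per-bin sequencing depth cancels, so scaling any one
#' bin's counts and total leaves the result unchanged.
#'
#' @param counts Integer matrix (variants x bins) of raw read counts, row
#'   names = variant (or barcode) ids.
#' @param cal A [bin_calibration()].
#' @param bin_totals Per-bin totals; derived as column sums when `NULL`
#'   (supply externally when `counts` is a subset of the library).
#' @return List with `normalized` (rows sum to 1; `NA` rows for zero-read
#'   variants, also listed in `flagged`), `adjusted` (`a_vb`), `S` (`S_v`)
#'   and `total_reads`.
#' @export
normalize_reads <- function(counts, cal = bin_calibration(), bin_totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stopf("read counts must be non-negative")
  if (is.null(bin_totals)) bin_totals <- colSums(counts)
  if (length(bin_totals) != ncol(counts))
    stopf("bin_totals length must match the number of bins")
  frac <- sweep(counts, 2, ifelse(bin_totals > 0, bin_totals, 1), "/")
  adjusted <- sweep(frac, 2, cal$bin_areas, "*")
  S <- rowSums(adjusted)
  normalized <- adjusted / ifelse(S > 0, S, NA_real_)
  total_reads <- rowSums(counts)
  list(normalized = normalized, adjusted = adjusted, S = S,
       total_reads = total_reads,
       flagged = rownames(counts)[total_reads == 0])
}

#' Bin-weighted mean fluorescent expression
#'
#' `Expression (A.U.) = MeanBin1*x + MeanBin2*y + MeanBin3*z + MeanBin4*w`
#' for a normalized bin vector `(x, y, z, w)`. The result is bounded by the
#' first and last bin means.
#'
#' @param normalized Normalized bin vector, or a matrix with one vector per
#'   row (each row must sum to 1 within 1e-6; `NA` rows propagate).
#' @param cal A [bin_calibration()].
#' @return Numeric vector of expression values (A.U.).
#' @export
compute_expression <- function(normalized, cal = bin_calibration()) {
  if (is.null(dim(normalized))) normalized <- matrix(normalized, nrow = 1)
  rs <- rowSums(normalized)
  bad <- which(!is.na(rs) & abs(rs - 1) > 1e-6)
  if (length(bad) > 0L)
    stopf("normalized vector in row %d does not sum to 1", bad[1])
  as.vector(normalized %*% cal$bin_means)
}

#' Classify a variant's quality group
#'
#' Group 3: fewer than `min_reads` total reads (under-sampled). Group 2: at
#' least `min_reads` reads but more than `saturation_frac` of the normalized
#' mass in the top bin (saturated). Group 1: everything else -- the
#' well-sampled variants carried into downstream analysis. Variants with
#' exactly `min_reads` reads fall into groups 1/2.
#'
#' @param normalized Normalized bin matrix (rows sum to 1).
#' @param total_reads Total read counts per row.
#' @param min_reads Read threshold (default 40).
#' @param saturation_frac Top-bin saturation threshold (default 0.90).
#' @return Integer vector of groups (1, 2 or 3).
#' @export
classify_group <- function(normalized, total_reads, min_reads = 40,
                           saturation_frac = 0.90) {
  if (is.null(dim(normalized))) normalized <- matrix(normalized, nrow = 1)
  top <- normalized[, ncol(normalized)]
  ifelse(total_reads < min_reads, 3L,
         ifelse(!is.na(top) & top > saturation_frac, 2L, 1L))
}

#' Quantify expression from a bin count table
#'
#' Runs normalization, expression and group classification in one step.
#'
#' @param counts Variant (or barcode) x bin count matrix.
#' @param cal A [bin_calibration()].
#' @param bin_totals Optional externally supplied per-bin totals.
#' @param min_reads,saturation_frac Group thresholds (see [classify_group()]).
#' @return A data.frame (`expression_records`) with `variant_id`, normalized
#'   bin columns `x`,`y`,`z`,`w` (more for >4 bins), `expression`,
#'   `total_reads` and `group`.
#' @export
quantify_expression <- function(counts, cal = bin_calibration(),
                                bin_totals = NULL, min_reads = 40,
                                saturation_frac = 0.90) {
  nr <- normalize_reads(counts, cal, bin_totals)
  expr <- rep(NA_real_, nrow(nr$normalized))
  okr <- !is.na(rowSums(nr$normalized))
  if (any(okr)) expr[okr] <- compute_expression(nr$normalized[okr, , drop = FALSE], cal)
  grp <- classify_group(nr$normalized, nr$total_reads, min_reads, saturation_frac)
  cols <- c("x", "y", "z", "w")
  norm_df <- as.data.frame(nr$normalized)
  names(norm_df) <- if (ncol(norm_df) == 4) cols else paste0("n", seq_len(ncol(norm_df)))
  out <- cbind(data.frame(variant_id = rownames(counts) %||% sprintf("v%d", seq_len(nrow(counts))),
                          stringsAsFactors = FALSE),
               norm_df,
               data.frame(expression = expr, total_reads = nr$total_reads,
                          group = grp))
  rownames(out) <- NULL
  class(out) <- c("expression_records", "data.frame")
  out
}

#' Aggregate barcode-level records to variant level
#'
#' Each barcode is quantified separately; per variant the normalized vectors
#' and expression are combined either by read-weighted averaging (default,
#' preserves the pooled-bin estimate) or by pooling raw counts first.
#'
#' @param records Barcode-level `expression_records` (from
#'   [quantify_expression()] on a barcode x bin table).
#' @param barcode_to_variant Character vector mapping each record row to its
#'   variant id.
#' @param counts Raw barcode x bin counts; required for `mode = "pooled"`.
#' @param cal A [bin_calibration()].
#' @param mode `"weighted"` (read-weighted mean of barcode vectors) or
#'   `"pooled"` (sum counts, then normalize).
#' @param min_reads,saturation_frac Group thresholds applied to the pooled totals.
#' @return Variant-level `expression_records`.
#' @export
aggregate_barcodes <- function(records, barcode_to_variant, counts = NULL,
                               cal = bin_calibration(),
                               mode = c("weighted", "pooled"),
                               min_reads = 40, saturation_frac = 0.90) {
  mode <- match.arg(mode)
  stopifnot(length(barcode_to_variant) == nrow(records))
  if (mode == "pooled") {
    if (is.null(counts)) stopf("pooled aggregation needs the raw counts")
    pooled <- rowsum(as.matrix(counts), group = barcode_to_variant)
    return(quantify_expression(pooled, cal, min_reads = min_reads,
                               saturation_frac = saturation_frac))
  }
  ncols <- intersect(c("x", "y", "z", "w"), names(records))
  w <- records$total_reads
  split_idx <- split(seq_len(nrow(records)), barcode_to_variant)
  rows <- lapply(split_idx, function(ix) {
    tw <- sum(w[ix])
    if (tw == 0) {
      norm <- rep(NA_real_, length(ncols))
    } else {
      keep <- ix[w[ix] > 0 & !is.na(records$expression[ix])]
      norm <- colSums(as.matrix(records[keep, ncols, drop = FALSE]) * w[keep]) / sum(w[keep])
    }
    c(norm, total = tw)
  })
  mat <- do.call(rbind, rows)
  norm <- mat[, seq_along(ncols), drop = FALSE]
  total <- mat[, ncol(mat)]
  expr <- rep(NA_real_, nrow(mat))
  okr <- !is.na(rowSums(norm))
  if (any(okr)) expr[okr] <- compute_expression(norm[okr, , drop = FALSE], cal)
  out <- cbind(data.frame(variant_id = names(split_idx), stringsAsFactors = FALSE),
               stats::setNames(as.data.frame(norm), ncols),
               data.frame(expression = expr, total_reads = total,
                          group = classify_group(norm, total, min_reads,
                                                 saturation_frac)))
  rownames(out) <- NULL
  class(out) <- c("expression_records", "data.frame")
  out
}

#' Per-motif expression distributions
#'
#' For each catalog motif (and the desert sentinel) collects the expression
#' of every variant containing it at least once; a variant carrying a motif
#' twice still contributes a single observation to that motif's group.
#'
#' @param records Variant-level `expression_records` (typically group 1 only).
#' @param variants Variant table (needs `variant_id` and `motifs` columns).
#' @param catalog A [motif_catalog()].
#' @param include_desert Also report the desert sentinel group under the
#'   catalog's desert id (default TRUE): variants with at least one unfilled
#'   motif slot, i.e. arity below the design's maximum, which carry the
#'   desert spacer as a "motif".
#' @return List with `summary` (data.frame `motif_id`, `n`, `median`, `q1`,
#'   `q3`) and `values` (named list of expression vectors).
#' @export
per_motif_distributions <- function(records, variants, catalog,
                                    include_desert = TRUE) {
  motif_lists <- variant_motif_list(variants)
  names(motif_lists) <- variants$variant_id
  expr <- stats::setNames(records$expression, records$variant_id)
  ids <- catalog$motif_id
  values <- lapply(ids, function(m) {
    vs <- variants$variant_id[vapply(motif_lists, function(x) m %in% x, logical(1))]
    unname(expr[intersect(vs, names(expr))])
  })
  names(values) <- ids
  if (include_desert) {
    arity <- vapply(motif_lists, length, integer(1))
    vs <- variants$variant_id[arity < max(arity)]
    values[[attr(catalog, "desert_id") %||% "desert"]] <-
      unname(expr[intersect(vs, names(expr))])
  }
  values <- lapply(values, function(v) v[!is.na(v)])
  summary <- data.frame(motif_id = names(values),
                        n = vapply(values, length, integer(1)),
                        median = vapply(values, function(v)
                          if (length(v)) stats::median(v) else NA_real_, 1),
                        q1 = vapply(values, function(v)
                          if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_, 1),
                        q3 = vapply(values, function(v)
                          if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_, 1),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, values = values)
}

#' Rank-shift test between motif expression distributions
#'
#' Orders motif groups by median expression; each group is compared (two-sided
#' Wilcoxon rank-sum) against the pooled variants of all groups ranked at
#' least `rank_offset` positions away, and p-values are Benjamini-Hochberg
#' adjusted at the given FDR.
#'
#' @param distributions Result of [per_motif_distributions()].
#' @param rank_offset Minimum rank separation of the comparison groups
#'   (default 5).
#' @param fdr BH false-discovery rate (default 0.10).
#' @return Data.frame `motif_id`, `rank`, `n`, `median`, `p`, `p_adj`,
#'   `significant`; groups with fewer than 2 observations are skipped with a
#'   message.
#' @export
rank_shift_test <- function(distributions, rank_offset = 5, fdr = 0.10) {
  vals <- distributions$values
  usable <- vapply(vals, length, integer(1)) >= 2L
  if (any(!usable))
    message("skipping ", sum(!usable), " motif group(s) with fewer than 2 variants")
  vals <- vals[usable]
  med <- vapply(vals, stats::median, numeric(1))
  ord <- order(-med)
  vals <- vals[ord]; med <- med[ord]
  k <- length(vals)
  p <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    far <- which(abs(seq_len(k) - i) >= rank_offset)
    if (length(far) == 0L) next
    ref <- unlist(vals[far], use.names = FALSE)
    p[i] <- stats::wilcox.test(vals[[i]], ref, exact = FALSE)$p.value
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(motif_id = names(vals), rank = seq_len(k),
             n = vapply(vals, length, integer(1)), median = med,
             p = p, p_adj = p_adj,
             significant = !is.na(p_adj) & p_adj < fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation between barcode pairs of the same variant
#'
#' For every variant measured with at least two barcodes, the Pearson
#' correlation of the two barcodes' normalized 4-bin vectors (all barcode
#' pairs are reported for deeper-barcoded variants). Zero-variance vectors
#' give an undefined correlation, returned as `NA` with `flagged = TRUE`.
#'
#' @param records Barcode-level `expression_records` (row per barcode).
#' @param barcode_to_variant Variant id per record row.
#' @return Data.frame `variant_id`, `r`, `expr1`, `expr2`, `flagged`.
#' @export
barcode_pair_correlation <- function(records, barcode_to_variant) {
  ncols <- intersect(c("x", "y", "z", "w"), names(records))
  split_idx <- split(seq_len(nrow(records)), barcode_to_variant)
  out <- list()
  for (v in names(split_idx)) {
    ix <- split_idx[[v]]
    ix <- ix[!is.na(records$expression[ix])]
    if (length(ix) < 2L) next
    prs <- utils::combn(ix, 2)
    for (j in seq_len(ncol(prs))) {
      a <- as.numeric(records[prs[1, j], ncols])
      b <- as.numeric(records[prs[2, j], ncols])
      flagged <- stats::sd(a) == 0 || stats::sd(b) == 0
      r <- if (flagged) NA_real_ else stats::cor(a, b)
      out[[length(out) + 1L]] <- data.frame(
        variant_id = v, r = r,
        expr1 = records$expression[prs[1, j]],
        expr2 = records$expression[prs[2, j]],
        flagged = flagged, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(variant_id = character(0), r = numeric(0),
                      expr1 = numeric(0), expr2 = numeric(0),
                      flagged = logical(0)))
  do.call(rbind, out)
}

#' Correlation between motif-group medians and group sizes
#'
#' @param distributions Result of [per_motif_distributions()] (needs at least
#'   3 non-empty groups).
#' @return List `r` (Pearson), `n_groups`, `flagged` (TRUE when degenerate).
#' @export
median_vs_count_correlation <- function(distributions) {
  s <- distributions$summary
  s <- s[s$n > 0 & !is.na(s$median), ]
  if (nrow(s) < 3L) stopf("need at least 3 motif groups")
  if (stats::sd(s$median) == 0 || stats::sd(s$n) == 0)
    return(list(r = NA_real_, n_groups = nrow(s), flagged = TRUE))
  list(r = stats::cor(s$median, s$n), n_groups = nrow(s), flagged = FALSE)
}
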