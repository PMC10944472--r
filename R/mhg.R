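# Minimum-hypergeometric (mHG) enrichment of motifs in expression-ranked
# variant lists.
#
# For a binary label vector ordered by expression, the mHG statistic is the
# minimum over prefix cutoffs n of the hypergeometric tail
# P(X >= b(n) | N, B, n). Its exact p-value is the probability, over all
# C(N,B) equally likely orderings, that this minimum is at most the observed
# score; it is computed by dynamic programming on the (n, b) lattice.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= b)` for `X ~ Hypergeometric(N, B, n)` (population N with B
#' successes, sample of size n), computed in log space for stability.
#'
#' @param b Observed successes in the sample (0 <= b <= min(n, B)).
#' @param n Sample (prefix) size.
#' @param B Total successes in the population.
#' @param N Population size.
#' @param log.p Return the log probability.
#' @return The tail probability (vectorized over the arguments).
#' @export
hypergeometric_tail <- function(b, n, B, N, log.p = FALSE) {
  if (any(b < 0 | b > pmin(n, B)) || any(n > N) || any(B > N))
    stopf("invalid hypergeometric arguments (need 0 <= b <= min(n,B), n <= N, B <= N)")
  stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE, log.p = log.p)
}

#' Minimum-hypergeometric score of a labeled ranked list
#'
#' Evaluates the hypergeometric tail at every prefix cutoff `n = 1..N-1`
#' (the full list always has tail 1) and returns the minimum together with
#' the smallest cutoff attaining it.
#'
#' @param labels Binary vector (1 = item carries the motif) in ranked order.
#' @return List `score`, `log_score`, `n_star` (NA when no labeled items),
#'   `N`, `B`.
#' @export
mhg_score <- function(labels) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), length(labels) >= 1L)
  N <- length(labels); B <- sum(labels)
  if (B == 0L || B == N || N == 1L)
    return(list(score = 1, log_score = 0, n_star = NA_integer_, N = N, B = B))
  n <- seq_len(N - 1L)
  b <- cumsum(labels)[n]
  lt <- stats::phyper(b - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE)
  i <- which.min(lt)
  list(score = exp(lt[i]), log_score = lt[i], n_star = i, N = N, B = B)
}

#' Exact p-value of an mHG score
#'
#' The probability that a uniformly random arrangement of B ones among N
#' items attains a minimal hypergeometric tail no larger than `score`.
#' Computed by a dynamic program over the (prefix length, ones seen) lattice:
#' the hypergeometric random walk is propagated while zeroing every cell
#' whose tail probability is at most the score ("rejection region"); the
#' surviving mass at (N, B) is the probability of never entering the region.
#'
#' @param score The observed mHG score (or its log via `log_score`).
#' @param N List length.
#' @param B Number of labeled items.
#' @param log_score Optional log of the score (more precise when supplied).
#' @return The exact p-value in `[score, min(1, N * score)]`.
#' @export
mhg_exact_pvalue <- function(score, N, B, log_score = log(score)) {
  stopifnot(N >= 1, B >= 0, B <= N)
  if (B == 0L || B == N || N == 1L) return(1)
  if (log_score >= 0) return(1)
  tol <- 1e-9
  # rejection region membership for cell (n, b): tail(b; n) <= score
  p <- numeric(B + 1L)  # p[b + 1] = P(walk at (n, b) without having entered R)
  p[1L] <- 1
  bs <- 0:B
  for (n in seq_len(N)) {
    remaining <- N - n + 1L
    p_take <- (B - bs) / remaining        # move (n-1,b) -> (n,b+1)
    p_take[p_take < 0] <- 0
    pn <- p * (1 - p_take)
    pn[-1L] <- pn[-1L] + p[-(B + 1L)] * p_take[-(B + 1L)]
    p <- pn
    if (n <= N - 1L) {
      bmax <- min(n, B)
      bb <- 0:bmax
      lt <- stats::phyper(bb - 1, B, N - B, n, lower.tail = FALSE, log.p = TRUE)
      reject <- lt <= log_score + tol
      if (any(reject)) p[seq_len(bmax + 1L)][reject] <- 0
    }
  }
  max(0, min(1, 1 - p[B + 1L]))
}

#' Minimum-hypergeometric enrichment test
#'
#' Ranks items by `score` (descending for `direction = "up"`, ascending for
#' `"down"`; ties broken by a stable sort on `ids` since the statistic is
#' order-sensitive), labels the items carrying the feature, and computes the
#' mHG score with its exact p-value.
#'
#' @param labels Logical/binary vector: item carries the motif.
#' @param score Ranking score (e.g. mean fluorescent expression).
#' @param direction `"up"` (enrichment at high scores) or `"down"`.
#' @param ids Optional item ids used for deterministic tie-breaking.
#' @return Object of class `mhg` with fields `score`, `n_star`, `p_exact`,
#'   `N`, `B`, `direction`.
#' @export
mhg_test <- function(labels, score, direction = c("up", "down"), ids = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(labels) == length(score))
  key <- if (direction == "up") -score else score
  ord <- if (is.null(ids)) order(key) else order(key, ids)
  s <- mhg_score(as.integer(labels[ord]))
  p <- mhg_exact_pvalue(s$score, s$N, s$B, log_score = s$log_score)
  structure(list(score = s$score, log_score = s$log_score, n_star = s$n_star,
                 p_exact = p, N = s$N, B = s$B, direction = direction),
            class = "mhg")
}

#' @export
print.mhg <- function(x, ...) {
  cat(sprintf("mHG (%s): score %.3g at prefix %s of %d (B = %d); exact p = %.3g\n",
              x$direction, x$score,
              ifelse(is.na(x$n_star), "-", x$n_star), x$N, x$B, x$p_exact))
  invisible(x)
}

#' mHG motif enrichment over an expression-ranked variant set
#'
#' For every catalog motif (and the desert sentinel: variants with at least
#' one unfilled motif slot) the variants are ranked by expression -- descending to detect activating
#' enrichment (`"up"`), ascending for repressing (`"down"`) -- labeled by
#' contains-the-motif-at-least-once, and tested with the exact mHG statistic.
#'
#' @param records Variant-level `expression_records` for the analysis set
#'   (the deep-barcode group-1 variants in the reference configuration).
#' @param variants Variant table (`variant_id`, `motifs`).
#' @param catalog A [motif_catalog()].
#' @param direction `"up"`, `"down"`, or `"both"` (default) for both rankings.
#' @param alpha Significance cutoff on the exact p-value (default 1e-4).
#' @param include_desert Also test the desert sentinel (default TRUE).
#' @return Data.frame with one row per motif x direction: `motif_id`,
#'   `direction`, `B`, `N`, `mhg_score`, `n_star`, `p_exact`, `significant`.
#' @export
enrich_motifs <- function(records, variants, catalog,
                          direction = c("both", "up", "down"), alpha = 1e-4,
                          include_desert = TRUE) {
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("up", "down") else direction
  records <- records[!is.na(records$expression), ]
  motif_lists <- variant_motif_list(variants)
  names(motif_lists) <- variants$variant_id
  motif_lists <- motif_lists[records$variant_id]
  ids <- catalog$motif_id
  feats <- lapply(ids, function(m)
    vapply(motif_lists, function(x) m %in% x, logical(1)))
  names(feats) <- ids
  if (include_desert) {
    arity <- vapply(motif_lists, length, integer(1))
    feats[[attr(catalog, "desert_id") %||% "desert"]] <- arity < max(arity)
  }
  rows <- list()
  for (d in dirs) {
    for (m in names(feats)) {
      t <- mhg_test(feats[[m]], records$expression, direction = d,
                    ids = records$variant_id)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = m, direction = d, B = t$B, N = t$N,
        mhg_score = t$score, n_star = t$n_star, p_exact = t$p_exact,
        significant = t$p_exact < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' mHG sub-motif enrichment over realized sub-variants
#'
#' Expands every mixed-base motif into its concrete sub-motifs, realizes each
#' observed sub-variant's variable region (the designed region with its K/M
#' positions replaced by the observed bases), labels a sub-variant record as
#' carrying a sub-motif when the realized region contains it as a substring,
#' and runs the mHG test per sub-motif and direction. Plain (non-mixed)
#' motifs are carried through unchanged, so the reference catalog yields the
#' plain motifs plus the expanded sub-motifs. Sub-variant records without
#' reads are excluded.
#'
#' @param sub_records Data.frame with `variant_id`, `subvariant`,
#'   `expression`, `total_reads` (one row per observed sub-variant; see
#'   [quantify_expression()] applied to sub-variant tallies).
#' @param variants Variant table (`variant_id`, `motifs`).
#' @param catalog A [motif_catalog()].
#' @param chassis Desert chassis (sequence or [design_desert()] object).
#' @param direction,alpha As in [enrich_motifs()].
#' @return Data.frame as in [enrich_motifs()] plus `parent_id`, `assignment`,
#'   `sequence`.
#' @export
enrich_submotifs <- function(sub_records, variants, catalog, chassis,
                             direction = c("both", "up", "down"),
                             alpha = 1e-4) {
  direction <- match.arg(direction)
  dirs <- if (direction == "both") c("up", "down") else direction
  sub_records <- sub_records[sub_records$total_reads > 0 &
                               !is.na(sub_records$expression), ]
  if (nrow(sub_records) == 0L) stopf("no sub-variant records with reads")
  motif_lists <- variant_motif_list(variants)
  names(motif_lists) <- variants$variant_id
  # realized variable region per record
  regions <- vapply(seq_len(nrow(sub_records)), function(i) {
    v <- sub_records$variant_id[i]
    design <- variable_region(motif_lists[[v]], catalog, chassis)
    realize_region(design, sub_records$subvariant[i])
  }, character(1))
  expansions <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i)
    expand_mixed_motif(mixed_base_motif(catalog$motif_id[i], catalog$sequence[i],
                                        catalog$known_function[i],
                                        catalog$source_organism[i]))))
  rows <- list()
  for (j in seq_len(nrow(expansions))) {
    lab <- grepl(expansions$sequence[j], regions, fixed = TRUE)
    for (d in dirs) {
      t <- mhg_test(lab, sub_records$expression, direction = d,
                    ids = paste(sub_records$variant_id, sub_records$subvariant))
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = ifelse(expansions$assignment[j] == "", expansions$parent_id[j],
                          paste0(expansions$parent_id[j], "_", expansions$assignment[j])),
        parent_id = expansions$parent_id[j],
        assignment = expansions$assignment[j],
        sequence = expansions$sequence[j],
        direction = d, B = t$B, N = t$N, mhg_score = t$score,
        n_star = t$n_star, p_exact = t$p_exact,
        significant = t$p_exact < alpha, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Fill the K/M positions of a designed region with the observed assignment.
realize_region <- function(design, assignment) {
  chars <- strsplit(design, "", fixed = TRUE)[[1]]
  mixed <- which(chars %in% names(MIXED_CODES))
  if (length(mixed) == 0L) return(design)
  obs <- strsplit(assignment, "", fixed = TRUE)[[1]]
  if (length(obs) != length(mixed))
    stopf("assignment '%s' does not match %d mixed positions", assignment,
          length(mixed))
  chars[mixed] <- obs
  paste(chars, collapse = "")
}

#' Classify motifs as activating / repressing / undetermined
#'
#' A motif is activating when its up-direction exact p-value is below `alpha`
#' and its down-direction p-value is not; repressing for the reverse;
#' undetermined otherwise. The (never expected) both-significant case is
#' reported as undetermined with `conflict = TRUE` rather than silently
#' assigned.
#'
#' @param up_results,down_results Enrichment tables from [enrich_motifs()]
#'   (may be the rows of a single `direction = "both"` run).
#' @param alpha Significance cutoff (default 1e-4).
#' @return Data.frame `motif_id`, `p_up`, `p_down`, `class`, `conflict`.
#' @export
classify_motifs <- function(up_results, down_results = NULL, alpha = 1e-4) {
  if (is.null(down_results)) {
    down_results <- up_results[up_results$direction == "down", ]
    up_results <- up_results[up_results$direction == "up", ]
  }
  m <- merge(up_results[, c("motif_id", "p_exact")],
             down_results[, c("motif_id", "p_exact")],
             by = "motif_id", suffixes = c("_up", "_down"))
  up_sig <- m$p_exact_up < alpha
  down_sig <- m$p_exact_down < alpha
  cls <- ifelse(up_sig & !down_sig, "activating",
                ifelse(down_sig & !up_sig, "repressing", "undetermined"))
  data.frame(motif_id = m$motif_id, p_up = m$p_exact_up, p_down = m$p_exact_down,
             class = cls, conflict = up_sig & down_sig,
             stringsAsFactors = FALSE)
}
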