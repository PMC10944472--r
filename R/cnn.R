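# Convolutional sequence-to-expression model.
#
# Architecture: one-hot DNA input -> 1D convolution (ReLU) -> global max
# pooling -> optional concatenation of a motif-count vector (the hybrid
# "MLAM" configuration) -> dense ReLU layer -> linear output (mean
# fluorescent expression) or 4-way softmax (bin distribution). Trained with
# Adam on (weighted) squared error or weighted cross-entropy. The network
# and its training loop are implemented in base R matrix algebra, sized so
# that reduced-scale ensembles train in seconds on one CPU.

#' CNN configuration
#'
#' Defaults are the desk-scale configuration (64 kernels, ensemble of 5);
#' `paper_config = TRUE` restores the full-scale reference setting of 1024
#' kernels and a 100-member ensemble (minutes to hours of training).
#'
#' @param n_kernels Number of convolution kernels (default 64).
#' @param kernel_width Kernel width in bases (default 6).
#' @param dense_units Dense-layer width (default 16).
#' @param epochs Training epochs (default 5).
#' @param batch_size Minibatch size (default 32).
#' @param ensemble_size Independently initialized models averaged at
#'   prediction time (default 5).
#' @param learning_rate Adam step size (default 1e-3).
#' @param output_mode `"scalar"` (expression, squared-error loss) or
#'   `"bins"` (4-bin distribution, weighted cross-entropy).
#' @param pad_value Per-channel value used to uniform-pad sequences shorter
#'   than the maximum input length (default 0.25).
#' @param max_input_length Maximum input length; `NULL` = longest training
#'   sequence. Training on short sequences with padding lets the model score
#'   longer designs (e.g. 101-nt library variants and 186-nt validation
#'   chassis).
#' @param include_motif_counts Concatenate a motif-count vector after the
#'   pooling layer (the hybrid model).
#' @param use_sample_weights Weight samples by read support (default TRUE
#'   when weights are supplied).
#' @param seed Integer seed; identical seeds give identical ensembles.
#' @param paper_config Restore the full-scale configuration.
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(n_kernels = 64, kernel_width = 6, dense_units = 16,
                       epochs = 5, batch_size = 32, ensemble_size = 5,
                       learning_rate = 1e-3,
                       output_mode = c("scalar", "bins"), pad_value = 0.25,
                       max_input_length = NULL, include_motif_counts = FALSE,
                       use_sample_weights = TRUE, seed = 1,
                       paper_config = FALSE) {
  output_mode <- match.arg(output_mode)
  if (paper_config) { n_kernels <- 1024; ensemble_size <- 100 }
  cfg <- list(n_kernels = n_kernels, kernel_width = kernel_width,
              dense_units = dense_units, epochs = epochs,
              batch_size = batch_size, ensemble_size = ensemble_size,
              learning_rate = learning_rate, output_mode = output_mode,
              pad_value = pad_value, max_input_length = max_input_length,
              include_motif_counts = include_motif_counts,
              use_sample_weights = use_sample_weights, seed = seed)
  if (any(vapply(cfg[c("n_kernels", "kernel_width", "dense_units", "epochs",
                       "batch_size", "ensemble_size", "learning_rate")],
                 function(v) v <= 0, logical(1))))
    stopf("all CNN hyperparameters must be positive")
  structure(cfg, class = "cnn_config")
}

#' One-hot encode a DNA sequence
#'
#' @param sequence Sequence over `{A,C,G,T}`.
#' @param max_length Output width; positions beyond the sequence are filled
#'   with `pad_value` in every channel so column sums stay 1.
#' @param pad_value Padding value per channel (default 0.25).
#' @return 4 x `max_length` matrix with rows `A`, `C`, `G`, `T`.
#' @export
one_hot_encode <- function(sequence, max_length = nchar(sequence),
                           pad_value = 0.25) {
  if (nchar(sequence) > max_length)
    stopf("sequence length %d exceeds max_length %d", nchar(sequence), max_length)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  code <- match(chars, BASES)
  if (anyNA(code))
    stopf("illegal character '%s' in sequence", chars[which(is.na(code))[1]])
  m <- matrix(pad_value, nrow = 4, ncol = max_length, dimnames = list(BASES, NULL))
  if (length(code) > 0L) {
    m[, seq_along(code)] <- 0
    m[cbind(code, seq_along(code))] <- 1
  }
  m
}

# Sliding-window design matrix for the convolution: one row per
# (sequence, window), sample-major with the window index fastest; each row is
# the flattened 4 x width one-hot block (channel fastest within position).
encode_windows <- function(sequences, max_length, width, pad_value) {
  n <- length(sequences)
  codes <- lapply(strsplit(toupper(sequences), "", fixed = TRUE), function(ch) {
    code <- match(ch, BASES)
    if (anyNA(code))
      stopf("illegal character '%s' in sequence", ch[which(is.na(code))[1]])
    code
  })
  lens <- lengths(codes)
  if (any(lens > max_length)) stopf("sequence longer than max_input_length")
  H <- matrix(pad_value, nrow = n, ncol = 4L * max_length)
  for (i in seq_len(n)) {
    code <- codes[[i]]
    cols <- 4L * (seq_along(code) - 1L)
    H[i, rep(cols, each = 4L) + rep(1:4, length(code))] <- 0
    H[i, cols + code] <- 1
  }
  P <- max_length - width + 1L
  X <- matrix(0, nrow = n * P, ncol = 4L * width)
  rows <- (seq_len(n) - 1L) * P
  for (p in seq_len(P)) {
    X[rows + p, ] <- H[, (4L * (p - 1L) + 1L):(4L * (p - 1L) + 4L * width),
                       drop = FALSE]
  }
  list(X = X, n = n, P = P)
}

relu <- function(x) { x[x < 0] <- 0; x }

init_member <- function(cfg, extra_inputs, seed) {
  set.seed(seed)
  fan_in <- 4L * cfg$kernel_width
  K <- cfg$n_kernels; D <- cfg$dense_units
  n_out <- if (cfg$output_mode == "scalar") 1L else 4L
  list(W1 = matrix(stats::rnorm(fan_in * K, sd = sqrt(2 / fan_in)), fan_in, K),
       b1 = numeric(K),
       W2 = matrix(stats::rnorm((K + extra_inputs) * D,
                                sd = sqrt(2 / (K + extra_inputs))),
                   K + extra_inputs, D),
       b2 = numeric(D),
       W3 = matrix(stats::rnorm(D * n_out, sd = sqrt(1 / D)), D, n_out),
       b3 = numeric(n_out))
}

# Forward pass for a set of rows of the window matrix.
cnn_forward <- function(params, Xb, nb, P, counts_b = NULL) {
  K <- ncol(params$W1)
  Z <- Xb %*% params$W1
  Z <- relu(sweep(Z, 2, params$b1, "+"))
  tZ <- t(matrix(Z, nrow = P))            # (nb*K) x P, pair index k-major
  amax <- max.col(tZ, ties.method = "first")
  hmax <- tZ[cbind(seq_len(nrow(tZ)), amax)]
  Hpool <- matrix(hmax, nrow = nb, ncol = K)
  Hfull <- if (is.null(counts_b)) Hpool else cbind(Hpool, counts_b)
  Apre <- sweep(Hfull %*% params$W2, 2, params$b2, "+")
  A <- relu(Apre)
  out <- sweep(A %*% params$W3, 2, params$b3, "+")
  list(out = out, A = A, Apre = Apre, Hfull = Hfull, amax = amax,
       hmax = hmax, K = K)
}

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

# One Adam step over a minibatch; returns updated params and moments.
cnn_train_member <- function(params, enc, y, counts, sw, cfg, seed) {
  set.seed(seed)
  n <- enc$n; P <- enc$P
  lr <- cfg$learning_rate; beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  mom <- lapply(params, function(p) p * 0)
  vel <- lapply(params, function(p) p * 0)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    for (ib in batches) {
      nb <- length(ib)
      xrows <- rep((ib - 1L) * P, each = P) + seq_len(P)
      Xb <- enc$X[xrows, , drop = FALSE]
      counts_b <- if (is.null(counts)) NULL else counts[ib, , drop = FALSE]
      fw <- cnn_forward(params, Xb, nb, P, counts_b)
      swb <- sw[ib] / sum(sw[ib])
      if (cfg$output_mode == "scalar") {
        err <- fw$out[, 1] - y[ib]
        gout <- matrix(2 * swb * err, ncol = 1)
      } else {
        Tb <- y[ib, , drop = FALSE]
        pr <- softmax_rows(fw$out)
        cw <- attr(y, "class_weights")
        s_i <- as.vector(Tb %*% cw)
        gout <- swb * (pr * s_i - sweep(Tb, 2, cw, "*"))
      }
      grads <- cnn_backward(params, fw, Xb, gout, nb, P,
                            has_counts = !is.null(counts_b))
      step <- step + 1L
      for (nm in names(params)) {
        mom[[nm]] <- beta1 * mom[[nm]] + (1 - beta1) * grads[[nm]]
        vel[[nm]] <- beta2 * vel[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - beta1^step)
        vhat <- vel[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  params
}

cnn_backward <- function(params, fw, Xb, gout, nb, P, has_counts) {
  K <- fw$K
  gA <- (gout %*% t(params$W3)) * (fw$Apre > 0)
  dW3 <- t(fw$A) %*% gout
  db3 <- colSums(gout)
  dW2 <- t(fw$Hfull) %*% gA
  db2 <- colSums(gA)
  gH <- gA %*% t(params$W2)
  gPool <- gH[, seq_len(K), drop = FALSE]
  gval <- as.vector(gPool) * (fw$hmax > 0)
  j <- seq_len(nb * K)
  i_loc <- ((j - 1L) %% nb) + 1L
  k_idx <- ((j - 1L) %/% nb) + 1L
  G <- matrix(0, nrow = nb * P, ncol = K)
  G[cbind((i_loc - 1L) * P + fw$amax, k_idx)] <- gval
  dW1 <- t(Xb) %*% G
  db1 <- colSums(G)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Train a convolutional expression model ensemble
#'
#' Trains `ensemble_size` independently initialized networks (different
#' weights and batch orders, all derived from the configuration seed) and
#' averages their outputs at prediction time. In `"scalar"` mode targets are
#' standardized internally and predictions are returned on the original
#' expression scale; in `"bins"` mode targets are normalized 4-bin vectors
#' and the loss is a weighted cross-entropy with per-bin weights inversely
#' proportional to the read mass of each bin.
#'
#' @param sequences Character vector of training sequences over `{A,C,G,T}`.
#' @param targets Numeric expression vector (`"scalar"`) or an N x 4 matrix
#'   of normalized bin vectors (`"bins"`).
#' @param motif_counts Optional N x m motif-count matrix, concatenated after
#'   the pooling layer (required when `config$include_motif_counts`).
#' @param sample_weights Optional non-negative weights (read support);
#'   normalized to sum to 1.
#' @param config A [cnn_config()].
#' @return Object of class `surs_cnn` with a `predict()` method.
#' @export
surs_cnn <- function(sequences, targets, motif_counts = NULL,
                     sample_weights = NULL, config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  n <- length(sequences)
  if (n == 0L) stopf("empty training set")
  if (config$include_motif_counts && is.null(motif_counts))
    stopf("include_motif_counts = TRUE but motif_counts missing")
  if (!config$include_motif_counts) motif_counts <- NULL
  if (!is.null(motif_counts)) {
    motif_counts <- as.matrix(motif_counts)
    if (nrow(motif_counts) != n) stopf("motif_counts rows must match sequences")
  }
  max_len <- config$max_input_length %||% max(nchar(sequences))
  if (config$output_mode == "scalar") {
    y <- as.numeric(targets)
    if (length(y) != n) stopf("targets length must match sequences")
    y_center <- mean(y); y_scale <- stats::sd(y)
    if (is.na(y_scale) || y_scale == 0) y_scale <- 1
    y_std <- (y - y_center) / y_scale
  } else {
    y_std <- as.matrix(targets)
    if (nrow(y_std) != n || ncol(y_std) != 4L)
      stopf("bins mode needs an N x 4 target matrix")
    if (any(abs(rowSums(y_std) - 1) > 1e-6))
      stopf("bin targets must sum to 1 per row")
    y_center <- 0; y_scale <- 1
    cw <- 1 / pmax(colMeans(y_std), 1e-6)
    attr(y_std, "class_weights") <- cw / mean(cw)
  }
  sw <- if (is.null(sample_weights) || !config$use_sample_weights)
    rep(1, n) else as.numeric(sample_weights)
  if (any(sw < 0)) stopf("sample weights must be non-negative")
  sw <- sw / sum(sw)
  enc <- encode_windows(sequences, max_len, config$kernel_width,
                        config$pad_value)
  extra <- if (is.null(motif_counts)) 0L else ncol(motif_counts)
  members <- lapply(seq_len(config$ensemble_size), function(m) {
    seed_m <- config$seed + 7919L * m
    params <- init_member(config, extra, seed_m)
    cnn_train_member(params, enc, y_std, motif_counts, sw, config,
                     seed = seed_m + 1L)
  })
  structure(list(members = members, config = config, max_len = max_len,
                 y_center = y_center, y_scale = y_scale,
                 n_motif_inputs = extra, n_train = n),
            class = "surs_cnn")
}

#' @export
print.surs_cnn <- function(x, ...) {
  cat(sprintf(paste0("Convolutional expression model: %d-member ensemble, ",
                     "%d kernels x %d nt, %s output%s; trained on %d sequences ",
                     "(input length %d)\n"),
              length(x$members), x$config$n_kernels, x$config$kernel_width,
              x$config$output_mode,
              if (x$n_motif_inputs > 0)
                sprintf(", + %d motif-count inputs", x$n_motif_inputs) else "",
              x$n_train, x$max_len))
  invisible(x)
}

#' Predict with a trained CNN ensemble
#'
#' @param object A [surs_cnn()] model.
#' @param sequences Sequences to score (length at most the model's input
#'   length; shorter sequences are uniform-padded).
#' @param motif_counts Motif-count matrix; required for a hybrid model.
#' @param ... Unused.
#' @return Numeric vector of expression scores (`"scalar"`), or an N x 4
#'   matrix of bin probabilities summing to 1 (`"bins"`); in both cases the
#'   ensemble mean.
#' @export
predict.surs_cnn <- function(object, sequences, motif_counts = NULL, ...) {
  cfg <- object$config
  if (object$n_motif_inputs > 0) {
    if (is.null(motif_counts)) stopf("this model requires motif_counts")
    motif_counts <- as.matrix(motif_counts)
    if (ncol(motif_counts) != object$n_motif_inputs)
      stopf("motif_counts must have %d columns", object$n_motif_inputs)
  } else motif_counts <- NULL
  enc <- encode_windows(sequences, object$max_len, cfg$kernel_width,
                        cfg$pad_value)
  n <- enc$n
  acc <- NULL
  for (params in object$members) {
    fw <- cnn_forward(params, enc$X, n, enc$P, motif_counts)
    out <- if (cfg$output_mode == "bins") softmax_rows(fw$out) else fw$out
    acc <- if (is.null(acc)) out else acc + out
  }
  out <- acc / length(object$members)
  if (cfg$output_mode == "scalar")
    as.vector(out) * object$y_scale + object$y_center
  else out
}

#' Motif-count matrix for hybrid-model input
#'
#' Counts occurrences of every catalog motif. For a variant table the counts
#' come from the designed motif lists; for raw sequences each motif (with
#' K/M treated as IUPAC ambiguities) is scanned on the forward strand.
#'
#' @param x A variant table (with `motifs` column) or a character vector of
#'   sequences.
#' @param catalog A [motif_catalog()].
#' @return Integer matrix, one row per input, one column per catalog motif.
#' @export
motif_count_matrix <- function(x, catalog) {
  ids <- catalog$motif_id
  if (is.data.frame(x)) {
    lists <- variant_motif_list(x)
    out <- t(vapply(lists, function(ms)
      vapply(ids, function(m) sum(ms == m), integer(1)), integer(length(ids))))
  } else {
    subj <- Biostrings::DNAStringSet(x)
    out <- vapply(catalog$sequence, function(m)
      Biostrings::vcountPattern(Biostrings::DNAString(m), subj, fixed = FALSE),
      integer(length(x)))
    if (is.null(dim(out))) out <- matrix(out, nrow = length(x))
  }
  colnames(out) <- ids
  out
}

#' Evaluate predictions against observations
#'
#' Pearson correlation with a bootstrap scheme matched to the dataset size:
#' `"all_subsets"` enumerates every subset of size `n - 2` (e.g. all 55
#' subsets of 9 out of 11 validation points) and averages the subset
#' correlations; `"random_subsets"` draws `n_boot` random subsets of
#' `subset_size` points (30 for condition datasets, 16 for the smaller
#' mammalian sets).
#'
#' @param predictions,observations Paired numeric vectors (n >= 3).
#' @param scheme `"none"`, `"all_subsets"` or `"random_subsets"`.
#' @param subset_size Subset size for the random scheme (default 30).
#' @param n_boot Number of random subsets (default 100).
#' @param seed Seed for the random scheme.
#' @return List `r`, `bootstrap_mean`, `bootstrap_sd`, `n`, `scheme`,
#'   `flagged` (TRUE when a correlation was undefined).
#' @export
evaluate_predictions <- function(predictions, observations,
                                 scheme = c("none", "all_subsets",
                                            "random_subsets"),
                                 subset_size = 30, n_boot = 100, seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(length(predictions) == length(observations))
  n <- length(predictions)
  if (n < 3L) stopf("need at least 3 paired points")
  flagged <- stats::sd(predictions) == 0 || stats::sd(observations) == 0
  r <- if (flagged) NA_real_ else stats::cor(predictions, observations)
  bm <- bs <- NA_real_; n_subsets <- NA_integer_
  if (scheme == "all_subsets") {
    subs <- utils::combn(n, n - 2L)
    rs <- apply(subs, 2, function(ix) stats::cor(predictions[ix], observations[ix]))
    bm <- mean(rs); bs <- stats::sd(rs); n_subsets <- ncol(subs)
  } else if (scheme == "random_subsets") {
    if (subset_size > n) stopf("subset_size exceeds the number of points")
    set.seed(seed)
    rs <- replicate(n_boot, {
      ix <- sample.int(n, subset_size)
      stats::cor(predictions[ix], observations[ix])
    })
    bm <- mean(rs); bs <- stats::sd(rs); n_subsets <- n_boot
  }
  list(r = r, bootstrap_mean = bm, bootstrap_sd = bs, n = n,
       n_subsets = n_subsets, scheme = scheme, flagged = flagged)
}

#' Select a model training set from expression records
#'
#' `"adm"` (all-data): variants above a total-read cutoff, or the `n_top`
#' best-supported variants; `"amm"` (all-motif): the deep-barcode variants;
#' `"mbo"` (mixed-base only): deep-barcode variants containing at least one
#' mixed-base motif (a subset of `"amm"` by construction).
#'
#' @param records Variant-level `expression_records` with logical columns
#'   `deep` and `has_mixed` (see [annotate_records()]).
#' @param mode `"adm"`, `"amm"` or `"mbo"`.
#' @param read_cutoff ADM total-read cutoff; when `NULL`, the top `n_top`
#'   variants by read count are taken.
#' @param n_top ADM training-set size when no cutoff is given (default 20000).
#' @param holdout Fraction held out as a test split (default 0: no split).
#' @param seed Seed for the held-out draw.
#' @return The selected records, or `list(train, test)` when `holdout > 0`.
#' @export
select_training_set <- function(records, mode = c("adm", "amm", "mbo"),
                                read_cutoff = NULL, n_top = 20000,
                                holdout = 0, seed = 1) {
  mode <- match.arg(mode)
  sel <- switch(mode,
    adm = if (!is.null(read_cutoff)) {
      records[records$total_reads > read_cutoff, ]
    } else {
      records[order(-records$total_reads), ][seq_len(min(n_top, nrow(records))), ]
    },
    amm = records[isTRUE_vec(records$deep), ],
    mbo = records[isTRUE_vec(records$deep) & isTRUE_vec(records$has_mixed), ])
  if (nrow(sel) == 0L) stopf("empty training-set selection (mode '%s')", mode)
  if (holdout <= 0) return(sel)
  set.seed(seed)
  n_test <- max(1L, round(holdout * nrow(sel)))
  test_ix <- sample.int(nrow(sel), n_test)
  list(train = sel[-test_ix, ], test = sel[test_ix, ])
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Annotate expression records with design metadata
#'
#' Adds the `deep` (22-barcode) flag and `has_mixed` (contains a mixed-base
#' motif) flag used by [select_training_set()], plus the variable-region
#' sequence.
#'
#' @param records Variant-level `expression_records`.
#' @param manifest A `design_manifest`.
#' @param catalog A [motif_catalog()].
#' @return The records with `deep`, `has_mixed`, `motifs` and
#'   `variable_region` columns added.
#' @export
annotate_records <- function(records, manifest, catalog) {
  vm <- manifest[!duplicated(manifest$variant_id),
                 c("variant_id", "motifs", "deep", "variable_region")]
  mixed_ids <- catalog$motif_id[catalog$n_mixed > 0]
  vm$has_mixed <- vapply(strsplit(vm$motifs, ",", fixed = TRUE), function(ms)
    any(ms %in% mixed_ids), logical(1))
  merge(records, vm, by = "variant_id", sort = FALSE)
}
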