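# Unsupervised outlier detectors over the feature matrix. Every scorer
# returns one finite real per epoch with a uniform orientation: higher =
# more anomalous (ABOD and the one-class SVM are sign-flipped accordingly).

.as_matrix_fm <- function(fm) {
  if (inherits(fm, "qeeg_features")) feature_matrix(fm) else as.matrix(fm)
}

#' Histogram-based outlier scores (HBOS)
#'
#' Per feature, a histogram of the training values is built and each value is
#' scored by the log inverse density of its bin; the per-feature scores are
#' summed. With `dynamic_bins = TRUE` the bins are equal-frequency (quantile
#' edges) rather than equal-width. Values falling outside the histogram range
#' are assigned the edge bin provided they lie within `tol` times the range
#' of it ("relaxed" scoring); beyond that they receive the minimum density.
#' Constant features are uninformative and contribute zero.
#'
#' @param fm a `qeeg_features` tibble (standardize first) or numeric matrix.
#' @param n_bins number of histogram bins (>= 2).
#' @param tol out-of-range tolerance, as a fraction of the feature's range.
#' @param dynamic_bins use equal-frequency bin edges.
#' @return Numeric score per row; higher = more anomalous.
#' @export
hbos_scores <- function(fm, n_bins = 10L, tol = 0.1, dynamic_bins = FALSE) {
  m <- .as_matrix_fm(fm)
  if (n_bins < 2L) stop_param("n_bins must be >= 2")
  n <- nrow(m)
  eps <- 1e-12
  score <- numeric(n)
  for (f in seq_len(ncol(m))) {
    x <- m[, f]
    rng <- range(x)
    if (rng[1] == rng[2]) next
    edges <- if (dynamic_bins) {
      e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                                  names = FALSE, type = 7))
      if (length(e) < 3L) e <- seq(rng[1], rng[2], length.out = n_bins + 1L)
      e
    } else {
      seq(rng[1], rng[2], length.out = n_bins + 1L)
    }
    nb <- length(edges) - 1L
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nb)
    widths <- pmax(diff(edges), eps)
    dens <- counts / (n * widths)
    slack <- tol * (rng[2] - rng[1])
    d <- dens[idx]
    out_lo <- x < rng[1] - slack
    out_hi <- x > rng[2] + slack
    d[out_lo | out_hi] <- eps
    score <- score + log(1 / (d + eps))
  }
  score
}

#' Local outlier factor (LOF)
#'
#' Classic density-ratio LOF: the average local reachability density of a
#' point's k nearest neighbours divided by its own. Values near 1 are
#' inliers; larger values indicate locally sparse points.
#'
#' @param fm feature tibble or matrix.
#' @param k_neighbors neighbourhood size (default 20).
#' @export
lof_scores <- function(fm, k_neighbors = 20L) {
  m <- .as_matrix_fm(fm)
  n <- nrow(m)
  k <- min(k_neighbors, n - 1L)
  if (k < 1L) stop_param("need at least 2 rows for LOF")
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  ord <- apply(D, 1L, order)                 # [n x n] neighbour indices per row
  kdist <- vapply(seq_len(n), function(i) D[i, ord[k, i]], 0)
  nbrs <- lapply(seq_len(n), function(i) {
    # k-distance neighbourhood (includes ties at the k-distance)
    which(D[i, ] <= kdist[i])
  })
  lrd <- vapply(seq_len(n), function(i) {
    nb <- nbrs[[i]]
    reach <- pmax(kdist[nb], D[i, nb])
    1 / (mean(reach) + 1e-12)
  }, 0)
  vapply(seq_len(n), function(i) mean(lrd[nbrs[[i]]]) / lrd[i], 0)
}

#' Angle-based outlier scores (ABOD)
#'
#' For each point, the variance over pairs of its k nearest neighbours of the
#' normalized angle statistic `<a-x, b-x> / (|a-x|^2 |b-x|^2)`. Outliers see
#' their neighbourhood within a narrow cone, so their angle variance is
#' small; the returned score is the negated variance (higher = more
#' anomalous).
#'
#' @param fm feature tibble or matrix.
#' @param k_neighbors neighbours considered per point (default 10).
#' @export
abod_scores <- function(fm, k_neighbors = 10L) {
  m <- .as_matrix_fm(fm)
  n <- nrow(m)
  k <- min(k_neighbors, n - 1L)
  if (k < 2L) stop_param("ABOD needs at least 3 rows")
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  score <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    V <- sweep(m[nb, , drop = FALSE], 2L, m[i, ])
    nrm2 <- rowSums(V^2)
    G <- V %*% t(V)
    pairs <- which(upper.tri(G), arr.ind = TRUE)
    vals <- G[pairs] / (nrm2[pairs[, 1L]] * nrm2[pairs[, 2L]] + 1e-300)
    score[i] <- -stats::var(vals)
  }
  score
}

#' One-class SVM boundary-distance scores
#'
#' A nu-parameterized one-class support vector machine (RBF kernel by
#' default, via libsvm) is fit on all rows; the score is the negated signed
#' distance to the learned boundary, so points outside the support region
#' score highest.
#'
#' @param fm feature tibble or matrix.
#' @param nu upper bound on the margin-violation fraction (default 0.2).
#' @param kernel libsvm kernel name.
#' @export
ocsvm_scores <- function(fm, nu = 0.2, kernel = "radial") {
  m <- .as_matrix_fm(fm)
  fit <- e1071::svm(m, y = NULL, type = "one-classification", nu = nu,
                    kernel = kernel, scale = FALSE)
  pr <- stats::predict(fit, m, decision.values = TRUE)
  -as.numeric(attr(pr, "decision.values"))
}

#' PCA reconstruction-error scores
#'
#' Projects the rows onto the top principal components and back; the score is
#' the squared reconstruction error, large for points off the dominant linear
#' manifold.
#'
#' @param fm feature tibble or matrix.
#' @param n_components components kept (default half the features).
#' @export
pca_recon_scores <- function(fm, n_components = NULL) {
  m <- .as_matrix_fm(fm)
  k <- min(n_components %||% max(1L, ncol(m) %/% 2L), ncol(m), nrow(m) - 1L)
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  centred <- sweep(m, 2L, pc$center)
  recon <- centred %*% rot %*% t(rot)
  rowSums((centred - recon)^2)
}

#' Autoencoder reconstruction-error scores
#'
#' A small dense autoencoder (tanh hidden layers, linear output) is trained
#' on the full matrix; the score is the per-row mean squared reconstruction
#' error. Training is full-batch and seeded, so scores are deterministic.
#'
#' @param fm feature tibble or matrix (standardized recommended).
#' @param hidden_sizes encoder-bottleneck-decoder layer widths.
#' @param epochs training iterations.
#' @param lr Adam learning rate.
#' @param seed integer seed.
#' @export
autoencoder_scores <- function(fm, hidden_sizes = c(32L, 8L, 32L),
                               epochs = 300L, lr = 1e-2, seed = 0L) {
  m <- .as_matrix_fm(fm)
  net <- nn_train(m, m, hidden_sizes, epochs = epochs, lr = lr, seed = seed)
  rowMeans((nn_predict(net, m) - m)^2)
}

#' Variational-autoencoder reconstruction scores
#'
#' As [autoencoder_scores()], but the encoder emits a Gaussian posterior and
#' training adds the KL penalty toward a standard normal latent; the score
#' remains the (mean-latent) reconstruction error only.
#'
#' @inheritParams autoencoder_scores
#' @param latent_dim latent dimension.
#' @param hidden hidden layer width.
#' @param beta KL weight.
#' @export
vae_scores <- function(fm, latent_dim = 4L, hidden = 32L, epochs = 300L,
                       lr = 1e-2, beta = 1, seed = 0L) {
  m <- .as_matrix_fm(fm)
  v <- vae_train(m, latent_dim, hidden, epochs, lr, beta, seed)
  rowMeans((vae_reconstruct(v, m) - m)^2)
}

#' Detector configuration
#'
#' A lightweight method + parameter bundle consumed by [run_detection()],
#' [lscp_scores()] and [random_search()].
#'
#' @param method one of `"hbos"`, `"lof"`, `"abod"`, `"ocsvm"`, `"pca"`,
#'   `"autoencoder"`, `"vae"`, `"lscp"`.
#' @param ... method parameters passed through to the scorer.
#' @export
detector_config <- function(method, ...) {
  method <- match.arg(method, c("hbos", "lof", "abod", "ocsvm", "pca",
                                "autoencoder", "vae", "lscp"))
  structure(list(method = method, params = list(...)), class = "detector_config")
}

# Dispatch a detector_config on a feature matrix.
.detector_scores <- function(fm, cfg, seed = 0L) {
  p <- cfg$params
  switch(cfg$method,
    hbos = do.call(hbos_scores, c(list(fm), p)),
    lof = do.call(lof_scores, c(list(fm), p)),
    abod = do.call(abod_scores, c(list(fm), p)),
    ocsvm = do.call(ocsvm_scores, c(list(fm), p)),
    pca = do.call(pca_recon_scores, c(list(fm), p)),
    autoencoder = do.call(autoencoder_scores,
                          c(list(fm), p[setdiff(names(p), "seed")],
                            list(seed = p$seed %||% seed))),
    vae = do.call(vae_scores, c(list(fm), p[setdiff(names(p), "seed")], list(seed = p$seed %||% seed))),
    lscp = do.call(lscp_scores, c(list(fm), p[setdiff(names(p), "seed")], list(seed = p$seed %||% seed))),
    stop_param(sprintf("unknown detection method '%s'", cfg$method))
  )
}

#' Locally selective combination of parallel outlier ensembles (LSCP)
#'
#' Fits every base detector on the full matrix and z-normalizes their scores.
#' The pseudo ground truth is the per-row mean of the normalized base scores.
#' Each row is then scored by the single base detector whose scores best
#' Pearson-correlate with the pseudo target over the row's `k_local` nearest
#' training rows. The default base set is the configuration reported to work
#' best in practice: two HBOS detectors (many bins with a rigid
#' out-of-range policy, few bins with a relaxed one) plus one one-class SVM.
#'
#' @param fm feature tibble or matrix.
#' @param base list of [detector_config()]s (>= 2).
#' @param k_local size of the local region (default 30).
#' @param seed seed passed to stochastic base detectors.
#' @export
lscp_scores <- function(fm, base = NULL, k_local = 30L, seed = 0L) {
  m <- .as_matrix_fm(fm)
  n <- nrow(m)
  base <- base %||% list(detector_config("hbos", n_bins = 50L, tol = 0.1),
                         detector_config("hbos", n_bins = 10L, tol = 0.5),
                         detector_config("ocsvm"))
  if (length(base) < 2L) stop_param("LSCP needs at least 2 base detectors")
  if (k_local >= n) stop_param("k_local must be smaller than the number of rows")
  S <- vapply(seq_along(base),
              function(b) .detector_scores(m, base[[b]], seed = sub_seed(seed, b)),
              numeric(n))
  Z <- apply(S, 2L, function(s) {
    sdv <- stats::sd(s)
    if (sdv > 0) (s - mean(s)) / sdv else s * 0
  })
  target <- rowMeans(Z)
  D <- as.matrix(stats::dist(m))
  diag(D) <- Inf
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k_local)]
    cors <- vapply(seq_along(base), function(b) {
      s <- Z[nb, b]
      if (stats::sd(s) == 0 || stats::sd(target[nb]) == 0) return(-Inf)
      stats::cor(s, target[nb])
    }, 0)
    out[i] <- Z[i, which.max(cors)]
  }
  out
}

#' Flag the top-scoring epochs at a contamination level
#'
#' Flags exactly `ceiling(contamination * n)` rows with the largest scores;
#' ties at the cut are broken toward the lower epoch index.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param contamination expected artifact fraction in `[0, 1)`.
#' @return Logical vector of flags.
#' @export
threshold_by_contamination <- function(scores, contamination) {
  if (contamination < 0 || contamination >= 1) stop_param("contamination must be in [0, 1)")
  n <- length(scores)
  k <- ceiling(contamination * n)
  flags <- logical(n)
  if (k > 0L) flags[order(-scores, seq_len(n))[seq_len(k)]] <- TRUE
  flags
}

#' Run artifact detection over an epoch set
#'
#' Scores the feature matrix with the configured detector and thresholds at
#' the contamination level. `mode = "per_subject"` fits and thresholds
#' independently inside each subject's epochs (capturing subject-specific
#' idiosyncrasies) and merges the results; `mode = "aggregated"` fits once on
#' all epochs.
#'
#' @param es the [epoch_set()] the features came from (provides subject ids).
#' @param fm the (standardized) `qeeg_features` tibble.
#' @param method detection method name or a [detector_config()].
#' @param contamination expected artifact fraction.
#' @param mode `"aggregated"` or `"per_subject"`.
#' @param seed seed for stochastic detectors.
#' @param ... parameters for the method (when `method` is a name).
#' @return A tibble of class `artifact_detection` with columns `epoch_index`,
#'   `subject_id`, `score`, `flag`; attributes record the configuration.
#' @export
run_detection <- function(es, fm, method = "lscp", contamination = 0.172,
                          mode = c("aggregated", "per_subject"), seed = 0L, ...) {
  mode <- match.arg(mode)
  cfg <- if (inherits(method, "detector_config")) method else detector_config(method, ...)
  m <- .as_matrix_fm(fm)
  n <- nrow(m)
  subj <- es$subject_ids
  stopifnot(length(subj) == n)
  scores <- numeric(n)
  flags <- logical(n)
  if (mode == "per_subject") {
    for (s in unique(subj)) {
      idx <- which(subj == s)
      sc <- .detector_scores(m[idx, , drop = FALSE], cfg, seed = seed)
      scores[idx] <- sc
      flags[idx] <- threshold_by_contamination(sc, contamination)
    }
  } else {
    scores <- .detector_scores(m, cfg, seed = seed)
    flags <- threshold_by_contamination(scores, contamination)
  }
  out <- tibble::tibble(epoch_index = seq_len(n), subject_id = subj,
                        score = scores, flag = flags)
  class(out) <- c("artifact_detection", class(out))
  attr(out, "method") <- cfg
  attr(out, "contamination") <- contamination
  attr(out, "mode") <- mode
  out
}

#' Random hyper-parameter search against annotations
#'
#' Samples `n_trials` parameter settings uniformly from `param_space`,
#' scores each configuration by F-score against the supplied annotations at
#' `contamination = mean(truth)`, and returns the best configuration plus the
#' full trial log.
#'
#' @param fm feature tibble or matrix.
#' @param truth logical ground-truth artifact flags.
#' @param method detection method name.
#' @param param_space named list; each element is a vector of candidate
#'   values for one parameter.
#' @param n_trials number of sampled configurations.
#' @param seed search seed.
#' @return A list with `best` (a [detector_config()]), `best_f1`, and `log`
#'   (a tibble, one row per trial).
#' @export
random_search <- function(fm, truth, method, param_space, n_trials = 50L, seed = 0L) {
  m <- .as_matrix_fm(fm)
  contamination <- mean(truth)
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    params <- with_seed(sub_seed(seed, t), {
      lapply(param_space, function(v) v[[sample.int(length(v), 1L)]])
    })
    cfg <- do.call(detector_config, c(list(method), params))
    sc <- .detector_scores(m, cfg, seed = sub_seed(seed, t, 999))
    f1 <- f_score(threshold_by_contamination(sc, contamination), truth)
    trials[[t]] <- tibble::tibble(trial = t, f1 = f1,
                                  params = list(params))
  }
  log <- dplyr::bind_rows(trials)
  best_t <- which.max(log$f1)
  list(best = do.call(detector_config, c(list(method), log$params[[best_t]])),
       best_f1 = log$f1[best_t], log = log)
}
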