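# Agreement metrics between predicted artifact flags and annotations, the
# size-matched random-classifier baseline, and the downstream classifier
# probe that measures whether correction helps an actual decoding task.

#' Confusion counts for binary artifact flags
#' @param pred,truth logical vectors (artifact = TRUE).
#' @return Named vector `(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  c(tp = sum(pred & truth), fp = sum(pred & !truth),
    fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' F-score of binary artifact flags
#'
#' `2 TP / (2 TP + FP + FN)`, defined as 0 when the denominator vanishes.
#' @inheritParams confusion_counts
#' @export
f_score <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  den <- 2 * cc[["tp"]] + cc[["fp"]] + cc[["fn"]]
  if (den == 0) 0 else 2 * cc[["tp"]] / den
}

#' Cohen's kappa of binary artifact flags
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the chance
#' agreement computed from the marginals; defined as 0 when `p_e = 1`.
#' @inheritParams confusion_counts
#' @export
cohens_kappa <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  n <- sum(cc)
  if (n == 0) return(0)
  po <- (cc[["tp"]] + cc[["tn"]]) / n
  p1 <- (cc[["tp"]] + cc[["fp"]]) / n; t1 <- (cc[["tp"]] + cc[["fn"]]) / n
  pe <- p1 * t1 + (1 - p1) * (1 - t1)
  if (abs(1 - pe) < 1e-15) 0 else (po - pe) / (1 - pe)
}

#' Evaluate a detection result against annotations
#'
#' @param det an `artifact_detection` tibble (or any tibble with
#'   `epoch_index`, `subject_id`, `flag`).
#' @param truth logical ground-truth flags, in epoch order.
#' @return A tibble of class `detection_metrics`: one row per subject plus an
#'   `"(all)"` row, with confusion counts, `f_score` and `kappa`.
#' @export
evaluate_detection <- function(det, truth) {
  one <- function(pred, tr, subject) {
    cc <- confusion_counts(pred, tr)
    tibble::tibble(subject_id = subject, n = length(tr),
                   tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]], tn = cc[["tn"]],
                   f_score = f_score(pred, tr), kappa = cohens_kappa(pred, tr))
  }
  rows <- lapply(unique(det$subject_id), function(s) {
    idx <- det$epoch_index[det$subject_id == s]
    one(det$flag[det$subject_id == s], truth[idx], s)
  })
  out <- dplyr::bind_rows(c(rows, list(one(det$flag, truth[det$epoch_index], "(all)"))))
  class(out) <- c("detection_metrics", class(out))
  out
}

#' Expected performance of a size-matched random detector
#'
#' Simulates a detector that knows only the number of artifacts: in each
#' replicate it flags exactly `k` of `n` epochs uniformly at random (without
#' replacement) and is scored against a truth with `k` positives. Returns the
#' mean F-score and mean Cohen's kappa over replicates. The closed form for
#' the mean F is `k / n` (since `E[TP] = k^2 / n` and F reduces to `TP / k`).
#'
#' @param n number of epochs.
#' @param k number of artifact epochs (= number flagged per replicate).
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return A list `(expected_f, expected_kappa)`.
#' @export
random_baseline <- function(n, k, reps = 10000L, seed = 0L) {
  if (k > n) stop_param("k must be <= n")
  truth <- c(rep(TRUE, k), rep(FALSE, n - k))
  with_seed(seed, {
    fs <- numeric(reps); ks <- numeric(reps)
    for (r in seq_len(reps)) {
      pred <- logical(n)
      pred[sample.int(n, k)] <- TRUE
      fs[r] <- f_score(pred, truth)
      ks[r] <- cohens_kappa(pred, truth)
    }
    list(expected_f = mean(fs), expected_kappa = mean(ks))
  })
}

# Stratified fold assignment: balanced within each label, deterministic.
.stratified_folds <- function(labels, n_folds, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (l in unique(labels)) {
      idx <- which(labels == l)
      if (length(idx) < n_folds)
        stop_param(sprintf("label class %s has fewer members (%d) than folds (%d)",
                           l, length(idx), n_folds))
      folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  folds
}

# Design matrix for the probe: flattened down-sampled epochs, or the
# standardized 58-feature vectors.
.probe_design <- function(es, representation, target_fs) {
  if (representation == "features") {
    feature_matrix(standardize_features(extract_features(es, permissive = TRUE)))
  } else {
    ds <- if (target_fs < es$fs) resample_epochs(es, target_fs) else es
    matrix(ds$data, nrow = n_epochs(ds))
  }
}

#' Downstream classification probe
#'
#' Measures the effect of artifact correction on a real decoding task: for
#' every variant of the same epoch set (e.g. raw / corrected /
#' control-corrected), a linear max-margin classifier (SVM) is trained to
#' predict the condition label under stratified k-fold cross-validation.
#' Fold assignments are identical across variants so differences isolate the
#' data treatment.
#'
#' @param variants named list of [epoch_set()]s sharing epoch order and
#'   labels.
#' @param labels condition labels (default: taken from the first variant).
#' @param n_folds cross-validation folds (default 5).
#' @param seed fold-assignment seed.
#' @param representation `"downsampled"` (flattened epochs resampled to
#'   `target_fs`) or `"features"` (standardized 58-feature vectors).
#' @param target_fs resampling rate for the down-sampled representation.
#' @param cost SVM cost parameter.
#' @return A tibble of class `downstream_probe`: `variant`, `fold`,
#'   `accuracy`.
#' @export
downstream_probe <- function(variants, labels = NULL, n_folds = 5L, seed = 0L,
                             representation = c("downsampled", "features"),
                             target_fs = 25, cost = 1) {
  representation <- match.arg(representation)
  stopifnot(length(variants) >= 1L, !is.null(names(variants)))
  labels <- labels %||% variants[[1L]]$labels
  if (anyNA(labels)) stop_param("all epochs need condition labels for the probe")
  folds <- .stratified_folds(labels, n_folds, seed)
  y <- factor(labels)
  rows <- list()
  preds <- list()
  for (v in names(variants)) {
    X <- .probe_design(variants[[v]], representation, target_fs)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    acc <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      p <- stats::predict(fit, X[!tr, , drop = FALSE])
      pred[!tr] <<- p
      mean(p == y[!tr])
    }, 0)
    rows[[v]] <- tibble::tibble(variant = v, fold = seq_len(n_folds), accuracy = acc)
    preds[[v]] <- tibble::tibble(variant = v, epoch_index = seq_along(y),
                                 fold = folds, actual = y, predicted = pred)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("downstream_probe", class(out))
  attr(out, "representation") <- representation
  attr(out, "predictions") <- dplyr::bind_rows(preds)
  out
}

# ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy artifact_detection
#' @export
tidy.artifact_detection <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance artifact_detection
#' @export
glance.artifact_detection <- function(x, ...) {
  tibble::tibble(n_epochs = nrow(x), n_flagged = sum(x$flag),
                 contamination = attr(x, "contamination"),
                 method = attr(x, "method")$method, mode = attr(x, "mode"))
}

#' @method tidy interpolator_ensemble
#' @export
tidy.interpolator_ensemble <- function(x, ...) {
  tibble::tibble(offset = seq_len(x$G) - 1L, final_loss = x$final_loss)
}

#' @method glance interpolator_ensemble
#' @export
glance.interpolator_ensemble <- function(x, ...) {
  tibble::tibble(G = x$G, h = x$h, n_channels = x$n_channels, fs = x$fs,
                 mean_final_loss = mean(x$final_loss))
}

#' @method tidy downstream_probe
#' @export
tidy.downstream_probe <- function(x, ...) tibble::as_tibble(unclass(x))

#' @method glance downstream_probe
#' @export
glance.downstream_probe <- function(x, ...) {
  dplyr::summarise(tibble::as_tibble(unclass(x)),
                   mean_accuracy = mean(.data$accuracy),
                   sd_accuracy = stats::sd(.data$accuracy),
                   .by = "variant")
}

#' @method glance detection_metrics
#' @export
glance.detection_metrics <- function(x, ...) {
  dplyr::filter(tibble::as_tibble(unclass(x)), .data$subject_id == "(all)")
}
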