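#' Percentile vector of a distance sample
#'
#' The `m` values separating the percentiles of an empirical distribution,
#' by the nearest-rank estimator: component `i` is the sorted sample value
#' at rank `ceiling(i * n / m)`, so at least `i/m` of the sample is less
#' than or equal to it. With the default `m = 100` this is the vector of
#' 100 non-decreasing threshold levels used for both the target (`alpha`)
#' and the predictor (`beta`) distances.
#'
#' @param values Non-empty numeric vector.
#' @param m Number of levels (default 100).
#' @return A non-decreasing numeric vector of length `m`.
#' @export
percentile_vector <- function(values, m = 100) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) stop("percentile_vector: empty input")
  # ranks via exact integer products (i*n <= 2^53), no floating-point fuzz
  unname(sort(values)[ceiling(seq_len(m) * n / m)])
}

#' Confusion counts of a threshold prediction
#'
#' Applies the threshold rule "target predicted <= `alpha` iff predictor
#' <= `beta`" to a pair sample and counts true positives (target <= alpha
#' and predictor <= beta), false negatives, true negatives and false
#' positives.
#'
#' @param pairs A `pair_sample` or a pair data frame with the two distance
#'   columns populated.
#' @param target,predictor Distance column names (`"bt"`, `"nw"`, `"bl"`,
#'   `"af"`).
#' @param alpha Threshold on the target distance.
#' @param beta Threshold on the predictor distance.
#' @return A named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_at <- function(pairs, target, predictor, alpha, beta) {
  d <- pair_distance_columns(pairs, target, predictor)
  confusion_counts(d$d1, d$d2, alpha, beta)
}

pair_distance_columns <- function(pairs, target, predictor) {
  if (inherits(pairs, "pair_sample")) pairs <- pairs$pairs
  for (col in c(target, predictor)) {
    if (is.null(pairs[[col]])) stop("unknown distance column '", col, "'")
    if (anyNA(pairs[[col]])) {
      bad <- which(is.na(pairs[[col]]))
      stop("distance '", col, "' missing for ", length(bad),
           " pair(s), e.g. (", pairs$id1[bad[1]], ", ", pairs$id2[bad[1]],
           ")")
    }
  }
  list(d1 = pairs[[target]], d2 = pairs[[predictor]])
}

confusion_counts <- function(d1, d2, alpha, beta) {
  pos <- d1 <= alpha
  pred <- d2 <= beta
  c(tp = sum(pos & pred), fp = sum(!pos & pred),
    tn = sum(!pos & !pred), fn = sum(pos & !pred))
}

# TPR/FPR at every candidate beta in one pass: sort the predictor values of
# each class once, then count values <= beta by binary search.
rates_over_betas <- function(d1, d2, alpha, betas) {
  pos <- d1 <= alpha
  n_pos <- sum(pos); n_neg <- sum(!pos)
  tp <- findInterval(betas, sort(d2[pos]))
  fp <- findInterval(betas, sort(d2[!pos]))
  # an empty positive class leaves TPR undefined; with no negatives there
  # are no false positives at any threshold, so FPR is identically 0
  list(tpr = if (n_pos > 0) tp / n_pos else rep(NA_real_, length(betas)),
       fpr = if (n_neg > 0) fp / n_neg else rep(0, length(betas)),
       n_pos = n_pos, n_neg = n_neg)
}

#' ROC curve of a threshold predictor at one target level
#'
#' For a fixed target threshold `alpha`, sweeps the predictor threshold over
#' `candidate_betas`, plotting the true positive rate against the false
#' positive rate; the anchors (0,0) and (1,1) are appended and the area
#' under the curve is computed by the trapezoidal rule after sorting the
#' points by FPR (ties on FPR sorted by TPR). With every distinct predictor
#' value offered as a candidate, this area equals the Mann-Whitney
#' statistic.
#'
#' @inheritParams confusion_at
#' @param candidate_betas Non-empty vector of predictor thresholds.
#' @return A list with `level` (alpha), `points` (data frame `beta`, `fpr`,
#'   `tpr`, anchors have `beta = NA`) and `auc`.
#' @export
roc_curve <- function(pairs, target, predictor, alpha, candidate_betas) {
  if (length(candidate_betas) == 0L) stop("candidate_betas is empty")
  if (is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0,1], got ", alpha)
  }
  d <- pair_distance_columns(pairs, target, predictor)
  r <- rates_over_betas(d$d1, d$d2, alpha, candidate_betas)
  points <- data.frame(beta = c(NA, candidate_betas, NA),
                       fpr = c(0, r$fpr, 1), tpr = c(0, r$tpr, 1))
  list(level = alpha, points = points, auc = trapezoid_auc(points))
}

trapezoid_auc <- function(points) {
  if (anyNA(points$fpr) || anyNA(points$tpr)) return(NA_real_)
  # ties on fpr sort by tpr; vertical runs then contribute zero width, so
  # the trapezoid sum reproduces the staircase area (= Mann-Whitney)
  ord <- order(points$fpr, points$tpr)
  fpr <- points$fpr[ord]; tpr <- points$tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Train a percentile threshold predictor
#'
#' Builds the mapping `m(alpha_i) = beta_i` over `m` percentile levels of
#' the target distance: `alpha` is the percentile vector of the target,
#' the candidate `beta` values are the percentile vector of the predictor,
#' and for each level the candidate maximizing the sum of true positive and
#' true negative rates is adopted (ties resolved toward the smallest
#' `beta`). The per-level AUC over the candidate set is stored. Because
#' both thresholds and candidates are percentile-based, training is
#' invariant under strictly increasing transforms of the predictor
#' distance.
#'
#' @inheritParams confusion_at
#' @param m Number of percentile levels (default 100).
#' @return A `threshold_predictor`: list with `target`, `predictor`,
#'   `alpha`, `beta`, `beta_index`, `auc` (all of length `m`) and `m`.
#' @export
train_predictor <- function(pairs, target = "bt", predictor = "af",
                            m = 100) {
  d <- pair_distance_columns(pairs, target, predictor)
  if (length(d$d1) < m) {
    stop("sample has ", length(d$d1), " pairs; need at least m = ", m)
  }
  if (min(d$d1) == max(d$d1)) {
    stop("degenerate target distance: all values equal ", d$d1[1])
  }
  alpha <- percentile_vector(d$d1, m)
  betas <- percentile_vector(d$d2, m)
  beta <- numeric(m); beta_index <- integer(m); auc <- numeric(m)
  for (i in seq_len(m)) {
    r <- rates_over_betas(d$d1, d$d2, alpha[i], betas)
    j <- which.max(ifelse(is.na(r$tpr), 0, r$tpr) +
                     ifelse(is.na(r$fpr), 1, 1 - r$fpr))
    beta_index[i] <- j
    beta[i] <- betas[j]
    auc[i] <- trapezoid_auc(data.frame(fpr = c(0, r$fpr, 1),
                                       tpr = c(0, r$tpr, 1)))
  }
  structure(list(target = target, predictor = predictor, alpha = alpha,
                 beta = beta, beta_index = beta_index, auc = auc, m = m),
            class = "threshold_predictor")
}

#' @export
print.threshold_predictor <- function(x, ...) {
  cat("threshold_predictor of '", x$target, "' by '", x$predictor,
      "' over ", x$m, " percentile levels\n", sep = "")
  cat("  per-level AUC: min ", round(min(x$auc, na.rm = TRUE), 3),
      ", median ", round(stats::median(x$auc, na.rm = TRUE), 3),
      ", max ", round(max(x$auc, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained predictor at one level on a test sample
#'
#' Applies the trained thresholds `(alpha_i, beta_i)` of level `level` to a
#' pair sample (normally one not used for training) and reports the
#' confusion counts and the true positive rate `tp / (tp + fn)` and true
#' negative rate `tn / (tn + fp)`. A rate whose class is empty is `NA`, not
#' 0.
#'
#' @param object A `threshold_predictor` from [train_predictor()].
#' @param pairs A `pair_sample` or pair data frame.
#' @param level Level index in `1..m`.
#' @return A list with `counts` (`tp`, `fp`, `tn`, `fn`), `tp_rate`,
#'   `tn_rate`.
#' @export
evaluate_level <- function(object, pairs, level) {
  stopifnot(inherits(object, "threshold_predictor"))
  if (level < 1 || level > object$m) {
    stop("level must be in 1..", object$m, ", got ", level)
  }
  counts <- confusion_at(pairs, object$target, object$predictor,
                         object$alpha[level], object$beta[level])
  list(counts = counts, tp_rate = rate_or_na(counts["tp"], counts["fn"]),
       tn_rate = rate_or_na(counts["tn"], counts["fp"]))
}

rate_or_na <- function(hit, miss) {
  n <- hit + miss
  if (n == 0) NA_real_ else unname(hit / n)
}

# map requested reference values of the target distance to trained levels
reference_levels <- function(alpha, reference_values) {
  vapply(reference_values, function(v) which.min(abs(alpha - v)), integer(1))
}

#' Cross-validate a threshold predictor over several pair samples
#'
#' Rotates the training role over the samples: for each fold the predictor
#' is trained on one sample and evaluated on all the others, pooling the
#' test samples' confusion counts per level. Rates are reported at the
#' levels whose trained `alpha` is nearest to each requested reference
#' value of the target distance, per fold and averaged across folds, with
#' the total precision `(tp + tn) / n`. Levels with an empty class give
#' `NA` rates and are excluded from averages.
#'
#' @param samples A list of at least two `pair_sample` objects with the two
#'   distances populated.
#' @inheritParams train_predictor
#' @param reference_values Target-distance values at which to report rates.
#' @return A list with `per_fold` (data frame: `fold`, `reference`,
#'   `level`, `alpha`, `beta`, `tp_pct`, `tn_pct`, `total_pct`) and
#'   `average` (per-reference means across folds).
#' @export
cross_validate <- function(samples, target = "bt", predictor = "af",
                           m = 100,
                           reference_values = c(0.105, 0.15, 0.205, 0.25)) {
  if (length(samples) < 2L) stop("cross-validation needs >= 2 samples")
  labels <- vapply(seq_along(samples), function(f) {
    if (inherits(samples[[f]], "pair_sample")) samples[[f]]$label
    else as.character(f)
  }, character(1))
  rows <- list()
  for (f in seq_along(samples)) {
    fit <- train_predictor(samples[[f]], target, predictor, m)
    lev <- reference_levels(fit$alpha, reference_values)
    test <- samples[-f]
    for (r in seq_along(reference_values)) {
      counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
      for (s in test) {
        d <- pair_distance_columns(s, target, predictor)
        counts <- counts + confusion_counts(d$d1, d$d2, fit$alpha[lev[r]],
                                            fit$beta[lev[r]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fold = labels[f], reference = reference_values[r], level = lev[r],
        alpha = fit$alpha[lev[r]], beta = fit$beta[lev[r]],
        tp_pct = 100 * rate_or_na(counts["tp"], counts["fn"]),
        tn_pct = 100 * rate_or_na(counts["tn"], counts["fp"]),
        total_pct = 100 * (counts["tp"] + counts["tn"]) / sum(counts),
        row.names = NULL)
    }
  }
  per_fold <- do.call(rbind, rows)
  na_levels <- sum(is.na(per_fold$tp_pct)) + sum(is.na(per_fold$tn_pct))
  if (na_levels > 0L) {
    message("cross_validate: ", na_levels,
            " undefined rate(s) (empty class) excluded from averages")
  }
  average <- do.call(rbind, lapply(split(per_fold, per_fold$reference),
    function(g) data.frame(reference = g$reference[1],
                           tp_pct = mean(g$tp_pct, na.rm = TRUE),
                           tn_pct = mean(g$tn_pct, na.rm = TRUE),
                           total_pct = mean(g$total_pct, na.rm = TRUE),
                           row.names = NULL)))
  list(per_fold = per_fold, average = average)
}

#' Pearson correlation matrix of the four pair distances
#'
#' @param pairs A `pair_sample` or pair data frame with all four distance
#'   columns populated.
#' @return A symmetric 4x4 correlation matrix with unit diagonal, rows and
#'   columns `bt`, `nw`, `bl`, `af`.
#' @export
pearson_matrix <- function(pairs) {
  if (inherits(pairs, "pair_sample")) pairs <- pairs$pairs
  cols <- c("bt", "nw", "bl", "af")
  x <- as.matrix(pairs[, cols])
  if (anyNA(x)) stop("pearson_matrix: missing distance values")
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance distance column '", cols[v == 0][1], "'")
  }
  stats::cor(x)
}
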