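#' Euclidean distance between two feature vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean <- function(x, y) {
  if (length(x) != length(y))
    abort("euclidean: vectors have different lengths")
  sqrt(sum((x - y)^2))
}

stage_labels <- list(motion = c("still", "active"),
                     audio = c("tv", "pc", "unknown"))

#' Labelled-instance memory for one classification stage
#'
#' The training store is the classifier: k-NN keeps every training
#' instance and classifies new feature vectors by their neighbours.
#' Stores are per stage so motion (6-dim) and audio (26-dim) features,
#' with their different units, never mix.
#'
#' @param features numeric matrix, one instance per row.
#' @param labels character vector of instance labels; must come from the
#'   stage's closed label set (`motion`: still/active; `audio`:
#'   tv/pc/unknown).
#' @param stage `"motion"` or `"audio"`.
#' @return A list of class `training_store` with `features`, `labels`,
#'   `stage`, `n` and `feature_length`. Insertion order (row order) is
#'   the distance tie-break.
#' @export
training_store <- function(features, labels, stage = c("motion", "audio")) {
  stage <- match.arg(stage)
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    abort("training_store: features rows and labels lengths differ")
  if (nrow(features) < 1L)
    abort("training_store: store needs at least one instance")
  bad <- setdiff(unique(labels), stage_labels[[stage]])
  if (length(bad))
    abort(sprintf("training_store: label(s) outside the %s set: %s",
                  stage, paste(bad, collapse = ", ")))
  structure(list(features = unname(features), labels = as.character(labels),
                 stage = stage, n = nrow(features),
                 feature_length = ncol(features)),
            class = "training_store")
}

#' @export
print.training_store <- function(x, ...) {
  cat(sprintf("<training_store[%s]: %d instances x %d features; %s>\n",
              x$stage, x$n, x$feature_length,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = " ")))
  invisible(x)
}

#' Classify a feature vector by its k nearest neighbours
#'
#' The k stored instances closest in Euclidean distance vote; the
#' majority label wins. A tie in the vote is broken by the single
#' nearest neighbour's label; a tie in distance is broken by lower
#' insertion index, so classification is deterministic and stable under
#' store order.
#'
#' @param cfv current feature vector (length must match the store).
#' @param store a [training_store()].
#' @param k number of neighbours (default 3); if the store holds fewer
#'   than `k` instances, all are used.
#' @return List with `label`, `neighbours` (insertion indices) and
#'   `distances`.
#' @export
knn_classify <- function(cfv, store, k = 3) {
  if (!inherits(store, "training_store") || store$n < 1L)
    abort("knn_classify: empty or invalid training store")
  if (length(cfv) != store$feature_length)
    abort("knn_classify: feature vector length does not match the store")
  if (k < 1) abort("knn_classify: k must be >= 1")
  d <- sqrt(colSums((t(store$features) - as.numeric(cfv))^2))
  ord <- order(d, seq_along(d))  # distance, then insertion index
  sel <- ord[seq_len(min(k, store$n))]
  votes <- table(store$labels[sel])
  top <- names(votes)[votes == max(votes)]
  label <- if (length(top) == 1L) top else {
    # vote tie: the nearest neighbour whose label is among the tied ones
    store$labels[sel][match(TRUE, store$labels[sel] %in% top)]
  }
  list(label = label, neighbours = sel, distances = d[sel])
}

#' Stratified train/validation/test split
#'
#' Mirrors the 60:10:30 evaluation protocol: within each label, instances
#' are shuffled under `seed` and cut at the cumulative ratios (floor for
#' the first two cuts, remainder to test), so the splits are disjoint,
#' exhaustive and reproducible. The validation part is held out but
#' unused for tuning (k is fixed at 3).
#'
#' @param labels character vector of instance labels.
#' @param ratios train/validation/test proportions summing to 1.
#' @param seed integer seed for the per-class shuffles.
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, ratios = c(0.6, 0.1, 0.3), seed = 1L) {
  if (abs(sum(ratios) - 1) > 1e-9)
    abort("split_dataset: ratios must sum to 1")
  counts <- table(labels)
  if (any(counts < 3))
    abort(sprintf("split_dataset: class(es) with < 3 instances: %s",
                  paste(names(counts)[counts < 3], collapse = ", ")))
  out <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (lab in sort(names(counts))) {
      idx <- sample(which(labels == lab))
      n <- length(idx)
      n_tr <- floor(ratios[1] * n)
      n_va <- floor(ratios[2] * n)
      out$train <- c(out$train, idx[seq_len(n_tr)])
      out$validation <- c(out$validation, idx[n_tr + seq_len(n_va)])
      out$test <- c(out$test, idx[(n_tr + n_va + 1):n])
    }
  })
  out
}

#' Accuracy and confusion matrix of a store on a test set
#'
#' @param store a [training_store()].
#' @param test_features numeric matrix of test instances (rows).
#' @param test_labels true labels of the test instances.
#' @param k neighbours per query (default 3).
#' @return List with `accuracy` and `confusion` (rows = true labels,
#'   columns = predicted, over the stage's full label set).
#' @export
evaluate_store <- function(store, test_features, test_labels, k = 3) {
  test_features <- as.matrix(test_features)
  if (!nrow(test_features)) abort("evaluate_store: empty test set")
  pred <- vapply(seq_len(nrow(test_features)), function(i)
    knn_classify(test_features[i, ], store, k)$label, character(1))
  lev <- stage_labels[[store$stage]]
  confusion <- table(true = factor(test_labels, lev),
                     predicted = factor(pred, lev))
  list(accuracy = mean(pred == test_labels), confusion = confusion)
}
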