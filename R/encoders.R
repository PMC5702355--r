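# Input encoders: the noisy two-class toy generator, latency encoding of
# feature vectors, and row/column encoding of grayscale images.

#' Generate the two-class toy spike-pattern dataset
#'
#' Three pre-synaptic neurons fire once each: at base times `baseA` ms
#' (default 1, 5, 13) for class A and `baseB` ms (default 13, 9, 1) for class
#' B, each time jittered by an independent uniform draw from
#' `[-jitter, +jitter]` and snapped to the grid. The two classes are the same
#' multiset of times in different spatial order, so they are separable only
#' through the temporal structure across neurons.
#'
#' @param nPerClass number of patterns per class.
#' @param baseA,baseB base spike times in ms, one per neuron.
#' @param jitter half-width of the uniform timing noise in ms.
#' @param grid a [TimeGrid-class].
#' @param seed optional integer seed.
#' @return A labelled [SpikeDataset-class] with `2 * nPerClass` patterns
#'   (class "A" first).
#' @examples
#' toy <- generateToyDataset(3, seed = 7)
#' patternLabels(toy)
#' @export
generateToyDataset <- function(nPerClass, baseA = c(1, 5, 13),
                               baseB = c(13, 9, 1), jitter = 1,
                               grid = timeGrid(), seed = NULL) {
  if (nPerClass < 1L) stop("'nPerClass' must be >= 1")
  if (length(baseA) != length(baseB))
    stop("'baseA' and 'baseB' must have the same length")
  if (!is.null(seed)) set.seed(seed)
  n <- length(baseA)
  make <- function(base) {
    spikePattern(seq_len(n),
                 pmax(base + stats::runif(n, -jitter, jitter), 0),
                 nNeurons = n, grid = grid)
  }
  pats <- c(replicate(nPerClass, make(baseA), simplify = FALSE),
            replicate(nPerClass, make(baseB), simplify = FALSE))
  spikeDataset(pats, labels = rep(c("A", "B"), each = nPerClass))
}

#' Latency-encoding ranges for a feature table
#'
#' Records the per-feature (min, max) used by [encodeFeatureVector()],
#' computed from the supplied data (typically the training split, so that
#' held-out data reuse the training normalization).
#'
#' @param data numeric matrix or data frame of feature columns.
#' @param tMax encoding ceiling in ms: the feature maximum maps to `tMax`.
#' @return List with elements `min`, `max` (per feature) and `tMax`.
#' @export
featureRanges <- function(data, tMax = 10) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("features must be numeric")
  rng <- list(min = apply(data, 2, min), max = apply(data, 2, max),
              tMax = as.numeric(tMax))
  if (any(rng$max <= rng$min))
    stop("each feature must have max > min")
  rng
}

#' Latency-encode a feature vector
#'
#' Maps each real-valued feature to a single first-spike time by affine
#' normalization: feature `k_i` with range `(min_i, max_i)` yields a spike of
#' neuron `i` at `tMax * (k_i - min_i) / (max_i - min_i)` ms, snapped to the
#' grid. The minimum maps to 0 ms and the maximum to `tMax` ms; the encoding
#' is order-preserving. Out-of-range values (possible on held-out data, since
#' ranges come from the training split) are clipped into range with a
#' warning.
#'
#' @param features numeric vector, one value per neuron.
#' @param ranges ranges from [featureRanges()].
#' @param grid a [TimeGrid-class].
#' @return A [SpikePattern-class] with exactly one spike per neuron.
#' @examples
#' rng <- list(min = 4.3, max = 7.9, tMax = 10)
#' patternEvents(encodeFeatureVector(6.1, rng))   # 10 * (6.1-4.3)/3.6 = 5 ms
#' @export
encodeFeatureVector <- function(features, ranges, grid = timeGrid()) {
  if (any(!is.finite(features))) stop("features must be finite")
  if (length(features) != length(ranges$min))
    stop("feature count must match the ranges")
  if (ranges$tMax > grid@period)
    stop("'tMax' exceeds the experimental period")
  out <- (features < ranges$min) | (features > ranges$max)
  if (any(out)) {
    warning(sum(out), " feature value(s) outside the encoding range; clipped")
    features <- pmin(pmax(features, ranges$min), ranges$max)
  }
  s <- ranges$tMax * (features - ranges$min) / (ranges$max - ranges$min)
  spikePattern(seq_along(features), s, nNeurons = length(features), grid = grid)
}

#' Latency-encode a feature table
#'
#' @param data data frame (or matrix) of numeric feature columns, optionally
#'   with a label column.
#' @param ranges ranges from [featureRanges()]; computed from `data` itself
#'   when `NULL`.
#' @param labelColumn name of the label column, if present.
#' @param tMax encoding ceiling in ms (used only when `ranges` is `NULL`).
#' @param grid a [TimeGrid-class].
#' @return A [SpikeDataset-class].
#' @export
encodeFeatureTable <- function(data, ranges = NULL, labelColumn = "label",
                               tMax = 10, grid = timeGrid()) {
  data <- as.data.frame(data)
  labels <- character()
  if (labelColumn %in% names(data)) {
    labels <- as.character(data[[labelColumn]])
    data <- data[setdiff(names(data), labelColumn)]
  }
  feats <- as.matrix(data)
  if (is.null(ranges)) ranges <- featureRanges(feats, tMax)
  pats <- lapply(seq_len(nrow(feats)), function(r)
    encodeFeatureVector(feats[r, ], ranges, grid))
  spikeDataset(pats, labels = labels)
}

#' Encode a grayscale image as a spike pattern
#'
#' Rows become pre-synaptic neurons and columns become spike times: neuron
#' `i` fires at `(j - 1) * msPerColumn` ms for every column `j` whose pixel
#' `(i, j)` exceeds `threshold`. A neuron may therefore fire many times, and
#' an all-background image yields an empty pattern.
#'
#' @param image numeric matrix of intensities in `[0, 1]`, rows = neurons.
#' @param threshold intensity above which a pixel produces a spike.
#' @param msPerColumn time between adjacent columns in ms.
#' @param grid a [TimeGrid-class].
#' @return A [SpikePattern-class] with `nrow(image)` neurons.
#' @export
encodeImage <- function(image, threshold = 0.5, msPerColumn = 1,
                        grid = timeGrid()) {
  image <- as.matrix(image)
  if ((ncol(image) - 1) * msPerColumn >= grid@period)
    stop("image is wider than the experimental period allows")
  hit <- which(image > threshold, arr.ind = TRUE)
  spikePattern(hit[, 1], (hit[, 2] - 1) * msPerColumn,
               nNeurons = nrow(image), grid = grid)
}
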