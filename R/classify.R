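# Quantile decision boundaries over post-synaptic spike timing, majority
# voting for the Bernoulli readout, and the unsupervised accuracy metric.

#' Timing summary of a post-synaptic train
#'
#' Reduces a train to weighted timing votes. The Multinoulli readout yields
#' its single spike with weight 1. A Bernoulli train distributes a total
#' weight of 1 over its spikes (each weighted by the inverse spike count), so
#' patterns with bursts do not dominate the pooled timing distribution. A
#' silent Bernoulli train is recorded as an exceptionally late spike at
#' `period - delta` with weight 1.
#'
#' @param post a [SpikeTrain-class].
#' @param grid the [TimeGrid-class] (used for the silent-train sentinel).
#' @return `data.frame(time, weight)`; weights sum to 1.
#' @export
timingSummary <- function(post, grid = timeGrid()) {
  k <- length(post@times)
  if (k == 0L)
    return(data.frame(time = grid@period - grid@delta, weight = 1))
  data.frame(time = post@times, weight = rep(1 / k, k))
}

#' Fit quantile decision boundaries
#'
#' Pools the (time, weight) pairs of all summaries and places the `n / nGroups`
#' (n = 1, ..., nGroups - 1) weighted quantiles of the pooled empirical timing
#' distribution as thresholds. The quantile is of the inverted-CDF kind: the
#' lowest pooled time whose cumulative weight reaches `n / nGroups`, with ties
#' in timing kept in stable input order. On a balanced two-class set of
#' unit-weight timings the single threshold is the median and splits the
#' sorted timings in half.
#'
#' @param summaries list of timing summaries (see [timingSummary()]).
#' @param nGroups number of groups (>= 2).
#' @return A [DecisionBoundaries-class].
#' @export
fitBoundaries <- function(summaries, nGroups) {
  nGroups <- as.integer(nGroups)
  if (nGroups < 2L) stop("'nGroups' must be >= 2")
  if (length(summaries) < nGroups)
    stop("need at least 'nGroups' patterns to fit boundaries")
  pooled <- do.call(rbind, summaries)
  ord <- order(pooled$time)            # stable: ties keep input order
  tt <- pooled$time[ord]
  cw <- cumsum(pooled$weight[ord]) / sum(pooled$weight)
  thr <- vapply(seq_len(nGroups - 1L), function(n) {
    tt[which(cw >= n / nGroups - 1e-12)[1]]
  }, numeric(1))
  new("DecisionBoundaries", nGroups = nGroups, thresholds = thr)
}

#' Assign a pattern to a group
#'
#' Each (time, weight) vote of the summary falls in the interval that
#' contains its time -- a time exactly equal to a threshold belongs to the
#' lower group -- and the group collecting the largest total weight wins
#' (ties to the earlier group). For the single-spike Multinoulli readout this
#' reduces to an interval lookup.
#'
#' @param summary a timing summary (see [timingSummary()]).
#' @param boundaries a fitted [DecisionBoundaries-class].
#' @return Integer group index in `[1, nGroups]`.
#' @export
assignGroup <- function(summary, boundaries) {
  thr <- boundaries@thresholds
  g <- vapply(summary$time, function(tm) sum(thr < tm), numeric(1)) + 1L
  votes <- numeric(boundaries@nGroups)
  for (r in seq_along(g)) votes[g[r]] <- votes[g[r]] + summary$weight[r]
  which.max(votes)
}

# all permutations of a vector (small n only)
.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(.perms(v[-i]), function(p) c(v[i], p)))
  out
}

#' Best group-to-class mapping
#'
#' The timing groups of an unsupervised run carry no class identity, so
#' accuracy is measured under the injective group-to-class assignment that
#' maximizes agreement with the true labels. Intended to be computed on the
#' training split and frozen for test evaluation.
#'
#' @param assigned integer group indices.
#' @param labels true class labels (same length).
#' @param nGroups number of groups; default `max(assigned)`.
#' @return Character vector: `mapping[g]` is the class label assigned to
#'   group `g`.
#' @export
bestGroupMapping <- function(assigned, labels, nGroups = max(assigned)) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (nGroups > length(classes))
    stop("more groups (", nGroups, ") than classes (", length(classes), ")")
  best <- NULL
  bestAcc <- -1
  for (sel in .injections(classes, nGroups)) {
    acc <- mean(sel[assigned] == labels)
    if (acc > bestAcc) {
      bestAcc <- acc
      best <- sel
    }
  }
  best
}

# all injective assignments of k out of the given classes (ordered)
.injections <- function(classes, k) {
  if (k == length(classes)) return(.perms(classes))
  sets <- utils::combn(classes, k, simplify = FALSE)
  do.call(c, lapply(sets, .perms))
}

#' Permutation-maximized clustering accuracy
#'
#' Fraction of patterns whose mapped group label matches the true class,
#' under `mapping` if given, otherwise under the best mapping for these very
#' labels (see [bestGroupMapping()]); the latter is never below `1 / nGroups`
#' on balanced data and equals `max(a, 1 - a)` for two classes.
#'
#' @param assigned integer group indices.
#' @param labels true class labels.
#' @param mapping optional frozen mapping from [bestGroupMapping()].
#' @param nGroups number of groups; default `max(assigned)`.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
clusteringAccuracy <- function(assigned, labels, mapping = NULL,
                               nGroups = max(assigned)) {
  if (length(assigned) != length(labels))
    stop("'assigned' and 'labels' must have the same length")
  labels <- as.character(labels)
  if (is.null(mapping))
    mapping <- bestGroupMapping(assigned, labels, nGroups)
  mean(mapping[assigned] == labels)
}

#' Classify datasets with a trained model
#'
#' Runs the full unsupervised read-out pipeline: sample one post-synaptic
#' train per pattern, reduce to timing summaries, fit the quantile decision
#' boundaries and the best group-to-class mapping on the training split, and
#' evaluate train (and optionally test) accuracy with boundaries and mapping
#' frozen. Sampling uses the current RNG state.
#'
#' @param model a trained [DelaySNN-class].
#' @param train labelled training [SpikeDataset-class].
#' @param test optional labelled held-out [SpikeDataset-class].
#' @param nGroups number of groups; default = number of training classes.
#' @return List with elements `trainAccuracy`, `testAccuracy` (NA if no test
#'   set), `boundaries`, `mapping`, `trainAssigned`, `testAssigned`.
#' @export
evaluateModel <- function(model, train, test = NULL, nGroups = NULL) {
  labels <- patternLabels(train)
  if (!length(labels)) stop("the training dataset must be labelled")
  if (is.null(nGroups)) nGroups <- length(unique(labels))
  sampler <- if (model@kind == "mb") mbSampleSpike else bbSampleSpikes
  summarize <- function(ds) lapply(ds@patterns, function(p)
    timingSummary(sampler(p, model), model@grid))
  trainSum <- summarize(train)
  boundaries <- fitBoundaries(trainSum, nGroups)
  trainAssigned <- vapply(trainSum, assignGroup, integer(1), boundaries)
  mapping <- bestGroupMapping(trainAssigned, labels, nGroups)
  out <- list(
    trainAccuracy = clusteringAccuracy(trainAssigned, labels, mapping),
    testAccuracy = NA_real_, boundaries = boundaries, mapping = mapping,
    trainAssigned = trainAssigned, testAssigned = integer())
  if (!is.null(test)) {
    testSum <- summarize(test)
    testAssigned <- vapply(testSum, assignGroup, integer(1), boundaries)
    out$testAccuracy <- clusteringAccuracy(testAssigned, patternLabels(test),
                                           mapping)
    out$testAssigned <- testAssigned
  }
  out
}
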