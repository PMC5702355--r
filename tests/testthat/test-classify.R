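# Quantile boundaries, weighted voting, permutation-maximized accuracy.

test_that("timing summaries carry unit total weight and the silent sentinel", {
  g <- timeGrid()
  s4 <- timingSummary(spikeTrain(c(10, 11, 12, 13), "bb"), g)
  expect_equal(s4$weight, rep(0.25, 4))
  expect_equal(sum(s4$weight), 1)
  s1 <- timingSummary(spikeTrain(12.3, "mb"), g)
  expect_equal(s1, data.frame(time = 12.3, weight = 1))
  # silent Bernoulli train counts as an exceptionally late spike
  s0 <- timingSummary(spikeTrain(numeric(), "bb"), g)
  expect_equal(s0, data.frame(time = 49.95, weight = 1))
})

test_that("two-group boundary is the median and splits a balanced set 50/50", {
  set.seed(91)
  times <- sample(seq(1, 40, by = 0.05), 100)
  sums <- lapply(times, function(t) data.frame(time = t, weight = 1))
  b <- fitBoundaries(sums, 2)
  expect_equal(b@thresholds, sort(times)[50])
  groups <- vapply(sums, assignGroup, integer(1), b)
  expect_equal(sum(groups == 1L), 50)
  expect_equal(sum(groups == 2L), 50)
})

test_that("three-group boundaries are the 1/3 and 2/3 quantiles", {
  sums <- lapply(1:9, function(t) data.frame(time = t, weight = 1))
  b <- fitBoundaries(sums, 3)
  expect_equal(b@thresholds, c(3, 6))
  expect_equal(vapply(sums, assignGroup, integer(1), b),
               rep(1:3, each = 3))
})

test_that("degenerate and invalid boundary fits behave as specified", {
  same <- lapply(1:10, function(i) data.frame(time = 5, weight = 1))
  b <- fitBoundaries(same, 2)
  expect_equal(b@thresholds, 5)
  # a time equal to the threshold falls in the lower group
  expect_identical(assignGroup(data.frame(time = 5, weight = 1), b), 1L)
  expect_error(fitBoundaries(same, 1), ">= 2")
  expect_error(fitBoundaries(same[1], 2), "at least")
})

test_that("weighted majority voting matches a brute-force tally", {
  b <- new("DecisionBoundaries", nGroups = 3L, thresholds = c(10, 20))
  s <- data.frame(time = c(5, 15, 16, 25), weight = c(0.25, 0.25, 0.25, 0.25))
  expect_identical(assignGroup(s, b), 2L)
  s2 <- data.frame(time = c(5, 25), weight = c(0.75, 0.25))
  expect_identical(assignGroup(s2, new("DecisionBoundaries", nGroups = 2L,
                                       thresholds = 10)), 1L)
  set.seed(101)
  for (rep in 1:1000) {
    k <- sample(1:5, 1)
    s <- data.frame(time = runif(k, 0, 30), weight = rep(1 / k, k))
    got <- assignGroup(s, b)
    tally <- c(sum(s$weight[s$time <= 10]),
               sum(s$weight[s$time > 10 & s$time <= 20]),
               sum(s$weight[s$time > 20]))
    expect_identical(got, which.max(tally))
  }
})

test_that("clustering accuracy is invariant to group relabelling", {
  labels <- rep(c("A", "B"), each = 10)
  swapped <- rep(c(2L, 1L), each = 10)
  expect_equal(clusteringAccuracy(swapped, labels), 1)
  expect_equal(clusteringAccuracy(rep(c(1L, 2L), each = 10), labels), 1)
  lab3 <- rep(c("a", "b", "c"), each = 5)
  expect_equal(clusteringAccuracy(rep(1:3, each = 5), lab3), 1)
  expect_error(clusteringAccuracy(rep(1:3, each = 5), rep("a", 15)), "classes")
  expect_error(clusteringAccuracy(1:3, c("a", "b")), "length")
})

test_that("random assignment of two balanced classes scores about one half", {
  set.seed(111)
  n <- 1e4
  labels <- rep(c("A", "B"), each = n / 2)
  assigned <- sample(1:2, n, replace = TRUE)
  acc <- clusteringAccuracy(assigned, labels)
  expect_gte(acc, 0.5)          # permutation maximization can only help
  expect_lt(acc, 0.53)
  # frozen mapping on new data can do worse than the refitted optimum
  mapping <- bestGroupMapping(assigned, labels)
  expect_equal(clusteringAccuracy(assigned, labels, mapping), acc)
})

test_that("quantile group sizes are reproduced up to boundary ties", {
  set.seed(121)
  sums <- lapply(runif(90, 0, 45), function(t) data.frame(time = t, weight = 1))
  for (nG in 2:3) {
    b <- fitBoundaries(sums, nG)
    groups <- vapply(sums, assignGroup, integer(1), b)
    expect_true(all(abs(tabulate(groups, nG) - 90 / nG) <= 1))
  }
})

test_that("evaluateModel freezes boundaries and mapping for the test split", {
  set.seed(131)
  toy <- generateToyDataset(15)
  test <- generateToyDataset(15)
  m <- delaySNN(3)
  res <- evaluateModel(m, toy, test)
  expect_true(res$trainAccuracy >= 0.5)   # two balanced classes
  expect_true(res$testAccuracy >= 0 && res$testAccuracy <= 1)
  expect_s4_class(res$boundaries, "DecisionBoundaries")
  expect_length(res$mapping, 2)
  expect_error(evaluateModel(m, generateToyDataset(3)[0]), "label")
})
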