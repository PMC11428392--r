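test_that("the default hand topology matches its stated structure", {
  t <- defaultHandTopology()
  expect_equal(length(t), 37L)
  expect_equal(length(globalSet(t)), 12L)
  expect_setequal(globalSet(t), c(2, 6, 14:18, 21, 25, 29, 33, 37))
  expect_true(validateTopology(t)$connected)
  # a global landmark reaches every other landmark's extended neighborhood
  for (i in setdiff(1:37, 6)) expect_true(6 %in% extendedNeighborhood(t, i))
  # no self-messages
  for (i in 1:37) expect_false(i %in% extendedNeighborhood(t, i))
  # message pairs enumerate exactly the extended neighborhoods
  mp <- messagePairs(t)
  expect_equal(nrow(mp), sum(vapply(1:37, function(i)
    length(extendedNeighborhood(t, i)), integer(1))))
})

test_that("finger grouping covers the 24 occludable joints", {
  g <- fingerGrouping()
  expect_equal(length(g), 5L)
  expect_equal(length(g$thumb), 4L)
  all24 <- unlist(g)
  expect_equal(length(all24), 24L)
  expect_equal(anyDuplicated(all24), 0L)
})

test_that("topology files round-trip and are validated", {
  t <- defaultHandTopology()
  f <- tempfile(fileext = ".txt")
  writeTopology(t, f)
  back <- readTopology(f)
  expect_equal(back@edges, t@edges)
  expect_equal(back@globalSet, t@globalSet)
  expect_equal(back@nLandmarks, t@nLandmarks)
  # duplicate edges collapse to one
  writeLines(c("n: 6", "2 6", "2 6", "1 2"), f)
  t2 <- readTopology(f)
  expect_equal(nrow(t2@edges), 2)
  # out-of-range index
  writeLines(c("n: 37", "0 99"), f)
  expect_error(readTopology(f), "range")
  # malformed line is reported with its number
  writeLines(c("1 2", "not an edge"), f)
  expect_error(readTopology(f), "line 2")
})

test_that("JSON topology conversion preserves the graph", {
  t <- defaultHandTopology()
  f <- tempfile(fileext = ".json")
  writeTopologyJSON(t, f)
  back <- readTopologyJSON(f)
  expect_equal(back@edges, t@edges)
  expect_equal(back@globalSet, t@globalSet)
})
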