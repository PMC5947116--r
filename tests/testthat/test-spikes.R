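# The cluster rule and P_C, on hand-evaluable spike trains.

test_that("the worked partition example is reproduced", {
  tr <- spike_train(c(1000, 1100, 1200, 1600), t_start = 0, t_end = 2000)
  part <- partition_clusters(tr)
  expect_length(part$clusters, 1)
  expect_equal(part$clusters[[1]], 1:3)
  expect_equal(part$unclustered, 4L)
  expect_equal(part$pc, 0.75)
})

test_that("tonic firing with short ISIs is a single cluster with P_C = 1", {
  tr <- train_from_isis(rep(150, 120), t0 = 500, t_end = 20000)
  part <- partition_clusters(tr)
  expect_length(part$clusters, 1)
  expect_equal(part$pc, 1)
  expect_equal(part$spikes_per_cluster, 121L)
})

test_that("gaps in [250, 300] neither chain nor count as quiescence", {
  tr <- train_from_isis(rep(270, 20))
  part <- partition_clusters(tr)
  expect_length(part$clusters, 0)
  expect_equal(part$pc, 0)
  # runs flanked by such a gap fail the quiescence condition
  tr2 <- train_from_isis(c(100, 100, 270, 100, 100), t0 = 1000, t_end = 3000)
  part2 <- partition_clusters(tr2)
  expect_length(part2$clusters, 0)
  expect_equal(part2$pc, 0)
})

test_that("boundary strictness: ISI < 250 chains, gaps > 300 quiesce", {
  # internal ISI exactly 250 breaks the chain
  a <- partition_clusters(train_from_isis(c(100, 250, 100), t0 = 1000,
                                          t_end = 3000))
  expect_length(a$clusters, 0)
  # flanking gap exactly 300 is not quiescence
  b <- partition_clusters(train_from_isis(c(300, 100, 100, 300), t0 = 1000,
                                          t_end = 3000))
  expect_length(b$clusters, 0)
  # just inside both bounds
  d <- partition_clusters(train_from_isis(c(301, 100, 249, 301), t0 = 1000,
                                          t_end = 3000))
  expect_length(d$clusters, 1)
  expect_equal(d$spikes_per_cluster, 3L)
})

test_that("degenerate trains: empty is undefined, a single spike has P_C 0", {
  expect_true(is.nan(partition_clusters(spike_train(numeric(0), 0, 1000))$pc))
  expect_equal(partition_clusters(spike_train(500, 0, 1000))$pc, 0)
})

test_that("every spike is assigned exactly once", {
  set.seed(31)
  for (rep in 1:20) {
    isis <- sample(c(50, 120, 260, 280, 400, 800), 40, replace = TRUE)
    part <- partition_clusters(train_from_isis(isis))
    got <- sort(c(unlist(part$clusters), part$unclustered))
    expect_identical(got, seq_len(part$n_spikes))
    expect_true(is.nan(part$pc) || (part$pc >= 0 && part$pc <= 1))
  }
})

test_that("P_C is invariant under time translation and recording padding", {
  isis <- c(100, 120, 500, 90, 80, 400, 1000, 60)
  a <- partition_clusters(train_from_isis(isis, t0 = 400))
  ts <- 400 + cumsum(c(0, isis))
  b <- partition_clusters(spike_train(ts + 5000, 0, max(ts) + 6000))
  d <- partition_clusters(spike_train(ts, -10000, max(ts) + 50000))
  expect_equal(a$pc, b$pc)
  expect_equal(a$pc, d$pc)
  expect_equal(a$spikes_per_cluster, d$spikes_per_cluster)
})

test_that("dilating all gaps beyond quiescence yields P_C = 0", {
  isis <- c(100, 120, 500, 90, 80, 400)
  part <- partition_clusters(train_from_isis(isis * 10))
  expect_length(part$clusters, 0)
  expect_equal(part$pc, 0)
})

test_that("mean_pc aggregates over defined values only", {
  t1 <- train_from_isis(rep(150, 30), t_end = 10000) # pc 1
  t2 <- train_from_isis(c(100, 100, 400, 400, 100), t0 = 1000, t_end = 10000)
  p2 <- partition_clusters(t2)$pc
  empty <- spike_train(numeric(0), 0, 10000)
  m <- mean_pc(list(t1, t2, empty))
  expect_equal(m$mean, (1 + p2) / 2)
  expect_equal(m$n, 2)
  expect_equal(m$n_undefined, 1)
  # trivial two-value mean
  m2 <- mean_pc(list(t1, t1))
  expect_equal(m2$mean, 1)
  expect_equal(m2$se, 0)
})

test_that("deterministic regime classification covers the label set", {
  expect_equal(classify_deterministic(spike_train(numeric(0), 0, 1000)), "SS")
  expect_equal(classify_deterministic(train_from_isis(rep(200, 40))), "T")
  burst3 <- train_from_isis(rep(c(150, 160, 900), 8))
  expect_equal(classify_deterministic(burst3), "3")
  doublet <- train_from_isis(rep(c(180, 700), 10))
  expect_equal(classify_deterministic(doublet), "2")
  irregular <- train_from_isis(rep(c(150, 160, 900, 150, 900), 6))
  expect_equal(classify_deterministic(irregular), "C")
  expect_equal(classify_deterministic(train_from_isis(rep(200, 5))),
               "inconclusive")
})
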