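make_assignment <- function(rows, chans = c("chA", "chB")) {
  matrix(rows, ncol = length(chans), byrow = TRUE,
         dimnames = list(NULL, chans))
}

test_that("the sort decision matches full/partial/none set logic", {
  cl <- sort_cluster(c(chA = 0, chB = 1))
  a <- make_assignment(c(0, 1,   # full
                         0, 0,   # partial (chA only)
                         2, 1,   # partial (chB only)
                         2, 2))  # none
  expect_equal(as.character(decide(a, cl)),
               c("full", "partial", "partial", "none"))
  # brute-force oracle over random assignments
  set.seed(51)
  r <- matrix(sample(0:3, 1000 * 2, replace = TRUE), 1000, 2,
              dimnames = list(NULL, c("chA", "chB")))
  got <- decide(r, cl)
  hits <- (r[, "chA"] == 0) + (r[, "chB"] == 1)
  oracle <- c("none", "partial", "full")[hits + 1]
  expect_identical(as.character(got), oracle)
  # categories partition the events
  expect_equal(sum(table(got)), 1000)
  expect_error(decide(make_assignment(c(0, 1), c("chA", "chC")), cl),
               "no assignment for channel")
})

test_that("a lone target is sorted with purity and yield 1", {
  cl <- sort_cluster(c(chA = 0))
  out <- run_sort(0.5, matrix(0L, 1, 1, dimnames = list(NULL, "chA")), cl,
                  labels = "tgt")
  expect_identical(out$sorted, 0L)
  expect_length(out$co_sorted, 0)
  expect_length(out$dropped, 0)
  expect_equal(out$purity[["tgt"]], 1)
  expect_equal(out$yield, 1)
})

test_that("coincident neighbours are co-sorted; distant ones are not", {
  # hand-timed trace, default timing: trigger at t engages [t+200, t+600] us;
  # events arrive at the sort point at trigger + 300 us.
  cl <- sort_cluster(c(chA = 0))
  tm <- timing_config()
  a <- matrix(c(0L, 1L), 2, 1, dimnames = list(NULL, "chA"))
  # neighbour 100 us later: arrival 400 us after the target trigger -> inside
  out <- run_sort(c(0, 100e-6), a, cl, tm, labels = c("tgt", "other"))
  expect_identical(sort(c(out$sorted, out$co_sorted)), 0:1)
  expect_equal(unname(out$purity[c("tgt", "other")]), c(0.5, 0.5))
  # neighbour 400 us later: arrival 700 us -> after disengage onset, clear
  out2 <- run_sort(c(0, 400e-6), a, cl, tm, labels = c("tgt", "other"))
  expect_identical(out2$sorted, 0L)
  expect_length(out2$co_sorted, 0)
  # with deflection during the falling ramp enabled it is caught again
  tm2 <- timing_config(deflect_during_disengage = TRUE)
  out3 <- run_sort(c(0, 400e-6), a, cl, tm2, labels = c("tgt", "other"))
  expect_identical(out3$co_sorted, 1L)
  # a neighbour arriving before the tube engages (trigger 150 us before the
  # target: arrival at -150+300 = 150 us < 200 us) passes through
  a3 <- matrix(c(1L, 0L), 2, 1, dimnames = list(NULL, "chA"))
  out4 <- run_sort(c(0, 150e-6), a3, cl, tm, labels = c("other", "tgt"))
  expect_identical(out4$sorted, 1L)
  expect_length(out4$co_sorted, 0)
})

test_that("triggers during the refractory window are dropped, not queued", {
  cl <- sort_cluster(c(chA = 0))
  tm <- timing_config(refractory = 1e-3)
  a <- matrix(0L, 3, 1, dimnames = list(NULL, "chA"))
  out <- run_sort(c(0, 0.5e-3, 1.5e-3), a, cl, tm, labels = rep("t", 3))
  expect_identical(out$dropped, 1L)        # the 0.5 ms trigger
  expect_identical(out$sorted, c(0L, 2L))  # 0 and 1.5 ms both cycle
  expect_equal(out$n_cycles, 2)
  # no event is both sorted and dropped; categories are disjoint
  expect_length(intersect(out$sorted, out$dropped), 0)
  expect_error(run_sort(c(1, 0.5), a[1:2, , drop = FALSE], cl),
               "strictly increasing")
})

test_that("saturated triggering converges to the 1/refractory cycle rate", {
  cl <- sort_cluster(c(chA = 0))
  tm <- timing_config()
  set.seed(53)
  # Poisson stream at 50,000 full matches/s (the electronics' decision
  # throughput) for ~1 s
  ts <- cumsum(stats::rexp(50000, 5e4))
  a <- matrix(0L, length(ts), 1, dimnames = list(NULL, "chA"))
  out <- run_sort(ts, a, cl, tm)
  rate <- out$n_cycles / max(ts)
  expect_lt(abs(rate - 1 / tm$refractory) / (1 / tm$refractory), 0.02)
  expect_equal(1 / tm$refractory, 300)
})

test_that("decision logic is rate-independent", {
  cl <- sort_cluster(c(chA = 0, chB = 1))
  set.seed(54)
  a <- matrix(sample(0:2, 200, replace = TRUE), 100, 2,
              dimnames = list(NULL, c("chA", "chB")))
  slow <- run_sort(sort(stats::runif(100, 0, 100)), a, cl)
  fast <- run_sort(sort(stats::runif(100, 0, 0.1)), a, cl)
  expect_identical(slow$decisions, fast$decisions)
})

test_that("at low rates the sorted composition equals the full-match set", {
  # rate 2/s: windows never overlap, refractory never binds
  s <- simulate_stream(demo_populations(), 2, 50, seed = 55)
  model <- demo_model()
  clusters <- enumerate_conjunctions(predict(model), k = model$k)
  sel <- rank_and_select(demo_stream()$label, clusters)
  cl <- clusters[[sel$selected$G2M$cluster[1]]]
  a <- predict(model, s)
  out <- run_sort(s$timestamp, a, cl, labels = s$label)
  full <- which(decide(a, cl) == "full") - 1L
  expect_identical(out$sorted, full)
  expect_length(out$co_sorted, 0)
  expect_length(out$dropped, 0)
})

test_that("re-analysis reproduces hand counts and pre-sort enrichment", {
  labels <- c(rep("A", 4), rep("B", 12))  # prevalence A = 25%
  out <- structure(list(sorted = c(0L, 1L), co_sorted = c(2L, 3L),
                        dropped = integer(0), cluster = "toy"),
                   class = "sort_outcome")
  rep1 <- reanalyze(out, labels)
  expect_equal(rep1$fractions[["A"]], 1)   # all four deflected are A
  expect_equal(rep1$enrichment[["A"]], 4)  # 1 / 0.25
  expect_false(rep1$empty)
  # a deflected set matching the pre-sort composition is unenriched
  out2 <- structure(list(sorted = 0:3, co_sorted = 4:15,
                         dropped = integer(0), cluster = "all"),
                    class = "sort_outcome")
  rep2 <- reanalyze(out2, labels)
  expect_equal(unname(rep2$enrichment), c(1, 1))
  # toy 10-event outcome against hand counts
  lab10 <- c("A", "A", "B", "B", "B", "A", "B", "B", "A", "B")
  out3 <- structure(list(sorted = c(0L, 1L, 5L), co_sorted = c(2L, 9L),
                         dropped = integer(0), cluster = "toy"),
                    class = "sort_outcome")
  rep3 <- reanalyze(out3, lab10)
  expect_equal(rep3$fractions[["A"]], 3 / 5)
  expect_equal(rep3$n_sorted, 3L)
  expect_equal(rep3$n_co_sorted, 2L)
  # empty outcome is flagged
  out4 <- structure(list(sorted = integer(0), co_sorted = integer(0),
                         dropped = integer(0), cluster = "none"),
                    class = "sort_outcome")
  expect_true(reanalyze(out4, labels)$empty)
})

test_that("purity degrades monotonically with event rate", {
  model <- demo_model()
  clusters <- enumerate_conjunctions(predict(model), k = model$k)
  sel <- rank_and_select(demo_stream()$label, clusters)
  cl <- clusters[[sel$selected$G2M$cluster[1]]]
  purities <- vapply(c(50, 1000, 3000), function(rate) {
    s <- simulate_stream(demo_populations(), rate, 2000 / rate, seed = 57)
    out <- run_sort(s$timestamp, predict(model, s), cl, labels = s$label)
    out$purity[["G2M"]]
  }, numeric(1))
  expect_true(all(diff(purities) <= 0))
})
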