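test_that("conjunction enumeration counts and memberships are exact", {
  # 4 channels x 6 clusters, order 2: C(4,2) * 36 = 216 combined clusters
  set.seed(41)
  a4 <- matrix(sample(0:5, 400 * 4, replace = TRUE), 400, 4,
               dimnames = list(NULL, c("SSC", "FSC23", "FSC8", "FSC4")))
  cl4 <- enumerate_conjunctions(a4, k = 6)
  expect_length(cl4, choose(4, 2) * 36)
  # 2 channels x 2 clusters: 4 combined clusters
  a2 <- matrix(sample(0:1, 20, replace = TRUE), 10, 2,
               dimnames = list(NULL, c("A", "B")))
  expect_length(enumerate_conjunctions(a2, k = 2), 4)
  # 5-event toy assignment: membership is the exact set intersection
  toy <- matrix(c(0, 0, 1, 0, 1,
                  1, 0, 1, 1, 0), 5, 2,
                dimnames = list(NULL, c("chA", "chB")))
  cls <- enumerate_conjunctions(toy, k = 2)
  target <- Filter(function(cl)
    cl$parts[["chA"]] == 0 && cl$parts[["chB"]] == 1, cls)[[1]]
  brute <- intersect(which(toy[, "chA"] == 0), which(toy[, "chB"] == 1)) - 1L
  expect_identical(target$members, brute)
  expect_identical(target$members, c(0L, 3L))
  # conjunction membership is a subset of each parent single-channel cluster
  for (cl in cls) {
    for (ch in names(cl$parts)) {
      expect_true(all(cl$members %in% (which(toy[, ch] == cl$parts[[ch]]) - 1L)))
    }
  }
  expect_error(enumerate_conjunctions(a2, k = 2, order = 3), "order")
})

test_that("enrichment follows its defining ratio", {
  labels <- c(rep("P", 100), rep("Q", 300), rep("R", 600))
  # the whole sample is unenriched in everything
  all_e <- enrichment(labels, 0:999)
  expect_equal(unname(all_e$x), c(1, 1, 1))
  # a pure cluster of a 25%-prevalence population reaches 1/0.25 = 4
  lab2 <- c(rep("P", 250), rep("Q", 750))
  pure <- enrichment(lab2, 0:49)  # 50 events, all P
  expect_equal(pure$x[["P"]], 4)
  expect_equal(pure$x[["Q"]], 0)
  # direct arithmetic: N(P,c)=30, N(.,c)=40, N(P,.)=100, N(.,.)=1000 -> 7.5
  members <- c(0:29, 100:109)  # 30 P events + 10 Q events
  e <- enrichment(labels, members)
  expect_equal(e$x[["P"]], (30 / 40) / (100 / 1000))
  expect_equal(e$x[["P"]], 7.5)
  # empty membership is flagged, not an error
  empty <- enrichment(labels, integer(0))
  expect_true(empty$flagged)
  expect_true(all(is.na(empty$x)))
  expect_error(enrichment(labels, 1000), "out of range")
})

test_that("maximum achievable enrichment is the reciprocal prevalence", {
  lab <- c(rep("A", 100), rep("B", 300), rep("C", 600))
  expect_equal(max_achievable_enrichment(lab, "A"), 10)
  expect_equal(max_achievable_enrichment(rep("A", 50), "A"), 1)
  expect_equal(max_achievable_enrichment(c(rep("A", 10), rep("B", 90)), "A"), 10)
  expect_error(max_achievable_enrichment(lab, "Z"), "absent")
})

test_that("enrichment satisfies its weighted-mean and range identities", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    labels <- sample(c("G1", "S", "G2M"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    members <- sample(0:(n - 1), sample(seq_len(n), 1))
    e <- enrichment(labels, members)
    # sum_P x(P,c) * N(P,.) = N(.,.)
    expect_equal(sum(e$x * e$N_P), e$N, tolerance = 1e-12)
    # 0 <= x <= x_max
    for (p in names(e$x)) {
      expect_gte(e$x[[p]], 0)
      expect_lte(e$x[[p]], max_achievable_enrichment(labels, p) + 1e-12)
    }
  }
})

test_that("uniformly random memberships are unenriched", {
  set.seed(44)
  labels <- sample(c("G1", "S", "G2M"), 20000, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
  members <- sample(0:19999, 8000)
  e <- enrichment(labels, members)
  for (p in names(e$x)) {
    prev <- e$N_P[[p]] / e$N
    se <- sqrt((1 - prev) / (prev * 8000))  # binomial error on x around 1
    expect_lt(abs(e$x[[p]] - 1), 4 * se)
  }
})

test_that("the two rankings select as specified on a hand-checkable table", {
  # 10 P events (prevalence 10%, x_max = 10), 90 Q
  labels <- c(rep("P", 10), rep("Q", 90))
  mk <- function(members) sort_cluster(c(chA = 0, chB = 0), members = members)
  clusters <- list(
    tiny_pure   = mk(0:1),              # x = 10, size 2
    small_pure  = mk(0:3),              # x = 10, size 4
    big_rich    = mk(c(0:7, 10:11)),    # x = 8, size 10
    big_mixed   = mk(c(0:4, 10:24)),    # x = 2.5, size 20
    background  = mk(10:59)             # x = 0, size 50
  )
  sel <- rank_and_select(labels, clusters, threshold_frac = 0.75, top_n = 3,
                         min_size_frac = 0.05, populations = "P")
  tab <- sel$table[sel$table$population == "P", ]
  # ranking B: exactly the clusters with x >= 7.5, size-ordered
  above <- tab$name[!is.na(tab$x) & tab$x >= 7.5]
  expect_setequal(tab$cluster[!is.na(tab$x) & tab$x >= 7.5], c(1, 2, 3))
  picked <- sel$selected$P
  # preferred: above-threshold clusters meeting min size (big_rich first,
  # then small_pure at 4%...no, below min_size 5), then top-enrichment fills
  expect_equal(picked$cluster[1], 3)           # big_rich: size 10, x = 8
  expect_setequal(picked$cluster, c(3, 1, 2))  # the three above-threshold ones
  # ties in x rank the larger cluster first (small_pure before tiny_pure)
  expect_lt(which(picked$cluster == 2), which(picked$cluster == 1))
  lab_tie <- c(rep("P", 20), rep("Q", 80))
  tie_cl <- list(a = mk(0:4), b = mk(0:9))  # both pure, x = 5; b larger
  sel_tie <- rank_and_select(lab_tie, tie_cl, threshold_frac = 0.9, top_n = 2,
                             min_size_frac = 0, populations = "P")
  expect_equal(sel_tie$selected$P$cluster[1], 2)
  # fewer eligible clusters than requested: warn and return all
  expect_warning(
    short <- rank_and_select(labels, clusters["tiny_pure"], top_n = 3,
                             populations = "P"),
    "eligible"
  )
  expect_equal(nrow(short$selected$P), 1)
  expect_identical(short$short, "P")
})

test_that("empty clusters are never selected", {
  labels <- c(rep("P", 5), rep("Q", 5))
  clusters <- list(
    sort_cluster(c(chA = 0), members = 0:4),
    sort_cluster(c(chA = 1), members = integer(0))
  )
  sel <- suppressWarnings(
    rank_and_select(labels, clusters, top_n = 3, min_size_frac = 0,
                    populations = "P"))
  expect_false(2 %in% sel$selected$P$cluster)
})

test_that("three demo populations yield nine selected sort clusters", {
  s <- demo_stream()
  model <- demo_model()
  clusters <- enumerate_conjunctions(predict(model), k = model$k)
  sel <- rank_and_select(s$label, clusters)
  expect_equal(sum(vapply(sel$selected, nrow, integer(1))), 9)
  expect_length(sel$short, 0)
})
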