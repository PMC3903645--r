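test_that("hit counting respects the identity threshold inclusively", {
  hits <- data.frame(env = c("soil", "soil", "marine"),
                     identity = c(0.981, 0.962, 0.910))
  expect_equal(count_hits_per_env(hits, 0.97), c(soil = 1L))
  expect_equal(count_hits_per_env(hits, 0.90),
               c(marine = 1L, soil = 2L))
  # the boundary is inclusive: a hit exactly at c is counted
  expect_equal(count_hits_per_env(hits, 0.962), c(soil = 2L))
  expect_length(count_hits_per_env(hits[0, ], 0.9), 0)
})

test_that("compute_mhi matches the brute-force IDF oracle and is log-base invariant", {
  counts <- c(e1 = 3L, e2 = 1L)
  r <- c(e1 = 2L, e2 = 8L)
  got <- compute_mhi(counts, r, total = 10)
  oracle_e <- mhi_oracle(counts, r, 10, base = exp(1))
  oracle_10 <- mhi_oracle(counts, r, 10, base = 10)
  expect_equal(got, oracle_e, tolerance = 1e-12)
  expect_equal(got, oracle_10, tolerance = 1e-12)
  expect_equal(unname(got[["e1"]]), 95.58, tolerance = 1e-3)
  expect_equal(unname(got[["e2"]]), 4.42, tolerance = 1e-3)
  expect_equal(sum(got), 100)
})

test_that("equal counts with equal reference sizes split evenly", {
  got <- compute_mhi(c(a = 5L, b = 5L), c(a = 7L, b = 7L), total = 20)
  expect_equal(unname(got), c(50, 50))
})

test_that("MHI percentages are invariant to scaling the counts", {
  set.seed(25)
  for (i in 1:10) {
    n_env <- sample(2:6, 1)
    envs <- paste0("e", seq_len(n_env))
    counts <- setNames(sample(1:50, n_env, replace = TRUE), envs)
    r <- setNames(sample(1:30, n_env, replace = TRUE), envs)
    total <- sum(r) + sample(1:20, 1)
    base <- compute_mhi(counts, r, total = total)
    scaled <- compute_mhi(counts * 7L, r, total = total)
    expect_equal(base, scaled, tolerance = 1e-9)
    expect_equal(sum(base), 100, tolerance = 1e-9)
  }
})

test_that("with equal counts the rarer environment gets the strictly larger MHI", {
  set.seed(26)
  for (i in 1:20) {
    r_small <- sample(1:20, 1)
    r_big <- r_small + sample(1:30, 1)
    total <- r_small + r_big + sample(1:50, 1)
    n <- sample(1:10, 1)
    got <- compute_mhi(c(rare = n, common = n),
                       c(rare = r_small, common = r_big), total = total)
    expect_gt(got[["rare"]], got[["common"]])
  }
})

test_that("degenerate all-zero weights are flagged instead of divided by", {
  expect_warning(
    out <- compute_mhi(c(only = 4L), c(only = 10L), total = 10),
    "undefined")
  expect_length(out, 0)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_error(compute_mhi(c(x = 1L), c(y = 5L), total = 10), "not present")
  expect_error(compute_mhi(c(x = 1L), c(x = 12L), total = 10), "exceed")
})

test_that("sub-floor environments are grouped into other with totals preserved", {
  expect_equal(group_other(c(A = 99.5, B = 0.5)),
               c(A = 99.5, other = 0.5), ignore_attr = TRUE)
  unchanged <- group_other(c(A = 60, B = 40))
  expect_equal(unname(unchanged[c("A", "B")]), c(60, 40))
  expect_false("other" %in% names(unchanged))
  mixed <- group_other(c(A = 0.6, B = 0.5, C = 98.9))
  expect_equal(mixed[["other"]], 1.1)
  expect_equal(sum(mixed), 100)
  expect_setequal(attr(mixed, "other_members"), c("A", "B"))
})

test_that("profiling a perfect-match query yields a single 100% environment", {
  set.seed(27)
  store <- store_from_seqs(list(soil = replicate(2, rand_seq(600)),
                                marine = replicate(2, rand_seq(600))))
  q <- seq_record("q", store$entries$residues[1])
  prof <- profile_query(q, store)
  col <- prof$per_threshold[["97"]]
  expect_equal(col$n_hits, 1L)
  expect_equal(unname(col$mhi_percent[["soil"]]), 100)

  # unrelated query: no threshold columns at all
  none <- suppressWarnings(
    profile_query(seq_record("q", rand_seq(80)), store))
  expect_length(none$per_threshold, 0)
  expect_equal(format_statistics(none), "no hits above any identity threshold")

  # sub-500-bp queries warn but still profile
  expect_warning(profile_query(seq_record("q", substr(
    store$entries$residues[1], 1, 400)), store), "500")
})

test_that("a 4%-diverged query wins its source environment at genus level and below", {
  # at 4% divergence the per-hit identity straddles the 97% species
  # boundary (binomial spread, end-trimming by the local aligner), so the
  # presence of the species column is statistical; the argmax is not
  set.seed(28)
  p <- sim_params(seed = 28)
  templates <- generate_templates(p)
  store <- store_from_seqs(lapply(templates, unname))
  q <- generate_query(templates, "soil", divergence = 0.04, length = 800,
                      seed = 281)
  prof <- profile_query(q, store)
  # 95/90 separate the environments (cross-environment identity ~83-86%
  # cannot reach them); at 85/80 both environments' templates qualify and
  # the ranking carries no habitat signal
  for (lab in c("95", "90")) {
    col <- prof$per_threshold[[lab]]
    expect_false(is.null(col), label = paste("column", lab))
    expect_equal(names(which.max(col$mhi_percent)), "soil")
  }
})

test_that("collective profiling pools counts and duplicating a query changes nothing", {
  set.seed(29)
  store <- store_from_seqs(list(soil = replicate(3, rand_seq(600)),
                                marine = replicate(3, rand_seq(600))))
  q <- seq_record("q", mutate_seq(store$entries$residues[1], 6))
  single <- profile_query(q, store)
  doubled <- profile_collective(list(q, q), store)
  for (lab in names(single$per_threshold)) {
    expect_equal(doubled$per_threshold[[lab]]$mhi_percent,
                 single$per_threshold[[lab]]$mhi_percent, tolerance = 1e-9)
    expect_equal(doubled$per_threshold[[lab]]$n_hits,
                 2L * single$per_threshold[[lab]]$n_hits)
  }

  # one query per environment, symmetric store: 50/50 split
  q1 <- seq_record("q1", store$entries$residues[1])
  q2 <- seq_record("q2", store$entries$residues[4])
  both <- profile_collective(list(q1, q2), store)
  col <- both$per_threshold[["97"]]
  expect_equal(unname(col$mhi_percent[c("soil", "marine")]), c(50, 50))

  # mean mode agrees here by symmetry
  both_mean <- profile_collective(list(q1, q2), store, mode = "mean")
  expect_equal(sort(both_mean$per_threshold[["97"]]$mhi_percent),
               sort(col$mhi_percent), tolerance = 1e-9)
})

test_that("statistics formatting follows the per-threshold line convention", {
  prof <- structure(list(
    query_ids = "q",
    per_threshold = list(
      "97" = list(level = 0.97, n_hits = 36L,
                  counts = c(freshwater = 30L, marine = 6L),
                  mhi_percent = c(freshwater = 88.15, marine = 11.85),
                  grouped = structure(c(freshwater = 88.15, marine = 11.85),
                                      other_members = character(0)),
                  other_members = character(0)))),
    class = "mhi_profile")
  expect_equal(format_statistics(prof),
               "(97%, 36 hits) freshwater: 88.15%; marine: 11.85%")
  prof$per_threshold[["97"]]$n_hits <- 1L
  prof$per_threshold[["97"]]$grouped <-
    structure(c(soil = 100), other_members = character(0))
  expect_equal(format_statistics(prof), "(97%, 1 hit) soil: 100.00%")
})

test_that("profile tables expose grouped percentages with per-environment counts", {
  set.seed(30)
  store <- store_from_seqs(list(soil = replicate(2, rand_seq(600)),
                                marine = replicate(2, rand_seq(600))))
  q <- seq_record("q", store$entries$residues[1])
  tab <- profile_to_csv(profile_query(q, store))
  expect_true(all(c("threshold", "environment", "n_hits", "mhi_percent")
                  %in% names(tab)))
  sums <- tapply(tab$mhi_percent, tab$threshold, sum)
  expect_true(all(abs(sums - 100) < 1e-6))
})

test_that("threshold sets must be strictly decreasing identities", {
  expect_error(threshold_set(c(0.9, 0.97)), "")
  expect_error(threshold_set(c(0.9, 0.9)), "")
  expect_silent(threshold_set(c(0.99, 0.5)))
})
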