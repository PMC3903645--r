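test_that("near-duplicate clustering merges prefixes and separates diverged reads", {
  set.seed(5)
  a <- rand_seq(300)
  two <- list(seq_record("x", a), seq_record("y", a))
  cl <- dedup_near_duplicates(two, 0.99)
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$members, c("x", "y"))

  b <- mutate_seq(a, 15)  # 5% diverged
  cl2 <- dedup_near_duplicates(list(seq_record("x", a), seq_record("y", b)),
                               0.99)
  expect_length(cl2, 2)

  # a truncated prefix copy joins its source; representative is the longest
  pre <- substr(a, 1, 250)
  cl3 <- dedup_near_duplicates(list(seq_record("short", pre),
                                    seq_record("long", a)), 0.99)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$representative$id, "long")
})

test_that("dedup recovers planted duplicates from the generator", {
  p <- sim_params(n_reads = 100, rate_duplicate = 0.6, rate_chimera = 0,
                  rate_short = 0, rate_ambiguous = 0, n_envs = 1,
                  templates_per_env = 4, seed = 13)
  corpus <- simulate_corpus(p)
  res <- run_qc(corpus$reads, qc_params(adapters = p$adapter))
  cl <- dedup_near_duplicates(res$records, 0.99)
  n_dup <- sum(corpus$truth$type == "duplicate")
  expect_equal(length(res$records) - length(cl), n_dup)
  # every duplicate sits in the same cluster as its source
  for (i in which(corpus$truth$type == "duplicate")) {
    id <- corpus$truth$id[i]
    src <- corpus$truth$duplicate_of[i]
    home <- which(vapply(cl, function(x) id %in% x$members, logical(1)))
    expect_true(src %in% cl[[home]]$members)
  }
})

test_that("clustering partitions the input and matches a brute-force greedy oracle", {
  set.seed(8)
  for (rep in 1:3) {
    templates <- replicate(3, rand_seq(120))
    reads <- list()
    for (i in 1:15) {
      t <- sample(3, 1)
      reads[[i]] <- seq_record(sprintf("r%02d", i),
                               mutate_seq(substr(templates[t], 1,
                                                 sample(90:120, 1)),
                                          sample(0:2, 1)))
    }
    got <- cluster_by_identity(reads, 0.97)
    # partition property
    all_members <- unlist(lapply(got, `[[`, "members"))
    expect_setequal(all_members, vapply(reads, `[[`, character(1), "id"))
    expect_equal(anyDuplicated(all_members), 0L)

    # oracle: same greedy rule, but identity from the independent DP and
    # coverage computed by hand
    lens <- vapply(reads, function(r) nchar(r$residues), integer(1))
    ids <- vapply(reads, `[[`, character(1), "id")
    ord <- order(-lens, ids)
    reps <- integer(0)
    assign <- integer(length(reads))
    for (i in ord) {
      placed <- FALSE
      for (ci in seq_along(reps)) {
        r <- reps[ci]
        # run the DP with the shorter read as the subject so its aligned
        # span is columns minus gaps in the subject row
        shorter <- min(lens[i], lens[r])
        pair <- if (lens[i] <= lens[r]) c(r, i) else c(i, r)
        al <- sw_affine(reads[[pair[1]]]$residues, reads[[pair[2]]]$residues)
        idy <- al$matches / al$columns
        span <- al$columns - al$gaps_in_b
        if (span / shorter >= 0.9 && idy >= 0.97) {
          assign[i] <- r
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        reps <- c(reps, i)
        assign[i] <- i
      }
    }
    expect_equal(length(got), length(reps))
    got_sets <- lapply(got, function(cl) sort(cl$members))
    oracle_sets <- lapply(reps, function(r) sort(ids[assign == r]))
    expect_setequal(got_sets, oracle_sets)
  }
})

test_that("cluster count is monotone in the identity threshold", {
  set.seed(9)
  templates <- replicate(4, rand_seq(150))
  reads <- lapply(1:20, function(i) {
    seq_record(sprintf("r%02d", i),
               mutate_seq(templates[sample(4, 1)], sample(0:6, 1)))
  })
  n_clusters <- vapply(c(0.80, 0.90, 0.95, 0.99),
                       function(idy) length(cluster_by_identity(reads, idy)),
                       numeric(1))
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("rRNA screening keeps true positives and rejects unrelated sequence", {
  set.seed(10)
  ref <- seq_record("ref", rand_seq(500))
  params <- cluster_params()

  same <- screen_rrna(seq_record("q", ref$residues), list(ref), params)
  expect_true(same$keep)
  expect_equal(same$score, 1.0)

  junk <- screen_rrna(seq_record("q", rand_seq(500)), list(ref), params)
  expect_false(junk$keep)
  expect_lt(junk$score, 0.05)

  # 3% substitutions at k=15: expected shared fraction ~0.97^15 ~ 0.63;
  # verify the package score against a direct independent count
  mut <- mutate_seq(ref$residues, 15)
  res <- screen_rrna(seq_record("q", mut), list(ref), params)
  k <- params$kmer_size_screen
  starts <- seq_len(nchar(mut) - k + 1)
  qk <- unique(substring(mut, starts, starts + k - 1))
  rk <- unique(substring(ref$residues, starts, starts + k - 1))
  direct <- sum(qk %in% rk) / length(qk)
  expect_equal(res$score, direct, tolerance = 1e-12)
  expect_true(res$keep)
  expect_gt(res$score, 0.4)

  too_short <- screen_rrna(seq_record("q", "ACGT"), list(ref), params)
  expect_false(too_short$keep)
  expect_equal(too_short$score, 0)
})

test_that("chimera detection flags a perfect two-parent read and spares its parents", {
  set.seed(12)
  a <- rand_seq(400)
  b <- mutate_seq(a, 40)  # ~10% diverged
  candidates <- list(seq_record("A", a), seq_record("B", b))
  chim <- seq_record("C", paste0(substr(a, 1, 200), substr(b, 201, 400)))
  v <- detect_chimera(chim, candidates)
  expect_true(v$is_chimera)
  expect_equal(v$best_chimeric_identity, 1.0)
  expect_setequal(v$parents, c("A", "B"))
  expect_gte(v$best_chimeric_identity, v$best_single_identity)

  # an exact copy of a parent cannot be improved on
  self <- detect_chimera(seq_record("A2", a), candidates)
  expect_false(self$is_chimera)
  expect_equal(self$best_single_identity, 1.0)

  # a candidate with the same id is never its own parent
  own <- detect_chimera(seq_record("A", a), candidates)
  expect_false(own$is_chimera)
})

test_that("planted chimeras are flagged without false positives", {
  p <- sim_params(n_reads = 50, rate_chimera = 0.2, rate_duplicate = 0,
                  rate_short = 0, rate_ambiguous = 0, n_envs = 1,
                  templates_per_env = 5, seed = 31)
  corpus <- simulate_corpus(p)
  recs <- run_qc(corpus$reads, qc_params(adapters = p$adapter))$records
  truth_type <- setNames(corpus$truth$type, corpus$truth$id)
  flagged <- character(0)
  accepted <- list()
  lens <- vapply(recs, function(r) nchar(r$residues), integer(1))
  ids <- vapply(recs, `[[`, character(1), "id")
  for (i in order(-lens, ids)) {
    if (length(accepted) >= 2 &&
        detect_chimera(recs[[i]], accepted)$is_chimera) {
      flagged <- c(flagged, recs[[i]]$id)
    } else {
      accepted <- c(accepted, recs[i])
    }
  }
  expect_setequal(flagged, corpus$truth$id[corpus$truth$type == "chimera"])
})

test_that("build_reference collapses redundancy and recovers template counts", {
  # two environments, one template each, ten near-identical reads each
  set.seed(14)
  t1 <- rand_seq(320)
  t2 <- rand_seq(320)
  mk <- function(tmpl, env) {
    lapply(1:10, function(i) {
      seq_record(sprintf("%s_%02d", env, i),
                 mutate_seq(substr(tmpl, 1, sample(280:320, 1)), 2))
    })
  }
  screen <- list(seq_record("s1", t1), seq_record("s2", t2))
  store <- build_reference(list(e1 = mk(t1, "e1"), e2 = mk(t2, "e2")), screen)
  expect_equal(store$counts_per_env, c(e1 = 1L, e2 = 1L))
  expect_equal(store$total, 2L)

  # an environment whose reads all fail the rRNA screen is omitted
  junk <- lapply(1:3, function(i) seq_record(paste0("j", i), rand_seq(300)))
  expect_warning(
    store2 <- build_reference(list(e1 = mk(t1, "e1"), bad = junk), screen),
    "omitted")
  expect_equal(names(store2$counts_per_env), "e1")
})

test_that("build_reference recovers per-environment template counts and stage plants", {
  p <- sim_params(seed = 2)
  corpus <- simulate_corpus(p)
  by_env <- sim_reads_by_env(corpus)
  qcd <- lapply(by_env, function(r) {
    run_qc(r, qc_params(adapters = p$adapter))$records
  })
  store <- build_reference(qcd, corpus$screen_ref)
  report <- attr(store, "condense_report")
  for (e in p$envs) {
    planted <- corpus$truth[corpus$truth$env == e, ]
    expect_equal(unname(store$counts_per_env[[e]]), p$templates_per_env)
    expect_equal(report$dedup_removed[report$env == e],
                 sum(planted$type == "duplicate"))
    expect_equal(report$chimera_removed[report$env == e],
                 sum(planted$type == "chimera"))
    expect_equal(report$rrna_removed[report$env == e], 0L)
  }
})
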