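# Condensing QC-passed reads into the compact labelled reference:
# 99% near-duplicate removal, k-mer rRNA screening, two-parent chimera
# detection, and greedy 97% identity clustering within each environment.

#' Clustering and screening parameters
#'
#' @param dedup_identity Identity for near-duplicate (prefix) clustering;
#'   artificial duplicates from amplicon sequencing collapse at 0.99.
#' @param otu_identity Identity for per-environment centroid clustering;
#'   0.97 is the accepted species boundary for prokaryotic 16S rRNA.
#' @param kmer_size_screen k-mer size of the rRNA screen.
#' @param rrna_score_min Minimum shared canonical k-mer fraction for a read
#'   to be called 16S-like.
#' @param chimera_min_improvement Identity margin by which the best
#'   two-parent model must beat the best single parent.
#' @param chimera_min_model_identity Minimum identity each parent must reach
#'   on its own segment (and hence the two-parent model overall); a chimera
#'   call requires parents that actually explain their halves of the read.
#' @param chimera_breakpoint_step Breakpoint grid spacing in bp.
#' @param chimera_end_exclusion Bases excluded from the grid at either end.
#' @return List of class `cluster_params`.
#' @export
cluster_params <- function(dedup_identity = 0.99, otu_identity = 0.97,
                           kmer_size_screen = 15L, rrna_score_min = 0.2,
                           chimera_min_improvement = 0.02,
                           chimera_min_model_identity = 0.9,
                           chimera_breakpoint_step = 10L,
                           chimera_end_exclusion = 50L) {
  stopifnot(dedup_identity > 0, dedup_identity <= 1,
            otu_identity > 0, otu_identity <= 1,
            dedup_identity >= otu_identity,
            kmer_size_screen >= 4L,
            rrna_score_min >= 0, rrna_score_min <= 1,
            chimera_min_improvement >= 0,
            chimera_min_model_identity >= 0, chimera_min_model_identity <= 1,
            chimera_breakpoint_step >= 1L, chimera_end_exclusion >= 0L)
  structure(list(dedup_identity = dedup_identity,
                 otu_identity = otu_identity,
                 kmer_size_screen = as.integer(kmer_size_screen),
                 rrna_score_min = rrna_score_min,
                 chimera_min_improvement = chimera_min_improvement,
                 chimera_min_model_identity = chimera_min_model_identity,
                 chimera_breakpoint_step = as.integer(chimera_breakpoint_step),
                 chimera_end_exclusion = as.integer(chimera_end_exclusion)),
            class = "cluster_params")
}

revcomp_str <- function(x) {
  paste(rev(seq_chars(chartr("ACGTN", "TGCAN", x))), collapse = "")
}

# distinct canonical (strand-symmetric) k-mers of a sequence
canonical_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(x, starts, starts + k - 1L)
  rc <- revcomp_str(x)
  rev <- substring(rc, n - starts - k + 2L, n - starts + 1L)
  unique(pmin(fwd, rev))
}

# greedy order used by both clustering passes: longest first, ties by id
greedy_order <- function(reads) {
  lens <- vapply(reads, function(r) nchar(r$residues), integer(1))
  ids <- vapply(reads, `[[`, character(1), "id")
  order(-lens, ids)
}

# identity of the 5'-anchored overlap (shorter read as near-prefix of the
# longer): matches / shorter length
prefix_identity <- function(a_chars, b_chars) {
  n <- min(length(a_chars), length(b_chars))
  if (n == 0L) return(0)
  sum(a_chars[seq_len(n)] == b_chars[seq_len(n)]) / n
}

#' Collapse near-duplicate reads
#'
#' Greedy clustering in longest-first order (ties by id). A read joins the
#' first cluster whose representative matches it at `identity` or better
#' over the 5'-anchored overlap (the shorter sequence treated as a
#' near-prefix of the longer, the convention for artificial-duplicate
#' removal in pyrosequencing data); otherwise it founds a new cluster.
#' Representatives are the longest member.
#'
#' @param reads Non-empty list of [seq_record] objects.
#' @param identity Identity threshold (default 0.99).
#' @return List of clusters: each a list with `representative` (a
#'   [seq_record]) and `members` (character vector of read ids).
#' @export
dedup_near_duplicates <- function(reads, identity = 0.99) {
  stopifnot(length(reads) > 0)
  ord <- greedy_order(reads)
  chars <- lapply(reads, function(r) seq_chars(r$residues))
  rep_idx <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      if (prefix_identity(chars[[rep_idx[ci]]], chars[[i]]) >= identity) {
        members[[ci]] <- c(members[[ci]], reads[[i]]$id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      members[[length(rep_idx)]] <- reads[[i]]$id
    }
  }
  lapply(seq_along(rep_idx), function(ci) {
    list(representative = reads[[rep_idx[ci]]], members = members[[ci]])
  })
}

#' Greedy centroid clustering by local-alignment identity
#'
#' Longest-first greedy clustering: a read joins the first cluster whose
#' representative aligns to it at `identity` or better, where identity is
#' matches / alignment columns of the best local alignment and the alignment
#' must cover at least `coverage` of the shorter sequence (preventing
#' tiny-overlap joins); otherwise the read founds a new cluster.
#'
#' @param reads Non-empty list of [seq_record] objects.
#' @param identity Identity threshold (default 0.97, the species boundary).
#' @param coverage Minimum aligned fraction of the shorter sequence.
#' @return List of clusters as in [dedup_near_duplicates].
#' @export
cluster_by_identity <- function(reads, identity = 0.97, coverage = 0.9) {
  stopifnot(length(reads) > 0)
  ord <- greedy_order(reads)
  rep_idx <- integer(0)
  members <- list()
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(rep_idx)) {
      al <- local_identity(reads[[i]]$residues,
                           reads[[rep_idx[ci]]]$residues)
      if (al$coverage_shorter >= coverage && al$identity >= identity) {
        members[[ci]] <- c(members[[ci]], reads[[i]]$id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      members[[length(rep_idx)]] <- reads[[i]]$id
    }
  }
  lapply(seq_along(rep_idx), function(ci) {
    list(representative = reads[[rep_idx[ci]]], members = members[[ci]])
  })
}

#' Build an rRNA screening index
#'
#' Pre-computes the canonical k-mer sets of the screening reference so that
#' many reads can be screened without re-hashing it.
#'
#' @param screen_ref Non-empty list of [seq_record] screening sequences.
#' @param k k-mer size.
#' @return Object of class `screen_index`.
#' @export
build_screen_index <- function(screen_ref, k = 15L) {
  stopifnot(length(screen_ref) > 0)
  structure(list(k = as.integer(k),
                 kmer_sets = lapply(screen_ref, function(r) {
                   canonical_kmers(r$residues, k)
                 })),
            class = "screen_index")
}

#' Screen a read for 16S rRNA-likeness
#'
#' Scores the read as the maximum, over screening sequences, of the fraction
#' of the read's distinct canonical k-mers shared with that sequence. Reads
#' scoring below `rrna_score_min` (or shorter than k) are discarded.
#'
#' @param rec A [seq_record].
#' @param screen_ref List of screening [seq_record]s, or a pre-built
#'   [build_screen_index] object.
#' @param params A [cluster_params] (supplies `kmer_size_screen` and
#'   `rrna_score_min`; ignored for k if an index is given).
#' @return List with `keep` (logical) and `score` (fraction in `[0, 1]`).
#' @export
screen_rrna <- function(rec, screen_ref, params = cluster_params()) {
  idx <- if (inherits(screen_ref, "screen_index")) screen_ref
         else build_screen_index(screen_ref, params$kmer_size_screen)
  qk <- canonical_kmers(rec$residues, idx$k)
  if (length(qk) == 0L) {
    return(list(keep = FALSE, score = 0))
  }
  score <- max(vapply(idx$kmer_sets, function(s) {
    sum(qk %in% s) / length(qk)
  }, numeric(1)))
  list(keep = score >= params$rrna_score_min, score = score)
}

# Most promising ungapped offsets between two sequences from shared-k-mer
# diagonals. Offset o means candidate position j aligns read position j + o.
seed_offsets <- function(read_str, cand_str, k = 12L, top = 3L) {
  n1 <- nchar(read_str)
  n2 <- nchar(cand_str)
  if (n1 < k || n2 < k) return(integer(0))
  s1 <- seq_len(n1 - k + 1L)
  s2 <- seq_len(n2 - k + 1L)
  k1 <- substring(read_str, s1, s1 + k - 1L)
  k2 <- substring(cand_str, s2, s2 + k - 1L)
  hit <- match(k2, k1)
  ok <- !is.na(hit)
  if (!any(ok)) return(integer(0))
  diffs <- hit[ok] - s2[ok]
  tab <- sort(table(diffs), decreasing = TRUE)
  as.integer(names(tab))[seq_len(min(top, length(tab)))]
}

# per-position match/coverage profile of candidate against read at the best
# seeded ungapped offset; NULL when no seed is shared
ungapped_profile <- function(read_chars, cand_chars, offsets) {
  if (length(offsets) == 0L) return(NULL)
  L <- length(read_chars)
  cl <- length(cand_chars)
  best <- NULL
  best_m <- -1L
  for (o in offsets) {
    lo <- max(1L, 1L + o)
    hi <- min(L, cl + o)
    if (hi < lo) next
    m <- logical(L)
    cov <- logical(L)
    cov[lo:hi] <- TRUE
    m[lo:hi] <- read_chars[lo:hi] == cand_chars[(lo:hi) - o]
    nm <- sum(m)
    if (nm > best_m) {
      best_m <- nm
      best <- list(match = m, cover = cov)
    }
  }
  best
}

#' Two-parent chimera test
#'
#' For each breakpoint on a fixed grid, the read's left segment is matched
#' to its best ungapped-aligning candidate and the right segment to the best
#' *different* candidate; segment identities (uncovered positions count as
#' mismatches, and a candidate must cover at least 90% of a segment to be
#' eligible for it) combine into a chimeric-model identity. A candidate is
#' only eligible as a parent for a segment it matches at
#' `chimera_min_model_identity` or better — a distant relative cannot prop
#' up one short segment of an otherwise single-parent model. The read is
#' called chimeric iff the best two-parent model beats the best single
#' parent by `chimera_min_improvement` and the two parents differ. A
#' candidate with the same id as `rec` is never its own parent.
#'
#' @param rec A [seq_record].
#' @param candidates Non-empty list of candidate parent [seq_record]s.
#' @param params A [cluster_params].
#' @return List of class `chimera_verdict`: `is_chimera`,
#'   `best_single_identity`, `best_chimeric_identity`, `parents` (character
#'   pair or `NULL`), `breakpoint` (position or `NULL`).
#' @export
detect_chimera <- function(rec, candidates, params = cluster_params()) {
  stopifnot(length(candidates) > 0)
  verdict <- function(is_chimera, single, chimeric, parents = NULL,
                      breakpoint = NULL) {
    structure(list(is_chimera = is_chimera,
                   best_single_identity = single,
                   best_chimeric_identity = chimeric,
                   parents = parents, breakpoint = breakpoint),
              class = "chimera_verdict")
  }
  L <- nchar(rec$residues)
  rv <- seq_chars(rec$residues)
  ex <- params$chimera_end_exclusion
  grid <- seq.int(ex, L - ex, by = params$chimera_breakpoint_step)
  grid <- grid[grid >= 1L & grid < L]
  cand_ids <- character(0)
  mcum <- list()   # cumulative matches along the read, per candidate
  ccum <- list()   # cumulative coverage
  for (cand in candidates) {
    if (identical(cand$id, rec$id)) next
    offs <- seed_offsets(rec$residues, cand$residues)
    prof <- ungapped_profile(rv, seq_chars(cand$residues), offs)
    if (is.null(prof)) next
    cand_ids <- c(cand_ids, cand$id)
    mcum[[length(cand_ids)]] <- cumsum(prof$match)
    ccum[[length(cand_ids)]] <- cumsum(prof$cover)
  }
  if (length(cand_ids) == 0L) return(verdict(FALSE, 0, 0))
  total_m <- vapply(mcum, function(x) x[L], numeric(1))
  best_single <- max(total_m) / L
  if (length(cand_ids) < 2L || length(grid) == 0L) {
    return(verdict(FALSE, best_single, best_single))
  }
  best_chim <- -Inf
  best_pair <- NULL
  best_bp <- NULL
  for (b in grid) {
    lm <- vapply(mcum, `[[`, numeric(1), b)
    lc <- vapply(ccum, `[[`, numeric(1), b)
    rm <- total_m - lm
    rc <- vapply(ccum, function(x) x[L], numeric(1)) - lc
    lm[lc < 0.9 * b | lm < params$chimera_min_model_identity * b] <- -Inf
    rm[rc < 0.9 * (L - b) |
         rm < params$chimera_min_model_identity * (L - b)] <- -Inf
    lo <- order(lm, decreasing = TRUE)[seq_len(min(2L, length(lm)))]
    ro <- order(rm, decreasing = TRUE)[seq_len(min(2L, length(rm)))]
    for (i in lo) {
      for (j in ro) {
        if (i == j || !is.finite(lm[i]) || !is.finite(rm[j])) next
        chim <- (lm[i] + rm[j]) / L
        if (chim > best_chim) {
          best_chim <- chim
          best_pair <- c(cand_ids[i], cand_ids[j])
          best_bp <- b
        }
      }
    }
  }
  if (!is.finite(best_chim)) return(verdict(FALSE, best_single, best_single))
  is_chim <- best_chim - best_single >= params$chimera_min_improvement
  verdict(is_chim, best_single, best_chim,
          parents = if (is_chim) best_pair else NULL,
          breakpoint = if (is_chim) best_bp else NULL)
}

#' Build the environment-labelled reference from QC-passed reads
#'
#' Per environment: near-duplicate removal at `dedup_identity`, rRNA
#' screening, chimera removal, then greedy clustering at `otu_identity`.
#' Chimera screening is sequential in longest-first order: each
#' representative is tested with [detect_chimera] against the
#' representatives already accepted as non-chimeric, so a chimera can never
#' act as another read's parent. Cluster representatives become the
#' reference entries, numbered 1..R(e) within each environment. An
#' environment whose reads are all filtered out is omitted with a warning.
#'
#' @param reads_by_env Named list: environment label -> list of
#'   [seq_record] objects (at least one environment with >= 1 read).
#' @param screen_ref List of screening [seq_record]s (or a
#'   [build_screen_index] object).
#' @param params A [cluster_params].
#' @return A [reference_store]; its `"condense_report"` attribute is a data
#'   frame of per-environment, per-stage read accounting.
#' @export
build_reference <- function(reads_by_env, screen_ref,
                            params = cluster_params()) {
  stopifnot(is.list(reads_by_env), length(reads_by_env) > 0,
            !is.null(names(reads_by_env)), all(nzchar(names(reads_by_env))))
  idx <- if (inherits(screen_ref, "screen_index")) screen_ref
         else build_screen_index(screen_ref, params$kmer_size_screen)
  entries <- list()
  rep_rows <- list()
  for (env in names(reads_by_env)) {
    reads <- reads_by_env[[env]]
    n_in <- length(reads)
    if (n_in == 0L) {
      warning("environment '", env, "' has no reads; omitted from reference")
      next
    }
    clusters <- dedup_near_duplicates(reads, params$dedup_identity)
    reps <- lapply(clusters, `[[`, "representative")
    n_dedup <- n_in - length(reps)
    kept <- Filter(function(r) screen_rrna(r, idx, params)$keep, reps)
    n_screen <- length(reps) - length(kept)
    # sequential chimera screening in longest-first order: only reads
    # already accepted as non-chimeric can serve as parents, so two
    # chimeras with the same parent pair cannot vouch for each other
    accepted <- list()
    n_chim <- 0L
    for (i in greedy_order(kept)) {
      if (length(accepted) >= 2L &&
          detect_chimera(kept[[i]], accepted, params)$is_chimera) {
        n_chim <- n_chim + 1L
      } else {
        accepted[[length(accepted) + 1L]] <- kept[[i]]
      }
    }
    survivors <- accepted
    if (length(survivors) == 0L) {
      warning("environment '", env,
              "' lost all reads during condensing; omitted from reference")
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        env = env, input = n_in, dedup_removed = n_dedup,
        rrna_removed = n_screen, chimera_removed = n_chim,
        representatives = 0L, stringsAsFactors = FALSE)
      next
    }
    otus <- cluster_by_identity(survivors, params$otu_identity)
    entries[[length(entries) + 1L]] <- data.frame(
      env = env,
      ordinal = seq_along(otus),
      residues = vapply(otus, function(cl) cl$representative$residues,
                        character(1)),
      stringsAsFactors = FALSE)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      env = env, input = n_in, dedup_removed = n_dedup,
      rrna_removed = n_screen, chimera_removed = n_chim,
      representatives = length(otus), stringsAsFactors = FALSE)
  }
  if (length(entries) == 0L) {
    stop("empty reference store: all environments were filtered out")
  }
  store <- reference_store(do.call(rbind, entries))
  attr(store, "condense_report") <- do.call(rbind, rep_rows)
  store
}
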