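# Microbial Habitability Indices: per-threshold environment hit counts,
# inverse-document-frequency weighting, 100% normalization, "other"
# grouping, and per-query versus collective profiling.

#' Identity threshold set
#'
#' The default levels 0.97, 0.95, 0.90, 0.85, 0.80 correspond approximately
#' to the species, genus, family, order and class ranks of 16S rRNA
#' identity.
#'
#' @param levels Strictly decreasing identities in `(0, 1]`.
#' @return Validated numeric vector of class `threshold_set`.
#' @export
threshold_set <- function(levels = c(0.97, 0.95, 0.90, 0.85, 0.80)) {
  levels <- as.numeric(levels)
  stopifnot(length(levels) >= 1, all(levels > 0), all(levels <= 1),
            all(diff(levels) < 0))
  structure(levels, class = "threshold_set")
}

threshold_label <- function(level) {
  formatC(level * 100, format = "fg")
}

#' Count hits per environment above an identity threshold
#'
#' Each hit with identity at or above `c` contributes one count to its
#' environment (`N_c(e)`); hits below `c` are excluded.
#'
#' @param hits A `hit_table` from [search_reference] (or any data frame
#'   with `env` and `identity` columns).
#' @param c Identity threshold in `(0, 1]`.
#' @return Named integer vector `env -> N_c(e)` (empty when nothing
#'   qualifies).
#' @export
count_hits_per_env <- function(hits, c) {
  sel <- hits$env[hits$identity >= c]
  if (length(sel) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tb <- table(sel)
  stats::setNames(as.integer(tb), names(tb))
}

#' Compute MHI percentages from environment counts
#'
#' Each environment's count is weighted by the inverse-document-frequency
#' style factor `log(R_total / R(e))`, down-weighting environments that
#' contribute many sequences to the reference, and the weighted values are
#' normalized to percentages:
#' `MHI(e) = 100 * N_c(e) log(R_total/R(e)) / sum_e' N_c(e') log(R_total/R(e'))`.
#' The natural logarithm is used; the base is immaterial after
#' normalization. If every weight is zero (each counted environment equals
#' the whole store) an empty result flagged with attribute
#' `degenerate = TRUE` is returned with a warning instead of percentages.
#'
#' @param counts Named integer vector `env -> N_c(e)`.
#' @param store_counts A [reference_store], or a named vector of
#'   per-environment totals `R(e)` (then `total` must be given).
#' @param total `R_total`; taken from the store when one is supplied.
#' @return Named numeric vector of percentages summing to 100 (zero-count
#'   environments omitted), or a degenerate empty result (see above).
#' @export
compute_mhi <- function(counts, store_counts, total = NULL) {
  if (inherits(store_counts, "reference_store")) {
    total <- store_counts$total
    store_counts <- store_counts$counts_per_env
  }
  stopifnot(!is.null(total), total >= 1)
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  missing <- setdiff(names(counts), names(store_counts))
  if (length(missing)) {
    stop("environment not present in the reference store: ",
         paste(missing, collapse = ", "))
  }
  r <- store_counts[names(counts)]
  if (any(r <= 0)) stop("R(e) must be positive for every counted environment")
  if (any(r > total)) stop("R(e) cannot exceed R_total")
  raw <- counts * log(total / r)
  s <- sum(raw)
  if (s == 0) {
    warning("all IDF weights are zero (every counted environment spans the ",
            "whole store); MHI percentages are undefined")
    return(structure(stats::setNames(numeric(0), character(0)),
                     degenerate = TRUE))
  }
  100 * raw / s
}

#' Group sub-threshold environments into "other"
#'
#' Environments whose MHI is below `floor` percent are summarized under the
#' single key `"other"`; the total is preserved and `"other"` is omitted
#' when nothing falls below the floor.
#'
#' @param mhi Named numeric vector of percentages (summing to 100).
#' @param floor Percentage floor (default 1).
#' @return Named numeric vector; attribute `other_members` lists the
#'   grouped environments.
#' @export
group_other <- function(mhi, floor = 1.0) {
  if (length(mhi) == 0L) return(mhi)
  small <- mhi < floor
  if (!any(small)) {
    return(structure(mhi, other_members = character(0)))
  }
  out <- c(mhi[!small], other = sum(mhi[small]))
  structure(out, other_members = names(mhi)[small])
}

new_mhi_profile <- function(query_ids, per_threshold) {
  structure(list(query_ids = query_ids, per_threshold = per_threshold),
            class = "mhi_profile")
}

profile_from_counts <- function(query_ids, counts_by_level, thresholds,
                                store, other_floor) {
  per_threshold <- list()
  for (lv in as.numeric(thresholds)) {
    counts <- counts_by_level[[threshold_label(lv)]]
    if (is.null(counts) || sum(counts) == 0L) next
    mhi <- compute_mhi(counts, store)
    grouped <- group_other(mhi, other_floor)
    per_threshold[[threshold_label(lv)]] <-
      list(level = lv, n_hits = sum(counts), counts = counts,
           mhi_percent = mhi, grouped = grouped,
           other_members = attr(grouped, "other_members"))
  }
  new_mhi_profile(query_ids, per_threshold)
}

#' Profile one query's habitability
#'
#' Searches the query once against the store, then per identity threshold
#' counts hits by environment, computes MHI percentages and groups
#' sub-floor environments into `"other"`. Thresholds with no hits are
#' omitted from the profile. Queries shorter than 500 bp trigger a warning
#' (the ranking favours queries longer than the reference sequences).
#'
#' @param query A [seq_record].
#' @param store A [reference_store].
#' @param thresholds A [threshold_set].
#' @param params A [search_params].
#' @param other_floor Percentage floor of the "other" grouping.
#' @return Object of class `mhi_profile`: `query_ids` plus `per_threshold`,
#'   a list keyed by threshold label with `level`, `n_hits`, `counts`,
#'   `mhi_percent`, `grouped`, `other_members`.
#' @export
profile_query <- function(query, store, thresholds = threshold_set(),
                          params = search_params(), other_floor = 1.0) {
  stopifnot(inherits(store, "reference_store"))
  if (nchar(query$residues) < 500L) {
    warning("query '", query$id, "' is ", nchar(query$residues),
            " bp; queries longer than 500 bp are recommended")
  }
  hits <- search_reference(query, store, params)
  counts_by_level <- list()
  for (lv in as.numeric(thresholds)) {
    counts_by_level[[threshold_label(lv)]] <- count_hits_per_env(hits, lv)
  }
  profile_from_counts(query$id, counts_by_level, thresholds, store,
                      other_floor)
}

#' Profile multiple queries collectively
#'
#' In the default `"sum"` mode, per-query hit lists are computed
#' independently and, per threshold, the environment counts are summed
#' across queries before a single MHI computation. The alternative
#' `"mean"` mode averages the per-query MHI percentages instead (over the
#' queries that have the threshold column).
#'
#' @param queries Non-empty list of [seq_record] objects.
#' @param store A [reference_store].
#' @param thresholds A [threshold_set].
#' @param params A [search_params].
#' @param mode `"sum"` (count pooling, the primary mode) or `"mean"`.
#' @param other_floor Percentage floor of the "other" grouping.
#' @return An `mhi_profile` (see [profile_query]).
#' @export
profile_collective <- function(queries, store, thresholds = threshold_set(),
                               params = search_params(),
                               mode = c("sum", "mean"), other_floor = 1.0) {
  mode <- match.arg(mode)
  stopifnot(length(queries) >= 1)
  ids <- vapply(queries, `[[`, character(1), "id")
  if (mode == "sum") {
    pooled <- list()
    for (q in queries) {
      if (nchar(q$residues) < 500L) {
        warning("query '", q$id, "' is ", nchar(q$residues),
                " bp; queries longer than 500 bp are recommended")
      }
      hits <- search_reference(q, store, params)
      for (lv in as.numeric(thresholds)) {
        lab <- threshold_label(lv)
        counts <- count_hits_per_env(hits, lv)
        acc <- pooled[[lab]]
        if (is.null(acc)) {
          pooled[[lab]] <- counts
        } else {
          envs <- union(names(acc), names(counts))
          merged <- stats::setNames(integer(length(envs)), envs)
          merged[names(acc)] <- acc
          merged[names(counts)] <- merged[names(counts)] + counts
          pooled[[lab]] <- merged
        }
      }
    }
    return(profile_from_counts(ids, pooled, thresholds, store, other_floor))
  }
  profiles <- lapply(queries, profile_query, store = store,
                     thresholds = thresholds, params = params,
                     other_floor = other_floor)
  per_threshold <- list()
  for (lv in as.numeric(thresholds)) {
    lab <- threshold_label(lv)
    cols <- Filter(Negate(is.null),
                   lapply(profiles, function(p) p$per_threshold[[lab]]))
    if (length(cols) == 0L) next
    envs <- unique(unlist(lapply(cols, function(cl) names(cl$mhi_percent))))
    mat <- vapply(cols, function(cl) {
      v <- stats::setNames(numeric(length(envs)), envs)
      v[names(cl$mhi_percent)] <- cl$mhi_percent
      v
    }, numeric(length(envs)))
    mat <- matrix(mat, nrow = length(envs), dimnames = list(envs, NULL))
    mhi <- rowMeans(mat)
    counts <- Reduce(function(a, b) {
      u <- union(names(a), names(b))
      v <- stats::setNames(integer(length(u)), u)
      v[names(a)] <- a
      v[names(b)] <- v[names(b)] + b
      v
    }, lapply(cols, `[[`, "counts"))
    grouped <- group_other(mhi, other_floor)
    per_threshold[[lab]] <- list(level = lv, n_hits = sum(counts),
                                 counts = counts, mhi_percent = mhi,
                                 grouped = grouped,
                                 other_members = attr(grouped, "other_members"))
  }
  new_mhi_profile(ids, per_threshold)
}

#' Format a profile as a statistics text block
#'
#' One line per emitted threshold, in the style
#' `"(97%, 36 hits) freshwater: 88.15%; marine: 11.85%"`, environments in
#' descending MHI order with two decimals. An empty profile yields
#' `"no hits above any identity threshold"`.
#'
#' @param profile An `mhi_profile`.
#' @return Character vector of lines.
#' @export
format_statistics <- function(profile) {
  stopifnot(inherits(profile, "mhi_profile"))
  if (length(profile$per_threshold) == 0L) {
    return("no hits above any identity threshold")
  }
  vapply(profile$per_threshold, function(col) {
    g <- sort(col$grouped, decreasing = TRUE)
    sprintf("(%s%%, %d %s) %s",
            threshold_label(col$level), col$n_hits,
            if (col$n_hits == 1L) "hit" else "hits",
            paste(sprintf("%s: %.2f%%", names(g), g), collapse = "; "))
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.mhi_profile <- function(x, ...) {
  cat(sprintf("<mhi_profile> query: %s\n",
              paste(x$query_ids, collapse = ", ")))
  cat(format_statistics(x), sep = "\n")
  invisible(x)
}

#' Profile as a tidy table
#'
#' One row per (threshold, environment) with the grouped percentages
#' (sub-floor environments appear as `"other"`), suitable for bar plotting.
#'
#' @param profile An `mhi_profile`.
#' @return Data frame with columns `threshold`, `environment`, `n_hits`,
#'   `mhi_percent`.
#' @export
profile_to_csv <- function(profile) {
  rows <- lapply(profile$per_threshold, function(col) {
    g <- sort(col$grouped, decreasing = TRUE)
    n <- stats::setNames(integer(length(g)), names(g))
    for (e in names(g)) {
      n[[e]] <- if (e == "other") {
        sum(col$counts[col$other_members])
      } else {
        col$counts[[e]]
      }
    }
    data.frame(threshold = threshold_label(col$level),
               environment = names(g), n_hits = as.integer(n),
               mhi_percent = as.numeric(g), stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(threshold = character(), environment = character(),
               n_hits = integer(), mhi_percent = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Profile as a JSON-ready list (full precision)
#'
#' @param profile An `mhi_profile`.
#' @param provenance Optional provenance string embedded in the document.
#' @return A list mirroring the profile: per threshold `hits`, `counts`,
#'   `mhi_percent`, `other_members`.
#' @export
profile_to_json <- function(profile, provenance = NULL) {
  doc <- list(query_ids = profile$query_ids,
              per_threshold = lapply(profile$per_threshold, function(col) {
                list(level = col$level, hits = col$n_hits,
                     counts = as.list(col$counts),
                     mhi_percent = as.list(col$mhi_percent),
                     other_members = as.list(col$other_members))
              }))
  if (!is.null(provenance)) doc$`_provenance` <- provenance
  doc
}
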