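# Query-versus-reference search: seeded candidate selection, affine-gap
# local alignment on both strands, Karlin-Altschul e-values, and the
# sort-ratio ranking that feeds the MHI computation.

#' Search parameters
#'
#' Scoring mirrors common nucleotide-BLAST defaults (match +2, mismatch -3,
#' gap open 5, gap extend 2). `karlin_lambda` and `karlin_k` are the
#' constants of the e-value model `E = K m n exp(-lambda S)`; the defaults
#' (0.625, 0.41) are approximations appropriate for this scoring scheme,
#' without edge-effect or gapped recalibration.
#'
#' @param evalue_max Maximum e-value for a hit to be retained.
#' @param max_hits Cap on the number of significant hits kept (best by
#'   e-value) before ranking.
#' @param match_score,mismatch_penalty Substitution scores (penalty given
#'   as a negative number).
#' @param gap_open,gap_extend Affine gap penalties (positive; a gap of
#'   length L costs `gap_open + gap_extend * L`).
#' @param karlin_lambda,karlin_k E-value constants.
#' @param seed_kmer k-mer size of the candidate prefilter; any reference
#'   entry sharing at least one canonical seed with the query is aligned.
#' @return List of class `search_params`.
#' @export
search_params <- function(evalue_max = 1e-10, max_hits = 10000L,
                          match_score = 2, mismatch_penalty = -3,
                          gap_open = 5, gap_extend = 2,
                          karlin_lambda = 0.625, karlin_k = 0.41,
                          seed_kmer = 12L) {
  stopifnot(evalue_max > 0, max_hits >= 1, match_score > 0,
            mismatch_penalty < 0, gap_open >= 0, gap_extend > 0,
            karlin_lambda > 0, karlin_k > 0, seed_kmer >= 4L)
  structure(list(evalue_max = evalue_max, max_hits = as.integer(max_hits),
                 match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 seed_kmer = as.integer(seed_kmer)),
            class = "search_params")
}

subst_matrix <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch_penalty, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- params$match_score
  m["N", ] <- params$mismatch_penalty
  m[, "N"] <- params$mismatch_penalty
  m
}

# best local alignment of two sequence strings; returns score and the two
# aligned (gapped) strings
align_core <- function(pattern, subject, params = search_params()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = subst_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  list(score = Biostrings::score(aln),
       pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

# identity and shorter-sequence coverage of the best local alignment
# (forward strand); used by the 97% clustering
local_identity <- function(a, b, params = search_params()) {
  al <- align_core(a, b, params)
  p <- seq_chars(al$pattern)
  s <- seq_chars(al$subject)
  matches <- sum(p == s & p != "-")
  cols <- length(p)
  shorter <- min(nchar(a), nchar(b))
  span <- if (nchar(a) <= nchar(b)) sum(p != "-") else sum(s != "-")
  list(identity = if (cols > 0) matches / cols else 0,
       coverage_shorter = if (shorter > 0) span / shorter else 0)
}

#' Karlin-Altschul e-value
#'
#' `E = K * query_len * db_total_len * exp(-lambda * score)`; monotonically
#' decreasing in the score.
#'
#' @param score Alignment score (>= 0).
#' @param query_len Query length in bp (> 0).
#' @param db_total_len Total reference length in bp (> 0).
#' @param params A [search_params] supplying `karlin_lambda` and `karlin_k`.
#' @return The e-value.
#' @export
evalue <- function(score, query_len, db_total_len, params = search_params()) {
  if (query_len <= 0 || db_total_len <= 0) {
    stop("sequence lengths must be positive")
  }
  stopifnot(score >= 0)
  params$karlin_k * query_len * db_total_len *
    exp(-params$karlin_lambda * score)
}

#' Align a query against one reference sequence
#'
#' Best affine-gap local alignment on the given strand and on the reverse
#' complement of the query; the higher-scoring strand is reported (forward
#' on ties). Returns `NULL` when no alignment scores above zero.
#'
#' @param query,subject [seq_record] objects (non-empty).
#' @param params A [search_params].
#' @param db_total_len Reference length used in the e-value; defaults to
#'   the subject's own length, and is set to the full database length by
#'   [search_reference].
#' @return A list of class `alignment_hit` with fields `query_id`,
#'   `subject_id`, `strand`, `matches`, `aligned_columns`, `gaps_in_hit`
#'   (gap positions opened in the hit sequence), `hit_length` (full subject
#'   length), `score`, `evalue`, `identity` (matches / aligned columns) and
#'   `sort_key` (matches / (hit_length + gaps_in_hit)), or `NULL`.
#' @export
align_pair <- function(query, subject, params = search_params(),
                       db_total_len = nchar(subject$residues)) {
  stopifnot(nzchar(query$residues), nzchar(subject$residues))
  fwd <- align_core(query$residues, subject$residues, params)
  rev <- align_core(revcomp_str(query$residues), subject$residues, params)
  strand <- if (rev$score > fwd$score) "-" else "+"
  al <- if (strand == "-") rev else fwd
  if (al$score <= 0) return(NULL)
  p <- seq_chars(al$pattern)
  s <- seq_chars(al$subject)
  matches <- sum(p == s & p != "-")
  cols <- length(p)
  gaps_in_hit <- sum(s == "-")
  hit_length <- nchar(subject$residues)
  structure(list(query_id = query$id,
                 subject_id = subject$id,
                 strand = strand,
                 matches = matches,
                 aligned_columns = cols,
                 gaps_in_hit = gaps_in_hit,
                 hit_length = hit_length,
                 score = al$score,
                 evalue = evalue(al$score, nchar(query$residues),
                                 db_total_len, params),
                 identity = matches / cols,
                 sort_key = matches / (hit_length + gaps_in_hit)),
            class = "alignment_hit")
}

#' Search a query against the reference store
#'
#' Candidate entries are selected by a shared canonical seed k-mer
#' prefilter and aligned with [align_pair]; hits with e-value at most
#' `evalue_max` are kept, capped at the `max_hits` best by e-value, and
#' finally ranked by `sort_key` (the ratio of matched bases to hit length
#' plus gaps opened in the hit) descending, with ties broken by e-value
#' ascending and then `(env, ordinal)`.
#'
#' @param query A [seq_record].
#' @param store A [reference_store].
#' @param params A [search_params].
#' @return A data frame of class `hit_table`, one row per hit in rank
#'   order: `query_id`, `env`, `ordinal`, `strand`, `matches`,
#'   `aligned_columns`, `gaps_in_hit`, `hit_length`, `score`, `evalue`,
#'   `identity`, `sort_key`.
#' @export
search_reference <- function(query, store, params = search_params()) {
  stopifnot(inherits(store, "reference_store"))
  entries <- store$entries
  db_total_len <- sum(nchar(entries$residues))
  qk <- canonical_kmers(query$residues, params$seed_kmer)
  hits <- list()
  for (i in seq_len(nrow(entries))) {
    sk <- canonical_kmers(entries$residues[i], params$seed_kmer)
    if (!any(sk %in% qk)) next
    subject <- seq_record(paste(entries$env[i], entries$ordinal[i], sep = "."),
                          entries$residues[i])
    hit <- align_pair(query, subject, params, db_total_len = db_total_len)
    if (is.null(hit) || hit$evalue > params$evalue_max) next
    hits[[length(hits) + 1L]] <-
      data.frame(query_id = query$id, env = entries$env[i],
                 ordinal = entries$ordinal[i], strand = hit$strand,
                 matches = hit$matches, aligned_columns = hit$aligned_columns,
                 gaps_in_hit = hit$gaps_in_hit, hit_length = hit$hit_length,
                 score = hit$score, evalue = hit$evalue,
                 identity = hit$identity, sort_key = hit$sort_key,
                 stringsAsFactors = FALSE)
  }
  tab <- if (length(hits)) do.call(rbind, hits) else
    data.frame(query_id = character(), env = character(), ordinal = integer(),
               strand = character(), matches = integer(),
               aligned_columns = integer(), gaps_in_hit = integer(),
               hit_length = integer(), score = numeric(), evalue = numeric(),
               identity = numeric(), sort_key = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(tab) > params$max_hits) {
    keep <- order(tab$evalue, tab$env, tab$ordinal)[seq_len(params$max_hits)]
    tab <- tab[keep, , drop = FALSE]
  }
  tab <- tab[order(-tab$sort_key, tab$evalue, tab$env, tab$ordinal), ,
             drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("hit_table", "data.frame")
  tab
}

#' Write a ranked hit table as TSV
#'
#' One row per hit in rank order; identity is reported in percent.
#'
#' @param hits A `hit_table` from [search_reference].
#' @param path Output path.
#' @param header_comment Optional `#` comment line(s).
#' @export
write_hits_tsv <- function(hits, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  out <- data.frame(query_id = hits$query_id, env = hits$env,
                    ordinal = hits$ordinal,
                    identity_pct = round(100 * hits$identity, 2),
                    matches = hits$matches,
                    aligned_columns = hits$aligned_columns,
                    gaps_in_hit = hits$gaps_in_hit, score = hits$score,
                    evalue = format(hits$evalue, digits = 3),
                    sort_key = round(hits$sort_key, 6),
                    stringsAsFactors = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
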