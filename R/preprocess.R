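# Read quality control: 3' quality trimming, adapter removal, ambiguity
# filtering, homopolymer trimming, and the 200-bp length floor applied after
# every trimming stage.

QC_STAGES <- c("quality", "adapter", "ambiguous", "homopolymer")

#' Quality-control parameters
#'
#' Defaults follow the amplicon-curation conventions this package targets:
#' bases under Phred 20 are trimmed from the 3' end, reads shorter than
#' 200 bp are dropped after every trimming stage, and homopolymer runs of
#' 5 bp or longer truncate the read.
#'
#' @param quality_floor Phred threshold; 3' bases below it are trimmed.
#' @param min_length Minimum surviving read length in bp.
#' @param homopolymer_min_run Minimum single-base run length that triggers
#'   truncation.
#' @param adapters Character vector of 3' adapter sequences to remove
#'   (empty = skip the adapter stage).
#' @param adapter_min_overlap Minimum read/adapter overlap in bp.
#' @param adapter_max_error_rate Maximum mismatch fraction in the overlap.
#' @return List of class `qc_params`.
#' @export
qc_params <- function(quality_floor = 20L, min_length = 200L,
                      homopolymer_min_run = 5L, adapters = character(),
                      adapter_min_overlap = 3L, adapter_max_error_rate = 0.1) {
  stopifnot(quality_floor >= 0, min_length >= 1, homopolymer_min_run >= 2,
            adapter_min_overlap >= 1,
            adapter_max_error_rate >= 0, adapter_max_error_rate < 0.5)
  adapters <- toupper(as.character(adapters))
  structure(list(quality_floor = as.integer(quality_floor),
                 min_length = as.integer(min_length),
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 adapters = adapters,
                 adapter_min_overlap = as.integer(adapter_min_overlap),
                 adapter_max_error_rate = adapter_max_error_rate),
            class = "qc_params")
}

truncate_record <- function(rec, keep) {
  res <- substr(rec$residues, 1L, keep)
  qual <- if (is.null(rec$qualities)) NULL else rec$qualities[seq_len(keep)]
  structure(list(id = rec$id, residues = if (keep > 0L) res else "",
                 qualities = qual),
            class = "seq_record")
}

#' Trim low-quality 3' tails
#'
#' Removes the longest suffix whose bases all fall below `floor`; residues
#' and qualities are truncated together. Trimming is 3'-only: pyrosequencing
#' and similar long-read amplicon chemistries accumulate error towards the
#' 3' end.
#'
#' @param rec A [seq_record] with qualities.
#' @param floor Phred threshold.
#' @return The trimmed record (possibly empty; a downstream length filter
#'   removes such reads).
#' @export
trim_quality <- function(rec, floor = 20L) {
  if (is.null(rec$qualities)) stop("record lacks quality scores")
  q <- rec$qualities
  ok <- which(q >= floor)
  keep <- if (length(ok)) max(ok) else 0L
  if (keep == length(q)) rec else truncate_record(rec, keep)
}

#' Remove 3' adapter sequence
#'
#' Finds the best semi-global match of any configured adapter: the adapter
#' may start anywhere in the read and run off its 3' end, with at most
#' `adapter_max_error_rate` mismatches over an overlap of at least
#' `adapter_min_overlap`. The match and everything 3' of it are removed;
#' with no match the record is returned unchanged.
#'
#' @param rec A [seq_record].
#' @param params A [qc_params] supplying `adapters`, `adapter_min_overlap`,
#'   `adapter_max_error_rate`.
#' @return The (possibly trimmed) record.
#' @export
remove_adapters <- function(rec, params = qc_params()) {
  if (length(params$adapters) == 0L || !nzchar(rec$residues)) return(rec)
  rv <- seq_chars(rec$residues)
  rlen <- length(rv)
  best_score <- -Inf
  best_start <- 0L
  for (ad in params$adapters) {
    av <- seq_chars(ad)
    alen <- length(av)
    for (s in seq_len(rlen)) {
      ov <- min(alen, rlen - s + 1L)
      if (ov < params$adapter_min_overlap) next
      mism <- sum(rv[s + seq_len(ov) - 1L] != av[seq_len(ov)])
      if (mism > floor(params$adapter_max_error_rate * ov)) next
      score <- (ov - mism) - mism
      if (score > best_score) {
        best_score <- score
        best_start <- s
      }
    }
  }
  if (best_start == 0L) rec else truncate_record(rec, best_start - 1L)
}

#' Ambiguity filter
#'
#' Keep decision for a read: `TRUE` iff the residues are non-empty and
#' contain only `A`, `C`, `G`, `T`. Reads with any ambiguous base are
#' discarded whole (not trimmed).
#'
#' @param rec A [seq_record].
#' @return Logical keep decision.
#' @export
filter_ambiguous <- function(rec) {
  nzchar(rec$residues) && !grepl("[^ACGT]", rec$residues)
}

#' Truncate at long homopolymer runs
#'
#' The read is cut immediately before the first single-base run of length
#' `min_run` or more; the 5' prefix is kept. Reads without such a run are
#' returned unchanged.
#'
#' @param rec A [seq_record].
#' @param min_run Minimum run length triggering truncation (>= 2).
#' @return The (possibly truncated) record.
#' @export
trim_homopolymers <- function(rec, min_run = 5L) {
  stopifnot(min_run >= 2L)
  if (!nzchar(rec$residues)) return(rec)
  r <- rle(seq_chars(rec$residues))
  bad <- which(r$lengths >= min_run)
  if (length(bad) == 0L) return(rec)
  keep <- if (bad[1L] == 1L) 0L else sum(r$lengths[seq_len(bad[1L] - 1L)])
  truncate_record(rec, keep)
}

#' Run the full QC cascade
#'
#' Stages are applied in order quality trim, adapter removal, ambiguity
#' filter, homopolymer trim. After each trimming stage, reads shorter than
#' `min_length` are removed and attributed to that stage; reads lacking
#' quality scores are removed at the quality stage.
#'
#' @param reads List of [seq_record] objects.
#' @param params A [qc_params].
#' @return List with `records` (survivors, in input order) and `report`
#'   (a `qc_report`: input/surviving counts plus per-stage removed read and
#'   trimmed base counts).
#' @export
run_qc <- function(reads, params = qc_params()) {
  removed <- stats::setNames(integer(length(QC_STAGES)), QC_STAGES)
  trimmed <- stats::setNames(integer(length(QC_STAGES)), QC_STAGES)
  out <- vector("list", length(reads))
  n_out <- 0L
  for (rec in reads) {
    if (is.null(rec$qualities)) {
      removed[["quality"]] <- removed[["quality"]] + 1L
      next
    }
    r1 <- trim_quality(rec, params$quality_floor)
    trimmed[["quality"]] <- trimmed[["quality"]] +
      nchar(rec$residues) - nchar(r1$residues)
    if (nchar(r1$residues) < params$min_length) {
      removed[["quality"]] <- removed[["quality"]] + 1L
      next
    }
    r2 <- remove_adapters(r1, params)
    trimmed[["adapter"]] <- trimmed[["adapter"]] +
      nchar(r1$residues) - nchar(r2$residues)
    if (nchar(r2$residues) < params$min_length) {
      removed[["adapter"]] <- removed[["adapter"]] + 1L
      next
    }
    if (!filter_ambiguous(r2)) {
      removed[["ambiguous"]] <- removed[["ambiguous"]] + 1L
      next
    }
    r3 <- trim_homopolymers(r2, params$homopolymer_min_run)
    trimmed[["homopolymer"]] <- trimmed[["homopolymer"]] +
      nchar(r2$residues) - nchar(r3$residues)
    if (nchar(r3$residues) < params$min_length) {
      removed[["homopolymer"]] <- removed[["homopolymer"]] + 1L
      next
    }
    n_out <- n_out + 1L
    out[[n_out]] <- r3
  }
  report <- structure(list(input_count = length(reads),
                           surviving_count = n_out,
                           removed_by_stage = removed,
                           trimmed_bases_by_stage = trimmed),
                      class = "qc_report")
  stopifnot(report$input_count ==
              report$surviving_count + sum(report$removed_by_stage))
  list(records = out[seq_len(n_out)], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d in, %d surviving\n",
              x$input_count, x$surviving_count))
  for (s in names(x$removed_by_stage)) {
    cat(sprintf("  %-12s removed %5d reads, trimmed %7d bases\n",
                s, x$removed_by_stage[[s]], x$trimmed_bases_by_stage[[s]]))
  }
  invisible(x)
}

# merge per-file reports into one
combine_qc_reports <- function(reports) {
  structure(list(
    input_count = sum(vapply(reports, `[[`, integer(1), "input_count")),
    surviving_count = sum(vapply(reports, `[[`, integer(1), "surviving_count")),
    removed_by_stage = Reduce(`+`, lapply(reports, `[[`, "removed_by_stage")),
    trimmed_bases_by_stage =
      Reduce(`+`, lapply(reports, `[[`, "trimmed_bases_by_stage"))),
    class = "qc_report")
}

qc_report_list <- function(report) {
  list(input_count = report$input_count,
       surviving_count = report$surviving_count,
       removed_by_stage = as.list(report$removed_by_stage),
       trimmed_bases_by_stage = as.list(report$trimmed_bases_by_stage))
}
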