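# Sequence records, FASTA/FASTQ input/output, and the environment-labelled
# reference store.

#' Create a sequence record
#'
#' The basic unit handled by the package: an identified nucleotide sequence
#' with optional per-base Phred quality scores. Residues are upper-cased and
#' RNA `U` is mapped to `T` on construction.
#'
#' @param id Character identifier (non-empty).
#' @param residues Nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param qualities Optional integer vector of Phred scores, one per residue.
#' @param allow_empty Permit an empty residue string (used internally for
#'   fully trimmed reads that a downstream length filter will drop).
#' @return A list of class `seq_record` with elements `id`, `residues`,
#'   `qualities`.
#' @export
seq_record <- function(id, residues, qualities = NULL, allow_empty = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("record id must be a non-empty string")
  }
  residues <- chartr("u", "T", chartr("U", "T", toupper(residues)))
  if (!allow_empty && !nzchar(residues)) {
    stop("record '", id, "' has an empty sequence")
  }
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(residues)) {
      stop("record '", id, "': qualities length (", length(qualities),
           ") does not match sequence length (", nchar(residues), ")")
    }
  }
  structure(list(id = id, residues = residues, qualities = qualities),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp%s)\n", x$id, nchar(x$residues),
              if (is.null(x$qualities)) "" else ", with qualities"))
  invisible(x)
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Read a FASTA file
#'
#' Returns records in file order. Multi-line sequences are concatenated;
#' blank lines and `;` comment lines are skipped. Malformed input (sequence
#' data before any header, or a header with no sequence) raises an error
#' naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return List of [seq_record] objects (qualities absent).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  id <- NULL
  header_line <- 0L
  pieces <- character()
  flush <- function() {
    if (is.null(id)) return()
    seq <- paste(pieces, collapse = "")
    if (!nzchar(seq)) {
      stop("FASTA record '", id, "' (header at line ", header_line,
           ") has no sequence")
    }
    records[[length(records) + 1L]] <<- seq_record(id, seq)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, ";")) next
    if (startsWith(ln, ">")) {
      flush()
      id <- trimws(substring(ln, 2L))
      if (!nzchar(id)) stop("malformed FASTA header at line ", i)
      header_line <- i
      pieces <- character()
    } else {
      if (is.null(id)) stop("sequence data before any header at line ", i)
      pieces <- c(pieces, trimws(ln))
    }
  }
  flush()
  records
}

#' Write records to FASTA
#'
#' @param records List of [seq_record] objects.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @param header_comment Optional character vector written as leading `;`
#'   comment lines (skipped by [read_fasta]).
#' @export
write_fasta <- function(records, path, width = 70L, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("; ", header_comment), con)
  }
  for (rec in records) {
    writeLines(paste0(">", rec$id), con)
    n <- nchar(rec$residues)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(rec$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' Expects the 4-line-per-record layout. Quality strings are decoded to
#' integer Phred scores; characters below `!` are rejected as non-Phred+33.
#' A quality line whose length differs from its sequence line is a parse
#' error naming the line.
#'
#' @param path Path to a FASTQ file.
#' @return List of [seq_record] objects with qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) && !nzchar(lines[[length(lines)]])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ: ", length(lines),
         " lines is not a multiple of 4 in ", path)
  }
  n <- length(lines) %/% 4L
  records <- vector("list", n)
  for (k in seq_len(n)) {
    base <- (k - 1L) * 4L
    hdr <- lines[[base + 1L]]
    seq <- lines[[base + 2L]]
    plus <- lines[[base + 3L]]
    qual <- lines[[base + 4L]]
    if (!startsWith(hdr, "@")) stop("expected '@' header at line ", base + 1L)
    if (!startsWith(plus, "+")) stop("expected '+' separator at line ", base + 3L)
    if (nchar(seq) != nchar(qual)) {
      stop("quality length (", nchar(qual), ") does not match sequence length (",
           nchar(seq), ") at line ", base + 4L)
    }
    if (!nzchar(qual)) {
      stop("record without quality scores at line ", base + 4L)
    }
    q <- utf8ToInt(qual) - 33L
    if (any(q < 0L)) stop("quality characters below '!' at line ", base + 4L,
                          ": not Phred+33")
    id <- trimws(sub("\\s.*$", "", substring(hdr, 2L)))
    records[[k]] <- seq_record(id, seq, qualities = q)
  }
  records
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records List of [seq_record] objects; all must carry qualities.
#' @param path Output path.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (rec in records) {
    if (is.null(rec$qualities)) {
      stop("record '", rec$id, "' lacks quality scores; cannot write FASTQ")
    }
    writeLines(c(paste0("@", rec$id), rec$residues, "+",
                 intToUtf8(rec$qualities + 33L)), con)
  }
  invisible(path)
}

#' Construct a reference store
#'
#' An environment-labelled collection of representative sequences, together
#' with the per-environment counts `R(e)` and total `R_total` that enter the
#' MHI weighting.
#'
#' @param entries Data frame with columns `env` (character), `ordinal`
#'   (positive integer, unique within `env`), `residues` (character).
#' @return Object of class `reference_store`: a list with `entries`,
#'   `counts_per_env` (named integer, `R(e)`), and `total` (`R_total`).
#' @export
reference_store <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0L) stop("empty reference store")
  stopifnot(all(c("env", "ordinal", "residues") %in% names(entries)))
  entries$env <- as.character(entries$env)
  entries$ordinal <- as.integer(entries$ordinal)
  entries$residues <- as.character(entries$residues)
  if (any(!nzchar(entries$env))) stop("empty environment label in reference store")
  if (any(entries$ordinal < 1L)) stop("reference ordinals must be >= 1")
  if (any(!nzchar(entries$residues))) stop("empty sequence in reference store")
  key <- paste(entries$env, entries$ordinal, sep = ".")
  if (anyDuplicated(key)) {
    stop("duplicated reference entry: ", key[duplicated(key)][1L])
  }
  envs <- unique(entries$env)
  counts <- vapply(envs, function(e) sum(entries$env == e), integer(1))
  structure(list(entries = entries,
                 counts_per_env = counts,
                 total = nrow(entries)),
            class = "reference_store")
}

#' @export
print.reference_store <- function(x, ...) {
  cat(sprintf("<reference_store> %d sequences across %d environments\n",
              x$total, length(x$counts_per_env)))
  for (e in names(x$counts_per_env)) {
    cat(sprintf("  %-24s R(e) = %d\n", e, x$counts_per_env[[e]]))
  }
  invisible(x)
}

#' Load a labelled reference FASTA
#'
#' Headers must follow the `<env>.<ordinal>` convention, split on the final
#' dot so environment labels may themselves contain dots or spaces
#' (e.g. `human gut.12`).
#'
#' @param path Path to a reference FASTA.
#' @return A [reference_store].
#' @export
load_reference <- function(path) {
  records <- read_fasta(path)
  if (length(records) == 0L) stop("empty reference store: ", path)
  ids <- vapply(records, `[[`, character(1), "id")
  ok <- grepl("^.+\\.[0-9]+$", ids)
  if (any(!ok)) {
    stop("reference header does not follow '<env>.<ordinal>': '",
         ids[!ok][1L], "'")
  }
  reference_store(data.frame(
    env = sub("\\.[0-9]+$", "", ids),
    ordinal = as.integer(sub("^.*\\.", "", ids)),
    residues = vapply(records, `[[`, character(1), "residues"),
    stringsAsFactors = FALSE))
}

#' Export a reference store to FASTA
#'
#' Within each environment `E` entries are written as `E.1`, `E.2`, ... in
#' ordinal order; the result round-trips bit-exactly through
#' [load_reference].
#'
#' @param store A [reference_store].
#' @param path Output path.
#' @param header_comment Optional `;` comment line(s).
#' @export
export_reference <- function(store, path, header_comment = NULL) {
  stopifnot(inherits(store, "reference_store"))
  records <- list()
  for (e in names(store$counts_per_env)) {
    sub <- store$entries[store$entries$env == e, , drop = FALSE]
    sub <- sub[order(sub$ordinal), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      records[[length(records) + 1L]] <-
        seq_record(paste(e, sub$ordinal[i], sep = "."), sub$residues[i])
    }
  }
  write_fasta(records, path, header_comment = header_comment)
}

# reference entries as seq_records (ids follow the header convention)
store_records <- function(store) {
  lapply(seq_len(nrow(store$entries)), function(i) {
    seq_record(paste(store$entries$env[i], store$entries$ordinal[i], sep = "."),
               store$entries$residues[i])
  })
}
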