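# Ground-truthed synthetic data: per-environment 16S-like templates,
# artifact-laden amplicon reads for the QC/condense pipeline, and
# divergence-controlled queries for habitat-recovery tests.

SIM_BASES <- c("A", "C", "G", "T")

SIM_ENV_VOCAB <- c("soil", "marine", "human gut", "freshwater", "sediment",
                   "compost", "hot springs", "bovine gut", "rhizosphere",
                   "wastewater")

#' Simulation parameters
#'
#' Defaults define the package's reference study conditions: two
#' environments of five templates each, 1000-bp templates at ~15% pairwise
#' divergence, 200 prefix-anchored reads of 250-400 bp at 1% divergence
#' from their template, and artifact rates of 15% duplicates, 5% chimeras,
#' 5% too-short reads and 5% ambiguous reads. Reads are 5'-anchored
#' template prefixes (amplicon primer anchoring), and per-read mutations
#' sit on strided position lattices so pairwise read divergence is
#' controlled exactly (~2x `read_divergence`); see the methods vignette.
#'
#' @param n_envs Number of environmental categories.
#' @param templates_per_env Templates per environment.
#' @param template_len Template length in bp (>= 4x the read minimum).
#' @param template_divergence Target pairwise divergence between templates.
#' @param n_reads Total number of reads to emit.
#' @param read_len_range Length range (bp) of the template-derived insert.
#' @param read_divergence Per-read substitution divergence from the
#'   template (lattice density).
#' @param rate_duplicate,rate_chimera,rate_short,rate_ambiguous Per-read
#'   artifact probabilities (the remainder are genuine reads).
#' @param adapter 3' adapter appended to reads, or `NULL` for none.
#' @param quality_profile Named numeric vector `c(high=, low=, decay=)`:
#'   insert/adapter Phred score, the tail's final score, and the length of
#'   the planted low-quality 3' tail (every tail base is below 20 so the
#'   expected trim point is the adapter boundary).
#' @param envs Environment labels (defaults to a built-in vocabulary).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_envs = 2L, templates_per_env = 5L,
                       template_len = 1000L, template_divergence = 0.15,
                       n_reads = 200L, read_len_range = c(250L, 400L),
                       read_divergence = 0.01, rate_duplicate = 0.15,
                       rate_chimera = 0.05, rate_short = 0.05,
                       rate_ambiguous = 0.05, adapter = "AGTCAGTCAGTC",
                       quality_profile = c(high = 38, low = 10, decay = 60),
                       envs = NULL, seed = 1L) {
  rates <- c(rate_duplicate, rate_chimera, rate_short, rate_ambiguous)
  stopifnot(n_envs >= 1, templates_per_env >= 1, template_len >= 1,
            n_reads >= 1, length(read_len_range) == 2,
            read_len_range[1] <= read_len_range[2],
            template_len >= 4 * read_len_range[1],
            read_divergence >= 0, read_divergence < 0.5,
            template_divergence >= 0, template_divergence < 1,
            all(rates >= 0), all(rates <= 1), sum(rates) <= 1,
            all(c("high", "low", "decay") %in% names(quality_profile)),
            quality_profile[["high"]] >= 20, quality_profile[["low"]] >= 0,
            quality_profile[["low"]] < 20, quality_profile[["decay"]] >= 1)
  if (is.null(envs)) {
    if (n_envs > length(SIM_ENV_VOCAB)) {
      envs <- paste0("env", seq_len(n_envs))
    } else {
      envs <- SIM_ENV_VOCAB[seq_len(n_envs)]
    }
  }
  stopifnot(length(envs) == n_envs)
  if (!is.null(adapter)) adapter <- toupper(adapter)
  structure(list(n_envs = as.integer(n_envs),
                 templates_per_env = as.integer(templates_per_env),
                 template_len = as.integer(template_len),
                 template_divergence = template_divergence,
                 n_reads = as.integer(n_reads),
                 read_len_range = as.integer(read_len_range),
                 read_divergence = read_divergence,
                 rate_duplicate = rate_duplicate,
                 rate_chimera = rate_chimera,
                 rate_short = rate_short,
                 rate_ambiguous = rate_ambiguous,
                 adapter = adapter,
                 quality_profile = quality_profile,
                 envs = envs,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# random sequence with no two adjacent equal bases; substitutions that also
# avoid both neighbours can then never build a homopolymer run, keeping the
# homopolymer filter inert on non-planted artifacts
random_adjacent_distinct <- function(len) {
  out <- character(len)
  out[1L] <- sample(SIM_BASES, 1L)
  for (i in seq_len(len - 1L) + 1L) {
    out[i] <- sample(setdiff(SIM_BASES, out[i - 1L]), 1L)
  }
  out
}

# substitute the given positions with a base differing from the original and
# from both neighbours
mutate_positions <- function(chars, positions) {
  n <- length(chars)
  for (p in positions) {
    forbid <- chars[p]
    if (p > 1L) forbid <- c(forbid, chars[p - 1L])
    if (p < n) forbid <- c(forbid, chars[p + 1L])
    allowed <- setdiff(SIM_BASES, forbid)
    chars[p] <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }
  chars
}

#' Generate per-environment template sequences
#'
#' All templates are drawn by substitution-mutating a common ancestor at
#' `template_divergence / 2` so that pairwise template divergence (within
#' and between environments) is approximately `template_divergence`.
#' Deterministic under the seed.
#'
#' @param params A [sim_params].
#' @return Named list `env -> named character vector of templates`
#'   (`t1`, `t2`, ...); the ancestor is attached as attribute `"ancestor"`.
#' @export
generate_templates <- function(params = sim_params()) {
  set.seed(params$seed)
  len <- params$template_len
  ancestor <- random_adjacent_distinct(len)
  m <- round(len * params$template_divergence / 2)
  out <- list()
  for (env in params$envs) {
    tmpls <- character(params$templates_per_env)
    for (j in seq_len(params$templates_per_env)) {
      chars <- ancestor
      if (m > 0) chars <- mutate_positions(chars, sample(len, m))
      tmpls[j] <- paste(chars, collapse = "")
    }
    names(tmpls) <- paste0("t", seq_len(params$templates_per_env))
    out[[env]] <- tmpls
  }
  attr(out, "ancestor") <- paste(ancestor, collapse = "")
  out
}

# low-quality 3' tail: random bases whose scores ramp linearly below the
# trimming floor
make_tail <- function(params) {
  decay <- as.integer(params$quality_profile[["decay"]])
  list(residues = paste(sample(SIM_BASES, decay, replace = TRUE),
                        collapse = ""),
       qualities = as.integer(round(seq(19, params$quality_profile[["low"]],
                                        length.out = decay))))
}

assemble_read <- function(id, insert, params, with_adapter = TRUE,
                          with_tail = TRUE) {
  high <- as.integer(params$quality_profile[["high"]])
  res <- insert
  qual <- rep(high, nchar(insert))
  if (with_adapter && !is.null(params$adapter)) {
    res <- paste0(res, params$adapter)
    qual <- c(qual, rep(high, nchar(params$adapter)))
  }
  if (with_tail) {
    tail <- make_tail(params)
    res <- paste0(res, tail$residues)
    qual <- c(qual, tail$qualities)
  }
  seq_record(id, res, qualities = qual)
}

#' Simulate artifact-laden reads with ground truth
#'
#' Reads are 5'-anchored prefixes of their template, substitution-mutated
#' on a per-read strided position lattice (stride `1 / read_divergence`,
#' distinct lattice offsets per read) so that two reads of the same
#' template diverge by almost exactly `2 * read_divergence`. Artifacts are
#' planted per read with the configured probabilities and recorded in the
#' truth table: exact prefix duplicates of earlier genuine reads, two-parent
#' same-environment chimeras (breakpoint in the middle 40-70% of the read),
#' short inserts (150-199 bp), and reads with planted `N` bases. Every read
#' carries a high-quality body and a sub-Phred-20 3' tail; the adapter, when
#' configured, sits between body and tail.
#'
#' @param templates Output of [generate_templates].
#' @param params A [sim_params].
#' @return List with `reads` (list of [seq_record]) and `truth` (data frame
#'   with one row per read: `id`, `env`, `template`, `type`,
#'   `duplicate_of`, `parent_left`, `parent_right`, `breakpoint`,
#'   `insert_len`).
#' @export
simulate_reads <- function(templates, params = sim_params()) {
  stopifnot(length(templates) > 0)
  set.seed(params$seed + 1L)
  # lattice spacing of the planted substitutions (divergence 0 = none)
  stride <- if (params$read_divergence > 0) {
    max(2L, as.integer(round(min(1 / params$read_divergence,
                                 params$template_len + 1))))
  } else {
    params$template_len + 1L
  }
  lattice <- list()   # per (env, template): shuffled lattice offsets + counter
  next_offset <- function(env, tmpl) {
    key <- paste0(env, "\r", tmpl)
    st <- lattice[[key]]
    if (is.null(st)) st <- list(perm = sample(stride), used = 0L)
    st$used <- st$used + 1L
    lattice[[key]] <<- st
    st$perm[((st$used - 1L) %% stride) + 1L]
  }
  mutate_insert <- function(chars, offset) {
    if (params$read_divergence == 0 || offset > length(chars)) return(chars)
    mutate_positions(chars, seq.int(offset, length(chars), by = stride))
  }
  types <- c("genuine", "duplicate", "chimera", "short", "ambiguous")
  probs <- c(1 - params$rate_duplicate - params$rate_chimera -
               params$rate_short - params$rate_ambiguous,
             params$rate_duplicate, params$rate_chimera,
             params$rate_short, params$rate_ambiguous)
  minl <- params$read_len_range[1]
  maxl <- params$read_len_range[2]
  reads <- vector("list", params$n_reads)
  truth <- vector("list", params$n_reads)
  genuine_pool <- list()   # id, insert, env, template
  warned_chimera <- FALSE
  for (i in seq_len(params$n_reads)) {
    id <- sprintf("r%04d", i)
    env <- sample(params$envs, 1L)
    type <- sample(types, 1L, prob = probs)
    if (type == "duplicate" && length(genuine_pool) == 0L) type <- "genuine"
    if (type == "chimera" && params$templates_per_env < 2L) {
      if (!warned_chimera) {
        warning("chimera planting requires >= 2 templates per environment; ",
                "emitting genuine reads instead")
        warned_chimera <- TRUE
      }
      type <- "genuine"
    }
    row <- list(id = id, env = env, template = NA_character_, type = type,
                duplicate_of = NA_character_, parent_left = NA_character_,
                parent_right = NA_character_, breakpoint = NA_integer_,
                insert_len = NA_integer_)
    if (type == "duplicate") {
      src <- genuine_pool[[sample(length(genuine_pool), 1L)]]
      dlen <- sample(seq.int(minl - 20L, nchar(src$insert)), 1L)
      insert <- substr(src$insert, 1L, dlen)
      reads[[i]] <- assemble_read(id, insert, params)
      row$env <- src$env
      row$template <- src$template
      row$duplicate_of <- src$id
      row$insert_len <- dlen
    } else if (type == "chimera") {
      pair <- sample(names(templates[[env]]), 2L)
      len <- minl
      a <- seq_chars(substr(templates[[env]][[pair[1L]]], 1L, len))
      b <- seq_chars(substr(templates[[env]][[pair[2L]]], 1L, len))
      bp <- sample(seq.int(round(0.4 * len), round(0.7 * len)), 1L)
      joined <- c(a[seq_len(bp)], b[seq.int(bp + 1L, len)])
      insert <- mutate_insert(joined, next_offset(env, pair[1L]))
      reads[[i]] <- assemble_read(id, paste(insert, collapse = ""), params)
      row$template <- pair[1L]
      row$parent_left <- pair[1L]
      row$parent_right <- pair[2L]
      row$breakpoint <- bp
      row$insert_len <- len
    } else {
      tmpl <- sample(names(templates[[env]]), 1L)
      len <- if (type == "short") sample(150:199, 1L) else
        sample(seq.int(minl, maxl), 1L)
      chars <- seq_chars(substr(templates[[env]][[tmpl]], 1L, len))
      chars <- mutate_insert(chars, next_offset(env, tmpl))
      if (type == "ambiguous") {
        chars[sample(len, sample(2:4, 1L))] <- "N"
      }
      insert <- paste(chars, collapse = "")
      reads[[i]] <- assemble_read(id, insert, params,
                                  with_adapter = type != "short",
                                  with_tail = type != "short")
      row$template <- tmpl
      row$insert_len <- len
      if (type == "genuine") {
        genuine_pool[[length(genuine_pool) + 1L]] <-
          list(id = id, insert = insert, env = env, template = tmpl)
      }
    }
    truth[[i]] <- row
  }
  truth <- do.call(rbind, lapply(truth, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  list(reads = reads, truth = truth)
}

#' Generate a divergence-controlled query
#'
#' A 5' fragment of one of `env`'s templates, substitution-mutated at the
#' given per-base rate (mismatch count is binomial around
#' `divergence * length`).
#'
#' @param templates Output of [generate_templates].
#' @param env Environment label present in `templates`.
#' @param divergence Per-base substitution probability.
#' @param length Query length in bp (capped at the template length with a
#'   warning).
#' @param seed Optional seed for this draw.
#' @return A [seq_record]; attribute `"truth"` records the source
#'   environment and template.
#' @export
generate_query <- function(templates, env, divergence, length = 600L,
                           seed = NULL) {
  if (!env %in% names(templates)) stop("unknown environment: ", env)
  if (!is.null(seed)) set.seed(seed)
  tmpl <- sample(names(templates[[env]]), 1L)
  full <- templates[[env]][[tmpl]]
  if (length > nchar(full)) {
    warning("requested query length ", length, " exceeds template length ",
            nchar(full), "; truncating")
    length <- nchar(full)
  }
  chars <- seq_chars(substr(full, 1L, length))
  pos <- which(stats::runif(length) < divergence)
  if (length(pos)) chars <- mutate_positions(chars, pos)
  rec <- seq_record(sprintf("q_%s_%s", gsub("[^A-Za-z0-9]+", "_", env), tmpl),
                    paste(chars, collapse = ""))
  attr(rec, "truth") <- list(env = env, template = tmpl)
  rec
}

#' Simulate a full corpus (templates + reads + screening reference)
#'
#' Runs [generate_templates] and [simulate_reads] under the single seed in
#' `params`; the rRNA screening reference emitted alongside the reads is
#' the template set itself. Optionally writes everything to a directory in
#' the formats the command-line workflow consumes.
#'
#' @param params A [sim_params].
#' @param dir Optional output directory (created if needed); see
#'   [write_simulation].
#' @return List of class `sim_corpus`: `params`, `templates`, `reads`,
#'   `truth`, `screen_ref`.
#' @export
simulate_corpus <- function(params = sim_params(), dir = NULL) {
  templates <- generate_templates(params)
  sim <- simulate_reads(templates, params)
  screen_ref <- list()
  for (env in names(templates)) {
    for (t in names(templates[[env]])) {
      screen_ref[[length(screen_ref) + 1L]] <-
        seq_record(sprintf("screen_%s_%s", gsub("[^A-Za-z0-9]+", "_", env), t),
                   templates[[env]][[t]])
    }
  }
  corpus <- structure(list(params = params, templates = templates,
                           reads = sim$reads, truth = sim$truth,
                           screen_ref = screen_ref),
                      class = "sim_corpus")
  if (!is.null(dir)) write_simulation(corpus, dir)
  corpus
}

#' Group simulated reads by their true source environment
#'
#' @param corpus A `sim_corpus` (or the list returned by [simulate_reads]
#'   plus its truth table).
#' @return Named list `env -> list of reads`, suitable for
#'   [build_reference] after QC.
#' @export
sim_reads_by_env <- function(corpus) {
  out <- list()
  for (i in seq_along(corpus$reads)) {
    env <- corpus$truth$env[i]
    out[[env]] <- c(out[[env]], corpus$reads[i])
  }
  out
}

#' Write a simulated corpus to disk
#'
#' Emits one FASTQ per environment, the `file<TAB>env` mapping TSV, the
#' screening reference FASTA, the template FASTA, and a JSON truth file.
#'
#' @param corpus A `sim_corpus`.
#' @param dir Output directory.
#' @return Invisibly, the named list of written paths.
#' @export
write_simulation <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  by_env <- sim_reads_by_env(corpus)
  map <- data.frame(file = character(), env = character(),
                    stringsAsFactors = FALSE)
  paths <- list()
  for (env in names(by_env)) {
    slug <- gsub("[^A-Za-z0-9]+", "_", env)
    fq <- sprintf("reads_%s.fastq", slug)
    write_fastq(by_env[[env]], file.path(dir, fq))
    map <- rbind(map, data.frame(file = fq, env = env,
                                 stringsAsFactors = FALSE))
    paths[[paste0("fastq_", slug)]] <- file.path(dir, fq)
  }
  paths$env_map <- file.path(dir, "env_map.tsv")
  utils::write.table(map, paths$env_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$screen_ref <- file.path(dir, "screen_ref.fasta")
  write_fasta(corpus$screen_ref, paths$screen_ref)
  tmpl_recs <- list()
  for (env in names(corpus$templates)) {
    for (t in names(corpus$templates[[env]])) {
      tmpl_recs[[length(tmpl_recs) + 1L]] <-
        seq_record(sprintf("template_%s_%s",
                           gsub("[^A-Za-z0-9]+", "_", env), t),
                   corpus$templates[[env]][[t]])
    }
  }
  paths$templates <- file.path(dir, "templates.fasta")
  write_fasta(tmpl_recs, paths$templates)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(seed = corpus$params$seed,
                            envs = corpus$params$envs,
                            truth = corpus$truth),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
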