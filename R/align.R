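# Seeded pairwise nucleotide search: affine-gap Smith-Waterman core (C++),
# BLAST-style e-values, and a k-mer seeded database search used both to
# annotate flagged OTUs and to recruit amplicons onto MAG 16S genes.

#' Default alignment scoring scheme
#'
#' Match/mismatch/gap parameters in the style of ungapped BLASTN conventions.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param match Match reward (positive).
#' @param mismatch Mismatch penalty (negative).
#' @param gap_open Gap opening penalty (negative).
#' @param gap_extend Per-base gap extension penalty (negative).
#' @return Named list of the four scores.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L) {
  if (match <= 0 || mismatch >= 0 || gap_open > 0 || gap_extend >= 0) {
    ts_abort("scoring must have match > 0 and penalties < 0", "ts_config_error")
  }
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Karlin-Altschul e-value parameters
#'
#' @param K Prefactor (> 0).
#' @param lambda Scale per score unit (> 0).
#' @param m Query length in nt.
#' @param n Total database length in nt.
#' @return Named list of parameters.
#' @export
evalue_params <- function(K = 0.711, lambda = 1.374, m, n) {
  if (K <= 0 || lambda <= 0) {
    ts_abort("K and lambda must be positive", "ts_config_error")
  }
  list(K = K, lambda = lambda, m = as.numeric(m), n = as.numeric(n))
}

#' Expectation value of an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`.
#'
#' @param score Integer alignment score(s).
#' @param params Parameters from [evalue_params()].
#' @return Numeric expectation value(s).
#' @export
evalue <- function(score, params) {
  params$K * params$m * params$n * exp(-params$lambda * score)
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Affine-gap Smith-Waterman with IUPAC-aware matching: an aligned column
#' counts as a match iff the two codes' IUPAC sets intersect, and such
#' columns count toward the aligned length. Identity is
#' `matches / aligned columns * 100` over the local alignment (no end gaps
#' by construction); query coverage is
#' `aligned query positions / query length * 100`. Ties are broken
#' deterministically: highest score, then smallest query start, then
#' smallest subject start.
#'
#' @param query,subject Either single sequence strings or one-row sequence
#'   tibbles (`id`, `seq`).
#' @param scoring A [scoring_scheme()].
#' @param eval_params Optional [evalue_params()]; when `NULL`, defaults with
#'   `m` = query length and `n` = subject length are used.
#' @param strand Strand label recorded in the result (the caller aligns the
#'   reverse complement for minus-strand searches).
#' @return One-row tibble: `query_id`, `subject_id`, `score`, `identity`,
#'   `query_coverage`, `evalue`, `strand`, `q_start`, `q_end`, `s_start`,
#'   `s_end` (0-based half-open), `n_columns`, `n_matches`.
#' @export
#' @examples
#' align_pair("ACGTACGTAC", "ACGTACGTAC")
align_pair <- function(query, subject, scoring = scoring_scheme(),
                       eval_params = NULL, strand = "+") {
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  sid <- if (is.data.frame(subject)) subject$id[1] else "subject"
  q <- if (is.data.frame(query)) query$seq[1] else query
  s <- if (is.data.frame(subject)) subject$seq[1] else subject
  if (is.na(q) || is.na(s) || !nzchar(q) || !nzchar(s)) {
    ts_abort("sequences must be non-empty", "ts_input_error")
  }
  q <- toupper(q); s <- toupper(s)
  r <- .sw_align_cpp(q, s, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend)
  if (is.null(eval_params)) {
    eval_params <- evalue_params(m = nchar(q), n = nchar(s))
  }
  tibble::tibble(
    query_id = qid, subject_id = sid,
    score = as.integer(r$score),
    identity = r$identity,
    query_coverage = r$query_coverage,
    evalue = evalue(r$score, eval_params),
    strand = strand,
    q_start = as.integer(r$qstart), q_end = as.integer(r$qend),
    s_start = as.integer(r$sstart), s_end = as.integer(r$send),
    n_columns = as.integer(r$ncol), n_matches = as.integer(r$nmatch)
  )
}

#' Build a k-mer seed index over a reference database
#'
#' Postings are complete for every exact k-mer of every subject on the sense
#' strand; queries are searched as-is and reverse-complemented.
#'
#' @param db Reference tibble with columns `id`, `seq`, and optionally
#'   `taxonomy` and `environment_source`.
#' @param k Word size (>= 4).
#' @return A `seed_index` object.
#' @export
build_index <- function(db, k = 8L) {
  k <- as.integer(k)
  if (k < 4L) ts_abort("word size k must be >= 4", "ts_config_error")
  if (all(nchar(db$seq) < k)) {
    ts_abort("k exceeds the length of every subject", "ts_index_error")
  }
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(db))) {
    s <- db$seq[i]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    for (w in unique(kmers)) {
      postings[[w]] <- c(postings[[w]], i)
    }
  }
  structure(list(k = k, postings = postings, db = db,
                 total_length = sum(nchar(db$seq))),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> k=%d over %d subjects (%d nt)\n",
              x$k, nrow(x$db), x$total_length))
  invisible(x)
}

index_candidates <- function(index, seq) {
  n <- nchar(seq) - index$k + 1L
  if (n < 1L) return(integer(0))
  kmers <- unique(substring(seq, seq_len(n), seq_len(n) + index$k - 1L))
  hits <- unlist(lapply(kmers, function(w) index$postings[[w]]),
                 use.names = FALSE)
  sort(unique(hits))
}

#' Search a query against a seeded reference index
#'
#' Candidate subjects sharing at least one exact seed with the query (on
#' either strand) are fully aligned with [align_pair()]; results are ranked
#' by score (ties: lower e-value, then lexicographic subject id) and at most
#' `top_k` are returned, each carrying the subject's `taxonomy` and
#' `environment_source` when the database provides them.
#'
#' @param query A sequence string or one-row sequence tibble.
#' @param index A [build_index()] result.
#' @param top_k Maximum number of hits (default 10, the number of closest
#'   reference matches reported per flagged OTU).
#' @param scoring A [scoring_scheme()].
#' @param eval_params Optional [evalue_params()]; defaults use the query
#'   length and the total database length.
#' @return Tibble of ranked alignment results (possibly empty).
#' @export
seed_search <- function(query, index, top_k = 10L,
                        scoring = scoring_scheme(), eval_params = NULL) {
  qid <- if (is.data.frame(query)) query$id[1] else "query"
  q <- toupper(if (is.data.frame(query)) query$seq[1] else query)
  if (is.null(eval_params)) {
    eval_params <- evalue_params(m = nchar(q), n = index$total_length)
  }
  qrc <- rev_comp(q)
  cand_fwd <- index_candidates(index, q)
  cand_rev <- index_candidates(index, qrc)
  cand <- union(cand_fwd, cand_rev)
  if (length(cand) == 0L) return(empty_hits())
  rows <- lapply(cand, function(i) {
    srec <- index$db[i, ]
    best <- NULL
    if (i %in% cand_fwd) {
      best <- align_pair(seq_tbl(qid, q), srec, scoring, eval_params, "+")
    }
    if (i %in% cand_rev) {
      r <- align_pair(seq_tbl(qid, qrc), srec, scoring, eval_params, "-")
      if (is.null(best) || r$score > best$score) best <- r
    }
    best$subject_id <- srec$id
    best$taxonomy <- if (!is.null(srec$taxonomy)) srec$taxonomy else NA_character_
    best$environment_source <-
      if (!is.null(srec$environment_source)) srec$environment_source else NA_character_
    best
  })
  hits <- dplyr::bind_rows(rows)
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$evalue,
                         .data$subject_id)
  head(hits, top_k)
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), score = integer(),
    identity = numeric(), query_coverage = numeric(), evalue = numeric(),
    strand = character(), q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(), n_columns = integer(),
    n_matches = integer(), taxonomy = character(),
    environment_source = character()
  )
}
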