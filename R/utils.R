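# Internal helpers: error signalling, seeded RNG scopes, sequence utilities.

ts_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "taxonsluice_error"), ...)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    ts_abort("`seed` must be a single integer", "ts_spec_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Reverse-complement a nucleotide string
#'
#' Complements every IUPAC code (ambiguity codes map to the complement of
#' their set, e.g. `R` -> `Y`) and reverses the sequence.
#'
#' @param x Character vector of nucleotide sequences (IUPAC codes).
#' @return Character vector of the same length.
#' @export
#' @examples
#' rev_comp("ACGTR")
rev_comp <- function(x) {
  vapply(x, function(s) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAString(s))
    as.character(rc)
  }, character(1), USE.NAMES = FALSE)
}

assert_dna <- function(seqs, what = "sequence") {
  bad <- !grepl("^[ACGTURYSWKMBDHVNacgturyswkmbdhvn]+$", seqs)
  if (any(is.na(seqs)) || any(bad) || any(!nzchar(seqs))) {
    ts_abort(
      paste0(what, " must be non-empty and restricted to IUPAC nucleotide codes"),
      "ts_format_error"
    )
  }
  invisible(toupper(seqs))
}

# named character vector of sequences -> tibble(id, seq, description)
seq_tbl <- function(ids, seqs, description = "") {
  tibble::tibble(id = as.character(ids), seq = toupper(as.character(seqs)),
                 description = description)
}
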