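# Independent brute-force dynamic-programming oracle for local alignment,
# written in plain R against the documented contract: affine gaps costing
# gap_open + L * gap_extend, IUPAC-intersection matching, identity over the
# columns of the local alignment, coverage over aligned query positions,
# ties resolved by smallest (query start, subject start, query end,
# subject end) with traceback preferring diagonal, then up, then left, and
# gap states preferring to close the gap.

iupac_mask_r <- function(chars) {
  table <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
             S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L,
             V = 7L, N = 15L)
  m <- unname(table[chars])
  m[is.na(m)] <- 0L
  m
}

oracle_align <- function(q, s, scoring = list(match = 2L, mismatch = -3L,
                                              gap_open = -5L,
                                              gap_extend = -2L)) {
  qm <- iupac_mask_r(strsplit(toupper(q), "")[[1]])
  sm <- iupac_mask_r(strsplit(toupper(s), "")[[1]])
  m <- length(qm); n <- length(sm)
  NEGINF <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEGINF, m + 1, n + 1)
  F_ <- matrix(NEGINF, m + 1, n + 1)
  go_ge <- scoring$gap_open + scoring$gap_extend
  ge <- scoring$gap_extend
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] + go_ge, E[i, j - 1] + ge)
      F_[i, j] <- max(H[i - 1, j] + go_ge, F_[i - 1, j] + ge)
      sub <- if (bitwAnd(qm[i - 1], sm[j - 1]) > 0) scoring$match
             else scoring$mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F_[i, j])
    }
  }
  best <- max(H)
  if (best <= 0) {
    return(list(score = 0L, identity = 0, query_coverage = 0,
                qstart = 0L, qend = 0L, sstart = 0L, send = 0L))
  }
  cells <- which(H == best, arr.ind = TRUE)
  cells <- cells[order(cells[, 1], cells[, 2]), , drop = FALSE]
  bt <- NULL
  for (r in seq_len(nrow(cells))) {
    ei <- unname(cells[r, 1]); ej <- unname(cells[r, 2])
    i <- ei; j <- ej; state <- "H"; ncol <- 0L; nmatch <- 0L
    repeat {
      if (state == "H") {
        if (H[i, j] == 0) break
        sub <- if (bitwAnd(qm[i - 1], sm[j - 1]) > 0) scoring$match
               else scoring$mismatch
        if (H[i, j] == H[i - 1, j - 1] + sub) {
          ncol <- ncol + 1L
          if (bitwAnd(qm[i - 1], sm[j - 1]) > 0) nmatch <- nmatch + 1L
          i <- i - 1L; j <- j - 1L
        } else if (H[i, j] == F_[i, j]) {
          state <- "F"
        } else {
          state <- "E"
        }
      } else if (state == "F") {
        ncol <- ncol + 1L
        state <- if (F_[i, j] == H[i - 1, j] + go_ge) "H" else "F"
        i <- i - 1L
      } else {
        ncol <- ncol + 1L
        state <- if (E[i, j] == H[i, j - 1] + go_ge) "H" else "E"
        j <- j - 1L
      }
    }
    cand <- list(qstart = i - 1L, sstart = j - 1L, qend = ei - 1L,
                 send = ej - 1L, ncol = ncol, nmatch = nmatch)
    better <- is.null(bt) ||
      cand$qstart < bt$qstart ||
      (cand$qstart == bt$qstart && cand$sstart < bt$sstart) ||
      (cand$qstart == bt$qstart && cand$sstart == bt$sstart &&
         cand$qend < bt$qend) ||
      (cand$qstart == bt$qstart && cand$sstart == bt$sstart &&
         cand$qend == bt$qend && cand$send < bt$send)
    if (better) bt <- cand
  }
  list(score = as.integer(best),
       identity = 100 * bt$nmatch / bt$ncol,
       query_coverage = 100 * (bt$qend - bt$qstart) / m,
       qstart = bt$qstart, qend = bt$qend,
       sstart = bt$sstart, send = bt$send)
}

# Exhaustive search oracle: align the query against every database record on
# both strands, rank by score, then e-value, then subject id.
oracle_search <- function(query, db, top_k = 10L,
                          scoring = list(match = 2L, mismatch = -3L,
                                         gap_open = -5L, gap_extend = -2L),
                          K = 0.711, lambda = 1.374) {
  n_total <- sum(nchar(db$seq))
  qrc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(query)))
  rows <- lapply(seq_len(nrow(db)), function(i) {
    fwd <- oracle_align(query, db$seq[i], scoring)
    rev <- oracle_align(qrc, db$seq[i], scoring)
    r <- if (rev$score > fwd$score) c(rev, strand = "-") else
      c(fwd, strand = "+")
    data.frame(subject_id = db$id[i], score = r$score,
               identity = r$identity,
               evalue = K * nchar(query) * n_total * exp(-lambda * r$score),
               strand = r$strand)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$evalue, out$subject_id), , drop = FALSE]
  head(out, top_k)
}
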