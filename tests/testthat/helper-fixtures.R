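# Shared test utilities: small sequence constructors with controlled edits.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Substitute bases at given 1-based positions (deterministic: next base in
# alphabet order), keeping edits >= 2 nt from either end when interior=TRUE.
substitute_at <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1]]
  for (p in positions) {
    alt <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    chars[p] <- alt
  }
  paste(chars, collapse = "")
}

# A small count table with explicit counts and roles.
toy_table <- function(counts, roles) {
  count_table(counts, roles)
}

# A database in which every record carries a fixed seed tag and its reverse
# complement, so a query derived from any record is seeded against every
# record on both strands and seeded search must equal the exhaustive
# ranking.
seeded_db <- function(n, tag = "ACGTTGCA") {
  rctag <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tag)))
  tibble::tibble(
    id = sprintf("ref%02d", seq_len(n)),
    seq = replicate(n, paste0(rand_seq(40), tag, rand_seq(60), rctag,
                              rand_seq(40))),
    taxonomy = NA_character_,
    environment_source = NA_character_
  )
}

# Mutate only the middle segment (positions 49..108) of a seeded_db record,
# leaving both seed tags intact.
mutate_seeded <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  substitute_at(seq, sample(49:108, n_sub))
}
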