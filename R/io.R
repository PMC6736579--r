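# Readers/writers for every external format the toolkit touches.
#
# Coordinate conventions: external GFF3 and depth files are 1-based inclusive
# (their standards); everything returned to callers uses 0-based half-open
# intervals. Conversion happens only here, at the I/O boundary.

ROLE_LEVELS <- c("blank", "specimen")

#' Construct and validate an OTU count table
#'
#' A `count_table` is a wide tibble with an `otu_id` column followed by one
#' integer column per sample, carrying a `roles` attribute mapping each
#' sample to `"blank"` or `"specimen"`.
#'
#' @param counts A data frame with an `otu_id` column and one numeric column
#'   per sample. Counts must be non-negative integers.
#' @param roles Named character vector (`sample_id -> role`) or a data frame
#'   with columns `sample_id` and `role`. Roles must be `"blank"` or
#'   `"specimen"` and cover every sample column.
#' @return A tibble of class `count_table`.
#' @export
count_table <- function(counts, roles) {
  counts <- tibble::as_tibble(counts)
  if (!"otu_id" %in% names(counts)) {
    names(counts)[1] <- "otu_id"
  }
  counts$otu_id <- as.character(counts$otu_id)
  sample_ids <- setdiff(names(counts), "otu_id")
  if (length(sample_ids) == 0L) {
    ts_abort("count table has no sample columns", "ts_format_error")
  }
  if (anyDuplicated(counts$otu_id)) {
    ts_abort("duplicate otu_id values in count table", "ts_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    ts_abort("duplicate sample columns in count table", "ts_format_error")
  }
  mat <- as.matrix(counts[sample_ids])
  if (!is.numeric(mat) || anyNA(mat) || any(mat < 0) ||
      any(mat != floor(mat))) {
    ts_abort("counts must be non-negative integers", "ts_format_error")
  }
  counts[sample_ids] <- lapply(counts[sample_ids], as.integer)

  if (is.data.frame(roles)) {
    roles <- setNames(as.character(roles$role), as.character(roles$sample_id))
  }
  missing <- setdiff(sample_ids, names(roles))
  if (length(missing) > 0L) {
    ts_abort(
      paste0("samples missing from roles manifest: ",
             paste(missing, collapse = ", ")),
      "ts_manifest_error"
    )
  }
  roles <- roles[sample_ids]
  if (!all(roles %in% ROLE_LEVELS)) {
    ts_abort("roles must be 'blank' or 'specimen'", "ts_manifest_error")
  }
  structure(counts,
            roles = roles,
            class = c("count_table", class(counts)))
}

#' @export
print.count_table <- function(x, ...) {
  r <- sample_roles(x)
  cat(sprintf("<count_table> %d OTUs x %d samples (%d blank, %d specimen)\n",
              nrow(x), length(r), sum(r == "blank"), sum(r == "specimen")))
  NextMethod()
}

#' Sample roles of a count table
#'
#' @param x A `count_table`.
#' @return Named character vector mapping sample id to role.
#' @export
sample_roles <- function(x) {
  r <- attr(x, "roles", exact = TRUE)
  if (is.null(r)) ts_abort("object carries no sample roles", "ts_manifest_error")
  r
}

sample_ids <- function(x) setdiff(names(x), "otu_id")

count_matrix <- function(x) {
  m <- as.matrix(x[sample_ids(x)])
  rownames(m) <- x$otu_id
  m
}

#' Read a sample-role manifest
#'
#' A two-column TSV (`sample_id`, `role`); a header line is optional.
#'
#' @param path Path to the manifest.
#' @return Named character vector (`sample_id -> role`).
#' @export
read_roles <- function(path) {
  if (!file.exists(path)) {
    ts_abort(paste0("roles manifest not found: ", path), "ts_manifest_error")
  }
  tbl <- readr::read_tsv(path, col_names = c("sample_id", "role"),
                         col_types = "cc", progress = FALSE)
  if (nrow(tbl) > 0 && identical(tolower(tbl$sample_id[1]), "sample_id")) {
    tbl <- tbl[-1, ]
  }
  if (nrow(tbl) == 0L || anyDuplicated(tbl$sample_id)) {
    ts_abort("roles manifest must list each sample exactly once",
             "ts_manifest_error")
  }
  setNames(tbl$role, tbl$sample_id)
}

#' Read an OTU count table
#'
#' Two dialects are supported: `plain_tsv` (rows = OTUs, first column OTU id,
#' remaining columns samples) and `mothur_shared` (rows = samples, with
#' `label`, `Group` and `numOtus` columns; `Group` becomes the sample id and
#' the bookkeeping columns are dropped). Both parse to the same logical
#' table.
#'
#' @param path Path to the table.
#' @param dialect `"plain_tsv"` or `"mothur_shared"`.
#' @param roles_path Path to the sample-role manifest (see [read_roles()]).
#' @param roles Optional named role vector, used instead of `roles_path`.
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, dialect = c("plain_tsv", "mothur_shared"),
                             roles_path = NULL, roles = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    ts_abort(paste0("count table not found: ", path), "ts_format_error")
  }
  if (is.null(roles)) {
    if (is.null(roles_path)) {
      ts_abort("either `roles_path` or `roles` is required", "ts_manifest_error")
    }
    roles <- read_roles(roles_path)
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (dialect == "mothur_shared") {
    lower <- tolower(names(raw))
    drop <- lower %in% c("label", "numotus")
    grp <- which(lower == "group")
    if (length(grp) != 1L) {
      ts_abort("mothur shared file lacks a Group column", "ts_format_error")
    }
    otu_cols <- names(raw)[!drop & lower != "group"]
    if (anyDuplicated(raw[[grp]])) {
      ts_abort("duplicate Group (sample) rows in shared file", "ts_format_error")
    }
    wide <- tibble::tibble(otu_id = otu_cols)
    for (i in seq_len(nrow(raw))) {
      wide[[as.character(raw[[grp]][i])]] <-
        as.numeric(unlist(raw[i, otu_cols], use.names = FALSE))
    }
    raw <- wide
  } else {
    names(raw)[1] <- "otu_id"
  }
  count_table(raw, roles)
}

#' Write an OTU count table as plain wide TSV
#'
#' @param x A `count_table` (or compatible tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(as.data.frame(x)), path, progress = FALSE)
  invisible(path)
}

#' Write an OTU count table in the mothur shared dialect
#'
#' Rows are samples, with `label`, `Group` and `numOtus` bookkeeping
#' columns; [read_count_table()] with `dialect = "mothur_shared"` parses it
#' back to the identical logical table.
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @param label Value of the mothur `label` column.
#' @return `path`, invisibly.
#' @export
write_mothur_shared <- function(x, path, label = "0.03") {
  m <- count_matrix(x)
  out <- dplyr::bind_cols(
    tibble::tibble(label = label, Group = colnames(m),
                   numOtus = nrow(m)),
    tibble::as_tibble(t(m))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` (upper-cased), `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    ts_abort(paste0("FASTA not found: ", path), "ts_format_error")
  }
  set <- Biostrings::readDNAStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(set))
  assert_dna(seqs, "FASTA sequence")
  seq_tbl(ids, seqs, desc)
}

#' Write sequences to a FASTA file
#'
#' @param x A tibble with columns `id`, `seq` and optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  if ("description" %in% names(x)) {
    nm <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
    names(set) <- nm
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Keeps rows whose `type` is in `types` (by default rRNA and gene records)
#' and converts coordinates to 0-based half-open intervals.
#'
#' @param path Path to a GFF3 file.
#' @param types Feature types to retain.
#' @return A tibble with columns `gene_id`, `contig_id`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`).
#' @export
read_gff3_genes <- function(path, types = c("rRNA", "gene")) {
  if (!file.exists(path)) {
    ts_abort(paste0("GFF3 not found: ", path), "ts_format_error")
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  g <- g[as.character(g$type) %in% types, , drop = FALSE]
  strand <- as.character(g$strand)
  if (any(!strand %in% c("+", "-"))) {
    ts_abort("GFF3 gene rows must have strand '+' or '-'", "ts_format_error")
  }
  if (any(g$end < g$start)) {
    ts_abort("GFF3 record with end < start", "ts_format_error")
  }
  id <- if ("ID" %in% names(g)) as.character(g$ID) else NA_character_
  if (all(is.na(id)) && "Name" %in% names(g)) id <- as.character(g$Name)
  if (any(is.na(id))) {
    ts_abort("GFF3 gene rows must carry an ID attribute", "ts_format_error")
  }
  out <- tibble::tibble(
    gene_id = id,
    contig_id = as.character(g$seqid),
    start = as.integer(g$start) - 1L,   # to 0-based half-open
    end = as.integer(g$end),
    strand = strand
  )
  if ("mag_id" %in% names(g)) out$mag_id <- as.character(g$mag_id)
  out
}

#' Extract gene sequences from contigs, on the sense strand
#'
#' Minus-strand genes are reverse-complemented here so that all downstream
#' comparisons are on the gene's sense strand.
#'
#' @param contigs Sequence tibble (`id`, `seq`) of contigs.
#' @param genes Gene tibble as returned by [read_gff3_genes()].
#' @return Sequence tibble (`id` = gene id, `seq`, `description` naming the
#'   parent contig).
#' @export
extract_genes <- function(contigs, genes) {
  lookup <- setNames(contigs$seq, contigs$id)
  miss <- setdiff(genes$contig_id, names(lookup))
  if (length(miss) > 0L) {
    ts_abort(paste0("genes reference unknown contigs: ",
                    paste(miss, collapse = ", ")), "ts_format_error")
  }
  seqs <- purrr::pmap_chr(genes, function(gene_id, contig_id, start, end,
                                          strand, ...) {
    s <- substr(lookup[[contig_id]], start + 1L, end)
    if (strand == "-") rev_comp(s) else s
  })
  seq_tbl(genes$gene_id, seqs, description = genes$contig_id)
}

#' Read a samtools-depth-style per-base depth table
#'
#' Three tab-separated columns (contig, 1-based position, depth), no header.
#' Positions absent from the file are interpreted as depth 0.
#'
#' @param path Path to the depth table.
#' @return A tibble with columns `contig_id`, `pos` (1-based) and `depth`.
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) {
    ts_abort(paste0("depth table not found: ", path), "ts_format_error")
  }
  d <- readr::read_tsv(path, col_names = c("contig_id", "pos", "depth"),
                       col_types = "cii", progress = FALSE)
  if (anyNA(d$pos) || anyNA(d$depth) || any(d$depth < 0) || any(d$pos < 1)) {
    ts_abort("depth table must have positive positions and depth >= 0",
             "ts_format_error")
  }
  ok <- unlist(tapply(d$pos, d$contig_id, function(p) all(diff(p) > 0)),
               use.names = FALSE)
  if (!all(ok)) {
    ts_abort("depth positions must be strictly increasing per contig",
             "ts_format_error")
  }
  d
}

#' Write a per-base depth table
#'
#' @param x Depth tibble as returned by [read_depth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth <- function(x, path) {
  readr::write_tsv(x[c("contig_id", "pos", "depth")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Dense per-base depth over a 0-based half-open interval; absent positions 0.
depth_vector <- function(depth, contig_id, start = 0L, end = NULL) {
  d <- depth[depth$contig_id == contig_id, , drop = FALSE]
  if (is.null(end)) end <- if (nrow(d) > 0) max(d$pos) else 0L
  len <- end - start
  if (len <= 0L) ts_abort("empty interval for depth extraction", "ts_input_error")
  v <- integer(len)
  keep <- d$pos > start & d$pos <= end
  v[d$pos[keep] - start] <- d$depth[keep]
  v
}

#' Serialize a report
#'
#' JSON reports preserve all fields (lossless round-trip) and include the
#' report's `version` and `parameters` blocks; TSV serializes the tabular
#' part of the report only.
#'
#' @param report A named list (JSON) or data frame (either format). Lists
#'   written as TSV must contain a data frame element named `table` or
#'   `records`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
  } else {
    tbl <- if (is.data.frame(report)) {
      report
    } else if (!is.null(report$table)) {
      report$table
    } else if (!is.null(report$records)) {
      report$records
    } else {
      ts_abort("report has no tabular component for TSV output",
               "ts_format_error")
    }
    tbl <- tibble::as_tibble(tbl)
    tbl <- tbl[!vapply(tbl, is.list, logical(1))]
    readr::write_tsv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON report.
#' @return The deserialized report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
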