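# Partition MAGs into biofilm-linked vs planktonic fractions by amplicon
# recruitment, with a 16S coverage-uniformity QC replacing the manual
# inspection step, and OTU-by-metagenome read recruitment.

#' Amplicon-to-MAG linking configuration
#'
#' Defaults follow the conventional recruitment thresholds (99% identity
#' over 90% of the amplicon length). The QC bounds quantify "uniform enough"
#' read coverage over a reconstructed 16S gene: the coefficient of variation
#' of per-base gene depth must not exceed `cv_max`, and the gene/contig mean
#' depth ratio must fall within `[ratio_lo, ratio_hi]`; all boundaries
#' inclusive.
#'
#' @param min_identity Minimum percent identity (default 99.0).
#' @param min_query_coverage Minimum percent query coverage (default 90.0).
#' @param cv_max Maximum coefficient of variation of per-base gene depth.
#' @param ratio_lo,ratio_hi Bounds on gene/contig mean-depth ratio.
#' @return Named list of class `link_config`.
#' @export
link_config <- function(min_identity = 99.0, min_query_coverage = 90.0,
                        cv_max = 1.0, ratio_lo = 0.25, ratio_hi = 4.0) {
  if (min_identity <= 0 || min_identity > 100 ||
      min_query_coverage <= 0 || min_query_coverage > 100) {
    ts_abort("identity and coverage thresholds must lie in (0, 100]",
             "ts_config_error")
  }
  structure(list(min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 cv_max = cv_max, ratio_lo = ratio_lo, ratio_hi = ratio_hi),
            class = "link_config")
}

#' Coverage-uniformity QC for reconstructed 16S genes
#'
#' For each gene, computes the mean per-base depth over the gene, the
#' coefficient of variation (population standard deviation / mean) of that
#' per-base profile, and the ratio of gene mean depth to the parent contig's
#' mean depth. A gene passes iff `cv <= cv_max` and
#' `ratio_lo <= depth_ratio <= ratio_hi` (inclusive). A gene with zero mean
#' depth fails, with `cv` recorded as infinite.
#'
#' @param genes Gene tibble with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open; as from [read_gff3_genes()]). Extra columns
#'   (e.g. `mag_id`) are carried through.
#' @param gene_depth Depth tibble (as [read_depth()]) indexed by gene id:
#'   per-base depth along each extracted gene sequence.
#' @param contig_depth Depth tibble indexed by contig id.
#' @param config A [link_config()].
#' @return Tibble with `gene_id`, carried-through columns,
#'   `gene_mean_depth`, `contig_mean_depth`, `cv`, `depth_ratio`, `pass`.
#' @export
qc_coverage <- function(genes, gene_depth, contig_depth,
                        config = link_config()) {
  if (nrow(gene_depth) == 0L && nrow(contig_depth) == 0L) {
    ts_abort("empty depth tracks", "ts_input_error")
  }
  res <- purrr::pmap(genes, function(gene_id, contig_id, start, end, ...) {
    len <- end - start
    gv <- depth_vector(gene_depth, gene_id, 0L, len)
    gmean <- mean(gv)
    cv <- if (gmean == 0) Inf else sqrt(mean((gv - gmean)^2)) / gmean
    cv_ <- contig_depth[contig_depth$contig_id == contig_id, , drop = FALSE]
    cmean <- if (nrow(cv_) == 0L) 0 else {
      mean(depth_vector(contig_depth, contig_id, 0L, max(cv_$pos)))
    }
    ratio <- if (cmean == 0) Inf else gmean / cmean
    tibble::tibble(gene_mean_depth = gmean, contig_mean_depth = cmean,
                   cv = cv, depth_ratio = ratio)
  })
  out <- dplyr::bind_cols(genes, dplyr::bind_rows(res))
  out$pass <- is.finite(out$cv) & out$cv <= config$cv_max &
    out$depth_ratio >= config$ratio_lo & out$depth_ratio <= config$ratio_hi
  out
}

best_strand_alignment <- function(query, subject, scoring, strand = "both") {
  fwd <- align_pair(query, subject, scoring, strand = "+")
  if (strand != "both") return(fwd)
  qrc <- query
  qrc$seq <- rev_comp(qrc$seq)
  rev <- align_pair(qrc, subject, scoring, strand = "-")
  if (rev$score > fwd$score) rev else fwd
}

#' Match amplicons against MAG 16S genes
#'
#' Every amplicon is aligned (both strands) against every QC-passing gene;
#' pairs reaching both thresholds (inclusive) are emitted as evidence rows.
#'
#' @param amplicons Sequence tibble (`id`, `seq`) of amplicon/OTU
#'   representatives.
#' @param genes Gene tibble with columns `gene_id`, `mag_id`, `seq` (sense
#'   strand).
#' @param config A [link_config()].
#' @param qc Optional [qc_coverage()] result; genes with `pass == FALSE`
#'   are ignored.
#' @param scoring A [scoring_scheme()].
#' @return Evidence tibble: `otu_id`, `mag_id`, `gene_id`, `identity`,
#'   `query_coverage`, `score`, `strand`.
#' @export
match_amplicons <- function(amplicons, genes, config = link_config(),
                            qc = NULL, scoring = scoring_scheme()) {
  if (!is.null(qc)) {
    genes <- genes[genes$gene_id %in% qc$gene_id[qc$pass], , drop = FALSE]
  }
  if (nrow(genes) == 0L || is.null(amplicons) || nrow(amplicons) == 0L) {
    return(tibble::tibble(otu_id = character(), mag_id = character(),
                          gene_id = character(), identity = numeric(),
                          query_coverage = numeric(), score = integer(),
                          strand = character()))
  }
  rows <- list()
  for (a in seq_len(nrow(amplicons))) {
    for (g in seq_len(nrow(genes))) {
      r <- best_strand_alignment(amplicons[a, ],
                                 seq_tbl(genes$gene_id[g], genes$seq[g]),
                                 scoring)
      if (r$identity >= config$min_identity &&
          r$query_coverage >= config$min_query_coverage) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          otu_id = amplicons$id[a], mag_id = genes$mag_id[g],
          gene_id = genes$gene_id[g], identity = r$identity,
          query_coverage = r$query_coverage, score = r$score,
          strand = r$strand
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(otu_id = character(), mag_id = character(),
                          gene_id = character(), identity = numeric(),
                          query_coverage = numeric(), score = integer(),
                          strand = character()))
  }
  dplyr::bind_rows(rows)
}

#' Partition MAGs into biofilm-linked, planktonic and excluded fractions
#'
#' Excluded: MAGs with no 16S genes, or whose genes all fail QC.
#' Biofilm-linked: non-excluded MAGs with at least one evidence row.
#' Planktonic: the remaining non-excluded MAGs. The three sets are disjoint
#' and cover the input.
#'
#' @param mag_ids Character vector of all MAG ids under consideration.
#' @param genes Gene tibble (`gene_id`, `mag_id`, ...); MAGs absent here
#'   have no 16S genes.
#' @param evidence Evidence tibble from [match_amplicons()].
#' @param qc Optional [qc_coverage()] result used to fail genes.
#' @return A `mag_partition` object.
#' @export
partition_mags <- function(mag_ids, genes, evidence, qc = NULL) {
  mag_ids <- as.character(mag_ids)
  unknown <- setdiff(unique(evidence$mag_id), mag_ids)
  if (length(unknown) > 0L) {
    ts_abort(paste0("evidence references unknown MAG(s): ",
                    paste(unknown, collapse = ", ")), "ts_consistency_error")
  }
  passing_genes <- if (is.null(qc)) genes$gene_id else qc$gene_id[qc$pass]
  usable_mags <- unique(genes$mag_id[genes$gene_id %in% passing_genes])
  excluded <- setdiff(mag_ids, usable_mags)
  ev_ok <- evidence[evidence$gene_id %in% passing_genes, , drop = FALSE]
  biofilm <- intersect(setdiff(mag_ids, excluded), unique(ev_ok$mag_id))
  planktonic <- setdiff(mag_ids, c(excluded, biofilm))
  structure(list(
    biofilm_linked = sort(biofilm),
    planktonic = sort(planktonic),
    excluded = sort(excluded),
    evidence = ev_ok,
    mag_ids = mag_ids
  ), class = "mag_partition")
}

#' @export
print.mag_partition <- function(x, ...) {
  cat(sprintf("<mag_partition> %d biofilm-linked, %d planktonic, %d excluded\n",
              length(x$biofilm_linked), length(x$planktonic),
              length(x$excluded)))
  invisible(x)
}

#' Tidiers for MAG partitions
#'
#' @param x A `mag_partition`.
#' @param ... Unused.
#' @return `tidy()` returns one row per MAG with its fraction; `glance()` a
#'   one-row count summary.
#' @name mag_partition-methods
#' @export
tidy.mag_partition <- function(x, ...) {
  tibble::tibble(
    mag_id = c(x$biofilm_linked, x$planktonic, x$excluded),
    fraction = rep(c("biofilm_linked", "planktonic", "excluded"),
                   c(length(x$biofilm_linked), length(x$planktonic),
                     length(x$excluded)))
  )
}

#' @rdname mag_partition-methods
#' @export
glance.mag_partition <- function(x, ...) {
  tibble::tibble(
    n_mags = length(x$mag_ids),
    n_biofilm_linked = length(x$biofilm_linked),
    n_planktonic = length(x$planktonic),
    n_excluded = length(x$excluded),
    n_evidence = nrow(x$evidence)
  )
}

#' Plot a MAG partition
#'
#' @param object A `mag_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of fraction sizes.
#' @export
autoplot.mag_partition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, fill = .data$fraction)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "MAGs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Recruit metagenomic reads to OTU representatives
#'
#' Each read is assigned to the single best OTU whose alignment passes the
#' thresholds, with percent coverage measured on the shorter of read and OTU
#' representative (metagenome reads may be shorter than the amplicon). Ties
#' are broken by higher score, then higher identity, then lexicographic OTU
#' id.
#'
#' @param otu_reps Sequence tibble of OTU representatives.
#' @param read_sets Named list: metagenome id -> sequence tibble of reads.
#' @param config A [link_config()].
#' @param k Seed word size for the candidate search.
#' @param scoring A [scoring_scheme()].
#' @return Long tibble (`otu_id`, `metagenome_id`, `n_reads`, `recruited`)
#'   complete over all OTU-by-metagenome combinations.
#' @export
recruit_reads <- function(otu_reps, read_sets, config = link_config(),
                          k = 8L, scoring = scoring_scheme()) {
  index <- build_index(otu_reps, k = k)
  counts <- matrix(0L, nrow = nrow(otu_reps), ncol = length(read_sets),
                   dimnames = list(otu_reps$id, names(read_sets)))
  for (mg in names(read_sets)) {
    reads <- read_sets[[mg]]
    for (i in seq_len(nrow(reads))) {
      rseq <- reads$seq[i]
      cand <- union(index_candidates(index, rseq),
                    index_candidates(index, rev_comp(rseq)))
      if (length(cand) == 0L) next
      best <- NULL
      for (ci in cand) {
        rep <- otu_reps[ci, ]
        r <- best_strand_alignment(seq_tbl(reads$id[i], rseq), rep, scoring)
        short_is_query <- nchar(rseq) <= nchar(rep$seq)
        short_len <- min(nchar(rseq), nchar(rep$seq))
        aligned_short <- if (short_is_query) r$q_end - r$q_start
                         else r$s_end - r$s_start
        cov_short <- 100 * aligned_short / short_len
        if (r$identity >= config$min_identity &&
            cov_short >= config$min_query_coverage) {
          cand_row <- list(otu_id = rep$id, score = r$score,
                           identity = r$identity)
          if (is.null(best) ||
              cand_row$score > best$score ||
              (cand_row$score == best$score &&
                 cand_row$identity > best$identity) ||
              (cand_row$score == best$score &&
                 cand_row$identity == best$identity &&
                 cand_row$otu_id < best$otu_id)) {
            best <- cand_row
          }
        }
      }
      if (!is.null(best)) {
        counts[best$otu_id, mg] <- counts[best$otu_id, mg] + 1L
      }
    }
  }
  out <- tibble::as_tibble(as.data.frame.table(counts,
                                               stringsAsFactors = FALSE))
  names(out) <- c("otu_id", "metagenome_id", "n_reads")
  out$n_reads <- as.integer(out$n_reads)
  out$recruited <- out$n_reads > 0L
  dplyr::arrange(out, .data$metagenome_id, .data$otu_id)
}
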