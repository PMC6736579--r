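# Multi-blank contaminant screen: flag OTUs whose depth-normalized abundance
# concentrates in extraction blanks, annotate flagged OTUs against a
# reference database, and apply reviewed culling.
#
# The flagging statistic: with b = mean relative abundance of an OTU across
# blank libraries and s = the mean across specimen libraries, the blank
# share is b / (b + s) (0 when both are 0). An OTU is flagged iff its blank
# share is >= tau (boundary inclusive). Mean-of-relative-abundances is used
# rather than raw read pooling so that library-size imbalance between blanks
# and specimens cannot dominate the statistic.

#' Decontamination configuration
#'
#' @param tau Blank-share flagging threshold in (0, 1]; default 0.10, the
#'   conventional 10% screening threshold.
#' @param top_k Reference hits reported per flagged OTU (default 10).
#' @param pseudo_depth_min Minimum library size for a usable sample.
#' @return A named list of class `decontam_config`.
#' @export
decontam_config <- function(tau = 0.10, top_k = 10L, pseudo_depth_min = 1L) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    ts_abort("tau must lie in (0, 1]", "ts_config_error")
  }
  if (top_k < 1L) ts_abort("top_k must be >= 1", "ts_config_error")
  structure(list(tau = tau, top_k = as.integer(top_k),
                 pseudo_depth_min = as.integer(pseudo_depth_min)),
            class = "decontam_config")
}

#' Per-sample relative abundances
#'
#' Divides each sample column by its library size; every column of the
#' result sums to 1 and zeros are preserved.
#'
#' @param table A [count_table()].
#' @param pseudo_depth_min Minimum usable library size.
#' @return A tibble (`otu_id` + one numeric column per sample).
#' @export
relative_abundance <- function(table, pseudo_depth_min = 1L) {
  m <- count_matrix(table)
  depths <- colSums(m)
  bad <- depths < pseudo_depth_min | depths == 0
  if (any(bad)) {
    ts_abort(paste0("sample(s) below minimum depth: ",
                    paste(colnames(m)[bad], collapse = ", ")),
             "ts_depth_error")
  }
  rel <- sweep(m, 2, depths, "/")
  dplyr::bind_cols(tibble::tibble(otu_id = table$otu_id),
                   tibble::as_tibble(rel))
}

share_stats <- function(table, pseudo_depth_min = 1L) {
  roles <- sample_roles(table)
  if (!any(roles == "blank") || !any(roles == "specimen")) {
    ts_abort("decontamination requires at least one blank and one specimen",
             "ts_config_error")
  }
  rel <- relative_abundance(table, pseudo_depth_min)
  relm <- as.matrix(rel[-1])
  blanks <- names(roles)[roles == "blank"]
  specs <- names(roles)[roles == "specimen"]
  b <- rowMeans(relm[, blanks, drop = FALSE])
  s <- rowMeans(relm[, specs, drop = FALSE])
  share <- ifelse(b + s == 0, 0, b / (b + s))
  per_blank <- lapply(seq_len(nrow(relm)), function(i) {
    as.list(relm[i, blanks, drop = TRUE])
  })
  tibble::tibble(
    otu_id = table$otu_id,
    blank_share = share,
    mean_blank_relabund = b,
    mean_specimen_relabund = s,
    per_blank_relabund = per_blank
  )
}

#' Blank share of one OTU
#'
#' @param table A [count_table()].
#' @param otu_id A single OTU identifier.
#' @return The OTU's blank share, a fraction in `[0, 1]`.
#' @export
blank_share <- function(table, otu_id) {
  st <- share_stats(table)
  i <- match(otu_id, st$otu_id)
  if (is.na(i)) {
    ts_abort(paste0("unknown otu_id: ", otu_id), "ts_key_error")
  }
  st$blank_share[i]
}

#' Blank shares of every OTU
#'
#' @param table A [count_table()].
#' @return Tibble with per-OTU blank-share statistics.
#' @export
blank_shares <- function(table) share_stats(table)

#' Flag candidate contaminant OTUs
#'
#' An OTU is flagged iff its blank share is `>= tau` (inclusive). OTUs
#' absent from every blank can never be flagged for any positive `tau`.
#'
#' @param table A [count_table()] with both roles present.
#' @param config A [decontam_config()].
#' @return A tibble of class `flag_table` with one row per OTU, sorted by
#'   descending blank share (ties by OTU id): `otu_id`, `blank_share`,
#'   per-blank and specimen-mean relative abundances, `flagged`, `decision`
#'   (`"pending"`), and a `hits` list-column (empty until
#'   [annotate_flagged()]).
#' @export
flag_contaminants <- function(table, config = decontam_config()) {
  st <- share_stats(table, config$pseudo_depth_min)
  st$flagged <- st$blank_share >= config$tau
  st$decision <- "pending"
  st$hits <- replicate(nrow(st), NULL, simplify = FALSE)
  st <- dplyr::arrange(st, dplyr::desc(.data$blank_share), .data$otu_id)
  structure(st, config = config, class = c("flag_table", class(st)))
}

#' @export
print.flag_table <- function(x, ...) {
  cfg <- attr(x, "config", exact = TRUE)
  cat(sprintf("<flag_table> %d OTUs screened, %d flagged (tau = %g)\n",
              nrow(x), sum(x$flagged), cfg$tau))
  NextMethod()
}

#' Annotate flagged OTUs with their closest reference matches
#'
#' Runs [seed_search()] for each flagged OTU's representative sequence
#' against the reference database and stores the ranked hits (percent
#' identity, query coverage, e-value, taxonomy, environmental source) in the
#' `hits` list-column. Unflagged OTUs are untouched.
#'
#' @param flags A `flag_table` from [flag_contaminants()].
#' @param rep_seqs Sequence tibble (`id`, `seq`) of OTU representatives.
#' @param db Reference tibble (`id`, `seq`, `taxonomy`,
#'   `environment_source`).
#' @param config A [decontam_config()] (for `top_k`); defaults to the
#'   configuration stored on `flags`.
#' @param k Seed word size.
#' @param scoring A [scoring_scheme()].
#' @return `flags` with `hits` populated for flagged OTUs.
#' @export
annotate_flagged <- function(flags, rep_seqs, db,
                             config = attr(flags, "config"),
                             k = 8L, scoring = scoring_scheme()) {
  if (is.null(config)) config <- decontam_config()
  flagged_ids <- flags$otu_id[flags$flagged]
  if (length(flagged_ids) == 0L) return(flags)
  missing <- setdiff(flagged_ids, rep_seqs$id)
  if (length(missing) > 0L) {
    ts_abort(paste0("flagged OTU(s) lacking a representative sequence: ",
                    paste(missing, collapse = ", ")),
             "ts_annotation_error")
  }
  index <- build_index(db, k = k)
  for (oid in flagged_ids) {
    rec <- rep_seqs[match(oid, rep_seqs$id), ]
    i <- match(oid, flags$otu_id)
    flags$hits[[i]] <- seed_search(rec, index, top_k = config$top_k,
                                   scoring = scoring)
  }
  flags
}

#' Apply reviewed culling decisions
#'
#' Decisions may only address flagged OTUs; flagged OTUs without a decision
#' default to retain and keep `decision = "pending"`. Rows of removed OTUs
#' are deleted from the table. Total reads are conserved exactly between the
#' surviving table and the removed OTUs.
#'
#' @param table The [count_table()] the flags were computed from.
#' @param flags A `flag_table`.
#' @param decisions Named character vector (`otu_id -> "remove"/"retain"`)
#'   or a data frame with columns `otu_id` and `decision`.
#' @return A list with elements `table` (the culled [count_table()]) and
#'   `report` (a `retention_report`).
#' @export
apply_review <- function(table, flags, decisions = character(0)) {
  if (is.data.frame(decisions)) {
    decisions <- setNames(as.character(decisions$decision),
                          as.character(decisions$otu_id))
  }
  if (length(decisions) > 0 && !all(decisions %in% c("remove", "retain"))) {
    ts_abort("decisions must be 'remove' or 'retain'", "ts_review_error")
  }
  flagged_ids <- flags$otu_id[flags$flagged]
  stray <- setdiff(names(decisions), flagged_ids)
  if (length(stray) > 0L) {
    ts_abort(paste0("decision(s) for unflagged OTU(s): ",
                    paste(stray, collapse = ", ")), "ts_review_error")
  }
  flags$decision <- ifelse(flags$otu_id %in% names(decisions),
                           unname(decisions[flags$otu_id]), flags$decision)
  remove_ids <- names(decisions)[decisions == "remove"]

  m <- count_matrix(table)
  total <- sum(m)
  removed_reads <- sum(m[table$otu_id %in% remove_ids, , drop = FALSE])
  keep <- !(table$otu_id %in% remove_ids)
  culled <- count_table(tibble::as_tibble(as.data.frame(table))[keep, ],
                        sample_roles(table))
  cfg <- attr(flags, "config", exact = TRUE)
  if (is.null(cfg)) cfg <- decontam_config()
  report <- structure(list(
    version = as.character(utils::packageVersion("taxonsluice")),
    parameters = unclass(cfg),
    n_flagged = sum(flags$flagged),
    n_removed = length(remove_ids),
    n_retained_otus = sum(keep),
    pct_sequences_retained = 100 * (total - removed_reads) / total,
    total_reads = total,
    removed_reads = removed_reads,
    records = flags
  ), class = "retention_report")
  list(table = culled, report = report)
}

#' @export
print.retention_report <- function(x, ...) {
  cat(sprintf(paste0("<retention_report> %d flagged, %d removed; %d OTUs ",
                     "retained (%.1f%% of sequences)\n"),
              x$n_flagged, x$n_removed, x$n_retained_otus,
              x$pct_sequences_retained))
  invisible(x)
}

#' @rdname retention_report-methods
#' @param x A `retention_report`.
#' @param ... Unused.
#' @return `glance()` returns a one-row summary tibble; `tidy()` the per-OTU
#'   flag records.
#' @export
glance.retention_report <- function(x, ...) {
  tibble::tibble(
    n_flagged = x$n_flagged, n_removed = x$n_removed,
    n_retained_otus = x$n_retained_otus,
    pct_sequences_retained = x$pct_sequences_retained,
    total_reads = x$total_reads, removed_reads = x$removed_reads,
    tau = x$parameters$tau
  )
}

#' Tidiers for retention reports
#'
#' @name retention_report-methods
#' @export
tidy.retention_report <- function(x, ...) {
  tibble::as_tibble(x$records)
}

#' Plot blank shares against the flagging threshold
#'
#' @param object A `flag_table`.
#' @param ... Unused.
#' @return A ggplot: per-OTU blank share, flagged OTUs highlighted, with the
#'   threshold drawn as a horizontal line.
#' @export
autoplot.flag_table <- function(object, ...) {
  cfg <- attr(object, "config", exact = TRUE)
  df <- tibble::as_tibble(object)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$blank_share,
                                   colour = .data$flagged)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = cfg$tau, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d1495b",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "OTU rank (by blank share)", y = "blank share",
                  colour = "flagged") +
    ggplot2::theme_minimal()
}
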