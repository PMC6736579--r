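# Compare functional gene content between biofilm-linked and planktonic MAG
# fractions: ORF-normalized category profiles and marker-gene presence.

validate_annotations <- function(annotations, orf_totals) {
  need <- c("mag_id", "orf_id", "gene_symbol", "category")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0L) {
    ts_abort(paste0("annotation table lacks column(s): ",
                    paste(miss, collapse = ", ")), "ts_format_error")
  }
  if (anyDuplicated(annotations[c("mag_id", "orf_id", "gene_symbol")])) {
    ts_abort("duplicate (mag_id, orf_id, gene_symbol) annotation rows",
             "ts_format_error")
  }
  if (is.data.frame(orf_totals)) {
    orf_totals <- setNames(orf_totals$total_orfs, orf_totals$mag_id)
  }
  n_ann <- table(annotations$mag_id[!duplicated(
    annotations[c("mag_id", "orf_id")])])
  for (m in names(n_ann)) {
    if (is.na(orf_totals[m]) || orf_totals[m] < n_ann[[m]]) {
      ts_abort(paste0("orf_totals below annotated ORF count for ", m),
               "ts_format_error")
    }
  }
  orf_totals
}

#' Build an ORF-normalized functional profile for a MAG fraction
#'
#' Category abundance is the number of annotated genes in the category,
#' summed over the fraction's MAGs, divided by the fraction's total number
#' of predicted ORFs. Per-gene abundances within each category are computed
#' the same way.
#'
#' @param annotations Tibble with columns `mag_id`, `orf_id`, `gene_symbol`,
#'   `category`.
#' @param orf_totals Named numeric vector (`mag_id -> total predicted ORFs`)
#'   or tibble with columns `mag_id`, `total_orfs`.
#' @param mag_ids MAGs making up the fraction.
#' @param fraction Fraction label (e.g. `"biofilm_linked"`).
#' @return A `fraction_profile`: list with `fraction`, `total_orfs`,
#'   `categories` (tibble `category`, `n_genes`, `abundance`) and `genes`
#'   (tibble `category`, `gene`, `n_genes`, `abundance`).
#' @export
build_profile <- function(annotations, orf_totals, mag_ids, fraction) {
  orf_totals <- validate_annotations(annotations, orf_totals)
  mag_ids <- as.character(mag_ids)
  present <- intersect(mag_ids, names(orf_totals))
  total <- sum(orf_totals[present])
  if (length(present) == 0L || total <= 0) {
    ts_abort("fraction has zero total ORFs", "ts_input_error")
  }
  ann <- annotations[annotations$mag_id %in% mag_ids, , drop = FALSE]
  cats <- ann |>
    dplyr::count(.data$category, name = "n_genes") |>
    dplyr::mutate(abundance = .data$n_genes / total) |>
    dplyr::arrange(.data$category)
  genes <- ann |>
    dplyr::count(.data$category, .data$gene_symbol, name = "n_genes") |>
    dplyr::rename(gene = "gene_symbol") |>
    dplyr::mutate(abundance = .data$n_genes / total) |>
    dplyr::arrange(.data$category, .data$gene)
  structure(list(fraction = fraction, total_orfs = total,
                 mag_ids = mag_ids, categories = cats, genes = genes),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat(sprintf("<fraction_profile> %s: %d MAGs, %d ORFs, %d categories\n",
              x$fraction, length(x$mag_ids), x$total_orfs,
              nrow(x$categories)))
  invisible(x)
}

#' @rdname fraction_profile-methods
#' @export
glance.fraction_profile <- function(x, ...) {
  tibble::tibble(fraction = x$fraction, n_mags = length(x$mag_ids),
                 total_orfs = x$total_orfs,
                 n_categories = nrow(x$categories),
                 n_genes = nrow(x$genes))
}

#' Tidiers for fraction profiles
#'
#' @param x A `fraction_profile`.
#' @param ... Unused.
#' @name fraction_profile-methods
#' @export
tidy.fraction_profile <- function(x, ...) {
  dplyr::mutate(x$categories, fraction = x$fraction, .before = 1)
}

#' Compare two fraction profiles
#'
#' Per-category signed differences (`a - b`; categories present in only one
#' profile are treated as 0 in the other) and a per-gene table rescaled to
#' `[0, 1]` by each gene's maximum abundance across the two fractions (the
#' spider-plot scale: the dominant fraction sits at 1 unless both are 0).
#' Categories follow `category_order` when given, else lexicographic order.
#'
#' @param a,b `fraction_profile` objects built from the same category
#'   universe.
#' @param category_order Optional character vector fixing category order.
#' @return A `profile_comparison`: list with `fractions` (labels of a and
#'   b), `categories` (tibble `category`, `abundance_a`, `abundance_b`,
#'   `diff`) and `spider` (tibble `category`, `gene`, `abundance_a`,
#'   `abundance_b`, `scaled_a`, `scaled_b`).
#' @export
compare_profiles <- function(a, b, category_order = NULL) {
  cats <- dplyr::full_join(
    dplyr::select(a$categories, "category", abundance_a = "abundance"),
    dplyr::select(b$categories, "category", abundance_b = "abundance"),
    by = "category"
  )
  cats$abundance_a[is.na(cats$abundance_a)] <- 0
  cats$abundance_b[is.na(cats$abundance_b)] <- 0
  cats$diff <- cats$abundance_a - cats$abundance_b
  if (!is.null(category_order)) {
    cats <- cats[order(match(cats$category, category_order)), , drop = FALSE]
  } else {
    cats <- dplyr::arrange(cats, .data$category)
  }
  genes <- dplyr::full_join(
    dplyr::select(a$genes, "category", "gene", abundance_a = "abundance"),
    dplyr::select(b$genes, "category", "gene", abundance_b = "abundance"),
    by = c("category", "gene")
  )
  genes$abundance_a[is.na(genes$abundance_a)] <- 0
  genes$abundance_b[is.na(genes$abundance_b)] <- 0
  mx <- pmax(genes$abundance_a, genes$abundance_b)
  genes$scaled_a <- ifelse(mx == 0, 0, genes$abundance_a / mx)
  genes$scaled_b <- ifelse(mx == 0, 0, genes$abundance_b / mx)
  genes <- dplyr::arrange(genes, .data$category, .data$gene)
  structure(list(fractions = c(a$fraction, b$fraction),
                 categories = tibble::as_tibble(cats),
                 spider = tibble::as_tibble(genes)),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> %s vs %s: %d categories, %d genes\n",
              x$fractions[1], x$fractions[2], nrow(x$categories),
              nrow(x$spider)))
  invisible(x)
}

#' Tidiers for profile comparisons
#'
#' @param x A `profile_comparison`.
#' @param ... Unused.
#' @name profile_comparison-methods
#' @export
tidy.profile_comparison <- function(x, ...) x$categories

#' Spider plot of per-gene abundances within categories
#'
#' @param object A `profile_comparison`.
#' @param ... Unused.
#' @return A ggplot: per-gene 0-1 scaled abundances for both fractions on a
#'   polar axis, faceted by category.
#' @export
autoplot.profile_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$spider, c("scaled_a", "scaled_b"),
                            names_to = "fraction", values_to = "value")
  df$fraction <- ifelse(df$fraction == "scaled_a", object$fractions[1],
                        object$fractions[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$value,
                                   group = .data$fraction,
                                   colour = .data$fraction,
                                   fill = .data$fraction)) +
    ggplot2::geom_polygon(alpha = 0.2) +
    ggplot2::geom_point() +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(~category, scales = "free_x") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "relative abundance (0-1)") +
    ggplot2::theme_minimal()
}

split_symbols <- function(gene) {
  s <- unlist(strsplit(gene, "[/;,]"))
  s <- trimws(s)
  s[nzchar(s)]
}

#' Marker-gene presence/absence by MAG fraction
#'
#' A panel entry is present in a fraction iff any MAG of that fraction
#' carries at least one annotation whose gene symbol belongs to the entry's
#' symbol set (symbols separated by `/`, `;` or `,`). Excluded MAGs
#' contribute to neither fraction.
#'
#' @param annotations Annotation tibble (`mag_id`, `orf_id`, `gene_symbol`,
#'   `category`).
#' @param partition A `mag_partition` from [partition_mags()].
#' @param panel Marker panel tibble with columns `metabolism`, `fun`
#'   (function label) and `gene` (symbol or symbol set).
#' @return Tibble: `metabolism`, `fun`, `gene`, `biofilm_linked`,
#'   `planktonic` (logicals).
#' @export
marker_presence <- function(annotations, partition, panel) {
  if (any(!nzchar(trimws(panel$gene))) ||
      any(lengths(lapply(panel$gene, split_symbols)) == 0L)) {
    ts_abort("marker panel entry with empty symbol set", "ts_panel_error")
  }
  by_fraction <- function(mags) {
    syms <- unique(annotations$gene_symbol[annotations$mag_id %in% mags])
    vapply(panel$gene,
           function(g) any(split_symbols(g) %in% syms), logical(1),
           USE.NAMES = FALSE)
  }
  tibble::tibble(
    metabolism = panel$metabolism,
    fun = panel$fun,
    gene = panel$gene,
    biofilm_linked = by_fraction(partition$biofilm_linked),
    planktonic = by_fraction(partition$planktonic)
  )
}

#' Render a presence matrix with check marks
#'
#' @param presence Result of [marker_presence()].
#' @param check Mark used for presence (default a check mark).
#' @return Tibble with the logical columns rendered as `check`/empty.
#' @export
format_presence <- function(presence, check = "✓") {
  out <- presence
  for (col in c("biofilm_linked", "planktonic")) {
    out[[col]] <- ifelse(presence[[col]], check, "")
  }
  out
}
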