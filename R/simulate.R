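# Deterministic synthetic-data generator with recorded planted truth.
#
# The count-table model: each library is a multinomial draw of fixed depth
# from an expected composition. Blanks are dominated by a "kit community"
# (the planted contaminants, log-normal weights) with a small leak of the
# specimen community; specimens are dominated by a log-normal background
# community with per-contaminant leak coefficients solved from the planted
# blank-share targets. Background base abundances mix a log-normal with a
# uniform floor so that even the rarest background OTU keeps its sampled
# blank share several binomial standard errors below the default flagging
# threshold at the default depth.

#' Fixture specification
#'
#' Defaults describe the study conditions the toolkit is tested under:
#' low-biomass libraries of 5e4 reads, 4 specimens and 2 extraction blanks,
#' 200 OTUs of which 20 are planted kit contaminants, and a 23-MAG set with
#' 12 planted amplicon matches, 8 non-matching 16S-bearing MAGs and 3 MAGs
#' lacking a 16S gene.
#'
#' @param seed Integer seed; identical seeds give byte-identical fixtures.
#' @param n_otus,n_specimens,n_blanks,depth Count-table dimensions.
#' @param n_contaminants Number of planted kit contaminants.
#' @param contaminant_shares Target blank shares for the contaminants
#'   (default evenly spaced from 0.35 to 1).
#' @param blank_kit_fraction Fraction of each blank library drawn from the
#'   kit community (default 0.985; the complement is the background leak
#'   into blanks).
#' @param specimen_kit_mass_max Cap on the total expected kit mass leaked
#'   into specimen libraries.
#' @param sdlog Log-normal sigma of community base abundances.
#' @param bg_floor_frac Uniform-floor fraction mixed into background base
#'   abundances.
#' @param n_mags,n_biofilm_linked,n_no16s MAG-set composition.
#' @param amplicon_length,gene_length Sequence lengths in nt.
#' @param match_mutations Substitutions planted into matching amplicons
#'   (recycled over matching MAGs; interior positions only).
#' @param n_refdb Reference-database records beyond the kit sources.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_otus = 200L, n_specimens = 4L,
                         n_blanks = 2L, depth = 50000L,
                         n_contaminants = 20L, contaminant_shares = NULL,
                         blank_kit_fraction = 0.985,
                         specimen_kit_mass_max = 0.15,
                         sdlog = 1.0, bg_floor_frac = 0.3,
                         n_mags = 23L, n_biofilm_linked = 12L, n_no16s = 3L,
                         amplicon_length = 250L, gene_length = 1200L,
                         match_mutations = c(0L, 1L, 2L),
                         n_refdb = 30L) {
  if (is.null(contaminant_shares)) {
    contaminant_shares <- seq(0.35, 1.0, length.out = n_contaminants)
  }
  if (any(contaminant_shares < 0 | contaminant_shares > 1)) {
    ts_abort("planted shares must lie in [0, 1]", "ts_spec_error")
  }
  if (n_contaminants >= n_otus) {
    ts_abort("n_contaminants must be smaller than n_otus", "ts_spec_error")
  }
  if (n_biofilm_linked + n_no16s > n_mags) {
    ts_abort("n_biofilm_linked + n_no16s must not exceed n_mags",
             "ts_spec_error")
  }
  if (any(match_mutations > amplicon_length - 4L)) {
    ts_abort("mutation count exceeds amplicon length", "ts_spec_error")
  }
  structure(list(
    seed = as.integer(seed), n_otus = as.integer(n_otus),
    n_specimens = as.integer(n_specimens), n_blanks = as.integer(n_blanks),
    depth = as.integer(depth), n_contaminants = as.integer(n_contaminants),
    contaminant_shares = contaminant_shares,
    blank_kit_fraction = blank_kit_fraction,
    specimen_kit_mass_max = specimen_kit_mass_max,
    sdlog = sdlog, bg_floor_frac = bg_floor_frac,
    n_mags = as.integer(n_mags),
    n_biofilm_linked = as.integer(n_biofilm_linked),
    n_no16s = as.integer(n_no16s),
    amplicon_length = as.integer(amplicon_length),
    gene_length = as.integer(gene_length),
    match_mutations = as.integer(match_mutations),
    n_refdb = as.integer(n_refdb)
  ), class = "fixture_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute n_sub interior bases (>= 2 nt from either end) so the optimal
# local alignment keeps full coverage and identity = (L - n_sub) / L.
mutate_interior <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  L <- nchar(seq)
  pos <- sample(3:(L - 2L), n_sub)
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

contaminant_indices <- function(spec) {
  with_seed(spec$seed * 7L + 11L, sample(spec$n_otus, spec$n_contaminants))
}

otu_ids_of <- function(spec) {
  sprintf("OTU_%03d", seq_len(spec$n_otus))
}

#' Simulate an OTU count table with planted contaminants
#'
#' @param spec A [fixture_spec()].
#' @return List with `table` (a [count_table()]) and `truth` (tibble
#'   `otu_id`, `type`, `true_share`: the expected blank share under the
#'   generating composition).
#' @export
simulate_count_table <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    ids <- otu_ids_of(spec)
    cont_idx <- contaminant_indices(spec)
    bg_idx <- setdiff(seq_len(spec$n_otus), cont_idx)

    w <- rlnorm(spec$n_contaminants, sdlog = spec$sdlog)
    w <- w / sum(w)
    # pair heavier kit OTUs with higher targets (smaller specimen leak)
    t_sorted <- sort(spec$contaminant_shares)
    targets <- numeric(spec$n_contaminants)
    targets[order(w)] <- t_sorted

    v <- rlnorm(length(bg_idx), sdlog = spec$sdlog)
    v <- v / sum(v)
    v <- (1 - spec$bg_floor_frac) * v + spec$bg_floor_frac / length(bg_idx)

    kb <- spec$blank_kit_fraction
    blank_comp <- numeric(spec$n_otus)
    blank_comp[cont_idx] <- kb * w
    blank_comp[bg_idx] <- (1 - kb) * v

    leak <- blank_comp[cont_idx] * (1 - targets) /
      ifelse(targets == 0, 1, targets)
    leak[targets == 0] <- 0
    if (sum(leak) > spec$specimen_kit_mass_max) {
      leak <- leak * spec$specimen_kit_mass_max / sum(leak)
    }
    spec_comp <- numeric(spec$n_otus)
    spec_comp[cont_idx] <- leak
    spec_comp[bg_idx] <- (1 - sum(leak)) * v

    true_share <- ifelse(blank_comp + spec_comp == 0, 0,
                         blank_comp / (blank_comp + spec_comp))

    n_samp <- spec$n_specimens + spec$n_blanks
    counts <- matrix(0L, nrow = spec$n_otus, ncol = n_samp)
    s_names <- c(sprintf("S%02d", seq_len(spec$n_specimens)),
                 sprintf("BLANK%02d", seq_len(spec$n_blanks)))
    for (j in seq_len(spec$n_specimens)) {
      counts[, j] <- rmultinom(1, spec$depth, spec_comp)[, 1]
    }
    for (j in seq_len(spec$n_blanks)) {
      counts[, spec$n_specimens + j] <- rmultinom(1, spec$depth, blank_comp)[, 1]
    }
    tbl <- dplyr::bind_cols(
      tibble::tibble(otu_id = ids),
      tibble::as_tibble(setNames(as.data.frame(counts), s_names))
    )
    roles <- setNames(rep(c("specimen", "blank"),
                          c(spec$n_specimens, spec$n_blanks)), s_names)
    truth <- tibble::tibble(
      otu_id = ids,
      type = ifelse(seq_len(spec$n_otus) %in% cont_idx,
                    "contaminant", "background"),
      true_share = true_share
    )
    list(table = count_table(tbl, roles), truth = truth)
  })
}

ENV_SOURCES <- c("human skin", "soil", "laboratory reagent", "freshwater",
                 "marine sediment", "hydrothermal fluid", "subseafloor basalt",
                 "seawater")

#' Simulate a reference 16S database and OTU representative sequences
#'
#' Contaminant OTU representatives are near-copies (0-2 interior
#' substitutions) of kit-source reference records labelled with
#' contamination-typical environmental sources, so an annotation search
#' recovers them as rank-1 hits; background representatives get their own
#' habitat-labelled reference records.
#'
#' @param spec A [fixture_spec()].
#' @return List with `db` (tibble `id`, `seq`, `taxonomy`,
#'   `environment_source`), `rep_seqs` (tibble `id`, `seq`) and `truth`
#'   (tibble `otu_id`, `source_ref`).
#' @export
simulate_refdb <- function(spec = fixture_spec()) {
  with_seed(spec$seed * 13L + 3L, {
    ids <- otu_ids_of(spec)
    cont_idx <- contaminant_indices(spec)
    L <- spec$amplicon_length

    kit_ids <- sprintf("REF_KIT_%03d", seq_along(cont_idx))
    kit_seqs <- vapply(kit_ids, function(i) random_dna(L), character(1))
    kit_env <- sample(c("human skin", "laboratory reagent"),
                      length(cont_idx), replace = TRUE)

    n_extra <- max(spec$n_refdb - length(cont_idx), 0L)
    extra_ids <- sprintf("REF_ENV_%03d", seq_len(n_extra))
    extra_seqs <- vapply(extra_ids, function(i) random_dna(L), character(1))
    extra_env <- sample(setdiff(ENV_SOURCES,
                                c("human skin", "laboratory reagent")),
                        n_extra, replace = TRUE)

    db <- tibble::tibble(
      id = c(kit_ids, extra_ids),
      seq = unname(c(kit_seqs, extra_seqs)),
      taxonomy = paste0("Bacteria;Lineage_",
                        seq_len(length(kit_ids) + n_extra)),
      environment_source = c(kit_env, extra_env)
    )

    reps <- character(spec$n_otus)
    source_ref <- rep(NA_character_, spec$n_otus)
    for (i in seq_along(cont_idx)) {
      n_sub <- sample(0:2, 1)
      reps[cont_idx[i]] <- mutate_interior(kit_seqs[[i]], n_sub)
      source_ref[cont_idx[i]] <- kit_ids[i]
    }
    bg_idx <- setdiff(seq_len(spec$n_otus), cont_idx)
    for (i in bg_idx) reps[i] <- random_dna(L)

    list(db = db,
         rep_seqs = seq_tbl(ids, reps),
         truth = tibble::tibble(otu_id = ids, source_ref = source_ref))
  })
}

#' Simulate a MAG set with planted amplicon matches
#'
#' Matching MAGs carry a 16S gene whose amplicon-region window differs from
#' one of the supplied amplicons by 0-2 interior substitutions (so identity
#' stays at or above 99.2% with full coverage and at least one exact seed
#' k-mer is always shared); non-matching MAGs carry unrelated random genes;
#' the remainder carry no 16S gene. Genes are planted on contigs (half on
#' the minus strand) with flanking sequence, and their GFF3-style
#' coordinates are recorded.
#'
#' @param spec A [fixture_spec()].
#' @return List with `mag_ids`, `genes` (tibble `gene_id`, `mag_id`,
#'   `contig_id`, `seq` on the sense strand), `gene_coords` (0-based
#'   half-open, with `strand`), `contigs`, `amplicons` and `truth` (tibble
#'   `mag_id`, `fraction`).
#' @export
simulate_mag_set <- function(spec = fixture_spec()) {
  with_seed(spec$seed * 17L + 5L, {
    n_match <- spec$n_biofilm_linked
    n_none <- spec$n_no16s
    n_plank <- spec$n_mags - n_match - n_none
    mag_ids <- sprintf("MAG_%02d", seq_len(spec$n_mags))
    fraction <- rep(c("biofilm_linked", "planktonic", "excluded"),
                    c(n_match, n_plank, n_none))

    L <- spec$amplicon_length
    gene_rows <- list()
    coord_rows <- list()
    contig_rows <- list()
    amp_rows <- list()
    flank <- 120L
    for (i in seq_len(n_match + n_plank)) {
      gene <- random_dna(spec$gene_length)
      gid <- sprintf("gene16S_%02d", i)
      cid <- sprintf("contig_%02d", i)
      strand <- if (i %% 2L == 0L) "-" else "+"
      placed <- if (strand == "-") rev_comp(gene) else gene
      contig <- paste0(random_dna(flank), placed, random_dna(flank))
      gene_rows[[i]] <- tibble::tibble(gene_id = gid, mag_id = mag_ids[i],
                                       contig_id = cid, seq = gene)
      coord_rows[[i]] <- tibble::tibble(
        gene_id = gid, contig_id = cid, start = flank,
        end = flank + spec$gene_length, strand = strand, mag_id = mag_ids[i]
      )
      contig_rows[[i]] <- tibble::tibble(id = cid, seq = contig)
      if (i <= n_match) {
        offset <- sample(seq_len(spec$gene_length - L + 1L), 1)
        window <- substr(gene, offset, offset + L - 1L)
        # cap planted substitutions so a planted match always clears the
        # default 99% identity threshold at this amplicon length
        n_sub <- min(spec$match_mutations[((i - 1L) %%
                                             length(spec$match_mutations)) + 1L],
                     floor(0.01 * L))
        amp_rows[[i]] <- tibble::tibble(
          id = sprintf("AMP_%02d", i),
          seq = mutate_interior(window, n_sub)
        )
      }
    }
    empty <- function(...) tibble::tibble(...)
    list(
      mag_ids = mag_ids,
      genes = dplyr::bind_rows(
        empty(gene_id = character(), mag_id = character(),
              contig_id = character(), seq = character()), gene_rows),
      gene_coords = dplyr::bind_rows(
        empty(gene_id = character(), contig_id = character(),
              start = integer(), end = integer(), strand = character(),
              mag_id = character()), coord_rows),
      contigs = dplyr::bind_rows(
        empty(id = character(), seq = character()), contig_rows),
      amplicons = dplyr::bind_rows(
        empty(id = character(), seq = character()), amp_rows),
      truth = tibble::tibble(mag_id = mag_ids, fraction = fraction)
    )
  })
}

#' Simulate per-base depth tracks for a gene and its parent contig
#'
#' @param spec A [fixture_spec()].
#' @param profile `"uniform"` (flat 20x on gene and contig), `"spiked"`
#'   (100x over the first half of the gene, 0 over the second, contig at
#'   20x) or `"zero"` (unmapped gene).
#' @param gene_id,contig_id Track identifiers.
#' @param gene_length,contig_length Track lengths in nt.
#' @return List with `gene_depth` and `contig_depth` tibbles (1-based
#'   positions; zero-depth positions omitted, as samtools depth does).
#' @export
simulate_depth_tracks <- function(spec = fixture_spec(),
                                  profile = c("uniform", "spiked", "zero"),
                                  gene_id = "gene16S_01",
                                  contig_id = "contig_01",
                                  gene_length = spec$gene_length,
                                  contig_length = spec$gene_length + 240L) {
  profile <- match.arg(profile)
  gene_depth <- switch(
    profile,
    uniform = rep(20L, gene_length),
    spiked = rep(c(100L, 0L), c(gene_length %/% 2L,
                                gene_length - gene_length %/% 2L)),
    zero = rep(0L, gene_length)
  )
  gtrack <- tibble::tibble(contig_id = gene_id,
                           pos = seq_len(gene_length),
                           depth = gene_depth)
  gtrack <- gtrack[gtrack$depth > 0L, , drop = FALSE]
  ctrack <- tibble::tibble(contig_id = contig_id,
                           pos = seq_len(contig_length),
                           depth = 20L)
  list(gene_depth = gtrack, contig_depth = ctrack)
}

MARKER_PANEL <- tibble::tibble(
  metabolism = c("Carbon fixation", "Carbon fixation", "Nitrogen",
                 "Nitrogen", "Sulfur", "Sulfur", "Sulfur"),
  fun = c("Wood-Ljungdahl", "Calvin cycle", "Denitrification",
          "Nitrous oxide reduction", "Sulfite reduction",
          "Thiosulfate oxidation", "Sulfur oxidation"),
  gene = c("codhC/codhD", "rbcL", "nirS", "nosZ/nosD",
           "dsrA/dsrB/dsrC/dsrM/dsrK/dsrD", "soxY/soxZ",
           "dsrE/dsrF/dsrH")
)

KEGG_CATEGORIES <- c("Biofilm formation", "Flagellar assembly",
                     "Lipopolysaccharide biosynthesis", "Sulfur metabolism",
                     "Nitrogen metabolism", "Carbon fixation",
                     "Carbohydrate metabolism", "Energy metabolism")

#' Simulate functional annotations with a planted presence pattern
#'
#' Marker genes are planted so that the Wood-Ljungdahl CO-dehydrogenase
#' markers appear in both fractions, dissimilatory sulfite
#' reduction (`dsrD`), thiosulfate oxidation (`soxY/soxZ`) and
#' denitrification (`nirS`) markers only in biofilm-linked MAGs, and the
#' Calvin-cycle (`rbcL`), nitrous-oxide-reduction and sulfur-oxidation
#' markers only in planktonic MAGs. Background KO annotations are spread
#' over the standard functional categories.
#'
#' @param spec A [fixture_spec()].
#' @param truth MAG-fraction truth tibble (as from [simulate_mag_set()]).
#' @param orfs_per_mag Total predicted ORFs per MAG.
#' @param background_per_mag Background annotation rows per MAG.
#' @return List with `annotations`, `orf_totals`, `panel` (the marker
#'   panel) and `truth_presence` (tibble `gene`, `biofilm_linked`,
#'   `planktonic`).
#' @export
simulate_annotations <- function(spec = fixture_spec(), truth,
                                 orfs_per_mag = 2000L,
                                 background_per_mag = 40L) {
  with_seed(spec$seed * 19L + 7L, {
    biofilm <- truth$mag_id[truth$fraction == "biofilm_linked"]
    plank <- truth$mag_id[truth$fraction == "planktonic"]
    all_mags <- truth$mag_id
    rows <- list()
    add <- function(mag, sym, cat) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        mag_id = mag,
        orf_id = sprintf("%s_orf%05d", mag, length(rows) + 1L),
        gene_symbol = sym, category = cat
      )
    }
    # planted marker pattern
    both_syms <- c("codhC", "codhD")
    biofilm_syms <- c("dsrD", "soxY", "soxZ", "nirS")
    plank_syms <- c("rbcL", "nosZ", "dsrE")
    for (s in both_syms) {
      add(biofilm[1], s, "Carbon fixation")
      add(plank[1], s, "Carbon fixation")
    }
    for (s in biofilm_syms) add(biofilm[min(2, length(biofilm))], s,
                                "Sulfur metabolism")
    for (s in plank_syms) add(plank[min(2, length(plank))], s,
                              "Sulfur metabolism")
    planted <- dplyr::bind_rows(rows)

    bg <- dplyr::bind_rows(lapply(all_mags, function(m) {
      n <- background_per_mag
      tibble::tibble(
        mag_id = m,
        orf_id = sprintf("%s_bg%05d", m, seq_len(n)),
        gene_symbol = sprintf("K%05d", sample(10000:19999, n)),
        category = sample(KEGG_CATEGORIES, n, replace = TRUE)
      )
    }))
    annotations <- dplyr::bind_rows(planted, bg)
    orf_totals <- setNames(rep(orfs_per_mag, length(all_mags)), all_mags)
    truth_presence <- tibble::tibble(
      gene = MARKER_PANEL$gene,
      biofilm_linked = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
      planktonic = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
    )
    list(annotations = annotations, orf_totals = orf_totals,
         panel = MARKER_PANEL, truth_presence = truth_presence)
  })
}

write_gff3_genes <- function(coords, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\ttaxonsluice\trRNA\t%d\t%d\t.\t%s\t.\tID=%s;mag_id=%s",
                     coords$contig_id, coords$start + 1L, coords$end,
                     coords$strand, coords$gene_id, coords$mag_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic input set to a directory
#'
#' Emits every format the readers consume: the OTU table in both supported
#' dialects, the roles manifest, representative and reference FASTA with a
#' metadata TSV, amplicons, MAG genes and contigs with GFF3 coordinates,
#' depth tracks, annotation tables and the marker panel, plus a
#' `truth.json` recording every planted quantity.
#'
#' @param out_dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @return Invisibly, the list of generated objects.
#' @export
simulate_all <- function(out_dir, spec = fixture_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- simulate_count_table(spec)
  rf <- simulate_refdb(spec)
  ms <- simulate_mag_set(spec)
  an <- simulate_annotations(spec, ms$truth)

  p <- function(...) file.path(out_dir, ...)
  write_count_table(ct$table, p("otu_table.tsv"))
  write_mothur_shared(ct$table, p("otu_table.shared"))
  readr::write_tsv(tibble::tibble(sample_id = names(sample_roles(ct$table)),
                                  role = unname(sample_roles(ct$table))),
                   p("roles.tsv"), progress = FALSE)
  write_fasta(rf$rep_seqs, p("rep_seqs.fasta"))
  write_fasta(rf$db[c("id", "seq")], p("refdb.fasta"))
  readr::write_tsv(rf$db[c("id", "taxonomy", "environment_source")],
                   p("refdb_meta.tsv"), progress = FALSE)
  write_fasta(ms$amplicons, p("amplicons.fasta"))
  write_fasta(seq_tbl(ms$genes$gene_id, ms$genes$seq,
                      ms$genes$contig_id), p("mag_genes.fasta"))
  write_fasta(ms$contigs, p("contigs.fasta"))
  write_gff3_genes(ms$gene_coords, p("mag_genes.gff3"))
  readr::write_tsv(tibble::tibble(mag_id = ms$mag_ids), p("mags.tsv"),
                   progress = FALSE)

  gd <- list(); cd <- list()
  for (i in seq_len(nrow(ms$genes))) {
    tr <- simulate_depth_tracks(spec, "uniform",
                                gene_id = ms$genes$gene_id[i],
                                contig_id = ms$genes$contig_id[i],
                                gene_length = spec$gene_length)
    gd[[i]] <- tr$gene_depth; cd[[i]] <- tr$contig_depth
  }
  write_depth(dplyr::bind_rows(gd), p("gene_depth.tsv"))
  write_depth(dplyr::bind_rows(cd), p("contig_depth.tsv"))

  readr::write_tsv(an$annotations, p("annotations.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(mag_id = names(an$orf_totals),
                                  total_orfs = unname(an$orf_totals)),
                   p("orf_totals.tsv"), progress = FALSE)
  readr::write_tsv(an$panel, p("marker_panel.tsv"), progress = FALSE)

  truth <- list(
    version = as.character(utils::packageVersion("taxonsluice")),
    parameters = unclass(spec),
    count_table = ct$truth,
    otu_sources = rf$truth,
    mag_fractions = ms$truth,
    marker_presence = an$truth_presence
  )
  write_report(truth, p("truth.json"), "json")
  invisible(list(count = ct, refdb = rf, mags = ms, annotations = an))
}
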