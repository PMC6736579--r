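flat_gene <- tibble::tibble(gene_id = "g1", contig_id = "c1",
                            start = 0L, end = 100L)

make_tracks <- function(gene_depth_vec, contig_depth = 20L,
                        contig_len = 150L) {
  g <- tibble::tibble(contig_id = "g1",
                      pos = seq_along(gene_depth_vec),
                      depth = as.integer(gene_depth_vec))
  g <- g[g$depth > 0, ]
  c <- tibble::tibble(contig_id = "c1", pos = seq_len(contig_len),
                      depth = as.integer(contig_depth))
  list(gene = g, contig = c)
}

test_that("coverage QC arithmetic: uniform, spiked and unmapped genes", {
  tr <- make_tracks(rep(20L, 100))
  qc <- qc_coverage(flat_gene, tr$gene, tr$contig)
  expect_equal(qc$cv, 0)
  expect_equal(qc$depth_ratio, 1)
  expect_true(qc$pass)

  # half 100x / half 0x: mean 50, population sd 50 -> cv exactly 1;
  # against a 20x contig the ratio is 2.5
  tr2 <- make_tracks(rep(c(100L, 0L), each = 50))
  qc2 <- qc_coverage(flat_gene, tr2$gene, tr2$contig)
  expect_equal(qc2$cv, 1)
  expect_equal(qc2$depth_ratio, 2.5)
  expect_true(qc2$pass)    # cv_max = 1 is inclusive, ratio within bounds
  qc2b <- qc_coverage(flat_gene, tr2$gene, tr2$contig,
                      link_config(cv_max = 0.5))
  expect_false(qc2b$pass)

  tr3 <- make_tracks(rep(0L, 100))
  qc3 <- qc_coverage(flat_gene, tr3$gene, tr3$contig)
  expect_false(qc3$pass)
  expect_identical(qc3$cv, Inf)

  expect_error(qc_coverage(flat_gene, tr3$gene[0, ], tr3$contig[0, ]),
               class = "ts_input_error")
})

test_that("QC verdicts are invariant under joint depth scaling", {
  set.seed(12)
  prof <- sample(c(0L, 5L, 10L, 40L), 100, TRUE)
  tr <- make_tracks(prof, contig_depth = 8L)
  tr10 <- make_tracks(prof * 10L, contig_depth = 80L)
  q1 <- qc_coverage(flat_gene, tr$gene, tr$contig)
  q2 <- qc_coverage(flat_gene, tr10$gene, tr10$contig)
  expect_equal(q1$cv, q2$cv)
  expect_equal(q1$depth_ratio, q2$depth_ratio)
  expect_identical(q1$pass, q2$pass)
})

test_that("amplicon matching honours identity and coverage thresholds", {
  set.seed(13)
  gene <- rand_seq(800)
  amp <- substr(gene, 301, 550)           # identical 250-nt window
  genes <- tibble::tibble(gene_id = "g1", mag_id = "M1", seq = gene)

  ev <- match_amplicons(tibble::tibble(id = "a0", seq = amp), genes)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$identity, 100)
  expect_equal(ev$query_coverage, 100)

  amp2 <- substitute_at(amp, c(60, 130))      # 248/250 = 99.2 >= 99
  amp3 <- substitute_at(amp, c(60, 130, 200)) # 247/250 = 98.8 < 99
  ev2 <- match_amplicons(tibble::tibble(id = "a2", seq = amp2), genes)
  ev3 <- match_amplicons(tibble::tibble(id = "a3", seq = amp3), genes)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$identity, 99.2)
  expect_equal(nrow(ev3), 0L)

  # only 200 of 250 amplicon nt alignable -> coverage 80 < 90
  amp4 <- paste0(substr(amp, 1, 200), rand_seq(50))
  ev4 <- match_amplicons(tibble::tibble(id = "a4", seq = amp4), genes)
  expect_equal(nrow(ev4), 0L)

  # reverse-complemented amplicon still matches, on the minus strand
  ev5 <- match_amplicons(tibble::tibble(id = "a5", seq = rev_comp(amp)),
                         genes)
  expect_equal(nrow(ev5), 1L)
  expect_identical(ev5$strand, "-")
})

test_that("partition assigns matching, non-matching and 16S-less MAGs", {
  set.seed(14)
  geneA <- rand_seq(600); geneB <- rand_seq(600)
  genes <- tibble::tibble(gene_id = c("gA", "gB"),
                          mag_id = c("A", "B"),
                          seq = c(geneA, geneB))
  amps <- tibble::tibble(id = "amp1", seq = substr(geneA, 101, 350))
  ev <- match_amplicons(amps, genes)
  part <- partition_mags(c("A", "B", "C"), genes, ev)
  expect_identical(part$biofilm_linked, "A")
  expect_identical(part$planktonic, "B")
  expect_identical(part$excluded, "C")

  # with no amplicons, every QC-passing MAG is planktonic
  part0 <- partition_mags(c("A", "B", "C"), genes,
                          match_amplicons(amps[0, ], genes))
  expect_identical(part0$planktonic, c("A", "B"))

  stray <- dplyr::mutate(ev, mag_id = "ghost")
  expect_error(partition_mags(c("A", "B"), genes, stray),
               class = "ts_consistency_error")
})

test_that("partition recovers the planted MAG fractions", {
  spec <- fixture_spec(seed = 77, n_mags = 8, n_biofilm_linked = 4,
                       n_no16s = 1, gene_length = 400,
                       amplicon_length = 150)
  ms <- simulate_mag_set(spec)
  ev <- match_amplicons(ms$amplicons, ms$genes)
  part <- partition_mags(ms$mag_ids, ms$genes, ev)
  got <- tidy(part)
  truth <- ms$truth
  merged <- dplyr::inner_join(got, truth, by = "mag_id")
  expect_identical(merged$fraction.x, merged$fraction.y)
})

test_that("partition fractions are always a disjoint cover", {
  for (seed in 1:8) {
    spec <- fixture_spec(seed = seed, n_mags = sample(4:7, 1),
                         n_biofilm_linked = sample(1:3, 1), n_no16s = 1,
                         gene_length = 300, amplicon_length = 120)
    ms <- simulate_mag_set(spec)
    ev <- match_amplicons(ms$amplicons, ms$genes)
    part <- partition_mags(ms$mag_ids, ms$genes, ev)
    all_assigned <- c(part$biofilm_linked, part$planktonic, part$excluded)
    expect_setequal(all_assigned, ms$mag_ids)
    expect_equal(length(all_assigned), length(ms$mag_ids))  # disjoint
  }
})

test_that("tightening thresholds never adds biofilm-linked MAGs", {
  spec <- fixture_spec(seed = 21, n_mags = 6, n_biofilm_linked = 3,
                       n_no16s = 0, gene_length = 300,
                       amplicon_length = 120, match_mutations = 0:2)
  ms <- simulate_mag_set(spec)
  loose <- partition_mags(ms$mag_ids, ms$genes,
                          match_amplicons(ms$amplicons, ms$genes,
                                          link_config(min_identity = 97)))
  tight <- partition_mags(ms$mag_ids, ms$genes,
                          match_amplicons(ms$amplicons, ms$genes,
                                          link_config(min_identity = 99.9,
                                                      min_query_coverage = 99)))
  expect_true(all(tight$biofilm_linked %in% loose$biofilm_linked))
})

test_that("failing QC excludes a MAG from matching and partitioning", {
  set.seed(15)
  gene <- rand_seq(400)
  genes <- tibble::tibble(gene_id = "g1", mag_id = "A", seq = gene)
  amps <- tibble::tibble(id = "amp", seq = substr(gene, 51, 200))
  qc_fail <- tibble::tibble(gene_id = "g1", pass = FALSE)
  expect_equal(nrow(match_amplicons(amps, genes, qc = qc_fail)), 0L)
  part <- partition_mags("A", genes, match_amplicons(amps, genes,
                                                     qc = qc_fail),
                         qc = qc_fail)
  expect_identical(part$excluded, "A")
})

test_that("read recruitment assigns each read to at most one best OTU", {
  set.seed(16)
  otus <- tibble::tibble(id = c("OTU_1", "OTU_2"),
                         seq = c(rand_seq(250), rand_seq(250)))
  mutate_read <- function(s) {
    # divergence kept within the 99% identity threshold (<= 2 subs in 250)
    n <- sample(0:2, 1)
    if (n == 0) s else substitute_at(s, sample(3:248, n))
  }
  reads1 <- tibble::tibble(id = sprintf("r%03d", 1:60),
                           seq = replicate(60, mutate_read(otus$seq[1])))
  noise <- tibble::tibble(id = sprintf("n%02d", 1:10),
                          seq = replicate(10, rand_seq(250)))
  prev <- recruit_reads(otus, list(mgA = dplyr::bind_rows(reads1, noise),
                                   mgB = noise))
  m <- tidyr::pivot_wider(prev[c("otu_id", "metagenome_id", "n_reads")],
                          names_from = "metagenome_id",
                          values_from = "n_reads")
  # every read within the threshold recruits to its source OTU
  expect_equal(m$mgA[m$otu_id == "OTU_1"], 60L)
  expect_equal(m$mgA[m$otu_id == "OTU_2"], 0L)
  # a read just over the divergence threshold recruits nowhere
  over <- tibble::tibble(id = "d3", seq = substitute_at(otus$seq[1],
                                                        c(50, 120, 200)))
  prev3 <- recruit_reads(otus, list(m = over))
  expect_equal(sum(prev3$n_reads), 0L)
  expect_equal(sum(m$mgB), 0L)
  # column sums never exceed the number of reads in the metagenome
  expect_lte(sum(prev$n_reads[prev$metagenome_id == "mgA"]), 70L)

  # a read identical to a representative recruits to it
  one <- recruit_reads(otus, list(m = tibble::tibble(id = "x",
                                                     seq = otus$seq[2])))
  expect_equal(one$n_reads[one$otu_id == "OTU_2" & one$metagenome_id == "m"],
               1L)
})
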