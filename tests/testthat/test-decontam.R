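toy_roles <- c(S1 = "specimen", S2 = "specimen", B1 = "blank")

test_that("relative abundance normalizes every library to 1", {
  tbl <- count_table(tibble::tibble(otu_id = c("a", "b", "c"),
                                    S1 = c(10, 30, 60),
                                    S2 = c(5, 5, 0),
                                    B1 = c(1, 0, 1)), toy_roles)
  rel <- relative_abundance(tbl)
  expect_equal(rel$S1, c(0.1, 0.3, 0.6))
  expect_equal(unname(colSums(as.matrix(rel[-1]))), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(rel$S2[3], 0)  # zeros preserved

  zero <- count_table(tibble::tibble(otu_id = "a", S1 = 1L, S2 = 0L,
                                     B1 = 1L), toy_roles)
  expect_error(relative_abundance(zero), class = "ts_depth_error")
  expect_error(relative_abundance(zero), "S2")
})

test_that("blank share follows b/(b+s) on mean relative abundances", {
  roles <- c(S1 = "specimen", B1 = "blank")
  tbl <- count_table(tibble::tibble(otu_id = c("x", "rest"),
                                    S1 = c(900L, 100L),
                                    B1 = c(100L, 900L)), roles)
  # blank rel 0.10, specimen rel 0.90 -> 0.10 / (0.10 + 0.90)
  expect_equal(blank_share(tbl, "x"), 0.10)

  tbl2 <- count_table(tibble::tibble(otu_id = c("none", "only", "fill"),
                                     S1 = c(0L, 0L, 100L),
                                     B1 = c(0L, 40L, 60L)), roles)
  expect_equal(blank_share(tbl2, "none"), 0)   # absent everywhere
  expect_equal(blank_share(tbl2, "only"), 1)   # blank-only
  expect_error(blank_share(tbl2, "ghost"), class = "ts_key_error")
})

test_that("flagging is boundary-inclusive and sorted by blank share", {
  roles <- c(S1 = "specimen", B1 = "blank")
  tbl <- count_table(tibble::tibble(otu_id = c("at", "above", "below", "r"),
                                    S1 = c(900L, 500L, 950L, 100L),
                                    B1 = c(100L, 500L, 50L, 900L)), roles)
  fl <- flag_contaminants(tbl, decontam_config(tau = 0.10))
  expect_true(fl$flagged[fl$otu_id == "at"])       # share exactly 0.10
  expect_true(fl$flagged[fl$otu_id == "above"])
  expect_false(fl$flagged[fl$otu_id == "below"])
  expect_equal(fl$blank_share, sort(fl$blank_share, decreasing = TRUE))

  no_blank <- count_table(tibble::tibble(otu_id = "a", S1 = 1L, S2 = 1L),
                          c(S1 = "specimen", S2 = "specimen"))
  expect_error(flag_contaminants(no_blank), class = "ts_config_error")
})

test_that("blank-only OTUs always flag and blank-absent never flag", {
  for (seed in 1:5) {
    ct <- simulate_count_table(fixture_spec(seed = seed, n_otus = 40,
                                            n_specimens = 3, n_blanks = 2,
                                            depth = 3000,
                                            n_contaminants = 6,
                                            contaminant_shares =
                                              c(0.4, 0.6, 0.8, 0.9, 1, 1)))
    rel <- relative_abundance(ct$table)
    roles <- sample_roles(ct$table)
    m <- as.matrix(rel[-1])
    blank_only <- rowSums(m[, roles == "specimen", drop = FALSE]) == 0 &
      rowSums(m[, roles == "blank", drop = FALSE]) > 0
    blank_absent <- rowSums(m[, roles == "blank", drop = FALSE]) == 0
    for (tau in c(0.05, 0.3, 1)) {
      fl <- flag_contaminants(ct$table, decontam_config(tau = tau))
      fl <- fl[match(ct$table$otu_id, fl$otu_id), ]
      expect_true(all(fl$flagged[blank_only]))
      expect_false(any(fl$flagged[blank_absent]))
    }
  }
})

test_that("raising tau only ever shrinks the flagged set", {
  for (seed in 1:10) {
    ct <- simulate_count_table(fixture_spec(seed = seed, n_otus = 30,
                                            n_specimens = 2, n_blanks = 2,
                                            depth = 2000,
                                            n_contaminants = 5))
    taus <- sort(runif(4, 0.02, 0.9))
    flagged_sets <- lapply(taus, function(tau) {
      fl <- flag_contaminants(ct$table, decontam_config(tau = tau))
      fl$otu_id[fl$flagged]
    })
    for (i in seq_len(length(taus) - 1)) {
      expect_true(all(flagged_sets[[i + 1]] %in% flagged_sets[[i]]))
    }
  }
})

test_that("flags and report are invariant to OTU and sample order", {
  ct <- simulate_count_table(fixture_spec(seed = 3, n_otus = 25,
                                          n_specimens = 3, n_blanks = 2,
                                          depth = 2000, n_contaminants = 4))
  tbl <- ct$table
  perm <- tibble::as_tibble(as.data.frame(tbl))
  perm <- perm[sample(nrow(perm)), c("otu_id", sample(setdiff(names(perm),
                                                              "otu_id")))]
  tbl2 <- count_table(perm, sample_roles(tbl))
  f1 <- flag_contaminants(tbl)
  f2 <- flag_contaminants(tbl2)
  expect_identical(f1$otu_id, f2$otu_id)
  expect_equal(f1$blank_share, f2$blank_share)
  r1 <- apply_review(tbl, f1, setNames("remove", f1$otu_id[1]))$report
  r2 <- apply_review(tbl2, f2, setNames("remove", f2$otu_id[1]))$report
  expect_equal(glance(r1), glance(r2))
})

test_that("annotation attaches ranked reference hits to flagged OTUs only", {
  set.seed(8)
  db <- tibble::tibble(id = sprintf("ref%02d", 1:30),
                       seq = replicate(30, rand_seq(180)),
                       taxonomy = paste0("t", 1:30),
                       environment_source = c("human skin",
                                              rep("soil", 29)))
  roles <- c(S1 = "specimen", B1 = "blank")
  tbl <- count_table(tibble::tibble(otu_id = c("contam", "clean"),
                                    S1 = c(0L, 1000L),
                                    B1 = c(500L, 500L)), roles)
  reps <- tibble::tibble(id = c("contam", "clean"),
                         seq = c(db$seq[1], rand_seq(180)))
  fl <- flag_contaminants(tbl, decontam_config(tau = 0.5))
  fl <- annotate_flagged(fl, reps, db)
  hit <- fl$hits[[which(fl$otu_id == "contam")]]
  expect_identical(hit$subject_id[1], "ref01")
  expect_identical(hit$environment_source[1], "human skin")
  expect_equal(hit$identity[1], 100)
  expect_lte(nrow(hit), 10)
  expect_null(fl$hits[[which(fl$otu_id == "clean")]])

  # ranked hits equal the exhaustive top-k over seed-sharing candidates
  want <- oracle_search(db$seq[1], db, top_k = 30)
  shared <- want[want$subject_id %in% hit$subject_id, , drop = FALSE]
  expect_identical(hit$subject_id, head(shared$subject_id, nrow(hit)))

  # flagged OTU without representative sequence
  expect_error(annotate_flagged(fl, reps[2, ], db),
               class = "ts_annotation_error")
  # empty flag list passes through
  fl0 <- flag_contaminants(tbl, decontam_config(tau = 0.9999))
  expect_equal(sum(fl0$flagged), 1L)  # blank-only share is 1 -> still flagged
})

test_that("reviewed culling counts removals and conserves reads", {
  set.seed(9)
  # 30 OTUs, 22 flagged by construction, 17 removed
  n <- 30
  roles <- c(S1 = "specimen", B1 = "blank")
  counts <- tibble::tibble(
    otu_id = sprintf("o%02d", 1:n),
    S1 = c(rep(10L, 22), rep(300L, 8)),
    B1 = c(rep(100L, 22), rep(2L, 8))
  )
  tbl <- count_table(counts, roles)
  fl <- flag_contaminants(tbl, decontam_config(tau = 0.5))
  expect_equal(sum(fl$flagged), 22L)
  dec <- setNames(rep("remove", 17), head(fl$otu_id[fl$flagged], 17))
  res <- apply_review(tbl, fl, dec)
  g <- glance(res$report)
  expect_equal(g$n_flagged, 22L)
  expect_equal(g$n_removed, 17L)
  expect_equal(g$n_retained_otus, n - 17L)
  # conservation: input total = surviving + removed, exactly
  expect_identical(g$total_reads,
                   sum(as.matrix(res$table[-1])) + g$removed_reads)
  # undecided flagged OTUs stay pending, decided ones recorded
  rec <- tidy(res$report)
  expect_setequal(unique(rec$decision[rec$flagged]), c("remove", "pending"))

  expect_error(apply_review(tbl, fl, setNames("remove", "o30")),
               class = "ts_review_error")
})

test_that("retention percentage reflects removed read mass", {
  roles <- c(S1 = "specimen", B1 = "blank")
  # removed OTU carries 30.1% of all reads -> 69.9% retained
  tbl <- count_table(tibble::tibble(otu_id = c("kit", "bio"),
                                    S1 = c(1L, 599L),
                                    B1 = c(300L, 100L)), roles)
  fl <- flag_contaminants(tbl, decontam_config(tau = 0.5))
  res <- apply_review(tbl, fl, c(kit = "remove"))
  expect_equal(res$report$pct_sequences_retained, 69.9)

  none <- apply_review(tbl, fl)
  expect_equal(none$report$pct_sequences_retained, 100)
  expect_identical(tibble::as_tibble(as.data.frame(none$table)),
                   tibble::as_tibble(as.data.frame(tbl)))
})
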