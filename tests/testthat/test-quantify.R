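test_that("coverage tracks follow interval arithmetic", {
  expect_equal(as.integer(coverage_track(make_hits(integer(0), integer(0)),
                                         100)),
               rep(0L, 100))
  tr <- coverage_track(make_hits(c(0, 50), c(100, 150)), 200)
  expect_equal(as.integer(tr[1:50]), rep(1L, 50))
  expect_equal(as.integer(tr[51:100]), rep(2L, 50))
  expect_equal(as.integer(tr[101:150]), rep(1L, 50))
  expect_equal(as.integer(tr[151:200]), rep(0L, 50))

  # sub-threshold identity contributes nothing
  low <- make_hits(0, 100, identity = 94.9)
  expect_equal(sum(coverage_track(low, 200)), 0)
  # coordinates beyond the genome are invalid
  expect_error(coverage_track(make_hits(0, 300), 200), "outside")
})

test_that("presence rule requires one consecutive covered stretch", {
  t1 <- coverage_track(make_hits(10, 260), 1000)
  p1 <- call_presence(t1)
  expect_true(p1$present)
  expect_equal(p1$longest_run_bp, 250L)

  # two 150 bp islands do not add up to presence
  t2 <- coverage_track(make_hits(c(0, 500), c(150, 650)), 1000)
  p2 <- call_presence(t2)
  expect_false(p2$present)
  expect_equal(p2$longest_run_bp, 150L)

  # exactly 200 bp is present (inclusive boundary)
  t3 <- coverage_track(make_hits(100, 300), 1000)
  expect_true(call_presence(t3)$present)
  expect_false(call_presence(t3, min_run_bp = 201)$present)
})

test_that("presence agrees with a brute-force longest-run scanner", {
  withr::with_seed(17, {
    for (i in 1:200) {
      len <- sample(300:1200, 1)
      n_hits <- sample(0:15, 1)
      if (n_hits > 0) {
        start <- sample(0:(len - 50), n_hits, replace = TRUE)
        width <- sample(30:250, n_hits, replace = TRUE)
        hits <- make_hits(start, pmin(start + width, len))
      } else {
        hits <- make_hits(integer(0), integer(0))
      }
      tr <- coverage_track(hits, len)
      pc <- call_presence(tr)
      expect_identical(pc$longest_run_bp, brute_longest_run(tr))
      expect_identical(pc$present, brute_longest_run(tr) >= 200L)
    }
  })
})

test_that("median-coverage abundance normalises per million reads", {
  uniform <- coverage_track(make_hits(rep(0, 5), rep(1000, 5)), 1000)
  expect_equal(median_coverage_abundance(uniform, 2e6), 2.5)

  half <- coverage_track(make_hits(c(0, 0), c(500, 500)), 1000)
  expect_equal(median(as.numeric(half)), 1)  # even-length median, 500/500 split
  expect_equal(median_coverage_abundance(half, 1e6, min_run_bp = 200), 1)

  none <- coverage_track(make_hits(integer(0), integer(0)), 1000)
  expect_equal(median_coverage_abundance(none, 1e6), 0)
  expect_error(median_coverage_abundance(uniform, 0), "> 0")

  # absent under the presence rule means abundance 0 even with reads
  sparse <- coverage_track(make_hits(0, 150), 300)
  expect_equal(median_coverage_abundance(sparse, 1e6), 0)
  expect_gt(median_coverage_abundance(sparse, 1e6, min_run_bp = NULL,
                                      zeros = FALSE), 0)
})

test_that("adding qualifying reads never flips presence off or lowers abundance", {
  withr::with_seed(23, {
    for (i in 1:20) {
      len <- 800
      s1 <- sample(0:600, 5); hits1 <- make_hits(s1, s1 + 180)
      extra_start <- sample(0:600, 1)
      hits2 <- dplyr::bind_rows(hits1, make_hits(extra_start,
                                                 extra_start + 180,
                                                 read_id = "extra"))
      t1 <- coverage_track(hits1, len); t2 <- coverage_track(hits2, len)
      p1 <- call_presence(t1); p2 <- call_presence(t2)
      expect_true(!p1$present || p2$present)
      expect_gte(median_coverage_abundance(t2, 1e6),
                 median_coverage_abundance(t1, 1e6))
    }
  })
})

test_that("abundance matrices are built, normalised and aggregated", {
  q <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 3),
    genome_id = rep(c("g1", "g2", "g3"), 2),
    abundance = c(2, 2, 0, 1, 0, 0)
  )
  mat <- build_abundance_matrix(q)
  expect_equal(attr(mat, "value_kind"), "relative")
  expect_false("g3" %in% names(mat))           # absent everywhere: dropped
  m <- abund_matrix(mat)
  expect_equal(unname(rowSums(m)), c(1, 1))
  expect_equal(m["s1", "g1"], 0.5)
  expect_equal(m["s2", "g1"], 1)

  # single detected genome -> relative 1; all-zero sample kept with message
  q2 <- tibble::tibble(sample_id = c("s1", "s2"),
                       genome_id = c("g1", "g1"), abundance = c(3, 0))
  expect_message(mat2 <- build_abundance_matrix(q2), "all-zero")
  expect_equal(abund_matrix(mat2)["s1", "g1"], 1)
  expect_equal(abund_matrix(mat2)["s2", "g1"], 0)

  expect_error(build_abundance_matrix(dplyr::mutate(q, abundance = -1)),
               "non-negative")
})

test_that("host aggregation sums within taxa and conserves row mass", {
  ref <- tibble::tibble(
    genome_id = c("g1", "g2", "g3", "g4"),
    sequence = strrep("A", 4), length = 1000L,
    virus_type = c("phage", "phage", "phage", "eukaryotic"),
    host_phylum = c("Firmicutes", "Firmicutes", "Bacteriodetes", NA),
    host_genus = c("Streptococcus", "Streptococcus", "Prevotella", NA)
  )
  mat <- tibble::tibble(sample_id = c("s1", "s2"),
                        g1 = c(0.2, 0.1), g2 = c(0.3, 0.2),
                        g3 = c(0.5, 0.3), g4 = c(0, 0.4))
  byg <- aggregate_by_host(mat, ref, "genus")
  m <- abund_matrix(byg)
  expect_equal(m["s1", "Streptococcus"], 0.5)
  expect_equal(m["s2", "Eukaryotic viruses"], 0.4)
  expect_equal(unname(rowSums(m)), unname(rowSums(abund_matrix(mat))))

  byp <- aggregate_by_host(mat, ref, "phylum")
  expect_equal(abund_matrix(byp)["s1", "Firmicutes"], 0.5)

  refbad <- dplyr::mutate(ref,
                          host_genus = ifelse(genome_id == "g3",
                                              NA_character_, host_genus))
  expect_error(aggregate_by_host(mat, refbad, "genus"), "g3")
  expect_error(aggregate_by_host(dplyr::rename(mat, gX = g1), ref, "genus"),
               "missing")
})

test_that("quantification recovers a planted dominant genus", {
  ref <- generate_reference_db(100, seed = 61)
  spec <- default_effect_spec(
    fold_changes = tibble::tibble(host_genus = "Propionibacterium",
                                  fold_change = 8,
                                  enriched_group = "smoker"))
  des <- design_communities(ref, c(smoker = 6, nonsmoker = 4),
                            effect_spec = spec, deflate_planted = FALSE,
                            seed = 62)
  g <- aggregate_by_host(des$abundance, ref, "genus")
  m <- abund_matrix(g)
  totals <- colSums(m) / sum(m)
  expect_equal(names(which.max(totals)), "Propionibacterium")
})
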