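test_that("quality trimming removes low-quality ends and short reads", {
  # all qualities above threshold: identity
  r <- make_reads(c("ACGTACGT", "TTTTCCCC"))
  out <- quality_trim(r, phred_min = 10, min_length = 4)
  expect_equal(out$sequence, r$sequence)
  expect_equal(attr(out, "n_dropped"), 0)

  # all-low read dropped
  low <- tibble::tibble(read_id = "r1", sequence = "ACGTACGT",
                        quality = strrep(rawToChar(as.raw(33 + 2)), 8))
  out <- quality_trim(low, phred_min = 10, min_length = 4)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_dropped"), 1)

  # two low-quality bases at each end: trimmed to the inner 4
  q2 <- rawToChar(as.raw(33 + 2)); q30 <- rawToChar(as.raw(33 + 30))
  mixed <- tibble::tibble(
    read_id = "r1", sequence = "ACGTACGT",
    quality = paste0(strrep(q2, 2), strrep(q30, 4), strrep(q2, 2)))
  out <- quality_trim(mixed, phred_min = 10, min_length = 4)
  expect_equal(out$sequence, "GTAC")

  # malformed record: lengths differ
  bad <- tibble::tibble(read_id = "r1", sequence = "ACGT", quality = "FFF")
  expect_error(quality_trim(bad), "malformed")
})

test_that("deduplication keeps first occurrences only", {
  r <- make_reads(c("AAAA", "CCCC", "AAAA", "GGGG", "AAAA"))
  out <- deduplicate(r)
  expect_equal(out$sequence, c("AAAA", "CCCC", "GGGG"))
  expect_equal(out$read_id[1], "r001")
  expect_equal(attr(out, "n_removed"), 2)

  nodup <- make_reads(c("AAAA", "CCCC"))
  expect_equal(deduplicate(nodup)$sequence, nodup$sequence)
})

test_that("dedup removes close to the simulated duplicate fraction", {
  # genomes long enough that coincidental identical reads are rare
  ref <- small_reference(5, seed = 3, len = c(6000, 9000))
  des <- design_communities(
    ref, c(smoker = 2, nonsmoker = 2),
    effect_spec = null_effect_spec(richness = 5), seed = 3)
  cfg <- sim_config(reads_per_sample = 10000, read_length = 100,
                    duplicate_rate = 0.1, host_contamination_fraction = 0,
                    substitution_error_rate = 0.01, seed = 6)
  reads <- simulate_reads(des, simulate_host_genome(1000, 1), cfg,
                          samples = "S01")$reads$S01
  out <- deduplicate(reads)
  frac <- attr(out, "n_removed") / nrow(reads)
  # coincidental duplicates are possible on top of the planted ones
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.15)
})

test_that("mapper finds exact substrings at full identity and true offset", {
  g <- simulate_host_genome(3000, seed = 5)
  read <- substr(g, 501, 650)
  hits <- map_reads(make_reads(read), c(gA = g), seed_k = 21)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$percent_identity, 100)
  expect_equal(hits$start, 500)
  expect_equal(hits$end, 650)
  expect_equal(hits$strand, "+")
  expect_true(hits$best)
})

test_that("reverse-complemented reads hit on the minus strand, same span", {
  g <- simulate_host_genome(3000, seed = 5)
  read <- substr(g, 501, 650)
  hits <- map_reads(make_reads(revcomp(read)), c(gA = g), seed_k = 21)
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 500)
  expect_equal(hits$end, 650)
  expect_equal(hits$percent_identity, 100)
})

test_that("reads below the identity threshold yield no qualifying hit", {
  g <- simulate_host_genome(3000, seed = 5)
  read <- substr(g, 501, 650)
  # 10 substitutions spread over 150 bp: identity 140/150 = 93.33%
  mut <- substitute_bases(read, seq(8, 150, by = 15)[1:10])
  none <- map_reads(make_reads(mut), c(gA = g), seed_k = 8,
                    min_identity_pct = 95)
  expect_equal(nrow(none), 0)
  some <- map_reads(make_reads(mut), c(gA = g), seed_k = 8,
                    min_identity_pct = 90)
  expect_equal(nrow(some), 1)
  expect_equal(some$percent_identity, 100 * 140 / 150)
})

test_that("mapper input validation", {
  expect_error(map_reads(make_reads("ACGT"), character(0)), "empty")
  expect_error(map_reads(make_reads("ACGT"), c(g = "ACGTACGT"),
                         min_identity_pct = 150), "min_identity")
})

test_that("error-free synthetic reads recover their origin genome", {
  ref <- generate_reference_db(50, c(1000, 2000), seed = 21)
  des <- design_communities(ref, c(smoker = 2, nonsmoker = 2),
                            effect_spec = null_effect_spec(richness = 30),
                            seed = 2)
  cfg <- sim_config(reads_per_sample = 4000, substitution_error_rate = 0,
                    host_contamination_fraction = 0, duplicate_rate = 0,
                    seed = 4)
  sr <- simulate_reads(des, simulate_host_genome(1000, 1), cfg,
                       samples = "S01")
  hits <- map_reads(sr$reads$S01, ref)
  best <- hits[hits$best, ]
  m <- dplyr::inner_join(sr$truth, best, by = "read_id")
  expect_gte(nrow(m) / nrow(sr$reads$S01), 0.99)
  expect_gte(mean(m$origin == m$genome_id), 0.99)
})

test_that("host removal discards contaminant reads at the expected rate", {
  host <- simulate_host_genome(5e4, seed = 31)
  read_from_host <- make_reads(substr(host, 1001, 1150))
  expect_equal(nrow(remove_host(read_from_host, host)), 0)

  ref <- small_reference(10, seed = 32)
  des <- design_communities(ref, c(smoker = 2, nonsmoker = 2),
                            effect_spec = null_effect_spec(richness = 8),
                            seed = 33)
  cfg <- sim_config(reads_per_sample = 5000,
                    host_contamination_fraction = 0.3, duplicate_rate = 0,
                    seed = 34)
  sr <- simulate_reads(des, host, cfg, samples = "S01")
  out <- remove_host(sr$reads$S01, host)
  frac <- attr(out, "n_removed") / nrow(sr$reads$S01)
  expect_gte(frac, qbinom(0.005, 5000, 0.3) / 5000)
  expect_lte(frac, qbinom(0.995, 5000, 0.3) / 5000)
  # viral reads without host homology survive
  expect_gte(nrow(out) / sum(sr$truth$origin != "host"), 0.99)
})

test_that("process_reads enforces trim -> dedup -> host-removal accounting", {
  ref <- small_reference(10, seed = 41)
  des <- design_communities(ref, c(smoker = 2, nonsmoker = 2),
                            effect_spec = null_effect_spec(richness = 8),
                            seed = 42)
  host <- simulate_host_genome(2e4, seed = 43)
  cfg <- sim_config(reads_per_sample = 2000, seed = 44)
  reads <- simulate_reads(des, host, cfg, samples = "S01")$reads$S01
  pr <- process_reads(reads, host)
  expect_equal(pr$accounting$stage,
               c("raw", "trimmed", "deduplicated", "host_removed"))
  expect_true(all(diff(pr$accounting$reads) <= 0))
  expect_equal(pr$accounting$reads[4], nrow(pr$reads))
})
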