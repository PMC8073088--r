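make_counts <- function(pool_id, gene = "g", pos = 1L, ref = "G",
                        nA = 0L, nC = 0L, nG = 0L, nT = 0L) {
  data.frame(pool_id = pool_id, gene_id = gene, cds_pos = pos, ref = ref,
             nA = nA, nC = nC, nG = nG, nT = nT,
             depth = nA + nC + nG + nT)
}

test_that("qual matches an independent exact binomial-tail summation", {
  e <- 0.001
  for (case in list(c(960, 20), c(480, 10), c(960, 5), c(2000, 40))) {
    depth <- case[1]; k <- case[2]
    counts <- make_counts("V001", nA = k, nG = depth - k)
    call <- call_pool(counts, error_rate = e)
    expect_equal(nrow(call), 1L)
    oracle <- -10 * log10(binom_tail_oracle(k, depth, e / 3))
    expect_equal(call$qual, oracle, tolerance = 1e-8)
    expect_equal(call$af_hat, k / depth)
    expect_equal(call$alt_reads, k)
  }
})

test_that("no alt evidence yields no call; saturation hits the 3000 cap", {
  counts <- make_counts("V001", nG = 960L)
  expect_equal(nrow(call_pool(counts)), 0L)
  sat <- make_counts("V001", nA = 960L)
  expect_equal(call_pool(sat)$qual, 3000)
})

test_that("calls below min_alt_reads are suppressed and zero depth warns", {
  counts <- make_counts("V001", nA = 2L, nG = 958L)
  expect_equal(nrow(call_pool(counts, min_alt_reads = 3)), 0L)
  expect_equal(nrow(call_pool(counts, min_alt_reads = 2)), 1L)
  zero <- make_counts("V001")
  expect_warning(out <- call_pool(zero), "zero-depth")
  expect_equal(nrow(out), 0L)
})

test_that("multiple alt bases at one site are independent records", {
  counts <- make_counts("V001", nA = 5L, nC = 4L, nG = 951L)
  calls <- call_pool(counts)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("A", "C"))
})

test_that("two-pool support passes the filter, one-pool support does not", {
  sc <- build_scheme()
  calls <- rbind(
    data.frame(pool_id = "V001", gene_id = "g", cds_pos = 10L, ref = "G",
               alt = "A", af_hat = 0.02, qual = 900, alt_reads = 10L, depth = 480L),
    data.frame(pool_id = "H001", gene_id = "g", cds_pos = 10L, ref = "G",
               alt = "A", af_hat = 0.01, qual = 800, alt_reads = 10L, depth = 960L)
  )
  v <- integrate_and_filter(calls, sc, qual_min = 700, ac_min = 4)
  expect_equal(nrow(v), 1L)
  expect_equal(v$AC, 4L)
  expect_equal(v$QUAL, 800)
  expect_equal(v$filter, "PASS")
  expect_equal(v$vpools, "V001")
  expect_equal(v$hpools, "H001")

  v1 <- integrate_and_filter(calls[1, ], sc, qual_min = 700, ac_min = 4)
  expect_equal(v1$AC, 2L)
  expect_equal(v1$filter, "lowAC")
})

test_that("zero thresholds return the grouped input unfiltered", {
  sc <- build_scheme()
  calls <- data.frame(
    pool_id = c("V001", "H002", "V005"),
    gene_id = "g", cds_pos = c(10L, 10L, 99L), ref = "G", alt = "A",
    af_hat = 0.02, qual = c(5, 30, 12), alt_reads = 3L, depth = 480L
  )
  v <- integrate_and_filter(calls, sc, qual_min = 0, ac_min = 0)
  expect_equal(nrow(v), 2L)
  expect_true(all(v$filter == "PASS"))
  expect_equal(sum(v$n_pools), 3L)
})

test_that("a weak stray call elsewhere neither blocks nor boosts a variant", {
  sc <- build_scheme()
  calls <- rbind(
    data.frame(pool_id = "V001", gene_id = "g", cds_pos = 10L, ref = "G",
               alt = "A", af_hat = 0.02, qual = 150, alt_reads = 10L, depth = 480L),
    data.frame(pool_id = "H001", gene_id = "g", cds_pos = 10L, ref = "G",
               alt = "A", af_hat = 0.01, qual = 120, alt_reads = 10L, depth = 960L),
    # error-level call at the same site in an unrelated pool
    data.frame(pool_id = "H007", gene_id = "g", cds_pos = 10L, ref = "G",
               alt = "A", af_hat = 0.003, qual = 20, alt_reads = 3L, depth = 960L)
  )
  v <- integrate_and_filter(calls, sc, qual_min = 40, ac_min = 4)
  expect_equal(v$filter, "PASS")
  expect_equal(v$QUAL, 120)    # not dragged to 20
  expect_equal(v$AC, 4L)       # stray call does not inflate AC
  expect_equal(v$hpools, "H001")
})

test_that("variants referencing unknown pools raise an integration error", {
  sc <- build_scheme(6)
  calls <- data.frame(pool_id = "V199", gene_id = "g", cds_pos = 1L, ref = "G",
                      alt = "A", af_hat = 0.1, qual = 100, alt_reads = 5L,
                      depth = 100L)
  expect_error(integrate_and_filter(calls, sc), "unknown")
})

test_that("raising thresholds never adds variants (monotonicity)", {
  sc <- build_scheme(6)
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 576, density = 1 / 20000, seed = 13)
  counts <- simulate_pool_sequencing(pop, sc, seq_config(seed = 14))
  calls <- call_pool(counts)
  keys <- function(v) {
    p <- passing_variants(v)
    paste(p$gene_id, p$cds_pos, p$alt)
  }
  base <- keys(integrate_and_filter(calls, sc, qual_min = 20, ac_min = 2))
  tighter_q <- keys(integrate_and_filter(calls, sc, qual_min = 60, ac_min = 2))
  tighter_ac <- keys(integrate_and_filter(calls, sc, qual_min = 20, ac_min = 4))
  expect_true(all(tighter_q %in% base))
  expect_true(all(tighter_ac %in% base))
})

test_that("planted heterozygous singletons are retained at design depth", {
  # one het carrier in a 24-line vertical and a 48-line horizontal pool,
  # sequenced at defaults; both pool calls must survive the default filter
  sc <- build_scheme()
  retained <- vapply(seq_len(200), function(i) {
    vb <- sequence_pool(c(1L, rep(0L, 23)), ref = "G", alt = "A",
                        cfg = seq_config(seed = 2 * i), pool_id = "V001")
    hb <- sequence_pool(c(1L, rep(0L, 47)), ref = "G", alt = "A",
                        cfg = seq_config(seed = 2 * i + 1), pool_id = "H001")
    calls <- call_pool(rbind(vb, hb))
    v <- integrate_and_filter(calls, sc)
    nrow(passing_variants(v)) == 1L
  }, logical(1))
  expect_gte(mean(retained), 0.9)
})

test_that("a carrier-free simulation yields no passing variant", {
  # 36 pools x ~2800 sites ~ 1e5 pool-sites, no carriers anywhere
  sc <- build_scheme(6)
  genes <- list(gene_model("gA", random_cds(500L, seed = 21)),
                gene_model("gB", random_cds(436L, seed = 22)))
  pop <- simulate_population(genes, n_lines = 576, density = 1e-12, seed = 23)
  expect_equal(nrow(pop$mutations), 0L)
  counts <- simulate_pool_sequencing(pop, sc, seq_config(seed = 24))
  calls <- call_pool(counts)
  v <- integrate_and_filter(calls, sc)
  expect_equal(nrow(passing_variants(v)), 0L)
})
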