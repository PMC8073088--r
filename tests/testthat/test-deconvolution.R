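variant_row <- function(vpools = "V001", hpools = "H001", gene = "g",
                        pos = 10L, ref = "G", alt = "A") {
  data.frame(gene_id = gene, cds_pos = pos, ref = ref, alt = alt,
             vpools = vpools, hpools = hpools, n_pools = 2L, AC = 4L,
             QUAL = 100, AF = 0.02, filter = "PASS")
}

test_that("a variant in a sample's two pools decodes to its plate pair", {
  sc <- build_scheme()
  p <- pools_of(sc, 0, 3, 5)
  v <- variant_row(pool_label("V", p$vpool), pool_label("H", p$hpool))
  d <- demultiplex(v, sc)
  expect_equal(d$status, "candidates")
  expect_equal(d$n_candidates, 2L)
  cand <- d$candidates[[1]]
  expect_setequal(paste(cand$plate, cand$row, cand$col), c("0 3 5", "1 3 5"))
})

test_that("multi-pool support unions pairwise decodes (never products)", {
  sc <- build_scheme()
  p1 <- pools_of(sc, 0, 3, 5)  # lines in plate pair 0
  p2 <- pools_of(sc, 2, 6, 5)  # plate pair 1, same plate group, same column
  v <- variant_row(
    paste(pool_label("V", c(p1$vpool, p2$vpool)), collapse = ","),
    pool_label("H", p1$hpool)
  )
  d <- demultiplex(v, sc)
  expect_equal(d$status, "candidates")
  expect_lte(d$n_candidates, 4L)
  cand <- d$candidates[[1]]
  # the union of the two compatible decodes, not a 2x2 cross product of rows
  expect_setequal(paste(cand$plate, cand$row, cand$col),
                  c("0 3 5", "1 3 5", "2 6 5", "3 6 5"))
})

test_that("one-axis support is unresolvable, mismatched axes discordant", {
  sc <- build_scheme()
  v <- variant_row(vpools = "V001", hpools = "")
  expect_equal(demultiplex(v, sc)$status, "unresolvable")
  # vpool from plate pair 0 but hpool from plate group 1: empty intersection
  d <- demultiplex(variant_row("V001", pool_label("H", sc$n_cols)), sc)
  expect_equal(d$status, "discordant")
  expect_equal(d$n_candidates, 0L)
})

test_that("Sanger lookup resolves the planted carrier among two candidates", {
  sc <- build_scheme()
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 4032, density = 1e-12, seed = 1)
  # plant one known mutation in the line at (0,3,5)
  target <- pop$lines$line_id[pop$lines$plate == 0 & pop$lines$row == 3 &
                                pop$lines$col == 5]
  pop$mutations <- data.frame(line_id = target, gene_id = "geneA",
                              cds_pos = 50L, ref = substr(genes[[1]]$cds_seq, 50, 50),
                              alt = "A", zygosity = "heterozygous")
  p <- pools_of(sc, 0, 3, 5)
  v <- variant_row(pool_label("V", p$vpool), pool_label("H", p$hpool),
                   gene = "geneA", pos = 50L, alt = "A")
  res <- sanger_resolve(demultiplex(v, sc), pop)
  expect_equal(res$status, "resolved")
  expect_equal(res$resolved_line, target)
})

test_that("carrier-free variants are flagged false positives", {
  sc <- build_scheme()
  pop <- simulate_population(small_gene_panel(), n_lines = 4032,
                             density = 1e-12, seed = 2)
  p <- pools_of(sc, 5, 2, 7)
  v <- variant_row(pool_label("V", p$vpool), pool_label("H", p$hpool),
                   gene = "geneA", pos = 9L)
  res <- sanger_resolve(demultiplex(v, sc), pop)
  expect_equal(res$status, "false_positive")
  expect_true(is.na(res$resolved_line))
})

test_that("two carriers in one candidate set raise a collision flag", {
  sc <- build_scheme()
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 4032, density = 1e-12, seed = 3)
  # the two wells of one decode pair both carry the same mutation
  ids <- pop$lines$line_id[(pop$lines$plate %in% c(0, 1)) &
                             pop$lines$row == 3 & pop$lines$col == 5]
  expect_length(ids, 2L)
  ref <- substr(genes[[1]]$cds_seq, 50, 50)
  pop$mutations <- data.frame(line_id = ids, gene_id = "geneA", cds_pos = 50L,
                              ref = ref, alt = "A", zygosity = "heterozygous")
  p <- pools_of(sc, 0, 3, 5)
  v <- variant_row(pool_label("V", p$vpool), pool_label("H", p$hpool),
                   gene = "geneA", pos = 50L, alt = "A")
  res <- sanger_resolve(demultiplex(v, sc), pop)
  expect_equal(res$status, "collision")
  expect_setequal(strsplit(res$resolved_line, ",")[[1]], ids)
})

test_that("recovery rate is the resolved-correct fraction of planted truth", {
  planted <- data.frame(line_id = sprintf("L%02d", 1:10), gene_id = "g",
                        cds_pos = 1:10, alt = "A")
  resolved <- data.frame(gene_id = "g", cds_pos = 1:7, alt = "A",
                         status = "resolved",
                         resolved_line = sprintf("L%02d", 1:7))
  expect_equal(recovery_rate(planted, resolved), 0.7)
  expect_message(na <- recovery_rate(planted[0, ], resolved), "not applicable")
  expect_true(is.na(na))
})
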