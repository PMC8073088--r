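test_that("gene models reject malformed CDSs", {
  expect_error(gene_model("g", "ATGC"), "divisible by 3")
  expect_error(gene_model("g", "ATGNNN"), "A/C/G/T")
  expect_error(gene_model("g", "ATGTAACCC"), "internal stop")
  g <- gene_model("g", "ATGTGA")  # terminal stop is allowed
  expect_equal(g$amplicon_bp, 6L)
})

test_that("default spectrum carries the EMS transition bias and sums to 1", {
  sp <- spectrum_model()
  expect_equal(sum(sp), 1, tolerance = 1e-12)
  expect_equal(sp[["G>A"]], 0.424)
  expect_equal(sp[["C>T"]], 0.401)
  others <- setdiff(substitution_types(), c("G>A", "C>T"))
  expect_equal(unname(unclass(sp)[others]), rep(0.175 / 10, 10))
})

test_that("zero-density populations carry no mutations", {
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 50, density = 1e-12, seed = 1)
  expect_equal(nrow(pop$mutations), 0L)
})

test_that("a pure G>A spectrum yields only G>A mutations", {
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 400, density = 1 / 2000,
                             spectrum = spectrum_model(c("G>A" = 1)), seed = 2)
  expect_gt(nrow(pop$mutations), 50)
  expect_true(all(pop$mutations$ref == "G"))
  expect_true(all(pop$mutations$alt == "A"))
})

test_that("mutations match their reference base and are unique per line-gene", {
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 300, density = 1 / 1500, seed = 3)
  m <- pop$mutations
  expect_gt(nrow(m), 100)
  cds <- vapply(pop$genes, `[[`, character(1), "cds_seq")
  expect_equal(unname(substring(cds[m$gene_id], m$cds_pos, m$cds_pos)), m$ref)
  expect_true(all(m$ref != m$alt))
  expect_false(any(duplicated(m[, c("line_id", "gene_id", "cds_pos")])))
})

test_that("realized mutation count and spectrum recover the configured model", {
  genes <- synthetic_gene_panel(seed = 9)
  total_bp <- sum(vapply(genes, `[[`, integer(1), "amplicon_bp"))
  n_lines <- 4032L
  density <- 1 / 212000
  pop <- simulate_population(genes, n_lines = n_lines, density = density, seed = 4)
  lambda <- density * total_bp * n_lines  # ~274
  expect_lt(abs(nrow(pop$mutations) - lambda), 3 * sqrt(lambda))

  # spectrum recovery at high mutation count: a denser population
  pop2 <- simulate_population(genes, n_lines = 1000, density = 1 / 1000, seed = 5)
  m <- pop2$mutations
  expect_gt(nrow(m), 1e4)
  emp <- table(factor(paste0(m$ref, ">", m$alt), levels = substitution_types()))
  # expected marginals under joint position-type rejection: per gene, type
  # weight = spectrum * count of its reference base; genes contribute in
  # proportion to their amplicon size
  sp <- unclass(spectrum_model())
  type_ref <- substr(names(sp), 1, 1)
  expected <- 0
  amps <- vapply(genes, `[[`, integer(1), "amplicon_bp")
  for (g in genes) {
    nb <- table(factor(strsplit(g$cds_seq, "")[[1]], levels = c("A", "C", "G", "T")))
    w <- sp * as.numeric(nb[type_ref])
    expected <- expected + (g$amplicon_bp / sum(amps)) * w / sum(w)
  }
  for (ty in c("G>A", "C>T", "A>C", "T>G")) {
    phat <- emp[[ty]] / nrow(m)
    se <- sqrt(expected[[ty]] * (1 - expected[[ty]]) / nrow(m))
    expect_lt(abs(phat - expected[[ty]]), 2.58 * se + 0.005)
  }
  # and on this near-balanced panel the marginals sit close to the spectrum
  expect_lt(abs(emp[["G>A"]] / nrow(m) - sp[["G>A"]]), 0.05)
  expect_lt(abs(emp[["C>T"]] / nrow(m) - sp[["C>T"]]), 0.05)
})

test_that("population simulation is reproducible under a fixed seed", {
  genes <- small_gene_panel()
  p1 <- simulate_population(genes, n_lines = 100, density = 1 / 5000, seed = 7)
  p2 <- simulate_population(genes, n_lines = 100, density = 1 / 5000, seed = 7)
  expect_identical(p1$mutations, p2$mutations)
})

test_that("M2 zygosity follows het_fraction", {
  genes <- small_gene_panel()
  pop <- simulate_population(genes, n_lines = 500, density = 1 / 1000,
                             het_fraction = 1, seed = 8)
  expect_true(all(pop$mutations$zygosity == "heterozygous"))
  pop0 <- simulate_population(genes, n_lines = 500, density = 1 / 1000,
                              het_fraction = 0, seed = 8)
  expect_true(all(pop0$mutations$zygosity == "homozygous"))
})

test_that("selfing a heterozygote segregates 1:2:1 and homozygotes breed true", {
  het <- data.frame(line_id = "L1", gene_id = "g", cds_pos = 10L, ref = "G",
                    alt = "A", zygosity = "heterozygous")
  g <- self_to_m3(het, n_progeny = 40000L, seed = 11)
  frac <- c(g$n_wt, g$n_het, g$n_hom) / 40000
  expect_lt(abs(frac[1] - 0.25), 0.02)
  expect_lt(abs(frac[2] - 0.50), 0.02)
  expect_lt(abs(frac[3] - 0.25), 0.02)
  expect_equal(g$n_wt + g$n_het + g$n_hom, 40000L)

  hom <- het
  hom$zygosity <- "homozygous"
  gh <- self_to_m3(hom, n_progeny = 500L, seed = 11)
  expect_equal(gh$n_hom, 500L)
  expect_equal(gh$n_wt + gh$n_het, 0L)

  expect_identical(self_to_m3(het, n_progeny = 1L, seed = 3),
                   self_to_m3(het, n_progeny = 1L, seed = 3))
})
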