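test_that("default scheme reproduces the 168/84 pool geometry", {
  sc <- build_scheme(42, 8, 12, 2, 6)
  expect_equal(sc$n_samples, 4032L)
  expect_equal(sc$n_vpools, 168L)
  expect_equal(sc$n_hpools, 84L)
  expect_equal(sc$vpool_size, 24L)
  expect_equal(sc$hpool_size, 48L)
  for (id in c(0L, 57L, 167L)) expect_equal(nrow(pool_members(sc, "V", id)), 24L)
  for (id in c(0L, 41L, 83L)) expect_equal(nrow(pool_members(sc, "H", id)), 48L)
})

test_that("degenerate single-well scheme maps its sample to both pools", {
  sc <- build_scheme(1, 1, 1, 1, 1)
  expect_equal(sc$n_vpools, 1L)
  expect_equal(sc$n_hpools, 1L)
  expect_equal(pool_members(sc, "V", 0), data.frame(plate = 0L, row = 0L, col = 0L))
  expect_equal(pool_members(sc, "H", 0), data.frame(plate = 0L, row = 0L, col = 0L))
})

test_that("pool memberships match the brute-force enumeration oracle", {
  sc <- build_scheme(6, 8, 12, 2, 6)
  oracle <- brute_force_pooling(6, 8, 12, 2, 6)
  expect_equal(sc$n_vpools, 24L)
  expect_equal(sc$n_hpools, 12L)
  expect_length(oracle$vertical, 24L)
  expect_length(oracle$horizontal, 12L)
  for (id in seq_len(sc$n_vpools) - 1L) {
    m <- pool_members(sc, "V", id)
    expect_setequal(paste(m$plate, m$row, m$col), oracle$vertical[[as.character(id)]])
  }
  for (id in seq_len(sc$n_hpools) - 1L) {
    m <- pool_members(sc, "H", id)
    expect_setequal(paste(m$plate, m$row, m$col), oracle$horizontal[[as.character(id)]])
  }
})

test_that("non-divisible pool spans are rejected naming the parameter", {
  expect_error(build_scheme(42, 8, 12, 4, 6), "pair_size")
  expect_error(build_scheme(40, 8, 12, 2, 6), "group_size")
})

test_that("every sample belongs to exactly one pool per axis (partition)", {
  sc <- build_scheme()
  addr <- sample_address(sc, seq_len(sc$n_samples) - 1L)
  p <- pools_of(sc, addr$plate, addr$row, addr$col)
  # each pool id appears exactly pool-size times, and sizes sum to n_samples
  expect_equal(unname(table(p$vpool)), rep(sc$vpool_size, sc$n_vpools),
               ignore_attr = TRUE)
  expect_equal(unname(table(p$hpool)), rep(sc$hpool_size, sc$n_hpools),
               ignore_attr = TRUE)
  expect_equal(sum(table(p$vpool)), sc$n_samples)
  expect_equal(sum(table(p$hpool)), sc$n_samples)
})

test_that("pools_of follows the first-cell and last-cell conventions", {
  sc <- build_scheme()
  expect_equal(pools_of(sc, 0, 0, 0), data.frame(vpool = 0L, hpool = 0L))
  expect_equal(pools_of(sc, 41, 7, 11),
               data.frame(vpool = sc$n_vpools - 1L, hpool = sc$n_hpools - 1L))
  expect_error(pools_of(sc, 42, 0, 0), "out of range")
})

test_that("decoder round-trips every sample of the default scheme", {
  sc <- build_scheme()
  addr <- sample_address(sc, seq_len(sc$n_samples) - 1L)
  p <- pools_of(sc, addr$plate, addr$row, addr$col)
  # vectorized identity check over all 4032 samples: the decoded pair for a
  # sample's pools must contain the sample and have pair_size members
  dec_key <- mapply(function(v, h) {
    d <- decode_pools(sc, v, h)
    paste(paste(d$plate, d$row, d$col), collapse = ";")
  }, p$vpool, p$hpool)
  self_key <- paste(addr$plate, addr$row, addr$col)
  expect_true(all(mapply(grepl, self_key, dec_key, fixed = TRUE)))
  expect_true(all(lengths(strsplit(dec_key, ";", fixed = TRUE)) == sc$pair_size))
})

test_that("all pool-pair intersections have size 0 or pair_size", {
  sc <- build_scheme()
  sizes <- outer(seq_len(sc$n_vpools) - 1L, seq_len(sc$n_hpools) - 1L,
                 Vectorize(function(v, h) nrow(decode_pools(sc, v, h))))
  expect_setequal(unique(as.vector(sizes)), c(0L, 2L))
  # each vertical pool is compatible with exactly n_cols horizontal pools
  expect_true(all(rowSums(sizes > 0) == sc$n_cols))
  expect_true(all(colSums(sizes > 0) == (sc$group_size / sc$pair_size) * sc$n_rows))
})

test_that("incompatible plate spans decode to the empty set", {
  sc <- build_scheme()
  # vpool 0 lives on plates 0-1 (group 0); an hpool from group 1 cannot meet it
  expect_equal(nrow(decode_pools(sc, 0, sc$n_cols)), 0L)
})

test_that("manifest covers every well twice with 1-based labels", {
  sc <- build_scheme(6, 8, 12, 2, 6)
  man <- pool_manifest(sc)
  expect_equal(nrow(man), 2L * sc$n_samples)
  expect_setequal(unique(man$pool_axis), c("V", "H"))
  key <- paste(man$plate, man$well)
  expect_true(all(table(key) == 2L))
  expect_true(all(man$plate >= 1L & man$plate <= 6L))
  expect_match(man$well, "^[A-H](0[1-9]|1[0-2])$")
})

test_that("well and pool labels round-trip", {
  expect_equal(well_label(0, 0), "A01")
  expect_equal(parse_well("H12"), data.frame(row = 7L, col = 11L))
  lab <- pool_label(c("V", "H"), c(0L, 83L))
  expect_equal(lab, c("V001", "H084"))
  expect_equal(parse_pool_label(lab), data.frame(axis = c("V", "H"), id = c(0L, 83L)))
  expect_error(parse_pool_label("X01"), "malformed")
})
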