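# Independent oracles and tiny builders shared across the suite.

# Brute-force pooling oracle: enumerate every sample's two pool memberships
# directly from the design definition (loops, no package arithmetic).
brute_force_pooling <- function(n_plates, n_rows, n_cols, pair_size, group_size) {
  vmember <- list()
  hmember <- list()
  for (plate in seq_len(n_plates) - 1L) {
    for (row in seq_len(n_rows) - 1L) {
      for (col in seq_len(n_cols) - 1L) {
        key <- paste(plate, row, col)
        vid <- (plate %/% pair_size) * n_rows + row
        hid <- (plate %/% group_size) * n_cols + col
        vkey <- as.character(vid)
        hkey <- as.character(hid)
        vmember[[vkey]] <- c(vmember[[vkey]], key)
        hmember[[hkey]] <- c(hmember[[hkey]], key)
      }
    }
  }
  list(vertical = vmember, horizontal = hmember)
}

# Exact binomial upper-tail by explicit log-space summation (does not call
# pbinom, which the implementation uses).
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# A CDS that places a given codon at a given codon index, padded with a
# neutral codon elsewhere.
cds_with_codon <- function(codon_index, codon, n_codons = codon_index,
                           filler = "GCT") {
  codons <- rep(filler, n_codons)
  codons[codon_index] <- codon
  paste(codons, collapse = "")
}

# Small pooled screen used by several end-to-end tests: 6 plates, two modest
# genes, elevated density so a handful of mutations is planted.
small_run_config <- function(seed = 42L, ...) {
  run_config(
    n_plates = 6L, n_lines = 576L, density = 1 / 40000,
    seed = seed, ...
  )
}

small_gene_panel <- function(seed = 5L) {
  list(
    gene_model("geneA", random_cds(400L, seed = seed)),
    gene_model("geneB", random_cds(500L, seed = seed + 1L))
  )
}
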