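#' Sequencing configuration for pooled target capture
#'
#' Count-level model of pooled sequencing: read depth at a pool-site is
#' Poisson with mean \code{2 * n_lines * depth_per_haploid} (each line
#' contributes two haploid genomes), and each read reports the allele it
#' sampled with probability \code{1 - error_rate}, otherwise a uniformly
#' chosen other base.
#'
#' @param depth_per_haploid mean reads per haploid genome per site
#'   (default 10).
#' @param error_rate per-base miscall probability (default 0.001); must be
#'   below 0.25.
#' @param seed optional integer seed used by the simulators.
#' @return object of class \code{"seq_config"}.
#' @export
seq_config <- function(depth_per_haploid = 10, error_rate = 0.001, seed = NULL) {
  if (!is.numeric(depth_per_haploid) || length(depth_per_haploid) != 1L ||
      depth_per_haploid <= 0) {
    stopf("'depth_per_haploid' must be a positive number")
  }
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 0.25) {
    stopf("'error_rate' must be in [0, 0.25)")
  }
  structure(list(
    depth_per_haploid = as.numeric(depth_per_haploid),
    error_rate = as.numeric(error_rate),
    seed = if (is.null(seed)) NULL else check_count(seed, "seed")
  ), class = "seq_config")
}

empty_counts <- function() {
  data.frame(
    pool_id = character(), gene_id = character(), cds_pos = integer(),
    ref = character(), nA = integer(), nC = integer(), nG = integer(),
    nT = integer(), depth = integer()
  )
}

# multinomial base probabilities given ref, per-alt allele frequencies and
# the miscall rate; f_alt named by alt base
base_probs <- function(ref, f_alt, error_rate) {
  p <- stats::setNames(numeric(4L), DNA_BASES)
  f_ref <- 1 - sum(f_alt)
  contrib <- function(allele, f) {
    q <- rep(error_rate / 3, 4L)
    q[match(allele, DNA_BASES)] <- 1 - error_rate
    f * q
  }
  p <- p + contrib(ref, f_ref)
  for (b in names(f_alt)) p <- p + contrib(b, f_alt[[b]])
  p
}

#' Simulate pooled sequencing of one site in one pool
#'
#' The exact per-site model: the true pool alternate-allele frequency is the
#' number of alt allele copies over \code{2 * n} chromosomes, depth is
#' Poisson, and miscalls go uniformly to the other three bases, so the
#' expected observed alt fraction is
#' \code{f * (1 - error_rate) + (1 - f) * error_rate / 3}.
#'
#' @param genotypes integer vector of alt-allele copies (0, 1 or 2) for each
#'   of the pool's member lines.
#' @param ref reference base at the site.
#' @param alt alternate base the genotypes refer to.
#' @param cfg a [seq_config()].
#' @param pool_id,gene_id,cds_pos identifiers carried into the output record.
#' @return one-row data.frame with columns \code{pool_id, gene_id, cds_pos,
#'   ref, nA, nC, nG, nT, depth} (counts sum to depth).
#' @export
sequence_pool <- function(genotypes, ref, alt, cfg = seq_config(),
                          pool_id = "P1", gene_id = "gene", cds_pos = 1L) {
  if (!all(genotypes %in% 0:2)) stopf("'genotypes' must be alt copy numbers 0, 1 or 2")
  ref <- match.arg(ref, DNA_BASES)
  alt <- match.arg(alt, DNA_BASES)
  if (alt == ref) stopf("'alt' must differ from 'ref'")
  n <- length(genotypes)
  if (n == 0L) stopf("empty pool")
  f <- stats::setNames(sum(genotypes) / (2 * n), alt)
  with_seed(cfg$seed, {
    depth <- stats::rpois(1L, 2 * n * cfg$depth_per_haploid)
    counts <- if (depth > 0L) {
      as.integer(stats::rmultinom(1L, depth, base_probs(ref, f, cfg$error_rate)))
    } else integer(4L)
    data.frame(
      pool_id = pool_id, gene_id = gene_id, cds_pos = as.integer(cds_pos),
      ref = ref, nA = counts[1L], nC = counts[2L], nG = counts[3L],
      nT = counts[4L], depth = depth
    )
  })
}

#' Simulate pooled sequencing of a whole population across a pooling scheme
#'
#' Runs the [sequence_pool()] count model over every (pool, CDS site)
#' combination of the design. Pool-sites with no mutation carrier are
#' simulated under the error-only model (read counts are a multinomial with
#' ref probability \code{1 - error_rate}); pool-sites containing carriers use
#' the full allele-frequency model. To keep the output tractable only
#' pool-sites whose strongest non-reference base reaches \code{min_alt_emit}
#' reads are emitted (carrier pool-sites are always emitted); pool-sites
#' below that evidence level could never produce a variant call at an equal
#' or higher \code{min_alt_reads}.
#'
#' @param population a [simulate_population()] object.
#' @param scheme a [build_scheme()]; the population's wells must fit it.
#' @param cfg a [seq_config()].
#' @param min_alt_emit emission threshold on the per-base alt read count
#'   (default 3, matching the default calling threshold).
#' @return data.frame of pool-site counts (columns as [sequence_pool()]),
#'   pools labelled \code{"V..."}/\code{"H..."}.
#' @export
simulate_pool_sequencing <- function(population, scheme, cfg = seq_config(),
                                     min_alt_emit = 3L) {
  if (!inherits(population, "mutant_population")) {
    stopf("'population' must be a mutant_population")
  }
  if (!inherits(scheme, "pooling_scheme")) stopf("'scheme' must be a pooling_scheme")
  min_alt_emit <- check_count(min_alt_emit, "min_alt_emit", 1L)
  lines <- population$lines
  if (nrow(lines) > scheme$n_samples) {
    stopf("population has %d lines but the scheme holds %d samples",
          nrow(lines), scheme$n_samples)
  }
  if (max(lines$row) >= scheme$n_rows || max(lines$col) >= scheme$n_cols) {
    stopf("population plate geometry does not fit the scheme")
  }

  # site table across all genes
  gt <- gene_table(population$genes)
  sites <- do.call(rbind, lapply(population$genes, function(g) {
    data.frame(
      gene_id = g$gene_id,
      cds_pos = seq_len(nchar(g$cds_seq)),
      ref = strsplit(g$cds_seq, "", fixed = TRUE)[[1L]]
    )
  }))
  rownames(sites) <- NULL
  n_sites <- nrow(sites)

  # pool membership sizes (lines actually present, not wells)
  lp <- pools_of(scheme, lines$plate, lines$row, lines$col)
  v_members <- tabulate(lp$vpool + 1L, nbins = scheme$n_vpools)
  h_members <- tabulate(lp$hpool + 1L, nbins = scheme$n_hpools)
  pools <- data.frame(
    pool_id = c(pool_label("V", seq_len(scheme$n_vpools) - 1L),
                pool_label("H", seq_len(scheme$n_hpools) - 1L)),
    n_lines = c(v_members, h_members)
  )

  # carrier map: which (pool, gene, pos, alt) carry how many alt copies
  muts <- population$mutations
  carriers <- NULL
  if (nrow(muts) > 0L) {
    mline <- lines[match(muts$line_id, lines$line_id), ]
    mp <- pools_of(scheme, mline$plate, mline$row, mline$col)
    copies <- ifelse(muts$zygosity == "homozygous", 2L, 1L)
    carriers <- rbind(
      data.frame(pool_id = pool_label("V", mp$vpool), muts[, c("gene_id", "cds_pos", "ref", "alt")], copies = copies),
      data.frame(pool_id = pool_label("H", mp$hpool), muts[, c("gene_id", "cds_pos", "ref", "alt")], copies = copies)
    )
  }
  carrier_key <- if (is.null(carriers)) character() else {
    unique(paste(carriers$pool_id, carriers$gene_id, carriers$cds_pos))
  }

  e <- cfg$error_rate
  with_seed(cfg$seed, {
    out <- vector("list", nrow(pools) + 1L)
    for (pi in seq_len(nrow(pools))) {
      np <- pools$n_lines[pi]
      if (np == 0L) next
      depth <- stats::rpois(n_sites, 2 * np * cfg$depth_per_haploid)
      errs <- stats::rbinom(n_sites, depth, e)
      idx <- which(errs >= min_alt_emit)
      if (length(idx) == 0L) next
      e1 <- stats::rbinom(length(idx), errs[idx], 1 / 3)
      e2 <- stats::rbinom(length(idx), errs[idx] - e1, 1 / 2)
      e3 <- errs[idx] - e1 - e2
      keep <- pmax(e1, e2, e3) >= min_alt_emit
      if (!any(keep)) next
      idx <- idx[keep]
      alt_counts <- cbind(e1[keep], e2[keep], e3[keep])
      # distribute the three error piles over the three non-ref bases
      refm <- match(sites$ref[idx], DNA_BASES)
      cnt <- matrix(0L, length(idx), 4L)
      for (b in 1:4) {
        sel <- which(refm == b)
        if (length(sel) > 0L) {
          cnt[sel, -b] <- alt_counts[sel, , drop = FALSE]
          cnt[sel, b] <- depth[idx[sel]] - errs[idx[sel]]
        }
      }
      out[[pi]] <- data.frame(
        pool_id = pools$pool_id[pi], gene_id = sites$gene_id[idx],
        cds_pos = sites$cds_pos[idx], ref = sites$ref[idx],
        nA = cnt[, 1L], nC = cnt[, 2L], nG = cnt[, 3L], nT = cnt[, 4L],
        depth = depth[idx]
      )
    }

    # exact model at carrier pool-sites (overrides any error-only emission)
    if (!is.null(carriers)) {
      grp <- split(carriers, paste(carriers$pool_id, carriers$gene_id, carriers$cds_pos))
      rows <- lapply(grp, function(g) {
        np <- pools$n_lines[match(g$pool_id[1L], pools$pool_id)]
        f_alt <- tapply(g$copies, g$alt, sum) / (2 * np)
        depth <- stats::rpois(1L, 2 * np * cfg$depth_per_haploid)
        counts <- if (depth > 0L) {
          as.integer(stats::rmultinom(1L, depth, base_probs(g$ref[1L], f_alt, e)))
        } else integer(4L)
        data.frame(
          pool_id = g$pool_id[1L], gene_id = g$gene_id[1L],
          cds_pos = g$cds_pos[1L], ref = g$ref[1L],
          nA = counts[1L], nC = counts[2L], nG = counts[3L], nT = counts[4L],
          depth = depth
        )
      })
      out[[nrow(pools) + 1L]] <- do.call(rbind, rows)
    }

    res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(res)) return(empty_counts())
    # carrier rows were appended last and override error-only rows at the
    # same pool-site: keep the last occurrence of each key
    key <- paste(res$pool_id, res$gene_id, res$cds_pos)
    res <- res[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    res <- res[order(res$gene_id, res$cds_pos, res$pool_id), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}
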