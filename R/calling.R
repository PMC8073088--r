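#' Phred-scaled binomial error-tail quality score
#'
#' The confidence that \code{k} alt reads at a site are not all sequencing
#' error: \code{-10 * log10 P(X >= k)} with
#' \code{X ~ Binomial(depth, error_rate / 3)} (a miscall hits one specific
#' alternate base a third of the time). Capped at 3000; underflowing tail
#' probabilities hit the cap.
#'
#' @param k alt read count (vector).
#' @param depth total read depth (vector).
#' @param error_rate per-base miscall probability.
#' @return numeric vector of Phred scores in [0, 3000].
#' @export
qual_score <- function(k, depth, error_rate) {
  p <- error_rate / 3
  tail <- stats::pbinom(k - 1, depth, p, lower.tail = FALSE)
  q <- ifelse(tail <= 0, Inf, -10 * log10(tail))
  pmin(pmax(q, 0), 3000)
}

#' Call candidate variants from pool allele counts
#'
#' For every non-reference base with at least \code{min_alt_reads} supporting
#' reads a per-pool call is emitted, carrying the observed alt fraction
#' \code{af_hat = k / depth} and the error-model quality [qual_score()].
#'
#' @param counts data.frame of pool-site counts as produced by
#'   [sequence_pool()] / [simulate_pool_sequencing()] (columns
#'   \code{pool_id, gene_id, cds_pos, ref, nA, nC, nG, nT, depth}).
#' @param error_rate per-base miscall probability used in the score
#'   (default 0.001).
#' @param min_alt_reads minimum alt reads to emit a call (default 3;
#'   suppresses singleton sequencing errors before scoring).
#' @return data.frame of calls, sorted by pool, gene, position and alt base:
#'   \code{pool_id, gene_id, cds_pos, ref, alt, af_hat, qual, alt_reads,
#'   depth}. Zero-depth input sites are skipped with a warning.
#' @export
call_pool <- function(counts, error_rate = 0.001, min_alt_reads = 3L) {
  need <- c("pool_id", "gene_id", "cds_pos", "ref", "nA", "nC", "nG", "nT", "depth")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    stopf("'counts' must have columns %s", paste(need, collapse = ", "))
  }
  min_alt_reads <- check_count(min_alt_reads, "min_alt_reads", 1L)
  zero <- counts$depth == 0L
  if (any(zero)) {
    warning(sprintf("skipping %d zero-depth pool-site(s)", sum(zero)), call. = FALSE)
    counts <- counts[!zero, , drop = FALSE]
  }
  empty <- data.frame(
    pool_id = character(), gene_id = character(), cds_pos = integer(),
    ref = character(), alt = character(), af_hat = numeric(),
    qual = numeric(), alt_reads = integer(), depth = integer()
  )
  if (nrow(counts) == 0L) return(empty)

  cmat <- as.matrix(counts[, c("nA", "nC", "nG", "nT")])
  long <- do.call(rbind, lapply(seq_len(4L), function(b) {
    k <- cmat[, b]
    i <- which(k >= min_alt_reads & counts$ref != DNA_BASES[b])
    if (length(i) == 0L) return(NULL)
    data.frame(
      pool_id = counts$pool_id[i], gene_id = counts$gene_id[i],
      cds_pos = counts$cds_pos[i], ref = counts$ref[i],
      alt = DNA_BASES[b], alt_reads = as.integer(k[i]), depth = counts$depth[i]
    )
  }))
  if (is.null(long)) return(empty)
  long$af_hat <- long$alt_reads / long$depth
  long$qual <- qual_score(long$alt_reads, long$depth, error_rate)
  long <- long[order(long$pool_id, long$gene_id, long$cds_pos, long$alt), ,
               drop = FALSE]
  rownames(long) <- NULL
  long[, c("pool_id", "gene_id", "cds_pos", "ref", "alt", "af_hat", "qual",
           "alt_reads", "depth")]
}

#' Integrate per-pool calls across the design and apply the QUAL/AC filter
#'
#' Calls are grouped by variant key (gene, position, ref, alt). The
#' \emph{supporting} calls of a variant are those meeting the per-pool
#' quality threshold \code{qual_min}; a marginal error-level call at the
#' same site in some unrelated pool neither counts toward AC nor drags the
#' variant's QUAL down. Each supporting pool contributes two estimated
#' alternate allele copies (one heterozygous carrier appears once in its
#' vertical and once in its horizontal pool), so \code{AC = 2 * number of
#' supporting pools}; the variant's \code{QUAL} is the minimum quality over
#' its supporting calls (for a variant with no supporting call, the maximum
#' over its calls, flagged \code{lowQUAL}). A variant passes when it has
#' supporting calls and \code{AC >= ac_min}; with \code{ac_min = 4} a true
#' singleton must be detected on \emph{both} axes.
#'
#' The default \code{qual_min = 40} corresponds to a per-pool error-null
#' p-value of 1e-4 on the [qual_score()] scale; combined with the two-pool
#' AC requirement it suppresses error calls while retaining singleton
#' heterozygous carriers at the design depth (see the package vignette).
#'
#' @param calls data.frame from [call_pool()] (pool ids labelled
#'   \code{"V..."}/\code{"H..."}).
#' @param scheme a [build_scheme()]; calls referencing pools outside the
#'   scheme raise an error.
#' @param qual_min minimum variant QUAL (default 40).
#' @param ac_min minimum estimated alt allele copies (default 4).
#' @return data.frame with one row per variant: \code{gene_id, cds_pos, ref,
#'   alt, vpools, hpools} (comma-separated supporting pool labels),
#'   \code{n_pools, AC, QUAL, AF} (mean observed alt fraction over
#'   supporting calls) and \code{filter} (\code{"PASS"} or semicolon-joined
#'   \code{lowQUAL}/\code{lowAC} flags). Thresholds are kept as attributes
#'   \code{qual_min}/\code{ac_min}.
#' @export
integrate_and_filter <- function(calls, scheme, qual_min = 40, ac_min = 4L) {
  need <- c("pool_id", "gene_id", "cds_pos", "ref", "alt", "qual")
  if (!is.data.frame(calls) || !all(need %in% names(calls))) {
    stopf("'calls' must have columns %s", paste(need, collapse = ", "))
  }
  out <- data.frame(
    gene_id = character(), cds_pos = integer(), ref = character(),
    alt = character(), vpools = character(), hpools = character(),
    n_pools = integer(), AC = integer(), QUAL = numeric(), AF = numeric(),
    filter = character()
  )
  if (nrow(calls) > 0L) {
    pools <- parse_pool_label(calls$pool_id)
    bad <- (pools$axis == "V" & pools$id >= scheme$n_vpools) |
      (pools$axis == "H" & pools$id >= scheme$n_hpools) | pools$id < 0L
    if (any(bad)) {
      stopf("calls reference pools unknown to the scheme: %s",
            paste(unique(calls$pool_id[bad]), collapse = ", "))
    }
    key <- paste(calls$gene_id, calls$cds_pos, calls$ref, calls$alt, sep = "\r")
    grp <- split(seq_len(nrow(calls)), key)
    first <- vapply(grp, function(i) i[[1L]], integer(1))
    # supporting calls are those meeting the per-pool quality threshold; a
    # weak co-located error call in some other pool neither counts toward AC
    # nor drags the variant's QUAL down
    supp <- lapply(grp, function(i) {
      s <- i[calls$qual[i] >= qual_min]
      if (length(s) > 0L) s else i
    })
    has_supp <- vapply(grp, function(i) any(calls$qual[i] >= qual_min), logical(1))
    join_axis <- function(ax) {
      vapply(supp, function(i) {
        paste(sort(unique(calls$pool_id[i][pools$axis[i] == ax])), collapse = ",")
      }, character(1))
    }
    vp <- join_axis("V")
    hp <- join_axis("H")
    npool <- vapply(supp, function(i) length(unique(calls$pool_id[i])), integer(1))
    af <- if ("af_hat" %in% names(calls)) {
      vapply(supp, function(i) mean(calls$af_hat[i]), numeric(1))
    } else NA_real_
    out <- data.frame(
      gene_id = calls$gene_id[first], cds_pos = calls$cds_pos[first],
      ref = calls$ref[first], alt = calls$alt[first],
      vpools = vp, hpools = hp, n_pools = npool, AC = 2L * npool,
      QUAL = vapply(seq_along(grp), function(j) {
        if (has_supp[j]) min(calls$qual[supp[[j]]]) else max(calls$qual[grp[[j]]])
      }, numeric(1)),
      AF = af
    )
    flags <- ifelse(has_supp, "", "lowQUAL")
    low_ac <- out$AC < ac_min
    flags <- ifelse(low_ac, ifelse(nzchar(flags), paste0(flags, ";lowAC"), "lowAC"), flags)
    out$filter <- ifelse(nzchar(flags), flags, "PASS")
    out <- out[order(out$gene_id, out$cds_pos, out$alt), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "qual_min") <- qual_min
  attr(out, "ac_min") <- ac_min
  out
}

#' Retained variants of an integrated call set
#'
#' @param variants output of [integrate_and_filter()].
#' @return the subset with \code{filter == "PASS"}.
#' @export
passing_variants <- function(variants) {
  variants[variants$filter == "PASS", , drop = FALSE]
}
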