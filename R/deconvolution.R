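#' Demultiplex filtered variants to candidate lines
#'
#' A variant supported by one vertical and one horizontal pool decodes to the
#' intersection of the two pools: under the default design, the two wells
#' sharing a row and a column on the two plates of one plate pair. When more
#' than one pool per axis supports the variant (possible carrier collisions)
#' the candidate set is the union over all supporting (V, H) pairs of their
#' decodes. Variants lacking support on one axis are flagged
#' \code{"unresolvable"}; variants whose supporting pools have no well in
#' common are flagged \code{"discordant"} rather than dropped.
#'
#' @param variants data.frame from [integrate_and_filter()] (typically the
#'   [passing_variants()] subset), with \code{vpools}/\code{hpools} columns.
#' @param scheme the [build_scheme()] the pools came from.
#' @return data.frame with the variant key columns plus \code{status}
#'   (\code{"candidates"}, \code{"unresolvable"} or \code{"discordant"}),
#'   \code{n_candidates}, \code{candidate_wells} (comma-separated
#'   \code{"plate:well"} labels, 1-based) and a list-column
#'   \code{candidates} of 0-based address data.frames.
#' @export
demultiplex <- function(variants, scheme) {
  need <- c("gene_id", "cds_pos", "ref", "alt", "vpools", "hpools")
  if (!is.data.frame(variants) || !all(need %in% names(variants))) {
    stopf("'variants' must have columns %s", paste(need, collapse = ", "))
  }
  split_pools <- function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ",", fixed = TRUE)[[1L]]
  }
  n <- nrow(variants)
  status <- character(n)
  cand <- vector("list", n)
  for (i in seq_len(n)) {
    vs <- split_pools(variants$vpools[i])
    hs <- split_pools(variants$hpools[i])
    if (length(vs) == 0L || length(hs) == 0L) {
      status[i] <- "unresolvable"
      cand[[i]] <- data.frame(plate = integer(), row = integer(), col = integer())
      next
    }
    pairs <- expand.grid(v = vs, h = hs, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    sets <- mapply(function(v, h) {
      decode_pools(scheme, parse_pool_label(v)$id, parse_pool_label(h)$id)
    }, pairs$v, pairs$h, SIMPLIFY = FALSE)
    u <- unique(do.call(rbind, sets))
    rownames(u) <- NULL
    cand[[i]] <- u
    status[i] <- if (nrow(u) == 0L) "discordant" else "candidates"
  }
  out <- variants[, c("gene_id", "cds_pos", "ref", "alt")]
  out$status <- status
  out$n_candidates <- vapply(cand, nrow, integer(1))
  out$candidate_wells <- vapply(cand, function(a) {
    if (nrow(a) == 0L) return("")
    paste(sprintf("%02d:%s", a$plate + 1L, well_label(a$row, a$col)), collapse = ",")
  }, character(1))
  out$candidates <- I(cand)
  rownames(out) <- NULL
  out
}

#' Resolve the carrier among candidate lines by (simulated) Sanger lookup
#'
#' Sanger sequencing of the candidate lines is modelled as a genotype lookup
#' against the population truth, optionally with a per-lookup miss
#' probability (\code{sanger_error}, default 0: a carrier is never missed).
#' The outcome per variant is \code{"resolved"} (exactly one candidate
#' carries the alt allele), \code{"false_positive"} (none does) or
#' \code{"collision"} (two or more do; all carriers are recorded).
#'
#' @param cands output of [demultiplex()].
#' @param population the [simulate_population()] truth (or any
#'   \code{mutant_population} acting as the assay).
#' @param sanger_error probability a carrier lookup misses (default 0).
#' @param seed optional seed (only used when \code{sanger_error > 0}).
#' @return \code{cands} with columns \code{resolved_line} (the carrier line,
#'   comma-joined carriers for collisions, \code{NA} otherwise) and an
#'   updated \code{status}; this is the per-variant resolution report.
#' @export
sanger_resolve <- function(cands, population, sanger_error = 0, seed = NULL) {
  if (!inherits(population, "mutant_population")) {
    stopf("'population' must be a mutant_population")
  }
  sanger_error <- check_prob(sanger_error, "sanger_error")
  lines <- population$lines
  line_key <- paste(lines$plate, lines$row, lines$col)
  mut_key <- paste(population$mutations$line_id, population$mutations$gene_id,
                   population$mutations$cds_pos, population$mutations$alt)
  with_seed(seed, {
    resolved <- rep(NA_character_, nrow(cands))
    status <- cands$status
    for (i in seq_len(nrow(cands))) {
      if (status[i] != "candidates") next
      a <- cands$candidates[[i]]
      ids <- lines$line_id[match(paste(a$plate, a$row, a$col), line_key)]
      ids <- ids[!is.na(ids)]
      hits <- ids[paste(ids, cands$gene_id[i], cands$cds_pos[i], cands$alt[i]) %in% mut_key]
      if (sanger_error > 0 && length(hits) > 0L) {
        hits <- hits[stats::runif(length(hits)) >= sanger_error]
      }
      if (length(hits) == 0L) {
        status[i] <- "false_positive"
      } else if (length(hits) == 1L) {
        status[i] <- "resolved"
        resolved[i] <- hits
      } else {
        status[i] <- "collision"
        resolved[i] <- paste(hits, collapse = ",")
      }
    }
    cands$status <- status
    cands$resolved_line <- resolved
    cands
  })
}

#' Fraction of planted mutations recovered to the correct line
#'
#' @param planted data.frame of truth mutations (\code{line_id, gene_id,
#'   cds_pos, alt}), e.g. \code{population$mutations}.
#' @param resolved output of [sanger_resolve()].
#' @return the fraction of planted mutations whose variant was resolved to
#'   the carrying line; \code{NA} (with a message) when nothing was planted.
#' @export
recovery_rate <- function(planted, resolved) {
  if (nrow(planted) == 0L) {
    message("no planted mutations; recovery rate is not applicable")
    return(NA_real_)
  }
  ok <- resolved$status == "resolved"
  res_key <- paste(resolved$resolved_line[ok], resolved$gene_id[ok],
                   resolved$cds_pos[ok], resolved$alt[ok])
  mean(paste(planted$line_id, planted$gene_id, planted$cds_pos, planted$alt) %in% res_key)
}
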