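FA_COLS <- c("16:0" = "p16_0", "18:0" = "p18_0", "18:1" = "p18_1",
             "18:2" = "p18_2", "18:3" = "p18_3")

#' Mutation density per kb of screened sequence
#'
#' The screen's density denominator is the total screened opportunity,
#' \code{screened_bp * n_lines}; one mutation per \code{density_bp} bases is
#' rendered the way such screens report it, \code{"1/<kb> kb"} with the kb
#' figure rounded half up.
#'
#' @param screened_bp total screened bases (sum of amplicon sizes).
#' @param n_lines number of screened lines.
#' @param n_mutations total base changes discovered.
#' @return list with \code{density_bp} (bases per mutation) and
#'   \code{label} (e.g. \code{"1/212 kb"}).
#' @examples
#' mutation_density(14440, 4032, 274)  # 1/212 kb
#' @export
mutation_density <- function(screened_bp, n_lines, n_mutations) {
  if (n_mutations <= 0) stopf("'n_mutations' must be positive")
  density_bp <- screened_bp * n_lines / n_mutations
  list(
    density_bp = density_bp,
    label = sprintf("1/%d kb", as.integer(round_half_up(density_bp / 1000)))
  )
}

tally_types <- function(ref, alt) {
  types <- substitution_types()
  t0 <- stats::setNames(integer(length(types)), types)
  tt <- table(factor(paste0(ref, ">", alt), levels = types))
  t0[names(tt)] <- as.integer(tt)
  t0
}

#' Summarize mutation spectrum, effect classes and density
#'
#' Accepts either mutation-level records (data.frame with \code{gene_id},
#' \code{ref}, \code{alt} and optionally \code{effect} columns, e.g. the
#' truth of [simulate_population()] or annotated variants) together with the
#' gene panel, or an already-tallied per-gene count table (as loaded by
#' [load_mutation_summary_table()]). Reports per-gene and aggregate counts
#' of G>A, C>T and other substitutions, the EMS-type fraction, effect-class
#' counts, and the mutation density over \code{screened_bp * n_lines}.
#'
#' @param x mutation records or a \code{mutation_count_table}.
#' @param genes gene panel (list of [gene_model()]s or a data.frame with
#'   \code{gene_id, amplicon_bp}); ignored for count tables, which carry
#'   their own amplicon sizes.
#' @param n_lines number of screened lines (default 4032).
#' @return object of class \code{"spectrum_summary"}: a list with
#'   \code{per_gene} (counts by gene), \code{type_counts} (aggregate counts
#'   of the 12 substitution types, when mutation-level input was given),
#'   \code{total}, \code{ga}, \code{ct}, \code{others}, \code{ems_count},
#'   \code{ems_fraction_pct} (one decimal, half-up), \code{effects},
#'   \code{screened_bp}, \code{n_lines}, \code{density_bp},
#'   \code{density_label}.
#' @export
spectrum_summary <- function(x, genes = NULL, n_lines = 4032L) {
  n_lines <- check_count(n_lines, "n_lines", 1L)
  type_counts <- NULL
  if (inherits(x, "mutation_count_table") ||
      all(c("ga", "ct", "others") %in% names(x))) {
    per_gene <- data.frame(
      gene_id = x$gene_id, amplicon_bp = x$amplicon_bp,
      ga = x$ga, ct = x$ct, others = x$others,
      total = x$ga + x$ct + x$others
    )
    effects <- c(
      missense = sum(x$missense), silent = sum(x$silent),
      nonsense = sum(x$nonsense), stop_loss = 0L
    )
  } else if (all(c("gene_id", "ref", "alt") %in% names(x))) {
    if (is.null(genes)) stopf("'genes' is required for mutation-level input")
    gt <- if (is.data.frame(genes)) genes else gene_table(genes)
    unknown <- setdiff(unique(x$gene_id), gt$gene_id)
    if (length(unknown) > 0L) {
      stopf("mutations reference unknown gene(s): %s", paste(unknown, collapse = ", "))
    }
    type_counts <- tally_types(x$ref, x$alt)
    per_gene <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
      xi <- x[x$gene_id == gt$gene_id[i], , drop = FALSE]
      tc <- tally_types(xi$ref, xi$alt)
      data.frame(
        gene_id = gt$gene_id[i], amplicon_bp = gt$amplicon_bp[i],
        ga = tc[["G>A"]], ct = tc[["C>T"]],
        others = sum(tc) - tc[["G>A"]] - tc[["C>T"]], total = sum(tc)
      )
    }))
    effects <- if ("effect" %in% names(x)) {
      eff <- table(factor(x$effect, levels = c("missense", "silent", "nonsense", "stop_loss")))
      stats::setNames(as.integer(eff), names(eff))
    } else NULL
  } else {
    stopf("'x' must be a count table (ga/ct/others) or mutation records (gene_id/ref/alt)")
  }
  total <- sum(per_gene$total)
  if (total == 0L) stopf("no mutations to summarize")
  ga <- sum(per_gene$ga)
  ct <- sum(per_gene$ct)
  dens <- mutation_density(sum(per_gene$amplicon_bp), n_lines, total)
  structure(list(
    per_gene = per_gene, type_counts = type_counts,
    total = total, ga = ga, ct = ct, others = total - ga - ct,
    ems_count = ga + ct,
    ems_fraction_pct = round_half_up(100 * (ga + ct) / total, 1),
    effects = effects,
    screened_bp = sum(per_gene$amplicon_bp), n_lines = n_lines,
    density_bp = dens$density_bp, density_label = dens$label
  ), class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Mutation spectrum over %d gene(s), %d lines:\n",
              nrow(x$per_gene), x$n_lines))
  cat(sprintf("  %d base changes: %d G>A, %d C>T, %d others (EMS-type %.1f%%)\n",
              x$total, x$ga, x$ct, x$others, x$ems_fraction_pct))
  if (!is.null(x$effects)) {
    cat(sprintf("  coding effects: %d missense, %d silent, %d nonsense\n",
                x$effects[["missense"]], x$effects[["silent"]],
                x$effects[["nonsense"]]))
  }
  cat(sprintf("  density: one mutation per %.0f bp screened (%s)\n",
              x$density_bp, x$density_label))
  invisible(x)
}

#' Date gene duplications from synonymous divergence
#'
#' Converts a synonymous substitution rate Ks into a divergence time using a
#' molecular clock of \code{lambda} substitutions per synonymous site per
#' year: \code{T = Ks / (2 * lambda) * 1e-6} million years ago. The Ka/Ks
#' ratio classifies the selective regime (\code{< 1} purifying, \code{> 1}
#' positive); it is undefined (flagged \code{NA}) when \code{Ks = 0}.
#'
#' @param ks synonymous substitution rate(s), >= 0.
#' @param ka optional nonsynonymous rate(s), >= 0.
#' @param lambda clock rate, substitutions/site/year (default 6.1e-9, a
#'   soybean calibration).
#' @param gene_pair optional labels.
#' @return data.frame of class \code{"duplication_dating"}: \code{gene_pair,
#'   ka, ks, ka_ks, selection} (\code{purifying}/\code{neutral}/
#'   \code{positive}/\code{NA}), \code{t_mya}.
#' @examples
#' date_duplication(ks = 0.0122)          # 1.0 Mya
#' date_duplication(ks = 0.6, ka = 0.3)   # Ka/Ks = 0.5, purifying
#' @export
date_duplication <- function(ks, ka = NA_real_, lambda = 6.1e-9,
                             gene_pair = NULL) {
  if (any(ks < 0, na.rm = TRUE)) stopf("'ks' must be >= 0")
  if (any(ka < 0, na.rm = TRUE)) stopf("'ka' must be >= 0")
  if (!is.numeric(lambda) || lambda <= 0) stopf("'lambda' must be positive")
  n <- max(length(ks), length(ka))
  ks <- rep_len(as.numeric(ks), n)
  ka <- rep_len(as.numeric(ka), n)
  ratio <- ifelse(ks > 0, ka / ks, NA_real_)
  selection <- ifelse(is.na(ratio), NA_character_,
                      ifelse(ratio < 1, "purifying",
                             ifelse(ratio > 1, "positive", "neutral")))
  out <- data.frame(
    gene_pair = if (is.null(gene_pair)) paste0("pair", seq_len(n)) else rep_len(gene_pair, n),
    ka = ka, ks = ks, ka_ks = ratio, selection = selection,
    t_mya = ks / (2 * lambda) * 1e-6
  )
  class(out) <- c("duplication_dating", "data.frame")
  out
}

#' Per-family fatty-acid ranges and fold changes of a mutant phenotype table
#'
#' Computes, for each gene family and each of the five major fatty acids
#' (16:0, 18:0, 18:1, 18:2, 18:3, as percent of total seed fatty acids), the
#' minimum/maximum over the family's mutants and the wild-type value, plus
#' per-mutant fold changes versus wild type. Members of the same omega-3
#' desaturase family (ids starting \code{GmFAD3}) are pooled into one
#' family, the way such screens report linolenic-acid ranges.
#'
#' @param tbl phenotype table as loaded by [load_phenotype_table()]
#'   (columns \code{gene_id, plant_id, nt_change, aa_change, p16_0, p18_0,
#'   p18_1, p18_2, p18_3}); must contain the wild-type row
#'   (\code{plant_id == wt_id}).
#' @param wt_id plant id of the wild-type row (default \code{"F-WT"}).
#' @return list of class \code{"phenotype_stats"}: \code{ranges} (family x
#'   fatty acid min/max/range with the plants attaining them and the WT
#'   value) and \code{fold_changes} (per mutant x fatty acid, value / WT).
#' @export
phenotype_table_stats <- function(tbl, wt_id = "F-WT") {
  need <- c("gene_id", "plant_id", unname(FA_COLS))
  if (!is.data.frame(tbl) || !all(need %in% names(tbl))) {
    stopf("'tbl' must have columns %s", paste(need, collapse = ", "))
  }
  wt <- tbl[tbl$plant_id == wt_id, , drop = FALSE]
  if (nrow(wt) != 1L) stopf("wild-type row '%s' missing (or duplicated)", wt_id)
  mut <- tbl[tbl$plant_id != wt_id, , drop = FALSE]
  if (nrow(mut) == 0L) stopf("no mutant rows")
  family <- ifelse(startsWith(mut$gene_id, "GmFAD3"), "GmFAD3", mut$gene_id)

  ranges <- do.call(rbind, lapply(unique(family), function(fam) {
    rows <- mut[family == fam, , drop = FALSE]
    do.call(rbind, lapply(names(FA_COLS), function(fa) {
      v <- rows[[FA_COLS[[fa]]]]
      data.frame(
        family = fam, fatty_acid = fa, n_mutants = nrow(rows),
        min = min(v), min_plant = rows$plant_id[which.min(v)],
        max = max(v), max_plant = rows$plant_id[which.max(v)],
        range = max(v) - min(v), wt = wt[[FA_COLS[[fa]]]]
      )
    }))
  }))
  rownames(ranges) <- NULL

  fold <- do.call(rbind, lapply(names(FA_COLS), function(fa) {
    data.frame(
      plant_id = mut$plant_id, family = family, fatty_acid = fa,
      value = mut[[FA_COLS[[fa]]]], wt = wt[[FA_COLS[[fa]]]],
      fold_change = mut[[FA_COLS[[fa]]]] / wt[[FA_COLS[[fa]]]]
    )
  }))
  fold <- fold[order(fold$plant_id, fold$fatty_acid), , drop = FALSE]
  rownames(fold) <- NULL
  structure(list(ranges = ranges, fold_changes = fold, wt_id = wt_id),
            class = "phenotype_stats")
}

#' @export
print.phenotype_stats <- function(x, ...) {
  cat(sprintf("Fatty-acid phenotype ranges vs wild type (%s):\n", x$wt_id))
  print(x$ranges, row.names = FALSE)
  invisible(x)
}
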