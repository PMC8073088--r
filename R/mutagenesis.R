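#' Simulate an EMS-mutagenized M2 population with known truth
#'
#' Draws, for every line and every target gene, an induced-mutation count
#' \code{~ Poisson(density * amplicon_bp)}; each mutation's (position, type)
#' pair is drawn jointly -- position uniform over the CDS and type from the
#' spectrum, rejecting pairs whose reference bases disagree -- so that on
#' base-balanced sequence the realized substitution types follow the
#' spectrum and lesions concentrate at the spectrum's preferred (for EMS,
#' G/C) sites. Positions are unique per line and gene. EMS produces
#' essentially only point mutations, so no indels are simulated. At the M2 generation mutations are
#' heterozygous with probability \code{het_fraction} (default 1: virtually
#' all EMS lesions are still segregating at M2).
#'
#' @param genes list of [gene_model()] objects (e.g. [synthetic_gene_panel()]).
#' @param n_lines number of M2 lines (default 4032, a 42-plate library).
#' @param density induced mutations per bp per line; the default 1/212,000
#'   reproduces a screen that recovered one mutation per 212 kb screened.
#' @param spectrum a [spectrum_model()] (default: EMS-biased).
#' @param het_fraction probability a mutation is heterozygous (default 1).
#' @param seed optional integer seed; fixed seed gives identical populations.
#' @param n_rows,n_cols plate geometry used to assign each line a well.
#' @return An object of class \code{"mutant_population"}: a list with
#'   \describe{
#'     \item{lines}{data.frame \code{line_id, sample, plate, row, col,
#'       generation}, one row per line (0-based addresses);}
#'     \item{mutations}{data.frame \code{line_id, gene_id, cds_pos} (1-based),
#'       \code{ref, alt, zygosity}, one row per induced mutation;}
#'     \item{genes}{the gene list.}
#'   }
#' @export
simulate_population <- function(genes, n_lines = 4032L, density = 1 / 212000,
                                spectrum = spectrum_model(), het_fraction = 1,
                                seed = NULL, n_rows = 8L, n_cols = 12L) {
  genes <- check_gene_list(genes)
  n_lines <- check_count(n_lines, "n_lines", 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0) {
    stopf("'density' must be a positive mutation rate per bp per line")
  }
  if (!inherits(spectrum, "spectrum_model")) spectrum <- spectrum_model(spectrum)
  het_fraction <- check_prob(het_fraction, "het_fraction")

  types <- substitution_types()
  type_ref <- substr(types, 1L, 1L)
  type_alt <- substr(types, 3L, 3L)

  lines <- data.frame(
    line_id = sprintf("L%04d", seq_len(n_lines)),
    sample = seq_len(n_lines) - 1L
  )
  per_plate <- n_rows * n_cols
  lines$plate <- lines$sample %/% per_plate
  lines$row <- (lines$sample %% per_plate) %/% n_cols
  lines$col <- lines$sample %% n_cols
  lines$generation <- "M2"

  with_seed(seed, {
    mut <- vector("list", length(genes))
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      bases <- strsplit(g$cds_seq, "", fixed = TRUE)[[1L]]
      pos_by_base <- split(seq_along(bases), factor(bases, levels = DNA_BASES))
      # (position, type) pairs are drawn jointly, rejecting incompatible
      # combinations: equivalently, a type is drawn with weight
      # spectrum[type] * #{positions with its reference base} and the
      # position uniformly among those. On base-balanced sequence this keeps
      # marginal type frequencies at the spectrum (and concentrates EMS
      # lesions at G/C sites, as the chemistry does).
      w <- unclass(spectrum) * lengths(pos_by_base)[type_ref]
      counts <- stats::rpois(n_lines, density * g$amplicon_bp)
      if (sum(w) <= 0) {
        if (any(counts > 0L)) {
          stopf("gene '%s' has no position compatible with the spectrum", g$gene_id)
        }
        next
      }
      counts <- pmin(counts, sum(lengths(pos_by_base)[unique(type_ref[w > 0])]))
      total <- sum(counts)
      if (total == 0L) next
      line_of <- rep.int(seq_len(n_lines), counts)
      ti <- sample.int(12L, total, replace = TRUE, prob = w)
      draw_pos <- function(ti_sub) {
        out <- integer(length(ti_sub))
        for (b in DNA_BASES) {
          i <- which(type_ref[ti_sub] == b)
          if (length(i) > 0L) {
            pb <- pos_by_base[[b]]
            out[i] <- pb[sample.int(length(pb), length(i), replace = TRUE)]
          }
        }
        out
      }
      pos <- draw_pos(ti)
      # enforce unique positions per line by redrawing clashing positions
      # (within the same reference-base class, preserving the drawn type)
      for (iter in seq_len(1000L)) {
        dup <- duplicated(paste(line_of, pos))
        if (!any(dup)) break
        pos[dup] <- draw_pos(ti[dup])
      }
      dup <- duplicated(paste(line_of, pos))
      if (any(dup)) {  # pathological saturation; drop the clashes
        line_of <- line_of[!dup]; ti <- ti[!dup]; pos <- pos[!dup]
      }
      mut[[gi]] <- data.frame(
        line_id = lines$line_id[line_of], gene_id = g$gene_id,
        cds_pos = pos, ref = type_ref[ti], alt = type_alt[ti]
      )
    }
    mutations <- if (all(vapply(mut, is.null, logical(1)))) {
      data.frame(line_id = character(), gene_id = character(),
                 cds_pos = integer(), ref = character(), alt = character(),
                 zygosity = character())
    } else {
      m <- do.call(rbind, mut)
      m$zygosity <- ifelse(stats::runif(nrow(m)) < het_fraction,
                           "heterozygous", "homozygous")
      m <- m[order(m$line_id, m$gene_id, m$cds_pos), , drop = FALSE]
      rownames(m) <- NULL
      m
    }
    structure(
      list(lines = lines, mutations = mutations, genes = genes,
           density = density, spectrum = spectrum, het_fraction = het_fraction),
      class = "mutant_population"
    )
  })
}

#' @export
print.mutant_population <- function(x, ...) {
  cat(sprintf(
    "Simulated mutant population: %d %s lines, %d genes, %d induced mutations\n",
    nrow(x$lines), x$lines$generation[1L], length(x$genes), nrow(x$mutations)
  ))
  if (nrow(x$mutations) > 0L) {
    zyg <- table(x$mutations$zygosity)
    cat("  zygosity:", paste(sprintf("%s %d", names(zyg), zyg), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Self an M2 line to M3 and tabulate progeny genotypes per mutation
#'
#' Heterozygous mutations segregate 1:2:1 on selfing, so among M3 progeny 25\%
#' revert to wild type, 50\% are heterozygous and 25\% are homozygous for the
#' mutation; homozygous M2 mutations breed true.
#'
#' @param x a \code{mutant_population} (then \code{line_id} selects the line)
#'   or a data.frame of mutation records with a \code{zygosity} column.
#' @param line_id line to self when \code{x} is a population.
#' @param n_progeny number of M3 progeny to draw per mutation.
#' @param seed optional integer seed.
#' @return data.frame with the mutation key columns plus integer counts
#'   \code{n_wt}, \code{n_het}, \code{n_hom} (summing to \code{n_progeny}).
#' @export
self_to_m3 <- function(x, line_id = NULL, n_progeny = 100L, seed = NULL) {
  muts <- if (inherits(x, "mutant_population")) {
    if (is.null(line_id)) stopf("'line_id' is required when selfing a population")
    x$mutations[x$mutations$line_id == line_id, , drop = FALSE]
  } else {
    x
  }
  if (!is.data.frame(muts) || !"zygosity" %in% names(muts)) {
    stopf("'x' must be a mutant_population or a mutation data.frame with a 'zygosity' column")
  }
  n_progeny <- check_count(n_progeny, "n_progeny", 1L)
  with_seed(seed, {
    out <- muts
    out$n_wt <- 0L
    out$n_het <- 0L
    out$n_hom <- 0L
    for (i in seq_len(nrow(out))) {
      if (out$zygosity[i] == "homozygous") {
        out$n_hom[i] <- n_progeny
      } else {
        g <- stats::rmultinom(1L, n_progeny, c(0.25, 0.5, 0.25))
        out$n_wt[i] <- g[1L]
        out$n_het[i] <- g[2L]
        out$n_hom[i] <- g[3L]
      }
    }
    rownames(out) <- NULL
    out
  })
}
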