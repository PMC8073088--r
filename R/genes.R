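#' Construct a gene model (CDS plus screened-amplicon size)
#'
#' A gene model is the unit the screen targets: a coding sequence in CDS
#' coordinates (5' to 3', sense strand) and the number of bases actually
#' screened by the capture probes (\code{amplicon_bp}), which sets the
#' per-line mutation opportunity. Partial models are allowed (no start codon
#' required) but the CDS length must be a multiple of 3 and the interior must
#' be free of stop codons.
#'
#' @param gene_id character scalar.
#' @param cds_seq character scalar over A/C/G/T.
#' @param amplicon_bp screened bases; defaults to the CDS length.
#' @return An object of class \code{"gene_model"} with elements
#'   \code{gene_id}, \code{cds_seq}, \code{amplicon_bp}.
#' @export
gene_model <- function(gene_id, cds_seq, amplicon_bp = nchar(cds_seq)) {
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id)) {
    stopf("'gene_id' must be a non-empty string")
  }
  cds_seq <- toupper(as.character(cds_seq))
  if (length(cds_seq) != 1L || nchar(cds_seq) == 0L ||
      grepl("[^ACGT]", cds_seq)) {
    stopf("CDS of '%s' must be a non-empty A/C/G/T string", gene_id)
  }
  if (nchar(cds_seq) %% 3L != 0L) {
    stopf("CDS length of '%s' (%d) is not divisible by 3", gene_id, nchar(cds_seq))
  }
  codons <- codon_split(cds_seq)
  interior <- codons[-length(codons)]
  if (any(interior %in% STOP_CODONS)) {
    stopf("CDS of '%s' contains an internal stop codon", gene_id)
  }
  amplicon_bp <- check_count(amplicon_bp, "amplicon_bp", 1L)
  structure(list(gene_id = gene_id, cds_seq = cds_seq, amplicon_bp = amplicon_bp),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s: CDS %d bp (%d codons), amplicon %d bp\n",
              x$gene_id, nchar(x$cds_seq), nchar(x$cds_seq) %/% 3L, x$amplicon_bp))
  invisible(x)
}

codon_split <- function(cds_seq) {
  n <- nchar(cds_seq) %/% 3L
  substring(cds_seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

check_gene_list <- function(genes) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  if (!is.list(genes) || length(genes) == 0L ||
      !all(vapply(genes, inherits, logical(1), "gene_model"))) {
    stopf("'genes' must be a non-empty list of gene_model objects")
  }
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stopf("duplicated gene ids: %s", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(genes) <- ids
  genes
}

gene_table <- function(genes) {
  genes <- check_gene_list(genes)
  data.frame(
    gene_id = names(genes),
    cds_bp = vapply(genes, function(g) nchar(g$cds_seq), integer(1)),
    amplicon_bp = vapply(genes, `[[`, integer(1), "amplicon_bp"),
    row.names = NULL
  )
}

#' The 12 single-nucleotide substitution types
#'
#' @return character vector \code{"A>C", "A>G", ..., "T>G"}.
#' @export
substitution_types <- function() {
  g <- expand.grid(alt = DNA_BASES, ref = DNA_BASES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  paste0(g$ref, ">", g$alt)
}

#' Build an EMS substitution-spectrum model
#'
#' A probability distribution over the 12 single-nucleotide substitution
#' types. EMS alkylates guanine, so induced mutations are dominated by G:C to
#' A:T transitions; the default puts 42.4\% on G>A and 40.1\% on C>T and
#' splits the remaining 17.5\% uniformly over the other ten types, matching
#' the spectrum observed across a large screened soybean gene panel.
#'
#' @param probs optional named numeric vector giving probabilities for a
#'   subset of the 12 types (names like \code{"G>A"}); unnamed mass is split
#'   uniformly over the remaining types. \code{NULL} gives the EMS default.
#' @return named numeric vector of length 12 summing to 1, of class
#'   \code{"spectrum_model"}.
#' @examples
#' spectrum_model()                       # EMS default
#' spectrum_model(c("G>A" = 1))           # transitions at G only
#' @export
spectrum_model <- function(probs = NULL) {
  types <- substitution_types()
  if (is.null(probs)) {
    probs <- c("G>A" = 0.424, "C>T" = 0.401)
  }
  if (is.null(names(probs)) || !all(names(probs) %in% types)) {
    stopf("'probs' must be named with substitution types such as \"G>A\"")
  }
  if (any(probs < 0) || sum(probs) > 1 + 1e-12) {
    stopf("'probs' must be nonnegative and sum to at most 1")
  }
  p <- stats::setNames(numeric(12L), types)
  p[names(probs)] <- probs
  rest <- setdiff(types, names(probs))
  if (length(rest) > 0L) p[rest] <- (1 - sum(probs)) / length(rest)
  if (abs(sum(p) - 1) > 1e-12) stopf("spectrum probabilities must sum to 1")
  structure(p, class = "spectrum_model")
}

#' @export
print.spectrum_model <- function(x, ...) {
  cat("Substitution spectrum (EMS-type mass",
      sprintf("%.1f%%):\n", 100 * (x[["G>A"]] + x[["C>T"]])))
  print(round(unclass(x), 4))
  invisible(x)
}

# spectrum mass by reference base: 4 x 4 matrix P[ref, alt]
spectrum_matrix <- function(spectrum) {
  m <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  parts <- strsplit(names(spectrum), ">", fixed = TRUE)
  for (i in seq_along(spectrum)) {
    m[parts[[i]][1L], parts[[i]][2L]] <- spectrum[[i]]
  }
  m
}

#' Generate a random stop-free CDS
#'
#' Codons are drawn uniformly from the 61 sense codons, so the sequence is
#' roughly GC-balanced and free of stop codons anywhere.
#'
#' @param n_codons number of codons.
#' @param seed optional integer seed.
#' @return character scalar of length \code{3 * n_codons}.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  n_codons <- check_count(n_codons, "n_codons", 1L)
  sense <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  with_seed(seed, paste(sample(sense, n_codons, replace = TRUE), collapse = ""))
}

#' Synthetic six-gene desaturase-style screening panel
#'
#' The study conditions of the simulated screen: six target genes whose
#' screened amplicon sizes (1800, 1920, 3320, 2480, 2480 and 2440 bp; 14,440
#' bp in total) match a six-member fatty-acid desaturase panel. The CDS
#' sequences themselves are \emph{synthetic} (random stop-free codons; the
#' real cultivar sequences are not published), with CDS length equal to the
#' amplicon size rounded down to a codon multiple.
#'
#' @param seed integer seed for the random sequences (default 1).
#' @return named list of six [gene_model()] objects.
#' @export
synthetic_gene_panel <- function(seed = 1L) {
  sizes <- c(
    "GmSACPD-C" = 1800L, "GmFAD2-1A" = 1920L, "GmFAD2-1B" = 3320L,
    "GmFAD3A" = 2480L, "GmFAD3B" = 2480L, "GmFAD3C" = 2440L
  )
  with_seed(seed, {
    genes <- lapply(names(sizes), function(id) {
      gene_model(id, random_cds(sizes[[id]] %/% 3L), amplicon_bp = sizes[[id]])
    })
    names(genes) <- names(sizes)
    genes
  })
}
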