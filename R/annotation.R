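#' Annotate the codon-level effect of a CDS point mutation
#'
#' Translates the reference and mutated codons under the standard genetic
#' code and classifies the change as \code{missense}, \code{silent},
#' \code{nonsense} (stop gained) or \code{stop_loss}. Substitutions are
#' rendered in the usual \code{"R108W"} notation (stop as \code{"*"}), with
#' the residue index \code{floor((cds_pos - 1) / 3) + 1}.
#'
#' @param gene a [gene_model()].
#' @param cds_pos 1-based position in the CDS.
#' @param ref,alt reference and alternate base; \code{ref} must match the
#'   gene's CDS at \code{cds_pos} (a mismatch signals a wrong gene model or
#'   coordinate base and raises an error).
#' @return one-row data.frame: \code{gene_id, cds_pos, ref, alt,
#'   codon_index, in_codon_offset} (0/1/2), \code{ref_codon, alt_codon,
#'   ref_aa, alt_aa, substitution, effect}.
#' @examples
#' g <- gene_model("g", "ATGCGGTGA")  # M R *
#' annotate_mutation(g, 4, "C", "T")  # R2W missense
#' @export
annotate_mutation <- function(gene, cds_pos, ref, alt) {
  if (!inherits(gene, "gene_model")) stopf("'gene' must be a gene_model")
  cds_pos <- check_count(cds_pos, "cds_pos", 1L)
  if (cds_pos > nchar(gene$cds_seq)) {
    stopf("cds_pos %d beyond CDS of '%s' (%d bp)", cds_pos, gene$gene_id,
          nchar(gene$cds_seq))
  }
  ref <- match.arg(ref, DNA_BASES)
  alt <- match.arg(alt, DNA_BASES)
  if (ref == alt) stopf("'alt' must differ from 'ref'")
  have <- substr(gene$cds_seq, cds_pos, cds_pos)
  if (have != ref) {
    stopf("reference mismatch at %s:%d: CDS has %s, mutation says %s",
          gene$gene_id, cds_pos, have, ref)
  }
  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  offset <- (cds_pos - 1L) %% 3L
  ref_codon <- substr(gene$cds_seq, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, offset + 1L, offset + 1L) <- alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])
  effect <- if (ref_aa == alt_aa) "silent"
    else if (alt_aa == "*") "nonsense"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  data.frame(
    gene_id = gene$gene_id, cds_pos = cds_pos, ref = ref, alt = alt,
    codon_index = codon_index, in_codon_offset = offset,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    substitution = format_aa_substitution(ref_aa, codon_index, alt_aa),
    effect = effect
  )
}

#' Annotate a table of CDS mutations against a gene panel
#'
#' @param genes list of [gene_model()] objects.
#' @param mutations data.frame with columns \code{gene_id, cds_pos, ref,
#'   alt} (extra columns are carried through).
#' @return \code{mutations} with the [annotate_mutation()] columns appended.
#' @export
annotate_variants <- function(genes, mutations) {
  genes <- check_gene_list(genes)
  unknown <- setdiff(unique(mutations$gene_id), names(genes))
  if (length(unknown) > 0L) {
    stopf("mutations reference unknown gene(s): %s", paste(unknown, collapse = ", "))
  }
  if (nrow(mutations) == 0L) {
    ann0 <- annotate_mutation(gene_model("g", "ATG"), 1L, "A", "C")
    extra <- setdiff(names(ann0), names(mutations))
    for (nm in extra) mutations[[nm]] <- ann0[[nm]][0]
    return(mutations)
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(mutations)), function(i) {
    annotate_mutation(genes[[mutations$gene_id[i]]], mutations$cds_pos[i],
                      mutations$ref[i], mutations$alt[i])
  }))
  cbind(mutations, ann[, setdiff(names(ann), names(mutations)), drop = FALSE])
}

#' Render and parse amino-acid substitution notation
#'
#' \code{format_aa_substitution(ref_aa, index, alt_aa)} gives strings like
#' \code{"R108W"} or \code{"W247*"}; \code{parse_aa_substitution()} inverts
#' it (round-trip identity).
#'
#' @param ref_aa,alt_aa single-letter amino acids (\code{"*"} for stop).
#' @param index residue index (1-based codon number).
#' @return \code{format_aa_substitution()}: character vector.
#'   \code{parse_aa_substitution()}: data.frame \code{ref_aa, codon_index,
#'   alt_aa}.
#' @export
format_aa_substitution <- function(ref_aa, index, alt_aa) {
  paste0(ref_aa, index, alt_aa)
}

#' @rdname format_aa_substitution
#' @param x character vector of substitution strings (internal spaces, as in
#'   some printed tables, are tolerated).
#' @export
parse_aa_substitution <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  m <- regmatches(x, regexec("^([A-Z*])([0-9]+)([A-Z*])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stopf("malformed substitution(s): %s", paste(x[bad], collapse = ", "))
  data.frame(
    ref_aa = vapply(m, `[`, character(1), 2L),
    codon_index = as.integer(vapply(m, `[`, character(1), 3L)),
    alt_aa = vapply(m, `[`, character(1), 4L)
  )
}

parse_nt_change <- function(x) {
  x <- gsub("[[:space:]]", "", x)
  m <- regmatches(x, regexec("^([ACGT])([0-9]+)([ACGT])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stopf("malformed nucleotide change(s): %s", paste(x[bad], collapse = ", "))
  data.frame(
    ref = vapply(m, `[`, character(1), 2L),
    cds_pos = as.integer(vapply(m, `[`, character(1), 3L)),
    alt = vapply(m, `[`, character(1), 4L)
  )
}

#' Check nucleotide-change / residue-substitution pairs for codon consistency
#'
#' For each record with a nucleotide change (e.g. \code{"C322T"}) and a
#' printed substitution (e.g. \code{"R108W"}) this verifies that (a) the
#' printed residue index equals \code{floor((pos - 1) / 3) + 1} and (b) some
#' codon encoding the printed reference amino acid carries the reference
#' base at the implied codon offset and, after the base change, encodes the
#' printed alternate amino acid. This is the strongest check available when
#' the underlying CDS sequence itself is not published.
#'
#' @param records data.frame with columns \code{nt_change} and
#'   \code{aa_change} (e.g. the packaged mutant phenotype table, see
#'   [load_phenotype_table()]); rows with empty \code{nt_change} (wild-type
#'   entries) are skipped.
#' @return data.frame with one row per checked record: the parsed fields,
#'   the computed codon index/offset, logicals \code{index_ok} and
#'   \code{codon_ok}, and \code{consistent} (both).
#' @export
check_table2_consistency <- function(records) {
  need <- c("nt_change", "aa_change")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stopf("'records' must have columns %s", paste(need, collapse = ", "))
  }
  records <- records[!is.na(records$nt_change) & nzchar(records$nt_change), ,
                     drop = FALSE]
  nt <- parse_nt_change(records$nt_change)
  aa <- parse_aa_substitution(records$aa_change)
  code <- Biostrings::GENETIC_CODE
  out <- data.frame(
    nt_change = gsub("[[:space:]]", "", records$nt_change),
    aa_change = gsub("[[:space:]]", "", records$aa_change),
    ref = nt$ref, cds_pos = nt$cds_pos, alt = nt$alt,
    ref_aa = aa$ref_aa, printed_index = aa$codon_index, alt_aa = aa$alt_aa
  )
  out$codon_index <- (out$cds_pos - 1L) %/% 3L + 1L
  out$offset <- (out$cds_pos - 1L) %% 3L
  out$index_ok <- out$codon_index == out$printed_index
  out$codon_ok <- vapply(seq_len(nrow(out)), function(i) {
    cands <- names(code)[code == out$ref_aa[i]]
    off <- out$offset[i] + 1L
    for (codon in cands) {
      if (substr(codon, off, off) != out$ref[i]) next
      mutated <- codon
      substr(mutated, off, off) <- out$alt[i]
      if (unname(code[mutated]) == out$alt_aa[i]) return(TRUE)
    }
    FALSE
  }, logical(1))
  out$consistent <- out$index_ok & out$codon_ok
  out
}
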