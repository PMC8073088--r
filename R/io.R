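#' Read target gene models from a FASTA file
#'
#' CDS sequences are read with \pkg{Biostrings}; screened-amplicon sizes can
#' be supplied as a named vector or a table (e.g. the amplicon column of the
#' packaged mutation summary), and default to the CDS lengths.
#'
#' @param path FASTA file of CDS sequences (record names are gene ids).
#' @param amplicon optional named integer vector, or data.frame with
#'   \code{gene_id} and \code{amplicon_bp} columns.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_fasta <- function(path, amplicon = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stopf("no sequences in '%s'", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (is.data.frame(amplicon)) {
    amplicon <- stats::setNames(amplicon$amplicon_bp, amplicon$gene_id)
  }
  genes <- lapply(seq_along(seqs), function(i) {
    amp <- if (!is.null(amplicon) && ids[i] %in% names(amplicon)) {
      amplicon[[ids[i]]]
    } else {
      length(seqs[[i]])
    }
    gene_model(ids[i], as.character(seqs[[i]]), amplicon_bp = amp)
  })
  names(genes) <- ids
  check_gene_list(genes)
}

#' @rdname read_gene_fasta
#' @param genes list of [gene_model()] objects to write.
#' @export
write_gene_fasta <- function(genes, path) {
  genes <- check_gene_list(genes)
  set <- Biostrings::DNAStringSet(vapply(genes, `[[`, character(1), "cds_seq"))
  names(set) <- names(genes)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

COUNT_COLS <- c("pool_id", "gene_id", "cds_pos", "ref", "nA", "nC", "nG", "nT", "depth")

#' Read and write pool allele-count tables (TSV)
#'
#' @param counts data.frame of pool-site counts (see [sequence_pool()]).
#' @param path TSV path.
#' @return \code{read_counts_tsv()}: the counts data.frame.
#' @export
write_counts_tsv <- function(counts, path) {
  if (!all(COUNT_COLS %in% names(counts))) {
    stopf("'counts' must have columns %s", paste(COUNT_COLS, collapse = ", "))
  }
  utils::write.table(counts[, COUNT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  counts <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stopf("cannot parse counts TSV '%s': %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(COUNT_COLS, names(counts))
  if (length(missing_cols) > 0L) {
    stopf("counts TSV '%s' lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  bad <- which(counts$nA + counts$nC + counts$nG + counts$nT != counts$depth)
  if (length(bad) > 0L) {
    stopf("counts TSV '%s': base counts do not sum to depth at line %d",
          path, bad[1L] + 1L)
  }
  counts[, COUNT_COLS]
}

#' Write filtered variants as a minimal VCF 4.2 file
#'
#' One record per variant: \code{CHROM} is the gene id, \code{POS} the
#' 1-based CDS position, \code{QUAL} the variant quality, \code{FILTER} the
#' \code{PASS}/\code{lowQUAL}/\code{lowAC} flags, and \code{INFO} carries
#' \code{AF} (mean observed alt fraction over supporting pools), \code{AC}
#' (estimated alt allele copies) and \code{POOLS} (supporting pool labels,
#' \code{|}-separated).
#'
#' @param variants data.frame from [integrate_and_filter()].
#' @param path output path.
#' @return \code{read_vcf()}: a data.frame with the same columns as
#'   [integrate_and_filter()] output (plus \code{AF}).
#' @export
write_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tillseq",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Mean observed alt allele fraction over supporting pools\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Estimated alt allele copies (2 per supporting pool)\">",
    "##INFO=<ID=POOLS,Number=.,Type=String,Description=\"Supporting pool labels\">",
    "##FILTER=<ID=lowQUAL,Description=\"Variant QUAL below threshold\">",
    "##FILTER=<ID=lowAC,Description=\"Alt allele copies below threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- character(0)
  if (nrow(variants) > 0L) {
    af <- if ("AF" %in% names(variants)) variants$AF else NA_real_
    pools <- paste(variants$vpools, variants$hpools, sep = ",")
    pools <- gsub("^,|,$", "", pools)
    pools <- gsub(",", "|", pools, fixed = TRUE)
    info <- sprintf("AF=%s;AC=%d;POOLS=%s",
                    ifelse(is.na(af), ".", sprintf("%.6g", af)),
                    variants$AC, pools)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                    variants$gene_id, variants$cds_pos, variants$ref,
                    variants$alt, sprintf("%.6g", variants$QUAL),
                    variants$filter, info)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0L || ln[1L] != "##fileformat=VCFv4.2") {
    stopf("'%s' is not a VCF 4.2 file", path)
  }
  body <- ln[!startsWith(ln, "#")]
  out <- data.frame(
    gene_id = character(), cds_pos = integer(), ref = character(),
    alt = character(), vpools = character(), hpools = character(),
    n_pools = integer(), AC = integer(), QUAL = numeric(), AF = numeric(),
    filter = character()
  )
  if (length(body) == 0L) return(out)
  fields <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 8L)
  if (length(bad) > 0L) {
    stopf("malformed VCF record at line %d of '%s'",
          which(!startsWith(ln, "#"))[bad[1L]], path)
  }
  m <- do.call(rbind, fields)
  info_get <- function(info, key) {
    vapply(strsplit(info, ";", fixed = TRUE), function(kv) {
      hit <- kv[startsWith(kv, paste0(key, "="))]
      if (length(hit) == 0L) NA_character_ else sub("^[^=]*=", "", hit[1L])
    }, character(1))
  }
  pools <- strsplit(info_get(m[, 8L], "POOLS"), "|", fixed = TRUE)
  vp <- vapply(pools, function(p) paste(sort(p[startsWith(p, "V")]), collapse = ","), character(1))
  hp <- vapply(pools, function(p) paste(sort(p[startsWith(p, "H")]), collapse = ","), character(1))
  af <- info_get(m[, 8L], "AF")
  out <- data.frame(
    gene_id = m[, 1L], cds_pos = as.integer(m[, 2L]), ref = m[, 4L],
    alt = m[, 5L], vpools = vp, hpools = hp,
    n_pools = lengths(pools),
    AC = as.integer(info_get(m[, 8L], "AC")),
    QUAL = as.numeric(m[, 6L]),
    AF = ifelse(af == ".", NA_real_, suppressWarnings(as.numeric(af))),
    filter = m[, 7L]
  )
  rownames(out) <- NULL
  out
}

#' Load the packaged six-gene mutation summary table
#'
#' Per-gene screened amplicon sizes and tallies of base-change types (G>A,
#' C>T, other) and coding effects (missense, nonsense, silent) for a
#' six-member fatty-acid desaturase panel screened in 4032 lines. Row sums
#' are validated on load (each gene's type counts must add to its base
#' changes, and effect counts to its amino-acid substitutions).
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return data.frame of class \code{"mutation_count_table"} with columns
#'   \code{gene_id, amplicon_bp, base_changes, ga, ct, others,
#'   aa_substitutions, missense, nonsense, silent}.
#' @export
load_mutation_summary_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mutation_summary_six_genes.tsv",
                        package = "tillseq", mustWork = TRUE)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "amplicon_bp", "base_changes", "ga", "ct", "others",
            "aa_substitutions", "missense", "nonsense", "silent")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stopf("mutation summary lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad <- which(x$ga + x$ct + x$others != x$base_changes)
  if (length(bad) > 0L) {
    stopf("type counts of '%s' do not sum to its base changes", x$gene_id[bad[1L]])
  }
  bad <- which(x$missense + x$nonsense + x$silent != x$aa_substitutions)
  if (length(bad) > 0L) {
    stopf("effect counts of '%s' do not sum to its substitutions", x$gene_id[bad[1L]])
  }
  class(x) <- c("mutation_count_table", "data.frame")
  x
}

#' Load the packaged mutant fatty-acid phenotype table
#'
#' Twenty-four confirmed desaturase mutants with their nucleotide change,
#' amino-acid substitution and five seed fatty-acid percentages, plus the
#' wild-type reference row. Completeness is validated on load.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @param wt_id wild-type plant id expected in the table (default
#'   \code{"F-WT"}).
#' @return data.frame with columns \code{gene_id, plant_id, nt_change,
#'   aa_change, p16_0, p18_0, p18_1, p18_2, p18_3}.
#' @export
load_phenotype_table <- function(path = NULL, wt_id = "F-WT") {
  if (is.null(path)) {
    path <- system.file("extdata", "mutant_fatty_acid_phenotypes.tsv",
                        package = "tillseq", mustWork = TRUE)
  }
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("gene_id", "plant_id", "nt_change", "aa_change", unname(FA_COLS))
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0L) {
    stopf("phenotype table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (sum(x$plant_id == wt_id) != 1L) {
    stopf("phenotype table must contain exactly one wild-type row '%s'", wt_id)
  }
  if (anyNA(x[, unname(FA_COLS)])) stopf("phenotype table has missing fatty-acid values")
  mut <- x[x$plant_id != wt_id, ]
  if (anyNA(mut$nt_change) || anyNA(mut$aa_change)) {
    stopf("mutant rows must carry nucleotide and amino-acid changes")
  }
  x
}
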