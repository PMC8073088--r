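#' Configuration of a full pooled-screen simulation run
#'
#' The defaults reproduce the reference screen: a 42-plate (4032-line) M2
#' library pooled into 168 vertical pools of 24 and 84 horizontal pools of
#' 48, mutagenized at one induced mutation per 212 kb screened with an
#' EMS-biased spectrum, sequenced at 10 reads per haploid genome with a
#' 0.001 miscall rate, and filtered at \code{QUAL >= 40} (the error-null
#' analogue of a conservative pool-caller threshold, see
#' [integrate_and_filter()]) and \code{AC >= 4}.
#'
#' @param n_plates,n_rows,n_cols,pair_size,group_size pooling design, see
#'   [build_scheme()].
#' @param n_lines number of M2 lines.
#' @param density induced mutations per bp per line.
#' @param spectrum a [spectrum_model()].
#' @param het_fraction probability an induced mutation is heterozygous.
#' @param depth_per_haploid,error_rate sequencing model, see [seq_config()].
#' @param min_alt_reads,qual_min,ac_min calling/filter thresholds, see
#'   [call_pool()] and [integrate_and_filter()].
#' @param sanger_error per-candidate probability the confirmation assay
#'   misses a carrier (default 0).
#' @param seed integer seed making the whole run reproducible.
#' @param out_dir optional directory for TSV/VCF artifacts.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(n_plates = 42L, n_rows = 8L, n_cols = 12L,
                       pair_size = 2L, group_size = 6L, n_lines = 4032L,
                       density = 1 / 212000, spectrum = spectrum_model(),
                       het_fraction = 1, depth_per_haploid = 10,
                       error_rate = 0.001, min_alt_reads = 3L, qual_min = 40,
                       ac_min = 4L, sanger_error = 0, seed = 1L,
                       out_dir = NULL) {
  scheme <- build_scheme(n_plates, n_rows, n_cols, pair_size, group_size)
  n_lines <- check_count(n_lines, "n_lines", 1L)
  if (n_lines > scheme$n_samples) {
    stopf("'n_lines' (%d) exceeds the scheme's capacity (%d wells)",
          n_lines, scheme$n_samples)
  }
  cfg <- list(
    n_plates = scheme$n_plates, n_rows = scheme$n_rows,
    n_cols = scheme$n_cols, pair_size = scheme$pair_size,
    group_size = scheme$group_size, n_lines = n_lines, density = density,
    spectrum = if (inherits(spectrum, "spectrum_model")) spectrum else spectrum_model(spectrum),
    het_fraction = check_prob(het_fraction, "het_fraction"),
    depth_per_haploid = depth_per_haploid, error_rate = error_rate,
    min_alt_reads = check_count(min_alt_reads, "min_alt_reads", 1L),
    qual_min = qual_min, ac_min = ac_min,
    sanger_error = check_prob(sanger_error, "sanger_error"),
    seed = check_count(seed, "seed"), out_dir = out_dir
  )
  # validate the sequencing parameters eagerly, before any stage runs
  seq_config(cfg$depth_per_haploid, cfg$error_rate)
  if (!is.numeric(density) || density <= 0) stopf("'density' must be positive")
  structure(cfg, class = "run_config")
}

#' Run the full pooled TILLING screen simulation end to end
#'
#' Executes simulate -> pool -> sequence -> call -> filter -> demultiplex ->
#' resolve -> annotate -> summarize and reconciles every planted mutation
#' against the screen's outcome. Fully reproducible under a fixed
#' \code{cfg$seed}; when \code{cfg$out_dir} is set, the truth table, pool
#' manifest, counts, calls, VCF and resolution report are written there as
#' TSV/VCF text.
#'
#' @param cfg a [run_config()].
#' @param genes gene panel; defaults to [synthetic_gene_panel()] seeded from
#'   \code{cfg$seed}.
#' @return object of class \code{"tillseq_run"}: a list with the scheme,
#'   population (truth), counts, calls, \code{variants} (all integrated,
#'   with filter flags), \code{resolution} (per passing variant), annotated
#'   passing variants, \code{summary} (a [spectrum_summary()] of the
#'   resolved mutations), \code{recovery} (fraction of planted mutations
#'   resolved to the right line) and \code{status_counts}.
#' @export
run_pipeline <- function(cfg = run_config(), genes = NULL) {
  if (!inherits(cfg, "run_config")) stopf("'cfg' must be a run_config")
  scheme <- build_scheme(cfg$n_plates, cfg$n_rows, cfg$n_cols,
                         cfg$pair_size, cfg$group_size)
  if (is.null(genes)) genes <- synthetic_gene_panel(seed = cfg$seed)
  genes <- check_gene_list(genes)

  population <- simulate_population(
    genes, n_lines = cfg$n_lines, density = cfg$density,
    spectrum = cfg$spectrum, het_fraction = cfg$het_fraction,
    seed = cfg$seed, n_rows = cfg$n_rows, n_cols = cfg$n_cols
  )
  scfg <- seq_config(cfg$depth_per_haploid, cfg$error_rate,
                     seed = cfg$seed + 1L)
  counts <- simulate_pool_sequencing(population, scheme, scfg,
                                     min_alt_emit = cfg$min_alt_reads)
  calls <- call_pool(counts, error_rate = cfg$error_rate,
                     min_alt_reads = cfg$min_alt_reads)
  variants <- integrate_and_filter(calls, scheme, qual_min = cfg$qual_min,
                                   ac_min = cfg$ac_min)
  pass <- passing_variants(variants)
  cands <- demultiplex(pass, scheme)
  resolution <- sanger_resolve(cands, population,
                               sanger_error = cfg$sanger_error,
                               seed = cfg$seed + 2L)
  annotated <- annotate_variants(genes, pass)
  resolved <- resolution$status == "resolved"
  summary <- if (any(resolved)) {
    spectrum_summary(
      annotated[match(
        paste(resolution$gene_id, resolution$cds_pos, resolution$alt)[resolved],
        paste(annotated$gene_id, annotated$cds_pos, annotated$alt)
      ), , drop = FALSE],
      genes = genes, n_lines = cfg$n_lines
    )
  } else NULL
  recovery <- recovery_rate(population$mutations, resolution)
  status_counts <- table(factor(
    resolution$status,
    levels = c("resolved", "false_positive", "collision", "unresolvable", "discordant")
  ))

  run <- structure(list(
    config = cfg, scheme = scheme, genes = genes, population = population,
    counts = counts, calls = calls, variants = variants,
    resolution = resolution, annotated = annotated, summary = summary,
    recovery = recovery, status_counts = status_counts
  ), class = "tillseq_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(cfg$out_dir, f)
    utils::write.table(pool_manifest(scheme), p("pool_manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth <- population$mutations
    truth <- cbind(truth,
                   population$lines[match(truth$line_id, population$lines$line_id),
                                    c("plate", "row", "col")])
    truth$well <- well_label(truth$row, truth$col)
    utils::write.table(
      truth[, c("line_id", "plate", "well", "gene_id", "cds_pos", "ref", "alt", "zygosity")],
      p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_gene_fasta(genes, p("genes.fasta"))
    write_counts_tsv(counts, p("pool_counts.tsv"))
    utils::write.table(calls, p("pool_calls.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_vcf(variants, p("variants.vcf"))
    rep <- resolution[, setdiff(names(resolution), "candidates")]
    utils::write.table(rep, p("resolution.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  run
}

#' @export
print.tillseq_run <- function(x, ...) {
  cat("Pooled TILLING screen simulation\n")
  print(x$scheme)
  cat(sprintf("  planted mutations: %d in %d lines\n",
              nrow(x$population$mutations), nrow(x$population$lines)))
  cat(sprintf("  pool calls: %d; variants: %d (%d PASS)\n",
              nrow(x$calls), nrow(x$variants), sum(x$variants$filter == "PASS")))
  st <- x$status_counts
  cat("  resolution:", paste(sprintf("%s %d", names(st), st), collapse = ", "), "\n")
  cat(sprintf("  recovery rate: %s\n",
              ifelse(is.na(x$recovery), "n/a", sprintf("%.1f%%", 100 * x$recovery))))
  invisible(x)
}

#' @export
#' @method summary tillseq_run
summary.tillseq_run <- function(object, ...) {
  print(object)
  if (!is.null(object$summary)) print(object$summary)
  invisible(object)
}
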