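#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis: the synthetic cohort (or
#' paths to real inputs), the somatic filter thresholds, GSEA settings and
#' the dual driver FDR gates, and the germline cohort sizes. Every
#' published threshold is a named, overridable key.
#'
#' @param out_dir Directory for all stage outputs (created if absent).
#' @param cohort A [cohort_spec] used to simulate inputs, or `NULL` when
#'   `variants_path`/`scores_path` point at real data.
#' @param variants_path,scores_path Optional MAF-like TSV / score TSV
#'   inputs; when given they replace the simulated ones.
#' @param n_samples Total assayed samples for frequency denominators
#'   (defaults to the cohort's pair count).
#' @param filter A [filter_config].
#' @param gene_sets Named list of gene sets; `NULL` generates a planted
#'   pathway (the cohort's driver genes plus a few passengers) alongside
#'   random passenger sets.
#' @param gsea_n_perm,weight_exponent GSEA settings.
#' @param chasm_fdr_threshold,vest_fdr_threshold Driver dual-gate
#'   thresholds (defaults 0.25 and 0.10).
#' @param cohort_sizes Named germline cohort sizes for the burden stage.
#' @param seed Integer seed governing every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_spec(),
                            variants_path = NULL,
                            scores_path = NULL,
                            n_samples = NULL,
                            filter = filter_config(),
                            gene_sets = NULL,
                            gsea_n_perm = 1000L,
                            weight_exponent = 1,
                            chasm_fdr_threshold = 0.25,
                            vest_fdr_threshold = 0.10,
                            cohort_sizes = c(case = 52L, ita1000g = 107L,
                                             eur1000g = 396L, house = 106L),
                            seed = 1L) {
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_spec"))
  if (!(chasm_fdr_threshold > 0 && chasm_fdr_threshold < 1 &&
        vest_fdr_threshold > 0 && vest_fdr_threshold < 1))
    stop("FDR thresholds must lie in (0, 1)")
  for (p in c(variants_path, scores_path))
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p)
  structure(list(out_dir = out_dir, cohort = cohort,
                 variants_path = variants_path, scores_path = scores_path,
                 n_samples = n_samples, filter = filter,
                 gene_sets = gene_sets, gsea_n_perm = as.integer(gsea_n_perm),
                 weight_exponent = weight_exponent,
                 chasm_fdr_threshold = chasm_fdr_threshold,
                 vest_fdr_threshold = vest_fdr_threshold,
                 cohort_sizes = cohort_sizes, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

default_gene_sets <- function(spec) {
  with_seed(spec$rng_seed + stable_hash("gene-sets"), {
    pool <- spec$passenger_gene_pool
    sets <- list(PLANTED_PATHWAY = unique(c(names(spec$driver_genes),
                                            sample(pool, 8L))))
    for (i in 1:8)
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sample(pool, 25L)
    sets
  })
}

#' Run the full analysis pipeline
#'
#' Chains all stages on simulated or file-based inputs: somatic filtering,
#' 96-context spectrum and class fractions, signature decomposition,
#' driver-gene summarization under the dual FDR gate, preranked GSEA over
#' the pathogenicity-ranked genes, and the germline burden report. Each
#' stage writes its result as a TSV under `out_dir` and a JSON manifest
#' records the seed, per-stage row counts and file digests; an identical
#' config and seed reproduces identical manifest digests. A failing stage
#' aborts with the stage named.
#'
#' @param config A [pipeline_config].
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$cohort
  if (!is.null(spec)) spec$rng_seed <- config$seed
  out_file <- function(name) file.path(config$out_dir, name)

  variants <- stage("simulate/read variants", {
    if (!is.null(config$variants_path))
      read_variant_table(config$variants_path)
    else simulate_somatic_variants(spec)
  })
  write_variant_table(variants, out_file("variants.maf.tsv"))

  filt <- stage("somatic filter", filter_somatic_variants(variants, config$filter))
  write_variant_table(filt$retained, out_file("retained.maf.tsv"))
  write.table(data.frame(rule = names(filt$audit), n_rejected = filt$audit),
              out_file("audit.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  spectrum <- stage("spectrum", suppressMessages(build_spectrum(filt$retained)))
  write.table(data.frame(context = names(spectrum), count = spectrum),
              out_file("spectrum.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  fractions <- stage("class fractions", class_fractions(spectrum))

  refs <- if (!is.null(spec)) spec$signature_profiles else example_signatures()
  exposures <- stage("signature decomposition", decompose_signatures(spectrum, refs))
  write.table(data.frame(signature = names(exposures$weights),
                         weight = exposures$weights),
              out_file("exposures.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- stage("pathogenicity scores", {
    if (!is.null(config$scores_path))
      read.delim(config$scores_path, sep = "\t", stringsAsFactors = FALSE)
    else simulate_pathogenicity_scores(variants, spec)
  })
  n_samples <- if (!is.null(config$n_samples)) config$n_samples
               else length(unique(variants$sample_id))
  drivers <- stage("driver summarization",
                   suppressWarnings(summarize_genes(
                     filt$retained, scores, n_samples,
                     chasm_fdr_threshold = config$chasm_fdr_threshold,
                     vest_fdr_threshold = config$vest_fdr_threshold)))
  write.table(drivers, out_file("drivers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  enrichment <- stage("pathway enrichment", {
    sets <- config$gene_sets
    if (is.null(sets)) sets <- default_gene_sets(spec)
    ranked <- rank_genes(drivers)
    overlap <- vapply(sets, function(s) sum(ranked$gene_symbol %in% s), integer(1))
    if (any(overlap == 0L)) {
      warning("dropping gene set(s) with no mutated member: ",
              paste(names(sets)[overlap == 0L], collapse = ", "), call. = FALSE)
      sets <- sets[overlap > 0L]
    }
    gsea_preranked(ranked, sets, n_perm = config$gsea_n_perm,
                   seed = config$seed, weight_exponent = config$weight_exponent)
  })
  write.table(enrichment, out_file("enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  burden <- stage("germline burden", {
    counts <- simulate_carrier_tables(spec, config$cohort_sizes)
    names(counts)[names(counts) == "gene"] <- "gene"
    suppressWarnings(burden_report(counts))
  })
  write.table(burden, out_file("burden.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  files <- c("variants.maf.tsv", "retained.maf.tsv", "audit.tsv", "spectrum.tsv",
             "exposures.tsv", "drivers.tsv", "enrichment.tsv", "burden.tsv")
  manifest <- list(
    seed = config$seed,
    n_samples = n_samples,
    stage_rows = list(variants = nrow(variants), retained = nrow(filt$retained),
                      genes = nrow(drivers), gene_sets = nrow(enrichment),
                      burden_genes = nrow(burden)),
    file_md5 = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$file_md5) <- files
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(variants = variants, retained = filt$retained,
                 audit = filt$audit, spectrum = spectrum,
                 class_fractions = fractions, exposures = exposures,
                 drivers = drivers, enrichment = enrichment, burden = burden,
                 manifest = manifest))
}
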