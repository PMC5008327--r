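#' Germline candidate filter configuration
#'
#' Rare-variant germline filtering keeps variants in a curated cancer
#' predisposition gene list, not reported as common polymorphisms (dbSNP
#' flag), and predicted pathogenic by a VEST-style p-value strictly below
#' the threshold (default 0.10).
#'
#' @param predisposition_genes Character vector of gene symbols.
#' @param exclude_common_db Drop dbSNP-flagged variants (default TRUE).
#' @param vest_p_threshold Strict upper bound on the VEST p-value, in
#'   (0, 1).
#' @return A `germline_filter_config` list.
#' @export
germline_filter_config <- function(predisposition_genes,
                                   exclude_common_db = TRUE,
                                   vest_p_threshold = 0.10) {
  if (!length(predisposition_genes)) stop("predisposition gene list is empty")
  if (!(vest_p_threshold > 0 && vest_p_threshold < 1))
    stop("vest_p_threshold must lie in (0, 1)")
  structure(list(predisposition_genes = unique(predisposition_genes),
                 exclude_common_db = isTRUE(exclude_common_db),
                 vest_p_threshold = vest_p_threshold),
            class = "germline_filter_config")
}

#' Filter germline variants to burden-test candidates
#'
#' Retains a variant iff its gene is in the predisposition list, it is not
#' a known common polymorphism (when `exclude_common_db`), and its
#' VEST-style p-value is strictly below the threshold (a p-value equal to
#' the threshold is rejected). Variants lacking a VEST score are an error.
#'
#' @param variants Validated variant `data.frame`.
#' @param scores Score table with columns `key` and `vest_p`.
#' @param config A [germline_filter_config].
#' @return The retained variant `data.frame`.
#' @export
filter_germline_candidates <- function(variants, scores, config) {
  stopifnot(inherits(config, "germline_filter_config"))
  validate_variants(variants)
  key <- variant_key(variants)
  vest <- scores$vest_p[match(key, scores$key)]
  in_list <- variants$gene_symbol %in% config$predisposition_genes
  no_score <- in_list & is.na(vest)
  if (any(no_score))
    stop("variant(s) missing a VEST score: ",
         paste(utils::head(key[no_score], 5), collapse = ", "))
  keep <- in_list & vest < config$vest_p_threshold
  if (config$exclude_common_db) keep <- keep & !variants$dbsnp_member
  keep[is.na(keep)] <- FALSE
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: with margins
#' fixed, the p-value is the sum of hypergeometric point probabilities not
#' exceeding that of the observed table (within relative tolerance 1e-7).
#' Evaluation is in log space over the full fixed-margin support, so it is
#' stable for large margins.
#'
#' @param a,b Case carriers / non-carriers.
#' @param c,d Control carriers / non-carriers.
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' fisher_two_sided(4, 100, 0, 107)  # 0.057
fisher_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table")
  r1 <- a + b          # cases
  c1 <- a + c          # carriers
  c2 <- b + d
  lo <- max(0, r1 - c2)
  hi <- min(r1, c1)
  support <- lo:hi
  lp <- dhyper(support, c1, c2, r1, log = TRUE)
  lobs <- lp[support == a]
  min(1, sum(exp(lp[lp <= lobs + log(1 + 1e-7)])))
}

#' Combined p-value against pooled controls
#'
#' Pools the control cohorts by summing their carrier / non-carrier counts
#' and applies [fisher_two_sided] to the resulting single 2x2 table. With
#' one cohort this reduces to the per-cohort test.
#'
#' @param case_with,case_without Case carrier counts.
#' @param cohorts List of `c(with, without)` control count pairs.
#' @return Two-sided pooled p-value.
#' @export
combined_pooled_p <- function(case_with, case_without, cohorts) {
  if (!length(cohorts)) stop("no control cohorts")
  w <- sum(vapply(cohorts, `[[`, numeric(1), 1))
  wo <- sum(vapply(cohorts, `[[`, numeric(1), 2))
  fisher_two_sided(case_with, case_without, w, wo)
}

#' Fold enrichment of case carriers over pooled controls
#'
#' Ratio of the case carrier frequency to the pooled-control carrier
#' frequency. When no control carries a variant the ratio is undefined;
#' by default a pseudocount of 1 is then added to the control carriers
#' (and to the control total), otherwise no pseudocount is used.
#'
#' @param case_with,case_without Case counts.
#' @param pooled_with,pooled_without Pooled control counts.
#' @param pseudocount Non-negative; `NULL` (default) means 1 if
#'   `pooled_with == 0`, else 0.
#' @return Positive fold enrichment.
#' @export
fold_enrichment <- function(case_with, case_without, pooled_with,
                            pooled_without, pseudocount = NULL) {
  if (case_with + case_without == 0) stop("no cases")
  if (is.null(pseudocount)) pseudocount <- if (pooled_with == 0) 1 else 0
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  den <- (pooled_with + pseudocount) / (pooled_with + pooled_without + pseudocount)
  if (den <= 0) stop("control carrier frequency is zero; supply a pseudocount")
  (case_with / (case_with + case_without)) / den
}

#' Per-gene germline burden report
#'
#' Runs, for every gene of a carrier-count table, the per-cohort two-sided
#' Fisher's exact tests, the pooled-control combined test and the fold
#' enrichment, returning one row per gene sorted by combined p-value
#' (ties broken by gene symbol). Cohorts are detected from paired
#' `<cohort>_with` / `<cohort>_without` columns; `case_with`/`case_without`
#' are the case columns. Genes may have different assayed case totals
#' (e.g. when only a subset of genes was covered by both platforms);
#' differing cohort sizes across genes raise a warning, not an error.
#'
#' @param counts `data.frame` with columns `gene`, `case_with`,
#'   `case_without` and `<cohort>_with`/`<cohort>_without` pairs.
#' @return `data.frame`: gene, all counts, per-cohort `p_<cohort>`
#'   columns, `combined_p`, `fold_enrichment`.
#' @export
burden_report <- function(counts) {
  stopifnot(all(c("gene", "case_with", "case_without") %in% names(counts)),
            nrow(counts) > 0)
  with_cols <- grep("_with$", names(counts), value = TRUE)
  cohorts <- setdiff(sub("_with$", "", with_cols), "case")
  if (!length(cohorts)) stop("no control cohort columns found")
  missing_wo <- paste0(cohorts, "_without")[!paste0(cohorts, "_without") %in% names(counts)]
  if (length(missing_wo)) stop("missing column(s): ", paste(missing_wo, collapse = ", "))

  for (co in c("case", cohorts)) {
    sizes <- counts[[paste0(co, "_with")]] + counts[[paste0(co, "_without")]]
    if (length(unique(sizes)) > 1L)
      warning("cohort ", co, " has differing totals across genes (",
              paste(unique(sizes), collapse = ", "), ")", call. = FALSE)
  }

  out <- counts
  for (co in cohorts) {
    out[[paste0("p_", co)]] <- mapply(fisher_two_sided,
                                      counts$case_with, counts$case_without,
                                      counts[[paste0(co, "_with")]],
                                      counts[[paste0(co, "_without")]])
  }
  pooled_w <- Reduce(`+`, lapply(cohorts, function(co) counts[[paste0(co, "_with")]]))
  pooled_wo <- Reduce(`+`, lapply(cohorts, function(co) counts[[paste0(co, "_without")]]))
  out$combined_p <- mapply(fisher_two_sided, counts$case_with,
                           counts$case_without, pooled_w, pooled_wo)
  out$fold_enrichment <- mapply(fold_enrichment, counts$case_with,
                                counts$case_without, pooled_w, pooled_wo)
  out <- out[order(out$combined_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select genes consistently enriched across all control cohorts
#'
#' A gene can reach a small pooled p-value on the strength of a single
#' control cohort; the published candidate selection instead demanded
#' enrichment against every cohort. This helper returns the genes whose
#' per-cohort p-values are all strictly below `max_cohort_p` (default
#' 0.10, a conventional suggestive level), ordered by combined p-value.
#'
#' @param report Output of [burden_report].
#' @param max_cohort_p Strict per-cohort p-value bound.
#' @return Character vector of gene symbols, ordered by `combined_p`.
#' @export
top_burden_genes <- function(report, max_cohort_p = 0.10) {
  pcols <- grep("^p_", names(report), value = TRUE)
  if (!length(pcols)) stop("report has no per-cohort p-value columns")
  ok <- apply(report[, pcols, drop = FALSE] < max_cohort_p, 1L, all)
  report$gene[ok][order(report$combined_p[ok])]
}

#' Published germline carrier counts (bundled fixture)
#'
#' The per-gene case/control carrier counts of the published
#' aggressive-neuroblastoma germline burden analysis: 52 patients (104 for
#' BARD1, assayed on both platforms) against three control cohorts -- 107
#' Italian and 396 European 1000 Genomes individuals and 106 in-house
#' exomes. The `printed_fold` column reproduces the published
#' fold-enrichment values as data (their formula is not recomputable from
#' the counts alone).
#'
#' @return `data.frame` in [burden_report] input format, plus
#'   `printed_fold`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "nbmut",
                      mustWork = TRUE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
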