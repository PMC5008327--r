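#' Combine per-mutation p-values to a gene-level p-value
#'
#' Two combination rules are offered. `fisher_combination` (default
#' downstream) refers all mutations of a gene jointly: the statistic
#' `-2 * sum(log p)` is chi-squared with `2k` degrees of freedom under the
#' null of k independent passenger mutations. `min_p_bonferroni` takes the
#' Bonferroni-corrected minimum, `min(1, k * min(p))`, sensitive to a
#' single strong driver mutation.
#'
#' @param mutation_ps Per-mutation p-values in (0, 1]; exact zeros are
#'   clamped to 1e-300 with a warning.
#' @param method `"fisher_combination"` or `"min_p_bonferroni"`.
#' @return A single combined p-value.
#' @export
gene_level_p <- function(mutation_ps,
                         method = c("fisher_combination", "min_p_bonferroni")) {
  method <- match.arg(method)
  if (!length(mutation_ps)) stop("empty p-value list")
  if (any(is.na(mutation_ps)) || any(mutation_ps < 0 | mutation_ps > 1))
    stop("p-values must lie in (0, 1]")
  if (any(mutation_ps == 0)) {
    warning("p-value of exactly 0 clamped to 1e-300", call. = FALSE)
    mutation_ps[mutation_ps == 0] <- 1e-300
  }
  k <- length(mutation_ps)
  switch(method,
         fisher_combination =
           pchisq(-2 * sum(log(mutation_ps)), df = 2 * k, lower.tail = FALSE),
         min_p_bonferroni = min(1, k * min(mutation_ps)))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up FDR q-values: `q_i = min_{j: p_(j) >= p_(i)} m * p_(j) / j`,
#' returned in the input order. A validated wrapper around
#' `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Summarize mutations to gene-level driver statistics
#'
#' Aggregates per-mutation CHASM-style and VEST-style p-values to gene
#' level (Fisher combination by default), computes Benjamini-Hochberg FDRs
#' across all summarized genes for each score, counts distinct carrier
#' samples, and applies the dual significance gate: a gene is a candidate
#' driver iff CHASM FDR < `chasm_fdr_threshold` AND VEST FDR <
#' `vest_fdr_threshold` (defaults 0.25 and 0.10).
#'
#' Only non-silent mutations contribute. A gene none of whose mutations
#' carry a usable score is excluded with a warning. Carrier frequency is
#' distinct mutated samples / `n_samples` (also reported rounded to one
#' decimal percent, the convention for printed frequencies).
#'
#' @param variants Validated variant `data.frame`.
#' @param scores Score table with columns `key`, `chasm_p`, `vest_p`
#'   (see [simulate_pathogenicity_scores] for the key convention).
#' @param n_samples Total assayed samples (>= distinct samples observed).
#' @param method Gene-level combination method, see [gene_level_p].
#' @param chasm_fdr_threshold,vest_fdr_threshold Dual-gate thresholds.
#' @return `data.frame` with one row per gene: mutation and carrier
#'   counts, carrier_frequency and carrier_pct, gene-level p-values, FDRs
#'   and the `significant` flag, sorted by chasm_fdr then gene symbol.
#' @export
summarize_genes <- function(variants, scores, n_samples,
                            method = "fisher_combination",
                            chasm_fdr_threshold = 0.25,
                            vest_fdr_threshold = 0.10) {
  validate_variants(variants)
  stopifnot(all(c("key", "chasm_p", "vest_p") %in% names(scores)))
  v <- variants[variants$functional_class %in% NONSILENT_CLASSES, , drop = FALSE]
  if (!nrow(v)) stop("no non-silent variants to summarize")
  n_obs <- length(unique(v$sample_id))
  if (n_samples < n_obs)
    stop("n_samples (", n_samples, ") is below the ", n_obs,
         " distinct samples observed")
  idx <- match(variant_key(v), scores$key)
  v$chasm_p <- scores$chasm_p[idx]
  v$vest_p <- scores$vest_p[idx]
  scored_snv <- v$variant_class == "SNV" &
    (!is.na(v$chasm_p) | !is.na(v$vest_p))
  if (any(!scored_snv & v$variant_class == "SNV"))
    stop("non-silent SNV(s) without pathogenicity scores: ",
         paste(utils::head(variant_key(v)[v$variant_class == "SNV" & !scored_snv], 5),
               collapse = ", "))

  rows <- lapply(split(v, v$gene_symbol), function(g) {
    chasm <- g$chasm_p[!is.na(g$chasm_p)]
    vest <- g$vest_p[!is.na(g$vest_p)]
    if (!length(chasm) || !length(vest)) return(NULL)
    # duplicated mutation rows within one sample count once per carrier
    n_carriers <- length(unique(g$sample_id))
    data.frame(gene_symbol = g$gene_symbol[1],
               n_nonsilent_mutations = nrow(g),
               n_carrier_samples = n_carriers,
               carrier_frequency = n_carriers / n_samples,
               carrier_pct = round(100 * n_carriers / n_samples, 1),
               chasm_gene_p = gene_level_p(chasm, method),
               vest_gene_p = gene_level_p(vest, method),
               stringsAsFactors = FALSE)
  })
  dropped <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("gene(s) without any scored mutation excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) stop("no gene with scored mutations")
  out$chasm_fdr <- bh_fdr(out$chasm_gene_p)
  out$vest_fdr <- bh_fdr(out$vest_gene_p)
  out$significant <- out$chasm_fdr < chasm_fdr_threshold &
    out$vest_fdr < vest_fdr_threshold
  out <- out[order(out$chasm_fdr, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
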