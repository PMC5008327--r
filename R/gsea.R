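#' Rank mutated genes by pathogenicity
#'
#' Orders gene-level driver summaries by decreasing `-log10` of the
#' CHASM-style gene p-value, breaking ties lexicographically by gene
#' symbol so the ranking is fully deterministic.
#'
#' @param summaries Output of [summarize_genes].
#' @return `data.frame` with columns `gene_symbol`, `score`, in rank order.
#' @export
rank_genes <- function(summaries) {
  stopifnot(nrow(summaries) > 0,
            all(c("gene_symbol", "chasm_gene_p") %in% names(summaries)))
  if (anyDuplicated(summaries$gene_symbol))
    stop("duplicate gene symbols in summaries")
  score <- -log10(pmax(summaries$chasm_gene_p, 1e-300))
  ord <- order(-score, summaries$gene_symbol)
  out <- data.frame(gene_symbol = summaries$gene_symbol[ord],
                    score = score[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The classic preranked GSEA running statistic: walking down the ranked
#' list, set members ("hits") increment the running sum by
#' `|score|^weight_exponent` normalized over all hits, non-members
#' decrement it by `1 / (N - N_hits)`. The enrichment score is the
#' extremum of the running sum by absolute value. The leading edge
#' comprises the set members at or before the extremum (positive ES) or at
#' or after it (negative ES).
#'
#' @param ranked A [rank_genes] table.
#' @param gene_set Character vector of member symbols.
#' @param weight_exponent Non-negative weighting exponent (0 = classic
#'   unweighted KS; default 1).
#' @return List with `es`, `running` (length-N running sum) and
#'   `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  stopifnot(weight_exponent >= 0)
  N <- nrow(ranked)
  hit <- ranked$gene_symbol %in% gene_set
  m <- sum(hit)
  if (m == 0L) stop("gene set has no overlap with the ranked list")
  if (m == N) stop("gene set covers the whole ranked list")
  w <- abs(ranked$score)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1  # all-zero hit scores: fall back to unweighted
  inc <- w / sum(w)
  dec <- 1 / (N - m)
  running <- cumsum(ifelse(hit, inc, -dec))
  es <- running[which.max(abs(running))]
  peak <- which.max(abs(running))
  leading <- if (es >= 0) ranked$gene_symbol[seq_len(peak)][hit[seq_len(peak)]]
             else ranked$gene_symbol[peak:N][hit[peak:N]]
  list(es = es, running = running, leading_edge = leading)
}

# ES from sorted hit positions only; O(m) per evaluation, used for
# permutations. `w` are the |score|^exponent weights of the whole list.
es_from_hits <- function(idx, w, N) {
  m <- length(idx)
  idx <- sort(idx)
  wh <- w[idx]
  if (sum(wh) == 0) wh <- rep(1, m)
  cw <- cumsum(wh) / sum(wh)
  d <- 1 / (N - m)
  after <- cw - d * (idx - seq_len(m))        # running sum just after hit j
  before <- c(0, cw[-m]) - d * (idx - seq_len(m))  # just before hit j
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene-set enrichment analysis
#'
#' For each gene set, computes the observed enrichment score, a gene-label
#' permutation null (set membership assigned to random list positions,
#' scores fixed), a nominal permutation p-value, a normalized enrichment
#' score (NES = ES / mean same-sign permutation ES), and an FDR by the
#' canonical pooled-NES procedure (all sets' permutation NES pooled per
#' sign). The nominal p-value uses the same-sign permutations with an
#' add-one estimator, so it is never zero and is uniform under the null.
#' Results are fully reproducible for a fixed seed.
#'
#' @param ranked A [rank_genes] table.
#' @param sets Named list of gene sets (see [read_gmt]).
#' @param n_perm Number of membership permutations (>= 100).
#' @param seed Integer RNG seed.
#' @param weight_exponent Passed to [enrichment_score].
#' @return `data.frame`: `set_name`, `size`, `es`, `nes`, `p_perm`, `fdr`,
#'   `leading_edge` (comma-separated), sorted by `p_perm` then set name.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = 1L,
                           weight_exponent = 1) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("gene sets must be named")
  N <- nrow(ranked)
  too_big <- vapply(sets, function(s) length(unique(s)) >= N, logical(1))
  if (any(too_big))
    stop("gene set(s) as large as the ranked list: ",
         paste(names(sets)[too_big], collapse = ", "))
  w <- abs(ranked$score)^weight_exponent

  obs <- lapply(sets, function(s) enrichment_score(ranked, s, weight_exponent))
  sizes <- vapply(sets, function(s) sum(ranked$gene_symbol %in% s), integer(1))

  perm_es <- with_seed(seed, {
    lapply(seq_along(sets), function(i) {
      m <- sizes[[i]]
      vapply(seq_len(n_perm), function(b)
        es_from_hits(sample.int(N, m), w, N), numeric(1))
    })
  })

  es <- vapply(obs, `[[`, numeric(1), "es")
  nes <- p_perm <- numeric(length(sets))
  perm_nes <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    pe <- perm_es[[i]]
    pos <- pe[pe >= 0]; neg <- pe[pe < 0]
    if (es[i] >= 0) {
      p_perm[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
      nes[i] <- if (length(pos)) es[i] / mean(pos) else NA_real_
    } else {
      p_perm[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
      nes[i] <- if (length(neg)) -(es[i] / mean(neg)) else NA_real_
    }
    pn <- rep(NA_real_, n_perm)
    if (length(pos)) pn[pe >= 0] <- pe[pe >= 0] / mean(pos)
    if (length(neg)) pn[pe < 0] <- -(pe[pe < 0] / mean(neg))
    perm_nes[[i]] <- pn[!is.na(pn)]
  }

  pooled <- unlist(perm_nes)
  fdr <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      num_den <- sum(pooled >= 0)
      num <- if (num_den > 0) sum(pooled >= nes[i]) / num_den else 0
      den_den <- sum(nes >= 0, na.rm = TRUE)
      den <- if (den_den > 0) sum(nes >= nes[i], na.rm = TRUE) / den_den else 1
    } else {
      num_den <- sum(pooled < 0)
      num <- if (num_den > 0) sum(pooled <= nes[i]) / num_den else 0
      den_den <- sum(nes < 0, na.rm = TRUE)
      den <- if (den_den > 0) sum(nes <= nes[i], na.rm = TRUE) / den_den else 1
    }
    if (den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  out <- data.frame(
    set_name = names(sets), size = sizes, es = es, nes = nes,
    p_perm = p_perm, fdr = fdr,
    leading_edge = vapply(obs, function(o)
      paste(o$leading_edge, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$p_perm, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pathway carrier and exclusivity summary
#'
#' Counts, over the non-silent mutations falling in a pathway's genes:
#' distinct carrier samples, the carrier frequency (also to one decimal
#' percent), the number of mutations, and the mutual-exclusivity fraction
#' (carrier samples with exactly one mutated pathway gene).
#'
#' @param variants Validated variant `data.frame`.
#' @param pathway Character vector of pathway gene symbols.
#' @param n_samples Total assayed samples.
#' @return List: `n_carriers`, `frequency`, `frequency_pct`,
#'   `n_mutations`, `exclusivity_fraction`.
#' @export
pathway_carrier_summary <- function(variants, pathway, n_samples) {
  validate_variants(variants)
  v <- variants[variants$functional_class %in% NONSILENT_CLASSES &
                  variants$gene_symbol %in% pathway, , drop = FALSE]
  n_obs <- length(unique(variants$sample_id))
  if (n_samples < n_obs)
    stop("n_samples is below the distinct samples observed")
  if (!nrow(v))
    return(list(n_carriers = 0L, frequency = 0, frequency_pct = 0,
                n_mutations = 0L, exclusivity_fraction = NA_real_))
  genes_per_sample <- tapply(v$gene_symbol, v$sample_id,
                             function(g) length(unique(g)))
  n_carriers <- length(genes_per_sample)
  list(n_carriers = n_carriers,
       frequency = n_carriers / n_samples,
       frequency_pct = round(100 * n_carriers / n_samples, 1),
       n_mutations = nrow(v),
       exclusivity_fraction = mean(genes_per_sample == 1L))
}
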