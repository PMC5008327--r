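#' Synthetic cohort specification
#'
#' Describes the statistical structure of a simulated tumor-normal study:
#' cohort size, mutation load, the mutational-signature mixture generating
#' trinucleotide contexts, planted driver genes with per-sample mutation
#' probabilities, the pathogenicity-score distribution of drivers, and
#' per-gene case/control germline carrier frequencies. The defaults mirror
#' a small aggressive-neuroblastoma exome study: 17 tumor-normal pairs, a
#' mean of 17 somatic mutations per sample, and a C>T/C>A signature
#' mixture of 0.532/0.468.
#'
#' @param n_tumor_normal_pairs Number of simulated tumor-normal pairs.
#' @param mean_mutations_per_sample Poisson mean of per-sample mutation
#'   counts (passenger mutations; planted drivers add their own).
#' @param signature_mixture Named non-negative weights summing to 1;
#'   names must match columns of `signature_profiles`.
#' @param signature_profiles 96 x k signature matrix used to draw
#'   trinucleotide context classes.
#' @param driver_genes Named per-sample mutation probabilities for planted
#'   driver genes (may be NULL for none).
#' @param passenger_gene_pool Symbols passenger mutations are drawn from.
#' @param driver_score_beta Two shape parameters; planted driver
#'   CHASM/VEST-style p-values are drawn from this Beta (concentrated near
#'   zero for `c(1, 50)`), passengers from Uniform(0,1).
#' @param case_control_carrier_freqs Named list, one element per gene: a
#'   named vector of per-cohort carrier probabilities (must include every
#'   cohort passed to [simulate_carrier_tables]).
#' @param tumor_vaf_beta Tumor variant-allele-fraction Beta parameters;
#'   the default `c(8, 12)` mimics clonal mutations in tumors of roughly
#'   75% purity.
#' @param mean_depth Mean tumor/normal sequencing depth.
#' @param rng_seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_tumor_normal_pairs = 17L,
                        mean_mutations_per_sample = 17,
                        signature_mixture = c(sig_ct_deamination_like = 0.532,
                                              sig_ca_like = 0.468),
                        signature_profiles = example_signatures(),
                        driver_genes = c(ALK = 0.081, CHD9 = 0.04),
                        passenger_gene_pool = sprintf("GENE%03d", 1:300),
                        driver_score_beta = c(1, 50),
                        case_control_carrier_freqs = default_carrier_freqs(),
                        tumor_vaf_beta = c(8, 12),
                        mean_depth = 110,
                        rng_seed = 1L) {
  spec <- list(n_tumor_normal_pairs = as.integer(n_tumor_normal_pairs),
               mean_mutations_per_sample = mean_mutations_per_sample,
               signature_mixture = signature_mixture,
               signature_profiles = signature_profiles,
               driver_genes = driver_genes,
               passenger_gene_pool = passenger_gene_pool,
               driver_score_beta = driver_score_beta,
               case_control_carrier_freqs = case_control_carrier_freqs,
               tumor_vaf_beta = tumor_vaf_beta,
               mean_depth = mean_depth,
               rng_seed = as.integer(rng_seed))
  if (spec$n_tumor_normal_pairs < 1L) stop("need at least one pair")
  if (spec$mean_mutations_per_sample <= 0) stop("mean mutations must be positive")
  if (!length(spec$signature_mixture)) stop("signature_mixture must be non-empty")
  if (abs(sum(spec$signature_mixture) - 1) > 1e-8)
    stop("signature_mixture weights must sum to 1")
  if (any(spec$signature_mixture < 0)) stop("signature_mixture weights must be >= 0")
  spec$signature_profiles <- validate_signature_matrix(spec$signature_profiles,
                                                       renormalize = TRUE)
  missing_sig <- setdiff(names(spec$signature_mixture),
                         colnames(spec$signature_profiles))
  if (length(missing_sig))
    stop("no profile for signature(s): ", paste(missing_sig, collapse = ", "))
  if (length(spec$driver_genes) &&
      (is.null(names(spec$driver_genes)) ||
       any(spec$driver_genes < 0 | spec$driver_genes > 1)))
    stop("driver_genes must be a named vector of probabilities in [0,1]")
  if (length(spec$driver_score_beta) != 2L || any(spec$driver_score_beta <= 0))
    stop("driver_score_beta must be two positive shapes")
  for (g in names(spec$case_control_carrier_freqs)) {
    f <- spec$case_control_carrier_freqs[[g]]
    if (any(f < 0 | f > 1)) stop("carrier frequencies for ", g, " outside [0,1]")
  }
  class(spec) <- "cohort_spec"
  spec
}

#' Default germline carrier frequencies
#'
#' Six cancer-predisposition genes with a single planted burden gene:
#' BARD1 carries rare variants in ~7.7% of cases versus ~0.3% of controls;
#' the other genes have equal case/control frequencies.
#'
#' @return Named list of per-cohort carrier probability vectors.
#' @export
default_carrier_freqs <- function() {
  flat <- function(p) c(case = p, ita1000g = p, eur1000g = p, house = p)
  list(BARD1 = c(case = 0.077, ita1000g = 0.003, eur1000g = 0.003, house = 0.003),
       CHEK2 = flat(0.01), AXIN2 = flat(0.01), MC1R = flat(0.05),
       APC = flat(0.02), PALB2 = flat(0.01))
}

# Evaluate expr under a temporary RNG state; the caller's RNG is restored.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% 2147483647)
  force(expr)
}

PASSENGER_CLASS_PROBS <- c(missense = 0.55, nonsense = 0.07, splice_site = 0.05,
                           frameshift_indel = 0.06, inframe_indel = 0.02,
                           silent = 0.18, noncoding = 0.07)

#' Simulate somatic variant calls
#'
#' Draws per-sample mutation counts from Poisson(`mean_mutations_per_sample`),
#' assigns functional classes, draws each SNV's trinucleotide context class
#' from the spec's signature mixture (reported on a random strand, so
#' downstream canonicalization is exercised), tumor VAFs from the spec's
#' Beta, and near-zero normal alt counts. Planted driver genes receive an
#' additional missense SNV per sample with their stated probability.
#' Each sample uses an RNG substream derived from the global seed and a
#' stable hash of the sample id, so output is reproducible and independent
#' of sample insertion order.
#'
#' @param spec A [cohort_spec].
#' @return A validated variant `data.frame`.
#' @export
simulate_somatic_variants <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  samples <- sprintf("NB%03d", seq_len(spec$n_tumor_normal_pairs))
  per_sample <- lapply(samples, function(sid) {
    with_seed(spec$rng_seed + stable_hash(sid),
              simulate_one_sample(sid, spec))
  })
  v <- do.call(rbind, per_sample)
  rownames(v) <- NULL
  validate_variants(v)
  v
}

simulate_one_sample <- function(sid, spec) {
  n_pass <- rpois(1L, spec$mean_mutations_per_sample)
  fclass <- if (n_pass) sample(names(PASSENGER_CLASS_PROBS), n_pass,
                               replace = TRUE, prob = PASSENGER_CLASS_PROBS)
            else character(0)
  genes <- if (n_pass) sample(spec$passenger_gene_pool, n_pass, replace = TRUE)
           else character(0)
  # planted drivers: one extra missense SNV with the stated probability
  for (g in names(spec$driver_genes)) {
    if (runif(1) < spec$driver_genes[[g]]) {
      fclass <- c(fclass, "missense")
      genes <- c(genes, g)
    }
  }
  n <- length(fclass)
  if (!n) return(empty_variant_table())

  is_indel <- fclass %in% c("frameshift_indel", "inframe_indel")
  vclass <- ifelse(is_indel,
                   ifelse(runif(n) < 0.5, "insertion", "deletion"),
                   "SNV")
  ref <- alt <- ctx <- rep(NA_character_, n)

  snv <- which(vclass == "SNV")
  if (length(snv)) {
    sig <- sample(names(spec$signature_mixture), length(snv), replace = TRUE,
                  prob = spec$signature_mixture)
    cls_idx <- vapply(sig, function(s)
      sample.int(96L, 1L, prob = spec$signature_profiles[, s]), integer(1))
    parts <- context_from_index(cls_idx)
    flip <- runif(length(snv)) < 0.5
    ref[snv] <- ifelse(flip, unname(COMPLEMENT[parts$ref_allele]), parts$ref_allele)
    alt[snv] <- ifelse(flip, unname(COMPLEMENT[parts$alt_allele]), parts$alt_allele)
    ctx[snv] <- ifelse(flip, revcomp(parts$trinucleotide_context),
                       parts$trinucleotide_context)
  }
  ins <- which(vclass == "insertion")
  ref[ins] <- "A"
  alt[ins] <- vapply(ins, function(i)
    paste0("A", paste(sample(BASES, sample(1:3, 1), replace = TRUE), collapse = "")),
    character(1))
  del <- which(vclass == "deletion")
  alt[del] <- "A"
  ref[del] <- vapply(del, function(i)
    paste0("A", paste(sample(BASES, sample(1:3, 1), replace = TRUE), collapse = "")),
    character(1))

  tumor_depth <- pmax(rpois(n, spec$mean_depth), 20L)
  vaf <- rbeta(n, spec$tumor_vaf_beta[1], spec$tumor_vaf_beta[2])
  tumor_alt <- pmin(pmax(rbinom(n, tumor_depth, vaf), 1L), tumor_depth)
  normal_depth <- pmax(rpois(n, spec$mean_depth), 10L)
  normal_alt <- pmin(rbinom(n, normal_depth, 0.002), normal_depth)

  data.frame(
    sample_id = sid,
    chrom = sample(paste0("chr", 1:22), n, replace = TRUE),
    pos = sample.int(200000000L, n),
    ref_allele = ref, alt_allele = alt,
    variant_class = vclass, functional_class = fclass,
    gene_symbol = genes,
    tumor_depth = tumor_depth, tumor_alt_count = tumor_alt,
    normal_depth = normal_depth, normal_alt_count = normal_alt,
    dbsnp_member = runif(n) < 0.02,
    trinucleotide_context = ctx,
    stringsAsFactors = FALSE
  )
}

empty_variant_table <- function() {
  data.frame(sample_id = character(0), chrom = character(0), pos = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             variant_class = character(0), functional_class = character(0),
             gene_symbol = character(0), tumor_depth = integer(0),
             tumor_alt_count = integer(0), normal_depth = integer(0),
             normal_alt_count = integer(0), dbsnp_member = logical(0),
             trinucleotide_context = character(0), stringsAsFactors = FALSE)
}

#' Simulate per-mutation pathogenicity scores
#'
#' Emulates CHASM-style and VEST-style p-values as consumed by the driver
#' and germline stages: mutations in planted driver genes draw from
#' `Beta(driver_score_beta)` (concentrated near zero), all others from
#' Uniform(0,1). Every non-silent SNV receives both scores; non-silent
#' indels receive a VEST-style score only (CHASM scores missense SNVs).
#'
#' @param variants Validated variant `data.frame` with unique
#'   (sample, locus, alleles) keys.
#' @param spec A [cohort_spec].
#' @return `data.frame` with columns `key`, `gene_symbol`, `chasm_p`,
#'   `vest_p` (NA where a score does not apply).
#' @export
simulate_pathogenicity_scores <- function(variants, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_variants(variants)
  key <- variant_key(variants)
  if (anyDuplicated(key))
    stop("variant keys are not unique: ", key[duplicated(key)][1])
  n <- nrow(variants)
  out <- data.frame(key = key, gene_symbol = variants$gene_symbol,
                    chasm_p = rep(NA_real_, n), vest_p = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  with_seed(spec$rng_seed + stable_hash("pathogenicity-scores"), {
    nonsilent <- variants$functional_class %in% NONSILENT_CLASSES
    is_driver <- variants$gene_symbol %in% names(spec$driver_genes)
    draw <- function(sel) {
      p <- runif(n)
      drv <- sel & is_driver
      p[drv] <- rbeta(sum(drv), spec$driver_score_beta[1], spec$driver_score_beta[2])
      ifelse(sel, p, NA_real_)
    }
    chasm_sel <- nonsilent & variants$variant_class == "SNV"
    out$chasm_p <- draw(chasm_sel)
    out$vest_p <- draw(nonsilent)
  })
  out
}

#' Simulate germline carrier-count tables
#'
#' Draws, for every gene of the spec and every cohort, the number of
#' individuals carrying a qualifying rare variant as
#' Binomial(cohort size, per-cohort carrier frequency); the with/without
#' columns sum to the cohort size by construction.
#'
#' @param spec A [cohort_spec] with `case_control_carrier_freqs`.
#' @param cohort_sizes Named positive integers; names must match the
#'   per-gene frequency vectors (e.g. `case`, `ita1000g`, ...).
#' @return `data.frame`: `gene`, then `<cohort>_with` / `<cohort>_without`
#'   column pairs.
#' @export
simulate_carrier_tables <- function(spec, cohort_sizes) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!length(cohort_sizes) || any(cohort_sizes < 1))
    stop("cohort_sizes must be positive")
  cohort_sizes <- setNames(as.integer(cohort_sizes), names(cohort_sizes))
  genes <- names(spec$case_control_carrier_freqs)
  if (!length(genes)) stop("spec has no case_control_carrier_freqs")
  rows <- lapply(genes, function(g) {
    freqs <- spec$case_control_carrier_freqs[[g]]
    missing_cohort <- setdiff(names(cohort_sizes), names(freqs))
    if (length(missing_cohort))
      stop("gene ", g, " lacks carrier frequency for cohort(s): ",
           paste(missing_cohort, collapse = ", "))
    with_seed(spec$rng_seed + stable_hash(paste0("carriers:", g)), {
      row <- list(gene = g)
      for (co in names(cohort_sizes)) {
        w <- rbinom(1L, cohort_sizes[[co]], freqs[[co]])
        row[[paste0(co, "_with")]] <- w
        row[[paste0(co, "_without")]] <- as.integer(cohort_sizes[[co]] - w)
      }
      as.data.frame(row, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
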