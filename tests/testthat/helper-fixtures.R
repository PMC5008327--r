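# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write.

make_variant <- function(sample_id = "S1", chrom = "chr1", pos = 1000L,
                         ref_allele = "C", alt_allele = "A",
                         variant_class = "SNV", functional_class = "missense",
                         gene_symbol = "GENE1", tumor_depth = 100L,
                         tumor_alt_count = 40L, normal_depth = 100L,
                         normal_alt_count = 0L, dbsnp_member = FALSE,
                         trinucleotide_context = "ACA") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos,
             ref_allele = ref_allele, alt_allele = alt_allele,
             variant_class = variant_class, functional_class = functional_class,
             gene_symbol = gene_symbol, tumor_depth = tumor_depth,
             tumor_alt_count = tumor_alt_count, normal_depth = normal_depth,
             normal_alt_count = normal_alt_count, dbsnp_member = dbsnp_member,
             trinucleotide_context = trinucleotide_context,
             stringsAsFactors = FALSE)
}

# n context-bearing SNVs with valid random fields
random_variants <- function(n, seed = 1, n_samples = 5) {
  set.seed(seed)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  cls <- sample(classes, n, replace = TRUE)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  ctx <- paste0(sample(c("A", "C", "G", "T"), n, TRUE), ref,
                sample(c("A", "C", "G", "T"), n, TRUE))
  td <- sample(30:200, n, TRUE)
  ta <- pmin(td, sample(5:80, n, TRUE))
  nd <- sample(30:200, n, TRUE)
  make_variant(sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n, TRUE),
               chrom = sample(paste0("chr", 1:5), n, TRUE),
               pos = sample.int(1e7, n),
               ref_allele = ref, alt_allele = alt,
               functional_class = sample(nonsilent_classes()[1:3], n, TRUE),
               gene_symbol = sample(sprintf("G%03d", 1:50), n, TRUE),
               tumor_depth = td, tumor_alt_count = ta,
               normal_depth = nd, normal_alt_count = 0L,
               dbsnp_member = FALSE, trinucleotide_context = ctx)
}

variant_keys <- function(v) {
  paste(v$sample_id, v$chrom, v$pos, v$ref_allele, v$alt_allele, sep = ":")
}

# Independent quadratic-time BH step-up, the brute-force oracle:
# q_i = min over order statistics p_(j) >= p_i of m * p_(j) / j, capped at 1
bh_bruteforce <- function(p) {
  m <- length(p)
  sp <- sort(p)
  cand <- m * sp / seq_len(m)
  vapply(p, function(pi) min(1, min(cand[sp >= pi])), numeric(1))
}

# Independent brute-force weighted KS enrichment score: literal walk
es_bruteforce <- function(scores, hit, weight_exponent) {
  N <- length(scores)
  w <- abs(scores)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) w[i] / sum(w) else -1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}
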