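test_that("canonical_context enforces the pyrimidine-strand convention", {
  # G>T in AGC lies on the purine strand; reverse complement is C>A in GCT
  expect_identical(names(canonical_context("G", "T", "AGC")), "G[C>A]T")
  expect_identical(names(canonical_context("C", "T", "GCG")), "G[C>T]G")
  # context reported on the opposite strand of ref is accepted
  expect_identical(canonical_context("G", "T", "GCT"),
                   canonical_context("C", "A", "GCT"))
  expect_error(canonical_context("C", "A", "ANA"), "invalid")
  expect_error(canonical_context("C", "C", "ACA"), "differ")
  expect_error(canonical_context("C", "A", "AAA"), "middle base")
})

test_that("all 192 strand-resolved mutations collapse onto 96 classes, each twice", {
  bases <- c("A", "C", "G", "T")
  hits <- integer(96)
  n_enum <- 0L
  for (ref in bases) for (alt in setdiff(bases, ref))
    for (p5 in bases) for (p3 in bases) {
      idx <- canonical_context(ref, alt, paste0(p5, ref, p3))
      hits[idx] <- hits[idx] + 1L
      n_enum <- n_enum + 1L
    }
  expect_identical(n_enum, 192L)      # 12 substitutions x 16 flank pairs
  expect_true(all(hits == 2L))        # each class hit by exactly two strands
})

test_that("canonical_context composed with reverse complement is the identity", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
  set.seed(5)
  for (i in 1:50) {
    ref <- sample(c("C", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ctx <- paste0(sample(c("A", "C", "G", "T"), 1), ref,
                  sample(c("A", "C", "G", "T"), 1))
    expect_identical(canonical_context(unname(comp[ref]), unname(comp[alt]), rc(ctx)),
                     canonical_context(ref, alt, ctx))
  }
})

test_that("build_spectrum counts SNVs into the right bins", {
  expect_identical(unname(build_spectrum(random_variants(1)[0, ])), integer(96))

  ten <- do.call(rbind, replicate(10, make_variant(ref_allele = "C",
                                                   alt_allele = "T",
                                                   trinucleotide_context = "GCG"),
                                  simplify = FALSE))
  ten$pos <- seq_len(10)
  sp <- build_spectrum(ten)
  expect_identical(sum(sp), 10L)
  expect_identical(unname(sp["G[C>T]G"]), 10L)

  v <- rbind(random_variants(50, seed = 8),
             make_variant(variant_class = "insertion", ref_allele = "A",
                          alt_allele = "AT", functional_class = "frameshift_indel",
                          trinucleotide_context = NA))
  expect_message(sp2 <- build_spectrum(v), "skipped 1 non-SNV")
  expect_identical(sum(sp2), 50L)

  bad <- make_variant(trinucleotide_context = NA)
  expect_error(build_spectrum(bad), "without trinucleotide context")
})

test_that("spectrum of simulated variants matches the simulator's SNV count", {
  spec <- cohort_spec(rng_seed = 21)
  v <- simulate_somatic_variants(spec)
  sp <- suppressMessages(build_spectrum(v))
  expect_identical(sum(sp), sum(v$variant_class == "SNV"))
})

test_that("class_fractions reproduces the published C>A / C>T percentages", {
  # 64 C>A and 84 C>T of 228 substitutions, the inversion of the printed
  # 28.07% / 36.84%
  sp <- setNames(integer(96), context_labels())
  sp["A[C>A]A"] <- 64L
  sp["A[C>T]A"] <- 84L
  sp["A[T>C]A"] <- 80L
  fr <- class_fractions(sp)
  expect_equal(round(100 * unname(fr["C>A"]), 2), 28.07)
  expect_equal(round(100 * unname(fr["C>T"]), 2), 36.84)
  expect_equal(sum(fr), 1)
})

test_that("class_fractions is scale invariant, uniform on uniform input", {
  u <- setNames(rep(3L, 96), context_labels())
  expect_equal(unname(class_fractions(u)), rep(1 / 6, 6))
  set.seed(9)
  sp <- setNames(rpois(96, 10), context_labels())
  expect_equal(class_fractions(sp), class_fractions(sp * 7L))
  one <- setNames(integer(96), context_labels()); one[40] <- 5L
  expect_equal(unname(class_fractions(one)["C>T"]), 1)
  expect_error(class_fractions(one * 0L), "empty")
})

test_that("cosine_similarity matches a direct dot-product oracle", {
  expect_equal(cosine_similarity(rep(1, 96), rep(1, 96)), 1)
  a <- c(rep(1, 48), rep(0, 48)); b <- c(rep(0, 48), rep(1, 48))
  expect_equal(cosine_similarity(a, b), 0)
  set.seed(10)
  for (i in 1:20) {
    x <- runif(96); y <- runif(96)
    fx <- x / sum(x); fy <- y / sum(y)
    oracle <- sum(fx * fy) / (sqrt(sum(fx^2)) * sqrt(sum(fy^2)))
    expect_equal(cosine_similarity(x, y), oracle, tolerance = 1e-12)
  }
  expect_error(cosine_similarity(rep(0, 96), rep(1, 96)), "zero")
})

test_that("decomposition is exact on a pure reference spectrum", {
  refs <- example_signatures()
  sp <- round(refs[, 1] * 1e6)
  d <- decompose_signatures(sp, refs)
  expect_equal(unname(d$weights), c(1, 0), tolerance = 1e-4)
  expect_lt(d$residual_norm, 1e-4)
})

test_that("decomposition recovers a planted 60/40 mixture from 50,000 draws", {
  refs <- example_signatures()
  set.seed(31)
  draws <- sample.int(96, 50000, replace = TRUE,
                      prob = 0.6 * refs[, 1] + 0.4 * refs[, 2])
  sp <- tabulate(draws, 96)
  names(sp) <- context_labels()
  d <- decompose_signatures(sp, refs)
  expect_equal(unname(d$weights[1]), 0.6, tolerance = 0.02)
  expect_equal(unname(d$weights[2]), 0.4, tolerance = 0.02)
})

test_that("two-signature decomposition agrees with a simplex grid search", {
  refs <- example_signatures()
  set.seed(32)
  for (i in 1:3) {
    w_true <- runif(1)
    f <- w_true * refs[, 1] + (1 - w_true) * refs[, 2] + abs(rnorm(96, 0, 1e-3))
    sp <- f / sum(f)
    d <- decompose_signatures(sp * 1e6, refs)
    # brute force over the 1-simplex at step 1e-3, scaled mixtures s*(w, 1-w)
    grid <- seq(0, 1, by = 1e-3)
    obj <- vapply(grid, function(w) {
      p <- w * refs[, 1] + (1 - w) * refs[, 2]
      s <- sum(p * sp / sum(sp)) / sum(p * p)  # optimal non-negative scale
      sqrt(sum((sp / sum(sp) - max(s, 0) * p)^2))
    }, numeric(1))
    w_grid <- grid[which.min(obj)]
    expect_lt(abs(unname(d$weights[1]) - w_grid), 1e-3)  # within one grid step
    expect_lte(d$residual_norm, min(obj) + 1e-9)
  }
})

test_that("decomposition residual never exceeds any single-signature fit", {
  refs <- example_signatures()
  set.seed(33)
  sp <- setNames(rpois(96, 20) + 1, context_labels())
  d <- decompose_signatures(sp, refs)
  f <- as.numeric(sp) / sum(sp)
  for (k in seq_len(ncol(refs))) {
    vertex <- sqrt(sum((f - refs[, k])^2))
    expect_lte(d$residual_norm, vertex + 1e-12)
  }
})
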