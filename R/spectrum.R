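#' Build a 96-context mutation spectrum
#'
#' Counts the single-nucleotide variants of a variant table into the 96
#' canonical trinucleotide context classes. Insertions and deletions carry
#' no substitution context and are skipped with a message; an SNV without
#' a context is an error (the offending rows are listed), since a silent
#' drop would bias the spectrum.
#'
#' @param variants Validated variant `data.frame`.
#' @return Named integer vector of length 96 (canonical context order).
#' @export
build_spectrum <- function(variants) {
  validate_variants(variants)
  spec <- setNames(integer(96), context_labels())
  if (!nrow(variants)) return(spec)
  snv <- variants$variant_class == "SNV"
  n_skipped <- sum(!snv)
  if (n_skipped)
    message("build_spectrum: skipped ", n_skipped, " non-SNV variant(s)")
  v <- variants[snv, , drop = FALSE]
  if (!nrow(v)) return(spec)
  missing_ctx <- is.na(v$trinucleotide_context)
  if (any(missing_ctx))
    stop("SNV(s) without trinucleotide context at row(s): ",
         paste(utils::head(which(snv)[missing_ctx], 10), collapse = ", "))
  idx <- canonical_context(v$ref_allele, v$alt_allele, v$trinucleotide_context)
  counts <- tabulate(idx, nbins = 96L)
  spec + counts
}

#' Fractions of the six substitution classes
#'
#' Collapses a 96-context spectrum to the six pyrimidine-reference
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) and returns each
#' class total as a fraction of all counted substitutions.
#'
#' @param spectrum Named 96-vector as returned by [build_spectrum].
#' @return Named numeric vector of 6 fractions summing to 1.
#' @export
class_fractions <- function(spectrum) {
  stopifnot(length(spectrum) == 96L)
  total <- sum(spectrum)
  if (total <= 0) stop("spectrum is empty; class fractions are undefined")
  cls <- rep(SUBSTITUTION_CLASSES, each = 16L)
  totals <- tapply(as.numeric(spectrum), factor(cls, levels = SUBSTITUTION_CLASSES), sum)
  setNames(as.numeric(totals), SUBSTITUTION_CLASSES) / total
}

#' Cosine similarity between two spectra
#'
#' Spectra are frequency-normalized before the standard cosine, so the
#' statistic compares mutational profiles independently of mutation load.
#'
#' @param a,b 96-vectors of non-negative counts or frequencies.
#' @return Similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (sum(a) <= 0 || sum(b) <= 0) stop("cosine similarity of a zero spectrum")
  fa <- a / sum(a); fb <- b / sum(b)
  sum(fa * fb) / sqrt(sum(fa^2) * sum(fb^2))
}

#' Decompose a spectrum onto reference signatures
#'
#' Fits non-negative exposure weights `w` minimizing `||f - P w||_2`,
#' where `f` is the frequency-normalized observed spectrum and `P` the
#' 96 x k reference profile matrix, by non-negative least squares.
#' Weights are reported renormalized to sum to 1 (the percentage
#' contribution of each signature); `residual_norm` is the minimized
#' Euclidean norm of the unnormalized fit.
#'
#' @param spectrum Named 96-vector of counts with positive total.
#' @param refs 96 x k signature matrix (see [read_signature_matrix]).
#' @return List with `weights` (named, sums to 1), `raw_weights` (the
#'   NNLS solution before renormalization) and `residual_norm`.
#' @export
decompose_signatures <- function(spectrum, refs) {
  stopifnot(length(spectrum) == 96L)
  refs <- validate_signature_matrix(refs, renormalize = TRUE)
  if (sum(spectrum) <= 0) stop("cannot decompose an empty spectrum")
  if (any(colSums(refs) == 0)) stop("all-zero reference profile")
  f <- as.numeric(spectrum) / sum(spectrum)
  fit <- pracma::lsqnonneg(refs, f)
  w <- fit$x
  names(w) <- colnames(refs)
  if (sum(w) <= 0) stop("degenerate decomposition: all exposures zero")
  list(weights = w / sum(w),
       raw_weights = w,
       residual_norm = sqrt(sum((f - as.numeric(refs %*% w))^2)))
}

#' Built-in synthetic reference signatures
#'
#' Two deterministic, fully synthetic 96-context profiles that emulate the
#' two processes dominating the neuroblastoma somatic spectrum: an
#' age-related C>T deamination-like profile peaked at NpCpG trinucleotides
#' (`sig_ct_deamination_like`) and a broad C>A profile with extra mass at
#' TpCpT (`sig_ca_like`). They are stand-ins for published signature
#' vectors -- useful for simulation and testing -- not reproductions of
#' any published matrix.
#'
#' @return A 96 x 2 signature matrix.
#' @export
example_signatures <- function() {
  labs <- context_labels()
  p5 <- substr(labs, 1, 1)
  cls <- substr(labs, 3, 5)
  p3 <- substr(labs, 7, 7)

  ct <- numeric(96)
  ct[cls == "C>T"] <- 1
  ct[cls == "C>T" & p3 == "G"] <- 8          # NpCpG deamination peak
  ct <- ct + 0.02                            # faint uniform background

  ca <- numeric(96)
  ca[cls == "C>A"] <- 1
  ca[cls == "C>A" & p5 == "T" & p3 == "T"] <- 5   # TpCpT emphasis
  ca <- ca + 0.02

  m <- cbind(sig_ct_deamination_like = ct / sum(ct),
             sig_ca_like = ca / sum(ca))
  rownames(m) <- labs
  m
}
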