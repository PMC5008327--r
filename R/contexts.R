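#' Trinucleotide mutation context machinery
#'
#' Somatic single-nucleotide variants are classified into 96 classes
#' defined by the substitution type and the bases immediately 5' and 3'
#' of the mutated position. Substitutions are always expressed with a
#' pyrimidine (C or T) reference base: a mutation reported on the purine
#' strand is reverse-complemented first, so `G>T` in context `AGC`
#' becomes `C>A` in context `GCT`, i.e. class `G[C>A]T`.
#'
#' @name contexts
NULL

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Canonical 96-context labels
#'
#' Labels in COSMIC style (`"A[C>A]A"`), ordered substitution class major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base (A,C,G,T), then 3' base
#' (A,C,G,T).
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(context_labels())
context_labels <- function() {
  labs <- character(96)
  i <- 1L
  for (cls in SUBSTITUTION_CLASSES) for (p5 in BASES) for (p3 in BASES) {
    labs[i] <- paste0(p5, "[", cls, "]", p3)
    i <- i + 1L
  }
  labs
}

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) paste(rev(unname(COMPLEMENT[b])), collapse = ""),
         character(1))
}

#' Map a mutation to its canonical 96-class index
#'
#' Classifies single-base substitutions into the 96 trinucleotide context
#' classes. Purine-reference mutations (ref A or G) are reverse-complemented
#' onto the pyrimidine strand, so exactly 96 classes cover all 192
#' strand-resolved possibilities, each hit by two strand representations.
#'
#' @param ref,alt Single reference/alternate bases (vectorized).
#' @param context 3-letter context with the reference base (or its
#'   complement) in the middle position.
#' @return Integer vector of class indices in 1..96, named with the
#'   canonical context label.
#' @export
#' @examples
#' canonical_context("G", "T", "AGC")  # -> class "G[C>A]T"
#' canonical_context("C", "T", "GCG")  # -> class "G[C>T]G"
canonical_context <- function(ref, alt, context) {
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  context <- rep_len(toupper(context), n)

  bad_len <- nchar(context) != 3L | grepl("[^ACGT]", context)
  if (any(bad_len))
    stop("invalid trinucleotide context(s): ",
         paste(unique(context[bad_len]), collapse = ", "))
  if (any(ref == alt))
    stop("ref and alt allele must differ")
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref and alt must be single bases in {A,C,G,T}")

  # The context may be reported on either strand: its middle base must be
  # the ref base or its complement. In the latter case re-express ref/alt
  # on the context's strand before canonicalizing.
  mid <- substr(context, 2, 2)
  opp <- mid != ref & mid == unname(COMPLEMENT[ref])
  if (any(opp)) {
    ref[opp] <- unname(COMPLEMENT[ref[opp]])
    alt[opp] <- unname(COMPLEMENT[alt[opp]])
  }
  if (any(mid != ref))
    stop("context middle base must equal the reference base or its complement; offending: ",
         paste(unique(context[mid != ref]), collapse = ", "))

  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    context[flip] <- revcomp(context[flip])
    ref[flip] <- unname(COMPLEMENT[ref[flip]])
    alt[flip] <- unname(COMPLEMENT[alt[flip]])
  }

  cls <- match(paste0(ref, ">", alt), SUBSTITUTION_CLASSES)
  p5 <- match(substr(context, 1, 1), BASES)
  p3 <- match(substr(context, 3, 3), BASES)
  idx <- (cls - 1L) * 16L + (p5 - 1L) * 4L + p3
  names(idx) <- context_labels()[idx]
  idx
}

# Decompose a canonical class index back into (ref, alt, context) on the
# pyrimidine strand. Inverse of canonical_context for pyrimidine input.
context_from_index <- function(idx) {
  stopifnot(all(idx >= 1L & idx <= 96L))
  cls <- SUBSTITUTION_CLASSES[(idx - 1L) %/% 16L + 1L]
  rem <- (idx - 1L) %% 16L
  p5 <- BASES[rem %/% 4L + 1L]
  p3 <- BASES[rem %% 4L + 1L]
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  data.frame(ref_allele = ref, alt_allele = alt,
             trinucleotide_context = paste0(p5, ref, p3),
             stringsAsFactors = FALSE)
}
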