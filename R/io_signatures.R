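#' Read a reference signature matrix
#'
#' Long-form TSV: a `context` column with the 96 COSMIC-style labels
#' (`"A[C>A]A"`, in any row order) plus one column per signature holding
#' non-negative probabilities. Rows are re-ordered to the canonical
#' context order (see [context_labels]); each profile must sum to 1
#' within 1e-3 and is renormalized exactly.
#'
#' @param path TSV file.
#' @return Numeric 96 x k matrix; rownames are context labels, colnames
#'   the signature names.
#' @export
read_signature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  if (!"context" %in% names(d))
    stop("signature TSV must have a 'context' column")
  labs <- context_labels()
  missing_ctx <- setdiff(labs, d$context)
  if (length(missing_ctx))
    stop("signature TSV is missing context(s): ",
         paste(utils::head(missing_ctx, 5), collapse = ", "))
  dup <- unique(d$context[duplicated(d$context)])
  if (length(dup))
    stop("duplicate context label(s): ", paste(utils::head(dup, 5), collapse = ", "))
  extra <- setdiff(d$context, labs)
  if (length(extra))
    stop("unknown context label(s): ", paste(utils::head(extra, 5), collapse = ", "))
  sig_cols <- setdiff(names(d), "context")
  if (!length(sig_cols)) stop("signature TSV has no signature columns")
  m <- as.matrix(d[match(labs, d$context), sig_cols, drop = FALSE])
  rownames(m) <- labs
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0))
    stop("signature profiles must be non-negative and complete")
  validate_signature_matrix(m, renormalize = TRUE)
}

#' Validate (and optionally renormalize) a signature matrix
#'
#' @param m Numeric 96 x k matrix, rownames = canonical context labels.
#' @param renormalize Rescale each column to sum exactly to 1 when its sum
#'   lies within `[0.999, 1.001]`; sums outside that band are an error.
#' @return The validated matrix.
#' @export
validate_signature_matrix <- function(m, renormalize = FALSE) {
  if (!is.matrix(m) || nrow(m) != 96L)
    stop("signature matrix must have exactly 96 rows")
  if (!identical(rownames(m), context_labels()))
    stop("signature matrix rows must be in canonical context order")
  if (any(m < 0)) stop("signature profiles must be non-negative")
  s <- colSums(m)
  if (renormalize) {
    off <- s < 0.999 | s > 1.001
    if (any(off))
      stop("signature profile(s) ", paste(colnames(m)[off], collapse = ", "),
           " sum outside [0.999, 1.001]")
    m <- sweep(m, 2, s, "/")
  } else if (any(abs(s - 1) > 1e-8)) {
    stop("signature profile(s) ",
         paste(colnames(m)[abs(s - 1) > 1e-8], collapse = ", "),
         " do not sum to 1")
  }
  m
}

#' Write a signature matrix as long-form TSV
#'
#' @param m Numeric 96 x k signature matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signature_matrix <- function(m, path) {
  validate_signature_matrix(m, renormalize = TRUE)
  d <- data.frame(context = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
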