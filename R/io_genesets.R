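#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: one set per line, fields are set name,
#' description, then member symbols. Duplicate member symbols within a set
#' are de-duplicated with a warning; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return Named list of character vectors of gene symbols; the
#'   description is kept in the `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate member symbol(s) in gene set ", f[[1]],
              "; de-duplicated", call. = FALSE)
      genes <- unique(genes)
    }
    structure(genes, description = f[[2]])
  })
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (as returned by [read_gmt]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named")
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
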