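#' Variant tables
#'
#' The canonical in-memory representation of variant calls is a plain
#' `data.frame` with one row per called variant and the 14 columns below
#' (the same schema as the MAF-like TSV on disk):
#'
#' \describe{
#'   \item{sample_id}{tumor sample identifier}
#'   \item{chrom, pos}{1-based, fully closed coordinates (VCF convention)}
#'   \item{ref_allele, alt_allele}{alleles as annotated; no left-alignment
#'     is performed}
#'   \item{variant_class}{`SNV`, `insertion` or `deletion`}
#'   \item{functional_class}{`missense`, `nonsense`, `splice_site`,
#'     `frameshift_indel`, `inframe_indel`, `silent` or `noncoding`}
#'   \item{gene_symbol}{HGNC-style symbol}
#'   \item{tumor_depth, tumor_alt_count, normal_depth, normal_alt_count}{
#'     read support in the tumor and matched normal}
#'   \item{dbsnp_member}{logical; TRUE when the site is a known dbSNP
#'     polymorphism (carried as an input flag, never looked up live)}
#'   \item{trinucleotide_context}{optional 3-letter context with the
#'     reference base, or its complement, in the middle (NA allowed)}
#' }
#'
#' @name variant_table
NULL

VARIANT_COLUMNS <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                     "variant_class", "functional_class", "gene_symbol",
                     "tumor_depth", "tumor_alt_count",
                     "normal_depth", "normal_alt_count",
                     "dbsnp_member", "trinucleotide_context")

#' Validate a variant table
#'
#' Checks the schema and per-row invariants of the canonical variant
#' representation: allele-count bounds (0 <= alt count <= depth), distinct
#' single-base alleles for SNVs, and context consistency (middle base equal
#' to the reference base or its complement). Errors name the first
#' offending rows and the violated field.
#'
#' @param variants A variant `data.frame`.
#' @return The validated `data.frame`, invisibly unchanged.
#' @export
validate_variants <- function(variants) {
  if (!is.data.frame(variants))
    stop("variants must be a data.frame")
  missing_cols <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_cols))
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(variants) == 0L) return(invisible(variants))

  fail <- function(rows, field, msg) {
    if (any(rows))
      stop("invalid variant row(s) ", paste(utils::head(which(rows), 5), collapse = ", "),
           " [", field, "]: ", msg)
  }
  v <- variants
  fail(!v$variant_class %in% VARIANT_CLASSES, "variant_class",
       "must be one of SNV, insertion, deletion")
  fail(!v$functional_class %in% FUNCTIONAL_CLASSES, "functional_class",
       paste("must be one of", paste(FUNCTIONAL_CLASSES, collapse = ", ")))
  fail(v$pos < 1 | v$pos != round(v$pos), "pos", "must be a positive integer")
  fail(v$tumor_alt_count < 0 | v$tumor_alt_count > v$tumor_depth,
       "tumor_alt_count", "must satisfy 0 <= alt count <= depth")
  fail(v$normal_alt_count < 0 | v$normal_alt_count > v$normal_depth,
       "normal_alt_count", "must satisfy 0 <= alt count <= depth")
  fail(v$ref_allele == v$alt_allele, "alt_allele", "ref and alt must differ")
  snv <- v$variant_class == "SNV"
  fail(snv & (nchar(v$ref_allele) != 1L | nchar(v$alt_allele) != 1L),
       "ref_allele", "SNV alleles must have length 1")
  fail(!is.logical(v$dbsnp_member) | is.na(v$dbsnp_member), "dbsnp_member",
       "must be TRUE or FALSE")

  has_ctx <- !is.na(v$trinucleotide_context)
  if (any(has_ctx)) {
    ctx <- v$trinucleotide_context[has_ctx]
    bad <- nchar(ctx) != 3L | grepl("[^ACGT]", ctx)
    mid <- substr(ctx, 2, 2)
    ref <- v$ref_allele[has_ctx]
    ok_mid <- nchar(ref) == 1L & (mid == ref | mid == unname(COMPLEMENT[ref]))
    bad <- bad | !ok_mid
    idx <- logical(nrow(v)); idx[which(has_ctx)[bad]] <- TRUE
    fail(idx, "trinucleotide_context",
         "must be 3 bases over ACGT with ref (or its complement) in the middle")
  }
  invisible(variants)
}

#' Read a variant table
#'
#' Reads called variants from either the package's 14-column MAF-like TSV
#' or a VCF 4.x file with a tumor and a normal genotype column, returning
#' the canonical variant `data.frame` (see [variant_table]) with row order
#' preserved. All records are validated; a malformed row aborts with its
#' line number and the violated field.
#'
#' @param path Input file.
#' @param dialect `"maf_tsv"` (default) or `"vcf"`.
#' @param tumor_sample,normal_sample Genotype column names, required for
#'   the VCF dialect. Depths are taken from the per-sample DP and AD
#'   fields.
#' @return A validated variant `data.frame`.
#' @export
read_variant_table <- function(path, dialect = c("maf_tsv", "vcf"),
                               tumor_sample = NULL, normal_sample = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  v <- switch(dialect,
              maf_tsv = read_maf_tsv(path),
              vcf = read_vcf_pair(path, tumor_sample, normal_sample))
  validate_variants(v)
  v
}

read_maf_tsv <- function(path) {
  v <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character", na.strings = c("NA", ""))
  missing_cols <- setdiff(VARIANT_COLUMNS, names(v))
  if (length(missing_cols))
    stop("MAF-like TSV ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  v <- v[, VARIANT_COLUMNS, drop = FALSE]
  for (col in c("pos", "tumor_depth", "tumor_alt_count",
                "normal_depth", "normal_alt_count")) {
    x <- suppressWarnings(as.integer(v[[col]]))
    if (nrow(v) && any(is.na(x) != is.na(v[[col]])))
      stop("non-integer value in column ", col, " at line ",
           which(is.na(x) & !is.na(v[[col]]))[1] + 1L, " of ", path)
    v[[col]] <- x
  }
  v$dbsnp_member <- v$dbsnp_member %in% c("TRUE", "true", "T", "1")
  rownames(v) <- NULL
  v
}

#' Write a variant table as MAF-like TSV
#'
#' @param variants Validated variant `data.frame`.
#' @param path Output file (UTF-8, LF line endings).
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  validate_variants(variants)
  write.table(variants[, VARIANT_COLUMNS, drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# VCF reading is delegated to vcfR; tumor/normal depths come from the two
# named genotype columns' DP and AD fields. Functional annotation columns
# are taken from the INFO keys GENE, FCLASS, VCLASS, DBSNP, CTX when
# present (the package's own writers do not emit VCF).
read_vcf_pair <- function(path, tumor_sample, normal_sample) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  if (is.null(tumor_sample) || is.null(normal_sample))
    stop("VCF dialect requires tumor_sample and normal_sample names")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  smp <- colnames(vcf@gt)[-1]
  for (s in c(tumor_sample, normal_sample))
    if (!s %in% smp) stop("sample ", s, " not present in ", path)

  fix <- vcf@fix  # always a matrix, unlike getFIX() on a single record
  as_mat <- function(x) if (is.matrix(x)) x else t(x)
  dp <- as_mat(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  ad <- as_mat(vcfR::extract.gt(vcf, element = "AD"))
  colnames(dp) <- colnames(ad) <- smp
  alt_from_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",")
    vapply(parts, function(p) suppressWarnings(as.integer(p[2])), integer(1))
  }
  info_field <- function(key, default = NA_character_) {
    val <- vcfR::extract.info(vcf, element = key)
    if (is.null(val)) rep(default, nrow(fix)) else val
  }
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  vclass <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV",
                   ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
  vc_in <- info_field("VCLASS"); vclass[!is.na(vc_in)] <- vc_in[!is.na(vc_in)]
  fclass <- info_field("FCLASS", "noncoding")
  fclass[is.na(fclass)] <- "noncoding"
  data.frame(
    sample_id = tumor_sample,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref_allele = ref,
    alt_allele = alt,
    variant_class = vclass,
    functional_class = fclass,
    gene_symbol = info_field("GENE"),
    tumor_depth = as.integer(dp[, tumor_sample]),
    tumor_alt_count = alt_from_ad(ad[, tumor_sample]),
    normal_depth = as.integer(dp[, normal_sample]),
    normal_alt_count = alt_from_ad(ad[, normal_sample]),
    dbsnp_member = !is.na(info_field("DBSNP")) &
      info_field("DBSNP") %in% c("1", "TRUE", "true"),
    trinucleotide_context = info_field("CTX"),
    stringsAsFactors = FALSE
  )
}
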