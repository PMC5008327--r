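#' Somatic filter configuration
#'
#' Thresholds for the post-calling filter cascade that reduces raw
#' tumor-normal calls to a high-confidence set of functionally relevant
#' somatic changes. Defaults approximate common VarScan2-era practice:
#' tumor depth >= 14, normal depth >= 8, >= 4 tumor alt reads, tumor
#' VAF >= 0.10, normal VAF <= 0.05, dbSNP sites excluded, and only
#' non-silent functional classes retained.
#'
#' @param min_tumor_depth,min_normal_depth Minimum read depths (>= 1).
#' @param min_tumor_alt_reads Minimum alt-supporting tumor reads.
#' @param min_tumor_vaf Minimum tumor variant allele fraction.
#' @param max_normal_vaf Maximum normal variant allele fraction; must be
#'   strictly below `min_tumor_vaf`.
#' @param exclude_dbsnp Drop variants flagged as dbSNP members.
#' @param retained_functional_classes Functional classes kept.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_tumor_depth = 14L,
                          min_normal_depth = 8L,
                          min_tumor_alt_reads = 4L,
                          min_tumor_vaf = 0.10,
                          max_normal_vaf = 0.05,
                          exclude_dbsnp = TRUE,
                          retained_functional_classes = nonsilent_classes()) {
  cfg <- list(min_tumor_depth = as.integer(min_tumor_depth),
              min_normal_depth = as.integer(min_normal_depth),
              min_tumor_alt_reads = as.integer(min_tumor_alt_reads),
              min_tumor_vaf = min_tumor_vaf,
              max_normal_vaf = max_normal_vaf,
              exclude_dbsnp = isTRUE(exclude_dbsnp),
              retained_functional_classes = retained_functional_classes)
  if (cfg$min_tumor_depth < 1L || cfg$min_normal_depth < 1L)
    stop("depth thresholds must be >= 1")
  if (cfg$min_tumor_alt_reads < 0L)
    stop("min_tumor_alt_reads must be >= 0")
  if (!(cfg$max_normal_vaf >= 0 && cfg$max_normal_vaf < cfg$min_tumor_vaf &&
        cfg$min_tumor_vaf <= 1))
    stop("need 0 <= max_normal_vaf < min_tumor_vaf <= 1")
  bad <- setdiff(cfg$retained_functional_classes, FUNCTIONAL_CLASSES)
  if (length(bad)) stop("unknown functional class(es): ", paste(bad, collapse = ", "))
  class(cfg) <- "filter_config"
  cfg
}

# Fixed rule order; each rejected call is attributed to its FIRST failed
# rule so audits are reproducible.
FILTER_RULES <- c("depth", "alt_reads", "tumor_vaf", "normal_vaf",
                  "dbsnp", "functional_class")

#' Filter somatic variant calls
#'
#' Applies the filter cascade in a fixed rule order (depth, alt reads,
#' tumor VAF, normal VAF, dbSNP, functional class). A call is retained iff
#' it passes every rule; the audit attributes each rejected call to the
#' first rule it failed, so the audit counts sum to the number rejected.
#'
#' @param calls Validated variant `data.frame`.
#' @param config A [filter_config].
#' @return List with `retained` (variant `data.frame`) and `audit`
#'   (named integer vector over the six rules).
#' @export
filter_somatic_variants <- function(calls, config = filter_config()) {
  if (!inherits(config, "filter_config"))
    config <- do.call(filter_config, config)
  validate_variants(calls)
  audit <- setNames(integer(length(FILTER_RULES)), FILTER_RULES)
  if (!nrow(calls)) return(list(retained = calls, audit = audit))

  tvaf <- ifelse(calls$tumor_depth > 0, calls$tumor_alt_count / calls$tumor_depth, 0)
  nvaf <- ifelse(calls$normal_depth > 0, calls$normal_alt_count / calls$normal_depth, 0)
  fails <- cbind(
    depth = calls$tumor_depth < config$min_tumor_depth |
      calls$normal_depth < config$min_normal_depth,
    alt_reads = calls$tumor_alt_count < config$min_tumor_alt_reads,
    tumor_vaf = tvaf < config$min_tumor_vaf,
    normal_vaf = nvaf > config$max_normal_vaf,
    dbsnp = config$exclude_dbsnp & calls$dbsnp_member,
    functional_class = !calls$functional_class %in% config$retained_functional_classes
  )
  first_fail <- apply(fails, 1L, function(f) which(f)[1])
  rejected <- !is.na(first_fail)
  tab <- table(factor(FILTER_RULES[first_fail[rejected]], levels = FILTER_RULES))
  audit[] <- as.integer(tab)
  retained <- calls[!rejected, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, audit = audit)
}

#' Classify a sample into its clinical subgroup
#'
#' Maps risk group and outcome to the analysis subgroups. `hr_event3` is
#' the clinically aggressive subgroup: high-risk patients with any adverse
#' event (tumor progression, relapse or death) within 36 months of
#' diagnosis, boundary inclusive. All other samples map directly to their
#' risk group.
#'
#' @param meta A `data.frame` with columns `sample_id`, `risk_group`
#'   (`low`/`intermediate`/`high`), `adverse_event` (logical) and
#'   `months_to_event` (non-negative, present iff `adverse_event`).
#' @return Character vector (`low_risk`, `intermediate_risk`, `high_risk`
#'   or `hr_event3`), one per row.
#' @export
classify_subgroup <- function(meta) {
  stopifnot(all(c("sample_id", "risk_group", "adverse_event",
                  "months_to_event") %in% names(meta)))
  if (any(!meta$risk_group %in% c("low", "intermediate", "high")))
    stop("risk_group must be low, intermediate or high")
  bad <- meta$adverse_event != !is.na(meta$months_to_event)
  if (any(bad))
    stop("months_to_event must be present iff adverse_event; sample(s): ",
         paste(meta$sample_id[bad], collapse = ", "))
  if (any(meta$months_to_event < 0, na.rm = TRUE))
    stop("months_to_event must be non-negative")
  out <- paste0(meta$risk_group, "_risk")
  hr3 <- meta$risk_group == "high" & meta$adverse_event &
    !is.na(meta$months_to_event) & meta$months_to_event <= 36
  out[hr3] <- "hr_event3"
  out
}

#' Per-sample non-silent mutation counts
#'
#' Counts non-silent variants per sample and the cohort median. The median
#' is the lower median for an even number of samples, so it is always an
#' attained count.
#'
#' @param retained Variant `data.frame` (typically the output of
#'   [filter_somatic_variants]).
#' @return List with `per_sample` (`data.frame`: sample_id, n_nonsilent)
#'   and `median_nonsilent`.
#' @export
per_sample_summary <- function(retained) {
  validate_variants(retained)
  if (!nrow(retained)) stop("no retained variants to summarize")
  ns <- retained[retained$functional_class %in% NONSILENT_CLASSES, , drop = FALSE]
  counts <- table(factor(ns$sample_id, levels = sort(unique(retained$sample_id))))
  per_sample <- data.frame(sample_id = names(counts),
                           n_nonsilent = as.integer(counts),
                           stringsAsFactors = FALSE)
  x <- sort(per_sample$n_nonsilent)
  med <- x[ceiling(length(x) / 2)]  # lower median
  list(per_sample = per_sample, median_nonsilent = med)
}
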