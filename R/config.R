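#' Filter configuration
#'
#' Builds the configuration object holding every numeric threshold used by
#' the triage cascade. Defaults encode the screening rules of the targeted
#' PID-panel approach: calls at read depth <= 2 or Phred quality <= 20 are
#' removed; a heterozygous (monoallelic-hypothesis) variant is excluded when
#' its population allele frequency exceeds 0.01%, a biallelic-hypothesis
#' variant when it exceeds 1%; CADD-scaled scores of 20 and 30 mark the top
#' 1% and top 0.1% of reference SNVs for cohort summaries.
#'
#' @param het_af_max Maximum population allele frequency tolerated under a
#'   monoallelic hypothesis (default `1e-4`, i.e. 0.01%).
#' @param biallelic_af_max Maximum allele frequency under a biallelic
#'   hypothesis (default `1e-2`, i.e. 1%).
#' @param min_depth_exclusive Read depth at or below which a call is removed
#'   (default 2).
#' @param min_gq_exclusive Phred-scaled genotype/site quality at or below
#'   which a call is removed (default 20).
#' @param cadd_benign_scaled CADD-scaled threshold for "top 1%" summary
#'   fractions (default 20). Not a filter.
#' @param cadd_strong_scaled CADD-scaled threshold for "top 0.1%" summary
#'   fractions (default 30). Not a filter.
#' @param msc_override_enabled When `TRUE` (default) a variant whose CADD
#'   score falls below the gene-specific mutation significance cutoff (MSC)
#'   still passes the gate if the patient's phenotype matches the gene,
#'   mirroring how biallelic LRBA variants were retained on phenotype
#'   grounds despite sub-MSC CADD scores.
#' @param quality_connective `"either"` (default) removes a call when depth
#'   *or* quality is at/below its cutoff; `"both"` requires both conditions.
#'
#' @return A named list of class `triage_config`.
#' @examples
#' cfg <- triage_config()
#' cfg$het_af_max
#' @export
triage_config <- function(het_af_max = 1e-4,
                          biallelic_af_max = 1e-2,
                          min_depth_exclusive = 2,
                          min_gq_exclusive = 20,
                          cadd_benign_scaled = 20,
                          cadd_strong_scaled = 30,
                          msc_override_enabled = TRUE,
                          quality_connective = c("either", "both")) {
  quality_connective <- match.arg(quality_connective)
  cfg <- list(
    het_af_max = as.numeric(het_af_max),
    biallelic_af_max = as.numeric(biallelic_af_max),
    min_depth_exclusive = as.numeric(min_depth_exclusive),
    min_gq_exclusive = as.numeric(min_gq_exclusive),
    cadd_benign_scaled = as.numeric(cadd_benign_scaled),
    cadd_strong_scaled = as.numeric(cadd_strong_scaled),
    msc_override_enabled = isTRUE(msc_override_enabled),
    quality_connective = quality_connective
  )
  num <- unlist(cfg[c("het_af_max", "biallelic_af_max", "min_depth_exclusive",
                      "min_gq_exclusive", "cadd_benign_scaled",
                      "cadd_strong_scaled")])
  if (any(!is.finite(num))) {
    stop("all triage_config thresholds must be finite", call. = FALSE)
  }
  if (!(cfg$het_af_max > 0 && cfg$het_af_max <= cfg$biallelic_af_max &&
        cfg$biallelic_af_max <= 1)) {
    stop("need 0 < het_af_max <= biallelic_af_max <= 1", call. = FALSE)
  }
  structure(cfg, class = "triage_config")
}

#' Read a filter configuration from YAML
#'
#' The YAML keys mirror the arguments of [triage_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `triage_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(triage_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "),
            call. = FALSE)
    raw <- raw[intersect(names(raw), known)]
  }
  do.call(triage_config, raw)
}

#' @export
print.triage_config <- function(x, ...) {
  cat("<triage_config>\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}
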