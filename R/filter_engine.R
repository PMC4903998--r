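#' Call-quality filter
#'
#' Removes genotype calls supported by too little evidence: read depth at
#' or below `min_depth_exclusive` (default 2x) or Phred-scaled quality at
#' or below `min_gq_exclusive` (default 20). Absent metrics pass — inputs
#' validated by orthogonal means carry no depth/quality and must not be
#' dropped. With `quality_connective = "both"` a call is removed only when
#' both conditions hold.
#'
#' @param depth,gq Numeric vectors (NA = metric absent).
#' @param cfg A [triage_config()].
#' @return A decision tibble with columns `passed` and `reason`.
#' @export
quality_filter <- function(depth, gq, cfg = triage_config()) {
  low_dp <- !is.na(depth) & depth <= cfg$min_depth_exclusive
  low_gq <- !is.na(gq) & gq <= cfg$min_gq_exclusive
  fail <- if (cfg$quality_connective == "either") low_dp | low_gq else
    low_dp & low_gq
  reason <- dplyr::case_when(
    !fail & (is.na(depth) | is.na(gq)) ~ "quality_metrics_absent",
    !fail ~ "",
    low_dp & low_gq ~ sprintf("depth<=%g;gq<=%g", cfg$min_depth_exclusive,
                              cfg$min_gq_exclusive),
    low_dp ~ sprintf("depth<=%g", cfg$min_depth_exclusive),
    TRUE ~ sprintf("gq<=%g", cfg$min_gq_exclusive))
  tibble::tibble(passed = !fail, reason = reason)
}

#' Gene-panel membership filter
#'
#' A variant passes iff its gene symbol is on the panel (case-insensitive).
#'
#' @param gene Character vector of gene symbols (NA = unannotated).
#' @param panel A `triage_panel`.
#' @return A decision tibble with `passed` and `reason`.
#' @export
panel_filter <- function(gene, panel) {
  on_panel <- !is.na(gene) & toupper(gene) %in% toupper(panel$gene)
  tibble::tibble(passed = on_panel,
                 reason = ifelse(on_panel, "", "off_panel"))
}

#' Population-frequency filter with rarity labels
#'
#' Excludes variants too common in the reference population for the
#' inheritance hypothesis under consideration. A variant never observed in
#' the population (absent frequency) passes as `novel`. Under a monoallelic
#' hypothesis the governing threshold is `het_af_max` (default 0.01%),
#' under a biallelic hypothesis `biallelic_af_max` (default 1%); a variant
#' at or below its governing threshold passes as `rare`, above it fails as
#' `common`. Exclusion is strict (`>` threshold), so a frequency exactly at
#' the cutoff passes.
#'
#' @param exac_af Numeric vector of population allele frequencies
#'   (NA = novel).
#' @param hypothesis `"monoallelic"` or `"biallelic"` (vectorised).
#' @param cfg A [triage_config()].
#' @return A tibble with `passed`, `reason`, `rarity`.
#' @export
frequency_filter <- function(exac_af, hypothesis, cfg = triage_config()) {
  if (any(!is.na(exac_af) & (exac_af < 0 | exac_af > 1))) {
    stop("exac_af outside [0, 1]", call. = FALSE)
  }
  if (!all(hypothesis %in% c("monoallelic", "biallelic"))) {
    stop("hypothesis must be monoallelic or biallelic", call. = FALSE)
  }
  thr <- ifelse(hypothesis == "monoallelic", cfg$het_af_max,
                cfg$biallelic_af_max)
  rarity <- dplyr::case_when(is.na(exac_af) ~ "novel",
                             exac_af <= thr ~ "rare",
                             TRUE ~ "common")
  tibble::tibble(
    passed = rarity != "common",
    reason = ifelse(rarity == "common",
                    sprintf("af>%g_under_%s", thr, hypothesis), ""),
    rarity = rarity)
}

#' CADD vs gene-specific MSC gate
#'
#' A variant passes when its CADD-scaled score reaches the gene-specific
#' mutation significance cutoff (MSC). A sub-MSC variant is rescued when
#' the override is enabled and the patient's phenotype matches the gene's
#' deficiency (reason `msc_override_phenotype`) — the auditable form of the
#' expert judgement that retained sub-MSC biallelic LRBA variants on
#' phenotype grounds. Variants without a CADD score, or genes without an
#' MSC, pass ungated (reason `ungated`).
#'
#' @param cadd_scaled Numeric vector of CADD-scaled scores (NA = unscored).
#' @param msc Numeric vector of gene-specific cutoffs (NA = none).
#' @param phenotype_match Logical vector from [phenotype_match()].
#' @param cfg A [triage_config()].
#' @return A tibble with `passed` and `reason`.
#' @export
cadd_msc_gate <- function(cadd_scaled, msc, phenotype_match,
                          cfg = triage_config()) {
  ungated <- is.na(cadd_scaled) | is.na(msc)
  meets <- !ungated & cadd_scaled >= msc
  rescued <- !ungated & !meets & cfg$msc_override_enabled & phenotype_match
  tibble::tibble(
    passed = ungated | meets | rescued,
    reason = dplyr::case_when(ungated ~ "ungated",
                              rescued ~ "msc_override_phenotype",
                              meets ~ "",
                              TRUE ~ "cadd_below_msc"))
}

#' Run the full exclusion cascade
#'
#' Applies, in order: the call-quality filter, the panel restriction, the
#' zygosity-dependent population-frequency filter, and the CADD/MSC gate,
#' over every carrier call (het or hom_alt) of every patient. The frequency
#' hypothesis for a call is derived from the patient's zygosity pattern in
#' that gene among quality- and panel-surviving calls: a hom_alt call, or a
#' het call in an AR-capable panel gene holding at least two het calls,
#' is judged under the biallelic threshold; every other call under the
#' monoallelic threshold. Every removal is logged with stage and reason.
#'
#' @param callset A `triage_callset`.
#' @param pedigree A `triage_pedigree` (defines the patient set).
#' @param panel A `triage_panel`.
#' @param phenotypes Tibble `sample_id` + list column `tags` (may be
#'   missing/empty; phenotype matches then never rescue sub-MSC variants).
#' @param cfg A [triage_config()].
#' @param patients Character vector of proband ids; defaults to
#'   [ped_patients()] of the pedigree.
#' @return A list of class `triage_cascade`: `survivors` (call table with
#'   variant annotations and assigned `hypothesis`), `decisions` (log of
#'   every stage decision), `callset`, `panel`, `config`, `patients`.
#' @export
run_cascade <- function(callset, pedigree, panel, phenotypes = NULL,
                        cfg = triage_config(),
                        patients = ped_patients(pedigree)) {
  stopifnot(inherits(callset, "triage_callset"))
  calls <- carrier_calls(callset)
  calls <- calls[calls$sample_id %in% patients, ]
  v <- callset$variants
  calls <- dplyr::left_join(
    calls,
    v[, c("key", "chrom", "pos", "ref", "alt", "gene", "transcript", "hgvs_c",
          "hgvs_p", "cadd_scaled", "exac_af", "hgmd_known")],
    by = "key")
  decisions <- list()
  log_stage <- function(calls, stage, dec, hypothesis = NA_character_) {
    decisions[[stage]] <<- tibble::tibble(
      subject = paste(calls$sample_id, calls$key, sep = "@"),
      stage = stage, passed = dec$passed,
      reason = ifelse(dec$passed & dec$reason == "", "pass", dec$reason),
      hypothesis = hypothesis)
    calls[dec$passed, , drop = FALSE]
  }

  dec_q <- quality_filter(calls$depth, calls$gq, cfg)
  calls <- log_stage(calls, "quality", dec_q)

  dec_p <- panel_filter(calls$gene, panel)
  calls <- log_stage(calls, "panel", dec_p)

  calls$hypothesis <- assign_hypothesis(calls, panel)

  dec_f <- frequency_filter(calls$exac_af, calls$hypothesis, cfg)
  calls <- log_stage(calls, "frequency", dec_f, hypothesis = calls$hypothesis)

  pheno_ok <- phenotype_match_calls(calls, panel, phenotypes)
  msc <- panel$msc[match(toupper(calls$gene), toupper(panel$gene))]
  dec_c <- cadd_msc_gate(calls$cadd_scaled, msc, pheno_ok, cfg)
  calls <- log_stage(calls, "cadd_msc", dec_c, hypothesis = calls$hypothesis)

  structure(list(survivors = calls,
                 decisions = dplyr::bind_rows(decisions),
                 callset = callset, panel = panel, config = cfg,
                 patients = patients, phenotypes = phenotypes),
            class = "triage_cascade")
}

# Frequency hypothesis from the patient's zygosity pattern per gene:
# hom_alt => biallelic; >=2 het calls in an AR/XL-capable gene => biallelic
# for those het calls; anything else monoallelic.
assign_hypothesis <- function(calls, panel) {
  if (nrow(calls) == 0) return(character(0))
  ar_capable <- vapply(panel$inheritance_modes,
                       function(m) any(c("AR", "XL") %in% m), logical(1))
  ar_genes <- toupper(panel$gene[ar_capable])
  grp <- paste(calls$sample_id, toupper(calls$gene), sep = "\r")
  n_het <- stats::ave(calls$zygosity == "het", grp, FUN = sum)
  ifelse(calls$zygosity == "hom_alt", "biallelic",
         ifelse(n_het >= 2 & toupper(calls$gene) %in% ar_genes,
                "biallelic", "monoallelic"))
}

# Per-call phenotype match between the carrying patient and the gene entry.
phenotype_match_calls <- function(calls, panel, phenotypes) {
  if (nrow(calls) == 0) return(logical(0))
  if (is.null(phenotypes) || nrow(phenotypes) == 0) {
    return(rep(FALSE, nrow(calls)))
  }
  gi <- match(toupper(calls$gene), toupper(panel$gene))
  pi <- match(calls$sample_id, phenotypes$sample_id)
  vapply(seq_len(nrow(calls)), function(i) {
    if (is.na(gi[i]) || is.na(pi[i])) return(FALSE)
    phenotype_match(phenotypes$tags[[pi[i]]], panel$phenotype_tags[[gi[i]]])
  }, logical(1))
}

#' @export
print.triage_cascade <- function(x, ...) {
  cat(sprintf("<triage_cascade> %d surviving calls across %d patients\n",
              nrow(x$survivors), length(unique(x$survivors$sample_id))))
  tab <- table(x$decisions$stage[!x$decisions$passed])
  if (length(tab) > 0) {
    cat("  removals:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
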