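#' Phenotype match between a patient and a panel gene
#'
#' Both the patient and the panel entry carry tags from a small controlled
#' vocabulary (e.g. `autoimmune_cytopenia`, `granulomatous_disease`,
#' `low_B_cells`, `hypogammaglobulinemia`); a match is a non-empty
#' intersection. This is a deliberately mechanical stand-in for the expert
#' phenotype judgement of a clinical review: tag curation, not inference.
#'
#' @param patient_tags Character vector of patient phenotype tags.
#' @param entry_tags Character vector of gene phenotype tags (or a one-row
#'   `triage_panel` slice).
#' @return `TRUE` iff the tag sets intersect.
#' @export
phenotype_match <- function(patient_tags, entry_tags) {
  if (is.data.frame(entry_tags)) entry_tags <- entry_tags$phenotype_tags[[1]]
  length(intersect(patient_tags, entry_tags)) > 0
}

# hypothesis vs published inheritance mode compatibility:
# monoallelic <-> AD; biallelic hom/comphet <-> AR (hom also covers
# hemizygous XL); unphased pairs are never promoted.
hypothesis_compatible <- function(hypothesis, modes) {
  switch(hypothesis,
         monoallelic = "AD" %in% modes,
         biallelic_hom = any(c("AR", "XL") %in% modes),
         biallelic_comphet = "AR" %in% modes,
         biallelic_unphased = FALSE,
         FALSE)
}

#' Assign a reporting tier to one candidate group
#'
#' Tiers: `likely_disease_causing` requires the hypothesis to be compatible
#' with the gene's published inheritance modes (monoallelic with AD;
#' homozygous or phased compound-het with AR; hemizygous with XL) *and* a
#' phenotype match. Genes carrying an association tier override (weakly
#' disease-associated genes such as `TNFRSF13B`) classify as
#' `disease_associated` regardless of the other checks. Everything else is
#' `other_damaging`, with the failed checks (`zygosity_mismatch`,
#' `phenotype_mismatch`, `phase_unknown`) as machine-readable reasons.
#' Published (HGMD) support is reported as evidence but never raises a
#' tier.
#'
#' @param group A one-row resolved candidate tibble.
#' @param panel A `triage_panel`.
#' @param patient_tags Character vector of the patient's phenotype tags.
#' @param variants The cohort variant table (for HGMD support lookup).
#' @return A one-row finding tibble: the group columns plus `tier`,
#'   `reasons` (list), `hgmd_support`, and `variants` (list of the group's
#'   annotated variant rows).
#' @export
classify <- function(group, panel, patient_tags, variants) {
  stopifnot(nrow(group) == 1)
  entry <- panel_entry(panel, group$gene)
  keys <- group$variant_keys[[1]]
  vrows <- variants[match(keys, variants$key), ]
  hgmd <- any(vrows$hgmd_known, na.rm = TRUE)
  if (nrow(entry) == 0) {
    tier <- "other_damaging"
    reasons <- "off_panel"
  } else if (!is.na(entry$tier_override)) {
    tier <- entry$tier_override
    reasons <- "association_tier_override"
  } else {
    compat <- hypothesis_compatible(group$hypothesis,
                                    entry$inheritance_modes[[1]])
    pm <- phenotype_match(patient_tags, entry$phenotype_tags[[1]])
    if (compat && pm) {
      tier <- "likely_disease_causing"
      reasons <- character(0)
    } else {
      tier <- "other_damaging"
      reasons <- c(
        if (!compat && group$hypothesis == "biallelic_unphased")
          "phase_unknown",
        if (!compat && group$hypothesis != "biallelic_unphased")
          "zygosity_mismatch",
        if (!pm) "phenotype_mismatch")
    }
  }
  out <- group
  out$tier <- tier
  out$reasons <- list(reasons)
  out$hgmd_support <- hgmd
  out$variants <- list(vrows)
  out
}

#' Classify every resolved candidate group of a cohort
#'
#' @param groups A resolved candidate tibble from [resolve_candidates()].
#' @param cascade The `triage_cascade` the groups came from.
#' @param phenotypes Tibble `sample_id` + list column `tags` (optional).
#' @return A findings tibble, one row per classified group.
#' @export
classify_candidates <- function(groups, cascade, phenotypes = NULL) {
  variants <- cascade$callset$variants
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    pid <- groups$patient_id[i]
    tags <- character(0)
    if (!is.null(phenotypes)) {
      j <- match(pid, phenotypes$sample_id)
      if (!is.na(j)) tags <- phenotypes$tags[[j]]
    }
    out[[i]] <- classify(groups[i, ], cascade$panel, tags, variants)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- empty_groups()
    res$tier <- character(0)
    res$reasons <- list()
    res$hgmd_support <- logical(0)
    res$variants <- list()
  }
  res
}

#' Cohort-level summary statistics
#'
#' Computes the diagnostic-yield report for one triage run: how many
#' patients carried any panel-gene variant, how many variants survived to
#' the private-or-rare set, how many distinct variants reached the top
#' tier (a variant shared by related patients counts once), the number of
#' diagnosed patients and the diagnostic yield, a per-gene patient
#' breakdown in which each patient appears under exactly one gene (top
#' tier takes precedence), and the fractions of private-or-rare variants
#' at CADD-scaled >= 20 (top 1% of reference SNVs) and >= 30 (top 0.1%).
#'
#' @param findings A findings tibble from [classify_candidates()].
#' @param cascade The `triage_cascade` of the run.
#' @param cfg A [triage_config()] (summary CADD thresholds).
#' @return A named list of class `cohort_summary`.
#' @export
summarize_cohort <- function(findings, cascade, cfg = cascade$config) {
  dec <- cascade$decisions
  n_patients <- length(cascade$patients)
  panel_pass <- dec[dec$stage == "panel" & dec$passed, ]
  subj <- strsplit(panel_pass$subject, "@", fixed = TRUE)
  panel_patients <- unique(vapply(subj, `[`, character(1), 1))
  freq_pass <- dec[dec$stage == "frequency" & dec$passed, ]
  rare_keys <- unique(vapply(strsplit(freq_pass$subject, "@", fixed = TRUE),
                             `[`, character(1), 2))
  v <- cascade$callset$variants
  rare_cadd <- v$cadd_scaled[match(rare_keys, v$key)]
  rare_cadd <- rare_cadd[!is.na(rare_cadd)]

  likely <- findings[findings$tier == "likely_disease_causing", ]
  likely_keys <- unique(unlist(likely$variant_keys))
  likely_patients <- unique(likely$patient_id)

  tier_rank <- c(likely_disease_causing = 1, disease_associated = 2,
                 other_damaging = 3)
  breakdown <- tibble::tibble(gene = character(0), tier = character(0),
                              n_patients = integer(0))
  if (nrow(findings) > 0) {
    best <- findings |>
      dplyr::mutate(rank = tier_rank[.data$tier]) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::slice_min(.data$rank, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    breakdown <- best |>
      dplyr::count(.data$gene, .data$tier, name = "n_patients") |>
      dplyr::arrange(.data$tier, .data$gene)
  }

  structure(list(
    n_patients = n_patients,
    n_patients_with_panel_variant = length(panel_patients),
    n_variants_total = nrow(panel_pass),
    n_variants_private_or_rare = length(rare_keys),
    n_unique_likely = length(likely_keys),
    n_patients_likely = length(likely_patients),
    diagnostic_yield = if (n_patients > 0)
      length(likely_patients) / n_patients else 0,
    tier_breakdown = breakdown,
    cadd_ge20_frac = if (length(rare_cadd) > 0)
      mean(rare_cadd >= cfg$cadd_benign_scaled) else NA_real_,
    cadd_ge30_frac = if (length(rare_cadd) > 0)
      mean(rare_cadd >= cfg$cadd_strong_scaled) else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  cat(sprintf("  patients: %d (%d with a panel variant)\n", x$n_patients,
              x$n_patients_with_panel_variant))
  cat(sprintf("  panel-gene variant calls: %d; private-or-rare variants: %d\n",
              x$n_variants_total, x$n_variants_private_or_rare))
  cat(sprintf("  likely disease-causing: %d variants in %d patients (yield %.0f%%)\n",
              x$n_unique_likely, x$n_patients_likely,
              100 * x$diagnostic_yield))
  invisible(x)
}

#' Run the complete triage pipeline
#'
#' Filter cascade, candidate grouping with phasing and segregation, tier
#' classification, and cohort summary, in one call.
#'
#' @param callset A `triage_callset`.
#' @param pedigree A `triage_pedigree`.
#' @param panel A `triage_panel`.
#' @param phenotypes Optional phenotype-tag tibble.
#' @param cfg A [triage_config()].
#' @param patients Proband ids; defaults to every affected sample.
#' @return A list of class `triage_result` with elements `cascade`,
#'   `groups`, `findings`, `summary`.
#' @examples
#' \donttest{
#' fx <- cvid_case_fixture()
#' res <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
#' res$summary
#' }
#' @export
triage_run <- function(callset, pedigree, panel, phenotypes = NULL,
                       cfg = triage_config(),
                       patients = ped_patients(pedigree)) {
  cascade <- run_cascade(callset, pedigree, panel, phenotypes, cfg,
                         patients = patients)
  groups <- resolve_candidates(cascade, pedigree)
  findings <- classify_candidates(groups, cascade, phenotypes)
  summary <- summarize_cohort(findings, cascade, cfg)
  structure(list(cascade = cascade, groups = groups, findings = findings,
                 summary = summary),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
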