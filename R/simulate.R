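#' Scenario specification for the cohort generator
#'
#' A scenario plants one configuration of causal or decoy variants in a
#' number of patients. Kinds: `AD_de_novo` (het variant absent from both
#' genotyped parents), `AD_inherited_penetrant` (het variant shared with an
#' affected carrier parent), `AD_incomplete_penetrance` (het variant shared
#' with an unaffected carrier parent), `AR_homozygous` (hom_alt with het
#' carrier parents), `AR_compound_het` (two het variants in one recessive
#' gene, one traceable to each parent), `cis_false_comphet` (two het
#' variants in a recessive gene, both inherited from one parent),
#' `TACI_associated` (het variant in the weakly disease-associated gene),
#' and the decoys `decoy_common` (population frequency above the governing
#' threshold), `decoy_low_cadd` (CADD below the gene's MSC, in a gene whose
#' phenotype the patient does not match), `decoy_off_panel` (damaging
#' variant in a non-panel gene), `decoy_low_quality` (call removed by the
#' depth/quality gate).
#'
#' @param kind One of the scenario kinds above.
#' @param count Number of patients to receive the scenario.
#' @param af_range Optional length-2 numeric interval for the planted
#'   population frequency (`NA` entries allowed through kind defaults).
#' @param cadd_range Optional length-2 interval for the planted CADD score.
#' @return A one-row scenario tibble.
#' @export
scenario_spec <- function(kind, count, af_range = NULL, cadd_range = NULL) {
  kinds <- c("AD_de_novo", "AD_inherited_penetrant",
             "AD_incomplete_penetrance", "AR_homozygous", "AR_compound_het",
             "cis_false_comphet", "TACI_associated", "decoy_common",
             "decoy_low_cadd", "decoy_off_panel", "decoy_low_quality")
  if (!kind %in% kinds) stop("unknown scenario kind: ", kind, call. = FALSE)
  if (count < 0) stop("count must be >= 0", call. = FALSE)
  tibble::tibble(kind = kind, count = as.integer(count),
                 af_range = list(af_range), cadd_range = list(cadd_range))
}

#' Default scenario mix
#'
#' Emulates the composition of a severe-phenotype CVID exome cohort:
#' 15 causal patients out of 50 (diagnostic yield 30%) split across
#' dominant (de novo, penetrant familial, incomplete-penetrance) and
#' recessive (homozygous, compound-heterozygote) configurations, a small
#' group of weakly-associated-gene carriers, one false compound
#' heterozygote in cis, and one decoy patient per filter stage.
#'
#' @return A scenario tibble.
#' @export
default_scenarios <- function() {
  dplyr::bind_rows(
    scenario_spec("AD_de_novo", 2),
    scenario_spec("AD_inherited_penetrant", 4),
    scenario_spec("AD_incomplete_penetrance", 4),
    scenario_spec("AR_homozygous", 1),
    scenario_spec("AR_compound_het", 4),
    scenario_spec("TACI_associated", 3),
    scenario_spec("cis_false_comphet", 1),
    scenario_spec("decoy_common", 4),
    scenario_spec("decoy_low_cadd", 4),
    scenario_spec("decoy_off_panel", 4),
    scenario_spec("decoy_low_quality", 4))
}

#' Synthetic PID panel used by the generator
#'
#' A reduced panel with dominant, recessive, and X-linked genes drawn from
#' well-known PID loci, gene-specific MSC values, one distinct phenotype
#' tag per gene, and the association-tier override on `TNFRSF13B`.
#'
#' @return A `triage_panel`.
#' @export
synthetic_panel <- function() {
  genes <- tibble::tibble(
    gene = c("NFKB1", "STAT3", "CTLA4", "PIK3CD", "IKZF1", "NFKB2",
             "LRBA", "STXBP2", "ICOS", "CD19", "PRKCD", "SH2D1A",
             "TNFRSF13B"),
    inheritance_modes = c(rep("AD", 6), rep("AR", 5), "XL", "AD,AR"),
    msc = c(3.3, 10, 15, 20, 20, 12, 25, 20, 10, 8, 12, 10, 20),
    tier_override = c(rep(NA_character_, 12), "disease_associated"))
  genes$phenotype_tags <- paste0("pheno_", tolower(genes$gene))
  build_panel(genes)
}

#' Cohort generator configuration
#'
#' @param n_patients Cohort size (default 50).
#' @param n_familial Number of patients given an affected genotyped
#'   relative (default 8, matching a cohort of 42 sporadic and 8 familial
#'   cases).
#' @param seed Integer seed; identical configurations and seeds give
#'   identical cohorts.
#' @param scenarios A scenario tibble ([default_scenarios()]).
#' @param background_variants_per_patient Off-panel background variants per
#'   patient (default 10).
#' @param panel A `triage_panel` ([synthetic_panel()]).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50, n_familial = 8, seed = 1,
                          scenarios = default_scenarios(),
                          background_variants_per_patient = 10,
                          panel = synthetic_panel()) {
  if (sum(scenarios$count) > n_patients) {
    stop("scenario counts (", sum(scenarios$count),
         ") exceed n_patients (", n_patients, ")", call. = FALSE)
  }
  if (n_familial > n_patients) {
    stop("n_familial must not exceed n_patients", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_familial = as.integer(n_familial),
                 seed = as.integer(seed), scenarios = scenarios,
                 background_variants_per_patient =
                   as.integer(background_variants_per_patient),
                 panel = panel),
            class = "cohort_config")
}

# kind metadata: does the scenario need genotyped parents, which gene class
# it draws from, and its intended classification tier.
kind_info <- function(kind) {
  switch(kind,
    AD_de_novo = list(parents = TRUE, class = "AD",
                      tier = "likely_disease_causing"),
    AD_inherited_penetrant = list(parents = TRUE, class = "AD",
                                  tier = "likely_disease_causing"),
    AD_incomplete_penetrance = list(parents = TRUE, class = "AD",
                                    tier = "likely_disease_causing"),
    AR_homozygous = list(parents = TRUE, class = "AR",
                         tier = "likely_disease_causing"),
    AR_compound_het = list(parents = TRUE, class = "AR",
                           tier = "likely_disease_causing"),
    cis_false_comphet = list(parents = TRUE, class = "AR",
                             tier = "other_damaging"),
    TACI_associated = list(parents = FALSE, class = "ASSOC",
                           tier = "disease_associated"),
    decoy_common = list(parents = FALSE, class = "AD", tier = "excluded"),
    decoy_low_cadd = list(parents = FALSE, class = "AD", tier = "excluded"),
    decoy_off_panel = list(parents = FALSE, class = "OFF", tier = "excluded"),
    decoy_low_quality = list(parents = FALSE, class = "AD", tier = "excluded"))
}

#' Generate a seeded synthetic cohort
#'
#' Builds a cohort of affected patients with planted scenario variants,
#' genotyped parents where the scenario requires them, affected carrier
#' relatives for the familial fraction, and off-panel background variants
#' with log-uniform population frequencies and uniform CADD scores. The
#' output is deterministic for a fixed configuration and seed. A truth
#' table records every planted group's intended tier for
#' [recovery_report()].
#'
#' Planted parameters default to the separable regime: causal variants lie
#' strictly inside every threshold (novel or ultra-rare, CADD above the
#' gene MSC, good call quality, matching phenotype tag) and each decoy lies
#' strictly outside exactly one.
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort`: `callset`, `pedigree`,
#'   `phenotypes`, `panel`, `truth`, `config`, and `patient_ids` — the
#'   cohort probands (affected relatives recruited for segregation, such
#'   as a transmitting affected parent, are not probands).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  panel <- config$panel
  modes <- panel$inheritance_modes
  ad_genes <- panel$gene[vapply(modes, function(m) "AD" %in% m, logical(1)) &
                           is.na(panel$tier_override)]
  ar_genes <- panel$gene[vapply(modes, function(m) "AR" %in% m, logical(1)) &
                           is.na(panel$tier_override)]
  assoc_genes <- panel$gene[!is.na(panel$tier_override)]
  off_genes <- sprintf("OFFP%02d", 1:20)
  if (length(assoc_genes) == 0) assoc_genes <- ad_genes[1]

  n <- config$n_patients
  pids <- sprintf("PT%03d", seq_len(n))
  scen_rows <- config$scenarios[rep(seq_len(nrow(config$scenarios)),
                                    config$scenarios$count), ]
  assignment <- tibble::tibble(patient = pids,
                               kind = c(scen_rows$kind,
                                        rep(NA_character_,
                                            n - nrow(scen_rows))),
                               af_range = c(scen_rows$af_range,
                                            rep(list(NULL),
                                                n - nrow(scen_rows))),
                               cadd_range = c(scen_rows$cadd_range,
                                              rep(list(NULL),
                                                  n - nrow(scen_rows))))

  samples <- list()
  variants <- list()
  calls <- list()
  pheno <- list()
  truth <- list()
  pos_counter <- new.env(parent = emptyenv())
  next_pos <- function(contig) {
    cur <- if (is.null(pos_counter[[contig]])) 0L else pos_counter[[contig]]
    pos_counter[[contig]] <- cur + 1L
    1000L + 500L * cur
  }
  gene_cursor <- new.env(parent = emptyenv())
  pick_gene <- function(class) {
    pool <- switch(class, AD = ad_genes, AR = ar_genes, ASSOC = assoc_genes,
                   OFF = off_genes)
    cur <- if (is.null(gene_cursor[[class]])) 0L else gene_cursor[[class]]
    gene_cursor[[class]] <- cur + 1L
    pool[(cur %% length(pool)) + 1L]
  }
  ok_depth <- function(k = 1) round(stats::runif(k, 25, 60))
  ok_gq <- function(k = 1) round(stats::runif(k, 45, 99))
  add_variant <- function(gene, af, cadd) {
    pos <- next_pos(gene)
    key <- paste(gene, pos, "A", "G", sep = ":")
    variants[[length(variants) + 1L]] <<- tibble::tibble(
      chrom = gene, pos = pos, ref = "A", alt = "G", gene = gene,
      transcript = paste0("NM_", gene), hgvs_c = paste0("c.", pos, "A>G"),
      hgvs_p = NA_character_, cadd_scaled = cadd, exac_af = af,
      hgmd_known = FALSE)
    key
  }
  add_call <- function(sample, key, zyg, depth = ok_depth(), gq = ok_gq()) {
    calls[[length(calls) + 1L]] <<- tibble::tibble(
      sample_id = sample, key = key, zygosity = zyg,
      depth = depth, gq = gq)
  }
  add_sample <- function(id, family, affected, mother = NA, father = NA) {
    samples[[length(samples) + 1L]] <<- tibble::tibble(
      sample_id = id, family_id = family,
      sex = c("male", "female")[1 + (stats::runif(1) < 0.5)],
      affected = affected, mother_id = mother, father_id = father)
  }
  draw <- function(range, default, log_scale = FALSE) {
    r <- if (is.null(range)) default else range
    if (anyNA(r)) return(NA_real_)
    if (log_scale) exp(stats::runif(1, log(r[1]), log(r[2])))
    else stats::runif(1, r[1], r[2])
  }
  causal_af <- function(range) {
    # half novel, half ultra-rare, well inside the monoallelic threshold
    if (!is.null(range)) return(draw(range, NULL, log_scale = TRUE))
    if (stats::runif(1) < 0.5) NA_real_ else
      exp(stats::runif(1, log(1e-6), log(5e-5)))
  }
  gene_msc <- function(gene) {
    m <- panel$msc[match(gene, panel$gene)]
    if (length(m) == 0 || is.na(m)) 15 else m
  }

  # familial cases: pairs of affected relatives sharing a family (like
  # sibling or cousin pairs), drawn from the scenario-free patients; they
  # share background only — in cohorts like this most familial cases stay
  # genetically unexplained
  fam_override <- stats::setNames(character(0), character(0))
  unassigned <- pids[is.na(assignment$kind)]
  n_pairs <- min(config$n_familial %/% 2, length(unassigned) %/% 2)
  if (n_pairs > 0) {
    for (p in seq_len(n_pairs)) {
      pair <- unassigned[c(2 * p - 1, 2 * p)]
      fam_override[pair] <- paste0("FAMPAIR", p)
    }
  }

  for (i in seq_len(n)) {
    pid <- assignment$patient[i]
    kind <- assignment$kind[i]
    info <- if (is.na(kind)) NULL else kind_info(kind)
    fam <- if (pid %in% names(fam_override)) fam_override[[pid]] else
      paste0("F", substring(pid, 3))
    needs_parents <- !is.null(info) && info$parents
    mo <- fa <- NA_character_
    if (needs_parents) {
      mo <- paste0(pid, "m")
      fa <- paste0(pid, "f")
    }
    tags <- "hypogammaglobulinemia"
    planted_keys <- character(0)
    planted_gene <- NA_character_
    hypothesis <- NA_character_

    if (!is.null(info)) {
      g <- pick_gene(info$class)
      planted_gene <- g
      msc <- gene_msc(g)
      cadd_hi <- function() draw(assignment$cadd_range[[i]],
                                 c(msc + 2, msc + 20))
      par_aff <- "unaffected"
      if (kind == "AD_inherited_penetrant") par_aff <- "affected"

      if (kind %in% c("AD_de_novo", "AD_inherited_penetrant",
                      "AD_incomplete_penetrance", "TACI_associated",
                      "decoy_common", "decoy_low_cadd", "decoy_off_panel",
                      "decoy_low_quality")) {
        af <- switch(kind,
          decoy_common = draw(assignment$af_range[[i]], c(0.02, 0.5),
                              log_scale = TRUE),
          causal_af(assignment$af_range[[i]]))
        cadd <- if (kind == "decoy_low_cadd") {
          draw(assignment$cadd_range[[i]], c(max(0, msc - 10),
                                             max(0.5, msc - 1)))
        } else cadd_hi()
        key <- add_variant(g, af, cadd)
        if (kind == "decoy_low_quality") {
          add_call(pid, key, "het", depth = 1, gq = 10)
        } else {
          add_call(pid, key, "het")
        }
        planted_keys <- key
        hypothesis <- "monoallelic"
        if (kind %in% c("AD_de_novo")) {
          add_call(mo, key, "hom_ref"); add_call(fa, key, "hom_ref")
        }
        if (kind %in% c("AD_inherited_penetrant",
                        "AD_incomplete_penetrance")) {
          add_call(mo, key, "het"); add_call(fa, key, "hom_ref")
        }
      } else if (kind == "AR_homozygous") {
        key <- add_variant(g, causal_af(assignment$af_range[[i]]), cadd_hi())
        add_call(pid, key, "hom_alt")
        add_call(mo, key, "het"); add_call(fa, key, "het")
        planted_keys <- key
        hypothesis <- "biallelic_hom"
      } else if (kind %in% c("AR_compound_het", "cis_false_comphet")) {
        k1 <- add_variant(g, causal_af(assignment$af_range[[i]]), cadd_hi())
        k2 <- add_variant(g, causal_af(assignment$af_range[[i]]), cadd_hi())
        add_call(pid, k1, "het"); add_call(pid, k2, "het")
        if (kind == "AR_compound_het") {
          add_call(mo, k1, "het"); add_call(mo, k2, "hom_ref")
          add_call(fa, k1, "hom_ref"); add_call(fa, k2, "het")
          hypothesis <- "biallelic_comphet"
        } else {
          add_call(mo, k1, "hom_ref"); add_call(mo, k2, "hom_ref")
          add_call(fa, k1, "het"); add_call(fa, k2, "het")
          hypothesis <- "monoallelic"
        }
        planted_keys <- c(k1, k2)
      }
      # patient phenotype matches the planted gene except for the
      # low-CADD decoy, which must not be rescued by the override
      g_tag <- paste0("pheno_", tolower(g))
      if (kind != "decoy_low_cadd" && info$class != "OFF") {
        tags <- c(tags, g_tag)
      }
      if (needs_parents) {
        add_sample(mo, fam, par_aff)
        add_sample(fa, fam, "unaffected")
      }
      truth[[length(truth) + 1L]] <- tibble::tibble(
        patient_id = pid, gene = g, kind = kind,
        hypothesis = hypothesis, intended_tier = info$tier,
        variant_keys = list(planted_keys))
    }

    add_sample(pid, fam, "affected", mother = mo, father = fa)
    pheno[[length(pheno) + 1L]] <- tibble::tibble(sample_id = pid,
                                                  tags = list(unique(tags)))

    for (b in seq_len(config$background_variants_per_patient)) {
      g <- pick_gene("OFF")
      key <- add_variant(g, exp(stats::runif(1, log(1e-6), log(0.5))),
                         stats::runif(1, 0, 40))
      add_call(pid, key, "het")
    }
  }

  samples <- dplyr::bind_rows(samples)
  pedigree <- build_pedigree(samples)
  callset <- build_callset(dplyr::bind_rows(variants),
                           dplyr::bind_rows(calls),
                           provenance = list(generator = "generate_cohort",
                                             seed = config$seed))
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(patient_id = character(0), gene = character(0),
                   kind = character(0), hypothesis = character(0),
                   intended_tier = character(0), variant_keys = list())
  structure(list(callset = callset, pedigree = pedigree,
                 phenotypes = dplyr::bind_rows(pheno), panel = panel,
                 truth = truth, config = config,
                 patient_ids = pids),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits `cohort.vcf`, `cohort.ped`, `annotations.tsv` (sidecar),
#' `phenotypes.tsv`, `panel.tsv`, and `truth.tsv` into a directory. Output
#' bytes are deterministic for a fixed configuration and seed.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             ped = file.path(dir, "cohort.ped"),
             sidecar = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             panel = file.path(dir, "panel.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(cohort$callset, paths["vcf"])
  write_ped(cohort$pedigree, paths["ped"])
  write_sidecar(cohort$callset$variants, paths["sidecar"])
  write_phenotypes(cohort$phenotypes, paths["phenotypes"])
  write_panel_file(cohort$panel, paths["panel"])
  tr <- cohort$truth
  tr$variant_keys <- vapply(tr$variant_keys, paste, character(1),
                            collapse = ",")
  utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Compare pipeline findings with the generator truth table
#'
#' For each planted scenario, checks whether the pipeline recovered the
#' (patient, gene) group at its intended tier; decoys count as recovered
#' when no finding exists for their (patient, gene). Sensitivity is the
#' recovered fraction of planted likely-disease-causing groups; specificity
#' is one minus the fraction of non-causal planted scenarios that
#' nevertheless produced a likely-disease-causing finding.
#'
#' @param truth A generator truth table.
#' @param findings A findings tibble from the pipeline run on that cohort.
#' @return A list with `per_kind` (planted/recovered counts),
#'   `sensitivity`, `specificity`.
#' @export
recovery_report <- function(truth, findings) {
  if (nrow(truth) > 0 &&
      length(setdiff(truth$patient_id,
                     c(findings$patient_id, truth$patient_id))) > 0) {
    stop("truth and findings come from different cohorts", call. = FALSE)
  }
  fkey <- paste(findings$patient_id, findings$gene)
  recovered <- vapply(seq_len(nrow(truth)), function(i) {
    tk <- paste(truth$patient_id[i], truth$gene[i])
    hit <- findings[fkey == tk, ]
    if (truth$intended_tier[i] == "excluded") return(nrow(hit) == 0)
    any(hit$tier == truth$intended_tier[i])
  }, logical(1))
  per_kind <- tibble::tibble(kind = truth$kind, recovered = recovered) |>
    dplyr::count(.data$kind, .data$recovered) |>
    tidyr::pivot_wider(names_from = "recovered", values_from = "n",
                       values_fill = 0L)
  planted_likely <- truth$intended_tier == "likely_disease_causing"
  sens <- if (any(planted_likely)) mean(recovered[planted_likely]) else
    NA_real_
  likely_found <- findings[findings$tier == "likely_disease_causing", ]
  truth_likely_keys <- paste(truth$patient_id, truth$gene)[planted_likely]
  fp <- sum(!paste(likely_found$patient_id, likely_found$gene) %in%
              truth_likely_keys)
  n_noncausal <- sum(!planted_likely)
  spec <- if (n_noncausal > 0) max(0, 1 - fp / n_noncausal) else
    (if (fp == 0) 1 else 0)
  list(per_kind = per_kind, sensitivity = sens, specificity = spec)
}
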