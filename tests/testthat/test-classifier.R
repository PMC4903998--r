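test_that("phenotype match is non-empty tag intersection", {
  lrba <- tibble::tibble(
    gene = "LRBA", inheritance_modes = list("AR"),
    phenotype_tags = list(c("autoimmune_cytopenia", "granulomatous_disease",
                            "enteropathy")))
  expect_true(phenotype_match(
    c("autoimmune_cytopenia", "granulomatous_disease"), lrba))
  expect_false(phenotype_match(
    c("sinopulmonary_infections"), c("hemophagocytosis")))
  expect_false(phenotype_match(character(0), lrba))
  expect_false(phenotype_match(c("a", "b"), character(0)))
})

test_that("tiers follow inheritance-mode and phenotype compatibility", {
  fx <- cvid_case_fixture()
  cascade <- run_cascade(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  v <- fx$callset$variants

  # monoallelic nonsense variant in an AD gene with matching phenotype
  nfkb1 <- new_group("P04", "NFKB1", "monoallelic",
                     v$key[v$hgvs_p %in% "p.Y319*"])
  f <- classify(nfkb1, fx$panel, c("hypogammaglobulinemia"), v)
  expect_equal(f$tier, "likely_disease_causing")
  expect_length(f$reasons[[1]], 0)

  # phased compound het in an AR gene with matching phenotype
  stxbp2 <- new_group("P15", "STXBP2", "biallelic_comphet",
                      v$key[v$gene == "STXBP2"])
  f <- classify(stxbp2, fx$panel, c("ebv_susceptibility"), v)
  expect_equal(f$tier, "likely_disease_causing")
  expect_true(f$hgmd_support)

  # het call in an AR-only gene: zygosity mismatch
  mono_ar <- new_group("PX", "STXBP2", "monoallelic",
                       v$key[v$hgvs_p %in% "p.P334L"])
  f <- classify(mono_ar, fx$panel, c("ebv_susceptibility"), v)
  expect_equal(f$tier, "other_damaging")
  expect_true("zygosity_mismatch" %in% f$reasons[[1]])

  # phenotype mismatch alone also demotes
  f <- classify(nfkb1, fx$panel, c("hemophagocytosis"), v)
  expect_equal(f$tier, "other_damaging")
  expect_equal(f$reasons[[1]], "phenotype_mismatch")

  # unphased pair in an AR-only gene reports phase_unknown
  unph <- new_group("PX", "STXBP2", "biallelic_unphased",
                    v$key[v$gene == "STXBP2"])
  f <- classify(unph, fx$panel, c("ebv_susceptibility"), v)
  expect_equal(f$tier, "other_damaging")
  expect_true("phase_unknown" %in% f$reasons[[1]])
})

test_that("association-override genes classify as disease_associated", {
  fx <- cvid_case_fixture()
  v <- tibble::tibble(chrom = "TNFRSF13B", pos = 1000L, ref = "C", alt = "T",
                      gene = "TNFRSF13B", cadd_scaled = 25,
                      exac_af = NA_real_, hgmd_known = FALSE,
                      hgvs_c = "c.310T>C", hgvs_p = "p.C104R",
                      transcript = "NM_012452")
  v$key <- variant_key(v)
  g <- new_group("P20", "TNFRSF13B", "monoallelic", v$key)
  f <- classify(g, fx$panel, c("hypogammaglobulinemia"), v)
  expect_equal(f$tier, "disease_associated")
  expect_equal(f$reasons[[1]], "association_tier_override")
  # override wins regardless of hypothesis, even unphased biallelic
  g2 <- new_group("P20", "TNFRSF13B", "biallelic_unphased",
                  c(v$key, v$key))
  expect_equal(classify(g2, fx$panel, character(0), v)$tier,
               "disease_associated")
})

test_that("every resolved group receives exactly one tier", {
  co <- generate_cohort(cohort_config(seed = 3))
  res <- triage_run(co$callset, co$pedigree, co$panel, co$phenotypes,
                    patients = co$patient_ids)
  expect_equal(nrow(res$findings), nrow(res$groups))
  expect_true(all(res$findings$tier %in%
                    c("likely_disease_causing", "disease_associated",
                      "other_damaging")))
  demoted <- res$findings[res$findings$tier != "likely_disease_causing", ]
  expect_true(all(lengths(demoted$reasons) > 0))
})

test_that("summary dedupes shared variants and counts patients once", {
  fx <- cvid_case_fixture()
  res <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  s <- res$summary
  expect_equal(s$n_patients, 50)
  expect_equal(s$n_patients_with_panel_variant, 15)
  expect_equal(s$n_variants_total, 18)
  expect_equal(s$n_variants_private_or_rare, 17)
  expect_equal(s$n_unique_likely, 17)
  expect_equal(s$n_patients_likely, 15)
  expect_equal(s$diagnostic_yield, 0.30)
  expect_true(s$n_patients_likely <= s$n_patients)
  expect_lte(s$diagnostic_yield,
             s$n_patients_with_panel_variant / s$n_patients)

  # duplicating a patient's finding rows does not change unique counts
  dup <- dplyr::bind_rows(res$findings, res$findings[1, ])
  s2 <- summarize_cohort(dup, res$cascade)
  expect_equal(s2$n_unique_likely, s$n_unique_likely)
  expect_equal(s2$n_patients_likely, s$n_patients_likely)
})

test_that("CADD summary fractions are computed over the rare-or-novel set", {
  fx <- cvid_case_fixture()
  res <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  cadd <- fx$callset$variants$cadd_scaled
  expect_equal(res$summary$cadd_ge20_frac, mean(cadd >= 20))
  expect_equal(res$summary$cadd_ge30_frac, mean(cadd >= 30))
})

test_that("removing the association override migrates only that gene's tier", {
  fx <- cvid_case_fixture()
  v <- dplyr::bind_rows(
    fx$callset$variants,
    {
      taci <- tibble::tibble(chrom = "TNFRSF13B", pos = 1000L, ref = "C",
                             alt = "T", gene = "TNFRSF13B",
                             transcript = "NM_012452", hgvs_c = "c.310T>C",
                             hgvs_p = "p.C104R", cadd_scaled = 25,
                             exac_af = NA_real_, hgmd_known = FALSE)
      taci$key <- variant_key(taci)
      taci
    })
  calls <- dplyr::bind_rows(
    fx$callset$calls,
    tibble::tibble(sample_id = "P20", key = "TNFRSF13B:1000:C:T",
                   zygosity = "het"))
  cs <- build_callset(v, calls)
  with_override <- triage_run(cs, fx$pedigree, fx$panel, fx$phenotypes)
  panel2 <- fx$panel
  panel2$tier_override[panel2$gene == "TNFRSF13B"] <- NA
  without <- triage_run(cs, fx$pedigree, panel2, fx$phenotypes)

  taci_tier <- function(res) {
    res$findings$tier[res$findings$gene == "TNFRSF13B"]
  }
  expect_equal(taci_tier(with_override), "disease_associated")
  # P20 has the matching tag and a het call in an AD-capable gene
  expect_equal(taci_tier(without), "likely_disease_causing")
  other <- function(res) {
    f <- res$findings[res$findings$gene != "TNFRSF13B", ]
    f[order(f$patient_id, f$gene), c("patient_id", "gene", "tier")]
  }
  expect_equal(other(with_override), other(without))
})
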