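test_that("candidates group by patient, gene, and zygosity pattern", {
  fx <- cvid_case_fixture()
  cascade <- run_cascade(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  groups <- group_candidates(cascade$survivors, fx$panel)
  # two het STXBP2 calls in an AR gene form one biallelic candidate
  p15 <- groups[groups$patient_id == "P15", ]
  expect_equal(nrow(p15), 1)
  expect_equal(p15$hypothesis, "biallelic_unphased")
  expect_length(p15$variant_keys[[1]], 2)
  # one het IKZF1 call forms a monoallelic candidate
  p12 <- groups[groups$patient_id == "P12", ]
  expect_equal(p12$hypothesis, "monoallelic")
  # every surviving call appears in exactly one group of its patient
  in_groups <- groups |>
    dplyr::mutate(key = .data$variant_keys) |>
    tidyr::unnest("key")
  expect_setequal(paste(in_groups$patient_id, in_groups$key),
                  paste(cascade$survivors$sample_id, cascade$survivors$key))
  expect_false(anyDuplicated(paste(in_groups$patient_id, in_groups$key)) > 0)
})

test_that("single het calls in AR-only genes stay monoallelic; hom_alt routes biallelic", {
  panel <- toy_panel()
  survivors <- tibble::tibble(
    sample_id = c("A", "B"), key = c("GENE1:1:A:G", "GENE1:2:A:G"),
    zygosity = c("het", "hom_alt"), gene = "GENE1")
  groups <- group_candidates(survivors, panel)
  expect_equal(groups$hypothesis[groups$patient_id == "A"], "monoallelic")
  expect_equal(groups$hypothesis[groups$patient_id == "B"], "biallelic_hom")
  # two hets in an AD-only gene give two monoallelic groups, not a comphet
  ad2 <- tibble::tibble(
    sample_id = "C", key = c("GENEAD:1:A:G", "GENEAD:2:A:G"),
    zygosity = "het", gene = "GENEAD")
  gad <- group_candidates(ad2, panel)
  expect_equal(gad$hypothesis, c("monoallelic", "monoallelic"))
})

test_that("trio phasing matches the brute-force parental-origin oracle", {
  zygs <- c("hom_ref", "het", "hom_alt")
  grid <- expand.grid(m1 = zygs, m2 = zygs, f1 = zygs, f2 = zygs,
                      stringsAsFactors = FALSE)
  ped <- trio_pedigree()
  for (i in seq_len(nrow(grid))) {
    gm <- c(grid$m1[i], grid$m2[i])
    gf <- c(grid$f1[i], grid$f2[i])
    cs <- trio_callset(gm, gf)
    group <- new_group("kid", "GENE1", "biallelic_unphased",
                       cs$variants$key)
    phased <- suppressWarnings(phase_compound_het(group, ped, cs$calls))
    got <- if (nrow(phased) > 1) "cis" else
      switch(phased$hypothesis, biallelic_comphet = "trans",
             biallelic_unphased = "unphased")
    expect_equal(got, oracle_phase(gm, gf),
                 label = paste(c(gm, gf), collapse = "/"))
  }
})

test_that("three-variant candidates phase like the oracle on sampled trios", {
  zygs <- c("hom_ref", "het", "hom_alt")
  ped <- trio_pedigree()
  set.seed(42)
  for (rep in 1:60) {
    gm <- sample(zygs, 3, replace = TRUE)
    gf <- sample(zygs, 3, replace = TRUE)
    cs <- trio_callset(gm, gf)
    group <- new_group("kid", "GENE1", "biallelic_unphased",
                       cs$variants$key)
    phased <- suppressWarnings(phase_compound_het(group, ped, cs$calls))
    got <- if (nrow(phased) > 1) "cis" else
      switch(phased$hypothesis, biallelic_comphet = "trans",
             biallelic_unphased = "unphased")
    expect_equal(got, oracle_phase(gm, gf),
                 label = paste(c(gm, gf), collapse = "/"))
  }
})

test_that("phasing the documented families recovers trans and cis patterns", {
  fx <- cvid_case_fixture()
  res <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  comphet <- res$groups[res$groups$hypothesis == "biallelic_comphet", ]
  expect_setequal(comphet$patient_id, c("P13", "P14", "P15"))

  # two variants inherited from the same healthy father lie in cis and
  # split into monoallelic groups
  ped <- trio_pedigree()
  cs <- trio_callset(gm = c("hom_ref", "hom_ref"), gf = c("het", "het"))
  split <- phase_compound_het(
    new_group("kid", "GENE1", "biallelic_unphased", cs$variants$key),
    ped, cs$calls)
  expect_equal(nrow(split), 2)
  expect_true(all(split$hypothesis == "monoallelic"))

  # no parental genotypes: phase stays unknown
  lone <- build_pedigree(tibble::tibble(sample_id = "kid",
                                        affected = "affected"))
  un <- phase_compound_het(
    new_group("kid", "GENE1", "biallelic_unphased", cs$variants$key),
    lone, cs$calls[cs$calls$sample_id == "kid", ])
  expect_equal(un$hypothesis, "biallelic_unphased")
  expect_true("phase_unknown" %in% un$segregation[[1]])
})

test_that("a child allele absent from both genotyped parents warns", {
  ped <- trio_pedigree()
  cs <- trio_callset(gm = c("hom_ref", "het"), gf = c("hom_ref", "hom_ref"))
  expect_warning(
    out <- phase_compound_het(
      new_group("kid", "GENE1", "biallelic_unphased", cs$variants$key),
      ped, cs$calls),
    "Mendelian")
  expect_equal(out$hypothesis, "biallelic_unphased")
})

test_that("de novo detection requires both parents genotyped reference", {
  ped <- trio_pedigree()
  cs <- trio_callset(gm = "hom_ref", gf = "hom_ref")
  g <- new_group("kid", "GENE1", "monoallelic", cs$variants$key)
  expect_true("de_novo" %in%
                detect_de_novo(g, ped, cs$calls)$segregation[[1]])

  # carrier unaffected father
  cs2 <- trio_callset(gm = "hom_ref", gf = "het")
  g2 <- detect_de_novo(g, ped, cs2$calls)
  expect_true("inherited_unaffected_parent" %in% g2$segregation[[1]])
  expect_false("de_novo" %in% g2$segregation[[1]])

  # one parent ungenotyped: no flag either way
  cs3 <- trio_callset(gm = "hom_ref", gf = "none")
  g3 <- detect_de_novo(g, ped, cs3$calls)
  expect_length(g3$segregation[[1]], 0)
})

test_that("segregation flags reproduce the documented family patterns", {
  fx <- cvid_case_fixture()
  res <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  flags <- stats::setNames(res$groups$segregation, res$groups$patient_id)
  expect_true("de_novo" %in% flags$P06)
  expect_true("de_novo" %in% flags$P10)
  expect_true("inherited_unaffected_parent" %in% flags$P07)
  expect_true("incomplete_penetrance" %in% flags$P07)
  # carrier unaffected mother and two carrier unaffected siblings
  expect_true("incomplete_penetrance" %in% flags$P08)
  p08 <- res$groups[res$groups$patient_id == "P08", ]
  expect_equal(nrow(p08$carrier_relatives[[1]]), 3)
  expect_true("incomplete_penetrance" %in% flags$P09)
  # mildly hypogammaglobulinemic carrier mother
  expect_true("variable_expressivity" %in% flags$P12)
  # affected second cousin shares the splice variant, no unaffected carriers
  expect_true("segregates_with_disease" %in% flags$P01)
  expect_true("segregates_with_disease" %in% flags$P02)
  # de novo and inherited_unaffected_parent never co-occur
  for (f in res$groups$segregation) {
    expect_false(all(c("de_novo", "inherited_unaffected_parent") %in% f))
  }
})

test_that("flags are stable under relabeling of sample ids", {
  fx <- cvid_case_fixture()
  res1 <- triage_run(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  relabel <- function(x) paste0("Z_", x)
  ped2 <- fx$pedigree
  ped2$sample_id <- relabel(ped2$sample_id)
  ped2$mother_id <- ifelse(is.na(ped2$mother_id), NA,
                           relabel(ped2$mother_id))
  ped2$father_id <- ifelse(is.na(ped2$father_id), NA,
                           relabel(ped2$father_id))
  calls2 <- fx$callset$calls
  calls2$sample_id <- relabel(calls2$sample_id)
  cs2 <- build_callset(fx$callset$variants, calls2)
  ph2 <- fx$phenotypes
  ph2$sample_id <- relabel(ph2$sample_id)
  res2 <- triage_run(cs2, build_pedigree(ped2), fx$panel, ph2)
  expect_equal(res2$groups$patient_id, relabel(res1$groups$patient_id))
  expect_equal(res2$groups$segregation, res1$groups$segregation)
  expect_equal(res2$groups$hypothesis, res1$groups$hypothesis)
})
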