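test_that("quality gate removes low-depth or low-quality calls", {
  cases <- tibble::tribble(
    ~depth, ~gq, ~passed, ~reason,
    2,      60,  FALSE,   "depth<=2",
    40,     20,  FALSE,   "gq<=20",
    40,     99,  TRUE,    "",
    3,      21,  TRUE,    "",
    1,      10,  FALSE,   "depth<=2;gq<=20",
    NA,     NA,  TRUE,    "quality_metrics_absent",
    NA,     15,  FALSE,   "gq<=20")
  dec <- quality_filter(cases$depth, cases$gq)
  expect_equal(dec$passed, cases$passed)
  expect_equal(dec$reason, cases$reason)
})

test_that("quality connective 'both' only removes doubly-failing calls", {
  cfg <- triage_config(quality_connective = "both")
  dec <- quality_filter(c(2, 40, 1), c(60, 20, 10), cfg)
  expect_equal(dec$passed, c(TRUE, TRUE, FALSE))
})

test_that("panel membership is case-insensitive and vacuous on empty panels", {
  panel <- toy_panel()
  dec <- panel_filter(c("gene1", "GENEAD", "NOTONPANEL", NA), panel)
  expect_equal(dec$passed, c(TRUE, TRUE, FALSE, FALSE))
  empty <- build_panel(tibble::tibble(gene = character(0),
                                      inheritance_modes = character(0)))
  expect_false(any(panel_filter(c("GENE1", "GENEAD"), empty)$passed))
})

test_that("frequency gate applies the zygosity-dependent threshold", {
  cases <- tibble::tribble(
    ~af,          ~hyp,          ~passed, ~rarity,
    0.000008256,  "monoallelic", TRUE,    "rare",
    0.002165,     "biallelic",   TRUE,    "rare",
    0.002165,     "monoallelic", FALSE,   "common",
    NA,           "monoallelic", TRUE,    "novel",
    NA,           "biallelic",   TRUE,    "novel",
    0.05,         "biallelic",   FALSE,   "common",
    0.001532,     "biallelic",   TRUE,    "rare",
    0.0002160,    "biallelic",   TRUE,    "rare",
    0.00004944,   "biallelic",   TRUE,    "rare")
  dec <- frequency_filter(cases$af, cases$hyp)
  expect_equal(dec$passed, cases$passed)
  expect_equal(dec$rarity, cases$rarity)
})

test_that("exclusion is strict: a frequency exactly at the cutoff passes", {
  cfg <- triage_config()
  at <- frequency_filter(c(cfg$het_af_max, cfg$biallelic_af_max),
                         c("monoallelic", "biallelic"), cfg)
  expect_true(all(at$passed))
  above <- frequency_filter(c(cfg$het_af_max, cfg$biallelic_af_max) * 1.01,
                            c("monoallelic", "biallelic"), cfg)
  expect_false(any(above$passed))
  expect_error(frequency_filter(1.2, "monoallelic"), "outside")
  expect_error(frequency_filter(0.1, "dominant"), "hypothesis")
})

test_that("CADD/MSC gate compares, rescues on phenotype, and passes ungated", {
  dec <- cadd_msc_gate(
    cadd_scaled = c(33, 19, 19, NA, 25),
    msc = c(20, 30, 30, 20, NA),
    phenotype_match = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(dec$passed, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(dec$reason,
               c("", "msc_override_phenotype", "cadd_below_msc",
                 "ungated", "ungated"))
  # override disabled: phenotype match no longer rescues
  off <- triage_config(msc_override_enabled = FALSE)
  expect_false(cadd_msc_gate(19, 30, TRUE, off)$passed)
})

test_that("the full cascade keeps all 18 case-series calls", {
  fx <- cvid_case_fixture()
  cascade <- run_cascade(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  expect_equal(nrow(cascade$survivors), 18)
  # the shared NFKB1 splice variant survives for both second cousins
  expect_setequal(
    cascade$survivors$sample_id[cascade$survivors$hgvs_c == "c.1301-1G>A"],
    c("P01", "P02"))
  # sub-MSC LRBA variants survive via the phenotype override, and are
  # flagged as such in the decision log
  lrba_dec <- cascade$decisions[
    cascade$decisions$stage == "cadd_msc" &
      grepl("LRBA", cascade$decisions$subject), ]
  expect_true(all(lrba_dec$reason == "msc_override_phenotype"))
})

test_that("a zeroed heterozygous threshold keeps only novel monoallelic calls", {
  fx <- cvid_case_fixture()
  cfg <- triage_config(het_af_max = 1e-12)
  cascade <- run_cascade(fx$callset, fx$pedigree, fx$panel, fx$phenotypes,
                         cfg)
  mono <- cascade$survivors[cascade$survivors$hypothesis == "monoallelic", ]
  expect_true(all(is.na(mono$exac_af)))
  # the single observed-in-ExAC monoallelic variant is now removed
  expect_false("c.259-4A>G" %in% mono$hgvs_c)
})

test_that("a planted common decoy is removed at the frequency stage", {
  fx <- cvid_case_fixture()
  v <- fx$callset$variants
  decoy <- tibble::tibble(
    chrom = "STAT3", pos = 99000L, ref = "A", alt = "G", gene = "STAT3",
    cadd_scaled = 35, exac_af = 0.05)
  decoy$key <- variant_key(decoy)
  v2 <- dplyr::bind_rows(v, decoy)
  c2 <- dplyr::bind_rows(fx$callset$calls,
                         tibble::tibble(sample_id = "P20", key = decoy$key,
                                        zygosity = "het"))
  cs <- build_callset(v2, c2)
  cascade <- run_cascade(cs, fx$pedigree, fx$panel, fx$phenotypes)
  expect_equal(nrow(cascade$survivors), 18)
  logged <- cascade$decisions[
    cascade$decisions$subject == paste0("P20@", decoy$key), ]
  freq_row <- logged[logged$stage == "frequency", ]
  expect_false(freq_row$passed)
  expect_match(freq_row$reason, "af>")
})

test_that("raising frequency thresholds never shrinks the surviving set", {
  co <- generate_cohort(cohort_config(seed = 11,
                                      background_variants_per_patient = 4))
  surv_ids <- function(cfg) {
    s <- run_cascade(co$callset, co$pedigree, co$panel, co$phenotypes, cfg,
                     patients = co$patient_ids)$survivors
    paste(s$sample_id, s$key)
  }
  base <- surv_ids(triage_config())
  for (cfg in list(triage_config(het_af_max = 1e-3),
                   triage_config(biallelic_af_max = 0.1),
                   triage_config(het_af_max = 1e-3,
                                 biallelic_af_max = 0.1),
                   triage_config(min_depth_exclusive = 0,
                                 min_gq_exclusive = 0))) {
    expect_true(all(base %in% surv_ids(cfg)))
  }
  # and lowering them never grows it
  tight <- surv_ids(triage_config(het_af_max = 1e-6,
                                  biallelic_af_max = 1e-4))
  expect_true(all(tight %in% base))
})

test_that("the cascade is idempotent and logs a complete decision set", {
  fx <- cvid_case_fixture()
  run1 <- run_cascade(fx$callset, fx$pedigree, fx$panel, fx$phenotypes)
  again <- run_cascade(subset_callset(fx$callset, run1$survivors),
                       fx$pedigree, fx$panel, fx$phenotypes)
  expect_setequal(paste(run1$survivors$sample_id, run1$survivors$key),
                  paste(again$survivors$sample_id, again$survivors$key))

  co <- generate_cohort(cohort_config(seed = 5))
  runa <- run_cascade(co$callset, co$pedigree, co$panel, co$phenotypes,
                      patients = co$patient_ids)
  runb <- run_cascade(subset_callset(co$callset, runa$survivors),
                      co$pedigree, co$panel, co$phenotypes,
                      patients = co$patient_ids)
  expect_setequal(paste(runa$survivors$sample_id, runa$survivors$key),
                  paste(runb$survivors$sample_id, runb$survivors$key))

  # per stage, inputs = survivors + logged failures
  dec <- runa$decisions
  n_in <- sum(runa$callset$calls$zygosity %in% c("het", "hom_alt") &
                runa$callset$calls$sample_id %in% co$patient_ids)
  for (stage in c("quality", "panel", "frequency", "cadd_msc")) {
    d <- dec[dec$stage == stage, ]
    expect_equal(nrow(d), n_in, label = stage)
    n_in <- sum(d$passed)
  }
  expect_equal(n_in, nrow(runa$survivors))
})

test_that("frequency and CADD/MSC stages commute", {
  co <- generate_cohort(cohort_config(seed = 13))
  cascade <- run_cascade(co$callset, co$pedigree, co$panel, co$phenotypes,
                         patients = co$patient_ids)
  # reconstruct the post-panel call table with hypotheses, then apply the
  # two per-call gates in both orders
  dec <- cascade$decisions
  panel_pass <- dec$subject[dec$stage == "panel" & dec$passed]
  freq <- dec[dec$stage == "frequency", ]
  hyp <- stats::setNames(freq$hypothesis, freq$subject)
  v <- co$callset$variants
  calls <- co$callset$calls
  subj <- paste(calls$sample_id, calls$key, sep = "@")
  keep <- subj %in% panel_pass
  calls <- calls[keep, ]; subj <- subj[keep]
  af <- v$exac_af[match(calls$key, v$key)]
  cadd <- v$cadd_scaled[match(calls$key, v$key)]
  msc <- co$panel$msc[match(v$gene[match(calls$key, v$key)], co$panel$gene)]
  pm <- rep(FALSE, nrow(calls))
  f <- frequency_filter(af, hyp[subj])$passed
  g <- cadd_msc_gate(cadd, msc, pm)$passed
  fg <- subj[f][g[f]]
  gf <- subj[g][f[g]]
  expect_setequal(fg, gf)
  expect_setequal(fg, subj[f & g])
})
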