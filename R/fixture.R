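#' Curated CVID case-series fixture
#'
#' An in-memory cohort encoding a published-style case series of severe
#' CVID: 50 affected patients, of whom 15 carry 18 triage-surviving variant
#' calls (17 distinct variants — two related patients share one NFKB1
#' splice variant) across NFKB1, STAT3, CTLA4, PIK3CD, IKZF1 (monoallelic)
#' and LRBA, STXBP2 (compound heterozygous). Pedigree facts cover the
#' informative segregation patterns: a de novo STAT3 and a de novo CTLA4
#' variant, a STAT3 variant inherited from an unaffected father, carrier
#' unaffected mothers and siblings (incomplete penetrance), a mildly
#' hypogammaglobulinemic carrier mother (variable expressivity), and
#' parental origins resolving all three compound heterozygotes in trans.
#'
#' Genomic coordinates are synthetic (one contig per gene): tier logic
#' reads only annotations and genotypes, never coordinates. Phenotype tags
#' are curated so that the documented tier assignments are reproduced —
#' they stand in for expert case review, not for inference. Call depth and
#' quality are absent, as for variants confirmed by orthogonal Sanger
#' sequencing; such calls pass the quality gate by design.
#'
#' The remaining 35 patients carry no panel variants and stand in for the
#' genetically unexplained remainder of the cohort.
#'
#' @return A list with `callset`, `pedigree`, `panel`, `phenotypes`.
#' @examples
#' fx <- cvid_case_fixture()
#' nrow(fx$callset$variants)  # 17 distinct variants
#' @export
cvid_case_fixture <- function() {
  list(callset = fixture_callset(), pedigree = fixture_pedigree(),
       panel = fixture_panel(), phenotypes = fixture_phenotypes())
}

fixture_variants <- function() {
  tibble::tribble(
    ~chrom, ~pos, ~ref, ~alt, ~gene, ~transcript, ~hgvs_c, ~hgvs_p,
    ~cadd_scaled, ~exac_af, ~hgmd_known,
    "NFKB1", 1000L, "G", "A", "NFKB1", "NM_003998.3", "c.1301-1G>A",
    NA, 24, NA, FALSE,
    "NFKB1", 2000L, "A", "G", "NFKB1", "NM_003998.3", "c.259-4A>G",
    NA, 9.635, 0.000008256, FALSE,
    "NFKB1", 3000L, "T", "A", "NFKB1", "NM_003998.3", "c.957T>A",
    "p.Y319*", 36, NA, FALSE,
    "NFKB1", 4000L, "CT", "C", "NFKB1", "NM_003998.3", "c.1375delT",
    "p.F459Lfs*26", 23.2, NA, FALSE,
    "STAT3", 1000L, "G", "A", "STAT3", "NM_139276.2", "c.737G>A",
    "p.R246Q", 33, NA, FALSE,
    "STAT3", 2000L, "T", "C", "STAT3", "NM_139276.2", "c.937T>C",
    "p.F313L", 16.66, NA, FALSE,
    "STAT3", 3000L, "C", "T", "STAT3", "NM_139276.2", "c.307C>T",
    "p.R103W", 34, NA, FALSE,
    "CTLA4", 1000L, "A", "ACTGG", "CTLA4", "NM_005214.4", "c.56_57insCTGG",
    "p.T19Tfs*42", 19.5, NA, FALSE,
    "CTLA4", 2000L, "C", "G", "CTLA4", "NM_005214.4", "c.406C>G",
    "p.P136A", 23.8, NA, FALSE,
    "PIK3CD", 1000L, "G", "A", "PIK3CD", "NM_005026.3", "c.3061G>A",
    "p.E1021K", 31, NA, TRUE,
    "IKZF1", 1000L, "G", "A", "IKZF1", "NM_006060.5", "c.551G>A",
    "p.R184Q", 27.9, NA, FALSE,
    "LRBA", 1000L, "A", "G", "LRBA", "NM_006726.4", "c.1399A>G",
    "p.M467V", 19, 0.002165, FALSE,
    "LRBA", 2000L, "C", "G", "LRBA", "NM_006726.4", "c.8351C>G",
    "p.A2784G", 25.7, NA, FALSE,
    "LRBA", 3000L, "G", "A", "LRBA", "NM_006726.4", "c.2674G>A",
    "p.A892T", 24.4, 0.001532, FALSE,
    "LRBA", 4000L, "T", "C", "LRBA", "NM_006726.4", "c.6695T>C",
    "p.I2232T", 27.9, 0.0002160, FALSE,
    "STXBP2", 1000L, "TCTTCCCCAGG", "TGA", "STXBP2", "NM_006949.3",
    "c.474_483delinsGA", "p.C158Wfs*78", 33, NA, TRUE,
    "STXBP2", 2000L, "C", "T", "STXBP2", "NM_006949.3", "c.1001C>T",
    "p.P334L", 23.4, 0.00004944, TRUE)
}

# carrier map: which fixture sample is het/hom_alt at which variant, and
# which relatives are genotyped hom_ref for de novo / segregation calls
fixture_calls <- function(variants) {
  k <- function(hgvs_c) variants$key[variants$hgvs_c == hgvs_c]
  het <- function(sample, hgvs_c) {
    tibble::tibble(sample_id = sample, key = k(hgvs_c), zygosity = "het")
  }
  ref <- function(sample, hgvs_c) {
    tibble::tibble(sample_id = sample, key = k(hgvs_c), zygosity = "hom_ref")
  }
  dplyr::bind_rows(
    het("P01", "c.1301-1G>A"), het("P02", "c.1301-1G>A"),
    het("P03", "c.259-4A>G"),
    het("P04", "c.957T>A"),
    het("P05", "c.1375delT"),
    # STAT3 de novo: both parents genotyped reference
    het("P06", "c.737G>A"), ref("P06m", "c.737G>A"), ref("P06f", "c.737G>A"),
    # STAT3 inherited from the unaffected father
    het("P07", "c.937T>C"), ref("P07m", "c.937T>C"), het("P07f", "c.937T>C"),
    # STAT3 shared with carrier mother and two unaffected siblings
    het("P08", "c.307C>T"), het("P08m", "c.307C>T"),
    het("P08s1", "c.307C>T"), het("P08s2", "c.307C>T"),
    # CTLA4 shared with the asymptomatic mother
    het("P09", "c.56_57insCTGG"), het("P09m", "c.56_57insCTGG"),
    # CTLA4 de novo
    het("P10", "c.406C>G"), ref("P10m", "c.406C>G"), ref("P10f", "c.406C>G"),
    het("P11", "c.3061G>A"),
    # IKZF1 shared with the mildly hypogammaglobulinemic mother
    het("P12", "c.551G>A"), het("P12m", "c.551G>A"),
    # LRBA compound heterozygotes, one allele traceable to each parent
    het("P13", "c.1399A>G"), het("P13", "c.8351C>G"),
    het("P13m", "c.1399A>G"), ref("P13m", "c.8351C>G"),
    ref("P13f", "c.1399A>G"), het("P13f", "c.8351C>G"),
    het("P14", "c.2674G>A"), het("P14", "c.6695T>C"),
    het("P14m", "c.2674G>A"), ref("P14m", "c.6695T>C"),
    ref("P14f", "c.2674G>A"), het("P14f", "c.6695T>C"),
    # STXBP2 compound heterozygote, one allele from each parent
    het("P15", "c.474_483delinsGA"), het("P15", "c.1001C>T"),
    het("P15m", "c.474_483delinsGA"), ref("P15m", "c.1001C>T"),
    ref("P15f", "c.474_483delinsGA"), het("P15f", "c.1001C>T"))
}

fixture_callset <- function() {
  variants <- fixture_variants()
  variants$key <- variant_key(variants)
  build_callset(variants, fixture_calls(variants),
                provenance = list(source = "cvid_case_fixture"))
}

fixture_pedigree <- function() {
  sexes <- c(P01 = "male", P02 = "female", P03 = "male", P04 = "female",
             P05 = "female", P06 = "female", P07 = "male", P08 = "female",
             P09 = "female", P10 = "male", P11 = "female", P12 = "female",
             P13 = "female", P14 = "male", P15 = "male")
  rows <- list(
    # P01 and P02 are second cousins: one family, no shared parents
    tibble::tibble(sample_id = c("P01", "P02"), family_id = "FAM01",
                   sex = c("male", "female"), affected = "affected",
                   mother_id = NA_character_, father_id = NA_character_))
  singleton <- function(id) {
    tibble::tibble(sample_id = id, family_id = paste0("FAM", substring(id, 2)),
                   sex = sexes[[id]], affected = "affected",
                   mother_id = NA_character_, father_id = NA_character_)
  }
  trio <- function(id, extra = NULL, mother_status = "unaffected") {
    fam <- paste0("FAM", substring(id, 2))
    dplyr::bind_rows(
      tibble::tibble(sample_id = id, family_id = fam, sex = sexes[[id]],
                     affected = "affected",
                     mother_id = paste0(id, "m"), father_id = paste0(id, "f")),
      tibble::tibble(sample_id = paste0(id, c("m", "f")), family_id = fam,
                     sex = c("female", "male"),
                     affected = c(mother_status, "unaffected"),
                     mother_id = NA_character_, father_id = NA_character_),
      extra)
  }
  duo_mother <- function(id, mother_status = "unaffected") {
    fam <- paste0("FAM", substring(id, 2))
    dplyr::bind_rows(
      tibble::tibble(sample_id = id, family_id = fam, sex = sexes[[id]],
                     affected = "affected", mother_id = paste0(id, "m"),
                     father_id = NA_character_),
      tibble::tibble(sample_id = paste0(id, "m"), family_id = fam,
                     sex = "female", affected = mother_status,
                     mother_id = NA_character_, father_id = NA_character_))
  }
  p08_sibs <- tibble::tibble(
    sample_id = c("P08s1", "P08s2"), family_id = "FAM08",
    sex = c("female", "male"), affected = "unaffected",
    mother_id = "P08m", father_id = "P08f")
  p08 <- dplyr::bind_rows(
    tibble::tibble(sample_id = "P08", family_id = "FAM08", sex = "female",
                   affected = "affected", mother_id = "P08m",
                   father_id = "P08f"),
    tibble::tibble(sample_id = c("P08m", "P08f"), family_id = "FAM08",
                   sex = c("female", "male"), affected = "unaffected",
                   mother_id = NA_character_, father_id = NA_character_),
    p08_sibs)
  rest <- tibble::tibble(
    sample_id = sprintf("P%02d", 16:50),
    family_id = sprintf("FAM%02d", 16:50),
    sex = rep(c("female", "male"), length.out = 35),
    affected = "affected",
    mother_id = NA_character_, father_id = NA_character_)
  build_pedigree(dplyr::bind_rows(
    rows, lapply(c("P03", "P04", "P05", "P11"), singleton),
    trio("P06"), trio("P07"), p08, duo_mother("P09"), trio("P10"),
    duo_mother("P12", mother_status = "mildly_affected"),
    trio("P13"), trio("P14"), trio("P15"), rest))
}

fixture_panel <- function() {
  build_panel(tibble::tribble(
    ~gene, ~inheritance_modes, ~msc, ~phenotype_tags, ~tier_override,
    "NFKB1", "AD", 3.3,
    "hypogammaglobulinemia,autoimmune_cytopenia,granulomatous_disease",
    NA_character_,
    "STAT3", "AD", 10,
    "autoimmune_cytopenia,granulomatous_disease,early_onset_autoimmunity",
    NA_character_,
    "CTLA4", "AD", 15, "autoimmune_cytopenia,low_B_cells,enteropathy",
    NA_character_,
    "PIK3CD", "AD", 20,
    "sinopulmonary_infections,lymphoproliferation,enteropathy",
    NA_character_,
    "IKZF1", "AD", 20, "hypogammaglobulinemia,low_B_cells", NA_character_,
    # fixture MSC above every observed LRBA CADD score: these variants
    # survive only through the phenotype-match override
    "LRBA", "AR", 30, "autoimmune_cytopenia,granulomatous_disease,enteropathy",
    NA_character_,
    "STXBP2", "AR", 20, "hemophagocytosis,ebv_susceptibility", NA_character_,
    "TNFRSF13B", "AD,AR", 20, "hypogammaglobulinemia", "disease_associated"))
}

fixture_phenotypes <- function() {
  tags <- list(
    P01 = c("hypogammaglobulinemia", "granulomatous_disease", "enteropathy"),
    P02 = c("hypogammaglobulinemia", "autoimmune_cytopenia"),
    P03 = c("hypogammaglobulinemia", "sinopulmonary_infections"),
    P04 = c("hypogammaglobulinemia", "autoimmune_cytopenia"),
    P05 = c("hypogammaglobulinemia", "enteropathy", "granulomatous_disease"),
    P06 = c("autoimmune_cytopenia", "granulomatous_disease"),
    P07 = c("autoimmune_cytopenia", "early_onset_autoimmunity"),
    P08 = c("autoimmune_cytopenia", "granulomatous_disease"),
    P09 = c("autoimmune_cytopenia", "low_B_cells", "enteropathy"),
    P10 = c("autoimmune_cytopenia", "granulomatous_disease", "low_B_cells"),
    P11 = c("sinopulmonary_infections", "enteropathy",
            "lymphoproliferation"),
    P12 = c("hypogammaglobulinemia", "low_B_cells",
            "sinopulmonary_infections"),
    P13 = c("autoimmune_cytopenia", "granulomatous_disease"),
    P14 = c("autoimmune_cytopenia", "granulomatous_disease"),
    P15 = c("hypogammaglobulinemia", "low_B_cells", "ebv_susceptibility"))
  rest <- sprintf("P%02d", 16:50)
  tibble::tibble(
    sample_id = c(names(tags), rest),
    tags = c(unname(tags),
             rep(list("hypogammaglobulinemia"), length(rest))))
}
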