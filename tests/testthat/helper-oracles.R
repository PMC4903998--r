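# Brute-force parental-origin oracle for compound-het phasing.
#
# For a child heterozygous at k variants in one gene, enumerates all 2^k
# assignments of each alternate allele to a donor parent and keeps those
# consistent with Mendelian transmission: the donor must carry the
# alternate allele and the other parent must be able to donate the
# reference allele. Classification:
#   "trans"    every consistent assignment draws on both parents
#   "cis"      every consistent assignment draws on a single parent
#   "unphased" anything else (no consistent assignment, a missing parental
#              genotype, or a mix of cis and trans assignments)
oracle_phase <- function(gm, gf) {
  k <- length(gm)
  stopifnot(length(gf) == k)
  if (anyNA(gm) || anyNA(gf)) return("unphased")
  donors <- expand.grid(rep(list(c("M", "F")), k), stringsAsFactors = FALSE)
  ok <- apply(donors, 1, function(d) {
    all(vapply(seq_len(k), function(i) {
      donor_gt <- if (d[i] == "M") gm[i] else gf[i]
      other_gt <- if (d[i] == "M") gf[i] else gm[i]
      donor_gt %in% c("het", "hom_alt") && other_gt %in% c("het", "hom_ref")
    }, logical(1)))
  })
  cons <- donors[ok, , drop = FALSE]
  if (nrow(cons) == 0) return("unphased")
  both <- apply(cons, 1, function(d) length(unique(d)) == 2)
  if (all(both)) return("trans")
  if (all(!both)) return("cis")
  "unphased"
}

# Build a trio callset holding one compound-het candidate: child het at
# every variant, parents at the supplied zygosities ("none" = parent not
# genotyped there).
trio_callset <- function(gm, gf) {
  k <- length(gm)
  variants <- tibble::tibble(
    chrom = "GENE1", pos = 1000L * seq_len(k), ref = "A", alt = "G",
    gene = "GENE1")
  variants$key <- variant_key(variants)
  calls <- list(tibble::tibble(sample_id = "kid", key = variants$key,
                               zygosity = "het"))
  add <- function(sample, z) {
    keep <- z != "none"
    tibble::tibble(sample_id = sample, key = variants$key[keep],
                   zygosity = z[keep])
  }
  calls <- dplyr::bind_rows(c(calls, list(add("mom", gm), add("dad", gf))))
  build_callset(variants, calls)
}

trio_pedigree <- function() {
  build_pedigree(tibble::tibble(
    sample_id = c("kid", "mom", "dad"), family_id = "FAM",
    affected = c("affected", "unaffected", "unaffected"),
    mother_id = c("mom", NA, NA), father_id = c("dad", NA, NA)))
}

# Restrict a callset to the (sample, key) pairs named in a survivor table,
# so the cascade can be re-run on its own output.
subset_callset <- function(callset, survivors) {
  keep <- paste(callset$calls$sample_id, callset$calls$key) %in%
    paste(survivors$sample_id, survivors$key)
  build_callset(callset$variants, callset$calls[keep, ],
                provenance = callset$provenance)
}

# A minimal panel / single-variant callset for filter unit tests.
toy_panel <- function() {
  build_panel(tibble::tibble(
    gene = c("GENE1", "GENEAD", "TACIX"),
    inheritance_modes = c("AR", "AD", "AD,AR"),
    msc = c(20, 10, NA),
    phenotype_tags = c("tagA", "tagB", "tagC"),
    tier_override = c(NA, NA, "disease_associated")))
}
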