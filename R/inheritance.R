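#' Group surviving calls into per-patient, per-gene candidates
#'
#' Each candidate group holds one patient's surviving calls in one gene
#' under an inheritance hypothesis: a hom_alt call forms a `biallelic_hom`
#' group (hemizygous male calls on X arrive encoded hom_alt and route the
#' same way); two or more het calls in an AR- or XL-capable panel gene form
#' a compound-heterozygote candidate (initially `biallelic_unphased`, to be
#' resolved by [phase_compound_het()]); any other het call forms a
#' `monoallelic` group. A single het call in an AR-only gene still yields a
#' monoallelic group — the classifier later down-ranks it as a zygosity
#' mismatch rather than silently dropping it.
#'
#' @param survivors Survivor call table from [run_cascade()] (`$survivors`).
#' @param panel A `triage_panel`.
#' @return A tibble of candidate groups: `patient_id`, `gene`, `hypothesis`,
#'   `variant_keys` (list), `segregation` (list, empty), `carrier_relatives`
#'   (list, empty).
#' @export
group_candidates <- function(survivors, panel) {
  if (nrow(survivors) == 0) return(empty_groups())
  ar_capable <- vapply(panel$inheritance_modes,
                       function(m) any(c("AR", "XL") %in% m), logical(1))
  ar_genes <- toupper(panel$gene[ar_capable])
  pieces <- survivors |>
    dplyr::group_by(.data$sample_id, .data$gene) |>
    dplyr::group_map(function(df, grp) {
      out <- list()
      hom <- df[df$zygosity == "hom_alt", ]
      for (k in hom$key) {
        out[[length(out) + 1L]] <- new_group(grp$sample_id, grp$gene,
                                             "biallelic_hom", k)
      }
      het <- df[df$zygosity == "het", ]
      if (nrow(het) >= 2 && toupper(grp$gene) %in% ar_genes) {
        out[[length(out) + 1L]] <- new_group(grp$sample_id, grp$gene,
                                             "biallelic_unphased",
                                             sort(het$key))
      } else {
        for (k in het$key) {
          out[[length(out) + 1L]] <- new_group(grp$sample_id, grp$gene,
                                               "monoallelic", k)
        }
      }
      dplyr::bind_rows(out)
    })
  out <- dplyr::bind_rows(pieces)
  out[order(out$patient_id, out$gene, vapply(out$variant_keys, `[`,
                                             character(1), 1)), ]
}

new_group <- function(patient_id, gene, hypothesis, keys) {
  tibble::tibble(patient_id = patient_id, gene = gene,
                 hypothesis = hypothesis, variant_keys = list(keys),
                 segregation = list(character(0)),
                 carrier_relatives = list(empty_relatives()))
}

empty_groups <- function() {
  tibble::tibble(patient_id = character(0), gene = character(0),
                 hypothesis = character(0), variant_keys = list(),
                 segregation = list(), carrier_relatives = list())
}

empty_relatives <- function() {
  tibble::tibble(sample_id = character(0), affected = character(0))
}

# Zygosity of `sample` at `key`; NA when the sample was never genotyped
# there or the genotype is missing.
zygosity_of <- function(calls, sample, key) {
  z <- calls$zygosity[calls$sample_id == sample & calls$key == key]
  if (length(z) == 0 || z[1] == "missing") NA_character_ else z[1]
}

# Which parent can have transmitted the alternate allele of a het child?
# The donor parent must carry the alternate; the other parent must be able
# to donate the reference allele.
variant_origin <- function(gm, gf) {
  if (is.na(gm) || is.na(gf)) return("unknown")
  maternal <- gm %in% c("het", "hom_alt") && gf %in% c("het", "hom_ref")
  paternal <- gf %in% c("het", "hom_alt") && gm %in% c("het", "hom_ref")
  if (maternal && paternal) "ambiguous"
  else if (maternal) "maternal"
  else if (paternal) "paternal"
  else "inconsistent"
}

#' Phase a compound-heterozygote candidate through parental genotypes
#'
#' For each het variant of the group, the parental genotypes determine
#' which parent can have donated the alternate allele. Once two variants
#' are unambiguously traced to different parents, alleles sit on both
#' parental haplotypes: the group becomes `biallelic_comphet`. When every
#' variant traces unambiguously to the same parent the variants lie in cis
#' and the group is split into monoallelic groups (a false compound
#' heterozygote). Otherwise — a parent ungenotyped at some variant, or
#' origins ambiguous because both parents carry a variant, without an
#' established trans pair — phase cannot be resolved and the group stays
#' `biallelic_unphased` with flag `phase_unknown`. A Mendelian
#' inconsistency (child allele absent from both genotyped parents) logs a
#' warning and leaves the group unphased. Sibling-only phasing is not
#' attempted.
#'
#' @param group A one-row candidate tibble with >= 2 het variants.
#' @param pedigree A `triage_pedigree`.
#' @param calls The full call table (`callset$calls`), parents included.
#' @return A candidate tibble of one or more rows (cis splits into several).
#' @export
phase_compound_het <- function(group, pedigree, calls) {
  stopifnot(nrow(group) == 1, length(group$variant_keys[[1]]) >= 2)
  pid <- group$patient_id
  row <- pedigree[pedigree$sample_id == pid, ]
  mother <- row$mother_id
  father <- row$father_id
  keys <- group$variant_keys[[1]]
  if (nrow(row) == 0 || is.na(mother) || is.na(father)) {
    group$hypothesis <- "biallelic_unphased"
    group$segregation[[1]] <- union(group$segregation[[1]], "phase_unknown")
    return(group)
  }
  origins <- vapply(keys, function(k) {
    variant_origin(zygosity_of(calls, mother, k),
                   zygosity_of(calls, father, k))
  }, character(1))
  if (any(origins == "inconsistent")) {
    warning("Mendelian inconsistency phasing ", pid, "/", group$gene,
            "; variant(s) treated as unphased", call. = FALSE)
  }
  determinate <- origins[origins %in% c("maternal", "paternal")]
  if (!any(origins %in% c("unknown", "inconsistent"))) {
    if (length(unique(determinate)) == 2) {
      # alleles established on both parental haplotypes: in trans,
      # whatever the remaining (ambiguous-origin) variants turn out to be
      group$hypothesis <- "biallelic_comphet"
      return(group)
    }
    if (length(determinate) == length(origins)) {
      # all alleles from one parent: in cis, not a biallelic genotype
      return(dplyr::bind_rows(lapply(keys, function(k) {
        new_group(pid, group$gene, "monoallelic", k)
      })))
    }
  }
  group$hypothesis <- "biallelic_unphased"
  group$segregation[[1]] <- union(group$segregation[[1]], "phase_unknown")
  group
}

#' Detect de novo and transmitted monoallelic variants
#'
#' A monoallelic candidate is flagged `de_novo` when the proband is het and
#' both parents are genotyped homozygous reference. If instead a genotyped
#' parent carries the variant and that parent is unaffected, the group is
#' flagged `inherited_unaffected_parent`. With any parent ungenotyped,
#' neither flag is set — transmission cannot be excluded.
#'
#' @param group A one-row monoallelic candidate tibble.
#' @param pedigree A `triage_pedigree`.
#' @param calls The full call table.
#' @return The group with updated `segregation` flags.
#' @export
detect_de_novo <- function(group, pedigree, calls) {
  stopifnot(nrow(group) == 1)
  if (group$hypothesis != "monoallelic") return(group)
  pid <- group$patient_id
  row <- pedigree[pedigree$sample_id == pid, ]
  if (nrow(row) == 0) return(group)
  key <- group$variant_keys[[1]][1]
  parent_ids <- c(row$mother_id, row$father_id)
  gpar <- vapply(parent_ids, function(p) {
    if (is.na(p)) NA_character_ else zygosity_of(calls, p, key)
  }, character(1))
  gp <- zygosity_of(calls, pid, key)
  flags <- group$segregation[[1]]
  both_ref <- !is.na(row$mother_id) && !is.na(row$father_id) &&
    !anyNA(gpar) && all(gpar == "hom_ref")
  if (both_ref && identical(gp, "het")) {
    flags <- union(flags, "de_novo")
  } else {
    carrier_parent <- parent_ids[!is.na(gpar) & gpar %in% c("het", "hom_alt")]
    if (length(carrier_parent) > 0) {
      status <- pedigree$affected[match(carrier_parent, pedigree$sample_id)]
      if (any(status == "unaffected")) {
        flags <- union(flags, "inherited_unaffected_parent")
      }
    }
  }
  group$segregation[[1]] <- flags
  group
}

# Does `sample` carry the group's genotype pattern? NA when any required
# genotype is missing.
carries_pattern <- function(sample, group, calls) {
  keys <- group$variant_keys[[1]]
  z <- vapply(keys, function(k) zygosity_of(calls, sample, k), character(1))
  if (any(is.na(z))) return(NA)
  if (group$hypothesis == "biallelic_hom") return(all(z == "hom_alt"))
  all(z %in% c("het", "hom_alt"))
}

#' Annotate familial segregation of a candidate group
#'
#' Examines every genotyped relative (same pedigree family) of the patient
#' and records the carriers of the group's genotype pattern. Flags:
#' `incomplete_penetrance` when an unaffected relative carries the pattern;
#' `variable_expressivity` when a mildly affected relative carries it;
#' `segregates_with_disease` when at least one other affected relative is
#' genotyped, every genotyped affected relative carries the pattern, and no
#' genotyped unaffected relative does. Unaffected carriers are only ever
#' flagged, never grounds for automatic rejection.
#'
#' @param group A one-row candidate tibble.
#' @param pedigree A `triage_pedigree`.
#' @param calls The full call table.
#' @return The group with `carrier_relatives` and `segregation` updated.
#' @export
assess_segregation <- function(group, pedigree, calls) {
  stopifnot(nrow(group) == 1)
  pid <- group$patient_id
  fam <- pedigree$family_id[match(pid, pedigree$sample_id)]
  rel <- pedigree[pedigree$family_id %in% fam & pedigree$sample_id != pid, ]
  if (nrow(rel) == 0) return(group)
  carries <- vapply(rel$sample_id, carries_pattern, logical(1),
                    group = group, calls = calls)
  genotyped <- !is.na(carries)
  carriers <- rel[genotyped & carries, ]
  group$carrier_relatives[[1]] <- tibble::tibble(
    sample_id = carriers$sample_id, affected = carriers$affected)
  flags <- group$segregation[[1]]
  if (any(carriers$affected == "unaffected")) {
    flags <- union(flags, "incomplete_penetrance")
  }
  if (any(carriers$affected == "mildly_affected")) {
    flags <- union(flags, "variable_expressivity")
  }
  aff_genotyped <- rel$affected == "affected" & genotyped
  if (any(aff_genotyped) &&
      all(carries[aff_genotyped]) &&
      !any(carriers$affected == "unaffected")) {
    flags <- union(flags, "segregates_with_disease")
  }
  group$segregation[[1]] <- flags
  group
}

#' Build and resolve all candidate groups for a cascade result
#'
#' Convenience driver: groups the cascade survivors, phases every
#' compound-heterozygote candidate, detects de novo events, and annotates
#' segregation for each resulting group.
#'
#' @param cascade A `triage_cascade` from [run_cascade()].
#' @param pedigree A `triage_pedigree`.
#' @return A resolved candidate-group tibble.
#' @export
resolve_candidates <- function(cascade, pedigree) {
  groups <- group_candidates(cascade$survivors, cascade$panel)
  calls <- cascade$callset$calls
  out <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    if (g$hypothesis == "biallelic_unphased") {
      g <- phase_compound_het(g, pedigree, calls)
    }
    out[[i]] <- g
  }
  groups <- dplyr::bind_rows(out)
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- detect_de_novo(groups[i, ], pedigree, calls)
    out[[i]] <- assess_segregation(g, pedigree, calls)
  }
  dplyr::bind_rows(out)
}
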