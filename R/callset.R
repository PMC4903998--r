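#' Assemble a validated call set
#'
#' A call set pairs the annotated alternate alleles observed in a cohort
#' with every sample's genotype at those alleles. Each variant is one
#' alternate allele at a site, identified by the key
#' `chrom:pos:ref:alt`; multi-allelic sites are decomposed upstream so the
#' key is unique. Annotations ride on the variant: gene symbol, transcript,
#' HGVS coding/protein change, CADD-scaled deleteriousness, ExAC population
#' allele frequency (`NA` = never observed, i.e. novel), and whether the
#' variant is published as disease-causing/-associated (HGMD).
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `gene`, `transcript`, `hgvs_c`, `hgvs_p`,
#'   `cadd_scaled`, `exac_af`, `hgmd_known`.
#' @param calls Data frame with columns `sample_id`, `key`, `zygosity`
#'   (`hom_ref`, `het`, `hom_alt`, `missing`), and optionally `depth`, `gq`
#'   (`NA` = metric not recorded).
#' @param provenance Optional named list recording source files and parse
#'   counts.
#' @return A list of class `triage_callset` with elements `variants`,
#'   `calls`, `provenance`.
#' @export
build_callset <- function(variants, calls, provenance = list()) {
  variants <- tibble::as_tibble(variants)
  calls <- tibble::as_tibble(calls)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  variants$ref <- as.character(variants$ref)
  variants$alt <- as.character(variants$alt)
  opt <- list(gene = NA_character_, transcript = NA_character_,
              hgvs_c = NA_character_, hgvs_p = NA_character_,
              cadd_scaled = NA_real_, exac_af = NA_real_, hgmd_known = FALSE)
  for (col in names(opt)) {
    if (!col %in% names(variants)) variants[[col]] <- opt[[col]]
  }
  variants$cadd_scaled <- as.numeric(variants$cadd_scaled)
  variants$exac_af <- as.numeric(variants$exac_af)
  variants$hgmd_known <- !is.na(variants$hgmd_known) &
    as.logical(variants$hgmd_known)
  if (any(variants$pos < 1, na.rm = TRUE)) {
    stop("positions must be >= 1", call. = FALSE)
  }
  if (any(variants$ref == variants$alt)) {
    stop("ref must differ from alt", call. = FALSE)
  }
  af <- variants$exac_af
  if (any(!is.na(af) & (af < 0 | af > 1))) {
    stop("exac_af must lie in [0, 1]", call. = FALSE)
  }
  variants$key <- variant_key(variants)
  if (anyDuplicated(variants$key)) {
    dup <- unique(variants$key[duplicated(variants$key)])
    stop("duplicate variant keys: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  if (!all(c("sample_id", "key", "zygosity") %in% names(calls))) {
    stop("calls need columns sample_id, key, zygosity", call. = FALSE)
  }
  calls$sample_id <- as.character(calls$sample_id)
  calls$key <- as.character(calls$key)
  if (!"depth" %in% names(calls)) calls$depth <- NA_real_
  if (!"gq" %in% names(calls)) calls$gq <- NA_real_
  calls$depth <- as.numeric(calls$depth)
  calls$gq <- as.numeric(calls$gq)
  bad_z <- setdiff(unique(calls$zygosity),
                   c("hom_ref", "het", "hom_alt", "missing"))
  if (length(bad_z) > 0) {
    stop("unknown zygosity codes: ", paste(bad_z, collapse = ", "),
         call. = FALSE)
  }
  if (any(calls$depth < 0 | calls$gq < 0, na.rm = TRUE)) {
    stop("depth and gq must be >= 0", call. = FALSE)
  }
  orphan <- setdiff(calls$key, variants$key)
  if (length(orphan) > 0) {
    stop("calls reference unknown variants: ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(calls[, c("sample_id", "key")])) {
    stop("at most one call per (sample, variant)", call. = FALSE)
  }
  structure(list(variants = variants, calls = calls, provenance = provenance),
            class = "triage_callset")
}

#' Variant identity key
#'
#' @param variants A data frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector `chrom:pos:ref:alt`.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' @export
print.triage_callset <- function(x, ...) {
  cat(sprintf("<triage_callset> %d variants, %d calls, %d samples\n",
              nrow(x$variants), nrow(x$calls),
              length(unique(x$calls$sample_id))))
  invisible(x)
}

# Calls where the sample actually carries the alternate allele.
carrier_calls <- function(callset) {
  callset$calls[callset$calls$zygosity %in% c("het", "hom_alt"), ]
}
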