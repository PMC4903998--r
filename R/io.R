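#' Read a multi-sample annotated VCF into a call set
#'
#' Parses a VCF 4.x file with per-sample `GT` (and `DP`/`GQ` when present)
#' into a [build_callset()] container. Multi-allelic rows are decomposed to
#' one variant record per alternate allele; a sample's zygosity for allele
#' *i* is the number of copies of *i* in its genotype. Annotations are taken
#' from the INFO keys `GENE`, `HGVSC`, `HGVSP`, `CADD_PHRED`, `EXAC_AF`,
#' `HGMD`, or joined from a sidecar TSV on the `chrom:pos:ref:alt` identity
#' key; a sidecar value wins over an INFO value. Missing annotation fields
#' stay absent (`NA`), never zero. Calls lacking `DP`/`GQ` carry `NA` and
#' later pass the quality gate: triage inputs confirmed by orthogonal means
#' (e.g. Sanger) must not be dropped for absent quality metadata.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sidecar Optional path to an annotation sidecar TSV with header
#'   `chrom pos ref alt gene transcript hgvs_c hgvs_p cadd exac_af hgmd`.
#' @return A `triage_callset`.
#' @export
read_annotated_vcf <- function(path, sidecar = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(build_callset(
      tibble::tibble(chrom = character(), pos = integer(),
                     ref = character(), alt = character()),
      tibble::tibble(sample_id = character(), key = character(),
                     zygosity = character()),
      provenance = list(vcf = path, n_rows = 0L)))
  }

  info_field <- function(key) {
    out <- tryCatch(vcfR::extract.info(vcf, element = key),
                    error = function(e) NULL)
    if (is.null(out)) rep(NA_character_, nrow(fix)) else as.character(out)
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  num_fmt <- function(key) {
    out <- tryCatch(
      suppressWarnings(vcfR::extract.gt(vcf, element = key, as.numeric = TRUE)),
      error = function(e) NULL)
    if (is.null(out)) {
      matrix(NA_real_, nrow = nrow(gt_mat), ncol = ncol(gt_mat),
             dimnames = dimnames(gt_mat))
    } else out
  }
  dp_mat <- num_fmt("DP")
  gq_mat <- num_fmt("GQ")
  samples <- colnames(gt_mat)

  ann <- list(gene = info_field("GENE"), transcript = info_field("TRANSCRIPT"),
              hgvs_c = info_field("HGVSC"), hgvs_p = info_field("HGVSP"),
              cadd = info_field("CADD_PHRED"), exac = info_field("EXAC_AF"),
              hgmd = info_field("HGMD"))

  variants <- list()
  calls <- list()
  for (row in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[row], ",", fixed = TRUE)[[1]]
    # per-ALT annotation values may be comma-joined in the same allele order
    per_alt <- lapply(ann, function(v) {
      parts <- if (is.na(v[row])) NA_character_ else
        strsplit(v[row], ",", fixed = TRUE)[[1]]
      if (length(parts) == length(alts)) parts else rep(parts[1], length(alts))
    })
    gts <- gt_mat[row, , drop = TRUE]
    split_gt <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
    for (ai in seq_along(alts)) {
      variants[[length(variants) + 1L]] <- tibble::tibble(
        chrom = fix$CHROM[row], pos = as.integer(fix$POS[row]),
        ref = fix$REF[row], alt = alts[ai],
        gene = na_if_dot(per_alt$gene[ai]),
        transcript = na_if_dot(per_alt$transcript[ai]),
        hgvs_c = na_if_dot(per_alt$hgvs_c[ai]),
        hgvs_p = na_if_dot(per_alt$hgvs_p[ai]),
        cadd_scaled = suppressWarnings(as.numeric(na_if_dot(per_alt$cadd[ai]))),
        exac_af = suppressWarnings(as.numeric(na_if_dot(per_alt$exac[ai]))),
        hgmd_known = !is.na(per_alt$hgmd[ai]) &
          per_alt$hgmd[ai] %in% c("1", "TRUE", "true", "DM", "yes"))
      key <- paste(fix$CHROM[row], fix$POS[row], fix$REF[row], alts[ai],
                   sep = ":")
      n_alt <- vapply(split_gt, function(g) {
        if (all(g == ".")) NA_integer_ else sum(g == as.character(ai))
      }, integer(1))
      zyg <- dplyr::case_when(
        is.na(n_alt) ~ "missing",
        n_alt == 0 ~ "hom_ref",
        n_alt == 1 ~ "het",
        TRUE ~ "hom_alt")
      calls[[length(calls) + 1L]] <- tibble::tibble(
        sample_id = samples, key = key, zygosity = zyg,
        depth = unname(dp_mat[row, ]), gq = unname(gq_mat[row, ]))
    }
  }
  variants <- dplyr::bind_rows(variants)
  calls <- dplyr::bind_rows(calls)

  if (!is.null(sidecar)) {
    variants <- join_sidecar(variants, read_sidecar(sidecar))
  }
  build_callset(variants, calls,
                provenance = list(vcf = path, sidecar = sidecar,
                                  n_rows = nrow(fix),
                                  n_variants = nrow(variants)))
}

na_if_dot <- function(x) {
  ifelse(is.na(x) | x %in% c(".", "", "-"), NA_character_, x)
}

#' Read an annotation sidecar TSV
#'
#' @param path TSV with header
#'   `chrom pos ref alt gene transcript hgvs_c hgvs_p cadd exac_af hgmd`.
#'   Empty fields, `.` and `-` denote absent values.
#' @return A tibble of annotations keyed by `chrom:pos:ref:alt`.
#' @export
read_sidecar <- function(path) {
  sc <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = c("", ".", "-"))
  need <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
            "hgvs_c", "hgvs_p", "cadd", "exac_af", "hgmd")
  miss <- setdiff(need, names(sc))
  if (length(miss) > 0) {
    stop("sidecar missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    chrom = sc$chrom, pos = as.integer(sc$pos), ref = sc$ref, alt = sc$alt,
    gene = sc$gene, transcript = sc$transcript,
    hgvs_c = sc$hgvs_c, hgvs_p = sc$hgvs_p,
    cadd_scaled = as.numeric(sc$cadd),
    exac_af = as.numeric(sc$exac_af),
    hgmd_known = !is.na(sc$hgmd) & sc$hgmd %in% c("1", "TRUE", "true", "DM"),
    key = paste(sc$chrom, as.integer(sc$pos), sc$ref, sc$alt, sep = ":"))
}

# Sidecar annotations override whatever the INFO column carried.
join_sidecar <- function(variants, sidecar) {
  variants$key <- variant_key(variants)
  unmatched <- setdiff(sidecar$key, variants$key)
  if (length(unmatched) > 0) {
    warning(length(unmatched), " sidecar row(s) match no variant; ignored: ",
            paste(utils::head(unmatched, 3), collapse = ", "), call. = FALSE)
  }
  idx <- match(variants$key, sidecar$key)
  hit <- !is.na(idx)
  for (col in c("gene", "transcript", "hgvs_c", "hgvs_p",
                "cadd_scaled", "exac_af", "hgmd_known")) {
    variants[[col]][hit] <- sidecar[[col]][idx[hit]]
  }
  variants
}

#' Write an annotation sidecar TSV
#'
#' Inverse of [read_sidecar()]: round-trips all annotation fields.
#'
#' @param variants A variant tibble (e.g. `callset$variants`).
#' @param path Output path.
#' @export
write_sidecar <- function(variants, path) {
  out <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt,
    gene = tsv_field(variants$gene), transcript = tsv_field(variants$transcript),
    hgvs_c = tsv_field(variants$hgvs_c), hgvs_p = tsv_field(variants$hgvs_p),
    cadd = tsv_field(variants$cadd_scaled),
    exac_af = tsv_field(format_af(variants$exac_af)),
    hgmd = ifelse(variants$hgmd_known, "1", "0"),
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

tsv_field <- function(x) ifelse(is.na(x), ".", as.character(x))
format_af <- function(x) {
  ifelse(is.na(x), NA_character_,
         sub("0+$", "", sub("\\.?0+e", "e", format(x, scientific = FALSE,
                                                   trim = TRUE, digits = 12))))
}

#' Read a PLINK-style 6-column PED file
#'
#' Columns: family id, individual id, father id, mother id, sex
#' (1 = male, 2 = female, 0 = unknown), phenotype (2 = affected,
#' 1 = unaffected, 0/-9 = unknown). `0` parent ids mean missing. A sidecar
#' status TSV (`sample_id<TAB>status`) may refine the affected status, e.g.
#' to `mildly_affected` for a carrier with a partial phenotype.
#'
#' @param path PED file path.
#' @param status_sidecar Optional path to a two-column status TSV.
#' @return A sample tibble ready for [build_pedigree()].
#' @export
read_ped <- function(path, status_sidecar = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 6)
  if (length(bad) > 0) {
    stop("PED line ", bad[1], " has ", lengths(fields)[bad[1]],
         " columns (expected 6)", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  samples <- tibble::tibble(
    family_id = m[, 1], sample_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = unname(c("0" = "unknown", "1" = "male", "2" = "female")[m[, 5]]),
    affected = dplyr::case_when(m[, 6] == "2" ~ "affected",
                                m[, 6] == "1" ~ "unaffected",
                                TRUE ~ "unknown"))
  samples$sex[is.na(samples$sex)] <- "unknown"
  if (!is.null(status_sidecar)) {
    st <- utils::read.delim(status_sidecar, sep = "\t", header = TRUE,
                            colClasses = "character")
    idx <- match(samples$sample_id, st$sample_id)
    samples$affected[!is.na(idx)] <- st$status[idx[!is.na(idx)]]
  }
  samples
}

#' Write a 6-column PED file
#'
#' @param samples A sample tibble or `triage_pedigree`. `mildly_affected`
#'   maps to phenotype code 1 in the PED proper (use the status sidecar to
#'   keep the refinement).
#' @param path Output path.
#' @export
write_ped <- function(samples, path) {
  sex_code <- c(male = "1", female = "2", unknown = "0")
  aff_code <- c(affected = "2", unaffected = "1", mildly_affected = "1",
                unknown = "0")
  fam <- if ("family_id" %in% names(samples)) samples$family_id else
    samples$sample_id
  out <- cbind(fam, samples$sample_id,
               ifelse(is.na(samples$father_id), "0", samples$father_id),
               ifelse(is.na(samples$mother_id), "0", samples$mother_id),
               sex_code[samples$sex], aff_code[samples$affected])
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a gene panel TSV
#'
#' Header `gene inheritance_modes msc phenotype_tags tier_override`; modes
#' and tags comma-joined; empty `msc`/`tier_override` mean absent.
#'
#' @param path TSV path.
#' @return A `triage_panel`.
#' @export
read_panel_file <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character",
                           na.strings = c("", ".", "-"))
  build_panel(tibble::tibble(
    gene = raw$gene,
    inheritance_modes = raw$inheritance_modes,
    msc = suppressWarnings(as.numeric(raw$msc)),
    phenotype_tags = ifelse(is.na(raw$phenotype_tags), "",
                            raw$phenotype_tags),
    tier_override = raw$tier_override))
}

#' @rdname read_panel_file
#' @param panel A `triage_panel`.
#' @export
write_panel_file <- function(panel, path) {
  out <- data.frame(
    gene = panel$gene,
    inheritance_modes = vapply(panel$inheritance_modes, paste,
                               character(1), collapse = ","),
    msc = tsv_field(panel$msc),
    phenotype_tags = vapply(panel$phenotype_tags, paste,
                            character(1), collapse = ","),
    tier_override = tsv_field(panel$tier_override))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient phenotype tags
#'
#' TSV with header `sample_id tags`, tags comma-joined from the controlled
#' vocabulary.
#'
#' @param path TSV path.
#' @return Tibble with `sample_id` and list column `tags`.
#' @export
read_phenotypes <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  tibble::tibble(sample_id = raw$sample_id, tags = split_tokens(raw$tags))
}

#' @rdname read_phenotypes
#' @param phenotypes A phenotype tibble.
#' @export
write_phenotypes <- function(phenotypes, path) {
  out <- data.frame(
    sample_id = phenotypes$sample_id,
    tags = vapply(phenotypes$tags, paste, character(1), collapse = ","))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a call set as a multi-sample VCF 4.2 file
#'
#' Emits one row per variant with `GT:DP:GQ` per sample and annotations in
#' the INFO column, readable back with [read_annotated_vcf()].
#'
#' @param callset A `triage_callset`.
#' @param path Output path.
#' @export
write_vcf <- function(callset, path) {
  v <- callset$variants
  ord <- order(v$chrom, v$pos, v$ref, v$alt)
  v <- v[ord, ]
  samples <- sort(unique(callset$calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=TRANSCRIPT,Number=A,Type=String,Description=\"RefSeq transcript\">",
    "##INFO=<ID=HGVSC,Number=A,Type=String,Description=\"HGVS coding change\">",
    "##INFO=<ID=HGVSP,Number=A,Type=String,Description=\"HGVS protein change\">",
    "##INFO=<ID=CADD_PHRED,Number=A,Type=Float,Description=\"CADD scaled score\">",
    "##INFO=<ID=EXAC_AF,Number=A,Type=Float,Description=\"ExAC allele frequency\">",
    "##INFO=<ID=HGMD,Number=A,Type=Integer,Description=\"Published disease variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  calls <- callset$calls
  call_idx <- paste(calls$sample_id, calls$key)
  rows <- vapply(seq_len(nrow(v)), function(i) {
    info <- paste0(
      "GENE=", tsv_field(v$gene[i]),
      ";TRANSCRIPT=", tsv_field(v$transcript[i]),
      ";HGVSC=", tsv_field(v$hgvs_c[i]),
      ";HGVSP=", tsv_field(v$hgvs_p[i]),
      ";CADD_PHRED=", tsv_field(v$cadd_scaled[i]),
      ";EXAC_AF=", tsv_field(format_af(v$exac_af[i])),
      ";HGMD=", ifelse(v$hgmd_known[i], "1", "0"))
    idx <- match(paste(samples, v$key[i]), call_idx)
    geno <- vapply(idx, function(j) {
      if (is.na(j)) return("./.:.:.")
      paste(gt_code[[calls$zygosity[j]]],
            tsv_field(calls$depth[j]), tsv_field(calls$gq[j]), sep = ":")
    }, character(1))
    paste(c(v$chrom[i], v$pos[i], ".", v$ref[i], v$alt[i], ".", "PASS",
            info, "GT:DP:GQ", geno), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write the triage report
#'
#' Emits a per-finding TSV (one row per variant within a classified
#' finding, ordered by patient, gene, position) and a JSON cohort summary
#' whose keys match the fields of [summarize_cohort()].
#'
#' @param findings A findings tibble from [classify_candidates()].
#' @param summary A `CohortSummary` list from [summarize_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(findings, summary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- file.path(dir, "findings.tsv")
  json <- file.path(dir, "summary.json")
  rows <- report_rows(findings)
  utils::write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(summary), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(findings = tsv, summary = json))
}

# Flatten findings (one row per variant within each finding), sorted by
# patient, gene, position.
report_rows <- function(findings) {
  cols <- c("patient", "gene", "hgvs_c", "hgvs_p", "zygosity_hypothesis",
            "cadd", "exac_af", "tier", "reasons", "segregation")
  if (nrow(findings) == 0) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                         cols))
    return(out)
  }
  rows <- purrr::pmap_dfr(findings, function(patient_id, gene, hypothesis,
                                             variants, segregation, reasons,
                                             tier, ...) {
    tibble::tibble(
      patient = patient_id, gene = gene,
      hgvs_c = tsv_field(variants$hgvs_c),
      hgvs_p = tsv_field(variants$hgvs_p),
      zygosity_hypothesis = hypothesis,
      cadd = tsv_field(variants$cadd_scaled),
      exac_af = tsv_field(format_af(variants$exac_af)),
      tier = tier,
      reasons = paste(reasons, collapse = ","),
      segregation = paste(sort(segregation), collapse = ","),
      pos = variants$pos)
  })
  rows <- rows[order(rows$patient, rows$gene, rows$pos), ]
  rows$pos <- NULL
  rows
}
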