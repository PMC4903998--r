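#' Construct and validate a gene panel
#'
#' A panel row describes one PID-associated gene: its published inheritance
#' modes, its gene-specific mutation significance cutoff (MSC, in
#' CADD-scaled units), the controlled phenotype tags of the deficiency it
#' causes, and an optional tier override used to mark genes that are only
#' weakly disease-associated (e.g. `TNFRSF13B`), whose variants are reported
#' as `disease_associated` rather than likely disease-causing.
#'
#' @param entries A data frame with columns `gene`, `inheritance_modes`
#'   (list column of character vectors, or comma-joined strings, drawn from
#'   `AD`, `AR`, `XL`), and optionally `msc` (numeric, `NA` = no cutoff),
#'   `phenotype_tags` (list column or comma-joined strings), and
#'   `tier_override` (`NA` or a tier name).
#' @return A tibble of class `triage_panel`.
#' @examples
#' panel <- build_panel(tibble::tibble(
#'   gene = c("NFKB1", "LRBA"),
#'   inheritance_modes = c("AD", "AR"),
#'   msc = c(3.3, 30),
#'   phenotype_tags = c("hypogammaglobulinemia", "autoimmune_cytopenia")
#' ))
#' panel_size(panel)
#' @export
build_panel <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("gene", "inheritance_modes") %in% names(entries))) {
    stop("panel needs gene and inheritance_modes columns", call. = FALSE)
  }
  entries$gene <- as.character(entries$gene)
  if (anyDuplicated(toupper(entries$gene))) {
    dup <- unique(entries$gene[duplicated(toupper(entries$gene))])
    stop("duplicate panel genes: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  entries$inheritance_modes <- split_tokens(entries$inheritance_modes)
  bad <- vapply(entries$inheritance_modes, function(m) {
    length(m) == 0 || !all(m %in% c("AD", "AR", "XL"))
  }, logical(1))
  if (any(bad)) {
    stop("inheritance_modes must be a non-empty subset of {AD, AR, XL}; bad: ",
         paste(entries$gene[bad], collapse = ", "), call. = FALSE)
  }
  if (!"msc" %in% names(entries)) entries$msc <- NA_real_
  entries$msc <- as.numeric(entries$msc)
  if (any(!is.na(entries$msc) & entries$msc < 0)) {
    stop("msc must be >= 0 when present", call. = FALSE)
  }
  if (!"phenotype_tags" %in% names(entries)) entries$phenotype_tags <- ""
  entries$phenotype_tags <- split_tokens(entries$phenotype_tags)
  if (!"tier_override" %in% names(entries)) {
    entries$tier_override <- NA_character_
  }
  entries$tier_override <- as.character(entries$tier_override)
  known_tiers <- c("likely_disease_causing", "disease_associated",
                   "other_damaging")
  bad_tier <- !is.na(entries$tier_override) &
    !entries$tier_override %in% known_tiers
  if (any(bad_tier)) {
    stop("unknown tier_override: ",
         paste(unique(entries$tier_override[bad_tier]), collapse = ", "),
         call. = FALSE)
  }
  class(entries) <- c("triage_panel", class(entries))
  entries
}

#' @rdname build_panel
#' @param panel A `triage_panel`.
#' @export
panel_size <- function(panel) nrow(panel)

#' Look up a panel entry by gene symbol (case-insensitive)
#'
#' @param panel A `triage_panel`.
#' @param gene A gene symbol.
#' @return A one-row tibble, or a zero-row tibble when the gene is off-panel.
#' @export
panel_entry <- function(panel, gene) {
  panel[toupper(panel$gene) == toupper(gene), ]
}

# "AD,AR" -> c("AD","AR"); pass list columns through; "" -> character(0)
split_tokens <- function(x) {
  if (is.list(x)) {
    return(lapply(x, function(v) {
      v <- as.character(v)
      v[nzchar(v) & !is.na(v)]
    }))
  }
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(character(0))
    trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}
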