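#' Construct a validated pedigree
#'
#' Takes a sample table and returns an indexed pedigree supporting parent,
#' child, sibling, and founder lookups. Validation rejects duplicate sample
#' ids, parent references to samples absent from the table, and cyclic
#' parentage (including a sample listed as its own parent).
#'
#' @param samples A data frame with columns `sample_id`, and optionally
#'   `family_id`, `sex` (`"male"`, `"female"`, `"unknown"`), `affected`
#'   (`"affected"`, `"unaffected"`, `"mildly_affected"`, `"unknown"`),
#'   `mother_id`, `father_id` (`NA` = unknown parent).
#' @return A tibble of class `triage_pedigree`, one row per sample with
#'   normalised columns.
#' @examples
#' ped <- build_pedigree(data.frame(
#'   sample_id = c("P", "M", "F"),
#'   mother_id = c("M", NA, NA),
#'   father_id = c("F", NA, NA),
#'   affected  = c("affected", "unaffected", "unaffected")
#' ))
#' ped_parents(ped, "P")
#' @export
build_pedigree <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (!"sample_id" %in% names(samples)) {
    stop("samples must have a sample_id column", call. = FALSE)
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop("duplicate sample ids: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  defaults <- list(family_id = samples$sample_id, sex = "unknown",
                   affected = "unknown", mother_id = NA_character_,
                   father_id = NA_character_)
  for (col in names(defaults)) {
    if (!col %in% names(samples)) samples[[col]] <- defaults[[col]]
  }
  samples$mother_id <- as.character(samples$mother_id)
  samples$father_id <- as.character(samples$father_id)
  bad_sex <- setdiff(unique(samples$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop("unknown sex codes: ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  bad_aff <- setdiff(unique(samples$affected),
                     c("affected", "unaffected", "mildly_affected", "unknown"))
  if (length(bad_aff) > 0) {
    stop("unknown affected codes: ", paste(bad_aff, collapse = ", "),
         call. = FALSE)
  }
  parents <- stats::na.omit(c(samples$mother_id, samples$father_id))
  dangling <- setdiff(parents, samples$sample_id)
  if (length(dangling) > 0) {
    stop("parent ids absent from sample table: ",
         paste(unique(dangling), collapse = ", "), call. = FALSE)
  }
  cyc <- find_parentage_cycle(samples)
  if (!is.null(cyc)) {
    stop("cyclic parentage: ", paste(cyc, collapse = " -> "), call. = FALSE)
  }
  samples <- samples[, c("sample_id", "family_id", "sex", "affected",
                         "mother_id", "father_id",
                         setdiff(names(samples),
                                 c("sample_id", "family_id", "sex", "affected",
                                   "mother_id", "father_id")))]
  class(samples) <- c("triage_pedigree", class(samples))
  samples
}

# Depth-first walk over parent edges; returns the first cycle found or NULL.
find_parentage_cycle <- function(samples) {
  up <- split(
    c(samples$mother_id, samples$father_id),
    rep(samples$sample_id, 2)
  )
  up <- lapply(up, function(x) x[!is.na(x)])
  state <- new.env(parent = emptyenv())
  visit <- function(id, path) {
    mark <- state[[id]]
    if (identical(mark, "open")) return(c(path[match(id, path):length(path)], id))
    if (identical(mark, "done")) return(NULL)
    state[[id]] <- "open"
    for (p in up[[id]]) {
      cyc <- visit(p, c(path, id))
      if (!is.null(cyc)) return(cyc)
    }
    state[[id]] <- "done"
    NULL
  }
  for (id in samples$sample_id) {
    cyc <- visit(id, character(0))
    if (!is.null(cyc)) return(cyc)
  }
  NULL
}

#' Pedigree lookups
#'
#' Accessors over a [build_pedigree()] result. `ped_parents()` returns the
#' known parent ids of a sample, `ped_children()` its children,
#' `ped_siblings()` samples sharing at least one known parent, and
#' `ped_founders()` the samples with no known parent.
#'
#' @param ped A `triage_pedigree`.
#' @param sample_id A single sample id.
#' @return A character vector of sample ids.
#' @name pedigree-lookups
NULL

#' @rdname pedigree-lookups
#' @export
ped_parents <- function(ped, sample_id) {
  row <- ped[ped$sample_id == sample_id, ]
  if (nrow(row) == 0) stop("unknown sample: ", sample_id, call. = FALSE)
  stats::na.omit(c(row$mother_id, row$father_id))
}

#' @rdname pedigree-lookups
#' @export
ped_children <- function(ped, sample_id) {
  ped$sample_id[!is.na(ped$mother_id) & ped$mother_id == sample_id |
                !is.na(ped$father_id) & ped$father_id == sample_id]
}

#' @rdname pedigree-lookups
#' @export
ped_siblings <- function(ped, sample_id) {
  own <- ped_parents(ped, sample_id)
  if (length(own) == 0) return(character(0))
  other <- ped[ped$sample_id != sample_id, ]
  share <- vapply(other$sample_id, function(id) {
    length(intersect(ped_parents(ped, id), own)) > 0
  }, logical(1))
  unname(other$sample_id[share])
}

#' @rdname pedigree-lookups
#' @export
ped_founders <- function(ped) {
  ped$sample_id[is.na(ped$mother_id) & is.na(ped$father_id)]
}

#' Cohort patients in a pedigree
#'
#' The probands of a triage run: every sample recorded as affected.
#' Relatives submitted only for segregation (unaffected or mildly affected
#' carriers, ungenotyped parents) are excluded.
#'
#' @param ped A `triage_pedigree`.
#' @return Character vector of sample ids.
#' @export
ped_patients <- function(ped) {
  ped$sample_id[ped$affected == "affected"]
}
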