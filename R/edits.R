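# Constrained interactive-editing operations. Every operation rebuilds
# and re-validates the pedigree before returning, so no edit can produce
# an invalid pedigree: it either returns a clean pedigree or raises a
# pedchart_constraint_error / pedchart_duplicate_id condition.

#' Describe an individual for an edit operation
#'
#' @param id Individual ID token (non-empty, no whitespace, not "0").
#' @param sex One of \code{"male"}, \code{"female"}, \code{"unknown"}.
#' @param phenotype One of \code{"unaffected"}, \code{"affected"},
#'   \code{"missing"}.
#' @param annotations Character vector of annotation keywords.
#' @return A list usable as the \code{child}/\code{partner}/parent
#'   argument of the edit operations.
#' @export
individual <- function(id, sex = "unknown", phenotype = "missing",
                       annotations = character()) {
  stopifnot_token(id, "individual id")
  if (id == "0") ped_stop("constraint_error", "individual ID must not be '0'")
  sex <- match.arg(sex, c("male", "female", "unknown"))
  phenotype <- match.arg(phenotype, c("unaffected", "affected", "missing"))
  list(id = id, sex = sex, phenotype = phenotype,
       annotations = unique(as.character(annotations)))
}

rebuild_and_check <- function(records, family_id) {
  ped <- build_pedigree(records, family_id)
  validate_or_stop(ped)
  ped
}

check_new_id <- function(ped, id) {
  if (id %in% ped$ind$id) {
    ped_stop("duplicate_id", sprintf("individual '%s' already exists", id))
  }
}

append_individual <- function(recs, family_id, spec, father = "0", mother = "0") {
  rbind(recs, new_record(family_id, spec$id, father, mother,
                         spec$sex, spec$phenotype, spec$annotations))
}

#' Edit operations on a pedigree
#'
#' Constrained edits mirroring interactive pedigree editing: each returns
#' a new, validated pedigree, or raises an error if the edit would break
#' the family logic. In particular, the sex of a current parent cannot be
#' changed, a miscarriage cannot have children, and an individual may have
#' at most two partners.
#'
#' \code{remove_individual} deletes a leaf outright; removing a parent
#' whose children remain substitutes an inferred placeholder parent so
#' that the children keep a full parent pair.
#'
#' @param pedigree A valid \code{pedigree}.
#' @param father_id,mother_id,id,old_id,new_id Individual IDs.
#' @param child,partner,father,mother Individual descriptions from
#'   \code{\link{individual}}.
#' @param sex,phenotype,annotation Attribute values; see
#'   \code{\link{individual}} for the accepted sex/phenotype levels.
#' @param on Logical: switch the annotation on or off.
#' @return The edited \code{pedigree}.
#' @name ped_edits
NULL

#' @rdname ped_edits
#' @export
add_child <- function(pedigree, father_id, mother_id, child) {
  stopifnot(inherits(pedigree, "pedigree"))
  check_new_id(pedigree, child$id)
  fi <- ind_row(pedigree, father_id)
  mi <- ind_row(pedigree, mother_id)
  for (i in c(fi, mi)) {
    if ("miscarriage" %in% pedigree$ind$annotations[[i]]) {
      ped_stop("constraint_error", sprintf(
        "'%s' is flagged as a miscarriage and cannot have children",
        pedigree$ind$id[i]))
    }
  }
  if (pedigree$ind$sex[fi] != "male") {
    ped_stop("constraint_error", sprintf("father '%s' must be male", father_id))
  }
  if (pedigree$ind$sex[mi] != "female") {
    ped_stop("constraint_error", sprintf("mother '%s' must be female", mother_id))
  }
  recs <- append_individual(ped_records(pedigree), pedigree$family_id, child,
                            father_id, mother_id)
  rebuild_and_check(recs, pedigree$family_id)
}

#' @rdname ped_edits
#' @export
add_partner <- function(pedigree, id, partner) {
  stopifnot(inherits(pedigree, "pedigree"))
  check_new_id(pedigree, partner$id)
  i <- ind_row(pedigree, id)
  sex <- pedigree$ind$sex[i]
  if (sex == "unknown") {
    ped_stop("constraint_error",
             sprintf("'%s' has unknown sex and cannot be a partner", id))
  }
  want <- if (sex == "male") "female" else "male"
  if (partner$sex == "unknown") partner$sex <- want
  if (partner$sex != want) {
    ped_stop("constraint_error", sprintf(
      "partner of %s '%s' must be %s", sex, id, want))
  }
  memb <- union_memberships(pedigree)
  if (length(memb[[id]]) >= 2L) {
    ped_stop("constraint_error",
             sprintf("'%s' already has two partners", id))
  }
  recs <- append_individual(ped_records(pedigree), pedigree$family_id, partner)
  ped <- build_pedigree(recs, pedigree$family_id)
  pair <- if (sex == "male") {
    data.frame(father_id = id, mother_id = partner$id, stringsAsFactors = FALSE)
  } else {
    data.frame(father_id = partner$id, mother_id = id, stringsAsFactors = FALSE)
  }
  ped$extra_unions <- rbind(pedigree$extra_unions, pair)
  ped <- derive_unions(ped)
  validate_or_stop(ped)
  ped
}

#' @rdname ped_edits
#' @export
add_parents <- function(pedigree, id, father, mother) {
  stopifnot(inherits(pedigree, "pedigree"))
  i <- ind_row(pedigree, id)
  if (pedigree$ind$father_id[i] != "0") {
    ped_stop("constraint_error", sprintf("'%s' already has parents", id))
  }
  check_new_id(pedigree, father$id)
  if (father$id == mother$id) {
    ped_stop("constraint_error", "father and mother must be distinct")
  }
  check_new_id(pedigree, mother$id)
  father$sex <- "male"; mother$sex <- "female"
  recs <- ped_records(pedigree)
  recs$father_id[recs$individual_id == id] <- father$id
  recs$mother_id[recs$individual_id == id] <- mother$id
  recs <- append_individual(recs, pedigree$family_id, father)
  recs <- append_individual(recs, pedigree$family_id, mother)
  rebuild_and_check(recs, pedigree$family_id)
}

#' @rdname ped_edits
#' @export
remove_individual <- function(pedigree, id) {
  stopifnot(inherits(pedigree, "pedigree"))
  ind_row(pedigree, id)
  recs <- ped_records(pedigree)
  recs <- recs[recs$individual_id != id, , drop = FALSE]
  # children keep a full parent pair: the removed parent becomes "0" and
  # normalization substitutes an inferred placeholder
  recs$father_id[recs$father_id == id] <- "0"
  recs$mother_id[recs$mother_id == id] <- "0"
  if (nrow(recs) == 0L) {
    ped_stop("constraint_error", "cannot remove the last individual")
  }
  extra <- pedigree$extra_unions
  extra <- extra[extra$father_id != id & extra$mother_id != id, , drop = FALSE]
  ped <- build_pedigree(recs, pedigree$family_id)
  ped$extra_unions <- extra
  ped <- derive_unions(ped)
  validate_or_stop(ped)
  ped
}

#' @rdname ped_edits
#' @export
set_sex <- function(pedigree, id, sex) {
  stopifnot(inherits(pedigree, "pedigree"))
  sex <- match.arg(sex, c("male", "female", "unknown"))
  i <- ind_row(pedigree, id)
  if (id %in% c(pedigree$ind$father_id, pedigree$ind$mother_id) ||
      any(vapply(pedigree$unions, function(u) id %in% c(u$father_id, u$mother_id),
                 logical(1)))) {
    if (sex != pedigree$ind$sex[i]) {
      ped_stop("constraint_error", sprintf(
        "the sex of '%s' cannot be changed: '%s' is a parent or partner", id, id))
    }
    return(pedigree)
  }
  recs <- ped_records(pedigree)
  recs$sex[recs$individual_id == id] <- sex
  rebuild_and_check(recs, pedigree$family_id)
}

#' @rdname ped_edits
#' @export
set_phenotype <- function(pedigree, id, phenotype) {
  stopifnot(inherits(pedigree, "pedigree"))
  phenotype <- match.arg(phenotype, c("unaffected", "affected", "missing"))
  ind_row(pedigree, id)
  recs <- ped_records(pedigree)
  recs$phenotype[recs$individual_id == id] <- phenotype
  rebuild_and_check(recs, pedigree$family_id)
}

#' @rdname ped_edits
#' @export
set_annotation <- function(pedigree, id, annotation, on = TRUE) {
  stopifnot(inherits(pedigree, "pedigree"), is_flag(on))
  stopifnot_token(annotation, "annotation keyword")
  i <- ind_row(pedigree, id)
  if (on && annotation == "miscarriage" &&
      id %in% c(pedigree$ind$father_id, pedigree$ind$mother_id)) {
    ped_stop("constraint_error", sprintf(
      "'%s' has children and cannot be flagged as a miscarriage", id))
  }
  recs <- ped_records(pedigree)
  j <- which(recs$individual_id == id)
  ann <- recs$annotations[[j]]
  ann <- if (on) union(ann, annotation) else setdiff(ann, annotation)
  recs$annotations[[j]] <- ann
  ped <- rebuild_and_check(recs, pedigree$family_id)
  ped$extra_unions <- pedigree$extra_unions
  derive_unions(ped)
}

#' @rdname ped_edits
#' @export
rename_individual <- function(pedigree, old_id, new_id) {
  stopifnot(inherits(pedigree, "pedigree"))
  stopifnot_token(new_id, "new individual id")
  ind_row(pedigree, old_id)
  if (new_id == "0") ped_stop("constraint_error", "individual ID must not be '0'")
  check_new_id(pedigree, new_id)
  recs <- ped_records(pedigree)
  recs$individual_id[recs$individual_id == old_id] <- new_id
  recs$father_id[recs$father_id == old_id] <- new_id
  recs$mother_id[recs$mother_id == old_id] <- new_id
  extra <- pedigree$extra_unions
  extra$father_id[extra$father_id == old_id] <- new_id
  extra$mother_id[extra$mother_id == old_id] <- new_id
  ped <- rebuild_and_check(recs, pedigree$family_id)
  ped$extra_unions <- extra
  derive_unions(ped)
}
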