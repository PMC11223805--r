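# Family graph: building, validation, consanguinity detection.

new_issue <- function(code, severity, subjects, message) {
  data.frame(code = code, severity = severity, message = message,
             subjects = I(list(subjects)), stringsAsFactors = FALSE)
}

empty_issues <- function() {
  data.frame(code = character(), severity = character(),
             message = character(), subjects = I(list()),
             stringsAsFactors = FALSE)
}

#' Build a pedigree object from PED records
#'
#' Indexes individuals, derives the unions (one per distinct
#' father--mother pair over the children, plus any explicitly asserted
#' childless partnership) and computes the founder set. A parent that is
#' referenced but has no record of its own is auto-created as an inferred
#' founder; this is reported as a \code{missing_parent_ref} warning by
#' \code{\link{validate_pedigree}}, not as an error.
#'
#' @param records A record data frame (as in a \code{ped_document}), all
#'   rows sharing one family ID.
#' @param family_id The family these records belong to; defaults to the
#'   single family ID present in \code{records}.
#' @return An object of class \code{pedigree}: a list with elements
#'   \code{family_id}, \code{ind} (individuals data frame in natural ID
#'   order), \code{unions} (list of father/mother/children/consanguineous),
#'   \code{founders} and \code{build_issues}.
#' @export
build_pedigree <- function(records, family_id = NULL) {
  if (inherits(records, "ped_document")) {
    fams <- split_families(records)
    if (length(fams) != 1L) {
      ped_stop("build_error",
               "document holds more than one family; use split_families()")
    }
    records <- fams[[1]]
  }
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    ped_stop("build_error", "cannot build a pedigree from zero records")
  }
  fam <- unique(records$family_id)
  if (is.null(family_id)) {
    if (length(fam) != 1L) {
      ped_stop("build_error", "records span multiple family IDs")
    }
    family_id <- fam
  } else if (!all(records$family_id == family_id)) {
    ped_stop("build_error", "records do not all share the given family ID")
  }

  dup <- duplicated(records$individual_id)
  if (any(dup)) {
    ped_stop("duplicate_id", sprintf(
      "duplicate individual ID(s): %s",
      paste(unique(records$individual_id[dup]), collapse = ", ")))
  }
  records <- normalize_single_parents(records)

  issues <- empty_issues()
  # repair dangling parent references as inferred founders
  referenced <- setdiff(unique(c(records$father_id, records$mother_id)), "0")
  missing <- setdiff(referenced, records$individual_id)
  for (pid in natural_sort(missing)) {
    sex <- if (pid %in% records$father_id) "male" else "female"
    records <- rbind(records,
                     new_record(family_id, pid, "0", "0", sex, "missing",
                                inferred = TRUE))
    issues <- rbind(issues, new_issue(
      "missing_parent_ref", "warning", pid,
      sprintf("parent '%s' is referenced but has no record; created as inferred founder", pid)))
  }

  ind <- records[natural_order(records$individual_id), , drop = FALSE]
  names(ind)[names(ind) == "individual_id"] <- "id"
  ind$family_id <- NULL
  rownames(ind) <- NULL

  ped <- structure(list(family_id = family_id, ind = ind,
                        unions = list(), founders = character(),
                        extra_unions = empty_partnerships(),
                        build_issues = issues),
                   class = "pedigree")
  derive_unions(ped)
}

empty_partnerships <- function() {
  data.frame(father_id = character(), mother_id = character(),
             stringsAsFactors = FALSE)
}

# (Re)derive unions and founders from the individual table plus asserted
# childless partnerships; union order is natural order of (father, mother).
derive_unions <- function(ped) {
  ind <- ped$ind
  has_parents <- ind$father_id != "0"
  keys <- paste(ind$father_id[has_parents], ind$mother_id[has_parents],
                sep = "\r")
  children <- split(ind$id[has_parents], keys)
  extra <- ped$extra_unions
  if (nrow(extra) > 0L) {
    ekeys <- paste(extra$father_id, extra$mother_id, sep = "\r")
    for (k in setdiff(ekeys, names(children))) children[[k]] <- character()
  }
  if (length(children) > 0L) {
    pairs <- do.call(rbind, strsplit(names(children), "\r", fixed = TRUE))
    ord <- order(natural_key(pairs[, 1]), natural_key(pairs[, 2]))
    ped$unions <- lapply(ord, function(i) {
      list(father_id = pairs[i, 1], mother_id = pairs[i, 2],
           children = natural_sort(children[[i]]),
           consanguineous = "no")
    })
  } else {
    ped$unions <- list()
  }
  ped$founders <- ind$id[ind$father_id == "0"]
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  n_con <- sum(vapply(x$unions, function(u) u$consanguineous != "no", logical(1)))
  cat(sprintf("Pedigree '%s': %d individuals, %d unions (%d consanguineous), %d founders\n",
              x$family_id, nrow(x$ind), length(x$unions), n_con,
              length(x$founders)))
  invisible(x)
}

#' Individual records of a pedigree, in PED-document form
#'
#' @param pedigree A \code{pedigree} object.
#' @return A record data frame with a \code{family_id} column, suitable
#'   for \code{\link{build_pedigree}}.
#' @export
ped_records <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  ind <- pedigree$ind
  data.frame(family_id = pedigree$family_id, individual_id = ind$id,
             father_id = ind$father_id, mother_id = ind$mother_id,
             sex = ind$sex, phenotype = ind$phenotype,
             annotations = I(ind$annotations), inferred = ind$inferred,
             stringsAsFactors = FALSE)
}

ind_row <- function(ped, id) {
  i <- match(id, ped$ind$id)
  if (is.na(i)) {
    ped_stop("lookup_error", sprintf("unknown individual '%s'", id))
  }
  i
}

# unions each individual participates in (as a partner), by index
union_memberships <- function(ped) {
  m <- lapply(ped$ind$id, function(id) integer())
  names(m) <- ped$ind$id
  for (k in seq_along(ped$unions)) {
    u <- ped$unions[[k]]
    for (p in c(u$father_id, u$mother_id)) m[[p]] <- c(m[[p]], k)
  }
  m
}

#' Validate the logical consistency of a pedigree
#'
#' Checks for impossible or unsupported structures: individuals who are
#' their own ancestors (cycles of any length), fathers that are not male or
#' mothers that are not female (unknown-sex parents count as conflicts),
#' miscarriage-flagged individuals with children, matings that would force
#' one person onto two different generation rows (generation-spanning
#' parents), and individuals with more than two partners. Warnings (such
#' as auto-repaired dangling parent references) do not block drawing;
#' errors do.
#'
#' @param pedigree A \code{pedigree} object.
#' @return A data frame of issues with columns \code{code},
#'   \code{severity} (\code{"error"} or \code{"warning"}), \code{message}
#'   and \code{subjects} (list column of individual IDs). Zero error rows
#'   means the pedigree is drawable.
#' @export
validate_pedigree <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  ped <- pedigree
  ind <- ped$ind
  issues <- ped$build_issues

  self <- ind$id == ind$father_id | ind$id == ind$mother_id
  for (id in ind$id[self]) {
    issues <- rbind(issues, new_issue(
      "self_parent", "error", id,
      sprintf("'%s' is recorded as its own parent", id)))
  }
  if (any(self)) return(issues)

  fathers <- unique(ind$father_id[ind$father_id != "0"])
  mothers <- unique(ind$mother_id[ind$mother_id != "0"])
  for (f in fathers) {
    s <- ind$sex[match(f, ind$id)]
    if (!is.na(s) && s != "male") {
      issues <- rbind(issues, new_issue(
        "parent_sex_conflict", "error", f,
        sprintf("'%s' is referenced as a father but has sex '%s'", f, s)))
    }
  }
  for (m in mothers) {
    s <- ind$sex[match(m, ind$id)]
    if (!is.na(s) && s != "female") {
      issues <- rbind(issues, new_issue(
        "parent_sex_conflict", "error", m,
        sprintf("'%s' is referenced as a mother but has sex '%s'", m, s)))
    }
  }
  both <- intersect(fathers, mothers)
  for (p in both) {
    issues <- rbind(issues, new_issue(
      "parent_sex_conflict", "error", p,
      sprintf("'%s' is referenced both as a father and as a mother", p)))
  }

  parents <- unique(c(fathers, mothers))
  for (id in ind$id[vapply(ind$annotations, function(a) "miscarriage" %in% a,
                           logical(1))]) {
    if (id %in% parents) {
      issues <- rbind(issues, new_issue(
        "miscarriage_with_children", "error", id,
        sprintf("'%s' is flagged as a miscarriage but has children", id)))
    }
  }

  cyc <- cycle_members(ped)
  if (length(cyc) > 0L) {
    issues <- rbind(issues, new_issue(
      "cycle", "error", cyc,
      sprintf("impossible pedigree: %s would be their own ancestor(s)",
              paste(natural_sort(cyc), collapse = ", "))))
    return(issues)
  }

  gen <- try_generations(ped)
  if (!is.null(gen$conflict)) {
    issues <- rbind(issues, new_issue(
      "generation_conflict", "error", gen$conflict,
      sprintf("generation-spanning mating: %s cannot be placed on a single generation row",
              paste(natural_sort(gen$conflict), collapse = ", "))))
  }

  memb <- union_memberships(ped)
  over <- names(memb)[vapply(memb, length, integer(1)) > 2L]
  for (id in over) {
    issues <- rbind(issues, new_issue(
      "nested_loop_unsupported", "error", id,
      sprintf("'%s' has more than two partners; such structures cannot be drawn", id)))
  }
  issues
}

# ids that lie on a directed cycle of the parent->child relation:
# repeatedly strip nodes with no remaining parents, then nodes that are
# not parents of any remaining node; what survives both prunes is cyclic
cycle_members <- function(ped) {
  ind <- ped$ind
  ids <- ind$id
  alive <- stats::setNames(rep(TRUE, length(ids)), ids)
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      if (!alive[i]) next
      ps <- setdiff(c(ind$father_id[i], ind$mother_id[i]), "0")
      ps <- ps[ps %in% ids]  # dangling references cannot close a cycle
      if (!any(alive[ps])) { alive[i] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  repeat {
    parents_of_alive <- unique(c(ind$father_id[alive], ind$mother_id[alive]))
    drop <- alive & !(ids %in% parents_of_alive)
    if (!any(drop)) break
    alive[drop] <- FALSE
  }
  ids[alive]
}

# Generation propagation: partners share a row, a child sits one row below
# its parents. Returns list(gen = named integer (min 0 per component),
# conflict = NULL or the ids where constraints clash).
try_generations <- function(ped, max_iterations = 100L) {
  ids <- ped$ind$id
  n <- length(ids)
  gen <- rep(NA_integer_, n)
  names(gen) <- ids
  # adjacency: list of (neighbour index, offset) meaning gen[nb] = gen[i] + off
  adj <- vector("list", n)
  add_edge <- function(i, j, off) {
    adj[[i]][[length(adj[[i]]) + 1L]] <<- c(j, off)
    adj[[j]][[length(adj[[j]]) + 1L]] <<- c(i, -off)
  }
  for (u in ped$unions) {
    fi <- match(u$father_id, ids); mi <- match(u$mother_id, ids)
    add_edge(fi, mi, 0L)
    for (ch in u$children) add_edge(fi, match(ch, ids), 1L)
  }
  conflict <- character()
  for (start in seq_len(n)) {
    if (!is.na(gen[start])) next
    gen[start] <- 0L
    queue <- start
    passes <- 0L
    while (length(queue) > 0L) {
      passes <- passes + 1L
      if (passes > max_iterations * n + n) {
        ped_stop("unsupported", "generation assignment did not converge")
      }
      i <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[i]]) {
        j <- e[1L]; want <- gen[i] + e[2L]
        if (is.na(gen[j])) {
          gen[j] <- want
          queue <- c(queue, j)
        } else if (gen[j] != want) {
          conflict <- union(conflict, ids[c(i, j)])
        }
      }
    }
  }
  # normalize each connected component to minimum 0
  comp_id <- component_ids(adj, n)
  for (c in unique(comp_id)) {
    sel <- comp_id == c
    gen[sel] <- gen[sel] - min(gen[sel])
  }
  list(gen = gen, conflict = if (length(conflict)) conflict else NULL)
}

component_ids <- function(adj, n) {
  comp <- rep(NA_integer_, n)
  next_id <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    next_id <- next_id + 1L
    queue <- start
    comp[start] <- next_id
    while (length(queue) > 0L) {
      i <- queue[1L]; queue <- queue[-1L]
      for (e in adj[[i]]) {
        j <- e[1L]
        if (is.na(comp[j])) { comp[j] <- next_id; queue <- c(queue, j) }
      }
    }
  }
  comp
}

validate_or_stop <- function(ped) {
  iss <- validate_pedigree(ped)
  err <- iss[iss$severity == "error", , drop = FALSE]
  if (nrow(err) > 0L) {
    ped_stop("validation_error",
             paste0("pedigree is not valid:\n",
                    paste(sprintf("  [%s] %s", err$code, err$message),
                          collapse = "\n")),
             issues = iss)
  }
  invisible(iss)
}

#' Ancestors of an individual
#'
#' Transitive closure over the parent links, excluding the individual
#' itself (and including inferred placeholder parents).
#'
#' @param pedigree A \code{pedigree} object with an acyclic parent relation.
#' @param id An individual ID present in the pedigree.
#' @return Character vector of ancestor IDs (possibly empty), in natural
#'   sort order.
#' @export
ancestors <- function(pedigree, id) {
  stopifnot(inherits(pedigree, "pedigree"))
  ind <- pedigree$ind
  i <- ind_row(pedigree, id)
  seen <- character()
  frontier <- setdiff(c(ind$father_id[i], ind$mother_id[i]), "0")
  guard <- 0L
  while (length(frontier) > 0L) {
    guard <- guard + 1L
    if (guard > nrow(ind) + 1L) {
      ped_stop("validation_error",
               sprintf("parent relation contains a cycle reachable from '%s'", id))
    }
    seen <- union(seen, frontier)
    rows <- match(frontier, ind$id)
    rows <- rows[!is.na(rows)]
    frontier <- setdiff(unique(c(ind$father_id[rows], ind$mother_id[rows])),
                        c("0", seen))
  }
  natural_sort(seen)
}

#' Detect consanguineous unions
#'
#' A union is marked \code{"auto"} when the two partners share at least one
#' common ancestor within the pedigree, or when one partner is an ancestor
#' of the other. It is marked \code{"asserted"} when either partner carries
#' the manual \code{consanguineous_partner} annotation, which lets users
#' declare relatedness even when the shared ancestors are not part of the
#' chart; \code{"asserted"} takes precedence over \code{"auto"} in the
#' report, and both render as a double partner line.
#'
#' @param pedigree A \code{pedigree} whose parent relation is acyclic
#'   (cycle errors from \code{\link{validate_pedigree}} must be absent).
#' @return The pedigree with each union's \code{consanguineous} field set
#'   to \code{"no"}, \code{"auto"} or \code{"asserted"}.
#' @export
detect_consanguinity <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  if (length(cycle_members(pedigree)) > 0L) {
    ped_stop("validation_error",
             "cannot detect consanguinity: parent relation contains a cycle")
  }
  ped <- pedigree
  anc <- lapply(ped$ind$id, function(id) ancestors(ped, id))
  names(anc) <- ped$ind$id
  flagged <- ped$ind$id[vapply(ped$ind$annotations,
                               function(a) "consanguineous_partner" %in% a,
                               logical(1))]
  ped$unions <- lapply(ped$unions, function(u) {
    f <- u$father_id; m <- u$mother_id
    related <- length(intersect(anc[[f]], anc[[m]])) > 0L ||
      f %in% anc[[m]] || m %in% anc[[f]]
    u$consanguineous <-
      if (f %in% flagged || m %in% flagged) "asserted"
      else if (related) "auto"
      else "no"
    u
  })
  ped
}

#' Compare two pedigrees for semantic equality
#'
#' Two pedigrees are equal when they describe the same family: same
#' individual IDs with the same parent links, sex, phenotype and
#' annotation sets. Inferred placeholder parents (\code{_p} ids) are
#' compared structurally, not by name, so a pedigree survives a
#' write/parse round trip even though placeholder numbering may differ.
#'
#' @param a,b \code{pedigree} objects.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
ped_equal <- function(a, b) {
  stopifnot(inherits(a, "pedigree"), inherits(b, "pedigree"))
  canon <- function(p) {
    ind <- p$ind[natural_order(p$ind$id), , drop = FALSE]
    ph <- ind$inferred & grepl("^_p[0-9]+$", ind$id)
    ph_ids <- ind$id[ph]
    ind <- ind[!ph, , drop = FALSE]
    ind$father_id[ind$father_id %in% ph_ids] <- "0"
    ind$mother_id[ind$mother_id %in% ph_ids] <- "0"
    lines <- vapply(seq_len(nrow(ind)), function(i) {
      paste(ind$id[i], ind$father_id[i], ind$mother_id[i], ind$sex[i],
            ind$phenotype[i], annotation_string(ind$annotations[[i]]))
    }, character(1))
    paste(c(p$family_id, lines), collapse = "\n")
  }
  identical(canon(a), canon(b))
}
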