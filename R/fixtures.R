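# Synthetic pedigree generation. The generator emulates the structure of
# clinical human pedigrees: one founding couple, sibships of 1-8 children
# (truncated-Poisson sized), children marrying unrelated founders, an
# occasional second partner, and optionally a planted first-cousin
# consanguineous loop. IDs are assigned in generation-then-birth order so
# natural ID sorting reproduces the intended left-to-right order.

#' Parameters for the synthetic pedigree generator
#'
#' @param n_generations Number of generation rows (>= 1).
#' @param mean_children Mean sibship size (Poisson, truncated to 1..8).
#' @param p_second_partner Probability that a married non-founder takes a
#'   second partner.
#' @param p_consanguineous_loop Probability of planting one first-cousin
#'   loop (needs \code{n_generations >= 3}).
#' @param p_annotations Per-flag probability of auxiliary annotations
#'   (deceased, miscarriage, proband, consultand, manual relatedness).
#' @param p_marry Probability that a child founds a family of their own.
#' @param max_individuals Soft cap on pedigree size.
#' @param seed Integer seed; equal seeds give identical pedigrees.
#' @return A \code{generator_params} list.
#' @export
generator_params <- function(n_generations = 4, mean_children = 2.5,
                             p_second_partner = 0.15,
                             p_consanguineous_loop = 0.2,
                             p_annotations = 0.1, p_marry = 0.6,
                             max_individuals = 40L, seed = 1L) {
  p <- list(n_generations = as.integer(n_generations),
            mean_children = mean_children,
            p_second_partner = p_second_partner,
            p_consanguineous_loop = p_consanguineous_loop,
            p_annotations = p_annotations, p_marry = p_marry,
            max_individuals = as.integer(max_individuals),
            seed = as.integer(seed))
  probs <- unlist(p[c("p_second_partner", "p_consanguineous_loop",
                      "p_annotations", "p_marry")])
  if (p$n_generations < 1L || p$mean_children <= 0 ||
      any(probs < 0 | probs > 1)) {
    ped_stop("parse_error", "invalid generator parameters")
  }
  structure(p, class = "generator_params")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic pedigree
#'
#' @param params A \code{\link{generator_params}} object.
#' @param family_id Family ID token for the generated records.
#' @return A \code{\link{pedigree}} that passes
#'   \code{\link{validate_pedigree}} with zero errors, with consanguinity
#'   flags already detected.
#' @export
generate_pedigree <- function(params = generator_params(), family_id = "FAM") {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, generate_pedigree_impl(params, family_id))
}

generate_pedigree_impl <- function(params, family_id) {
  sexes <- character()      # per person
  father <- character(); mother <- character()
  person_gen <- integer()
  persons <- character()
  unions <- list()          # list(f, m, children (birth order), gen)

  new_person <- function(sex, gen, fa = "0", mo = "0") {
    nm <- paste0("tmp", length(persons) + 1L)
    persons[[length(persons) + 1L]] <<- nm
    sexes[[nm]] <<- sex
    father[[nm]] <<- fa
    mother[[nm]] <<- mo
    person_gen[[nm]] <<- gen
    nm
  }
  sib_size <- function() {
    k <- stats::rpois(1, params$mean_children)
    min(max(k, 1L), 8L)
  }

  f0 <- new_person("male", 0L)
  m0 <- new_person("female", 0L)
  unions[[1]] <- list(f = f0, m = m0, children = character(), gen = 0L)

  n_unions_of <- function(p) {
    sum(vapply(unions, function(u) p %in% c(u$f, u$m), logical(1)))
  }

  for (g in seq_len(max(params$n_generations - 1L, 0L))) {
    gu <- which(vapply(unions, function(u) u$gen == g - 1L, logical(1)))
    for (k in gu) {
      if (length(persons) >= params$max_individuals) break
      n_ch <- sib_size()
      for (j in seq_len(n_ch)) {
        if (length(persons) >= params$max_individuals) break
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        ch <- new_person(sex, g, unions[[k]]$f, unions[[k]]$m)
        unions[[k]]$children <- c(unions[[k]]$children, ch)
        if (g < params$n_generations - 1L &&
            stats::runif(1) < params$p_marry &&
            length(persons) < params$max_individuals) {
          sp <- new_person(if (sex == "male") "female" else "male", g)
          u <- if (sex == "male") list(f = ch, m = sp) else list(f = sp, m = ch)
          unions[[length(unions) + 1L]] <- c(u, list(children = character(),
                                                     gen = g))
          if (stats::runif(1) < params$p_second_partner &&
              length(persons) < params$max_individuals) {
            sp2 <- new_person(if (sex == "male") "female" else "male", g)
            u2 <- if (sex == "male") list(f = ch, m = sp2)
                  else list(f = sp2, m = ch)
            unions[[length(unions) + 1L]] <- c(u2, list(children = character(),
                                                        gen = g))
          }
        }
      }
    }
  }

  # plant one first-cousin loop: the father comes last in the left
  # branch's sibship, the mother first in the adjacent right branch's
  if (params$n_generations >= 3L &&
      stats::runif(1) < params$p_consanguineous_loop) {
    # make sure the root couple has two adjacent children married exactly
    # once, marrying in fresh spouses where needed
    while (length(unions[[1]]$children) < 2L) {
      sex <- if (stats::runif(1) < 0.5) "male" else "female"
      ch <- new_person(sex, 1L, unions[[1]]$f, unions[[1]]$m)
      unions[[1]]$children <- c(unions[[1]]$children, ch)
    }
    root_ch <- unions[[1]]$children
    usable <- vapply(root_ch, function(p) n_unions_of(p) <= 1L, logical(1))
    adj <- which(usable[-length(usable)] & usable[-1])
    if (length(adj) == 0L) {
      # no adjacent usable pair: append two fresh root children
      for (j in 1:2) {
        sex <- if (stats::runif(1) < 0.5) "male" else "female"
        ch <- new_person(sex, 1L, unions[[1]]$f, unions[[1]]$m)
        unions[[1]]$children <- c(unions[[1]]$children, ch)
      }
      root_ch <- unions[[1]]$children
      adj <- length(root_ch) - 1L
    }
    if (length(adj) > 0L) {
      a <- root_ch[adj[1]]; b <- root_ch[adj[1] + 1L]
      for (p in c(a, b)) {
        if (n_unions_of(p) == 0L) {
          sp <- new_person(if (sexes[[p]] == "male") "female" else "male", 1L)
          u <- if (sexes[[p]] == "male") list(f = p, m = sp)
               else list(f = sp, m = p)
          unions[[length(unions) + 1L]] <- c(u, list(children = character(),
                                                     gen = 1L))
        }
      }
      ua <- which(vapply(unions, function(u) a %in% c(u$f, u$m) & u$gen == 1L,
                         logical(1)))[1]
      ub <- which(vapply(unions, function(u) b %in% c(u$f, u$m) & u$gen == 1L,
                         logical(1)))[1]
      X <- new_person("male", 2L, unions[[ua]]$f, unions[[ua]]$m)
      Y <- new_person("female", 2L, unions[[ub]]$f, unions[[ub]]$m)
      unions[[ua]]$children <- c(unions[[ua]]$children, X)
      unions[[ub]]$children <- c(Y, unions[[ub]]$children)
      # the loop union always gets offspring (a childless couple cannot
      # be expressed in PED), adding a fourth row when n_generations is 3
      lu <- list(f = X, m = Y, children = character(), gen = 2L)
      for (j in seq_len(min(sib_size(), 3L))) {
        ch <- new_person(if (stats::runif(1) < 0.5) "male" else "female",
                         3L, X, Y)
        lu$children <- c(lu$children, ch)
      }
      unions[[length(unions) + 1L]] <- lu
    }
  }

  # final IDs in generation-then-birth order: children of each union in
  # creation order, then the founders/spouses of that generation
  final_id <- character()
  counter <- 0L
  take <- function(p) {
    counter <<- counter + 1L
    final_id[[p]] <<- sprintf("P%d", counter)
  }
  for (g in 0:max(person_gen)) {
    for (u in unions) {
      for (ch in u$children) if (person_gen[[ch]] == g && is.na(final_id[ch] %||% NA)) take(ch)
    }
    for (p in persons) {
      if (person_gen[[p]] == g && is.na(final_id[p] %||% NA)) take(p)
    }
  }

  # annotations
  ann <- stats::setNames(vector("list", length(persons)), persons)
  for (p in persons) ann[[p]] <- character()
  is_parent <- unique(unlist(lapply(unions, function(u)
    if (length(u$children)) c(u$f, u$m) else character())))
  in_union <- unique(unlist(lapply(unions, function(u) c(u$f, u$m))))
  pheno <- stats::setNames(
    sample(c("affected", "unaffected", "missing"), length(persons),
           replace = TRUE, prob = c(0.25, 0.70, 0.05)), persons)
  for (p in persons) {
    if (stats::runif(1) < params$p_annotations) {
      ann[[p]] <- c(ann[[p]], "deceased")
    }
    if (!(p %in% in_union) && stats::runif(1) < params$p_annotations / 2) {
      ann[[p]] <- c(ann[[p]], "miscarriage")
    }
  }
  affected <- persons[pheno[persons] == "affected"]
  if (length(affected) > 0L && stats::runif(1) < 3 * params$p_annotations) {
    pb <- sample(affected, 1L)
    ann[[pb]] <- union(ann[[pb]], "proband")
  }
  if (stats::runif(1) < params$p_annotations) {
    cand <- persons[!vapply(ann, function(a) "proband" %in% a, logical(1))]
    if (length(cand)) {
      cs <- sample(cand, 1L)
      ann[[cs]] <- union(ann[[cs]], "consultand")
    }
  }
  if (stats::runif(1) < params$p_annotations && length(unions) > 0L) {
    u <- unions[[sample(length(unions), 1L)]]
    ann[[u$f]] <- union(ann[[u$f]], "consanguineous_partner")
  }

  recs <- empty_records()
  for (p in persons) {
    fa <- if (father[[p]] == "0") "0" else final_id[[father[[p]]]]
    mo <- if (mother[[p]] == "0") "0" else final_id[[mother[[p]]]]
    recs <- rbind(recs, new_record(family_id, final_id[[p]], fa, mo,
                                   sexes[[p]], pheno[[p]], ann[[p]]))
  }
  ped <- build_pedigree(recs, family_id)
  iss <- validate_pedigree(ped)
  if (any(iss$severity == "error")) {
    stop("internal error: generated pedigree failed validation")
  }
  detect_consanguinity(ped)
}

#' Plant a structural defect into a valid pedigree
#'
#' Produces a record list that, when built and validated, exhibits the
#' requested issue; used for negative testing of the validation logic.
#'
#' @param pedigree A valid \code{pedigree}.
#' @param defect One of \code{"cycle"}, \code{"parent_sex_conflict"},
#'   \code{"miscarriage_with_children"}, \code{"dangling_parent"}.
#' @return A record data frame (pass to \code{\link{build_pedigree}}).
#' @export
plant_defect <- function(pedigree, defect = c("cycle", "parent_sex_conflict",
                                              "miscarriage_with_children",
                                              "dangling_parent")) {
  stopifnot(inherits(pedigree, "pedigree"))
  defect <- match.arg(defect)
  recs <- ped_records(pedigree)
  with_children <- vapply(pedigree$unions, function(u) length(u$children) > 0L,
                          logical(1))
  if (!any(with_children)) {
    ped_stop("constraint_error",
             sprintf("cannot plant '%s': the pedigree has no parent-child link",
                     defect))
  }
  u <- pedigree$unions[[which(with_children)[1]]]
  child <- u$children[1]
  switch(defect,
    cycle = {
      # make the child's father a child of the child: a two-person cycle
      i <- which(recs$individual_id == u$father_id)
      recs$father_id[i] <- child
      recs$mother_id[i] <- "0"
      sx <- recs$sex[recs$individual_id == child]
      if (sx != "male") {
        recs$father_id[i] <- "0"
        recs$mother_id[i] <- child
        if (sx != "female") recs$sex[recs$individual_id == child] <- "female"
      }
    },
    parent_sex_conflict = {
      recs$sex[recs$individual_id == u$father_id] <- "female"
    },
    miscarriage_with_children = {
      i <- which(recs$individual_id == u$father_id)
      recs$annotations[[i]] <- union(recs$annotations[[i]], "miscarriage")
    },
    dangling_parent = {
      i <- which(recs$individual_id == child)
      recs$father_id[i] <- "ZZmissing"
    })
  recs
}
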