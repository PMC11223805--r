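test_that("build_pedigree derives unions, founders and repairs dangling parents", {
  ped <- figure_family()
  expect_length(ped$unions, 1L)
  expect_equal(ped$unions[[1]]$children, c("C1", "C2", "C3"))
  expect_setequal(ped$founders, c("F1", "M1"))

  solo <- build_pedigree(parse_ped("S A 0 0 1 1")$records)
  expect_length(solo$unions, 0L)
  expect_equal(solo$founders, "A")

  # one father, two mothers -> two unions sharing the father
  two <- build_pedigree(parse_ped(c(
    "T F 0 0 1 1", "T M1 0 0 2 1", "T M2 0 0 2 1",
    "T C1 F M1 1 1", "T C2 F M2 2 1"))$records)
  expect_length(two$unions, 2L)
  expect_equal(vapply(two$unions, `[[`, character(1), "father_id"), c("F", "F"))

  # dangling parent reference becomes an inferred founder + warning issue
  dang <- build_pedigree(parse_ped(c("D M 0 0 2 1", "D C ZZ M 1 1"))$records)
  iss <- validate_pedigree(dang)
  expect_true("missing_parent_ref" %in% iss$code)
  expect_true(all(iss$severity[iss$code == "missing_parent_ref"] == "warning"))
  expect_true("ZZ" %in% dang$ind$id)
  expect_true(dang$ind$inferred[dang$ind$id == "ZZ"])
})

test_that("validate_pedigree detects each impossible-structure class", {
  # two-person cycle: each is the other's parent
  cyc <- data.frame(family_id = "X", individual_id = c("A", "B"),
                    father_id = c("B", "A"), mother_id = c("0", "0"),
                    sex = c("male", "male"),
                    phenotype = c("unaffected", "unaffected"),
                    annotations = I(list(character(), character())),
                    inferred = FALSE, stringsAsFactors = FALSE)
  iss <- validate_pedigree(build_pedigree(cyc))
  expect_true("cycle" %in% iss$code)
  expect_setequal(intersect(iss$subjects[[which(iss$code == "cycle")]],
                            c("A", "B")), c("A", "B"))

  # father recorded as female
  recs <- parse_ped(c("P F 0 0 2 1", "P M 0 0 2 1", "P C F M 1 1"))$records
  iss <- validate_pedigree(build_pedigree(recs))
  expect_true("parent_sex_conflict" %in% iss$code)
  # unknown-sex parent is a conflict too
  recs2 <- parse_ped(c("P F 0 0 0 1", "P M 0 0 2 1", "P C F M 1 1"))$records
  expect_true("parent_sex_conflict" %in%
                validate_pedigree(build_pedigree(recs2))$code)

  # miscarriage with children
  recs3 <- parse_ped(c("P F 0 0 1 1 miscarriage", "P M 0 0 2 1",
                       "P C F M 1 1"))$records
  iss3 <- validate_pedigree(build_pedigree(recs3))
  expect_true("miscarriage_with_children" %in% iss3$code)
  expect_equal(iss3$subjects[[which(iss3$code == "miscarriage_with_children")]],
               "F")

  # generation-spanning mating (uncle-niece)
  iss4 <- validate_pedigree(build_pedigree(uncle_niece_records()))
  expect_true("generation_conflict" %in% iss4$code)

  # a valid family has no errors
  expect_equal(sum(validate_pedigree(figure_family())$severity == "error"), 0L)
})

test_that("cycle detection agrees with a topological-sort oracle", {
  for (s in 0:49) {
    p <- gen_ped(s)
    recs <- ped_records(p)
    expect_false(oracle_has_cycle(recs))
    expect_false("cycle" %in% validate_pedigree(p)$code)
    if (length(p$unions) > 0 &&
        any(lengths(lapply(p$unions, `[[`, "children")) > 0)) {
      bad <- plant_defect(p, "cycle")
      expect_true(oracle_has_cycle(bad), info = paste("seed", s))
      expect_true("cycle" %in% validate_pedigree(build_pedigree(bad))$code,
                  info = paste("seed", s))
    }
  }
})

test_that("ancestors matches exhaustive path enumeration", {
  ped <- build_pedigree(cousin_loop_records())
  expect_length(ancestors(ped, "G1"), 0L)
  expect_setequal(ancestors(ped, "A1"), c("G1", "G2"))
  expect_setequal(ancestors(ped, "X1"), c("A1", "A2", "G1", "G2"))
  expect_setequal(ancestors(ped, "K1"),
                  c("X1", "Y1", "A1", "A2", "B1", "B2", "G1", "G2"))
  for (s in 0:29) {
    p <- gen_ped(s)
    for (id in p$ind$id) {
      expect_equal(sort(ancestors(p, id)), oracle_ancestors(p, id),
                   info = paste("seed", s, "id", id))
    }
  }
  expect_error(ancestors(ped, "nobody"), class = "pedchart_lookup_error")
})

test_that("consanguinity detection agrees with the brute-force oracle", {
  # planted first-cousin loop
  loop <- detect_consanguinity(build_pedigree(cousin_loop_records()))
  flags <- vapply(loop$unions, `[[`, character(1), "consanguineous")
  who <- vapply(loop$unions, function(u) paste(u$father_id, u$mother_id),
                character(1))
  expect_equal(flags[who == "X1 Y1"], "auto")
  expect_true(all(flags[who != "X1 Y1"] == "no"))

  # uncle-niece and ancestor-descendant count as consanguineous
  un <- detect_consanguinity(build_pedigree(uncle_niece_records()))
  unw <- vapply(un$unions, function(u) paste(u$father_id, u$mother_id),
                character(1))
  expect_equal(vapply(un$unions, `[[`, character(1), "consanguineous")[
    unw == "U1 N1"], "auto")

  # double first cousins' offspring union shares two grandparental couples
  dc <- detect_consanguinity(build_pedigree(double_cousin_records()))
  dcw <- vapply(dc$unions, function(u) paste(u$father_id, u$mother_id),
                character(1))
  expect_equal(vapply(dc$unions, `[[`, character(1), "consanguineous")[
    dcw == "X1 Y1"], "auto")

  # manual flag on founders whose ancestors are absent from the chart
  fig <- detect_consanguinity(figure_family())
  expect_equal(fig$unions[[1]]$consanguineous, "asserted")

  # two plain founders are never consanguineous
  plain <- detect_consanguinity(build_pedigree(parse_ped(
    c("P F 0 0 1 1", "P M 0 0 2 1", "P C F M 1 1"))$records))
  expect_equal(plain$unions[[1]]$consanguineous, "no")

  for (s in 0:39) {
    p <- gen_ped(s, n_generations = 3 + s %% 3,
                 p_consanguineous_loop = (s %% 2))
    for (u in p$unions) {
      expected <- if (oracle_consanguineous(p, u$father_id, u$mother_id))
        c("auto", "asserted") else c("no", "asserted")
      expect_true(u$consanguineous %in% expected,
                  info = paste("seed", s, u$father_id, u$mother_id))
    }
  }
})

test_that("edit operations apply atomically and enforce the family logic", {
  ped <- figure_family()

  # constructive edits
  p2 <- add_child(ped, "F1", "M1", individual("C4", "male", "affected"))
  expect_equal(p2$unions[[1]]$children, c("C1", "C2", "C3", "C4"))
  p3 <- add_partner(ped, "C1", individual("H1"))
  expect_equal(p3$ind$sex[p3$ind$id == "H1"], "male")
  expect_length(p3$unions, 2L)
  p4 <- add_parents(ped, "F1", individual("GF"), individual("GM"))
  expect_equal(p4$ind$father_id[p4$ind$id == "F1"], "GF")
  p5 <- set_phenotype(ped, "C2", "affected")
  expect_equal(p5$ind$phenotype[p5$ind$id == "C2"], "affected")
  p6 <- set_annotation(ped, "C2", "proband")
  expect_true("proband" %in% p6$ind$annotations[[match("C2", p6$ind$id)]])

  # rename updates references atomically and is invertible
  p7 <- rename_individual(ped, "F1", "K9")
  expect_true(all(p7$ind$father_id[p7$ind$id %in% c("C1", "C2", "C3")] == "K9"))
  expect_true(ped_equal(rename_individual(p7, "K9", "F1"), ped))
  expect_error(rename_individual(ped, "F1", "M1"), class = "pedchart_duplicate_id")

  # constrained edits are rejected
  expect_error(set_sex(ped, "F1", "female"), "cannot be changed",
               class = "pedchart_constraint_error")
  expect_error(add_child(ped, "F1", "M1", individual("C1")),
               class = "pedchart_duplicate_id")
  misc <- set_annotation(ped, "C3", "miscarriage")
  expect_error(add_child(misc, "F1", "M1", individual("Z", "male")),
               NA)  # other children still fine
  ml <- add_partner(misc, "C1", individual("H1"))
  expect_error(set_annotation(ml, "C1", "miscarriage"), NA) # childless union ok
  withkid <- add_child(ml, "H1", "C1", individual("G1", "male"))
  expect_error(set_annotation(withkid, "C1", "miscarriage"),
               class = "pedchart_constraint_error")
  expect_error(add_child(withkid, "H1", "C3", individual("G2")),
               class = "pedchart_constraint_error")  # C3 is a miscarriage

  # set_sex on a non-parent works
  p8 <- set_sex(ped, "C2", "unknown")
  expect_equal(p8$ind$sex[p8$ind$id == "C2"], "unknown")

  # removing a parent substitutes a placeholder, removing a leaf deletes
  p9 <- remove_individual(ped, "F1")
  expect_false("F1" %in% p9$ind$id)
  kid_fathers <- p9$ind$father_id[p9$ind$id %in% c("C1", "C2", "C3")]
  expect_length(unique(kid_fathers), 1L)
  expect_true(p9$ind$inferred[p9$ind$id == unique(kid_fathers)])
  p10 <- remove_individual(ped, "C3")
  expect_false("C3" %in% p10$ind$id)
  expect_equal(p10$unions[[1]]$children, c("C1", "C2"))

  # third partner is refused
  two <- add_partner(add_partner(ped, "C1", individual("H1")),
                     "C1", individual("H2"))
  expect_error(add_partner(two, "C1", individual("H3")),
               class = "pedchart_constraint_error")
})

test_that("randomized edit sequences never yield an invalid pedigree", {
  set.seed(424242)
  n_ops <- 0L
  for (s in 1:25) {
    p <- gen_ped(s %% 10, n_generations = 2 + s %% 3)
    for (k in 1:20) {
      op <- sample(c("add_child", "add_partner", "set_sex", "set_phenotype",
                     "set_annotation", "rename", "remove"), 1)
      id <- sample(p$ind$id, 1)
      res <- tryCatch({
        switch(op,
          add_child = {
            u <- p$unions[[sample(max(length(p$unions), 1), 1)]]
            if (is.null(u)) p else
              add_child(p, u$father_id, u$mother_id,
                        individual(paste0("N", s, "_", k),
                                   sample(c("male", "female"), 1)))
          },
          add_partner = add_partner(p, id, individual(paste0("S", s, "_", k))),
          set_sex = set_sex(p, id, sample(c("male", "female", "unknown"), 1)),
          set_phenotype = set_phenotype(p, id, sample(
            c("affected", "unaffected", "missing"), 1)),
          set_annotation = set_annotation(p, id, sample(
            c("deceased", "miscarriage", "proband", "consultand"), 1),
            on = sample(c(TRUE, FALSE), 1)),
          rename = rename_individual(p, id, paste0("R", s, "_", k)),
          remove = if (nrow(p$ind) > 3) remove_individual(p, id) else p)
      }, pedchart_error = function(e) NULL)
      if (!is.null(res)) {
        iss <- validate_pedigree(res)
        expect_equal(sum(iss$severity == "error"), 0L,
                     info = paste("seed", s, "op", k, op))
        p <- res
        n_ops <- n_ops + 1L
      }
    }
  }
  expect_gt(n_ops, 200L)
})
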