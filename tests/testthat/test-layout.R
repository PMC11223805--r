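test_that("generation assignment places partners level and children one row down", {
  gi <- assign_generations(figure_family())
  expect_s3_class(gi, "generation_index")
  expect_equal(gi$generation[c("F1", "M1", "C1", "C2", "C3")],
               c(F1 = 0L, M1 = 0L, C1 = 1L, C2 = 1L, C3 = 1L))
  expect_setequal(gi$index[c("C1", "C2", "C3")], 0:2)

  solo <- build_pedigree(parse_ped("S A 0 0 1 1")$records)
  gis <- assign_generations(solo)
  expect_equal(unname(gis$generation), 0L)
  expect_equal(unname(gis$index), 0L)

  # founder spouse marrying a generation-1 person lands on generation 1
  recs <- parse_ped(c("F G1 0 0 1 1", "F G2 0 0 2 1", "F C G1 G2 1 1",
                      "F W 0 0 2 1", "F K C W 2 1"))$records
  gi2 <- assign_generations(build_pedigree(recs))
  expect_equal(unname(gi2$generation["W"]), 1L)
  expect_equal(unname(gi2$generation["K"]), 2L)

  # brute-force check on small generated pedigrees: the assignment is the
  # unique solution of the partner-equality / child = parent + 1 system
  for (s in 0:9) {
    p <- gen_ped(s, n_generations = 2 + s %% 2)
    gi <- assign_generations(p)
    g <- gi$generation
    ind <- p$ind
    for (i in seq_len(nrow(ind))) {
      if (ind$father_id[i] != "0") {
        expect_equal(unname(g[ind$id[i]]), unname(g[ind$father_id[i]]) + 1L)
        expect_equal(unname(g[ind$father_id[i]]), unname(g[ind$mother_id[i]]))
      }
    }
    expect_equal(min(g), 0L)
  }
})

test_that("nuclear families are centred, father-left, siblings in ID order", {
  ped <- figure_family()
  lay <- compute_layout(ped)
  x <- stats::setNames(lay$positions$x, lay$positions$id)
  expect_lt(x[["F1"]], x[["M1"]])
  expect_equal(mean(x[c("C1", "C2", "C3")]), (x[["F1"]] + x[["M1"]]) / 2,
               tolerance = 1e-9)
  expect_true(x[["C1"]] < x[["C2"]] && x[["C2"]] < x[["C3"]])
  expect_equal(nrow(check_layout(lay, ped)), 0L)

  solo <- build_pedigree(parse_ped("S A 0 0 1 1")$records)
  lsolo <- compute_layout(solo)
  expect_equal(lsolo$positions$x, 0)
  expect_equal(lsolo$positions$y, 0)
  expect_length(layout_segments(lsolo$unions, lsolo$params), 0L)
})

test_that("a parent with two partners draws without any line crossings", {
  recs <- parse_ped(c(
    "T F 0 0 1 1", "T M1 0 0 2 1", "T M2 0 0 2 1",
    "T C1 F M1 1 1", "T C2 F M1 2 1", "T C3 F M2 2 1"))$records
  ped <- build_pedigree(recs)
  lay <- compute_layout(ped)
  expect_equal(nrow(check_layout(lay, ped)), 0L)
  x <- stats::setNames(lay$positions$x, lay$positions$id)
  # father sits between his two partners
  expect_true(x[["F"]] > min(x[c("M1", "M2")]) && x[["F"]] < max(x[c("M1", "M2")]))
})

test_that("a first-cousin loop closes with the couple adjacent and centred", {
  ped <- detect_consanguinity(build_pedigree(cousin_loop_records()))
  lay <- compute_layout(ped)
  expect_equal(nrow(check_layout(lay, ped)), 0L)
  x <- stats::setNames(lay$positions$x, lay$positions$id)
  expect_lt(x[["X1"]], x[["Y1"]])
  expect_equal(unname(x[["K1"]]), unname((x[["X1"]] + x[["Y1"]]) / 2),
               tolerance = lay$params$tolerance)
})

test_that("layout invariants hold across generated pedigrees", {
  for (s in 0:59) {
    p <- gen_ped(s, n_generations = 2 + s %% 4,
                 p_consanguineous_loop = 0.5)
    lay <- compute_layout(p)
    v <- check_layout(lay, p)
    expect_equal(nrow(v), 0L,
                 info = paste("seed", s, paste(v$code, collapse = ",")))
    # exact generation rows
    expect_equal(lay$positions$y,
                 lay$positions$generation * lay$params$row_height)
    # determinism
    expect_identical(lay, compute_layout(p))
  }
})

test_that("father-left holds in every union without a second partner", {
  for (s in 0:29) {
    p <- gen_ped(s, p_second_partner = 0.3)
    lay <- compute_layout(p)
    x <- stats::setNames(lay$positions$x, lay$positions$id)
    memb <- table(unlist(lapply(p$unions, function(u)
      c(u$father_id, u$mother_id))))
    for (u in p$unions) {
      if (memb[[u$father_id]] == 1L && memb[[u$mother_id]] == 1L) {
        expect_lt(x[[u$father_id]], x[[u$mother_id]])
      }
    }
  }
})

test_that("adding a child never shrinks the chart", {
  for (s in c(1, 5, 9)) {
    p <- gen_ped(s, n_generations = 3)
    w0 <- diff(compute_layout(p)$bounds[c("xmin", "xmax")])
    u <- p$unions[[1]]
    p2 <- add_child(p, u$father_id, u$mother_id, individual("ZZ9", "male"))
    w1 <- diff(compute_layout(p2)$bounds[c("xmin", "xmax")])
    expect_gte(w1 + 1e-9, w0)
  }
})

test_that("check_layout flags planted geometric defects", {
  ped <- figure_family()
  lay <- compute_layout(ped)
  # coincident symbols -> clearance violation
  bad <- lay
  bad$positions$x[bad$positions$id == "C2"] <-
    bad$positions$x[bad$positions$id == "C1"]
  expect_true("clearance" %in% check_layout(bad, ped)$code)
  # father moved right of mother
  bad2 <- lay
  bad2$positions$x[bad2$positions$id == "F1"] <-
    lay$positions$x[lay$positions$id == "M1"] + 2
  expect_true("father_left" %in% check_layout(bad2, ped)$code)
  # child pushed off the generation grid
  bad3 <- lay
  bad3$positions$y[bad3$positions$id == "C1"] <- 1.3
  expect_true("row_alignment" %in% check_layout(bad3, ped)$code)
  # crossing partner lines, built by hand from two couples
  two <- build_pedigree(parse_ped(c(
    "W A 0 0 1 1", "W B 0 0 2 1", "W C 0 0 1 1", "W D 0 0 2 1",
    "W K1 A B 1 1", "W K2 C D 1 1"))$records)
  ltwo <- compute_layout(two)
  bad4 <- ltwo
  # swap the two mothers' positions so the partner lines overlap
  ib <- bad4$positions$id == "B"; id_ <- bad4$positions$id == "D"
  tmp <- bad4$positions$x[ib]
  bad4$positions$x[ib] <- bad4$positions$x[id_]
  bad4$positions$x[id_] <- tmp
  bad4$unions <- lapply(bad4$unions, function(g) {
    g$x_father <- bad4$positions$x[bad4$positions$id == g$father_id]
    g$x_mother <- bad4$positions$x[bad4$positions$id == g$mother_id]
    g$mid_x <- (g$x_father + g$x_mother) / 2
    g$bus_x <- c(min(g$child_x, g$mid_x), max(g$child_x, g$mid_x))
    g
  })
  expect_true(any(c("crossing", "through_symbol", "father_left") %in%
                    check_layout(bad4, two)$code))
})

test_that("unsupported structures raise a structured layout error", {
  # nested loops: double-first-cousin offspring marriage
  dped <- build_pedigree(double_cousin_records())
  expect_equal(sum(validate_pedigree(dped)$severity == "error"), 0L)
  expect_error(compute_layout(dped), class = "pedchart_unsupported")
  # generation-spanning mating is already a validation error
  expect_error(compute_layout(build_pedigree(uncle_niece_records())),
               class = "pedchart_validation_error")
})
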