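test_that("parse_ped decodes the column structure, annotations and dialects", {
  doc <- parse_ped(c("FAM F1 0 0 1 1",
                     "# a comment",
                     "",
                     "FAM M1 0 0 2 0",
                     "FAM C1 F1 M1 2 2 deceased"))
  expect_s3_class(doc, "ped_document")
  expect_equal(doc$source_dialect, "annotated7")
  expect_equal(doc$records$individual_id, c("F1", "M1", "C1"))
  f1 <- doc$records[1, ]
  expect_equal(f1$sex, "male")
  expect_equal(f1$phenotype, "unaffected")
  expect_equal(f1$father_id, "0")
  expect_length(doc$records$annotations[[1]], 0)
  expect_equal(doc$records$annotations[[3]], "deceased")
  expect_equal(doc$records$phenotype[2], "missing")

  # tabs, CRLF, -9 phenotype, unknown keywords kept verbatim
  doc2 <- parse_ped("F\tA\t0\t0\t1\t-9\tdeceased,customflag\r\nF\tB\t0\t0\t2\t2\r\n")
  expect_equal(doc2$records$phenotype, c("missing", "affected"))
  expect_true("customflag" %in% doc2$records$annotations[[1]])
  expect_equal(doc2$source_dialect, "annotated7")
  expect_equal(parse_ped("F A 0 0 1 1")$source_dialect, "strict6")
})

test_that("parse errors name the offending line and condition", {
  expect_error(parse_ped("FAM X1 0 0 1"), "line 1", class = "pedchart_parse_error")
  expect_error(parse_ped(c("FAM A 0 0 1 1", "FAM B 0 0 9 1")),
               "line 2", class = "pedchart_parse_error")
  expect_error(parse_ped("FAM A 0 0 x 1"), class = "pedchart_parse_error")
  expect_error(parse_ped(c("FAM A 0 0 1 1", "FAM A 0 0 2 1")),
               class = "pedchart_duplicate_id")
  expect_error(parse_ped("FAM A A 0 1 1"), "own parent",
               class = "pedchart_parse_error")
  expect_error(parse_ped("   \n# only comments\n"), class = "pedchart_parse_error")
  # genotype columns beyond 6 are ignored with a warning, not an error
  expect_warning(doc <- parse_ped("FAM A 0 0 1 2 1 1 2 2"), "genotype")
  expect_length(doc$records$annotations[[1]], 0)
})

test_that("single-known-parent rows get a shared inferred placeholder", {
  doc <- parse_ped(c("F P1 0 0 1 1",
                     "F C1 P1 0 2 1",
                     "F C2 P1 0 1 1"))
  recs <- doc$records
  ph <- recs[recs$inferred, ]
  expect_equal(nrow(ph), 1L)  # one shared placeholder mother
  expect_equal(ph$sex, "female")
  expect_equal(unique(recs$mother_id[recs$individual_id %in% c("C1", "C2")]),
               ph$individual_id)
})

test_that("split_families partitions records order-preservingly", {
  doc <- parse_ped(c("A a1 0 0 1 1", "B b1 0 0 1 1",
                     "A a2 0 0 2 1", "B b2 0 0 2 1"))
  fams <- split_families(doc)
  expect_named(fams, c("A", "B"))
  expect_equal(fams$A$individual_id, c("a1", "a2"))
  expect_equal(fams$B$individual_id, c("b1", "b2"))
  # concatenation is a permutation of the input records
  expect_setequal(unlist(lapply(fams, `[[`, "individual_id")),
                  doc$records$individual_id)
  one <- split_families(parse_ped("A a1 0 0 1 1"))
  expect_length(one, 1L)
})

test_that("write_ped round-trips and the strict dialect drops annotations", {
  ped <- figure_family()
  txt <- write_ped(ped, include_annotations = TRUE)
  expect_true(ped_equal(ped, build_pedigree(parse_ped(txt))))
  expect_match(txt, "consanguineous_partner")

  strict <- write_ped(ped, include_annotations = FALSE)
  expect_false(grepl("consanguineous_partner", strict))
  doc <- parse_ped(strict)
  expect_equal(doc$source_dialect, "strict6")
  expect_equal(max(lengths(doc$records$annotations)), 0L)

  # rows come out in natural ID order
  ids <- vapply(strsplit(strsplit(txt, "\n")[[1]], " "), `[`, character(1), 2)
  expect_equal(ids, natural_sort(ids))
})

test_that("format round-trip holds property-style across generated pedigrees", {
  for (s in 0:39) {
    p <- gen_ped(s)
    expect_true(ped_equal(p, build_pedigree(parse_ped(write_ped(p, TRUE)))),
                info = paste("annotated round trip, seed", s))
    expect_error(parse_ped(write_ped(p, FALSE)), NA)
  }
})

test_that("compact codec is a deterministic bijection that keeps annotations", {
  ped <- figure_family()
  tok <- encode_compact(ped)
  expect_match(tok, "^[A-Za-z0-9_-]+$")
  expect_identical(tok, encode_compact(figure_family()))
  back <- decode_compact(tok)
  expect_true(ped_equal(ped, back))
  expect_true("consanguineous_partner" %in%
                unlist(back$ind$annotations[back$ind$id == "F1"]))

  for (s in 0:39) {
    p <- gen_ped(s)
    expect_true(ped_equal(p, decode_compact(encode_compact(p))),
                info = paste("codec seed", s))
  }
  # token no longer than annotated PED text for families of >= 10
  big <- gen_ped(3, n_generations = 4)
  expect_gte(nrow(big$ind), 10)
  expect_lte(nchar(encode_compact(big)), nchar(write_ped(big, TRUE)))
})

test_that("corrupted or malformed compact payloads are rejected, never wrong", {
  ped <- figure_family()
  tok <- encode_compact(ped)
  expect_error(decode_compact(""), class = "pedchart_decode_error")
  expect_error(decode_compact("not base64url!!"), class = "pedchart_decode_error")
  expect_error(decode_compact(substr(tok, 1, nchar(tok) - 5)),
               class = "pedchart_decode_error")
  alphabet <- c(LETTERS, letters, 0:9, "-", "_")
  for (pos in seq(1, nchar(tok), by = 3)) {
    ch <- substr(tok, pos, pos)
    repl <- setdiff(alphabet, ch)[1]
    bad <- paste0(substr(tok, 1, pos - 1), repl,
                  substr(tok, pos + 1, nchar(tok)))
    res <- tryCatch(decode_compact(bad), error = function(e) NULL)
    # either rejected or (for padding-bit flips) decodes to the same family
    if (!is.null(res)) expect_true(ped_equal(res, ped))
  }
})
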