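# Reading and writing PED (pre-makeped) pedigree files.
#
# The supported dialects are the strict 6-column format
#   family_id individual_id father_id mother_id sex phenotype
# and an annotated 7-column dialect whose last column holds a
# comma-separated list of lowercase annotation keywords (deceased,
# miscarriage, proband, consultand, consanguineous_partner; unknown
# keywords are preserved verbatim). "0" marks a missing parent; sex is
# 1 = male, 2 = female, 0 = unknown; phenotype is 1 = unaffected,
# 2 = affected, 0 or -9 = missing.

SEX_CODES <- c("1" = "male", "2" = "female", "0" = "unknown")
PHENO_CODES <- c("1" = "unaffected", "2" = "affected", "0" = "missing",
                 "-9" = "missing")

empty_records <- function() {
  data.frame(family_id = character(), individual_id = character(),
             father_id = character(), mother_id = character(),
             sex = character(), phenotype = character(),
             annotations = I(list()), inferred = logical(),
             stringsAsFactors = FALSE)
}

new_record <- function(family_id, individual_id, father_id, mother_id,
                       sex, phenotype, annotations = character(),
                       inferred = FALSE) {
  data.frame(family_id = family_id, individual_id = individual_id,
             father_id = father_id, mother_id = mother_id,
             sex = sex, phenotype = phenotype,
             annotations = I(list(annotations)), inferred = inferred,
             stringsAsFactors = FALSE)
}

#' Parse PED-format pedigree text
#'
#' Reads whitespace-delimited PED data in the strict 6-column or annotated
#' 7-column dialect. Blank lines and lines starting with \code{#} are
#' skipped. Lines with more than 7 fields are treated as LINKAGE-style
#' genotype rows: columns beyond the sixth are ignored with a warning.
#'
#' Rows with exactly one known parent are normalized by synthesizing a
#' placeholder founder of the missing sex (ids \code{_p1}, \code{_p2}, ...,
#' flagged as inferred); placeholders are collapsed back to \code{"0"} by
#' \code{\link{write_ped}}.
#'
#' @param text A character scalar holding PED text (may contain newlines)
#'   or a character vector of lines.
#' @return An object of class \code{ped_document}: a list with elements
#'   \code{records} (one data frame row per individual, with an
#'   \code{annotations} list column), \code{family_ids} (distinct family
#'   tokens in first-appearance order) and \code{source_dialect}
#'   (\code{"strict6"} or \code{"annotated7"}).
#' @seealso \code{\link{read_ped}}, \code{\link{write_ped}},
#'   \code{\link{split_families}}
#' @examples
#' doc <- parse_ped(c("FAM F1 0 0 1 1",
#'                    "FAM M1 0 0 2 1",
#'                    "FAM C1 F1 M1 2 2 deceased"))
#' doc$records$individual_id
#' @export
parse_ped <- function(text) {
  if (!is.character(text) || length(text) < 1L) {
    ped_stop("parse_error", "PED input must be character text")
  }
  lines <- unlist(strsplit(text, "\r?\n"), use.names = FALSE)
  keep <- !grepl("^[[:space:]]*$", lines) & !grepl("^[[:space:]]*#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    ped_stop("parse_error", "PED input contains no data lines")
  }

  recs <- empty_records()
  dialect <- "strict6"
  genotype_warned <- FALSE
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(f) < 6L) {
      ped_stop("parse_error", sprintf(
        "line %d: expected at least 6 whitespace-delimited fields, got %d",
        lineno[k], length(f)))
    }
    if (length(f) > 7L) {
      if (!genotype_warned) {
        warning(sprintf(
          "line %d: %d fields found; genotype columns beyond column 6 are ignored",
          lineno[k], length(f)), call. = FALSE)
        genotype_warned <- TRUE
      }
      f <- f[1:6]
    }
    if (!f[5] %in% names(SEX_CODES)) {
      ped_stop("parse_error", sprintf(
        "line %d: invalid sex code '%s' (expected 1, 2 or 0)", lineno[k], f[5]))
    }
    if (!f[6] %in% names(PHENO_CODES)) {
      ped_stop("parse_error", sprintf(
        "line %d: invalid phenotype code '%s' (expected 1, 2, 0 or -9)",
        lineno[k], f[6]))
    }
    if (f[2] == "0") {
      ped_stop("parse_error", sprintf(
        "line %d: individual ID must not be '0'", lineno[k]))
    }
    if (f[2] %in% c(f[3], f[4])) {
      ped_stop("parse_error", sprintf(
        "line %d: individual '%s' listed as its own parent", lineno[k], f[2]))
    }
    ann <- character()
    if (length(f) == 7L) {
      dialect <- "annotated7"
      ann <- parse_annotations(f[7])
    }
    recs <- rbind(recs, new_record(f[1], f[2], f[3], f[4],
                                   SEX_CODES[[f[5]]], PHENO_CODES[[f[6]]],
                                   ann))
  }

  dup <- duplicated(paste(recs$family_id, recs$individual_id, sep = "\r"))
  if (any(dup)) {
    ped_stop("duplicate_id", sprintf(
      "duplicate individual ID(s) within a family: %s",
      paste(unique(recs$individual_id[dup]), collapse = ", ")))
  }

  recs <- normalize_single_parents(recs)
  structure(list(records = recs,
                 family_ids = unique(recs$family_id),
                 source_dialect = dialect),
            class = "ped_document")
}

parse_annotations <- function(field) {
  if (field %in% c("", "-", ".")) return(character())
  unique(strsplit(field, ",", fixed = TRUE)[[1]])
}

# Rows with exactly one known parent get a shared placeholder partner of
# the missing sex. Placeholders are grouped by (family, known parent,
# missing side) so all children of the same single parent share one
# placeholder, and numbered in natural order of the known parent so the
# ids do not depend on row order.
normalize_single_parents <- function(recs) {
  single <- xor(recs$father_id == "0", recs$mother_id == "0")
  if (!any(single)) return(recs)
  need <- unique(data.frame(
    family_id = recs$family_id[single],
    known = ifelse(recs$father_id[single] == "0",
                   recs$mother_id[single], recs$father_id[single]),
    side = ifelse(recs$father_id[single] == "0", "father", "mother"),
    stringsAsFactors = FALSE))
  need <- need[order(natural_key(need$family_id), natural_key(need$known),
                     need$side), , drop = FALSE]
  counter <- 0L
  used <- recs$individual_id
  new_rows <- empty_records()
  for (i in seq_len(nrow(need))) {
    repeat {
      counter <- counter + 1L
      pid <- paste0("_p", counter)
      if (!pid %in% used) break
    }
    used <- c(used, pid)
    sex <- if (need$side[i] == "father") "male" else "female"
    sel <- single & recs$family_id == need$family_id[i] &
      (if (need$side[i] == "father") recs$mother_id else recs$father_id) == need$known[i]
    if (need$side[i] == "father") recs$father_id[sel] <- pid
    else recs$mother_id[sel] <- pid
    new_rows <- rbind(new_rows, new_record(need$family_id[i], pid, "0", "0",
                                           sex, "missing", inferred = TRUE))
  }
  rbind(recs, new_rows)
}

#' Read a PED file from disk
#'
#' @param path Path to a PED file (UTF-8; LF or CRLF line endings).
#' @return A \code{ped_document}; see \code{\link{parse_ped}}.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) {
    ped_stop("io_error", sprintf("PED file not found: %s", path))
  }
  parse_ped(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' Split a multi-family PED document into per-family record sets
#'
#' @param doc A \code{ped_document} from \code{\link{parse_ped}}.
#' @return A named list, one record data frame per family ID, in
#'   first-appearance order; record order within each family is preserved.
#' @export
split_families <- function(doc) {
  stopifnot(inherits(doc, "ped_document"))
  if (nrow(doc$records) == 0L) return(structure(list(), names = character()))
  out <- lapply(doc$family_ids, function(f) {
    doc$records[doc$records$family_id == f, , drop = FALSE]
  })
  names(out) <- doc$family_ids
  out
}

annotation_string <- function(ann) {
  known <- KNOWN_ANNOTATIONS[KNOWN_ANNOTATIONS %in% ann]
  other <- sort(setdiff(ann, KNOWN_ANNOTATIONS))
  paste(c(known, other), collapse = ",")
}

#' Write a pedigree as PED text
#'
#' Emits one line per individual, sorted by natural ID order. Inferred
#' placeholder parents (ids \code{_p1}, ...) are collapsed back to
#' \code{"0"} and receive no row of their own, so
#' \code{parse_ped(write_ped(p, TRUE))} reconstructs a record set
#' semantically equal to \code{p}'s.
#'
#' @param pedigree A valid \code{\link{pedigree}} object.
#' @param include_annotations If \code{TRUE}, a 7th column with the
#'   annotation keywords is emitted for annotated individuals; if
#'   \code{FALSE} the output is strict 6-column PED with all auxiliary
#'   information dropped.
#' @param path Optional path; when given the text is also written there
#'   (LF line endings, UTF-8).
#' @return The PED text as a single character scalar, invisibly when
#'   \code{path} is given.
#' @export
write_ped <- function(pedigree, include_annotations = TRUE, path = NULL) {
  stopifnot(inherits(pedigree, "pedigree"), is_flag(include_annotations))
  ind <- pedigree$ind
  placeholder <- ind$inferred & grepl("^_p[0-9]+$", ind$id)
  ph_ids <- ind$id[placeholder]
  out <- ind[!placeholder, , drop = FALSE]
  out <- out[natural_order(out$id), , drop = FALSE]
  sex_code <- c(male = "1", female = "2", unknown = "0")
  phe_code <- c(unaffected = "1", affected = "2", missing = "0")
  lines <- vapply(seq_len(nrow(out)), function(i) {
    fa <- out$father_id[i]; mo <- out$mother_id[i]
    if (fa %in% ph_ids) fa <- "0"
    if (mo %in% ph_ids) mo <- "0"
    base <- paste(pedigree$family_id, out$id[i], fa, mo,
                  sex_code[[out$sex[i]]], phe_code[[out$phenotype[i]]])
    ann <- out$annotations[[i]]
    if (include_annotations && length(ann) > 0L) {
      paste(base, annotation_string(ann))
    } else base
  }, character(1))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
    return(invisible(text))
  }
  text
}

COMPACT_VERSION <- as.raw(1L)

# Adler-32 over a raw vector, returned as 4 raw bytes (big-endian).
# Verifying this checksum before decompression means a corrupted payload
# is rejected up front, never handed to the decompressor.
adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1; b <- 0
  n <- length(bytes)
  step <- 3000L
  i <- 1L
  while (i <= n) {
    xi <- as.integer(bytes[i:min(i + step - 1L, n)])
    b <- (b + length(xi) * a + sum(cumsum(xi))) %% MOD
    a <- (a + sum(xi)) %% MOD
    i <- i + step
  }
  as.raw(c(b %/% 256, b %% 256, a %/% 256, a %% 256))
}

#' Compact URL-safe serialization of a pedigree
#'
#' Encodes the complete pedigree, including all annotations, as a short
#' URL-safe token: the canonical annotated PED text is deflate-compressed
#' (gzip), prefixed with a one-byte format version and an Adler-32
#' checksum of the compressed bytes, and base64url-encoded. The checksum
#' is verified before decompression, so corrupted tokens are rejected up
#' front; the gzip CRC gives a second integrity line. Equal pedigrees
#' always produce identical strings.
#'
#' @param pedigree A valid \code{\link{pedigree}} object.
#' @return A character scalar using only \code{A-Z a-z 0-9 - _}.
#' @seealso \code{\link{decode_compact}}
#' @export
encode_compact <- function(pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  text <- write_ped(pedigree, include_annotations = TRUE)
  z <- memCompress(charToRaw(text), type = "gzip")
  payload <- c(COMPACT_VERSION, adler32(z), z)
  b64 <- gsub("\n", "", jsonlite::base64_enc(payload), fixed = TRUE)
  gsub("=", "", chartr("+/", "-_", b64))
}

#' Decode a compact pedigree token
#'
#' Inverse of \code{\link{encode_compact}}. Any malformed, truncated or
#' corrupted payload raises a decode error (condition class
#' \code{pedchart_decode_error}); a corrupted token never yields a
#' silently wrong pedigree because the compressed payload is CRC-checked.
#'
#' @param payload A token produced by \code{\link{encode_compact}}.
#' @return A \code{\link{pedigree}} object.
#' @export
decode_compact <- function(payload) {
  fail <- function(msg) ped_stop("decode_error", paste0("cannot decode pedigree token: ", msg))
  if (!is.character(payload) || length(payload) != 1L || is.na(payload) ||
      !nzchar(payload)) {
    fail("empty or non-character payload")
  }
  if (grepl("[^A-Za-z0-9_-]", payload)) fail("invalid characters")
  b64 <- chartr("-_", "+/", payload)
  b64 <- paste0(b64, strrep("=", (4L - nchar(b64) %% 4L) %% 4L))
  raw <- tryCatch(jsonlite::base64_dec(b64), error = function(e) NULL)
  if (is.null(raw) || length(raw) < 6L) fail("not valid base64url data")
  if (raw[1] != COMPACT_VERSION) fail("unsupported format version")
  z <- raw[-(1:5)]
  if (!identical(raw[2:5], adler32(z))) fail("checksum mismatch")
  text <- tryCatch(rawToChar(memDecompress(z, type = "gzip")),
                   error = function(e) NULL)
  if (is.null(text)) fail("corrupted payload (decompression failed)")
  ped <- tryCatch({
    doc <- parse_ped(text)
    fams <- split_families(doc)
    if (length(fams) != 1L) fail("payload does not hold exactly one family")
    build_pedigree(fams[[1]], names(fams))
  }, pedchart_decode_error = function(e) stop(e),
     error = function(e) NULL)
  if (is.null(ped)) fail("payload is not a valid pedigree")
  ped
}
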