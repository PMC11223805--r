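# Independent geometric verification of a layout. This deliberately does
# not reuse the placement logic of compute_layout: it re-derives the
# union structure from the pedigree and checks the drawing conventions by
# pure geometry, so it can serve as an oracle for the layout engine.

new_violation <- function(code, message) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

empty_violations <- function() {
  data.frame(code = character(), message = character(),
             stringsAsFactors = FALSE)
}

#' Check a layout against the pedigree drawing conventions
#'
#' Verifies, by direct geometry, that: every symbol sits exactly on its
#' generation row and partners share a row; fathers are left of mothers in
#' every union where neither partner has a second partner; children are
#' centred under the parental midpoint (within \code{tolerance}) whenever
#' both parents have a single union; siblings run left-to-right in natural
#' ID order; symbols in one row keep at least \code{min_gap} edge
#' clearance (\code{couple_gap} centre distance within a couple); no two
#' connector segments of different unions cross or overlap; and no
#' segment passes through a symbol it is not attached to.
#'
#' @param layout A \code{ped_layout}.
#' @param pedigree The \code{pedigree} the layout was computed for.
#' @param params The \code{\link{layout_params}} in force.
#' @return A data frame of violations (columns \code{code},
#'   \code{message}); zero rows means the layout satisfies all
#'   conventions.
#' @export
check_layout <- function(layout, pedigree, params = layout$params) {
  stopifnot(inherits(layout, "ped_layout"), inherits(pedigree, "pedigree"))
  v <- empty_violations()
  pos <- layout$positions
  x <- stats::setNames(pos$x, pos$id)
  y <- stats::setNames(pos$y, pos$id)
  rh <- params$row_height
  ss <- params$symbol_size
  tol <- params$tolerance
  ind <- pedigree$ind

  if (!setequal(pos$id, ind$id)) {
    return(new_violation("structure", "layout and pedigree hold different individuals"))
  }

  # unions derived afresh from the parent columns + asserted partnerships
  has_par <- ind$father_id != "0"
  key <- paste(ind$father_id[has_par], ind$mother_id[has_par], sep = "\r")
  fam <- split(ind$id[has_par], key)
  extra <- pedigree$extra_unions
  if (nrow(extra) > 0L) {
    for (k in setdiff(paste(extra$father_id, extra$mother_id, sep = "\r"),
                      names(fam))) {
      fam[[k]] <- character()
    }
  }
  pairs <- if (length(fam)) do.call(rbind, strsplit(names(fam), "\r", fixed = TRUE))
           else matrix(character(), ncol = 2)
  n_unions_of <- table(c(pairs[, 1], pairs[, 2]))
  partner_pairs <- character()

  if (any(abs(y / rh - round(y / rh)) > 1e-9)) {
    v <- rbind(v, new_violation("row_alignment",
                                "symbol y coordinates are not multiples of row_height"))
  }

  for (i in seq_len(nrow(pairs))) {
    f <- pairs[i, 1]; m <- pairs[i, 2]
    kids <- natural_sort(fam[[paste(f, m, sep = "\r")]])
    partner_pairs <- c(partner_pairs, paste(sort(c(f, m)), collapse = "\r"))

    if (abs(y[[f]] - y[[m]]) > 1e-9) {
      v <- rbind(v, new_violation("partner_row", sprintf(
        "partners %s and %s are not on the same row", f, m)))
    }
    for (c_id in kids) {
      if (abs(y[[c_id]] - y[[f]] - rh) > 1e-9) {
        v <- rbind(v, new_violation("row_alignment", sprintf(
          "child %s is not exactly one row below parents %s/%s", c_id, f, m)))
      }
    }
    single <- n_unions_of[[f]] == 1L && n_unions_of[[m]] == 1L
    if (single && x[[f]] >= x[[m]]) {
      v <- rbind(v, new_violation("father_left", sprintf(
        "father %s is not left of mother %s", f, m)))
    }
    if (abs(x[[f]] - x[[m]]) < params$couple_gap - tol) {
      v <- rbind(v, new_violation("couple_separation", sprintf(
        "partners %s and %s are closer than couple_gap", f, m)))
    }
    if (single && length(kids) > 0L) {
      off <- abs(mean(x[kids]) - (x[[f]] + x[[m]]) / 2)
      if (off > tol) {
        v <- rbind(v, new_violation("centering", sprintf(
          "children of %s/%s are off-centre by %.3f units", f, m, off)))
      }
    }
    if (length(kids) > 1L && any(diff(x[kids]) <= 0)) {
      v <- rbind(v, new_violation("sibling_order", sprintf(
        "children of %s/%s are not in natural ID order left-to-right", f, m)))
    }
  }

  # horizontal clearance within each row
  for (r in unique(y)) {
    ids_r <- pos$id[abs(y[pos$id] - r) < 1e-9]
    ids_r <- ids_r[order(x[ids_r])]
    if (length(ids_r) < 2L) next
    for (i in seq_len(length(ids_r) - 1L)) {
      a <- ids_r[i]; b <- ids_r[i + 1L]
      dx <- x[[b]] - x[[a]]
      is_couple <- paste(sort(c(a, b)), collapse = "\r") %in% partner_pairs
      need <- if (is_couple) params$couple_gap else params$min_gap + ss
      if (dx < need - tol) {
        v <- rbind(v, new_violation("clearance", sprintf(
          "symbols %s and %s are %.3f units apart (need %.3f)", a, b, dx, need)))
      }
    }
  }

  # segment-level checks
  segs <- layout_segments(layout$unions, params)
  if (length(segs) > 1L) {
    for (i in seq_len(length(segs) - 1L)) {
      for (j in seq((i + 1L), length(segs))) {
        if (segs[[i]]$union == segs[[j]]$union) next
        if (segments_conflict(segs[[i]], segs[[j]])) {
          v <- rbind(v, new_violation("crossing", sprintf(
            "%s line of union %d crosses %s line of union %d",
            segs[[i]]$kind, segs[[i]]$union, segs[[j]]$kind, segs[[j]]$union)))
        }
      }
    }
  }
  for (s in segs) {
    g <- layout$unions[[s$union]]
    owners <- switch(s$kind,
                     partner = c(g$father_id, g$mother_id),
                     drop = g$children,
                     character())
    for (id in pos$id) {
      if (id %in% owners) next
      if (segment_in_box(s, x[[id]], y[[id]], ss / 2)) {
        v <- rbind(v, new_violation("through_symbol", sprintf(
          "%s line of union %d passes through the symbol of %s",
          s$kind, s$union, id)))
      }
    }
  }
  v
}

# TRUE if two segments of different unions intersect at a point interior
# to at least one of them, or overlap collinearly; a shared endpoint alone
# is not a conflict
segments_conflict <- function(a, b, eps = 1e-9) {
  p <- c(a$x1, a$y1); q <- c(a$x2, a$y2)
  r <- c(b$x1, b$y1); s <- c(b$x2, b$y2)
  d1 <- q - p; d2 <- s - r
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < eps) {
    # parallel: check collinear overlap of positive length
    cross <- d1[1] * (r[2] - p[2]) - d1[2] * (r[1] - p[1])
    if (abs(cross) > eps) return(FALSE)
    len2 <- sum(d1^2)
    if (len2 < eps) return(FALSE)
    t1 <- sum((r - p) * d1) / len2
    t2 <- sum((s - p) * d1) / len2
    lo <- max(min(t1, t2), 0); hi <- min(max(t1, t2), 1)
    return(hi - lo > eps)
  }
  t <- ((r[1] - p[1]) * d2[2] - (r[2] - p[2]) * d2[1]) / denom
  u <- ((r[1] - p[1]) * d1[2] - (r[2] - p[2]) * d1[1]) / denom
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(FALSE)
  endpoint_a <- t < eps || t > 1 - eps
  endpoint_b <- u < eps || u > 1 - eps
  !(endpoint_a && endpoint_b)
}

# TRUE if the segment passes through the open square of half-width hw
# centred at (cx, cy) for a positive length (Liang-Barsky clipping)
segment_in_box <- function(s, cx, cy, hw, eps = 1e-9) {
  x1 <- s$x1 - cx; y1 <- s$y1 - cy
  x2 <- s$x2 - cx; y2 <- s$y2 - cy
  dx <- x2 - x1; dy <- y2 - y1
  t0 <- 0; t1 <- 1
  for (k in 1:4) {
    pk <- switch(k, -dx, dx, -dy, dy)
    qk <- switch(k, x1 + hw, hw - x1, y1 + hw, hw - y1)
    if (abs(pk) < eps) {
      if (qk < -eps) return(FALSE)
    } else {
      tk <- qk / pk
      if (pk < 0) t0 <- max(t0, tk) else t1 <- min(t1, tk)
      if (t0 > t1) return(FALSE)
    }
  }
  (t1 - t0) * sqrt(dx^2 + dy^2) > 1e-6
}
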