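# Two-phase chart layout.
#
# Phase 1 (indexing): generation numbers are propagated over the family
# graph -- partners share a row, children sit one row below their parents
# -- revisiting nodes until a fixed point; each individual then gets an
# index (its position within its generation row).
#
# Phase 2 (drawing): nuclear families are laid out bottom-up as rigid
# blocks with per-row extent contours. Children subtrees are packed
# left-to-right in natural ID order, the parent couple is centred over
# the mean child position (father on the left), and couples with two
# partners or consanguineous loops are resolved by dedicated placement
# rules. Contour separation guarantees that symbols and connector lines
# of different nuclear families never overlap.

#' Layout parameters
#'
#' All lengths are in abstract grid units; the renderer scales them to
#' pixels. \code{min_gap} is the minimum horizontal clearance between the
#' edges of two symbols that are not partners; \code{couple_gap} is the
#' centre-to-centre distance of a partner pair, so it must exceed
#' \code{symbol_size}.
#'
#' @param symbol_size Symbol width/height in units.
#' @param min_gap Minimum horizontal edge clearance between non-partner
#'   symbols in one row.
#' @param row_height Vertical distance between generation rows.
#' @param couple_gap Horizontal centre distance between partners.
#' @param double_line_offset Half-separation of the double (consanguinity)
#'   partner line.
#' @param max_iterations Bound on indexing/adjustment passes.
#' @param tolerance Convergence and geometry-check tolerance; must be
#'   smaller than \code{min_gap}.
#' @return A \code{layout_params} list.
#' @export
layout_params <- function(symbol_size = 0.6, min_gap = 1.0, row_height = 2.0,
                          couple_gap = 1.0, double_line_offset = 0.07,
                          max_iterations = 100L, tolerance = 0.01) {
  p <- list(symbol_size = symbol_size, min_gap = min_gap,
            row_height = row_height, couple_gap = couple_gap,
            double_line_offset = double_line_offset,
            max_iterations = as.integer(max_iterations),
            tolerance = tolerance)
  num <- unlist(p[c("symbol_size", "min_gap", "row_height", "couple_gap",
                    "double_line_offset", "tolerance")])
  if (any(!is.finite(num)) || any(num <= 0) || p$max_iterations < 1L) {
    ped_stop("parse_error", "layout parameters must all be positive")
  }
  if (p$tolerance >= p$min_gap) {
    ped_stop("parse_error", "tolerance must be smaller than min_gap")
  }
  if (p$couple_gap <= p$symbol_size) {
    ped_stop("parse_error", "couple_gap must exceed symbol_size")
  }
  structure(p, class = "layout_params")
}

unsup <- function(msg, subjects = character()) {
  ped_stop("unsupported",
           paste0("unsupported pedigree structure (nested_loop_unsupported): ",
                  msg),
           code = "nested_loop_unsupported", subjects = subjects)
}

# ---- block primitives -------------------------------------------------
# A block is a rigid partial layout: symbol centre x per id plus, per
# generation row, the x interval spanned by everything in the block
# (symbols, sibship buses, stems and drop lines, in centre coordinates).

blk_symbol <- function(id, row) {
  list(xs = stats::setNames(0, id),
       rowint = stats::setNames(list(c(0, 0)), as.character(row)))
}

blk_shift <- function(b, dx) {
  b$xs <- b$xs + dx
  b$rowint <- lapply(b$rowint, function(r) r + dx)
  b
}

blk_merge <- function(a, b) {
  xs <- c(a$xs, b$xs)
  rows <- union(names(a$rowint), names(b$rowint))
  rowint <- lapply(rows, function(r) {
    ra <- a$rowint[[r]]; rb <- b$rowint[[r]]
    if (is.null(ra)) rb
    else if (is.null(rb)) ra
    else c(min(ra[1], rb[1]), max(ra[2], rb[2]))
  })
  names(rowint) <- rows
  list(xs = xs, rowint = rowint)
}

blk_add_interval <- function(b, row, lo, hi) {
  r <- as.character(row)
  cur <- b$rowint[[r]]
  b$rowint[[r]] <- if (is.null(cur)) c(lo, hi) else
    c(min(cur[1], lo), max(cur[2], hi))
  b
}

# minimal shift of b so that every shared row keeps `sep` centre distance
blk_sep <- function(a, b, sep) {
  shared <- intersect(names(a$rowint), names(b$rowint))
  if (length(shared) > 0L) {
    max(vapply(shared, function(r) a$rowint[[r]][2] - b$rowint[[r]][1] + sep,
               numeric(1)))
  } else {
    max(vapply(a$rowint, `[`, numeric(1), 2)) -
      min(vapply(b$rowint, `[`, numeric(1), 1)) + sep
  }
}

blk_hi <- function(b, row) {
  r <- b$rowint[[as.character(row)]]
  if (is.null(r)) -Inf else r[2]
}

blk_lo <- function(b, row) {
  r <- b$rowint[[as.character(row)]]
  if (is.null(r)) Inf else r[1]
}

# ---- the engine -------------------------------------------------------

layout_engine <- function(ped, params) {
  validate_or_stop(ped)
  ind <- ped$ind
  ids <- ind$id
  gen <- try_generations(ped)$gen
  unions <- ped$unions
  m <- length(unions)
  sep <- params$min_gap + params$symbol_size
  cg <- params$couple_gap

  is_founder <- stats::setNames(ind$father_id == "0", ids)
  punion <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (k in seq_len(m)) punion[unions[[k]]$children] <- k
  memb <- union_memberships(ped)

  kind <- character(m)
  anchor <- character(m)
  for (k in seq_len(m)) {
    u <- unions[[k]]
    ff <- is_founder[[u$father_id]]; fm <- is_founder[[u$mother_id]]
    if (ff && fm) { kind[k] <- "root"; anchor[k] <- NA_character_ }
    else if (ff) { kind[k] <- "anchored"; anchor[k] <- u$mother_id }
    else if (fm) { kind[k] <- "anchored"; anchor[k] <- u$father_id }
    else { kind[k] <- "mount"; anchor[k] <- NA_character_ }
  }

  # persons with two partners: both partner unions must be anchored at
  # them (or both root), i.e. every spouse has exactly one union
  for (id in ids) {
    uu <- memb[[id]]
    if (length(uu) == 2L) {
      for (k in uu) {
        if (kind[k] == "mount") {
          unsup(sprintf("'%s' is in a consanguineous loop and has a second partner", id), id)
        }
        other <- setdiff(c(unions[[k]]$father_id, unions[[k]]$mother_id), id)
        if (length(memb[[other]]) > 1L) {
          unsup(sprintf("partners '%s' and '%s' both have two unions", id, other),
                c(id, other))
        }
      }
      if (!is_founder[[id]]) {
        for (k in uu) {
          other <- setdiff(c(unions[[k]]$father_id, unions[[k]]$mother_id), id)
          if (!is_founder[[other]]) {
            unsup(sprintf("spouse '%s' of twice-married '%s' has recorded parents", other, id),
                  c(id, other))
          }
        }
      }
    }
  }

  # chain from a non-founder up to its root union, as a top-down list of
  # (union index, child descended through)
  chain_up <- function(p) {
    steps <- list()
    cur <- p
    repeat {
      pu <- punion[[cur]]
      if (is.na(pu)) unsup(sprintf("cannot trace ancestry of '%s'", p), p)
      steps[[length(steps) + 1L]] <- list(u = pu, child = cur)
      if (kind[pu] == "root") break
      if (kind[pu] == "mount") {
        unsup(sprintf("nested consanguineous loops around '%s'", p), p)
      }
      cur <- anchor[pu]
    }
    rev(steps)
  }

  # analyse mount unions (both partners have recorded parents): either a
  # cousin-type loop under a common ancestor union, or a marriage joining
  # two separate root families
  mounts <- list()
  for (k in which(kind == "mount")) {
    u <- unions[[k]]
    X <- u$father_id; Y <- u$mother_id
    if (length(memb[[X]]) > 1L || length(memb[[Y]]) > 1L) {
      unsup(sprintf("loop partners '%s'/'%s' may not have further partners", X, Y),
            c(X, Y))
    }
    cx <- chain_up(X); cy <- chain_up(Y)
    if (cx[[1]]$u != cy[[1]]$u) {
      # joins two root families
      below_x <- cx; below_y <- cy
      div <- 0L
    } else {
      i <- 1L
      while (i <= min(length(cx), length(cy)) &&
             cx[[i]]$u == cy[[i]]$u && cx[[i]]$child == cy[[i]]$child) {
        i <- i + 1L
      }
      if (i > min(length(cx), length(cy)) ||
          cx[[i]]$u != cy[[i]]$u) {
        unsup(sprintf("loop between '%s' and '%s' does not branch from a single union", X, Y),
              c(X, Y))
      }
      div <- cx[[i]]$u
      below_x <- cx[seq(i, length(cx))]
      below_y <- cy[seq(i, length(cy))]
    }
    if (length(below_x) != length(below_y)) {
      unsup(sprintf("loop partners '%s' and '%s' sit on different generation rows", X, Y),
            c(X, Y))
    }
    # below the divergence, the father's line must hug the right edge of
    # its blocks and the mother's line the left edge, so the partners end
    # up adjacent across the gap
    start <- if (div == 0L) 1L else 2L
    for (j in seq(start, length(below_x))) {
      s <- below_x[[j]]
      ch <- unions[[s$u]]$children
      if (s$child != ch[length(ch)]) {
        unsup(sprintf("loop member '%s' must be the last sibling of its sibship to close the loop without crossings", s$child),
              s$child)
      }
    }
    for (j in seq(start, length(below_y))) {
      s <- below_y[[j]]
      ch <- unions[[s$u]]$children
      if (s$child != ch[1L]) {
        unsup(sprintf("loop member '%s' must be the first sibling of its sibship to close the loop without crossings", s$child),
              s$child)
      }
    }
    mounts[[length(mounts) + 1L]] <- list(
      idx = k, X = X, Y = Y, div = div,
      bx = below_x[[1L]]$child, by = below_y[[1L]]$child,
      root_x = cx[[1L]]$u, root_y = cy[[1L]]$u)
  }

  div_mounts <- list()  # keyed by "<div union>|<left child>"
  root_mounts <- list() # keyed by left root union index
  for (mo in mounts) {
    if (mo$div > 0L) {
      u <- unions[[mo$div]]
      px <- match(mo$bx, u$children); py <- match(mo$by, u$children)
      if (py != px + 1L) {
        unsup(sprintf("loop branches of '%s' and '%s' are not adjacent sibships (father's branch must lie immediately left of the mother's)",
                      mo$X, mo$Y), c(mo$X, mo$Y))
      }
      key <- paste0(mo$div, "|", mo$bx)
      if (!is.null(div_mounts[[key]])) unsup("competing loops on one sibship")
      div_mounts[[key]] <- mo
    } else {
      key <- as.character(mo$root_x)
      if (!is.null(root_mounts[[key]])) {
        unsup("two marriages join the same pair of root families")
      }
      root_mounts[[key]] <- mo
    }
  }

  drawn <- rep(FALSE, m)
  geo_children <- lapply(unions, function(u) u$children)

  compose_children <- function(k) {
    ch <- unions[[k]]$children
    cum <- NULL
    pending <- NULL
    for (c_id in ch) {
      b <- build_person_block(c_id)
      if (is.null(cum)) {
        cum <- b
      } else if (!is.null(pending)) {
        if (pending$by != c_id) {
          unsup(sprintf("loop expects '%s' next to '%s'", pending$by, pending$bx))
        }
        cum <- insert_mount(cum, b, pending)
        pending <- NULL
      } else {
        s <- blk_sep(cum, b, sep)
        cum <- blk_merge(cum, blk_shift(b, s))
      }
      key <- paste0(k, "|", c_id)
      if (!is.null(div_mounts[[key]])) pending <- div_mounts[[key]]
    }
    if (!is.null(pending)) {
      unsup(sprintf("loop branch '%s' has no right-hand sibship", pending$bx))
    }
    cum
  }

  # place block b to the right of cum with mount union mo's couple
  # spanning the gap and the loop children hung centred underneath
  insert_mount <- function(cum, b, mo) {
    L <- unions[[mo$idx]]
    X <- L$father_id; Y <- L$mother_id
    g_blk <- NULL; mu_g <- 0
    if (length(L$children) > 0L) {
      g_blk <- compose_children(mo$idx)
      mu_g <- mean(g_blk$xs[L$children])
    }
    xX <- cum$xs[[X]]
    yY <- b$xs[[Y]]
    s <- max(blk_sep(cum, b, sep), xX + cg - yY)
    if (!is.null(g_blk)) {
      for (r in names(g_blk$rowint)) {
        glo <- g_blk$rowint[[r]][1]; ghi <- g_blk$rowint[[r]][2]
        s <- max(s, 2 * (blk_hi(cum, r) + sep - glo + mu_g) - xX - yY)
        s <- max(s, (xX + yY) + 2 * (ghi - mu_g + sep - blk_lo(b, r)))
      }
    }
    cum <- blk_merge(cum, blk_shift(b, s))
    if (!is.null(g_blk)) {
      anchor_x <- (xX + yY + s) / 2
      g_blk <- blk_shift(g_blk, anchor_x - mu_g)
      cum <- blk_merge(cum, g_blk)
      child_x <- g_blk$xs[L$children]
      cum <- blk_add_interval(cum, gen[[X]] + 1L,
                              min(child_x, anchor_x), max(child_x, anchor_x))
    }
    drawn[mo$idx] <<- TRUE
    cum
  }

  # couple + composed children for union k whose couple is (father,mother);
  # returns the finished block
  build_couple_block <- function(k) {
    u <- unions[[k]]
    g <- gen[[u$father_id]]
    kids <- compose_children(k)
    if (is.null(kids)) {
      blk <- blk_symbol(u$father_id, g)
      blk <- blk_merge(blk, blk_shift(blk_symbol(u$mother_id, g), cg))
    } else {
      mu <- mean(kids$xs[u$children])
      blk <- kids
      blk <- blk_merge(blk, blk_shift(blk_symbol(u$father_id, g), mu - cg / 2))
      blk <- blk_merge(blk, blk_shift(blk_symbol(u$mother_id, g), mu + cg / 2))
      child_x <- kids$xs[u$children]
      blk <- blk_add_interval(blk, g + 1L,
                              min(child_x, mu), max(child_x, mu))
    }
    drawn[k] <<- TRUE
    blk
  }

  # person p with two unions, both spouses placed beside p
  build_trio_block <- function(p, uu) {
    others <- vapply(uu, function(k) {
      setdiff(c(unions[[k]]$father_id, unions[[k]]$mother_id), p)
    }, character(1))
    ord <- natural_order(others)
    kL <- uu[ord[1]]; kR <- uu[ord[2]]
    sL <- others[ord[1]]; sR <- others[ord[2]]
    g <- gen[[p]]
    gl <- compose_children(kL)
    gr <- compose_children(kR)
    if (!is.null(gl) && !is.null(gr)) {
      gr <- blk_shift(gr, blk_sep(gl, gr, sep))
      blk <- blk_merge(gl, gr)
      # the shared parent sits between the two sibships so that the two
      # bus lines (both one row down) cannot overlap: each partner-line
      # midpoint then lies outside the other union's child span
      max_l <- max(gl$xs[unions[[kL]]$children])
      min_r <- min(gr$xs[unions[[kR]]$children])
      px <- (max_l + min_r) / 2
    } else if (!is.null(gl)) {
      blk <- gl
      px <- mean(gl$xs[unions[[kL]]$children]) + cg / 2
    } else if (!is.null(gr)) {
      blk <- gr
      px <- mean(gr$xs[unions[[kR]]$children]) - cg / 2
    } else {
      blk <- NULL
      px <- 0
    }
    trio <- blk_shift(blk_symbol(sL, g), px - cg)
    trio <- blk_merge(trio, blk_shift(blk_symbol(p, g), px))
    trio <- blk_merge(trio, blk_shift(blk_symbol(sR, g), px + cg))
    blk <- if (is.null(blk)) trio else blk_merge(blk, trio)
    for (k in c(kL, kR)) {
      u <- unions[[k]]
      if (length(u$children) > 0L) {
        mid <- (blk$xs[[u$father_id]] + blk$xs[[u$mother_id]]) / 2
        child_x <- blk$xs[u$children]
        blk <- blk_add_interval(blk, g + 1L,
                                min(child_x, mid), max(child_x, mid))
      }
      drawn[k] <<- TRUE
    }
    blk
  }

  build_person_block <- function(p) {
    uu <- memb[[p]]
    uu <- uu[kind[uu] == "anchored" & anchor[uu] == p]
    if (length(uu) == 0L) return(blk_symbol(p, gen[[p]]))
    if (length(uu) == 1L) return(build_couple_block(uu))
    build_trio_block(p, uu)
  }

  # ---- root units -----------------------------------------------------
  root_idx <- which(kind == "root")
  unit_of_union <- stats::setNames(rep(NA_integer_, m), seq_len(m))
  units <- list()
  for (k in root_idx) {
    u <- unions[[k]]
    joined <- NA_integer_
    for (i in seq_along(units)) {
      if (any(c(u$father_id, u$mother_id) %in% units[[i]]$people)) joined <- i
    }
    if (is.na(joined)) {
      units[[length(units) + 1L]] <- list(unions = k,
                                          people = c(u$father_id, u$mother_id))
      unit_of_union[k] <- length(units)
    } else {
      units[[joined]]$unions <- c(units[[joined]]$unions, k)
      units[[joined]]$people <- union(units[[joined]]$people,
                                      c(u$father_id, u$mother_id))
      unit_of_union[k] <- joined
    }
  }
  # founders drawn nowhere else become isolated singles
  consumed <- unique(unlist(c(
    lapply(unions, function(u) u$children),
    lapply(unions, function(u) c(u$father_id, u$mother_id)))))
  for (id in ids[is_founder[ids] & !(ids %in% consumed)]) {
    units[[length(units) + 1L]] <- list(unions = integer(), people = id)
  }

  build_unit_block <- function(unit) {
    if (length(unit$unions) == 0L) return(blk_symbol(unit$people, gen[[unit$people]]))
    if (length(unit$unions) == 1L) return(build_couple_block(unit$unions))
    if (length(unit$unions) == 2L) {
      shared <- intersect(
        c(unions[[unit$unions[1]]]$father_id, unions[[unit$unions[1]]]$mother_id),
        c(unions[[unit$unions[2]]]$father_id, unions[[unit$unions[2]]]$mother_id))
      return(build_trio_block(shared, unit$unions))
    }
    unsup("a chain of more than two founder unions cannot be drawn")
  }

  # order units: natural order of their smallest member id, then chain
  # units linked by cross-family marriages into adjacent positions
  unit_key <- vapply(units, function(u) natural_key(natural_sort(u$people)[1]),
                     character(1))
  ord <- order(unit_key)
  seq_units <- as.list(ord)
  for (key in names(root_mounts)) {
    mo <- root_mounts[[key]]
    a <- unit_of_union[[mo$root_x]]; b <- unit_of_union[[mo$root_y]]
    ia <- which(vapply(seq_units, function(g) a %in% g, logical(1)))
    ib <- which(vapply(seq_units, function(g) b %in% g, logical(1)))
    if (ia == ib) unsup("two marriages join the same pair of root families")
    ga <- seq_units[[ia]]; gb <- seq_units[[ib]]
    if (ga[length(ga)] != a || gb[1] != b) {
      unsup("conflicting cross-family marriages cannot be drawn side by side")
    }
    seq_units[[ia]] <- c(ga, gb)
    seq_units <- seq_units[-ib]
  }
  unit_order <- unlist(seq_units)

  mount_for_units <- function(a, b) {
    for (key in names(root_mounts)) {
      mo <- root_mounts[[key]]
      if (unit_of_union[[mo$root_x]] == a && unit_of_union[[mo$root_y]] == b) {
        return(mo)
      }
    }
    NULL
  }

  cum <- NULL
  prev_unit <- NA_integer_
  for (ui in unit_order) {
    b <- build_unit_block(units[[ui]])
    if (is.null(cum)) {
      cum <- b
    } else {
      mo <- if (!is.na(prev_unit)) mount_for_units(prev_unit, ui) else NULL
      if (!is.null(mo)) {
        cum <- insert_mount(cum, b, mo)
      } else {
        s <- blk_sep(cum, b, sep)
        cum <- blk_merge(cum, blk_shift(b, s))
      }
    }
    prev_unit <- ui
  }
  if (is.null(cum)) unsup("nothing to lay out")
  if (!all(drawn)) {
    unsup(sprintf("union(s) %s could not be placed",
                  paste(which(!drawn), collapse = ", ")))
  }
  if (!setequal(names(cum$xs), ids) || anyDuplicated(names(cum$xs)) > 0L) {
    unsup("some individuals could not be placed exactly once")
  }

  xs <- cum$xs[ids]
  xs <- xs - min(xs)
  list(xs = xs, gen = gen)
}

#' Assign generation numbers and within-row indexes
#'
#' Phase one of the chart algorithm: each individual receives a
#' generation number (0 = topmost row; partners share a row, children sit
#' one row below their parents, a founder marrying into generation g is
#' placed at g) and an index giving its position within its generation
#' row, with partners adjacent and sibships contiguous in natural ID
#' order.
#'
#' @param pedigree A valid \code{pedigree} (no validation errors).
#' @param params A \code{\link{layout_params}} object.
#' @return An object of class \code{generation_index}: list with named
#'   integer vectors \code{generation} and \code{index}.
#' @export
assign_generations <- function(pedigree, params = layout_params()) {
  eng <- layout_engine(pedigree, params)
  rows <- split(names(eng$xs), eng$gen[names(eng$xs)])
  index <- integer(0)
  for (r in names(rows)) {
    ids_r <- rows[[r]]
    ids_r <- ids_r[order(eng$xs[ids_r])]
    index[ids_r] <- seq_along(ids_r) - 1L
  }
  structure(list(generation = eng$gen[names(eng$xs)],
                 index = index[names(eng$xs)]),
            class = "generation_index")
}

#' Compute symbol coordinates and connector geometry
#'
#' Phase two of the chart algorithm: resolves 2-D coordinates for every
#' symbol (y = generation row, x packed so that fathers sit left of
#' mothers, siblings run left-to-right in natural ID order, children are
#' centred under their parents, non-partner symbols keep at least
#' \code{min_gap} edge clearance, and no connector lines of different
#' unions cross), plus the partner-line, sibship-bus and drop-line
#' geometry needed for rendering.
#'
#' @param pedigree A valid \code{pedigree}; run
#'   \code{\link{detect_consanguinity}} first if double partner lines are
#'   wanted.
#' @param gi Optional \code{generation_index}; when supplied it is
#'   checked for consistency with the pedigree.
#' @param params A \code{\link{layout_params}} object.
#' @return An object of class \code{ped_layout}: list with
#'   \code{positions} (data frame id/x/y/generation), \code{unions}
#'   (geometry per union: partner segment endpoints, double-line flag,
#'   bus and drop coordinates), \code{generation}, \code{index},
#'   \code{bounds} (xmin, ymin, xmax, ymax with margin) and
#'   \code{params}.
#' @export
compute_layout <- function(pedigree, gi = NULL, params = layout_params()) {
  stopifnot(inherits(pedigree, "pedigree"))
  eng <- layout_engine(pedigree, params)
  if (!is.null(gi)) {
    stopifnot(inherits(gi, "generation_index"))
    if (!identical(gi$generation[names(eng$gen)], eng$gen)) {
      ped_stop("unsupported", "generation index is inconsistent with the pedigree")
    }
  }
  ids <- pedigree$ind$id
  rh <- params$row_height
  ss <- params$symbol_size
  xs <- eng$xs[ids]
  ys <- eng$gen[ids] * rh

  ugeo <- lapply(pedigree$unions, function(u) {
    y <- ys[[u$father_id]]
    fx <- xs[[u$father_id]]; mx <- xs[[u$mother_id]]
    mid <- (fx + mx) / 2
    g <- list(father_id = u$father_id, mother_id = u$mother_id,
              children = u$children,
              consanguineous = u$consanguineous,
              double = u$consanguineous != "no",
              x_father = fx, x_mother = mx, y = y, mid_x = mid)
    if (length(u$children) > 0L) {
      cx <- xs[u$children]
      g$bus_y <- y + 0.6 * rh
      g$bus_x <- c(min(cx, mid), max(cx, mid))
      g$child_x <- cx
      g$child_y <- y + rh
    }
    g
  })

  segs <- layout_segments(ugeo, params)
  all_x <- c(xs - ss / 2, xs + ss / 2,
             unlist(lapply(segs, function(s) c(s$x1, s$x2))))
  all_y <- c(ys - ss / 2, ys + ss / 2,
             unlist(lapply(segs, function(s) c(s$y1, s$y2))))
  margin <- 1.0
  bounds <- c(xmin = min(all_x) - margin, ymin = min(all_y) - margin,
              xmax = max(all_x) + margin, ymax = max(all_y) + margin)

  rows <- split(ids, eng$gen[ids])
  index <- integer(0)
  for (r in names(rows)) {
    ids_r <- rows[[r]][order(xs[rows[[r]]])]
    index[ids_r] <- seq_along(ids_r) - 1L
  }

  layout <- structure(list(
    positions = data.frame(id = ids, x = unname(xs), y = unname(ys),
                           generation = unname(eng$gen[ids]),
                           stringsAsFactors = FALSE),
    unions = ugeo,
    generation = eng$gen[ids],
    index = index[ids],
    bounds = bounds,
    params = params), class = "ped_layout")

  viol <- check_layout(layout, pedigree, params)
  if (nrow(viol) > 0L) {
    unsup(paste0("layout constraints could not all be satisfied:\n",
                 paste(sprintf("  [%s] %s", viol$code, viol$message),
                       collapse = "\n")))
  }
  layout
}

#' @export
print.ped_layout <- function(x, ...) {
  cat(sprintf("Pedigree layout: %d symbols, %d unions, canvas %.1f x %.1f units\n",
              nrow(x$positions), length(x$unions),
              x$bounds[["xmax"]] - x$bounds[["xmin"]],
              x$bounds[["ymax"]] - x$bounds[["ymin"]]))
  invisible(x)
}

# all connector segments of a layout, tagged with the owning union
layout_segments <- function(ugeo, params) {
  ss <- params$symbol_size
  dlo <- params$double_line_offset
  segs <- list()
  add <- function(union, kind, x1, y1, x2, y2) {
    segs[[length(segs) + 1L]] <<- list(union = union, kind = kind,
                                       x1 = x1, y1 = y1, x2 = x2, y2 = y2)
  }
  for (k in seq_along(ugeo)) {
    g <- ugeo[[k]]
    lx <- min(g$x_father, g$x_mother) + ss / 2
    rx <- max(g$x_father, g$x_mother) - ss / 2
    if (isTRUE(g$double)) {
      add(k, "partner", lx, g$y - dlo, rx, g$y - dlo)
      add(k, "partner", lx, g$y + dlo, rx, g$y + dlo)
    } else {
      add(k, "partner", lx, g$y, rx, g$y)
    }
    if (!is.null(g$bus_y)) {
      add(k, "stem", g$mid_x, g$y, g$mid_x, g$bus_y)
      add(k, "bus", g$bus_x[1], g$bus_y, g$bus_x[2], g$bus_y)
      for (i in seq_along(g$child_x)) {
        add(k, "drop", g$child_x[[i]], g$bus_y, g$child_x[[i]],
            g$child_y - ss / 2)
      }
    }
  }
  segs
}
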