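# SVG chart emission following standardized pedigree nomenclature:
# squares for males, circles for females, diamonds for unknown sex, a
# small triangle for miscarriages; filled symbols for affected
# individuals, a central "?" for missing phenotype; a diagonal slash for
# deceased persons; an arrow (with "P") for the proband and a bare arrow
# for the consultand; a double partner line for consanguineous unions.
# Output is byte-deterministic: fixed element order (lines, symbols,
# marks, then text) and fixed numeric formatting.

#' Rendering options
#'
#' @param show_ids Draw individual IDs beneath the symbols (default
#'   \code{TRUE}); switching them off yields an anonymous chart.
#' @param px_per_unit Scale: pixels per abstract layout unit.
#' @param font_size Label font size in px.
#' @param stroke_width Line width in px.
#' @param background Background colour token, or \code{NULL} for a
#'   transparent canvas.
#' @return A \code{render_options} list.
#' @export
render_options <- function(show_ids = TRUE, px_per_unit = 40,
                           font_size = 11, stroke_width = 1.4,
                           background = "white") {
  stopifnot(is_flag(show_ids), px_per_unit > 0, font_size > 0,
            stroke_width > 0)
  structure(list(show_ids = show_ids, px_per_unit = px_per_unit,
                 font_size = font_size, stroke_width = stroke_width,
                 background = background),
            class = "render_options")
}

fmt <- function(x) sprintf("%.2f", x)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a pedigree layout as an SVG document
#'
#' @param layout A \code{ped_layout} from \code{\link{compute_layout}};
#'   rendering is refused if \code{\link{check_layout}} reports any
#'   violation.
#' @param pedigree The corresponding \code{pedigree} (run
#'   \code{\link{detect_consanguinity}} beforehand so consanguineous
#'   unions get their double line).
#' @param options A \code{\link{render_options}} object.
#' @return An object of class \code{svg_document}: list with
#'   \code{xml_text}, \code{width_px}, \code{height_px}.
#' @export
render_svg <- function(layout, pedigree, options = render_options()) {
  stopifnot(inherits(layout, "ped_layout"), inherits(pedigree, "pedigree"),
            inherits(options, "render_options"))
  viol <- check_layout(layout, pedigree, layout$params)
  if (nrow(viol) > 0L) {
    ped_stop("render_error",
             paste0("refusing to render a layout with geometry violations:\n",
                    paste(sprintf("  [%s] %s", viol$code, viol$message),
                          collapse = "\n")))
  }
  p <- layout$params
  ppu <- options$px_per_unit
  b <- layout$bounds
  X <- function(x) (x - b[["xmin"]]) * ppu
  Y <- function(y) (y - b[["ymin"]]) * ppu
  w_px <- (b[["xmax"]] - b[["xmin"]]) * ppu
  h_px <- (b[["ymax"]] - b[["ymin"]]) * ppu
  sw <- options$stroke_width
  ss <- p$symbol_size * ppu   # symbol size in px
  hw <- ss / 2

  lines <- character()
  symbols <- character()
  marks <- character()
  texts <- character()
  seg_line <- function(x1, y1, x2, y2, cls) {
    sprintf('<line class="%s" x1="%s" y1="%s" x2="%s" y2="%s"/>',
            cls, fmt(x1), fmt(y1), fmt(x2), fmt(y2))
  }

  for (k in seq_along(layout$unions)) {
    for (s in layout_segments(layout$unions[k], p)) {
      cls <- if (s$kind == "partner" && isTRUE(layout$unions[[k]]$double)) {
        "partner double"
      } else s$kind
      lines <- c(lines, seg_line(X(s$x1), Y(s$y1), X(s$x2), Y(s$y2), cls))
    }
  }

  ind <- pedigree$ind
  ord <- natural_order(ind$id)
  for (i in ord) {
    id <- ind$id[i]
    pos <- layout$positions[layout$positions$id == id, ]
    cx <- X(pos$x); cy <- Y(pos$y)
    ann <- ind$annotations[[i]]
    affected <- ind$phenotype[i] == "affected"
    fill <- if (affected) "#000000" else "#ffffff"
    if ("miscarriage" %in% ann) {
      r <- hw * 0.75
      pts <- sprintf("%s,%s %s,%s %s,%s",
                     fmt(cx), fmt(cy - r), fmt(cx - r * 0.866), fmt(cy + r / 2),
                     fmt(cx + r * 0.866), fmt(cy + r / 2))
      symbols <- c(symbols, sprintf(
        '<polygon class="symbol miscarriage" points="%s" fill="%s"/>', pts, fill))
    } else if (ind$sex[i] == "male") {
      symbols <- c(symbols, sprintf(
        '<rect class="symbol sex-male" x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        fmt(cx - hw), fmt(cy - hw), fmt(ss), fmt(ss), fill))
    } else if (ind$sex[i] == "female") {
      symbols <- c(symbols, sprintf(
        '<circle class="symbol sex-female" cx="%s" cy="%s" r="%s" fill="%s"/>',
        fmt(cx), fmt(cy), fmt(hw), fill))
    } else {
      pts <- sprintf("%s,%s %s,%s %s,%s %s,%s",
                     fmt(cx), fmt(cy - hw * 1.2), fmt(cx + hw * 1.2), fmt(cy),
                     fmt(cx), fmt(cy + hw * 1.2), fmt(cx - hw * 1.2), fmt(cy))
      symbols <- c(symbols, sprintf(
        '<polygon class="symbol sex-unknown" points="%s" fill="%s"/>', pts, fill))
    }
    if ("deceased" %in% ann) {
      marks <- c(marks, seg_line(cx - hw * 1.35, cy + hw * 1.35,
                                 cx + hw * 1.35, cy - hw * 1.35, "deceased"))
    }
    if (any(c("proband", "consultand") %in% ann)) {
      # arrow from the lower left pointing at the symbol corner
      tail_x <- cx - hw * 3.0; tail_y <- cy + hw * 3.0
      tip_x <- cx - hw * 1.5; tip_y <- cy + hw * 1.5
      cls <- if ("proband" %in% ann) "proband-arrow" else "consultand-arrow"
      marks <- c(marks, seg_line(tail_x, tail_y, tip_x, tip_y, cls))
      ah <- hw * 0.6
      pts <- sprintf("%s,%s %s,%s %s,%s",
                     fmt(tip_x), fmt(tip_y),
                     fmt(tip_x - ah), fmt(tip_y + ah * 0.15),
                     fmt(tip_x - ah * 0.15), fmt(tip_y + ah))
      marks <- c(marks, sprintf('<polygon class="%s-head" points="%s" fill="#000000"/>',
                                cls, pts))
      if ("proband" %in% ann) {
        texts <- c(texts, sprintf(
          '<text class="proband-label" x="%s" y="%s" text-anchor="middle">P</text>',
          fmt(tail_x - hw * 0.6), fmt(tail_y + hw * 0.4)))
      }
    }
    if (ind$phenotype[i] == "missing" && !"miscarriage" %in% ann) {
      texts <- c(texts, sprintf(
        '<text class="pheno-missing" x="%s" y="%s" text-anchor="middle">?</text>',
        fmt(cx), fmt(cy + options$font_size * 0.35)))
    }
    if (options$show_ids) {
      texts <- c(texts, sprintf(
        '<text class="pid" x="%s" y="%s" text-anchor="middle">%s</text>',
        fmt(cx), fmt(cy + hw + options$font_size * 1.15), xml_escape(id)))
    }
  }

  bg <- if (!is.null(options$background)) {
    sprintf('<rect class="background" x="0" y="0" width="%s" height="%s" fill="%s" stroke="none"/>',
            fmt(w_px), fmt(h_px), options$background)
  } else character()
  style <- paste0(
    "line,rect,circle,polygon{stroke:#000;stroke-width:", fmt(sw), "px;}",
    "text{font-family:sans-serif;font-size:", fmt(options$font_size),
    "px;fill:#000;stroke:none;}")
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">\n',
            fmt(w_px), fmt(h_px), fmt(w_px), fmt(h_px)),
    sprintf('<style>%s</style>\n', style),
    paste(c(bg,
            '<g class="lines">', lines, '</g>',
            '<g class="symbols">', symbols, '</g>',
            '<g class="marks">', marks, '</g>',
            '<g class="texts">', texts, '</g>'), collapse = "\n"),
    '\n</svg>\n')
  structure(list(xml_text = xml, width_px = w_px, height_px = h_px),
            class = "svg_document")
}

#' @export
print.svg_document <- function(x, ...) {
  cat(sprintf("SVG pedigree chart, %.0f x %.0f px, %d bytes\n",
              x$width_px, x$height_px, nchar(x$xml_text)))
  invisible(x)
}

#' Write an SVG document to a file
#'
#' @param svg An \code{svg_document}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_svg <- function(svg, path) {
  stopifnot(inherits(svg, "svg_document"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(svg$xml_text), con)
  invisible(path)
}

#' Rasterize an SVG pedigree chart to PNG
#'
#' Renders the package's own SVG element subset (lines, rectangles,
#' circles, polygons, text) onto a PNG canvas whose pixel dimensions are
#' the SVG dimensions scaled by \code{dpi / 96}.
#'
#' @param svg An \code{svg_document} (or SVG text produced by
#'   \code{\link{render_svg}}).
#' @param dpi Output resolution; 96 dpi reproduces the SVG pixel size.
#' @param path Optional output path; when omitted the PNG bytes are
#'   returned.
#' @return Raw vector of PNG bytes (invisibly when \code{path} is given).
#' @export
render_png <- function(svg, dpi = 96, path = NULL) {
  if (!capabilities("png")) {
    ped_stop("capability_error",
             "this R build has no PNG device; SVG output remains available")
  }
  xml_text <- if (inherits(svg, "svg_document")) svg$xml_text else svg
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) NULL)
  if (is.null(doc) || xml2::xml_name(doc) != "svg") {
    ped_stop("render_error", "input is not a well-formed SVG document")
  }
  w_svg <- as.numeric(xml2::xml_attr(doc, "width"))
  h_svg <- as.numeric(xml2::xml_attr(doc, "height"))
  if (!is.finite(w_svg) || !is.finite(h_svg)) {
    ped_stop("render_error", "SVG is missing numeric width/height")
  }
  w_px <- round(w_svg * dpi / 96)
  h_px <- round(h_svg * dpi / 96)

  out <- if (is.null(path)) tempfile(fileext = ".png") else path
  grDevices::png(out, width = w_px, height = h_px)
  ok <- FALSE
  tryCatch({
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, w_svg), ylim = c(h_svg, 0))
    draw_svg_nodes(doc, dpi)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) ped_stop("render_error", "PNG rasterization failed")
  bytes <- readBin(out, "raw", n = file.info(out)$size)
  if (is.null(path)) {
    unlink(out)
    bytes
  } else {
    invisible(bytes)
  }
}

draw_svg_nodes <- function(doc, dpi) {
  ns <- c(svg = "http://www.w3.org/2000/svg")
  font_px <- 11
  style <- xml2::xml_find_first(doc, ".//svg:style", ns)
  if (!inherits(style, "xml_missing")) {
    m <- regmatches(xml2::xml_text(style),
                    regexec("font-size:([0-9.]+)px", xml2::xml_text(style)))[[1]]
    if (length(m) == 2L) font_px <- as.numeric(m[2])
  }
  cex <- font_px / 12 * dpi / 96 / (graphics::par("cin")[2] * 96 / 12) # approx
  nodes <- xml2::xml_find_all(
    doc, ".//svg:line|.//svg:rect|.//svg:circle|.//svg:polygon|.//svg:text", ns)
  num <- function(n, a) as.numeric(xml2::xml_attr(n, a))
  for (n in nodes) {
    fill <- xml2::xml_attr(n, "fill")
    col_fill <- if (is.na(fill) || fill == "none") NA else fill
    switch(xml2::xml_name(n),
      line = graphics::segments(num(n, "x1"), num(n, "y1"),
                                num(n, "x2"), num(n, "y2"), lwd = 1.5),
      rect = graphics::rect(num(n, "x"), num(n, "y"),
                            num(n, "x") + num(n, "width"),
                            num(n, "y") + num(n, "height"),
                            col = col_fill, border = "black", lwd = 1.5),
      circle = graphics::symbols(num(n, "cx"), num(n, "cy"),
                                 circles = num(n, "r"), inches = FALSE,
                                 add = TRUE, bg = col_fill, fg = "black",
                                 lwd = 1.5),
      polygon = {
        pts <- strsplit(strsplit(xml2::xml_attr(n, "points"), " ")[[1]], ",")
        xy <- vapply(pts, as.numeric, numeric(2))
        graphics::polygon(xy[1, ], xy[2, ], col = col_fill, border = "black",
                          lwd = 1.5)
      },
      text = graphics::text(num(n, "x"), num(n, "y"), xml2::xml_text(n),
                            adj = c(0.5, 0.2), cex = max(cex, 0.3)))
  }
  invisible()
}
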