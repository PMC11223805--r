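# Internal helpers shared across the package.

KNOWN_ANNOTATIONS <- c("deceased", "miscarriage", "proband", "consultand",
                       "consanguineous_partner")

#' Natural sort order for identifier tokens
#'
#' Orders tokens so that runs of digits compare numerically and everything
#' else compares case-insensitively, so that \code{C2} sorts before
#' \code{C10}. This is the order used for sibships, exported PED rows and
#' all deterministic tie-breaking in the package.
#'
#' @param ids Character vector of identifier tokens.
#' @return Integer permutation, as from \code{\link[base]{order}}.
#' @examples
#' ids <- c("C10", "C2", "C1")
#' ids[natural_order(ids)]
#' @export
natural_order <- function(ids) {
  order(natural_key(ids), ids)
}

#' @rdname natural_order
#' @export
natural_sort <- function(ids) {
  ids[natural_order(ids)]
}

# A sortable key: lowercase, digit runs zero-padded to width 20.
natural_key <- function(ids) {
  pad <- function(id) {
    m <- gregexpr("[0-9]+", id)[[1]]
    if (m[1] == -1L) return(tolower(id))
    runs <- regmatches(id, gregexpr("[0-9]+", id))[[1]]
    padded <- vapply(runs, function(r) {
      r <- sub("^0+(?=[0-9])", "", r, perl = TRUE)
      paste0(strrep("0", max(0L, 20L - nchar(r))), r)
    }, character(1))
    out <- id
    regmatches(out, gregexpr("[0-9]+", out)) <- list(padded)
    tolower(out)
  }
  vapply(as.character(ids), pad, character(1), USE.NAMES = FALSE)
}

# Structured error helpers. Every condition carries class
# c("pedchart_<type>", "pedchart_error", "error", "condition").
ped_stop <- function(type, msg, ...) {
  stop(errorCondition(msg, ..., class = c(paste0("pedchart_", type),
                                          "pedchart_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopifnot_token <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x) ||
      grepl("[[:space:]]", x)) {
    ped_stop("parse_error", sprintf("%s must be a non-empty token without whitespace", what))
  }
  invisible(x)
}
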