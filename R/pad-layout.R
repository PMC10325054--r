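#' Whisker pad layout and spatial arrangement schemes
#'
#' The pad layout places every tracked whisker on an integer-ish grid:
#' mystacial rows A-E are grid rows 1-5, arcs 1-4 are grid columns 1-4,
#' the straddlers (alpha-delta) sit in column 0 beside their neighbouring
#' row, and the two supra-orbital whiskers (lSO, sSO) sit dorsally at
#' grid row -1. The layout ships as an editable YAML resource.
#'
#' @param path Optional path to a layout YAML file with one
#'   `whisker: [row, col]` entry per whisker. Defaults to the resource
#'   bundled with the package.
#' @return A data frame with columns `whisker_id`, `row`, `col` and class
#'   `pad_layout`.
#' @export
#' @examples
#' head(pad_layout())
pad_layout <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pad_layout.yaml", package = "anemowhisk")
  }
  raw <- yaml::read_yaml(path)
  ids <- names(raw$whiskers)
  if (anyDuplicated(ids)) {
    stop("pad layout contains duplicated whisker ids")
  }
  pos <- do.call(rbind, raw$whiskers)
  out <- data.frame(
    whisker_id = ids,
    row = as.numeric(pos[, 1]),
    col = as.numeric(pos[, 2]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pad_layout", "data.frame")
  out
}

#' Build an arrangement scheme over a pad layout
#'
#' An arrangement scheme partitions the laid-out whiskers into spatial
#' groups. Six named schemes are supported, all derived geometrically
#' from the grid positions:
#' \describe{
#'   \item{arcs}{group by grid column (straddlers are arc 0, the
#'     supra-orbitals form their own group).}
#'   \item{rows}{group by grid row; straddlers join the row they flank;
#'     supra-orbitals form their own group.}
#'   \item{semicircles_A1}{concentric bands of rounded Euclidean
#'     distance from the A1 position.}
#'   \item{oblique45_A1}{45-degree diagonals (constant row + col),
#'     indexed from A1.}
#'   \item{oblique135_A4}{135-degree diagonals (constant row - col),
#'     indexed from A4.}
#'   \item{opposite_semicircle_E4}{distance bands centred on E4.}
#' }
#' A `custom` scheme takes an explicit whisker -> group map.
#'
#' @param name Scheme name, one of the six above or `"custom"`.
#' @param layout A `pad_layout` data frame.
#' @param groups For `name = "custom"`, a named character vector mapping
#'   whisker ids to group labels.
#' @return An object of class `arrangement_scheme`: a list with `name`,
#'   `groups` (named character vector) and `layout`.
#' @export
arrangement_scheme <- function(name, layout = pad_layout(), groups = NULL) {
  stopifnot(inherits(layout, "data.frame"))
  ids <- layout$whisker_id
  r <- layout$row
  co <- layout$col
  anchor <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) stop("layout has no whisker '", id, "'")
    c(r[i], co[i])
  }
  g <- switch(
    name,
    arcs = {
      lab <- ifelse(r < 0, "SO", paste0("arc", co))
      lab
    },
    rows = {
      rowletter <- c("A", "B", "C", "D", "E")
      lab <- ifelse(r < 0, "SO", rowletter[pmax(pmin(round(r), 5), 1)])
      lab
    },
    semicircles_A1 = {
      a <- anchor("A1")
      paste0("SC", round(sqrt((r - a[1])^2 + (co - a[2])^2)))
    },
    oblique45_A1 = {
      a <- anchor("A1")
      paste0("O", (r + co) - (a[1] + a[2]))
    },
    oblique135_A4 = {
      a <- anchor("A4")
      paste0("O", (r - co) - (a[1] - a[2]))
    },
    opposite_semicircle_E4 = {
      a <- anchor("E4")
      paste0("SC", round(sqrt((r - a[1])^2 + (co - a[2])^2)))
    },
    custom = {
      if (is.null(groups)) stop("custom scheme needs a 'groups' map")
      if (!all(ids %in% names(groups))) {
        stop("custom groups must cover every laid-out whisker")
      }
      unname(groups[ids])
    },
    stop("unknown arrangement scheme '", name, "'")
  )
  g <- stats::setNames(as.character(g), ids)
  if (length(unique(g)) < 2) stop("scheme '", name, "' yields fewer than 2 groups")
  structure(list(name = name, groups = g, layout = layout),
            class = "arrangement_scheme")
}

#' The six standard arrangement schemes
#'
#' @param layout A `pad_layout`.
#' @return Named list of `arrangement_scheme` objects in their declared
#'   (tie-breaking) order: arcs, rows, semicircles_A1, oblique45_A1,
#'   oblique135_A4, opposite_semicircle_E4.
#' @export
standard_schemes <- function(layout = pad_layout()) {
  nm <- c("arcs", "rows", "semicircles_A1", "oblique45_A1",
          "oblique135_A4", "opposite_semicircle_E4")
  stats::setNames(lapply(nm, arrangement_scheme, layout = layout), nm)
}

#' @export
print.arrangement_scheme <- function(x, ...) {
  cat("Arrangement scheme:", x$name, "\n")
  tab <- table(x$groups)
  cat(length(tab), "groups:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  invisible(x)
}
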