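# Compartment geometry: tumor boundary -> {TU_CORE, MARG_500_IN, MARG_500_OUT}.
#
# All coordinates are micrometres, taken from the input as-is (no axis flip).
# Areas are reported in mm^2 (1 mm^2 = 1e6 um^2), the unit in which densities
# are expressed throughout.

# ---- polygon plumbing -------------------------------------------------------

# Shoelace signed area; positive for counter-clockwise vertex order.
signed_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Coerce a ring (matrix / data.frame with x,y) to a counter-clockwise list.
as_ring <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c(1L, 2L)])
  if (is.list(p) && !is.null(p$x)) p <- cbind(p$x, p$y)
  if (!is.matrix(p) || ncol(p) < 2L || nrow(p) < 3L) {
    stop("a polygon ring needs at least 3 (x, y) vertices", call. = FALSE)
  }
  x <- as.numeric(p[, 1L]); y <- as.numeric(p[, 2L])
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("polygon vertices must be finite", call. = FALSE)
  }
  # drop an explicitly closed last vertex
  n <- length(x)
  if (n > 3L && x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]; y <- y[-n]
  }
  if (signed_area(x, y) < 0) {
    x <- rev(x); y <- rev(y)
  }
  list(x = x, y = y)
}

# Does the ring self-intersect? Brute-force segment pair test; rings here are
# at most a few hundred vertices, so O(n^2) is fine.
ring_is_simple <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      # skip adjacent segments (they share an endpoint)
      if (j == i + 1L || (i == 1L && j == n)) next
      d1 <- cross(x[i], y[i], x2[i], y2[i], x[j], y[j])
      d2 <- cross(x[i], y[i], x2[i], y2[i], x2[j], y2[j])
      d3 <- cross(x[j], y[j], x2[j], y2[j], x[i], y[i])
      d4 <- cross(x[j], y[j], x2[j], y2[j], x2[i], y2[i])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# One or more rings -> polygonal owin. Multi-part tumors are a list of rings.
rings_to_owin <- function(rings) {
  if (is.matrix(rings) || is.data.frame(rings) ||
      (is.list(rings) && !is.null(rings$x))) {
    rings <- list(rings)
  }
  rings <- lapply(rings, as_ring)
  ok <- vapply(rings, ring_is_simple, logical(1L))
  if (!all(ok)) {
    stop("polygon ring ", which(!ok)[1L], " is self-intersecting", call. = FALSE)
  }
  spatstat.geom::owin(poly = if (length(rings) == 1L) rings[[1L]] else rings,
                      check = TRUE, fix = TRUE)
}

owin_area_mm2 <- function(w) {
  if (is.null(w)) return(0)
  spatstat.geom::area.owin(w) / UM2_PER_MM2
}

empty_owin <- function(like) {
  spatstat.geom::emptywindow(spatstat.geom::Frame(like))
}

# ---- region annotation ------------------------------------------------------

#' Region annotation for one slide
#'
#' Bundles the tumor boundary (one simple closed polygon, or several disjoint
#' polygons for a multi-part tumor) and an optional tissue polygon used to
#' clip the compartments at the tissue edge. Coordinates are micrometres.
#'
#' @param tumor a matrix/data.frame of (x, y) vertices in um, a list with
#'   `x`/`y` components, or a list of such rings for a multi-part tumor.
#' @param tissue optional tissue boundary in the same formats.
#' @return an object of class `region_annotation`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' ann <- region_annotation(cbind(1500 * cos(th), 1500 * sin(th)))
#' @export
region_annotation <- function(tumor, tissue = NULL) {
  tumor_w <- rings_to_owin(tumor)
  tissue_w <- if (!is.null(tissue)) rings_to_owin(tissue) else NULL
  if (!is.null(tissue_w)) {
    inter <- spatstat.geom::intersect.owin(tumor_w, tissue_w, fatal = FALSE)
    if (is.null(inter) || spatstat.geom::is.empty(inter)) {
      stop("tissue polygon does not intersect the tumor polygon", call. = FALSE)
    }
  }
  structure(list(tumor = tumor_w, tissue = tissue_w),
            class = "region_annotation")
}

#' @export
print.region_annotation <- function(x, ...) {
  cat("Region annotation: tumor area",
      format(owin_area_mm2(x$tumor), digits = 4), "mm^2",
      if (!is.null(x$tissue)) {
        paste0("; tissue area ", format(owin_area_mm2(x$tissue), digits = 4), " mm^2")
      } else {
        "; no tissue polygon"
      }, "\n")
  invisible(x)
}

# ---- compartments -----------------------------------------------------------

#' Build the three spatial compartments around a tumor boundary
#'
#' Erodes the tumor polygon by `margin_width` to obtain the tumor core
#' (`TU_CORE`), takes the ring between tumor and core as the inner invasive
#' margin (`MARG_500_IN`), and the ring between the dilated tumor and the
#' tumor as the outer invasive margin (`MARG_500_OUT`). Buffering uses
#' Euclidean morphology with round joins; multi-part tumors are buffered
#' jointly so overlapping outer margins merge. When a tissue polygon is
#' present all three compartments are clipped to it.
#'
#' If the erosion annihilates the tumor (its maximal inscribed radius is at
#' most `margin_width`), `TU_CORE` is returned empty with area 0 and a
#' warning is raised; the inner margin then equals the whole tumor.
#'
#' @param annotation a [region_annotation()].
#' @param margin_width margin width in micrometres (default 500).
#' @return an object of class `compartment_set`: polygonal geometries for the
#'   three compartments, their areas in mm^2, and the margin width.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 129)[-129]
#' ann <- region_annotation(cbind(1500 * cos(th), 1500 * sin(th)))
#' cs <- build_compartments(ann)
#' cs$areas  # ~ pi * (1, 1.25, 1.75) mm^2 annuli
#' @export
build_compartments <- function(annotation, margin_width = 500) {
  if (!inherits(annotation, "region_annotation")) {
    annotation <- region_annotation(annotation)
  }
  stopifnot_scalar_pos(margin_width, "margin_width")
  tumor <- annotation$tumor

  core <- tryCatch(
    spatstat.geom::erosion(tumor, margin_width, polygonal = TRUE),
    error = function(e) NULL
  )
  if (is.null(core) || spatstat.geom::is.empty(core) ||
      spatstat.geom::area.owin(core) <= 0) {
    warning("erosion by ", margin_width,
            " um annihilates the tumor core; TU_CORE is empty", call. = FALSE)
    core <- empty_owin(tumor)
  }

  dil <- spatstat.geom::dilation(tumor, margin_width, polygonal = TRUE,
                                 tight = FALSE)
  inner <- spatstat.geom::setminus.owin(tumor, core)
  outer <- spatstat.geom::setminus.owin(dil, tumor)

  if (!is.null(annotation$tissue)) {
    clip <- function(w) {
      out <- spatstat.geom::intersect.owin(w, annotation$tissue, fatal = FALSE)
      if (is.null(out)) empty_owin(tumor) else out
    }
    core <- clip(core); inner <- clip(inner); outer <- clip(outer)
  }

  geoms <- list(TU_CORE = core, MARG_500_IN = inner, MARG_500_OUT = outer)
  areas <- vapply(geoms, owin_area_mm2, numeric(1L))
  structure(
    list(geoms = geoms, areas = areas, margin_width = margin_width,
         tumor = tumor, tissue = annotation$tissue),
    class = "compartment_set"
  )
}

#' @export
print.compartment_set <- function(x, ...) {
  cat("Compartment set (margin", x$margin_width, "um); areas in mm^2:\n")
  print(round(x$areas, 4))
  invisible(x)
}

# Minimum Euclidean distance from each point to the boundary segments of a
# polygonal window. Vectorized over points, looped over segments.
dist_to_boundary <- function(px, py, w) {
  d <- rep(Inf, length(px))
  for (ring in spatstat.geom::as.polygonal(w)$bdry) {
    x <- ring$x; y <- ring$y
    n <- length(x)
    x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
    for (i in seq_len(n)) {
      vx <- x2[i] - x[i]; vy <- y2[i] - y[i]
      len2 <- vx * vx + vy * vy
      t <- if (len2 > 0) pmin(1, pmax(0, ((px - x[i]) * vx + (py - y[i]) * vy) / len2)) else 0
      dx <- px - (x[i] + t * vx); dy <- py - (y[i] + t * vy)
      d <- pmin(d, sqrt(dx * dx + dy * dy))
    }
  }
  d
}

#' Assign points to compartments
#'
#' Assigns each (x, y) location to exactly one compartment or to
#' `"unassigned"` when it lies outside the outer margin. The core/margin
#' split uses the exact Euclidean distance to the tumor boundary, so a point
#' exactly on a compartment boundary is assigned to the innermost containing
#' compartment (core before inner margin before outer margin), which makes
#' assignment deterministic and order-stable. Points outside the tissue
#' polygon (when present) are unassigned.
#'
#' @param x,y point coordinates in micrometres.
#' @param compartments a [build_compartments()] result.
#' @return a factor with levels `TU_CORE`, `MARG_500_IN`, `MARG_500_OUT`,
#'   `unassigned`, one per point.
#' @export
assign_cells <- function(x, y, compartments) {
  stopifnot(inherits(compartments, "compartment_set"), length(x) == length(y))
  tol <- 1e-9
  m <- compartments$margin_width
  d <- dist_to_boundary(x, y, compartments$tumor)
  in_tumor <- spatstat.geom::inside.owin(x, y, compartments$tumor) | d <= tol
  out <- rep("unassigned", length(x))
  out[in_tumor & d >= m - tol] <- "TU_CORE"
  out[in_tumor & d < m - tol] <- "MARG_500_IN"
  out[!in_tumor & d <= m + tol] <- "MARG_500_OUT"
  if (!is.null(compartments$tissue)) {
    dt <- dist_to_boundary(x, y, compartments$tissue)
    in_tissue <- spatstat.geom::inside.owin(x, y, compartments$tissue) | dt <= tol
    out[!in_tissue] <- "unassigned"
  }
  factor(out, levels = c(COMPARTMENTS, "unassigned"))
}

#' Count positive cells per compartment
#'
#' Counts `cell_class == "positive"` records per compartment; negative
#' records are accepted but ignored (their number is returned as an
#' attribute), mirroring how cell-detection exports carry both classes.
#'
#' @param cells data.frame with columns `x_um`, `y_um` and optionally
#'   `cell_class` (all records count as positive when absent).
#' @param compartments a [build_compartments()] result.
#' @return named integer vector of counts over the three compartments, with
#'   attributes `unassigned` (positive cells outside all compartments) and
#'   `n_negative` (ignored negative records).
#' @export
compartment_counts <- function(cells, compartments) {
  stopifnot(is.data.frame(cells))
  if (!all(c("x_um", "y_um") %in% names(cells))) {
    stop("'cells' needs columns x_um and y_um", call. = FALSE)
  }
  pos <- if ("cell_class" %in% names(cells)) cells$cell_class == "positive" else rep(TRUE, nrow(cells))
  n_neg <- sum(!pos)
  cells <- cells[pos, , drop = FALSE]
  asg <- assign_cells(cells$x_um, cells$y_um, compartments)
  tab <- table(asg)
  counts <- as.integer(tab[COMPARTMENTS])
  names(counts) <- COMPARTMENTS
  structure(counts,
            unassigned = as.integer(tab[["unassigned"]]),
            n_negative = as.integer(n_neg))
}

#' Convert counts and areas to densities
#'
#' Density is count / area in cells/mm^2. Compartments with zero area yield
#' `NA` (never 0 or infinity): a slide whose core was annihilated simply has
#' no core density.
#'
#' @param counts named non-negative counts.
#' @param areas named non-negative areas in mm^2, same names as `counts`.
#' @return named numeric densities in cells/mm^2.
#' @export
compartment_densities <- function(counts, areas) {
  if (!all(names(counts) %in% names(areas))) {
    stop("'counts' and 'areas' must share names", call. = FALSE)
  }
  areas <- areas[names(counts)]
  if (any(counts < 0, na.rm = TRUE) || any(areas < 0, na.rm = TRUE)) {
    stop("counts and areas must be non-negative", call. = FALSE)
  }
  dens <- ifelse(areas > 0, counts / areas, NA_real_)
  names(dens) <- names(counts)
  dens
}

#' Per-slide density table
#'
#' Runs assignment and density computation for every marker on a slide and
#' returns the long-format density table consumed by the classification and
#' clustering stages.
#'
#' @param cells data.frame with columns `slide_id`, `marker`, `x_um`, `y_um`,
#'   `cell_class`.
#' @param compartments a [build_compartments()] result for this slide.
#' @param slide_id slide identifier; defaults to the one in `cells`.
#' @return data.frame with columns `slide_id`, `marker`, `compartment`,
#'   `count`, `area_mm2`, `density`.
#' @export
slide_densities <- function(cells, compartments, slide_id = NULL) {
  stopifnot(is.data.frame(cells))
  if (is.null(slide_id)) {
    slide_id <- if (nrow(cells)) as.character(cells$slide_id[1L]) else "slide"
  }
  markers <- unique(as.character(cells$marker))
  if (!length(markers)) markers <- character(0)
  out <- lapply(markers, function(m) {
    cnt <- compartment_counts(cells[cells$marker == m, , drop = FALSE], compartments)
    data.frame(
      slide_id = slide_id, marker = m, compartment = COMPARTMENTS,
      count = as.integer(cnt), area_mm2 = unname(compartments$areas),
      density = unname(compartment_densities(cnt, compartments$areas)),
      stringsAsFactors = FALSE
    )
  })
  if (!length(out)) {
    return(data.frame(slide_id = character(), marker = character(),
                      compartment = character(), count = integer(),
                      area_mm2 = numeric(), density = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
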