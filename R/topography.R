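# Topography classification: percentile normalization, pooled median
# cutoffs, compartment collapsing, cold / immune-excluded / hot labels, and
# bivariate phenotype grids.
#
# Classification always operates on absolute densities (cells/mm^2);
# percentile normalization is used for visualization (target plots) and for
# the cross-entity similarity analysis only.

#' Percentile-normalize a vector of densities
#'
#' Quantile normalization with 100 quantiles: value i maps to
#' `100 * (rank_i - 0.5) / n` with average ranks for ties, computed over the
#' non-missing values. Outputs lie strictly inside (0, 100); missing values
#' propagate as missing. Any strictly monotone transform of the input leaves
#' the output unchanged.
#'
#' @param values numeric vector of densities for one marker (NAs allowed).
#' @return numeric vector of percentiles, same length and order.
#' @export
percentile_normalize <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) stop("all values are missing", call. = FALSE)
  n <- sum(ok)
  out <- rep(NA_real_, length(values))
  out[ok] <- 100 * (rank(values[ok], ties.method = "average") - 0.5) / n
  out
}

#' Pooled median cutoffs per marker
#'
#' The cutoff separating "high" from "low" density for a marker is the
#' median density over all slides, all tumor entities and all three
#' compartments pooled (one observation per slide x compartment), mirroring
#' a cohort-wide median split.
#'
#' @param profile density table with columns `marker` and `density`
#'   (e.g. from [slide_densities()] rows bound over slides).
#' @return data.frame with columns `marker`, `cutoff`, `n_obs`.
#' @export
median_cutoffs <- function(profile) {
  stopifnot(is.data.frame(profile), all(c("marker", "density") %in% names(profile)))
  if (!nrow(profile)) stop("empty density profile", call. = FALSE)
  markers <- unique(as.character(profile$marker))
  out <- lapply(markers, function(m) {
    d <- profile$density[profile$marker == m]
    d <- d[!is.na(d)]
    if (length(d) < 3L) {
      warning("marker ", m, " has fewer than 3 observations; cutoff unstable",
              call. = FALSE)
    }
    data.frame(marker = m, cutoff = stats::median(d), n_obs = length(d),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Inside density of a slide, pooled or core-only
#'
#' The tumor core and inner invasive margin are highly correlated and can be
#' collapsed into one "inside" compartment. Pooled mode computes
#' `(count_core + count_inner) / (area_core + area_inner)`, a count-weighted
#' pooling that always lies between the two compartment densities;
#' `core_only` returns the tumor-core density alone.
#'
#' @param counts named counts including `TU_CORE` and `MARG_500_IN`.
#' @param areas named areas (mm^2) with the same names.
#' @param mode `"pooled"` (default) or `"core_only"`.
#' @return single density in cells/mm^2, `NA` when the relevant area is 0.
#' @export
inside_density <- function(counts, areas, mode = c("pooled", "core_only")) {
  mode <- match.arg(mode)
  need <- if (mode == "pooled") c("TU_CORE", "MARG_500_IN") else "TU_CORE"
  if (!all(need %in% names(counts)) || !all(need %in% names(areas))) {
    stop("counts/areas must name compartments ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  a <- sum(areas[need]); k <- sum(counts[need])
  if (is.na(a) || a <= 0) return(NA_real_)
  k / a
}

#' Classify a slide as cold, immune-excluded or hot
#'
#' The rule: inside density above the cutoff is hot regardless of the
#' outside density; inside at or below the cutoff with outside above it is
#' immune-excluded; both at or below are cold. "High" means strictly greater
#' than the cutoff, so a density exactly at the median counts as low.
#' Vectorized; missing inside or outside densities yield `NA`.
#'
#' @param inside inside density (pooled or core-only), cells/mm^2.
#' @param outside outer invasive margin density, cells/mm^2.
#' @param cutoff positive cutoff density, cells/mm^2.
#' @return factor with levels cold, excluded, hot.
#' @export
classify_topography <- function(inside, outside, cutoff) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  lab <- ifelse(is.na(inside) | is.na(outside), NA_character_,
                ifelse(inside > cutoff, "hot",
                       ifelse(outside > cutoff, "excluded", "cold")))
  factor(lab, levels = TOPO_LEVELS)
}

#' Label every slide x marker in a density table
#'
#' Joins the per-compartment density table with per-marker cutoffs and
#' applies [classify_topography()]. Slides missing a required compartment
#' (for example an annihilated core with `core_only` mode, or a missing
#' outer margin) are returned with `NA` labels rather than imputed.
#'
#' @param profile density table with columns `slide_id`, `marker`,
#'   `compartment`, `count`, `area_mm2`, `density`.
#' @param cutoffs data.frame `marker`, `cutoff` (see [median_cutoffs()]), or
#'   a named numeric vector.
#' @param mode inside-density mode, `"pooled"` or `"core_only"`.
#' @return data.frame `slide_id`, `marker`, `inside_density`,
#'   `outside_density`, `label` with attribute `inside_mode`.
#' @export
classify_slides <- function(profile, cutoffs, mode = c("pooled", "core_only")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(profile))
  if (is.data.frame(cutoffs)) {
    cutoffs <- stats::setNames(cutoffs$cutoff, cutoffs$marker)
  }
  keys <- unique(profile[, c("slide_id", "marker")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- profile[profile$slide_id == keys$slide_id[i] &
                     profile$marker == keys$marker[i], , drop = FALSE]
    counts <- stats::setNames(sub$count, sub$compartment)
    areas <- stats::setNames(sub$area_mm2, sub$compartment)
    ins <- tryCatch(inside_density(counts, areas, mode),
                    error = function(e) NA_real_)
    out_row <- sub[sub$compartment == "MARG_500_OUT", , drop = FALSE]
    outs <- if (nrow(out_row)) out_row$density[1L] else NA_real_
    data.frame(slide_id = keys$slide_id[i], marker = keys$marker[i],
               inside_density = ins, outside_density = outs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  lab <- rep(NA_character_, nrow(res))
  for (m in unique(as.character(res$marker))) {
    sel <- res$marker == m
    if (is.na(cutoffs[m])) next
    lab[sel] <- as.character(classify_topography(
      res$inside_density[sel], res$outside_density[sel], cutoffs[[m]]))
  }
  res$label <- factor(lab, levels = TOPO_LEVELS)
  attr(res, "inside_mode") <- mode
  res
}

#' Between-compartment correlation structure
#'
#' Correlations between the three compartment densities across slides,
#' computed per marker (or per marker and entity) on pairwise-complete
#' observations. A high core/inner-margin correlation together with low
#' correlations to the outer margin is the empirical basis for collapsing
#' core and inner margin into a single "inside" compartment.
#'
#' @param profile density table (`slide_id`, `marker`, `compartment`,
#'   `density`), optionally with an `entity` column.
#' @param per `"marker"` or `"marker_entity"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return named list, one element per group, each with `r` (3x3 correlation
#'   matrix) and `n` (3x3 pair counts). Entries with fewer than 3 pairs are
#'   `NA`.
#' @export
compartment_correlations <- function(profile, per = c("marker", "marker_entity"),
                                     method = c("pearson", "spearman")) {
  per <- match.arg(per); method <- match.arg(method)
  stopifnot(is.data.frame(profile))
  key <- if (per == "marker") as.character(profile$marker) else
    paste(profile$marker, profile$entity, sep = ":")
  out <- list()
  for (g in unique(key)) {
    sub <- profile[key == g, , drop = FALSE]
    wide <- stats::reshape(
      sub[, c("slide_id", "compartment", "density")],
      idvar = "slide_id", timevar = "compartment", direction = "wide")
    cols <- paste0("density.", COMPARTMENTS)
    missing_cols <- setdiff(cols, names(wide))
    for (mc in missing_cols) wide[[mc]] <- NA_real_
    m <- as.matrix(wide[, cols])
    colnames(m) <- COMPARTMENTS
    r <- matrix(NA_real_, 3L, 3L, dimnames = list(COMPARTMENTS, COMPARTMENTS))
    nmat <- matrix(0L, 3L, 3L, dimnames = list(COMPARTMENTS, COMPARTMENTS))
    for (i in 1:3) for (j in 1:3) {
      ok <- !is.na(m[, i]) & !is.na(m[, j])
      nmat[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; next }
      if (sum(ok) >= 3L && stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
        r[i, j] <- stats::cor(m[ok, i], m[ok, j], method = method)
      }
    }
    out[[g]] <- list(r = r, n = nmat)
  }
  out
}

#' Bivariate 3x3 phenotype count grid
#'
#' Cross-tabulates the topography labels of two markers over the slides
#' labeled for both. Marginals equal the univariate label counts on that
#' intersection.
#'
#' @param labels_a,labels_b named (by slide id) label vectors/factors, or
#'   data.frames with `slide_id` and `label` columns.
#' @return 3x3 integer matrix, rows = marker A label, cols = marker B label.
#' @export
bivariate_table <- function(labels_a, labels_b) {
  grab <- function(l) {
    if (is.data.frame(l)) stats::setNames(as.character(l$label), l$slide_id)
    else stats::setNames(as.character(l), names(l))
  }
  a <- grab(labels_a); b <- grab(labels_b)
  common <- intersect(names(a)[!is.na(a)], names(b)[!is.na(b)])
  if (!length(common)) stop("no slides labeled for both markers", call. = FALSE)
  table(factor(a[common], levels = TOPO_LEVELS),
        factor(b[common], levels = TOPO_LEVELS))
}

#' Per-entity distribution of topography phenotypes
#'
#' @param labels label vector/factor (cold/excluded/hot, NAs allowed).
#' @param entity tumor-type code per slide, same length.
#' @return data.frame `entity`, `cold`, `excluded`, `hot`, `n`; proportions
#'   over non-missing labels sum to 1 per entity. Entities with no
#'   non-missing labels are omitted with a warning.
#' @export
phenotype_distribution <- function(labels, entity) {
  stopifnot(length(labels) == length(entity))
  labels <- factor(as.character(labels), levels = TOPO_LEVELS)
  out <- list()
  for (e in unique(as.character(entity))) {
    l <- labels[entity == e]
    l <- l[!is.na(l)]
    if (!length(l)) {
      warning("entity ", e, " has no non-missing labels; omitted", call. = FALSE)
      next
    }
    p <- as.numeric(table(l)) / length(l)
    out[[e]] <- data.frame(entity = e, cold = p[1L], excluded = p[2L],
                           hot = p[3L], n = length(l), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(entity = character(), cold = numeric(),
                      excluded = numeric(), hot = numeric(), n = integer()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# percentile of new values within a reference vector, consistent with
# percentile_normalize applied to c(reference, v) and read at v
percentile_within <- function(v, reference) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("empty reference", call. = FALSE)
  n <- length(reference)
  vapply(v, function(vi) {
    if (is.na(vi)) return(NA_real_)
    100 * (sum(reference < vi) + (sum(reference == vi) + 1) / 2) / (n + 1)
  }, numeric(1L))
}

#' Target-plot ring values for one slide and marker
#'
#' Maps the slide's three compartment densities to their percentile within
#' the reference cohort's pooled densities for that marker, ordered for
#' display as concentric rings: outer margin, inner margin, core.
#'
#' @param slide_densities named densities with names among the three
#'   compartments (missing compartments give missing rings).
#' @param reference numeric vector of pooled reference densities for the
#'   marker (all slides x compartments).
#' @return named numeric of length 3: `MARG_500_OUT`, `MARG_500_IN`,
#'   `TU_CORE`, values in (0, 100).
#' @export
target_plot_data <- function(slide_densities, reference) {
  ring_order <- rev(COMPARTMENTS)
  v <- stats::setNames(rep(NA_real_, 3L), ring_order)
  present <- intersect(names(slide_densities), ring_order)
  v[present] <- percentile_within(as.numeric(slide_densities[present]), reference)
  v
}

#' Draw a target plot
#'
#' Concentric-ring visualization of percentile-normalized densities: outer
#' ring = outer invasive margin, middle ring = inner invasive margin, bull's
#' eye = tumor core.
#'
#' @param rings output of [target_plot_data()].
#' @param main plot title.
#' @param palette function mapping \[0, 1\] to colors.
#' @return invisibly, the ring values.
#' @export
plot_target <- function(rings, main = "",
                        palette = grDevices::colorRampPalette(c("navy", "white", "firebrick"))) {
  cols <- palette(101)
  idx <- function(p) if (is.na(p)) NA_integer_ else round(p) + 1L
  radii <- c(1, 2 / 3, 1 / 3)
  graphics::plot.new()
  graphics::plot.window(c(-1.1, 1.1), c(-1.1, 1.1), asp = 1)
  th <- seq(0, 2 * pi, length.out = 181)
  for (i in 1:3) {
    ci <- idx(rings[[i]])
    graphics::polygon(radii[i] * cos(th), radii[i] * sin(th),
                      col = if (is.na(ci)) "grey80" else cols[ci],
                      border = "grey30")
  }
  graphics::title(main = main)
  invisible(rings)
}
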