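# Readers and writers for the pipeline's exchange formats: GeoJSON region
# annotations, delimited cell tables, clinical tables and stage outputs.
# Coordinates in the files are micrometres.

#' Read a region annotation from GeoJSON
#'
#' Expects a FeatureCollection whose features carry a `name` property equal
#' to `TUMOR` or `TISSUE` and a Polygon or MultiPolygon geometry with
#' coordinates in micrometres. Only the outer ring of each polygon is used
#' (annotation holes are not supported).
#'
#' @param path GeoJSON file path.
#' @return a [region_annotation()].
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  rings_for <- function(feature) {
    geom <- feature$geometry
    ring_to_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
    }
    switch(geom$type,
           Polygon = list(ring_to_mat(geom$coordinates[[1L]])),
           MultiPolygon = lapply(geom$coordinates,
                                 function(po) ring_to_mat(po[[1L]])),
           stop("unsupported geometry type: ", geom$type, call. = FALSE))
  }
  tumor <- NULL; tissue <- NULL
  for (f in gj$features) {
    nm <- toupper(f$properties$name %||% "")
    if (nm == "TUMOR") tumor <- c(tumor %||% list(), rings_for(f))
    if (nm == "TISSUE") tissue <- c(tissue %||% list(), rings_for(f))
  }
  if (is.null(tumor)) {
    stop("no feature with name 'TUMOR' in ", path, call. = FALSE)
  }
  region_annotation(tumor, tissue)
}

owin_rings <- function(w) {
  lapply(w$bdry, function(b) {
    # close the ring explicitly, GeoJSON style
    xs <- c(b$x, b$x[1L]); ys <- c(b$y, b$y[1L])
    lapply(seq_along(xs), function(i) c(xs[i], ys[i]))
  })
}

#' Write a region annotation to GeoJSON
#'
#' @param annotation a [region_annotation()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_regions_geojson <- function(annotation, path) {
  stopifnot(inherits(annotation, "region_annotation"))
  feat <- function(w, name) {
    rings <- owin_rings(spatstat.geom::as.polygonal(w))
    geometry <- if (length(rings) == 1L) {
      list(type = "Polygon", coordinates = rings)
    } else {
      list(type = "MultiPolygon", coordinates = lapply(rings, list))
    }
    list(type = "Feature", properties = list(name = name), geometry = geometry)
  }
  features <- list(feat(annotation$tumor, "TUMOR"))
  if (!is.null(annotation$tissue)) {
    features <- c(features, list(feat(annotation$tissue, "TISSUE")))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a cell-centroid table (CSV or TSV)
#'
#' Columns: `slide_id`, `marker`, `x_um`, `y_um`, `cell_class`
#' (`positive`/`negative`; missing column means all positive). The delimiter
#' is auto-detected from the header line.
#'
#' @param path file path.
#' @return data.frame of cell records.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("cells file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("cells file is empty: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  if (!nrow(df)) stop("cells file has no records: ", path, call. = FALSE)
  need <- c("slide_id", "marker", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("cells file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"cell_class" %in% names(df)) df$cell_class <- "positive"
  if (!all(is.finite(df$x_um)) || !all(is.finite(df$y_um))) {
    stop("cell coordinates must be finite", call. = FALSE)
  }
  df
}

#' Write a cell table as CSV
#' @param cells data.frame of cell records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells[, c("slide_id", "marker", "x_um", "y_um", "cell_class")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clinical table CSV
#'
#' Columns: `patient_id`, `time`, `event`, `stage`, `age`, `sex`.
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("clinical file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$event <- as.logical(df$event)
  df
}

#' Write a clinical table as CSV
#' @param clinical data.frame with at least patient_id, time, event.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_clinical_csv <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated cohort to a directory of standard files
#'
#' Materializes a [simulate_cohort()] result (run with `make_slides = TRUE`)
#' as the on-disk layout the pipeline consumes: `cells.csv`, one
#' `regions/<slide_id>.geojson` per slide, `clinical.csv` and the ground
#' truth `truth.csv`.
#'
#' @param cohort a `sim_cohort` with slides.
#' @param out_dir output directory (created if needed).
#' @return the output directory, invisibly.
#' @export
simulate_cohort_files <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$slides)) {
    stop("cohort was simulated without slides (make_slides = FALSE)",
         call. = FALSE)
  }
  dir.create(file.path(out_dir, "regions"), recursive = TRUE,
             showWarnings = FALSE)
  cells <- do.call(rbind, lapply(cohort$slides, function(s) s$cells))
  write_cells_csv(cells, file.path(out_dir, "cells.csv"))
  for (s in cohort$slides) {
    write_regions_geojson(region_annotation(s$polygon),
                          file.path(out_dir, "regions",
                                    paste0(s$slide_id, ".geojson")))
  }
  write_clinical_csv(
    cohort$clinical[, c("patient_id", "time", "event", "stage", "age", "sex")],
    file.path(out_dir, "clinical.csv"))
  truth <- do.call(rbind, lapply(cohort$slides, function(s) {
    data.frame(slide_id = s$slide_id, marker = names(s$truth),
               label = unname(s$truth), stringsAsFactors = FALSE)
  }))
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(out_dir)
}
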