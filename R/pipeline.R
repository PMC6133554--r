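# End-to-end orchestration: geometry -> densities -> cutoffs -> labels ->
# bivariate grids -> optional clustering -> optional survival, under one
# YAML-configurable run with a content-hashed manifest.

default_config <- function() {
  list(
    paths = list(cells = NULL, regions = NULL, clinical = NULL, output = "."),
    margin_width = 500,
    inside_mode = "pooled",
    markers = NULL,
    cutoffs = "computed",      # "computed" or a CSV path (marker, cutoff)
    clustering = list(enabled = FALSE,
                      methods = c("gmm", "kmeans", "hierarchical"),
                      criteria = c("davies_bouldin", "calinski_harabasz",
                                   "silhouette"),
                      k_min = 1, k_max = 12, replicates = 10),
    survival = list(enabled = FALSE,
                    covariates = c("stage", "age", "sex"),
                    reference = NULL,
                    markers = c("CD8", "CD163")),
    seed = 1
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' @param config a YAML file path or a named list; unspecified fields take
#'   the package defaults (500 um margin, pooled inside density, computed
#'   median cutoffs, k = 1..12 with 10 replicates, double-cold reference).
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  stopifnot_scalar_pos(cfg$margin_width, "margin_width")
  cfg$inside_mode <- match.arg(cfg$inside_mode, c("pooled", "core_only"))
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  for (p in c("cells", "regions")) {
    if (is.null(cfg$paths[[p]])) {
      stop("config must set paths$", p, call. = FALSE)
    }
    if (!file.exists(cfg$paths[[p]])) {
      stop("path does not exist: ", cfg$paths[[p]], call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

read_region_dir <- function(regions_path, slide_ids) {
  if (dir.exists(regions_path)) {
    files <- stats::setNames(
      file.path(regions_path, paste0(slide_ids, ".geojson")), slide_ids)
    missing <- !file.exists(files)
    if (any(missing)) {
      stop("no region annotation for slide(s): ",
           paste(slide_ids[missing], collapse = ", "), call. = FALSE)
    }
    lapply(files, read_regions_geojson)
  } else {
    # single shared annotation file
    ann <- read_regions_geojson(regions_path)
    stats::setNames(rep(list(ann), length(slide_ids)), slide_ids)
  }
}

#' Run the full immune-topography pipeline
#'
#' Stages: read cells and region annotations; build compartments per slide;
#' compute the per-slide density table; derive (or load) per-marker median
#' cutoffs; classify every slide x marker into cold/excluded/hot; build the
#' bivariate phenotype grid for every marker pair; optionally run the
#' cluster-number protocol on the density feature matrix; optionally join
#' the clinical table and fit the phenotype-stratified survival models. All
#' stage outputs are written as CSV under the configured output directory
#' and listed, with MD5 content hashes, in `manifest.json`.
#'
#' @param config a [pipeline_config()], YAML path or list.
#' @return invisibly, a list with all stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  out_dir <- cfg$paths$output %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cells <- read_cells(cfg$paths$cells)
  if (!is.null(cfg$markers)) cells <- cells[cells$marker %in% cfg$markers, ]
  slide_ids <- unique(cells$slide_id)
  regions <- read_region_dir(cfg$paths$regions, slide_ids)

  # stage 1: geometry + densities
  density_tab <- do.call(rbind, lapply(slide_ids, function(sid) {
    cs <- build_compartments(regions[[sid]], cfg$margin_width)
    slide_densities(cells[cells$slide_id == sid, , drop = FALSE], cs,
                    slide_id = sid)
  }))

  # stage 2: cutoffs
  cutoffs <- if (identical(cfg$cutoffs, "computed")) {
    median_cutoffs(density_tab)
  } else {
    utils::read.csv(cfg$cutoffs, stringsAsFactors = FALSE)
  }

  # stage 3: labels
  labels <- classify_slides(density_tab, cutoffs, mode = cfg$inside_mode)

  # stage 4: bivariate grids for every marker pair
  markers <- unique(as.character(density_tab$marker))
  bivar <- list()
  if (length(markers) >= 2L) {
    pairs <- utils::combn(markers, 2L, simplify = FALSE)
    for (pr in pairs) {
      tab <- tryCatch(
        bivariate_table(labels[labels$marker == pr[1L], ],
                        labels[labels$marker == pr[2L], ]),
        error = function(e) NULL)
      if (!is.null(tab)) bivar[[paste(pr, collapse = "_")]] <- tab
    }
  }

  results <- list(config = cfg, densities = density_tab, cutoffs = cutoffs,
                  labels = labels, bivariate = bivar)

  # stage 5 (optional): cluster-number protocol on the density matrix
  if (isTRUE(cfg$clustering$enabled)) {
    # slide x (marker x compartment) feature matrix of absolute densities
    X <- local({
      keys <- unique(density_tab[, c("marker", "compartment")])
      m <- matrix(NA_real_, length(slide_ids), nrow(keys),
                  dimnames = list(slide_ids,
                                  paste(keys$marker, keys$compartment, sep = ".")))
      for (r in seq_len(nrow(density_tab))) {
        m[density_tab$slide_id[r],
          paste(density_tab$marker[r], density_tab$compartment[r], sep = ".")] <-
          density_tab$density[r]
      }
      m
    })
    runs <- cluster_scores(
      X,
      methods = cfg$clustering$methods, criteria = cfg$clustering$criteria,
      k_range = seq(cfg$clustering$k_min, cfg$clustering$k_max),
      replicates = cfg$clustering$replicates, seed = cfg$seed)
    results$cluster_runs <- runs
    results$cluster_summary <- modal_optimum(runs)
  }

  # stage 6 (optional): survival
  if (isTRUE(cfg$survival$enabled)) {
    if (is.null(cfg$paths$clinical)) {
      stop("survival stage enabled but paths$clinical not set", call. = FALSE)
    }
    clinical <- read_clinical(cfg$paths$clinical)
    mk <- cfg$survival$markers
    la <- labels[labels$marker == mk[1L], c("slide_id", "label")]
    lb <- labels[labels$marker == mk[2L], c("slide_id", "label")]
    joined <- merge(merge(clinical, la, by.x = "patient_id", by.y = "slide_id"),
                    lb, by.x = "patient_id", by.y = "slide_id",
                    suffixes = c("_a", "_b"))
    ok <- !is.na(joined$label_a) & !is.na(joined$label_b)
    joined$phenotype <- ifelse(ok, sprintf("%s-%s_%s-%s", mk[1L],
                                           joined$label_a, mk[2L],
                                           joined$label_b), NA_character_)
    results$patients <- joined
    complete <- joined[!is.na(joined$phenotype), , drop = FALSE]
    # fall back to the most prevalent phenotype with an event when the
    # configured (default double-cold) reference cell is empty or event-free
    ref <- cfg$survival$reference %||% phenotype_levels(mk)[1L]
    ref_events <- sum(complete$event[complete$phenotype == ref])
    if (!ref_events) {
      ev_by_ph <- tapply(complete$event, complete$phenotype, sum)
      ev_by_ph <- ev_by_ph[!is.na(ev_by_ph) & ev_by_ph > 0]
      n_by_ph <- table(complete$phenotype)[names(ev_by_ph)]
      ref <- names(n_by_ph)[which.max(n_by_ph)]
      warning("reference phenotype has no events; using ", ref, call. = FALSE)
    }
    results$hazard <- phenotype_hazard_table(
      complete, markers = mk, reference = ref,
      covariates = cfg$survival$covariates)
    results$km <- km_estimate(joined[!is.na(joined$phenotype), ],
                              group = joined$phenotype[!is.na(joined$phenotype)])
    if (length(unique(stats::na.omit(joined$phenotype))) >= 2L) {
      keep <- !is.na(joined$phenotype)
      results$logrank <- logrank_test(joined[keep, ], joined$phenotype[keep])
    }
  }

  # write outputs + manifest
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  files <- c(
    wcsv(density_tab, "densities.csv"),
    wcsv(cutoffs, "cutoffs.csv"),
    wcsv(labels, "labels.csv")
  )
  for (nm in names(bivar)) {
    df <- as.data.frame(bivar[[nm]])
    names(df) <- c("label_a", "label_b", "count")
    files <- c(files, wcsv(df, paste0("bivariate_", nm, ".csv")))
  }
  if (!is.null(results$cluster_runs)) {
    files <- c(files, wcsv(results$cluster_runs$best, "cluster_best_k.csv"),
               wcsv(results$cluster_summary$by_combination,
                    "cluster_summary.csv"))
  }
  if (!is.null(results$hazard)) {
    files <- c(files, wcsv(results$hazard$table, "hazard_table.csv"),
               wcsv(results$km, "km_curves.csv"))
  }
  manifest <- list(
    package = "immunotopo",
    version = as.character(utils::packageVersion("immunotopo")),
    seed = cfg$seed,
    margin_width = cfg$margin_width,
    inside_mode = cfg$inside_mode,
    n_slides = length(slide_ids),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}

#' Replicate concordance check
#'
#' Pearson correlation between paired per-slide densities measured on
#' replicate slides, the reproducibility check for a digital-pathology
#' pipeline (adjacent sections, re-annotated and re-counted, are expected to
#' correlate strongly).
#'
#' @param densities_a,densities_b paired density vectors (same slides, same
#'   order); pairs with a missing value are dropped.
#' @return list `r`, `p` (two-sided), `n`.
#' @export
replicate_concordance <- function(densities_a, densities_b) {
  stopifnot(length(densities_a) == length(densities_b))
  ok <- !is.na(densities_a) & !is.na(densities_b)
  a <- densities_a[ok]; b <- densities_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a replicate vector", call. = FALSE)
  }
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}
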