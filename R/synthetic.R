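# Synthetic cohort: tumor shapes, inhomogeneous Poisson cell patterns with
# known topography archetypes, and survival outcomes with known hazard
# ratios. Every downstream stage of the pipeline is testable against the
# ground truth carried by these generators.

# ---- archetypes -------------------------------------------------------------

#' Topography archetype: piecewise-constant intensities per compartment
#'
#' An archetype fixes the expected cell density (cells/mm^2) in each of the
#' three compartments. The intensity model is piecewise constant per
#' compartment, which matches the per-compartment density readout and keeps
#' Poisson count expectations analytic.
#'
#' @param label one of `"hot"`, `"cold"`, `"excluded"`.
#' @param lambda_core,lambda_inner,lambda_outer intensities in cells/mm^2.
#' @param cutoff optional classification cutoff the archetype is generated
#'   against; when supplied, the label is checked for consistency with the
#'   classification rule (hot: pooled inside intensity above the cutoff;
#'   excluded: inside at or below and outside above; cold: both at or below).
#' @return an object of class `archetype_spec`.
#' @export
archetype_spec <- function(label, lambda_core, lambda_inner, lambda_outer,
                           cutoff = NULL) {
  label <- match.arg(label, TOPO_LEVELS)
  lam <- c(TU_CORE = lambda_core, MARG_500_IN = lambda_inner,
           MARG_500_OUT = lambda_outer)
  if (any(!is.finite(lam)) || any(lam < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(cutoff)) {
    # pooled inside intensity for roughly equal core/inner areas
    inside <- mean(c(lambda_core, lambda_inner))
    implied <- as.character(classify_topography(inside, lambda_outer, cutoff))
    if (implied != label) {
      stop(sprintf("intensities imply label '%s', not '%s'", implied, label),
           call. = FALSE)
    }
  }
  structure(list(label = label, lambda = lam), class = "archetype_spec")
}

#' Standard hot / cold / excluded archetypes around a cutoff
#'
#' Intensities are placed at `separation` times the cutoff on the high side
#' and `cutoff / separation` on the low side, i.e. a `separation^2`-fold
#' dynamic range. With the default 4-fold separation the Poisson sampling
#' noise of realistic compartment areas almost never crosses the cutoff, so
#' these archetypes are recovered by the classifier with high probability.
#'
#' @param cutoff classification cutoff in cells/mm^2.
#' @param separation fold-change between each intensity and the cutoff.
#' @return named list of three [archetype_spec()] objects.
#' @export
archetype_presets <- function(cutoff = 25, separation = 4) {
  stopifnot_scalar_pos(cutoff, "cutoff")
  stopifnot_scalar_pos(separation, "separation")
  hi <- cutoff * separation
  lo <- cutoff / separation
  list(
    hot      = archetype_spec("hot", hi, hi, lo, cutoff = cutoff),
    cold     = archetype_spec("cold", lo, lo, lo, cutoff = cutoff),
    excluded = archetype_spec("excluded", lo, lo, hi, cutoff = cutoff)
  )
}

# ---- tumor shapes -----------------------------------------------------------

#' Generate a random tumor boundary polygon
#'
#' Builds a star-shaped polygon by radial perturbation of a circle:
#' `n_vertices` equally spaced angles get radii
#' `mean_radius * (1 + irregularity * u)` with `u` uniform on (-1, 1),
#' lightly smoothed along the boundary so the outline resembles a tumor
#' front rather than a noise burst. Star-shaped polygons around the origin
#' are simple by construction; simplicity is verified and the perturbation
#' is re-drawn (up to 20 times) in the degenerate case.
#'
#' @param seed integer seed; identical inputs give vertex-identical polygons.
#' @param mean_radius mean radius in micrometres.
#' @param irregularity relative radial perturbation amplitude, >= 0;
#'   0 gives a regular polygon approximation of the circle.
#' @param n_vertices number of vertices (>= 8).
#' @return a data.frame of `x`, `y` vertices in um (counter-clockwise,
#'   not explicitly closed).
#' @examples
#' p <- generate_tumor_shape(seed = 1, mean_radius = 1500)
#' @export
generate_tumor_shape <- function(seed, mean_radius = 1500, irregularity = 0.3,
                                 n_vertices = 64) {
  stopifnot_scalar_pos(mean_radius, "mean_radius")
  if (irregularity < 0) stop("'irregularity' must be >= 0", call. = FALSE)
  if (n_vertices < 8) stop("'n_vertices' must be >= 8", call. = FALSE)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  with_seed(seed, {
    for (attempt in 1:20) {
      u <- stats::runif(n_vertices, -1, 1)
      # circular moving average (window 3) smooths the outline
      u <- (u + u[c(n_vertices, seq_len(n_vertices - 1L))] +
              u[c(seq_len(n_vertices - 1L) + 1L, 1L)]) / 3
      r <- mean_radius * (1 + irregularity * u)
      if (any(r <= 0)) next
      ring <- list(x = r * cos(theta), y = r * sin(theta))
      if (ring_is_simple(ring)) {
        return(data.frame(x = ring$x, y = ring$y))
      }
    }
    stop("could not generate a simple polygon after 20 attempts", call. = FALSE)
  })
}

# ---- cell patterns ----------------------------------------------------------

# Uniform points in a polygonal window by rejection sampling from its
# bounding box; hard retry bound of 1e6 proposals.
runif_in_owin <- function(n, w) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0)))
  bb <- spatstat.geom::Frame(w)
  xs <- numeric(0); ys <- numeric(0)
  proposed <- 0L
  while (length(xs) < n) {
    m <- max(2L * (n - length(xs)), 100L)
    if (proposed + m > 1e6) stop("rejection sampling exceeded 1e6 proposals",
                                 call. = FALSE)
    px <- stats::runif(m, bb$xrange[1L], bb$xrange[2L])
    py <- stats::runif(m, bb$yrange[1L], bb$yrange[2L])
    keep <- spatstat.geom::inside.owin(px, py, w)
    xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
    proposed <- proposed + m
  }
  data.frame(x = xs[seq_len(n)], y = ys[seq_len(n)])
}

#' Simulate an immune-cell point pattern over a compartment set
#'
#' Piecewise-constant inhomogeneous Poisson process: per compartment the cell
#' count is Poisson with mean intensity x area (area in mm^2) and positions
#' are uniform within the compartment polygon.
#'
#' @param compartments a [build_compartments()] result.
#' @param archetype an [archetype_spec()].
#' @param marker marker name for the output records.
#' @param seed integer seed.
#' @param slide_id slide identifier for the output records.
#' @return data.frame with columns `slide_id`, `marker`, `x_um`, `y_um`,
#'   `cell_class` (all `"positive"`).
#' @export
simulate_cells <- function(compartments, archetype, marker = "CD3", seed = 1,
                           slide_id = "slide") {
  stopifnot(inherits(compartments, "compartment_set"),
            inherits(archetype, "archetype_spec"))
  lam <- archetype$lambda
  zero_area <- compartments$areas <= 0 & lam[COMPARTMENTS] > 0
  if (any(zero_area)) {
    stop("compartment ", names(which(zero_area))[1L],
         " has zero area but positive intensity", call. = FALSE)
  }
  with_seed(seed, {
    pieces <- lapply(COMPARTMENTS, function(comp) {
      mu <- lam[[comp]] * compartments$areas[[comp]]
      n <- if (mu > 0) stats::rpois(1L, mu) else 0L
      pts <- runif_in_owin(n, compartments$geoms[[comp]])
      if (!nrow(pts)) return(NULL)
      data.frame(slide_id = slide_id, marker = marker,
                 x_um = pts$x, y_um = pts$y, cell_class = "positive",
                 stringsAsFactors = FALSE)
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
    if (!length(pieces)) {
      return(data.frame(slide_id = character(), marker = character(),
                        x_um = numeric(), y_um = numeric(),
                        cell_class = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, pieces)
  })
}

#' Simulate one slide: shape, compartments and per-marker cell patterns
#'
#' @param seed integer seed (drives shape and all markers).
#' @param archetypes named list (by marker) of [archetype_spec()] objects.
#' @param slide_id slide identifier.
#' @param mean_radius,irregularity,n_vertices passed to
#'   [generate_tumor_shape()].
#' @param margin_width margin width in um.
#' @return list with `slide_id`, `polygon`, `compartments`, `cells`
#'   (one data.frame over all markers) and `truth` (marker -> label).
#' @export
simulate_slide <- function(seed, archetypes, slide_id = "slide",
                           mean_radius = 1500, irregularity = 0.2,
                           n_vertices = 64, margin_width = 500) {
  stopifnot(is.list(archetypes), length(archetypes) >= 1L,
            !is.null(names(archetypes)))
  poly <- generate_tumor_shape(seed, mean_radius, irregularity, n_vertices)
  cs <- build_compartments(region_annotation(poly), margin_width)
  cells <- do.call(rbind, lapply(seq_along(archetypes), function(i) {
    simulate_cells(cs, archetypes[[i]], marker = names(archetypes)[i],
                   seed = substream_seed(seed, i), slide_id = slide_id)
  }))
  truth <- vapply(archetypes, function(a) a$label, character(1L))
  list(slide_id = slide_id, polygon = poly, compartments = cs,
       cells = cells, truth = truth)
}

# ---- survival model ---------------------------------------------------------

#' Bivariate phenotype level names
#'
#' The nine combinations of cold/excluded/hot for two markers, in a fixed
#' order with the double-cold reference first.
#'
#' @param markers character vector of two marker names.
#' @return character vector of 9 phenotype labels like `"CD8-cold_CD163-cold"`.
#' @export
phenotype_levels <- function(markers = c("CD8", "CD163")) {
  stopifnot(length(markers) == 2L)
  grid <- expand.grid(b = TOPO_LEVELS, a = TOPO_LEVELS,
                      stringsAsFactors = FALSE)
  sprintf("%s-%s_%s-%s", markers[1L], grid$a, markers[2L], grid$b)
}

#' Generative survival model with phenotype-dependent hazards
#'
#' Exponential baseline hazard with multiplicative (proportional) effects of
#' the bivariate phenotype and of stage/age/sex confounders, plus an
#' independent exponential censoring time. Cox model assumptions hold
#' exactly under this generator.
#'
#' @param baseline_rate events per time unit of the exponential baseline.
#' @param log_hr named numeric: log hazard ratio per phenotype versus the
#'   reference (missing phenotypes get 0; the reference must be 0).
#' @param censor_rate rate of the independent exponential censoring time;
#'   0 disables censoring.
#' @param covariate_effects list with `stage` (length-3 log-HRs for stages
#'   II-IV vs I), `age` (log-HR per year, age centred at 65) and `sex`
#'   (log-HR for male vs female).
#' @return object of class `survival_spec`.
#' @export
survival_spec <- function(baseline_rate = 0.1, log_hr = NULL,
                          censor_rate = 0.02,
                          covariate_effects = list(stage = c(0, 0, 0),
                                                   age = 0, sex = 0)) {
  stopifnot_scalar_pos(baseline_rate, "baseline_rate")
  if (censor_rate < 0) stop("'censor_rate' must be >= 0", call. = FALSE)
  ce <- covariate_effects
  ce$stage <- ce$stage %||% c(0, 0, 0)
  ce$age <- ce$age %||% 0
  ce$sex <- ce$sex %||% 0
  stopifnot(length(ce$stage) == 3L)
  structure(list(baseline_rate = baseline_rate, log_hr = log_hr,
                 censor_rate = censor_rate, covariate_effects = ce),
            class = "survival_spec")
}

# ---- cohort -----------------------------------------------------------------

#' Simulate a patient cohort with known bivariate phenotypes and hazards
#'
#' Per patient, a bivariate phenotype is drawn, covariates (UICC stage, age,
#' sex) are sampled, and an event time is drawn from the proportional-hazards
#' generator in [survival_spec()]. Each patient uses a deterministic
#' substream of the master seed, so enlarging `n_patients` leaves earlier
#' patients unchanged. Optionally a slide (tumor shape plus cell patterns for
#' both markers, archetypes matching the true phenotype) is simulated per
#' patient.
#'
#' With the default `concordance = NULL` the phenotype is drawn jointly from
#' `phenotype_probs`, so empirical phenotype frequencies converge to it. A
#' numeric `concordance` in \[0, 1\] switches to a marginal model: marker A's
#' label is drawn from the A-marginal of `phenotype_probs`, and marker B
#' copies A's label with probability `concordance`, otherwise drawing
#' independently from the B-marginal.
#'
#' @param n_patients number of patients (>= 1).
#' @param phenotype_probs probabilities over the 9 phenotypes in
#'   [phenotype_levels()] order; must sum to 1.
#' @param concordance `NULL` (joint sampling) or copy probability in \[0, 1\].
#' @param survival a [survival_spec()].
#' @param seed master integer seed.
#' @param markers two marker names.
#' @param make_slides simulate a slide per patient (slower).
#' @param cutoff,separation archetype intensity scale when `make_slides`;
#'   see [archetype_presets()].
#' @param mean_radius,irregularity,margin_width slide geometry when
#'   `make_slides`.
#' @return object of class `sim_cohort`: `clinical` (data.frame with
#'   patient_id, time, event, stage, age, sex, phenotype, plus the two true
#'   per-marker labels), `slides` (list or NULL), `markers`, `spec`.
#' @export
simulate_cohort <- function(n_patients, phenotype_probs = rep(1 / 9, 9),
                            concordance = NULL, survival = survival_spec(),
                            seed = 1, markers = c("CD8", "CD163"),
                            make_slides = FALSE, cutoff = 25, separation = 4,
                            mean_radius = 1500, irregularity = 0.2,
                            margin_width = 500) {
  stopifnot(n_patients >= 1, inherits(survival, "survival_spec"))
  levels9 <- phenotype_levels(markers)
  if (length(phenotype_probs) != 9L) {
    stop("'phenotype_probs' must have length 9", call. = FALSE)
  }
  if (abs(sum(phenotype_probs) - 1) > 1e-9) {
    stop("'phenotype_probs' must sum to 1", call. = FALSE)
  }
  if (!any(phenotype_probs > 0)) stop("empty phenotype support", call. = FALSE)
  if (!is.null(concordance) && (concordance < 0 || concordance > 1)) {
    stop("'concordance' must be in [0, 1]", call. = FALSE)
  }
  log_hr <- stats::setNames(rep(0, 9L), levels9)
  if (!is.null(survival$log_hr)) {
    unknown <- setdiff(names(survival$log_hr), levels9)
    if (length(unknown)) {
      stop("unknown phenotype in log_hr: ", unknown[1L], call. = FALSE)
    }
    log_hr[names(survival$log_hr)] <- survival$log_hr
  }
  if (log_hr[[1L]] != 0) {
    stop("reference phenotype ", levels9[1L], " must have log_hr = 0",
         call. = FALSE)
  }
  # joint matrix: rows = marker A label, cols = marker B label
  pmat <- matrix(phenotype_probs, nrow = 3L, byrow = TRUE,
                 dimnames = list(TOPO_LEVELS, TOPO_LEVELS))
  ce <- survival$covariate_effects
  stage_levels <- c("I", "II", "III", "IV")
  stage_eff <- c(0, ce$stage)

  presets <- if (make_slides) archetype_presets(cutoff, separation) else NULL
  rows <- vector("list", n_patients)
  slides <- if (make_slides) vector("list", n_patients) else NULL

  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%04d", i)
    sub <- substream_seed(seed, i)
    rec <- with_seed(sub, {
      if (is.null(concordance)) {
        ph <- sample.int(9L, 1L, prob = phenotype_probs)
        la <- TOPO_LEVELS[(ph - 1L) %/% 3L + 1L]
        lb <- TOPO_LEVELS[(ph - 1L) %% 3L + 1L]
      } else {
        la <- sample(TOPO_LEVELS, 1L, prob = rowSums(pmat))
        lb <- if (stats::runif(1L) < concordance) la else
          sample(TOPO_LEVELS, 1L, prob = colSums(pmat))
      }
      phenotype <- sprintf("%s-%s_%s-%s", markers[1L], la, markers[2L], lb)
      stage <- sample(stage_levels, 1L, prob = c(0.2, 0.3, 0.3, 0.2))
      age <- 0
      repeat {
        age <- stats::rnorm(1L, 65, 10)
        if (age >= 30 && age <= 95) break
      }
      sex <- sample(c("female", "male"), 1L)
      lp <- log_hr[[phenotype]] +
        stage_eff[match(stage, stage_levels)] +
        ce$age * (age - 65) +
        ce$sex * (sex == "male")
      t_event <- stats::rexp(1L, rate = survival$baseline_rate * exp(lp))
      t_cens <- if (survival$censor_rate > 0) {
        stats::rexp(1L, rate = survival$censor_rate)
      } else {
        Inf
      }
      list(la = la, lb = lb, phenotype = phenotype, stage = stage, age = age,
           sex = sex, time = min(t_event, t_cens), event = t_event <= t_cens)
    })
    rows[[i]] <- data.frame(
      patient_id = pid, time = rec$time, event = rec$event,
      stage = rec$stage, age = rec$age, sex = rec$sex,
      phenotype = rec$phenotype, label_a = rec$la, label_b = rec$lb,
      stringsAsFactors = FALSE
    )
    if (make_slides) {
      arch <- stats::setNames(list(presets[[rec$la]], presets[[rec$lb]]),
                              markers)
      slides[[i]] <- simulate_slide(
        seed = substream_seed(sub, 1L), archetypes = arch, slide_id = pid,
        mean_radius = mean_radius, irregularity = irregularity,
        margin_width = margin_width
      )
    }
  }
  clinical <- do.call(rbind, rows)
  names(clinical)[names(clinical) == "label_a"] <- paste0("label_", markers[1L])
  names(clinical)[names(clinical) == "label_b"] <- paste0("label_", markers[2L])
  clinical$phenotype <- factor(clinical$phenotype, levels = levels9)
  structure(list(clinical = clinical, slides = slides, markers = markers,
                 spec = survival, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$clinical), "patients;",
      sum(x$clinical$event), "events;",
      if (is.null(x$slides)) "no slides" else "with slides", "\n")
  invisible(x)
}
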