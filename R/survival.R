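# Phenotype-stratified survival: multivariable Cox proportional hazards
# (Efron ties), Kaplan-Meier curves with Greenwood variance, and the
# log-rank test. The bivariate phenotype enters as indicator terms against
# the double-cold reference; UICC stage, age and sex are confounders.

normalize_records <- function(records, reference = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("time", "event")
  if (!all(need %in% names(records))) {
    stop("records need 'time' and 'event' columns", call. = FALSE)
  }
  if (any(records$time <= 0, na.rm = TRUE)) {
    stop("follow-up times must be > 0", call. = FALSE)
  }
  records$event <- as.logical(records$event)
  if ("stage" %in% names(records)) {
    records$stage <- factor(as.character(records$stage),
                            levels = c("I", "II", "III", "IV"))
  }
  if ("sex" %in% names(records)) {
    records$sex <- factor(records$sex)
  }
  if ("phenotype" %in% names(records)) {
    ph <- factor(as.character(records$phenotype))
    if (!is.null(reference)) {
      if (!reference %in% levels(ph)) {
        stop("reference phenotype '", reference, "' not present", call. = FALSE)
      }
      ph <- stats::relevel(ph, ref = reference)
    }
    records$phenotype <- ph
  }
  records
}

#' Fit a multivariable Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood with Efron tie correction
#' (tight convergence control, `eps = 1e-12`). Patients with a missing
#' phenotype or missing covariates are dropped with a reported count.
#' Non-estimable terms (for example a phenotype group with no events,
#' i.e. complete separation) are flagged rather than reported with an HR.
#'
#' @param records data.frame with `time`, `event` and the model covariates
#'   (`phenotype`, `stage`, `age`, `sex` by default).
#' @param covariates character vector of covariate column names.
#' @param reference reference level for the phenotype factor (the HR-1
#'   baseline), when `"phenotype"` is among the covariates.
#' @return object of class `cox_result`: `coefficients` (data.frame with
#'   term, estimate = log-HR, hr, se, z, p, ci_low, ci_high, estimable),
#'   `n`, `n_events`, `n_dropped`, `converged`, `ties`, `loglik`, `score_test`,
#'   and the underlying `survival::coxph` fit.
#' @export
fit_cox <- function(records, covariates = c("phenotype", "stage", "age", "sex"),
                    reference = NULL) {
  records <- normalize_records(records, reference = reference)
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop("missing covariate columns: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  use <- stats::complete.cases(records[, c("time", "event", covariates)])
  n_dropped <- sum(!use)
  dat <- droplevels(records[use, , drop = FALSE])
  if (sum(dat$event) < 2L) stop("need at least 2 events", call. = FALSE)
  constant <- vapply(covariates, function(cv) {
    length(unique(dat[[cv]])) < 2L
  }, logical(1L))
  if (any(constant)) {
    stop("covariate constant across records: ",
         paste(covariates[constant], collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(
    fml, data = dat, ties = "efron",
    control = survival::coxph.control(eps = 1e-12, toler.chol = 1e-13,
                                      iter.max = 100)
  )
  sm <- summary(fit)
  est <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  estimable <- is.finite(est) & is.finite(se) & se < 1e3
  z <- est / se
  ci <- cbind(est - stats::qnorm(0.975) * se, est + stats::qnorm(0.975) * se)
  coefs <- data.frame(
    term = names(est),
    estimate = unname(est),
    hr = exp(unname(est)),
    se = unname(se),
    z = unname(z),
    p = 2 * stats::pnorm(-abs(unname(z))),
    ci_low = exp(ci[, 1L]),
    ci_high = exp(ci[, 2L]),
    estimable = unname(estimable),
    stringsAsFactors = FALSE
  )
  coefs[!coefs$estimable, c("hr", "se", "z", "p", "ci_low", "ci_high")] <- NA
  structure(list(coefficients = coefs, n = fit$n, n_events = fit$nevent,
                 n_dropped = n_dropped,
                 converged = is.null(fit$info) || fit$iter < 100,
                 ties = "efron", loglik = fit$loglik,
                 score_test = unname(sm$sctest["test"]),
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat("Cox proportional-hazards fit (Efron ties):", x$n, "patients,",
      x$n_events, "events", if (x$n_dropped) paste0("(", x$n_dropped, " dropped)"),
      "\n")
  print(cbind(x$coefficients[, c("term", "hr", "p")],
              hr = NULL), digits = digits)
  invisible(x)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with Greenwood standard errors and log-transformed
#' pointwise 95% confidence intervals, in long format (one row per group and
#' distinct time).
#'
#' @param records data.frame with `time` and `event`.
#' @param group optional grouping vector (default: one group).
#' @return data.frame `group`, `time`, `n_risk`, `n_event`, `survival`,
#'   `std_err`, `ci_low`, `ci_high`.
#' @export
km_estimate <- function(records, group = NULL) {
  records <- normalize_records(records)
  if (is.null(group)) group <- rep("all", nrow(records))
  stopifnot(length(group) == nrow(records))
  dat <- data.frame(time = records$time, event = records$event,
                    group = as.character(group), stringsAsFactors = FALSE)
  out <- lapply(unique(dat$group), function(g) {
    sub <- dat[dat$group == g, ]
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub,
                            conf.type = "log")
    data.frame(group = g, time = sf$time, n_risk = sf$n.risk,
               n_event = sf$n.event, survival = sf$surv,
               std_err = sf$surv * sf$std.err,  # Greenwood, survival scale
               ci_low = sf$lower, ci_high = sf$upper,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled event
#' times, with `groups - 1` degrees of freedom.
#'
#' @param records data.frame with `time` and `event`.
#' @param group grouping vector with at least two non-empty groups.
#' @return list `statistic`, `df`, `p`.
#' @export
logrank_test <- function(records, group) {
  records <- normalize_records(records)
  group <- as.character(group)
  stopifnot(length(group) == nrow(records))
  if (length(unique(group)) < 2L) {
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  }
  if (sum(records$event) < 1L) stop("need at least 1 event", call. = FALSE)
  dat <- data.frame(time = records$time, event = records$event, group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' 3x3 hazard-ratio table over bivariate phenotypes
#'
#' One multivariable Cox fit with eight phenotype indicators (versus the
#' double-cold reference) plus stage, age and sex, unfolded into the 3x3
#' phenotype grid. Cells with no patients get no HR; the reference cell has
#' HR 1 by definition. No multiplicity correction is applied across the
#' eight phenotype terms.
#'
#' @param records data.frame with `time`, `event`, `phenotype`, `stage`,
#'   `age`, `sex`. Phenotype labels must follow [phenotype_levels()] naming.
#' @param markers the two marker names encoded in the phenotype labels.
#' @param reference reference phenotype (default double-cold).
#' @param covariates confounders to include beside the phenotype.
#' @return list: `table` (data.frame label_a, label_b, phenotype, n, events,
#'   hr, p, ci_low, ci_high, estimable, reference) and `fit` (the
#'   `cox_result`, `NULL` if everyone is in the reference group).
#' @export
phenotype_hazard_table <- function(records, markers = c("CD8", "CD163"),
                                   reference = NULL,
                                   covariates = c("stage", "age", "sex")) {
  levels9 <- phenotype_levels(markers)
  reference <- reference %||% levels9[1L]
  records <- normalize_records(records)
  if (!"phenotype" %in% names(records)) {
    stop("records need a 'phenotype' column", call. = FALSE)
  }
  ph <- as.character(records$phenotype)
  counts <- table(factor(ph, levels = levels9))
  events <- tapply(records$event, factor(ph, levels = levels9), sum)
  events[is.na(events)] <- 0
  if (counts[[reference]] == 0L || events[[reference]] < 1) {
    stop("reference phenotype must be non-empty with at least 1 event",
         call. = FALSE)
  }
  only_reference <- all(ph == reference)
  fit <- NULL
  if (!only_reference) {
    fit <- fit_cox(records, covariates = c("phenotype", covariates),
                   reference = reference)
  }
  grid <- expand.grid(b = TOPO_LEVELS, a = TOPO_LEVELS, stringsAsFactors = FALSE)
  tab <- data.frame(
    label_a = grid$a, label_b = grid$b, phenotype = levels9,
    n = as.integer(counts), events = as.integer(events),
    hr = NA_real_, p = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    estimable = FALSE, reference = levels9 == reference,
    stringsAsFactors = FALSE
  )
  tab$hr[tab$reference] <- 1
  tab$estimable[tab$reference] <- TRUE
  if (!is.null(fit)) {
    cf <- fit$coefficients
    for (lev in setdiff(levels9, reference)) {
      i <- which(tab$phenotype == lev)
      if (tab$n[i] == 0L) next  # never an HR for an empty cell
      row <- cf[cf$term == paste0("phenotype", lev), , drop = FALSE]
      if (!nrow(row)) next
      tab$hr[i] <- row$hr; tab$p[i] <- row$p
      tab$ci_low[i] <- row$ci_low; tab$ci_high[i] <- row$ci_high
      tab$estimable[i] <- isTRUE(row$estimable)
    }
  }
  list(table = tab, fit = fit)
}

#' Univariate density-survival association (negative control)
#'
#' Mirrors the univariate analysis in which raw cell densities, entered as
#' continuous covariates per marker and compartment, are tested against
#' overall survival with the same confounders. Densities are scaled per
#' cells/mm^2, so HRs are per one cell/mm^2 and expected to sit at ~1.00
#' when density carries no prognostic signal.
#'
#' @param records clinical data.frame with `time`, `event` and confounders.
#' @param densities data.frame `patient_id`, `marker`, `compartment`,
#'   `density`; joined to `records` on `patient_id`.
#' @param covariates confounders.
#' @return data.frame `marker`, `compartment`, `hr`, `p`, `n`.
#' @export
density_survival <- function(records, densities,
                             covariates = c("stage", "age", "sex")) {
  stopifnot(is.data.frame(densities),
            all(c("patient_id", "marker", "compartment", "density")
                %in% names(densities)))
  combos <- unique(densities[, c("marker", "compartment")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- densities[densities$marker == combos$marker[i] &
                       densities$compartment == combos$compartment[i],
                     c("patient_id", "density")]
    dat <- merge(records, sub, by = "patient_id")
    dat <- dat[!is.na(dat$density), , drop = FALSE]
    res <- tryCatch({
      fit <- fit_cox(dat, covariates = c("density", covariates))
      row <- fit$coefficients[fit$coefficients$term == "density", ]
      data.frame(marker = combos$marker[i], compartment = combos$compartment[i],
                 hr = row$hr, p = row$p, n = fit$n, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(marker = combos$marker[i], compartment = combos$compartment[i],
                 hr = NA_real_, p = NA_real_, n = nrow(dat),
                 stringsAsFactors = FALSE)
    })
    res
  })
  do.call(rbind, out)
}
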