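# Percentile normalization, median cutoffs, compartment collapsing and the
# cold / immune-excluded / hot classification rule.

test_that("percentile normalization hits the half-open rank grid", {
  set.seed(1)
  v <- sample(rnorm(100))
  p <- percentile_normalize(v)
  expect_equal(sort(p), seq(0.5, 99.5, by = 1))
  expect_equal(order(p), order(v))
})

test_that("ties map to their average percentile and constants map to 50", {
  expect_equal(percentile_normalize(rep(3.2, 7)), rep(50, 7))
  p <- percentile_normalize(c(1, 2, 2, 4))
  expect_equal(p, c(12.5, 50, 50, 87.5))
})

test_that("percentile normalization is invariant to monotone transforms", {
  set.seed(2)
  v <- rexp(57)
  expect_equal(percentile_normalize(v), percentile_normalize(log(v)))
  expect_equal(percentile_normalize(v), percentile_normalize(v^3 + 10))
})

test_that("missing densities propagate and all-missing errors", {
  p <- percentile_normalize(c(1, NA, 3))
  expect_true(is.na(p[2]) && !anyNA(p[c(1, 3)]))
  expect_error(percentile_normalize(c(NA_real_, NA_real_)), "missing")
})

test_that("median cutoffs pool slide x compartment observations", {
  prof <- data.frame(marker = "CD3",
                     density = c(10, 20, 30, 40),
                     slide_id = paste0("s", 1:4), compartment = "TU_CORE")
  expect_equal(median_cutoffs(prof)$cutoff, 25)
  prof3 <- data.frame(marker = "CD3", density = c(10, 20, 30))
  expect_equal(median_cutoffs(prof3)$cutoff, 20)
})

test_that("cutoffs equal a sort-based median oracle on random profiles", {
  set.seed(3)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    d <- rexp(n, 1 / 50)
    prof <- data.frame(marker = "M", density = d)
    got <- median_cutoffs(prof)$cutoff
    s <- sort(d)
    want <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(got, want)
  }
})

test_that("cutoff computation warns on sparse markers", {
  expect_warning(median_cutoffs(data.frame(marker = "X", density = c(1, 2))),
                 "fewer than 3")
})

test_that("inside density pools counts over areas", {
  expect_equal(inside_density(c(TU_CORE = 10, MARG_500_IN = 10),
                              c(TU_CORE = 1, MARG_500_IN = 1)), 10)
  expect_equal(inside_density(c(TU_CORE = 0, MARG_500_IN = 30),
                              c(TU_CORE = 1, MARG_500_IN = 2)), 10)
  expect_equal(inside_density(c(TU_CORE = 8, MARG_500_IN = 100),
                              c(TU_CORE = 2, MARG_500_IN = 1),
                              mode = "core_only"), 4)
  expect_true(is.na(inside_density(c(TU_CORE = 0, MARG_500_IN = 0),
                                   c(TU_CORE = 0, MARG_500_IN = 0))))
})

test_that("pooled density lies between the compartment densities", {
  set.seed(4)
  for (i in 1:100) {
    counts <- c(TU_CORE = rpois(1, 50), MARG_500_IN = rpois(1, 50))
    areas <- c(TU_CORE = runif(1, 0.2, 5), MARG_500_IN = runif(1, 0.2, 5))
    pooled <- inside_density(counts, areas)
    d <- counts / areas
    expect_gte(pooled, min(d) - 1e-12)
    expect_lte(pooled, max(d) + 1e-12)
  }
})

test_that("the classification rule matches its conceptual definition", {
  # high inside is hot regardless of outside
  expect_equal(as.character(classify_topography(30, 10, 25)), "hot")
  expect_equal(as.character(classify_topography(30, 90, 25)), "hot")
  # low inside, high outside is immune excluded
  expect_equal(as.character(classify_topography(10, 30, 25)), "excluded")
  # low both is cold; exactly at the cutoff counts as low
  expect_equal(as.character(classify_topography(10, 10, 25)), "cold")
  expect_equal(as.character(classify_topography(25, 25, 25)), "cold")
  # missing either density yields a missing label
  expect_true(is.na(classify_topography(NA, 10, 25)))
  expect_true(is.na(classify_topography(10, NA, 25)))
})

test_that("every slide with complete densities gets exactly one label", {
  set.seed(5)
  inside <- rexp(500, 1 / 30); outside <- rexp(500, 1 / 30)
  lab <- classify_topography(inside, outside, 25)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("cold", "excluded", "hot")))
})

test_that("scaling densities scales the cutoff and preserves labels", {
  set.seed(6)
  n <- 120
  prof <- data.frame(
    slide_id = rep(paste0("s", 1:n), each = 3),
    marker = "CD8",
    compartment = rep(c("TU_CORE", "MARG_500_IN", "MARG_500_OUT"), n),
    count = rpois(3 * n, 40),
    area_mm2 = runif(3 * n, 0.5, 4)
  )
  prof$density <- prof$count / prof$area_mm2
  cut1 <- median_cutoffs(prof)
  lab1 <- classify_slides(prof, cut1)
  prof2 <- prof
  prof2$density <- prof2$density * 7.3
  prof2$area_mm2 <- prof2$area_mm2 / 7.3   # counts fixed, areas shrink
  cut2 <- median_cutoffs(prof2)
  expect_equal(cut2$cutoff, cut1$cutoff * 7.3)
  lab2 <- classify_slides(prof2, cut2)
  expect_equal(lab1$label, lab2$label)
})

test_that("at most half the pooled observations sit strictly above the cutoff", {
  set.seed(7)
  for (i in 1:20) {
    d <- c(rexp(sample(5:60, 1), 1 / 20), rep(10, sample(0:5, 1)))
    cut <- median(d)
    expect_lte(mean(d > cut), 0.5)
  }
})

test_that("compartment correlations recover constructed structure", {
  # duplicated core as inner margin: r = 1
  n <- 50
  core <- rexp(n, 1 / 40)
  prof <- data.frame(
    slide_id = rep(paste0("s", 1:n), 3),
    marker = "CD3",
    compartment = rep(c("TU_CORE", "MARG_500_IN", "MARG_500_OUT"), each = n),
    density = c(core, core, rexp(n, 1 / 40))
  )
  cc <- compartment_correlations(prof)[["CD3"]]
  expect_equal(cc$r["TU_CORE", "MARG_500_IN"], 1)
  expect_equal(diag(cc$r), c(TU_CORE = 1, MARG_500_IN = 1, MARG_500_OUT = 1))
  expect_true(all(cc$r >= -1 & cc$r <= 1))
  expect_true(isSymmetric(cc$r))
})

test_that("independent compartments show near-zero correlation", {
  set.seed(8)
  n <- 500
  prof <- data.frame(
    slide_id = rep(paste0("s", 1:n), 3),
    marker = "CD8",
    compartment = rep(c("TU_CORE", "MARG_500_IN", "MARG_500_OUT"), each = n),
    density = rexp(3 * n, 1 / 40)
  )
  cc <- compartment_correlations(prof)[["CD8"]]
  off <- cc$r[upper.tri(cc$r)]
  expect_true(all(abs(off) < 0.15))
})

test_that("core ~ inner-margin correlation with independent outer margin", {
  set.seed(9)
  n <- 300
  core <- rexp(n, 1 / 50)
  inner <- core + rnorm(n, 0, 5)
  prof <- data.frame(
    slide_id = rep(paste0("s", 1:n), 3),
    marker = "CD8",
    compartment = rep(c("TU_CORE", "MARG_500_IN", "MARG_500_OUT"), each = n),
    density = c(core, inner, rexp(n, 1 / 50))
  )
  cc <- compartment_correlations(prof)[["CD8"]]$r
  expect_gt(cc["TU_CORE", "MARG_500_IN"], 0.9)
  expect_lt(abs(cc["TU_CORE", "MARG_500_OUT"]), 0.3)
  expect_lt(abs(cc["MARG_500_IN", "MARG_500_OUT"]), 0.3)
})

test_that("bivariate grids conserve counts and marginals", {
  a <- setNames(factor(c("hot", "hot", "cold", "excluded", "hot"),
                       levels = c("cold", "excluded", "hot")),
                paste0("s", 1:5))
  tab_diag <- bivariate_table(a, a)
  expect_equal(unname(diag(tab_diag)), c(1, 1, 3))
  b <- setNames(rep("cold", 5), paste0("s", 1:5))
  a_hot <- setNames(rep("hot", 5), paste0("s", 1:5))
  tab <- bivariate_table(a_hot, b)
  expect_equal(unname(tab["hot", "cold"]), 5)
  expect_equal(sum(tab), 5)
  # marginals equal univariate counts on the intersection
  b2 <- setNames(sample(c("cold", "excluded", "hot"), 4, replace = TRUE),
                 paste0("s", 2:5))
  tab2 <- bivariate_table(a, b2)
  expect_equal(sum(tab2), 4)
  expect_equal(unname(rowSums(tab2)),
               unname(as.numeric(table(a[paste0("s", 2:5)]))))
  expect_error(bivariate_table(setNames("hot", "x"), setNames("hot", "y")),
               "no slides")
})

test_that("phenotype distributions sum to one per entity", {
  lab <- c("hot", "hot", "cold", "excluded")
  d <- phenotype_distribution(lab, rep("STAD", 4))
  expect_equal(d$cold + d$excluded + d$hot, 1)
  expect_equal(unlist(d[, c("cold", "excluded", "hot")], use.names = FALSE),
               c(0.25, 0.25, 0.5))
  expect_equal(d$n, 4)
  # proportions times n round back to integer counts
  expect_equal(round(unlist(d[, c("cold", "excluded", "hot")]) * d$n),
               c(cold = 1, excluded = 1, hot = 2))
  expect_warning(
    d2 <- phenotype_distribution(c("hot", NA), c("MEL", "OV")),
    "OV")
  expect_equal(d2$entity, "MEL")
})

test_that("target plot rings agree with the rank-interpolation oracle", {
  set.seed(10)
  ref <- rexp(200, 1 / 40)
  slide <- c(TU_CORE = 30, MARG_500_IN = 55, MARG_500_OUT = 90)
  rings <- target_plot_data(slide, ref)
  expect_equal(names(rings), c("MARG_500_OUT", "MARG_500_IN", "TU_CORE"))
  for (comp in names(rings)) {
    joint <- percentile_normalize(c(ref, slide[[comp]]))
    expect_equal(rings[[comp]], joint[length(joint)], tolerance = 1)
  }
  # slide at the reference maximum maps to the top percentile
  top <- target_plot_data(c(TU_CORE = max(ref), MARG_500_IN = max(ref),
                            MARG_500_OUT = max(ref)), ref)
  expect_true(all(top > 99))
  # slide at the reference median maps to ~50
  med <- target_plot_data(c(TU_CORE = median(ref), MARG_500_IN = median(ref),
                            MARG_500_OUT = median(ref)), ref)
  expect_true(all(abs(med - 50) < 1))
  # missing compartment gives a missing ring
  part <- target_plot_data(c(TU_CORE = 30), ref)
  expect_true(is.na(part["MARG_500_OUT"]) && !is.na(part["TU_CORE"]))
})

test_that("archetype slides at 4x separation are recovered by classification", {
  cutoff <- 25
  pre <- archetype_presets(cutoff, 4)
  n_per <- 40
  hits <- 0; total <- 0
  for (arch_name in names(pre)) {
    for (i in seq_len(n_per)) {
      sl <- simulate_slide(1000 * match(arch_name, names(pre)) + i,
                           setNames(list(pre[[arch_name]]), "CD8"),
                           mean_radius = 1300, irregularity = 0.2,
                           n_vertices = 48)
      dt <- slide_densities(sl$cells, sl$compartments, sl$slide_id)
      lab <- classify_slides(dt, c(CD8 = cutoff))$label
      total <- total + 1
      hits <- hits + (as.character(lab) == arch_name)
    }
  }
  expect_gte(hits / total, 0.95)
})
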