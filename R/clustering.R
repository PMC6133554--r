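# Optimal cluster-number protocol: three clustering algorithms (Gaussian
# mixture, k-means, hierarchical/Ward) scored over k = 1..12 by three
# internal criteria (Davies-Bouldin, Calinski-Harabasz, silhouette), with
# technical replicates; plus the cross-entity hierarchical similarity
# analysis.

# ---- internal criteria ------------------------------------------------------

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case ratio (s_i + s_j) / d_ij, where s_i
#' is the average distance of cluster members to their centroid and d_ij the
#' distance between centroids. Lower is better; undefined for k < 2 or when
#' any two centroids coincide.
#'
#' @param X numeric matrix (observations x features).
#' @param labels integer/factor cluster assignment.
#' @return the index, or `NA` when undefined.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) return(NA_real_)
  cent <- vapply(seq_len(k), function(g) colMeans(X[labels == g, , drop = FALSE]),
                 numeric(ncol(X)))
  cent <- t(cent)
  s <- vapply(seq_len(k), function(g) {
    d <- sweep(X[labels == g, , drop = FALSE], 2L, cent[g, ])
    mean(sqrt(rowSums(d^2)))
  }, numeric(1L))
  dc <- as.matrix(stats::dist(cent))
  if (any(dc[upper.tri(dc)] == 0)) return(NA_real_)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (s[i] + s[j]) / dc[i, j], numeric(1L)))
  }, numeric(1L))
  mean(r)
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `(B / (k - 1)) / (W / (n - k))`. Higher is better; undefined for k < 2,
#' k = n, or zero within-cluster dispersion.
#'
#' @inheritParams davies_bouldin
#' @return the index, or `NA` when undefined.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(X)
  if (k < 2L || k >= n) return(NA_real_)
  gm <- colMeans(X)
  B <- 0; W <- 0
  for (g in seq_len(k)) {
    Xg <- X[labels == g, , drop = FALSE]
    cg <- colMeans(Xg)
    B <- B + nrow(Xg) * sum((cg - gm)^2)
    W <- W + sum(sweep(Xg, 2L, cg)^2)
  }
  if (W <= 0) return(NA_real_)
  (B / (k - 1)) / (W / (n - k))
}

#' Mean silhouette width
#'
#' Average silhouette over all observations (via [cluster::silhouette()]).
#' Higher is better; undefined for k < 2 or k = n.
#'
#' @inheritParams davies_bouldin
#' @param d optional precomputed `dist` object on the rows of `X`.
#' @return mean silhouette width, or `NA` when undefined.
#' @export
silhouette_score <- function(X, labels, d = NULL) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L || k >= length(labels)) return(NA_real_)
  if (is.null(d)) d <- stats::dist(X)
  mean(cluster::silhouette(labels, d)[, "sil_width"])
}

# ---- fitting ----------------------------------------------------------------

fit_labels <- function(X, method, k) {
  n <- nrow(X)
  if (k == 1L) return(rep(1L, n))
  if (k >= n) return(NULL)
  switch(
    method,
    kmeans = {
      km <- tryCatch(stats::kmeans(X, centers = k, nstart = 10L, iter.max = 50L),
                     error = function(e) NULL)
      if (is.null(km)) NULL else km$cluster
    },
    gmm = {
      init <- stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L)$cluster
      z <- mclust::unmap(init, groups = seq_len(k))
      fit <- tryCatch(
        suppressWarnings(mclust::me(data = X, modelName = "VVV", z = z)),
        error = function(e) NULL
      )
      if (is.null(fit) || is.null(fit$z) || anyNA(fit$z)) NULL
      else mclust::map(fit$z)
    },
    hierarchical = {
      hc <- stats::hclust(stats::dist(X), method = "ward.D2")
      stats::cutree(hc, k = k)
    },
    stop("unknown method: ", method, call. = FALSE)
  )
}

score_labels <- function(X, labels, criterion, d = NULL) {
  if (is.null(labels)) return(NA_real_)
  k_eff <- length(unique(labels))
  if (k_eff < 2L) return(NA_real_)
  switch(criterion,
         davies_bouldin = davies_bouldin(X, labels),
         calinski_harabasz = calinski_harabasz(X, labels),
         silhouette = silhouette_score(X, labels, d = d),
         stop("unknown criterion: ", criterion, call. = FALSE))
}

#' Score cluster numbers over methods, criteria and replicates
#'
#' For each replicate and method, fits every k in `k_range` and evaluates
#' each internal criterion. k = 1 is part of the scanned range but all
#' three criteria are mathematically undefined there, so it is recorded
#' with a missing score rather than silently skipped; consequently "no
#' clustering" can never be selected as optimal. `best_k` maximizes
#' Calinski-Harabasz and silhouette and minimizes Davies-Bouldin over the
#' evaluable k.
#'
#' @param X numeric matrix of absolute densities (slides x features).
#' @param methods subset of `c("gmm", "kmeans", "hierarchical")`.
#' @param criteria subset of
#'   `c("davies_bouldin", "calinski_harabasz", "silhouette")`.
#' @param k_range integer vector of cluster numbers (default 1:12).
#' @param replicates technical replicates per method (default 10).
#' @param seed integer seed; the run is reproducible per seed.
#' @return object of class `cluster_runs`: `scores` (long data.frame with
#'   method, criterion, replicate, k, score) and `best` (method, criterion,
#'   replicate, best_k).
#' @export
cluster_scores <- function(X,
                           methods = c("gmm", "kmeans", "hierarchical"),
                           criteria = c("davies_bouldin", "calinski_harabasz",
                                        "silhouette"),
                           k_range = 1:12, replicates = 10, seed = 1) {
  X <- as.matrix(X)
  methods <- match.arg(methods, several.ok = TRUE)
  criteria <- match.arg(criteria, several.ok = TRUE)
  if (nrow(X) < max(k_range) + 1L) {
    stop("need at least max(k_range) + 1 rows", call. = FALSE)
  }
  # mean-impute missing features (count logged as attribute)
  n_imputed <- 0L
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) {
      X[miss, j] <- mean(X[, j], na.rm = TRUE)
      n_imputed <- n_imputed + sum(miss)
    }
  }
  d <- stats::dist(X)
  scores <- list()
  with_seed(seed, {
    for (rep_i in seq_len(replicates)) {
      for (method in methods) {
        for (k in sort(unique(as.integer(k_range)))) {
          labels <- fit_labels(X, method, k)
          for (crit in criteria) {
            scores[[length(scores) + 1L]] <- data.frame(
              method = method, criterion = crit, replicate = rep_i, k = k,
              score = score_labels(X, labels, crit, d = d),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  })
  scores <- do.call(rbind, scores)
  best <- list()
  for (method in methods) for (crit in criteria) for (rep_i in seq_len(replicates)) {
    sub <- scores[scores$method == method & scores$criterion == crit &
                    scores$replicate == rep_i & !is.na(scores$score), , drop = FALSE]
    bk <- if (!nrow(sub)) NA_integer_ else if (crit == "davies_bouldin") {
      sub$k[which.min(sub$score)]
    } else {
      sub$k[which.max(sub$score)]
    }
    best[[length(best) + 1L]] <- data.frame(
      method = method, criterion = crit, replicate = rep_i, best_k = bk,
      stringsAsFactors = FALSE
    )
  }
  structure(list(scores = scores, best = do.call(rbind, best),
                 k_range = sort(unique(as.integer(k_range))),
                 n_imputed = n_imputed),
            class = "cluster_runs")
}

smallest_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(mode = NA_integer_, tie = FALSE))
  tab <- table(x)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(mode = min(winners), tie = length(winners) > 1L)
}

#' Modal optimal cluster number
#'
#' Mode of `best_k` over replicates, per method x criterion and overall.
#' Ties are reported as the smaller k with a tie flag.
#'
#' @param runs a [cluster_scores()] result.
#' @return list with `by_combination` (data.frame method, criterion,
#'   modal_k, tie) and `overall` (modal k over all runs) and `overall_tie`.
#' @export
modal_optimum <- function(runs) {
  stopifnot(inherits(runs, "cluster_runs"))
  best <- runs$best
  combos <- unique(best[, c("method", "criterion")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- best[best$method == combos$method[i] &
                  best$criterion == combos$criterion[i], ]
    m <- smallest_mode(sub$best_k)
    data.frame(method = combos$method[i], criterion = combos$criterion[i],
               modal_k = m$mode, tie = m$tie, stringsAsFactors = FALSE)
  })
  ov <- smallest_mode(best$best_k)
  list(by_combination = do.call(rbind, rows),
       overall = ov$mode, overall_tie = ov$tie)
}

#' @export
print.cluster_runs <- function(x, ...) {
  cat("Cluster-number runs:", length(unique(x$best$method)), "methods x",
      length(unique(x$best$criterion)), "criteria x",
      max(x$best$replicate), "replicates; k in",
      paste(range(x$k_range), collapse = ".."), "\n")
  invisible(x)
}

# ---- entity similarity ------------------------------------------------------

#' Hierarchical similarity of tumor entities
#'
#' Restricts to patients with a complete feature vector (all markers x
#' compartments non-missing), aggregates to per-entity mean vectors,
#' computes pairwise distances and agglomerates. Intended for
#' percentile-normalized density matrices.
#'
#' @param X numeric matrix, patients x (markers x compartments).
#' @param entities entity code per row of `X`.
#' @param distance distance metric for [stats::dist()] (default euclidean).
#' @param linkage agglomeration method for [stats::hclust()]
#'   (default average).
#' @return object of class `entity_linkage`: `hclust`, `phylo` (ape tree
#'   with branch lengths derived from merge heights), `entity_means`,
#'   `n_complete` per entity.
#' @export
entity_similarity <- function(X, entities, distance = "euclidean",
                              linkage = "average") {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(entities))
  complete <- stats::complete.cases(X)
  ent <- as.character(entities)
  keep_entities <- character(0)
  means <- list()
  n_complete <- integer(0)
  for (e in unique(ent)) {
    sel <- complete & ent == e
    if (!any(sel)) {
      warning("entity ", e, " has no complete patients; excluded", call. = FALSE)
      next
    }
    means[[e]] <- colMeans(X[sel, , drop = FALSE])
    n_complete[e] <- sum(sel)
    keep_entities <- c(keep_entities, e)
  }
  if (length(keep_entities) < 2L) {
    stop("need at least 2 entities with complete patients", call. = FALSE)
  }
  M <- do.call(rbind, means)
  hc <- stats::hclust(stats::dist(M, method = distance), method = linkage)
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 entity_means = M, n_complete = n_complete),
            class = "entity_linkage")
}

#' Export an entity dendrogram as Newick
#'
#' @param linkage an [entity_similarity()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(linkage, path) {
  stopifnot(inherits(linkage, "entity_linkage"))
  ape::write.tree(linkage$phylo, file = path)
  invisible(path)
}
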