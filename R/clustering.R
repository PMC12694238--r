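# Functional parameter groups, feature preparation, DBSCAN with
# silhouette-driven hyperparameter selection, and t-SNE embedding.

#' Four functional parameter groups
#'
#' Splits the feature-table parameters into the four functional groups used
#' for clustering: (1) forehead impedance parameters, (2) arm impedance
#' parameters, (3) parameters using both recording channels, (4) LDF
#' parameters. The volumetric blood filling is a forehead-channel quantity
#' and sits in group 1 by default; set `dv_in_group3 = TRUE` to treat it as
#' a cross-channel parameter instead.
#'
#' @param table Optional feature table; when given, parameters absent or
#'   entirely missing from it are dropped and empty groups are flagged via
#'   an `empty` attribute.
#' @param dv_in_group3 Where to place `dv`.
#' @return Named list of four character vectors
#'   (`forehead`, `arm`, `cross`, `ldf`).
#' @export
build_feature_groups <- function(table = NULL, dv_in_group3 = FALSE) {
  groups <- list(
    forehead = c("z_base_forehead", "dz_forehead", "s_z_forehead",
                 "ri_forehead", "ad_forehead", "t_ad_forehead",
                 "rtt_forehead", "alpha", if (!dv_in_group3) "dv"),
    arm = c("z_base_arm", "dz_arm", "s_z_arm", "ri_arm", "ad_arm",
            "t_ad_arm", "rtt_arm", "lvet"),
    cross = c("dt_z", "icp", "rz", if (dv_in_group3) "dv"),
    ldf = c("mc", "a_mc"))
  if (!is.null(table)) {
    groups <- lapply(groups, function(ps) {
      ps <- intersect(ps, names(table))
      ps[vapply(ps, function(p) any(is.finite(table[[p]])), logical(1))]
    })
    attr(groups, "empty") <- names(groups)[lengths(groups) == 0L]
  }
  groups
}

#' Prepare the clustering feature matrix for one parameter group
#'
#' Keeps rows complete for the group's parameters, standardises each
#' numeric column to mean 0 and sd 1, drops zero-variance columns with a
#' warning, and appends the surgical stage as five unscaled one-hot
#' indicator columns.
#'
#' @param table Feature table.
#' @param params Character vector of parameter columns.
#' @return Numeric matrix with attributes `rows` (the retained row indices
#'   of `table`) and `dropped` (zero-variance columns removed).
#' @export
prepare_features <- function(table, params) {
  if (!length(params)) abort_rheo("empty parameter group", "parameter_error")
  x <- as.matrix(table[, params, drop = FALSE])
  ok <- stats::complete.cases(x) & !is.na(table$stage_id)
  x <- x[ok, , drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(dropped, collapse = ", ")))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  x <- scale(x)
  onehot <- sapply(1:5, function(s) as.numeric(table$stage_id[ok] == s))
  colnames(onehot) <- paste0("stage_", 1:5)
  out <- cbind(x, onehot)
  attr(out, "rows") <- which(ok)
  attr(out, "dropped") <- dropped
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Density-based clustering (DBSCAN)
#'
#' Classic DBSCAN with Euclidean distances: a point is a core point when at
#' least `min_samples` points (itself included) lie within `eps`; clusters
#' grow from core points; non-core points within `eps` of a cluster become
#' border members; remaining points are noise (label -1). Deterministic for
#' a fixed row order.
#'
#' @param x Numeric matrix (rows = observations), or `NULL` when `dmat` is
#'   supplied.
#' @param eps Neighbourhood radius.
#' @param min_samples Minimum neighbourhood size for a core point
#'   (including the point itself).
#' @param dmat Optional precomputed distance matrix.
#' @return Integer label vector: 1..k for clusters, -1 for noise.
#' @export
dbscan_fit <- function(x, eps, min_samples, dmat = NULL) {
  if (is.null(dmat)) dmat <- as.matrix(stats::dist(x))
  n <- nrow(dmat)
  nbrs <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- lengths(nbrs) >= min_samples
  labels <- rep(0L, n)  # 0 = unvisited, -1 = noise
  k <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    k <- k + 1L
    labels[i] <- k
    queue <- setdiff(nbrs[[i]], i)
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (labels[q] == -1L) labels[q] <- k      # noise becomes border
      if (labels[q] != 0L) next
      labels[q] <- k
      if (core[q]) queue <- c(queue, nbrs[[q]][labels[nbrs[[q]]] == 0L])
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

# Mean silhouette over non-noise points; NA when fewer than 2 clusters.
silhouette_score <- function(labels, dmat) {
  keep <- labels != -1L
  cl <- labels[keep]
  if (length(unique(cl)) < 2L || sum(keep) < 3L) return(NA_real_)
  sil <- cluster::silhouette(cl, dmatrix = dmat[keep, keep, drop = FALSE])
  mean(sil[, "sil_width"])
}

#' DBSCAN with silhouette-maximising hyperparameter selection
#'
#' Runs DBSCAN over a grid of `eps` and `min_samples` values and returns
#' the configuration maximising the mean silhouette (computed on non-noise
#' points), among runs producing at least `min_clusters` clusters with at
#' most `max_noise_frac` noise. The default eps grid is the 10th-90th
#' percentiles (step 10) of the 4-nearest-neighbour distances. Ties break
#' deterministically toward smaller eps, then smaller min_samples. When no
#' grid point is admissible, a no-structure result is returned
#' (`n_clusters <= 1`, silhouette `NA`).
#'
#' @param x Numeric matrix (>= 20 rows).
#' @param eps_grid Candidate eps values; computed from the data when `NULL`.
#' @param min_samples_grid Candidate min_samples values.
#' @param min_clusters Minimum acceptable number of clusters.
#' @param max_noise_frac Maximum acceptable fraction of noise points.
#' @return List of class `cluster_result`: labels, eps, min_samples,
#'   n_clusters, silhouette, noise_frac, grid (data.frame of all evaluated
#'   configurations).
#' @export
dbscan_auto <- function(x, eps_grid = NULL, min_samples_grid = 3:10,
                        min_clusters = 2L, max_noise_frac = 0.2) {
  x <- as.matrix(x)
  if (nrow(x) < 20L)
    abort_rheo("need at least 20 rows for clustering", "insufficient_data_error")
  dmat <- as.matrix(stats::dist(x))
  if (is.null(eps_grid)) {
    knn4 <- apply(dmat, 1, function(r) sort(r)[5])  # 4-NN distance
    eps_grid <- unique(stats::quantile(knn4, seq(0.1, 0.9, by = 0.1),
                                       names = FALSE, type = 7))
    eps_grid <- eps_grid[eps_grid > 0]
  }
  grid <- expand.grid(eps = sort(eps_grid), min_samples = sort(min_samples_grid))
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    labels <- dbscan_fit(NULL, grid$eps[g], grid$min_samples[g], dmat = dmat)
    nc <- length(unique(labels[labels != -1L]))
    nf <- mean(labels == -1L)
    sil <- if (nc >= 2L) silhouette_score(labels, dmat) else NA_real_
    res[[g]] <- list(labels = labels, n_clusters = nc, noise_frac = nf,
                     silhouette = sil)
  }
  grid$n_clusters <- vapply(res, `[[`, numeric(1), "n_clusters")
  grid$noise_frac <- vapply(res, `[[`, numeric(1), "noise_frac")
  grid$silhouette <- vapply(res, `[[`, numeric(1), "silhouette")
  admissible <- which(grid$n_clusters >= min_clusters &
                        grid$noise_frac <= max_noise_frac &
                        is.finite(grid$silhouette))
  if (!length(admissible)) {
    return(structure(list(labels = rep(1L, nrow(x)), eps = NA_real_,
                          min_samples = NA_integer_, n_clusters = 1L,
                          silhouette = NA_real_, noise_frac = 0,
                          grid = grid),
                     class = "cluster_result"))
  }
  # grid rows are ordered by (min_samples, eps); strict > keeps the
  # smallest eps then smallest min_samples among ties
  ord <- admissible[order(grid$eps[admissible], grid$min_samples[admissible])]
  best <- ord[1]
  for (g in ord[-1]) if (grid$silhouette[g] > grid$silhouette[best]) best <- g
  structure(list(labels = res[[best]]$labels, eps = grid$eps[best],
                 min_samples = grid$min_samples[best],
                 n_clusters = grid$n_clusters[best],
                 silhouette = grid$silhouette[best],
                 noise_frac = grid$noise_frac[best], grid = grid),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d cluster(s), silhouette %.3f (eps %.3g, min_samples %s, noise %.0f%%)\n",
    x$n_clusters, x$silhouette, x$eps, x$min_samples, 100 * x$noise_frac))
  invisible(x)
}

#' Two-dimensional t-SNE embedding for cluster visualisation
#'
#' Thin deterministic wrapper around Rtsne for plotting only (the embedding
#' is never used for clustering). The perplexity is reduced automatically
#' (with a warning) when the matrix has fewer than `3 * perplexity + 1`
#' rows.
#'
#' @param x Numeric matrix.
#' @param seed Integer seed; fixed seed gives a reproducible embedding.
#' @param perplexity t-SNE perplexity, default 30.
#' @param max_iter Gradient-descent iterations.
#' @return n x 2 numeric matrix (columns `tsne1`, `tsne2`).
#' @export
tsne_embed <- function(x, seed = 1L, perplexity = 30, max_iter = 500) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) abort_rheo("need at least 4 rows for t-SNE",
                         "insufficient_data_error")
  if (n < 3 * perplexity + 1) {
    perplexity <- max(1, floor((n - 1) / 3))
    warning(sprintf("too few rows; perplexity reduced to %g", perplexity))
  }
  set.seed(as.integer(seed))
  emb <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = TRUE,
                      max_iter = max_iter, verbose = FALSE)$Y
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

#' Cohort summary of clustering results per functional group
#'
#' Aggregates per-subject, per-group cluster results into the cohort shape:
#' median and range of the number of clusters, and mean, sample sd, min and
#' max of the silhouette.
#'
#' @param results data.frame with columns `group`, `subject_id`,
#'   `n_clusters`, `silhouette` (one row per subject x group), or a list of
#'   such rows.
#' @return data.frame with one row per group.
#' @export
cluster_summary <- function(results) {
  if (!is.data.frame(results)) results <- do.call(rbind, results)
  if (!nrow(results)) abort_rheo("no cluster results", "insufficient_data_error")
  groups <- unique(results$group)
  rows <- lapply(groups, function(g) {
    r <- results[results$group == g, ]
    sil <- r$silhouette[is.finite(r$silhouette)]
    data.frame(group = g, n_subjects = nrow(r),
               n_clusters_median = stats::median(r$n_clusters),
               n_clusters_min = min(r$n_clusters),
               n_clusters_max = max(r$n_clusters),
               silhouette_mean = if (length(sil)) mean(sil) else NA_real_,
               silhouette_sd = if (length(sil) > 1) stats::sd(sil) else NA_real_,
               silhouette_min = if (length(sil)) min(sil) else NA_real_,
               silhouette_max = if (length(sil)) max(sil) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
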