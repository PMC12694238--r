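# Stage-wise summaries, correlation structure and mutual information.

# Canonical feature-table parameter columns (everything except identifiers).
FEATURE_PARAMS <- c("z_base_forehead", "dz_forehead", "s_z_forehead",
                    "ri_forehead", "ad_forehead", "t_ad_forehead",
                    "rtt_forehead", "alpha",
                    "z_base_arm", "dz_arm", "s_z_arm", "ri_arm", "ad_arm",
                    "t_ad_arm", "rtt_arm", "lvet",
                    "dt_z", "icp", "rz", "dv", "mc", "a_mc")

#' Merge per-recording metric tables into one cohort feature table
#'
#' One row per valid cycle, sorted by subject, stage and time. Metrics of
#' degenerate cycles are already `NA`; rows whose identifiers are missing
#' are dropped.
#'
#' @param tables A single data.frame from [compute_cycle_metrics()] or a
#'   list of them (one per subject).
#' @return A sorted data.frame.
#' @export
build_feature_table <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  tab <- do.call(rbind, tables)
  if (is.null(tab) || !nrow(tab))
    abort_rheo("no cycle metrics to assemble", "insufficient_data_error")
  tab <- tab[!is.na(tab$subject_id) & !is.na(tab$stage_id), , drop = FALSE]
  tab <- tab[order(tab$subject_id, tab$stage_id, tab$r_time), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Per-stage summary of one parameter with Mann-Whitney tests
#'
#' For each stage present: n, median, quartiles (linear interpolation),
#' mean, sd, and the two-sided Mann-Whitney U p-value against the previous
#' stage present in the data (so the post-bypass stage is compared with the
#' pre-bypass stage across the recording gap). The exact test is used when
#' the combined sample is at most 20 and untied; otherwise the tie-corrected
#' normal approximation with continuity correction.
#'
#' @param table Feature table from [build_feature_table()].
#' @param parameter Column name to summarise.
#' @param min_n Minimum records per stage for the test (summary still
#'   emitted below it, with `test_skipped = TRUE`).
#' @return data.frame with one row per stage.
#' @export
stage_summary <- function(table, parameter, min_n = 3L) {
  if (!parameter %in% names(table))
    abort_rheo(sprintf("unknown parameter '%s'", parameter), "parameter_error")
  stages <- sort(unique(table$stage_id))
  prev <- c(NA, stages[-length(stages)])
  rows <- lapply(seq_along(stages), function(k) {
    x <- table[[parameter]][table$stage_id == stages[k]]
    x <- x[is.finite(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    p <- NA_real_; skipped <- TRUE
    if (!is.na(prev[k])) {
      y <- table[[parameter]][table$stage_id == prev[k]]
      y <- y[is.finite(y)]
      if (length(x) >= min_n && length(y) >= min_n) {
        exact <- (length(x) + length(y)) <= 20L
        p <- suppressWarnings(
          stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
        skipped <- FALSE
      }
    }
    data.frame(stage_id = stages[k], n = length(x), median = q[2],
               q1 = q[1], q3 = q[3], mean = mean(x), sd = stats::sd(x),
               p_vs_previous = p, test_skipped = skipped)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

new_assoc_matrix <- function(m, params, n_pairs, class, extra = list()) {
  dimnames(m) <- list(params, params)
  structure(c(list(params = params, matrix = m, n_pairs = n_pairs), extra),
            class = class)
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d parameters\n", length(x$params)))
  print(round(x$matrix, 2))
  invisible(x)
}

#' @export
print.nmi_matrix <- function(x, ...) {
  cat(sprintf("<nmi_matrix> %d parameters, %d equal-frequency bins\n",
              length(x$params), x$n_bins))
  print(round(x$matrix, 2))
  invisible(x)
}

pearson_matrix <- function(tab, params) {
  x <- as.matrix(tab[, params, drop = FALSE])
  m <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(x))
  diag(m)[diag(n_pairs) > 0] <- 1
  new_assoc_matrix(m, params, n_pairs, "correlation_matrix")
}

#' Pairwise Pearson correlations within one surgical stage
#'
#' Pairwise-complete Pearson r between parameters over the cycles of one
#' stage (optionally restricted to one subject). Zero-variance parameters
#' yield `NA` entries.
#'
#' @param table Feature table.
#' @param params Parameter columns; defaults to every metric column present.
#' @param stage_id Stage to analyse.
#' @param subject_id Optional subject restriction.
#' @return A `correlation_matrix` (list: params, matrix, n_pairs).
#' @export
pearson_within_stage <- function(table, params = NULL, stage_id,
                                 subject_id = NULL) {
  params <- params %||% intersect(FEATURE_PARAMS, names(table))
  tab <- table[table$stage_id == stage_id, , drop = FALSE]
  if (!is.null(subject_id))
    tab <- tab[tab$subject_id %in% subject_id, , drop = FALSE]
  if (nrow(tab) < 3L)
    abort_rheo("need at least 3 records in the stage", "insufficient_data_error")
  pearson_matrix(tab, params)
}

#' Pearson correlations over the whole recording of one subject
#'
#' The global (stage-pooled) association structure for one subject, used to
#' build the cohort mean/std heatmaps.
#'
#' @inheritParams pearson_within_stage
#' @return A `correlation_matrix`.
#' @export
pearson_whole_record <- function(table, params = NULL, subject_id) {
  params <- params %||% intersect(FEATURE_PARAMS, names(table))
  tab <- table[table$subject_id == subject_id, , drop = FALSE]
  if (nrow(tab) < 3L)
    abort_rheo("need at least 3 records for the subject",
               "insufficient_data_error")
  pearson_matrix(tab, params)
}

#' Pearson correlations between stage-averaged parameter profiles
#'
#' Each parameter is reduced to a per-stage value (mean within subject and
#' stage, then averaged across subjects), and correlations are computed over
#' those stage points. This is the aggregation under which intraoperative
#' parameter couplings strengthen relative to within-stage correlations.
#'
#' @param table Feature table.
#' @param params Parameter columns.
#' @return A `correlation_matrix` over the stage profiles, with the stage
#'   profile matrix attached as `$stage_profiles`.
#' @export
pearson_stage_averaged <- function(table, params = NULL) {
  params <- params %||% intersect(FEATURE_PARAMS, names(table))
  stages <- sort(unique(table$stage_id))
  if (length(stages) < 3L)
    abort_rheo("need at least 3 stages for stage-averaged correlation",
               "insufficient_data_error")
  prof <- sapply(params, function(p) {
    vapply(stages, function(s) {
      sub <- table[table$stage_id == s, c("subject_id", p)]
      per_subj <- tapply(sub[[p]], sub$subject_id,
                         function(v) mean(v[is.finite(v)]))
      mean(per_subj, na.rm = TRUE)
    }, numeric(1))
  })
  m <- suppressWarnings(stats::cor(prof, use = "pairwise.complete.obs"))
  n_pairs <- crossprod(!is.na(prof))
  diag(m)[diag(n_pairs) > 0] <- 1
  new_assoc_matrix(m, params, n_pairs, "correlation_matrix",
                   extra = list(stage_profiles = prof, stages = stages))
}

#' Cohort mean and standard-deviation heatmap matrices
#'
#' Element-wise mean and sample (n-1) standard deviation of per-subject
#' correlation matrices, ignoring undefined entries, plus a stability mask
#' marking entries whose between-subject standard deviation is below
#' `stable_sd` (default 0.15).
#'
#' @param per_subject_matrices List of `correlation_matrix` objects sharing
#'   one parameter set (>= 2 subjects).
#' @param stable_sd Stability threshold on the between-subject sd.
#' @return List: mean, sd (matrices), stable (logical matrix), n_subjects.
#' @export
cohort_heatmaps <- function(per_subject_matrices, stable_sd = 0.15) {
  if (length(per_subject_matrices) < 2L)
    abort_rheo("need at least 2 subjects", "insufficient_data_error")
  params <- per_subject_matrices[[1]]$params
  arr <- simplify2array(lapply(per_subject_matrices, function(m) {
    stopifnot(identical(m$params, params))
    m$matrix
  }))
  mn <- apply(arr, c(1, 2), function(v) if (all(is.na(v))) NA_real_ else
    mean(v, na.rm = TRUE))
  sdv <- apply(arr, c(1, 2), function(v) if (sum(!is.na(v)) < 2L) NA_real_ else
    stats::sd(v, na.rm = TRUE))
  list(mean = mn, sd = sdv, stable = !is.na(sdv) & sdv < stable_sd,
       n_subjects = length(per_subject_matrices), params = params)
}

# Equal-frequency discretisation into at most n_bins bins; returns integer
# codes and whether bins had to be collapsed because of ties.
equal_freq_bins <- function(x, n_bins) {
  br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  collapsed <- (length(br) - 1L) < n_bins
  if (length(br) < 2L) return(list(codes = rep(1L, length(x)), collapsed = TRUE))
  codes <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  list(codes = codes, collapsed = collapsed)
}

# Mutual information and entropies (nats) from two integer code vectors.
mi_from_codes <- function(cx, cy) {
  joint <- table(cx, cy) / length(cx)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  mi <- sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  list(mi = mi, hx = hx, hy = hy)
}

#' Normalized mutual information matrix between parameters
#'
#' Each parameter is discretised into `n_bins` equal-frequency bins; mutual
#' information is computed from the joint histogram with natural-log
#' entropies, pairwise on listwise-complete observations, and normalised by
#' the average of the two marginal entropies:
#' `NMI(X, Y) = MI / ((H(X) + H(Y)) / 2)`. The diagonal is exactly 1.
#' Equal-frequency binning makes the measure invariant under strictly
#' monotone transforms of either variable.
#'
#' @param table Feature table.
#' @param params Parameter columns.
#' @param n_bins Number of equal-frequency bins, default 16.
#' @param min_records Minimum complete records required, default 50.
#' @return An `nmi_matrix` (list: params, matrix, n_pairs, n_bins,
#'   collapsed - logical vector flagging parameters whose bins collapsed).
#' @export
nmi_matrix <- function(table, params = NULL, n_bins = 16L, min_records = 50L) {
  params <- params %||% intersect(FEATURE_PARAMS, names(table))
  x <- as.matrix(table[, params, drop = FALSE])
  if (sum(stats::complete.cases(x)) < min_records)
    abort_rheo(sprintf("need at least %d complete records", min_records),
               "insufficient_data_error")
  p <- length(params)
  m <- matrix(NA_real_, p, p)
  n_pairs <- matrix(0L, p, p)
  collapsed <- logical(p)
  for (i in seq_len(p)) {
    for (j in i:p) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      n_pairs[i, j] <- n_pairs[j, i] <- sum(ok)
      if (sum(ok) < 2L) next
      bi <- equal_freq_bins(x[ok, i], n_bins)
      bj <- equal_freq_bins(x[ok, j], n_bins)
      collapsed[i] <- collapsed[i] || bi$collapsed
      collapsed[j] <- collapsed[j] || bj$collapsed
      if (i == j) { m[i, i] <- 1; next }
      e <- mi_from_codes(bi$codes, bj$codes)
      denom <- (e$hx + e$hy) / 2
      v <- if (denom > 0) max(0, min(1, e$mi / denom)) else NA_real_
      m[i, j] <- m[j, i] <- v
    }
  }
  names(collapsed) <- params
  new_assoc_matrix(m, params, n_pairs, "nmi_matrix",
                   extra = list(n_bins = as.integer(n_bins),
                                collapsed = collapsed))
}
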