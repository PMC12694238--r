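# Shared lazily built fixtures (kept in an env so expensive synthetic
# cohorts are generated once per test run).

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A short clean single recording for quick unit checks.
quick_recording <- function(snr = Inf, ...) {
  generate_recording(synth_config(
    duration_per_stage = c(12, 12, 8, 12, 8), cpb_gap_s = 10,
    cautery_gaps = list(), noise_snr_db = snr, seed = 7L, ...))
}

# Match metric rows to ground-truth cycles by window start time.
match_truth <- function(tab, gt, tol_s = 0.03) {
  j <- vapply(tab$r_time, function(tt) {
    k <- which.min(abs(gt$start_time - tt))
    if (abs(gt$start_time[k] - tt) < tol_s) k else NA_integer_
  }, integer(1))
  ok <- !is.na(j)
  list(tab = tab[ok, , drop = FALSE], gt = gt[j[ok], , drop = FALSE])
}

# Independent naive DBSCAN oracle: direct textbook definition via repeated
# set expansion (no shared code with dbscan_fit's queue-based traversal).
naive_dbscan <- function(x, eps, min_pts) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- which(lengths(nbr) >= min_pts)
  labels <- rep(-1L, n)
  k <- 0L
  assigned <- logical(n)
  for (c0 in core) {
    if (assigned[c0]) next
    k <- k + 1L
    # fixed-point expansion of the core-connected set
    members <- c0
    repeat {
      grown <- unique(unlist(nbr[intersect(members, core)]))
      grown <- union(members, grown)
      if (length(grown) == length(members)) break
      members <- grown
    }
    core_members <- intersect(members, core)
    labels[core_members] <- k
    assigned[core_members] <- TRUE
    # border points: non-core in a core member's neighbourhood
    border <- setdiff(members, core_members)
    border <- border[!assigned[border]]
    labels[border] <- k
    assigned[border] <- TRUE
  }
  labels
}

# Two labelings agree up to a permutation of cluster ids (noise fixed).
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == -1L) == (b == -1L))) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) ==
    length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# Gaussian blob generator for clustering tests.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd), n_per),
          2, centers[i, ], `+`)))
}
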