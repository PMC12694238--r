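# Stage summaries, correlation structure, NMI.

fake_table <- function(n_per_stage = 40, n_subjects = 2, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(subject = seq_len(n_subjects), stage = 1:5,
                      i = seq_len(n_per_stage))
  data.frame(subject_id = sprintf("S%02d", rows$subject),
             stage_id = rows$stage, cycle_index = rows$i,
             r_time = rows$i, dv = rnorm(nrow(rows), 5),
             ri_forehead = rnorm(nrow(rows), 1),
             a_mc = rnorm(nrow(rows), 2))
}

test_that("stage_summary computes interpolated quartiles and stage tests", {
  tab <- data.frame(subject_id = "a", stage_id = rep(1:2, each = 5),
                    r_time = 1:10, x = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5))
  s <- stage_summary(tab, "x")
  expect_equal(s$median[1], 3)
  expect_equal(s$q1[1], 2)
  expect_equal(s$q3[1], 4)
  # identical samples: no evidence of a shift
  expect_equal(s$p_vs_previous[2], 1, tolerance = 1e-9)
  expect_true(is.na(s$p_vs_previous[1]))
})

test_that("stage_summary flags a strong location shift between stages", {
  set.seed(1)
  tab <- data.frame(subject_id = "a", stage_id = rep(c(1, 2), each = 200),
                    r_time = 1:400,
                    x = c(rnorm(200, 0, 1), rnorm(200, 2, 1)))
  s <- stage_summary(tab, "x")
  expect_lt(s$p_vs_previous[2], 0.001)
})

test_that("stage comparison crosses the bypass gap and skips tiny stages", {
  tab <- data.frame(subject_id = "a", stage_id = c(rep(3, 30), rep(4, 30)),
                    r_time = 1:60, x = rnorm(60))
  s <- stage_summary(tab, "x")
  expect_false(s$test_skipped[2])   # stage 4 tested against stage 3
  tab2 <- data.frame(subject_id = "a", stage_id = c(rep(1, 2), rep(2, 30)),
                     r_time = 1:32, x = rnorm(32))
  s2 <- stage_summary(tab2, "x")
  expect_true(s2$test_skipped[2])
})

test_that("Pearson matrices hit the exact linear limits and sampling bounds", {
  set.seed(2)
  x <- rnorm(100)
  tab <- data.frame(subject_id = "a", stage_id = 1, r_time = 1:100,
                    p1 = x, p2 = 2 * x + 1, p3 = -x)
  cm <- pearson_within_stage(tab, c("p1", "p2", "p3"), stage_id = 1)
  expect_equal(cm$matrix["p1", "p2"], 1, tolerance = 1e-12)
  expect_equal(cm$matrix["p1", "p3"], -1, tolerance = 1e-12)
  expect_true(all(diag(cm$matrix) == 1))
  expect_true(all(abs(cm$matrix) <= 1 + 1e-12))
  expect_true(isSymmetric(cm$matrix))
  # independent uniforms: |r| below the ~2/sqrt(n) sampling bound
  set.seed(3)
  n <- 1e4
  tab2 <- data.frame(subject_id = "a", stage_id = 1, r_time = 1:n,
                     u = runif(n), v = runif(n))
  cm2 <- pearson_within_stage(tab2, c("u", "v"), stage_id = 1)
  expect_lt(abs(cm2$matrix["u", "v"]), 0.05)
  # zero-variance parameter flagged undefined
  tab3 <- data.frame(subject_id = "a", stage_id = 1, r_time = 1:10,
                     u = rnorm(10), k = rep(1, 10))
  cm3 <- pearson_within_stage(tab3, c("u", "k"), stage_id = 1)
  expect_true(is.na(cm3$matrix["u", "k"]))
})

test_that("stage-averaged correlation recovers constructed stage profiles", {
  prof <- c(1, 2, 3, 4, 5)
  set.seed(4)
  rows <- expand.grid(stage = 1:5, i = 1:30)
  tab <- data.frame(subject_id = "a", stage_id = rows$stage, r_time = rows$i,
                    up = prof[rows$stage] + rnorm(nrow(rows), sd = 1e-6),
                    down = -prof[rows$stage] + rnorm(nrow(rows), sd = 1e-6))
  cm <- pearson_stage_averaged(tab, c("up", "down"))
  expect_equal(cm$matrix["up", "down"], -1, tolerance = 1e-6)
  expect_error(pearson_stage_averaged(tab[tab$stage_id <= 2, ],
                                      c("up", "down")),
               class = "rheomicro_insufficient_data_error")
})

test_that("stage averaging strengthens a coupling hidden by within-stage noise", {
  # one subject, five stages sharing a modifier profile: within any stage
  # the two parameters fluctuate independently (|r| small), yet their
  # stage-averaged profiles are almost perfectly correlated
  set.seed(9)
  prof <- c(1, 0.95, 1, 0.65, 0.35)
  rows <- expand.grid(stage = 1:5, i = 1:100)
  tab <- data.frame(subject_id = "a", stage_id = rows$stage, r_time = rows$i,
                    ri = prof[rows$stage] + rnorm(nrow(rows), sd = 0.15),
                    amc = 2 * prof[rows$stage] + rnorm(nrow(rows), sd = 0.3))
  within <- vapply(1:5, function(s)
    pearson_within_stage(tab, c("ri", "amc"), s)$matrix["ri", "amc"],
    numeric(1))
  expect_lt(median(abs(within)), 0.3)
  sa <- pearson_stage_averaged(tab, c("ri", "amc"))
  expect_gt(sa$matrix["ri", "amc"], 0.9)
})

test_that("cohort heatmaps use the sample-sd convention and stability mask", {
  m1 <- structure(list(params = c("a", "b"),
                       matrix = matrix(c(1, 1, 1, 1), 2,
                                       dimnames = list(c("a", "b"), c("a", "b"))),
                       n_pairs = matrix(10, 2, 2)),
                  class = "correlation_matrix")
  m2 <- m1
  m2$matrix["a", "b"] <- m2$matrix["b", "a"] <- -1
  hm <- cohort_heatmaps(list(m1, m2))
  expect_equal(hm$mean["a", "b"], 0)
  expect_equal(hm$sd["a", "b"], sd(c(1, -1)))  # sample (n-1) convention
  expect_false(hm$stable["a", "b"])
  expect_true(hm$stable["a", "a"])
  hm2 <- cohort_heatmaps(list(m1, m1))
  expect_true(all(hm2$sd == 0))
  expect_true(all(hm2$stable))
})

test_that("NMI is 1 for identical and monotone-related variables, near 0 for independent", {
  set.seed(5)
  n <- 1e4
  x <- runif(n)
  tab <- data.frame(subject_id = "a", stage_id = 1, r_time = 1:n,
                    x = x, same = x, mono = exp(3 * x), indep = runif(n))
  nm <- nmi_matrix(tab, c("x", "same", "mono", "indep"))
  expect_equal(nm$matrix["x", "same"], 1, tolerance = 1e-12)
  expect_equal(nm$matrix["x", "mono"], 1, tolerance = 1e-12)
  expect_lt(nm$matrix["x", "indep"], 0.05)
  expect_true(all(diag(nm$matrix) == 1))
  expect_true(isSymmetric(nm$matrix))
  expect_true(all(nm$matrix >= 0 & nm$matrix <= 1))
  expect_error(nmi_matrix(tab[1:20, ], c("x", "indep")),
               class = "rheomicro_insufficient_data_error")
})

test_that("feature tables merge, sort and keep degenerate rows with NAs", {
  t1 <- fake_table(n_per_stage = 3, n_subjects = 1, seed = 6)
  t2 <- fake_table(n_per_stage = 3, n_subjects = 1, seed = 7)
  t2$subject_id <- "S99"
  t2$dv[1] <- NA
  tab <- build_feature_table(list(t2, t1))
  expect_equal(nrow(tab), 30)
  expect_true(!is.unsorted(tab$subject_id))
  expect_true(any(is.na(tab$dv)))
})
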