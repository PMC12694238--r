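# Per-cycle metric battery: closed-form oracles, identities, flags.

test_that("triangular pulse metrics match the closed form", {
  fs <- 500
  A <- 80
  rise <- 0.1; fall <- 0.4
  t <- (0:(0.8 * fs - 1)) / fs
  pulse <- ifelse(t <= rise, A * t / rise,
                  pmax(0, A * (1 - (t - rise) / fall)))
  m <- impedance_metrics(pulse, rep(100, length(t)), fs, "forehead")
  expect_true(m$valid)
  expect_equal(m$dz, A)
  # max slope lives on the rising edge: t_ad within [0, rise]
  expect_gte(m$t_ad, 0); expect_lte(m$t_ad, rise)
  expect_equal(m$ad, A / rise, tolerance = 0.02)
  # triangle area = A * (rise + fall) / 2 = 0.25 * A
  expect_equal(m$s_z, 0.25 * A, tolerance = 0.02)
  expect_equal(m$ri, A / (100 * 1000))
})

test_that("the identity ri * z_base * 1000 = dz holds exactly on every cycle", {
  rec <- quick_recording(snr = 20)
  tab <- compute_cycle_metrics(rec)
  ok <- is.finite(tab$ri_forehead)
  expect_true(sum(ok) > 50)
  expect_equal(tab$ri_forehead[ok] * tab$z_base_forehead[ok] * 1000,
               tab$dz_forehead[ok], tolerance = 1e-12)
})

test_that("flat and degenerate cycles are flagged invalid", {
  m <- impedance_metrics(rep(0, 400), rep(100, 400), 500, "forehead")
  expect_false(m$valid)
  expect_true(is.na(m$dz))
  m2 <- impedance_metrics(rnorm(400, sd = 0.1), rep(100, 400), 500, "arm",
                          noise_floor_mohm = 5)
  expect_false(m2$valid)
})

test_that("alpha lies in (0, 90) degrees and steepens with faster decay", {
  fs <- 500
  t <- (0:(0.9 * fs - 1)) / fs
  mk <- function(fall) ifelse(t <= 0.1, 100 * t / 0.1,
                              100 * exp(-(t - 0.1) / fall))
  m_slow <- impedance_metrics(mk(0.40), rep(100, length(t)), fs, "forehead")
  m_fast <- impedance_metrics(mk(0.15), rep(100, length(t)), fs, "forehead")
  expect_gt(m_slow$alpha, 0); expect_lt(m_slow$alpha, 90)
  expect_gt(m_fast$alpha, m_slow$alpha)
})

test_that("LVET is undetectable on a monotone ramp and orders with ejection length", {
  expect_true(is.na(lvet_from_dzdt((1:400) * 0.5, 500)))
  rec1 <- quick_recording(pulse_shape = list(rise = 0.13, decay = 0.45,
                                             dicrotic_amp = 0.25,
                                             dicrotic_delay = 0.28,
                                             dicrotic_width = 0.045))
  rec2 <- quick_recording(pulse_shape = list(rise = 0.13, decay = 0.45,
                                             dicrotic_amp = 0.25,
                                             dicrotic_delay = 0.38,
                                             dicrotic_width = 0.045))
  l1 <- median(compute_cycle_metrics(rec1)$lvet, na.rm = TRUE)
  l2 <- median(compute_cycle_metrics(rec2)$lvet, na.rm = TRUE)
  expect_lt(l1, l2)
})

test_that("cross-channel metrics follow the defining ratios exactly", {
  fore <- list(valid = TRUE, rtt = 0.15, dz = 60, z_base = 120)
  arm <- list(valid = TRUE, rtt = 0.25, dz = 120, z_base = 60)
  cc <- cross_channel_metrics(fore, arm)
  expect_equal(cc$dt_z, 0.10)
  expect_equal(cc$icp, 0.5)
  expect_equal(cc$rz, 2.0)
  arm0 <- list(valid = TRUE, rtt = 0.25, dz = 0, z_base = 0)
  cc0 <- cross_channel_metrics(fore, arm0)
  expect_true(is.na(cc0$icp) && is.na(cc0$rz))
  expect_true(all(is.na(unlist(cross_channel_metrics(list(valid = FALSE), arm)))))
})

test_that("volumetric blood filling is linear in dz and scale-invariant in z_base", {
  p <- dv_model_params()
  expect_equal(volumetric_blood_filling(0, 110, 70, p), 0)
  v1 <- volumetric_blood_filling(100, 110, 70, p)
  expect_equal(volumetric_blood_filling(200, 110, 70, p), 2 * v1)
  expect_equal(volumetric_blood_filling(100, 220, 70, p), v1 / 4)
  expect_equal(volumetric_blood_filling(100, 110, 140, p), 2 * v1)
  expect_error(dv_model_params(rho_blood = -1),
               class = "rheomicro_parameter_error")
  expect_error(volumetric_blood_filling(100, 110, 0, p),
               class = "rheomicro_parameter_error")
})

test_that("LDF metrics recover tone amplitude, reject out-of-band tones, add up", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  m0 <- ldf_metrics(rep(5, 20 * fs), fs)
  expect_equal(m0$mc, 5)
  expect_lt(m0$a_mc, 0.01)
  m1 <- ldf_metrics(5 + 2 * sin(2 * pi * 1.0 * t), fs)
  expect_equal(m1$mc, 5, tolerance = 0.01)
  expect_equal(m1$a_mc, 2, tolerance = 0.02)
  m3 <- ldf_metrics(5 + 2 * sin(2 * pi * 3.0 * t), fs)
  expect_lt(m3$a_mc, 0.02)
  # additivity of well-separated in-band tones
  a <- 1.2 * sin(2 * pi * 0.8 * t)
  b <- 0.8 * sin(2 * pi * 1.4 * t)
  ma <- ldf_metrics(5 + a, fs)$a_mc
  mb <- ldf_metrics(5 + b, fs)$a_mc
  mab <- ldf_metrics(5 + a + b, fs)$a_mc
  expect_equal(mab, ma + mb, tolerance = 0.05)
  expect_error(ldf_metrics(rep(5, fs), fs),
               class = "rheomicro_insufficient_data_error")
})

test_that("parameters are recovered from clean and noisy recordings", {
  check <- function(snr, tol_rel, tol_ms) {
    rec <- get_fixture(paste0("rec_", snr), function()
      generate_recording(synth_config(noise_snr_db = snr,
                                      cautery_gaps = list(), seed = 21L)))
    tab <- get_fixture(paste0("tab_", snr), function()
      compute_cycle_metrics(rec))
    m <- match_truth(tab, rec$ground_truth$cycles)
    relerr <- function(a, b) median(abs(a - b) / abs(b), na.rm = TRUE)
    abserr <- function(a, b) median(abs(a - b), na.rm = TRUE)
    expect_lte(relerr(m$tab$dz_forehead, m$gt$dz_forehead), tol_rel)
    expect_lte(relerr(m$tab$z_base_forehead, m$gt$z_base_forehead), tol_rel)
    expect_lte(relerr(m$tab$ri_forehead,
                      m$gt$dz_forehead / (m$gt$z_base_forehead * 1000)), tol_rel)
    expect_lte(abserr(m$tab$rtt_forehead, m$gt$rtt_forehead), tol_ms / 1000)
    expect_lte(abserr(m$tab$rtt_arm, m$gt$rtt_arm), tol_ms / 1000)
    expect_lte(abserr(m$tab$t_ad_forehead, m$gt$t_ad_forehead), tol_ms / 1000)
    expect_lte(abserr(m$tab$lvet, m$gt$lvet_arm), tol_ms / 1000)
  }
  check(Inf, 0.05, 10)
  check(20, 0.10, 20)
})
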