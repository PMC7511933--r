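# baseline removal, smoothing, interval extraction

# narrow Gaussian peaks on a known smooth baseline
synthetic_spectrum <- function(n = 4000, peaks = c(800, 2000, 3200),
                               height = 50, sigma_pts = 3,
                               baseline_amp = 30) {
  i <- seq_len(n)
  baseline <- baseline_amp * exp(-i / 1500)
  signal <- rep(0, n)
  for (p in peaks) signal <- signal + height * exp(-(i - p)^2 / (2 * sigma_pts^2))
  list(truth = signal, baseline = baseline, observed = signal + baseline,
       peaks = peaks)
}

test_that("a flat spectrum is reduced to zero", {
  expect_true(all(baseline_remove(rep(7.5, 500), 20) == 0))
})

test_that("baseline removal recovers apex heights within 10 percent", {
  sp <- synthetic_spectrum()
  corrected <- baseline_remove(sp$observed, 20)
  for (p in sp$peaks) {
    expect_equal(corrected[p], sp$truth[p], tolerance = 0.1)
  }
  # already baseline-free peaks are preserved
  corrected2 <- baseline_remove(sp$truth, 20)
  for (p in sp$peaks) {
    expect_equal(corrected2[p], sp$truth[p], tolerance = 0.1)
  }
})

test_that("baseline removal is idempotent within one percent", {
  sp <- synthetic_spectrum()
  once <- baseline_remove(sp$observed, 20)
  twice <- baseline_remove(once, 20)
  expect_lt(max(abs(twice - once)), 0.01 * diff(range(once)))
})

test_that("kernel wider than the axis is a parameter error", {
  expect_error(baseline_remove(rep(1, 10), 20), "width")
})

test_that("smoothing preserves total ion current and reduces noise", {
  expect_identical(smooth_spectrum(1:100, "none"), 1:100)
  set.seed(42)
  noisy <- abs(rnorm(5000, 10, 3))
  sm <- smooth_spectrum(noisy, "medium")
  expect_lt(stats::var(diff(sm)), stats::var(diff(noisy)))
  expect_equal(sum(sm), sum(noisy), tolerance = 0.01)
  # a delta peak keeps its mass
  delta <- c(rep(0, 200), 100, rep(0, 200))
  expect_equal(sum(smooth_spectrum(delta, "medium")), 100, tolerance = 0.01)
  # stronger smoothing spreads more
  expect_lt(max(smooth_spectrum(delta, "strong")),
            max(smooth_spectrum(delta, "weak")))
})

test_that("interval mean of a constant spectrum is the constant", {
  mz <- seq(400, 500, 0.05)
  x <- rep(3.25, length(mz))
  expect_identical(interval_intensity(mz, x, 450), 3.25)
  expect_identical(interval_intensity(mz, x, 450, statistic = "max"), 3.25)
  expect_equal(interval_intensity(mz, x, 450, statistic = "sum"),
               3.25 * sum(abs(mz - 450) <= 0.156 + 1e-9))
})

test_that("interval mean of a rendered peak matches the analytic average", {
  # fine grid so that the discrete mean approximates the integral
  mz <- seq(600, 700, 0.005)
  center <- 650
  sigma <- 0.25 / (2 * sqrt(2 * log(2)))
  x <- exp(-(mz - center)^2 / (2 * sigma^2))
  hw <- 0.156
  analytic <- sigma * sqrt(2 * pi) *
    (2 * stats::pnorm(hw / sigma) - 1) / (2 * hw)
  expect_equal(interval_intensity(mz, x, center, hw), analytic,
               tolerance = 0.02)
})

test_that("boundary windows truncate and distant windows return zero", {
  mz <- seq(400, 500, 0.05)
  x <- seq_along(mz)
  at_edge <- interval_intensity(mz, x, 400.01)
  idx <- which(mz <= 400.01 + 0.156 + 1e-9)
  expect_equal(at_edge, mean(x[idx]))
  expect_warning(out <- interval_intensity(mz, x, 600), "outside")
  expect_identical(out, 0)
})

test_that("interval extraction is linear in the spectrum for the mean", {
  mz <- seq(400, 500, 0.05)
  set.seed(1)
  a <- abs(rnorm(length(mz)))
  b <- abs(rnorm(length(mz)))
  f <- function(x) interval_intensity(mz, x, 455)
  expect_equal(f(2 * a + 3 * b), 2 * f(a) + 3 * f(b), tolerance = 1e-12)
})

test_that("NA inside the window is a propagation error", {
  mz <- seq(400, 500, 0.05)
  x <- rep(1, length(mz))
  x[mz > 449.9 & mz < 450.1] <- NA
  expect_error(interval_intensity(mz, x, 450), "NaN|NA")
})

test_that("closed interval boundaries include grid points exactly on them", {
  mz <- seq(400, 401, 0.078)  # 400.312 is exactly target + 2*0.156
  x <- as.numeric(seq_along(mz))
  got <- interval_intensity(mz, x, 400.156)
  idx <- which(mz >= 400.0 - 1e-9 & mz <= 400.312 + 1e-9)
  expect_equal(got, mean(x[idx]))
})

test_that("end-to-end extraction is proportional to amount within 5 percent", {
  pan <- mini_panel()[2:3, ]  # the two cleavage fragments
  acq <- mini_acq(noise_sd = 0, baseline_amplitude = 0)
  ion <- stats::setNames(c(1, 2), pan$species_id)
  extract <- function(species_idx, amount) {
    am <- stats::setNames(c(0, 0), pan$species_id)
    am[species_idx] <- amount
    sp <- render_spectrum(am, pan, acq, ion)
    corrected <- baseline_remove(sp$intensity, 20)
    sm <- smooth_spectrum(corrected, "medium")
    interval_intensity(sp$mz, sm, pan$target_mz[species_idx])
  }
  for (i in 1:2) {
    amounts <- c(5, 20, 80)
    resp <- vapply(amounts, function(a) extract(i, a), 0)
    per_unit <- resp / (amounts * ion[i])
    expect_lt(max(abs(per_unit / mean(per_unit) - 1)), 0.05)
    # doubling the ionization factor doubles the response
    ion2 <- ion; ion2[i] <- ion[i] * 2
    am <- stats::setNames(c(0, 0), pan$species_id); am[i] <- 20
    sp <- render_spectrum(am, pan, acq, ion2)
    r2 <- interval_intensity(
      sp$mz, smooth_spectrum(baseline_remove(sp$intensity, 20), "medium"),
      pan$target_mz[i])
    expect_equal(unname(r2), unname(2 * resp[2]), tolerance = 0.05)
  }
})

test_that("a study is preprocessed with one shared configuration", {
  pan <- mini_panel()[2:3, ]
  ph <- make_phantom(8, 8, seed = 4)
  act <- uniform_activity_model(pan, k = 0.02, ionization = 1)
  acq <- mini_acq()
  study <- list(
    a = render_dataset(ph, act, ea_condition("active", 60), pan, acq, seed = 1),
    b = render_dataset(ph, act, ea_condition("active", 120), pan, acq, seed = 2)
  )
  res <- preprocess_study(study, pan, preprocess_config())
  expect_identical(res$datasets$a$preprocess$hash,
                   res$datasets$b$preprocess$hash)
  expect_identical(nrow(res$targets), 2L * 64L * 2L)
  # reprocessing is deterministic
  res2 <- preprocess_study(study, pan, preprocess_config())
  expect_identical(res$targets, res2$targets)

  # axis mismatch across datasets is a comparability error
  study$b$mz <- study$b$mz + 0.01
  expect_error(preprocess_study(study, pan), "axis mismatch")
})

test_that("TIC normalization equalizes total ion current across pixels", {
  pan <- mini_panel()[2:3, ]
  ph <- make_phantom(8, 8, seed = 4)
  act <- uniform_activity_model(pan, k = 0.02, ionization = 1)
  ds <- render_dataset(ph, act, ea_condition("active", 60), pan,
                       mini_acq(), seed = 3)
  dp <- preprocess_dataset(ds, preprocess_config(normalization = "TIC"))
  tics <- colSums(dp$intensity)
  # smoothing after normalization only perturbs edges; TIC stays equalized
  expect_lt(stats::sd(tics) / mean(tics), 1e-3)
})
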