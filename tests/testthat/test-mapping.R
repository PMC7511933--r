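# ion images, conversion maps, ROI statistics, grading, contrasts

mapped_setup <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pan <- mini_panel()[2:3, ]  # the two fragments of substrate 8
    ph <- make_phantom(12, 12, seed = 6)
    act <- uniform_activity_model(pan, k = 0.02, ionization = 1)
    acq <- mini_acq()
    ds <- render_dataset(ph, act, ea_condition("active", 60), pan, acq,
                         seed = 31)
    cache <<- list(pan = pan, ph = ph, act = act, acq = acq,
                   ds = preprocess_dataset(ds))
    cache
  }
})

test_that("ion images arrange pixel intensities on the acquisition grid", {
  s <- mapped_setup()
  img <- ion_image(s$ds, s$pan[1, ])
  expect_identical(dim(img$values), dim(s$ph$labels))
  expect_true(all(img$values >= 0))
  # on-tissue product signal clearly exceeds background
  expect_gt(mean(img$values[s$ph$labels > 0]),
            3 * mean(img$values[s$ph$labels == 0]))
})

test_that("species outside the acquired range cannot be imaged", {
  s <- mapped_setup()
  fake <- data.frame(species_id = "x", target_mz = 2500)
  expect_error(ion_image(s$ds, fake), "outside")
})

test_that("conversion map edge cases: all-substrate and all-product", {
  grid <- matrix(10, 4, 4)
  zeros <- matrix(0, 4, 4)
  img <- function(v, id) structure(list(values = v, species_id = id,
                                        condition = "active", time_min = 60),
                                   class = "ion_image")
  all_sub <- conversion_map(img(grid, "s.substrate"), img(zeros, "s.p1"))
  expect_true(all(all_sub$values == 0))
  all_prod <- conversion_map(img(zeros, "s.substrate"), img(grid, "s.p1"))
  expect_true(all(all_prod$values == 1))
  # below-floor pixels are undefined, not zero
  floored <- conversion_map(img(grid / 100, "s.substrate"),
                            img(zeros, "s.p1"), floor = 5)
  expect_true(all(is.na(floored$values)))
  expect_true(all(!floored$defined))
  expect_error(conversion_map(img(grid, "s"), img(matrix(0, 3, 3), "p")),
               "different grids")
})

test_that("conversion fraction is invariant under global intensity rescaling", {
  s <- mapped_setup()
  sub_img <- ion_image(s$ds, s$pan[1, ])
  prod_img <- ion_image(s$ds, s$pan[2, ])
  cm1 <- conversion_map(sub_img, prod_img)
  scaled_sub <- sub_img; scaled_sub$values <- sub_img$values * 7
  scaled_prod <- prod_img; scaled_prod$values <- prod_img$values * 7
  cm2 <- conversion_map(scaled_sub, scaled_prod)
  expect_equal(cm1$values, cm2$values, tolerance = 1e-12)
})

test_that("ROI statistics summarize constant images exactly", {
  s <- mapped_setup()
  const <- matrix(4.5, 12, 12)
  st <- roi_stats(const, s$ph)
  expect_identical(nrow(st), 2L)
  expect_true(all(st$mean == 4.5 & st$median == 4.5 &
                    st$q1 == 4.5 & st$q3 == 4.5))
  expect_true(all(st$q1 <= st$median & st$median <= st$q3))
})

test_that("whole-tissue ROI is the union of cortex and medulla", {
  s <- mapped_setup()
  img <- ion_image(s$ds, s$pan[1, ])
  st <- roi_stats(img, s$ph)
  n_tissue <- sum(s$ph$labels > 0)
  expect_identical(sum(st$n_pixels), n_tissue)
})

test_that("empty regions yield explicit zero-pixel records", {
  s <- mapped_setup()
  st <- roi_stats(matrix(1, 12, 12), s$ph, regions = c(1, 2, 7))
  row7 <- st[st$region == 7, ]
  expect_identical(row7$n_pixels, 0L)
  expect_true(is.na(row7$mean))
})

test_that("regional rate differences show up with the ground-truth sign", {
  pan <- mini_panel()[2:3, ]
  ph <- make_phantom(12, 12, seed = 8)
  act <- uniform_activity_model(pan, k = 0.02, ionization = 1)
  act$rates$k[act$rates$region == 2] <- 0.08  # medulla converts faster
  ds <- preprocess_dataset(
    render_dataset(ph, act, ea_condition("active", 60), pan, mini_acq(),
                   seed = 13))
  img <- ion_image(ds, pan[1, ])
  st <- roi_stats(img, ph)
  expect_gt(st$median[st$region == 2], st$median[st$region == 1])
})

test_that("detectability grading follows decade thresholds and scales", {
  noise <- list(center = 0, scale = 1)
  expect_identical(grade_detectability(rep(5, 10), noise)$grade, "+")
  expect_identical(grade_detectability(rep(50, 10), noise)$grade, "++")
  expect_identical(grade_detectability(rep(500, 10), noise)$grade, "+++")
  expect_identical(grade_detectability(rep(0, 10), noise)$grade, "-")
  expect_identical(grade_detectability(rep(2.9, 10), noise)$grade, "-")
  # scale invariance: multiply intensities and noise estimate together
  g1 <- grade_detectability(rep(42, 10), list(center = 1, scale = 2))
  g2 <- grade_detectability(rep(420, 10), list(center = 10, scale = 20))
  expect_identical(g1$grade, g2$grade)
  expect_equal(g1$snr, g2$snr, tolerance = 1e-12)
})

test_that("time course of substrate falls while product rises", {
  pan <- mini_panel()[2:3, ]
  ph <- make_phantom(10, 10, seed = 5)
  act <- uniform_activity_model(pan, k = 0.02, ionization = 1)
  acq <- mini_acq()
  study <- make_study(pan, ph, act, acq, times = c(5, 60), controls = NULL,
                      seed = 3)
  prep <- preprocess_study(study, pan, preprocess_config())
  tc <- time_course(prep$datasets, pan, pan$species_id[1], ph)
  expect_identical(nrow(tc), 2L)
  expect_gt(tc$mean_intensity[tc$time_min == 60],
            tc$mean_intensity[tc$time_min == 5])
})

test_that("identical datasets contrast to zero difference and unit ratio", {
  s <- mapped_setup()
  cc <- condition_contrast(s$ds, s$ds, s$pan[1, ], s$ph)
  expect_equal(cc$difference, 0)
  expect_equal(cc$ratio, 1)
  expect_equal(cc$cliffs_delta, 0, tolerance = 1e-12)
})

test_that("contrasting differently preprocessed datasets is an error", {
  s <- mapped_setup()
  other <- preprocess_dataset(
    render_dataset(s$ph, s$act, ea_condition("active", 60), s$pan, s$acq,
                   seed = 31),
    preprocess_config(smoothing = "strong"))
  expect_error(condition_contrast(s$ds, other, s$pan[1, ], s$ph),
               "mismatch")
})
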