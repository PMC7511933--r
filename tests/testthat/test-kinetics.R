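# ground-truth conversion kinetics per pixel

mini_model <- function(pan, k = 0.02, d = 0, S0 = 100) {
  uniform_activity_model(pan, k = k, d = d, S0 = S0, ionization = 1)
}

test_that("at time zero nothing is converted", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  am <- species_amounts(ph, mini_model(pan), ea_condition("active", 0), pan)
  on_tissue <- phantom_coords(ph)$label > 0
  expect_true(all(am["s08.substrate", on_tissue] == 100))
  expect_true(all(am[c("s08.p1", "s08.p2"), ] == 0))
  expect_true(all(am[, !on_tissue] == 0))
})

test_that("conversion saturates at long incubation without degradation", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  am <- species_amounts(ph, mini_model(pan, k = 1), ea_condition("active", 1e4), pan)
  on_tissue <- phantom_coords(ph)$label > 0
  expect_true(all(am["s08.substrate", on_tissue] < 1e-6))
  # split equally between the two fragments
  expect_equal(unname(am["s08.p1", on_tissue]), rep(50, sum(on_tissue)),
               tolerance = 1e-9)
  expect_equal(am["s08.p1", ], am["s08.p2", ], tolerance = 1e-12)
})

test_that("closed-form conversion fraction matches k*t evaluation", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  am <- species_amounts(ph, mini_model(pan, k = 0.02),
                        ea_condition("active", 60), pan)
  px <- which(phantom_coords(ph)$label > 0)[1]
  P <- unname(am["s08.p1", px] + am["s08.p2", px])
  S <- unname(am["s08.substrate", px])
  expect_equal(P / (P + S), 1 - exp(-1.2), tolerance = 1e-12)
})

test_that("kinetic conservation holds at all times without degradation", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  mod <- mini_model(pan, k = 0.037)
  on_tissue <- phantom_coords(ph)$label > 0
  for (t in c(0, 5, 15, 60, 120, 500)) {
    am <- species_amounts(ph, mod, ea_condition("active", t), pan)
    total <- am["s08.substrate", ] + am["s08.p1", ] + am["s08.p2", ]
    expect_equal(unname(total[on_tissue]), rep(100, sum(on_tissue)),
                 tolerance = 1e-9)
  }
})

test_that("product amount rises monotonically without degradation and
           rises then falls with degradation", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  px_product <- function(d, t) {
    am <- species_amounts(ph, mini_model(pan, k = 0.02, d = d),
                          ea_condition("active", t), pan)
    px <- which(phantom_coords(ph)$label > 0)[1]
    am["s08.p1", px] + am["s08.p2", px]
  }
  times <- c(5, 15, 60, 120)
  no_deg <- vapply(times, function(t) px_product(0, t), 0)
  expect_true(all(diff(no_deg) > 0))
  with_deg <- vapply(times, function(t) px_product(0.02, t), 0)
  expect_gt(with_deg[3], with_deg[2])   # still rising at 60 min
  expect_lt(with_deg[4], with_deg[3])   # declining by 120 min
})

test_that("degenerate degradation limit k == d stays finite and continuous", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  p_at <- function(d) {
    am <- species_amounts(ph, mini_model(pan, k = 0.02, d = d),
                          ea_condition("active", 60), pan)
    px <- which(phantom_coords(ph)$label > 0)[1]
    unname(am["s08.p1", px] + am["s08.p2", px])
  }
  expect_equal(p_at(0.02), p_at(0.02 + 1e-9), tolerance = 1e-5)
  expect_equal(p_at(0.02), 100 * 0.02 * 60 * exp(-1.2), tolerance = 1e-9)
})

test_that("controls zero out conversion or the whole panel", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  mod <- mini_model(pan)
  on_tissue <- phantom_coords(ph)$label > 0

  heat <- species_amounts(ph, mod, ea_condition("heat_inactivated", 60), pan)
  expect_true(all(heat[c("s08.p1", "s08.p2"), ] == 0))
  expect_true(all(heat["s08.substrate", on_tissue] == 100))

  none <- species_amounts(ph, mod, ea_condition("no_substrate", 60), pan)
  expect_true(all(none == 0))
})

test_that("partial heat attenuation scales the effective rate", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  am <- species_amounts(ph, mini_model(pan, k = 0.02),
                        ea_condition("heat_inactivated", 60,
                                     attenuation = 0.5), pan)
  px <- which(phantom_coords(ph)$label > 0)[1]
  expect_equal(unname(am["s08.substrate", px]), 100 * exp(-0.6),
               tolerance = 1e-12)
})

test_that("a missing regional rate is a configuration error", {
  pan <- mini_panel()
  ph <- make_phantom(12, 12, seed = 1)
  mod <- mini_model(pan)
  mod$rates <- mod$rates[mod$rates$region != 2, ]
  expect_error(
    species_amounts(ph, mod, ea_condition("active", 60), pan),
    "no activity rates"
  )
})
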