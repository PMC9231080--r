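test_that("the full peak table builds a library of exactly 20 materials", {
  lib <- full_library()
  expect_length(lib, 20)
  expect_s3_class(lib[["D-Glutamic acid"]], "thz_material")

  glu <- lib[["D-Glutamic acid"]]
  expect_equal(glu$oscillators$f, c(1.216, 2.038, 2.443))

  beta <- lib[["Beta-Alanine"]]
  expect_equal(nrow(beta$oscillators), 0)
  expect_gt(beta$baseline_slope, 0)
})

test_that("every class receives a distinct dielectric background", {
  lib <- full_library()
  featureless <- Filter(function(m) nrow(m$oscillators) == 0, lib)
  expect_length(featureless, 8)
  slopes <- vapply(featureless, `[[`, numeric(1), "baseline_slope")
  expect_equal(anyDuplicated(slopes), 0)
  eps_all <- vapply(lib, `[[`, numeric(1), "eps_inf")
  expect_equal(anyDuplicated(eps_all), 0)
  # background indices stay in the plausible pressed-tablet range
  expect_true(all(sqrt(eps_all) > 1.4 & sqrt(eps_all) < 1.9))
})

test_that("invalid peak tables are rejected", {
  expect_error(build_material_library(list(a = 1, a = 2)), "unique")
  expect_error(build_material_library(list(a = 1, b = 5.0)),
               "outside")
  expect_error(material_spec("x", c(1.2, 1.2)), "duplicate")
  expect_error(material_spec("x", -0.5), "positive")
  expect_error(material_spec("x", 1, eps_inf = 0.5), "eps_inf")
})

test_that("separable mode pushes grid-degenerate peaks apart", {
  lib <- build_material_library(separable = TRUE)
  d_ala <- lib[["D-Alanine"]]$oscillators$f
  l_ala <- lib[["L-Alanine"]]$oscillators$f
  expect_gte(abs(d_ala - l_ala), 0.02)

  # no two peaks of different classes remain grid-degenerate
  all_peaks <- lapply(lib, function(m) m$oscillators$f)
  for (i in seq_along(all_peaks)) for (j in seq_along(all_peaks)) {
    if (j <= i || !length(all_peaks[[i]]) || !length(all_peaks[[j]])) next
    gap <- min(abs(outer(all_peaks[[i]], all_peaks[[j]], `-`)))
    expect_gte(gap, 0.014)
  }

  # perturbed peaks stay close to their measured values
  orig <- amino_acid_peak_table()
  for (nm in names(orig)) {
    if (!length(orig[[nm]])) next
    expect_lt(max(abs(all_peaks[[nm]] - orig[[nm]])), 0.06)
  }
  # well-isolated peaks are untouched
  expect_true(1.88 %in% all_peaks[["L-Tryptophan"]])
  expect_true(0.854 %in% all_peaks[["L-Leucine"]])
})

test_that("oscillator-free material has constant index and zero kappa", {
  m <- material_spec("flat", numeric(0), eps_inf = 2.25,
                     baseline_slope = 0)
  nk <- complex_refractive_index(m, seq(0.1, 2.5, by = 0.1))
  expect_equal(nk$n, rep(1.5, length(nk$n)))
  expect_equal(nk$kappa, rep(0, length(nk$kappa)))
})

test_that("kappa peaks within one damping width of the oscillator", {
  m <- material_spec("one", 1.3, baseline_slope = 0, g = 0.06)
  f <- seq(0.5, 2.5, by = 1e-4)
  nk <- complex_refractive_index(m, f)
  f_max <- f[which.max(nk$kappa)]
  expect_lt(abs(f_max - 1.3), 0.06)
})

test_that("index below all resonances exceeds the index far above", {
  m <- material_spec("one", 1.3, baseline_slope = 0)
  nk <- complex_refractive_index(m, c(0.13, 13))
  expect_gt(nk$n[1], nk$n[2])
})

test_that("absorption lines have the documented scale and width", {
  m <- material_spec("one", 1.0, baseline_slope = 0)
  f <- seq(0.5, 1.5, by = 1e-3)
  nk <- complex_refractive_index(m, f)
  alpha <- 2 * nk$kappa * 2 * pi * f / thzamino:::THZ_C
  expect_gt(max(alpha), 1)
  expect_lt(max(alpha), 5)
  half <- f[alpha >= max(alpha) / 2]
  fwhm <- max(half) - min(half)
  expect_gt(fwhm, 0.04)
  expect_lt(fwhm, 0.1)
})
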