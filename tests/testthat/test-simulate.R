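test_that("noise-free generation ignores the seed and is reproducible", {
  instr <- quiet_instr()
  r1 <- simulate_reference(instr, seed = 1)
  r2 <- simulate_reference(instr, seed = 999)
  expect_identical(r1$amplitude, r2$amplitude)
})

test_that("instrument invariants are enforced", {
  expect_error(instrument_spec(delay_range = 90, time_step = 0.0251),
               "integer")
  expect_error(instrument_spec(noise_sigma_single = -1), ">= 0")
  expect_error(time_trace(c(0, 1, 3), c(0, 0, 0)), "uniform")
})

test_that("averaging scales the noise as one over sqrt(n)", {
  instr <- instrument_spec(noise_sigma_single = 0.01)
  clean <- simulate_reference(quiet_instr())$amplitude
  resid <- function(n_avg, seed) {
    simulate_reference(instr, seed = seed,
                       n_averaged = n_avg)$amplitude - clean
  }
  set.seed(1)
  seeds <- sample.int(1e6, 200)
  sd1 <- stats::sd(vapply(seeds[1:100], function(s) resid(1, s)[1000],
                          numeric(1)))
  sd100 <- stats::sd(vapply(seeds[101:200], function(s) resid(100, s)[1000],
                            numeric(1)))
  expect_equal(sd1 / sd100, 10, tolerance = 0.25)
})

test_that("the reference pulse respects the bandwidth contract", {
  sp <- fourier_spectrum(clean_reference(), 100)
  expect_lte(sp$amp[which.min(abs(sp$f - 4.5))], 0.01 * max(sp$amp))
})

test_that("a non-dispersive slab delays the pulse by (n-1)d/c", {
  instr <- quiet_instr()
  m <- material_spec("slab", numeric(0), eps_inf = 1.75^2,
                     baseline_slope = 0, thickness_d = 1.2)
  s <- simulate_sample_trace(m, instr, n_echoes = 0)
  r <- clean_reference()
  delay <- (which.max(s$amplitude) - which.max(r$amplitude)) *
    instr$time_step
  expect_equal(delay, 3.0, tolerance = 0.05)
})

test_that("an index-matched lossless slab transmits the reference unchanged", {
  m <- material_spec("air", numeric(0), eps_inf = 1, baseline_slope = 0)
  s <- simulate_sample_trace(m, quiet_instr(), n_echoes = 0)
  expect_equal(s$amplitude, clean_reference()$amplitude, tolerance = 1e-10)
})

test_that("etalon echoes appear at multiples of the round-trip delay", {
  instr <- quiet_instr()
  m <- material_spec("slab", numeric(0), eps_inf = 1.75^2,
                     baseline_slope = 0, thickness_d = 1.2)
  s <- simulate_sample_trace(m, instr, n_echoes = 2)
  peaks <- local_maxima(abs(s$amplitude), 0.002 * max(abs(s$amplitude)))
  # collapse plateaus of the same pulse: keep peaks > 5 ps apart
  t_pk <- (peaks - 1) * instr$time_step
  groups <- cumsum(c(TRUE, diff(t_pk) > 5))
  t_main <- vapply(split(seq_along(t_pk), groups), function(ii)
    t_pk[ii][which.max(abs(s$amplitude)[peaks[ii]])], numeric(1))
  expect_length(t_main, 3)  # main pulse + 2 echoes
  spacing <- diff(t_main)
  round_trip <- 2 * 1.75 * 1.2 / thzamino:::THZ_C
  expect_equal(unname(spacing), rep(round_trip, 2), tolerance = 0.02)
})

test_that("echoes beyond the delay window trigger a truncation warning", {
  m <- material_spec("thick", numeric(0), eps_inf = 16,
                     baseline_slope = 0, thickness_d = 4)
  expect_warning(simulate_sample_trace(m, quiet_instr(), n_echoes = 3),
                 "delay window")
})

test_that("the acquisition layout matches the measurement protocol", {
  lib2 <- full_library()[1:2]
  class(lib2) <- "thz_library"
  camp <- acquire_dataset(lib2, instrument_spec(), n_tablets = 5,
                          duration_s = 40, avg_counts = c(100), seed = 3)
  expect_equal(camp$raw_per_tablet, 2400)       # 60 Hz x 40 s
  labels <- vapply(camp$records[["100"]], `[[`, character(1), "label")
  expect_equal(as.integer(table(labels)), rep(120L, 2))  # 24/tablet x 5
})

test_that("full averaging yields a single record per tablet", {
  lib1 <- full_library()[1]
  class(lib1) <- "thz_library"
  camp <- acquire_dataset(lib1, instrument_spec(), n_tablets = 2,
                          duration_s = 40, avg_counts = c(2400), seed = 3)
  expect_length(camp$records[["2400"]], 2)
  expect_error(acquire_dataset(lib1, instrument_spec(), n_tablets = 1,
                               duration_s = 10, avg_counts = c(2400)),
               "exceeds")
})

test_that("campaigns are reproducible under a fixed seed", {
  lib1 <- full_library()[1]
  class(lib1) <- "thz_library"
  make <- function() acquire_dataset(lib1, instrument_spec(),
                                     n_tablets = 2, duration_s = 5,
                                     avg_counts = c(100, 10), seed = 42,
                                     max_records_per_tablet = 2)
  c1 <- make(); c2 <- make()
  expect_identical(c1$records[["10"]][[3]]$amplitude,
                   c2$records[["10"]][[3]]$amplitude)
  expect_identical(c1$reference$amplitude, c2$reference$amplitude)
})
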