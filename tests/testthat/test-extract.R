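test_that("zero padding to 100 ps yields a 0.01 THz frequency step", {
  sp <- fourier_spectrum(clean_reference(), 100)
  expect_equal(sp$f[2] - sp$f[1], 0.01, tolerance = 1e-12)
  expect_error(fourier_spectrum(clean_reference(), 50), "shorter")
})

test_that("the one-sided spectrum conserves energy (Parseval)", {
  tr <- clean_reference()
  sp <- fourier_spectrum(tr, 100)
  n <- 100 / (tr$t[2] - tr$t[1])
  half <- n %/% 2
  spec_energy <- (sp$amp[1]^2 + 2 * sum(sp$amp[2:half]^2) +
                    sp$amp[half + 1]^2) / n
  expect_equal(sum(tr$amplitude^2), spec_energy, tolerance = 1e-9)
})

test_that("transfer function of identical and scaled spectra", {
  sp <- fourier_spectrum(clean_reference(), 100)
  tf <- transfer_function(sp, sp)
  expect_equal(tf$rho[tf$valid], rep(1, sum(tf$valid)))
  expect_equal(tf$dphi[tf$valid], rep(0, sum(tf$valid)))

  half_tr <- clean_reference()
  half_tr$amplitude <- 0.5 * half_tr$amplitude
  tf2 <- transfer_function(fourier_spectrum(half_tr, 100), sp)
  expect_equal(tf2$rho[tf2$valid], rep(0.5, sum(tf2$valid)))
  expect_equal(max(abs(tf2$dphi[tf2$valid])), 0, tolerance = 1e-9)
})

test_that("a pure delay produces a phase linear in frequency", {
  tr <- clean_reference()
  shift <- 80                                # 2 ps at dt = 0.025 ps
  delayed <- tr
  delayed$amplitude <- c(numeric(shift),
                         tr$amplitude[1:(length(tr$amplitude) - shift)])
  tf <- transfer_function(fourier_spectrum(delayed, 100),
                          fourier_spectrum(tr, 100))
  tf <- unwrap_and_anchor_phase(tf)
  band <- tf$f >= 0.2 & tf$f <= 3
  expect_equal(tf$dphi[band], 2 * pi * tf$f[band] * 2, tolerance = 1e-6)
})

test_that("unwrapping recovers a wrapped linear phase and drops 2*pi offsets", {
  f <- seq(0, 5, by = 0.01)
  lin <- 2 * pi * f * 1.7                     # 1.7 ps delay
  wrapped <- (lin + pi) %% (2 * pi) - pi
  tf <- manual_tf(f, rep(0.8, length(f)), wrapped)
  tf$unwrapped <- FALSE
  out <- unwrap_and_anchor_phase(tf)
  expect_equal(out$dphi, lin, tolerance = 1e-9)

  tf2 <- manual_tf(f, rep(0.8, length(f)), lin + 2 * pi)
  out2 <- unwrap_and_anchor_phase(tf2)
  expect_equal(out2$dphi, lin, tolerance = 1e-9)
})

test_that("the refractive-index formula matches its closed form", {
  f <- seq(0.1, 2.5, by = 0.01)
  tf <- manual_tf(f, rep(0.9, length(f)), rep(0, length(f)))
  expect_equal(refractive_index(tf, 1.2), rep(1, length(f)))

  tf1 <- manual_tf(1, 0.9, 18.85)
  expect_equal(refractive_index(tf1, 1.2), 1.75, tolerance = 1e-3)
  # doubling d at fixed phase halves n - 1
  expect_equal(refractive_index(tf1, 2.4) - 1,
               (refractive_index(tf1, 1.2) - 1) / 2)
})

test_that("the absorption formula vanishes at the Fresnel limit", {
  n <- 1.75
  fresnel <- 4 * n / (n + 1)^2
  tf <- manual_tf(1, fresnel, 0)
  expect_equal(absorption_rate(tf, n, 1.2), 0, tolerance = 1e-12)

  tf1 <- manual_tf(1, 0.50800, 0)
  expect_equal(absorption_rate(tf1, 1.75, 1.2), 1.000, tolerance = 1e-3)

  tf2 <- manual_tf(1, 0.50800 / 2, 0)
  expect_equal(absorption_rate(tf2, 1.75, 1.2) -
                 absorption_rate(tf1, 1.75, 1.2),
               (2 / 1.2) * log(2), tolerance = 1e-12)
  # cm^-1 output option
  expect_equal(absorption_rate(tf1, 1.75, 1.2, units = "cm"),
               10 * absorption_rate(tf1, 1.75, 1.2))
})

test_that("band cropping keeps exactly the half-open default band", {
  instr <- quiet_instr()
  m <- material_spec("x", 1.2)
  s <- simulate_sample_trace(m, instr, n_echoes = 0)
  oc <- extract_optical_constants(s, clean_reference(), d = m$thickness_d)
  expect_length(oc$f, 240)
  expect_equal(oc$f[1], 0.10)
  expect_equal(oc$f[240], 2.49)

  full <- optical_constants(seq(0, 5, by = 0.01), rep(1.5, 501),
                            rep(0.2, 501), 1.2)
  expect_length(crop_band(full, 0.1, 0.2)$f, 10)
  expect_error(crop_band(full, 1, 1), "empty band")
  coarse <- optical_constants(seq(0, 5, by = 0.02), rep(1.5, 251),
                              rep(0.2, 251), 1.2)
  expect_error(crop_band(coarse), "step")
})

test_that("noise-free extraction recovers the programmed optical constants", {
  instr <- quiet_instr()
  ref <- clean_reference()
  for (m in full_library()[c("D-Glutamic acid", "Beta-Alanine")]) {
    s <- simulate_sample_trace(m, instr, n_echoes = 0)
    oc <- extract_optical_constants(s, ref, d = m$thickness_d)
    nk <- complex_refractive_index(m, oc$f)
    alpha_true <- 2 * nk$kappa * 2 * pi * oc$f / thzamino:::THZ_C
    band <- oc$f >= 0.3 & oc$f <= 2.2
    expect_lt(max(abs(oc$n - nk$n)[band]), 1e-3)
    expect_lt(max((abs(oc$alpha - alpha_true) / alpha_true)[band]), 0.01)
    expect_true(all(oc$n[band] >= 1))
  }
})

test_that("absorption peak positions survive avg-100 noise and etalon ripple", {
  instr <- instrument_spec()
  ref <- wavelet_denoise(simulate_reference(instr, seed = 5,
                                            n_averaged = 600))
  m <- full_library()[["D-Glutamic acid"]]
  s <- wavelet_denoise(simulate_sample_trace(m, instr, n_echoes = 2,
                                             seed = 6, n_averaged = 100))
  oc <- extract_optical_constants(s, ref, d = m$thickness_d)
  for (fj in m$oscillators$f) {
    win <- which(abs(oc$f - fj) <= 0.08)
    f_hat <- oc$f[win][which.max(oc$alpha[win])]
    expect_lte(abs(f_hat - fj), 0.011)
  }
})
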