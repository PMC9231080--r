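#' Instrument description for the synthetic THz-TDS spectrometer
#'
#' Captures the acquisition geometry of a desktop transmission THz
#' time-domain spectrometer: a delay line scanning a 90 ps window at
#' 60 traces per second, a band-limited single-cycle pulse, and additive
#' white noise whose standard deviation refers to a single (unaveraged)
#' acquisition.
#'
#' @param delay_range Delay window length (ps).
#' @param time_step Sampling interval (ps); `delay_range / time_step`
#'   must be an integer > 16.  The default (0.025 ps) gives 3600 samples
#'   and a Nyquist frequency of 20 THz.
#' @param acquisition_rate Traces acquired per second (Hz).
#' @param noise_sigma_single Standard deviation of the additive white
#'   noise of one raw acquisition, in units of the (unit-normalized)
#'   pulse peak amplitude.
#' @param pulse_center_freq Spectral shape parameter f0 (THz) of the
#'   emitted pulse; the amplitude spectrum is
#'   `(f/f0)^2 exp(-(f/f0)^2)`, which peaks at f0 and, with the default
#'   f0 = 1.6 THz, falls below 1% of its maximum beyond 4.5 THz.
#' @param t0 Arrival time of the reference pulse in the delay window (ps).
#' @param seed Optional default seed used when simulation functions are
#'   called without one.
#' @return Object of class `thz_instrument`.
#' @export
instrument_spec <- function(delay_range = 90, time_step = 0.025,
                            acquisition_rate = 60,
                            noise_sigma_single = 0.0035,
                            pulse_center_freq = 1.6, t0 = 10, seed = NULL) {
  n <- delay_range / time_step
  if (abs(n - round(n)) > 1e-9 || round(n) <= 16)
    stop("delay_range/time_step must be an integer sample count > 16")
  if (noise_sigma_single < 0) stop("noise_sigma_single must be >= 0")
  if (pulse_center_freq <= 0) stop("pulse_center_freq must be positive")
  structure(
    list(delay_range = delay_range, time_step = time_step,
         n_samples = as.integer(round(n)),
         acquisition_rate = acquisition_rate,
         noise_sigma_single = noise_sigma_single,
         pulse_center_freq = pulse_center_freq, t0 = t0, seed = seed),
    class = "thz_instrument"
  )
}

#' Construct a time trace
#'
#' @param t Uniform time axis (ps).
#' @param amplitude Field amplitude per sample (arbitrary units).
#' @param n_averaged Number of raw acquisitions averaged into this trace.
#' @param label Class name, or `"reference"`.
#' @param tablet_id Integer tablet identifier.
#' @return Object of class `thz_trace`.
#' @export
time_trace <- function(t, amplitude, n_averaged = 1L, label = "reference",
                       tablet_id = 0L) {
  t <- as.numeric(t); amplitude <- as.numeric(amplitude)
  if (length(t) < 2 || length(t) != length(amplitude))
    stop("t and amplitude must have equal length >= 2")
  dt <- diff(t)
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time axis must be uniform")
  if (n_averaged < 1) stop("n_averaged must be >= 1")
  structure(list(t = t, amplitude = amplitude,
                 n_averaged = as.integer(n_averaged),
                 label = as.character(label),
                 tablet_id = as.integer(tablet_id)),
            class = "thz_trace")
}

#' @export
print.thz_trace <- function(x, ...) {
  cat("<thz_trace>", x$label, " tablet", x$tablet_id,
      " n_averaged", x$n_averaged, "\n")
  cat("  ", length(x$t), "samples, dt =", x$t[2] - x$t[1], "ps, window",
      round(x$t[length(x$t)] - x$t[1] + (x$t[2] - x$t[1]), 3), "ps\n")
  invisible(x)
}

# One-sided frequency grid (THz) of an N-point trace with step dt (ps).
.one_sided_freqs <- function(n, dt) (0:(n %/% 2)) / (n * dt)

# Real inverse FFT of a one-sided spectrum (bins 0 .. N/2, N even).
.real_ifft_onesided <- function(spec, n) {
  full <- complex(n)
  half <- n %/% 2
  spec[1] <- complex(real = Re(spec[1]))            # DC real
  spec[half + 1] <- complex(real = Re(spec[half + 1]))  # Nyquist real
  full[1:(half + 1)] <- spec
  full[n:(half + 2)] <- Conj(spec[2:half])
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Noise-free reference spectrum on the one-sided instrument grid,
# normalized so the time-domain pulse peak is 1.
.clean_reference_spectrum <- function(instr) {
  n <- instr$n_samples
  f <- .one_sided_freqs(n, instr$time_step)
  x <- f / instr$pulse_center_freq
  mag <- x^2 * exp(-x^2)
  spec <- mag * exp(-2i * pi * f * instr$t0)
  pulse <- .real_ifft_onesided(spec, n)
  scale <- 1 / max(abs(pulse))
  list(f = f, spec = spec * scale)
}

# Deterministic seed mixing: maps a tuple of small non-negative integers
# to a seed in [1, 2^31 - 2].  Plain multiplicative hashing in double
# precision (all intermediates < 2^53).
.mix_seed <- function(...) {
  v <- c(...)
  h <- 104729
  for (x in v) h <- (h * 69069 + (x + 1) * 30011) %% 2147483629
  as.integer(h %% 2147483645) + 1L
}

#' Simulate the reference trace (empty beam path)
#'
#' Renders the band-limited single-cycle pulse on the delay window and
#' adds white Gaussian noise with standard deviation
#' `noise_sigma_single / sqrt(n_averaged)`.  With
#' `noise_sigma_single = 0` the output is deterministic and the seed is
#' ignored.
#'
#' @param instr A `thz_instrument`.
#' @param seed Integer seed for the noise draw (defaults to the
#'   instrument's seed).
#' @param n_averaged Number of raw acquisitions averaged.
#' @return A `thz_trace` labelled `"reference"`.
#' @export
simulate_reference <- function(instr, seed = instr$seed, n_averaged = 1L) {
  ref <- .clean_reference_spectrum(instr)
  amp <- .real_ifft_onesided(ref$spec, instr$n_samples)
  amp <- .add_trace_noise(amp, instr, n_averaged, seed)
  time_trace(t = (seq_len(instr$n_samples) - 1) * instr$time_step,
             amplitude = amp, n_averaged = n_averaged, label = "reference")
}

.add_trace_noise <- function(amp, instr, n_averaged, seed) {
  if (instr$noise_sigma_single > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- amp + stats::rnorm(length(amp),
                              sd = instr$noise_sigma_single / sqrt(n_averaged))
  }
  amp
}

# Complex slab transfer function H(f) of a material on a one-sided grid.
# Time convention: forward DFT uses exp(-i w t), so a delay t_d maps to
# exp(-i w t_d) and the complex index enters as n - i*kappa.
.slab_transfer <- function(material, f, n_echoes, thickness = NULL) {
  d <- if (is.null(thickness)) material$thickness_d else thickness
  nk <- complex_refractive_index(material, f)
  nc <- complex(real = nk$n, imaginary = -nk$kappa)
  w <- 2 * pi * f
  fres <- 4 * nc / (nc + 1)^2
  prop <- exp(-1i * w * (nc - 1) * d / THZ_C)
  h <- fres * prop
  if (n_echoes > 0) {
    r2 <- ((nc - 1) / (nc + 1))^2
    round_trip <- r2 * exp(-2i * w * nc * d / THZ_C)
    fp <- 1
    term <- 1
    for (m in seq_len(n_echoes)) {
      term <- term * round_trip
      fp <- fp + term
    }
    h <- h * fp
  }
  h
}

#' Simulate a transmitted sample trace
#'
#' Multiplies the reference spectrum by the slab transfer model - Fresnel
#' entry/exit factors, propagation phase and absorption from the complex
#' refractive index (referenced to the empty air path), and `n_echoes`
#' Fabry-Perot round-trip terms - then transforms back to the time
#' domain and adds averaging-scaled noise as in [simulate_reference()].
#'
#' @param material A `thz_material`.
#' @param instr A `thz_instrument`.
#' @param n_echoes Number of etalon echoes to render (>= 0).
#' @param seed Noise seed.
#' @param n_averaged Number of raw acquisitions averaged.
#' @param thickness Optional per-tablet thickness override (mm).
#' @param tablet_id Integer id carried on the trace.
#' @return A `thz_trace` labelled with the material name.
#' @export
simulate_sample_trace <- function(material, instr, n_echoes = 2,
                                  seed = instr$seed, n_averaged = 1L,
                                  thickness = NULL, tablet_id = 0L) {
  if (n_echoes < 0) stop("n_echoes must be >= 0")
  d <- if (is.null(thickness)) material$thickness_d else thickness
  ref <- .clean_reference_spectrum(instr)
  h <- .slab_transfer(material, ref$f, n_echoes, thickness = d)
  n_bar <- mean(complex_refractive_index(
    material, seq(0.2, 2.4, by = 0.1))$n)
  t_last <- instr$t0 + (n_bar - 1) * d / THZ_C + n_echoes * 2 * n_bar * d / THZ_C
  if (t_last > instr$delay_range)
    warning("last etalon echo (", round(t_last, 1),
            " ps) exceeds the delay window; it will be truncated")
  amp <- .real_ifft_onesided(ref$spec * h, instr$n_samples)
  amp <- .add_trace_noise(amp, instr, n_averaged, seed)
  time_trace(t = (seq_len(instr$n_samples) - 1) * instr$time_step,
             amplitude = amp, n_averaged = n_averaged,
             label = material$name, tablet_id = tablet_id)
}

#' Acquire a full synthetic measurement campaign
#'
#' Emulates the tablet measurement protocol: each tablet of each material
#' is scanned continuously for `duration_s` seconds at the instrument's
#' acquisition rate, and the raw acquisitions are block-averaged into
#' records of `avg_counts` acquisitions each
#' (`floor(duration_s * rate / avg)` records per tablet and averaging
#' level).  Averaged records are synthesized directly: the noise-free
#' tablet trace plus white noise of standard deviation
#' `noise_sigma_single / sqrt(avg)`.  Tablets of the same material differ
#' by a small random thickness perturbation.  All random draws are keyed
#' deterministically by (seed, class, tablet, averaging level, record),
#' so any subset of the campaign is reproducible in isolation.
#'
#' @param library A `thz_library` (list of `thz_material`).
#' @param instr A `thz_instrument`.
#' @param n_tablets Tablets pressed per material.
#' @param duration_s Continuous acquisition time per tablet (s).
#' @param avg_counts Averaging levels; each must divide into at least one
#'   record.
#' @param seed Campaign seed.
#' @param n_echoes Etalon echoes rendered on every tablet trace.
#' @param thickness_jitter Relative standard deviation of the per-tablet
#'   thickness perturbation.
#' @param max_records_per_tablet Optional cap on records kept per tablet
#'   and averaging level (useful for scaled-down runs); scalar or one
#'   value per entry of `avg_counts`.
#' @param reference_n_averaged Averaging count of the single reference
#'   record (default 600: a 10 s continuous acquisition at 60 Hz).
#' @return Object of class `thz_campaign`: a list with `records` (one
#'   list of `thz_trace` per averaging level, names = averaging counts),
#'   `reference`, `library`, `instr`, and the acquisition metadata.
#' @export
acquire_dataset <- function(library, instr, n_tablets = 5, duration_s = 40,
                            avg_counts = c(100, 20, 10), seed = 1,
                            n_echoes = 2, thickness_jitter = 0.01,
                            max_records_per_tablet = Inf,
                            reference_n_averaged = 600L) {
  total <- floor(duration_s * instr$acquisition_rate + 1e-9)
  if (any(avg_counts > total))
    stop("avg_count exceeds the ", total, " acquisitions per tablet")
  max_records_per_tablet <- rep_len(max_records_per_tablet,
                                    length(avg_counts))
  ref <- simulate_reference(instr, seed = .mix_seed(seed, 0, 0, 0, 0),
                            n_averaged = reference_n_averaged)
  t_axis <- (seq_len(instr$n_samples) - 1) * instr$time_step
  records <- stats::setNames(
    lapply(avg_counts, function(a) list()), as.character(avg_counts))
  for (i in seq_along(library)) {
    mat <- library[[i]]
    for (j in seq_len(n_tablets)) {
      set.seed(.mix_seed(seed, i, j, 0, 0))
      d_j <- mat$thickness_d * (1 + thickness_jitter * stats::rnorm(1))
      clean <- simulate_sample_trace(
        mat, .noise_free(instr), n_echoes = n_echoes,
        thickness = d_j, tablet_id = j)$amplitude
      for (ai in seq_along(avg_counts)) {
        a <- avg_counts[ai]
        n_rec <- min(floor(total / a), max_records_per_tablet[ai])
        if (n_rec < 1) stop("avg_count ", a, " yields no complete record")
        sd_rec <- instr$noise_sigma_single / sqrt(a)
        for (k in seq_len(n_rec)) {
          set.seed(.mix_seed(seed, i, j, ai, k))
          amp <- clean + stats::rnorm(length(clean), sd = sd_rec)
          records[[ai]][[length(records[[ai]]) + 1L]] <-
            time_trace(t_axis, amp, n_averaged = a, label = mat$name,
                       tablet_id = j)
        }
      }
    }
  }
  structure(
    list(records = records, reference = ref, library = library,
         instr = instr, n_tablets = n_tablets, duration_s = duration_s,
         avg_counts = avg_counts, seed = seed, n_echoes = n_echoes,
         thickness_jitter = thickness_jitter,
         raw_per_tablet = total),
    class = "thz_campaign"
  )
}

.noise_free <- function(instr) { instr$noise_sigma_single <- 0; instr }

#' @export
print.thz_campaign <- function(x, ...) {
  cat("<thz_campaign>", length(x$library), "classes x", x$n_tablets,
      "tablets,", x$duration_s, "s at", x$instr$acquisition_rate, "Hz (",
      x$raw_per_tablet, "raw acquisitions/tablet )\n")
  for (a in names(x$records))
    cat("  avg", a, ":", length(x$records[[a]]), "records\n")
  invisible(x)
}
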