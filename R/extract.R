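#' Fourier spectrum of a time trace
#'
#' Zero-pads the trace to `pad_to_ps` and returns the one-sided discrete
#' Fourier transform split into magnitude and phase.  The phase follows
#' the convention `E(f) = |E(f)| exp(-i phi(f))`, so a delayed pulse has
#' increasing phase.  Padding to 100 ps makes the frequency step exactly
#' 0.01 THz regardless of the native 90 ps delay window.
#'
#' @param trace A `thz_trace`.
#' @param pad_to_ps Total duration after zero padding (ps); must be at
#'   least the trace duration.
#' @return Object of class `thz_spectrum`: list with `f` (THz), `amp`,
#'   `phase` (radians).
#' @export
fourier_spectrum <- function(trace, pad_to_ps = 100) {
  stopifnot(inherits(trace, "thz_trace"))
  dt <- trace$t[2] - trace$t[1]
  n0 <- length(trace$amplitude)
  n <- pad_to_ps / dt
  if (abs(n - round(n)) > 1e-6)
    stop("pad_to_ps must be an integer multiple of the time step")
  n <- as.integer(round(n))
  if (n < n0) stop("pad_to_ps shorter than the trace duration")
  x <- c(trace$amplitude, numeric(n - n0))
  sp <- stats::fft(x)[1:(n %/% 2 + 1)]
  structure(list(f = .one_sided_freqs(n, dt), amp = Mod(sp),
                 phase = -Arg(sp)),
            class = "thz_spectrum")
}

#' Transfer function of a sample/reference spectrum pair
#'
#' Computes the amplitude ratio `rho = |E_samp| / |E_ref|` and the raw
#' (wrapped) phase change `dphi = phi_samp - phi_ref`, positive for a
#' delayed sample.  Bins where the reference magnitude vanishes are
#' flagged invalid.
#'
#' @param sample,ref `thz_spectrum` objects on identical frequency grids.
#' @return Object of class `thz_tf`: list with `f`, `rho`, `dphi`,
#'   logical `valid`, and `unwrapped = FALSE`.
#' @export
transfer_function <- function(sample, ref) {
  stopifnot(inherits(sample, "thz_spectrum"), inherits(ref, "thz_spectrum"))
  if (length(sample$f) != length(ref$f) ||
      max(abs(sample$f - ref$f)) > 1e-9)
    stop("sample and reference must share one frequency grid")
  valid <- ref$amp > 0
  rho <- ifelse(valid, sample$amp / ref$amp, NA_real_)
  dphi <- sample$phase - ref$phase
  dphi <- (dphi + pi) %% (2 * pi) - pi    # wrap to (-pi, pi]
  structure(list(f = sample$f, rho = rho, dphi = dphi, valid = valid,
                 unwrapped = FALSE),
            class = "thz_tf")
}

#' Unwrap the transfer-function phase and anchor its branch
#'
#' Unwraps `dphi` along frequency, then removes the 2*pi branch
#' ambiguity: a line is fitted to the unwrapped phase on a high-SNR
#' anchor band and the multiple of 2*pi nearest to the line's DC
#' intercept is subtracted, so that the extrapolated intercept is minimal
#' in magnitude (a sample slab produces a phase proportional to
#' frequency, hence zero intercept).
#'
#' @param tf A `thz_tf`.
#' @param anchor_band Frequency interval (THz) used for the line fit.
#' @param residual_warn Warn when the RMS residual of the anchor fit
#'   exceeds this value (radians), indicating low SNR.
#' @return The `thz_tf` with continuous, anchored `dphi` and
#'   `unwrapped = TRUE`.
#' @export
unwrap_and_anchor_phase <- function(tf, anchor_band = c(0.3, 1.0),
                                    residual_warn = 0.5) {
  stopifnot(inherits(tf, "thz_tf"))
  dphi <- signal::unwrap(tf$dphi)
  sel <- tf$f >= anchor_band[1] & tf$f <= anchor_band[2] & tf$valid
  if (sum(sel) < 3) stop("anchor band contains fewer than 3 valid bins")
  fit <- stats::lm.fit(cbind(1, tf$f[sel]), dphi[sel])
  if (sqrt(mean(fit$residuals^2)) > residual_warn)
    warning("anchor-band phase fit residual is large; low SNR?")
  dphi <- dphi - 2 * pi * round(fit$coefficients[1] / (2 * pi))
  tf$dphi <- dphi
  tf$unwrapped <- TRUE
  tf
}

#' Refractive index from the transfer-function phase
#'
#' Evaluates `n(f) = 1 + dphi * c / (omega * d)` elementwise (omega =
#' 2*pi*f).  The zero-frequency bin, where the expression is singular, is
#' returned as `NA`.
#'
#' @param tf An unwrapped `thz_tf` (see [unwrap_and_anchor_phase()]).
#' @param d Slab thickness (mm).
#' @return Numeric vector `n(f)` on `tf$f`.
#' @export
refractive_index <- function(tf, d) {
  stopifnot(inherits(tf, "thz_tf"))
  if (!isTRUE(tf$unwrapped))
    warning("transfer-function phase has not been unwrapped/anchored")
  if (d <= 0) stop("thickness d must be positive")
  w <- 2 * pi * tf$f
  n <- 1 + tf$dphi * THZ_C / (w * d)
  n[tf$f == 0] <- NA_real_
  n
}

#' Absorption rate from the transfer function
#'
#' Evaluates the thick-slab absorption rate
#' \deqn{\alpha(f) = \frac{2}{d}\,\ln\!\frac{4 n(f)}{\rho(f)\,(n(f)+1)^2}}
#' in mm^-1, the form in which a purely Fresnel-limited transmission
#' (`rho = 4n/(n+1)^2`) gives exactly zero absorption.  Bins where the
#' logarithm argument is non-positive or `rho` is invalid are flagged.
#'
#' @param tf A `thz_tf`.
#' @param n Refractive index from [refractive_index()].
#' @param d Slab thickness (mm).
#' @param units `"mm"` (default, mm^-1) or `"cm"` (cm^-1).
#' @return Numeric vector `alpha(f)`; invalid bins are `NA`.
#' @export
absorption_rate <- function(tf, n, d, units = c("mm", "cm")) {
  stopifnot(inherits(tf, "thz_tf"))
  units <- match.arg(units)
  if (d <= 0) stop("thickness d must be positive")
  arg <- 4 * n / (tf$rho * (n + 1)^2)
  ok <- tf$valid & is.finite(arg) & arg > 0 & is.finite(n)
  alpha <- rep(NA_real_, length(arg))
  alpha[ok] <- (2 / d) * log(arg[ok])
  if (units == "cm") alpha <- alpha * 10
  alpha
}

#' Crop optical constants to the analysis band
#'
#' Keeps the half-open interval `[f_lo, f_hi)`; with the default band
#' (0.1 to 2.5 THz) and the 0.01 THz grid enforced by 100 ps padding this
#' yields exactly 240 points.  Invalid (`NA`) absorption bins are clamped
#' to the nearest valid value so the band-length contract holds even in
#' deep-absorption regions.
#'
#' @param oc A `thz_optical` object (list with `f`, `n`, `alpha`, `d`).
#' @param f_lo,f_hi Band edges (THz), half-open `[f_lo, f_hi)`.
#' @param step Required frequency step (THz).
#' @return A `thz_optical` restricted to the band.
#' @export
crop_band <- function(oc, f_lo = 0.1, f_hi = 2.5, step = 0.01) {
  stopifnot(inherits(oc, "thz_optical"))
  df <- oc$f[2] - oc$f[1]
  if (abs(df - step) > 1e-9)
    stop("frequency grid step ", format(df), " does not match the required ",
         step, " THz (pad traces to 1/step ps)")
  keep <- which(oc$f >= f_lo - 1e-9 & oc$f < f_hi - 1e-9)
  if (!length(keep)) stop("empty band: f_lo must be below f_hi")
  oc$f <- oc$f[keep]
  oc$n <- oc$n[keep]
  oc$alpha <- .clamp_na(oc$alpha[keep])
  oc
}

# Replace NA runs by the nearest valid neighbour (last observation
# carried forward, first valid value carried backward at the start).
.clamp_na <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (!length(ok)) stop("no valid bins on the band")
  idx <- findInterval(seq_along(x), ok)
  idx[idx == 0] <- 1
  x[ok[idx]]
}

#' Optical constants container
#' @param f Frequency grid (THz).
#' @param n Refractive index.
#' @param alpha Absorption rate (mm^-1).
#' @param d Slab thickness (mm).
#' @return Object of class `thz_optical`.
#' @export
optical_constants <- function(f, n, alpha, d) {
  stopifnot(length(f) == length(n), length(f) == length(alpha), d > 0)
  structure(list(f = f, n = n, alpha = alpha, d = d), class = "thz_optical")
}

#' Extract optical constants from a sample/reference trace pair
#'
#' The full extraction chain: optional wavelet denoising of both traces,
#' zero-padded Fourier transform, transfer function, phase unwrapping and
#' anchoring, refractive index, absorption rate, and band cropping.
#'
#' @param sample,ref `thz_trace` objects on the same time axis.
#' @param d Slab thickness (mm).
#' @param pad_to_ps Zero-padding target (ps); 100 ps gives the 0.01 THz
#'   grid of the standard 240-point band.
#' @param denoise A [denoise_config()] or `NULL` to skip denoising.
#' @param f_lo,f_hi Analysis band (THz), half-open.
#' @param anchor_band Phase anchoring band passed to
#'   [unwrap_and_anchor_phase()].
#' @return A `thz_optical` on the cropped band.
#' @examples
#' instr <- instrument_spec(noise_sigma_single = 0)
#' mat <- material_spec("x", c(0.9, 1.6))
#' s <- simulate_sample_trace(mat, instr, n_echoes = 0)
#' r <- simulate_reference(instr)
#' oc <- extract_optical_constants(s, r, d = mat$thickness_d)
#' length(oc$f)  # 240
#' @export
extract_optical_constants <- function(sample, ref, d, pad_to_ps = 100,
                                      denoise = NULL, f_lo = 0.1, f_hi = 2.5,
                                      anchor_band = c(0.3, 1.0)) {
  if (!is.null(denoise)) {
    sample <- wavelet_denoise(sample, denoise)
    ref <- wavelet_denoise(ref, denoise)
  }
  sp_s <- fourier_spectrum(sample, pad_to_ps)
  sp_r <- fourier_spectrum(ref, pad_to_ps)
  tf <- transfer_function(sp_s, sp_r)
  tf <- unwrap_and_anchor_phase(tf, anchor_band)
  n <- refractive_index(tf, d)
  alpha <- absorption_rate(tf, n, d)
  step <- tf$f[2] - tf$f[1]
  crop_band(optical_constants(tf$f, n, alpha, d), f_lo, f_hi, step = step)
}
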