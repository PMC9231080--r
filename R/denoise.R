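# Standard symlet-4 orthogonal filter bank (8 taps).  Decomposition
# low-pass; the remaining filters follow from orthogonality:
#   dec_hi[m] = (-1)^m dec_lo[L-1-m],  rec_lo = rev(dec_lo),
#   rec_hi = rev(dec_hi).
.SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                   0.49761866763201545,  0.80373875180591614,
                   0.29785779560527736, -0.09921954357684722,
                  -0.01260396726203783,  0.03222310060404270)

.wavelet_filters <- function(wavelet_name) {
  if (!identical(wavelet_name, "sym4"))
    stop("only the sym4 wavelet is provided")
  lo <- .SYM4_DEC_LO
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi))
}

# Periodized single-level analysis: x (even length) -> list(a, d).
.dwt_step <- function(x, flt) {
  n <- length(x)
  half <- n %/% 2
  L <- length(flt$dec_lo)
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)          # even-indexed anchor, 0-based
  for (m in seq_len(L)) {
    idx <- (base + m - 1) %% n + 1
    a <- a + flt$dec_lo[m] * x[idx]
    d <- d + flt$dec_hi[m] * x[idx]
  }
  list(a = a, d = d)
}

# Periodized single-level synthesis, inverse of .dwt_step.
.idwt_step <- function(a, d, flt) {
  half <- length(a)
  n <- 2 * half
  L <- length(flt$dec_lo)
  x <- numeric(n)
  base <- 2 * (seq_len(half) - 1)
  for (m in seq_len(L)) {
    idx <- (base + m - 1) %% n + 1
    x[idx] <- x[idx] + flt$dec_lo[m] * a + flt$dec_hi[m] * d
  }
  x
}

# Multilevel periodized DWT.  The signal is zero-padded at the end to a
# multiple of 2^level (original length recorded for reconstruction).
.dwt <- function(x, level, flt) {
  n0 <- length(x)
  block <- 2^level
  n <- ceiling(n0 / block) * block
  x <- c(x, numeric(n - n0))
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- .dwt_step(a, flt)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details, n0 = n0)
}

.idwt <- function(decomp, flt) {
  a <- decomp$approx
  for (l in rev(seq_along(decomp$details)))
    a <- .idwt_step(a, decomp$details[[l]], flt)
  a[seq_len(decomp$n0)]
}

#' Wavelet shrinkage configuration
#'
#' @param wavelet_name Wavelet basis (only `"sym4"` is provided).
#' @param level Maximum decomposition level (default 5).
#' @param threshold_rule Threshold selection rule; `"universal"` uses
#'   `sigma * sqrt(2 log N)` with sigma estimated from the median
#'   absolute deviation of the finest detail coefficients.
#' @param threshold_mode `"soft"` (shrink) or `"hard"` (zero out).
#' @return Object of class `thz_denoise_config`.
#' @export
denoise_config <- function(wavelet_name = "sym4", level = 5,
                           threshold_rule = c("universal"),
                           threshold_mode = c("soft", "hard")) {
  if (level < 1) stop("level must be >= 1")
  structure(list(wavelet_name = wavelet_name, level = as.integer(level),
                 threshold_rule = match.arg(threshold_rule),
                 threshold_mode = match.arg(threshold_mode)),
            class = "thz_denoise_config")
}

#' Wavelet shrinkage denoising of a time trace
#'
#' Multilevel sym4 decomposition; detail coefficients at all levels are
#' thresholded (soft shrinkage by default) with the universal threshold
#' `sigma * sqrt(2 log N)`, where sigma is the MAD estimate from the
#' finest-level details; the trace is then reconstructed at its original
#' length.  The time axis and metadata are unchanged.
#'
#' @param trace A `thz_trace`.
#' @param cfg A [denoise_config()].
#' @param threshold Optional fixed threshold overriding the rule; `0`
#'   reproduces the input exactly (perfect reconstruction).
#' @return The denoised `thz_trace`.
#' @export
wavelet_denoise <- function(trace, cfg = denoise_config(), threshold = NULL) {
  stopifnot(inherits(trace, "thz_trace"))
  n <- length(trace$amplitude)
  max_level <- floor(log2(n))
  if (cfg$level > max_level)
    stop("decomposition level ", cfg$level, " infeasible for length ", n,
         "; maximum feasible level is ", max_level)
  flt <- .wavelet_filters(cfg$wavelet_name)
  dec <- .dwt(trace$amplitude, cfg$level, flt)
  if (is.null(threshold)) {
    sigma <- stats::mad(dec$details[[1]], center = 0)
    threshold <- sigma * sqrt(2 * log(n))
  }
  dec$details <- lapply(dec$details, .shrink, thr = threshold,
                        mode = cfg$threshold_mode)
  trace$amplitude <- .idwt(dec, flt)
  trace
}

.shrink <- function(d, thr, mode) {
  if (mode == "hard") {
    d[abs(d) < thr] <- 0
    d
  } else {
    sign(d) * pmax(abs(d) - thr, 0)
  }
}

#' Average a set of time traces
#'
#' Pointwise mean of traces sharing one time axis and label; the
#' averaging counts add.
#'
#' @param traces List of `thz_trace` objects.
#' @return A single `thz_trace`.
#' @export
average_traces <- function(traces) {
  if (!length(traces)) stop("no traces to average")
  t0 <- traces[[1]]$t
  lab <- traces[[1]]$label
  for (tr in traces) {
    if (length(tr$t) != length(t0) || max(abs(tr$t - t0)) > 1e-9)
      stop("traces must share one time axis")
    if (!identical(tr$label, lab)) stop("traces must share one label")
  }
  amp <- Reduce(`+`, lapply(traces, `[[`, "amplitude")) / length(traces)
  time_trace(t0, amp,
             n_averaged = sum(vapply(traces, `[[`, integer(1), "n_averaged")),
             label = lab, tablet_id = traces[[1]]$tablet_id)
}
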