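# Shared fixtures, memoized across test files to keep the suite fast.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

quiet_instr <- function() fixture("quiet_instr", function()
  instrument_spec(noise_sigma_single = 0))

clean_reference <- function() fixture("clean_reference", function()
  simulate_reference(quiet_instr()))

full_library <- function() fixture("full_library", function()
  build_material_library())

# Simple local-maximum finder used to locate pulse peaks and echoes.
local_maxima <- function(x, min_height) {
  n <- length(x)
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  idx[x[idx] >= min_height]
}

# A transfer-function object built directly from arrays (already
# unwrapped), for exercising the inversion formulas in isolation.
manual_tf <- function(f, rho, dphi) {
  structure(list(f = f, rho = rho, dphi = dphi,
                 valid = rep(TRUE, length(f)), unwrapped = TRUE),
            class = "thz_tf")
}

# Tiny feature container with known content for dataset-assembly tests:
# `n_per_class` records per class in the "100" group, plus smaller "20"
# and "10" groups.
toy_features <- function(n_classes = 4, n_per_class = 10, n_band = 24,
                         seed = 5) {
  set.seed(seed)
  mk_group <- function(n_per) {
    lab <- rep(seq_len(n_classes), each = n_per)
    list(alpha = matrix(rnorm(length(lab) * n_band, mean = lab), length(lab)),
         n = matrix(rnorm(length(lab) * n_band, mean = 1.5 + 0.1 * lab),
                    length(lab)),
         label = lab,
         tablet = rep_len(1:5, length(lab)))
  }
  structure(list(groups = list("100" = mk_group(n_per_class),
                               "20" = mk_group(3), "10" = mk_group(3)),
                 f = seq(0.1, by = 0.01, length.out = n_band),
                 class_names = paste0("class", seq_len(n_classes))),
            class = "thz_features")
}

# Small network geometry (input length 48) used for fast training tests.
small_net_config <- function(n_classes = 2, channels = 1, use_eca = TRUE)
  network_config(n_classes = n_classes, input_length = 48,
                 input_channels = channels, use_eca = use_eca)

# Linearly separable toy spectra for the small geometry.
toy_separable_set <- function(n_per_class = 40, seed = 2) {
  set.seed(seed)
  pattern <- sin(seq(0, 4 * pi, length.out = 48))
  n <- 2 * n_per_class
  x <- array(0, c(n, 48, 1))
  y <- rep(1:2, each = n_per_class)
  for (i in seq_len(n))
    x[i, , 1] <- (if (y[i] == 1) pattern else -pattern) + rnorm(48, sd = 0.1)
  list(x = x, y = y, split_tag = "toy")
}
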