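#' Hybrid N x 2 spectrum
#'
#' Stacks absorption rate and refractive index column-wise into the
#' N x 2 feature map used as classifier input (column 1 = absorption
#' rate, column 2 = refractive index).  Standardization, when requested,
#' uses externally supplied per-column statistics (from the training
#' split of a dataset assembler) to avoid information leakage.
#'
#' @param alpha_band,n_band Numeric vectors of equal length on one band.
#' @param f Optional frequency axis carried along.
#' @param standardize Standardize columns using `stats`.
#' @param stats List with `mean` and `sd`, each a length-2 vector
#'   (alpha, n); required when `standardize = TRUE`.
#' @return Object of class `thz_hybrid`: list with `matrix` (N x 2) and
#'   `f`.
#' @export
hybrid_spectrum <- function(alpha_band, n_band, f = NULL,
                            standardize = FALSE, stats = NULL) {
  if (length(alpha_band) != length(n_band))
    stop("alpha and n must have equal length")
  m <- cbind(alpha = alpha_band, n = n_band)
  if (standardize) {
    if (is.null(stats)) stop("standardize = TRUE requires training stats")
    m <- sweep(sweep(m, 2, stats$mean), 2, stats$sd, `/`)
  }
  if (any(!is.finite(m))) stop("non-finite entries in hybrid spectrum")
  structure(list(matrix = m, f = f), class = "thz_hybrid")
}

#' Extract per-record optical-constant features from a campaign
#'
#' Runs the extraction chain of [extract_optical_constants()] on every
#' record of a [acquire_dataset()] campaign, against the campaign's
#' reference trace.  The reference is denoised once and reused.
#'
#' @param campaign A `thz_campaign`.
#' @param denoise A [denoise_config()] applied to every trace, or `NULL`.
#' @param pad_to_ps,f_lo,f_hi,anchor_band See
#'   [extract_optical_constants()].
#' @return Object of class `thz_features`: per averaging level, a list
#'   with matrices `alpha` and `n` (records x band points), integer
#'   `label` (1-based class index), `tablet`, plus `f` (band),
#'   `class_names`.
#' @export
extract_feature_records <- function(campaign, denoise = denoise_config(),
                                    pad_to_ps = 100, f_lo = 0.1, f_hi = 2.5,
                                    anchor_band = c(0.3, 1.0)) {
  stopifnot(inherits(campaign, "thz_campaign"))
  class_names <- vapply(campaign$library, `[[`, character(1), "name")
  d_by_class <- vapply(campaign$library, `[[`, numeric(1), "thickness_d")
  ref <- campaign$reference
  if (!is.null(denoise)) ref <- wavelet_denoise(ref, denoise)
  groups <- list()
  f_band <- NULL
  for (a in names(campaign$records)) {
    recs <- campaign$records[[a]]
    alpha <- NULL; nmat <- NULL
    label <- integer(length(recs)); tablet <- integer(length(recs))
    for (i in seq_along(recs)) {
      tr <- recs[[i]]
      if (!is.null(denoise)) tr <- wavelet_denoise(tr, denoise)
      ci <- match(tr$label, class_names)
      if (is.na(ci)) stop("record label not in campaign library: ", tr$label)
      oc <- extract_optical_constants(tr, ref, d = d_by_class[ci],
                                      pad_to_ps = pad_to_ps, denoise = NULL,
                                      f_lo = f_lo, f_hi = f_hi,
                                      anchor_band = anchor_band)
      if (is.null(alpha)) {
        f_band <- oc$f
        alpha <- matrix(0, length(recs), length(oc$f))
        nmat <- matrix(0, length(recs), length(oc$f))
      }
      alpha[i, ] <- oc$alpha
      nmat[i, ] <- oc$n
      label[i] <- ci
      tablet[i] <- tr$tablet_id
    }
    groups[[a]] <- list(alpha = alpha, n = nmat, label = label,
                        tablet = tablet)
  }
  structure(list(groups = groups, f = f_band, class_names = class_names,
                 thickness_d = unname(d_by_class)),
            class = "thz_features")
}

#' Assemble train/validation/test datasets
#'
#' Splits the highest-averaging (cleanest) group - by convention the
#' avg-100 records - into training and validation sets with a
#' deterministic per-class shuffle, and exposes the noisier averaging
#' groups as held-out test sets.  Per-metric-column standardization
#' statistics (one mean and sd for the absorption column, one pair for
#' the refractive column) are computed on the training split only and
#' applied to every split, so the two metrics reach the network on
#' comparable scales without information leakage.
#'
#' @param features A `thz_features` from [extract_feature_records()].
#' @param input_mode `"hybrid"` (alpha and n, 2 channels),
#'   `"absorption"` or `"refractive"` (1 channel) - the ablation axis.
#' @param val_frac Fraction of the training group held out for
#'   validation (per class).
#' @param seed Shuffle seed.
#' @param train_group Name of the averaging group used for train/val
#'   (default: the largest averaging count present).
#' @param standardize Standardize inputs with training statistics.
#' @return List of class `thz_datasets` with elements `train`, `val`,
#'   and one `test<avg>` per remaining group; each split is a list with
#'   `x` (items x band x channels array), `y` (1-based labels),
#'   `split_tag`; plus `class_names` and the standardization `stats`.
#' @export
assemble_datasets <- function(features, input_mode = c("hybrid", "absorption",
                                                       "refractive"),
                              val_frac = 0.2, seed = 1, train_group = NULL,
                              standardize = TRUE) {
  stopifnot(inherits(features, "thz_features"))
  input_mode <- match.arg(input_mode)
  groups <- features$groups
  if (is.null(train_group))
    train_group <- names(groups)[which.max(as.numeric(names(groups)))]
  if (!train_group %in% names(groups))
    stop("averaging group ", train_group, " missing from features")

  to_x <- function(g) {
    switch(input_mode,
           hybrid = {
             x <- array(0, c(nrow(g$alpha), ncol(g$alpha), 2))
             x[, , 1] <- g$alpha; x[, , 2] <- g$n; x
           },
           absorption = array(g$alpha, c(dim(g$alpha), 1)),
           refractive = array(g$n, c(dim(g$n), 1)))
  }

  tg <- groups[[train_group]]
  set.seed(seed)
  val_idx <- integer(0)
  for (ci in sort(unique(tg$label))) {
    members <- which(tg$label == ci)
    n_val <- round(val_frac * length(members))
    val_idx <- c(val_idx, sample(members, n_val))
  }
  train_idx <- setdiff(seq_along(tg$label), val_idx)

  x_all <- to_x(tg)
  x_train <- x_all[train_idx, , , drop = FALSE]
  # one mean/sd per metric column (absorption, refractive), training only
  st <- list(mean = apply(x_train, 3, mean),
             sd = apply(x_train, 3, stats::sd))
  st$sd[st$sd == 0] <- 1
  apply_st <- function(x) {
    if (!standardize) return(x)
    for (ch in seq_len(dim(x)[3]))
      x[, , ch] <- (x[, , ch] - st$mean[ch]) / st$sd[ch]
    x
  }

  out <- list(
    train = list(x = apply_st(x_train), y = tg$label[train_idx],
                 tablet = tg$tablet[train_idx], split_tag = "train"),
    val = list(x = apply_st(x_all[val_idx, , , drop = FALSE]),
               y = tg$label[val_idx], tablet = tg$tablet[val_idx],
               split_tag = "val")
  )
  for (a in setdiff(names(groups), train_group)) {
    g <- groups[[a]]
    out[[paste0("test", a)]] <- list(x = apply_st(to_x(g)), y = g$label,
                                     tablet = g$tablet,
                                     split_tag = paste0("test", a))
  }
  out$class_names <- features$class_names
  out$stats <- if (standardize) st else NULL
  out$input_mode <- input_mode
  out$seed <- seed
  structure(out, class = "thz_datasets")
}

#' First principal component scores of a set of spectra
#'
#' Items (hybrid N x 2 matrices or 1-D spectra) are flattened row-major
#' (frequency-major), mean-centered, and projected on the leading
#' eigenvector of the sample covariance.  The sign is fixed by making
#' the largest-magnitude loading positive.
#'
#' @param spectra List of `thz_hybrid` objects, matrices, or numeric
#'   vectors (all of one shape).
#' @param n_components Number of leading components to return.
#' @return Matrix of scores (items x n_components).
#' @export
first_principal_component <- function(spectra, n_components = 1) {
  if (length(spectra) < 2) stop("need at least 2 items for PCA")
  rows <- lapply(spectra, function(s) {
    if (inherits(s, "thz_hybrid")) s <- s$matrix
    if (is.matrix(s)) as.vector(t(s)) else as.numeric(s)
  })
  X <- do.call(rbind, rows)
  if (all(apply(X, 2, stats::sd) == 0)) stop("rank-0 data: all items equal")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load_j <- pc$rotation[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}
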