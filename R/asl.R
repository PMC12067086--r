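#' Inversion-recovery signal model
#'
#' Non-selective control signal at inversion time `TI`,
#' `M_C(TI) = M0 (1 - 2^(-TI/T1))`. This is the model the multi-TI data are
#' fit to, written with a base-2 exponential; the same form is used by the
#' forward simulator so that fitting is the exact inverse of simulation.
#'
#' @param M0 equilibrium magnetization (array or scalar).
#' @param T1_ms longitudinal relaxation time in ms.
#' @param TI_ms inversion time in ms.
#' @return signal on the scale of `M0`.
#' @export
ir_signal <- function(M0, T1_ms, TI_ms) {
  M0 * (1 - 2^(-TI_ms / T1_ms))
}

# perfusion-weighted difference implied by the kinetic model at a given RBF
# (ml/min/100 g); inverse of rbf_from_dm
dm_from_rbf <- function(rbf, M0, T1_ms, TI_ms, lambda_partition) {
  rbf / 6e6 * (2 * M0 * TI_ms * exp(-TI_ms / T1_ms)) / lambda_partition
}

rbf_from_dm <- function(dM, M0, T1_ms, TI_ms, lambda_partition) {
  lambda_partition * dM / (2 * M0 * TI_ms * exp(-TI_ms / T1_ms)) * 6e6
}

#' Fit the inversion-recovery model voxel-wise
#'
#' Nonlinear least-squares fit of [ir_signal()] to a multi-TI series,
#' per voxel, with bounded parameters (`T1` in \[100, 5000\] ms, `M0 > 0`)
#' and a deterministic initializer: `M0` starts at the largest observed
#' signal and `T1` at 1.44 times the TI whose signal is nearest zero
#' (the null-point heuristic), clamped to the bounds.
#'
#' @param multiTI_signals array whose last dimension indexes TI, or a
#'   voxels-by-TI matrix, or an `asl_series`.
#' @param TI_list_ms inversion times (ms), length matching the last
#'   dimension; taken from the series when one is supplied.
#' @return list with arrays `M0`, `T1_ms` and logical `converged` (voxels
#'   that failed to converge are `NA` and flagged).
#' @export
fit_inversion_recovery <- function(multiTI_signals, TI_list_ms = NULL) {
  if (inherits(multiTI_signals, "asl_series")) {
    if (is.null(TI_list_ms)) TI_list_ms <- multiTI_signals$TI_list_ms
    multiTI_signals <- multiTI_signals$multiTI_signals
  }
  x <- as.array(multiTI_signals)
  nd <- length(dim(x))
  if (nd < 2) stop("multiTI_signals must have a trailing TI dimension")
  nTI <- dim(x)[nd]
  if (length(TI_list_ms) != nTI)
    stop("TI_list_ms length must match the trailing dimension")
  if (nTI < 3) stop("at least 3 TI points are required")
  if (any(!is.finite(x))) stop("signals must be finite")
  vshape <- dim(x)[-nd]
  nvox <- prod(vshape)
  sig <- matrix(x, nrow = nvox, ncol = nTI)
  TI <- as.numeric(TI_list_ms)

  M0_hat <- rep(NA_real_, nvox)
  T1_hat <- rep(NA_real_, nvox)
  conv <- rep(FALSE, nvox)
  lower <- c(M0 = 1e-9, T1 = 100)
  upper <- c(M0 = Inf, T1 = 5000)
  for (v in seq_len(nvox)) {
    y <- sig[v, ]
    m0_init <- max(y)
    if (m0_init <= 0) next
    t1_init <- min(max(1.44 * TI[which.min(abs(y))], lower["T1"]),
                   upper["T1"])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ ir_signal(M0, T1, TI),
                        data = list(y = y, TI = TI),
                        start = list(M0 = m0_init, T1 = t1_init),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- coef(fit)
      M0_hat[v] <- p[["M0"]]
      T1_hat[v] <- p[["T1"]]
      conv[v] <- TRUE
    }
  }
  if (length(vshape) > 1) {
    M0_hat <- array(M0_hat, dim = vshape)
    T1_hat <- array(T1_hat, dim = vshape)
    conv <- array(conv, dim = vshape)
  }
  list(M0 = M0_hat, T1_ms = T1_hat, converged = conv)
}

#' Perfusion-weighted signal from control/label repeats
#'
#' Averages the repeats and subtracts the mean non-selective (control)
#' signal from the mean slice-selective (label) signal, per voxel.
#'
#' @param control_repeats,label_repeats arrays whose last dimension indexes
#'   repeats (equal counts), or an `asl_series` as the first argument.
#' @return per-voxel dM array.
#' @export
perfusion_weighted_signal <- function(control_repeats, label_repeats = NULL) {
  if (inherits(control_repeats, "asl_series")) {
    label_repeats <- control_repeats$label_repeats
    control_repeats <- control_repeats$control_repeats
  }
  ctl <- as.array(control_repeats); lab <- as.array(label_repeats)
  if (!identical(dim(ctl), dim(lab)))
    stop("control and label series must have identical shape (equal repeats)")
  nd <- length(dim(ctl))
  nrep <- dim(ctl)[nd]
  vshape <- dim(ctl)[-nd]
  cm <- rowMeans(matrix(ctl, ncol = nrep))
  lm_ <- rowMeans(matrix(lab, ncol = nrep))
  dm <- lm_ - cm
  if (length(vshape) > 1) dm <- array(dm, dim = vshape)
  dm
}

#' Quantify renal blood flow from the perfusion-weighted signal
#'
#' Single-TI FAIR kinetic model:
#' `RBF = lambda * dM / (2 * M0 * TI * exp(-TI/T1))`, converted from
#' 1/ms * ml/g to ml/min/100 g (factor 6e6). Voxels with nonpositive or
#' non-finite `M0`/`T1` are masked out and counted.
#'
#' @param dM perfusion-weighted signal (array).
#' @param M0,T1_ms voxel-wise fits from [fit_inversion_recovery()].
#' @param TI_label_ms labelling inversion time (ms); 2000 ms by default.
#' @param lambda_partition blood-tissue partition coefficient (ml/g).
#' @return an `rbf_map`: list with `rbf` (ml/min/100 g, NA where masked),
#'   `M0`, `T1_ms`, `dM`, `lambda_partition`, `TI_label_ms`, `n_masked`.
#' @export
rbf_map <- function(dM, M0, T1_ms, TI_label_ms = 2000,
                    lambda_partition = 0.9) {
  dM <- as.array(dM); M0 <- as.array(M0); T1 <- as.array(T1_ms)
  if (!identical(dim(dM), dim(M0)) || !identical(dim(dM), dim(T1)))
    stop("dM, M0 and T1 must share a shape")
  bad <- !is.finite(M0) | !is.finite(T1) | M0 <= 0 | T1 <= 0 | !is.finite(dM)
  rbf <- rbf_from_dm(dM, M0, T1, TI_label_ms, lambda_partition)
  rbf[bad] <- NA_real_
  structure(list(rbf = rbf, M0 = M0, T1_ms = T1, dM = dM,
                 lambda_partition = lambda_partition,
                 TI_label_ms = TI_label_ms,
                 n_masked = sum(bad)),
            class = "rbf_map")
}

#' Summarize an RBF map over regions of interest
#'
#' @param rbf an `rbf_map` (or plain array of RBF values).
#' @param roi_masks named list of logical arrays (e.g. `cortex`, `medulla`,
#'   `cortex_cyst_free`), each aligned to the map.
#' @return data.frame with one row per ROI: mean, sd, n_voxels (valid),
#'   n_excluded (masked voxels inside the ROI).
#' @export
roi_summary <- function(rbf, roi_masks) {
  vals <- if (inherits(rbf, "rbf_map")) rbf$rbf else as.array(rbf)
  if (is.null(names(roi_masks)) || any(names(roi_masks) == ""))
    stop("roi_masks must be a named list")
  rows <- lapply(names(roi_masks), function(nm) {
    m <- as.array(roi_masks[[nm]])
    if (!identical(dim(m), dim(vals)))
      stop("ROI '", nm, "' shape does not match the map")
    v <- vals[as.logical(m)]
    if (length(v) == 0) stop("ROI '", nm, "' is empty")
    ok <- is.finite(v)
    if (!any(ok)) stop("ROI '", nm, "' contains no valid voxels")
    data.frame(roi = nm, mean = mean(v[ok]), sd = sd(v[ok]),
               n_voxels = sum(ok), n_excluded = sum(!ok))
  })
  do.call(rbind, rows)
}
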