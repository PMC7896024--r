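conformation_origin_list <- function(x) {
  if (inherits(x, "fiber_conformation")) return(list(x$origins))
  if (inherits(x, "ensemble")) {
    idx <- post_burnin(x)
    return(lapply(idx, function(i) ensemble_snapshot(x, i)$origins))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fiber_conformation")))
    return(lapply(x, function(f) f$origins))
  if (is.matrix(x)) return(list(x))
  stop("x must be a fiber_conformation, a list of them, an ensemble, or an origin matrix")
}

#' Fragment-length distribution of correlated DNA breaks
#'
#' For each fragment length n (in nt, taken equal to the bp separation along
#' the chain) the mean break-correlation weight over all bp pairs (i, i+n)
#' is computed, with weight `exp(-d / lambda)` in the three-dimensional
#' distance d between the bp origins. The exponential drop constant
#' defaults to 4.0 nm, the value describing radiation-induced correlated
#' break frequencies. For an ensemble the profile is the mean of the
#' post-burn-in per-snapshot profiles (the statistic is linear, so this
#' equals pooling all pairs).
#'
#' Fragment lengths exceeding the chain length are undefined and reported
#' absent rather than zero.
#'
#' @param x a `fiber_conformation`, a list of conformations, an `ensemble`,
#'   or an n x 3 origin matrix.
#' @param lambda_nm exponential drop constant, nm.
#' @param range integer fragment-length window `(n_min, n_max)`, nt.
#' @return An object of class `fld_profile`: a data.frame with columns
#'   `n_nt` and `value`, with attributes `lambda_nm` and `range`.
#' @export
fld_profile <- function(x, lambda_nm = 4.0, range = c(250, 400)) {
  if (lambda_nm <= 0) stop("lambda_nm must be positive")
  range <- as.integer(range)
  if (length(range) != 2 || range[1] > range[2] || range[1] < 1)
    stop("range must be an increasing positive integer pair")
  olist <- conformation_origin_list(x)
  N <- nrow(olist[[1]])
  if (!all(vapply(olist, nrow, integer(1)) == N))
    stop("all conformations must share the same bp count")
  acc <- NULL
  for (o in olist) {
    v <- cpp_fld(o, lambda_nm, range[1], range[2])
    acc <- if (is.null(acc)) v else acc + v
  }
  v <- acc / length(olist)
  n_nt <- seq(range[1], range[2])
  keep <- !is.na(v)
  out <- data.frame(n_nt = n_nt[keep], value = v[keep])
  attr(out, "lambda_nm") <- lambda_nm
  attr(out, "range") <- range
  class(out) <- c("fld_profile", "data.frame")
  out
}

#' Detect peaks in an FLD profile
#'
#' The profile is smoothed by a centered moving average (5 nt by default),
#' then local maxima with prominence at least `min_prominence` of the
#' smoothed profile's dynamic range are reported, sorted by position.
#'
#' @param profile an `fld_profile` (or data.frame with `n_nt`, `value`).
#' @param min_prominence prominence threshold as a fraction of the dynamic
#'   range.
#' @param window smoothing window, nt (odd).
#' @return A data.frame with `position` (nt), `height`, `prominence`;
#'   zero rows when the profile is empty or has no qualifying maxima.
#' @export
detect_peaks <- function(profile, min_prominence = 0.05, window = 5) {
  if (NROW(profile) == 0)
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  n <- profile$n_nt
  if (any(diff(n) != 1))
    stop("profile must be defined on a contiguous range")
  y <- profile$value
  k <- max(1L, as.integer(window))
  if (k %% 2 == 0) k <- k + 1L
  if (length(y) >= k) {
    sm <- stats::filter(y, rep(1 / k, k), sides = 2)
    half <- (k - 1L) / 2L
    # shrink the window near the edges instead of dropping them
    for (i in seq_len(half)) {
      sm[i] <- mean(y[1:(i + half)])
      j <- length(y) - i + 1L
      sm[j] <- mean(y[(j - half):length(y)])
    }
    y <- as.numeric(sm)
  }
  rng <- diff(range(y))
  if (rng <= 0) {
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  m <- length(y)
  peaks <- which(diff(sign(diff(y))) < 0) + 1L
  rows <- lapply(peaks, function(p) {
    h <- y[p]
    # prominence: lowest descent before re-ascending above the peak
    left_min <- h
    for (i in rev(seq_len(p - 1))) {
      if (y[i] > h) break
      left_min <- min(left_min, y[i])
      if (i == 1) left_min <- min(left_min, y[1])
    }
    right_min <- h
    for (i in seq(p + 1, m)) {
      if (y[i] > h) break
      right_min <- min(right_min, y[i])
    }
    prom <- h - max(left_min, right_min)
    data.frame(position = n[p], height = h, prominence = prom)
  })
  if (length(rows) == 0)
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[out$prominence >= min_prominence * rng, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}

centers_axes_list <- function(x) {
  if (inherits(x, "fiber_conformation"))
    return(list(list(centers = x$centers, axes = x$core_axes)))
  if (inherits(x, "ensemble")) {
    idx <- post_burnin(x)
    return(lapply(idx, function(i)
      list(centers = snapshot_centers(x, i), axes = snapshot_axes(x, i))))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fiber_conformation")))
    return(lapply(x, function(f) list(centers = f$centers, axes = f$core_axes)))
  stop("x must be a fiber_conformation, a list of them, or an ensemble")
}

stacked_matrix <- function(centers, axes, params) {
  n <- nrow(centers)
  d <- as.matrix(stats::dist(centers))
  cosang <- abs(tcrossprod(axes))
  within <- d <= params$stacking_distance + 3 * params$stacking_width
  # pairs below the minimum stacking separation are face-occluded
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  within[sep < (params$stack_min_sep %||% 2L)] <- FALSE
  within & cosang > 0.7
}

local_axis_radii <- function(centers, window = 5) {
  n <- nrow(centers)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    if (hi - lo + 1 < 3) {
      lo <- max(1, min(lo, n - 2))
      hi <- min(n, max(hi, 3))
    }
    w <- centers[lo:hi, , drop = FALSE]
    mu <- colMeans(w)
    sv <- svd(sweep(w, 2, mu))
    ax <- sv$v[, 1]
    rel <- centers[i, ] - mu
    perp <- rel - sum(rel * ax) * ax
    sqrt(sum(perp^2))
  }, numeric(1))
}

#' Classify internucleosome contacts
#'
#' Pairs of cores closer than `cutoff` (default 11 nm, one core diameter)
#' are close contacts, binned by neighbor offset |i - j| into 1, 2, 3 and
#' 4+. A nucleosome is stacked when it has a partner within the stacking
#' well cutoff with superhelical axes aligned to |cos(theta)| > 0.7; it is
#' flipped out when its center lies more than 1.5 times the fiber-axis
#' radius from the local fiber axis (a line fit through a 5-nucleosome
#' sliding window of core centers).
#'
#' @param x a `fiber_conformation`, list of conformations, or `ensemble`
#'   (post-burn-in snapshots); needs >= 4 nucleosomes.
#' @param cutoff close-contact distance, nm.
#' @param params an [energy_params()] object (stacking criterion).
#' @return An object of class `contact_stats`: close-contact `counts` by
#'   offset, `stacking_fraction`, `flipout_rate`, `n_snapshots`.
#' @export
classify_contacts <- function(x, cutoff = 11, params = energy_params()) {
  snaps <- centers_axes_list(x)
  n <- nrow(snaps[[1]]$centers)
  counts <- c(k1 = 0, k2 = 0, k3 = 0, k4plus = 0)
  stackfrac <- numeric(length(snaps))
  flips <- 0L
  npos <- 0L
  for (s in seq_along(snaps)) {
    cen <- snaps[[s]]$centers
    ax <- snaps[[s]]$axes
    if (n >= 2) {
      d <- as.matrix(stats::dist(cen))
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        if (d[i, j] < cutoff) {
          k <- j - i
          bin <- if (k >= 4) "k4plus" else paste0("k", k)
          counts[bin] <- counts[bin] + 1
        }
      }
      st <- stacked_matrix(cen, ax, params)
      stackfrac[s] <- mean(rowSums(st) > 0)
    }
    if (n >= 4) {
      r <- local_axis_radii(cen)
      fr <- stats::median(r)
      if (fr > 1e-9) flips <- flips + sum(r > 1.5 * fr)
      npos <- npos + n
    }
  }
  structure(list(counts = counts,
                 stacking_fraction = mean(stackfrac),
                 flipout_rate = if (npos > 0) flips / npos else 0,
                 n_snapshots = length(snaps),
                 n_nucleosomes = n,
                 cutoff = cutoff),
            class = "contact_stats")
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf("contacts (<%g nm) over %d snapshot(s) of %d nucleosomes:\n",
              x$cutoff, x$n_snapshots, x$n_nucleosomes))
  cat(sprintf("  offsets 1/2/3/4+: %d/%d/%d/%d\n",
              x$counts["k1"], x$counts["k2"], x$counts["k3"], x$counts["k4plus"]))
  cat(sprintf("  stacking fraction %.3f, flip-out rate %.4f\n",
              x$stacking_fraction, x$flipout_rate))
  invisible(x)
}

#' Fraction of stacked nucleosomes
#'
#' Mean over snapshots of the fraction of nucleosomes engaged in at least
#' one face-to-face stacking contact (within the stacking well cutoff and
#' with axes aligned beyond |cos(theta)| = 0.7). In thermal ensembles this
#' fraction separates the two fiber families: T2 arrays stay about twice as
#' stacked as T1 arrays at 1 kT.
#'
#' @param x a `fiber_conformation`, list of conformations, or `ensemble`
#'   (post-burn-in).
#' @param params an [energy_params()] object; for an `ensemble` the
#'   parameters it was sampled with are the default.
#' @return A fraction in `[0, 1]`.
#' @export
stacking_fraction <- function(x, params = NULL) {
  if (is.null(params))
    params <- if (inherits(x, "ensemble")) x$energy_params else energy_params()
  snaps <- centers_axes_list(x)
  mean(vapply(snaps, function(s)
    mean(rowSums(stacked_matrix(s$centers, s$axes, params)) > 0), numeric(1)))
}

#' Kirkwood sedimentation coefficient
#'
#' Double-sum bead approximation over core centers:
#' `s / s_mono = 1 + (2 R_eff / n) * sum_{i<j} 1 / d_ij`. More compact
#' arrays sediment faster; the coefficient is monotone under uniform
#' compression and equals `s_mono` for a mononucleosome.
#'
#' @param x a `fiber_conformation`, list of conformations, or `ensemble`
#'   (post-burn-in snapshots).
#' @param s_mono mononucleosome coefficient, Svedberg.
#' @param R_eff effective bead radius, nm.
#' @return An object of class `sedimentation_result`: ensemble mean `s20w`,
#'   `sd`, and `per_snapshot` values.
#' @export
sedimentation <- function(x, s_mono = 11.1, R_eff = 5.5) {
  snaps <- centers_axes_list(x)
  vals <- vapply(snaps, function(s) {
    cen <- s$centers
    n <- nrow(cen)
    if (n == 1) return(s_mono)
    d <- stats::dist(cen)
    if (any(d < 1e-9)) stop("degenerate: coincident core centers")
    s_mono * (1 + (2 * R_eff / n) * sum(1 / d))
  }, numeric(1))
  structure(list(s20w = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
                 per_snapshot = vals, s_mono = s_mono, R_eff = R_eff),
            class = "sedimentation_result")
}

#' @export
print.sedimentation_result <- function(x, ...) {
  cat(sprintf("s20,w = %.2f S (sd %.2f, %d snapshot(s); s_mono = %.1f S)\n",
              x$s20w, x$sd, length(x$per_snapshot), x$s_mono))
  invisible(x)
}
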