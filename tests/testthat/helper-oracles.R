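# Independent oracles used across the suite.

# quaternion composition: q = (w, x, y, z)
quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] +
      c(a[3] * b[4] - a[4] * b[3],
        a[4] * b[2] - a[2] * b[4],
        a[2] * b[3] - a[3] * b[2]))
}
quat_axis_angle <- function(axis, angle) {
  c(cos(angle / 2), sin(angle / 2) * axis / sqrt(sum(axis^2)))
}
# net rotation angle of Rz(a) Ry(g) Rz(b), composed with quaternions
quat_net_angle <- function(a, g, b) {
  q <- quat_mul(quat_axis_angle(c(0, 0, 1), a),
                quat_mul(quat_axis_angle(c(0, 1, 0), g),
                         quat_axis_angle(c(0, 0, 1), b)))
  2 * acos(min(1, abs(q[1])))
}

rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# smooth random closed curve from a low-order Fourier series
fourier_closed_curve <- function(n = 300, n_modes = 3, amp = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  base <- cbind(cos(t), sin(t), 0 * t)
  for (m in 2:n_modes) {
    coefs <- matrix(rnorm(6, 0, amp / m), 2, 3)
    base <- base + outer(cos(m * t), coefs[1, ]) + outer(sin(m * t), coefs[2, ])
  }
  10 * base
}

# carry a framing through a deformation: rotate each x axis by the minimal
# rotation taking the old vertex tangent onto the new one (a material frame,
# so the ribbon deforms without slipping and its linking number is conserved)
carry_framing <- function(old, new_vertices) {
  n <- nrow(old$origins)
  vt <- function(v) {
    tang <- v[c(2:n, 1), ] - v
    tang <- tang / sqrt(rowSums(tang^2))
    zt <- tang + tang[c(n, 1:(n - 1)), ]
    zt / sqrt(rowSums(zt^2))
  }
  z_old <- vt(old$origins)
  z_new <- vt(new_vertices)
  axes <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    x <- old$axes[k, 1:3]
    z0 <- z_old[k, ]
    z1 <- z_new[k, ]
    cr <- c(z0[2] * z1[3] - z0[3] * z1[2],
            z0[3] * z1[1] - z0[1] * z1[3],
            z0[1] * z1[2] - z0[2] * z1[1])
    s <- sqrt(sum(cr^2))
    if (s > 1e-14) {
      ax <- cr / s
      ang <- atan2(s, sum(z0 * z1))
      x <- x * cos(ang) +
        c(ax[2] * x[3] - ax[3] * x[2],
          ax[3] * x[1] - ax[1] * x[3],
          ax[1] * x[2] - ax[2] * x[1]) * sin(ang) +
        ax * sum(ax * x) * (1 - cos(ang))
    }
    x <- x - sum(x * z1) * z1
    x <- x / sqrt(sum(x^2))
    y <- c(z1[2] * x[3] - z1[3] * x[2],
           z1[3] * x[1] - z1[1] * x[3],
           z1[1] * x[2] - z1[2] * x[1])
    axes[k, ] <- c(x, y, z1)
  }
  list(origins = new_vertices, axes = axes)
}

# small optimal fibers are reused across observable tests; memoize per session
optimal_cache <- new.env(parent = emptyenv())
cached_optimum <- function(L, L_NCP, family = "auto", starts = 6, seed = 7) {
  key <- paste(L, L_NCP, family, starts, seed, sep = "_")
  if (!is.null(optimal_cache[[key]])) return(optimal_cache[[key]])
  res <- optimize_regular_fiber(
    fiber_spec(L = L, L_NCP = L_NCP, n_nucleosomes = 8, family_hint = family),
    starts = starts, seed = seed)
  optimal_cache[[key]] <- res
  res
}
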