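#' Build a nucleosome core particle template
#'
#' Places `L_NCP` base-pair frames on a left-handed superhelix, the
#' coarse-grained geometry of DNA wrapped around the histone octamer. The
#' default radius (4.18 nm), pitch (2.39 nm per turn) and wrap (1.65 turns
#' over 147 bp, 1.64 over 146 bp) follow the crystallographic core-particle
#' geometry. Frames are parallel-transported along the superhelix with an
#' imposed twist of 34.3 degrees per step, so the wrapped DNA is torsionally
#' relaxed and the core's whole topological contribution is writhe.
#'
#' The template is expressed in entry-frame coordinates: `bp_path[1]` is the
#' identity frame at the origin, which makes rigid placement during fiber
#' assembly a single frame composition.
#'
#' @param L_NCP core DNA length in bp; 146 (the "601" positioning sequence)
#'   or 147 (generic).
#' @param wrap_turns superhelical wrap in turns, restricted to `[1.5, 1.8]`.
#'   Defaults to 1.65 for 147 bp and 1.64 for 146 bp.
#' @param radius superhelix radius, nm.
#' @param pitch superhelix pitch per turn, nm.
#' @param handedness must be `"left"`; a right-handed wrap violates
#'   nucleosome chirality and is rejected.
#' @param index nucleosome index carried by the template (>= 0).
#' @return An object of class `nucleosome_core`.
#' @examples
#' core <- build_core(147)
#' @export
build_core <- function(L_NCP = 147, wrap_turns = NULL, radius = 4.18,
                       pitch = 2.39, handedness = c("left", "right"),
                       index = 0L) {
  handedness <- match.arg(handedness)
  if (handedness == "right")
    stop("right-handed wrapping rejected: the nucleosomal superhelix is left-handed")
  if (!L_NCP %in% c(146L, 147L)) stop("L_NCP must be 146 or 147 bp")
  if (is.null(wrap_turns)) wrap_turns <- if (L_NCP == 147) 1.65 else 1.64
  if (wrap_turns < 1.5 || wrap_turns > 1.8)
    stop("wrap_turns must lie in [1.5, 1.8]")
  if (radius <= 0 || pitch <= 0) stop("radius and pitch must be positive")

  n <- as.integer(L_NCP)
  t <- seq(0, 2 * pi * wrap_turns, length.out = n)
  # left-handed: z decreases as the xy angle advances counterclockwise
  origins <- cbind(radius * cos(t), radius * sin(t), -pitch * t / (2 * pi))
  tangents <- cbind(-radius * sin(t), radius * cos(t), rep(-pitch / (2 * pi), n))
  tangents <- tangents / sqrt(rowSums(tangents^2))

  # initial short axis: radially outward, orthogonalized against the tangent
  x0 <- c(1, 0, 0)
  x0 <- x0 - sum(x0 * tangents[1, ]) * tangents[1, ]
  x0 <- x0 / sqrt(sum(x0^2))

  axes <- matrix(0, n, 9)
  xk <- x0
  tw_step <- 34.3 * pi / 180
  for (k in seq_len(n)) {
    zk <- tangents[k, ]
    if (k > 1) {
      zprev <- tangents[k - 1, ]
      cr <- c(zprev[2] * zk[3] - zprev[3] * zk[2],
              zprev[3] * zk[1] - zprev[1] * zk[3],
              zprev[1] * zk[2] - zprev[2] * zk[1])
      s <- sqrt(sum(cr^2))
      if (s > 1e-14) {
        ax <- cr / s
        ang <- atan2(s, sum(zprev * zk))
        xk <- xk * cos(ang) +
          c(ax[2] * xk[3] - ax[3] * xk[2],
            ax[3] * xk[1] - ax[1] * xk[3],
            ax[1] * xk[2] - ax[2] * xk[1]) * sin(ang) +
          ax * sum(ax * xk) * (1 - cos(ang))
      }
      # imposed relaxed twist about the new tangent
      xk <- xk * cos(tw_step) +
        c(zk[2] * xk[3] - zk[3] * xk[2],
          zk[3] * xk[1] - zk[1] * xk[3],
          zk[1] * xk[2] - zk[2] * xk[1]) * sin(tw_step) +
        zk * sum(zk * xk) * (1 - cos(tw_step))
      xk <- xk - sum(xk * zk) * zk
      xk <- xk / sqrt(sum(xk^2))
    }
    yk <- c(zk[2] * xk[3] - zk[3] * xk[2],
            zk[3] * xk[1] - zk[1] * xk[3],
            zk[1] * xk[2] - zk[2] * xk[1])
    axes[k, ] <- c(xk, yk, zk)
  }

  # re-express in entry-frame coordinates
  E <- matrix(axes[1, ], 3, 3)
  o0 <- origins[1, ]
  loc_o <- t(crossprod(E, t(origins) - o0))
  loc_a <- matrix(0, n, 9)
  for (k in seq_len(n)) loc_a[k, ] <- as.numeric(crossprod(E, matrix(axes[k, ], 3, 3)))

  center <- as.numeric(crossprod(E, c(0, 0, (origins[1, 3] + origins[n, 3]) / 2) - o0))
  shaxis <- as.numeric(crossprod(E, c(0, 0, 1)))

  structure(list(
    index = as.integer(index),
    bp_origins = loc_o,
    bp_axes = loc_a,
    entry_frame = bp_frame(loc_o[1, ], matrix(loc_a[1, ], 3, 3)),
    exit_frame = bp_frame(loc_o[n, ], matrix(loc_a[n, ], 3, 3)),
    center = center,
    superhelical_axis = shaxis,
    entry_point = loc_o[1, ],
    exit_point = loc_o[n, ],
    L_NCP = n,
    wrap_turns = wrap_turns,
    radius = radius,
    pitch = pitch
  ), class = "nucleosome_core")
}

#' @export
print.nucleosome_core <- function(x, ...) {
  cat(sprintf(
    "nucleosome core: %d bp, %.2f left-handed turns (radius %.2f nm, pitch %.2f nm)\n",
    x$L_NCP, x$wrap_turns, x$radius, x$pitch))
  invisible(x)
}

# Assemble the list the compiled kernels expect for a core template.
# Excluded-volume spheres: one at the cylinder center plus a ring of six at
# (core_radius - half_height), all of radius half_height, which lets flat
# faces stack at the stacking distance while blocking lateral interpenetration.
core_cpp_template <- function(core, params, with_bp = TRUE) {
  hh <- params$core_half_height
  rr <- params$core_radius - hh
  ax <- core$superhelical_axis
  ref <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * ax) * ax
  u <- u / sqrt(sum(u^2))
  v <- c(ax[2] * u[3] - ax[3] * u[2],
         ax[3] * u[1] - ax[1] * u[3],
         ax[1] * u[2] - ax[2] * u[1])
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- t(vapply(ang, function(a) core$center + rr * (cos(a) * u + sin(a) * v),
                   numeric(3)))
  spheres <- rbind(core$center, ring)
  out <- list(
    exit_R = core$exit_frame$axes,
    exit_t = core$exit_frame$origin,
    center = core$center,
    axis = core$superhelical_axis,
    spheres = spheres,
    sphere_r = hh,
    l_ncp = core$L_NCP
  )
  if (with_bp) {
    out$bp_origins <- core$bp_origins
    out$bp_axes <- core$bp_axes
  }
  out
}
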