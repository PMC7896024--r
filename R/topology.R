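#' Closed curve
#'
#' Ordered vertices in nm with an implicit edge from the last vertex back to
#' the first; the discretization carrier for the Gauss double integral.
#'
#' @param vertices n x 3 numeric matrix, n >= 3, consecutive vertices
#'   distinct.
#' @return An object of class `closed_curve` (an n x 3 matrix).
#' @export
closed_curve <- function(vertices) {
  v <- as.matrix(vertices)
  if (ncol(v) != 3 || nrow(v) < 3) stop("need an n x 3 matrix with n >= 3")
  if (!all(is.finite(v))) stop("non-finite vertices")
  d <- sqrt(rowSums((v - v[c(2:nrow(v), 1), ])^2))
  if (any(d < 1e-12)) stop("consecutive vertices must be distinct")
  class(v) <- c("closed_curve", "matrix")
  v
}

#' Total twist from step parameters
#'
#' `Tw` is the summed step twist in turns; `dTw` is the excess over the same
#' number of steps at the relaxed B-DNA twist of 34.3 degrees.
#'
#' @param steps steps in any form accepted by [as_step_matrix()].
#' @param L_reference number of relaxed steps defining the reference twist;
#'   defaults to the number of steps supplied.
#' @return A list with `Tw` and `dTw`, both in turns.
#' @examples
#' twist_of(matrix(rep(c(0, 0, 36, 0, 0, 0.34), 10), ncol = 6, byrow = TRUE))
#' @export
twist_of <- function(steps, L_reference = NULL) {
  m <- as_step_matrix(steps)
  if (nrow(m) == 0) stop("steps must be nonempty")
  if (is.null(L_reference)) L_reference <- nrow(m)
  Tw <- sum(m[, "twist"]) / 360
  list(Tw = Tw, dTw = Tw - L_reference * 34.3 / 360)
}

#' Writhe of a closed curve
#'
#' Discrete Gauss double integral over ordered segment pairs. Two exact
#' per-pair solid-angle formulations are provided: `"gauss_pairs"` (the
#' arcsine form) and `"levitt_le_bret"` (two spherical-triangle solid
#' angles); they agree to well below 0.02 on curves with a few hundred
#' vertices.
#'
#' @param curve a [closed_curve()] or an n x 3 matrix of vertices.
#' @param method which per-pair formula to use.
#' @return The writhe (dimensionless).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' writhe(cbind(cos(th), sin(th), 0))  # planar circle: 0
#' @export
writhe <- function(curve, method = c("gauss_pairs", "levitt_le_bret")) {
  method <- match.arg(method)
  v <- closed_curve(curve)
  r <- cpp_writhe(unclass(v), TRUE, if (method == "gauss_pairs") 1L else 2L)
  if (isTRUE(r$degenerate))
    stop("degenerate curve: coplanar touching or intersecting segments")
  r$wr
}

#' Gauss linking number of two closed curves
#'
#' @param a,b n x 3 vertex matrices of two closed polygons.
#' @return The linking number (near-integer for non-touching curves).
#' @export
linking_number <- function(a, b) {
  cpp_linking(closed_curve(a), closed_curve(b))
}

#' Ribbon twist of a framed chain
#'
#' Exact twist of the material frame about the tangent, computed by
#' parallel-transporting the short axis between successive tangents and
#' summing the residual rotations. This is the `Tw` that pairs with the
#' Gauss-integral writhe in `Lk = Tw + Wr`.
#'
#' @param x a `fiber_conformation`, or a list with `origins` and `axes`
#'   (n x 9 flattened frames).
#' @param closed include the wrap-around step from the last frame to the
#'   first? Defaults to the conformation's own topology.
#' @return Twist in turns.
#' @export
ribbon_twist <- function(x, closed = NULL) {
  if (inherits(x, "fiber_conformation")) {
    if (is.null(closed)) closed <- x$spec$circular
    return(cpp_ribbon_twist(x$axes, isTRUE(closed)))
  }
  if (is.null(closed)) closed <- FALSE
  cpp_ribbon_twist(x$axes, isTRUE(closed))
}

#' Attach a closed framing to a closed curve
#'
#' Builds orthonormal frames along a closed polygon by parallel transport,
#' then distributes a uniform extra winding so the framing closes. Because
#' a closed ribbon has an integer linking number, the achievable ribbon
#' twist is quantized: the result carries `Tw = twist_turns - hol/2pi`,
#' where the holonomy term equals `-Wr mod 1` (Fuller), so that
#' `Lk = Tw + Wr` is the integer nearest `twist_turns + Wr`. For a planar
#' polygon the holonomy vanishes and `Tw = twist_turns` exactly (the
#' relaxed-closed-circle construction). Used for relaxed DNA circles and
#' the topology self-tests.
#'
#' @param vertices n x 3 closed polygon.
#' @param twist_turns requested winding of the framing, turns.
#' @return A list with `origins` and `axes` (n x 9).
#' @export
framed_closed_curve <- function(vertices, twist_turns = 0) {
  v <- closed_curve(vertices)
  n <- nrow(v)
  tang <- v[c(2:n, 1), ] - v
  tang <- tang / sqrt(rowSums(tang^2))
  # vertex tangents: average of incident edges
  zt <- (tang + tang[c(n, 1:(n - 1)), ])
  zt <- zt / sqrt(rowSums(zt^2))
  rot_about <- function(x, ax, ang) {
    x * cos(ang) +
      c(ax[2] * x[3] - ax[3] * x[2],
        ax[3] * x[1] - ax[1] * x[3],
        ax[1] * x[2] - ax[2] * x[1]) * sin(ang) +
      ax * sum(ax * x) * (1 - cos(ang))
  }
  pt <- function(x, z0, z1) {
    cr <- c(z0[2] * z1[3] - z0[3] * z1[2],
            z0[3] * z1[1] - z0[1] * z1[3],
            z0[1] * z1[2] - z0[2] * z1[1])
    s <- sqrt(sum(cr^2))
    if (s < 1e-14) return(x)
    rot_about(x, cr / s, atan2(s, sum(z0 * z1)))
  }
  ref <- if (abs(zt[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  x0 <- ref - sum(ref * zt[1, ]) * zt[1, ]
  x0 <- x0 / sqrt(sum(x0^2))
  # pure parallel transport around the loop to measure the holonomy
  xs <- matrix(0, n, 3)
  xs[1, ] <- x0
  for (k in 2:n) {
    xk <- pt(xs[k - 1, ], zt[k - 1, ], zt[k, ])
    xk <- xk - sum(xk * zt[k, ]) * zt[k, ]
    xs[k, ] <- xk / sqrt(sum(xk^2))
  }
  xback <- pt(xs[n, ], zt[n, ], zt[1, ])
  cr <- c(xback[2] * x0[3] - xback[3] * x0[2],
          xback[3] * x0[1] - xback[1] * x0[3],
          xback[1] * x0[2] - xback[2] * x0[1])
  hol <- atan2(sum(cr * zt[1, ]), sum(xback * x0))
  alpha <- (-hol + 2 * pi * twist_turns) / n
  axes <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    xk <- rot_about(xs[k, ], zt[k, ], alpha * (k - 1))
    xk <- xk - sum(xk * zt[k, ]) * zt[k, ]
    xk <- xk / sqrt(sum(xk^2))
    yk <- c(zt[k, 2] * xk[3] - zt[k, 3] * xk[2],
            zt[k, 3] * xk[1] - zt[k, 1] * xk[3],
            zt[k, 1] * xk[2] - zt[k, 2] * xk[1])
    axes[k, ] <- c(xk, yk, zt[k, ])
  }
  list(origins = unclass(v), axes = axes)
}

#' Mirror vertices through the xy-plane
#'
#' Chirality helper: mirroring flips the sign of writhe and of all
#' downstream linking-number changes.
#'
#' @param v n x 3 vertex matrix.
#' @export
mirror_vertices <- function(v) {
  v <- as.matrix(v)
  v[, 3] <- -v[, 3]
  v
}

#' Close an open fiber with a distant planar return path
#'
#' Completes an open chain into a closed curve the way flanking DNA closes a
#' nucleosome array on a plasmid: both termini are first extended along
#' their local tangents (so the topological contribution of the terminal
#' wraps is not short-circuited), then the extended ends are joined by a
#' smooth half-ellipse far from the fiber body. The return path is planar
#' and carries no frames, hence contributes zero net twist; its apex stands
#' clear of every fiber vertex by at least `clearance_factor` fiber
#' diameters, widened and retried up to five times if needed.
#'
#' @param fiber a `fiber_conformation` (open), or an n x 3 origin matrix of
#'   an open chain.
#' @param clearance_factor minimum apex clearance in units of fiber diameter.
#' @param n_return number of bridge vertices.
#' @return A [closed_curve()]; attribute `n_fiber` gives the number of
#'   leading vertices belonging to the fiber itself.
#' @export
close_fiber <- function(fiber, clearance_factor = 3, n_return = 200) {
  if (inherits(fiber, "fiber_conformation")) {
    if (fiber$spec$circular) stop("fiber is already closed (circular)")
    V <- fiber$origins
  } else {
    V <- as.matrix(fiber)
  }
  n <- nrow(V)
  if (n < 2) stop("need at least two vertices to close")
  a <- V[1, ]; b <- V[n, ]
  ctr <- colMeans(V)
  D <- max(sqrt(rowSums((V - matrix(ctr, n, 3, byrow = TRUE))^2))) * 2
  if (D < 1e-9) stop("degenerate fiber: zero extent")
  unit <- function(v) v / sqrt(sum(v^2))
  t_out <- unit(b - V[n - 1, ])   # leave along the exit tangent
  t_in <- unit(V[2, ] - a)        # return along the entry tangent
  ext <- max(D, 5)
  spacing <- max(ext / 50, 0.5)
  s_out <- seq(spacing, ext, by = spacing)
  ext_out <- outer(s_out, t_out) + matrix(b, length(s_out), 3, byrow = TRUE)
  ext_in <- outer(rev(s_out), -t_in) + matrix(a, length(s_out), 3, byrow = TRUE)
  b2 <- ext_out[nrow(ext_out), ]
  a2 <- ext_in[1, ]
  e <- b2 - a2
  if (sqrt(sum(e^2)) < 1e-9) e <- c(1, 0, 0) else e <- unit(e)
  ref1 <- if (abs(e[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w1 <- unit(ref1 - sum(ref1 * e) * e)
  w2 <- c(e[2] * w1[3] - e[3] * w1[2],
          e[3] * w1[1] - e[1] * w1[3],
          e[1] * w1[2] - e[2] * w1[1])
  cands <- list(w1, -w1, w2, -w2)
  M <- (a2 + b2) / 2
  score <- vapply(cands, function(w) {
    p <- M + D * w
    min(sqrt(rowSums((V - matrix(p, n, 3, byrow = TRUE))^2)))
  }, numeric(1))
  w <- cands[[which.max(score)]]
  H <- clearance_factor * D + D
  for (try in 1:5) {
    th <- seq(0, pi, length.out = n_return + 2)[-c(1, n_return + 2)]
    bridge <- t(vapply(th, function(t_) M + cos(t_) * (b2 - M) + sin(t_) * H * w,
                       numeric(3)))
    apex_clear <- min(sqrt(rowSums(
      (V - matrix(M + H * w, n, 3, byrow = TRUE))^2)))
    if (apex_clear >= clearance_factor * D) {
      out <- closed_curve(rbind(V, ext_out, bridge, ext_in))
      attr(out, "n_fiber") <- n
      return(out)
    }
    H <- H * 1.6
  }
  stop("could not find a non-intersecting closure after 5 retries")
}

topology_result <- function(Tw, dTw, Wr, n_nuc, per_nuc) {
  structure(list(Tw = Tw, dTw = dTw, Wr = Wr, dLk = dTw + Wr,
                 dLk_per_nucleosome = per_nuc, n_nucleosomes = n_nuc),
            class = "topology_result")
}

#' @export
print.topology_result <- function(x, ...) {
  cat(sprintf("topology: Tw %.4f, dTw %.4f, Wr %.4f, dLk %.4f (%.4f per nucleosome, n = %d)\n",
              x$Tw, x$dTw, x$Wr, x$dLk, x$dLk_per_nucleosome, x$n_nucleosomes))
  invisible(x)
}

#' Topology of a framed chain
#'
#' Core computation behind [delta_lk()]: ribbon twist from the frames, Gauss
#' writhe from the origin polygon, and `dLk = dTw + Wr` with the relaxed
#' B-DNA twist of the same number of steps as reference.
#'
#' @param origins n x 3 origin matrix of a closed chain.
#' @param axes n x 9 flattened frames.
#' @param n_nucleosomes divisor for the per-nucleosome value (default 1).
#' @return A `topology_result`.
#' @export
chain_topology <- function(origins, axes, n_nucleosomes = 1L) {
  Tw <- cpp_ribbon_twist(axes, TRUE)
  dTw <- Tw - nrow(origins) * 34.3 / 360
  Wr <- writhe(origins)
  topology_result(Tw, dTw, Wr, n_nucleosomes, (dTw + Wr) / n_nucleosomes)
}

open_chain_dlk <- function(fiber, clearance_factor = 3) {
  Tw <- cpp_ribbon_twist(fiber$axes, FALSE)
  dTw <- Tw - (nrow(fiber$origins) - 1) * 34.3 / 360
  Wr <- writhe(close_fiber(fiber, clearance_factor))
  c(Tw = Tw, dTw = dTw, Wr = Wr, dLk = dTw + Wr)
}

#' Linking-number change of a nucleosome fiber
#'
#' For a circular fiber the chain is already closed and
#' `dLk = dTw + Wr` is divided by the nucleosome count. For an open regular
#' fiber, end effects are cancelled by rebuilding the fiber at several array
#' sizes, closing each with a distant planar return path, and reporting the
#' slope of `dLk` versus `n` as the per-nucleosome value. An open irregular
#' fiber falls back to `dLk / n` of the single closed chain.
#'
#' @param fiber a `fiber_conformation`; open fibers need >= 4 nucleosomes,
#'   circular >= 2.
#' @param n_series array sizes used for the end-effect-cancelling slope.
#' @return A `topology_result`; `Tw`, `dTw`, `Wr`, `dLk` refer to the
#'   largest chain evaluated, `dLk_per_nucleosome` to the slope (regular
#'   open), the ratio (circular), or `dLk/n` (irregular open).
#' @export
delta_lk <- function(fiber, n_series = c(4, 6, 8)) {
  stopifnot(inherits(fiber, "fiber_conformation"))
  n <- fiber$spec$n_nucleosomes
  if (fiber$spec$circular) {
    if (n < 2) stop("circular fibers need >= 2 nucleosomes")
    Tw <- cpp_ribbon_twist(fiber$axes, TRUE)
    dTw <- Tw - nrow(fiber$origins) * 34.3 / 360
    Wr <- writhe(fiber$origins)
    return(topology_result(Tw, dTw, Wr, n, (dTw + Wr) / n))
  }
  if (n < 4) stop("open fibers need >= 4 nucleosomes to suppress end effects")
  if (is_regular(fiber) && length(fiber$linker_steps) > 0) {
    n_series <- sort(unique(c(n_series)))
    vals <- vapply(n_series, function(nn) {
      sp <- fiber$spec
      f <- assemble_fiber(fiber_spec(sp$L, sp$L_NCP, nn, FALSE, sp$family_hint),
                          fiber$linker_steps[[1]], fiber$core_template)
      open_chain_dlk(f)
    }, numeric(4))
    slope <- unname(coef(lm(vals["dLk", ] ~ n_series))[2])
    top <- vals[, length(n_series)]
    return(topology_result(top["Tw"], top["dTw"], top["Wr"],
                           max(n_series), slope))
  }
  v <- open_chain_dlk(fiber)
  topology_result(v["Tw"], v["dTw"], v["Wr"], n, v["dLk"] / n)
}
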