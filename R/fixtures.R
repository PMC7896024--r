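#' Closed-form test curves
#'
#' Generators for curves whose writhe is known independently of the Gauss
#' double integral: a planar circle (exactly zero), toroidal solenoids
#' (Fuller's closed form `|Wr| = N (1 - sin(alpha))` for tight coiling),
#' and the (2,3) torus-knot trefoil (checked against a fine-discretization
#' refinement of itself).
#'
#' @param n number of vertices.
#' @param radius circle radius.
#' @name test_curves
NULL

#' @rdname test_curves
#' @export
circle_curve <- function(n = 200, radius = 1) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(radius * cos(th), radius * sin(th), 0)
}

#' @rdname test_curves
#' @param N number of coils.
#' @param alpha pitch angle, radians; keep the coil radius below the axial
#'   radius (alpha not too small) or the torus self-intersects.
#' @param R_axis radius of the solenoid's circular axis.
#' @export
solenoid_curve <- function(N = 5, alpha = 0.5, R_axis = 10, n = 2000) {
  r <- R_axis / (N * tan(alpha))
  if (r >= R_axis)
    stop("self-intersecting solenoid: increase alpha or N")
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((R_axis + r * cos(N * t)) * cos(t),
        (R_axis + r * cos(N * t)) * sin(t),
        r * sin(N * t))
}

#' @rdname test_curves
#' @export
trefoil_curve <- function(n = 400) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind((2 + cos(3 * t)) * cos(2 * t),
        (2 + cos(3 * t)) * sin(2 * t),
        sin(3 * t))
}

#' Build the standard fixture set
#'
#' Canonical inputs for validating the topology pipeline: a planar circle,
#' three toroidal solenoids at different pitch angles, the trefoil, and the
#' canonical relaxed-linker T2 (L = 20) and T1 (L = 25) trinucleosome
#' geometries. Each curve fixture carries its expected writhe, a tolerance,
#' and a provenance tag saying how the expectation was obtained (closed
#' form, refinement oracle, or trivially zero).
#'
#' @param seed seed for the (deterministic) refinement oracle; kept for
#'   interface symmetry with the stochastic generators.
#' @return A list of fixtures; curve fixtures have `name`, `vertices`,
#'   `expected_writhe`, `tolerance`, `provenance`; fiber fixtures have
#'   `name`, `conformation`, `provenance`.
#' @export
make_fixtures <- function(seed = 1) {
  fx <- list()
  fx$circle <- list(name = "planar_circle", vertices = circle_curve(200),
                    expected_writhe = 0, tolerance = 1e-6,
                    provenance = "trivial: planar curve")
  for (alpha in c(0.3, 0.5, 0.7)) {
    nm <- sprintf("solenoid_a%02d", round(100 * alpha))
    fx[[nm]] <- list(
      name = nm, vertices = solenoid_curve(N = 5, alpha = alpha),
      expected_writhe = -5 * (1 - sin(alpha)),  # left-handed toroidal coil
      tolerance = 0.05 * 5 * (1 - sin(alpha)),
      provenance = "derived: Fuller closed form for tight solenoids")
  }
  fx$trefoil <- list(
    name = "trefoil", vertices = trefoil_curve(400),
    expected_writhe = writhe(trefoil_curve(4000)),
    tolerance = 0.02,
    provenance = "derived: 4000-vertex refinement oracle")
  for (L in c(20, 25)) {
    nm <- sprintf("relaxed_trinucleosome_L%d", L)
    fx[[nm]] <- list(
      name = nm,
      conformation = assemble_fiber(
        fiber_spec(L = L, L_NCP = 147, n_nucleosomes = 3), relaxed_step()),
      provenance = sprintf("model: canonical relaxed-linker %s geometry",
                           if (L %% 10 <= 4) "T2 (10n)" else "T1 (10n+5)"))
  }
  fx
}
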