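#' Energy parameters for fiber scoring
#'
#' Three ingredients score a conformation: a harmonic rigid-base-pair
#' elastic energy for linker DNA, an attractive face-to-face stacking well
#' between nucleosome cores, and hard-core excluded volume.
#'
#' The default diagonal stiffness is matched to DNA persistence lengths
#' (bending ~50 nm gives tilt/roll k = 0.043 kT/deg^2 per step; torsional
#' stiffness gives twist k = 0.06 kT/deg^2; shift/slide/rise are stiff at
#' 50 kT/nm^2). The stacking well has depth 18 kT centered at a 7.0 nm
#' core-center separation with 0.5 nm width: 7.0 nm is the closest
#' (i, i+-2) approach the rigid fully-wrapped core geometry affords at an
#' elastic cost the well can repay, so this calibration produces
#' predominantly (i, i+-2) stacking in optimal two-start fibers and
#' substantially but incompletely stacked thermal ensembles at 1 kT.
#'
#' @param step_equilibrium equilibrium step, default relaxed B-DNA.
#' @param step_stiffness 6 x 6 symmetric positive-definite stiffness, kT per
#'   deg^2 (rotations) or kT per nm^2 (displacements).
#' @param stacking_depth well depth, kT (> 0).
#' @param stacking_distance center-to-center distance of the well minimum, nm.
#' @param stacking_width radial width of the Gaussian well, nm. The well is
#'   cut off at `stacking_distance + 3 * stacking_width`.
#' @param core_radius,core_half_height nucleosome core cylinder, nm.
#' @param dna_radius linker DNA hard-core radius, nm.
#' @param stacking,excluded_volume logical switches for the attractive and
#'   hard-core terms.
#' @param stack_min_sep smallest sequence separation |i - j| whose pairs
#'   enter the stacking sum of a fiber energy. The default 2 encodes that
#'   the faces of sequence-neighbor nucleosomes are occluded by the linker
#'   DNA entering and exiting between them, which keeps the model inside
#'   the two-start structural class.
#' @param adjacent_center_floor stereochemical floor (nm) on the center
#'   distance of sequence-neighbor cores. Their cylinder check is waived
#'   (idealized parallel rigid cylinders of a compact zigzag formally graze
#'   where real tilted nucleosomes do not), but below ~6.5 nm real cores
#'   would interpenetrate regardless of tilt.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(step_equilibrium = relaxed_step(),
                          step_stiffness = diag(c(0.043, 0.043, 0.06, 50, 50, 50)),
                          stacking_depth = 18,
                          stacking_distance = 7.0,
                          stacking_width = 0.5,
                          core_radius = 5.5,
                          core_half_height = 2.75,
                          dna_radius = 1.0,
                          stacking = TRUE,
                          excluded_volume = TRUE,
                          stack_min_sep = 2L,
                          adjacent_center_floor = 6.5) {
  K <- as.matrix(step_stiffness)
  if (!all(dim(K) == c(6, 6)) || max(abs(K - t(K))) > 1e-9)
    stop("step_stiffness must be a symmetric 6x6 matrix")
  if (any(eigen(K, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("step_stiffness must be positive-definite")
  if (stacking_depth <= 0)
    stop("stacking_depth must be a positive magnitude (use stacking = FALSE to disable)")
  if (core_radius <= 0 || core_half_height <= 0 || dna_radius <= 0)
    stop("geometric radii must be positive")
  structure(list(
    step_equilibrium = as_step_matrix(step_equilibrium)[1, ],
    step_stiffness = K,
    stacking_depth = stacking_depth,
    stacking_distance = stacking_distance,
    stacking_width = stacking_width,
    core_radius = core_radius,
    core_half_height = core_half_height,
    dna_radius = dna_radius,
    stacking = isTRUE(stacking),
    excluded_volume = isTRUE(excluded_volume),
    stack_min_sep = max(1L, as.integer(stack_min_sep)),
    adjacent_center_floor = adjacent_center_floor
  ), class = "energy_params")
}

#' Harmonic elastic energy of one base-pair step
#'
#' `E = 1/2 (s - s0)' K (s - s0)` in kT, with `s0` the equilibrium step and
#' `K` the stiffness matrix. Exactly quadratic: doubling a deviation
#' quadruples its energy.
#'
#' @param step a step (any form accepted by [as_step_matrix()]); a matrix
#'   gives the summed energy of all rows.
#' @param params an [energy_params()] object.
#' @return Energy in kT (>= 0).
#' @export
step_energy <- function(step, params = energy_params()) {
  m <- as_step_matrix(step)
  d <- sweep(m, 2, params$step_equilibrium)
  sum(0.5 * rowSums((d %*% params$step_stiffness) * d))
}

#' Internucleosome stacking energy
#'
#' Attractive face-to-face well between two placed cores:
#' `-depth * f(d) * |cos(theta)|`, where `f` is a Gaussian well in the
#' core-center distance `d` centered at the stacking distance, and `theta`
#' is the angle between the two superhelical axes. Zero beyond the cutoff
#' `stacking_distance + 3 * stacking_width`.
#'
#' @param core_i,core_j placed cores: lists with `center` (nm 3-vector) and
#'   `axis` (unit 3-vector), as returned by [placed_cores()].
#' @param params an [energy_params()] object.
#' @return Energy in kT (<= 0).
#' @export
stacking_energy <- function(core_i, core_j, params = energy_params()) {
  d <- sqrt(sum((core_i$center - core_j$center)^2))
  if (d > params$stacking_distance + 3 * params$stacking_width) return(0)
  g <- abs(sum(core_i$axis * core_j$axis))
  x <- (d - params$stacking_distance) / params$stacking_width
  -params$stacking_depth * exp(-0.5 * x^2) * g
}

#' Extract placed cores from a fiber conformation
#'
#' @param fiber a `fiber_conformation`.
#' @return A list with one element per nucleosome: `index`, `center` (nm),
#'   `axis` (unit superhelical axis).
#' @export
placed_cores <- function(fiber) {
  lapply(seq_len(fiber$spec$n_nucleosomes), function(i) {
    list(index = i - 1L, center = fiber$centers[i, ], axis = fiber$core_axes[i, ])
  })
}

fiber_energy_cpp <- function(fiber, params) {
  tpl <- core_cpp_template(fiber$core_template, params, with_bp = FALSE)
  cpp_fiber_energy(fiber$linker_steps, fiber$spec$n_nucleosomes, tpl,
                   unclass(params))
}

#' Hard-core excluded-volume check
#'
#' A conformation is violated when any two non-adjacent core cylinders
#' overlap, when any linker bp center penetrates a core cylinder other than
#' the two its linker connects, or when two segments of distinct linkers
#' approach below twice the DNA radius.
#'
#' @param fiber a `fiber_conformation`.
#' @param params an [energy_params()] object.
#' @return `TRUE` if violated.
#' @export
excluded_volume <- function(fiber, params = energy_params()) {
  isTRUE(fiber_energy_cpp(fiber, params)$violated)
}

#' Total conformational energy
#'
#' Sums the elastic energies of all linker steps and the stacking terms of
#' all core pairs at sequence separation `stack_min_sep` or more, and flags
#' excluded-volume violations. The total carries an `Inf` sentinel when the
#' hard core is violated.
#'
#' @param fiber a `fiber_conformation`.
#' @param params an [energy_params()] object.
#' @return An object of class `energy_breakdown`: `elastic`, `stacking`,
#'   `excluded_volume_violated`, `total` (all kT).
#' @export
total_energy <- function(fiber, params = energy_params()) {
  r <- fiber_energy_cpp(fiber, params)
  viol <- isTRUE(r$violated)
  structure(list(elastic = r$elastic, stacking = r$stacking,
                 excluded_volume_violated = viol,
                 total = if (viol) Inf else r$elastic + r$stacking),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("energy: elastic %.3f kT + stacking %.3f kT = %s%s\n",
              x$elastic, x$stacking,
              if (is.finite(x$total)) sprintf("%.3f kT", x$total) else "Inf",
              if (x$excluded_volume_violated) " (excluded volume violated)" else ""))
  invisible(x)
}
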