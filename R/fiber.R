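#' Fiber specification
#'
#' Dimensions of a regular nucleosome array: free linker length `L`, core
#' length `L_NCP`, and the number of nucleosomes. The nucleosome repeat
#' length NRL = L_NCP + L is derived, never stored independently, as is the
#' linker-length class: `L mod 10` in 0..4 is "10n"-like (T2-prone), 5..9 is
#' "10n+5"-like (T1-prone).
#'
#' @param L free linker length, bp (>= 10).
#' @param L_NCP core length, 146 or 147 bp.
#' @param n_nucleosomes array size (>= 1).
#' @param circular logical; should the array be treated as a closed circle
#'   (with `n_nucleosomes` linkers) rather than an open chain?
#' @param family_hint `"T1"`, `"T2"` or `"auto"`; used by the optimizer to
#'   select among topological minima.
#' @return An object of class `fiber_spec`.
#' @examples
#' fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 8)
#' @export
fiber_spec <- function(L, L_NCP = 147, n_nucleosomes = 12, circular = FALSE,
                       family_hint = c("auto", "T1", "T2")) {
  family_hint <- match.arg(family_hint)
  L <- as.integer(L)
  L_NCP <- as.integer(L_NCP)
  n_nucleosomes <- as.integer(n_nucleosomes)
  if (L < 10) stop("linker length L must be >= 10 bp")
  if (!L_NCP %in% c(146L, 147L)) stop("L_NCP must be 146 or 147 bp")
  if (n_nucleosomes < 1) stop("need at least one nucleosome")
  structure(list(L = L, L_NCP = L_NCP, NRL = L + L_NCP,
                 n_nucleosomes = n_nucleosomes, circular = isTRUE(circular),
                 family_hint = family_hint),
            class = "fiber_spec")
}

#' @export
print.fiber_spec <- function(x, ...) {
  cat(sprintf("fiber spec: %d nucleosomes, L = %d bp, L_NCP = %d bp (NRL %d), %s, class %s\n",
              x$n_nucleosomes, x$L, x$L_NCP, x$NRL,
              if (x$circular) "circular" else "open", linker_class(x$L)))
  invisible(x)
}

#' Linker-length class
#'
#' @param L linker length, bp.
#' @return `"10n"` when `L mod 10` is in 0..4, else `"10n+5"`.
#' @export
linker_class <- function(L) {
  ifelse(L %% 10 <= 4, "10n", "10n+5")
}

n_linkers <- function(spec) {
  if (spec$circular) spec$n_nucleosomes else spec$n_nucleosomes - 1L
}

# Normalize linker input to a list of (L+1) x 6 matrices, one per linker.
# A linker with L free bp carries L + 1 base-pair steps (core exit -> L
# linker bp -> next core entry).
linker_step_list <- function(spec, linker_steps) {
  nl <- n_linkers(spec)
  nsteps <- spec$L + 1L
  if (nl == 0L) return(list())
  if (is.list(linker_steps) && !is.data.frame(linker_steps)) {
    if (length(linker_steps) != nl)
      stop(sprintf("need %d linkers, got %d", nl, length(linker_steps)))
    out <- lapply(linker_steps, as_step_matrix)
  } else {
    m <- as_step_matrix(linker_steps, n = nsteps)
    if (nrow(m) == 1L) m <- m[rep(1L, nsteps), , drop = FALSE]
    out <- replicate(nl, m, simplify = FALSE)
  }
  for (m in out)
    if (nrow(m) != nsteps)
      stop(sprintf("each linker must carry L + 1 = %d steps, got %d", nsteps, nrow(m)))
  out
}

#' Assemble a nucleosome fiber conformation
#'
#' Rigidly places copies of a core template along a chain of linkers: the
#' entry frame of core i+1 is reached from the exit frame of core i by
#' compounding that linker's base-pair steps. The concatenated base-pair
#' path is gap-free; steric feasibility is deliberately not checked here
#' (that is the energy module's job).
#'
#' @param spec a [fiber_spec()].
#' @param linker_steps one shared step (a `step_params` vector or an
#'   `(L+1) x 6` matrix) applied to every linker, or a list with one step
#'   matrix per linker.
#' @param core a [build_core()] template; defaults to the canonical core for
#'   `spec$L_NCP`.
#' @return An object of class `fiber_conformation` with the full base-pair
#'   path (`origins`, `axes`), per-bp region labels, per-core centers and
#'   superhelical axes, the spec, and the linker steps used.
#' @examples
#' spec <- fiber_spec(L = 20, n_nucleosomes = 3)
#' fib <- assemble_fiber(spec, relaxed_step())
#' @export
assemble_fiber <- function(spec, linker_steps = relaxed_step(), core = NULL) {
  stopifnot(inherits(spec, "fiber_spec"))
  if (is.null(core)) core <- build_core(spec$L_NCP)
  if (core$L_NCP != spec$L_NCP) stop("core template length does not match spec$L_NCP")
  linkers <- linker_step_list(spec, linker_steps)
  tpl <- core_cpp_template(core, energy_params(), with_bp = TRUE)
  if (length(linkers) == 0L) {
    built <- cpp_build_fiber(list(), spec$n_nucleosomes, tpl, FALSE)
  } else {
    built <- cpp_build_fiber(linkers, spec$n_nucleosomes, tpl, spec$circular)
  }
  structure(list(
    spec = spec,
    core_template = core,
    linker_steps = linkers,
    origins = built$origins,
    axes = built$axes,
    region = built$region,
    is_core = as.logical(built$is_core),
    centers = built$centers,
    core_axes = built$core_axes
  ), class = "fiber_conformation")
}

#' @export
print.fiber_conformation <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d bp frames (%d core, %d linker)\n",
              nrow(x$origins), sum(x$is_core), sum(!x$is_core)))
  invisible(x)
}

#' @export
as.data.frame.fiber_conformation <- function(x, ...) {
  data.frame(
    bp_index = seq_len(nrow(x$origins)) - 1L,
    x = x$origins[, 1], y = x$origins[, 2], z = x$origins[, 3],
    region = ifelse(x$is_core, sprintf("core_%d", x$region),
                    sprintf("linker_%d", x$region)),
    stringsAsFactors = FALSE
  )
}

#' Is a fiber regular?
#'
#' A fiber is regular when every linker carries an identical step set, so
#' nucleosome i+1 is generated from nucleosome i by a fixed screw transform.
#'
#' @param fiber a `fiber_conformation`.
#' @export
is_regular <- function(fiber) {
  ls <- fiber$linker_steps
  if (length(ls) <= 1L) return(TRUE)
  all(vapply(ls[-1], function(m) isTRUE(all.equal(m, ls[[1]], tolerance = 1e-12)),
             logical(1)))
}
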