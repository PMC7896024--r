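test_that("writhe reproduces closed-form and refinement oracles", {
  circ <- circle_curve(200)
  expect_equal(writhe(circ), 0, tolerance = 1e-6)
  expect_equal(writhe(circ, "levitt_le_bret"), 0, tolerance = 1e-6)

  # toroidal solenoids against Fuller's closed form, three pitch angles
  for (alpha in c(0.3, 0.5, 0.7)) {
    v <- solenoid_curve(N = 5, alpha = alpha)
    expected <- -5 * (1 - sin(alpha))  # left-handed coil
    expect_lt(abs(writhe(v) - expected), 0.05 * abs(expected))
  }

  # trefoil at 400 vertices vs the frozen 4000-vertex refinement value
  expect_lt(abs(writhe(trefoil_curve(400)) - (-3.518235)), 0.02)
  # the two per-pair formulations agree far below the stated 0.02
  expect_lt(abs(writhe(trefoil_curve(400)) -
                  writhe(trefoil_curve(400), "levitt_le_bret")), 1e-8)

  expect_error(writhe(matrix(0, 2, 3)), "n >= 3")
})

test_that("writhe is invariant under rigid motion and scale, odd under mirror", {
  set.seed(11)
  v <- fourier_closed_curve(250, seed = 5)
  w0 <- writhe(v)
  R <- random_rotation()
  moved <- v %*% t(R) + matrix(c(3, -7, 11), nrow(v), 3, byrow = TRUE)
  expect_equal(writhe(moved), w0, tolerance = 1e-9)
  expect_equal(writhe(v * 3.7), w0, tolerance = 1e-9)
  expect_equal(writhe(mirror_vertices(v)), -w0, tolerance = 1e-9)
})

test_that("linking number of interlocked circles is a unit integer", {
  a <- circle_curve(150)
  th <- seq(0, 2 * pi, length.out = 151)[-151]
  b <- cbind(1 + cos(th), 0 * th, sin(th))
  expect_equal(abs(linking_number(a, b)), 1, tolerance = 1e-6)
  far <- cbind(10 + cos(th), 0 * th, sin(th))
  expect_equal(linking_number(a, far), 0, tolerance = 1e-6)
})

test_that("twist bookkeeping matches direct sums and the relaxed reference", {
  m <- as_step_matrix(step_params(twist = 36, rise = 0.34), n = 10)
  expect_equal(twist_of(m)$Tw, 1.0, tolerance = 1e-12)

  relaxed <- as_step_matrix(relaxed_step(), n = 105)
  expect_equal(twist_of(relaxed)$dTw, 0, tolerance = 1e-12)

  set.seed(2)
  tw <- runif(50, 20, 45)
  mixed <- cbind(0, 0, tw, 0, 0, 0.34)
  colnames(mixed) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  expect_equal(twist_of(mixed)$Tw, sum(tw) / 360, tolerance = 1e-12)
})

test_that("Calugareanu/White: Lk = Tw + Wr for framed closed curves", {
  # explicit two-curve check: the ribbon edge offset along the x axis links
  # the axis exactly Tw + Wr times
  v <- fourier_closed_curve(300, seed = 9)
  fr <- framed_closed_curve(v, twist_turns = 3)
  edge <- fr$origins + 0.05 * fr$axes[, 1:3]
  lk <- linking_number(fr$origins, edge)
  tw <- ribbon_twist(fr, closed = TRUE)
  wr <- writhe(fr$origins)
  expect_lt(abs(lk - (tw + wr)), 0.02)
  expect_lt(abs(lk - round(lk)), 0.02)  # a closed ribbon links integrally
})

test_that("Tw + Wr is conserved under non-crossing deformation while each varies", {
  v <- fourier_closed_curve(300, seed = 13)
  fr <- framed_closed_curve(v, twist_turns = 2)
  lk0 <- ribbon_twist(fr, closed = TRUE) + writhe(fr$origins)
  tws <- numeric(0)
  wrs <- numeric(0)
  t_par <- seq(0, 2 * pi, length.out = 301)[-301]
  for (s in seq(0.3, 3, by = 0.3)) {
    # a chiral (helical) perturbation, so writhe genuinely changes
    vs <- v + s * cbind(0 * t_par, 1.2 * sin(2 * t_par), 1.2 * cos(2 * t_par))
    fr <- carry_framing(fr, vs)
    tws <- c(tws, ribbon_twist(fr, closed = TRUE))
    wrs <- c(wrs, writhe(fr$origins))
  }
  expect_lt(max(abs(tws + wrs - lk0)), 0.02)   # invariant
  expect_gt(diff(range(tws)), 0.05)            # while both parts move
  expect_gt(diff(range(wrs)), 0.05)
})

test_that("chain closure behaves for straight DNA, cores, and circular input", {
  straight <- build_chain(bp_frame(), as_step_matrix(relaxed_step(), n = 199))
  expect_equal(writhe(close_fiber(straight$origins)), 0, tolerance = 0.01)

  circ_spec <- fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 3, circular = TRUE)
  circ_fib <- assemble_fiber(circ_spec, relaxed_step())
  expect_error(close_fiber(circ_fib), "already closed")
})

test_that("relaxed closed circles carry no linking-number change", {
  # 210 bp at relaxed twist is within 0.01 turns of exactly 20 helical turns
  circ <- circle_curve(210, radius = 210 * 0.34 / (2 * pi))
  fr <- framed_closed_curve(circ, twist_turns = 20)
  top <- chain_topology(fr$origins, fr$axes, n_nucleosomes = 1L)
  expect_lt(abs(top$dLk), 0.01)
  expect_equal(top$dLk, top$dTw + top$Wr, tolerance = 1e-9)
})

test_that("per-nucleosome dLk of regular fibers is independent of array size", {
  fib <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 8),
                        relaxed_step())
  d46 <- delta_lk(fib, n_series = c(4, 6))$dLk_per_nucleosome
  d68 <- delta_lk(fib, n_series = c(6, 8))$dLk_per_nucleosome
  d812 <- delta_lk(fib, n_series = c(8, 12))$dLk_per_nucleosome
  expect_lt(abs(d46 - d68), 0.05)
  expect_lt(abs(d68 - d812), 0.05)

  expect_error(delta_lk(assemble_fiber(
    fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 3), relaxed_step())),
    ">= 4 nucleosomes")
})
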