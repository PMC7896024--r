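test_that("twist-only and zero steps give the expected transforms", {
  tf <- step_to_transform(step_params(twist = 36, rise = 0.34))
  expect_equal(tf$rotation,
               matrix(c(cos(pi / 5), sin(pi / 5), 0,
                        -sin(pi / 5), cos(pi / 5), 0,
                        0, 0, 1), 3, 3),
               tolerance = 1e-12)
  expect_equal(tf$translation, c(0, 0, 0.34), tolerance = 1e-12)

  id <- step_to_transform(step_params())
  expect_equal(id$rotation, diag(3), tolerance = 1e-12)
  expect_equal(id$translation, c(0, 0, 0), tolerance = 1e-12)

  # inverse composed with forward is the identity
  inv <- t(tf$rotation)
  expect_equal(inv %*% tf$rotation, diag(3), tolerance = 1e-10)
})

test_that("step rotation angle matches an independent quaternion oracle", {
  set.seed(42)
  for (i in 1:10) {
    s <- step_params(tilt = runif(1, -6, 6), roll = runif(1, -6, 6),
                     twist = runif(1, 28, 40),
                     shift = 0.1, slide = 0.1, rise = 0.34)
    tf <- step_to_transform(s)
    d2r <- pi / 180
    G <- sqrt(s[["tilt"]]^2 + s[["roll"]]^2) * d2r
    phi <- atan2(s[["tilt"]], s[["roll"]])
    tw <- s[["twist"]] * d2r
    expect_equal(rotation_angle(tf$rotation),
                 quat_net_angle(tw / 2 - phi, G, tw / 2 + phi),
                 tolerance = 1e-9)
  }
})

test_that("chains compound, close-form helices check out, and round-trips hold", {
  ch <- build_chain(bp_frame(), as_step_matrix(step_params(twist = 36, rise = 0.34), n = 10))
  expect_equal(nrow(ch$origins), 11L)
  expect_equal(ch$origins[11, ], c(0, 0, 3.4), tolerance = 1e-9)

  empty <- build_chain(bp_frame(), NULL)
  expect_equal(nrow(empty$origins), 1L)

  # constant pure roll bends the path into a planar arc; the end-to-end
  # distance must equal the analytic chord of that arc
  n_steps <- 146
  total_turn <- 1.65 * 360
  gamma <- total_turn / n_steps
  ch2 <- build_chain(bp_frame(),
                     as_step_matrix(step_params(roll = gamma, rise = 0.34), n = n_steps))
  R_arc <- (0.34 / 2) / sin(gamma / 2 * pi / 180)
  chord <- 2 * R_arc * abs(sin(total_turn / 2 * pi / 180))
  ee <- sqrt(sum((ch2$origins[n_steps + 1, ] - ch2$origins[1, ])^2))
  expect_equal(ee, chord, tolerance = 1e-6)

  # extraction inverts compounding to high precision
  set.seed(3)
  steps <- cbind(rnorm(40, 0, 4), rnorm(40, 0, 4), rnorm(40, 34.3, 3),
                 rnorm(40, 0, 0.1), rnorm(40, 0, 0.1), rnorm(40, 0.34, 0.02))
  colnames(steps) <- c("tilt", "roll", "twist", "shift", "slide", "rise")
  ch3 <- build_chain(bp_frame(), steps)
  back <- extract_steps(ch3$origins, ch3$axes)
  expect_equal(unname(back), unname(steps), tolerance = 1e-7)
  rebuilt <- build_chain(bp_frame(), back)
  expect_lt(max(abs(rebuilt$origins - ch3$origins)), 1e-6)

  expect_error(bp_frame(axes = matrix(1, 3, 3)), "orthonormal")
})

test_that("the core template is a left-handed superhelix with the right writhe", {
  core <- build_core(147)
  expect_equal(core$L_NCP, 147L)
  expect_equal(core$entry_frame$origin, core$bp_origins[1, ])
  expect_equal(core$exit_frame$origin, core$bp_origins[147, ])
  expect_equal(sqrt(sum(core$superhelical_axis^2)), 1, tolerance = 1e-9)

  wr <- writhe(close_fiber(core$bp_origins))
  expect_lt(abs(wr - (-1.5)), 0.2)

  # chirality: mirrored geometry flips the sign
  wr_m <- writhe(mirror_vertices(close_fiber(core$bp_origins)))
  expect_equal(wr_m, -wr, tolerance = 1e-6)

  expect_error(build_core(147, wrap_turns = 0), "wrap_turns")
  expect_error(build_core(147, handedness = "right"), "left-handed")
  expect_error(build_core(150), "146 or 147")
})

test_that("fibers assemble gap-free with the declared bp bookkeeping", {
  spec1 <- fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 1)
  f1 <- assemble_fiber(spec1, relaxed_step())
  expect_equal(nrow(f1$origins), 147L)

  spec3 <- fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 3)
  f3 <- assemble_fiber(spec3, relaxed_step())
  expect_equal(nrow(f3$origins), 3L * 147L + 2L * 20L)
  gaps <- sqrt(rowSums(diff(f3$origins)^2))
  expect_lt(max(gaps), 0.6)  # no jumps anywhere along the concatenated path
  expect_true(is_regular(f3))

  # round-trip invariant on the assembled conformation
  back <- extract_steps(f3$origins, f3$axes)
  rebuilt <- build_chain(bp_frame(f3$origins[1, ], matrix(f3$axes[1, ], 3, 3)), back)
  expect_lt(max(abs(rebuilt$origins - f3$origins)), 1e-6)

  # no two core centers coincide
  expect_gt(min(dist(f3$centers)), 1)

  expect_error(assemble_fiber(spec3, list(as_step_matrix(relaxed_step(), 21))),
               "need 2 linkers")
})

test_that("a 5-bp linker change flips the rotational setting by ~180 degrees", {
  # measure the orientation of nucleosome 2 about the (straight, relaxed)
  # linker axis; 5 extra bp of relaxed twist should rotate it by ~180 deg
  setting_angle <- function(L) {
    f <- assemble_fiber(fiber_spec(L = L, L_NCP = 147, n_nucleosomes = 2),
                        relaxed_step())
    u <- matrix(f$axes[148, ], 3, 3)[, 3]   # linker tangent at the exit
    a2 <- f$core_axes[2, ]
    ref <- matrix(f$axes[148, ], 3, 3)[, 1]
    p2 <- a2 - sum(a2 * u) * u
    cr <- c(ref[2] * p2[3] - ref[3] * p2[2],
            ref[3] * p2[1] - ref[1] * p2[3],
            ref[1] * p2[2] - ref[2] * p2[1])
    atan2(sum(cr * u), sum(ref * p2)) * 180 / pi
  }
  for (L in c(20, 30)) {
    dphi <- abs(setting_angle(L + 5) - setting_angle(L)) %% 360
    dphi <- min(dphi, 360 - dphi)
    expect_lt(abs(dphi - 180), 15)
  }
})
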