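test_that("the elastic term is the declared harmonic form", {
  p <- energy_params()
  expect_equal(step_energy(relaxed_step(), p), 0)

  one_tilt <- step_params(tilt = 1, twist = 34.3, rise = 0.34)
  expect_equal(step_energy(one_tilt, p), 0.5 * 0.043 * 1^2, tolerance = 1e-12)

  # exactly quadratic: doubling a deviation quadruples the energy
  two_tilt <- step_params(tilt = 2, twist = 34.3, rise = 0.34)
  expect_equal(step_energy(two_tilt, p), 4 * step_energy(one_tilt, p),
               tolerance = 1e-12)

  # general deviation, full-matrix closed form
  d <- c(1.5, -2, 3, 0.05, -0.02, 0.01)
  s <- step_params(tilt = d[1], roll = d[2], twist = 34.3 + d[3],
                   shift = d[4], slide = d[5], rise = 0.34 + d[6])
  expect_equal(step_energy(s, p),
               0.5 * sum(d * (p$step_stiffness %*% d)), tolerance = 1e-12)
  expect_gte(step_energy(s, p), 0)
})

test_that("the stacking well has the declared shape and symmetry", {
  p <- energy_params()
  d0 <- p$stacking_distance
  a <- list(center = c(0, 0, 0), axis = c(0, 0, 1))
  b <- list(center = c(0, 0, d0), axis = c(0, 0, 1))
  expect_equal(stacking_energy(a, b, p), -p$stacking_depth, tolerance = 1e-12)

  perp <- list(center = c(0, 0, d0), axis = c(1, 0, 0))
  expect_equal(stacking_energy(a, perp, p), 0, tolerance = 1e-12)

  far <- list(center = c(0, 0, 100), axis = c(0, 0, 1))
  expect_identical(stacking_energy(a, far, p), 0)

  expect_equal(stacking_energy(a, b, p), stacking_energy(b, a, p))

  # invariant under rigid motion of the pair
  R <- random_rotation()
  shift <- c(5, -2, 9)
  a2 <- list(center = as.numeric(R %*% a$center + shift), axis = as.numeric(R %*% a$axis))
  b2 <- list(center = as.numeric(R %*% b$center + shift), axis = as.numeric(R %*% b$axis))
  expect_equal(stacking_energy(a2, b2, p), stacking_energy(a, b, p),
               tolerance = 1e-9)
})

test_that("excluded volume flags clashes and passes clean fibers", {
  p <- energy_params()
  mono <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 1))
  expect_false(excluded_volume(mono, p))

  clean <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
                          relaxed_step())
  expect_false(excluded_volume(clean, p))

  # an absurdly inflated hard core makes every multi-nucleosome fiber clash
  fat <- energy_params(core_radius = 30, core_half_height = 15,
                       adjacent_center_floor = 40)
  expect_true(excluded_volume(clean, fat))
})

test_that("total energy is additive and carries the violation sentinel", {
  p <- energy_params()
  fib <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
                        relaxed_step())
  e <- total_energy(fib, p)
  expect_equal(e$total, e$elastic + e$stacking)
  expect_equal(e$elastic, 0, tolerance = 1e-9)  # relaxed linkers

  fat <- energy_params(core_radius = 30, core_half_height = 15,
                       adjacent_center_floor = 40)
  e2 <- total_energy(fib, fat)
  expect_true(e2$excluded_volume_violated)
  expect_identical(e2$total, Inf)

  # a slightly bent fiber pays exactly the per-step harmonic sum
  bent <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
                         step_params(roll = 1, twist = 34.3, rise = 0.34))
  e3 <- total_energy(bent, p)
  expect_equal(e3$elastic, 3 * 21 * 0.5 * 0.043, tolerance = 1e-9)
})

test_that("parameter validation catches unphysical settings", {
  expect_error(energy_params(stacking_depth = -1), "positive magnitude")
  expect_error(energy_params(stacking_depth = 0), "positive magnitude")
  bad <- diag(6)
  bad[1, 1] <- -1
  expect_error(energy_params(step_stiffness = bad), "positive-definite")
  expect_error(energy_params(step_stiffness = matrix(1, 5, 5)), "6x6")
})
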