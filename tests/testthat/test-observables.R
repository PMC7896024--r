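test_that("break-correlation weights follow exp(-d/lambda)", {
  pts <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0))
  prof <- fld_profile(pts, lambda_nm = 4, range = c(1, 2))
  expect_equal(prof$value[prof$n_nt == 1], exp(-1), tolerance = 1e-12)
  expect_equal(prof$value[prof$n_nt == 2], exp(-2), tolerance = 1e-12)

  # coincident points would weigh 1
  expect_equal(exp(-0 / 4), 1)

  # fragment lengths beyond the chain are absent, not zero
  prof2 <- fld_profile(pts, lambda_nm = 4, range = c(1, 10))
  expect_false(any(prof2$n_nt > 2))
})

test_that("straight DNA gives a strictly decreasing, peak-free profile", {
  straight <- build_chain(bp_frame(), as_step_matrix(relaxed_step(), n = 500))
  prof <- fld_profile(straight$origins, lambda_nm = 4, range = c(10, 120))
  expect_true(all(diff(prof$value) < 0))
  expect_equal(nrow(detect_peaks(prof)), 0L)
})

test_that("FLD is linear over conformations and rigid-motion invariant", {
  fib <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
                        relaxed_step())
  fib2 <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
                         step_params(roll = 2, twist = 34.3, rise = 0.34))
  pA <- fld_profile(fib, range = c(100, 200))
  pB <- fld_profile(fib2, range = c(100, 200))
  pAB <- fld_profile(list(fib, fib2), range = c(100, 200))
  expect_equal(pAB$value, (pA$value + pB$value) / 2, tolerance = 1e-12)

  set.seed(8)
  R <- random_rotation()
  moved <- fib$origins %*% t(R) + matrix(c(10, -4, 2), nrow(fib$origins), 3,
                                         byrow = TRUE)
  expect_equal(fld_profile(moved, range = c(100, 200))$value, pA$value,
               tolerance = 1e-9)

  # scaling coordinates by c is the same as scaling lambda down by c
  scaled <- fld_profile(fib$origins * 2, lambda_nm = 8, range = c(100, 200))
  expect_equal(scaled$value, pA$value, tolerance = 1e-12)
})

test_that("peak detection isolates bumps and respects prominence", {
  n <- 100:300
  bump <- exp(-(n - 180)^2 / 50)
  prof <- data.frame(n_nt = n, value = bump + 0.2)
  pk <- detect_peaks(prof, min_prominence = 0.05)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position - 180), 3)

  mono <- data.frame(n_nt = n, value = seq(1, 0, length.out = length(n)))
  expect_equal(nrow(detect_peaks(mono)), 0L)

  # two bumps, one tiny: the prominence threshold separates them
  two <- data.frame(n_nt = n, value = exp(-(n - 150)^2 / 40) +
                      0.02 * exp(-(n - 250)^2 / 40))
  expect_equal(nrow(detect_peaks(two, min_prominence = 0.05)), 1L)
  expect_equal(nrow(detect_peaks(two, min_prominence = 0.005)), 2L)
})

test_that("contact classification counts offsets and handles mononucleosomes", {
  mono <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 1))
  st <- classify_contacts(mono)
  expect_true(all(st$counts == 0))
  expect_equal(st$stacking_fraction, 0)
  expect_equal(st$flipout_rate, 0)

  # in a compact optimal two-start fiber every close contact is (i, i+-2)
  res <- cached_optimum(21, 146)
  best <- res[[1]]
  cc <- classify_contacts(best$conformation, cutoff = 8.5)
  expect_gt(cc$counts[["k2"]], 0)
  expect_equal(unname(cc$counts[["k3"]] + cc$counts[["k4plus"]]), 0)
  expect_equal(cc$flipout_rate, 0)  # regular fibers have no flipped-out cores
})

test_that("stacking fraction of a frozen optimal fiber ensemble stays high", {
  res <- cached_optimum(21, 146)
  best <- res[[1]]
  expect_lt(best$energy$stacking, -1)  # the optimum itself is stacked
  ens <- suppressWarnings(  # near-zero temperature floors the acceptance rate
    mc_sample(best$conformation, energy_params(),
              mc_params(temperature = 1e-6, n_steps = 3000, seed = 2,
                        record_every = 300)))
  expect_gte(stacking_fraction(ens), 0.8)
})

test_that("Kirkwood sedimentation has its limits and monotonicity", {
  mono <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 1))
  expect_equal(sedimentation(mono)$s20w, 11.1)

  fib <- assemble_fiber(fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 12),
                        relaxed_step())
  s1 <- sedimentation(fib)$s20w
  expect_gt(s1, 11.1)

  squeezed <- fib
  squeezed$centers <- fib$centers / 2
  s2 <- sedimentation(squeezed)$s20w
  expect_gt(s2, s1)

  both <- fib
  both$centers <- fib$centers * 0  # coincident centers are degenerate
  expect_error(sedimentation(both), "degenerate")
})
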