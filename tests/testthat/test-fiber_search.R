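small_start <- function(L = 15, n = 3) {
  assemble_fiber(fiber_spec(L = L, L_NCP = 147, n_nucleosomes = n),
                 relaxed_step())
}

test_that("identical seeds give bit-identical MC trajectories", {
  start <- small_start()
  ep <- energy_params()
  mcp <- mc_params(n_steps = 5000, seed = 99, record_every = 100)
  e1 <- mc_sample(start, ep, mcp)
  e2 <- mc_sample(start, ep, mcp)
  expect_identical(e1$energies, e2$energies)
  expect_identical(e1$snap_centers, e2$snap_centers)

  e3 <- mc_sample(start, ep, mc_params(n_steps = 5000, seed = 100, record_every = 100))
  expect_false(identical(e1$energies, e3$energies))
})

test_that("ensembles respect their bookkeeping invariants", {
  start <- small_start()
  ens <- mc_sample(start, energy_params(),
                   mc_params(n_steps = 4000, seed = 5, record_every = 200))
  expect_equal(ens$n_snapshots, 4000 / 200)
  expect_gt(ens$acceptance_rate, 0)
  expect_lt(ens$acceptance_rate, 1)
  expect_length(post_burnin(ens), ens$n_snapshots - ens$burnin)

  snap <- ensemble_snapshot(ens, ens$n_snapshots)
  expect_s3_class(snap, "fiber_conformation")
  expect_equal(nrow(snap$origins), nrow(start$origins))
})

test_that("the zero-temperature limit collapses onto the start", {
  start <- small_start()
  # near-zero temperature drives the acceptance rate to the floor, which
  # the sampler rightly warns about
  expect_warning(
    ens <- mc_sample(start, energy_params(),
                     mc_params(temperature = 1e-6, n_steps = 5000, seed = 3,
                               record_every = 250)),
    "acceptance rate")
  expect_true(all(diff(ens$energies) <= 1e-4))
})

test_that("optimization finds feasible two-start minima with consistent labels", {
  res <- cached_optimum(20, 147)
  expect_gt(length(res), 0)
  energies <- vapply(res, function(o) o$energy$total, numeric(1))
  expect_true(!is.unsorted(energies))
  for (o in res) {
    expect_false(o$energy$excluded_volume_violated)
    expect_identical(o$family,
                     if (o$topology$dLk_per_nucleosome <= -1.25) "T2" else "T1")
    expect_lte(abs(o$topology$dLk_per_nucleosome), 2.5)
  }
})

test_that("an impossible hard core yields the infeasibility report", {
  res <- optimize_regular_fiber(
    fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 4),
    params = energy_params(core_radius = 40, core_half_height = 20,
                           adjacent_center_floor = 60),
    starts = 3, seed = 1)
  expect_length(res, 0)
  expect_match(attr(res, "reason"), "feasible|minima")
})

test_that("a single-L scan agrees with the optimizer it wraps", {
  tab <- scan_linkers(20, 22, by = 2, L_NCP = 147, n_nucleosomes = 6,
                      starts = 4, seed = 3)
  expect_true(all(c(20, 22) %in% tab$L))
  direct <- optimize_regular_fiber(
    fiber_spec(L = 20, L_NCP = 147, n_nucleosomes = 6),
    starts = 4, seed = 3 + 1009L * 20L)
  sub <- tab[tab$L == 20 & !is.na(tab$dLk_per_nucleosome), ]
  expect_equal(nrow(sub), length(direct))
  expect_equal(sub$dLk_per_nucleosome[1],
               direct[[1]]$topology$dLk_per_nucleosome, tolerance = 1e-9)
  expect_error(scan_linkers(5, 80), "10 <= L_min")
})

test_that("MC parameter validation holds", {
  expect_error(mc_params(n_steps = 0), "positive")
  expect_error(mc_params(n_steps = 100, record_every = 1000), "record_every")
})
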