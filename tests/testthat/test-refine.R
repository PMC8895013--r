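# shared noise-free simulation for the refinement tests
refine_fixture <- local({
  st <- make_toy_structure("bent_triatomic_P1")
  src <- synthetic_density_source("spherical_promolecule")
  rs <- simulate_reflections(st, src, d_min = 0.7)
  list(st = st, src = src, rs = rs)
})

test_that("refinement started at the truth does not move", {
  fx <- refine_fixture
  ffr <- ff_iam(fx$st, fx$src, fx$rs$hkl)
  res <- refine_lsq(fx$st, fx$rs, ffr$ff, ffr$images)
  expect_true(res$converged)
  expect_lt(res$wr2, 1e-10)
  expect_lt(max_position_error(res$structure, fx$st), 1e-10)
  expect_equal(res$scale, 1, tolerance = 1e-8)
})

test_that("perturbed parameters are recovered from noise-free data", {
  fx <- refine_fixture
  set.seed(20)
  pert <- perturb_structure(fx$st, dist = 0.05, u_factor = 1.2)
  ffr <- ff_iam(pert, fx$src, fx$rs$hkl)
  res <- refine_lsq(pert, fx$rs, ffr$ff, ffr$images)
  expect_true(res$converged)
  expect_lt(res$wr2, 1e-8)
  expect_lt(max_position_error(res$structure, fx$st), 1e-4)
  for (i in seq_along(fx$st$atoms))
    expect_lt(max(abs(res$structure$atoms[[i]]$uaniso - fx$st$atoms[[i]]$uaniso)),
              1e-5)
  # objective history is non-increasing over accepted cycles
  expect_true(all(diff(res$f_history) <= 0))
})

test_that("an atom on an inversion centre never moves", {
  st <- make_toy_structure("special_position_toy")
  src <- synthetic_density_source("spherical_promolecule")
  rs <- simulate_reflections(st, src, d_min = 0.75, noise = 0.02, seed = 21)
  res <- har_iterate(st, rs, src, refinement_settings(max_har_cycles = 0))
  expect_equal(res$structure$atoms[[1]]$frac_pos, c(0, 0, 0))
})

test_that("objective is invariant under re-indexing and lattice translation", {
  fx <- refine_fixture
  ffr <- ff_iam(fx$st, fx$src, fx$rs$hkl)
  set.seed(22)
  pert <- perturb_structure(fx$st, dist = 0.02)
  prob <- refinement_problem(pert, fx$rs, ffr$ff, ffr$images,
                             refinement_settings())
  f0 <- prob$fn(prob$p0)
  # permute the reflection list
  ord <- sample(nrow(fx$rs$hkl))
  rs2 <- reflection_set(fx$rs$hkl[ord, ], fx$rs$fo2[ord], fx$rs$sigma[ord],
                        fx$rs$wavelength)
  ffr2 <- ff_iam(pert, fx$src, rs2$hkl)
  prob2 <- refinement_problem(pert, rs2, ffr2$ff, ffr2$images,
                              refinement_settings())
  expect_equal(prob2$fn(prob2$p0), f0, tolerance = 1e-10)
  # translate the whole structure by a lattice vector
  shifted <- pert
  for (i in seq_along(shifted$atoms))
    shifted$atoms[[i]]$frac_pos <- shifted$atoms[[i]]$frac_pos + c(1, -1, 2)
  prob3 <- refinement_problem(shifted, fx$rs, ffr$ff, ffr$images,
                              refinement_settings())
  expect_equal(prob3$fn(prob3$p0), f0, tolerance = 1e-8)
})

test_that("analytic gradients match finite differences for every parameter class", {
  # seeded P-1 structure exercising positions, aniso U, iso U, GC3, GC4
  # and extinction in one objective
  cell <- unit_cell(7, 7.5, 8, 92, 95, 88)
  set.seed(23)
  atoms <- list(
    atom("N1", "N", c(0.12, 0.23, 0.31),
         uaniso = c(0.012, 0.010, 0.014, 0.002, -0.001, 0.001),
         gc3 = rnorm(10, sd = 5e-4), gc4 = rnorm(15, sd = 5e-5)),
    atom("H1", "H", c(0.22, 0.33, 0.38), uiso = 0.03)
  )
  st <- crystal_structure(cell, list(symop(diag(3)), symop(-diag(3))), atoms)
  src <- synthetic_density_source("spherical_promolecule")
  rs <- simulate_reflections(st, src, d_min = 0.8, noise = 0.05, seed = 23)
  ffr <- ff_iam(st, src, rs$hkl)
  settings <- refinement_settings(gc3_atoms = "N1", gc4_atoms = "N1",
                                  refine_extinction = TRUE, fix_origin = FALSE)
  prob <- refinement_problem(st, rs, ffr$ff, ffr$images, settings)
  p <- prob$p0 + rnorm(length(prob$p0), sd = 1e-4)  # off the optimum
  g <- prob$gr(p)
  g_fd <- fd_gradient(prob$fn, p, h = 1e-6)
  expect_lt(max(abs(g - g_fd) / pmax(abs(g_fd), 1e-6 * max(abs(g_fd)))), 1e-5)
})

test_that("extinction refined on extinction-free data converges to zero", {
  fx <- refine_fixture
  res <- har_iterate(fx$st, fx$rs, fx$src,
                     refinement_settings(max_har_cycles = 0,
                                         refine_extinction = TRUE))
  expect_lt(abs(res$extinction), 1e-6)
  expect_lt(res$wr2, 1e-10)
})

test_that("degenerate outer loop reproduces the IAM refinement", {
  fx <- refine_fixture
  set.seed(24)
  pert <- perturb_structure(fx$st, dist = 0.03)
  res0 <- har_iterate(pert, fx$rs, fx$src,
                      refinement_settings(max_har_cycles = 0))
  ffr <- ff_iam(pert, fx$src, fx$rs$hkl)
  res_direct <- refine_lsq(pert, fx$rs, ffr$ff, ffr$images)
  expect_equal(res0$wr2, res_direct$wr2, tolerance = 1e-10)
  expect_equal(res0$har_cycles, 0L)
  expect_lt(max_position_error(res0$structure, res_direct$structure), 1e-10)
})

test_that("spherical-source HAR outer loop converges immediately", {
  # spherical form factors do not change with small shifts, so beyond the
  # first density cycle at most one more is needed
  fx <- refine_fixture
  set.seed(25)
  pert <- perturb_structure(fx$st, dist = 0.02)
  res <- har_iterate(pert, fx$rs, fx$src,
                     refinement_settings(max_har_cycles = 5,
                                         grid_spacing = 0.15))
  expect_true(res$har_converged)
  expect_lte(res$har_cycles, 3)
})

test_that("significance cutoff is applied once before refinement", {
  fx <- refine_fixture
  rs_noisy <- simulate_reflections(fx$st, fx$src, d_min = 0.7, noise = 0.1,
                                   seed = 26)
  res <- har_iterate(fx$st, rs_noisy, fx$src,
                     refinement_settings(max_har_cycles = 0, fsig_cutoff = 3))
  kept <- filter_significance(rs_noisy, 3)
  expect_equal(length(res$fc), nrow(kept$hkl))
})
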