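# shared small promolecule fixture: one C atom in a cubic box
grid_fixture <- local({
  cell <- unit_cell(8, 8, 8)
  src <- synthetic_density_source("spherical_promolecule")
  at <- atom("C1", "C", c(0.3, 0.4, 0.55))
  shape <- grid_shape_for_spacing(cell, 0.1)
  pm <- promolecule_on_grid(list(at), list(C = src$proatom("C")), shape, cell)
  list(cell = cell, src = src, at = at, shape = shape, pm = pm)
})

test_that("promolecule grid integrates to the electron count", {
  # valence density of C carries 4 electrons; 0.1 A spacing, 0.1% tolerance
  expect_equal(grid_integral(grid_fixture$pm$total), 4, tolerance = 1e-3)
})

test_that("promolecule is periodic and additive", {
  fx <- grid_fixture
  at2 <- fx$at
  at2$frac_pos <- fx$at$frac_pos + c(1, -2, 3)  # full lattice translation
  pm2 <- promolecule_on_grid(list(at2), list(C = fx$src$proatom("C")),
                             fx$shape, fx$cell)
  expect_equal(pm2$total$values, fx$pm$total$values, tolerance = 1e-12)
  atb <- atom("N1", "N", c(0.7, 0.2, 0.1))
  pros <- list(C = fx$src$proatom("C"), N = fx$src$proatom("N"))
  both <- promolecule_on_grid(list(fx$at, atb), pros, fx$shape, fx$cell)
  single_n <- promolecule_on_grid(list(atb), pros, fx$shape, fx$cell)
  expect_equal(both$total$values,
               fx$pm$total$values + single_n$total$values, tolerance = 1e-12)
  expect_equal(both$total$values,
               both$per_atom[[1]]$values + both$per_atom[[2]]$values)
  expect_error(promolecule_on_grid(list(atom("Xx1", "S", c(0, 0, 0))),
                                   pros, fx$shape, fx$cell), "pro-atom density")
})

test_that("Hirshfeld partition conserves the valence density", {
  fx <- grid_fixture
  atb <- atom("N1", "N", c(0.55, 0.45, 0.5))
  pros <- list(C = fx$src$proatom("C"), N = fx$src$proatom("N"))
  pm <- promolecule_on_grid(list(fx$at, atb), pros, fx$shape, fx$cell)
  parts <- hirshfeld_partition(pm$total, pm$per_atom)
  # valence := promolecule -> each atom recovers its own pro contribution
  expect_equal(parts[[1]]$values, pm$per_atom[[1]]$values, tolerance = 1e-12)
  expect_equal(parts[[2]]$values, pm$per_atom[[2]]$values, tolerance = 1e-12)
  # conservation for an arbitrary valence density where promolecule > eps
  arb <- density_grid(pm$total$values * (1 + 0.3 * sin(seq_len(length(pm$total$values)))),
                      fx$cell)
  dim(arb$values) <- fx$shape
  parts <- hirshfeld_partition(arb, pm$per_atom)
  total <- parts[[1]]$values + parts[[2]]$values
  denom <- pm$total$values
  expect_lt(max(abs(total - arb$values)[denom > 1e-30]), 1e-10)
  # one-atom cell: partition is the identity
  parts1 <- hirshfeld_partition(fx$pm$total, fx$pm$per_atom)
  expect_equal(parts1[[1]]$values, fx$pm$total$values, tolerance = 1e-12)
  bad <- density_grid(array(0, fx$shape + 2L), fx$cell)
  expect_error(hirshfeld_partition(bad, fx$pm$per_atom), "shape")
})

test_that("grid form factors match the closed-form Gaussian transform", {
  fx <- grid_fixture
  hkl <- as.matrix(expand.grid(h = 0:6, k = c(0, 2), l = c(0, 3)))
  f <- grid_form_factor(fx$pm$per_atom[[1]], fx$at$frac_pos, hkl)
  expect_equal(Re(f[1]), 4, tolerance = 1e-3)  # f(000) = valence count
  expect_lt(max(abs(Im(f))), 1e-6)             # spherical atom, recentred
  s <- resolution(hkl, fx$cell)
  sh <- gridhar:::synthetic_element_shells("C")$valence
  f_ref <- gaussian_mixture_ff(sh$n, sh$alpha, s)
  expect_equal(Re(f), f_ref, tolerance = 1e-3)
})

test_that("grid form factors are invariant when atom and density move together", {
  fx <- grid_fixture
  hkl <- rbind(c(1, 0, 0), c(2, 3, 1), c(5, -2, 4))
  f1 <- grid_form_factor(fx$pm$per_atom[[1]], fx$at$frac_pos, hkl)
  # shift by a whole number of grid steps so the sampled values translate
  delta <- c(7, -3, 11) / fx$shape
  at2 <- fx$at; at2$frac_pos <- fx$at$frac_pos + delta
  pm2 <- promolecule_on_grid(list(at2), list(C = fx$src$proatom("C")),
                             fx$shape, fx$cell)
  f2 <- grid_form_factor(pm2$per_atom[[1]], at2$frac_pos, hkl)
  expect_equal(f2, f1, tolerance = 1e-10)
})

test_that("hkl beyond the Nyquist limit is refused by name", {
  fx <- grid_fixture
  expect_error(grid_form_factor(fx$pm$total, fx$at$frac_pos,
                                rbind(c(0, 0, 0), c(45, 0, 0))),
               "45.*Nyquist|Nyquist.*45")
})

test_that("Fourier interpolation preserves integral and band-limited values", {
  cell <- unit_cell(6, 6, 6)
  n <- 12L
  fr <- gridhar:::axis_frac(n)
  g <- expand.grid(x = fr, y = fr, z = fr)
  # band-limited field: a few low-order Fourier modes
  fvals <- function(x, y, z)
    1 + 0.5 * cos(2 * pi * (2 * x - y)) + 0.25 * sin(2 * pi * (x + z)) +
      0.1 * cos(2 * pi * 3 * y)
  grid <- density_grid(array(fvals(g$x, g$y, g$z), rep(n, 3)), cell)
  expect_identical(interpolate_grid(grid, 1), grid)
  fine <- interpolate_grid(grid, 3)
  expect_equal(grid_integral(fine), grid_integral(grid), tolerance = 1e-12)
  frf <- gridhar:::axis_frac(3L * n)
  gf <- expand.grid(x = frf, y = frf, z = frf)
  expect_equal(fine$values, array(fvals(gf$x, gf$y, gf$z), rep(3L * n, 3)),
               tolerance = 1e-10)
  # even-size Nyquist handling keeps real output real and DC exact
  set.seed(9)
  rnd <- density_grid(array(rnorm(8^3), rep(8L, 3)), cell)
  up <- interpolate_grid(rnd, 2)
  expect_equal(grid_integral(up), grid_integral(rnd), tolerance = 1e-12)
})
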