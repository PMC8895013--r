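test_that("Debye-Waller factors match the Cartesian-frame oracle", {
  cl <- unit_cell(10, 10, 10)
  at0 <- atom("A", "C", c(0, 0, 0), uaniso = rep(0, 6))
  hkl <- rbind(c(1, 2, 3), c(4, 0, 1))
  expect_equal(debye_waller(hkl, at0, cl), c(1, 1))
  # cubic cell: anisotropic U = u I equals the isotropic formula
  u <- 0.015
  at_a <- atom("A", "C", c(0, 0, 0), uaniso = c(u, u, u, 0, 0, 0))
  at_i <- atom("A", "C", c(0, 0, 0), uiso = u)
  expect_equal(debye_waller(hkl, at_a, cl), debye_waller(hkl, at_i, cl),
               tolerance = 1e-12)
  # triclinic: T = exp(-2 pi^2 q' U_cart q) with q the reciprocal vector
  cl <- unit_cell(5.78, 6.15, 12.32, 85.2, 92.1, 104.3)
  u6 <- c(0.021, 0.018, 0.025, 0.003, -0.002, 0.004)
  at_t <- atom("A", "C", c(0, 0, 0), uaniso = u6)
  Ucart <- u_cif_to_cart(u6, cl)
  Bstar <- t(solve(orthogonalization_matrix(cl)))
  set.seed(10)
  for (i in 1:6) {
    h <- sample(-6:6, 3, TRUE)
    q <- as.numeric(Bstar %*% h)
    expect_equal(debye_waller(h, at_t, cl),
                 exp(-2 * pi^2 * as.numeric(t(q) %*% Ucart %*% q)),
                 tolerance = 1e-10)
  }
})

test_that("Gram-Charlier multiplier agrees with the naive full contraction", {
  expect_equal(gram_charlier(c(2, 3, 1)), 1 + 0i)
  set.seed(11)
  gc3 <- rnorm(10, sd = 1e-3)
  gc4 <- rnorm(15, sd = 1e-4)
  # pure third order: real part exactly 1 (i^3 parity)
  m3 <- gram_charlier(rbind(c(1, 2, 3), c(4, -1, 2)), gc3 = gc3)
  expect_equal(Re(m3), c(1, 1))
  for (i in 1:6) {
    h <- sample(-5:5, 3, TRUE)
    expect_equal(gram_charlier(h, gc3, gc4)[1],
                 naive_gram_charlier(h, gc3, gc4), tolerance = 1e-12)
  }
})

test_that("structure factors obey point-atom and centrosymmetric limits", {
  cl <- unit_cell(10, 10, 10)
  st <- crystal_structure(cl, atoms = list(atom("A", "C", c(0, 0, 0),
                                                uaniso = rep(0, 6))))
  hkl <- rbind(c(1, 0, 0), c(2, 3, 1), c(5, 5, 5))
  images <- expand_to_p1(st)
  ff <- matrix(6 + 0i, nrow(hkl), 1)  # f = Z, U = 0
  expect_equal(calc_structure_factors(st, images, ff, hkl),
               rep(6 + 0i, 3), tolerance = 1e-12)
  # centrosymmetric pair: Fc = 2 f T cos(2 pi h.x), imaginary part 0
  st2 <- crystal_structure(cl, list(symop(diag(3)), symop(-diag(3))),
                           list(atom("A", "N", c(0.1, 0.2, 0.3),
                                     uaniso = c(0.01, 0.01, 0.01, 0, 0, 0))))
  img2 <- expand_to_p1(st2)
  ff2 <- matrix(3.5 + 0i, nrow(hkl), 2)
  fc <- calc_structure_factors(st2, img2, ff2, hkl)
  Tdw <- debye_waller(hkl, st2$atoms[[1]], cl)
  expect_equal(Im(fc), rep(0, 3), tolerance = 1e-12)
  expect_equal(Re(fc),
               2 * 3.5 * Tdw * cos(2 * pi * as.numeric(hkl %*% c(0.1, 0.2, 0.3))),
               tolerance = 1e-12)
})

test_that("FFT pipeline matches the direct-summation oracle on 5 random atoms", {
  set.seed(12)
  cell <- unit_cell(8, 8.5, 9)
  els <- c("C", "N", "O", "H", "C")
  atoms <- lapply(1:5, function(i)
    atom(paste0("A", i), els[i], runif(3),
         uaniso = c(0.01, 0.011, 0.012, 0.001, -0.001, 0.002) * runif(1, 0.8, 1.2)))
  st <- crystal_structure(cell, atoms = atoms)
  hkl <- enumerate_hkl(cell, 0.9)[1:150, ]
  src <- synthetic_density_source("spherical_promolecule")
  ffr <- ff_from_source(st, src, hkl, spacing = 0.08)
  fc <- calc_structure_factors(st, ffr$images, ffr$ff, hkl)
  fc_ref <- direct_sum_fc(st, hkl)
  expect_lt(max(Mod(fc - fc_ref) / Mod(fc_ref)), 1e-6)
})

test_that("extinction correction follows the squared Fc* convention", {
  cl <- unit_cell(10, 10, 10)
  hkl <- rbind(c(1, 1, 0), c(3, 2, 1), c(5, 0, 2))
  fc2 <- c(1e4, 500, 50)
  expect_identical(apply_extinction(fc2, hkl, 0.71, cl, 0), fc2)
  # strictly decreasing in x
  xs <- seq(0, 5, by = 0.5)
  vals <- vapply(xs, function(x) apply_extinction(fc2[1], hkl[1, , drop = FALSE],
                                                  0.71, cl, x), numeric(1))
  expect_true(all(diff(vals) < 0))
  # hand evaluation of the stated expression at sin(2 theta) = 0.5
  lam <- 0.71; x <- 1; f2 <- 1e4
  s <- resolution(c(3, 2, 1), cl)
  st_ <- s * lam; s2t <- 2 * st_ * sqrt(1 - st_^2)
  expect_equal(apply_extinction(f2, c(3, 2, 1), lam, cl, x),
               f2 * (1 + 0.001 * x * f2 * lam^3 / s2t)^(-0.5), tolerance = 1e-12)
  expect_equal(f2 * (1 + 0.001 * 1 * f2 * 0.71^3 / 0.5)^(-0.5),
               f2 / sqrt(1 + 0.001 * f2 * 0.71^3 / 0.5))
})

test_that("optimal scale matches a 1-d golden-section scan", {
  expect_equal(optimal_scale(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 1)
  expect_equal(optimal_scale(2 * c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 2)
  set.seed(13)
  fo2 <- runif(50, 1, 100); sig <- runif(50, 0.5, 3); fc2 <- fo2 * runif(50, 0.7, 1.3)
  k <- optimal_scale(fo2, sig, fc2)
  k_scan <- stats::optimize(function(k) sum((fo2 - k * fc2)^2 / sig^2),
                            c(0, 10), tol = 1e-10)$minimum
  expect_equal(k, k_scan, tolerance = 1e-8)
  expect_error(optimal_scale(fo2, sig, rep(0, 50)), "zero")
})

test_that("wR2 reproduces the spreadsheet formula", {
  expect_equal(wr2(c(4, 9), c(1, 2), c(2, 4.5), 2), 0)
  expect_equal(wr2(4, 1, 2, 1), 0.5)
  set.seed(14)
  fo2 <- runif(30, 1, 50); sig <- runif(30, 0.5, 2); fc2 <- runif(30, 1, 50)
  k <- 1.2
  w <- 1 / sig^2
  expect_equal(wr2(fo2, sig, fc2, k),
               sqrt(sum(w * (fo2 - k * fc2)^2) / sum(w * fo2^2)),
               tolerance = 1e-12)
})
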