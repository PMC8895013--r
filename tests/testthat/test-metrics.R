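test_that("Blessing ADP scaling recovers constructed (q, DeltaU) exactly", {
  set.seed(30)
  u_n <- lapply(1:4, function(i) random_psd_u(0.015))
  expect_equal(scale_neutron_adps(u_n, u_n)$q, 1, tolerance = 1e-12)
  expect_equal(scale_neutron_adps(u_n, u_n)$delta_u, matrix(0, 3, 3),
               tolerance = 1e-12)
  du <- diag(c(0.002, 0.001, 0.003))
  u_x <- lapply(u_n, function(u) 1.07 * u + du)
  fit <- scale_neutron_adps(u_x, u_n)
  expect_equal(fit$q, 1.07, tolerance = 1e-12)
  expect_equal(fit$delta_u, du, tolerance = 1e-12)
  expect_lt(fit$residual_rms, 1e-14)
  expect_equal(fit$correct(u_n[[2]]), u_x[[2]], tolerance = 1e-12)
  expect_error(scale_neutron_adps(u_n[1], u_n[1]), "under-determined")
})

test_that("q recovery is unbiased on noisy synthetic inputs", {
  set.seed(31)
  u_n <- lapply(1:6, function(i) random_psd_u(0.015))
  q_true <- 1.05
  du <- diag(c(0.001, -0.0005, 0.002))
  qs <- vapply(1:100, function(rep) {
    u_x <- lapply(u_n, function(u) {
      noise <- matrix(rnorm(9, sd = 5e-4), 3); noise <- (noise + t(noise)) / 2
      q_true * u + du + noise
    })
    scale_neutron_adps(u_x, u_n)$q
  }, numeric(1))
  se <- sd(qs) / sqrt(length(qs))
  expect_lt(abs(mean(qs) - q_true), 2 * se + 1e-12)
})

test_that("bond-length differences follow each structure's own metric", {
  st <- make_toy_structure("diatomic_P1")
  bonds <- data.frame(from = "H1", to = "C1")
  expect_equal(delta_r(st, st, bonds)$delta_r, 0)
  # displace H by +0.01 A along the bond
  st2 <- st
  u <- c(1, 1, 0) / sqrt(2)
  st2$atoms[[2]]$frac_pos <- st2$atoms[[2]]$frac_pos +
    cart_to_frac(0.01 * u, st$cell)
  d <- delta_r(st2, st, bonds)
  expect_equal(d$delta_r, 0.01, tolerance = 1e-10)
  expect_equal(d$abs_delta_r, 0.01, tolerance = 1e-10)
  # antisymmetric under swapping the structures
  expect_equal(delta_r(st, st2, bonds)$delta_r, -d$delta_r)
  # triclinic case against the Cartesian-coordinates oracle
  cl <- unit_cell(6.1, 7.2, 8.3, 95, 101, 84)
  a1 <- atom("C1", "C", c(0.2, 0.3, 0.4)); a2 <- atom("H1", "H", c(0.31, 0.36, 0.47))
  stt <- crystal_structure(cl, atoms = list(a1, a2))
  d_cart <- sqrt(sum((frac_to_cart(a1$frac_pos, cl) -
                        frac_to_cart(a2$frac_pos, cl))^2))
  expect_equal(delta_r(stt, stt, data.frame(from = "C1", to = "H1"))$r_a,
               d_cart, tolerance = 1e-10)
  expect_error(delta_r(st, st, data.frame(from = "H9", to = "C1")), "H9")
})

test_that("S12 matches the numeric Gaussian-overlap quadrature", {
  set.seed(32)
  u1 <- random_psd_u(0.015)
  expect_equal(s12(u1, u1), 0, tolerance = 1e-12)
  for (i in 1:4) {
    a <- random_psd_u(0.02); b <- random_psd_u(0.02)
    expect_equal(s12(a, b), s12(b, a), tolerance = 1e-12)
    expect_gt(s12(a, b), 0)
    # invariant under a common rotation
    th <- runif(1, 0, pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    expect_equal(s12(R %*% a %*% t(R), R %*% b %*% t(R)), s12(a, b),
                 tolerance = 1e-10)
  }
  # isotropic U2 = c U1 against the brute-force overlap integral
  u1 <- diag(rep(0.02, 3))
  u2 <- 1.5 * u1
  expect_equal(s12(u1, u2), numeric_s12(u1, u2), tolerance = 1e-4)
  expect_error(s12(diag(c(1, 1, -1)) * 0.01, u1), "positive definite")
})

test_that("hydrogen bonding motifs classify by the geometric criteria", {
  # methane-like fragment: all C-H
  cl <- unit_cell(10, 10, 10)
  ch <- crystal_structure(cl, atoms = list(
    atom("C1", "C", c(0.5, 0.5, 0.5)),
    atom("H1", "H", c(0.5, 0.5, 0.5) + cart_to_frac(c(1.09, 0, 0), cl)),
    atom("H2", "H", c(0.5, 0.5, 0.5) + cart_to_frac(c(-0.36, 1.03, 0), cl))))
  cls <- classify_bonds(ch)
  expect_true(all(cls$class == "C-H"))
  # water dimer toy: O1-H1...O2 at 1.9 A, angle about 165 degrees
  o1 <- c(0.3, 0.3, 0.3)
  h1 <- o1 + cart_to_frac(c(0.96, 0, 0), cl)
  o2_near <- h1 + cart_to_frac(c(1.9 * cos(0.26), 1.9 * sin(0.26), 0), cl)
  dimer <- crystal_structure(cl, atoms = list(
    atom("O1", "O", o1), atom("H1", "H", h1), atom("O2", "O", o2_near)))
  frg <- c(O1 = 1, H1 = 1, O2 = 2)
  cls <- classify_bonds(dimer, fragments = frg)
  expect_equal(cls$class[cls$h_label == "H1"], "inter X-H...Y")
  expect_equal(cls$acceptor[cls$h_label == "H1"], "O2")
  # same donor and acceptor in one fragment -> intra
  cls_in <- classify_bonds(dimer)
  expect_equal(cls_in$class[cls_in$h_label == "H1"], "intra X-H...Y")
  # stretched acceptor: no hydrogen bond
  o2_far <- h1 + cart_to_frac(c(3.5, 0.5, 0), cl)
  far <- crystal_structure(cl, atoms = list(
    atom("O1", "O", o1), atom("H1", "H", h1), atom("O2", "O", o2_far)))
  cls <- classify_bonds(far)
  expect_equal(cls$class[cls$h_label == "H1"], "other X-H")
  # dangling H warns and is excluded
  lone <- crystal_structure(cl, atoms = list(
    atom("C1", "C", c(0.1, 0.1, 0.1)), atom("H1", "H", c(0.6, 0.6, 0.6))))
  expect_warning(cls <- classify_bonds(lone), "covalent partner")
  expect_true(is.null(cls) || !"H1" %in% cls$h_label)
})

test_that("quality report deviations vanish for identical structures", {
  cl <- unit_cell(9, 9, 9)
  st <- crystal_structure(cl, atoms = list(
    atom("O1", "O", c(0.30, 0.30, 0.30), uaniso = c(0.010, 0.011, 0.012, 0.001, 0, 0)),
    atom("C1", "C", c(0.45, 0.30, 0.30), uaniso = c(0.011, 0.010, 0.013, 0, 0.001, 0)),
    atom("N1", "N", c(0.30, 0.45, 0.30), uaniso = c(0.012, 0.013, 0.010, 0, 0, 0.001)),
    atom("H1", "H", c(0.30, 0.30, 0.30) + cart_to_frac(c(0, 0, 0.96), cl),
         uaniso = c(0.02, 0.022, 0.024, 0.001, 0, 0))))
  rep <- quality_report(st, st, wr2 = 0.02)
  expect_equal(unname(rep$s12["H1"]), 0, tolerance = 1e-10)
  expect_equal(rep$bonds$delta_r, 0, tolerance = 1e-12)
  expect_equal(max(abs(rep$delta_u$delta_u)), 0, tolerance = 1e-12)
  expect_equal(rep$adp_scaling$q, 1, tolerance = 1e-10)
})

test_that("report summaries match an independent order-statistics oracle", {
  v <- c(0.003, -0.001, 0.007, 0.002, -0.004, 0.011, 0.0)
  bs <- gridhar:::box_summary(v)
  expect_equal(bs$median, stats::quantile(v, 0.5, type = 8, names = FALSE))
  expect_equal(bs$q1, stats::quantile(v, 0.25, type = 8, names = FALSE))
  expect_equal(bs$q3, stats::quantile(v, 0.75, type = 8, names = FALSE))
  srt <- sort(v)
  expect_equal(bs$whisker_low, min(srt[srt >= bs$q1 - 1.5 * (bs$q3 - bs$q1)]))
  expect_equal(bs$whisker_high, max(srt[srt <= bs$q3 + 1.5 * (bs$q3 - bs$q1)]))
  expect_equal(bs$mean_abs, mean(abs(v)))
})

test_that("sigma-scaled deviations equal raw deviations at sigma = 1", {
  cl <- unit_cell(9, 9, 9)
  st <- crystal_structure(cl, atoms = list(
    atom("O1", "O", c(0.3, 0.3, 0.3), uaniso = c(0.010, 0.011, 0.012, 0.001, 0, 0)),
    atom("C1", "C", c(0.45, 0.3, 0.3), uaniso = c(0.011, 0.010, 0.013, 0, 0.001, 0)),
    atom("N1", "N", c(0.3, 0.45, 0.3), uaniso = c(0.012, 0.013, 0.010, 0, 0, 0.001)),
    atom("H1", "H", c(0.3, 0.3, 0.3) + cart_to_frac(c(0, 0, 0.96), cl),
         uaniso = c(0.02, 0.022, 0.024, 0.001, 0, 0))))
  ref <- st
  ref$atoms[[4]]$frac_pos <- ref$atoms[[4]]$frac_pos +
    cart_to_frac(c(0, 0, 0.01), cl)
  rep1 <- quality_report(st, ref, sigma_r = 1)
  rep2 <- quality_report(st, ref, sigma_r = 0.002)
  cls <- rep1$bonds$class[1]
  expect_equal(rep1$per_class_r[[cls]]$mean_abs_dr_over_sigma,
               mean(rep1$bonds$abs_delta_r))
  expect_equal(rep2$per_class_r[[cls]]$mean_abs_dr_over_sigma,
               rep1$per_class_r[[cls]]$mean_abs_dr_over_sigma / 0.002)
  # serialization writes JSON and CSV
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_quality_report(rep1, jp, cp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$adp_scaling$q, rep1$adp_scaling$q, tolerance = 1e-10)
  expect_equal(nrow(utils::read.csv(cp)), nrow(rep1$bonds))
})
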