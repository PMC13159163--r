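# Classical nucleation theory machinery: cluster work, critical size and
# barrier, Zeldovich factor, attachment frequency, assembled rates, and the
# closed-form identities they must satisfy.

ctx_ref <- nucleation_context(gamma = 1.8e-6, delta_g = -4e-22,
                              vm = 1.38e-23, c_num = 1.98e23, T = 300)

test_that("molecular volume is Mw/(NA c)", {
  expect_equal(molecular_volume(300, 2500), 1.38378255598e-23, tolerance = 1e-10)
  expect_equal(molecular_volume(0.82, 2500), 5.06261910724e-21, tolerance = 1e-10)
  expect_equal(molecular_volume(600, 2500), molecular_volume(300, 2500) / 2)
  expect_error(molecular_volume(0, 2500), "positive")
})

test_that("cluster work has the right endpoints, maximum and barrier", {
  expect_identical(cluster_work(0, ctx_ref), 0)
  nc <- critical_size_molecules(ctx_ref)
  # the maximum of W(n) sits at n_c = (4/3) pi r_c^3 / vm
  rc <- critical_radius(ctx_ref)
  expect_equal(nc, (4 / 3) * pi * rc^3 / ctx_ref$vm, tolerance = 1e-12)
  eps <- nc * 1e-4
  expect_gt(cluster_work(nc, ctx_ref), cluster_work(nc - eps, ctx_ref))
  expect_gt(cluster_work(nc, ctx_ref), cluster_work(nc + eps, ctx_ref))
  # W(n_c) equals the closed-form barrier
  expect_equal(cluster_work(nc, ctx_ref), critical_work(ctx_ref),
               tolerance = 1e-10)
  expect_error(cluster_work(10, nucleation_context(1e-6, 1e-22, 1e-23, 1e20, 300)),
               "negative")
})

test_that("critical work matches hand arithmetic and its scalings", {
  expect_equal(critical_work(ctx_ref), 1.16306585522e-19, tolerance = 1e-9)
  expect_equal(critical_work(ctx_ref) / kbt(300), 28.08, tolerance = 1e-3)
  ctx2 <- ctx_ref; ctx2$gamma <- 2 * ctx_ref$gamma
  expect_equal(critical_work(ctx2), 8 * critical_work(ctx_ref), tolerance = 1e-12)
  ctx3 <- ctx_ref; ctx3$delta_g <- 2 * ctx_ref$delta_g
  expect_equal(critical_work(ctx3), critical_work(ctx_ref) / 4, tolerance = 1e-12)
})

test_that("critical radius is the Gibbs-Thomson radius", {
  ctx <- ctx_ref; ctx$delta_g <- -1e-21
  expect_equal(critical_radius(ctx), 4.968e-8, tolerance = 1e-10)
  # within the 10-100 nm range over the relevant driving-force span
  for (dg in -c(2e-22, 5e-22, 1e-21, 4e-21)) {
    ctx$delta_g <- dg
    r <- critical_radius(ctx)
    expect_gt(r, 1e-8 * 0.5)
    expect_lt(r, 1.2e-7 * 3)
  }
  # diverges as the driving force vanishes
  ctx$delta_g <- -1e-30
  expect_gt(critical_radius(ctx), 1)
})

test_that("Zeldovich factor agrees with the curvature of cluster work", {
  # independent finite-difference evaluation of z = sqrt(-W''(nc)/(2 pi kBT))
  for (g in c(5e-7, 1.8e-6, 1e-5)) {
    ctx <- ctx_ref; ctx$gamma <- g
    nc <- critical_size_molecules(ctx)
    h <- nc * 1e-4
    wpp <- (cluster_work(nc + h, ctx) - 2 * cluster_work(nc, ctx) +
              cluster_work(nc - h, ctx)) / h^2
    z_fd <- sqrt(-wpp / (2 * pi * kbt(ctx$T)))
    expect_equal(zeldovich(ctx), z_fd, tolerance = 1e-6)
  }
  # z also equals the closed form dg^2 / (8 pi vm sqrt(gamma^3 kBT))
  z_closed <- ctx_ref$delta_g^2 /
    (8 * pi * ctx_ref$vm * sqrt(ctx_ref$gamma^3 * kbt(300)))
  expect_equal(zeldovich(ctx_ref), z_closed, tolerance = 1e-12)
  # z decreases with increasing tension at fixed driving force
  zs <- sapply(c(1e-6, 2e-6, 4e-6), function(g) {
    ctx <- ctx_ref; ctx$gamma <- g; zeldovich(ctx)
  })
  expect_true(all(diff(zs) < 0))
})

test_that("attachment frequency: both printed forms agree, linear in c", {
  set.seed(42)
  for (i in 1:50) {
    ctx <- nucleation_context(gamma = 10^runif(1, -7, -4),
                              delta_g = -10^runif(1, -22, -20),
                              vm = 10^runif(1, -24, -20),
                              c_num = 10^runif(1, 18, 24),
                              T = runif(1, 280, 330))
    nc <- critical_size_molecules(ctx)
    f1 <- (48 * pi^2 * ctx$vm)^(1 / 3) * ctx$c_num * 1e-13 * nc^(1 / 3)
    f2 <- 8 * pi * ctx$c_num * 1e-13 * ctx$gamma * ctx$vm / abs(ctx$delta_g)
    expect_equal(f1, f2, tolerance = 1e-10)
    expect_equal(attachment_frequency(ctx, 1e-13), f1, tolerance = 1e-10)
  }
  ctx2 <- ctx_ref; ctx2$c_num <- 2 * ctx_ref$c_num
  expect_equal(attachment_frequency(ctx2, 1e-13),
               2 * attachment_frequency(ctx_ref, 1e-13), tolerance = 1e-12)
})

test_that("assembled rate equals the collapsed closed form", {
  # J = theta z fc rho_m exp(-Wc/kBT) must equal
  # theta D c |dg| / (vm sqrt(gamma kBT)) exp(-Wc/kBT): verified over a
  # random parameter sweep
  set.seed(7)
  n <- 10000
  gamma <- 10^runif(n, -7, -4)
  dg <- -10^runif(n, -22, -19.5)
  vm <- 10^runif(n, -24, -20)
  cc <- 10^runif(n, 18, 24)
  T <- runif(n, 280, 330)
  kin <- kinetic_params(theta = 1.5e-10, D_plus = 1.3e-13, Mw = 2500)
  idx <- sample(n, 200) # full product evaluation on a subsample
  for (i in idx) {
    ctx <- nucleation_context(gamma[i], dg[i], vm[i], cc[i], T[i])
    J_product <- nucleation_rate(ctx, kin, "void")
    wc <- critical_work(ctx)
    J_closed <- kin$theta * kin$D_plus * cc[i] * abs(dg[i]) /
      (vm[i] * sqrt(gamma[i] * kbt(T[i]))) * exp(-wc / kbt(T[i]))
    if (J_closed > 0) {
      expect_equal(J_product, J_closed, tolerance = 1e-10)
    } else {
      expect_equal(J_product, 0)
    }
  }
  # and the vectorised log-rate core over the whole sweep
  lnJ <- condnuc:::ln_nucleation_rate(gamma, dg, vm, cc, kin$D_plus,
                                      kin$theta, T)
  wc <- (16 * pi / 3) * gamma^3 * vm^2 / dg^2
  lnJ_closed <- log(kin$theta * kin$D_plus * cc * abs(dg) /
                      (vm * sqrt(gamma * kbt(T)))) - wc / kbt(T)
  expect_equal(lnJ, lnJ_closed, tolerance = 1e-10)
})

test_that("rates are zero without supersaturation and scale correctly", {
  kin <- kinetic_params(theta = 1, D_plus = 1e-13, Mw = 2500)
  ctx0 <- nucleation_context(1e-6, 0.0, 1e-23, 1e20, 300)
  expect_identical(nucleation_rate(ctx0, kin, "void"), 0)
  ctx0$delta_g <- 1e-22
  expect_identical(nucleation_rate(ctx0, kin, "condensate"), 0)
  # underflow policy: enormous barrier -> 0, not NaN
  ctx_hi <- nucleation_context(1e-2, -1e-22, 1e-23, 1e20, 300)
  expect_identical(nucleation_rate(ctx_hi, kin, "void"), 0)

  # ln J monotone increasing in |dg| and decreasing in gamma
  dgs <- -seq(2e-22, 2e-21, length.out = 30)
  lnJ_dg <- condnuc:::ln_nucleation_rate(1.8e-6, dgs, 1.38e-23, 1e23,
                                         1e-13, 1, 300)
  expect_true(all(diff(lnJ_dg) > 0))
  gammas <- seq(5e-7, 5e-6, length.out = 30)
  lnJ_g <- condnuc:::ln_nucleation_rate(gammas, -5e-22, 1.38e-23, 1e23,
                                        1e-13, 1, 300)
  expect_true(all(diff(lnJ_g) < 0))
})

test_that("rate has dimensions of m^-3 s^-1 (length-scaling audit)", {
  # multiply all length-bearing quantities by lambda: vm ~ L^3, c ~ L^-3,
  # D ~ L^2, gamma ~ L^-2 (J/m^2 at fixed energy); J must scale as L^-3
  lam <- 1.7
  base <- list(gamma = 2e-6, dg = -5e-22, vm = 2e-23, c = 5e22, D = 1e-13)
  J1 <- exp(condnuc:::ln_nucleation_rate(base$gamma, base$dg, base$vm,
                                         base$c, base$D, 1, 300))
  J2 <- exp(condnuc:::ln_nucleation_rate(base$gamma / lam^2, base$dg,
                                         base$vm * lam^3, base$c / lam^3,
                                         base$D * lam^2, 1, 300))
  expect_equal(J2, J1 / lam^3, tolerance = 1e-9)
})
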