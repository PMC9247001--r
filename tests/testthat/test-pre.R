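# the experimental delay grid used throughout
pre_delays <- c(0, 6, 15, 25, 36, 50, 100) / 1000

test_that("exponential decay fitting recovers rates and applies the 3-sigma gate", {
  I <- rbind(p1 = 100 * exp(-50 * pre_delays),
             p2 = rep(80, length(pre_delays)),        # R2 = 0
             p3 = 100 * exp(-120 * pre_delays))
  fit <- fit_decay(pre_delays, I, noise = 0, mc_iterations = 0)
  expect_equal(fit$R2[fit$peak_id == "p1"], 50, tolerance = 1e-6)
  expect_equal(fit$R2[fit$peak_id == "p2"], 0, tolerance = 1e-8)
  expect_equal(fit$R2[fit$peak_id == "p3"], 120, tolerance = 1e-6)

  # peak at 2 sigma at 6 ms is excluded with the gate reason
  noise <- 0.5 * I["p1", 2]                # I(6ms) == 2 sigma
  fit2 <- fit_decay(pre_delays, I, noise = noise, mc_iterations = 0)
  expect_false("p1" %in% fit2$peak_id)
  exc <- attr(fit2, "excluded")
  expect_equal(exc$reason[exc$peak_id == "p1"], "3-sigma gate")

  expect_error(fit_decay(c(0.006, 0, 0.015), I[, 1:3]), "unsorted|delays")
})

test_that("Monte Carlo decay errors scale roughly linearly with noise", {
  I <- matrix(100 * exp(-40 * pre_delays), 1,
              dimnames = list("p1", NULL))
  sds <- sapply(c(1, 2), function(s)
    fit_decay(pre_delays, I, noise = s, mc_iterations = 150,
              seed = 7)$R2_sd)
  expect_equal(sds[2] / sds[1], 2, tolerance = 0.35)
  expect_gt(sds[1], 0)
})

test_that("gamma2 differences rates with quadrature errors", {
  g <- gamma2(30, 10)
  expect_equal(g$gamma2, 20)
  expect_equal(gamma2(10, 10)$gamma2, 0)
  expect_equal(gamma2(30, 10, 3, 4)$sd, 5)
})

test_that("the SBM rate matches an independent constants evaluation", {
  phys <- pre_physics(tau_r = 30, tau_s = 9.6, frequency_mhz = 600,
                      S = 2.5, g = 2)
  # frozen from an independent scipy-constants evaluation of the same
  # expression (see also the ~3.7e2 magnitude expected at 15 A)
  expect_equal(sbm_gamma2(15, phys), 367.1756, tolerance = 1e-4)
  expect_equal(phys$tau_c, 1 / (1 / 30 + 1 / 9.6))

  # r^-6 law and scaling properties
  expect_equal(sbm_gamma2(30, phys), sbm_gamma2(15, phys) / 64,
               tolerance = 1e-12)
  r <- seq(8, 40, by = 4)
  expect_true(all(diff(sbm_gamma2(r, phys)) < 0))
  f0 <- pre_physics(30, 9.6, 600, bound_fraction = 0)
  expect_equal(sbm_gamma2(15, f0), 0)
  half <- pre_physics(30, 9.6, 600, bound_fraction = 0.5)
  expect_equal(sbm_gamma2(15, half), sbm_gamma2(15, phys) / 2)
  s1 <- pre_physics(30, 9.6, 600, S = 0.5)
  expect_lt(sbm_gamma2(15, s1), sbm_gamma2(15, phys))
})

test_that("Curie-spin relaxation is a minor, field-dependent share for Mn2+", {
  # the standard Curie expression keeps the share below ~6% across
  # plausible rotational correlation times at 600 MHz
  for (tr in c(10, 20, 30, 40)) {
    f <- curie_fraction(pre_physics(tau_r = tr, tau_s = 9.6,
                                    frequency_mhz = 600), 293)
    expect_gt(f, 0); expect_lt(f, 0.06)
  }
  expect_equal(curie_fraction(pre_physics(S = 0)), 0)
  # monotone in B0 at fixed taus
  fr <- sapply(c(400, 600, 800, 1000), function(mhz)
    curie_fraction(pre_physics(30, 9.6, mhz), 293))
  expect_true(all(diff(fr) > 0))
})

test_that("metal position is recovered from noiseless PREs", {
  toy <- get_toy(40, seed = 3)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  truth <- ctr + c(4, 2, -3)
  phys <- pre_physics(30, 9.6, 600, bound_fraction = 0.0241)
  sim <- simulate_pre(truth, meth, phys, noise_frac = 0, seed = 2)
  obs <- setNames(sim$gamma2, sim$key)

  fit <- fit_metal_position(obs, sim$sd, meth, phys,
                            init = truth + c(5, 0, 0),
                            mc_iterations = 0, seed = 4)
  expect_lt(sqrt(sum((fit$coordinates - truth)^2)), 0.1)
  expect_lt(fit$cost, 1e-4)
  expect_lt(fit$Q, 1e-5)

  # cost at the truth position is zero on noiseless data
  co <- array(as.matrix(meth[, c("x", "y", "z")]),
              dim = c(nrow(meth), 3, 1),
              dimnames = list(meth$key, NULL, NULL))
  expect_equal(methylwalk:::.pre_cost(truth, co, obs, sim$sd, phys), 0,
               tolerance = 1e-8)

  # ensemble of two identical models: same optimum, cost scaled by 4
  ens <- build_ensemble(list(toy$structures$A, toy$structures$A))
  fit2 <- fit_metal_position(obs, sim$sd, ens, phys,
                             init = truth + c(5, 0, 0),
                             mc_iterations = 0, seed = 4)
  expect_lt(sqrt(sum((fit2$coordinates - fit$coordinates)^2)), 0.05)

  expect_error(fit_metal_position(setNames(rep(0, 10), meth$key[1:10]),
                                  rep(1, 10), meth, phys, init = ctr),
               "unconstrained")
  expect_error(fit_metal_position(obs[1:3], sim$sd[1:3], meth, phys,
                                  init = ctr), "at least 4")
})

test_that("PRE validation flags swapped assignments and proposes unique matches", {
  toy <- get_toy(40, seed = 3)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  metal <- ctr + c(4, 2, -3)
  phys <- pre_physics(30, 9.6, 600, bound_fraction = 0.0241)
  sim <- simulate_pre(metal, meth, phys, noise_frac = 0, seed = 2)
  truth <- toy$truth$assignment
  obs <- setNames(sim$gamma2[match(truth, sim$key)], names(truth))
  sds <- rep(0.5, length(obs))

  fit <- fit_metal_position(setNames(sim$gamma2, sim$key)[1:20],
                            rep(1, 20), meth, phys,
                            init = metal + c(3, 0, 0),
                            mc_iterations = 0)
  cons <- data.frame(peak_id = names(truth), methyl = unname(truth),
                     count = 8, n_trials = 8, status = "consistent",
                     fixed = FALSE, candidates = "",
                     stringsAsFactors = FALSE)
  ok <- validate_assignment_pre(cons, obs, sds, fit, phys, meth)
  expect_length(ok$flagged, 0)
  expect_gt(nrow(ok$checked), 0)

  # swap two assignments at clearly different radii inside the band
  r <- sqrt(rowSums(sweep(as.matrix(meth[, c("x", "y", "z")]), 2,
                          fit$coordinates)^2))
  names(r) <- meth$key
  inband <- names(r)[r > 11 & r < 28]
  ord <- inband[order(r[inband])]
  k_near <- ord[1]; k_far <- ord[length(ord)]
  p_near <- names(truth)[truth == k_near]
  p_far <- names(truth)[truth == k_far]
  bad <- cons
  bad$methyl[bad$peak_id == p_near] <- k_far
  bad$methyl[bad$peak_id == p_far] <- k_near
  chk <- validate_assignment_pre(bad, obs, sds, fit, phys, meth)
  expect_true(all(c(p_near, p_far) %in% chk$flagged))

  # one unassigned peak with a unique in-band radius match is proposed
  cons2 <- cons
  cons2$status[cons2$peak_id == p_near] <- "ambiguous"
  cons2$methyl[cons2$peak_id == p_near] <- NA
  prop <- validate_assignment_pre(cons2, obs, sds, fit, phys, meth)
  if (nrow(prop$proposed)) {
    expect_equal(prop$proposed$peak_id, p_near)
    expect_equal(prop$proposed$methyl, k_near)
  }
})

test_that("PRE- and PCS-derived metal positions agree on shared truth", {
  toy <- get_toy(40, seed = 3)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  metal <- ctr + c(4, 2, -3)
  truth_tensor <- dchi_tensor(c(2.1, -0.8, 0.5, -0.3, 0.9), metal)
  phys <- pre_physics(30, 9.6, 600, bound_fraction = 0.0241)

  sim_pcs <- simulate_pcs(truth_tensor, meth, noise_hz = 0,
                          bleach_radius = 8)
  m_pcs <- fit_tensor(setNames(sim_pcs$pcs_ppm, sim_pcs$key), meth,
                      init_metal = metal + c(3, -1, 2))$tensor$metal
  sim_pre <- simulate_pre(metal, meth, phys, noise_frac = 0, seed = 2)
  m_pre <- fit_metal_position(setNames(sim_pre$gamma2, sim_pre$key),
                              sim_pre$sd, meth, phys,
                              init = metal + c(-2, 3, 1),
                              mc_iterations = 0)$coordinates
  expect_lt(sqrt(sum((m_pcs - m_pre)^2)), 0.2)
})
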