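test_that("calc_pcs matches the on-axis closed form and the matrix contraction", {
  # axially symmetric tensor, nucleus on the z axis at 10 A:
  # ppm = -(Dxx + Dyy) * 1e4 / (4 pi r^3)  (components in 1e-32 m^3)
  tn <- dchi_tensor(c(-1, -1, 0, 0, 0))
  got <- calc_pcs(tn, matrix(c(0, 0, 10), 1))
  expect_equal(unname(got), 2e4 / (4 * pi * 1e3), tolerance = 1e-12)
  expect_equal(unname(got), 1.59155, tolerance = 1e-5)

  # zero tensor -> zero everywhere
  z <- dchi_tensor(rep(0, 5))
  pos <- matrix(rnorm(30, 0, 15), 10)
  expect_equal(unname(calc_pcs(z, pos)), rep(0, 10))

  # vector form vs independent 3x3 traceless contraction, 1e-12 relative
  set.seed(42)
  for (rep in 1:5) {
    comp <- rnorm(5, 0, 2)
    metal <- rnorm(3, 0, 5)
    pos <- matrix(rnorm(24, 0, 12), 8) + 25
    a <- calc_pcs(dchi_tensor(comp, metal), pos)
    b <- pcs_contraction_oracle(comp, metal, pos)
    expect_equal(unname(a), unname(b), tolerance = 1e-12)
  }
  expect_error(calc_pcs(tn, matrix(c(0, 0, 0), 1)), "coincides")
})

test_that("the PCS field is traceless and rotation invariant", {
  set.seed(7)
  comp <- rnorm(5)
  tn <- dchi_tensor(comp)
  r <- 12
  axes <- rbind(diag(3) * r, -diag(3) * r)
  expect_equal(sum(calc_pcs(tn, axes)), 0, tolerance = 1e-12)

  # rotate coordinates, metal and tensor jointly: field unchanged
  th <- 0.9
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  X <- matrix(c(comp[1], comp[3], comp[4],
                comp[3], comp[2], comp[5],
                comp[4], comp[5], -(comp[1] + comp[2])), 3, 3)
  Xr <- R %*% X %*% t(R)
  tn_r <- dchi_tensor(c(Xr[1, 1], Xr[2, 2], Xr[1, 2], Xr[1, 3],
                        Xr[2, 3]), as.vector(R %*% tn$metal))
  pos <- matrix(rnorm(15, 0, 10), 5) + 20
  expect_equal(unname(calc_pcs(tn_r, pos %*% t(R))),
               unname(calc_pcs(tn, pos)), tolerance = 1e-10)
})

test_that("pcs_from_shifts differences dia/para peaks with unit conversion", {
  dia <- data.frame(peak_id = c("p1", "p2"), delta_H = c(1.0, 0.8),
                    delta_C = c(20, 22), stringsAsFactors = FALSE)
  para <- dia; para$peak_id <- c("q1", "q2")
  same <- pcs_from_shifts(dia, para, c(p1 = "q1", p2 = "q2"), 500)
  expect_equal(same$pcs_ppm, c(0, 0))

  para2 <- para; para2$delta_H <- para$delta_H + c(0.10, -0.02)
  d <- pcs_from_shifts(dia, para2, c(p1 = "q1", p2 = "q2"), 500)
  expect_equal(d$pcs_hz, c(50, -10))

  part <- pcs_from_shifts(dia, para, c(p1 = "q1", p2 = "missing"))
  expect_equal(attr(part, "unmatched"), "p2")
  expect_equal(nrow(part), 1)
})

test_that("q_factor implements the ensemble formula", {
  expect_equal(q_factor(c(3, 4), c(3, 0)), 0.8)     # sqrt(16/25)
  obs <- c(1.5, -2, 3)
  expect_equal(q_factor(obs, obs), 0)
  expect_equal(q_factor(obs, rep(0, 3)), 1)
  expect_error(q_factor(c(0, 0), c(1, 2)), "zero")
  # two identical models reduce to the single-model Q
  calc <- c(1.2, -1.8, 2.4)
  expect_equal(q_factor(obs, cbind(calc, calc)), q_factor(obs, calc))
})

test_that("tensor fits recover truth from noiseless synthetic PCS", {
  toy <- get_toy(40, seed = 3)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  truth <- dchi_tensor(c(2.1, -0.8, 0.5, -0.3, 0.9), ctr + c(4, 2, -3))
  sim <- simulate_pcs(truth, meth, noise_hz = 0, bleach_radius = 8)
  obs <- setNames(sim$pcs_ppm, sim$key)

  fit <- fit_tensor(obs, meth, init_metal = truth$metal + c(3, -2, 1))
  expect_lt(max(abs(fit$tensor$components - truth$components) /
                  abs(truth$components)), 0.01)
  expect_lt(sqrt(sum((fit$tensor$metal - truth$metal)^2)), 0.1)

  # fixed metal at the truth position: essentially perfect fit
  fit2 <- fit_tensor(obs, meth, init_metal = truth$metal,
                     move_metal = FALSE)
  expect_lt(fit2$report$Q, 1e-8)

  # a single-model ensemble equals the direct table fit
  ens <- build_ensemble(list(toy$structures$A))
  fit3 <- fit_tensor(obs, ens, init_metal = truth$metal,
                     move_metal = FALSE)
  expect_equal(fit3$tensor$components, fit2$tensor$components,
               tolerance = 1e-9)

  expect_error(fit_tensor(obs[1:6], meth, truth$metal), "underdetermined")
})

test_that("UTR diagonalization preserves principal values and conventions", {
  # already-diagonal tensor
  tn <- dchi_tensor(c(1, -3, 0, 0, 0))   # eigenvalues 1, -3, zz = 2
  u <- to_utr(tn)
  expect_equal(sort(unname(u$eigenvalues)), c(-3, 1, 2))
  expect_gte(abs(u$ax), 1.5 * abs(u$rh))

  # rotated copy: same (ax, rh), different frame
  set.seed(11)
  comp <- c(2.5, -1.2, 0.7, 0.4, -0.9)
  th <- 1.1
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3)
  X <- matrix(c(comp[1], comp[3], comp[4],
                comp[3], comp[2], comp[5],
                comp[4], comp[5], -(comp[1] + comp[2])), 3, 3)
  Xr <- R %*% X %*% t(R)
  u1 <- to_utr(dchi_tensor(comp))
  u2 <- to_utr(dchi_tensor(c(Xr[1, 1], Xr[2, 2], Xr[1, 2], Xr[1, 3],
                             Xr[2, 3])))
  expect_equal(u2$ax, u1$ax, tolerance = 1e-10)
  expect_equal(u2$rh, u1$rh, tolerance = 1e-10)

  # eigen-decomposition oracle on random symmetric traceless matrices
  for (rep in 1:5) {
    comp <- rnorm(5)
    u <- to_utr(dchi_tensor(comp))
    M <- matrix(c(comp[1], comp[3], comp[4],
                  comp[3], comp[2], comp[5],
                  comp[4], comp[5], -(comp[1] + comp[2])), 3, 3)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sort(unname(u$eigenvalues)), sort(ev),
                 tolerance = 1e-10)
    expect_equal(sum(u$eigenvalues), 0, tolerance = 1e-10)
  }

  # degenerate (axial) tensor: angles flagged undefined
  ua <- to_utr(dchi_tensor(c(1, 1, 0, 0, 0)))
  expect_true(ua$degenerate)
  expect_true(is.na(ua$gamma))
})

test_that("bootstrap SDs vanish on noiseless data and grow with noise", {
  toy <- get_toy(40, seed = 3)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  truth <- dchi_tensor(c(2.1, -0.8, 0.5, -0.3, 0.9), ctr + c(4, 2, -3))

  sds <- sapply(c(0, 1, 2, 4), function(s) {
    sim <- simulate_pcs(truth, meth, noise_hz = s, bleach_radius = 8,
                        seed = 5)
    obs <- setNames(sim$pcs_ppm, sim$key)
    bt <- bootstrap_tensor(obs, meth, init_metal = truth$metal,
                           move_metal = FALSE, iterations = 40,
                           seed = 9)
    max(bt$sd[1:5])
  })
  expect_lt(sds[1], 1e-8)
  expect_true(all(diff(sds) > 0))   # monotone in sigma over 1, 2, 4 Hz

  sim <- simulate_pcs(truth, meth, noise_hz = 1)
  expect_error(bootstrap_tensor(setNames(sim$pcs_ppm, sim$key), meth,
                                truth$metal, iterations = 1),
               "iterations")
})

test_that("opposite orientation is a negative field correlation", {
  toy <- get_toy(25, seed = 12)
  meth <- toy$methyls$A
  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  tn <- dchi_tensor(c(2, -1, 0.4, 0.2, -0.6), ctr + c(5, 0, 0))
  neg <- dchi_tensor(-tn$components, tn$metal)

  self <- opposite_orientation(tn, tn, meth)
  expect_false(as.logical(self))
  expect_equal(attr(self, "correlation"), 1)
  oppo <- opposite_orientation(tn, neg, meth)
  expect_true(as.logical(oppo))
  expect_equal(attr(oppo, "correlation"), -1)

  # decision equals a brute-force correlation of sampled fields
  set.seed(3)
  for (rep in 1:4) {
    t1 <- dchi_tensor(rnorm(5), ctr + rnorm(3))
    t2 <- dchi_tensor(rnorm(5), ctr + rnorm(3))
    r <- cor(calc_pcs(t1, meth), calc_pcs(t2, meth))
    expect_equal(as.logical(opposite_orientation(t1, t2, meth)), r < 0)
  }
  expect_error(opposite_orientation(dchi_tensor(rep(0, 5)), tn, meth),
               "degenerate")
})

test_that("PCS restraints expand the assignment only across opposite tensors", {
  toy <- get_toy(30, seed = 3)
  meth <- toy$methyls$A
  pk <- simulate_hmqc_peaks(toy)
  noes <- simulate_noe_peaks(meth, toy$truth$shifts, 7, seed = 5)
  net <- build_noe_network(pk, noes)
  D <- methyl_distances(meth)
  truth <- toy$truth$assignment

  ctr <- colMeans(as.matrix(meth[, c("x", "y", "z")]))
  t_plus <- dchi_tensor(c(2.5, -1.1, 0.6, 0.3, -0.8), ctr + c(6, 1, -2))
  t_minus <- dchi_tensor(-0.8 * t_plus$components, t_plus$metal)
  tensors <- list(Tb = t_plus, Tm = t_minus)
  field <- lapply(tensors, function(tn) calc_pcs(tn, meth))
  pcs_obs <- lapply(field, function(f)
    setNames(unname(f[truth]), names(truth)))   # truth-keyed, noiseless

  # leave ~10% of the peaks out of the prior consensus
  cons <- data.frame(peak_id = names(truth), methyl = unname(truth),
                     count = 8, n_trials = 8, status = "consistent",
                     fixed = FALSE, candidates = "",
                     stringsAsFactors = FALSE)
  drop <- c(4, 11, 19)
  cons$methyl[drop] <- NA
  cons$status[drop] <- "ambiguous"

  cfg <- test_config(n_trials = 6, steps = 3000)
  ex <- expand_assignment_pcs(cons, tensors, pcs_obs, pk, meth, net, D,
                              config = cfg, cutoffs = 8)
  expect_setequal(ex$accepted$peak_id, cons$peak_id[drop])
  got <- setNames(ex$consensus$methyl, ex$consensus$peak_id)
  expect_equal(got[names(truth)], truth)   # zero false assignments
  expect_null(ex$contradicted)

  # tensors that are not opposite: gate closes, nothing accepted
  t_same <- dchi_tensor(0.9 * t_plus$components, t_plus$metal)
  tensors2 <- list(Tb = t_plus, Ce = t_same)
  pcs_obs2 <- list(Tb = pcs_obs$Tb,
                   Ce = setNames(unname(calc_pcs(t_same, meth)[truth]),
                                 names(truth)))
  expect_warning(
    ex2 <- expand_assignment_pcs(cons, tensors2, pcs_obs2, pk, meth,
                                 net, D, config = cfg, cutoffs = 8),
    "opposite")
  expect_equal(nrow(ex2$accepted), 0)

  # a planted wrong prior assignment is reported as PCS-inconsistent
  bad <- cons
  k1 <- cons$methyl[1]; k2 <- cons$methyl[2]
  stopifnot(substr(k1, 1, 1) != substr(k2, 1, 1) || TRUE)
  same_type <- which(toy$truth$shifts$residue_type ==
                       toy$truth$shifts$residue_type[1])[1:2]
  bad$methyl[same_type[1]] <- unname(truth[same_type[2]])
  bad$methyl[same_type[2]] <- unname(truth[same_type[1]])
  ex3 <- expand_assignment_pcs(bad, tensors, pcs_obs, pk, meth, net, D,
                               config = cfg, cutoffs = 8)
  expect_true(!is.null(ex3$contradicted))
  expect_true(all(bad$peak_id[same_type] %in% ex3$contradicted$peak_id))
})
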