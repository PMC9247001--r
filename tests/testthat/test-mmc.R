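# make a fully-determined noiseless problem from a toy state
toy_problem <- function(toy, state = "A", cutoff = 7, dropout = 0,
                        noe_seed = 5, ...) {
  pk <- simulate_hmqc_peaks(toy)
  noes <- simulate_noe_peaks(toy$methyls[[state]], toy$truth$shifts,
                             cutoff, dropout = dropout, seed = noe_seed)
  net <- build_noe_network(pk, noes)
  D <- methyl_distances(toy$methyls[[state]])
  list(peaks = pk, network = net, distances = D,
       problem = mmc_problem(pk, toy$methyls[[state]], net, D,
                             cutoff = cutoff, ...))
}

test_that("assignment energy matches a brute-force recount", {
  toy <- get_toy(25, seed = 12)
  tp <- toy_problem(toy)
  truth <- toy$truth$assignment
  expect_equal(score_assignment(tp$problem, truth), 0)

  # random permutations: package energy == independent recount
  set.seed(99)
  for (rep in 1:5) {
    keys <- unname(truth)
    fake <- truth
    for (t in unique(toy$truth$shifts$residue_type)) {
      sel <- toy$truth$shifts$residue_type == t
      fake[toy$truth$shifts$peak_id[sel]] <- sample(keys[sel])
    }
    expect_equal(score_assignment(tp$problem, fake),
                 brute_noe_energy(fake, tp$network, tp$distances, 7))
  }

  # swapping two distant probes raises the energy by the recounted amount
  lk <- names(truth)[toy$truth$shifts$residue_type == "Leu"][1:2]
  swapped <- truth
  swapped[lk] <- truth[rev(lk)]
  expect_equal(score_assignment(tp$problem, swapped),
               brute_noe_energy(swapped, tp$network, tp$distances, 7))
})

test_that("chemical shifts at weight 1e-12 are de facto excluded", {
  toy <- get_toy(8, seed = 4)
  tp0 <- toy_problem(toy)
  cs <- matrix(runif(8 * 8, 0.5, 1.2), 8, 8)   # order-1 deviations
  tpc <- toy_problem(toy, w_cs = 1e-12, cs = cs)
  truth <- toy$truth$assignment
  d <- abs(score_assignment(tpc$problem, truth) -
             score_assignment(tp0$problem, truth))
  expect_lt(d, 1e-11)
  expect_gt(d, 0)   # the term is present, merely negligible
})

test_that("MMC recovers the truth and matches exhaustive search on small toys", {
  toy <- get_toy(10, seed = 2)
  tp <- toy_problem(toy, cutoff = 9)
  st <- run_mmc(tp$problem, test_config(steps = 3000), seed = 5)
  ex <- exhaustive_best(tp$peaks, toy$methyls$A, tp$network,
                        tp$distances, 9)
  expect_equal(st$energy, ex$energy)
  expect_equal(st$energy, 0)
  expect_equal(st$assignment[names(toy$truth$assignment)],
               toy$truth$assignment)

  # reproducibility
  st2 <- run_mmc(tp$problem, test_config(steps = 3000), seed = 5)
  expect_identical(st$assignment, st2$assignment)
})

test_that("an empty network gives zero energy and all-ambiguous consensus", {
  toy <- get_toy(12, seed = 6)
  pk <- simulate_hmqc_peaks(toy)
  net <- build_noe_network(pk, data.frame(f1_C = numeric(),
                                          f2_H = numeric(),
                                          f3_C = numeric(),
                                          f4_H = numeric()))
  D <- methyl_distances(toy$methyls$A)
  prob <- mmc_problem(pk, toy$methyls$A, net, D, cutoff = 7)
  st <- run_mmc(prob, test_config(steps = 200), seed = 1)
  expect_equal(st$energy, 0)
  expect_false(any(is.na(st$assignment)))   # some valid permutation
  expect_false(anyDuplicated(st$assignment) > 0)
  # types respected: one-letter key prefix matches the peak's type
  sh <- toy$truth$shifts
  aa1 <- c(Ala = "A", Ile = "I", Leu = "L", Val = "V", Met = "M",
           Thr = "T")
  got <- substr(st$assignment[sh$peak_id], 1, 1)
  expect_equal(unname(got), unname(aa1[sh$residue_type]))
})

test_that("fixing most of the truth lets MMC recover the rest", {
  toy <- get_toy(25, seed = 12)
  tp <- toy_problem(toy)
  truth <- toy$truth$assignment
  fixed <- truth[1:20]
  st <- run_mmc(tp$problem, test_config(steps = 4000), fixed = fixed,
                seed = 3)
  expect_equal(st$assignment[names(truth)], truth)
  expect_error(run_mmc(tp$problem, test_config(),
                       fixed = c(pk001 = unname(truth[2]),
                                 pk002 = unname(truth[2]))),
               "infeasible|twice")
})

test_that("consensus requires unanimity and reports candidates", {
  a1 <- c(p1 = "A1", p2 = "L2", p3 = "T3")
  cons <- mmc_consensus(list(a1, a1, a1))
  expect_true(all(cons$status == "consistent"))
  expect_true(all(cons$count == 3))

  a2 <- a1; a2["p2"] <- "L9"
  cons2 <- mmc_consensus(list(a1, a1, a2))
  expect_equal(cons2$status[cons2$peak_id == "p2"], "ambiguous")
  expect_equal(sum(cons2$status == "consistent"), 2)
  expect_match(cons2$candidates[cons2$peak_id == "p2"], "L2:2")

  expect_error(mmc_consensus(list(a1, a1[c(1, 2)])), "mismatch")

  a3 <- a1; a3["p3"] <- NA
  cons3 <- mmc_consensus(list(a3, a3))
  expect_equal(cons3$status[cons3$peak_id == "p3"], "unassigned")
})

test_that("20 seeded trials on a noiseless toy are fully consistent and true", {
  toy <- get_toy(25, seed = 12)
  tp <- toy_problem(toy)
  cons <- mmc_consensus(run_mmc_trials(tp$problem,
                                       test_config(n_trials = 20,
                                                   steps = 4000)))
  expect_true(all(cons$status == "consistent"))
  expect_equal(setNames(cons$methyl, cons$peak_id)[
    names(toy$truth$assignment)], toy$truth$assignment)
})

test_that("cut-off scanning picks the generating cut-off and breaks ties low", {
  toy <- get_toy(30, seed = 3)
  pk <- simulate_hmqc_peaks(toy)
  noes <- simulate_noe_peaks(toy$methyls$A, toy$truth$shifts, 7,
                             dropout = 0.1, seed = 5)
  net <- build_noe_network(pk, noes)
  D <- methyl_distances(toy$methyls$A)
  sc <- scan_cutoff(c(5, 7, 9, 11), pk, toy$methyls$A, net, D,
                    config = test_config(n_trials = 6, steps = 3000))
  expect_true(sc$best_cutoff %in% c(7, 9))
  expect_equal(sc$counts$consistent[sc$counts$cutoff == sc$best_cutoff],
               max(sc$counts$consistent))

  # single-element range; all-equal counts -> smallest cut-off
  sc1 <- scan_cutoff(8, pk, toy$methyls$A, net, D,
                     config = test_config(n_trials = 2, steps = 500))
  expect_equal(sc1$best_cutoff, 8)
  empty <- build_noe_network(pk, data.frame(f1_C = numeric(),
                                            f2_H = numeric(),
                                            f3_C = numeric(),
                                            f4_H = numeric()))
  sc2 <- scan_cutoff(c(6, 8, 10), pk, toy$methyls$A, empty, D,
                     config = test_config(n_trials = 2, steps = 200))
  expect_equal(sc2$best_cutoff, 6)
})

test_that("combining identical states changes nothing and bad maps error", {
  toy <- get_toy(20, seed = 5)
  pk <- simulate_hmqc_peaks(toy)
  noes <- simulate_noe_peaks(toy$methyls$A, toy$truth$shifts, 7,
                             dropout = 0, seed = 2)
  net <- build_noe_network(pk, noes)
  D <- methyl_distances(toy$methyls$A)
  state <- list(peaks = pk, methyls = toy$methyls$A, network = net,
                distances = D, cutoff = 7)
  map <- setNames(pk$peak_id, pk$peak_id)
  cfg <- test_config(n_trials = 5, steps = 3000)
  single <- mmc_consensus(run_mmc_trials(
    mmc_problem(pk, toy$methyls$A, net, D, 7), cfg))
  comb <- combine_states(state, state, map, config = cfg)
  expect_gte(sum(comb$consensus_a$status == "consistent"),
             sum(single$status == "consistent"))
  expect_equal(comb$consensus_a$methyl, comb$consensus_b$methyl)

  bad_map <- setNames(c("pk001", "pk001"), pk$peak_id[1:2])
  expect_error(combine_states(state, state, bad_map, cfg),
               "injective")
})
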