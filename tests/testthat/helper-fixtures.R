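# Shared fixtures and independent oracles for the test suite.
# The oracles here re-derive quantities by brute force and stay
# independent of the package code paths they check.

# small two-state toy, cached per (n, seed) within a session
toy_cache <- new.env(parent = emptyenv())
get_toy <- function(n = 30, seed = 3, hinge_fraction = 0.4,
                    hinge_angle = 17) {
  key <- paste(n, seed, hinge_fraction, hinge_angle)
  if (is.null(toy_cache[[key]]))
    toy_cache[[key]] <- make_two_state_toy(n, hinge_fraction,
                                           hinge_angle, seed = seed)
  toy_cache[[key]]
}

# all permutations of a vector (for the exhaustive assignment oracle)
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], p)
  out
}

# brute-force NOE energy: plain loop over edges, no shared code with
# score_assignment internals
brute_noe_energy <- function(assignment, network, distances, cutoff) {
  e <- 0
  ed <- network$edges
  for (k in seq_len(nrow(ed))) {
    mi <- assignment[[ed$from[k]]]
    mj <- assignment[[ed$to[k]]]
    viol <- is.na(mi) || is.na(mj) || distances[mi, mj] > cutoff
    e <- e + ed$weight[k] * viol
  }
  e
}

# exhaustive minimum-energy assignment over per-type permutations
# (feasible for <= ~6 peaks per type); returns list(energy, assignment)
exhaustive_best <- function(peaks, methyls, network, distances, cutoff) {
  prob <- mmc_problem(peaks, methyls, network, distances, cutoff)
  types <- unique(peaks$residue_type)
  per_type <- lapply(types, function(t) {
    pk <- peaks$peak_id[peaks$residue_type == t]
    pr <- methyls$key[methyls$residue_type == t]
    stopifnot(length(pk) <= length(pr))
    maps <- list()
    for (sel in perms(pr)) {
      m <- setNames(sel[seq_along(pk)], pk)
      maps[[length(maps) + 1]] <- m
    }
    unique(maps)
  })
  best <- NULL
  grid <- expand.grid(lapply(per_type, seq_along))
  for (r in seq_len(nrow(grid))) {
    asn <- unlist(lapply(seq_along(types), function(i)
      per_type[[i]][[grid[r, i]]]))
    en <- score_assignment(prob, asn)
    if (is.null(best) || en < best$energy)
      best <- list(energy = en, assignment = asn)
  }
  best
}

# independent four-state oracle: 1-D scan over free metal with nested
# closed-form two-state solves
four_state_oracle <- function(k1, k2, k4, pt, ut, mt) {
  g <- function(M) {
    keff <- k2 * (1 + M / k1) / (1 + M / k4)
    b <- pt + ut + keff
    C <- (b - sqrt(b^2 - 4 * pt * ut)) / 2
    U <- (ut - C) / (1 + M / k1)
    UMP <- C * (M / k4) / (1 + M / k4)
    M + U * M / k1 + UMP - mt
  }
  M <- if (mt == 0) 0 else uniroot(g, c(0, mt), tol = 1e-13)$root
  keff <- k2 * (1 + M / k1) / (1 + M / k4)
  b <- pt + ut + keff
  C <- (b - sqrt(b^2 - 4 * pt * ut)) / 2
  U <- (ut - C) / (1 + M / k1)
  UMP <- C * (M / k4) / (1 + M / k4)
  list(P = pt - C, U = U, M = M, UP = C - UMP,
       UM = U * M / k1, UMP = UMP, fraction_UMP = UMP / pt)
}

# PCS via the full 3x3 traceless matrix contraction r' X r / (4 pi r^5)
# -- algebraically equivalent route to the 5-parameter vector form
pcs_contraction_oracle <- function(components, metal, pos) {
  X <- matrix(c(components[1], components[3], components[4],
                components[3], components[2], components[5],
                components[4], components[5],
                -(components[1] + components[2])), 3, 3)
  apply(pos, 1, function(p) {
    d <- p - metal
    r <- sqrt(sum(d^2))
    1e4 * as.numeric(t(d) %*% X %*% d) / (4 * pi * r^5)
  })
}

# default fast MMC config for tests
test_config <- function(n_trials = 8, steps = 4000, seed = 11)
  mmc_config(n_trials = n_trials, steps = steps, seed = seed)
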