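# Metropolis Monte Carlo assignment of typed HMQC peaks to methyl probes.
#
# The energy is a restraint-violation count: an NOE edge between two peaks
# is violated when the mapped probes lie further apart than the cut-off
# (or when either end is unassigned). Mutual edges count 1, one-sided
# edges 1/2. Optional PCS and chemical-shift terms are absolute
# observed-vs-calculated deviations summed over mapped peaks. The energy
# of the true mapping on noiseless data generated at the same cut-off is
# exactly zero, which is what makes the scheme oracle-checkable.

#' MMC run configuration
#'
#' @param n_trials number of independent annealing trials entering the
#'   consensus
#' @param steps Monte Carlo proposals per trial
#' @param t_start,t_end start/end pseudo-temperatures of the geometric
#'   cooling schedule (energy units)
#' @param n_levels number of temperature levels
#' @param seed base RNG seed; trial k uses `seed + k`
#' @return an `mmc_config` list
#' @export
mmc_config <- function(n_trials = 20, steps = 20000, t_start = 5,
                       t_end = 0.01, n_levels = 50, seed = 1) {
  stopifnot(n_trials >= 1, steps >= 1, t_start > 0, t_end > 0,
            t_end <= t_start, n_levels >= 1)
  structure(list(n_trials = n_trials, steps = steps, t_start = t_start,
                 t_end = t_end, n_levels = n_levels, seed = seed),
            class = "mmc_config")
}

#' Assemble an MMC assignment problem
#'
#' Encodes peaks, probes, the NOE network and the distance table into the
#' integer form the sampler works on. Peaks without a residue type are
#' kept but never assigned (their edges count as violated); within each
#' residue type the peak -> probe mapping is injective, surplus peaks or
#' probes float.
#'
#' @param peaks peak list with a `residue_type` column
#' @param methyls a `methyl_table` (needs `key`, `residue_type`)
#' @param network an `noe_network` over the peak ids
#' @param distances distance matrix over the methyl keys (Angstrom),
#'   from [methyl_distances()]
#' @param cutoff NOE distance cut-off (Angstrom)
#' @param w_noe,w_pcs,w_cs term weights; the default `w_cs = 1e-12`
#'   de facto excludes chemical-shift information
#' @param pcs optional list with `obs` (named by peak id) and `calc`
#'   (named by probe key), same units; enters as
#'   `w_pcs * sum(|obs - calc|)` over mapped peaks with data
#' @param cs optional precomputed peak-by-probe shift-deviation matrix
#' @return an `mmc_problem`
#' @export
mmc_problem <- function(peaks, methyls, network, distances, cutoff,
                        w_noe = 1, w_pcs = 0, w_cs = 1e-12,
                        pcs = NULL, cs = NULL) {
  stopifnot(cutoff > 0, w_noe >= 0, w_pcs >= 0, w_cs >= 0)
  if (is.null(peaks$residue_type))
    stop("peaks need a residue_type column (see classify_residue_types)")
  keys <- methyls$key
  if (!all(keys %in% rownames(distances)))
    stop("distance table does not cover all methyl keys")
  D <- distances[keys, keys, drop = FALSE]

  pk_id <- peaks$peak_id
  np <- length(pk_id); nm <- length(keys)
  pk_type <- peaks$residue_type
  pr_type <- methyls$residue_type

  # per-type peak and probe index pools
  types <- sort(unique(stats::na.omit(pk_type)))
  pool <- lapply(types, function(t)
    list(peaks = which(!is.na(pk_type) & pk_type == t),
         probes = which(pr_type == t)))
  names(pool) <- types

  # edges in integer form (drop edges whose ends are not in the peak list)
  ed <- network$edges
  ei <- match(ed$from, pk_id); ej <- match(ed$to, pk_id)
  ok <- !is.na(ei) & !is.na(ej)
  ei <- ei[ok]; ej <- ej[ok]; ew <- ed$weight[ok]
  adj <- vector("list", np)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], k)
    adj[[ej[k]]] <- c(adj[[ej[k]]], k)
  }

  pen <- matrix(0, np, nm)          # per-peak, per-probe penalty term
  if (!is.null(pcs)) {
    obs <- pcs$obs[names(pcs$obs) %in% pk_id]
    calc <- pcs$calc
    if (!all(keys %in% names(calc)))
      stop("pcs$calc must cover all methyl keys")
    rows <- match(names(obs), pk_id)
    pen[rows, ] <- pen[rows, ] +
      w_pcs * abs(outer(unname(obs), unname(calc[keys]), `-`))
  }
  if (!is.null(cs)) pen <- pen + w_cs * cs

  structure(list(
    peak_id = pk_id, keys = keys, pk_type = pk_type, pool = pool,
    E_i = ei, E_j = ej, E_w = ew, adj = adj,
    Dgt = D > cutoff, cutoff = cutoff,
    w_noe = w_noe, pen = pen, has_pen = any(pen != 0)),
    class = "mmc_problem")
}

# edge violation weight for the edges `eids` under integer assignment `a`
.edge_energy <- function(prob, eids, a) {
  if (!length(eids)) return(0)
  ii <- a[prob$E_i[eids]]; jj <- a[prob$E_j[eids]]
  viol <- ii == 0L | jj == 0L
  ok <- which(!viol)
  if (length(ok)) viol[ok] <- prob$Dgt[cbind(ii[ok], jj[ok])]
  sum(prob$E_w[eids] * viol)
}

.pen_energy <- function(prob, a) {
  on <- which(a > 0L)
  if (!length(on)) return(0)
  sum(prob$pen[cbind(on, a[on])])
}

.as_int_assignment <- function(prob, assignment) {
  a <- integer(length(prob$peak_id))
  if (!is.null(assignment) && length(assignment)) {
    idx <- match(names(assignment), prob$peak_id)
    val <- match(assignment, prob$keys)
    sel <- !is.na(idx) & !is.na(assignment)
    a[idx[sel]] <- ifelse(is.na(val[sel]), 0L, val[sel])
  }
  a
}

.as_named_assignment <- function(prob, a) {
  out <- ifelse(a > 0L, prob$keys[a], NA_character_)
  names(out) <- prob$peak_id
  out
}

#' Score a peak-to-probe assignment
#'
#' Energy = `w_noe` x (violation weight of NOE edges whose mapped probe
#' pair exceeds the cut-off, or with an unassigned end; one-sided edges
#' count 1/2) + the summed PCS/shift penalty of mapped peaks. Lower is
#' better; the truth mapping on noiseless same-cut-off data scores 0.
#'
#' @param problem an `mmc_problem`
#' @param assignment named character vector peak_id -> methyl key (NA =
#'   unassigned)
#' @return energy (unitless)
#' @export
score_assignment <- function(problem, assignment) {
  a <- .as_int_assignment(problem, assignment)
  problem$w_noe * .edge_energy(problem, seq_along(problem$E_i), a) +
    .pen_energy(problem, a)
}

#' Per-peak NOE violation fractions
#'
#' Diagnostic used to spot implausible (e.g. wrongly fixed) assignments:
#' the violated fraction of each peak's incident edge weight under a
#' given assignment.
#'
#' @inheritParams score_assignment
#' @return data frame `peak_id`, `total` (incident edge weight),
#'   `violated`, `fraction`
#' @export
peak_violations <- function(problem, assignment) {
  a <- .as_int_assignment(problem, assignment)
  n <- length(problem$peak_id)
  tot <- viol <- numeric(n)
  for (p in seq_len(n)) {
    eids <- problem$adj[[p]]
    tot[p] <- sum(problem$E_w[eids])
    viol[p] <- .edge_energy(problem, eids, a)
  }
  data.frame(peak_id = problem$peak_id, total = tot, violated = viol,
             fraction = ifelse(tot > 0, viol / tot, 0),
             stringsAsFactors = FALSE)
}

.check_fixed <- function(prob, fixed) {
  if (is.null(fixed) || !length(fixed)) return(integer(0))
  idx <- match(names(fixed), prob$peak_id)
  if (any(is.na(idx)))
    stop("fixed assignment names unknown peak(s): ",
         paste(names(fixed)[is.na(idx)], collapse = ", "))
  val <- match(fixed, prob$keys)
  if (any(is.na(val)))
    stop("fixed assignment names unknown methyl(s): ",
         paste(fixed[is.na(val)], collapse = ", "))
  if (anyDuplicated(val))
    stop("infeasible fixed set: methyl ",
         prob$keys[val[duplicated(val)]][1], " used twice")
  ptype <- prob$pk_type[idx]
  mtype <- vapply(val, function(v) {
    for (t in names(prob$pool)) if (v %in% prob$pool[[t]]$probes) return(t)
    NA_character_
  }, "")
  bad <- !is.na(ptype) & !is.na(mtype) & ptype != mtype
  if (any(bad))
    stop("type-inconsistent fixed assignment: ",
         names(fixed)[bad][1], " -> ", fixed[bad][1])
  setNames(val, idx)
}

#' Run one Metropolis Monte Carlo annealing trial
#'
#' Starts from a random type-respecting permutation honouring the fixed
#' entries, proposes within-type swaps and relocations to free probes,
#' accepts by the Metropolis rule under a geometric cooling schedule, and
#' returns the best-energy state visited. Reproducible given `seed`.
#'
#' @param problem an `mmc_problem`
#' @param config an [mmc_config()]; only `steps`, `t_start`, `t_end`,
#'   `n_levels` are used here
#' @param fixed named character vector of fixed assignments (peak ->
#'   methyl key); fixed peaks are never touched
#' @param seed RNG seed for this trial (default `config$seed`)
#' @return an `mmc_state`: list with `assignment` (named character),
#'   `energy`, `noe_energy`, `seed`
#' @export
run_mmc <- function(problem, config = mmc_config(), fixed = NULL,
                    seed = config$seed) {
  fx <- .check_fixed(problem, fixed)
  set.seed(seed)
  np <- length(problem$peak_id)
  a <- integer(np)
  fixed_peaks <- as.integer(names(fx))
  a[fixed_peaks] <- as.integer(fx)
  used <- rep(FALSE, length(problem$keys))
  used[a[a > 0L]] <- TRUE

  movable <- integer(0)
  for (t in names(problem$pool)) {
    pk <- setdiff(problem$pool[[t]]$peaks, fixed_peaks)
    pr <- problem$pool[[t]]$probes[!used[problem$pool[[t]]$probes]]
    k <- min(length(pk), length(pr))
    if (k > 0) {
      tgt <- if (length(pr) == 1) pr else sample(pr, k)
      src <- if (length(pk) == 1) pk else sample(pk, k)
      a[src[seq_len(k)]] <- tgt[seq_len(k)]
      used[tgt[seq_len(k)]] <- TRUE
    }
    if (length(pk) > 1 || (length(pk) == 1 && length(pr) > 1))
      movable <- c(movable, pk)
  }

  E <- problem$w_noe * .edge_energy(problem, seq_along(problem$E_i), a) +
    .pen_energy(problem, a)
  best_E <- E; best_a <- a
  if (length(movable) == 0 || config$steps < 1)
    return(structure(list(assignment = .as_named_assignment(problem, best_a),
                          energy = best_E,
                          noe_energy = problem$w_noe *
                            .edge_energy(problem, seq_along(problem$E_i),
                                         best_a),
                          seed = seed), class = "mmc_state"))

  temps <- exp(seq(log(config$t_start), log(config$t_end),
                   length.out = config$n_levels))
  spl <- ceiling(config$steps / config$n_levels)
  w_noe <- problem$w_noe
  pen <- problem$pen; has_pen <- problem$has_pen
  pool <- problem$pool; adj <- problem$adj
  pk_type <- problem$pk_type

  for (lvl in seq_len(config$n_levels)) {
    Tk <- temps[lvl]
    ps <- sample(movable, spl, replace = TRUE)
    mv <- runif(spl); ac <- runif(spl)
    for (s in seq_len(spl)) {
      p <- ps[s]; t <- pk_type[p]
      pr <- pool[[t]]$probes
      free <- pr[!used[pr]]
      peers <- setdiff(pool[[t]]$peaks, c(p, fixed_peaks))
      relocate <- length(free) > 0 && (mv[s] < 0.5 || !length(peers))
      if (relocate) {
        m_new <- if (length(free) == 1) free else sample(free, 1)
        eids <- adj[[p]]
        dE <- -w_noe * .edge_energy(problem, eids, a)
        if (has_pen && a[p] > 0L) dE <- dE - pen[p, a[p]]
        m_old <- a[p]; a[p] <- m_new
        dE <- dE + w_noe * .edge_energy(problem, eids, a) + pen[p, m_new]
        if (dE <= 0 || ac[s] < exp(-dE / Tk)) {
          used[m_new] <- TRUE
          if (m_old > 0L) used[m_old] <- FALSE
          E <- E + dE
          if (E < best_E) { best_E <- E; best_a <- a }
        } else a[p] <- m_old
      } else {
        if (!length(peers)) next
        q <- if (length(peers) == 1) peers else sample(peers, 1)
        eids <- unique(c(adj[[p]], adj[[q]]))
        dE <- -w_noe * .edge_energy(problem, eids, a)
        if (has_pen) {
          if (a[p] > 0L) dE <- dE - pen[p, a[p]]
          if (a[q] > 0L) dE <- dE - pen[q, a[q]]
        }
        tmp <- a[p]; a[p] <- a[q]; a[q] <- tmp
        dE <- dE + w_noe * .edge_energy(problem, eids, a)
        if (has_pen) {
          if (a[p] > 0L) dE <- dE + pen[p, a[p]]
          if (a[q] > 0L) dE <- dE + pen[q, a[q]]
        }
        if (dE <= 0 || ac[s] < exp(-dE / Tk)) {
          E <- E + dE
          if (E < best_E) { best_E <- E; best_a <- a }
        } else { tmp <- a[p]; a[p] <- a[q]; a[q] <- tmp }
      }
    }
  }

  structure(list(assignment = .as_named_assignment(problem, best_a),
                 energy = best_E,
                 noe_energy = w_noe *
                   .edge_energy(problem, seq_along(problem$E_i), best_a),
                 seed = seed),
            class = "mmc_state")
}

#' Run independent MMC trials
#'
#' Trial k runs [run_mmc()] with seed `config$seed + k`.
#'
#' @inheritParams run_mmc
#' @return list of `mmc_state`s of length `config$n_trials`
#' @export
run_mmc_trials <- function(problem, config = mmc_config(), fixed = NULL) {
  lapply(seq_len(config$n_trials), function(k)
    run_mmc(problem, config, fixed, seed = config$seed + k))
}

#' Consensus over MMC trials
#'
#' A peak is `consistent` only when every trial maps it to the same
#' methyl (strict unanimity, or a relaxed quorum via `quorum < 1`);
#' otherwise it is `ambiguous` with the candidate multiset reported, or
#' `unassigned` when no trial assigns it.
#'
#' @param trials list of `mmc_state`s (or named assignment vectors) over
#'   identical peak sets
#' @param fixed optional named character vector; marked in the `fixed`
#'   column
#' @param quorum fraction of trials that must agree (default 1 =
#'   unanimity)
#' @return a `consensus_assignment` data frame: `peak_id`, `methyl`,
#'   `count`, `n_trials`, `status`, `fixed`, `candidates`
#' @export
mmc_consensus <- function(trials, fixed = NULL, quorum = 1) {
  stopifnot(length(trials) >= 1, quorum > 0, quorum <= 1)
  asn <- lapply(trials, function(t)
    if (inherits(t, "mmc_state")) t$assignment else t)
  ids <- names(asn[[1]])
  for (t in asn)
    if (!identical(sort(names(t)), sort(ids)))
      stop("trials have mismatched peak sets")
  mat <- vapply(asn, function(t) t[ids], character(length(ids)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(ids))
  n_tr <- ncol(mat)

  methyl <- rep(NA_character_, length(ids))
  count <- integer(length(ids))
  status <- character(length(ids))
  candidates <- character(length(ids))
  for (i in seq_along(ids)) {
    v <- mat[i, ]
    nz <- v[!is.na(v)]
    if (!length(nz)) {
      status[i] <- "unassigned"; candidates[i] <- ""
      next
    }
    tab <- sort(table(nz), decreasing = TRUE)
    count[i] <- tab[1]
    if (tab[1] >= quorum * n_tr && length(nz) == n_tr &&
        (length(tab) == 1 || quorum < 1)) {
      methyl[i] <- names(tab)[1]
      status[i] <- "consistent"
    } else {
      status[i] <- "ambiguous"
    }
    candidates[i] <- paste(paste0(names(tab), ":", tab), collapse = ",")
  }
  out <- data.frame(peak_id = ids, methyl = methyl, count = count,
                    n_trials = n_tr, status = status,
                    fixed = ids %in% names(fixed),
                    candidates = candidates, stringsAsFactors = FALSE)
  class(out) <- c("consensus_assignment", "data.frame")
  out
}

#' Scan NOE cut-off distances
#'
#' Runs the full trial consensus at each cut-off and picks the cut-off
#' maximising the number of consistently assigned peaks; ties go to the
#' smallest cut-off.
#'
#' @param cutoffs numeric vector of cut-offs (Angstrom)
#' @param peaks,methyls,network,distances as in [mmc_problem()]
#' @param config an [mmc_config()]
#' @param fixed optional fixed assignments
#' @param ... further arguments passed to [mmc_problem()]
#' @return list with `best_cutoff`, `counts` (data frame cutoff x
#'   consistent count) and `consensus` (the consensus at the best cut-off)
#' @export
scan_cutoff <- function(cutoffs, peaks, methyls, network, distances,
                        config = mmc_config(), fixed = NULL, ...) {
  stopifnot(length(cutoffs) >= 1)
  res <- lapply(cutoffs, function(co) {
    prob <- mmc_problem(peaks, methyls, network, distances, cutoff = co,
                        ...)
    mmc_consensus(run_mmc_trials(prob, config, fixed), fixed = fixed)
  })
  n_cons <- vapply(res, function(r) sum(r$status == "consistent"), 0L)
  ord <- order(-n_cons, cutoffs)
  best <- ord[1]
  list(best_cutoff = cutoffs[best],
       counts = data.frame(cutoff = cutoffs, consistent = n_cons),
       consensus = res[[best]])
}

#' Combine assignments from two protein states
#'
#' Independent consensus per state; then assignments consistent in
#' exactly one state are transferred through the titration-derived peak
#' map and fixed in a re-run of the complementary state, iterating until
#' the consistent sets stop growing. Transfers that contradict a
#' consistent assignment of the target state are reported as conflicts,
#' never silently overwritten.
#'
#' @param state_a,state_b each a list with `peaks`, `network`,
#'   `distances`, `methyls`, `cutoff` and optionally `fixed`
#' @param peak_map named character vector mapping state-A peak ids to
#'   state-B peak ids (injective)
#' @param config an [mmc_config()]
#' @param max_passes safety bound on the fixing iterations
#' @param violation_threshold fixed peaks whose incident-NOE violation
#'   fraction exceeds this in the final state are flagged `suspect_fixed`
#' @return list with `consensus_a`, `consensus_b`, `conflicts`,
#'   `suspect_fixed`, `history` (consistent counts per pass)
#' @export
combine_states <- function(state_a, state_b, peak_map,
                           config = mmc_config(), max_passes = 10,
                           violation_threshold = 0.5) {
  if (anyDuplicated(peak_map))
    stop("peak_map is not injective: ",
         peak_map[duplicated(peak_map)][1], " mapped twice")
  rev_map <- setNames(names(peak_map), peak_map)

  prob <- list(
    a = mmc_problem(state_a$peaks, state_a$methyls, state_a$network,
                    state_a$distances, state_a$cutoff),
    b = mmc_problem(state_b$peaks, state_b$methyls, state_b$network,
                    state_b$distances, state_b$cutoff))
  fixed <- list(a = state_a$fixed, b = state_b$fixed)
  conflicts <- list()
  history <- data.frame(pass = integer(), consistent_a = integer(),
                        consistent_b = integer())
  cons <- list(a = NULL, b = NULL)
  best <- list(total = -1)

  for (pass in seq_len(max_passes)) {
    # identical trial seeds every pass: successive passes differ only by
    # the grown fixed sets, so the consistent set can only widen
    for (st in c("a", "b")) {
      cons[[st]] <- mmc_consensus(
        run_mmc_trials(prob[[st]], config, fixed[[st]]),
        fixed = fixed[[st]])
    }
    na <- sum(cons$a$status == "consistent")
    nb <- sum(cons$b$status == "consistent")
    history <- rbind(history, data.frame(pass = pass, consistent_a = na,
                                         consistent_b = nb))
    improved <- na + nb > best$total
    if (improved)
      best <- list(total = na + nb, cons = cons, fixed = fixed)
    if (!improved && pass > 1) break

    # transfer state-exclusive consistent assignments into the other state
    for (dir in list(c("a", "b"), c("b", "a"))) {
      from <- dir[1]; to <- dir[2]
      map <- if (from == "a") peak_map else rev_map
      cf <- cons[[from]]; ct <- cons[[to]]
      solo <- cf[cf$status == "consistent" & cf$peak_id %in% names(map), ]
      for (r in seq_len(nrow(solo))) {
        tgt <- unname(map[solo$peak_id[r]])
        m <- solo$methyl[r]
        existing <- ct$methyl[ct$peak_id == tgt & ct$status == "consistent"]
        if (length(existing) && !is.na(existing[1])) {
          if (existing[1] != m)
            conflicts[[length(conflicts) + 1]] <- data.frame(
              peak_a = if (from == "a") solo$peak_id[r] else tgt,
              peak_b = if (from == "a") tgt else solo$peak_id[r],
              methyl_a = if (from == "a") m else existing[1],
              methyl_b = if (from == "a") existing[1] else m,
              stringsAsFactors = FALSE)
          next   # target state already settled this peak
        }
        if (!is.null(fixed[[to]]) && tgt %in% names(fixed[[to]])) next
        if (m %in% fixed[[to]]) next   # methyl already fixed elsewhere
        fixed[[to]][tgt] <- m
      }
    }
  }

  cons <- best$cons; fixed <- best$fixed
  suspect <- lapply(c(a = "a", b = "b"), function(st) {
    if (is.null(fixed[[st]]) || !length(fixed[[st]])) return(character(0))
    full <- setNames(cons[[st]]$methyl, cons[[st]]$peak_id)
    full[names(fixed[[st]])] <- fixed[[st]]
    pv <- peak_violations(prob[[st]], full)
    pv$peak_id[pv$peak_id %in% names(fixed[[st]]) & pv$total > 0 &
                 pv$fraction > violation_threshold]
  })

  list(consensus_a = cons$a, consensus_b = cons$b,
       conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
         NULL,
       suspect_fixed = suspect, history = history,
       fixed_a = fixed$a, fixed_b = fixed$b)
}
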