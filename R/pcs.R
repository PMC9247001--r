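# Pseudocontact shifts: the five-parameter delta-chi tensor, fitting with
# a movable metal position, unique tensor representation, bootstrap
# errors, Q factors and PCS-driven assignment expansion.
#
# Working units: tensor components in 1e-32 m^3, coordinates in Angstrom,
# PCS in ppm internally (Hz at I/O given a spectrometer 1H frequency).
# With those units the PCS of a nucleus at offset (x, y, z) from the
# metal is
#   ppm = 1e4/(4 pi r^5) * [x^2-z^2, y^2-z^2, 2xy, 2xz, 2yz] . comp
# (the 1e4 collects 1e-32 m^3, the two Angstrom->metre powers and the
# 1e6 ppm scaling).

.PCS_UNIT <- 1e4

#' Construct a delta-chi tensor
#'
#' @param components numeric(5): Dchi_xx, Dchi_yy, Dchi_xy, Dchi_xz,
#'   Dchi_yz in 1e-32 m^3 (the traceless zz component is implied:
#'   Dchi_zz = -(Dchi_xx + Dchi_yy))
#' @param metal metal position, Angstrom triple
#' @return a `dchi_tensor`
#' @export
dchi_tensor <- function(components, metal = c(0, 0, 0)) {
  components <- as.numeric(components)
  stopifnot(length(components) == 5, length(metal) == 3,
            all(is.finite(components)), all(is.finite(metal)))
  names(components) <- c("xx", "yy", "xy", "xz", "yz")
  structure(list(components = components, metal = as.numeric(metal)),
            class = "dchi_tensor")
}

#' @export
print.dchi_tensor <- function(x, ...) {
  cat("Delta-chi tensor (1e-32 m^3):\n")
  print(round(x$components, 4))
  cat("metal position (A):", paste(round(x$metal, 3), collapse = ", "),
      "\n")
  invisible(x)
}

# 3x3 symmetric traceless matrix form
.tensor_matrix <- function(tensor) {
  cm <- tensor$components
  matrix(c(cm["xx"], cm["xy"], cm["xz"],
           cm["xy"], cm["yy"], cm["yz"],
           cm["xz"], cm["yz"], -(cm["xx"] + cm["yy"])),
         3, 3)
}

.coords_matrix <- function(positions) {
  if (inherits(positions, "methyl_table"))
    return(structure(as.matrix(positions[, c("x", "y", "z")]),
                     dimnames = list(positions$key, NULL)))
  m <- as.matrix(positions)
  if (ncol(m) != 3) stop("positions must be an n x 3 matrix")
  m
}

# n x 5 design matrix of Eq-5 geometry factors for nuclei at `pos`
# (Angstrom) around `metal`; design %*% components gives ppm
.pcs_design <- function(pos, metal) {
  d <- sweep(pos, 2, metal)
  r2 <- rowSums(d^2)
  if (any(r2 == 0)) stop("nucleus coincides with the metal position")
  x <- d[, 1]; y <- d[, 2]; z <- d[, 3]
  cbind(x^2 - z^2, y^2 - z^2, 2 * x * y, 2 * x * z, 2 * y * z) *
    (.PCS_UNIT / (4 * pi * r2^2.5))
}

#' Calculate pseudocontact shifts from a delta-chi tensor
#'
#' Evaluates the five-parameter PCS expression at given nuclear
#' positions.
#'
#' @param tensor a [dchi_tensor()]
#' @param positions n x 3 matrix of positions (Angstrom), a
#'   `methyl_table`, or a `methyl_ensemble` (ensemble: the per-model PCS
#'   are averaged)
#' @return numeric vector of PCS in ppm (named when positions carry keys)
#' @export
calc_pcs <- function(tensor, positions) {
  if (inherits(positions, "methyl_ensemble")) {
    per <- .calc_pcs_models(tensor, positions$coords)
    return(setNames(rowMeans(per), positions$keys))
  }
  pos <- .coords_matrix(positions)
  setNames(as.vector(.pcs_design(pos, tensor$metal) %*%
                       tensor$components),
           rownames(pos))
}

# per-model PCS matrix (n_probes x n_models) for a coords array
.calc_pcs_models <- function(tensor, coords) {
  vapply(seq_len(dim(coords)[3]), function(m)
    as.vector(.pcs_design(matrix(coords[, , m], ncol = 3),
                          tensor$metal) %*% tensor$components),
    numeric(dim(coords)[1]))
}

#' Extract PCS from diamagnetic/paramagnetic peak pairs
#'
#' PCS = delta(1H)_para - delta(1H)_dia in the proton dimension, reported
#' in both ppm and Hz at the stated spectrometer frequency. Unmatched
#' peaks are listed in the `"unmatched"` attribute, never fabricated.
#' The 13C difference is carried along for bookkeeping but is not used in
#' tensor fits.
#'
#' @param dia,para peak lists of the diamagnetic and paramagnetic samples
#' @param peak_map named character vector dia peak id -> para peak id
#' @param frequency_mhz spectrometer 1H frequency (MHz)
#' @return data frame `key` (dia peak id), `pcs_ppm`, `pcs_hz`,
#'   `pcs_c_ppm`; attribute `"unmatched"`
#' @export
pcs_from_shifts <- function(dia, para, peak_map, frequency_mhz = 500) {
  .check_peaks(dia); .check_peaks(para)
  di <- match(names(peak_map), dia$peak_id)
  pi_ <- match(unname(peak_map), para$peak_id)
  ok <- !is.na(di) & !is.na(pi_)
  unmatched <- names(peak_map)[!ok]
  di <- di[ok]; pi_ <- pi_[ok]
  out <- data.frame(
    key = dia$peak_id[di],
    pcs_ppm = para$delta_H[pi_] - dia$delta_H[di],
    pcs_c_ppm = para$delta_C[pi_] - dia$delta_C[di],
    stringsAsFactors = FALSE)
  out$pcs_hz <- out$pcs_ppm * frequency_mhz
  out <- out[, c("key", "pcs_ppm", "pcs_hz", "pcs_c_ppm")]
  attr(out, "unmatched") <- unmatched
  out
}

#' Ensemble Q factor
#'
#' Goodness of fit between observed and calculated paramagnetic
#' observables (PCS or PRE):
#' `Q = sqrt( sum_i [sum_m (obs_i - calc_{m,i})]^2 /
#'            sum_i [sum_m obs_i]^2 )`,
#' with m running over ensemble models. For a single model this reduces
#' to the standard Q factor.
#'
#' @param observed numeric vector (one value per atom)
#' @param calculated numeric vector, or an atoms x models matrix of
#'   per-model calculated values
#' @return Q (unitless, >= 0; 0 iff perfect fit)
#' @export
q_factor <- function(observed, calculated) {
  calc <- if (is.matrix(calculated)) calculated else
    matrix(calculated, ncol = 1)
  stopifnot(length(observed) == nrow(calc))
  if (all(observed == 0)) stop("all observed values are zero")
  n_m <- ncol(calc)
  num <- sum((n_m * observed - rowSums(calc))^2)
  den <- sum((n_m * observed)^2)
  sqrt(num / den)
}

#' Fit a delta-chi tensor to observed PCS
#'
#' The PCS expression is linear in the five tensor components, so at any
#' metal position they are obtained by a linear least-squares solve; when
#' `move_metal = TRUE` the metal coordinates are refined jointly by BFGS
#' over the profiled residual. For an ensemble the calculated PCS of each
#' probe is the average over models, matching the ensemble Q factor.
#'
#' @param pcs_obs named numeric vector of observed 1H PCS (ppm), names =
#'   methyl keys
#' @param positions a `methyl_table`, n x 3 matrix with keys as rownames,
#'   or a `methyl_ensemble`
#' @param init_metal starting metal position (Angstrom); in practice the
#'   crystallographic metal site
#' @param move_metal refine the metal position (default TRUE)
#' @return list with `tensor` (the fitted [dchi_tensor()]), `report`
#'   (`Q`, `residuals` in ppm, `rss`, `convergence`, `n_obs`)
#' @export
fit_tensor <- function(pcs_obs, positions, init_metal,
                       move_metal = TRUE) {
  coords <- if (inherits(positions, "methyl_ensemble")) positions$coords
            else {
              m <- .coords_matrix(positions)
              array(m, dim = c(nrow(m), 3, 1),
                    dimnames = list(rownames(m), NULL, NULL))
            }
  keys <- dimnames(coords)[[1]]
  if (is.null(keys)) stop("positions must carry methyl keys")
  obs_keys <- names(pcs_obs)
  if (!all(obs_keys %in% keys))
    stop("PCS observations for unknown methyl(s): ",
         paste(setdiff(obs_keys, keys), collapse = ", "))
  idx <- match(obs_keys, keys)
  n <- length(pcs_obs)
  need <- if (move_metal) 8 else 5
  if (n < need)
    stop("underdetermined fit: ", n, " observations for ", need,
         " parameters")

  n_m <- dim(coords)[3]
  design_at <- function(metal) {
    A <- 0
    for (m in seq_len(n_m))
      A <- A + .pcs_design(matrix(coords[idx, , m], ncol = 3), metal)
    A / n_m
  }
  solve_comp <- function(metal) {
    A <- design_at(metal)
    fit <- lm.fit(A, pcs_obs)
    list(comp = fit$coefficients, rss = sum(fit$residuals^2),
         residuals = fit$residuals)
  }

  metal <- as.numeric(init_metal)
  convergence <- 0L
  if (move_metal) {
    opt <- optim(metal, function(p) solve_comp(p)$rss, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    metal <- opt$par
    convergence <- opt$convergence
    if (convergence != 0)
      stop("metal-position refinement did not converge (optim code ",
           convergence, ")")
  }
  sol <- solve_comp(metal)
  tensor <- dchi_tensor(sol$comp, metal)
  calc <- .calc_pcs_models(tensor, coords[idx, , , drop = FALSE])
  list(tensor = tensor,
       report = list(Q = q_factor(pcs_obs, calc),
                     residuals = setNames(sol$residuals, obs_keys),
                     rss = sol$rss, convergence = convergence,
                     n_obs = n))
}

#' Unique tensor representation (UTR)
#'
#' Diagonalizes the traceless 3x3 tensor and reports axial and rhombic
#' anisotropies under the `|chi_zz| >= |chi_yy| >= |chi_xx|` convention:
#' `Dchi_ax = chi_zz - (chi_xx + chi_yy)/2`, `Dchi_rh = chi_xx - chi_yy`,
#' plus the ZYZ Euler angles of the principal frame. Angles are flagged
#' undefined (`NA`) for degenerate eigenvalues.
#'
#' @param tensor a [dchi_tensor()]
#' @return list with `ax`, `rh` (1e-32 m^3), `eigenvalues` (ordered
#'   xx, yy, zz), `alpha`, `beta`, `gamma` (degrees), `degenerate`
#' @export
to_utr <- function(tensor) {
  M <- .tensor_matrix(tensor)
  e <- eigen(M, symmetric = TRUE)
  ord <- order(abs(e$values))           # xx, yy, zz by |eigenvalue|
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 1] <- -vecs[, 1]
  ax <- vals[3] - (vals[1] + vals[2]) / 2
  rh <- vals[1] - vals[2]
  degenerate <- any(abs(diff(sort(vals))) < 1e-10 * max(abs(vals), 1e-30))
  if (degenerate) {
    ang <- c(NA_real_, NA_real_, NA_real_)
  } else {
    R <- vecs
    beta <- acos(max(-1, min(1, R[3, 3])))
    if (abs(sin(beta)) < 1e-9) {
      alpha <- atan2(R[2, 1], R[1, 1]); gamma <- 0
    } else {
      alpha <- atan2(R[2, 3], R[1, 3])
      gamma <- atan2(R[3, 2], -R[3, 1])
    }
    ang <- c(alpha, beta, gamma) * 180 / pi
  }
  list(ax = unname(ax), rh = unname(rh),
       eigenvalues = setNames(vals, c("xx", "yy", "zz")),
       alpha = ang[1], beta = ang[2], gamma = ang[3],
       degenerate = degenerate)
}

#' Bootstrap errors of a tensor fit
#'
#' Refits the tensor on random subsets of the observations (default 80%
#' without replacement, 1000 iterations) and reports one standard
#' deviation per parameter. Draws too small to determine the fit are
#' skipped and counted.
#'
#' @inheritParams fit_tensor
#' @param iterations number of bootstrap draws (>= 2)
#' @param sample_fraction fraction of observations per draw
#' @param seed RNG seed
#' @return list with `sd` (named: five components, `metal_x/y/z`,
#'   `metal_position` = RMS spatial SD in Angstrom), `skipped`,
#'   `iterations`
#' @export
bootstrap_tensor <- function(pcs_obs, positions, init_metal,
                             move_metal = TRUE, iterations = 1000,
                             sample_fraction = 0.8, seed = 1) {
  if (iterations < 2)
    stop("bootstrap SD undefined for iterations < 2")
  set.seed(seed)
  n <- length(pcs_obs)
  k <- max(1, floor(sample_fraction * n))
  need <- if (move_metal) 8 else 5
  draws <- matrix(NA_real_, iterations, 8)
  skipped <- 0L
  for (it in seq_len(iterations)) {
    sub <- sample(n, k)
    if (k < need) { skipped <- skipped + 1L; next }
    fit <- tryCatch(
      fit_tensor(pcs_obs[sub], positions, init_metal, move_metal),
      error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    draws[it, ] <- c(fit$tensor$components, fit$tensor$metal)
  }
  ok <- stats::complete.cases(draws)
  if (sum(ok) < 2)
    stop("too few successful bootstrap draws (", sum(ok), ")")
  sds <- apply(draws[ok, , drop = FALSE], 2, sd)
  names(sds) <- c("xx", "yy", "xy", "xz", "yz",
                  "metal_x", "metal_y", "metal_z")
  list(sd = c(sds, metal_position = sqrt(sum(sds[6:8]^2))),
       skipped = skipped, iterations = iterations)
}

#' Are two delta-chi tensors oppositely oriented?
#'
#' Operationalised as a negative Pearson correlation between the PCS
#' fields the two tensors predict over the given probe positions. The
#' inclusion rule for PCS-based assignment expansion requires agreement
#' in at least two such opposite tensors.
#'
#' @param tensor_a,tensor_b fitted [dchi_tensor()]s on the same structure
#' @param positions probe positions (see [calc_pcs()])
#' @return logical; attribute `"correlation"` carries the correlation
#' @export
opposite_orientation <- function(tensor_a, tensor_b, positions) {
  fa <- calc_pcs(tensor_a, positions)
  fb <- calc_pcs(tensor_b, positions)
  if (sd(fa) == 0 || sd(fb) == 0)
    stop("degenerate (constant) PCS field; orientation undefined")
  r <- cor(fa, fb)
  structure(r < 0, correlation = r)
}

#' Expand an NOE consensus assignment with PCS restraints
#'
#' Re-runs the MMC assignment once per paramagnetic tensor with the PCS
#' deviation term enabled (weight `w_pcs`, default 10) and all previously
#' consistent assignments fixed, scanning the given cut-off range. A new
#' assignment is accepted only when at least two tensors with opposite
#' field orientations agree on it. Prior assignments contradicted by the
#' PCS runs are reported, never deleted.
#'
#' @param consensus a `consensus_assignment` from the NOE stage
#' @param tensors named list of fitted [dchi_tensor()]s
#' @param pcs_obs named list (same names) of per-peak observed PCS
#'   vectors (ppm, names = peak ids), including unassigned peaks
#' @param peaks,methyls,network,distances as in [mmc_problem()]
#' @param config an [mmc_config()]
#' @param cutoffs cut-off scan range (Angstrom)
#' @param w_pcs PCS weighting factor
#' @return list with `consensus` (augmented, with a `source` column),
#'   `accepted` (new assignments and their supporting tensors),
#'   `contradicted` (prior assignments not reproduced in a PCS run),
#'   `per_tensor` (each tensor's consensus)
#' @export
expand_assignment_pcs <- function(consensus, tensors, pcs_obs,
                                  peaks, methyls, network, distances,
                                  config = mmc_config(),
                                  cutoffs = 7:13, w_pcs = 10) {
  stopifnot(length(tensors) >= 2,
            identical(sort(names(tensors)), sort(names(pcs_obs))))
  fixed <- setNames(consensus$methyl, consensus$peak_id)
  fixed <- fixed[consensus$status == "consistent"]

  per_tensor <- list(); contradicted <- list()
  for (nm in names(tensors)) {
    calc <- calc_pcs(tensors[[nm]], methyls)
    sc <- scan_cutoff(cutoffs, peaks, methyls, network, distances,
                      config = config, fixed = fixed,
                      w_pcs = w_pcs, pcs = list(obs = pcs_obs[[nm]],
                                                calc = calc))
    per_tensor[[nm]] <- sc$consensus

    # prior (non-fixed-run) consistency check: rerun once without fixing
    # to see whether the PCS data reproduce the prior assignments
    prob <- mmc_problem(peaks, methyls, network, distances,
                        cutoff = sc$best_cutoff, w_pcs = w_pcs,
                        pcs = list(obs = pcs_obs[[nm]], calc = calc))
    free_cons <- mmc_consensus(run_mmc_trials(prob, config))
    bad <- merge(
      data.frame(peak_id = names(fixed), prior = unname(fixed),
                 stringsAsFactors = FALSE),
      free_cons[free_cons$status == "consistent",
                c("peak_id", "methyl")], by = "peak_id")
    bad <- bad[bad$prior != bad$methyl, , drop = FALSE]
    if (nrow(bad))
      contradicted[[nm]] <- data.frame(tensor = nm, bad,
                                       stringsAsFactors = FALSE)
  }

  # pairwise orientation of the tensor fields over the probe coordinates
  nms <- names(tensors)
  opp <- matrix(FALSE, length(nms), length(nms),
                dimnames = list(nms, nms))
  for (i in seq_along(nms)) for (j in seq_along(nms)) if (i < j) {
    o <- opposite_orientation(tensors[[i]], tensors[[j]], methyls)
    opp[i, j] <- opp[j, i] <- as.logical(o)
  }
  if (!any(opp)) {
    warning("no pair of tensors with opposite orientations; ",
            "no PCS-based expansions accepted")
  }

  # candidate new assignments: consistent in a PCS run, absent before
  cand <- list()
  for (nm in nms) {
    cc <- per_tensor[[nm]]
    new <- cc[cc$status == "consistent" & !(cc$peak_id %in% names(fixed)), ]
    if (nrow(new))
      cand[[nm]] <- data.frame(tensor = nm, peak_id = new$peak_id,
                               methyl = new$methyl,
                               stringsAsFactors = FALSE)
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(tensor = character(), peak_id = character(),
               methyl = character(), stringsAsFactors = FALSE)

  accepted <- list()
  for (pk in unique(cand$peak_id)) {
    rows <- cand[cand$peak_id == pk, ]
    for (m in unique(rows$methyl)) {
      sup <- rows$tensor[rows$methyl == m]
      if (length(sup) >= 2 &&
          any(opp[sup, sup, drop = FALSE])) {
        accepted[[length(accepted) + 1]] <- data.frame(
          peak_id = pk, methyl = m,
          tensors = paste(sup, collapse = ","),
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  accepted <- if (length(accepted)) do.call(rbind, accepted) else
    data.frame(peak_id = character(), methyl = character(),
               tensors = character(), stringsAsFactors = FALSE)

  out <- consensus
  out$source <- ifelse(out$status == "consistent", "noe", NA_character_)
  hit <- match(accepted$peak_id, out$peak_id)
  out$methyl[hit] <- accepted$methyl
  out$status[hit] <- "consistent"
  out$source[hit] <- "pcs"

  list(consensus = out, accepted = accepted,
       contradicted = if (length(contradicted))
         do.call(rbind, contradicted) else NULL,
       per_tensor = per_tensor, opposite = opp)
}
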