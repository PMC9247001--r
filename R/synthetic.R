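# Ground-truthed synthetic data: two-state toy methyl constellations,
# NOE cross-peak lists with dropout and false peaks, PCS fields from a
# known tensor, SBM PREs from a known metal position, and fast-exchange
# CSP titrations obeying the two-state isotherm.
#
# Every generator is a pure function of (parameters, seed). Chemical
# shifts are drawn from literature-like spectral regions per residue
# type so that overlap statistics are realistic; the region table below
# is a documented choice of this package, not a measured property of any
# particular protein.

# 13C / 1H shift regions (ppm) per methyl type
.shift_regions <- data.frame(
  residue_type = c("Ala", "Ile", "Leu", "Val", "Met", "Thr"),
  c_lo = c(16, 9,  20, 19, 15, 19),
  c_hi = c(23, 15, 26, 24, 19, 23),
  h_lo = c(1.0, 0.5, 0.6, 0.7, 1.7, 1.0),
  h_hi = c(1.6, 1.1, 1.2, 1.3, 2.2, 1.4),
  stringsAsFactors = FALSE)

# residue-type proportions of the 199-probe LmUGP-like constellation
.lmugp_type_counts <- c(Ala = 43, Ile = 16, Leu = 50, Met = 19,
                        Thr = 30, Val = 41)

.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

#' Generate a two-state toy methyl constellation
#'
#' Places `n_probes` methyl probes with realistic packing (pairwise
#' minimum 4 Angstrom, typical nearest-neighbour spacing 5-8 Angstrom),
#' draws residue types with LmUGP-like proportions and per-probe
#' chemical shifts from type-specific spectral regions, then creates a
#' second conformational state by rotating a spatially contiguous subset
#' of probes (a "hinge domain") about a random axis. Mirrors a
#' ligand-induced domain tilt between crystal forms.
#'
#' @param n_probes number of probes (>= 6); `199` with
#'   `exact_counts = TRUE` reproduces the LmUGP-scale type composition
#' @param hinge_fraction fraction of probes in the moving domain
#' @param hinge_angle rotation angle (degrees)
#' @param seed RNG seed
#' @param min_dist packing minimum distance (Angstrom)
#' @param min_shift_sep minimum peak separation in the scaled shift
#'   metric (ppm); 0 permits overlapped peaks
#' @param exact_counts use the exact 43/16/50/19/30/41 type counts
#'   (requires `n_probes = 199`)
#' @return a `two_state_toy`: list with `methyls` (list of
#'   `methyl_table`s `A`, `B`), `structures` (list of `structure_model`s),
#'   `truth` (list: `assignment` peak_id -> key, `shifts` data frame with
#'   per-peak types and shifts, `hinge_keys`, `seed`)
#' @export
make_two_state_toy <- function(n_probes = 50, hinge_fraction = 0.4,
                               hinge_angle = 17, seed = 1,
                               min_dist = 4, min_shift_sep = 0.06,
                               exact_counts = FALSE) {
  stopifnot(n_probes >= 6, hinge_fraction >= 0, hinge_fraction <= 1)
  set.seed(seed)

  # residue types
  if (exact_counts) {
    if (n_probes != sum(.lmugp_type_counts))
      stop("exact_counts requires n_probes = ",
           sum(.lmugp_type_counts))
    types <- sample(rep(names(.lmugp_type_counts), .lmugp_type_counts))
  } else {
    types <- sample(names(.lmugp_type_counts), n_probes, replace = TRUE,
                    prob = .lmugp_type_counts / sum(.lmugp_type_counts))
  }

  # sequential packing in a cube sized for ~6 A typical spacing
  side <- 6.2 * n_probes^(1 / 3)
  xyz <- matrix(NA_real_, n_probes, 3)
  for (i in seq_len(n_probes)) {
    placed <- FALSE
    for (try in 1:2000) {
      p <- runif(3, 0, side)
      if (i == 1 || min(sqrt(rowSums(sweep(xyz[seq_len(i - 1), ,
                                               drop = FALSE], 2,
                                           p)^2))) >= min_dist) {
        xyz[i, ] <- p; placed <- TRUE; break
      }
    }
    if (!placed) stop("could not pack ", n_probes,
                      " probes at min_dist = ", min_dist)
  }

  # hinge domain: the probes beyond the (1 - fraction) quantile along a
  # random direction -> spatially contiguous
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  proj <- as.vector(xyz %*% dir)
  n_h <- round(hinge_fraction * n_probes)
  hinge <- if (n_h > 0) order(proj, decreasing = TRUE)[seq_len(n_h)]
           else integer(0)

  xyz_b <- xyz
  if (length(hinge) && hinge_angle != 0) {
    ok <- FALSE
    for (try in 1:20) {
      axis <- rnorm(3)
      R <- .rotation_matrix(axis, hinge_angle)
      ctr <- colMeans(xyz[hinge, , drop = FALSE])
      moved <- sweep(sweep(xyz[hinge, , drop = FALSE], 2, ctr) %*% t(R),
                     2, ctr, `+`)
      cand <- xyz; cand[hinge, ] <- moved
      keep <- setdiff(seq_len(n_probes), hinge)
      clash <- if (length(keep))
        min(apply(moved, 1, function(p)
          min(sqrt(rowSums(sweep(cand[keep, , drop = FALSE], 2,
                                 p)^2))))) else Inf
      if (clash >= 0.85 * min_dist) { xyz_b <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("hinge rotation produced unresolvable clashes")
  }

  # chemical shifts from the type regions; a minimum separation in the
  # scaled (dH, dC/5) metric keeps peaks resolvable, as observed for
  # well-dispersed methyl TROSY spectra (196/199 resolved at LmUGP scale)
  reg <- .shift_regions[match(types, .shift_regions$residue_type), ]
  dC <- dH <- numeric(n_probes)
  for (i in seq_len(n_probes)) {
    for (try in 1:2000) {
      ci <- runif(1, reg$c_lo[i], reg$c_hi[i])
      hi <- runif(1, reg$h_lo[i], reg$h_hi[i])
      if (i == 1 || min(.scaled_dist(dH[seq_len(i - 1)] - hi,
                                     dC[seq_len(i - 1)] - ci)) >=
            min_shift_sep) break
      if (try == 2000) stop("could not separate ", n_probes,
                            " peaks at min_shift_sep = ", min_shift_sep)
    }
    dC[i] <- ci; dH[i] <- hi
  }

  scheme <- default_labeling_scheme()
  resid3 <- .type2aa3[types]
  atoms <- scheme[resid3]
  mk_table <- function(coords, model_id) {
    sm <- structure_model(seq_len(n_probes), resid3, atoms, coords,
                          model_id = model_id)
    extract_methyls(sm, scheme)
  }
  tab_a <- mk_table(xyz, "A"); tab_b <- mk_table(xyz_b, "B")
  key_of <- setNames(tab_a$key[match(seq_len(n_probes), tab_a$resno)],
                     NULL)

  peak_id <- sprintf("pk%03d", seq_len(n_probes))
  shifts <- data.frame(peak_id = peak_id, key = key_of,
                       residue_type = types, delta_H = dH, delta_C = dC,
                       stringsAsFactors = FALSE)
  list(methyls = list(A = tab_a, B = tab_b),
       structures = list(
         A = structure_model(seq_len(n_probes), resid3, atoms, xyz,
                             model_id = "A"),
         B = structure_model(seq_len(n_probes), resid3, atoms, xyz_b,
                             model_id = "B")),
       truth = list(assignment = setNames(key_of, peak_id),
                    shifts = shifts,
                    hinge_keys = key_of[hinge], seed = seed))
}

#' HMQC peak list of a toy constellation
#'
#' @param toy a [make_two_state_toy()] result (or its `truth$shifts`)
#' @param jitter_h,jitter_c Gaussian shift noise (ppm)
#' @param seed RNG seed
#' @return peak list data frame with the truth `residue_type` attached
#' @export
simulate_hmqc_peaks <- function(toy, jitter_h = 0, jitter_c = 0,
                                seed = 1) {
  sh <- if (is.data.frame(toy)) toy else toy$truth$shifts
  set.seed(seed)
  data.frame(peak_id = sh$peak_id,
             delta_H = sh$delta_H + rnorm(nrow(sh), 0, jitter_h),
             delta_C = sh$delta_C + rnorm(nrow(sh), 0, jitter_c),
             intensity = 100,
             residue_type = sh$residue_type,
             assignment = NA_character_,
             stringsAsFactors = FALSE)
}

#' Simulate a 4D NOE cross-peak list
#'
#' Every probe pair within the cut-off produces cross-peaks in both
#' directions; each direction is dropped independently with probability
#' `dropout`. False cross-peaks between pairs beyond the cut-off are
#' added at `false_rate` (expected fraction of the true directed count).
#' Cross-peaks whose four coordinates agree within `overlap_merge_tol`
#' are merged, emulating overlapped signals.
#'
#' @param methyls a `methyl_table` (one state)
#' @param shifts truth shift table (`key`, `delta_H`, `delta_C`)
#' @param cutoff NOE distance cut-off (Angstrom)
#' @param dropout per-direction dropout probability
#' @param false_rate expected false peaks as a fraction of true directed
#'   peaks
#' @param overlap_merge_tol merge tolerance (ppm, scaled metric)
#' @param seed RNG seed
#' @return data frame `f1_C`, `f2_H`, `f3_C`, `f4_H`, `intensity`;
#'   attributes `"true_pairs"` (within-cutoff key pairs) and
#'   `"kept_pairs"` (key pairs surviving with >= 1 direction)
#' @export
simulate_noe_peaks <- function(methyls, shifts, cutoff, dropout = 0,
                               false_rate = 0, overlap_merge_tol = 0,
                               seed = 1) {
  stopifnot(dropout >= 0, dropout <= 1, false_rate >= 0, false_rate < 1)
  set.seed(seed)
  D <- methyl_distances(methyls)
  keys <- methyls$key
  sh <- shifts[match(keys, shifts$key), ]
  within <- which(upper.tri(D) & D <= cutoff, arr.ind = TRUE)

  rows <- list(); kept <- character()
  add_row <- function(i, j) {           # source i -> destination j
    data.frame(f1_C = sh$delta_C[j], f2_H = sh$delta_H[j],
               f3_C = sh$delta_C[i], f4_H = sh$delta_H[i],
               intensity = 50, stringsAsFactors = FALSE)
  }
  for (r in seq_len(nrow(within))) {
    i <- within[r, 1]; j <- within[r, 2]
    d1 <- runif(1) < dropout; d2 <- runif(1) < dropout
    if (!d1) rows[[length(rows) + 1]] <- add_row(i, j)
    if (!d2) rows[[length(rows) + 1]] <- add_row(j, i)
    if (!d1 || !d2)
      kept <- c(kept, paste(sort(c(keys[i], keys[j])), collapse = "|"))
  }
  n_true <- length(rows)
  n_false <- if (false_rate > 0) stats::rpois(1, false_rate * n_true)
             else 0
  far <- which(upper.tri(D) & D > cutoff * 1.5, arr.ind = TRUE)
  if (n_false > 0 && nrow(far) > 0) {
    pick <- sample(nrow(far), min(n_false, nrow(far)))
    for (r in pick) {
      i <- far[r, 1]; j <- far[r, 2]
      rows[[length(rows) + 1]] <- add_row(i, j)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(f1_C = numeric(), f2_H = numeric(), f3_C = numeric(),
               f4_H = numeric(), intensity = numeric())

  if (overlap_merge_tol > 0 && nrow(out) > 1) {
    sig <- paste(round(out$f1_C / overlap_merge_tol),
                 round(out$f2_H / overlap_merge_tol),
                 round(out$f3_C / overlap_merge_tol),
                 round(out$f4_H / overlap_merge_tol))
    out <- stats::aggregate(out, by = list(sig = sig), FUN = mean)
    out$sig <- NULL
  }
  rownames(out) <- NULL
  attr(out, "true_pairs") <- apply(within, 1, function(ij)
    paste(sort(keys[ij]), collapse = "|"))
  attr(out, "kept_pairs") <- unique(kept)
  out
}

#' Simulate a PCS dataset from a known tensor
#'
#' @param tensor the truth [dchi_tensor()]
#' @param methyls probe positions (`methyl_table` or `methyl_ensemble`)
#' @param noise_hz Gaussian noise (Hz)
#' @param frequency_mhz spectrometer 1H frequency
#' @param bleach_radius optional PRE-bleaching radius: probes closer to
#'   the metal are dropped (near the paramagnetic centre signals vanish)
#' @param seed RNG seed
#' @return data frame `key`, `pcs_ppm`, `pcs_hz`, `sd_hz`, `r`
#' @export
simulate_pcs <- function(tensor, methyls, noise_hz = 0,
                         frequency_mhz = 500, bleach_radius = NULL,
                         seed = 1) {
  stopifnot(noise_hz >= 0)
  set.seed(seed)
  field <- calc_pcs(tensor, methyls)
  pos <- if (inherits(methyls, "methyl_ensemble"))
    apply(methyls$coords, c(1, 2), mean) else .coords_matrix(methyls)
  r <- sqrt(rowSums(sweep(pos, 2, tensor$metal)^2))
  out <- data.frame(key = names(field),
                    pcs_ppm = unname(field), r = unname(r),
                    stringsAsFactors = FALSE)
  if (!is.null(bleach_radius))
    out <- out[out$r >= bleach_radius, , drop = FALSE]
  out$pcs_hz <- out$pcs_ppm * frequency_mhz +
    rnorm(nrow(out), 0, noise_hz)
  out$pcs_ppm <- out$pcs_hz / frequency_mhz
  out$sd_hz <- rep(noise_hz, nrow(out))
  rownames(out) <- NULL
  out[, c("key", "pcs_ppm", "pcs_hz", "sd_hz", "r")]
}

#' Simulate a PRE dataset from a known metal position
#'
#' Observed Gamma2 are the bound-fraction-scaled SBM rates plus Gaussian
#' noise of magnitude `noise_frac * Gamma2 + sd_floor`, which is also
#' the reported per-observation uncertainty.
#'
#' @param metal metal position (Angstrom triple)
#' @param methyls probe positions (`methyl_table`)
#' @param physics a [pre_physics()]
#' @param noise_frac relative noise level
#' @param sd_floor additive uncertainty floor (s^-1)
#' @param seed RNG seed
#' @return data frame `key`, `gamma2`, `sd`, `r`
#' @export
simulate_pre <- function(metal, methyls, physics, noise_frac = 0,
                         sd_floor = 1, seed = 1) {
  stopifnot(noise_frac >= 0, sd_floor >= 0)
  set.seed(seed)
  pos <- .coords_matrix(methyls)
  r <- sqrt(rowSums(sweep(pos, 2, metal)^2))
  g <- sbm_gamma2(r, physics)
  sds <- noise_frac * g + sd_floor
  data.frame(key = rownames(pos) %||% methyls$key,
             gamma2 = g + if (noise_frac > 0)
               rnorm(length(g), 0, noise_frac * g) else 0,
             sd = pmax(sds, 1e-6), r = r, stringsAsFactors = FALSE)
}

#' Simulate a fast-exchange CSP titration
#'
#' Each peak moves along a straight line in shift space; the displacement
#' at each titration point is the two-state bound fraction times the
#' peak's `dnu_max`, plus Gaussian noise. Proton and carbon components
#' split by a random per-peak direction.
#'
#' @param kd dissociation constant (uM)
#' @param dnu_max named numeric vector: per-peak maximum CSP (Hz)
#' @param p_total protein concentration (uM)
#' @param l_schedule ligand concentrations (uM), non-decreasing, first
#'   typically 0
#' @param peaks0 optional starting peak list; defaults to random
#'   positions
#' @param noise_hz Gaussian shift noise per dimension (Hz)
#' @param frequency_mhz spectrometer 1H frequency
#' @param seed RNG seed
#' @return a [titration_series()]
#' @export
simulate_titration <- function(kd, dnu_max, p_total, l_schedule,
                               peaks0 = NULL, noise_hz = 0,
                               frequency_mhz = 500, seed = 1) {
  stopifnot(!is.unsorted(l_schedule), p_total > 0, kd > 0)
  set.seed(seed)
  n <- length(dnu_max)
  ids <- names(dnu_max)
  if (is.null(ids)) ids <- sprintf("pk%03d", seq_len(n))
  if (is.null(peaks0))
    peaks0 <- data.frame(peak_id = ids,
                         delta_H = runif(n, 0.4, 2.3),
                         delta_C = runif(n, 9, 26),
                         intensity = 100, residue_type = NA_character_,
                         assignment = NA_character_,
                         stringsAsFactors = FALSE)
  theta <- runif(n, 0, 2 * pi)
  c_mhz <- frequency_mhz / 4          # 13C Larmor approx gammaC/gammaH

  points <- lapply(l_schedule, function(lt) {
    f <- two_state_isotherm(p_total, lt, kd)
    dh_hz <- cos(theta) * dnu_max * f + rnorm(n, 0, noise_hz)
    dc_hz <- sin(theta) * dnu_max * f + rnorm(n, 0, noise_hz)
    pk <- peaks0
    pk$delta_H <- peaks0$delta_H + dh_hz / frequency_mhz
    pk$delta_C <- peaks0$delta_C + dc_hz / c_mhz
    list(ligand_total = lt, protein_total = p_total, peaks = pk)
  })
  titration_series(points, frequency_mhz)
}
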