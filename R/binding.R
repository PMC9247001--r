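# Quantitative binding machinery: Euclidean CSPs, two-state isotherm
# K_D fitting with Monte Carlo errors, the four-state UTP/metal/protein
# equilibrium and paramagnetic sample planning.
#
# The four-state system couples
#   U + M  <-> UM   (K_D1)      U + P  <-> UP   (K_D2)
#   UM + P <-> UMP  (K_D3)      UP + M <-> UMP  (K_D4)
# with the thermodynamic cycle K_D1 * K_D3 = K_D2 * K_D4. Specific PCS
# and PREs arise only from the ternary UMP complex; free metal must stay
# low to avoid unspecific paramagnetic effects.

#' Euclidean chemical shift perturbation
#'
#' @param dnu_h,dnu_c shift changes in the 1H and 13C dimensions (Hz)
#' @return `sqrt(dnu_h^2 + dnu_c^2)` (Hz), vectorised
#' @export
euclidean_csp <- function(dnu_h, dnu_c) {
  stopifnot(all(is.finite(dnu_h)), all(is.finite(dnu_c)))
  sqrt(dnu_h^2 + dnu_c^2)
}

#' Two-state binding isotherm
#'
#' Closed-form solution of `P + L <-> PL` under the law of mass action:
#' `Dnu_obs = ((P_t + L_t + K_D) - sqrt((P_t + L_t + K_D)^2 -
#' 4 P_t L_t)) / (2 P_t) * Dnu_max`.
#'
#' @param p_total,l_total total protein and ligand concentrations (uM)
#' @param kd dissociation constant (uM)
#' @param dnu_max maximum CSP at saturation (Hz); default 1 gives the
#'   bound fraction itself
#' @return observed CSP (Hz), vectorised over `l_total`
#' @export
two_state_isotherm <- function(p_total, l_total, kd, dnu_max = 1) {
  stopifnot(p_total > 0, kd >= 0)
  b <- p_total + l_total + kd
  (b - sqrt(b^2 - 4 * p_total * l_total)) / (2 * p_total) * dnu_max
}

#' Global K_D fit from a titration series
#'
#' Computes per-peak Euclidean CSPs relative to the first titration
#' point, selects informative peaks by the "mean + 2 SD at the highest
#' ligand point" rule, and fits one shared K_D with per-peak `Dnu_max`
#' by global nonlinear least squares (the `Dnu_max` are profiled out
#' linearly at each candidate K_D). The K_D uncertainty is one standard
#' deviation over Monte Carlo refits with Gaussian shift noise.
#'
#' @param series a [titration_series()] with tracked trajectories, or a
#'   list with `l_total` (uM), `p_total` (uM) and `csp` (peaks x points
#'   matrix of Euclidean CSPs in Hz, rownames = peak ids)
#' @param mc_iterations Monte Carlo refits
#' @param noise shift noise for the Monte Carlo error (Hz); defaults to
#'   the RMS fit residual
#' @param seed RNG seed
#' @param select apply the mean + 2 SD selection rule (default TRUE)
#' @param kd_range search interval for K_D (uM)
#' @return a `kd_fit`: list with `kd`, `kd_sd` (uM), `dnu_max` (named,
#'   Hz), `selected` (peak ids), `residual_rms`
#' @export
fit_kd_global <- function(series, mc_iterations = 1000, noise = NULL,
                          seed = 1, select = TRUE,
                          kd_range = c(1e-3, 1e6)) {
  dat <- .titration_csp(series)
  csp <- dat$csp; lt <- dat$l_total; pt <- dat$p_total
  if (length(lt) < 4) stop("need at least 4 titration points")

  endpoint <- csp[, ncol(csp)]
  if (select) {
    thr <- mean(endpoint) + 2 * sd(endpoint)
    sel <- which(endpoint > thr)
    if (!length(sel))
      stop("no peak passes the mean + 2 SD selection rule; ",
           "select peaks manually (select = FALSE)")
  } else sel <- seq_len(nrow(csp))
  y <- csp[sel, , drop = FALSE]

  # bound-fraction curve is shared; Dnu_max profiled per peak
  rss_kd <- function(kd) {
    f <- two_state_isotherm(pt, lt, kd)
    ss <- 0
    for (i in seq_len(nrow(y))) {
      dmax <- sum(f * y[i, ]) / sum(f^2)
      ss <- ss + sum((y[i, ] - dmax * f)^2)
    }
    ss
  }
  fit_once <- function(yy) {
    o <- optimize(function(lk) {
      f <- two_state_isotherm(pt, lt, exp(lk))
      ss <- 0
      for (i in seq_len(nrow(yy))) {
        dmax <- sum(f * yy[i, ]) / sum(f^2)
        ss <- ss + sum((yy[i, ] - dmax * f)^2)
      }
      ss
    }, log(kd_range))
    exp(o$minimum)
  }
  kd <- fit_once(y)
  f <- two_state_isotherm(pt, lt, kd)
  dnu_max <- apply(y, 1, function(r) sum(f * r) / sum(f^2))
  resid <- y - outer(dnu_max, f)
  rms <- sqrt(mean(resid^2))
  if (is.null(noise)) noise <- rms

  kd_sd <- NA_real_
  if (mc_iterations >= 2 && noise > 0) {
    set.seed(seed)
    draws <- vapply(seq_len(mc_iterations), function(i)
      fit_once(y + matrix(rnorm(length(y), 0, noise), nrow(y))), 0)
    kd_sd <- sd(draws)
  } else if (noise == 0) kd_sd <- 0

  structure(list(kd = kd, kd_sd = kd_sd,
                 dnu_max = setNames(dnu_max, rownames(y)),
                 selected = rownames(y), p_total = pt,
                 residual_rms = rms),
            class = "kd_fit")
}

# normalise titration input to (l_total, p_total, csp matrix in Hz)
.titration_csp <- function(series) {
  if (!inherits(series, "titration_series")) {
    stopifnot(is.matrix(series$csp), length(series$l_total) ==
                ncol(series$csp))
    return(list(csp = series$csp, l_total = series$l_total,
                p_total = series$p_total))
  }
  tr <- track_titration(series, max_step = Inf)
  pts <- series$points
  p0 <- pts[[1]]$peaks
  ids <- rownames(tr$trajectories)
  mhz <- series$frequency_mhz
  csp <- matrix(0, length(ids), length(pts),
                dimnames = list(ids, NULL))
  for (k in seq_along(pts)) {
    pk <- pts[[k]]$peaks
    j <- match(tr$trajectories[, k], pk$peak_id)
    i0 <- match(ids, p0$peak_id)
    dh <- (pk$delta_H[j] - p0$delta_H[i0]) * mhz
    dc <- (pk$delta_C[j] - p0$delta_C[i0]) * mhz / 4   # gamma_C/gamma_H
    csp[, k] <- euclidean_csp(ifelse(is.na(dh), 0, dh),
                              ifelse(is.na(dc), 0, dc))
  }
  list(csp = csp,
       l_total = vapply(pts, function(p) p$ligand_total, 0),
       p_total = pts[[1]]$protein_total)
}

#' Four-state equilibrium constants
#'
#' Collects the dissociation constants of the UTP (U) / metal (M) /
#' protein (P) system. A missing `K_D3` or `K_D4` is filled through the
#' thermodynamic cycle `K_D1 K_D3 = K_D2 K_D4`; when both are supplied
#' the cycle deviation is reported and `K_D4` takes precedence for UMP
#' formation (the measured-vs-borrowed Mn case).
#'
#' @param k_d1 UTP-metal dissociation constant (uM)
#' @param k_d2 UTP-protein dissociation constant (uM)
#' @param k_d3 UTP-protein at metal saturation (uM); optional
#' @param k_d4 metal-(UTP:protein) dissociation constant (uM); optional
#' @param provenance named character flags (`"measured"`,
#'   `"cycle-derived"`, `"approximated"`, ...)
#' @return a `four_state_constants` list with all four constants, the
#'   provenance flags and the relative cycle deviation
#' @export
four_state_constants <- function(k_d1, k_d2, k_d3 = NULL, k_d4 = NULL,
                                 provenance = NULL) {
  stopifnot(k_d1 > 0, k_d2 > 0)
  if (is.null(k_d3) && is.null(k_d4))
    stop("need K_D3 or K_D4 (the cycle determines the other)")
  prov <- c(K_D1 = "measured", K_D2 = "measured",
            K_D3 = "measured", K_D4 = "measured")
  if (!is.null(provenance)) prov[names(provenance)] <- provenance
  if (is.null(k_d4)) {
    k_d4 <- k_d1 * k_d3 / k_d2
    prov["K_D4"] <- "cycle-derived"
  } else if (is.null(k_d3)) {
    k_d3 <- k_d2 * k_d4 / k_d1
    prov["K_D3"] <- "cycle-derived"
  }
  stopifnot(k_d3 > 0, k_d4 > 0)
  cycle_dev <- abs(k_d1 * k_d3 - k_d2 * k_d4) / (k_d2 * k_d4)
  structure(list(K_D1 = k_d1, K_D2 = k_d2, K_D3 = k_d3, K_D4 = k_d4,
                 provenance = prov, cycle_deviation = cycle_dev),
            class = "four_state_constants")
}

#' K_D4 from the thermodynamic cycle
#'
#' `K_D4 = K_D1 * K_D3 / K_D2`. For the Eu3+ constants (28, 112, 152 uM)
#' this closes to 38 uM.
#'
#' @param k_d1,k_d2,k_d3 dissociation constants (uM)
#' @return K_D4 (uM)
#' @export
kd4_from_cycle <- function(k_d1, k_d2, k_d3) {
  stopifnot(k_d1 > 0, k_d2 > 0, k_d3 > 0)
  k_d1 * k_d3 / k_d2
}

#' Four-state constants for a metal of the LmUGP study
#'
#' Convenience constructor reading [lmugp_binding_constants()]: fills
#' Tb/Tm K_D1 with the averaged lanthanide value, borrows the Mg K_D2
#' (and K_D3) for Mn, and closes the cycle for missing constants.
#'
#' @param metal one of `"La"`, `"Lu"`, `"Eu"`, `"Ce"`, `"Tb"`, `"Tm"`,
#'   `"Mn"`, `"Mg"`
#' @return a [four_state_constants()]
#' @export
metal_constants <- function(metal) {
  tab <- lmugp_binding_constants()
  row <- tab[tab$metal == metal, ]
  if (nrow(row) != 1) stop("unknown metal: ", metal)
  k1 <- row$K_D1; k2 <- row$K_D2
  if (is.na(k1)) k1 <- .lanthanide_mean_kd1()
  if (is.na(k2)) k2 <- tab$K_D2[tab$metal == "Mg"]
  prov <- c(K_D1 = row$provenance_K_D1, K_D2 = row$provenance_K_D2,
            K_D3 = row$provenance_K_D3, K_D4 = row$provenance_K_D4)
  prov <- prov[!is.na(prov)]
  if (metal == "Mn") {
    # K_D3 borrowed from Mg but K_D4 independently approximated;
    # the cycle is knowingly open, K_D4 governs UMP formation
    four_state_constants(k1, k2,
                         k_d3 = tab$K_D3[tab$metal == "Mg"],
                         k_d4 = row$K_D4, provenance = prov)
  } else {
    four_state_constants(k1, k2,
                         k_d3 = if (is.na(row$K_D3)) NULL else row$K_D3,
                         k_d4 = if (is.na(row$K_D4)) NULL else row$K_D4,
                         provenance = prov)
  }
}

#' Solve the four-state equilibrium
#'
#' Solves the three mass balances
#' `P_t = P + UP + UMP`, `U_t = U + UP + UM + UMP`,
#' `M_t = M + UM + UMP` with `UP = P U / K_D2`, `UM = U M / K_D1`,
#' `UMP = P U M / (K_D2 K_D4)` for the free concentrations by damped
#' Newton iteration on log concentrations (guaranteeing positivity),
#' falling back to a nested-bisection scan over free metal.
#'
#' @param constants a [four_state_constants()] (or [metal_constants()])
#' @param p_total,u_total,m_total total concentrations (uM)
#' @param tol relative residual tolerance
#' @return a `species_concentrations` list: free `P`, `U`, `M`,
#'   complexes `UP`, `UM`, `UMP`, `fraction_UMP` (= UMP / P_t) and
#'   `free_metal` (= M), with the totals attached
#' @export
solve_four_state <- function(constants, p_total, u_total, m_total,
                             tol = 1e-10) {
  stopifnot(inherits(constants, "four_state_constants"),
            p_total > 0, u_total >= 0, m_total >= 0)
  k1 <- constants$K_D1; k2 <- constants$K_D2; k4 <- constants$K_D4
  tot <- c(p_total, u_total, m_total)

  species <- function(P, U, M) {
    UP <- P * U / k2; UM <- U * M / k1; UMP <- P * U * M / (k2 * k4)
    list(P = P, U = U, M = M, UP = UP, UM = UM, UMP = UMP)
  }
  residual <- function(s)
    c(s$P + s$UP + s$UMP - p_total,
      s$U + s$UP + s$UM + s$UMP - u_total,
      s$M + s$UM + s$UMP - m_total)

  # damped Newton on x = log(P, U, M)
  x <- log(pmax(tot / 2, 1e-12))
  scale <- pmax(tot, 1)
  ok <- FALSE
  for (it in 1:200) {
    s <- species(exp(x[1]), exp(x[2]), exp(x[3]))
    f <- residual(s)
    if (max(abs(f) / scale) < tol) { ok <- TRUE; break }
    J <- matrix(c(
      s$P + s$UP + s$UMP, s$UP + s$UMP,               s$UMP,
      s$UP + s$UMP,       s$U + s$UP + s$UM + s$UMP,  s$UM + s$UMP,
      s$UMP,              s$UM + s$UMP,               s$M + s$UM + s$UMP),
      3, 3, byrow = TRUE)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    f0 <- sum((f / scale)^2)
    repeat {
      xn <- x - lambda * step
      sn <- species(exp(xn[1]), exp(xn[2]), exp(xn[3]))
      fn <- residual(sn)
      if (sum((fn / scale)^2) < f0 || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6) break
    x <- xn
  }

  if (!ok) {
    # nested bisection over free metal (monotone residual)
    if (m_total == 0 || u_total == 0) {
      M <- 0
      keff <- k2 * (1 + M / k1) / (1 + M / k4)
      b <- p_total + u_total + keff
      C <- (b - sqrt(b^2 - 4 * p_total * u_total)) / 2
      s <- species(p_total - C, (u_total - C) / (1 + M / k1), M)
    } else {
      g <- function(M) {
        keff <- k2 * (1 + M / k1) / (1 + M / k4)
        b <- p_total + u_total + keff
        C <- (b - sqrt(pmax(b^2 - 4 * p_total * u_total, 0))) / 2
        U <- (u_total - C) / (1 + M / k1)
        UMP <- C * (M / k4) / (1 + M / k4)
        M + U * M / k1 + UMP - m_total
      }
      M <- uniroot(g, c(0, m_total), tol = 1e-13)$root
      keff <- k2 * (1 + M / k1) / (1 + M / k4)
      b <- p_total + u_total + keff
      C <- (b - sqrt(pmax(b^2 - 4 * p_total * u_total, 0))) / 2
      s <- species(p_total - C, (u_total - C) / (1 + M / k1), M)
    }
    f <- residual(s)
    if (max(abs(f) / scale) > 1e-6)
      stop("four-state solver failed to converge; residuals: ",
           paste(signif(f, 3), collapse = ", "))
  }

  structure(c(s, list(fraction_UMP = s$UMP / p_total, free_metal = s$M,
                      p_total = p_total, u_total = u_total,
                      m_total = m_total)),
            class = "species_concentrations")
}

#' @export
print.species_concentrations <- function(x, ...) {
  cat(sprintf(
    "free P/U/M: %.3g / %.3g / %.3g uM; UP %.3g, UM %.3g, UMP %.3g uM\n",
    x$P, x$U, x$M, x$UP, x$UM, x$UMP))
  cat(sprintf("fraction UMP = %.4f, free metal = %.3g uM\n",
              x$fraction_UMP, x$free_metal))
  invisible(x)
}

#' Plan a paramagnetic sample
#'
#' Solves the four-state equilibrium over a grid of total metal
#' concentrations, producing the UMP-occupancy and free-metal curves,
#' and recommends the largest total metal whose free-metal concentration
#' stays below the ceiling (default 80 uM, above which unspecific
#' paramagnetic effects appear on solvent-exposed methyls).
#'
#' @param constants a [four_state_constants()]
#' @param p_total,u_total totals (uM)
#' @param m_grid grid of total metal concentrations (uM)
#' @param free_metal_ceiling maximum tolerable free metal (uM)
#' @param occupancy_target optional desired UMP fraction; reported
#'   against the achieved one
#' @return list with `curves` (data frame `m_total`, `fraction_UMP`,
#'   `free_metal`), `recommended_m_total`, `achieved_occupancy`,
#'   `achieved_free_metal`, `target_met`
#' @export
plan_sample <- function(constants, p_total, u_total, m_grid,
                        free_metal_ceiling = 80,
                        occupancy_target = NULL) {
  stopifnot(length(m_grid) >= 1)
  m_grid <- sort(m_grid)
  sols <- lapply(m_grid, function(mt)
    solve_four_state(constants, p_total, u_total, mt))
  curves <- data.frame(
    m_total = m_grid,
    fraction_UMP = vapply(sols, function(s) s$fraction_UMP, 0),
    free_metal = vapply(sols, function(s) s$free_metal, 0))
  ok <- which(curves$free_metal <= free_metal_ceiling)
  if (!length(ok)) {
    best <- 1L
    warning("no grid point keeps free metal below the ceiling; ",
            "reporting the lowest-metal point")
  } else best <- max(ok)
  achieved <- curves$fraction_UMP[best]
  list(curves = curves,
       recommended_m_total = curves$m_total[best],
       achieved_occupancy = achieved,
       achieved_free_metal = curves$free_metal[best],
       target_met = if (is.null(occupancy_target)) NA else
         achieved >= occupancy_target)
}
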