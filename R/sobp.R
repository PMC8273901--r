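#' Bragg-Kleeman transport closure for protons in water
#'
#' Analytic stand-in for Monte Carlo proton transport: the
#' Bragg-Kleeman range-energy rule \eqn{R = \alpha E^p} with Gaussian
#' range straggling \eqn{\sigma_R = s R^t} and exponential loss of
#' primaries to nuclear interactions with attenuation length `lambda`.
#' Defaults are standard water values: alpha = 0.0022 cm/MeV^p,
#' p = 1.77, s = 0.012, t = 0.935, lambda = 100 cm (about 1% of primaries
#' removed per cm).
#'
#' @param alpha Range coefficient in cm MeV^-p, > 0.
#' @param p Range exponent, in (1, 2).
#' @param straggling_s,straggling_t Coefficients of sigma_R = s R^t (cm).
#' @param lambda Nuclear attenuation length in cm.
#' @return An object of class `bragg_kleeman_params`.
#' @export
bragg_kleeman_params <- function(alpha = 0.0022, p = 1.77,
                                 straggling_s = 0.012, straggling_t = 0.935,
                                 lambda = 100) {
  stopifnot(alpha > 0, p > 1, p < 2, straggling_s > 0, lambda > 0)
  structure(list(alpha = alpha, p = p, straggling_s = straggling_s,
                 straggling_t = straggling_t, lambda = lambda),
            class = "bragg_kleeman_params")
}

#' Range-energy conversions
#'
#' `range_energy()` gives the continuous-slowing-down range R = alpha E^p
#' in cm of water; `energy_from_range()` is its exact algebraic inverse
#' E = (R/alpha)^(1/p).
#'
#' @param bk A [bragg_kleeman_params()] object.
#' @param E Kinetic energy in MeV, > 0.
#' @param R Range in cm, > 0.
#' @return Range in cm, or energy in MeV.
#' @export
range_energy <- function(bk, E) {
  stopifnot(inherits(bk, "bragg_kleeman_params"))
  if (any(E <= 0)) stop("energy must be > 0", call. = FALSE)
  bk$alpha * E^bk$p
}

#' @rdname range_energy
#' @export
energy_from_range <- function(bk, R) {
  stopifnot(inherits(bk, "bragg_kleeman_params"))
  if (any(R <= 0)) stop("range must be > 0", call. = FALSE)
  (R / bk$alpha)^(1 / bk$p)
}

.sigma_R <- function(bk, R) bk$straggling_s * R^bk$straggling_t

# depth-dose (Gy per unit weight) of single pencil beams on a depth grid:
# rows = depths, cols = beams.  Uses the same spectral machinery as the
# public profile functions.
.beam_dose_matrix <- function(bk, ranges, z, sp) {
  A <- matrix(0, length(z), length(ranges))
  for (k in seq_along(ranges)) {
    for (i in seq_along(z)) {
      spec <- .depth_spectrum_raw(bk, ranges[k], 1, z[i])
      if (!is.null(spec)) {
        A[i, k] <- GY_PER_MEV_G *
          .trapz(spec$E, spec$psi * sp$fun(spec$E))
      }
    }
  }
  A
}

# residual-energy fluence density of one straggled beam at depth z, on the
# fixed 0.25 MeV grid; NULL when the depth is beyond range + 4 sigma.
.depth_spectrum_raw <- function(bk, range_k, weight, z,
                                grid_step = 0.25) {
  sig <- .sigma_R(bk, range_k)
  if (z >= range_k + 4 * sig) return(NULL)
  # straggled ranges reach range_k + 4 sigma; residual energy tops out there
  E_top <- energy_from_range(bk, range_k + 4 * sig - z + 1e-9)
  E <- seq(grid_step / 2, E_top + grid_step, by = grid_step)
  R <- z + bk$alpha * E^bk$p                      # range of a proton with
  jac <- bk$alpha * bk$p * E^(bk$p - 1)           # residual energy E at z
  f <- dnorm(R, mean = range_k, sd = sig) * jac
  f[abs(R - range_k) > 4 * sig] <- 0
  psi <- weight * exp(-z / bk$lambda) * f
  list(E = E, psi = psi)
}

#' Pencil-beam weights for a flat spread-out Bragg peak
#'
#' Computes non-negative weights for `n` pencil beams whose ranges are
#' equally spaced across the modulation interval, such that the composed
#' depth-dose is flat on the plateau.  The primary route is the
#' closed-form power-law weighting (bin integrals of the continuous
#' density \eqn{w(R) \propto (R_{distal} - R)^{-1/p}}, the exact flat
#' solution for pristine peaks of the form \eqn{(R-z)^{1/p-1}}).  When
#' range straggling degrades the achieved flatness beyond `tol`, a
#' non-negative least-squares refinement against the straggled dose
#' engine replaces it.  Weights are scaled so the mean plateau dose is
#' 1 Gy (per unit fluence normalisation).
#'
#' @param n Number of beams, >= 1.
#' @param proximal,distal Plateau interval in cm depth, distal > proximal.
#' @param bk A [bragg_kleeman_params()] object.
#' @param tol Flatness tolerance: max |dose - mean| / mean on the plateau
#'   (default 0.02).
#' @return A numeric weight vector with attributes `ranges` (cm),
#'   `achieved_flatness` and `flat` (whether `tol` was met; an
#'   unattainable tolerance is flagged, not an error).
#' @export
sobp_weights <- function(n, proximal, distal, bk = bragg_kleeman_params(),
                         tol = 0.02) {
  stopifnot(n >= 1, distal > proximal, proximal >= 0)
  sp <- stopping_power_bragg_kleeman("proton", bk)
  ranges <- if (n == 1L) distal else seq(proximal, distal, length.out = n)
  if (n == 1L) {
    w <- 1
  } else {
    # bin integrals of the continuous density (distal - R)^(-1/p),
    # distal bin clipped at the distal edge
    q <- 1 - 1 / bk$p
    h <- (distal - proximal) / (n - 1)
    lo <- ranges - h / 2
    hi <- pmin(ranges + h / 2, distal)
    w <- (distal - lo)^q - pmax(distal - hi, 0)^q
  }
  # flatness measured away from the straggling-smeared edges
  margin <- max(2 * .sigma_R(bk, distal), 0.1)
  zp <- seq(proximal + margin, distal - margin, by = 0.1)
  A <- .beam_dose_matrix(bk, ranges, zp, sp)
  flatness <- function(w) {
    d <- as.vector(A %*% w)
    max(abs(d - mean(d))) / mean(d)
  }
  flat <- flatness(w)
  if (flat > tol && n > 1L) {
    # non-negative least squares against the straggled dose engine,
    # polished toward minimax flatness by Lawson-style reweighting;
    # the best iterate wins
    b <- rep(1, length(zp))
    u <- b
    for (it in seq_len(30L)) {
      su <- sqrt(u)
      w_it <- pracma::lsqnonneg(A * su, b * su)$x
      flat_it <- flatness(w_it)
      if (flat_it < flat) {
        w <- w_it
        flat <- flat_it
      }
      r <- abs(as.vector(A %*% w_it) - b)
      u <- u * (r + 1e-12)
      u <- u * (length(u) / sum(u))
    }
  }
  w <- w / mean(as.vector(A %*% w))   # unit mean plateau dose
  structure(w, ranges = ranges, achieved_flatness = flat, flat = flat <= tol)
}

#' Compose a spread-out Bragg peak plan
#'
#' Builds the default demonstrator scenario: `n_beams` proton pencil
#' beams with ranges equally spaced so the highest-energy beam
#' (`max_energy`, default 180 MeV) sits at the distal edge and the
#' modulation (plateau) width is `modulation` cm.
#'
#' @param n_beams Number of pencil beams.
#' @param max_energy Maximal nominal energy in MeV.
#' @param modulation Plateau width in cm.
#' @param bk A [bragg_kleeman_params()] object.
#' @param tol Flatness tolerance passed to [sobp_weights()].
#' @return An object of class `sobp_plan` with fields `beams` (data frame
#'   of `energy_MeV`, `range_cm`, `weight`), `proximal`, `distal`, `bk`
#'   and `flatness`.
#' @export
sobp_plan <- function(n_beams = 20, max_energy = 180, modulation = 10,
                      bk = bragg_kleeman_params(), tol = 0.02) {
  stopifnot(n_beams >= 1, max_energy > 0, modulation > 0)
  distal <- range_energy(bk, max_energy)
  proximal <- distal - modulation
  if (proximal <= 0) {
    stop("modulation exceeds the distal range", call. = FALSE)
  }
  w <- sobp_weights(n_beams, proximal, distal, bk = bk, tol = tol)
  ranges <- attr(w, "ranges")
  structure(
    list(beams = data.frame(energy_MeV = energy_from_range(bk, ranges),
                            range_cm = ranges,
                            weight = as.numeric(w)),
         proximal = proximal, distal = distal, bk = bk,
         flatness = attr(w, "achieved_flatness"),
         flat = attr(w, "flat")),
    class = "sobp_plan"
  )
}

#' @export
print.sobp_plan <- function(x, ...) {
  cat(sprintf(
    "<sobp_plan> %d proton beams, %.1f-%.1f MeV, plateau [%.2f, %.2f] cm\n",
    nrow(x$beams), min(x$beams$energy_MeV), max(x$beams$energy_MeV),
    x$proximal, x$distal))
  cat(sprintf("  plateau flatness %.3f%% (target met: %s)\n",
              100 * x$flatness, x$flat))
  invisible(x)
}

#' Primary-proton fluence spectrum at depth
#'
#' The residual-energy spectrum of the plan's primary protons at depth
#' `z`: each beam's straggled range distribution (Gaussian, truncated at
#' +/- 4 sigma) is mapped through the Bragg-Kleeman inverse to a residual
#' energy density, attenuated by nuclear interactions as exp(-z/lambda),
#' and the weighted mixture is discretised on a fixed 0.25 MeV grid.
#' Beams whose range (+ 4 sigma) is exceeded contribute nothing;
#' secondary particles are outside this demonstrator.
#'
#' @param plan An [sobp_plan()] object.
#' @param z Depth in cm, >= 0.
#' @return A [fluence_spectrum()]; zero fluence past all ranges.
#' @export
depth_spectrum <- function(plan, z) {
  stopifnot(inherits(plan, "sobp_plan"), length(z) == 1L)
  if (z < 0) stop("depth must be >= 0", call. = FALSE)
  bk <- plan$bk
  E_max <- max(plan$beams$range_cm + 4 * .sigma_R(bk, plan$beams$range_cm))
  grid <- seq(0.125, energy_from_range(bk, E_max) + 0.25, by = 0.25)
  psi <- numeric(length(grid))
  for (k in seq_len(nrow(plan$beams))) {
    s <- .depth_spectrum_raw(bk, plan$beams$range_cm[k],
                             plan$beams$weight[k], z)
    if (!is.null(s)) {
      idx <- seq_along(s$E)
      keep <- idx[idx <= length(grid)]
      psi[keep] <- psi[keep] + s$psi[keep]
    }
  }
  fluence_spectrum("proton", grid, psi)
}

#' Depth-resolved dose, damage and OER profile of an SOBP
#'
#' Walks the depth grid, builds the primary-proton spectrum at each
#' depth, and evaluates dose, damage per oxygen level and the
#' spectrum-level OER_d against the fully hypoxic reference.
#'
#' @param plan An [sobp_plan()] object.
#' @param model A proton [fd_model()].
#' @param sp A `stopping_power` model (defaults to the Bragg-Kleeman
#'   closure of the plan).
#' @param O2_levels Oxygen levels in percent; must include the reference 0.
#' @param z_grid Depths in cm (default 1 mm steps over 30 cm).
#' @return An object of class `depth_profile`: list with `z_cm`, `dose_Gy`
#'   and matrices `damage` / `oer` (one column per oxygen level, named
#'   `p<level>`).
#' @export
depth_oer_profile <- function(plan, model, sp = NULL,
                              O2_levels = c(0, 0.1, 10, 20),
                              z_grid = seq(0.05, 30, by = 0.1)) {
  stopifnot(inherits(plan, "sobp_plan"), inherits(model, "fd_model"))
  if (!0 %in% O2_levels) {
    stop("O2_levels must include the hypoxic reference 0", call. = FALSE)
  }
  if (is.null(sp)) sp <- stopping_power_bragg_kleeman("proton", plan$bk)
  nz <- length(z_grid)
  dose <- numeric(nz)
  dmg <- matrix(0, nz, length(O2_levels),
                dimnames = list(NULL, paste0("p", O2_levels)))
  for (i in seq_len(nz)) {
    spec <- depth_spectrum(plan, z_grid[i])
    if (all(spec$fluence == 0)) next
    dose[i] <- dose_integral(spec, sp)
    for (j in seq_along(O2_levels)) {
      dmg[i, j] <- damage_integral(spec, sp, model, O2_levels[j])
    }
  }
  ref <- dmg[, "p0"]
  oer <- dmg / ifelse(ref > 0, ref, NA_real_)
  structure(
    list(z_cm = z_grid, dose_Gy = dose, damage = dmg, oer = oer,
         O2_levels = O2_levels, plan = plan),
    class = "depth_profile"
  )
}

#' Summarise the OER structure of a depth profile
#'
#' Extracts the quantities of interest from a depth-OER profile at one
#' oxygen level: the OER_d at the proximal and distal ends of the
#' high-dose plateau (measured just inside the straggling-smeared
#' edges), its relative decrease across the plateau, and the OER_d just
#' beyond the Bragg peak (first depth where the dose has fallen below 5%
#' of the plateau mean) with its relative drop from the distal plateau
#' value.
#'
#' @param profile A [depth_oer_profile()] result.
#' @param O2 Oxygen level (percent) to summarise; must be one of the
#'   profile's levels.
#' @return A list with `oer_proximal`, `oer_distal`,
#'   `plateau_decrease_percent`, `oer_beyond_peak`,
#'   `beyond_peak_drop_percent` and the depths used.
#' @export
sobp_oer_summary <- function(profile, O2 = 10) {
  stopifnot(inherits(profile, "depth_profile"))
  col <- paste0("p", O2)
  if (!col %in% colnames(profile$oer)) {
    stop("profile has no oxygen level ", O2, call. = FALSE)
  }
  plan <- profile$plan
  z <- profile$z_cm
  margin <- max(2 * .sigma_R(plan$bk, plan$distal), 0.1)
  i_prox <- which.min(abs(z - (plan$proximal + margin)))
  i_dist <- which.min(abs(z - (plan$distal - margin)))
  plateau <- z >= plan$proximal + margin & z <= plan$distal - margin
  d_plat <- mean(profile$dose_Gy[plateau])
  oer <- profile$oer[, col]
  beyond <- which(z > plan$distal & profile$dose_Gy < 0.05 * d_plat &
                    profile$dose_Gy > 0)
  i_bey <- if (length(beyond)) beyond[1] else NA_integer_
  list(
    oer_proximal = oer[i_prox],
    oer_distal = oer[i_dist],
    plateau_decrease_percent =
      100 * (oer[i_prox] - oer[i_dist]) / oer[i_prox],
    oer_beyond_peak = if (is.na(i_bey)) NA_real_ else oer[i_bey],
    beyond_peak_drop_percent =
      if (is.na(i_bey)) NA_real_ else 100 * (1 - oer[i_bey] / oer[i_dist]),
    z_proximal = z[i_prox], z_distal = z[i_dist],
    z_beyond_peak = if (is.na(i_bey)) NA_real_ else z[i_bey]
  )
}

#' Write a depth profile as CSV
#'
#' Columns `z_cm,dose_Gy,oer_p<level>,...`, one row per depth.
#'
#' @param profile A [depth_oer_profile()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_depth_profile <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  df <- data.frame(z_cm = profile$z_cm, dose_Gy = profile$dose_Gy)
  oer <- profile$oer
  colnames(oer) <- paste0("oer_", colnames(oer))
  df <- cbind(df, as.data.frame(oer))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
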