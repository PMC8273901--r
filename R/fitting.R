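#' Fit the arctangent energy model to one oxygen level
#'
#' Stage-1 fit of the four-parameter arctangent LET-transition model to
#' the energy dependence of yields observed at a single oxygen tension.
#' Positivity of the asymptotes, the midpoint and the width is enforced by
#' parameterization (the asymptotes on a natural-log scale and the
#' energy-scale parameters on a log10 axis), so the Levenberg-Marquardt
#' minimisation stays unconstrained.  Starting points are deterministic
#' and scale-free: the yield extrema for the asymptotes, the mid-yield
#' crossing energy for the midpoint, and a small multi-start over
#' candidate widths (half the span of the central 10-90% yield band, and
#' fractions of the midpoint energy) guarding against the known
#' degeneracy in which a vanishing midpoint with a broad width mimics
#' the transition; the start with the lowest objective wins.
#'
#' @param table A [damage_yield_table()] restricted to one oxygen level
#'   with at least 5 distinct energies spanning the transition.
#' @return An [arctan_params()] object with attributes `se` (delta-method
#'   standard errors of the four natural-scale parameters), `ssr` and
#'   `n_iterations`.
#' @export
fit_arctan <- function(table) {
  stopifnot(inherits(table, "damage_yield_table"))
  if (length(unique(table$oxygen_percent)) != 1L) {
    stop("fit_arctan expects a single oxygen level", call. = FALSE)
  }
  E <- table$energy_MeV
  y <- table$yield_dsb_per_cell_gbp_gy
  w <- if ("sigma" %in% names(table) && all(table$sigma > 0)) {
    1 / table$sigma
  } else {
    rep(1, length(y))
  }
  ord <- order(E)
  E <- E[ord]; y <- y[ord]; w <- w[ord]
  if (length(unique(E)) < 5L) {
    stop("need at least 5 distinct energies", call. = FALSE)
  }
  if ((max(y) - min(y)) < 0.05 * mean(y)) {
    stop("transition not identifiable: yield dynamic range below 5% of mean",
         call. = FALSE)
  }
  fn <- function(th) {
    p <- .arctan_untransform(th)
    w * (y - arctan_damage(p, E))
  }
  fit <- NULL
  for (th0 in .arctan_starts(E, y)) {
    cand <- minpack.lm::nls.lm(
      par = th0, fn = fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0))
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  pars <- .arctan_untransform(fit$par)
  # delta method: natural-scale se from log-scale covariance
  se <- rep(NA_real_, 4)
  cv <- try(vcov(fit), silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv)))) {
    scale <- c(pars$dsb0, pars$dsb_inf, pars$E0 * log(10), pars$Gamma * log(10))
    se <- sqrt(pmax(diag(cv), 0)) * scale
  }
  attr(pars, "se") <- setNames(se, c("dsb0", "dsb_inf", "E0", "Gamma"))
  attr(pars, "ssr") <- sum(fn(fit$par)^2)
  attr(pars, "n_iterations") <- fit$niter
  pars
}

# theta = (log dsb0, log dsb_inf, log10 E0, log10 Gamma)
.arctan_untransform <- function(th) {
  arctan_params(dsb0 = exp(th[1]), dsb_inf = exp(th[2]),
                E0 = 10^th[3], Gamma = 10^th[4])
}

.arctan_starts <- function(E, y) {
  lo <- min(y); hi <- max(y); mid <- (lo + hi) / 2
  # first energy (ascending) at which the yield falls through the midpoint
  below <- y <= mid
  k <- which(below)[1]
  E0 <- if (is.na(k) || k == 1L) {
    exp(mean(log(range(E))))
  } else {
    # log-linear interpolation of the crossing
    f <- (mid - y[k - 1]) / (y[k] - y[k - 1])
    10^(log10(E[k - 1]) + f * (log10(E[k]) - log10(E[k - 1])))
  }
  band <- E[y > lo + 0.1 * (hi - lo) & y < lo + 0.9 * (hi - lo)]
  g_band <- if (length(band) >= 2L) (max(band) - min(band)) / 2 else E0
  lapply(unique(pmax(c(g_band, E0 / 2, E0 / 10), 1e-12)),
         function(g) c(log(hi), log(lo), log10(E0), log10(g)))
}

# fit a rational saturation g(p) = (a p + b)/(p + c) to points (p, v),
# all v > 0.  Linear relaxation (a p + b - c v = v p) seeds a log-scale
# LM polish; with < 3 distinct p the scale c is pinned at 1.
.fit_rational <- function(p, v) {
  stopifnot(length(p) == length(v), all(v > 0))
  np <- length(unique(p))
  if (np < 3L) {
    A <- cbind(p, 1)
    ab <- qr.solve(A, v * (p + 1))
    return(rational_coeffs(a = max(ab[1], 1e-12), b = max(ab[2], 1e-12), c = 1))
  }
  A <- cbind(p, 1, -v)
  abc <- qr.solve(A, v * p)
  a0 <- abc[1]; b0 <- abc[2]; c0 <- abc[3]
  floor_ <- 1e-8 * max(abs(v))
  th0 <- log(c(max(a0, floor_), max(b0, floor_), max(c0, 1e-6)))
  fn <- function(th) v - (exp(th[1]) * p + exp(th[2])) / (p + exp(th[3]))
  fit <- minpack.lm::nls.lm(
    par = th0, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  rational_coeffs(a = exp(fit$par[1]), b = exp(fit$par[2]),
                  c = exp(fit$par[3]))
}

#' Bootstrap the twelve-coefficient damage surface from a yield table
#'
#' Three-stage Levenberg-Marquardt procedure: (1) the arctangent model is
#' fitted independently at every oxygen level ([fit_arctan()]); (2) each
#' of the four rational saturation functions g1..g4 is fitted to the
#' stage-1 parameters versus oxygen; (3) all twelve coefficients are
#' refined jointly against every record, starting from stages 1-2.  All
#' scale coefficients are log-parameterized, keeping the minimisation
#' unconstrained while guaranteeing positivity.  Records are sorted
#' internally, so the result is invariant to input order.  If the joint
#' refinement fails to improve the stage-1/2 initialisation it is
#' discarded; if the high-LET branch dips below the low-LET branch
#' (g4 < g3) at any fitted oxygen level the result is flagged, not
#' clipped.
#'
#' @param table A [damage_yield_table()] with at least 2 oxygen levels and
#'   5 distinct energies.  When a `sigma` column is present its inverse is
#'   used as weights; otherwise the fit is unweighted.
#' @return An object of class `fit_result`: a list with elements `model`
#'   (the fitted [fd_model()]), `residuals` (observed - predicted, in
#'   table order after sorting), `residual_std` (population standard
#'   deviation), `residual_range`, `per_level_arctan` (stage-1
#'   diagnostics), `converged`, `g4_ge_g3` and `n_iterations`.
#' @export
fit_fd <- function(table) {
  stopifnot(inherits(table, "damage_yield_table"))
  tab <- as.data.frame(table)
  tab <- tab[order(tab$oxygen_percent, tab$energy_MeV,
                   tab$yield_dsb_per_cell_gbp_gy), , drop = FALSE]
  rownames(tab) <- NULL
  levels <- sort(unique(tab$oxygen_percent))
  if (length(levels) < 2L) {
    stop("need at least 2 distinct oxygen levels", call. = FALSE)
  }
  if (length(unique(tab$energy_MeV)) < 5L) {
    stop("need at least 5 distinct energies", call. = FALSE)
  }
  species <- tab$species[1]

  # stage 1: per-level arctangent fits
  per_level <- lapply(levels, function(p) {
    sl <- tab[tab$oxygen_percent == p, , drop = FALSE]
    cls <- class(table)
    class(sl) <- cls
    list(oxygen_percent = p, params = fit_arctan(sl))
  })
  s1 <- data.frame(
    oxygen_percent = levels,
    E0 = vapply(per_level, function(l) l$params$E0, 0),
    Gamma = vapply(per_level, function(l) l$params$Gamma, 0),
    dsb_inf = vapply(per_level, function(l) l$params$dsb_inf, 0),
    dsb0 = vapply(per_level, function(l) l$params$dsb0, 0)
  )

  # stage 2: oxygen saturation of each arctangent parameter
  g1 <- .fit_rational(s1$oxygen_percent, s1$E0)
  g2 <- .fit_rational(s1$oxygen_percent, s1$Gamma)
  g3 <- .fit_rational(s1$oxygen_percent, s1$dsb_inf)
  g4 <- .fit_rational(s1$oxygen_percent, s1$dsb0)

  E <- tab$energy_MeV
  p <- tab$oxygen_percent
  y <- tab$yield_dsb_per_cell_gbp_gy
  w <- if ("sigma" %in% names(tab) && all(tab$sigma > 0)) {
    1 / tab$sigma
  } else {
    rep(1, length(y))
  }
  mk_model <- function(th) {
    fd_model(species,
             g1 = rational_coeffs(exp(th[1]), exp(th[2]), exp(th[3])),
             g2 = rational_coeffs(exp(th[4]), exp(th[5]), exp(th[6])),
             g3 = rational_coeffs(exp(th[7]), exp(th[8]), exp(th[9])),
             g4 = rational_coeffs(exp(th[10]), exp(th[11]), exp(th[12])),
             energy_range = range(E), oxygen_range = range(p),
             provenance = sprintf("fitted to %d records", length(y)))
  }
  th0 <- log(unlist(lapply(list(g1, g2, g3, g4),
                           function(g) c(g$a, g$b, g$c))))
  fn <- function(th) {
    m <- try(mk_model(th), silent = TRUE)
    if (inherits(m, "try-error")) return(rep(1e6, length(y)))
    w * (y - .fd_eval_raw(m, E, p))
  }
  ssr0 <- sum(fn(th0)^2)

  # stage 3: joint refinement of all twelve coefficients
  fit <- minpack.lm::nls.lm(
    par = th0, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0))
  converged <- fit$info %in% 1:4
  use_joint <- converged && sum(fit$fvec^2) <= ssr0
  th <- if (use_joint) fit$par else th0
  model <- mk_model(th)

  lo <- rational_eval(model$g3, levels)
  hi <- rational_eval(model$g4, levels)
  res <- y - .fd_eval_raw(model, E, p)
  structure(
    list(model = model,
         table = tab,
         residuals = res,
         residual_std = sqrt(mean(res^2) - mean(res)^2),
         residual_range = range(res),
         per_level_arctan = per_level,
         stage1 = s1,
         converged = use_joint,
         g4_ge_g3 = all(hi >= lo),
         n_iterations = fit$niter),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d records, %d oxygen levels\n",
              length(x$residuals), nrow(x$stage1)))
  cat(sprintf("  residual std %.4g, range [%.4g, %.4g]\n",
              x$residual_std, x$residual_range[1], x$residual_range[2]))
  cat(sprintf("  converged: %s   g4 >= g3 on fitted grid: %s\n",
              x$converged, x$g4_ge_g3))
  print(x$model)
  invisible(x)
}

#' Residual summary of a surface fit
#'
#' @param result A [fit_fd()] result.
#' @return A list with `std` (population standard deviation, divisor n),
#'   `min`, `max`, and `max_rel_percent` (largest absolute residual
#'   relative to the observed yield, in percent).
#' @export
residual_stats <- function(result) {
  r <- if (inherits(result, "fit_result")) result$residuals else result
  if (!length(r)) stop("no residuals", call. = FALSE)
  obs <- if (inherits(result, "fit_result")) {
    result$table$yield_dsb_per_cell_gbp_gy
  } else {
    NULL
  }
  out <- list(std = sqrt(mean(r^2) - mean(r)^2), min = min(r), max = max(r))
  out$max_rel_percent <- if (!is.null(obs)) 100 * max(abs(r) / obs) else NA_real_
  out
}
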