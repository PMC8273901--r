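#' The combined energy-oxygen damage surface
#'
#' The central object of the package: a twelve-coefficient analytic
#' surface giving the complex-damage yield (DSBc per cell per Gbp per Gy)
#' of one particle species as a joint function of kinetic energy E (MeV)
#' and oxygen tension p (percent),
#' \deqn{F_d(E, p) = |g_4(p) - g_3(p)|
#'   \left[\frac{1}{\pi}\arctan\frac{g_1(p) - E}{g_2(p)} + \frac12\right]
#'   + g_3(p),}
#' where each \eqn{g_i(p) = (a_i p + b_i)/(p + c_i)} is a rational
#' saturation function of oxygen.  g1 supplies the transition midpoint
#' (MeV), g2 the transition width (MeV), g3 the high-energy (low-LET)
#' asymptote and g4 the low-energy (high-LET) asymptote.
#'
#' @param species Species name or [particle_species()] object.
#' @param g1,g2,g3,g4 [rational_coeffs()] objects (or 3-element lists with
#'   fields `a`, `b`, `c`) mapping oxygen percent to the arctangent
#'   parameters.
#' @param energy_range Validity window in MeV, length-2 increasing.
#' @param oxygen_range Validity window in percent, length-2 increasing.
#' @param provenance Free-text note carried through serialization.
#' @return An object of class `fd_model`.
#' @seealso [fd_eval()], [oer_point()], [fit_fd()], [write_fd_model()]
#' @export
fd_model <- function(species, g1, g2, g3, g4,
                     energy_range = c(0.01, 1000),
                     oxygen_range = c(0, 100),
                     provenance = "") {
  as_rc <- function(g) {
    if (inherits(g, "rational_coeffs")) g else rational_coeffs(g$a, g$b, g$c)
  }
  g1 <- as_rc(g1); g2 <- as_rc(g2); g3 <- as_rc(g3); g4 <- as_rc(g4)
  stopifnot(length(energy_range) == 2L, energy_range[1] < energy_range[2],
            length(oxygen_range) == 2L, oxygen_range[1] <= oxygen_range[2])
  m <- structure(
    list(species = particle_species(species),
         g1 = g1, g2 = g2, g3 = g3, g4 = g4,
         energy_range = as.numeric(energy_range),
         oxygen_range = as.numeric(oxygen_range),
         provenance = provenance),
    class = "fd_model"
  )
  # width and both asymptotes must stay positive across the oxygen window
  pgrid <- seq(oxygen_range[1], oxygen_range[2], length.out = 33L)
  if (any(rational_eval(g2, pgrid) <= 0)) {
    stop("g2(p) must be > 0 over the oxygen range", call. = FALSE)
  }
  if (any(rational_eval(g3, pgrid) <= 0) || any(rational_eval(g4, pgrid) <= 0)) {
    stop("g3(p) and g4(p) must be > 0 over the oxygen range", call. = FALSE)
  }
  m
}

#' @export
print.fd_model <- function(x, ...) {
  cat(sprintf("<fd_model> species = %s\n", x$species$name))
  for (nm in c("g1", "g2", "g3", "g4")) {
    g <- x[[nm]]
    cat(sprintf("  %s: (%.8g p + %.8g) / (p + %.8g)\n", nm, g$a, g$b, g$c))
  }
  cat(sprintf("  energy range  [%g, %g] MeV\n",
              x$energy_range[1], x$energy_range[2]))
  cat(sprintf("  oxygen range  [%g, %g] %%\n",
              x$oxygen_range[1], x$oxygen_range[2]))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Evaluate the damage surface
#'
#' Evaluates F_d(E, p) elementwise; `E` and `O2` recycle against each
#' other as usual.  Arguments outside the model's stated validity window
#' raise a warning but are still evaluated (the closed form is globally
#' defined; only the fit is range-limited).
#'
#' @param model An [fd_model()] object.
#' @param E Kinetic energy in MeV, > 0 (scalar or vector).
#' @param O2 Oxygen tension ([oxygen_tension()] or percent values).
#' @return Yield in DSB per cell per Gbp per Gy.
#' @export
fd_eval <- function(model, E, O2) {
  stopifnot(inherits(model, "fd_model"))
  if (any(!is.finite(E)) || any(E <= 0)) {
    stop("kinetic energy must be finite and > 0", call. = FALSE)
  }
  p <- .o2_percent(O2)
  if (any(E < model$energy_range[1]) || any(E > model$energy_range[2])) {
    warning("energy outside the model's fitted range [",
            model$energy_range[1], ", ", model$energy_range[2],
            "] MeV; extrapolating", call. = FALSE)
  }
  if (any(p < model$oxygen_range[1]) || any(p > model$oxygen_range[2])) {
    warning("oxygen tension outside the model's fitted range; extrapolating",
            call. = FALSE)
  }
  .fd_eval_raw(model, E, p)
}

# inner evaluator without window warnings (hot path for integrals/fitting)
.fd_eval_raw <- function(model, E, p) {
  e0 <- rational_eval(model$g1, p)
  gm <- rational_eval(model$g2, p)
  lo <- rational_eval(model$g3, p)
  hi <- rational_eval(model$g4, p)
  s <- atan((e0 - E) / gm) / pi + 0.5
  abs(hi - lo) * s + lo
}

#' Point oxygen enhancement ratio of damage
#'
#' The damage-based OER at a single kinetic energy,
#' \deqn{OER_d(E, [O_2]) = F_d(E, [O_2]) / F_d(E, [O_2]_{ref}),}
#' with the fully hypoxic environment (0% oxygen) as the default
#' reference.
#'
#' @inheritParams fd_eval
#' @param O2_ref Reference oxygen tension (default 0%).
#' @return The dimensionless ratio; exactly 1 when `O2 == O2_ref`.
#' @export
oer_point <- function(model, E, O2, O2_ref = 0) {
  num <- fd_eval(model, E, O2)
  den <- fd_eval(model, E, O2_ref)
  if (any(den == 0)) stop("reference damage is zero", call. = FALSE)
  num / den
}

#' Read and write damage-surface model files
#'
#' Models serialize to JSON with keys `species`, `g1`..`g4` (each with
#' `a`, `b`, `c`), `energy_range_MeV`, `oxygen_range_percent` and
#' `provenance`.  Numbers are written with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param model An [fd_model()] object.
#' @param path File path.
#' @return `write_fd_model()` returns `path` invisibly; `read_fd_model()`
#'   returns the [fd_model()].
#' @export
write_fd_model <- function(model, path) {
  stopifnot(inherits(model, "fd_model"))
  gl <- function(g) list(a = g$a, b = g$b, c = g$c)
  obj <- list(
    species = model$species$name,
    g1 = gl(model$g1), g2 = gl(model$g2),
    g3 = gl(model$g3), g4 = gl(model$g4),
    energy_range_MeV = model$energy_range,
    oxygen_range_percent = model$oxygen_range,
    provenance = model$provenance
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_fd_model
#' @export
read_fd_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  need <- c("species", "g1", "g2", "g3", "g4",
            "energy_range_MeV", "oxygen_range_percent")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    stop("model file is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fd_model(
    species = obj$species,
    g1 = obj$g1, g2 = obj$g2, g3 = obj$g3, g4 = obj$g4,
    energy_range = obj$energy_range_MeV,
    oxygen_range = obj$oxygen_range_percent,
    provenance = if (is.null(obj$provenance)) "" else obj$provenance
  )
}
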