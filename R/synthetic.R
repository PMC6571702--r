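#' Debye form factor of a Gaussian chain
#'
#' `P(q) = 2 (exp(-x) + x - 1) / x^2` with `x = (q Rg)^2`; `P(0) = 1`.
#' The small-x branch uses the series expansion for numerical stability.
#'
#' @param q Scattering vector, 1/A.
#' @param rg Radius of gyration, A.
#' @return Form factor values in (0, 1].
#' @export
#' @examples
#' debye_form_factor(0.1, 13)
debye_form_factor <- function(q, rg) {
  stopifnot(all(q >= 0), rg > 0)
  x <- (q * rg)^2
  out <- ifelse(x < 1e-4,
                1 - x / 3 + x^2 / 12,
                2 * (exp(-x) + x - 1) / x^2)
  out
}

#' Default instrument q-grid
#'
#' Logarithmic grid spanning the measured scattering-vector range
#' 0.0036-0.49 1/A.
#'
#' @param n Number of points.
#' @return Numeric vector of q values, 1/A.
#' @export
saxs_q_grid <- function(n = 200) {
  exp(seq(log(0.0036), log(0.49), length.out = n))
}

#' Synthetic SAXS curve of a coil / oligomer mixture
#'
#' Generates a scattering curve for a mixture of Gaussian-chain species:
#' oligomers of `s` chains scatter with forward intensity proportional to
#' `s^2` per particle and radius of gyration `rg * s^nu`. With chain (mass)
#' fractions `f_s`, the per-chain-normalised intensity is
#' `I(q) = I0 * sum_s f_s * s * P(q; rg_s)`, so the forward scattering of a
#' 90% monomer / 10% dimer mixture is 1.1 times that of pure monomer at
#' equal mass concentration. Noise is multiplicative Gaussian with relative
#' level `noise` (the per-point `sigma` column records `noise * I`).
#'
#' @param rg Monomer radius of gyration, A.
#' @param i0 Forward intensity of the pure monomer at this concentration.
#' @param fractions Named numeric vector of chain fractions by oligomer
#'   size, e.g. `c("1" = 0.9, "2" = 0.1)`; must sum to 1.
#' @param q q-grid, 1/A (default [saxs_q_grid()]).
#' @param noise Relative noise level (>= 0).
#' @param nu Size-scaling exponent for oligomer Rg (`rg_s = rg * s^nu`).
#' @param concentration Metadata, mg/mL.
#' @param seed Optional seed; the curve is a pure function of
#'   (arguments, seed).
#' @param label Curve label.
#' @return A `"scattering_curve"`.
#' @export
#' @examples
#' crv <- synth_saxs_curve(rg = 13, i0 = 3, noise = 0.01, seed = 1)
synth_saxs_curve <- function(rg = 13, i0 = 1, fractions = c("1" = 1),
                             q = saxs_q_grid(), noise = 0, nu = 0.5,
                             concentration = 1, seed = NULL,
                             label = "synthetic") {
  stopifnot(rg > 0, i0 > 0, noise >= 0, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-9)
  sizes <- as.numeric(names(fractions))
  if (any(is.na(sizes)) || any(sizes < 1)) {
    stop("`fractions` must be named by integer oligomer size", call. = FALSE)
  }
  intensity <- rowSums(vapply(seq_along(sizes), function(k) {
    s <- sizes[k]
    fractions[k] * s * debye_form_factor(q, rg * s^nu)
  }, numeric(length(q))))
  intensity <- i0 * intensity
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (noise > 0) {
    intensity <- intensity * (1 + noise * stats::rnorm(length(q)))
  }
  scattering_curve(q, intensity,
                   sigma = if (noise > 0) noise * abs(intensity) else NULL,
                   concentration = concentration, label = label)
}

#' Synthetic PFG-NMR diffusion dataset
#'
#' Stejskal-Tanner decays for one or more peaks with known diffusion
#' constants, on the standard acquisition grid of 32 gradient strengths
#' from 2% to 98% of maximum, with multiplicative Gaussian noise.
#'
#' @param d Named numeric vector of diffusion constants per peak, m^2/s.
#' @param i0 Zero-gradient intensity (recycled over peaks).
#' @param noise Relative noise level (>= 0).
#' @param n_gradients Number of gradient points.
#' @param g_range Gradient range as fractions of maximum.
#' @param delta,Delta,gamma,g_max Pulse parameters as in [pfg_dataset()].
#' @param seed Optional seed.
#' @return A `"pfg_dataset"`.
#' @export
#' @examples
#' d <- synth_pfg_dataset(c(protein = 1.1e-10), noise = 0.02, seed = 1)
synth_pfg_dataset <- function(d = c(peak1 = 1.1e-10), i0 = 1, noise = 0,
                              n_gradients = 32, g_range = c(0.02, 0.98),
                              delta = 2e-3, Delta = 200e-3,
                              gamma = 2.6752218744e8, g_max = 0.5,
                              seed = NULL) {
  stopifnot(all(d > 0), noise >= 0, n_gradients >= 5,
            g_range[1] >= 0, g_range[2] <= 1, g_range[1] < g_range[2])
  if (is.null(names(d))) names(d) <- paste0("peak", seq_along(d))
  i0 <- rep_len(i0, length(d))
  g <- seq(g_range[1], g_range[2], length.out = n_gradients)
  b <- (g * g_max)^2 * gamma^2 * delta^2 * (Delta - delta / 3)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rows <- purrr::map_dfr(seq_along(d), function(k) {
    I <- i0[k] * exp(-b * d[k])
    if (noise > 0) I <- I * (1 + noise * stats::rnorm(length(I)))
    tibble::tibble(gradient = g, peak = names(d)[k], intensity = pmax(I, 1e-12))
  })
  pfg_dataset(rows$gradient, rows$intensity, rows$peak,
              delta = delta, Delta = Delta, gamma = gamma, g_max = g_max)
}
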