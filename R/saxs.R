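#' Construct a scattering curve
#'
#' A small-angle scattering curve: intensity `I` (arbitrary or absolute
#' units) on a strictly increasing positive `q` grid (1/A), with optional
#' per-point errors and concentration metadata.
#'
#' @param q Scattering vector, 1/A, strictly increasing and positive.
#' @param I Intensities, finite.
#' @param sigma Optional per-point errors, positive.
#' @param concentration Mass concentration, mg/mL (optional metadata).
#' @param label Optional label.
#' @return A tibble of class `"scattering_curve"` with columns `q`, `I`
#'   (and `sigma` when present) and attributes `concentration`, `label`.
#' @export
scattering_curve <- function(q, I, sigma = NULL, concentration = NA_real_,
                             label = NULL) {
  stopifnot(length(q) == length(I), all(is.finite(q)), all(q > 0),
            all(is.finite(I)))
  if (is.unsorted(q, strictly = TRUE)) {
    stop("q must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sigma)) {
    stopifnot(length(sigma) == length(q), all(sigma > 0))
  }
  out <- if (is.null(sigma)) tibble::tibble(q = q, I = I)
         else tibble::tibble(q = q, I = I, sigma = sigma)
  attr(out, "concentration") <- concentration
  attr(out, "label") <- label
  class(out) <- c("scattering_curve", class(out))
  out
}

#' Guinier analysis of a scattering curve
#'
#' Fits `ln I = ln I0 - (Rg^2 / 3) q^2` over a low-q window restricted
#' iteratively until `max(q) * Rg <= qrg_max` (default 0.8). The window
#' starts at the first usable point; its upper bound is iterated downward
#' from `qrg_start` for stability.
#'
#' @param curve A `"scattering_curve"` (or tibble with `q`, `I`).
#' @param qrg_max Final Guinier-validity limit on `q * Rg`.
#' @param qrg_start Initial, looser limit used in the first iterations.
#' @param min_points Minimum points required in the converged window.
#' @return Object of class `"guinier_fit"`: list with `rg`, `i0`, `qmin`,
#'   `qmax`, `n_points`, `iterations`, and the underlying `lm` fit.
#' @export
#' @examples
#' crv <- scattering_curve(q = seq(0.005, 0.4, 5e-4),
#'                         I = 7 * exp(-seq(0.005, 0.4, 5e-4)^2 * 13^2 / 3))
#' guinier_fit(crv)$rg  # 13
guinier_fit <- function(curve, qrg_max = 0.8, qrg_start = 1.3,
                        min_points = 5) {
  q <- curve$q; I <- curve$I
  keep <- is.finite(I) & I > 0
  q <- q[keep]; I <- I[keep]
  if (length(q) < min_points) stop("too few usable points", call. = FALSE)
  fit_window <- function(idx) {
    f <- stats::lm(log(I[idx]) ~ I(q[idx]^2))
    slope <- unname(stats::coef(f)[2])
    list(fit = f, slope = slope,
         rg = if (slope < 0) sqrt(-3 * slope) else NA_real_,
         i0 = exp(unname(stats::coef(f)[1])))
  }
  idx <- seq_along(q)  # start from the whole usable curve for a first slope
  res <- fit_window(idx)
  if (!is.finite(res$rg) || res$rg <= 0) {
    stop("Guinier fit failed: non-negative slope (flat or rising curve)",
         call. = FALSE)
  }
  limits <- c(qrg_start, (qrg_start + qrg_max) / 2, rep(qrg_max, 30))
  iterations <- 0L
  for (lim in limits) {
    iterations <- iterations + 1L
    idx_new <- which(q * res$rg <= lim)
    if (length(idx_new) < min_points) {
      stop("Guinier window collapsed below ", min_points, " points",
           call. = FALSE)
    }
    converged <- identical(idx_new, idx) && lim == qrg_max
    idx <- idx_new
    res <- fit_window(idx)
    if (!is.finite(res$rg)) {
      stop("Guinier fit failed: non-negative slope within window",
           call. = FALSE)
    }
    if (converged) break
  }
  if (max(q[idx]) * res$rg > qrg_max + 1e-8) {
    stop("Guinier fit did not converge to q*Rg <= ", qrg_max, call. = FALSE)
  }
  structure(
    list(rg = res$rg, i0 = res$i0, qmin = min(q[idx]), qmax = max(q[idx]),
         n_points = length(idx), iterations = iterations, fit = res$fit),
    class = "guinier_fit"
  )
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg = %.3f A, I0 = %.4g (%d points, q in [%.4g, %.4g], qmax*Rg = %.2f)\n",
              x$rg, x$i0, x$n_points, x$qmin, x$qmax, x$qmax * x$rg))
  invisible(x)
}

#' @rdname guinier_fit
#' @param x A `"guinier_fit"` object.
#' @param ... Unused.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg", "i0"),
    estimate = c(x$rg, x$i0),
    std.error = {
      cf <- suppressWarnings(summary(x$fit))$coefficients
      # delta method on Rg = sqrt(-3 slope)
      c(3 * cf[2, 2] / (2 * x$rg), x$i0 * cf[1, 2])
    }
  )
}

#' @rdname guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(rg = x$rg, i0 = x$i0, qmin = x$qmin, qmax = x$qmax,
                 qmax_rg = x$qmax * x$rg, n_points = x$n_points,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Goodness of fit between experimental and simulated curves
#'
#' `chi2 = (1/Np) * sum(((I_exp - s * I_sim) / (s * I_sim))^2)`, the
#' residual measured relative to the (scaled) simulated intensity. The
#' scale `s` is conventionally chosen so that the scaled simulated forward
#' scattering matches the experimental I0. An optional sigma-weighted
#' variant divides residuals by per-point errors instead.
#'
#' @param i_exp,i_sim Intensities on a shared q grid (equal lengths >= 2);
#'   alternatively two `"scattering_curve"` objects with identical grids.
#' @param scale Scale factor `s` applied to `i_sim` (default 1).
#' @param sigma Optional per-point errors; used only when
#'   `weighted = TRUE`.
#' @param weighted If `TRUE`, use `((I_exp - s I_sim) / sigma)^2` instead.
#' @return chi-square value (not reduced by fitted parameters).
#' @export
#' @examples
#' chi_square(1.1 * (1:10), as.numeric(1:10))  # 0.01
chi_square <- function(i_exp, i_sim, scale = 1, sigma = NULL,
                       weighted = FALSE) {
  if (inherits(i_exp, "scattering_curve") &&
      inherits(i_sim, "scattering_curve")) {
    if (length(i_exp$q) != length(i_sim$q) ||
        any(abs(i_exp$q - i_sim$q) > 1e-12)) {
      stop("q grids differ; resample one curve onto the other explicitly",
           call. = FALSE)
    }
    if (is.null(sigma) && "sigma" %in% names(i_exp)) sigma <- i_exp$sigma
    i_exp <- i_exp$I; i_sim <- i_sim$I
  }
  stopifnot(length(i_exp) == length(i_sim), length(i_exp) >= 2,
            all(i_sim > 0), scale > 0)
  res <- i_exp - scale * i_sim
  if (weighted) {
    if (is.null(sigma)) stop("weighted chi-square needs sigma", call. = FALSE)
    mean((res / sigma)^2)
  } else {
    mean((res / (scale * i_sim))^2)
  }
}

#' Oligomerisation ratio from forward scattering
#'
#' `beta = (I0_zn / c_zn) / (I0 / c)`: the concentration-normalised forward
#' scattering with zinc over that without. `beta = 1` indicates no
#' oligomer formation (no mass increase); `beta > 1` indicates oligomers.
#'
#' @param i0_zn,c_zn Forward intensity and concentration (mg/mL) with Zn2+.
#' @param i0,c Forward intensity and concentration without Zn2+.
#' @return beta (dimensionless). Vectorised.
#' @export
#' @examples
#' beta_ratio(8.22, 1.03, 3.07, 1.01)  # 2.63 for wild-type Hst5
beta_ratio <- function(i0_zn, c_zn, i0, c) {
  vals <- c(i0_zn, c_zn, i0, c)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all beta inputs must be finite and positive", call. = FALSE)
  }
  (i0_zn / c_zn) / (i0 / c)
}

#' Measured SAXS summary for Hst5 and variants
#'
#' The published concentrations, Guinier radii, forward intensities,
#' histidine counts and oligomerisation ratios for wild-type Hst5 and the
#' five variants, with and without Zn2+, at pH 6.7 and 150 mM ionic
#' strength.
#'
#' @return Tibble with one row per variant: `name`, `c_p`, `c_p_zn`
#'   (mg/mL), `rg`, `rg_zn` (A), `i0`, `i0_zn`, `n_his`, `beta_printed`.
#' @export
hst5_saxs_table <- function() {
  tibble::tibble(
    name = c("WT", "RAN", "DZM", "ZM", "2H", "DH"),
    c_p = c(1.01, 0.94, 0.92, 1.13, 1.27, 1.08),
    c_p_zn = c(1.03, 0.94, 1.09, 1.23, 1.10, 1.07),
    rg = c(13.4, 11.9, 12.1, 12.8, 14.1, 13.9),
    rg_zn = c(11.5, 11.1, 11.5, 13.6, 12.9, 13.4),
    i0 = c(3.07, 3.47, 2.99, 3.12, 3.25, 3.45),
    i0_zn = c(8.22, 6.80, 4.91, 5.24, 3.44, 3.27),
    n_his = c(7L, 7L, 4L, 3L, 2L, 0L),
    beta_printed = c(2.63, 1.96, 1.39, 1.48, 1.21, 0.96)
  )
}

#' Mass fractal dimension from the intermediate-q power law
#'
#' At intermediate q the intensity follows `I ~ q^(-Dm)`; the mass fractal
#' dimension `Dm` is minus the slope of the least-squares line of log I vs
#' log q over the chosen window. A well-solvated coil gives about 1.7, a
#' rigid rod 1, compact or oligomeric states larger values.
#'
#' @param curve A `"scattering_curve"` (or tibble with `q`, `I`).
#' @param q_window Two-element window `c(qmin, qmax)`, 1/A.
#' @return List of class `"fractal_fit"`: `dm`, `n_points`, `q_window`,
#'   `fit`.
#' @export
#' @examples
#' q <- seq(0.05, 0.2, 1e-3)
#' fractal_dimension(scattering_curve(q, q^-1.6))$dm  # 1.6
fractal_dimension <- function(curve, q_window = c(0.05, 0.2)) {
  stopifnot(length(q_window) == 2, q_window[1] < q_window[2])
  idx <- curve$q >= q_window[1] & curve$q <= q_window[2] &
    is.finite(curve$I) & curve$I > 0
  if (sum(idx) < 5) {
    stop("fewer than 5 points in the fractal q-window", call. = FALSE)
  }
  f <- stats::lm(log10(I) ~ log10(q), data = curve[idx, ])
  structure(
    list(dm = -unname(stats::coef(f)[2]), n_points = sum(idx),
         q_window = q_window, fit = f),
    class = "fractal_fit"
  )
}

#' @export
print.fractal_fit <- function(x, ...) {
  cat(sprintf("<fractal_fit> Dm = %.3f (%d points, q in [%.3g, %.3g])\n",
              x$dm, x$n_points, x$q_window[1], x$q_window[2]))
  invisible(x)
}

#' Kratky transforms of a scattering curve
#'
#' Standard Kratky representation `q^2 I` vs `q`, or the dimensionless form
#' `(q Rg)^2 I / I0` vs `q Rg` (requires `rg` and `i0`, e.g. from
#' [guinier_fit()]). No smoothing is applied, and the transform is exactly
#' invertible.
#'
#' @param curve A `"scattering_curve"`.
#' @param rg,i0 Radius of gyration and forward intensity for the
#'   dimensionless form.
#' @param dimensionless Use the dimensionless representation?
#' @return Tibble with columns `x`, `y` (and the original `q`, `I`).
#' @export
kratky_transform <- function(curve, rg = NULL, i0 = NULL,
                             dimensionless = FALSE) {
  if (dimensionless) {
    if (is.null(rg) || is.null(i0) || rg <= 0 || i0 <= 0) {
      stop("dimensionless Kratky needs positive rg and i0", call. = FALSE)
    }
    tibble::tibble(q = curve$q, I = curve$I, x = curve$q * rg,
                   y = (curve$q * rg)^2 * curve$I / i0)
  } else {
    tibble::tibble(q = curve$q, I = curve$I, x = curve$q,
                   y = curve$q^2 * curve$I)
  }
}
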