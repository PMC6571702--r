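#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_abline scale_x_log10 scale_y_log10 labs theme_bw
NULL

#' Plot a scattering curve
#'
#' Log-log intensity plot, optionally as a (dimensionless) Kratky
#' representation.
#'
#' @param object A `"scattering_curve"`.
#' @param representation `"loglog"`, `"kratky"` or `"kratky_dimensionless"`.
#' @param rg,i0 Needed for the dimensionless Kratky form.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scattering_curve <- function(object, representation = "loglog",
                                      rg = NULL, i0 = NULL, ...) {
  representation <- match.arg(representation,
                              c("loglog", "kratky", "kratky_dimensionless"))
  if (representation == "loglog") {
    p <- ggplot(object, aes(x = .data$q, y = .data$I)) +
      geom_point(size = 0.6, alpha = 0.7) +
      scale_x_log10() + scale_y_log10() +
      labs(x = expression(q ~ ("Å"^-1)), y = "I(q)",
           title = attr(object, "label"))
  } else {
    k <- kratky_transform(object, rg = rg, i0 = i0,
                          dimensionless = representation == "kratky_dimensionless")
    xlab <- if (representation == "kratky") expression(q ~ ("Å"^-1))
            else expression(q %.% R[g])
    ylab <- if (representation == "kratky") expression(q^2 * I(q))
            else expression((q * R[g])^2 * I(q) / I(0))
    p <- ggplot(k, aes(x = .data$x, y = .data$y)) +
      geom_line() +
      labs(x = xlab, y = ylab, title = attr(object, "label"))
  }
  p + theme_bw()
}

#' Plot a Guinier fit
#'
#' ln I vs q^2 with the fitted line and the converged window highlighted.
#'
#' @param object A `"guinier_fit"`.
#' @param curve The `"scattering_curve"` that was fitted.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.guinier_fit <- function(object, curve, ...) {
  df <- tibble::tibble(q2 = curve$q^2, lnI = log(curve$I),
                       in_window = curve$q >= object$qmin &
                         curve$q <= object$qmax)
  df <- df[is.finite(df$lnI) & df$q2 <= (2 * object$qmax)^2, ]
  ggplot(df, aes(x = .data$q2, y = .data$lnI, colour = .data$in_window)) +
    geom_point(size = 0.8) +
    geom_abline(intercept = log(object$i0), slope = -object$rg^2 / 3) +
    labs(x = expression(q^2 ~ ("Å"^-2)), y = "ln I(q)",
         colour = "in Guinier window",
         subtitle = sprintf("Rg = %.2f Å, I0 = %.3g", object$rg,
                            object$i0)) +
    theme_bw()
}

#' Plot an oligomer size distribution
#'
#' Bar chart of the percentage of chains per size class with subdivision
#' error bars.
#'
#' @param object An `"oligomer_distribution"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.oligomer_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$species <- factor(df$species, levels = df$species)
  ggplot(df, aes(x = .data$species, y = .data$fraction_pct)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$fraction_pct - .data$se_pct,
                      ymax = .data$fraction_pct + .data$se_pct),
                  width = 0.2, na.rm = TRUE) +
    labs(x = NULL, y = "chains in size class (%)",
         subtitle = sprintf("number-average cluster size N_ass = %.3f",
                            attr(object, "n_ass"))) +
    theme_bw()
}

#' Plot per-subdivision observable traces of a run
#'
#' Quick stationarity diagnostic: the per-subdivision means of each
#' observable across the production run.
#'
#' @param object An `"mc_run"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mc_run <- function(object, ...) {
  long <- tidyr::pivot_longer(object$sub_means, -"subdivision",
                              names_to = "observable")
  ggplot(long, aes(x = .data$subdivision, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    labs(x = "subdivision", y = "subdivision mean") +
    theme_bw()
}

#' Plot a Stejskal-Tanner fit
#'
#' Intensity decay vs the gradient factor b with the fitted exponential.
#'
#' @param object A `"stejskal_fit"`.
#' @param data The fitted `"pfg_dataset"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stejskal_fit <- function(object, data, ...) {
  d <- data[data$peak == object$peak, ]
  g_abs <- d$gradient * attr(data, "g_max")
  b <- g_abs^2 * attr(data, "gamma")^2 * attr(data, "delta")^2 *
    (attr(data, "Delta") - attr(data, "delta") / 3)
  df <- tibble::tibble(b = b, intensity = d$intensity,
                       fitted = object$i0 * exp(-b * object$d))
  ggplot(df, aes(x = .data$b)) +
    geom_point(aes(y = .data$intensity)) +
    geom_line(aes(y = .data$fitted), colour = "firebrick") +
    labs(x = expression(b == g^2 * gamma^2 * delta^2 * (Delta - delta / 3) ~
                          (s / m^2)),
         y = "intensity",
         subtitle = sprintf("peak %s: D = %.4g m²/s", object$peak,
                            object$d)) +
    theme_bw()
}
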