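#' Monte Carlo run configuration
#'
#' Schedule and move-set parameters for the canonical (NVT) Metropolis
#' simulation. A "pass" is one trial move per bead. Four move types are
#' used: single-bead translation, pivot rotation, whole-chain translation
#' and a slithering (reptation) move, attempted in the ratio
#' 20 : 1 : 1 : 1 so that single-particle moves are twenty times more
#' frequent. The published schedule is 2e5 equilibration passes and 2e6
#' production passes divided into ten subdivisions; shorter schedules are
#' appropriate for exploratory work.
#'
#' @param equilibration Equilibration passes (trial moves per bead).
#' @param production Production passes.
#' @param n_subdivisions Number of production subdivisions used for error
#'   estimation (>= 2).
#' @param move_weights Relative attempt weights for
#'   single-bead : pivot : chain-translation : slither moves.
#' @param amp_single,amp_translate Initial displacement amplitudes, A.
#' @param amp_pivot Initial pivot half-angle, radians.
#' @param tune Auto-tune amplitudes toward ~30% acceptance during
#'   equilibration only (frozen in production to preserve detailed balance).
#' @param obs_stride Accumulate scalar observables every this many passes.
#' @param cluster_stride Evaluate the cluster partition every this many
#'   passes.
#' @param frame_stride Store coordinate frames every this many passes
#'   (0 = store none).
#' @param cluster_cutoff Bead-bead contact distance defining an oligomer, A.
#' @param seed Integer seed for the run.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(equilibration = 2e5, production = 2e6,
                      n_subdivisions = 10,
                      move_weights = c(single = 20, pivot = 1,
                                       translate = 1, slither = 1),
                      amp_single = 1.5, amp_translate = 10,
                      amp_pivot = 0.6, tune = TRUE,
                      obs_stride = 10, cluster_stride = 100,
                      frame_stride = 0, cluster_cutoff = 6,
                      seed = NULL) {
  stopifnot(equilibration >= 0, production > 0, n_subdivisions >= 2,
            length(move_weights) == 4, all(move_weights >= 0),
            sum(move_weights) > 0, amp_single > 0, amp_translate > 0,
            amp_pivot > 0, obs_stride >= 1, cluster_cutoff > 0)
  structure(
    list(equilibration = equilibration, production = production,
         n_subdivisions = as.integer(n_subdivisions),
         move_weights = as.numeric(move_weights),
         amp_single = amp_single, amp_translate = amp_translate,
         amp_pivot = amp_pivot, tune = isTRUE(tune),
         obs_stride = as.integer(obs_stride),
         cluster_stride = as.integer(cluster_stride),
         frame_stride = as.integer(frame_stride),
         cluster_cutoff = cluster_cutoff, seed = seed),
    class = "mc_config"
  )
}

#' Metropolis acceptance rule
#'
#' Accepts a trial move with probability `min(1, exp(-delta_U / kT))`.
#' Infinite `delta_U` (hard-sphere overlap) is never accepted.
#'
#' @param delta_U Energy change(s), kJ/mol.
#' @param temperature Temperature, K.
#' @return Logical vector of acceptance decisions.
#' @export
#' @examples
#' metropolis_accept(0)    # always TRUE
#' metropolis_accept(Inf)  # always FALSE
metropolis_accept <- function(delta_U, temperature = 298) {
  kT <- .r_gas_kj * temperature
  p <- exp(-pmax(delta_U, 0) / kT)  # 1 for delta_U <= 0, 0 for +Inf
  stats::runif(length(delta_U)) < p
}

#' Standard deviation of the mean from subdivision averages
#'
#' The sampling uncertainty of a simulated observable is estimated from the
#' spread of per-subdivision means:
#' `sigma^2 = 1 / (ns (ns - 1)) * sum((x_s - mean(x))^2)`.
#'
#' @param sub_means Numeric vector of subdivision means (>= 2 values).
#' @return The standard deviation of the mean.
#' @export
#' @examples
#' subdivision_error(c(1, 2, 3))  # 0.5774
subdivision_error <- function(sub_means) {
  sub_means <- sub_means[!is.na(sub_means)]
  ns <- length(sub_means)
  if (ns < 2) stop("need at least 2 subdivision means", call. = FALSE)
  sqrt(sum((sub_means - mean(sub_means))^2) / (ns * (ns - 1)))
}

#' Run the Metropolis Monte Carlo simulation
#'
#' Samples the coarse-grained system in the canonical ensemble. The
#' equilibration phase (with optional amplitude tuning) is discarded;
#' production observables (energy, mean radius of gyration, mean
#' end-to-end distance, cluster statistics under the 6 A rule) are
#' accumulated per subdivision, and coordinate frames are optionally
#' stored. Runs are reproducible from `config$seed`.
#'
#' @param system An `"mc_system"` from [build_system()].
#' @param params An [energy_params()] object.
#' @param config An [mc_config()] object.
#' @return An object of class `"mc_run"`: list with `sub_means` (tibble of
#'   per-subdivision observable means), `summary` (tibble of estimates with
#'   subdivision errors), `acceptance`, `acceptance_by_type`, `amplitudes`,
#'   `frames` (list of coordinate matrices), `final_system`, `energy`
#'   (running vs recomputed final energy), plus the inputs.
#' @export
run_simulation <- function(system, params = energy_params(),
                           config = mc_config()) {
  stopifnot(inherits(system, "mc_system"), inherits(params, "energy_params"),
            inherits(config, "mc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- run_mc_cpp(
    system$coords, system$n_chains, system$chain$n_beads,
    as.numeric(system$chain$charges), system$chain$sticky,
    system$box_length, .params_cpp(params),
    list(equilibration = config$equilibration,
         production = config$production,
         n_subdivisions = config$n_subdivisions,
         move_weights = config$move_weights,
         amp_single = config$amp_single,
         amp_translate = config$amp_translate,
         amp_pivot = config$amp_pivot,
         tune = config$tune,
         obs_stride = config$obs_stride,
         cluster_stride = config$cluster_stride,
         frame_stride = config$frame_stride,
         cluster_cutoff = config$cluster_cutoff)
  )
  sub <- tibble::as_tibble(as.data.frame(res$sub_means))
  sub <- dplyr::mutate(sub, subdivision = dplyr::row_number(),
                       .before = 1)
  est <- purrr::map_dfr(
    setdiff(names(sub), "subdivision"),
    function(nm) {
      x <- sub[[nm]]
      tibble::tibble(
        observable = nm,
        estimate = mean(x, na.rm = TRUE),
        std_error = if (sum(!is.na(x)) >= 2) subdivision_error(x) else NA_real_
      )
    }
  )
  final_system <- system
  final_system$coords <- res$final_coords
  structure(
    list(sub_means = sub, summary = est,
         acceptance = res$acceptance,
         acceptance_by_type = res$acceptance_by_type,
         amplitudes = res$amplitudes,
         frames = res$frames,
         final_system = final_system,
         energy = c(running = res$energy_running, final = res$energy_final),
         system = system, params = params, config = config),
    class = "mc_run"
  )
}

#' @export
print.mc_run <- function(x, ...) {
  cat("<mc_run> ", x$system$n_chains, " chain(s), ",
      format(x$config$production, big.mark = ","), " production passes, ",
      "acceptance ", sprintf("%.1f%%", 100 * x$acceptance), "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_simulation
#' @param x An `"mc_run"` object.
#' @param ... Unused.
#' @export
tidy.mc_run <- function(x, ...) x$summary

#' @rdname run_simulation
#' @export
glance.mc_run <- function(x, ...) {
  tibble::tibble(
    n_chains = x$system$n_chains,
    box_length = x$system$box_length,
    equilibration = x$config$equilibration,
    production = x$config$production,
    n_subdivisions = x$config$n_subdivisions,
    acceptance = x$acceptance,
    n_frames = length(x$frames),
    energy_drift = abs(x$energy[["running"]] - x$energy[["final"]])
  )
}

# ---- R-level move proposals (reference implementation used in testing) ----

.mi_r <- function(d, box) d - box * round(d / box)

.dists_to <- function(coords, pos, box) {
  dx <- .mi_r(coords[, 1] - pos[1], box)
  dy <- .mi_r(coords[, 2] - pos[2], box)
  dz <- .mi_r(coords[, 3] - pos[3], box)
  sqrt(dx^2 + dy^2 + dz^2)
}

# Energy of bead g at position pos against the rest of the system
.site_energy <- function(system, params, g, pos) {
  L <- system$chain$n_beads
  Z <- rep(system$chain$charges, system$n_chains)
  ST <- rep(system$chain$sticky, system$n_chains)
  r <- .dists_to(system$coords, pos, system$box_length)
  li <- ((g - 1) %% L) + 1
  bonded <- c(if (li > 1) g - 1L, if (li < L) g + 1L)
  if (any(r[-g] < 2 * params$bead_radius)) return(Inf)
  u <- sum(bond_energy(r[bonded], params))
  nb <- setdiff(seq_along(r)[-g], bonded)
  rr <- r[nb]
  eps <- ifelse(ST[g] & ST[nb], params$eps_sticky,
                ifelse(ST[g] | ST[nb], params$eps_cross, params$eps_generic))
  el <- params$elconst * Z[g] * Z[nb] *
    exp(-params$kappa * (rr - 2 * params$bead_radius)) /
    (1 + params$kappa * params$bead_radius)^2 / rr
  unb <- el - eps / rr^6
  unb[rr > params$cutoff] <- 0
  u + sum(unb)
}

# Intra + inter energy of chain c with trial coordinates ch (L x 3)
.chain_energy <- function(system, params, c_idx, ch) {
  L <- system$chain$n_beads
  box <- system$box_length
  Z <- system$chain$charges
  ST <- system$chain$sticky
  contact <- 2 * params$bead_radius
  kap <- params$kappa
  pre <- params$elconst / (1 + kap * params$bead_radius)^2
  u <- 0
  for (i in seq_len(L)) {
    if (i < L) {
      js <- (i + 1):L
      r <- .dists_to(ch[js, , drop = FALSE], ch[i, ], box)
      if (any(r < contact)) return(Inf)
      u <- u + bond_energy(r[1], params)
      if (length(js) > 1) {
        rr <- r[-1]; jn <- js[-1]
        eps <- ifelse(ST[i] & ST[jn], params$eps_sticky,
                      ifelse(ST[i] | ST[jn], params$eps_cross,
                             params$eps_generic))
        unb <- pre * Z[i] * Z[jn] * exp(-kap * (rr - contact)) / rr - eps / rr^6
        unb[rr > params$cutoff] <- 0
        u <- u + sum(unb)
      }
    }
  }
  others <- setdiff(seq_len(system$n_chains), c_idx)
  for (d in others) {
    od <- (d - 1) * L
    oc <- system$coords[od + seq_len(L), , drop = FALSE]
    for (i in seq_len(L)) {
      r <- .dists_to(oc, ch[i, ], box)
      if (any(r < contact)) return(Inf)
      eps <- ifelse(ST[i] & ST, params$eps_sticky,
                    ifelse(ST[i] | ST, params$eps_cross, params$eps_generic))
      unb <- pre * Z[i] * Z * exp(-kap * (r - contact)) / r - eps / r^6
      unb[r > params$cutoff] <- 0
      u <- u + sum(unb)
    }
  }
  u
}

.rand_unit_r <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

.rotate_about_r <- function(pts, axis, angle, origin) {
  v <- sweep(pts, 2, origin)
  k <- axis
  cs <- cos(angle); sn <- sin(angle)
  crossm <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
                  k[3] * v[, 1] - k[1] * v[, 3],
                  k[1] * v[, 2] - k[2] * v[, 1])
  dt <- drop(v %*% k)
  out <- v * cs + crossm * sn + outer(dt * (1 - cs), k)
  sweep(out, 2, origin, `+`)
}

#' Propose a trial Monte Carlo move
#'
#' Reference (R-level) implementation of the four move types. The energy
#' change is computed from the affected interaction terms only and equals
#' the full-energy difference; the production engine uses the same
#' bookkeeping in compiled code.
#'
#' @param system An `"mc_system"`.
#' @param kind One of `"single-bead"`, `"pivot"`, `"chain-translate"`,
#'   `"slither"`.
#' @param params An [energy_params()] object.
#' @param amplitude Displacement amplitude (A) or pivot half-angle
#'   (radians).
#' @return List with `coords` (trial coordinates for the whole system),
#'   `delta_U` (kJ/mol, `Inf` on overlap), `kind`, and `moved` (global bead
#'   indices whose positions changed).
#' @export
propose_move <- function(system, kind = c("single-bead", "pivot",
                                          "chain-translate", "slither"),
                         params = energy_params(), amplitude = 1.5) {
  stopifnot(inherits(system, "mc_system"))
  kind <- match.arg(kind)
  L <- system$chain$n_beads
  n <- system$n_chains
  coords <- system$coords
  if (kind == "single-bead") {
    g <- sample.int(nrow(coords), 1)
    pos_new <- coords[g, ] + stats::runif(3, -amplitude, amplitude)
    u_old <- .site_energy(system, params, g, coords[g, ])
    u_new <- .site_energy(system, params, g, pos_new)
    coords[g, ] <- pos_new
    return(list(coords = coords, delta_U = u_new - u_old, kind = kind,
                moved = g))
  }
  c_idx <- sample.int(n, 1)
  rows <- (c_idx - 1) * L + seq_len(L)
  ch_old <- coords[rows, , drop = FALSE]
  ch_new <- ch_old
  if (kind == "pivot") {
    if (L < 3) stop("pivot requires at least 3 beads", call. = FALSE)
    piv <- sample(2:(L - 1), 1)
    side <- if (piv - 1 <= L - piv) seq_len(piv - 1) else (piv + 1):L
    ang <- stats::runif(1, -amplitude, amplitude)
    ch_new[side, ] <- .rotate_about_r(ch_old[side, , drop = FALSE],
                                      .rand_unit_r(), ang, ch_old[piv, ])
    moved <- rows[side]
  } else if (kind == "chain-translate") {
    dv <- stats::runif(3, -amplitude, amplitude)
    ch_new <- sweep(ch_old, 2, dv, `+`)
    moved <- rows
  } else {
    sig <- sqrt(params$kT / params$k_bond)
    lmax <- params$r0 + 5 * sig
    repeat {
      l <- stats::rnorm(1, params$r0, sig)
      if (l >= 2 * params$bead_radius && l <= lmax &&
          stats::runif(1) < (l / lmax)^2) break
    }
    dir_fwd <- stats::runif(1) < 0.5
    u <- .rand_unit_r()
    if (dir_fwd) {
      ch_new[seq_len(L - 1), ] <- ch_old[2:L, , drop = FALSE]
      ch_new[L, ] <- ch_old[L, ] + l * u
    } else {
      ch_new[2:L, ] <- ch_old[seq_len(L - 1), , drop = FALSE]
      ch_new[1, ] <- ch_old[1, ] + l * u
    }
    moved <- rows
  }
  u_old <- .chain_energy(system, params, c_idx, ch_old)
  u_new <- .chain_energy(system, params, c_idx, ch_new)
  coords[rows, ] <- ch_new
  list(coords = coords, delta_U = u_new - u_old, kind = kind, moved = moved)
}
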