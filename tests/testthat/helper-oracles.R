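# Independent brute-force oracles used to validate the compiled kernels.
# These deliberately re-derive every quantity from first principles with
# plain R loops, sharing no code with the package internals.

mi_vec <- function(d, box) d - box * round(d / box)

# Full double-loop potential energy (hard sphere + screened Coulomb +
# 1/r^6 + harmonic bonds), minimum image throughout.
oracle_total_energy <- function(sys, params) {
  L <- sys$chain$n_beads
  n <- sys$n_chains
  box <- sys$box_length
  Z <- rep(sys$chain$charges, n)
  ST <- rep(sys$chain$sticky, n)
  chain_of <- rep(seq_len(n), each = L)
  idx_of <- rep(seq_len(L), n)
  X <- sys$coords
  N <- nrow(X)
  pre <- params$elconst / (1 + params$kappa * params$bead_radius)^2
  contact <- 2 * params$bead_radius
  U <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      r <- sqrt(sum(mi_vec(X[i, ] - X[j, ], box)^2))
      if (r < contact) return(Inf)
      if (chain_of[i] == chain_of[j] && abs(idx_of[i] - idx_of[j]) == 1) {
        U <- U + params$k_bond / 2 * (r - params$r0)^2
      } else if (r <= params$cutoff) {
        eps <- if (ST[i] && ST[j]) params$eps_sticky
               else if (ST[i] || ST[j]) params$eps_cross
               else params$eps_generic
        U <- U - eps / r^6 +
          pre * Z[i] * Z[j] * exp(-params$kappa * (r - contact)) / r
      }
    }
  }
  U
}

# Cluster membership by boolean transitive closure of the chain-chain
# contact matrix (no union-find).
oracle_clusters <- function(coords, n_chains, n_beads, box, cutoff = 6) {
  A <- diag(n_chains) > 0
  for (ci in seq_len(n_chains)) {
    for (cj in seq_len(n_chains)) {
      if (cj <= ci) next
      ri <- coords[(ci - 1) * n_beads + seq_len(n_beads), , drop = FALSE]
      rj <- coords[(cj - 1) * n_beads + seq_len(n_beads), , drop = FALSE]
      hit <- FALSE
      for (k in seq_len(n_beads)) {
        d2 <- mi_vec(rj[, 1] - ri[k, 1], box)^2 +
              mi_vec(rj[, 2] - ri[k, 2], box)^2 +
              mi_vec(rj[, 3] - ri[k, 3], box)^2
        if (any(d2 <= cutoff^2)) { hit <- TRUE; break }
      }
      A[ci, cj] <- A[cj, ci] <- hit
    }
  }
  R <- A
  for (k in seq_len(n_chains)) R <- ((R %*% A) > 0) | R
  membership <- integer(n_chains)
  next_id <- 0L
  for (i in seq_len(n_chains)) {
    if (membership[i] == 0L) {
      next_id <- next_id + 1L
      membership[R[i, ]] <- next_id
    }
  }
  membership
}

# Orientationally averaged scattering by explicit direction sampling of
# |sum exp(i q.r)|^2 / N over a quasi-uniform (Fibonacci) set of unit
# vectors, whose quadrature error vanishes much faster than random
# directions for these smooth integrands.
oracle_sq_direction_average <- function(coords, q, n_dir = 2000) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n_dir
  s <- sqrt(1 - z^2)
  u <- cbind(s * cos(phi), s * sin(phi), z)
  N <- nrow(coords)
  vapply(q, function(qk) {
    phase <- (coords %*% t(u)) * qk      # N x n_dir
    re <- colSums(cos(phase))
    im <- colSums(sin(phase))
    mean(re^2 + im^2) / N
  }, numeric(1))
}

# Boltzmann statistics of a single harmonic bond between two hard spheres:
# p(r) ~ r^2 exp(-U_bond(r)/kT) for r >= contact.
oracle_bond_moment <- function(params, moment = 1, upper = 30) {
  w <- function(r) r^2 * exp(-bond_energy(r, params) / params$kT)
  z <- stats::integrate(w, 2 * params$bead_radius, upper)$value
  stats::integrate(function(r) r^moment * w(r),
                   2 * params$bead_radius, upper)$value / z
}

# Two partitions are the same up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(stats::ave(seq_along(a), a, FUN = min) ==
        stats::ave(seq_along(b), b, FUN = min))
}

# Small helper: a compact random multi-chain system for oracle tests
make_small_system <- function(n_chains = 3, box = 80, seed = 1,
                              variant = "WT", zinc = TRUE) {
  build_system(build_peptide(variant), box_length = box,
               n_chains = n_chains, zinc_present = zinc, seed = seed)
}
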