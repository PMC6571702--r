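#' Radius of gyration of one chain
#'
#' Mass-uniform radius of gyration about the centroid. Coordinates must be
#' unwrapped (the chain continuous in space); a consecutive-bead separation
#' larger than `max_bond` is taken as evidence of a wrapped chain and is an
#' error.
#'
#' @param coords Numeric matrix (n_beads x 3), A.
#' @param max_bond Largest plausible bond length, A.
#' @return Rg in A.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(4.1, 0, 0)))  # 2.05
radius_of_gyration <- function(coords, max_bond = 10) {
  coords <- rbind(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  .check_unwrapped(coords, max_bond)
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' End-to-end distance of one chain
#'
#' @inheritParams radius_of_gyration
#' @return First-to-last bead distance in A.
#' @export
end_to_end <- function(coords, max_bond = 10) {
  coords <- rbind(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) >= 1)
  .check_unwrapped(coords, max_bond)
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}

.check_unwrapped <- function(coords, max_bond) {
  if (nrow(coords) < 2) return(invisible())
  d <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                     coords[-nrow(coords), , drop = FALSE])^2))
  if (any(d > max_bond)) {
    stop("chain appears wrapped across the periodic boundary ",
         "(consecutive-bead separation > ", max_bond, " A); unwrap first",
         call. = FALSE)
  }
  invisible()
}

#' Partition chains into oligomers (clusters)
#'
#' Two chains belong to the same oligomer if any bead of one lies within
#' `cutoff` (default 6 A, centre-centre, minimum image) of any bead of the
#' other; the partition is the transitive closure of this contact relation.
#'
#' @param x An `"mc_system"`, or a coordinate matrix with `n_chains`,
#'   `n_beads` and `box_length` supplied.
#' @param cutoff Contact distance, A.
#' @param n_chains,n_beads,box_length Required when `x` is a bare matrix.
#' @return An object of class `"cluster_partition"`: list with `membership`
#'   (integer cluster id per chain), `clusters` (list of chain-index
#'   vectors), `sizes`, `n_chains`, `cutoff`.
#' @export
find_clusters <- function(x, cutoff = 6, n_chains = NULL, n_beads = NULL,
                          box_length = NULL) {
  if (inherits(x, "mc_system")) {
    coords <- x$coords; n_chains <- x$n_chains
    n_beads <- x$chain$n_beads; box_length <- x$box_length
  } else {
    coords <- x
    stopifnot(!is.null(n_chains), !is.null(n_beads), !is.null(box_length))
  }
  stopifnot(nrow(coords) == n_chains * n_beads, cutoff > 0)
  parent <- seq_len(n_chains)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  if (n_chains > 1) {
    for (ci in seq_len(n_chains - 1)) {
      rows_i <- (ci - 1) * n_beads + seq_len(n_beads)
      for (cj in (ci + 1):n_chains) {
        if (find(ci) == find(cj)) next
        rows_j <- (cj - 1) * n_beads + seq_len(n_beads)
        if (.chains_in_contact(coords[rows_i, , drop = FALSE],
                               coords[rows_j, , drop = FALSE],
                               box_length, cutoff)) {
          parent[find(ci)] <- find(cj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n_chains), find, integer(1))
  membership <- match(roots, unique(roots))
  clusters <- split(seq_len(n_chains), membership)
  structure(
    list(membership = membership, clusters = unname(clusters),
         sizes = unname(lengths(clusters)), n_chains = n_chains,
         cutoff = cutoff),
    class = "cluster_partition"
  )
}

.chains_in_contact <- function(a, b, box, cutoff) {
  for (k in seq_len(nrow(a))) {
    dx <- .mi_r(b[, 1] - a[k, 1], box)
    dy <- .mi_r(b[, 2] - a[k, 2], box)
    dz <- .mi_r(b[, 3] - a[k, 3], box)
    if (any(dx^2 + dy^2 + dz^2 <= cutoff^2)) return(TRUE)
  }
  FALSE
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> ", x$n_chains, " chains in ",
      length(x$clusters), " cluster(s); sizes: ",
      paste(sort(x$sizes, decreasing = TRUE), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Oligomer size distribution over frames
#'
#' Aggregates a set of per-frame cluster partitions into the oligomer-size
#' distribution: the percentage of chains residing in monomers, dimers,
#' trimers and tetramers-or-larger, plus the number-average cluster size
#' `N_ass = (total chains) / (number of clusters)` averaged over frames.
#' Sampling errors are estimated by splitting the frame sequence into
#' subdivisions and applying [subdivision_error()].
#'
#' @param partitions A list of `"cluster_partition"` objects (one per
#'   frame, in time order).
#' @param n_subdivisions Subdivisions for the error estimate.
#' @return An object of class `"oligomer_distribution"`: a tibble with
#'   columns `species`, `size`, `fraction_pct`, `se_pct`, and attributes
#'   `n_ass`, `n_ass_se`, `n_frames`.
#' @export
cluster_statistics <- function(partitions, n_subdivisions = 10) {
  if (length(partitions) < 1) stop("no partitions supplied", call. = FALSE)
  per_frame <- purrr::map_dfr(partitions, function(p) {
    s <- p$sizes
    n <- p$n_chains
    tibble::tibble(
      n_ass = n / length(s),
      frac1 = sum(s[s == 1]) / n, frac2 = sum(s[s == 2]) / n,
      frac3 = sum(s[s == 3]) / n, frac4p = sum(s[s >= 4]) / n
    )
  })
  nf <- nrow(per_frame)
  nsub <- min(n_subdivisions, nf)
  sub_id <- ceiling(seq_len(nf) / (nf / nsub))
  sub_means <- dplyr::summarise(
    dplyr::group_by(per_frame, sub = sub_id),
    dplyr::across(dplyr::everything(), mean), .groups = "drop"
  )
  est <- function(col) mean(per_frame[[col]])
  se <- function(col) {
    if (nsub >= 2) subdivision_error(sub_means[[col]]) else NA_real_
  }
  out <- tibble::tibble(
    species = c("monomer", "dimer", "trimer", "tetramer+"),
    size = c(1L, 2L, 3L, 4L),
    fraction_pct = 100 * c(est("frac1"), est("frac2"), est("frac3"),
                           est("frac4p")),
    se_pct = 100 * c(se("frac1"), se("frac2"), se("frac3"), se("frac4p"))
  )
  attr(out, "n_ass") <- est("n_ass")
  attr(out, "n_ass_se") <- se("n_ass")
  attr(out, "n_frames") <- nf
  class(out) <- c("oligomer_distribution", class(out))
  out
}

#' Oligomer distribution from a simulation run
#'
#' Extracts the oligomer-size distribution accumulated by
#' [run_simulation()] (per-subdivision means of the chain fractions in each
#' size class), with subdivision errors.
#'
#' @param run An `"mc_run"` object.
#' @return An `"oligomer_distribution"` tibble as in [cluster_statistics()].
#' @export
oligomer_distribution <- function(run) {
  stopifnot(inherits(run, "mc_run"))
  sm <- run$sub_means
  cols <- c("frac1", "frac2", "frac3", "frac4p")
  out <- tibble::tibble(
    species = c("monomer", "dimer", "trimer", "tetramer+"),
    size = c(1L, 2L, 3L, 4L),
    fraction_pct = vapply(cols, function(cc) 100 * mean(sm[[cc]], na.rm = TRUE),
                          numeric(1), USE.NAMES = FALSE),
    se_pct = vapply(cols, function(cc) {
      x <- sm[[cc]][!is.na(sm[[cc]])]
      if (length(x) >= 2) 100 * subdivision_error(x) else NA_real_
    }, numeric(1), USE.NAMES = FALSE)
  )
  attr(out, "n_ass") <- mean(sm$n_ass, na.rm = TRUE)
  x <- sm$n_ass[!is.na(sm$n_ass)]
  attr(out, "n_ass_se") <- if (length(x) >= 2) subdivision_error(x) else NA_real_
  attr(out, "n_frames") <- sum(!is.na(sm$n_ass))
  class(out) <- c("oligomer_distribution", class(out))
  out
}

#' Debye structure factor from coordinate frames
#'
#' Orientationally averaged structure factor per scatterer via the Debye
#' double sum `S(q) = (1/N) * sum_jk sin(q r_jk) / (q r_jk)` (self terms
#' equal 1), averaged over frames, with minimum-image pair distances. Also
#' returns the intra-chain (single-chain form-factor) and inter-chain
#' contributions.
#'
#' @param frames A list of coordinate matrices (N x 3), or an `"mc_run"`
#'   whose `frames` are used.
#' @param q Scattering-vector grid, 1/A, positive ascending.
#' @param n_chains,n_beads,box_length System geometry (taken from the run
#'   when `frames` is an `"mc_run"`).
#' @return A tibble with columns `q`, `s_total`, `s_intra`, `s_inter`.
#' @export
structure_factor <- function(frames, q, n_chains = NULL, n_beads = NULL,
                             box_length = NULL) {
  if (inherits(frames, "mc_run")) {
    run <- frames
    n_chains <- run$system$n_chains
    n_beads <- run$system$chain$n_beads
    box_length <- run$system$box_length
    frames <- run$frames
  }
  stopifnot(length(frames) >= 1, all(q > 0), !is.unsorted(q),
            !is.null(n_chains), !is.null(n_beads), !is.null(box_length))
  nq <- length(q)
  acc_tot <- numeric(nq); acc_intra <- numeric(nq)
  N <- n_chains * n_beads
  chain_of <- rep(seq_len(n_chains), each = n_beads)
  for (fr in frames) {
    stopifnot(nrow(fr) == N)
    dx <- .mi_r(outer(fr[, 1], fr[, 1], `-`), box_length)
    dy <- .mi_r(outer(fr[, 2], fr[, 2], `-`), box_length)
    dz <- .mi_r(outer(fr[, 3], fr[, 3], `-`), box_length)
    r <- sqrt(dx^2 + dy^2 + dz^2)
    same <- outer(chain_of, chain_of, `==`)
    up <- upper.tri(r)
    r_all <- r[up]
    r_intra <- r[up & same]
    for (k in seq_len(nq)) {
      qk <- q[k]
      acc_tot[k] <- acc_tot[k] + (N + 2 * sum(sin(qk * r_all) / (qk * r_all))) / N
      acc_intra[k] <- acc_intra[k] +
        (N + 2 * sum(sin(qk * r_intra) / (qk * r_intra))) / N
    }
  }
  nf <- length(frames)
  tibble::tibble(
    q = q,
    s_total = acc_tot / nf,
    s_intra = acc_intra / nf,
    s_inter = (acc_tot - acc_intra) / nf
  )
}
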