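test_that("radius of gyration and end-to-end match independent formulas", {
  expect_identical(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4.1, 0, 0))), 2.05)
  expect_equal(end_to_end(rbind(c(0, 0, 0), c(3, 4, 0))), 5)
  # random walk chain: Rg^2 equals the pair-distance identity
  # (1 / 2N^2) * sum_ij d_ij^2, an independent route to the same quantity
  set.seed(21)
  steps <- matrix(stats::rnorm(23 * 3), ncol = 3)
  steps <- 4.1 * steps / sqrt(rowSums(steps^2))
  coords <- apply(rbind(c(0, 0, 0), steps), 2, cumsum)
  d2 <- as.matrix(stats::dist(coords))^2
  expect_equal(radius_of_gyration(coords)^2,
               sum(d2) / (2 * nrow(coords)^2), tolerance = 1e-10)
  # a wrapped (discontinuous) chain is rejected
  bad <- coords
  bad[10, ] <- bad[10, ] + c(220, 0, 0)
  expect_error(radius_of_gyration(bad), "wrapped")
  expect_error(end_to_end(bad), "wrapped")
})

test_that("clusters follow the 6 A contact rule with transitive closure", {
  wt <- build_peptide("WT")
  sys <- build_system(wt, 300, n_chains = 3, seed = 31)
  L <- sys$chain$n_beads
  # place chains deliberately: B touching A, C far away
  template <- sys$coords[seq_len(L), ]
  shift <- function(v) sweep(template, 2, v, `+`)
  sys$coords[L + seq_len(L), ] <- shift(c(5, 0, 0))    # beads within 6 A
  sys$coords[2 * L + seq_len(L), ] <- shift(c(150, 150, 0))
  part <- find_clusters(sys)
  expect_equal(sort(part$sizes), c(1L, 2L))
  expect_equal(part$membership[1], part$membership[2])
  expect_false(part$membership[1] == part$membership[3])
  # all chains far apart: all singletons
  sys$coords[L + seq_len(L), ] <- shift(c(0, 150, 0))
  part2 <- find_clusters(sys)
  expect_equal(part2$sizes, c(1L, 1L, 1L))
  # chain contact through the periodic boundary is honoured
  sys$coords[L + seq_len(L), ] <- shift(c(298, 0, 0))  # 2 A via min image
  part3 <- find_clusters(sys)
  expect_equal(sort(part3$sizes), c(1L, 2L))
})

test_that("cluster partition agrees with the brute-force closure oracle", {
  for (seed in c(2, 7, 13)) {
    sys <- make_small_system(n_chains = 5, box = 70, seed = seed)
    part <- find_clusters(sys)
    ref <- oracle_clusters(sys$coords, 5, sys$chain$n_beads, 70)
    expect_true(same_partition(part$membership, ref))
    # invariance under global translation
    sys2 <- sys
    sys2$coords <- sweep(sys$coords, 2, c(31, -17, 55), `+`)
    expect_true(same_partition(find_clusters(sys2)$membership,
                               part$membership))
    # invariance under chain relabeling
    perm <- sample(5)
    L <- sys$chain$n_beads
    rows <- as.vector(vapply(perm, function(k) (k - 1L) * L + seq_len(L),
                             integer(L)))
    sys3 <- sys
    sys3$coords <- sys$coords[rows, ]
    expect_true(same_partition(find_clusters(sys3)$membership,
                               part$membership[perm]))
  }
})

test_that("cluster statistics aggregate frames into the size distribution", {
  wt <- build_peptide("WT")
  sys <- build_system(wt, 300, n_chains = 3, seed = 31)
  L <- sys$chain$n_beads
  template <- sys$coords[seq_len(L), ]
  shift <- function(v) sweep(template, 2, v, `+`)
  sys$coords[L + seq_len(L), ] <- shift(c(5, 0, 0))
  sys$coords[2 * L + seq_len(L), ] <- shift(c(150, 150, 0))
  part <- find_clusters(sys)  # {A,B},{C}
  stats <- cluster_statistics(list(part, part, part, part))
  expect_equal(attr(stats, "n_ass"), 1.5)  # (2 + 1) / 2 clusters
  expect_equal(stats$fraction_pct[stats$species == "monomer"], 100 / 3,
               tolerance = 1e-10)
  expect_equal(stats$fraction_pct[stats$species == "dimer"], 200 / 3,
               tolerance = 1e-10)
  expect_equal(sum(stats$fraction_pct), 100, tolerance = 1e-9)
  expect_error(cluster_statistics(list()), "no partitions")
})

test_that("structure factor matches closed forms and the direction-average oracle", {
  # two point scatterers 10 A apart: S(q) = 1 + sin(q d) / (q d)
  frames <- list(rbind(c(0, 0, 0), c(10, 0, 0)))
  sq <- structure_factor(frames, q = c(0.1, 0.2), n_chains = 1, n_beads = 2,
                         box_length = 1e5)
  expect_equal(sq$s_total[1], 1 + sin(1) / 1, tolerance = 1e-12)
  expect_equal(sq$s_total[2], 1 + sin(2) / 2, tolerance = 1e-12)
  # q -> 0 coherent limit: S -> N for one rigid object
  sqN <- structure_factor(frames, q = 1e-6, n_chains = 1, n_beads = 2,
                          box_length = 1e5)
  expect_equal(sqN$s_total, 2, tolerance = 1e-9)
  # Debye sum equals the numerical orientational average within 0.5%
  set.seed(5)
  steps <- matrix(stats::rnorm(25 * 3), ncol = 3)
  coords <- apply(rbind(c(0, 0, 0), 4.1 * steps / sqrt(rowSums(steps^2))),
                  2, cumsum)
  q <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  sq2 <- structure_factor(list(coords), q, n_chains = 1, n_beads = 26,
                          box_length = 1e5)
  ref <- oracle_sq_direction_average(coords, q, n_dir = 4000)
  expect_true(all(abs(sq2$s_total - ref) / ref < 0.005))
  # intra + inter decomposition is exact
  expect_equal(sq2$s_intra + sq2$s_inter, sq2$s_total, tolerance = 1e-12)
})

test_that("oligomer distribution from a run sums to 100% of chains", {
  sys <- make_small_system(n_chains = 4, box = 80, seed = 17)
  run <- run_simulation(sys, energy_params(),
                        mc_config(equilibration = 200, production = 1000,
                                  seed = 3, cluster_stride = 20))
  od <- oligomer_distribution(run)
  expect_equal(sum(od$fraction_pct), 100, tolerance = 1e-6)
  expect_gte(attr(od, "n_ass"), 1)
})
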