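random_rmsd_matrix <- function(n, scale = 4) {
  X <- matrix(runif(n * 3, 0, scale), n, 3)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(sprintf("p%02d", 1:n), sprintf("p%02d", 1:n))
  D
}

test_that("degenerate matrices give all-singletons or one cluster", {
  D <- matrix(10, 4, 4); diag(D) <- 0
  dimnames(D) <- list(letters[1:4], letters[1:4])
  cs <- daura_cluster(D, cutoff = 3)
  expect_equal(nrow(cs$clusters), 4)
  expect_true(all(cs$clusters$size == 1))

  D2 <- matrix(1, 4, 4); diag(D2) <- 0
  dimnames(D2) <- dimnames(D)
  cs2 <- daura_cluster(D2, cutoff = 3)
  expect_equal(nrow(cs2$clusters), 1)
  expect_equal(cs2$clusters$size, 4L)
  expect_error(daura_cluster(D, cutoff = 0), "cutoff")
})

test_that("greedy extraction matches the independent re-count oracle", {
  set.seed(101)
  for (rep in 1:40) {
    D <- random_rmsd_matrix(12)
    cutoff <- runif(1, 1, 4)
    cs <- daura_cluster(D, cutoff = cutoff)
    oracle <- daura_oracle(D, cutoff)
    got <- lapply(cs$clusters$members, function(m) sort(match(m, rownames(D))))
    expect_identical(got, oracle)
  }
})

test_that("clusters partition the poses and obey the seed-radius rule", {
  set.seed(55)
  for (rep in 1:10) {
    D <- random_rmsd_matrix(20)
    cutoff <- runif(1, 1, 4)
    cs <- daura_cluster(D, cutoff = cutoff)
    ids <- unlist(cs$clusters$members)
    expect_setequal(ids, rownames(D))
    expect_equal(length(ids), nrow(D))    # pairwise disjoint
    for (k in seq_len(nrow(cs$clusters))) {
      seed <- cs$clusters$seed_id[k]
      mem <- setdiff(cs$clusters$members[[k]], seed)
      if (length(mem) > 0) expect_true(all(D[seed, mem] < cutoff))
    }
  }
})

test_that("cluster medians follow the even/odd conventions and rank order", {
  D <- matrix(10, 7, 7); diag(D) <- 0
  D[1:3, 1:3] <- 0.5; D[4:5, 4:5] <- 0.5; D[6:7, 6:7] <- 0.5
  diag(D) <- 0
  ids <- letters[1:7]
  dimnames(D) <- list(ids, ids)
  cs <- daura_cluster(D, cutoff = 1)
  tmpl <- mk_atoms(c(0, 0, 0), resno = 33)
  ens <- mk_ensemble(tmpl, rep(list(matrix(0, 1, 3)), 7), ids = ids,
                     peptide_range = c(33, 33))
  ens <- attach_scores(ens, tibble::tibble(
    pose_id = ids, score = c(-5, -1, -3, -4, -2, -7, -7)))
  cs <- cluster_scores(cs, ens)
  td <- tidy(cs)
  # {-5,-1,-3} -> -3; {-4,-2} -> -3 (even size: mean of central pair);
  # {-7,-7} -> -7; ranked ascending, best median first
  expect_equal(td$median_score, sort(c(-3, -3, -7)))
  expect_equal(td$rank, 1:3)
  expect_equal(td$median_score[1], -7)
})

test_that("the score ANOVA agrees with a sum-of-squares oracle", {
  # three groups in singleton-forced clusters
  g <- list(c(-9, -8.5, -9.5), c(-5, -4, -6, -5), c(-2, -1, -3))
  n <- sum(lengths(g))
  ids <- sprintf("p%02d", 1:n)
  D <- matrix(10, n, n)
  off <- 0
  for (gg in g) {
    idx <- off + seq_along(gg); D[idx, idx] <- 0.1; off <- off + length(gg)
  }
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  cs <- daura_cluster(D, cutoff = 1)
  tmpl <- mk_atoms(c(0, 0, 0), resno = 33)
  ens <- mk_ensemble(tmpl, rep(list(matrix(0, 1, 3)), n), ids = ids,
                     peptide_range = c(33, 33))
  ens <- attach_scores(ens, tibble::tibble(pose_id = ids, score = unlist(g)))
  out <- cluster_score_anova(cs, ens)

  # independent variance decomposition
  y <- unlist(g)
  grand <- mean(y)
  ss_b <- sum(lengths(g) * (sapply(g, mean) - grand)^2)
  ss_w <- sum(unlist(lapply(g, function(v) (v - mean(v))^2)))
  f_oracle <- (ss_b / (length(g) - 1)) / (ss_w / (length(y) - length(g)))
  expect_equal(out$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(out$df_between, 2)
  expect_equal(out$df_within, length(y) - 3)
})

test_that("ANOVA edge cases: equal means, zero variance, too few groups", {
  mk_scored <- function(scores_by_group) {
    n <- sum(lengths(scores_by_group))
    ids <- sprintf("p%02d", 1:n)
    D <- matrix(10, n, n); off <- 0
    for (gg in scores_by_group) {
      idx <- off + seq_along(gg); D[idx, idx] <- 0.1; off <- off + length(gg)
    }
    diag(D) <- 0
    dimnames(D) <- list(ids, ids)
    tmpl <- mk_atoms(c(0, 0, 0), resno = 33)
    ens <- mk_ensemble(tmpl, rep(list(matrix(0, 1, 3)), n), ids = ids,
                       peptide_range = c(33, 33))
    ens <- attach_scores(ens, tibble::tibble(pose_id = ids,
                                             score = unlist(scores_by_group)))
    list(cs = daura_cluster(D, cutoff = 1), ens = ens)
  }
  # identical group means with spread: F = 0
  f0 <- mk_scored(list(c(-4, -6), c(-3, -7)))
  expect_equal(cluster_score_anova(f0$cs, f0$ens)$statistic, 0,
               tolerance = 1e-12)
  # zero within-group variance, unequal means: F = Inf with a note
  finf <- mk_scored(list(c(-4, -4), c(-6, -6)))
  out <- cluster_score_anova(finf$cs, finf$ens)
  expect_equal(out$statistic, Inf)
  expect_match(out$note, "zero within-group")
  # all observations equal: degenerate
  expect_error(cluster_score_anova(mk_scored(list(c(-4, -4), c(-4, -4)))$cs,
                                   mk_scored(list(c(-4, -4), c(-4, -4)))$ens),
               "identical")
  # fewer than two eligible groups
  few <- mk_scored(list(c(-4, -5), c(-6)))
  expect_error(cluster_score_anova(few$cs, few$ens, min_size = 2), ">= 2")
})

test_that("cluster occupancy counts match a direct membership lookup", {
  set.seed(77)
  D <- random_rmsd_matrix(30)
  cs <- daura_cluster(D, cutoff = 2)
  all_ids <- rownames(D)
  # subset = everything: fractions are size / N
  occ_all <- cluster_occupancy(cs, all_ids)
  expect_equal(occ_all$count, cs$clusters$size)
  expect_equal(occ_all$fraction, cs$clusters$size / 30)
  expect_equal(sum(occ_all$fraction), 1)
  # subset inside one cluster
  big <- which.max(cs$clusters$size)
  inside <- cs$clusters$members[[big]]
  occ_in <- cluster_occupancy(cs, inside)
  expect_equal(occ_in$fraction[big], 1)
  expect_equal(sum(occ_in$fraction), 1)
  # random subset vs lookup oracle
  sub <- sample(all_ids, 11)
  occ <- cluster_occupancy(cs, sub)
  oracle <- sapply(cs$clusters$members, function(m) sum(sub %in% m))
  expect_equal(occ$count, as.integer(oracle))
  expect_error(cluster_occupancy(cs, c(sub, "zz")), "not clustered")
})

test_that("planted positional clusters are recovered exactly", {
  centers <- tibble::tibble(
    dx = c(0, 8, -8, 0, 0), dy = c(0, 0, 0, 8, -8),
    depth = 6, azimuth = 40, weight = 0.2)
  cfg <- generator_config(seed = 19, n_poses = 150,
                          cluster_centers = centers, cluster_spread = 1,
                          angular_sd = 0, decoy_fraction = 0)
  sim <- generate_ensemble(cfg)
  cs <- daura_cluster(rmsd_matrix(sim$ensemble), cutoff = 3)
  expect_equal(nrow(cs$clusters), 5)
  joined <- dplyr::left_join(cs$membership, sim$ground_truth, by = "pose_id")
  tab <- table(joined$cluster_id, joined$cluster)
  expect_true(all(rowSums(tab > 0) == 1))   # each found cluster is pure
  expect_true(all(colSums(tab > 0) == 1))   # each planted cluster intact
})
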