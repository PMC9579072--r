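test_that("community matrix averages on the chosen scale and drops rare groups", {
  rows <- rbind(
    survey_rows("S1", "North", 1, c(0, 3, 6), "Amphipoda"),
    survey_rows("S1", "North", 1, c(1, 1, 1), "Bivalvia"),
    survey_rows("S2", "North", 1, c(2, 2, 2), "Amphipoda"),
    survey_rows("S2", "North", 1, c(0, 0, 0), "Bivalvia"))
  M <- build_community_matrix(rows, min_prevalence = 0)
  # transform-then-average: mean(ln 1, ln 4, ln 7)
  expect_equal(M$values["S1@1", "Amphipoda"], (log(1) + log(4) + log(7)) / 3,
               tolerance = 1e-12)
  expect_equal(M$values["S1@1", "Amphipoda"], 1.1107, tolerance = 1e-4)
  M2 <- build_community_matrix(rows, min_prevalence = 0,
                               transform_first = FALSE)
  expect_equal(M2$values["S1@1", "Amphipoda"], log1p(3), tolerance = 1e-12)
  expect_identical(M$dropped, character(0))

  # a group at 1 of 25 visits (prevalence 0.04) is dropped at 5%
  many <- do.call(rbind, lapply(1:25, function(i) {
    rbind(survey_rows(sprintf("S%02d", i), "North", 1, c(1, 2, 3),
                      "Amphipoda"),
          survey_rows(sprintf("S%02d", i), "North", 1,
                      if (i == 1) c(5, 5, 5) else c(0, 0, 0), "Isopoda"))
  }))
  M3 <- build_community_matrix(many, min_prevalence = 0.05)
  expect_identical(M3$dropped, "Isopoda")
  expect_error(build_community_matrix(many, min_prevalence = 1), "min_prev")
})

test_that("Bray-Curtis matches the hand formula and its invariants", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 2, 1), c = c(1, 2, 3))
  d <- bray_curtis(x)
  expect_equal(d["a", "b"], 3 / 11, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  expect_equal(bray_curtis(rbind(c(1, 0), c(0, 1)))[1, 2], 1)
  expect_error(bray_curtis(rbind(c(-1, 0), c(0, 1))), "non-negative")
  expect_warning(dz <- bray_curtis(rbind(z1 = c(0, 0), z2 = c(0, 0),
                                         p = c(1, 1))), "all-zero")
  expect_equal(dz["z1", "z2"], 0)
  # random matrices: symmetry, zero diagonal, unit range
  set.seed(42)
  for (i in 1:5) {
    m <- matrix(rexp(60), 10, 6)
    dd <- bray_curtis(m)
    expect_equal(unclass(dd), t(unclass(dd)), ignore_attr = TRUE)
    expect_true(all(diag(dd) == 0))
    expect_true(all(dd >= 0 & dd <= 1))
  }
})

test_that("NMDS recovers exact low-dimensional structure and improves with k", {
  set.seed(7)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  ord <- nmds(D, k = 2, n_starts = 10, seed = 3)
  expect_lt(ord$stress, 1e-3)                 # perfectly embeddable
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-8)              # centered
  # stress cannot increase with embedding dimension
  hi <- matrix(rnorm(60), 12, 5)
  Dh <- as.matrix(dist(hi))
  s2 <- suppressWarnings(nmds(Dh, k = 2, n_starts = 8, seed = 5))$stress
  s3 <- suppressWarnings(nmds(Dh, k = 3, n_starts = 8, seed = 5))$stress
  expect_lte(s3, s2 + 1e-6)
})

test_that("centroids and confidence intervals follow the t formula", {
  pts <- rbind(c(1, 1), c(1, 1), c(1, 1), c(-2, 2), c(2, -2),
               c(0, 1), c(2, 3), c(4, 5))
  g <- c("a", "a", "a", "b", "b", "c", "c", "c")
  cen <- centroids_ci(pts, g)
  # identical points: zero-width interval
  expect_equal(cen$halfwidth1[cen$group == "a"], 0)
  # symmetric pair: centroid at the origin
  expect_equal(cen$centroid1[cen$group == "b"], 0)
  expect_equal(cen$centroid2[cen$group == "b"], 0)
  # hand computation on (0, 2, 4): t(2, .975) * sd / sqrt(3)
  expect_equal(cen$halfwidth1[cen$group == "c"],
               qt(0.975, 2) * sd(c(0, 2, 4)) / sqrt(3), tolerance = 1e-12)
  s <- centroids_ci(rbind(c(0, 0), c(1, 1)), c("x", "y"))
  expect_false(any(s$ci_defined))
  expect_true(all(is.na(s$halfwidth1)))
})

test_that("NPMANOVA p equals the exhaustive-permutation oracle on 6 rows", {
  set.seed(13)
  vals <- rbind(matrix(rexp(9, 1), 3, 3), matrix(rexp(9, 0.3), 3, 3))
  rownames(vals) <- paste0("r", 1:6)
  g <- factor(rep(c("A", "B"), each = 3))
  d <- bray_curtis(vals)
  res <- npmanova(d, terms = "g", permutations = all_perms(6),
                  data = data.frame(g = g))
  F_all <- apply(all_perms(6), 1, function(p)
    two_group_pseudo_F(d[p, p], g))
  p_oracle <- mean(F_all >= two_group_pseudo_F(unclass(d), g) - 1e-12)
  expect_equal(res$aov_table$p, p_oracle, tolerance = 1e-12)
  # the Gower-partition pseudo-F agrees with the direct decomposition
  expect_equal(res$aov_table$pseudo_F, two_group_pseudo_F(unclass(d), g),
               tolerance = 1e-10)
})

test_that("NPMANOVA matches vegan's sequential partition and is seed-stable", {
  d <- make_design(small_spec())
  tab <- simulate_biomass(d, default_sim_params(), seed = 17)
  M <- build_community_matrix(tab)
  res <- npmanova(M, n_perm = 199, seed = 9)
  dd <- stats::as.dist(bray_curtis(M))
  meta <- M$meta
  for (v in c("period", "zone", "sediment", "depth")) {
    meta[[v]] <- factor(meta[[v]])
  }
  ref <- vegan::adonis2(dd ~ period + zone + sediment + depth + period:zone,
                        data = meta, permutations = 2, by = "terms")
  expect_equal(res$aov_table$pseudo_F, ref$F[1:5], tolerance = 1e-8)
  expect_equal(res$aov_table$R2, ref$R2[1:5], tolerance = 1e-8)
  expect_equal(res$aov_table$df, ref$Df[1:5])
  # SS decomposition and permutation-p floor
  expect_equal(sum(res$aov_table$SS) + res$residual$SS, res$total$SS,
               tolerance = 1e-8)
  expect_true(all(res$aov_table$p >= 1 / 200))
  expect_identical(npmanova(M, n_perm = 199, seed = 9)$aov_table,
                   res$aov_table)
  expect_error(npmanova(M, terms = c("zone", "zone")), "confounded")
})

test_that("pairwise permutation tests use the Holm step-down adjustment", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "holm"),
               c(0.03, 0.04, 0.04))
  d <- make_design(small_spec(per_zone = c(North = 4L, Middle = 4L,
                                           South = 4L), periods = 1:2))
  tab <- simulate_biomass(d, flat_params(), seed = 23)
  M <- build_community_matrix(tab)
  pw <- pairwise_permutation(M, n_perm = 99, seed = 2)
  expect_equal(nrow(pw), choose(6, 2))  # 2 periods x 3 zones
  # step-down definition applied to the raw p-values
  o <- order(pw$p_raw)
  m <- nrow(pw)
  adj <- cummax(pmin(1, (m - seq_len(m) + 1) * pw$p_raw[o]))[order(o)]
  expect_equal(pw$p_holm, adj, tolerance = 1e-12)
  expect_identical(pw$significant, pw$p_holm <= 0.05)
  # label invariance of the two-group pseudo-F
  g <- rep(c("A", "B"), each = 12)
  g2 <- rep(c("B", "A"), each = 12)
  vals <- matrix(rexp(24 * 4), 24, 4)
  dmat <- bray_curtis(vals)
  f1 <- npmanova(dmat, terms = "g", n_perm = 99, seed = 1,
                 data = data.frame(g = g))$aov_table$pseudo_F
  f2 <- npmanova(dmat, terms = "g", n_perm = 99, seed = 1,
                 data = data.frame(g = g2))$aov_table$pseudo_F
  expect_equal(f1, f2, tolerance = 1e-12)
})
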