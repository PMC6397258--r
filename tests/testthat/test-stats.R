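hand_distance <- function() {
  # 2 groups of 2; within-pair distance 1, all between distances 2
  d <- matrix(2, 4, 4)
  d[1, 2] <- d[2, 1] <- 1
  d[3, 4] <- d[4, 3] <- 1
  diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  d
}

test_that("Bray-Curtis matches the min-sum formula", {
  x <- rbind(u = c(1, 1, 0), v = c(0, 1, 1), w = c(1, 1, 0),
             y = c(5, 0, 0), z = c(0, 0, 7))
  colnames(x) <- paste0("f", 1:3)
  d <- bray_curtis(x)
  expect_equal(d["u", "v"], 0.5)        # 1 - 2*1/4
  expect_equal(d["u", "w"], 0)          # identical rows
  expect_equal(d["y", "z"], 1)          # disjoint supports
  expect_error(bray_curtis(rbind(x, bad = c(0, 0, 0))), "all-zero")
})

test_that("PERMANOVA reproduces the hand-computed sums-of-squares case", {
  res <- permanova(hand_distance(), c("g1", "g1", "g2", "g2"),
                   n_perm = 99, seed = 1)
  expect_equal(res$statistic, 7)
  expect_equal(res$R2, 3.5 / 4.5)
  expect_gt(res$p_raw, 0)

  # all pairwise distances equal -> F = 1 by symmetry
  deq <- matrix(1, 4, 4); diag(deq) <- 0
  dimnames(deq) <- dimnames(hand_distance())
  expect_equal(permanova(deq, c("a", "a", "b", "b"), n_perm = 19,
                         seed = 1)$statistic, 1)

  expect_error(permanova(hand_distance(), c("g1", "g1", "g2", "g3")),
               "singleton")
})

test_that("distance sums of squares always add up (SS_A + SS_W = SS_T)", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    pts <- matrix(rnorm(2 * n), n, 2)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("u", 1:n), paste0("u", 1:n))
    g <- sample(rep(1:2, length.out = n))
    parts <- spongenet:::permanova_F(d^2, g)
    expect_equal(parts[["SST"]],
                 parts[["SSW"]] + (parts[["SST"]] - parts[["SSW"]]))
    ssa <- parts[["SST"]] - parts[["SSW"]]
    expect_gte(parts[["SSW"]], 0)
    # recompute F from the partition and compare
    a <- 2
    expect_equal(parts[["F"]],
                 (ssa / (a - 1)) / (parts[["SSW"]] / (n - a)))
  }
})

test_that("PERMANOVA F on 1-D Euclidean distances equals the ANOVA F", {
  set.seed(67)
  for (rep in 1:5) {
    y <- rnorm(12)
    g <- factor(rep(c("a", "b", "c"), each = 4))
    d <- as.matrix(stats::dist(y))
    dimnames(d) <- list(paste0("s", 1:12), paste0("s", 1:12))
    res <- permanova(d, as.character(g), n_perm = 19, seed = 1)
    f_aov <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
    expect_equal(res$statistic, f_aov, tolerance = 1e-10)
  }
})

test_that("PERMANOVA agrees with the vegan implementation", {
  set.seed(71)
  x <- matrix(rpois(10 * 8, 12), 10, 8,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:8)))
  g <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(x)
  mine <- permanova(d, g, n_perm = 199, seed = 5)
  ref <- vegan::adonis2(stats::as.dist(d) ~ grp,
                        data = data.frame(grp = g), permutations = 199)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA permutation test is calibrated under the null", {
  set.seed(73)
  n_rep <- 300
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    pts <- matrix(rnorm(2 * 10), 10, 2)
    d <- as.matrix(stats::dist(pts))
    dimnames(d) <- list(paste0("u", 1:10), paste0("u", 1:10))
    g <- sample(rep(1:2, each = 5))
    p <- permanova(d, g, n_perm = 99, seed = 5000 + r)$p_raw
    if (p <= 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 1e-9)
})

test_that("pairwise PERMANOVA applies the chosen FDR correction", {
  set.seed(79)
  # three separated clusters in 2-D
  pts <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 4), 4),
               matrix(rnorm(8, 8), 4))
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("u", 1:12), paste0("u", 1:12))
  g <- rep(c("a", "b", "c"), each = 4)
  by <- pairwise_permanova(d, g, correction = "BY", n_perm = 99, seed = 2)
  bh <- pairwise_permanova(d, g, correction = "BH", n_perm = 99, seed = 2)
  expect_equal(nrow(by), 3L)
  expect_equal(by$p_raw, bh$p_raw)  # same seeds, same raw values
  expect_true(all(by$p_adjusted >= bh$p_adjusted - 1e-12))
  expect_true(all(bh$p_adjusted >= bh$p_raw - 1e-12))
  expect_equal(by$p_adjusted, stats::p.adjust(by$p_raw, "BY"))

  # single pair: adjusted equals raw
  one <- pairwise_permanova(d[1:8, 1:8], g[1:8], n_perm = 99, seed = 2)
  expect_equal(one$p_adjusted, one$p_raw)
})

test_that("Benjamini-Yekutieli worked example and ordering property hold", {
  p <- c(0.01, 0.02, 0.04)
  by <- stats::p.adjust(p, "BY")
  expect_equal(by, c(0.055, 0.055, 11 / 150), tolerance = 1e-12)
  set.seed(83)
  for (rep in 1:20) {
    pv <- runif(sample(3:12, 1))
    expect_true(all(stats::p.adjust(pv, "BY") >=
                      stats::p.adjust(pv, "BH") - 1e-12))
    expect_true(all(stats::p.adjust(pv, "BH") >= pv - 1e-12))
  }
})

test_that("dispersion homogeneity measures distance to group centroids", {
  # each group a pair of identical points -> zero dispersion
  d0 <- matrix(0, 4, 4); d0[1:2, 3:4] <- 5; d0[3:4, 1:2] <- 5
  dimnames(d0) <- list(paste0("u", 1:4), paste0("u", 1:4))
  bd0 <- suppressWarnings(beta_dispersion(d0, c("a", "a", "b", "b"),
                                          n_perm = 19, seed = 1))
  expect_equal(unname(bd0$dispersion), c(0, 0))

  # a segment of length 2: both members sit 1 from the centroid
  seg <- as.matrix(stats::dist(c(0, 2, 10, 12)))
  dimnames(seg) <- list(paste0("u", 1:4), paste0("u", 1:4))
  bd <- suppressWarnings(beta_dispersion(seg, c("a", "a", "b", "b"),
                                         n_perm = 19, seed = 1))
  expect_equal(unname(bd$dispersion), c(1, 1))

  # translation invariance: dispersions depend on d only
  set.seed(89)
  pts <- matrix(rnorm(16), 8, 2)
  g8 <- rep(c("a", "b"), each = 4)
  d1 <- as.matrix(stats::dist(pts))
  d2 <- as.matrix(stats::dist(sweep(pts, 2, c(100, -50), "+")))
  dimnames(d1) <- dimnames(d2) <- list(paste0("u", 1:8), paste0("u", 1:8))
  expect_equal(beta_dispersion(d1, g8, n_perm = 19, seed = 1)$dispersion,
               beta_dispersion(d2, g8, n_perm = 19, seed = 1)$dispersion)

  # looser generator sigma gives larger dispersion in most seeds
  wins <- 0L
  for (s in 1:40) {
    set.seed(900 + s)
    tight <- matrix(rnorm(10, sd = 0.1), 5, 2)
    loose <- matrix(rnorm(10, sd = 1.0), 5, 2)
    dd <- as.matrix(stats::dist(rbind(tight, loose)))
    dimnames(dd) <- list(paste0("u", 1:10), paste0("u", 1:10))
    disp <- beta_dispersion(dd, rep(c("t", "l"), each = 5),
                            n_perm = 19, seed = s)$dispersion
    if (disp["t"] < disp["l"]) wins <- wins + 1L
  }
  expect_gte(wins / 40, 0.95)
})

test_that("PCoA recovers Euclidean geometry and flags degeneracy", {
  # equilateral triangle: two equal positive eigenvalues, third ~ 0
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  dimnames(tri) <- list(paste0("p", 1:3), paste0("p", 1:3))
  pc <- pcoa(tri)
  expect_equal(pc$eigenvalues[1], pc$eigenvalues[2], tolerance = 1e-9)
  expect_lt(abs(pc$eigenvalues[3]), 1e-9)

  # collinear points: one positive eigenvalue, distances reproduced
  lin <- as.matrix(stats::dist(c(0, 1, 3)))
  dimnames(lin) <- list(paste0("p", 1:3), paste0("p", 1:3))
  pc2 <- pcoa(lin)
  expect_equal(sum(pc2$eigenvalues > 1e-9), 1L)
  expect_equal(as.matrix(stats::dist(pc2$points)), lin,
               ignore_attr = TRUE, tolerance = 1e-9)

  # all-zero distances: every eigenvalue 0
  z <- matrix(0, 3, 3)
  dimnames(z) <- list(paste0("p", 1:3), paste0("p", 1:3))
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-12))
})

test_that("KS statistic follows the ECDF supremum", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_equal(ks_two_sample(c(1, 3), c(2, 4))$D, 0.5)
  expect_equal(ks_two_sample(c(1, 2), c(1, 2))$D, 0)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("Nemenyi rank comparisons separate and calibrate", {
  # disjoint ranges with n = 10 each: decisive rejection
  v <- c(1:10, 101:110)
  g <- rep(c("a", "b"), each = 10)
  expect_lt(nemenyi_ranks(v, g)["a", "b"], 0.05)

  # identical constant values: ties give p = 1
  expect_equal(nemenyi_ranks(rep(5, 8), rep(c("a", "b"), each = 4))["a", "b"],
               1)

  expect_error(nemenyi_ranks(1:5, rep("a", 5)), "2 groups")

  # same-distribution groups rarely rejected
  set.seed(97)
  hits <- 0L
  for (r in 1:200) {
    vv <- rnorm(20)
    gg <- rep(c("a", "b"), each = 10)
    if (nemenyi_ranks(vv, gg)["a", "b"] < 0.05) hits <- hits + 1L
  }
  expect_lt(hits / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("indicator r.g matches a weighted-Pearson oracle", {
  # perfect association, equal groups
  feat <- matrix(c(5, 5, 5, 0, 0, 0), 6, 1,
                 dimnames = list(paste0("s", 1:6), "f1"))
  g <- rep(c("A", "B"), each = 3)
  res <- indicator_analysis(feat, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic[res$group == "A"], 1)

  # constant feature: r.g = 0 with p = 1, flagged
  feat2 <- cbind(feat, f2 = rep(3, 6))
  res2 <- indicator_analysis(feat2, g, n_perm = 99, seed = 1)
  expect_equal(res2$statistic[res2$feature == "f2"], c(0, 0))
  expect_equal(res2$p_raw[res2$feature == "f2"], c(1, 1))
  expect_true(all(res2$constant[res2$feature == "f2"]))

  # unbalanced 6-sample toy against the brute-force weighted Pearson
  x <- c(4, 7, 1, 0, 2, 0)
  gu <- c("A", "A", "A", "A", "B", "B")
  featu <- matrix(x, 6, 1, dimnames = list(paste0("s", 1:6), "fx"))
  resu <- indicator_analysis(featu, gu, n_perm = 99, seed = 1)
  w <- 1 / as.vector(table(gu)[gu])
  oracle <- weighted_pearson(x, as.numeric(gu == "A"), w)
  expect_equal(resu$statistic[resu$group == "A"], oracle, tolerance = 1e-12)
  expect_equal(resu$statistic[resu$group == "B"], -oracle, tolerance = 1e-12)

  # BH adjustment across the family
  expect_equal(res2$p_adjusted, stats::p.adjust(res2$p_raw, "BH"))
})

test_that("permutation machinery reproduces exactly under a fixed seed", {
  set.seed(103)
  x <- matrix(rpois(8 * 5, 10), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("f", 1:5)))
  g <- rep(c("a", "b"), each = 4)
  d <- bray_curtis(x)
  expect_identical(permanova(d, g, n_perm = 99, seed = 9),
                   permanova(d, g, n_perm = 99, seed = 9))
  expect_identical(pairwise_permanova(d, g, n_perm = 99, seed = 9),
                   pairwise_permanova(d, g, n_perm = 99, seed = 9))
  expect_identical(indicator_analysis(x, g, n_perm = 49, seed = 9),
                   indicator_analysis(x, g, n_perm = 49, seed = 9))
})
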