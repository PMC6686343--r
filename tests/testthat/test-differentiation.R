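test_that("binary mismatch distance handles missing cells and degenerate pairs", {
  x <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 1), c = c(1, 1, 0, 0),
             d = c(0, 0, 1, 1))
  d <- binary_distance(x)
  expect_equal(d$d["a", "b"], 0.5)
  expect_equal(d$d["a", "c"], 0)
  expect_equal(d$d["a", "d"], 1)
  expect_true(isSymmetric(d$d))
  # joint scoring: mismatch proportion over jointly observed columns only
  y <- rbind(a = c(1, NA, 0), b = c(0, 1, NA))
  expect_equal(binary_distance(y)$d["a", "b"], 1)   # only column 1 joint
  z <- rbind(a = c(1, NA), b = c(NA, 1))
  expect_error(binary_distance(z), "jointly scored")
})

test_that("allelic mismatch distance counts shared alleles per locus", {
  g <- make_geno(list(A = list(c(1, 1)), B = list(c(1, 1)), C = list(c(2, 2)),
                      D = list(c(1, 2)), E = list(c(1, 3)), F = list(c(2, 3))))
  d <- msat_distance(g)
  expect_equal(d$d["A", "B"], 0)
  expect_equal(d$d["A", "C"], 2)
  expect_equal(d$d["D", "E"], 1)
  expect_equal(d$d["D", "F"], 1)
  expect_equal(d$d["A", "D"], 1)
  expect_equal(d$d["C", "E"], 2)
  # averaged over jointly scored loci
  g2 <- make_geno(list(A = list(c(1, 1), c(1, 2)), B = list(c(1, 2), c(3, 4))))
  expect_equal(msat_distance(g2)$d["A", "B"], (1 + 2) / 2)
})

test_that("AMOVA hits the textbook extremes", {
  # two groups of identical clones, constant distance between groups
  dm <- matrix(1, 6, 6) - diag(6)
  dm[1:3, 1:3] <- 0; dm[4:6, 4:6] <- 0
  res <- amova(dm, rep(c("g1", "g2"), each = 3), n_perm = 99, seed = 1)
  expect_equal(res$phi_st, 1)
  expect_equal(res$percent_among + res$percent_within, 100)
  # all individuals identical: Phi undefined
  res0 <- amova(matrix(0, 5, 5), rep(c("a", "b"), c(2, 3)), n_perm = 99)
  expect_true(is.na(res0$phi_st))
  expect_error(amova(dm, rep("g", 6)), "2 groups")
})

test_that("AMOVA equals the brute-force variance-component oracle on small instances", {
  set.seed(202)
  for (rep in 1:12) {
    n <- sample(5:12, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 3), n)
    dm <- as.matrix(dist(pts))
    rownames(dm) <- colnames(dm) <- paste0("i", 1:n)
    groups <- sample(paste0("g", 1:k), n, replace = TRUE)
    while (length(unique(groups)) < k) groups <- sample(paste0("g", 1:k), n, TRUE)
    res <- amova(dm, groups, n_perm = 0)
    expect_equal(res$phi_st, oracle_amova_phi(dm, groups), tolerance = 1e-10)
  }
})

test_that("AMOVA permutation p-values stay in (0, 1] and detect true structure", {
  set.seed(77)
  x <- rbind(matrix(rbinom(10 * 40, 1, 0.1), 10),
             matrix(rbinom(10 * 40, 1, 0.9), 10))
  rownames(x) <- paste0("i", 1:20)
  d <- binary_distance(x)
  res <- amova(d, rep(c("a", "b"), each = 10), n_perm = 999, seed = 4)
  expect_gte(res$p, 1 / 1000)
  expect_lte(res$p, 1)
  expect_lte(res$p, 0.01)
})

test_that("pairwise Phi is symmetric and consistent with two-group AMOVA", {
  set.seed(55)
  x <- matrix(rbinom(18 * 30, 1, 0.5), 18)
  rownames(x) <- paste0("i", 1:18)
  groups <- rep(c("a", "b", "c"), each = 6)
  d <- binary_distance(x)
  pw <- pairwise_phi(d, groups, n_perm = 99, seed = 9)
  expect_equal(pw$phi["a", "b"], pw$phi["b", "a"])
  sub <- which(groups != "c")
  direct <- amova(d$d[sub, sub], groups[sub], n_perm = 0)
  expect_equal(pw$phi["a", "b"], direct$phi_st)
})

test_that("stronger divergence yields larger pairwise Phi", {
  set.seed(91)
  hits <- 0L
  for (rep in 1:50) {
    ref <- rbinom(60, 1, 0.5)
    flip <- function(p) ifelse(runif(60) < p, 1 - ref, ref)
    x <- rbind(t(replicate(6, flip(0.02))),   # group c ~ reference
               t(replicate(6, flip(0.15))),   # group b mildly diverged
               t(replicate(6, flip(0.35))))   # group a strongly diverged
    rownames(x) <- paste0("i", 1:18)
    groups <- rep(c("c", "b", "a"), each = 6)
    pw <- pairwise_phi(binary_distance(x), groups, n_perm = 0)
    hits <- hits + (pw$phi["a", "c"] >= pw$phi["b", "c"])
  }
  expect_gte(hits, 45)   # >= 90% of seeds
})

test_that("PCoA reproduces known geometries", {
  # three equidistant points: two equal positive eigenvalues
  dm <- matrix(1, 3, 3) - diag(3)
  p <- pcoa(dm)
  ev <- p$eigenvalues[p$eigenvalues > 1e-12]
  expect_equal(length(ev), 2)
  expect_equal(ev[1], ev[2])
  # collinear points at 0, 1, 3: axis 1 recovers spacing up to sign/shift
  dm2 <- as.matrix(dist(c(0, 1, 3)))
  p2 <- pcoa(dm2)
  ax1 <- p2$coordinates[, 1]
  ax1 <- (ax1 - ax1[1]) * sign(ax1[3] - ax1[1])
  expect_equal(unname(ax1), c(0, 1, 3), tolerance = 1e-9)
  # duplicated individual gets identical coordinates
  dm3 <- as.matrix(dist(c(0, 0, 2, 5)))
  p3 <- pcoa(dm3)
  expect_equal(p3$coordinates[1, ], p3$coordinates[2, ])
  # agrees with classical MDS on random Euclidean data
  set.seed(8)
  pts <- matrix(rnorm(24), 8)
  dm4 <- as.matrix(dist(pts))
  p4 <- pcoa(dm4)
  ref <- cmdscale(dm4, k = 2)
  for (ax in 1:2)
    expect_equal(abs(cor(p4$coordinates[, ax], ref[, ax])), 1,
                 tolerance = 1e-9)
})

test_that("Mantel r is exact on identical and affine-related matrices", {
  set.seed(66)
  pts <- matrix(rnorm(20), 10)
  d1 <- as.matrix(dist(pts))
  rownames(d1) <- colnames(d1) <- paste0("i", 1:10)
  m <- mantel_test(d1, d1, n_perm = 199, seed = 2)
  expect_equal(m$r, 1)
  expect_gte(m$p, 1 / 200)
  d2 <- 3 * d1 + 0.5; diag(d2) <- 0
  expect_equal(mantel_test(d1, d2, n_perm = 99, seed = 2)$r, 1)
  d0 <- d1 * 0
  expect_error(mantel_test(d1, d0), "zero variance")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(14)
  d1 <- as.matrix(dist(matrix(rnorm(30), 15)))
  d2 <- as.matrix(dist(matrix(rnorm(30), 15)))
  dimnames(d1) <- dimnames(d2) <- list(paste0("i", 1:15), paste0("i", 1:15))
  ours <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})
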