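test_that("dietary FA selection drops rare FAs and re-closes rows", {
  set.seed(2)
  prof <- data.frame(trip_id = paste0("T", 1:10),
                     a = runif(10, 10, 20), b = runif(10, 5, 10),
                     c = runif(10, 0.2, 0.6), d = runif(10, 30, 40))
  prof$c <- prof$c * 0.4 / mean(prof$c)       # force mean exactly 0.4
  sel <- select_dietary_fas(prof, threshold = 0.5)
  expect_false("c" %in% names(sel))
  expect_true(all(c("a", "b", "d") %in% names(sel)))
  expect_equal(rowSums(sel[, -1]), rep(100, 10), tolerance = 1e-9)
  # all above threshold: everything kept
  sel2 <- select_dietary_fas(prof[, c("trip_id", "a", "b", "d")],
                             threshold = 0.5)
  expect_identical(ncol(sel2), 4L)
  expect_error(select_dietary_fas(prof, threshold = 50), "fewer than 2")
})

test_that("clr transform has the defining compositional properties", {
  # uniform composition maps to the zero vector
  expect_equal(clr_transform(rep(25, 4)), rep(0, 4) ,
               ignore_attr = TRUE)
  set.seed(4)
  x <- matrix(rexp(60), 10)
  x <- 100 * x / rowSums(x)
  z <- clr_transform(x)
  expect_equal(rowSums(z), rep(0, 10), tolerance = 1e-9)
  # scale invariance
  expect_equal(clr_transform(5 * x[1, ]), z[1, ], tolerance = 1e-12)
  # zeros replaced multiplicatively, then defined everywhere
  w <- c(0, 10, 40, 50)
  zz <- clr_transform(w, zero_replacement = 0.65)
  expect_true(all(is.finite(zz)))
  expect_equal(sum(zz), 0, tolerance = 1e-12)
})

test_that("Ward linkage matches direct objective minimization", {
  # two points: single merge at their squared distance
  two <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  hc <- ward_cluster(two)
  expect_equal(hc$height, 25)
  # three collinear points: first merge is the close pair
  three <- matrix(c(0, 1, 10), ncol = 1)
  hc3 <- ward_cluster(three)
  expect_identical(sort(hc3$merge[1, ]), c(-2L, -1L))
  # random sets vs brute-force greedy Ward (n <= 8)
  set.seed(9)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    hc <- ward_cluster(x)
    br <- brute_ward(x)
    expect_equal(hc$height, br$heights, tolerance = 1e-9)
    for (k in 2:(n - 1)) {
      expect_equal(ari(cutree(hc, k), br$partitions[[n - k]]), 1)
    }
  }
})

test_that("adaptive tree cut recovers planted structure", {
  set.seed(2)
  x4 <- do.call(rbind, lapply(0:3, function(k)
    matrix(rnorm(30 * 5, mean = 6 * k), 30)))
  lab <- dynamic_tree_cut(ward_cluster(x4), min_cluster_size = 10)
  expect_identical(length(unique(lab)), 4L)
  expect_equal(ari(lab, rep(1:4, each = 30)), 1)
  # two blobs
  x2 <- rbind(matrix(rnorm(40 * 5), 40), matrix(rnorm(40 * 5, mean = 5), 40))
  lab2 <- dynamic_tree_cut(ward_cluster(x2), min_cluster_size = 10)
  expect_identical(length(unique(lab2)), 2L)
  expect_equal(ari(lab2, rep(1:2, each = 40)), 1)
  # min_cluster_size > n collapses to one cluster
  expect_identical(unique(dynamic_tree_cut(ward_cluster(x2),
                                           min_cluster_size = 100)), 1L)
  # identical profiles are one cluster
  same <- matrix(1, 20, 3)
  expect_identical(unique(dynamic_tree_cut(ward_cluster(same),
                                           min_cluster_size = 5)), 1L)
})

test_that("clustering is invariant to input row order", {
  set.seed(6)
  x <- rbind(matrix(rnorm(25 * 4), 25), matrix(rnorm(25 * 4, mean = 6), 25),
             matrix(rnorm(25 * 4, mean = -6), 25))
  truth <- rep(1:3, each = 25)
  perm <- sample(nrow(x))
  lab1 <- dynamic_tree_cut(ward_cluster(x), min_cluster_size = 10)
  lab2 <- dynamic_tree_cut(ward_cluster(x[perm, ]), min_cluster_size = 10)
  expect_equal(ari(lab1, truth), 1)
  expect_equal(ari(lab2, truth[perm]), 1)
  expect_equal(ari(lab1[perm], lab2), 1)
})

test_that("LDA ranks the single differing FA first", {
  set.seed(8)
  base <- matrix(rnorm(80 * 6, sd = 0.2), 80)
  colnames(base) <- paste0("fa", 1:6)
  base[41:80, 1] <- base[41:80, 1] + 3          # clusters differ only in fa1
  labels <- rep(1:2, each = 40)
  ld <- discriminating_fas(base, labels)
  expect_identical(ld$ranking[1], "fa1")
  # label permutation leaves the ranking unchanged
  ld2 <- discriminating_fas(base, 3 - labels)
  expect_identical(ld$ranking, ld2$ranking)
  # degenerate scatter is ridge-regularized with a warning
  const <- matrix(rep(c(0, 1), each = 12), ncol = 3)
  expect_warning(discriminating_fas(const, rep(1:2, each = 4)), "ridge")
})

test_that("hand-rolled LDA agrees with MASS::lda discriminant direction", {
  skip_if_not_installed("MASS")
  set.seed(10)
  x <- rbind(matrix(rnorm(50 * 4), 50),
             matrix(rnorm(50 * 4, mean = c(1.5, 0, -1, 0.5)), 50,
                    byrow = FALSE))
  labels <- rep(1:2, each = 50)
  ld <- discriminating_fas(x, labels)
  mass_fit <- MASS::lda(x, grouping = labels)
  s1 <- as.numeric(x %*% ld$loadings[, 1])
  s2 <- as.numeric(x %*% mass_fit$scaling[, 1])
  expect_gt(abs(cor(s1, s2)), 0.999)
})

test_that("the full pipeline separates Dirichlet diet clusters", {
  set.seed(5)
  fp <- simulate_fa_profiles(240, c(.3, .25, .25, .2))
  m <- fa_cluster_pipeline(fp$profiles, min_cluster_size = 20)
  expect_identical(m$n_clusters, 4L)
  expect_gte(ari(m$labels, fp$labels), 0.9)
  expect_s3_class(m$lda, "fa_lda")
  expect_equal(rowSums(m$clr), rep(0, nrow(m$clr)), tolerance = 1e-9)
})
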