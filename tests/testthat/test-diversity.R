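test_that("shannon matches closed forms and the hand-derived example", {
  expect_equal(shannon(c(25, 25, 25, 25)), log(4), tolerance = 1e-12)
  expect_equal(shannon(7), 0)
  # -sum(p log p) for p = (0.1, 0.2, 0.3, 0.4), evaluated by hand
  expect_equal(shannon(c(1, 2, 3, 4)), 1.2798542, tolerance = 1e-6)
  expect_equal(shannon(c(2, 2), base = 2), 1)
  expect_error(shannon(c(0, 0)), class = "soursentinel_domain_error")
  expect_error(shannon(c(-1, 2)), class = "soursentinel_domain_error")
})

test_that("simpson matches closed forms in both variants", {
  expect_equal(simpson(c(25, 25, 25, 25)), 0.75)
  expect_equal(simpson(7), 0)
  expect_equal(simpson(c(1, 2, 3, 4)), 0.70, tolerance = 1e-12)
  expect_equal(simpson(c(1, 2, 3, 4), variant = "dominance"), 0.30,
               tolerance = 1e-12)
  # scale invariance
  expect_equal(simpson(c(3, 9, 18)), simpson(c(1, 3, 6) * 1e4))
  expect_error(simpson(numeric(0)), class = "soursentinel_domain_error")
})

test_that("shannon is bounded by log richness with equality only at uniformity", {
  set.seed(7)
  for (i in 1:30) {
    x <- rgamma(sample(2:20, 1), 1)
    expect_lte(shannon(x), log(sum(x > 0)) + 1e-12)
  }
  expect_equal(shannon(rep(3, 12)), log(12), tolerance = 1e-12)
})

test_that("bray_curtis matches the direct formula and its axioms", {
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 0)), 1 - 4 / 12,
               tolerance = 1e-12)
  expect_equal(bray_curtis(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(bray_curtis(c(5, 0), c(0, 3)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)),
               class = "soursentinel_domain_error")
  expect_error(bray_curtis(1:3, 1:4), class = "soursentinel_validation_error")

  set.seed(11)
  for (i in 1:50) {
    a <- rpois(8, 5); b <- rpois(8, 5)
    if (sum(a) + sum(b) == 0) next
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(b, a))                  # symmetry
    perm <- sample(8)
    expect_equal(d, bray_curtis(a[perm], b[perm]))      # taxon permutation
    # independent oracle: 1 - 2 sum(min) / (sum a + sum b)
    expect_equal(d, 1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b)),
                 tolerance = 1e-12)
  }
})

test_that("pcoa embeds a line exactly and handles degenerate input", {
  m <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  ord <- pcoa(m, k = 2)
  tol <- max(abs(ord$eig)) * 1e-8
  expect_equal(sum(ord$eig > tol), 1)
  ax <- sort(ord$points[, 1])
  expect_equal(unname(diff(ax)), c(1, 1), tolerance = 1e-8)

  zero <- matrix(0, 4, 4, dimnames = list(1:4, 1:4))
  ordz <- pcoa(zero, k = 2)
  expect_true(all(ordz$points == 0))

  asym <- m; asym[1, 2] <- 5
  expect_error(pcoa(asym), class = "soursentinel_validation_error")
})

test_that("pcoa reconstructs Euclidean configurations", {
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rnorm(10), 5, 2)
    d <- as.matrix(dist(x))
    ord <- pcoa(d, k = 4)
    expect_lt(max(abs(as.matrix(dist(ord$points)) - d)), 1e-8)
    expect_true(all(diff(ord$eig) <= 1e-9))  # eigenvalues descending
    # retained axes are orthogonal
    cp <- crossprod(scale(ord$points, scale = FALSE))
    expect_lt(max(abs(cp[lower.tri(cp)])), 1e-8)
  }
})

test_that("rank tests reproduce exact and degenerate cases", {
  w <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)),
                     "wilcoxon_rank_sum")
  expect_equal(w$p_value, 0.1)   # exact two-sided permutation p
  expect_error(group_compare(list(a = 1:3), "wilcoxon_rank_sum"),
               class = "soursentinel_validation_error")
  expect_error(group_compare(list(a = 1:3, b = numeric(0)), "kruskal_wallis"),
               class = "soursentinel_validation_error")
  k <- group_compare(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)),
                     "kruskal_wallis")
  expect_equal(k$statistic, 0)
  k3 <- group_compare(list(a = rnorm(5), b = rnorm(5) + 3, c = rnorm(5)),
                      "kruskal_wallis")
  expect_true(k3$p_value >= 0 && k3$p_value <= 1)
})

test_that("the rank-sum statistic responds monotonically to a location shift", {
  set.seed(5)
  x <- rnorm(6); y <- rnorm(6)
  # W (Mann-Whitney U of x vs y) can only fall as y is shifted upward,
  # reaching 0 (maximal separation from the null mean 18) in the limit
  prev <- Inf
  for (shift in c(0, 0.5, 1, 2, 4, 8, 50)) {
    s <- group_compare(list(x, y + shift), "wilcoxon_rank_sum")$statistic
    expect_lte(s, prev + 1e-9)
    prev <- s
  }
  expect_equal(prev, 0)   # complete separation
})
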