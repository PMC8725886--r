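test_that("fisher_z is the clipped atanh with odd symmetry", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1.2), "not a correlation")
  r <- seq(-0.999999, 0.999999, length.out = 101)
  expect_lt(max(abs(tanh(fisher_z(r)) - r)), 1e-9)
})

test_that("one_sample_t_map matches the textbook scalar computation", {
  toy <- c(0.1, 0.2, 0.15, 0.12, 0.18)
  z <- array(rep(toy, 4), c(5, 2, 2))
  g <- one_sample_t_map(z)
  o <- scalar_t(toy)
  expect_equal(g$t[1, 1], o$t, tolerance = 1e-12)
  expect_equal(g$p[1, 1], o$p, tolerance = 1e-12)
  expect_equal(g$df[1, 1], 4)
  # symmetric values around zero
  zs <- array(c(-1, 1, -2, 2), c(4, 1, 1))
  gs <- one_sample_t_map(zs)
  expect_equal(gs$t[1, 1], 0)
  expect_equal(gs$p[1, 1], 1)
  # below n_min and NaN handling
  z2 <- array(rnorm(5 * 2 * 2), c(5, 2, 2))
  z2[3:5, 1, 1] <- NaN
  g2 <- one_sample_t_map(z2, n_min = 3)
  expect_true(is.nan(g2$t[1, 1]))
  expect_false(is.nan(g2$t[2, 2]))
})

test_that("one_sample_t_map equals scalar t on random stacks", {
  set.seed(31)
  for (i in 1:5) {
    z <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
    z[sample(length(z), 10)] <- NaN
    g <- one_sample_t_map(z, n_min = 3)
    for (a in 1:3) for (b in 1:3) {
      x <- z[, a, b]
      if (sum(is.finite(x)) >= 3) {
        o <- scalar_t(x)
        expect_equal(g$t[a, b], o$t, tolerance = 1e-10)
        expect_equal(g$p[a, b], o$p, tolerance = 1e-10)
      }
    }
  }
})

test_that("bh_fdr matches the brute-force step-up and p.adjust", {
  expect_false(any(bh_fdr(rep(1, 20), 0.05)$mask))
  expect_true(bh_fdr(0.001, 0.01)$mask)
  set.seed(32)
  for (i in 1:50) {
    m <- sample(5:60, 1)
    p <- runif(m)^sample(1:3, 1)
    p[sample(m, m %/% 10)] <- NaN
    q <- sample(c(0.01, 0.05, 0.1), 1)
    got <- bh_fdr(p, q)
    expect_identical(got$mask, bh_oracle(p, q))
    fin <- is.finite(p)
    expect_equal(got$p_adj[fin], p.adjust(p[fin], "BH"), tolerance = 1e-12)
    # adjusted p monotone in raw-p rank
    o <- order(p[fin])
    expect_true(all(diff(got$p_adj[fin][o]) >= -1e-15))
  }
})

test_that("bh_fdr controls the false-rejection fraction on true nulls", {
  set.seed(33)
  q <- 0.05; m <- 200; reps <- 500
  fdp <- vapply(seq_len(reps), function(i) {
    mask <- bh_fdr(runif(m), q)$mask
    if (any(mask)) 1 else 0   # all nulls: any rejection is a false discovery
  }, 0)
  mc_se <- sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), q + 3 * mc_se)
})

test_that("williams_t handles equality, signs, and degeneracies", {
  expect_equal(williams_t(0.4, 0.4, 0.2, 50)$t, 0)
  expect_equal(williams_t(0.4, 0.4, 0.2, 50)$df, 47)
  expect_gt(williams_t(0.6, 0.3, 0.4, 50)$t, 0)
  expect_lt(williams_t(0.3, 0.6, 0.4, 50)$t, 0)
  expect_error(williams_t(0.4, 0.2, 0.3, 3), "n > 3")
  expect_error(williams_t(0.9, -0.9, 0.9, 50), "incoherent")
  expect_error(williams_t(1.2, 0, 0, 50), "\\[-1, 1\\]")
  expect_equal(steiger_z(0.4, 0.4, 0.2, 50)$z, 0)
})

test_that("williams_t is calibrated under a trivariate-normal null", {
  # reduced-rep sanity version of the acceptance calibration
  set.seed(34)
  reps <- 800; n <- 100
  S <- matrix(c(1, .3, .3, .3, 1, .5, .3, .5, 1), 3)
  L <- chol(S)
  rej <- vapply(seq_len(reps), function(i) {
    X <- matrix(rnorm(n * 3), n) %*% L
    r <- cor(X)
    w <- williams_t(r[1, 2], r[1, 3], r[2, 3], n)
    2 * pt(-abs(w$t), w$df) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("dependent comparison map behaves at the null and degenerates", {
  set.seed(35)
  S <- 12; n <- 8
  maps_a <- maps_b <- r23 <- vector("list", S)
  for (s in seq_len(S)) {
    # both channels generated identically (same population)
    X <- matrix(rnorm(200), 200)
    maps_a[[s]] <- matrix(cor(X[1:100], X[101:200]) + rnorm(n * n, 0, 0.1),
                          n, n)
    maps_b[[s]] <- maps_a[[s]] + rnorm(n * n, 0, 0.1)
    maps_a[[s]][] <- pmin(0.9, pmax(-0.9, maps_a[[s]]))
    maps_b[[s]][] <- pmin(0.9, pmax(-0.9, maps_b[[s]]))
    r23[[s]] <- matrix(0.5, n, n)
  }
  cmp <- dependent_comparison_map(maps_a, maps_b, r23, rep(200, S), q = 0.05)
  expect_lte(mean(cmp$q_mask), 0.05)
  expect_equal(dim(cmp$group$t), c(n, n))
  expect_error(dependent_comparison_map(maps_a[1], maps_b[1], r23[1], 200),
               "2 subjects")
})

test_that("upper_lower_test contrasts the window halves", {
  set.seed(36)
  # odd-sized map: exact mirror about the excluded center row
  sym <- matrix(rnorm(71 * 71, 0, 0.1), 71, 71)
  sym[37:71, ] <- sym[35:1, ]
  r <- upper_lower_test(sym)
  expect_equal(r$t, 0)
  shifted <- matrix(rnorm(70 * 70, 0, 0.05), 70, 70)
  shifted[1:35, ] <- shifted[1:35, ] - 0.2
  r2 <- upper_lower_test(shifted)
  expect_lt(r2$t, 0)
  expect_lt(r2$p, 0.01)
  bad <- shifted; bad[1:35, ] <- NaN
  expect_error(upper_lower_test(bad), "insufficient")
})
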