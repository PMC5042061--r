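test_that("OLS reproduces exact and hand-computed small fits", {
  exact <- suppressWarnings(ols_fit(c(0, 1, 2), c(1, 3, 5)))
  expect_equal(unname(coef(exact)), c(1, 2))
  expect_equal(exact$r_squared, 1)
  flat <- suppressWarnings(ols_fit(c(1, 2, 3), c(2, 2, 2)))
  expect_equal(unname(coef(flat)[2]), 0)
  expect_equal(flat$r_squared, 0)
  # 4-point case against the closed-form least-squares oracle
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  sxx <- sum((x - mean(x))^2); syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  fit <- ols_fit(x, y)
  expect_equal(unname(coef(fit)[2]), sxy / sxx)            # 0.6
  expect_equal(unname(coef(fit)[1]), mean(y) - sxy / sxx * mean(x))  # 1.0
  expect_equal(fit$r_squared, sxy^2 / (sxx * syy))          # 0.36
  expect_equal(unname(coef(fit)), c(1, 0.6))
})

test_that("OLS agrees with the closed-form simple-regression solution on random draws", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- 0.3 + 0.7 * x + rnorm(n)
    fit <- ols_fit(x, y)
    b1 <- cov(x, y) / var(x); b0 <- mean(y) - b1 * mean(x)
    expect_equal(unname(coef(fit)), c(b0, b1), tolerance = 1e-10)
    expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-10)
    expect_equal(fit$adj_r_squared,
                 1 - (1 - fit$r_squared) * (n - 1) / (n - 2),
                 tolerance = 1e-12)
  }
})

test_that("OLS reporting keeps negative adjusted R^2 and flags rank deficiency", {
  set.seed(9)
  x <- data.frame(a = rnorm(8), b = rnorm(8), c = rnorm(8))
  fit <- ols_fit(x, rnorm(8))
  expect_lt(fit$adj_r_squared, fit$r_squared)
  expect_lt(fit$adj_r_squared, 0)  # pure noise, tiny n: must not be clipped
  x$d <- x$a + x$b
  expect_error(ols_fit(x, rnorm(8)), "collinear.*d")
  expect_error(ols_fit(data.frame(a = rnorm(3), b = rnorm(3)), rnorm(3)),
               "n > k")
})

test_that("VIF is exactly 1 on orthogonal designs and infinite under duplication", {
  x <- data.frame(a = rep(c(-1, 1), 4), b = rep(c(-1, -1, 1, 1), 2))
  expect_equal(sum(x$a * x$b), 0)  # centered and orthogonal by construction
  expect_equal(unname(vif(x)), c(1, 1))
  dup <- data.frame(a = rnorm(10))
  dup$b <- dup$a
  expect_warning(v <- vif(dup), "collinear")
  expect_true(all(!is.finite(v)))
})

test_that("VIF matches the auxiliary-regression identity and car::vif", {
  set.seed(13)
  n <- 40
  z <- rnorm(n)
  x <- data.frame(a = z + rnorm(n), b = z + rnorm(n), c = z + rnorm(n))
  v <- vif(x)
  for (j in 1:3) {
    r2 <- summary(lm(x[[j]] ~ ., data = x[-j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-10)
  }
  if (requireNamespace("car", quietly = TRUE)) {
    y <- rnorm(n)
    expect_equal(unname(v), unname(car::vif(lm(y ~ a + b + c, data = x))),
                 tolerance = 1e-8)
  }
})

test_that("hierarchical partitioning equals the brute-force ordering average", {
  set.seed(17)
  for (k in 2:5) {
    n <- 30
    x <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(x) <- paste0("p", 1:k)
    x[[2]] <- x[[2]] + 0.8 * x[[1]]          # induce correlation
    y <- rowSums(x[, 1:min(2, k)]) + rnorm(n)
    hp <- hier_part(x, y)
    # oracle: explicit average over all k! entry orderings
    r2 <- function(cols) if (!length(cols)) 0 else
      summary(lm(y ~ ., data = x[, cols, drop = FALSE]))$r.squared
    I <- numeric(k)
    perms <- all_perms(k)
    for (ord in perms) {
      prev <- integer(0)
      for (j in ord) {
        I[j] <- I[j] + r2(c(prev, j)) - r2(prev)
        prev <- c(prev, j)
      }
    }
    I <- I / length(perms)
    expect_equal(hp$partition$independent, I, tolerance = 1e-10)
    # identities: independents sum to the full-model R^2; I + J = marginal R^2
    expect_equal(sum(hp$partition$independent), hp$r_squared_full,
                 tolerance = 1e-10)
    marg <- vapply(1:k, function(j) r2(j), numeric(1))
    expect_equal(hp$partition$independent + hp$partition$joint, marg,
                 tolerance = 1e-10)
    expect_equal(sum(hp$partition$i_pct), 100, tolerance = 1e-8)
  }
})

test_that("partitioning degenerates correctly for one or orthogonal predictors", {
  set.seed(19)
  x1 <- rnorm(25); y <- 2 * x1 + rnorm(25)
  hp1 <- hier_part(data.frame(x = x1), y)
  expect_equal(hp1$partition$independent, ols_fit(x1, y)$r_squared,
               tolerance = 1e-12)
  # exactly orthogonal predictors: no shared variance, J = 0
  a <- rep(c(-1, 1), 10)
  b <- rep(c(-1, -1, 1, 1), 5)
  y2 <- a + 0.5 * b + rnorm(20, sd = 0.2)
  hp2 <- hier_part(data.frame(a = a, b = b), y2)
  marg <- c(ols_fit(a, y2)$r_squared, ols_fit(b, y2)$r_squared)
  expect_equal(hp2$partition$independent, marg, tolerance = 1e-10)
  expect_equal(hp2$partition$joint, c(0, 0), tolerance = 1e-10)
  expect_error(hier_part(data.frame(a = a, b = a), y2), "rank-deficient")
})
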