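test_that("paired t matches the textbook formula and is sign symmetric", {
  d <- c(1, 2, 3)
  cmp <- paired_t(d)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(t_hand, 2 * sqrt(3))
  expect_equal(cmp$p_value, 2 * pt(-t_hand, df = 2), tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.0742, tolerance = 1e-3)
  expect_equal(cmp$estimate, 2)

  neg <- paired_t(-d)
  expect_equal(neg$p_value, cmp$p_value)
  expect_equal(neg$estimate, -cmp$estimate)

  expect_error(paired_t(rep(0.5, 4)), "zero variance")
  expect_error(paired_t(1), ">= 2")
})

test_that("paired t agrees with the formula oracle on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    d <- rnorm(sample(3:20, 1), sd = runif(1, 0.5, 3))
    cmp <- paired_t(d)
    n <- length(d)
    t_hand <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-10)
    half <- qt(0.975, n - 1) * sd(d) / sqrt(n)
    expect_equal(c(cmp$ci_lower, cmp$ci_upper),
                 c(mean(d) - half, mean(d) + half), tolerance = 1e-10)
  }
})

chisq_hand <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

test_that("2x2 chi-square reproduces the hand value for the any-episode table", {
  cmp <- chi_square_2x2(16, 1, 7, 10)
  expect_equal(attr(cmp, "chi_sq"), chisq_hand(16, 1, 7, 10),
               tolerance = 1e-12)
  expect_equal(attr(cmp, "chi_sq"), 10.886, tolerance = 1e-3)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(attr(cmp, "proportions"), c(16 / 17, 7 / 17))

  null <- chi_square_2x2(5, 5, 5, 5)
  expect_equal(attr(null, "chi_sq"), 0)
  expect_equal(null$p_value, 1)

  swapped <- chi_square_2x2(7, 10, 16, 1)
  expect_equal(attr(swapped, "chi_sq"), attr(cmp, "chi_sq"))

  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
  expect_error(chi_square_2x2(1.5, 2, 3, 4), "integer")
})

test_that("chi-square matches the formula oracle on random tables", {
  set.seed(77)
  for (i in 1:60) {
    tab <- rpois(4, lambda = 8) + 1
    cmp <- chi_square_2x2(tab[1], tab[2], tab[3], tab[4])
    x2 <- chisq_hand(tab[1], tab[2], tab[3], tab[4])
    expect_equal(attr(cmp, "chi_sq"), x2, tolerance = 1e-10)
    expect_equal(cmp$p_value, pchisq(x2, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("exact Poisson intervals match the chi-square quantile oracle", {
  ci0 <- poisson_rate_ci(0, 1)
  expect_equal(ci0$ci_lower, 0)
  ci10 <- poisson_rate_ci(10, 1)
  expect_equal(ci10$ci_lower, 4.795, tolerance = 1e-3)
  expect_equal(ci10$ci_upper, 18.39, tolerance = 1e-3)
  # agreement with the base-R exact test across counts
  for (k in c(0, 1, 3, 10, 40)) {
    ours <- poisson_rate_ci(k, 2.5)
    ref <- poisson.test(k, 2.5)$conf.int
    expect_equal(c(ours$ci_lower, ours$ci_upper), as.numeric(ref),
                 tolerance = 1e-8, label = paste("k =", k))
  }
  # doubling exposure halves the rate and both limits
  a <- poisson_rate_ci(10, 1)
  b <- poisson_rate_ci(10, 2)
  expect_equal(b$rate, a$rate / 2)
  expect_equal(b$ci_lower, a$ci_lower / 2)
  expect_equal(b$ci_upper, a$ci_upper / 2)
  expect_error(poisson_rate_ci(-1, 1), "non-negative")
})

test_that("exact Poisson intervals achieve nominal coverage", {
  set.seed(2718)
  for (lambda in c(0.5, 2, 10)) {
    k <- rpois(2000, lambda)
    covered <- vapply(k, function(ki) {
      ci <- poisson_rate_ci(ki, 1)
      ci$ci_lower <= lambda && lambda <= ci$ci_upper
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  }
})

test_that("rate comparison: ratio arithmetic, null behaviour and zero-event flag", {
  eq <- rate_compare(50, 10, 50, 10)
  expect_equal(eq$estimate, 1)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)

  cmp <- rate_compare(100, 1, 50, 1)
  expect_equal(cmp$estimate, 2)
  z_hand <- log(2) / sqrt(1 / 100 + 1 / 50)
  expect_equal(cmp$p_value, 2 * pnorm(-z_hand), tolerance = 1e-12)

  z0 <- rate_compare(0, 1, 5, 1)
  expect_true(grepl("unbounded", z0$note))
  expect_true(is.na(z0$ci_lower))
  expect_error(rate_compare(5, 0, 5, 1), "exposure")
})

test_that("the rate-ratio z test holds its type-I error under a Poisson null", {
  set.seed(1234)
  n_rep <- 1000
  rejections <- vapply(seq_len(n_rep), function(i) {
    k1 <- rpois(1, 60)
    k2 <- rpois(1, 60)
    if (k1 == 0 || k2 == 0) return(FALSE)
    rate_compare(k1, 1, k2, 1)$p_value < 0.05
  }, logical(1))
  alpha_hat <- mean(rejections)
  bound <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(alpha_hat - 0.05), bound + 0.01)
})

test_that("unadjusted regressions collapse to the closed-form estimates", {
  # binary outcome, no covariates: OR equals the cross-product ratio
  df <- data.frame(
    y = rep(c(1, 0, 1, 0), c(16, 1, 7, 10)),
    g = factor(rep(c("low", "high"), c(17, 17)), levels = c("high", "low")))
  cmp <- adjusted_models(df, "y", "g", family = "binomial")
  expect_equal(cmp$estimate, (16 * 10) / (1 * 7), tolerance = 1e-6)

  # Poisson with offset, single binary factor: RR = ratio of observed rates
  pd <- data.frame(k = c(30, 12), g = factor(c("low", "high"),
                                             levels = c("high", "low")),
                   t = c(9.5, 11))
  pc <- adjusted_models(pd, "k", "g", family = "poisson", offset = "t")
  expect_equal(pc$estimate, (30 / 9.5) / (12 / 11), tolerance = 1e-8)
})

test_that("adjusted logistic regression recovers a known group log-odds ratio", {
  set.seed(97)
  true_logor <- 0.7
  ests <- ses <- numeric(20)
  for (r in 1:20) {
    n <- 2000
    g <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    eta <- -0.5 + true_logor * g + 0.4 * x
    y <- rbinom(n, 1, plogis(eta))
    df <- data.frame(y = y, g = factor(g), x = x)
    cmp <- adjusted_models(df, "y", "g", covariates = "x",
                           family = "binomial")
    ests[r] <- log(cmp$estimate)
    ses[r] <- (log(cmp$ci_upper) - log(cmp$ci_lower)) / (2 * 1.96)
  }
  se_mean <- mean(ses) / sqrt(20)
  expect_lt(abs(mean(ests) - true_logor), 2 * se_mean + 0.02)
})

test_that("adjustment by covariates orthogonal to group and outcome changes little", {
  set.seed(55)
  n <- 3000
  g <- factor(rbinom(n, 1, 0.5))
  z <- rnorm(n)                       # independent of both g and y|g
  y <- rbinom(n, 1, ifelse(g == 1, 0.4, 0.25))
  df <- data.frame(y = y, g = g, z = z)
  un <- adjusted_models(df, "y", "g", family = "binomial")
  ad <- adjusted_models(df, "y", "g", covariates = "z", family = "binomial")
  expect_equal(log(ad$estimate), log(un$estimate), tolerance = 0.05)
})
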