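test_that("perfect predictions give perfect classification metrics", {
  y <- factor(rep(c("C1", "C2", "C3"), times = c(5, 8, 4)))
  rep_ <- classification_report(y, y, n_boot = 50, seed = 1)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$precision, 1)
  expect_equal(rep_$recall, 1)
  expect_equal(rep_$f1, 1)
  expect_true(all(rep_$per_class$specificity == 1))
})

test_that("a worked confusion matrix reproduces hand counts", {
  # rows = true: [[5,1,0],[1,8,1],[0,1,3]], n = 20
  true <- rep(c("C1", "C2", "C3"), times = c(6, 10, 4))
  pred <- c(rep("C1", 5), "C2",
            "C1", rep("C2", 8), "C3",
            "C2", rep("C3", 3))
  rep_ <- classification_report(true, pred, n_boot = 200, seed = 2)
  expect_equal(rep_$accuracy, 16 / 20)
  expect_equal(rep_$per_class$sensitivity[1L], 5 / 6)
  expect_equal(unname(rep_$confusion["C2", "C3"]), 1)
  # CIs contain the point estimates
  expect_true(all(rep_$ci$lower <= rep_$ci$estimate + 1e-9))
  expect_true(all(rep_$ci$upper >= rep_$ci$estimate - 1e-9))
})

test_that("bootstrap intervals tighten as the sample grows", {
  set.seed(401)
  make <- function(n) {
    y <- factor(sample(c("C1", "C2", "C3"), n, replace = TRUE))
    p <- as.character(y)
    flip <- runif(n) < 0.25
    p[flip] <- sample(c("C1", "C2", "C3"), sum(flip), replace = TRUE)
    classification_report(y, p, n_boot = 300, seed = 5)
  }
  small <- make(100)
  large <- make(1000)
  w <- function(r) diff(unlist(r$ci[r$ci$metric == "accuracy",
                                    c("lower", "upper")]))
  expect_lt(w(large), w(small))
})

test_that("empty or malformed label input is rejected", {
  expect_error(classification_report(character(), character()), "empty")
  expect_error(classification_report(c("C1", "C4"), c("C1", "C1")),
               "C1, C2, C3")
})

test_that("concordance matches hand-enumerated and degenerate cases", {
  expect_equal(concordance_index(c(2, 4, 5), c(1, 1, 0), c(0.9, 0.5, 0.1)),
               1.0)
  expect_equal(concordance_index(c(2, 4, 5), c(1, 1, 0), c(0.1, 0.5, 0.9)),
               0.0)
  expect_equal(concordance_index(c(2, 4, 5), c(1, 1, 0), c(0.4, 0.4, 0.4)),
               0.5)
  expect_error(concordance_index(5, 0, 1), "no comparable pairs")
})

test_that("concordance agrees with pairwise enumeration on random instances", {
  set.seed(402)
  for (r in seq_len(200)) {
    n <- sample(3:50, 1)
    t <- sample(1:20, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6)
    g <- round(rnorm(n), 1)          # induces tied risks
    if (sum(e == 1 & t < max(t)) == 0) next
    ok <- any(outer(t, t, "<") & (e == 1))
    if (!ok) next
    expect_equal(concordance_index(t, e, g), cindex_oracle(t, e, g))
  }
})

test_that("concordance and the reversed ordering sum to one without ties", {
  set.seed(403)
  t <- runif(30)
  e <- rbinom(30, 1, 0.7); e[1] <- 1
  g <- rnorm(30)
  expect_equal(concordance_index(t, e, g) + concordance_index(t, e, -g), 1)
})

test_that("concordance agrees with the survival package on untied data", {
  set.seed(404)
  n <- 150
  t <- runif(n, 1, 100)
  e <- rbinom(n, 1, 0.6); e[1] <- 1
  g <- rnorm(n)
  ours <- concordance_index(t, e, g)
  ref <- survival::concordance(survival::Surv(t, e) ~ g, reverse = TRUE)
  expect_equal(ours, as.numeric(ref$concordance), tolerance = 1e-12)
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km$surv_at(c(0.5, 1, 2)), c(1, 0.5, 0))
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv_at(1), 2 / 3)
  expect_equal(km2$surv_at(3), 0)
  km3 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km3$surv_at(c(0, 1, 5)), c(1, 1, 1))
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("without censoring the estimator equals the empirical survival function", {
  set.seed(405)
  t <- sample(1:30, 200, replace = TRUE)
  km <- kaplan_meier(t, rep(1L, 200))
  grid <- seq(0, 31, by = 0.5)
  expect_equal(km$surv_at(grid),
               vapply(grid, function(u) mean(t > u), numeric(1L)),
               tolerance = 1e-12)
})

test_that("Kaplan-Meier agrees with survfit under censoring", {
  set.seed(406)
  t <- runif(120, 1, 50)
  e <- rbinom(120, 1, 0.6); e[1] <- 1
  km <- kaplan_meier(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  s_ref <- summary(sf, times = km$time)$surv
  expect_equal(km$survival, s_ref, tolerance = 1e-12)
})

test_that("the Brier score hits its closed-form values without censoring", {
  set.seed(407)
  n <- 50
  t <- sample(1:20, n, replace = TRUE)
  e <- rep(1L, n)
  grid <- seq(1, 20, length.out = 40)
  # oracle predictions: S(t|x) = 1{t_i > t} exactly
  s_perfect <- t(vapply(t, function(ti) as.numeric(ti > grid),
                        numeric(length(grid))))
  expect_equal(as.numeric(integrated_brier_score(s_perfect, t, e, grid)), 0)
  s_half <- matrix(0.5, n, length(grid))
  ibs_half <- integrated_brier_score(s_half, t, e, grid)
  expect_equal(as.numeric(ibs_half), 0.25, tolerance = 1e-12)
  expect_equal(unname(attr(ibs_half, "bs")), rep(0.25, length(grid)))
})

test_that("the trapezoid integral is stable under grid refinement", {
  set.seed(408)
  n <- 300
  t <- rexp(n, 0.1)
  e <- rep(1L, n)
  lam <- 0.1
  coarse <- seq(min(t), quantile(t, 0.9), length.out = 100)
  fine <- seq(min(t), quantile(t, 0.9), length.out = 1000)
  surv_at <- function(grid) {
    matrix(rep(exp(-lam * grid), each = n), nrow = n)
  }
  i1 <- as.numeric(integrated_brier_score(surv_at(coarse), t, e, coarse))
  i2 <- as.numeric(integrated_brier_score(surv_at(fine), t, e, fine))
  expect_lt(abs(i1 - i2), 1e-3)
})
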