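test_that("1-D k-means reproduces the worked partition and threshold", {
  v <- c(0.10, 0.12, 0.50, 0.52, 0.95, 0.97)
  cl <- kmeans_1d(v, k = 3, seed = 1)
  expect_equal(cl$cluster, c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(cl$centers, c(0.11, 0.51, 0.96))
  expect_equal(risk_threshold(cl), 0.95)
  # the threshold strictly exceeds everything in the moderate cluster
  expect_gt(risk_threshold(cl), max(cl$values[cl$cluster == 2L]))
})

test_that("k = 1 collapses to the mean and too few distinct values error", {
  v <- c(1, 2, 3, 4)
  cl <- kmeans_1d(v, k = 1, seed = 2)
  expect_equal(cl$centers, mean(v))
  expect_error(kmeans_1d(c(1, 1, 2), k = 3), "distinct values")
})

test_that("cluster assignments are invariant to input order", {
  set.seed(501)
  v <- runif(40)
  a <- kmeans_1d(v, seed = 3)
  perm <- sample(length(v))
  b <- kmeans_1d(v[perm], seed = 3)
  expect_equal(b$cluster[order(perm)], a$cluster)
})

test_that("best-of-restarts matches the exhaustive contiguous-partition oracle", {
  set.seed(502)
  for (r in seq_len(100)) {
    n <- sample(4:12, 1)
    v <- round(runif(n), 3)
    if (length(unique(v)) < 3) next
    cl <- kmeans_1d(v, k = 3, seed = r)
    ours <- sum(vapply(1:3, function(g) {
      x <- v[cl$cluster == g]
      sum((x - mean(x))^2)
    }, numeric(1L)))
    oracle <- contiguous_partition_oracle(v, 3L)
    expect_equal(ours, oracle$ss, tolerance = 1e-9)
  }
})

test_that("expected-mode projection reproduces hand-computed flows", {
  prof <- data.frame(
    patient_id = c("a", "b", "c", "d"),
    class = factor(c("C1", "C1", "C2", "C3"), levels = c("C1", "C2", "C3")),
    H5 = c(0.22, 0.92, 0.01, 2),
    p5 = c(0.2, 0.6, 0.0, 0.9)
  )
  tt <- project_transitions(prof, mode = "expected")
  expect_equal(unname(tt["C1", "C2"]), (0.2 + 0.6) / 4)
  expect_equal(unname(tt["C1", "C1"]), (0.8 + 0.4) / 4)
  expect_equal(unname(tt["C3", "C3"]), 1 / 4)   # top class absorbing
  expect_equal(sum(tt), 1)
})

test_that("degenerate projections behave as expected", {
  prof <- data.frame(
    patient_id = letters[1:6],
    class = factor(rep(c("C1", "C2", "C3"), each = 2),
                   levels = c("C1", "C2", "C3")),
    H5 = rep(0, 6), p5 = rep(0, 6)
  )
  tt <- project_transitions(prof, mode = "expected")
  expect_equal(unname(diag(tt)), as.numeric(table(prof$class) / 6))
  m <- transition_marginals(tt)
  expect_equal(m$from, m$to)

  prof$p5 <- ifelse(prof$class == "C1", 1, 0)
  tt2 <- project_transitions(prof, mode = "expected")
  expect_equal(unname(tt2["C1", "C1"]), 0)
  expect_equal(unname(tt2["C1", "C2"]), 2 / 6)
})

test_that("threshold mode moves exactly the high-risk patients", {
  prof <- data.frame(
    patient_id = letters[1:4],
    class = factor(c("C1", "C2", "C2", "C3"), levels = c("C1", "C2", "C3")),
    H5 = c(0.5, 1.2, 0.3, 3), p5 = 1 - exp(-c(0.5, 1.2, 0.3, 3))
  )
  tt <- project_transitions(prof, mode = "threshold", threshold = 1.0)
  expect_equal(unname(tt["C2", "C3"]), 1 / 4)  # only the H5 = 1.2 patient
  expect_equal(unname(tt["C1", "C2"]), 0)
  expect_error(project_transitions(prof, mode = "nonsense"))
})

test_that("transition tables conserve mass and never flow downward", {
  set.seed(503)
  for (r in 1:20) {
    n <- 50
    cls <- factor(sample(c("C1", "C2", "C3"), n, replace = TRUE),
                  levels = c("C1", "C2", "C3"))
    H5 <- rexp(n, 1)
    rp <- risk_profiles(sprintf("p%02d", 1:n), cls, H5, seed = r)
    tt <- project_transitions(rp)
    expect_equal(sum(tt), 1, tolerance = 1e-9)
    expect_true(all(tt[lower.tri(tt)] == 0))
    expect_equal(unname(transition_marginals(tt)$from),
                 as.numeric(table(cls) / n), tolerance = 1e-9)
  }
})

test_that("Sankey export writes positive flows only and round-trips", {
  prof <- data.frame(
    patient_id = letters[1:6],
    class = factor(rep(c("C1", "C2", "C3"), each = 2),
                   levels = c("C1", "C2", "C3")),
    H5 = rep(0, 6), p5 = rep(0, 6)
  )
  identity_tt <- project_transitions(prof)
  flows <- sankey_export(identity_tt)
  expect_equal(nrow(flows), 3L)
  expect_true(all(flows$source_class == flows$target_class))
  expect_equal(sum(flows$flow), 1)

  prof$p5 <- c(0.4, 0.1, 0.3, 0.2, 0, 0)
  tt <- project_transitions(prof)
  back <- sankey_import(sankey_export(tt))
  expect_equal(unclass(back), unclass(tt), tolerance = 1e-12)
})

test_that("risk profiles expose calibrated probabilities and cluster labels", {
  set.seed(504)
  H5 <- c(rexp(30, 5), 1 + rexp(30, 5), 3 + rexp(30, 5))
  cls <- factor(sample(c("C1", "C2", "C3"), 90, replace = TRUE),
                levels = c("C1", "C2", "C3"))
  rp <- risk_profiles(sprintf("p%03d", 1:90), cls, H5, seed = 6)
  expect_true(all(rp$profiles$p5 >= 0 & rp$profiles$p5 <= 1))
  expect_equal(rp$profiles$p5, 1 - exp(-rp$profiles$H5))
  expect_identical(levels(rp$profiles$risk_cluster),
                   c("low", "moderate", "high"))
  expect_true(all(rp$profiles$H5[rp$profiles$risk_cluster == "high"] >=
                    rp$threshold))
})

test_that("yearly distributions sum to one and track the latent truth", {
  cfg <- sim_config(n_patients = 3000, seed = 12)
  reg <- simulate_registry(cfg)
  cases <- find_cases(reg$prescriptions, reg$admissions, reg$outpatients)
  excl <- apply_exclusions(cases, reg$demographics)
  feats <- build_features(excl$included, reg$prescriptions, reg$admissions,
                          reg$outpatients)
  labs <- label_cohort(feats, reg$clinical_edss)
  clf <- train_classifier(feats, labs, classifier_config(epochs = 60,
                                                         seed = 1))
  yearly <- yearly_distribution(clf, excl$included, reg$prescriptions,
                                reg$admissions, reg$outpatients,
                                years = 2016:2021)
  expect_equal(rowSums(yearly[, c("C1", "C2", "C3")]),
               rep(1, nrow(yearly)), tolerance = 1e-9)
  pop <- reg$population
  for (i in seq_len(nrow(yearly))) {
    ws <- as.Date(sprintf("%d-01-01", yearly$year[i]))
    ids <- excl$included$patient_id[excl$included$entry_date <= ws]
    sub <- pop[pop$patient_id %in% ids, ]
    true_mix <- as.numeric(table(factor(latent_class_on(sub,
                                                        add_months(ws, 6L)),
                                        1:3)) / nrow(sub))
    pred_mix <- as.numeric(yearly[i, c("C1", "C2", "C3")])
    expect_lt(max(abs(pred_mix - true_mix)), 0.05)
  }
  expect_warning(
    yearly_distribution(clf, excl$included, reg$prescriptions,
                        reg$admissions, reg$outpatients, years = 2040),
    "no active patients")
})
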