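make_labelled_table <- function(n_per_class, mu_stress, mu_relax, sd = 1,
                                users = "P01", seed = 1) {
  set.seed(seed)
  rows <- lapply(users, function(u) {
    n <- n_per_class
    data.frame(
      participant_id = u,
      task_id = rep(c("T1", "T2"), each = n),
      window_start_s = seq_len(2 * n) * 10,
      label = rep(c("stress", "relax"), each = n),
      A1 = c(rnorm(n, mu_stress, sd), rnorm(n, mu_relax, sd)),
      A2 = rnorm(2 * n), A3 = rnorm(2 * n), B1 = rnorm(2 * n),
      B2 = rnorm(2 * n), C1 = rnorm(2 * n), C2 = rnorm(2 * n),
      C3 = rnorm(2 * n), D1 = runif(2 * n, 0, 25), D2 = runif(2 * n, 0, 25))
  })
  feature_table(do.call(rbind, rows))
}

test_that("ground-truth labelling keeps only condition-consistent tasks", {
  ses <- generate_session(2)
  ft <- suppressMessages(
    extract_features(ses$insole, ses$ankle, ses$meta, default_layout()))
  meta <- session_meta("P02", ses$meta$segments,
                       data.frame(task_id = c("T1", "T2", "T3", "T4"),
                                  stress = c(5L, 5L, 4L, 2L)))
  lab <- suppressMessages(label_windows(ft, meta))
  # stress task rated 5 kept; relax task rated 5 dropped; rating 4 dropped;
  # relax task rated 2 kept
  expect_setequal(unique(lab$task_id), c("T1", "T4"))

  # missing rating excludes the task
  meta2 <- session_meta("P02", ses$meta$segments,
                        data.frame(task_id = c("T1", "T2", "T4"),
                                   stress = c(6L, 2L, 1L)))
  lab2 <- suppressMessages(label_windows(ft, meta2))
  expect_false("T3" %in% lab2$task_id)
})

test_that("1-D LDA places the boundary at the midpoint of separated classes", {
  # two well-separated Gaussians, delta mu = 4 sd
  tab <- make_labelled_table(500, mu_stress = 4, mu_relax = 0, sd = 1,
                             seed = 42)
  m <- fit_lda(tab, "A1", zscore = FALSE)
  # scan for the decision boundary on a fine grid
  grid <- data.frame(A1 = seq(0, 4, by = 0.001))
  pred <- predict(m, grid)
  boundary <- grid$A1[max(which(pred$label == "relax"))]
  expect_equal(boundary, 2, tolerance = 0.1 / 2)  # midpoint +/- 0.1 sd

  # identical class distributions: training accuracy near chance
  null_tab <- make_labelled_table(500, 0, 0, seed = 43)
  m0 <- fit_lda(null_tab, "A1")
  acc0 <- mean(predict(m0, null_tab)$label == null_tab$label)
  expect_gt(acc0, 0.4)
  expect_lt(acc0, 0.6)

  # planted 4-feature synthetic data at large effect: near-perfect training
  tab4 <- suppressMessages(generate_cohort_table(5, n_users = 3,
                                                 task_plan = plan_with_windows(8)))
  m4 <- fit_lda(tab4, c("A1", "B2", "C3", "D1"))
  expect_gte(100 * mean(predict(m4, tab4)$label == tab4$label), 95)
})

test_that("prediction agrees with an independent Gaussian-Bayes oracle", {
  tab <- make_labelled_table(200, 1.5, 0, seed = 7)
  m <- fit_lda(tab, c("A1", "B2"), zscore = FALSE)
  set.seed(8)
  newdata <- data.frame(A1 = rnorm(100, 0.75, 2), B2 = rnorm(100, 0, 2))
  got <- predict(m, newdata)
  # brute-force Bayes rule under the fitted Gaussians: density ratio with
  # the pooled covariance, computed without the discriminant algebra
  dens <- function(x, mu, sigma) {
    d <- x - mu
    exp(-0.5 * sum(d * solve(sigma, d))) / sqrt((2 * pi)^2 * det(sigma))
  }
  oracle <- vapply(seq_len(nrow(newdata)), function(i) {
    x <- as.numeric(newdata[i, c("A1", "B2")])
    ps <- m$priors[1] * dens(x, m$means["stress", ], m$sigma)
    pr <- m$priors[2] * dens(x, m$means["relax", ], m$sigma)
    if (ps > pr) "stress" else "relax"
  }, character(1))
  expect_identical(got$label, oracle)

  # row at a class mean classifies to that class
  at_mean <- as.data.frame(t(m$means["stress", ]))
  expect_identical(predict(m, at_mean)$label, "stress")
  # exact posterior tie resolves to relax: symmetric hand-built model,
  # query at the midpoint
  m_tie <- m
  m_tie$priors <- c(0.5, 0.5)
  m_tie$means <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE,
                        dimnames = list(c("stress", "relax"),
                                        c("A1", "B2")))
  m_tie$sigma <- diag(2)
  m_tie$sigma_inv <- diag(2)
  expect_identical(predict(m_tie, data.frame(A1 = 0, B2 = 0))$label, "relax")

  # missing feature is named in the error
  expect_error(predict(m, data.frame(A1 = 1)), "B2")
})

test_that("degenerate covariance triggers logged ridge regularisation", {
  tab <- make_labelled_table(50, 1, 0, seed = 3)
  tab$B1 <- tab$A1  # perfectly collinear pair
  expect_message(fit_lda(tab, c("A1", "B1")), "ridge")
})

test_that("leave-one-user-out holds the tested user out of training", {
  expect_error(assert_fold_disjoint(c("P01", "P02"), "P01"), "P01")
  expect_silent(assert_fold_disjoint(c("P01", "P02"), "P03"))

  tab <- suppressMessages(generate_cohort_table(6, n_users = 4,
                                                task_plan = plan_with_windows(6)))
  rep <- suppressMessages(leave_one_user_out(tab, c("A1", "C3")))
  expect_identical(sort(rep$per_user$participant_id),
                   sort(unique(tab$participant_id)))
  expect_true(all(rep$per_user$accuracy >= 0 & rep$per_user$accuracy <= 100))
  expect_gte(rep$sd_accuracy, 0)
  expect_true(all(diff(rep$curve$window_index) > 0))
  expect_error(leave_one_user_out(tab[tab$participant_id %in%
                                        c("P01", "P02"), ], "A1"),
               "at least 3")
})

test_that("separation test handles degenerate pairings explicitly", {
  expect_equal(separation_test(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7)), 1)
  set.seed(10)
  d <- 0.3 + rnorm(8, 0, 0.005)
  base <- runif(8, 0.2, 0.4)
  expect_lt(separation_test(base + d, base), 0.001)
  expect_true(is.na(suppressMessages(separation_test(c(1, 2), c(0, 1)))))
  expect_equal(suppressMessages(separation_test(rep(1, 5), rep(0.6, 5))), 0)
})

test_that("separation p-values are calibrated under the null", {
  set.seed(20)
  reps <- 200
  p <- replicate(reps, {
    s <- rnorm(8, 0.5, 0.1)
    r <- rnorm(8, 0.5, 0.1)
    separation_test(s, r)
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the model grid ranks planted-signal features first", {
  # signal only in C3: its singleton must outrank D1's
  prof <- stress_profile(forefoot_gain = 1, cop_shift_mm = 0,
                         posture_delta_g = 0.3, tap_prob = 0)
  tab <- suppressMessages(generate_cohort_table(9, n_users = 4,
                                                profile = prof,
                                                task_plan = plan_with_windows(6)))
  grid <- suppressMessages(model_grid(tab, subsets = list(
    C3 = "C3", D1 = "D1", ALL = FEATURE_NAMES)))
  rank_of <- function(m) which(grid$summary$model == m)
  expect_lt(rank_of("C3"), rank_of("D1"))
  expect_gte(grid$reports$C3$mean_accuracy, 85)
  expect_true(all(c("mean_accuracy", "sd_accuracy", "p_separation") %in%
                    names(grid$summary)))

  # duplicate features in a subset are rejected
  expect_error(leave_one_user_out(tab, c("A1", "A1")), "duplicate")
})

test_that("the discriminant agrees with an independent reference LDA", {
  # z-scoring is affine, so the decision rule must match a reference
  # implementation fitted on the raw features with the same priors
  tab <- suppressMessages(generate_cohort_table(13, n_users = 3,
                                                task_plan = plan_with_windows(6)))
  feats <- c("A1", "B2", "C3", "D1")
  ours <- predict(fit_lda(tab, feats), tab)$label
  ref <- MASS::lda(as.matrix(tab[, feats]),
                   grouping = factor(tab$label, c("stress", "relax")))
  theirs <- as.character(predict(ref, as.matrix(tab[, feats]))$class)
  expect_gte(mean(ours == theirs), 0.99)
})
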