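random_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(mean_given_energy = runif(n),
             mean_correlation = runif(n, -1, 1),
             time_period = sample(100:5000, n, replace = TRUE))
}

test_that("PC1 scores match a direct eigendecomposition", {
  for (seed in 1:5) {
    ft <- random_feature_table(10, seed)
    scores <- pca_first_component(ft)
    x <- scale(as.matrix(ft))
    eig <- eigen(crossprod(x) / (nrow(x) - 1))
    v <- eig$vectors[, 1]
    if (v[1] < 0) v <- -v  # same sign convention: given_energy loading >= 0
    expect_equal(unname(as.numeric(scores)), unname(as.vector(x %*% v)),
                 tolerance = 1e-8)
  }
})

test_that("PC1 captures all retained variance in the rank-1 case", {
  n <- 20
  g <- runif(n)
  ft <- data.frame(mean_given_energy = g, mean_correlation = 2 * g - 1,
                   time_period = rep(1000, n))
  expect_warning(scores <- pca_first_component(ft), "time_period")
  expect_equal(attr(scores, "explained"), 1)
})

test_that("PC1 magnitudes are invariant to response sign flips", {
  ft <- random_feature_table(15, 3)
  s1 <- pca_first_component(ft)
  ft2 <- ft
  ft2$mean_correlation <- -ft2$mean_correlation
  s2 <- pca_first_component(ft2)
  expect_equal(abs(as.numeric(s1)), abs(as.numeric(s2)), tolerance = 1e-10)
})

test_that("PCA refuses degenerate tables", {
  expect_error(pca_first_component(random_feature_table(1)), "two rows")
  ft <- data.frame(mean_given_energy = rep(1, 5),
                   mean_correlation = rep(0, 5), time_period = rep(1, 5))
  expect_warning(expect_error(pca_first_component(ft), "constant"))
})

planted_predictors <- function(n, seed) {
  set.seed(seed)
  data.frame(n_people = sample(100:500, n, TRUE),
             prob_resource = runif(n), min_energy = runif(n),
             sharing_tournament_size = runif(n),
             strategy_tournament_size = runif(n, 0.01, 1),
             prob_mutation = runif(n, 0.01, 1),
             rounds_per_generation = sample(10:50, n, TRUE))
}

test_that("importance normalizes to one and recovers a planted signal", {
  x <- planted_predictors(300, 1)
  y <- sin(pi * x$prob_resource) + rnorm(300, sd = 0.05)
  set.seed(2)
  imp <- variable_importance(x, y, n_trees = 300)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$parameter[1], "prob_resource")
  expect_gt(imp$importance[1], 0.8)
})

test_that("planted signals are recovered across repeated seeds", {
  hits <- vapply(1:20, function(s) {
    x <- planted_predictors(150, 100 + s)
    y <- x$min_energy^2 + rnorm(150, sd = 0.05)
    set.seed(s)
    imp <- variable_importance(x, y, n_trees = 150)
    imp$parameter[1] == "min_energy"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pure noise produces no dominant parameter on average", {
  x <- planted_predictors(200, 7)
  imps <- sapply(1:5, function(s) {
    set.seed(s)
    y <- rnorm(200)
    imp <- variable_importance(x, y, n_trees = 300)
    imp$importance[match(names(x), imp$parameter)]
  })
  avg <- rowMeans(imps)
  expect_lte(max(avg), 2 * min(avg))
})

test_that("permutation importance is also normalized and nonnegative", {
  x <- planted_predictors(200, 8)
  y <- x$prob_resource + rnorm(200, sd = 0.1)
  set.seed(3)
  imp <- variable_importance(x, y, n_trees = 300,
                             method = "permutation_oob")
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_true(all(imp$importance >= 0))
  expect_identical(imp$parameter[1], "prob_resource")
})

test_that("the CV grid search returns the minimizing combination", {
  x <- planted_predictors(80, 9)
  y <- x$prob_resource + rnorm(80, sd = 0.1)
  set.seed(4)
  one <- cv_grid_search(x, y, n_trees_grid = 100, max_features_grid = 3)
  expect_equal(one$n_trees, 100)
  expect_equal(one$max_features, 3)
  expect_equal(nrow(one$cv), 1)

  set.seed(5)
  cv <- cv_grid_search(x, y, n_trees_grid = c(50, 100),
                       max_features_grid = c(2, 4), folds = 5)
  expect_equal(nrow(cv$cv), 4)
  expect_equal(min(cv$cv$mse),
               cv$cv$mse[cv$cv$n_trees == cv$n_trees &
                         cv$cv$max_features == cv$max_features])
  # selection consistency: under a fresh seed the chosen pair stays within
  # one standard error of the global minimum
  set.seed(6)
  cv2 <- cv_grid_search(x, y, n_trees_grid = c(50, 100),
                        max_features_grid = c(2, 4), folds = 5)
  chosen <- cv2$cv$mse[cv2$cv$n_trees == cv$n_trees &
                       cv2$cv$max_features == cv$max_features]
  expect_lte(chosen, min(cv2$cv$mse) + cv2$cv$se[which.min(cv2$cv$mse)])
})

test_that("CV refuses fewer rows than folds", {
  x <- planted_predictors(5, 10)
  expect_error(cv_grid_search(x, rnorm(5), 100, 2, folds = 10), "folds")
})

test_that("the published hyperparameter grids contain the printed optimum", {
  g <- rf_grid()
  expect_true(800 %in% g$n_trees)
  expect_true(5 %in% g$max_features)
  expect_length(g$n_trees, 8)
  expect_length(g$max_features, 6)
})

test_that("the state-space KDE integrates to one and finds planted modes", {
  set.seed(11)
  tr <- make_trace(pmin(pmax(rnorm(600, 0.5, 0.01), 0), 1),
                   pmin(pmax(rnorm(600, 0.5, 0.01), -1), 1))
  d <- kde_state_space(tr, burn_in = 0)
  expect_false(d$point_mass)
  dx <- diff(d$given_energy[1:2]); dy <- diff(d$correlation[1:2])
  expect_equal(sum(d$density) * dx * dy, 1, tolerance = 0.02)
  expect_true(all(d$density >= 0))
  mode <- density_mode(d)
  expect_lt(abs(mode["given_energy"] - 0.5), 0.05)
  expect_lt(abs(mode["correlation"] - 0.5), 0.05)
})

test_that("uniform samples give a flat interior density", {
  set.seed(12)
  tr <- make_trace(runif(4000), runif(4000, -1, 1))
  d <- kde_state_space(tr, burn_in = 0)
  interior <- d$density[d$given_energy >= 0.15 & d$given_energy <= 0.85,
                        d$correlation >= -0.7 & d$correlation <= 0.7]
  expect_lt(max(interior) / min(interior), 3)
})

test_that("identical points degrade to a labelled point mass", {
  tr <- make_trace(rep(0.4, 50), rep(0.1, 50))
  d <- kde_state_space(tr, burn_in = 0)
  expect_true(d$point_mass)
  expect_equal(unname(d$location), c(0.4, 0.1))
})

test_that("burn-in equal to all but one record keeps the final state only", {
  tr <- make_trace(seq(0, 1, length.out = 100), rep(0, 100), rpg = 1)
  post <- trace_after_burn_in(tr, 99)
  expect_equal(nrow(post), 1)
  expect_equal(post$mean_given_energy, 1)
})

test_that("regime labels match their definitions on synthetic traces", {
  # locked on the surplus norm with positive partner bias -> intermediate
  coord <- make_trace(rep(0.5, 400) + rnorm(400, sd = 0.005),
                      rep(0.5, 400))
  r1 <- regime_summary(coord, min_energy = 0.5, burn_in = 0)
  expect_identical(r1$label, "intermediate")

  # white noise spanning the whole space -> high stress
  set.seed(13)
  noisy <- make_trace(runif(400), runif(400, -1, 1))
  r2 <- regime_summary(noisy, min_energy = 0.5, burn_in = 0)
  expect_identical(r2$label, "high_stress")

  # flat trace far from the surplus norm, no positive bias -> low stress
  flat <- make_trace(rep(0.5, 400), rep(-0.2, 400))
  r3 <- regime_summary(flat, min_energy = 0.2, burn_in = 0)
  expect_identical(r3$label, "low_stress")

  # per-replicate labels are reported
  r4 <- regime_summary(list(coord, coord), min_energy = 0.5, burn_in = 0)
  expect_equal(r4$replicates$label, c("intermediate", "intermediate"))
})

test_that("feature tables join designs with traces in both row modes", {
  d <- grid_design(p_values = c(0.4, 0.6), e_values = 0.5, replicates = 1,
                   generations = 20, fixed = desk_params(), master_seed = 9)
  b <- run_batch(d)
  ft <- build_feature_table(d, b$traces)
  expect_equal(nrow(ft), 2)
  expect_equal(ft$time_period, c(200, 200))
  expect_true(all(c("prob_resource", "mean_given_energy",
                    "mean_correlation", "time_period") %in% names(ft)))
  ftp <- build_feature_table(d, b$traces, rows = "period")
  expect_equal(nrow(ftp), 2 * 16)  # 20 generations minus 20% burn-in
  # failed runs are dropped
  traces2 <- b$traces; traces2[[1]] <- NULL
  expect_equal(nrow(build_feature_table(d, traces2)), 1)
})
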