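# small, fast GA settings for unit tests (acceptance uses the defaults)
fast_ga <- function(seed = 1, model_size = 3)
  ga_params(population_size = 40, model_size = model_size,
            max_generations = 60, seed = seed)

test_that("constant, undefined and collinear columns are filtered", {
  set.seed(1)
  x <- rnorm(30)
  tbl <- cbind(A = x, B = x + rnorm(30, sd = 1e-4), C = 3.0,
               D = rnorm(30), E = c(NA, rnorm(29)))
  # duplicate-like pair: keep the higher-variance member
  out <- filter_descriptors(tbl, r2_cut = 0.90)
  expect_false("C" %in% colnames(out))   # constant
  expect_false("E" %in% colnames(out))   # undefined cells
  expect_true("D" %in% colnames(out))
  expect_equal(sum(c("A", "B") %in% colnames(out)), 1)
  # explicit variance rule: r2 = 1, variances 1 vs 4 -> low-variance goes
  tbl2 <- cbind(lo = x, hi = 2 * x, other = rnorm(30))
  out2 <- filter_descriptors(tbl2)
  expect_identical(colnames(out2), c("hi", "other"))
  expect_error(filter_descriptors(cbind(k = rep(1, 10))), "no informative")
})

test_that("OLS fit statistics behave and recover planted coefficients", {
  set.seed(7)
  X <- matrix(rnorm(52 * 3), 52, 3, dimnames = list(NULL, c("a", "b", "c")))
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta) + 1
  m <- fit_mlr(X, y)                       # exact linear data
  expect_equal(m$r2, 1)
  expect_equal(m$s, 0, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), beta)
  expect_equal(m$intercept, 1)

  yr <- rnorm(52)                          # pure noise, 1 regressor
  m0 <- fit_mlr(X[, 1, drop = FALSE], yr)
  expect_lt(m0$r2, 0.15)
  expect_gt(m0$p_value, 0.01)

  sim <- gen_planted_qsar(planted_qsar_spec(noise_sd = 0.05, seed = 3))
  mt <- fit_mlr(sim$table[, sim$truth$descriptors], sim$y)
  se <- sqrt(diag(solve(crossprod(
    cbind(1, sim$table[, sim$truth$descriptors]))))) * mt$s
  expect_true(all(abs(mt$coefficients - sim$truth$coefficients) <=
                    3 * se[-1]))

  expect_error(fit_mlr(cbind(a = X[, 1], b = X[, 1]), y), "rank-deficient")
})

test_that("LOO shortcut is identical to the explicit refit loop", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(15:40, 1); k <- sample(1:4, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    y <- drop(X %*% runif(k, -2, 2)) + rnorm(n, sd = 0.5)
    got <- loo_q2(X, y)
    want <- oracle_loo(X, y)
    expect_equal(got$q2, want$q2, tolerance = 1e-10)
    expect_equal(got$s_cv, want$s_cv, tolerance = 1e-10)
  }
})

test_that("Q2 limits: near 1 for noiseless data, <= 0 for permuted responses", {
  sim <- gen_planted_qsar(planted_qsar_spec(noise_sd = 0, seed = 9))
  X <- sim$table[, sim$truth$descriptors]
  expect_gt(loo_q2(X, sim$y)$q2, 0.999)
  expect_lte(loo_q2(X, sim$y)$q2, fit_mlr(X, sim$y)$r2)  # Q2 <= R2

  q2s <- vapply(1:20, function(s) {
    yp <- with(list(), { set.seed(s); sample(sim$y) })
    loo_q2(X, yp)$q2
  }, numeric(1))
  expect_lt(mean(q2s), 0)
})

test_that("GA selection finds planted signal, is deterministic, validates input", {
  set.seed(11)
  n <- 40
  tbl <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, sprintf("d%02d", 1:20)))
  y <- drop(tbl[, c(3, 8, 15)] %*% c(2, -1.5, 1)) + rnorm(n, sd = 0.1)
  m <- ga_select(tbl, y, fast_ga(seed = 2))
  expect_setequal(m$descriptor_names, c("d03", "d08", "d15"))
  m2 <- ga_select(tbl, y, fast_ga(seed = 2))
  expect_identical(m$descriptor_names, m2$descriptor_names)
  expect_identical(m$coefficients, m2$coefficients)

  # model_size 1 with a single informative column
  y1 <- 3 * tbl[, "d05"] + rnorm(n, sd = 0.05)
  m1 <- ga_select(tbl, y1, fast_ga(seed = 4, model_size = 1))
  expect_equal(m1$descriptor_names, "d05")

  expect_error(ga_params(population_size = 2, tournament_size = 5),
               "tournament")
  expect_error(ga_select(tbl[1:12, ], y[1:12], fast_ga(model_size = 3)),
               "n_train/5")
})

test_that("GA best fitness is monotone non-increasing and terminates", {
  set.seed(21)
  tbl <- matrix(rnorm(40 * 15), 40, 15,
                dimnames = list(NULL, sprintf("d%02d", 1:15)))
  y <- drop(tbl[, c(2, 9)] %*% c(1, -1)) + rnorm(40, sd = 0.2)
  m <- ga_select(tbl, y, ga_params(population_size = 30, model_size = 2,
                                   convergence_fraction = 1,
                                   max_generations = 500, seed = 5))
  expect_true(all(diff(m$ga$best_fitness) <= 1e-12))
  expect_lte(m$ga$generations, 500)
})

test_that("prediction applies the linear model and checks columns", {
  m <- eq1_model()
  z <- matrix(0, 3, 6, dimnames = list(NULL, m$descriptor_names))
  expect_equal(unname(predict(m, z)), rep(-12.7, 3))
  expect_error(predict(m, z[, -2]), "MATS1e")

  sim <- gen_planted_qsar(planted_qsar_spec(noise_sd = 0.1, seed = 13))
  X <- sim$table[, sim$truth$descriptors]
  mf <- fit_mlr(X, sim$y)
  expect_equal(unname(predict(mf, X)), mf$fitted, tolerance = 1e-10)
  expect_equal(mf$fitted + mf$residuals, sim$y, tolerance = 1e-10)
})

test_that("squared_pearson validates input and matches cor()^2", {
  a <- c(1, 2, 3, 5); b <- c(2, 1, 4, 4)
  expect_equal(squared_pearson(a, b), cor(a, b)^2)
  expect_equal(squared_pearson(a, a), 1)
  expect_error(squared_pearson(a, rep(1, 4)), "constant")
})

test_that("residual analysis bins and sorts as specified", {
  rec <- data.frame(id = c("x", "y", "z", "w"),
                    exp_log_inv_ic50 = c(0, 1, 2, 3),
                    pred_log_inv_ic50 = c(0.4, 1.6, 2.8, 4.2),
                    is_test = c(FALSE, FALSE, FALSE, TRUE))
  ra <- residual_analysis(rec, "train")
  expect_equal(as.integer(ra$bins), c(1L, 1L, 1L, 0L))
  expect_equal(ra$residuals$id, c("z", "y", "x"))  # sorted descending
  rec$pred_log_inv_ic50 <- rec$exp_log_inv_ic50
  expect_true(all(residual_analysis(rec, "all")$residuals$abs_residual == 0))
})

test_that("y_scramble degrades fit quality and is reproducible", {
  sim <- gen_planted_qsar(planted_qsar_spec(n_compounds = 40,
                                            n_descriptors = 15, k_true = 3,
                                            noise_sd = 0.1, seed = 17))
  set.seed(17); tr <- sort(sample(40, 32))
  params <- fast_ga(seed = 1)
  true_fit <- ga_select(filter_descriptors(sim$table[tr, ]), sim$y[tr], params)
  sc <- y_scramble(sim$table, sim$y, tr, n_replicas = 3, params = params,
                   seed = 5)
  expect_equal(nrow(sc), 3)
  expect_lt(mean(sc$q2), true_fit$q2_loo - 0.3)      # clear deterioration
  expect_lt(mean(sc$r2_test, na.rm = TRUE), 0.5)
  sc2 <- y_scramble(sim$table, sim$y, tr, n_replicas = 3, params = params,
                    seed = 5)
  expect_identical(sc, sc2)
  expect_equal(nrow(y_scramble(sim$table, sim$y, tr, n_replicas = 0)), 0)
})

test_that("replicate splits keep sizes, average sensibly, reproduce per seed", {
  sim <- gen_planted_qsar(planted_qsar_spec(n_compounds = 40,
                                            n_descriptors = 15, k_true = 3,
                                            noise_sd = 0.1, seed = 19))
  params <- fast_ga(seed = 1)
  rs <- replicate_splits(sim$table, sim$y, n_replicas = 3, n_test = 8,
                         params = params, seed = 23)
  expect_equal(nrow(rs), 3)
  av <- attr(rs, "averages")
  expect_true(all(is.finite(av)))
  expect_gt(av[["r2"]], 0.9)  # strong planted signal survives resplitting
  rs2 <- replicate_splits(sim$table, sim$y, n_replicas = 3, n_test = 8,
                          params = params, seed = 23)
  expect_equal(rs, rs2)
})

test_that("recovered Q2 decreases with the planted noise level", {
  q2_at <- function(noise) {
    sim <- gen_planted_qsar(planted_qsar_spec(noise_sd = noise, seed = 29))
    tr <- 1:52
    loo_q2(sim$table[tr, sim$truth$descriptors], sim$y[tr])$q2
  }
  expect_gt(q2_at(0.05), q2_at(0.3))
})
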