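## qsar: descriptor filtering, GA-MLR variable selection, internal and
## external validation, residual analysis, replicate splits, Y-scrambling.

new_qsar_model <- function(descriptor_names, coefficients, intercept, n_train,
                           r2, s, f_stat, p_value, q2_loo = NA_real_,
                           s_cv = NA_real_, fitted = NULL, residuals = NULL,
                           source = "fitted", ga = NULL) {
  stopifnot(length(coefficients) == length(descriptor_names))
  structure(list(descriptor_names = descriptor_names,
                 coefficients = setNames(coefficients, descriptor_names),
                 intercept = intercept, n_train = n_train, r2 = r2, s = s,
                 f_stat = f_stat, p_value = p_value, q2_loo = q2_loo,
                 s_cv = s_cv, fitted = fitted, residuals = residuals,
                 source = source, ga = ga),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, digits = 3, ...) {
  cat("<qsar_model> (", x$source, ") ", length(x$coefficients),
      " descriptors, N = ", x$n_train, "\n", sep = "")
  cat("  log(1/IC50) =",
      paste(sprintf("%+.3g x %s", x$coefficients, x$descriptor_names),
            collapse = " "),
      sprintf("%+.3g", x$intercept), "\n")
  cat(sprintf("  R2 = %.3f, s = %.3f, F = %.3g, p = %.3g", x$r2, x$s,
              x$f_stat, x$p_value))
  if (is.finite(x$q2_loo))
    cat(sprintf(", Q2(LOO) = %.3f, s_cv = %.3f", x$q2_loo, x$s_cv))
  cat("\n")
  invisible(x)
}

#' Drop constant and collinear descriptor columns
#'
#' Columns containing undefined cells (`NA`) or with zero variance are
#' removed first.  Then every pair of surviving columns with squared
#' Pearson correlation above `r2_cut` is resolved greedily, scanning pairs
#' in canonical column order and discarding the lower-variance member
#' (ties broken by column name, the lexicographically later one going).
#'
#' @param tbl numeric matrix (compounds x descriptors) with column names.
#' @param r2_cut collinearity threshold on squared correlation
#'   (default 0.90).
#' @return the filtered matrix.
#' @export
filter_descriptors <- function(tbl, r2_cut = 0.90) {
  tbl <- as.matrix(tbl)
  stopifnot(nrow(tbl) >= 2, !is.null(colnames(tbl)))
  defined <- colSums(is.na(tbl)) == 0L
  vr <- rep(0, ncol(tbl)); vr[defined] <- apply(tbl[, defined, drop = FALSE], 2, var)
  keep <- defined & vr > 1e-12
  if (!any(keep)) stop("no informative descriptors after constant filtering")
  tbl <- tbl[, keep, drop = FALSE]
  vr <- vr[keep]
  p <- ncol(tbl)
  alive <- rep(TRUE, p)
  cm <- suppressWarnings(cor(tbl))
  for (i in seq_len(p - 1L)) {
    if (!alive[i]) next
    for (j in seq.int(i + 1L, p)) {
      if (!alive[j] || !alive[i]) next
      if (!is.na(cm[i, j]) && cm[i, j]^2 > r2_cut) {
        drop <- if (vr[i] < vr[j]) i
                else if (vr[j] < vr[i]) j
                else c(i, j)[order(colnames(tbl)[c(i, j)])[2]]  # later name
        alive[drop] <- FALSE
      }
    }
  }
  out <- tbl[, alive, drop = FALSE]
  if (ncol(out) == 0) stop("no informative descriptors after collinearity filtering")
  out
}

#' Ordinary least squares fit of activities on descriptors
#'
#' @param X numeric matrix (n x k) of descriptor values, with column names.
#' @param y numeric activities, length n.
#' @return a `qsar_model` with coefficients, intercept, `r2`, regression
#'   standard deviation `s` (denominator `n - k - 1`), F statistic and its
#'   p-value (df `k`, `n - k - 1`).
#' @export
fit_mlr <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n >= k + 2)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  if (anyNA(X) || anyNA(y)) stop("undefined cells in regression input")
  Xd <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(Xd, y)
  if (fit$rank < k + 1) stop("rank-deficient descriptor matrix")
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  dfres <- n - k - 1
  s <- sqrt(rss / dfres)
  f <- (r2 / k) / ((1 - r2) / dfres)
  p <- stats::pf(f, k, dfres, lower.tail = FALSE)
  new_qsar_model(colnames(X), unname(fit$coefficients[-1]),
                 unname(fit$coefficients[1]), n, r2, s, f, p,
                 fitted = unname(fit$fitted.values), residuals = unname(res))
}

#' Leave-one-out cross-validation of an OLS model
#'
#' Computes PRESS via the hat-matrix identity (algebraically identical to
#' refitting without each observation), `Q2 = 1 - PRESS/SS_tot` and the
#' cross-validated standard deviation `s_cv` with an `n - k - 1`
#' denominator.
#'
#' @inheritParams fit_mlr
#' @return list with elements `q2` and `s_cv`.
#' @export
loo_q2 <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n >= k + 2)
  if (anyNA(X) || anyNA(y)) stop("undefined cells in regression input")
  Xd <- cbind(1, X)
  qr_ <- qr(Xd)
  if (qr_$rank < k + 1) stop("rank-deficient descriptor matrix")
  res <- qr.resid(qr_, y)
  h <- rowSums(qr.Q(qr_)^2)
  press <- sum((res / (1 - h))^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, s_cv = sqrt(press / (n - k - 1)))
}

#' Genetic-algorithm parameters
#'
#' @param population_size number of chromosomes (default 100).
#' @param model_size number of descriptors per model (default 6).
#' @param tournament_size tournament selection size (default 3).
#' @param crossover_rate probability a child is produced by uniform
#'   crossover of two parents' gene pools rather than cloned (default 0.9).
#' @param mutation_rate probability of a single-point mutation (swap one
#'   descriptor for a random outsider; default 0.3).
#' @param convergence_fraction stop when at least this fraction of the
#'   population shares the best fitness (default 0.90).
#' @param max_generations hard cap on generations (default 150).
#' @param seed RNG seed making the search deterministic.
#' @return a list of class `ga_params`.
#' @export
ga_params <- function(population_size = 100, model_size = 6,
                      tournament_size = 3, crossover_rate = 0.9,
                      mutation_rate = 0.3, convergence_fraction = 0.90,
                      max_generations = 150, seed = 1) {
  stopifnot(population_size >= 2, model_size >= 1,
            convergence_fraction > 0, convergence_fraction <= 1)
  if (population_size < tournament_size)
    stop("population_size must be >= tournament_size")
  structure(list(population_size = population_size, model_size = model_size,
                 tournament_size = tournament_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 convergence_fraction = convergence_fraction,
                 max_generations = max_generations, seed = seed),
            class = "ga_params")
}

#' Genetic-algorithm descriptor subset selection
#'
#' Fixed-size descriptor subsets are evolved with tournament selection,
#' uniform crossover of the parents' gene pools, single-point mutation and
#' one-elite survival.  Fitness is the mean squared error of the OLS fit.
#' The search stops when at least `convergence_fraction` of the population
#' shares the best fitness, or after `max_generations`.  Deterministic for
#' a given `params$seed`.
#'
#' @param tbl filtered descriptor matrix (see [filter_descriptors()]).
#' @param y numeric activities.
#' @param params a [ga_params()] list.
#' @return the `qsar_model` of the best subset (via [fit_mlr()]), with a
#'   `$ga` element recording generations run, convergence and the
#'   best-fitness trajectory.
#' @export
ga_select <- function(tbl, y, params = ga_params()) {
  tbl <- as.matrix(tbl)
  n <- nrow(tbl); p <- ncol(tbl); k <- params$model_size
  stopifnot(length(y) == n, k <= p)
  if (k >= n / 5) stop("model_size must be below n_train/5")
  pop_n <- params$population_size

  fit_cache <- new.env(parent = emptyenv())
  mse <- function(genes) {
    key <- paste(genes, collapse = ",")
    hit <- fit_cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- stats::lm.fit(cbind(1, tbl[, genes, drop = FALSE]), y)
    v <- if (f$rank < k + 1) Inf else mean(f$residuals^2)
    fit_cache[[key]] <- v
    v
  }

  with_seed(params$seed, {
    pop <- replicate(pop_n, sort(sample.int(p, k)), simplify = FALSE)
    fitness <- vapply(pop, mse, numeric(1))
    history <- numeric(0)
    converged <- FALSE
    gen <- 0L
    while (gen < params$max_generations) {
      gen <- gen + 1L
      best <- min(fitness)
      history[gen] <- best
      share <- mean(fitness <= best * (1 + 1e-12) + 1e-15)
      if (share >= params$convergence_fraction) { converged <- TRUE; break }
      tournament <- function() {
        cand <- sample.int(pop_n, params$tournament_size)
        pop[[cand[which.min(fitness[cand])]]]
      }
      newpop <- vector("list", pop_n)
      newpop[[1]] <- pop[[which.min(fitness)]]  # elitism
      for (i in 2:pop_n) {
        p1 <- tournament()
        child <- if (runif(1) < params$crossover_rate) {
          pool <- union(p1, tournament())
          if (length(pool) < k) pool <- union(pool, sample.int(p, k))
          sort(sample(pool, k))
        } else p1
        if (runif(1) < params$mutation_rate) {
          out <- setdiff(seq_len(p), child)
          child[sample.int(k, 1)] <- out[sample.int(length(out), 1)]
          child <- sort(child)
        }
        newpop[[i]] <- child
      }
      pop <- newpop
      fitness <- vapply(pop, mse, numeric(1))
    }
    best_genes <- pop[[which.min(fitness)]]
    m <- fit_mlr(tbl[, best_genes, drop = FALSE], y)
    cv <- loo_q2(tbl[, best_genes, drop = FALSE], y)
    m$q2_loo <- cv$q2; m$s_cv <- cv$s_cv
    m$ga <- list(generations = gen, converged = converged,
                 best_fitness = history, seed = params$seed)
    m
  })
}

#' Predict activities from a QSAR model
#'
#' @param object a `qsar_model`.
#' @param newdata matrix or data.frame containing (at least) the model's
#'   descriptor columns.
#' @param ... unused.
#' @return numeric vector of predicted activities.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missing <- setdiff(object$descriptor_names, colnames(newdata))
  if (length(missing) > 0)
    stop("missing descriptor column(s): ", paste(missing, collapse = ", "))
  X <- newdata[, object$descriptor_names, drop = FALSE]
  drop(object$intercept + X %*% object$coefficients)
}

#' The published six-descriptor activity model, as a literal fixture
#'
#' The reported topological activity model for the DPDA series:
#' `log(1/IC50) = 4.76 ATS1m + 32.3 MATS1e + 6.42 MATS7e + 3.07 MATS8e +
#' 14.9 MATS1p - 5.62 GATS5e - 12.7` with N = 52, R2 = 0.674, s = 0.586,
#' F = 15.5, Q2 = 0.549, s_cv = 0.689.  Packaged as a literal model for
#' [predict.qsar_model()]; its coefficients are tied to the original
#' descriptor software's property scaling and are not re-derived here.
#'
#' @return a `qsar_model` with `source = "literature fixture"`.
#' @export
eq1_model <- function() {
  new_qsar_model(
    descriptor_names = c("ATS1m", "MATS1e", "MATS7e", "MATS8e", "MATS1p",
                         "GATS5e"),
    coefficients = c(4.76, 32.3, 6.42, 3.07, 14.9, -5.62),
    intercept = -12.7, n_train = 52, r2 = 0.674, s = 0.586,
    f_stat = 15.5, p_value = 1e-5, q2_loo = 0.549, s_cv = 0.689,
    source = "literature fixture")
}

#' Squared Pearson correlation
#'
#' @param a,b equal-length numeric vectors (length >= 3, both
#'   non-constant).
#' @return the square of the Pearson correlation coefficient.
#' @export
squared_pearson <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) < 1e-12 || sd(b) < 1e-12)
    stop("squared_pearson: constant input")
  cor(a, b)^2
}

#' Residual analysis of experimental versus predicted activities
#'
#' Absolute residuals binned into `[0, 0.5)`, `[0.5, 0.75)`, `[0.75, 1.0)`
#' and `[1.0, Inf)` (half-open, lower edge inclusive), plus the
#' per-compound listing sorted by decreasing residual.
#'
#' @param records data.frame with columns `id`, `exp_log_inv_ic50`,
#'   `pred_log_inv_ic50` and `is_test` (e.g. from [load_paper_dataset()]).
#' @param subset `"train"`, `"test"` or `"all"`.
#' @return list with `residuals` (data.frame `id`, `exp`, `pred`,
#'   `abs_residual`, sorted descending) and `bins` (named integer counts).
#' @export
residual_analysis <- function(records, subset = c("train", "test", "all")) {
  subset <- match.arg(subset)
  d <- switch(subset, train = records[!records$is_test, ],
              test = records[records$is_test, ], all = records)
  r <- abs(d$exp_log_inv_ic50 - d$pred_log_inv_ic50)
  edges <- c(0, 0.5, 0.75, 1.0, Inf)
  bins <- table(cut(r, edges, right = FALSE,
                    labels = c("[0,0.5)", "[0.5,0.75)", "[0.75,1)", "[1,Inf)")))
  res <- data.frame(id = d$id, exp = d$exp_log_inv_ic50,
                    pred = d$pred_log_inv_ic50, abs_residual = r,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$abs_residual), ]
  rownames(res) <- NULL
  list(residuals = res, bins = bins)
}

# One full modelling pass: filter -> GA -> OLS -> LOO -> external test.
qsar_pipeline <- function(tbl, y, train, params = ga_params(),
                          r2_cut = 0.90) {
  tbl <- as.matrix(tbl)
  test <- setdiff(seq_len(nrow(tbl)), train)
  ft <- filter_descriptors(tbl[train, , drop = FALSE], r2_cut = r2_cut)
  m <- ga_select(ft, y[train], params)
  r2_test <- if (length(test) >= 3) {
    pr <- predict(m, tbl[test, colnames(ft), drop = FALSE])
    squared_pearson(pr, y[test])
  } else NA_real_
  list(model = m, r2 = m$r2, q2 = m$q2_loo, r2_test = r2_test,
       selected = m$descriptor_names)
}

#' Y-scrambling (response randomization) test
#'
#' Permutes the activity vector and reruns the full selection + fit +
#' validation pipeline per replica; a real structure-activity relationship
#' shows a clear collapse of fit quality under scrambling.
#'
#' @param tbl descriptor matrix (unfiltered is fine; filtering is applied
#'   inside the pipeline on the training rows).
#' @param y numeric activities.
#' @param train integer indices of the training rows (remaining rows form
#'   the test set).
#' @param n_replicas number of scrambles (default 6).
#' @param params [ga_params()] for the inner GA; its seed is advanced per
#'   replica.
#' @param seed RNG seed for the permutations.
#' @return data.frame with one row per replica: `replica`, `r2`, `q2`,
#'   `r2_test`.
#' @export
y_scramble <- function(tbl, y, train, n_replicas = 6, params = ga_params(),
                       seed = 1) {
  if (n_replicas == 0) {
    return(data.frame(replica = integer(0), r2 = numeric(0),
                      q2 = numeric(0), r2_test = numeric(0)))
  }
  perms <- with_seed(seed, replicate(n_replicas, sample(length(y)),
                                     simplify = FALSE))
  out <- lapply(seq_len(n_replicas), function(i) {
    params_i <- params; params_i$seed <- params$seed + i
    pl <- qsar_pipeline(tbl, y[perms[[i]]], train, params_i)
    data.frame(replica = i, r2 = pl$r2, q2 = pl$q2, r2_test = pl$r2_test)
  })
  do.call(rbind, out)
}

#' Replicate random training/test splits
#'
#' Repeats the full modelling pipeline over independent random splits of
#' the dataset and reports per-replica and averaged statistics.
#'
#' @inheritParams y_scramble
#' @param n_test test-set size per split (default 12).
#' @return data.frame with one row per replica (`r2`, `q2`, `r2_test`);
#'   the attribute `"averages"` holds their means.
#' @export
replicate_splits <- function(tbl, y, n_replicas = 6, n_test = 12,
                             params = ga_params(), seed = 1) {
  n <- nrow(tbl)
  stopifnot(n_test < n)
  splits <- with_seed(seed, replicate(n_replicas, sample.int(n, n - n_test),
                                      simplify = FALSE))
  out <- lapply(seq_len(n_replicas), function(i) {
    params_i <- params; params_i$seed <- params$seed + i
    pl <- qsar_pipeline(tbl, y, sort(splits[[i]]), params_i)
    data.frame(replica = i, r2 = pl$r2, q2 = pl$q2, r2_test = pl$r2_test)
  })
  out <- do.call(rbind, out)
  attr(out, "averages") <- colMeans(out[, c("r2", "q2", "r2_test")])
  out
}
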