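#' Build a fused-LASSO design from anomalies and monthly environment
#'
#' Assembles the regression design for the linear anomaly model
#' \deqn{\delta_{k,Y} = a_0^k + \sum_i a_i^{k,C} C_{Y,i} + \sum_i
#'   a_i^{k,T} T_{Y,i} + \sum_i a_i^{k,I} I_{Y,i} + \sum_i a_i^{k,S}
#'   S_{Y,i}}
#' where `i` runs over the 16-month cycle ([cycle_months()]) and each
#' factor contributes one contiguous month-ordered block of columns.
#' Climate indices are smoothed with a trailing 9-month moving average
#' before extraction (the same rule as [correlation_screen()]); all
#' columns are then standardized to zero mean and unit variance over the
#' training years.
#'
#' @param anomalies tibble with columns `year` and `delta` (the response).
#' @param env long environment table (`year`, `month`, `factor`, `value`).
#' @param factors factor blocks to include, in block order.
#' @param smooth_factors factors entering as 9-month moving averages.
#' @param ma_window moving-average window for the smoothed factors.
#' @return An object of class `factor_design`: list with `X` (standardized
#'   matrix, years x months-by-factor), `X_raw`, `y`, `years`, `factor`
#'   and `cycle_month` (per column), `center`, `scale`, `factors`.
#' @export
factor_design <- function(anomalies, env,
                          factors = c("Chl", "T", "Ice", "SAM"),
                          smooth_factors = c("SAM", "AAO", "SOI", "Nino3.4"),
                          ma_window = 9) {
  missing_f <- setdiff(factors, unique(env$factor))
  if (length(missing_f)) {
    stop("factor(s) not in environment table: ",
      paste(missing_f, collapse = ", "))
  }
  blocks <- lapply(factors, function(f) {
    env_cycle_matrix(env, f, anomalies$year,
      smooth = f %in% smooth_factors, ma_window = ma_window
    )
  })
  X_raw <- do.call(cbind, blocks)
  colnames(X_raw) <- unlist(lapply(factors, function(f) {
    sprintf("%s_m%02d", f, 1:16)
  }))
  if (anyNA(X_raw)) {
    stop("environment table does not cover the 16-month window of every year")
  }
  center <- colMeans(X_raw)
  scale <- apply(X_raw, 2, stats::sd)
  scale[scale == 0] <- 1
  X <- sweep(sweep(X_raw, 2, center), 2, scale, "/")
  structure(
    list(
      X = X, X_raw = X_raw, y = anomalies$delta, years = anomalies$year,
      factor = rep(factors, each = 16), cycle_month = rep(1:16, length(factors)),
      center = center, scale = scale, factors = factors
    ),
    class = "factor_design"
  )
}

# FISTA with adaptive restart on the quadratic-plus-L1 composite
#   F(a) = 0.5 a'Ha - b'a + lambda |a|_1   (constant terms dropped)
.fl_solve <- function(H, b, Lip, lambda, start, max_iter = 5000,
                      tol = 1e-9) {
  step <- 1 / Lip
  a <- z <- start
  tmom <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    v <- z - step * (drop(H %*% z) - b)
    a_new <- sign(v) * pmax(abs(v) - step * lambda, 0)
    if (sum((z - a_new) * (a_new - a)) > 0) {  # gradient-based restart
      tmom <- 1
      z <- a_new
    } else {
      tmom_new <- (1 + sqrt(1 + 4 * tmom^2)) / 2
      z <- a_new + ((tmom - 1) / tmom_new) * (a_new - a)
      tmom <- tmom_new
    }
    delta <- max(abs(a_new - a))
    a <- a_new
    if (delta < tol * max(1, max(abs(a)))) {
      converged <- TRUE
      break
    }
  }
  list(a = a, iterations = iter, converged = converged)
}

.fusion_matrix <- function(factor_of_col) {
  p <- length(factor_of_col)
  rows <- which(factor_of_col[-1] == factor_of_col[-p])
  D <- matrix(0, length(rows), p)
  for (k in seq_along(rows)) {
    D[k, rows[k]] <- -1
    D[k, rows[k] + 1] <- 1
  }
  D
}

#' Fused-LASSO objective
#'
#' \deqn{J(a_0, a) = \frac{1}{2m}\sum_i [y_i - a_0 - x_i^\top a]^2 +
#'   \lambda \sum_j |a_j| + \tau_{fuse} \sum_F \sum_{i_F}
#'   (a_{i_F} - a_{i_F - 1})^2}
#' The intercept is unpenalized; the quadratic fusion penalty couples only
#' adjacent months within the same factor block.
#'
#' @param coefficients slope vector (length `ncol(design$X)`).
#' @param design a [factor_design()].
#' @param lambda_l1 L1 penalty weight.
#' @param tau_fuse fusion penalty weight.
#' @param intercept unpenalized intercept `a_0`.
#' @return scalar objective value.
#' @export
fused_lasso_objective <- function(coefficients, design, lambda_l1, tau_fuse,
                                  intercept = 0) {
  m <- length(design$y)
  resid <- design$y - intercept - drop(design$X %*% coefficients)
  D <- .fusion_matrix(design$factor)
  sum(resid^2) / (2 * m) + lambda_l1 * sum(abs(coefficients)) +
    tau_fuse * sum(drop(D %*% coefficients)^2)
}

#' Fit a grouped fused-LASSO regression
#'
#' Minimizes [fused_lasso_objective()] by accelerated proximal-gradient
#' descent (FISTA with adaptive restart): the squared-error and quadratic
#' fusion terms form the smooth part, whose gradient is exact, and the L1
#' term enters through soft-thresholding. Exact zeros in the solution are
#' therefore attainable. Columns are assumed standardized (see
#' [factor_design()]), so the unpenalized intercept decouples as the
#' response mean.
#'
#' @param design a [factor_design()].
#' @param lambda_l1,tau_fuse penalty weights (>= 0).
#' @param max_iter iteration cap.
#' @param tol relative objective-change convergence tolerance.
#' @param start optional warm-start coefficient vector.
#' @return An object of class `fused_lasso`: list with `intercept`,
#'   `coefficients` (tibble `factor`, `cycle_month`, `term`, `estimate`),
#'   `lambda_l1`, `tau_fuse`, `fitted`, `r_squared`, `objective`,
#'   `iterations`, `converged`, `center`, `scale`, `factors`.
#' @export
fused_lasso <- function(design, lambda_l1, tau_fuse, max_iter = 5000,
                        tol = 1e-9, start = NULL) {
  X <- design$X
  m <- length(design$y)
  if (m < 3) stop("need at least 3 training rows")
  a0 <- mean(design$y)
  yc <- design$y - a0
  p <- ncol(X)
  D <- .fusion_matrix(design$factor)
  H <- crossprod(X) / m + 2 * tau_fuse * crossprod(D)
  b <- drop(crossprod(X, yc)) / m
  Lip <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  sol <- .fl_solve(H, b, Lip, lambda_l1,
    start = if (is.null(start)) numeric(p) else start,
    max_iter = max_iter, tol = tol
  )
  a <- sol$a
  iter <- sol$iterations
  converged <- sol$converged
  obj_old <- sum((yc - drop(X %*% a))^2) / (2 * m) +
    lambda_l1 * sum(abs(a)) + tau_fuse * sum(drop(D %*% a)^2)
  fitted <- a0 + drop(X %*% a)
  sst <- sum((design$y - mean(design$y))^2)
  r2 <- if (sst > 0) 1 - sum((design$y - fitted)^2) / sst else NA_real_
  structure(
    list(
      intercept = a0,
      coefficients = tibble::tibble(
        factor = design$factor, cycle_month = design$cycle_month,
        term = colnames(X), estimate = unname(a)
      ),
      lambda_l1 = lambda_l1, tau_fuse = tau_fuse,
      fitted = fitted, r_squared = r2,
      objective = obj_old, iterations = iter, converged = converged,
      center = design$center, scale = design$scale, factors = design$factors
    ),
    class = "fused_lasso"
  )
}

#' @export
print.fused_lasso <- function(x, ...) {
  cat(
    "<fused_lasso>", paste(x$factors, collapse = "+"),
    " lambda =", format(x$lambda_l1), " tau_fuse =", format(x$tau_fuse),
    " R2 =", format(x$r_squared, digits = 3), "\n"
  )
  invisible(x)
}

#' @export
tidy.fused_lasso <- function(x, ...) x$coefficients

#' @export
glance.fused_lasso <- function(x, ...) {
  tibble::tibble(
    lambda_l1 = x$lambda_l1, tau_fuse = x$tau_fuse,
    r_squared = x$r_squared, objective = x$objective,
    iterations = x$iterations, converged = x$converged
  )
}

#' @export
predict.fused_lasso <- function(object, design, ...) {
  Xs <- sweep(sweep(design$X_raw, 2, object$center), 2, object$scale, "/")
  if (!identical(colnames(Xs), object$coefficients$term)) {
    stop("design columns do not match the fitted model")
  }
  object$intercept + drop(Xs %*% object$coefficients$estimate)
}

#' Predict anomalies from a fitted fused-LASSO model and score the fit
#'
#' Applies the linear anomaly model to (raw) design rows, standardizing
#' with the model's training parameters, and reports
#' `R^2 = 1 - SSE/SST` against the supplied anomalies.
#'
#' @param model a [fused_lasso()] fit.
#' @param design a [factor_design()] holding the rows to predict (its `y`
#'   is the comparison anomaly series).
#' @return list with `predictions` (tibble `year`, `observed`,
#'   `predicted`) and `r_squared`.
#' @export
predict_and_score <- function(model, design) {
  pred <- predict.fused_lasso(model, design)
  sst <- sum((design$y - mean(design$y))^2)
  r2 <- if (sst > 0) 1 - sum((design$y - pred)^2) / sst else NA_real_
  list(
    predictions = tibble::tibble(
      year = design$years, observed = design$y, predicted = pred
    ),
    r_squared = r2
  )
}

.make_folds <- function(m, K, type = c("contiguous", "shuffled"), seed = 1) {
  type <- match.arg(type)
  if (K < 2 || K > m) stop("K must satisfy 2 <= K <= number of rows")
  idx <- seq_len(m)
  if (type == "shuffled") {
    set.seed(seed)
    idx <- sample(idx)
  }
  split(idx, cut(seq_len(m), K, labels = FALSE))
}

.refit_design <- function(design, rows) {
  X_raw <- design$X_raw[rows, , drop = FALSE]
  center <- colMeans(X_raw)
  scale <- apply(X_raw, 2, stats::sd)
  scale[scale == 0] <- 1
  d <- design
  d$X_raw <- X_raw
  d$X <- sweep(sweep(X_raw, 2, center), 2, scale, "/")
  d$y <- design$y[rows]
  d$years <- design$years[rows]
  d$center <- center
  d$scale <- scale
  d
}

#' K-fold cross-validation over the fused-LASSO hyperparameter grid
#'
#' For every `(lambda_l1, tau_fuse)` grid point the model is fitted `K`
#' times on `K - 1` folds (re-standardized on the training rows) and
#' scored on the held-out fold; the CV error is the mean held-out squared
#' error pooled over folds. Folds are contiguous blocks of years by
#' default (years are autocorrelated); a seeded shuffled assignment is
#' optional. The result also carries the no-signal diagnostic: whether the
#' tau-profiled CV error attains its minimum at the largest `lambda` of
#' the grid, the behaviour expected when no linear combination of the
#' predictors beats the response mean.
#'
#' @param design a [factor_design()].
#' @param lambda_grid,tau_grid penalty grids (default logarithmic,
#'   `10^seq(-4, 1)`, 12 points each).
#' @param K number of folds (default 9).
#' @param seed fold-assignment seed (used when `fold_type = "shuffled"`).
#' @param fold_type `"contiguous"` or `"shuffled"`.
#' @return list of class `cv_fused_lasso`: `lambda_l1`, `tau_fuse` (the
#'   argmin), `surface` (tibble `lambda_l1`, `tau_fuse`, `cv_error`),
#'   `no_signal`, `K`.
#' @export
cv_fused_lasso <- function(design,
                           lambda_grid = 10^seq(-4, 1, length.out = 12),
                           tau_grid = 10^seq(-4, 1, length.out = 12),
                           K = 9, seed = 1,
                           fold_type = c("contiguous", "shuffled")) {
  m <- length(design$y)
  folds <- .make_folds(m, K, match.arg(fold_type), seed)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)  # warm-start path
  tau_grid <- sort(tau_grid)
  # per-fold training designs and their fixed matrices, computed once
  fold_fit <- lapply(folds, function(te) {
    d <- .refit_design(design, setdiff(seq_len(m), te))
    mk <- length(d$y)
    D <- .fusion_matrix(d$factor)
    list(
      d = d, XtX_m = crossprod(d$X) / mk,
      b = drop(crossprod(d$X, d$y - mean(d$y))) / mk,
      DtD = crossprod(D), a0 = mean(d$y), te = te
    )
  })
  p <- ncol(design$X)
  sq_err <- array(NA_real_,
    c(length(lambda_grid), length(tau_grid), length(folds)))
  for (k in seq_along(fold_fit)) {
    ff <- fold_fit[[k]]
    te <- ff$te
    Xs_te <- sweep(
      sweep(design$X_raw[te, , drop = FALSE], 2, ff$d$center),
      2, ff$d$scale, "/"
    )
    for (it in seq_along(tau_grid)) {
      H <- ff$XtX_m + 2 * tau_grid[it] * ff$DtD
      Lip <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
      a <- numeric(p)
      for (il in seq_along(lambda_grid)) {
        a <- .fl_solve(H, ff$b, Lip, lambda_grid[il], start = a,
          max_iter = 1000, tol = 1e-5)$a
        pred <- ff$a0 + drop(Xs_te %*% a)
        sq_err[il, it, k] <- sum((design$y[te] - pred)^2)
      }
    }
  }
  n_test <- vapply(folds, length, integer(1))
  grid <- expand.grid(lambda_l1 = lambda_grid, tau_fuse = tau_grid)
  cv_err <- vapply(seq_len(nrow(grid)), function(g) {
    il <- match(grid$lambda_l1[g], lambda_grid)
    it <- match(grid$tau_fuse[g], tau_grid)
    sum(sq_err[il, it, ]) / sum(n_test)
  }, numeric(1))
  surface <- tibble::tibble(
    lambda_l1 = grid$lambda_l1, tau_fuse = grid$tau_fuse, cv_error = cv_err
  )
  best <- which.min(cv_err)
  lams <- sort(unique(surface$lambda_l1))      # increasing for the diagnostic
  profile <- vapply(lams, function(l) {
    min(surface$cv_error[surface$lambda_l1 == l])
  }, numeric(1))
  # fired when the tau-profiled CV error bottoms out at the largest lambda
  # (ties, e.g. the all-zero plateau, count toward the largest)
  no_signal <- max(which(profile <= min(profile) * (1 + 1e-12))) ==
    length(lams)
  structure(
    list(
      lambda_l1 = grid$lambda_l1[best], tau_fuse = grid$tau_fuse[best],
      cv_error = cv_err[best], surface = surface,
      no_signal = no_signal, K = K
    ),
    class = "cv_fused_lasso"
  )
}

#' Fit and compare all non-empty factor subsets
#'
#' Fits one cross-validated fused-LASSO model for every non-empty subset
#' of the candidate factors (15 models for 4 factors) and selects the one
#' with the lowest CV error, breaking near-ties — a relative difference
#' below `tie_tol` (default 2 percent) — in favour of the model with fewer
#' factors.
#'
#' @param anomalies tibble `year`, `delta`.
#' @param env long environment table.
#' @param factors candidate factors (default the four drivers `Chl`, `T`,
#'   `Ice`, `SAM`).
#' @param K,lambda_grid,tau_grid,seed,fold_type passed to
#'   [cv_fused_lasso()].
#' @param smooth_factors passed to [factor_design()].
#' @param tie_tol relative CV-error band treated as a tie.
#' @return An object of class `subset_selection`: list with `table`
#'   (tibble `subset`, `n_factors`, `cv_error`, `lambda_l1`, `tau_fuse`,
#'   `r_squared`, `selected`), `models` (named list of [fused_lasso()]
#'   fits on the full data), `selected` (the chosen model), `designs`.
#' @export
select_factor_subset <- function(anomalies, env,
                                 factors = c("Chl", "T", "Ice", "SAM"),
                                 K = 9,
                                 lambda_grid = 10^seq(-4, 1, length.out = 12),
                                 tau_grid = 10^seq(-4, 1, length.out = 12),
                                 seed = 1, fold_type = "contiguous",
                                 smooth_factors = c("SAM", "AAO", "SOI", "Nino3.4"),
                                 tie_tol = 0.02) {
  subsets <- unlist(
    lapply(seq_along(factors), function(k) {
      utils::combn(factors, k, simplify = FALSE)
    }),
    recursive = FALSE
  )
  labels <- vapply(subsets, paste, character(1), collapse = "+")
  models <- designs <- vector("list", length(subsets))
  names(models) <- names(designs) <- labels
  rows <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    d <- factor_design(anomalies, env, factors = subsets[[s]],
      smooth_factors = smooth_factors)
    cv <- cv_fused_lasso(d, lambda_grid, tau_grid, K = K, seed = seed,
      fold_type = fold_type)
    fit <- fused_lasso(d, cv$lambda_l1, cv$tau_fuse)
    designs[[s]] <- d
    models[[s]] <- fit
    rows[[s]] <- tibble::tibble(
      subset = labels[s], n_factors = length(subsets[[s]]),
      cv_error = cv$cv_error, lambda_l1 = cv$lambda_l1,
      tau_fuse = cv$tau_fuse, r_squared = fit$r_squared,
      no_signal = cv$no_signal
    )
  }
  tab <- dplyr::bind_rows(rows)
  best_err <- min(tab$cv_error)
  tied <- tab$cv_error <= best_err * (1 + tie_tol)
  cand <- tab[tied, ]
  cand <- cand[order(cand$n_factors, cand$cv_error), ]
  sel <- cand$subset[1]
  tab$selected <- tab$subset == sel
  structure(
    list(
      table = tab, models = models, designs = designs,
      selected = models[[sel]], selected_subset = sel,
      selected_design = designs[[sel]]
    ),
    class = "subset_selection"
  )
}

#' @export
print.subset_selection <- function(x, ...) {
  cat("<subset_selection> selected:", x$selected_subset, "\n")
  print(x$table[order(x$table$cv_error), ], n = 15)
  invisible(x)
}

#' Ensemble importance of each environmental factor
#'
#' For factor `F`, the mean absolute coefficient of `F` over the whole
#' subset-model ensemble: each of the 15 models contributes the mean
#' `|a_i^F|` over its `F` block (zero when the model excludes `F`), and
#' the contributions are averaged over the 15 models.
#'
#' @param selection a [select_factor_subset()] result.
#' @return tibble `factor`, `importance`, sorted decreasing.
#' @export
factor_importance <- function(selection) {
  all_factors <- unique(unlist(strsplit(names(selection$models), "\\+")))
  imp <- vapply(all_factors, function(f) {
    per_model <- vapply(selection$models, function(m) {
      est <- m$coefficients$estimate[m$coefficients$factor == f]
      if (length(est) == 0) 0 else mean(abs(est))
    }, numeric(1))
    mean(per_model)
  }, numeric(1))
  out <- tibble::tibble(factor = all_factors, importance = imp)
  out[order(-out$importance), ]
}

#' Bootstrap confidence bands for fused-LASSO coefficients
#'
#' Resamples years with replacement, refits at fixed hyperparameters
#' (re-standardizing on each resample), and takes per-coefficient
#' percentile intervals (5th/95th at the default 90 percent level).
#' Degenerate resamples containing a single unique year are redrawn.
#'
#' @param design a [factor_design()].
#' @param lambda_l1,tau_fuse the selected hyperparameters.
#' @param B number of bootstrap resamples (>= 200).
#' @param level confidence level (default 0.90).
#' @param seed integer seed.
#' @return tibble of class `fused_lasso_bands`: `factor`, `cycle_month`,
#'   `term`, `estimate`, `ci_low`, `ci_high`.
#' @export
bootstrap_bands <- function(design, lambda_l1, tau_fuse, B = 500,
                            level = 0.90, seed = 1) {
  if (B < 200) stop("B must be at least 200 for stable percentile bands")
  m <- length(design$y)
  full <- fused_lasso(design, lambda_l1, tau_fuse)
  set.seed(seed)
  boot <- matrix(NA_real_, B, ncol(design$X))
  start <- full$coefficients$estimate
  for (bb in seq_len(B)) {
    repeat {
      rows <- sample.int(m, m, replace = TRUE)
      if (length(unique(rows)) > 1) break
    }
    # pairs bootstrap under the fixed training scale; columns re-centred
    # only (the solver treats the intercept as the response mean)
    d <- design
    Xb <- design$X[rows, , drop = FALSE]
    d$X <- sweep(Xb, 2, colMeans(Xb))
    d$X_raw <- design$X_raw[rows, , drop = FALSE]
    d$y <- design$y[rows]
    d$years <- design$years[rows]
    boot[bb, ] <- fused_lasso(d, lambda_l1, tau_fuse,
      max_iter = 2000, tol = 1e-8, start = start)$coefficients$estimate
  }
  alpha <- (1 - level) / 2
  qs <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha))
  out <- tibble::tibble(
    factor = design$factor, cycle_month = design$cycle_month,
    term = colnames(design$X),
    estimate = full$coefficients$estimate,
    ci_low = qs[1, ], ci_high = qs[2, ]
  )
  class(out) <- c("fused_lasso_bands", class(out))
  out
}

#' Plot fused-LASSO coefficient runs
#'
#' Monthly coefficient profiles per factor; with bands, a ribbon shows the
#' bootstrap confidence envelope.
#'
#' @param object a `fused_lasso` fit or a [bootstrap_bands()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fused_lasso <- function(object, ...) {
  df <- object$coefficients
  df$label <- factor(cycle_months()$label[df$cycle_month],
    levels = cycle_months()$label)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$estimate, colour = .data$factor,
    group = .data$factor
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "month of cycle", y = "coefficient", colour = "factor") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @rdname autoplot.fused_lasso
#' @export
autoplot.fused_lasso_bands <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(cycle_months()$label[df$cycle_month],
    levels = cycle_months()$label)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$estimate, colour = .data$factor,
    group = .data$factor
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high,
        fill = .data$factor),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "month of cycle", y = "coefficient") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
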