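# Run expr with a temporary, seeded RNG state; the caller's stream is
# untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ix <- c(seed, ...)
  s <- 0
  for (v in ix) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483629
  as.integer(s)
}

unpack_params <- function(theta, d, h) {
  list(w_in = matrix(theta[seq_len(d * h)], d, h),
       b_h = theta[d * h + seq_len(h)],
       w_out = theta[d * h + h + seq_len(h)],
       b_out = theta[d * h + 2L * h + 1L])
}

mlp_raw_output <- function(p, X, activation) {
  a <- X %*% p$w_in + matrix(p$b_h, nrow(X), length(p$b_h), byrow = TRUE)
  a <- activation(a)
  list(a = a, y = drop(a %*% p$w_out) + p$b_out)
}

#' Forward pass of the regression MLP
#'
#' Computes `y = sum_j w_j * g(sum_i w_ij * x_i + b_j) + b`, the output of a
#' single-hidden-layer perceptron with hidden activation `g` (tanh by
#' default) and a linear output unit, floored at 0 because the estimated
#' AHI is a nonnegative rate. Inputs are standardized with the location and
#' scale stored in the model at training time.
#'
#' @param model An `mlp_model` from [mlp_train()] (or built by hand with the
#'   same fields).
#' @param x Numeric vector of length `d`, or a matrix with `d` columns (one
#'   row per subject). Columns are matched by name when both are named.
#' @return Estimated AHI (events/h), one value per input row.
#' @export
mlp_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (ncol(x) != model$d) stop("expected ", model$d, " features, got ", ncol(x))
  if (!is.null(colnames(x)) && !is.null(model$features) &&
      all(model$features %in% colnames(x))) {
    x <- x[, model$features, drop = FALSE]
  }
  z <- sweep(sweep(x, 2L, model$scaler$center), 2L, model$scaler$scale, "/")
  act <- if (identical(model$g_t, "logistic")) stats::plogis else tanh
  y <- mlp_raw_output(model, z, act)$y
  pmax(y, 0)
}

#' Train the regression MLP with weight decay
#'
#' Fits the network by penalized least squares: minimizes
#' `sum((y - f(x))^2) + nu * (||w_in||^2 + ||w_out||^2)` (weight decay on
#' the connection weights; biases are not penalized) by quasi-Newton (BFGS)
#' optimization with analytic gradients, starting from a seeded uniform
#' initialization scaled by fan-in. Features are standardized internally
#' (z-score on the training set) and the scaler is stored in the model, so
#' prediction takes raw feature values. Training is deterministic given the
#' seed.
#'
#' @param X Numeric matrix/data.frame of features (n x d, named columns).
#' @param y Numeric target (reference AHI), length n.
#' @param n_hidden Hidden-layer size `N_H` (default 12).
#' @param nu Weight-decay coefficient (default 1).
#' @param seed Integer seed for the weight initialization.
#' @param activation `"tanh"` (default) or `"logistic"`.
#' @param maxit,reltol Optimizer budget and relative tolerance.
#' @return An `mlp_model`: weights, biases, scaler, architecture and
#'   training metadata.
#' @export
mlp_train <- function(X, y, n_hidden = 12L, nu = 1, seed = 1L,
                      activation = c("tanh", "logistic"),
                      maxit = 500L, reltol = 1e-8) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L) stop("need at least two training subjects")
  if (nrow(X) != length(y)) stop("X and y differ in length")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite training values")
  d <- ncol(X); h <- as.integer(n_hidden)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  act <- if (activation == "logistic") stats::plogis else tanh
  dact <- if (activation == "logistic") function(a) a * (1 - a) else function(a) 1 - a^2
  np <- d * h + 2L * h + 1L
  theta0 <- with_local_seed(seed, {
    c(stats::runif(d * h, -0.5, 0.5) / sqrt(d),
      stats::runif(h, -0.5, 0.5),
      stats::runif(h, -0.5, 0.5) / sqrt(h),
      mean(y))
  })
  obj <- function(theta) {
    p <- unpack_params(theta, d, h)
    out <- mlp_raw_output(p, Z, act)
    e <- out$y - y
    sum(e^2) + nu * (sum(p$w_in^2) + sum(p$w_out^2))
  }
  grad <- function(theta) {
    p <- unpack_params(theta, d, h)
    out <- mlp_raw_output(p, Z, act)
    e <- out$y - y
    g_wout <- 2 * drop(crossprod(out$a, e)) + 2 * nu * p$w_out
    g_bout <- 2 * sum(e)
    delta <- (2 * e %o% p$w_out) * dact(out$a)
    g_win <- crossprod(Z, delta) + 2 * nu * p$w_in
    g_bh <- colSums(delta)
    c(as.vector(g_win), g_bh, g_wout, g_bout)
  }
  fit <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = reltol))
  p <- unpack_params(fit$par, d, h)
  structure(list(d = d, n_hidden = h, nu = nu, g_t = activation,
                 w_in = p$w_in, b_h = p$b_h, w_out = p$w_out, b_out = p$b_out,
                 scaler = list(center = ctr, scale = scl),
                 features = colnames(X), seed = seed,
                 value = fit$value, convergence = fit$convergence),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> d=%d, N_H=%d, nu=%g, activation=%s (objective %.4g)\n",
              x$d, x$n_hidden, x$nu, x$g_t, x$value))
  invisible(x)
}

#' Leave-one-out cross-validated AHI estimates
#'
#' For each subject, trains on the remaining n-1 and predicts the held-out
#' one. Per-fold initialization seeds are derived deterministically from
#' `seed` and the fold index.
#'
#' @inheritParams mlp_train
#' @return Numeric vector of held-out AHI estimates, length n.
#' @export
mlp_loocv <- function(X, y, n_hidden = 12L, nu = 1, seed = 1L, ...) {
  X <- as.matrix(X)
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    m <- mlp_train(X[-i, , drop = FALSE], y[-i], n_hidden = n_hidden, nu = nu,
                   seed = derive_seed(seed, i), ...)
    pred[i] <- mlp_forward(m, X[i, , drop = FALSE])
  }
  pred
}

#' Grid model selection by repeated leave-one-out cross-validation
#'
#' For every candidate (N_H, nu) cell, runs `reps` repetitions of full
#' leave-one-out cross-validation (repetitions differ only in the random
#' weight initialization), scores each repetition by the intraclass
#' correlation between held-out estimates and the reference AHI, and
#' averages. The chosen cell maximizes mean ICC; ties prefer the smaller
#' N_H, then the larger nu (the simpler, more regularized model).
#'
#' @inheritParams mlp_train
#' @param n_hidden_grid,nu_grid Candidate values (defaults
#'   `seq(2, 20, 2)` and `c(0.1, 0.5, 1, 2, 4, 8)`).
#' @param reps Repetitions per cell (default 100).
#' @param icc_variant ICC variant used as the selection metric (see
#'   [icc()]).
#' @return A `model_selection_grid`: matrix of mean ICCs (rows = N_H,
#'   columns = nu) plus the chosen cell.
#' @export
select_model <- function(X, y, n_hidden_grid = seq(2L, 20L, 2L),
                         nu_grid = c(0.1, 0.5, 1, 2, 4, 8),
                         reps = 100L, seed = 1L, icc_variant = "agreement", ...) {
  if (length(n_hidden_grid) == 0L || length(nu_grid) == 0L) stop("empty grid")
  if (stats::var(y) == 0) stop("degenerate target: ICC undefined for constant y")
  scores <- matrix(NA_real_, length(n_hidden_grid), length(nu_grid),
                   dimnames = list(paste0("NH", n_hidden_grid),
                                   paste0("nu", nu_grid)))
  for (a in seq_along(n_hidden_grid)) {
    for (b in seq_along(nu_grid)) {
      vals <- vapply(seq_len(reps), function(r) {
        pred <- mlp_loocv(X, y, n_hidden = n_hidden_grid[a], nu = nu_grid[b],
                          seed = derive_seed(seed, a, b, r), ...)
        icc(y, pred, variant = icc_variant)$icc
      }, numeric(1))
      scores[a, b] <- mean(vals)
    }
  }
  best <- which(scores == max(scores), arr.ind = TRUE)
  # ties: smaller N_H, then larger nu
  best <- best[order(best[, 1L], -best[, 2L]), , drop = FALSE][1L, ]
  structure(list(scores = scores,
                 n_hidden_grid = n_hidden_grid, nu_grid = nu_grid,
                 reps = reps,
                 chosen = list(n_hidden = n_hidden_grid[best[1L]],
                               nu = nu_grid[best[2L]])),
            class = "model_selection_grid")
}

#' @export
print.model_selection_grid <- function(x, ...) {
  cat(sprintf("<model_selection_grid> %d cells x %d reps; chosen N_H=%d, nu=%g\n",
              length(x$scores), x$reps, x$chosen$n_hidden, x$chosen$nu))
  print(round(x$scores, 3))
  invisible(x)
}

#' Published architecture presets
#'
#' The validated screening networks use N_H = 12 hidden units with weight
#' decay nu = 1 for supervised in-laboratory oximetry (9 selected features)
#' and nu = 4 for unattended at-home oximetry (8 selected features).
#'
#' @return Named list of presets with `features`, `n_hidden` and `nu`.
#' @export
osas_presets <- function() {
  list(
    lab = list(features = c("M1t", "M2t", "M3t", "M4t", "MF", "PR",
                            "SampEn", "CTM", "LZC"),
               n_hidden = 12L, nu = 1),
    home = list(features = c("M1t", "M3t", "M4t", "SE", "PR",
                             "SampEn", "CTM", "LZC"),
                n_hidden = 12L, nu = 4)
  )
}

#' Estimate the AHI of a raw recording
#'
#' Composition of the full pipeline for a single subject: preprocessing,
#' feature extraction, restriction to the model's selected features, and
#' the MLP forward pass.
#'
#' @param model An `mlp_model`.
#' @param rec A raw [spo2_recording()] (artifacts allowed).
#' @param features Feature names to use; defaults to the model's stored
#'   feature names (e.g. the FCBF-selected subset it was trained on).
#' @param ... Passed to [extract_features()].
#' @return Estimated AHI in events/h (nonnegative scalar).
#' @export
predict_ahi <- function(model, rec, features = model$features, ...) {
  clean <- preprocess_spo2(rec)
  fv <- extract_features(clean$samples, ...)
  mlp_forward(model, fv[features])
}

#' Serialize / restore an MLP model as JSON
#' @param model An `mlp_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$w_in <- as.vector(model$w_in)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$w_in <- matrix(obj$w_in, obj$d, obj$n_hidden)
  obj$scaler <- list(center = stats::setNames(as.numeric(obj$scaler$center), obj$features),
                     scale = stats::setNames(as.numeric(obj$scaler$scale), obj$features))
  structure(obj, class = "mlp_model")
}
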