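# Developmental-age prediction from expression profiles with a small
# multilayer perceptron (hidden layers 4 and 2, linear output, mean absolute
# error loss, L2 weight penalty), plus the evaluation protocol: train/test
# trials, shuffled controls, feature-count sweeps, representative-marker
# comparison and small-subset search.

#' Configuration for the age-prediction network
#'
#' @param hidden hidden-layer widths.
#' @param lambda L2 penalty coefficient on weights (biases unpenalized).
#' @param train_frac fraction of samples used for training in each trial.
#' @param max_iter full-batch Adam iterations.
#' @param learning_rate Adam step size.
#' @param tol convergence tolerance on the loss (checked every 20
#'   iterations).
#' @param n_restarts independent seeded initializations per fit; the run
#'   with the lowest final training loss is kept. A network this small has
#'   genuine bad local minima under MAE loss, so single-init training is
#'   unreliable.
#' @param activation hidden activation; `"relu"` only.
#' @return list of class `age_model_config`.
#' @export
age_model_config <- function(hidden = c(4, 2), lambda = 7.3e-5, train_frac = 0.9,
                             max_iter = 800, learning_rate = 0.01, tol = 1e-6,
                             n_restarts = 3, activation = "relu") {
  if (any(hidden < 1)) stop("hidden widths must be positive", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0,1)", call. = FALSE)
  structure(
    list(hidden = as.integer(hidden), lambda = lambda, train_frac = train_frac,
         max_iter = as.integer(max_iter), learning_rate = learning_rate,
         tol = tol, n_restarts = as.integer(n_restarts), activation = activation),
    class = "age_model_config"
  )
}

# Forward pass; returns activations per layer. W[[l]] is (in x out).
mlp_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]] + matrix(b[[l]], nrow(X), length(b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

#' Fit the age-prediction network
#'
#' Trains a small feed-forward network (ReLU hidden layers, linear output)
#' on log2(RPM+1) profiles with mean-absolute-error loss and an L2 weight
#' penalty, by full-batch Adam. Inputs are standardized per gene and the
#' target age per cohort using training-set statistics only; predictions
#' are returned in minutes. Deterministic given the seed.
#'
#' @param x numeric samples x genes matrix (log2 RPM scale), or an
#'   [expression_matrix()] (transformed internally with `log2(x+1)`).
#' @param ages training ages, minutes.
#' @param genes optional gene-id subset.
#' @param config an [age_model_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `age_model` (weights, standardization, genes,
#'   config, final loss).
#' @export
fit_age_model <- function(x, ages, genes = NULL, config = age_model_config(), seed = 1L) {
  X <- if (inherits(x, "expression_matrix")) t(log2(x$values + 1)) else as.matrix(x)
  if (!is.null(genes)) {
    if (!length(genes)) stop("gene subset must be non-empty", call. = FALSE)
    X <- X[, genes, drop = FALSE]
  }
  if (any(!is.finite(X)) || any(!is.finite(ages))) stop("non-finite inputs", call. = FALSE)
  if (nrow(X) < 10) stop("need at least 10 training samples", call. = FALSE)
  if (stats::sd(ages) == 0) stop("constant target ages", call. = FALSE)

  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  y_center <- mean(ages)
  y_scale <- stats::sd(ages)
  ys <- (ages - y_center) / y_scale

  widths <- c(ncol(X), config$hidden, 1L)
  best <- NULL
  for (r in seq_len(max(1L, config$n_restarts))) {
    fit <- mlp_fit_once(Xs, ys, widths, config, child_seed(seed, 7919L * r))
    if (is.null(best) || fit$loss < best$loss) best <- fit
  }
  structure(
    list(W = best$W, b = best$b, x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         genes = colnames(X), config = config, seed = as.integer(seed),
         final_loss = best$loss),
    class = "age_model"
  )
}

# One seeded initialization + full-batch Adam run; returns weights and the
# final penalized training loss.
mlp_fit_once <- function(Xs, ys, widths, config, seed) {
  L <- length(widths) - 1L
  with_seed(seed, {
    W <- lapply(seq_len(L), function(l) {
      matrix(stats::rnorm(widths[l] * widths[l + 1], sd = sqrt(2 / widths[l])),
             widths[l], widths[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(widths[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    n <- nrow(Xs)
    prev_loss <- Inf
    loss <- NA_real_
    for (it in seq_len(config$max_iter)) {
      A <- mlp_forward(W, b, Xs)
      resid <- A[[L + 1]][, 1] - ys
      loss <- mean(abs(resid)) +
        config$lambda * sum(vapply(W, function(w) sum(w^2), numeric(1)))
      delta <- matrix(sign(resid) / n, n, 1)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + 2 * config$lambda * W[[l]]
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
        }
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^it; corr2 <- 1 - beta2^it
        W[[l]] <- W[[l]] - config$learning_rate * (mW[[l]] / corr1) /
          (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - config$learning_rate * (mb[[l]] / corr1) /
          (sqrt(vb[[l]] / corr2) + eps)
      }
      if (it %% 20 == 0) {
        if (abs(prev_loss - loss) < config$tol) break
        prev_loss <- loss
      }
    }
    list(W = W, b = b, loss = loss)
  })
}

#' Predict developmental age (minutes)
#'
#' @param object an `age_model`.
#' @param newdata samples x genes matrix (log2 RPM scale) or an
#'   [expression_matrix()]; must contain the model's genes.
#' @param ... unused.
#' @return numeric vector of predicted ages in minutes.
#' @export
predict.age_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "expression_matrix")) t(log2(newdata$values + 1)) else as.matrix(newdata)
  X <- X[, object$genes, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  A <- mlp_forward(object$W, object$b, Xs)
  as.numeric(A[[length(A)]]) * object$y_scale + object$y_center
}

#' Evaluate a trained model on held-out samples
#'
#' @param model an `age_model`.
#' @param test_x held-out samples x genes matrix (log2 RPM scale) or
#'   [expression_matrix()].
#' @param test_ages true ages, minutes.
#' @return list with `mae` (minutes) and `predictions` (data.frame
#'   `true_age`, `predicted_age`, `abs_error`).
#' @export
evaluate_trial <- function(model, test_x, test_ages) {
  if (length(test_ages) == 0) stop("empty test set", call. = FALSE)
  pred <- predict(model, test_x)
  err <- abs(pred - test_ages)
  list(
    mae = mean(err),
    predictions = data.frame(true_age = test_ages, predicted_age = pred, abs_error = err)
  )
}

#' Shuffled-prediction control error
#'
#' Permutes the predictions uniformly at random against the true ages and
#' reports the MAE of the permuted pairing, estimating chance-level error.
#'
#' @param predictions numeric predicted ages.
#' @param true_ages numeric true ages.
#' @param seed integer seed.
#' @return shuffled MAE, minutes.
#' @export
shuffled_control <- function(predictions, true_ages, seed = 1L) {
  if (length(predictions) < 2) stop("need at least 2 test samples", call. = FALSE)
  with_seed(seed, mean(abs(sample(predictions) - true_ages)))
}

# One train/test trial on a fixed gene subset. The split is drawn from
# `split_seed`, the network init from a seed derived from it.
age_trial <- function(X, ages, genes, config, split_seed) {
  n <- nrow(X)
  n_train <- round(config$train_frac * n)
  idx <- with_seed(split_seed, sample.int(n, n_train))
  model <- fit_age_model(X[idx, , drop = FALSE], ages[idx], genes = genes,
                         config = config, seed = child_seed(split_seed, 1L))
  ev <- evaluate_trial(model, X[-idx, , drop = FALSE], ages[-idx])
  sh <- shuffled_control(ev$predictions$predicted_age, ev$predictions$true_age,
                         seed = child_seed(split_seed, 2L))
  list(mae = ev$mae, shuffled_mae = sh, model = model, eval = ev,
       train_idx = idx)
}

prep_sweep_matrix <- function(matrix) {
  if (inherits(matrix, "expression_matrix")) t(log2(matrix$values + 1)) else as.matrix(matrix)
}

#' Prediction-error sweep over feature counts
#'
#' For each requested gene-set size and trial: a fresh random gene subset
#' (drawn without replacement, independently per size) and a fresh
#' train/test split. The split-seed stream is shared across sizes, so trial
#' t uses the same split at every size and sizes differ only in the genes
#' drawn.
#'
#' @param matrix an [expression_matrix()] (RPM) or samples x genes matrix on
#'   log2 scale.
#' @param ages sample ages, minutes.
#' @param sizes integer vector of gene-subset sizes.
#' @param trials trials per size.
#' @param seed master seed.
#' @param config an [age_model_config()].
#' @return list of class `age_model_report`: `per_trial` (data.frame size,
#'   trial, mae, shuffled_mae, genes), `summary` (per size: mean real and
#'   shuffled MAE).
#' @export
feature_sweep <- function(matrix, ages, sizes, trials = 100, seed = 1L,
                          config = age_model_config()) {
  X <- prep_sweep_matrix(matrix)
  all_genes <- colnames(X)
  if (any(sizes > length(all_genes))) stop("size exceeds available genes", call. = FALSE)
  rows <- list()
  for (si in seq_along(sizes)) {
    size <- sizes[si]
    for (t in seq_len(trials)) {
      split_seed <- child_seed(seed, t)  # shared across sizes
      gene_seed <- child_seed(seed, si * 100003L + t)
      genes <- with_seed(gene_seed, sample(all_genes, size))
      tr <- age_trial(X, ages, genes, config, split_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        size = size, trial = t, mae = tr$mae, shuffled_mae = tr$shuffled_mae,
        genes = paste(genes[seq_len(min(5, length(genes)))], collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  per_trial <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_trial, per_trial$size), function(d) {
    data.frame(size = d$size[1], mean_mae = mean(d$mae),
               mean_shuffled_mae = mean(d$shuffled_mae), trials = nrow(d))
  }))
  summary <- summary[order(summary$size), ]
  rownames(summary) <- NULL
  structure(list(per_trial = per_trial, summary = summary, seed = seed),
            class = "age_model_report")
}

#' @export
print.age_model_report <- function(x, ...) {
  cat("<age_model_report>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Representative markers versus random gene sets
#'
#' Paired trials: in each trial the same train/test split is evaluated with
#' (a) the representative genes, (b) a random set of the same size, and
#' (c) all genes. Significance of (a) vs (b) is a two-sided Mann-Whitney
#' test over per-trial MAEs.
#'
#' @inheritParams feature_sweep
#' @param representatives character gene ids (e.g. from
#'   [representative_genes()]).
#' @param include_all_genes also evaluate the full gene set each trial.
#' @return list with `per_trial` (trial, mae_representative, mae_random,
#'   mae_all), means, and `p_value`.
#' @export
marker_eval <- function(matrix, ages, representatives, trials = 100, seed = 1L,
                        config = age_model_config(), include_all_genes = TRUE) {
  X <- prep_sweep_matrix(matrix)
  all_genes <- colnames(X)
  if (!all(representatives %in% all_genes)) stop("unknown representative gene id(s)", call. = FALSE)
  k <- length(representatives)
  rows <- lapply(seq_len(trials), function(t) {
    split_seed <- child_seed(seed, t)
    rand <- with_seed(child_seed(seed, 300007L + t), {
      g <- sample(all_genes, k)
      # a draw identical to the representative set is re-drawn (impossible to
      # avoid in the degenerate all-genes case, where the sets must coincide)
      while (k < length(all_genes) && setequal(g, representatives)) {
        g <- sample(all_genes, k)
      }
      g
    })
    rep_tr <- age_trial(X, ages, representatives, config, split_seed)
    rand_tr <- age_trial(X, ages, rand, config, split_seed)
    all_mae <- if (include_all_genes) age_trial(X, ages, NULL, config, split_seed)$mae else NA_real_
    data.frame(trial = t, mae_representative = rep_tr$mae,
               mae_random = rand_tr$mae, mae_all = all_mae)
  })
  per_trial <- do.call(rbind, rows)
  p <- stats::wilcox.test(per_trial$mae_representative, per_trial$mae_random)$p.value
  list(
    per_trial = per_trial,
    mean_mae_representative = mean(per_trial$mae_representative),
    mean_mae_random = mean(per_trial$mae_random),
    mean_mae_all = mean(per_trial$mae_all),
    p_value = p
  )
}

#' Search small subsets of the representative genes
#'
#' Draws `n_draws` random subsets of `draw_size` representatives, scores
#' each by its mean test MAE over `trials` train/test trials (split stream
#' shared across draws), and returns the draws ranked by error.
#'
#' @inheritParams marker_eval
#' @param draw_size genes per subset.
#' @param n_draws number of random subsets.
#' @param trials trials per draw.
#' @return data.frame ranked ascending by `mean_mae`: `rank`, `mean_mae`,
#'   `mean_shuffled_mae`, `genes` (";"-joined).
#' @export
subset_search <- function(matrix, ages, representatives, draw_size = 5,
                          n_draws = 1000, trials = 3, seed = 1L,
                          config = age_model_config()) {
  if (draw_size > length(representatives)) stop("draw_size exceeds representative set", call. = FALSE)
  X <- prep_sweep_matrix(matrix)
  draws <- lapply(seq_len(n_draws), function(d) {
    with_seed(child_seed(seed, 500009L + d), sort(sample(representatives, draw_size)))
  })
  rows <- lapply(seq_along(draws), function(d) {
    maes <- shs <- numeric(trials)
    for (t in seq_len(trials)) {
      tr <- age_trial(X, ages, draws[[d]], config, child_seed(seed, t))
      maes[t] <- tr$mae; shs[t] <- tr$shuffled_mae
    }
    data.frame(mean_mae = mean(maes), mean_shuffled_mae = mean(shs),
               genes = paste(draws[[d]], collapse = ";"), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_mae), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "mean_mae", "mean_shuffled_mae", "genes")]
}
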