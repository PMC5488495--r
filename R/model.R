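#' Model configuration
#'
#' Hyperparameters of the MAP training loop. The defaults follow the
#' package's standard protocol: plain gradient descent at rate 0.05 with
#' step halving whenever a step would increase the objective, 500
#' supervised warm-up iterations followed by 500 joint iterations, noise
#' scales re-estimated in closed form every 10 weight steps, and weights
#' initialized uniformly in (-0.1, 0.1) under the run seed.
#'
#' @param lr Gradient-descent learning rate (phase 1).
#' @param lr_joint Learning rate of the joint phase (defaults to `lr`).
#' @param step_rule How steps interact with the objective: `"backtrack"`
#'   (default) rejects steps that would increase the objective and halves
#'   the rate (it recovers geometrically after accepted steps), giving a
#'   monotone, reproducible trajectory; `"halving"` takes every step but
#'   halves the rate after an increase; `"fixed"` is plain constant-rate
#'   descent. The two non-monotone rules are offered because their noisy
#'   trajectories are occasionally useful diagnostics, but they can
#'   oscillate violently on this objective.
#' @param iters_sup Phase-1 (supervised + prior) iterations.
#' @param iters_joint Phase-2 (full objective) iterations.
#' @param sigma_every Weight steps between closed-form sigma updates.
#' @param sigma_floor Lower bound for both noise scales. The floor keeps
#'   the inverse-variance weights of the two likelihoods commensurate: with
#'   a classifier flexible enough to interpolate a small supervised set the
#'   closed-form scales would otherwise collapse and turn one term into an
#'   effectively hard constraint.
#' @param hidden Hidden-layer width; `NULL` means `floor(D / 2)`.
#' @param init_scale Half-width of the uniform weight initialization.
#' @param seed RNG seed for the weight initialization.
#' @return List of class `model_config`.
#' @export
model_config <- function(lr = 0.05, lr_joint = lr,
                         iters_sup = 500L, iters_joint = 500L,
                         step_rule = c("backtrack", "halving", "fixed"),
                         sigma_every = 10L, sigma_floor = 0.05, hidden = NULL,
                         init_scale = 0.1, seed = 1L) {
  step_rule <- match.arg(step_rule)
  stopifnot(lr > 0, lr_joint > 0, iters_sup >= 0, iters_joint >= 0,
            sigma_every >= 1, sigma_floor > 0)
  structure(list(lr = lr, lr_joint = lr_joint, iters_sup = as.integer(iters_sup),
                 iters_joint = as.integer(iters_joint), step_rule = step_rule,
                 sigma_every = as.integer(sigma_every),
                 sigma_floor = sigma_floor, hidden = hidden,
                 init_scale = init_scale, seed = as.integer(seed)),
            class = "model_config")
}

# ---- one-hidden-layer perceptron --------------------------------------------

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize MLP parameters
#'
#' One hidden tanh layer of width `floor(D / 2)` (the input dimension D
#' includes the bias feature); the scalar output is mapped to (0, 1) by a
#' logistic sigmoid so region scores are probabilities.
#'
#' @param D Input dimension including the bias entry.
#' @param hidden Hidden width (default `floor(D / 2)`).
#' @param init_scale Uniform initialization half-width.
#' @param seed RNG seed.
#' @return List of class `mlp_params` with `W1` (hidden x D) and `w2`
#'   (hidden + 1, the extra entry an output bias).
#' @export
mlp_init <- function(D, hidden = NULL, init_scale = 0.1, seed = 1L) {
  if (is.null(hidden)) hidden <- max(1L, D %/% 2L)
  with_seed(seed, {
    structure(list(
      W1 = matrix(runif(hidden * D, -init_scale, init_scale), hidden, D),
      w2 = runif(hidden + 1, -init_scale, init_scale),
      D = as.integer(D), hidden = as.integer(hidden)), class = "mlp_params")
  })
}

params_to_vec <- function(params) c(params$W1, params$w2)

vec_to_params <- function(w, D, hidden) {
  structure(list(W1 = matrix(w[seq_len(hidden * D)], hidden, D),
                 w2 = w[hidden * D + seq_len(hidden + 1)],
                 D = as.integer(D), hidden = as.integer(hidden)),
            class = "mlp_params")
}

mlp_forward <- function(params, X) {
  Hd <- tanh(X %*% t(params$W1))
  f <- sigmoid(cbind(Hd, 1) %*% params$w2)
  list(f = as.vector(f), hidden = Hd)
}

# Gradient of sum_i alpha_i * f_i with respect to the packed weight vector.
mlp_backprop <- function(params, X, alpha, fwd = NULL) {
  if (is.null(fwd)) fwd <- mlp_forward(params, X)
  d <- alpha * fwd$f * (1 - fwd$f)
  grad_w2 <- as.vector(crossprod(cbind(fwd$hidden, 1), d))
  M <- (1 - fwd$hidden^2) *
    matrix(params$w2[seq_len(params$hidden)], nrow(X), params$hidden,
           byrow = TRUE) * d
  grad_W1 <- crossprod(M, X)  # hidden x D, same layout as params$W1
  c(as.vector(grad_W1), grad_w2)
}

#' Score regions with the MLP
#'
#' @param params An [mlp_init()] parameter set (or a trained model's
#'   `params`).
#' @param X Feature matrix (rows are regions; last column is the bias) or a
#'   single feature vector.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
score_region <- function(params, X) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.vector(X)) X <- matrix(X, 1)
  if (ncol(X) != params$D)
    stopf("feature dimension %d does not match the model (%d)", ncol(X), params$D)
  mlp_forward(params, X)$f
}

# ---- path-consistency loss --------------------------------------------------

#' Exact at-most-one path indicator
#'
#' Evaluates the disjunctive normal form over a path's binary selections:
#' one conjunction per "exactly node j selected" plus one all-negated
#' conjunction for the empty selection. Returns 1 exactly when at most one
#' node on the path is selected.
#'
#' @param f Binary vector (0/1) of per-node selections along one path.
#' @return 0 or 1.
#' @export
path_indicator_exact <- function(f) {
  stopifnot(all(f %in% c(0, 1)))
  n <- length(f)
  disjuncts <- vapply(seq_len(n), function(j) {
    lits <- ifelse(seq_len(n) == j, f, 1 - f)
    prod(lits)
  }, numeric(1))
  empty <- prod(1 - f)
  as.integer(max(c(disjuncts, empty)) > 0)
}

#' Relaxed differentiable path loss
#'
#' The DNF of [path_indicator_exact()] with conjunctions replaced by
#' products and the disjunction by its De Morgan product complement:
#' `F = 1 - prod_j (1 - P_j)` where `P_j = f_j * prod_{k != j} (1 - f_k)`
#' and the extra disjunct negates every node. `F` lies in \[0, 1\] and
#' coincides with the exact indicator at binary scores.
#'
#' @param f Numeric vector of per-node scores in \[0, 1\] along one path.
#' @return Scalar path satisfaction in \[0, 1\] (the loss penalizes
#'   `1 - F`).
#' @export
path_loss_relaxed <- function(f) {
  stopifnot(length(f) >= 1, all(f >= 0 & f <= 1))
  path_loss_terms(as.numeric(f), list(seq_along(f)), FALSE)$F
}

# Batch path losses and the per-region gradient coefficients
# coef_r = sum_i (1 - F_i) dF_i/df_r for the unsupervised loss gradient.
path_losses <- function(scores, paths, want_coef = FALSE) {
  path_loss_terms(as.numeric(scores), unclass(paths), want_coef)
}

# ---- MAP objective ----------------------------------------------------------

# A training problem: standardized supervised features/labels and the
# unsupervised region features with their root-to-leaf paths (row indices
# into X_u).
training_problem <- function(X_s, y_s, X_u = NULL, paths = list()) {
  stopifnot(is.matrix(X_s), length(y_s) == nrow(X_s), all(y_s %in% c(0, 1)))
  if (length(paths) > 0) stopifnot(is.matrix(X_u))
  list(X_s = X_s, y_s = as.numeric(y_s), X_u = X_u, paths = paths)
}

#' Negative log-posterior of the detection model
#'
#' `L = N_p log(sigma_u) + ||1 - F||^2 / (2 sigma_u^2) + ||w||^2 / 2 +
#' ||y_s - f(X_s)||^2 / (2 sigma_s^2) + N_s log(sigma_s)`, combining the
#' unsupervised path-consistency likelihood, a standard-normal weight
#' prior, and the supervised quadratic likelihood. With `include_unsup =
#' FALSE` the path terms are dropped (phase-1 training).
#'
#' @param params MLP parameters.
#' @param sigma_s,sigma_u Noise scales (> 0).
#' @param prob A training problem (see [train_model()] inputs).
#' @param include_unsup Include the path-consistency terms?
#' @return Scalar objective value.
#' @export
map_objective <- function(params, sigma_s, sigma_u, prob,
                          include_unsup = TRUE) {
  w <- params_to_vec(params)
  f_s <- mlp_forward(params, prob$X_s)$f
  L <- sum(w^2) / 2 +
    sum((prob$y_s - f_s)^2) / (2 * sigma_s^2) +
    length(prob$y_s) * log(sigma_s)
  if (include_unsup && length(prob$paths) > 0) {
    f_u <- mlp_forward(params, prob$X_u)$f
    Fi <- path_losses(f_u, prob$paths)$F
    L <- L + length(prob$paths) * log(sigma_u) +
      sum((1 - Fi)^2) / (2 * sigma_u^2)
  }
  if (!is.finite(L)) stopf("objective is not finite")
  L
}

#' Closed-form noise-scale updates
#'
#' Setting the partial derivatives of the negative log-posterior with
#' respect to the noise scales to zero gives
#' `sigma_u = ||1 - F|| / sqrt(N_p)` and `sigma_s = ||y_s - f(X_s)|| /
#' sqrt(N_s)`; both are floored to avoid division blow-up when residuals
#' vanish.
#'
#' @param path_residuals Vector `1 - F` over all paths.
#' @param sup_residuals Vector `y_s - f(X_s)`.
#' @param floor Lower bound applied to both scales.
#' @return List with `sigma_u` and `sigma_s` (either may be `NA` if the
#'   corresponding residual vector is empty).
#' @export
update_sigmas <- function(path_residuals, sup_residuals, floor = 1e-4) {
  sig <- function(r) {
    if (length(r) == 0) return(NA_real_)
    max(sqrt(sum(r^2) / length(r)), floor)
  }
  list(sigma_u = sig(path_residuals), sigma_s = sig(sup_residuals))
}

#' Analytic gradient of the MAP objective
#'
#' Combines the prior term `w`, the supervised term
#' `-(1/sigma_s^2) sum_i (y_i - f_i) df_i/dw`, and the unsupervised chain
#' term `-(1/sigma_u^2) sum_p (1 - F_p) dF_p/dw`, where `dF_p/dw` expands
#' as a sum over the path's disjuncts of leave-one-out products (computed in
#' compiled code) times per-region score gradients.
#'
#' @inheritParams map_objective
#' @return Numeric vector, the gradient with respect to the packed weights.
#' @export
map_gradient <- function(params, sigma_s, sigma_u, prob,
                         include_unsup = TRUE) {
  w <- params_to_vec(params)
  fwd_s <- mlp_forward(params, prob$X_s)
  alpha_s <- -(prob$y_s - fwd_s$f) / sigma_s^2
  g <- w + mlp_backprop(params, prob$X_s, alpha_s, fwd_s)
  if (include_unsup && length(prob$paths) > 0) {
    fwd_u <- mlp_forward(params, prob$X_u)
    terms <- path_losses(fwd_u$f, prob$paths, want_coef = TRUE)
    alpha_u <- -terms$coef / sigma_u^2
    g <- g + mlp_backprop(params, prob$X_u, alpha_u, fwd_u)
  }
  g
}

# ---- training loop ----------------------------------------------------------

#' Train the region classifier by alternating MAP estimation
#'
#' Phase 1 minimizes the supervised loss plus the weight prior by gradient
#' descent from a random initialization with `sigma_s = 1`, re-estimating
#' `sigma_s` in closed form every few steps. Phase 2 continues on the full
#' objective including the unsupervised path-consistency loss, alternating
#' weight steps with closed-form updates of both noise scales. Steps that
#' would increase the objective are rejected and the learning rate halved
#' (it recovers geometrically after accepted steps), so the objective is
#' non-increasing at fixed noise scales; the closed-form sigma updates
#' minimize the objective in sigma and therefore never increase it either.
#'
#' @param X_s Standardized supervised feature matrix (bias column last).
#' @param y_s Binary labels for `X_s` (at least one of each class).
#' @param X_u Standardized feature matrix of all unsupervised regions.
#' @param paths List of root-to-leaf paths as row indices into `X_u`.
#' @param config A [model_config()].
#' @return Object of class `model_state`: `params`, `sigma_s`, `sigma_u`,
#'   `log` (per-iteration objective and scales), `config`.
#' @export
train_model <- function(X_s, y_s, X_u = NULL, paths = list(),
                        config = model_config()) {
  prob <- training_problem(X_s, y_s, X_u, paths)
  if (length(unique(prob$y_s)) < 2)
    stopf("supervised set needs at least one positive and one negative region")
  D <- ncol(X_s)
  params <- mlp_init(D, config$hidden, config$init_scale, config$seed)
  sigma_s <- 1
  sigma_u <- 1
  log_rows <- list()

  run_phase <- function(params, sigma_s, sigma_u, iters, include_unsup, phase) {
    lr0 <- if (include_unsup) config$lr_joint else config$lr
    lr <- lr0
    L <- map_objective(params, sigma_s, sigma_u, prob, include_unsup)
    w <- params_to_vec(params)
    for (it in seq_len(iters)) {
      g <- map_gradient(params, sigma_s, sigma_u, prob, include_unsup)
      if (config$step_rule == "backtrack") {
        for (bt in 1:30) {
          w_new <- w - lr * g
          params_new <- vec_to_params(w_new, D, params$hidden)
          L_new <- map_objective(params_new, sigma_s, sigma_u, prob, include_unsup)
          if (!is.finite(L_new))
            stopf("objective diverged at %s iteration %d", phase, it)
          if (L_new <= L) {
            w <- w_new; params <- params_new; L <- L_new
            lr <- min(lr * 1.2, lr0)
            break
          }
          lr <- lr / 2
        }
      } else {
        w <- w - lr * g
        params <- vec_to_params(w, D, params$hidden)
        L_new <- map_objective(params, sigma_s, sigma_u, prob, include_unsup)
        if (!is.finite(L_new))
          stopf("objective diverged at %s iteration %d", phase, it)
        if (config$step_rule == "halving" && L_new > L) lr <- lr / 2
        L <- L_new
      }
      if (it %% config$sigma_every == 0) {
        f_s <- mlp_forward(params, prob$X_s)$f
        ru <- if (include_unsup && length(prob$paths) > 0) {
          1 - path_losses(mlp_forward(params, prob$X_u)$f, prob$paths)$F
        } else numeric(0)
        sig <- update_sigmas(ru, prob$y_s - f_s, config$sigma_floor)
        sigma_s <- sig$sigma_s
        if (!is.na(sig$sigma_u)) sigma_u <- sig$sigma_u
        L <- map_objective(params, sigma_s, sigma_u, prob, include_unsup)
      }
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        phase = phase, iter = it, objective = L,
        sigma_s = sigma_s, sigma_u = sigma_u)
    }
    list(params = params, sigma_s = sigma_s, sigma_u = sigma_u)
  }

  st <- run_phase(params, sigma_s, sigma_u, config$iters_sup, FALSE, "supervised")
  st <- run_phase(st$params, st$sigma_s, st$sigma_u, config$iters_joint,
                  TRUE, "joint")
  structure(list(params = st$params, sigma_s = st$sigma_s,
                 sigma_u = st$sigma_u,
                 log = do.call(rbind, log_rows), config = config),
            class = "model_state")
}

#' @export
print.model_state <- function(x, ...) {
  cat(sprintf("region classifier: D=%d, hidden=%d, sigma_s=%.4g, sigma_u=%.4g\n",
              x$params$D, x$params$hidden, x$sigma_s, x$sigma_u))
  invisible(x)
}
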