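# Approximate Bayesian computation for SPFL dynamics.  The reference table
# pairs prior draws of (alpha, k[, fraction]) with the (a, b) summary
# statistics of subtree-conditioned simulations; fitting is rejection on
# normalized Euclidean distance followed by local ridge-regression
# adjustment of the accepted parameters.

#' Prior specification for ABC
#'
#' Defaults follow the uniform priors k in [-100, 100], fraction in [0, 1]
#' (three-parameter model only) and log10(alpha) in [-1.5, 1].
#'
#' @param model `"two_param"` (alpha, k; every subtree drifts) or
#'   `"three_param"` (alpha, k, fraction of subtrees that drift).
#' @param k_range,frac_range,log10_alpha_range Numeric length-2 ranges.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(model = c("two_param", "three_param"),
                       k_range = c(-100, 100), frac_range = c(0, 1),
                       log10_alpha_range = c(-1.5, 1)) {
  model <- match.arg(model)
  chk <- function(r) length(r) == 2 && r[1] < r[2]
  if (!chk(k_range) || !chk(frac_range) || !chk(log10_alpha_range))
    stop("prior ranges must be non-degenerate intervals")
  structure(list(model = model, k_range = k_range, frac_range = frac_range,
                 log10_alpha_range = log10_alpha_range),
            class = "prior_spec")
}

draw_prior <- function(prior, n) {
  data.frame(
    alpha = 10^runif(n, prior$log10_alpha_range[1], prior$log10_alpha_range[2]),
    k = runif(n, prior$k_range[1], prior$k_range[2]),
    fraction = if (prior$model == "three_param")
      runif(n, prior$frac_range[1], prior$frac_range[2]) else rep(1, n))
}

shapes_for_cpp <- function(subtree_list) {
  lapply(unclass(subtree_list), function(e)
    list(parent = e$shape$parent, child = e$shape$child,
         len = e$shape$len, age = e$shape$age, count = e$count))
}

#' Simulate pooled branch observations over a subtree list
#'
#' Runs the subtree-conditioned simulator once: every subtree in the list
#' (replicated by its count, truncated at `cap`) is started at its gain
#' with all 20 log fitnesses drawn i.i.d. from Gamma(alpha, rate = alpha);
#' with probability `fraction` the resident's log fitness drifts at rate
#' `k`, otherwise the landscape is static.  The observed member branches
#' (contiguous descent of the gained allele) are pooled.
#'
#' @param subtree_list A `subtree_list` from [pool_subtrees()].
#' @param alpha,k,fraction Simulation parameters.
#' @param model A [rate_model()].
#' @param dt Drift discretization step (dS).
#' @param cap Maximum number of subtrees simulated.
#' @return Matrix with columns `length`, `age`, `s`.
#' @export
simulate_subtree_branches <- function(subtree_list, alpha, k, fraction = 1,
                                      model = rate_model(), dt = 0.01,
                                      cap = 100000) {
  if (!length(subtree_list)) stop("subtree list is empty")
  if (cap < 1) stop("cap must be at least 1")
  cpp_sim_subtree_stats(shapes_for_cpp(subtree_list), alpha, k, fraction,
                        model$mu, dt, as.integer(cap))
}

sim_stats <- function(subtree_list, alpha, k, fraction, model, dt, cap) {
  br <- simulate_subtree_branches(subtree_list, alpha, k, fraction, model,
                                  dt, cap)
  st <- summary_regression(br)
  c(a = st$a, b = st$b, c = st$c)
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the prior and, for each, simulates
#' the full subtree list and records the summary statistics.
#'
#' @param subtree_list A `subtree_list` from [pool_subtrees()].
#' @param prior A [prior_spec()].
#' @param n_sims Prior size (default 10^4).
#' @param cap Maximum subtrees per simulation (default 10^5).
#' @param model A [rate_model()].
#' @param dt Drift discretization step.
#' @param seed Optional integer seed recorded in the table.
#' @return A data frame of class `abc_reference` with columns alpha, k,
#'   fraction, a, b, c.
#' @export
simulate_reference <- function(subtree_list, prior, n_sims = 10000,
                               cap = 100000, model = rate_model(),
                               dt = 0.01, seed = NULL) {
  if (!length(subtree_list)) stop("subtree list is empty")
  if (cap < 1) stop("cap must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  pars <- draw_prior(prior, n_sims)
  stats <- matrix(NA_real_, n_sims, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (i in seq_len(n_sims)) {
    stats[i, ] <- sim_stats(subtree_list, pars$alpha[i], pars$k[i],
                            pars$fraction[i], model, dt, cap)
  }
  out <- cbind(pars, as.data.frame(stats))
  attr(out, "prior") <- prior
  attr(out, "seed") <- seed
  attr(out, "mu") <- model$mu
  class(out) <- c("abc_reference", "data.frame")
  out
}

#' Simulate an independent test set of (parameters, statistics)
#'
#' Draws parameters from the prior (optionally restricted to `|k| >=
#' min_abs_k`) and simulates each one over the subtree list, optionally at
#' a rescaled overall substitution rate.
#'
#' @inheritParams simulate_reference
#' @param n Number of test simulations.
#' @param min_abs_k Lower bound on `|k|` of the drawn parameters.
#' @param mu_factor Multiplier on the substitution rate used for the test
#'   simulations (for rate-robustness checks).
#' @return Data frame like a reference table.
#' @export
simulate_test_set <- function(subtree_list, prior, n, min_abs_k = 0,
                              mu_factor = 1, cap = 100000,
                              model = rate_model(), dt = 0.01) {
  pars <- draw_prior(prior, n)
  if (min_abs_k > 0) {
    for (i in seq_len(n)) {
      while (abs(pars$k[i]) < min_abs_k) {
        p <- draw_prior(prior, 1)
        pars[i, ] <- p
      }
    }
  }
  test_model <- rate_model(model$mu * mu_factor)
  stats <- t(vapply(seq_len(n), function(i)
    sim_stats(subtree_list, pars$alpha[i], pars$k[i], pars$fraction[i],
              test_model, dt, cap), c(a = 0, b = 0, c = 0)))
  cbind(pars, as.data.frame(stats))
}

# ---- fitting ---------------------------------------------------------------

ref_scale <- function(S) {
  sc <- apply(S, 2, stats::mad)
  sd_fallback <- apply(S, 2, sd)
  sc[sc == 0] <- sd_fallback[sc == 0]
  sc[sc == 0] <- 1
  sc
}

logit <- function(p, eps = 1e-6) {
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# Weighted ridge regression of y on X (with intercept), penalty lambda on
# the slopes only; GCV-selected lambda over a fixed grid.
ridge_gcv <- function(X, y, w, lambdas = c(0, 10^seq(-6, 2, by = 1))) {
  A <- cbind(1, X)
  p <- ncol(A)
  W <- w / mean(w)
  AtWA <- crossprod(A * W, A)
  AtWy <- crossprod(A * W, y)
  best <- NULL
  for (lam in lambdas) {
    P <- diag(c(0, rep(lam, p - 1)), p)
    H <- AtWA + P
    sol <- tryCatch(solve(H, cbind(AtWy, t(A * W))), error = function(e) NULL)
    if (is.null(sol)) next
    beta <- sol[, 1]
    hat_diag <- rowSums(A * t(sol[, -1, drop = FALSE]))
    fitted <- drop(A %*% beta)
    n <- length(y)
    edf <- sum(hat_diag)
    gcv <- sum(W * (y - fitted)^2) / n / (1 - min(edf / n, 0.99))^2
    if (is.null(best) || gcv < best$gcv)
      best <- list(beta = beta, gcv = gcv, lambda = lam, fitted = fitted)
  }
  if (is.null(best)) stop("ridge adjustment failed: singular design")
  best
}

#' Fit the ABC posterior of SPFL-dynamics parameters
#'
#' Rejection ABC with optional local ridge-regression adjustment.
#' Distances are Euclidean in the (a, b) summary-statistic space after
#' dividing each statistic by its median absolute deviation across the
#' reference table; the `tolerance` fraction of reference rows nearest the
#' observed statistics is accepted.  With `adjust = "ridge"`, each
#' parameter (k on its natural scale, log alpha, logit fraction) is
#' regressed on the normalized statistics among the accepted rows with
#' Epanechnikov weights and a GCV-chosen ridge penalty, and the residual-
#' corrected samples are back-transformed.  The adjustment is applied only
#' when the observed statistics lie inside the span of the accepted set in
#' every coordinate; otherwise the local model would extrapolate and the
#' unadjusted rejection samples are returned (`$adjusted` records which).
#'
#' @param observed Observed summary statistics: a `summary_stats` object or
#'   a vector/list with elements `a` and `b`.
#' @param ref An `abc_reference` table.
#' @param tolerance Accepted fraction of the reference table (default 0.01).
#' @param adjust `"ridge"` or `"none"`.
#' @return An object of class `spfl_abc` with the accepted (adjusted)
#'   samples, per-parameter posterior medians and 95% posterior probability
#'   intervals (2.5 and 97.5 percentiles).
#' @export
abc_fit <- function(observed, ref, tolerance = 0.01,
                    adjust = c("ridge", "none")) {
  adjust <- match.arg(adjust)
  if (!nrow(ref)) stop("empty reference table")
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  obs <- as_stats_vector(observed)
  S <- as.matrix(ref[, c("a", "b")])
  sc <- ref_scale(S)
  Z <- sweep(S, 2, sc, "/")
  z_obs <- obs / sc
  d <- sqrt((Z[, 1] - z_obs[1])^2 + (Z[, 2] - z_obs[2])^2)
  n_acc <- ceiling(tolerance * nrow(ref))
  if (n_acc < 2) stop("fewer than 2 accepted rows; increase tolerance or prior size")
  idx <- order(d)[seq_len(n_acc)]
  prior <- attr(ref, "prior")
  model <- if (!is.null(prior)) prior$model else "three_param"
  acc <- ref[idx, c("alpha", "k", "fraction")]
  d_acc <- d[idx]
  d_max <- max(d_acc)
  w <- if (d_max > 0) 1 - (d_acc / d_max)^2 else rep(1, n_acc)
  w[w <= 0] <- min(w[w > 0], 1e-8)

  samples <- acc
  lambda <- c(alpha = NA_real_, k = NA_real_, fraction = NA_real_)
  adjusted <- FALSE
  if (adjust == "ridge") {
    X <- sweep(Z[idx, , drop = FALSE], 2, z_obs, "-")
    # Local regression is only valid as an interpolation: if the observed
    # statistics lie outside the span of the accepted set (every accepted
    # point on the same side in some coordinate), adjusting would
    # extrapolate the local model, so the rejection samples are kept as-is.
    inside <- apply(X, 2, function(x) min(x) < 0 && max(x) > 0)
    adjusted <- all(inside)
  }
  if (adjust == "ridge" && adjusted) {
    adj_one <- function(y) {
      fit <- ridge_gcv(X, y, w)
      list(adj = y - drop(X %*% fit$beta[-1]), lambda = fit$lambda)
    }
    ak <- adj_one(acc$k)
    samples$k <- ak$adj
    lambda["k"] <- ak$lambda
    aa <- adj_one(log(acc$alpha))
    samples$alpha <- exp(aa$adj)
    lambda["alpha"] <- aa$lambda
    if (model == "three_param" && var(acc$fraction) > 0) {
      af <- adj_one(logit(acc$fraction))
      samples$fraction <- stats::plogis(af$adj)
      lambda["fraction"] <- af$lambda
    }
  }
  qs <- function(v) c(median = median(v), lo = unname(quantile(v, 0.025)),
                      hi = unname(quantile(v, 0.975)))
  est <- t(vapply(samples, qs, c(median = 0, lo = 0, hi = 0)))
  structure(list(samples = samples, unadjusted = acc, weights = w,
                 distances = d_acc, observed = obs, tolerance = tolerance,
                 adjust = adjust, adjusted = adjusted, model = model,
                 lambda = lambda,
                 estimates = as.data.frame(est)), class = "spfl_abc")
}

#' @export
print.spfl_abc <- function(x, ...) {
  cat("ABC posterior (", x$model, ", tolerance ", x$tolerance,
      ", adjustment ", x$adjust, ")\n", sep = "")
  e <- x$estimates
  for (p in rownames(e)) {
    if (p == "fraction" && x$model == "two_param") next
    cat(sprintf("  %-8s median %8.3f  95%% PPI (%.3f, %.3f)\n",
                p, e[p, "median"], e[p, "lo"], e[p, "hi"]))
  }
  invisible(x)
}

#' @export
summary.spfl_abc <- function(object, ...) {
  out <- object$estimates
  out$accepted <- nrow(object$samples)
  direction <- if (out["k", "median"] > 0) "entrenchment" else "senescence"
  attr(out, "direction") <- direction
  attr(out, "k_sign_certain") <- out["k", "lo"] > 0 || out["k", "hi"] < 0
  class(out) <- c("summary.spfl_abc", "data.frame")
  out
}

#' @export
print.summary.spfl_abc <- function(x, ...) {
  print.data.frame(x)
  cat("Direction of the posterior-median fitness change:",
      attr(x, "direction"),
      if (attr(x, "k_sign_certain")) "(95% PPI excludes 0)\n"
      else "(95% PPI overlaps 0)\n")
  invisible(x)
}

#' @export
coef.spfl_abc <- function(object, ...) {
  e <- object$estimates[, "median"]
  names(e) <- rownames(object$estimates)
  if (object$model == "two_param") e <- e[c("alpha", "k")]
  e
}

#' @export
plot.spfl_abc <- function(x, ...) {
  pars <- if (x$model == "two_param") c("alpha", "k")
          else c("alpha", "k", "fraction")
  op <- graphics::par(mfrow = c(1, length(pars)))
  on.exit(graphics::par(op))
  for (p in pars) {
    graphics::hist(x$samples[[p]], breaks = 20, main = p, xlab = p,
                   col = "grey80", border = "white", ...)
    graphics::abline(v = x$estimates[p, "median"], col = "red", lwd = 2)
  }
  invisible(x)
}

# ---- validation ------------------------------------------------------------

#' Leave-one-out cross-validation of ABC prediction error
#'
#' For `n_test` randomly chosen reference rows, fits ABC against the table
#' with that row removed and reports, per parameter, the normalized
#' prediction error `sum((true - est)^2) / sum((true - mean(true))^2)` of
#' the posterior medians.
#'
#' @param ref An `abc_reference` table.
#' @param n_test Number of held-out rows (default 100).
#' @param tolerance Rejection tolerance.
#' @param adjust Passed to [abc_fit()].
#' @return Data frame with one row per parameter: `error`, `n_test`.
#' @export
cross_validate <- function(ref, n_test = 100, tolerance = 0.01,
                           adjust = "ridge") {
  stopifnot(n_test < nrow(ref))
  prior <- attr(ref, "prior")
  pars <- if (!is.null(prior) && prior$model == "two_param")
    c("alpha", "k") else c("alpha", "k", "fraction")
  idx <- sample.int(nrow(ref), n_test)
  est <- matrix(NA_real_, n_test, length(pars), dimnames = list(NULL, pars))
  for (j in seq_len(n_test)) {
    i <- idx[j]
    sub <- ref[-i, , drop = FALSE]
    attr(sub, "prior") <- prior
    class(sub) <- class(ref)
    fit <- abc_fit(c(a = ref$a[i], b = ref$b[i]), sub, tolerance, adjust)
    est[j, ] <- coef(fit)[pars]
  }
  truth <- as.matrix(ref[idx, pars])
  err <- vapply(pars, function(p)
    sum((truth[, p] - est[, p])^2) / sum((truth[, p] - mean(truth[, p]))^2), 0)
  data.frame(parameter = pars, error = unname(err), n_test = n_test)
}

#' Confusion matrix for the sign of k (senescence vs entrenchment)
#'
#' Classifies each test simulation by the sign of the posterior median of
#' `k` and tabulates against the true sign.  If no `test` table is given,
#' test rows are drawn from the reference table and fitted leave-one-out.
#'
#' @param ref An `abc_reference` table.
#' @param n_test Number of test rows when drawing from `ref`.
#' @param tolerance Rejection tolerance.
#' @param test Optional independent test table (from [simulate_test_set()]).
#' @param min_abs_k Exclude test rows with `|k|` below this bound.
#' @param adjust Passed to [abc_fit()].
#' @return List with `table` (2x2 true x inferred counts),
#'   `misclassification` (off-diagonal fraction), `overlap_zero` (number of
#'   misclassified cases whose 95% interval includes 0), and `details`.
#' @export
abc_confusion <- function(ref, n_test = 100, tolerance = 0.01, test = NULL,
                          min_abs_k = 0, adjust = "ridge") {
  prior <- attr(ref, "prior")
  loo <- is.null(test)
  if (loo) {
    cand <- which(abs(ref$k) >= min_abs_k & ref$k != 0)
    idx <- sample(cand, min(n_test, length(cand)))
    test <- ref[idx, , drop = FALSE]
  } else {
    test <- test[abs(test$k) >= min_abs_k & test$k != 0, , drop = FALSE]
    idx <- NULL
  }
  n <- nrow(test)
  true_sign <- ifelse(test$k > 0, "entrenched", "senescing")
  est_k <- numeric(n)
  lo <- numeric(n)
  hi <- numeric(n)
  for (j in seq_len(n)) {
    r <- ref
    if (loo) {
      r <- ref[-idx[j], , drop = FALSE]
      attr(r, "prior") <- prior
      class(r) <- class(ref)
    }
    fit <- abc_fit(c(a = test$a[j], b = test$b[j]), r, tolerance, adjust)
    est_k[j] <- fit$estimates["k", "median"]
    lo[j] <- fit$estimates["k", "lo"]
    hi[j] <- fit$estimates["k", "hi"]
  }
  est_sign <- ifelse(est_k > 0, "entrenched", "senescing")
  lev <- c("senescing", "entrenched")
  tab <- table(factor(true_sign, lev), factor(est_sign, lev),
               dnn = c("true", "inferred"))
  wrong <- true_sign != est_sign
  list(table = tab,
       misclassification = mean(wrong),
       overlap_zero = sum(wrong & lo <= 0 & hi >= 0),
       details = data.frame(true_k = test$k, est_k = est_k, lo = lo, hi = hi,
                            misclassified = wrong))
}

#' Robustness of inference to a rescaled overall substitution rate
#'
#' Simulates a test set at `factor` times the substitution rate assumed by
#' the reference table, fits each against the unchanged reference, and
#' reports the signed bias of k (and fraction) and the sign-classification
#' outcome.
#'
#' @param subtree_list The `subtree_list` the reference was built on.
#' @param ref An `abc_reference` table.
#' @param n_test Number of test simulations.
#' @param factor Rate multiplier for the test simulations (default 2).
#' @param tolerance Rejection tolerance.
#' @param min_abs_k Restrict test draws to `|k| >=` this bound.
#' @param cap Maximum subtrees per simulation.
#' @return List with `k_bias`, `fraction_bias`, `misclassification`, and
#'   the per-test `details`.
#' @export
robustness_rate_doubling <- function(subtree_list, ref, n_test = 50,
                                     factor = 2, tolerance = 0.01,
                                     min_abs_k = 1, cap = 100000) {
  prior <- attr(ref, "prior")
  mu <- attr(ref, "mu")
  if (is.null(mu)) mu <- 1
  test <- simulate_test_set(subtree_list, prior, n_test, min_abs_k,
                            mu_factor = factor, cap = cap,
                            model = rate_model(mu))
  cm <- abc_confusion(ref, tolerance = tolerance, test = test,
                      min_abs_k = min_abs_k)
  det <- cm$details
  list(k_bias = mean(det$est_k - det$true_k),
       fraction_bias = if (prior$model == "three_param") {
         frac_est <- vapply(seq_len(nrow(test)), function(j) {
           fit <- abc_fit(c(a = test$a[j], b = test$b[j]), ref, tolerance)
           fit$estimates["fraction", "median"]
         }, 0)
         mean(frac_est - test$fraction)
       } else NA_real_,
       misclassification = cm$misclassification,
       details = det)
}
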