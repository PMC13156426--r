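# Diffusion signal models (ADC, kurtosis, sphere, ball+sphere), bounded
# multi-start least-squares fitting, corrected AIC, and first-order error
# propagation.

.model_param_names <- list(
  adc = c("S0", "D"),
  dki = c("S0", "D", "K"),
  sphere = c("S0", "D", "R"),
  ballsphere = c("S0", "f_sphere", "D_sphere", "R", "D_ball")
)

.model_lower <- list(
  adc = c(S0 = 0.5, D = 0.01),
  dki = c(S0 = 0.5, D = 0.01, K = 0),
  sphere = c(S0 = 0.5, D = 0.01, R = 0.5),
  ballsphere = c(S0 = 0.5, f_sphere = 0, D_sphere = 0.01, R = 0.5,
                 D_ball = 0.01)
)

.model_upper <- list(
  adc = c(S0 = 1.5, D = 3),
  dki = c(S0 = 1.5, D = 3, K = 5),
  sphere = c(S0 = 1.5, D = 3, R = 40),
  ballsphere = c(S0 = 1.5, f_sphere = 1, D_sphere = 3, R = 40, D_ball = 3)
)

# Fixed deterministic multi-start grids (8 starts per model).
.model_starts <- function(model) {
  switch(model,
    adc = cbind(S0 = 1, D = c(0.1, 0.3, 0.5, 0.8, 1.2, 1.8, 2.4, 3.0)),
    dki = {
      g <- expand.grid(D = c(0.5, 1.0, 1.5, 2.0), K = c(0.5, 2))
      cbind(S0 = 1, D = g$D, K = g$K)
    },
    sphere = {
      g <- expand.grid(D = c(0.5, 1.0), R = c(3, 8, 15, 25))
      cbind(S0 = 1, D = g$D, R = g$R)
    },
    ballsphere = {
      g <- expand.grid(f_sphere = c(0.15, 0.35), R = c(5, 12),
                       D_ball = c(0.5, 1.0))
      cbind(S0 = 1, f_sphere = g$f_sphere, D_sphere = 0.8, R = g$R,
            D_ball = g$D_ball)
    },
    stop("unknown model: ", model)
  )
}

#' Predicted normalised signal for a diffusion model
#'
#' Forward evaluation over a set of sequences:
#' * `adc`: S0 exp(-b D)
#' * `dki`: S0 exp(-b D + K b^2 D^2 / 6)
#' * `sphere`: S0 * E_sphere(b, delta, Delta; R, D) ([sphere_signal()])
#' * `ballsphere`: S0 * (f_sphere E_sphere(..., R, D_sphere) +
#'   (1 - f_sphere) exp(-b D_ball))
#'
#' @param model one of `"adc"`, `"dki"`, `"sphere"`, `"ballsphere"`.
#' @param params named numeric vector (or list) of model parameters; see
#'   `esldmri:::.model_param_names`.
#' @param sequences data frame with columns `b`, `delta`, `Delta` (the
#'   diffusion-weighted rows of an `esl_protocol`).
#' @return Numeric vector of predicted signals, one per sequence.
#' @examples
#' seqs <- steam_sequences()
#' model_forward("adc", c(S0 = 1, D = 2), seqs)
#' @export
model_forward <- function(model, params, sequences) {
  p <- unlist(params)
  need <- .model_param_names[[model]]
  if (is.null(need)) stop("unknown model: ", model)
  if (!all(need %in% names(p)))
    stop("model '", model, "' needs parameters: ", paste(need, collapse = ", "))
  b <- sequences$b
  switch(model,
    adc = p["S0"] * exp(-b * p["D"]),
    dki = p["S0"] * exp(-b * p["D"] + p["K"] * b^2 * p["D"]^2 / 6),
    sphere = p["S0"] * as.numeric(
      sphere_signal(b, sequences$delta, sequences$Delta,
                    D = p["D"], R = p["R"])),
    ballsphere = {
      sph <- as.numeric(sphere_signal(b, sequences$delta, sequences$Delta,
                                      D = p["D_sphere"], R = p["R"]))
      p["S0"] * (p["f_sphere"] * sph +
                   (1 - p["f_sphere"]) * exp(-b * p["D_ball"]))
    }
  )
}

#' Corrected Akaike information criterion for a least-squares fit
#'
#' AICc = n log(rss/n) + 2 k' + 2 k' (k' + 1) / (n - k' - 1). With
#' `count_variance = TRUE` (default) k' = k + 1, counting the Gaussian
#' residual-variance parameter alongside the k model parameters, the
#' standard convention for least-squares AIC.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of data points.
#' @param k number of fitted model parameters.
#' @param count_variance whether to add the residual variance to the
#'   parameter count.
#' @return AICc value; `NA` with a warning when n <= k' + 1.
#' @export
aicc <- function(rss, n, k, count_variance = TRUE) {
  if (rss <= 0) stop("aicc needs rss > 0")
  kk <- if (count_variance) k + 1 else k
  if (n <= kk + 1) {
    warning("AICc undefined: n <= k' + 1")
    return(NA_real_)
  }
  n * log(rss / n) + 2 * kk + 2 * kk * (kk + 1) / (n - kk - 1)
}

#' First-order standard errors for least-squares parameter estimates
#'
#' SE = sqrt(diag(sigma^2 (J^T J)^-1)) with sigma^2 = rss / (n - k), J the
#' Jacobian of model predictions at the optimum. A rank-deficient J^T J is
#' inverted with a pseudo-inverse and the result flagged via attribute
#' `reliable = FALSE`.
#'
#' @param jacobian n x k Jacobian matrix at the optimum.
#' @param rss residual sum of squares.
#' @param n number of data points.
#' @param k number of fitted parameters.
#' @return Numeric vector of per-parameter standard errors.
#' @export
param_se <- function(jacobian, rss, n, k) {
  sigma2 <- if (n > k) rss / (n - k) else NA_real_
  jtj <- crossprod(jacobian)
  reliable <- TRUE
  cov <- tryCatch(solve(jtj), error = function(e) NULL)
  if (is.null(cov) || !all(is.finite(cov))) {
    warning("J^T J singular; using pseudo-inverse, SEs unreliable")
    s <- svd(jtj)
    pos <- s$d > max(s$d) * 1e-12
    cov <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    reliable <- FALSE
  }
  se <- sqrt(pmax(diag(cov) * sigma2, 0))
  names(se) <- colnames(jacobian)
  attr(se, "reliable") <- reliable
  se
}

# Central-difference Jacobian of model_forward w.r.t. params.
.num_jacobian <- function(model, params, sequences) {
  k <- length(params)
  J <- matrix(0, nrow(sequences), k, dimnames = list(NULL, names(params)))
  for (j in seq_len(k)) {
    h <- 1e-6 * (1 + abs(params[j]))
    pp <- pm <- params
    pp[j] <- pp[j] + h
    pm[j] <- pm[j] - h
    J[, j] <- (model_forward(model, pp, sequences) -
                 model_forward(model, pm, sequences)) / (2 * h)
  }
  J
}

#' Fit a diffusion signal model to a signal profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) minimising the sum of squared differences between
#' the measured profile and [model_forward()]. The optimiser is started from
#' a fixed deterministic grid (default 8 starts) and the lowest-RSS solution
#' is kept. Bounds: S0 in [0.5, 1.5], diffusivities in [0.01, 3] um^2/ms,
#' K in [0, 5], R in [0.5, 40] um, f_sphere in [0, 1].
#'
#' @param signal numeric vector of normalised signals, one per sequence.
#' @param sequences data frame with columns `b`, `delta`, `Delta` matching
#'   `signal`.
#' @param model one of `"adc"`, `"dki"`, `"sphere"`, `"ballsphere"`.
#' @param starts optional matrix of start values (columns named as the model
#'   parameters) overriding the default grid.
#' @param compute_se whether to compute first-order standard errors.
#' @param count_variance passed to [aicc()].
#' @return A list of class `dmri_fit`: `model`, `params` (named vector),
#'   `se`, `rss`, `n`, `k`, `aicc`, `converged`, `at_bound` (logical per
#'   parameter), `fitted`.
#' @examples
#' seqs <- steam_sequences()
#' y <- model_forward("adc", c(S0 = 1, D = 0.7), seqs)
#' fit_model(y, seqs, "adc")$params
#' @export
fit_model <- function(signal, sequences, model,
                      starts = NULL, compute_se = TRUE,
                      count_variance = TRUE) {
  pn <- .model_param_names[[model]]
  if (is.null(pn)) stop("unknown model: ", model)
  n <- length(signal)
  k <- length(pn)
  if (n < k + 2) stop("profile too short: need at least k + 2 points")
  if (!all(is.finite(signal))) stop("signal profile contains non-finite values")
  lower <- .model_lower[[model]]
  upper <- .model_upper[[model]]
  if (is.null(starts)) starts <- .model_starts(model)
  starts <- starts[, pn, drop = FALSE]
  # deterministic extra start from a closed-form log-linear ADC fit, so
  # models nesting ADC never fit worse than it
  if (model %in% c("dki", "ballsphere") && all(signal > 0)) {
    b <- sequences$b
    ly <- log(signal)
    D0 <- min(max(-stats::cov(b, ly) / stats::var(b), 0.01), 3)
    S0 <- min(max(exp(mean(ly) + D0 * mean(b)), 0.5), 1.5)
    extra <- if (model == "dki") c(S0 = S0, D = D0, K = 0.01) else
      c(S0 = S0, f_sphere = 0.01, D_sphere = 0.8, R = 5, D_ball = D0)
    starts <- rbind(starts, extra[pn])
  }

  resid_fn <- function(p) {
    names(p) <- pn
    signal - model_forward(model, p, sequences)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[i, ], lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fn, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_ok <- n_ok + 1L
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(structure(list(model = model,
                          params = stats::setNames(rep(NA_real_, k), pn),
                          se = NULL, rss = NA_real_, n = n, k = k,
                          aicc = NA_real_, converged = FALSE,
                          at_bound = NULL, fitted = NULL,
                          n_starts_converged = 0L),
                     class = "dmri_fit"))
  }
  p <- stats::setNames(best$fit$par, pn)
  rss <- best$rss
  at_bound <- (p - lower) < 1e-6 * (upper - lower) |
    (upper - p) < 1e-6 * (upper - lower)
  se <- NULL
  if (compute_se) {
    J <- .num_jacobian(model, p, sequences)
    se <- param_se(J, rss, n, k)
  }
  ic <- if (rss > 0) aicc(rss, n, k, count_variance) else -Inf
  structure(list(model = model, params = p, se = se, rss = rss, n = n,
                 k = k, aicc = ic, converged = TRUE, at_bound = at_bound,
                 fitted = signal - best$fit$fvec,
                 n_starts_converged = n_ok),
            class = "dmri_fit")
}

#' @export
print.dmri_fit <- function(x, ...) {
  cat("Diffusion model fit:", x$model, "\n")
  if (!x$converged) {
    cat("  (no start converged)\n")
    return(invisible(x))
  }
  tab <- data.frame(estimate = signif(x$params, 4))
  if (!is.null(x$se)) tab$se <- signif(x$se, 3)
  tab$at_bound <- x$at_bound
  print(tab)
  cat(sprintf("  RSS = %.4g  n = %d  AICc = %.2f\n", x$rss, x$n, x$aicc))
  invisible(x)
}

#' Reference parameter sets for benign prostate tissue components
#'
#' Published aggregate-fit parameter values for benign prostate epithelium
#' and stroma under each signal model (diffusivities in um^2/ms, radii in
#' um). These are the package defaults for the synthetic phantom's
#' component forward models and useful ground truths for round-trip tests.
#'
#' @param model model name.
#' @param component `"epithelium"` or `"stroma"`.
#' @return Named numeric vector of parameters for [model_forward()].
#' @examples
#' reference_params("ballsphere", "epithelium")
#' @export
reference_params <- function(model = c("ballsphere", "adc", "dki", "sphere"),
                             component = c("epithelium", "stroma")) {
  model <- match.arg(model)
  component <- match.arg(component)
  tab <- list(
    epithelium = list(
      adc = c(S0 = 0.975, D = 0.433),
      dki = c(S0 = 0.999, D = 0.584, K = 1.52),
      sphere = c(S0 = 0.995, D = 0.564, R = 23.5),
      ballsphere = c(S0 = 1.000, f_sphere = 0.278, D_sphere = 0.641,
                     R = 6.42, D_ball = 0.611)
    ),
    stroma = list(
      adc = c(S0 = 0.983, D = 0.708),
      dki = c(S0 = 1.000, D = 0.899, K = 0.885),
      sphere = c(S0 = 0.994, D = 0.847, R = 36.5),
      ballsphere = c(S0 = 1.000, f_sphere = 0.175, D_sphere = 0.532,
                     R = 6.38, D_ball = 0.943)
    )
  )
  tab[[component]][[model]]
}
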