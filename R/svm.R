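# Soft-margin linear classifier and Platt probability calibration.
#
# The margin classifier minimises
#   0.5 ||w||^2 + C * sum_i c_i * max(0, 1 - y_i (w.x_i + b))^2
# with y in {-1,+1} and c_i = j for positive examples, 1 for negatives
# (the cost factor j makes errors on positives outweigh errors on
# negatives). The squared hinge keeps the objective differentiable so a
# quasi-Newton solve is deterministic and fast; the optimum is the L2-SVM
# solution at the same (C, j).

#' Fit a soft-margin linear classifier
#'
#' @param X numeric matrix (rows = examples, already standardised by the
#'   caller if desired).
#' @param y binary labels (0/1).
#' @param C error/margin trade-off (larger = less regularisation).
#' @param j cost factor multiplying the penalty of positive-class errors.
#' @param maxit optimiser iteration cap.
#' @return List with `w`, `b`, `converged`.
#' @export
fit_linear_svm <- function(X, y, C = 1, j = 1, maxit = 500L) {
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) {
    stop("training set must contain both labels", call. = FALSE)
  }
  ys <- ifelse(y == 1, 1, -1)
  cost <- ifelse(y == 1, C * j, C)
  d <- ncol(X)
  obj <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    xi <- pmax(0, 1 - ys * (drop(X %*% w) + b))
    0.5 * sum(w * w) + sum(cost * xi^2)
  }
  grad <- function(par) {
    w <- par[seq_len(d)]; b <- par[d + 1L]
    xi <- pmax(0, 1 - ys * (drop(X %*% w) + b))
    coef <- -2 * cost * ys * xi
    c(w + drop(t(X) %*% coef), sum(coef))
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L],
       converged = fit$convergence == 0L)
}

#' Decision values of a linear classifier
#'
#' @param model output of [fit_linear_svm()].
#' @param X feature matrix on the model's scale.
#' @return Numeric vector `X w + b`.
#' @export
decision_values <- function(model, X) {
  drop(X %*% model$w) + model$b
}

#' Platt sigmoid calibration
#'
#' Fits `P(y = 1 | f) = 1 / (1 + exp(A f + B))` to decision values by
#' maximum likelihood with the standard smoothed targets
#' `t+ = (N+ + 1)/(N+ + 2)`, `t- = 1/(N- + 2)`, which regularise the fit on
#' small calibration sets. On failure to converge the fallback `A = -1,
#' B = 0` is returned with a warning.
#'
#' @param f decision values on a held-out calibration set.
#' @param y binary labels (0/1) of the same examples.
#' @return List with `A`, `B`, `converged`.
#' @export
fit_platt <- function(f, y) {
  stopifnot(length(f) == length(y), all(y %in% c(0, 1)))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  t_pos <- (n_pos + 1) / (n_pos + 2)
  t_neg <- 1 / (n_neg + 2)
  t <- ifelse(y == 1, t_pos, t_neg)
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # stable log(1+exp(z)) and cross-entropy in terms of z
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  gr <- function(par) {
    z <- par[1] * f + par[2]
    p <- 1 / (1 + exp(-z))     # sigmoid(z) = 1 - P(y = 1)
    d <- p - (1 - t)
    c(sum(d * f), sum(d))
  }
  init <- c(0, log((n_neg + 1) / (n_pos + 1)))
  fit <- tryCatch(
    stats::optim(init, nll, gr, method = "BFGS",
                 control = list(maxit = 200L, reltol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit) || fit$convergence != 0L || !all(is.finite(fit$par))) {
    warning("Platt sigmoid fit did not converge; using A = -1, B = 0")
    return(list(A = -1, B = 0, converged = FALSE))
  }
  list(A = fit$par[1], B = fit$par[2], converged = TRUE)
}

#' Calibrated probability from decision values
#'
#' @param platt list with `A`, `B`.
#' @param f decision values.
#' @return Probabilities in (0, 1).
#' @export
platt_probability <- function(platt, f) {
  z <- platt$A * f + platt$B
  1 / (1 + exp(z))
}

# Standardisation helper: centre/scale statistics from a training matrix.
fit_scaler <- function(X) {
  centre <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(centre = centre, scale = scale)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$centre, "-"), 2, scaler$scale, "/")
}
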