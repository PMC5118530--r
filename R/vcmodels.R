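#' Specify a variance-components model
#'
#' The model is y ~ N(X beta, Omega) with Omega = sigma2 * (sum_c f_c K_c +
#' e2 * I), where the K_c are PSD relatedness kernels (typically 2*Phi from
#' [pedigree_kinship()] and/or 2*E from [empirical_kinship()]) and the
#' variance fractions f_c, e2 live on the unit simplex. All inputs must share
#' one complete-case individual index; rows with missing response or
#' covariates must be dropped before construction.
#'
#' @param y numeric response vector, no NA.
#' @param X fixed-effect design matrix including the intercept.
#' @param kernels list of one or two n x n symmetric PSD matrices.
#' @param kernel_names names for the variance fractions (default
#'   `h_r2` and, if present, `h_geff2`).
#' @return A list of class `"variance_model"`.
#' @export
variance_model <- function(y, X, kernels,
                           kernel_names = c("h_r2", "h_geff2")[seq_along(kernels)]) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (!is.list(kernels)) kernels <- list(kernels)
  n <- length(y)
  stopifnot(nrow(X) == n, all(vapply(kernels, nrow, 0L) == n),
            all(vapply(kernels, ncol, 0L) == n))
  if (anyNA(y) || anyNA(X)) stop("variance_model requires complete cases")
  if (stats::var(y) <= 0) stop("response has no variance")
  if (n <= ncol(X) + length(kernels)) {
    stop("need more observations than fixed effects + variance components")
  }
  for (K in kernels) {
    if (max(abs(K - t(K))) > 1e-8) stop("kernel is not symmetric")
  }
  structure(list(y = y, X = X, kernels = lapply(kernels, unclass),
                 kernel_names = kernel_names, n = n),
            class = "variance_model")
}

# Gaussian profile log-likelihood on a diagonalized scale.
# yt, Xt: rotated response/design; v: positive eigenvalue profile of the
# unit-scale covariance. beta and sigma2 are profiled out (ML, divisor n).
.ll_diag <- function(yt, Xt, v, want_fit = FALSE) {
  w <- 1 / sqrt(v)
  fit <- stats::lm.fit(Xt * w, yt * w)
  rss <- sum(fit$residuals^2)
  n <- length(yt)
  ll <- -0.5 * (n * log(2 * pi) + n * log(rss / n) + sum(log(v)) + n)
  if (!want_fit) return(ll)
  sigma2 <- rss / n
  XtWX <- crossprod(Xt * w)
  cov_beta <- tryCatch(sigma2 * solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(Xt), ncol(Xt))
  })
  list(ll = ll, beta = fit$coefficients, beta_se = sqrt(diag(cov_beta)),
       sigma2 = sigma2)
}

# Profile the total genetic fraction gamma in v_i = gamma*d_i + (1-gamma)
# on [0, 1]. Prefers the boundary gamma = 0 on likelihood ties (within tol),
# so unidentifiable no-relatedness designs collapse cleanly to OLS.
.profile_gamma <- function(yt, Xt, d, tol = 1e-9) {
  upper <- 1 - 1e-8
  f <- function(g) .ll_diag(yt, Xt, g * d + (1 - g))
  opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = tol)
  g <- opt$maximum; ll <- opt$objective
  ll0 <- f(0); ll1 <- f(upper)
  if (ll1 > ll + 1e-8) { g <- upper; ll <- ll1 }
  if (ll0 >= ll - 1e-8) { g <- 0; ll <- ll0 }
  if (g >= upper) g <- 1
  list(gamma = g, ll = ll)
}

# Eigen-rotation of a kernel plus the fixed design (reusable across fits
# that share the kernel and design -- the scan fast path).
.vc_rotation <- function(K, X) {
  eg <- eigen(K, symmetric = TRUE)
  list(U = eg$vectors, d = pmax(eg$values, 0), Xt = crossprod(eg$vectors, X))
}

#' Maximum-likelihood fit of a variance-components model
#'
#' Single-kernel models use a one-time eigendecomposition of the kernel so
#' each likelihood evaluation is O(n) (the scan fast path). Two-kernel
#' models profile over the kernel-mixing weight lambda (K(lambda) =
#' (1-lambda) K1 + lambda K2) on a grid with golden-section refinement, with
#' one eigendecomposition per candidate lambda; the total genetic fraction,
#' beta and sigma2 are profiled out in closed form at every step. Boundary
#' solutions (a fraction at 0 or 1) are legitimate results, not errors.
#'
#' @param model a [variance_model()].
#' @param lambda_grid grid for the two-kernel mixing weight.
#' @param refine golden-section refinement of lambda around the grid optimum
#'   (default TRUE; grid-only when a `cache` is supplied).
#' @param cache optional precomputed rotation cache from [vc_cache()]; must
#'   match the model's kernels and design.
#' @return A list of class `"vcfit"`: `fractions` (named, summing to 1 with
#'   the environmental fraction `e2` last), `sigma2`, `beta`, `beta_se`,
#'   `loglik`, `converged`, `n`.
#' @export
fit_ml <- function(model, lambda_grid = seq(0, 1, length.out = 21),
                   refine = TRUE, cache = NULL) {
  stopifnot(inherits(model, "variance_model"))
  y <- model$y; X <- model$X
  nk <- length(model$kernels)
  if (nk == 1) {
    rot <- if (!is.null(cache)) cache$rotations[[1]] else .vc_rotation(model$kernels[[1]], X)
    yt <- crossprod(rot$U, y)
    pr <- .profile_gamma(yt, rot$Xt, rot$d)
    best <- list(gamma = pr$gamma, lambda = NA_real_, ll = pr$ll, rot = rot, yt = yt)
    fractions <- stats::setNames(c(pr$gamma, 1 - pr$gamma),
                                 c(model$kernel_names[1], "e2"))
  } else if (nk == 2) {
    eval_lambda <- function(lam, rot = NULL) {
      if (is.null(rot)) {
        K <- (1 - lam) * model$kernels[[1]] + lam * model$kernels[[2]]
        rot <- .vc_rotation(K, X)
      }
      yt <- crossprod(rot$U, y)
      pr <- .profile_gamma(yt, rot$Xt, rot$d)
      list(gamma = pr$gamma, lambda = lam, ll = pr$ll, rot = rot, yt = yt)
    }
    if (!is.null(cache)) {
      lambda_grid <- cache$lambda_grid
      fits <- lapply(seq_along(lambda_grid), function(i) {
        eval_lambda(lambda_grid[i], rot = cache$rotations[[i]])
      })
      refine <- FALSE
    } else {
      fits <- lapply(lambda_grid, eval_lambda)
    }
    lls <- vapply(fits, `[[`, 0, "ll")
    best <- fits[[which.max(lls)]]
    if (refine && length(lambda_grid) > 2) {
      i <- which.max(lls)
      lo <- lambda_grid[max(1, i - 1L)]
      hi <- lambda_grid[min(length(lambda_grid), i + 1L)]
      opt <- stats::optimize(function(l) eval_lambda(l)$ll, c(lo, hi),
                             maximum = TRUE, tol = 1e-6)
      if (opt$objective > best$ll) best <- eval_lambda(opt$maximum)
    }
    # at gamma = 0 lambda is unidentifiable; report it as 0
    lam <- if (best$gamma == 0) 0 else best$lambda
    fractions <- stats::setNames(
      c(best$gamma * (1 - lam), best$gamma * lam, 1 - best$gamma),
      c(model$kernel_names, "e2"))
  } else {
    stop("only one or two kernels are supported")
  }
  g <- best$gamma
  v <- if (nk == 1 || is.na(best$lambda)) g * best$rot$d + (1 - g) else g * best$rot$d + (1 - g)
  at_opt <- .ll_diag(best$yt, best$rot$Xt, v, want_fit = TRUE)
  beta <- stats::setNames(at_opt$beta, colnames(X))
  structure(list(fractions = fractions, sigma2 = at_opt$sigma2,
                 beta = beta, beta_se = stats::setNames(at_opt$beta_se, colnames(X)),
                 loglik = at_opt$ll, converged = is.finite(at_opt$ll),
                 n = model$n, df_fixed = ncol(X)),
            class = "vcfit")
}

#' @export
print.vcfit <- function(x, ...) {
  cat("vcfit: n =", x$n, " logLik =", format(x$loglik, digits = 8), "\n")
  cat("  fractions:", paste(names(x$fractions),
                            signif(x$fractions, 4), sep = " = ", collapse = ", "), "\n")
  cat("  sigma2 =", signif(x$sigma2, 5), "\n")
  invisible(x)
}

#' Precompute eigen-rotations for repeated two-kernel fits
#'
#' For calibration loops that refit the same kernels and fixed design against
#' thousands of simulated responses: eigendecompositions of K(lambda) over a
#' fixed lambda grid are done once, after which every fit costs O(n^2) per
#' lambda. Fits using a cache take the grid optimum (no refinement).
#'
#' @param kernels list of one or two kernels as in [variance_model()].
#' @param X fixed design matrix.
#' @param lambda_grid mixing-weight grid (ignored for a single kernel).
#' @return A list of class `"vc_cache"`.
#' @export
vc_cache <- function(kernels, X, lambda_grid = seq(0, 1, length.out = 21)) {
  if (!is.list(kernels)) kernels <- list(kernels)
  X <- as.matrix(X)
  if (length(kernels) == 1) {
    rotations <- list(.vc_rotation(unclass(kernels[[1]]), X))
    lambda_grid <- NA_real_
  } else {
    rotations <- lapply(lambda_grid, function(lam) {
      K <- (1 - lam) * unclass(kernels[[1]]) + lam * unclass(kernels[[2]])
      .vc_rotation(K, X)
    })
  }
  structure(list(rotations = rotations, lambda_grid = lambda_grid,
                 n_kernels = length(kernels)),
            class = "vc_cache")
}

#' Likelihood-ratio test between nested variance-components fits
#'
#' Lambda = 2 (logLik_full - logLik_null), clipped at zero (a small negative
#' difference beyond solver tolerance triggers a warning), with the p-value
#' from the upper tail of chi-square with `df` degrees of freedom.
#'
#' @param fit_full,fit_null [fit_ml()] results on the same response and
#'   individuals, null nested in full.
#' @param df degrees of freedom of the test.
#' @return List with `stat`, `df`, `p`.
#' @export
lrt <- function(fit_full, fit_null, df = 1) {
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  if (stat < -1e-4) {
    warning("full model log-likelihood below null by ", format(-stat / 2),
            "; statistic clipped to 0 (check nesting / convergence)")
  }
  stat <- max(0, stat)
  list(stat = stat, df = df,
       p = if (stat == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE))
}

#' P-value under the 1/2:1/2 chi-square mixture null
#'
#' Boundary null distribution for testing a variance fraction constrained to
#' be non-negative: a 50:50 mixture of a point mass at zero and chi-square
#' with 1 df. p = 0.5 P(chi2_1 >= Lambda) for Lambda > 0 and p = 1 at
#' Lambda = 0 (the point mass carries the event).
#'
#' @param stat non-negative likelihood-ratio statistic.
#' @return p-value in (0, 1].
#' @export
mixture_p <- function(stat) {
  if (any(stat < 0)) stop("mixture_p requires a non-negative statistic")
  ifelse(stat == 0, 1, 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Direct (Cholesky) evaluation of the profile log-likelihood at arbitrary
# fractions -- the slow, rotation-free route used for standard errors and
# internal cross-checks of the eigen fast path.
.vc_loglik_direct <- function(y, X, kernels, fractions) {
  e2 <- 1 - sum(fractions)
  if (e2 < -1e-10 || any(fractions < -1e-10)) return(-Inf)
  V0 <- diag(max(e2, 1e-12), length(y))
  for (i in seq_along(kernels)) V0 <- V0 + fractions[i] * unclass(kernels[[i]])
  R <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -0.5 * (n * log(2 * pi) + n * log(rss / n) + 2 * sum(log(diag(R))) + n)
}
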