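# Binary C-SVC solved exactly as the dual QP with quadprog. LIBSVM-style
# conventions: poly kernel (gamma x'z + coef0)^degree with gamma = 1/n_features,
# coef0 = 0, C = 1 by default. No SVM package is available offline, and the
# exact QP is deterministic (no working-set heuristics), which the training
# contracts require.

svm_kernel <- function(X, Z, kernel, degree, gamma, coef0) {
  G <- X %*% t(Z)
  switch(kernel,
         linear = G,
         polynomial = (gamma * G + coef0)^degree,
         stop("unknown kernel: ", kernel))
}

#' Fit a binary SVM (linear or polynomial kernel)
#'
#' @param X numeric feature matrix (rows = samples)
#' @param y labels in {-1, +1} (or a 2-level factor / logical)
#' @param kernel "linear" or "polynomial"
#' @param degree polynomial degree
#' @param cost soft-margin C
#' @param gamma kernel scale; default 1/ncol(X)
#' @param coef0 polynomial offset
#' @param scale standardize columns before fitting
#' @return object of class \code{rpl_svm}
#' @export
svm_fit <- function(X, y, kernel = c("linear", "polynomial"), degree = 3,
                    cost = 1, gamma = NULL, coef0 = 0, scale = FALSE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  if (is.factor(y)) y <- ifelse(y == levels(y)[2], 1, -1)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  stopifnot(all(y %in% c(-1, 1)), nrow(X) == length(y))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (scale) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd); scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  n <- nrow(X)
  K <- svm_kernel(X, X, kernel, degree, gamma, coef0)
  D <- (y %o% y) * K
  # ridge large enough that the active-set solver's solution (and hence the
  # support set and bias) is unique and independent of row order; the kernel
  # matrix is typically rank-deficient (linear kernel in low dimension,
  # near-duplicate samples)
  D <- D + diag(1e-4 * max(1, mean(diag(D))), n)
  # min 1/2 a'Da - 1'a  s.t.  y'a = 0, 0 <= a <= C
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-cost, n))
  sol <- quadprog::solve.QP(D, rep(1, n), Amat, bvec, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), cost)
  sv <- alpha > 1e-6 * cost
  # bias: mean KKT residual over margin vectors (0 < alpha < C); for fully
  # separable data with no margin vectors, midpoint of the class extremes.
  # f0 is invariant to null-space ambiguity of the dual, so b (and the
  # decision function) do not depend on training-row order.
  f0 <- as.vector(K[, sv, drop = FALSE] %*% (alpha[sv] * y[sv]))
  marg <- sv & alpha < cost * (1 - 1e-6)
  b <- if (any(marg)) mean(y[marg] - f0[marg])
       else -(max(f0[y == -1]) + min(f0[y == 1])) / 2
  structure(list(kernel = kernel, degree = degree, gamma = gamma,
                 coef0 = coef0, cost = cost,
                 sv = X[sv, , drop = FALSE], sv_coef = alpha[sv] * y[sv],
                 b = b, center = ctr, scale = scl, scaled = scale,
                 trained = TRUE),
            class = "rpl_svm")
}

#' Decision values of a fitted SVM
#'
#' @param model \code{rpl_svm}
#' @param X feature matrix
#' @return numeric decision values; sign gives the class (+1 positive)
#' @export
svm_predict <- function(model, X) {
  stopifnot(inherits(model, "rpl_svm"), isTRUE(model$trained))
  X <- as.matrix(X)
  if (model$scaled)
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  K <- svm_kernel(X, model$sv, model$kernel, model$degree, model$gamma,
                  model$coef0)
  as.vector(K %*% model$sv_coef) + model$b
}
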