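#' Correlation-matrix PCA of a feature table
#'
#' Eigen-decomposition of the feature correlation matrix (features are
#' standardised to unit variance first), with component scores and a fixed
#' sign convention: the largest-magnitude loading entry of each component is
#' made positive.
#'
#' @param tab Well-level feature table (or a bare numeric matrix).
#' @return A `pca_model`: `eigenvalues`, `vectors` (eigenvectors),
#'   `loadings` (eigenvectors scaled by sqrt(eigenvalue)), `scores`,
#'   `center`/`scale` used for standardisation, feature names.
#' @export
fit_pca <- function(tab) {
  m <- if (is.matrix(tab)) tab else {assert_feature_table(tab); feature_matrix(tab)}
  if (nrow(m) <= 2) stop("need more than 2 rows to fit a PCA")
  if (any(!is.finite(m))) stop("non-finite values in feature matrix")
  center <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(scl == 0))
    stop("zero-variance feature(s); run drop_degenerate() first")
  xs <- sweep(sweep(m, 2, center), 2, scl, "/")
  R <- crossprod(xs) / (nrow(m) - 1)
  e <- eigen(R, symmetric = TRUE)
  v <- e$vectors
  # sign convention: largest-|loading| entry positive per component
  flip <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  v <- sweep(v, 2, flip, "*")
  lam <- pmax(e$values, 0)
  colnames(v) <- sprintf("PC%02d", seq_len(ncol(v)))
  rownames(v) <- colnames(m)
  structure(list(eigenvalues = lam,
                 vectors = v,
                 loadings = sweep(v, 2, sqrt(lam), "*"),
                 scores = xs %*% v,
                 center = center, scale = scl,
                 features = colnames(m), n = nrow(m)),
            class = "pca_model")
}

#' Choose the number of retained components
#'
#' @param eigenvalues Non-increasing eigenvalues from correlation-matrix PCA.
#' @param rule `"kaiser"` (count of eigenvalues strictly greater than 1),
#'   `"scree"` (elbow at the maximum second difference of the eigenvalue
#'   curve) or `"fixed"` (use `k`, capped at the number of components).
#' @param k Component count for `rule = "fixed"`.
#' @export
select_components <- function(eigenvalues, rule = c("kaiser", "scree", "fixed"),
                              k = 50) {
  rule <- match.arg(rule)
  if (!length(eigenvalues)) stop("empty eigenvalue vector")
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be non-increasing")
  switch(rule,
    kaiser = sum(eigenvalues > 1),
    scree = {
      if (length(eigenvalues) < 3) return(1L)
      d2 <- diff(diff(eigenvalues))  # second difference at components 2..m-1
      which.max(d2) + 1L
    },
    fixed = min(as.integer(k), length(eigenvalues)))
}

# direct oblimin criterion and gradient (gamma = 0 is direct quartimin)
oblimin_criterion <- function(L, gamma = 0) {
  k <- ncol(L)
  L2 <- L^2
  X <- L2 %*% (matrix(1, k, k) - diag(k))
  if (gamma != 0) {
    p <- nrow(L)
    X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  }
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

#' Oblique (oblimin) rotation by gradient projection
#'
#' Minimises the direct oblimin criterion over oblique rotations of a loading
#' matrix (gradient-projection algorithm). `gamma = 0` gives direct quartimin.
#' Convergence is declared when the projected gradient norm falls below `tol`
#' (the criterion is then stationary well beyond the `1e-8` change level).
#'
#' @param loadings n_features x k unrotated loading matrix, k >= 2.
#' @param gamma Oblimin family parameter (default 0).
#' @param n_starts Number of rotation starts: the identity plus
#'   `n_starts - 1` seeded random orthogonal starts; the solution with the
#'   lowest criterion is returned.
#' @param tol Convergence tolerance on the projected gradient norm.
#' @param f_tol Convergence tolerance on the criterion change per iteration
#'   (either rule suffices; near-flat rotation manifolds stop on this one).
#' @param max_iter Iteration cap per start.
#' @param seed Seed for the random starts.
#' @return list with `loadings` (rotated pattern matrix), `rotation` (the
#'   oblique rotation matrix T with unit-length columns), `phi` (factor
#'   correlation matrix `t(T) %*% T`), `criterion`, `iterations`,
#'   `converged`, and the per-iteration criterion `trace`.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, n_starts = 10,
                           tol = 1e-10, f_tol = 1e-10, max_iter = 1000,
                           seed = 42) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2) stop("rotation needs at least 2 components")
  starts <- vector("list", n_starts)
  starts[[1]] <- diag(k)
  if (n_starts > 1) {
    starts[2:n_starts] <- with_seed(seed, lapply(seq_len(n_starts - 1),
      function(i) qr.Q(qr(matrix(rnorm(k * k), k, k)))))
  }
  best <- NULL
  for (Tmat in starts) {
    fit <- gpa_oblq(A, Tmat, gamma, tol, f_tol, max_iter)
    if (is.null(best) || fit$criterion < best$criterion) best <- fit
  }
  if (!best$converged)
    warning("oblimin rotation did not converge; criterion trace attached")
  colnames(best$loadings) <- colnames(A)
  rownames(best$loadings) <- rownames(A)
  best
}

# Gradient-projection algorithm for oblique rotation (Jennrich 2002 family).
gpa_oblq <- function(A, Tmat, gamma, tol, f_tol, max_iter) {
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vq <- oblimin_criterion(L, gamma)
  f <- vq$f
  G <- -t(t(L) %*% vq$Gq %*% Ti)
  trace <- f
  converged <- FALSE
  iter <- 0
  flat <- 0L  # consecutive near-zero criterion changes (plateau detector)
  while (iter < max_iter) {
    iter <- iter + 1
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(Tmat))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- sweep(X, 2, sqrt(colSums(X^2)), "/")
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vq <- oblimin_criterion(L, gamma)
      if (vq$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    df <- f - vq$f
    f <- vq$f
    trace <- c(trace, f)
    G <- -t(t(L) %*% vq$Gq %*% Ti)
    flat <- if (abs(df) < f_tol) flat + 1L else 0L
    if (flat >= 3L) { converged <- TRUE; break }
  }
  phi <- crossprod(Tmat)
  dimnames(phi) <- list(colnames(A), colnames(A))
  list(loadings = L, rotation = Tmat, phi = phi, criterion = f,
       iterations = iter, converged = converged, trace = trace)
}

# symmetric matrix power via eigen-decomposition
mat_power <- function(S, pow, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (pow < 0 && any(e$values < tol * max(e$values)))
    stop("matrix is (near-)rank-deficient; run drop_degenerate() on the features")
  e$vectors %*% (e$values^pow * t(e$vectors))
}

#' Correlation-preserving (ten Berge) factor scores
#'
#' Computes factor scores by the ten Berge construction: among least-squares
#' score estimates, the one whose score correlation matrix reproduces the
#' factor correlation matrix Phi exactly. With orthogonal factors
#' (`Phi = I`) the scores are uncorrelated with unit variance.
#'
#' @param x Standardised data matrix (n x p, columns mean 0 / sd 1) or a
#'   feature table to be standardised internally.
#' @param loadings Rotated pattern matrix Lambda (p x k).
#' @param phi Factor correlation matrix (k x k).
#' @param R Optional feature correlation matrix; computed from `x` if absent.
#' @return list with `scores` (n x k; their correlation matrix equals `phi`)
#'   and `weights` (p x k matrix W with scores = x %*% W, reusable on new
#'   standardised data).
#' @export
tenberge_scores <- function(x, loadings, phi, R = NULL) {
  if (!is.matrix(x)) { assert_feature_table(x); x <- scale(feature_matrix(x)) }
  Lam <- as.matrix(loadings)
  phi <- as.matrix(phi)
  if (nrow(Lam) != ncol(x) || any(dim(phi) != ncol(Lam)))
    stop("dimension mismatch between data, loadings and phi")
  if (is.null(R)) R <- crossprod(x) / (nrow(x) - 1)
  L <- Lam %*% mat_power(phi, 0.5)
  Rm <- mat_power(R, -0.5)
  Ri <- mat_power(R, -1)
  C <- Rm %*% L %*% mat_power(t(L) %*% Ri %*% L, -0.5)
  W <- Rm %*% C %*% mat_power(phi, 0.5)
  colnames(W) <- colnames(Lam)
  list(scores = x %*% W, weights = W)
}

#' Reduce a QC'd well-level table to rotated component scores
#'
#' The full dimension-reduction stage: correlation-matrix PCA, component
#' selection, optional oblimin rotation of the retained loadings and ten
#' Berge scores on the rotated solution. With `rotation = "none"` the scores
#' are the ordinary (unit-variance) PCA scores.
#'
#' @param tab Well-level feature table.
#' @param rule,k Component selection (see [select_components()]);
#'   default: fixed k = 50.
#' @param rotation `"oblimin"` (default) or `"none"`.
#' @param gamma Oblimin parameter.
#' @param n_starts Rotation starts passed to [oblimin_rotate()]; the stage
#'   stage default is the single identity start, the standard practice for
#'   screen-scale loading matrices.
#' @return A `reduction_model`: standardisation parameters, eigenvalues,
#'   unrotated and rotated loadings, rotation matrix, `phi`, score weights,
#'   `k`, `scores` (data.frame of metadata + PC columns). Use
#'   [predict.reduction_model()] to project new records.
#' @export
reduce_profiles <- function(tab, rule = "fixed", k = 50,
                            rotation = c("oblimin", "none"), gamma = 0,
                            n_starts = 1) {
  rotation <- match.arg(rotation)
  assert_feature_table(tab)
  pca <- fit_pca(tab)
  kk <- select_components(pca$eigenvalues, rule, k)
  if (kk < 1) stop("component selection returned k = 0")
  A <- pca$loadings[, seq_len(kk), drop = FALSE]
  xs <- sweep(sweep(feature_matrix(tab), 2, pca$center), 2, pca$scale, "/")
  R <- crossprod(xs) / (nrow(xs) - 1)
  if (rotation == "oblimin" && kk >= 2) {
    rot <- oblimin_rotate(A, gamma, n_starts = n_starts)
    Lam <- rot$loadings; phi <- rot$phi; Tmat <- rot$rotation
    rot_info <- rot[c("converged", "iterations", "criterion")]
  } else {
    Lam <- A; phi <- diag(kk); Tmat <- diag(kk)
    dimnames(phi) <- list(colnames(A), colnames(A))
    rot_info <- NULL
  }
  ts <- tenberge_scores(xs, Lam, phi, R)
  sc <- as.data.frame(ts$scores)
  names(sc) <- sprintf("PC%02d", seq_len(kk))
  model <- structure(list(center = pca$center, scale = pca$scale,
                          eigenvalues = pca$eigenvalues,
                          unrotated = A, loadings = Lam,
                          rotation_matrix = Tmat, phi = phi,
                          weights = ts$weights,
                          rule = rule, k = kk, rotation = rotation,
                          rotation_info = rot_info,
                          features = pca$features),
                     class = "reduction_model")
  model$scores <- cbind(as.data.frame(tab)[, META_COLS], sc)
  model
}

#' Project records into the fitted component space
#'
#' Standardises `newdata` with the training centre/scale and applies the
#' stored ten Berge score weights; no parameter is re-estimated, so held-out
#' or image-level records can be scored without leakage.
#'
#' @param object A `reduction_model`.
#' @param newdata Feature table containing at least the training features.
#' @param ... Unused.
#' @return data.frame of metadata + component score columns.
#' @export
predict.reduction_model <- function(object, newdata, ...) {
  assert_feature_table(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing))
    stop("newdata lacks trained features: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  m <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  xs <- sweep(sweep(m, 2, object$center), 2, object$scale, "/")
  sc <- as.data.frame(xs %*% object$weights)
  names(sc) <- sprintf("PC%02d", seq_len(object$k))
  cbind(as.data.frame(newdata)[, META_COLS], sc)
}

#' @export
print.reduction_model <- function(x, ...) {
  cat(sprintf("reduction_model: %d features -> k = %d components (%s selection, %s rotation)\n",
              length(x$features), x$k, x$rule, x$rotation))
  invisible(x)
}
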