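#' Linear maximum mean discrepancy between two domains
#'
#' With a linear kernel the squared MMD between two samples is the squared
#' Euclidean distance between their column-mean vectors.
#'
#' @param Xs,Xt Numeric matrices with the same number of columns and at
#'   least one row each.
#' @return Non-negative scalar.
#' @export
mmd_linear <- function(Xs, Xt) {
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  if (ncol(Xs) != ncol(Xt)) stop("domains must share the feature dimension")
  if (nrow(Xs) < 1 || nrow(Xt) < 1) stop("each domain needs at least one row")
  sum((colMeans(Xs) - colMeans(Xt))^2)
}

#' Fit primal (linear) Transfer Component Analysis
#'
#' Learns a d x m projection W that shrinks the maximum mean discrepancy
#' between source and target while preserving pooled variance. With stacked
#' data X (n x d), MMD block matrix L (entries 1/ns^2, 1/nt^2, -1/(ns nt))
#' and centring matrix H = I - 11'/n, W's columns are the eigenvectors of
#' `(X'LX + mu I)^{-1} X'HX` for the m largest real eigenvalues. For the
#' linear kernel X'LX reduces to the rank-one outer product of the domain
#' mean difference and X'HX to the pooled centred scatter, which is what is
#' computed here.
#'
#' Columns are unit-norm with the largest-magnitude entry positive; complex
#' eigenvector components (numerical artifacts of the non-symmetric product)
#' are resolved by taking real parts and re-orthonormalizing.
#'
#' @param Xs,Xt Source and target feature matrices (>= 2 rows each, same
#'   columns).
#' @param m Embedding dimensionality (default 5), `m <= ncol(Xs)`.
#' @param mu Ridge regularizer on X'LX (default 1).
#' @return An object of class `tca_model`: `W` (d x m), `eigenvalues`
#'   (descending, length m), `m`, `mu`, `variant = "primal"`, `features`
#'   (column names), plus diagnostic `mmd_raw` and `mmd_embedded` for the
#'   fitted pair.
#' @export
fit_tca_primal <- function(Xs, Xt, m = 5, mu = 1) {
  Xs <- as.matrix(Xs); Xt <- as.matrix(Xt)
  if (ncol(Xs) != ncol(Xt)) stop("domains must share the feature dimension")
  if (nrow(Xs) < 2 || nrow(Xt) < 2) stop("each domain needs at least two rows")
  d <- ncol(Xs)
  if (m > d) stop("m cannot exceed the number of features")
  X <- rbind(Xs, Xt)

  delta <- colMeans(Xs) - colMeans(Xt)
  XLX <- tcrossprod(delta)                       # X'LX, rank one
  Xc <- sweep(X, 2, colMeans(X))
  XHX <- crossprod(Xc)                           # X'HX, pooled scatter

  A <- XLX + mu * diag(d)
  if (mu == 0 && rcond(A) < .Machine$double.eps) {
    stop("singular system: X'LX is rank deficient and mu = 0")
  }
  eig <- eigen(solve(A, XHX))
  vals <- Re(eig$values)
  ord <- order(vals, decreasing = TRUE)[seq_len(m)]
  W <- eig$vectors[, ord, drop = FALSE]
  had_complex <- is.complex(W) && any(abs(Im(W)) > 0)
  W <- Re(W)
  if (had_complex) W <- qr.Q(qr(W))              # re-orthonormalize
  # unit columns, sign fixed: largest-magnitude entry positive
  for (j in seq_len(ncol(W))) {
    W[, j] <- W[, j] / sqrt(sum(W[, j]^2))
    piv <- which.max(abs(W[, j]))
    if (W[piv, j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- list(colnames(Xs), paste0("TC", seq_len(m)))

  structure(list(W = W, eigenvalues = vals[ord], m = m, mu = mu,
                 variant = "primal", features = colnames(Xs),
                 mmd_raw = mmd_linear(Xs, Xt),
                 mmd_embedded = mmd_linear(Xs %*% W, Xt %*% W)),
            class = "tca_model")
}

#' Project data through a fitted TCA model
#'
#' @param object A `tca_model`.
#' @param newdata Matrix or data frame with the model's feature columns.
#' @param ... Unused.
#' @return The n x m embedded matrix `newdata %*% W`.
#' @export
predict.tca_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != nrow(object$W)) {
    if (!is.null(object$features) && all(object$features %in% colnames(X))) {
      X <- X[, object$features, drop = FALSE]
    } else {
      stop("newdata column count does not match the fitted projection")
    }
  }
  X %*% object$W
}

#' @export
print.tca_model <- function(x, ...) {
  cat(sprintf("<tca_model> primal TCA: %d -> %d components (mu = %g)\n",
              nrow(x$W), x$m, x$mu))
  cat(sprintf("  MMD raw %.4g -> embedded %.4g\n", x$mmd_raw, x$mmd_embedded))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a TCA model: one row per (feature, component) loading
#'
#' @param x A `tca_model`.
#' @param ... Unused.
#' @return Tibble with `feature`, `component`, `loading`, `eigenvalue`.
#' @export
tidy.tca_model <- function(x, ...) {
  W <- x$W
  tibble::tibble(
    feature = rep(rownames(W) %||% paste0("x", seq_len(nrow(W))),
                  times = ncol(W)),
    component = rep(colnames(W), each = nrow(W)),
    loading = as.vector(W),
    eigenvalue = rep(x$eigenvalues, each = nrow(W))
  )
}

#' Glance at a TCA model
#'
#' @param x A `tca_model`.
#' @param ... Unused.
#' @return One-row tibble: `m`, `mu`, `mmd_raw`, `mmd_embedded`,
#'   `top_eigenvalue`.
#' @export
glance.tca_model <- function(x, ...) {
  tibble::tibble(m = x$m, mu = x$mu, mmd_raw = x$mmd_raw,
                 mmd_embedded = x$mmd_embedded,
                 top_eigenvalue = x$eigenvalues[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
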