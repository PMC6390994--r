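.EPS <- 1e-12

#' Fitting configuration for NMF
#'
#' @param max_iter maximum multiplicative-update iterations (>= 1).
#' @param tol relative change in the penalized objective below which the fit
#'   is declared converged (> 0).
#' @param n_restarts number of starts; the first uses \code{init}, further
#'   starts use random-uniform initialization. The winner has the lowest
#'   final objective, ties broken by start order.
#' @param seed integer seed controlling the random starts.
#' @param init \code{"nndsvd"} (deterministic, SVD-based, zeros backfilled
#'   with the matrix mean so multiplicative updates can escape them) or
#'   \code{"random"} (uniform).
#' @return list of class \code{"fitConfig"}.
#' @export
fitConfig <- function(max_iter = 500L, tol = 1e-6, n_restarts = 1L,
                      seed = 1L, init = c("nndsvd", "random")) {
  init <- match.arg(init)
  stopifnot(max_iter >= 1, tol > 0, n_restarts >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), init = init),
            class = "fitConfig")
}

## NNDSVD initialization (zeros backfilled with mean(X))
.init_nndsvd <- function(X, k) {
  sv <- svd(X, nu = k, nv = k)
  m <- nrow(X); n <- ncol(X)
  W <- matrix(0, m, k); H <- matrix(0, k, n)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k > 1) for (j in 2:k) {
    u <- sv$u[, j]; v <- sv$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
    nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
    if (npos >= nneg && npos > 0) {
      W[, j] <- sqrt(sv$d[j] * npos) * up / sqrt(sum(up^2))
      H[j, ] <- sqrt(sv$d[j] * npos) * vp / sqrt(sum(vp^2))
    } else if (nneg > 0) {
      W[, j] <- sqrt(sv$d[j] * nneg) * un / sqrt(sum(un^2))
      H[j, ] <- sqrt(sv$d[j] * nneg) * vn / sqrt(sum(vn^2))
    }
  }
  mu <- mean(X)
  if (mu <= 0) mu <- .EPS
  W[W <= 0] <- mu
  H[H <= 0] <- mu
  list(W = W, H = H)
}

.objective <- function(X, W, H, alpha) sum((X - W %*% H)^2) + alpha * sum(W)

## one MU engine run from a given start
.mu_run <- function(X, W, H, alpha, max_iter, tol) {
  trace <- numeric(max_iter + 1L)
  obj <- .objective(X, W, H, alpha)
  trace[1] <- obj
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    HHt <- tcrossprod(H)
    W <- W * (X %*% t(H)) / (W %*% HHt + alpha / 2 + .EPS)
    WtW <- crossprod(W)
    H <- H * (crossprod(W, X)) / (WtW %*% H + .EPS)
    newobj <- .objective(X, W, H, alpha)
    trace[it + 1L] <- newobj
    if (abs(obj - newobj) <= tol * max(obj, .EPS)) {
      converged <- TRUE
      obj <- newobj
      break
    }
    obj <- newobj
  }
  list(W = W, H = H, objective = obj, trace = trace[seq_len(it + 1L)],
       converged = converged)
}

## non-negative least-squares solve for H with W fixed, one active-set
## solve per column (exact and deterministic, unlike the slow tail of
## multiplicative updates). All-zero columns of X map to exactly zero.
.solve_H <- function(W, X) {
  k <- ncol(W)
  H <- matrix(0, k, ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (any(x != 0)) H[, j] <- pracma::lsqnonneg(W, x)$x
  }
  H
}

#' Fit a sparse non-negative matrix factorization
#'
#' Minimizes \eqn{\|X - WH\|_F^2 + \alpha \|W\|_1} over non-negative
#' \eqn{W} (features x factors) and \eqn{H} (factors x patients) by
#' multiplicative updates, which never increase the penalized objective.
#' The L1 penalty acts on \eqn{W} only: sparse joint patterns are the goal
#' while patient scores stay dense for group assignment. After convergence
#' the scores are re-solved to convergence with \eqn{W} fixed, and each
#' \eqn{W} column is normalized to unit maximum (loadings read as 0--100\%
#' contributions) with the compensation folded into \eqn{H}; the removed
#' per-factor scales are stored.
#'
#' @param X non-negative matrix (features x patients).
#' @param k integer rank, at most \code{min(dim(X))}.
#' @param alpha L1 penalty weight on \code{W} (>= 0).
#' @param config a \code{\link{fitConfig}}.
#' @return a \linkS4class{FactorModel}.
#' @export
fitNMF <- function(X, k, alpha = 0, config = fitConfig()) {
  if (any(X < 0)) stop("X must be non-negative")
  if (k > min(dim(X))) stop("rank k = ", k, " exceeds min(dim(X)) = ", min(dim(X)))
  if (alpha < 0) stop("alpha must be >= 0")
  k <- as.integer(k)
  best <- NULL
  best_seed <- config$seed
  for (r in seq_len(config$n_restarts)) {
    if (r == 1L && config$init == "nndsvd") {
      st <- .init_nndsvd(X, k)
    } else {
      set.seed(config$seed + r - 1L)
      st <- list(W = matrix(stats::runif(nrow(X) * k, 0.1, 1), nrow(X), k),
                 H = matrix(stats::runif(k * ncol(X), 0.1, 1), k, ncol(X)))
    }
    run <- .mu_run(X, st$W, st$H, alpha, config$max_iter, config$tol)
    if (is.null(best) || run$objective < best$objective) {
      best <- run
      best_seed <- config$seed + r - 1L
    }
  }
  W <- best$W
  H <- .solve_H(W, X)
  s <- apply(W, 2, max)
  s[s == 0] <- 1
  W <- sweep(W, 2, s, "/")
  H <- H * s
  dimnames(W) <- list(rownames(X), paste0("F", seq_len(k)))
  dimnames(H) <- list(paste0("F", seq_len(k)), colnames(X))
  new("FactorModel", W = W, H = H, k = k, alpha = alpha, scale = s,
      sparsifyThreshold = 0, sparsified = FALSE,
      scoreCor = rep(NA_real_, k), converged = best$converged,
      objectiveTrace = best$trace, seed = as.integer(best_seed))
}

setMethod("show", "FactorModel", function(object) {
  cat("FactorModel: k =", object@k, "(", nrow(object@W), "features x",
      ncol(object@H), "patients ), alpha =", object@alpha,
      if (object@sparsified) paste0(", sparsified at ",
                                    object@sparsifyThreshold) else "",
      "\n  final objective:", utils::tail(object@objectiveTrace, 1),
      if (object@converged) "(converged)" else "(max_iter reached)", "\n")
})

#' Sparsify a fitted factor model
#'
#' Sets loadings below \code{threshold} times their column maximum to zero,
#' then re-estimates the patient scores with the sparsified \eqn{W} held
#' fixed (non-negative least squares per patient). The per-factor Spearman
#' correlation between pre- and post-sparsification scores is recorded so
#' the user can verify that sparsification preserved patient ordering on
#' every factor.
#'
#' @param model a fitted \linkS4class{FactorModel}.
#' @param X the matrix the model was fitted to.
#' @param threshold fraction of the column maximum in [0, 1); default 0.1.
#' @return a sparsified \linkS4class{FactorModel}.
#' @export
sparsify <- function(model, X, threshold = 0.1) {
  stopifnot(threshold >= 0, threshold < 1)
  W <- model@W
  cmax <- apply(W, 2, max)
  Ws <- W
  Ws[W < threshold * rep(cmax, each = nrow(W))] <- 0
  dead <- which(colSums(Ws) == 0)
  if (length(dead))
    stop("sparsification zeroed entire factor(s) ",
         paste(dead, collapse = ", "), "; lower the threshold")
  Hs <- .solve_H(Ws, X)
  sc <- vapply(seq_len(model@k), function(f) {
    if (stats::sd(model@H[f, ]) == 0 || stats::sd(Hs[f, ]) == 0) return(NA_real_)
    stats::cor(model@H[f, ], Hs[f, ], method = "spearman")
  }, numeric(1))
  out <- model
  out@W <- Ws
  out@H <- Hs
  out@sparsifyThreshold <- threshold
  out@sparsified <- TRUE
  out@scoreCor <- sc
  out
}

#' Reconstruct the input from a factor model
#'
#' @param model a \linkS4class{FactorModel}.
#' @return the matrix \code{W \%*\% H}.
#' @export
reconstruct <- function(model) model@W %*% model@H

#' Held-out reconstruction accuracy Q-squared
#'
#' \eqn{Q^2 = 1 - \sum_{mask} (X - \hat X)^2 / \sum_{mask} (X - \bar
#' X_{mask})^2}, computed over the masked entries (all entries when
#' \code{mask} is NULL). May be negative when the prediction is worse than
#' the mask mean. \code{method = "corr"} instead returns the squared Pearson
#' correlation between masked entries of \code{X} and \code{Xhat}.
#'
#' @param X,Xhat conforming matrices.
#' @param mask optional logical matrix or index vector selecting held-out
#'   entries.
#' @param method \code{"press"} (default, 1 - PRESS/TSS) or \code{"corr"}.
#' @return a single numeric.
#' @export
q2 <- function(X, Xhat, mask = NULL, method = c("press", "corr")) {
  method <- match.arg(method)
  stopifnot(all(dim(X) == dim(Xhat)))
  x <- if (is.null(mask)) as.vector(X) else X[mask]
  xh <- if (is.null(mask)) as.vector(Xhat) else Xhat[mask]
  if (method == "corr") {
    if (stats::sd(x) == 0 || stats::sd(xh) == 0)
      stop("constant values over the mask: correlation undefined")
    return(stats::cor(x, xh)^2)
  }
  tss <- sum((x - mean(x))^2)
  if (tss == 0) stop("X is constant over the mask: Q2 undefined")
  1 - sum((x - xh)^2) / tss
}

#' Project new patients onto a frozen factor model
#'
#' Solves for non-negative scores \eqn{H_{new}} with the loadings \eqn{W}
#' and all stored scaling parameters held fixed (multiplicative updates on
#' \eqn{H} only, deterministic given inputs). All-zero patient columns map
#' to exactly zero scores.
#'
#' @param X_new matrix whose rows match the model's feature space (same
#'   names, same order).
#' @param model a \linkS4class{FactorModel}.
#' @return scores matrix (k x new patients).
#' @export
projectScores <- function(X_new, model) {
  if (!is.null(rownames(model@W)) &&
      !identical(rownames(X_new), rownames(model@W)))
    stop("feature space mismatch: rownames of X_new must equal the model's")
  if (nrow(X_new) != nrow(model@W)) stop("feature dimension mismatch")
  H <- .solve_H(model@W, X_new)
  dimnames(H) <- list(colnames(model@W), colnames(X_new))
  H
}
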