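## Owen-Perry prediction of a held-out block A from the three training
## blocks: A-hat = B D+ C, with the pseudo-inverse taken through the rank-k
## factorization of D (D ~ W H, D+ ~ ginv(H) ginv(W)).
.bicv_predict <- function(B, C, D, k, alpha, config) {
  fit <- fitNMF(D, k = k, alpha = alpha, config = config)
  Dp <- MASS::ginv(fit@H) %*% MASS::ginv(fit@W)
  B %*% Dp %*% C
}

#' Bi-cross-validation over rank and regularization grids
#'
#' Per replicate, rows and columns are independently partitioned uniformly
#' at random into \code{folds} groups. For each of the
#' \code{folds^2} held-out (row-block, column-block) pairs, the model is
#' fitted on the complementary training submatrix \eqn{D} only, and the
#' held-out block \eqn{A} is predicted by the Owen-Perry reconstruction
#' \eqn{\hat A = B D^+ C}, with the pseudo-inverse of \eqn{D} taken through
#' its rank-k fit. Held-out entries are never seen by the fit used to
#' predict them. Each matrix entry is held out exactly once per replicate,
#' so the per-replicate \eqn{Q^2} pools all entries.
#'
#' @param X non-negative matrix.
#' @param ranks integer vector of candidate ranks.
#' @param alphas numeric vector of candidate L1 penalties.
#' @param folds number of row/column folds (default 3).
#' @param replicates number of random re-partitions (the study default is
#'   2,000; smaller values are appropriate interactively).
#' @param seed integer seed.
#' @param config a \code{\link{fitConfig}} used for every training fit.
#' @return a \linkS4class{BiCVGrid}.
#' @export
bicv <- function(X, ranks, alphas = 0, folds = 3L, replicates = 50L,
                 seed = 1L, config = fitConfig(max_iter = 300L)) {
  folds <- as.integer(folds)
  train_min <- floor(min(dim(X)) * (folds - 1) / folds)
  if (max(ranks) > train_min)
    stop("max rank ", max(ranks), " infeasible for fold sizes (training ",
         "blocks have min dimension ", train_min, ")")
  rows <- list()
  for (r in seq_len(replicates)) {
    set.seed(seed + r)
    rf <- sample(rep(seq_len(folds), length.out = nrow(X)))
    cf <- sample(rep(seq_len(folds), length.out = ncol(X)))
    for (k in ranks) for (a in alphas) {
      sse <- 0
      held <- numeric(0)
      pred <- numeric(0)
      for (fr in seq_len(folds)) for (fc in seq_len(folds)) {
        I <- rf == fr; J <- cf == fc
        A <- X[I, J, drop = FALSE]
        Ahat <- .bicv_predict(X[I, !J, drop = FALSE],
                              X[!I, J, drop = FALSE],
                              X[!I, !J, drop = FALSE], k, a, config)
        held <- c(held, as.vector(A))
        pred <- c(pred, as.vector(Ahat))
      }
      tss <- sum((held - mean(held))^2)
      rows[[length(rows) + 1L]] <- data.frame(
        k = k, alpha = a, replicate = r,
        q2 = 1 - sum((held - pred)^2) / tss)
    }
  }
  new("BiCVGrid", grid = do.call(rbind, rows), folds = folds,
      replicates = as.integer(replicates), seed = as.integer(seed))
}

setMethod("show", "BiCVGrid", function(object) {
  g <- object@grid
  cat("BiCVGrid:", object@folds, "folds x", object@replicates,
      "replicates; ranks", paste(sort(unique(g$k)), collapse = ","),
      "; alphas", paste(sort(unique(g$alpha)), collapse = ","), "\n")
})

#' Summarize a BiCV grid
#'
#' @param grid a \linkS4class{BiCVGrid}.
#' @return data.frame with per-(k, alpha) mean q2 and its standard error
#'   across replicates (0 when there is a single replicate).
#' @export
bicvSummary <- function(grid) {
  g <- grid@grid
  agg <- aggregate(q2 ~ k + alpha, data = g,
                   FUN = function(v) c(mean = mean(v),
                                       se = if (length(v) > 1)
                                         stats::sd(v) / sqrt(length(v)) else 0))
  data.frame(k = agg$k, alpha = agg$alpha,
             mean_q2 = agg$q2[, "mean"], se = agg$q2[, "se"])
}

#' One-standard-error selection of rank and regularization
#'
#' \code{selectRank} returns the smallest rank whose mean held-out Q2 lies
#' within one standard error of the maximum mean Q2 (parsimony rule).
#' \code{selectAlpha} returns the largest penalty whose mean Q2 lies within
#' one standard error of the unpenalized (alpha = 0) mean, i.e. the
#' sparsest model that costs essentially nothing in held-out accuracy.
#'
#' @param grid a \linkS4class{BiCVGrid}.
#' @param alpha_fixed for \code{selectRank}: restrict to this alpha (needed
#'   only if the grid covers several).
#' @param k_fixed for \code{selectAlpha}: restrict to this rank (needed only
#'   if the grid covers several).
#' @return the selected integer rank / numeric alpha.
#' @export
selectRank <- function(grid, alpha_fixed = NULL) {
  s <- bicvSummary(grid)
  if (is.null(alpha_fixed)) {
    if (length(unique(s$alpha)) > 1)
      stop("grid covers several alphas; pass alpha_fixed")
  } else s <- s[s$alpha == alpha_fixed, , drop = FALSE]
  if (!nrow(s)) stop("empty grid axis")
  s <- s[order(s$k), ]
  best <- which.max(s$mean_q2)
  ok <- s$mean_q2 >= s$mean_q2[best] - s$se[best]
  as.integer(s$k[which(ok)[1]])
}

#' @rdname selectRank
#' @export
selectAlpha <- function(grid, k_fixed = NULL) {
  s <- bicvSummary(grid)
  if (is.null(k_fixed)) {
    if (length(unique(s$k)) > 1)
      stop("grid covers several ranks; pass k_fixed")
  } else s <- s[s$k == k_fixed, , drop = FALSE]
  if (!nrow(s)) stop("empty grid axis")
  if (!any(s$alpha == 0)) stop("selectAlpha requires alpha = 0 in the grid")
  ref <- s[s$alpha == 0, ]
  ok <- s$mean_q2 >= ref$mean_q2 - ref$se
  max(s$alpha[ok])
}
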