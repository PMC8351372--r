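## Regression back-ends. Every fitted regressor is reduced at fit time to a
## portable numeric form (tree tables for the forest, affine coefficients
## for the linear families) so that predictions are reproducible bitwise,
## independent of the fitting library being loaded, and serializable as
## plain text. All models take an n x p numeric matrix and log-unit
## activities.

.fitRegressor <- function(X, y, config) {
  X <- as.matrix(X)
  p <- ncol(X)
  kind <- config@modelType
  if (p == 0 || nrow(X) == 0)
    stop("cannot fit a regressor without input features")
  colVar <- apply(X, 2, stats::var)
  if (all(colVar < 1e-12) && kind != "random_forest")
    return(list(kind = "const", mean = mean(y), p = p))
  switch(kind,
    random_forest = .fitForest(X, y, config),
    ridge = c(.fitRidgeAffine(X, y, lambda = 1), list(kind = "linear", p = p)),
    pls = .fitPLS(X, y, config),
    pca_ridge = .fitPCAThen(X, y, ridge = TRUE),
    pca_linear = .fitPCAThen(X, y, ridge = FALSE),
    stop("unknown modelType: ", kind)
  )
}

.fitForest <- function(X, y, config) {
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  dat <- data.frame(y = y, X, check.names = FALSE)
  fit <- ranger::ranger(y ~ ., data = dat,
                        num.trees = config@rfNEstimators,
                        max.depth = config@rfMaxDepth,
                        mtry = ncol(X), min.node.size = 1,
                        seed = config@randomSeed, num.threads = 1)
  trees <- do.call(rbind, lapply(seq_len(fit$num.trees), function(i) {
    ti <- ranger::treeInfo(fit, i)
    data.frame(tree = i, nodeID = ti$nodeID, leftChild = ti$leftChild,
               rightChild = ti$rightChild, splitvarID = ti$splitvarID,
               splitval = ti$splitval, terminal = ti$terminal,
               prediction = ti$prediction)
  }))
  list(kind = "forest", trees = trees, p = ncol(X))
}

## exact ridge with unpenalised intercept (centred normal equations)
.fitRidgeAffine <- function(X, y, lambda = 1) {
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2, mx)
  beta <- solve(crossprod(Xc) + lambda * diag(ncol(X)),
                crossprod(Xc, y - my))
  list(coef = as.numeric(beta), intercept = my - sum(mx * beta))
}

.fitPLS <- function(X, y, config) {
  keep <- which(apply(X, 2, stats::var) > 1e-12)
  Xk <- X[, keep, drop = FALSE]
  colnames(Xk) <- paste0("f", seq_len(ncol(Xk)))
  if (ncol(Xk) == 1) {
    ## univariate PLS reduces to simple least squares
    b <- stats::cov(Xk[, 1], y) / stats::var(Xk[, 1])
    coef <- numeric(ncol(X)); coef[keep] <- b
    return(list(kind = "linear", coef = coef,
                intercept = mean(y) - b * mean(Xk[, 1]), p = ncol(X)))
  }
  ncomp <- max(1L, min(2L, ncol(Xk), nrow(Xk) - 1L))
  fit <- mixOmics::pls(Xk, y, ncomp = ncomp, mode = "regression",
                       scale = FALSE)
  ## PLS prediction is affine in x; recover the coefficients by probing
  ## the mean point and one unit step per coordinate in a single call
  mu <- colMeans(Xk)
  probe <- rbind(mu, sweep(diag(ncol(Xk)), 2, mu, "+"))
  dimnames(probe) <- list(seq_len(nrow(probe)), colnames(Xk))
  preds <- predict(fit, probe)$predict[, 1, ncomp]
  b0 <- preds[1]
  coefK <- as.numeric(preds[-1] - b0)
  base <- matrix(mu, 1)
  coef <- numeric(ncol(X)); coef[keep] <- coefK
  list(kind = "linear", coef = coef,
       intercept = b0 - sum(base[1, ] * coefK), p = ncol(X))
}

.fitPCAThen <- function(X, y, ridge = TRUE) {
  keep <- which(apply(X, 2, stats::var) > 1e-12)
  Xk <- X[, keep, drop = FALSE]
  pc <- stats::prcomp(Xk, center = TRUE, scale. = FALSE)
  nc <- sum(pc$sdev > 1e-8)
  nc <- max(1L, min(nc, nrow(Xk) - 1L))
  S <- pc$x[, seq_len(nc), drop = FALSE]
  aff <- if (ridge) .fitRidgeAffine(S, y, lambda = 1)
         else {
           fitlm <- stats::lm.fit(cbind(1, S), y)
           list(coef = as.numeric(fitlm$coefficients[-1]),
                intercept = as.numeric(fitlm$coefficients[1]))
         }
  aff$coef[is.na(aff$coef)] <- 0
  ## collapse projection + regression into one affine map on the input space
  V <- pc$rotation[, seq_len(nc), drop = FALSE]
  coefK <- as.numeric(V %*% aff$coef)
  coef <- numeric(ncol(X)); coef[keep] <- coefK
  intercept <- aff$intercept - sum(pc$center * coefK)
  list(kind = "linear", coef = coef, intercept = intercept, p = ncol(X))
}

.predictForestMatrix <- function(trees, X) {
  treeIds <- unique(trees$tree)
  preds <- matrix(0, nrow(X), length(treeIds))
  for (t in seq_along(treeIds)) {
    tr <- trees[trees$tree == treeIds[t], , drop = FALSE]
    tr <- tr[order(tr$nodeID), , drop = FALSE]
    for (r in seq_len(nrow(X))) {
      node <- 0L
      repeat {
        row <- tr[node + 1L, ]
        if (row$terminal) { preds[r, t] <- row$prediction; break }
        node <- if (X[r, row$splitvarID + 1L] <= row$splitval)
          row$leftChild else row$rightChild
      }
    }
  }
  rowMeans(preds)
}

.predictRegressor <- function(reg, X) {
  X <- as.matrix(X)
  if (ncol(X) != reg$p)
    stop("input vector length ", ncol(X), " does not match model dimension ",
         reg$p)
  switch(reg$kind,
    const = rep(reg$mean, nrow(X)),
    linear = as.numeric(X %*% reg$coef + reg$intercept),
    forest = .predictForestMatrix(reg$trees, X),
    stop("unknown regressor kind: ", reg$kind)
  )
}

.serializeRegressor <- function(reg) {
  if (reg$kind == "forest")
    reg$trees <- as.list(reg$trees)   # column-wise, JSON-friendly
  reg
}

.deserializeRegressor <- function(obj) {
  reg <- obj
  reg$p <- as.integer(obj$p)
  if (reg$kind == "forest") {
    tr <- as.data.frame(obj$trees)
    tr$leftChild <- as.integer(tr$leftChild)
    tr$rightChild <- as.integer(tr$rightChild)
    tr$splitvarID <- as.integer(tr$splitvarID)
    tr$terminal <- as.logical(tr$terminal)
    reg$trees <- tr
  } else if (reg$kind == "linear") {
    reg$coef <- as.numeric(unlist(obj$coef))
    reg$intercept <- as.numeric(obj$intercept)
  } else if (reg$kind == "const") {
    reg$mean <- as.numeric(obj$mean)
  }
  reg
}
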