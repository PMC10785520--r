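## Feed-forward multilayer perceptron for the deep-neural-network model
## variant, implemented in base R matrix operations.
##
## Architecture and optimization follow the fixed configuration of the
## DNN variant: three hidden layers of 128 rectified-linear units,
## rectified-linear output (so predictions are always non-negative),
## inverted dropout (rate 0.2) on the hidden layers, Adam with learning
## rate 1e-5, mean-squared-error loss, mini-batches of 32, up to 750
## epochs with early stopping when the validation MSE has not improved
## for 50 epochs.

.mlpInit <- function(nIn, hiddenLayers, units, seed) {
    set.seed(seed)
    sizes <- c(nIn, rep(units, hiddenLayers), 1L)
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
        ## He initialization for rectifier nets
        W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                               sd = sqrt(2 / sizes[l])),
                         sizes[l], sizes[l + 1L])
        b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
}

## Forward pass; at train time applies inverted dropout to hidden
## activations using the supplied masks.
.mlpForward <- function(params, X, dropMasks = NULL) {
    L <- length(params$W)
    acts <- vector("list", L + 1L)
    acts[[1L]] <- X
    for (l in seq_len(L)) {
        Z <- acts[[l]] %*% params$W[[l]] +
            rep(params$b[[l]], each = nrow(X))
        A <- pmax(Z, 0)  # rectifier on hidden and output layers
        if (!is.null(dropMasks) && l < L)
            A <- A * dropMasks[[l]]
        acts[[l + 1L]] <- A
    }
    acts
}

## Backward pass for MSE loss; returns gradients for W and b.
.mlpBackward <- function(params, acts, y, dropMasks) {
    L <- length(params$W)
    n <- length(y)
    gW <- vector("list", L)
    gb <- vector("list", L)
    pred <- acts[[L + 1L]][, 1L]
    ## dLoss/dA_out for MSE, through the output rectifier
    delta <- matrix(2 * (pred - y) / n, ncol = 1L) * (acts[[L + 1L]] > 0)
    for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(acts[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1L) {
            delta <- (delta %*% t(params$W[[l]])) * (acts[[l]] > 0)
            if (!is.null(dropMasks) && (l - 1L) <= length(dropMasks))
                delta <- delta * dropMasks[[l - 1L]]
        }
    }
    list(W = gW, b = gb)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
    state$t <- state$t + 1L
    corr1 <- 1 - beta1^state$t
    corr2 <- 1 - beta2^state$t
    for (l in seq_along(params$W)) {
        state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
        state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
        params$W[[l]] <- params$W[[l]] -
            lr * (state$mW[[l]] / corr1) /
            (sqrt(state$vW[[l]] / corr2) + eps)
        state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
        state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
        params$b[[l]] <- params$b[[l]] -
            lr * (state$mb[[l]] / corr1) /
            (sqrt(state$vb[[l]] / corr2) + eps)
    }
    list(params = params, state = state)
}

## Train the MLP.  The last validationFraction of the shuffled training
## rows is held out to monitor validation MSE for early stopping; the
## parameters from the best validation epoch are returned.
.mlpTrain <- function(X, y, config, seed) {
    n <- nrow(X)
    set.seed(subSeed(seed, "mlp-shuffle"))
    perm <- sample.int(n)
    X <- X[perm, , drop = FALSE]
    y <- y[perm]
    nVal <- max(1L, floor(config$validationFraction * n))
    valIdx <- seq.int(n - nVal + 1L, n)
    Xtr <- X[-valIdx, , drop = FALSE]; ytr <- y[-valIdx]
    Xva <- X[valIdx, , drop = FALSE]; yva <- y[valIdx]

    center <- rep(0, ncol(X)); scale <- rep(1, ncol(X))
    if (isTRUE(config$standardize)) {
        center <- colMeans(Xtr)
        scale <- apply(Xtr, 2L, sd)
        scale[scale == 0] <- 1
        Xtr <- sweep(sweep(Xtr, 2L, center), 2L, scale, "/")
        Xva <- sweep(sweep(Xva, 2L, center), 2L, scale, "/")
    }

    params <- .mlpInit(ncol(X), config$hiddenLayers, config$unitsPerLayer,
                       subSeed(seed, "mlp-init"))
    ## start the rectified output unit in its active regime at the target
    ## mean, so gradients flow from the first batch
    params$b[[length(params$b)]] <- mean(ytr)
    zeros <- lapply(params$W, function(w) w * 0)
    zerosB <- lapply(params$b, function(b) b * 0)
    state <- list(mW = zeros, vW = zeros, mb = zerosB, vb = zerosB, t = 0L)

    nTr <- nrow(Xtr)
    batch <- min(config$batchSize, nTr)
    keep <- 1 - config$dropoutRate
    best <- list(mse = Inf, params = params, epoch = 0L)
    set.seed(subSeed(seed, "mlp-batches"))
    sinceBest <- 0L
    epoch <- 0L
    while (epoch < config$maxEpochs) {
        epoch <- epoch + 1L
        ord <- sample.int(nTr)
        for (start in seq.int(1L, nTr, by = batch)) {
            idx <- ord[start:min(start + batch - 1L, nTr)]
            Xb <- Xtr[idx, , drop = FALSE]
            masks <- NULL
            if (config$dropoutRate > 0) {
                masks <- lapply(seq_len(config$hiddenLayers), function(l)
                    matrix(rbinom(length(idx) * config$unitsPerLayer, 1L,
                                  keep) / keep,
                           length(idx), config$unitsPerLayer))
            }
            acts <- .mlpForward(params, Xb, masks)
            grads <- .mlpBackward(params, acts, ytr[idx], masks)
            upd <- .adamStep(params, grads, state, config$learningRate)
            params <- upd$params
            state <- upd$state
        }
        valPred <- .mlpForward(params, Xva)[[config$hiddenLayers + 2L]][, 1L]
        valMse <- mean((valPred - yva)^2)
        if (valMse < best$mse - 1e-12) {
            best <- list(mse = valMse, params = params, epoch = epoch)
            sinceBest <- 0L
        } else {
            sinceBest <- sinceBest + 1L
            if (sinceBest >= config$earlyStopPatience) break
        }
    }
    list(params = best$params, center = center, scale = scale,
         epochsRun = epoch, bestEpoch = best$epoch, valMse = best$mse,
         config = config)
}

.mlpPredict <- function(fit, X) {
    X <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
    L <- length(fit$params$W)
    .mlpForward(fit$params, X)[[L + 1L]][, 1L]
}
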