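# Vectorised neural-network primitives. All layers operate on batches
# stored row-wise (n x features) so every heavy step is a BLAS matmul.
# Parameter collections are nested lists of numeric arrays ("trees");
# gradients mirror the tree structure exactly, which lets one Adam walker
# update any model.

sigmoidAct <- function(x) stats::plogis(x)

reluAct <- function(x) (x > 0) * x

addBias <- function(XW, b) XW + rep(b, each = nrow(XW))

heInit <- function(fanIn, fanOut) {
    matrix(rnorm(fanIn * fanOut, sd = sqrt(2 / fanIn)), fanIn, fanOut)
}

glorotInit <- function(fanIn, fanOut) {
    s <- sqrt(6 / (fanIn + fanOut))
    matrix(runif(fanIn * fanOut, -s, s), fanIn, fanOut)
}

## ---- parameter trees -------------------------------------------------

treeMap <- function(f, ...) {
    xs <- list(...)
    x1 <- xs[[1L]]
    if (is.list(x1)) {
        out <- vector("list", length(x1))
        names(out) <- names(x1)
        for (i in seq_along(x1))
            out[[i]] <- do.call(treeMap, c(list(f), lapply(xs, `[[`, i)))
        out
    } else {
        do.call(f, xs)
    }
}

treeZero <- function(p) treeMap(function(x) x * 0, p)

## ---- Adam optimiser --------------------------------------------------

adamInit <- function(params) {
    list(m = treeZero(params), v = treeZero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    state$t <- state$t + 1L
    state$m <- treeMap(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
    state$v <- treeMap(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
    c1 <- 1 - beta1^state$t
    c2 <- 1 - beta2^state$t
    params <- treeMap(function(p, m, v)
        p - lr * (m / c1) / (sqrt(v / c2) + eps),
        params, state$m, state$v)
    list(params = params, state = state)
}

## ---- dense layer -----------------------------------------------------

denseForward <- function(X, W, b) {
    list(Y = addBias(X %*% W, b), X = X)
}

denseBackward <- function(cache, W, dY) {
    list(dW = crossprod(cache$X, dY),
         db = colSums(dY),
         dX = tcrossprod(dY, W))
}

## ---- batch normalisation --------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# train mode normalises by batch statistics; buffers (running mean/var)
# are returned updated but never entered into the gradient tree
bnForward <- function(X, gamma, beta, runMean, runVar,
                      mode = c("train", "infer")) {
    mode <- match.arg(mode)
    if (mode == "train") {
        mu <- colMeans(X)
        xc <- X - rep(mu, each = nrow(X))
        v <- colMeans(xc * xc)
        istd <- 1 / sqrt(v + BN_EPS)
        xhat <- xc * rep(istd, each = nrow(X))
        runMean <- BN_MOMENTUM * runMean + (1 - BN_MOMENTUM) * mu
        runVar <- BN_MOMENTUM * runVar + (1 - BN_MOMENTUM) * v
        cache <- list(xhat = xhat, istd = istd)
    } else {
        istd <- 1 / sqrt(runVar + BN_EPS)
        xhat <- (X - rep(runMean, each = nrow(X))) *
            rep(istd, each = nrow(X))
        cache <- NULL
    }
    Y <- xhat * rep(gamma, each = nrow(X)) + rep(beta, each = nrow(X))
    list(Y = Y, cache = cache, runMean = runMean, runVar = runVar)
}

bnBackward <- function(cache, gamma, dY) {
    n <- nrow(dY)
    xhat <- cache$xhat
    dgamma <- colSums(dY * xhat)
    dbeta <- colSums(dY)
    dxhat <- dY * rep(gamma, each = n)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dX <- (dxhat - rep(s1 / n, each = n) - xhat * rep(s2 / n, each = n)) *
        rep(cache$istd, each = n)
    list(dgamma = dgamma, dbeta = dbeta, dX = dX)
}

## ---- encoder: 4 x (dense -> batchnorm -> relu) -> dense -------------

# par: W[[1..B]], b[[..]], gamma[[..]], beta[[..]], Wout, bout
# buf: mean[[1..B]], var[[1..B]]
encoderInit <- function(inputLength, widths, dZ) {
    nb <- length(widths)
    fanIn <- c(inputLength, widths[-nb])
    par <- list(
        W = lapply(seq_len(nb), function(i) heInit(fanIn[i], widths[i])),
        b = lapply(widths, function(w) numeric(w)),
        gamma = lapply(widths, function(w) rep(1, w)),
        beta = lapply(widths, function(w) numeric(w)),
        Wout = heInit(widths[nb], dZ),
        bout = numeric(dZ))
    buf <- list(mean = lapply(widths, function(w) numeric(w)),
                var = lapply(widths, function(w) rep(1, w)))
    structure(list(par = par, buf = buf,
                   dims = list(inputLength = inputLength,
                               widths = widths, dZ = dZ)),
              class = c("EncoderParams", "list"))
}

encoderForward <- function(enc, X, mode = c("infer", "train")) {
    mode <- match.arg(mode)
    nb <- length(enc$par$W)
    caches <- vector("list", nb)
    H <- X
    for (i in seq_len(nb)) {
        d <- denseForward(H, enc$par$W[[i]], enc$par$b[[i]])
        bn <- bnForward(d$Y, enc$par$gamma[[i]], enc$par$beta[[i]],
                        enc$buf$mean[[i]], enc$buf$var[[i]], mode)
        A <- reluAct(bn$Y)
        caches[[i]] <- list(dense = d, bn = bn$cache, act = bn$Y)
        if (mode == "train") {
            enc$buf$mean[[i]] <- bn$runMean
            enc$buf$var[[i]] <- bn$runVar
        }
        H <- A
    }
    out <- denseForward(H, enc$par$Wout, enc$par$bout)
    list(Z = out$Y, cache = list(blocks = caches, out = out), enc = enc)
}

encoderBackward <- function(enc, cache, dZ) {
    nb <- length(enc$par$W)
    g <- list(W = vector("list", nb), b = vector("list", nb),
              gamma = vector("list", nb), beta = vector("list", nb))
    dOut <- denseBackward(cache$out, enc$par$Wout, dZ)
    g$Wout <- dOut$dW
    g$bout <- dOut$db
    dH <- dOut$dX
    for (i in rev(seq_len(nb))) {
        dA <- dH * (cache$blocks[[i]]$act > 0)
        dBn <- bnBackward(cache$blocks[[i]]$bn, enc$par$gamma[[i]], dA)
        g$gamma[[i]] <- dBn$dgamma
        g$beta[[i]] <- dBn$dbeta
        dD <- denseBackward(cache$blocks[[i]]$dense, enc$par$W[[i]],
                            dBn$dX)
        g$W[[i]] <- dD$dW
        g$b[[i]] <- dD$db
        dH <- dD$dX
    }
    list(grads = g[c("W", "b", "gamma", "beta", "Wout", "bout")], dX = dH)
}

## ---- GRU over a fixed-length latent sequence -------------------------

gruInit <- function(dIn, dHidden) {
    list(Wr = glorotInit(dIn, dHidden), Ur = glorotInit(dHidden, dHidden),
         br = numeric(dHidden),
         Wu = glorotInit(dIn, dHidden), Uu = glorotInit(dHidden, dHidden),
         bu = numeric(dHidden),
         Wn = glorotInit(dIn, dHidden), Un = glorotInit(dHidden, dHidden),
         bn = numeric(dHidden))
}

# Zs: list of t input matrices (batch x dIn); returns final hidden state
gruForward <- function(par, Zs) {
    b <- nrow(Zs[[1L]])
    dH <- ncol(par$Ur)
    h <- matrix(0, b, dH)
    steps <- vector("list", length(Zs))
    for (k in seq_along(Zs)) {
        Z <- Zs[[k]]
        r <- sigmoidAct(addBias(Z %*% par$Wr + h %*% par$Ur, par$br))
        u <- sigmoidAct(addBias(Z %*% par$Wu + h %*% par$Uu, par$bu))
        hu <- h %*% par$Un
        n <- tanh(addBias(Z %*% par$Wn + r * hu, par$bn))
        hNew <- (1 - u) * n + u * h
        steps[[k]] <- list(Z = Z, hPrev = h, r = r, u = u, n = n, hu = hu)
        h <- hNew
    }
    list(h = h, cache = steps)
}

gruBackward <- function(par, cache, dh) {
    g <- treeZero(par)
    dZs <- vector("list", length(cache))
    for (k in rev(seq_along(cache))) {
        st <- cache[[k]]
        dn <- dh * (1 - st$u)
        du <- dh * (st$hPrev - st$n)
        dhPrev <- dh * st$u
        dnPre <- dn * (1 - st$n * st$n)
        g$Wn <- g$Wn + crossprod(st$Z, dnPre)
        g$bn <- g$bn + colSums(dnPre)
        dr <- dnPre * st$hu
        dhu <- dnPre * st$r
        g$Un <- g$Un + crossprod(st$hPrev, dhu)
        dhPrev <- dhPrev + tcrossprod(dhu, par$Un)
        drPre <- dr * st$r * (1 - st$r)
        g$Wr <- g$Wr + crossprod(st$Z, drPre)
        g$Ur <- g$Ur + crossprod(st$hPrev, drPre)
        g$br <- g$br + colSums(drPre)
        dhPrev <- dhPrev + tcrossprod(drPre, par$Ur)
        duPre <- du * st$u * (1 - st$u)
        g$Wu <- g$Wu + crossprod(st$Z, duPre)
        g$Uu <- g$Uu + crossprod(st$hPrev, duPre)
        g$bu <- g$bu + colSums(duPre)
        dhPrev <- dhPrev + tcrossprod(duPre, par$Uu)
        dZs[[k]] <- tcrossprod(dnPre, par$Wn) + tcrossprod(drPre, par$Wr) +
            tcrossprod(duPre, par$Wu)
        dh <- dhPrev
    }
    list(grads = g, dZs = dZs)
}

## ---- 1-D convolution over a short sequence axis ----------------------

# Inputs are lists of per-position matrices (batch x channels); the kernel
# is a list of kernel-position matrices (channelsIn x channelsOut). Valid
# padding: Lout = Lin - kernel + 1.
convInit <- function(channelsIn, filters, kernel) {
    list(W = lapply(seq_len(kernel),
                    function(i) heInit(channelsIn, filters) / sqrt(kernel)),
         b = numeric(filters))
}

convForward <- function(par, Xs) {
    kernel <- length(par$W)
    lOut <- length(Xs) - kernel + 1L
    stopIfNot(lOut >= 1L, "sequence shorter than convolution kernel")
    Ys <- vector("list", lOut)
    for (p in seq_len(lOut)) {
        acc <- Xs[[p]] %*% par$W[[1L]]
        if (kernel > 1L)
            for (k in 2:kernel)
                acc <- acc + Xs[[p + k - 1L]] %*% par$W[[k]]
        Ys[[p]] <- addBias(acc, par$b)
    }
    list(Ys = Ys, Xs = Xs)
}

convBackward <- function(par, cache, dYs) {
    kernel <- length(par$W)
    lIn <- length(cache$Xs)
    g <- list(W = lapply(par$W, function(w) w * 0), b = par$b * 0)
    dXs <- lapply(cache$Xs, function(x) x * 0)
    for (p in seq_along(dYs)) {
        dY <- dYs[[p]]
        g$b <- g$b + colSums(dY)
        for (k in seq_len(kernel)) {
            q <- p + k - 1L
            g$W[[k]] <- g$W[[k]] + crossprod(cache$Xs[[q]], dY)
            dXs[[q]] <- dXs[[q]] + tcrossprod(dY, par$W[[k]])
        }
    }
    list(grads = g, dXs = dXs)
}

## ---- softmax / cross-entropy -----------------------------------------

softmaxRows <- function(X) {
    m <- apply(X, 1L, max)
    e <- exp(X - m)
    e / rowSums(e)
}

# one-hot categorical cross-entropy; labels are 0-based ids
crossEntropy <- function(P, labels) {
    n <- nrow(P)
    idx <- cbind(seq_len(n), labels + 1L)
    -mean(log(pmax(P[idx], 1e-12)))
}
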