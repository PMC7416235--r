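## Small feed-forward classifier in base R: fully-connected layers with
## per-feature batch normalisation, ReLU, inverted dropout, softmax output,
## categorical cross-entropy loss, Adam updates on mini-batches.
## Architecture for the reference configuration: d -> 300 -> 200 -> 100 -> K.

mlp_init <- function(d_in, hidden, n_class) {
  sizes <- c(d_in, hidden)
  layers <- vector("list", length(hidden))
  for (l in seq_along(hidden)) {
    fan_in <- sizes[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * hidden[l], sd = sqrt(2 / fan_in)),
                 fan_in, hidden[l]),
      gamma = rep(1, hidden[l]), beta = rep(0, hidden[l]),
      run_mean = rep(0, hidden[l]), run_var = rep(1, hidden[l])
    )
  }
  out <- list(
    W = matrix(stats::rnorm(hidden[length(hidden)] * n_class,
                            sd = sqrt(2 / hidden[length(hidden)])),
               hidden[length(hidden)], n_class),
    b = rep(0, n_class)
  )
  list(layers = layers, out = out)
}

## flatten/apply helpers for Adam state over arbitrary parameter lists
mlp_params <- function(net) {
  p <- list()
  for (l in seq_along(net$layers)) {
    p[[paste0("W", l)]] <- net$layers[[l]]$W
    p[[paste0("g", l)]] <- net$layers[[l]]$gamma
    p[[paste0("b", l)]] <- net$layers[[l]]$beta
  }
  p$Wo <- net$out$W
  p$bo <- net$out$b
  p
}

mlp_set_params <- function(net, p) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- p[[paste0("W", l)]]
    net$layers[[l]]$gamma <- p[[paste0("g", l)]]
    net$layers[[l]]$beta <- p[[paste0("b", l)]]
  }
  net$out$W <- p$Wo
  net$out$b <- p$bo
  net
}

mlp_forward <- function(net, X, training = FALSE, dropout = 0.5,
                        bn_eps = 1e-5, bn_momentum = 0.9) {
  cache <- list(A = list(), Zhat = list(), inv_sd = list(), mask = list())
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2L, mu)^2)
      inv_sd <- 1 / sqrt(v + bn_eps)
      Zhat <- sweep(sweep(Z, 2L, mu), 2L, inv_sd, "*")
      net$layers[[l]]$run_mean <- bn_momentum * ly$run_mean + (1 - bn_momentum) * mu
      net$layers[[l]]$run_var <- bn_momentum * ly$run_var + (1 - bn_momentum) * v
    } else {
      inv_sd <- 1 / sqrt(ly$run_var + bn_eps)
      Zhat <- sweep(sweep(Z, 2L, ly$run_mean), 2L, inv_sd, "*")
    }
    H <- sweep(sweep(Zhat, 2L, ly$gamma, "*"), 2L, ly$beta, "+")
    H <- pmax(H, 0)
    relu_mask <- H > 0
    if (training && dropout > 0) {
      keep <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H))
      H <- H * keep / (1 - dropout)
      cache$mask[[l]] <- keep
    }
    cache$A[[l]] <- A
    cache$Zhat[[l]] <- Zhat
    cache$inv_sd[[l]] <- inv_sd
    cache$relu[[l]] <- relu_mask
    A <- H
  }
  scores <- sweep(A %*% net$out$W, 2L, net$out$b, "+")
  scores <- scores - apply(scores, 1L, max)
  e <- exp(scores)
  probs <- e / rowSums(e)
  list(probs = probs, top = A, cache = cache, net = net)
}

mlp_backward <- function(net, fwd, Y, dropout = 0.5) {
  n <- nrow(Y)
  grads <- list()
  dscores <- (fwd$probs - Y) / n
  grads$Wo <- crossprod(fwd$top, dscores)
  grads$bo <- colSums(dscores)
  dA <- tcrossprod(dscores, net$out$W)      # dscores %*% t(Wo)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cache <- fwd$cache
    if (!is.null(cache$mask[[l]]))
      dA <- dA * cache$mask[[l]] / (1 - dropout)
    dH <- dA * cache$relu[[l]]
    Zhat <- cache$Zhat[[l]]
    grads[[paste0("g", l)]] <- colSums(dH * Zhat)
    grads[[paste0("b", l)]] <- colSums(dH)
    dZhat <- sweep(dH, 2L, ly$gamma, "*")
    ## batch-norm backward under batch statistics:
    ## dZ = inv_sd * (dZhat - mean(dZhat) - Zhat * mean(dZhat * Zhat))
    m1 <- colMeans(dZhat)
    m2 <- colMeans(dZhat * Zhat)
    dZ <- sweep(dZhat, 2L, m1) - sweep(Zhat, 2L, m2, "*")
    dZ <- sweep(dZ, 2L, cache$inv_sd[[l]], "*")
    grads[[paste0("W", l)]] <- crossprod(cache$A[[l]], dZ)
    dA <- tcrossprod(dZ, ly$W)               # dZ %*% t(W)
  }
  grads
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the feed-forward network classifier
#'
#' Fully-connected network with hidden layers (default 300/200/100), ReLU
#' activations, per-feature batch normalisation and inverted dropout on each
#' hidden layer, a softmax output, categorical cross-entropy loss, and Adam
#' mini-batch updates (batch size 32, learning rate 1e-3 by default).
#' Training and prediction are deterministic given `seed`.
#'
#' @param x numeric feature matrix (samples x features).
#' @param y factor of class labels.
#' @param hidden hidden layer sizes (default `c(300, 200, 100)`).
#' @param dropout dropout probability per hidden layer (default 0.5).
#' @param batch_size mini-batch size (default 32).
#' @param epochs training epochs (default 200).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for initialisation, shuffling and dropout.
#' @return object of class `"mlp_model"` with a [predict.mlp_model()] method;
#'   field `epoch_loss` records the mean training loss per epoch.
#' @export
train_mlp <- function(x, y, hidden = c(300L, 200L, 100L), dropout = 0.5,
                      batch_size = 32L, epochs = 200L, lr = 1e-3, seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  set.seed(as.integer(seed))
  K <- nlevels(y)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  net <- mlp_init(ncol(x), hidden, K)
  params <- mlp_params(net)
  state <- list(t = 0L,
                m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- nrow(x)
  epoch_loss <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      if (length(idx) < 2L) next               # batch-norm needs >= 2 rows
      fwd <- mlp_forward(net, x[idx, , drop = FALSE], training = TRUE,
                         dropout = dropout)
      net <- fwd$net                           # updated running statistics
      p <- pmax(fwd$probs, 1e-12)
      losses <- c(losses, -mean(rowSums(Y[idx, , drop = FALSE] * log(p))))
      grads <- mlp_backward(net, fwd, Y[idx, , drop = FALSE], dropout)
      upd <- adam_step(mlp_params(net), grads, state, lr = lr)
      state <- upd$state
      net <- mlp_set_params(net, upd$params)
    }
    epoch_loss[ep] <- mean(losses)
  }
  structure(list(net = net, levels = levels(y), hidden = hidden,
                 dropout = dropout, epoch_loss = epoch_loss),
            class = "mlp_model")
}

#' Predict method for the feed-forward network
#'
#' Uses batch-normalisation running statistics and no dropout, so prediction
#' is deterministic given the fitted state.
#'
#' @param object an `"mlp_model"`.
#' @param newdata feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @export
predict.mlp_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  fwd <- mlp_forward(object$net, as.matrix(newdata), training = FALSE)
  if (type == "prob") {
    colnames(fwd$probs) <- object$levels
    return(fwd$probs)
  }
  factor(object$levels[max.col(fwd$probs, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("feed-forward classifier:", paste(x$hidden, collapse = "-"),
      "hidden units; final epoch loss",
      format(x$epoch_loss[length(x$epoch_loss)], digits = 4), "\n")
  invisible(x)
}
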