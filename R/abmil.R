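#' ABMIL hyperparameter configuration
#'
#' Architecture and optimization settings for the gated attention-based
#' multiple instance learning head. Defaults follow common ABMIL practice for
#' whole-slide modelling: a 512-unit patch embedder with ReLU and dropout
#' 0.25, a 384-dimensional gated attention (parallel tanh and sigmoid
#' branches combined elementwise and projected to a scalar score per patch),
#' AdamW with learning rate 1e-4, at most 40 epochs with early stopping on
#' validation loss (patience 5), one bag per optimization step.
#'
#' @param embed_dim Patch embedder width `L`.
#' @param attention_dim Gated-attention width `D`.
#' @param dropout Dropout probability on the embedded patches, in `[0, 1)`;
#'   active in training only.
#' @param lr AdamW learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @return Object of class `abmil_config`.
#' @export
abmil_config <- function(embed_dim = 512, attention_dim = 384, dropout = 0.25,
                         lr = 1e-4, weight_decay = 1e-2,
                         max_epochs = 40, patience = 5) {
  stopifnot(embed_dim >= 1, attention_dim >= 1,
            dropout >= 0, dropout < 1, lr > 0, max_epochs >= 1, patience >= 1)
  structure(list(embed_dim = as.integer(embed_dim),
                 attention_dim = as.integer(attention_dim),
                 dropout = dropout, lr = lr, weight_decay = weight_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience)),
            class = "abmil_config")
}

# Glorot-uniform weight initialization; RNG state is the caller's concern.
.abmil_init <- function(d, L, D, K) {
  gl <- function(fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
  }
  list(W1 = gl(d, L), b1 = numeric(L),
       V = gl(L, D), bV = numeric(D),
       U = gl(L, D), bU = numeric(D),
       w = drop(gl(D, 1)), bw = 0,
       W2 = gl(L, K), b2 = numeric(K))
}

# add a per-column bias vector to an N x k matrix
.addb <- function(M, b) M + rep(b, each = nrow(M))

# Forward pass through the gated ABMIL head.
#   h_i   = dropout(relu(W1 x_i))
#   a_i   = w' (tanh(V h_i) * sigmoid(U h_i))
#   alpha = softmax(a); z = sum_i alpha_i h_i; out = W2' z
# Returns output, attention, and (optionally) the cache for backprop.
.abmil_forward <- function(params, X, dropout = 0, cache = FALSE) {
  pre1 <- .addb(X %*% params$W1, params$b1)
  H0 <- pre1 * (pre1 > 0)
  if (dropout > 0) {
    mask <- matrix((stats::runif(length(H0)) >= dropout) / (1 - dropout),
                   nrow(H0), ncol(H0))
    H <- H0 * mask
  } else {
    mask <- NULL
    H <- H0
  }
  At <- tanh(.addb(H %*% params$V, params$bV))
  As <- stats::plogis(.addb(H %*% params$U, params$bU))
  G <- At * As
  a <- drop(G %*% params$w) + params$bw
  e <- exp(a - max(a))
  alpha <- e / sum(e)
  z <- drop(crossprod(alpha, H))
  out <- drop(z %*% params$W2) + params$b2
  res <- list(out = out, attention = alpha)
  if (cache) {
    res$cache <- list(X = X, pre1 = pre1, mask = mask, H = H, At = At,
                      As = As, G = G, alpha = alpha, z = z)
  }
  res
}

# Backward pass; dout is dLoss/dout (length K). Returns gradients named as
# the parameter list.
.abmil_backward <- function(params, cache, dout) {
  X <- cache$X; H <- cache$H; alpha <- cache$alpha
  dW2 <- tcrossprod(cache$z, dout)           # L x K
  db2 <- dout
  dz <- drop(params$W2 %*% dout)             # L
  dalpha <- drop(H %*% dz)                   # N
  dH <- tcrossprod(alpha, dz)                # N x L (from z = alpha' H)
  da <- alpha * (dalpha - sum(alpha * dalpha))
  dG <- tcrossprod(da, params$w)             # N x D
  dw <- drop(crossprod(cache$G, da))
  dbw <- sum(da)
  dpre_t <- dG * cache$As * (1 - cache$At^2)
  dpre_s <- dG * cache$At * cache$As * (1 - cache$As)
  dV <- crossprod(H, dpre_t); dbV <- colSums(dpre_t)
  dU <- crossprod(H, dpre_s); dbU <- colSums(dpre_s)
  dH <- dH + tcrossprod(dpre_t, params$V) + tcrossprod(dpre_s, params$U)
  if (!is.null(cache$mask)) dH <- dH * cache$mask
  dpre1 <- dH * (cache$pre1 > 0)
  dW1 <- crossprod(X, dpre1); db1 <- colSums(dpre1)
  list(W1 = dW1, b1 = db1, V = dV, bV = dbV, U = dU, bU = dbU,
       w = dw, bw = dbw, W2 = dW2, b2 = db2)
}

# per-bag loss and output gradient
.abmil_loss <- function(out, y, task) {
  if (task == "classification") {
    p <- exp(out - max(out)); p <- p / sum(p)
    loss <- -log(max(p[y + 1L], 1e-12))
    dout <- p; dout[y + 1L] <- dout[y + 1L] - 1
  } else {
    loss <- (out - y)^2
    dout <- 2 * (out - y)
  }
  list(loss = loss, dout = dout)
}

# one AdamW step over the parameter list; returns updated (params, m, v)
.adamw_step <- function(params, grads, m, v, t, lr, wd,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g^2
    mh <- m[[nm]] / (1 - beta1^t)
    vh <- v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * (mh / (sqrt(vh) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, m = m, v = v)
}

.mean_loss <- function(params, X_list, y, task) {
  mean(vapply(seq_along(X_list), function(i) {
    fw <- .abmil_forward(params, X_list[[i]])
    .abmil_loss(fw$out, y[i], task)$loss
  }, numeric(1)))
}

#' Fit a gated attention-based multiple instance learning model
#'
#' Trains the gated ABMIL head on bags of patch embeddings. Each patch is
#' embedded through a fully connected ReLU layer with dropout; a gated
#' attention mechanism (elementwise product of a tanh branch and a sigmoid
#' branch, linearly projected) scores each patch, softmax-normalized scores
#' weight the patch embeddings into a slide-level vector, and a final linear
#' layer produces two logits (classification of high vs low/medium risk) or
#' one continuous score (ROR-P regression). Optimized with AdamW,
#' cross-entropy or squared-error loss, one bag per step, early-stopped on a
#' validation set; the returned weights are those of the best validation
#' epoch. Training is deterministic given `seed`.
#'
#' @param x List of [embedding_bag()] objects (or bare numeric matrices),
#'   the training bags.
#' @param y Labels aligned to `x`: 0/1 for `task = "classification"`,
#'   continuous scores for `task = "regression"`. Regression targets are
#'   standardized internally; predictions are returned on the original scale.
#' @param task `"classification"` or `"regression"`.
#' @param val_x,val_y Validation bags and labels (disjoint from training at
#'   the participant level in any honest evaluation). When omitted, a
#'   stratified random ~15 percent of the training bags is held out.
#' @param config An [abmil_config()].
#' @param seed Integer seed controlling initialization, dropout and data
#'   order.
#' @return Object of class `abmil` with elements `params`, `task`, `config`,
#'   `history` (per-epoch train/validation loss), `best_epoch`, and the
#'   regression target scaling. Supports [predict.abmil()], `print`,
#'   `summary`, `coef`, `residuals` and `fitted`.
#' @export
abmil <- function(x, y, task = c("classification", "regression"),
                  val_x = NULL, val_y = NULL,
                  config = abmil_config(), seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(config, "abmil_config"))
  X_list <- lapply(x, .bag_features)
  if (length(X_list) == 0L) stop("empty training set", call. = FALSE)
  if (length(y) != length(X_list)) stop("y must align with x", call. = FALSE)
  d <- ncol(X_list[[1]])
  if (any(vapply(X_list, ncol, integer(1)) != d)) {
    stop("all bags must share the embedding dimension", call. = FALSE)
  }
  set.seed(as.integer(seed))

  if (is.null(val_x)) {
    n <- length(X_list)
    if (n < 5L) stop("too few bags to split off a validation set", call. = FALSE)
    strat <- if (task == "classification") y else rep(0L, n)
    hold <- unlist(lapply(split(seq_len(n), strat), function(ix) {
      sample(ix, max(1L, round(0.15 * length(ix))))
    }), use.names = FALSE)
    val_X <- X_list[hold]; val_yy <- y[hold]
    X_list <- X_list[-hold]; y <- y[-hold]
  } else {
    if (length(val_x) == 0L) stop("empty validation set", call. = FALSE)
    val_X <- lapply(val_x, .bag_features)
    val_yy <- val_y
  }
  if (length(X_list) == 0L) stop("empty training split", call. = FALSE)

  y_center <- 0; y_scale <- 1
  if (task == "regression") {
    y_center <- mean(y)
    y_scale <- stats::sd(y)
    if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
    y <- (y - y_center) / y_scale
    val_yy <- (val_yy - y_center) / y_scale
  } else {
    y <- as.integer(y)
    val_yy <- as.integer(val_yy)
    if (any(!(y %in% c(0L, 1L)))) stop("classification labels must be 0/1",
                                       call. = FALSE)
  }

  K <- if (task == "classification") 2L else 1L
  params <- .abmil_init(d, config$embed_dim, config$attention_dim, K)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  t_step <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  bad_epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(length(X_list))
    tr_loss <- 0
    for (i in ord) {
      fw <- .abmil_forward(params, X_list[[i]], dropout = config$dropout,
                           cache = TRUE)
      ls <- .abmil_loss(fw$out, y[i], task)
      tr_loss <- tr_loss + ls$loss
      grads <- .abmil_backward(params, fw$cache, ls$dout)
      t_step <- t_step + 1L
      upd <- .adamw_step(params, grads, m, v, t_step,
                         config$lr, config$weight_decay)
      params <- upd$params; m <- upd$m; v <- upd$v
    }
    val_loss <- .mean_loss(params, val_X, val_yy, task)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = tr_loss / length(X_list),
                                val_loss = val_loss))
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }

  fit <- structure(
    list(params = best$params, task = task, config = config,
         input_dim = d, n_train = length(X_list), n_val = length(val_X),
         y_center = y_center, y_scale = y_scale,
         history = history, best_epoch = best$epoch,
         best_val_loss = best$loss, seed = as.integer(seed)),
    class = "abmil"
  )
  fit
}

.bag_features <- function(b) {
  if (inherits(b, "embedding_bag")) b$features
  else if (is.matrix(b)) b
  else stop("bags must be embedding_bag objects or numeric matrices",
            call. = FALSE)
}

#' Predict from a fitted ABMIL model
#'
#' Evaluation-mode forward passes (dropout inactive, deterministic).
#'
#' @param object A fitted [abmil()] model.
#' @param newdata A single bag or a list of bags ([embedding_bag()] objects
#'   or numeric matrices with the model's input dimension).
#' @param type `"response"` (positive-class probability for classification,
#'   score on the original scale for regression), `"prob"` (matrix of class
#'   probabilities), `"logits"`, or `"attention"` (list of per-patch softmax
#'   attention vectors, each summing to 1).
#' @param ... Unused.
#' @return Numeric vector, matrix, or list according to `type`.
#' @export
predict.abmil <- function(object, newdata,
                          type = c("response", "prob", "logits", "attention"),
                          ...) {
  type <- match.arg(type)
  if (inherits(newdata, "embedding_bag") || is.matrix(newdata)) {
    newdata <- list(newdata)
  }
  X_list <- lapply(newdata, .bag_features)
  for (X in X_list) {
    if (ncol(X) != object$input_dim) {
      stop(sprintf("bag has %d feature columns; model expects %d",
                   ncol(X), object$input_dim), call. = FALSE)
    }
  }
  fws <- lapply(X_list, function(X) .abmil_forward(object$params, X))
  if (type == "attention") {
    return(lapply(fws, `[[`, "attention"))
  }
  outs <- do.call(rbind, lapply(fws, `[[`, "out"))
  if (object$task == "classification") {
    pm <- exp(outs - apply(outs, 1, max))
    pm <- pm / rowSums(pm)
    colnames(pm) <- c("low_medium", "high")
    switch(type,
           response = unname(pm[, 2]),
           prob = pm,
           logits = unname(outs))
  } else {
    sc <- drop(outs) * object$y_scale + object$y_center
    switch(type,
           response = unname(sc),
           prob = stop("type = 'prob' applies to classification models",
                       call. = FALSE),
           logits = unname(drop(outs)))
  }
}

#' @export
print.abmil <- function(x, ...) {
  cat(sprintf("gated ABMIL %s model: d = %d -> L = %d, D = %d\n",
              x$task, x$input_dim, x$config$embed_dim, x$config$attention_dim))
  cat(sprintf("trained on %d bags (%d validation); best epoch %d, val loss %.4g\n",
              x$n_train, x$n_val, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
summary.abmil <- function(object, ...) {
  npar <- sum(vapply(object$params, length, integer(1)))
  cat(sprintf("gated ABMIL (%s), %d parameters\n", object$task, npar))
  print(utils::tail(object$history, 5))
  invisible(object)
}

#' @export
coef.abmil <- function(object, ...) object$params

#' Residuals and fitted values on a bag list
#' @param object A fitted [abmil()] model.
#' @param newdata,y Bags and their labels.
#' @param ... Unused.
#' @export
residuals.abmil <- function(object, newdata, y, ...) {
  y - predict(object, newdata, type = "response")
}
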