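#' Single graph-convolution layer
#'
#' Applies `nonlinearity(A_norm %*% H_in %*% W)`: each cell aggregates its
#' own and its neighbors' features under the degree-normalized, self-looped
#' operator before the linear map.
#'
#' @param A_norm renormalized adjacency from [normalize_adjacency()].
#' @param H_in cells x p input features.
#' @param W p x q weight matrix.
#' @param nonlinearity `"relu"`, `"identity"`, or a function.
#' @return cells x q matrix.
#' @export
gcn_layer <- function(A_norm, H_in, W, nonlinearity = "relu") {
  H_in <- as.matrix(H_in); W <- as.matrix(W)
  if (nrow(A_norm) != ncol(A_norm) || ncol(A_norm) != nrow(H_in))
    stop_param("A_norm (", nrow(A_norm), "x", ncol(A_norm),
               ") does not conform with H_in (", nrow(H_in), " rows)")
  if (ncol(H_in) != nrow(W))
    stop_param("H_in has ", ncol(H_in), " columns but W has ", nrow(W), " rows")
  f <- if (is.function(nonlinearity)) nonlinearity else
    switch(nonlinearity,
           relu = function(z) pmax(z, 0),
           identity = identity,
           stop_param("unknown nonlinearity: ", nonlinearity))
  f(as.matrix(A_norm %*% H_in) %*% W)
}

#' Row-wise numerically stable softmax
#'
#' Maps each row of logits to a probability distribution proportional to the
#' exponentials of its entries; the row maximum is subtracted first so the
#' result is shift-invariant and overflow-free.
#'
#' @param z numeric matrix (or vector, treated as one row).
#' @return Matrix of the same shape with positive rows summing to 1.
#' @export
row_softmax <- function(z) {
  z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (any(!is.finite(z))) stop_param("softmax requires finite inputs")
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Initialize a two-layer GCN model
#'
#' Glorot-uniform weights, seeded for reproducibility.
#'
#' @param n_genes input features (genes).
#' @param h latent dimension of the first layer.
#' @param classes character vector of condition names (lexicographic class
#'   order is the caller's responsibility; [train_gcn()] handles it).
#' @param seed integer seed for the weight draw.
#' @param activation layer-1 nonlinearity, default `"relu"`.
#' @return A `cello_model` with fields `W0` (genes x h), `W1` (h x c),
#'   `h`, `classes`, `activation`, `seed`.
#' @export
init_model <- function(n_genes, h, classes, seed = 1, activation = "relu") {
  check_scalar(h, "h", lower = 1, integerish = TRUE)
  if (length(classes) < 2) stop_param("need >= 2 classes")
  withr::with_seed(seed, {
    structure(list(W0 = glorot_uniform(n_genes, h),
                   W1 = glorot_uniform(h, length(classes)),
                   h = as.integer(h), classes = as.character(classes),
                   activation = activation, seed = as.integer(seed)),
              class = "cello_model")
  })
}

#' Forward pass of the two-layer GCN
#'
#' `H0 = activation(A_norm X W0)` is the latent embedding;
#' `P = row_softmax(A_norm H0 W1)` the per-cell condition probabilities.
#'
#' @param model a `cello_model`.
#' @param A_norm renormalized adjacency.
#' @param X cells x genes feature matrix.
#' @return List with `H0` (cells x h) and `P` (cells x c, rows sum to 1).
#' @export
gcn_forward <- function(model, A_norm, X) {
  H0 <- gcn_layer(A_norm, X, model$W0, model$activation)
  P <- row_softmax(as.matrix(A_norm %*% H0) %*% model$W1)
  colnames(P) <- model$classes
  list(H0 = H0, P = P)
}

#' Sample semi-supervised train/validation/test masks
#'
#' Draws exactly `budget_per_condition` training cells uniformly without
#' replacement from each condition (a fraction below 1 is interpreted per
#' condition, e.g. `0.03` labels 3% of each condition's cells, at least one).
#' Remaining cells are split into validation (`val_fraction`) and test.
#'
#' @param labels per-cell condition factor.
#' @param budget_per_condition integer count, or fraction in (0, 1).
#' @param val_fraction fraction of non-training cells used for validation.
#' @param seed integer seed.
#' @return A `cello_masks` list with disjoint integer index vectors
#'   `train_idx`, `val_idx`, `test_idx` and the resolved per-condition budget.
#' @export
sample_masks <- function(labels, budget_per_condition, val_fraction = 0.2,
                         seed = 1) {
  labels <- as_condition_factor(labels)
  check_scalar(val_fraction, "val_fraction", lower = 0, upper = 1)
  sizes <- tabulate(labels, nbins = nlevels(labels))
  names(sizes) <- levels(labels)
  budgets <- if (budget_per_condition < 1) {
    pmax(1L, as.integer(round(budget_per_condition * sizes)))
  } else {
    rep(as.integer(budget_per_condition), nlevels(labels))
  }
  over <- budgets > sizes
  if (any(over))
    stop_param("training budget (", paste(budgets[over], collapse = ","),
               ") exceeds condition size for: ",
               paste(levels(labels)[over], collapse = ", "))
  withr::with_seed(seed, {
    train_idx <- sort(unlist(lapply(seq_len(nlevels(labels)), function(c) {
      pool <- which(as.integer(labels) == c)
      sample(pool, budgets[c])
    })))
    rest <- setdiff(seq_along(labels), train_idx)
    n_val <- floor(val_fraction * length(rest))
    val_idx <- sort(sample(rest, n_val))
    test_idx <- sort(setdiff(rest, val_idx))
    structure(list(train_idx = train_idx, val_idx = val_idx,
                   test_idx = test_idx, per_condition_budget = budgets),
              class = "cello_masks")
  })
}

#' Masked categorical cross-entropy
#'
#' Mean over the masked cells of `-log P(true class)`; probabilities are
#' clipped below at `eps` so a zero predicted probability yields a large
#' finite loss rather than `Inf`.
#'
#' @param P cells x c row-stochastic matrix.
#' @param labels per-cell class (factor or integer codes `1..c`).
#' @param mask integer indices of the cells entering the loss.
#' @param eps clipping floor for predicted probabilities.
#' @return Non-negative scalar; exactly 0 iff every masked cell puts
#'   probability 1 on its class.
#' @export
cross_entropy <- function(P, labels, mask, eps = 1e-12) {
  if (length(mask) == 0) stop_param("mask must be nonempty")
  y <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  p_true <- P[cbind(mask, y[mask])]
  mean(-log(pmax(p_true, eps)))
}

#' Training configuration
#'
#' Defaults: 200 epochs with early stopping at patience 30 on validation
#' loss, Adam with learning rate 0.01 and weight decay 5e-4.
#'
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation-loss improvement before stopping.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param h latent dimension of the first layer.
#' @param seed integer seed controlling initialization.
#' @return A `cello_train_config` list.
#' @export
train_config <- function(max_epochs = 200, patience = 30,
                         learning_rate = 0.01, weight_decay = 5e-4,
                         h = 32, seed = 1) {
  check_scalar(max_epochs, "max_epochs", lower = 1, integerish = TRUE)
  check_scalar(patience, "patience", lower = 1, integerish = TRUE)
  if (patience > max_epochs)
    stop_param("patience (", patience, ") must be <= max_epochs (",
               max_epochs, ")")
  check_scalar(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar(weight_decay, "weight_decay", lower = 0)
  check_scalar(h, "h", lower = 1, integerish = TRUE)
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 h = as.integer(h), seed = as.integer(seed)),
            class = "cello_train_config")
}

#' Train the two-layer GCN by masked cross-entropy
#'
#' Full-batch Adam on the training-mask cross-entropy, observing the whole
#' graph but only the training cells' labels. Training stops at `max_epochs`
#' or once the validation loss has not improved for `patience` consecutive
#' epochs; the returned weights are those of the best validation epoch.
#' Fully reproducible for a fixed `config$seed`.
#'
#' @param X cells x genes feature matrix (preprocessed expression).
#' @param A_norm renormalized adjacency.
#' @param labels per-cell condition labels; classes are ordered
#'   lexicographically by name.
#' @param masks a `cello_masks` from [sample_masks()].
#' @param config a [train_config()].
#' @return A `cello_model` augmented with `history` (per-epoch data frame of
#'   train/val loss and accuracy) and `best_epoch`.
#' @export
train_gcn <- function(X, A_norm, labels, masks, config = train_config()) {
  stopifnot(inherits(masks, "cello_masks"))
  labels <- as_condition_factor(labels)
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X); cls <- levels(labels); C <- length(cls)
  y <- as.integer(labels)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), y)] <- 1

  model <- init_model(m, config$h, cls, seed = config$seed)
  SX <- as.matrix(A_norm %*% X)
  tr <- masks$train_idx; va <- masks$val_idx
  ntr <- length(tr)

  adam <- function(shape) list(m = array(0, shape), v = array(0, shape))
  st0 <- adam(dim(model$W0)); st1 <- adam(dim(model$W1))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay

  best_val <- Inf; best <- model; best_epoch <- 0L; wait <- 0L
  hist <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    Z0 <- SX %*% model$W0
    H0 <- pmax(Z0, 0)
    SH0 <- as.matrix(A_norm %*% H0)
    Z1 <- SH0 %*% model$W1
    P <- row_softmax(Z1)
    if (any(!is.finite(P)))
      stop_param("non-finite probabilities at epoch ", epoch,
                 "; lower the learning rate")

    train_loss <- cross_entropy(P, y, tr)
    val_loss <- if (length(va)) cross_entropy(P, y, va) else train_loss
    pred <- max.col(P, ties.method = "first")
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = train_loss, val_loss = val_loss,
      train_acc = mean(pred[tr] == y[tr]),
      val_acc = if (length(va)) mean(pred[va] == y[va]) else NA_real_)

    if (val_loss < best_val) {
      best_val <- val_loss; best <- model; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) { hist <- hist[seq_len(epoch)]; break }
    }

    # backward pass: dL/dZ1 = (P - Y)/n_train on training rows, 0 elsewhere
    G1 <- P - Y
    G1[-tr, ] <- 0
    G1 <- G1 / ntr
    dW1 <- crossprod(SH0, G1) + wd * model$W1
    dH0 <- as.matrix(A_norm %*% (G1 %*% t(model$W1)))
    dZ0 <- dH0 * (Z0 > 0)
    dW0 <- crossprod(SX, dZ0) + wd * model$W0

    step <- function(W, g, st, t) {
      st$m <- b1 * st$m + (1 - b1) * g
      st$v <- b2 * st$v + (1 - b2) * g^2
      mh <- st$m / (1 - b1^t); vh <- st$v / (1 - b2^t)
      list(W = W - lr * mh / (sqrt(vh) + aeps), st = st)
    }
    s0 <- step(model$W0, dW0, st0, epoch); model$W0 <- s0$W; st0 <- s0$st
    s1 <- step(model$W1, dW1, st1, epoch); model$W1 <- s1$W; st1 <- s1$st
  }

  best$history <- do.call(rbind, hist)
  best$best_epoch <- best_epoch
  best$masks <- masks
  rownames(best$W0) <- colnames(X)
  best
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding both weight matrices, the
#' class-name order, latent dimension, activation and seed.
#'
#' @param model a `cello_model`.
#' @param path checkpoint file path.
#' @return `path` (write) or the restored `cello_model` (read).
#' @export
write_checkpoint <- function(model, path) {
  obj <- list(W0 = model$W0, W1 = model$W1, h = model$h,
              classes = model$classes, activation = model$activation,
              seed = model$seed, gene_names = rownames(model$W0))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(W0 = as.matrix(obj$W0), W1 = as.matrix(obj$W1),
                h = as.integer(obj$h), classes = obj$classes,
                activation = obj$activation, seed = as.integer(obj$seed))
  if (!is.null(obj$gene_names)) rownames(model$W0) <- obj$gene_names
  structure(model, class = "cello_model")
}
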