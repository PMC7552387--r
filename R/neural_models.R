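#' Pyramid network architecture specification
#'
#' The default classifier is a 6-layer pyramid: input, fully connected 128
#' nodes + dropout, fully connected 64 nodes + dropout, logistic output.
#' Hidden layers use ReLU activation.
#'
#' @param input_nodes Number of input features.
#' @param hidden Ordered hidden layer sizes.
#' @param dropout_p Dropout probability after each hidden layer (training
#'   only).
#' @return Object of class `net_spec`.
#' @export
net_spec <- function(input_nodes, hidden = c(128L, 64L), dropout_p = 0.5) {
  stopifnot(input_nodes >= 1, dropout_p >= 0, dropout_p < 1)
  structure(list(input_nodes = as.integer(input_nodes),
                 hidden = as.integer(hidden), dropout_p = dropout_p),
            class = "net_spec")
}

#' Training hyperparameters for the pyramid network
#'
#' Defaults follow the benchmark's standard setting: learning rate 0.01, no
#' decay, batch size 20, 100 epochs, Nesterov momentum 0.9, dropout 0.5, and
#' L1/L2 penalty weights 0.001 each.
#'
#' @param lr Initial learning rate (> 0).
#' @param lr_decay Per-epoch decay: `lr_t = lr / (1 + lr_decay * t)` with
#'   `t` the 0-based epoch index.
#' @param batch_size Mini-batch size.
#' @param max_iter Number of epochs (one pass over shuffled data; the final
#'   partial batch is kept).
#' @param momentum Nesterov momentum coefficient in `[0, 1)`.
#' @param dropout_p Dropout probability override (`NULL` = use the `net_spec` value).
#' @param lambda1,lambda2 L1 and L2 penalty weights on connection weights
#'   (biases unpenalized).
#' @param l2_squared If `TRUE` (default) the L2 term is the squared norm
#'   `lambda2 * ||W||^2` (weight decay); `FALSE` uses the unsquared norm.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 0.01, lr_decay = 0, batch_size = 20L,
                         max_iter = 100L, momentum = 0.9, dropout_p = NULL,
                         lambda1 = 0.001, lambda2 = 0.001, l2_squared = TRUE,
                         seed = 1L) {
  stopifnot(lr > 0, lr_decay >= 0, batch_size >= 1, max_iter >= 0,
            momentum >= 0, momentum < 1, lambda1 >= 0, lambda2 >= 0)
  structure(list(lr = lr, lr_decay = lr_decay,
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter), momentum = momentum,
                 dropout_p = dropout_p, lambda1 = lambda1, lambda2 = lambda2,
                 l2_squared = isTRUE(l2_squared), seed = as.integer(seed)),
            class = "train_config")
}

as_y01 <- function(y) {
  if (all(y %in% c(-1, 1))) (y + 1) / 2
  else if (all(y %in% c(0, 1))) as.numeric(y)
  else stop("labels must be coded -1/+1 or 0/1")
}

#' Train the pyramid classifier by mini-batch SGD with Nesterov momentum
#'
#' @param X Standardized feature matrix (samples in rows).
#' @param y Labels in `{-1, +1}` (or `{0, 1}`).
#' @param spec A [net_spec()]; its `input_nodes` must match `ncol(X)`.
#' @param cfg A [train_config()].
#' @param init Optional warm-start `net_state` (e.g. for fine-tuning).
#' @return Object of class `net_state`: weight list `W`, bias list `b`,
#'   per-epoch `loss_log`, and the architecture/training configuration used.
#' @export
mlp_train <- function(X, y, spec, cfg = train_config(), init = NULL) {
  stopifnot(inherits(spec, "net_spec"), inherits(cfg, "train_config"))
  if (ncol(X) != spec$input_nodes)
    stop("ncol(X) = ", ncol(X), " does not match input_nodes = ",
         spec$input_nodes)
  y01 <- as_y01(y)
  if (length(unique(y01)) < 2) stop("both classes must be present in y")
  dp <- if (is.null(cfg$dropout_p)) spec$dropout_p else cfg$dropout_p
  init_list <- if (!is.null(init)) list(W = init$W, b = init$b)
  fit <- mlp_train_cpp(X, y01, spec$hidden, cfg$lr, cfg$lr_decay,
                       cfg$batch_size, cfg$max_iter, cfg$momentum, dp,
                       cfg$lambda1, cfg$lambda2, cfg$l2_squared, cfg$seed,
                       init_list)
  structure(list(W = fit$W, b = fit$b, loss_log = as.numeric(fit$loss_log),
                 spec = spec, cfg = cfg),
            class = "net_state")
}

#' Predicted positive-class probabilities
#'
#' Deterministic forward pass with dropout disabled.
#'
#' @param net A `net_state` (from [mlp_train()] or a transfer method).
#' @param X Feature matrix with the same number of columns the network was
#'   trained on.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(net, X) {
  if (ncol(X) != nrow(net$W[[1]]))
    stop("X has ", ncol(X), " features but the network expects ",
         nrow(net$W[[1]]))
  as.numeric(mlp_predict_cpp(net$W, net$b, X))
}

#' Regularized cross-entropy loss of a network on a batch
#'
#' Mean binary cross-entropy over the batch (predictions clipped at 1e-7)
#' plus `lambda1 * sum(|W|)` and the L2 term over connection weights.
#'
#' @inheritParams predict_proba
#' @param y Labels in `{-1, +1}` or `{0, 1}`.
#' @param lambda1,lambda2 Penalty weights.
#' @param l2_squared Squared-norm (default) vs unsquared L2 convention.
#' @return Scalar loss.
#' @export
mlp_loss <- function(net, X, y, lambda1 = 0, lambda2 = 0, l2_squared = TRUE) {
  mlp_loss_grad_cpp(net$W, net$b, X, as_y01(y), lambda1, lambda2,
                    l2_squared)$loss
}

#' Analytic gradients of the regularized loss
#'
#' Dropout-free full-batch gradients of [mlp_loss()] with respect to every
#' weight and bias; used for finite-difference verification.
#'
#' @inheritParams mlp_loss
#' @return List with `loss`, `gW` (list of matrices), `gb` (list of vectors).
#' @export
mlp_loss_grad <- function(net, X, y, lambda1 = 0, lambda2 = 0,
                          l2_squared = TRUE) {
  mlp_loss_grad_cpp(net$W, net$b, X, as_y01(y), lambda1, lambda2, l2_squared)
}

#' Rectified linear unit
#'
#' @param x Numeric vector/matrix.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) pmax(x, 0)

#' Stacked denoising autoencoder specification
#'
#' Five layers: input, coding layer (128), bottleneck (64), decoding layer
#' (128), and a linear output reconstructing the input. Hidden layers are
#' ReLU; training corrupts a fraction of input entries to zero per
#' presentation and minimises squared reconstruction error.
#'
#' @param input_nodes Input (= output) dimension.
#' @param hidden Encoder/decoder sizes, mirror-symmetric.
#' @param corruption_level Fraction of entries masked to zero, in `[0, 1)`.
#' @param lr Learning rate.
#' @param batch_size Mini-batch size.
#' @param max_iter Number of epochs.
#' @param seed Integer seed.
#' @return Object of class `sda_spec`.
#' @export
sda_spec <- function(input_nodes, hidden = c(128L, 64L, 128L),
                     corruption_level = 0.3, lr = 0.01, batch_size = 32L,
                     max_iter = 500L, seed = 1L) {
  stopifnot(corruption_level >= 0, corruption_level < 1)
  h <- as.integer(hidden)
  if (!identical(h, rev(h)))
    stop("hidden sizes must be mirror-symmetric, got ",
         paste(h, collapse = "-"))
  structure(list(input_nodes = as.integer(input_nodes), hidden = h,
                 corruption_level = corruption_level, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "sda_spec")
}

#' Pretrain a stacked denoising autoencoder
#'
#' @param X Standardized (unlabeled) feature matrix.
#' @param spec An [sda_spec()].
#' @return List of class `sda_state`: full `W`/`b`, `encoder_W`/`encoder_b`
#'   (input -> 128 -> 64), and the per-epoch reconstruction `loss_log`.
#' @export
sda_pretrain <- function(X, spec) {
  stopifnot(inherits(spec, "sda_spec"))
  if (ncol(X) != spec$input_nodes)
    stop("ncol(X) does not match sda input_nodes")
  fit <- ae_train_cpp(X, spec$hidden, spec$corruption_level, spec$lr,
                      spec$batch_size, spec$max_iter, 0, spec$seed)
  n_enc <- (length(spec$hidden) + 1) %/% 2
  structure(list(W = fit$W, b = fit$b,
                 encoder_W = fit$W[seq_len(n_enc)],
                 encoder_b = fit$b[seq_len(n_enc)],
                 loss_log = as.numeric(fit$loss_log), spec = spec),
            class = "sda_state")
}

#' Reconstruct inputs through a trained autoencoder
#'
#' @param sda An `sda_state` from [sda_pretrain()].
#' @param X Matrix to reconstruct.
#' @return Reconstructed matrix of the same shape.
#' @export
sda_reconstruct <- function(sda, X) {
  ae_reconstruct_cpp(sda$W, sda$b, X)
}
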