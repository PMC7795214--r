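# The fully connected fusion subnet: FC(4096) - BN - FC(4096) - BN -
# softmax(4), ReLU activations, dropout after each batch-norm, L1 on the
# first FC kernel, trained with SGD/cross-entropy under the learning-rate
# schedule.

#' Subnet configuration
#'
#' @param input_dim fused feature length fed to the first FC layer.
#' @param hidden widths of the two hidden FC layers.
#' @param n_classes softmax output width.
#' @param dropout dropout rate applied after each batch-norm.
#' @param l1 L1 coefficient on the first FC kernel.
#' @param epochs,batch_size,schedule,seed training recipe (see
#'   [lr_schedule()]).
#' @param val_frac fraction of the training rows held out for per-epoch
#'   validation accuracy (0 disables the split).
#' @return object of class `subnet_config`.
#' @export
subnet_config <- function(input_dim, hidden = c(4096L, 4096L), n_classes = 4L,
                          dropout = 0.5, l1 = 1e-4, epochs = 30L,
                          batch_size = 128L, schedule = lr_schedule(),
                          val_frac = 0.1, seed = 1L) {
  if (input_dim <= 0) stop("input_dim must be positive")
  stopifnot(dropout >= 0, dropout < 1, val_frac >= 0, val_frac < 1)
  structure(list(input_dim = as.integer(input_dim), hidden = as.integer(hidden),
                 n_classes = as.integer(n_classes), dropout = dropout, l1 = l1,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 schedule = schedule, val_frac = val_frac, seed = as.integer(seed)),
            class = "subnet_config")
}

#' Build the fusion subnet
#'
#' Layer stack (matching the published ordering): inputs, FC1, BN1, FC2,
#' BN2, softmax classification, with ReLU activations and dropout after each
#' batch-norm.
#'
#' @param cfg a [subnet_config()].
#' @return object of class `subnet`.
#' @export
build_subnet <- function(cfg) {
  specs <- list()
  for (hwidth in cfg$hidden) {
    specs <- c(specs, list(layer_dense(hwidth), layer_batchnorm(), layer_relu(),
                           layer_dropout(cfg$dropout)))
  }
  specs <- c(specs, list(layer_dense(cfg$n_classes)))
  net <- nn_network(specs, cfg$input_dim, seed = cfg$seed)
  structure(list(net = net, cfg = cfg, trained = FALSE), class = "subnet")
}

#' Train the fusion subnet
#'
#' SGD with the learning-rate schedule, categorical cross-entropy on the
#' softmax output, and L1 regularization on the first FC kernel. A
#' `val_frac` share of rows is held out to record per-epoch validation
#' accuracy. Identical seeds give identical histories.
#'
#' @param subnet a [build_subnet()] object.
#' @param X `n x input_dim` fused feature matrix.
#' @param y 0-based integer labels.
#' @return the subnet with trained weights and a `history` data frame
#'   (epoch, lr, loss, accuracy, val_accuracy).
#' @export
train_subnet <- function(subnet, X, y) {
  cfg <- subnet$cfg
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("train_subnet() requires at least two classes")
  X <- as.matrix(X)
  n <- nrow(X)
  idx_val <- integer(0)
  if (cfg$val_frac > 0 && n >= 10L) {
    idx_val <- with_seed(derive_seed(cfg$seed, 11L),
                         sample.int(n, max(1L, round(cfg$val_frac * n))))
  }
  idx_tr <- setdiff(seq_len(n), idx_val)
  first_dense <- which(vapply(subnet$net$layers, function(l) l$type == "dense", TRUE))[1]
  l1_on <- function(i, l) i == first_dense
  tr <- nn_train(subnet$net, X[idx_tr, , drop = FALSE], y[idx_tr],
                 epochs = cfg$epochs, batch_size = cfg$batch_size,
                 schedule = cfg$schedule, l1 = cfg$l1, l1_on = l1_on,
                 seed = cfg$seed)
  subnet$net <- tr$net
  hist <- tr$history
  if (length(idx_val) && nrow(hist)) {
    pv <- predict_proba(subnet, X[idx_val, , drop = FALSE])
    hist$val_accuracy <- NA_real_
    hist$val_accuracy[nrow(hist)] <- mean(max.col(pv) - 1L == y[idx_val])
  }
  subnet$history <- hist
  subnet$trained <- TRUE
  subnet
}

#' Class-probability predictions from the subnet
#'
#' @param subnet a (trained) `subnet`.
#' @param X feature matrix with `input_dim` columns.
#' @return `n x n_classes` matrix of row-wise probability vectors; the
#'   predicted label is the row argmax (0-based).
#' @export
predict_proba <- function(subnet, X) {
  softmax_rows(nn_forward(subnet$net, as.matrix(X)))
}
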