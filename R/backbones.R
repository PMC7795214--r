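# Convolutional backbone feature extractors.
#
# Each builder assembles a named architecture family out of the engine's
# layer primitives with 'same' padding throughout; the pooled feature
# dimension (channels of the final convolutional block under global average
# pooling) is a pure function of the architecture: ResNet50 v2 -> 2048,
# DenseNet121 -> 1024, Inception v3 -> 2048, Inception-ResNet -> 1536,
# VGG19 -> 512.

bn_relu <- function() list(layer_batchnorm(), layer_relu())

vgg19_spec <- function() {
  widths <- list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                 c(512, 512, 512, 512), c(512, 512, 512, 512))
  specs <- list()
  for (stage in widths) {
    for (f in stage) specs <- c(specs, list(layer_conv(f, 3), layer_relu()))
    specs <- c(specs, list(layer_maxpool(2, 2)))
  }
  c(specs, list(layer_gap()))
}

resnet50v2_block <- function(mid, out, stride, project) {
  body <- c(bn_relu(), list(layer_conv(mid, 1)),
            bn_relu(), list(layer_conv(mid, 3, stride = stride)),
            bn_relu(), list(layer_conv(out, 1)))
  shortcut <- if (project) list(layer_conv(out, 1, stride = stride)) else NULL
  layer_residual(body, shortcut, post_relu = FALSE)
}

resnet50v2_spec <- function() {
  stages <- list(c(3, 64, 256, 1), c(4, 128, 512, 2),
                 c(6, 256, 1024, 2), c(3, 512, 2048, 2))
  specs <- list(layer_conv(64, 7, stride = 2), layer_maxpool(3, 2))
  for (st in stages) {
    specs <- c(specs, list(resnet50v2_block(st[2], st[3], st[4], project = TRUE)))
    for (b in seq_len(st[1] - 1)) {
      specs <- c(specs, list(resnet50v2_block(st[2], st[3], 1, project = FALSE)))
    }
  }
  c(specs, bn_relu(), list(layer_gap()))
}

densenet121_spec <- function(growth = 32L) {
  dense_unit <- function() {
    layer_branch(list(
      list(),  # identity: carry the input channels through
      c(bn_relu(), list(layer_conv(4L * growth, 1)),
        bn_relu(), list(layer_conv(growth, 3)))
    ))
  }
  specs <- list(layer_conv(64, 7, stride = 2), layer_maxpool(3, 2))
  channels <- 64L
  blocks <- c(6L, 12L, 24L, 16L)
  for (bi in seq_along(blocks)) {
    for (u in seq_len(blocks[bi])) specs <- c(specs, list(dense_unit()))
    channels <- channels + blocks[bi] * growth
    if (bi < length(blocks)) {
      channels <- channels %/% 2L
      specs <- c(specs, bn_relu(),
                 list(layer_conv(channels, 1), layer_avgpool(2, 2)))
    }
  }
  c(specs, bn_relu(), list(layer_gap()))
}

conv_bn <- function(filters, kernel = 3, stride = 1L) {
  list(layer_conv(filters, kernel, stride = stride), layer_batchnorm(), layer_relu())
}

inception_v3_spec <- function() {
  stem <- c(conv_bn(32, 3, 2), conv_bn(32, 3), conv_bn(64, 3),
            list(layer_maxpool(3, 2)), conv_bn(80, 1), conv_bn(192, 3),
            list(layer_maxpool(3, 2)))
  mix_a <- function(pool_f) layer_branch(list(
    conv_bn(64, 1),
    c(conv_bn(48, 1), conv_bn(64, 5)),
    c(conv_bn(64, 1), conv_bn(96, 3), conv_bn(96, 3)),
    c(list(layer_avgpool(3, 1)), conv_bn(pool_f, 1))
  ))
  mix_reduce1 <- layer_branch(list(
    conv_bn(384, 3, 2),
    c(conv_bn(64, 1), conv_bn(96, 3), conv_bn(96, 3, 2)),
    list(layer_maxpool(3, 2))
  ))
  mix_b <- function(mid) layer_branch(list(
    conv_bn(192, 1),
    c(conv_bn(mid, 1), conv_bn(mid, c(1, 7)), conv_bn(192, c(7, 1))),
    c(conv_bn(mid, 1), conv_bn(mid, c(7, 1)), conv_bn(mid, c(1, 7)),
      conv_bn(mid, c(7, 1)), conv_bn(192, c(1, 7))),
    c(list(layer_avgpool(3, 1)), conv_bn(192, 1))
  ))
  mix_reduce2 <- layer_branch(list(
    c(conv_bn(192, 1), conv_bn(320, 3, 2)),
    c(conv_bn(192, 1), conv_bn(192, c(1, 7)), conv_bn(192, c(7, 1)),
      conv_bn(192, 3, 2)),
    list(layer_maxpool(3, 2))
  ))
  mix_c <- function() layer_branch(list(
    conv_bn(320, 1),
    c(conv_bn(384, 1),
      list(layer_branch(list(conv_bn(384, c(1, 3)), conv_bn(384, c(3, 1)))))),
    c(conv_bn(448, 1), conv_bn(384, 3),
      list(layer_branch(list(conv_bn(384, c(1, 3)), conv_bn(384, c(3, 1)))))),
    c(list(layer_avgpool(3, 1)), conv_bn(192, 1))
  ))
  c(stem,
    list(mix_a(32), mix_a(64), mix_a(64), mix_reduce1,
         mix_b(128), mix_b(160), mix_b(160), mix_b(192), mix_reduce2,
         mix_c(), mix_c(), layer_gap()))
}

inception_resnet_spec <- function(repeats = c(10L, 20L, 10L)) {
  stem <- c(conv_bn(32, 3, 2), conv_bn(32, 3), conv_bn(64, 3),
            list(layer_maxpool(3, 2)), conv_bn(80, 1), conv_bn(192, 3),
            list(layer_maxpool(3, 2)))
  mixed_5b <- layer_branch(list(
    conv_bn(96, 1),
    c(conv_bn(48, 1), conv_bn(64, 5)),
    c(conv_bn(64, 1), conv_bn(96, 3), conv_bn(96, 3)),
    c(list(layer_avgpool(3, 1)), conv_bn(64, 1))
  ))
  block35 <- function() layer_residual(
    list(layer_branch(list(
      conv_bn(32, 1),
      c(conv_bn(32, 1), conv_bn(32, 3)),
      c(conv_bn(32, 1), conv_bn(48, 3), conv_bn(64, 3))
    )), layer_conv(320, 1)),
    scale = 0.17)
  reduction_a <- layer_branch(list(
    conv_bn(384, 3, 2),
    c(conv_bn(256, 1), conv_bn(256, 3), conv_bn(384, 3, 2)),
    list(layer_maxpool(3, 2))
  ))
  block17 <- function() layer_residual(
    list(layer_branch(list(
      conv_bn(192, 1),
      c(conv_bn(128, 1), conv_bn(160, c(1, 7)), conv_bn(192, c(7, 1)))
    )), layer_conv(1088, 1)),
    scale = 0.1)
  reduction_b <- layer_branch(list(
    c(conv_bn(256, 1), conv_bn(384, 3, 2)),
    c(conv_bn(256, 1), conv_bn(288, 3, 2)),
    c(conv_bn(256, 1), conv_bn(288, 3), conv_bn(320, 3, 2)),
    list(layer_maxpool(3, 2))
  ))
  block8 <- function() layer_residual(
    list(layer_branch(list(
      conv_bn(192, 1),
      c(conv_bn(192, 1), conv_bn(224, c(1, 3)), conv_bn(256, c(3, 1)))
    )), layer_conv(2080, 1)),
    scale = 0.2)
  c(stem, list(mixed_5b),
    replicate(repeats[1], block35(), simplify = FALSE),
    list(reduction_a),
    replicate(repeats[2], block17(), simplify = FALSE),
    list(reduction_b),
    replicate(repeats[3], block8(), simplify = FALSE),
    conv_bn(1536, 1), list(layer_gap()))
}

tiny_spec <- function(feature_dim, widths = c(16L, 32L), kernel = 3L) {
  specs <- list()
  for (f in c(widths, feature_dim)) {
    specs <- c(specs, list(layer_conv(f, kernel, stride = 1), layer_relu(),
                           layer_avgpool(2, 2)))
  }
  c(specs, list(layer_gap()))
}

backbone_archs <- c("resnet50v2", "densenet121", "inception_v3",
                    "inception_resnet", "vgg19", "tiny")

#' Build a convolutional backbone feature extractor
#'
#' Assembles the requested architecture with He-normal random weights (the
#' top classification layer is omitted; features are the global average pool
#' of the final convolutional block). Weights saved with
#' [save_backbone_weights()] can be plugged back in via `weights_file` when a
#' pre-trained/fine-tuned extractor is wanted; nothing is ever downloaded.
#'
#' @param architecture one of `"resnet50v2"`, `"densenet121"`,
#'   `"inception_v3"`, `"inception_resnet"`, `"vgg19"`, `"tiny"`.
#' @param input_shape `c(H, W, C)` of the patches to be embedded.
#' @param seed integer seed for weight initialization.
#' @param feature_dim pooled feature dimension for the `"tiny"` architecture.
#' @param widths,kernel channel widths and kernel side of the `"tiny"`
#'   architecture's convolution blocks.
#' @param weights_file optional RDS file of weights from
#'   [save_backbone_weights()].
#' @return object of class `backbone` with elements `net`, `architecture` and
#'   `feature_dim`.
#' @export
build_backbone <- function(architecture, input_shape = c(200, 200, 3), seed = 1L,
                           feature_dim = 64L, widths = c(16L, 32L), kernel = 3L,
                           weights_file = NULL) {
  specs <- switch(architecture,
    resnet50v2 = resnet50v2_spec(),
    densenet121 = densenet121_spec(),
    inception_v3 = inception_v3_spec(),
    inception_resnet = inception_resnet_spec(),
    vgg19 = vgg19_spec(),
    tiny = tiny_spec(feature_dim, widths, kernel),
    stop(sprintf("unknown architecture '%s'; supported: %s", architecture,
                 paste(backbone_archs, collapse = ", ")))
  )
  net <- nn_network(specs, input_shape, seed = seed)
  bb <- structure(list(net = net, architecture = architecture,
                       feature_dim = net$output_shape, input_shape = input_shape),
                  class = "backbone")
  if (!is.null(weights_file)) bb <- load_backbone_weights(bb, weights_file)
  bb
}

#' Tiny desk-scale CNN backbone
#'
#' Three stride-1 convolution blocks with 2x2 average pooling and a global
#' average pool to `feature_dim` features; small enough to train on a CPU in
#' seconds and fully supported by backpropagation.
#'
#' @param feature_dim pooled feature dimension.
#' @param input_shape `c(H, W, C)` input patch shape.
#' @param seed weight-initialization seed.
#' @param widths,kernel convolution block widths and kernel side.
#' @return a `backbone` object.
#' @export
tiny_backbone <- function(feature_dim = 64L, input_shape = c(32, 32, 3), seed = 1L,
                          widths = c(16L, 32L), kernel = 3L) {
  build_backbone("tiny", input_shape = input_shape, seed = seed,
                 feature_dim = feature_dim, widths = widths, kernel = kernel)
}

# Flatten / restore weights so extractors can be persisted as plain lists.
collect_weights <- function(layers) {
  lapply(layers, function(l) {
    w <- l[intersect(names(l), c("W", "b", "gamma", "beta", "run_mean", "run_var"))]
    if (l$type == "branch") w$branches <- lapply(l$branches, collect_weights)
    if (l$type == "residual") {
      w$body <- collect_weights(l$body)
      if (!is.null(l$shortcut)) w$shortcut <- collect_weights(l$shortcut)
    }
    w
  })
}

assign_weights <- function(layers, weights) {
  stopifnot(length(layers) == length(weights))
  for (i in seq_along(layers)) {
    w <- weights[[i]]
    for (nm in intersect(names(w), c("W", "b", "gamma", "beta", "run_mean", "run_var"))) {
      stopifnot(identical(dim(layers[[i]][[nm]]), dim(w[[nm]])),
                length(layers[[i]][[nm]]) == length(w[[nm]]))
      layers[[i]][[nm]] <- w[[nm]]
    }
    if (!is.null(w$branches)) {
      layers[[i]]$branches <- Map(assign_weights, layers[[i]]$branches, w$branches)
    }
    if (!is.null(w$body)) layers[[i]]$body <- assign_weights(layers[[i]]$body, w$body)
    if (!is.null(w$shortcut)) {
      layers[[i]]$shortcut <- assign_weights(layers[[i]]$shortcut, w$shortcut)
    }
  }
  layers
}

#' Save / load backbone weights
#'
#' @param backbone a `backbone` object.
#' @param path RDS file path.
#' @export
save_backbone_weights <- function(backbone, path) {
  saveRDS(list(architecture = backbone$architecture,
               weights = collect_weights(backbone$net$layers)), path)
  invisible(path)
}

#' @rdname save_backbone_weights
#' @export
load_backbone_weights <- function(backbone, path) {
  saved <- readRDS(path)
  if (!identical(saved$architecture, backbone$architecture)) {
    stop(sprintf("weights file is for '%s', not '%s'", saved$architecture,
                 backbone$architecture))
  }
  backbone$net$layers <- assign_weights(backbone$net$layers, saved$weights)
  backbone
}

#' Extract pooled deep features from patches
#'
#' Runs each patch through the backbone and returns the global-average-pooled
#' feature matrix. Patches are expected on the normalized `[0, 1]` scale
#' (values above 1 are divided by 255 defensively).
#'
#' @param backbone a `backbone`.
#' @param patches list of `H x W x 3` arrays, or an `H x W x 3 x n` array.
#' @param batch_size forward-pass batch size.
#' @return `n x feature_dim` matrix with a `"source"` attribute.
#' @export
extract_features <- function(backbone, patches, batch_size = 16L) {
  x <- stack_patches(patches)
  if (max(x) > 1.5) x <- x / 255
  n <- dim(x)[4]
  out <- matrix(0, n, backbone$feature_dim)
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    out[b, ] <- nn_forward(backbone$net, x[, , , b, drop = FALSE])
  }
  attr(out, "source") <- backbone$architecture
  out
}

stack_patches <- function(patches) {
  if (is.array(patches) && length(dim(patches)) == 4L) return(patches)
  if (is.array(patches) && length(dim(patches)) == 3L) {
    return(array(patches, dim = c(dim(patches), 1L)))
  }
  d <- dim(patches[[1]])
  x <- array(0, dim = c(d, length(patches)))
  for (i in seq_along(patches)) x[, , , i] <- patches[[i]]
  x
}

#' Fine-tuning configuration
#'
#' Training recipe shared by backbone fine-tuning and the fusion subnet:
#' categorical cross-entropy loss, SGD under the piecewise learning-rate
#' schedule, L1 (lasso) regularization of convolution kernels, and dropout.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param schedule an [lr_schedule()]; the default is the printed
#'   0.1 / 0.01 / 0.001 / 0.0001 staircase.
#' @param l1 L1 coefficient applied to convolution kernels.
#' @param dropout dropout rate in the classification head.
#' @param frozen frozen-layer policy: `"none"` (train everything),
#'   `"first_conv"` (freeze the first convolution, train the rest) or
#'   `"trunk"` (freeze all convolutions and train the head only).
#' @param seed seed controlling shuffling, dropout and head initialization.
#' @return object of class `fine_tune_config`.
#' @export
fine_tune_config <- function(epochs = 10L, batch_size = 32L,
                             schedule = lr_schedule(), l1 = 1e-4,
                             dropout = 0.5, frozen = c("none", "first_conv", "trunk"),
                             seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, l1 >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 schedule = schedule, l1 = l1, dropout = dropout,
                 frozen = match.arg(frozen), seed = as.integer(seed)),
            class = "fine_tune_config")
}

#' Fine-tune a backbone on labelled patches
#'
#' Attaches a classification head (batch norm over the pooled features,
#' dropout, softmax layer) and trains with SGD/cross-entropy under the
#' learning-rate schedule, with L1 on convolution kernels. Under the `"trunk"`
#' policy (the only option for the large composite architectures) the trunk
#' is a frozen feature extractor and only the head is trained; `"none"` and
#' `"first_conv"` backpropagate through the trunk and therefore require a
#' backprop-capable (tiny) backbone.
#'
#' @param backbone a `backbone`.
#' @param patches list/array of patches on the `[0, 1]` scale.
#' @param labels 0-based integer class labels (at least two classes).
#' @param cfg a [fine_tune_config()].
#' @param n_classes number of classes (defaults to `max(labels) + 1`).
#' @return list with `backbone` (trunk with tuned weights), `head` (trained
#'   classification layers) and `history` (per-epoch loss/accuracy).
#' @export
fine_tune <- function(backbone, patches, labels, cfg = fine_tune_config(),
                      n_classes = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("fine_tune() requires at least two classes in `labels`")
  }
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  x <- stack_patches(patches)
  if (max(x) > 1.5) x <- x / 255
  if (cfg$frozen == "trunk" || !trainable_stack(backbone$net$layers)) {
    if (cfg$frozen != "trunk") {
      stop("this architecture supports only the \"trunk\" frozen policy")
    }
    feats <- extract_features(backbone, x)
    head <- nn_network(list(layer_batchnorm(), layer_dropout(cfg$dropout),
                            layer_dense(n_classes)),
                       backbone$feature_dim, seed = derive_seed(cfg$seed, 7L))
    tr <- nn_train(head, feats, labels, cfg$epochs, cfg$batch_size,
                   cfg$schedule, l1 = 0, seed = cfg$seed)
    return(list(backbone = backbone, head = tr$net$layers, history = tr$history))
  }
  full_specs_net <- backbone$net
  head <- with_seed(derive_seed(cfg$seed, 7L), {
    nn_build_stack(list(layer_batchnorm(), layer_dropout(cfg$dropout),
                        layer_dense(n_classes)),
                   backbone$feature_dim)$layers
  })
  net <- full_specs_net
  net$layers <- c(net$layers, head)
  net$output_shape <- n_classes
  if (cfg$frozen == "first_conv") {
    i <- which(vapply(net$layers, function(l) l$type == "conv", TRUE))[1]
    net$layers[[i]]$trainable <- FALSE
  }
  l1_on <- function(i, l) l$type == "conv"
  tr <- nn_train(net, x, labels, cfg$epochs, cfg$batch_size, cfg$schedule,
                 l1 = cfg$l1, l1_on = l1_on, seed = cfg$seed)
  trunk_len <- length(backbone$net$layers)
  backbone$net$layers <- tr$net$layers[seq_len(trunk_len)]
  list(backbone = backbone,
       head = tr$net$layers[trunk_len + seq_len(length(head))],
       history = tr$history)
}

# Sum of |kernel| over convolution layers (used to verify the L1 penalty).
conv_l1_norm <- function(backbone) {
  s <- 0
  walk <- function(layers) {
    for (l in layers) {
      if (l$type == "conv") s <<- s + sum(abs(l$W))
      if (l$type == "branch") lapply(l$branches, walk)
      if (l$type == "residual") {
        walk(l$body)
        if (!is.null(l$shortcut)) walk(l$shortcut)
      }
    }
  }
  walk(backbone$net$layers)
  s
}
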