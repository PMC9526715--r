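# Multi-Resolution U-Net 3D with instance normalization and two heads:
# softmax lobe classification and tanh t-SDF regression.
#
# Each MultiRes block factorizes a 7x7x7 receptive field into three chained
# 3x3x3 convolutions whose intermediate outputs are concatenated along the
# channel axis; a 1x1x1 convolution forms the residual path. Skip connections
# run through residual "res-path" blocks (more blocks for shallower levels) to
# narrow the encoder/decoder semantic gap. All normalization is instance
# normalization so batch size 1 is usable.

#' Model configuration
#'
#' @param depth number of encoder levels (>= 2).
#' @param base_filters channel budget of level 1 before the MultiRes width
#'   multiplier.
#' @param alpha MultiRes width multiplier.
#' @param in_channels input channels (3 HU windows).
#' @param n_classes segmentation classes (background, right lobe, left lobe).
#' @param n_tsdf_channels t-SDF regression channels (one per lobe).
#' @param activation hidden activation, currently `"relu"`.
#' @return object of class `model_config`.
#' @export
model_config <- function(depth = 5L, base_filters = 32L, alpha = 1.67,
                         in_channels = 3L, n_classes = 3L,
                         n_tsdf_channels = 2L, activation = "relu") {
  assert_that(depth >= 2, "depth must be >= 2")
  assert_that(base_filters >= 4, "base_filters must be >= 4")
  assert_that(in_channels == 3L, "the composite input has 3 channels")
  assert_that(n_classes == 3L, "three classes: background, right lobe, left lobe")
  assert_that(identical(activation, "relu"), "only relu is implemented")
  structure(list(depth = as.integer(depth), base_filters = as.integer(base_filters),
                 alpha = alpha, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 n_tsdf_channels = as.integer(n_tsdf_channels),
                 activation = activation),
            class = "model_config")
}

# Channel split of a MultiRes width budget into the three chained branches
# (1/6, 1/3, 1/2 of the budget).
multires_widths <- function(width_budget) {
  assert_that(width_budget >= 6, "width budget too small to split into three branches")
  w1 <- max(1L, as.integer(floor(width_budget / 6)))
  w2 <- max(1L, as.integer(floor(width_budget / 3)))
  w3 <- max(1L, as.integer(floor(width_budget / 2)))
  c(w1, w2, w3)
}

level_budget <- function(cfg, level) as.integer(round(cfg$base_filters * cfg$alpha * 2^(level - 1)))

new_param_env <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e
}

add_param <- function(penv, name, value) {
  node <- ag_param(value)
  penv$params[[name]] <- node
  node
}

he_init <- function(cin, k, cout) {
  sdv <- sqrt(2 / (cin * prod(k)))
  array(rnorm(cin * prod(k) * cout, sd = sdv), dim = c(cin, k, cout))
}

make_conv <- function(penv, name, cin, k, cout) {
  w <- add_param(penv, paste0(name, ".w"), he_init(cin, k, cout))
  b <- add_param(penv, paste0(name, ".b"), numeric(cout))
  function(x) ag_conv3d(x, w, b)
}

make_inorm <- function(penv, name, C) {
  g <- add_param(penv, paste0(name, ".gamma"), rep(1, C))
  b <- add_param(penv, paste0(name, ".beta"), numeric(C))
  function(x) ag_instance_norm(x, g, b)
}

# MultiRes block: out = relu(inorm(concat(c1, c2, c3)) + conv1x1(x)).
make_multires_block <- function(penv, name, cin, width_budget) {
  w <- multires_widths(width_budget)
  cout <- sum(w)
  c1 <- make_conv(penv, paste0(name, ".c1"), cin, c(3L, 3L, 3L), w[1])
  c2 <- make_conv(penv, paste0(name, ".c2"), w[1], c(3L, 3L, 3L), w[2])
  c3 <- make_conv(penv, paste0(name, ".c3"), w[2], c(3L, 3L, 3L), w[3])
  res <- make_conv(penv, paste0(name, ".res"), cin, c(1L, 1L, 1L), cout)
  no <- make_inorm(penv, paste0(name, ".norm"), cout)
  list(out_channels = cout,
       forward = function(x) {
         a <- ag_relu(c1(x))
         b <- ag_relu(c2(a))
         cc <- ag_relu(c3(b))
         ag_relu(ag_add(no(ag_concat(list(a, b, cc))), res(x)))
       })
}

# One res-path unit: relu(inorm(conv3(x)) + conv1(x)); channels preserved.
make_res_path <- function(penv, name, channels, n_blocks) {
  units <- lapply(seq_len(n_blocks), function(i) {
    conv <- make_conv(penv, paste0(name, ".b", i, ".conv"), channels, c(3L, 3L, 3L), channels)
    res <- make_conv(penv, paste0(name, ".b", i, ".res"), channels, c(1L, 1L, 1L), channels)
    no <- make_inorm(penv, paste0(name, ".b", i, ".norm"), channels)
    function(x) ag_relu(ag_add(no(conv(x)), res(x)))
  })
  function(x) {
    for (u in units) x <- u(x)
    x
  }
}

#' Build the Multi-Resolution U-Net 3D
#'
#' Constructs the dual-head network: an encoder of MultiRes blocks with
#' 2x2x2 max pooling (the z axis is only pooled while its extent is at least
#' 8 slices, keeping thin stacks alive at depth), res-path processed skips,
#' a nearest-neighbour-upsample + convolution decoder, and two 1x1x1 heads
#' (softmax over 3 classes; tanh over 2 t-SDF channels).
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return object of class `lobeseg_model`.
#' @export
build_network <- function(cfg = model_config(), seed = 1L) {
  assert_that(inherits(cfg, "model_config"), "cfg must be a model_config")
  with_seed(derive_seed(seed, "init"), {
    penv <- new_param_env()
    depth <- cfg$depth
    budgets <- vapply(seq_len(depth), function(l) level_budget(cfg, l), integer(1))

    enc <- vector("list", depth)
    cin <- cfg$in_channels
    for (l in seq_len(depth)) {
      enc[[l]] <- make_multires_block(penv, sprintf("enc%d", l), cin, budgets[l])
      cin <- enc[[l]]$out_channels
    }
    skips <- lapply(seq_len(depth - 1), function(l)
      make_res_path(penv, sprintf("skip%d", l), enc[[l]]$out_channels, depth - l))

    dec <- vector("list", depth - 1)
    upc <- vector("list", depth - 1)
    up_norm <- vector("list", depth - 1)
    prev <- enc[[depth]]$out_channels
    for (l in rev(seq_len(depth - 1))) {
      upc[[l]] <- make_conv(penv, sprintf("up%d.conv", l), prev, c(3L, 3L, 3L),
                            enc[[l]]$out_channels)
      up_norm[[l]] <- make_inorm(penv, sprintf("up%d.norm", l), enc[[l]]$out_channels)
      dec[[l]] <- make_multires_block(penv, sprintf("dec%d", l),
                                      2L * enc[[l]]$out_channels, budgets[l])
      prev <- dec[[l]]$out_channels
    }
    head_cls <- make_conv(penv, "head.cls", prev, c(1L, 1L, 1L), cfg$n_classes)
    head_sdf <- make_conv(penv, "head.sdf", prev, c(1L, 1L, 1L), cfg$n_tsdf_channels)

    structure(list(cfg = cfg, penv = penv,
                   enc = enc, skips = skips, dec = dec, upc = upc,
                   up_norm = up_norm,
                   head_cls = head_cls, head_sdf = head_sdf),
              class = "lobeseg_model")
  })
}

# Pooling factors for the current z extent: pool z only while >= 8 slices.
pool_factor <- function(z_extent) c(if (z_extent >= 8) 2L else 1L, 2L, 2L)

#' Network forward pass
#'
#' @param model a `lobeseg_model`.
#' @param x numeric array (3, z, y, x) in `[-1, 1]` (a composite crop).
#' @return list with `probs` and `tsdf` graph nodes (use `$value` for the
#'   arrays) suitable for loss computation and backprop.
#' @export
forward_network <- function(model, x) {
  assert_that(inherits(model, "lobeseg_model"), "model must be a lobeseg_model")
  assert_that(length(dim(x)) == 4L && dim(x)[1] == model$cfg$in_channels,
              "input must be (3, z, y, x)")
  depth <- model$cfg$depth
  d <- dim(x)[-1]
  assert_that(d[2] %% 2^(depth - 1) == 0 && d[3] %% 2^(depth - 1) == 0,
              "in-plane extent must be divisible by 2^(depth-1)")
  node <- ag_const(x)
  feats <- vector("list", depth)
  ks <- vector("list", depth - 1)
  for (l in seq_len(depth)) {
    feats[[l]] <- model$enc[[l]]$forward(node)
    if (l < depth) {
      k <- pool_factor(dim(feats[[l]]$value)[2])
      assert_that(dim(feats[[l]]$value)[2] %% k[1] == 0,
                  "z extent must be divisible by the pooling kernel")
      ks[[l]] <- k
      node <- ag_maxpool(feats[[l]], k)
    }
  }
  y <- feats[[depth]]
  for (l in rev(seq_len(depth - 1))) {
    # channel-reducing 3x3x3 convolution at the coarse grid, then
    # nearest-neighbour upsampling: a block-constant transposed convolution
    up <- ag_upsample_nn(ag_relu(model$up_norm[[l]](model$upc[[l]](y))),
                         ks[[l]])
    skip <- model$skips[[l]](feats[[l]])
    y <- model$dec[[l]]$forward(ag_concat(list(skip, up)))
  }
  list(probs = ag_softmax(model$head_cls(y)),
       tsdf = ag_tanh(model$head_sdf(y)))
}

#' Trainable parameters of a model
#'
#' @param model a `lobeseg_model`.
#' @return named list of parameter nodes.
#' @export
model_parameters <- function(model) model$penv$params

#' Total number of trainable scalars
#'
#' @param model a `lobeseg_model`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(model_parameters(model), function(p) length(p$value), numeric(1)))
}

#' Save a model checkpoint (weights + configuration)
#'
#' @param model a `lobeseg_model`.
#' @param path destination file.
#' @param meta optional metadata list stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path, meta = list()) {
  weights <- lapply(model_parameters(model), function(p) p$value)
  saveRDS(list(cfg = model$cfg, weights = weights, meta = meta), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file written by [save_checkpoint()].
#' @return a `lobeseg_model` with restored weights (metadata in
#'   `attr(, "meta")`).
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg, seed = 1L)
  params <- model_parameters(model)
  assert_that(identical(sort(names(params)), sort(names(ck$weights))),
              "checkpoint does not match the architecture")
  for (nm in names(params)) params[[nm]]$value <- ck$weights[[nm]]
  attr(model, "meta") <- ck$meta
  model
}

#' @export
print.lobeseg_model <- function(x, ...) {
  cat(sprintf("<lobeseg_model> depth %d, base filters %d, alpha %.2f, %d parameters\n",
              x$cfg$depth, x$cfg$base_filters, x$cfg$alpha, count_parameters(x)))
  invisible(x)
}
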