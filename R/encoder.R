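#' Encoder specification
#'
#' Describes the shared encoder that maps a 1-channel T x F sub-view to a
#' unit-norm L-dimensional embedding: a backbone producing a D-dimensional
#' feature vector, followed by a projection head (linear D -> hidden,
#' batch normalization, ReLU, linear hidden -> L) and L2 normalization.
#' One encoder is shared by all sub-views so their embeddings live in a
#' common representation space.
#'
#' The default `"tiny_cnn"` backbone is a small convolutional stack
#' (three 3x3 conv / ReLU / 2x2 average-pool blocks and global average
#' pooling) sized to train on a CPU in minutes; with it the defaults are
#' D = 32, hidden 64, L = 32. The `"resnet18_pretrained"` backbone mirrors
#' the full-scale configuration (D = 512, hidden 512, L = 128) but needs
#' externally downloaded weights, so constructing it here raises an
#' informative error.
#'
#' @param backbone `"tiny_cnn"` or `"resnet18_pretrained"`.
#' @param channels integer vector of the three tiny-CNN block widths; the
#'   last entry is the backbone feature dimension D.
#' @param head_hidden width of the projection-head hidden layer.
#' @param embed_dim embedding dimension L.
#' @param replicate_channels replicate the 1-channel input to 3 identical
#'   channels (for backbones expecting RGB input).
#' @return an object of class `"encoder_spec"`.
#' @export
encoder_spec <- function(backbone = c("tiny_cnn", "resnet18_pretrained"),
                         channels = c(8L, 16L, 32L),
                         head_hidden = NULL, embed_dim = NULL,
                         replicate_channels = FALSE) {
  backbone <- match.arg(backbone)
  if (backbone == "resnet18_pretrained") {
    if (is.null(head_hidden)) head_hidden <- 512L
    if (is.null(embed_dim)) embed_dim <- 128L
    feature_dim <- 512L
    replicate_channels <- TRUE
  } else {
    stopifnot(length(channels) == 3L, all(channels >= 1L))
    if (is.null(head_hidden)) head_hidden <- 64L
    if (is.null(embed_dim)) embed_dim <- 32L
    feature_dim <- as.integer(channels[3L])
  }
  stopifnot(head_hidden >= 1L, embed_dim >= 1L)
  structure(
    list(backbone = backbone, channels = as.integer(channels),
         feature_dim = feature_dim, head_hidden = as.integer(head_hidden),
         embed_dim = as.integer(embed_dim),
         replicate_channels = isTRUE(replicate_channels)),
    class = "encoder_spec"
  )
}

#' Construct a default backbone specification
#'
#' `"tiny_cnn"` returns an [encoder_spec()] for the bundled small
#' convolutional backbone. `"resnet18_pretrained"` is recognized but
#' unavailable without its external weight file, so it raises an error
#' directing the user to a custom encoder instead.
#'
#' @param kind backbone name.
#' @return an [encoder_spec()].
#' @export
make_default_backbone <- function(kind = c("tiny_cnn", "resnet18_pretrained")) {
  kind <- match.arg(kind)
  if (kind == "resnet18_pretrained") {
    stop("the pretrained ResNet-18 backbone requires an external weight ",
         "download and is not bundled; use encoder_spec(\"tiny_cnn\") or ",
         "supply your own encoder")
  }
  encoder_spec("tiny_cnn")
}

# Initialize all encoder parameters (He-style init). Draws from the
# caller's RNG stream; seed management is the caller's responsibility.
.init_encoder_params <- function(spec, n_classes = NULL) {
  if (spec$backbone != "tiny_cnn") {
    stop("only the tiny_cnn backbone can be initialized without external ",
         "weights")
  }
  cin <- if (spec$replicate_channels) 3L else 1L
  ch <- spec$channels
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  params <- list(
    enc_convW1 = he(9L * cin, ch[1L]),
    enc_convb1 = numeric(ch[1L]),
    enc_convW2 = he(9L * ch[1L], ch[2L]),
    enc_convb2 = numeric(ch[2L]),
    enc_convW3 = he(9L * ch[2L], ch[3L]),
    enc_convb3 = numeric(ch[3L]),
    enc_headW1 = he(spec$feature_dim, spec$head_hidden),
    enc_headb1 = numeric(spec$head_hidden),
    enc_bn_gamma = rep(1, spec$head_hidden),
    enc_bn_beta = numeric(spec$head_hidden),
    enc_headW2 = he(spec$head_hidden, spec$embed_dim),
    enc_headb2 = numeric(spec$embed_dim)
  )
  if (!is.null(n_classes)) {
    params$enc_clsW <- he(spec$embed_dim, n_classes)
    params$enc_clsb <- numeric(n_classes)
  }
  params
}

# Full encoder forward pass.
# X: array (H, W, N, 1). Returns the (optionally L2-normalized) N x L
# embedding matrix, the caches needed for backward, and updated batch-norm
# running statistics.
.encoder_forward <- function(params, X, spec, bn_running, train = TRUE,
                             normalize = TRUE) {
  if (spec$replicate_channels && dim(X)[4L] == 1L) {
    X <- X[, , , c(1L, 1L, 1L), drop = FALSE]
  }
  c1 <- .conv_forward(X, params$enc_convW1, params$enc_convb1)
  r1 <- .relu_forward(c1$out)
  p1 <- .pool_forward(r1$out)
  c2 <- .conv_forward(p1$out, params$enc_convW2, params$enc_convb2)
  r2 <- .relu_forward(c2$out)
  p2 <- .pool_forward(r2$out)
  c3 <- .conv_forward(p2$out, params$enc_convW3, params$enc_convb3)
  r3 <- .relu_forward(c3$out)
  p3 <- .pool_forward(r3$out)
  g <- .gap_forward(p3$out)
  h1 <- sweep(g$out %*% params$enc_headW1, 2L, params$enc_headb1, `+`)
  bn <- .bn_forward(h1, params$enc_bn_gamma, params$enc_bn_beta, bn_running,
                    train = train)
  hr <- pmax(bn$out, 0)
  v <- sweep(hr %*% params$enc_headW2, 2L, params$enc_headb2, `+`)
  if (!all(is.finite(v))) {
    stop("non-finite activations in the encoder forward pass; ",
         "check input scaling and learning rates")
  }
  out <- v
  l2 <- NULL
  if (normalize) {
    l2 <- .l2norm_forward(v)
    out <- l2$out
  }
  list(out = out,
       cache = list(c1 = c1, m1 = r1$mask, p1 = p1,
                    c2 = c2, m2 = r2$mask, p2 = p2,
                    c3 = c3, m3 = r3$mask, p3 = p3,
                    g = g, feats = g$out, bn = bn, hr_mask = bn$out > 0,
                    hr = hr, v = v, l2 = l2, normalize = normalize,
                    replicated = spec$replicate_channels),
       bn_running = bn$running)
}

# Backward pass matching .encoder_forward. dout is the gradient at the
# (normalized) embedding. Returns parameter gradients plus the gradient
# with respect to the input batch (needed by the sub-band filters).
.encoder_backward <- function(dout, cache, params) {
  dv <- if (cache$normalize) .l2norm_backward(dout, cache$l2) else dout
  dhr <- tcrossprod(dv, params$enc_headW2)
  gW2 <- crossprod(cache$hr, dv)
  gb2 <- colSums(dv)
  dbn_out <- dhr * cache$hr_mask
  bnb <- .bn_backward(dbn_out, cache$bn, params$enc_bn_gamma)
  dh1 <- bnb$dX
  gW1 <- crossprod(cache$feats, dh1)
  gb1 <- colSums(dh1)
  dfeats <- tcrossprod(dh1, params$enc_headW1)
  dX3 <- .gap_backward(dfeats, cache$g)
  dX3 <- .pool_backward(dX3, cache$p3)
  dX3 <- dX3 * cache$m3
  cb3 <- .conv_backward(dX3, cache$c3, params$enc_convW3)
  dX2 <- .pool_backward(cb3$dX, cache$p2)
  dX2 <- dX2 * cache$m2
  cb2 <- .conv_backward(dX2, cache$c2, params$enc_convW2)
  dX1 <- .pool_backward(cb2$dX, cache$p1)
  dX1 <- dX1 * cache$m1
  cb1 <- .conv_backward(dX1, cache$c1, params$enc_convW1)
  dX <- cb1$dX
  if (cache$replicated && dim(dX)[4L] == 3L) {
    dX <- dX[, , , 1L, drop = FALSE] + dX[, , , 2L, drop = FALSE] +
      dX[, , , 3L, drop = FALSE]
  }
  list(grads = list(enc_convW1 = cb1$dW, enc_convb1 = cb1$db,
                    enc_convW2 = cb2$dW, enc_convb2 = cb2$db,
                    enc_convW3 = cb3$dW, enc_convb3 = cb3$db,
                    enc_headW1 = gW1, enc_headb1 = gb1,
                    enc_bn_gamma = bnb$dgamma, enc_bn_beta = bnb$dbeta,
                    enc_headW2 = gW2, enc_headb2 = gb2),
       dX = dX)
}

#' Initialize an untrained encoder
#'
#' Creates the parameter set and batch-normalization running statistics
#' of a fresh encoder, reproducibly under a seed.
#'
#' @param spec an [encoder_spec()].
#' @param seed integer seed for the weight draw.
#' @return an object of class `"ebdl_encoder"`: a list with `params`,
#'   `bn_running` and `spec`.
#' @export
init_encoder <- function(spec = encoder_spec(), seed = 1024L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  structure(
    list(params = .init_encoder_params(spec),
         bn_running = list(mean = numeric(spec$head_hidden),
                           var = rep(1, spec$head_hidden)),
         spec = spec),
    class = "ebdl_encoder"
  )
}

#' Encode sub-views into unit-norm embeddings
#'
#' Runs each sub-view through the shared encoder in evaluation mode
#' (batch-norm running statistics, deterministic) and returns one
#' L2-normalized embedding per sub-view. Identical sub-views map to
#' identical embeddings because the encoder is shared.
#'
#' @param views a `"subview_set"` from [apply_filters()], a list of equal
#'   shape T x F matrices, or a single matrix.
#' @param encoder an `"ebdl_encoder"` from [init_encoder()] (or the
#'   `$encoder` component of a fitted [ebdl()] model).
#' @return an M x L matrix of unit-norm embeddings, one row per sub-view.
#' @export
encode_subviews <- function(views, encoder) {
  stopifnot(inherits(encoder, "ebdl_encoder"))
  if (is.matrix(views)) views <- list(views)
  d <- dim(views[[1L]])
  X <- array(0, dim = c(d[1L], d[2L], length(views), 1L))
  for (i in seq_along(views)) {
    if (!identical(dim(views[[i]]), d)) stop("all views must share one shape")
    X[, , i, 1L] <- views[[i]]
  }
  fw <- .encoder_forward(encoder$params, X, encoder$spec, encoder$bn_running,
                         train = FALSE, normalize = TRUE)
  fw$out
}
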