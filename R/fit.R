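#' Fit a band-dependent learning model
#'
#' Trains, end to end, the three coupled components of the model: a bank
#' of M generalized-Gaussian sub-band filters (trainable location and
#' scale per filter), a shared convolutional encoder mapping each
#' filtered sub-view to a unit-norm embedding, and M x C class proxies
#' trained with the sub-view contrastive loss ([scloss()]). Each
#' parameter group has its own Adam learning rate; the filter parameters
#' use a much larger rate (default 0.25) than the encoder, which lets the
#' filters sweep across the frequency axis within a few epochs.
#' Prediction is by nearest proxy across sub-views ([nearest_proxy()]).
#'
#' With `loss = "cross_entropy"` the identical encoder is instead trained
#' as a plain softmax classifier on the unfiltered TFR (no filter bank,
#' no proxies) — the natural baseline for measuring what the sub-band
#' machinery buys.
#'
#' @param x training samples: a list of [tfr_sample()] objects, or a
#'   T x F x N array (then `labels` is required).
#' @param labels optional label vector overriding the samples' own labels.
#' @param val validation samples (same forms as `x`), or `NULL`. When
#'   given, the returned model carries the parameters of the epoch with
#'   the best validation metric.
#' @param n_filters number of sub-band filters M.
#' @param beta shape exponent of the filters (positive even integer).
#' @param encoder an [encoder_spec()].
#' @param loss `"scloss"` (the sub-view contrastive model) or
#'   `"cross_entropy"` (baseline).
#' @param epochs maximum number of training epochs.
#' @param batch_size mini-batch size.
#' @param lr_encoder,lr_filters,lr_proxies Adam learning rates of the
#'   encoder, the filter (mu, sigma) parameters, and the proxies.
#' @param seed integer seed governing initialization, shuffling and
#'   augmentation; identical seeds and data give identical fits.
#' @param mix_class optional label of the majority (resting) class: each
#'   epoch, minority classes are topped up with mix-augmented samples
#'   (([mix_augment()])) until class counts match the majority's.
#' @param select_metric validation metric for checkpoint selection:
#'   `"accuracy"` or `"balanced_accuracy"`.
#' @param stop_at_val_acc optional early-stop threshold: training stops
#'   once the validation metric reaches this value.
#' @param verbose print per-epoch progress.
#' @return an object of class `"ebdl"` with components `filters` (a
#'   [filter_bank()]), `encoder`, `proxies`, `classes`, `history` (per
#'   epoch: loss, validation metric), `filter_history` and `config`.
#'   Methods: [predict.ebdl()], `print`, `summary`, [coef.ebdl()],
#'   [plot.ebdl()], [evaluate()].
#' @examples
#' \donttest{
#' cfg <- synthetic_config(n_classes = 2, samples_per_class = 30,
#'                         tfr_shape = c(16, 32), seed = 7)
#' samples <- gen_band_task(cfg)
#' split <- split_dataset(samples, c(7, 1.5, 1.5), seed = 7)
#' fit <- ebdl(split$train, val = split$validation, n_filters = 2,
#'             epochs = 3, batch_size = 16)
#' evaluate(fit, split$test)
#' }
#' @export
ebdl <- function(x, labels = NULL, val = NULL,
                 n_filters = 3L, beta = 8,
                 encoder = encoder_spec(),
                 loss = c("scloss", "cross_entropy"),
                 epochs = 15L, batch_size = 32L,
                 lr_encoder = 1e-4, lr_filters = 0.25,
                 lr_proxies = lr_encoder,
                 seed = 1024L, mix_class = NULL,
                 select_metric = c("accuracy", "balanced_accuracy"),
                 stop_at_val_acc = NULL, verbose = FALSE) {
  loss <- match.arg(loss)
  select_metric <- match.arg(select_metric)
  stopifnot(epochs >= 1L, batch_size >= 1L,
            lr_encoder > 0, lr_filters >= 0, lr_proxies > 0)
  dat <- .as_tfr_array(x, labels)
  classes <- sort(unique(dat$labels))
  C <- length(classes)
  if (C < 2L) stop("training needs at least two classes")
  y <- match(dat$labels, classes)
  n <- length(y)
  d <- dim(dat$x)
  spec <- encoder
  M <- as.integer(n_filters)

  vdat <- NULL
  if (!is.null(val)) {
    vdat <- .as_tfr_array(val)
    vdat$y <- match(vdat$labels, classes)
    if (anyNA(vdat$y)) stop("validation labels outside the training classes")
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  params <- .init_encoder_params(spec,
                                 n_classes = if (loss == "cross_entropy") C)
  if (loss == "scloss") {
    bank0 <- init_filter_bank(M, dat$freq_axis, beta = beta)
    params$mu <- bank0$mu
    params$sigma <- bank0$sigma
    params$proxies <- {
      p <- array(stats::rnorm(spec$embed_dim * C * M),
                 dim = c(spec$embed_dim, C, M))
      for (i in seq_len(M)) for (cc in seq_len(C)) {
        p[, cc, i] <- p[, cc, i] / sqrt(sum(p[, cc, i]^2))
      }
      p
    }
  }
  bn_running <- list(mean = numeric(spec$head_hidden),
                     var = rep(1, spec$head_hidden))

  lr <- lapply(params, function(p) lr_encoder)
  if (loss == "scloss") {
    lr$mu <- lr_filters; lr$sigma <- lr_filters; lr$proxies <- lr_proxies
  }
  opt <- .adam_init(params)

  mix_idx <- NULL
  if (!is.null(mix_class)) {
    mix_int <- match(mix_class, classes)
    if (is.na(mix_int)) stop("mix_class is not one of the training classes")
    mix_idx <- mix_int
  }

  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_metric = numeric())
  filter_history <- list()
  best <- list(metric = -Inf, params = params, bn_running = bn_running,
               epoch = 0L)

  for (epoch in seq_len(epochs)) {
    ep_x <- dat$x; ep_y <- y
    if (!is.null(mix_idx)) {
      aug <- .mix_balance(ep_x, ep_y, mix_idx)
      ep_x <- aug$x; ep_y <- aug$y
    }
    ord <- sample.int(length(ep_y))
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, length(ord), by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1L, length(ord))]
      if (length(idx) < 2L) next   # batch norm needs >= 2 samples
      Xb <- ep_x[, , idx, drop = FALSE]
      yb <- ep_y[idx]
      step <- tryCatch({
        if (loss == "scloss") {
          .train_step_scloss(params, Xb, yb, spec, bn_running, dat$freq_axis,
                             beta)
        } else {
          .train_step_ce(params, Xb, yb, spec, bn_running, C)
        }
      }, error = function(e) {
        stop(sprintf("training aborted at epoch %d, batch %d: %s",
                     epoch, n_batches + 1L, conditionMessage(e)),
             call. = FALSE)
      })
      if (!is.finite(step$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d, batch %d",
                     epoch, n_batches + 1L))
      }
      bn_running <- step$bn_running
      upd <- .adam_step(params, step$grads, opt, lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + step$loss; n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / max(n_batches, 1L)

    vm <- NA_real_
    if (!is.null(vdat)) {
      pred <- .model_predict_int(params, bn_running, spec, vdat$x,
                                 dat$freq_axis, beta, loss, C, M)
      vm <- .split_metric(vdat$y, pred, C, select_metric)
      if (vm > best$metric) {   # first epoch achieving the best metric wins
        best <- list(metric = vm, params = params, bn_running = bn_running,
                     epoch = epoch)
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = ep_loss,
                                val_metric = vm))
    if (loss == "scloss") {
      filter_history[[epoch]] <- list(mu = params$mu, sigma = params$sigma)
    }
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  val %s\n", epoch, ep_loss,
                  ifelse(is.na(vm), "-", sprintf("%.4f", vm))))
    }
    if (!is.null(stop_at_val_acc) && !is.na(vm) && vm >= stop_at_val_acc) break
  }

  if (is.null(vdat)) {
    best <- list(metric = NA_real_, params = params, bn_running = bn_running,
                 epoch = nrow(history))
  }
  fp <- best$params
  enc_params <- fp[grep("^enc_", names(fp))]
  structure(
    list(loss_type = loss,
         classes = classes,
         filters = if (loss == "scloss") {
           filter_bank(fp$mu, fp$sigma, beta, dat$freq_axis)
         },
         encoder = structure(list(params = enc_params,
                                  bn_running = best$bn_running,
                                  spec = spec),
                             class = "ebdl_encoder"),
         proxies = if (loss == "scloss") {
           structure(fp$proxies, class = "proxy_bank")
         },
         freq_axis = dat$freq_axis,
         history = history,
         filter_history = filter_history,
         best_epoch = best$epoch,
         config = list(n_filters = M, beta = beta, epochs = epochs,
                       batch_size = batch_size, lr_encoder = lr_encoder,
                       lr_filters = lr_filters, lr_proxies = lr_proxies,
                       seed = seed, select_metric = select_metric,
                       input_shape = d[1:2])),
    class = "ebdl"
  )
}

# Build the M-view image batch from raw TFRs and the current filter
# profiles. Xb: (T, F, Nb); returns (T, F, M*Nb, 1), view-major.
.make_view_batch <- function(Xb, g) {
  d <- dim(Xb); M <- nrow(g)
  big <- array(0, dim = c(d[1L], d[2L], M * d[3L], 1L))
  for (i in seq_len(M)) {
    scale <- rep(g[i, ], each = d[1L])
    big[, , ((i - 1L) * d[3L] + 1L):(i * d[3L]), 1L] <- Xb * as.vector(scale)
  }
  big
}

.train_step_scloss <- function(params, Xb, yb, spec, bn_running, freq_axis,
                               beta) {
  d <- dim(Xb); Nb <- d[3L]
  M <- length(params$mu)
  bankish <- list(mu = params$mu, sigma = params$sigma, beta = beta,
                  freq_axis = freq_axis)
  pg <- .filter_profile_grads(bankish)
  big <- .make_view_batch(Xb, pg$g)
  fw <- .encoder_forward(params, big, spec, bn_running, train = TRUE,
                         normalize = TRUE)
  lc <- .scloss_core(fw$out, yb, params$proxies, grad = TRUE)
  bw <- .encoder_backward(lc$dZ, fw$cache, params)
  dmu <- numeric(M); dsigma <- numeric(M)
  for (i in seq_len(M)) {
    dview <- bw$dX[, , ((i - 1L) * Nb + 1L):(i * Nb), 1L, drop = FALSE]
    dim(dview) <- d
    el <- Xb * dview
    dg <- rowSums(colSums(el))               # sum over time and batch -> F
    dmu[i] <- sum(dg * pg$dmu[i, ])
    dsigma[i] <- sum(dg * pg$dsigma[i, ])
  }
  grads <- bw$grads
  grads$mu <- dmu; grads$sigma <- dsigma; grads$proxies <- lc$dP
  list(loss = lc$value, grads = grads, bn_running = fw$bn_running)
}

.train_step_ce <- function(params, Xb, yb, spec, bn_running, C) {
  d <- dim(Xb); Nb <- d[3L]
  X <- array(Xb, dim = c(d[1L], d[2L], Nb, 1L))
  fw <- .encoder_forward(params, X, spec, bn_running, train = TRUE,
                         normalize = FALSE)
  v <- fw$out
  logits <- sweep(v %*% params$enc_clsW, 2L, params$enc_clsb, `+`)
  sm <- exp(logits - apply(logits, 1L, max))
  sm <- sm / rowSums(sm)
  ll <- -mean(log(sm[cbind(seq_len(Nb), yb)] + 1e-12))
  dlogits <- sm
  dlogits[cbind(seq_len(Nb), yb)] <- dlogits[cbind(seq_len(Nb), yb)] - 1
  dlogits <- dlogits / Nb
  dv <- tcrossprod(dlogits, params$enc_clsW)
  bw <- .encoder_backward(dv, fw$cache, params)
  grads <- bw$grads
  grads$enc_clsW <- crossprod(v, dlogits)
  grads$enc_clsb <- colSums(dlogits)
  list(loss = ll, grads = grads, bn_running = fw$bn_running)
}

# Epoch-level mix balancing: top minority classes up to the majority
# count with 0.5/0.5 mixes of a resting-class and a minority-class draw.
.mix_balance <- function(x, y, resting) {
  counts <- tabulate(y, nbins = max(y))
  target <- max(counts)
  add_x <- list(); add_y <- integer()
  rest_idx <- which(y == resting)
  for (cl in seq_along(counts)) {
    if (cl == resting || counts[cl] == 0L) next
    need <- target - counts[cl]
    if (need <= 0L) next
    cls_idx <- which(y == cl)
    r <- sample(rest_idx, need, replace = TRUE)
    m <- sample(cls_idx, need, replace = TRUE)
    mix <- 0.5 * x[, , r, drop = FALSE] + 0.5 * x[, , m, drop = FALSE]
    add_x[[length(add_x) + 1L]] <- mix
    add_y <- c(add_y, rep(cl, need))
  }
  if (!length(add_x)) return(list(x = x, y = y))
  d <- dim(x)
  total <- d[3L] + length(add_y)
  out <- array(0, dim = c(d[1L], d[2L], total))
  out[, , seq_len(d[3L])] <- x
  at <- d[3L]
  for (blk in add_x) {
    nb <- dim(blk)[3L]
    out[, , at + seq_len(nb)] <- blk
    at <- at + nb
  }
  list(x = out, y = c(y, add_y))
}

# Evaluation-mode predictions (integer class indices) for an array of
# TFRs, chunked to bound memory.
.model_predict_int <- function(params, bn_running, spec, Xarr, freq_axis,
                               beta, loss, C, M, chunk = 64L) {
  n <- dim(Xarr)[3L]
  preds <- integer(n)
  if (loss == "scloss") {
    bankish <- list(mu = params$mu, sigma = params$sigma, beta = beta,
                    freq_axis = freq_axis)
    g <- .filter_profile_grads(bankish)$g
  }
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    Xb <- Xarr[, , idx, drop = FALSE]
    if (loss == "scloss") {
      big <- .make_view_batch(Xb, g)
      fw <- .encoder_forward(params, big, spec, bn_running, train = FALSE,
                             normalize = TRUE)
      preds[idx] <- .predict_proxy_core(fw$out, length(idx), params$proxies)
    } else {
      X <- array(Xb, dim = c(dim(Xb)[1L], dim(Xb)[2L], length(idx), 1L))
      fw <- .encoder_forward(params, X, spec, bn_running, train = FALSE,
                             normalize = FALSE)
      logits <- sweep(fw$out %*% params$enc_clsW, 2L, params$enc_clsb, `+`)
      preds[idx] <- max.col(logits, ties.method = "first")
    }
  }
  preds
}

.split_metric <- function(truth, pred, C, metric) {
  if (metric == "accuracy") return(mean(truth == pred))
  sens <- vapply(seq_len(C), function(cc) {
    tp <- sum(truth == cc & pred == cc)
    n_c <- sum(truth == cc)
    if (n_c == 0L) NA_real_ else tp / n_c
  }, numeric(1))
  mean(sens, na.rm = TRUE)
}
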