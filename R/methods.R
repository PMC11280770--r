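#' Predict classes for new TFR samples
#'
#' Applies the trained filter bank, encodes each sub-view with the shared
#' encoder in evaluation mode, and assigns the class of the most similar
#' proxy across all sub-views (ties to the lowest class index). For a
#' cross-entropy baseline model the prediction is the argmax of the
#' classifier logits on the unfiltered input.
#'
#' @param object a fitted [ebdl()] model.
#' @param newdata a [tfr_sample()], a list of them, a T x F matrix, or a
#'   T x F x N array.
#' @param type `"class"` (default) for labels, `"embedding"` for the
#'   M x L unit-norm embeddings of each sample (sub-view contrastive
#'   models only).
#' @param ... unused.
#' @return a vector of predicted labels in the training label vocabulary,
#'   or a list of embedding matrices for `type = "embedding"`.
#' @export
predict.ebdl <- function(object, newdata, type = c("class", "embedding"),
                         ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- tfr_sample(newdata)
  dat <- if (is.array(newdata) && length(dim(newdata)) == 3L) {
    list(x = newdata, labels = rep(NA, dim(newdata)[3L]))
  } else {
    .as_tfr_array(newdata)
  }
  d <- dim(dat$x)
  if (!identical(as.integer(d[1:2]), as.integer(object$config$input_shape))) {
    stop("newdata shape does not match the shape the model was trained on")
  }
  params <- object$encoder$params
  if (object$loss_type == "scloss") {
    params$mu <- object$filters$mu
    params$sigma <- object$filters$sigma
    params$proxies <- unclass(object$proxies)
  }
  if (type == "embedding") {
    if (object$loss_type != "scloss") {
      stop("embeddings are only defined for the sub-view contrastive model")
    }
    g <- filter_profiles(object$filters)
    out <- vector("list", d[3L])
    for (n in seq_len(d[3L])) {
      views <- apply_filters(dat$x[, , n], object$filters)
      out[[n]] <- encode_subviews(unclass(views), object$encoder)
    }
    return(out)
  }
  pred_int <- .model_predict_int(params, object$encoder$bn_running,
                                 object$encoder$spec, dat$x,
                                 object$freq_axis, object$config$beta,
                                 object$loss_type, length(object$classes),
                                 object$config$n_filters)
  object$classes[pred_int]
}

#' @export
print.ebdl <- function(x, ...) {
  cat("Band-dependent learning model\n")
  cat(sprintf("  loss: %s   classes: %s\n", x$loss_type,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  input: %d x %d TFR   encoder: %s (L = %d)\n",
              x$config$input_shape[1L], x$config$input_shape[2L],
              x$encoder$spec$backbone, x$encoder$spec$embed_dim))
  if (x$loss_type == "scloss") {
    cat(sprintf("  %d sub-band filters (beta = %g):\n",
                length(x$filters$mu), x$filters$beta))
    for (i in seq_along(x$filters$mu)) {
      cat(sprintf("    mu = %7.3f   sigma = %7.3f\n",
                  x$filters$mu[i], x$filters$sigma[i]))
    }
  }
  cat(sprintf("  trained %d epoch(s); best checkpoint at epoch %d\n",
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' @export
summary.ebdl <- function(object, ...) {
  out <- list(model = object,
              final_loss = utils::tail(object$history$loss, 1L),
              best_val = if (all(is.na(object$history$val_metric))) NA_real_
                         else max(object$history$val_metric, na.rm = TRUE))
  class(out) <- "summary.ebdl"
  out
}

#' @export
print.summary.ebdl <- function(x, ...) {
  print(x$model)
  cat(sprintf("  final training loss: %.4f\n", x$final_loss))
  if (!is.na(x$best_val)) {
    cat(sprintf("  best validation %s: %.4f\n",
                x$model$config$select_metric, x$best_val))
  }
  invisible(x)
}

#' Extract the learned filter parameters
#'
#' @param object a fitted [ebdl()] model.
#' @param ... unused.
#' @return a matrix with columns `mu` and `sigma`, one row per filter
#'   (or `NULL` for a cross-entropy baseline model).
#' @export
coef.ebdl <- function(object, ...) {
  if (object$loss_type != "scloss") return(NULL)
  cbind(mu = object$filters$mu, sigma = object$filters$sigma)
}

#' Plot a fitted model's filter bank or training history
#'
#' `which = "filters"` draws the learned sub-band scaling profiles over
#' the normalized frequency axis; `which = "history"` draws the training
#' loss (and validation metric, when present) per epoch.
#'
#' @param x a fitted [ebdl()] model.
#' @param which `"filters"` or `"history"`.
#' @param ... passed to the underlying plotting function.
#' @return `x`, invisibly.
#' @export
plot.ebdl <- function(x, which = c("filters", "history"), ...) {
  which <- match.arg(which)
  if (which == "filters") {
    if (x$loss_type != "scloss") stop("baseline models have no filter bank")
    plot(x$filters, main = "Learned sub-band filters", ...)
  } else {
    h <- x$history
    graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                   ylab = "training loss", ...)
    if (!all(is.na(h$val_metric))) {
      op <- graphics::par(new = TRUE)
      on.exit(graphics::par(op))
      graphics::plot(h$epoch, h$val_metric, type = "b", col = 2, axes = FALSE,
                     xlab = "", ylab = "", ylim = c(0, 1))
      graphics::axis(4, col.axis = 2)
    }
  }
  invisible(x)
}

#' Pairwise proxy similarities per sub-view
#'
#' Prints, for each sub-view, the C x C matrix of cosine similarities
#' between its class proxies — a quick check of how separated the classes
#' are in each sub-view's region of the representation space.
#'
#' @param object a fitted [ebdl()] model (sub-view contrastive).
#' @return a list of C x C similarity matrices, one per sub-view,
#'   invisibly.
#' @export
inspect_proxies <- function(object) {
  stopifnot(inherits(object, "ebdl"))
  if (object$loss_type != "scloss") stop("baseline models have no proxies")
  p <- .normalize_proxies(unclass(object$proxies))
  d <- dim(p)
  out <- vector("list", d[3L])
  for (i in seq_len(d[3L])) {
    s <- crossprod(p[, , i])
    dimnames(s) <- list(object$classes, object$classes)
    out[[i]] <- s
    cat(sprintf("sub-view %d proxy similarities:\n", i))
    print(round(s, 3))
  }
  invisible(out)
}
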