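#' Initialize a proxy bank
#'
#' Creates the M x C trainable class proxies (one per sub-view and class),
#' drawn from an isotropic Gaussian and L2-normalized, reproducibly under
#' a seed. Proxies are stored unconstrained and renormalized wherever
#' similarities are computed, so any optimizer update keeps the unit-norm
#' contract at use time.
#'
#' @param n_views number of sub-views M.
#' @param n_classes number of classes C.
#' @param embed_dim embedding dimension L.
#' @param seed integer seed.
#' @return an object of class `"proxy_bank"`: an L x C x M array with
#'   attributes recording the dimensions.
#' @export
init_proxies <- function(n_views, n_classes, embed_dim, seed = 1024L) {
  stopifnot(n_views >= 1L, n_classes >= 1L, embed_dim >= 1L)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p <- array(stats::rnorm(embed_dim * n_classes * n_views),
             dim = c(embed_dim, n_classes, n_views))
  for (i in seq_len(n_views)) for (c in seq_len(n_classes)) {
    p[, c, i] <- p[, c, i] / sqrt(sum(p[, c, i]^2))
  }
  structure(p, class = "proxy_bank")
}

#' @export
print.proxy_bank <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<proxy_bank> %d views x %d classes, embedding dim %d\n",
              d[3L], d[2L], d[1L]))
  invisible(x)
}

# Proxies in unit-norm form: L x C x M array of normalized columns.
.normalize_proxies <- function(bank) {
  d <- dim(bank)
  nrm <- sqrt(colSums(array(bank^2, dim = c(d[1L], d[2L] * d[3L])))) + 1e-12
  array(sweep(array(bank, dim = c(d[1L], d[2L] * d[3L])), 2L, nrm, `/`),
        dim = d)
}

#' Partition proxies relative to one sub-view embedding
#'
#' For the embedding of sub-view `view_index` with class `class_label`,
#' the M x C proxies split into four groups: the same-view same-class
#' proxy (the positive), the C-1 same-view other-class proxies `A` (pushed
#' away), the M-1 other-view same-class proxies `B` (their similarity is
#' capped at zero so each sub-view specializes), and the remaining
#' proxies, which take no part in the loss.
#'
#' @param bank a [init_proxies()] bank.
#' @param view_index sub-view index i in 1..M.
#' @param class_label class index c in 1..C.
#' @return a list with `positive`, `same_view_other_classes`,
#'   `other_views_same_class` and `excluded`, each a two-column matrix of
#'   (view, class) index pairs.
#' @export
partition_proxies <- function(bank, view_index, class_label) {
  d <- dim(bank)
  C <- d[2L]; M <- d[3L]
  stopifnot(view_index >= 1L, view_index <= M,
            class_label >= 1L, class_label <= C)
  pos <- cbind(view = view_index, class = class_label)
  a_cls <- setdiff(seq_len(C), class_label)
  A <- cbind(view = rep(view_index, length(a_cls)), class = a_cls)
  b_views <- setdiff(seq_len(M), view_index)
  B <- cbind(view = b_views, class = rep(class_label, length(b_views)))
  all_pairs <- cbind(view = rep(seq_len(M), each = C),
                     class = rep(seq_len(C), times = M))
  used <- rbind(pos, A, B)
  key <- function(m) paste(m[, 1L], m[, 2L])
  excl <- all_pairs[!(key(all_pairs) %in% key(used)), , drop = FALSE]
  list(positive = pos, same_view_other_classes = A,
       other_views_same_class = B, excluded = excl)
}

# Core of the sub-view contrastive loss on a batch.
# Z: (M*N) x L matrix of unit-norm embeddings, rows ordered view-major
#    (row (i-1)*N + n is view i of sample n).
# labels: integer class indices (1..C) of the N samples.
# bank: raw proxy bank (normalized internally).
# Returns the scalar loss (mean over samples of the per-sample mean over
# views), the per-(view, sample) terms, and, if grad = TRUE, gradients
# with respect to Z and the raw proxies.
.scloss_core <- function(Z, labels, bank, grad = FALSE) {
  d <- dim(bank); L <- d[1L]; C <- d[2L]; M <- d[3L]
  N <- length(labels)
  stopifnot(nrow(Z) == M * N, ncol(Z) == L)
  phat <- .normalize_proxies(bank)
  Pmat <- matrix(phat, nrow = L)                   # col (i-1)*C + c
  S <- Z %*% Pmat                                  # (MN) x (CM)
  terms <- matrix(0, M, N)
  dS <- if (grad) matrix(0, M * N, C * M) else NULL
  for (i in seq_len(M)) {
    same_cols <- (i - 1L) * C + seq_len(C)
    for (n in seq_len(N)) {
      q <- (i - 1L) * N + n
      cn <- labels[n]
      s_same <- S[q, same_cols]
      e_same <- exp(s_same)
      num <- e_same[cn]
      den <- sum(e_same)
      b_terms <- 0
      b_cols <- integer(0)
      if (M > 1L) {
        b_views <- setdiff(seq_len(M), i)
        b_cols <- (b_views - 1L) * C + cn
        sb <- S[q, b_cols]
        eb <- exp(pmax(sb, 0))
        b_terms <- sum(eb)
        den <- den + b_terms
      }
      terms[i, n] <- -log(num / den)
      if (grad) {
        w <- 1 / (M * N)
        gsame <- e_same / den
        gsame[cn] <- gsame[cn] - 1
        dS[q, same_cols] <- w * gsame
        if (length(b_cols)) {
          sb <- S[q, b_cols]
          dS[q, b_cols] <- w * ifelse(sb > 0, exp(sb), 0) / den
        }
      }
    }
  }
  out <- list(value = mean(terms), per_view_terms = terms)
  if (grad) {
    out$dZ <- dS %*% t(Pmat)                      # MN x L
    dPmat <- crossprod(dS, Z)                     # (CM) x L
    dP <- array(0, dim = d)
    for (i in seq_len(M)) for (c in seq_len(C)) {
      col <- (i - 1L) * C + c
      praw <- bank[, c, i]
      nrm <- sqrt(sum(praw^2)) + 1e-12
      ph <- praw / nrm
      dph <- dPmat[col, ]
      dP[, c, i] <- (dph - ph * sum(dph * ph)) / nrm
    }
    out$dP <- dP
  }
  out
}

#' Sub-view contrastive loss for one sample
#'
#' Computes the proxy-based contrastive loss over the M sub-view
#' embeddings of one sample. For view i with positive proxy p+, same-view
#' other-class proxies A(i) and other-view same-class proxies B(i), the
#' per-view term is
#' `-log( e^(p+ . z_i) / (e^(p+ . z_i) + sum_A e^(p . z_i) + sum_B e^(ReLU(p . z_i))) )`
#' and the loss is the mean of the M terms. All similarities are dot
#' products of unit vectors (cosine similarities); the ReLU caps the
#' reward for cross-view same-class similarity at zero, pushing distinct
#' sub-views to encode different features.
#'
#' @param z an M x L matrix of unit-norm sub-view embeddings (a single
#'   vector is treated as M = 1).
#' @param bank a [init_proxies()] bank with matching M and L.
#' @param class_label class index in 1..C.
#' @return an object of class `"scloss_value"`: list with `value` (the
#'   mean) and `per_view_terms` (length M).
#' @examples
#' p <- init_proxies(1, 2, 4, seed = 1)
#' scloss(matrix(p[, 1, 1], 1), p, class_label = 1)
#' @export
scloss <- function(z, bank, class_label) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  d <- dim(bank)
  if (ncol(z) != d[1L]) stop("embedding dimension does not match the proxies")
  if (nrow(z) != d[3L]) stop("need one embedding per sub-view")
  res <- .scloss_core(z, labels = as.integer(class_label), bank = bank)
  structure(list(value = res$value,
                 per_view_terms = as.vector(res$per_view_terms)),
            class = "scloss_value")
}

#' @export
print.scloss_value <- function(x, ...) {
  cat(sprintf("<scloss> value=%.6f over %d views\n", x$value,
              length(x$per_view_terms)))
  invisible(x)
}

#' Nearest-proxy classification of one embedding set
#'
#' Compares each sub-view embedding to the proxies of its own sub-view
#' (cosine similarity) and returns the class of the globally most similar
#' proxy, i.e. the minimum proxy-to-sample distance across all views.
#' Ties break towards the lowest class index.
#'
#' @param z an M x L matrix of unit-norm sub-view embeddings.
#' @param bank a [init_proxies()] bank with matching M and L.
#' @return the predicted class index in 1..C.
#' @export
nearest_proxy <- function(z, bank) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  d <- dim(bank)
  stopifnot(ncol(z) == d[1L], nrow(z) == d[3L])
  .predict_proxy_core(z, labels_n = 1L, bank = bank)
}

# Batch nearest-proxy prediction. Z is (M*N) x L, view-major; returns
# integer predictions of length N.
.predict_proxy_core <- function(Z, labels_n, bank) {
  d <- dim(bank); L <- d[1L]; C <- d[2L]; M <- d[3L]
  N <- labels_n
  phat <- .normalize_proxies(bank)
  Pmat <- matrix(phat, nrow = L)
  S <- Z %*% Pmat
  preds <- integer(N)
  for (n in seq_len(N)) {
    simc <- rep(-Inf, C)
    for (i in seq_len(M)) {
      q <- (i - 1L) * N + n
      simc <- pmax(simc, S[q, (i - 1L) * C + seq_len(C)])
    }
    preds[n] <- which.max(simc)   # first max: ties to the lowest class
  }
  preds
}
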