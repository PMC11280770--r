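#' Generalized-Gaussian sub-band scaling factor
#'
#' The per-frequency-bin scaling factor
#' `g(fb; mu, sigma, beta) = exp(-(|fb - mu| / sigma)^beta)`
#' of a sub-band filter. `mu` locates the band center on the normalized
#' frequency axis, `sigma` sets the bandwidth and `beta` (a fixed even
#' integer, default 8) the steepness of the band edges. Values lie in
#' (0, 1] with the peak value 1 attained exactly at `fb = mu`; because
#' `beta` is even, the sign of `sigma` is irrelevant, so learned negative
#' scales are legal.
#'
#' @param fb numeric vector of normalized frequencies (any reals; filters
#'   are evaluated on \[-1, 1\] in practice but `mu` may wander outside).
#' @param mu location parameter.
#' @param sigma scale parameter, nonzero.
#' @param beta positive even integer shape parameter.
#' @return numeric vector of scaling factors in (0, 1].
#' @examples
#' gaussian_scale(0.2, mu = 0.2, sigma = 1)       # 1
#' gaussian_scale(1.5, mu = 0.5, sigma = 1)       # exp(-1)
#' @export
gaussian_scale <- function(fb, mu, sigma, beta = 8) {
  .check_beta(beta)
  if (any(sigma == 0)) stop("sigma must be nonzero")
  exp(-((fb - mu) / sigma)^beta)
}

.check_beta <- function(beta) {
  if (!(length(beta) == 1L && is.finite(beta) && beta > 0 &&
        beta == round(beta) && beta %% 2 == 0)) {
    stop("beta must be a positive even integer")
  }
  invisible(beta)
}

#' Construct a sub-band filter bank
#'
#' A bank of M generalized-Gaussian filters sharing one shape exponent
#' and one normalized frequency axis. Locations and scales are the
#' trainable parameters; they are deliberately unconstrained (training can
#' and does move `mu` outside \[-1, 1\] and flip the sign of `sigma`).
#'
#' @param mu numeric vector of M filter locations.
#' @param sigma numeric vector of M nonzero filter scales.
#' @param beta positive even integer shape exponent shared by the bank.
#' @param freq_axis strictly increasing normalized frequency axis.
#' @return an object of class `"filter_bank"`.
#' @seealso [init_filter_bank()], [apply_filters()], [filter_profiles()]
#' @export
filter_bank <- function(mu, sigma, beta = 8, freq_axis) {
  .check_beta(beta)
  stopifnot(length(mu) == length(sigma), length(mu) >= 1L,
            all(is.finite(mu)), all(is.finite(sigma)), all(sigma != 0),
            all(diff(freq_axis) > 0))
  structure(
    list(mu = as.numeric(mu), sigma = as.numeric(sigma), beta = beta,
         freq_axis = as.numeric(freq_axis)),
    class = "filter_bank"
  )
}

#' Initialize a filter bank with uniformly spread centers
#'
#' Standard initialization: the M locations are uniformly distributed
#' along the normalized frequency axis at the interior points
#' `mu_i = -1 + 2 i / (M + 1)` and every scale starts at 1. With M = 3
#' this places filters at -0.5, 0, 0.5.
#'
#' @param n_filters number of filters M.
#' @param freq_axis normalized frequency axis the bank will be evaluated
#'   on.
#' @param beta shape exponent, default 8.
#' @return a [filter_bank()].
#' @export
init_filter_bank <- function(n_filters, freq_axis = normalized_freq_axis(512L),
                             beta = 8) {
  stopifnot(n_filters >= 1L)
  i <- seq_len(n_filters)
  filter_bank(mu = -1 + 2 * i / (n_filters + 1),
              sigma = rep(1, n_filters), beta = beta, freq_axis = freq_axis)
}

#' Evaluate every filter of a bank on its frequency axis
#'
#' @param bank a [filter_bank()].
#' @return an M x F matrix; row i is filter i's scaling profile.
#' @export
filter_profiles <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  t(vapply(seq_along(bank$mu), function(i) {
    gaussian_scale(bank$freq_axis, bank$mu[i], bank$sigma[i], bank$beta)
  }, numeric(length(bank$freq_axis))))
}

# Gradients of the filter profiles with respect to mu and sigma:
# returns list(g, dmu, dsigma), each an M x F matrix. With u = (f-mu)/sigma,
# dg/dmu = g * beta * u^(beta-1) / sigma and dg/dsigma = g * beta * u^beta / sigma.
.filter_profile_grads <- function(bank) {
  f <- bank$freq_axis
  beta <- bank$beta
  m <- length(bank$mu)
  g <- matrix(0, m, length(f))
  dmu <- g; dsigma <- g
  for (i in seq_len(m)) {
    u <- (f - bank$mu[i]) / bank$sigma[i]
    gi <- exp(-u^beta)
    g[i, ] <- gi
    dmu[i, ] <- gi * beta * u^(beta - 1) / bank$sigma[i]
    dsigma[i, ] <- gi * beta * u^beta / bank$sigma[i]
  }
  list(g = g, dmu = dmu, dsigma = dsigma)
}

#' Apply a filter bank to a TFR, producing sub-views
#'
#' Scales the TFR columnwise by each filter's profile: sub-view i is
#' `x[t, f] * g(freq_axis[f]; mu_i, sigma_i, beta)`. The operation leaves
#' the shape unchanged and is smooth in the filter parameters, which is
#' what lets the bank be trained by gradient descent. Applied to
#' standardized TFRs the scaling shrinks values towards 0 (the
#' post-standardization mean) outside each filter's band.
#'
#' @param x a [tfr_sample()] or a T x F numeric matrix.
#' @param bank a [filter_bank()] whose `freq_axis` matches `x`'s.
#' @return a list of class `"subview_set"` with M matrices, one per
#'   filter, each of the input's shape.
#' @export
apply_filters <- function(x, bank) {
  stopifnot(inherits(bank, "filter_bank"))
  if (inherits(x, "tfr_sample")) {
    if (length(x$freq_axis) != length(bank$freq_axis) ||
        max(abs(x$freq_axis - bank$freq_axis)) > 1e-9) {
      stop("the filter bank's frequency axis does not match the sample's")
    }
    vals <- x$values
  } else {
    vals <- as.matrix(x)
    if (ncol(vals) != length(bank$freq_axis)) {
      stop("the filter bank's frequency axis does not match the input width")
    }
  }
  prof <- filter_profiles(bank)
  views <- lapply(seq_len(nrow(prof)), function(i) {
    sweep(vals, 2L, prof[i, ], `*`)
  })
  structure(views, class = "subview_set")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> M=%d filters, beta=%g, %d frequency bins\n",
              length(x$mu), x$beta, length(x$freq_axis)))
  for (i in seq_along(x$mu)) {
    cat(sprintf("  filter %d: mu=%8.4f  sigma=%8.4f\n", i, x$mu[i], x$sigma[i]))
  }
  invisible(x)
}

#' Plot the scaling profiles of a filter bank
#'
#' Draws every filter's generalized-Gaussian profile over the normalized
#' frequency axis, the standard way to inspect which sub-bands a trained
#' model attends to.
#'
#' @param x a [filter_bank()].
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.filter_bank <- function(x, ...) {
  prof <- filter_profiles(x)
  graphics::matplot(x$freq_axis, t(prof), type = "l", lty = 1,
                    xlab = "normalized frequency", ylab = "scaling factor",
                    ylim = c(0, 1.05), ...)
  graphics::legend("topright",
                   legend = sprintf("mu=%.2f, sigma=%.2f", x$mu, x$sigma),
                   col = seq_along(x$mu), lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Serialize a filter bank to JSON
#'
#' Writes per-filter `(mu, sigma, beta)` plus the frequency-axis length to
#' a small JSON file for inspection or exchange; [read_filter_bank()]
#' restores it.
#'
#' @param bank a [filter_bank()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_filter_bank <- function(bank, path) {
  stopifnot(inherits(bank, "filter_bank"))
  obj <- list(
    filters = data.frame(mu = bank$mu, sigma = bank$sigma),
    beta = bank$beta,
    freq_axis = bank$freq_axis
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  filter_bank(mu = obj$filters$mu, sigma = obj$filters$sigma,
              beta = obj$beta, freq_axis = obj$freq_axis)
}
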