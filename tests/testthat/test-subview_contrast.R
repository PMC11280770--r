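test_that("proxy initialization is reproducible, unit-norm, and counted", {
  p <- init_proxies(3, 4, 16, seed = 7)
  expect_identical(dim(unclass(p)), c(16L, 4L, 3L))
  nrms <- apply(unclass(p), c(2, 3), function(v) sqrt(sum(v^2)))
  expect_equal(as.vector(nrms), rep(1, 12), tolerance = 1e-12)
  expect_identical(unclass(init_proxies(3, 4, 16, seed = 7)), unclass(p))
  expect_false(identical(unclass(init_proxies(3, 4, 16, seed = 8)),
                         unclass(p)))
})

test_that("proxies partition into the four stated groups", {
  p <- init_proxies(1, 2, 4)
  g <- partition_proxies(p, 1, 1)
  expect_equal(g$positive, cbind(view = 1, class = 1))
  expect_equal(nrow(g$same_view_other_classes), 1L)
  expect_equal(g$same_view_other_classes[1, "class"], c(class = 2))
  expect_equal(nrow(g$other_views_same_class), 0L)

  p <- init_proxies(2, 3, 4)
  g <- partition_proxies(p, 2, 3)
  expect_equal(nrow(g$same_view_other_classes), 2L)   # C - 1
  expect_equal(nrow(g$other_views_same_class), 1L)    # M - 1
  expect_equal(nrow(g$excluded), 2L)
  total <- 1 + nrow(g$same_view_other_classes) +
    nrow(g$other_views_same_class) + nrow(g$excluded)
  expect_equal(total, 2 * 3)

  p <- init_proxies(1, 1, 4)
  g <- partition_proxies(p, 1, 1)
  expect_equal(nrow(g$same_view_other_classes), 0L)
  expect_equal(nrow(g$other_views_same_class), 0L)
})

test_that("the loss reproduces hand-evaluated micro-instances", {
  # M = 1, C = 2, orthonormal proxies
  p <- init_proxies(1, 2, 4, seed = 1)
  p[, 1, 1] <- c(1, 0, 0, 0)
  p[, 2, 1] <- c(0, 1, 0, 0)
  # embedding equal to its positive proxy, negative proxy orthogonal
  aligned <- scloss(matrix(c(1, 0, 0, 0), 1), p, class_label = 1)
  expect_equal(aligned$value, -log(exp(1) / (exp(1) + 1)), tolerance = 1e-12)
  # all dot products zero: ratio 1/2
  sym <- scloss(matrix(c(0, 0, 1, 0), 1), p, class_label = 1)
  expect_equal(sym$value, log(2), tolerance = 1e-12)
  # per-view terms average to the value
  p2 <- init_proxies(3, 2, 8, seed = 2)
  z <- random_unit_rows(3, 8, seed = 3)
  v <- scloss(z, p2, class_label = 2)
  expect_equal(v$value, mean(v$per_view_terms))
  expect_gte(v$value, 0)
})

test_that("cross-view proxies with nonpositive similarity contribute e^0", {
  # M = 2: a B-proxy orthogonal (or opposed) to z adds exactly 1 to the
  # denominator, and perturbing it inside the nonpositive region leaves
  # the loss unchanged (the ReLU's flat region)
  L <- 4
  p <- init_proxies(2, 2, L, seed = 5)
  p[, 1, 1] <- c(1, 0, 0, 0); p[, 2, 1] <- c(0, 1, 0, 0)
  p[, 1, 2] <- c(0, 0, 1, 0); p[, 2, 2] <- c(0, 0, 0, 1)
  z <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0))
  base <- scloss(z, p, class_label = 1)
  # view 1 term: positive sim 1, A sim 0, B proxy p[,1,2] sim 0 -> e^0 = 1
  expect_equal(base$per_view_terms[1],
               -log(exp(1) / (exp(1) + 1 + 1)), tolerance = 1e-12)
  # rotate the B-proxy within the subspace orthogonal to z1: loss unchanged
  p_rot <- p
  p_rot[, 1, 2] <- c(0, 1 / sqrt(2), -1 / sqrt(2), 0)
  expect_equal(scloss(z, p_rot, class_label = 1)$per_view_terms[1],
               base$per_view_terms[1], tolerance = 1e-12)
  # but pushing it to positive similarity raises the loss
  p_pos <- p
  p_pos[, 1, 2] <- c(0.6, 0, 0.8, 0)
  expect_gt(scloss(z, p_pos, class_label = 1)$per_view_terms[1],
            base$per_view_terms[1])
})

test_that("the loss moves the right way under directional perturbations", {
  L <- 6
  p <- init_proxies(1, 3, L, seed = 9)
  z <- random_unit_rows(1, L, seed = 10)
  base <- scloss(z, p, 1)$value
  # nudging the positive proxy toward z lowers the loss
  p_to <- unclass(p)
  p_to[, 1, 1] <- p_to[, 1, 1] + 0.2 * as.vector(z)
  expect_lt(scloss(z, structure(p_to, class = "proxy_bank"), 1)$value, base)
  # nudging an A-proxy toward z raises the loss
  p_a <- unclass(p)
  p_a[, 2, 1] <- p_a[, 2, 1] + 0.2 * as.vector(z)
  expect_gt(scloss(z, structure(p_a, class = "proxy_bank"), 1)$value, base)
})

test_that("loss gradients match central finite differences", {
  core <- ebdl:::.scloss_core
  set.seed(14)
  for (rep in 1:4) {
    M <- sample(1:3, 1); C <- sample(2:4, 1); L <- sample(4:8, 1)
    N <- sample(1:3, 1)
    Z <- random_unit_rows(M * N, L, seed = rep)
    P <- array(rnorm(L * C * M), dim = c(L, C, M))
    labels <- sample(C, N, replace = TRUE)
    res <- core(Z, labels, P, grad = TRUE)
    eps <- 1e-6
    for (i in sample(length(P), 8)) {
      P1 <- P; P1[i] <- P1[i] + eps
      P2 <- P; P2[i] <- P2[i] - eps
      fd <- (core(Z, labels, P1)$value - core(Z, labels, P2)$value) / (2 * eps)
      expect_equal(res$dP[i], fd, tolerance = 1e-5)
    }
    for (i in sample(length(Z), 8)) {
      Z1 <- Z; Z1[i] <- Z1[i] + eps
      Z2 <- Z; Z2[i] <- Z2[i] - eps
      fd <- (core(Z1, labels, P)$value - core(Z2, labels, P)$value) / (2 * eps)
      expect_equal(res$dZ[i], fd, tolerance = 1e-5)
    }
  }
})

test_that("nearest-proxy prediction matches exhaustive enumeration", {
  set.seed(19)
  for (rep in 1:20) {
    M <- sample(1:3, 1); C <- sample(2:4, 1); L <- 6
    p <- init_proxies(M, C, L, seed = rep)
    z <- random_unit_rows(M, L, seed = 100 + rep)
    got <- nearest_proxy(z, p)
    # brute force: max cosine similarity over all (view, class) pairs,
    # comparing each embedding only to its own view's proxies
    best <- -Inf; best_class <- NA
    for (i in seq_len(M)) for (cc in seq_len(C)) {
      pr <- p[, cc, i] / sqrt(sum(p[, cc, i]^2))
      s <- sum(z[i, ] * pr)
      if (s > best + 1e-15) { best <- s; best_class <- cc }
    }
    expect_identical(got, best_class)
  }
})

test_that("prediction breaks ties toward the lowest class index", {
  p <- init_proxies(1, 3, 4, seed = 2)
  p[, 1, 1] <- c(1, 0, 0, 0)
  p[, 2, 1] <- c(0, 1, 0, 0)
  p[, 3, 1] <- c(1, 0, 0, 0)        # classes 1 and 3 tie exactly
  z <- matrix(c(1, 0, 0, 0), 1)
  expect_identical(nearest_proxy(z, p), 1L)
})

test_that("single-view prediction is nearest-centroid on the sphere", {
  set.seed(33)
  C <- 4; L <- 8
  p <- init_proxies(1, C, L, seed = 3)
  for (rep in 1:10) {
    z <- random_unit_rows(1, L, seed = 200 + rep)
    cent <- which.max(vapply(seq_len(C), function(cc) {
      pr <- p[, cc, 1]
      sum(z * pr / sqrt(sum(pr^2)))
    }, numeric(1)))
    expect_identical(nearest_proxy(z, p), cent)
  }
})
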