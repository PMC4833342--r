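test_that("service normalisation scales, round-trips and rejects constants", {
  raw <- tibble::tibble(
    pixel_id = 1:20, x = 1:20, y = 1,
    carbon = runif(20, 100, 500), msa = runif(20)
  )
  z <- normalize_services(raw, "z")
  expect_equal(unname(colMeans(z[c("carbon", "msa")])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(denormalize_services(z)$carbon, raw$carbon,
               tolerance = 1e-12)

  m <- normalize_services(raw, "max")
  expect_equal(max(m$carbon), 100)
  expect_equal(denormalize_services(m)$msa, raw$msa, tolerance = 1e-12)

  # cross-scenario reference: the global maximum maps to 100
  other <- dplyr::mutate(raw, carbon = carbon * 2)
  mm <- normalize_services(raw, "max", reference = list(raw, other))
  expect_equal(max(mm$carbon), 50, tolerance = 1e-12)

  flat <- dplyr::mutate(raw, msa = 0.5)
  expect_error(normalize_services(flat, "z"), "constant")
})

test_that("k-means bundles recover structure and bookkeeping", {
  raw <- tibble::tibble(pixel_id = 1:30, a = rnorm(30), b = rnorm(30))
  one <- kmeans_bundles(raw, k = 1, seed = 1)
  expect_equal(one$frequencies$n, 30)
  cent <- tidyr::pivot_wider(one$raw_centroids, names_from = "service",
                             values_from = "mean")
  expect_equal(cent$a, mean(raw$a))
  expect_equal(cent$b, mean(raw$b))

  set.seed(2)
  blobs <- tibble::tibble(
    pixel_id = 1:200,
    a = c(rnorm(100, -6), rnorm(100, 6)),
    b = c(rnorm(100, -6), rnorm(100, 6))
  )
  two <- kmeans_bundles(blobs, k = 2, seed = 3)
  split <- table(two$labels$bundle[1:100])
  expect_equal(length(split), 1L)  # first blob entirely in one bundle
  expect_equal(sum(two$frequencies$n), 200)
  expect_true(all(sort(unique(two$labels$bundle)) == 1:2))

  again <- kmeans_bundles(blobs, k = 2, seed = 3)
  expect_identical(two$labels, again$labels)
  expect_error(kmeans_bundles(raw, k = 31), "1..number")
})

test_that("clustering is invariant to column order and affine rescaling", {
  set.seed(9)
  raw <- tibble::tibble(
    pixel_id = 1:150,
    a = rnorm(150), b = rnorm(150, 5, 3), c = runif(150, -2, 2)
  )
  base <- kmeans_bundles(raw, k = 3, seed = 4)
  perm <- kmeans_bundles(raw[, c("pixel_id", "c", "a", "b")], k = 3, seed = 4)
  scaled <- kmeans_bundles(
    dplyr::mutate(raw, a = 10 * a + 100, b = -2 * b), k = 3, seed = 4
  )
  same_partition <- function(l1, l2) {
    all(apply(table(l1, l2) > 0, 1, sum) == 1)
  }
  expect_true(same_partition(base$labels$bundle, perm$labels$bundle))
  expect_true(same_partition(base$labels$bundle, scaled$labels$bundle))
})

test_that("moving-window composition counts the circular buffer", {
  g <- grid_spec(25, 25, cell_size = 500)
  forest <- pixels_from_matrix(matrix("forest", 25, 25), g)
  out <- moving_window_composition(forest, g)
  expect_equal(out$pct_forest, rep(100, 625), tolerance = 1e-9)

  lu <- matrix("forest", 25, 25)
  lu[13, 13] <- "SRC"
  out1 <- moving_window_composition(pixels_from_matrix(lu, g), g)
  # disk of radius 10 cells around the centre pixel
  n_buffer <- sum(outer((-10:10)^2, (-10:10)^2, "+") <= 100)
  centre <- out1[out1$row == 13 & out1$col == 13, ]
  expect_equal(centre$pct_SRC, 100 / n_buffer, tolerance = 1e-9)

  pct <- as.matrix(out1[grep("^pct_", names(out1))])
  expect_equal(rowSums(pct), rep(100, 625), tolerance = 1e-9)
  # an edge pixel sees a truncated but complete buffer
  corner <- out1[out1$row == 1 & out1$col == 1, ]
  expect_equal(corner$pct_forest, 100, tolerance = 1e-9)
})

test_that("VIF screening matches the regression oracle", {
  set.seed(7)
  X <- tibble::tibble(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  vf <- vif_filter(X)
  expect_equal(nrow(vf$removed), 0)
  expect_true(all(vf$vif < 1.2))
  # oracle: 1 / (1 - R^2) from explicit regressions
  r2a <- summary(lm(a ~ b + c, data = X))$r.squared
  expect_equal(unname(vf$vif["a"]), 1 / (1 - r2a), tolerance = 1e-9)

  dup <- dplyr::mutate(X, d = a)
  vfd <- vif_filter(dup)
  expect_equal(nrow(vfd$removed), 1)
  expect_true(vfd$removed$variable %in% c("a", "d"))
  expect_equal(ncol(vfd$data), 3)

  collin <- dplyr::mutate(X, d = a + 0.99 * b + rnorm(200, 0, 0.01))
  vfc <- vif_filter(collin, threshold = 10)
  expect_true(all(vfc$vif <= 10))
})

test_that("backward stepwise keeps real effects and drops pure noise", {
  set.seed(31)
  n <- 2000
  X <- as.data.frame(matrix(rnorm(n * 4), n,
                            dimnames = list(NULL, c("signal", paste0("n", 1:3)))))
  y <- rbinom(n, 1, plogis(2 * X$signal))
  fit <- backward_stepwise_logit(cbind(X, y = y), "y")
  expect_true("signal" %in% fit$retained)
  co <- tidy(fit)
  expect_gt(co$estimate[co$term == "signal"], 0)
  expect_lte(fit$aic, fit$aic_full + 1e-9)

  again <- backward_stepwise_logit(cbind(X, y = y), "y")
  expect_identical(fit$retained, again$retained)
  expect_equal(tidy(fit)$estimate, tidy(again)$estimate)

  g <- glance(fit)
  expect_gt(g$null_chisq, 100)
  expect_lt(g$null_p_value, 1e-10)
})

test_that("stepwise coefficient recovery stays within 3 SE of truth", {
  set.seed(55)
  beta <- c(1, -1, 0.5)
  hits <- trials <- 0
  for (rep in 1:100) {
    n <- 5000
    X <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("b1", "b2", "b3")))
    y <- rbinom(n, 1, plogis(X %*% beta))
    fit <- backward_stepwise_logit(data.frame(X, y = y), "y")
    co <- tidy(fit)
    for (j in 1:3) {
      row <- co[co$term == paste0("b", j), ]
      if (nrow(row)) {
        trials <- trials + 1
        hits <- hits + (abs(row$estimate - beta[j]) <= 3 * row$std_error)
      }
    }
  }
  expect_gte(hits / trials, 0.95)
})

test_that("perfect separation is reported with the offending variable", {
  n <- 60
  sep <- data.frame(x = c(rnorm(30, -5), rnorm(30, 5)),
                    z = rnorm(n), y = rep(0:1, each = 30))
  expect_error(suppressWarnings(backward_stepwise_logit(sep, "y")),
               "Perfect separation.*x")
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  set.seed(12)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  d$y <- rbinom(300, 1, plogis(d$x1))
  small <- glm(y ~ x1, binomial(), data = d)
  big <- glm(y ~ x1 + x2, binomial(), data = d)
  lr <- lr_test(small, big)
  expect_equal(lr$df, 1L)
  expect_gte(lr$chisq, 0)
  expect_equal(lr$p_value,
               pchisq(lr$chisq, 1, lower.tail = FALSE))

  same <- lr_test(small, small)
  expect_equal(same$chisq, 0)
  expect_equal(same$df, 0L)
  expect_equal(same$p_value, 1)

  # distribution-function cross-check on reference values
  registerS3method("logLik", "srcscape_fake",
                   function(object, ...) {
                     structure(object$ll, df = object$df, class = "logLik")
                   })
  fake <- function(ll, df) structure(list(ll = ll, df = df),
                                     class = "srcscape_fake")
  lr3 <- lr_test(fake(-100, 4), fake(-100 + 30.706 / 2, 7))
  expect_equal(lr3$chisq, 30.706, tolerance = 1e-9)
  expect_equal(lr3$df, 3L)
  expect_equal(lr3$p_value, 9.801e-7, tolerance = 1e-3)
})

test_that("the coordinate LR check flags spatial structure and only that", {
  set.seed(77)
  n <- 400
  coords <- tibble::tibble(x = runif(n), y = runif(n))
  X <- data.frame(a = rnorm(n), b = rnorm(n))

  # strongly x-gradient response: significant coordinate improvement
  yg <- rbinom(n, 1, plogis(4 * scale(coords$x)))
  fitg <- backward_stepwise_logit(cbind(X, y = yg), "y",
                                  predictors = c("a", "b"))
  spg <- spatial_autocorrelation_check(fitg, coords)
  expect_equal(spg$lr$df, 2L)
  expect_lt(spg$lr$p_value, 1e-6)
  exg <- spatial_autocorrelation_check(fitg, coords,
                                       include_interaction = TRUE)
  expect_equal(exg$lr$df, 3L)
  expect_gte(exg$lr$chisq, 0)

  # covariate-only responses: the check stays quiet in >= 90% of nulls
  rejections <- 0
  for (rep in 1:100) {
    y0 <- rbinom(n, 1, plogis(0.8 * X$a))
    f0 <- backward_stepwise_logit(cbind(X, y = y0), "y",
                                  predictors = c("a", "b"))
    p <- spatial_autocorrelation_check(f0, coords)$lr$p_value
    rejections <- rejections + (p < 0.05)
  }
  expect_gte(100 - rejections, 90)
})
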