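# site-pair table from an explicit generating transform of one predictor
gdm_scenario <- function(seed, n = 70, alpha = 0.1,
                         f = function(x) 1.2 * (x / 10)^2) {
  set.seed(seed)
  cells <- sprintf("%d:%d", seq_len(n), 0L)
  env <- data.frame(cell_id = cells, x1 = runif(n, 0, 10),
                    x2 = runif(n, 0, 10), x3 = runif(n, 0, 10))
  ij <- t(utils::combn(n, 2))
  d <- 1 - exp(-(alpha + abs(f(env$x1[ij[, 1]]) - f(env$x1[ij[, 2]]))))
  pairs <- data.frame(cell_i = cells[ij[, 1]], cell_j = cells[ij[, 2]],
                      dissimilarity = d, distance_km = 0)
  for (v in c("x1", "x2", "x3")) {
    pairs[[paste0("s1.", v)]] <- env[[v]][ij[, 1]]
    pairs[[paste0("s2.", v)]] <- env[[v]][ij[, 2]]
  }
  attr(pairs, "predictors") <- c("x1", "x2", "x3")
  class(pairs) <- c("site_pair_table", "data.frame")
  list(pairs = pairs, env = env, f = f)
}

test_that("ispline basis: endpoints, monotonicity, partition at the knots", {
  kn <- c(0, 3, 10)
  expect_equal(ispline_basis(0, kn), cbind(b1 = 0, b2 = 0, b3 = 0))
  expect_equal(ispline_basis(10, kn), cbind(b1 = 1, b2 = 1, b3 = 1))
  g <- seq(0, 10, length.out = 400)
  B <- ispline_basis(g, kn)
  expect_true(all(diff(B[, 1]) >= -1e-12))
  expect_true(all(diff(B[, 2]) >= -1e-12))
  expect_true(all(diff(B[, 3]) >= -1e-12))
  expect_true(all(B >= 0 & B <= 1))
  # values outside the span are clamped
  expect_equal(ispline_basis(c(-5, 15), kn),
               ispline_basis(c(0, 10), kn))
  expect_error(ispline_basis(1, c(2, 2, 2)), "degenerate")
})

test_that("nnls_solve matches lm on the unconstrained-optimum case", {
  set.seed(11)
  A <- matrix(rnorm(200), 50, 4)
  xtrue <- c(1, 2, 0.5, 3)
  b <- A %*% xtrue + rnorm(50, 0, 0.01)
  ls <- qr.coef(qr(A), b)
  expect_true(all(ls > 0))                  # interior optimum
  expect_equal(nnls_solve(A, b), as.numeric(ls), tolerance = 1e-8)
  # active constraints: solution never negative, residual no worse than 0
  b2 <- -A[, 1] + rnorm(50, 0, 0.01)
  x2 <- nnls_solve(A, b2)
  expect_true(all(x2 >= 0))
  expect_lte(sum((A %*% x2 - b2)^2), sum(b2^2) + 1e-9)
})

test_that("build_site_pairs enumerates, subsamples reproducibly", {
  pam <- pam_from_lists(c("0:0", "1:0", "2:0"),
                        list(c("A a", "B b"), c("A a", "B b"),
                             c("C c", "D d")))
  env <- data.frame(cell_id = pam$cells, x = c(1, 1, 5))
  sp <- build_site_pairs(pam, env)
  expect_equal(nrow(sp), 3)                 # 3 cells -> 3 pairs
  ident <- sp[sp$cell_i == "0:0" & sp$cell_j == "1:0", ]
  expect_equal(ident$dissimilarity, 0)      # identical cells
  # seeded subsample reproducibility
  pam2 <- pam_from_lists(sprintf("%d:0", 1:30),
                         lapply(1:30, function(i)
                           sprintf("S s%d", sample(20, 5))))
  env2 <- data.frame(cell_id = pam2$cells, x = rnorm(30))
  a <- build_site_pairs(pam2, env2, max_pairs = 50, seed = 3)
  b <- build_site_pairs(pam2, env2, max_pairs = 50, seed = 3)
  expect_identical(a, b)
  expect_equal(nrow(a), 50)
})

test_that("fit_gdm degenerate cases collapse as they should", {
  sc <- gdm_scenario(13, n = 40)
  # all dissimilarities zero -> intercept and coefficients -> 0
  p0 <- sc$pairs; p0$dissimilarity <- 0
  f0 <- fit_gdm(p0)
  expect_lt(f0$intercept, 1e-6)
  expect_lt(sum(unlist(f0$coefficients)), 1e-6)
  expect_true(all(f0$fitted < 1e-6))
  # zero environmental contrast -> only the intercept can act
  pc <- sc$pairs
  for (v in c("x1", "x2", "x3")) {
    pc[[paste0("s1.", v)]] <- 5; pc[[paste0("s2.", v)]] <- 5
  }
  pc$dissimilarity <- 0.4
  fc <- fit_gdm(pc)
  expect_lt(sum(unlist(fc$coefficients)), 1e-8)
  expect_equal(1 - exp(-fc$intercept), 0.4, tolerance = 1e-6)
  expect_error(fit_gdm(sc$pairs[1:10, ]), "30 site pairs")
})

test_that("fit_gdm recovers a known monotone transform", {
  sc <- gdm_scenario(17)
  fit <- fit_gdm(sc$pairs)
  imp <- predictor_importance(fit)
  expect_equal(imp$predictor[1], "x1")      # driver ranked first
  # fitted transform within 10% RMS of truth (relative to its range)
  g <- seq(0, 10, length.out = 60)
  truth <- sc$f(g) - sc$f(0)
  est <- gdm_transform(fit, "x1", g)
  rms <- sqrt(mean((est - truth)^2)) / diff(range(truth))
  expect_lt(rms, 0.10)
  # fitted dissimilarities live in [0, 1)
  expect_true(all(fit$fitted >= 0 & fit$fitted < 1))
  # deviance explained in [0, 100] and high for a noiseless construction
  expect_gt(fit$deviance_explained, 90)
  expect_lte(fit$deviance_explained, 100)
})

test_that("gdm invariants: monotone transforms, deviance monotone in terms", {
  sc <- gdm_scenario(19, n = 50)
  # mild noise so the fit is not exact
  set.seed(19)
  pr <- sc$pairs
  pr$dissimilarity <- pmin(0.999, pmax(0, pr$dissimilarity +
                                         rnorm(nrow(pr), 0, 0.03)))
  f1 <- fit_gdm(pr, predictors = "x1")
  f13 <- fit_gdm(pr, predictors = c("x1", "x3"))
  expect_gte(f13$deviance_explained, f1$deviance_explained - 1e-6)
  for (v in c("x1", "x3")) {
    tr <- gdm_transform(f13, v, seq(0, 10, length.out = 100))
    expect_true(all(diff(tr) >= -1e-12))
  }
  # predicted dissimilarity nondecreasing in the x1 contrast
  base <- ispline_basis(5, f1$knots$x1)
  etas <- sapply(seq(5, 10, length.out = 20), function(x2v) {
    db <- abs(ispline_basis(x2v, f1$knots$x1) - base)
    f1$intercept + sum(db * f1$coefficients$x1)
  })
  expect_true(all(diff(1 - exp(-etas)) >= -1e-12))
})

test_that("importance heights: zero for unused, equivariant, driver wins", {
  sc <- gdm_scenario(23)
  fit <- fit_gdm(sc$pairs)
  imp <- predictor_importance(fit)
  h <- setNames(imp$height, imp$predictor)
  expect_equal(h[["x1"]], sum(fit$coefficients$x1))
  expect_gt(h[["x1"]], max(h[["x2"]], h[["x3"]]))
  # reordering predictors permutes heights
  fit2 <- fit_gdm(sc$pairs, predictors = c("x3", "x1", "x2"))
  imp2 <- predictor_importance(fit2)
  expect_equal(imp2$height[imp2$predictor == "x1"], h[["x1"]],
               tolerance = 1e-6)
  # driver ranked first across seeds
  firsts <- vapply(1:8, function(s) {
    predictor_importance(fit_gdm(gdm_scenario(100 + s, n = 50)$pairs)
    )$predictor[1]
  }, "")
  expect_gte(mean(firsts == "x1"), 0.9)
})

test_that("transform_and_map separates environmental regimes as colors", {
  # two regimes in x1; x2/x3 pure noise
  sc <- gdm_scenario(29, n = 60)
  fit <- fit_gdm(sc$pairs)
  env <- sc$env
  rgbm <- suppressWarnings(transform_and_map(fit, env))
  expect_true(all(rgbm$R >= 0 & rgbm$R <= 255))
  lowx <- env$x1 < 3; highx <- env$x1 > 7
  within_lo <- mean(dist(rgbm$R[lowx]))
  between <- mean(abs(outer(rgbm$R[lowx], rgbm$R[highx], "-")))
  expect_gt(between, within_lo)
  # identical cells everywhere -> a single color
  env1 <- env; env1$x1 <- 5; env1$x2 <- 1; env1$x3 <- 2
  expect_warning(m1 <- transform_and_map(fit, env1), "zero-padded")
  expect_equal(length(unique(paste(m1$R, m1$G, m1$B))), 1L)
  # PCA scores match an eigen-decomposition oracle up to sign
  keep <- predictor_importance(fit)
  keep <- keep$predictor[keep$retained]
  tx <- sapply(keep, function(v) gdm_transform(fit, v, env[[v]]))
  tx <- scale(tx, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(tx) / (nrow(tx) - 1))
  sc1 <- tx %*% ev$vectors[, 1]
  got <- attr(rgbm, "scores")[, 1]
  expect_gt(abs(cor(sc1, got)), 1 - 1e-9)
})
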