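test_that("K = 1 recovers the closed-form Gaussian MLE exactly", {
  set.seed(5)
  pts <- cbind(rnorm(120, 2), rnorm(120, -1, 2))
  fit <- fit_em(pts, 1, seed = 9)
  mle_cov <- crossprod(sweep(pts, 2, colMeans(pts))) / nrow(pts)
  expect_equal(fit$means[, 1], unname(colMeans(pts)), tolerance = 1e-12)
  expect_equal(fit$covariances[, , 1], unname(mle_cov), tolerance = 1e-12)
  expect_equal(fit$proportions, 1)
})

test_that("EM log-likelihood is non-decreasing on varied inputs", {
  for (s in 1:10) {
    set.seed(s)
    n1 <- sample(30:120, 1)
    n2 <- sample(30:120, 1)
    pts <- rbind(cbind(rnorm(n1), rnorm(n1)),
                 cbind(rnorm(n2, s %% 4), rnorm(n2, 1)))
    for (K in 2:3) {
      fit <- fit_em(pts, K, seed = s + 100)
      expect_true(all(diff(fit$loglik_trace) >= -1e-8),
                  label = paste("monotone trace, seed", s, "K", K))
    }
  }
})

test_that("fit invariants hold: proportions, responsibilities, covariances, labels", {
  set.seed(17)
  pts <- rbind(cbind(rnorm(150), rnorm(150)), cbind(rnorm(150, 5), rnorm(150, 5)))
  for (family in c("free_full", "free_volume_common_shape")) {
    fit <- fit_em(pts, 3, family = family, seed = 21)
    expect_equal(sum(fit$proportions), 1, tolerance = 1e-9)
    expect_equal(rowSums(fit$responsibilities), rep(1, nrow(pts)),
                 tolerance = 1e-9)
    for (k in 1:3) {
      S <- fit$covariances[, , k]
      expect_equal(S[1, 2], S[2, 1])
      expect_gt(det(S), 0)
    }
    expect_identical(fit$labels,
                     max.col(fit$responsibilities, ties.method = "first"))
  }
})

test_that("well-separated cluster centers are recovered", {
  set.seed(33)
  pts <- rbind(cbind(rnorm(200), rnorm(200)),
               cbind(rnorm(200, 10), rnorm(200, 10)))
  fit <- fit_em(pts, 2, seed = 4)
  centers <- t(fit$means)[order(fit$means[1, ]), ]
  expect_true(all(abs(centers[1, ] - c(0, 0)) < 0.2))
  expect_true(all(abs(centers[2, ] - c(10, 10)) < 0.2))
})

test_that("BIC follows -2L + nu log N with the family's parameter count", {
  set.seed(2)
  pts <- cbind(rnorm(100), rnorm(100))
  f1 <- fit_em(pts, 1, seed = 1)
  expect_equal(f1$bic, -2 * f1$log_likelihood + 5 * log(100), tolerance = 1e-12)
  f2 <- fit_em(rbind(pts, pts + 8), 2, seed = 1)
  expect_equal(f2$bic, -2 * f2$log_likelihood + 11 * log(200), tolerance = 1e-12)
  expect_error(score_bic(f1, 1), "N >= 2")
})

test_that("BIC at K = 1 matches a by-hand density computation on 10 points", {
  set.seed(8)
  pts <- cbind(rnorm(10), rnorm(10))
  fit <- fit_em(pts, 1, seed = 2)
  mu <- colMeans(pts)
  S <- crossprod(sweep(pts, 2, mu)) / 10
  Sinv <- solve(S)
  ll <- sum(apply(pts, 1, function(x) {
    d <- x - mu
    -log(2 * pi) - 0.5 * log(det(S)) - 0.5 * drop(t(d) %*% Sinv %*% d)
  }))
  expect_equal(fit$log_likelihood, ll, tolerance = 1e-10)
  expect_equal(fit$bic, -2 * ll + 5 * log(10), tolerance = 1e-8)
})

test_that("ICL equals BIC at zero assignment entropy", {
  set.seed(3)
  pts <- cbind(rnorm(80), rnorm(80))
  f1 <- fit_em(pts, 1, seed = 1)
  expect_identical(f1$icl, f1$bic)
  # far-separated clusters: responsibilities are effectively 0/1
  far <- rbind(pts, pts + 100)
  f2 <- fit_em(far, 2, seed = 5)
  expect_equal(f2$icl, f2$bic, tolerance = 1e-6)
})

test_that("uniform responsibilities give the maximal-entropy ICL penalty", {
  fake <- structure(
    list(K = 2L, family = "free_full", log_likelihood = -100,
         responsibilities = matrix(0.5, 50, 2)),
    class = "gmm_fit")
  expect_equal(score_icl(fake, 50) - score_bic(fake, 50), 2 * 50 * log(2),
               tolerance = 1e-12)
})

test_that("ICL and BIC are invariant under component relabeling", {
  set.seed(6)
  pts <- rbind(cbind(rnorm(100), rnorm(100)), cbind(rnorm(100, 6), rnorm(100)))
  fit <- fit_em(pts, 2, seed = 11)
  perm <- fit
  perm$proportions <- rev(fit$proportions)
  perm$means <- fit$means[, 2:1]
  perm$covariances <- fit$covariances[, , 2:1]
  perm$responsibilities <- fit$responsibilities[, 2:1]
  expect_equal(score_bic(perm, 200), score_bic(fit, 200))
  expect_equal(score_icl(perm, 200), score_icl(fit, 200), tolerance = 1e-12)
})

test_that("select_components honours the feasibility bound at tiny N", {
  pts <- cbind(c(0, 1), c(0, 1.5))
  fit <- select_components(pts, K_max = 5, seed = 1)
  expect_identical(fit$K, 1L)
})

test_that("select_components agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC   # Mclust looks it up in the caller
  set.seed(12)
  pts <- rbind(cbind(rnorm(200), rnorm(200)),
               cbind(rnorm(200, 8), rnorm(200, 8)))
  ours <- select_components(pts, K_max = 3, seed = 3)
  ref <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_identical(ours$K, 2L)
  # both reach the same global optimum on well-separated data
  expect_equal(ours$log_likelihood, ref$loglik, tolerance = 1e-4)
})

test_that("tidy and glance summarise a fit", {
  set.seed(14)
  pts <- rbind(cbind(rnorm(60), rnorm(60)), cbind(rnorm(60, 9), rnorm(60, 9)))
  fit <- select_components(pts, seed = 2)
  td <- tidy(fit)
  expect_identical(nrow(td), fit$K)
  expect_equal(sum(td$size), 120L)
  gl <- glance(fit)
  expect_identical(gl$K, fit$K)
  expect_true(gl$icl >= gl$bic - 1e-9)
})
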