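rand_problem <- function(n, p, seed, latent = 3, noise = 0.3) {
  set.seed(seed)
  Tm <- matrix(rnorm(n * latent), n)
  P <- matrix(rnorm(p * latent), p)
  X <- Tm %*% t(P) + matrix(rnorm(n * p, sd = 0.2), n)
  y <- Tm %*% rnorm(latent) + rnorm(n, sd = noise)
  list(X = X, y = as.numeric(y))
}

test_that("a noiseless single-latent-direction response is fit exactly", {
  set.seed(21)
  t_ <- rnorm(20)
  X <- t_ %*% t(rnorm(15))                 # rank-1 descriptor matrix
  y <- 2.5 * t_ + 1
  fit <- fit_pls(X, y, 1)
  expect_equal(fit$r2_ncv, 1, tolerance = 1e-10)
  expect_lt(fit$SEE, 1e-8)
  expect_equal(predict(fit, X), y, tolerance = 1e-8)
})

test_that("coefficients match an independent PLS implementation", {
  pr <- rand_problem(15, 40, seed = 22)
  colnames(pr$X) <- paste0("v", seq_len(ncol(pr$X)))
  for (nc in c(2, 3, 5)) {
    fit <- fit_pls(pr$X, pr$y, nc)
    ref <- mixOmics::pls(pr$X, pr$y, ncomp = nc, mode = "regression",
                         scale = FALSE)
    B <- predict(ref, pr$X)$B.hat[, 1, nc]
    expect_lt(max(abs(fit$coefficients - B)), 1e-6)
  }
})

test_that("degenerate fits are rejected", {
  pr <- rand_problem(10, 8, seed = 23)
  expect_error(fit_pls(pr$X, rep(1, 10), 2), "zero variance")
  expect_error(fit_pls(pr$X, pr$y, 10), "exceeds")
  expect_error(fit_pls(pr$X, pr$y, 0), ">= 1")
})

test_that("fast LOO path is identical to naive refitting", {
  for (seed in c(31, 32)) {
    pr <- rand_problem(12, 25, seed = seed)
    for (nc in 1:4) {
      fast <- loo_q2(pr$X, pr$y, nc, method = "fast")
      naive <- loo_q2(pr$X, pr$y, nc, method = "naive")
      expect_lt(max(abs(fast$pred - naive$pred)), 1e-8)
      expect_equal(fast$q2, naive$q2, tolerance = 1e-8)
    }
  }
})

test_that("q2 behaves at the limits and under affine response rescaling", {
  set.seed(24)
  t_ <- rnorm(15)
  X <- cbind(t_ %*% t(rnorm(10)))
  y <- 3 * t_ + 0.5
  expect_gt(loo_q2(X, y, 1)$q2, 0.999)     # perfect-model limit
  pr <- rand_problem(14, 20, seed = 25)
  base <- loo_q2(pr$X, pr$y, 3)
  resc <- loo_q2(pr$X, -2.7 * pr$y + 11, 3)
  expect_equal(resc$q2, base$q2, tolerance = 1e-10)
  # PRESS from cross-validation never beats the full-fit residual SS
  fit <- fit_pls(pr$X, pr$y, 3)
  expect_gte(base$PRESS, sum(fit$residuals^2) - 1e-12)
})

test_that("statistics are invariant to the ordering of samples", {
  pr <- rand_problem(13, 18, seed = 26)
  perm <- sample(13)
  f1 <- fit_pls(pr$X, pr$y, 3)
  f2 <- fit_pls(pr$X[perm, ], pr$y[perm], 3)
  expect_lt(abs(f1$r2_ncv - f2$r2_ncv), 1e-10)
  expect_lt(abs(f1$F - f2$F), 1e-8)
  expect_lt(abs(loo_q2(pr$X, pr$y, 2)$q2 -
                loo_q2(pr$X[perm, ], pr$y[perm], 2)$q2), 1e-10)
})

test_that("component selection maximises q2 with ties to smaller N", {
  pr <- rand_problem(16, 20, seed = 27)
  sel <- select_components(pr$X, pr$y, max_N = 6)
  prof <- sel$profile
  expect_equal(sel$q2, max(prof$q2))
  expect_equal(sel$n_components, prof$N[which.max(prof$q2)])
  # planted 3-factor structure: three orthogonal latent directions of
  # clearly different X-variance all feed y, so the LOO q2 profile peaks
  # at exactly 3 components
  hits <- 0
  n <- 80; p <- 30
  for (s in 1:50) {
    set.seed(100 + s)
    Tm <- qr.Q(qr(matrix(rnorm(n * 3), n)))
    P <- qr.Q(qr(matrix(rnorm(p * 3), p)))
    X <- Tm %*% (t(P) * c(6, 2.5, 1)) + matrix(rnorm(n * p, sd = 0.002), n)
    y <- as.numeric(Tm %*% c(1, 1, 1)) + rnorm(n, sd = 0.05)
    if (select_components(X, y, max_N = 6)$n_components == 3)
      hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("y-scrambling destroys the cross-validated signal", {
  syn <- generate_toy_set(synthetic_spec(seed = 41))
  bl <- filter_columns(field_blocks(syn$molecules,
                                    fields = c("comsia_E", "comsia_A")))
  X <- assemble_descriptors(bl)$X
  y <- syn$activities$pE
  set.seed(42)
  q2s <- replicate(20, loo_q2(X, sample(y), 2)$q2)
  expect_lt(mean(q2s), 0.2)
  expect_gt(loo_q2(X, y, 2)$q2, 0.5)       # the unscrambled signal is real
})

test_that("field-combination enumeration covers every non-empty subset", {
  syn <- generate_toy_set(synthetic_spec(n_molecules = 12, seed = 43))
  bl <- filter_columns(field_blocks(syn$molecules))
  y <- syn$activities$pE
  comsia <- enumerate_field_models(bl[grep("comsia", names(bl))], y,
                                   max_N = 3, prefix = "CoMSIA-")
  expect_equal(nrow(comsia), 31)
  expect_true(all(!duplicated(comsia$fields)))
  comfa <- enumerate_field_models(bl[grep("comfa", names(bl))], y, max_N = 3,
                                  prefix = "CoMFA-")
  expect_equal(nrow(comfa), 3)
  expect_setequal(comfa$fields, c("CoMFA-S", "CoMFA-E", "CoMFA-SE"))
  single <- enumerate_field_models(bl["comsia_E"], y, max_N = 3)
  expect_equal(nrow(single), 1)
  expect_equal(single$pct_E, 100)
})

test_that("field contributions are normalised, symmetric and verifiable", {
  syn <- generate_toy_set(synthetic_spec(n_molecules = 14, seed = 44))
  bl <- filter_columns(field_blocks(syn$molecules,
                                    fields = c("comsia_E", "comsia_H")))
  y <- syn$activities$pE
  fm <- fit_field_model(bl, y, max_N = 3)
  expect_equal(sum(fm$contributions), 1, tolerance = 1e-12)
  expect_true(all(fm$contributions >= 0))
  # independent recomputation from coefficients and column stdevs
  desc <- fm$descriptors
  w <- abs(fm$coefficients) * apply(desc$X, 2, sd)
  oracle <- tapply(w, desc$col_block, sum)
  oracle <- oracle / sum(oracle)
  expect_equal(as.numeric(fm$contributions[names(oracle)]),
               as.numeric(oracle), tolerance = 1e-10)
  # duplicated block in a symmetric role -> 50/50
  dup <- bl["comsia_E"]
  dup$comsia_H <- dup$comsia_E
  dup$comsia_H$kind <- "comsia_H"
  fm2 <- fit_field_model(dup, y, max_N = 2)
  expect_equal(unname(fm2$contributions), c(0.5, 0.5), tolerance = 1e-9)
})
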