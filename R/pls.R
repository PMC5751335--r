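#' Fit a PLS1 regression (NIPALS)
#'
#' Mean-centres X and y (no per-column autoscaling: field columns are kept
#' on their block-scaled energy scale, the CoMFA convention) and extracts
#' `n_components` latent components by the classical NIPALS sequence for a
#' single response. Training-set statistics follow the QSAR conventions:
#' `r2_ncv` is the squared correlation of fitted vs observed (equal to
#' explained variance for a least-squares fit), `SEE =
#' sqrt(RSS / (n - N - 1))`, and `F = (r2/N) / ((1 - r2)/(n - N - 1))`.
#'
#' @param X descriptor matrix (n samples x p columns).
#' @param y response vector (pE units).
#' @param n_components number of latent components N.
#' @return a `qsar_pls` object with coefficients on the scale of the input
#'   `X`, intercept, scores/loadings, fitted values and fit statistics.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (sd(y) == 0) stop("response has zero variance")
  if (n_components < 1L) stop("n_components must be >= 1")
  if (n_components > min(n - 1L, p))
    stop("n_components exceeds min(n - 1, ncol(X))")
  if (n < n_components + 2L)
    stop("need at least n_components + 2 samples")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  cvec <- numeric(n_components)
  Xa <- Xc; ya <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("component ", a, " exceeds the rank of the centred problem")
    w <- w / nw
    t_ <- Xa %*% w
    tt <- sum(t_^2)
    p_ <- crossprod(Xa, t_) / tt
    c_ <- sum(ya * t_) / tt
    W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; cvec[a] <- c_
    Xa <- Xa - tcrossprod(t_, p_)
    ya <- ya - c_ * t_
  }
  beta <- W %*% solve(crossprod(P, W), cvec)
  fitted <- as.numeric(Xc %*% beta) + ym
  rss <- sum((y - fitted)^2)
  tss <- sum((y - ym)^2)
  r2 <- 1 - rss / tss
  dfres <- n - n_components - 1L
  see <- if (dfres > 0) sqrt(rss / dfres) else NA_real_
  f <- if (dfres > 0) (r2 / n_components) / ((1 - r2) / dfres) else NA_real_
  structure(list(n_components = n_components, coefficients = as.numeric(beta),
                 intercept = ym - sum(xm * beta),
                 x_means = xm, y_mean = ym,
                 weights = W, loadings = P, scores = Tm, y_loadings = cvec,
                 fitted = fitted, residuals = y - fitted,
                 r2_ncv = r2, SEE = see, F = f, n = n, p = p,
                 col_sd = apply(X, 2, sd)),
            class = "qsar_pls")
}

#' @export
print.qsar_pls <- function(x, ...) {
  cat(sprintf("<qsar_pls> N = %d, n = %d, p = %d | r2_ncv = %.3f, SEE = %.3f, F = %.1f\n",
              x$n_components, x$n, x$p, x$r2_ncv, x$SEE, x$F))
  if (!is.null(x$q2))
    cat(sprintf("  LOO: q2 = %.3f, SEP = %.3f\n", x$q2, x$SEP))
  invisible(x)
}

#' @export
predict.qsar_pls <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.numeric(newdata %*% object$coefficients) + object$intercept
}

# Leave-one-out predictions by naive refitting (the reference path).
.loo_naive <- function(X, y, n_components) {
  n <- nrow(X)
  vapply(seq_len(n), function(i) {
    fit <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components)
    predict(fit, X[i, , drop = FALSE])
  }, 0)
}

# Gram-matrix (kernel) PLS1: algebraically identical to NIPALS PLS1 but
# works entirely in sample space, so a full LOO costs O(n^3 N) instead of
# O(n^2 p N). This is the fast covariance-based path in the spirit of
# SAMPLS; equivalence with the naive path is enforced by tests.
.loo_fast <- function(X, y, n_components) {
  X <- as.matrix(X); n <- nrow(X)
  K <- tcrossprod(X)                       # raw Gram matrix, computed once
  pred <- numeric(n)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    m <- length(idx)
    Kt <- K[idx, idx]
    rm_ <- rowMeans(Kt); gm <- mean(Kt)
    G <- Kt - outer(rm_, rep(1, m)) - outer(rep(1, m), rm_) + gm
    ytr <- y[idx]; ym <- mean(ytr)
    r <- ytr - ym
    k0 <- K[i, idx]
    g <- k0 - mean(k0) - rm_ + gm        # centred cross-kernel row
    yhat <- ym
    for (a in seq_len(n_components)) {
      nu2 <- as.numeric(crossprod(r, G %*% r))
      if (nu2 < 1e-24) break
      nu <- sqrt(nu2)
      t_ <- as.numeric(G %*% r) / nu
      tt <- sum(t_^2)
      c_ <- sum(r * t_) / tt
      tstar <- sum(g * r) / nu
      yhat <- yhat + c_ * tstar
      Gt <- as.numeric(G %*% t_)
      tGt <- sum(t_ * Gt)
      # deflate the cross-kernel row, then G and r:
      # g' = g - t* (G t)/tt - ((g.t)/tt) t + t* (t'Gt/tt^2) t
      g <- g - tstar * Gt / tt - (sum(g * t_) / tt) * t_ +
        tstar * (tGt / tt^2) * t_
      G <- G - tcrossprod(t_, Gt) / tt - tcrossprod(Gt, t_) / tt +
        (tGt / tt^2) * tcrossprod(t_)
      r <- r - c_ * t_
    }
    pred[i] <- yhat
  }
  pred
}

#' Leave-one-out cross-validation of a PLS model
#'
#' Each sample is predicted from a model fitted without it. `q2 = 1 -
#' PRESS / sum((y - mean(y))^2)` and `SEP = sqrt(PRESS / (n - N - 1))`.
#' The fast path runs PLS in sample (Gram-matrix) space and is exactly
#' equivalent to naive refitting.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param n_components number of components.
#' @param method `"fast"` (Gram-matrix path) or `"naive"` (refit loop).
#' @return list with `q2`, `SEP`, `PRESS`, `pred` (LOO predictions).
#' @export
loo_q2 <- function(X, y, n_components, method = c("fast", "naive")) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("leave-one-out needs at least 3 samples")
  if (sd(y) == 0) stop("response has zero variance")
  if (n_components > min(n - 2L, ncol(X)))
    stop("n_components too large for leave-one-out")
  pred <- switch(method,
                 fast = .loo_fast(X, y, n_components),
                 naive = .loo_naive(X, y, n_components))
  press <- sum((y - pred)^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  dfres <- n - n_components - 1L
  sep <- if (dfres > 0) sqrt(press / dfres) else NA_real_
  list(q2 = q2, SEP = sep, PRESS = press, pred = pred)
}

#' Choose the number of PLS components by LOO q2
#'
#' Scans `N = 1..max_N` (capped by sample size and rank) and returns the N
#' with the highest q2; exact ties go to the smaller N.
#'
#' @param X descriptor matrix.
#' @param y response.
#' @param max_N largest N considered (20 by convention).
#' @param method LOO path, see [loo_q2()].
#' @return list with `n_components`, `q2`, `SEP`, and the full `profile`
#'   data frame (N, q2, SEP).
#' @export
select_components <- function(X, y, max_N = 20, method = "fast") {
  X <- as.matrix(X)
  hi <- min(max_N, nrow(X) - 2L, ncol(X))
  if (hi < 1L) stop("not enough samples/columns to fit any component")
  prof <- data.frame(N = seq_len(hi), q2 = NA_real_, SEP = NA_real_)
  for (k in seq_len(hi)) {
    cv <- tryCatch(loo_q2(X, y, k, method = method), error = function(e) NULL)
    if (is.null(cv)) break
    prof$q2[k] <- cv$q2; prof$SEP[k] <- cv$SEP
  }
  prof <- prof[!is.na(prof$q2), , drop = FALSE]
  best <- which.max(prof$q2)               # first maximum = smallest N
  list(n_components = prof$N[best], q2 = prof$q2[best], SEP = prof$SEP[best],
       profile = prof)
}

#' Per-field contribution fractions of a fitted model
#'
#' Contribution of field b = sum over its columns of |coefficient| x column
#' standard deviation, normalised across fields to sum to 1. Computed on
#' the descriptor matrix actually fed to PLS (i.e. after block scaling).
#'
#' @param model a `qsar_pls` fit.
#' @param col_block character vector assigning each descriptor column to a
#'   field (as returned by [assemble_descriptors()]).
#' @return named numeric vector of fractions summing to 1.
#' @export
field_contributions <- function(model, col_block) {
  if (length(col_block) != model$p)
    stop("col_block length does not match the model's column count")
  w <- abs(model$coefficients) * model$col_sd
  contrib <- tapply(w, factor(col_block, levels = unique(col_block)), sum)
  tot <- sum(contrib)
  if (tot == 0) contrib[] <- 1 / length(contrib) else contrib <- contrib / tot
  as.numeric(contrib) |> setNames(names(contrib))
}

#' Fit the full QSAR model for one field combination
#'
#' Convenience wrapper: assembles descriptors from the given blocks,
#' selects N by LOO q2, fits the final model and attaches q2/SEP and the
#' per-field contributions.
#'
#' @param blocks filtered `qsar_field_block` list.
#' @param y response (pE).
#' @param max_N cap on the component search.
#' @param block_scale see [assemble_descriptors()].
#' @param method LOO path.
#' @return a `qsar_pls` with extra elements `q2`, `SEP`, `contributions`,
#'   `descriptors` (the assembly metadata).
#' @export
fit_field_model <- function(blocks, y, max_N = 20, block_scale = TRUE,
                            method = "fast") {
  desc <- assemble_descriptors(blocks, block_scale = block_scale)
  if (ncol(desc$X) < 1L) stop("no descriptor columns left after filtering")
  sel <- select_components(desc$X, y, max_N = max_N, method = method)
  model <- fit_pls(desc$X, y, sel$n_components)
  model$q2 <- sel$q2; model$SEP <- sel$SEP
  model$q2_profile <- sel$profile
  model$contributions <- field_contributions(model, desc$col_block)
  model$descriptors <- desc
  model
}

# single-letter label for a block kind ("comsia_E" -> "E", comfa too)
.kind_letter <- function(kind) {
  map <- c(comfa_steric = "S", comfa_electrostatic = "E",
           comsia_S = "S", comsia_E = "E", comsia_H = "H",
           comsia_D = "D", comsia_A = "A")
  unname(map[kind])
}

#' Exhaustive model search over field combinations
#'
#' Fits one PLS model per non-empty subset of the supplied field blocks
#' (2^k - 1 models for k fields: 31 for the five CoMSIA fields, 3 for the
#' two CoMFA fields) and tabulates the conventional summary statistics.
#' Errors in individual fits are recorded in the `error` column without
#' aborting the search.
#'
#' @param blocks filtered `qsar_field_block` list (all same molecule set).
#' @param y response (pE).
#' @param max_N,block_scale,method see [fit_field_model()].
#' @param prefix label prefix, e.g. `"CoMSIA-"`.
#' @return data frame with one row per combination: `fields`, `q2`, `N`,
#'   `SEP`, `SEE`, `r2_ncv`, `F`, one `pct_<letter>` column per field, and
#'   `error`; attribute `"models"` holds the fitted models.
#' @export
enumerate_field_models <- function(blocks, y, max_N = 20, block_scale = TRUE,
                                   method = "fast", prefix = "") {
  k <- length(blocks)
  if (k < 1L) stop("need at least one field block")
  letters_ <- vapply(blocks, function(b) .kind_letter(b$kind), "")
  subsets <- unlist(lapply(seq_len(k), function(m)
    combn(k, m, simplify = FALSE)), recursive = FALSE)
  rows <- vector("list", length(subsets))
  models <- vector("list", length(subsets))
  for (s in seq_along(subsets)) {
    sel <- subsets[[s]]
    label <- paste0(prefix, paste(letters_[sel], collapse = ""))
    res <- tryCatch(fit_field_model(blocks[sel], y, max_N = max_N,
                                    block_scale = block_scale,
                                    method = method),
                    error = function(e) e)
    if (inherits(res, "error")) {
      rows[[s]] <- data.frame(fields = label, q2 = NA, N = NA, SEP = NA,
                              SEE = NA, r2_ncv = NA, F = NA,
                              error = conditionMessage(res))
    } else {
      models[[s]] <- res
      pct <- setNames(rep(NA_real_, k), letters_)
      pct[letters_[sel]] <- 100 * res$contributions
      row <- data.frame(fields = label, q2 = res$q2, N = res$n_components,
                        SEP = res$SEP, SEE = res$SEE, r2_ncv = res$r2_ncv,
                        F = res$F, error = NA_character_)
      for (L in letters_) row[[paste0("pct_", L)]] <- unname(pct[L])
      rows[[s]] <- row
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    for (L in letters_)
      if (is.null(r[[paste0("pct_", L)]])) r[[paste0("pct_", L)]] <- NA_real_
    r
  }))
  rownames(out) <- NULL
  names(models) <- out$fields
  attr(out, "models") <- models
  out
}
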