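#' Standardized effect sizes with AICc all-subsets model selection
#'
#' Fits the full quadratic response surface of a sensitivity (or any
#' response) in the three main predictors -- food-web temperature,
#' self-limitation `lam`, and log10 dispersal ability `ahat` -- after
#' rescaling the mains to z-scores: the nine terms are the three mains,
#' their three pairwise products, and their three squares (products and
#' squares are formed *after* standardization, so the coefficients are
#' standardized effect sizes). All `2^9 = 512` models nested in the full
#' model (intercept always included, no hierarchy constraint) are compared
#' by the corrected Akaike information criterion
#' `AICc = n*log(RSS/n) + 2k + 2k(k+1)/(n-k-1)`, with `k` the number of
#' parameters including the intercept.
#'
#' @param design a data frame with numeric columns `temperature`, `lam`,
#'   `ahat`, and the response column.
#' @param response name of the response column (default `"S"`).
#' @return an object of class `effect_size_table`: `coefficients` (term,
#'   estimate, se, t, p for the full model), `aicc` (one row per candidate:
#'   terms, k, AICc, delta), `best_terms`, `full_model_best`, `n`.
#' @examples
#' d <- data.frame(temperature = runif(40), lam = runif(40), ahat = runif(40))
#' zs <- scale(d)
#' d$S <- 2 * zs[, 1] - zs[, 2] + rnorm(40, 0, 0.01)
#' effect_sizes(d)
#' @export
effect_sizes <- function(design, response = "S") {
  stopifnot(all(c("temperature", "lam", "ahat", response) %in% names(design)))
  y <- design[[response]]
  ok <- !is.na(y)
  y <- y[ok]
  n <- length(y)
  if (n < 11L) stop("need at least 11 rows to fit the 10-parameter full model")
  z <- function(v, name) {
    v <- v[ok]
    s <- stats::sd(v)
    if (is.na(s) || s == 0) stop("predictor '", name, "' does not vary")
    (v - mean(v)) / s
  }
  zT <- z(design$temperature, "temperature")
  zL <- z(design$lam, "lam")
  zA <- z(design$ahat, "ahat")
  X <- cbind(T = zT, lam = zL, ahat = zA,
             `T:lam` = zT * zL, `T:ahat` = zT * zA, `lam:ahat` = zL * zA,
             `T^2` = zT^2, `lam^2` = zL^2, `ahat^2` = zA^2)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("rank-deficient design; collinear terms: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm(y ~ X)
  cf <- summary(fit)$coefficients
  coefficients <- data.frame(term = c("(Intercept)", colnames(X)),
                             estimate = cf[, 1L], se = cf[, 2L],
                             t = cf[, 3L], p = cf[, 4L],
                             row.names = NULL)

  # all-subsets AICc
  nt <- ncol(X)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), nt))
  aicc_rows <- lapply(seq_len(nrow(subsets)), function(i) {
    sel <- as.logical(subsets[i, ])
    k <- sum(sel) + 1L          # + intercept
    if (n - k - 1L <= 0L) {
      warning("candidate with k = ", k, " skipped (n - k - 1 <= 0)")
      return(NULL)
    }
    Xi <- cbind(1, X[, sel, drop = FALSE])
    rss <- sum(stats::lm.fit(Xi, y)$residuals^2)
    # exact fits leave only floating-point dust in the RSS; floor it so
    # such models are compared by parsimony, not by log(dust)
    rss <- max(rss, n * max(mean(y^2), 1) * .Machine$double.eps^1.5)
    data.frame(terms = paste(colnames(X)[sel], collapse = "+"),
               k = k,
               aicc = n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  })
  aicc <- do.call(rbind, aicc_rows)
  aicc$delta <- aicc$aicc - min(aicc$aicc)
  aicc <- aicc[order(aicc$aicc), , drop = FALSE]
  row.names(aicc) <- NULL
  structure(list(coefficients = coefficients, aicc = aicc,
                 best_terms = aicc$terms[1L],
                 full_model_best = aicc$k[1L] == nt + 1L, n = n),
            class = "effect_size_table")
}

#' @export
print.effect_size_table <- function(x, ...) {
  cat(sprintf("standardized effect sizes (n = %d):\n", x$n))
  print(x$coefficients, digits = 3)
  cat(sprintf("AICc-best model: {%s}%s\n", x$best_terms,
              if (x$full_model_best) " (the full model)" else ""))
  invisible(x)
}
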