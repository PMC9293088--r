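#' Screen out highly rank-correlated predictors
#'
#' Computes pairwise Kendall's tau among candidate predictors and, while any
#' pair exceeds the threshold in absolute value, drops the member of the
#' offending pairs with the larger mean absolute tau against all remaining
#' predictors. Constant predictors (tau undefined) are flagged and removed
#' first.
#'
#' @param X data frame of numeric candidate predictors.
#' @param tau_threshold absolute Kendall's tau above which a pair is
#'   considered redundant.
#' @return list with `retained` (column names), `dropped`, and `constant`.
#' @export
kendall_screen <- function(X, tau_threshold = 0.8) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("need at least two predictors")
  if (nrow(X) < 3) stop("need at least three rows")
  const <- names(X)[vapply(X, function(v) stats::sd(v, na.rm = TRUE) == 0,
                           logical(1))]
  if (length(const))
    warning("constant predictor(s) excluded from screening: ",
            paste(const, collapse = ", "))
  keep <- setdiff(names(X), const)
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    tau <- suppressWarnings(
      stats::cor(X[keep], method = "kendall", use = "pairwise"))
    diag(tau) <- 0
    if (max(abs(tau), na.rm = TRUE) <= tau_threshold) break
    offending <- unique(unlist(apply(abs(tau) > tau_threshold, 1, which)))
    cand <- keep[offending]
    mean_tau <- vapply(cand, function(v)
      mean(abs(tau[v, setdiff(keep, v)]), na.rm = TRUE), numeric(1))
    worst <- cand[which.max(mean_tau)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  list(retained = keep, dropped = dropped, constant = const)
}

#' Fit an ordinary linear model with fit diagnostics
#'
#' OLS fit of a response on a predictor table, optionally transforming
#' predictors first (named transforms, e.g. `c(catchment_area = "log",
#' betweenness_directed = "log1p")`; `log1p` is the convention for
#' betweenness, which is exactly zero at leaf nodes). Reports the Gaussian
#' log-likelihood AIC `n*log(2*pi*RSS/n) + n + 2*(k+1)` (identical to R's
#' `AIC()` for `lm` objects), the small-sample AICc, R-squared statistics,
#' the overall F test and per-predictor variance inflation factors.
#'
#' @param y numeric response vector.
#' @param X data frame of predictors (numeric or factor).
#' @param transforms named character vector mapping predictor names to
#'   `"log"`, `"log1p"` or `"sqrt"`.
#' @return object of class `rpg_lm`: list with the underlying `lm` fit and
#'   elements `coefficients`, `n`, `k`, `RSS`, `sigma2`, `AIC`, `AICc`,
#'   `R2`, `R2_adj`, `F`, `df`, `p_value`, `vif`, `transforms`.
#' @export
fit_lm <- function(y, X, transforms = NULL) {
  X <- as.data.frame(X)
  if (!is.null(transforms)) {
    for (v in names(transforms)) {
      if (!v %in% names(X)) stop("transform for unknown predictor: ", v)
      X[[v]] <- switch(transforms[[v]],
                       log = log(X[[v]]),
                       log1p = log1p(X[[v]]),
                       sqrt = sqrt(X[[v]]),
                       stop("unknown transform: ", transforms[[v]]))
    }
  }
  if (length(y) != nrow(X)) stop("response and predictors differ in length")
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  .wrap_lm(fit, transforms)
}

.wrap_lm <- function(fit, transforms = NULL) {
  n <- length(stats::residuals(fit))
  k <- length(stats::coef(fit))
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((fit$model[[1]] - mean(fit$model[[1]]))^2)
  r2 <- 1 - rss / tss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k)
  aic <- n * log(2 * pi * rss / n) + n + 2 * (k + 1)
  aicc <- if (n - k - 2 > 0) aic + 2 * (k + 1) * (k + 2) / (n - k - 2)
          else NA_real_
  Fstat <- if (k > 1) (r2 / (k - 1)) / ((1 - r2) / (n - k)) else NA_real_
  pval <- if (k > 1) stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
          else NA_real_
  X <- fit$model[-1]
  num <- names(X)[vapply(X, is.numeric, logical(1))]
  v <- if (length(num) >= 2) vif(X[num]) else NULL
  structure(list(lm = fit, coefficients = stats::coef(fit), n = n, k = k,
                 RSS = rss, sigma2 = rss / n, AIC = aic, AICc = aicc,
                 R2 = r2, R2_adj = r2_adj, F = Fstat,
                 df = c(k - 1, n - k), p_value = pval, vif = v,
                 transforms = transforms),
            class = "rpg_lm")
}

#' @export
print.rpg_lm <- function(x, ...) {
  cat("linear model:", deparse(stats::formula(x$lm)), "\n")
  cat(sprintf("  n = %d, k = %d, R2 = %.3f, R2_adj = %.3f\n",
              x$n, x$k, x$R2, x$R2_adj))
  cat(sprintf("  AIC = %.2f, AICc = %.2f, F(%d, %d) = %.2f, p = %.3g\n",
              x$AIC, x$AICc, x$df[1], x$df[2], x$F, x$p_value))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Backward stepwise model reduction by AIC
#'
#' Iteratively removes the single term whose removal most decreases AIC
#' until no removal improves it, respecting marginality (main effects are
#' removable only after their interactions). Delegates to [stats::step()].
#' @param fit an `rpg_lm` from [fit_lm()] or a formula-interface `lm`.
#' @return the reduced model as an `rpg_lm`.
#' @export
backward_stepwise <- function(fit) {
  lmfit <- if (inherits(fit, "rpg_lm")) fit$lm else fit
  # refit against a local copy of the model frame so step()'s re-evaluation
  # of the call can always find the data
  dat <- stats::model.frame(lmfit)
  lmfit <- stats::lm(stats::formula(lmfit), data = dat)
  red <- stats::step(lmfit, direction = "backward", trace = 0)
  .wrap_lm(red, if (inherits(fit, "rpg_lm")) fit$transforms else NULL)
}

#' All-subsets model comparison by AICc
#'
#' Fits every subset of the candidate predictors (main effects only,
#' including the intercept-only model) and ranks them by AICc.
#' @param y numeric response.
#' @param X data frame of candidate predictors (at most 15).
#' @return list with `table` (one row per model: `terms`, `k`, `AIC`,
#'   `AICc`, `delta_AICc`, ranked best first) and `best` (the best model as
#'   an `rpg_lm`).
#' @export
all_subsets <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (p > 15) stop("too many predictors for exhaustive enumeration (> 15)")
  rows <- list(); fits <- list()
  for (mask in 0:(2^p - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    f <- if (length(sel)) fit_lm(y, X[sel]) else .wrap_lm(
      stats::lm(.y ~ 1, data = data.frame(.y = y)))
    rows[[mask + 1]] <- data.frame(
      terms = if (length(sel)) paste(names(X)[sel], collapse = " + ")
              else "(intercept only)",
      k = f$k, AIC = f$AIC, AICc = f$AICc, stringsAsFactors = FALSE)
    fits[[mask + 1]] <- f
  }
  tab <- do.call(rbind, rows)
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_AICc <- tab$AICc - tab$AICc[1]
  rownames(tab) <- NULL
  list(table = tab, best = fits[[ord[1]]])
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j`
#' on the remaining predictors; `Inf` under perfect collinearity.
#' @param X data frame of numeric predictors (at least two).
#' @return named numeric vector.
#' @export
vif <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2) stop("VIF needs at least two predictors")
  vapply(names(X), function(j) {
    f <- stats::lm(stats::reformulate(names(X)[names(X) != j], response = j),
                   data = X)
    r2 <- suppressWarnings(summary(f)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Isolation-by-distance power-term scan
#'
#' Fits `fst ~ distance^p * species` for a grid of powers `p` and returns
#' the power minimizing AIC, capturing saturating isolation-by-distance
#' relationships. Negative differentiation values (estimator artefacts) are
#' set to zero before fitting. At `p = 0` the distance term is constant and
#' is dropped (species-only model, or intercept-only without species).
#'
#' @param fst numeric vector of pairwise differentiation values.
#' @param dist numeric vector of instream distances, matched to `fst`.
#' @param species optional factor (pair-level species labels) entering as a
#'   main effect and interaction with the distance term.
#' @param powers grid of exponents to scan.
#' @return list with `best_power`, `best_fit` (`rpg_lm`), and `scan` (data
#'   frame of power vs AIC).
#' @export
power_scan <- function(fst, dist, species = NULL,
                       powers = seq(0, 1, by = 0.01)) {
  if (length(fst) != length(dist)) stop("fst and dist differ in length")
  if (!length(fst)) stop("empty pair set")
  fst <- pmax(fst, 0)
  dat <- data.frame(fst = fst, dist = dist)
  has_sp <- !is.null(species)
  if (has_sp) dat$species <- factor(species)
  aics <- numeric(length(powers))
  fits <- vector("list", length(powers))
  for (i in seq_along(powers)) {
    p <- powers[i]
    if (p == 0) {
      f <- if (has_sp) stats::lm(fst ~ species, data = dat)
           else stats::lm(fst ~ 1, data = dat)
    } else {
      dat$dp <- dat$dist^p
      f <- if (has_sp) stats::lm(fst ~ dp * species, data = dat)
           else stats::lm(fst ~ dp, data = dat)
    }
    w <- .wrap_lm(f)
    aics[i] <- w$AIC
    fits[[i]] <- w
  }
  best <- which.min(aics)
  list(best_power = powers[best], best_fit = fits[[best]],
       scan = data.frame(power = powers, AIC = aics))
}
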