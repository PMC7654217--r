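glm_family <- function(tag) {
  switch(tag,
         continuous = stats::gaussian(),
         count = stats::poisson(),
         binary = stats::binomial(),
         stop2(paste0("unknown family tag: ", tag)))
}

#' Family-dispatched regression of one motor outcome
#'
#' Poisson regression for count outcomes, logistic for binary, ordinary
#' least squares for continuous, via [stats::glm()]. Coefficients are on the
#' per-unit-of-percent scale of the MRI predictors. Rank deficiency and
#' logistic separation are flagged on the result rather than raised.
#'
#' @param data data.frame holding outcome and predictors; rows with missing
#'   values in the used columns are dropped (listwise deletion).
#' @param y outcome column name.
#' @param x_vars predictor column names (may be empty for an intercept-only
#'   fit).
#' @param family family tag: `continuous`, `count` or `binary`.
#' @return object of class `cm_glm_fit`: list with `coefs` (data.frame:
#'   term, estimate, se, p), `family`, `n`, `flags` (character), `fit`.
#' @export
fit_glm <- function(data, y, x_vars = character(0), family = "continuous") {
  used <- c(y, x_vars)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, used, drop = FALSE]
  fml <- stats::as.formula(paste(
    sprintf("`%s`", y), "~",
    if (length(x_vars)) paste(sprintf("`%s`", x_vars), collapse = " + ")
    else "1"))
  flags <- character(0)
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = glm_family(family)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        flags <<- union(flags, "separation")
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", conditionMessage(w))) {
        flags <<- union(flags, "nonconvergence")
        invokeRestart("muffleWarning")
      }
    })
  if (anyNA(stats::coef(fit))) flags <- union(flags, "rank_deficient")
  sm <- summary(fit)$coefficients
  terms_all <- names(stats::coef(fit))
  coefs <- data.frame(term = terms_all,
                      estimate = unname(stats::coef(fit)),
                      se = NA_real_, p = NA_real_)
  present <- match(rownames(sm), terms_all)
  coefs$se[present] <- sm[, 2]
  coefs$p[present] <- sm[, 4]
  structure(list(coefs = coefs, family = family, n = nrow(d),
                 flags = flags, fit = fit),
            class = "cm_glm_fit")
}

#' @export
print.cm_glm_fit <- function(x, ...) {
  cat("<cm_glm_fit> family ", x$family, ", n = ", x$n, sep = "")
  if (length(x$flags)) cat(" [", paste(x$flags, collapse = ", "), "]", sep = "")
  cat("\n")
  print(x$coefs, digits = 4)
  invisible(x)
}

#' Multivariable model over the significant predictors
#'
#' Joint fit of one motor outcome on the MRI variables found individually
#' significant; the adjusted (mutually controlled) estimates are the ones
#' carried into the report.
#'
#' @inheritParams fit_glm
#' @param significant_mri_vars predictor names (>= 1).
#' @return a `cm_glm_fit`.
#' @export
multivariable_model <- function(data, y, significant_mri_vars,
                                family = "continuous") {
  assert_that(length(significant_mri_vars) >= 1,
              "need at least one significant predictor")
  fit_glm(data, y, significant_mri_vars, family)
}

#' Bagged bootstrap regression estimates
#'
#' Fits the model on `B` bootstrap copies of the rows (sampled with
#' replacement) and reports, per coefficient, the ensemble mean as the
#' estimate, the ensemble SD as its SE, and a two-sided p-value from the
#' normal approximation on mean/SD. Degenerate resamples -- rank-deficient
#' designs or a predictor collapsing to a single value -- are redrawn and
#' counted; more than `10 * B` redraws abort with a diagnostic.
#'
#' @inheritParams fit_glm
#' @param B number of bootstrap copies (default 1000, the study's setting).
#' @param seed integer seed; results are fully reproducible.
#' @return object of class `bagged_estimate`: list with `coefs`
#'   (data.frame: term, estimate, se, p), `B`, `n_redraws`, `family`,
#'   `seed`. With `B = 1` the SE and p are reported as `NA`.
#' @export
bagged_fit <- function(data, y, x_vars, family = "continuous", B = 1000L,
                       seed = 1L) {
  assert_that(B >= 1, "B must be at least 1")
  used <- c(y, x_vars)
  cc <- stats::complete.cases(data[, used, drop = FALSE])
  d <- data[cc, used, drop = FALSE]
  n <- nrow(d)
  p <- length(x_vars) + 1L
  assert_that(n >= p + 1, "need more rows than coefficients")
  mm <- cbind(`(Intercept)` = 1,
              as.matrix(d[, x_vars, drop = FALSE]))
  yv <- d[[y]]
  fam <- if (family != "continuous") glm_family(family) else NULL
  set.seed(seed)
  coef_mat <- matrix(NA_real_, nrow = B, ncol = p,
                     dimnames = list(NULL, colnames(mm)))
  n_redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- mm[idx, , drop = FALSE]
      degenerate <- p > 1 &&
        any(apply(Xb[, -1, drop = FALSE], 2,
                  function(v) length(unique(v)) <= 1L))
      cf <- NULL
      if (!degenerate) {
        if (is.null(fam)) {
          ft <- stats::lm.fit(Xb, yv[idx])
          if (ft$rank == p) cf <- ft$coefficients
        } else {
          ft <- tryCatch(
            suppressWarnings(stats::glm.fit(Xb, yv[idx], family = fam)),
            error = function(e) NULL)
          if (!is.null(ft) && ft$rank == p && !anyNA(ft$coefficients)) {
            cf <- ft$coefficients
          }
        }
      }
      if (!is.null(cf)) break
      n_redraws <- n_redraws + 1L
      if (n_redraws > 10L * B) {
        stop2("bagged_fit: exceeded 10*B degenerate bootstrap redraws")
      }
    }
    coef_mat[b, ] <- cf
  }
  est <- colMeans(coef_mat)
  if (B > 1) {
    se <- apply(coef_mat, 2, stats::sd)
    # zero ensemble SD (e.g. noiseless data): the estimate is exact
    pv <- ifelse(se > 0, 2 * stats::pnorm(-abs(est) / se),
                 ifelse(est != 0, 0, 1))
  } else {
    se <- rep(NA_real_, p)
    pv <- rep(NA_real_, p)
  }
  structure(list(coefs = data.frame(term = colnames(mm), estimate = est,
                                    se = se, p = pv, row.names = NULL),
                 B = as.integer(B), n = n, n_redraws = n_redraws,
                 family = family, seed = seed),
            class = "bagged_estimate")
}

#' @export
print.bagged_estimate <- function(x, ...) {
  cat("<bagged_estimate> family ", x$family, ", B = ", x$B, ", n = ", x$n,
      ", redraws = ", x$n_redraws, "\n", sep = "")
  print(x$coefs, digits = 4)
  invisible(x)
}
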