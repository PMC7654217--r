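#' Drop zero-variance columns
#'
#' Variables with a single unique (non-missing) value carry no information
#' and are removed before screening.
#'
#' @param data data.frame.
#' @param cols columns to consider (default: all except `subject_id`).
#' @return list with `data` (reduced), `dropped` (character).
#' @export
drop_zero_variance <- function(data, cols = NULL) {
  if (is.null(cols)) cols <- setdiff(names(data), "subject_id")
  zv <- vapply(cols, function(cn) {
    v <- data[[cn]]
    length(unique(v[!is.na(v)])) <= 1L
  }, TRUE)
  dropped <- cols[zv]
  assert_that(length(dropped) < length(cols),
              "all candidate columns have zero variance")
  list(data = data[, setdiff(names(data), dropped), drop = FALSE],
       dropped = dropped)
}

#' Spearman screening of MRI-motor variable pairs
#'
#' Rank correlation (average ranks on ties) with a two-sided p-value for
#' every (MRI, motor) pair; a pair is flagged `correlated` when both
#' `|rho| >= rho_min` and `p < alpha`. Pairs with fewer than 3 complete
#' observations are undefined and flagged with `NA`.
#'
#' @param data data.frame.
#' @param mri_vars,motor_vars column name vectors.
#' @param alpha screening significance level (default 0.05).
#' @param rho_min minimal absolute correlation deemed non-weak
#'   (default 0.4).
#' @return data.frame: mri, motor, n, rho, p, correlated.
#' @export
spearman_screen <- function(data, mri_vars, motor_vars, alpha = 0.05,
                            rho_min = 0.4) {
  grid <- expand.grid(mri = mri_vars, motor = motor_vars,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    x <- data[[grid$mri[i]]]; y <- data[[grid$motor[i]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3) {
      return(data.frame(mri = grid$mri[i], motor = grid$motor[i], n = n,
                        rho = NA_real_, p = NA_real_, correlated = NA))
    }
    ct <- suppressWarnings(
      stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate)
    data.frame(mri = grid$mri[i], motor = grid$motor[i], n = n, rho = rho,
               p = ct$p.value,
               correlated = abs(rho) >= rho_min & ct$p.value < alpha)
  })
  do.call(rbind, res)
}

#' Boruta all-relevant feature selection
#'
#' Shadow-feature selection against a random-forest importance baseline:
#' at every iteration each predictor is duplicated as a permuted "shadow"
#' copy, a forest of `num_trees` trees is fitted on real plus shadow
#' features, and a real feature scores a hit when its permutation importance
#' exceeds the largest shadow importance. After `n_iter` iterations each
#' feature's hit count is compared with the Binomial(n_iter, 1/2) reference
#' by a two-sided binomial test at `alpha`: significantly more hits than
#' chance confirms the feature, significantly fewer rejects it, anything
#' else stays tentative.
#'
#' @param X data.frame or matrix of predictors (>= 2 columns).
#' @param y response; a factor (or 0/1 with `family = "binary"`) triggers
#'   classification forests, otherwise regression forests.
#' @param family optional tag `continuous`/`count`/`binary` controlling the
#'   forest type; inferred from `y` when NULL.
#' @param n_iter iterations (default 100).
#' @param alpha significance level of the binomial decision test
#'   (default 0.01).
#' @param num_trees forest size per iteration (default 500).
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return list with `decision` (named factor: confirmed/tentative/
#'   rejected), `hits`, `n_iter`, `alpha`.
#' @export
boruta_select <- function(X, y, family = NULL, n_iter = 100L, alpha = 0.01,
                          num_trees = 500L, seed = 1L) {
  X <- as.data.frame(X)
  assert_that(ncol(X) >= 2, "Boruta needs at least 2 features")
  assert_that(nrow(X) >= 5, "Boruta needs at least 5 observations")
  assert_that(length(unique(y)) > 1, "constant response: importance undefined")
  if (is.null(family)) {
    family <- if (is.factor(y) || all(y %in% c(0, 1))) "binary" else "continuous"
  }
  yy <- if (family == "binary") factor(y) else as.numeric(y)
  p <- ncol(X)
  real <- colnames(X)
  hits <- stats::setNames(integer(p), real)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    shadow <- as.data.frame(lapply(X, sample))
    names(shadow) <- paste0("shadow_", real)
    d <- cbind(y = yy, X, shadow)
    fit <- ranger::ranger(dependent.variable.name = "y", data = d,
                          num.trees = num_trees,
                          importance = "permutation", num.threads = 1,
                          seed = sample.int(.Machine$integer.max, 1),
                          probability = FALSE)
    imp <- fit$variable.importance
    # a variable used in no tree has undefined permutation importance
    imp[is.na(imp)] <- 0
    max_shadow <- max(imp[paste0("shadow_", real)])
    hits <- hits + as.integer(imp[real] > max_shadow)
  }
  decide <- function(h) {
    pv <- stats::binom.test(h, n_iter, 0.5)$p.value
    if (pv < alpha && h > n_iter / 2) "confirmed"
    else if (pv < alpha && h < n_iter / 2) "rejected"
    else "tentative"
  }
  decision <- factor(vapply(hits, decide, ""),
                     levels = c("confirmed", "tentative", "rejected"))
  names(decision) <- real
  list(decision = decision, hits = hits, n_iter = n_iter, alpha = alpha)
}

#' Screen a cohort: correlation plus importance
#'
#' Runs [spearman_screen()] over all (MRI, motor) pairs and, optionally,
#' [boruta_select()] of the MRI variables for each motor outcome, and
#' combines both into per-pair `correlated` / `important` flags.
#'
#' @param cohort a `cohort_table` (zero-variance columns should be dropped
#'   first; [build_report()] does this).
#' @param alpha_screen significance level for the correlation flag.
#' @param rho_min minimal non-weak absolute correlation.
#' @param use_boruta run the Boruta importance screen (default TRUE).
#' @param boruta_n_iter,boruta_alpha,num_trees Boruta settings.
#' @param seed integer seed (one deterministic sub-stream per motor
#'   variable).
#' @return object of class `screening_result`: list with `pairs`
#'   (data.frame: mri, motor, n, rho, p, correlated, important), `mri_kept`,
#'   `motor_kept`, `params`.
#' @export
screen_cohort <- function(cohort, alpha_screen = 0.05, rho_min = 0.4,
                          use_boruta = TRUE, boruta_n_iter = 100L,
                          boruta_alpha = 0.01, num_trees = 500L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  pairs <- spearman_screen(cohort$data, cohort$mri_vars, cohort$motor_vars,
                           alpha = alpha_screen, rho_min = rho_min)
  pairs$correlated[is.na(pairs$correlated)] <- FALSE
  pairs$important <- FALSE
  if (use_boruta && length(cohort$mri_vars) >= 2) {
    for (k in seq_along(cohort$motor_vars)) {
      mv <- cohort$motor_vars[k]
      y <- cohort$data[[mv]]
      if (length(unique(y[!is.na(y)])) <= 1) next
      sel <- boruta_select(cohort$data[, cohort$mri_vars, drop = FALSE], y,
                           family = cohort$families[[mv]],
                           n_iter = boruta_n_iter, alpha = boruta_alpha,
                           num_trees = num_trees,
                           seed = substream_seed(seed, k))
      imp <- names(sel$decision)[sel$decision == "confirmed"]
      pairs$important[pairs$motor == mv & pairs$mri %in% imp] <- TRUE
    }
  }
  kept <- retain_variables(list(pairs = pairs))
  structure(list(pairs = pairs, mri_kept = kept$mri_kept,
                 motor_kept = kept$motor_kept,
                 params = list(alpha_screen = alpha_screen,
                               rho_min = rho_min, use_boruta = use_boruta,
                               boruta_n_iter = boruta_n_iter,
                               boruta_alpha = boruta_alpha,
                               num_trees = num_trees, seed = seed)),
            class = "screening_result")
}

#' Variable retention from screening flags
#'
#' An MRI variable is kept iff it is correlated with, or an important
#' predictor of, at least one motor outcome; a motor outcome is kept iff at
#' least one MRI variable is correlated with or important for it.
#'
#' @param screen a `screening_result` (or any list with a `pairs`
#'   data.frame carrying `correlated` and `important` flags).
#' @return list with `mri_kept` and `motor_kept` character vectors.
#' @export
retain_variables <- function(screen) {
  p <- screen$pairs
  flag <- p$correlated | p$important
  list(mri_kept = sort(unique(p$mri[flag])),
       motor_kept = sort(unique(p$motor[flag])))
}
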