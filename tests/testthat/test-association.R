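test_that("zero-variance columns are dropped and logged", {
  d <- data.frame(subject_id = 1:6, a = rep(2, 6), b = c(1, 1, 1, 2, 1, 1),
                  c = rnorm(6))
  dz <- drop_zero_variance(d)
  expect_equal(dz$dropped, "a")
  expect_true(all(c("b", "c") %in% names(dz$data)))
  expect_error(drop_zero_variance(data.frame(a = rep(1, 5), b = rep(2, 5))),
               "all candidate columns")
  # a noise-free cohort with no planted effects is entirely uninformative
  cs <- cohort_spec(n_subjects = 8, null_motor = c(m1 = "linear",
                                                   m2 = "linear"),
                    noise_sd = 0, seed = 2)
  co <- make_cohort(cs)
  dz2 <- drop_zero_variance(co$data, c(co$mri_vars, co$motor_vars))
  expect_setequal(dz2$dropped, c("m1", "m2"))
})

test_that("Spearman screening reproduces hand-computed rank correlations", {
  x <- c(1, 2, 3, 4, 5)
  d <- data.frame(x = x, up = exp(x), down = -x^3,
                  hand_x = c(1, 2, 3, 4, 100), hand_y = c(2, 1, 4, 3, 100))
  sc <- spearman_screen(d, "x", c("up", "down"), alpha = 0.05, rho_min = 0.4)
  expect_equal(sc$rho[sc$motor == "up"], 1)
  expect_equal(sc$rho[sc$motor == "down"], -1)
  # x = (1,2,3,4), y = (2,1,4,3): rho = 1 - 6*4 / (4*15) = 0.6
  sc2 <- spearman_screen(d[1:4, ], "hand_x", "hand_y", alpha = 0.05,
                         rho_min = 0.4)
  expect_equal(sc2$rho, 0.6)
  # fewer than 3 complete pairs is undefined and flagged
  d$short <- c(1, 2, NA, NA, NA)
  sc3 <- spearman_screen(d, "x", "short", alpha = 0.05, rho_min = 0.4)
  expect_true(is.na(sc3$rho))
})

test_that("a duplicated informative feature is not rejected by Boruta", {
  set.seed(3)
  n <- 200
  x1 <- rnorm(n)
  X <- data.frame(x1 = x1, dup = x1, n1 = rnorm(n), n2 = rnorm(n))
  y <- 3 * x1 + rnorm(n, sd = 0.5)
  sel <- boruta_select(X, y, n_iter = 40, seed = 5)
  expect_true(all(sel$decision[c("x1", "dup")] != "rejected"))
  expect_error(boruta_select(X, rep(1, n)), "constant")
})

test_that("variable retention mirrors brute-force set construction", {
  pairs <- expand.grid(mri = paste0("m", 1:4), motor = paste0("y", 1:6),
                       stringsAsFactors = FALSE)
  pairs$correlated <- FALSE
  pairs$important <- FALSE
  ret0 <- retain_variables(list(pairs = pairs))
  expect_length(ret0$mri_kept, 0)
  expect_length(ret0$motor_kept, 0)
  pairs$correlated[pairs$mri == "m1" & pairs$motor == "y3"] <- TRUE
  ret1 <- retain_variables(list(pairs = pairs))
  expect_equal(ret1$mri_kept, "m1")
  expect_equal(ret1$motor_kept, "y3")
  set.seed(11)
  pairs$correlated <- runif(nrow(pairs)) < 0.2
  pairs$important <- runif(nrow(pairs)) < 0.1
  ret2 <- retain_variables(list(pairs = pairs))
  flag <- pairs$correlated | pairs$important
  expect_setequal(ret2$mri_kept, unique(pairs$mri[flag]))
  expect_setequal(ret2$motor_kept, unique(pairs$motor[flag]))
})

test_that("family-dispatched GLMs hit their closed-form solutions", {
  d <- data.frame(y2 = rep(2L, 20), yb = rep(c(0, 1), 10),
                  x = seq(0, 1, length.out = 20))
  f1 <- fit_glm(d, "y2", family = "count")
  expect_equal(f1$coefs$estimate, log(2), tolerance = 1e-8)
  f2 <- fit_glm(d, "yb", family = "binary")
  expect_equal(f2$coefs$estimate, 0, tolerance = 1e-8)
  d$ylin <- 1 + 2 * d$x
  f3 <- fit_glm(d, "ylin", "x", family = "continuous")
  expect_equal(f3$coefs$estimate, c(1, 2), tolerance = 1e-10)
})

test_that("rank deficiency and separation are flagged, not fatal", {
  set.seed(1)
  d <- data.frame(x = rnorm(20))
  d$x2 <- d$x                      # exact duplicate
  d$y <- 1 + d$x + rnorm(20, sd = 0.1)
  f <- fit_glm(d, "y", c("x", "x2"), family = "continuous")
  expect_true("rank_deficient" %in% f$flags)
  d$yb <- as.integer(d$x > 0)      # perfectly separated
  fb <- fit_glm(d, "yb", "x", family = "binary")
  expect_true("separation" %in% fb$flags)
})

test_that("multivariable fits recover orthogonal planted slopes", {
  d <- data.frame(x1 = rep(c(-1, 1), each = 8), x2 = rep(c(-1, 1), 8))
  d$y <- 2 + 0.5 * d$x1 - 1.5 * d$x2
  mm <- multivariable_model(d, "y", c("x1", "x2"))
  expect_equal(mm$coefs$estimate, c(2, 0.5, -1.5), tolerance = 1e-10)
  u <- fit_glm(d, "y", "x1")
  m1 <- multivariable_model(d, "y", "x1")
  expect_equal(m1$coefs, u$coefs)
  expect_error(multivariable_model(d, "y", character(0)), "at least one")
})

test_that("bagged estimates collapse to the exact fit on noiseless data", {
  d <- data.frame(x = seq_len(12))
  d$y <- 1 + 2 * d$x
  bf <- bagged_fit(d, "y", "x", B = 100, seed = 3)
  expect_equal(bf$coefs$estimate, c(1, 2), tolerance = 1e-8)
  expect_lt(max(bf$coefs$se), 1e-8)
  b1 <- bagged_fit(d, "y", "x", B = 1, seed = 3)
  expect_true(all(is.na(b1$coefs$se)))
  expect_equal(b1$coefs$estimate, c(1, 2), tolerance = 1e-8)
})

test_that("bagging is seed-reproducible and converges to the full-data fit", {
  set.seed(20)
  d <- data.frame(x = runif(50, 0, 100))
  d$y <- 5 - 0.03 * d$x + rnorm(50, sd = 1)
  b1 <- bagged_fit(d, "y", "x", B = 400, seed = 9)
  b2 <- bagged_fit(d, "y", "x", B = 400, seed = 9)
  expect_identical(b1$coefs, b2$coefs)
  full <- fit_glm(d, "y", "x")
  expect_lt(abs(b1$coefs$estimate[2] - full$coefs$estimate[2]),
            2 * b1$coefs$se[2])
  # Poisson bagging keeps the family under the bootstrap
  d$cnt <- rpois(50, exp(1 - 0.01 * d$x))
  bp <- bagged_fit(d, "cnt", "x", family = "count", B = 200, seed = 4)
  fp <- fit_glm(d, "cnt", "x", family = "count")
  expect_lt(abs(bp$coefs$estimate[2] - fp$coefs$estimate[2]),
            2 * bp$coefs$se[2])
})

test_that("the report pipeline recovers strong planted effects end to end", {
  cs <- cohort_spec(
    n_subjects = 13,
    effect_map = list(
      list(mri = "mri_total", motor = "motor_a", effect = -0.9,
           family = "linear"),
      list(mri = "mri_right", motor = "motor_b", effect = 0.65,
           family = "linear")),
    intercepts = c(motor_a = 80, motor_b = 20),
    noise_sd = c(motor_a = 5, motor_b = 4),
    null_motor = c(motor_c = "linear"),
    seed = 5)
  co <- make_cohort(cs)
  rep <- build_report(co, B = 300, seed = 21)
  key <- paste(rep$significant$motor, rep$significant$mri)
  expect_true("motor_a mri_total" %in% key)
  expect_true("motor_b mri_right" %in% key)
  est_a <- rep$significant$adj_estimate[key == "motor_a mri_total"]
  expect_lt(abs(est_a - (-0.9)), 3 * rep$significant$adj_se[key == "motor_a mri_total"])
  # provenance records the governing settings
  expect_equal(rep$provenance$B, 300)
  expect_equal(rep$provenance$seed, 21)
})

test_that("reports with no signal have an empty significant table", {
  cs <- cohort_spec(n_subjects = 13,
                    null_motor = c(m1 = "linear", m2 = "linear"), seed = 31)
  co <- make_cohort(cs)
  rep <- build_report(co, use_boruta = FALSE, alpha_screen = 0.001,
                      B = 100, seed = 2)
  expect_equal(nrow(rep$significant), 0)
  expect_true(is.data.frame(rep$full))
})

test_that("report tables round-trip through CSV losslessly", {
  cs <- cohort_spec(
    n_subjects = 13,
    effect_map = list(list(mri = "mri_total", motor = "motor_a",
                           effect = -0.9, family = "linear")),
    intercepts = c(motor_a = 80), noise_sd = c(motor_a = 5), seed = 5)
  rep <- build_report(make_cohort(cs), use_boruta = FALSE, B = 200, seed = 3)
  dir <- withr::local_tempdir()
  write_report(rep, dir)
  back <- read_report_significant(dir)
  expect_equal(back$adj_estimate, rep$significant$adj_estimate,
               tolerance = 1e-12)
  expect_equal(back$motor, rep$significant$motor)
})

test_that("cohort tables round-trip through CSV with their family sidecar", {
  cs <- cohort_spec(n_subjects = 10,
                    null_motor = c(mc = "poisson", mb = "logistic",
                                   ml = "linear"), seed = 6)
  co <- make_cohort(cs)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(co, path)
  co2 <- read_cohort_csv(path)
  expect_equal(co2$data[co2$motor_vars], co$data[co$motor_vars])
  expect_equal(co2$families, co$families)
  # declared invariants are enforced on assembly
  bad <- co$data; bad$mc <- bad$mc + 0.5
  expect_error(cohort_table(bad, co$families, co$mri_vars, co$motor_vars),
               "nonnegative integers")
})
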