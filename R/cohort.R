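#' Specification for a synthetic subject cohort
#'
#' Describes a cohort table of MRI spared-tissue percentages and motor
#' outcomes with planted effects: each motor outcome is generated from a
#' generalized linear model on the MRI variables (identity, log or logit
#' link), so downstream screening and regression can be checked against
#' known coefficients.
#'
#' @param n_subjects number of subjects (>= 3; the study scale is 13).
#' @param effect_map list of planted effects, each
#'   `list(mri = "mri_total", motor = "motor_x", effect = -0.02,
#'   family = "linear")` with family one of `"linear"`, `"poisson"`,
#'   `"logistic"`. Several effects may target one motor variable (additive
#'   on the link scale); all effects on a motor variable must share its
#'   family.
#' @param intercepts named numeric, link-scale intercept per motor variable
#'   (default 0).
#' @param noise_sd named numeric (or scalar), Gaussian noise SD for linear
#'   motor variables (default 1); ignored for Poisson/logistic, whose noise
#'   is the sampling distribution itself.
#' @param null_motor named character vector adding motor variables with no
#'   planted effect, e.g. `c(motor_tasks = "poisson")`.
#' @param mri_vars names of the MRI percent variables, drawn independently
#'   uniform on [0, 100].
#' @param seed integer seed; generation is reproducible per column (adding a
#'   motor variable does not perturb the others).
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13L, effect_map = list(),
                        intercepts = numeric(0), noise_sd = 1,
                        null_motor = character(0),
                        mri_vars = c("mri_total", "mri_anterior",
                                     "mri_posterior", "mri_left",
                                     "mri_right"),
                        seed = 1L) {
  assert_that(n_subjects >= 3, "need at least 3 subjects")
  fams <- c("linear", "poisson", "logistic")
  motor_family <- character(0)
  for (ef in effect_map) {
    assert_that(all(c("mri", "motor", "effect", "family") %in% names(ef)),
                "each effect needs mri, motor, effect, family")
    assert_that(ef$family %in% fams,
                paste0("unknown family: ", ef$family))
    assert_that(is.finite(ef$effect), "effect sizes must be finite")
    assert_that(ef$mri %in% mri_vars, paste0("unknown MRI variable: ", ef$mri))
    if (ef$motor %in% names(motor_family)) {
      assert_that(motor_family[[ef$motor]] == ef$family,
                  "conflicting families for one motor variable")
    } else {
      motor_family[ef$motor] <- ef$family
    }
  }
  for (nm in names(null_motor)) {
    assert_that(null_motor[[nm]] %in% fams,
                paste0("unknown family: ", null_motor[[nm]]))
    assert_that(!(nm %in% names(motor_family)),
                "null_motor name collides with an effect_map motor variable")
    motor_family[nm] <- null_motor[[nm]]
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 effect_map = effect_map, intercepts = intercepts,
                 noise_sd = noise_sd, motor_family = motor_family,
                 mri_vars = mri_vars, seed = as.integer(seed)),
            class = "cohort_spec")
}

family_tag <- function(family) {
  c(linear = "continuous", poisson = "count", logistic = "binary")[[family]]
}

#' Generate a synthetic cohort table
#'
#' MRI variables are drawn uniform on the 0-100 percent scale; each motor
#' variable is generated from its declared family with the planted link-scale
#' coefficients and, for linear variables, additive Gaussian noise.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort_table`: list with `data` (data.frame, `subject_id` +
#'   MRI + motor columns), `families` (named tags `continuous`/`count`/
#'   `binary` per motor column), `mri_vars`, `motor_vars`, `truth` (planted
#'   coefficients), `spec`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  set.seed(substream_seed(spec$seed, 0L))
  X <- matrix(runif(n * length(spec$mri_vars), 0, 100), nrow = n,
              dimnames = list(NULL, spec$mri_vars))
  motor_vars <- names(spec$motor_family)
  noise <- if (length(names(spec$noise_sd))) spec$noise_sd else
    stats::setNames(rep_len(spec$noise_sd, length(motor_vars)), motor_vars)
  out <- data.frame(subject_id = sprintf("sub-%02d", seq_len(n)))
  out <- cbind(out, as.data.frame(X))
  fam_tags <- character(0)
  for (k in seq_along(motor_vars)) {
    mv <- motor_vars[k]
    fam <- spec$motor_family[[mv]]
    eta <- rep(spec$intercepts[mv] %|na|% 0, n)
    for (ef in spec$effect_map) {
      if (ef$motor == mv) eta <- eta + ef$effect * X[, ef$mri]
    }
    assert_that(all(is.finite(eta)),
                paste0("non-finite linear predictor for ", mv))
    set.seed(substream_seed(spec$seed, k))
    y <- switch(fam,
                linear = eta + stats::rnorm(n, sd = noise[mv] %|na|% 1),
                poisson = stats::rpois(n, exp(eta)),
                logistic = stats::rbinom(n, 1, stats::plogis(eta)))
    out[[mv]] <- y
    fam_tags[mv] <- family_tag(fam)
  }
  structure(list(data = out, families = fam_tags, mri_vars = spec$mri_vars,
                 motor_vars = motor_vars,
                 truth = spec$effect_map, spec = spec),
            class = "cohort_table")
}

`%|na|%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Assemble a cohort table from existing data
#'
#' @param data data.frame with MRI and motor columns (and optionally
#'   `subject_id`).
#' @param families named character, `continuous`/`count`/`binary` per motor
#'   column.
#' @param mri_vars,motor_vars column name vectors.
#' @param max_tasks optional cap for declared task-count variables; counts
#'   above it trigger a warning.
#' @return a `cohort_table`.
#' @export
cohort_table <- function(data, families, mri_vars, motor_vars,
                         max_tasks = NULL) {
  assert_that(all(c(mri_vars, motor_vars) %in% names(data)),
              "missing declared columns in cohort data")
  assert_that(all(motor_vars %in% names(families)),
              "every motor column needs a declared family")
  for (mv in motor_vars) {
    y <- data[[mv]]
    tag <- families[[mv]]
    assert_that(tag %in% c("continuous", "count", "binary"),
                paste0("unknown family tag for ", mv))
    if (tag == "count") {
      ok <- all(is.na(y) | (y >= 0 & y == round(y)))
      assert_that(ok, paste0(mv, ": counts must be nonnegative integers"))
      if (!is.null(max_tasks) && any(y > max_tasks, na.rm = TRUE)) {
        warning(mv, ": counts exceed the declared number of tasks",
                call. = FALSE)
      }
    }
    if (tag == "binary") {
      assert_that(all(is.na(y) | y %in% c(0, 1)),
                  paste0(mv, ": binary values must be 0/1"))
    }
  }
  structure(list(data = data, families = families[motor_vars],
                 mri_vars = mri_vars, motor_vars = motor_vars,
                 truth = NULL, spec = NULL),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " subjects, ",
      length(x$mri_vars), " MRI + ", length(x$motor_vars),
      " motor variables\n", sep = "")
  invisible(x)
}

#' Write / read a cohort table as CSV with a YAML family sidecar
#'
#' @param cohort a `cohort_table`.
#' @param path CSV path; the sidecar goes to `<path>.yaml`.
#' @return invisibly, the file paths.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$data, path, row.names = FALSE)
  side <- paste0(path, ".yaml")
  yaml::write_yaml(list(mri_vars = cohort$mri_vars,
                        motor_vars = cohort$motor_vars,
                        families = as.list(cohort$families)), side)
  invisible(c(csv = path, sidecar = side))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  data <- utils::read.csv(path, check.names = FALSE)
  cohort_table(data, unlist(side$families), side$mri_vars, side$motor_vars)
}
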