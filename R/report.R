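#' Full screening-and-regression association report
#'
#' Runs the complete statistical ledger on a cohort table:
#' \enumerate{
#'   \item drop zero-variance variables;
#'   \item Spearman-correlation and (optionally) Boruta-importance
#'     screening of all (MRI, motor) pairs;
#'   \item retain MRI variables correlated with or important for at least
#'     one motor outcome, and motor outcomes with at least one such MRI
#'     variable;
#'   \item per retained motor outcome, univariable family-dispatched GLMs
#'     (Poisson for counts, logistic for binaries, linear otherwise) on each
#'     retained MRI variable;
#'   \item combine the individually significant MRI variables into one
#'     multivariable model per motor outcome and, to tame small-sample
#'     variance, refit it on `B` bootstrap copies, reporting the bagged
#'     ensemble mean (SE = ensemble SD) as the adjusted estimate.
#' }
#'
#' @param cohort a `cohort_table`.
#' @param alpha significance level for univariable selection and for the
#'   significant-rows filter (default 0.05).
#' @param alpha_screen significance level of the correlation screen
#'   (default: `alpha`).
#' @param rho_min minimal non-weak absolute Spearman correlation
#'   (default 0.4).
#' @param use_boruta run the Boruta importance screen (default TRUE).
#' @param boruta_n_iter,boruta_alpha,num_trees Boruta settings.
#' @param bagging bag the multivariable fits (default TRUE); when FALSE the
#'   adjusted columns come from the plain multivariable fit.
#' @param B bootstrap copies for bagging (default 1000).
#' @param seed integer seed governing every stochastic step.
#' @return object of class `association_report`: list with `significant`
#'   (data.frame of rows with adjusted p < alpha: motor, mri, estimate, se,
#'   p), `full` (all retained pairs with screening, univariable and adjusted
#'   columns), `screen` (the `screening_result`), `dropped`, `provenance`.
#' @export
build_report <- function(cohort, alpha = 0.05, alpha_screen = alpha,
                         rho_min = 0.4, use_boruta = TRUE,
                         boruta_n_iter = 100L, boruta_alpha = 0.01,
                         num_trees = 500L, bagging = TRUE, B = 1000L,
                         seed = 1L) {
  stopifnot(inherits(cohort, "cohort_table"))
  dz <- drop_zero_variance(cohort$data,
                           c(cohort$mri_vars, cohort$motor_vars))
  mri_vars <- setdiff(cohort$mri_vars, dz$dropped)
  motor_vars <- setdiff(cohort$motor_vars, dz$dropped)
  reduced <- cohort
  reduced$data <- dz$data
  reduced$mri_vars <- mri_vars
  reduced$motor_vars <- motor_vars
  reduced$families <- cohort$families[motor_vars]

  screen <- screen_cohort(reduced, alpha_screen = alpha_screen,
                          rho_min = rho_min, use_boruta = use_boruta,
                          boruta_n_iter = boruta_n_iter,
                          boruta_alpha = boruta_alpha,
                          num_trees = num_trees,
                          seed = substream_seed(seed, 1L))

  full <- merge(screen$pairs,
                expand.grid(mri = screen$mri_kept, motor = screen$motor_kept,
                            stringsAsFactors = FALSE),
                by = c("mri", "motor"))
  for (cn in c("uni_estimate", "uni_se", "uni_p",
               "adj_estimate", "adj_se", "adj_p")) {
    full[[cn]] <- rep(NA_real_, nrow(full))
  }
  full$flags <- rep("", nrow(full))

  for (k in seq_along(screen$motor_kept)) {
    mv <- screen$motor_kept[k]
    fam <- reduced$families[[mv]]
    sig <- character(0)
    for (xv in screen$mri_kept) {
      uf <- fit_glm(dz$data, mv, xv, fam)
      row <- uf$coefs[uf$coefs$term == sprintf("`%s`", xv) |
                        uf$coefs$term == xv, ]
      i <- full$mri == xv & full$motor == mv
      full$uni_estimate[i] <- row$estimate
      full$uni_se[i] <- row$se
      full$uni_p[i] <- row$p
      if (length(uf$flags)) {
        full$flags[i] <- paste(uf$flags, collapse = ";")
      }
      if (is.finite(row$p) && row$p < alpha) sig <- c(sig, xv)
    }
    if (length(sig) == 0) next
    adj <- if (bagging) {
      bagged_fit(dz$data, mv, sig, fam, B = B,
                 seed = substream_seed(seed, 100L + k))
    } else {
      multivariable_model(dz$data, mv, sig, fam)
    }
    for (xv in sig) {
      row <- adj$coefs[adj$coefs$term == sprintf("`%s`", xv) |
                         adj$coefs$term == xv, ]
      i <- full$mri == xv & full$motor == mv
      full$adj_estimate[i] <- row$estimate
      full$adj_se[i] <- row$se
      full$adj_p[i] <- row$p
    }
  }
  full <- full[order(full$motor, full$mri), ]
  rownames(full) <- NULL
  sig_rows <- !is.na(full$adj_p) & full$adj_p < alpha
  significant <- full[sig_rows,
                      c("motor", "mri", "adj_estimate", "adj_se", "adj_p")]
  rownames(significant) <- NULL
  structure(list(significant = significant, full = full, screen = screen,
                 dropped = dz$dropped,
                 provenance = list(alpha = alpha,
                                   alpha_screen = alpha_screen,
                                   rho_min = rho_min,
                                   use_boruta = use_boruta,
                                   boruta_n_iter = boruta_n_iter,
                                   boruta_alpha = boruta_alpha,
                                   num_trees = num_trees,
                                   bagging = bagging, B = B, seed = seed,
                                   n_subjects = nrow(dz$data))),
            class = "association_report")
}

#' @export
print.association_report <- function(x, ...) {
  pv <- x$provenance
  cat("<association_report> n = ", pv$n_subjects, ", alpha = ", pv$alpha,
      ", B = ", pv$B, ", seed = ", pv$seed, "\n", sep = "")
  if (length(x$dropped)) {
    cat("  zero-variance dropped:", paste(x$dropped, collapse = ", "), "\n")
  }
  cat("  retained:", length(x$screen$mri_kept), "MRI x",
      length(x$screen$motor_kept), "motor variables\n")
  if (nrow(x$significant)) {
    cat("  significant associations (adjusted):\n")
    print(x$significant, digits = 3)
  } else {
    cat("  no significant associations\n")
  }
  invisible(x)
}

#' Write an association report to disk
#'
#' `report_full.csv`, `report_significant.csv`, and a human-readable
#' `report_summary.txt` including the provenance block (thresholds, seeds,
#' B).
#'
#' @param report an `association_report`.
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pf <- file.path(dir, "report_full.csv")
  ps <- file.path(dir, "report_significant.csv")
  pt <- file.path(dir, "report_summary.txt")
  utils::write.csv(report$full, pf, row.names = FALSE)
  utils::write.csv(report$significant, ps, row.names = FALSE)
  con <- file(pt, "w")
  on.exit(close(con))
  writeLines(utils::capture.output({
    print(report)
    cat("\nprovenance:\n")
    utils::str(report$provenance)
  }), con)
  invisible(c(full = pf, significant = ps, summary = pt))
}

#' Read back the significant-associations table
#'
#' @param dir directory written by [write_report()].
#' @return data.frame.
#' @export
read_report_significant <- function(dir) {
  utils::read.csv(file.path(dir, "report_significant.csv"))
}
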