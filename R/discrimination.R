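# Diet-tissue discrimination: lipid normalization, delta computation,
# group summaries, mixed-model analysis and the two-diet comparison.

#' Lipid-normalize carbon isotope values using the C:N ratio
#'
#' Lipids are depleted in 13C, so bulk-tissue delta13C is corrected
#' arithmetically from the sample's C:N ratio. The default normalization is
#' `delta13C' = delta13C - 3.32 + 0.99 * C:N`; it is strictly increasing in
#' C:N and has no net effect at C:N = 3.32/0.99. Samples without a C:N ratio
#' (`NA`, or `c_n_ratio = NULL` for all) pass through uncorrected.
#'
#' @param d13c_raw Raw delta13C values (permil).
#' @param c_n_ratio C:N ratios, positive; `NULL` or `NA` means no correction.
#' @param intercept,slope Coefficients of the normalization, injectable for
#'   other calibrations.
#' @return Corrected delta13C values.
#' @examples
#' lipid_normalize_d13c(-20, 4)        # -19.36
#' lipid_normalize_d13c(-20, NULL)     # pass-through
#' @export
lipid_normalize_d13c <- function(d13c_raw, c_n_ratio = NULL,
                                 intercept = -3.32, slope = 0.99) {
  if (is.null(c_n_ratio)) return(d13c_raw)
  if (any(!is.na(c_n_ratio) & c_n_ratio <= 0)) {
    abort("`c_n_ratio` must be positive.")
  }
  ifelse(is.na(c_n_ratio), d13c_raw,
         d13c_raw + intercept + slope * c_n_ratio)
}

#' Diet-tissue discrimination factor
#'
#' The discrimination (Delta) of a tissue relative to the diet is the plain
#' difference of delta values for one isotope: `delta_tissue - delta_diet`.
#' Negative values are permitted.
#'
#' @param tissue_delta,diet_delta Delta values (permil), same isotope.
#' @return Delta (permil).
#' @export
discrimination_factor <- function(tissue_delta, diet_delta) {
  if (any(!is.finite(tissue_delta)) || any(!is.finite(diet_delta))) {
    abort("Delta values must be finite.")
  }
  tissue_delta - diet_delta
}

#' Compute discrimination records from measurements and diet signatures
#'
#' Joins the long measurement table with the diet-signature table on
#' `diet` and `isotope` and computes `Delta = delta_tissue - delta_diet`.
#' For delta13C, the tissue value is lipid-normalized via
#' [lipid_normalize_d13c()] whenever a `c_n_ratio` is present and
#' `lipid_correct = TRUE`; records without a C:N ratio keep the raw value
#' and are flagged `lipid_corrected = FALSE` (never imputed).
#'
#' @param data Long measurement table (see [read_isotope_measurements()]).
#' @param diet_signatures Table with columns `diet`, `isotope`,
#'   `delta_permil` (one row per diet x isotope).
#' @param lipid_correct Apply the C:N normalization to delta13C?
#' @return A tibble of discrimination records: one row per input
#'   measurement with `discrimination` and `lipid_corrected`.
#' @export
compute_discrimination <- function(data, diet_signatures,
                                   lipid_correct = TRUE) {
  data <- as_tibble(data)
  sig <- as_tibble(diet_signatures)
  req <- c("diet", "isotope", "delta_permil")
  if (!all(req %in% names(sig))) {
    abort("`diet_signatures` needs columns diet, isotope, delta_permil.")
  }
  if (anyDuplicated(sig[, c("diet", "isotope")])) {
    abort("`diet_signatures` must have one row per diet x isotope.")
  }
  need <- distinct(data, .data$diet, .data$isotope)
  missing_sig <- anti_join(need, sig, by = c("diet", "isotope"))
  if (nrow(missing_sig)) {
    abort(paste0("No diet signature for: ",
                 paste(paste0(missing_sig$diet, "/", missing_sig$isotope),
                       collapse = ", ")))
  }
  has_cn <- "c_n_ratio" %in% names(data)
  sig_small <- rename(sig, diet_delta = "delta_permil")[,
                      c("diet", "isotope", "diet_delta")]
  out <- left_join(data, sig_small, by = c("diet", "isotope"))
  cn <- if (has_cn) out$c_n_ratio else rep(NA_real_, nrow(out))
  correct <- lipid_correct & out$isotope == "d13C" & !is.na(cn)
  tissue_delta <- ifelse(correct,
                         lipid_normalize_d13c(out$delta_permil, cn),
                         out$delta_permil)
  keep <- intersect(c("individual_id", "sex", "age", "tissue", "diet",
                      "isotope"), names(out))
  res <- out[, keep]
  res$discrimination <- tissue_delta - out$diet_delta
  res$lipid_corrected <- correct
  res
}

#' Summarise discrimination by groups
#'
#' Per-group mean, standard deviation (n - 1 denominator; reported only when
#' n >= 2) and count of a discrimination table, with a deterministic group
#' ordering.
#'
#' @param records Discrimination records ([compute_discrimination()] output
#'   or any table with a `discrimination` column).
#' @param by Character vector of grouping keys (columns of `records`).
#' @return A tibble with the grouping keys plus `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(records, by = c("tissue", "diet")) {
  records <- as_tibble(records)
  bad <- setdiff(by, names(records))
  if (length(bad)) {
    abort(paste0("Unknown grouping key(s): ", paste(bad, collapse = ", ")))
  }
  if (!nrow(records)) abort("`records` is empty.")
  records %>%
    group_by(across(all_of(by))) %>%
    summarise(mean = mean(.data$discrimination),
              sd = if (n() >= 2) sd(.data$discrimination) else NA_real_,
              n = n(), .groups = "drop") %>%
    arrange(across(all_of(by)))
}

#' Overall discrimination means across demographic cells
#'
#' "Overall" rows collapse the sex x age cells of a tissue. By default this
#' is the n-weighted mean (i.e. the plain mean over records); the unweighted
#' mean of cell means is available for balanced comparisons.
#'
#' @param records Discrimination records.
#' @param by Keys defining the rows of the output (default tissue and
#'   isotope).
#' @param cells Keys defining the demographic cells being collapsed.
#' @param weighted If `TRUE` (default), n-weighted.
#' @return Tibble with `by` keys plus `mean`, `n`.
#' @export
overall_means <- function(records, by = c("tissue", "isotope"),
                          cells = c("sex", "age"), weighted = TRUE) {
  records <- as_tibble(records)
  if (weighted) {
    records %>%
      group_by(across(all_of(by))) %>%
      summarise(mean = mean(.data$discrimination), n = n(),
                .groups = "drop")
  } else {
    summarize_groups(records, by = c(by, cells)) %>%
      group_by(across(all_of(by))) %>%
      summarise(mean = mean(.data$mean), n = sum(.data$n), .groups = "drop")
  }
}

# candidate fixed-effect formulas: all subsets of the main effects, plus the
# full model with all two-way interactions
.discr_ladder <- function(mains, interactions) {
  subsets <- unlist(lapply(0:length(mains), function(k) {
    utils::combn(mains, k, simplify = FALSE)
  }), recursive = FALSE)
  rhs <- vapply(subsets, function(s) {
    if (!length(s)) "1" else paste(s, collapse = " + ")
  }, character(1))
  if (interactions && length(mains) >= 2) {
    rhs <- c(rhs, paste0("(", paste(mains, collapse = " + "), ")^2"))
  }
  rhs
}

#' Mixed-model analysis of discrimination
#'
#' Models discrimination as a function of diet, tissue, sex and age (those
#' with at least two observed levels) with a Gaussian random intercept per
#' individual. A candidate ladder from the intercept-only model up to all
#' main effects plus all two-way interactions is fitted by maximum
#' likelihood; the most parsimonious model within 2 AIC units of the best is
#' selected (the same rule as [select_model()]) and refitted by restricted
#' maximum likelihood for the reported coefficients and Wald 95% intervals.
#'
#' @param records Discrimination records for one isotope, or with an
#'   `isotope` column filtered via `isotope`.
#' @param isotope Which isotope to analyse (`"d13C"` or `"d15N"`).
#' @param fixed Candidate fixed effects (default diet, tissue, sex, age;
#'   constant columns are dropped with a message).
#' @param interactions Include the all-two-way-interactions model?
#' @param delta_aic Parsimony cut-off for selection (default 2).
#' @return A `discrimination_fit` object with the AIC ladder, the selected
#'   formula, the REML refit and its coefficient table.
#' @export
fit_discrimination_model <- function(records, isotope = NULL,
                                     fixed = c("diet", "tissue", "sex",
                                               "age"),
                                     interactions = TRUE, delta_aic = 2) {
  records <- as_tibble(records)
  if (!is.null(isotope)) {
    records <- filter(records, .data$isotope == !!isotope)
  }
  if (!nrow(records)) abort("No records to analyse.")
  if (length(unique(records$individual_id)) < 2) {
    abort("Mixed-model analysis needs >= 2 individuals.")
  }
  present <- intersect(fixed, names(records))
  dropped <- setdiff(fixed, present)
  mains <- present[vapply(present, function(v) {
    length(unique(records[[v]])) >= 2
  }, logical(1))]
  dropped <- c(dropped, setdiff(present, mains))
  if (length(dropped)) {
    message("Dropping constant/absent factor(s): ",
            paste(dropped, collapse = ", "))
  }
  # empty-cell guard for the interaction model
  if (interactions && length(mains) >= 2) {
    for (i in seq_len(length(mains) - 1)) {
      for (j in (i + 1):length(mains)) {
        cells <- table(records[[mains[i]]], records[[mains[j]]])
        if (any(cells == 0)) {
          empty <- which(cells == 0, arr.ind = TRUE)[1, ]
          abort(sprintf(
            "Empty design cell: %s=%s x %s=%s; cannot fit interactions.",
            mains[i], rownames(cells)[empty[1]],
            mains[j], colnames(cells)[empty[2]]))
        }
      }
    }
  }
  rhs <- .discr_ladder(mains, interactions)
  fits_ml <- map(rhs, function(r) {
    form <- stats::as.formula(paste("discrimination ~", r,
                                    "+ (1 | individual_id)"))
    suppressMessages(lme4::lmer(form, data = records, REML = FALSE))
  })
  n_fix <- vapply(fits_ml, function(f) length(lme4::fixef(f)), integer(1))
  aics <- vapply(fits_ml, AIC, numeric(1))
  ladder <- tibble(formula = rhs, aic = aics, n_fixed_terms = n_fix,
                   df = vapply(fits_ml, function(f)
                     attr(logLik(f), "df"), numeric(1)))
  ladder$delta_aic <- ladder$aic - min(ladder$aic)
  within <- which(ladder$delta_aic <= delta_aic)
  sel_idx <- within[order(ladder$df[within], ladder$n_fixed_terms[within],
                          ladder$aic[within])][1]
  sel_rhs <- rhs[sel_idx]
  final <- suppressMessages(lme4::lmer(
    stats::as.formula(paste("discrimination ~", sel_rhs,
                            "+ (1 | individual_id)")),
    data = records, REML = TRUE))
  fe <- lme4::fixef(final)
  se <- sqrt(diag(as.matrix(vcov(final))))
  z <- qnorm(0.975)
  coefs <- tibble(term = names(fe), estimate = unname(fe),
                  std.error = unname(se),
                  conf.low = unname(fe - z * se),
                  conf.high = unname(fe + z * se))
  vc <- as.data.frame(lme4::VarCorr(final))
  structure(list(
    ladder = arrange(ladder, .data$aic),
    selected_formula = sel_rhs,
    model = final,
    coefficients = coefs,
    re_sd = vc$sdcor[vc$grp == "individual_id"],
    sigma = vc$sdcor[vc$grp == "Residual"],
    n_individuals = length(unique(records$individual_id)),
    n_records = nrow(records)
  ), class = "discrimination_fit")
}

#' @export
print.discrimination_fit <- function(x, ...) {
  cat("Discrimination mixed-model analysis\n")
  cat(sprintf("  selected fixed effects: ~ %s\n", x$selected_formula))
  cat(sprintf("  individual SD %.3f, residual SD %.3f (%d individuals, %d records)\n",
              x$re_sd, x$sigma, x$n_individuals, x$n_records))
  print(x$coefficients)
  invisible(x)
}

#' Two-sample comparison of discrimination between diets
#'
#' Welch's two-sample comparison of discrimination between two diet groups
#' within one tissue (the design used for tissues with too few samples for
#' the mixed model, such as liver).
#'
#' @param records Discrimination records.
#' @param tissue Tissue to compare within.
#' @param isotope Isotope to compare.
#' @param diets Optional length-2 character vector ordering the comparison
#'   (difference is `diets[1] - diets[2]`); defaults to the two diets
#'   present.
#' @return One-row tibble: mean difference, 95% CI, t statistic, Welch df,
#'   p value, group means and sizes.
#' @export
compare_diets_two_sample <- function(records, tissue, isotope = "d15N",
                                     diets = NULL) {
  records <- as_tibble(records)
  rec <- filter(records, .data$tissue == !!tissue,
                .data$isotope == !!isotope)
  if (is.null(diets)) {
    diets <- sort(unique(as.character(rec$diet)))
  }
  if (length(diets) != 2) {
    abort("Exactly two diets are required for the comparison.")
  }
  g1 <- rec$discrimination[rec$diet == diets[1]]
  g2 <- rec$discrimination[rec$diet == diets[2]]
  if (length(g1) < 2 || length(g2) < 2) {
    abort(sprintf("Each diet needs >= 2 records (got %d and %d).",
                  length(g1), length(g2)))
  }
  tt <- t.test(g1, g2)
  tibble(tissue = tissue, isotope = isotope,
         diet_1 = diets[1], diet_2 = diets[2],
         estimate = unname(tt$estimate[1] - tt$estimate[2]),
         conf.low = tt$conf.int[1], conf.high = tt$conf.int[2],
         statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value,
         mean_1 = unname(tt$estimate[1]), mean_2 = unname(tt$estimate[2]),
         n_1 = length(g1), n_2 = length(g2))
}
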