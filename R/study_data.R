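# Bundled contingency tables from a clinical feasibility study of 3D HPRF
# Doppler RVol estimation in aortic and mitral regurgitation, used for
# worked examples of the agreement statistics.

#' Bundled clinical study tables
#'
#' Small summary tables from a clinical feasibility cohort of 3D HPRF
#' Doppler regurgitant-volume estimation (45 aortic- and 45
#' mitral-regurgitation patients): cross-tabulations of overall
#' echocardiographic severity grade against categorized reference RVol, and
#' feasibility counts stratified by severity, jet direction and image
#' quality.
#'
#' @return list with
#' * `crosstabs`: named list (`AR`, `MR`) of 3x3 count matrices, rows =
#'   TTE severity grade (mild/moderate/severe), columns = reference RVol
#'   category (`<30`, `30-59`, `>=60` mL);
#' * `feasibility`: data.frame of feasible/total counts per cohort and
#'   stratum.
#' @export
study_tables <- function() {
  xt <- utils::read.csv(system.file("extdata", "severity_crosstabs.csv",
                                    package = "hprfdoppler"))
  crosstabs <- lapply(split(xt, xt$cohort), function(d) {
    m <- as.matrix(d[, c("rvol_lt30", "rvol_30_59", "rvol_ge60")])
    dimnames(m) <- list(grade = d$tte_grade,
                        rvol = c("<30", "30-59", ">=60"))
    m
  })
  feas <- utils::read.csv(system.file("extdata", "feasibility_counts.csv",
                                      package = "hprfdoppler"))
  list(crosstabs = crosstabs, feasibility = feas)
}

#' Worked agreement examples from the bundled study tables
#'
#' Recomputes the headline agreement and feasibility numbers from the
#' bundled tables: unweighted Cohen's kappa of the severity cross-tables,
#' pooled feasibility rates, and Pearson chi-square of feasibility by jet
#' direction.
#'
#' @return list: `kappa_ar`, `kappa_mr`, `feasibility_overall_pct`,
#'   `feasibility_severe_pct`, `chi2_direction_ar` and `chi2_direction_mr`
#'   (each a [pearson_chi2()] result).
#' @export
study_worked_examples <- function() {
  tb <- study_tables()
  feas <- tb$feasibility
  pooled <- function(stratum, group = NULL) {
    d <- feas[feas$stratum == stratum, ]
    if (!is.null(group)) d <- d[d$group %in% group, ]
    100 * sum(d$feasible) / sum(d$total)
  }
  dir_tab <- function(cohort) {
    d <- feas[feas$cohort == cohort & feas$stratum == "jet_direction", ]
    m <- rbind(central = c(d$feasible[d$group == "central"],
                           d$total[d$group == "central"] -
                             d$feasible[d$group == "central"]),
               eccentric = c(d$feasible[d$group == "eccentric"],
                             d$total[d$group == "eccentric"] -
                               d$feasible[d$group == "eccentric"]))
    colnames(m) <- c("feasible", "non_feasible")
    m
  }
  list(
    kappa_ar = cohen_kappa(tb$crosstabs$AR)$kappa,
    kappa_mr = cohen_kappa(tb$crosstabs$MR)$kappa,
    feasibility_overall_pct = pooled("overall"),
    feasibility_severe_pct = pooled("severity", "severe"),
    chi2_direction_ar = pearson_chi2(dir_tab("AR")),
    chi2_direction_mr = pearson_chi2(dir_tab("MR"))
  )
}
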