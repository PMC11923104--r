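## Cohort filtering, Kaplan-Meier estimation, group comparison and Cox
## modeling with the p < 0.05 carry-forward rule.  Model fitting is
## delegated to the survival package (Efron tie handling, log(-log)
## median CIs); this module supplies the analysis skeleton around it.

#' Filter a cohort for survival analysis
#'
#' Removes perioperative mortality -- deaths within 30 days of surgery
#' (\code{event == 1} and \code{os_days <= 30} when a day-resolution
#' column is present, otherwise \code{os_months < 1}) -- and records with
#' missing time or event.  Removals are reported via \code{message()}.
#'
#' @param records \code{data.frame} with at least \code{os_months} and
#'   \code{event}; an optional \code{os_days} column takes precedence for
#'   the 30-day rule.
#' @return The filtered \code{data.frame}.
#' @examples
#' d <- data.frame(os_months = c(0.5, 12), event = c(1, 1))
#' filterCohort(d)   # the day-20 death is excluded
#' @export
filterCohort <- function(records) {
  stopifnot(all(c("os_months", "event") %in% names(records)))
  missing <- is.na(records$os_months) | is.na(records$event)
  early <- if ("os_days" %in% names(records))
    records$event == 1 & records$os_days <= 30
  else
    records$event == 1 & records$os_months < 1
  early[is.na(early)] <- FALSE
  drop <- missing | early
  if (any(drop))
    message("filterCohort: removed ", sum(early & !missing),
            " perioperative death(s) and ", sum(missing),
            " record(s) with missing time/event")
  out <- records[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop("all records removed by filtering")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier fit with median OS and confidence interval
#'
#' Product-limit estimator via \code{survival::survfit} with log(-log)
#' confidence intervals; the median is the earliest time at which the
#' survival estimate drops to 0.5 or below, reported as not reached
#' (\code{NA}) when the curve never does.
#'
#' @param time,event survival times (months) and event indicators.
#' @return A \code{SurvivalSummary} (see \code{\link{medianOS}},
#'   \code{\link{medianCI}}, \code{\link{kmCurve}}).
#' @examples
#' s <- kmFit(c(5, 8, 12, 20), c(1, 1, 1, 0))
#' medianOS(s)
#' @export
kmFit <- function(time, event) {
  if (sum(event) < 1L) stop("need at least one event")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  ci <- unname(c(tab["0.95LCL"], tab["0.95UCL"]))
  curve <- data.frame(time = fit$time, nRisk = fit$n.risk,
                      nEvent = fit$n.event, surv = fit$surv,
                      lower = fit$lower, upper = fit$upper)
  new("SurvivalSummary", medianOS = med, medianCI = ci, curve = curve,
      n = as.integer(fit$n), nEvents = as.integer(sum(fit$n.event)))
}

#' Compare survival between groups
#'
#' Per-group Kaplan-Meier summaries, the overall log-rank p-value, and
#' univariate Cox hazard-ratio contrasts of the first group level against
#' each other level and against all others pooled (the
#' "Group 1 vs Group 2 / vs Group 3 / vs Others" reporting pattern).
#'
#' @param records cohort \code{data.frame}.
#' @param groupVar name of the grouping column.
#' @param timeVar,eventVar column names (defaults \code{os_months},
#'   \code{event}).
#' @return List with \code{logrank_p}, \code{groups} (named list of
#'   \code{SurvivalSummary}) and \code{contrasts} (\code{data.frame} with
#'   \code{contrast}, \code{hr}, \code{lower}, \code{upper}, \code{p}).
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 150, seed = 4))
#' cmp <- compareGroups(d, "sip_group_true")
#' cmp$logrank_p
#' @export
compareGroups <- function(records, groupVar, timeVar = "os_months",
                          eventVar = "event") {
  g <- records[[groupVar]]
  if (is.factor(g) && any(table(g) == 0)) {
    warning("dropping empty group level(s): ",
            paste(levels(g)[table(g) == 0], collapse = ", "))
    g <- droplevels(g)
  }
  g <- as.factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups")
  time <- records[[timeVar]]
  event <- records[[eventVar]]
  lr <- logrankTest(time, event, g)
  groups <- lapply(levels(g), function(lv)
    kmFit(time[g == lv], event[g == lv]))
  names(groups) <- levels(g)
  ref <- levels(g)[1]
  contr <- NULL
  hrOf <- function(sel, indicator, label) {
    fit <- survival::coxph(
      survival::Surv(time[sel], event[sel]) ~ indicator[sel])
    ci <- exp(stats::confint(fit))
    s <- summary(fit)
    data.frame(contrast = label, hr = unname(exp(coef(fit)[1])),
               lower = ci[1, 1], upper = ci[1, 2],
               p = s$coefficients[1, "Pr(>|z|)"])
  }
  ind <- as.numeric(g == ref)
  for (lv in levels(g)[-1]) {
    sel <- g %in% c(ref, lv)
    contr <- rbind(contr, hrOf(sel, ind, paste(ref, "vs", lv)))
  }
  if (nlevels(g) > 2L)
    contr <- rbind(contr, hrOf(rep(TRUE, length(g)), ind,
                               paste(ref, "vs others")))
  rownames(contr) <- NULL
  list(logrank_p = lr$p.value, groups = groups, contrasts = contr)
}

coxTermTable <- function(fit, variable) {
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  data.frame(variable = variable, term = rownames(co),
             hr = unname(co[, "exp(coef)"]),
             lower = unname(ci[, "lower .95"]),
             upper = unname(ci[, "upper .95"]),
             p = unname(co[, "Pr(>|z|)"]),
             stringsAsFactors = FALSE)
}

#' Univariate Cox screens
#'
#' One proportional-hazards fit per variable (Efron tie handling).
#' Degenerate or non-converging fits are flagged and excluded from the
#' carry-forward set.
#'
#' @param records cohort \code{data.frame}.
#' @param variables character vector of covariate column names.
#' @param timeVar,eventVar column names.
#' @return \code{data.frame} with one row per model term: \code{variable},
#'   \code{term}, \code{hr}, \code{lower}, \code{upper}, \code{p},
#'   \code{converged}.
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 150, seed = 5))
#' coxUnivariate(d, c("sip", "lip", "age"))
#' @export
coxUnivariate <- function(records, variables, timeVar = "os_months",
                          eventVar = "event") {
  stopifnot(sum(records[[eventVar]]) >= 1L)
  out <- NULL
  for (v in variables) {
    x <- records[[v]]
    if (length(unique(x[!is.na(x)])) < 2L) {
      out <- rbind(out, data.frame(variable = v, term = v, hr = NA_real_,
                                   lower = NA_real_, upper = NA_real_,
                                   p = NA_real_, converged = FALSE))
      next
    }
    flag <- TRUE
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(as.formula(
          paste0("survival::Surv(", timeVar, ", ", eventVar, ") ~ ", v)),
          data = records),
        warning = function(w) {
          flag <<- FALSE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || anyNA(coef(fit)) ||
        any(!is.finite(sqrt(diag(vcov(fit)))))) {
      out <- rbind(out, data.frame(variable = v, term = v, hr = NA_real_,
                                   lower = NA_real_, upper = NA_real_,
                                   p = NA_real_, converged = FALSE))
      next
    }
    tab <- coxTermTable(fit, v)
    tab$converged <- flag
    out <- rbind(out, tab)
  }
  rownames(out) <- NULL
  out
}

#' Multivariate Cox model on selected variables
#'
#' Joint proportional-hazards fit; variables keeping \code{p < 0.05} in
#' the joint model are marked as independent predictors.  Collinear
#' selections (aliased coefficients) raise an error naming the terms.
#'
#' @inheritParams coxUnivariate
#' @param variables variables to enter jointly (normally those with
#'   univariate \code{p < 0.05}).
#' @return \code{data.frame} with \code{variable}, \code{term}, \code{hr},
#'   \code{lower}, \code{upper}, \code{p}, \code{independent}.
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 200, seed = 6))
#' coxMultivariate(d, c("sip", "lip"))
#' @export
coxMultivariate <- function(records, variables, timeVar = "os_months",
                            eventVar = "event") {
  stopifnot(length(variables) >= 1L)
  fml <- as.formula(paste0("survival::Surv(", timeVar, ", ", eventVar,
                           ") ~ ", paste(variables, collapse = " + ")))
  fit <- survival::coxph(fml, data = records)
  if (anyNA(coef(fit)))
    stop("collinear selection: aliased term(s) ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  tab <- coxTermTable(fit, NA_character_)
  # map terms back to variables by prefix (factor terms carry level suffixes)
  tab$variable <- vapply(tab$term, function(tm) {
    hit <- variables[startsWith(tm, variables)]
    if (length(hit)) hit[which.max(nchar(hit))] else tm
  }, character(1))
  tab$independent <- tab$p < 0.05
  rownames(tab) <- NULL
  tab
}

#' Univariate screen with p < 0.05 carry-forward to a multivariate model
#'
#' @inheritParams coxUnivariate
#' @param alpha carry-forward significance level (default 0.05).
#' @return List with \code{univariate} (full screen), \code{selected}
#'   (variables carried forward) and \code{multivariate} (joint model
#'   table, \code{NULL} when nothing was selected).
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 200, seed = 7))
#' fit <- coxCarryForward(d, c("sip", "lip", "age"))
#' fit$selected
#' @export
coxCarryForward <- function(records, variables, timeVar = "os_months",
                            eventVar = "event", alpha = 0.05) {
  uni <- coxUnivariate(records, variables, timeVar, eventVar)
  okVars <- unique(uni$variable[uni$converged & !is.na(uni$p) &
                                  uni$p < alpha])
  multi <- if (length(okVars))
    coxMultivariate(records, okVars, timeVar, eventVar)
  else NULL
  list(univariate = uni, selected = okVars, multivariate = multi)
}

linearByLinear <- function(x, y) {
  sx <- as.numeric(x); sy <- as.numeric(y)
  r <- cor(sx, sy)
  stat <- (length(sx) - 1) * r^2
  list(statistic = stat, p.value = pchisq(stat, 1, lower.tail = FALSE))
}

#' Baseline characteristics table with group-comparison tests
#'
#' Continuous covariates are compared across groups by rank tests
#' (Mann-Whitney U for two groups, Kruskal-Wallis otherwise); nominal
#' covariates by the uncorrected chi-square test; ordered factors by the
#' linear-by-linear association test.  Covariates that are entirely
#' missing are skipped with a warning.
#'
#' @param records cohort \code{data.frame}.
#' @param groupVar grouping column name.
#' @param continuous,categorical character vectors of covariate names
#'   (ordered factors inside \code{categorical} get the trend test).
#' @return \code{data.frame} with \code{variable}, \code{test},
#'   \code{statistic}, \code{p}.
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 120, seed = 8))
#' groupBaselineTables(d, "sip_group_true", continuous = "age",
#'                     categorical = "sex")
#' @export
groupBaselineTables <- function(records, groupVar, continuous = character(),
                                categorical = character()) {
  g <- as.factor(records[[groupVar]])
  if (nlevels(droplevels(g)) < 2L) stop("need at least two groups")
  out <- NULL
  for (v in continuous) {
    x <- records[[v]]
    if (all(is.na(x))) { warning("skipping all-missing covariate ", v); next }
    if (nlevels(droplevels(g)) == 2L) {
      tst <- wilcox.test(x ~ g, exact = FALSE)
      out <- rbind(out, data.frame(variable = v, test = "mann-whitney",
                                   statistic = unname(tst$statistic),
                                   p = tst$p.value))
    } else {
      tst <- kruskal.test(x ~ g)
      out <- rbind(out, data.frame(variable = v, test = "kruskal-wallis",
                                   statistic = unname(tst$statistic),
                                   p = tst$p.value))
    }
  }
  for (v in categorical) {
    x <- records[[v]]
    if (all(is.na(x))) { warning("skipping all-missing covariate ", v); next }
    if (is.ordered(x)) {
      tst <- linearByLinear(x, g)
      out <- rbind(out, data.frame(variable = v, test = "linear-by-linear",
                                   statistic = tst$statistic,
                                   p = tst$p.value))
    } else {
      tst <- suppressWarnings(chisq.test(table(x, g), correct = FALSE))
      out <- rbind(out, data.frame(variable = v, test = "chi-square",
                                   statistic = unname(tst$statistic),
                                   p = tst$p.value))
    }
  }
  rownames(out) <- NULL
  out
}
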