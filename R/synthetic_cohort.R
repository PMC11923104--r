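## Synthetic survival cohorts with the SIP/LIP-dependent hazard structure
## the downstream analysis assumes.

drawMarker <- function(dist, n) {
  switch(dist$name,
    beta    = rbeta(n, dist$shape1, dist$shape2),
    uniform = runif(n, dist$min, dist$max),
    fixed   = rep(dist$value, n),
    stop("unknown distribution name: ", dist$name))
}

#' Generate a synthetic survival cohort
#'
#' Draws per-patient SIP and LIP markers, assigns each patient to the true
#' \{SIP-intermediate, SIP-LH\} x \{LIP-low, LIP-high\} cell via the true
#' cuts, and draws an exponential event time with the cell's rate.  The
#' observed time is the minimum of the event time, an independent
#' exponential censoring time and the administrative cutoff; \code{event}
#' flags which happened first.  Covariates \code{age} (normal) and
#' \code{sex} are generated independently of survival.  Identical seeds
#' give identical tables.
#'
#' @param params a \code{\link{cohortParams}} object.
#' @return \code{data.frame} with columns \code{patient_id},
#'   \code{os_months}, \code{event}, \code{sip}, \code{lip}, \code{age},
#'   \code{sex}, plus the generating truth \code{sip_group_true},
#'   \code{lip_group_true}, \code{true_rate}.
#' @examples
#' head(generateCohort(cohortParams(nPatients = 20, seed = 5)))
#' @export
generateCohort <- function(params) {
  stopifnot(is(params, "CohortParams"))
  validObject(params)
  n <- params@nPatients
  withSeed(params@seed, {
    s <- drawMarker(params@sipDistribution, n)
    l <- drawMarker(params@lipDistribution, n)
    sipInt <- s > params@sipCutsTrue[1] & s <= params@sipCutsTrue[2]
    lipHigh <- l > params@lipCutTrue
    cell <- ifelse(sipInt,
                   ifelse(lipHigh, "int.high", "int.low"),
                   ifelse(lipHigh, "lh.high", "lh.low"))
    rate <- unname(params@hazardByGroup[cell])
    tEvent <- rexp(n, rate)
    tCens <- if (params@censoringRate > 0) rexp(n, params@censoringRate)
             else rep(Inf, n)
    tCens <- pmin(tCens, params@adminCensorMonths)
    osMonths <- pmin(tEvent, tCens)
    event <- as.integer(tEvent <= tCens)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      os_months = osMonths,
      event = event,
      sip = s,
      lip = l,
      age = round(rnorm(n, 66, 9), 1),
      sex = sample(c("male", "female"), n, replace = TRUE,
                   prob = c(0.55, 0.45)),
      sip_group_true = ifelse(sipInt, "SIP-intermediate", "SIP-LH"),
      lip_group_true = ifelse(lipHigh, "LIP-high", "LIP-low"),
      true_rate = rate,
      stringsAsFactors = FALSE)
  })
}
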