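## Optimal survival cutpoints: k-group log-rank test, maximally selected
## rank statistics (binary cut, log-rank scores with permutation
## variance, Lausen-Schumacher adjusted p), exhaustive two-threshold
## three-group search, SIP-LH merge and combined risk grouping.

#' k-group log-rank test
#'
#' Standard log-rank chi-square over distinct event times with the
#' hypergeometric variance; deterministic.  This is the statistic
#' maximized by the two-cut search.
#'
#' @param time,event survival times and event indicators (0/1).
#' @param group group labels (>= 2 non-empty groups).
#' @return List with \code{statistic}, \code{df} and \code{p.value}.
#' @examples
#' logrankTest(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
#' @export
logrankTest <- function(time, event, group) {
  g <- as.integer(factor(group))
  k <- max(g)
  if (k < 2L) stop("need at least 2 non-empty groups")
  if (sum(event) < 1L) stop("no events: log-rank statistic undefined")
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord]); g <- g[ord]
  n <- length(time)
  nrisk <- tabulate(g, k)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  a <- 1L
  while (a <= n) {
    b <- a
    while (b < n && time[b + 1L] == time[a]) b <- b + 1L
    dj <- tabulate(g[a:b][event[a:b] == 1L], k)
    d <- sum(dj)
    ntot <- n - a + 1L
    if (d > 0L) {
      O <- O + dj
      E <- E + d * nrisk / ntot
      if (ntot > 1L) {
        f <- d * (ntot - d) / (ntot - 1)
        V <- V + f * (diag(nrisk * (ntot - nrisk), k) -
                        outer(nrisk, nrisk) *
                        (1 - diag(k))) / ntot^2
      }
    }
    nrisk <- nrisk - tabulate(g[a:b], k)
    a <- b + 1L
  }
  u <- (O - E)[-1L]
  Vi <- V[-1L, -1L, drop = FALSE]
  stat <- tryCatch(drop(t(u) %*% solve(Vi, u)),
                   error = function(e) {
                     dg <- diag(Vi)
                     if (all(dg < 1e-12)) 0 else sum(u[dg > 1e-12]^2 /
                                                       dg[dg > 1e-12])
                   })
  list(statistic = as.numeric(stat), df = k - 1L,
       p.value = pchisq(as.numeric(stat), k - 1L, lower.tail = FALSE))
}

# Log-rank (Nelson-Aalen) scores: a_i = event_i - cumulative hazard at
# t_i.  They sum to zero.
logrankScores <- function(time, event) {
  n <- length(time)
  ord <- order(time)
  ts <- time[ord]; es <- as.integer(event[ord])
  cumhaz <- numeric(n)
  L <- 0
  a <- 1L
  while (a <= n) {
    b <- a
    while (b < n && ts[b + 1L] == ts[a]) b <- b + 1L
    d <- sum(es[a:b])
    L <- L + d / (n - a + 1L)
    cumhaz[a:b] <- L
    a <- b + 1L
  }
  sc <- numeric(n)
  sc[ord] <- es - cumhaz
  sc
}

# Standardized statistics for all admissible splits "marker <= cut".
# Returns candidate cuts, the low-group sizes and the z values.
maxstatScan <- function(marker, time, event, minGroupFrac) {
  n <- length(marker)
  sc <- logrankScores(time, event)
  ord <- order(marker)
  ms <- marker[ord]
  cs <- cumsum(sc[ord])
  boundary <- which(diff(ms) > 0)          # low group = 1..m
  if (length(boundary) == 0L) stop("need at least 2 distinct marker values")
  m <- boundary
  keep <- pmin(m, n - m) >= minGroupFrac * n
  if (!any(keep))
    stop("no admissible cut under the minimum group-size constraint")
  m <- m[keep]
  cuts <- (ms[m] + ms[m + 1L]) / 2
  s2 <- sum(sc^2)
  z <- cs[m] / sqrt(m * (n - m) / (n * (n - 1)) * s2)
  list(cuts = cuts, m = m, z = z, n = n)
}

# Lausen & Schumacher improved-Bonferroni approximation for
# P(sup |B(t)/sqrt(t(1-t))| >= b) over t in [t1, t2].
lausenP <- function(b, t1, t2) {
  if (b <= 0) return(1)
  p <- dnorm(b) * ((b - 1 / b) * log(t2 * (1 - t1) / (t1 * (1 - t2))) +
                     4 / b)
  min(1, max(p, 2 * pnorm(-b)))   # never below the single-look bound
}

#' Maximally selected rank statistic (binary cutpoint)
#'
#' Scans candidate cuts at midpoints between consecutive distinct marker
#' values whose smaller resulting group holds at least
#' \code{minGroupFrac} of the cohort, and returns the cut maximizing the
#' absolute standardized log-rank statistic (log-rank scores with
#' permutation variance).  Ties in the maximum break toward the smaller
#' cut.  The p-value is adjusted for the multiple looks with the
#' Lausen-Schumacher improved-Bonferroni approximation; optionally a
#' permutation p-value is computed instead.
#'
#' @param marker numeric marker values (e.g. LIP).
#' @param time,event survival times and event indicators.
#' @param minGroupFrac minimum fraction of patients per group (default
#'   0.10).
#' @param pMethod \code{"lausen"} (default) or \code{"permutation"}.
#' @param nPerm,permSeed permutation count and seed for
#'   \code{pMethod = "permutation"}.
#' @param labels two group labels, low then high.
#' @param markerName name stored in the result.
#' @return A \code{CutpointResult} (see \code{\link{cutValues}},
#'   \code{\link{maxStatistic}}, \code{\link{cutPValue}},
#'   \code{\link{groupLabels}}).
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 120, seed = 2))
#' maxstatBinary(d$lip, d$os_months, d$event,
#'               labels = c("LIP-low", "LIP-high"), markerName = "lip")
#' @export
maxstatBinary <- function(marker, time, event, minGroupFrac = 0.10,
                          pMethod = c("lausen", "permutation"),
                          nPerm = 1000L, permSeed = 1L,
                          labels = c("low", "high"), markerName = "marker") {
  pMethod <- match.arg(pMethod)
  n <- length(marker)
  if (n < 10L) stop("need at least 10 patients")
  if (length(unique(marker)) < 2L)
    stop("need at least 2 distinct marker values")
  sc <- maxstatScan(marker, time, event, minGroupFrac)
  az <- abs(sc$z)
  iBest <- which.max(az)                   # first max = smallest cut
  b <- az[iBest]
  cut <- sc$cuts[iBest]
  if (pMethod == "lausen") {
    p <- lausenP(b, min(sc$m) / n, max(sc$m) / n)
  } else {
    obs <- b
    scores <- logrankScores(time, event)
    s2 <- sum(scores^2)
    m <- sc$m
    sdv <- sqrt(m * (n - m) / (n * (n - 1)) * s2)
    ordm <- order(marker)
    exceed <- 0L
    withSeed(permSeed, {
      for (r in seq_len(nPerm)) {
        ps <- sample(scores)
        zz <- abs(cumsum(ps[ordm])[m] / sdv)
        if (max(zz) >= obs - 1e-12) exceed <- exceed + 1L
      }
    })
    p <- (exceed + 1) / (nPerm + 1)
  }
  lab <- factor(ifelse(marker <= cut, labels[1], labels[2]),
                levels = labels)
  new("CutpointResult", cuts = cut, maxStatistic = b, pValue = p,
      groupLabels = lab, marker = markerName)
}

#' Exhaustive two-threshold three-group cutpoint search
#'
#' X-tile-style search: over all admissible pairs of candidate cuts
#' (midpoints of consecutive distinct marker values; each of the three
#' resulting groups at least \code{minGroupFrac} of the cohort), returns
#' the pair maximizing the unadjusted 3-group log-rank chi-square.  Ties
#' break toward the lexicographically smallest pair.  The reported
#' chi-square is selection-biased (it is the maximum over many looks) and
#' is meant descriptively, as in X-tile plots.
#'
#' @inheritParams maxstatBinary
#' @param labels three group labels, low / intermediate / high.
#' @return A \code{CutpointResult} with two cuts; \code{pValue} is
#'   \code{NA}.
#' @examples
#' d <- generateCohort(cohortParams(nPatients = 150, seed = 3))
#' xtileTwoCut(d$sip, d$os_months, d$event, markerName = "sip")
#' @export
xtileTwoCut <- function(marker, time, event, minGroupFrac = 0.10,
                        labels = c("SIP-low", "SIP-intermediate",
                                   "SIP-high"),
                        markerName = "marker") {
  n <- length(marker)
  if (n < 15L) stop("need at least 15 patients")
  if (length(unique(marker)) < 3L)
    stop("need at least 3 distinct marker values")
  if (sum(event) < 1L) stop("no events: log-rank statistic undefined")
  res <- xtile_scan_cpp(as.numeric(marker), as.numeric(time),
                        as.integer(event), minGroupFrac)
  lab <- factor(labels[1L + (marker > res$c1) + (marker > res$c2)],
                levels = labels)
  new("CutpointResult", cuts = c(res$c1, res$c2),
      maxStatistic = res$chisq, pValue = NA_real_, groupLabels = lab,
      marker = markerName)
}

#' Merge SIP-low and SIP-high into SIP-LH
#'
#' Both extreme stromal groups carry unfavorable prognosis, so they are
#' pooled against the protective intermediate band.
#'
#' @param labels factor or character with values \code{"SIP-low"},
#'   \code{"SIP-intermediate"}, \code{"SIP-high"}.
#' @return Factor with levels \code{"SIP-intermediate"}, \code{"SIP-LH"}.
#' @examples
#' mergeSipLH(c("SIP-low", "SIP-intermediate", "SIP-high"))
#' @export
mergeSipLH <- function(labels) {
  lab <- as.character(labels)
  known <- c("SIP-low", "SIP-intermediate", "SIP-high")
  if (any(!lab %in% known))
    stop("unknown SIP label(s): ",
         paste(unique(setdiff(lab, known)), collapse = ", "))
  out <- ifelse(lab == "SIP-intermediate", "SIP-intermediate", "SIP-LH")
  factor(out, levels = c("SIP-intermediate", "SIP-LH"))
}

#' Combined SIP x LIP risk groups
#'
#' Group 1: SIP-intermediate and LIP-high (optimal stroma and high
#' lymphocyte infiltration).  Group 3: SIP-LH and LIP-low (both
#' unfavorable).  Group 2: everything else (exactly one favorable
#' feature).
#'
#' @param sipBinary factor/character with values \code{"SIP-intermediate"}
#'   or \code{"SIP-LH"}.
#' @param lipBinary factor/character with values \code{"LIP-low"} or
#'   \code{"LIP-high"}.
#' @return Integer vector with values 1, 2, 3.
#' @examples
#' combinedGroups(c("SIP-intermediate", "SIP-LH"),
#'                c("LIP-high", "LIP-low"))   # 1 3
#' @export
combinedGroups <- function(sipBinary, lipBinary) {
  s <- as.character(sipBinary)
  l <- as.character(lipBinary)
  if (length(s) != length(l)) stop("label vectors differ in length")
  if (any(is.na(s)) || any(is.na(l))) stop("missing group label")
  if (any(!s %in% c("SIP-intermediate", "SIP-LH")))
    stop("unknown SIP label(s)")
  if (any(!l %in% c("LIP-low", "LIP-high")))
    stop("unknown LIP label(s)")
  ifelse(s == "SIP-intermediate" & l == "LIP-high", 1L,
         ifelse(s == "SIP-LH" & l == "LIP-low", 3L, 2L))
}
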