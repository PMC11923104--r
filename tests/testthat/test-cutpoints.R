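test_that("log-rank statistic matches survdiff on random cohorts", {
  for (s in 1:10) {
    d <- randomCohort(60 + 5 * s, seed = 200 + s)
    k <- if (s %% 2) 2 else 3
    g <- sample(letters[1:k], length(d$time), TRUE)
    lt <- logrankTest(d$time, d$event, g)
    sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
    expect_equal(lt$statistic, sd$chisq, tolerance = 1e-10)
    expect_equal(lt$df, k - 1L)
    expect_equal(lt$p.value,
                 pchisq(sd$chisq, k - 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("log-rank is zero for symmetric groups and invariant to labels", {
  # label-balanced duplication: both groups see identical survival
  time <- c(3, 5, 8, 12, 20, 3, 5, 8, 12, 20)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1)
  g <- rep(c("a", "b"), each = 5)
  expect_equal(logrankTest(time, event, g)$statistic, 0, tolerance = 1e-12)
  # permuting the label alphabet does not change the statistic
  d <- randomCohort(80, seed = 5)
  g2 <- sample(c("x", "y", "z"), 80, TRUE)
  s1 <- logrankTest(d$time, d$event, g2)$statistic
  relabeled <- c(x = "z", y = "x", z = "y")[g2]
  expect_equal(logrankTest(d$time, d$event, relabeled)$statistic, s1)
  expect_error(logrankTest(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("binary cutpoint search separates a forced split", {
  # marker cleanly separates early failures from late failures at 0.02
  set.seed(12)
  n <- 40
  marker <- c(runif(n / 2, 0.001, 0.015), runif(n / 2, 0.025, 0.06))
  time <- c(rexp(n / 2, 0.5), rexp(n / 2, 0.02))
  event <- rep(1L, n)
  r <- maxstatBinary(marker, time, event, labels = c("LIP-low", "LIP-high"))
  expect_gt(cutValues(r), max(marker[1:(n / 2)]))
  expect_lt(cutValues(r), min(marker[(n / 2 + 1):n]))
  expect_lt(cutPValue(r), 0.001)
  expect_equal(levels(groupLabels(r)), c("LIP-low", "LIP-high"))
  expect_error(maxstatBinary(rep(0.5, 20), rexp(20), rep(1, 20)),
               "distinct")
})

test_that("binary scan equals the exhaustive oracle", {
  for (s in 1:5) {
    d <- randomCohort(70, seed = 300 + s)
    r <- maxstatBinary(d$marker, d$time, d$event)
    o <- maxstatOracle(d$marker, d$time, d$event)
    expect_equal(unname(cutValues(r)), o$cut)
    expect_equal(maxStatistic(r), o$stat, tolerance = 1e-9)
  }
})

test_that("permutation p-value agrees with the adjusted approximation", {
  d <- randomCohort(80, seed = 9)
  rl <- maxstatBinary(d$marker, d$time, d$event, pMethod = "lausen")
  rp <- maxstatBinary(d$marker, d$time, d$event, pMethod = "permutation",
                      nPerm = 500, permSeed = 2)
  expect_true(rp@pValue > 0 && rp@pValue <= 1)
  # same selected cut either way; p-values on the same order
  expect_equal(cutValues(rl), cutValues(rp))
})

test_that("two-cut scan equals the double-loop oracle", {
  for (s in 1:3) {
    d <- randomCohort(60, seed = 400 + s)
    r <- xtileTwoCut(d$marker, d$time, d$event)
    o <- xtileOracle(d$marker, d$time, d$event)
    expect_equal(unname(cutValues(r)), o$cuts)
    expect_equal(maxStatistic(r), o$stat, tolerance = 1e-8)
    # group-size constraint honored
    expect_true(min(table(groupLabels(r))) >= 0.1 * 60)
  }
})

test_that("two-cut search respects constraints with only two true strata", {
  # monotone hazard in the marker: still returns an admissible pair
  set.seed(44)
  n <- 80
  marker <- runif(n)
  time <- rexp(n, ifelse(marker > 0.5, 0.2, 0.02))
  r <- xtileTwoCut(marker, time, rep(1L, n))
  cc <- cutValues(r)
  expect_lt(cc[1], cc[2])
  expect_true(all(cc > min(marker) & cc < max(marker)))
  expect_true(min(table(groupLabels(r))) >= 0.1 * n)
})

test_that("SIP-LH merge pools the extreme stroma groups", {
  expect_equal(as.character(mergeSipLH(
    c("SIP-low", "SIP-intermediate", "SIP-high"))),
    c("SIP-LH", "SIP-intermediate", "SIP-LH"))
  allInt <- rep("SIP-intermediate", 4)
  expect_true(all(mergeSipLH(allInt) == "SIP-intermediate"))
  set.seed(3)
  lab <- sample(c("SIP-low", "SIP-intermediate", "SIP-high"), 50, TRUE)
  merged <- mergeSipLH(lab)
  expect_equal(sum(merged == "SIP-LH"),
               sum(lab %in% c("SIP-low", "SIP-high")))
  expect_error(mergeSipLH(c("SIP-low", "weird")), "unknown")
})

test_that("combined groups implement the SIP x LIP rule", {
  expect_equal(combinedGroups("SIP-intermediate", "LIP-high"), 1L)
  expect_equal(combinedGroups("SIP-LH", "LIP-low"), 3L)
  expect_equal(combinedGroups("SIP-intermediate", "LIP-low"), 2L)
  expect_equal(combinedGroups("SIP-LH", "LIP-high"), 2L)
  expect_error(combinedGroups("SIP-LH", NA), "missing")
  expect_error(combinedGroups("nope", "LIP-low"), "unknown SIP")
})
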