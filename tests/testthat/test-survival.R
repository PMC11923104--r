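test_that("perioperative mortality is excluded by the 30-day rule", {
  d <- data.frame(os_days = c(20, 20, 45, 31, 50),
                  os_months = c(0.66, 0.66, 1.5, 1.02, 1.64),
                  event = c(1, 0, 1, 1, NA))
  suppressMessages(out <- filterCohort(d))
  # death at day 20 excluded; censored day-20 record retained; death at
  # day 31 retained; missing-event record dropped
  expect_equal(nrow(out), 3L)
  expect_equal(out$os_days, c(20, 45, 31))
  expect_false(any(out$event == 1 & out$os_days <= 30))
  # month-only fallback
  d2 <- data.frame(os_months = c(0.5, 0.5, 3), event = c(1, 0, 1))
  suppressMessages(out2 <- filterCohort(d2))
  expect_equal(out2$os_months, c(0.5, 3))
  # clean cohorts unchanged
  d3 <- data.frame(os_months = c(5, 9), event = c(1, 0))
  expect_identical(filterCohort(d3), d3)
  expect_error(suppressMessages(
    filterCohort(data.frame(os_months = 0.2, event = 1))), "all records")
})

test_that("KM estimates match hand-computed product limits", {
  # single subject, event at 5: survival drops 1 -> 0, median 5
  s1 <- kmFit(5, 1)
  expect_equal(medianOS(s1), 5)
  expect_equal(kmCurve(s1)$surv, 0)

  # classic 6-subject worked example: times 6, 4.5+, 7, 9+, 3, 10
  time <- c(6, 4.5, 7, 9, 3, 10)
  event <- c(1, 0, 1, 0, 1, 1)
  s <- kmFit(time, event)
  cv <- kmCurve(s)
  # hand-computed product-limit at event times 3, 6, 7, 10:
  # 5/6, 5/6*3/4, 5/6*3/4*2/3, 0
  handS <- c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0)
  expect_equal(cv$surv[cv$nEvent > 0], handS)
  expect_equal(medianOS(s), 7)   # first time with survival <= 0.5
  expect_equal(s@n, 6L)
  expect_error(kmFit(c(1, 2), c(0, 0)), "event")
})

test_that("KM median matches the exponential closed form", {
  set.seed(8)
  lambda <- 0.05
  t <- rexp(2000, lambda)
  s <- kmFit(t, rep(1L, 2000))
  expect_lt(abs(medianOS(s) - log(2) / lambda) / (log(2) / lambda), 0.1)
  # CI brackets the median
  expect_true(medianCI(s)[1] <= medianOS(s) &&
                medianOS(s) <= medianCI(s)[2])
})

test_that("group comparison reports log-rank p and first-vs-rest contrasts", {
  set.seed(15)
  n <- 1200
  grp <- sample(1:3, n, TRUE)
  rate <- c(0.02, 0.05, 0.09)[grp]
  d <- data.frame(os_months = rexp(n, rate), event = 1L, group = grp)
  cmp <- compareGroups(d, "group")
  expect_lt(cmp$logrank_p, 1e-6)
  expect_named(cmp$groups, c("1", "2", "3"))
  hr <- cmp$contrasts
  h12 <- hr$hr[hr$contrast == "1 vs 2"]
  h13 <- hr$hr[hr$contrast == "1 vs 3"]
  # ordered hazards: HR(1v3) < HR(1v2) < 1
  expect_lt(h13, h12)
  expect_lt(h12, 1)
  expect_true("1 vs others" %in% hr$contrast)

  # identical groups (same survival data duplicated): p = 1, HR = 1
  base <- data.frame(os_months = rep(c(4, 8, 15, 30, 6, 20), 20),
                     event = rep(c(1, 1, 0, 1, 1, 0), 20))
  d2 <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  cmp2 <- compareGroups(d2, "group")
  expect_gt(cmp2$logrank_p, 0.95)
  expect_equal(cmp2$contrasts$hr[1], 1, tolerance = 0.05)
})

test_that("Cox screens recover generating effects and flag degeneracies", {
  set.seed(23)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  d <- data.frame(os_months = rexp(n, 0.03 * 2^x), event = 1L,
                  x = x, noise = noise, konst = 1)
  uni <- coxUnivariate(d, c("x", "noise", "konst"))
  expect_lt(abs(uni$hr[uni$variable == "x"] - 2), 0.2)
  expect_lt(abs(log(uni$hr[uni$variable == "noise"])), 0.1)
  expect_false(uni$converged[uni$variable == "konst"])

  # single selected variable: multivariate equals univariate
  multi1 <- coxMultivariate(d, "x")
  expect_equal(multi1$hr, uni$hr[uni$variable == "x"], tolerance = 1e-10)

  # carry-forward keeps only p < 0.05 variables
  cf <- coxCarryForward(d, c("x", "noise", "konst"))
  expect_true("x" %in% cf$selected)
  expect_false("konst" %in% cf$selected)
  expect_true(all(cf$multivariate$variable %in% cf$selected))
})

test_that("joint Cox fits adjust confounded copies toward the truth", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  copy <- x + rnorm(n, 0, 0.3)      # noisy copy, no own effect
  d <- data.frame(os_months = rexp(n, 0.03 * exp(-0.7 * x)), event = 1L,
                  x = x, copy = copy)
  uni <- coxUnivariate(d, c("x", "copy"))
  multi <- coxMultivariate(d, c("x", "copy"))
  # marginal effect of the copy is attenuated toward HR 1 after adjustment
  margCopy <- log(uni$hr[uni$variable == "copy"])
  adjCopy <- log(multi$hr[multi$variable == "copy"])
  expect_lt(abs(adjCopy), abs(margCopy))
  expect_lt(abs(log(multi$hr[multi$variable == "x"]) - (-0.7)), 0.15)
  # exactly collinear selection errors with a diagnostic
  d$dup <- d$x
  expect_error(coxMultivariate(d, c("x", "dup")), "collinear")
})

test_that("baseline tables use the right test per covariate type", {
  set.seed(41)
  n <- 500
  g <- rep(c("a", "b"), n / 2)
  d <- data.frame(group = g,
                  shifted = rnorm(n) + (g == "b"),
                  flat = rnorm(n),
                  cat = sample(c("x", "y"), n, TRUE),
                  ord = factor(sample(1:3, n, TRUE), ordered = TRUE))
  tab <- groupBaselineTables(d, "group", continuous = c("shifted", "flat"),
                             categorical = c("cat", "ord"))
  expect_equal(tab$test[tab$variable == "shifted"], "mann-whitney")
  expect_lt(tab$p[tab$variable == "shifted"], 1e-6)
  expect_gt(tab$p[tab$variable == "flat"], 0.01)
  expect_equal(tab$test[tab$variable == "cat"], "chi-square")
  expect_equal(tab$test[tab$variable == "ord"], "linear-by-linear")

  # hand-checked 2x2 chi-square: [[10,20],[20,10]] -> 20/3 uncorrected
  d2 <- data.frame(group = rep(c("a", "b"), each = 30),
                   v = c(rep("x", 10), rep("y", 20),
                         rep("x", 20), rep("y", 10)))
  tab2 <- groupBaselineTables(d2, "group", categorical = "v")
  expect_equal(tab2$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(tab2$statistic,
               unname(chisq.test(table(d2$v, d2$group),
                                 correct = FALSE)$statistic))
  expect_warning(
    groupBaselineTables(cbind(d2, miss = NA_real_), "group",
                        continuous = "miss"), "all-missing")
})
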