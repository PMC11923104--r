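# Independent oracles: deliberately brute-force implementations kept
# separate from the package's own code paths.

# Per-pixel even-odd point-in-polygon via ray casting to +x.
pipOracle <- function(poly, width, height) {
  out <- matrix(FALSE, height, width)
  px <- poly[, 1]; py <- poly[, 2]
  nx <- c(px[-1], px[1]); ny <- c(py[-1], py[1])
  for (r in seq_len(height)) {
    for (cc in seq_len(width)) {
      x <- cc - 0.5; y <- r - 0.5
      cross <- 0L
      for (e in seq_along(px)) {
        if ((py[e] <= y) != (ny[e] <= y)) {
          xc <- px[e] + (y - py[e]) * (nx[e] - px[e]) / (ny[e] - py[e])
          if (x < xc) cross <- cross + 1L
        }
      }
      out[r, cc] <- (cross %% 2L) == 1L
    }
  }
  out
}

# Log-rank (Nelson-Aalen) scores, nested-loop implementation.
scoresOracle <- function(time, event) {
  n <- length(time)
  sc <- numeric(n)
  uts <- sort(unique(time[event == 1]))
  for (i in seq_len(n)) {
    L <- 0
    for (tt in uts[uts <= time[i]]) {
      L <- L + sum(time == tt & event == 1) / sum(time >= tt)
    }
    sc[i] <- event[i] - L
  }
  sc
}

# Standardized rank statistic for the split marker <= cut, from
# precomputed scores.
zFromScores <- function(a, marker, cut) {
  n <- length(marker)
  lo <- marker <= cut
  m <- sum(lo)
  S <- sum(a[lo])
  abar <- mean(a)
  v <- m * (n - m) / (n * (n - 1)) * sum((a - abar)^2)
  (S - m * abar) / sqrt(v)
}

# Exhaustive binary maximally-selected scan.
maxstatOracle <- function(marker, time, event, minfrac = 0.1) {
  a <- scoresOracle(time, event)
  v <- sort(unique(marker))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(marker)
  best <- -Inf; bc <- NA_real_
  for (cc in cand) {
    m <- sum(marker <= cc)
    if (min(m, n - m) < minfrac * n) next
    z <- abs(zFromScores(a, marker, cc))
    if (z > best + 1e-10) { best <- z; bc <- cc }
  }
  list(cut = bc, stat = best)
}

# Exhaustive double-loop two-cut scan scored by survival::survdiff.
xtileOracle <- function(marker, time, event, minfrac = 0.1) {
  v <- sort(unique(marker))
  cand <- (v[-1] + v[-length(v)]) / 2
  n <- length(marker)
  best <- -Inf; bc <- c(NA_real_, NA_real_)
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (j <= i) next
      g <- 1 + (marker > cand[i]) + (marker > cand[j])
      if (min(tabulate(g, 3L)) < minfrac * n) next
      st <- survival::survdiff(survival::Surv(time, event) ~ g)$chisq
      if (st > best + 1e-9) { best <- st; bc <- c(cand[i], cand[j]) }
    }
  }
  list(cuts = bc, stat = best)
}

# Random survival cohort for oracle comparisons.
randomCohort <- function(n, seed) {
  set.seed(seed)
  list(marker = round(runif(n), 2),
       time = round(rexp(n, 0.05), 1) + 0.1,
       event = rbinom(n, 1, 0.75))
}

# A small labeled training tile at scene-generator defaults.
mkTrainTile <- function(seed, spec = tileSpec()) {
  sc <- generateTileScene(sceneParams(imageSize = c(396L, 396L),
                                      seed = seed))
  list(x = sc$image, y = cropToOutput(sc$mask, spec))
}

# Tiny U-Net geometry that is valid and fast (32 -> 16 at depth 1).
tinySpec <- function(dropoutRate = 0.1) {
  unetSpec(depth = 1L, baseChannels = 4L, inputPx = 32L,
           dropoutRate = dropoutRate)
}
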