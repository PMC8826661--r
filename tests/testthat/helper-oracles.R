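# Fixture builders and independent brute-force oracles used across tests.
# Oracles deliberately avoid the package's analytic crossing formulas:
# integrals use dense sub-sampling of the piecewise-linear trace, and
# threshold crossings are located numerically with uniroot().

t_origin <- as.POSIXct("2021-06-01 00:00:00", tz = "UTC")

make_trace <- function(hours, glucose, id = "P1") {
  as_cgm_trace(tibble::tibble(participant_id = id,
                              time = t_origin + hours * 3600,
                              glucose = glucose))
}

# Regular 15-min one-day trace from a glucose vector (recycled)
day_trace <- function(glucose, id = "P1") {
  hours <- seq(0, 24 - 0.25, by = 0.25)
  make_trace(hours, rep_len(glucose, length(hours)), id)
}

# Random smooth one-day trace with bump excursions at given meal hours so
# meal iAUCs are well away from zero.
random_day_trace <- function(seed, meal_hours = c(8, 13, 19)) {
  set.seed(seed)
  hours <- seq(0, 24 - 0.25, by = 0.25)
  level <- 120 + runif(1, -15, 15)
  noise <- as.numeric(stats::filter(rnorm(length(hours), 0, 4), 0.8,
                                    method = "recursive"))
  g <- level + noise
  for (h in meal_hours) {
    s <- (hours - h) / 2
    w <- s >= 0 & s <= 1
    g[w] <- g[w] + runif(1, 30, 80) * sin(pi * s[w])^2
  }
  make_trace(hours, pmin(pmax(g, 40), 400))
}

# Brute-force positive-part integral of the interpolated trace minus
# baseline over [from, to] (hours), by dense per-segment sub-sampling.
oracle_iauc <- function(trace, from, to, baseline = NULL, nsub = 2^17,
                        clip = TRUE) {
  hours <- as.numeric(trace$time - t_origin, units = "hours")
  f <- approxfun(hours, trace$glucose)
  if (is.null(baseline)) baseline <- f(from)
  knots <- sort(unique(c(from, to, hours[hours > from & hours < to])))
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    grid <- seq(knots[i], knots[i + 1L], length.out = nsub)
    y <- f(grid) - baseline
    if (clip) y <- pmax(y, 0)
    total <- total + sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
  }
  total
}

# Brute-force daily hours above thresholds: numeric root-finding at
# crossings, midnight splits done by clipping segments to day bounds.
oracle_time_above <- function(trace, thresholds = c(140, 150, 160, 170, 180),
                              min_daily = 48) {
  hours <- as.numeric(trace$time - t_origin, units = "hours")
  g <- trace$glucose
  conn <- trace$connection
  days <- unique(floor(hours / 24))
  counts <- table(floor(hours / 24))
  res <- matrix(NA_real_, nrow = length(thresholds), ncol = 0)
  for (d in days) {
    if (is.na(counts[as.character(d)]) || counts[as.character(d)] < min_daily) next
    lo <- d * 24; hi <- lo + 24
    observed <- 0
    above <- numeric(length(thresholds))
    for (i in seq_len(length(hours) - 1L)) {
      if (conn[i + 1L] != conn[i]) next
      a <- max(hours[i], lo); b <- min(hours[i + 1L], hi)
      if (b <= a) next
      observed <- observed + (b - a)
      seg <- approxfun(hours[i:(i + 1L)], g[i:(i + 1L)])
      for (k in seq_along(thresholds)) {
        thr <- thresholds[k]
        fa <- seg(a) - thr; fb <- seg(b) - thr
        if (fa > 0 && fb > 0) {
          above[k] <- above[k] + (b - a)
        } else if (fa <= 0 && fb <= 0) {
          # nothing
        } else {
          r <- uniroot(function(t) seg(t) - thr, c(a, b), tol = 1e-13)$root
          above[k] <- above[k] + if (fa > 0) r - a else b - r
        }
      }
    }
    if (observed > 0) res <- cbind(res, 24 * above / observed)
  }
  if (ncol(res) == 0L) {
    return(setNames(rep(NA_real_, length(thresholds)), as.character(thresholds)))
  }
  setNames(rowMeans(res), as.character(thresholds))
}

# Brute-force blocked averaged PPGR: explicit block bookkeeping plus the
# dense-grid integral oracle per block.
oracle_averaged_ppgr <- function(trace, block = 9) {
  vals <- c()
  for (cn in unique(trace$connection)) {
    sub <- trace[trace$connection == cn, ]
    nb <- floor(nrow(sub) / block)
    for (b in seq_len(nb)) {
      rows <- ((b - 1) * block + 1):(b * block)
      blk <- sub[rows, ]
      h <- as.numeric(blk$time - t_origin, units = "hours")
      vals <- c(vals, oracle_iauc(blk, h[1], h[length(h)],
                                  baseline = blk$glucose[1], nsub = 2^14))
    }
  }
  if (length(vals) == 0L) NA_real_ else mean(vals)
}

rel_err <- function(x, ref) abs(x - ref) / pmax(abs(ref), 1e-8)

# Three-meal adherence log from the trial's printed worked example
worked_example_meals <- function() {
  tibble::tibble(
    participant_id = "P1",
    time = t_origin + c(8, 13, 19) * 3600,
    kcal = c(600, 1000, 80),
    meal_score = c(2L, 5L, 1L)
  )
}
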