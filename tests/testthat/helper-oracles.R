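# Straightforward, loop-based re-implementations of every index, written
# directly from the index definitions and kept independent of the package
# internals. Used to cross-check the vectorized implementations.

MMOL <- 18.016

o_mean <- function(g) sum(g) / length(g)

o_sd <- function(g) {
  m <- o_mean(g)
  sqrt(sum((g - m)^2) / (length(g) - 1))
}

o_tir <- function(g) {
  k <- 0
  for (v in g) if (v >= 70 && v <= 180) k <- k + 1
  100 * k / length(g)
}

o_acf <- function(g, K) {
  m <- o_mean(g)
  denom <- sum((g - m)^2)
  r <- numeric(K)
  n <- length(g)
  for (k in seq_len(K)) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + (g[t] - m) * (g[t + k] - m)
    r[k] <- s / denom
  }
  r
}

o_ac_metrics <- function(g, K) {
  r <- o_acf(g, K)
  c(mean = o_mean(r), var = sum((r - o_mean(r))^2) / (K - 1))
}

o_conga <- function(g, step_min, n_hours = 1) {
  lag <- n_hours * 60 / step_min
  d <- c()
  for (t in seq_along(g)) {
    if (t + lag <= length(g)) d <- c(d, g[t + lag] - g[t])
  }
  o_sd(d / MMOL)
}

o_li <- function(g_hourly) {
  gm <- g_hourly / MMOL
  tot <- 0
  for (i in seq_len(length(gm) - 1)) tot <- tot + (gm[i + 1] - gm[i])^2
  tot / (length(gm) - 1)
}

o_jindex <- function(g) 0.324 * ((o_mean(g) + o_sd(g)) / MMOL)^2

o_risk <- function(g) {
  f <- 1.509 * (log(g)^1.084 - 5.381)
  list(rl = ifelse(f < 0, 10 * f^2, 0), rh = ifelse(f > 0, 10 * f^2, 0))
}

o_hbgi <- function(g) o_mean(o_risk(g)$rh)

o_grade <- function(g) {
  sc <- c()
  for (v in g) {
    s <- 425 * (log10(log10(v / MMOL)) + 0.16)^2
    sc <- c(sc, min(s, 50))
  }
  o_mean(sc)
}

o_modd <- function(tt, g, tol) {
  d <- c()
  for (i in seq_along(tt)) for (j in seq_along(tt)) {
    if (abs(tt[j] - tt[i] - 1440) <= tol) d <- c(d, abs(g[j] - g[i]))
  }
  o_mean(d) / MMOL
}

# step-by-step restatement of the excursion algorithm: collapse plateaus,
# list turning points, repeatedly drop the smallest sub-threshold
# amplitude, re-enforcing alternation by scanning from scratch
o_mage <- function(g) {
  s <- o_sd(g)
  if (s == 0) return(0)
  compress <- function(v) {
    out <- v[1]
    for (x in v[-1]) if (x != out[length(out)]) out <- c(out, x)
    out
  }
  turns <- function(v) {
    if (length(v) < 3) return(numeric(0))
    keep <- rep(FALSE, length(v))
    for (i in 2:(length(v) - 1)) {
      if ((v[i] > v[i - 1] && v[i] > v[i + 1]) ||
          (v[i] < v[i - 1] && v[i] < v[i + 1])) keep[i] <- TRUE
    }
    v[keep]
  }
  alternate <- function(e) {
    repeat {
      if (length(e) < 3) return(e)
      drop <- 0
      for (i in 2:(length(e) - 1)) {
        d1 <- sign(e[i] - e[i - 1]); d2 <- sign(e[i + 1] - e[i])
        if (d1 == d2) { drop <- i; break }
      }
      if (drop == 0) return(e)
      e <- e[-drop]
    }
  }
  e <- alternate(turns(compress(g)))
  repeat {
    if (length(e) < 2) return(0)
    amps <- abs(diff(e))
    if (min(amps) >= s) break
    i <- which.min(amps)
    if (i == 1) e <- e[-1]
    else if (i == length(e) - 1) e <- e[-length(e)]
    else e <- e[-c(i, i + 1)]
    e <- alternate(e)
  }
  o_mean(abs(diff(e))) / MMOL
}

o_adrr <- function(tt, g, step_min) {
  days <- unique(floor(tt / 1440))
  vals <- c()
  for (d in days) {
    idx <- which(floor(tt / 1440) == d)
    if (length(idx) * step_min < 20 * 60) next
    r <- o_risk(g[idx])
    vals <- c(vals, max(r$rl) + max(r$rh))
  }
  o_mean(vals)
}

o_mvalue <- function(g) {
  tot <- 0
  for (v in g) tot <- tot + abs(10 * log10(v / 120))^3
  tot / length(g) + (max(g) - min(g)) / 20
}

o_mag <- function(tt, g) {
  tot <- 0
  for (i in seq_len(length(g) - 1)) tot <- tot + abs(g[i + 1] - g[i]) / MMOL
  tot / ((tt[length(tt)] - tt[1]) / 60)
}

# random uniform synthetic trace for oracle comparisons
random_trace <- function(seed, days = 2, step = 5) {
  set.seed(seed)
  n <- days * 24 * 60 / step
  tt <- (seq_len(n) - 1) * step
  mu <- runif(1, 90, 170)
  phi <- runif(1, 0.7, 0.95)
  g <- mu + as.numeric(stats::filter(rnorm(n, 0, runif(1, 3, 10)), phi,
                                     "recursive"))
  bumps <- runif(days * 3, 0, 60)
  onsets <- sort(runif(days * 3, 0, max(tt)))
  for (k in seq_along(onsets)) {
    u <- (tt - onsets[k]) / 40
    g <- g + bumps[k] * ifelse(u > 0, u * exp(1 - u), 0)
  }
  g <- pmax(g, 45)
  glucose_trace(paste0("R", seed), tt, g, step)
}
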