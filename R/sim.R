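#' Parameters of the delay-integral glucose-insulin model
#'
#' The model couples glucose G (mg/dL) and insulin I (arbitrary
#' insulin-units) through
#' \deqn{dG/dt = -k_{glu} G - k_{sen} I G + k_{pro} + f(t)}
#' \deqn{dI/dt = (k_{sec}/k_{tim}) \int_{t-k_{tim}}^{t} G\,ds - k_{cle} I}
#' so insulin secretion responds to the average glucose over the trailing
#' `k_tim` minutes (a distributed delay), and insulin accelerates glucose
#' disposal. `f(t)` is an external glucose appearance rate; the default is
#' a 5 mg/dL/min bolus on [30, 40) min.
#'
#' @param k_glu Insulin-independent glucose clearance, 1/min.
#' @param k_sen Insulin-dependent disposal, per (insulin-unit x min).
#' @param k_pro Endogenous glucose production, mg/dL/min.
#' @param k_sec Secretion gain, insulin-unit/(mg/dL x min).
#' @param k_tim Secretion averaging window, min (> 0).
#' @param k_cle Insulin clearance, 1/min.
#' @param input Function of time (min) giving f(t) in mg/dL/min, or NULL
#'   for the default bolus.
#' @param horizon Simulation length, min.
#' @param step Integration step, min.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(k_glu = 0.01, k_sen = 1e-4, k_pro = 1.0,
                       k_sec = 0.02, k_tim = 60, k_cle = 0.1,
                       input = NULL, horizon = 240, step = 0.1) {
  stopifnot(k_glu >= 0, k_sen >= 0, k_pro >= 0, k_sec >= 0,
            k_tim > 0, k_cle >= 0, horizon > 0, step > 0)
  if (is.null(input))
    input <- function(t) ifelse(t >= 30 & t < 40, 5, 0)
  structure(list(k_glu = k_glu, k_sen = k_sen, k_pro = k_pro,
                 k_sec = k_sec, k_tim = k_tim, k_cle = k_cle,
                 input = input, horizon = horizon, step = step),
            class = "sim_params")
}

#' Basal steady state of the model
#'
#' With f = 0 the secretion integral of a constant G equals k_tim * G, so
#' I* = (k_sec / k_cle) G* and G* is the positive root of
#' k_sen (k_sec/k_cle) G^2 + k_glu G - k_pro = 0 (linear when the
#' quadratic coefficient vanishes).
#'
#' @param params A [sim_params].
#' @return Named vector `c(G, I)`.
#' @export
steady_state <- function(params) {
  p <- params
  if (p$k_cle <= 0) stop("k_cle must be positive for a steady state")
  if (p$k_pro <= 0) stop("no positive steady state: k_pro = 0")
  a <- p$k_sen * p$k_sec / p$k_cle
  b <- p$k_glu
  if (a == 0) {
    if (b == 0) stop("no positive steady state: no glucose clearance")
    G <- p$k_pro / b
  } else {
    G <- (-b + sqrt(b^2 + 4 * a * p$k_pro)) / (2 * a)
  }
  c(G = G, I = p$k_sec / p$k_cle * G)
}

#' Simulate the delay-integral glucose-insulin model
#'
#' Classical fixed-step 4th-order Runge-Kutta with the distributed-delay
#' term evaluated through the cumulative glucose integral Z(t) =
#' int_0^t G ds: the trailing-window integral is Z(t) - Z(t - k_tim),
#' with the pre-history G(s <= 0) = G(0) contributing analytically and
#' lagged values of Z read from the stored grid by linear interpolation.
#' Initial conditions default to the basal steady state.
#'
#' @param params A [sim_params].
#' @param G0,I0 Initial state; default the steady state.
#' @param summary_sampling Minutes between samples of G used for the
#'   summary statistics (default 5, the common CGM interval).
#' @return A list of class `sim_result`: `time`, `G`, `I` on the
#'   integration grid, and `summary` = mean, Std and AC_Var of G sampled
#'   every `summary_sampling` min (AC lags span 150 min, as for CGM).
#' @export
simulate_glucose <- function(params, G0 = NULL, I0 = NULL,
                             summary_sampling = 5) {
  p <- params
  if (p$step > p$k_tim / 4) stop("delay under-resolved: step > k_tim/4")
  ss <- tryCatch(steady_state(p), error = function(e) NULL)
  if (is.null(G0)) G0 <- if (!is.null(ss)) ss[["G"]] else 100
  if (is.null(I0)) I0 <- if (!is.null(ss)) ss[["I"]] else 0
  n <- floor(p$horizon / p$step) + 1L
  tg <- (seq_len(n) - 1L) * p$step
  G <- numeric(n); I <- numeric(n); Z <- numeric(n)
  G[1] <- G0; I[1] <- I0; Z[1] <- 0

  # trailing integral of G over [t - k_tim, t]; Zt is the cumulative
  # integral at time t, Zfun interpolates stored Z on [0, t]
  window_int <- function(t, Zt, Zhist, upto) {
    t0 <- t - p$k_tim
    if (t0 <= 0) return(Zt + (-t0) * G0)
    # linear interpolation of Z at t0 from the stored grid
    i <- floor(t0 / p$step) + 1
    i <- min(max(i, 1L), upto - 1L)
    w <- (t0 - tg[i]) / p$step
    Zt - ((1 - w) * Zhist[i] + w * Zhist[i + 1])
  }

  derivs <- function(t, g, ii, z, Zhist, upto) {
    wi <- window_int(t, z, Zhist, upto)
    c(dG = -p$k_glu * g - p$k_sen * ii * g + p$k_pro + p$input(t),
      dI = p$k_sec / p$k_tim * wi - p$k_cle * ii,
      dZ = g)
  }

  for (k in seq_len(n - 1L)) {
    t <- tg[k]; h <- p$step
    y <- c(G[k], I[k], Z[k])
    k1 <- derivs(t,         y[1],              y[2],              y[3],              Z, k)
    k2 <- derivs(t + h / 2, y[1] + h / 2 * k1[1], y[2] + h / 2 * k1[2], y[3] + h / 2 * k1[3], Z, k)
    k3 <- derivs(t + h / 2, y[1] + h / 2 * k2[1], y[2] + h / 2 * k2[2], y[3] + h / 2 * k2[3], Z, k)
    k4 <- derivs(t + h,     y[1] + h * k3[1],     y[2] + h * k3[2],     y[3] + h * k3[3],     Z, k)
    ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (ynew[1] <= 0)
      stop(sprintf("negative glucose at t = %.2f; diagnostics: G = %.4g, I = %.4g",
                   t + h, ynew[1], ynew[2]))
    G[k + 1] <- ynew[1]; I[k + 1] <- ynew[2]; Z[k + 1] <- ynew[3]
  }

  res <- list(time = tg, G = G, I = I,
              summary = sim_summary(tg, G, summary_sampling))
  class(res) <- "sim_result"
  res
}

# mean, Std and AC_Var of G sampled on an even coarse grid
sim_summary <- function(tg, G, sampling) {
  idx <- which(abs((tg / sampling) - round(tg / sampling)) < 1e-9)
  g5 <- G[idx]
  K <- as.integer(round(150 / sampling))
  acv <- if (length(g5) > K + 1 && stats::var(g5) > 0) {
    tr <- glucose_trace("sim", (seq_along(g5) - 1) * sampling, g5, sampling)
    ac_metrics(trace_acf(tr, K))[["AC_Var"]]
  } else NA_real_
  c(mean = mean(g5), sd = stats::sd(g5), AC_Var = acv)
}

#' @method print sim_result
#' @export
print.sim_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sim_result> %d steps to %g min; G mean %.2f, Std %.3f, AC_Var %.4g\n",
              length(x$time), max(x$time), s[["mean"]], s[["sd"]], s[["AC_Var"]]))
  invisible(x)
}

#' Find trace pairs in which exactly one glucose-dynamics component moves
#'
#' Grid-searches the model's parameter space and returns, for each of the
#' three components (mean, Std, AC_Var of simulated glucose), a pair of
#' simulations in which that component differs by at least
#' `differ_margin` (relative) while the other two agree within
#' `match_tol` (relative). This demonstrates that the three components of
#' glucose dynamics are independently adjustable.
#'
#' @param base A [sim_params] giving defaults for parameters not swept.
#' @param ranges Named list of parameter ranges, each `c(lo, hi)`, over
#'   the `sim_params` rate constants. Default ranges span plausible
#'   normal-glucose-tolerance physiology around `base`.
#' @param n_grid Grid points per swept parameter (default 4).
#' @param differ_margin Minimum relative difference for the moving
#'   component (default 0.2).
#' @param match_tol Maximum relative difference for the two matched
#'   components (default 0.05).
#' @param mean_range Simulations whose glucose mean falls outside this
#'   physiological window (mg/dL) are excluded from pairing.
#' @return Named list over `c("mean", "sd", "AC_Var")`; each element has
#'   the two parameter sets (`params_a`, `params_b`) and their summaries.
#' @export
component_sweep <- function(base = sim_params(step = 0.5),
                            ranges = default_sweep_ranges(base),
                            n_grid = 4, differ_margin = 0.2,
                            match_tol = 0.05, mean_range = c(50, 300)) {
  if (!length(ranges)) stop("ranges must be non-empty")
  degenerate <- vapply(ranges, function(r) diff(range(r)) == 0, logical(1))
  if (all(degenerate)) stop("degenerate ranges: no grid to search")
  # a range may be c(lo, hi) (expanded to n_grid log-spaced points) or an
  # explicit vector of grid values
  axes <- lapply(ranges, function(r) {
    if (length(r) > 2) r
    else exp(seq(log(r[1]), log(r[2]), length.out = n_grid))
  })
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  sims <- vector("list", nrow(grid))
  summ <- matrix(NA_real_, nrow(grid), 3,
                 dimnames = list(NULL, c("mean", "sd", "AC_Var")))
  for (i in seq_len(nrow(grid))) {
    p <- base
    for (nm in names(grid)) p[[nm]] <- grid[i, nm]
    class(p) <- "sim_params"
    r <- tryCatch(simulate_glucose(p), error = function(e) NULL)
    if (is.null(r)) next
    sims[[i]] <- p
    summ[i, ] <- r$summary
  }
  # keep simulations with a physiologically plausible glucose level
  ok <- which(stats::complete.cases(summ) &
                summ[, "mean"] >= mean_range[1] &
                summ[, "mean"] <= mean_range[2])
  if (length(ok) < 2) stop("fewer than 2 usable simulations in the grid")
  comps <- c("mean", "sd", "AC_Var")
  rel_mat <- function(v) {
    d <- abs(outer(v, v, "-")) / pmax(outer(abs(v), abs(v), pmax), 1e-300)
    d
  }
  rels <- lapply(comps, function(cc) rel_mat(summ[ok, cc]))
  names(rels) <- comps
  out <- stats::setNames(vector("list", 3), comps)
  closest <- stats::setNames(rep(Inf, 3), comps)
  for (target in comps) {
    others <- setdiff(comps, target)
    hit <- which(rels[[target]] >= differ_margin &
                   rels[[others[1]]] <= match_tol &
                   rels[[others[2]]] <= match_tol &
                   upper.tri(rels[[target]]), arr.ind = TRUE)
    if (nrow(hit)) {
      a <- ok[hit[1, 1]]; b <- ok[hit[1, 2]]
      i1 <- hit[1, 1]; i2 <- hit[1, 2]
      out[[target]] <- list(
        params_a = sims[[a]], params_b = sims[[b]],
        summary_a = summ[a, ], summary_b = summ[b, ],
        rel_diff = stats::setNames(
          c(rels[[target]][i1, i2], rels[[others[1]]][i1, i2],
            rels[[others[2]]][i1, i2]), c(target, others)))
    } else {
      sc <- pmax(rels[[others[1]]], rels[[others[2]]]) +
        pmax(0, differ_margin - rels[[target]])
      closest[target] <- min(sc[upper.tri(sc)])
    }
  }
  missing <- comps[vapply(out, is.null, logical(1))]
  if (length(missing))
    stop("no qualifying pair for: ", paste(missing, collapse = ", "),
         "; closest candidate scores: ",
         paste(sprintf("%s=%.3g", missing, closest[missing]), collapse = ", "))
  out
}

#' Default parameter ranges for [component_sweep]
#'
#' Plausible spans around the base parameters for non-diabetic
#' physiology. Glucose clearance and production (k_glu, k_pro) move the
#' level and, jointly, the damping of the bolus response; the
#' secretion-delay window and insulin clearance (k_tim, k_cle) shape the
#' autocorrelation of the response at nearly fixed level and spread.
#' Each axis is an explicit grid so the sweep covers compensated
#' combinations (e.g. fast clearance with high production).
#'
#' @param base A [sim_params].
#' @return Named list of grid-value vectors.
#' @export
default_sweep_ranges <- function(base = sim_params()) {
  list(k_glu = base$k_glu * c(0.5, 1, 2, 4),
       k_pro = base$k_pro * c(0.5, 1, 2, 4),
       k_sen = base$k_sen * c(0.5, 1, 2, 4),
       k_sec = base$k_sec * c(0.5, 1, 2, 4),
       k_tim = base$k_tim * c(0.5, 1, 2),
       k_cle = base$k_cle * c(0.5, 1, 2))
}
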