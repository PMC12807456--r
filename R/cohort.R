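# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate one synthetic CGM trace (AR(1) + meals)
#'
#' Glucose is mu + X_t + meal bumps, where X_t is a stationary AR(1)
#' process with coefficient `phi` and innovation scale `sigma`, sampled
#' every `sampling_interval` minutes. Three meal excursions per day
#' (gamma-shaped bumps peaking ~45 min after onset) are placed near
#' 08:00, 13:00 and 19:00 with timing jitter. Values are floored at
#' 40 mg/dL. Deterministic given `seed`.
#'
#' @param subject_id Subject identifier.
#' @param mu Baseline glucose level, mg/dL.
#' @param sigma AR(1) innovation standard deviation, mg/dL.
#' @param phi AR(1) coefficient in [0, 1).
#' @param meal_amp Peak meal excursion height, mg/dL (0 disables meals).
#' @param days Number of simulated days.
#' @param sampling_interval Minutes between readings.
#' @param seed Integer seed.
#' @param meal_jitter_sd Std of meal-onset jitter, minutes.
#' @return A [glucose_trace].
#' @export
generate_trace <- function(subject_id, mu, sigma, phi, meal_amp = 0,
                           days = 3, sampling_interval = 5, seed = 0,
                           meal_jitter_sd = 30) {
  stopifnot(phi >= 0, phi < 1, sigma >= 0, days >= 1)
  with_seed(seed, {
    n <- as.integer(days * 24 * 60 / sampling_interval)
    tt <- (seq_len(n) - 1L) * sampling_interval
    x <- if (sigma > 0) {
      innov <- stats::rnorm(n, 0, sigma)
      x0 <- stats::rnorm(1, 0, sigma / sqrt(1 - phi^2))
      as.numeric(stats::filter(innov, phi, method = "recursive",
                               init = x0))
    } else rep(0, n)
    g <- mu + x
    if (meal_amp > 0) {
      onsets <- as.vector(outer(c(8, 13, 19) * 60,
                                (seq_len(days) - 1L) * 1440, "+")) +
        stats::rnorm(3L * days, 0, meal_jitter_sd)
      for (m in onsets) {
        u <- (tt - m) / 45
        bump <- ifelse(u > 0, u * exp(1 - u), 0)
        g <- g + meal_amp * bump
      }
    }
    g <- pmax(g, 40)
    glucose_trace(as.character(subject_id), tt, g, sampling_interval)
  })
}

#' Specification for a synthetic cohort
#'
#' Defaults emulate the structure of the clinical study cohort: 8 NGT,
#' 16 IGT and 29 T2DM subjects, each with at least three consecutive
#' days of 5-min CGM, and a continuous plaque-vulnerability outcome
#' driven by three latent components of the glucose traces via
#' \%NC = b0 + b_mean z(mean) + b_var z(Std) + b_ac z(AC_Var) + e,
#' e ~ N(0, sigma_nc), truncated to [0, 100].
#'
#' @param n_ngt,n_igt,n_t2dm Class sizes (defaults 8/16/29).
#' @param days CGM days per subject (default 3).
#' @param sampling_interval Minutes (default 5).
#' @param beta Named numeric: intercept `b0` and component coefficients
#'   `b_mean`, `b_var`, `b_ac` on the z-scored empirical components.
#' @param sigma_nc Outcome noise Std, \%NC points.
#' @param class_params Per-class distributions of the trace parameters:
#'   a list with one row-list per class giving the normal mean/sd of mu,
#'   sigma, meal amplitude and the uniform range of phi.
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_ngt = 8, n_igt = 16, n_t2dm = 29, days = 3,
                        sampling_interval = 5,
                        beta = c(b0 = 18, b_mean = 4, b_var = 3, b_ac = 3),
                        sigma_nc = 4,
                        class_params = default_class_params(),
                        seed = 0) {
  stopifnot(n_ngt >= 0, n_igt >= 0, n_t2dm >= 0,
            n_ngt + n_igt + n_t2dm >= 2, sigma_nc > 0)
  structure(list(n_ngt = n_ngt, n_igt = n_igt, n_t2dm = n_t2dm,
                 days = days, sampling_interval = sampling_interval,
                 beta = beta, sigma_nc = sigma_nc,
                 class_params = class_params, seed = seed),
            class = "cohort_spec")
}

#' Default per-class trace-parameter distributions
#'
#' Baseline level, variability and meal size increase from NGT through
#' IGT to T2DM; the AR coefficient (hence trace autocorrelation) varies
#' across the same range in every class, reflecting the low
#' multicollinearity of the autocorrelation component with mean and
#' variance.
#'
#' @return Named list of per-class parameter distributions.
#' @export
default_class_params <- function() {
  list(
    NGT  = list(mu = c(100, 8),  sigma = c(4, 1),  meal = c(30, 8),
                phi = c(0.80, 0.97)),
    IGT  = list(mu = c(130, 10), sigma = c(7, 1.5), meal = c(50, 12),
                phi = c(0.80, 0.97)),
    T2DM = list(mu = c(165, 20), sigma = c(11, 2.5), meal = c(70, 18),
                phi = c(0.80, 0.97))
  )
}

# diagnostic windows per class: HbA1c, FPG, PG120 (lo, hi)
CLASS_WINDOWS <- list(
  NGT  = list(hba1c = c(4.8, 5.99), fpg = c(75, 109.9), pg120 = c(80, 139.9)),
  IGT  = list(hba1c = c(6.0, 6.4),  fpg = c(110, 125.9), pg120 = c(140, 199.9)),
  T2DM = list(hba1c = c(6.5, 11),   fpg = c(126, 220),   pg120 = c(200, 350))
)

rnorm_window <- function(n, mean, sd, lo, hi, cap = 50) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- stats::rnorm(1, mean, sd); tries <- 1
    while ((v < lo || v > hi) && tries < cap) {
      v <- stats::rnorm(1, mean, sd); tries <- tries + 1
    }
    if (v < lo || v > hi) {
      warning("class threshold resampling cap hit; clamping")
      v <- min(max(v, lo), hi)
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic cohort
#'
#' Produces per-subject CGM traces, empirical glucose-dynamics components
#' (mean, Std, AC_Var of each trace), conventional glycemic markers
#' (FBG, HbA1c, PG120) that are class-consistent and driven by the mean
#' component only, OGTT glucose/insulin samples, inert covariates (BMI,
#' SBP, DBP, TG, LDL-C, HDL-C), and the \%NC outcome from the spec's
#' three-component linear model. Full generation metadata (true
#' coefficients and per-subject components) is returned for recovery
#' tests.
#'
#' @param spec A [cohort_spec].
#' @param panel Compute the full 15-value CGM index panel per subject
#'   (slower; needed for factor/clustering analyses).
#' @return List with `traces`, `cohort` (data.frame), and `truth`
#'   (list: `beta`, `sigma_nc`, per-subject `components` and trace
#'   parameters).
#' @export
generate_cohort <- function(spec = cohort_spec(), panel = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- rep(c("NGT", "IGT", "T2DM"),
                 c(spec$n_ngt, spec$n_igt, spec$n_t2dm))
  n <- length(classes)
  with_seed(spec$seed, {
    pars <- lapply(seq_len(n), function(i) {
      cp <- spec$class_params[[classes[i]]]
      list(mu = stats::rnorm(1, cp$mu[1], cp$mu[2]),
           sigma = max(stats::rnorm(1, cp$sigma[1], cp$sigma[2]), 0.5),
           meal = max(stats::rnorm(1, cp$meal[1], cp$meal[2]), 0),
           phi = stats::runif(1, cp$phi[1], cp$phi[2]))
    })
    trace_seeds <- sample.int(.Machine$integer.max, n)
    outcome_noise <- stats::rnorm(n, 0, spec$sigma_nc)
    marker_noise <- matrix(stats::rnorm(3 * n), n, 3)
    insulin_noise <- matrix(stats::rnorm(2 * n, 1, 0.15), n, 2)
    covars <- data.frame(
      BMI = stats::rnorm(n, 24, 3), SBP = stats::rnorm(n, 125, 10),
      DBP = stats::rnorm(n, 75, 8), TG = stats::rnorm(n, 130, 35),
      LDLC = stats::rnorm(n, 95, 15), HDLC = stats::rnorm(n, 52, 10))
    markers <- do.call(rbind, lapply(seq_len(n), function(i) {
      w <- CLASS_WINDOWS[[classes[i]]]
      mu <- pars[[i]]$mu
      data.frame(
        FBG = rnorm_window(1, 0.72 * mu + 22, 8, w$fpg[1], w$fpg[2]),
        HbA1c = rnorm_window(1, 3.1 + 0.023 * mu, 0.3, w$hba1c[1],
                             w$hba1c[2]),
        PG120 = rnorm_window(1, 1.25 * mu, 18, w$pg120[1], w$pg120[2]))
    }))
    traces <- vector("list", n)
    comp <- matrix(NA_real_, n, 3,
                   dimnames = list(NULL, c("CGM_Mean", "CGM_Std", "AC_Var")))
    for (i in seq_len(n)) {
      p <- pars[[i]]
      tr <- generate_trace(sprintf("S%03d", i), p$mu, p$sigma, p$phi,
                           p$meal, spec$days, spec$sampling_interval,
                           seed = trace_seeds[i])
      traces[[i]] <- tr
      s <- summary_stats(tr)
      K <- ac_lag_window(tr$sampling_interval)
      comp[i, ] <- c(s[["CGM_Mean"]], s[["CGM_Std"]],
                     ac_metrics(trace_acf(tr, K))[["AC_Var"]])
    }
    z <- scale(comp)
    b <- spec$beta
    nc <- b[["b0"]] + b[["b_mean"]] * z[, 1] + b[["b_var"]] * z[, 2] +
      b[["b_ac"]] * z[, 3] + outcome_noise
    nc <- pmin(pmax(nc, 0), 100)
    # OGTT curves consistent with FBG / PG120; insulin scaled down with
    # worsening tolerance so I.I. and composite fall from NGT to T2DM
    ogtt <- do.call(rbind, lapply(seq_len(n), function(i) {
      g0 <- markers$FBG[i]; g120 <- markers$PG120[i]
      g30 <- g0 + 0.75 * (g120 - g0) + 35
      g60 <- g0 + 0.95 * (g120 - g0) + 20
      g90 <- g0 + 1.0 * (g120 - g0) + 8
      sens <- c(NGT = 1, IGT = 0.6, T2DM = 0.35)[[classes[i]]]
      i0 <- 8 * insulin_noise[i, 1]
      ipk <- i0 + sens * 60 * insulin_noise[i, 2]
      data.frame(PG0 = g0, PG30 = g30, PG60 = g60, PG90 = g90,
                 PG120 = g120, IRI0 = i0, IRI30 = ipk,
                 IRI60 = 0.8 * ipk, IRI90 = 0.55 * ipk,
                 IRI120 = 0.35 * ipk)
    }))
    cohort <- data.frame(subject_id = vapply(traces, `[[`, "",
                                             "subject_id"),
                         class = classes, as.data.frame(comp), markers,
                         ogtt, covars, NC = as.numeric(nc))
    if (panel) {
      pan <- index_panel_table(traces)
      keep <- setdiff(names(pan), c("subject_id", "CGM_Mean", "CGM_Std",
                                    "AC_Var"))
      cohort <- cbind(cohort, pan[, keep])
    }
    list(traces = traces, cohort = cohort,
         truth = list(beta = b, sigma_nc = spec$sigma_nc,
                      components = comp, params = pars,
                      z_components = unclass(z)))
  })
}

#' Generate an index-like table with known factor structure
#'
#' Variables are Lambda F + unique noise with block-structured loadings:
#' `k_true` orthogonal factors, each loading `loading` on its own block
#' of `p_per_block` variables and 0 elsewhere; unique noise has variance
#' 1 - loading^2 so variables have unit variance. Used as the recovery
#' fixture for the factor-analysis stage.
#'
#' @param n Number of rows (subjects).
#' @param k_true Number of generating factors.
#' @param p_per_block Variables per factor block.
#' @param loading Common primary loading (default 0.85).
#' @param seed Integer seed.
#' @return List: `table` (data.frame n x p), `Lambda` (p x k), `F`
#'   (n x k factor scores).
#' @export
generate_index_table <- function(n = 300, k_true = 3, p_per_block = 4,
                                 loading = 0.85, seed = 0) {
  stopifnot(k_true >= 1, p_per_block >= 1, loading > 0, loading < 1)
  with_seed(seed, {
    p <- k_true * p_per_block
    Lambda <- matrix(0, p, k_true)
    for (k in seq_len(k_true))
      Lambda[(k - 1) * p_per_block + seq_len(p_per_block), k] <- loading
    F <- matrix(stats::rnorm(n * k_true), n, k_true)
    E <- matrix(stats::rnorm(n * p, 0, sqrt(1 - loading^2)), n, p)
    X <- F %*% t(Lambda) + E
    colnames(X) <- paste0("V", seq_len(p))
    list(table = as.data.frame(X), Lambda = Lambda, F = F)
  })
}
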