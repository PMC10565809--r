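# Seeded generators for synthetic solubilization screens and stability
# time courses. The chi -> solubility link is a deliberately simple
# monotone test harness (log-linear in chi), not a thermodynamic model;
# see the methods vignette.

#' Solubilization model for synthetic screens
#'
#' True maximum solubility per pair is
#' `S = S0 * exp(-k * chi) * (polymer_feed / 10)`; the measured solubilized
#' concentration is `min(eta * drug_feed, S) * (1 + e)` with multiplicative
#' truncated-normal noise `e ~ N(0, cv^2)` (truncated so the measurement
#' stays non-negative), emulating the relative error of HPLC
#' quantification.
#'
#' @param S0 maximum solubility at chi = 0 per 10 g/L polymer, g/L (> 0).
#' @param k chi sensitivity, > 0 for a decreasing chi-solubility link.
#' @param eta intrinsic solubilization efficiency in (0, 1].
#' @param cv coefficient of variation of the multiplicative measurement
#'   noise (>= 0, default 0.02).
#' @param seed integer seed making all draws reproducible.
#' @return a `solubilization_model`.
#' @export
solubilization_model <- function(S0 = 10, k = 1, eta = 0.9, cv = 0.02,
                                 seed = 1L) {
  if (!is.numeric(S0) || S0 <= 0) stop("S0 must be > 0", call. = FALSE)
  if (!is.numeric(k) || k < 0) stop("k must be >= 0", call. = FALSE)
  if (!is.numeric(eta) || eta <= 0 || eta > 1) {
    stop("eta must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(S0 = S0, k = k, eta = eta, cv = cv,
                 seed = as.integer(seed)),
            class = "solubilization_model")
}

#' Simulate a thin-film solubilization screen
#'
#' Generates one formulation record per polymer x drug-feed combination
#' under a [solubilization_model()]. Records carry the noise-free ground
#' truth (`true_solubility`) alongside the noisy measurement so recovery
#' tests can compare against it.
#'
#' @param chis named numeric vector: Flory-Huggins chi per polymer.
#' @param drug_feeds drug feed concentrations, g/L (default the
#'   2-10 g/L design).
#' @param polymer_feed polymer feed, g/L (default 10).
#' @param model a [solubilization_model()].
#' @return data.frame of records with columns
#'   `polymer_id,drug_id,polymer_feed,drug_feed,solubilized,day,medium,
#'   chi,true_solubility`.
#' @export
simulate_screen <- function(chis, drug_feeds = c(2, 4, 6, 8, 10),
                            polymer_feed = 10,
                            model = solubilization_model()) {
  stopifnot(inherits(model, "solubilization_model"))
  if (length(chis) == 0L || is.null(names(chis)) || any(!nzchar(names(chis)))) {
    stop("`chis` must be a non-empty named vector", call. = FALSE)
  }
  check_pos(polymer_feed, "polymer_feed")
  check_pos(drug_feeds, "drug_feeds")
  grid <- expand.grid(polymer_id = names(chis), drug_feed = drug_feeds,
                      stringsAsFactors = FALSE)
  withr::with_seed(model$seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      pid <- grid$polymer_id[i]
      feed <- grid$drug_feed[i]
      S <- model$S0 * exp(-model$k * chis[[pid]]) * (polymer_feed / 10)
      noisefree <- min(model$eta * feed, S)
      eps <- if (model$cv > 0) stats::rnorm(1, 0, model$cv) else 0
      eps <- max(eps, -1)                      # keep the measurement >= 0
      measured <- noisefree * (1 + eps)
      rec <- formulation_record(pid, "drug", polymer_feed, feed,
                                measured, day = 0, medium = "water",
                                tolerance = max(0.05, 5 * model$cv))
      rec$chi <- chis[[pid]]
      rec$true_solubility <- S
      rec
    })
    do.call(rbind, rows)
  })
}

#' Stability decay model
#'
#' Loading capacity relaxes exponentially toward an equilibrium value:
#' `LC(t) = lc_eq + (LC0 - lc_eq) * exp(-t / tau)`. With probability
#' `precipitation_probability` a series instead precipitates completely at
#' a day drawn uniformly from the sampling days after day 0 (solubilized
#' drops to 0 from that day on).
#'
#' @param tau decay time constant, days (> 0; `Inf` gives a constant
#'   series).
#' @param lc_eq equilibrium loading capacity, wt % (>= 0).
#' @param precipitation_probability probability of the
#'   complete-precipitation branch per series, in [0, 1].
#' @param cv multiplicative measurement noise on the sampled points
#'   (default 0.02; day-0 is reported noise-free as the series anchor).
#' @param seed integer seed.
#' @return a `stability_model`.
#' @export
stability_model <- function(tau = 5, lc_eq = 0,
                            precipitation_probability = 0, cv = 0.02,
                            seed = 1L) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be > 0", call. = FALSE)
  if (!is.numeric(lc_eq) || lc_eq < 0) stop("lc_eq must be >= 0", call. = FALSE)
  if (precipitation_probability < 0 || precipitation_probability > 1) {
    stop("precipitation_probability must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(tau = tau, lc_eq = lc_eq,
                 precipitation_probability = precipitation_probability,
                 cv = cv, seed = as.integer(seed)),
            class = "stability_model")
}

#' Simulate a stability time course for one formulation
#'
#' @param record a day-0 `formulation_record`.
#' @param model a [stability_model()].
#' @param days sampling days (default `c(0, 1, 5, 15)`).
#' @return a [stability_series()].
#' @export
simulate_stability <- function(record, model = stability_model(),
                               days = c(0, 1, 5, 15)) {
  stopifnot(inherits(model, "stability_model"))
  lc0 <- loading_capacity(record$solubilized, record$polymer_feed)
  if (model$lc_eq > lc0) {
    stop("lc_eq (", model$lc_eq, ") exceeds the initial LC (",
         round(lc0, 2), ")", call. = FALSE)
  }
  withr::with_seed(model$seed, {
    lc_t <- model$lc_eq + (lc0 - model$lc_eq) * exp(-days / model$tau)
    sol <- solubility_from_lc(lc_t, record$polymer_feed)
    if (model$cv > 0 && length(days) > 1L) {
      eps <- pmax(stats::rnorm(length(days) - 1L, 0, model$cv), -1)
      sol[-1] <- sol[-1] * (1 + eps)
    }
    if (model$precipitation_probability > 0 &&
        stats::runif(1) < model$precipitation_probability) {
      fail_day <- sample(days[days > 0], 1L)
      sol[days >= fail_day] <- 0
    }
    stability_series(record, days, sol)
  })
}

#' Recover the decay time constant from a stability series
#'
#' Assumes the equilibrium LC is zero, so `log LC(t)` is linear in `t` with
#' slope `-1/tau`; fits it by ordinary least squares. Non-positive LC
#' points (complete precipitation) are excluded; at least three positive
#' points are required. A constant series has slope 0 and returns the
#' documented sentinel `Inf`.
#'
#' @param series a [stability_series()].
#' @return estimated tau in days (`Inf` for a non-decaying series).
#' @export
recover_decay_rate <- function(series) {
  stopifnot(inherits(series, "stability_series"))
  lc <- loading_capacity(series$solubilized, series$record$polymer_feed)
  keep <- lc > 0
  if (sum(keep) < 3L) {
    stop("fewer than 3 positive points; cannot fit a decay rate",
         call. = FALSE)
  }
  fit <- stats::lm(log(lc[keep]) ~ series$days[keep])
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) return(Inf)
  -1 / slope
}
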