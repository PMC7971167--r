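# Simulated psychophysics. A stochastic observer with a Weibull
# psychometric function (plus guess and lapse rates) answers yes/no to
# single-electrode stimuli; an adaptive hybrid estimator (coarse staircase,
# then maximum-likelihood Weibull proposals at the running 50% point)
# recovers the perceptual threshold. Catch (stimulus-absent) trials audit
# the false-positive rate per block of six electrodes.

#' Simulated observer
#'
#' Response probability `p(I) = gamma + (1 - gamma - lambda) W(I)` where
#' `W(I) = 1 - exp(-(I/alpha)^beta)` is anchored so that `p` crosses the
#' definition of perceptual threshold (50% "yes") at `threshold_uA` when
#' `gamma = lambda = 0`.
#'
#' @param threshold_uA true 50% threshold (uA).
#' @param slope Weibull shape `beta` (dimensionless), > 0.
#' @param guess_rate false-positive ("yes" at zero stimulus) rate `gamma`
#'   in \[0, 1).
#' @param lapse_rate miss rate at asymptote `lambda` in \[0, 1).
#' @return Object of class `observer_model`.
#' @export
observer_model <- function(threshold_uA, slope = 4, guess_rate = 0,
                           lapse_rate = 0) {
  stopifnot(threshold_uA > 0, slope > 0,
            guess_rate >= 0, guess_rate < 1,
            lapse_rate >= 0, lapse_rate < 1)
  structure(list(threshold_uA = threshold_uA, slope = slope,
                 guess_rate = guess_rate, lapse_rate = lapse_rate,
                 alpha = threshold_uA / log(2)^(1 / slope)),
            class = "observer_model")
}

#' @rdname observer_model
#' @param obs an `observer_model`.
#' @param amplitude_uA stimulus amplitude(s), uA (0 = catch).
#' @return `observer_prob()` returns the yes-probability;
#'   `observer_response()` draws yes/no from the active RNG stream.
#' @export
observer_prob <- function(obs, amplitude_uA) {
  stopifnot(all(amplitude_uA >= 0))
  w <- 1 - exp(-(amplitude_uA / obs$alpha)^obs$slope)
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) * w
}

#' @rdname observer_model
#' @export
observer_response <- function(obs, amplitude_uA) {
  stats::runif(length(amplitude_uA)) < observer_prob(obs, amplitude_uA)
}

# Maximum-likelihood Weibull fit (alpha, beta) of yes/no data; returns the
# 50% point. Guess/lapse are NOT fitted -- which is exactly why observer
# false positives drag the estimate leftward.
weibull_ml_t50 <- function(amp, yes, beta_bounds = c(0.8, 12),
                           start = NULL) {
  keep <- amp > 0
  amp <- amp[keep]; yes <- yes[keep]
  if (length(amp) < 2 || length(unique(yes)) < 1) return(NA_real_)
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    p <- 1 - exp(-(amp / a)^b)
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    -sum(ifelse(yes, log(p), log(1 - p))) +
      1e-3 * par[2]^2   # weak shrinkage keeps beta finite on degenerate data
  }
  p0 <- start %||% c(log(stats::median(amp)), log(3))
  fit <- stats::optim(p0, nll, method = "L-BFGS-B",
                      lower = c(log(1e-2), log(beta_bounds[1])),
                      upper = c(log(1e5), log(beta_bounds[2])))
  alpha <- exp(fit$par[1]); beta <- exp(fit$par[2])
  alpha * log(2)^(1 / beta)
}

#' Adaptive hybrid threshold session
#'
#' Runs a simulated measurement session over a block of electrodes:
#' an initial coarse up/down staircase (to 3 reversals) per electrode, then
#' maximum-likelihood Weibull proposals at the running 50% estimate, with
#' randomized electrode interleaving and interspersed catch trials.
#' Stops per electrode when the running estimate stabilizes (successive
#' change below 5% over 10 trials) or at the session trial budget.
#'
#' @param observers named list of [observer_model()] objects, one per electrode
#'   (a single observer is recycled).
#' @param electrodes electrode labels (a block is nominally 6).
#' @param seed integer seed for the whole session.
#' @param n_trials session trial budget (300-400 nominal).
#' @param n_catch number of catch trials in the block (default 32).
#' @param start_uA initial staircase amplitude (uA).
#' @param step_factor staircase multiplicative step.
#' @param stable_rel stabilization tolerance (0.05).
#' @param stable_window trials over which stabilization is assessed.
#' @param amp_range_uA admissible amplitude range (uA).
#' @return List of class `hybrid_session`: `estimates` (data.frame per
#'   electrode: `threshold_uA`, `n_trials`, `converged`), `trials` (the
#'   TrialLog data.frame: trial, electrode, amplitude_uA, catch, response),
#'   `fpr` (block false-positive rate).
#' @export
run_hybrid_threshold <- function(observers, electrodes, seed,
                                 n_trials = 400, n_catch = 32,
                                 start_uA = 100, step_factor = 1.8,
                                 stable_rel = 0.05, stable_window = 10,
                                 amp_range_uA = c(1, 2000)) {
  if (inherits(observers, "observer_model"))
    observers <- stats::setNames(rep(list(observers), length(electrodes)),
                                 electrodes)
  stopifnot(all(electrodes %in% names(observers)))
  with_seed(seed, {
    st <- lapply(electrodes, function(e) list(
      amp = start_uA, dir = 0, reversals = 0L, phase = "staircase",
      amps = numeric(0), yes = logical(0), est_hist = numeric(0),
      done = FALSE, t50 = NA_real_))
    names(st) <- electrodes
    log_rows <- vector("list", n_trials + n_catch)
    catch_at <- sort(sample.int(n_trials + n_catch, n_catch))
    ti <- 0L; stim_done <- 0L
    while (ti < n_trials + n_catch) {
      ti <- ti + 1L
      if (ti %in% catch_at) {
        # catch responses are driven by the (first) observer's guess rate
        resp <- observer_response(observers[[electrodes[1]]], 0)
        log_rows[[ti]] <- data.frame(trial = ti, electrode = "catch",
                                     amplitude_uA = 0, catch = TRUE,
                                     response = resp)
        next
      }
      open_e <- electrodes[!vapply(st, `[[`, logical(1), "done")]
      if (!length(open_e)) break
      e <- sample(open_e, 1L)
      s <- st[[e]]
      amp <- min(max(s$amp, amp_range_uA[1]), amp_range_uA[2])
      resp <- observer_response(observers[[e]], amp)
      s$amps <- c(s$amps, amp); s$yes <- c(s$yes, resp)
      stim_done <- stim_done + 1L
      if (s$phase == "staircase") {
        dir_new <- if (resp) -1 else 1
        if (s$dir != 0 && dir_new != s$dir) s$reversals <- s$reversals + 1L
        s$dir <- dir_new
        s$amp <- amp * step_factor^dir_new
        if (s$reversals >= 3L) s$phase <- "ml"
      } else {
        t50 <- weibull_ml_t50(s$amps, s$yes)
        if (!is.na(t50)) {
          t50 <- min(max(t50, amp_range_uA[1]), amp_range_uA[2])
          s$est_hist <- c(s$est_hist, t50)
          s$t50 <- t50
          s$amp <- t50
          k <- length(s$est_hist)
          if (k >= stable_window) {
            win <- s$est_hist[(k - stable_window + 1):k]
            if (all(abs(diff(win)) / win[-length(win)] < stable_rel))
              s$done <- TRUE
          }
        } else {
          s$amp <- amp * step_factor
        }
      }
      st[[e]] <- s
      log_rows[[ti]] <- data.frame(trial = ti, electrode = e,
                                   amplitude_uA = amp, catch = FALSE,
                                   response = resp)
      if (stim_done >= n_trials) break
    }
    # the block contract is a fixed number of catch trials: deliver any
    # still pending even when every electrode converged early
    n_catch_done <- sum(vapply(log_rows, function(r)
      !is.null(r) && r$catch, logical(1)))
    while (n_catch_done < n_catch) {
      ti <- ti + 1L
      resp <- observer_response(observers[[electrodes[1]]], 0)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(trial = ti, electrode = "catch", amplitude_uA = 0,
                   catch = TRUE, response = resp)
      n_catch_done <- n_catch_done + 1L
    }
    trials <- do.call(rbind, log_rows[!vapply(log_rows, is.null, logical(1))])
    est <- do.call(rbind, lapply(electrodes, function(e) {
      s <- st[[e]]
      t50 <- if (!is.na(s$t50)) s$t50 else weibull_ml_t50(s$amps, s$yes)
      data.frame(electrode = e, threshold_uA = t50,
                 n_trials = length(s$amps), converged = s$done)
    }))
    fpr <- if (any(trials$catch)) mean(trials$response[trials$catch]) else NA_real_
    structure(list(estimates = est, trials = trials, fpr = fpr, seed = seed),
              class = "hybrid_session")
  })
}

#' Audit a block's catch trials
#'
#' Excludes the block iff the false-positive rate on catch trials is
#' strictly above the cutoff (the ">25% yes on catch" exclusion rule).
#'
#' @param trials TrialLog data.frame with `catch` and `response` columns
#'   (or a `hybrid_session`).
#' @param fpr_cutoff exclusion cutoff (default 0.25).
#' @return List: `fpr`, `n_catch`, `n_yes`, `exclude`.
#' @export
audit_block <- function(trials, fpr_cutoff = 0.25) {
  if (inherits(trials, "hybrid_session")) trials <- trials$trials
  ct <- trials[trials$catch, , drop = FALSE]
  if (!nrow(ct))
    return(list(fpr = NA_real_, n_catch = 0L, n_yes = 0L, exclude = NA,
                flag = "no_catch_trials"))
  fpr <- mean(ct$response)
  list(fpr = fpr, n_catch = nrow(ct), n_yes = sum(ct$response),
       exclude = fpr > fpr_cutoff)
}

#' Compare model and observed thresholds
#'
#' Pearson correlation (two-sided test) and least-squares regression of
#' observed on model thresholds over paired electrodes, optionally
#' dropping pairs whose observed threshold is below a floor (low observed
#' thresholds are the ones most distorted by false positives).
#'
#' @param model_uA,observed_uA paired per-electrode thresholds (uA).
#' @param min_observed_uA optional filter: drop pairs with
#'   `observed < min_observed_uA`.
#' @return List: `r`, `p_value`, `slope`, `intercept`, `n`; `r` is `NA`
#'   with flag `degenerate` when either vector has zero variance.
#' @export
compare_thresholds <- function(model_uA, observed_uA,
                               min_observed_uA = NULL) {
  stopifnot(length(model_uA) == length(observed_uA))
  keep <- !is.na(model_uA) & !is.na(observed_uA)
  if (!is.null(min_observed_uA)) keep <- keep & observed_uA >= min_observed_uA
  x <- model_uA[keep]; y <- observed_uA[keep]
  if (length(x) < 3) stop_config("need at least 3 paired electrodes")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(x), flag = "degenerate"))
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}

#' One-way fixed-effects ANOVA across blocks
#'
#' @param blocks list of numeric vectors (per-block thresholds).
#' @return List: `F`, `p_value`, `df`.
#' @export
block_anova <- function(blocks) {
  stopifnot(length(blocks) >= 2, all(vapply(blocks, length, 1L) >= 2))
  v <- unlist(blocks)
  g <- factor(rep(seq_along(blocks), vapply(blocks, length, 1L)))
  if (stats::sd(v) == 0)
    return(list(F = 0, p_value = 1,
                df = c(length(blocks) - 1L, length(v) - length(blocks))))
  a <- stats::anova(stats::lm(v ~ g))
  list(F = a$`F value`[1], p_value = a$`Pr(>F)`[1], df = a$Df)
}
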