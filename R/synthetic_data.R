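# Synthetic cohorts with planted, recoverable spatiotemporal structure.
#
# Base signal model per subject: C independent stationary AR(1) latent
# processes (coefficient 0.7, unit marginal variance) mixed through a
# random orthonormal loading, plus white observation noise.  Class-1
# subjects additionally receive a shared latent driver on a subset of
# components — either confined to a short event window ("spiky"), spread
# evenly across time ("flat"), or always-on (connectivity shift) — which
# plants known salient cells and known affected component pairs.

ar1_matrix <- function(C, Tn, coef = 0.7, innov_sd = NULL) {
  # unit stationary variance by default
  if (is.null(innov_sd)) innov_sd <- sqrt(1 - coef^2)
  x <- matrix(0, C, Tn)
  x[, 1L] <- stats::rnorm(C, 0, innov_sd / sqrt(1 - coef^2))
  e <- matrix(stats::rnorm(C * (Tn - 1L), 0, innov_sd), C, Tn - 1L)
  for (t in 2:Tn) x[, t] <- coef * x[, t - 1L] + e[, t - 1L]
  x
}

random_orthonormal <- function(C) {
  qr.Q(qr(matrix(stats::rnorm(C * C), C, C)))
}

#' Specification of a synthetic two-class cohort
#'
#' @param n_per_class Subjects per class.
#' @param C Components (default 53).
#' @param T Time points (default 140).
#' @param effect_type `"connectivity_shift"` (always-on shared driver on
#'   the affected components, raising their pairwise correlations),
#'   `"focal_event"` (driver confined to `event_window` for the
#'   `"spiky"` profile or spread evenly over time for `"flat"`), or
#'   `"both"`.
#' @param affected_components Indices (1-based) of the components
#'   carrying the class signal; default the first 6.
#' @param event_window Length-2 vector, 0-based half-open interval
#'   `[t_start, t_end)`; default `c(60, 80)` (length 20).
#' @param effect_size Amplitude of the shared driver; with driver
#'   variance 1 the planted correlation between two affected components
#'   is `effect_size^2 * q / (1 + noise_sd^2 + effect_size^2 * q)` where
#'   `q` is the fraction of time the driver is active.
#' @param noise_sd White observation-noise standard deviation.
#' @param temporal_profile `"spiky"` or `"flat"` layout of the class-1
#'   focal signal.
#' @param control_signal `"none"` (default) leaves class 0 as pure
#'   background; `"flat"` gives class-0 subjects an energy-matched
#'   diffuse driver on the same components, so the two classes differ in
#'   the temporal *layout* of their signal rather than its presence —
#'   the regime for contrasting focal (spiky) against temporally
#'   diffuse discriminative activity.
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_class = 50L, C = 53L, T = 140L,
                        effect_type = c("focal_event", "connectivity_shift",
                                        "both"),
                        affected_components = 1:6,
                        event_window = c(60L, 80L),
                        effect_size = 2.5, noise_sd = 0.5,
                        temporal_profile = c("spiky", "flat"),
                        control_signal = c("none", "flat"),
                        seed = 1L) {
  effect_type <- match.arg(effect_type)
  temporal_profile <- match.arg(temporal_profile)
  control_signal <- match.arg(control_signal)
  stopifnot(C >= 2L, T >= 2L, effect_size >= 0, noise_sd > 0,
            all(affected_components >= 1L),
            all(affected_components <= C))
  if (length(event_window) != 2L || event_window[1L] < 0L ||
      event_window[2L] > T || event_window[1L] >= event_window[2L]) {
    stop("event_window must be a half-open [start, end) inside [0, T)")
  }
  structure(list(n_per_class = as.integer(n_per_class), C = as.integer(C),
                 T = as.integer(T), effect_type = effect_type,
                 affected_components = as.integer(affected_components),
                 event_window = as.integer(event_window),
                 effect_size = effect_size, noise_sd = noise_sd,
                 temporal_profile = temporal_profile,
                 control_signal = control_signal,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort with planted ground truth
#'
#' @param spec A [cohort_spec].
#' @return List with `records` (2 * `n_per_class`
#'   [timecourse_record]s, controls then patients) and `ground_truth`:
#'   per-subject logical `C x T` masks of planted salient cells (all
#'   `FALSE` for controls unless `control_signal = "flat"`), the
#'   affected component indices, the affected component pairs, and the
#'   event window.
#' @examples
#' ch <- generate_cohort(cohort_spec(n_per_class = 5, C = 10, T = 60,
#'                                   event_window = c(20, 40)))
#' table(vapply(ch$records, `[[`, 0L, "label"))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  seeds <- derive_seeds(spec$seed, n)
  Tn <- spec$T; C <- spec$C
  aff <- spec$affected_components
  win_cols <- (spec$event_window[1L] + 1L):spec$event_window[2L]
  w_len <- length(win_cols)

  env <- switch(spec$temporal_profile,
    spiky = { e <- numeric(Tn); e[win_cols] <- 1; e },
    flat = rep(sqrt(w_len / Tn), Tn))
  env_flat <- rep(sqrt(w_len / Tn), Tn)

  records <- vector("list", n)
  masks <- vector("list", n)
  # one orthonormal loading shared by the cohort: subjects differ through
  # their AR sample paths and noise, not through private mixing matrices
  # (a private mixing matrix would give every subject a covariance
  # fingerprint that small-sample classifiers can memorize)
  Q <- with_seed(spec$seed, random_orthonormal(C))
  for (i in seq_len(n)) {
    made <- with_seed(seeds[i], {
      base <- Q %*% ar1_matrix(C, Tn) +
        matrix(stats::rnorm(C * Tn, 0, spec$noise_sd), C, Tn)
      mask <- matrix(FALSE, C, Tn)
      if (labels[i] == 0L && spec$control_signal == "flat" &&
          spec$effect_size > 0 &&
          spec$effect_type %in% c("focal_event", "both")) {
        driver <- ar1_matrix(1L, Tn)
        base[aff, ] <- base[aff, ] + spec$effect_size *
          matrix(env_flat * drop(driver), length(aff), Tn, byrow = TRUE)
        mask[aff, ] <- TRUE
      }
      if (labels[i] == 1L && spec$effect_size > 0) {
        driver <- ar1_matrix(1L, Tn)
        if (spec$effect_type %in% c("focal_event", "both")) {
          add <- spec$effect_size *
            matrix(env * drop(driver), length(aff), Tn, byrow = TRUE)
          base[aff, ] <- base[aff, ] + add
          if (spec$temporal_profile == "spiky") {
            mask[aff, win_cols] <- TRUE
          } else {
            mask[aff, ] <- TRUE
          }
        }
        if (spec$effect_type %in% c("connectivity_shift", "both")) {
          driver2 <- ar1_matrix(1L, Tn)
          base[aff, ] <- base[aff, ] + spec$effect_size *
            matrix(drop(driver2), length(aff), Tn, byrow = TRUE)
          mask[aff, ] <- TRUE
        }
      }
      list(rec = timecourse_record(sprintf("subj%03d", i), base,
                                   label = labels[i],
                                   cohort_tag = spec$effect_type),
           mask = mask)
    })
    records[[i]] <- made$rec
    masks[[i]] <- made$mask
  }
  pairs <- t(utils::combn(aff, 2L))
  colnames(pairs) <- c("component_i", "component_j")
  list(records = records,
       ground_truth = list(masks = masks, affected_components = aff,
                           affected_pairs = pairs,
                           event_window = spec$event_window,
                           spec = spec))
}

#' Generate an unlabeled pretraining pool with subject-specific dynamics
#'
#' The pool emulates a bank of healthy subjects who share a common
#' functional backbone but differ in their individual dynamics: all
#' subjects share one orthonormal loading, and each subject draws (i)
#' its own per-component AR(1) coefficients (uniform on 0.3-0.9, a
#' spectral signature), (ii) a few private persistent co-activation
#' drivers — shared latent signals added to random component subsets,
#' giving each subject a private connectivity profile — and (iii) a few
#' spontaneous transient events (short bursts on random component
#' subsets at random times), the healthy analogue of the focal events
#' the labeled cohorts plant.  Windows therefore carry both
#' subject-identifying and window-identifying structure, so the
#' window/sequence mutual-information objective is learnable above
#' chance, and the features it rewards (co-activation and burst
#' detectors) are of the same family as the downstream class signals.
#'
#' @param n_subjects Pool size (>= 2).
#' @param C,T Components and time points.
#' @param noise_sd Observation-noise standard deviation.
#' @param n_drivers Private persistent co-activation drivers per subject.
#' @param n_events Spontaneous transient events per subject (default 3).
#' @param event_length Length of each event in time steps (default 20).
#' @param n_event_components Components recruited by each driver/event
#'   (default 6).
#' @param seed Master seed.
#' @return List of unlabeled [timecourse_record]s.
#' @export
generate_pretraining_pool <- function(n_subjects, C = 53L, T = 140L,
                                      noise_sd = 0.3, n_drivers = 3L,
                                      n_events = 3L, event_length = 20L,
                                      n_event_components = 6L, seed = 1L) {
  stopifnot(n_subjects >= 2L, event_length <= T, n_event_components <= C)
  seeds <- derive_seeds(seed, n_subjects + 1L)
  Q <- with_seed(seeds[n_subjects + 1L], random_orthonormal(C))
  lapply(seq_len(n_subjects), function(i) {
    with_seed(seeds[i], {
      coefs <- stats::runif(C, 0.3, 0.9)
      lat <- matrix(0, C, T)
      lat[, 1L] <- stats::rnorm(C)
      for (t in 2:T) {
        lat[, t] <- coefs * lat[, t - 1L] +
          stats::rnorm(C, 0, sqrt(1 - coefs^2))
      }
      x <- Q %*% lat + matrix(stats::rnorm(C * T, 0, noise_sd), C, T)
      for (d in seq_len(n_drivers)) {
        comps <- sample.int(C, n_event_components)
        amp <- stats::runif(1L, 1.2, 2.2)
        drv <- ar1_matrix(1L, T)
        x[comps, ] <- x[comps, ] +
          amp * matrix(drop(drv), length(comps), T, byrow = TRUE)
      }
      for (ev in seq_len(n_events)) {
        comps <- sample.int(C, n_event_components)
        start <- sample.int(T - event_length + 1L, 1L)
        cols <- start:(start + event_length - 1L)
        amp <- stats::runif(1L, 1.5, 3)
        drv <- ar1_matrix(1L, event_length)
        x[comps, cols] <- x[comps, cols] +
          amp * matrix(drop(drv), length(comps), event_length, byrow = TRUE)
      }
      timecourse_record(sprintf("pool%03d", i), x, cohort_tag = "pool")
    })
  })
}
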