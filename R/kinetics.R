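# Digestion kinetics from densitometry time courses: resistance gate,
# first-order decay with half-life, and the consecutive-reaction (transient
# fragment) model. Nonlinear fits use Levenberg-Marquardt damped least squares
# (minpack.lm); initial values are deterministic so fits are reproducible.

#' Reference digestion-kinetics conditions
#'
#' Rate constants of intact Pru p 3 (and of the ~7 kDa fragment where it
#' accumulates) under the in vitro intestinal digestion conditions, as
#' reported by densitometric analysis: high/low enzyme test, pH 6.5/8.0, with
#' and without bile salts. `K` is NA for conditions where the parent protein
#' is statistically resistant (half-life infinite); `fragment_K` is NA where
#' no fragment kinetics were determined, and `fragment_class` is "transient"
#' where the fragment accumulates then decays.
#'
#' @return Data frame with columns condition_id, enzyme_level, pH, bile_mM,
#'   K, fragment_K, fragment_class.
#' @export
reference_conditions <- function() {
  data.frame(
    condition_id = c("high_pH6.5_0mM", "high_pH6.5_4mM", "high_pH8.0_0mM",
                     "high_pH8.0_4mM", "low_pH6.5_0mM", "low_pH6.5_1mM",
                     "low_pH8.0_0mM", "low_pH8.0_1mM"),
    enzyme_level = rep(c("high", "low"), each = 4),
    pH = c(6.5, 6.5, 8.0, 8.0, 6.5, 6.5, 8.0, 8.0),
    bile_mM = c(0, 4, 0, 4, 0, 1, 0, 1),
    K = c(0.0022, 0.0451, 0.0055, 0.1292, NA, 0.0016, NA, 0.0073),
    fragment_K = c(NA, NA, NA, NA, NA, 0.0126, NA, 0.0216),
    fragment_class = c(NA, "transient", NA, "transient", NA, "rising", NA,
                       "rising"),
    stringsAsFactors = FALSE)
}

#' Resistance gate: is the protein digested at all?
#'
#' Two-tailed two-sample Student's t-test between the relative band intensity
#' of the undigested control (IU) and the final time point. Series that do
#' not differ significantly are classified resistant, excluded from decay
#' fitting, and reported with infinite half-life.
#'
#' @param iu_intensities Replicate intensities of the IU control.
#' @param final_intensities Replicate intensities at the final time point.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Equal-variance Student's test by default; set FALSE for
#'   Welch.
#' @return List with `p_value` and `resistant` (p >= alpha).
#' @export
resistance_test <- function(iu_intensities, final_intensities, alpha = 0.05,
                            var_equal = TRUE) {
  if (length(iu_intensities) < 2L || length(final_intensities) < 2L)
    stop("resistance_test requires >= 2 replicates per group")
  if (stats::sd(iu_intensities) == 0 && stats::sd(final_intensities) == 0 &&
      isTRUE(all.equal(mean(iu_intensities), mean(final_intensities)))) {
    p <- 1  # identical constant groups: no evidence of digestion
  } else {
    p <- stats::t.test(iu_intensities, final_intensities,
                       var.equal = var_equal)$p.value
  }
  list(p_value = p, resistant = p >= alpha)
}

# internal: deterministic log-linear start values for I0*exp(-K t)
.decay_start <- function(time, intensity) {
  pos <- intensity > 0
  if (sum(pos) >= 2L && stats::sd(time[pos]) > 0) {
    co <- stats::coef(stats::lm(log(intensity[pos]) ~ time[pos]))
    K0 <- max(-co[2], 0)
    I0 <- exp(co[1])
  } else {
    K0 <- 0; I0 <- max(intensity, 1e-6)
  }
  c(I0 = unname(I0), K = unname(K0))
}

#' Fit first-order decay to a densitometry time course
#'
#' Least-squares fit of I(t) = I0 * exp(-K t) by Levenberg-Marquardt damped
#' least squares. Initial values come from a log-linear regression on the
#' positive intensities, so the fit is deterministic. Goodness of fit is the
#' residual standard error RSE = sqrt(SSE / (n - 2)).
#'
#' @param time_min Times in minutes (replicates as repeated times).
#' @param intensity Relative band intensities (fractions of the IU control).
#' @param resistant Logical; when TRUE no fit is attempted and the result
#'   reports K = 0, infinite half-life.
#' @param p_value Optional p-value of the resistance gate, stored in the fit.
#' @return An object of class `decay_fit`: K (min^-1), I0, stderr_K, RSE,
#'   t_half (min; Inf when resistant or K = 0), resistant, p_value,
#'   degenerate (TRUE when the series is constant and K collapses to 0), n.
#' @examples
#' t <- c(0, 10, 20, 40, 60, 90, 120)
#' fit <- fit_decay(t, exp(-0.1 * t))
#' fit$K  # 0.1
#' @export
fit_decay <- function(time_min, intensity, resistant = FALSE,
                      p_value = NA_real_) {
  stopifnot(length(time_min) == length(intensity))
  if (any(time_min < 0) || any(intensity < 0))
    stop("times and intensities must be >= 0")
  if (resistant) {
    return(structure(list(K = 0, I0 = mean(intensity), stderr_K = NA_real_,
                          RSE = NA_real_, t_half = Inf, resistant = TRUE,
                          p_value = p_value, degenerate = FALSE,
                          n = length(time_min)), class = "decay_fit"))
  }
  if (length(unique(time_min)) < 3L)
    stop("fit_decay requires >= 3 distinct time points")
  if (all(intensity == 0)) stop("all intensities are zero; nothing to fit")
  start <- .decay_start(time_min, intensity)
  degenerate <- FALSE
  if (stats::sd(intensity) == 0) {
    # constant series: K = 0 exactly, flagged
    K <- 0; I0 <- intensity[1]; se <- 0
    rse <- 0
    degenerate <- TRUE
  } else {
    fit <- .lm_fit(
      par = list(I0 = unname(start["I0"]), K = max(unname(start["K"]), 1e-6)),
      fn = function(p) intensity - p$I0 * exp(-p$K * time_min),
      lower = c(0, 0))
    K <- fit$par[["K"]]; I0 <- fit$par[["I0"]]
    se <- fit$stderr[["K"]]
    rse <- sqrt(fit$sse / (length(time_min) - 2))
  }
  structure(list(K = K, I0 = I0, stderr_K = se, RSE = rse,
                 t_half = half_life(K), resistant = FALSE, p_value = p_value,
                 degenerate = degenerate, n = length(time_min)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> K = %.4g min^-1, t1/2 = %.1f min, RSE = %.3g%s\n",
              x$K, x$t_half, x$RSE,
              if (x$resistant) " (resistant)" else ""))
  invisible(x)
}

#' Half-life of a first-order decay
#'
#' t1/2 = ln(2)/K; infinite for K = 0. Values are returned unrounded;
#' rounding to one decimal is a presentation choice.
#'
#' @param K Rate constant in min^-1 (vectorised).
#' @return Half-life in minutes.
#' @examples
#' round(half_life(0.0451), 1)  # 15.4
#' @export
half_life <- function(K) {
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0")
  ifelse(K == 0, Inf, log(2) / K)
}

#' Ratio of two half-lives
#'
#' Fold change t_half(a) / t_half(b); an infinite numerator (resistant
#' series) propagates to Inf.
#' @param fit_a,fit_b `decay_fit` objects, or numeric half-lives.
#' @return Fold change (possibly Inf).
#' @export
fold_change_half_life <- function(fit_a, fit_b) {
  th <- function(x) if (inherits(x, "decay_fit")) x$t_half else as.numeric(x)
  a <- th(fit_a); b <- th(fit_b)
  if (is.infinite(a)) return(Inf)
  a / b
}

# internal: consecutive first-order model, with the analytic equal-rate limit
.transient_model <- function(t, A, kf, kd) {
  if (abs(kf - kd) < 1e-12) return(A * kf * t * exp(-kf * t))
  A * kf / (kd - kf) * (exp(-kf * t) - exp(-kd * t))
}

#' Fit the transient-fragment model to a time course
#'
#' Digestion intermediates follow consecutive first-order reactions:
#' B(t) = A k_form/(k_deg - k_form) (exp(-k_form t) - exp(-k_deg t)),
#' which rises then decays ("transient"); as k_deg -> 0 it reduces to the
#' rising-saturation form B(t) = A (1 - exp(-k_form t)). Both are fitted by
#' Levenberg-Marquardt; the classification is `rising` when the fitted k_deg
#' is indistinguishable from zero (k_deg < 1e-8 or stderr(k_deg) >= k_deg, or
#' the two-rate fit fails while the rising fit succeeds), in which case
#' k_form is the fragment's reported rate constant. Otherwise the
#' classification is `transient` and the peak time
#' ln(k_form/k_deg)/(k_form - k_deg) is reported.
#'
#' @param time_min Times in minutes.
#' @param intensity Fragment band intensities.
#' @return An object of class `transient_fit`: k_form, k_deg, amplitude,
#'   classification ("rising" or "transient"), peak_time_min (NA for rising),
#'   RSE.
#' @export
fit_transient <- function(time_min, intensity) {
  stopifnot(length(time_min) == length(intensity))
  if (length(unique(time_min)) < 4L)
    stop("fit_transient requires >= 4 distinct time points")
  ymax <- max(intensity)
  tpk <- time_min[which.max(intensity)]
  rises_to_end <- which.max(intensity) >= length(intensity) - 1L
  # deterministic starts from the peak-position heuristic
  kf0 <- if (tpk > 0) 1 / tpk else 0.1
  kd0 <- if (rises_to_end) 1e-4 else kf0 / 2
  rising_fit <- tryCatch(.lm_fit(
    par = list(A = ymax, kf = kf0),
    fn = function(p) intensity - p$A * (1 - exp(-p$kf * time_min)),
    lower = c(0, 0)), error = function(e) NULL)
  trans_fit <- tryCatch(.lm_fit(
    par = list(A = if (rises_to_end) ymax else 2 * ymax, kf = kf0, kd = kd0),
    fn = function(p) intensity -
      .transient_model(time_min, p$A, p$kf, p$kd),
    lower = c(0, 1e-10, 0)), error = function(e) NULL)
  rse_of <- function(fit, p) sqrt(fit$sse / max(length(time_min) - p, 1))
  use_rising <- FALSE
  if (is.null(trans_fit)) {
    if (is.null(rising_fit)) stop("transient fit failed to converge")
    use_rising <- TRUE
  } else {
    kd_hat <- trans_fit$par[["kd"]]
    se_kd <- trans_fit$stderr[["kd"]]
    if (kd_hat < 1e-8 || is.na(se_kd) || se_kd >= kd_hat) {
      use_rising <- !is.null(rising_fit) &&
        rse_of(rising_fit, 2) <= rse_of(trans_fit, 3) * (1 + 1e-6)
    }
  }
  if (use_rising) {
    out <- list(k_form = rising_fit$par[["kf"]], k_deg = 0,
                amplitude = rising_fit$par[["A"]], classification = "rising",
                peak_time_min = NA_real_, RSE = rse_of(rising_fit, 2))
  } else {
    kf <- trans_fit$par[["kf"]]; kd <- trans_fit$par[["kd"]]
    pk <- if (kf > 0 && kd > 0 && abs(kf - kd) > 1e-12)
      log(kf / kd) / (kf - kd) else if (kf > 0) 1 / kf else NA_real_
    out <- list(k_form = kf, k_deg = kd, amplitude = trans_fit$par[["A"]],
                classification = "transient", peak_time_min = pk,
                RSE = rse_of(trans_fit, 3))
  }
  structure(out, class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("<transient_fit> %s: k_form = %.4g, k_deg = %.4g min^-1%s\n",
              x$classification, x$k_form, x$k_deg,
              if (!is.na(x$peak_time_min))
                sprintf(", peak at %.1f min", x$peak_time_min) else ""))
  invisible(x)
}

#' Analyse a set of densitometry time courses
#'
#' Convenience driver: for each condition in a long-format time-course table,
#' applies the resistance gate (IU control = intensities at time 0 vs the
#' final time point), fits the decay where not resistant, and summarises K,
#' half-life and RSE in a table mirroring the reporting convention
#' (condition, K, t_half, resistant).
#'
#' @param tc Data frame with columns condition_id, band, replicate, time_min,
#'   rel_intensity.
#' @param alpha Resistance-gate significance level.
#' @return Data frame: condition_id, band, K, stderr_K, t_half, RSE,
#'   resistant, p_value, fragment classification where a fragment band is
#'   present (NA otherwise).
#' @export
analyse_timecourses <- function(tc, alpha = 0.05) {
  need <- c("condition_id", "band", "replicate", "time_min", "rel_intensity")
  miss <- setdiff(need, names(tc))
  if (length(miss)) stop("time-course table lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- NULL
  for (cid in unique(tc$condition_id)) {
    for (bd in unique(tc$band[tc$condition_id == cid])) {
      d <- tc[tc$condition_id == cid & tc$band == bd, , drop = FALSE]
      if (bd == "parent") {
        t0 <- min(d$time_min); tf <- max(d$time_min)
        gate <- resistance_test(d$rel_intensity[d$time_min == t0],
                                d$rel_intensity[d$time_min == tf],
                                alpha = alpha)
        fit <- fit_decay(d$time_min, d$rel_intensity,
                         resistant = gate$resistant, p_value = gate$p_value)
        row <- data.frame(condition_id = cid, band = bd, K = fit$K,
                          stderr_K = fit$stderr_K, t_half = fit$t_half,
                          RSE = fit$RSE, resistant = fit$resistant,
                          p_value = fit$p_value,
                          classification = NA_character_,
                          stringsAsFactors = FALSE)
      } else {
        tf <- fit_transient(d$time_min, d$rel_intensity)
        row <- data.frame(condition_id = cid, band = bd, K = tf$k_form,
                          stderr_K = NA_real_, t_half = NA_real_,
                          RSE = tf$RSE, resistant = FALSE, p_value = NA_real_,
                          classification = tf$classification,
                          stringsAsFactors = FALSE)
      }
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}
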