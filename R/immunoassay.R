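# Four-parameter logistic inhibition-ELISA analysis: IC50 with censoring at
# the edges of the tested concentration range, and fold-change reporting.

#' Default inhibition-ELISA concentration grid
#'
#' Seven decades of inhibitor concentration, 1e-5 to 10 ug/mL of intact
#' protein equivalent.
#' @return Numeric vector of concentrations (ug/mL).
#' @export
elisa_grid <- function() 10^seq(-5, 1)

#' Fit a four-parameter logistic inhibition curve
#'
#' Least-squares fit of y = d + (a - d) / (1 + (x/c)^b) by
#' Levenberg-Marquardt, where a is the uninhibited (upper) asymptote, d the
#' fully inhibited (lower) asymptote, b the slope and c the inflection
#' concentration. IC50 is defined as c, the concentration at the midpoint
#' between the asymptotes. When the estimated c falls outside the tested
#' concentration range the IC50 is censored ("< min tested" or "> max
#' tested") rather than reported as a point estimate; poorly constrained
#' fits (stderr(c)/c > 0.5) are flagged approximate ("~").
#'
#' Initialisation is deterministic: a = max response, d = min response,
#' c = geometric mid-concentration, b = 1.
#'
#' @param conc Inhibitor concentrations (> 0), ug/mL.
#' @param response Assay responses (A450), >= 0.
#' @param flag_rel_stderr Relative stderr(c) threshold above which the fit is
#'   flagged approximate (default 0.5).
#' @return An object of class `fourpl_fit`: a, d, b, c, ic50 (numeric; equal
#'   to c, or to the censoring bound), censored ("none", "left", "right"),
#'   approximate (logical), RSE, conc_range.
#' @examples
#' x <- elisa_grid()
#' y <- 0.2 + (2 - 0.2) / (1 + (x / 0.05))
#' fit_4pl(x, y)$c  # 0.05
#' @export
fit_4pl <- function(conc, response, flag_rel_stderr = 0.5) {
  stopifnot(length(conc) == length(response))
  if (any(conc <= 0)) stop("concentrations must be > 0 (store the buffer control separately)")
  if (any(response < 0)) stop("responses must be >= 0")
  if (length(unique(conc)) < 5L) stop("fit_4pl requires >= 5 concentration points")
  a0 <- max(response); d0 <- min(response)
  lc0 <- mean(log(range(conc)))
  # internally fit log(c): the dose axis is logarithmic and the log-c
  # parameterisation keeps the damped least squares well scaled when the
  # inflection sits near or beyond the edge of the tested range
  lx <- log(conc)
  fit <- .lm_fit(
    par = list(a = a0, d = d0, b = 1, lc = lc0),
    fn = function(p) response -
      (p$d + (p$a - p$d) / (1 + exp(p$b * (lx - p$lc)))),
    lower = c(0, 0, 1e-3, log(1e-12)), upper = c(Inf, Inf, 50, log(1e12)),
    maxiter = 1000, ftol = 1e-10, ptol = 1e-10, allow_maxiter = TRUE)
  co <- c(a = fit$par[["a"]], d = fit$par[["d"]], b = fit$par[["b"]],
          c = exp(fit$par[["lc"]]))
  if (co["a"] < co["d"]) {  # canonical orientation: a is the upper asymptote
    tmp <- co["a"]; co["a"] <- co["d"]; co["d"] <- tmp
    co["b"] <- -co["b"]
  }
  se_c <- unname(exp(fit$par[["lc"]]) * fit$stderr[["lc"]])  # delta method
  rse <- sqrt(fit$sse / max(length(conc) - 4, 1))
  rng <- range(conc)
  cc <- unname(co["c"])
  censored <- "none"; ic50 <- cc
  if (cc < rng[1]) { censored <- "left"; ic50 <- rng[1] }
  if (cc > rng[2]) { censored <- "right"; ic50 <- rng[2] }
  # monotonicity sanity: responses should not rise with concentration beyond noise
  ord <- order(conc)
  if (stats::cor(conc[ord], response[ord], method = "spearman") > 0.5)
    warning("responses increase with inhibitor concentration; check curve orientation")
  # flagged approximate when c is weakly constrained, or when the damped
  # least squares exhausted its iteration budget crawling along a ridge of
  # near-equivalent solutions (as happens when the inflection lies far
  # outside the tested range and a, c trade off freely)
  approx_flag <- (is.finite(se_c) && cc > 0 && (se_c / cc) > flag_rel_stderr) ||
    fit$maxed
  structure(list(a = unname(co["a"]), d = unname(co["d"]),
                 b = unname(co["b"]), c = cc, ic50 = ic50,
                 censored = censored, approximate = approx_flag,
                 stderr_c = se_c, RSE = rse, conc_range = rng),
            class = "fourpl_fit")
}

#' Format an IC50 value with its censoring
#' @param fit A `fourpl_fit`.
#' @param digits Significant digits (default 3).
#' @return Character such as "0.40", "< 0.01", "> 10" or "~ 0.25".
#' @export
format_ic50 <- function(fit, digits = 3) {
  v <- signif(fit$ic50, digits)
  switch(fit$censored,
         left = paste("<", v),
         right = paste(">", v),
         if (fit$approximate) paste("~", v) else as.character(v))
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("<fourpl_fit> a = %.3g, d = %.3g, b = %.3g, IC50 = %s ug/mL\n",
              x$a, x$d, x$b, format_ic50(x)))
  invisible(x)
}

#' Fold change between two IC50s, propagating censoring
#'
#' test IC50 / reference IC50. A left-censored reference ("< r") makes the
#' ratio a lower bound ("> t/r"); a right-censored test value likewise yields
#' a lower bound; a right-censored reference or left-censored test yields an
#' upper bound.
#'
#' @param reference,test `fourpl_fit` objects (or numeric IC50s, uncensored).
#' @return List with `value` (the ratio of the reported values) and `bound`
#'   ("exact", "greater" or "less"), plus a `label` such as "> 40".
#' @export
ic50_fold_change <- function(reference, test) {
  get <- function(x) {
    if (inherits(x, "fourpl_fit")) list(v = x$ic50, cens = x$censored)
    else list(v = as.numeric(x), cens = "none")
  }
  r <- get(reference); t <- get(test)
  v <- t$v / r$v
  lower <- (r$cens == "left") || (t$cens == "right")
  upper <- (r$cens == "right") || (t$cens == "left")
  bound <- if (lower && !upper) "greater" else if (upper && !lower) "less"
           else "exact"
  label <- switch(bound, greater = paste(">", signif(v, 3)),
                  less = paste("<", signif(v, 3)),
                  as.character(signif(v, 3)))
  list(value = v, bound = bound, label = label)
}
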