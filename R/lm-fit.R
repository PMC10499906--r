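# Shared Levenberg-Marquardt driver. All nonlinear fits in the package go
# through nls.lm with analytic-free residuals, deterministic starts and box
# constraints; standard errors come from the damped-least-squares covariance
# (J'J)^-1 * s^2 when it is invertible, NA otherwise.

.lm_fit <- function(par, fn, lower = rep(-Inf, length(par)),
                    upper = rep(Inf, length(par)), maxiter = 500,
                    ftol = 1e-12, ptol = 1e-12, allow_maxiter = FALSE) {
  out <- minpack.lm::nls.lm(
    par = par, fn = fn, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = ptol))
  maxed <- out$info == 5
  if (out$info == 0 || (maxed && !allow_maxiter))
    stop("Levenberg-Marquardt did not converge (info = ", out$info,
         "); last iterate: ",
         paste(sprintf("%s=%.6g", names(out$par), unlist(out$par)),
               collapse = ", "))
  est <- unlist(out$par)
  sse <- out$deviance
  nres <- length(fn(out$par))
  dof <- max(nres - length(est), 1)
  se <- tryCatch({
    covm <- solve(out$hessian) * 2 * sse / dof
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(est)))
  names(se) <- names(est)
  list(par = est, stderr = se, sse = sse, n = nres, dof = dof,
       rse = sqrt(sse / dof), info = out$info, maxed = maxed)
}
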