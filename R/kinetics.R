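#' Validate a methylation time course
#'
#' @param time minutes, non-negative, strictly increasing within each
#'   experiment.
#' @param signal normalized band intensities (unitless).
#' @param substrate substrate label, e.g. \code{"H3K4"}.
#' @param experiment experiment identifier (replicate experiments are
#'   fitted jointly).
#' @return data.frame with the four columns.
#' @export
kineticSeries <- function(time, signal, substrate = "H3K4",
                          experiment = 1L) {
  df <- data.frame(time = time, signal = signal, substrate = substrate,
                   experiment = experiment, stringsAsFactors = FALSE)
  if (any(df$time < 0)) stop("times must be non-negative")
  if (!all(is.finite(df$signal))) stop("signals must be finite")
  for (e in split(df, df$experiment))
    if (is.unsorted(e$time, strictly = TRUE))
      stop("times must be strictly increasing within an experiment")
  df
}

#' Progress-curve model
#'
#' Signal(t) = A + B (1 - exp(-k t)): mono-exponential approach of the
#' methylation signal to the amplitude A + B with rate constant k per
#' minute, so the initial rate is B k.
#'
#' @param t time in minutes.
#' @param A baseline signal.
#' @param B amplitude.
#' @param k rate constant per minute.
#' @return model signal.
#' @export
progressSignal <- function(t, A, B, k) A + B * (1 - exp(-k * t))

initRate <- function(time, signal, A0, B0) {
  y <- 1 - (signal - A0) / B0
  keep <- time > 0 & y > 1e-6 & y < 1
  if (sum(keep) < 2L) return(1 / max(stats::median(time[time > 0]), 1e-6))
  z <- -log(y[keep])
  tt <- time[keep]
  max(sum(tt * z) / sum(tt^2), 1e-6)
}

#' Shared-amplitude two-rate progress-curve fit
#'
#' Joint least squares over both substrate time courses of
#' Signal = A + B (1 - exp(-k t)) with one A and one B shared between
#' the curves and substrate-specific rate constants. Because B is
#' shared, the ratio of initial methylation rates (B k) reduces to the
#' rate-constant ratio kH3K4 / kH3K36. All replicate experiments enter
#' one unweighted residual. The optimizer is Levenberg-Marquardt with
#' the analytic model Jacobian; standard errors come from the
#' Gauss-Newton covariance approximation at the optimum and the ratio
#' error from the delta method including the rate covariance (the fit
#' reports them explicitly as approximations).
#'
#' @param seriesK4,seriesK36 time courses from
#'   \code{\link{kineticSeries}} (at least 3 distinct time points each).
#' @return a \linkS4class{SharedFitResult}.
#' @export
fitSharedProgress <- function(seriesK4, seriesK36) {
  for (s in list(seriesK4, seriesK36))
    if (length(unique(s$time)) < 3L)
      stop("need at least 3 distinct time points per substrate")
  t4 <- seriesK4$time;  y4 <- seriesK4$signal
  t36 <- seriesK36$time; y36 <- seriesK36$signal
  yAll <- c(y4, y36)
  if (diff(range(yAll)) < 1e-12)
    stop("degenerate data: flat signal, amplitude unidentifiable")
  A0 <- min(yAll)
  B0 <- max(yAll) - min(yAll)
  p0 <- c(A = A0, B = B0, kH3K4 = initRate(t4, y4, A0, B0),
          kH3K36 = initRate(t36, y36, A0, B0))
  resid <- function(p) {
    c(progressSignal(t4, p[1L], p[2L], p[3L]) - y4,
      progressSignal(t36, p[1L], p[2L], p[4L]) - y36)
  }
  jac <- function(p) {
    e4 <- exp(-p[3L] * t4); e36 <- exp(-p[4L] * t36)
    rbind(cbind(1, 1 - e4, p[2L] * t4 * e4, 0),
          cbind(1, 1 - e36, 0, p[2L] * t36 * e36))
  }
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid, jac = jac,
    lower = c(-Inf, 1e-12, 1e-12, 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  p <- fit$par
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("shared progress fit did not converge: ", fit$message)
  n <- length(yAll)
  rss <- sum(resid(p)^2)
  J <- jac(p)
  jtj <- crossprod(J)
  covm <- tryCatch({
    sigma2 <- rss / max(n - 4L, 1L)
    sigma2 * solve(jtj)
  }, error = function(e) matrix(NA_real_, 4L, 4L))
  dimnames(covm) <- list(names(p0), names(p0))
  se <- sqrt(pmax(diag(covm), 0))
  k4 <- p[[3L]]; k36 <- p[[4L]]
  ratio <- k4 / k36
  ratioSE <- if (anyNA(covm)) NA_real_ else
    abs(ratio) * sqrt(covm[3L, 3L] / k4^2 + covm[4L, 4L] / k36^2 -
                        2 * covm[3L, 4L] / (k4 * k36))
  est <- as.numeric(p); names(est) <- names(p0)
  names(se) <- names(p0)
  new("SharedFitResult", estimate = est, se = se, cov = covm,
      ratio = ratio, ratioSE = ratioSE, rss = rss, nObs = as.integer(n),
      converged = converged, message = fit$message)
}

#' @describeIn rateRatio fitted kH3K4 / kH3K36 with its delta-method SE
#' @export
setMethod("rateRatio", "SharedFitResult",
          function(x) list(ratio = x@ratio, se = x@ratioSE))

#' @describeIn fitSharedProgress fitted coefficients
#' @param object a \linkS4class{SharedFitResult}.
#' @param ... ignored.
#' @export
setMethod("coef", "SharedFitResult", function(object, ...) object@estimate)

setMethod("show", "SharedFitResult", function(object) {
  cat("Shared-amplitude progress-curve fit (A, B shared)\n")
  est <- object@estimate; se <- object@se
  for (nm in names(est))
    cat(sprintf("  %-7s %10.6g  (approx. SE %.3g)\n", nm, est[[nm]],
                se[[nm]]))
  cat(sprintf("  kH3K4/kH3K36 = %.4g (approx. SE %.3g)\n", object@ratio,
              object@ratioSE))
  cat(sprintf("  RSS %.4g over %d points; converged: %s\n", object@rss,
              object@nObs, object@converged))
})

#' Initial methylation rate from a shared fit
#'
#' The initial slope of A + B (1 - exp(-k t)) at t = 0 is B k. With B
#' shared between substrates the initial-rate ratio equals the
#' rate-constant ratio exactly.
#'
#' @param fit a \linkS4class{SharedFitResult}.
#' @param substrate \code{"H3K4"} or \code{"H3K36"}.
#' @return initial rate in signal units per minute.
#' @export
initialRate <- function(fit, substrate = c("H3K4", "H3K36")) {
  substrate <- match.arg(substrate)
  k <- fit@estimate[[if (substrate == "H3K4") "kH3K4" else "kH3K36"]]
  fit@estimate[["B"]] * k
}

#' Normalize signals to a reference signal
#'
#' @param signals numeric signals.
#' @param referenceSignal positive reference (e.g. the wild-type H3K4
#'   signal); maps to 1.
#' @return signals divided by the reference.
#' @export
normalizeToReference <- function(signals, referenceSignal) {
  if (length(referenceSignal) != 1L || !is.finite(referenceSignal) ||
      referenceSignal <= 0)
    stop("reference signal must be a single positive number")
  signals / referenceSignal
}

#' Substrate preference of an enzyme variant with propagated error
#'
#' Ratio of mean relative H3K4 to mean relative H3K36 methylation signal
#' with the first-order propagated standard error
#' ratio * sqrt((semK4/meanK4)^2 + (semK36/meanK36)^2).
#'
#' @param meanK4,semK4 mean and SEM of the relative H3K4 signal.
#' @param meanK36,semK36 mean and SEM of the relative H3K36 signal.
#' @param enzymeLabel variant name.
#' @param nReplicates replicate count carried to the output.
#' @return one-row data.frame: \code{enzyme}, means/SEMs, \code{ratio},
#'   \code{ratio_error}, \code{flag} (\code{"ok"} or
#'   \code{"undefined_ratio"} when a mean is non-positive, as for
#'   variants with abolished activity).
#' @export
mutantPreference <- function(meanK4, semK4, meanK36, semK36,
                             enzymeLabel = "variant", nReplicates = 3L) {
  if (any(c(semK4, semK36) < 0)) stop("SEMs must be non-negative")
  ok <- meanK4 > 0 && meanK36 > 0
  ratio <- if (ok) meanK4 / meanK36 else NA_real_
  err <- if (ok)
    ratio * sqrt((semK4 / meanK4)^2 + (semK36 / meanK36)^2)
  else NA_real_
  data.frame(enzyme = enzymeLabel, mean_H3K4 = meanK4, sem_H3K4 = semK4,
             mean_H3K36 = meanK36, sem_H3K36 = semK36,
             n_replicates = nReplicates, ratio = ratio,
             ratio_error = err,
             flag = if (ok) "ok" else "undefined_ratio",
             stringsAsFactors = FALSE)
}

#' Standard error of the mean of replicate measurements
#'
#' @param x replicate values.
#' @return sample SD / sqrt(n).
#' @export
semOf <- function(x) stats::sd(x) / sqrt(length(x))

#' Read a delimited kinetic time-course table
#'
#' Columns: \code{time_min}, \code{signal}, \code{substrate},
#' \code{experiment_id}.
#'
#' @param path input file.
#' @return data.frame in \code{\link{kineticSeries}} layout.
#' @export
readKineticTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("time_min", "signal", "substrate", "experiment_id")
  if (!all(need %in% names(df)))
    stop("kinetic table must have columns: ", paste(need, collapse = ", "))
  data.frame(time = df$time_min, signal = df$signal,
             substrate = df$substrate, experiment = df$experiment_id,
             stringsAsFactors = FALSE)
}

#' Write a kinetic time-course table
#'
#' @param series data.frame in \code{\link{kineticSeries}} layout.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeKineticTable <- function(series, path) {
  out <- data.frame(time_min = series$time, signal = series$signal,
                    substrate = series$substrate,
                    experiment_id = series$experiment)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
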