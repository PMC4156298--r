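# Steady-state kinetics: the Hill equation, nonlinear least-squares
# fitting, and mutant-versus-wild-type fold changes.

#' Hill-equation velocity
#'
#' v = Vmax * S^h / (Km^h + S^h).  With h = 1 this is the
#' Michaelis--Menten equation; h > 1 gives sigmoidal (cooperative)
#' saturation.  Continuous and strictly increasing in S, bounded by Vmax.
#'
#' @param S substrate concentration(s), uM; must be >= 0.
#' @param Vmax maximal velocity (same units as the measured velocities).
#' @param Km half-saturation constant, uM.
#' @param h Hill coefficient (default 1).
#' @return velocity, recycled over `S`.
#' @examples
#' hillVelocity(12, Vmax = 0.646, Km = 12)      # Vmax / 2
#' hillVelocity(120, Vmax = 0.646, Km = 12)     # (10/11) * Vmax
#' @export
hillVelocity <- function(S, Vmax, Km, h = 1) {
  stopifnot(all(S >= 0), Vmax > 0, Km > 0, h > 0)
  ifelse(S == 0, 0, Vmax * S^h / (Km^h + S^h))
}

nonConvergedFit <- function(enzymeConc, nobs, fixedH) {
  new("KineticFit",
      estimates = c(Vmax = NA_real_, Km = NA_real_, h = NA_real_),
      se = c(Vmax = NA_real_, Km = NA_real_, h = NA_real_),
      enzymeConc = enzymeConc, kcat = NA_real_, kcatSe = NA_real_,
      kcatOverKm = NA_real_, kcatOverKmSe = NA_real_,
      rss = NA_real_, nobs = as.integer(nobs),
      fixedH = fixedH, converged = FALSE)
}

#' Fit the Hill equation to saturation data
#'
#' Nonlinear least squares (Levenberg--Marquardt) on
#' v = Vmax * S^h / (Km^h + S^h), with positivity of all parameters
#' enforced by fitting on the log scale.  Standard errors on the natural
#' scale come from the fit covariance by the delta method.  kcat is
#' Vmax / `enzymeConc`; set `enzymeConc = 1` to report Vmax itself as
#' kcat.  Replicates are fitted pooled, preserving the error structure
#' for the standard errors.
#'
#' Starting values: Vmax at the largest observed velocity, Km at the
#' concentration whose velocity is nearest half of that, h = 1.
#' Degenerate data with no saturation signal (velocity range below
#' `flatTol` times the velocity scale) yield a non-converged fit rather
#' than silent estimates.
#'
#' @param data data.frame with columns `substrate_conc_uM` and
#'   `velocity` (a `replicate` column may be present but is not needed).
#' @param enzymeConc total enzyme concentration, uM; required for kcat.
#' @param fixH optional fixed Hill coefficient; `fixH = 1` reduces the
#'   model to Michaelis--Menten.
#' @param flatTol relative velocity-range threshold below which the data
#'   are declared flat (default 1e-8).
#' @return a [KineticFit-class].
#' @examples
#' d <- simulateKinetics(kcat = 0.646, Km = 12, cv = 0, seed = 1)
#' fitHill(d, enzymeConc = 1, fixH = 1)
#' @export
fitHill <- function(data, enzymeConc, fixH = NULL, flatTol = 1e-8) {
  if (missing(enzymeConc) || is.null(enzymeConc))
    stop("enzymeConc is required to convert Vmax to kcat")
  stopifnot(is.numeric(enzymeConc), enzymeConc > 0)
  need <- c("substrate_conc_uM", "velocity")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  S <- data$substrate_conc_uM
  v <- data$velocity
  if (any(S < 0)) stop("negative substrate concentrations in data")
  if (any(!is.finite(v))) stop("non-finite velocities in data")
  if (length(unique(S)) < 4L)
    stop("need at least 4 distinct substrate concentrations")
  fixedH <- !is.null(fixH)
  if (fixedH) stopifnot(fixH > 0)
  if (diff(range(v)) <= flatTol * max(abs(v), 1))
    return(nonConvergedFit(enzymeConc, length(v), fixedH))

  v0 <- max(v)
  km0 <- S[which.min(abs(v - v0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S[S > 0])
  model <- function(p) {
    hh <- if (fixedH) fixH else exp(p[["lh"]])
    exp(p[["lV"]]) * S^hh / (exp(p[["lK"]])^hh + S^hh)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15)
  # Levenberg-Marquardt on the log-parameter residuals; multiple starts
  # guard against poor initial curvature on sparse grids.
  starts <- list(c(1, 1), c(1.1, 1.3), c(0.9, 0.6), c(1.5, 3))
  fit <- NULL
  for (s in starts) {
    p0 <- c(lV = log(v0 * s[1L]), lK = log(km0 * s[2L]))
    if (!fixedH) p0 <- c(p0, lh = 0)
    cand <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = function(p) v - model(p),
                         control = ctrl),
      error = function(e) NULL)
    if (!is.null(cand) && cand$info %in% 1:3 &&
        all(is.finite(unlist(cand$par)))) {
      if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
    }
  }
  if (is.null(fit)) return(nonConvergedFit(enzymeConc, length(v), fixedH))

  cf <- unlist(fit$par)
  npar <- length(cf)
  sigma2 <- fit$deviance / max(length(v) - npar, 1L)
  vc <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0))
    vc <- matrix(0, npar, npar)
  dimnames(vc) <- list(names(cf), names(cf))
  Vmax <- exp(cf[["lV"]])
  Km <- exp(cf[["lK"]])
  h <- if (fixedH) fixH else exp(cf[["lh"]])
  # delta method: SE(exp(p)) = exp(p) * SE(p)
  seV <- Vmax * sqrt(vc["lV", "lV"])
  seK <- Km * sqrt(vc["lK", "lK"])
  seH <- if (fixedH) 0 else h * sqrt(vc["lh", "lh"])
  kcat <- Vmax / enzymeConc
  kcatSe <- seV / enzymeConc
  kOverK <- kcat / Km
  # var(log(kcat/Km)) = var(lV) + var(lK) - 2 cov(lV, lK)
  varLog <- vc["lV", "lV"] + vc["lK", "lK"] - 2 * vc["lV", "lK"]
  kOverKSe <- kOverK * sqrt(max(varLog, 0))
  new("KineticFit",
      estimates = c(Vmax = Vmax, Km = Km, h = h),
      se = c(Vmax = seV, Km = seK, h = seH),
      enzymeConc = enzymeConc, kcat = kcat, kcatSe = kcatSe,
      kcatOverKm = kOverK, kcatOverKmSe = kOverKSe,
      rss = fit$deviance, nobs = length(v),
      fixedH = fixedH, converged = TRUE)
}

#' Fold changes between two kinetic fits
#'
#' Elementwise ratios a/b of kcat, Km and kcat/Km, e.g. a mutant over the
#' wild type.  `foldChange(a, b) * foldChange(b, a) = 1` elementwise.
#'
#' @param a,b converged [KineticFit-class] objects (numerator and
#'   denominator respectively).
#' @return named numeric: `kcat`, `Km`, `kcat_over_Km`.
#' @export
foldChange <- function(a, b) {
  if (!a@converged || !b@converged)
    stop("both fits must have converged")
  denom <- c(b@kcat, b@estimates[["Km"]], b@kcatOverKm)
  if (any(denom == 0)) stop("zero denominator in fold change")
  c(kcat = a@kcat / b@kcat,
    Km = a@estimates[["Km"]] / b@estimates[["Km"]],
    kcat_over_Km = a@kcatOverKm / b@kcatOverKm)
}

#' Read a saturation-assay table
#'
#' Delimited text with a header and columns `substrate_conc_uM`,
#' `velocity` and optionally `replicate`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data.frame.
#' @export
readAssayTable <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("substrate_conc_uM", "velocity")
  if (!all(need %in% names(df)))
    stop("assay table ", path, " must have columns: ",
         paste(need, collapse = ", "))
  df
}
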