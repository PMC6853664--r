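# Gene-wise cell-mean linear models across a two-condition time course,
# empirical-Bayes variance moderation (Smyth 2004 method-of-moments), and
# moderated t / F statistics for the five contrast families.

#' Fit gene-wise cell-mean models for a two-condition time course
#'
#' Each (condition, time) cell mean is estimated by the replicate mean of
#' log2 expression; the pooled residual variance (df = n_samples - n_cells)
#' is then squeezed towards an empirical prior by the method-of-moments
#' estimator on log-variances, yielding the moderated variance used by all
#' downstream contrast tests.
#'
#' @param tce a \linkS4class{TimecourseExperiment}.
#' @param control,experimental condition labels; the control enters contrast
#'   denominators, so positive LFC means overexpression in
#'   \code{experimental}.
#' @return a \linkS4class{ModeratedFit}.
#' @export
fitTimecourse <- function(tce, control, experimental) {
  if (identical(control, experimental))
    stop("control and experimental conditions must differ")
  cond <- sampleConditions(tce)
  for (cc in c(control, experimental))
    if (!cc %in% cond) stop("condition not present in the data: ", cc)
  keep <- cond %in% c(control, experimental)
  vals <- exprValues(tce)[, keep, drop = FALSE]
  cond <- cond[keep]
  tm <- sampleTimes(tce)[keep]
  tCtrl <- sort(unique(tm[cond == control]))
  tExp <- sort(unique(tm[cond == experimental]))
  if (!identical(tCtrl, tExp))
    stop("the contrasted conditions must share an identical time grid")
  if (length(tCtrl) < 2L) stop("at least 2 time points are required")
  times <- tCtrl
  cellCondition <- rep(c(control, experimental), each = length(times))
  cellTime <- rep(times, 2L)
  cellId <- paste(cellCondition, cellTime, sep = "@")
  sampleCell <- match(paste(cond, tm, sep = "@"), cellId)
  cellN <- tabulate(sampleCell, nbins = length(cellId))
  if (any(cellN < 2L))
    stop("cell(s) with fewer than 2 replicates: ",
         paste(cellId[cellN < 2L], collapse = ", "))
  # cell means via group indicator
  G <- matrix(0, ncol(vals), length(cellId))
  G[cbind(seq_along(sampleCell), sampleCell)] <- 1 / cellN[sampleCell]
  coef <- vals %*% G
  colnames(coef) <- cellId
  fitted <- coef[, sampleCell, drop = FALSE]
  dfResidual <- ncol(vals) - length(cellId)
  sigma2 <- rowSums((vals - fitted)^2) / dfResidual
  sq <- squeezeVariances(sigma2, dfResidual)
  new("ModeratedFit",
      coefficients = coef,
      cellCondition = cellCondition, cellTime = cellTime,
      cellN = as.integer(cellN),
      sigma2 = sigma2, dfResidual = dfResidual,
      dfPrior = sq$dfPrior, s2Prior = sq$s2Prior, s2Post = sq$s2Post,
      control = control, experimental = experimental, times = times)
}

# Smyth (2004) method-of-moments squeeze of gene-wise variances towards an
# empirical prior; equal-df case.  With < 2 genes no prior can be estimated
# and the sample variances are returned unshrunk.
squeezeVariances <- function(s2, df) {
  n <- length(s2)
  if (n < 2L)
    return(list(dfPrior = 0, s2Prior = NA_real_, s2Post = s2))
  s2f <- pmax(s2, 1e-10)
  e <- log(s2f) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    dfPrior <- 2 * trigammaInverse(evar)
    s2Prior <- exp(emean + digamma(dfPrior / 2) - log(dfPrior / 2))
    s2Post <- (df * s2 + dfPrior * s2Prior) / (df + dfPrior)
  } else {
    # no excess spread beyond chi-square sampling noise: infinite prior df,
    # prior at the mean variance (all genes share one variance estimate)
    dfPrior <- Inf
    s2Prior <- mean(s2f)
    s2Post <- rep(s2Prior, n)
  }
  list(dfPrior = dfPrior, s2Prior = s2Prior, s2Post = s2Post)
}

# Newton solve of trigamma(x) = y (y > 0), with asymptotic starts.
trigammaInverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# contrast matrix L (cells x contrasts) for a family, given a ModeratedFit's
# cell layout: control cells (by time) first, then experimental cells.
contrastDefinition <- function(fit, family) {
  family <- match.arg(family, CONTRAST_FAMILIES)
  T <- length(fit@times)
  ctrl <- seq_len(T)
  expi <- T + seq_len(T)
  nc <- 2L * T
  col <- function(plus, minus) {
    v <- numeric(nc)
    v[plus] <- v[plus] + 1
    v[minus] <- v[minus] - 1
    v
  }
  tlab <- function(i) paste0("t", fit@times[i])
  switch(family,
    "PW" = {
      L <- vapply(seq_len(T), function(i) col(expi[i], ctrl[i]), numeric(nc))
      colnames(L) <- vapply(seq_len(T), tlab, "")
      L
    },
    "TS" = {
      L <- vapply(2:T, function(i) col(expi[i], expi[i - 1]), numeric(nc))
      colnames(L) <- vapply(2:T, function(i) paste0(tlab(i), "-", tlab(i - 1)), "")
      L
    },
    "AR" = {
      L <- vapply(2:T, function(i) col(expi[i], expi[1]), numeric(nc))
      colnames(L) <- vapply(2:T, function(i) paste0(tlab(i), "-", tlab(1)), "")
      L
    },
    "PW-TS" = {
      L <- vapply(2:T, function(i)
        col(expi[i], expi[i - 1]) - col(ctrl[i], ctrl[i - 1]), numeric(nc))
      colnames(L) <- vapply(2:T, function(i) paste0(tlab(i), "-", tlab(i - 1)), "")
      L
    },
    "PW-AR" = {
      L <- vapply(2:T, function(i)
        col(expi[i], expi[1]) - col(ctrl[i], ctrl[1]), numeric(nc))
      colnames(L) <- vapply(2:T, function(i) paste0(tlab(i), "-", tlab(1)), "")
      L
    })
}

#' Log fold changes for one contrast family
#'
#' The LFC is the difference of mean log2 expression for the contrasted
#' cells (control in the denominator of the implied fold change): PW
#' contrasts compare conditions at each time; TS compares consecutive times
#' and AR each time versus time 0, both within the experimental condition;
#' PW-TS / PW-AR difference the temporal contrasts against the control
#' condition.
#'
#' @param fit a \linkS4class{ModeratedFit}.
#' @param family one of \code{"PW"}, \code{"TS"}, \code{"AR"},
#'   \code{"PW-TS"}, \code{"PW-AR"}.
#' @return genes x contrasts matrix of LFCs (log2 units).
#' @export
contrastLFC <- function(fit, family) {
  L <- contrastDefinition(fit, family)
  fit@coefficients %*% L
}

#' Moderated contrast tests for one family
#'
#' Per-contrast moderated t statistics (lfc / (s~ * u), u the unscaled
#' standard error from the design), two-sided p-values on
#' \code{dfResidual + dfPrior} degrees of freedom, a moderated family F test
#' across the family's contrasts, and BH adjustment applied across genes
#' separately per contrast column and for the F p-values.
#'
#' @inheritParams contrastLFC
#' @return a \linkS4class{ContrastResult}.
#' @export
contrastTests <- function(fit, family) {
  L <- contrastDefinition(fit, family)
  lfc <- fit@coefficients %*% L
  u2 <- colSums(L^2 / fit@cellN)
  se <- sqrt(outer(fit@s2Post, u2))
  tstat <- lfc / se
  df2 <- fit@dfResidual + fit@dfPrior
  p <- 2 * pt(-abs(tstat), df = df2)
  pAdj <- apply(p, 2, bhAdjust)
  dimnames(pAdj) <- dimnames(p)
  # moderated F across the family's contrasts: l' V^{-1} l / (C s2Post),
  # V the unscaled covariance of the contrast estimators.
  V <- t(L) %*% (L / fit@cellN)
  U <- chol(solve(V))
  q <- lfc %*% t(U)
  C <- ncol(L)
  fStat <- rowSums(q^2) / (C * fit@s2Post)
  fP <- pf(fStat, df1 = C, df2 = df2, lower.tail = FALSE)
  new("ContrastResult", family = family, lfc = lfc, t = tstat,
      p = p, pAdj = pAdj, fStat = fStat, fP = fP, fPAdj = bhAdjust(fP),
      df1 = C, df2 = df2)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' order-preserving.  Thin wrapper over \code{stats::p.adjust}.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values, same order as the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' @describeIn contrastTests LFC matrix of a ContrastResult
#' @param x a ContrastResult.
#' @export
setMethod("lfcValues", "ContrastResult", function(x) x@lfc)

#' @describeIn contrastTests BH-adjusted per-contrast p-values
#' @export
setMethod("adjustedP", "ContrastResult", function(x) x@pAdj)

#' @describeIn contrastTests family F-test p-values (BH-adjusted by default)
#' @param adjusted return BH-adjusted values?
#' @export
setMethod("overallFP", "ContrastResult",
          function(x, adjusted = TRUE) if (adjusted) x@fPAdj else x@fP)

#' @describeIn contrastTests contrast family label
#' @export
setMethod("contrastFamily", "ContrastResult", function(x) x@family)

setMethod("show", "ContrastResult", function(object) {
  cat("ContrastResult (", object@family, "): ", nrow(object@lfc), " genes x ",
      ncol(object@lfc), " contrasts [", paste(colnames(object@lfc),
      collapse = ", "), "]\n", sep = "")
})

setMethod("show", "ModeratedFit", function(object) {
  cat("ModeratedFit:", nrow(object@coefficients), "genes,",
      length(object@cellN), "cells (", object@control, "vs",
      object@experimental, ")\n")
  cat("residual df:", object@dfResidual, " prior df:",
      format(object@dfPrior, digits = 4), "\n")
})
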