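# Independent oracles and small builders used across the suite.

# Two-pass population variance, element by element.
oraclePopVar <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / length(x)
}

# Brute-force extrusion length: fine Riemann cumulation of the stiffness
# integral until the work budget is exhausted.
oracleExtrusion <- function(F, profile, du = 0.005, eMax = 500) {
  u <- seq(du / 2, eMax, by = du)
  b <- c(0, profile@breaksKbp)
  s <- profile@stiffness[findInterval(u, b)]
  w <- cumsum(s * du)
  idx <- which(w > F)
  if (!length(idx)) stop("oracle grid too short")
  (idx[1] - 1L) * du
}

# Closed-form pooled variance of l', derived from first principles per
# model (independent of theoreticalVariance()).
oraclePooledVar <- function(d, l, model, eps, meanF = mean(l / d)) {
  perSegVar <- switch(model,
    "additive-mean-relative" = (eps * meanF)^2 * d^2,
    "additive-absolute" = eps^2 * d^2,
    "multiplicative" = eps^2 * l^2 + 0 * d,
    "brownian" = eps^2 * d)
  mean(perSegVar)
}

# 3-standard-error band of the pooled-variance MC estimator
# (Var((x - mu)^2) = 2 v^2 for Gaussian noise).
oraclePooledVarSE <- function(d, l, model, eps, R, meanF = mean(l / d)) {
  v <- switch(model,
    "additive-mean-relative" = (eps * meanF)^2 * d^2,
    "additive-absolute" = eps^2 * d^2,
    "multiplicative" = eps^2 * l^2 + 0 * d,
    "brownian" = eps^2 * d)
  sqrt(2 * mean(v^2) / (R * length(d)))
}

oraclePooledMeanSE <- function(d, l, model, eps, R, meanF = mean(l / d)) {
  v <- oraclePooledVar(d, l, model, eps, meanF)
  sqrt(v / (R * length(d)))
}

mouseDistances <- c(15, 16, 26, 10, 6, 10, 5, 6)

defaultSimParts <- function(cluster, lambda = 3, alpha = 1, stiff = 1) {
  field <- MorphogenField(axisLength = 10, decayLambda = lambda,
                          peakValue = 1)
  list(field = field,
       schedule = defaultSchedule(field, nGenes(cluster)),
       charges = ChargeModel(cluster, alpha = alpha),
       profile = uniformProfile(stiff),
       kernel = ActivationKernel())
}
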