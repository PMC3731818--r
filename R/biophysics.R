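# Force model: morphogen gradient and thresholds, pulling force F = P * N,
# quasi-static extrusion against a stiffness profile, activation near the
# transcription factory, and the three collinearity checks.

#' Morphogen concentration along the axis
#'
#' `M(x) = M0 * exp(-(axisLength - x) / lambda)`: strictly increasing in x,
#' peak `M0` at the posterior end.
#'
#' @param field a [MorphogenField-class].
#' @param x axis position(s), in `[0, axisLength]`.
#' @return concentration(s), same length as `x`.
#' @export
morphogenAt <- function(field, x) {
  stopifnot(is(field, "MorphogenField"))
  if (any(x < 0 | x > field@axisLength))
    stop("'x' must lie within [0, axisLength]")
  field@peakValue * exp(-(field@axisLength - x) / field@decayLambda)
}

#' Default threshold/time schedule for a gene count
#'
#' Thresholds are the morphogen values at n equispaced axis positions
#' starting at the anterior end (so the first domain is the whole axis and
#' each later domain is a nested posterior part), times are 1..n.
#'
#' @param field a [MorphogenField-class].
#' @param n number of genes.
#' @return a [ThresholdSchedule-class].
#' @export
defaultSchedule <- function(field, n) {
  x <- field@axisLength * (seq_len(n) - 1L) / n
  ThresholdSchedule(morphogenAt(field, x), seq_len(n))
}

#' Expression domain of the k-th gene
#'
#' `Sk = {x : M(x) >= Tk}`: the posterior axis interval above threshold Tk.
#' Domains are nested, `S1` contains `S2` contains ..., and all share the
#' posterior end. A threshold above the peak gives an empty domain,
#' returned as `c(NA, NA)`.
#'
#' @param field a [MorphogenField-class].
#' @param schedule a [ThresholdSchedule-class].
#' @param k gene rank, 1-based.
#' @return numeric `c(anterior, posterior)` boundaries of Sk.
#' @export
expressionDomain <- function(field, schedule, k) {
  stopifnot(is(schedule, "ThresholdSchedule"))
  if (k < 1L || k > length(schedule@thresholds))
    stop("'k' out of range")
  Tk <- schedule@thresholds[k]
  if (Tk > field@peakValue)
    return(c(anterior = NA_real_, posterior = NA_real_))
  xmin <- max(0, field@axisLength + field@decayLambda * log(Tk / field@peakValue))
  c(anterior = xmin, posterior = field@axisLength)
}

#' Pulling force on the cluster
#'
#' `F = P(x, t) * N` with `P(x, t) = alpha * M(x) * t`: P-molecules
#' accumulate linearly in time at a rate set by the local morphogen
#' concentration, and the force scales with the cluster charge N. F is
#' nondecreasing in x, t and cluster span; at `t = 0` no force is exerted
#' (the ground state).
#'
#' @param charges a [ChargeModel-class].
#' @param field a [MorphogenField-class].
#' @param x axis position(s).
#' @param t time(s) >= 0 (arbitrary units).
#' @return force value(s).
#' @export
pullForce <- function(charges, field, x, t) {
  stopifnot(is(charges, "ChargeModel"))
  if (any(t < 0)) stop("'t' must be >= 0")
  charges@alpha * morphogenAt(field, x) * t * charges@N
}

setMethod("show", "ElasticityProfile", function(object) {
  k <- length(object@breaksKbp)
  cat(sprintf("ElasticityProfile: %d step(s)\n", k + 1L))
  from <- c(0, object@breaksKbp)
  to <- c(object@breaksKbp, Inf)
  for (i in seq_len(k + 1L))
    cat(sprintf("  [%g, %g) Kbp: s = %g\n", from[i], to[i],
                object@stiffness[i]))
})

# Work needed to extrude the fiber to length e: integral_0^e s(u) du.
.profileWork <- function(profile, e) {
  b <- c(0, profile@breaksKbp)
  s <- profile@stiffness
  w <- 0
  for (i in seq_along(s)) {
    lo <- b[i]
    hi <- if (i < length(s)) min(b[i + 1L], e) else e
    if (hi <= lo) break
    w <- w + (hi - lo) * s[i]
  }
  w
}

#' Extruded fiber length under a force
#'
#' Quasi-static work balance of the elastic-spring analogue: the fiber is
#' extruded from the anterior (3') end to the largest `E` whose stiffness
#' integral does not exceed the effective force,
#' `E = max(e : integral_0^e s(u) du <= F_eff)`. With the posterior 5'
#' anchor intact `F_eff = F`; when a splitting has removed the anchor the
#' spring is loose at both ends and decondenses with abnormally smaller
#' forces, modeled as `F_eff = F / rho` with `0 < rho < 1`. A uniform
#' profile gives the linear spring `E = F_eff / s`.
#'
#' @param F force, >= 0 (vectorized).
#' @param profile an [ElasticityProfile-class].
#' @param fixedEndIntact logical(1), is the 5' anchor present?
#' @param looseEndGain rho in (0, 1), resistance factor once the anchor is
#'   removed.
#' @return extruded length(s) E in Kbp, nondecreasing in F.
#' @examples
#' extrusionLength(10, uniformProfile(1))          # 10
#' extrusionLength(10, uniformProfile(1), FALSE)   # 20 at rho = 0.5
#' @export
extrusionLength <- function(F, profile, fixedEndIntact = TRUE,
                            looseEndGain = 0.5) {
  stopifnot(is(profile, "ElasticityProfile"))
  if (any(F < 0)) stop("'F' must be >= 0")
  if (!fixedEndIntact && (looseEndGain <= 0 || looseEndGain >= 1))
    stop("'looseEndGain' must be in (0, 1) when the fixed end is removed")
  Feff <- if (fixedEndIntact) F else F / looseEndGain
  b <- profile@breaksKbp
  s <- profile@stiffness
  widths <- diff(c(0, b))
  cw <- cumsum(widths * s[seq_along(widths)])  # work to reach each break
  vapply(Feff, function(f) {
    i <- findInterval(f, c(0, cw), rightmost.closed = FALSE)
    # i-th step is being stretched; work already spent: cw[i - 1]
    spent <- if (i > 1L) cw[i - 1L] else 0
    base <- if (i > 1L) b[i - 1L] else 0
    base + (f - spent) / s[min(i, length(s))]
  }, numeric(1))
}

# Remove the fiber interval [x1, x2] from a stiffness profile (deletion
# surgery): s_new(u) = s(u) for u < x1, s(u + (x2 - x1)) beyond.
.exciseProfile <- function(profile, x1, x2) {
  stopifnot(x2 >= x1, x1 >= 0)
  if (x2 == x1) return(profile)
  from <- c(0, profile@breaksKbp)
  to <- c(profile@breaksKbp, Inf)
  s <- profile@stiffness
  keepF <- pmin(from, x1)
  keepT <- pmin(to, x1)
  shiftF <- pmax(from, x2) - (x2 - x1)
  shiftT <- pmax(to, x2) - (x2 - x1)
  segs <- rbind(data.frame(from = keepF, to = keepT, s = s),
                data.frame(from = shiftF, to = shiftT, s = s))
  segs <- segs[segs$to > segs$from, , drop = FALSE]
  segs <- segs[order(segs$from), , drop = FALSE]
  # merge adjacent equal-stiffness steps (segments are contiguous after
  # excision, so run ends delimit the new breaks)
  runs <- rle(segs$s)
  ends <- segs$to[cumsum(runs$lengths)]
  ElasticityProfile(breaksKbp = ends[-length(ends)],
                    stiffness = runs$values)
}

#' Activation intensity of an extruded gene
#'
#' Zero while the gene is inside the chromosome territory
#' (`delta <= 0`); once past the CT/ICD border, a triangular kernel peaked
#' at the transcription-factory offset: intensity
#' `I0 * max(0, 1 - |delta - tfOffset| / width)`. With the factory at the
#' border (default `tfOffset = 0`) intensity strictly decreases as the gene
#' moves deeper into the ICD, so at any axis point the most posterior
#' extruded gene — the one nearest the factory — is the most strongly
#' expressed (quantitative collinearity).
#'
#' @param delta signed distance(s) of the gene past the CT/ICD border
#'   (`E - L_g`, Kbp).
#' @param kernel an [ActivationKernel-class].
#' @return intensity value(s).
#' @export
activationIntensity <- function(delta, kernel = ActivationKernel()) {
  stopifnot(is(kernel, "ActivationKernel"))
  ifelse(delta <= 0, 0,
         kernel@peakIntensity *
           pmax(0, 1 - abs(delta - kernel@tfOffset) / kernel@width))
}

#' Simulate per-gene expression at one axis position and time
#'
#' Composes the force model deterministically: the pulling force at (x, t)
#' sets the extruded fiber length on the elasticity profile; each gene's
#' position past the CT/ICD border sets its activation intensity.
#'
#' @param cluster a [HoxCluster-class].
#' @param field a [MorphogenField-class].
#' @param schedule a [ThresholdSchedule-class] (carried in the state for
#'   domain bookkeeping; the force model itself generates the collinear
#'   pattern).
#' @param charges a [ChargeModel-class] built from `cluster`.
#' @param profile an [ElasticityProfile-class].
#' @param kernel an [ActivationKernel-class].
#' @param x axis position.
#' @param t time >= 0.
#' @param looseEndGain rho used if the cluster's 5' anchor is removed.
#' @return an [ExtrusionState-class]; see [intensities()].
#' @examples
#' cl <- hoxFixture("mouse_hoxd")
#' fld <- MorphogenField()
#' st <- simulateExpression(cl, fld, defaultSchedule(fld, nGenes(cl)),
#'                          ChargeModel(cl), uniformProfile(),
#'                          ActivationKernel(), x = 10, t = 1)
#' intensities(st)
#' @export
simulateExpression <- function(cluster, field, schedule, charges, profile,
                               kernel, x, t, looseEndGain = 0.5) {
  F <- pullForce(charges, field, x, t)
  E <- extrusionLength(F, profile,
                       fixedEndIntact = cluster@fixedPosteriorEnd,
                       looseEndGain = looseEndGain)
  L <- genePositions(cluster)
  delta <- E - L
  new("ExtrusionState", force = F, extrudedLength = E,
      geneNumbers = cluster@geneNumbers, deltas = unname(delta),
      intensities = unname(activationIntensity(delta, kernel)))
}

#' @describeIn simulateExpression per-gene activation intensities, named by
#'   gene number.
#' @param object an [ExtrusionState-class].
#' @export
setMethod("intensities", "ExtrusionState", function(object) {
  stats::setNames(object@intensities, object@geneNumbers)
})

setMethod("show", "ExtrusionState", function(object) {
  cat(sprintf("ExtrusionState: F = %.4g, E = %.4g Kbp\n",
              object@force, object@extrudedLength))
  print(round(intensities(object), 4))
})

#' Check the three collinearities on a space-time grid
#'
#' Simulates expression on an axis/time grid and verifies: (i) spatial
#' collinearity — the anterior expression boundary (at the final time)
#' moves posterior with gene rank; (ii) temporal collinearity — the first
#' activation time (at the posterior end) increases with gene rank; (iii)
#' quantitative collinearity — wherever several genes are active, the most
#' posterior active gene has the highest intensity. Monotonicity is checked
#' weakly (ties at grid resolution are allowed); every gene must activate
#' somewhere on the grid. The default time horizon scales itself so the
#' whole cluster extrudes at the posterior end.
#'
#' @inheritParams simulateExpression
#' @param nx,nt grid sizes (>= 2).
#' @param tMax time horizon; default 1.5x the time at which the most
#'   posterior gene extrudes at the posterior end.
#' @return list with logicals `spatial`, `temporal`, `quantitative`,
#'   `all_pass`, plus `boundaries` (anterior boundary per gene),
#'   `first_times` (first activation time per gene at the posterior end)
#'   and `witness` (coordinates of the first quantitative violation, or
#'   NULL).
#' @export
collinearityReport <- function(cluster, field, schedule, charges, profile,
                               kernel, nx = 41, nt = 41, tMax = NULL,
                               looseEndGain = 0.5) {
  if (nx < 2 || nt < 2) stop("degenerate grid: need nx >= 2 and nt >= 2")
  L <- genePositions(cluster)
  if (is.null(tMax)) {
    needF <- .profileWork(profile, max(L)) + 1e-9
    Fposterior <- pullForce(charges, field, field@axisLength, 1)
    if (!cluster@fixedPosteriorEnd) Fposterior <- Fposterior / looseEndGain
    tMax <- 1.5 * needF / Fposterior
  }
  xs <- seq(0, field@axisLength, length.out = nx)
  ts <- seq(0, tMax, length.out = nt)
  ng <- length(L)
  inten <- array(0, dim = c(ng, nx, nt))
  for (it in seq_along(ts)) {
    Fx <- pullForce(charges, field, xs, ts[it])
    Ex <- extrusionLength(Fx, profile,
                          fixedEndIntact = cluster@fixedPosteriorEnd,
                          looseEndGain = looseEndGain)
    delta <- outer(-L, Ex, `+`)            # ng x nx
    inten[, , it] <- activationIntensity(delta, kernel)
  }
  activeAnywhere <- apply(inten > 0, 1, any)

  # (i) spatial: anterior boundary at final time, per gene
  finalI <- inten[, , nt, drop = FALSE]
  boundaries <- vapply(seq_len(ng), function(g) {
    on <- which(finalI[g, , 1] > 0)
    if (length(on)) xs[min(on)] else NA_real_
  }, numeric(1))
  spatial <- all(activeAnywhere) && !anyNA(boundaries) &&
    !is.unsorted(boundaries)

  # (ii) temporal: first activation time at the posterior end
  firstTimes <- vapply(seq_len(ng), function(g) {
    on <- which(inten[g, nx, ] > 0)
    if (length(on)) ts[min(on)] else NA_real_
  }, numeric(1))
  temporal <- !anyNA(firstTimes) && !is.unsorted(firstTimes)

  # (iii) quantitative: most posterior active gene is the strongest
  witness <- NULL
  quantitative <- TRUE
  for (it in seq_along(ts)) {
    for (ix in seq_along(xs)) {
      v <- inten[, ix, it]
      act <- which(v > 0)
      if (length(act) >= 2L && which.max(v) != max(act)) {
        quantitative <- FALSE
        witness <- c(x = xs[ix], t = ts[it])
        break
      }
    }
    if (!quantitative) break
  }

  list(spatial = spatial, temporal = temporal, quantitative = quantitative,
       all_pass = spatial && temporal && quantitative,
       boundaries = stats::setNames(boundaries, names(L)),
       first_times = stats::setNames(firstTimes, names(L)),
       witness = witness)
}
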