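#' @import methods
NULL

#' HoxCluster: an ordered Hox gene cluster with intergenic distances
#'
#' Represents a contiguous Hox cluster as an ordered list of genes, anterior
#' (3') end first, together with the intergenic distances `d(i,i+1)` in Kbp
#' between successive genes. Gene paralog numbers increase from anterior to
#' posterior. The posterior (5') end is anchored inside the chromosome
#' territory unless `fixedPosteriorEnd` is `FALSE` (as after a splitting that
#' removes the anchor region).
#'
#' Gene lengths default to 0: the model works purely with intergenic
#' distances, and nonzero lengths only affect [clusterSpan()] and gene fiber
#' positions.
#'
#' @slot organism character(1) label for the cluster.
#' @slot geneNumbers integer paralog indices, all >= 1. Clusters read from
#'   files must be strictly increasing anterior to posterior; a tandem
#'   duplication mutant carries repeated numbers.
#' @slot geneLabels character labels, one per gene (e.g. `"Hoxd11"`).
#' @slot geneLengthsKbp numeric gene lengths on the fiber, >= 0.
#' @slot distancesKbp numeric intergenic distances, length = genes - 1,
#'   all > 0.
#' @slot fixedPosteriorEnd logical(1), TRUE when the 5' anchor is intact.
#'
#' @seealso [readClusterTable()], [clusterStats()], [restrictToGenes()],
#'   [clusterSpan()]
#' @export
setClass("HoxCluster", representation(
  organism = "character",
  geneNumbers = "integer",
  geneLabels = "character",
  geneLengthsKbp = "numeric",
  distancesKbp = "numeric",
  fixedPosteriorEnd = "logical"
))

setValidity("HoxCluster", function(object) {
  n <- length(object@geneNumbers)
  msg <- character(0)
  if (length(object@organism) != 1L)
    msg <- c(msg, "'organism' must be a single string")
  if (n < 1L)
    msg <- c(msg, "cluster must contain at least one gene")
  if (length(object@geneLabels) != n)
    msg <- c(msg, "'geneLabels' must align with 'geneNumbers'")
  if (length(object@geneLengthsKbp) != n)
    msg <- c(msg, "'geneLengthsKbp' must align with 'geneNumbers'")
  if (length(object@distancesKbp) != max(n - 1L, 0L))
    msg <- c(msg, "need exactly one intergenic distance per successive gene pair")
  # Strictly increasing numbers are a property of wild-type clusters and are
  # enforced by readClusterTable(); tandem-duplication mutants repeat numbers.
  if (n >= 1L && any(object@geneNumbers < 1L))
    msg <- c(msg, "gene numbers must be >= 1")
  if (any(object@geneLengthsKbp < 0))
    msg <- c(msg, "gene lengths must be >= 0")
  if (length(object@distancesKbp) && any(object@distancesKbp <= 0))
    msg <- c(msg, "all intergenic distances must be > 0")
  if (length(object@fixedPosteriorEnd) != 1L || is.na(object@fixedPosteriorEnd))
    msg <- c(msg, "'fixedPosteriorEnd' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname HoxCluster-class
#' @param organism character(1) label.
#' @param geneNumbers integer paralog indices, anterior first.
#' @param distancesKbp intergenic distances in Kbp (one fewer than genes).
#' @param geneLabels optional labels; defaults to `Hox<number>`.
#' @param geneLengthsKbp gene lengths in Kbp, recycled; default 0.
#' @param fixedPosteriorEnd logical(1); default TRUE.
#' @return A validated `HoxCluster` object.
#' @examples
#' HoxCluster("toy", c(1L, 2L, 3L), c(10, 20))
#' @export
HoxCluster <- function(organism, geneNumbers, distancesKbp,
                       geneLabels = paste0("Hox", geneNumbers),
                       geneLengthsKbp = 0,
                       fixedPosteriorEnd = TRUE) {
  geneNumbers <- as.integer(geneNumbers)
  geneLengthsKbp <- rep_len(as.numeric(geneLengthsKbp), length(geneNumbers))
  new("HoxCluster",
      organism = as.character(organism),
      geneNumbers = geneNumbers,
      geneLabels = as.character(geneLabels),
      geneLengthsKbp = geneLengthsKbp,
      distancesKbp = as.numeric(distancesKbp),
      fixedPosteriorEnd = fixedPosteriorEnd)
}

#' FPRProfile: factors of phenotypic realization for one cluster
#'
#' The factor of phenotypic realization (FPR) of segment `(i,i+1)` converts
#' the functioning time of gene `i` (proportional to the intergenic distance
#' `d(i,i+1)`) into a phenotypic segment length: `f(i,i+1) = l / d(i,i+1)`,
#' so that unperturbed every segment has the ideal length `l`.
#'
#' @slot idealLength numeric(1), the ideal segment length `l` (> 0, arbitrary
#'   phenotypic units).
#' @slot factors numeric, one FPR per intergenic distance.
#' @seealso [computeFPR()], [perturbAndRealize()]
#' @export
setClass("FPRProfile", representation(
  idealLength = "numeric",
  factors = "numeric"
))

setValidity("FPRProfile", function(object) {
  if (length(object@idealLength) != 1L || object@idealLength <= 0)
    return("'idealLength' must be a single positive number")
  if (any(object@factors <= 0))
    return("all FPR factors must be > 0")
  TRUE
})

#' NoiseSpec: a Gaussian white-noise perturbation specification
#'
#' @slot model character(1), one of `"additive-mean-relative"` (default
#'   elsewhere; sd of the additive FPR perturbation is `level * mean(f)`),
#'   `"additive-absolute"` (sd = `level`), `"multiplicative"`
#'   (`f' = f * (1 + eta)`, sd(eta) = `level`) or `"brownian"`
#'   (`l' = l + eta`, sd(eta) = `level * sqrt(d)`, noise accumulating over
#'   the functioning time which is proportional to `d`).
#' @slot level numeric(1) noise level `eps` >= 0.
#' @slot realizations integer(1) number of Monte-Carlo realizations R >= 1.
#' @slot seed integer(1) RNG seed.
#' @seealso [perturbAndRealize()], [theoreticalVariance()]
#' @export
setClass("NoiseSpec", representation(
  model = "character",
  level = "numeric",
  realizations = "integer",
  seed = "integer"
))

.noiseModels <- c("additive-mean-relative", "additive-absolute",
                  "multiplicative", "brownian")

setValidity("NoiseSpec", function(object) {
  msg <- character(0)
  if (length(object@model) != 1L || !object@model %in% .noiseModels)
    msg <- c(msg, paste0("'model' must be one of: ",
                         paste(.noiseModels, collapse = ", ")))
  if (length(object@level) != 1L || is.na(object@level) || object@level < 0)
    msg <- c(msg, "'level' must be a single number >= 0")
  if (length(object@realizations) != 1L || object@realizations < 1L)
    msg <- c(msg, "'realizations' must be >= 1")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' @rdname NoiseSpec-class
#' @param model noise model name.
#' @param level noise level (standard-deviation scale), >= 0.
#' @param realizations number of Monte-Carlo realizations.
#' @param seed RNG seed.
#' @return A validated `NoiseSpec`.
#' @examples
#' NoiseSpec(level = 0.05, realizations = 250, seed = 1)
#' @export
NoiseSpec <- function(model = "additive-mean-relative", level = 0.05,
                      realizations = 250L, seed = 1L) {
  new("NoiseSpec", model = model, level = as.numeric(level),
      realizations = as.integer(realizations), seed = as.integer(seed))
}

#' PerturbedSegments: noise-perturbed phenotypic segment lengths
#'
#' One row per Monte-Carlo realization, one column per intergenic segment;
#' entry `(r, i)` is the perturbed segment length `l'(i,i+1)` of realization
#' `r`, `l'(i,i+1) = f'(i,i+1) * d(i,i+1)`.
#'
#' @slot lengths numeric matrix, R x n_segments.
#' @slot idealLength numeric(1), the unperturbed segment length `l`.
#' @slot noise the [NoiseSpec-class] that produced the matrix.
#' @seealso [segmentStats()]
#' @export
setClass("PerturbedSegments", representation(
  lengths = "matrix",
  idealLength = "numeric",
  noise = "NoiseSpec"
))

setValidity("PerturbedSegments", function(object) {
  if (!is.numeric(object@lengths) || nrow(object@lengths) < 1L ||
      ncol(object@lengths) < 1L)
    return("'lengths' must be a nonempty numeric matrix")
  TRUE
})

#' MorphogenField: exponential morphogen gradient along the embryonic axis
#'
#' Concentration `M(x) = M0 * exp(-(axisLength - x) / decayLambda)`:
#' strictly increasing toward the posterior end `x = axisLength`, where it
#' attains the peak `M0`. The functional form is the standard minimal choice;
#' every model conclusion only uses its monotonicity.
#'
#' @slot axisLength numeric(1) > 0, anterior-posterior axis length
#'   (arbitrary embryo units; anterior at x = 0).
#' @slot decayLambda numeric(1) > 0, gradient decay length.
#' @slot peakValue numeric(1) > 0, posterior peak concentration M0.
#' @seealso [morphogenAt()], [expressionDomain()]
#' @export
setClass("MorphogenField", representation(
  axisLength = "numeric",
  decayLambda = "numeric",
  peakValue = "numeric"
))

setValidity("MorphogenField", function(object) {
  for (s in c("axisLength", "decayLambda", "peakValue")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v <= 0)
      return(sprintf("'%s' must be a single positive number", s))
  }
  TRUE
})

#' @rdname MorphogenField-class
#' @param axisLength axis length (anterior at 0, posterior peak at
#'   `axisLength`).
#' @param decayLambda decay length of the gradient.
#' @param peakValue peak concentration at the posterior end.
#' @return A validated `MorphogenField`.
#' @examples
#' morphogenAt(MorphogenField(10, 3, 1), c(0, 5, 10))
#' @export
MorphogenField <- function(axisLength = 10, decayLambda = 3, peakValue = 1) {
  new("MorphogenField", axisLength = as.numeric(axisLength),
      decayLambda = as.numeric(decayLambda), peakValue = as.numeric(peakValue))
}

#' ThresholdSchedule: concentration thresholds and activation times
#'
#' Strictly increasing concentration thresholds `T1 < T2 < ...` divide the
#' axis into nested expression domains `Sk = {x : M(x) >= Tk}`, and the
#' strictly increasing times `t1 < t2 < ...` order gene activation.
#'
#' @slot thresholds numeric, strictly increasing, > 0.
#' @slot times numeric, strictly increasing, same length.
#' @seealso [expressionDomain()], [defaultSchedule()]
#' @export
setClass("ThresholdSchedule", representation(
  thresholds = "numeric",
  times = "numeric"
))

setValidity("ThresholdSchedule", function(object) {
  msg <- character(0)
  if (length(object@thresholds) != length(object@times))
    msg <- c(msg, "'thresholds' and 'times' must have equal length")
  if (length(object@thresholds) < 1L)
    msg <- c(msg, "schedule must contain at least one threshold")
  if (any(object@thresholds <= 0))
    msg <- c(msg, "thresholds must be > 0")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    msg <- c(msg, "thresholds must be strictly increasing")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname ThresholdSchedule-class
#' @param thresholds strictly increasing concentration thresholds.
#' @param times strictly increasing activation times.
#' @return A validated `ThresholdSchedule`.
#' @export
ThresholdSchedule <- function(thresholds, times = seq_along(thresholds)) {
  new("ThresholdSchedule", thresholds = as.numeric(thresholds),
      times = as.numeric(times))
}

#' ChargeModel: the pulling-force charges P and N
#'
#' The extruding force is `F = P * N` where `N` is a "charge" distributed
#' over the whole cluster, proportional to its fiber content
#' (`N = kappaN * clusterSpan`), and `P(x, t) = alpha * M(x) * t` is the
#' pulling capacity of the P-molecules that accumulate linearly in time at a
#' rate set by the local morphogen concentration. Units are arbitrary; only
#' orderings and ratios are meaningful.
#'
#' @slot alpha numeric(1) >= 0, P-molecule accumulation rate.
#' @slot kappaN numeric(1) > 0, charge per Kbp of fiber.
#' @slot N numeric(1) >= 0, total cluster charge.
#' @seealso [pullForce()]
#' @export
setClass("ChargeModel", representation(
  alpha = "numeric",
  kappaN = "numeric",
  N = "numeric"
))

setValidity("ChargeModel", function(object) {
  if (length(object@alpha) != 1L || object@alpha < 0)
    return("'alpha' must be a single number >= 0")
  if (length(object@kappaN) != 1L || object@kappaN <= 0)
    return("'kappaN' must be a single positive number")
  if (length(object@N) != 1L || object@N < 0)
    return("'N' must be a single number >= 0")
  TRUE
})

#' @rdname ChargeModel-class
#' @param cluster a [HoxCluster-class]; its span carries the charge N.
#' @param alpha P-molecule accumulation rate.
#' @param kappaN charge per Kbp of cluster fiber.
#' @return A validated `ChargeModel` with `N = kappaN * clusterSpan(cluster)`.
#' @examples
#' ChargeModel(HoxCluster("toy", 1:3, c(10, 20)))
#' @export
ChargeModel <- function(cluster, alpha = 1, kappaN = 1) {
  new("ChargeModel", alpha = as.numeric(alpha), kappaN = as.numeric(kappaN),
      N = as.numeric(kappaN) * clusterSpan(cluster))
}

#' ElasticityProfile: piecewise-constant stiffness along the fiber
#'
#' Local elastic stiffness `s(u) > 0` of the chromatin fiber as a step
#' function of the fiber coordinate `u` (Kbp from the anterior, 3', end).
#' The last step extends indefinitely. Extrusion against the profile is a
#' quasi-static work balance: the fiber is extruded to the largest `E` with
#' `integral_0^E s(u) du <= F_eff`.
#'
#' @slot breaksKbp numeric, strictly increasing positive right edges of the
#'   first `k` steps (may be empty for a uniform profile).
#' @slot stiffness numeric of length `k + 1`, all > 0; `stiffness[i]` applies
#'   on `(breaksKbp[i-1], breaksKbp[i]]`, the last value beyond the final
#'   break.
#' @seealso [extrusionLength()], [uniformProfile()], [generateProfile()]
#' @export
setClass("ElasticityProfile", representation(
  breaksKbp = "numeric",
  stiffness = "numeric"
))

setValidity("ElasticityProfile", function(object) {
  msg <- character(0)
  if (length(object@stiffness) != length(object@breaksKbp) + 1L)
    msg <- c(msg, "'stiffness' must have one more value than 'breaksKbp'")
  if (any(object@stiffness <= 0) || anyNA(object@stiffness))
    msg <- c(msg, "stiffness must be > 0 everywhere")
  if (length(object@breaksKbp) &&
      (any(object@breaksKbp <= 0) ||
       is.unsorted(object@breaksKbp, strictly = TRUE)))
    msg <- c(msg, "'breaksKbp' must be strictly increasing and positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ElasticityProfile-class
#' @param breaksKbp right edges of the finite steps (Kbp), possibly empty.
#' @param stiffness step values, one more than `breaksKbp`.
#' @return A validated `ElasticityProfile`.
#' @export
ElasticityProfile <- function(breaksKbp = numeric(0), stiffness = 1) {
  new("ElasticityProfile", breaksKbp = as.numeric(breaksKbp),
      stiffness = as.numeric(stiffness))
}

#' @rdname ElasticityProfile-class
#' @param s uniform stiffness value.
#' @export
uniformProfile <- function(s = 1) ElasticityProfile(numeric(0), s)

#' ActivationKernel: activation intensity as a function of ICD position
#'
#' A gene at signed distance `delta` past the CT/ICD border (`delta = E - L`,
#' extruded length minus the gene's fiber position) is silent while inside
#' the chromosome territory (`delta <= 0`). Once extruded, its activation
#' intensity is a triangular kernel peaked at the transcription-factory
#' offset `tfOffset` and reaching zero at `tfOffset +/- width`: intensity
#' drops sharply as the gene moves away from the factory, which entails
#' quantitative collinearity. The default `tfOffset = 0` places the factory
#' at the CT/ICD border.
#'
#' @slot tfOffset numeric(1) >= 0, factory position inside the ICD (Kbp).
#' @slot width numeric(1) > 0, kernel half-width (Kbp).
#' @slot peakIntensity numeric(1) > 0, intensity at the peak.
#' @seealso [activationIntensity()]
#' @export
setClass("ActivationKernel", representation(
  tfOffset = "numeric",
  width = "numeric",
  peakIntensity = "numeric"
))

setValidity("ActivationKernel", function(object) {
  if (length(object@tfOffset) != 1L || object@tfOffset < 0)
    return("'tfOffset' must be a single number >= 0")
  if (length(object@width) != 1L || object@width <= 0)
    return("'width' must be a single positive number")
  if (length(object@peakIntensity) != 1L || object@peakIntensity <= 0)
    return("'peakIntensity' must be a single positive number")
  TRUE
})

#' @rdname ActivationKernel-class
#' @param tfOffset transcription-factory offset into the ICD (Kbp).
#' @param width kernel half-width (Kbp).
#' @param peakIntensity peak intensity.
#' @return A validated `ActivationKernel`.
#' @export
ActivationKernel <- function(tfOffset = 0, width = 200, peakIntensity = 1) {
  new("ActivationKernel", tfOffset = as.numeric(tfOffset),
      width = as.numeric(width), peakIntensity = as.numeric(peakIntensity))
}

#' ExtrusionState: per-gene positions and intensities at one (x, t)
#'
#' @slot force numeric(1), the pulling force F.
#' @slot extrudedLength numeric(1), extruded fiber length E (Kbp past the
#'   CT/ICD border, from the anterior end).
#' @slot geneNumbers integer, gene paralog numbers.
#' @slot deltas numeric, per-gene `delta_g = E - L_g` (L_g = fiber distance
#'   from the anterior end to gene g).
#' @slot intensities numeric, per-gene activation intensity.
#' @seealso [simulateExpression()]
#' @export
setClass("ExtrusionState", representation(
  force = "numeric",
  extrudedLength = "numeric",
  geneNumbers = "integer",
  deltas = "numeric",
  intensities = "numeric"
))

#' Manipulation: a genetic edit of a Hox cluster
#'
#' A deletion, tandem duplication, or splitting/inversion. Deletions and
#' duplications address either a named gene range (`genesFrom`..`genesTo`,
#' optionally with the intergenic region "i" between Hoxd4 and Hoxd8) or an
#' explicit fiber interval in Kbp. Splittings record whether the fixed 5'
#' anchor (the region between Evx2 and Hoxd13) is removed from the cluster.
#'
#' @slot kind character(1): `"deletion"`, `"duplication"` or
#'   `"split_inversion"`.
#' @slot genesFrom,genesTo integer(1) gene-number range (NA when absent).
#' @slot fiberFromKbp,fiberToKbp numeric(1) explicit fiber interval (NA when
#'   absent).
#' @slot includeI logical(1): include the intergenic region "i" (the
#'   `iKbp` Kbp immediately 3' of Hoxd8).
#' @slot iKbp numeric(1) length of region "i" in Kbp (its true length is not
#'   known; default 10).
#' @slot removesFixedEnd logical(1): splitting removes the 5' anchor.
#' @slot includesEvx2Boundary logical(1): an inversion whose breakpoint
#'   includes the Evx2-Hoxd13 boundary region (equivalent to removing the
#'   anchor).
#' @slot label character(1) free-text label.
#' @seealso [deletionOf()], [duplicationOf()], [splitInversion()],
#'   [applyManipulation()]
#' @export
setClass("Manipulation", representation(
  kind = "character",
  genesFrom = "integer",
  genesTo = "integer",
  fiberFromKbp = "numeric",
  fiberToKbp = "numeric",
  includeI = "logical",
  iKbp = "numeric",
  removesFixedEnd = "logical",
  includesEvx2Boundary = "logical",
  label = "character"
))

setValidity("Manipulation", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("deletion", "duplication", "split_inversion"))
    msg <- c(msg, "'kind' must be deletion, duplication or split_inversion")
  if (!is.na(object@genesFrom) && !is.na(object@genesTo) &&
      object@genesFrom > object@genesTo)
    msg <- c(msg, "'genesFrom' must be <= 'genesTo'")
  if (!is.na(object@fiberFromKbp) && !is.na(object@fiberToKbp) &&
      object@fiberFromKbp >= object@fiberToKbp)
    msg <- c(msg, "fiber interval must have positive extent")
  if (object@iKbp < 0)
    msg <- c(msg, "'iKbp' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Outcome: qualitative expression verdict for a probe gene
#'
#' @slot verdict character(1): `"UNCHANGED"`, `"ANTERIORIZED"`,
#'   `"ANTERIORIZED_WITH_GAIN"`, `"POSTERIORIZED_DELAYED"` or `"SILENCED"`.
#' @slot caseLabel character(1): `"case1"`, `"case2"`, `"case3"` (anterior
#'   deletions only), `"posterior_rule"`, `"split_rule"` or `"none"`.
#' @slot downregulated logical(1): probe additionally downregulated (moved
#'   away from the transcription factory; posterior duplications).
#' @slot probe integer(1) probe gene number.
#' @slot rationale character(1) trace of the comparison that decided the
#'   verdict.
#' @seealso [classifyAnteriorDeletion()], [classifyPosteriorEdit()],
#'   [classifySplit()]
#' @export
setClass("Outcome", representation(
  verdict = "character",
  caseLabel = "character",
  downregulated = "logical",
  probe = "integer",
  rationale = "character"
))

.verdicts <- c("UNCHANGED", "ANTERIORIZED", "ANTERIORIZED_WITH_GAIN",
               "POSTERIORIZED_DELAYED", "SILENCED")

setValidity("Outcome", function(object) {
  msg <- character(0)
  if (!object@verdict %in% .verdicts)
    msg <- c(msg, paste0("'verdict' must be one of: ",
                         paste(.verdicts, collapse = ", ")))
  if (!object@caseLabel %in% c("case1", "case2", "case3", "posterior_rule",
                               "split_rule", "none"))
    msg <- c(msg, "invalid 'caseLabel'")
  if (length(msg)) msg else TRUE
})

.Outcome <- function(verdict, caseLabel = "none", downregulated = FALSE,
                     probe = NA_integer_, rationale = "") {
  new("Outcome", verdict = verdict, caseLabel = caseLabel,
      downregulated = downregulated, probe = as.integer(probe),
      rationale = rationale)
}
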