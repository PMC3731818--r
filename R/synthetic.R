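# Seed-deterministic generators of synthetic clusters and stiffness
# profiles, emulating compact/regular versus loose/irregular cluster
# geometries so every stage of the analysis is testable without downloads.

#' Generate a synthetic Hox-like cluster
#'
#' Draws intergenic distances from a positive distribution with the given
#' mean and coefficient of variation. The lognormal default is strictly
#' positive and right-skewed like real intergenic distances (loose
#' invertebrate-type clusters mix 5 and 100 Kbp gaps); `"uniform"` draws
#' from a symmetric interval (truncated at a small positive floor), and
#' `"fixed"` (or `dispersion = 0`) gives equal distances. Distances are
#' rounded to 0.1 Kbp so written fixtures stay human-readable (cosmetic;
#' below any tolerance used). Deterministic given `seed`.
#'
#' @param nGenes number of genes (>= 2); paralog numbers 1..nGenes.
#' @param law `"lognormal"`, `"uniform"` or `"fixed"`.
#' @param meanKbp mean intergenic distance, > 0.
#' @param dispersion coefficient of variation of the distance law, >= 0.
#' @param seed RNG seed.
#' @param organism label for the generated cluster.
#' @return a validated [HoxCluster-class].
#' @examples
#' generateCluster(10, "lognormal", meanKbp = 30, dispersion = 0.8, seed = 1)
#' @export
generateCluster <- function(nGenes, law = c("lognormal", "uniform", "fixed"),
                            meanKbp = 30, dispersion = 0.5, seed = 1,
                            organism = NULL) {
  law <- match.arg(law)
  if (nGenes < 2L) stop("'nGenes' must be >= 2")
  if (meanKbp <= 0) stop("'meanKbp' must be > 0")
  if (dispersion < 0) stop("'dispersion' must be >= 0")
  n <- nGenes - 1L
  d <- .withSeed(seed, {
    if (dispersion == 0 || law == "fixed") {
      rep(meanKbp, n)
    } else if (law == "lognormal") {
      sdlog <- sqrt(log1p(dispersion^2))
      stats::rlnorm(n, meanlog = log(meanKbp) - sdlog^2 / 2, sdlog = sdlog)
    } else {
      h <- meanKbp * dispersion * sqrt(3)
      stats::runif(n, min = meanKbp - h, max = meanKbp + h)
    }
  })
  d <- pmax(round(d, 1), 0.1)
  if (is.null(organism))
    organism <- sprintf("synthetic_%s_n%d_cv%g_seed%g", law, nGenes,
                        dispersion, seed)
  HoxCluster(organism, seq_len(nGenes), d)
}

#' Generate a random step stiffness profile
#'
#' Positive piecewise-constant stiffness with `nSegments` steps of random
#' widths; used for property-based exploration of the extrusion mechanics.
#' Deterministic given `seed`.
#'
#' @param nSegments number of steps (>= 1).
#' @param law `"constant"` (uniform profile at `meanStiffness`),
#'   `"lognormal"` or `"uniform"` stiffness values.
#' @param seed RNG seed.
#' @param meanStiffness mean stiffness.
#' @param dispersion coefficient of variation of the stiffness law.
#' @param widthRangeKbp range the step widths are drawn from.
#' @return an [ElasticityProfile-class].
#' @export
generateProfile <- function(nSegments, law = c("constant", "lognormal",
                                               "uniform"),
                            seed = 1, meanStiffness = 1, dispersion = 0.5,
                            widthRangeKbp = c(5, 50)) {
  law <- match.arg(law)
  if (nSegments < 1L) stop("'nSegments' must be >= 1")
  .withSeed(seed, {
    widths <- stats::runif(nSegments, widthRangeKbp[1], widthRangeKbp[2])
    s <- switch(law,
      constant = rep(meanStiffness, nSegments),
      lognormal = {
        sdlog <- sqrt(log1p(dispersion^2))
        stats::rlnorm(nSegments, log(meanStiffness) - sdlog^2 / 2, sdlog)
      },
      uniform = {
        h <- meanStiffness * min(dispersion, 0.55) * sqrt(3)
        stats::runif(nSegments, meanStiffness - h, meanStiffness + h)
      })
    ElasticityProfile(breaksKbp = cumsum(widths)[-nSegments], stiffness = s)
  })
}

#' A ladder of clusters with increasing distance dispersion
#'
#' Clusters sharing the same mean intergenic distance but increasingly
#' irregular spacing — the geometry axis along which loose, irregular
#' clusters transmit developmental noise into a fuzzier body plan. Used to
#' verify that the pooled noise variance is monotone in the dispersion
#' statistic of each noise model's closed form.
#'
#' @param nGenes genes per cluster.
#' @param meanKbp shared mean distance.
#' @param dispersions ascending coefficients of variation.
#' @param law distance law, as in [generateCluster()].
#' @param seed RNG seed (each rung gets a derived sub-seed).
#' @return list of [HoxCluster-class], one per dispersion.
#' @examples
#' ladder <- clusterLadder(10, 20, c(0, 0.5, 1))
#' sapply(ladder, function(cl)
#'   theoreticalVariance(cl, 100, NoiseSpec("additive-absolute", 0.05)))
#' @export
clusterLadder <- function(nGenes = 10, meanKbp = 20,
                          dispersions = c(0, 0.5, 1), law = "lognormal",
                          seed = 1) {
  if (is.unsorted(dispersions))
    stop("'dispersions' must be sorted ascending")
  lapply(seq_along(dispersions), function(k) {
    generateCluster(nGenes, law, meanKbp, dispersions[k],
                    seed = .subSeed(seed, sprintf("ladder%d", k)),
                    organism = sprintf("ladder_cv%g", dispersions[k]))
  })
}
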