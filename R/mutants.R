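# Cluster-manipulation algebra (deletions, tandem duplications, splittings)
# and the qualitative outcome classifier for a probe gene's expression.

#' Construct cluster manipulations
#'
#' `deletionOf(from, to)` deletes the fiber from the anterior edge of gene
#' `from` to the posterior edge of gene `to` (the named genes and the
#' intergenic DNA between them); `includeI = TRUE` extends the deletion 3'
#' by the intergenic region "i" (the `iKbp` Kbp between Hoxd4 and Hoxd8,
#' immediately adjacent to Hoxd8). `deletionOf(NULL, includeI = TRUE)`
#' deletes region "i" alone. `deletionOfInterval(x1, x2)` deletes an
#' explicit fiber interval in Kbp coordinates. `duplicationOf(from, to)`
#' inserts a tandem copy of the gene range immediately 5' of the original,
#' separated by a junction spacer (defaulting to the region's anterior
#' flanking distance). `splitInversion()` splits/inverts part of the
#' cluster away; what matters to the force model is only whether the fixed
#' 5' anchor — the region between Evx2 and Hoxd13 — stays with the cluster.
#'
#' @param from,to gene-number range (both inclusive); `from = NULL` with
#'   `includeI = TRUE` addresses region "i" alone.
#' @param includeI logical, include intergenic region "i".
#' @param iKbp assumed length of region "i" in Kbp (not known precisely;
#'   default 10).
#' @param x1,x2 fiber interval in Kbp from the anterior end.
#' @param removesFixedEnd logical, the splitting removes the 5' anchor.
#' @param includesEvx2Boundary logical, the inversion breakpoint takes the
#'   Evx2-Hoxd13 boundary region away from the cluster (equivalent to
#'   removing the anchor).
#' @param label free-text label.
#' @return a [Manipulation-class].
#' @examples
#' deletionOf(8, 10)                      # del(8-10)
#' deletionOf(8, 10, includeI = TRUE)     # del(i-8-10)
#' deletionOf(NULL, includeI = TRUE)      # del(i)
#' splitInversion(removesFixedEnd = TRUE)
#' @export
deletionOf <- function(from = NULL, to = from, includeI = FALSE, iKbp = 10,
                       label = NULL) {
  if (is.null(from) && !includeI)
    stop("a deletion must remove genes and/or the intergenic region 'i'")
  if (is.null(label))
    label <- paste0("del(", paste(c(if (includeI) "i", from,
                                    if (!is.null(to) && !identical(to, from))
                                      to), collapse = "-"), ")")
  new("Manipulation", kind = "deletion",
      genesFrom = if (is.null(from)) NA_integer_ else as.integer(from),
      genesTo = if (is.null(to)) NA_integer_ else as.integer(to),
      fiberFromKbp = NA_real_, fiberToKbp = NA_real_,
      includeI = includeI, iKbp = as.numeric(iKbp),
      removesFixedEnd = FALSE, includesEvx2Boundary = FALSE, label = label)
}

#' @rdname deletionOf
#' @export
deletionOfInterval <- function(x1, x2, label = sprintf("del[%g,%g]", x1, x2)) {
  new("Manipulation", kind = "deletion",
      genesFrom = NA_integer_, genesTo = NA_integer_,
      fiberFromKbp = as.numeric(x1), fiberToKbp = as.numeric(x2),
      includeI = FALSE, iKbp = 0,
      removesFixedEnd = FALSE, includesEvx2Boundary = FALSE, label = label)
}

#' @rdname deletionOf
#' @param junctionKbp spacer between the original region and its copy;
#'   `NA` (default) uses the region's anterior flanking distance.
#' @export
duplicationOf <- function(from, to = from, junctionKbp = NA_real_,
                          label = sprintf("dup(%d-%d)", from, to)) {
  new("Manipulation", kind = "duplication",
      genesFrom = as.integer(from), genesTo = as.integer(to),
      fiberFromKbp = NA_real_, fiberToKbp = as.numeric(junctionKbp),
      includeI = FALSE, iKbp = 0,
      removesFixedEnd = FALSE, includesEvx2Boundary = FALSE, label = label)
}

#' @rdname deletionOf
#' @export
splitInversion <- function(removesFixedEnd = FALSE,
                           includesEvx2Boundary = removesFixedEnd,
                           label = "split_inversion") {
  new("Manipulation", kind = "split_inversion",
      genesFrom = NA_integer_, genesTo = NA_integer_,
      fiberFromKbp = NA_real_, fiberToKbp = NA_real_,
      includeI = FALSE, iKbp = 0,
      removesFixedEnd = removesFixedEnd,
      includesEvx2Boundary = includesEvx2Boundary, label = label)
}

setMethod("show", "Manipulation", function(object) {
  cat(sprintf("Manipulation '%s' (%s)\n", object@label, object@kind))
})

setMethod("show", "Outcome", function(object) {
  cat(sprintf("Outcome for probe gene %s: %s%s [%s]\n  %s\n",
              ifelse(is.na(object@probe), "?", object@probe),
              object@verdict,
              if (object@downregulated) " + DOWNREGULATED" else "",
              object@caseLabel, object@rationale))
})

# Fiber interval [x1, x2] addressed by a deletion/duplication on 'cluster'.
# Anterior gene edges a_g, posterior edges b_g from genePositions().
.manipulationInterval <- function(cluster, m) {
  pos <- genePositions(cluster)          # posterior edges
  aEdge <- pos - cluster@geneLengthsKbp  # anterior edges
  if (!is.na(m@fiberFromKbp)) return(c(m@fiberFromKbp, m@fiberToKbp))
  iOff <- if (m@includeI) m@iKbp else 0
  if (is.na(m@genesFrom)) {
    if (!m@includeI) stop("manipulation addresses no region")
    # region "i" alone: the iKbp immediately 3' of gene 8
    i8 <- match(8L, cluster@geneNumbers)
    if (is.na(i8)) stop("cluster has no gene 8; cannot place region 'i'")
    return(c(aEdge[i8] - m@iKbp, aEdge[i8]))
  }
  iFrom <- match(m@genesFrom, cluster@geneNumbers)
  iTo <- match(m@genesTo, cluster@geneNumbers)
  if (is.na(iFrom) || is.na(iTo))
    stop("gene range ", m@genesFrom, "-", m@genesTo, " not in cluster")
  c(aEdge[iFrom] - iOff, pos[iTo])
}

#' Apply a manipulation to a cluster
#'
#' Deletions excise the addressed fiber interval: genes inside are removed,
#' flanking distances merge, and the span (hence the charge N, which
#' follows the span) drops by the deleted length D. Duplications insert a
#' tandem copy of the region 5' of the original (span grows by the copied
#' length plus the junction spacer; the copy's genes repeat their paralog
#' numbers, labels suffixed `".1"`). Splittings leave the distances
#' untouched but record the loss of the 5' anchor via
#' `fixedPosteriorEnd = FALSE` when the anchor region is removed.
#'
#' @param cluster a [HoxCluster-class].
#' @param m a [Manipulation-class].
#' @return the mutant [HoxCluster-class].
#' @examples
#' applyManipulation(hoxFixture("mouse_hoxd"), deletionOf(8, 10))
#' @export
setMethod("applyManipulation", signature("HoxCluster", "Manipulation"),
          function(cluster, m) {
  if (m@kind == "split_inversion") {
    out <- cluster
    if (m@removesFixedEnd || m@includesEvx2Boundary)
      out@fixedPosteriorEnd <- FALSE
    validObject(out)
    return(out)
  }
  pos <- genePositions(cluster)
  aEdge <- pos - cluster@geneLengthsKbp
  if (m@kind == "deletion") {
    xx <- .manipulationInterval(cluster, m)
    x1 <- xx[1]; x2 <- xx[2]
    if (x1 < 0 || x2 > clusterSpan(cluster))
      stop("deletion region crosses the cluster boundary")
    keep <- if (!is.na(m@genesFrom)) {
      # named range: remove exactly the genes from..to (plus region "i"
      # fiber when includeI)
      !seq_along(pos) %in% match(m@genesFrom, cluster@geneNumbers):
        match(m@genesTo, cluster@geneNumbers)
    } else if (m@includeI) {
      rep(TRUE, length(pos))      # region "i" alone is intergenic
    } else {
      # explicit fiber interval: remove genes whose midpoint is in (x1, x2]
      mid <- (aEdge + pos) / 2
      !(mid > x1 & mid <= x2)
    }
    if (sum(keep) < 1L) stop("deletion would remove every gene")
    D <- x2 - x1
    newPos <- pos[keep] - ifelse(pos[keep] >= x2, D, 0)
    newA <- aEdge[keep] - ifelse(aEdge[keep] >= x2, D, 0)
    newd <- newA[-1] - newPos[-length(newPos)]
    if (any(newd <= 0))
      stop("deletion would fuse genes (a merged intergenic distance is <= 0)")
    out <- HoxCluster(paste0(cluster@organism, ":", m@label),
                      cluster@geneNumbers[keep], newd,
                      geneLabels = cluster@geneLabels[keep],
                      geneLengthsKbp = cluster@geneLengthsKbp[keep],
                      fixedPosteriorEnd = cluster@fixedPosteriorEnd)
    return(out)
  }
  # duplication
  iFrom <- match(m@genesFrom, cluster@geneNumbers)
  iTo <- match(m@genesTo, cluster@geneNumbers)
  if (is.na(iFrom) || is.na(iTo))
    stop("gene range ", m@genesFrom, "-", m@genesTo, " not in cluster")
  junction <- m@fiberToKbp
  if (is.na(junction))
    junction <- if (iFrom > 1L) cluster@distancesKbp[iFrom - 1L] else 10
  idx <- iFrom:iTo
  regionD <- if (iTo > iFrom) cluster@distancesKbp[iFrom:(iTo - 1L)]
             else numeric(0)
  n <- length(cluster@geneNumbers)
  newNumbers <- append(cluster@geneNumbers, cluster@geneNumbers[idx],
                       after = iTo)
  newLabels <- append(cluster@geneLabels,
                      paste0(cluster@geneLabels[idx], ".1"), after = iTo)
  newLengths <- append(cluster@geneLengthsKbp, cluster@geneLengthsKbp[idx],
                       after = iTo)
  # distances: ... d(iTo-1,iTo), junction, copy-internal, d(iTo, iTo+1) ...
  before <- if (iTo > 1L) cluster@distancesKbp[seq_len(iTo - 1L)]
            else numeric(0)
  after <- if (iTo < n) cluster@distancesKbp[iTo:(n - 1L)] else numeric(0)
  newd <- c(before, junction, regionD, after)
  mut <- new("HoxCluster",
             organism = paste0(cluster@organism, ":", m@label),
             geneNumbers = as.integer(newNumbers),
             geneLabels = as.character(newLabels),
             geneLengthsKbp = as.numeric(newLengths),
             distancesKbp = as.numeric(newd),
             fixedPosteriorEnd = cluster@fixedPosteriorEnd)
  validObject(mut)
  mut
})

# Verdict from the three-way comparison of E against (L - D) at relative
# tolerance eta (ties at the boundary fall to case 1).
.anteriorCaseVerdict <- function(E, L, D, eta, genesDeleted = TRUE) {
  band <- eta * L
  if (abs(E - (L - D)) <= band) {
    c(verdict = "UNCHANGED", caseLabel = "case1")
  } else if (E > (L - D) + band) {
    c(verdict = if (genesDeleted) "ANTERIORIZED_WITH_GAIN"
                else "ANTERIORIZED",
      caseLabel = "case2")
  } else {
    c(verdict = "SILENCED", caseLabel = "case3")
  }
}

#' Classify an anterior deletion's effect on a probe gene
#'
#' An anterior deletion D acts in two steps: the lost fiber reduces the
#' cluster charge N, so the wild-type force F drops to
#' `F_c = F * N_mut / N_wt`; the weaker force then extrudes the mutant
#' fiber to length E on the post-deletion elasticity profile. E is compared
#' with the naive shortened length `L - D` (L = wild-type fiber distance
#' from the anterior end to the probe), at relative tolerance `eta`:
#'
#' * `|E - (L - D)| <= eta * L` (case 1): the probe keeps its position at
#'   the CT/ICD interface — expression UNCHANGED.
#' * `E > (L - D) + eta * L` (case 2): the probe shifts deeper into the
#'   ICD; a weaker P suffices for its expression, so it is prematurely
#'   ANTERIORIZED. When the deletion removed gene-containing fiber the
#'   probe's retreat toward the CT/ICD border — where activation is
#'   strongest — additionally predicts a gain of expression
#'   (ANTERIORIZED_WITH_GAIN).
#' * `E < (L - D) - eta * L` (case 3): the probe stays inside the CT and
#'   cannot be activated. For the most posterior gene of the cluster no
#'   further posteriorization is available, so the verdict is SILENCED.
#'
#' The wild-type force is taken as the force that just extrudes the probe
#' on the wild-type profile, `F = integral_0^L s(u) du`.
#'
#' @param wt wild-type [HoxCluster-class].
#' @param m a deletion [Manipulation-class] entirely anterior to the probe.
#' @param probe probe gene number.
#' @param profile wild-type [ElasticityProfile-class]; the mutant profile
#'   is the same profile with the deleted interval excised.
#' @param eta relative tolerance for treating E and L - D as equal
#'   (default 0.05).
#' @return an [Outcome-class].
#' @examples
#' classifyAnteriorDeletion(hoxFixture("mouse_hoxd"), deletionOf(8, 10), 11)
#' @export
classifyAnteriorDeletion <- function(wt, m, probe,
                                     profile = uniformProfile(),
                                     eta = 0.05) {
  stopifnot(is(wt, "HoxCluster"), is(m, "Manipulation"))
  if (m@kind != "deletion") stop("'m' must be a deletion")
  iProbe <- match(as.integer(probe), wt@geneNumbers)
  if (is.na(iProbe)) stop("probe gene ", probe, " not in cluster")
  pos <- genePositions(wt)
  aEdge <- pos - wt@geneLengthsKbp
  xx <- .manipulationInterval(wt, m)
  if (xx[2] > aEdge[iProbe])
    stop("deleted region is not entirely anterior to the probe gene")
  L <- pos[[iProbe]]
  D <- xx[2] - xx[1]
  mut <- applyManipulation(wt, m)
  Fwt <- .profileWork(profile, L)
  Fc <- Fwt * clusterSpan(mut) / clusterSpan(wt)
  mutProfile <- .exciseProfile(profile, xx[1], xx[2])
  E <- extrusionLength(Fc, mutProfile,
                       fixedEndIntact = wt@fixedPosteriorEnd)
  genesDeleted <- !is.na(m@genesFrom) ||
    (!is.na(m@fiberFromKbp) && any(aEdge >= xx[1] & pos <= xx[2]))
  v <- .anteriorCaseVerdict(E, L, D, eta, genesDeleted)
  .Outcome(v[["verdict"]], v[["caseLabel"]], probe = probe,
           rationale = sprintf(
             paste0("%s, probe %s: L=%.2f D=%.2f F_wt=%.2f F_c=%.2f ",
                    "E=%.2f vs L-D=%.2f (band %.2f)"),
             m@label, probe, L, D, Fwt, Fc, E, L - D, eta * L))
}

#' Classify a posterior deletion or duplication
#'
#' For edits entirely posterior to the probe the elastic details drop out
#' and the force balance `F = P * N` decides directly. A posterior deletion
#' reduces N, so P must rise before the probe extrudes: its expression is
#' delayed and posteriorized (POSTERIORIZED_DELAYED). A posterior
#' duplication increases N: the probe extrudes prematurely (ANTERIORIZED)
#' but is carried further into the ICD, away from the CT/ICD border and the
#' transcription factory, so its expression level drops (the
#' `downregulated` flag) — quantitative collinearity acting on a mutant.
#'
#' @param wt wild-type [HoxCluster-class].
#' @param m a deletion or duplication [Manipulation-class] posterior to the
#'   probe, or NULL/zero-extent for a no-op (UNCHANGED).
#' @param probe probe gene number.
#' @return an [Outcome-class].
#' @examples
#' classifyPosteriorEdit(hoxFixture("mouse_hoxd"), deletionOf(12, 13), 11)
#' @export
classifyPosteriorEdit <- function(wt, m, probe) {
  stopifnot(is(wt, "HoxCluster"))
  iProbe <- match(as.integer(probe), wt@geneNumbers)
  if (is.na(iProbe)) stop("probe gene ", probe, " not in cluster")
  if (is.null(m))
    return(.Outcome("UNCHANGED", "posterior_rule", probe = probe,
                    rationale = "empty edit: N unchanged"))
  stopifnot(is(m, "Manipulation"))
  if (!m@kind %in% c("deletion", "duplication"))
    stop("'m' must be a deletion or duplication")
  xx <- .manipulationInterval(wt, m)
  pos <- genePositions(wt)
  if (xx[1] < pos[[iProbe]])
    stop("edited region is not posterior to the probe gene")
  # the charge change is read off the applied mutant (deleting an end gene
  # also drops its flanking distance, which the raw interval misses)
  mut <- applyManipulation(wt, m)
  dN <- clusterSpan(mut) - clusterSpan(wt)
  if (dN == 0)
    return(.Outcome("UNCHANGED", "posterior_rule", probe = probe,
                    rationale = "zero-extent edit: N unchanged"))
  if (m@kind == "deletion") {
    .Outcome("POSTERIORIZED_DELAYED", "posterior_rule", probe = probe,
             rationale = sprintf(
               "%s: N reduced by %.2f Kbp; P must increase to restore F, so probe %s expression is delayed/posteriorized",
               m@label, -dN, probe))
  } else {
    .Outcome("ANTERIORIZED", "posterior_rule", downregulated = TRUE,
             probe = probe,
             rationale = sprintf(
               "%s: N increased by %.2f Kbp; stronger F extrudes probe %s prematurely (anteriorized) and carries it away from the transcription factory (downregulated)",
               m@label, dN, probe))
  }
}

#' Classify a splitting/inversion
#'
#' If the splitting removes the fixed 5' anchor (the region between Evx2
#' and Hoxd13), the elastic spring is loose at both ends and decondenses
#' with abnormally smaller forces: the remaining genes are prematurely
#' ANTERIORIZED. An inversion that spares the anchor region leaves the
#' force balance intact and the probes UNCHANGED — the force model's
#' distinguishing prediction against regulatory-landscape explanations,
#' which expect anteriorization in both layouts.
#'
#' @param wt wild-type [HoxCluster-class].
#' @param m a split_inversion [Manipulation-class].
#' @param probes probe gene numbers.
#' @return list of [Outcome-class], one per probe.
#' @export
classifySplit <- function(wt, m, probes) {
  stopifnot(is(wt, "HoxCluster"), is(m, "Manipulation"))
  if (m@kind != "split_inversion") stop("'m' must be a split_inversion")
  anchorLost <- m@removesFixedEnd || m@includesEvx2Boundary
  lapply(probes, function(p) {
    if (anchorLost) {
      .Outcome("ANTERIORIZED", "split_rule", probe = p,
               rationale = sprintf(
                 "%s: 5' anchor removed; spring loose at both ends, extrusion with abnormally smaller forces anteriorizes probe %s",
                 m@label, p))
    } else {
      .Outcome("UNCHANGED", "split_rule", probe = p,
               rationale = sprintf(
                 "%s: Evx2-Hoxd13 anchor region intact; force balance unchanged for probe %s",
                 m@label, p))
    }
  })
}
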