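# Preset scenarios: the engineered-mutant experiments the force model
# explains, with their declared elasticity profiles, and the runner that
# re-derives every verdict from the classifiers.

#' Packaged scenario elasticity profiles
#'
#' Reads the step profiles shipped with the package (one per scenario
#' `profile_ref`) into [ElasticityProfile-class] objects.
#'
#' @param path optional path to a profiles TSV (columns `profile_ref`,
#'   `from_kbp`, `to_kbp`, `stiffness`); defaults to the packaged file.
#' @return named list of [ElasticityProfile-class].
#' @export
scenarioProfiles <- function(path = system.file("extdata", "profiles.tsv",
                                                package = "hoxphys",
                                                mustWork = TRUE)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- lapply(split(tab, tab$profile_ref), function(p) {
    p <- p[order(p$from_kbp), , drop = FALSE]
    ElasticityProfile(breaksKbp = p$to_kbp[is.finite(p$to_kbp)],
                      stiffness = p$stiffness)
  })
  out
}

# Parse a scenario 'region' string into a Manipulation.
.parseScenarioRow <- function(row) {
  kind <- row$kind
  region <- as.character(row$region)
  if (kind == "split_inversion") {
    return(switch(region,
      fixed_end = splitInversion(removesFixedEnd = TRUE,
                                 label = row$scenario_id),
      spare_anchor = splitInversion(removesFixedEnd = FALSE,
                                    includesEvx2Boundary = FALSE,
                                    label = row$scenario_id),
      stop("unknown split region: ", region)))
  }
  includeI <- grepl("(^|-)i($|-)", region)
  nums <- suppressWarnings(
    as.integer(strsplit(gsub("(^|-)i($|-)", "\\1", region), "-")[[1]]))
  nums <- nums[!is.na(nums)]
  if (kind == "deletion") {
    if (length(nums) == 0L) {
      if (!includeI) stop("deletion region is empty: ", region)
      deletionOf(NULL, includeI = TRUE, label = row$scenario_id)
    } else {
      deletionOf(min(nums), max(nums), includeI = includeI,
                 label = row$scenario_id)
    }
  } else if (kind == "duplication") {
    if (length(nums) == 0L) stop("duplication region is empty: ", region)
    duplicationOf(min(nums), max(nums), label = row$scenario_id)
  } else {
    stop("unknown manipulation kind: ", kind)
  }
}

#' The preset manipulation scenarios
#'
#' The nine engineered-mutant scenarios on the mouse HoxD cluster, each
#' with its manipulation, probe gene, declared elasticity profile and the
#' expected qualitative verdict: del(8-10)/Hoxd11 UNCHANGED,
#' del(i-8-10)/Hoxd11 ANTERIORIZED_WITH_GAIN, del(10-12)/Hoxd13 UNCHANGED,
#' del(9-12)/Hoxd13 SILENCED, a posterior deletion POSTERIORIZED_DELAYED, a
#' posterior duplication ANTERIORIZED + downregulated, the fixed-end split
#' ANTERIORIZED, del(i)/Hoxd11 ANTERIORIZED, and the anchor-sparing
#' inversion UNCHANGED.
#'
#' @param path optional path to a scenarios TSV (columns `scenario_id`,
#'   `kind`, `region`, `probe`, `profile_ref`, `expected_verdict`,
#'   `expected_downregulated`); defaults to the packaged file.
#' @return data.frame of scenarios.
#' @seealso [runScenarios()]
#' @export
presetScenarios <- function(path = system.file("extdata", "scenarios.tsv",
                                               package = "hoxphys",
                                               mustWork = TRUE)) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

# Route one scenario row through the appropriate classifier.
.classifyScenario <- function(cluster, row, profiles, eta = 0.05) {
  m <- .parseScenarioRow(row)
  probe <- as.integer(row$probe)
  if (m@kind == "split_inversion")
    return(classifySplit(cluster, m, probe)[[1L]])
  pos <- genePositions(cluster)
  aEdge <- pos - cluster@geneLengthsKbp
  iProbe <- match(probe, cluster@geneNumbers)
  if (is.na(iProbe)) stop("probe gene ", probe, " not in cluster")
  xx <- .manipulationInterval(cluster, m)
  if (xx[1] >= pos[[iProbe]]) {
    if (m@kind == "duplication" || m@kind == "deletion")
      return(classifyPosteriorEdit(cluster, m, probe))
  }
  if (m@kind == "duplication")
    stop("anterior duplications are only weakly constrained; no preset rule")
  prof <- profiles[[row$profile_ref]]
  if (is.null(prof)) stop("unknown profile_ref: ", row$profile_ref)
  classifyAnteriorDeletion(cluster, m, probe, profile = prof, eta = eta)
}

#' Run manipulation scenarios through the classifiers
#'
#' Re-derives each scenario's verdict from the force model (no looked-up
#' answers: anterior deletions run the full L/D/E comparison on the
#' scenario's profile, posterior edits and splits apply the charge and
#' anchor rules) and compares it with the expected verdict. Malformed rows
#' are reported with their row number and skipped; the run continues.
#'
#' @param cluster wild-type [HoxCluster-class] (the mouse HoxD fixture for
#'   the presets).
#' @param scenarios data.frame as returned by [presetScenarios()].
#' @param profiles named list as returned by [scenarioProfiles()].
#' @param eta case-1 tolerance for anterior deletions.
#' @return data.frame: scenario_id, kind, region, probe, expected_verdict,
#'   computed_verdict, expected_downregulated, computed_downregulated,
#'   match, rationale; skipped rows carry NA verdicts and the error in
#'   `rationale`.
#' @examples
#' res <- runScenarios(hoxFixture("mouse_hoxd"))
#' sum(res$match)  # 9
#' @export
runScenarios <- function(cluster = hoxFixture("mouse_hoxd"),
                         scenarios = presetScenarios(),
                         profiles = scenarioProfiles(),
                         eta = 0.05) {
  rows <- lapply(seq_len(nrow(scenarios)), function(i) {
    row <- scenarios[i, , drop = FALSE]
    res <- tryCatch(.classifyScenario(cluster, row, profiles, eta),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("scenario row ", i, " (",
              paste(row$scenario_id, collapse = ""), ") skipped: ",
              conditionMessage(res), call. = FALSE)
      data.frame(scenario_id = row$scenario_id, kind = row$kind,
                 region = row$region, probe = row$probe,
                 expected_verdict = row$expected_verdict,
                 computed_verdict = NA_character_,
                 expected_downregulated = row$expected_downregulated,
                 computed_downregulated = NA,
                 match = FALSE,
                 rationale = paste("skipped:", conditionMessage(res)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(scenario_id = row$scenario_id, kind = row$kind,
                 region = row$region, probe = row$probe,
                 expected_verdict = row$expected_verdict,
                 computed_verdict = res@verdict,
                 expected_downregulated = row$expected_downregulated,
                 computed_downregulated = res@downregulated,
                 match = identical(res@verdict, row$expected_verdict) &&
                   identical(res@downregulated,
                             as.logical(row$expected_downregulated)),
                 rationale = res@rationale,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
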