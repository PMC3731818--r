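# Report writers: plain TSV with '#'-prefixed metadata headers so every
# report is diff-friendly and reproducible bit-for-bit from its recorded
# configuration and seed.

.writeReport <- function(df, out, meta = character(0)) {
  if (is.null(out)) return(invisible(NULL))
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# hoxphys %s",
                       as.character(utils::packageVersion("hoxphys"))),
               paste0("# ", meta)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Distance-statistics report
#'
#' One row per cluster with the descriptive statistics of its intergenic
#' distances ([clusterStats()]): the compact-versus-loose geometry
#' comparison at a glance.
#'
#' @param clusters list of [HoxCluster-class]; defaults to the three
#'   packaged reference clusters.
#' @param out optional output TSV path.
#' @return data.frame: organism, n_genes, n_distances, total_kbp, mean_kbp,
#'   variance_kbp2.
#' @examples
#' distanceStatsReport()
#' @export
distanceStatsReport <- function(clusters = list(hoxFixture("mouse_hoxd"),
                                                hoxFixture("amphioxus"),
                                                hoxFixture("amphioxus_modified")),
                                out = NULL) {
  rows <- lapply(clusters, function(cl) {
    st <- clusterStats(cl)
    data.frame(organism = organism(cl), n_genes = nGenes(cl),
               n_distances = st$n_distances, total_kbp = st$total_kbp,
               mean_kbp = st$mean_kbp, variance_kbp2 = st$variance_kbp2,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  .writeReport(df, out, "intergenic distance statistics (population variance, divisor n)")
  df
}

#' Noise-experiment report
#'
#' Runs [compareOrganisms()] and reports pooled mean/variance, the
#' closed-form variance, and the variance ranking. The header records the
#' noise configuration and the standing caveat: the published calibration
#' of the noise level is under-specified, so the reproducible claim is the
#' variance ordering across cluster geometries, not exact variance values.
#'
#' @param clusters list of [HoxCluster-class] (>= 2).
#' @param l ideal segment length.
#' @param noise a [NoiseSpec-class].
#' @param out optional output TSV path.
#' @return the [compareOrganisms()] data.frame.
#' @export
noiseVarianceReport <- function(clusters = list(hoxFixture("mouse_hoxd"),
                                                hoxFixture("amphioxus"),
                                                hoxFixture("amphioxus_modified")),
                                l = 100, noise = NoiseSpec(), out = NULL) {
  df <- compareOrganisms(clusters, l = l, noise = noise)
  .writeReport(df, out, c(
    sprintf("model=%s level=%g realizations=%d seed=%d l=%g",
            noise@model, noise@level, noise@realizations, noise@seed, l),
    "identical noise applied to every cluster (common pooled FPR scale)",
    "caveat: noise calibration under-specified; the variance ordering, not exact values, is the reproducible claim"))
  df
}

#' Scenario-verdict report
#'
#' Runs [runScenarios()] and writes the expected-versus-computed verdict
#' table.
#'
#' @inheritParams runScenarios
#' @param out optional output TSV path.
#' @return the [runScenarios()] data.frame.
#' @export
scenarioReport <- function(cluster = hoxFixture("mouse_hoxd"),
                           scenarios = presetScenarios(),
                           profiles = scenarioProfiles(), eta = 0.05,
                           out = NULL) {
  df <- runScenarios(cluster, scenarios, profiles, eta)
  .writeReport(df, out, c(
    sprintf("cluster=%s eta=%g", organism(cluster), eta),
    sprintf("matches=%d/%d", sum(df$match), nrow(df))))
  df
}
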