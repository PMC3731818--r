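#' @describeIn HoxCluster-class organism label.
#' @export
setMethod("organism", "HoxCluster", function(object) object@organism)

#' @describeIn HoxCluster-class gene paralog numbers, anterior first.
#' @export
setMethod("geneNumbers", "HoxCluster", function(object) object@geneNumbers)

#' @describeIn HoxCluster-class gene labels.
#' @export
setMethod("geneLabels", "HoxCluster", function(object) object@geneLabels)

#' @describeIn HoxCluster-class intergenic distances d(i,i+1) in Kbp.
#' @export
setMethod("distancesKbp", "HoxCluster", function(object) object@distancesKbp)

#' @describeIn HoxCluster-class gene lengths in Kbp.
#' @export
setMethod("geneLengthsKbp", "HoxCluster",
          function(object) object@geneLengthsKbp)

#' @describeIn HoxCluster-class is the 5' anchor intact?
#' @export
setMethod("fixedPosteriorEnd", "HoxCluster",
          function(object) object@fixedPosteriorEnd)

#' @describeIn HoxCluster-class number of genes.
#' @export
setMethod("nGenes", "HoxCluster", function(object) length(object@geneNumbers))

setMethod("show", "HoxCluster", function(object) {
  cat(sprintf("HoxCluster '%s': %d genes, span %.3g Kbp%s\n",
              object@organism, nGenes(object), clusterSpan(object),
              if (object@fixedPosteriorEnd) "" else " (5' anchor removed)"))
  cat("  genes:", paste(object@geneLabels, collapse = " "), "\n")
  if (length(object@distancesKbp))
    cat("  d(i,i+1) Kbp:", paste(format(object@distancesKbp), collapse = " "),
        "\n")
})

#' Total fiber span of a cluster
#'
#' Sum of all intergenic distances plus all gene lengths, in Kbp. The span
#' carries the cluster charge N of the force model (N is distributed over
#' the whole cluster), so deletions reduce N proportionally.
#'
#' @param cluster a [HoxCluster-class].
#' @return numeric(1), span in Kbp.
#' @examples
#' clusterSpan(hoxFixture("mouse_hoxd"))  # 94
#' @export
setMethod("clusterSpan", "HoxCluster", function(cluster) {
  sum(cluster@distancesKbp) + sum(cluster@geneLengthsKbp)
})

#' Fiber positions of the genes
#'
#' Fiber coordinate (Kbp from the anterior, 3', end of the cluster) of the
#' posterior edge of each gene: gene g is counted as extruded into the ICD
#' once the extruded length E reaches this position. With zero gene lengths
#' the first gene sits at 0.
#'
#' @param cluster a [HoxCluster-class].
#' @return named numeric vector, one position per gene.
#' @export
setMethod("genePositions", "HoxCluster", function(cluster) {
  p <- cumsum(cluster@geneLengthsKbp) + c(0, cumsum(cluster@distancesKbp))
  names(p) <- cluster@geneLabels
  p
})

#' Descriptive statistics of the intergenic distances
#'
#' Total, mean and population variance (divisor n, which reproduces the
#' printed comparative statistics for the packaged clusters; divisor n - 1
#' does not) of the intergenic distances.
#'
#' @param cluster a [HoxCluster-class] with at least 2 genes.
#' @return list with `total_kbp`, `mean_kbp`, `variance_kbp2`,
#'   `n_distances`.
#' @examples
#' clusterStats(hoxFixture("mouse_hoxd"))
#' @export
setMethod("clusterStats", "HoxCluster", function(cluster) {
  d <- cluster@distancesKbp
  if (length(d) < 1L)
    stop("cluster must have at least 2 genes (one intergenic distance)")
  list(total_kbp = sum(d),
       mean_kbp = mean(d),
       variance_kbp2 = mean((d - mean(d))^2),
       n_distances = length(d))
})

#' Restrict a cluster to a subset of its genes
#'
#' Retains only the genes whose numbers are in `keep`; each new intergenic
#' distance is the sum of the original distances (and skipped genes'
#' lengths) it spans, so the fiber span between the outermost retained genes
#' is conserved. This is how the "modified" loose-cluster fixture is derived
#' from the full amphioxus cluster: only the gene numbers present in the
#' mouse HoxD cluster are retained and the spanned distances are summed.
#'
#' @param cluster a [HoxCluster-class].
#' @param keep integer vector of gene numbers to retain (>= 2 of them, all
#'   present in the cluster).
#' @return a [HoxCluster-class] with the retained genes in original order.
#' @examples
#' amphi <- hoxFixture("amphioxus")
#' restrictToGenes(amphi, c(1, 3, 4, 8, 9, 10, 11, 12, 13, 14))
#' @export
setMethod("restrictToGenes", "HoxCluster", function(cluster, keep) {
  keep <- as.integer(keep)
  absent <- setdiff(keep, cluster@geneNumbers)
  if (length(absent))
    stop("gene numbers not present in cluster: ",
         paste(absent, collapse = ", "))
  idx <- which(cluster@geneNumbers %in% keep)
  if (length(idx) < 2L)
    stop("'keep' must retain at least 2 genes")
  newd <- vapply(seq_len(length(idx) - 1L), function(k) {
    i <- idx[k]; j <- idx[k + 1L]
    # distances spanned plus lengths of skipped genes
    sum(cluster@distancesKbp[i:(j - 1L)]) +
      sum(cluster@geneLengthsKbp[setdiff(seq(i, j), c(i, j))])
  }, numeric(1))
  HoxCluster(cluster@organism, cluster@geneNumbers[idx], newd,
             geneLabels = cluster@geneLabels[idx],
             geneLengthsKbp = cluster@geneLengthsKbp[idx],
             fixedPosteriorEnd = cluster@fixedPosteriorEnd)
})

#' Read a Hox cluster description from a file
#'
#' Two dialects are supported. `"distance-list"` is a TSV with a header line
#' and columns `gene_from`, `gene_to`, `distance_kbp`, one row per
#' successive gene pair in anterior order; `#`-prefixed lines are comments,
#' and a `# organism: <label>` comment names the cluster. `"bed-intervals"`
#' is standard BED (0-based, half-open, one strand) with interval names
#' ending in the gene paralog number; genes are ordered by start coordinate
#' and distances are computed between successive interval start positions,
#' with coordinates interpreted in bp and converted to Kbp.
#'
#' @param path file path.
#' @param dialect `"distance-list"` (default) or `"bed-intervals"`.
#' @param organism optional organism label; defaults to a `# organism:`
#'   comment (distance-list) or the file name.
#' @return a validated [HoxCluster-class]; gene numbers strictly increasing.
#' @examples
#' readClusterTable(system.file("extdata", "mouse_hoxd.tsv",
#'                              package = "hoxphys"))
#' @export
readClusterTable <- function(path,
                             dialect = c("distance-list", "bed-intervals"),
                             organism = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "distance-list") {
    lines <- readLines(path)
    if (is.null(organism)) {
      om <- grep("^#\\s*organism:", lines, value = TRUE)
      organism <- if (length(om)) {
        trimws(sub("^#\\s*organism:\\s*", "", om[1]))
      } else {
        sub("\\.[^.]*$", "", basename(path))
      }
    }
    body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(body) < 2L)
      stop("invalid distance-list file (no data rows): ", path)
    tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    need <- c("gene_from", "gene_to", "distance_kbp")
    if (!all(need %in% names(tab)))
      stop("distance-list file must have columns: ",
           paste(need, collapse = ", "))
    gfrom <- as.integer(tab$gene_from)
    gto <- as.integer(tab$gene_to)
    d <- as.numeric(tab$distance_kbp)
    if (any(d <= 0) || anyNA(d))
      stop("all distances must be positive numbers")
    if (any(gto <= gfrom))
      stop("each row must have gene_from < gene_to")
    if (length(gfrom) > 1L && any(gfrom[-1] != gto[-length(gto)]))
      stop("rows must chain: gene_to of one row is gene_from of the next")
    numbers <- c(gfrom, gto[length(gto)])
    if (is.unsorted(numbers, strictly = TRUE))
      stop("gene numbers must be strictly increasing (unsorted or duplicated)")
    HoxCluster(organism, numbers, d)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) < 2L) stop("BED file must contain at least 2 intervals")
    gr <- gr[order(GenomicRanges::start(gr))]
    nm <- gr$name
    if (is.null(nm) || anyNA(nm))
      stop("BED intervals must carry gene names")
    numbers <- suppressWarnings(as.integer(sub("^.*?(\\d+)$", "\\1", nm)))
    if (anyNA(numbers))
      stop("BED interval names must end in the gene paralog number")
    if (is.unsorted(numbers, strictly = TRUE))
      stop("gene numbers must be strictly increasing along the fiber")
    starts <- GenomicRanges::start(gr)
    d <- diff(starts) / 1000
    if (any(d <= 0)) stop("all start-to-start distances must be > 0")
    if (is.null(organism))
      organism <- sub("\\.[^.]*$", "", basename(path))
    HoxCluster(organism, numbers, d, geneLabels = nm)
  }
}

#' Write a Hox cluster description to a file
#'
#' Inverse of [readClusterTable()]: `write` then `read` reproduces an
#' identical cluster for both dialects (the BED dialect stores start-to-start
#' distances as bp, so distances must be whole multiples of 0.001 Kbp).
#'
#' @param cluster a [HoxCluster-class].
#' @param path output file path.
#' @param dialect `"distance-list"` or `"bed-intervals"`.
#' @return `path`, invisibly.
#' @export
writeClusterTable <- function(cluster, path,
                              dialect = c("distance-list", "bed-intervals")) {
  dialect <- match.arg(dialect)
  if (dialect == "distance-list") {
    g <- cluster@geneNumbers
    n <- length(g)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# organism: %s", cluster@organism), con)
    writeLines("gene_from\tgene_to\tdistance_kbp", con)
    writeLines(sprintf("%d\t%d\t%s", g[-n], g[-1],
                       format(cluster@distancesKbp, trim = TRUE,
                              scientific = FALSE)), con)
  } else {
    starts <- round(c(0, cumsum(cluster@distancesKbp)) * 1000)
    gr <- GenomicRanges::GRanges(
      seqnames = cluster@organism,
      ranges = IRanges::IRanges(start = starts + 1L, width = 1L),
      strand = "+")
    gr$name <- cluster@geneLabels
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  }
  invisible(path)
}

#' Packaged reference clusters
#'
#' Loads one of the three clusters shipped with the package:
#' `"mouse_hoxd"` (the compact vertebrate mouse HoxD cluster, 9 genes,
#' total 94 Kbp), `"amphioxus"` (the loose cephalochordate cluster, 14
#' genes, total 446 Kbp) and `"amphioxus_modified"` (the amphioxus cluster
#' restricted to the gene numbers present in mouse HoxD, distances summed
#' across the removed genes; it keeps the printed 13-14 distance of 62 Kbp
#' and is stored exactly as published, not re-derived).
#'
#' @param name fixture name.
#' @return a [HoxCluster-class].
#' @examples
#' hoxFixture("mouse_hoxd")
#' @export
hoxFixture <- function(name = c("mouse_hoxd", "amphioxus",
                                "amphioxus_modified")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "hoxphys",
                      mustWork = TRUE)
  cl <- readClusterTable(path)
  if (name == "mouse_hoxd")
    cl@geneLabels <- paste0("Hoxd", cl@geneNumbers)
  cl
}
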