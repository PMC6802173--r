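#' Pipeline configuration
#'
#' Bundles every numeric parameter of the analysis. Defaults reproduce the
#' published analysis settings: 12.5-kb stitching with a 2.5-kb TSS exclusion
#' zone for super-enhancer calling; promoters at +/-2 kb and upstream elements
#' at 2--20 kb from the TSS for feature annotation; a 500-bp center-distance
#' window for peak overlap; a 100-gene moving-average window; +/-3-kb, 100-bp
#' bins for signal profiling; +/-20 kb around the gene body for target-gene
#' assignment; top/bottom 10% extremes with >= 3 supporting datasets for the
#' dysregulation screen; and the >22-factor / >8-factor co-occupancy
#' thresholds.
#'
#' @param stitchDistance Maximum gap (bp) between peaks merged into one
#'   stitched region.
#' @param tssExclusion Half-width (bp) of the TSS exclusion zone; peaks fully
#'   contained in it are dropped before stitching. `0` disables the filter.
#' @param promoterHalfwidth Promoter half-width (bp) around the TSS.
#' @param upstreamMax Outer bound (bp) of the strand-aware upstream element.
#' @param overlapWindow Center-distance (bp) below which two peaks from
#'   different factors are the same binding site.
#' @param maWindow Moving-average window (number of genes).
#' @param profileHalfwidth Half-width (bp) of the signal profile around peak
#'   centers.
#' @param profileBin Profile bin size (bp).
#' @param networkWindow Extension (bp) of the gene body used for target-gene
#'   assignment.
#' @param extremeFraction Fraction of genes taken in each expression extreme
#'   (tail) per dataset in the dysregulation screen.
#' @param minDatasetHits Minimum number of datasets in which a gene must be
#'   extreme to be called dysregulated.
#' @param cooccupancyGeneThreshold Genes bound by strictly more than this many
#'   factors form the co-regulated gene set.
#' @param cooccupancySeThreshold Super-enhancers bound by strictly more than
#'   this many factors count as multi-TF co-occupied.
#' @param nClasses Number of time-course expression classes.
#' @param pseudocount Pseudocount added before expression/occupancy ratios.
#' @param minSignal Optional minimum peak signal; peaks below it are dropped
#'   at read time. Default `0` (off).
#' @param rngSeed Integer seed used by pipeline stages that sample.
#' @return A validated `PipelineConfig` (named list).
#' @examples
#' cfg <- pipelineConfig()
#' cfg$stitchDistance
#' @export
pipelineConfig <- function(stitchDistance = 12500,
                           tssExclusion = 2500,
                           promoterHalfwidth = 2000,
                           upstreamMax = 20000,
                           overlapWindow = 500,
                           maWindow = 100,
                           profileHalfwidth = 3000,
                           profileBin = 100,
                           networkWindow = 20000,
                           extremeFraction = 0.10,
                           minDatasetHits = 3,
                           cooccupancyGeneThreshold = 22,
                           cooccupancySeThreshold = 8,
                           nClasses = 4,
                           pseudocount = 1.0,
                           minSignal = 0,
                           rngSeed = 1L) {
  cfg <- list(
    stitchDistance = as.numeric(stitchDistance),
    tssExclusion = as.numeric(tssExclusion),
    promoterHalfwidth = as.numeric(promoterHalfwidth),
    upstreamMax = as.numeric(upstreamMax),
    overlapWindow = as.numeric(overlapWindow),
    maWindow = as.integer(maWindow),
    profileHalfwidth = as.numeric(profileHalfwidth),
    profileBin = as.numeric(profileBin),
    networkWindow = as.numeric(networkWindow),
    extremeFraction = as.numeric(extremeFraction),
    minDatasetHits = as.integer(minDatasetHits),
    cooccupancyGeneThreshold = as.integer(cooccupancyGeneThreshold),
    cooccupancySeThreshold = as.integer(cooccupancySeThreshold),
    nClasses = as.integer(nClasses),
    pseudocount = as.numeric(pseudocount),
    minSignal = as.numeric(minSignal),
    rngSeed = as.integer(rngSeed)
  )
  lengths <- c("stitchDistance", "promoterHalfwidth", "upstreamMax",
               "overlapWindow", "profileHalfwidth", "profileBin",
               "networkWindow")
  for (f in lengths)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("config: '%s' must be > 0", f))
  if (cfg$tssExclusion < 0)
    stop("config: 'tssExclusion' must be >= 0")
  if (cfg$maWindow < 1L)
    stop("config: 'maWindow' must be >= 1")
  if (cfg$extremeFraction <= 0 || cfg$extremeFraction >= 0.5)
    stop("config: 'extremeFraction' must lie in (0, 0.5)")
  if (cfg$minDatasetHits < 1L)
    stop("config: 'minDatasetHits' must be >= 1")
  if (cfg$pseudocount <= 0)
    stop("config: 'pseudocount' must be > 0")
  if (cfg$nClasses < 1L)
    stop("config: 'nClasses' must be >= 1")
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys under `params:` (or at top level) override [pipelineConfig()]
#' defaults; unknown parameter keys are an error so typos do not silently
#' fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  params <- if (!is.null(raw$params)) raw$params else raw
  known <- names(formals(pipelineConfig))
  extra <- setdiff(names(params), known)
  if (length(extra))
    stop("config: unknown parameter key(s): ", paste(extra, collapse = ", "))
  do.call(pipelineConfig, params)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `PipelineConfig`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(list(params = unclass(config)), path)
  invisible(path)
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}
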