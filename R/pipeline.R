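# Orchestration: run the per-species pipeline (haplotypes -> diversity ->
# structure -> network -> demography, plus the cross-species niche
# comparison) from a single configuration, writing CSV/JSON artifacts.

# one global seed expands deterministically into per-stage seeds
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

.defaultSettings <- function() {
  list(permutations = 1000L, bootstraps = 1000L, samovaStarts = 100L,
       samovaK = 2:5, identityReps = 100L, rMax = 0.70,
       rounding = "published", seed = 1L, neutralitySims = 1000L,
       model = "gaussian_envelope")
}

#' Run the comparative-phylogeography pipeline
#'
#' Executes, for each configured species, haplotype collapsing, diversity
#' and differentiation with the permutation U-test, the latitude
#' regression, the SAMOVA scan, the median-joining network, neutrality
#' tests and the mismatch-distribution analysis with dating; when niche
#' inputs are configured, the pairwise identity tests as well. All outputs
#' are written under \code{outdir} (per-species CSV/JSON plus a
#' cross-species \code{report.json}); with fixed seeds the report is
#' byte-reproducible.
#'
#' @param config a list, or path to a YAML file, with entries
#'   \code{species} (named list: \code{fasta}, \code{popTable}, optional
#'   \code{locusBounds}, \code{inversions}, \code{mu}, \code{k}, \code{g},
#'   \code{labelPrefix}) and optional \code{settings} overriding
#'   permutations, bootstraps, samovaStarts, samovaK, identityReps, rMax,
#'   rounding, seed, neutralitySims, model; optional \code{niche}
#'   (\code{rasters} = named .asc paths, \code{occurrences} = CSV with
#'   species/lon/lat).
#' @param outdir output directory.
#' @return (invisibly) the nested results list written to report.json.
#' @export
runPipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  st <- utils::modifyList(.defaultSettings(), config$settings %||% list())
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  report <- list(settings = st, species = list())

  for (sp in names(config$species)) {
    cf <- config$species[[sp]]
    spDir <- file.path(outdir, sp)
    dir.create(spDir, showWarnings = FALSE, recursive = TRUE)
    aln <- readAlignment(cf$fasta, cf$locusBounds)
    pops <- readPopulationTable(cf$popTable)
    mm <- recodeMutations(aln, cf$inversions)
    hset <- collapseHaplotypes(mm, pops, cf$labelPrefix %||% "H")
    d <- pairwiseDifferences(hset)
    writeHaplotypeSet(hset, file.path(spDir, "membership.csv"),
                      file.path(spDir, "haplotype_counts.csv"))
    writeDistanceMatrix(d, file.path(spDir, "distances.csv"))

    perPop <- perPopulationDiversity(hset, pops)
    write.csv(perPop, file.path(spDir, "diversity_per_population.csv"),
              row.names = FALSE)
    diffr <- differentiation(hset, d)
    utest <- nstGstPermutationTest(hset, d, nPerm = st$permutations,
                                   seed = .stageSeed(st$seed, "utest"))
    latFit <- tryCatch(diversityVsLatitude(perPop), error = function(e) NULL)

    nPops <- nrow(hset@popCounts)
    Kr <- st$samovaK[st$samovaK < nPops & st$samovaK >= 2L]
    sam <- if (length(Kr) && nPops >= 3L)
      samovaScan(hset, d, pops, Kr, nStarts = st$samovaStarts,
                 seed = .stageSeed(st$seed, "samova"))
    else NULL
    if (!is.null(sam)) {
      write.csv(sam$profile, file.path(spDir, "samova_profile.csv"),
                row.names = FALSE)
      bestG <- sam$results[[paste0("K", sam$suggestedK)]]@grouping
      write.csv(data.frame(population = names(bestG), group = bestG),
                file.path(spDir, "samova_grouping.csv"), row.names = FALSE)
    }

    net <- if (length(hset@labels) >= 2L) medianJoiningNetwork(hset) else NULL
    if (!is.null(net))
      writeNetwork(net, file.path(spDir, "network_edges.csv"),
                   file.path(spDir, "network_nodes.csv"))

    taj <- tajimaD(hset, d, nSim = st$neutralitySims,
                   seed = .stageSeed(st$seed, "tajima"))
    fs <- fuFs(hset, d, nSim = st$neutralitySims,
               seed = .stageSeed(st$seed, "fufs"))
    hist <- mismatchHistogram(hset, d)
    write.csv(data.frame(differences = as.integer(names(hist)),
                         pairs = as.integer(hist)),
              file.path(spDir, "mismatch.csv"), row.names = FALSE)
    fit <- fitSuddenExpansion(hist, sum(hset@popCounts))
    fit <- expansionGof(fit, nBoot = st$bootstraps,
                        seed = .stageSeed(st$seed, "gof"))
    date <- if (!is.null(cf$mu))
      dateExpansion(cf$tau %||% fit@tau, cf$mu, cf$k, cf$g,
                    rounding = st$rounding, tauCI = fit@gof$tauCI)
    else NULL

    res <- list(
      nSamples = sum(hset@popCounts),
      nPopulations = nPops,
      nHaplotypes = length(hset@labels),
      polymorphicSites = ncol(hset@vectors),
      hS = diffr$hS, hT = diffr$hT, GST = diffr$GST, NST = diffr$NST,
      U = utest$U, pU = utest$p,
      latitude = if (is.null(latFit)) NULL else
        latFit[c("slope", "t", "p", "r.squared")],
      samova = if (is.null(sam)) NULL else
        list(profile = sam$profile, suggestedK = sam$suggestedK,
             reliable = sam$reliable),
      tajimaD = taj[c("D", "p")], fuFS = fs[c("FS", "p")],
      mismatch = list(tau = fit@tau, theta0 = fit@theta0,
                      theta1 = fit@theta1, SSD = fit@ssd,
                      pSSD = fit@gof$pSSD, HRag = fit@raggedness,
                      pRag = fit@gof$pRag, tauCI = fit@gof$tauCI,
                      modality = fit@modality),
      dating = date)
    jsonlite::write_json(res, file.path(spDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    report$species[[sp]] <- res
  }

  if (!is.null(config$niche)) {
    stack <- readAsciiGridStack(unlist(config$niche$rasters))
    filt <- filterVariables(stack, st$rMax)
    occAll <- read.csv(config$niche$occurrences, stringsAsFactors = FALSE)
    sps <- unique(occAll$species)
    ovl <- NULL
    for (pr in combn(sps, 2L, simplify = FALSE)) {
      it <- identityTest(occAll[occAll$species == pr[1L], ],
                         occAll[occAll$species == pr[2L], ],
                         filt$stack, model = st$model,
                         nReps = st$identityReps,
                         seed = .stageSeed(st$seed, paste0("identity", pr[1L])))
      ovl <- rbind(ovl, data.frame(species1 = pr[1L], species2 = pr[2L],
                                   D = it@D, I = it@I, pD = it@pD,
                                   pI = it@pI))
    }
    write.csv(ovl, file.path(outdir, "niche_overlap.csv"), row.names = FALSE)
    report$niche <- list(retained = filt$retained, overlap = ovl)
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Published reference statistics as optional targets
#'
#' The study's real-data statistics (haplotype counts, h_T, N_ST/G_ST/U,
#' the SAMOVA F_CT plateau, neutrality statistics) depend on the deposited
#' haplotype sequences and the supplementary per-population tables, which
#' this package does not bundle. They are encoded here as optional targets:
#' \code{referenceTargets()} lists the expected values, and
#' \code{computeReferenceTargets()} activates them when the input files are
#' supplied, returning the recomputed statistics next to the expectations.
#'
#' @return data.frame of species, statistic, expected value.
#' @export
referenceTargets <- function() {
  data.frame(
    species = c(rep("C. tibetana", 6), rep("M. thunbergii", 6),
                rep("S. superba", 7)),
    statistic = c("nHaplotypes", "hT", "hS", "NST", "GST", "tajimaD",
                  "nHaplotypes", "hT", "hS", "NST", "GST", "tajimaD",
                  "nHaplotypes", "hT", "hS", "NST", "GST", "tajimaD", "FCT"),
    expected = c(19, 0.797, 0.151, 0.851, 0.815, -1.011,
                 13, 0.644, 0.165, 0.767, 0.752, -0.746,
                 9, 0.765, 0.136, 0.906, 0.825, 1.93, 0.894))
}

#' @rdname referenceTargets
#' @param inputs named list, one entry per species, each with \code{fasta}
#'   and \code{popTable} paths (and optional \code{inversions},
#'   \code{samovaK}); NULL entries leave that species' targets inactive.
#' @param nStarts annealing starts for the F_CT target.
#' @param seed RNG seed.
#' @return the \code{referenceTargets()} frame with columns \code{value}
#'   (recomputed, NA while inactive) and \code{active}.
#' @export
computeReferenceTargets <- function(inputs = NULL, nStarts = 25L, seed = 1L) {
  targets <- referenceTargets()
  targets$value <- NA_real_
  targets$active <- FALSE
  if (is.null(inputs)) return(targets)
  for (sp in names(inputs)) {
    inp <- inputs[[sp]]
    if (is.null(inp)) next
    aln <- readAlignment(inp$fasta, inp$locusBounds)
    pops <- readPopulationTable(inp$popTable)
    hset <- collapseHaplotypes(recodeMutations(aln, inp$inversions), pops)
    d <- pairwiseDifferences(hset)
    diffr <- differentiation(hset, d)
    taj <- tajimaD(hset, d, nSim = 0L)
    vals <- c(nHaplotypes = length(hset@labels), hT = diffr$hT,
              hS = diffr$hS, NST = diffr$NST, GST = diffr$GST,
              tajimaD = taj$D)
    if (!is.null(inp$samovaK)) {
      sam <- samova(hset, d, pops, K = inp$samovaK, nStarts = nStarts,
                    seed = seed)
      vals <- c(vals, FCT = sam@fct)
    }
    sel <- targets$species == sp & targets$statistic %in% names(vals)
    targets$value[sel] <- vals[targets$statistic[sel]]
    targets$active[sel] <- TRUE
  }
  targets
}
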