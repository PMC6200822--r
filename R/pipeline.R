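#' Pipeline configuration with layered precedence
#'
#' One flat, typed key-value set holding every threshold of the marker
#' development workflow, with defaults equal to the protocol's printed
#' values: exons > 600 bp (`exon_min_len = 601`), orthology identity
#' > 80% and coverage > 50%, primers 18-25 bp with GC 20-80%,
#' self-complementarity < 6.00 and 3' scores < 3.00, products
#' 700-1200 bp, universal-panel PSR >= 80%, 1000 bootstrap replicates,
#' and the cyt-b reference rate 0.01035 substitutions/site/My. The
#' `demo_*` keys parameterise the bundled simulated demo only.
#' Precedence is defaults < config file < direct overrides; the
#' provenance of every key is recorded in the `"provenance"` attribute.
#'
#' @param ... key = value overrides (highest precedence).
#' @param file optional config file of `key = value` lines (`#`
#'   comments allowed).
#' @return Named list of class `pipelineConfig`. Unknown keys are an
#'   error listing them.
#' @export
pipelineConfig <- function(..., file = NULL) {
  defaults <- list(
    exon_min_len = 601L,
    min_identity = 0.80, min_coverage = 0.50,
    primer_len_min = 18L, primer_len_max = 25L,
    gc_min = 0.20, gc_max = 0.80,
    self_any_max = 6.00, self_three_max = 3.00, pair_three_max = 3.00,
    product_min = 700L, product_max = 1200L,
    psr_threshold = 0.80,
    bootstrap_reps = 1000L,
    mu_cytb = 0.01035,
    align_match = 1L, align_mismatch = -2L,
    align_gap_open = -5L, align_gap_extend = -2L,
    align_k = 11L, align_xdrop = 20L,
    max_candidates_per_side = 200L, max_pairs = 50L,
    demo_n_exons = 10L, demo_divergence = 0.08,
    demo_n_paralogs = 2L, demo_deletion_prob = 0.10,
    demo_cytb_divergence = 0.20,
    demo_coalescent_n = 10L, demo_coalescent_theta = 5,
    demo_tree_bootstrap = 100L)
  cfg <- defaults
  prov <- setNames(rep("default", length(cfg)), names(cfg))
  apply_layer <- function(vals, label) {
    unknown <- setdiff(names(vals), names(defaults))
    if (length(unknown))
      stop("unknown configuration key(s): ",
           paste(unknown, collapse = ", "))
    for (k in names(vals)) {
      cfg[[k]] <<- if (is.integer(defaults[[k]]))
        as.integer(vals[[k]]) else vals[[k]]
      prov[k] <<- label
    }
  }
  if (!is.null(file)) {
    lines <- readLines(file)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    vals <- lapply(kv, function(p)
      utils::type.convert(p[2], as.is = TRUE))
    names(vals) <- vapply(kv, `[`, character(1), 1L)
    apply_layer(vals, "file")
  }
  dots <- list(...)
  if (length(dots)) apply_layer(dots, "override")
  structure(cfg, provenance = prov, class = "pipelineConfig")
}

# Translate config keys into the per-module parameter objects.
configAlignParams <- function(cfg) {
  alignParams(match = cfg$align_match, mismatch = cfg$align_mismatch,
              gapOpen = cfg$align_gap_open,
              gapExtend = cfg$align_gap_extend, k = cfg$align_k,
              xdrop = cfg$align_xdrop)
}

configPrimerConstraints <- function(cfg) {
  primerConstraints(
    lenRange = c(cfg$primer_len_min, cfg$primer_len_max),
    gcRange = c(cfg$gc_min, cfg$gc_max),
    selfAnyMax = cfg$self_any_max, self3Max = cfg$self_three_max,
    pair3Max = cfg$pair_three_max,
    productRange = c(cfg$product_min, cfg$product_max))
}

#' Run the full marker-development demo on simulated data
#'
#' End-to-end smoke pipeline: simulate an annotated genome pair, write
#' and re-read the standard files, mine long exons, flag single-copy
#' loci, screen orthologs, design primer pairs, estimate
#' cyt-b-calibrated rates from the per-locus template/query alignments
#' (with a simulated fast-evolving mitochondrial reference), compute
#' coalescent polymorphism statistics with Tajima's D and a two-locus
#' HKA test, and build a supermatrix, NJ tree and bootstrap supports.
#' All artifacts land under `outDir`, with a manifest recording seeds
#' and parameter provenance. Deterministic given `seed`.
#'
#' @param outDir run directory (created; not cleaned).
#' @param seed integer master seed.
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the main in-memory results (`truth`,
#'   `exons`, `hits`, `primers`, `rates`, `popgen`, `hka`, `tree`).
#' @export
runFullDemo <- function(outDir, seed = 1L, config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outDir, "run.log")
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  ap <- configAlignParams(config)
  pc <- configPrimerConstraints(config)

  logmsg("simulate: genome pair with planted truth")
  simCfg <- genomeSimConfig(
    nExons = config$demo_n_exons, divergence = config$demo_divergence,
    nParalogs = config$demo_n_paralogs,
    deletionProb = config$demo_deletion_prob,
    seed = childSeed(seed, 1L))
  sim <- simulateGenomePair(simCfg)
  inDir <- file.path(outDir, "inputs")
  writeGenomeSim(sim, inDir)

  logmsg("mine-exons / mark-single-copy / screen-orthologs")
  genome1 <- readFastaSet(file.path(inDir, "genome1.fasta"))
  genome2 <- readFastaSet(file.path(inDir, "genome2.fasta"))
  ann <- readGff3Exons(file.path(inDir, "genome1.gff3"))
  exons <- mineExons(genome1, ann, minLen = config$exon_min_len)
  exons <- markSingleCopy(exons, genome1,
                          minIdentity = config$min_identity,
                          minCoverage = config$min_coverage, params = ap)
  hits <- screenOrthologs(exons, genome2,
                          minIdentity = config$min_identity,
                          minCoverage = config$min_coverage, params = ap)
  writeTsv(hits[, setdiff(names(hits), c("qaln", "saln"))],
           file.path(outDir, "ortholog_hits.tsv"))

  logmsg("design-primers: ", nrow(hits), " loci")
  primerTabs <- lapply(seq_len(nrow(hits)), function(i) {
    ex <- exons[match(hits$exon_id[i], exons$exon_id)]
    designPairs(ex$sequence, hit = as.list(hits[i, ]), constraints = pc,
                locusId = hits$exon_id[i],
                maxCandidatesPerSide = config$max_candidates_per_side,
                maxPairs = config$max_pairs)
  })
  primers <- do.call(rbind, primerTabs)
  writeTsv(primers, file.path(outDir, "primer_candidates.tsv"))
  topPairs <- do.call(rbind, lapply(primerTabs, function(x)
    if (nrow(x)) x[1L, ] else NULL))
  writeTsv(topPairs, file.path(outDir, "selected_primers.tsv"))

  logmsg("estimate-rates: cyt-b-calibrated")
  cytb <- withSeed(childSeed(seed, 2L), {
    a <- randomDNA(1000L)
    c(tmpl = a, qry = mutateJC(a, config$demo_cytb_divergence))
  })
  dCytb <- overallMeanDistance(cytb, model = "p",
                               bootstrapReps = config$bootstrap_reps,
                               seed = childSeed(seed, 3L),
                               locusId = "cytb_sim")
  lociAln <- lapply(seq_len(nrow(hits)), function(i) {
    c(tmpl = gsub("-", "N", hits$qaln[i]),
      qry = gsub("-", "N", hits$saln[i]))
  })
  names(lociAln) <- hits$exon_id
  rates <- lapply(names(lociAln), function(lc) {
    dl <- overallMeanDistance(lociAln[[lc]], model = "p",
                              bootstrapReps = config$bootstrap_reps,
                              seed = childSeed(seed, 100L + match(lc, names(lociAln))),
                              locusId = lc)
    calibrateRate(dl, dCytb, muCytb = config$mu_cytb)
  })
  ranked <- rankRates(rates, references = c(cytb = config$mu_cytb))
  writeTsv(ranked$report, file.path(outDir, "mutation_rates.tsv"))

  logmsg("popgen-stats: coalescent samples, Tajima's D, HKA")
  popCfgs <- expand.grid(locus = c("locusA", "locusB"),
                         pop = c("pop1", "pop2"),
                         stringsAsFactors = FALSE)
  dataset <- lapply(seq_len(nrow(popCfgs)), function(i) {
    h <- simulateCoalescentSample(coalescentConfig(
      n = config$demo_coalescent_n, theta = config$demo_coalescent_theta,
      L = 1000L, seed = childSeed(seed, 200L + i)))
    h@locusId <- popCfgs$locus[i]
    h@populationId <- popCfgs$pop[i]
    h
  })
  popReport <- perPopulationReport(dataset)
  writeTsv(popReport, file.path(outDir, "popgen_stats.tsv"))
  pooled <- popReport[popReport$population == "pooled", ]
  hka <- hkaTest(data.frame(
    locus = pooled$locus, S = pooled$S, n = pooled$n,
    D = pmax(pooled$k_hat * 4, 1), L_poly = pooled$L,
    L_div = pooled$L))
  writeTsv(hkaTable(hka), file.path(outDir, "hka_table.tsv"))

  logmsg("build-supermatrix / nj-tree")
  sm <- concatenateLoci(lociAln)
  writePhylip(sm, file.path(outDir, "supermatrix.phy"))
  writeRaxmlPartitions(sm, file.path(outDir, "partitions.txt"))
  hapMat <- asAlignmentMatrix(haplotypes(dataset[[1]]))
  bs <- bootstrapSupport(hapMat, reps = config$demo_tree_bootstrap,
                         seed = childSeed(seed, 4L))
  writeNewick(bs$tree, file.path(outDir, "nj_tree.nwk"))

  logmsg("summarize-validation (synthetic PCR matrix)")
  vm <- withSeed(childSeed(seed, 5L), {
    markers <- hits$exon_id
    species <- sprintf("species%02d", 1:8)
    cells <- matrix(rbinom(length(markers) * 8L, 1L, 0.85),
                    nrow = length(markers),
                    dimnames = list(markers, species))
    validationMatrix(cells, orders = rep(sprintf("order%d", 1:4),
                                         each = 2L))
  })
  panel <- summarizeValidation(vm, threshold = config$psr_threshold)
  writeTsv(perMarkerPSR(panel), file.path(outDir, "marker_psr.tsv"))

  prov <- attr(config, "provenance")
  manifest <- c(
    sprintf("NPCLtools %s",
            as.character(utils::packageVersion("NPCLtools"))),
    sprintf("seed %d", seed),
    sprintf("%s = %s [%s]", names(config), vapply(config, format,
                                                  character(1)), prov))
  writeLines(manifest, file.path(outDir, "manifest.txt"))
  logmsg("done")
  invisible(list(truth = sim$truth, exons = exons, hits = hits,
                 primers = primers, rates = ranked, popgen = popReport,
                 hka = hka, tree = bs))
}
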