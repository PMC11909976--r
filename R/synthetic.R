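#' @include AllClasses.R utils.R sequence-model.R consequence.R mutation-model.R
#' @include observed-counts.R constraint-metrics.R
NULL

#' Configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator that emulates the workflow's inputs:
#' a random CpG-depleted reference, planted sORFs of the six classes,
#' variant sites sampled under the mutation model with per-consequence
#' selection factors, 37 methylation tracks with CpG-localised signal, and
#' a sliding-window score track. The defaults are the package's reference
#' study conditions (see the methods vignette for their motivation); the
#' seed fixes every downstream draw.
#'
#' @param seed integer seed; the generator stages use `seed`..`seed + 3`.
#' @param genomeLength reference length in bases.
#' @param gc GC fraction of the raw random sequence.
#' @param cpgDepletion fraction of random-expectation CpG dinucleotides
#'   retained (human-like depletion; the rest are deaminated C->T).
#' @param nPerClass named integer vector of sORF counts per class.
#' @param lengthCodons inclusive range of sORF lengths in codons.
#' @param maxBlocks maximum blocks (exons) per sORF (1..3 by default).
#' @param intronLength inclusive range of intron lengths in bases.
#' @param minusFraction fraction of sORFs planted on the minus strand.
#' @param selection named per-consequence-class selection factors in (0, 1]
#'   (1 = neutral; the probability a possible variant segregates is
#'   multiplied by this factor).
#' @param cohortScale cohort scale factor standing in for sample size: a
#'   possible variant with rate `mu` is observed with probability
#'   `1 - exp(-cohortScale * mu * selection)`. 0 gives zero variants.
#' @param nMethylomes number of per-epigenome methylation tracks.
#' @param scoreWindow,scoreSlide score-track window and slide, bases.
#' @param constantScore when non-NULL, every score-track window gets this
#'   score (useful for track-matching tests).
#' @param afHighFraction fraction of simulated variants given a common
#'   allele frequency (>= 0.001, so they are filtered/excluded).
#' @param nonPassRate fraction of simulated variants flagged non-PASS
#'   (their positions become low-quality sites).
#' @param lowCoverageRate fraction of coding positions with depth < 1.
#' @param depthMean mean per-site depth elsewhere.
#' @return a `SimulationConfig` (a validated list).
#' @export
simulationConfig <- function(seed = 1L,
                             genomeLength = 5e5,
                             gc = 0.42,
                             cpgDepletion = 0.25,
                             nPerClass = c(uORF = 150L, dORF = 120L,
                                           intORF = 90L, uoORF = 60L,
                                           doORF = 60L, `lncRNA-ORF` = 120L),
                             lengthCodons = c(20L, 100L),
                             maxBlocks = 3L,
                             intronLength = c(40L, 200L),
                             minusFraction = 0.5,
                             selection = c(synonymous = 1, missense = 1,
                                           stop_gain = 1, stop_loss = 1,
                                           start_loss = 1),
                             cohortScale = 6e6,
                             nMethylomes = 37L,
                             scoreWindow = 1000L,
                             scoreSlide = 100L,
                             constantScore = NULL,
                             afHighFraction = 0.02,
                             nonPassRate = 0.02,
                             lowCoverageRate = 0.01,
                             depthMean = 30) {
  stopifnot(genomeLength >= 1, gc > 0, gc < 1,
            cpgDepletion >= 0, cpgDepletion <= 1,
            all(nPerClass >= 0), lengthCodons[1] >= 2,
            lengthCodons[2] >= lengthCodons[1], maxBlocks >= 1,
            cohortScale >= 0, nMethylomes >= 1,
            scoreWindow >= 1, scoreSlide >= 1,
            afHighFraction >= 0, afHighFraction <= 1)
  if (!all(names(selection) %in% .CONSEQUENCES) ||
      !all(.CONSEQUENCES %in% names(selection)))
    stop("selection must be named by the five consequence classes")
  if (any(selection <= 0 | selection > 1))
    stop("selection factors must lie in (0, 1]")
  if (!all(names(nPerClass) %in% setdiff(.SORF_CLASSES, "unknown")))
    stop("nPerClass must be named by sORF classes")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "SimulationConfig")
}

#' Generate a random CpG-depleted reference sequence
#'
#' Bases are drawn i.i.d. at the configured GC; then a fraction
#' `1 - cpgDepletion` of CpG dinucleotides is deaminated (C->T), emulating
#' the CpG depletion of real genomes. Reproducible under the config seed.
#'
#' @param config a [simulationConfig()].
#' @param path optional FASTA output path.
#' @return named `DNAStringSet` with one chromosome `chrS`.
#' @export
generateReference <- function(config, path = NULL) {
  set.seed(config$seed)
  L <- as.integer(config$genomeLength)
  gc <- config$gc
  raw <- sample(.BASES, L, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  s <- Biostrings::DNAString(paste(raw, collapse = ""))
  cg <- Biostrings::start(Biostrings::matchPattern("CG", s))
  if (length(cg) && config$cpgDepletion < 1) {
    kill <- cg[stats::runif(length(cg)) > config$cpgDepletion]
    if (length(kill))
      s <- Biostrings::replaceLetterAt(s, kill, rep("T", length(kill)))
  }
  g <- Biostrings::DNAStringSet(stats::setNames(list(s), "chrS"))
  if (!is.null(path)) Biostrings::writeXStringSet(g, path)
  g
}

.STOPS <- c("TAA", "TAG", "TGA")
.NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), .STOPS)

#' Plant sORFs of the six classes into a reference
#'
#' Writes ATG...stop reading frames (no internal stop codons) into
#' non-overlapping genomic slots, split into 1..`maxBlocks` blocks separated
#' by intron gaps, on either strand. Overlap classes (intORF, uoORF, doORF)
#' are additionally embedded in a planted canonical-gene interval that is
#' recorded alongside; non-overlap classes get a nearby neighbour gene
#' interval.
#'
#' @param config a [simulationConfig()].
#' @param genome reference `DNAStringSet` from [generateReference()].
#' @return list with `genome` (modified reference), `sorfs` (a
#'   [SorfSet-class]), and `genes` (`GRanges` of planted gene intervals,
#'   with `gene_id` and associated `sorf_id`).
#' @export
plantSorfs <- function(config, genome) {
  set.seed(config$seed + 1L)
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  classes <- rep(names(config$nPerClass), config$nPerClass)
  n <- length(classes)
  if (n == 0L) stop("no sORFs requested")
  lens <- sample(seq(config$lengthCodons[1], config$lengthCodons[2]), n,
                 replace = TRUE)
  nBlocks <- sample(seq_len(config$maxBlocks), n, replace = TRUE)
  strands <- ifelse(stats::runif(n) < config$minusFraction, "-", "+")
  # coding sequences: ATG + non-stop codons + stop
  codingSeq <- vapply(lens, function(l) {
    paste0("ATG",
           paste(sample(.NONSTOP_CODONS, l - 2L, replace = TRUE),
                 collapse = ""),
           sample(.STOPS, 1L))
  }, character(1))
  introns <- lapply(seq_len(n), function(i) {
    if (nBlocks[i] == 1L) integer() else
      sample(seq(config$intronLength[1], config$intronLength[2]),
             nBlocks[i] - 1L, replace = TRUE)
  })
  spans <- lens * 3L + vapply(introns, sum, numeric(1))
  gaps <- sample(100:300, n, replace = TRUE)
  starts <- 50L + cumsum(c(0L, (spans + gaps)[-n]))
  if (max(starts + spans) + 50L > L)
    stop("genome too short for the requested sORFs; increase genomeLength")
  ids <- sprintf("sorf%04d", seq_len(n))
  blocksList <- vector("list", n)
  repAt <- vector("list", n)
  for (i in seq_len(n)) {
    cs <- codingSeq[i]
    gseq <- if (strands[i] == "-") .revcomp(cs) else cs
    nb <- nBlocks[i]
    total <- nchar(gseq)
    # split the genomic-strand sequence into nb contiguous pieces
    if (nb > 1L) {
      cuts <- sort(sample(seq_len(total - 1L), nb - 1L))
    } else cuts <- integer()
    pieceLen <- diff(c(0L, cuts, total))
    off <- starts[i]
    bs <- integer(nb); be <- integer(nb)
    for (b in seq_len(nb)) {
      bs[b] <- off
      be[b] <- off + pieceLen[b] - 1L
      off <- be[b] + 1L + if (b < nb) introns[[i]][b] else 0L
    }
    blocksList[[i]] <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(bs, be), strands[i])
    repAt[[i]] <- list(at = IRanges::IRanges(bs, be),
                       value = substring(gseq, cumsum(c(1L, pieceLen[-nb])),
                                         cumsum(pieceLen)))
  }
  at <- do.call(c, lapply(repAt, `[[`, "at"))
  val <- unlist(lapply(repAt, `[[`, "value"))
  seqNew <- Biostrings::replaceAt(genome[[chrom]], at,
                                  Biostrings::DNAStringSet(val))
  genome[[chrom]] <- seqNew
  bl <- GenomicRanges::GRangesList(blocksList)
  names(bl) <- ids
  sorfs <- SorfSet(bl, classes)
  # planted gene intervals: embedding for overlap classes, neighbours else
  spanStart <- starts
  spanEnd <- starts + spans - 1L
  overlap <- classes %in% c("intORF", "uoORF", "doORF")
  gStart <- ifelse(overlap, pmax(1L, spanStart - 200L), spanEnd + 20L)
  gEnd <- ifelse(overlap, pmin(L, spanEnd + 200L),
                 pmin(L, spanEnd + 20L + 150L))
  genes <- GenomicRanges::GRanges(chrom, IRanges::IRanges(gStart, gEnd), "+",
                                  gene_id = sprintf("gene%04d", seq_len(n)),
                                  sorf_id = ids)
  list(genome = genome, sorfs = sorfs, genes = genes)
}

#' Generate methylation and score tracks for a reference
#'
#' Methylation: per CpG site a true methylation level is drawn from a
#' bimodal Beta mixture (mostly-methylated genome background with a
#' hypomethylated minority); each of the `nMethylomes` epigenomes observes
#' a Beta-noised copy at both the C and the G position. Non-CpG positions
#' carry no methylation calls. Score track: sliding windows of
#' `scoreWindow` bases every `scoreSlide` bases with standard-normal scores
#' (or `constantScore`).
#'
#' @param config a [simulationConfig()].
#' @param genome reference `DNAStringSet` (after planting).
#' @return list with `methylation` (list of per-epigenome `data.table`s:
#'   `chrom`, `pos`, `fraction`) and `score` (`GRanges` with `score`).
#' @export
generateTracks <- function(config, genome) {
  set.seed(config$seed + 3L)
  chrom <- names(genome)[1]
  L <- Biostrings::width(genome)[1]
  cg <- Biostrings::start(Biostrings::matchPattern("CG", genome[[chrom]]))
  pos <- sort(c(cg, cg + 1L))  # C and G of each CpG
  nSite <- length(cg)
  mTrue <- ifelse(stats::runif(nSite) < 0.75,
                  stats::rbeta(nSite, 6, 1.5), stats::rbeta(nSite, 1.5, 6))
  mPos <- rep(mTrue, each = 2L)  # same site value at C and G
  conc <- 20
  meth <- lapply(seq_len(config$nMethylomes), function(e) {
    f <- stats::rbeta(length(mPos), mPos * conc, (1 - mPos) * conc)
    f[is.na(f)] <- mPos[is.na(f)]  # degenerate Beta at 0/1
    data.table(chrom = chrom, pos = pos, fraction = f)
  })
  ws <- seq(1L, max(1L, L - config$scoreWindow + 1L), by = config$scoreSlide)
  sc <- if (!is.null(config$constantScore))
    rep(config$constantScore, length(ws)) else stats::rnorm(length(ws))
  score <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(ws, width = config$scoreWindow), score = sc)
  list(methylation = meth, score = score)
}

#' Simulate a variant-site table under the mutation model
#'
#' Inverts the constraint model: each possible variant (context,
#' methylation and consequence aware) is observed as a segregating site
#' with probability `1 - exp(-cohortScale * mu * selection[class])`.
#' Observed sites get an allele frequency (a configured fraction is common,
#' >= 0.001), a FILTER status, and a per-site depth; positions carrying a
#' non-PASS variant are flagged low-quality, and a configured fraction of
#' coding positions gets depth < 1. A per-position coverage table for all
#' coding positions is returned alongside.
#'
#' @param config a [simulationConfig()].
#' @param cds a [CodingSequence-class], list of them, or a possible-variant
#'   table from [enumeratePossible()] (then `rates`/`methylation` are not
#'   needed).
#' @param rates a [MutationRateTable-class] (when `cds` is not already a
#'   possible-variant table).
#' @param methylation a [MethylationMap-class] or NULL.
#' @return list with `variants` (`chrom`, `pos`, `ref`, `alt`, `af`,
#'   `filter`, `passed_filters`, `depth`, `low_quality`), `coverage`
#'   (`chrom`, `pos`, `depth`, `low_quality`), and `possible` (the
#'   enumerated possible-variant table used).
#' @export
simulateVariants <- function(config, cds, rates = NULL, methylation = NULL) {
  set.seed(config$seed + 2L)
  poss <- if (is.data.frame(cds) && "mu" %in% names(cds)) as.data.table(cds)
          else enumeratePossible(classifyAll(cds), rates, methylation)
  sel <- config$selection[poss$consequence]
  p <- 1 - exp(-config$cohortScale * poss$mu * unname(sel))
  hit <- stats::runif(nrow(poss)) < p
  v <- poss[hit, .(chrom, pos = gpos, ref = gref, alt = galt)]
  nV <- nrow(v)
  common <- stats::runif(nV) < config$afHighFraction
  v[, af := ifelse(common, stats::runif(nV, 0.001, 0.01),
                   10^stats::runif(nV, log10(2e-6), log10(9e-4)))]
  nonPass <- stats::runif(nV) < config$nonPassRate
  v[, filter := ifelse(nonPass, "AC0", "PASS")]
  v[, passed_filters := !nonPass]
  v[, low_quality := nonPass]
  # per-position coverage over all coding positions
  cov <- unique(poss[, .(chrom, pos = gpos)])
  nP <- nrow(cov)
  lowcov <- stats::runif(nP) < config$lowCoverageRate
  cov[, depth := ifelse(lowcov, stats::runif(nP, 0, 0.99),
                        stats::rgamma(nP, shape = 20,
                                      scale = config$depthMean / 20))]
  lqPos <- unique(v[low_quality == TRUE, .(chrom, pos)])
  cov[, low_quality := FALSE]
  if (nrow(lqPos))
    cov[lqPos, on = c("chrom", "pos"), low_quality := TRUE]
  v[, depth := cov[v, on = c("chrom", "pos"), x.depth]]
  setorderv(v, c("chrom", "pos", "alt"))
  setorderv(cov, c("chrom", "pos"))
  list(variants = v[], coverage = cov[], possible = poss)
}

#' Run a complete synthetic constraint study
#'
#' Generates a reference, plants sORFs, simulates tracks and variant sites,
#' then runs the full constraint workflow on them: consequence
#' classification, possible-variant enumeration and filtering, observed
#' counting, calibration on synonymous counts, expected counts, and the
#' OEUF table for SNVOEUF/MOEUF/LOEUF.
#'
#' @param config a [simulationConfig()].
#' @param rates optional [MutationRateTable-class] (default
#'   [toyRateTable()]).
#' @param calibration `"proportion"` (default) fits the saturation-aware
#'   proportion-observed curve ([fitProportionCalibration()]) on the
#'   synonymous sites; `"linear"` uses the plain zero-intercept factor
#'   ([fitCalibration()]). See the methods vignette for why proportion is
#'   the default at large cohort scales.
#' @return list with every intermediate: `config`, `genome`, `sorfs`,
#'   `genes`, `score`, `methylation` (a [MethylationMap-class]),
#'   `methylationTracks`, `rates`, `consequences`, `possible` (filtered),
#'   `variants`, `coverage`, `calibrationK` (the linear factor, always
#'   reported), `calibration`, `observed`, `expected`, `oeuf`.
#' @export
simulateSorfStudy <- function(config, rates = toyRateTable(),
                              calibration = c("proportion", "linear")) {
  calibration <- match.arg(calibration)
  ref <- generateReference(config)
  pl <- plantSorfs(config, ref)
  tr <- generateTracks(config, pl$genome)
  mmap <- buildMethylationMap(tr$methylation)
  cons <- classifyAll(.codingBaseTable(pl$genome, pl$sorfs))
  poss0 <- enumeratePossible(cons, rates, mmap)
  sim <- simulateVariants(config, poss0)
  poss <- filterPossible(poss0, variants = sim$variants,
                         coverage = sim$coverage)
  obs <- filterObserved(sim$variants)
  retained <- poss[excluded == FALSE]
  counts <- countObserved(obs, cons, retained = retained)
  ec0 <- expectedCounts(poss, calibrationK = 1, quiet = TRUE)
  synEx <- ec0[consequence == "synonymous"]
  synObs <- as.data.table(counts)[consequence == "synonymous"]
  m <- synEx[synObs, on = "sorf_id"]
  k <- fitCalibration(m$observed, m$rate_sum)
  ec <- if (calibration == "proportion") {
    expectedCountsProportion(poss, fitProportionCalibration(retained, obs))
  } else {
    expectedCounts(poss, calibrationK = k)
  }
  oeuf <- oeufTable(counts, ec)
  list(config = config, genome = pl$genome, sorfs = pl$sorfs,
       genes = pl$genes, score = tr$score, methylation = mmap,
       methylationTracks = tr$methylation, rates = rates,
       consequences = cons, possible = poss, variants = sim$variants,
       coverage = sim$coverage, calibrationK = k, calibration = calibration,
       observed = counts, expected = ec, oeuf = oeuf)
}

#' Write the synthetic inputs of a study to disk
#'
#' Emits the exact formats the pipeline reads --- FASTA reference, BED12
#' sORFs, variant-site and coverage TSVs, per-epigenome methylation TSVs,
#' the score track, the rate table --- plus a `manifest.yaml` recording the
#' seed and all generator parameters.
#'
#' @param study output of [simulateSorfStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulatedInputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(study$genome, fp("reference.fa"))
  writeBed12(study$sorfs, fp("sorfs.bed"))
  data.table::fwrite(study$variants[, .(chrom, pos, ref, alt, af, filter,
                                        depth, low_quality)],
                     fp("variants.tsv"), sep = "\t")
  data.table::fwrite(study$coverage, fp("coverage.tsv"), sep = "\t")
  dir.create(fp("methylation"), showWarnings = FALSE)
  for (i in seq_along(study$methylationTracks))
    data.table::fwrite(study$methylationTracks[[i]],
                       fp("methylation", sprintf("epigenome%02d.tsv", i)),
                       sep = "\t")
  writeScoreTrack(study$score, fp("score_track.tsv"))
  writeRateTable(study$rates, fp("rates.tsv"))
  cfg <- study$config
  cfg$constantScore <- if (is.null(cfg$constantScore)) "none" else
    cfg$constantScore
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.numeric(x) || is.character(x)) x else as.character(x)),
    fp("manifest.yaml"))
  invisible(dir)
}
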