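#' @include AllClasses.R io-sorfs.R io-variants.R io-tracks.R synthetic.R
NULL

.defaultPipelineConfig <- function() {
  list(
    af_max = 0.001, depth_min = 1, powered_min_expected = 10,
    grid_step = 0.001, grid_max = 2.0, gnocchi_cutoff = 4,
    utr_min_len = 800, match_mode = "within", cpg_only_methylation = TRUE,
    seed = 1L)
}

#' Read a pipeline configuration file
#'
#' YAML file holding input paths and thresholds; unset keys fall back to
#' the defaults (`af_max` 0.001, `depth_min` 1, `powered_min_expected` 10,
#' `grid_step` 0.001, `grid_max` 2, `gnocchi_cutoff` 4, `utr_min_len` 800,
#' `match_mode` "within", `cpg_only_methylation` TRUE, `seed` 1).
#'
#' @param path YAML path, or NULL for pure defaults.
#' @return named list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- .defaultPipelineConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  stopifnot(cfg$af_max > 0, cfg$depth_min > 0, cfg$powered_min_expected > 0,
            cfg$grid_step > 0, cfg$grid_max > 0)
  cfg$hash <- .configHash(cfg)
  cfg
}

.configHash <- function(cfg) {
  cfg$hash <- NULL
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small stable polynomial hash; enough to fingerprint a config
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

.writeStageTable <- function(dt, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sorfConstraint %s config_hash=%s seed=%s",
                     as.character(utils::packageVersion("sorfConstraint")),
                     cfg$hash, cfg$seed), con)
  out <- as.data.table(dt)
  num <- vapply(out, is.double, logical(1))
  for (cn in names(out)[num]) out[[cn]] <- formatC(out[[cn]], digits = 10,
                                                   format = "g")
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage table written by the pipeline
#' @param path TSV path (first line is a provenance comment).
#' @return `data.table`.
#' @export
readStageTable <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, skip = 1L)
}

.needFile <- function(path, producer) {
  if (is.null(path) || !file.exists(path))
    stop(sprintf("missing input %s; run `%s` first (or point the config at it)",
                 if (is.null(path)) "<unset>" else path, producer),
         call. = FALSE)
  path
}

#' Run the sORF constraint pipeline
#'
#' Subcommand dispatcher behind the command-line entry point
#' (`inst/scripts/sorf-constraint`). Subcommands, each reading/writing only
#' declared files under `--out` and re-runnable deterministically:
#' \describe{
#'   \item{simulate}{generate a full synthetic input set plus the chained
#'     constraint results (manifest records seed and parameters);
#'     `scale=<f>` shrinks or grows the default study size.}
#'   \item{annotate}{BED12 + FASTA -> sORF GTF + per-possible-variant
#'     consequence table.}
#'   \item{observed}{consequence table + variant table -> per-element
#'     observed class counts.}
#'   \item{expected}{consequence table + rate table (+ methylation,
#'     coverage, variants) -> per-element expected class counts;
#'     `calibration=<k>` fixes the factor, `observed=<counts.tsv>` fits it
#'     on synonymous counts, else raw rate sums are emitted.}
#'   \item{oeuf}{observed + expected counts -> constraint table (OEUF
#'     bounds, powered flags, deciles).}
#'   \item{match}{BED12 + score track -> per-element mean scores and
#'     constraint calls.}
#'   \item{compare}{constraint table -> group comparison report.}
#' }
#'
#' @param args character vector: subcommand then `key=value` pairs
#'   (`config=<yaml>` plus stage-specific paths; `out=<dir>` default
#'   `"sorf_out"`).
#' @return invisibly, the main result of the stage.
#' @export
runSorfPipeline <- function(args) {
  if (!length(args))
    stop("usage: sorf-constraint <simulate|annotate|observed|expected|oeuf|match|compare> key=value ...")
  cmd <- args[1]
  kv <- strsplit(args[-1], "=", fixed = TRUE)
  opts <- stats::setNames(
    lapply(kv, function(x) paste(x[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1))
  cfg <- readPipelineConfig(opts$config)
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out <- if (is.null(opts$out)) "sorf_out" else opts$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  op <- function(name, default = NULL)
    if (is.null(opts[[name]])) default else opts[[name]]
  message(sprintf("[sorf-constraint] %s (config %s)", cmd, cfg$hash))
  switch(cmd,
    simulate = {
      scale <- as.numeric(op("scale", 1))
      sc <- simulationConfig(
        seed = cfg$seed,
        genomeLength = max(5e4, ceiling(5e5 * scale)),
        nPerClass = vapply(simulationConfig()$nPerClass, function(n)
          max(2L, as.integer(round(n * scale))), integer(1)))
      study <- simulateSorfStudy(sc)
      writeSimulatedInputs(study, out)
      .writeStageTable(study$oeuf, file.path(out, "constraint.tsv"), cfg)
      invisible(study)
    },
    annotate = {
      sorfs <- readBed12(.needFile(op("bed"), "simulate"))
      genome <- readReference(.needFile(op("fasta"), "simulate"))
      writeSorfGtf(sorfs, file.path(out, "sorfs.gtf"))
      cons <- classifyAll(.codingBaseTable(genome, sorfs))
      .writeStageTable(cons, file.path(out, "consequences.tsv"), cfg)
      invisible(cons)
    },
    observed = {
      cons <- readStageTable(.needFile(op("consequences"), "annotate"))
      v <- readVariantSites(.needFile(op("variants"), "simulate"))
      obs <- filterObserved(v, afMax = cfg$af_max, depthMin = cfg$depth_min)
      counts <- countObserved(obs, cons)
      .writeStageTable(counts, file.path(out, "observed_counts.tsv"), cfg)
      invisible(counts)
    },
    expected = {
      cons <- readStageTable(.needFile(op("consequences"), "annotate"))
      rates <- readRateTable(.needFile(op("rates"), "simulate"))
      methDir <- op("methylation")
      mmap <- if (!is.null(methDir)) {
        buildMethylationMap(lapply(list.files(methDir, full.names = TRUE),
                                   readMethylationTrack))
      } else NULL
      poss <- enumeratePossible(cons, rates, mmap,
                                cpgOnlyMethylation = cfg$cpg_only_methylation)
      v <- if (!is.null(op("variants"))) readVariantSites(op("variants"))
      cov <- if (!is.null(op("coverage")))
        data.table::fread(op("coverage"), sep = "\t")
      poss <- filterPossible(poss, variants = v, coverage = cov,
                             afMax = cfg$af_max, depthMin = cfg$depth_min)
      k <- if (!is.null(op("calibration"))) {
        as.numeric(op("calibration"))
      } else if (!is.null(op("observed"))) {
        # fit the synonymous calibration against an observed-counts table
        counts <- readStageTable(.needFile(op("observed"), "observed"))
        ec0 <- expectedCounts(poss, calibrationK = 1, quiet = TRUE)
        m <- merge(ec0[consequence == "synonymous"],
                   as.data.table(counts)[consequence == "synonymous"],
                   by = "sorf_id")
        fitCalibration(m$observed, m$rate_sum)
      } else {
        message("no calibration supplied; expected counts are relative rates")
        1
      }
      ec <- expectedCounts(poss, calibrationK = k, quiet = TRUE)
      .writeStageTable(ec, file.path(out, "expected_counts.tsv"), cfg)
      invisible(ec)
    },
    oeuf = {
      obs <- readStageTable(.needFile(op("observed"), "observed"))
      ec <- readStageTable(.needFile(op("expected"), "expected"))
      res <- oeufTable(obs, ec, poweredMin = cfg$powered_min_expected,
                       step = cfg$grid_step, gridMax = cfg$grid_max)
      .writeStageTable(res, file.path(out, "constraint.tsv"), cfg)
      invisible(res)
    },
    match = {
      sorfs <- readBed12(.needFile(op("bed"), "simulate"))
      track <- readScoreTrack(.needFile(op("track"), "simulate"))
      sp <- sorfSpans(sorfs)
      sc <- vapply(seq_along(sp), function(i)
        suppressWarnings(matchElement(sp[i], track, mode = cfg$match_mode)),
        numeric(1))
      res <- data.table(element_id = names(sp), score = sc,
                        constrained = gnocchiConstrained(sc,
                                                         cfg$gnocchi_cutoff))
      .writeStageTable(res, file.path(out, "track_match.tsv"), cfg)
      invisible(res)
    },
    compare = {
      res <- readStageTable(.needFile(op("constraint"), "oeuf"))
      bed <- op("bed")
      cls <- if (!is.null(bed)) sorfClass(readBed12(bed)) else NULL
      d <- as.data.table(res)[class %in% c("SNVOEUF", "MOEUF") & powered ==
                                TRUE & !is.na(upper)]
      dat <- d[, .(group = class, value = upper,
                   sorf_class = if (is.null(cls)) "unknown" else
                     unname(cls[element_id]), pair_id = element_id)]
      plan <- data.frame(name = "MOEUF_vs_SNVOEUF", groupA = "MOEUF",
                         groupB = "SNVOEUF", paired = FALSE, kendall = FALSE)
      rep <- runComparisons(dat, plan)
      .writeStageTable(rep, file.path(out, "comparisons.tsv"), cfg)
      invisible(rep)
    },
    stop(sprintf("unknown subcommand '%s'", cmd))
  )
}
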