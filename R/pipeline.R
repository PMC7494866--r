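# Orchestration: run the whole analysis from a configuration list or YAML
# file and emit the per-lineage summary tables with provenance headers.

#' Default pipeline configuration
#'
#' @return Named list of defaults; override any entry via the `config`
#'   argument of [runPipeline()] or a YAML file.
#' @export
defaultConfig <- function() {
  list(
    alignment = NULL, annotation = NULL, mask = NULL, lineages = NULL,
    output_dir = "porpopgen_out",
    partitions = c("whole", "noncoding", "cds_concat"),
    rarefaction = list(k = 3L, B = 2500L, seed = 1L),
    mk = list(outgroup_lineages = NULL, code = "2"),
    neutrality = list(n_sims = 10000L, seed = 1L, min_n = 4L),
    mismatch = list(B = 10000L, seed = 1L, min_n = 10L),
    conversions = list(rate_per_site_per_year = 5e-8,
                       generation_years = 10))
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [defaultConfig()].
#' @return Config list.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stopInput("config file not found: %s", path)
  mergeConfig(defaultConfig(), yaml::read_yaml(path))
}

writeTsv <- function(df, path, configHash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# porpopgen %s",
                       as.character(utils::packageVersion("porpopgen"))),
               sprintf("# config_hash: %s", configHash)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full mitogenome population-genetics pipeline
#'
#' Ingests the alignment, annotation, mask and lineage table named in the
#' configuration, then per lineage (and species) computes the diversity
#' table over the requested partitions, rarefied pi, the per-lineage
#' McDonald-Kreitman table against each configured outgroup lineage, the
#' neutrality-test table with simulation p-values, and mismatch-
#' distribution fits — writing one TSV/JSON per stage plus a log. Groups
#' below the minimum sample size for a stage are skipped with a logged
#' reason; the run continues.
#'
#' @param config A config list (see [defaultConfig()]), a YAML path, or a
#'   list with preloaded objects in `alignment`/`annotation`/`lineages`.
#' @return Invisibly, a list with every computed table and the output
#'   paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readConfig(config)
  cfg <- mergeConfig(defaultConfig(), config)
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    message(msg)
  }
  aln <- if (methods::is(cfg$alignment, "MitoAlignment")) cfg$alignment
         else readAlignment(cfg$alignment)
  ann <- if (is.null(cfg$annotation)) NULL
         else if (methods::is(cfg$annotation, "GRanges")) cfg$annotation
         else readAnnotation(cfg$annotation)
  lineages <- if (is.data.frame(cfg$lineages)) lineageTable(cfg$lineages)
              else readLineageTable(cfg$lineages)
  if (!is.null(cfg$mask)) {
    mask <- if (methods::is(cfg$mask, "IRanges")) cfg$mask
            else readMask(cfg$mask)
    say("masking %d interval(s) totalling %d bp", length(mask),
        sum(IRanges::width(mask)))
    aln <- applyMask(aln, mask)
  }
  validateLineages(lineages, aln)
  cfgHash <- substr(digestConfig(cfg), 1, 12)
  dir <- cfg$output_dir
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- list(config = cfg)

  say("diversity table: %d lineages x %d partitions",
      length(unique(lineages$lineage)), length(cfg$partitions))
  out$diversity <- diversityTable(aln, lineages, ann,
                                  partitions = cfg$partitions)

  groups <- split(lineages$sample_id, lineages$lineage)
  rarRows <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], sampleIds(aln))
    if (length(ids) < cfg$rarefaction$k) {
      say("rarefaction skipped for %s: n = %d < k = %d", g, length(ids),
          cfg$rarefaction$k)
      next
    }
    rp <- rarefiedPi(subsetSamples(aln, ids), k = cfg$rarefaction$k,
                     B = cfg$rarefaction$B, seed = cfg$rarefaction$seed)
    rarRows[[g]] <- data.frame(lineage = g, k = rp$k, B = rp$B,
                               pi_median = rp$median, pi_mean = rp$mean,
                               ci_low = rp$ciLow, ci_high = rp$ciHigh)
  }
  out$rarefaction <- do.call(rbind, rarRows)

  if (!is.null(ann)) {
    out$region_diversity <- regionDiversity(aln, ann)
    caln <- codonAlignment(aln, ann, cfg$mk$code)
    outLin <- cfg$mk$outgroup_lineages
    if (!is.null(outLin)) {
      mkRows <- list()
      for (og in outLin) {
        ogIds <- intersect(groups[[og]], sampleIds(aln))
        for (g in setdiff(names(groups), og)) {
          ids <- intersect(groups[[g]], sampleIds(aln))
          if (length(ids) < 2L) {
            say("MK test skipped for %s vs %s: n < 2", g, og)
            next
          }
          mk <- mkTest(subsetCodons(caln, ids), subsetCodons(caln, ogIds))
          pn <- piNpiS(subsetCodons(caln, ids))
          mkRows[[paste(g, og)]] <-
            data.frame(lineage = g, outgroup = og,
                       Dn = mk$table[["Dn"]], Ds = mk$table[["Ds"]],
                       Pn = mk$table[["Pn"]], Ps = mk$table[["Ps"]],
                       NI = mk$NI, G = mk$G, p_G = mk$pG,
                       p_Fisher = mk$pFisher,
                       pi_N = pn$piN, pi_S = pn$piS,
                       pi_N_pi_S = pn$ratio)
        }
      }
      out$mk <- do.call(rbind, mkRows)
    }
  }

  neutRows <- list(); mmFits <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], sampleIds(aln))
    sub <- if (length(ids) >= 2L) subsetSamples(aln, ids) else NULL
    if (length(ids) >= cfg$neutrality$min_n) {
      ns <- neutralityStats(sub, nSims = cfg$neutrality$n_sims,
                            seed = cfg$neutrality$seed)
      neutRows[[g]] <- cbind(data.frame(lineage = g), ns)
    } else {
      say("neutrality tests skipped for %s: n = %d < %d", g, length(ids),
          cfg$neutrality$min_n)
    }
    if (length(ids) >= cfg$mismatch$min_n) {
      h <- mismatchHistogram(sub)
      mmFits[[g]] <- fitSuddenExpansion(h, B = cfg$mismatch$B,
                                        seed = cfg$mismatch$seed)
    } else {
      say("mismatch fit skipped for %s: n = %d < %d", g, length(ids),
          cfg$mismatch$min_n)
    }
  }
  out$neutrality <- do.call(rbind, neutRows)
  out$mismatch <- mmFits

  if (!is.null(dir)) {
    paths <- list()
    paths$diversity <- writeTsv(out$diversity,
                                file.path(dir, "diversity.tsv"), cfgHash)
    if (!is.null(out$rarefaction))
      paths$rarefaction <- writeTsv(out$rarefaction,
                                    file.path(dir, "rarefaction.tsv"),
                                    cfgHash)
    if (!is.null(out$mk))
      paths$mk <- writeTsv(out$mk, file.path(dir, "mk.tsv"), cfgHash)
    if (!is.null(out$neutrality))
      paths$neutrality <- writeTsv(out$neutrality,
                                   file.path(dir, "neutrality.tsv"),
                                   cfgHash)
    if (length(mmFits)) {
      mm <- lapply(mmFits, function(f)
        list(model = f@model, theta0 = f@theta0, theta1 = f@theta1,
             tau = f@tau, ssd = f@ssd, p_ssd = f@pSsd, B = f@B,
             seed = f@seed,
             ci = if (nrow(f@ci)) apply(f@ci, 1L, as.list) else NULL,
             histogram = f@observed))
      paths$mismatch <- file.path(dir, "mismatch.json")
      jsonlite::write_json(mm, paths$mismatch, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    }
    writeLines(c(sprintf("# porpopgen run, config %s", cfgHash), log),
               file.path(dir, "run.log"))
    paths$log <- file.path(dir, "run.log")
    out$paths <- paths
  }
  out$log <- log
  invisible(out)
}

# stable fingerprint of the analysis-relevant configuration (the output
# location does not change the results and is excluded)
digestConfig <- function(cfg) {
  cfg$output_dir <- NULL
  s <- jsonlite::toJSON(rapply(cfg, function(x)
    if (methods::is(x, "MitoAlignment") || methods::is(x, "GRanges"))
      "object" else x, how = "replace"), auto_unbox = TRUE)
  # polynomial rolling hash over the serialized config (doubles stay exact
  # below 2^53)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^44
  sprintf("%.0f-%d", h, length(bytes))
}
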