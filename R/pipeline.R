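## End-to-end orchestration: reads the study inputs, runs diversity
## profiles, the factorial dispersion design (null models x taxa pools x
## weightings x support-collapse thresholds), guild tests, trait nulls and
## UniFrac, and writes provenance-stamped TSV outputs plus a machine-
## readable manifest. Re-running with the same configuration and seed
## reproduces every output byte-identically.

.configDefaults <- function() {
  list(table = NULL, metadata = NULL, tree = NULL, taxonomy = NULL,
       traits = NULL, trait_categories = NULL, out_dir = NULL, seed = NULL,
       depth_policy = "min", n_rarefactions = 10, n_null = 199,
       q_min = 0, q_max = 5, q_step = 0.5,
       null_models = "taxa.labels,phylogeny.pool,independent.swap",
       pool_scopes = "all,year,core",
       weightings = "presence,proportional",
       collapse_thresholds = "0,50,80",
       guilds = "default", guild_null_model = "taxa.labels",
       trait_namespace = "KO", trait_pool_by = NULL)
}

.splitKey <- function(x) strsplit(as.character(x), ",[ ]*")[[1L]]

#' Read (or validate) an analysis configuration
#'
#' Configurations are flat key = value text files (or named lists). Keys:
#' input paths (`table`, `metadata`, `tree`, `taxonomy`, `traits`,
#' `trait_categories`), `out_dir`, a mandatory integer `seed` (wall-clock
#' seeding is deliberately impossible), `depth_policy` ("min" or a fixed
#' integer), `n_rarefactions`, `n_null`, the q grid (`q_min`, `q_max`,
#' `q_step`), and comma-separated factor lists `null_models`, `pool_scopes`,
#' `weightings`, `collapse_thresholds`. `guilds` is "default" (the built-in
#' guild set), "none", or absent. Unknown null models, scopes or weightings
#' are rejected here, before any computation.
#'
#' @param config path to a key = value file, or a named list.
#' @return validated config list of class "AnalysisConfig".
#' @export
readAnalysisConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    lines <- readLines(config)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    config <- setNames(lapply(kv, function(x) trimws(x[3L])),
                       vapply(kv, function(x) trimws(x[2L]), character(1)))
  }
  cfg <- .configDefaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  if (is.null(cfg$seed)) stop("config must set an integer 'seed'")
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("n_rarefactions", "n_null")) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("q_min", "q_max", "q_step")) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$null_models <- .splitKey(cfg$null_models)
  cfg$pool_scopes <- .splitKey(cfg$pool_scopes)
  cfg$weightings <- .splitKey(cfg$weightings)
  cfg$collapse_thresholds <- as.numeric(.splitKey(cfg$collapse_thresholds))
  badNm <- setdiff(cfg$null_models,
                   c("taxa.labels", "phylogeny.pool", "independent.swap"))
  if (length(badNm)) stop("unknown null model(s): ",
                          paste(badNm, collapse = ", "))
  badSc <- setdiff(cfg$pool_scopes, c("all", "year", "core"))
  if (length(badSc)) stop("unknown pool scope(s): ",
                          paste(badSc, collapse = ", "))
  badWt <- setdiff(cfg$weightings, c("presence", "proportional"))
  if (length(badWt)) stop("unknown weighting(s): ",
                          paste(badWt, collapse = ", "))
  for (k in c("table", "metadata")) {
    if (is.null(cfg[[k]])) stop("config must set '", k, "'")
    if (!file.exists(cfg[[k]])) stop("config ", k, " path does not exist: ",
                                     cfg[[k]])
  }
  for (k in c("tree", "taxonomy", "traits", "trait_categories")) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("config ", k, " path does not exist: ", cfg[[k]])
  }
  if (is.null(cfg$out_dir)) stop("config must set 'out_dir'")
  structure(cfg, class = "AnalysisConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full study-shaped analysis
#'
#' Executes, under one seed: rarefied naive and phylogenetic diversity
#' profiles per sample; the factorial dispersion design (every configured
#' null model x taxa-pool scope x weighting x support-collapse threshold);
#' guild-level dispersion; trait-richness nulls (when a trait table is
#' configured); and the unweighted UniFrac matrix. Outputs are TSVs with a
#' provenance header (configuration hash and seed) plus `manifest.json`
#' listing the factorial cells and the md5 of every file.
#'
#' @param config an \code{\link{readAnalysisConfig}} result, a named list,
#'   or a path to a key = value config file.
#' @param stages which stages to run (default all; profiles, dispersion,
#'   traits, unifrac). The manifest is always written.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, stages = c("profiles", "dispersion",
                                           "traits", "unifrac")) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- if (inherits(config, "AnalysisConfig")) config
         else readAnalysisConfig(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .hashObject(unclass(cfg)[order(names(unclass(cfg)))])

  comm <- .stage("read_inputs",
    readCommunityTable(cfg$table, cfg$metadata, treePath = cfg$tree,
                       taxonomyPath = cfg$taxonomy))
  tt <- if (!is.null(cfg$traits))
    .stage("read_inputs",
      readTraitTable(cfg$traits, categoryPath = cfg$trait_categories,
                     namespace = cfg$trait_namespace)) else NULL
  depth <- if (identical(cfg$depth_policy, "min")) min(sampleDepths(comm))
           else as.integer(cfg$depth_policy)
  qGrid <- seq(cfg$q_min, cfg$q_max, by = cfg$q_step)
  if ("proportional" %in% cfg$weightings)
    message("note: sequence counts are an imperfect proxy for proportional ",
            "abundance; proportional weighting is reported alongside ",
            "presence/absence, not instead of it")
  outputs <- character()

  ## diversity profiles
  if ("profiles" %in% stages) {
  profiles <- .stage("profiles", {
    rbind(communityProfiles(comm, "naive", qGrid = qGrid, depth = depth,
                            nReps = cfg$n_rarefactions,
                            seed = cfg$seed + 1L),
          communityProfiles(comm, "phylogenetic", qGrid = qGrid,
                            depth = depth, nReps = cfg$n_rarefactions,
                            seed = cfg$seed + 2L))
  })
  outputs["profiles"] <- file.path(cfg$out_dir, "profiles.tsv")
  .writeOutput(profiles, outputs["profiles"], hash, cfg$seed)
  }

  ## factorial dispersion design
  cells <- NULL
  if ("dispersion" %in% stages) {
  cells <- expand.grid(threshold = cfg$collapse_thresholds,
                       null_model = cfg$null_models,
                       pool_scope = cfg$pool_scopes,
                       weighting = cfg$weightings,
                       stringsAsFactors = FALSE)
  dispersion <- .stage("dispersion", {
    res <- lapply(seq_len(nrow(cells)), function(i) {
      thr <- cells$threshold[i]
      treeT <- collapseLowSupport(communityTree(comm), thr)
      out <- sesMPD(comm, nullModel = cells$null_model[i],
                    poolScope = cells$pool_scope[i],
                    weighting = cells$weighting[i],
                    nNull = cfg$n_null, rarefyDepth = depth,
                    nRarefactions = cfg$n_rarefactions,
                    distMatrix = copheneticDistances(treeT),
                    seed = cfg$seed + 100L + i)
      cbind(out, collapse_threshold = thr)
    })
    do.call(rbind, res)
  })
  if (!identical(cfg$guilds, "none") && !is.null(taxonomyLineage(comm))) {
    gd <- .stage("guild_dispersion",
      guildDispersion(comm, nullModel = cfg$guild_null_model,
                      poolScope = cfg$pool_scopes[1L],
                      weighting = cfg$weightings[1L],
                      nNull = cfg$n_null, rarefyDepth = depth,
                      nRarefactions = cfg$n_rarefactions,
                      seed = cfg$seed + 99L))
    dispersion <- rbind(dispersion, cbind(gd, collapse_threshold = 0))
  }
  outputs["dispersion"] <- file.path(cfg$out_dir, "dispersion.tsv")
  .writeOutput(dispersion, outputs["dispersion"], hash, cfg$seed)
  }

  ## trait nulls
  if ("traits" %in% stages && !is.null(tt)) {
    traitRes <- .stage("traits",
      traitSES(tt, nReps = cfg$n_rarefactions, nNull = cfg$n_null,
               seed = cfg$seed + 3L, poolBy = cfg$trait_pool_by))
    outputs["traits"] <- file.path(cfg$out_dir, "traits.tsv")
    .writeOutput(traitRes, outputs["traits"], hash, cfg$seed)
  }

  ## beta diversity
  if ("unifrac" %in% stages) {
  uf <- .stage("unifrac",
    unifracMatrix(comm, depth = depth, nReps = cfg$n_rarefactions,
                  seed = cfg$seed + 4L))
  outputs["unifrac"] <- file.path(cfg$out_dir, "unifrac.tsv")
  ufm <- uf
  attributes(ufm) <- attributes(uf)[c("dim", "dimnames")]
  ufdf <- data.frame(sample = rownames(ufm), as.data.frame(ufm),
                     check.names = FALSE)
  .writeOutput(ufdf, outputs["unifrac"], hash, cfg$seed)
  }

  manifest <- list(
    package = "matdiversity",
    version = as.character(utils::packageVersion("matdiversity")),
    config = unclass(cfg), config_hash = hash, seed = cfg$seed,
    rarefaction_depth = depth,
    dispersion_cells = cells,
    outputs = lapply(as.list(outputs), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  manifestPath <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
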