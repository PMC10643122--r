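# Single-config orchestration of the analysis stages
# (curate -> features -> annotate; massphot), with a run manifest.

#' Read a pipeline configuration from YAML
#' @param path path to a YAML config.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("config parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  cfg$config_path <- normalizePath(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config` (or plain list).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$config_path <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a pipeline configuration
#'
#' Checks the invariants of every referenced parameter block and the
#' existence of referenced input paths. Problems name the offending key.
#'
#' @param config a list from [read_pipeline_config()] (or built in code).
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  cur <- config$curation
  if (!is.null(cur)) {
    if (!is.null(cur$e_max) && cur$e_max <= 0) note("curation.e_max: must be > 0")
    if (!is.null(cur$cov_min) && (cur$cov_min <= 0 || cur$cov_min > 100)) {
      note("curation.cov_min: must be in (0, 100]")
    }
    if (!is.null(cur$identity_threshold) &&
        (cur$identity_threshold <= 0 || cur$identity_threshold > 1)) {
      note("curation.identity_threshold: must be in (0, 1]")
    }
  }
  pr <- config$patch_rule
  if (!is.null(pr)) {
    win <- if (is.null(pr$window)) 4L else pr$window
    mb <- if (is.null(pr$min_basic)) 3L else pr$min_basic
    if (mb < 1 || mb > win) note("patch_rule.min_basic: must satisfy 1 <= min_basic <= window")
  }
  st <- config$support_thresholds
  if (!is.null(st)) {
    one <- if (is.null(st$one_star)) 75 else st$one_star
    two <- if (is.null(st$two_star)) 100 else st$two_star
    if (!(one > 0 && one < two && two <= 100)) {
      note("support_thresholds: require 0 < one_star < two_star <= 100")
    }
  }
  for (key in c("fasta", "hits", "msa", "tree", "clades", "events")) {
    p <- config$inputs[[key]]
    if (!is.null(p) && !file.exists(p)) {
      note(paste0("inputs.", key, ": file not found: ", p))
    }
  }
  for (an in config$anchors) {
    ok <- tryCatch({compile_motif(an$pattern); TRUE}, error = function(e) FALSE)
    if (!ok) note(paste0("anchors.", an$name, ".pattern: invalid motif"))
  }
  mp <- config$massphot
  if (!is.null(mp)) {
    if (!is.null(mp$c_total_nM) && mp$c_total_nM <= 0) note("massphot.c_total_nM: must be > 0")
    if (!is.null(mp$monomer_kda) && mp$monomer_kda <= 0) note("massphot.monomer_kda: must be > 0")
  }
  problems
}

.stage_segments_from_config <- function(config) {
  segs <- list()
  for (seg in config$segments) {
    up <- config$anchors[[seg$upstream]]
    down <- config$anchors[[seg$downstream]]
    if (is.null(up) || is.null(down)) {
      stop("segment '", seg$name, "' references undeclared anchors", call. = FALSE)
    }
    segs[[seg$name]] <- list(
      upstream = anchor_spec(seg$upstream, up$pattern,
                             expected_position = up$expected_position,
                             search_window = if (is.null(up$search_window)) 300 else up$search_window),
      downstream = anchor_spec(seg$downstream, down$pattern,
                               expected_position = down$expected_position,
                               search_window = if (is.null(down$search_window)) 300 else down$search_window),
      scan_patches = isTRUE(seg$scan_patches)
    )
  }
  segs
}

#' Run the configured analysis stages
#'
#' Executes, in order and as configured: curation (hit filtering +
#' redundancy reduction), feature measurement, tree annotation with a
#' per-clade summary, and mass-photometry Kd estimation. Every stage
#' writes its outputs under `out_dir`, and a JSON manifest records input
#' hashes, the config hash, the seed, and per-stage record counts.
#' Identical config and inputs yield identical outputs.
#'
#' @param config a validated `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("config error:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("lrrksig")),
    seed = config$seed,
    stages = list(),
    inputs = lapply(Filter(Negate(is.null), config$inputs),
                    function(p) unname(tools::md5sum(p)))
  )
  if (!is.null(config$config_path)) {
    manifest$config_md5 <- unname(tools::md5sum(config$config_path))
  }

  feature_input <- NULL
  if (!is.null(config$inputs$fasta)) {
    feature_input <- read_fasta(config$inputs$fasta)
  }

  if (!is.null(config$inputs$hits) && !is.null(feature_input)) {
    hits <- read_hit_table(config$inputs$hits)
    cur <- config$curation
    params <- curation_params(
      e_max = if (is.null(cur$e_max)) 1e-20 else cur$e_max,
      cov_min = if (is.null(cur$cov_min)) 40 else cur$cov_min,
      identity_threshold = if (is.null(cur$identity_threshold)) 0.8 else cur$identity_threshold
    )
    curated <- curate(hits, feature_input, params, exclude = cur$exclude)
    write_fasta(curated, file.path(out_dir, "curated.fasta"))
    manifest$stages$curate <- list(counts = as.list(attr(curated, "counts")))
    feature_input <- curated
  }

  features <- NULL
  if (!is.null(config$segments) && !is.null(feature_input)) {
    segs <- .stage_segments_from_config(config)
    pr <- config$patch_rule
    rule <- patch_rule(
      window = if (is.null(pr$window)) 4L else pr$window,
      min_basic = if (is.null(pr$min_basic)) 3L else pr$min_basic,
      basic_set = if (is.null(pr$basic_set)) DEFAULT_BASIC else pr$basic_set
    )
    features <- measure_features(feature_input, segs, rule = rule)
    write_feature_table(features, file.path(out_dir, "features.tsv"))
    n_anchor_na <- sum(is.na(features[grep("_len$", names(features))]))
    manifest$stages$features <- list(
      sequences = nrow(features),
      missing_anchor_measurements = n_anchor_na
    )
  }

  if (!is.null(config$inputs$tree) && !is.null(features)) {
    tree <- read_newick(path = config$inputs$tree)
    ann <- annotate_tips(tree, features)
    clade_map <- if (!is.null(config$inputs$clades)) {
      utils::read.table(config$inputs$clades, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    } else {
      data.frame(id = features$id, clade = features$clade,
                 stringsAsFactors = FALSE)
    }
    report <- clade_summary(tree, clade_map, features)
    write_feature_table(report, file.path(out_dir, "clade_report.tsv"))
    manifest$stages$annotate <- list(
      tips = length(tree$tip.label),
      unmatched_tips = length(ann$unmatched)
    )
  }

  if (!is.null(config$inputs$events)) {
    mp <- config$massphot
    ev <- utils::read.csv(config$inputs$events)
    if (!"mass" %in% names(ev)) names(ev)[1] <- "mass"
    if (!"replicate" %in% names(ev)) ev$replicate <- 1L
    sets <- lapply(split(ev$mass, ev$replicate), function(m) {
      mass_events(m, c_total = mp$c_total_nM)
    })
    for (i in seq_along(sets)) sets[[i]]$replicate <- names(sets)[i]
    est <- estimate_kd(sets, monomer_kda = mp$monomer_kda)
    jsonlite::write_json(
      list(per_replicate = est$per_replicate, kd_nM = est$kd_nM,
           kd_uM = est$kd_uM),
      file.path(out_dir, "kd.json"), auto_unbox = TRUE, digits = NA
    )
    manifest$stages$massphot <- list(replicates = nrow(est$per_replicate),
                                     kd_nM = est$kd_nM)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
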