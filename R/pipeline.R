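## End-to-end orchestration: build (or load) per-species CREF matrices,
## decompose, run stability and cross-species comparison, enrichment and
## repeat-motif analysis, with seeded reproducibility and a manifest of
## every output file.

#' Assemble and validate a pipeline configuration
#'
#' @param species Named list; each element is a list with either `cref`
#'   (path to a precomputed CREF TSV) or `genome` + `annotation` paths.
#' @param pwms PWM library: a `pwm_library`, or a path to a
#'   TRANSFAC-format file.
#' @param profile Threshold profile for scanning.
#' @param n_levels Decomposition depth.
#' @param lambda,tol,max_rank Passed to [rpca_ialm()].
#' @param reference Name of the reference species for comparisons
#'   (default: the first).
#' @param compare_levels Levels compared across species (default
#'   1..n_levels-1).
#' @param r_conserved,d_small Classification thresholds.
#' @param gmt Optional GMT path for enrichment.
#' @param enrich_levels Levels tested for enrichment.
#' @param repeats Optional repeat-consensus FASTA path for MPA analysis.
#' @param pole_size Pole size for MPA counting.
#' @param seed Global seed recorded in the manifest.
#' @param out_dir Output directory (created if absent).
#' @return A validated `cref_config` list.
#' @export
cref_config <- function(species, pwms = NULL, profile = "minFN",
                        n_levels = 6L, lambda = "auto", tol = 1e-7,
                        max_rank = Inf, reference = names(species)[1],
                        compare_levels = NULL, r_conserved = 0.95,
                        d_small = 0.05, gmt = NULL,
                        enrich_levels = NULL, repeats = NULL,
                        pole_size = 100L, seed = 1L, out_dir = ".") {
  stopifnot(is.list(species), length(species) >= 1L,
            !is.null(names(species)))
  for (nm in names(species)) {
    sp <- species[[nm]]
    if (!is.null(sp$cref)) {
      if (!file.exists(sp$cref))
        stop_cref(sprintf("species %s: cref file not found", nm),
                  "config_error")
    } else {
      if (is.null(sp$genome) || is.null(sp$annotation))
        stop_cref(sprintf("species %s needs cref or genome+annotation",
                          nm), "config_error")
      if (!file.exists(sp$genome) || !file.exists(sp$annotation))
        stop_cref(sprintf("species %s: genome/annotation not found", nm),
                  "config_error")
    }
  }
  if (is.character(pwms) && !file.exists(pwms))
    stop_cref("PWM file not found", "config_error")
  if (!reference %in% names(species))
    stop_cref("reference species not in species list", "config_error")
  structure(list(species = species, pwms = pwms, profile = profile,
                 n_levels = as.integer(n_levels), lambda = lambda,
                 tol = tol, max_rank = max_rank, reference = reference,
                 compare_levels = compare_levels,
                 r_conserved = r_conserved, d_small = d_small,
                 gmt = gmt, enrich_levels = enrich_levels,
                 repeats = repeats, pole_size = as.integer(pole_size),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cref_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML path with the fields of [cref_config()].
#' @export
read_cref_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_cref("the yaml package is required to read YAML configs",
              "config_error")
  do.call(cref_config, yaml::read_yaml(path))
}

#' Run the full CREF analysis pipeline
#'
#' Executes build (or load) -> decompose -> stability/compare -> enrich
#' -> repeat-motif analysis, skipping optional stages whose inputs are
#' absent (with a logged warning), and writes a manifest with seeds,
#' package version, per-stage outputs and checksums. Reruns with the
#' same config and seed produce byte-identical outputs.
#'
#' @param config A `cref_config`.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cref_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings_log <- character(0)
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    message("run_pipeline: ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  opath <- function(...) file.path(config$out_dir, paste0(...))

  pwm_lib <- stage("build", {
    if (inherits(config$pwms, "pwm_library")) config$pwms
    else if (!is.null(config$pwms)) read_transfac(config$pwms)
    else NULL
  })

  crefs <- stage("build", {
    out <- list()
    for (nm in names(config$species)) {
      sp <- config$species[[nm]]
      cm <- if (!is.null(sp$cref)) read_cref(sp$cref, species = nm)
      else {
        if (is.null(pwm_lib))
          stop_cref("building a CREF matrix requires a PWM library",
                    "config_error")
        build_cref(sp$genome, sp$annotation, pwm_lib,
                   profile = config$profile, species = nm)
      }
      p <- opath("cref_", nm, ".tsv")
      write_cref(cm, p)
      outputs <- c(outputs, p)
      out[[nm]] <- cm
    }
    out
  })

  decomps <- stage("decompose", {
    out <- list()
    for (nm in names(crefs)) {
      dec <- decompose_cref(crefs[[nm]], n_levels = config$n_levels,
                            lambda = config$lambda, tol = config$tol,
                            max_rank = config$max_rank)
      outputs <- c(outputs, write_decomposition(dec,
                                                 opath("decomp_", nm)))
      out[[nm]] <- dec
    }
    out
  })

  comparison <- stage("compare", {
    gaps_ref <- relative_distances(decomps[[config$reference]],
                                   gap_threshold = config$d_small)
    p <- opath("stability_", config$reference, ".tsv")
    write_tsv(gaps_ref, p)
    outputs <- c(outputs, p)
    others <- setdiff(names(decomps), config$reference)
    out <- list()
    for (nm in others) {
      lv <- config$compare_levels %||% seq_len(config$n_levels - 1L)
      cmp <- compare_species(decomps[[config$reference]], decomps[[nm]],
                             levels = lv,
                             r_conserved = config$r_conserved,
                             d_small = config$d_small)
      p <- opath("compare_", config$reference, "_vs_", nm, ".tsv")
      write_tsv(cmp, p)
      outputs <- c(outputs, p)
      out[[nm]] <- cmp
    }
    out
  })

  enrichment <- if (is.null(config$gmt)) NULL
  else if (!file.exists(config$gmt)) {
    note(sprintf("enrichment skipped: GMT file '%s' not found",
                 config$gmt))
    NULL
  } else stage("enrich", {
    collection <- read_gmt(config$gmt)
    lv <- config$enrich_levels %||% seq_len(config$n_levels)
    out <- list()
    for (nm in names(decomps)) {
      tab <- enrich_all(decomps[[nm]], collection, levels = lv)
      n_unres <- sum(tab$n_unresolved)
      if (n_unres > 0)
        note(sprintf("enrichment %s: %d unresolved set members", nm,
                     n_unres))
      p <- opath("enrichment_", nm, ".tsv")
      write_tsv(tab, p)
      outputs <- c(outputs, p)
      out[[nm]] <- tab
    }
    out
  })

  mpa <- if (is.null(config$repeats)) NULL
  else if (!file.exists(config$repeats)) {
    note(sprintf("MPA stage skipped: repeat FASTA '%s' not found",
                 config$repeats))
    NULL
  } else stage("mpa", {
    if (is.null(pwm_lib))
      stop_cref("MPA analysis requires a PWM library", "config_error")
    mpa_set <- find_mpa(pwm_lib, config$repeats, profile = config$profile)
    p <- opath("mpa_set.tsv")
    write_tsv(data.frame(motif_id = mpa_set), p)
    outputs <- c(outputs, p)
    others <- setdiff(names(decomps), config$reference)
    out <- list(mpa_set = mpa_set)
    for (nm in others) {
      rep_tab <- mpa_report(decomps[[config$reference]], decomps[[nm]],
                            mpa_set,
                            levels = seq_len(config$n_levels),
                            n = min(config$pole_size,
                                    length(decomps[[nm]]$motif_ids)))
      p <- opath("mpa_", config$reference, "_vs_", nm, ".tsv")
      write_tsv(rep_tab, p)
      outputs <- c(outputs, p)
      out[[nm]] <- rep_tab
    }
    out
  })

  manifest <- list(
    package = "crefdual",
    version = as.character(utils::packageVersion("crefdual")),
    seed = config$seed,
    reference = config$reference,
    species = names(config$species),
    stages = list(build = TRUE, decompose = TRUE,
                  compare = length(comparison) > 0,
                  enrich = !is.null(enrichment), mpa = !is.null(mpa)),
    warnings = as.list(warnings_log),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, crefs = crefs, decomps = decomps,
                 comparison = comparison, enrichment = enrichment,
                 mpa = mpa))
}
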