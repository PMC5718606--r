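## Pipeline orchestration: a serializable run configuration (YAML), stage
## toggles, dependency-checked execution and a reproducibility manifest.
## One global seed fans out to per-stage child seeds by stable hashing of
## stage names, so toggling one stage never shifts another stage's stream.

default_run_config <- function() {
  list(
    seed = 1L,
    scale = 1,
    stages = list(simulate = TRUE, chem = TRUE, alpha = TRUE, beta = TRUE,
                  diff = TRUE, core = TRUE, varpart = TRUE),
    generator = list(),         # overrides for generator_config()
    beta = list(metrics = c("braycurtis", "jaccard", "thetayc", "morisitahorn"),
                unifrac = TRUE, n_perm = 10000, mantel_n_perm = 9999,
                rarefy = TRUE, depth = NULL),
    diff = list(n_perm = 1999, effect_threshold = 0.25),
    core = list(grid_points = 30),
    varpart = list(screen_n_perm = 5000, partition_n_perm = 999,
                   alpha = 0.05, r_max = 0.8))
}

check_known_keys <- function(x, ref, path = "") {
  extra <- setdiff(names(x), names(ref))
  if (length(extra))
    stop_gutenv("unknown config key(s): ",
                paste0(path, extra, collapse = ", "))
  for (nm in names(x)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(x[[nm]]))
      check_known_keys(x[[nm]], ref[[nm]], paste0(path, nm, "$"))
  }
}

#' Load (and validate) a pipeline run configuration
#'
#' Reads a YAML file, fills defaults, rejects unknown keys and validates
#' field values (generator overrides are validated through
#' [generator_config()], so errors name the offending field). An empty file
#' yields the full default configuration.
#'
#' @param path YAML file path.
#' @return object of class `gutenv_run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_gutenv("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_run_config(user)
}

#' Build a run configuration from a list of overrides
#'
#' @param overrides named list; see `default_run_config` structure in
#'   [load_config()].
#' @return object of class `gutenv_run_config`.
#' @export
as_run_config <- function(overrides = list()) {
  ref <- default_run_config()
  ## generator block is free-form over generator_config()'s arguments
  ref_check <- ref
  ref_check$generator <- NULL
  user_check <- overrides
  gen_over <- user_check$generator %||% list()
  user_check$generator <- NULL
  check_known_keys(user_check, ref_check)
  bad_gen <- setdiff(names(gen_over), names(formals(generator_config)))
  if (length(bad_gen))
    stop_gutenv("unknown generator key(s): ",
                paste0("generator$", bad_gen, collapse = ", "))
  cfg <- modifyList(ref, overrides, keep.null = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$scale <= 0) stop_gutenv("scale must be positive")
  ## validates generator fields (errors name the field)
  do.call(generator_config,
          c(cfg$generator[setdiff(names(cfg$generator), c("scale", "seed"))],
            list(scale = cfg$scale, seed = cfg$seed)))
  structure(cfg, class = "gutenv_run_config")
}

#' Serialize a run configuration to YAML
#'
#' Round-trips through [load_config()] to the identical configuration.
#'
#' @param config a `gutenv_run_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "gutenv_run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.gutenv_run_config <- function(x, ...) {
  on_off <- vapply(x$stages, isTRUE, TRUE)
  cat(sprintf("gutenv run config: seed %d, scale %g\n", x$seed, x$scale))
  cat("  stages:", paste0(names(on_off), ifelse(on_off, "", " (off)"),
                          collapse = ", "), "\n")
  invisible(x)
}

stage_log <- function(quiet, ...) if (!quiet) message(sprintf(...))

need_stage <- function(state, what, stage, needed_by) {
  if (is.null(state[[what]]))
    stop_gutenv("stage '", needed_by, "' requires output '", what,
                "' of disabled/failed stage '", stage, "'")
  state[[what]]
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate, chem, alpha,
#' beta, diff, core, varpart), writes every stage's tabular outputs under
#' `out_dir` and a `manifest.json` recording package version, seed, stage
#' wall times and output digests. A disabled upstream stage makes dependent
#' stages fail fast with the missing dependency named. With a fixed config
#' and seed, all numeric outputs are reproducible; manifests of two
#' identical runs differ only in their timestamps.
#'
#' @param config a `gutenv_run_config` (or path to a YAML config).
#' @param out_dir output directory.
#' @param quiet suppress per-stage messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "gutenv_run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  state <- list()
  times <- list()
  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      stage_log(quiet, "stage %s: skipped", name)
      return(invisible(NULL))
    }
    stage_log(quiet, "stage %s: running", name)
    t0 <- proc.time()[["elapsed"]]
    fun()
    times[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }

  run_stage("simulate", function() {
    gcfg <- do.call(generator_config,
                    c(config$generator[setdiff(names(config$generator),
                                               c("scale", "seed"))],
                      list(scale = config$scale, seed = config$seed)))
    ds <- generate_dataset(gcfg, dir = out_dir)
    state$dataset <<- ds
    state$counts <<- ds$counts
    state$design <<- ds$design
    state$gcfg <<- gcfg
  })

  run_stage("chem", function() {
    ds <- need_stage(state, "dataset", "simulate", "chem")
    dom <- dom_indices_table(ds$spectra, ds$tsoc, path_length = ds$path_length)
    tsv(dom, "dom_indices.tsv")
    iec <- calibrate_conductivity(ds$conductivity$samples,
                                  ds$conductivity$standards)
    tsv(iec$iec, "iec.tsv")
    prof <- lapply(names(ds$peaks), function(cl) {
      pk <- ds$peaks[[cl]]
      do.call(rbind, lapply(split(pk, pk$sample_id), function(s) {
        fp <- fingerprint_profile(s$area)
        data.frame(sample_id = s$sample_id[1], class = cl, total = fp$total,
                   peak_id = s$peak_id, fraction = fp$profile,
                   stringsAsFactors = FALSE)
      }))
    })
    chem_profiles <- do.call(rbind, prof)
    rownames(chem_profiles) <- NULL
    tsv(chem_profiles, "chem_profiles.tsv")
    ## chemical diversity of each fingerprint (profile-mode indices)
    chem_div <- do.call(rbind, lapply(split(chem_profiles,
                                            list(chem_profiles$sample_id,
                                                 chem_profiles$class),
                                            drop = TRUE), function(s) {
      idx <- alpha_profile(s$fraction, mode = "profile")
      data.frame(sample_id = s$sample_id[1], class = s$class[1],
                 t(idx), check.names = FALSE, stringsAsFactors = FALSE)
    }))
    rownames(chem_div) <- NULL
    tsv(chem_div, "chem_diversity.tsv")
    state$chem <<- list(dom = dom, iec = iec, profiles = chem_profiles,
                        diversity = chem_div)
  })

  run_stage("alpha", function() {
    counts <- need_stage(state, "counts", "simulate", "alpha")
    cts <- if (isTRUE(config$beta$rarefy))
      rarefy_counts(counts, depth = config$beta$depth,
                    seed = child_seed(config$seed, "alpha_rarefy"))
    else counts
    tab <- alpha_table(cts, mode = "counts")
    tsv(tab, "alpha.tsv")  # Shannon is ln-based; see package docs
    state$alpha <<- tab
  })

  run_stage("beta", function() {
    counts <- need_stage(state, "counts", "simulate", "beta")
    design <- state$design
    cts <- if (isTRUE(config$beta$rarefy))
      rarefy_counts(counts, depth = config$beta$depth,
                    seed = child_seed(config$seed, "beta_rarefy"))
    else counts
    design <- design[match(colnames(cts), design$sample_id), ]
    dms <- list()
    for (m in config$beta$metrics) {
      dms[[m]] <- pairwise_distance(cts, m)
      tsv(data.frame(sample_id = rownames(dms[[m]]), dms[[m]],
                     check.names = FALSE), sprintf("dm_%s.tsv", m))
    }
    if (isTRUE(config$beta$unifrac)) {
      tree <- state$dataset$tree
      for (w in c(FALSE, TRUE)) {
        nm <- if (w) "wunifrac" else "unifrac"
        dms[[nm]] <- unifrac(cts, tree, weighted = w)
        tsv(data.frame(sample_id = rownames(dms[[nm]]), dms[[nm]],
                       check.names = FALSE), sprintf("dm_%s.tsv", nm))
      }
    }
    np <- config$beta$n_perm
    tests <- list()
    for (nm in names(dms)) {
      grp <- design$arm
      tests[[length(tests) + 1]] <- data.frame(
        matrix = nm, method = "PERMANOVA",
        statistic = (t <- permanova(dms[[nm]], grp, n_perm = np,
                                    seed = config$seed))$statistic,
        p = t$p.value, n_perm = np, stringsAsFactors = FALSE)
      tests[[length(tests) + 1]] <- data.frame(
        matrix = nm, method = "AMOVA",
        statistic = (t <- amova(dms[[nm]], grp, n_perm = np,
                                seed = config$seed))$statistic,
        p = t$p.value, n_perm = np, stringsAsFactors = FALSE)
      tests[[length(tests) + 1]] <- data.frame(
        matrix = nm, method = "HOMOVA",
        statistic = (t <- homova(dms[[nm]], grp, n_perm = np,
                                 seed = config$seed))$statistic,
        p = t$p.value, n_perm = np, stringsAsFactors = FALSE)
    }
    mt <- mantel_test(dms[[1]], dms[[length(dms)]],
                      n_perm = config$beta$mantel_n_perm, seed = config$seed)
    tests[[length(tests) + 1]] <- data.frame(
      matrix = paste(names(dms)[c(1, length(dms))], collapse = "~"),
      method = "Mantel", statistic = mt$statistic, p = mt$p.value,
      n_perm = mt$n.perm, stringsAsFactors = FALSE)
    tests <- do.call(rbind, tests)
    tests$p_bh <- bh_fdr(tests$p)
    tsv(tests, "tests.tsv")
    state$beta <<- list(dms = dms, tests = tests, rarefied = cts)
  })

  run_stage("diff", function() {
    counts <- need_stage(state, "counts", "simulate", "diff")
    design <- state$design
    gcfg <- state$gcfg
    eff <- design$sample_id[design$arm == gcfg$effect_arm &
                              design$day %in% gcfg$effect_days]
    other_arms <- setdiff(ARM_LEVELS, gcfg$effect_arm)
    out <- list()
    for (arm in other_arms) {
      ref <- design$sample_id[design$arm == arm &
                                design$day %in% gcfg$effect_days]
      bat <- differential_battery(
        counts, eff, ref, n_perm = config$diff$n_perm, seed = config$seed,
        effect_threshold = config$diff$effect_threshold)
      con <- bat$congruency
      con$contrast <- paste(gcfg$effect_arm, "vs", arm)
      out[[arm]] <- con
    }
    diff_tab <- do.call(rbind, out)
    rownames(diff_tab) <- NULL
    tsv(diff_tab, "differential.tsv")
    fb <- fb_ratio_series(counts, state$dataset$taxonomy, design)
    tsv(fb$per_sample, "fb_ratio.tsv")
    tsv(fb$rates, "fb_rates.tsv")
    state$diff <<- list(battery = diff_tab, fb = fb)
  })

  run_stage("core", function() {
    counts <- need_stage(state, "counts", "simulate", "core")
    design <- state$design
    P <- relative_abundance(counts)
    grid <- abundance_grid(P, n = config$core$grid_points)
    surfaces <- list()
    plot_data <- list()
    for (arm in ARM_LEVELS) {
      cohort <- design$sample_id[design$arm == arm]
      surf <- core_fraction_surface(P, cohort, grid,
                                    seq(0.1, 1, by = 0.1))
      surfaces[[arm]] <- surf
      pd <- classify_cores(P, cohort)
      pd$cohort <- arm
      plot_data[[arm]] <- pd
    }
    plot_tab <- do.call(rbind, plot_data)
    rownames(plot_tab) <- NULL
    tsv(plot_tab, "core_plot.tsv")
    surf_long <- do.call(rbind, lapply(names(surfaces), function(arm) {
      s <- surfaces[[arm]]
      data.frame(cohort = arm,
                 abundance = rep(as.numeric(rownames(s)), ncol(s)),
                 ubiquity = rep(as.numeric(colnames(s)), each = nrow(s)),
                 fraction = as.numeric(s), stringsAsFactors = FALSE)
    }))
    tsv(surf_long, "core_surface.tsv")
    gcfg <- state$gcfg
    eff <- design$sample_id[design$arm == gcfg$effect_arm &
                              design$day %in% gcfg$effect_days]
    ref_arm <- setdiff(ARM_LEVELS, gcfg$effect_arm)[1]
    ref <- design$sample_id[design$arm == ref_arm &
                              design$day %in% gcfg$effect_days]
    aw <- awks_test(P, eff, ref, n_perm = config$diff$n_perm,
                    seed = config$seed)
    tsv(aw, "awks.tsv")
    state$core <<- list(plot = plot_tab, surfaces = surfaces, awks = aw)
  })

  run_stage("varpart", function() {
    counts <- need_stage(state, "counts", "simulate", "varpart")
    ds <- state$dataset
    H <- hellinger_transform(counts)
    retained <- list()
    screens <- list()
    for (nm in names(ds$meta)) {
      sc <- stepdown_screen(H, ds$meta[[nm]],
                            n_perm = config$varpart$screen_n_perm,
                            alpha = config$varpart$alpha,
                            r_max = config$varpart$r_max,
                            seed = child_seed(config$seed, paste0("screen_", nm)))
      screens[[nm]] <- sc
      retained[[nm]] <- sc$retained
    }
    ret_tab <- do.call(rbind, lapply(names(screens), function(nm) {
      t <- screens[[nm]]$table
      if (nrow(t)) cbind(matrix = nm, t) else NULL
    }))
    tsv(ret_tab, "retained_vars.tsv")
    nonempty <- names(retained)[vapply(retained, length, 0L) > 0]
    if (length(nonempty) >= 1) {
      mats <- lapply(nonempty, function(nm)
        ds$meta[[nm]][, retained[[nm]], drop = FALSE])
      vp <- partition_variation(H, mats[[1]], if (length(mats) > 1) mats[[2]],
                                if (length(mats) > 2) mats[[3]],
                                n_perm = config$varpart$partition_n_perm,
                                seed = config$seed)
      frac_tab <- data.frame(fraction = names(vp$fractions),
                             value = as.numeric(vp$fractions),
                             stringsAsFactors = FALSE)
      tsv(frac_tab, "partition.tsv")
      state$varpart <<- list(partition = vp, screens = screens,
                             matrices = nonempty)
    } else {
      state$varpart <<- list(partition = NULL, screens = screens,
                             matrices = character())
    }
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package = "gutenv",
    version = as.character(packageVersion("gutenv")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    scale = config$scale,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stage_seconds = times,
    outputs = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(state = state, manifest = manifest))
}
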