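#' Pipeline configuration
#'
#' Bundles every choice of a full analysis run: the synthetic universe (or
#' input paths), exposure coding, confounder set, sampler settings, mesh
#' settings and seeds. Every random stage derives its seed from the single
#' master seed, so a run is fully reproducible from its config.
#'
#' @param outdir run directory (created).
#' @param seed master seed.
#' @param sim a [sim_config()] for the `simulate` stage.
#' @param sex `"men"` or `"women"` (which mortality series is analysed).
#' @param adjusted also fit the confounder-adjusted model (default TRUE).
#' @param run_joint fit approach B (default TRUE).
#' @param n_iter,burnin MCMC lengths for the fits.
#' @param n_neighbours kriging neighbourhood size.
#' @param site_label cancer-site label written into the report tables.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir, seed = 1L, sim = sim_config(),
                            sex = "men", adjusted = TRUE, run_joint = TRUE,
                            n_iter = 600, burnin = 300, n_neighbours = 64,
                            site_label = "all_sites") {
  structure(list(format_version = 1L, outdir = outdir, seed = as.integer(seed),
                 sim = sim, sex = sex, adjusted = adjusted,
                 run_joint = run_joint, n_iter = n_iter, burnin = burnin,
                 n_neighbours = n_neighbours, site_label = site_label),
            class = "pipeline_config")
}

config_hash <- function(cfg, stage) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(list(stage = stage, cfg = unclass(cfg)), tmp,
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: `simulate` (synthetic universe),
#' `standardise` (indirect standardisation), `krige` (variogram + ordinary
#' kriging exposure), `fit_bym` (approach A: unadjusted, adjusted and trend
#' fits), `fit_joint` (approach B), `compare_groups` (emitter contrast) and
#' `report` (combined relative-risk tables). Each stage writes its artifacts
#' under `outdir` and records a content hash in `manifest.json`; rerunning
#' with an unchanged config skips completed stages, and reruns are
#' byte-identical. A stage failure is recorded in the manifest and aborts
#' downstream stages.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (invisibly a list), with `$tables` holding the
#'   report tables.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(config$outdir, "manifest.json")
  manifest <- if (file.exists(man_path)) {
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  } else {
    list(format_version = 1L, stages = list())
  }
  if (!is.null(manifest$format_version) && manifest$format_version != 1L) {
    stop("unknown manifest format version in ", man_path)
  }

  done <- function(stage, outputs) {
    h <- config_hash(config, stage)
    rec <- manifest$stages[[stage]]
    !is.null(rec) && identical(rec$hash, h) && identical(rec$status, "ok") &&
      all(file.exists(file.path(config$outdir, outputs)))
  }
  record <- function(stage, outputs, status = "ok") {
    manifest$stages[[stage]] <<- list(hash = config_hash(config, stage),
                                      status = status, outputs = outputs)
    jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  run_stage <- function(stage, outputs, fun) {
    if (done(stage, outputs)) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      record(stage, outputs, status = paste("failed:", conditionMessage(e)))
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    if (ok) record(stage, outputs)
  }

  od <- config$outdir
  obs <- paste0("observed_", config$sex)
  exps <- paste0("expected_", config$sex)

  run_stage("simulate", "universe/areas.csv", function() {
    u <- simulate_universe(config$sim, seed = derive_seed(config$seed, "sim"))
    write_universe(u, file.path(od, "universe"), geojson = TRUE)
  })
  universe <- read_universe(file.path(od, "universe"))

  run_stage("standardise", "expected.csv", function() {
    u <- standardise_universe(universe)
    write_table_csv(u$rates_used, file.path(od, "rates.csv"))
    keep <- c("id", grep("^expected_", names(u$areas), value = TRUE))
    write_table_csv(u$areas[, keep], file.path(od, "expected.csv"))
  })
  expected <- read_table_csv(file.path(od, "expected.csv"))
  universe$areas <- merge(universe$areas[,
    setdiff(names(universe$areas), grep("^expected_", names(universe$areas),
                                        value = TRUE))],
    expected, by = "id", sort = TRUE)

  run_stage("krige", c("exposure.csv", "variogram.json"), function() {
    ev <- empirical_variogram(universe$samples)
    vm <- fit_variogram(ev)
    jsonlite::write_json(unclass(vm), file.path(od, "variogram.json"),
                         auto_unbox = TRUE, digits = NA)
    pred <- krige_to_centroids(universe, vm,
                               n_neighbours = config$n_neighbours)
    write_table_csv(pred, file.path(od, "exposure.csv"))
  })
  exposure <- read_table_csv(file.path(od, "exposure.csv"))
  areas <- attach_exposure(universe$areas, exposure)

  fits_path <- file.path(od, "fits")
  dir.create(fits_path, showWarnings = FALSE)
  specs <- list(
    list(name = "A_unadjusted", coding = "quartile_factor", adj = FALSE),
    list(name = "A_trend", coding = "quartile_ordinal", adj = FALSE))
  if (config$adjusted) {
    specs <- c(specs, list(
      list(name = "A_adjusted", coding = "quartile_factor", adj = TRUE),
      list(name = "A_trend_adjusted", coding = "quartile_ordinal",
           adj = TRUE)))
  }
  for (sp in specs) {
    out_csv <- file.path("fits", paste0(sp$name, ".csv"))
    local({
      sp <- sp
      run_stage(sp$name, out_csv, function() {
        spec <- bym_spec(coding = sp$coding,
                         covariates = if (sp$adj)
                           c("illiteracy", "unemployment") else character(0),
                         size_class = if (sp$adj) "size_class",
                         industry = if (sp$adj) "industry_within_5km")
        fit <- suppressWarnings(fit_bym(areas, universe$edges, obs, exps,
                       spec,
                       mcmc_config(n_iter = config$n_iter,
                                   burnin = config$burnin,
                                   seed = derive_seed(config$seed, sp$name))))
        write_table_csv(fit$rr_table, file.path(od, out_csv))
        write_table_csv(fit$diagnostics,
                        file.path(od, "fits", paste0(sp$name, "_diag.csv")))
        if (sp$name == "A_unadjusted") {
          rrmap <- smoothed_risk_map(fit, areas)
          write_table_csv(rrmap[, c("id", "rr_mean", "rr_q2.5", "rr_q97.5",
                                    "rr_class")],
                          file.path(od, "risk_map.csv"))
        }
      })
    })
  }

  if (config$run_joint) {
    run_stage("B_joint", "fits/B_joint.csv", function() {
      fit <- suppressWarnings(fit_joint(universe$samples, universe$areas,
                       universe$edges, obs, exps, joint_spec(),
                       mcmc_config(n_iter = config$n_iter,
                                   burnin = config$burnin,
                                   seed = derive_seed(config$seed, "joint"))))
      write_table_csv(fit$rr_table, file.path(od, "fits", "B_joint.csv"))
      write_table_csv(fit$field_summary,
                      file.path(od, "fits", "B_joint_field.csv"))
      mesh_to_files(fit$mesh, file.path(od, "mesh"))
    })
  }

  run_stage("compare_groups", "emitter_contrast.json", function() {
    gc <- emitter_contrast(areas, seed = derive_seed(config$seed, "emit"))
    jsonlite::write_json(
      list(mean = gc$mean, q2.5 = gc$q2.5, q97.5 = gc$q97.5,
           n_with = gc$n_a, n_without = gc$n_b),
      file.path(od, "emitter_contrast.json"), auto_unbox = TRUE, digits = NA)
  })

  run_stage("report", "rr_tables.csv", function() {
    fits <- list.files(fits_path, pattern = "^(A_|B_).*\\.csv$",
                       full.names = TRUE)
    fits <- fits[!grepl("_diag|_field", fits)]
    tabs <- lapply(fits, function(f) {
      tb <- read_table_csv(f)
      if (nrow(tb) == 0) return(NULL)
      nm <- sub("\\.csv$", "", basename(f))
      data.frame(site = config$site_label, sex = config$sex,
                 approach = ifelse(grepl("^A_", nm), "A", "B"),
                 model = nm, level = tb$parameter,
                 rr = tb$mean, ci_low = tb$q2.5, ci_high = tb$q97.5,
                 significant = tb$significant)
    })
    write_table_csv(do.call(rbind, tabs), file.path(od, "rr_tables.csv"))
  })

  manifest$tables <- read_table_csv(file.path(od, "rr_tables.csv"))
  invisible(manifest)
}

#' Serialise a mesh to CSV files (vertices, triangles)
#' @param mesh an `spde_mesh`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
mesh_to_files <- function(mesh, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(data.frame(x_km = mesh$vertices[, 1],
                             y_km = mesh$vertices[, 2],
                             interior = mesh$interior_mask),
                  file.path(dir, "vertices.csv"))
  write_table_csv(as.data.frame(mesh$triangles),
                  file.path(dir, "triangles.csv"))
  invisible(dir)
}
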