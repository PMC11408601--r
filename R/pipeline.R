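PIPELINE_ANALYSES <- c("dispersion", "nucleolus_fold", "line_profile",
                       "laminar_area", "hotspot_coloc", "pixel_correlation",
                       "top_percentile")

#' Default pipeline parameters
#'
#' The run defaults live here so every manifest is self-documenting: hotspot
#' window 4 px and top 20, per-pixel denominator threshold 20 counts,
#' nucleolus detection at 2x the nuclear mean and 1-3 um diameter, laminar
#' trace threshold 30 percent with 3-px count pooling, top percentile 5.
#'
#' @return named list of defaults.
#' @export
pipeline_defaults <- function() {
  list(window = 4L, top_n = 20L, min_denominator = 20,
       nucleolus_fold = 2, nucleolus_min_diameter_um = 1,
       nucleolus_max_diameter_um = 3,
       trace_threshold = 30, trace_smooth = 3L,
       percentile = 5,
       hsi = list(lower = 0, upper = 300),
       primary_tracer = "15N_RNA", density_tracer = "13C_DNA")
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    ext <- tolower(tools::file_ext(config))
    config <- switch(ext,
      yaml = , yml = yaml::read_yaml(config),
      json = jsonlite::read_json(config, simplifyVector = TRUE),
      stop(sprintf("config error: unsupported config format '%s'", ext),
           call. = FALSE))
  }
  if (!is.list(config)) stop("config error: config must be a list or a path",
                             call. = FALSE)
  config
}

#' Run a configuration-driven analysis pipeline
#'
#' Simulates a scene and/or analyzes a stack, executing the requested
#' analyses in order and writing every artifact (TIFF stacks and masks, PNG
#' renders, TSV tables, JSON summaries) under \code{output_dir} with
#' deterministic filenames, plus a JSON manifest listing inputs, seed,
#' per-analysis parameters and the MD5 checksum of each file. Identical
#' config and seed reproduce byte-identical artifacts. A failing stage
#' aborts with the stage name; artifacts already written are retained and
#' the manifest records the failed stage.
#'
#' @param config named list, or path to a YAML/JSON document with fields:
#'   \code{mode} ("simulate", "analyze" or "simulate+analyze"),
#'   \code{scene} (arguments for [scene_spec()]; simulate modes),
#'   \code{stack_path} (analyze mode), \code{analyses} (subset of
#'   dispersion, nucleolus_fold, line_profile, laminar_area, hotspot_coloc,
#'   pixel_correlation, top_percentile), \code{output_dir}, \code{seed},
#'   and optional overrides of [pipeline_defaults()] under \code{params}.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  mode <- cfg$mode %||% "simulate+analyze"
  if (!mode %in% c("simulate", "analyze", "simulate+analyze"))
    stop(sprintf("config error: unknown mode '%s'", mode), call. = FALSE)
  analyses <- unlist(cfg$analyses %||% character(0))
  if (mode != "simulate" && length(analyses) == 0L)
    stop("config error: at least one analysis is required", call. = FALSE)
  bad <- setdiff(analyses, PIPELINE_ANALYSES)
  if (length(bad))
    stop(sprintf("config error: unknown analyses: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(cfg$output_dir))
    stop("config error: output_dir is required", call. = FALSE)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  par <- utils::modifyList(pipeline_defaults(), as.list(cfg$params %||% list()))
  rds <- tracer_definitions()

  manifest <- list(mode = mode, seed = seed, analyses = as.list(analyses),
                   params = par, package_version =
                     as.character(utils::packageVersion("mimsr")),
                   files = list(), stages = list())
  add_file <- function(path, what) {
    manifest$files[[basename(path)]] <<- list(
      role = what, md5 = unname(tools::md5sum(path)))
  }
  log_stage <- function(stage, status, t0) {
    manifest$stages[[stage]] <<- status
    message(sprintf("[mimsr] stage %-16s %s (%.2fs, seed %d)",
                    stage, status, as.numeric(Sys.time()) - t0, seed))
  }
  run_stage <- function(stage, fun) {
    t0 <- as.numeric(Sys.time())
    tryCatch({ fun(); log_stage(stage, "OK", t0) },
             error = function(e) {
               log_stage(stage, "FAILED", t0)
               write_manifest()
               stop(sprintf("stage '%s' failed: %s", stage,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  truth <- NULL; stack <- NULL
  if (mode %in% c("simulate", "simulate+analyze")) {
    run_stage("simulate", function() {
      spec <- do.call(scene_spec, c(as.list(cfg$scene %||% list()),
                                    list(seed = seed)))
      truth <<- build_scene(spec)
      stack <<- sample_counts(truth, seed = seed)
      save_stack(stack, file.path(out, "stack.tif"))
      add_file(file.path(out, "stack.tif"), "ion-count stack")
      add_file(file.path(out, "stack.tif.json"), "stack sidecar")
      cm <- truth$compartment_map
      tiff::writeTIFF(cm / 255, file.path(out, "compartments.tif"),
                      bits.per.sample = 8L, compression = "none")
      jsonlite::write_json(as.list(truth$compartments),
                           file.path(out, "compartments.tif.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      add_file(file.path(out, "compartments.tif"), "ground-truth labels")
      add_file(file.path(out, "compartments.tif.json"), "label legend")
      utils::write.table(scene_truth_summary(truth),
                         file.path(out, "truth_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add_file(file.path(out, "truth_summary.tsv"), "ground-truth summary")
    })
  } else {
    run_stage("load", function() {
      if (is.null(cfg$stack_path))
        stop("config error: analyze mode requires stack_path", call. = FALSE)
      stack <<- load_stack(cfg$stack_path)
    })
  }
  if (mode == "simulate") {
    manifest$files[["manifest.json"]] <- list(role = "run manifest")
    write_manifest()
    return(invisible(manifest))
  }

  rd_p <- rds[[par$primary_tracer]]
  rd_d <- rds[[par$density_tracer]]
  nucleus <- nucleoli <- NULL
  run_stage("segment", function() {
    nucleus <<- segment_nucleus(stack, "P_threshold")
    enr_p <- enrichment_image(stack, rd_p, par$min_denominator, smooth = 3L)
    nucleoli <<- nucleolus_detect(enr_p, nucleus, par$nucleolus_fold,
                                  par$nucleolus_min_diameter_um,
                                  par$nucleolus_max_diameter_um)
  })
  enr_p <- enrichment_image(stack, rd_p, par$min_denominator)
  enr_d <- enrichment_image(stack, rd_d, par$min_denominator)
  excl <- if (length(nucleoli))
    Reduce(`|`, lapply(nucleoli, function(r) r$mask)) else NULL

  run_stage("hsi_render", function() {
    spec <- hsi_spec(par$hsi$lower, par$hsi$upper)
    for (nm in c(par$primary_tracer, par$density_tracer)) {
      e <- if (nm == par$primary_tracer) enr_p else enr_d
      p <- file.path(out, sprintf("hsi_%s.png", nm))
      png::writePNG(render_hsi(e, spec), p)
      add_file(p, sprintf("HSI render (%g-%g%%)", par$hsi$lower,
                          par$hsi$upper))
    }
  })

  for (an in analyses) {
    run_stage(an, switch(an,
      dispersion = function() {
        v <- enr_p$values[nucleus$mask & enr_p$valid]
        d <- dispersion(v)
        jsonlite::write_json(unclass(d)[c("median", "mad", "mean", "sd",
                                          "cov", "n")],
                             file.path(out, "dispersion.json"),
                             auto_unbox = TRUE, digits = NA)
        add_file(file.path(out, "dispersion.json"), "nuclear pixel dispersion")
        dump <- data.frame(pixel_id = seq_along(v) - 1L, enrichment_pct = v)
        utils::write.table(dump, file.path(out, "pixel_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_file(file.path(out, "pixel_enrichment.tsv"), "per-pixel dump")
      },
      nucleolus_fold = function() {
        rows <- lapply(seq_along(nucleoli), function(i) {
          f <- fold_enrichment(nucleoli[[i]], nucleus, enr_p)
          data.frame(nucleolus = i, area_px = sum(nucleoli[[i]]$mask),
                     fold = f$fold, se = f$se)
        })
        tab <- if (length(rows)) do.call(rbind, rows)
               else data.frame(nucleolus = integer(0), area_px = integer(0),
                               fold = numeric(0), se = numeric(0))
        utils::write.table(tab, file.path(out, "nucleolus_fold.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_file(file.path(out, "nucleolus_fold.tsv"), "nucleolar fold enrichment")
      },
      line_profile = function() {
        d <- dim(stack); mid <- round(d[1L] / 2)
        lp <- line_profile(list(RNA = enr_p, DNA = enr_d),
                           rbind(c(mid, 2), c(mid, d[2L] - 1)), width = 3L)
        tab <- data.frame(position_px = lp$position,
                          RNA = lp$samples$RNA, DNA = lp$samples$DNA)
        utils::write.table(tab, file.path(out, "line_profile.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_file(file.path(out, "line_profile.tsv"), "membrane line profile")
      },
      laminar_area = function() {
        ep <- enrichment_image(stack, rd_p, par$min_denominator,
                               smooth = par$trace_smooth)
        ed <- enrichment_image(stack, rd_d, par$min_denominator,
                               smooth = par$trace_smooth)
        dna <- labeled_area_roi(ed, par$trace_threshold, "dna_trace")
        rna <- labeled_area_roi(ep, par$trace_threshold, "rna_trace")
        res <- list(dna_area_px = sum(dna$mask), rna_area_px = sum(rna$mask),
                    unlabeled_margin_pct = unlabeled_margin_fraction(dna, rna),
                    threshold_pct = par$trace_threshold)
        jsonlite::write_json(res, file.path(out, "laminar_area.json"),
                             auto_unbox = TRUE, digits = NA)
        add_file(file.path(out, "laminar_area.json"), "laminar silencing metric")
      },
      hotspot_coloc = function() {
        hs <- detect_hotspots(stack, rd_p, par$window, par$top_n,
                              nucleus, exclusion_mask = excl)
        hs <- colocalize_hotspots(hs, rd_d, stack, reference_roi = nucleus)
        write_hotspot_table(hs, file.path(out, "hotspots.tsv"))
        add_file(file.path(out, "hotspots.tsv"), "hotspot table")
        ov <- hotspot_overlay(hs, render_hsi(enr_d, hsi_spec(par$hsi$lower,
                                                             par$hsi$upper)))
        png::writePNG(ov, file.path(out, "hotspot_overlay.png"))
        add_file(file.path(out, "hotspot_overlay.png"), "hotspot overlay")
      },
      pixel_correlation = function() {
        m <- nucleus$mask
        if (!is.null(excl)) m <- m & !excl
        fit <- pixel_regression(enr_d, enr_p, m, cell_id = "cell_1")
        tab <- data.frame(cell_id = fit$cell_id, slope = fit$slope,
                          intercept = fit$intercept, r_squared = fit$r_squared,
                          p_value = fit$p_value, n = fit$n)
        utils::write.table(tab, file.path(out, "pixel_correlation.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        add_file(file.path(out, "pixel_correlation.tsv"),
                 "non-nucleolar pixel regression")
      },
      top_percentile = function() {
        res <- top_percentile_subset(enr_d, nucleus, par$percentile,
                                     stack = stack, companion_rd = rd_p)
        js <- list(pct = par$percentile, cutoff = res$cutoff,
                   n_subset = res$n_subset, n_mask = res$n_mask,
                   companion_enrichment_pct = res$companion$enrichment,
                   companion_ratio_x1e4 = ratio_to_scaled(res$companion$ratio),
                   background_x1e4 = res$background_scaled)
        jsonlite::write_json(js, file.path(out, "top_percentile.json"),
                             auto_unbox = TRUE, digits = NA)
        add_file(file.path(out, "top_percentile.json"),
                 "top-percentile density subset")
      }))
  }
  manifest$files[["manifest.json"]] <- list(role = "run manifest")
  write_manifest()
  invisible(manifest)
}
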