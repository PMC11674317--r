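#' Pipeline configuration
#'
#' Bundles the per-stage configuration of an end-to-end run. The
#' defaults describe a small but complete experiment: a 150 µm cube at
#' full striatal density (about 270 neurons), three morphology variants
#' per type, hybrid PD construction for PD0/PD2, an 8-neuron kernel
#' (4 dSPN + 4 iSPN) and the desk-scale drive grid. The configuration
#' round-trips losslessly through JSON.
#'
#' @param cube_side cube side, µm.
#' @param density neurons per mm3.
#' @param morph_variants morphology draws per cell type.
#' @param stages PD stages to build (always includes PD0).
#' @param method PD build method name.
#' @param max_distance,voxel_size touch-detection parameters, µm.
#' @param kernel_composition named kernel type counts.
#' @param max_dim maximum clique dimension.
#' @param run_drive also run the input-drive protocol (slowest stage).
#' @param drive_scale protocol scale, `"desk"` or `"full"`.
#' @param seed global seed; stage seeds derive from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cube_side = 150, density = 80500,
                            morph_variants = 2L,
                            stages = c("PD0", "PD2"),
                            method = "hybrid", max_distance = 3,
                            voxel_size = 10,
                            kernel_composition = c(dSPN = 4L, iSPN = 4L),
                            max_dim = 13L, run_drive = FALSE,
                            drive_scale = "desk", seed = 1L) {
  stages <- union("PD0", stages)
  structure(list(cube_side = cube_side, density = density,
                 morph_variants = as.integer(morph_variants),
                 stages = stages, method = method,
                 max_distance = max_distance, voxel_size = voxel_size,
                 kernel_composition = kernel_composition,
                 max_dim = as.integer(max_dim),
                 run_drive = isTRUE(run_drive),
                 drive_scale = drive_scale, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read/write a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) / the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw),
                                              "kernel_composition")])
  cfg$kernel_composition <- unlist(raw$kernel_composition)
  cfg
}

#' Run the end-to-end pipeline
#'
#' Stages, in order: synthetic morphology library; neuron placement;
#' touch detection and pruning (PD0); stage morphologies (dendritic
#' degeneration, FS axonal growth) and PD network construction;
#' kernel/core selection and directed-clique counting per stage (full
#' and interneuron-ablated); optionally the input-drive protocol. Every
#' output is a CSV/TSV file listed in `manifest.json` together with the
#' configuration, the seeds and MD5 checksums, so a rerun with the same
#' configuration and seed reproduces identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return The manifest, invisibly (list with `files`, `md5`, `config`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, msg) {
    message(sprintf("[striatnet] %-12s %s", stage, msg))
  }
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, name)
    path
  }

  log_stage("morphology", "generating morphology library")
  morphs <- tryCatch(
    generate_morphology_library(
      cell_types = c("dSPN", "iSPN", "FS", "ChIN", "LTS"),
      n_each = config$morph_variants, seed = config$seed),
    error = function(e) stop("stage morphology failed: ",
                             conditionMessage(e)))
  emit(attr(morphs, "manifest"), "morphometry_PD0.csv")

  log_stage("placement", "placing neurons")
  pc <- placement_config(cube_side = config$cube_side,
                         density = config$density,
                         seed = config$seed + 1L,
                         morph_variants = config$morph_variants)
  placement <- place_neurons(pc)
  emit(placement$instances, "placement.csv")

  log_stage("network", "touch detection + pruning (PD0)")
  rules <- default_pruning_rules()
  putative <- touch_detect(placement, morphs,
                           max_distance = config$max_distance,
                           voxel_size = config$voxel_size)
  pd0 <- prune(putative, rules, seed = config$seed + 2L)
  write_synapse_table(pd0, file.path(out_dir, "synapses_PD0.tsv"))
  files <- c(files, "synapses_PD0.tsv")

  tables <- list(PD0 = pd0)
  for (stage in setdiff(config$stages, "PD0")) {
    log_stage("pd-build", paste(stage, "via", config$method))
    ms <- stage_morphologies(morphs, stage)
    tables[[stage]] <- build_pd_network(
      pd0, placement, ms, stage,
      method = pd_build_method(config$method), rules = rules,
      seed = config$seed + 3L, max_distance = config$max_distance,
      voxel_size = config$voxel_size)
    write_synapse_table(tables[[stage]],
                        file.path(out_dir,
                                  paste0("synapses_", stage, ".tsv")))
    files <- c(files, paste0("synapses_", stage, ".tsv"))
    mm <- morphometry_table(ms)
    mm$stage <- stage
    emit(mm, paste0("morphometry_", stage, ".csv"))
  }

  log_stage("topology", "directed clique counts")
  clique_rows <- list()
  for (stage in names(tables)) {
    tab <- tables[[stage]]
    g <- digraph_from_synapses(tab, instances = placement$instances)
    sel <- select_kernel_core(placement, g,
                              composition = config$kernel_composition)
    core_g <- induced_subgraph(g, sel$core)
    for (variant in c("full", "interneuron_ablated")) {
      gt <- if (variant == "full") core_g else {
        digraph_from_synapses(
          ablate_types(tab, c("FS", "ChIN", "LTS")),
          instances = placement$instances) |>
          induced_subgraph(sel$core)
      }
      cc <- count_directed_cliques(gt, kernel = sel$kernel,
                                   max_dim = config$max_dim)
      clique_rows[[paste(stage, variant)]] <- data.frame(
        stage = stage, variant = variant,
        dimension = as.integer(names(cc$counts)),
        count = as.numeric(cc$counts))
    }
  }
  emit(do.call(rbind, clique_rows), "clique_counts.csv")

  if (config$run_drive) {
    log_stage("drive", "input-drive protocol (dSPN)")
    m0 <- morphs[["dSPN_1"]]
    m2 <- degenerate(m0, "PD2")
    neuron <- surrogate_neuron("dSPN_PD0")
    n0 <- calibrate_input_count(neuron, m0, duration = 2,
                                seed = config$seed + 4L)
    drive <- run_drive_protocol("dSPN", m0, m2, n0,
                                grid = protocol_grid(config$drive_scale),
                                repeats = 2L, duration = 2,
                                seed = config$seed + 5L)
    emit(drive, "drive_rates.csv")
  }

  cfg_path <- file.path(out_dir, "config.json")
  write_pipeline_config(config, cfg_path)
  files <- c(files, "config.json")
  md5 <- tools::md5sum(file.path(out_dir, files))
  names(md5) <- files
  manifest <- list(files = files, md5 = as.list(md5),
                   seed = config$seed, config = unclass(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", paste(length(files), "artifacts in", out_dir))
  invisible(manifest)
}

#' Figures and tables from a pipeline run directory
#'
#' Renders the standard report: clique-count curves per stage (log
#' scale), the interneuron-ablation comparison, morphometry summaries
#' and, when present, the drive marginal curves. Every figure has a CSV
#' twin already emitted by [run_pipeline()]; missing stages are noted,
#' not errors.
#'
#' @param run_dir a [run_pipeline()] output directory.
#' @return Character vector of written figure paths (possibly empty),
#'   invisibly; attribute `"notes"` lists skipped items.
#' @export
report <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json"))) {
    stop("no manifest.json in ", run_dir, "; not a pipeline run directory")
  }
  written <- character(0)
  notes <- character(0)
  cc_path <- file.path(run_dir, "clique_counts.csv")
  if (file.exists(cc_path)) {
    cc <- utils::read.csv(cc_path)
    cc <- cc[cc$count > 0 & cc$dimension >= 1, ]
    if (nrow(cc)) {
      p <- ggplot2::ggplot(cc, ggplot2::aes(
        x = dimension, y = count, colour = stage, linetype = variant)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "clique dimension", y = "directed clique count",
                      title = "Directed cliques per stage") +
        ggplot2::theme_minimal()
      f <- file.path(run_dir, "clique_curves.pdf")
      ggplot2::ggsave(f, p, width = 6, height = 4)
      written <- c(written, f)
    } else {
      notes <- c(notes, "clique_counts.csv present but empty; plot skipped")
    }
  } else {
    notes <- c(notes, "no topology output found")
  }
  drive_path <- file.path(run_dir, "drive_rates.csv")
  if (file.exists(drive_path)) {
    dr <- utils::read.csv(drive_path)
    marg <- protocol_marginals(dr)
    p <- ggplot2::ggplot(marg$by_rate, ggplot2::aes(
      x = rate, y = output_rate, colour = scenario)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "input rate (Hz)", y = "output rate (Hz)",
                    title = "Drive marginals (over correlations)") +
      ggplot2::theme_minimal()
    f <- file.path(run_dir, "drive_marginals.pdf")
    ggplot2::ggsave(f, p, width = 6, height = 4)
    written <- c(written, f)
  } else {
    notes <- c(notes, "no drive output found")
  }
  if (length(notes)) message("report notes: ", paste(notes, collapse = "; "))
  attr(written, "notes") <- notes
  invisible(written)
}
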