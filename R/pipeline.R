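# Pipeline orchestration: run the 2D phagocytosis quantification, the 3D
# overlap quantification, or the statistics battery from a single
# configuration, writing auditable CSV outputs and a JSON run record.

#' Pipeline run configuration
#'
#' Bundles every tunable constant of the quantification with its default:
#' the analysis constants (percentile bounds 1/99, circularity minimum 0.7,
#' size window 5-20 um, DAPI inclusion ratio 0.5, marker positivity ratio
#' 0.5) plus plumbing (channel roles, connectivity, perimeter estimator,
#' seed). A config round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param channel_roles named list mapping roles (`cells`, `beads`,
#'   `nuclei`) to channel names for the 2D assay.
#' @param pixel_size_um optional pixel size override for images lacking
#'   metadata.
#' @param low_pct,high_pct normalization percentiles.
#' @param circ_min circularity threshold.
#' @param diam_range_um size window (equivalent diameter, um).
#' @param size_mode `"diameter"` or `"area"`.
#' @param connectivity_2d,connectivity_3d component connectivity.
#' @param perimeter perimeter estimator, `"chain"` or `"crack"`.
#' @param threshold_3d foreground threshold for 3D channels.
#' @param dapi_threshold,marker_threshold 3D inclusion / positivity ratios.
#' @param seed integer seed recorded with every run.
#' @return A validated list of class `RunConfig`.
#' @export
run_config <- function(channel_roles = list(cells = "tdTomato",
                                            beads = "beads",
                                            nuclei = "nuclei"),
                       pixel_size_um = NULL,
                       low_pct = 1, high_pct = 99,
                       circ_min = 0.7,
                       diam_range_um = c(5, 20),
                       size_mode = "diameter",
                       connectivity_2d = 8L,
                       connectivity_3d = 26L,
                       perimeter = "chain",
                       threshold_3d = 0.5,
                       dapi_threshold = 0.5,
                       marker_threshold = 0.5,
                       seed = 1L) {
  cfg <- list(channel_roles = channel_roles, pixel_size_um = pixel_size_um,
              low_pct = low_pct, high_pct = high_pct, circ_min = circ_min,
              diam_range_um = as.numeric(diam_range_um),
              size_mode = size_mode,
              connectivity_2d = as.integer(connectivity_2d),
              connectivity_3d = as.integer(connectivity_3d),
              perimeter = perimeter, threshold_3d = threshold_3d,
              dapi_threshold = dapi_threshold,
              marker_threshold = marker_threshold, seed = as.integer(seed))
  stopifnot(cfg$low_pct < cfg$high_pct, cfg$circ_min >= 0,
            length(cfg$diam_range_um) == 2,
            cfg$diam_range_um[1] < cfg$diam_range_um[2],
            cfg$size_mode %in% c("diameter", "area"),
            cfg$connectivity_2d %in% c(4L, 8L),
            cfg$connectivity_3d %in% c(6L, 26L),
            cfg$perimeter %in% c("chain", "crack"),
            cfg$threshold_3d >= 0, cfg$threshold_3d <= 1,
            cfg$dapi_threshold >= 0, cfg$dapi_threshold <= 1,
            cfg$marker_threshold >= 0, cfg$marker_threshold <= 1)
  structure(cfg, class = "RunConfig")
}

#' @rdname run_config
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "RunConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

stage_log <- function(run_dir, ...) {
  line <- sprintf(...)
  cat(line, "\n", sep = "", file = file.path(run_dir, "run.log"),
      append = TRUE)
  invisible(line)
}

write_run_record <- function(run_dir, config, extra = list()) {
  rec <- c(list(config = unclass(config),
                package_version = as.character(utils::packageVersion("phagoquant")),
                r_version = paste(R.version$major, R.version$minor, sep = ".")),
           extra)
  jsonlite::write_json(rec, file.path(run_dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the 2D phagocytosis quantification
#'
#' For every input image: maximum intensity projection (if 3D), per-channel
#' percentile normalization, 2-class K-means segmentation of the cell and
#' bead channels, connected-component labeling, morphometry, circularity
#' and size filtering, bead-intersection scoring, then per-animal
#' averaging. Writes `objects.csv` (all measured cells with filter flags),
#' `per_image.csv`, `per_animal.csv`, a structured `run.log` (counts in and
#' out of every filter per image) and `run_record.json`. Re-running with
#' identical inputs and config reproduces byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @param images named list of [image_stack()] objects, or a character
#'   vector of TIFF paths (names become image ids; basenames otherwise).
#' @param image_to_animal data frame with `image_id`, `animal_id`.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `objects`, `per_image`, `per_animal`.
#' @export
run_phagocytosis <- function(config, images, image_to_animal, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  if (length(images) == 0L) stop("no input images given")
  images <- resolve_images(images, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "run.log"))

  roles <- config$channel_roles
  all_cells <- list(); per_image <- list()
  for (id in names(images)) {
    res <- tryCatch({
      stk <- images[[id]]
      if (is_3d(stk)) stk <- max_intensity_projection(stk)
      stk <- percentile_normalize(stk, config$low_pct, config$high_pct)
      cell_mask <- kmeans2_mask(get_channel(stk, roles$cells))
      bead_mask <- kmeans2_mask(get_channel(stk, roles$beads))
      lm <- label_components(cell_mask, config$connectivity_2d,
                             pixel_size_um = stk$pixel_size_um)
      recs <- measure_regions(lm, perimeter = config$perimeter)
      recs <- apply_shape_filters(recs, config$circ_min,
                                  config$diam_range_um, config$size_mode)
      aud <- filter_audit(recs)
      stage_log(out_dir,
                "image=%s stage=segment n_objects=%d | stage=filter excluded_circularity=%d excluded_size=%d retained=%d",
                id, lm$n_objects, aud$n_excluded_circularity,
                aud$n_excluded_size, aud$n_retained)
      sc <- engulfment_fraction(recs, lm, bead_mask, image_id = id)
      stage_log(out_dir, "image=%s stage=score n_engulfing=%d percent=%.4f",
                id, sc$result$n_engulfing, sc$result$percent_engulfing)
      sc
    }, error = function(e) {
      stop(sprintf("image '%s': %s", id, conditionMessage(e)), call. = FALSE)
    })
    res$cells$image_id <- id
    all_cells[[id]] <- res$cells
    per_image[[id]] <- res$result
  }
  objects <- do.call(rbind, c(all_cells, list(make.row.names = FALSE)))
  per_image <- do.call(rbind, c(per_image, list(make.row.names = FALSE)))
  per_animal <- aggregate_per_animal(per_image, image_to_animal)

  write.csv(objects, file.path(out_dir, "objects.csv"), row.names = FALSE)
  write.csv(per_image, file.path(out_dir, "per_image.csv"), row.names = FALSE)
  write.csv(per_animal, file.path(out_dir, "per_animal.csv"),
            row.names = FALSE)
  write_run_record(out_dir, config,
                   list(n_images = length(images),
                        analysis = "phagocytosis_2d"))
  invisible(list(objects = objects, per_image = per_image,
                 per_animal = per_animal))
}

resolve_images <- function(images, config) {
  if (is.character(images)) {
    nms <- if (!is.null(names(images))) names(images) else
      sub("\\.[^.]*$", "", basename(images))
    images <- lapply(images, load_stack, pixel_size_um = config$pixel_size_um)
    names(images) <- nms
  }
  if (is.null(names(images)) || any(names(images) == ""))
    names(images) <- paste0("image", seq_along(images))
  if (!all(vapply(images, inherits, TRUE, "ImageStack")))
    stop("images must be ImageStack objects or TIFF paths")
  images
}

#' Run the 3D overlap quantification
#'
#' Thresholds the tdTomato channel into labeled 3D objects, thresholds
#' DAPI/Iba1/P2ry12 into marker masks, classifies every object (DAPI
#' inclusion, hierarchical Iba1/P2ry12 positivity), and writes the
#' per-object table (`objects3d.csv`), the positivity summary
#' (`summary3d.csv`) and a run record.
#'
#' @param config a [run_config()].
#' @param stacks named list of 3D [image_stack()]s with channels
#'   `tdTomato`, `DAPI`, `Iba1`, `P2ry12` (or TIFF paths).
#' @param out_dir output directory.
#' @return Invisibly, a list with `objects` (per-object, per-stack rows)
#'   and `summary` (per-stack percentages).
#' @export
run_overlap3d <- function(config, stacks, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  if (length(stacks) == 0L) stop("no input stacks given")
  stacks <- resolve_images(stacks, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "run.log"))
  all_obj <- list(); summaries <- list()
  for (id in names(stacks)) {
    res <- tryCatch({
      stk <- stacks[[id]]
      if (!is_3d(stk)) stop("3D stack required")
      objects <- segment_channel_3d(get_channel(stk, "tdTomato"),
                                    config$threshold_3d,
                                    config$connectivity_3d,
                                    voxel_size_um = stk$pixel_size_um)
      masks <- lapply(setNames(nm = c("DAPI", "Iba1", "P2ry12")),
                      function(ch) get_channel(stk, ch) >= config$threshold_3d)
      recs <- classify_objects_3d(objects, masks,
                                  voxel_size_um = stk$pixel_size_um,
                                  dapi_threshold = config$dapi_threshold,
                                  marker_threshold = config$marker_threshold)
      sm <- summarize_marker_positivity(recs)
      stage_log(out_dir,
                "stack=%s stage=classify n_objects=%d included=%d pct_iba1=%.4f pct_iba1_p2ry12=%.4f",
                id, nrow(recs), sm$n_included, sm$percent_iba1,
                sm$percent_iba1_p2ry12)
      list(recs = recs, sm = sm)
    }, error = function(e) {
      stop(sprintf("stack '%s': %s", id, conditionMessage(e)), call. = FALSE)
    })
    res$recs$stack_id <- id
    all_obj[[id]] <- res$recs
    summaries[[id]] <- data.frame(stack_id = id,
                                  n_included = res$sm$n_included,
                                  percent_iba1 = res$sm$percent_iba1,
                                  percent_iba1_p2ry12 = res$sm$percent_iba1_p2ry12)
  }
  objects <- do.call(rbind, c(all_obj, list(make.row.names = FALSE)))
  summary <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))
  write.csv(objects, file.path(out_dir, "objects3d.csv"), row.names = FALSE)
  write.csv(summary, file.path(out_dir, "summary3d.csv"), row.names = FALSE)
  write_run_record(out_dir, config, list(n_stacks = length(stacks),
                                         analysis = "overlap_3d"))
  invisible(list(objects = objects, summary = summary))
}

#' Run the statistics battery on a long-format table
#'
#' Reads (or accepts) a long table (`animal_id`, `group`, `level`,
#' `value`), optionally removes per-group ROUT outliers (per-group, before
#' testing), then applies the configured tests: per-level two-group
#' t-tests, and — when the design is complete — the two-way
#' repeated-measures ANOVA with Greenhouse-Geisser correction and Sidak
#' comparisons. Writes `stats_effects.csv` and `stats_comparisons.csv`.
#'
#' @param config a [run_config()].
#' @param table a data frame or CSV path with columns `animal_id`,
#'   `group`, `level`, `value`.
#' @param out_dir output directory.
#' @param rout_q ROUT Q in percent, or `NULL` (default) to skip outlier
#'   removal. Outlier removal drops whole animals from the RM ANOVA when
#'   any of their values is flagged (the design must stay complete).
#' @return Invisibly, a list with `effects`, `comparisons`,
#'   `outliers_removed`.
#' @export
run_stats <- function(config, table, out_dir, rout_q = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  if (is.character(table)) table <- read.csv(table)
  need <- c("animal_id", "group", "level", "value")
  if (!all(need %in% names(table)))
    stop(sprintf("malformed table: need columns %s",
                 paste(need, collapse = ", ")))
  if (!is.numeric(table$value)) stop("malformed table: value must be numeric")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  removed <- character(0)
  if (!is.null(rout_q)) {
    for (g in unique(table$group)) for (l in unique(table$level)) {
      idx <- which(table$group == g & table$level == l)
      if (length(idx) >= 3L) {
        fl <- rout_outliers(table$value[idx], Q = rout_q)$outliers
        removed <- union(removed, as.character(table$animal_id[idx[fl]]))
      }
    }
    table <- table[!(as.character(table$animal_id) %in% removed), ,
                   drop = FALSE]
  }

  fit <- rm_anova_two_way(table, value = "value", subject = "animal_id",
                          between = "group", within = "level")
  write.csv(fit$effects, file.path(out_dir, "stats_effects.csv"),
            row.names = FALSE)
  comps <- fit$comparisons
  if (is.null(comps))
    comps <- data.frame(level = character(0), mean_diff = numeric(0),
                        p_value = numeric(0), p_sidak = numeric(0))
  write.csv(comps, file.path(out_dir, "stats_comparisons.csv"),
            row.names = FALSE)
  write_run_record(out_dir, config,
                   list(analysis = "stats",
                        rout_q = if (is.null(rout_q)) NA else rout_q,
                        outliers_removed = removed))
  invisible(list(effects = fit$effects, comparisons = comps,
                 outliers_removed = removed, epsilon_gg = fit$epsilon_gg))
}
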