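#' Pipeline configuration
#'
#' Bundles all tunables with the published defaults: v1 = 0.7, v2 = 0.4,
#' delta_v = 0.1, alpha1 = 0.6, alpha2 = 0.4, gamma1 = 0.25, gamma2 = 1,
#' delta_gamma = 0.25, 64 intensity bins, 12 words, 8 px patches, C = 128.
#'
#' @param mser \code{mser_params()}
#' @param validation \code{validation_params()}
#' @param contrast \code{contrast_params()}
#' @param seed integer seed recorded with every run
#' @param verbose keep intermediate masks in the run record
#' @return list of class \code{rpl_config}
#' @export
pipeline_config <- function(mser = mser_params(),
                            validation = validation_params(),
                            contrast = contrast_params(),
                            seed = 1L, verbose = FALSE) {
  structure(list(mser = mser, validation = validation, contrast = contrast,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "rpl_config")
}

#' Serialize / parse a pipeline configuration
#' @param config \code{rpl_config}
#' @return JSON string
#' @export
serialize_config <- function(config) {
  jsonlite::toJSON(lapply(unclass(config), unclass), auto_unbox = TRUE,
                   digits = NA)
}

#' @rdname serialize_config
#' @param json JSON string from \code{serialize_config}
#' @export
parse_config <- function(json) {
  x <- jsonlite::fromJSON(json)
  pipeline_config(mser = do.call(mser_params, x$mser),
                  validation = do.call(validation_params, x$validation),
                  contrast = do.call(contrast_params, x$contrast),
                  seed = x$seed, verbose = x$verbose)
}

detections_to_mask <- function(regions, image, dims, seeds = NULL) {
  assemble_result(lapply(regions, `[[`, "pixels"), image, dims, seeds = seeds)
}

#' Localize cell nuclei in one image
#'
#' Runs the three stages end to end: contrast-enhanced salient region
#' detection, decluster processing, and CRF contour refinement, followed by
#' assembly and small-segment post-processing.
#'
#' @param image integer intensity matrix (grayscale)
#' @param models trained \code{rpl_models}
#' @param config \code{pipeline_config()}
#' @return list(mask = instance label matrix, record = run record with
#'   per-stage counts, Q values, gamma values and, if verbose, per-stage masks)
#' @export
localize <- function(image, models, config = pipeline_config()) {
  stopifnot(inherits(models, "rpl_models"))
  dims <- dim(image)
  record <- list(config = serialize_config(config), stages = list())
  s1 <- tryCatch(run_initial_segmentation(image, config$mser,
                                          merge_model = models$merge_model),
                 error = function(e) {
                   if (grepl("no interest regions", conditionMessage(e)))
                     NULL
                   else stop(e)
                 })
  if (is.null(s1)) {   # blank / structureless image: empty result, no error
    record$stages$initial <- list(n_regions = 0L)
    return(list(mask = matrix(0L, dims[1], dims[2]), record = record))
  }
  record$stages$initial <- list(n_regions = n_regions(s1$hierarchy),
                                region_counts = s1$region_counts,
                                used_max_variation = s1$used_max_variation)
  detected <- decluster_process(s1$image, s1$hierarchy, models,
                                config$validation,
                                min_candidate_area = config$mser$min_area)
  record$stages$decluster <-
    list(n_detected = length(detected),
         Q = vapply(detected, `[[`, numeric(1), "Q"),
         provenance = vapply(detected, `[[`, character(1), "provenance"))
  refined <- lapply(detected, function(d)
    refine_contour(d$pixels, s1$image, config$contrast))
  record$stages$refine <-
    list(gamma_G = vapply(refined, `[[`, numeric(1), "gamma_G"),
         energy = vapply(refined, `[[`, numeric(1), "energy"))
  mask <- detections_to_mask(refined, s1$image, dims,
                             seeds = lapply(detected, `[[`, "pixels"))
  if (config$verbose) {
    record$stage_masks <- list(
      s1 = stage1_mask(s1, dims),
      s2 = detections_to_mask(detected, s1$image, dims))
  }
  list(mask = mask, record = record)
}

# stage-1 instance mask: single- and upper-level regions are the detections
stage1_mask <- function(s1, dims) {
  lev <- region_levels(s1$hierarchy)
  regs <- s1$hierarchy$regions[lev %in% c("single", "upper")]
  detections_to_mask(lapply(regs, function(r) list(pixels = r$pixels)),
                     s1$image, dims)
}

#' Batch localization over a directory of images
#'
#' @param image_dir directory of .png/.tif images (files ending in
#'   \code{_truth.tif} are treated as ground truth for the matching stem)
#' @param models trained \code{rpl_models}
#' @param config \code{pipeline_config()}
#' @param out_dir optional directory for instance masks (16-bit TIFF)
#' @return list(per_image, summary); errors on unreadable files are logged
#'   and skipped, and the call fails only if every image fails
#' @export
run_batch <- function(image_dir, models, config = pipeline_config(),
                      out_dir = NULL) {
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                      full.names = TRUE)
  files <- files[!grepl("_truth\\.tiff?$", files)]
  if (length(files) == 0L) stop("no readable images in ", image_dir)
  per <- list(); failed <- 0L
  for (f in files) {
    res <- tryCatch({
      img <- read_image(f)
      loc <- localize(img, models, config)
      stem <- tools::file_path_sans_ext(basename(f))
      entry <- list(file = f, n_detected = max(loc$mask))
      tf <- file.path(dirname(f), paste0(stem, "_truth.tif"))
      if (file.exists(tf)) {
        met <- evaluate(loc$mask, read_image(tf))
        entry$metrics <- met
      }
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        write_image(loc$mask, file.path(out_dir, paste0(stem, "_mask.tif")),
                    bits = 16L)
      }
      entry
    }, error = function(e) {
      warning("skipping ", f, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- failed + 1L else per[[length(per) + 1L]] <- res
  }
  if (length(per) == 0L) stop("all ", failed, " images failed")
  summary <- NULL
  with_metrics <- Filter(function(e) !is.null(e$metrics), per)
  if (length(with_metrics) > 0) {
    agg <- function(field) mean(vapply(with_metrics,
                                       function(e) e$metrics[[field]],
                                       numeric(1)), na.rm = TRUE)
    summary <- list(R = agg("R"), P = agg("P"), A = agg("A"),
                    dice = agg("dice"), nsd = agg("nsd"), hd = agg("hd"),
                    n_images = length(with_metrics))
  }
  list(per_image = per, summary = summary)
}

#' Per-stage ablation on a fixture suite
#'
#' Evaluates the output after stage 1 only, stages 1-2, and the full
#' pipeline, mirroring the usual S-1/S-2/S-3 reporting.
#'
#' @param fixtures list of fixtures from \code{generate_suite}
#' @param models trained \code{rpl_models}
#' @param config \code{pipeline_config()}
#' @return list(per_stage = 3 aggregated metric lists, per_image)
#' @export
stage_ablation <- function(fixtures, models, config = pipeline_config()) {
  cfg <- config; cfg$verbose <- TRUE
  rows <- lapply(fixtures, function(fx) {
    loc <- localize(fx$image, models, cfg)
    list(s1 = evaluate(loc$record$stage_masks$s1, fx$truth),
         s2 = evaluate(loc$record$stage_masks$s2, fx$truth),
         s3 = evaluate(loc$mask, fx$truth))
  })
  agg_stage <- function(st) {
    g <- function(field) mean(vapply(rows, function(r) r[[st]][[field]],
                                     numeric(1)), na.rm = TRUE)
    list(R = g("R"), P = g("P"), A = g("A"),
         dice = g("dice"), nsd = g("nsd"), hd = g("hd"))
  }
  list(per_stage = list(s1 = agg_stage("s1"), s2 = agg_stage("s2"),
                        s3 = agg_stage("s3")),
       per_image = rows)
}
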