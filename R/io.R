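# NIfTI input/output, JSON configuration, and the end-to-end driver that
# reproduces the synthetic consensus-contour experiment.

#' Read a NIfTI volume
#'
#' Voxel sizes are stored in mm in the NIfTI header (the format's
#' convention) and converted to cm on read.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param mask logical; if `TRUE` return a `binary_mask` (nonzero voxels).
#' @return an `image_volume` or `binary_mask`.
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("read_volume: no such file: %s", path))
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop(sprintf("read_volume: cannot read '%s' as NIfTI: %s", path,
                 conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop(sprintf("read_volume: '%s' is not a 3-D volume", path))
  spacing_cm <- RNifti::pixdim(img)[1:3] / 10
  attributes(arr) <- list(dim = dim(arr))
  if (mask) binary_mask(arr != 0, spacing_cm)
  else image_volume(arr, spacing_cm)
}

#' Write a volume or mask as NIfTI
#'
#' @param vol an `image_volume` or `binary_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- if (inherits(vol, "binary_mask")) {
    a <- array(0L, vol_dims(vol))
    a[vol$data] <- 1L
    a
  } else {
    vol$data
  }
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing * 10
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Full experiment configuration
#'
#' @param phantom a [phantom_config()].
#' @param seg_params list of segmentation parameter overrides (see
#'   [run_all()]).
#' @param vote_threshold consensus vote threshold (default strict majority).
#' @param bin_width fixed SUV bin width for feature extraction.
#' @param designs reliability designs to run.
#' @param seed master seed: every random draw in the pipeline derives from
#'   it.
#' @param out_dir optional output directory for CSV/JSON (and NIfTI when
#'   `write_volumes`).
#' @param write_volumes write per-case NIfTI volumes (image, GT, masks).
#' @return a `run_config` list.
#' @export
run_config <- function(phantom = phantom_config(), seg_params = list(),
                       vote_threshold = NULL, bin_width = 0.25,
                       designs = c("between_masks", "among_methods",
                                   "vs_ground_truth"),
                       seed = 42L, out_dir = NULL, write_volumes = FALSE) {
  structure(list(phantom = phantom, seg_params = seg_params,
                 vote_threshold = vote_threshold, bin_width = bin_width,
                 designs = designs, seed = as.integer(seed),
                 out_dir = out_dir, write_volumes = isTRUE(write_volumes)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return `read_config` returns a `run_config`; `write_config` the path.
#' @export
write_config <- function(cfg, path) {
  plain <- unclass(cfg)
  plain$phantom <- unclass(plain$phantom)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph <- do.call(phantom_config, j$phantom[setdiff(names(j$phantom), NULL)])
  run_config(phantom = ph,
             seg_params = if (is.null(j$seg_params)) list() else j$seg_params,
             vote_threshold = j$vote_threshold, bin_width = j$bin_width,
             designs = j$designs, seed = j$seed, out_dir = j$out_dir,
             write_volumes = isTRUE(j$write_volumes))
}

# one row of the feature table
feature_row <- function(case_id, method, mask_style, fv) {
  row <- as.data.frame(as.list(unclass(fv)))
  colnames(row) <- names(fv)
  cbind(data.frame(case = case_id, method = method, mask_style = mask_style,
                   stringsAsFactors = FALSE), row)
}

#' Run the full synthetic consensus-contour experiment
#'
#' Generates the phantom suite, segments every case with the four individual
#' methods and the consensus contour under both initial-mask styles,
#' extracts the 107-feature vector for every segmentation and for the
#' ground truth, computes per-feature ICC tables for the requested designs,
#' category summaries, the stable-feature set, and Spearman correlation
#' matrices for the consensus contour under both mask styles. Everything is
#' a deterministic function of the configuration and its master seed.
#'
#' @param cfg a [run_config()].
#' @return list with elements `suite`, `features`, `contours`, `icc`,
#'   `summaries`, `stable`, `correlations`, `failures`, `config`.
#' @export
run_experiment <- function(cfg = run_config()) {
  n <- cfg$phantom$n_cases
  seeds <- derive_seeds(cfg$seed, 1L + 2L * n)
  suite <- generate_suite(cfg$phantom, seed = seeds[1])
  ext <- extraction_config(bin_width = cfg$bin_width)

  rows <- list()
  contours <- list()
  failures <- list()
  styles <- c(rectangular = "rect_mask", irregular = "irreg_mask")
  for (i in seq_len(n)) {
    case <- suite$cases[[i]]
    img <- case$image
    for (si in seq_along(styles)) {
      style <- names(styles)[si]
      init <- case[[styles[[si]]]]
      ap_seed <- seeds[1L + (si - 1L) * n + i]
      res <- run_all(img, init, cfg$seg_params, seed = ap_seed)
      if (length(attr(res, "failures")))
        failures[[paste(i, style)]] <- attr(res, "failures")
      cs <- conseg(img, init, vote_threshold = cfg$vote_threshold,
                   results = res)
      all_res <- c(res, list(ConSeg = cs))
      for (m in names(all_res)) {
        sm <- all_res[[m]]$mask
        fv <- extract_all(img, sm, ext)
        rows[[length(rows) + 1]] <- feature_row(i, m, style, fv)
        contours[[length(contours) + 1]] <- data.frame(
          case = i, method = m, mask_style = style,
          volume_cm3 = sum(sm$data) * voxel_volume(sm),
          suvmax = max(img$data[sm$data]))
      }
    }
    fv <- extract_all(img, case$gt_mask, ext)
    rows[[length(rows) + 1]] <- feature_row(i, "GT", "none", fv)
    contours[[length(contours) + 1]] <- data.frame(
      case = i, method = "GT", mask_style = "none",
      volume_cm3 = gt_volume(case),
      suvmax = max(img$data[case$gt_mask$data]))
  }
  features <- do.call(rbind, rows)
  contours <- do.call(rbind, contours)

  icc <- list()
  summaries <- list()
  for (d in cfg$designs) {
    tab <- run_design(features, design_spec(d))
    icc[[d]] <- tab
    summaries[[d]] <- summarize_icc(tab)
  }
  stable <- summarize_icc(do.call(rbind, icc))

  correlations <- NULL
  if (n >= 3L) {  # Spearman needs at least 3 subjects
    cons_rect <- spearman_matrix(features, method = "ConSeg",
                                 mask_style = "rectangular")
    cons_irreg <- spearman_matrix(features, method = "ConSeg",
                                  mask_style = "irregular")
    correlations <- list(
      conseg_rectangular = cons_rect,
      conseg_irregular = cons_irreg,
      reference_order = reference_order(cons_irreg),
      similarity_rect_irreg = compare_matrices(cons_rect, cons_irreg))
  }

  out <- list(suite = suite, features = features, contours = contours,
              icc = icc, summaries = summaries, stable = stable,
              correlations = correlations, failures = failures,
              config = cfg)
  if (!is.null(cfg$out_dir)) write_experiment(out, cfg$out_dir)
  out
}

# persist the report bundle as CSV/JSON (and optionally NIfTI volumes)
write_experiment <- function(exp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(exp$features, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(exp$contours, file.path(out_dir, "contours.csv"),
                   row.names = FALSE)
  for (d in names(exp$icc))
    utils::write.csv(exp$icc[[d]], file.path(out_dir, paste0("icc_", d,
                                                             ".csv")),
                     row.names = FALSE)
  summaries <- lapply(exp$summaries, function(s)
    list(category_counts = as.data.frame(s$category_counts),
         median_icc = as.list(s$median_icc),
         negative_fraction = as.list(s$negative_fraction),
         n_stable = s$n_stable, pct_stable = s$pct_stable))
  jsonlite::write_json(
    list(summaries = summaries,
         stable_features = exp$stable$stable_features,
         excellent_features = exp$stable$excellent_features,
         n_stable = exp$stable$n_stable,
         pct_stable = exp$stable$pct_stable,
         similarity_rect_irreg =
           if (is.null(exp$correlations)) NA
           else exp$correlations$similarity_rect_irreg,
         seed = exp$config$seed),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_config(exp$config, file.path(out_dir, "config.json"))
  if (isTRUE(exp$config$write_volumes)) {
    for (i in seq_along(exp$suite$cases)) {
      case <- exp$suite$cases[[i]]
      pre <- file.path(out_dir, sprintf("case%02d", i))
      write_volume(case$image, paste0(pre, "_image.nii.gz"))
      write_volume(case$gt_mask, paste0(pre, "_gt.nii.gz"))
      write_volume(case$rect_mask, paste0(pre, "_rect.nii.gz"))
      write_volume(case$irreg_mask, paste0(pre, "_irreg.nii.gz"))
    }
  }
  invisible(out_dir)
}
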