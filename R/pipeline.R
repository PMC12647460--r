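#' Batch measurement and evaluation orchestration
#'
#' Thin orchestration over the measurement and evaluation layers: resolve
#' each image's annotation (label-map PNG or LabelMe JSON) or run a baseline
#' segmenter, measure the 64-trait record per image, and write tables and
#' metric reports. Batch mode over a set of images equals the concatenation
#' of single-image runs; all randomness flows from one seed.
#'
#' @name pipeline
NULL

# Resolve the annotation path for one image: explicit vector entry, or a
# sibling file named <stem>_label.png / <stem>.json.
resolve_annotation <- function(image_path, annotation = NULL) {
  if (!is.null(annotation) && !is.na(annotation)) return(annotation)
  stem <- sub("\\.[^.]+$", "", image_path)
  for (cand in c(paste0(stem, "_label.png"), paste0(stem, ".json"))) {
    if (file.exists(cand)) return(cand)
  }
  NA_character_
}

read_annotation_map <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rasterize_polygons(read_labelme(path))
  } else {
    read_label_map(path)
  }
}

#' Measure trait tables for a batch of images
#'
#' @param image_paths character vector of image files (PNG/JPEG).
#' @param annotation_paths optional character vector (same length) of label
#'   maps (PNG) or LabelMe JSON files; `NA` entries are resolved from sibling
#'   files `<stem>_label.png` / `<stem>.json`.
#' @param organ `"leaf"` or `"silique"`.
#' @param baseline `"none"` (annotations required), `"otsu"` or `"kmeans"`.
#' @param output_dir if non-`NULL`, the trait table (and log) are written
#'   there as `traits.csv`/`traits.xlsx` and `measure_log.csv`.
#' @param format `"csv"` or `"xlsx"`.
#' @param iou_threshold unused here (kept so one config can drive both
#'   [run_measure()] and [run_evaluate()]).
#' @param seed seed for baseline segmentation.
#' @param verbose log one line per image to stderr.
#' @return list with `traits` (tibble, one row per measured image), `log`
#'   (tibble `image_id`, `status`, `n_instances`, `message`), and `n_failed`.
#'   A non-empty `n_failed` maps to a nonzero exit code in the CLI.
#' @export
run_measure <- function(image_paths, annotation_paths = NULL,
                        organ = c("leaf", "silique"),
                        baseline = c("none", "otsu", "kmeans"),
                        output_dir = NULL, format = c("csv", "xlsx"),
                        iou_threshold = 0.5, seed = 1L, verbose = FALSE) {
  organ <- match.arg(organ)
  baseline <- match.arg(baseline)
  format <- match.arg(format)
  if (!is.null(annotation_paths) && length(annotation_paths) != length(image_paths)) {
    stop_organtraits("annotation_paths must match image_paths in length")
  }
  rows <- list()
  logs <- list()
  for (i in seq_along(image_paths)) {
    ip <- image_paths[i]
    id <- sub("\\.[^.]+$", "", basename(ip))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      {
        img <- read_image(ip)
        map <- if (baseline == "none") {
          ap <- resolve_annotation(ip, annotation_paths[i] %||% NULL)
          if (is.na(ap)) stop_organtraits("no annotation found for ", ip)
          read_annotation_map(ap)
        } else {
          segment_baseline(img, method = baseline, seed = seed + i)
        }
        assert_same_dim(img, map)
        list(row = measure_traits(img, map, image_id = id, organ = organ))
      },
      error = function(e) list(error = conditionMessage(e))
    )
    el <- proc.time()[["elapsed"]] - t0
    if (is.null(res$error)) {
      rows[[length(rows) + 1L]] <- res$row
      n_inst <- res$row[["Total Leaf Number"]]
      logs[[i]] <- tibble::tibble(
        image_id = id, status = "ok", n_instances = n_inst,
        elapsed_s = round(el, 3), message = ""
      )
      if (verbose) message(sprintf("[measure] %s: %d instances (%.2fs)", id, n_inst, el))
    } else {
      logs[[i]] <- tibble::tibble(
        image_id = id, status = "failed", n_instances = NA_real_,
        elapsed_s = round(el, 3), message = res$error
      )
      if (verbose) message(sprintf("[measure] %s: FAILED (%s)", id, res$error))
    }
  }
  traits <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    measure_traits(array(0, c(1, 1, 3)), matrix(0L, 1, 1), organ = organ)[0, ]
  log <- dplyr::bind_rows(logs)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(
      traits,
      file.path(output_dir, paste0("traits.", format)),
      format = format
    )
    readr::write_csv(log, file.path(output_dir, "measure_log.csv"))
  }
  list(traits = traits, log = log, n_failed = sum(log$status == "failed"))
}

#' Evaluate predicted annotations against ground truth for a batch
#'
#' Computes per-image TP/FP/FN, precision, recall, F1 and DiC, plus the batch
#' means. Paths may be label-map PNGs or LabelMe JSON files.
#'
#' @param pred_paths,truth_paths equal-length character vectors of
#'   annotation files (every image must be paired).
#' @param iou_threshold IoU matching threshold (default 0.5).
#' @param image_ids optional identifiers (default: truth file stems).
#' @return list with `per_image` (tibble of per-image metrics) and `summary`
#'   (one-row tibble of batch means: `precision`, `recall`, `f1`, `mean_dic`).
#' @export
run_evaluate <- function(pred_paths, truth_paths, iou_threshold = 0.5,
                         image_ids = NULL) {
  if (length(pred_paths) != length(truth_paths)) {
    stop_organtraits(
      "unpaired inputs: ", length(pred_paths), " predictions vs ",
      length(truth_paths), " truths"
    )
  }
  ids <- image_ids %||% sub("\\.[^.]+$", "", basename(truth_paths))
  per <- lapply(seq_along(pred_paths), function(i) {
    pred <- read_annotation_map(pred_paths[i])
    truth <- read_annotation_map(truth_paths[i])
    m <- match_instances(pred, truth, iou_threshold)
    prf <- suppressWarnings(precision_recall_f1(m))
    tibble::tibble(
      image_id = ids[i],
      TP = m$TP, FP = m$FP, FN = m$FN,
      precision = prf[["precision"]], recall = prf[["recall"]], f1 = prf[["f1"]],
      n_pred = m$n_pred, n_truth = m$n_truth,
      dic = dic(m$n_pred, m$n_truth)
    )
  })
  per <- dplyr::bind_rows(per)
  # batch P/R/F1 from pooled counts; DiC as the mean of per-image values
  pooled <- precision_recall_f1(list(TP = sum(per$TP), FP = sum(per$FP), FN = sum(per$FN)))
  list(
    per_image = per,
    summary = tibble::tibble(
      precision = pooled[["precision"]],
      recall = pooled[["recall"]],
      f1 = pooled[["f1"]],
      mean_dic = mean(per$dic)
    )
  )
}

#' Per-trait agreement between an automated and a manual trait table
#'
#' Joins two trait tables on `image_id` and, for every shared numeric trait
#' column, computes MAPE (where defined) and the R-squared of the
#' manual-on-automated regression.
#'
#' @param auto,manual trait tibbles (or CSV paths) sharing `image_id`.
#' @return tibble with `trait`, `n`, `mape_percent`, `r_squared`.
#' @export
evaluate_trait_agreement <- function(auto, manual) {
  if (is.character(auto)) auto <- read_trait_table(auto)
  if (is.character(manual)) manual <- read_trait_table(manual)
  common <- intersect(intersect(names(auto), names(manual)), trait_catalog())
  j <- dplyr::inner_join(auto, manual, by = "image_id", suffix = c("_a", "_m"))
  rows <- lapply(common, function(tr) {
    xa <- j[[paste0(tr, "_a")]]
    xm <- j[[paste0(tr, "_m")]]
    ok <- is.finite(xa) & is.finite(xm)
    xa <- xa[ok]; xm <- xm[ok]
    mp <- if (length(xa) >= 1L && all(xm != 0)) mape(xa, xm) else NA_real_
    r2 <- if (length(xa) >= 2L && stats::var(xa) > 0) {
      trait_agreement(xa, xm)$r_squared
    } else NA_real_
    tibble::tibble(trait = tr, n = length(xa), mape_percent = mp, r_squared = r2)
  })
  dplyr::bind_rows(rows)
}

#' Materialize paired fixture files for a set of synthetic scenes
#'
#' Writes, per scene, an image PNG, a label-map PNG (`*_label.png`) and a
#' per-organ ground-truth CSV (`*_truth.csv`), and a `manifest.csv`.
#'
#' @param dir output directory (created if needed).
#' @param n_scenes number of scenes.
#' @param organ `"leaf"` or `"silique"`.
#' @param seed base seed; scene `i` uses `seed + i - 1`.
#' @param ... further arguments to [scene_spec()].
#' @return tibble manifest: `scene`, `image`, `label_map`, `truth`,
#'   `n_organs`.
#' @export
make_fixtures <- function(dir, n_scenes = 3L, organ = c("leaf", "silique"),
                          seed = 1L, ...) {
  organ <- match.arg(organ)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(n_scenes), function(i) {
    sc <- generate_scene(scene_spec(organ = organ, seed = seed + i - 1L, ...))
    stem <- file.path(dir, sprintf("%s_scene_%03d", organ, i))
    write_image(sc$image, paste0(stem, ".png"))
    write_label_map(sc$truth$map, paste0(stem, "_label.png"))
    readr::write_csv(sc$truth$organs, paste0(stem, "_truth.csv"))
    tibble::tibble(
      scene = i,
      image = paste0(stem, ".png"),
      label_map = paste0(stem, "_label.png"),
      truth = paste0(stem, "_truth.csv"),
      n_organs = nrow(sc$truth$organs)
    )
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  manifest
}
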