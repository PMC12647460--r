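#' The 64-trait catalog
#'
#' Fixed, versioned column order of the per-image trait table: 35
#' morphological traits, then 7 color traits, then 22 texture traits
#' (7 Hu moments + 15 GGCM features). The same catalog applies to both organ
#' classes, so a leaf study and a silique study emit 64 traits each (128
#' across both classes). All lengths/areas are pixel units.
#'
#' @return character vector of 64 trait names.
#' @export
trait_catalog <- function() {
  c(
    morph_trait_names(),
    c(
      "R_Ratio_mean", "STD_R_mean", "G_Ratio_mean", "STD_G_mean",
      "B_Ratio_mean", "STD_B_mean", "G_All_mean"
    ),
    paste0("Hu_moment", 1:7),
    ggcm_feature_names()
  )
}

#' Measure all 64 traits of one image
#'
#' Assembles the morphological, color and texture trait sets of a single
#' image into a one-row tibble. Undefined traits (e.g. averages of an empty
#' scene) are `NA`, never 0, so downstream aggregation is not silently
#' biased.
#'
#' @param image `H x W x 3` RGB array in `[0, 255]`.
#' @param map integer instance label matrix of matching size.
#' @param image_id identifier written into the `image_id` column.
#' @param organ organ class label (`"leaf"` or `"silique"`); recorded in the
#'   `organ` column and used to guard against mixing classes in one table.
#' @return tibble with columns `image_id`, `organ`, then the 64 catalog
#'   traits in [trait_catalog()] order.
#' @export
measure_traits <- function(image, map, image_id = "image", organ = "leaf") {
  assert_same_dim(image, map)
  rec <- instance_records(map)
  vals <- c(
    aggregate_morphology(rec),
    color_traits(image, map),
    texture_traits(image, map)
  )
  stopifnot(identical(names(vals), trait_catalog()))
  out <- tibble::as_tibble(as.list(vals))
  dplyr::bind_cols(
    tibble::tibble(image_id = as.character(image_id), organ = organ),
    out
  )
}

#' Write a trait table to CSV or XLSX
#'
#' One row per image, columns `image_id`, `organ`, then the 64 traits in
#' catalog order. All rows must share one organ class. CSV (RFC 4180) is the
#' canonical format — undefined traits are written as empty cells and values
#' round-trip to at least 6 significant digits; XLSX is a formatting layer
#' over the same table (written via the system Python's openpyxl).
#'
#' @param records trait tibble from [measure_traits()] (rows may be bound
#'   with [dplyr::bind_rows()]); an empty tibble yields a header-only file.
#' @param path output file path.
#' @param format `"csv"` or `"xlsx"` (default from the file extension).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.xlsx$", path, ignore.case = TRUE)) "xlsx" else "csv")
  format <- match.arg(format, c("csv", "xlsx"))
  if (nrow(records) > 0L && length(unique(records$organ)) > 1L) {
    stop_organtraits(
      "trait table mixes organ classes: ",
      paste(unique(records$organ), collapse = ", ")
    )
  }
  missing_cols <- setdiff(trait_catalog(), names(records))
  if (length(missing_cols) > 0L) {
    stop_organtraits(
      "records lack ", length(missing_cols), " catalog columns (first: ",
      missing_cols[1], ")"
    )
  }
  if (format == "csv") {
    readr::write_csv(records, path, na = "")
  } else {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(tmp), add = TRUE)
    readr::write_csv(records, tmp, na = "")
    csv_to_xlsx(tmp, path)
  }
  invisible(path)
}

# Convert a CSV file to XLSX using the system Python's openpyxl (no R xlsx
# writer is part of this package's dependency set).
csv_to_xlsx <- function(csv_path, xlsx_path) {
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") stop_organtraits("no python interpreter found for xlsx export")
  script <- paste(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); ws = wb.active",
    "with open(sys.argv[1], newline='') as f:",
    "    for i, row in enumerate(csv.reader(f)):",
    "        ws.append([c if i == 0 or c == '' else _num(c) for c in row])",
    "wb.save(sys.argv[2])",
    sep = "\n"
  )
  helper <- paste(
    "def _num(c):",
    "    try:",
    "        return float(c)",
    "    except ValueError:",
    "        return c",
    sep = "\n"
  )
  code <- paste(helper, script, sep = "\n")
  status <- system2(python, c("-c", shQuote(code), shQuote(csv_path), shQuote(xlsx_path)))
  if (status != 0L) stop_organtraits("xlsx conversion failed (openpyxl)")
  invisible(xlsx_path)
}

#' Read a trait table written by [write_trait_table()]
#' @param path CSV path.
#' @return tibble; empty cells become `NA`.
#' @export
read_trait_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"))
}
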