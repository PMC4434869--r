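# Required columns per table schema; used by read_table_csv validation.
table_schemas <- list(
  bead_series = c("pmt_voltage", "nominal_level", "replicate", "measured"),
  cell_record = c("sample_id", "cell_id", "area",
                  "ctcf_keratin", "ctcf_vimentin", "ctcf_cd45", "ctcf_dapi",
                  "mean_intensity_keratin", "mean_intensity_vimentin",
                  "mean_intensity_cd45", "mean_intensity_dapi",
                  "is_dapi_positive", "is_cd45_negative", "is_ctc"),
  ratio_record = c("cell_id", "numerator_marker", "denominator_marker",
                   "ratio", "ratio_defined"),
  patient_record = c("patient_id", "er_status", "pr_status", "her2_status",
                     "triple_negative", "os_months", "os_event"),
  ctc_keratin = c("patient_id", "keratin")
)

#' Write a table as CSV with provenance metadata
#'
#' Writes comma-separated UTF-8 CSV ('.' decimal). Provenance (seed, config
#' hash, package version, plus any extra fields) is written as
#' \code{# key: value} comment lines above the header so the file remains a
#' plain CSV for any reader that skips comments.
#'
#' @param x Data frame to write.
#' @param path Output file path.
#' @param meta Named list of metadata values (e.g. \code{seed}); a
#'   \code{config} element is hashed rather than serialized.
#' @return \code{path}, invisibly.
#' @export
write_table_csv <- function(x, path, meta = list()) {
  if (!is.null(meta$config)) {
    meta$config_hash <- digest::digest(meta$config)
    meta$config <- NULL
  }
  meta$package_version <- as.character(utils::packageVersion("ctcEMT"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = ",")), con)
  }
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table and validate its schema
#'
#' Reads a comma-separated file written by \code{\link{write_table_csv}}
#' (\code{#}-comment metadata lines are skipped) and checks that all
#' required columns of the named schema are present, erroring with the
#' missing column names otherwise.
#'
#' @param path File path.
#' @param schema One of \code{"bead_series"}, \code{"cell_record"},
#'   \code{"ratio_record"}, \code{"patient_record"}, \code{"ctc_keratin"},
#'   or \code{NULL} to skip validation.
#' @return Data frame.
#' @export
read_table_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    required <- table_schemas[[match.arg(schema, names(table_schemas))]]
    missing <- setdiff(required, names(x))
    if (length(missing) > 0) {
      stop(sprintf("file '%s' does not match schema '%s'; missing columns: %s",
                   path, schema, paste(missing, collapse = ", ")))
    }
  }
  x
}

#' Write a multi-channel image as multi-page TIFF with sidecar metadata
#'
#' One 16-bit grayscale page per channel, in the channel order of the
#' array; the channel order, bit depth, seed and config hash go to a JSON
#' sidecar at \code{<path>.meta.json} so the pages can be re-identified.
#'
#' @param image Numeric array rows x cols x channels (channel names in
#'   \code{dimnames}); values are clamped to [0, 2^bit_depth - 1].
#' @param path Output TIFF path.
#' @param bit_depth Bits per sample (default 16).
#' @param meta Extra metadata stored in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_cytospin_tiff <- function(image, path, bit_depth = 16L, meta = list()) {
  stopifnot(length(dim(image)) == 3L)
  channels <- dimnames(image)[[3]] %||% paste0("channel", seq_len(dim(image)[3]))
  maxval <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(image)[3]), function(k) {
    m <- image[, , k]
    m[m < 0] <- 0; m[m > maxval] <- maxval
    m / maxval  # tiff package expects [0,1]
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  side <- c(list(channels = channels, bit_depth = bit_depth,
                 shape = dim(image)[1:2]), meta)
  if (!is.null(side$config)) {
    side$config_hash <- digest::digest(side$config)
    side$config <- NULL
  }
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF written by \code{write_cytospin_tiff}
#'
#' Restores the rows x cols x channels array with channel names from the
#' JSON sidecar and intensities rescaled back to counts.
#'
#' @param path TIFF path; \code{<path>.meta.json} must exist alongside.
#' @return Numeric array with channel dimnames.
#' @export
read_cytospin_tiff <- function(path) {
  side_path <- paste0(path, ".meta.json")
  if (!file.exists(side_path)) {
    stop("sidecar metadata not found: ", side_path)
  }
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maxval <- 2^side$bit_depth - 1
  img <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)),
               dimnames = list(NULL, NULL, side$channels))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    img[, , k] <- p * maxval
  }
  img
}
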