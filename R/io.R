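# Volume and table I/O.
#
# Volumes travel as NRRD (self-contained header + raw little-endian data,
# written here directly since the format is a simple key-value header) or as
# NIfTI-1 via RNifti. Spacing and origin survive both round trips.

nrrd_type_map <- c("unsigned char" = "uint8", "uchar" = "uint8",
                   "uint8" = "uint8", "uint8_t" = "uint8",
                   "short" = "int16", "int16" = "int16", "int16_t" = "int16",
                   "int" = "int32", "int32" = "int32", "int32_t" = "int32",
                   "float" = "float", "double" = "double")

write_nrrd <- function(volume, path, type = "double") {
  g <- volume$grid
  v <- volume$voxels
  stopifnot(type %in% c("double", "float", "uint8", "int16", "int32"))
  size <- switch(type, double = 8L, float = 4L, uint8 = 1L, int16 = 2L,
                 int32 = 4L)
  header <- c(
    "NRRD0004",
    sprintf("type: %s", type),
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %s", paste(g$shape, collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            g$spacing[1], g$spacing[2], g$spacing[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            g$origin[1], g$origin[2], g$origin[3]),
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  what <- if (type %in% c("double", "float")) as.numeric(v) else as.integer(v)
  writeBin(what, con, size = size, endian = "little",
           useBytes = TRUE)
  invisible(path)
}

parse_nrrd_vectors <- function(s) {
  m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
  vals <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
  lapply(vals, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header")
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  type <- nrrd_type_map[[trimws(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  sizes <- as.integer(strsplit(trimws(fields[["sizes"]]), " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported")
  enc <- trimws(fields[["encoding"]])
  if (!enc %in% c("raw")) stop("unsupported NRRD encoding: ", enc)
  endian <- if (!is.null(fields[["endian"]])) trimws(fields[["endian"]])
            else "little"
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_nrrd_vectors(fields[["space directions"]])
    spacing <- vapply(seq_len(3L), function(i) sqrt(sum(dirs[[i]]^2)),
                      numeric(1L))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(trimws(fields[["spacings"]]), " +")[[1]])
  } else stop("NRRD header carries no spacing information")
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- parse_nrrd_vectors(fields[["space origin"]])[[1]]
  n <- prod(sizes)
  v <- switch(type,
    double = readBin(con, "numeric", n, size = 8L, endian = endian),
    float = readBin(con, "numeric", n, size = 4L, endian = endian),
    uint8 = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE,
                               endian = endian)),
    int16 = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    int32 = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)))
  if (length(v) != n) stop("truncated NRRD data block")
  image_volume(array(v, sizes), grid_spec(sizes, spacing, origin))
}

#' Read / write an image volume
#'
#' Dispatches on the file extension: `.nrrd` (self-contained, raw encoding)
#' or `.nii` / `.nii.gz` (NIfTI-1 via RNifti). Voxels, spacing and origin
#' survive a round trip; NIfTI stores the geometry in the sform.
#'
#' @param path file path with a supported extension.
#' @return [read_volume()] returns an [image_volume].
#' @export
read_volume <- function(path) {
  ext <- volume_format(path)
  if (ext == "nrrd") return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- vapply(1:3, function(i) sqrt(sum(aff[1:3, i]^2)), numeric(1L))
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               grid_spec(dim(img)[1:3], spacing, aff[1:3, 4]))
}

#' @param volume an [image_volume].
#' @param type storage type for NRRD: "double", "float", "uint8", "int16" or
#'   "int32" (masks are typically written as "uint8").
#' @rdname read_volume
#' @export
write_volume <- function(volume, path, type = "double") {
  stopifnot(inherits(volume, "image_volume"))
  ext <- volume_format(path)
  if (ext == "nrrd") return(write_nrrd(volume, path, type))
  g <- volume$grid
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- g$spacing
  aff <- structure(rbind(cbind(diag(g$spacing), g$origin), c(0, 0, 0, 1)),
                   code = 2L)
  RNifti::sform(img) <- aff
  RNifti::qform(img) <- aff
  RNifti::writeNifti(img, path,
                     datatype = if (type == "uint8") "uint8" else "double")
  invisible(path)
}

volume_format <- function(path) {
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  stop(errorCondition(
    sprintf("unsupported volume format: '%s' (use .nrrd, .nii or .nii.gz)",
            basename(path)),
    class = c("igrt_format_error", "error", "condition")))
}

shift_table_columns <- c("patient_id", "fraction", "kind",
                         "lr_mm", "si_mm", "ap_mm")

#' Write shift series to a CSV table
#'
#' Long-per-fraction, wide-per-axis schema with header
#' `patient_id, fraction, kind, lr_mm, si_mm, ap_mm`.
#'
#' @param series_list list of [shift_series].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_shift_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(patient_id = s$patient_id,
               fraction = seq_len(nrow(s$shifts)), kind = s$kind,
               lr_mm = s$shifts[, 1], si_mm = s$shifts[, 2],
               ap_mm = s$shifts[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a shift table CSV into shift series
#'
#' Validates the schema and the values: all six columns must be present,
#' `kind` must be "inter" or "intra", and every shift must be numeric
#' (violations report the offending line).
#'
#' @param path CSV path.
#' @return list of [shift_series], one per (patient, kind), ordered by
#'   fraction.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(shift_table_columns, names(df))
  if (length(missing) > 0L)
    stop(errorCondition(
      sprintf("shift table is missing column(s): %s",
              paste(missing, collapse = ", ")),
      class = c("igrt_schema_error", "error", "condition"),
      columns = missing))
  bad_kind <- which(!df$kind %in% c("inter", "intra"))
  if (length(bad_kind) > 0L)
    stop(errorCondition(
      sprintf("unknown shift kind '%s' at line %d", df$kind[bad_kind[1]],
              bad_kind[1] + 1L),
      class = c("igrt_schema_error", "error", "condition")))
  for (col in c("fraction", "lr_mm", "si_mm", "ap_mm")) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]))
    if (length(bad) > 0L)
      stop(errorCondition(
        sprintf("non-numeric value '%s' in column %s at line %d",
                df[[col]][bad[1]], col, bad[1] + 1L),
        class = c("igrt_schema_error", "error", "condition"), line = bad[1] + 1L))
    df[[col]] <- x
  }
  out <- list()
  for (key in unique(paste(df$patient_id, df$kind))) {
    sub <- df[paste(df$patient_id, df$kind) == key, ]
    sub <- sub[order(sub$fraction), ]
    out[[length(out) + 1L]] <-
      shift_series(sub$patient_id[1], sub$kind[1],
                   as.matrix(sub[, c("lr_mm", "si_mm", "ap_mm")]))
  }
  out
}

#' Write cohort error statistics
#'
#' CSV mirrors the conventional report layout (rows mu, SD, Sigma, sigma;
#' columns LR, SI, AP); JSON carries the unrounded numbers plus provenance.
#'
#' @param stats an [error_stats] object.
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @return `stats`, invisibly.
#' @export
write_error_stats <- function(stats, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(stats, "error_stats"))
  if (!is.null(path_csv))
    utils::write.csv(data.frame(statistic = rownames(stats$stats),
                                stats$stats, check.names = FALSE),
                     path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(stats = as.data.frame(stats$stats),
           n_patients = stats$n_patients, n_fractions = stats$n_fractions),
      path_json, auto_unbox = TRUE, digits = NA)
  invisible(stats)
}

#' Write a margin table
#'
#' @param margins a `margin_table` from [margin_report()].
#' @param path_csv,path_json output paths (either may be `NULL`); the CSV is
#'   the display block (rounded, rows Sigma/sigma/Stroom/van Herk), the JSON
#'   the unrounded per-axis values.
#' @return `margins`, invisibly.
#' @export
write_margin_table <- function(margins, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(margins, "margin_table"))
  if (!is.null(path_csv)) {
    block <- format_margin_block(margins)
    utils::write.csv(data.frame(quantity = rownames(block), block,
                                check.names = FALSE),
                     path_csv, row.names = FALSE)
  }
  if (!is.null(path_json))
    jsonlite::write_json(as.data.frame(margins), path_json,
                         auto_unbox = TRUE, digits = NA)
  invisible(margins)
}

#' Write a DVH curve as CSV
#'
#' Columns `bin_gy, volume_pct` plus `sd_pct` when present.
#' @param curve a `dvh_curve`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dvh <- function(curve, path) {
  df <- data.frame(bin_gy = curve$dose_gy, volume_pct = curve$volume_pct)
  if (!is.null(curve$sd_pct)) df$sd_pct <- curve$sd_pct
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
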