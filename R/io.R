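# File interfaces: NIfTI volumes/masks, TSV tables, plain-text key=value
# configs, JSON results.

#' Write a subject dataset as a 4D NIfTI volume plus a mask
#'
#' Voxels are binned onto their lattice; out-of-mask cells are zero. The
#' affine maps voxel indices (0-based) to the mm coordinates stored in the
#' dataset, with the left hemisphere at negative x.
#'
#' @param dataset a [subject_dataset()].
#' @param path output `.nii`/`.nii.gz` path for the 4D series.
#' @param mask_path optional path for a 3D 0/1 mask volume.
#' @return invisibly, the written array dimensions.
#' @export
write_dataset_nifti <- function(dataset, path, mask_path = NULL) {
  coords <- dataset$voxel_coords_mm
  sp <- vapply(1:3, function(j) {
    u <- sort(unique(coords[, j]))
    if (length(u) > 1) min(diff(u)) else 1
  }, numeric(1))
  orig <- vapply(1:3, function(j) min(coords[, j]), numeric(1))
  idx <- sweep(sweep(coords, 2, orig), 2, sp, "/")
  idx <- round(idx) + 1
  dims <- apply(idx, 2, max)
  nt <- ncol(dataset$voxel_series)
  arr <- array(0, c(dims, nt))
  for (v in seq_len(nrow(idx))) {
    arr[idx[v, 1], idx[v, 2], idx[v, 3], ] <- dataset$voxel_series[v, ]
  }
  img <- RNifti::asNifti(arr)
  img <- RNifti::`pixdim<-`(img, c(sp, dataset$tr_seconds))
  RNifti::writeNifti(img, path)
  if (!is.null(mask_path)) {
    m <- array(0L, dims)
    m[idx] <- 1L
    mimg <- RNifti::asNifti(m)
    mimg <- RNifti::`pixdim<-`(mimg, sp)
    RNifti::writeNifti(mimg, mask_path)
  }
  invisible(c(dims, nt))
}

#' Read a 4D NIfTI volume (with mask) back into a subject dataset
#'
#' @param path 4D NIfTI path.
#' @param mask_path 3D mask path; voxels where the mask is nonzero are
#'   extracted. An all-zero mask is an error.
#' @param origin_mm mm coordinate of voxel (1,1,1) (default 0,0,0).
#' @param subject_id label.
#' @param tr_seconds repetition time; default taken from pixdim[4].
#' @return a [subject_dataset()].
#' @export
read_dataset_nifti <- function(path, mask_path, origin_mm = c(0, 0, 0),
                               subject_id = "S01", tr_seconds = NULL) {
  img <- RNifti::readNifti(path)
  mask <- RNifti::readNifti(mask_path)
  if (!all(dim(img)[1:3] == dim(mask)[1:3])) {
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(dim(img)[1:3], collapse = "x"),
                 paste(dim(mask)[1:3], collapse = "x")))
  }
  sel <- which(mask != 0, arr.ind = TRUE)
  if (nrow(sel) == 0) stop("read_dataset_nifti: mask contains zero voxels")
  pd <- RNifti::pixdim(img)
  sp <- pd[1:3]
  tr <- tr_seconds %||% (if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
  nt <- if (length(dim(img)) == 4) dim(img)[4] else 1
  series <- t(vapply(seq_len(nrow(sel)), function(i) {
    if (nt == 1) img[sel[i, 1], sel[i, 2], sel[i, 3]] else img[sel[i, 1], sel[i, 2], sel[i, 3], ]
  }, numeric(nt)))
  coords <- sweep(sweep(sel - 1, 2, sp, "*"), 2, origin_mm, "+")
  subject_dataset(series, tr, coords,
                  hemisphere = ifelse(coords[, 1] < 0, "L", "R"),
                  subject_id = subject_id)
}

#' Read a TSV table, enforcing required columns
#'
#' @param path TSV path (header row required).
#' @param required character vector of required column names.
#' @return data frame.
#' @export
read_tsv_table <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("read_tsv_table: no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("read_tsv_table: ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Write a data frame or matrix as TSV
#' @param x data frame or matrix.
#' @param path output path.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = is.matrix(x) && !is.null(rownames(x)))
  invisible(path)
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments and
#' blank lines ignored; numeric-looking values are converted, `TRUE`/`FALSE`
#' become logical, and comma-separated values become vectors (so a
#' [write_config()] snapshot reads back usable). Unknown keys (not in
#' `known`) are rejected.
#'
#' @param path config path.
#' @param known character vector of accepted keys (NULL accepts all).
#' @return named list.
#' @export
read_config <- function(path, known = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("read_config: cannot parse line: ", ln)
    key <- m[2]; val <- trimws(m[3])
    if (!is.null(known) && !(key %in% known)) {
      stop("read_config: unknown key '", key, "'")
    }
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) {
      num
    } else if (all(parts %in% c("TRUE", "FALSE"))) {
      as.logical(parts)
    } else {
      parts
    }
  }
  out
}

#' Write a key = value configuration snapshot
#' @param config named list of scalar values.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(format(v, digits = 15), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
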