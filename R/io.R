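# On-disk dataset layout and format I/O.
#
# One directory per subject:
#   images.nii.gz   H x W x n_frames float volume (frames as slices)
#   masks.nii.gz    H x W x n_frames integer class volume (0/1/2)
#   indices.csv     frame,area_cav,...,phase (the lvq_csv_columns schema)
# Predicted masks can additionally be exported as single-channel PNG label
# maps (codes 0/1/2).

#' Write one subject to a directory
#' @param subject an `lvq_subject`
#' @param path subject directory (created if missing)
#' @return the path, invisibly
#' @export
write_subject <- function(subject, path) {
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("cannot create subject directory: ", path)
  img <- RNifti::asNifti(subject$images)
  RNifti::pixdim(img) <- rep(subject$spacing %||% lvq_default_spacing, 3)
  RNifti::writeNifti(img, file.path(path, "images.nii.gz"))
  msk <- RNifti::asNifti(array(as.integer(subject$masks),
                               dim = dim(subject$masks)),
                         datatype = "uint8")
  RNifti::writeNifti(msk, file.path(path, "masks.nii.gz"))
  write_indices_csv(subject$indices, file.path(path, "indices.csv"))
  invisible(path)
}

#' Write an index table in the indices.csv schema
#' @param indices tibble with the schema columns
#' @param path file path
#' @return the path, invisibly
#' @export
write_indices_csv <- function(indices, path) {
  missing_cols <- setdiff(lvq_csv_columns, names(indices))
  if (length(missing_cols))
    stop("index table lacks columns: ", paste(missing_cols, collapse = ", "))
  readr::write_csv(indices[, lvq_csv_columns], path)
  invisible(path)
}

#' Read and validate an index table
#' @param path CSV file path
#' @return a tibble in the schema column order
#' @export
read_indices_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(lvq_csv_columns, names(tab))
  if (length(missing_cols))
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  bad <- vapply(lvq_index_names, function(j)
    any(!is.finite(tab[[j]]) | tab[[j]] < 0 | tab[[j]] >= 1), logical(1))
  if (any(bad))
    stop("schema error in ", path, ": values of ",
         paste(lvq_index_names[bad], collapse = ", "),
         " outside [0, 1)")
  if (any(!tab$phase %in% c(0L, 1L)))
    stop("schema error in ", path, ": phase must be binary 0/1")
  tab[, lvq_csv_columns]
}

#' Load one subject from a directory
#'
#' Validates the layout: 20 square frames, 3-class masks, the full 11-index
#' CSV schema.
#'
#' @param path subject directory
#' @param n_frames expected frame count
#' @return an `lvq_subject`
#' @export
load_subject <- function(path, n_frames = 20L) {
  f_img <- file.path(path, "images.nii.gz")
  f_msk <- file.path(path, "masks.nii.gz")
  f_idx <- file.path(path, "indices.csv")
  for (f in c(f_img, f_msk, f_idx))
    if (!file.exists(f)) stop("missing file: ", f)
  nii <- RNifti::readNifti(f_img)
  images <- array(as.numeric(nii), dim = dim(nii))
  spacing <- RNifti::pixdim(nii)[1]
  masks <- array(as.integer(RNifti::readNifti(f_msk)), dim = dim(images))
  d <- dim(images)
  if (length(d) != 3L || d[1] != d[2])
    stop("images must be a stack of square frames")
  if (d[3] != n_frames)
    stop("expected ", n_frames, " frames, found ", d[3])
  if (!all(masks %in% 0:2))
    stop("masks must use class codes 0/1/2")
  indices <- read_indices_csv(f_idx)
  if (nrow(indices) != d[3])
    stop("indices.csv has ", nrow(indices), " rows for ", d[3], " frames")
  structure(list(id = basename(path), images = images, masks = masks,
                 indices = indices, spacing = spacing, spec = NULL),
            class = "lvq_subject")
}

#' List and load all subjects of a dataset directory
#' @param dir dataset directory containing one sub-directory per subject
#' @param n_frames expected frame count
#' @return list of `lvq_subject`
#' @export
load_dataset <- function(dir, n_frames = 20L) {
  subs <- list.dirs(dir, recursive = FALSE)
  if (!length(subs)) stop("no subject directories under ", dir)
  lapply(sort(subs), load_subject, n_frames = n_frames)
}

#' Write a mask stack as PNG label maps
#' @param masks `H x W x n_frames` class array
#' @param dir output directory
#' @param prefix file-name prefix
#' @return written paths, invisibly
#' @export
write_mask_png <- function(masks, dir, prefix = "mask") {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- character(dim(masks)[3])
  for (f in seq_len(dim(masks)[3])) {
    paths[f] <- file.path(dir, sprintf("%s_%02d.png", prefix, f - 1L))
    png::writePNG(masks[, , f] / 255, paths[f])
  }
  invisible(paths)
}

#' Load a run configuration from YAML
#'
#' Missing sections fall back to the package defaults; the resolved
#' configuration carries `seg`, `reg`, `train` and `data` entries.
#'
#' @param path YAML file (or `NULL` for all defaults)
#' @return a named list of configuration objects
#' @export
load_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build <- function(fn, section) do.call(fn, raw[[section]] %||% list())
  cfg <- list(seg = build(seg_config, "seg"),
              reg = build(reg_config, "reg"),
              train = build(train_config, "train"),
              data = raw$data %||% list())
  if (!is.null(raw$train$weights))
    cfg$train$weights <- do.call(loss_weights, raw$train$weights)
  cfg
}

#' Write the fully resolved run configuration next to run outputs
#' @param cfg list from [load_run_config()]
#' @param path output YAML path
#' @return the path, invisibly
#' @export
write_run_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) if (is.list(x)) lapply(unclass(x), unclass) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}
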