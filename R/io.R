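#' Read a NIfTI volume
#'
#' Loads a 3D NIfTI-1 image (plain or gzipped) as an [image_volume()]. The
#' mask may be given as a path to a {0,1} NIfTI of the same shape, a logical
#' array, or omitted (full grid).
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param mask optional mask path or logical array.
#' @return An `image_volume`.
#' @export
load_volume <- function(path, mask = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in '", path, "', got ",
         length(dim(arr)), "D")
  arr <- array(as.numeric(arr), dim(arr))  # strip nifti internals
  spacing <- RNifti::pixdim(img)[1:3]
  if (is.character(mask)) {
    mvol <- load_volume(mask)
    mask <- mvol$data != 0
  }
  if (!is.null(mask) && !identical(dim(as.array(mask)), dim(arr)))
    stop("mask shape mismatch for '", path, "'")
  image_volume(arr, mask, spacing)
}

#' Write a NIfTI volume
#'
#' Saves an [image_volume()] as NIfTI-1 (float32 on disk; correlations and
#' regressions elsewhere in the package accumulate in double precision).
#' Gzipped output is selected by the `.gz` extension.
#'
#' @param vol an `image_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
save_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Resample a volume to a target grid shape
#'
#' Deterministic grid resampling used to bring native-resolution images to
#' the cubic network input shape: trilinear interpolation for image data and
#' nearest-neighbour for the mask (so mask values stay binary). Grid corners
#' are aligned (the first and last voxel centres map onto each other).
#'
#' @param vol an `image_volume`.
#' @param shape target dimensions, scalar or length 3, each >= 4.
#' @param method `"trilinear"` (default) or `"nearest"` for the image data.
#' @return An `image_volume` on the target grid.
#' @export
resample_to_shape <- function(vol, shape, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(vol, "image_volume"))
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (any(shape < 4L)) stop("target dimensions must be >= 4")
  d <- dim(vol$data)
  if (identical(d, shape)) return(vol)
  src_coord <- function(n_out, n_in) {
    if (n_out == 1L) return(rep((n_in + 1) / 2, 1))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  cx <- src_coord(shape[1], d[1])
  cy <- src_coord(shape[2], d[2])
  cz <- src_coord(shape[3], d[3])
  interp <- function(arr, nearest) {
    if (nearest) {
      arr[round(cx), round(cy), round(cz), drop = FALSE]
    } else {
      x0 <- pmin(floor(cx), d[1] - 1L); fx <- cx - x0
      y0 <- pmin(floor(cy), d[2] - 1L); fy <- cy - y0
      z0 <- pmin(floor(cz), d[3] - 1L); fz <- cz - z0
      out <- array(0, shape)
      for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wx <- if (dx == 0) 1 - fx else fx
        wy <- if (dy == 0) 1 - fy else fy
        wz <- if (dz == 0) 1 - fz else fz
        w <- outer(outer(wx, wy), wz)
        out <- out + w * arr[x0 + dx, y0 + dy, z0 + dz, drop = FALSE]
      }
      out
    }
  }
  data_out <- interp(vol$data, nearest = (method == "nearest"))
  mask_out <- interp(array(as.numeric(vol$mask), d), nearest = TRUE) > 0.5
  if (!any(mask_out)) mask_out <- array(TRUE, shape)
  new_spacing <- vol$spacing * (d - 1) / pmax(shape - 1, 1)
  image_volume(array(data_out, shape), array(mask_out, shape),
               new_spacing, vol$orientation)
}

#' Read a subject manifest
#'
#' Reads the TSV manifest schema used throughout the package: columns
#' `subject_id`, `modality`, `timepoint` (`baseline` or `followup`), `path`
#' (relative to the manifest's directory unless absolute).
#'
#' @param path manifest TSV path.
#' @return data.frame with resolved absolute paths.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "modality", "timepoint", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(m$timepoint), c("baseline", "followup"))
  if (length(bad))
    stop("unknown timepoint value(s): ", paste(bad, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(normalizePath(path)), m$path[rel])
  m
}

#' Load longitudinal pairs from a manifest
#'
#' Assembles [longitudinal_pair()] objects for one modality from a manifest
#' data.frame, attaching a shared mask.
#'
#' @param manifest data.frame from [read_manifest()].
#' @param mask mask path or logical array, shared by all volumes.
#' @param modality modality to select (default: the first present).
#' @param interval_years stored on each pair.
#' @return List of `longitudinal_pair` objects.
#' @export
load_pairs <- function(manifest, mask = NULL, modality = NULL,
                       interval_years = 2) {
  if (is.null(modality)) modality <- manifest$modality[1]
  m <- manifest[manifest$modality == modality, ]
  if (is.character(mask)) mask <- load_volume(mask)$data != 0
  subjects <- unique(m$subject_id)
  lapply(subjects, function(s) {
    bp <- m$path[m$subject_id == s & m$timepoint == "baseline"]
    fp <- m$path[m$subject_id == s & m$timepoint == "followup"]
    if (length(bp) != 1L || length(fp) != 1L)
      stop("subject ", s, " must have exactly one baseline and one followup")
    longitudinal_pair(s, load_volume(bp, mask), load_volume(fp, mask),
                      interval_years)
  })
}

#' Write a per-subject report table as TSV
#'
#' @param df data.frame with one row per subject (or per phenotype).
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run-summary sidecar
#'
#' Records the seed, a hash of the configuration, and package version next
#' to every artifact, so any output can be regenerated deterministically.
#'
#' @param path output `.json` path.
#' @param seed integer seed used for the run.
#' @param config list of configuration values (hashed and embedded).
#' @param extra optional named list of additional fields.
#' @return Invisibly, `path`.
#' @export
write_run_summary <- function(path, seed, config = list(), extra = list()) {
  cfg_str <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sidecar <- c(list(
    seed = seed,
    config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                        (seq_along(utf8ToInt(cfg_str)) %% 97 + 1)) %% 4294967291),
    package_version = as.character(utils::packageVersion("longipred")),
    config = config), extra)
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' @param path YAML file describing a run (paths, target mode, network and
#'   training blocks, evaluation block, seed).
#' @return Named list with class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}
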