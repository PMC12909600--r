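grid_to_xform <- function(grid) {
  m <- diag(4)
  m[1, 1] <- grid$spacing_mm[1]
  m[2, 2] <- grid$spacing_mm[2]
  m[3, 3] <- grid$spacing_mm[3]
  m[1:3, 4] <- grid$origin_mm
  structure(m, code = 2L)
}

xform_to_grid <- function(xf, dims) {
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))) || any(diag(rot) <= 0))
    stop("unsupported orientation: only axis-aligned grids with positive ",
         "spacing are supported")
  voxel_grid(xf[1:3, 4], diag(rot), dims)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path)
  grid <- xform_to_grid(RNifti::xform(img), dim(arr))
  list(grid = grid, values = arr)
}

write_volume <- function(values, grid, path, datatype) {
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::qform(img) <- grid_to_xform(grid)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read and write structure masks and dose grids (NIfTI-1)
#'
#' One structure or dose per file. The grid geometry (voxel spacing and the
#' world position of the first voxel center) is stored in the NIfTI
#' transform; only axis-aligned grids with positive spacing are supported
#' and any other orientation raises an error. Write-then-read round-trips
#' preserve occupancy bit-exactly and dose to single float precision.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param name,role Structure label and role for the loaded mask.
#' @return `read_mask()` a [structure_mask()]; `read_dose()` a
#'   [dose_grid()]; the writers return `path` invisibly.
#' @export
read_mask <- function(path, name = role, role = "GTV") {
  v <- read_volume(path)
  structure_mask(v$grid, v$values != 0, name, role)
}

#' @rdname read_mask
#' @param mask A [structure_mask()] to write.
#' @export
write_mask <- function(mask, path) {
  write_volume(array(as.integer(mask$occupancy), mask$grid$dims),
               mask$grid, path, "uint8")
}

#' @rdname read_mask
#' @param phase_label Phase label for the loaded dose.
#' @export
read_dose <- function(path, phase_label = "phase1") {
  v <- read_volume(path)
  dose_grid(v$grid, v$values, phase_label)
}

#' @rdname read_mask
#' @param dose A [dose_grid()] to write.
#' @export
write_dose <- function(dose, path) {
  write_volume(dose$dose_gy, dose$grid, path, "double")
}

#' Write and read a synthetic case as files plus a JSON manifest
#'
#' The manifest records the case id, the common grid geometry, and one entry
#' (structure name, role, file) per mask. All masks of one case must share a
#' single grid; a mismatch on load raises a geometry-mismatch error. Exactly
#' one GTV and one Body entry are required per case.
#'
#' @param case A generated case from [generate_case()].
#' @param dir Output directory (created if needed).
#' @return `write_case()` the manifest path (invisibly); `read_case()` a
#'   case list with `case_id`, `grid`, `masks` and the manifest tibble.
#' @export
write_case <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(names(case$masks), function(nm) {
    file <- paste0(nm, ".nii.gz")
    write_mask(case$masks[[nm]], file.path(dir, file))
    list(name = nm, role = case$masks[[nm]]$role, file = file)
  })
  g <- case$grid
  manifest <- list(case_id = case$case_id,
                   grid = list(origin_mm = g$origin_mm,
                               spacing_mm = g$spacing_mm, dims = g$dims),
                   entries = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_case
#' @param manifest_path Path to a `manifest.json` written by [write_case()].
#' @export
read_case <- function(manifest_path) {
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  roles <- vapply(man$entries, `[[`, character(1), "role")
  if (sum(roles == "GTV") != 1L || sum(roles == "Body") != 1L)
    stop("manifest must contain exactly one GTV and one Body entry")
  masks <- list()
  grid <- NULL
  for (e in man$entries) {
    m <- read_mask(file.path(dir, e$file), e$name, e$role)
    if (is.null(grid)) grid <- m$grid
    else check_same_grid(grid, m$grid, paste0("case masks (", e$name, ")"))
    masks[[e$name]] <- m
  }
  manifest_tbl <- tibble::tibble(
    name = vapply(man$entries, `[[`, character(1), "name"),
    role = roles,
    file = vapply(man$entries, `[[`, character(1), "file"))
  list(case_id = man$case_id, grid = grid, masks = masks,
       manifest = manifest_tbl)
}
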