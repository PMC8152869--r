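## NIfTI-1 readers/writers and cohort directory serialization.

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1 file.
#' @param expected_lmax Optional: for a 4D SH-coefficient volume, validate
#'   that the 4th dimension equals \code{sh_basis_size(expected_lmax)}.
#' @return An \code{RNifti} image (array with header attributes; 0-based
#'   voxel indexing convention at the world/affine boundary only).
#' @export
read_volume <- function(path, expected_lmax = NULL) {
  if (!file.exists(path)) stop("no such volume: ", path)
  img <- RNifti::readNifti(path)
  if (!is.null(expected_lmax)) {
    want <- sh_basis_size(expected_lmax)
    got <- if (length(dim(img)) >= 4) dim(img)[4] else 1L
    if (got != want)
      stop(path, ": 4th dimension is ", got, ", expected ", want,
           " SH coefficients (lmax = ", expected_lmax, ")")
  }
  img
}

#' Write a NIfTI volume
#'
#' @param data Numeric/integer array (3D or 4D).
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Voxel dimensions in mm (default 1).
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, max(0, length(dim(data)) - 3)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## Check that two volumes share a grid.
check_same_grid <- function(a, b, name_a = "a", name_b = "b") {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(as.integer(da), as.integer(db)))
    stop("grid mismatch: ", name_a, " is ", paste(da, collapse = "x"),
         " but ", name_b, " is ", paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Write a synthetic cohort to a directory tree
#'
#' Layout: \code{template/} (mask, ground-truth parcellation, pathway
#' labels), \code{subjects/<id>/} (fod, field, tensor, truth parcellation),
#' \code{meta.tsv}, and \code{manifest.json} holding the generator
#' configuration and the planted ground truth (for tests).
#'
#' @param cohort A \code{\link{make_cohort}} result.
#' @param dir Output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "template"), recursive = TRUE,
             showWarnings = FALSE)
  write_volume(cohort$template$mask + 0L, file.path(dir, "template",
                                                    "mask.nii.gz"))
  write_volume(cohort$template$parcellation,
               file.path(dir, "template", "parcellation.nii.gz"))
  write_volume(cohort$template$fod, file.path(dir, "template", "fod.nii.gz"))
  if (!is.null(cohort$template$pathways))
    write_volume(cohort$template$pathways$labels,
                 file.path(dir, "template", "pathways.nii.gz"))
  for (s in cohort$subjects) {
    sd <- file.path(dir, "subjects", s$id)
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_volume(s$fod, file.path(sd, "fod.nii.gz"))
    write_volume(s$field, file.path(sd, "field.nii.gz"))
    write_volume(s$tensor, file.path(sd, "tensor.nii.gz"))
    write_volume(s$labels_truth, file.path(sd, "parcellation_truth.nii.gz"))
  }
  utils::write.table(cohort$meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    phantom = unclass(cohort$phantom), effects = unclass(cohort$effects),
    seed = cohort$seed,
    n_targets = if (is.null(cohort$template$pathways)) 0L else
      cohort$template$pathways$n_targets,
    pathway_table = cohort$template$pathways$table,
    pathway_voxels = cohort$template$pathways$voxels,
    truth = cohort$truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{write_cohort}}
#'
#' @param dir Cohort directory.
#' @return A \code{synthetic_cohort} list (the SH basis is rebuilt from the
#'   stored configuration).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  ph <- manifest$phantom
  phantom <- phantom_config(grid_shape = ph$grid_shape,
                            k_nuclei = ph$k_nuclei, lmax = ph$lmax,
                            orientations = matrix(unlist(ph$orientations),
                                                  ncol = 3),
                            kappa = ph$kappa, amplitude = ph$amplitude,
                            snr = ph$snr,
                            amplitude_profile = unlist(ph$amplitude_profile),
                            tessellation_level = ph$tessellation_level,
                            seed = ph$seed)
  effects <- do.call(effect_config, manifest$effects[names(formals(
    effect_config))])
  basis <- sh_basis(phantom$lmax, phantom$tessellation_level)
  tdir <- file.path(dir, "template")
  mask <- array(read_volume(file.path(tdir, "mask.nii.gz")) > 0,
                phantom$grid_shape)
  template <- list(
    fod = array(as.numeric(read_volume(file.path(tdir, "fod.nii.gz"),
                                       expected_lmax = phantom$lmax)),
                c(phantom$grid_shape, sh_basis_size(phantom$lmax))),
    mask = mask,
    parcellation = array(as.integer(read_volume(
      file.path(tdir, "parcellation.nii.gz"))), phantom$grid_shape))
  pathways <- NULL
  if (file.exists(file.path(tdir, "pathways.nii.gz"))) {
    pathways <- structure(list(
      labels = array(as.integer(read_volume(file.path(tdir,
                                                      "pathways.nii.gz"))),
                     phantom$grid_shape),
      table = as.data.frame(manifest$pathway_table),
      voxels = as.data.frame(manifest$pathway_voxels),
      n_targets = manifest$n_targets), class = "pathway_set")
  }
  template$pathways <- pathways
  meta <- utils::read.delim(file.path(dir, "meta.tsv"),
                            stringsAsFactors = FALSE)
  meta$group <- factor(meta$group, levels = c("HC", "MCS", "VS"))
  subjects <- lapply(meta$id, function(id) {
    sd <- file.path(dir, "subjects", id)
    fod <- read_volume(file.path(sd, "fod.nii.gz"),
                       expected_lmax = phantom$lmax)
    field <- read_volume(file.path(sd, "field.nii.gz"))
    check_same_grid(fod, field, paste0(id, "/fod"), paste0(id, "/field"))
    lt <- array(as.integer(read_volume(
      file.path(sd, "parcellation_truth.nii.gz"))), phantom$grid_shape)
    list(id = id,
         fod = array(as.numeric(fod), c(phantom$grid_shape,
                                        sh_basis_size(phantom$lmax))),
         field = array(as.numeric(field), c(phantom$grid_shape, 3)),
         tensor = array(as.numeric(read_volume(file.path(sd,
                                                         "tensor.nii.gz"))),
                        c(phantom$grid_shape, 3)),
         mask = mask, labels_truth = lt)
  })
  structure(list(template = template, subjects = subjects, meta = meta,
                 truth = manifest$truth, basis = basis, phantom = phantom,
                 effects = effects, seed = manifest$seed),
            class = "synthetic_cohort")
}
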