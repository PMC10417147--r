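#' Read a volumetric image from NIfTI
#'
#' Voxels, spacing and origin are restored exactly as written by
#' [write_volume()]; integer-typed volumes round-trip bit-exactly.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param intensity_kind Intensity kind to tag the volume with (the file
#'   format does not carry it); see [volume_image()].
#' @return A `volume_image`.
#' @export
read_volume <- function(path, intensity_kind = "HU") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("unreadable volume '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L) {
    stop(sprintf("'%s' is %dD, expected a 3D volume", path, length(dim(a))),
         call. = FALSE)
  }
  a <- array(as.double(a), dim = dim(a))  # plain double array, no classes
  xf <- RNifti::xform(img)
  volume_image(a, spacing = RNifti::pixdim(img)[1:3], origin = xf[1:3, 4],
               kind = intensity_kind)
}

#' Write a volumetric image to NIfTI
#'
#' Integer-valued HU volumes within int16 range are stored as int16 (and so
#' round-trip bit-exactly); everything else is stored as float64.
#'
#' @param img A `volume_image`.
#' @param path Destination `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(img, path) {
  stopifnot_volume(img)
  nif <- RNifti::asNifti(img$voxels)
  RNifti::pixdim(nif) <- img$spacing
  aff <- rbind(cbind(diag(img$spacing), img$origin), c(0, 0, 0, 1))
  RNifti::`qform<-`(nif, structure(aff, code = 2L)) -> nif
  v <- img$voxels
  is_int <- all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767
  RNifti::writeNifti(nif, path, datatype = if (is_int) "int16" else "double")
  invisible(path)
}

#' Write a structure set as a labeled volume plus JSON sidecar
#'
#' Masks can overlap (targets lie inside the external contour), so the
#' labeled integer volume encodes each mask as a bit flag
#' (`label = sum(2^bit)`); the sidecar maps bit to name and role and records
#' the grid.
#'
#' @param structs A `structure_set`.
#' @param path Output NIfTI path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structs, path) {
  nmask <- length(structs$masks)
  if (nmask > 30L) stop("at most 30 masks supported in the bit-flag encoding", call. = FALSE)
  lab <- array(0, dim = structs$grid$shape)
  for (b in seq_len(nmask)) lab <- lab + structs$masks[[b]] * 2^(b - 1)
  vol <- volume_image(lab, structs$grid$spacing, structs$grid$origin, "HU")
  write_volume(vol, path)
  sidecar <- list(
    encoding = "bitmask",
    masks = lapply(seq_len(nmask), function(b) {
      list(bit = b - 1L, name = names(structs$masks)[b],
           role = unname(structs$roles[[b]]))
    }),
    grid = list(shape = structs$grid$shape, spacing = structs$grid$spacing,
                origin = structs$grid$origin)
  )
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a structure set written by [write_structures()]
#'
#' @param path Path to the labeled NIfTI volume (sidecar found next to it).
#' @return A `structure_set`.
#' @export
read_structures <- function(path) {
  sidecar <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  vol <- read_volume(path, "HU")
  lab <- vol$voxels
  masks <- list(); roles <- character()
  for (i in seq_len(nrow(sidecar$masks))) {
    bit <- sidecar$masks$bit[i]
    nm <- sidecar$masks$name[i]
    masks[[nm]] <- array(bitwAnd(as.integer(lab), as.integer(2^bit)) > 0,
                         dim = dim(lab))
    roles[nm] <- sidecar$masks$role[i]
  }
  structure_set(masks, roles, grid_of(vol), check_fov_connectivity = FALSE)
}

sidecar_path <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", path)
  paste0(base, ".json")
}
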