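#' Named structure masks on a common reference grid
#'
#' Holds the binary masks used by the pipeline (clinical target volumes,
#' CBCT field of view, patient external contour) with a role per mask.
#' All masks must share the reference grid; CTV masks must be non-empty and
#' the FOV, when present, must be a single connected region.
#'
#' @param masks Named list of logical 3D arrays sharing one shape.
#' @param roles Named character vector mapping mask name to one of
#'   `"CTV_HIGH"`, `"CTV_STANDARD"`, `"FOV"`, `"EXTERNAL"`, `"OTHER"`.
#'   Masks without an entry default to `"OTHER"`.
#' @param grid `grid_spec` of the reference grid.
#' @param check_fov_connectivity Verify the single-component FOV invariant
#'   (costs a flood fill; disable for large grids you have already checked).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(masks, roles = NULL, grid,
                          check_fov_connectivity = TRUE) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec", call. = FALSE)
  if (length(masks) == 0L || is.null(names(masks)) || any(names(masks) == "")) {
    stop("`masks` must be a non-empty named list", call. = FALSE)
  }
  roles_full <- rep("OTHER", length(masks))
  names(roles_full) <- names(masks)
  if (!is.null(roles)) {
    bad <- setdiff(roles, structure_roles())
    if (length(bad)) stop("unknown roles: ", paste(bad, collapse = ", "), call. = FALSE)
    roles_full[names(roles)] <- roles
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!is.logical(m)) {
      m <- array(m > 0.5, dim = dim(m))
      masks[[nm]] <- m
    }
    if (!identical(dim(m), as.integer(grid$shape))) {
      stop(sprintf("mask '%s' does not match the reference grid shape", nm),
           call. = FALSE)
    }
    if (roles_full[[nm]] %in% c("CTV_HIGH", "CTV_STANDARD") && !any(m)) {
      stop(sprintf("CTV mask '%s' is empty", nm), call. = FALSE)
    }
    if (roles_full[[nm]] == "FOV" && check_fov_connectivity && any(m) &&
        n_components(m) != 1L) {
      stop(sprintf("FOV mask '%s' is not a single connected region", nm),
           call. = FALSE)
    }
  }
  structure(list(masks = masks, roles = roles_full, grid = grid),
            class = "structure_set")
}

#' @rdname structure_set
#' @export
structure_roles <- function() c("CTV_HIGH", "CTV_STANDARD", "FOV", "EXTERNAL", "OTHER")

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d masks on %s grid\n", length(x$masks),
              paste(x$grid$shape, collapse = "x")))
  for (nm in names(x$masks)) {
    cat(sprintf("  %-14s %-12s %7d voxels (%.1f cc)\n", nm, x$roles[[nm]],
                sum(x$masks[[nm]]), mask_volume_cc(x$masks[[nm]], x$grid)))
  }
  invisible(x)
}

#' Fetch the first mask with a given role
#'
#' @param structs A `structure_set`.
#' @param role One of [structure_roles()].
#' @param required Error (rather than return `NULL`) when absent.
#' @return Logical mask array or `NULL`.
#' @export
mask_by_role <- function(structs, role, required = TRUE) {
  hit <- names(structs$roles)[structs$roles == role]
  if (length(hit) == 0L) {
    if (required) stop(sprintf("no mask with role %s", role), call. = FALSE)
    return(NULL)
  }
  structs$masks[[hit[1]]]
}

#' Resample every mask of a structure set onto a target grid
#'
#' @param structs A `structure_set`.
#' @param target A `grid_spec`.
#' @return A `structure_set` on the target grid.
#' @export
resample_structures <- function(structs, target) {
  masks <- lapply(structs$masks, resample_mask, source = structs$grid,
                  target = target)
  structure_set(masks, structs$roles, target, check_fov_connectivity = FALSE)
}
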