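#' Compartment roles recognised in a label volume
#'
#' @return character vector of role names.
#' @export
volume_roles <- function() {
  c("ecs", "astrocyte", "bouton", "spine", "dendrite_shaft", "other")
}

#' Default compartment label map
#'
#' Maps each compartment role to the integer id used in the voxel grid.
#'
#' @return named integer vector (names are roles).
#' @export
default_label_map <- function() {
  c(ecs = 0L, astrocyte = 1L, bouton = 2L, spine = 3L,
    dendrite_shaft = 4L, other = 5L)
}

#' Construct a voxelised compartment label volume
#'
#' The geometric substrate of every other computation: a 3D integer grid with
#' one compartment id per voxel, an anisotropic physical pitch, and a map from
#' ids to compartment roles. The default pitch (6, 6, 30) nm and grid shape
#' (201, 201, 41) correspond to a 1.2 x 1.2 x 1.2 um neuropil sample at
#' serial-EM resolution.
#'
#' @param labels 3D integer array of compartment ids.
#' @param pitch_nm voxel pitch (dx, dy, dz) in nm, all strictly positive.
#' @param label_map named integer vector mapping role -> id; must contain an
#'   `ecs` entry. Roles outside [volume_roles()] are rejected.
#' @param origin_nm physical coordinate of the (0,0,0) voxel corner, nm.
#'   Voxel indices are 0-based; voxel `(i,j,k)` occupies the half-open box
#'   `origin + [i*dx, (i+1)*dx) x ...`.
#' @return an object of class `calf_volume`.
#' @export
label_volume <- function(labels,
                         pitch_nm = c(6, 6, 30),
                         label_map = default_label_map(),
                         origin_nm = c(0, 0, 0)) {
  if (length(dim(labels)) != 3L) {
    abort("`labels` must be a 3D array.")
  }
  storage.mode(labels) <- "integer"
  pitch_nm <- as.double(pitch_nm)
  if (length(pitch_nm) != 3L || any(!is.finite(pitch_nm)) || any(pitch_nm <= 0)) {
    abort("`pitch_nm` must be three strictly positive lengths in nm.")
  }
  if (is.null(names(label_map)) || !("ecs" %in% names(label_map))) {
    abort("`label_map` must be named and contain an `ecs` role.")
  }
  bad <- setdiff(names(label_map), volume_roles())
  if (length(bad)) {
    abort(paste0("Unknown roles in `label_map`: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(label_map)) {
    abort("`label_map` ids must be unique.")
  }
  if (anyNA(labels)) abort("`labels` must not contain NA.")
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, unname(label_map))
  if (length(unknown)) {
    abort(paste0("Voxel labels not in `label_map`: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(
    list(labels = labels,
         pitch_nm = pitch_nm,
         label_map = setNames(as.integer(label_map), names(label_map)),
         origin_nm = as.double(origin_nm)),
    class = "calf_volume")
}

#' @export
print.calf_volume <- function(x, ...) {
  d <- dim(x$labels)
  ext <- d * x$pitch_nm
  cat(sprintf("<calf_volume> %d x %d x %d voxels, pitch (%g, %g, %g) nm, extent (%g, %g, %g) nm\n",
              d[1], d[2], d[3], x$pitch_nm[1], x$pitch_nm[2], x$pitch_nm[3],
              ext[1], ext[2], ext[3]))
  fr <- compartment_fractions(x)
  fr <- fr[fr$fraction > 0, ]
  cat(paste(sprintf("  %s: %.1f%%", fr$role, 100 * fr$fraction), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
dim.calf_volume <- function(x) dim(x$labels)

role_id <- function(vol, role) {
  if (!role %in% names(vol$label_map)) {
    abort(sprintf("Role `%s` is not present in the volume's label map.", role))
  }
  unname(vol$label_map[[role]])
}

# Physical extent (nm) of the volume along each axis.
volume_extent_nm <- function(vol) dim(vol$labels) * vol$pitch_nm

voxel_volume_l <- function(vol) nm3_to_litre(prod(vol$pitch_nm))

# logical mask for a role
role_mask <- function(vol, role) vol$labels == role_id(vol, role)

# Volume (litres) occupied by a role.
role_volume_l <- function(vol, role) {
  sum(role_mask(vol, role)) * voxel_volume_l(vol)
}

#' Construct a synapse record
#'
#' Bundles a label volume with the postsynaptic-density centroid and the
#' categorical attributes needed by the five-criterion synapse selection
#' filter.
#'
#' @param volume a [label_volume()].
#' @param centroid_nm 3D point (nm) of the PSD centroid; must lie inside the
#'   volume's physical extent.
#' @param axon_type `"excitatory"` or `"inhibitory"`.
#' @param has_terminal logical; `FALSE` marks an en-passant synapse.
#' @param is_multisynaptic logical; `TRUE` marks a multi-synaptic bouton.
#' @param target_is_spine logical; `FALSE` marks a shaft synapse.
#' @param id optional identifier carried through tables.
#' @return an object of class `calf_synapse`.
#' @export
synapse_record <- function(volume, centroid_nm,
                           axon_type = c("excitatory", "inhibitory"),
                           has_terminal = TRUE,
                           is_multisynaptic = FALSE,
                           target_is_spine = TRUE,
                           id = NULL) {
  stopifnot(inherits(volume, "calf_volume"))
  axon_type <- match.arg(axon_type)
  centroid_nm <- as.double(centroid_nm)
  ext <- volume_extent_nm(volume)
  rel <- centroid_nm - volume$origin_nm
  if (length(centroid_nm) != 3L || any(rel < 0) || any(rel >= ext)) {
    abort("`centroid_nm` must lie inside the volume's physical extent.")
  }
  structure(
    list(volume = volume, centroid_nm = centroid_nm, axon_type = axon_type,
         has_terminal = isTRUE(has_terminal),
         is_multisynaptic = isTRUE(is_multisynaptic),
         target_is_spine = isTRUE(target_is_spine),
         id = id %||% NA_character_),
    class = "calf_synapse")
}

#' @export
print.calf_synapse <- function(x, ...) {
  cat(sprintf("<calf_synapse> id=%s axon=%s terminal=%s multi=%s spine=%s\n",
              x$id, x$axon_type, x$has_terminal, x$is_multisynaptic,
              x$target_is_spine))
  print(x$volume)
  invisible(x)
}
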