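# Shift an array by `s` voxels along axis `ax`, so that result[i] = a[i + s]
# (the neighbour in the +s direction). Positions whose neighbour falls outside
# the grid are filled with `fill`; NA fill therefore marks sample-boundary
# neighbours, which are excluded from surface and erosion rules (the tissue
# continues outside the sample).
shifted <- function(a, ax, s, fill = NA) {
  d <- dim(a)
  n <- d[ax]
  out <- array(fill, d)
  storage.mode(out) <- storage.mode(a)
  if (abs(s) >= n) return(out)
  i_dst <- lapply(d, seq_len)
  i_src <- i_dst
  if (s > 0) {
    i_dst[[ax]] <- 1:(n - s)
    i_src[[ax]] <- (1 + s):n
  } else {
    i_dst[[ax]] <- (1 - s):n
    i_src[[ax]] <- 1:(n + s)
  }
  src <- do.call(`[`, c(list(a), i_src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), i_dst, list(value = src)))
}

#' Correct a label volume for fixation-induced extracellular shrinkage
#'
#' Chemically fixed EM tissue under-represents the extracellular space (ECS).
#' The correction erodes every cellular segment by `shrink_nm` and relabels
#' the eroded shell as ECS: a non-ECS voxel becomes ECS when its in-plane
#' face-neighbourhood within `shrink_nm` contains a voxel of a different
#' label (another cell or ECS). Erosion acts in the xy plane only: the axial
#' pitch (30 nm by default) exceeds the 6 nm shrink distance, so eroding in z
#' would over-correct.
#'
#' @param vol a [label_volume()].
#' @param shrink_nm erosion distance; must be a positive multiple of the
#'   in-plane pitch.
#' @return the corrected `calf_volume`; the ECS fraction never decreases.
#' @export
apply_ecs_correction <- function(vol, shrink_nm = 6) {
  stopifnot(inherits(vol, "calf_volume"))
  px <- vol$pitch_nm[1]
  if (vol$pitch_nm[2] != px) {
    abort("ECS correction requires equal in-plane pitches.")
  }
  if (!is.finite(shrink_nm) || shrink_nm <= 0 ||
      abs(shrink_nm / px - round(shrink_nm / px)) > 1e-9) {
    abort(sprintf(
      "`shrink_nm` (%g nm) must be a positive multiple of the in-plane pitch (%g nm).",
      shrink_nm, px))
  }
  k <- as.integer(round(shrink_nm / px))
  ecs <- role_id(vol, "ecs")
  L <- vol$labels
  for (iter in seq_len(k)) {
    mark <- array(FALSE, dim(L))
    for (ax in 1:2) {
      for (s in c(-1L, 1L)) {
        nb <- shifted(L, ax, s, fill = NA)
        mark <- mark | (!is.na(nb) & nb != L)
      }
    }
    newly <- mark & (L != ecs)
    if (!any(newly)) break
    L[newly] <- ecs
  }
  vol$labels <- L
  vol
}

#' Volume fraction of every compartment role
#'
#' @param vol a [label_volume()].
#' @return tibble with columns `role` and `fraction`; fractions sum to 1.
#' @export
compartment_fractions <- function(vol) {
  stopifnot(inherits(vol, "calf_volume"))
  counts <- vapply(names(vol$label_map), function(r) sum(vol$labels == vol$label_map[[r]]),
                   numeric(1))
  tibble(role = names(vol$label_map),
         fraction = unname(counts) / length(vol$labels))
}

# Exposed-face count and area of the voxel set labelled `id`, using
# anisotropic face areas. Faces on the sample boundary are not counted.
exposed_surface <- function(vol, id) {
  surface_cpp(vol$labels, dim(vol$labels), vol$pitch_nm, as.integer(id))
}

#' Astrocytic surface area, volume and surface-to-volume ratio
#'
#' Surface is defined by 6-connectivity: every astrocyte voxel face exposed to
#' a differently labelled in-sample voxel contributes its anisotropic face
#' area (dy dz, dx dz or dx dy). Faces on the sample-volume boundary are not
#' counted, since the process continues outside the sample. SVR is the exposed
#' area divided by the voxel volume of the astrocytic segment, in inverse
#' micrometres. Note that for curved surfaces the summed axis-aligned face
#' area over-estimates the true area by the Manhattan factor (3/2 for an
#' isotropically oriented surface); an axis-aligned slab is measured exactly.
#'
#' @param vol a [label_volume()].
#' @return one-row tibble: `area_um2`, `volume_um3`, `svr_um_inv`.
#' @export
astro_surface_area_volume <- function(vol) {
  stopifnot(inherits(vol, "calf_volume"))
  id <- role_id(vol, "astrocyte")
  n_vox <- sum(vol$labels == id)
  if (n_vox == 0L) {
    abort("The volume contains no astrocyte voxels (empty segment).")
  }
  surf <- exposed_surface(vol, id)
  area_um2 <- surf$area_nm2 / 1e6
  volume_um3 <- n_vox * prod(vol$pitch_nm) / 1e9
  tibble(area_um2 = area_um2,
         volume_um3 = volume_um3,
         svr_um_inv = area_um2 / volume_um3)
}

#' Astrocytic coverage of a synaptic element
#'
#' Fraction of the target segment's surface voxels that have an astrocyte
#' voxel within `contact_dist_nm` along face-connected paths through the ECS
#' (or are in direct face contact). Surface voxels are target voxels with at
#' least one differently labelled in-sample face neighbour.
#'
#' @param vol a [label_volume()].
#' @param target_role `"bouton"` or `"spine"`.
#' @param contact_dist_nm close-contact distance, nm. The default 12 nm
#'   allows up to two in-plane ECS voxels between membrane and astrocyte,
#'   which is the regime left after the ECS fixation correction.
#' @return coverage fraction in \[0, 1\].
#' @export
synaptic_coverage <- function(vol, target_role = c("bouton", "spine"),
                              contact_dist_nm = 12) {
  stopifnot(inherits(vol, "calf_volume"))
  target_role <- match.arg(target_role)
  tid <- role_id(vol, target_role)
  if (!any(vol$labels == tid)) {
    abort(sprintf("Target segment `%s` is absent from the volume.", target_role))
  }
  if (!"astrocyte" %in% names(vol$label_map) ||
      !any(vol$labels == role_id(vol, "astrocyte"))) {
    return(0)
  }
  coverage_cpp(vol$labels, dim(vol$labels), vol$pitch_nm,
               tid, role_id(vol, "astrocyte"), role_id(vol, "ecs"),
               contact_dist_nm)
}

#' Morphometric summary of a synapse volume
#'
#' One row with the quantities used to characterise a tripartite synapse:
#' astrocytic SVR, pre- and postsynaptic astrocytic coverage, and ECS /
#' astrocyte volume fractions. Coverage is `NA` when the corresponding
#' segment is absent.
#'
#' @param vol a [label_volume()] or [synapse_record()].
#' @param contact_dist_nm close-contact distance for coverage, nm.
#' @return one-row tibble: `svr_um_inv`, `coverage_pre`, `coverage_post`,
#'   `ecs_fraction`, `astro_fraction`, `area_um2`, `volume_um3`.
#' @export
measure_morphometrics <- function(vol, contact_dist_nm = 12) {
  if (inherits(vol, "calf_synapse")) vol <- vol$volume
  stopifnot(inherits(vol, "calf_volume"))
  fr <- compartment_fractions(vol)
  frac <- function(r) if (r %in% fr$role) fr$fraction[fr$role == r] else 0
  has_astro <- frac("astrocyte") > 0
  sv <- if (has_astro) astro_surface_area_volume(vol) else
    tibble(area_um2 = 0, volume_um3 = 0, svr_um_inv = NA_real_)
  cov_of <- function(role) {
    if (!role %in% fr$role || frac(role) == 0) return(NA_real_)
    synaptic_coverage(vol, role, contact_dist_nm)
  }
  tibble(svr_um_inv = sv$svr_um_inv,
         coverage_pre = cov_of("bouton"),
         coverage_post = cov_of("spine"),
         ecs_fraction = frac("ecs"),
         astro_fraction = frac("astrocyte"),
         area_um2 = sv$area_um2,
         volume_um3 = sv$volume_um3)
}

synapse_flags <- function(rec, i) {
  need <- c("axon_type", "has_terminal", "is_multisynaptic", "target_is_spine")
  for (f in need) {
    v <- rec[[f]]
    if (is.null(v) || length(v) != 1L || (is.logical(v) && is.na(v))) {
      abort(sprintf("Synapse record %s is missing attribute `%s`.",
                    rec$id %||% i, f))
    }
  }
  rec
}

#' Filter a synapse population by the five selection criteria
#'
#' A record is kept iff (1) the axon is excitatory, (2) an axon terminal is
#' present (not en-passant), (3) the bouton is not multi-synaptic, (4) the
#' postsynaptic element is a spine, and (5) the astrocytic volume fraction is
#' at least `min_astro_fraction` (inclusive threshold). Order is preserved.
#'
#' @param records a list of [synapse_record()]s, or a tibble with a `synapse`
#'   list-column of records (e.g. from [make_population()]).
#' @param min_astro_fraction criterion-5 threshold, default 2%.
#' @return the filtered list (or tibble).
#' @export
select_synapses <- function(records, min_astro_fraction = 0.02) {
  is_tbl <- is.data.frame(records)
  recs <- if (is_tbl) records$synapse else records
  if (is_tbl && is.null(recs)) {
    abort("A tibble input must carry a `synapse` list-column of synapse records.")
  }
  keep <- vapply(seq_along(recs), function(i) {
    rec <- synapse_flags(recs[[i]], i)
    af <- compartment_fractions(rec$volume)
    astro <- if ("astrocyte" %in% af$role) af$fraction[af$role == "astrocyte"] else 0
    rec$axon_type == "excitatory" &&
      rec$has_terminal &&
      !rec$is_multisynaptic &&
      rec$target_is_spine &&
      astro >= min_astro_fraction
  }, logical(1))
  if (is_tbl) records[keep, , drop = FALSE] else recs[keep]
}
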