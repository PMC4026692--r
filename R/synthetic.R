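#' Specification of a synthetic three-group shape cohort
#'
#' Defines the generative model of the package's synthetic cohort: a single
#' ellipsoidal template structure whose subjects differ by (a) a global size
#' factor (drawn per subject, partially coupled to a simulated intracranial
#' volume, creating overlapping volume distributions across groups), (b) a
#' group-specific smooth focal outward bump -- at the anterior pole of the
#' long axis for the FTD-like group, at the posterior pole for the AD-like
#' group, absent in controls -- mimicking the spatially distinct ventricular
#' expansion patterns of the two dementias, and (c) small i.i.d. vertex
#' jitter. Because all subjects deform one template mesh, vertex
#' correspondence is exact by construction.
#'
#' @param group_sizes named integer vector, default c(NC=14, AD=34, FTD=30).
#' @param semi_axes template ellipsoid semi-axes in mm (longest first).
#' @param scale_sd SD of the per-subject linear size factor (dimensionless).
#' @param group_scale named mean size factor per group; patients are set
#'   slightly larger than controls (ventricular expansion) but equal to each
#'   other, so gross size cannot separate the two dementias.
#' @param bump_amplitude focal bump height in mm (0 disables).
#' @param bump_width angular width (radians) of the Gaussian falloff.
#' @param jitter_sd SD of i.i.d. vertex jitter in mm.
#' @param mesh_subdiv icosphere subdivision rounds of the template mesh.
#' @param spacing voxel spacing (mm) used when voxelising masks.
#' @param icv_mean,icv_sd intracranial volume distribution (mm^3).
#' @param icv_coupling linear size change (fraction) per 1 SD of ICV;
#'   induces the structure-volume-on-ICV slope the normalisation removes.
#' @param seed master seed.
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(group_sizes = c(NC = 14L, AD = 34L, FTD = 30L),
                        semi_axes = c(18, 11, 9),
                        scale_sd = 0.06,
                        group_scale = c(NC = 1.00, AD = 1.03, FTD = 1.03),
                        bump_amplitude = 2,
                        bump_width = 0.35,
                        jitter_sd = 0.05,
                        mesh_subdiv = 3L,
                        spacing = c(1, 1, 1),
                        icv_mean = 1.5e6, icv_sd = 1.5e5,
                        icv_coupling = 0.02,
                        seed = 42L) {
  if (any(group_sizes < 2L)) stop("every group needs >= 2 subjects")
  if (bump_amplitude < 0) stop("bump_amplitude must be >= 0")
  structure(list(group_sizes = group_sizes, semi_axes = semi_axes,
                 scale_sd = scale_sd, group_scale = group_scale,
                 bump_amplitude = bump_amplitude, bump_width = bump_width,
                 jitter_sd = jitter_sd, mesh_subdiv = mesh_subdiv,
                 spacing = spacing, icv_mean = icv_mean, icv_sd = icv_sd,
                 icv_coupling = icv_coupling, seed = seed),
            class = "cohort_spec")
}

# bump locus directions: anterior/posterior poles of the longest semi-axis
bump_locus <- function(group) {
  switch(group,
         AD = c(-1, 0, 0),    # posterior pole
         FTD = c(1, 0, 0),    # anterior pole
         NULL)                # controls: no bump
}

# surface radius along unit direction u: scaled ellipsoid plus additive
# Gaussian angular bump (amplitude in mm)
radial_function <- function(u, spec, scale, group) {
  re <- 1 / sqrt(rowSums(sweep(u^2, 2L, spec$semi_axes^2, "/")))
  r <- scale * re
  locus <- bump_locus(group)
  if (!is.null(locus) && spec$bump_amplitude > 0) {
    cosang <- pmin(1, pmax(-1, u %*% locus))
    ang <- acos(cosang)
    r <- r + spec$bump_amplitude * exp(-ang^2 / (2 * spec$bump_width^2))
  }
  r
}

#' Template mesh of a cohort specification
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return the undeformed ellipsoid \code{\link{surface_mesh}} all subjects
#'   correspond to.
#' @export
template_mesh <- function(spec) {
  icosphere(spec$mesh_subdiv, radius = spec$semi_axes)
}

#' Generate one synthetic subject
#'
#' Draws the subject's size factor and ICV, deforms the template radially
#' (scale + group bump), jitters the mesh vertices, and voxelises the smooth
#' (unjittered) shape by the analytic point-inside-surface test on a regular
#' grid. An empty or badly disconnected mask triggers regeneration with a
#' new sub-seed (at most 5 attempts).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param group group label ("NC", "AD" or "FTD").
#' @param seed subject seed.
#' @param make_mask if FALSE, skip voxelisation (mesh-only studies).
#' @return list with \code{mesh} (in template vertex correspondence),
#'   \code{mask} (\code{\link{binary_mask}} or NULL), \code{icv}, and the
#'   ground-truth \code{scale} and \code{bump_amplitude}.
#' @export
generate_subject <- function(spec, group, seed, make_mask = TRUE) {
  for (attempt in 0:4) {
    set.seed(seed + attempt * 100003L)
    z_icv <- stats::rnorm(1)
    icv <- spec$icv_mean + spec$icv_sd * z_icv
    scale <- spec$group_scale[[group]] *
      (1 + spec$icv_coupling * z_icv + spec$scale_sd * stats::rnorm(1))
    tmpl <- template_mesh(spec)
    u <- tmpl$vertices / sqrt(rowSums(tmpl$vertices^2))
    r <- radial_function(u, spec, scale, group)
    verts <- u * as.numeric(r)
    if (spec$jitter_sd > 0)
      verts <- verts + matrix(stats::rnorm(length(verts), 0, spec$jitter_sd),
                              ncol = 3L)
    mesh <- surface_mesh(verts, tmpl$faces)
    if (!make_mask)
      return(list(mesh = mesh, mask = NULL, icv = icv, scale = scale,
                  bump_amplitude = if (is.null(bump_locus(group))) 0
                                   else spec$bump_amplitude))
    mask <- try(voxelize_shape(spec, scale, group), silent = TRUE)
    if (!inherits(mask, "try-error"))
      return(list(mesh = mesh, mask = mask, icv = icv, scale = scale,
                  bump_amplitude = if (is.null(bump_locus(group))) 0
                                   else spec$bump_amplitude))
  }
  stop("failed to generate a valid mask in 5 attempts (group ", group, ")")
}

# analytic voxelisation: the deformed shape is star-shaped about its
# centre, so voxel centre p is inside iff |p| <= R(p/|p|)
voxelize_shape <- function(spec, scale, group) {
  margin <- 3
  half <- max(spec$semi_axes) * scale + spec$bump_amplitude + margin
  nx <- ceiling(2 * half / spec$spacing)
  ctr <- (nx + 1) / 2
  g <- expand.grid(i = seq_len(nx[1]), j = seq_len(nx[2]), k = seq_len(nx[3]))
  p <- cbind((g$i - ctr[1]) * spec$spacing[1],
             (g$j - ctr[2]) * spec$spacing[2],
             (g$k - ctr[3]) * spec$spacing[3])
  pn <- sqrt(rowSums(p^2))
  pn[pn == 0] <- 1e-12
  u <- p / pn
  inside <- pn <= radial_function(u, spec, scale, group)
  vox <- array(as.integer(inside), dim = nx)
  m <- binary_mask(vox, spacing = spec$spacing)
  fg <- m$voxels != 0L
  biggest <- largest_component(fg)
  if (sum(biggest) < 0.99 * sum(fg)) stop("disconnected mask")
  m
}

#' Generate a full synthetic cohort
#'
#' Produces all subjects of the spec (deterministically from the spec seed),
#' optionally writing every artefact to disk in the formats the package
#' reads back: NIfTI masks, ASCII PLY meshes, a cohort CSV (subject_id,
#' group, icv, file paths) and a manifest CSV with the ground-truth
#' generative parameters per subject (for parameter-recovery tests).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param dir output directory; NULL (default) keeps everything in memory.
#' @param make_masks generate voxel masks (needed for volume/spectral
#'   features; mesh-only cohorts are much faster).
#' @return list with \code{cohort} (a \code{cohort_table}), \code{masks},
#'   \code{meshes} (named lists), \code{manifest}, \code{template},
#'   \code{spec}.
#' @export
generate_cohort <- function(spec, dir = NULL, make_masks = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(n))
  masks <- list()
  meshes <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- generate_subject(spec, groups[i], seed = spec$seed + 1000L * i,
                          make_mask = make_masks)
    masks[[ids[i]]] <- s$mask
    meshes[[ids[i]]] <- s$mesh
    rows[[i]] <- data.frame(subject_id = ids[i], group = groups[i],
                            icv = s$icv, true_scale = s$scale,
                            true_bump_amplitude = s$bump_amplitude,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  cohort <- validate_cohort(manifest[, c("subject_id", "group", "icv")],
                            groups = names(spec$group_sizes))
  out <- list(cohort = cohort, masks = if (make_masks) masks else NULL,
              meshes = meshes, manifest = manifest,
              template = template_mesh(spec), spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    mask_paths <- character(n)
    mesh_paths <- character(n)
    for (i in seq_len(n)) {
      if (make_masks) {
        mask_paths[i] <- file.path(dir, paste0(ids[i], "_mask.nii.gz"))
        write_mask(masks[[ids[i]]], mask_paths[i])
      }
      mesh_paths[i] <- file.path(dir, paste0(ids[i], "_surf.ply"))
      write_mesh(meshes[[ids[i]]], mesh_paths[i])
    }
    write_mesh(out$template, file.path(dir, "template.ply"))
    tab <- cbind(as.data.frame(cohort),
                 mask_path = if (make_masks) mask_paths else NA,
                 mesh_path = mesh_paths)
    utils::write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  out
}
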