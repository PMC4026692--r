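#' Least-squares rigid alignment (Kabsch)
#'
#' Finds the proper rotation R (det = +1) and translation t minimising
#' ||R moving + t - fixed||^2 over corresponding points. Scaling is
#' deliberately excluded: size differences are signal for the displacement
#' features, only pose is removed.
#'
#' @param moving n x 3 matrix of source points.
#' @param fixed n x 3 matrix of target points, row-correspondent.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (root-mean-square residual, mm).
#' @export
rigid_align <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed))) stop("point sets differ in shape")
  if (nrow(moving) < 3L) stop("need at least 3 corresponding points")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  M0 <- sweep(moving, 2L, cm); F0 <- sweep(fixed, 2L, cf)
  if (qr(M0)$rank < 2L) stop("degenerate (collinear) point configuration")
  H <- crossprod(M0, F0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  aligned <- sweep(moving %*% t(R), 2L, t, "+")
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums((aligned - fixed)^2))))
}

apply_rigid <- function(points, transform) {
  sweep(as.matrix(points) %*% t(transform$rotation), 2L,
        transform$translation, "+")
}

#' Per-vertex surface displacement field
#'
#' Given a template mesh and a target mesh in vertex correspondence (same
#' vertex count and order, identical faces), computes for every vertex j the
#' Euclidean distance between template vertex j and target vertex j -- the
#' local atrophy/expansion feature -- plus a signed variant obtained by
#' projecting the displacement vector on the template outward vertex normal
#' (positive = outward expansion), which is what group-difference maps use.
#'
#' @param template a \code{\link{surface_mesh}}.
#' @param target a \code{\link{surface_mesh}} with the same vertex count and
#'   faces.
#' @param prealign if TRUE (default), the target is first rigidly aligned to
#'   the template over corresponding vertices, so any rigid motion of the
#'   target leaves the field unchanged.
#' @return object of class \code{displacement_field}: list with
#'   \code{magnitudes} (mm, >= 0), \code{signed} (mm), \code{prealigned}.
#' @export
displacement_field <- function(template, target, prealign = TRUE) {
  stopifnot(inherits(template, "surface_mesh"),
            inherits(target, "surface_mesh"))
  if (nrow(template$vertices) != nrow(target$vertices))
    stop("vertex count mismatch between template and target")
  if (!identical(dim(template$faces), dim(target$faces)))
    stop("face arrays differ between template and target")
  tv <- target$vertices
  if (prealign) {
    tr <- rigid_align(tv, template$vertices)
    tv <- apply_rigid(tv, tr)
  }
  disp <- tv - template$vertices
  mags <- sqrt(rowSums(disp^2))
  nrm <- vertex_normals(template)
  structure(list(magnitudes = mags, signed = rowSums(disp * nrm),
                 prealigned = prealign),
            class = "displacement_field")
}

#' Partition a surface into patches by k-means on vertex coordinates
#'
#' Clusters template vertex coordinates into \code{n_patches} spatially
#' compact patches (k-means++ seeding, Lloyd iterations, several restarts,
#' best within-cluster sum kept). Patch-averaged displacements reduce the
#' per-vertex field to an interpretable, anatomically local feature vector.
#' Every patch is guaranteed nonempty; the assignment is deterministic for
#' a given seed.
#'
#' @param mesh template \code{\link{surface_mesh}}.
#' @param n_patches number of patches (default 300).
#' @param seed RNG seed for the k-means++ initialisation (default 42).
#' @param n_restarts restarts, best total within-patch variance kept.
#' @param max_iter Lloyd iterations per restart.
#' @return object of class \code{patch_partition}: list with
#'   \code{assignment} (vertex -> patch id, 1..n_patches), \code{centroids},
#'   \code{n_patches}, \code{seed}.
#' @export
partition_surface <- function(mesh, n_patches = 300L, seed = 42L,
                              n_restarts = 10L, max_iter = 100L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  X <- mesh$vertices
  nv <- nrow(X)
  if (n_patches > nv) stop("n_patches (", n_patches,
                           ") exceeds vertex count (", nv, ")")
  if (n_patches == nv) {
    return(structure(list(assignment = seq_len(nv), centroids = X,
                          n_patches = n_patches, seed = seed),
                     class = "patch_partition"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centers <- kmeanspp_init(X, n_patches)
    km <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = max_iter,
                    algorithm = "Lloyd"),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd"))
      })
    if (is.null(km)) next
    km <- fix_empty_patches(X, km)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  structure(list(assignment = as.integer(best$cluster),
                 centroids = best$centers, n_patches = n_patches,
                 seed = seed),
            class = "patch_partition")
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1, ])^2)
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j, ] <- X[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# reassign the farthest vertices to any empty patch and recompute centres
fix_empty_patches <- function(X, km) {
  k <- nrow(km$centers)
  empty <- setdiff(seq_len(k), unique(km$cluster))
  if (length(empty) == 0L) return(km)
  for (e in empty) {
    d2 <- rowSums((X - km$centers[km$cluster, ])^2)
    far <- which.max(d2)
    km$cluster[far] <- e
    km$centers[e, ] <- X[far, ]
  }
  for (j in seq_len(k)) {
    sel <- km$cluster == j
    if (any(sel)) km$centers[j, ] <- colMeans(X[sel, , drop = FALSE])
  }
  km$tot.withinss <- sum(rowSums((X - km$centers[km$cluster, ])^2))
  km
}

#' Patch-averaged displacement features
#'
#' Feature p is the arithmetic mean of the per-vertex displacement values
#' over the vertices assigned to patch p. The vertex-count-weighted mean of
#' the patch features equals the global mean of the field.
#'
#' @param field a \code{\link{displacement_field}} (or plain numeric vector
#'   of per-vertex values).
#' @param partition a \code{\link{patch_partition}} on the same template.
#' @param use one of "magnitudes" (default, feeds the classifier) or
#'   "signed".
#' @return named numeric vector (patch_001, ...) of length n_patches.
#' @export
patch_features <- function(field, partition, use = c("magnitudes", "signed")) {
  use <- match.arg(use)
  vals <- if (inherits(field, "displacement_field")) field[[use]]
          else as.numeric(field)
  if (length(vals) != length(partition$assignment))
    stop("field length (", length(vals), ") does not match partition (",
         length(partition$assignment), " vertices)")
  means <- vapply(split(vals, partition$assignment), mean, numeric(1))
  out <- numeric(partition$n_patches)
  out[as.integer(names(means))] <- means
  names(out) <- sprintf("patch_%03d", seq_len(partition$n_patches))
  out
}

#' Patch-wise two-group comparison of displacement features
#'
#' Per-patch Welch two-sample t statistic between two diagnostic groups with
#' Benjamini--Hochberg control of the false discovery rate across patches.
#' This is a desk-scale surrogate for vertex-wise random-field-theory
#' cluster statistics: it answers the same question (which surface regions
#' differ between groups) at patch resolution.
#'
#' @param features subjects x patches numeric matrix of patch features
#'   (signed fields recommended for directional interpretation).
#' @param labels group label per subject (factor or character).
#' @param groups length-2 character vector: the two groups to compare
#'   (difference is group1 - group2).
#' @param q FDR level (default 0.05).
#' @return data.frame with patch, t, p, p_adj, significant.
#' @export
patch_group_difference <- function(features, labels, groups, q = 0.05) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(length(groups) == 2L)
  a <- features[labels == groups[1], , drop = FALSE]
  b <- features[labels == groups[2], , drop = FALSE]
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("need at least 2 subjects per group")
  tp <- vapply(seq_len(ncol(features)), function(j) {
    if (stats::sd(a[, j]) == 0 && stats::sd(b[, j]) == 0) {
      dm <- mean(a[, j]) - mean(b[, j])
      # zero-variance patch: identical constants carry no evidence,
      # different constants are an exact separation
      return(if (dm == 0) c(t = 0, p = 1) else c(t = sign(dm) * Inf, p = 0))
    }
    ht <- stats::t.test(a[, j], b[, j])
    c(t = unname(ht$statistic), p = ht$p.value)
  }, numeric(2))
  p_adj <- stats::p.adjust(tp[2, ], method = "BH")
  data.frame(patch = seq_len(ncol(features)), t = tp[1, ], p = tp[2, ],
             p_adj = p_adj, significant = p_adj < q)
}
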