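rot_z <- function(th) rbind(c(cos(th), -sin(th), 0),
                            c(sin(th), cos(th), 0),
                            c(0, 0, 1))

test_that("Kabsch alignment recovers a known rigid transform", {
  ic <- icosphere(1, radius = 10)
  mv <- ic$vertices
  idt <- rigid_align(mv, mv)
  expect_equal(idt$rotation, diag(3), tolerance = 1e-12)
  expect_equal(idt$translation, c(0, 0, 0), tolerance = 1e-12)

  R <- rot_z(pi / 6)
  t <- c(1, 2, 3)
  fx <- sweep(mv %*% t(R), 2, t, "+")
  tr <- rigid_align(mv, fx)
  expect_equal(tr$rotation, R, tolerance = 1e-9)
  expect_equal(tr$translation, t, tolerance = 1e-9)
  expect_lt(tr$rmsd, 1e-9)
})

test_that("alignment returns a proper rotation even for reflections", {
  ic <- icosphere(1, radius = 5)
  mv <- ic$vertices
  fx <- mv %*% diag(c(-1, 1, 1))      # mirrored point set
  tr <- rigid_align(mv, fx)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  expect_gt(tr$rmsd, 0.1)
  expect_error(rigid_align(cbind(1:5, 0, 0), cbind(2:6, 0, 0)), "collinear")
})

test_that("displacement fields remove rigid motion only when asked", {
  ic <- icosphere(2, radius = 10)
  same <- displacement_field(ic, ic)
  expect_equal(max(same$magnitudes), 0)

  shifted <- surface_mesh(sweep(ic$vertices, 2, c(3, 0, 0), "+"), ic$faces)
  on_ <- displacement_field(ic, shifted, prealign = TRUE)
  off <- displacement_field(ic, shifted, prealign = FALSE)
  expect_lt(max(on_$magnitudes), 1e-9)
  expect_equal(off$magnitudes, rep(3, nrow(ic$vertices)), tolerance = 1e-12)

  # general rigid motion is absorbed by the pre-alignment
  moved <- surface_mesh(sweep(ic$vertices %*% t(rot_z(0.7)), 2,
                              c(-2, 5, 1), "+"), ic$faces)
  inv <- displacement_field(ic, moved, prealign = TRUE)
  expect_lt(max(inv$magnitudes), 1e-6)
})

test_that("radial inflation produces a uniform outward signed field", {
  ic <- icosphere(3, radius = 10)
  target <- surface_mesh(ic$vertices * 1.05, ic$faces)
  fld <- displacement_field(ic, target, prealign = FALSE)
  expect_equal(fld$magnitudes, rep(0.5, nrow(ic$vertices)), tolerance = 1e-9)
  expect_true(all(fld$signed > 0.49))
  expect_true(all(abs(fld$signed) <= fld$magnitudes + 1e-9))
  expect_error(displacement_field(ic, icosphere(2, radius = 10)), "mismatch")
})

test_that("surface partitions are complete, nonempty and reproducible", {
  ic <- icosphere(2, radius = c(14, 8, 6))
  p1 <- partition_surface(ic, n_patches = 1L)
  expect_true(all(p1$assignment == 1L))

  pv <- partition_surface(ic, n_patches = nrow(ic$vertices))
  expect_equal(sort(unique(pv$assignment)), seq_len(nrow(ic$vertices)))

  p30a <- partition_surface(ic, n_patches = 30L, seed = 9L)
  p30b <- partition_surface(ic, n_patches = 30L, seed = 9L)
  expect_identical(p30a$assignment, p30b$assignment)
  expect_equal(sort(unique(p30a$assignment)), 1:30)   # none empty
  expect_error(partition_surface(ic, n_patches = 10000L), "exceeds")
})

test_that("patch averages preserve the global mean displacement", {
  ic <- icosphere(2, radius = 10)
  set.seed(8)
  vals <- runif(nrow(ic$vertices), 0, 4)
  part <- partition_surface(ic, n_patches = 25L, seed = 3L)
  pf <- patch_features(vals, part)
  # brute-force per-patch means
  expect_equal(unname(pf),
               as.numeric(tapply(vals, part$assignment,
                                 mean)[as.character(1:25)]))
  counts <- tabulate(part$assignment, 25L)
  expect_equal(sum(pf * counts) / sum(counts), mean(vals), tolerance = 1e-9)
  expect_true(all(pf >= min(vals) & pf <= max(vals)))
  cst <- patch_features(rep(2.5, nrow(ic$vertices)), part)
  expect_equal(unname(cst), rep(2.5, 25))
})

test_that("patch-wise group tests are calibrated under the null", {
  set.seed(42)
  n_rep <- 200L
  frac <- replicate(n_rep, {
    f <- matrix(rnorm(40 * 20), 40, 20)
    res <- patch_group_difference(f, rep(c("A", "B"), each = 20),
                                  c("A", "B"))
    mean(res$significant)
  })
  expect_lte(mean(frac), 0.05)
})

test_that("patch-wise group tests detect a strong focal shift", {
  set.seed(1)
  f <- matrix(rnorm(40 * 20), 40, 20)
  f[1:20, 7] <- f[1:20, 7] + 10        # 10 SD shift in one patch, group A
  res <- patch_group_difference(f, rep(c("A", "B"), each = 20), c("A", "B"))
  expect_true(res$significant[7])
  expect_lte(sum(res$significant[-7]), 1)

  dup <- rbind(f[1:5, ], f[1:5, ])     # identical group means
  res0 <- patch_group_difference(dup, rep(c("A", "B"), each = 5), c("A", "B"))
  expect_true(all(res0$t == 0))
  expect_false(any(res0$significant))
  expect_error(patch_group_difference(f[1:3, ], c("A", "A", "B"),
                                      c("A", "B")), "2 subjects")
})
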