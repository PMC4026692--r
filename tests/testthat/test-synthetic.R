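noiseless_spec <- function(...) {
  cohort_spec(group_sizes = c(NC = 2L, AD = 2L, FTD = 2L),
              semi_axes = c(10, 7, 6), scale_sd = 0,
              group_scale = c(NC = 1, AD = 1, FTD = 1),
              bump_amplitude = 0, jitter_sd = 0, icv_coupling = 0,
              mesh_subdiv = 2L, seed = 1L, ...)
}

test_that("a noiseless spec reproduces the template exactly", {
  spec <- noiseless_spec()
  s <- generate_subject(spec, "AD", seed = 5L, make_mask = FALSE)
  tmpl <- template_mesh(spec)
  expect_equal(s$mesh$vertices, tmpl$vertices, tolerance = 1e-12)
  fld <- displacement_field(tmpl, s$mesh)
  expect_lt(max(fld$magnitudes), 1e-9)
  expect_equal(s$bump_amplitude, 0)
})

test_that("controls never receive a focal bump", {
  spec <- cohort_spec(group_sizes = c(NC = 2L, AD = 2L, FTD = 2L),
                      semi_axes = c(10, 7, 6), mesh_subdiv = 2L, seed = 2L)
  s <- generate_subject(spec, "NC", seed = 9L, make_mask = FALSE)
  expect_equal(s$bump_amplitude, 0)
  sa <- generate_subject(spec, "AD", seed = 9L, make_mask = FALSE)
  expect_equal(sa$bump_amplitude, spec$bump_amplitude)
})

test_that("cohort generation is deterministic and complete", {
  spec <- cohort_spec(group_sizes = c(NC = 2L, AD = 3L, FTD = 2L),
                      semi_axes = c(9, 6, 5), mesh_subdiv = 2L, seed = 21L)
  a <- generate_cohort(spec, make_masks = FALSE)
  b <- generate_cohort(spec, make_masks = FALSE)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$meshes[["sub-004"]]$vertices,
                   b$meshes[["sub-004"]]$vertices)
  expect_equal(nrow(a$cohort), 7)
  expect_equal(as.vector(table(a$cohort$group)[c("NC", "AD", "FTD")]),
               c(2, 3, 2))
  # default spec carries the study's group sizes, 78 subjects in total
  dflt <- cohort_spec()
  expect_equal(unname(dflt$group_sizes[c("NC", "AD", "FTD")]),
               c(14L, 34L, 30L))
  expect_equal(sum(dflt$group_sizes), 78L)
})

test_that("cohort artefacts round-trip through the on-disk formats", {
  spec <- cohort_spec(group_sizes = c(NC = 2L, AD = 2L, FTD = 2L),
                      semi_axes = c(8, 6, 5), mesh_subdiv = 1L,
                      spacing = c(2, 2, 2), seed = 3L)
  dir <- tempfile()
  cd <- generate_cohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  tab <- read.csv(file.path(dir, "cohort.csv"))
  m <- read_mask(tab$mask_path[1])
  expect_identical(m$voxels, cd$masks[[tab$subject_id[1]]]$voxels)
  msh <- read_mesh(tab$mesh_path[3])
  expect_equal(msh$vertices, cd$meshes[[tab$subject_id[3]]]$vertices,
               tolerance = 1e-6)
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_true(all(c("true_scale", "true_bump_amplitude") %in% names(man)))
})

test_that("group volume distributions overlap by construction", {
  spec <- cohort_spec(group_sizes = c(NC = 30L, AD = 30L, FTD = 30L),
                      mesh_subdiv = 1L, seed = 17L)
  cd <- generate_cohort(spec, make_masks = FALSE)
  # volume scales as the cube of the drawn size factor
  vol <- cd$manifest$true_scale^3
  grp <- cd$manifest$group
  bc <- function(g1, g2) {
    m1 <- mean(vol[grp == g1]); s1 <- sd(vol[grp == g1])
    m2 <- mean(vol[grp == g2]); s2 <- sd(vol[grp == g2])
    sqrt(2 * s1 * s2 / (s1^2 + s2^2)) *
      exp(-(m1 - m2)^2 / (4 * (s1^2 + s2^2)))
  }
  expect_gt(bc("NC", "AD"), 0.5)
  expect_gt(bc("NC", "FTD"), 0.5)
  expect_gt(bc("AD", "FTD"), 0.5)
})

test_that("the two dementia-like groups deform opposite poles", {
  spec <- cohort_spec(mesh_subdiv = 2L, seed = 13L)
  cd <- generate_cohort(spec, make_masks = FALSE)
  tmpl <- cd$template
  u <- tmpl$vertices / sqrt(rowSums(tmpl$vertices^2))
  post <- order(u[, 1])[1:10]    # vertices nearest the posterior (AD) locus
  ant <- order(-u[, 1])[1:10]    # vertices nearest the anterior (FTD) locus
  signed_at <- function(id, idx) {
    fld <- displacement_field(tmpl, cd$meshes[[id]])
    mean(fld$signed[idx])
  }
  grp <- cd$cohort$group
  ids <- cd$cohort$subject_id
  post_ad <- vapply(ids[grp == "AD"], signed_at, numeric(1), idx = post)
  post_ftd <- vapply(ids[grp == "FTD"], signed_at, numeric(1), idx = post)
  ant_ad <- vapply(ids[grp == "AD"], signed_at, numeric(1), idx = ant)
  ant_ftd <- vapply(ids[grp == "FTD"], signed_at, numeric(1), idx = ant)
  expect_lt(t.test(post_ad, post_ftd, alternative = "greater")$p.value, 0.01)
  expect_lt(t.test(ant_ftd, ant_ad, alternative = "greater")$p.value, 0.01)
})

test_that("flagged group-difference patches concentrate at the bump loci", {
  acc <- acceptance_cohort()
  bio <- acc$bio
  labels <- acc$cd$cohort$group
  part <- bio$partition
  res <- patch_group_difference(
    t(apply(acc$bio$signed_fields, 1L, patch_features, partition = part)),
    labels, c("AD", "FTD"))
  expect_gt(sum(res$significant), 0)
  cen <- part$centroids
  ucen <- cen / sqrt(rowSums(cen^2))
  # equal-area patch angular radius on a closed surface: ~2/sqrt(N)
  two_radii <- 2 * (2 / sqrt(part$n_patches))
  near_locus <- acos(pmin(1, abs(ucen[, 1]))) <= two_radii
  expect_gte(mean(near_locus[res$significant]), 0.8)
})
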