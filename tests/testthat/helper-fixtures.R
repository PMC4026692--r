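# fixtures built in code; nothing on disk

# digitized ball of radius R0 voxels inside an (2*R0+4)^3 grid
ball_mask <- function(R0, spacing = c(1, 1, 1), pad = 2L) {
  n1 <- ceiling(2 * R0) + 2L * pad
  ctr <- (n1 + 1) / 2
  g <- expand.grid(x = seq_len(n1), y = seq_len(n1), z = seq_len(n1))
  fg <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= R0^2
  binary_mask(array(as.integer(fg), c(n1, n1, n1)), spacing = spacing)
}

# solid cube of side voxels
cube_mask <- function(side, spacing = c(1, 1, 1)) {
  binary_mask(array(1L, c(side, side, side)), spacing = spacing)
}

# three well-separated Gaussian clusters in feature space
separable_features <- function(n_per = 8L, p = 4L, gap = 10, seed = 1L) {
  set.seed(seed)
  centers <- matrix(c(0, gap, -gap), 3L, p)
  x <- do.call(rbind, lapply(1:3, function(g)
    matrix(rnorm(n_per * p, centers[g, 1]), n_per, p)))
  colnames(x) <- sprintf("f%d", seq_len(p))
  list(x = x, y = rep(c("A", "B", "C"), each = n_per))
}

# shared reduced-resolution synthetic cohort for the pipeline-level checks;
# built once per session (the masks and spectra dominate the cost)
acceptance_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      spec <- cohort_spec(spacing = c(1.5, 1.5, 1.5), seed = 11L)
      cd <- generate_cohort(spec)
      bio <- extract_biomarkers(cd, n_eigen = 25L, n_patches = 60L)
      memo <<- list(cd = cd, bio = bio)
    }
    memo
  }
})

reduced_grid <- function() default_grid(log10_C = -1:3, log10_gamma = -2:1)
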