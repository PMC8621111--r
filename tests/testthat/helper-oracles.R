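# Independent numeric oracles used to validate the package's
# superposition and scoring code. These deliberately avoid kabsch_fit()
# and pca_rmsd(): rotations come from a quaternion grid plus local
# refinement, and the symmetry score from a plain double loop.

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# minimum RMSD of a onto b over all proper rotations + translations,
# by quaternion-grid search refined with Nelder-Mead
brute_force_rmsd <- function(a, b, n_grid = 2000) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rmsd_rot <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((a %*% t(R) - b)^2)))
  }
  set.seed(4242)
  quats <- rbind(c(1, 0, 0, 0),
                 matrix(rnorm(4 * n_grid), ncol = 4))
  vals <- apply(quats, 1, rmsd_rot)
  best <- quats[which.min(vals), ]
  opt <- optim(best, rmsd_rot, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  opt2 <- optim(opt$par, rmsd_rot, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 5000))
  min(vals[which.min(vals)], opt$value, opt2$value)
}

# Eq.-style ordered double sum over all chain pairs, with bio3d doing
# the per-pair superposition (independent of the package's Kabsch code)
double_loop_pcarmsd <- function(model) {
  M <- n_chains(model)
  total <- 0
  for (i in seq_len(M))
    for (j in seq_len(M))
      if (i != j) {
        a <- as.vector(t(model$chains[[i]]$ca))
        b <- as.vector(t(model$chains[[j]]$ca))
        fitted <- bio3d::fit.xyz(fixed = b, mobile = a,
                                 fixed.inds = seq_along(b),
                                 mobile.inds = seq_along(a))
        total <- total + sqrt(sum((fitted - b)^2) / (length(b) / 3))
      }
  total / (M^2 - M)
}

# arbitrary (but reproducible) rigid motion for invariance tests
random_rigid <- function(seed) {
  set.seed(seed)
  rigid_transform(quat_to_rot(rnorm(4)), rnorm(3, sd = 10))
}

# model with per-atom Gaussian jitter (CA and backbone), independent of
# the generator's own noise path
jitter_model <- function(model, sigma, seed) {
  set.seed(seed)
  model$chains <- lapply(model$chains, function(ch) {
    for (at in c("ca", "n", "c", "o"))
      if (!is.null(ch[[at]]))
        ch[[at]] <- ch[[at]] + matrix(rnorm(length(ch[[at]]), sd = sigma),
                                      ncol = 3)
    ch
  })
  model
}

# small protofilament used across tests
toy_protofilament <- function(n_chains = 5, rise = 4.47, twist = 9,
                              sigma = 0, seed = NULL)
  make_fibril(n_chains = n_chains, rise = rise, twist = twist,
              noise_sigma = sigma, seed = seed)
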