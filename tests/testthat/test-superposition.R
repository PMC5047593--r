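test_that("atoms pair on identity and substituted side chains drop out", {
  m <- generate_chain(2 + 8 %/% 5, seed = 1)          # 10 atoms
  p <- pair_atoms(m, m)
  expect_equal(nrow(p), n_atoms(m))
  expect_equal(attr(p, "n_unpaired_wt"), 0L)
  expect_equal(attr(p, "n_unpaired_mut"), 0L)

  dn <- asp_asn_pair()
  p2 <- pair_atoms(dn$wt, dn$mut)
  paired45 <- dn$wt$atoms$atom_name[p2$wt_index][
    dn$wt$atoms$residue_number[p2$wt_index] == 45L]
  expect_setequal(paired45, c("N", "CA", "C", "O", "CB", "CG", "OD1"))
  expect_equal(attr(p2, "n_unpaired_wt"), 1L)   # OD2
  expect_equal(attr(p2, "n_unpaired_mut"), 1L)  # ND2

  other <- m
  other$atoms$chain_id <- "B"
  expect_error(pair_atoms(m, other), "no atoms in common")
})

test_that("rigid motions are recovered exactly and inverted", {
  wt <- generate_chain(15, "helix", seed = 2)
  sp0 <- superpose(wt, wt)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(unname(sp0$translation), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sp0$fit_rmsd_ca, 0, tolerance = 1e-9)

  R <- rot_axis(c(0, 0, 1), pi / 2)
  mut <- apply_rigid(wt, R, c(1, 1, 1))
  sp <- superpose(wt, mut)
  expect_lt(sp$fit_rmsd_ca, 1e-9)
  # recovered transform is orthonormal with det +1 and inverts the motion
  expect_equal(t(sp$rotation) %*% sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  back <- apply_transform(mut, sp)
  expect_equal(coords(back), coords(wt), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the fitted RMSD matches a brute-force rigid-fit oracle", {
  wt <- ca_model(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0)))
  mut <- ca_model(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1.2, 0)))
  sp <- superpose(wt, mut)

  # independent oracle: numeric minimisation over Euler angles and
  # translation, multiple starts
  P <- coords(wt)
  Q <- coords(mut)
  obj <- function(par) {
    R <- rot_axis(c(1, 0, 0), par[1]) %*% rot_axis(c(0, 1, 0), par[2]) %*%
      rot_axis(c(0, 0, 1), par[3])
    Qt <- sweep(Q %*% t(R), 2L, par[4:6], `+`)
    sqrt(mean(rowSums((Qt - P)^2)))
  }
  set.seed(11)
  best <- Inf
  for (k in 1:20) {
    start <- c(stats::runif(3, -pi, pi), stats::rnorm(3, 0, 0.5))
    fit <- stats::optim(start, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  expect_equal(sp$fit_rmsd_ca, best, tolerance = 1e-6)
  expect_gt(sp$fit_rmsd_ca, 0)
})

test_that("the Kabsch fit is optimal against random rigid transforms", {
  wt <- generate_chain(12, seed = 4)
  p <- perturb_structure(wt, data.frame(residue_number = c(3L, 9L),
                                        magnitude = c(0.4, 0.6)),
                         seed = 8)
  pairing <- pair_atoms(wt, p$model)
  sp <- superpose(wt, p$model, pairing)
  is_ca <- wt$atoms$atom_name[pairing$wt_index] == "CA"
  P <- coords(wt)[pairing$wt_index[is_ca], ]
  Q <- coords(p$model)[pairing$mut_index[is_ca], ]
  set.seed(21)
  for (k in 1:300) {
    R <- random_rotation()
    tv <- stats::rnorm(3, 0, 2)
    rmsd_k <- sqrt(mean(rowSums((sweep(Q %*% t(R), 2, tv, `+`) - P)^2)))
    expect_gte(rmsd_k, sp$fit_rmsd_ca - 1e-12)
  }
})

test_that("fit and displacements are invariant to pre-applied rigid motion and symmetric", {
  wt <- generate_chain(14, "helix", seed = 6)
  mut <- perturb_structure(wt, data.frame(residue_number = 7L,
                                          magnitude = 0.5),
                           seed = 3)$model
  pert0 <- perturbation(wt, mut)

  set.seed(31)
  moved <- apply_rigid(mut, random_rotation(), stats::rnorm(3, 0, 5))
  pert1 <- perturbation(wt, moved)
  expect_equal(pert1$superposition$fit_rmsd_ca,
               pert0$superposition$fit_rmsd_ca, tolerance = 1e-6)
  expect_equal(pert1$displacements$displacement,
               pert0$displacements$displacement, tolerance = 1e-6)

  expect_equal(superpose(mut, wt)$fit_rmsd_ca,
               superpose(wt, mut)$fit_rmsd_ca, tolerance = 1e-9)
})

test_that("superposition agrees with an established reference implementation", {
  skip_if_not_installed("bio3d")
  wt <- generate_chain(10, "helix", seed = 13)
  mut <- perturb_structure(wt, data.frame(residue_number = 5L,
                                          magnitude = 0.8),
                           seed = 14)$model
  pairing <- pair_atoms(wt, mut)
  sp <- superpose(wt, mut, pairing)
  is_ca <- wt$atoms$atom_name[pairing$wt_index] == "CA"
  P <- coords(wt)[pairing$wt_index[is_ca], ]
  Q <- coords(mut)[pairing$mut_index[is_ca], ]
  fitted <- bio3d::fit.xyz(as.vector(t(P)), as.vector(t(Q)),
                           fixed.inds = seq_len(length(P)),
                           mobile.inds = seq_len(length(Q)))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3,
                                        byrow = TRUE) - P)^2)))
  expect_equal(sp$fit_rmsd_ca, ref_rmsd, tolerance = 1e-6)
})

test_that("degenerate C-alpha sets are rejected", {
  wt <- ca_model(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_error(superpose(wt, wt), "collinear")
  two <- ca_model(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(superpose(two, two), ">= 3")
})

test_that("displacements are plain per-pair Euclidean distances", {
  wt <- generate_chain(6, seed = 10)
  pairing <- pair_atoms(wt, wt)
  d0 <- compute_displacements(wt, wt, pairing)
  expect_true(all(d0$displacement == 0))

  mut <- wt
  i <- which(mut$atoms$atom_name == "CB")[2]
  mut$atoms$x[i] <- mut$atoms$x[i] + 0.3
  d1 <- compute_displacements(wt, mut, pairing)
  expect_equal(d1$displacement[d1$wt_index == i], 0.3)
  expect_true(all(d1$displacement[d1$wt_index != i] == 0))
})
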