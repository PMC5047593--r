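test_that("affected-atom counting is strict at the cutoff and region-aware", {
  m <- generate_chain(10, seed = 1)   # residues 1..10, no active site
  nA <- n_atoms(m)
  zero <- data.frame(wt_index = seq_len(nA), displacement = 0)
  expect_equal(count_affected(zero, m),
               list(n_main_chain = 0L, n_side_chain = 0L,
                    n_active_site = 0L))

  # 10 main-chain atoms at 0.20, everything else untouched
  d <- rep(0, nA)
  main_idx <- which(classify_atom(m$atoms$atom_name) == "main_chain")[1:10]
  d[main_idx] <- 0.20
  cnt <- count_affected(d, m)
  expect_equal(cnt$n_main_chain, 10L)
  expect_equal(cnt$n_side_chain, 0L)
  expect_equal(cnt$n_active_site, 0L)

  # displacement of exactly the cutoff is NOT affected ("more than")
  d[main_idx] <- 0.15
  expect_equal(count_affected(d, m)$n_main_chain, 0L)
  d[main_idx] <- 0.15 + 1e-9
  expect_equal(count_affected(d, m)$n_main_chain, 10L)
})

test_that("active-site counting follows residue membership of either class", {
  m <- generate_chain(50, seed = 2)   # residues include 45 and 46
  d <- rep(0, n_atoms(m))
  in_as <- which(m$atoms$residue_number %in% c(45L, 46L))
  d[in_as] <- 0.3
  cnt <- count_affected(d, m)
  expect_equal(cnt$n_active_site, length(in_as))
  expect_equal(cnt$n_main_chain + cnt$n_side_chain, length(in_as))

  # direct recount oracle from the affected-atom list
  affected <- d > 0.15
  expect_equal(cnt$n_active_site,
               sum(affected & m$atoms$residue_number %in% ids_active_site()))
})

test_that("raising the cutoff never increases any affected count", {
  m <- generate_chain(20, seed = 3)
  set.seed(7)
  d <- stats::rexp(n_atoms(m), rate = 8)
  prev <- c(Inf, Inf, Inf)
  for (cutoff in c(0.05, 0.1, 0.15, 0.25, 0.5, 1)) {
    cnt <- count_affected(d, m, cutoff = cutoff)
    now <- c(cnt$n_main_chain, cnt$n_side_chain, cnt$n_active_site)
    expect_true(all(now <= prev))
    prev <- now
  }
})

test_that("all-atom RMSD follows the closed form and scales linearly", {
  expect_equal(rmsd_all_atoms(c(0, 0, 0)), 0)
  expect_equal(rmsd_all_atoms(c(0.3, 0.4)), sqrt((0.09 + 0.16) / 2))
  expect_equal(round(rmsd_all_atoms(c(0.3, 0.4)), 4), 0.3536)
  expect_error(rmsd_all_atoms(numeric(0)), "empty")

  set.seed(12)
  d <- stats::runif(40, 0, 0.6)
  for (c_scale in c(0.5, 2, 7.3)) {
    expect_equal(rmsd_all_atoms(c_scale * d), c_scale * rmsd_all_atoms(d))
  }
})

test_that("a rigidly moved copy yields an all-zero report", {
  wt <- generate_chain(12, "helix", seed = 4)
  moved <- apply_rigid(wt, rot_axis(c(1, 2, 3), 0.7), c(-2, 5, 1))
  pert <- perturbation(wt, moved)
  expect_equal(pert$n_main_chain, 0L)
  expect_equal(pert$n_side_chain, 0L)
  expect_equal(pert$n_active_site, 0L)
  expect_lt(pert$rmsd_all_atoms, 1e-9)
  expect_equal(pert$n_pairs, n_atoms(wt))
})

test_that("a constructed displacement field is recovered region by region", {
  # 140 residues (N, CA, C, O, CB): displace N/C/O of residues 1-7 and of
  # active-site residues 45, 46, 84 (30 main-chain atoms) plus the CB of
  # 45, 46, 84, 135 and of residues 90-125 (40 side-chain atoms); 13 of
  # the 70 sit in active-site residues. C-alpha atoms stay put, so the
  # fit is the identity and the intended 0.2 Angstrom is realised exactly.
  wt <- generate_chain(140, seed = 5)
  a <- wt$atoms
  main_res <- c(1:7, 45L, 46L, 84L)
  side_res <- c(45L, 46L, 84L, 135L, 90:125)
  idx <- c(which(a$residue_number %in% main_res &
                   a$atom_name %in% c("N", "C", "O")),
           which(a$residue_number %in% side_res & a$atom_name == "CB"))
  expect_length(idx, 70L)

  mut <- wt
  set.seed(99)
  for (i in idx) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    mut$atoms$x[i] <- mut$atoms$x[i] + 0.2 * u[1]
    mut$atoms$y[i] <- mut$atoms$y[i] + 0.2 * u[2]
    mut$atoms$z[i] <- mut$atoms$z[i] + 0.2 * u[3]
  }
  pert <- perturbation(wt, mut)
  expect_equal(pert$n_main_chain, 30L)
  expect_equal(pert$n_side_chain, 40L)
  expect_equal(pert$n_active_site, 13L)
  expect_equal(pert$rmsd_all_atoms, sqrt(70 * 0.2^2 / n_atoms(wt)),
               tolerance = 1e-9)
  expect_equal(pert$n_pairs, n_atoms(wt))
  expect_equal(pert$n_unpaired, 0L)

  # internal consistency: counts equal a recount over the per-atom table
  tab <- pert$displacements
  expect_equal(pert$n_main_chain,
               sum(tab$affected & tab$atom_class == "main_chain"))
  expect_equal(pert$n_active_site,
               sum(tab$affected &
                     tab$residue_number %in% ids_active_site()))
})

test_that("report invariants hold on seeded random perturbations", {
  for (seed in 1:5) {
    wt <- generate_chain(30, seed = seed)
    spec <- data.frame(residue_number = c(5L, 14L, 23L),
                       atom_class = c("any", "side_chain", "main_chain"),
                       magnitude = c(0.3, 0.18, 0.5))
    p <- perturb_structure(wt, spec, seed = seed + 100)
    pert <- perturbation(wt, p$model)
    expect_gte(pert$rmsd_all_atoms, 0)
    expect_lte(pert$n_active_site, pert$n_main_chain + pert$n_side_chain)
    expect_equal(sum(pert$displacements$affected),
                 pert$n_main_chain + pert$n_side_chain)
  }
})
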