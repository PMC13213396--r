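# SASA / BSA closed forms, interface RMSD, contacts, shortlisting.

test_that("Shrake-Rupley SASA matches sphere closed forms within 2%", {
  r <- 1.9; w <- 1.4; R <- r + w
  # isolated sphere
  s1 <- sasa(matrix(0, 1, 3), r, probe = w, n_points = 960)
  expect_equal(s1, 4 * pi * R^2, tolerance = 0.02)
  # fully separated pair: no occlusion
  s2 <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), c(r, r), probe = w, 960)
  expect_equal(s2, rep(4 * pi * R^2, 2), tolerance = 0.02)
  # overlapping pair: analytic two-sphere lens (equal radii, distance d):
  # each sphere loses a cap of height h = R - d/2
  d <- 3.5
  s3 <- sum(sasa(rbind(c(0, 0, 0), c(d, 0, 0)), c(r, r), probe = w, 960))
  h <- R - d / 2
  exact <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(s3, exact, tolerance = 0.02)
  # resolution convergence: 960 vs 4000 points within 2% per atom
  withr::with_seed(12, X <- matrix(rnorm(60, sd = 4), ncol = 3))
  radii <- rep(c(1.7, 1.55, 1.52, 1.8), 5)
  a960 <- sasa(X, radii, n_points = 960)
  a4000 <- sasa(X, radii, n_points = 4000)
  rel <- abs(a960 - a4000) / (4 * pi * (radii + 1.4)^2)
  expect_lt(max(rel), 0.02)
  # coincident atoms do not crash
  expect_no_error(sasa(matrix(0, 2, 3), c(1.7, 1.7)))
})

test_that("BSA vanishes for separated chains and is chain-symmetric", {
  XA <- cbind(seq(0, 18, by = 2), 0, 0)
  XB_far <- cbind(seq(0, 18, by = 2), 100, 0)
  XB_near <- cbind(seq(1, 19, by = 2), 4.5, 0)
  chains <- rep(c("A", "B"), each = 10)
  far <- bead_ensemble(rbind(XA, XB_far), chains)
  expect_lt(bsa(far, 1), 0.1)
  near <- bead_ensemble(rbind(XA, XB_near), chains)
  b1 <- bsa(near, 1)
  expect_gt(b1, 0)
  # high-resolution recomputation agrees within 2%
  expect_equal(b1, bsa(near, 1, n_points = 4000), tolerance = 0.02)
  # relabeling chains leaves BSA unchanged
  swapped <- bead_ensemble(rbind(XB_near, XA), rep(c("A", "B"), each = 10))
  expect_equal(b1, bsa(swapped, 1), tolerance = 1e-6)
  # doubling the probe changes BSA without a sign flip
  expect_gte(bsa(near, 1, probe = 2.8), 0)
  # single-chain frame is an error
  expect_error(bsa(bead_ensemble(XA, rep("A", 10)), 1), "two chains")
})

test_that("interface RMSD is zero under identity and rigid motion", {
  spec <- toy_interface_spec()
  sim <- gen_interface_ensemble(
    interface_ensemble_spec(spec$chain_templates,
                            list(list(R = diag(3), t = c(9, 0, 0))),
                            matrix(1, 1, 1), jitter_sigma = 0),
    n_frames = 3, seed = 1)
  ens <- sim$ensemble
  expect_lt(interface_rmsd(ens, 1, frames = 1)$mean, 1e-10)
  # rigid whole-complex motion of a frame: still ~0 after superposition
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- ens
  moved$coords[, , 2] <- sweep(moved$coords[, , 2] %*% t(Rz), 2, c(5, -3, 2), `+`)
  expect_lt(interface_rmsd(moved, 1, frames = 2)$mean, 1e-6)
})

test_that("interface RMSD matches an independent superposition oracle", {
  # chain B shifted 2 A along x in the scored frame; oracle: numerical
  # minimization of the chain-A-interface RMSD over rotations+translations
  spec <- toy_interface_spec(n_res_a = 8, n_res_b = 6, n_sites = 1)
  tmpl <- spec$chain_templates
  X0 <- as.matrix(tmpl[, c("x", "y", "z")])
  isB <- tmpl$chain == "B"
  X1 <- X0; X1[isB, 1] <- X1[isB, 1] + 6  # reference: B docked at +6 x
  X2 <- X1; X2[isB, 1] <- X2[isB, 1] + 2  # frame: B shifted 2 A more
  atoms <- tmpl[, setdiff(names(tmpl), c("x", "y", "z"))]
  ens <- structure_ensemble(array(c(X1, X2), c(nrow(tmpl), 3, 2)), atoms)
  got <- interface_rmsd(ens, 1, frames = 2, interface_cutoff = 12)$mean

  # oracle: brute-force rigid fit by optim over (angles, translation)
  at <- atoms
  ia <- which(at$chain == "A"); ib <- which(at$chain == "B")
  d <- as.matrix(dist(X1))[ia, ib]
  resA <- unique(at$residue[ia][apply(d < 12, 1, any)])
  resB <- unique(at$residue[ib][apply(d < 12, 2, any)])
  fitA <- which(at$chain == "A" & at$residue %in% resA)
  cas <- which(at$is_ca & ((at$chain == "A" & at$residue %in% resA) |
                             (at$chain == "B" & at$residue %in% resB)))
  rotmat <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rx %*% Ry %*% Rz
  }
  obj <- function(p) {
    Y <- sweep(X2 %*% t(rotmat(p[1:3])), 2, p[4:6], `+`)
    mean(rowSums((Y[fitA, ] - X1[fitA, ])^2))
  }
  opt <- optim(rep(0, 6), obj, method = "BFGS")
  Y <- sweep(X2 %*% t(rotmat(opt$par[1:3])), 2, opt$par[4:6], `+`)
  oracle <- sqrt(mean(rowSums((Y[cas, ] - X1[cas, ])^2)))
  expect_equal(got, oracle, tolerance = 0.02)
})

test_that("contact frequencies match thresholds and a counting oracle", {
  mk <- function(dy) {
    XA <- rbind(c(0, 0, 0))
    XB <- rbind(c(0, dy, 0))
    bead_ensemble(rbind(XA, XB), c("A", "B"))
  }
  expect_equal(as.numeric(contact_frequency(mk(4.0), cutoff = 4.5)$frequency), 1.0)
  expect_equal(as.numeric(contact_frequency(mk(5.0), cutoff = 4.5)$frequency), 0.0)

  # jittered fixture vs direct double-loop enumeration
  spec <- toy_interface_spec(n_res_a = 6, n_res_b = 5, n_sites = 1)
  sim <- gen_interface_ensemble(
    interface_ensemble_spec(spec$chain_templates,
                            list(list(R = diag(3), t = c(8, 0, 0))),
                            matrix(1, 1, 1), jitter_sigma = 0.8),
    n_frames = 60, seed = 5)
  cf <- contact_frequency(sim$ensemble, cutoff = 4.5)
  at <- sim$ensemble$atoms
  ia <- which(at$chain == "A"); ib <- which(at$chain == "B")
  resA <- sort(unique(at$residue[ia])); resB <- sort(unique(at$residue[ib]))
  naive <- matrix(0, length(resA), length(resB))
  for (f in 1:60) {
    X <- sim$ensemble$coords[, , f]
    for (a in seq_along(resA)) for (b in seq_along(resB)) {
      aa <- ia[at$residue[ia] == resA[a]]
      bb <- ib[at$residue[ib] == resB[b]]
      dmin <- min(sqrt(outer(rowSums(X[aa, , drop = FALSE]^2),
                             rowSums(X[bb, , drop = FALSE]^2), `+`) -
                         2 * tcrossprod(X[aa, , drop = FALSE],
                                        X[bb, , drop = FALSE])))
      if (dmin < 4.5) naive[a, b] <- naive[a, b] + 1
    }
  }
  expect_equal(unname(cf$frequency), naive / 60, tolerance = 1e-12)
  # class fractions sum to 1 when contacts exist
  expect_equal(sum(cf$class_fractions$A), 1)
  expect_equal(sum(cf$class_fractions$B), 1)

  # atom-order invariance
  perm <- rev(seq_len(nrow(at)))
  ens2 <- structure_ensemble(sim$ensemble$coords[perm, , , drop = FALSE],
                             at[perm, ])
  cf2 <- contact_frequency(ens2, cutoff = 4.5)
  expect_equal(cf$frequency, cf2$frequency, tolerance = 1e-12)
})

test_that("representative structure follows population and tie rules", {
  proj <- matrix(c(0, 0, 1, 1.4, 10, 10.4), ncol = 1)
  labels <- c(1L, 1L, 1L, 1L, 2L, 2L)
  # microstate 1 more populated: center of its frames ~0.6 -> frame 3
  expect_equal(representative_structure(proj, labels, c(0.7, 0.3)), 3L)
  # tie: lower microstate index wins
  expect_equal(representative_structure(proj, labels, c(0.5, 0.5)), 3L)
  # single frame
  expect_equal(representative_structure(matrix(1), 1L, 1), 1L)
  expect_error(representative_structure(matrix(0, 0, 1), integer(0), 1),
               "no frames")
})

test_that("shortlisting separates heterogeneous and weakly buried states", {
  # six states: all populated > 5%, one
  # heterogeneous (iRMSD 12 A), two weakly buried -> exactly 4 pass
  mk_report <- function(id, irmsd, bsa_m, pop) {
    structure(list(state = id, population = pop, representative_frame = 1L,
                   irmsd_mean = irmsd, irmsd_sd = 0.5,
                   bsa_mean = bsa_m, bsa_sd = 10,
                   contact_frequency = NULL, residue_class_fractions = NULL),
              class = "StateInterfaceReport")
  }
  reports <- list(
    mk_report("I", 4, 600, 0.28), mk_report("II", 5, 150, 0.09),
    mk_report("III", 3, 650, 0.22), mk_report("IV", 6, 550, 0.16),
    mk_report("V", 5, 500, 0.15), mk_report("VI", 12, 180, 0.10))
  sl <- shortlist_states(reports)
  expect_equal(sl$state[sl$pass], c("I", "III", "IV", "V"))
  expect_match(sl$reasons[sl$state == "VI"], "heterogeneity")
  expect_match(sl$reasons[sl$state == "II"], "burial")

  # all identical and passing
  same <- replicate(3, mk_report("x", 3, 500, 0.3), simplify = FALSE)
  expect_true(all(shortlist_states(same)$pass))

  # population threshold edge
  edge <- list(mk_report("lo", 3, 500, 0.04), mk_report("hi", 3, 500, 0.5))
  sle <- shortlist_states(edge)
  expect_false(sle$pass[1])
  expect_match(sle$reasons[1], "population")
})
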