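# Membrane-trajectory analytics.

test_that("trajectory IO: multi-model frames, stride, coordinate round trip", {
  g <- gen_membrane_trajectory(n_frames = 5, seed = 31)
  top_f <- withr::local_tempfile(fileext = ".gro")
  frm_f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(g$traj, top_f, frm_f)
  t2 <- read_trajectory(top_f, frm_f)
  expect_equal(nrow(t2$xyz), 5)
  expect_equal(nrow(t2$topology), nrow(g$traj$topology))
  expect_equal(t2$topology$segment, g$traj$topology$segment)
  # PDB frame precision: 3 decimals
  expect_lt(max(abs(t2$xyz - g$traj$xyz)), 5.5e-4)
  # stride keeps every n-th frame
  g100 <- gen_membrane_trajectory(n_frames = 100, seed = 32)
  write_trajectory(g100$traj, top_f, frm_f)
  t10 <- read_trajectory(top_f, frm_f, stride = 10)
  expect_equal(nrow(t10$xyz), 10)
  expect_equal(t10$dt_ns, 10)
  expect_equal(t10$xyz[2, ], g100$traj$xyz[11, ], tolerance = 5.5e-4)
})

test_that("atom-count mismatch between topology and frames is an error", {
  g5 <- gen_membrane_trajectory(n_frames = 2, seed = 33)
  gBig <- gen_membrane_trajectory(n_frames = 2, n_lipids = c(LPG = 10, PG = 4),
                                  seed = 33)
  top_f <- withr::local_tempfile(fileext = ".gro")
  frm_f <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(g5$traj, top_f, "/dev/null")
  write_trajectory(gBig$traj, withr::local_tempfile(fileext = ".gro"), frm_f)
  expect_error(read_trajectory(top_f, frm_f), "mismatch")
})

test_that("leaflet assignment splits by the per-frame midplane", {
  # two lipids at +-20 around the midplane
  top <- data.frame(eleno = 1:2, elety = "PO4", resid = "LPG",
                    resno = 1:2, chain = "L", segment = "lipid", elesy = "P")
  xyz <- matrix(c(0, 0, 20, 0, 0, -20), 1)
  t <- trajectory(top, xyz, dt_ns = 1)
  la <- assign_leaflets(t)
  expect_equal(as.character(la$labels[1, ]), c("upper", "lower"))
  # identical z: strict inequality sends everything lower, with a warning
  t2 <- trajectory(top, matrix(c(0, 0, 5, 0, 0, 5), 1), dt_ns = 1)
  expect_warning(la2 <- assign_leaflets(t2), "midplane")
  expect_equal(as.character(la2$labels[1, ]), c("lower", "lower"))
  # generated bilayer: assignments match the planted labels in every frame
  g <- gen_membrane_trajectory(n_frames = 20, seed = 34)
  la3 <- assign_leaflets(g$traj)
  planted <- g$manifest$leaflets
  for (f in c(1, 10, 20)) {
    got <- la3$labels[f, match(planted$resno, la3$lipids$resno)]
    expect_equal(unname(got), planted$leaflet)
  }
})

test_that("residency grid: point mass, conservation, pocket recovery", {
  # a single immobile headgroup occupies exactly one bin with density 1
  top <- data.frame(eleno = 1:3,
                    elety = c("BB", "PO4", "PO4"),
                    resid = c("ALA", "LPG", "LPG"),
                    resno = 1:3, chain = c("P", "L", "L"),
                    segment = c("protein", "lipid", "lipid"), elesy = c("C", "P", "P"))
  xyz <- matrix(rep(c(0, 0, 0,  5, 5, 10,  -40, -40, -10), 50), 50, 9, byrow = TRUE)
  t <- trajectory(top, xyz, dt_ns = 1)
  grid <- residency_histogram(t, "LPG", "upper", stride = 1)
  expect_equal(sum(grid$counts == 50), 1)
  expect_equal(max(grid$density), 1)
  expect_equal(sum(grid$density > 0), 1)
  # conservation: counts + dropped = all strided headgroup observations
  g <- gen_membrane_trajectory(n_frames = 100, pocket_occupancy = 0.4, seed = 35)
  gr <- residency_histogram(g$traj, "LPG", "upper", stride = 10)
  n_upper_lpg <- sum(g$manifest$leaflets$resid == "LPG" &
                     g$manifest$leaflets$leaflet == "upper")
  expect_equal(sum(gr$counts) + gr$dropped, length(gr$frames) * n_upper_lpg)
  expect_equal(gr$n_obs, length(gr$frames) * n_upper_lpg)
  # argmax bin sits inside the planted pocket footprint
  gr1 <- residency_histogram(g$traj, "LPG", "upper", stride = 1)
  am <- which(gr1$counts == max(gr1$counts), arr.ind = TRUE)[1, ]
  bx <- (gr1$x_edges[am[1]] + gr1$x_edges[am[1] + 1]) / 2
  by <- (gr1$y_edges[am[2]] + gr1$y_edges[am[2] + 1]) / 2
  expect_lt(sqrt(sum((c(bx, by) - g$manifest$pocket_center)^2)), 5)
  # unknown lipid types are rejected with the present types listed
  expect_error(residency_histogram(g$traj, "CHOL", "upper"), "LPG")
})

test_that("uniform headgroup positions fill the grid uniformly (multinomial bounds)", {
  set.seed(36)
  n_lip <- 250; n_frames <- 400
  half <- 37.5
  # one protein bead, the uniform upper-leaflet lipids, plus one
  # lower-leaflet lipid that keeps the midplane below the slab
  top <- rbind(
    data.frame(eleno = 1, elety = "BB", resid = "ALA", resno = 1,
               chain = "P", segment = "protein", elesy = "C"),
    data.frame(eleno = 1 + seq_len(n_lip + 1), elety = "PO4", resid = "LPG",
               resno = 1 + seq_len(n_lip + 1), chain = "L", segment = "lipid",
               elesy = "P"))
  xyz <- matrix(0, n_frames, 3 * (n_lip + 2))
  for (f in seq_len(n_frames)) {
    xs <- runif(n_lip, -half, half); ys <- runif(n_lip, -half, half)
    coords <- rbind(c(0, 0, 0), cbind(xs, ys, 20), c(0, 0, -20))
    xyz[f, ] <- as.numeric(t(coords))
  }
  t <- trajectory(top, xyz, dt_ns = 1)
  grid <- residency_histogram(t, "LPG", "upper", stride = 1,
                              center = c(0, 0))
  n <- sum(grid$counts)
  expect_equal(n + grid$dropped, n_lip * n_frames)
  p <- 1 / 900
  expected <- n * p
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(max(abs(grid$counts - expected)), 4.5 * sigma)
})

test_that("analytics are invariant to a uniform xy translation of every frame", {
  g <- gen_membrane_trajectory(n_frames = 40, pocket_occupancy = 0.5, seed = 37)
  t2 <- g$traj
  shift <- rep(c(13, -7, 0), nrow(t2$topology))
  t2$xyz <- sweep(t2$xyz, 2, -shift)   # add (13, -7, 0) to every atom
  g1 <- residency_histogram(g$traj, "LPG", "upper", stride = 2)
  g2 <- residency_histogram(t2, "LPG", "upper", stride = 2)
  expect_equal(g2$counts, g1$counts)
  p1 <- contact_propensity(g$traj, g$manifest$tagged_lipid,
                           residues = g$manifest$pocket_residues)
  p2 <- contact_propensity(t2, g$manifest$tagged_lipid,
                           residues = g$manifest$pocket_residues)
  expect_equal(p2$propensity, p1$propensity)
})

test_that("z-trace is flat at the midplane and recovers a planted extraction", {
  # lipid pinned to the midplane
  top <- data.frame(eleno = 1:2, elety = "PO4", resid = c("LPG", "PG"),
                    resno = 1:2, chain = "L", segment = "lipid", elesy = "P")
  xyz <- matrix(rep(c(0, 0, 10, 0, 0, -10), 20), 20, 6, byrow = TRUE)
  t <- trajectory(top, xyz, dt_ns = 1)
  tr <- z_trace(t, 1)
  expect_equal(tr$z, rep(10, 20))     # midplane at 0, head at +10
  # planted 15 A extraction over the last third
  g <- gen_membrane_trajectory(n_frames = 90, pocket_occupancy = 0.3,
                               extraction = list(start_frame = 60, rise = 15),
                               seed = 38)
  tr2 <- z_trace(g$traj, g$manifest$tagged_lipid)
  rise <- mean(tail(tr2$z, 3)) - mean(head(tr2$z, 3))
  expect_equal(rise, 15, tolerance = 1)
  # stride halves the trace
  tr3 <- z_trace(g$traj, g$manifest$tagged_lipid, stride = 2)
  expect_equal(nrow(tr3), 45)
})

test_that("contact propensity equals the planted schedule exactly", {
  g <- gen_membrane_trajectory(n_frames = 60, pocket_occupancy = 0.5, seed = 39)
  cp <- contact_propensity(g$traj, g$manifest$tagged_lipid,
                           residues = g$manifest$pocket_residues)
  expect_equal(cp$propensity, rep(0.5, 3))
  expect_equal(cp$n_contact, rep(length(g$manifest$contact_frames), 3))
  # never-near lipid: zero everywhere
  far_lipids <- setdiff(g$manifest$leaflets$resno[g$manifest$leaflets$resid == "PE"],
                        g$manifest$tagged_lipid)
  cp0 <- contact_propensity(g$traj, far_lipids[1],
                            residues = g$manifest$pocket_residues)
  expect_true(all(cp0$propensity == 0))
  expect_error(contact_propensity(g$traj, 99999), "lipid")
})

test_that("RMSF and RMSD behave under static, tumbling and jittered motion", {
  g <- gen_membrane_trajectory(n_frames = 10, jitter_sigma = 0, seed = 40)
  sel <- select_atoms(g$traj, segment = "protein")
  expect_true(all(rmsf(g$traj, sel)$rmsf < 1e-12))
  expect_true(all(rmsd_series(g$traj, sel)$rmsd < 1e-12))
  # rigid-body tumbling: rotate every frame; superposition removes it
  t2 <- g$traj
  for (f in 1:10) {
    th <- 0.1 * f
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
    M <- matrix(t2$xyz[f, ], ncol = 3, byrow = TRUE) %*% t(R)
    t2$xyz[f, ] <- as.numeric(t(M))
  }
  expect_true(all(rmsd_series(t2, sel)$rmsd < 1e-9))
  expect_error(rmsf(trajectory(g$traj$topology, g$traj$xyz[1, , drop = FALSE]),
                    sel), "2 frames")
})

test_that("isotropic Gaussian jitter gives RMSF near sigma * sqrt(3)", {
  sigma <- 0.5
  g <- gen_membrane_trajectory(n_frames = 1000, n_lipids = c(LPG = 4, PG = 4),
                               jitter_sigma = sigma, seed = 41)
  r <- rmsf(g$traj, select_atoms(g$traj, segment = "protein"))
  expect_equal(mean(r$rmsf), sigma * sqrt(3), tolerance = 0.05 * sigma * sqrt(3))
})
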