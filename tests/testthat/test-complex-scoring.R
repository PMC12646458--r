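# Interface scoring: contacts, pDockQ, clashscore, Pareto ranking.

pdockq_sigmoid <- function(x) 0.724 / (1 + exp(-0.052 * (x - 152.611))) + 0.018

test_that("disjoint chains and a zero cutoff give no contacts", {
  far <- make_ca_structure(data.frame(
    chain = rep(c("A", "B"), each = 3), resno = rep(1:3, 2),
    x = c(0, 4, 8, 0, 4, 8), y = c(0, 0, 0, 50, 50, 50), z = 0),
    resid = "GLY")   # CA fallback applies; no CB present
  expect_equal(nrow(find_interface_contacts(far, "A", "B")), 0)
  g <- gen_complex(10, 10, 5, 90, 60, 0, seed = 1)
  expect_equal(nrow(find_interface_contacts(g$model, "A", "B", cutoff = 0)), 0)
})

test_that("planted cross-chain contacts are found exactly and match brute force", {
  for (seed in c(1, 9)) {
    g <- gen_complex(20, 20, 10, 90, 60, 0, seed = seed)
    got <- find_interface_contacts(g$model, "A", "B")
    expect_equal(nrow(got), 10)
    oracle <- brute_contacts(g$model, "A", "B")
    expect_equal(nrow(got), oracle$n)
    expect_equal(got$resno_a, g$manifest$contacts$resno_a)
    expect_equal(got$resno_b, g$manifest$contacts$resno_b)
    # deterministic ordering
    expect_true(!is.unsorted(got$resno_a))
  }
})

test_that("glycine residues fall back to the C-alpha representative atom", {
  g <- gen_complex(20, 20, 10, 90, 60, 0, seed = 3, glycine_a = c(2, 15))
  got <- find_interface_contacts(g$model, "A", "B")
  expect_equal(nrow(got), 10)          # glycine at a contact position still pairs
  expect_true(2 %in% got$resno_a)
  expect_equal(got$resid_a[got$resno_a == 2], "GLY")
})

test_that("pDockQ floor, planted-value agreement, bounds and monotonicity hold", {
  # zero contacts -> floor score by convention
  g0 <- gen_complex(10, 10, 0, 90, 60, 0, seed = 1)
  p0 <- compute_pdockq(g0$model, "A", "B")
  expect_equal(p0$score, 0.018)
  expect_equal(p0$n_contacts, 0L)
  expect_equal(p0$x, 0)
  # planted complex: 10 contacts, interface pLDDT 90 -> x = 90*log10(10) = 90
  g <- gen_complex(20, 20, 10, 90, 60, 0, seed = 4)
  p <- compute_pdockq(g$model, "A", "B")
  expect_equal(p$mean_if_plddt, 90)
  expect_equal(p$x, 90)
  expect_equal(p$score, pdockq_sigmoid(90), tolerance = 1e-12)
  # strictly increasing in interface pLDDT at fixed contact count; bounded
  scores <- vapply(c(40, 60, 80, 95), function(pl) {
    compute_pdockq(gen_complex(20, 20, 10, pl, 30, 0, seed = 4)$model,
                   "A", "B")$score
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores >= 0.018 & scores <= 0.742))
})

test_that("pDockQ refuses structures not flagged as predicted", {
  g <- gen_complex(10, 10, 5, 90, 60, 0, seed = 1)
  s <- g$model
  s$predicted <- FALSE
  expect_error(compute_pdockq(s, "A", "B"), "predicted")
})

test_that("clashscore counts planted overlaps per 1000 heavy atoms", {
  # two distant carbons: no overlap
  two <- make_ca_structure(data.frame(chain = "A", resno = 1:2,
                                      x = c(0, 5), y = 0, z = 0))
  expect_equal(compute_clashscore(two)$clashscore, 0)
  # 100 heavy atoms with exactly one planted non-bonded overlap -> 10.0
  g <- gen_complex(9, 9, 4, 90, 60, 1, seed = 2)
  cs <- compute_clashscore(g$model)
  expect_equal(cs$n_heavy_atoms, 100)
  expect_equal(nrow(cs$clashes), 1)
  expect_equal(cs$clashscore, 10.0)
  expect_gte(cs$clashes$overlap, 0.5)
})

test_that("spatial-hash clash search equals brute force on random atom clouds", {
  for (seed in 1:4) {
    s <- random_atom_cloud(n = 300, box = 35, seed = seed)
    cell <- compute_clashscore(s, method = "cell")
    brute <- compute_clashscore(s, method = "brute")
    expect_equal(cell$clashes[, c("i", "j", "distance")],
                 brute$clashes[, c("i", "j", "distance")])
    expect_equal(cell$clashscore, brute$clashscore)
  }
})

test_that("clashscore is rigid-motion invariant and diluted by far atoms", {
  g <- gen_complex(10, 10, 5, 90, 60, 2, seed = 6)
  base <- compute_clashscore(g$model)
  th <- 0.9
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  moved <- transform_structure(g$model, R, c(11, 5, -3))
  expect_equal(compute_clashscore(moved)$clashscore, base$clashscore)
  # adding a far-away heavy atom increases n and decreases the score
  s2 <- g$model
  extra <- s2$atom[1, ]
  extra$eleno <- max(s2$atom$eleno) + 1L
  extra$resno <- 9999L; extra$x <- 500; extra$y <- 500; extra$z <- 500
  s2$atom <- rbind(s2$atom, extra)
  expect_lt(compute_clashscore(s2)$clashscore, base$clashscore)
})

test_that("Pareto ranking reproduces exhaustive dominance", {
  ranked <- rank_screen(data.frame(
    candidate_id = c("A", "B", "C"),
    pdockq = c(0.7, 0.2, 0.6), clashscore = c(5, 50, 2)))
  expect_equal(sort(ranked$candidate_id[ranked$pareto_rank == 1]), c("A", "C"))
  expect_equal(ranked$pareto_rank[ranked$candidate_id == "B"], 2)
  # singleton
  expect_equal(rank_screen(data.frame(candidate_id = "X", pdockq = 0.3,
                                      clashscore = 9))$pareto_rank, 1)
  # all identical: every entry rank 1, sorted by id
  same <- rank_screen(data.frame(candidate_id = c("c", "a", "b"),
                                 pdockq = 0.4, clashscore = 7))
  expect_equal(same$pareto_rank, rep(1L, 3))
  expect_equal(same$candidate_id, c("a", "b", "c"))
})

test_that("ranking is a permutation of inputs and fronts verify exhaustively", {
  set.seed(17)
  n <- 60
  entries <- data.frame(candidate_id = sprintf("m%02d", 1:n),
                        pdockq = runif(n, 0.018, 0.742),
                        clashscore = runif(n, 0, 80))
  ranked <- rank_screen(entries)
  expect_setequal(ranked$candidate_id, entries$candidate_id)
  # exhaustive dominance: an entry is rank 1 iff nothing dominates it
  for (k in seq_len(n)) {
    p <- ranked$pdockq[k]; c_ <- ranked$clashscore[k]
    dominated <- any(ranked$pdockq >= p & ranked$clashscore <= c_ &
                     (ranked$pdockq > p | ranked$clashscore < c_))
    expect_equal(ranked$pareto_rank[k] == 1, !dominated)
  }
})

test_that("non-finite scores are rejected with a warning", {
  expect_warning(
    ranked <- rank_screen(data.frame(candidate_id = c("a", "b"),
                                     pdockq = c(0.5, NaN),
                                     clashscore = c(3, 4))),
    "non-finite")
  expect_equal(ranked$candidate_id, "a")
})

test_that("screen_models scores a directory of generated models end to end", {
  dir <- withr::local_tempdir()
  specs <- list(good = c(contacts = 15, plddt = 92, clash = 0),
                mid = c(contacts = 6, plddt = 70, clash = 2),
                bad = c(contacts = 2, plddt = 40, clash = 6))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    g <- gen_complex(20, 20, sp[["contacts"]], sp[["plddt"]], 50,
                     sp[["clash"]], seed = 8)
    write_structure(g$model, file.path(dir, paste0(nm, ".pdb")))
  }
  tab <- screen_models(dir)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$candidate_id[1], "good")
  expect_equal(tab$pareto_rank[tab$candidate_id == "good"], 1)
})
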