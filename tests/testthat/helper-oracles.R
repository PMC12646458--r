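# Test-only oracles and fixture builders, independent of the package's
# implementation paths.

# Horn's quaternion method for optimal rigid superposition: independent
# oracle for the SVD-based Kabsch fit.
quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  e2 <- sum(Pc^2) + sum(Qc^2) - 2 * lam
  sqrt(max(0, e2) / nrow(P))
}

# Minimal CA-only structure from a residue table (chain, resno, x, y, z).
make_ca_structure <- function(df, id = "ca_model", predicted = FALSE,
                              b = 0, resid = "ALA") {
  atom <- data.frame(
    eleno = seq_len(nrow(df)), elety = "CA", altloc = "", resid = resid,
    chain = df$chain, resno = df$resno, icode = "",
    x = df$x, y = df$y, z = df$z, o = 1, b = b, elesy = "C",
    stringsAsFactors = FALSE)
  structure_model(atom, id = id, predicted = predicted)
}

# Brute-force O(n^2) interface-contact oracle on representative atoms
# (CB, CA for glycine), mirroring the documented contact definition.
brute_contacts <- function(s, chain_a, chain_b, cutoff = 8) {
  rep_of <- function(chain) {
    a <- s$atom[s$atom$chain == chain, ]
    out <- NULL
    for (rn in unique(a$resno)) {
      r <- a[a$resno == rn, ]
      row <- r[r$elety == "CB", ][1, ]
      if (is.na(row$eleno) && r$resid[1] == "GLY") row <- r[r$elety == "CA", ][1, ]
      if (!is.na(row$eleno)) out <- rbind(out, row)
    }
    out
  }
  ra <- rep_of(chain_a); rb <- rep_of(chain_b)
  hits <- 0L
  pairs <- list()
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
    d <- sqrt(sum((as.numeric(ra[i, c("x", "y", "z")]) -
                   as.numeric(rb[j, c("x", "y", "z")]))^2))
    if (d <= cutoff) {
      hits <- hits + 1L
      pairs[[hits]] <- c(ra$resno[i], rb$resno[j])
    }
  }
  list(n = hits, pairs = pairs)
}

# Random all-heavy-atom structure: each atom its own residue, so the only
# pair exclusion in play is the covalent-record (< 1.2 A) rule shared by
# both neighbor-search paths.
random_atom_cloud <- function(n = 500, box = 40, seed = 1) {
  set.seed(seed)
  atom <- data.frame(
    eleno = seq_len(n), elety = "X", altloc = "", resid = "UNK",
    chain = "A", resno = seq_len(n), icode = "",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    o = 1, b = 0, elesy = sample(c("C", "N", "O", "S"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  structure_model(atom, id = paste0("cloud", seed))
}

# Synthetic stand-in models for the two conformational states of the
# transporter: CA-only chains A/B (ATP-binding-cassette monomers carrying
# Ser50/Ser148) and P (transmembrane subunit carrying Leu403/Leu754), with
# the reporter pairs planted at the state's characteristic distances.
standin_state_model <- function(state = c("bound", "apo")) {
  state <- match.arg(state)
  d <- if (state == "bound") c(site1 = 8.1, site2 = 8.1, leu = 6.6)
       else c(site1 = 17.2, site2 = 23.6, leu = 19.2)
  df <- data.frame(
    chain = c("A", "B", "B", "A", "P", "P"),
    resno = c(50, 148, 50, 148, 403, 754),
    x = c(0, d[["site1"]], 0, d[["site2"]], 0, d[["leu"]]),
    y = c(0, 0, 30, 30, 60, 60),
    z = 0)
  make_ca_structure(df, id = paste0("synthetic_standin_", state))
}
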