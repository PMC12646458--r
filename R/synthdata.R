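# Synthetic-data generators. Each generator is deterministic under
# (parameters, seed), plants a known statistical structure (contacts,
# clashes, coevolving pairs, lipid occupancy, kinetic parameters) and
# returns a machine-readable manifest of the planted truth next to the
# data. Generators plant statistics, not physics: the geometries are
# minimal poly-alanine / bead constructions, not force-field realistic.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Write a generator manifest as JSON
#'
#' @param manifest list of planted truths.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Heavy-atom template for one synthetic residue: local offsets from CA.
# Alanine (N, CA, C, O, CB); glycine drops CB.
.RES_TEMPLATE <- matrix(c(
  -1.20,  0.80, 0.00,   # N
   0.00,  0.00, 0.00,   # CA
   1.20,  0.80, 0.00,   # C
   2.30,  0.45, 0.00,   # O
   0.00, -1.53, 0.00),  # CB
  ncol = 3, byrow = TRUE,
  dimnames = list(c("N", "CA", "C", "O", "CB"), NULL))
.RES_ELESY <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")

# One residue's atom rows: CA placed at `origin`, CB direction given by a
# rotation applied to the template.
.mk_residue <- function(chain, resno, origin, rot = diag(3), gly = FALSE) {
  tpl <- .RES_TEMPLATE
  if (gly) tpl <- tpl[rownames(tpl) != "CB", , drop = FALSE]
  xyz <- tpl %*% t(rot) + matrix(origin, nrow(tpl), 3, byrow = TRUE)
  data.frame(eleno = 0L, elety = rownames(tpl), altloc = "",
             resid = if (gly) "GLY" else "ALA", chain = chain,
             resno = as.integer(resno), icode = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             o = 1.0, b = 0.0, elesy = unname(.RES_ELESY[rownames(tpl)]),
             stringsAsFactors = FALSE)
}

.ROT_FLIP_Y <- diag(c(1, -1, 1))                    # CB points +y
.ROT_CB_UP <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)   # CB -> +z
.ROT_CB_DOWN <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, 3, byrow = TRUE) # CB -> -z

#' Generate a synthetic two-chain complex with planted contacts and clashes
#'
#' Builds a poly-alanine two-chain model with exactly \code{n_contacts}
#' cross-chain representative-atom pairs within 8 Angstrom (planted at
#' 6 Angstrom), exactly \code{n_clashes} non-bonded heavy-atom overlaps of
#' about 0.9 Angstrom (planted as intra-chain CB-CB pairs at 2.5 Angstrom,
#' well away from the interface), and the stated pLDDT values written into
#' the B-factor column (interface residues get \code{interface_plddt},
#' everything else \code{background_plddt}). A small uniform coordinate
#' jitter (within 0.05 Angstrom per coordinate) decorrelates seeds without
#' crossing any planted threshold.
#'
#' @param n_res_a,n_res_b residues per chain.
#' @param n_contacts planted cross-chain contacts
#'   (<= min(n_res_a, n_res_b)).
#' @param interface_plddt,background_plddt pLDDT values in [0, 100].
#' @param n_clashes planted steric clashes.
#' @param seed integer seed.
#' @param glycine_a chain-A residue indices converted to glycine (no CB;
#'   exercises the C-alpha fallback).
#' @return list with \code{model} (StructureModel, \code{predicted = TRUE})
#'   and \code{manifest}.
#' @export
gen_complex <- function(n_res_a = 20, n_res_b = 20, n_contacts = 10,
                        interface_plddt = 90, background_plddt = 60,
                        n_clashes = 0, seed = 1, glycine_a = integer(0)) {
  if (n_contacts > min(n_res_a, n_res_b))
    stop("infeasible geometry: n_contacts must be <= min(n_res_a, n_res_b)")
  if (any(c(interface_plddt, background_plddt) < 0) ||
      any(c(interface_plddt, background_plddt) > 100))
    stop("pLDDT values must lie in [0, 100]")
  if (any(glycine_a > n_res_a)) stop("glycine_a index beyond chain A")
  rows <- list()
  # chain A: row of residues along x, CB pointing -y
  for (i in seq_len(n_res_a)) {
    rows[[length(rows) + 1]] <- .mk_residue("A", i, c(12 * (i - 1), 0, 0),
                                            gly = i %in% glycine_a)
  }
  # chain B: first n_contacts residues paired under chain A (CB up, 6 A
  # CB-CB gap); the rest parked far away
  for (j in seq_len(n_res_b)) {
    if (j <= n_contacts) {
      origin <- c(12 * (j - 1), -9.06, 0)
      rows[[length(rows) + 1]] <- .mk_residue("B", j, origin, .ROT_FLIP_Y)
    } else {
      rows[[length(rows) + 1]] <- .mk_residue("B", j, c(12 * (j - 1), -60, 0))
    }
  }
  # planted clashes: isolated intra-chain-A CB-CB overlaps at 2.5 A
  clash_resnos <- list()
  for (k in seq_len(n_clashes)) {
    xk <- -30 - 20 * k
    r1 <- n_res_a + 2 * k - 1
    r2 <- n_res_a + 2 * k
    rows[[length(rows) + 1]] <- .mk_residue("A", r1, c(xk, 0, 0), .ROT_CB_UP)
    rows[[length(rows) + 1]] <- .mk_residue("A", r2, c(xk, 0, 5.53), .ROT_CB_DOWN)
    clash_resnos[[k]] <- c(r1, r2)
  }
  atom <- do.call(rbind, rows)
  atom$eleno <- seq_len(nrow(atom))
  # pLDDT
  if_a <- seq_len(n_contacts)
  atom$b <- ifelse((atom$chain == "A" & atom$resno %in% if_a & atom$resno <= n_res_a) |
                   (atom$chain == "B" & atom$resno %in% if_a),
                   interface_plddt, background_plddt)
  # seeded jitter, too small to cross any planted threshold
  atom <- .with_seed(seed, {
    n <- nrow(atom)
    atom$x <- atom$x + stats::runif(n, -0.05, 0.05)
    atom$y <- atom$y + stats::runif(n, -0.05, 0.05)
    atom$z <- atom$z + stats::runif(n, -0.05, 0.05)
    atom
  })
  model <- structure_model(atom, id = sprintf("synthetic_complex_seed%d", seed),
                           predicted = TRUE)
  n_heavy <- nrow(atom)
  manifest <- list(
    generator = "gen_complex", seed = seed,
    n_res_a = n_res_a, n_res_b = n_res_b,
    n_contacts = n_contacts,
    contacts = if (n_contacts > 0)
      data.frame(resno_a = if_a, resno_b = if_a) else NULL,
    n_clashes = n_clashes,
    clash_residues = clash_resnos,
    interface_plddt = interface_plddt,
    background_plddt = background_plddt,
    expected_clashscore = 1000 * n_clashes / n_heavy,
    glycine_a = glycine_a)
  list(model = model, manifest = manifest)
}

#' Generate a coupling matrix with planted high-Z inter-chain pairs
#'
#' The full matrix is filled with half-normal |N(0, scale)| noise
#' (symmetric, zero diagonal). Planted inter-chain cells are then set to
#' mu + target_z * sigma, where mu and sigma are the mean and population
#' standard deviation of the realized inter-chain background.
#'
#' @param len_a,len_b chain lengths.
#' @param planted data.frame \code{pos_a, pos_b, target_z} (may be empty).
#' @param noise_scale half-normal scale (> 0).
#' @param seed integer seed.
#' @return list with \code{matrix} (\code{coupling_matrix}) and
#'   \code{manifest}.
#' @export
gen_coupling <- function(len_a, len_b, planted = NULL, noise_scale = 1,
                         seed = 1) {
  if (!is.finite(noise_scale) || noise_scale <= 0)
    stop("noise_scale must be > 0 (degenerate background otherwise)")
  L <- len_a + len_b
  if (!is.null(planted) && nrow(planted) > 0) {
    if (any(planted$pos_a < 1 | planted$pos_a > len_a |
            planted$pos_b < 1 | planted$pos_b > len_b))
      stop("planted positions outside the chain partition")
    if (anyDuplicated(planted[, c("pos_a", "pos_b")]) > 0)
      stop("duplicate planted positions")
  }
  m <- .with_seed(seed, {
    m <- matrix(0, L, L)
    ut <- upper.tri(m)
    m[ut] <- abs(stats::rnorm(sum(ut), 0, noise_scale))
    m + t(m)
  })
  diag(m) <- 0
  block <- m[seq_len(len_a), len_a + seq_len(len_b), drop = FALSE]
  mu <- mean(block)
  sigma <- sqrt(mean((block - mu)^2))
  if (!is.null(planted) && nrow(planted) > 0) {
    for (k in seq_len(nrow(planted))) {
      i <- planted$pos_a[k]; j <- len_a + planted$pos_b[k]
      m[i, j] <- m[j, i] <- mu + planted$target_z[k] * sigma
    }
  }
  cm <- list(scores = m, L = L)
  class(cm) <- "coupling_matrix"
  manifest <- list(generator = "gen_coupling", seed = seed,
                   len_a = len_a, len_b = len_b,
                   noise_scale = noise_scale,
                   background_mean = mu, background_sd = sigma,
                   planted = planted)
  list(matrix = cm, manifest = manifest)
}

#' Generate a synthetic membrane trajectory
#'
#' Builds a two-leaflet lipid slab (headgroup bead \code{PO4} plus two tail
#' beads per lipid, half of each type per leaflet) around a static
#' bead-model protein: a transmembrane cylinder at the box center plus
#' three pocket-lining residues ringing a 5 Angstrom pocket disc in the
#' upper leaflet. One tagged LysoPG (\code{LPG}) spends a stated fraction
#' of frames with its headgroup at the pocket center (in contact with the
#' lining residues); the remaining lipids redraw uniform positions each
#' frame, avoiding the pocket and protein footprints. An optional
#' extraction event raises the tagged headgroup linearly by \code{rise}
#' Angstrom from \code{start_frame} to the last frame. Protein beads
#' receive isotropic Gaussian jitter of standard deviation
#' \code{jitter_sigma} per coordinate per frame.
#'
#' @param n_frames number of frames.
#' @param dt_ns time per frame (ns).
#' @param n_lipids named vector of lipid counts per type (even counts
#'   keep the leaflets balanced).
#' @param box box lengths in Angstrom.
#' @param pocket_center_xy pocket center; default box center + (14, 0).
#' @param pocket_occupancy fraction of frames the tagged lipid spends in
#'   the pocket, in [0, 1].
#' @param extraction optional \code{list(start_frame, rise)}.
#' @param jitter_sigma protein-bead positional noise (Angstrom).
#' @param seed integer seed.
#' @return list with \code{traj} (\code{\link{trajectory}}) and
#'   \code{manifest} (leaflet labels, occupancy/contact schedule, pocket
#'   residues, extraction).
#' @export
gen_membrane_trajectory <- function(n_frames = 100, dt_ns = 1,
                                    n_lipids = c(LPG = 8, LPE = 8, PG = 8, PE = 8),
                                    box = c(100, 100, 100),
                                    pocket_center_xy = NULL,
                                    pocket_occupancy = 0.4,
                                    extraction = NULL,
                                    jitter_sigma = 0, seed = 1) {
  if (pocket_occupancy < 0 || pocket_occupancy > 1)
    stop("pocket_occupancy must lie in [0, 1]")
  if (any(box <= 0)) stop("box lengths must be positive")
  center <- box[1:2] / 2
  if (is.null(pocket_center_xy)) pocket_center_xy <- center + c(14, 0)
  if (any(pocket_center_xy < 0) || any(pocket_center_xy > box[1:2]))
    stop("pocket center outside the box")
  z0 <- box[3] / 2
  leaf_dz <- 18
  # --- topology ---
  rows <- list()
  resno <- 0L
  # transmembrane cylinder: 8 rings x 8 beads, radius 6
  n_ring <- 8; n_levels <- 8
  zlev <- seq(z0 - 24, z0 + 24, length.out = n_levels)
  prot_xyz <- list()
  for (l in seq_len(n_levels)) {
    for (k in seq_len(n_ring)) {
      resno <- resno + 1L
      th <- 2 * pi * (k - 1) / n_ring
      prot_xyz[[resno]] <- c(center[1] + 6 * cos(th), center[2] + 6 * sin(th), zlev[l])
      rows[[resno]] <- data.frame(eleno = 0L, elety = "BB", resid = "ALA",
                                  resno = resno, chain = "P",
                                  segment = "protein", elesy = "C",
                                  stringsAsFactors = FALSE)
    }
  }
  # pocket-lining residues: 3 beads at radius 3 around the pocket center
  pocket_res <- integer(3)
  for (k in 1:3) {
    resno <- resno + 1L
    th <- 2 * pi * (k - 1) / 3
    prot_xyz[[resno]] <- c(pocket_center_xy[1] + 3 * cos(th),
                           pocket_center_xy[2] + 3 * sin(th), z0 + leaf_dz)
    rows[[resno]] <- data.frame(eleno = 0L, elety = "BB", resid = "ALA",
                                resno = resno, chain = "P",
                                segment = "protein", elesy = "C",
                                stringsAsFactors = FALSE)
    pocket_res[k] <- resno
  }
  n_prot <- resno
  prot_base <- do.call(rbind, lapply(prot_xyz, function(v) matrix(v, 1)))
  # lipids: head bead (PO4) + two tail beads, half per leaflet
  lipid_rows <- list(); lipid_meta <- list()
  for (tp in names(n_lipids)) {
    nt <- n_lipids[[tp]]
    for (k in seq_len(nt)) {
      resno <- resno + 1L
      leaf <- if (k <= ceiling(nt / 2)) "upper" else "lower"
      lipid_meta[[length(lipid_meta) + 1]] <-
        data.frame(resno = resno, resid = tp, leaflet = leaf,
                   stringsAsFactors = FALSE)
      lipid_rows[[length(lipid_rows) + 1]] <-
        data.frame(eleno = 0L, elety = c("PO4", "C1", "C2"), resid = tp,
                   resno = resno, chain = "L", segment = "lipid",
                   elesy = c("P", "C", "C"), stringsAsFactors = FALSE)
    }
  }
  lipids <- do.call(rbind, lipid_meta)
  top <- rbind(do.call(rbind, rows), do.call(rbind, lipid_rows))
  top$eleno <- seq_len(nrow(top))
  n_atoms <- nrow(top)
  tagged <- lipids$resno[lipids$resid == "LPG" & lipids$leaflet == "upper"][1]
  if (is.na(tagged)) stop("need at least one upper-leaflet LPG lipid")
  if (!is.null(extraction)) {
    if (is.null(extraction$start_frame) || is.null(extraction$rise))
      stop("extraction needs start_frame and rise")
    if (extraction$start_frame < 1 || extraction$start_frame > n_frames)
      stop("extraction start_frame outside trajectory")
  }
  # --- frames ---
  out <- .with_seed(seed, {
    # occupancy schedule: random frame subset (drawn before extraction
    # frames are forced in)
    free_frames <- if (is.null(extraction)) seq_len(n_frames) else
      seq_len(max(0, extraction$start_frame - 1))
    k_occ <- round(pocket_occupancy * length(free_frames))
    occ <- sort(sample(free_frames, k_occ))
    if (!is.null(extraction)) occ <- sort(union(occ, extraction$start_frame:n_frames))
    xyz <- matrix(0, n_frames, 3 * n_atoms)
    # uniform xy avoiding the pocket and protein footprints
    draw_xy <- function() {
      repeat {
        p <- c(stats::runif(1, 0, box[1]), stats::runif(1, 0, box[2]))
        if (sum((p - pocket_center_xy)^2) > 12^2 && sum((p - center)^2) > 12^2)
          return(p)
      }
    }
    for (f in seq_len(n_frames)) {
      P <- prot_base
      if (jitter_sigma > 0)
        P <- P + matrix(stats::rnorm(length(P), 0, jitter_sigma), nrow(P), 3)
      coords <- matrix(0, n_atoms, 3)
      coords[seq_len(n_prot), ] <- P
      for (li in seq_len(nrow(lipids))) {
        rn <- lipids$resno[li]
        leaf <- lipids$leaflet[li]
        zh <- z0 + if (leaf == "upper") leaf_dz else -leaf_dz
        tail_dir <- if (leaf == "upper") -1 else 1
        if (rn == tagged) {
          in_pocket <- f %in% occ
          xy <- if (in_pocket) pocket_center_xy else draw_xy()
          if (!is.null(extraction) && f >= extraction$start_frame) {
            frac <- (f - extraction$start_frame) /
              max(1, n_frames - extraction$start_frame)
            zh <- zh + extraction$rise * frac
          }
        } else {
          xy <- draw_xy()
        }
        aidx <- which(top$resno == rn)
        coords[aidx[1], ] <- c(xy, zh)
        coords[aidx[2], ] <- c(xy, zh + 5 * tail_dir)
        coords[aidx[3], ] <- c(xy, zh + 10 * tail_dir)
      }
      xyz[f, ] <- as.numeric(t(coords))
    }
    list(xyz = xyz, occ = occ)
  })
  traj <- trajectory(top, out$xyz, box = matrix(box, 1), dt_ns = dt_ns)
  # contact schedule: in-pocket frames where the rising headgroup is still
  # within 4 A of a lining bead (lining ring radius 3 -> contact while the
  # vertical offset is below sqrt(4^2 - 3^2))
  contact_frames <- out$occ
  if (!is.null(extraction)) {
    dz <- vapply(contact_frames, function(f) {
      if (f < extraction$start_frame) 0 else
        extraction$rise * (f - extraction$start_frame) /
          max(1, n_frames - extraction$start_frame)
    }, numeric(1))
    contact_frames <- contact_frames[dz < sqrt(16 - 9)]
  }
  manifest <- list(
    generator = "gen_membrane_trajectory", seed = seed,
    n_frames = n_frames, dt_ns = dt_ns, box = box,
    pocket_center = pocket_center_xy, pocket_radius = 5,
    pocket_residues = pocket_res,
    tagged_lipid = tagged,
    leaflets = lipids,
    occupancy_frames = out$occ,
    contact_frames = contact_frames,
    extraction = extraction,
    jitter_sigma = jitter_sigma,
    n_protein_residues = n_prot)
  list(traj = traj, manifest = manifest)
}

#' Generate synthetic Michaelis-Menten rate data
#'
#' Rates are drawn as v = Vmax * S / (Km + S) + N(0, noise_sd), truncated
#' at zero. Optionally also emits linear progress curves whose slopes
#' equal the drawn rates.
#'
#' @param Km,Vmax true parameters (Km in the concentration unit of
#'   \code{concentrations}).
#' @param concentrations substrate concentrations (> 0).
#' @param noise_sd Gaussian noise standard deviation on the rates (>= 0).
#' @param n_replicates replicates per concentration.
#' @param seed integer seed.
#' @param curve_points when > 0, also generate progress curves with this
#'   many time points per (S, replicate).
#' @return list with \code{rates} (data.frame S, v, replicate), optional
#'   \code{curves} (named list of \code{progress_curve}), and
#'   \code{manifest}.
#' @export
gen_progress_curves <- function(Km, Vmax, concentrations,
                                noise_sd = 0, n_replicates = 1, seed = 1,
                                curve_points = 0) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  res <- .with_seed(seed, {
    S <- rep(concentrations, each = n_replicates)
    v_true <- Vmax * S / (Km + S)
    v <- pmax(0, v_true + stats::rnorm(length(S), 0, noise_sd))
    rates <- data.frame(S = S, v = v,
                        replicate = rep(seq_len(n_replicates),
                                        times = length(concentrations)))
    curves <- NULL
    if (curve_points > 0) {
      times <- seq(0, 60, length.out = curve_points)
      curves <- list()
      for (i in seq_len(nrow(rates))) {
        lbl <- sprintf("S%g_rep%d", rates$S[i], rates$replicate[i])
        curves[[lbl]] <- progress_curve(times, 0.05 + rates$v[i] * times,
                                        label = lbl)
      }
    }
    list(rates = rates, curves = curves)
  })
  manifest <- list(generator = "gen_progress_curves", seed = seed,
                   Km = Km, Vmax = Vmax,
                   concentrations = concentrations,
                   noise_sd = noise_sd, n_replicates = n_replicates)
  c(res, list(manifest = manifest))
}

#' Generate an apo/holo structure pair with a planted rigid motion
#'
#' The second structure equals the first with a selection rigidly
#' translated; everything else (including the implied static core used for
#' superposition) is untouched.
#'
#' @param base StructureModel.
#' @param moving list with \code{chain} and optionally \code{resno}
#'   (vector) selecting the moved atoms.
#' @param translation length-3 vector (Angstrom).
#' @return list with \code{apo} (= base), \code{holo} and \code{manifest}.
#' @export
gen_state_pair <- function(base, moving, translation) {
  stopifnot(inherits(base, "StructureModel"))
  a <- base$atom
  sel <- a$chain %in% moving$chain
  if (!is.null(moving$resno)) sel <- sel & a$resno %in% moving$resno
  if (!any(sel)) stop("empty moving selection")
  holo <- base
  holo$atom$x[sel] <- holo$atom$x[sel] + translation[1]
  holo$atom$y[sel] <- holo$atom$y[sel] + translation[2]
  holo$atom$z[sel] <- holo$atom$z[sel] + translation[3]
  holo$id <- paste0(base$id, "_moved")
  manifest <- list(generator = "gen_state_pair",
                   moving = moving, translation = translation,
                   n_moved_atoms = sum(sel))
  list(apo = base, holo = holo, manifest = manifest)
}
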