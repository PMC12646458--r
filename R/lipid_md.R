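# Membrane-trajectory analytics: lipid headgroup residency grids in the
# membrane plane, vertical extraction traces, per-residue lipid contact
# propensity, and RMSF/RMSD. Works identically for coarse-grained and
# atomistic inputs via atom-name configuration (phosphate bead "PO4" vs
# atom "P").

.LIPID_RESNAMES <- c("LPG", "LPE", "PG", "PE", "POPG", "POPE", "LYSOPG", "LYSOPE")
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.HEAD_ATOMS <- c("P", "PO4")

#' Construct a Trajectory
#'
#' @param topology data.frame with columns \code{eleno, elety, resid,
#'   resno, chain, segment, elesy}; \code{segment} is one of
#'   \code{"protein"}, \code{"lipid"}, \code{"solvent"}.
#' @param xyz frames x 3N coordinate matrix (Angstrom), one row per frame.
#' @param box frames x 3 matrix of orthorhombic box lengths (Angstrom), or
#'   NULL when unknown.
#' @param dt_ns time per frame in nanoseconds.
#' @return object of class \code{Trajectory}.
#' @export
trajectory <- function(topology, xyz, box = NULL, dt_ns = 1) {
  stopifnot(is.data.frame(topology))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(topology))
    stop("coordinate width (", ncol(xyz), ") does not match 3 x ",
         nrow(topology), " topology atoms")
  if (!is.null(box)) {
    box <- matrix(as.numeric(box), ncol = 3)
    if (nrow(box) == 1) box <- box[rep(1, nrow(xyz)), , drop = FALSE]
    if (any(box <= 0)) stop("box lengths must be positive")
  }
  out <- list(topology = topology, xyz = xyz, box = box, dt_ns = dt_ns)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  seg <- table(x$topology$segment)
  cat(sprintf("Trajectory: %d frames x %d atoms (dt %.3g ns): %s\n",
              nrow(x$xyz), nrow(x$topology), x$dt_ns,
              paste(names(seg), seg, sep = "=", collapse = ", ")))
  invisible(x)
}

.n_frames <- function(t) nrow(t$xyz)

# N x 3 coordinates of frame f (optionally only atoms `idx`)
.frame_xyz <- function(t, f, idx = NULL) {
  v <- t$xyz[f, ]
  m <- matrix(v, ncol = 3, byrow = TRUE)
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

# Infer segment labels from residue names.
.infer_segment <- function(resid, lipid_resnames = .LIPID_RESNAMES) {
  ifelse(toupper(resid) %in% lipid_resnames, "lipid",
         ifelse(toupper(resid) %in% .AA3, "protein", "solvent"))
}

# Parse a single-frame GRO file (fixed-width; nm converted to Angstrom).
.read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("truncated GRO file: ", path)
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms)) stop("bad atom count on line 2 of ", path)
  if (length(lines) < 2 + natoms + 1) stop("truncated GRO file: ", path)
  al <- lines[3:(2 + natoms)]
  resno <- as.integer(substr(al, 1, 5))
  resid <- trimws(substr(al, 6, 10))
  elety <- trimws(substr(al, 11, 15))
  eleno <- as.integer(substr(al, 16, 20))
  x <- as.numeric(substr(al, 21, 28)) * 10
  y <- as.numeric(substr(al, 29, 36)) * 10
  z <- as.numeric(substr(al, 37, 44)) * 10
  if (any(is.na(c(resno, x, y, z))))
    stop("unparseable atom record in GRO file ", path)
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + natoms]), "\\s+")[[1]]))
  box <- boxv[1:3] * 10
  list(atoms = data.frame(eleno = eleno, elety = elety, resid = resid,
                          resno = resno, stringsAsFactors = FALSE),
       xyz = cbind(x, y, z), box = box)
}

# Write one frame as GRO (Angstrom converted to nm).
.write_gro <- function(topology, xyz, box, path, title = "abcscreen frame") {
  n <- nrow(topology)
  lines <- character(n + 3)
  lines[1] <- title
  lines[2] <- sprintf("%5d", n)
  lines[3:(n + 2)] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              topology$resno %% 100000, topology$resid,
                              topology$elety, topology$eleno %% 100000,
                              xyz[, 1] / 10, xyz[, 2] / 10, xyz[, 3] / 10)
  b <- if (is.null(box)) c(0, 0, 0) else box / 10
  lines[n + 3] <- sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3])
  writeLines(lines, path)
  invisible(path)
}

#' Read a membrane trajectory
#'
#' Reads a topology (GRO or PDB) and trajectory frames (multi-model PDB or
#' DCD). Coordinates are normalized to Angstrom. Atom segments (protein /
#' lipid / solvent) are inferred from residue names unless the topology
#' already carries them.
#'
#' @param topology path to a GRO or PDB topology file.
#' @param frames optional path to frames (multi-model PDB or DCD). When
#'   NULL, models in the topology file itself are used.
#' @param stride keep every stride-th frame (default 1).
#' @param dt_ns time per stored frame in ns (before striding).
#' @param lipid_resnames residue names treated as lipids.
#' @return a \code{\link{trajectory}} object (\code{dt_ns} reflects the
#'   stride).
#' @export
read_trajectory <- function(topology, frames = NULL, stride = 1, dt_ns = 1,
                            lipid_resnames = .LIPID_RESNAMES) {
  stopifnot(stride >= 1)
  ext <- tolower(tools::file_ext(topology))
  box <- NULL
  if (ext == "gro") {
    g <- .read_gro(topology)
    top <- g$atoms
    top$chain <- "X"
    top$elesy <- toupper(substr(sub("^[0-9]*", "", top$elety), 1, 1))
    top_xyz <- matrix(as.numeric(t(g$xyz)), nrow = 1)
    box <- matrix(g$box, nrow = 1)
  } else {
    s <- read_structure(topology, format = "pdb", multi = is.null(frames))
    top <- s$atom[, c("eleno", "elety", "resid", "resno", "chain", "elesy")]
    mm <- attr(s, "xyz")
    top_xyz <- if (!is.null(mm)) mm else
      matrix(as.numeric(t(as.matrix(s$atom[, c("x", "y", "z")]))), nrow = 1)
  }
  top$segment <- .infer_segment(top$resid, toupper(lipid_resnames))
  if (!is.null(frames)) {
    fext <- tolower(tools::file_ext(frames))
    if (fext == "dcd") {
      xyz <- bio3d::read.dcd(frames, verbose = FALSE)
    } else {
      sf <- read_structure(frames, format = "pdb", multi = TRUE)
      mm <- attr(sf, "xyz")
      xyz <- if (!is.null(mm)) mm else
        matrix(as.numeric(t(as.matrix(sf$atom[, c("x", "y", "z")]))), nrow = 1)
    }
  } else {
    xyz <- top_xyz
  }
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(top))
    stop("atom-count mismatch: topology has ", nrow(top), " atoms, frames have ",
         ncol(xyz) / 3)
  keep <- seq(1, nrow(xyz), by = stride)
  trajectory(top, xyz[keep, , drop = FALSE],
             box = if (is.null(box)) NULL else box[rep(1, length(keep)), , drop = FALSE],
             dt_ns = dt_ns * stride)
}

#' Write a trajectory (GRO topology + multi-model PDB frames)
#'
#' @param t Trajectory.
#' @param topology_path output GRO path.
#' @param frames_path output multi-model PDB path.
#' @return invisibly, \code{c(topology_path, frames_path)}.
#' @export
write_trajectory <- function(t, topology_path, frames_path) {
  stopifnot(inherits(t, "Trajectory"))
  .write_gro(t$topology, .frame_xyz(t, 1),
             if (is.null(t$box)) NULL else t$box[1, ], topology_path)
  top <- t$topology
  bio3d::write.pdb(file = frames_path, xyz = t$xyz,
                   resno = top$resno, resid = top$resid, eleno = top$eleno,
                   elety = top$elety, chain = top$chain, elesy = top$elesy,
                   o = rep(1, nrow(top)), b = rep(0, nrow(top)))
  invisible(c(topology_path, frames_path))
}

#' Select atoms of a trajectory
#'
#' Simple clause-based selection: all supplied clauses must match.
#'
#' @param t Trajectory.
#' @param segment,resid,resno,elety optional filters (vectors).
#' @return integer atom indices.
#' @export
select_atoms <- function(t, segment = NULL, resid = NULL, resno = NULL,
                         elety = NULL) {
  top <- t$topology
  keep <- rep(TRUE, nrow(top))
  if (!is.null(segment)) keep <- keep & top$segment %in% segment
  if (!is.null(resid)) keep <- keep & toupper(top$resid) %in% toupper(resid)
  if (!is.null(resno)) keep <- keep & top$resno %in% resno
  if (!is.null(elety)) keep <- keep & top$elety %in% elety
  which(keep)
}

# Indices of lipid headgroup reference atoms (one per lipid is expected).
.head_idx <- function(t, head_elety = .HEAD_ATOMS, resid = NULL) {
  idx <- select_atoms(t, segment = "lipid", resid = resid, elety = head_elety)
  if (length(idx) == 0) stop("no lipid headgroup atoms (",
                             paste(head_elety, collapse = "/"), ") found",
                             if (!is.null(resid)) paste0(" for type ", resid) else "")
  idx
}

#' Assign lipids to leaflets
#'
#' Per frame, the bilayer midplane is the mean z of all lipid headgroup
#' reference atoms; a lipid is in the upper leaflet iff its headgroup z is
#' strictly above the midplane (ties assigned lower, with a warning).
#'
#' @param t Trajectory (>= 2 lipids).
#' @param head_elety headgroup reference atom names (default \code{P},
#'   \code{PO4}).
#' @return list with \code{lipids} (data.frame resno, resid, atom index),
#'   \code{labels} (frames x lipids character matrix "upper"/"lower"),
#'   \code{midplane} (per-frame z).
#' @export
assign_leaflets <- function(t, head_elety = .HEAD_ATOMS) {
  stopifnot(inherits(t, "Trajectory"))
  idx <- .head_idx(t, head_elety)
  if (length(idx) < 2) stop("need at least 2 lipids to assign leaflets")
  top <- t$topology
  nf <- .n_frames(t)
  zcols <- 3 * idx              # z coordinate columns in the xyz matrix
  zmat <- t$xyz[, zcols, drop = FALSE]
  if (nf == 1) zmat <- matrix(zmat, nrow = 1)
  midplane <- rowMeans(zmat)
  labels <- ifelse(zmat > midplane, "upper", "lower")
  if (any(zmat == midplane))
    warning("headgroup z equal to midplane in some frame(s); assigned lower")
  lipids <- data.frame(resno = top$resno[idx], resid = top$resid[idx],
                       atom = idx, stringsAsFactors = FALSE)
  colnames(labels) <- paste0(lipids$resid, lipids$resno)
  list(lipids = lipids, labels = labels, midplane = midplane)
}

#' Lipid headgroup residency grid
#'
#' Accumulates a 2D histogram (default 30 x 30 bins of 2.5 Angstrom) of
#' headgroup xy positions for lipids of one type in one leaflet, over
#' strided frames, centered on the time-averaged protein xy centroid.
#' Observations outside the grid window are dropped and counted. Density
#' is normalized to the per-grid maximum.
#'
#' @param t Trajectory.
#' @param lipid_type residue name of the lipid of interest (e.g.
#'   \code{"LPG"}).
#' @param leaflet \code{"upper"} or \code{"lower"}.
#' @param stride analyze every stride-th frame (default 10).
#' @param nbins number of bins per axis (default 30).
#' @param bin_size bin edge length in Angstrom (default 2.5).
#' @param center optional xy center; default time-averaged protein
#'   centroid.
#' @param head_elety headgroup reference atom names.
#' @return object of class \code{residency_grid}: \code{counts},
#'   \code{density}, \code{x_edges}, \code{y_edges}, \code{center},
#'   \code{n_obs}, \code{dropped}, \code{frames}.
#' @export
residency_histogram <- function(t, lipid_type, leaflet = c("upper", "lower"),
                                stride = 10, nbins = 30, bin_size = 2.5,
                                center = NULL, head_elety = .HEAD_ATOMS) {
  leaflet <- match.arg(leaflet)
  stopifnot(inherits(t, "Trajectory"))
  types_present <- unique(t$topology$resid[t$topology$segment == "lipid"])
  if (!toupper(lipid_type) %in% toupper(types_present))
    stop("unknown lipid type '", lipid_type, "'; types present: ",
         paste(types_present, collapse = ", "))
  la <- assign_leaflets(t, head_elety)
  sel <- toupper(la$lipids$resid) == toupper(lipid_type)
  frames <- seq(1, .n_frames(t), by = stride)
  if (is.null(center)) {
    pidx <- select_atoms(t, segment = "protein")
    if (length(pidx) == 0) stop("no protein atoms to center the grid on")
    cx <- mean(t$xyz[frames, 3 * pidx - 2])
    cy <- mean(t$xyz[frames, 3 * pidx - 1])
    center <- c(cx, cy)
  }
  half <- nbins * bin_size / 2
  x_edges <- center[1] - half + bin_size * (0:nbins)
  y_edges <- center[2] - half + bin_size * (0:nbins)
  counts <- matrix(0L, nbins, nbins)
  dropped <- 0L; n_obs <- 0L
  aidx <- la$lipids$atom[sel]
  for (f in frames) {
    inleaf <- la$labels[f, sel] == leaflet
    if (!any(inleaf)) next
    xs <- t$xyz[f, 3 * aidx[inleaf] - 2]
    ys <- t$xyz[f, 3 * aidx[inleaf] - 1]
    n_obs <- n_obs + length(xs)
    bx <- floor((xs - x_edges[1]) / bin_size) + 1
    by <- floor((ys - y_edges[1]) / bin_size) + 1
    ok <- bx >= 1 & bx <= nbins & by >= 1 & by <= nbins
    dropped <- dropped + sum(!ok)
    for (k in which(ok)) counts[bx[k], by[k]] <- counts[bx[k], by[k]] + 1L
  }
  if (n_obs == 0)
    warning("no headgroup observations of type ", lipid_type,
            " in the ", leaflet, " leaflet")
  mx <- max(counts)
  density <- if (mx > 0) counts / mx else counts * 0
  out <- list(counts = counts, density = density, x_edges = x_edges,
              y_edges = y_edges, center = center, n_obs = n_obs,
              dropped = dropped, frames = frames)
  class(out) <- "residency_grid"
  out
}

#' @export
print.residency_grid <- function(x, ...) {
  am <- which(x$counts == max(x$counts), arr.ind = TRUE)[1, ]
  cat(sprintf("residency grid %dx%d: %d observations (%d dropped), argmax bin (%d,%d) at (%.1f, %.1f) A\n",
              nrow(x$counts), ncol(x$counts), x$n_obs, x$dropped, am[1], am[2],
              (x$x_edges[am[1]] + x$x_edges[am[1] + 1]) / 2,
              (x$y_edges[am[2]] + x$y_edges[am[2] + 1]) / 2))
  invisible(x)
}

#' Heatmap of a residency grid
#'
#' @param grid \code{residency_grid}.
#' @param ... passed to \code{image}.
#' @export
plot_residency <- function(grid, ...) {
  graphics::image(x = grid$x_edges, y = grid$y_edges, z = grid$density,
                  xlab = "x (A)", ylab = "y (A)", useRaster = TRUE, ...)
  invisible(grid)
}

#' Vertical (z) trace of one lipid
#'
#' Height of the chosen lipid atom relative to the per-frame bilayer
#' midplane (default) or to the upper-leaflet headgroup plane. Positive z
#' is the periplasmic side by convention.
#'
#' @param t Trajectory.
#' @param lipid_resno residue number of the lipid.
#' @param elety atom to track (default headgroup reference atoms).
#' @param stride analyze every stride-th frame.
#' @param reference \code{"midplane"} or \code{"upper_leaflet"}.
#' @return data.frame \code{frame, time_ns, z}.
#' @export
z_trace <- function(t, lipid_resno, elety = .HEAD_ATOMS, stride = 1,
                    reference = c("midplane", "upper_leaflet")) {
  reference <- match.arg(reference)
  stopifnot(inherits(t, "Trajectory"))
  idx <- select_atoms(t, segment = "lipid", resno = lipid_resno, elety = elety)
  if (length(idx) == 0)
    stop("lipid residue ", lipid_resno, " with atom ",
         paste(elety, collapse = "/"), " not found")
  idx <- idx[1]
  la <- assign_leaflets(t)
  frames <- seq(1, .n_frames(t), by = stride)
  zs <- t$xyz[frames, 3 * idx]
  ref <- if (reference == "midplane") {
    la$midplane[frames]
  } else {
    vapply(frames, function(f) {
      up <- la$labels[f, ] == "upper"
      mean(t$xyz[f, 3 * la$lipids$atom[up]])
    }, numeric(1))
  }
  data.frame(frame = frames, time_ns = (frames - 1) * t$dt_ns, z = zs - ref)
}

#' Lipid-residue contact propensity
#'
#' For each protein residue, the fraction of analyzed frames in which any
#' heavy-atom pair between the selected lipid and the residue is closer
#' than \code{cutoff}.
#'
#' @param t Trajectory.
#' @param lipid_resno residue number(s) of the lipid selection.
#' @param residues optional protein residue numbers (default all).
#' @param cutoff contact cutoff in Angstrom (default 4).
#' @param stride analyze every stride-th frame.
#' @return data.frame \code{chain, resno, resid, propensity, n_contact,
#'   n_frames}.
#' @export
contact_propensity <- function(t, lipid_resno, residues = NULL, cutoff = 4.0,
                               stride = 1) {
  stopifnot(inherits(t, "Trajectory"))
  lidx <- select_atoms(t, segment = "lipid", resno = lipid_resno)
  lidx <- lidx[!toupper(t$topology$elesy[lidx]) %in% c("H", "D")]
  if (length(lidx) == 0) stop("empty lipid selection")
  pidx <- select_atoms(t, segment = "protein", resno = residues)
  pidx <- pidx[!toupper(t$topology$elesy[pidx]) %in% c("H", "D")]
  if (length(pidx) == 0) stop("empty protein residue selection")
  top <- t$topology
  res_key <- paste(top$chain[pidx], top$resno[pidx], sep = "\r")
  res_u <- unique(res_key)
  frames <- seq(1, .n_frames(t), by = stride)
  n_contact <- setNames(integer(length(res_u)), res_u)
  for (f in frames) {
    L <- .frame_xyz(t, f, lidx)
    P <- .frame_xyz(t, f, pidx)
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    mind <- sqrt(pmax(0, apply(d2, 1, min)))
    hit_res <- unique(res_key[mind < cutoff])
    n_contact[hit_res] <- n_contact[hit_res] + 1L
  }
  first <- match(res_u, res_key)
  out <- data.frame(chain = top$chain[pidx][first],
                    resno = top$resno[pidx][first],
                    resid = top$resid[pidx][first],
                    propensity = as.numeric(n_contact) / length(frames),
                    n_contact = as.integer(n_contact),
                    n_frames = length(frames), stringsAsFactors = FALSE)
  out[order(out$chain, out$resno), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Superpose every frame onto a reference frame over `idx` atoms; returns a
# frames x (3*length(idx)) matrix of fitted selected coordinates.
.superposed_selection <- function(t, idx, reference_frame = 1) {
  nf <- .n_frames(t)
  ref <- .frame_xyz(t, reference_frame, idx)
  out <- matrix(0, nf, 3 * length(idx))
  for (f in seq_len(nf)) {
    P <- .frame_xyz(t, f, idx)
    fit <- .kabsch(P, ref)
    Pf <- P %*% t(fit$rotation) + matrix(fit$translation, nrow(P), 3, byrow = TRUE)
    out[f, ] <- as.numeric(t(Pf))
  }
  out
}

#' Per-atom root-mean-square fluctuation
#'
#' Each frame is superposed onto the first frame over the selection; the
#' RMSF of each selected atom is measured about its mean fitted position.
#'
#' @param t Trajectory (>= 2 frames).
#' @param selection integer atom indices (default: all protein atoms).
#' @return data.frame \code{atom, chain, resno, elety, rmsf}.
#' @export
rmsf <- function(t, selection = NULL) {
  stopifnot(inherits(t, "Trajectory"))
  if (.n_frames(t) < 2) stop("RMSF needs at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(t, segment = "protein")
  if (length(selection) == 0) stop("empty selection")
  M <- .superposed_selection(t, selection)
  n <- length(selection)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    X <- M[, (3 * i - 2):(3 * i), drop = FALSE]
    mu <- colMeans(X)
    vals[i] <- sqrt(mean(rowSums(sweep(X, 2, mu)^2)))
  }
  top <- t$topology
  data.frame(atom = selection, chain = top$chain[selection],
             resno = top$resno[selection], elety = top$elety[selection],
             rmsf = vals, stringsAsFactors = FALSE)
}

#' Per-frame RMSD relative to a reference frame
#'
#' Each frame is superposed onto the reference frame over the selection
#' before measurement.
#'
#' @param t Trajectory (>= 2 frames).
#' @param selection integer atom indices (default: all protein atoms).
#' @param reference_frame reference frame index (default 1, the start
#'   frame).
#' @return data.frame \code{frame, time_ns, rmsd}.
#' @export
rmsd_series <- function(t, selection = NULL, reference_frame = 1) {
  stopifnot(inherits(t, "Trajectory"))
  if (.n_frames(t) < 2) stop("RMSD series needs at least 2 frames")
  if (is.null(selection)) selection <- select_atoms(t, segment = "protein")
  if (length(selection) == 0) stop("empty selection")
  M <- .superposed_selection(t, selection, reference_frame)
  ref <- M[reference_frame, ]
  rmsd <- sqrt(rowMeans((sweep(M, 2, ref))^2) * 3)
  data.frame(frame = seq_len(.n_frames(t)),
             time_ns = (seq_len(.n_frames(t)) - 1) * t$dt_ns,
             rmsd = rmsd)
}
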