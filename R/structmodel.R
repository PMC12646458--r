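# Structure container and geometric primitives.
#
# A StructureModel stores one conformer as a flat atom table (one row per
# atom) plus metadata. Columns follow PDB semantics: eleno, elety (atom
# name), altloc, resid (3-letter residue name), chain, resno (author
# numbering), icode, x/y/z (Angstrom), o (occupancy), b (B-factor; pLDDT
# 0-100 for predicted models), elesy (element symbol).

.ATOM_COLS <- c("eleno", "elety", "altloc", "resid", "chain", "resno",
                "icode", "x", "y", "z", "o", "b", "elesy")

#' Construct a StructureModel
#'
#' Low-level constructor used by \code{\link{read_structure}} and the
#' synthetic generators. Validates the atom table and orders residues
#' monotonically within each chain (ties broken by insertion code).
#'
#' @param atom data.frame with columns \code{eleno, elety, altloc, resid,
#'   chain, resno, icode, x, y, z, o, b, elesy}.
#' @param id character identifier.
#' @param predicted logical; when TRUE the B-factor column is interpreted as
#'   per-residue pLDDT and must lie in [0, 100].
#' @param source_format one of \code{"PDB"}, \code{"mmCIF"}, \code{"memory"}.
#' @return An object of class \code{StructureModel}.
#' @export
structure_model <- function(atom, id = "model", predicted = FALSE,
                            source_format = "memory") {
  stopifnot(is.data.frame(atom))
  missing_cols <- setdiff(.ATOM_COLS, names(atom))
  if (length(missing_cols) > 0)
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  atom <- atom[, .ATOM_COLS]
  if (nrow(atom) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite coordinates in atom table")
  if (any(is.na(atom$elesy) | atom$elesy == ""))
    stop("element symbol missing for one or more atoms")
  if (predicted && (any(atom$b < 0 | atom$b > 100)))
    stop("predicted structure must carry pLDDT in [0,100] in the B-factor column")
  atom$chain <- as.character(atom$chain)
  atom$icode <- as.character(atom$icode)
  atom$icode[is.na(atom$icode)] <- ""
  atom$altloc <- as.character(atom$altloc)
  atom$altloc[is.na(atom$altloc)] <- ""
  # preserve chain order of first appearance, sort residues within chain
  chain_order <- match(atom$chain, unique(atom$chain))
  atom <- atom[order(chain_order, atom$resno, atom$icode), , drop = FALSE]
  rownames(atom) <- NULL
  out <- list(id = id, atom = atom, predicted = isTRUE(predicted),
              source_format = source_format)
  class(out) <- "StructureModel"
  out
}

#' @export
print.StructureModel <- function(x, ...) {
  ch <- unique(x$atom$chain)
  nres <- nrow(unique(x$atom[, c("chain", "resno", "icode")]))
  cat(sprintf("StructureModel '%s' (%s%s): %d chains [%s], %d residues, %d atoms\n",
              x$id, x$source_format, if (x$predicted) ", predicted" else "",
              length(ch), paste(ch, collapse = ","), nres, nrow(x$atom)))
  invisible(x)
}

# Convert a bio3d pdb object to the internal atom table.
.bio3d_to_atom <- function(pdb) {
  a <- pdb$atom
  data.frame(
    eleno = as.integer(a$eleno),
    elety = as.character(a$elety),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    resid = as.character(a$resid),
    chain = ifelse(is.na(a$chain), "A", as.character(a$chain)),
    resno = as.integer(a$resno),
    icode = if ("insert" %in% names(a)) ifelse(is.na(a$insert), "", as.character(a$insert)) else "",
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1.0, a$o),
    b = ifelse(is.na(a$b), 0.0, a$b),
    elesy = .fill_element(a),
    stringsAsFactors = FALSE
  )
}

# Element symbol: take the PDB column when present, else derive from the
# atom name (first alphabetic character, PDB convention for standard names).
.fill_element <- function(a) {
  el <- if ("elesy" %in% names(a)) as.character(a$elesy) else rep(NA_character_, nrow(a))
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    guess <- sub("^[0-9]*", "", as.character(a$elety[bad]))
    el[bad] <- toupper(substr(guess, 1, 1))
  }
  el
}

# Altloc policy: for each (chain, resno, icode, elety) keep the highest
# occupancy conformer; ties broken by altloc alphabetical order ('' < 'A').
.apply_altloc_policy <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$icode, atom$elety, sep = "\r")
  ord <- order(key, -atom$o, atom$altloc)
  atom <- atom[ord, , drop = FALSE]
  atom <- atom[!duplicated(key[ord]), , drop = FALSE]
  atom[order(as.integer(rownames(atom))), , drop = FALSE]
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Reads ATOM and HETATM records into a \code{\link{structure_model}}. For
#' multi-model files only the first model is returned unless
#' \code{multi = TRUE}, in which case all models are exposed as a trajectory
#' (see \code{\link{read_trajectory}}). Alternate locations are reduced to a
#' single conformer by keeping the highest-occupancy altloc (ties broken
#' alphabetically).
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#' @param predicted logical; flag the model as predicted (B-factor = pLDDT).
#' @param multi logical; return all models. When TRUE the result carries an
#'   attribute \code{"xyz"}: a frames x 3N coordinate matrix.
#' @return A \code{StructureModel}.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           predicted = FALSE, multi = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  atom <- .bio3d_to_atom(pdb)
  if (nrow(atom) == 0) stop("empty structure: ", path)
  atom <- .apply_altloc_policy(atom)
  s <- structure_model(atom, id = sub("\\.[^.]*$", "", basename(path)),
                       predicted = predicted,
                       source_format = if (format == "pdb") "PDB" else "mmCIF")
  if (multi && !is.null(pdb$xyz) && nrow(as.matrix(pdb$xyz)) > 1) {
    attr(s, "xyz") <- as.matrix(pdb$xyz)
  }
  s
}

#' Write a StructureModel as PDB
#'
#' Emits minimal conformant ATOM records (coordinates at 3 decimals).
#'
#' @param s StructureModel.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "StructureModel"))
  a <- s$atom
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, eleno = a$eleno,
                   elety = a$elety, chain = a$chain,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   alt = ifelse(a$altloc == "", NA, a$altloc),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Atom address
#'
#' A lightweight address identifying one atom by chain, author residue
#' number, atom name and (optionally) insertion code.
#'
#' @param chain chain identifier.
#' @param resno integer residue number.
#' @param elety atom name (default \code{"CA"}).
#' @param icode insertion code (default \code{""}).
#' @return list of class \code{atom_address}.
#' @export
atom_address <- function(chain, resno, elety = "CA", icode = "") {
  out <- list(chain = as.character(chain), resno = as.integer(resno),
              elety = as.character(elety), icode = as.character(icode))
  class(out) <- "atom_address"
  out
}

# Resolve an address to a row index in s$atom; error lists near matches.
.resolve_atom <- function(s, addr) {
  a <- s$atom
  hit <- which(a$chain == addr$chain & a$resno == addr$resno &
               a$icode == addr$icode & a$elety == addr$elety)
  if (length(hit) == 1) return(hit)
  if (length(hit) > 1)
    stop(sprintf("ambiguous atom address %s/%d%s/%s: %d matches",
                 addr$chain, addr$resno, addr$icode, addr$elety, length(hit)))
  near <- which(a$chain == addr$chain & a$resno == addr$resno)
  near_txt <- if (length(near) > 0) {
    paste0("; atoms present in ", addr$chain, "/", addr$resno, ": ",
           paste(a$elety[near], collapse = " "))
  } else {
    resnos <- a$resno[a$chain == addr$chain]
    if (length(resnos) > 0)
      sprintf("; chain %s spans residues %d-%d", addr$chain,
              min(resnos), max(resnos))
    else paste0("; no chain '", addr$chain, "' (chains: ",
                paste(unique(a$chain), collapse = ","), ")")
  }
  stop(sprintf("atom not found: %s/%d%s/%s%s", addr$chain, addr$resno,
               addr$icode, addr$elety, near_txt), call. = FALSE)
}

.addr_coords <- function(s, addr) {
  i <- .resolve_atom(s, addr)
  as.numeric(s$atom[i, c("x", "y", "z")])
}

#' Euclidean distance between two atoms
#'
#' @param s StructureModel.
#' @param a,b \code{\link{atom_address}} objects (or lists with fields
#'   \code{chain, resno, elety, icode}).
#' @return distance in Angstrom.
#' @export
atom_distance <- function(s, a, b) {
  pa <- .addr_coords(s, .as_addr(a))
  pb <- .addr_coords(s, .as_addr(b))
  sqrt(sum((pa - pb)^2))
}

.as_addr <- function(x) {
  if (inherits(x, "atom_address")) return(x)
  atom_address(x$chain, x$resno,
               if (is.null(x$elety)) "CA" else x$elety,
               if (is.null(x$icode)) "" else x$icode)
}

# Kabsch rigid-body superposition of Nx3 matrices (mobile P onto reference
# Q). Returns proper rotation R (det +1), translation t and post-fit rmsd,
# with transformed points given by P %*% t(R) + t (row-wise).
.kabsch <- function(P, Q) {
  stopifnot(is.matrix(P), is.matrix(Q), ncol(P) == 3, ncol(Q) == 3,
            nrow(P) == nrow(Q))
  n <- nrow(P)
  if (n < 3) stop("superposition needs at least 3 paired atoms")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check on both point sets
  for (M in list(Pc, Qc)) {
    sv <- svd(M)$d
    if (sv[2] < max(sv[1] * 1e-8, 1e-10))
      stop("degenerate (collinear) atom set: superposition undefined")
  }
  H <- crossprod(Pc, Qc)               # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- as.numeric(cq - R %*% cp)
  fitted <- P %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes \code{mobile} onto \code{reference} over a set of paired atoms
#' and returns the proper rotation, translation and post-fit RMSD, together
#' with the transformed mobile structure.
#'
#' @param mobile,reference StructureModel objects.
#' @param pairing data.frame of atom addresses. Either shared columns
#'   \code{chain, resno, elety} (optionally \code{icode}) applied to both
#'   structures, or separate \code{*_mobile} / \code{*_reference} columns.
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (length 3), \code{rmsd} (Angstrom, post-fit) and \code{mobile_fit}
#'   (transformed StructureModel).
#' @export
kabsch_superpose <- function(mobile, reference, pairing) {
  stopifnot(inherits(mobile, "StructureModel"),
            inherits(reference, "StructureModel"),
            is.data.frame(pairing))
  split_cols <- all(c("chain_mobile", "resno_mobile") %in% names(pairing))
  get_addr <- function(row, side) {
    if (split_cols) {
      atom_address(row[[paste0("chain_", side)]], row[[paste0("resno_", side)]],
                   if (!is.null(row[[paste0("elety_", side)]])) row[[paste0("elety_", side)]] else "CA",
                   if (!is.null(row[[paste0("icode_", side)]])) row[[paste0("icode_", side)]] else "")
    } else {
      atom_address(row$chain, row$resno,
                   if (!is.null(row$elety)) row$elety else "CA",
                   if (!is.null(row$icode)) row$icode else "")
    }
  }
  n <- nrow(pairing)
  P <- matrix(0, n, 3); Q <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    row <- as.list(pairing[k, , drop = FALSE])
    P[k, ] <- .addr_coords(mobile, get_addr(row, "mobile"))
    Q[k, ] <- .addr_coords(reference, get_addr(row, "reference"))
  }
  fit <- .kabsch(P, Q)
  fit$mobile_fit <- transform_structure(mobile, fit$rotation, fit$translation)
  fit
}

#' Apply a rigid transform to all atoms of a structure
#'
#' @param s StructureModel.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed StructureModel.
#' @export
transform_structure <- function(s, rotation, translation = c(0, 0, 0)) {
  xyz <- as.matrix(s$atom[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  s$atom$x <- xyz[, 1]; s$atom$y <- xyz[, 2]; s$atom$z <- xyz[, 3]
  s
}

# Residue table: one row per residue with indices into the atom table.
.residues <- function(s, chain = NULL) {
  a <- s$atom
  keep <- if (is.null(chain)) rep(TRUE, nrow(a)) else a$chain %in% chain
  key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  u <- !duplicated(key) & keep
  data.frame(chain = a$chain[u], resno = a$resno[u], icode = a$icode[u],
             resid = a$resid[u], stringsAsFactors = FALSE)
}
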