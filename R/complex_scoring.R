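# Scoring of predicted two-chain complexes: interface confidence (pDockQ)
# and a heavy-atom steric clashscore, plus Pareto ranking of a candidate
# library ("in silico pulldown" screen).

# pDockQ sigmoid parameterization (published calibration):
# score = L / (1 + exp(-k (x - x0))) + b, x = mean interface pLDDT * log10(#contacts)
.PDOCKQ_L <- 0.724
.PDOCKQ_K <- 0.052
.PDOCKQ_X0 <- 152.611
.PDOCKQ_B <- 0.018

# van der Waals radii (Angstrom) for the heavy-atom clash model
.VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.VDW_DEFAULT <- 1.70
.CLASH_OVERLAP <- 0.4   # serious-overlap threshold
.COVALENT_MIN <- 1.2    # pairs closer than this treated as covalent records

# Representative atom per residue for contact detection: CB, CA for glycine.
# Residues lacking a representative atom are skipped with a warning.
.rep_atoms <- function(s, chain) {
  a <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' not found or empty")
  key <- paste(a$resno, a$icode, sep = "\r")
  res_keys <- unique(key)
  idx <- integer(0); skipped <- character(0)
  for (k in res_keys) {
    rows <- which(key == k)
    cb <- rows[a$elety[rows] == "CB"]
    ca <- rows[a$elety[rows] == "CA"]
    if (length(cb) > 0) {
      idx <- c(idx, cb[1])
    } else if (length(ca) > 0 && a$resid[rows[1]] == "GLY") {
      idx <- c(idx, ca[1])
    } else {
      skipped <- c(skipped, paste0(chain, "/", a$resno[rows[1]], a$icode[rows[1]]))
    }
  }
  if (length(skipped) > 0)
    warning("skipped ", length(skipped),
            " residue(s) without representative atom (CB, or CA for GLY): ",
            paste(utils::head(skipped, 5), collapse = " "),
            if (length(skipped) > 5) " ..." else "")
  a[idx, , drop = FALSE]
}

#' Interface contacts between two chains
#'
#' A contact is a cross-chain residue pair whose representative atoms
#' (C-beta; C-alpha for glycine) lie within \code{cutoff} Angstrom. Result
#' rows are ordered by chain-A residue number, then chain-B.
#'
#' @param s StructureModel.
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return data.frame with columns \code{chain_a, resno_a, icode_a, resid_a,
#'   chain_b, resno_b, icode_b, resid_b, distance}.
#' @export
find_interface_contacts <- function(s, chain_a, chain_b, cutoff = 8.0) {
  stopifnot(inherits(s, "StructureModel"), cutoff >= 0)
  if (chain_a == chain_b) stop("chain_a and chain_b must differ")
  ra <- .rep_atoms(s, chain_a)
  rb <- .rep_atoms(s, chain_b)
  empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                      icode_a = character(0), resid_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      icode_b = character(0), resid_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(ra) == 0 || nrow(rb) == 0 || cutoff == 0) return(empty)
  A <- as.matrix(ra[, c("x", "y", "z")])
  B <- as.matrix(rb[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  out <- data.frame(
    chain_a = chain_a, resno_a = ra$resno[hit[, 1]],
    icode_a = ra$icode[hit[, 1]], resid_a = ra$resid[hit[, 1]],
    chain_b = chain_b, resno_b = rb$resno[hit[, 2]],
    icode_b = rb$icode[hit[, 2]], resid_b = rb$resid[hit[, 2]],
    distance = sqrt(d2[hit]), stringsAsFactors = FALSE)
  out <- out[order(out$resno_a, out$icode_a, out$resno_b, out$icode_b), ]
  rownames(out) <- NULL
  out
}

#' pDockQ interface-confidence score
#'
#' Computes the pDockQ score for a predicted two-chain complex:
#' interface residues are those appearing in at least one representative-atom
#' contact (\code{\link{find_interface_contacts}}); the score is the
#' published sigmoid of x = (mean interface pLDDT) x log10(number of
#' contacts). With zero contacts the score is the sigmoid floor 0.018 and
#' x is reported as 0.
#'
#' @param s StructureModel flagged \code{predicted} (B-factor = pLDDT).
#' @param chain_a,chain_b chain identifiers.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return list of class \code{pdockq} with \code{n_contacts},
#'   \code{mean_if_plddt}, \code{x}, \code{score}, \code{contacts}.
#' @export
compute_pdockq <- function(s, chain_a, chain_b, cutoff = 8.0) {
  stopifnot(inherits(s, "StructureModel"))
  if (!s$predicted)
    stop("compute_pdockq requires a structure flagged predicted ",
         "(B-factor column interpreted as pLDDT)")
  contacts <- find_interface_contacts(s, chain_a, chain_b, cutoff)
  n <- nrow(contacts)
  if (n == 0) {
    out <- list(n_contacts = 0L, mean_if_plddt = NA_real_, x = 0,
                score = .PDOCKQ_B, contacts = contacts)
    class(out) <- "pdockq"
    return(out)
  }
  # per-residue pLDDT = mean B over the residue's atoms
  a <- s$atom
  res_key <- paste(a$chain, a$resno, a$icode, sep = "\r")
  plddt_by_res <- tapply(a$b, res_key, mean)
  if_keys <- unique(c(paste(contacts$chain_a, contacts$resno_a, contacts$icode_a, sep = "\r"),
                      paste(contacts$chain_b, contacts$resno_b, contacts$icode_b, sep = "\r")))
  mean_if <- mean(plddt_by_res[if_keys])
  x <- mean_if * log10(n)
  score <- .PDOCKQ_L / (1 + exp(-.PDOCKQ_K * (x - .PDOCKQ_X0))) + .PDOCKQ_B
  out <- list(n_contacts = as.integer(n), mean_if_plddt = as.numeric(mean_if),
              x = as.numeric(x), score = as.numeric(score), contacts = contacts)
  class(out) <- "pdockq"
  out
}

#' @export
print.pdockq <- function(x, ...) {
  cat(sprintf("pDockQ = %.3f (contacts = %d, mean interface pLDDT = %s, x = %.2f)\n",
              x$score, x$n_contacts,
              if (is.na(x$mean_if_plddt)) "NA" else sprintf("%.1f", x$mean_if_plddt),
              x$x))
  invisible(x)
}

.heavy_atoms <- function(s) {
  a <- s$atom
  a[!(toupper(a$elesy) %in% c("H", "D")), , drop = FALSE]
}

.vdw_radius <- function(elesy) {
  r <- .VDW_RADII[toupper(elesy)]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elesy[unknown]), collapse = ","),
            ": using default vdW radius ", .VDW_DEFAULT, " A")
    r[unknown] <- .VDW_DEFAULT
  }
  as.numeric(r)
}

# Candidate neighbor pairs (i < j) within max_d, via a uniform cell grid
# (spatial hash). Exact: every returned pair is checked downstream.
.cell_pairs <- function(xyz, max_d) {
  n <- nrow(xyz)
  cell <- floor(xyz / max_d)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  buckets <- split(seq_len(n), key)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out_i <- integer(0); out_j <- integer(0)
  for (b in names(buckets)) {
    ijk <- as.integer(strsplit(b, ",", fixed = TRUE)[[1]])
    ids <- buckets[[b]]
    # same-cell pairs
    if (length(ids) > 1) {
      cmb <- utils::combn(ids, 2)
      out_i <- c(out_i, cmb[1, ]); out_j <- c(out_j, cmb[2, ])
    }
    # neighbor cells: only keys lexicographically after this one (no dupes)
    for (r in seq_len(nrow(offs))) {
      if (all(offs[r, ] == 0)) next
      nb <- paste(ijk[1] + offs[r, 1], ijk[2] + offs[r, 2], ijk[3] + offs[r, 3], sep = ",")
      if (nb <= b) next
      nb_ids <- buckets[[nb]]
      if (is.null(nb_ids)) next
      grid <- expand.grid(i = ids, j = nb_ids)
      out_i <- c(out_i, grid$i); out_j <- c(out_j, grid$j)
    }
  }
  if (length(out_i) == 0) return(matrix(integer(0), 0, 2))
  swap <- out_i > out_j
  tmp <- out_i[swap]; out_i[swap] <- out_j[swap]; out_j[swap] <- tmp
  cbind(out_i, out_j)
}

.brute_pairs <- function(xyz, max_d) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(0), 0, 2))
  d2 <- as.matrix(stats::dist(xyz))^2
  hit <- which(upper.tri(d2) & d2 <= max_d^2, arr.ind = TRUE)
  hit
}

#' Heavy-atom steric clashscore
#'
#' A clash is an unordered pair of non-bonded heavy atoms whose distance is
#' below the sum of their van der Waals radii minus 0.4 Angstrom. Bonded and
#' near-bonded pairs are excluded by rule: same residue; the backbone pairs
#' C(i)-N(i+1), C(i)-CA(i+1), O(i)-N(i+1) and CA(i)-N(i+1) of
#' sequence-adjacent residues; and any pair closer than 1.2 Angstrom
#' (assumed covalent record). The clashscore is clashes per 1000 heavy
#' atoms. This is a hydrogen-free approximation of the MolProbity
#' clashscore intended for relative ranking of predicted models.
#'
#' @param s StructureModel with at least 2 heavy atoms.
#' @param method neighbor search: \code{"cell"} (spatial hash, default) or
#'   \code{"brute"} (all-pairs; for cross-checking).
#' @return list of class \code{clash_report} with \code{n_heavy_atoms},
#'   \code{clashes} (data.frame: atom indices, names, overlap) and
#'   \code{clashscore}.
#' @export
compute_clashscore <- function(s, method = c("cell", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "StructureModel"))
  a <- .heavy_atoms(s)
  n <- nrow(a)
  if (n < 2) stop("clashscore needs at least 2 heavy atoms")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- suppressWarnings(.vdw_radius(a$elesy))
  if (any(!toupper(a$elesy) %in% names(.VDW_RADII)))
    warning("unknown element(s) assigned default vdW radius ", .VDW_DEFAULT, " A")
  max_d <- 2 * max(radii) - .CLASH_OVERLAP
  pairs <- if (method == "cell") .cell_pairs(xyz, max_d) else .brute_pairs(xyz, max_d)
  clashes <- data.frame(i = integer(0), j = integer(0),
                        atom_i = character(0), atom_j = character(0),
                        distance = numeric(0), overlap = numeric(0),
                        stringsAsFactors = FALSE)
  if (nrow(pairs) > 0) {
    i <- pairs[, 1]; j <- pairs[, 2]
    d <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    thresh <- radii[i] + radii[j] - .CLASH_OVERLAP
    cand <- d < thresh & d >= .COVALENT_MIN
    i <- i[cand]; j <- j[cand]; d <- d[cand]; thresh <- thresh[cand]
    if (length(i) > 0) {
      same_res <- a$chain[i] == a$chain[j] & a$resno[i] == a$resno[j] &
        a$icode[i] == a$icode[j]
      # sequence-adjacent backbone exclusions (directional: lower resno first)
      lo <- ifelse(a$resno[i] <= a$resno[j], i, j)
      hi <- ifelse(a$resno[i] <= a$resno[j], j, i)
      adj <- a$chain[i] == a$chain[j] & abs(a$resno[i] - a$resno[j]) == 1
      pair_name <- paste(a$elety[lo], a$elety[hi], sep = "-")
      backbone <- adj & pair_name %in% c("C-N", "C-CA", "O-N", "CA-N")
      keep <- !(same_res | backbone)
      i <- i[keep]; j <- j[keep]; d <- d[keep]; thresh <- thresh[keep]
      if (length(i) > 0) {
        ord <- order(i, j)
        i <- i[ord]; j <- j[ord]; d <- d[ord]; thresh <- thresh[ord]
        clashes <- data.frame(
          i = i, j = j,
          atom_i = paste0(a$chain[i], "/", a$resno[i], "/", a$elety[i]),
          atom_j = paste0(a$chain[j], "/", a$resno[j], "/", a$elety[j]),
          distance = d, overlap = thresh + .CLASH_OVERLAP - d,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(n_heavy_atoms = n, clashes = clashes,
              clashscore = 1000 * nrow(clashes) / n)
  class(out) <- "clash_report"
  out
}

#' @export
print.clash_report <- function(x, ...) {
  cat(sprintf("clashscore = %.2f (%d clashes / %d heavy atoms)\n",
              x$clashscore, nrow(x$clashes), x$n_heavy_atoms))
  invisible(x)
}

#' Pareto ranking of screen candidates
#'
#' Ranks candidate complexes on the (maximize pDockQ, minimize clashscore)
#' plane into successive Pareto fronts. Within a front, entries are sorted
#' by pDockQ descending with ties broken by candidate id. Entries with
#' non-finite scores are rejected with a warning. Front-1 entries with
#' pDockQ above \code{hit_threshold} are flagged as hits.
#'
#' @param entries data.frame with columns \code{candidate_id, pdockq,
#'   clashscore}.
#' @param hit_threshold pDockQ threshold for the report-only hit flag
#'   (default 0.5).
#' @return data.frame with added \code{pareto_rank} and \code{hit} columns.
#' @export
rank_screen <- function(entries, hit_threshold = 0.5) {
  stopifnot(is.data.frame(entries),
            all(c("candidate_id", "pdockq", "clashscore") %in% names(entries)))
  if (nrow(entries) == 0) stop("rank_screen needs at least one entry")
  ok <- is.finite(entries$pdockq) & is.finite(entries$clashscore)
  if (any(!ok)) {
    warning("rejecting ", sum(!ok), " entr(ies) with non-finite scores: ",
            paste(entries$candidate_id[!ok], collapse = ", "))
    entries <- entries[ok, , drop = FALSE]
  }
  if (nrow(entries) == 0) stop("no entries with finite scores")
  n <- nrow(entries)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  level <- 0L
  while (length(remaining) > 0) {
    level <- level + 1L
    p <- entries$pdockq[remaining]; c_ <- entries$clashscore[remaining]
    nondom <- vapply(seq_along(remaining), function(k) {
      dominated <- (p >= p[k]) & (c_ <= c_[k]) & ((p > p[k]) | (c_ < c_[k]))
      !any(dominated)
    }, logical(1))
    rank[remaining[nondom]] <- level
    remaining <- remaining[!nondom]
  }
  entries$pareto_rank <- rank
  entries$hit <- entries$pareto_rank == 1L & entries$pdockq > hit_threshold
  entries <- entries[order(entries$pareto_rank, -entries$pdockq,
                           entries$candidate_id), , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

#' Score a library of candidate complex models
#'
#' Runs \code{\link{compute_pdockq}} and \code{\link{compute_clashscore}}
#' over a set of model files and ranks the results with
#' \code{\link{rank_screen}}. Unreadable models are logged and skipped;
#' the run continues.
#'
#' @param paths character vector of PDB/mmCIF files (one candidate each),
#'   or a single directory.
#' @param chain_a,chain_b chain identifiers (transporter and candidate).
#' @param cutoff contact cutoff in Angstrom.
#' @param hit_threshold see \code{\link{rank_screen}}.
#' @return data.frame: \code{candidate_id, n_contacts, mean_if_plddt,
#'   pdockq, clashscore, pareto_rank, hit}.
#' @export
screen_models <- function(paths, chain_a = "A", chain_b = "B", cutoff = 8.0,
                          hit_threshold = 0.5) {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif|mmcif)$",
                        full.names = TRUE, ignore.case = TRUE)
  }
  if (length(paths) == 0) stop("no model files to screen")
  rows <- list()
  for (p in sort(paths)) {
    id <- sub("\\.[^.]*$", "", basename(p))
    res <- tryCatch({
      s <- read_structure(p, predicted = TRUE)
      pq <- compute_pdockq(s, chain_a, chain_b, cutoff)
      cs <- compute_clashscore(s)
      data.frame(candidate_id = id, n_contacts = pq$n_contacts,
                 mean_if_plddt = pq$mean_if_plddt, pdockq = pq$score,
                 clashscore = cs$clashscore, stringsAsFactors = FALSE)
    }, error = function(e) {
      message("screen: skipping '", id, "': ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  if (length(rows) == 0) stop("no candidate model could be scored")
  tab <- do.call(rbind, rows)
  ranked <- rank_screen(tab[, c("candidate_id", "pdockq", "clashscore")],
                        hit_threshold = hit_threshold)
  extra <- tab[match(ranked$candidate_id, tab$candidate_id),
               c("n_contacts", "mean_if_plddt"), drop = FALSE]
  out <- cbind(ranked, extra)
  rownames(out) <- NULL
  out[, c("candidate_id", "n_contacts", "mean_if_plddt", "pdockq",
          "clashscore", "pareto_rank", "hit")]
}

#' Scatter plot of a ranked screen
#'
#' Plots the (clashscore, pDockQ) plane with Pareto front-1 entries
#' highlighted.
#'
#' @param ranked output of \code{\link{rank_screen}} or
#'   \code{\link{screen_models}}.
#' @param ... passed to \code{plot}.
#' @return invisibly, \code{ranked}.
#' @export
plot_screen <- function(ranked, ...) {
  plot(ranked$clashscore, ranked$pdockq, xlab = "clashscore",
       ylab = "pDockQ", pch = 19,
       col = ifelse(ranked$pareto_rank == 1, "red", "grey40"), ...)
  hits <- ranked[ranked$hit, , drop = FALSE]
  if (nrow(hits) > 0)
    graphics::text(hits$clashscore, hits$pdockq, hits$candidate_id, pos = 4, cex = 0.8)
  invisible(ranked)
}
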