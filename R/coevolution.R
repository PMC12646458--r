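# Inter-protein coevolution Z-analysis. A coupling matrix for a
# concatenated two-protein alignment (CCMPred plain-matrix dialect: L rows
# of L whitespace-separated floats) is partitioned into two chains; the
# inter-chain block is standardized into Z-scores and thresholded into
# candidate contact pairs.

#' Read a coupling matrix (CCMPred plain-matrix dialect)
#'
#' Parses L rows of L whitespace-separated floats. The matrix is
#' symmetrized as (M + t(M))/2 with a warning when the asymmetry exceeds
#' 1e-6, and the diagonal is forced to zero.
#'
#' @param path file path.
#' @return list of class \code{coupling_matrix} with \code{scores} (L x L)
#'   and \code{L}.
#' @export
read_coupling_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty coupling matrix file: ", path)
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (any(is.na(v))) stop("non-numeric value in row ", i, " of ", path)
    v
  })
  L <- length(rows[[1]])
  len <- vapply(rows, length, integer(1))
  if (any(len != L))
    stop("ragged coupling matrix: row ", which(len != L)[1], " has ",
         len[len != L][1], " values, expected ", L)
  if (length(rows) != L)
    stop("coupling matrix not square: ", length(rows), " rows x ", L, " columns")
  m <- do.call(rbind, rows)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    warning(sprintf("coupling matrix asymmetry %.3g > 1e-6; symmetrizing as (M + t(M))/2", asym))
  m <- (m + t(m)) / 2
  diag(m) <- 0
  out <- list(scores = m, L = L)
  class(out) <- "coupling_matrix"
  out
}

#' Write a coupling matrix in the plain-matrix dialect
#'
#' Values are written at full double precision so that a write/read round
#' trip is bit-identical.
#'
#' @param m \code{coupling_matrix} (or plain square matrix).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_coupling_matrix <- function(m, path) {
  scores <- if (inherits(m, "coupling_matrix")) m$scores else as.matrix(m)
  txt <- apply(scores, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Extract the inter-chain block of a coupling matrix
#'
#' For a concatenated alignment partitioned into chain A (positions
#' 1..len_a) and chain B (positions len_a+1..L), returns one row per
#' (i in A, j in B) cell with 1-based within-chain positions.
#'
#' @param m \code{coupling_matrix}.
#' @param len_a,len_b chain lengths; must sum to L.
#' @return data.frame \code{pos_a, pos_b, raw} with len_a x len_b rows.
#' @export
extract_interchain <- function(m, len_a, len_b) {
  stopifnot(inherits(m, "coupling_matrix"))
  len_a <- as.integer(len_a); len_b <- as.integer(len_b)
  if (len_a < 1 || len_b < 1 || len_a + len_b != m$L)
    stop("invalid partition: len_a + len_b must equal L = ", m$L)
  block <- m$scores[seq_len(len_a), len_a + seq_len(len_b), drop = FALSE]
  out <- data.frame(
    pos_a = rep(seq_len(len_a), times = len_b),
    pos_b = rep(seq_len(len_b), each = len_a),
    raw = as.numeric(block))
  out[order(out$pos_a, out$pos_b), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Z-score a set of coupling pairs
#'
#' Standardizes raw coupling scores against the mean and population
#' standard deviation of a background population. By default the supplied
#' pair set (the inter-protein block) is both signal and background; a
#' whole-matrix background can be supplied instead via \code{background}.
#'
#' @param pairs data.frame with columns \code{pos_a, pos_b, raw}.
#' @param background optional numeric vector of raw scores to standardize
#'   against (e.g. all off-diagonal cells of the matrix); default uses
#'   \code{pairs$raw} itself.
#' @return the input with an added \code{z} column. With the default
#'   background, z has mean 0 and population sd 1.
#' @export
zscore_pairs <- function(pairs, background = NULL) {
  stopifnot(is.data.frame(pairs), all(c("pos_a", "pos_b", "raw") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("need at least 2 pairs to Z-score")
  bg <- if (is.null(background)) pairs$raw else as.numeric(background)
  mu <- mean(bg)
  sigma <- sqrt(mean((bg - mu)^2))   # population sd
  if (sigma == 0) stop("degenerate background: all raw scores equal")
  pairs$z <- (pairs$raw - mu) / sigma
  pairs
}

#' Average-product correction of a coupling matrix
#'
#' Applies the standard APC: corrected_ij = M_ij - mean_i * mean_j /
#' mean_all, computed over off-diagonal cells, with the diagonal kept at
#' zero. Off by default in the pipeline; exposed for sensitivity analysis.
#'
#' @param m \code{coupling_matrix}.
#' @return corrected \code{coupling_matrix}.
#' @export
apc_correct <- function(m) {
  stopifnot(inherits(m, "coupling_matrix"))
  sc <- m$scores
  L <- m$L
  off <- sum(sc) / (L * (L - 1))             # mean over off-diagonal cells
  rowm <- rowSums(sc) / (L - 1)
  corr <- sc - outer(rowm, rowm) / off
  diag(corr) <- 0
  out <- list(scores = corr, L = L)
  class(out) <- "coupling_matrix"
  out
}

#' Filter and sort high-Z coevolving pairs
#'
#' @param pairs Z-scored pair table (see \code{\link{zscore_pairs}}).
#' @param z_min threshold; pairs with z strictly above it are kept
#'   (default 10).
#' @return filtered data.frame sorted by z descending, ties by
#'   (pos_a, pos_b).
#' @export
top_pairs <- function(pairs, z_min = 10) {
  stopifnot(is.data.frame(pairs), "z" %in% names(pairs))
  out <- pairs[pairs$z > z_min, , drop = FALSE]
  out <- out[order(-out$z, out$pos_a, out$pos_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of coevolution Z-scores
#'
#' @param pairs Z-scored pair table.
#' @param bin_width positive bin width.
#' @return list with \code{edges} (length nbins+1, covering [min z, max z])
#'   and \code{counts} (summing to the number of pairs).
#' @export
z_histogram <- function(pairs, bin_width = 0.5) {
  stopifnot(is.data.frame(pairs), "z" %in% names(pairs))
  if (nrow(pairs) == 0) stop("no pairs to histogram")
  if (!is.finite(bin_width) || bin_width <= 0) stop("bin_width must be > 0")
  z <- pairs$z
  lo <- min(z)
  nbin <- max(1L, ceiling((max(z) - lo) / bin_width))
  edges <- lo + bin_width * (0:nbin)
  if (edges[length(edges)] < max(z)) edges <- c(edges, edges[length(edges)] + bin_width)
  counts <- as.integer(table(cut(z, breaks = edges, include.lowest = TRUE, right = FALSE)))
  # right-open bins: top value falls in the last bin via include.lowest on
  # the left; ensure the maximum is counted
  if (sum(counts) != length(z)) {
    counts[length(counts)] <- counts[length(counts)] + (length(z) - sum(counts))
  }
  list(edges = edges, counts = counts)
}

#' Map coevolving pairs onto a structure
#'
#' Translates within-chain alignment positions into author residue numbers
#' via a chain map and measures C-alpha and minimum heavy-atom distances
#' with the structure primitives. Unresolvable residues are reported in the
#' output (distances NA), not silently dropped.
#'
#' @param pairs Z-scored pair table.
#' @param s StructureModel.
#' @param chain_map named list with entries \code{a} and \code{b}, each
#'   \code{list(chain = <id>, offset = <int>)}; residue number =
#'   position + offset.
#' @return data.frame with per-pair \code{resno_a, resno_b, ca_distance,
#'   min_heavy_distance, resolved}.
#' @export
map_pairs_to_structure <- function(pairs, s, chain_map) {
  stopifnot(inherits(s, "StructureModel"), is.list(chain_map))
  for (side in c("a", "b")) {
    if (is.null(chain_map[[side]]) || is.null(chain_map[[side]]$chain))
      stop("chain_map must provide $", side, "$chain")
    if (is.null(chain_map[[side]]$offset)) chain_map[[side]]$offset <- 0L
  }
  ha <- .heavy_atoms(s)
  out <- pairs
  out$chain_a <- chain_map$a$chain
  out$chain_b <- chain_map$b$chain
  out$resno_a <- pairs$pos_a + chain_map$a$offset
  out$resno_b <- pairs$pos_b + chain_map$b$offset
  n <- nrow(out)
  out$ca_distance <- NA_real_
  out$min_heavy_distance <- NA_real_
  out$resolved <- FALSE
  for (k in seq_len(n)) {
    ia <- which(ha$chain == out$chain_a[k] & ha$resno == out$resno_a[k])
    ib <- which(ha$chain == out$chain_b[k] & ha$resno == out$resno_b[k])
    if (length(ia) == 0 || length(ib) == 0) next
    A <- as.matrix(ha[ia, c("x", "y", "z")])
    B <- as.matrix(ha[ib, c("x", "y", "z")])
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    out$min_heavy_distance[k] <- sqrt(max(0, min(d2)))
    ca_a <- ia[ha$elety[ia] == "CA"]; ca_b <- ib[ha$elety[ib] == "CA"]
    if (length(ca_a) == 1 && length(ca_b) == 1) {
      out$ca_distance[k] <- sqrt(sum((as.numeric(ha[ca_a, c("x", "y", "z")]) -
                                      as.numeric(ha[ca_b, c("x", "y", "z")]))^2))
    }
    out$resolved[k] <- TRUE
  }
  n_unres <- sum(!out$resolved)
  if (n_unres > 0)
    warning(n_unres, " pair(s) could not be resolved in the structure (reported with NA distances)")
  out
}
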