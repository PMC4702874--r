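# Network model: coarse-grained node selection and the Kirchhoff (graph
# Laplacian) connectivity matrix.

# Residue vocabularies. Amino acids cover the 20 standards; hetero residues
# are admitted as protein nodes only through an explicit parent mapping
# (e.g. selenomethionine), never by default.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.nt  <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DU", "DI")
.default_hetero_map <- c(MSE = "MET", SEC = "CYS", PYL = "LYS")

# Nucleotide node atoms, in within-residue order: phosphate, sugar, base.
.nt_node_atoms <- c("P", "C4'", "C2")

#' Select GNM nodes from a molecular structure
#'
#' Maps a parsed (and, if desired, assembly-resolved) structure onto the
#' coarse-grained network: one node per amino acid at its C-alpha, and up to
#' three nodes per nucleotide at the P, C4' and C2 atoms (phosphate, sugar
#' and base groups), in that within-residue order. Residues missing a
#' required atom (e.g. the 5'-terminal phosphate) simply contribute fewer
#' nodes. Ligands, waters and other hetero groups are not nodes unless
#' mapped to a parent standard residue via `hetero_map`.
#'
#' @param x A `gnm_structure`.
#' @param hetero_map Named character vector mapping modified residue names
#'   to standard parents (default covers MSE, SEC, PYL).
#' @return A `gnm_nodes` object: list with `xyz` (N x 3 matrix, Angstrom),
#'   `label` (data frame: `chain`, `resno`, `insert`, `elety`, `resid`),
#'   `node_class` (`"protein"` or `"nucleotide"`) and `b` (experimental
#'   B-factors, `NA` when absent).
#' @export
select_nodes <- function(x, hetero_map = .default_hetero_map) {
  stopifnot(inherits(x, "gnm_structure"))
  a <- x$atom
  resid_eff <- a$resid
  mapped <- a$resid %in% names(hetero_map)
  resid_eff[mapped] <- hetero_map[a$resid[mapped]]
  is_node <-
    (resid_eff %in% .aa3 & a$elety == "CA" &
       (a$type == "ATOM" | mapped)) |
    (resid_eff %in% .nt & a$elety %in% .nt_node_atoms & a$type == "ATOM")
  rows <- a[is_node, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("empty network: structure contains no eligible GNM nodes")

  cls <- ifelse(resid_eff[is_node] %in% .aa3, "protein", "nucleotide")
  # order nucleotide nodes P -> C4' -> C2 within each residue, keeping the
  # file's residue order
  res_key <- paste(rows$chain, rows$resno, rows$insert, sep = "|")
  res_rank <- match(res_key, unique(res_key))
  atom_rank <- match(rows$elety, .nt_node_atoms)
  atom_rank[cls == "protein"] <- 0L
  ord <- order(res_rank, atom_rank)
  rows <- rows[ord, , drop = FALSE]
  cls <- cls[ord]

  # each residue contributes at most one node per role
  dup <- duplicated(paste(rows$chain, rows$resno, rows$insert, rows$elety,
                          sep = "|"))
  rows <- rows[!dup, , drop = FALSE]
  cls <- cls[!dup]

  nt_res <- unique(paste(rows$chain, rows$resno, rows$insert)[cls == "nucleotide"])
  n_missing <- 3L * length(nt_res) - sum(cls == "nucleotide")
  if (n_missing > 0L)
    message("note: ", n_missing, " nucleotide node atom(s) absent ",
            "(e.g. 5'-terminal phosphates); affected residues contribute ",
            "fewer nodes")

  b <- rows$b
  if (!x$metadata$has_b) b <- rep(NA_real_, nrow(rows))
  out <- list(
    xyz = unname(as.matrix(rows[, c("x", "y", "z")])),
    label = data.frame(chain = rows$chain, resno = rows$resno,
                       insert = rows$insert, elety = rows$elety,
                       resid = rows$resid, stringsAsFactors = FALSE),
    node_class = cls,
    b = b)
  class(out) <- "gnm_nodes"
  out
}

gnm_n_nodes <- function(nodes) {
  stopifnot(inherits(nodes, "gnm_nodes"))
  nrow(nodes$xyz)
}

#' @export
print.gnm_nodes <- function(x, ...) {
  cat("gnm_nodes:", gnm_n_nodes(x), "nodes (",
      sum(x$node_class == "protein"), "protein /",
      sum(x$node_class == "nucleotide"), "nucleotide ),",
      length(unique(x$label$chain)), "chain(s)\n")
  invisible(x)
}

# All node pairs within `cutoff` Angstrom of each other. The cell-list path
# bins nodes into a cutoff-sized grid and compares only neighboring cells;
# below `brute_below` nodes a plain O(N^2) distance matrix is faster. Both
# paths return the identical pair set (i < j, ordered).
neighbor_pairs <- function(xyz, cutoff,
                           method = c("auto", "brute", "cell"),
                           brute_below = 500L) {
  method <- match.arg(method)
  n <- nrow(xyz)
  if (method == "auto") method <- if (n < brute_below) "brute" else "cell"
  if (method == "brute") {
    d <- as.matrix(stats::dist(xyz))
    hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
    ord <- order(hit[, 1], hit[, 2])
    return(cbind(i = hit[ord, 1], j = hit[ord, 2]))
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  dims <- apply(cell, 2, max) + 1L
  id <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  buckets <- split(seq_len(n), id)
  key_of <- function(cx, cy, cz) cx + dims[1] * (cy + dims[2] * cz)
  cell_xyz <- t(vapply(as.numeric(names(buckets)), function(k) {
    cx <- k %% dims[1]; k <- (k - cx) / dims[1]
    cy <- k %% dims[2]; cz <- (k - cy) / dims[2]
    c(cx, cy, cz)
  }, numeric(3)))
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  pairs <- vector("list", length(buckets) * 14L)
  np <- 0L
  bucket_key <- as.numeric(names(buckets))
  for (bi in seq_along(buckets)) {
    here <- buckets[[bi]]
    cx <- cell_xyz[bi, 1]; cy <- cell_xyz[bi, 2]; cz <- cell_xyz[bi, 3]
    # within-cell pairs
    if (length(here) > 1) {
      d <- as.matrix(stats::dist(xyz[here, , drop = FALSE]))
      hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
      if (nrow(hit)) {
        np <- np + 1L
        pairs[[np]] <- cbind(here[hit[, 1]], here[hit[, 2]])
      }
    }
    # half the neighbor cells, to visit each cell pair once
    for (oi in seq_len(nrow(offsets))) {
      off <- offsets[oi, ]
      if (off[1] == 0 && off[2] == 0 && off[3] == 0) next
      if (off[3] < 0 || (off[3] == 0 && (off[2] < 0 ||
          (off[2] == 0 && off[1] < 0)))) next
      nx <- cx + off[1]; ny <- cy + off[2]; nz <- cz + off[3]
      if (nx < 0 || ny < 0 || nz < 0 ||
          nx >= dims[1] || ny >= dims[2] || nz >= dims[3]) next
      bj <- match(key_of(nx, ny, nz), bucket_key)
      if (is.na(bj)) next
      there <- buckets[[bj]]
      dx <- outer(xyz[here, 1], xyz[there, 1], "-")
      dy <- outer(xyz[here, 2], xyz[there, 2], "-")
      dz <- outer(xyz[here, 3], xyz[there, 3], "-")
      hit <- which(dx * dx + dy * dy + dz * dz <= cutoff^2, arr.ind = TRUE)
      if (nrow(hit)) {
        np <- np + 1L
        pairs[[np]] <- cbind(here[hit[, 1]], there[hit[, 2]])
      }
    }
  }
  if (np == 0L) return(cbind(i = integer(0), j = integer(0)))
  out <- do.call(rbind, pairs[seq_len(np)])
  out <- cbind(i = pmin(out[, 1], out[, 2]), j = pmax(out[, 1], out[, 2]))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' Build the Kirchhoff (connectivity) matrix
#'
#' Constructs the graph Laplacian of the contact network: off-diagonal
#' entries are -1 for node pairs within the cutoff distance (boundary
#' inclusive) and 0 otherwise; each diagonal entry is the node's contact
#' count (degree), so every row sums to zero. The spring constant is
#' uniform and set to 1: it rescales fluctuation amplitudes but not their
#' distribution, correlations or mode shapes. The default cutoff of 7.3
#' Angstrom sits inside the 7.0-7.5 first coordination shell established
#' for folded proteins and is applied uniformly to all node pairs,
#' including protein-nucleotide and nucleotide-nucleotide contacts.
#'
#' @param nodes A `gnm_nodes` object, or an N x 3 coordinate matrix.
#' @param cutoff Contact cutoff distance r_c in Angstrom (default 7.3).
#' @param method Neighbor search: `"auto"` picks brute force below 500
#'   nodes and a cell-list grid above; both give identical results.
#' @return A `gnm_kirchhoff` object: list with `gamma` (N x N integer-valued
#'   symmetric matrix), `cutoff`, `n`, and `isolated` (indices of
#'   zero-degree nodes, flagged with a warning).
#' @export
build_kirchhoff <- function(nodes, cutoff = 7.3,
                            method = c("auto", "brute", "cell")) {
  xyz <- if (inherits(nodes, "gnm_nodes")) nodes$xyz else as.matrix(nodes)
  n <- nrow(xyz)
  stopifnot(n >= 2, cutoff > 0)
  pr <- neighbor_pairs(xyz, cutoff, method = match.arg(method))
  gamma <- matrix(0, n, n)
  if (nrow(pr)) {
    gamma[cbind(pr[, 1], pr[, 2])] <- -1
    gamma[cbind(pr[, 2], pr[, 1])] <- -1
  }
  diag(gamma) <- -rowSums(gamma)
  isolated <- which(diag(gamma) == 0)
  if (length(isolated))
    warning("isolated node(s) with no contacts at cutoff ", cutoff, " A: ",
            paste(head(isolated, 10), collapse = ", "))
  out <- list(gamma = gamma, cutoff = cutoff, n = n, isolated = isolated)
  class(out) <- "gnm_kirchhoff"
  out
}

#' @export
print.gnm_kirchhoff <- function(x, ...) {
  cat("gnm_kirchhoff:", x$n, "nodes,", sum(x$gamma == -1) / 2,
      "contacts, cutoff", x$cutoff, "A\n")
  invisible(x)
}

#' Connected components of the contact network
#'
#' The fluctuation formulas assume a single zero mode, i.e. a connected
#' network; disconnected pieces each contribute one zero eigenvalue. This
#' returns the partition of nodes into components, sorted by decreasing
#' size (ties: smallest member index first).
#'
#' @param k A `gnm_kirchhoff` object.
#' @return List of integer vectors of node indices.
#' @export
connected_components <- function(k) {
  stopifnot(inherits(k, "gnm_kirchhoff"))
  adj <- k$gamma != 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(k$n), memb)
  comps <- lapply(comps, as.integer)
  ord <- order(-lengths(comps), vapply(comps, min, integer(1)))
  unname(comps[ord])
}

#' Contact map of the network
#'
#' Binary N x N map with 1 wherever two distinct nodes are in contact;
#' the 2D analogue of the 3D spring network.
#'
#' @param k A `gnm_kirchhoff` object.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
contact_map <- function(k) {
  stopifnot(inherits(k, "gnm_kirchhoff"))
  (k$gamma == -1) * 1L
}

#' Export a contact map as plain text
#'
#' @param k A `gnm_kirchhoff` object.
#' @param path Output path.
#' @param format `"edges"` for a 3-column (i, j, 1) edge list over pairs
#'   i < j, or `"matrix"` for the dense 0/1 matrix.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(k, path, format = c("edges", "matrix")) {
  format <- match.arg(format)
  cm <- contact_map(k)
  if (format == "edges") {
    hit <- which(cm == 1 & upper.tri(cm), arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    write_tsv_det(data.frame(i = hit[, 1], j = hit[, 2],
                             contact = rep(1L, nrow(hit))), path)
  } else {
    df <- as.data.frame(cm)
    names(df) <- as.character(seq_len(ncol(cm)))
    write_tsv_det(df, path)
  }
  invisible(path)
}
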