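# Deterministic generator of synthetic toy structures as valid PDB files,
# so every pipeline stage is testable offline. Geometry constants are
# idealized textbook values (3.8 A C-alpha virtual bond; alpha-helix rise
# 1.5 A, 100 deg/residue, radius 2.3 A; B-form-like duplex spacing), not
# fits to any particular deposition.

#' Generate a synthetic toy structure as a PDB file
#'
#' Writes a small, valid PDB file of the requested kind with reproducible
#' (seeded) geometry, optionally with a synthetic B-factor column derived
#' from the structure's own fluctuation profile plus Gaussian noise.
#' Available kinds:
#' \describe{
#'   \item{`linear_chain`}{collinear C-alpha trace, 3.8 A spacing; its
#'     contact network at the default cutoff is the path graph.}
#'   \item{`ring`}{circular C-alpha trace with 3.8 A between neighbors.}
#'   \item{`helix`}{ideal alpha-helical C-alpha trace.}
#'   \item{`dumbbell`}{two compact lattice clusters joined by a 3-node
#'     collinear linker -- a planted two-domain/hinge geometry; the
#'     returned `info$segments` gives the cluster and linker node sets.}
#'   \item{`dimer_biomt`}{one helical chain plus a REMARK 350 block whose
#'     two operators (identity; rigid translation) generate a contacting
#'     dimer.}
#'   \item{`protein_dna`}{a short peptide packed against an idealized
#'     nucleic-acid duplex written with complete P/C4'/C2 node atoms.}
#'   \item{`ellipsoid_cloud`}{points on an ellipsoid surface of a stated
#'     axial ratio (shape-statistics fixture).}
#' }
#' Unless `ca_only = TRUE`, every amino-acid residue is written with a
#' carbonyl oxygen in addition to its C-alpha, so generated files do not
#' trip the C-alpha-only admission filter.
#'
#' @param kind Fixture kind (see above).
#' @param n Number of residues (for `protein_dna`: number of amino acids;
#'   for `ellipsoid_cloud`: number of points).
#' @param path Output PDB path.
#' @param spacing C-alpha virtual-bond length in Angstrom (default 3.8).
#' @param noise Coordinate jitter s.d. in Angstrom (default 0).
#' @param seed Integer seed controlling all fixture randomness.
#' @param b_model Optional synthetic B-factor model: a list with elements
#'   `c` (scale; `NULL` = choose so the mean B is 30 A^2), `noise_sd`
#'   (absolute Gaussian noise s.d. in B units) or `noise_rel` (noise s.d.
#'   as a multiple of the s.d. of the scaled profile), `seed` (noise seed,
#'   default `seed`), and `model` (`"asymmetric"` or `"assembly"`: which
#'   network the profile is computed on). B-factors are written as
#'   c * msf + noise, floored at 0.
#' @param cutoff Contact cutoff used when `b_model` runs the network
#'   internally (default 7.3 A).
#' @param ca_only Write bare C-alpha traces (for testing the admission
#'   filter).
#' @param n_nt Total nucleotides for `protein_dna` (split across the two
#'   strands).
#' @param axis_ratio Target axial ratio for `ellipsoid_cloud`.
#' @param dimer_op Second operator of `dimer_biomt`: a pure translation
#'   (default) or a proper 2-fold rotation (`"c2"`, giving an exactly
#'   symmetric dimer).
#' @return Invisibly, a list with `path`, `kind`, `n`, `seed`, and `info`
#'   (kind-specific metadata: planted segments, the msf and B values used
#'   by `b_model`, the applied scale).
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' gnm_fixture("linear_chain", n = 12, path = f)
#' @export
gnm_fixture <- function(kind = c("linear_chain", "ring", "helix", "dumbbell",
                                 "dimer_biomt", "protein_dna",
                                 "ellipsoid_cloud"),
                        n, path, spacing = 3.8, noise = 0, seed = 1,
                        b_model = NULL, cutoff = 7.3, ca_only = FALSE,
                        n_nt = 2L, axis_ratio = 10,
                        dimer_op = c("translate", "c2")) {
  dimer_op <- match.arg(dimer_op)
  kind <- match.arg(kind)
  info <- list()
  remarks <- character(0)

  geom <- with_seed(seed, {
    switch(kind,
      linear_chain = list(xyz = cbind((seq_len(n) - 1) * spacing, 0, 0)),
      ring = {
        r <- spacing / (2 * sin(pi / n))
        th <- 2 * pi * (seq_len(n) - 1) / n
        list(xyz = cbind(r * cos(th), r * sin(th), 0))
      },
      helix = list(xyz = helix_trace(n)),
      dumbbell = dumbbell_geometry(n, spacing),
      dimer_biomt = list(xyz = helix_trace(n)),
      protein_dna = protein_dna_geometry(n, n_nt, spacing),
      ellipsoid_cloud = {
        u <- matrix(rnorm(3 * n), ncol = 3)
        u <- u / sqrt(rowSums(u^2))
        semi <- 5 * c(axis_ratio, sqrt(axis_ratio), 1)
        list(xyz = sweep(u, 2, semi, "*"))
      })
  })
  xyz <- geom$xyz
  info$segments <- geom$segments
  if (noise > 0 && !is.null(xyz))
    xyz <- xyz + with_seed(seed + 1L,
                           matrix(rnorm(length(xyz), sd = noise), ncol = 3))

  if (kind == "protein_dna") {
    atoms <- protein_dna_atoms(xyz, geom, ca_only)
  } else {
    atoms <- ca_chain_atoms(xyz, chain = "A", ca_only = ca_only)
  }
  if (kind == "dimer_biomt") {
    shift <- 9
    rot2 <- if (identical(dimer_op, "c2")) diag(c(-1, -1, 1)) else diag(3)
    remarks <- c(
      "REMARK 350 BIOMOLECULE: 1",
      "REMARK 350 APPLY THE FOLLOWING TO CHAINS: A",
      biomt_lines(1, diag(3), c(0, 0, 0)),
      biomt_lines(2, rot2, c(0, shift, 0)))
    info$shift <- shift
  }

  s <- new_structure(atoms)

  if (!is.null(b_model)) {
    bm <- utils::modifyList(
      list(c = NULL, noise_sd = 0, noise_rel = NULL, seed = seed,
           model = "asymmetric"),
      b_model)
    target <- if (identical(bm$model, "assembly")) {
      s_ops <- s
      s_ops$assembly_ops <- parse_ops_from_remarks(remarks)
      build_assembly(s_ops, "first_assembly")
    } else s
    nodes_all <- select_nodes(target)
    modes <- gnm_modes(build_kirchhoff(nodes_all, cutoff = cutoff))
    msf <- gnm_profile(modes)$msf
    n_self <- gnm_n_nodes(select_nodes(s))
    msf <- msf[seq_len(n_self)]            # nodes of the deposited copy
    cc <- bm$c %||% (30 / mean(msf))
    if (!is.null(bm$noise_rel))
      bm$noise_sd <- bm$noise_rel * stats::sd(cc * msf)
    bvals <- cc * msf +
      with_seed(bm$seed, rnorm(n_self, sd = bm$noise_sd))
    bvals <- pmax(bvals, 0)
    info$msf <- msf; info$b <- bvals; info$scale_c <- cc
    s$atom$b <- node_b_to_atoms(s, bvals)
  }

  write_structure(s, path, remarks = remarks)
  invisible(list(path = path, kind = kind, n = n, seed = seed, info = info))
}

helix_trace <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  th <- (seq_len(n) - 1) * twist * pi / 180
  cbind((seq_len(n) - 1) * rise, radius * cos(th), radius * sin(th))
}

# Two dense helical domains joined by an extended 3-node linker, all one
# chain-contiguous trace (sequence neighbors are spatial neighbors, so the
# mode shapes are smooth along the sequence, as in real two-domain
# proteins). In the softest mode the domains move as anticorrelated
# near-rigid blocks: the shape is V-like with its minimum (the hinge) in
# the linker.
dumbbell_geometry <- function(n, spacing) {
  stopifnot(n >= 11)
  n_link <- 3L
  nc1 <- (n - n_link) %/% 2L
  nc2 <- n - n_link - nc1
  h1 <- helix_trace(nc1)
  x0 <- max(h1[, 1])
  link <- cbind(x0 + 3.0 + spacing * (seq_len(n_link) - 1), 0, 0)
  h2 <- helix_trace(nc2)
  h2[, 1] <- h2[, 1] + max(link[, 1]) + 3.0
  list(xyz = rbind(h1, link, h2),
       segments = list(cluster1 = seq_len(nc1),
                       linker = nc1 + seq_len(n_link),
                       cluster2 = nc1 + n_link + seq_len(nc2)))
}

# Peptide chain packed against an idealized duplex. Strand geometry uses a
# B-form-like rise (3.38 A) and twist (36 deg) with P, C4' and C2 placed at
# decreasing radii; only the node atoms are written for nucleotides.
protein_dna_geometry <- function(n_aa, n_nt, spacing) {
  nt1 <- as.integer(ceiling(n_nt / 2))
  nt2 <- n_nt - nt1
  rise <- 3.38; twist <- 36 * pi / 180
  strand <- function(m, phase, direction) {
    if (m == 0) return(NULL)
    lapply(seq_len(m), function(i) {
      th <- phase + direction * (i - 1) * twist
      z <- direction * (i - 1) * rise
      rbind(P   = c(9.4 * cos(th), 9.4 * sin(th), z),
            `C4'` = c(7.0 * cos(th + 0.35), 7.0 * sin(th + 0.35), z + 0.5),
            C2  = c(3.5 * cos(th + 0.8), 3.5 * sin(th + 0.8), z + 1.0))
    })
  }
  # peptide runs parallel to the duplex axis, close enough to groove
  # phosphates that complexes with >= 3 nt per strand are connected
  zmid <- (nt1 - 1) * rise / 2
  pep <- cbind(0, 12.4,
               zmid + (seq_len(n_aa) - (n_aa + 1) / 2) * spacing)
  list(xyz = NULL, peptide = pep,
       strand_b = strand(nt1, 0, +1),
       strand_c = strand(nt2, pi, +1))
}

ca_chain_atoms_raw <- function(xyz, chain = "A", ca_only = FALSE) {
  n <- nrow(xyz)
  ca <- data.frame(type = "ATOM", elety = "CA", resid = "ALA",
                   chain = chain, resno = seq_len(n), x = xyz[, 1],
                   y = xyz[, 2], z = xyz[, 3], elesy = "C",
                   stringsAsFactors = FALSE)
  if (ca_only) return(ca)
  ox <- ca
  ox$elety <- "O"; ox$elesy <- "O"
  ox$x <- ox$x + 0.6; ox$y <- ox$y + 0.8; ox$z <- ox$z + 0.4
  out <- rbind(ca, ox)
  out[order(out$resno, match(out$elety, c("CA", "O"))), ]
}

ca_chain_atoms <- function(xyz, chain = "A", ca_only = FALSE) {
  finish_atoms(ca_chain_atoms_raw(xyz, chain, ca_only))
}

protein_dna_atoms <- function(xyz_unused, geom, ca_only) {
  pep <- ca_chain_atoms_raw(geom$peptide, chain = "A", ca_only = ca_only)
  nt_atoms <- function(res_list, chain, resid) {
    if (is.null(res_list)) return(NULL)
    do.call(rbind, lapply(seq_along(res_list), function(i) {
      m <- res_list[[i]]
      data.frame(type = "ATOM", elety = rownames(m), resid = resid,
                 chain = chain, resno = i, x = m[, 1], y = m[, 2],
                 z = m[, 3], elesy = c("P", "C", "C"),
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(pep,
               nt_atoms(geom$strand_b, "B", "DA"),
               nt_atoms(geom$strand_c, "C", "DT"))
  finish_atoms(out)
}

finish_atoms <- function(df) {
  # coordinates are fixed to the PDB column precision here, so any profile
  # computed from the in-memory structure (e.g. a synthetic B-factor
  # model) is exactly reproducible from the written file
  df$x <- round(df$x, 3); df$y <- round(df$y, 3); df$z <- round(df$z, 3)
  df$eleno <- seq_len(nrow(df))
  df$alt <- ""; df$insert <- ""; df$o <- 1; df$b <- 0; df$segid <- ""
  rownames(df) <- NULL
  df[, c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
         "insert", "x", "y", "z", "o", "b", "segid", "elesy")]
}

new_structure <- function(atoms) {
  out <- list(atom = atoms, assembly_ops = list(),
              metadata = list(title = "", method = "", resolution = NA_real_,
                              has_b = any(atoms$b > 0)),
              nmodels = 1L, model = 1L, source = "<generated>")
  class(out) <- "gnm_structure"
  out
}

biomt_lines <- function(idx, rotation, translation) {
  vapply(1:3, function(r)
    sprintf("REMARK 350   BIOMT%d %3d%10.6f%10.6f%10.6f%15.5f",
            r, idx, rotation[r, 1], rotation[r, 2], rotation[r, 3],
            translation[r]),
    character(1))
}

# Turn the generator's own REMARK 350 lines back into operator lists
# (identity + translation dimers only need the simple form).
parse_ops_from_remarks <- function(remarks) {
  rows <- grep("BIOMT", remarks, value = TRUE)
  if (!length(rows)) return(list())
  num <- lapply(strsplit(trimws(sub(".*BIOMT[0-9]", "", rows)), "\\s+"),
                as.numeric)
  op_idx <- vapply(num, `[`, numeric(1), 1)
  ops <- lapply(unique(op_idx), function(k) {
    m <- do.call(rbind, lapply(num[op_idx == k], function(v) v[-1]))
    list(rotation = m[, 1:3], translation = m[, 4],
         chains = "A", index = as.integer(k))
  })
  list(ops)
}

# Spread per-node synthetic B values onto the atom table: node atoms carry
# their node's value, other atoms of the residue the residue mean.
node_b_to_atoms <- function(s, bvals) {
  nodes <- select_nodes(s)
  key <- function(chain, resno, insert, elety)
    paste(chain, resno, insert, elety, sep = "|")
  node_key <- key(nodes$label$chain, nodes$label$resno, nodes$label$insert,
                  nodes$label$elety)
  atom_key <- key(s$atom$chain, s$atom$resno, s$atom$insert, s$atom$elety)
  b <- unname(setNames(bvals, node_key)[atom_key])
  res_key <- paste(nodes$label$chain, nodes$label$resno, nodes$label$insert)
  res_mean <- tapply(bvals, res_key, mean)
  atom_res <- paste(s$atom$chain, s$atom$resno, s$atom$insert)
  b[is.na(b)] <- unname(res_mean[atom_res[is.na(b)]])
  b[is.na(b)] <- 0
  b
}
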