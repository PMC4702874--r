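# Structure I/O: PDB parsing, biological-assembly construction, admission
# filtering, and color-coded PDB output. File-format heavy lifting is
# delegated to bio3d; the contracts layered on top (model policy, alt-loc
# resolution, operator application, chain re-identification) live here.

#' Read a PDB file into a molecular structure
#'
#' Parses a PDB-format coordinate file (ATOM/HETATM records, MODEL/ENDMDL
#' blocks, REMARK 350 BIOMT assembly operators) into a `gnm_structure`.
#' Exactly one model is retained: by default the first, matching the usual
#' treatment of NMR ensembles where only the first deposited model enters
#' the network calculation. Alternate locations are resolved by keeping, for
#' each atom, the altloc with the highest occupancy (ties broken by the
#' lexicographically smallest altloc label).
#'
#' @param path Path to a PDB file.
#' @param model Model number to retain (1 = first). Ignored for files
#'   without MODEL cards.
#' @return An object of class `gnm_structure`: a list with elements
#'   `atom` (data frame of atom records with columns `type`, `eleno`,
#'   `elety`, `alt`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#'   `o`, `b`, `elesy`), `assembly_ops` (list of assemblies, each a list of
#'   operators with `rotation` 3x3, `translation` length-3, `chains`,
#'   `index`), `metadata` (title, experimental method, resolution, whether
#'   usable B-factors are present) and `nmodels`.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' gnm_fixture("linear_chain", n = 12, path = f)
#' s <- read_structure(f)
#' nrow(s$atom)
#' @export
read_structure <- function(path, model = 1) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0L)
    stop("empty structure: no ATOM/HETATM records in '", path, "'")

  nmodels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model < 1 || model > nmodels)
    stop("requested model ", model, " but file has ", nmodels, " model(s)")
  if (model > 1) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atom$x <- xyz[, 1]; atom$y <- xyz[, 2]; atom$z <- xyz[, 3]
  }

  for (col in c("alt", "insert", "segid", "chain"))
    atom[[col]][is.na(atom[[col]])] <- ""
  atom$o[is.na(atom$o)] <- 1

  atom <- resolve_altloc(atom)
  rownames(atom) <- NULL

  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  if (anyDuplicated(key))
    warning("duplicate atom identifiers after alt-loc resolution in '",
            path, "'")

  structure(
    list(atom = atom,
         assembly_ops = parse_assembly_ops(pdb),
         metadata = read_pdb_metadata(path, atom),
         nmodels = nmodels,
         model = model,
         source = path),
    class = "gnm_structure")
}

# Keep, per (chain, resno, insert, atom name), the altloc of highest
# occupancy; ties go to the lexicographically smallest altloc label.
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
  if (!anyDuplicated(key)) return(atom)
  ord <- order(key, -atom$o, atom$alt)
  atom <- atom[ord, ]
  atom <- atom[!duplicated(key[ord]), ]
  atom[order(as.integer(rownames(atom))), ]
}

parse_assembly_ops <- function(pdb) {
  bm <- pdb$remark$biomat
  if (is.null(bm) || is.null(bm$mat) || bm$num < 1) return(list())
  lapply(seq_len(bm$num), function(i) {
    mats <- bm$mat[[i]]
    default_chains <- bm$chain[[i]]
    lapply(seq_along(mats), function(j) {
      m <- mats[[j]]
      nm <- names(mats)[j]
      chains <- if (!is.null(nm) && nzchar(nm))
        strsplit(trimws(nm), "[[:space:],]+")[[1]] else default_chains
      list(rotation = m[, 1:3, drop = FALSE],
           translation = as.numeric(m[, 4]),
           chains = chains,
           index = j)
    })
  })
}

read_pdb_metadata <- function(path, atom) {
  lines <- readLines(path, n = 400L, warn = FALSE)
  title <- sub("^TITLE\\s+[0-9]*\\s*", "", grep("^TITLE", lines, value = TRUE))
  method <- trimws(sub("^EXPDTA\\s*", "", grep("^EXPDTA", lines, value = TRUE)))
  resol <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    num <- regmatches(rl[1], regexpr("[0-9]+\\.?[0-9]*", sub(".*RESOLUTION\\.?", "", rl[1])))
    if (length(num)) resol <- as.numeric(num)
  }
  has_b <- any(!is.na(atom$b) & atom$b > 0)
  list(title = if (length(title)) paste(trimws(title), collapse = " ") else "",
       method = if (length(method)) method[1] else "",
       resolution = resol,
       has_b = has_b)
}

#' Build a biological assembly from REMARK 350 operators
#'
#' Applies the rotation/translation operators of one assembly block to their
#' target chains. Copies are emitted operator-major (all chains of operator
#' 1, then operator 2, ...), and every copy receives a fresh, unique chain
#' identifier drawn from the sequence A-Z, a-z, 0-9, then two-character
#' combinations; a copy generated by an identity operator keeps its original
#' chain id when still free. Crystallographic depositions frequently store
#' only the asymmetric unit; the functional (biological) oligomer obtained
#' here is what inter-subunit contacts -- and hence realistic fluctuation
#' profiles -- come from.
#'
#' @param x A `gnm_structure`.
#' @param assembly `"asymmetric"` (return `x` unchanged) or
#'   `"first_assembly"` (apply the first REMARK 350 block), or an integer
#'   selecting another assembly block.
#' @return A `gnm_structure` holding the assembled coordinates.
#' @export
build_assembly <- function(x, assembly = c("first_assembly", "asymmetric")) {
  stopifnot(inherits(x, "gnm_structure"))
  if (is.character(assembly)) {
    assembly <- match.arg(assembly)
    if (assembly == "asymmetric") return(x)
    idx <- 1L
  } else {
    idx <- as.integer(assembly)
  }
  if (length(x$assembly_ops) < idx || !length(x$assembly_ops[[idx]]))
    stop("assembly error: no REMARK 350 operators for assembly ", idx)
  ops <- x$assembly_ops[[idx]]

  chain_order <- unique(x$atom$chain)
  pool <- chain_id_sequence(62L + length(ops) * length(chain_order))
  used <- character(0)
  pieces <- list()
  prev_coords <- list()   # per source chain: list of emitted coordinate matrices

  for (op in ops) {
    miss <- setdiff(op$chains, chain_order)
    if (length(miss))
      stop("assembly error: operator ", op$index,
           " references absent chain(s): ", paste(miss, collapse = ", "))
    for (ch in chain_order[chain_order %in% op$chains]) {
      rows <- x$atom[x$atom$chain == ch, , drop = FALSE]
      xyz <- as.matrix(rows[, c("x", "y", "z")]) %*% t(op$rotation)
      xyz <- sweep(xyz, 2, op$translation, "+")
      for (old in prev_coords[[ch]] %||% list()) {
        if (nrow(old) == nrow(xyz) && max(abs(old - xyz)) < 1e-6) {
          warning("duplicate positions: operator ", op$index,
                  " reproduces an earlier copy of chain ", ch,
                  "; both copies kept")
          break
        }
      }
      prev_coords[[ch]] <- c(prev_coords[[ch]] %||% list(), list(xyz))
      cand <- if (is_identity_op(op) && !(ch %in% used)) ch else
        pool[!(pool %in% used)][1]
      used <- c(used, cand)
      rows$x <- xyz[, 1]; rows$y <- xyz[, 2]; rows$z <- xyz[, 3]
      rows$chain <- cand
      pieces[[length(pieces) + 1L]] <- rows
    }
  }
  out <- x
  out$atom <- do.call(rbind, pieces)
  rownames(out$atom) <- NULL
  out$atom$eleno <- seq_len(nrow(out$atom))
  out$assembly_ops <- list()
  out$assembly_built <- idx
  out
}

#' Admission filter for network calculations
#'
#' Applies the database-style admission rules: structures with fewer than
#' `min_nodes` (default 12) or more than `max_nodes` (default 20000) network
#' nodes are rejected, as are depositions whose every residue consists of a
#' single C-alpha atom (no side chains or backbone deposited). The node cap
#' is a soft limit and can be raised; the C-alpha-only filter can be turned
#' off, since the network itself needs only C-alpha positions for proteins.
#'
#' @param nodes A `gnm_nodes` object from [select_nodes()].
#' @param structure Optional `gnm_structure` the nodes came from; required
#'   for the C-alpha-only check.
#' @param min_nodes,max_nodes Node-count admission window.
#' @param calpha_only_filter Reject C-alpha-only depositions?
#' @return A list of class `gnm_admission` with `accepted` (logical),
#'   `reason` (`NA` when accepted) and `n_nodes`.
#' @export
admit_structure <- function(nodes, structure = NULL, min_nodes = 12,
                            max_nodes = 20000, calpha_only_filter = TRUE) {
  n <- gnm_n_nodes(nodes)
  verdict <- function(ok, reason = NA_character_) {
    out <- list(accepted = ok, reason = reason, n_nodes = n)
    class(out) <- "gnm_admission"
    out
  }
  if (n < min_nodes) return(verdict(FALSE, "too few nodes"))
  if (n > max_nodes) return(verdict(FALSE, "too many nodes"))
  if (calpha_only_filter && !is.null(structure)) {
    elety <- structure$atom$elety[structure$atom$type == "ATOM"]
    if (length(elety) && all(elety == "CA"))
      return(verdict(FALSE, "calpha-only"))
  }
  verdict(TRUE)
}

#' @export
print.gnm_admission <- function(x, ...) {
  if (x$accepted) cat("accepted (", x$n_nodes, " nodes)\n", sep = "")
  else cat("rejected: ", x$reason, " (", x$n_nodes, " nodes)\n", sep = "")
  invisible(x)
}

#' @export
print.gnm_structure <- function(x, ...) {
  cat("gnm_structure:", nrow(x$atom), "atoms,",
      length(unique(x$atom$chain)), "chain(s),",
      x$nmodels, "model(s),",
      length(x$assembly_ops), "assembly block(s)\n")
  invisible(x)
}

# Plain PDB writer for internal use (fixtures, colored output). `remarks`
# lines are emitted before the coordinate records.
write_structure <- function(x, path, b = NULL, remarks = character()) {
  a <- x$atom
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = a$type, resno = a$resno,
                   resid = a$resid, eleno = a$eleno, elety = a$elety,
                   chain = substr(a$chain, 1, 1), insert = a$insert,
                   alt = a$alt, o = a$o, b = if (is.null(b)) a$b else b,
                   elesy = a$elesy)
  if (length(remarks)) {
    body <- readLines(path, warn = FALSE)
    con <- file(path, open = "wb")
    writeLines(c(remarks, body), con, sep = "\n")
    close(con)
  }
  invisible(path)
}

#' Write a PDB file color-coded through the B-factor column
#'
#' Emits the structure with each atom's B-factor column replaced by a
#' per-node quantity (a fluctuation profile, a mode shape, a sign map...)
#' rescaled linearly to the printable range [0, 99.99]; molecular viewers
#' then color by "temperature". Non-node atoms of a residue inherit the
#' residue's node value (the mean over the residue's nodes for 3-node
#' nucleotides). A constant input vector maps to all-zero columns.
#'
#' @param structure A `gnm_structure`.
#' @param nodes The `gnm_nodes` selected from `structure`.
#' @param values Numeric vector, one finite value per node.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_colored_pdb <- function(structure, nodes, values, path) {
  n <- gnm_n_nodes(nodes)
  if (length(values) != n)
    stop("contract error: length(values) = ", length(values),
         " but node count = ", n)
  if (!all(is.finite(values))) stop("contract error: values must be finite")
  rng <- range(values)
  scaled <- if (diff(rng) == 0) rep(0, n) else
    (values - rng[1]) / diff(rng) * 99.99

  res_key <- function(chain, resno, insert) paste(chain, resno, insert, sep = "|")
  node_res <- res_key(nodes$label$chain, nodes$label$resno, nodes$label$insert)
  per_res <- tapply(scaled, node_res, mean)
  atom_res <- res_key(structure$atom$chain, structure$atom$resno,
                      structure$atom$insert)
  b <- unname(per_res[atom_res])
  b[is.na(b)] <- 0
  write_structure(structure, path, b = b)
}
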