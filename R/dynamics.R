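# Interpreted outputs: B-factor agreement, sign-based domain separation and
# hinge (crossover) detection, slow-mode minima, fast-mode peaks, shape
# statistics, and the plain-text result bundle.

#' Pearson correlation between predicted and experimental B-factors
#'
#' Agreement between the model's fluctuation profile and crystallographic
#' temperature factors, the standard figure of merit for elastic-network
#' predictions. Nodes lacking an experimental value are excluded pairwise.
#' The coefficient is invariant under affine rescaling, so it can be
#' computed directly on the mean-square fluctuation profile.
#'
#' @param predicted,experimental Numeric vectors of equal length.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
bfactor_correlation <- function(predicted, experimental) {
  stopifnot(length(predicted) == length(experimental))
  ok <- !is.na(predicted) & !is.na(experimental)
  p <- predicted[ok]; e <- experimental[ok]
  if (length(p) < 3)
    stop("need at least 3 paired values with experimental B-factors")
  if (stats::sd(p) == 0 || stats::sd(e) == 0)
    stop("undefined correlation: zero-variance input")
  stats::cor(p, e)
}

#' Sign-based domain separation along a mode
#'
#' Each node moves in the positive or negative direction along a mode axis;
#' the sign of u_{k,i} splits the structure into two anticorrelated
#' subsets. In the global (soft) modes these subsets are spatially coherent
#' domains, and the nodes where the sign changes along a chain -- the
#' crossover nodes -- mark the interface, which typically contains the
#' global hinge. Components with |u| below `sign_tol` times the largest
#' component are treated as sign 0 and are themselves crossover members.
#' Crossovers are only detected between sequence-adjacent nodes of the same
#' chain.
#'
#' @param modes A `gnm_modes` object.
#' @param k Nonzero-mode index (1 = softest).
#' @param nodes The `gnm_nodes` the modes were computed from (chain map).
#' @param sign_tol Relative threshold for a "zero" eigenvector component.
#' @return A `gnm_domains` object: list with `mode`, `sign` (integer
#'   -1/0/+1 per node) and `crossover` (ordered node indices).
#' @export
domain_separation <- function(modes, k, nodes, sign_tol = 1e-6) {
  stopifnot(inherits(modes, "gnm_modes"), inherits(nodes, "gnm_nodes"))
  u <- nonzero_modes(modes, k)$vectors[, 1]
  tol <- sign_tol * max(abs(u))
  s <- as.integer(sign(u))
  s[abs(u) < tol] <- 0L
  chain <- nodes$label$chain
  cross <- which(s == 0L)
  n <- length(s)
  if (n > 1) {
    i <- seq_len(n - 1)
    flip <- chain[i] == chain[i + 1] & s[i] * s[i + 1] == -1L
    cross <- c(cross, i[flip], i[flip] + 1L)
  }
  out <- list(mode = k, sign = s, crossover = sort(unique(cross)))
  class(out) <- "gnm_domains"
  out
}

#' @export
print.gnm_domains <- function(x, ...) {
  cat("gnm_domains: mode", x$mode, "-", sum(x$sign > 0), "+ nodes,",
      sum(x$sign < 0), "- nodes,", length(x$crossover),
      "crossover node(s)\n")
  invisible(x)
}

#' Local minima of a slow-mode shape (hinge candidates)
#'
#' Minima in the square-displacement profile of the soft modes mark nodes
#' that stay nearly fixed while the rest of the structure moves -- hinge
#' sites and, frequently, catalytic sites. This sums the shapes of the
#' selected modes and reports strict local minima within a centered
#' window confined to each chain; chain termini (nodes without neighbors
#' on both sides) are not eligible, and plateaus yield no minimum.
#'
#' @param profile A `gnm_profile` object.
#' @param nodes The matching `gnm_nodes` (chain boundaries).
#' @param mode_subset Nonzero-mode indices to sum (default: softest mode).
#' @param window Odd window width (default 5).
#' @return Node indices of minima, sorted by ascending shape value.
#' @export
slow_mode_minima <- function(profile, nodes, mode_subset = 1L, window = 5L) {
  stopifnot(inherits(profile, "gnm_profile"), length(mode_subset) >= 1)
  p <- colSums(profile$shapes[mode_subset, , drop = FALSE])
  half <- window %/% 2L
  chain <- nodes$label$chain
  n <- length(p)
  hits <- integer(0)
  for (i in seq_len(n)) {
    nb <- (i - half):(i + half)
    nb <- nb[nb >= 1 & nb <= n & nb != i]
    nb <- nb[chain[nb] == chain[i]]
    if (!any(nb < i) || !any(nb > i)) next   # chain terminus
    if (all(p[i] < p[nb])) hits <- c(hits, i)
  }
  hits[order(p[hits])]
}

#' Peaks of the fast-mode shape (energy localization spots)
#'
#' The stiffest modes concentrate on a few tightly packed nodes; peaks in
#' their summed shape mark centers of energy localization. Sums the
#' `n_fast` highest-frequency modes and returns the nodes at or above the
#' `top_q` quantile of the summed shape, sorted by descending value.
#'
#' @param profile A `gnm_profile` object.
#' @param n_fast Number of highest-frequency modes to sum (default 10).
#' @param top_q Quantile threshold in [0, 1) (default 0.95; 0 returns all
#'   nodes).
#' @return Node indices, descending by summed shape value.
#' @export
fast_mode_peaks <- function(profile, n_fast = 10L, top_q = 0.95) {
  stopifnot(inherits(profile, "gnm_profile"), n_fast >= 1)
  nm <- nrow(profile$shapes)
  n_fast <- min(n_fast, nm)
  s <- colSums(profile$shapes[seq(nm - n_fast + 1, nm), , drop = FALSE])
  thr <- stats::quantile(s, top_q, names = FALSE)
  idx <- which(s >= thr)
  idx[order(-s[idx])]
}

#' Principal-axis shape statistics
#'
#' Principal axis lengths of the node cloud (square roots of the
#' coordinate-covariance eigenvalues, in Angstrom, descending) and the
#' axial ratio a = largest / smallest, a standard measure of structural
#' asymmetry: a = 1 for globular shapes, large a for elongated ones. A
#' near-degenerate smallest axis (collinear/planar clouds) is flagged and
#' reported as an infinite ratio.
#'
#' @param nodes A `gnm_nodes` object or an N x 3 coordinate matrix.
#' @return A `gnm_shape` object: list with `axis_lengths` (3, descending),
#'   `axial_ratio` and `degenerate` (logical).
#' @export
axial_ratio <- function(nodes) {
  xyz <- if (inherits(nodes, "gnm_nodes")) nodes$xyz else as.matrix(nodes)
  stopifnot(nrow(xyz) >= 3)
  ev <- sort(eigen(stats::cov(xyz), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  degenerate <- ev[3] < 1e-10 * ev[1]
  lengths <- sqrt(pmax(ev, 0))
  out <- list(axis_lengths = lengths,
              axial_ratio = if (degenerate) Inf else lengths[1] / lengths[3],
              degenerate = degenerate)
  class(out) <- "gnm_shape"
  out
}

#' @export
print.gnm_shape <- function(x, ...) {
  cat("gnm_shape: principal axes (A):",
      paste(signif(x$axis_lengths, 4), collapse = ", "),
      " axial ratio:", signif(x$axial_ratio, 4),
      if (x$degenerate) "(degenerate)" else "", "\n")
  invisible(x)
}

#' Write the plain-text result bundle for one structure
#'
#' Persists the analysis of one structure into a directory of TSV/PDB/JSON
#' files: all nonzero eigenvalues; eigenvectors and shapes of the stored
#' soft modes (the softest `ceiling(store_fraction * n_nonzero)` modes,
#' default 40% of the spectrum) and of the `n_fast` stiffest modes; the
#' fluctuation profile; the experimental-vs-predicted B-factor table with
#' its Pearson r; the cross-correlation map over `soft_subset`; per-mode
#' collectivities for the soft modes carrying 1/10 of the dynamics; a
#' sign/domain map per stored soft mode; and a B-factor-colored PDB per
#' mode in `soft_subset`. Output is written to a staging directory and
#' renamed into place, so a failed run never leaves a partial bundle.
#' Numeric output uses fixed formatting: identical inputs give
#' byte-identical bundles.
#'
#' @param dir Output directory (created; must not already exist).
#' @param structure,nodes,kirchhoff,modes,profile The pipeline objects.
#' @param store_fraction Fraction of the nonzero spectrum to store.
#' @param n_fast Number of stiff modes to store.
#' @param soft_subset Mode subset for the cross-correlation map and the
#'   colored PDB output (default: slowest three).
#' @param collectivity_fraction Dynamics share defining how many soft modes
#'   get a collectivity entry.
#' @param scale_policy B-factor scaling, `"fit"` or `"unit"`.
#' @return The summary list (also serialized as `summary.json`), invisibly.
#' @export
write_report <- function(dir, structure, nodes, kirchhoff, modes, profile,
                         store_fraction = 0.4, n_fast = 10L,
                         soft_subset = 1:3, collectivity_fraction = 0.1,
                         scale_policy = c("fit", "unit")) {
  scale_policy <- match.arg(scale_policy)
  if (dir.exists(dir)) stop("I/O error: output directory exists: ", dir)
  stage <- paste0(dir, ".partial")
  unlink(stage, recursive = TRUE)
  dir.create(stage, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(stage, recursive = TRUE))

  nm <- n_nonzero(modes)
  n_soft <- min(as.integer(ceiling(store_fraction * nm)), nm)
  n_fast <- min(as.integer(n_fast), nm)
  soft_subset <- soft_subset[soft_subset <= nm]
  if (!length(soft_subset)) soft_subset <- 1L
  lab <- nodes$label
  node_id <- seq_len(gnm_n_nodes(nodes))

  nzv <- nonzero_modes(modes)
  write_tsv_det(data.frame(mode = seq_len(nm), lambda = nzv$values),
                file.path(stage, "eigenvalues.tsv"))

  mode_table <- function(ks) {
    data.frame(mode = rep(ks, each = modes$n),
               node = rep(node_id, length(ks)),
               u = as.vector(nzv$vectors[, ks, drop = FALSE]),
               shape = as.vector(t(profile$shapes[ks, , drop = FALSE])))
  }
  write_tsv_det(mode_table(seq_len(n_soft)),
                file.path(stage, "modes_soft.tsv"))
  write_tsv_det(mode_table(seq(nm - n_fast + 1, nm)),
                file.path(stage, "modes_fast.tsv"))

  write_tsv_det(data.frame(node = node_id, chain = lab$chain,
                           resno = lab$resno, insert = lab$insert,
                           name = lab$elety, class = nodes$node_class,
                           msf = profile$msf),
                file.path(stage, "msf.tsv"))

  r_b <- NA_real_
  has_b <- any(!is.na(nodes$b)) && sum(!is.na(nodes$b)) >= 3 &&
    stats::sd(nodes$b[!is.na(nodes$b)]) > 0
  if (has_b) {
    pred <- theoretical_b_factors(profile, nodes$b, scale_policy)
    r_b <- bfactor_correlation(profile$msf, nodes$b)
    write_tsv_det(
      data.frame(node = node_id, chain = lab$chain, resno = lab$resno,
                 name = lab$elety, experimental = nodes$b,
                 predicted = pred$b),
      file.path(stage, "bfactor_compare.tsv"),
      header_lines = paste0("# pearson_r = ", fmt_num(r_b),
                            "  scale_c = ", fmt_num(pred$scale_c)))
  }

  cc <- cross_correlation(modes, soft_subset)
  cc_df <- as.data.frame(cc$values)
  names(cc_df) <- as.character(node_id)
  write_tsv_det(cc_df, file.path(stage, "crosscorr.tsv"),
                header_lines = paste0("# modes = ",
                                      paste(soft_subset, collapse = ",")))

  n_coll <- soft_mode_count(modes, collectivity_fraction)
  write_tsv_det(data.frame(mode = seq_len(n_coll),
                           kappa = collectivity(modes, seq_len(n_coll))),
                file.path(stage, "collectivity.tsv"))

  for (k in seq_len(n_soft)) {
    dom <- domain_separation(modes, k, nodes)
    write_tsv_det(
      data.frame(node = node_id, chain = lab$chain, resno = lab$resno,
                 sign = c("-", "0", "+")[dom$sign + 2L],
                 crossover = as.integer(node_id %in% dom$crossover)),
      file.path(stage, sprintf("domains_mode%d.tsv", k)))
  }
  for (k in soft_subset)
    write_colored_pdb(structure, nodes, profile$shapes[k, ],
                      file.path(stage, sprintf("colored_mode%d.pdb", k)))

  shape <- axial_ratio(nodes)
  summary <- list(
    n_nodes = modes$n,
    n_chains = length(unique(lab$chain)),
    n_components = modes$n_zero,
    cutoff = kirchhoff$cutoff,
    axial_ratio = if (is.finite(shape$axial_ratio)) shape$axial_ratio else "degenerate",
    r_bfactor = if (has_b) r_b else NULL,
    n_soft_stored = n_soft,
    n_fast_stored = n_fast,
    n_collectivity = n_coll,
    soft_subset = as.integer(soft_subset))
  jsonlite::write_json(summary, file.path(stage, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!file.rename(stage, dir))
    stop("I/O error: cannot move result bundle into place at ", dir)
  ok <- TRUE
  invisible(summary)
}
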