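# Spectral engine: eigendecomposition of the Kirchhoff matrix and the GNM
# observables derived from it. All quantities are computed in units where
# 3 k_B T / gamma = 1; absolute Angstrom^2 scales appear only in
# theoretical_b_factors().

#' Eigendecompose the Kirchhoff matrix
#'
#' Full symmetric eigendecomposition of the Kirchhoff matrix, sorted by
#' ascending eigenvalue. Eigenvalues below `zero_tol` times the largest are
#' classified as zero modes; for a valid Laplacian their count must equal
#' the number of connected components of the contact graph, and a mismatch
#' is raised as an internal-consistency error (it signals numerical
#' failure, not a property of the structure). Each eigenvector's sign is
#' fixed so that its largest-magnitude element is positive (ties: lowest
#' index), making downstream sign maps and text output reproducible across
#' solvers.
#'
#' @param k A `gnm_kirchhoff` object.
#' @param zero_tol Relative tolerance classifying zero eigenvalues.
#' @return A `gnm_modes` object: list with `values` (ascending
#'   eigenvalues), `vectors` (orthonormal columns, same order), `n_zero`
#'   (number of zero modes = components) and `n`.
#' @export
gnm_modes <- function(k, zero_tol = 1e-8) {
  stopifnot(inherits(k, "gnm_kirchhoff"))
  e <- eigen(k$gamma, symmetric = TRUE)
  ord <- seq(k$n, 1)                       # eigen() returns descending
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]

  # reproducible sign convention: the largest-magnitude element is made
  # positive; near-ties (within 1e-9) resolve to the lowest index
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    lead <- which(abs(v) >= max(abs(v)) - 1e-9)[1]
    if (v[lead] < 0) vectors[, j] <- -v
  }

  lam_max <- max(values)
  n_zero <- if (lam_max <= 0) k$n else sum(values <= zero_tol * lam_max)
  n_comp <- length(connected_components(k))
  if (n_zero != n_comp)
    stop("internal consistency error: ", n_zero, " zero mode(s) but ",
         n_comp, " connected component(s); eigendecomposition unreliable")
  out <- list(values = values, vectors = vectors, n_zero = n_zero, n = k$n)
  class(out) <- "gnm_modes"
  out
}

#' @export
print.gnm_modes <- function(x, ...) {
  nz <- x$n - x$n_zero
  cat("gnm_modes:", x$n, "nodes,", nz, "nonzero modes,", x$n_zero,
      "zero mode(s)\n")
  if (nz > 0)
    cat("  lambda_1 =", signif(x$values[x$n_zero + 1], 6),
        " lambda_max =", signif(x$values[x$n], 6), "\n")
  invisible(x)
}

n_nonzero <- function(modes) modes$n - modes$n_zero

# Eigenpairs of the nonzero modes; k (optional) selects nonzero-mode
# indices, 1 = softest.
nonzero_modes <- function(modes, k = NULL) {
  idx <- seq(modes$n_zero + 1, modes$n)
  if (!is.null(k)) {
    if (any(k < 1 | k > length(idx)))
      stop("mode index out of range: nonzero modes are 1..", length(idx))
    idx <- idx[k]
  }
  list(values = modes$values[idx],
       vectors = modes$vectors[, idx, drop = FALSE])
}

#' Pseudo-inverse of the Kirchhoff matrix
#'
#' The Kirchhoff matrix is singular (its rows sum to zero), so fluctuation
#' statistics use the Moore-Penrose pseudo-inverse, assembled from the
#' nonzero eigenpairs as the sum of lambda_k^-1 u_k u_k^T. Its diagonal
#' gives mean-square fluctuations and its off-diagonal the fluctuation
#' covariances, in units of 3 k_B T / gamma.
#'
#' @param modes A `gnm_modes` object.
#' @param allow_disconnected Proceed even when the network has more than
#'   one component (the extra zero modes are simply excluded).
#' @return N x N symmetric matrix.
#' @export
gnm_pinv <- function(modes, allow_disconnected = FALSE) {
  stopifnot(inherits(modes, "gnm_modes"))
  if (modes$n_zero > 1 && !allow_disconnected)
    stop("disconnected network: ", modes$n_zero, " components; the ",
         "fluctuation formulas assume a connected network ",
         "(set allow_disconnected = TRUE to override)")
  nz <- nonzero_modes(modes)
  v <- sweep(nz$vectors, 2, sqrt(nz$values), "/")
  tcrossprod(v)
}

#' Contribution of a single mode
#'
#' The rank-1 matrix lambda_k^-1 u_k u_k^T: mode k's additive share of the
#' pseudo-inverse, hence of mean-square fluctuations and cross-correlation.
#' The softest mode (k = 1) always contributes the most.
#'
#' @param modes A `gnm_modes` object.
#' @param k Nonzero-mode index (1 = softest).
#' @return N x N rank-1 matrix with trace 1/lambda_k.
#' @export
mode_contribution <- function(modes, k) {
  stopifnot(inherits(modes, "gnm_modes"), length(k) == 1)
  nz <- nonzero_modes(modes, k)
  tcrossprod(nz$vectors) / nz$values
}

#' Mean-square fluctuation profile and per-mode shapes
#'
#' Per-node mean-square fluctuations (the diagonal of the pseudo-inverse)
#' together with the per-mode square displacements lambda_k^-1 u_{k,i}^2
#' ("mode shapes"); the shapes sum over nonzero modes to the fluctuation
#' profile.
#'
#' @param modes A `gnm_modes` object.
#' @param allow_disconnected Passed through to the zero-mode check.
#' @return A `gnm_profile` object: list with `msf` (length N), `shapes`
#'   (nonzero-modes x N matrix, row k = shape of nonzero mode k) and `n`.
#' @export
gnm_profile <- function(modes, allow_disconnected = FALSE) {
  stopifnot(inherits(modes, "gnm_modes"))
  if (modes$n_zero > 1 && !allow_disconnected)
    stop("disconnected network: ", modes$n_zero, " components ",
         "(set allow_disconnected = TRUE to override)")
  nz <- nonzero_modes(modes)
  shapes <- t(nz$vectors^2) / nz$values   # rows = modes, cols = nodes
  out <- list(msf = colSums(shapes), shapes = shapes, n = modes$n)
  class(out) <- "gnm_profile"
  out
}

#' @export
print.gnm_profile <- function(x, ...) {
  cat("gnm_profile:", x$n, "nodes, msf range [",
      signif(min(x$msf), 4), ",", signif(max(x$msf), 4),
      "] (units of 3kT/gamma)\n")
  invisible(x)
}

#' Orientational cross-correlation map
#'
#' Normalized fluctuation covariances C_ij = G_ij / sqrt(G_ii G_jj), where
#' G is the pseudo-inverse restricted to a subset of nonzero modes (all of
#' them by default). Values lie in [-1, 1]: positive pairs move in the
#' same direction, negative pairs in opposite directions. Independent of
#' the spring constant.
#'
#' @param modes A `gnm_modes` object.
#' @param mode_subset Nonzero-mode indices to include (default: all).
#' @return A `gnm_crosscorr` object: list with `values` (N x N, diagonal
#'   exactly 1) and `mode_subset`.
#' @export
cross_correlation <- function(modes, mode_subset = NULL) {
  stopifnot(inherits(modes, "gnm_modes"))
  if (is.null(mode_subset)) mode_subset <- seq_len(n_nonzero(modes))
  if (!length(mode_subset)) stop("mode_subset must be nonempty")
  nz <- nonzero_modes(modes, mode_subset)
  v <- sweep(nz$vectors, 2, sqrt(nz$values), "/")
  g <- tcrossprod(v)
  d <- diag(g)
  if (any(d <= 1e-20 * max(d))) {
    bad <- which(d <= 1e-20 * max(d))
    stop("undefined correlation: node(s) with zero fluctuation in the ",
         "selected modes: ", paste(head(bad, 10), collapse = ", "))
  }
  cc <- g / sqrt(outer(d, d))
  over <- abs(cc) > 1
  cc[over] <- sign(cc[over])   # absorb rounding at the +/-1 boundary
  diag(cc) <- 1
  out <- list(values = cc, mode_subset = mode_subset)
  class(out) <- "gnm_crosscorr"
  out
}

#' @export
print.gnm_crosscorr <- function(x, ...) {
  cat("gnm_crosscorr:", nrow(x$values), "x", ncol(x$values),
      "map over mode(s)", paste(range(x$mode_subset), collapse = ".."), "\n")
  invisible(x)
}

#' Degree of collectivity of a mode
#'
#' Entropy-based measure of how many nodes a mode engages:
#' kappa_k = (1/N) exp(-sum_i u_{k,i}^2 ln u_{k,i}^2), ranging from 1/N
#' (motion localized on a single node) to 1 (all nodes participating
#' equally). Components with u^2 = 0 contribute nothing to the exponent
#' (the x ln x -> 0 limit). Soft modes are typically highly collective;
#' stiff modes highly localized.
#'
#' @param modes A `gnm_modes` object.
#' @param k Vector of nonzero-mode indices (1 = softest); default all.
#' @return Numeric vector of kappa values in [1/N, 1].
#' @export
collectivity <- function(modes, k = NULL) {
  stopifnot(inherits(modes, "gnm_modes"))
  if (is.null(k)) k <- seq_len(n_nonzero(modes))
  nz <- nonzero_modes(modes, k)
  apply(nz$vectors, 2, function(u) {
    u2 <- u^2
    pos <- u2 > 0
    exp(-sum(u2[pos] * log(u2[pos]))) / modes$n
  })
}

#' Number of soft modes carrying a given share of the dynamics
#'
#' The weight of mode k in the fluctuation budget is lambda_k^-1. This
#' returns the smallest m such that the m softest modes account for at
#' least `fraction` of the total (default 1/10), the usual cutoff for
#' reporting per-mode collectivities.
#'
#' @param modes A `gnm_modes` object (connected network).
#' @param fraction Target share of the overall dynamics, in (0, 1].
#' @return Integer m.
#' @export
soft_mode_count <- function(modes, fraction = 0.1) {
  stopifnot(inherits(modes, "gnm_modes"), fraction > 0, fraction <= 1)
  w <- 1 / nonzero_modes(modes)$values
  m <- which(cumsum(w) >= fraction * sum(w))[1]
  as.integer(m)
}

#' Theoretical B-factors from the fluctuation profile
#'
#' Crystallographic B-factors measure mean-square displacements through
#' B_i = (8 pi^2 / 3) <(Delta R_i)^2>. The model predicts fluctuations up
#' to the global scale 3 k_B T / gamma; with `scale_policy = "fit"` that
#' scale is set by the least-squares scalar c mapping the predicted profile
#' onto the experimental B-factors (regression through the origin), with
#' `"unit"` it is 1.
#'
#' @param profile A `gnm_profile` object (or a numeric msf vector).
#' @param experimental Experimental B-factors (needed for `"fit"`; nodes
#'   with `NA` are ignored in the fit but still predicted).
#' @param scale_policy `"fit"` or `"unit"`.
#' @return List with `b` (predicted B-factors, Angstrom^2), `scale_c` and
#'   `scale_policy`.
#' @export
theoretical_b_factors <- function(profile, experimental = NULL,
                                  scale_policy = c("fit", "unit")) {
  scale_policy <- match.arg(scale_policy)
  msf <- if (inherits(profile, "gnm_profile")) profile$msf else
    as.numeric(profile)
  b0 <- (8 * pi^2 / 3) * msf
  if (scale_policy == "unit")
    return(list(b = b0, scale_c = 1, scale_policy = "unit"))
  if (is.null(experimental) || all(is.na(experimental)))
    stop("missing data: scale_policy = 'fit' requires experimental B-factors")
  ok <- !is.na(experimental)
  cc <- sum(experimental[ok] * b0[ok]) / sum(b0[ok]^2)
  list(b = cc * b0, scale_c = cc, scale_policy = "fit")
}
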