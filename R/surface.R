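# Solvent accessible surface area (Shrake-Rupley point sampling) and the
# protein-DNA contact area feature (pdca).

#' Default van der Waals radii
#'
#' Element-keyed radii (Angstrom) in the NACCESS tradition, read from the
#' table shipped with the package (`inst/extdata/vdw_radii.tsv`).  Users can
#' supply their own named vector anywhere a `radii` argument appears.
#'
#' @param path optional path to a two-column (element, radius) TSV.
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdw_radii <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "vdw_radii.tsv", package = "tfdnaqa",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           comment.char = "#")
  stats::setNames(as.numeric(tab$radius), toupper(tab$element))
}

#' Quasi-uniform points on the unit sphere
#'
#' Deterministic generalized-spiral construction (no random number use), so
#' SASA values are bit-reproducible for a given `n`.
#'
#' @param n number of points (>= 2).
#' @return `n` x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  stopifnot(n >= 2)
  k <- seq_len(n)
  h <- -1 + 2 * (k - 1) / (n - 1)
  theta <- acos(pmin(1, pmax(-1, h)))
  phi <- numeric(n)
  for (i in 2:(n - 1))
    phi[i] <- (phi[i - 1] + 3.6 / sqrt(n * (1 - h[i]^2))) %% (2 * pi)
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# Express coordinates in a molecule-intrinsic principal-axes frame (axis
# signs fixed by the third moment) before point sampling, so that SASA is
# invariant under rigid motion of the input to floating-point precision
# rather than only up to sampling noise.
.principal_align <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(xyz)
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  e <- eigen(crossprod(X) / n, symmetric = TRUE)
  V <- e$vectors
  scale3 <- n * max(e$values[1], 1)^1.5
  for (k in 1:3) {
    s <- sum((X %*% V[, k])^3)
    if (abs(s) > 1e-8 * scale3 && s < 0) V[, k] <- -V[, k]
  }
  X %*% V
}

#' Solvent accessible surface area by point sampling
#'
#' Numerical SASA: each atom's sphere is expanded by the probe radius and
#' covered with `n_points` quasi-uniform points; the accessible area is the
#' fraction of points not buried inside any neighboring expanded sphere.
#' Hydrogens must be excluded by the caller (heavy-atom SASA convention).
#'
#' @param atoms data frame with columns `x`, `y`, `z`, `elem` (and
#'   optionally `is_h`, which must then be all `FALSE`).
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points points per atom; 960 balances speed and the <1%
#'   convergence documented in the package vignette.
#' @param radii named vector of per-element vdW radii; see [vdw_radii()].
#' @param align express coordinates in the molecule's principal-axes frame
#'   before sampling, making the result invariant under rigid motion of
#'   the input (disable when several calls must share one frame, as
#'   [compute_pdca()] does).
#' @return Object of class `sasa_result`: list with `per_atom` (Angstrom^2,
#'   one entry per input atom), `total`, `probe_radius`, `n_points`.
#' @export
compute_sasa <- function(atoms, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii(), align = TRUE) {
  stopifnot(nrow(atoms) >= 1L)
  if (!is.null(atoms$is_h) && any(atoms$is_h))
    .stop_tfdnaqa("hydrogens must be excluded before SASA computation",
                  "tfdnaqa_config_error")
  el <- toupper(atoms$elem)
  miss <- setdiff(unique(el), names(radii))
  if (length(miss) > 0L)
    .stop_tfdnaqa(paste0("no vdW radius for element(s): ",
                         paste(miss, collapse = ", ")),
                  "tfdnaqa_config_error")
  r <- unname(radii[el])
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (align) xyz <- .principal_align(xyz)
  per <- .sasa_kernel(xyz, r, probe_radius, sphere_points(n_points))
  structure(list(per_atom = per, total = sum(per),
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa_result")
}

#' Per-atom SASA table
#'
#' @param cx a `pdna_complex`.
#' @param path optional TSV output path.
#' @inheritParams compute_sasa
#' @return Data frame of heavy atoms with an `area` column (Angstrom^2).
#' @export
sasa_table <- function(cx, path = NULL, probe_radius = 1.4, n_points = 960,
                       radii = vdw_radii()) {
  a <- cx$atoms[!cx$atoms$is_h, , drop = FALSE]
  res <- compute_sasa(a, probe_radius, n_points, radii)
  out <- cbind(a[, c("chain", "resno", "resid", "name")],
               area = res$per_atom)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' Protein-DNA contact area (pdca)
#'
#' The contact area is the solvent accessible surface area buried on complex
#' formation: SASA(protein alone) + SASA(DNA alone) - SASA(complex), with
#' component coordinates unchanged (rigid separation).  The full, un-halved
#' difference is reported.
#'
#' @param cx a `pdna_complex` with protein and DNA chains.
#' @inheritParams compute_sasa
#' @return Contact area in Angstrom^2 (>= 0 up to point-sampling noise).
#' @export
compute_pdca <- function(cx, probe_radius = 1.4, n_points = 960,
                         radii = vdw_radii()) {
  pa <- .protein_atoms(cx)
  da <- .dna_atoms(cx)
  stopifnot(nrow(pa) > 0L, nrow(da) > 0L)
  # one shared frame (principal axes of the complex) for all three terms,
  # so component and complex burial patterns cancel exactly on separation
  both <- rbind(pa, da)
  xyz <- .principal_align(as.matrix(both[, c("x", "y", "z")]))
  both$x <- xyz[, 1]; both$y <- xyz[, 2]; both$z <- xyz[, 3]
  ip <- seq_len(nrow(pa))
  s_p <- compute_sasa(both[ip, ], probe_radius, n_points, radii,
                      align = FALSE)$total
  s_d <- compute_sasa(both[-ip, ], probe_radius, n_points, radii,
                      align = FALSE)$total
  s_c <- compute_sasa(both, probe_radius, n_points, radii,
                      align = FALSE)$total
  s_p + s_d - s_c
}
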