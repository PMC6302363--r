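# Rigid superposition and RMSD-based labeling of docked models.
#
# Models are compared to the native complex by superposing the protein
# components (C-alpha Kabsch fit) and measuring the root-mean-square
# deviation over DNA backbone heavy atoms.  Models at or below the RMSD
# cutoff (default 3 A, boundary inclusive) are "good"/positive.

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares proper rotation and translation mapping `mov_coords` onto
#' `ref_coords` (matched row order), computed via singular value
#' decomposition with the determinant correction that excludes reflections.
#'
#' @param ref_coords N x 3 reference coordinates.
#' @param mov_coords N x 3 moving coordinates, same row correspondence.
#' @return List of class `rigid_transform` with `rotation` (3 x 3, det +1),
#'   `translation` (length 3) such that `x %*% t(rotation) + translation`
#'   maps moving onto reference, and `rmsd` (post-fit, Angstrom).
#' @export
kabsch_superpose <- function(ref_coords, mov_coords) {
  ref_coords <- as.matrix(ref_coords)
  mov_coords <- as.matrix(mov_coords)
  n <- nrow(ref_coords)
  if (n < 3L || nrow(mov_coords) != n)
    .stop_tfdnaqa("superposition needs >= 3 matched points",
                  "tfdnaqa_geometry_error")
  cm_ref <- colMeans(ref_coords)
  cm_mov <- colMeans(mov_coords)
  P <- sweep(ref_coords, 2, cm_ref)
  Q <- sweep(mov_coords, 2, cm_mov)
  sv_ref <- svd(P)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    .stop_tfdnaqa("degenerate (collinear) reference points",
                  "tfdnaqa_geometry_error")
  H <- crossprod(Q, P)          # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Q %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - P)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cm_ref - R %*% cm_mov),
                 rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords N x 3 matrix.
#' @param tf a `rigid_transform` from [kabsch_superpose()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  sweep(as.matrix(coords) %*% t(tf$rotation), 2, -tf$translation)
}

.match_atoms <- function(ref, mov) {
  kr <- paste(ref$chain, ref$resno, ref$insert, ref$name, sep = "\r")
  km <- paste(mov$chain, mov$resno, mov$insert, mov$name, sep = "\r")
  idx <- match(kr, km)
  sel <- !is.na(idx)
  list(ref = ref[sel, , drop = FALSE], mov = mov[idx[sel], , drop = FALSE],
       frac = mean(sel))
}

#' DNA backbone RMSD of a docked model against the native complex
#'
#' Superposes the model on the reference using matched protein C-alpha
#' atoms (Kabsch), applies the fit to the whole model, and returns the RMSD
#' over matched DNA backbone heavy atoms (`P`, `OP1`, `OP2`, `O5'`, `C5'`,
#' `C4'`, `C3'`, `O3'`).  Atoms are matched by chain, residue number,
#' insertion code and atom name; a warning is raised when under 80% of the
#' reference atoms find a partner.
#'
#' @param reference,model `pdna_complex` objects sharing atom identities.
#' @param backbone_atoms DNA backbone atom-name set.
#' @return RMSD in Angstrom.
#' @export
dna_backbone_rmsd <- function(reference, model,
                              backbone_atoms = .DNA_BACKBONE) {
  ref_ca <- .protein_atoms(reference)
  ref_ca <- ref_ca[ref_ca$name == "CA", , drop = FALSE]
  mov_ca <- .protein_atoms(model)
  mov_ca <- mov_ca[mov_ca$name == "CA", , drop = FALSE]
  mca <- .match_atoms(ref_ca, mov_ca)
  if (nrow(mca$ref) < 3L)
    .stop_tfdnaqa("fewer than 3 matched protein C-alpha atoms",
                  "tfdnaqa_correspondence_error")
  if (mca$frac < 0.8)
    warning(sprintf("only %.0f%% of reference C-alpha atoms matched",
                    100 * mca$frac))
  tf <- kabsch_superpose(as.matrix(mca$ref[, c("x", "y", "z")]),
                         as.matrix(mca$mov[, c("x", "y", "z")]))
  ref_bb <- .dna_atoms(reference)
  ref_bb <- ref_bb[ref_bb$name %in% backbone_atoms, , drop = FALSE]
  mov_bb <- .dna_atoms(model)
  mov_bb <- mov_bb[mov_bb$name %in% backbone_atoms, , drop = FALSE]
  mbb <- .match_atoms(ref_bb, mov_bb)
  if (nrow(mbb$ref) < 1L)
    .stop_tfdnaqa("no matched DNA backbone atoms",
                  "tfdnaqa_correspondence_error")
  if (mbb$frac < 0.8)
    warning(sprintf("only %.0f%% of reference DNA backbone atoms matched",
                    100 * mbb$frac))
  fitted <- apply_transform(as.matrix(mbb$mov[, c("x", "y", "z")]), tf)
  sqrt(mean(rowSums((fitted - as.matrix(mbb$ref[, c("x", "y", "z")]))^2)))
}

#' Label a model by RMSD
#'
#' Models with backbone RMSD at or below the cutoff (default 3 A, boundary
#' inclusive) are "good"/positive predictions; others are "bad"/negative.
#'
#' @param rmsd backbone RMSD, Angstrom (>= 0).
#' @param cutoff positive/negative boundary, Angstrom.
#' @return List of class `rmsd_label`: `rmsd`, `positive`, `cutoff`.
#' @export
label_model <- function(rmsd, cutoff = 3) {
  if (any(rmsd < 0)) .stop_tfdnaqa("negative RMSD", "tfdnaqa_input_error")
  structure(list(rmsd = rmsd, positive = rmsd <= cutoff, cutoff = cutoff),
            class = "rmsd_label")
}

#' Number of residue-base contacts (NRBC)
#'
#' Counts distinct (protein residue, nucleotide) pairs with any protein
#' heavy atom within `contact_cutoff` of a base-moiety heavy atom of the
#' nucleotide.  Complexes with fewer than 10 contacts are "hard" docking
#' targets; others are "easy" (see [classify_target()]).
#'
#' @param cx a `pdna_complex`.
#' @param contact_cutoff heavy-atom distance cutoff, Angstrom.
#' @return Integer contact count.
#' @export
count_nrbc <- function(cx, contact_cutoff = 4.5) {
  pa <- .protein_atoms(cx)
  ba <- .dna_atoms(cx)
  ba <- ba[!is.na(ba$moiety) & ba$moiety == "base", , drop = FALSE]
  if (nrow(pa) == 0L || nrow(ba) == 0L) return(0L)
  dm <- outer(pa$x, ba$x, "-")^2 + outer(pa$y, ba$y, "-")^2 +
    outer(pa$z, ba$z, "-")^2
  hit <- which(dm <= contact_cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(0L)
  pres <- paste(pa$chain[hit[, 1L]], pa$resno[hit[, 1L]],
                pa$insert[hit[, 1L]])
  dres <- paste(ba$chain[hit[, 2L]], ba$resno[hit[, 2L]],
                ba$insert[hit[, 2L]])
  length(unique(paste(pres, dres, sep = "|")))
}

#' Classify a docking target as easy or hard
#'
#' Hard targets have fewer than 10 residue-base contacts.
#'
#' @param nrbc contact count from [count_nrbc()].
#' @return `"easy"` or `"hard"`.
#' @export
classify_target <- function(nrbc) {
  if (nrbc < 10) "hard" else "easy"
}

#' Per-model RMSD/label table
#'
#' @param reference native `pdna_complex`.
#' @param models named list of model `pdna_complex` objects.
#' @param cutoff RMSD cutoff, Angstrom.
#' @param path optional TSV output path.
#' @return Data frame with `model_id`, `rmsd`, `label` (1 = positive).
#' @export
rmsd_manifest <- function(reference, models, cutoff = 3, path = NULL) {
  ids <- names(models)
  if (is.null(ids)) ids <- sprintf("model_%03d", seq_along(models))
  rmsd <- vapply(models, function(m) dna_backbone_rmsd(reference, m),
                 numeric(1))
  out <- data.frame(model_id = ids, rmsd = as.numeric(rmsd),
                    label = as.integer(rmsd <= cutoff),
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
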