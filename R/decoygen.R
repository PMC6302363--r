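# Synthetic fixtures: an idealized B-DNA duplex builder, toy protein-DNA
# complexes with hydrogen-bonding probe residues, rigid-body decoy sets
# with controlled RMSD, and Gaussian feature-vector datasets.
#
# The duplex is a rigid-template construction: nucleotides are built from
# regular-polygon ring templates anchored at the standard-reference-frame
# glycosidic position, stacked with canonical B-form rise (3.38 A) and
# twist (36 degrees).  Watson-Crick donor/acceptor geometry and backbone
# phosphate spacing come out correct to a few tenths of an Angstrom;
# inter-residue covalent closure (O3'-P) is not refined, which no feature
# in this package depends on.

.RISE <- 3.38
.TWIST <- 36

.rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

.rot_axis <- function(axis, deg) {
  a <- deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Nucleotide templates in the strand-I pair frame: z axis = helix axis,
# glycosidic N at the standard-frame position, base in the z = 0 plane.
.nt_template <- function(base) {
  gN <- c(-1.289, 4.551)                      # glycosidic N (N9/N1)
  c1p <- c(-2.477, 5.402)
  u <- (gN - c1p) / sqrt(sum((gN - c1p)^2))   # C1' -> glycosidic direction
  ring_at <- function(center, r, ang_deg)
    center + r * c(cos(ang_deg * pi / 180), sin(ang_deg * pi / 180))
  out_dir <- function(p, center) (p - center) / sqrt(sum((p - center)^2))
  atoms <- list()
  add <- function(name, xy, z = 0) atoms[[name]] <<- c(xy, z)

  if (base %in% c("C", "T")) {
    ctr <- gN + 1.38 * u
    a0 <- atan2(gN[2] - ctr[2], gN[1] - ctr[1]) * 180 / pi
    ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
    pos <- lapply(0:5, function(k) ring_at(ctr, 1.38, a0 + 60 * k))
    names(pos) <- ring
    for (nm in ring) add(nm, pos[[nm]])
    add("O2", pos$C2 + 1.23 * out_dir(pos$C2, ctr))
    if (base == "C") {
      add("N4", pos$C4 + 1.34 * out_dir(pos$C4, ctr))
    } else {
      add("O4", pos$C4 + 1.23 * out_dir(pos$C4, ctr))
      add("C7", pos$C5 + 1.50 * out_dir(pos$C5, ctr))
    }
  } else {
    r5 <- 1.37 / (2 * sin(36 * pi / 180))
    pctr <- gN + r5 * u
    a0 <- atan2(gN[2] - pctr[2], gN[1] - pctr[1]) * 180 / pi
    pent <- c("N9", "C8", "N7", "C5", "C4")
    ppos <- lapply(0:4, function(k) ring_at(pctr, r5, a0 - 72 * k))
    names(ppos) <- pent
    for (nm in pent) add(nm, ppos[[nm]])
    mid <- (ppos$C4 + ppos$C5) / 2
    hctr <- mid - 1.204 * out_dir(pctr, mid)
    aC4 <- atan2(ppos$C4[2] - hctr[2], ppos$C4[1] - hctr[1]) * 180 / pi
    hex <- c("C4", "N3", "C2", "N1", "C6", "C5")
    hpos <- lapply(0:5, function(k) ring_at(hctr, 1.39, aC4 + 60 * k))
    names(hpos) <- hex
    for (nm in c("N3", "C2", "N1", "C6")) add(nm, hpos[[nm]])
    if (base == "A") {
      add("N6", hpos$C6 + 1.34 * out_dir(hpos$C6, hctr))
    } else {
      add("O6", hpos$C6 + 1.23 * out_dir(hpos$C6, hctr))
      add("N2", hpos$C2 + 1.34 * out_dir(hpos$C2, hctr))
    }
  }
  # sugar and phosphate (fixed template, shared by all bases)
  bb <- list(
    "C1'" = c(-2.477, 5.402, 0.00), "C2'" = c(-3.558, 5.567, -1.00),
    "C3'" = c(-4.759, 4.743, -0.62), "C4'" = c(-4.453, 3.658, 0.42),
    "O4'" = c(-3.079, 4.089, 0.74), "C5'" = c(-5.850, 4.050, 1.00),
    "O5'" = c(-6.560, 5.080, 0.35), "P" = c(-7.277, 6.106, -0.30),
    "OP1" = c(-6.377, 7.006, -1.20), "OP2" = c(-8.477, 6.706, 0.30),
    "O3'" = c(-5.690, 3.938, 0.11))
  coords <- c(lapply(atoms, function(p) c(p[1], p[2], p[3])), bb)
  nm <- names(coords)
  data.frame(name = nm, elem = .elem_from_name(nm),
             x = vapply(coords, `[`, 0, 1), y = vapply(coords, `[`, 0, 2),
             z = vapply(coords, `[`, 0, 3),
             resid = paste0("D", base), stringsAsFactors = FALSE,
             row.names = NULL)
}

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

#' Build an idealized B-DNA duplex
#'
#' Constructs a straight double helix (rise 3.38 A, twist 36 degrees per
#' step) with full backbone and base heavy atoms on two complementary
#' antiparallel chains.  Chain `chains[2]` carries the reverse complement
#' of `sequence`.  5'-terminal residues lack the phosphate group (P, OP1,
#' OP2) and keep O5'.
#'
#' @param sequence character string over `A`, `C`, `G`, `T`, length >= 4.
#' @param chains chain identifiers for the two strands.
#' @return A `pdna_complex` (DNA-only component; not dockable on its own).
#' @export
build_bdna <- function(sequence, chains = c("B", "C")) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) < 4L)
    .stop_tfdnaqa("sequence must have length >= 4", "tfdnaqa_sequence_error")
  if (!all(bases %in% c("A", "C", "G", "T")))
    .stop_tfdnaqa(sprintf("invalid character(s) in sequence '%s'", sequence),
                  "tfdnaqa_sequence_error")
  n <- length(bases)
  templates <- lapply(c(A = "A", C = "C", G = "G", T = "T"), .nt_template)
  rows <- list()
  for (t in seq_len(n) - 1L) {
    R <- .rot_z(.TWIST * t)
    dz <- .RISE * t
    # strand I residue (t+1)
    tm <- templates[[bases[t + 1L]]]
    xyz <- as.matrix(tm[, c("x", "y", "z")]) %*% t(R)
    a1 <- tm
    a1$x <- xyz[, 1]; a1$y <- xyz[, 2]; a1$z <- xyz[, 3] + dz
    a1$chain <- chains[1]
    a1$resno <- t + 1L
    # strand II partner: template of the complement, flipped about the
    # pair dyad (y -> -y, z -> -z), then the same helical transform
    tm2 <- templates[[.COMPLEMENT[bases[t + 1L]]]]
    flip <- as.matrix(tm2[, c("x", "y", "z")])
    flip[, 2] <- -flip[, 2]
    flip[, 3] <- -flip[, 3]
    xyz2 <- flip %*% t(R)
    a2 <- tm2
    a2$x <- xyz2[, 1]; a2$y <- xyz2[, 2]; a2$z <- xyz2[, 3] + dz
    a2$chain <- chains[2]
    a2$resno <- n - t
    rows[[length(rows) + 1L]] <- a1
    rows[[length(rows) + 1L]] <- a2
  }
  at <- do.call(rbind, rows)
  # drop 5'-phosphates (resno 1 on each chain), keep O5'
  drop <- at$resno == 1L & at$name %in% c("P", "OP1", "OP2")
  at <- at[!drop, , drop = FALSE]
  at <- at[order(match(at$chain, chains), at$resno), , drop = FALSE]
  atoms <- data.frame(serial = seq_len(nrow(at)), name = at$name,
                      elem = at$elem, resid = at$resid, chain = at$chain,
                      resno = at$resno, insert = "", x = at$x, y = at$y,
                      z = at$z, occ = 1, alt = "", is_h = FALSE,
                      stringsAsFactors = FALSE)
  new_complex(paste0("bdna_", sequence), atoms,
              stats::setNames(c("dna", "dna"), chains),
              require_both = FALSE)
}

# Poly-alanine alpha-helix backbone along +z in a local frame.
.poly_ala_helix <- function(n_res, chain = "A") {
  rows <- list()
  for (i in seq_len(n_res) - 1L) {
    phi <- 100 * i * pi / 180
    z <- 1.5 * i
    at <- rbind(
      N  = c(1.6 * cos(phi - 0.45), 1.6 * sin(phi - 0.45), z - 0.6),
      CA = c(2.3 * cos(phi), 2.3 * sin(phi), z),
      C  = c(2.0 * cos(phi + 0.50), 2.0 * sin(phi + 0.50), z + 0.55),
      O  = c(2.2 * cos(phi + 0.60), 2.2 * sin(phi + 0.60), z + 1.75),
      CB = c(3.4 * cos(phi - 0.10), 3.4 * sin(phi - 0.10), z - 0.45))
    rows[[i + 1L]] <- data.frame(name = rownames(at),
                                 elem = .elem_from_name(rownames(at)),
                                 resid = "ALA", chain = chain,
                                 resno = i + 1L, x = at[, 1], y = at[, 2],
                                 z = at[, 3], stringsAsFactors = FALSE,
                                 row.names = NULL)
  }
  do.call(rbind, rows)
}

# Replace residue `resno` of the helix with a probe residue whose terminal
# donor atoms are aimed at base acceptors of the duplex (synthetic
# geometry: donors are placed on the lone-pair extension of the target
# acceptor at hydrogen-bonding distance).
.place_probe <- function(prot, dna_atoms, resno, probe) {
  sel <- prot$resno == resno
  cb <- unlist(prot[sel & prot$name == "CB", c("x", "y", "z")])
  base_at <- dna_atoms[!is.na(dna_atoms$moiety) & dna_atoms$moiety == "base",
                       , drop = FALSE]
  ext_point <- function(res_sel, atom, antecedent, dist = 2.9) {
    A <- unlist(base_at[res_sel & base_at$name == atom,
                        c("x", "y", "z")][1, ])
    AA <- unlist(base_at[res_sel & base_at$name == antecedent,
                         c("x", "y", "z")][1, ])
    v <- A - AA
    A + dist * v / sqrt(sum(v^2))
  }
  add_atoms <- function(nm, coords) {
    add <- prot[sel, ][rep(1, length(nm)), ]
    add$name <- nm
    add$elem <- .elem_from_name(nm)
    add$x <- coords[, 1]; add$y <- coords[, 2]; add$z <- coords[, 3]
    add
  }
  if (probe == "ARG") {
    # bidentate target: nearest guanine O6 + N7 of the same base
    g <- base_at[base_at$resid == "DG" & base_at$name == "O6", , drop = FALSE]
    if (nrow(g) == 0L) return(prot)
    d <- (g$x - cb[1])^2 + (g$y - cb[2])^2 + (g$z - cb[3])^2
    tgt <- g[which.min(d), ]
    rsel <- base_at$chain == tgt$chain & base_at$resno == tgt$resno
    nh1 <- ext_point(rsel, "O6", "C6")
    nh2 <- ext_point(rsel, "N7", "C5")
    cz <- (nh1 + nh2) / 2 + 1.0 * (cb - (nh1 + nh2) / 2) /
      sqrt(sum((cb - (nh1 + nh2) / 2)^2))
    ne <- cz + 1.35 * (cb - cz) / sqrt(sum((cb - cz)^2))
    new <- add_atoms(c("NE", "CZ", "NH1", "NH2"), rbind(ne, cz, nh1, nh2))
  } else if (probe == "LYS") {
    acc <- base_at[base_at$name %in% c("O6", "N7", "O4", "N3"), ,
                   drop = FALSE]
    if (nrow(acc) == 0L) return(prot)
    d <- (acc$x - cb[1])^2 + (acc$y - cb[2])^2 + (acc$z - cb[3])^2
    tgt <- acc[which.min(d), ]
    rsel <- base_at$chain == tgt$chain & base_at$resno == tgt$resno
    ante <- c(O6 = "C6", N7 = "C5", O4 = "C4", N3 = "C2")[[tgt$name]]
    nz <- ext_point(rsel, tgt$name, ante)
    new <- add_atoms("NZ", rbind(nz))
  } else if (probe == "ASN") {
    acc <- base_at[base_at$name %in% c("N7", "O6", "O4"), , drop = FALSE]
    if (nrow(acc) == 0L) return(prot)
    d <- (acc$x - cb[1])^2 + (acc$y - cb[2])^2 + (acc$z - cb[3])^2
    tgt <- acc[which.min(d), ]
    rsel <- base_at$chain == tgt$chain & base_at$resno == tgt$resno
    ante <- c(O6 = "C6", N7 = "C5", O4 = "C4")[[tgt$name]]
    nd2 <- ext_point(rsel, tgt$name, ante)
    cg <- nd2 + 1.33 * (cb - nd2) / sqrt(sum((cb - nd2)^2))
    od1 <- cg + 1.23 * (cg - (nd2 + cb) / 2) /
      sqrt(sum((cg - (nd2 + cb) / 2)^2))
    new <- add_atoms(c("CG", "OD1", "ND2"), rbind(cg, od1, nd2))
  } else {
    return(prot)
  }
  prot$resid[sel] <- switch(probe, ARG = "ARG", LYS = "LYS", ASN = "ASN")
  new$resid <- prot$resid[sel][1]
  rbind(prot, new)
}

#' Build a toy protein-DNA complex
#'
#' Places a poly-alanine alpha-helix (optionally carrying an Arg/Lys/Asn
#' hydrogen-bonding probe residue) against the major-groove face of an
#' idealized B-DNA duplex, at a controlled closest heavy-atom separation.
#'
#' @param dna_length duplex length in base pairs (>= 4).
#' @param protein_size helix length in residues.
#' @param interface_offset target closest protein-DNA heavy-atom distance,
#'   Angstrom (small values create a contacting interface; ~30 gives a
#'   fully separated complex).
#' @param seed integer seed controlling the DNA sequence.
#' @param probe `"ARG"`, `"LYS"`, `"ASN"` or `"none"`; the probe residue's
#'   terminal atoms are aimed at base acceptors so that a contacting
#'   interface has genuine hydrogen-bond geometry.
#' @param id complex identifier.
#' @return A valid `pdna_complex` (chain A protein, chains B/C DNA).
#' @export
build_toy_complex <- function(dna_length = 12, protein_size = 12,
                              interface_offset = 3, seed = 1,
                              probe = c("ARG", "LYS", "ASN", "none"),
                              id = NULL) {
  probe <- match.arg(probe)
  seq_chars <- withr::with_seed(seed,
    sample(c("A", "C", "G", "T"), dna_length, replace = TRUE))
  seq_chars[ceiling(dna_length / 2)] <- "G"   # guarantee a purine target
  sequence <- paste(seq_chars, collapse = "")
  dna <- build_bdna(sequence)
  n <- dna_length
  t_mid <- floor((n - 1) / 2)
  groove_dir <- as.numeric(.rot_z(.TWIST * t_mid) %*% c(1, 0, 0))
  prot <- .poly_ala_helix(protein_size)
  # center helix on the middle pair, 20 A out along the groove direction
  prot_z_mid <- mean(range(prot$z))
  shift <- groove_dir * 20 + c(0, 0, .RISE * t_mid - prot_z_mid)
  prot$x <- prot$x + shift[1]
  prot$y <- prot$y + shift[2]
  prot$z <- prot$z + shift[3]
  # walk in along the groove direction until the closest heavy-atom
  # distance matches the requested offset
  min_gap <- function(p) {
    d2 <- outer(p$x, dna$atoms$x, "-")^2 + outer(p$y, dna$atoms$y, "-")^2 +
      outer(p$z, dna$atoms$z, "-")^2
    sqrt(min(d2))
  }
  for (it in 1:25) {
    g <- min_gap(prot)
    if (abs(g - interface_offset) < 0.05) break
    step <- (g - interface_offset)
    prot$x <- prot$x - step * groove_dir[1]
    prot$y <- prot$y - step * groove_dir[2]
    prot$z <- prot$z - step * groove_dir[3]
  }
  if (probe != "none" && interface_offset <= 6)
    prot <- .place_probe(prot, dna$atoms, ceiling(protein_size / 2), probe)
  prot <- prot[order(prot$resno), , drop = FALSE]
  pa <- data.frame(serial = seq_len(nrow(prot)), name = prot$name,
                   elem = prot$elem, resid = prot$resid, chain = "A",
                   resno = prot$resno, insert = "", x = prot$x, y = prot$y,
                   z = prot$z, occ = 1, alt = "", is_h = FALSE,
                   stringsAsFactors = FALSE)
  da <- dna$atoms[, names(pa)]
  da$serial <- nrow(pa) + seq_len(nrow(da))
  if (is.null(id))
    id <- sprintf("toy_%s_seed%d", tolower(probe), seed)
  new_complex(id, rbind(pa, da),
              c(A = "protein", B = "dna", C = "dna"))
}

#' Decoy generation settings
#'
#' Magnitude ranges and sampling seed for rigid-body decoys.  Defaults
#' mirror the docking-study conditions this package emulates: 200 models
#' per case with roughly 7.6% near-native placements.
#'
#' @param n_decoys number of decoys (>= 1).
#' @param max_translation maximum DNA translation, Angstrom.
#' @param min_translation minimum DNA translation, Angstrom; setting this
#'   above the RMSD cutoff emulates a sampling run that fails to produce
#'   any near-native model.
#' @param max_rotation maximum DNA rotation about its centroid, degrees.
#' @param seed integer seed.
#' @param near_native_fraction_target fraction of decoys drawn from a
#'   small-perturbation regime (translation <= 2.5 A, rotation <= 5
#'   degrees) so that decoy sets contain a controlled near-native share;
#'   `0` disables the regime.
#' @return List of class `decoy_spec`.
#' @export
decoy_spec <- function(n_decoys = 200, max_translation = 10,
                       min_translation = 0, max_rotation = 30, seed = 1,
                       near_native_fraction_target = 0.076) {
  stopifnot(n_decoys >= 1, max_translation >= 0,
            min_translation >= 0, min_translation <= max_translation,
            max_rotation >= 0,
            near_native_fraction_target >= 0,
            near_native_fraction_target <= 1)
  structure(list(n_decoys = as.integer(n_decoys),
                 max_translation = max_translation,
                 min_translation = min_translation,
                 max_rotation = max_rotation, seed = as.integer(seed),
                 near_native_fraction_target = near_native_fraction_target),
            class = "decoy_spec")
}

#' Generate rigid-body decoys of a native complex
#'
#' Each decoy keeps the protein fixed and applies a rigid motion to the
#' DNA: a rotation about a uniform random axis (angle uniform up to
#' `max_rotation`, about the DNA centroid) followed by a translation of
#' uniform magnitude up to `max_translation` in a uniform random
#' direction.  The reported RMSD is [dna_backbone_rmsd()] of the decoy
#' against the native.
#'
#' @param native a valid `pdna_complex`.
#' @param spec a [decoy_spec()].
#' @param rmsd_cutoff labeling cutoff passed to the manifest, Angstrom.
#' @return List of class `decoy_set`: `decoys` (named list of
#'   `pdna_complex`), `manifest` (data frame `model_id`, `rmsd`, `label`).
#' @export
generate_decoys <- function(native, spec = decoy_spec(), rmsd_cutoff = 3) {
  is_dna <- native$chain_class[native$atoms$chain] == "dna"
  centroid <- colMeans(native$atoms[is_dna, c("x", "y", "z")])
  n_near <- round(spec$near_native_fraction_target * spec$n_decoys)
  decoys <- withr::with_seed(spec$seed, lapply(seq_len(spec$n_decoys),
    function(k) {
      near <- k <= n_near
      min_t <- if (near) 0 else spec$min_translation
      max_t <- if (near) min(2.5, spec$max_translation)
               else spec$max_translation
      max_r <- if (near) min(5, spec$max_rotation) else spec$max_rotation
      axis <- stats::rnorm(3)
      ang <- stats::runif(1, 0, max_r)
      R <- .rot_axis(axis, ang)
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      tr <- dir * stats::runif(1, min_t, max_t)
      cx <- native
      xyz <- as.matrix(cx$atoms[is_dna, c("x", "y", "z")])
      xyz <- sweep(sweep(xyz, 2, centroid) %*% t(R), 2, -(centroid + tr))
      cx$atoms$x[is_dna] <- xyz[, 1]
      cx$atoms$y[is_dna] <- xyz[, 2]
      cx$atoms$z[is_dna] <- xyz[, 3]
      cx$id <- sprintf("%s_d%03d", native$id, k)
      cx
    }))
  names(decoys) <- vapply(decoys, `[[`, "", "id")
  manifest <- rmsd_manifest(native, decoys, cutoff = rmsd_cutoff)
  structure(list(native = native, decoys = decoys, manifest = manifest),
            class = "decoy_set")
}

#' Synthetic feature-dataset settings
#'
#' Two-Gaussian generative model over the four quality-assessment features
#' with a shared covariance.  Defaults emulate the class imbalance of the
#' docking study this package follows (7.6% positives at n = 2000) with a
#' 4-standard-deviation separation per feature.
#'
#' @param n_pos,n_neg class sizes (>= 0).
#' @param mean_pos,mean_neg length-4 class means.
#' @param covariance shared 4 x 4 symmetric positive semi-definite matrix.
#' @param seed integer seed.
#' @return List of class `feature_spec`.
#' @export
feature_spec <- function(n_pos = 152, n_neg = 1848,
                         mean_pos = c(2, 2, 2, 2),
                         mean_neg = c(-2, -2, -2, -2),
                         covariance = diag(4), seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, length(mean_pos) == 4,
            length(mean_neg) == 4, all(dim(covariance) == c(4, 4)))
  if (max(abs(covariance - t(covariance))) > 1e-8 ||
      min(eigen(covariance, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    .stop_tfdnaqa("covariance must be symmetric positive semi-definite",
                  "tfdnaqa_spec_error")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 mean_pos = mean_pos, mean_neg = mean_neg,
                 covariance = covariance, seed = as.integer(seed)),
            class = "feature_spec")
}

#' Generate a synthetic feature dataset
#'
#' @param spec a [feature_spec()].
#' @return List with `X` (numeric matrix, columns `ddna3`, `pdca`, `pbhb`,
#'   `bidentate_hb`) and `y` (integer labels, 1 = positive/near-native).
#' @export
generate_feature_dataset <- function(spec = feature_spec()) {
  X <- withr::with_seed(spec$seed, {
    xp <- if (spec$n_pos > 0)
      matrix(MASS::mvrnorm(spec$n_pos, spec$mean_pos, spec$covariance),
             ncol = 4)
    xn <- if (spec$n_neg > 0)
      matrix(MASS::mvrnorm(spec$n_neg, spec$mean_neg, spec$covariance),
             ncol = 4)
    rbind(if (spec$n_pos > 0) xp, if (spec$n_neg > 0) xn)
  })
  colnames(X) <- c("ddna3", "pdca", "pbhb", "bidentate_hb")
  y <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  list(X = X, y = y)
}
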