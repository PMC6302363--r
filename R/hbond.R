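# Geometric hydrogen-bond detection between protein and DNA, and the two
# hydrogen-bond features: pbhb (protein-DNA base hydrogen bonds) and the
# bidentate hydrogen-bond count.
#
# Criteria follow the common heavy-atom geometric convention (HBPLUS-style
# defaults): donor-acceptor distance <= 3.9 A and donor-acceptor-antecedent
# angle >= 90 degrees; when donor hydrogens are present in the structure the
# H...A distance (<= 2.5 A) and D-H-A angle (>= 90 degrees) are checked as
# well.  Crystal structures typically lack hydrogens, so the heavy-atom
# fallback is the default path; no hydrogen placement is attempted.

#' Hydrogen-bond donor/acceptor chemistry
#'
#' Returns the per-residue donor/acceptor dictionary used by
#' [detect_hbonds()]: one row per (residue, atom) with logical `donor` and
#' `acceptor` roles and the acceptor antecedent atom (the bonded heavy atom
#' defining the lone-pair direction).  Histidine is treated as both donor
#' and acceptor at ND1/NE2 (either tautomer); backbone N of every residue
#' except proline donates; backbone O accepts.  Edit the returned data frame
#' and pass it back through the `chemistry` argument to change the rules.
#'
#' @return Data frame with columns `resid`, `atom`, `donor`, `acceptor`,
#'   `antecedent`.
#' @export
hbond_chemistry <- function() {
  row <- function(resid, atom, donor, acceptor, antecedent = NA_character_)
    data.frame(resid = resid, atom = atom, donor = donor,
               acceptor = acceptor, antecedent = antecedent,
               stringsAsFactors = FALSE)
  out <- list()
  # protein backbone
  for (aa in .AA3) {
    if (aa != "PRO") out[[length(out) + 1L]] <- row(aa, "N", TRUE, FALSE)
    out[[length(out) + 1L]] <- row(aa, "O", FALSE, TRUE, "C")
    out[[length(out) + 1L]] <- row(aa, "OXT", FALSE, TRUE, "C")
  }
  # protein side chains
  sc <- list(
    row("ARG", "NE",  TRUE, FALSE), row("ARG", "NH1", TRUE, FALSE),
    row("ARG", "NH2", TRUE, FALSE),
    row("ASN", "ND2", TRUE, FALSE), row("ASN", "OD1", FALSE, TRUE, "CG"),
    row("ASP", "OD1", FALSE, TRUE, "CG"), row("ASP", "OD2", FALSE, TRUE, "CG"),
    row("GLN", "NE2", TRUE, FALSE), row("GLN", "OE1", FALSE, TRUE, "CD"),
    row("GLU", "OE1", FALSE, TRUE, "CD"), row("GLU", "OE2", FALSE, TRUE, "CD"),
    row("HIS", "ND1", TRUE, TRUE, "CG"), row("HIS", "NE2", TRUE, TRUE, "CD2"),
    row("LYS", "NZ",  TRUE, FALSE),
    row("SER", "OG",  TRUE, TRUE, "CB"), row("THR", "OG1", TRUE, TRUE, "CB"),
    row("TRP", "NE1", TRUE, FALSE),
    row("TYR", "OH",  TRUE, TRUE, "CZ"),
    row("CYS", "SG",  TRUE, TRUE, "CB"), row("MET", "SD", FALSE, TRUE, "CG"))
  # DNA bases
  dna <- list(
    row("DA", "N6", TRUE, FALSE),
    row("DA", "N1", FALSE, TRUE, "C6"), row("DA", "N3", FALSE, TRUE, "C2"),
    row("DA", "N7", FALSE, TRUE, "C5"),
    row("DG", "N1", TRUE, FALSE), row("DG", "N2", TRUE, FALSE),
    row("DG", "O6", FALSE, TRUE, "C6"), row("DG", "N3", FALSE, TRUE, "C2"),
    row("DG", "N7", FALSE, TRUE, "C5"),
    row("DC", "N4", TRUE, FALSE),
    row("DC", "O2", FALSE, TRUE, "C2"), row("DC", "N3", FALSE, TRUE, "C2"),
    row("DT", "N3", TRUE, FALSE),
    row("DT", "O2", FALSE, TRUE, "C2"), row("DT", "O4", FALSE, TRUE, "C4"))
  # DNA sugar/phosphate oxygens (weak ester/phosphate acceptors)
  bb <- list()
  for (nt in .DNA_RES) {
    bb[[length(bb) + 1L]] <- row(nt, "O4'", FALSE, TRUE, "C1'")
    bb[[length(bb) + 1L]] <- row(nt, "O3'", FALSE, TRUE, "C3'")
    bb[[length(bb) + 1L]] <- row(nt, "O5'", FALSE, TRUE, "C5'")
    bb[[length(bb) + 1L]] <- row(nt, "OP1", FALSE, TRUE, "P")
    bb[[length(bb) + 1L]] <- row(nt, "OP2", FALSE, TRUE, "P")
  }
  do.call(rbind, c(out, sc, dna, bb))
}

.angle_deg <- function(a, b, c) {
  # angle at vertex b, degrees
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Candidate donor/acceptor atom tables for one side of the interface.
.role_atoms <- function(atoms, chemistry, role) {
  key <- paste(atoms$resid, atoms$name, sep = "\r")
  chem <- chemistry[chemistry[[role]], , drop = FALSE]
  ckey <- paste(chem$resid, chem$atom, sep = "\r")
  idx <- match(key, ckey)
  sel <- !is.na(idx)
  out <- atoms[sel, , drop = FALSE]
  out$antecedent <- chem$antecedent[idx[sel]]
  out
}

.hb_pairs <- function(don, acc, atoms_all, max_da, max_ha, min_angle) {
  if (nrow(don) == 0L || nrow(acc) == 0L) return(NULL)
  dm <- sqrt(outer(don$x, acc$x, "-")^2 + outer(don$y, acc$y, "-")^2 +
             outer(don$z, acc$z, "-")^2)
  hits <- which(dm <= max_da, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  keep <- logical(nrow(hits))
  ha <- rep(NA_real_, nrow(hits))
  dha <- rep(NA_real_, nrow(hits))
  # index hydrogens by residue for the optional explicit-H check
  hyd <- atoms_all[atoms_all$is_h, , drop = FALSE]
  for (k in seq_len(nrow(hits))) {
    i <- hits[k, 1L]; j <- hits[k, 2L]
    D <- c(don$x[i], don$y[i], don$z[i])
    A <- c(acc$x[j], acc$y[j], acc$z[j])
    # donor-acceptor-antecedent angle at the acceptor
    ok <- TRUE
    ante <- acc$antecedent[j]
    if (!is.na(ante)) {
      sel <- atoms_all$chain == acc$chain[j] &
        atoms_all$resno == acc$resno[j] &
        atoms_all$insert == acc$insert[j] & atoms_all$name == ante
      if (any(sel)) {
        AA <- c(atoms_all$x[sel][1L], atoms_all$y[sel][1L],
                atoms_all$z[sel][1L])
        ok <- .angle_deg(D, A, AA) >= min_angle
      }
    }
    if (ok && nrow(hyd) > 0L) {
      hs <- hyd[hyd$chain == don$chain[i] & hyd$resno == don$resno[i] &
                  hyd$insert == don$insert[i], , drop = FALSE]
      if (nrow(hs) > 0L) {
        dh <- sqrt((hs$x - D[1])^2 + (hs$y - D[2])^2 + (hs$z - D[3])^2)
        hs <- hs[dh <= 1.15, , drop = FALSE]  # hydrogens bonded to donor
        if (nrow(hs) > 0L) {
          ok2 <- FALSE
          for (hh in seq_len(nrow(hs))) {
            H <- c(hs$x[hh], hs$y[hh], hs$z[hh])
            d_ha <- sqrt(sum((H - A)^2))
            a_dha <- .angle_deg(D, H, A)
            if (d_ha <= max_ha && a_dha >= min_angle) {
              ok2 <- TRUE
              ha[k] <- d_ha
              dha[k] <- a_dha
              break
            }
          }
          ok <- ok2
        }
      }
    }
    keep[k] <- ok
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  data.frame(
    donor_chain = don$chain[hits[, 1L]], donor_resno = don$resno[hits[, 1L]],
    donor_insert = don$insert[hits[, 1L]],
    donor_resid = don$resid[hits[, 1L]], donor_atom = don$name[hits[, 1L]],
    acceptor_chain = acc$chain[hits[, 2L]],
    acceptor_resno = acc$resno[hits[, 2L]],
    acceptor_insert = acc$insert[hits[, 2L]],
    acceptor_resid = acc$resid[hits[, 2L]],
    acceptor_atom = acc$name[hits[, 2L]],
    da_distance = dm[hits], ha_distance = ha[keep], dha_angle = dha[keep],
    stringsAsFactors = FALSE)
}

#' Detect protein-DNA hydrogen bonds
#'
#' Finds all hydrogen bonds across the protein-DNA interface in both
#' directions (protein donor to DNA acceptor and DNA donor to protein
#' acceptor) under the geometric criteria described above.
#'
#' @param cx a `pdna_complex`.
#' @param max_da maximum donor-acceptor distance, Angstrom.
#' @param max_ha maximum hydrogen-acceptor distance (only checked when the
#'   donor's hydrogen is present in the structure), Angstrom.
#' @param min_angle minimum donor-acceptor-antecedent and D-H-A angle,
#'   degrees.
#' @param chemistry donor/acceptor dictionary; see [hbond_chemistry()].
#' @return Data frame of class `hbond_list`, one row per bond, with donor
#'   and acceptor identities, `da_distance`, optional `ha_distance` /
#'   `dha_angle`, the side flag `protein_is_donor`, and `dna_moiety`
#'   (`base`, `sugar` or `phosphate` of the DNA partner atom).
#' @export
detect_hbonds <- function(cx, max_da = 3.9, max_ha = 2.5, min_angle = 90,
                          chemistry = hbond_chemistry()) {
  pa <- .protein_atoms(cx)
  da <- .dna_atoms(cx)
  all_atoms <- cx$atoms
  fwd <- .hb_pairs(.role_atoms(pa, chemistry, "donor"),
                   .role_atoms(da, chemistry, "acceptor"),
                   all_atoms, max_da, max_ha, min_angle)
  rev <- .hb_pairs(.role_atoms(da, chemistry, "donor"),
                   .role_atoms(pa, chemistry, "acceptor"),
                   all_atoms, max_da, max_ha, min_angle)
  if (!is.null(fwd)) fwd$protein_is_donor <- rep(TRUE, nrow(fwd))
  if (!is.null(rev)) rev$protein_is_donor <- rep(FALSE, nrow(rev))
  out <- rbind(fwd, rev)
  if (is.null(out)) {
    out <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_insert = character(), donor_resid = character(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(),
                      acceptor_insert = character(),
                      acceptor_resid = character(),
                      acceptor_atom = character(), da_distance = numeric(),
                      ha_distance = numeric(), dha_angle = numeric(),
                      protein_is_donor = logical(),
                      stringsAsFactors = FALSE)
  }
  # DNA partner moiety
  dna_res <- ifelse(out$protein_is_donor, out$acceptor_resid,
                    out$donor_resid)
  dna_atm <- ifelse(out$protein_is_donor, out$acceptor_atom,
                    out$donor_atom)
  out$dna_moiety <- if (nrow(out) > 0L)
    mapply(classify_dna_atom, dna_res, dna_atm, USE.NAMES = FALSE)
  else character()
  rownames(out) <- NULL
  class(out) <- c("hbond_list", "data.frame")
  out
}

#' Write a hydrogen-bond list as TSV
#'
#' @param bonds an `hbond_list` from [detect_hbonds()].
#' @param path output path.
#' @export
write_hbonds <- function(bonds, path) {
  utils::write.table(as.data.frame(bonds), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Count protein-DNA base hydrogen bonds (pbhb)
#'
#' Number of detected bonds whose DNA-side partner atom belongs to a
#' nucleobase (moiety `base`), as opposed to sugar or phosphate.
#'
#' @param bonds an `hbond_list` from [detect_hbonds()].
#' @return Integer count.
#' @export
count_pbhb <- function(bonds) {
  sum(bonds$dna_moiety == "base")
}

# Maximum bipartite matching (Kuhn's augmenting-path algorithm) on the tiny
# per-residue bond graphs; adj is a list: for each left node, integer vector
# of right neighbors.
.max_matching <- function(adj, n_right) {
  match_r <- rep(0L, n_right)
  size <- 0L
  for (u in seq_along(adj)) {
    seen <- rep(FALSE, n_right)
    dfs <- function(u) {
      for (v in adj[[u]]) {
        if (!seen[v]) {
          seen[v] <<- TRUE
          if (match_r[v] == 0L || dfs(match_r[v])) {
            match_r[v] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (dfs(u)) size <- size + 1L
  }
  size
}

#' Count bidentate hydrogen-bonding residues
#'
#' A protein residue is bidentate when its base-moiety hydrogen bonds
#' include at least two bonds that share no protein atom and no DNA atom
#' (maximum matching of size >= 2 on the residue's protein-atom x DNA-atom
#' bond graph).  By default the two bonds may reach different bases; set
#' `same_base_only = TRUE` to require a single base partner.
#'
#' @param bonds an `hbond_list` from [detect_hbonds()].
#' @param same_base_only require both bonds to land on the same nucleotide.
#' @return Integer count of bidentate residues.
#' @export
count_bidentate <- function(bonds, same_base_only = FALSE) {
  b <- bonds[bonds$dna_moiety == "base", , drop = FALSE]
  if (nrow(b) == 0L) return(0L)
  p_chain <- ifelse(b$protein_is_donor, b$donor_chain, b$acceptor_chain)
  p_resno <- ifelse(b$protein_is_donor, b$donor_resno, b$acceptor_resno)
  p_ins <- ifelse(b$protein_is_donor, b$donor_insert, b$acceptor_insert)
  p_atom <- ifelse(b$protein_is_donor, b$donor_atom, b$acceptor_atom)
  d_chain <- ifelse(b$protein_is_donor, b$acceptor_chain, b$donor_chain)
  d_resno <- ifelse(b$protein_is_donor, b$acceptor_resno, b$donor_resno)
  d_atom <- ifelse(b$protein_is_donor, b$acceptor_atom, b$donor_atom)
  res_key <- paste(p_chain, p_resno, p_ins)
  grp_key <- if (same_base_only) paste(res_key, d_chain, d_resno) else res_key
  n_bident <- 0L
  for (res in unique(res_key)) {
    found <- FALSE
    for (g in unique(grp_key[res_key == res])) {
      sel <- grp_key == g
      left <- factor(paste(p_atom[sel]))
      right <- factor(paste(d_chain[sel], d_resno[sel], d_atom[sel]))
      adj <- lapply(levels(left), function(l)
        unique(as.integer(right[left == l])))
      if (.max_matching(adj, nlevels(right)) >= 2L) {
        found <- TRUE
        break
      }
    }
    if (found) n_bident <- n_bident + 1L
  }
  n_bident
}
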