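# Structure input/output and chemical classification.
#
# The central container is the "pdna_complex": a flat atom table plus a
# per-chain classification (protein / dna) and, for DNA atoms, a moiety label
# (base / sugar / phosphate). Everything downstream (SASA, hydrogen bonds,
# the pair potential, RMSD) works off this container.

#' Standard residue and atom vocabularies
#'
#' Three-letter codes for the 20 standard amino acids, the residue names of
#' the four standard deoxyribonucleotides, and the DNA moiety membership used
#' throughout the package.
#'
#' @name vocabularies
#' @keywords internal
NULL

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.DNA_RES <- c("DA", "DC", "DG", "DT")

.WATER_RES <- c("HOH", "WAT", "DOD", "H2O", "TIP", "SOL")

# Moiety membership for DNA heavy atoms.  O5' travels with the phosphate
# group (and is kept as phosphate on 5'-terminal residues lacking P) so that
# base hydrogen-bond counts are reproducible under a fixed convention.
.DNA_PHOSPHATE <- c("P", "OP1", "OP2", "OP3", "O5'")
.DNA_SUGAR     <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O3'", "O2'")
.DNA_BASE <- list(
  DA = c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
  DG = c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
  DC = c("N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
  DT = c("N1", "C2", "O2", "N3", "C4", "O4", "C5", "C7", "C6")
)

# DNA backbone heavy atoms entering the backbone RMSD (sugar ring atoms
# C1'/C2'/O4' excluded by convention).
.DNA_BACKBONE <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "C3'", "O3'")

.stop_tfdnaqa <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tfdnaqa_error", "error")))
}

#' Construct a protein-DNA complex object
#'
#' Low-level constructor used by [read_complex()] and the fixture builders.
#' `atoms` is a data frame with one row per atom and columns `serial`,
#' `name`, `elem`, `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`,
#' `occ`, `alt`, `is_h`.  Moiety labels for DNA heavy atoms are filled in
#' here.
#'
#' @param id character identifier for the complex.
#' @param atoms atom table (see Details).
#' @param chain_class named character vector mapping chain id to
#'   `"protein"`, `"dna"` or `"other"`.
#' @param require_both error unless at least one protein and one DNA chain
#'   are present (the validity condition for a dockable complex).
#' @return An object of class `pdna_complex`.
#' @export
new_complex <- function(id, atoms, chain_class, require_both = TRUE) {
  needed <- c("serial", "name", "elem", "resid", "chain", "resno", "insert",
              "x", "y", "z", "occ", "alt", "is_h")
  miss <- setdiff(needed, names(atoms))
  if (length(miss) > 0L)
    .stop_tfdnaqa(paste0("atom table missing columns: ",
                         paste(miss, collapse = ", ")),
                  "tfdnaqa_format_error")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    .stop_tfdnaqa("non-finite atom coordinates", "tfdnaqa_format_error")
  if (!all(atoms$chain %in% names(chain_class)))
    .stop_tfdnaqa("every atom must belong to a classified chain",
                  "tfdnaqa_format_error")
  if (require_both) {
    if (!any(chain_class == "protein") || !any(chain_class == "dna"))
      .stop_tfdnaqa(
        "complex must contain at least one protein and one DNA chain",
        "tfdnaqa_composition_error")
  }
  atoms$moiety <- NA_character_
  is_dna <- chain_class[atoms$chain] == "dna" & !atoms$is_h
  if (any(is_dna)) {
    atoms$moiety[is_dna] <- mapply(classify_dna_atom,
                                   atoms$resid[is_dna],
                                   atoms$name[is_dna],
                                   USE.NAMES = FALSE)
  }
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, chain_class = chain_class),
            class = "pdna_complex")
}

#' @export
print.pdna_complex <- function(x, ...) {
  cc <- table(factor(x$chain_class, levels = c("protein", "dna", "other")))
  cat(sprintf("<pdna_complex '%s': %d atoms, %d protein / %d DNA chain(s)>\n",
              x$id, nrow(x$atoms), cc[["protein"]], cc[["dna"]]))
  invisible(x)
}

#' Classify a chain from its residue composition
#'
#' A chain is `dna` if at least 90% of its residues are standard
#' deoxyribonucleotides (after applying the `alias` table, e.g.
#' `c("5MC" = "DC")`), `protein` if at least 90% are standard amino acids,
#' and `other` otherwise.
#'
#' @param residue_names character vector of 3-letter codes, one per residue
#'   (a multiset; repeats count).
#' @param alias named character vector mapping modified residue codes to
#'   standard codes. Default empty (strict).
#' @return `"protein"`, `"dna"` or `"other"`.
#' @export
classify_chain <- function(residue_names, alias = character()) {
  stopifnot(length(residue_names) > 0L)
  rn <- residue_names
  hit <- rn %in% names(alias)
  rn[hit] <- alias[rn[hit]]
  f_dna <- mean(rn %in% .DNA_RES)
  f_pro <- mean(rn %in% .AA3)
  if (f_dna >= 0.9) "dna" else if (f_pro >= 0.9) "protein" else "other"
}

#' Classify a DNA heavy atom into base, sugar or phosphate moiety
#'
#' Phosphate is `P`, `OP1`, `OP2` (`OP3` on 5'-phosphorylated termini) plus
#' `O5'`; sugar is the primed carbons and oxygens other than `O5'`; base is
#' the ring and exocyclic atoms of the nucleobase.
#'
#' @param residue_name DNA residue code (`DA`, `DC`, `DG`, `DT`).
#' @param atom_name PDB atom name, e.g. `"C1'"`.
#' @return `"base"`, `"sugar"` or `"phosphate"`.
#' @export
classify_dna_atom <- function(residue_name, atom_name) {
  if (atom_name %in% .DNA_PHOSPHATE) return("phosphate")
  if (atom_name %in% .DNA_SUGAR) return("sugar")
  base_set <- .DNA_BASE[[residue_name]]
  if (!is.null(base_set) && atom_name %in% base_set) return("base")
  .stop_tfdnaqa(sprintf("unknown DNA atom %s in residue %s",
                        atom_name, residue_name),
                "tfdnaqa_classification_error")
}

.elem_from_name <- function(name) {
  # PDB atom names: strip leading digits (e.g. "1HB"), element is the
  # leading alphabetic field; two-letter elements are rare in protein/DNA
  # work so default to the first letter unless it forms a known pair.
  s <- sub("^[0-9']*", "", name)
  first <- toupper(substr(s, 1L, 1L))
  ifelse(first == "", "X", first)
}

#' Read a protein-DNA complex from a PDB file
#'
#' Parses a PDB file (via bio3d), removes waters, resolves alternate
#' locations (highest occupancy wins; ties go to altloc `A`), classifies
#' chains by residue composition and drops chains and residues that are
#' neither standard protein nor standard DNA.  Hydrogens are retained but
#' flagged (`is_h`).
#'
#' @param path path to a PDB file.
#' @param id complex identifier; defaults to the file name without extension.
#' @param alias modified-residue alias table passed to [classify_chain()]
#'   and applied to residue names (e.g. `c("5MC" = "DC")`).
#' @return A [new_complex()] object.
#' @export
read_complex <- function(path, id = NULL, alias = character()) {
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                     rm.alt = FALSE)),
    error = function(e) .stop_tfdnaqa(
      sprintf("cannot parse PDB file '%s': %s", path, conditionMessage(e)),
      "tfdnaqa_format_error"))
  at <- pdb$atom
  if (nrow(at) == 0L)
    .stop_tfdnaqa("PDB file contains no atoms", "tfdnaqa_format_error")
  at$chain[is.na(at$chain) | at$chain == ""] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # apply residue aliases, drop waters
  hit <- at$resid %in% names(alias)
  at$resid[hit] <- alias[at$resid[hit]]
  at <- at[!(at$resid %in% .WATER_RES), , drop = FALSE]
  if (nrow(at) == 0L)
    .stop_tfdnaqa("no non-water atoms in file", "tfdnaqa_composition_error")
  # altloc resolution: highest occupancy, ties to 'A' (then lexicographic)
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$o, at$alt != "A", at$alt)
    at <- at[ord, , drop = FALSE]
    key <- key[ord]
    at <- at[!duplicated(key), , drop = FALSE]
    at <- at[order(at$chain, at$resno, at$insert, at$eleno), , drop = FALSE]
  }
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .elem_from_name(at$elety[bad])
  elem <- toupper(elem)
  is_h <- elem %in% c("H", "D")
  # chain classification on heavy-atom residue multiset
  chains <- unique(at$chain)
  chain_class <- vapply(chains, function(ch) {
    sel <- at$chain == ch & !is_h
    res <- unique(paste(at$resno[sel], at$insert[sel], at$resid[sel],
                        sep = "\r"))
    classify_chain(sub("^.*\r", "", res))
  }, character(1))
  names(chain_class) <- chains
  keep_chain <- names(chain_class)[chain_class %in% c("protein", "dna")]
  if (length(keep_chain) == 0L ||
      !any(chain_class == "protein") || !any(chain_class == "dna"))
    .stop_tfdnaqa(
      sprintf("complex '%s' lacks a protein and/or a DNA chain", id),
      "tfdnaqa_composition_error")
  keep <- at$chain %in% keep_chain
  # within kept chains, drop residues that are not standard for the chain
  cls <- chain_class[at$chain]
  keep <- keep & ((cls == "protein" & at$resid %in% .AA3) |
                  (cls == "dna" & at$resid %in% .DNA_RES))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]; is_h <- is_h[keep]
  atoms <- data.frame(serial = at$eleno, name = at$elety, elem = elem,
                      resid = at$resid, chain = at$chain, resno = at$resno,
                      insert = at$insert, x = at$x, y = at$y, z = at$z,
                      occ = at$o, alt = at$alt, is_h = is_h,
                      stringsAsFactors = FALSE)
  new_complex(id, atoms, chain_class[keep_chain])
}

#' Write a complex to a PDB file
#'
#' @param cx a `pdna_complex`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_complex <- function(cx, path) {
  a <- cx$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid, eleno = a$serial,
                   elety = a$name, chain = a$chain, insert = a$insert,
                   alt = a$alt, o = a$occ, b = rep(0, nrow(a)),
                   elesy = a$elem)
  invisible(path)
}

#' Extract the protein or DNA component of a complex
#'
#' Coordinates are left unchanged; only atoms of chains with the requested
#' classification are retained.
#'
#' @param cx a `pdna_complex`.
#' @param which `"protein"` or `"dna"`.
#' @return A `pdna_complex` containing only the requested component.
#' @export
extract_component <- function(cx, which = c("protein", "dna")) {
  which <- match.arg(which)
  keep_chain <- names(cx$chain_class)[cx$chain_class == which]
  atoms <- cx$atoms[cx$atoms$chain %in% keep_chain, , drop = FALSE]
  new_complex(paste0(cx$id, "_", which), atoms,
              cx$chain_class[keep_chain], require_both = FALSE)
}

# Heavy-atom views used throughout the feature modules.
.protein_atoms <- function(cx, heavy = TRUE) {
  sel <- cx$chain_class[cx$atoms$chain] == "protein"
  if (heavy) sel <- sel & !cx$atoms$is_h
  cx$atoms[sel, , drop = FALSE]
}

.dna_atoms <- function(cx, heavy = TRUE) {
  sel <- cx$chain_class[cx$atoms$chain] == "dna"
  if (heavy) sel <- sel & !cx$atoms$is_h
  cx$atoms[sel, , drop = FALSE]
}

#' Chain classification report
#'
#' One row per chain with its classification and residue count; writable as
#' TSV with [utils::write.table()].
#'
#' @param cx a `pdna_complex`.
#' @param path optional path; when given the report is written as TSV.
#' @return Data frame with columns `chain`, `class`, `n_residues`, `n_atoms`.
#' @export
classification_report <- function(cx, path = NULL) {
  a <- cx$atoms
  out <- do.call(rbind, lapply(names(cx$chain_class), function(ch) {
    sel <- a$chain == ch
    data.frame(chain = ch, class = unname(cx$chain_class[ch]),
               n_residues = length(unique(paste(a$resno[sel], a$insert[sel]))),
               n_atoms = sum(sel), stringsAsFactors = FALSE)
  }))
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}
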