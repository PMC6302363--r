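# Distance-dependent atomic protein-DNA statistical potential.
#
# This is an inverse-Boltzmann potential with a finite-ideal-gas reference
# state in the DFIRE lineage: u(i,j,r) = -ln[(N_obs + q) / (N_ref + q)],
# where the reference count in bin r scales the last-bin observation by
# (r / r_last)^alpha.  It fills the atomic-potential feature slot of the
# quality-assessment model and can be derived from any set of complexes;
# externally computed energies can be ingested instead (see
# [load_external_scores()]).

.bin_centers <- function(dr, r_cut) {
  edges <- seq(0, r_cut, by = dr)
  (edges[-1] + edges[-length(edges)]) / 2
}

.atom_type <- function(atoms, typing) {
  switch(typing,
         exact = paste(atoms$resid, atoms$name, sep = "."),
         residue = atoms$resid,
         .stop_tfdnaqa(paste0("unknown typing '", typing, "'"),
                       "tfdnaqa_config_error"))
}

# Pooled pair counts for one complex: matrix over (type pair, bin).
# Pair keys are stored with the two types in sorted order so the table is
# symmetric by construction.
.pair_counts <- function(cx, dr, r_cut, typing) {
  pa <- .protein_atoms(cx)
  da <- .dna_atoms(cx)
  tp <- .atom_type(pa, typing)
  td <- .atom_type(da, typing)
  nb <- as.integer(round(r_cut / dr))
  d2 <- outer(pa$x, da$x, "-")^2 + outer(pa$y, da$y, "-")^2 +
    outer(pa$z, da$z, "-")^2
  hit <- which(d2 <= r_cut^2 & d2 > 0, arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(list(keys = character(), bins = integer(), nb = nb))
  d <- sqrt(d2[hit])
  bins <- pmin(pmax(ceiling(d / dr), 1L), nb)
  t1 <- tp[hit[, 1L]]
  t2 <- td[hit[, 2L]]
  keys <- ifelse(t1 <= t2, paste(t1, t2, sep = "|"),
                 paste(t2, t1, sep = "|"))
  list(keys = keys, bins = bins, nb = nb)
}

#' Build a potential table from raw pair counts
#'
#' Core inverse-Boltzmann step, exposed separately so the energy model can
#' be tested against closed-form expectations.  `obs` is a (pair-type x
#' bin) count matrix; the reference count for pair t in bin b is
#' `obs[t, nb] * (r_b / r_nb)^alpha` (uniform bin widths), and the energy is
#' `-log((obs + q) / (ref + q))` in RT units.
#'
#' @param obs numeric matrix, rows = type pairs (rownames `"a|b"` with the
#'   two types sorted), columns = distance bins.
#' @param dr bin width, Angstrom.
#' @param r_cut distance cutoff, Angstrom (`dr` must divide it).
#' @param alpha reference-state distance exponent.
#' @param pseudocount nonnegative regularizer `q`.
#' @return Object of class `potential_table`.
#' @export
potential_from_counts <- function(obs, dr = 0.5, r_cut = 15, alpha = 1.61,
                                  pseudocount = 0.5) {
  nb <- as.integer(round(r_cut / dr))
  if (abs(nb * dr - r_cut) > 1e-9)
    .stop_tfdnaqa("bin width must divide the cutoff",
                  "tfdnaqa_config_error")
  if (ncol(obs) != nb)
    .stop_tfdnaqa("count matrix has wrong number of bins",
                  "tfdnaqa_config_error")
  centers <- .bin_centers(dr, r_cut)
  scale_r <- (centers / centers[nb])^alpha
  ref <- outer(obs[, nb], scale_r)
  u <- -log((obs + pseudocount) / (ref + pseudocount))
  dimnames(u) <- list(rownames(obs), NULL)
  structure(list(energies = u, dr = dr, r_cut = r_cut, alpha = alpha,
                 pseudocount = pseudocount, centers = centers),
            class = "potential_table")
}

#' Derive a statistical potential from training complexes
#'
#' Pools protein-DNA heavy-atom pair counts over the training complexes and
#' applies the inverse-Boltzmann transform of [potential_from_counts()].
#' Atom typing is `(residue, atom name)` by default, with a coarse
#' residue-level fallback for sparse training sets.
#'
#' @param training list of `pdna_complex` objects (>= 1).
#' @param dr,r_cut,alpha,pseudocount see [potential_from_counts()].
#' @param typing `"exact"` for (residue, atom-name) types or `"residue"`
#'   for the coarse residue-level alphabet.
#' @return Object of class `potential_table` (with `typing` recorded).
#' @export
derive_potential <- function(training, dr = 0.5, r_cut = 15, alpha = 1.61,
                             pseudocount = 0.5,
                             typing = c("exact", "residue")) {
  typing <- match.arg(typing)
  if (length(training) == 0L)
    .stop_tfdnaqa("empty training set", "tfdnaqa_derivation_error")
  nb <- as.integer(round(r_cut / dr))
  keys <- character()
  bins <- integer()
  for (cx in training) {
    pc <- .pair_counts(cx, dr, r_cut, typing)
    keys <- c(keys, pc$keys)
    bins <- c(bins, pc$bins)
  }
  if (length(keys) == 0L)
    .stop_tfdnaqa("no protein-DNA pairs within cutoff in training set",
                  "tfdnaqa_derivation_error")
  ukeys <- sort(unique(keys))
  obs <- matrix(0, nrow = length(ukeys), ncol = nb,
                dimnames = list(ukeys, NULL))
  tab <- table(factor(keys, levels = ukeys), factor(bins, levels = 1:nb))
  obs[] <- as.numeric(tab)
  pt <- potential_from_counts(obs, dr, r_cut, alpha, pseudocount)
  pt$typing <- typing
  pt
}

#' Score a complex with a potential table
#'
#' Sum of bin energies over all protein-DNA heavy-atom pairs within the
#' cutoff.  Pairs whose type was never observed during derivation are
#' skipped; the number of skipped pairs is attached as attribute
#' `n_skipped`.
#'
#' @param cx a `pdna_complex`.
#' @param table a `potential_table`.
#' @return Total energy in RT units (0 when no pair is within the cutoff),
#'   with attribute `n_skipped`.
#' @export
score_complex <- function(cx, table) {
  typing <- if (is.null(table$typing)) "exact" else table$typing
  pc <- .pair_counts(cx, table$dr, table$r_cut, typing)
  if (length(pc$keys) == 0L)
    return(structure(0, n_skipped = 0L))
  row <- match(pc$keys, rownames(table$energies))
  known <- !is.na(row)
  e <- sum(table$energies[cbind(row[known], pc$bins[known])])
  structure(as.numeric(e), n_skipped = sum(!known))
}

#' Serialize / read a potential table as plain text
#'
#' Long format TSV: `type_i`, `type_j`, `bin_low`, `bin_high`, `energy`,
#' with the table parameters in `#`-prefixed header lines.
#'
#' @param table a `potential_table`.
#' @param path file path.
#' @return `path` ([write_potential()]) or a `potential_table`
#'   ([read_potential()]).
#' @export
write_potential <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dr=%g r_cut=%g alpha=%g pseudocount=%g typing=%s",
                     table$dr, table$r_cut, table$alpha, table$pseudocount,
                     if (is.null(table$typing)) "exact" else table$typing),
             con)
  keys <- rownames(table$energies)
  parts <- strsplit(keys, "|", fixed = TRUE)
  nb <- ncol(table$energies)
  lo <- (seq_len(nb) - 1L) * table$dr
  for (i in seq_along(keys)) {
    writeLines(sprintf("%s\t%s\t%g\t%g\t%.10g", parts[[i]][1],
                       parts[[i]][2], lo, lo + table$dr,
                       table$energies[i, ]), con)
  }
  invisible(path)
}

#' @rdname write_potential
#' @export
read_potential <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")][1]
  get <- function(k) {
    m <- regmatches(hdr, regexpr(paste0(k, "=[^ ]+"), hdr))
    sub(paste0(k, "="), "", m)
  }
  dr <- as.numeric(get("dr")); r_cut <- as.numeric(get("r_cut"))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            header = FALSE, stringsAsFactors = FALSE)
  names(body) <- c("type_i", "type_j", "bin_low", "bin_high", "energy")
  keys <- paste(body$type_i, body$type_j, sep = "|")
  ukeys <- unique(keys)
  nb <- as.integer(round(r_cut / dr))
  u <- matrix(0, length(ukeys), nb, dimnames = list(ukeys, NULL))
  u[cbind(match(keys, ukeys),
          as.integer(round(body$bin_low / dr)) + 1L)] <- body$energy
  structure(list(energies = u, dr = dr, r_cut = r_cut,
                 alpha = as.numeric(get("alpha")),
                 pseudocount = as.numeric(get("pseudocount")),
                 centers = .bin_centers(dr, r_cut), typing = get("typing")),
            class = "potential_table")
}

#' Load externally computed per-model energies
#'
#' Two-column TSV (model id, energy), no header.  Lets users supply scores
#' from a published potential in place of the derived table; feature
#' assembly prefers an external value when one is present for the model.
#'
#' @param path TSV path.
#' @return Named numeric vector (may be empty).
#' @export
load_external_scores <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(numeric(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- numeric(length(lines))
  ids <- character(length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    # tolerate unicode minus signs from copy-pasted tables
    val <- suppressWarnings(as.numeric(gsub("−", "-", p[2])))
    if (length(p) < 2L || is.na(val))
      .stop_tfdnaqa(sprintf("malformed score row at line %d: '%s'",
                            i, lines[i]),
                    "tfdnaqa_parse_error")
    ids[i] <- p[1]
    out[i] <- val
  }
  stats::setNames(out, ids)
}
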