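# Fixture builders shared across test files.  All fixtures are generated
# in code; PDB files are written to tempdir() when a file is needed.

# Minimal hand-placed complex: one protein residue + one DNA residue with
# fully controlled geometry.  `atoms` is a list of lists with fields
# name, resid, chain, resno, xyz.
make_mini_complex <- function(atoms, id = "mini") {
  df <- do.call(rbind, lapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    el <- tfdnaqa:::.elem_from_name(a$name)
    data.frame(serial = i, name = a$name, elem = el, resid = a$resid,
               chain = a$chain, resno = a$resno, insert = "",
               x = a$xyz[1], y = a$xyz[2], z = a$xyz[3], occ = 1,
               alt = "", is_h = el %in% c("H", "D"),
               stringsAsFactors = FALSE)
  }))
  chains <- unique(df$chain)
  cc <- vapply(chains, function(ch)
    classify_chain(df$resid[df$chain == ch]), character(1))
  new_complex(id, df, cc, require_both = TRUE)
}

atomrec <- function(name, resid, chain, resno, xyz)
  list(name = name, resid = resid, chain = chain, resno = resno, xyz = xyz)

# A serine OG donor at distance `d` from a guanine O6 acceptor, with the
# acceptor antecedent C6 placed so the approach is head-on (angle 180).
ser_gua_fixture <- function(d = 2.9) {
  make_mini_complex(list(
    atomrec("N",  "SER", "A", 1, c(d + 2.5, 1.2, 0)),
    atomrec("CA", "SER", "A", 1, c(d + 1.8, 0.5, 1.0)),
    atomrec("CB", "SER", "A", 1, c(d + 1.4, 0.2, -0.4)),
    atomrec("OG", "SER", "A", 1, c(d, 0, 0)),
    atomrec("O",  "SER", "A", 1, c(d + 3.0, 2.0, 1.5)),
    atomrec("C",  "SER", "A", 1, c(d + 2.6, 1.9, 2.2)),
    atomrec("O6", "DG", "B", 1, c(0, 0, 0)),
    atomrec("C6", "DG", "B", 1, c(-1.23, 0, 0)),
    atomrec("N1", "DG", "B", 1, c(-1.9, 1.1, 0)),
    atomrec("C1'", "DG", "B", 1, c(-3.5, 3.0, 1.0)),
    atomrec("P",  "DG", "B", 1, c(-6.0, 5.0, 2.0)),
    atomrec("OP1", "DG", "B", 1, c(-6.8, 5.6, 1.1))))
}

# Standard small toy complex reused across files (cached per session).
toy_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_toy_complex(12, 12, 3, seed = 1)
    cache
  }
})

# Write a tiny PDB file from raw text lines (for parser edge cases).
write_pdb_lines <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.0, alt = "", elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("[0-9']", "", name), 1, 1)
  # PDB fixed columns; atom names of <4 chars start in column 14
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, alt, resid, chain, resno, x, y, z, occ, 0, elem)
}
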