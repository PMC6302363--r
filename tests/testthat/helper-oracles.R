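# Independent oracles used across the suite.  These deliberately avoid the
# code paths they check: closed-form geometry, quaternion superposition,
# and naive double-loop enumerations.

# Exposed area of sphere 1 (radius R1) partially buried by sphere 2
# (radius R2) at center distance d: full sphere minus the buried spherical
# cap, 2*pi*R1*h with h the cap height from the intersection plane.
two_sphere_exposed <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * R1^2)
  h <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h
}

# Horn's closed-form quaternion superposition: returns the optimal proper
# rotation (3x3) and post-fit RMSD for matched point sets.
quaternion_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  P <- sweep(ref, 2, colMeans(ref))
  Q <- sweep(mov, 2, colMeans(mov))
  S <- crossprod(Q, P)  # S[i,j] = sum mov_i * ref_j
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
    3, 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Q %*% t(R) - P)^2)))
  list(rotation = R, rmsd = rmsd)
}

# Naive double-loop potential scorer (no vectorized distance matrix).
brute_force_score <- function(cx, table) {
  pa <- tfdnaqa:::.protein_atoms(cx)
  da <- tfdnaqa:::.dna_atoms(cx)
  typing <- if (is.null(table$typing)) "exact" else table$typing
  tp <- tfdnaqa:::.atom_type(pa, typing)
  td <- tfdnaqa:::.atom_type(da, typing)
  nb <- ncol(table$energies)
  total <- 0
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(da))) {
      d <- sqrt((pa$x[i] - da$x[j])^2 + (pa$y[i] - da$y[j])^2 +
                  (pa$z[i] - da$z[j])^2)
      if (d > table$r_cut || d == 0) next
      b <- min(max(ceiling(d / table$dr), 1L), nb)
      key <- if (tp[i] <= td[j]) paste(tp[i], td[j], sep = "|")
             else paste(td[j], tp[i], sep = "|")
      row <- match(key, rownames(table$energies))
      if (!is.na(row)) total <- total + table$energies[row, b]
    }
  }
  as.numeric(total)
}

# Naive all-pairs hydrogen-bond detector (distance + acceptor-antecedent
# angle on heavy atoms), independent of detect_hbonds internals.
brute_force_hbonds <- function(cx, max_da = 3.9, min_angle = 90) {
  chem <- hbond_chemistry()
  at <- cx$atoms[!cx$atoms$is_h, , drop = FALSE]
  side <- unname(cx$chain_class[at$chain])
  n <- nrow(at)
  hits <- 0L
  pairs <- list()
  role <- function(i, what) {
    r <- chem[chem$resid == at$resid[i] & chem$atom == at$name[i], ]
    if (nrow(r) == 0L) return(FALSE)
    r[[what]][1]
  }
  ante_ok <- function(di, ai) {
    r <- chem[chem$resid == at$resid[ai] & chem$atom == at$name[ai], ]
    an <- r$antecedent[1]
    if (is.na(an)) return(TRUE)
    sel <- which(at$chain == at$chain[ai] & at$resno == at$resno[ai] &
                   at$insert == at$insert[ai] & at$name == an)
    if (length(sel) == 0L) return(TRUE)
    A <- c(at$x[ai], at$y[ai], at$z[ai])
    D <- c(at$x[di], at$y[di], at$z[di])
    AA <- c(at$x[sel[1]], at$y[sel[1]], at$z[sel[1]])
    v1 <- D - A; v2 <- AA - A
    ang <- acos(min(1, max(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
    ang >= min_angle
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (side[i] == side[j]) next
      if (!(side[i] == "protein" && side[j] == "dna")) next
      for (dir in 1:2) {
        di <- if (dir == 1) i else j
        ai <- if (dir == 1) j else i
        if (!isTRUE(role(di, "donor")) || !isTRUE(role(ai, "acceptor")))
          next
        d <- sqrt((at$x[di] - at$x[ai])^2 + (at$y[di] - at$y[ai])^2 +
                    (at$z[di] - at$z[ai])^2)
        if (d > max_da) next
        if (!ante_ok(di, ai)) next
        pairs[[length(pairs) + 1L]] <-
          paste(at$chain[di], at$resno[di], at$name[di],
                at$chain[ai], at$resno[ai], at$name[ai])
      }
    }
  }
  unlist(pairs)
}

# Confusion counts from raw (predicted-positive, actually-positive) pairs.
counts_from_raw <- function(pred_pos, actual_pos) {
  confusion_counts(TP = sum(pred_pos & actual_pos),
                   TN = sum(!pred_pos & !actual_pos),
                   FP = sum(pred_pos & !actual_pos),
                   FN = sum(!pred_pos & actual_pos))
}

mcc_from_scores <- function(quality_scores, labels, cutoff = 0.5) {
  mcc(counts_from_raw(quality_scores < cutoff, labels == 1))
}
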