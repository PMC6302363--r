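test_that("the B-DNA builder produces a canonical duplex", {
  d <- build_bdna("ACGT")
  expect_equal(length(unique(paste(d$atoms$chain, d$atoms$resno))), 8L)
  expect_setequal(unique(d$atoms$chain), c("B", "C"))
  # successive intra-strand phosphate spacing near the B-form value
  for (ch in c("B", "C")) {
    p <- d$atoms[d$atoms$name == "P" & d$atoms$chain == ch, ]
    p <- p[order(p$resno), ]
    pp <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
    expect_true(all(abs(pp - 7.0) < 0.3))
  }
  # second strand is the reverse complement
  chB <- d$atoms[d$atoms$chain == "C", ]
  seqB <- chB$resid[!duplicated(chB$resno)][order(unique(chB$resno))]
  expect_equal(paste(sub("D", "", seqB), collapse = ""), "ACGT" |>
                 strsplit("") |> unlist() |> rev() |>
                 (\(x) c(A = "T", C = "G", G = "C", T = "A")[x])() |>
                 paste(collapse = ""))
  # 5'-terminal residues carry no phosphate but keep O5'
  for (ch in c("B", "C")) {
    first <- d$atoms[d$atoms$chain == ch & d$atoms$resno == 1, ]
    expect_false(any(first$name %in% c("P", "OP1", "OP2")))
    expect_true("O5'" %in% first$name)
  }
  expect_error(build_bdna("ACXT"), class = "tfdnaqa_sequence_error")
  expect_error(build_bdna("ACG"), class = "tfdnaqa_sequence_error")
})

test_that("Watson-Crick pairing geometry is hydrogen-bond plausible", {
  d <- build_bdna("GGGG")
  a <- d$atoms
  # G N1 (donor) to C N3 (acceptor) across the first pair
  n1 <- unlist(a[a$chain == "B" & a$resno == 1 & a$name == "N1",
                 c("x", "y", "z")])
  n3 <- unlist(a[a$chain == "C" & a$resno == 4 & a$name == "N3",
                 c("x", "y", "z")])
  expect_lt(sqrt(sum((n1 - n3)^2)), 3.4)
  expect_gt(sqrt(sum((n1 - n3)^2)), 2.4)
})

test_that("toy complexes give contacting or separated interfaces on demand", {
  cx <- build_toy_complex(12, 12, 3, seed = 1)
  expect_s3_class(cx, "pdna_complex")
  expect_gte(count_pbhb(detect_hbonds(cx)), 1L)
  sep <- build_toy_complex(12, 12, 30, seed = 1)
  expect_equal(compute_pdca(sep, n_points = 240), 0, tolerance = 1e-6)
  expect_equal(count_pbhb(detect_hbonds(sep)), 0L)
  # reproducibility
  again <- build_toy_complex(12, 12, 3, seed = 1)
  expect_identical(cx$atoms, again$atoms)
  other <- build_toy_complex(12, 12, 3, seed = 2)
  expect_false(identical(cx$atoms$x, other$atoms$x))
})

test_that("probe residues create the intended hydrogen-bond patterns", {
  arg <- build_toy_complex(12, 12, 3, seed = 4, probe = "ARG")
  expect_gte(count_bidentate(detect_hbonds(arg)), 1L)
  lys <- build_toy_complex(12, 12, 3, seed = 4, probe = "LYS")
  hb <- detect_hbonds(lys)
  expect_gte(nrow(hb), 1L)
  expect_true("NZ" %in% hb$donor_atom)
})

test_that("decoys keep the protein fixed and report exact RMSDs", {
  cx <- build_toy_complex(10, 10, 3, seed = 1)
  # zero-magnitude perturbations: RMSD identically 0
  ds0 <- generate_decoys(cx, decoy_spec(n_decoys = 5, max_translation = 0,
                                        max_rotation = 0, seed = 2,
                                        near_native_fraction_target = 0))
  expect_equal(ds0$manifest$rmsd, rep(0, 5), tolerance = 1e-9)
  # translation-only: RMSD equals the applied displacement magnitude
  dst <- generate_decoys(cx, decoy_spec(n_decoys = 10, max_translation = 5,
                                        max_rotation = 0, seed = 3,
                                        near_native_fraction_target = 0))
  sel <- cx$chain_class[cx$atoms$chain] == "dna"
  for (k in seq_along(dst$decoys)) {
    dd <- dst$decoys[[k]]$atoms
    disp <- c(dd$x[sel][1] - cx$atoms$x[sel][1],
              dd$y[sel][1] - cx$atoms$y[sel][1],
              dd$z[sel][1] - cx$atoms$z[sel][1])
    expect_equal(dst$manifest$rmsd[k], sqrt(sum(disp^2)),
                 tolerance = 1e-9)
    # protein untouched
    expect_identical(dd[dd$chain == "A", c("x", "y", "z")],
                     cx$atoms[cx$atoms$chain == "A", c("x", "y", "z")])
  }
  # seed-pinned reproducibility
  again <- generate_decoys(cx, decoy_spec(n_decoys = 10,
                                          max_translation = 5,
                                          max_rotation = 0, seed = 3,
                                          near_native_fraction_target = 0))
  expect_identical(dst$manifest, again$manifest)
})

test_that("default decoy sets straddle the 3-Angstrom boundary", {
  cx <- build_toy_complex(10, 10, 3, seed = 1)
  ds <- generate_decoys(cx, decoy_spec(n_decoys = 100, seed = 5))
  expect_gte(sum(ds$manifest$label == 1), 1L)
  expect_gte(sum(ds$manifest$label == 0), 1L)
  expect_equal(ds$manifest$label, as.integer(ds$manifest$rmsd <= 3))
})

test_that("synthetic feature datasets honor their spec", {
  d0 <- generate_feature_dataset(feature_spec(n_pos = 0, n_neg = 50))
  expect_true(all(d0$y == 0))
  expect_equal(nrow(d0$X), 50)
  expect_error(feature_spec(covariance = matrix(c(1, 2, 0, 0,
                                                  2, 1, 0, 0,
                                                  0, 0, 1, 0,
                                                  0, 0, 0, 1), 4, 4)),
               class = "tfdnaqa_spec_error")
  d1 <- generate_feature_dataset(feature_spec(seed = 9))
  d2 <- generate_feature_dataset(feature_spec(seed = 9))
  expect_identical(d1, d2)
  expect_equal(nrow(d1$X), 2000)
  expect_equal(mean(d1$y), 0.076)
})

test_that("4-SD per-feature separation leaves near-zero Bayes error", {
  # closed-form single-feature error, then empirical on a large draw
  expect_lt(pnorm(-2), 0.03)
  d <- generate_feature_dataset(feature_spec(n_pos = 1000, n_neg = 1000,
                                             seed = 13))
  # optimal rule for equal spherical Gaussians: sign of sum of features
  err <- mean((rowSums(d$X) > 0) != (d$y == 1))
  expect_lt(err, 0.03)
})
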