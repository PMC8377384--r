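test_that("property tables are standardized across the 20 amino acids", {
  for (nm in aa_property_names()) {
    tab <- aa_property(nm)
    expect_equal(nrow(tab), 20L)
    expect_lt(abs(mean(tab$normalized)), 1e-10)
    expect_lt(abs(sqrt(mean(tab$normalized^2)) - 1), 1e-10)
    v <- aa_property_vector(nm)
    expect_identical(unname(v[["X"]]), 0)
  }
})

test_that("encoder dimensional contracts hold at defaults and additively", {
  s <- random_protein(60)
  pssm <- pseudo_pssm(s)
  expect_length(encode_pseaac(s, lambda = 11), 31L)
  expect_length(encode_psepssm(pssm, xi = 9), 200L)
  expect_length(encode_rsiv(s), 197L)
  expect_length(encode_ad(s, lag = 11), 231L)
  v <- encode_protein(s, pssm)
  expect_length(v, 659L)
  # additivity of the contract at a non-default configuration
  cfg <- encoder_config(lambda = 0, xi = 0, lag = 1)
  expect_length(encode_protein(s, pssm, cfg), 20L + 20L + 197L + 21L)
  # naming contract
  expect_length(unique(names(v)), 659L)
  expect_true(all(grepl("^(pseaac|psepssm|rsiv|ad)_", names(v))))
})

test_that("pseudo amino acid composition matches its closed-form cases", {
  # homopolymer: all correlation factors vanish, all mass on one slot
  v <- encode_pseaac(strrep("A", 10), lambda = 1)
  expect_equal(unname(v[["pseaac_comp_A"]]), 1)
  expect_equal(unname(v[["pseaac_theta_1"]]), 0)
  expect_equal(sum(v != 0), 1L)
  # explicit short-sequence oracle
  v <- encode_pseaac("ACDCACDC", lambda = 2, w = 0.05)
  expect_equal(unname(v), oracle_pseaac("ACDCACDC", lambda = 2, w = 0.05),
               tolerance = 1e-12)
})

test_that("pseudo amino acid composition is a simplex vector on random input", {
  set.seed(101)
  for (i in 1:25) {
    s <- random_protein(sample(13:70, 1), include_x = (i %% 5 == 0))
    v <- encode_pseaac(s, lambda = 11)
    expect_true(all(v >= 0))
    expect_lt(abs(sum(v) - 1), 1e-9)
  }
  expect_error(encode_pseaac("ACDE", lambda = 11), "too short")
})

test_that("pseudo-PSSM handles degenerate rows and matches the literal oracle", {
  const <- matrix(5, nrow = 15, ncol = 20)
  expect_equal(unname(encode_psepssm(const, xi = 9)), rep(0, 200))

  set.seed(11)
  m <- matrix(sample(-8:8, 240, replace = TRUE), 12, 20)
  expect_equal(unname(encode_psepssm(m, xi = 3)), oracle_psepssm(m, xi = 3),
               tolerance = 1e-12)

  expect_error(encode_psepssm(m, xi = 12), "too short")
  expect_error(encode_psepssm(m, xi = 3, sequence = strrep("A", 10)), "10 residues")
  expect_error(encode_psepssm(m[, 1:19], xi = 3), "20 score columns")
})

test_that("reduced sequence and index-vector encoder matches enumerated counts", {
  # single-class homopolymer: G is in class 1
  v <- encode_rsiv("GGGG")
  expect_equal(unname(v[["rsiv_class_1"]]), 1)
  expect_equal(sum(v[grep("^rsiv_class_", names(v))] != 0), 1L)
  expect_equal(unname(v[["rsiv_di_1_1"]]), 1)
  expect_equal(sum(v[grep("^rsiv_di_", names(v))] != 0), 1L)
  expect_true(all(v[grep("^rsiv_tr_", names(v))] == 0))

  # hand-enumerated: A|R|N|D|C|Q -> classes 1,5,4,6,7,4; adjacent pairs
  # (1,5),(5,4),(4,6),(6,7),(7,4), each contributing 1/5
  v <- encode_rsiv("ARNDCQ")
  expect_equal(unname(v[["rsiv_di_1_5"]]), 1 / 5)
  expect_equal(unname(v[["rsiv_di_5_4"]]), 1 / 5)
  expect_equal(unname(v[["rsiv_tr_4_6"]]), 1 / 5)
  expect_equal(unname(v[["rsiv_tr_4_7"]]), 1 / 5)
  expect_equal(unname(v), oracle_rsiv("ARNDCQ"), tolerance = 1e-12)

  expect_error(encode_rsiv("A"), "too short")
})

test_that("autocorrelation descriptors match conventions and the literal oracle", {
  # constant signal: Moran and Geary collapse to 0, Moreau-Broto to P'(res)^2
  v <- encode_ad(strrep("W", 20), lag = 3)
  expect_true(all(v[grep("^ad_(ma|ga)_", names(v))] == 0))
  w_hyd <- aa_property_vector("hydrophobicity")[["W"]]
  expect_equal(unname(v[["ad_mba_hydrophobicity_2"]]), w_hyd^2)

  set.seed(12)
  s <- random_protein(15)
  expect_equal(unname(encode_ad(s, lag = 4)), oracle_ad(s, lag = 4),
               tolerance = 1e-12)
  expect_error(encode_ad(s, lag = 15), "too short")
})

test_that("autocorrelation descriptors respect their analytic ranges", {
  set.seed(13)
  for (i in 1:20) {
    v <- encode_ad(random_protein(sample(13:60, 1)), lag = 11)
    expect_true(all(v[grep("^ad_ga_", names(v))] >= 0))
    ma <- v[grep("^ad_ma_", names(v))]
    expect_true(all(ma >= -1 - 0.05 & ma <= 1 + 0.05))
  }
})

test_that("composition blocks are permutation-invariant, order blocks are not", {
  set.seed(14)
  s <- random_protein(40)
  sp <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  comp_cols <- function(v) v[grep("^(pseaac_comp_|rsiv_)", names(v))]
  v1 <- suppressWarnings(encode_protein(s))
  v2 <- suppressWarnings(encode_protein(sp))
  # amino-acid and index-vector compositions identical under permutation
  expect_equal(v1[grep("^rsiv_iv_", names(v1))], v2[grep("^rsiv_iv_", names(v2))])
  expect_equal(v1[grep("^rsiv_class_", names(v1))], v2[grep("^rsiv_class_", names(v2))])
  # raw composition counts scale identically; pseaac slots share the theta
  # denominator, so compare ratios instead of absolute values
  c1 <- v1[grep("^pseaac_comp_", names(v1))]
  c2 <- v2[grep("^pseaac_comp_", names(v2))]
  expect_equal(c1 / sum(c1), c2 / sum(c2), tolerance = 1e-12)
})

test_that("all four encoders agree with the brute-force oracles on random input", {
  set.seed(15)
  for (i in 1:12) {
    L <- sample(13:60, 1)
    s <- random_protein(L)
    expect_equal(unname(encode_pseaac(s, lambda = 11)),
                 oracle_pseaac(s, lambda = 11), tolerance = 1e-10)
    expect_equal(unname(encode_rsiv(s)), oracle_rsiv(s), tolerance = 1e-10)
    expect_equal(unname(encode_ad(s, lag = 11)), oracle_ad(s, lag = 11),
                 tolerance = 1e-10)
    m <- matrix(sample(-10:10, L * 20, replace = TRUE), L, 20)
    expect_equal(unname(encode_psepssm(m, xi = 9)), oracle_psepssm(m, xi = 9),
                 tolerance = 1e-10)
  }
})

test_that("per-pair vectors concatenate protein vectors in pair order", {
  set.seed(16)
  prots <- tibble::tibble(id = c("pa", "pb"),
                          sequence = c(random_protein(50), random_protein(45)))
  pf <- suppressWarnings(encode_proteins(prots))
  expect_equal(dim(pf), c(2L, 660L))

  pairs <- tibble::tibble(id_a = c("pa", "pa", "pb"),
                          id_b = c("pb", "pa", "pa"),
                          label = c(1L, 0L, 1L))
  pp <- encode_pairs(pairs, pf)
  expect_equal(ncol(pp) - 3L, 1318L)
  va <- as.numeric(pf[pf$protein_id == "pa", -1])
  vb <- as.numeric(pf[pf$protein_id == "pb", -1])
  # A-side then B-side
  expect_equal(as.numeric(pp[1, 4:662]), va)
  expect_equal(as.numeric(pp[1, 663:1321]), vb)
  # self-pair duplicates its halves
  expect_equal(as.numeric(pp[2, 4:662]), as.numeric(pp[2, 663:1321]))
  # swapped pair swaps the halves
  expect_equal(as.numeric(pp[3, 4:662]), vb)
  expect_equal(as.numeric(pp[3, 663:1321]), va)

  expect_error(encode_pairs(tibble::tibble(id_a = "zz", id_b = "pa", label = 1L), pf),
               "unencoded")
})

test_that("pair mirroring augmentation doubles the table when requested", {
  set.seed(17)
  prots <- tibble::tibble(id = c("pa", "pb"),
                          sequence = c(random_protein(50), random_protein(45)))
  pf <- suppressWarnings(encode_proteins(prots))
  pairs <- tibble::tibble(id_a = "pa", id_b = "pb", label = 1L)
  pp <- encode_pairs(pairs, pf, augment_mirrored = TRUE)
  expect_equal(nrow(pp), 2L)
  expect_equal(as.numeric(pp[1, 4:662]), as.numeric(pp[2, 663:1321]))
})

test_that("encoding warns once and falls back when PSSMs are absent", {
  prots <- tibble::tibble(id = "solo", sequence = random_protein(40))
  expect_warning(encode_proteins(prots), class = "ppiboost_pseudo_pssm")
  # the fallback equals the explicit pseudo-PSSM path
  pf1 <- suppressWarnings(encode_proteins(prots))
  pf2 <- encode_proteins(prots, pssms = list(solo = pseudo_pssm(prots$sequence)))
  expect_equal(pf1, pf2)
})
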