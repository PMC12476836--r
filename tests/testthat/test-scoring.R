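test_that("model confidence is the 0.2/0.8 pTM-ipTM blend and stays bounded", {
  expect_equal(model_confidence(1, 1), 1)
  expect_equal(model_confidence(0, 0), 0)
  expect_equal(model_confidence(0.5, 0.75), 0.7)
  expect_error(model_confidence(1.2, 0.5), class = "slimpae_domain_error")
  expect_error(model_confidence(0.5, -0.1), class = "slimpae_domain_error")
  set.seed(11)
  for (i in 1:25) {
    mc <- model_confidence(runif(1), runif(1))
    expect_gte(mc, 0); expect_lte(mc, 1)
  }
})

test_that("mini_pae finds the planted inter-chain minimum and ignores intra cells", {
  pae <- matrix(1.0, 4, 4)
  pae[1, 3] <- 12.0; pae[1, 4] <- 9.5
  pae[3, 1] <- 30.0; pae[4, 2] <- 28.0
  pae[2, 3] <- 30.0; pae[2, 4] <- 30.0
  pae[3, 2] <- 30.0; pae[4, 1] <- 30.0
  rec <- record_from_pae(pae, 2, 2)
  expect_equal(mini_pae(rec)$value, 9.5)

  # constant matrix
  rec2 <- record_from_pae(matrix(15, 6, 6), 3, 3)
  expect_equal(mini_pae(rec2)$value, 15)

  one <- prediction_record("m", chain_partition("A", 4), matrix(1, 4, 4),
                           rep(50, 4), 0.5, 0.5)
  expect_error(mini_pae(one), class = "slimpae_chain_count_error")
})

test_that("mini_pae matches the brute-force inter-chain scan on random matrices", {
  set.seed(202)
  for (i in 1:30) {
    len_a <- sample(2:30, 1); len_b <- sample(2:30, 1)
    pae <- random_two_chain_pae(len_a, len_b)
    rec <- record_from_pae(pae, len_a, len_b)
    expect_equal(mini_pae(rec)$value, bf_min_inter_pae(pae, len_a, len_b))
  }
  # one large instance at L = 200
  pae <- random_two_chain_pae(120, 80)
  rec <- record_from_pae(pae, 120, 80)
  expect_equal(mini_pae(rec)$value, bf_min_inter_pae(pae, 120, 80))
})

test_that("mini_pae is invariant under swapping the chain block order", {
  set.seed(77)
  len_a <- 12; len_b <- 7
  pae <- random_two_chain_pae(len_a, len_b)
  perm <- c(len_a + seq_len(len_b), seq_len(len_a))
  rec1 <- record_from_pae(pae, len_a, len_b)
  rec2 <- record_from_pae(pae[perm, perm], len_b, len_a)
  expect_equal(mini_pae(rec1)$value, mini_pae(rec2)$value)
})

test_that("per-residue minimum inter-chain PAE profiles match brute force", {
  # planted stripe, forced values
  len_a <- 20; len_b <- 15
  pae <- matrix(25, len_a + len_b, len_a + len_b)
  stripe <- 8:12
  pae[len_a + stripe, seq_len(len_a)] <- 2.0
  rec <- record_from_pae(pae, len_a, len_b)
  prof <- min_inter_pae_profile(rec, "B")
  expect_equal(prof$kind, "min_inter_pae")
  expect_equal(prof$values[stripe], rep(2.0, 5))
  expect_equal(prof$values[-stripe], rep(25, len_b - 5))

  # min over the profile equals MiniPAE, on both chains
  set.seed(303)
  for (i in 1:20) {
    la <- sample(3:18, 1); lb <- sample(3:18, 1)
    pae <- random_two_chain_pae(la, lb)
    rec <- record_from_pae(pae, la, lb)
    pb <- min_inter_pae_profile(rec, "B")
    pa <- min_inter_pae_profile(rec, "A")
    expect_equal(pb$values, bf_profile_chain2(pae, la, lb))
    expect_equal(min(pb$values), mini_pae(rec)$value)
    expect_equal(min(pa$values), mini_pae(rec)$value)
  }
  expect_error(min_inter_pae_profile(rec, "Q"), class = "slimpae_lookup_error")
})

test_that("AlphaSLiM profile multiplies contact counts by the pLDDT gain", {
  bound <- residue_profile("B", c(80, 80, 80), kind = "plddt")
  unbound <- residue_profile("B", c(60, 80, 90), kind = "plddt")
  cc <- contact_counts_from("B", c(5L, 3L, 2L))
  asl <- alphaslim_profile(bound, unbound, cc)
  expect_equal(asl$kind, "alphaslim")
  expect_equal(asl$values, c(5 * 20, 0, 2 * -10))

  # zero contacts kill the signal regardless of the pLDDT difference
  asl0 <- alphaslim_profile(bound, unbound, contact_counts_from("B", c(0L, 0L, 0L)))
  expect_equal(asl0$values, c(0, 0, 0))
  # equal tracks give zero everywhere
  expect_equal(alphaslim_profile(bound, bound, cc)$values, c(0, 0, 0))
  # odd in the pLDDT difference
  expect_equal(alphaslim_profile(unbound, bound, cc)$values, -asl$values)

  expect_error(
    alphaslim_profile(bound, residue_profile("B", c(1, 2), kind = "plddt"), cc),
    class = "slimpae_dimension_error")
  expect_error(
    alphaslim_profile(bound, residue_profile("C", c(1, 2, 3), kind = "plddt"), cc),
    class = "slimpae_dimension_error")
})

test_that("contact counts agree with an all-pairs distance check on fixtures", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(bait_len = 25L, candidate_len = 12L, motif_start = 4L,
                       motif_width = 5L, seed = 5L, record_id = "cc")
  files <- make_prediction_bundle(spec, dir)
  cc <- contact_counts(files$structure, "B", cutoff = 4.0)
  expect_length(cc$counts, 12L)

  # oracle: brute-force distances on the PDB coordinates
  pdb <- bio3d::read.pdb(files$structure, verbose = FALSE)
  cand <- pdb$atom[pdb$atom$chain == "B", ]
  bait <- pdb$atom[pdb$atom$chain == "A", ]
  oracle <- vapply(sort(unique(cand$resno)), function(r) {
    ra <- cand[cand$resno == r, c("x", "y", "z")]
    hits <- 0L
    for (bi in seq_len(nrow(bait))) {
      d <- sqrt(sum((as.numeric(ra[1, ]) - as.numeric(bait[bi, c("x", "y", "z")]))^2))
      if (d <= 4.0) hits <- hits + 1L
    }
    hits
  }, integer(1))
  expect_equal(cc$counts, oracle)
  expect_true(all(cc$counts[4:8] >= 1L))
  expect_true(all(cc$counts[-(4:8)] == 0L))

  # monotone non-decreasing in the cutoff
  cc6 <- contact_counts(files$structure, "B", cutoff = 6.0)
  expect_true(all(cc6$counts >= cc$counts))

  # chains far apart everywhere give all zeros
  spec_nb <- fixture_spec(bait_len = 10L, candidate_len = 6L,
                          motif_start = NULL, motif_width = NULL,
                          seed = 6L, record_id = "nb")
  files_nb <- make_prediction_bundle(spec_nb, dir)
  expect_equal(contact_counts(files_nb$structure, "B")$counts, rep(0L, 6L))
  expect_error(contact_counts(files$structure, "Z"),
               class = "slimpae_lookup_error")
})

test_that("direct normalization divides by the maximum and is scale-invariant", {
  expect_equal(normalize_direct(c(2, 4, 8)), c(0.25, 0.5, 1.0))
  expect_equal(normalize_direct(5), 1.0)
  set.seed(8)
  for (i in 1:10) {
    v <- runif(20, 0, 50)
    expect_equal(max(normalize_direct(v)), 1.0)
    expect_equal(normalize_direct(3.7 * v), normalize_direct(v))
  }
  expect_error(normalize_direct(c(0, 0)), class = "slimpae_degenerate_input_error")
  expect_error(normalize_direct(numeric()), class = "slimpae_degenerate_input_error")
  expect_error(normalize_direct(c(-1, 2)), class = "slimpae_domain_error")
})

test_that("inverse normalization applies the printed affine form verbatim", {
  expect_equal(normalize_inverse(c(2, 4)), c((0.5 - 0.25) / 0.5, 0))
  # the worst (largest) original score always maps to 0
  set.seed(9)
  for (i in 1:10) {
    v <- runif(15, 0.5, 30)
    out <- normalize_inverse(v)
    expect_equal(out[which.max(v)], 0)
    # best score maps to (inv_max - inv_min)/inv_max, not necessarily 1
    inv <- 1 / v
    expect_equal(out[which.min(v)], (max(inv) - min(inv)) / max(inv))
  }
  expect_equal(normalize_inverse(c(3, 3, 3)), c(0, 0, 0))
  expect_error(normalize_inverse(c(0, 2)), class = "slimpae_domain_error")
  expect_error(normalize_inverse(5), class = "slimpae_degenerate_input_error")
})

test_that("score_pair bundles derived metrics and echoes ingested ones", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(bait_len = 18L, candidate_len = 10L, motif_start = 3L,
                       motif_width = 4L, stripe_pae = 3.1, pae_noise_sd = 0,
                       ptm = 0.8, iptm = 0.9, seed = 10L, record_id = "sp")
  files <- make_prediction_bundle(spec, dir)
  rec <- read_colabfold_record(files$score, chain_lengths = c(18L, 10L))

  sp <- score_pair(rec, ingested = c(MinD = 4.2), label = "binder")
  expect_equal(sp$metrics$MC$value, 0.2 * 0.8 + 0.8 * 0.9)
  expect_equal(sp$metrics$MiniPAE$value, 3.1)
  expect_null(sp$metrics$AlphaSLiM_max)      # absent, not zero
  expect_false(sp$metrics$MinD$derived)
  expect_equal(sp$metrics$MinD$value, 4.2)

  mono <- make_monomer_plddt(spec)
  sp2 <- score_pair(rec, monomer_plddt = mono, structure_path = files$structure)
  expect_equal(sp2$metrics$AlphaSLiM_max$value, spec$plddt_boost * 1)

  expect_error(metric_value("MinD", 1, derived = TRUE),
               class = "slimpae_domain_error")
})

test_that("metric_by_label splits scores and drops unknowns with a message", {
  mk <- function(id, v, lab) scored_pair(id, "b", id,
                                         list(MiniPAE = metric_value("MiniPAE", v)),
                                         label = lab)
  pairs <- list(mk("a", 2, "binder"), mk("b", 11, "non_binder"),
                mk("c", 3, "binder"), mk("d", 9, "unknown"))
  expect_message(out <- metric_by_label(pairs, "MiniPAE"), "1 pair")
  expect_equal(out$binder, c(2, 3))
  expect_equal(out$non_binder, 11)
})
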