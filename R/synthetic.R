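# Synthetic AlphaFold-style fixtures: score bundles with planted inter-chain
# PAE structure, pLDDT tracks and matching CA-only structures, plus labeled
# score pools. These are statistical stand-ins for AlphaFold output (no
# attempt at realistic error covariance), built so every reader, scorer and
# evaluator in the package can be exercised without a prediction run.

#' Specification of one synthetic binary-complex prediction
#'
#' Describes a bait-candidate complex with an optional planted "motif
#' stripe": a block of candidate residues given low inter-chain PAE against
#' the bait (a confident interface), a pLDDT gain in the bound state, and
#' coordinates within contact range of the bait. Omitting `motif_start` /
#' `motif_width` yields a non-binder (uniform high inter-chain PAE, no
#' contacts).
#'
#' Defaults sketch a typical SLiM screen prediction: a ~100-residue bait
#' domain against a ~60-residue disordered candidate carrying an 8-residue
#' motif, stripe PAE 2 A against a 25 A background (binders in real screens
#' sit near or below ~3 A, non-binders near the PAE ceiling), base pLDDT 45
#' (disordered) with a +25 gain on the motif when bound.
#'
#' @param bait_len,candidate_len Residue counts of the two chains.
#' @param motif_start,motif_width Planted stripe position (1-based, within
#'   the candidate chain); both `NULL` for a non-binder.
#' @param stripe_pae,background_pae Inter-chain PAE levels (Angstrom) for
#'   stripe cells and everything else; `stripe_pae < background_pae`.
#' @param pae_noise_sd Gaussian noise on every PAE cell (Angstrom); draws
#'   are clipped to the practical AlphaFold range `[0.2, 31.75]`.
#' @param plddt_base,plddt_boost Candidate pLDDT level and its bound-state
#'   gain on motif residues (0-100 scale).
#' @param plddt_noise_sd Gaussian noise on pLDDT tracks.
#' @param ptm,iptm Global confidence fractions written to the bundle.
#' @param seed Integer seed; all bundle content is deterministic from it.
#' @param dialect Output flavour, `"af2_colabfold"` or `"af3_server"`.
#' @param record_id Name used for files and the parsed record.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(bait_len = 100L, candidate_len = 60L,
                         motif_start = 20L, motif_width = 8L,
                         stripe_pae = 2.0, background_pae = 25.0,
                         pae_noise_sd = 0.5,
                         plddt_base = 45, plddt_boost = 25,
                         plddt_noise_sd = 0,
                         ptm = 0.5, iptm = 0.6, seed = 1L,
                         dialect = c("af2_colabfold", "af3_server"),
                         record_id = "synthetic") {
  dialect <- match.arg(dialect)
  bait_len <- as.integer(bait_len); candidate_len <- as.integer(candidate_len)
  stopifnot(bait_len >= 1L, candidate_len >= 1L)
  has_motif <- !is.null(motif_start) && !is.null(motif_width)
  if (has_motif) {
    motif_start <- as.integer(motif_start); motif_width <- as.integer(motif_width)
    if (motif_width < 1L || motif_start < 1L ||
        motif_start + motif_width - 1L > candidate_len) {
      stop_slimpae("motif %d..%d falls outside the candidate chain (1..%d)",
                   "slimpae_spec_error", motif_start,
                   motif_start + motif_width - 1L, candidate_len)
    }
    if (!(stripe_pae < background_pae)) {
      stop_slimpae("binder specs need stripe_pae < background_pae",
                   "slimpae_spec_error")
    }
  } else {
    motif_start <- NULL; motif_width <- NULL
  }
  assert_scalar_number(ptm, "ptm", 0, 1)
  assert_scalar_number(iptm, "iptm", 0, 1)
  structure(
    list(bait_len = bait_len, candidate_len = candidate_len,
         motif_start = motif_start, motif_width = motif_width,
         stripe_pae = stripe_pae, background_pae = background_pae,
         pae_noise_sd = pae_noise_sd, plddt_base = plddt_base,
         plddt_boost = plddt_boost, plddt_noise_sd = plddt_noise_sd,
         ptm = ptm, iptm = iptm, seed = as.integer(seed), dialect = dialect,
         record_id = as.character(record_id)),
    class = "fixture_spec"
  )
}

motif_range <- function(spec) {
  if (is.null(spec$motif_start)) integer() else
    seq(spec$motif_start, spec$motif_start + spec$motif_width - 1L)
}

# Build the numeric content (PAE, pLDDT, coordinates) of a fixture in memory.
fixture_content <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nb <- spec$bait_len; nc <- spec$candidate_len
  L <- nb + nc
  motif <- motif_range(spec)
  with_seed(derive_seed(spec$seed, 11L), {
    pae <- matrix(spec$background_pae, L, L)
    bait_idx <- seq_len(nb)
    cand_idx <- nb + seq_len(nc)
    # confident intra-chain blocks
    pae[bait_idx, bait_idx] <- 3.0
    pae[cand_idx, cand_idx] <- 3.0
    if (length(motif)) {
      pae[bait_idx, nb + motif] <- spec$stripe_pae
      pae[nb + motif, bait_idx] <- spec$stripe_pae
    }
    if (spec$pae_noise_sd > 0) {
      pae <- pae + matrix(stats::rnorm(L * L, 0, spec$pae_noise_sd), L, L)
    }
    diag(pae) <- .PAE_MIN
    pae <- clip(pae, .PAE_MIN, .PAE_MAX)

    plddt <- rep(spec$plddt_base, L)
    plddt[nb + motif] <- spec$plddt_base + spec$plddt_boost
    if (spec$plddt_noise_sd > 0) {
      plddt <- plddt + stats::rnorm(L, 0, spec$plddt_noise_sd)
    }
    plddt <- clip(plddt, 0, 100)

    # CA-only geometry: bait along x; motif residues sit 3 A off their
    # paired bait CA (inside a 4 A contact cutoff), the rest 60 A away.
    bait_xyz <- cbind(4 * seq_len(nb), 0, 0)
    cand_xyz <- cbind(4 * seq_len(nc), 60, 0)
    if (length(motif)) {
      cand_xyz[motif, ] <- cbind(4 * seq_along(motif), 3.0, 0)
    }
    list(pae = pae, plddt = plddt, bait_xyz = bait_xyz, cand_xyz = cand_xyz)
  })
}

#' Write a synthetic prediction bundle to disk
#'
#' Emits a score bundle in the requested dialect plus a minimal CA-only
#' two-chain PDB (bait chain A, candidate chain B) whose geometry is
#' consistent with the planted stripe: motif residues lie within 4 A of a
#' bait atom, all other candidate residues far away. Re-running with the
#' same spec produces byte-identical files.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if missing).
#' @return List with paths: `score` (AF2) or `full`/`summary` (AF3),
#'   `structure`, plus `record_id`, `dialect` and the planted
#'   `motif_start`/`motif_end` (NULL for non-binders).
#' @export
make_prediction_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ct <- fixture_content(spec)
  nb <- spec$bait_len; nc <- spec$candidate_len

  pdb_path <- file.path(out_dir, paste0(spec$record_id, "_unrelaxed_rank_001.pdb"))
  xyz <- rbind(ct$bait_xyz, ct$cand_xyz)
  bio3d::write.pdb(
    file = pdb_path,
    xyz = as.numeric(t(xyz)),
    resno = c(seq_len(nb), seq_len(nc)),
    chain = rep(c("A", "B"), c(nb, nc)),
    resid = rep("ALA", nb + nc), elety = rep("CA", nb + nc),
    b = round(ct$plddt, 2)
  )

  motif <- motif_range(spec)
  out <- list(record_id = spec$record_id, dialect = spec$dialect,
              structure = pdb_path,
              motif_start = if (length(motif)) min(motif) else NULL,
              motif_end = if (length(motif)) max(motif) else NULL)

  if (spec$dialect == "af2_colabfold") {
    score_path <- file.path(
      out_dir,
      paste0(spec$record_id,
             "_scores_rank_001_alphafold2_multimer_v3_model_1_seed_000.json"))
    jsonlite::write_json(
      list(plddt = round(ct$plddt, 2), max_pae = .PAE_MAX,
           pae = round(ct$pae, 2), ptm = spec$ptm, iptm = spec$iptm),
      score_path, auto_unbox = TRUE, digits = NA)
    out$score <- score_path
  } else {
    full_path <- file.path(out_dir, paste0(spec$record_id, "_full_data_0.json"))
    summary_path <- file.path(out_dir,
                              paste0(spec$record_id, "_summary_confidences_0.json"))
    chain_ids <- rep(c("A", "B"), c(nb, nc))
    res_ids <- c(seq_len(nb), seq_len(nc))
    jsonlite::write_json(
      list(pae = round(ct$pae, 2),
           token_chain_ids = chain_ids, token_res_ids = res_ids,
           atom_chain_ids = chain_ids, atom_res_ids = res_ids,
           atom_plddts = round(ct$plddt, 2), max_pae = .PAE_MAX),
      full_path, auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(ptm = spec$ptm, iptm = spec$iptm),
                         summary_path, auto_unbox = TRUE, digits = NA)
    out$full <- full_path
    out$summary <- summary_path
    out$score <- full_path
  }
  out
}

#' Unbound-candidate pLDDT track for a fixture
#'
#' The monomer counterpart of a fixture's bound-state pLDDT: base level
#' everywhere (no bound-state boost), with its own noise stream, so the
#' bound-minus-unbound difference is positive exactly on the planted motif.
#'
#' @param spec A [fixture_spec()].
#' @return A [residue_profile()] of kind `"plddt"` for chain B.
#' @export
make_monomer_plddt <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  v <- rep(spec$plddt_base, spec$candidate_len)
  if (spec$plddt_noise_sd > 0) {
    v <- with_seed(derive_seed(spec$seed, 13L),
                   v + stats::rnorm(spec$candidate_len, 0, spec$plddt_noise_sd))
  }
  residue_profile("B", clip(v, 0, 100), kind = "plddt")
}

#' Generate labeled MiniPAE-like score pools
#'
#' Draws binder and non-binder score pools from named distributions,
#' clipped to the practical PAE range `[0.2, 31.75]`. Pool sizes default to
#' 26 binders and 1100 non-binders, the scale of a structure-independent
#' SLiM benchmark with a large shuffled-negative excess; the default
#' distributions put binders low (lognormal around ~3 A) and non-binders
#' high (normal around 15 A), overlapping enough that ranking is imperfect.
#'
#' @param n_pos,n_neg Pool sizes.
#' @param pos_dist,neg_dist Distribution specs: `list(family, location,
#'   scale)` with family `"normal"`, `"lognormal"`, `"exponential"`
#'   (location-shifted) or `"point"`.
#' @param seed Integer seed.
#' @return List with numeric vectors `pos` and `neg`.
#' @export
make_score_pools <- function(n_pos = 26L, n_neg = 1100L,
                             pos_dist = list(family = "lognormal",
                                             location = log(3), scale = 0.4),
                             neg_dist = list(family = "normal",
                                             location = 15, scale = 5),
                             seed = 1L) {
  list(
    pos = with_seed(derive_seed(seed, 21L),
                    clip(draw_dist(n_pos, pos_dist), .PAE_MIN, .PAE_MAX)),
    neg = with_seed(derive_seed(seed, 22L),
                    clip(draw_dist(n_neg, neg_dist), .PAE_MIN, .PAE_MAX))
  )
}

draw_dist <- function(n, dist) {
  stopifnot(is.list(dist), !is.null(dist$family))
  loc <- dist$location %||% 0
  scale <- dist$scale %||% 1
  switch(dist$family,
    normal = stats::rnorm(n, loc, scale),
    lognormal = stats::rlnorm(n, loc, scale),
    exponential = loc + stats::rexp(n, rate = 1 / scale),
    point = rep(loc, n),
    stop_slimpae("unknown distribution family '%s'", "slimpae_spec_error",
                 dist$family)
  )
}

#' Simulate a whole synthetic screen
#'
#' Writes `n_binders` binder and `n_nonbinders` non-binder bundles (seeds
#' derived from `seed`), together with a manifest data frame of ground
#' truth (record id, label, planted motif coordinates).
#'
#' @param n_binders,n_nonbinders Bundle counts.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param dialect Bundle dialect for all records.
#' @param ... Further arguments passed to [fixture_spec()] (e.g.
#'   `stripe_pae`, `background_pae`, chain lengths).
#' @return List with `manifest` (data frame) and `bundles` (list of
#'   [make_prediction_bundle()] outputs).
#' @export
simulate_screen <- function(n_binders, n_nonbinders, out_dir, seed = 1L,
                            dialect = "af2_colabfold", ...) {
  dots <- list(...)
  base_spec <- function(i, binder) {
    args <- c(list(seed = derive_seed(seed, 100L + i),
                   dialect = dialect,
                   record_id = sprintf("%s%03d",
                                       if (binder) "binder" else "nonbinder", i)),
              dots)
    if (!binder) {
      args["motif_start"] <- list(NULL)
      args["motif_width"] <- list(NULL)
    }
    do.call(fixture_spec, args)
  }
  specs <- c(lapply(seq_len(n_binders), base_spec, binder = TRUE),
             lapply(seq_len(n_nonbinders) + n_binders, base_spec, binder = FALSE))
  bundles <- lapply(specs, make_prediction_bundle, out_dir = out_dir)
  manifest <- do.call(rbind, lapply(seq_along(bundles), function(i) {
    b <- bundles[[i]]
    data.frame(record_id = b$record_id,
               label = if (i <= n_binders) "binder" else "non_binder",
               motif_start = b$motif_start %||% NA_integer_,
               motif_end = b$motif_end %||% NA_integer_)
  }))
  list(manifest = manifest, bundles = bundles, specs = specs)
}
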