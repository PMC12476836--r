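#' Read a ColabFold (AlphaFold2) score file into a prediction record
#'
#' ColabFold writes one JSON score file per ranked model, holding the PAE
#' matrix, the per-residue pLDDT track and the global pTM/ipTM. The score
#' JSON does not encode where the complex's chain boundary lies, so the
#' partition must come from explicit `chain_lengths` or from the chain
#' labels of the matching structure file.
#'
#' @param score_path Path to the ColabFold score JSON.
#' @param chain_lengths Optional integer vector of per-chain residue counts,
#'   in concatenation order. Chains are labelled "A", "B", ... in order.
#' @param structure_path Optional path to the matching PDB file; chain
#'   labels and lengths are taken from its CA records.
#' @param record_id Identifier; defaults to the score file's base name.
#' @return A [prediction_record()] with dialect `"af2_colabfold"`. The model
#'   rank is parsed from a `rank_00k` tag in the file name when present,
#'   else 1.
#' @examples
#' spec <- fixture_spec(bait_len = 12, candidate_len = 8, motif_start = 3,
#'                      motif_width = 4, seed = 7)
#' files <- make_prediction_bundle(spec, tempdir())
#' rec <- read_colabfold_record(files$score, structure_path = files$structure)
#' rec$partition$chain_lengths
#' @export
read_colabfold_record <- function(score_path, chain_lengths = NULL,
                                  structure_path = NULL, record_id = NULL) {
  dat <- read_score_json(score_path)
  pae <- score_json_pae(dat, score_path)
  L <- nrow(pae)

  if (is.null(chain_lengths) && is.null(structure_path)) {
    stop_slimpae(
      paste0("chain partition is not derivable from '%s': supply chain_lengths ",
             "or structure_path"),
      "slimpae_missing_partition_error", basename(score_path))
  }
  if (!is.null(chain_lengths) && !is.null(structure_path)) {
    stop_slimpae("supply exactly one of chain_lengths / structure_path",
                 "slimpae_missing_partition_error")
  }
  part <- if (!is.null(chain_lengths)) {
    chain_partition(LETTERS[seq_along(chain_lengths)], chain_lengths)
  } else {
    partition_from_structure(structure_path)
  }

  prediction_record(
    record_id = record_id %||% strip_json_ext(score_path),
    partition = part,
    pae = pae,
    plddt = need_key(dat, "plddt", score_path),
    ptm = need_key(dat, "ptm", score_path),
    iptm = need_key(dat, "iptm", score_path),
    max_pae = dat$max_pae %||% max(31.75, max(pae)),
    dialect = "af2_colabfold",
    model_rank = parse_model_rank(score_path)
  )
}

read_score_json <- function(path) {
  if (!file.exists(path)) {
    stop_slimpae("score file not found: %s", "slimpae_parse_error", path)
  }
  tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) {
      stop_slimpae("malformed JSON in '%s': %s", "slimpae_parse_error",
                   basename(path), conditionMessage(e))
    }
  )
}

# ColabFold has used both "pae" and "predicted_aligned_error" across versions.
score_json_pae <- function(dat, path) {
  pae <- dat$pae %||% dat$predicted_aligned_error
  if (is.null(pae)) {
    stop_slimpae("score JSON '%s' lacks key 'pae'", "slimpae_parse_error",
                 basename(path))
  }
  as.matrix(pae)
}

need_key <- function(dat, key, path) {
  if (is.null(dat[[key]])) {
    stop_slimpae("score JSON '%s' lacks key '%s'", "slimpae_parse_error",
                 basename(path), key)
  }
  dat[[key]]
}

parse_model_rank <- function(path) {
  m <- regmatches(basename(path), regexpr("rank_([0-9]+)", basename(path)))
  if (length(m) == 1L) as.integer(sub("rank_", "", m)) else 1L
}

strip_json_ext <- function(path) sub("\\.json$", "", basename(path))

# Chain labels + lengths from the CA atoms of a PDB file.
partition_from_structure <- function(structure_path) {
  pdb <- tryCatch(
    bio3d::read.pdb(structure_path, verbose = FALSE),
    error = function(e) {
      stop_slimpae("cannot parse structure '%s': %s", "slimpae_parse_error",
                   basename(structure_path), conditionMessage(e))
    }
  )
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) {
    stop_slimpae("structure '%s' has no CA atoms", "slimpae_parse_error",
                 basename(structure_path))
  }
  r <- rle(ca$chain)
  chain_partition(r$values, r$lengths)
}

#' Read an AlphaFold3 server output bundle into a prediction record
#'
#' The AF3 server emits a "full data" JSON (token-level PAE, token chain
#' ids, atom-level pLDDT, atom chain ids) and a "summary confidences" JSON
#' (pTM, ipTM). Atom pLDDTs are aggregated to one value per residue by
#' arithmetic mean over that residue's atoms; the token-level PAE is reduced
#' to residue resolution by taking, for each residue pair, the minimum PAE
#' over its token pairs (the identity for standard one-token-per-residue
#' proteins).
#'
#' @param bundle_path Either a directory holding the two JSON files, or the
#'   path of the full-data JSON (the summary file is located next to it).
#' @param record_id Identifier; defaults to a name derived from the bundle.
#' @return A [prediction_record()] with dialect `"af3_server"`.
#' @export
read_af3_record <- function(bundle_path, record_id = NULL) {
  paths <- locate_af3_bundle(bundle_path)
  full <- read_score_json(paths$full)
  summ <- read_score_json(paths$summary)

  token_chain <- need_key(full, "token_chain_ids", paths$full)
  token_res <- need_key(full, "token_res_ids", paths$full)
  pae_tok <- as.matrix(need_key(full, "pae", paths$full))
  if (length(token_chain) != nrow(pae_tok) || length(token_res) != nrow(pae_tok)) {
    stop_slimpae("token chain/residue arrays do not match the PAE dimension",
                 "slimpae_mapping_error")
  }

  # Residue axis in token order: one entry per distinct (chain, residue).
  token_key <- paste(token_chain, token_res, sep = ":")
  res_key <- unique(token_key)
  tok_of_res <- match(token_key, res_key)
  Lr <- length(res_key)

  pae <- if (Lr == length(token_key)) {
    pae_tok  # one token per residue: identity mapping
  } else {
    reduce_token_pae(pae_tok, tok_of_res, Lr)
  }

  atom_chain <- need_key(full, "atom_chain_ids", paths$full)
  atom_plddt <- need_key(full, "atom_plddts", paths$full)
  if (length(atom_chain) != length(atom_plddt)) {
    stop_slimpae("atom chain/pLDDT arrays differ in length", "slimpae_mapping_error")
  }
  atom_res <- full$atom_res_ids
  if (is.null(atom_res)) {
    if (length(atom_plddt) != Lr) {
      stop_slimpae(
        "bundle lacks atom_res_ids and atom count (%d) != residue count (%d)",
        "slimpae_mapping_error", length(atom_plddt), Lr)
    }
    atom_key <- res_key  # one atom per residue, in residue order
  } else {
    atom_key <- paste(atom_chain, atom_res, sep = ":")
  }
  if (!all(atom_key %in% res_key)) {
    stop_slimpae("atom chain/residue ids inconsistent with token ids",
                 "slimpae_mapping_error")
  }
  plddt <- as.numeric(tapply(atom_plddt, factor(atom_key, levels = res_key), mean))

  chain_of_res <- sub(":.*$", "", res_key)
  r <- rle(chain_of_res)
  part <- chain_partition(r$values, r$lengths)

  prediction_record(
    record_id = record_id %||% sub("_full_data.*$", "", basename(paths$full)),
    partition = part,
    pae = pae,
    plddt = plddt,
    ptm = need_key(summ, "ptm", paths$summary),
    iptm = need_key(summ, "iptm", paths$summary),
    max_pae = full$max_pae %||% max(31.75, max(pae)),
    dialect = "af3_server",
    model_rank = 1L
  )
}

locate_af3_bundle <- function(bundle_path) {
  if (dir.exists(bundle_path)) {
    full <- list.files(bundle_path, pattern = "full_data.*\\.json$",
                       full.names = TRUE)
    summary <- list.files(bundle_path, pattern = "summary_confidences.*\\.json$",
                          full.names = TRUE)
  } else {
    full <- if (file.exists(bundle_path)) bundle_path else character()
    summary <- sub("full_data", "summary_confidences", full)
    summary <- summary[file.exists(summary)]
  }
  if (length(full) < 1L || length(summary) < 1L) {
    stop_slimpae(
      "incomplete AF3 bundle at '%s': need full_data and summary_confidences JSON",
      "slimpae_bundle_incomplete_error", bundle_path)
  }
  list(full = sort(full)[1L], summary = sort(summary)[1L])
}

# Min over token pairs for each residue pair (conservative toward contacts).
reduce_token_pae <- function(pae_tok, tok_of_res, Lr) {
  out <- matrix(Inf, Lr, Lr)
  for (i in seq_len(nrow(pae_tok))) {
    ri <- tok_of_res[i]
    row <- pae_tok[i, ]
    agg <- tapply(row, tok_of_res, min)
    out[ri, ] <- pmin(out[ri, ], as.numeric(agg))
  }
  out
}

#' Write localized motif calls to a tab-separated table
#'
#' Columns, in stable order: `record_id`, `candidate_chain`, `motif_start`,
#' `motif_end` (1-based inclusive), `motif_sequence` (`"."` when no sequence
#' is attached), `minipae`, `passed_threshold`. Rows are sorted by record id
#' then motif start, so output is deterministic.
#'
#' @param calls List of [motif_call()] objects (possibly empty).
#' @param path Output file path.
#' @return Invisibly, the data frame written.
#' @export
write_motif_table <- function(calls, path) {
  df <- motif_calls_df(calls)
  df <- df[order(df$record_id, df$motif_start), , drop = FALSE]
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) {
      stop_slimpae("cannot write motif table to '%s': %s", "slimpae_io_error",
                   path, conditionMessage(e))
    }
  )
  invisible(df)
}

motif_calls_df <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(record_id = character(), candidate_chain = character(),
                      motif_start = integer(), motif_end = integer(),
                      motif_sequence = character(), minipae = numeric(),
                      passed_threshold = logical()))
  }
  do.call(rbind, lapply(calls, function(cl) {
    stopifnot(inherits(cl, "motif_call"))
    data.frame(
      record_id = cl$record_id,
      candidate_chain = cl$chain,
      motif_start = cl$start,
      motif_end = cl$end,
      motif_sequence = cl$sequence %||% ".",
      minipae = cl$score,
      passed_threshold = cl$passed %||% NA
    )
  }))
}

#' Write a score table for a set of scored pairs
#'
#' One CSV row per bait-candidate pair, with one column per metric
#' (missing metrics are NA).
#'
#' @param pairs List of [scored_pair()] objects.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_score_table <- function(pairs, path) {
  metrics <- unique(unlist(lapply(pairs, function(p) names(p$metrics))))
  df <- do.call(rbind, lapply(pairs, function(p) {
    row <- data.frame(pair_id = p$pair_id, bait_id = p$bait_id,
                      candidate_id = p$candidate_id, label = p$label)
    for (m in metrics) row[[m]] <- if (is.null(p$metrics[[m]])) NA else p$metrics[[m]]$value
    row
  }))
  if (is.null(df)) {
    df <- data.frame(pair_id = character(), bait_id = character(),
                     candidate_id = character(), label = character())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read candidate-chain sequences from a FASTA file
#'
#' Convenience wrapper for attaching motif sequences: returns a named
#' character vector (name = FASTA identifier, value = amino-acid string)
#' usable with [attach_sequences()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  out <- apply(fa$ali, 1L, function(row) paste(row[row != "-"], collapse = ""))
  stats::setNames(toupper(out), rownames(fa$ali))
}
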