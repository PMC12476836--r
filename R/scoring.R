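#' Model Confidence of a binary complex
#'
#' Combines the global pTM and interface ipTM into the standard weighted
#' Model Confidence, MC = 0.2 pTM + 0.8 ipTM. Higher is better.
#'
#' @param ptm,iptm Fractions in `[0, 1]`.
#' @return Numeric in `[0, 1]`.
#' @examples
#' model_confidence(0.5, 0.75)  # 0.7
#' @export
model_confidence <- function(ptm, iptm) {
  assert_scalar_number(ptm, "ptm", 0, 1)
  assert_scalar_number(iptm, "iptm", 0, 1)
  0.2 * ptm + 0.8 * iptm
}

inter_block_mask <- function(record) {
  part <- record$partition
  g <- rep.int(seq_along(part$chain_ids), part$chain_lengths)
  outer(g, g, "!=")
}

#' MiniPAE: minimum inter-chain predicted aligned error
#'
#' The lowest PAE over all residue pairs whose members lie in different
#' chains, considering both off-diagonal blocks of the (asymmetric) matrix.
#' A low MiniPAE indicates at least one confidently placed inter-chain
#' contact and is the primary screening signal for SLiM-mediated binding.
#' Lower is better.
#'
#' @param record A two-chain [prediction_record()].
#' @return A `metric_value` with name `"MiniPAE"` (Angstrom).
#' @export
mini_pae <- function(record) {
  assert_two_chains(record)
  metric_value("MiniPAE", min(record$pae[inter_block_mask(record)]))
}

#' Per-residue minimum inter-chain PAE profile
#'
#' For each residue of `chain`, the minimum PAE over all cells pairing it
#' with any residue of the other chain, in either orientation (its row and
#' its column). The minimum of this profile over either chain equals
#' [mini_pae()].
#'
#' @param record A two-chain [prediction_record()].
#' @param chain Chain label to profile.
#' @return A [residue_profile()] of kind `"min_inter_pae"`.
#' @export
min_inter_pae_profile <- function(record, chain) {
  assert_two_chains(record)
  idx <- chain_slice(record$partition, chain)
  other <- setdiff(seq_len(partition_length(record$partition)), idx)
  rows <- apply(record$pae[idx, other, drop = FALSE], 1L, min)
  cols <- apply(record$pae[other, idx, drop = FALSE], 2L, min)
  residue_profile(chain, pmin(rows, cols), kind = "min_inter_pae")
}

#' A named metric value
#'
#' @param name Metric name, one of `"MC"`, `"MiniPAE"`, `"AlphaSLiM_max"`,
#'   `"MinD"`, `"avg_model"`, `"interface_area"`, `"dG"`.
#' @param value Numeric value.
#' @param derived `TRUE` when computed by this package, `FALSE` when
#'   ingested from an external tool. `MinD`, `avg_model`, `interface_area`
#'   and `dG` are ingest-only and must carry `derived = FALSE`.
#' @return An object of class `metric_value`.
#' @export
metric_value <- function(name, value, derived = TRUE) {
  name <- match.arg(name, c("MC", "MiniPAE", "AlphaSLiM_max", "MinD",
                            "avg_model", "interface_area", "dG"))
  if (derived && name %in% c("MinD", "avg_model", "interface_area", "dG")) {
    stop_slimpae("metric '%s' is ingest-only (derived must be FALSE)",
                 "slimpae_domain_error", name)
  }
  assert_scalar_number(value, name)
  structure(list(name = name, value = value, derived = isTRUE(derived)),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("%s = %g%s\n", x$name, x$value,
              if (x$derived) "" else " (ingested)"))
  invisible(x)
}

#' Per-residue interface contact counts
#'
#' Counts, for each residue of the candidate chain, the number of heavy
#' atoms of the bait chain lying within `cutoff` of any heavy atom of that
#' residue. This is the interaction count N entering the AlphaSLiM score;
#' externally computed interaction counts (e.g. from a dedicated
#' interaction profiler) can be substituted via [contact_counts_from()].
#'
#' @param structure_path Path to a PDB file holding both chains.
#' @param candidate_chain Chain label to count contacts for.
#' @param cutoff Heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return An object of class `contact_counts` with fields `chain` and
#'   `counts` (one non-negative integer per residue).
#' @export
contact_counts <- function(structure_path, candidate_chain, cutoff = 4.0) {
  assert_scalar_number(cutoff, "cutoff", lo = 0)
  pdb <- tryCatch(
    bio3d::read.pdb(structure_path, verbose = FALSE),
    error = function(e) {
      stop_slimpae("cannot parse structure '%s': %s", "slimpae_parse_error",
                   basename(structure_path), conditionMessage(e))
    }
  )
  atoms <- pdb$atom
  atoms <- atoms[is.na(atoms$elesy) | atoms$elesy != "H", , drop = FALSE]
  chains <- unique(atoms$chain)
  if (!candidate_chain %in% chains) {
    stop_slimpae("chain '%s' absent from structure (chains: %s)",
                 "slimpae_lookup_error", candidate_chain,
                 paste(chains, collapse = ", "))
  }
  if (length(chains) != 2L) {
    stop_slimpae("contact counting requires exactly 2 chains, got %d",
                 "slimpae_chain_count_error", length(chains))
  }
  cand <- atoms[atoms$chain == candidate_chain, , drop = FALSE]
  bait <- atoms[atoms$chain != candidate_chain, , drop = FALSE]
  if (nrow(cand) == 0L || nrow(bait) == 0L) {
    stop_slimpae("structure '%s' lacks coordinates for one chain",
                 "slimpae_parse_error", basename(structure_path))
  }
  resno <- sort(unique(cand$resno))
  bx <- as.matrix(bait[, c("x", "y", "z")])
  counts <- vapply(resno, function(r) {
    rx <- as.matrix(cand[cand$resno == r, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(bx^2), rowSums(rx^2), "+") - 2 * (bx %*% t(rx))
    sum(apply(d2 <= cutoff^2 + 1e-9, 1L, any))
  }, integer(1))
  contact_counts_from(candidate_chain, counts)
}

#' Wrap externally supplied per-residue interaction counts
#'
#' @param chain Candidate chain label.
#' @param counts Non-negative integer vector, one entry per residue.
#' @return An object of class `contact_counts`.
#' @export
contact_counts_from <- function(chain, counts) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || anyNA(counts) || any(counts < 0L)) {
    stop_slimpae("counts must be non-negative integers", "slimpae_domain_error")
  }
  structure(list(chain = as.character(chain), counts = counts),
            class = "contact_counts")
}

#' AlphaSLiM per-residue score profile
#'
#' AlphaSLiM highlights disorder-to-order transitions caused by binding:
#' per residue, N * (pLDDT_bound - pLDDT_unbound), where N is that
#' residue's interface interaction count, pLDDT_bound comes from the
#' binary-complex prediction and pLDDT_unbound from a monomer prediction
#' of the candidate alone. Values can be negative where binding lowers
#' confidence. Higher is better.
#'
#' @param bound_plddt,unbound_plddt [residue_profile()]s of the candidate
#'   chain's pLDDT in the bound complex and the unbound monomer (0-100).
#' @param contacts A `contact_counts` for the same chain.
#' @return A [residue_profile()] of kind `"alphaslim"`.
#' @export
alphaslim_profile <- function(bound_plddt, unbound_plddt, contacts) {
  stopifnot(inherits(bound_plddt, "residue_profile"),
            inherits(unbound_plddt, "residue_profile"),
            inherits(contacts, "contact_counts"))
  n <- length(bound_plddt$values)
  if (length(unbound_plddt$values) != n || length(contacts$counts) != n) {
    stop_slimpae(
      "bound (%d), unbound (%d) and contact (%d) tracks must agree in length",
      "slimpae_dimension_error", n, length(unbound_plddt$values),
      length(contacts$counts))
  }
  if (!identical(bound_plddt$chain, unbound_plddt$chain) ||
      !identical(bound_plddt$chain, contacts$chain)) {
    stop_slimpae("all three tracks must describe the same chain",
                 "slimpae_dimension_error")
  }
  residue_profile(bound_plddt$chain,
                  contacts$counts * (bound_plddt$values - unbound_plddt$values),
                  kind = "alphaslim")
}

#' Normalize scores by the dataset maximum
#'
#' Direct 0-1 normalization for higher-is-better scores (AlphaSLiM, buried
#' surface area): each value divided by the maximum observed value, so the
#' maximum maps to exactly 1.
#'
#' @param values Non-negative numeric vector with at least one positive entry.
#' @return Numeric vector of fractions.
#' @export
normalize_direct <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values) || all(values == 0)) {
    stop_slimpae("need at least one strictly positive value",
                 "slimpae_degenerate_input_error")
  }
  if (any(values < 0)) {
    stop_slimpae("direct normalization expects non-negative values",
                 "slimpae_domain_error")
  }
  values / max(values)
}

#' Normalize lower-is-better scores by inversion
#'
#' For MiniPAE-like scores where lower is better: each score is inverted
#' (1/score), then shifted and scaled as
#' (inv - min(inv)) / max(inv). Note the denominator is the maximum
#' inverse, not the inverse range, so the best (lowest) original score maps
#' to (max(inv) - min(inv)) / max(inv), which is below 1 unless min(inv)
#' is 0; the worst score always maps to 0. This affine form is applied
#' exactly as defined, not rescaled to span `[0, 1]`.
#'
#' @param values Strictly positive numeric vector of length >= 2.
#' @return Numeric vector of normalized scores (higher is better).
#' @export
normalize_inverse <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop_slimpae("need at least two values", "slimpae_degenerate_input_error")
  }
  if (anyNA(values) || any(values <= 0)) {
    stop_slimpae("inverse normalization requires strictly positive scores",
                 "slimpae_domain_error")
  }
  inv <- 1 / values
  (inv - min(inv)) / max(inv)
}

#' Bundle all metrics for one bait-candidate prediction
#'
#' Computes Model Confidence and MiniPAE from the record; when a monomer
#' pLDDT track and a structure are supplied, additionally computes the
#' maximum AlphaSLiM score over the candidate chain. Externally computed
#' metrics (MinD, average-model score, interface area, solvation energy)
#' may be attached as ingested values.
#'
#' @param record A two-chain [prediction_record()].
#' @param candidate_chain Candidate chain label; defaults to the second chain.
#' @param monomer_plddt Optional [residue_profile()]: the candidate's
#'   unbound pLDDT from a monomer prediction.
#' @param structure_path Optional structure for contact counting, or a
#'   ready-made `contact_counts` via `contacts`.
#' @param contacts Optional `contact_counts`; overrides `structure_path`.
#' @param contact_cutoff Heavy-atom cutoff for [contact_counts()] (Angstrom).
#' @param ingested Named numeric vector of externally computed metric
#'   values (names among `MinD`, `avg_model`, `interface_area`, `dG`).
#' @param label `"binder"`, `"non_binder"` or `"unknown"`.
#' @param bait_id,candidate_id Identifiers; default to the chain labels.
#' @return A [scored_pair()].
#' @export
score_pair <- function(record, candidate_chain = NULL, monomer_plddt = NULL,
                       structure_path = NULL, contacts = NULL,
                       contact_cutoff = 4.0, ingested = NULL,
                       label = "unknown", bait_id = NULL, candidate_id = NULL) {
  assert_two_chains(record)
  part <- record$partition
  candidate_chain <- candidate_chain %||% part$chain_ids[2L]
  chain_index(part, candidate_chain)
  bait_chain <- setdiff(part$chain_ids, candidate_chain)

  metrics <- list(
    MC = metric_value("MC", model_confidence(record$ptm, record$iptm)),
    MiniPAE = mini_pae(record)
  )

  if (!is.null(monomer_plddt)) {
    if (is.null(contacts)) {
      if (is.null(structure_path)) {
        stop_slimpae("AlphaSLiM needs contacts or a structure_path",
                     "slimpae_domain_error")
      }
      contacts <- contact_counts(structure_path, candidate_chain,
                                 cutoff = contact_cutoff)
    }
    bound <- residue_profile(
      candidate_chain,
      record$plddt[chain_slice(part, candidate_chain)],
      kind = "plddt")
    asl <- alphaslim_profile(bound, monomer_plddt, contacts)
    metrics$AlphaSLiM_max <- metric_value("AlphaSLiM_max", max(asl$values))
  }

  for (nm in names(ingested)) {
    metrics[[nm]] <- metric_value(nm, ingested[[nm]], derived = FALSE)
  }

  scored_pair(
    pair_id = record$record_id,
    bait_id = bait_id %||% bait_chain,
    candidate_id = candidate_id %||% candidate_chain,
    metrics = metrics,
    label = label
  )
}

#' A scored bait-candidate pair
#'
#' @param pair_id,bait_id,candidate_id Identifiers.
#' @param metrics Named list of [metric_value()] objects.
#' @param label `"binder"`, `"non_binder"` or `"unknown"`.
#' @return An object of class `scored_pair`.
#' @export
scored_pair <- function(pair_id, bait_id, candidate_id, metrics = list(),
                        label = c("unknown", "binder", "non_binder")) {
  label <- match.arg(label)
  stopifnot(all(vapply(metrics, inherits, logical(1), "metric_value")))
  structure(
    list(pair_id = as.character(pair_id), bait_id = as.character(bait_id),
         candidate_id = as.character(candidate_id), metrics = metrics,
         label = label),
    class = "scored_pair"
  )
}

#' @export
print.scored_pair <- function(x, ...) {
  cat(sprintf("<scored_pair> %s (%s vs %s) [%s]\n",
              x$pair_id, x$bait_id, x$candidate_id, x$label))
  for (m in x$metrics) {
    cat(sprintf("  %s = %.4g%s\n", m$name, m$value,
                if (m$derived) "" else " (ingested)"))
  }
  invisible(x)
}

#' Extract one metric from scored pairs, split by label
#'
#' Pairs labelled `"unknown"` are excluded with a message reporting how
#' many were dropped.
#'
#' @param pairs List of [scored_pair()]s.
#' @param metric Metric name.
#' @return List with numeric vectors `binder` and `non_binder`.
#' @export
metric_by_label <- function(pairs, metric = "MiniPAE") {
  lab <- vapply(pairs, function(p) p$label, character(1))
  val <- vapply(pairs, function(p) {
    m <- p$metrics[[metric]]
    if (is.null(m)) NA_real_ else m$value
  }, numeric(1))
  n_unknown <- sum(lab == "unknown")
  if (n_unknown > 0L) {
    message(sprintf("excluding %d pair(s) with label 'unknown'", n_unknown))
  }
  list(binder = val[lab == "binder" & !is.na(val)],
       non_binder = val[lab == "non_binder" & !is.na(val)])
}
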