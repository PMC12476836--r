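#' Construct a prediction record for one AlphaFold binary-complex model
#'
#' A `prediction_record` is the dialect-neutral container the scoring and
#' motif modules operate on: the L x L predicted aligned error (PAE) matrix
#' (row = residue the prediction is aligned on, column = scored residue),
#' the per-residue pLDDT track on the 0-100 scale, the global pTM and ipTM
#' fractions, and the chain partition splitting the concatenated axis into
#' bait and candidate.
#'
#' @param record_id Identifier for the prediction.
#' @param partition A [chain_partition()].
#' @param pae Square numeric matrix, dimension `partition_length(partition)`,
#'   entries in `[0, max_pae]` Angstrom. Kept asymmetric as emitted.
#' @param plddt Numeric vector of per-residue confidence in `[0, 100]`.
#' @param ptm,iptm Global predicted TM-scores in `[0, 1]`.
#' @param max_pae Upper bound of the PAE scale (Angstrom).
#' @param dialect `"af2_colabfold"` or `"af3_server"`.
#' @param model_rank Positive integer rank of this model among the models
#'   of its prediction run (1 = best).
#' @return An object of class `prediction_record`.
#' @seealso [read_colabfold_record()], [read_af3_record()], [mini_pae()]
#' @export
prediction_record <- function(record_id, partition, pae, plddt, ptm, iptm,
                              max_pae = 31.75, dialect = "af2_colabfold",
                              model_rank = 1L) {
  stopifnot(inherits(partition, "chain_partition"))
  pae <- as.matrix(pae)
  L <- partition_length(partition)
  if (nrow(pae) != ncol(pae)) {
    stop_slimpae("PAE matrix must be square, got %d x %d",
                 "slimpae_dimension_error", nrow(pae), ncol(pae))
  }
  if (nrow(pae) != L) {
    stop_slimpae(
      "chain lengths sum to %d but PAE matrix has dimension %d",
      "slimpae_dimension_error", L, nrow(pae))
  }
  assert_scalar_number(max_pae, "max_pae", lo = 0)
  if (anyNA(pae) || any(pae < 0) || any(pae > max_pae + 1e-6)) {
    stop_slimpae("PAE entries must lie in [0, %g]", "slimpae_domain_error", max_pae)
  }
  plddt <- as.numeric(plddt)
  if (length(plddt) != L) {
    stop_slimpae("plddt has length %d, expected %d",
                 "slimpae_dimension_error", length(plddt), L)
  }
  if (anyNA(plddt) || any(plddt < 0) || any(plddt > 100)) {
    stop_slimpae("plddt entries must lie in [0, 100]", "slimpae_domain_error")
  }
  assert_scalar_number(ptm, "ptm", 0, 1)
  assert_scalar_number(iptm, "iptm", 0, 1)
  dialect <- match.arg(dialect, c("af2_colabfold", "af3_server"))
  model_rank <- as.integer(model_rank)
  stopifnot(length(model_rank) == 1L, model_rank >= 1L)
  structure(
    list(
      record_id = as.character(record_id),
      partition = partition,
      pae = unname(pae),
      plddt = plddt,
      ptm = as.numeric(ptm),
      iptm = as.numeric(iptm),
      max_pae = as.numeric(max_pae),
      dialect = dialect,
      model_rank = model_rank
    ),
    class = "prediction_record"
  )
}

#' @export
print.prediction_record <- function(x, ...) {
  cat(sprintf("<prediction_record> %s [%s, rank %d]\n",
              x$record_id, x$dialect, x$model_rank))
  cat("  chains:",
      paste(sprintf("%s (%d)", x$partition$chain_ids, x$partition$chain_lengths),
            collapse = " + "), "\n")
  cat(sprintf("  pTM %.3f | ipTM %.3f | max PAE %.2f A\n",
              x$ptm, x$iptm, x$max_pae))
  invisible(x)
}

n_chains <- function(record) length(record$partition$chain_ids)

assert_two_chains <- function(record) {
  if (!inherits(record, "prediction_record")) {
    stop_slimpae("expected a prediction_record", "slimpae_type_error")
  }
  if (n_chains(record) != 2L) {
    stop_slimpae(
      "inter-chain scoring requires exactly 2 chains (bait + candidate), got %d",
      "slimpae_chain_count_error", n_chains(record))
  }
  invisible(record)
}

#' Per-residue profile along one chain
#'
#' A thin container pairing one number per residue of a chain with the kind
#' of quantity it holds (e.g. the minimum inter-chain PAE track, a pLDDT
#' track, or an AlphaSLiM score track).
#'
#' @param chain Chain label the values belong to.
#' @param values Numeric vector, one entry per residue of that chain.
#' @param kind What the values are; one of `"min_inter_pae"`,
#'   `"delta_plddt"`, `"alphaslim"`, `"plddt"`, `"bsa"`, `"custom"`.
#' @return An object of class `residue_profile`.
#' @export
residue_profile <- function(chain, values,
                            kind = c("custom", "min_inter_pae", "delta_plddt",
                                     "alphaslim", "plddt", "bsa")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop_slimpae("profile must hold at least one residue", "slimpae_dimension_error")
  }
  if (kind != "min_inter_pae" && any(!is.finite(values))) {
    stop_slimpae("profile values must be finite", "slimpae_domain_error")
  }
  structure(list(chain = as.character(chain), values = values, kind = kind),
            class = "residue_profile")
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> chain %s, kind %s, %d residues (range %.3g..%.3g)\n",
              x$chain, x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.residue_profile <- function(x) length(x$values)
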