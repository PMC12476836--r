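#' Chain partition of a concatenated residue axis
#'
#' AlphaFold scores a binary complex on a single concatenated residue axis;
#' a chain partition records where each chain starts and ends on that axis.
#' Offsets are 0-based cumulative starts (array convention); residue
#' positions reported to the user are always 1-based within their chain
#' (biological convention).
#'
#' @param chain_ids Character vector of chain labels, in concatenation order.
#' @param chain_lengths Integer vector of residue counts, one per chain.
#' @return An object of class `chain_partition` with fields `chain_ids`,
#'   `chain_lengths` and `offsets` (0-based start of each chain).
#' @examples
#' part <- chain_partition(c("A", "B"), c(20, 10))
#' part$offsets  # 0 20
#' @export
chain_partition <- function(chain_ids, chain_lengths) {
  chain_ids <- as.character(chain_ids)
  chain_lengths <- as.integer(chain_lengths)
  if (length(chain_ids) != length(chain_lengths) || length(chain_ids) < 1L) {
    stop_slimpae("chain_ids and chain_lengths must be non-empty and of equal length",
                 "slimpae_partition_error")
  }
  if (anyDuplicated(chain_ids)) {
    stop_slimpae("duplicate chain labels: %s", "slimpae_partition_error",
                 paste(chain_ids[duplicated(chain_ids)], collapse = ", "))
  }
  if (any(chain_lengths < 1L)) {
    stop_slimpae("all chain lengths must be >= 1", "slimpae_partition_error")
  }
  structure(
    list(
      chain_ids = chain_ids,
      chain_lengths = chain_lengths,
      offsets = c(0L, cumsum(chain_lengths))[seq_along(chain_ids)]
    ),
    class = "chain_partition"
  )
}

#' Total residue count of a partition
#' @param part A `chain_partition`.
#' @return Integer, the summed chain length L.
#' @export
partition_length <- function(part) {
  stopifnot(inherits(part, "chain_partition"))
  sum(part$chain_lengths)
}

chain_index <- function(part, chain) {
  k <- match(chain, part$chain_ids)
  if (is.na(k)) {
    stop_slimpae("chain '%s' not present (chains: %s)", "slimpae_lookup_error",
                 chain, paste(part$chain_ids, collapse = ", "))
  }
  k
}

#' Concatenated indices covered by one chain
#'
#' @param part A `chain_partition`.
#' @param chain Chain label.
#' @return Integer vector of 1-based indices into the concatenated axis
#'   (usable directly for matrix subsetting).
#' @export
chain_slice <- function(part, chain) {
  k <- chain_index(part, chain)
  part$offsets[k] + seq_len(part$chain_lengths[k])
}

#' Map a concatenated index to (chain, within-chain position)
#'
#' @param part A `chain_partition`.
#' @param index 1-based index on the concatenated axis.
#' @return List with `chain` (label) and `pos` (1-based within-chain).
#' @export
index_to_chain_pos <- function(part, index) {
  index <- as.integer(index)
  L <- partition_length(part)
  if (any(index < 1L | index > L)) {
    stop_slimpae("index out of range 1..%d", "slimpae_lookup_error", L)
  }
  k <- findInterval(index - 1L, part$offsets)
  list(chain = part$chain_ids[k], pos = index - part$offsets[k])
}

#' Map (chain, within-chain position) to a concatenated index
#'
#' Inverse of [index_to_chain_pos()]; the two round-trip exactly.
#'
#' @param part A `chain_partition`.
#' @param chain Chain label.
#' @param pos 1-based within-chain position.
#' @return 1-based concatenated index.
#' @export
chain_pos_to_index <- function(part, chain, pos) {
  k <- chain_index(part, chain)
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > part$chain_lengths[k])) {
    stop_slimpae("position out of range 1..%d for chain '%s'",
                 "slimpae_lookup_error", part$chain_lengths[k], chain)
  }
  part$offsets[k] + pos
}

#' @export
print.chain_partition <- function(x, ...) {
  cat("Chain partition:",
      paste(sprintf("%s (%d)", x$chain_ids, x$chain_lengths), collapse = " + "),
      sprintf("= %d residues\n", partition_length(x)))
  invisible(x)
}
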