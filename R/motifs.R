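#' A localized SLiM candidate
#'
#' @param record_id Identifier of the prediction the call comes from.
#' @param chain Candidate chain label.
#' @param start,end 1-based inclusive within-chain coordinates.
#' @param anchor 1-based position of the minimum-PAE (or maximum-AlphaSLiM)
#'   residue; `start <= anchor <= end`.
#' @param score MiniPAE for PAE-based calls (lower is better), maximum
#'   AlphaSLiM for pLDDT-difference calls (higher is better).
#' @param method `"minipae"` or `"alphaslim"`.
#' @param sequence Optional amino-acid string of length `end - start + 1`.
#' @param passed Optional logical set by [filter_calls()].
#' @return An object of class `motif_call`.
#' @export
motif_call <- function(record_id, chain, start, end, anchor, score,
                       method = c("minipae", "alphaslim"),
                       sequence = NULL, passed = NULL) {
  method <- match.arg(method)
  start <- as.integer(start); end <- as.integer(end); anchor <- as.integer(anchor)
  if (!(1L <= start && start <= anchor && anchor <= end)) {
    stop_slimpae("need 1 <= start <= anchor <= end (got %d, %d, %d)",
                 "slimpae_domain_error", start, anchor, end)
  }
  if (!is.null(sequence) && nchar(sequence) != end - start + 1L) {
    stop_slimpae("sequence length %d != motif span %d", "slimpae_dimension_error",
                 nchar(sequence), end - start + 1L)
  }
  structure(
    list(record_id = as.character(record_id), chain = as.character(chain),
         start = start, end = end, anchor = anchor, score = as.numeric(score),
         sequence = sequence, method = method, passed = passed),
    class = "motif_call"
  )
}

#' @export
print.motif_call <- function(x, ...) {
  cat(sprintf("<motif_call> %s chain %s %d-%d (anchor %d) %s=%.3g%s%s\n",
              x$record_id, x$chain, x$start, x$end, x$anchor,
              if (x$method == "minipae") "MiniPAE" else "AlphaSLiM",
              x$score,
              if (!is.null(x$sequence)) paste0(" ", x$sequence) else "",
              if (is.null(x$passed)) "" else if (x$passed) " [pass]" else " [fail]"))
  invisible(x)
}

#' Localize the MiniPAE motif of a binary-complex prediction
#'
#' The candidate chain's minimum inter-chain PAE profile is computed; the
#' anchor is its arg-min (first occurrence on ties), and the motif is the
#' maximal contiguous run of residues containing the anchor whose profile
#' values lie within `delta` of the global minimum (MiniPAE). The call is
#' scored by MiniPAE itself. By construction one call is returned per
#' record; with `all_islands = TRUE`, every maximal run of residues within
#' the delta band is returned (sorted by its own minimum, ascending).
#'
#' @param record A two-chain [prediction_record()].
#' @param candidate_chain Candidate chain label; defaults to the second chain.
#' @param delta Band width above the minimum, in Angstrom (default 3.0).
#' @param all_islands Return secondary low-PAE islands as extra calls.
#' @return A `motif_call` (or a list of them when `all_islands = TRUE`).
#' @export
call_motif_minipae <- function(record, candidate_chain = NULL, delta = 3.0,
                               all_islands = FALSE) {
  assert_two_chains(record)
  candidate_chain <- candidate_chain %||% record$partition$chain_ids[2L]
  assert_scalar_number(delta, "delta", lo = 0)
  prof <- min_inter_pae_profile(record, candidate_chain)
  v <- prof$values
  minipae <- min(v)
  in_band <- v <= minipae + delta

  runs <- band_runs(in_band)
  anchor <- which.min(v)  # first occurrence on ties
  main <- runs[runs$start <= anchor & anchor <= runs$end, , drop = FALSE]

  make_call <- function(s, e) {
    a <- s - 1L + which.min(v[s:e])
    motif_call(record$record_id, candidate_chain, s, e, a,
               score = min(v[s:e]), method = "minipae")
  }
  main_call <- motif_call(record$record_id, candidate_chain,
                          main$start, main$end, anchor,
                          score = minipae, method = "minipae")
  if (!all_islands) return(main_call)

  others <- runs[!(runs$start == main$start & runs$end == main$end), , drop = FALSE]
  calls <- c(list(main_call),
             lapply(seq_len(nrow(others)),
                    function(i) make_call(others$start[i], others$end[i])))
  calls[order(vapply(calls, function(cl) cl$score, numeric(1)))]
}

band_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Call motifs from an AlphaSLiM profile
#'
#' Motif regions are the maximal contiguous runs of strictly positive
#' AlphaSLiM values (residues whose pLDDT rises on binding and that touch
#' the interface), each scored by its maximum AlphaSLiM value. Calls are
#' returned sorted by score, descending.
#'
#' @param profile A [residue_profile()] of kind `"alphaslim"`.
#' @param record_id Identifier attached to the calls.
#' @return List of `motif_call`s (possibly empty).
#' @export
call_motif_alphaslim <- function(profile, record_id = "alphaslim") {
  stopifnot(inherits(profile, "residue_profile"))
  if (profile$kind != "alphaslim") {
    stop_slimpae("profile kind must be 'alphaslim', got '%s'",
                 "slimpae_type_error", profile$kind)
  }
  v <- profile$values
  runs <- band_runs(v > 0)
  calls <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    a <- s - 1L + which.max(v[s:e])
    motif_call(record_id, profile$chain, s, e, a,
               score = max(v[s:e]), method = "alphaslim")
  })
  calls[order(-vapply(calls, function(cl) cl$score, numeric(1)))]
}

#' Screen-size-adaptive MiniPAE threshold
#'
#' The published power-law calibration of the expected minimum MiniPAE
#' among n non-binders: threshold(n) = 30.29 n^-0.2803 - 3.82 (Angstrom).
#' Larger screens therefore use stricter cutoffs; at n = 220 the threshold
#' is ~2.86 A. Strictly decreasing in n, approaching -3.82 as n grows.
#'
#' @param n Number of candidate predictions in the screen (>= 1).
#' @return Threshold in Angstrom.
#' @examples
#' adaptive_threshold(220)
#' @seealso [fit_power_law()] to refit the calibration on your own
#'   non-binder pool, [predict_threshold()] to evaluate the refitted model.
#' @export
adaptive_threshold <- function(n) {
  if (!is.numeric(n) || any(!is.finite(n)) || any(n < 1)) {
    stop_slimpae("screen size n must be >= 1", "slimpae_domain_error")
  }
  30.29 * n^(-0.2803) - 3.82
}

#' Filter motif calls by the adaptive MiniPAE threshold
#'
#' Calls with score <= threshold pass (a call exactly at threshold is
#' retained). The threshold is [adaptive_threshold()] at the screen size
#' `n`, unless an explicit `override_threshold` is given. Every call's
#' `passed` flag is set; by default only passing calls are returned, in
#' their input order.
#'
#' @param calls List of `motif_call`s with method `"minipae"`.
#' @param n Screen size for the adaptive threshold.
#' @param override_threshold Optional explicit threshold (Angstrom);
#'   required when mixing methods.
#' @param keep_all Return all calls (annotated) instead of only passing ones.
#' @return List of `motif_call`s with `passed` set.
#' @export
filter_calls <- function(calls, n = NULL, override_threshold = NULL,
                         keep_all = FALSE) {
  if (length(calls) == 0L) return(list())
  stopifnot(all(vapply(calls, inherits, logical(1), "motif_call")))
  methods <- unique(vapply(calls, function(cl) cl$method, character(1)))
  if (is.null(override_threshold)) {
    if (length(methods) > 1L || methods != "minipae") {
      stop_slimpae(
        "adaptive filtering applies to MiniPAE calls only; pass override_threshold",
        "slimpae_method_mismatch_error")
    }
    if (is.null(n)) {
      stop_slimpae("supply the screen size n or an override_threshold",
                   "slimpae_domain_error")
    }
    thr <- adaptive_threshold(n)
  } else {
    thr <- assert_scalar_number(override_threshold, "override_threshold")
  }
  calls <- lapply(calls, function(cl) {
    cl$passed <- cl$score <= thr
    cl
  })
  if (keep_all) calls else Filter(function(cl) cl$passed, calls)
}

#' Attach amino-acid sequences to motif calls
#'
#' Populates each call's `sequence` by 1-based inclusive slicing of the
#' chain's sequence. Calls whose chain is absent from `sequences` are left
#' untouched (sequence output as "." downstream).
#'
#' @param calls List of `motif_call`s.
#' @param sequences Named character vector mapping chain label (or record
#'   id, checked second) to an amino-acid string.
#' @return The calls, with sequences filled in where available.
#' @export
attach_sequences <- function(calls, sequences) {
  lapply(calls, function(cl) {
    seq <- if (cl$chain %in% names(sequences)) {
      sequences[[cl$chain]]
    } else if (cl$record_id %in% names(sequences)) {
      sequences[[cl$record_id]]
    }
    if (is.null(seq)) return(cl)
    if (cl$end > nchar(seq)) {
      stop_slimpae(
        "sequence for chain '%s' has %d residues but the call ends at %d",
        "slimpae_dimension_error", cl$chain, nchar(seq), cl$end)
    }
    cl$sequence <- substr(seq, cl$start, cl$end)
    cl
  })
}
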