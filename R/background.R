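#' Sample a matched background intron set
#'
#' For every retained intron draws, uniformly at random and without
#' replacement, one intron of similar length (within \code{len_window}
#' relative), similar GC content (within \code{gc_window} as an absolute
#' difference in fraction, i.e. 5 percentage points by default) and identical
#' internal pA-tract length, from genes that show no retention. Retained
#' introns with an empty candidate set are reported as unmatched, never
#' silently dropped.
#'
#' @param retained data.frame of retained introns with columns \code{gene_id},
#'   \code{intron_index}, \code{length}, \code{gc_fraction},
#'   \code{max_pa_tract} (see [intron_features()]).
#' @param pool candidate intron data.frame with the same columns; genes with
#'   any passed retention call must already be excluded, and any pool rows
#'   from genes present in \code{retained} are dropped defensively.
#' @param gc_window maximum absolute GC-fraction difference (default 0.05).
#' @param len_window maximum relative length difference (default 0.05).
#' @param seed RNG seed for reproducible pairing (optional; uses the current
#'   RNG state when NULL).
#' @return list: \code{pairs} (data.frame with retained and matched background
#'   columns plus \code{length_ratio}, \code{gc_delta}) and \code{unmatched}
#'   (rows of \code{retained} with no candidate).
#' @export
sample_matched_background <- function(retained, pool, gc_window = 0.05,
                                      len_window = 0.05, seed = NULL) {
  need <- c("gene_id", "intron_index", "length", "gc_fraction",
            "max_pa_tract")
  stopifnot(all(need %in% names(retained)), all(need %in% names(pool)))
  pool <- pool[!(pool$gene_id %in% retained$gene_id), , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  used <- logical(nrow(pool))
  pair_idx <- rep(NA_integer_, nrow(retained))
  for (i in seq_len(nrow(retained))) {
    cand <- which(!used &
      abs(pool$gc_fraction - retained$gc_fraction[i]) <= gc_window &
      abs(pool$length - retained$length[i]) <=
        len_window * retained$length[i] &
      pool$max_pa_tract == retained$max_pa_tract[i])
    if (length(cand) == 0L) next
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    pair_idx[i] <- pick
    used[pick] <- TRUE
  }
  ok <- !is.na(pair_idx)
  b <- pool[pair_idx[ok], , drop = FALSE]
  r <- retained[ok, , drop = FALSE]
  pairs <- data.frame(
    gene_id = r$gene_id, intron_index = r$intron_index,
    length = r$length, gc_fraction = r$gc_fraction,
    pa_len_retained = r$max_pa_tract,
    bg_gene_id = b$gene_id, bg_intron_index = b$intron_index,
    bg_length = b$length, bg_gc_fraction = b$gc_fraction,
    pa_len_background = b$max_pa_tract,
    length_ratio = b$length / r$length,
    gc_delta = abs(b$gc_fraction - r$gc_fraction),
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched = retained[!ok, , drop = FALSE])
}
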