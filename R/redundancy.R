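#' Alignment scoring parameters
#'
#' Scoring for the exact global (end-to-end, Needleman--Wunsch/Gotoh)
#' alignment underlying identity filtering. A gap run of length g costs
#' `gap_open + g * gap_extend`. Defaults: match 1, mismatch 0, gap open -5,
#' gap extend -1.
#'
#' @param match_score score for an identical aligned pair (> mismatch).
#' @param mismatch_score score for a non-identical aligned pair.
#' @param gap_open gap-opening penalty (<= 0).
#' @param gap_extend per-position gap penalty (<= 0).
#' @return An `alignment_params` list.
#' @export
alignment_params <- function(match_score = 1, mismatch_score = 0,
                             gap_open = -5, gap_extend = -1) {
  if (match_score <= mismatch_score) stop("match_score must exceed mismatch_score")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Pairwise sequence identity
#'
#' Optimal global alignment under `p` (maximizing score; among co-optimal
#' alignments, maximizing identities), normalized by the shorter sequence:
#' `sim = matches / min(|a|, |b|)`. Symmetric in its arguments.
#'
#' @param a,b residue strings (or single-row `protein_dataset`s).
#' @param p an [alignment_params()].
#' @return List with `sim` in `[0, 1]`, integer `matches`, `min_len`, and the
#'   alignment `score`.
#' @export
pairwise_similarity <- function(a, b, p = alignment_params()) {
  a <- as_residues(a); b <- as_residues(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- cpp_global_align(a, b, p$match_score, p$mismatch_score,
                        p$gap_open, p$gap_extend)
  min_len <- min(nchar(a), nchar(b))
  list(sim = r$matches / min_len, matches = as.integer(r$matches),
       min_len = as.integer(min_len), score = r$score)
}

as_residues <- function(x) {
  if (inherits(x, "protein_dataset")) {
    stopifnot(nrow(x) == 1L)
    return(x$residues)
  }
  as.character(x)
}

# exact upper bound on sim(a, b): any alignment matches each residue type at
# most min(count_a, count_b) times, so matches <= sum over residues of the
# composition overlap. Used to skip the full DP for provably dissimilar pairs
# (this is a provable bound, not CD-HIT's lossy k-mer heuristic).
composition_bound <- function(counts_a, counts_b, min_len) {
  sum(pmin(counts_a, counts_b)) / min_len
}

residue_counts <- function(s) {
  tabulate(match(strsplit(s, "")[[1]], AA_ALPHABET), nbins = 20L)
}

#' Greedy identity-based redundancy filtering
#'
#' CD-HIT-style greedy incremental clustering with exact alignment
#' semantics: sequences are processed in descending length order (ties
#' broken by lexicographic id); each sequence joins the first existing
#' representative with similarity >= `threshold`, otherwise it founds a new
#' cluster. Only representatives are retained, so every retained pair has
#' similarity below the threshold.
#'
#' @param ds a `protein_dataset`.
#' @param threshold identity threshold in (0, 1]; default 0.90.
#' @param p an [alignment_params()].
#' @return List with `dataset` (representatives, input order preserved) and
#'   `report` (class `cluster_report`: `representatives` ids, `removed` named
#'   map removed-id -> representative-id, `threshold`).
#' @export
filter_redundant <- function(ds, threshold = 0.90, p = alignment_params()) {
  stopifnot(inherits(ds, "protein_dataset"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("`threshold` must be in (0, 1]")
  }
  ord <- order(-nchar(ds$residues), ds$id)
  reps <- integer(0)          # row indices of representatives, creation order
  counts <- vector("list", nrow(ds))
  removed <- character(0); removed_to <- character(0)
  for (i in ord) {
    counts[[i]] <- residue_counts(ds$residues[i])
    assigned <- FALSE
    for (r in reps) {
      ml <- min(nchar(ds$residues[i]), nchar(ds$residues[r]))
      if (composition_bound(counts[[i]], counts[[r]], ml) < threshold) next
      s <- pairwise_similarity(ds$residues[i], ds$residues[r], p)
      if (s$sim >= threshold) {
        removed <- c(removed, ds$id[i])
        removed_to <- c(removed_to, ds$id[r])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) reps <- c(reps, i)
  }
  keep <- sort(reps)
  out <- protein_dataset(ds$id[keep], ds$residues[keep], ds$label[keep])
  report <- structure(
    list(representatives = ds$id[keep],
         removed = stats::setNames(removed_to, removed),
         threshold = threshold),
    class = "cluster_report")
  list(dataset = out, report = report)
}

#' Serialize a cluster report as JSON
#' @param report a `cluster_report` from [filter_redundant()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(report, path) {
  jsonlite::write_json(
    list(threshold = report$threshold,
         representatives = report$representatives,
         removed = as.list(report$removed)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
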