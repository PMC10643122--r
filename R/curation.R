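#' @importFrom Biostrings pairwiseAlignment nmatch
NULL

#' Curation parameters for homolog-set assembly
#'
#' Defaults reproduce the family-curation recipe used throughout the
#' package's analyses: homology hits kept at e-value \eqn{\le 10^{-20}} and
#' query coverage \eqn{\ge 40}\%, redundancy reduced at a 0.8 pairwise
#' identity cutoff.
#'
#' @param e_max maximum e-value (must be > 0).
#' @param cov_min minimum query coverage, percent in (0, 100].
#' @param identity_threshold greedy-clustering identity cutoff, fraction
#'   in (0, 1].
#' @return A validated list of class `curation_params`.
#' @export
curation_params <- function(e_max = 1e-20, cov_min = 40, identity_threshold = 0.8) {
  if (!is.numeric(e_max) || e_max <= 0) stop("e_max must be > 0", call. = FALSE)
  if (!is.numeric(cov_min) || cov_min <= 0 || cov_min > 100) {
    stop("cov_min must be in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(e_max = e_max, cov_min = cov_min,
                 identity_threshold = identity_threshold),
            class = "curation_params")
}

#' Filter homology hits by significance and coverage
#'
#' Keeps subjects with `e_value <= e_max` and `query_coverage >= cov_min`.
#' Input order is preserved and duplicate subject ids are collapsed to
#' their first occurrence.
#'
#' @param hits a hit table from [read_hit_table()].
#' @param params a [curation_params()].
#' @return Character vector of retained subject ids (possibly empty).
#' @export
filter_hits <- function(hits, params = curation_params()) {
  stopifnot(is.data.frame(hits))
  keep <- hits$e_value <= params$e_max & hits$query_coverage >= params$cov_min
  unique(hits$subject_id[keep])
}

#' Collapse exact-sequence duplicates
#'
#' @param seqs a [homolog_set()].
#' @return The subset with the first-seen record per distinct sequence.
#' @export
dedupe <- function(seqs) {
  stopifnot(is.data.frame(seqs))
  out <- seqs[!duplicated(seqs$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise sequence identity
#'
#' Global (Needleman-Wunsch) alignment with match 1, mismatch 0 and linear
#' gap penalty -1, purely to locate matched positions; identity is the
#' number of identical aligned positions divided by the shorter sequence's
#' length. This is the convention of greedy redundancy-reduction tools,
#' where a short sequence fully contained in a longer one scores 1.
#'
#' @param a,b amino-acid sequences (strings) or single-row homolog sets.
#' @return Identity fraction in \[0, 1\]; symmetric in its arguments.
#' @export
pairwise_identity <- function(a, b) {
  seq_of <- function(x) if (is.data.frame(x)) x$sequence[1] else as.character(x)
  sa <- seq_of(a); sb <- seq_of(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("empty sequence", call. = FALSE)
  alphabet <- c(AA_ALPHABET, "*")
  mat <- matrix(0, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::nmatch(aln) / min(nchar(sa), nchar(sb))
}

#' Greedy identity-based redundancy reduction
#'
#' CD-HIT-style greedy scheme: sequences are sorted by length descending
#' (ties broken lexicographically by id); each sequence joins the first
#' existing representative with which its identity exceeds `threshold`,
#' otherwise it founds a new cluster. Cluster founders are returned as
#' representatives.
#'
#' @param seqs a [homolog_set()].
#' @param threshold identity cutoff in (0, 1]; membership requires
#'   identity strictly greater than this value.
#' @return The representatives as a homolog set, with an attribute
#'   `clusters`: a named character vector mapping every input id to its
#'   founder's id.
#' @export
greedy_cluster <- function(seqs, threshold = 0.8) {
  stopifnot(is.data.frame(seqs))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]", call. = FALSE)
  ord <- order(-nchar(seqs$sequence), seqs$id)
  sorted <- seqs[ord, , drop = FALSE]
  founders <- integer(0)          # row indices into `sorted`
  assign <- character(nrow(sorted))
  names(assign) <- sorted$id
  for (i in seq_len(nrow(sorted))) {
    placed <- FALSE
    for (f in founders) {
      if (pairwise_identity(sorted$sequence[i], sorted$sequence[f]) > threshold) {
        assign[i] <- sorted$id[f]
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      founders <- c(founders, i)
      assign[i] <- sorted$id[i]
    }
  }
  reps <- sorted[founders, , drop = FALSE]
  rownames(reps) <- NULL
  attr(reps, "clusters") <- assign
  reps
}

#' Run the full curation recipe
#'
#' Significance/coverage filtering of the hit table, restriction of the
#' sequence set to retained ids, removal of an explicit blocklist (the
#' manual "poorly aligning" call), exact-duplicate removal, then greedy
#' redundancy reduction.
#'
#' @param hits hit table ([read_hit_table()]).
#' @param seqs candidate sequences ([homolog_set()]); ids must match the
#'   hit table's subject ids.
#' @param params a [curation_params()].
#' @param exclude character vector of ids to drop regardless of the
#'   automatic filters.
#' @return Curated representatives (homolog set), with attributes
#'   `clusters` (from [greedy_cluster()]) and `counts` (records surviving
#'   each stage).
#' @export
curate <- function(hits, seqs, params = curation_params(), exclude = NULL) {
  keep_ids <- filter_hits(hits, params)
  stage1 <- seqs[seqs$id %in% keep_ids, , drop = FALSE]
  stage2 <- stage1[!stage1$id %in% exclude, , drop = FALSE]
  stage3 <- dedupe(stage2)
  reps <- greedy_cluster(stage3, params$identity_threshold)
  attr(reps, "counts") <- c(input = nrow(seqs), filtered = nrow(stage1),
                            after_blocklist = nrow(stage2),
                            deduped = nrow(stage3), representatives = nrow(reps))
  reps
}
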