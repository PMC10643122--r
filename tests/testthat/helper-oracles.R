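# Independent brute-force oracles and small fixture builders.

random_seq <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H", "I",
                                       "K", "L", "M", "N", "P", "Q", "R", "S",
                                       "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force patch oracle: enumerate every window, take the union of
# qualifying windows as a per-position coverage set, split into runs,
# trim each run to its basic residues
oracle_scan_patches <- function(segment, window = 4L, min_basic = 3L,
                                basic_set = c("K", "R", "H")) {
  chars <- strsplit(toupper(segment), "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(data.frame(start = integer(0), end = integer(0)))
  basic <- chars %in% basic_set
  covered <- rep(FALSE, n)
  for (s in 1:(n - window + 1L)) {
    idx <- s:(s + window - 1L)
    if (sum(basic[idx]) >= min_basic) covered[idx] <- TRUE
  }
  if (!any(covered)) return(data.frame(start = integer(0), end = integer(0)))
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (covered[i]) {
      j <- i
      while (j < n && covered[j + 1L]) j <- j + 1L
      b <- which(basic[i:j]) + i - 1L
      runs[[length(runs) + 1L]] <- c(min(b), max(b))
      i <- j + 1L
    } else i <- i + 1L
  }
  out <- do.call(rbind, runs)
  data.frame(start = out[, 1], end = out[, 2])
}

# exhaustive greedy-clustering oracle: apply the definition literally on a
# precomputed identity matrix (no shortcut through greedy_cluster)
oracle_greedy <- function(seqs, threshold) {
  ord <- order(-nchar(seqs$sequence), seqs$id)
  sorted <- seqs[ord, , drop = FALSE]
  n <- nrow(sorted)
  idm <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    idm[i, j] <- lrrksig::pairwise_identity(sorted$sequence[i], sorted$sequence[j])
  }
  founders <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (f in founders) {
      if (idm[i, f] > threshold) { hit <- f; break }
    }
    if (hit == 0L) { founders <- c(founders, i); assign[i] <- i }
    else assign[i] <- hit
  }
  list(founder_ids = sorted$id[founders],
       assign = stats::setNames(sorted$id[assign], sorted$id),
       idm = idm, order_ids = sorted$id)
}

# default clade layout with a larger half-probability patch clade, for
# binomial-bound checks on planting fractions
.default_clades_for_test <- function() {
  cl <- lrrksig:::.default_clades()
  cl$LRRK2$n <- 40L
  cl$LRRK2$patch_prob <- c(patch1 = 0.5, patch2 = 1, patch3 = 1)
  cl
}

tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
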