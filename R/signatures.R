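# Motif-anchored structural-signature measurements: boundary-element
# location, intervening-residue counts, basic-patch detection, key-residue
# calls and consensus-column frequencies.

DEFAULT_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y", "C")
DEFAULT_BASIC <- c("K", "R", "H")

#' Compile a degenerate motif pattern
#'
#' The motif language used for boundary elements: uppercase letters match
#' themselves, `x` matches any residue, `ϕ` (or its ASCII alias `h`)
#' matches the hydrophobic class, and a bracketed set such as `[ST]`
#' matches any listed residue. Example: `"WxxGϕxϕ"`, the conserved
#' C-terminal boundary element of the COR-B loop region.
#'
#' @param pattern motif string.
#' @param hydrophobic residues matched by the hydrophobic class
#'   (default A, V, L, I, M, F, W, Y, C).
#' @return A list of class `motif` with the token list, compiled regular
#'   expression and motif length (in residues).
#' @export
compile_motif <- function(pattern, hydrophobic = DEFAULT_HYDROPHOBIC) {
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern)) {
    stop("pattern must be a non-empty string", call. = FALSE)
  }
  if (nchar(pattern) < 3) stop("motif pattern must cover at least 3 characters", call. = FALSE)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  tokens <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA_ALPHABET) {
          stop("motif pattern error: illegal residue '", chars[j],
               "' in bracketed set", call. = FALSE)
        }
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("motif pattern error: unclosed '['", call. = FALSE)
      if (length(set) == 0) stop("motif pattern error: empty bracketed set", call. = FALSE)
      tokens[[length(tokens) + 1L]] <- set
      i <- j + 1L
    } else if (ch == "x") {
      tokens[[length(tokens) + 1L]] <- "any"
      i <- i + 1L
    } else if (ch == "ϕ" || ch == "φ" || ch == "h") {
      tokens[[length(tokens) + 1L]] <- hydrophobic
      i <- i + 1L
    } else if (ch %in% setdiff(AA_ALPHABET, "X")) {
      tokens[[length(tokens) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("motif pattern error: illegal symbol '", ch, "'", call. = FALSE)
    }
  }
  rx_parts <- vapply(tokens, function(tok) {
    if (identical(tok, "any")) "." else if (length(tok) == 1) tok
    else paste0("[", paste(tok, collapse = ""), "]")
  }, character(1))
  structure(list(pattern = pattern, tokens = tokens,
                 regex = paste(rx_parts, collapse = ""),
                 length = length(tokens)),
            class = "motif")
}

#' Find all (possibly overlapping) motif match positions
#' @param motif a compiled [compile_motif()] (a pattern string is accepted
#'   and compiled on the fly).
#' @param seq amino-acid sequence.
#' @return Integer vector of 1-based match start positions (may be empty).
#' @export
motif_matches <- function(motif, seq) {
  if (!inherits(motif, "motif")) motif <- compile_motif(motif)
  seq <- if (is.data.frame(seq)) seq$sequence[1] else as.character(seq)
  m <- gregexpr(paste0("(?=", motif$regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Declare a boundary-element anchor
#'
#' An anchor is a short well-conserved motif flanking a variable region.
#' When `expected_position` is given, the match whose start is nearest to
#' it (within `search_window` residues) is chosen; equidistant candidates
#' resolve to the more N-terminal match. `manual_position` overrides the
#' search entirely — the escape hatch for homologs where the element sits
#' far from its usual position and must be placed by inspection.
#'
#' @param name anchor name.
#' @param pattern motif string (see [compile_motif()]).
#' @param expected_position optional 1-based residue index near which the
#'   match is expected.
#' @param search_window half-width, in residues, of the window around
#'   `expected_position` (default 300, wide enough to absorb large
#'   clade-specific offsets).
#' @param manual_position optional 1-based index that bypasses the search.
#' @return A list of class `anchor_spec`.
#' @export
anchor_spec <- function(name, pattern, expected_position = NULL,
                        search_window = 300, manual_position = NULL) {
  motif <- compile_motif(pattern)
  if (search_window <= 0) stop("search_window must be > 0", call. = FALSE)
  structure(list(name = name, pattern = pattern, motif = motif,
                 expected_position = expected_position,
                 search_window = search_window,
                 manual_position = manual_position),
            class = "anchor_spec")
}

#' Locate an anchor in a sequence
#'
#' @param seq amino-acid sequence (string or single-row homolog set).
#' @param spec an [anchor_spec()].
#' @return A list with `start`, `end` (1-based, inclusive) and `tie`
#'   (`TRUE` when two candidates were equidistant and the N-terminal one
#'   was taken).
#' @section Errors: signals a condition of class `anchor_not_found` when
#'   no match lies inside the search window.
#' @export
find_anchor <- function(seq, spec) {
  stopifnot(inherits(spec, "anchor_spec"))
  s <- if (is.data.frame(seq)) seq$sequence[1] else as.character(seq)
  if (!is.null(spec$manual_position)) {
    return(list(start = as.integer(spec$manual_position),
                end = as.integer(spec$manual_position) + spec$motif$length - 1L,
                tie = FALSE))
  }
  starts <- motif_matches(spec$motif, s)
  if (!is.null(spec$expected_position)) {
    dist <- abs(starts - spec$expected_position)
    starts <- starts[dist <= spec$search_window]
    dist <- dist[dist <= spec$search_window]
  }
  if (length(starts) == 0) {
    stop(structure(class = c("anchor_not_found", "error", "condition"),
                   list(message = paste0("anchor '", spec$name, "' not found"),
                        call = NULL)))
  }
  tie <- FALSE
  if (!is.null(spec$expected_position)) {
    best <- which(dist == min(dist))
    tie <- length(best) > 1
    pick <- min(starts[best])      # tie-break toward the N terminus
  } else {
    pick <- starts[1]
  }
  list(start = as.integer(pick), end = as.integer(pick) + spec$motif$length - 1L,
       tie = tie)
}

#' Count residues strictly between two boundary elements
#'
#' The unit of loop-length comparison across homologs: residues between
#' the last residue of the upstream element and the first residue of the
#' downstream element, excluding both elements.
#'
#' @param seq amino-acid sequence.
#' @param upstream,downstream [anchor_spec()]s.
#' @return A list with `length` (integer), `segment` (the intervening
#'   substring) and the resolved `upstream`/`downstream` anchor positions.
#' @export
intervening_length <- function(seq, upstream, downstream) {
  s <- if (is.data.frame(seq)) seq$sequence[1] else as.character(seq)
  up <- find_anchor(s, upstream)
  down <- find_anchor(s, downstream)
  if (down$start <= up$end) {
    stop("measurement error: anchors out of order or overlapping (",
         upstream$name, " ends at ", up$end, ", ", downstream$name,
         " starts at ", down$start, ")", call. = FALSE)
  }
  n <- down$start - up$end - 1L
  segment <- if (n > 0) substr(s, up$end + 1L, down$start - 1L) else ""
  list(length = n, segment = segment, upstream = up, downstream = down)
}

#' Inclusive length of a residue interval
#'
#' Companion to [intervening_length()] for explicitly numbered regions in
#' the `"residues a–b"` idiom: both endpoints are counted.
#'
#' @param start,end 1-based residue indices, `end >= start`.
#' @return `end - start + 1`.
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end must be >= start", call. = FALSE)
  as.integer(end - start + 1)
}

#' Basic-patch detection rule
#'
#' A basic patch is at least `min_basic` basic residues within a sliding
#' window of `window` residues. The basic set defaults to K, R, H and can
#' be restricted to K, R.
#'
#' @param window window length in residues.
#' @param min_basic minimum basic residues per qualifying window
#'   (`1 <= min_basic <= window`).
#' @param basic_set residues counted as basic.
#' @return A list of class `patch_rule`.
#' @export
patch_rule <- function(window = 4L, min_basic = 3L, basic_set = DEFAULT_BASIC) {
  if (min_basic < 1 || min_basic > window) {
    stop("min_basic must satisfy 1 <= min_basic <= window", call. = FALSE)
  }
  structure(list(window = as.integer(window), min_basic = as.integer(min_basic),
                 basic_set = basic_set),
            class = "patch_rule")
}

#' Scan a segment for basic patches
#'
#' Every window of length `rule$window` containing at least
#' `rule$min_basic` basic residues qualifies; overlapping qualifying
#' windows are merged and each merged run is trimmed to span from its
#' first to its last basic residue. Segments shorter than the window
#' yield no patches.
#'
#' @param segment amino-acid string (e.g. the intervening segment between
#'   two anchors).
#' @param rule a [patch_rule()].
#' @return A `data.frame` with columns `start`, `end` (1-based inclusive,
#'   relative to the segment); zero rows when no patch is present.
#' @export
scan_basic_patches <- function(segment, rule = patch_rule()) {
  stopifnot(inherits(rule, "patch_rule"))
  segment <- toupper(as.character(segment))
  n <- nchar(segment)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < rule$window) return(empty)
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  basic <- chars %in% rule$basic_set
  # rolling window counts via cumulative sums
  cs <- c(0L, cumsum(basic))
  starts <- seq_len(n - rule$window + 1L)
  counts <- cs[starts + rule$window] - cs[starts]
  qual <- starts[counts >= rule$min_basic]
  if (length(qual) == 0) return(empty)
  # union of qualifying windows -> coverage runs
  covered <- rep(FALSE, n)
  for (q in qual) covered[q:(q + rule$window - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts_run <- ends - r$lengths + 1L
  runs <- data.frame(start = starts_run[r$values], end = ends[r$values])
  # trim each run to its first/last basic residue
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start[i]:runs$end[i]
    b <- idx[basic[idx]]
    runs$start[i] <- min(b)
    runs$end[i] <- max(b)
  }
  runs
}

#' Is a basic patch present between two anchors?
#'
#' The intervening segment (anchors excluded) is scanned with
#' [scan_basic_patches()]. When either anchor cannot be located the result
#' is `NA` — absence of evidence, not evidence of absence.
#'
#' @param seq amino-acid sequence.
#' @param upstream,downstream [anchor_spec()]s.
#' @param rule a [patch_rule()].
#' @return `TRUE`, `FALSE`, or `NA` when an anchor was not found.
#' @export
region_has_patch <- function(seq, upstream, downstream, rule = patch_rule()) {
  res <- tryCatch(intervening_length(seq, upstream, downstream),
                  anchor_not_found = function(e) NULL)
  if (is.null(res)) return(NA)
  nrow(scan_basic_patches(res$segment, rule)) > 0
}

#' Declare a key residue
#'
#' @param name short label (e.g. `"F"` for the back-pocket phenylalanine,
#'   `"P1"`..`"P3"` for phosphosites).
#' @param position 1-based index in the reference sequence.
#' @param allowed residues counted as present (e.g. `c("S","T")` for a
#'   phosphosite).
#' @return A list of class `key_residue_spec`.
#' @export
key_residue_spec <- function(name, position, allowed) {
  if (position < 1) stop("position must be >= 1", call. = FALSE)
  if (length(allowed) == 0) stop("allowed set must be non-empty", call. = FALSE)
  structure(list(name = name, position = as.integer(position),
                 allowed = toupper(allowed)),
            class = "key_residue_spec")
}

#' Key-residue presence and interval containment
#'
#' For each spec, presence is whether the residue at the spec position is
#' in the allowed set. `count_in_interval` is the number of specs whose
#' *position* lies inside `loop_interval` (inclusive) — a purely
#' positional containment count.
#'
#' @param seq amino-acid sequence addressed directly by residue number.
#' @param specs list of [key_residue_spec()]s.
#' @param loop_interval optional `c(start, end)` inclusive interval.
#' @return A list with `present` (named logical), `count_in_interval`
#'   (or `NA` when no interval was given) and `flags` (names of specs that
#'   hit a gap character).
#' @export
key_residue_presence <- function(seq, specs, loop_interval = NULL) {
  s <- if (is.data.frame(seq)) seq$sequence[1] else as.character(seq)
  if (inherits(specs, "key_residue_spec")) specs <- list(specs)
  present <- logical(length(specs))
  flags <- character(0)
  nm <- vapply(specs, `[[`, character(1), "name")
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$position > nchar(s)) {
      stop("key-residue position ", sp$position, " beyond sequence end (",
           nchar(s), ")", call. = FALSE)
    }
    res <- substr(s, sp$position, sp$position)
    if (res == "-") {
      present[i] <- FALSE
      flags <- c(flags, sp$name)
    } else {
      present[i] <- res %in% sp$allowed
    }
  }
  names(present) <- nm
  count <- NA_integer_
  if (!is.null(loop_interval)) {
    pos <- vapply(specs, `[[`, integer(1), "position")
    count <- sum(pos >= loop_interval[1] & pos <= loop_interval[2])
  }
  list(present = present, count_in_interval = count, flags = flags)
}

#' Map reference residue positions to alignment columns
#'
#' Columns are addressed through the designated reference row: the k-th
#' non-gap character of that row sits in the column returned for
#' position k.
#'
#' @param msa an [msa()].
#' @param ref_id id of the reference row.
#' @param positions 1-based residue positions in the reference sequence.
#' @return Integer vector of alignment columns.
#' @export
map_ref_to_column <- function(msa, ref_id, positions) {
  stopifnot(inherits(msa, "msa"))
  row <- msa$aligned[match(ref_id, msa$ids)]
  if (is.na(row)) stop("reference id '", ref_id, "' not in alignment", call. = FALSE)
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  resno <- cumsum(chars != "-")
  cols <- vapply(positions, function(p) {
    hit <- which(resno == p & chars != "-")
    if (length(hit) == 0) {
      stop("reference position ", p, " beyond reference sequence end", call. = FALSE)
    }
    hit[1]
  }, integer(1))
  cols
}

#' Key-residue presence via alignment-column mapping
#'
#' Positions are given in the reference sequence's residue numbering and
#' mapped through the alignment onto the target row. A gap at the mapped
#' column yields `FALSE` and a flag.
#'
#' @param msa an [msa()].
#' @param row_id id of the row to examine.
#' @param ref_id id of the reference row whose numbering `specs` use.
#' @param specs list of [key_residue_spec()]s.
#' @param loop_interval optional inclusive interval in reference numbering.
#' @return As [key_residue_presence()].
#' @export
key_residue_presence_msa <- function(msa, row_id, ref_id, specs,
                                     loop_interval = NULL) {
  if (inherits(specs, "key_residue_spec")) specs <- list(specs)
  pos <- vapply(specs, `[[`, integer(1), "position")
  cols <- map_ref_to_column(msa, ref_id, pos)
  row <- msa$aligned[match(row_id, msa$ids)]
  if (is.na(row)) stop("row id '", row_id, "' not in alignment", call. = FALSE)
  mapped_specs <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    key_residue_spec(sp$name, cols[i], sp$allowed)
  })
  out <- key_residue_presence(row, mapped_specs, loop_interval = NULL)
  count <- NA_integer_
  if (!is.null(loop_interval)) {
    count <- sum(pos >= loop_interval[1] & pos <= loop_interval[2])
  }
  out$count_in_interval <- count
  out
}

#' Per-column residue frequencies of an alignment slice
#'
#' Frequencies are over non-gap residues and sum to 1 per column; the gap
#' fraction is reported separately. All-gap columns are marked and carry
#' no frequencies.
#'
#' @param msa an [msa()].
#' @param columns integer vector of columns (default: all).
#' @return A list of class `column_freqs`: `columns`, `freq` (list of
#'   named numeric vectors, `NULL` where all-gap), `gap_fraction`,
#'   `all_gap` (logical).
#' @export
column_frequencies <- function(msa, columns = seq_len(msa$column_count)) {
  stopifnot(inherits(msa, "msa"))
  if (any(columns < 1 | columns > msa$column_count)) {
    stop("columns outside 1..column_count", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(msa$aligned, "", fixed = TRUE))
  freq <- vector("list", length(columns))
  gapf <- numeric(length(columns))
  allg <- logical(length(columns))
  for (i in seq_along(columns)) {
    col <- mat[, columns[i]]
    gapf[i] <- mean(col == "-")
    res <- col[col != "-"]
    if (length(res) == 0) {
      allg[i] <- TRUE
      freq[i] <- list(NULL)
    } else {
      tab <- table(res)
      freq[[i]] <- as.numeric(tab) / length(res)
      names(freq[[i]]) <- names(tab)
    }
  }
  structure(list(columns = as.integer(columns), freq = freq,
                 gap_fraction = gapf, all_gap = allg),
            class = "column_freqs")
}

#' Most conserved contiguous window of an alignment slice
#'
#' Finds the k-column window maximising the mean modal-residue frequency
#' (all-gap columns contribute 0). Ties resolve to the leftmost window.
#'
#' @param freqs a [column_frequencies()] result.
#' @param k window length in columns (`k <=` number of columns scored).
#' @return `c(start, end)` in the column numbering of `freqs$columns`.
#' @export
most_conserved_window <- function(freqs, k) {
  stopifnot(inherits(freqs, "column_freqs"))
  n <- length(freqs$columns)
  if (k > n) stop("k exceeds the number of scored columns", call. = FALSE)
  modal <- vapply(freqs$freq, function(f) if (is.null(f)) 0 else max(f), numeric(1))
  score <- vapply(seq_len(n - k + 1L), function(i) mean(modal[i:(i + k - 1L)]),
                  numeric(1))
  best <- which.max(score)   # which.max takes the first (leftmost) maximum
  c(start = freqs$columns[best], end = freqs$columns[best + k - 1L])
}

#' Measure all declared signatures across a homolog set
#'
#' The workhorse behind the per-sequence feature table: for every
#' sequence, each declared segment's anchors are located and the
#' intervening length recorded (NA when an anchor is missing); segments
#' flagged for patch scanning get a patch boolean; key residues are
#' called against the declared reference positions.
#'
#' @param seqs a [homolog_set()].
#' @param segments named list; each element a list with `upstream` and
#'   `downstream` [anchor_spec()]s and optional `scan_patches = TRUE`.
#' @param rule a [patch_rule()] used for segments with
#'   `scan_patches = TRUE`.
#' @param key_specs optional list of [key_residue_spec()]s applied
#'   directly by residue numbering (use for reference-numbered sequences).
#' @param overrides optional nested list
#'   `overrides[[seq_id]][[segment]] = list(upstream = pos, downstream = pos)`
#'   of manual anchor placements for specific sequences.
#' @return A `data.frame` with columns `id`, `clade`, then per segment
#'   `<name>_len`, `<name>_up`, `<name>_down` (anchor starts) and, where
#'   scanned, `<name>_patch`; per key residue `<name>_present`.
#' @export
measure_features <- function(seqs, segments, rule = patch_rule(),
                             key_specs = NULL, overrides = NULL) {
  stopifnot(is.data.frame(seqs))
  rows <- vector("list", nrow(seqs))
  for (r in seq_len(nrow(seqs))) {
    id <- seqs$id[r]
    s <- seqs$sequence[r]
    row <- list(id = id, clade = seqs$clade[r])
    for (seg_name in names(segments)) {
      seg <- segments[[seg_name]]
      up <- seg$upstream
      down <- seg$downstream
      ov <- overrides[[id]][[seg_name]]
      if (!is.null(ov$upstream)) up$manual_position <- ov$upstream
      if (!is.null(ov$downstream)) down$manual_position <- ov$downstream
      meas <- tryCatch(intervening_length(s, up, down),
                       anchor_not_found = function(e) NULL)
      if (is.null(meas)) {
        row[[paste0(seg_name, "_len")]] <- NA_integer_
        row[[paste0(seg_name, "_up")]] <- NA_integer_
        row[[paste0(seg_name, "_down")]] <- NA_integer_
        if (isTRUE(seg$scan_patches)) row[[paste0(seg_name, "_patch")]] <- NA
      } else {
        row[[paste0(seg_name, "_len")]] <- meas$length
        row[[paste0(seg_name, "_up")]] <- meas$upstream$start
        row[[paste0(seg_name, "_down")]] <- meas$downstream$start
        if (isTRUE(seg$scan_patches)) {
          row[[paste0(seg_name, "_patch")]] <-
            nrow(scan_basic_patches(meas$segment, rule)) > 0
        }
      }
    }
    if (!is.null(key_specs)) {
      kr <- key_residue_presence(s, key_specs)
      for (nm in names(kr$present)) {
        row[[paste0(nm, "_present")]] <- unname(kr$present[nm])
      }
    }
    rows[[r]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
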