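#' @importFrom Biostrings readAAStringSet readBStringSet AAStringSet writeXStringSet
#' @importFrom ape read.tree write.tree
NULL

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Build a set of homolog records
#'
#' A homolog set is the package's basic container for unaligned protein
#' sequences: one row per homolog with an accession-style `id`, a free-text
#' `species`, an optional `clade` label and the amino-acid `sequence`
#' (1-letter codes, uppercase). Sequences are validated against the 20
#' standard residues plus `X`; ids must be unique.
#'
#' @param id character vector of unique accession-style identifiers.
#' @param sequence character vector of amino-acid sequences.
#' @param species optional character vector of species names.
#' @param clade optional character vector of clade labels
#'   (e.g. `"LRRK1"`, `"Amoebozoa"`).
#' @return A `data.frame` of class `homolog_set` with columns
#'   `id`, `species`, `clade`, `sequence`.
#' @export
homolog_set <- function(id, sequence, species = NA_character_, clade = NA_character_) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have equal length", call. = FALSE)
  }
  dup <- id[duplicated(id)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id(s): ", paste(id[!nzchar(sequence)], collapse = ", "),
         call. = FALSE)
  }
  bad <- vapply(sequence, function(s) {
    any(!strsplit(s, "", fixed = TRUE)[[1]] %in% AA_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    stop("sequence(s) contain non-amino-acid characters: ",
         paste(id[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    id = id,
    species = rep_len(as.character(species), length(id)),
    clade = rep_len(as.character(clade), length(id)),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  class(out) <- c("homolog_set", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Headers are parsed as `id [optional description]`; the description is
#' stored as the species field. Sequences are uppercased and validated.
#'
#' @param path path to a FASTA file.
#' @return A [homolog_set()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("FASTA format error: empty file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("FASTA format error: no records in ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), NA_character_)
  homolog_set(id = ids, sequence = as.character(aa), species = desc)
}

#' Write a homolog set to FASTA
#'
#' Inverse of [read_fasta()]: the species field, when present, is written
#' as the header description.
#'
#' @param x a [homolog_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "homolog_set") || is.data.frame(x))
  headers <- ifelse(is.na(x$species), x$id, paste(x$id, x$species))
  aa <- Biostrings::AAStringSet(x$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, filepath = path)
  invisible(path)
}

#' Construct a multiple sequence alignment object
#'
#' Rows are gapped sequences of identical length; `'.'` gaps are normalised
#' to `'-'` on construction. De-gapping a row reproduces the member's
#' unaligned sequence.
#'
#' @param ids character vector of row identifiers.
#' @param aligned character vector of equal-length gapped sequences.
#' @return A list of class `msa` with elements `ids`, `aligned`,
#'   `column_count`.
#' @export
msa <- function(ids, aligned) {
  ids <- as.character(ids)
  aligned <- gsub(".", "-", toupper(as.character(aligned)), fixed = TRUE)
  if (length(ids) != length(aligned)) stop("ids/aligned length mismatch", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate alignment id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  widths <- nchar(aligned)
  if (length(unique(widths)) > 1) {
    off <- widths != widths[1]
    stop("alignment format error: ragged rows (", ids[off][1], " has length ",
         widths[off][1], ", expected ", widths[1], ")", call. = FALSE)
  }
  structure(list(ids = ids, aligned = aligned, column_count = widths[1]),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned FASTA file; rows must have equal length.
#' @return An [msa()] object with `column_count` set.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("alignment format error: empty file: ", path, call. = FALSE)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("alignment format error: no records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(raw))
  msa(ids, as.character(raw))
}

#' Write an alignment to aligned FASTA
#' @param x an [msa()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  bs <- Biostrings::BStringSet(x$aligned)
  names(bs) <- x$ids
  Biostrings::writeXStringSet(bs, filepath = path)
  invisible(path)
}

#' Remove gap characters from an aligned row
#' @param x character vector of gapped sequences.
#' @return Ungapped sequences.
#' @export
degap <- function(x) gsub("-", "", gsub(".", "-", x, fixed = TRUE), fixed = TRUE)

# locate the position of the first unbalanced parenthesis, or 0 if balanced
.newick_unbalanced_at <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) return(i)
  }
  if (depth != 0L) return(length(chars))
  0L
}

#' Read a Newick tree with branch-support labels
#'
#' Internal-node labels of the form `"x/y"` are parsed as dual supports
#' (SH-aLRT percent, ultrafast-bootstrap percent), the convention used by
#' maximum-likelihood tree software run with both support measures. A
#' single-value label is stored as the ultrafast bootstrap with SH-aLRT
#' absent.
#'
#' @param text a Newick string, or `NULL` if `path` is given.
#' @param path path to a Newick file.
#' @return An `ape::phylo` tree of class `c("support_tree", "phylo")` with
#'   numeric vectors `shalrt` and `ufboot` (one entry per internal node, in
#'   `node.label` order; `NA` where absent).
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply `text` or `path`", call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  pos <- .newick_unbalanced_at(text)
  if (pos > 0) {
    stop("Newick parse error: unbalanced parentheses at position ", pos,
         call. = FALSE)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stop("Newick parse error in: ", substr(text, 1, 60), call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  shalrt <- rep(NA_real_, tree$Nnode)
  ufboot <- rep(NA_real_, tree$Nnode)
  dual <- grepl("/", labs, fixed = TRUE)
  parts <- strsplit(labs[dual], "/", fixed = TRUE)
  shalrt[dual] <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
  ufboot[dual] <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  single <- !dual & nzchar(labs)
  suppressWarnings(ufboot[single] <- as.numeric(labs[single]))
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 100))
  if (!ok(shalrt) || !ok(ufboot)) {
    stop("support values outside [0, 100] in node labels", call. = FALSE)
  }
  tree$shalrt <- shalrt
  tree$ufboot <- ufboot
  class(tree) <- c("support_tree", "phylo")
  tree
}

#' Write a support-annotated tree to Newick
#'
#' Dual supports are re-emitted as `"shalrt/ufboot"` labels; a lone
#' bootstrap value as a single label. Branch lengths are written with
#' enough digits to round trip.
#'
#' @param tree a tree from [read_newick()] (or any `phylo`).
#' @param path optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!is.null(tree$shalrt) || !is.null(tree$ufboot)) {
    sh <- tree$shalrt
    uf <- tree$ufboot
    fmt <- function(v) format(v, trim = TRUE, digits = 8, scientific = FALSE)
    lab <- character(tree$Nnode)
    for (i in seq_len(tree$Nnode)) {
      if (!is.na(sh[i]) && !is.na(uf[i])) {
        lab[i] <- paste0(fmt(sh[i]), "/", fmt(uf[i]))
      } else if (!is.na(uf[i])) {
        lab[i] <- fmt(uf[i])
      } else {
        lab[i] <- ""
      }
    }
    tree$node.label <- lab
  }
  class(tree) <- "phylo"
  txt <- ape::write.tree(tree, digits = 10)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a tabular homology-hit file
#'
#' Accepts either a headered TSV with columns named
#' `subject_id`/`e_value`/`query_coverage`/`percent_identity` (aliases
#' `subject`, `evalue`, `coverage`, `identity` are recognised) or a
#' headerless BLAST-style tabular file with the relevant columns extracted
#' by index.
#'
#' @param path path to the delimited file.
#' @param col_map for headerless input, a named integer vector giving the
#'   1-based column indices of `subject_id`, `e_value`, `query_coverage`,
#'   `percent_identity`.
#' @return A `data.frame` with those four typed columns, in file order.
#' @export
read_hit_table <- function(path,
                           col_map = c(subject_id = 1L, e_value = 2L,
                                       query_coverage = 3L, percent_identity = 4L)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("subject|e_?value|coverage|identity", first, ignore.case = TRUE)
  raw <- utils::read.table(path, header = has_header, sep = "",
                           stringsAsFactors = FALSE, comment.char = "")
  if (has_header) {
    nm <- tolower(names(raw))
    pick <- function(...) {
      cand <- c(...)
      hit <- match(cand, nm)
      hit <- hit[!is.na(hit)]
      if (length(hit) == 0) {
        stop("hit-table schema error: missing column (one of ",
             paste(cand, collapse = ", "), ")", call. = FALSE)
      }
      raw[[hit[1]]]
    }
    out <- data.frame(
      subject_id = as.character(pick("subject_id", "subject", "sseqid")),
      e_value = pick("e_value", "evalue"),
      query_coverage = pick("query_coverage", "coverage", "qcovs"),
      percent_identity = pick("percent_identity", "identity", "pident"),
      stringsAsFactors = FALSE
    )
  } else {
    if (ncol(raw) < max(col_map)) {
      stop("hit-table schema error: expected at least ", max(col_map),
           " columns, found ", ncol(raw), call. = FALSE)
    }
    out <- data.frame(
      subject_id = as.character(raw[[col_map[["subject_id"]]]]),
      e_value = raw[[col_map[["e_value"]]]],
      query_coverage = raw[[col_map[["query_coverage"]]]],
      percent_identity = raw[[col_map[["percent_identity"]]]],
      stringsAsFactors = FALSE
    )
  }
  for (col in c("e_value", "query_coverage", "percent_identity")) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    if (any(is.na(v) | is.nan(v))) {
      stop("hit-table value error: non-numeric or NaN in column ", col, call. = FALSE)
    }
    out[[col]] <- v
  }
  if (any(out$e_value < 0)) stop("hit-table value error: negative e-value", call. = FALSE)
  rng <- function(v) any(v < 0 | v > 100)
  if (rng(out$query_coverage) || rng(out$percent_identity)) {
    stop("hit-table value error: coverage/identity outside [0, 100]", call. = FALSE)
  }
  out
}

#' Write a per-sequence feature table to TSV
#'
#' One row per sequence; columns are `id`, `clade`, then segment lengths,
#' patch and key-residue booleans and anchor positions. Missing
#' measurements (for example an anchor that was not found) are written as
#' `NA`.
#'
#' @param table a `data.frame`, typically from [measure_features()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  ok <- tryCatch({
    utils::write.table(table, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a feature table written by [write_feature_table()]
#' @param path path to the TSV.
#' @return A `data.frame`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
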