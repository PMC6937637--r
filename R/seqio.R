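#' @include fcgrvec-package.R
NULL

# taxonomy ranks recognised in FASTA headers and label tables
.RANKS <- c("order", "family", "genus", "species", "strain")

# IUPAC nucleotide one-letter codes (unambiguous + ambiguity codes)
.IUPAC <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N", "-", ".")

#' Construct a labeled sequence corpus
#'
#' A corpus is a plain `data.frame` with character columns `id` and
#' `sequence` plus one optional column per taxonomy rank
#' (`order`, `family`, `genus`, `species`, `strain`; `NA` where a label
#' is unknown). Sequences are stored uppercased; ids must be unique and
#' nonempty; sequences must be nonempty and contain only IUPAC
#' nucleotide codes.
#'
#' @param id character vector of identifiers.
#' @param sequence character vector of nucleotide sequences.
#' @param labels optional `data.frame` (or `NULL`) of per-sequence rank
#'   columns, recycled checks applied.
#' @return A `data.frame` of class `seq_corpus`.
#' @export
seq_corpus <- function(id, sequence, labels = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (length(id) != length(sequence)) {
    stop("`id` and `sequence` must have equal length")
  }
  if (any(!nzchar(id))) stop("ids must be nonempty")
  if (anyDuplicated(id)) {
    stop("duplicate ids in corpus: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) {
    stop("empty sequence for id: ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  }
  bad <- vapply(sequence, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    any(!ch %in% .IUPAC)
  }, logical(1))
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(id[bad], collapse = ", "))
  }
  out <- data.frame(id = id, sequence = sequence, stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    labels <- as.data.frame(labels, stringsAsFactors = FALSE)
    if (nrow(labels) != nrow(out)) stop("labels must have one row per sequence")
    for (cn in intersect(names(labels), .RANKS)) out[[cn]] <- as.character(labels[[cn]])
  }
  class(out) <- c("seq_corpus", "data.frame")
  out
}

# parse "rank=value" tokens from the part of a FASTA header after the id
.parse_header_labels <- function(rest) {
  out <- stats::setNames(rep(NA_character_, length(.RANKS)), .RANKS)
  if (!nzchar(rest)) return(out)
  toks <- strsplit(trimws(rest), "\\s+")[[1]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  for (tk in toks) {
    kv <- strsplit(tk, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2 && kv[1] %in% .RANKS) out[[kv[1]]] <- kv[2]
  }
  out
}

#' Read a FASTA file into a sequence corpus
#'
#' The token before the first whitespace of each header becomes the id;
#' the remainder is scanned for `rank=value` pairs
#' (ranks: order, family, genus, species, strain). Sequences are
#' uppercased with line breaks removed. Labels can alternatively be
#' supplied in a sidecar table via `label_file` (see
#' [read_label_table()]); sidecar labels override header labels.
#'
#' @param path path to a FASTA file.
#' @param label_file optional path to a 2-column tab-separated label
#'   table.
#' @return A [seq_corpus()] `data.frame`.
#' @export
read_fasta <- function(path, label_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA (line ", first, " does not start with '>'): ", path)
  }
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  if (any(Biostrings::width(dss) == 0L)) {
    stop("empty record(s) in FASTA: ",
         paste(names(dss)[Biostrings::width(dss) == 0L], collapse = ", "))
  }
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  labs <- do.call(rbind, lapply(rest, .parse_header_labels))
  corpus <- seq_corpus(ids, as.character(dss),
                       labels = as.data.frame(labs, stringsAsFactors = FALSE))
  # drop all-NA rank columns so header-less files stay minimal
  for (cn in .RANKS) {
    if (cn %in% names(corpus) && all(is.na(corpus[[cn]]))) corpus[[cn]] <- NULL
  }
  if (!is.null(label_file)) corpus <- apply_labels(corpus, read_label_table(label_file))
  corpus
}

#' Write a sequence corpus to FASTA
#'
#' Rank labels are embedded in headers as `rank=value` tokens, so
#' `read_fasta(write_fasta(x))` round-trips ids, sequences and labels.
#'
#' @param corpus a [seq_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(corpus, path) {
  headers <- vapply(seq_len(nrow(corpus)), function(i) {
    h <- corpus$id[i]
    for (cn in intersect(.RANKS, names(corpus))) {
      v <- corpus[[cn]][i]
      if (!is.na(v)) h <- paste0(h, " ", cn, "=", v)
    }
    h
  }, character(1))
  dss <- Biostrings::DNAStringSet(corpus$sequence)
  names(dss) <- headers
  Biostrings::writeXStringSet(dss, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a sidecar label table
#'
#' Two tab-separated columns without header: sequence id, and a
#' `rank=value;rank=value` list.
#'
#' @param path path to the table.
#' @return A `data.frame` with column `id` plus one column per rank seen.
#' @export
read_label_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("label table must have two tab-separated columns")
  labs <- do.call(rbind, lapply(tab[[2]], function(s) {
    .parse_header_labels(gsub(";", " ", s, fixed = TRUE))
  }))
  out <- data.frame(id = tab[[1]], as.data.frame(labs, stringsAsFactors = FALSE),
                    stringsAsFactors = FALSE)
  out[, c(TRUE, !vapply(out[-1], function(x) all(is.na(x)), logical(1))), drop = FALSE]
}

#' Attach labels from a label table to a corpus
#'
#' @param corpus a [seq_corpus()].
#' @param labels a `data.frame` as returned by [read_label_table()].
#' @return The corpus with rank columns filled in (table values override
#'   header values).
#' @export
apply_labels <- function(corpus, labels) {
  m <- match(corpus$id, labels$id)
  for (cn in intersect(.RANKS, names(labels))) {
    v <- labels[[cn]][m]
    if (all(is.na(v))) next
    if (!cn %in% names(corpus)) corpus[[cn]] <- NA_character_
    corpus[[cn]] <- ifelse(is.na(v), corpus[[cn]], v)
  }
  corpus
}

#' Split genomes into non-overlapping fixed-length chunks
#'
#' Each genome yields `c = min(floor(len / chunk_len), max_chunks)`
#' chunks of exactly `chunk_len` bp with start offsets
#' `floor(i * (len - chunk_len) / (c - 1))`, `i = 0..c-1` (a single
#' chunk starts at 0), i.e. non-overlapping and approximately equally
#' spaced across the genome. Genomes shorter than `chunk_len` yield no
#' chunks (with a warning). Chunks inherit the parent's labels and are
#' named `<parent>_chunk<i>`.
#'
#' @param corpus a [seq_corpus()] (one row per genome).
#' @param chunk_len chunk length in bp (default 20000).
#' @param max_chunks maximum chunks retained per genome (default 37).
#' @return A [seq_corpus()] of chunks, with columns `parent` and `start`
#'   (1-based offset of the chunk in its genome).
#' @export
chunk_genome <- function(corpus, chunk_len = 20000L, max_chunks = 37L) {
  stopifnot(chunk_len >= 1, max_chunks >= 1)
  rank_cols <- intersect(.RANKS, names(corpus))
  pieces <- lapply(seq_len(nrow(corpus)), function(g) {
    len <- nchar(corpus$sequence[g])
    q <- len %/% chunk_len
    cc <- min(q, max_chunks)
    if (cc == 0L) {
      warning("genome '", corpus$id[g], "' (", len,
              " bp) is shorter than chunk_len; no chunks retained")
      return(NULL)
    }
    starts <- if (cc == 1L) 0L else {
      as.integer(floor((0:(cc - 1)) * (len - chunk_len) / (cc - 1)))
    }
    data.frame(
      id = paste0(corpus$id[g], "_chunk", seq_len(cc)),
      sequence = substring(corpus$sequence[g], starts + 1L, starts + chunk_len),
      parent = corpus$id[g],
      start = starts + 1L,
      corpus[g, rank_cols, drop = FALSE],
      row.names = NULL, stringsAsFactors = FALSE
    )
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    out <- data.frame(id = character(), sequence = character(),
                      parent = character(), start = integer(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, pieces)
  }
  class(out) <- c("seq_corpus", "data.frame")
  out
}

#' Sample short discontiguous fragments from a genome
#'
#' Takes `n_fragments` fragments of `frag_len` bp with starts
#' approximately equally spaced across the genome (same floor-based
#' placement as [chunk_genome()]); if `spacing` is given, starts are
#' instead laid out every `frag_len + spacing` bp from the genome start,
#' capped at `n_fragments` and at what fits.
#'
#' @param record one-row [seq_corpus()].
#' @param frag_len fragment length in bp (default 200).
#' @param n_fragments number of fragments requested.
#' @param spacing optional fixed gap (bp) between consecutive fragments.
#' @return A [seq_corpus()] of fragments named `<parent>_frag<i>`.
#' @export
sample_fragments <- function(record, frag_len = 200L, n_fragments, spacing = NULL) {
  stopifnot(nrow(record) == 1L, frag_len >= 1, n_fragments >= 1)
  len <- nchar(record$sequence)
  if (len < frag_len) stop("genome shorter than frag_len")
  if (is.null(spacing)) {
    cc <- min(n_fragments, len %/% frag_len)
    starts <- if (cc == 1L) 0L else {
      as.integer(floor((0:(cc - 1)) * (len - frag_len) / (cc - 1)))
    }
  } else {
    step <- frag_len + spacing
    starts <- seq.int(0L, len - frag_len, by = step)
    starts <- starts[seq_len(min(length(starts), n_fragments))]
  }
  rank_cols <- intersect(.RANKS, names(record))
  out <- data.frame(
    id = paste0(record$id, "_frag", seq_along(starts)),
    sequence = substring(record$sequence, starts + 1L, starts + frag_len),
    parent = record$id, start = starts + 1L,
    record[1, rank_cols, drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("seq_corpus", "data.frame")
  out
}

#' Stitch short fragments into longer composite sequences
#'
#' Fragments from one genome (equal length) are arranged row-wise into a
#' matrix with `group_size` columns, the matrix is transposed, and each
#' resulting row is concatenated: fragment `i` goes to stitched sequence
#' `(i - 1) mod group_size + 1`, so every stitched sequence samples
#' fragments spread across the genome. Trailing fragments beyond a
#' multiple of `group_size` are dropped; when fewer than `group_size`
#' fragments are supplied, all are used and each becomes its own
#' stitched sequence.
#'
#' @param fragments a [seq_corpus()] of equal-length fragments from one
#'   genome.
#' @param group_size number of matrix columns (default 20).
#' @return A [seq_corpus()] of stitched sequences named
#'   `<parent>_stitch<i>`; empty input returns an empty corpus.
#' @export
stitch_fragments <- function(fragments, group_size = 20L) {
  stopifnot(group_size >= 1)
  n <- nrow(fragments)
  if (n == 0L) {
    out <- fragments
    class(out) <- c("seq_corpus", "data.frame")
    return(out)
  }
  lens <- nchar(fragments$sequence)
  if (length(unique(lens)) != 1L) stop("fragments must all have equal length")
  g <- min(group_size, n)
  rows <- n %/% g
  used <- fragments$sequence[seq_len(rows * g)]
  mat <- matrix(used, nrow = rows, ncol = g, byrow = TRUE)
  stitched <- apply(t(mat), 1L, paste0, collapse = "")
  parent <- fragments$parent[1] %||% sub("_frag[0-9]+$", "", fragments$id[1])
  rank_cols <- intersect(.RANKS, names(fragments))
  out <- data.frame(
    id = paste0(parent, "_stitch", seq_len(g)),
    sequence = stitched, parent = parent,
    fragments[rep(1L, g), rank_cols, drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("seq_corpus", "data.frame")
  out
}
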