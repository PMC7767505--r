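# Sequence input/output, validation and numeric encoding.
#
# Channel order of the one-hot code is A, T, C, G (not alphabetical): each
# base maps to a unit 4-vector, A=(1,0,0,0), T=(0,1,0,0), C=(0,0,1,0),
# G=(0,0,0,1), so an 81-nt sequence becomes an 81 x 4 matrix.

.ONEHOT_ALPHABET <- c("A", "T", "C", "G")

#' Read DNA sequences from a FASTA file
#'
#' Parses a (multi-record, wrapped or unwrapped) FASTA file into a dataset
#' data frame. Sequences are uppercased; any character outside A/C/G/T
#' (including N and other IUPAC codes) is rejected. Labels may be embedded
#' in headers as `id|LABEL` (see [promoter_labels()]) or supplied separately
#' via [read_label_table()].
#'
#' @param path path to a FASTA file.
#' @param expect_length if non-NULL, every sequence must have this length
#'   (the benchmark window is 81 nt).
#' @param labels one of `"auto"` (use `id|LABEL` headers when present),
#'   `"header"` (require them), `"none"` (ignore headers after the id).
#' @return data frame with columns `id`, `seq` and, when labels are present,
#'   `label` (factor over [promoter_labels()]).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x|S70", strrep("ACGT", 20), "A"), fa)
#' read_fasta(fa, expect_length = 81)
read_fasta <- function(path, expect_length = NULL,
                       labels = c("auto", "header", "none")) {
  labels <- match.arg(labels)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop(sprintf("malformed FASTA: line %d does not start a record ('>')",
                 nonblank[1]), call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                             call. = FALSE)
  )
  headers <- names(set)
  seqs <- as.character(set)
  ids <- sub("\\|.*$", "", headers)
  ids <- sub("\\s.*$", "", ids)
  has_label <- grepl("\\|", headers)
  out <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  want_labels <- switch(labels,
    auto = any(has_label),
    header = TRUE,
    none = FALSE
  )
  if (want_labels) {
    if (!all(has_label)) {
      stop("missing 'id|LABEL' header for record(s): ",
           paste(utils::head(ids[!has_label], 5), collapse = ", "),
           call. = FALSE)
    }
    out$label <- as_promoter_label(sub("^[^|]*\\|", "", headers))
  }
  validate_dataset(out, labeled = want_labels, expect_length = expect_length)
}

#' Read a two-column tab-separated label file
#'
#' @param path TSV file with columns id and label (no header).
#' @param dataset optional dataset to attach labels to by id.
#' @return a data frame `id`/`label`, or `dataset` with a `label` column.
#' @export
read_label_table <- function(path, dataset = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("id", "label"),
                           colClasses = "character")
  tab$label <- as_promoter_label(tab$label)
  if (is.null(dataset)) return(tab)
  idx <- match(dataset$id, tab$id)
  if (anyNA(idx)) {
    stop("no label for record(s): ",
         paste(utils::head(dataset$id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  dataset$label <- tab$label[idx]
  validate_dataset(dataset, labeled = TRUE)
}

#' One-hot encode a DNA sequence
#'
#' Maps each base to a unit 4-vector with channel order A, T, C, G:
#' A=(1,0,0,0), T=(0,1,0,0), C=(0,0,1,0), G=(0,0,0,1). An 81-nt input
#' yields an 81 x 4 matrix.
#'
#' @param seq a single sequence string over A/C/G/T (lowercase accepted).
#' @return L x 4 integer matrix, one 1 per row; columns named A,T,C,G.
#' @seealso [one_hot_decode()], [encode_batch()]
#' @export
#' @examples
#' one_hot_encode("ACGT")
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  if (length(chars) == 0) stop("empty sequence", call. = FALSE)
  idx <- match(chars, .ONEHOT_ALPHABET)
  if (anyNA(idx)) {
    stop("invalid character(s) in sequence: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0L, nrow = length(idx), ncol = 4L,
              dimnames = list(NULL, .ONEHOT_ALPHABET))
  m[cbind(seq_along(idx), idx)] <- 1L
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of [one_hot_encode()]; every row must be a valid one-hot vector
#' (entries 0/1 summing to exactly 1).
#'
#' @param matrix L x 4 one-hot matrix.
#' @return the decoded sequence string.
#' @export
one_hot_decode <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) == 4)
  if (!all(matrix %in% c(0, 1)) || any(rowSums(matrix) != 1)) {
    stop("not a one-hot matrix: every row must have exactly one 1",
         call. = FALSE)
  }
  paste(.ONEHOT_ALPHABET[max.col(matrix)], collapse = "")
}

#' Encode a set of equal-length sequences as a 3-d array
#'
#' @param seqs character vector of equal-length sequences.
#' @return numeric array of dim (n, L, 4), channel order A,T,C,G.
#' @export
encode_batch <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1)
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must all have the same length",
                           call. = FALSE)
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  idx <- match(chars, .ONEHOT_ALPHABET)
  if (anyNA(idx)) stop("invalid character(s) in sequence set", call. = FALSE)
  x <- array(0, dim = c(length(seqs), L, 4L))
  x[cbind(rep(seq_len(length(seqs)), L),
          rep(seq_len(L), each = length(seqs)),
          idx)] <- 1
  x
}

#' Greedy identity-based redundancy filter
#'
#' First-seen-wins greedy filter for equal-length sequence sets: records
#' are scanned in input order and one is kept iff its ungapped identity
#' (matching positions / length) to every previously kept record is below
#' `threshold`. This is a transparent stand-in for word-based clustering
#' tools such as CD-HIT (identity 0.8 is the conventional redundancy cut);
#' it does not replicate their clustering heuristics.
#'
#' @param dataset dataset data frame (columns `id`, `seq`, optional `label`).
#' @param threshold identity threshold in (0, 1]; a pair at or above it is
#'   considered redundant. Values > 1 keep everything; 0 keeps only the
#'   first record.
#' @return the filtered dataset, input order preserved.
#' @export
greedy_identity_filter <- function(dataset, threshold = 0.8) {
  dataset <- validate_dataset(dataset)
  n <- nrow(dataset)
  if (n <= 1) return(dataset)
  L <- unique(nchar(dataset$seq))
  if (length(L) != 1) {
    stop("identity filter requires equal-length sequences", call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(dataset$seq, "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  kept <- 1L
  for (i in seq_len(n)[-1]) {
    ident <- rowMeans(chars[kept, , drop = FALSE] ==
                        matrix(chars[i, ], nrow = length(kept), ncol = L,
                               byrow = TRUE))
    if (all(ident < threshold)) kept <- c(kept, i)
  }
  dataset[kept, , drop = FALSE]
}
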