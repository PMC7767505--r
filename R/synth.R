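# Synthetic 81-nt promoter benchmark generator.
#
# The 81-nt window is registered with the transcription start site at
# position 61, so it spans -60..+20. The -10 consensus hexamer TATAAT then
# occupies positions 49-54 and the -35 hexamer TTGACA positions 24-29
# (1-based, inclusive). Sigma subclasses are made separable by planting one
# distinct 6-mer per class at positions 10-15; these class motifs are a test
# scaffold, not a model of real sigma-factor determinants.

.SYNTH_DEFAULT_CLASS_MOTIFS <- c(
  S70 = "CTGCAG", S54 = "GAGCTC", S38 = "AAGCTT",
  S32 = "GGATCC", S28 = "TCTAGA", S24 = "CCCGGG"
)

#' Configuration for the synthetic promoter generator
#'
#' @param n_per_class named vector/list of record counts per label (names
#'   from [promoter_labels()]); classes omitted get zero records.
#' @param mutation_rate per-position probability, in \[0,1\], that a planted
#'   motif position is substituted by a different base.
#' @param seed integer seed; the whole dataset is drawn from a single RNG
#'   stream keyed by it.
#' @param length window length in nt (benchmark convention: 81).
#' @param minus10_span,minus35_span,class_span 1-based inclusive start/end
#'   positions of the -10 hexamer, -35 hexamer and class motif.
#' @param minus10,minus35 consensus hexamers planted at those spans.
#' @param class_motifs named character vector of one 6-mer per sigma class.
#' @return object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_per_class = c(NON_PROMOTER = 5, S70 = 5), seed = 1)
#' generate_dataset(cfg)
synth_config <- function(n_per_class,
                         mutation_rate = 0.1,
                         seed = 1L,
                         length = 81L,
                         minus10_span = c(49L, 54L),
                         minus35_span = c(24L, 29L),
                         class_span = c(10L, 15L),
                         minus10 = "TATAAT",
                         minus35 = "TTGACA",
                         class_motifs = .SYNTH_DEFAULT_CLASS_MOTIFS) {
  n_per_class <- unlist(n_per_class)
  bad <- setdiff(names(n_per_class), promoter_labels())
  if (length(bad) > 0 || is.null(names(n_per_class))) {
    stop("n_per_class must be named by promoter labels; unknown: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_class < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must be in [0, 1]", call. = FALSE)
  }
  spans <- list(class = class_span, minus35 = minus35_span,
                minus10 = minus10_span)
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (length(sp) != 2 || sp[1] > sp[2] || sp[1] < 1 || sp[2] > length) {
      stop("span '", nm, "' must lie within 1..", length, call. = FALSE)
    }
  }
  occupied <- unlist(lapply(spans, function(sp) seq(sp[1], sp[2])))
  if (anyDuplicated(occupied)) {
    stop("motif spans must not overlap", call. = FALSE)
  }
  stopifnot(nchar(minus10) == minus10_span[2] - minus10_span[1] + 1,
            nchar(minus35) == minus35_span[2] - minus35_span[1] + 1)
  if (!all(sigma_labels() %in% names(class_motifs))) {
    stop("class_motifs must name all six sigma classes", call. = FALSE)
  }
  if (any(nchar(class_motifs) != class_span[2] - class_span[1] + 1)) {
    stop("class motifs must fill the class span exactly", call. = FALSE)
  }
  structure(list(
    n_per_class = n_per_class, mutation_rate = mutation_rate,
    seed = as.integer(seed), length = as.integer(length),
    minus10_span = as.integer(minus10_span),
    minus35_span = as.integer(minus35_span),
    class_span = as.integer(class_span),
    minus10 = toupper(minus10), minus35 = toupper(minus35),
    class_motifs = toupper(class_motifs[sigma_labels()])
  ), class = "synth_config")
}

#' Table-1-style class counts, optionally scaled
#'
#' The benchmark composition used throughout: 2860 non-promoters and
#' 1694/94/163/291/134/484 promoters for sigma70/54/38/32/28/24. `scale`
#' shrinks every count proportionally (ceiling, so no class vanishes).
#'
#' @param scale positive scaling factor applied to all counts.
#' @return named integer vector over all seven labels.
#' @export
table1_counts <- function(scale = 1) {
  stopifnot(scale > 0)
  n <- c(NON_PROMOTER = 2860, S70 = 1694, S54 = 94, S38 = 163,
         S32 = 291, S28 = 134, S24 = 484)
  ceiling(n * scale)
}

.random_seqs <- function(n, length) {
  if (n == 0) return(character())
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n * length, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# Plant `motif` at span in every row of the char matrix, then substitute each
# planted position independently with probability `rate` by a different base.
.plant <- function(chars, span, motif, rate) {
  pos <- seq(span[1], span[2])
  motif_chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  n <- nrow(chars)
  chars[, pos] <- matrix(motif_chars, nrow = n, ncol = length(pos),
                         byrow = TRUE)
  if (rate > 0) {
    hit <- which(matrix(stats::runif(n * length(pos)) < rate,
                        nrow = n, ncol = length(pos)), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      cur <- chars[cbind(hit[, 1], pos[hit[, 2]])]
      bases <- c("A", "C", "G", "T")
      # draw uniformly among the three bases differing from the current one
      repl <- vapply(cur, function(b) sample(setdiff(bases, b), 1), "")
      chars[cbind(hit[, 1], pos[hit[, 2]])] <- repl
    }
  }
  chars
}

#' Generate a labeled synthetic dataset
#'
#' Non-promoter records are uniform random background over A/C/G/T.
#' Promoter records are background with the -10 and -35 consensus hexamers
#' and the class-distinguishing 6-mer planted at their configured spans,
#' after which each planted position is independently substituted (by a
#' different base) with probability `mutation_rate`. Deterministic given
#' the config seed; record ids are `synth_<label>_<index>`.
#'
#' @param config a [synth_config()].
#' @return labeled dataset data frame (`id`, `seq`, `label`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)
  parts <- list()
  for (lab in promoter_labels()) {
    n <- config$n_per_class[lab]
    if (is.na(n) || n == 0) next
    seqs <- .random_seqs(n, config$length)
    if (lab != "NON_PROMOTER") {
      chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                      nrow = n, byrow = TRUE)
      chars <- .plant(chars, config$minus10_span, config$minus10,
                      config$mutation_rate)
      chars <- .plant(chars, config$minus35_span, config$minus35,
                      config$mutation_rate)
      chars <- .plant(chars, config$class_span, config$class_motifs[[lab]],
                      config$mutation_rate)
      seqs <- apply(chars, 1, paste, collapse = "")
    }
    parts[[lab]] <- data.frame(
      id = sprintf("synth_%s_%d", lab, seq_len(n)),
      seq = seqs, label = lab, stringsAsFactors = FALSE
    )
  }
  out <- if (length(parts) > 0) {
    do.call(rbind, c(parts, list(make.row.names = FALSE)))
  } else {
    data.frame(id = character(), seq = character(),
               label = character(), stringsAsFactors = FALSE)
  }
  out$label <- factor(out$label, levels = promoter_labels())
  validate_dataset(out, labeled = TRUE, expect_length = config$length)
}

#' Write a labeled dataset to FASTA
#'
#' Headers use the `id|LABEL` dialect so [read_fasta()] round-trips the
#' dataset exactly. Unlabeled datasets are written with bare ids.
#'
#' @param dataset dataset data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dataset_to_fasta <- function(dataset, path) {
  dataset <- validate_dataset(dataset, labeled = "label" %in% names(dataset))
  set <- Biostrings::DNAStringSet(dataset$seq)
  if (nrow(dataset) > 0) {
    names(set) <- if ("label" %in% names(dataset)) {
      paste0(dataset$id, "|", as.character(dataset$label))
    } else {
      dataset$id
    }
  }
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path)
    TRUE
  }, error = function(e) {
    stop("cannot write FASTA to '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
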