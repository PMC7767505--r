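#' Promoter class labels
#'
#' The seven-way label set used throughout the package: the non-promoter
#' class plus the six sigma-factor promoter subclasses of *E. coli*
#' (sigma70, sigma54, sigma38, sigma32, sigma28, sigma24).
#'
#' @return Character vector of the seven label codes, non-promoter first.
#' @export
#' @examples
#' promoter_labels()
#' sigma_labels()
promoter_labels <- function() {
  c("NON_PROMOTER", sigma_labels())
}

#' @rdname promoter_labels
#' @export
sigma_labels <- function() {
  c("S70", "S54", "S38", "S32", "S28", "S24")
}

#' Coerce a vector to promoter-label factor
#'
#' Accepts the canonical codes (case-insensitive); anything else errors.
#'
#' @param x character vector of label codes.
#' @return factor with levels `promoter_labels()`.
#' @export
as_promoter_label <- function(x) {
  up <- toupper(as.character(x))
  bad <- setdiff(unique(up), promoter_labels())
  if (length(bad) > 0) {
    stop("unknown promoter label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(promoter_labels(), collapse = ", "), ")",
         call. = FALSE)
  }
  factor(up, levels = promoter_labels())
}

#' Class counts of a labeled dataset
#'
#' @param dataset data frame with columns `id`, `seq`, `label`.
#' @return named integer vector over all seven labels (zero-filled).
#' @export
class_counts <- function(dataset) {
  dataset <- validate_dataset(dataset, labeled = TRUE)
  tab <- table(factor(dataset$label, levels = promoter_labels()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Validate a (possibly labeled) sequence dataset
#'
#' A dataset is a data frame with character columns `id` and `seq` and,
#' when labeled, a `label` column coercible via [as_promoter_label()].
#' Sequences are uppercased; characters outside A/C/G/T are rejected.
#'
#' @param dataset data frame to validate.
#' @param labeled require a label column.
#' @param expect_length if non-NULL, require all sequences to have this length.
#' @return the validated dataset (sequences uppercased, label a factor).
#' @export
validate_dataset <- function(dataset, labeled = FALSE, expect_length = NULL) {
  stopifnot(is.data.frame(dataset))
  if (!all(c("id", "seq") %in% names(dataset))) {
    stop("dataset must have columns 'id' and 'seq'", call. = FALSE)
  }
  dataset$id <- as.character(dataset$id)
  dataset$seq <- toupper(as.character(dataset$seq))
  ok <- !grepl("[^ACGT]", dataset$seq) & nzchar(dataset$seq)
  if (!all(ok)) {
    stop("invalid sequence characters (alphabet is A/C/G/T) in record(s): ",
         paste(utils::head(dataset$id[!ok], 5), collapse = ", "), call. = FALSE)
  }
  if (!is.null(expect_length)) {
    len <- nchar(dataset$seq)
    if (any(len != expect_length)) {
      off <- which(len != expect_length)[1]
      stop(sprintf("record '%s' has length %d, expected %d",
                   dataset$id[off], len[off], expect_length), call. = FALSE)
    }
  }
  if (labeled) {
    if (!"label" %in% names(dataset) || anyNA(dataset$label)) {
      stop("dataset must carry a label for every record", call. = FALSE)
    }
    dataset$label <- as_promoter_label(dataset$label)
  } else if ("label" %in% names(dataset)) {
    lab <- as.character(dataset$label)
    lab[!is.na(lab)] <- as.character(as_promoter_label(lab[!is.na(lab)]))
    dataset$label <- factor(lab, levels = promoter_labels())
  }
  dataset
}
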