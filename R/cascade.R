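# Elimination cascade: six binary classifiers applied in a fixed order.
#
# Stage order and one-vs-pool composition:
#   ProMN   : promoter (any sigma)  vs  non-promoter
#   Sigma70 : S70  vs  {S54, S38, S32, S28, S24}
#   Sigma24 : S24  vs  {S54, S38, S32, S28}
#   Sigma28 : S28  vs  {S54, S38, S32}
#   Sigma38 : S38  vs  {S54, S32}
#   Sigma32 : S32  vs  {S54}
# The first stage whose probability reaches its threshold fixes the label
# (first-accept), a ProMN rejection yields NON_PROMOTER, and a record that
# every sigma stage rejects falls through to the residual class S54, which
# has no classifier of its own.

#' Cascade stage definitions
#'
#' @return data frame with one row per stage: `stage`, `positive` (label or
#'   `"PROMOTER"` for the first stage) and the comma-separated negative pool.
#' @export
cascade_stages <- function() {
  data.frame(
    stage = c("ProMN", "Sigma70", "Sigma24", "Sigma28", "Sigma38", "Sigma32"),
    positive = c("PROMOTER", "S70", "S24", "S28", "S38", "S32"),
    negatives = c("NON_PROMOTER",
                  "S54,S38,S32,S28,S24",
                  "S54,S38,S32,S28",
                  "S54,S38,S32",
                  "S54,S32",
                  "S54"),
    stringsAsFactors = FALSE
  )
}

.stage_positive_labels <- function(stage) {
  if (stage == "ProMN") sigma_labels()
  else cascade_stages()$positive[cascade_stages()$stage == stage]
}

.stage_negative_labels <- function(stage) {
  strsplit(cascade_stages()$negatives[cascade_stages()$stage == stage],
           ",", fixed = TRUE)[[1]]
}

#' Per-stage training splits
#'
#' Splits a labeled dataset into the six one-vs-pool binary problems of the
#' cascade. The first stage opposes all promoters to non-promoters; each
#' sigma stage opposes its class to the pool of classes not yet eliminated.
#'
#' @param dataset labeled dataset data frame.
#' @param stages stage names to build (default: all six).
#' @return named list; each element has `positives` and `negatives` data
#'   frames.
#' @export
make_cascade_training_sets <- function(dataset,
                                       stages = cascade_stages()$stage) {
  dataset <- validate_dataset(dataset, labeled = TRUE)
  lab <- as.character(dataset$label)
  out <- list()
  for (st in stages) {
    pos <- dataset[lab %in% .stage_positive_labels(st), , drop = FALSE]
    neg <- dataset[lab %in% .stage_negative_labels(st), , drop = FALSE]
    if (nrow(pos) == 0) {
      stop("no positive examples for stage ", st, call. = FALSE)
    }
    if (nrow(neg) == 0) {
      stop("no negative examples for stage ", st, call. = FALSE)
    }
    out[[st]] <- list(positives = pos, negatives = neg)
  }
  out
}

#' Assemble a cascade from classifiers
#'
#' Wraps six binary classifiers (anything implementing [predict_proba()])
#' into a cascade model. [train_cascade()] is the usual way to obtain one;
#' this constructor also accepts stubs for testing the decision logic.
#'
#' @param classifiers named list of classifiers covering every stage in
#'   [cascade_stages()].
#' @param thresholds per-stage decision thresholds (single value recycled).
#' @return object of class `cascade_model`.
#' @export
cascade_model <- function(classifiers, thresholds = 0.5) {
  stage_names <- cascade_stages()$stage
  if (!all(stage_names %in% names(classifiers))) {
    stop("classifiers must be named for all stages: ",
         paste(stage_names, collapse = ", "), call. = FALSE)
  }
  if (length(thresholds) == 1) {
    thresholds <- stats::setNames(rep(thresholds, 6), stage_names)
  }
  stopifnot(all(stage_names %in% names(thresholds)),
            all(thresholds > 0 & thresholds < 1))
  structure(list(
    stages = classifiers[stage_names],
    thresholds = thresholds[stage_names],
    residual_label = "S54"
  ), class = "cascade_model")
}

#' Train the full promoter cascade
#'
#' Trains one binary CNN per stage on its [make_cascade_training_sets()]
#' split. Stage s uses seed `train$seed + s - 1` so the whole cascade is
#' deterministic given the one seed.
#'
#' @param dataset labeled dataset covering every stage's classes.
#' @param arch an [arch_config()].
#' @param train a [train_config()].
#' @param verbose print per-stage progress.
#' @return a `cascade_model` of six trained `promoter_cnn` stages.
#' @export
train_cascade <- function(dataset, arch = arch_config(),
                          train = train_config(), verbose = FALSE) {
  dataset <- validate_dataset(dataset, labeled = TRUE)
  L <- unique(nchar(dataset$seq))
  if (length(L) != 1) stop("sequences must share one length", call. = FALSE)
  sets <- make_cascade_training_sets(dataset)
  classifiers <- list()
  for (i in seq_along(sets)) {
    st <- names(sets)[i]
    if (verbose) message("training stage ", st)
    split <- sets[[st]]
    seqs <- c(split$positives$seq, split$negatives$seq)
    y <- rep(c(1, 0), c(nrow(split$positives), nrow(split$negatives)))
    stage_train <- train
    stage_train$seed <- train$seed + i - 1L
    m <- build_model(arch, input_length = L, seed = stage_train$seed,
                     name = st)
    classifiers[[st]] <- fit(m, seqs, y, stage_train, verbose = verbose)
  }
  cascade_model(classifiers, thresholds = train$decision_threshold)
}

#' Classify sequences with the cascade
#'
#' Stages are evaluated in the fixed cascade order with short-circuiting:
#' a record rejected by ProMN is labeled NON_PROMOTER and no sigma stage is
#' evaluated for it; the first sigma stage whose probability reaches its
#' threshold assigns its label; a record rejected by all sigma stages gets
#' the residual label S54. Per-stage probabilities are reported, with NA
#' for stages that were never evaluated for that record.
#'
#' @param model a `cascade_model`.
#' @param x dataset data frame, character vector of sequences, or encoded
#'   array.
#' @return data frame with `id` (when available), `label` (factor over
#'   [promoter_labels()]) and one `p_<stage>` column per stage.
#' @export
cascade_predict <- function(model, x) {
  stopifnot(inherits(model, "cascade_model"))
  ids <- NULL
  if (is.data.frame(x)) {
    x <- validate_dataset(x)
    ids <- x$id
    x <- x$seq
  }
  if (is.character(x)) x <- encode_batch(x)
  n <- dim(x)[1]
  stage_names <- names(model$stages)
  probs <- matrix(NA_real_, n, length(stage_names),
                  dimnames = list(NULL, paste0("p_", stage_names)))
  label <- rep(NA_character_, n)

  # ProMN gate
  p1 <- predict_proba(model$stages[["ProMN"]], x)
  probs[, 1] <- p1
  rejected <- p1 < model$thresholds[["ProMN"]]
  label[rejected] <- "NON_PROMOTER"
  undecided <- which(!rejected)

  for (j in seq_along(stage_names)[-1]) {
    if (length(undecided) == 0) break
    st <- stage_names[j]
    pj <- predict_proba(model$stages[[st]],
                        x[undecided, , , drop = FALSE])
    probs[undecided, j] <- pj
    accept <- pj >= model$thresholds[[st]]
    label[undecided[accept]] <- .stage_positive_labels(st)
    undecided <- undecided[!accept]
  }
  label[undecided] <- model$residual_label

  out <- data.frame(label = factor(label, levels = promoter_labels()),
                    stringsAsFactors = FALSE)
  if (!is.null(ids)) out <- cbind(data.frame(id = ids), out)
  cbind(out, as.data.frame(probs))
}

#' Stub classifier emitting a fixed probability
#'
#' A test double for cascade logic: always predicts `prob` and counts how
#' many prediction calls it has received (readable via `stub_calls()`),
#' which makes short-circuit behavior observable.
#'
#' @param prob fixed probability in (0,1).
#' @param name optional stage name.
#' @return object of class `stub_classifier`.
#' @export
stub_classifier <- function(prob, name = "stub") {
  stopifnot(prob > 0, prob < 1)
  env <- new.env(parent = emptyenv())
  env$calls <- 0L
  structure(list(prob = prob, name = name, env = env),
            class = "stub_classifier")
}

#' @rdname stub_classifier
#' @param object a `stub_classifier`.
#' @export
stub_calls <- function(object) object$env$calls

#' @rdname predict_proba
#' @export
predict_proba.stub_classifier <- function(object, x, ...) {
  object$env$calls <- object$env$calls + 1L
  n <- if (is.character(x)) length(x) else dim(x)[1]
  rep(object$prob, n)
}

#' Save / load a cascade bundle
#'
#' A cascade bundle is a directory with a `cascade.json` manifest (stage
#' order, thresholds, residual label) and one model bundle per stage.
#'
#' @param model a `cascade_model` of `promoter_cnn` stages.
#' @param path bundle directory.
#' @return `save_cascade()`: `path` invisibly; `load_cascade()`: the model.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format = "promcascade-cascade", version = 1L,
    stages = names(model$stages),
    thresholds = as.list(model$thresholds),
    residual_label = model$residual_label
  )
  jsonlite::write_json(manifest, file.path(path, "cascade.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (st in names(model$stages)) {
    save_model(model$stages[[st]], file.path(path, st))
  }
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  mf <- file.path(path, "cascade.json")
  if (!file.exists(mf)) {
    stop("not a cascade bundle (missing cascade.json): ", path, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "promcascade-cascade")) {
    stop("not a promcascade cascade bundle: ", path, call. = FALSE)
  }
  classifiers <- lapply(manifest$stages, function(st) {
    load_model(file.path(path, st))
  })
  names(classifiers) <- manifest$stages
  thr <- unlist(manifest$thresholds)
  cascade_model(classifiers, thresholds = thr)
}
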