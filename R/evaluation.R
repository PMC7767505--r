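# Evaluation: confusion counts, Sn/Sp/Acc/MCC, stratified k-fold CV,
# ROC/AUC, positive-only TP/FN reporting, and the hyper-parameter grid.

#' Confusion counts of a binary prediction
#'
#' @param predicted,actual 0/1 vectors (or logicals) of equal length.
#' @return object of class `confusion_counts`: named integer vector with
#'   TP, TN, FP, FN.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  predicted <- as.integer(as.logical(predicted))
  actual <- as.integer(as.logical(actual))
  counts <- c(
    TP = sum(predicted == 1 & actual == 1),
    TN = sum(predicted == 0 & actual == 0),
    FP = sum(predicted == 1 & actual == 0),
    FN = sum(predicted == 0 & actual == 1)
  )
  structure(counts, class = "confusion_counts")
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' Evaluates, from TP/TN/FP/FN:
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}.}
#' Sn (resp. Sp) is `NA` when no actual positives (negatives) exist. When
#' any MCC denominator factor is zero the MCC is reported as 0 with the
#' attribute/flag `mcc_undefined = TRUE`.
#'
#' @param counts a [confusion()] result or named vector with TP/TN/FP/FN.
#' @return list with `Sn`, `Sp`, `Acc`, `MCC`, `mcc_undefined`.
#' @export
metrics <- function(counts) {
  counts <- counts[c("TP", "TN", "FP", "FN")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must contain non-negative TP, TN, FP, FN", call. = FALSE)
  }
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion matrix", call. = FALSE)
  sn <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  acc <- (tp + tn) / n
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) {
    mcc <- 0
    undef <- TRUE
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(denom)
    undef <- FALSE
  }
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc, mcc_undefined = undef)
}

#' Positive-only TP/FN bookkeeping
#'
#' For independent test sets that contain promoters only, per-class
#' performance is reported as true positives (records of the target class
#' predicted as that class) and false negatives (records of the target class
#' predicted as anything else); TP + FN equals the class prevalence.
#'
#' @param predicted,actual 7-way label vectors (coercible via
#'   [as_promoter_label()]); every actual label must be a promoter class.
#' @param target the sigma class to report.
#' @return named integer vector `c(TP=, FN=)`.
#' @export
positive_only_counts <- function(predicted, actual, target) {
  predicted <- as_promoter_label(predicted)
  actual <- as_promoter_label(actual)
  target <- as.character(as_promoter_label(target))
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have equal length", call. = FALSE)
  }
  if (any(actual == "NON_PROMOTER")) {
    stop("positive-only evaluation requires promoter-only actual labels",
         call. = FALSE)
  }
  is_target <- actual == target
  c(TP = sum(is_target & predicted == actual),
    FN = sum(is_target & predicted != actual))
}

#' Stratified k-fold assignment
#'
#' Assigns every record to one of k folds, stratified by label so per-class
#' fold sizes differ by at most one; deterministic given the seed.
#'
#' @param labels label vector (any type; used for stratification) or a
#'   labeled dataset data frame.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param stratified set FALSE for a plain random split.
#' @return integer vector of fold indices in 1..k, one per record.
#' @export
kfold_split <- function(labels, k = 5L, seed = 1L, stratified = TRUE) {
  if (is.data.frame(labels)) labels <- labels$label
  n <- length(labels)
  stopifnot(k >= 2, n >= k)
  .with_local_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (lv in unique(labels)) {
        idx <- which(labels == lv)
        if (length(idx) < k) {
          stop("class '", lv, "' has fewer than k=", k, " records",
               call. = FALSE)
        }
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), n))
    }
    folds
  })
}

#' k-fold cross-validation of a binary CNN
#'
#' Trains one model per fold on the remaining folds and evaluates Sn, Sp,
#' Acc, MCC and AUC on the held-out fold, aggregating by unweighted mean.
#'
#' @param seqs character vector of equal-length sequences (or pre-encoded
#'   array).
#' @param y binary 0/1 labels.
#' @param arch an [arch_config()].
#' @param train a [train_config()]; fold f trains with seed
#'   `train$seed + 100 + f`.
#' @param k number of folds.
#' @param seed seed of the fold assignment.
#' @param stratified stratify folds by label.
#' @return list with `per_fold` (data frame, one row per fold) and `mean`
#'   (named numeric vector of metric means).
#' @export
cross_validate <- function(seqs, y, arch = arch_config(),
                           train = train_config(), k = 5L, seed = 1L,
                           stratified = TRUE) {
  y <- as.numeric(y)
  x <- if (is.character(seqs)) encode_batch(seqs) else seqs
  stopifnot(length(y) == dim(x)[1])
  folds <- kfold_split(y, k = k, seed = seed, stratified = stratified)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- folds != f
    fold_train <- train
    fold_train$seed <- train$seed + 100L + f
    m <- build_model(arch, input_length = dim(x)[2],
                     seed = fold_train$seed, name = sprintf("cv_fold%d", f))
    m <- fit(m, x[tr, , , drop = FALSE], y[tr], fold_train)
    p <- predict_proba(m, x[!tr, , , drop = FALSE])
    met <- metrics(confusion(p >= fold_train$decision_threshold, y[!tr]))
    auc <- roc_auc(p, y[!tr])$auc
    rows[[f]] <- data.frame(fold = f, Sn = met$Sn, Sp = met$Sp,
                            Acc = met$Acc, MCC = met$MCC, AUC = auc)
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("Sn", "Sp", "Acc", "MCC", "AUC")],
                       na.rm = TRUE))
}

#' ROC curve and AUC
#'
#' Sweeps all observed score thresholds and computes the AUC as the
#' Mann-Whitney concordance probability (ties between a positive and a
#' negative score count 0.5), via average ranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return object of class `roc_curve`: list with `thresholds`, `tpr`,
#'   `fpr` (sweep from strictest to most permissive) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("ROC requires both classes", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1) / npos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0) / nneg, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' The hyper-parameter tuning grid
#'
#' Candidate values: convolution filters {8,16,32,64,128}, kernel sizes
#' {3,5,7,9,11}, pooling sizes {2,4}, dropout ratios {0.15,...,0.45 by
#' 0.05}, dense-layer neurons {8,16,32,64}. In the default "tied" mode one
#' value is drawn per field and applied to both convolutions / both dropout
#' layers, giving 5*5*2*7*4 = 1400 configurations; "untied" mode draws the
#' two kernels and two dropout rates independently.
#'
#' @param conv_filters,kernel_sizes,pool_sizes,dropout_ratios,dense_units
#'   candidate value sets.
#' @param tied tie the two conv/dropout layers to one drawn value each.
#' @return data frame of configurations, one row each.
#' @export
hyper_grid <- function(conv_filters = c(8L, 16L, 32L, 64L, 128L),
                       kernel_sizes = c(3L, 5L, 7L, 9L, 11L),
                       pool_sizes = c(2L, 4L),
                       dropout_ratios = seq(0.15, 0.45, by = 0.05),
                       dense_units = c(8L, 16L, 32L, 64L),
                       tied = TRUE) {
  if (tied) {
    g <- expand.grid(conv_filters = conv_filters, kernel = kernel_sizes,
                     pool = pool_sizes, dropout = dropout_ratios,
                     dense_units = dense_units,
                     KEEP.OUT.ATTRS = FALSE)
    g$kernel1 <- g$kernel; g$kernel2 <- g$kernel
    g$dropout1 <- g$dropout; g$dropout2 <- g$dropout
    g$kernel <- NULL; g$dropout <- NULL
  } else {
    g <- expand.grid(conv_filters = conv_filters, kernel1 = kernel_sizes,
                     kernel2 = kernel_sizes, pool = pool_sizes,
                     dropout1 = dropout_ratios, dropout2 = dropout_ratios,
                     dense_units = dense_units, KEEP.OUT.ATTRS = FALSE)
  }
  g
}

#' Grid search over architectures by cross-validated MCC
#'
#' Evaluates grid rows by [cross_validate()] mean MCC and returns them
#' ranked (descending MCC, ties broken by grid order). With a `budget`, a
#' seeded random subsample of rows is evaluated.
#'
#' @param grid data frame from [hyper_grid()].
#' @param seqs,y training sequences and binary labels.
#' @param train a [train_config()].
#' @param k folds per evaluation.
#' @param budget optional number of configurations to evaluate.
#' @param seed seed for subsampling and fold assignment.
#' @return the evaluated grid rows with a `mean_mcc` column, ranked.
#' @export
grid_search <- function(grid, seqs, y, train = train_config(), k = 5L,
                        budget = NULL, seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0) {
    stop("empty hyper-parameter grid", call. = FALSE)
  }
  rows <- seq_len(nrow(grid))
  if (!is.null(budget) && budget < nrow(grid)) {
    rows <- sort(.with_local_seed(seed, sample(rows, budget)))
  }
  x <- if (is.character(seqs)) encode_batch(seqs) else seqs
  mcc <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)) {
    r <- grid[rows[i], ]
    arch <- arch_config(
      conv1_filters = r$conv_filters, conv1_kernel = r$kernel1,
      conv2_filters = r$conv_filters, conv2_kernel = r$kernel2,
      pool_size = r$pool, pool_stride = r$pool,
      dropout1 = r$dropout1, dropout2 = r$dropout2,
      dense1_units = r$dense_units
    )
    cv <- cross_validate(x, y, arch = arch, train = train, k = k,
                         seed = seed)
    mcc[i] <- cv$mean[["MCC"]]
  }
  out <- grid[rows, , drop = FALSE]
  out$mean_mcc <- mcc
  out$grid_row <- rows
  out[order(-out$mean_mcc, out$grid_row), , drop = FALSE]
}

#' Evaluate a trained cascade on a labeled dataset
#'
#' Computes the promoter-vs-non-promoter confusion metrics (using the ProMN
#' stage decision), the 7-way accuracy, per-sigma-class one-vs-rest metrics
#' of the final labels, and the ProMN ROC AUC when both classes are present.
#'
#' @param model a `cascade_model`.
#' @param dataset labeled dataset.
#' @return list with `predictions`, `promoter_metrics`, `sevenway_accuracy`,
#'   `per_class`, and `promn_auc` (NA if one class absent).
#' @export
evaluate_cascade <- function(model, dataset) {
  dataset <- validate_dataset(dataset, labeled = TRUE)
  pred <- cascade_predict(model, dataset)
  actual <- as.character(dataset$label)
  called <- as.character(pred$label)
  is_prom_actual <- actual != "NON_PROMOTER"
  is_prom_called <- called != "NON_PROMOTER"
  prom_metrics <- if (length(unique(is_prom_actual)) == 2) {
    metrics(confusion(is_prom_called, is_prom_actual))
  } else NULL
  per_class <- lapply(sigma_labels(), function(s) {
    m <- metrics(confusion(called == s, actual == s))
    data.frame(class = s, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC)
  })
  auc <- if (length(unique(is_prom_actual)) == 2) {
    roc_auc(pred$p_ProMN, as.numeric(is_prom_actual))$auc
  } else NA_real_
  list(
    predictions = pred,
    promoter_metrics = prom_metrics,
    sevenway_accuracy = mean(called == actual),
    per_class = do.call(rbind, per_class),
    promn_auc = auc
  )
}
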