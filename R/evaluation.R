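#' Overall classification accuracy
#'
#' Mean of the indicator that prediction equals truth.
#'
#' @param pred,truth equal-length, non-empty label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth))
    stop("pred and truth must be non-empty vectors of equal length")
  mean(pred == truth)
}

#' Per-class sensitivity
#'
#' Fraction of class-`c` samples predicted as class `c` (recall of the
#' class).
#'
#' @param pred,truth label vectors.
#' @param c class id; must be present in `truth` (otherwise the metric is
#'   undefined and an error is raised rather than reporting 0).
#' @return A fraction in `[0, 1]`.
#' @export
sensitivity <- function(pred, truth, c) {
  if (length(pred) != length(truth)) stop("length mismatch")
  in_c <- truth == c
  if (!any(in_c))
    stop("sensitivity undefined: class ", c, " absent from truth")
  mean(pred[in_c] == c)
}

#' Per-class specificity
#'
#' Fraction of non-`c` samples predicted as any class other than `c`
#' (recall of the complement).
#'
#' @inheritParams sensitivity
#' @return A fraction in `[0, 1]`.
#' @export
specificity <- function(pred, truth, c) {
  if (length(pred) != length(truth)) stop("length mismatch")
  not_c <- truth != c
  if (!any(not_c))
    stop("specificity undefined: no non-", c, " samples in truth")
  mean(pred[not_c] != c)
}

#' Build an evaluation report from labels
#'
#' @param pred,truth label vectors.
#' @param classes full set of class ids.
#' @param level `"patch"` or `"image"`.
#' @return An `evaluation_report`: list with `acc`, named vectors `sen` and
#'   `spe`, `n` and `level`. Classes absent from `truth` get `NA` metrics.
#' @export
evaluation_report <- function(pred, truth, classes = sort(unique(truth)),
                              level = c("patch", "image")) {
  level <- match.arg(level)
  sen <- spe <- setNames(rep(NA_real_, length(classes)),
                         as.character(classes))
  for (cl in classes) {
    if (any(truth == cl)) sen[as.character(cl)] <- sensitivity(pred, truth, cl)
    if (any(truth != cl)) spe[as.character(cl)] <- specificity(pred, truth, cl)
  }
  structure(list(acc = accuracy(pred, truth), sen = sen, spe = spe,
                 n = length(truth), level = level),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s level, n = %d\n", x$level, x$n))
  cat(sprintf("  ACC %.4f\n", x$acc))
  for (cl in names(x$sen))
    cat(sprintf("  class %s: SEN %.4f  SPE %.4f\n", cl, x$sen[cl], x$spe[cl]))
  invisible(x)
}

#' Image-level evaluation of patch predictions
#'
#' Aggregates patch labels into one label per image by [majority_vote()]
#' and evaluates against the image ground truth.
#'
#' @param patch_preds data frame with columns `image_id` and `label` (one
#'   row per patch); every image needs at least one patch.
#' @param image_truth named vector or data frame (`image_id`, `class`) of
#'   true image labels.
#' @return An `evaluation_report` at `"image"` level.
#' @export
evaluate_images <- function(patch_preds, image_truth) {
  if (!all(c("image_id", "label") %in% names(patch_preds)))
    stop("patch_preds needs columns image_id, label")
  if (is.data.frame(image_truth))
    image_truth <- setNames(image_truth$class, image_truth$image_id)
  ids <- names(image_truth)
  missing <- setdiff(ids, unique(as.character(patch_preds$image_id)))
  if (length(missing) > 0)
    stop("image(s) with no patch predictions: ",
         paste(missing, collapse = ", "))
  voted <- vapply(ids, function(id) {
    majority_vote(patch_preds$label[as.character(patch_preds$image_id) == id])
  }, numeric(1))
  evaluation_report(voted, as.numeric(image_truth),
                    classes = sort(unique(as.numeric(image_truth))),
                    level = "image")
}

#' Image-level k-fold cross-validation of the selector
#'
#' Assigns whole images to folds (stratified by class), so the patches of
#' one image never straddle a train/test split — a deliberately strict
#' protocol that prevents leakage between near-identical patches. For each
#' fold a selector is trained on the remaining images' patch features and
#' evaluated on the held-out patches (patch level) and on their
#' majority-voted image labels (image level).
#'
#' @param dataset list with `rgb` and `rec` (`N x feature_dim` patch
#'   feature matrices), `labels` (patch class ids) and `image_id` (patch ->
#'   image assignment).
#' @param k number of folds (>= 2).
#' @param config a [selector_config()] used for every fold's model.
#' @param seed seed for the fold assignment.
#' @return A `cv_report`: list with per-fold `evaluation_report`s
#'   (`patch_folds`, `image_folds`), fold means and standard deviations
#'   per metric, and the fold assignment.
#' @export
cross_validate <- function(dataset, k = 10L, config = selector_config(),
                           seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  image_id <- as.character(dataset$image_id)
  ids <- unique(image_id)
  img_class <- vapply(ids, function(id)
    dataset$labels[image_id == id][1], numeric(1))
  if (any(vapply(ids, function(id)
    length(unique(dataset$labels[image_id == id])), integer(1)) != 1L))
    stop("patches of one image must share a single label")
  # stratified fold assignment at the image level
  set.seed(seed)
  fold_of <- setNames(integer(length(ids)), ids)
  for (cl in sort(unique(img_class))) {
    members <- sample(ids[img_class == cl])
    fold_of[members] <- rep_len(seq_len(k), length(members))
  }
  classes <- sort(unique(dataset$labels))
  patch_folds <- image_folds <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- ids[fold_of[ids] == f]
    tr <- !(image_id %in% test_ids)
    if (length(test_ids) == 0) stop("fold ", f, " is empty; reduce k")
    missing_cl <- setdiff(classes, dataset$labels[tr])
    if (length(missing_cl) > 0)
      stop("fold ", f, ": class ", paste(missing_cl, collapse = ", "),
           " missing from the training split")
    model <- train_selector(dataset$rgb[tr, , drop = FALSE],
                            dataset$rec[tr, , drop = FALSE],
                            dataset$labels[tr], config, classes = classes)
    te <- !tr
    pr <- predict_patches(model,
                          dataset$rgb[te, , drop = FALSE],
                          dataset$rec[te, , drop = FALSE])
    patch_folds[[f]] <- evaluation_report(pr$labels, dataset$labels[te],
                                          classes = classes, level = "patch")
    truth <- setNames(img_class[test_ids], test_ids)
    image_folds[[f]] <- evaluate_images(
      data.frame(image_id = image_id[te], label = pr$labels), truth)
  }
  structure(list(k = k, classes = classes, fold_of = fold_of,
                 patch_folds = patch_folds, image_folds = image_folds,
                 patch_summary = summarize_folds(patch_folds),
                 image_summary = summarize_folds(image_folds)),
            class = "cv_report")
}

summarize_folds <- function(folds) {
  acc <- vapply(folds, `[[`, numeric(1), "acc")
  sen <- do.call(rbind, lapply(folds, `[[`, "sen"))
  spe <- do.call(rbind, lapply(folds, `[[`, "spe"))
  list(acc_mean = mean(acc), acc_sd = sd(acc),
       sen_mean = colMeans(sen, na.rm = TRUE),
       sen_sd = apply(sen, 2, sd, na.rm = TRUE),
       spe_mean = colMeans(spe, na.rm = TRUE),
       spe_sd = apply(spe, 2, sd, na.rm = TRUE))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds (image-level splits), classes %s\n",
              x$k, paste(x$classes, collapse = "/")))
  fmt <- function(m, s) sprintf("(%.4f ± %.3f)", m, s)
  for (lvl in c("patch", "image")) {
    s <- x[[paste0(lvl, "_summary")]]
    cat(sprintf("  %s level: ACC %s\n", lvl, fmt(s$acc_mean, s$acc_sd)))
    for (cl in names(s$sen_mean))
      cat(sprintf("    class %s: SEN %s  SPE %s\n", cl,
                  fmt(s$sen_mean[cl], s$sen_sd[cl]),
                  fmt(s$spe_mean[cl], s$spe_sd[cl])))
  }
  invisible(x)
}

#' Tabulate a cross-validation report
#'
#' @param report a [cross_validate()] `cv_report`.
#' @param level `"patch"` or `"image"`.
#' @return A data frame with rows ACC / per-class SEN / per-class SPE and a
#'   `mean ± std` presentation column.
#' @export
report_table <- function(report, level = c("patch", "image")) {
  level <- match.arg(level)
  s <- report[[paste0(level, "_summary")]]
  rows <- data.frame(
    index = c("ACC", paste0("SEN_", names(s$sen_mean)),
              paste0("SPE_", names(s$spe_mean))),
    mean = c(s$acc_mean, unname(s$sen_mean), unname(s$spe_mean)),
    sd = c(s$acc_sd, unname(s$sen_sd), unname(s$spe_sd)))
  rows$formatted <- sprintf("(%.4f ± %.3f)", rows$mean, rows$sd)
  rows
}
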