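#' Leave-one-case-out RBF-SVM classification of SSD patches
#'
#' For every case: a diffusion map and an RBF SVM are fitted on all other
#' cases' representation columns (so the held-out case influences neither
#' the kernel bandwidth, the eigenbasis nor the SVM); the held-out patches
#' are embedded by the Nystrom extension and predicted per patch; the case
#' label is the majority vote over its patches, with ties counted as
#' errors. Accuracy is reported at both patch and case level; the headline
#' metric is case-level.
#'
#' @param rep a [build_representation_matrix()] result.
#' @param d diffusion-map dimensionality.
#' @param eps_scale multiple of the median squared pairwise distance used
#'   as the diffusion kernel bandwidth inside each fold. Classification
#'   uses a wide kernel (default 100): group structure in SSD columns sits
#'   at fine scales relative to the dominant patch-composition manifold,
#'   and a wide-bandwidth map (which approaches a linear, PCA-like
#'   embedding) preserves those distances where a locally tuned kernel
#'   buries them in low-eigenvalue directions.
#' @param svm_cost SVM cost parameter C.
#' @param svm_gamma RBF width; `NULL` uses the median heuristic
#'   `1 / median(||x_i - x_j||^2)` over the training-fold coordinates.
#' @param seed RNG seed (the fit is deterministic; the seed pins any
#'   library-internal randomness).
#' @return An object of class `loocv_result`: `cases` (per-case truth,
#'   prediction, vote counts), `patches` (per-patch predictions),
#'   `confusion` (case-level confusion matrix; tied votes are tallied as
#'   the wrong class), `case_accuracy`, `patch_accuracy`.
#' @export
loocv_classify <- function(rep, d = 8, eps_scale = 100, svm_cost = 10,
                           svm_gamma = NULL, seed = 1) {
  stopifnot(inherits(rep, "representation_matrix"))
  meta <- rep$meta
  groups <- unique(meta$group)
  if (length(groups) != 2L) stopf("classification needs exactly two groups")
  case_group <- meta$group[!duplicated(meta$case_id)]
  names(case_group) <- meta$case_id[!duplicated(meta$case_id)]
  if (min(table(case_group)) < 2L) stopf("need at least 2 cases per group")
  set.seed(seed)
  cases <- names(case_group)
  patch_pred <- vector("list", length(cases))
  case_rows <- vector("list", length(cases))
  for (ci in seq_along(cases)) {
    cs <- cases[ci]
    test <- which(meta$case_id == cs)
    train <- which(meta$case_id != cs)
    ytr <- factor(meta$group[train], levels = groups)
    if (length(unique(ytr)) < 2L) stopf("training fold for '%s' has one class", cs)
    Rtr <- rep$R[, train, drop = FALSE]
    D2 <- dist2_cross(t(Rtr), t(Rtr))
    med <- stats::median(D2[upper.tri(D2)])
    eps <- if (is.finite(med) && med > 0) med * eps_scale else 1
    dm <- diffusion_embed(Rtr, d = d, eps = eps)
    gamma <- svm_gamma
    if (is.null(gamma)) {
      md2 <- stats::median(stats::dist(dm$coords)^2)
      gamma <- if (is.finite(md2) && md2 > 0) 1 / md2 else 1
    }
    # inverse class weights: every LOOCV fold is one case short in the
    # held-out class, and an unweighted fit drifts toward the majority
    # class — a bias the per-case majority vote then amplifies
    wts <- length(ytr) / (2 * table(ytr))
    fit <- e1071::svm(dm$coords, ytr, kernel = "radial", cost = svm_cost,
                      gamma = gamma, scale = FALSE,
                      class.weights = wts)
    te_coords <- predict(dm, rep$R[, test, drop = FALSE])
    pred <- as.character(predict(fit, te_coords))
    votes <- table(factor(pred, levels = groups))
    truth <- case_group[[cs]]
    vote_lab <- if (votes[1L] == votes[2L]) NA_character_ else
      names(votes)[which.max(votes)]
    patch_pred[[ci]] <- data.frame(case_id = cs, patch = meta$patch[test],
                                   truth = truth, pred = pred)
    case_rows[[ci]] <- data.frame(case_id = cs, truth = truth,
                                  pred = vote_lab,
                                  votes_1 = unname(votes[1L]),
                                  votes_2 = unname(votes[2L]))
  }
  patches <- do.call(rbind, patch_pred)
  case_df <- do.call(rbind, case_rows)
  names(case_df)[4:5] <- paste0("votes_", groups)
  case_df$correct <- !is.na(case_df$pred) & case_df$pred == case_df$truth
  # tied votes count against the true class so the confusion matrix still
  # sums to the number of evaluated cases
  eff_pred <- ifelse(is.na(case_df$pred),
                     ifelse(case_df$truth == groups[1L], groups[2L], groups[1L]),
                     case_df$pred)
  confusion <- table(truth = factor(case_df$truth, levels = groups),
                     predicted = factor(eff_pred, levels = groups))
  structure(list(cases = case_df, patches = patches, confusion = confusion,
                 case_accuracy = mean(case_df$correct),
                 patch_accuracy = mean(patches$pred == patches$truth),
                 d = d, groups = groups),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d cases, case accuracy %.1f%%, patch accuracy %.1f%%\n",
              nrow(x$cases), 100 * x$case_accuracy, 100 * x$patch_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Spectral patch classification of a cohort of images
#'
#' Convenience pipeline: patch selection per ROI, representation matrix,
#' leave-one-case-out classification and marker ranking.
#'
#' @param images list of [multichannel_image()]s.
#' @param manifest a [cohort_manifest()].
#' @param patch_params a [patch_params()].
#' @param pagerank_params a [pagerank_params()].
#' @param d diffusion-map dimensionality.
#' @param ... passed to [loocv_classify()].
#' @return list with `representation`, `loocv`, `ranking`.
#' @export
spectral_classify <- function(images, manifest, patch_params = patch_params(),
                              pagerank_params = pagerank_params(), d = 8, ...) {
  patch_sets <- lapply(images, select_patches, params = patch_params)
  rep <- build_representation_matrix(patch_sets, manifest, pagerank_params)
  list(representation = rep,
       loocv = loocv_classify(rep, d = d, ...),
       ranking = rank_markers(rep))
}
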