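## Sequential forward feature selection scored by cross-validated
## classification error, with the feature-set size chosen by a
## Bernoulli-error BIC, and cross-fold feature union.

#' Bernoulli-error BIC for a feature-set size
#'
#' The classification error over `n` validated images is treated as a
#' Bernoulli rate p; `BIC(k) = -2 log L + k log(n)` with
#' `log L = n [p log p + (1-p) log(1-p)]`, p clamped to
#' `[1/(2n), 1 - 1/(2n)]` so the likelihood stays finite at p = 0 or 1.
#' `penalty_n = "features"` replaces the penalty's sample size with the
#' total feature count (a literal reading of the criterion's wording);
#' the default uses the conventional sample size.
#'
#' @param p classification error rate in `[0, 1]`.
#' @param k number of selected features.
#' @param n number of validated images.
#' @param penalty_n `"sample"` (default) or `"features"`.
#' @param n_features total feature count, used only for
#'   `penalty_n = "features"`.
#' @return The BIC value.
#' @export
bernoulli_bic <- function(p, k, n, penalty_n = c("sample", "features"),
                          n_features = 65L) {
  penalty_n <- match.arg(penalty_n)
  pc <- min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  nll <- -n * (pc * log(pc) + (1 - pc) * log(1 - pc))
  pen <- if (penalty_n == "sample") log(n) else log(n_features)
  2 * nll + k * pen
}

#' Sequential forward feature search with BIC-selected set size
#'
#' Greedy search: at each step the feature whose addition minimizes the
#' leave-one-subset-out classification error on `M` (the scorer) is
#' appended, ties broken by lower registry index. After each addition the
#' Bernoulli-error BIC is evaluated; the returned `selected_set` is the
#' prefix of the ranking minimizing BIC.
#'
#' @param M a [feature_matrix()] (the training data; its subsets form the
#'   inner cross-validation folds).
#' @param max_features maximal number of features to rank.
#' @param k_candidates mixture sizes for the inner classifier fits
#'   (default 1 keeps the inner loop closed-form and fast).
#' @param seed integer seed.
#' @param scorer optional function(feature_names) -> error rate, replacing
#'   the default inner cross-validation.
#' @param penalty_n,n_features see [bernoulli_bic()].
#' @return A `feature_selection` list: `ranked_features`, `errors`,
#'   `bic_curve`, `selected_set`, `n_validated`, `row_ids`.
#' @export
sequential_forward_search <- function(M, max_features = 15L,
                                      k_candidates = 1L, seed = 1L,
                                      scorer = NULL,
                                      penalty_n = "sample",
                                      n_features = ncol(M$X)) {
  all_feats <- colnames(M$X)
  n <- nrow(M$X)
  if (is.null(scorer)) {
    scorer <- function(feats)
      1 - cross_validate(M, k_candidates = k_candidates, seed = seed,
                         features = feats)$overall_accuracy
  }
  ranked <- character(0)
  errors <- numeric(0)
  bic <- numeric(0)
  remaining <- all_feats
  max_features <- min(max_features, length(all_feats))
  while (length(ranked) < max_features) {
    errs <- vapply(remaining, function(f) scorer(c(ranked, f)), numeric(1))
    best <- which.min(errs)           # ties: first = lowest registry index
    ranked <- c(ranked, remaining[best])
    errors <- c(errors, errs[best])
    bic <- c(bic, bernoulli_bic(errs[best], length(ranked), n,
                                penalty_n = penalty_n,
                                n_features = n_features))
    remaining <- remaining[-best]
  }
  k_opt <- which.min(bic)
  structure(list(ranked_features = ranked, errors = errors, bic_curve = bic,
                 selected_set = ranked[seq_len(k_opt)], n_validated = n,
                 row_ids = seq_len(n)),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %d ranked, %d selected (min BIC %.2f): %s\n",
              length(x$ranked_features), length(x$selected_set),
              min(x$bic_curve), paste(x$selected_set, collapse = ", ")))
  invisible(x)
}

#' Union of per-fold feature sets
#'
#' With limited training data the per-fold selections differ; the union of
#' all relevant features is used downstream. Features are ordered by the
#' earliest selection step at which any fold picked them, then by name.
#'
#' @param per_fold_sets list of character vectors, each in selection order.
#' @return Character vector: the ordered union.
#' @export
union_over_folds <- function(per_fold_sets) {
  if (length(per_fold_sets) == 0) stop("need at least one fold")
  steps <- list()
  for (s in per_fold_sets) {
    for (i in seq_along(s)) {
      f <- s[i]
      if (is.null(steps[[f]]) || steps[[f]] > i) steps[[f]] <- i
    }
  }
  if (length(steps) == 0) return(character(0))
  nm <- names(steps)
  st <- unlist(steps)
  nm[order(st, nm)]
}

#' Cross-validated classification with per-fold feature selection
#'
#' The full nested procedure: each subset is held out in turn; a sequential
#' forward search (with its own inner leave-one-subset-out loop, restricted
#' to the training subsets) selects a feature set; class mixtures are
#' fitted on the training rows over the selected features; the held-out
#' rows are classified. Feature ranking never sees the held-out subset.
#'
#' @param M a [feature_matrix()] with at least 3 subsets.
#' @param max_features maximal ranked features per fold.
#' @param k_candidates_inner mixture sizes inside the forward search.
#' @param k_candidates_final mixture sizes for the per-fold final models.
#' @param seed integer seed.
#' @return A list: `cv` (a `cv_report`), `per_fold_sets` (named list),
#'   `union_set`, `per_fold_row_ids` (training rows seen by each fold's
#'   search, for auditing).
#' @export
cross_validate_reduced <- function(M, max_features = 10L,
                                   k_candidates_inner = 1L,
                                   k_candidates_final = 1:4, seed = 1L) {
  subsets <- sort(unique(M$subset_ids))
  if (length(subsets) < 3) stop("nested selection needs at least 3 subsets")
  labs <- sort(unique(M$labels))
  conf <- table(factor(character(), labs), factor(character(), labs))
  per_fold <- data.frame(subset = character(), n_correct = integer(),
                         n_total = integer())
  sets <- list()
  ranked <- list()
  row_ids <- list()
  for (s in subsets) {
    test <- M$subset_ids == s
    train <- which(!test)
    Mtr <- feature_matrix(M$X[train, , drop = FALSE],
                          M$labels[train], M$subset_ids[train])
    sel <- sequential_forward_search(Mtr, max_features = max_features,
                                     k_candidates = k_candidates_inner,
                                     seed = seed)
    feats <- sel$selected_set
    sets[[s]] <- feats
    ranked[[s]] <- sel$ranked_features
    row_ids[[s]] <- train
    models <- lapply(setNames(labs, labs), function(l)
      fit_class_gmm(M$X[train, feats, drop = FALSE][M$labels[train] == l, ,
                                                    drop = FALSE],
                    k_candidates_final, seed = seed))
    pred <- vapply(which(test), function(i)
      classify(M$X[i, feats], models)$assigned_class, character(1))
    truth <- M$labels[test]
    conf <- conf + table(factor(truth, labs), factor(pred, labs))
    per_fold <- rbind(per_fold,
                      data.frame(subset = s, n_correct = sum(pred == truth),
                                 n_total = length(truth)))
  }
  cv <- structure(list(per_fold = per_fold,
                       overall_accuracy = sum(per_fold$n_correct) /
                         sum(per_fold$n_total),
                       confusion = conf, skipped_folds = character(0)),
                  class = "cv_report")
  list(cv = cv, per_fold_sets = sets, per_fold_ranked = ranked,
       union_set = union_over_folds(sets), per_fold_row_ids = row_ids)
}
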