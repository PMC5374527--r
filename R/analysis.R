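#' Build the screening feature table
#'
#' Joins an experiment design with its recorded traces into the table the
#' sensitivity analysis consumes: the seven study parameters as predictors
#' and the recorded state variables — mean `given_energy`, mean
#' `correlation`, and the time period — as responses.
#'
#' With `rows = "experiment"` (default) each run contributes one row: the
#' post-burn-in time averages of the two strategy means, with
#' `time_period` equal to the run's total number of periods (runs differ in
#' length through `rounds_per_generation`). With `rows = "period"` each
#' post-burn-in record contributes a row and `time_period` is the record's
#' period index.
#'
#' @param design A `curp_design` data frame.
#' @param traces Named list of traces as returned by [run_batch()]; failed
#'   runs (`NULL` entries) are dropped along with their design rows.
#' Note that with `rows = "experiment"` and runs of equal generation count,
#' `time_period` is a deterministic function of `rounds_per_generation`;
#' when that parameter varies across the design, per-period rows keep the
#' time axis from trivially encoding a predictor and are the mode the
#' sensitivity pipeline uses.
#'
#' @param burn_in_frac Fraction of each run discarded as burn-in.
#' @param rows Aggregation mode, `"experiment"` or `"period"`.
#' @param thin For `rows = "period"`, keep every `thin`-th record (the
#'   trajectories are strongly autocorrelated, so thinning loses little).
#' @return A data frame with the seven predictor columns plus
#'   `mean_given_energy`, `mean_correlation`, `time_period`.
#' @export
build_feature_table <- function(design, traces, burn_in_frac = 0.2,
                                rows = c("experiment", "period"),
                                thin = 1L) {
  rows <- match.arg(rows)
  keep <- !vapply(traces[design$run_id], is.null, logical(1))
  design <- design[keep, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, , drop = FALSE]
    tr <- traces[[row$run_id]]
    total <- max(tr$period)
    post <- trace_after_burn_in(tr, burn_in_frac * total)
    if (rows == "period" && thin > 1L)
      post <- post[seq(1L, nrow(post), by = thin), , drop = FALSE]
    pred <- row[rep(1L, if (rows == "experiment") 1L else nrow(post)),
                PARAM_COLS, drop = FALSE]
    if (rows == "experiment") {
      cbind(pred,
            mean_given_energy = mean(post$mean_given_energy),
            mean_correlation = mean(post$mean_correlation),
            time_period = total)
    } else {
      cbind(pred,
            mean_given_energy = post$mean_given_energy,
            mean_correlation = post$mean_correlation,
            time_period = post$period)
    }
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  stopifnot(!anyNA(out))
  out
}

RESPONSE_COLS <- c("mean_given_energy", "mean_correlation", "time_period")

#' First principal component of the recorded state variables
#'
#' Standardizes the three response columns (zero mean, unit variance — they
#' live on incomparable scales), drops zero-variance columns with a
#' warning, and returns the first principal-component score of each row.
#' The sign is fixed so that the loading of `mean_given_energy` (or, if it
#' was dropped, the first retained column) is nonnegative.
#'
#' @param table A feature table from [build_feature_table()] (any data
#'   frame containing the three response columns works).
#' @return Numeric score vector with attributes `rotation`, `sdev`, and
#'   `explained` (proportion of retained variance in PC1).
#' @export
pca_first_component <- function(table) {
  if (nrow(table) < 2L)
    stop("need at least two rows for PCA", call. = FALSE)
  missing_col <- setdiff(RESPONSE_COLS, names(table))
  if (length(missing_col))
    stop("missing response column(s): ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(table[, RESPONSE_COLS, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0L)
      stop("all response columns are constant", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, 1]
  anchor <- if ("mean_given_energy" %in% names(rot))
    rot[["mean_given_energy"]] else rot[[1]]
  flip <- if (anchor < 0) -1 else 1
  scores <- flip * pc$x[, 1]
  attr(scores, "rotation") <- flip * rot
  attr(scores, "sdev") <- pc$sdev
  attr(scores, "explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  scores
}

#' Published random-forest hyperparameter grids
#'
#' @return List with `n_trees` and `max_features` grids.
#' @export
rf_grid <- function() {
  list(n_trees = c(100, 200, 300, 400, 500, 600, 800, 1000),
       max_features = 2:7)
}

#' Hyperparameter selection by 10-fold cross-validated grid search
#'
#' For every `(n_trees, max_features)` combination the data are split into
#' `folds` equal parts; each part serves once as the test set for a forest
#' trained on the rest, and the fold mean squared errors are averaged. The
#' combination with the lowest mean CV MSE wins.
#'
#' @param features Data frame of predictors.
#' @param response Numeric response (typically [pca_first_component()]
#'   scores).
#' @param n_trees_grid,max_features_grid Hyperparameter grids; defaults are
#'   the published ones ([rf_grid()]).
#' @param folds Number of CV folds.
#' @return List of class `curp_cv`: `n_trees`, `max_features` (the
#'   minimizer), and `cv` — the full table with mean MSE and its standard
#'   error per combination.
#' @export
cv_grid_search <- function(features, response,
                           n_trees_grid = rf_grid()$n_trees,
                           max_features_grid = rf_grid()$max_features,
                           folds = 10) {
  n <- nrow(features)
  if (n < folds)
    stop(sprintf("only %d rows for %d folds; reduce `folds`", n, folds),
         call. = FALSE)
  if (!is.numeric(response) || any(!is.finite(response)))
    stop("response must be finite numeric", call. = FALSE)
  fold_id <- sample(rep_len(seq_len(folds), n))
  grid <- expand.grid(n_trees = n_trees_grid,
                      max_features = max_features_grid,
                      KEEP.OUT.ATTRS = FALSE)
  cv <- lapply(seq_len(nrow(grid)), function(i) {
    nt <- grid$n_trees[i]
    mf <- min(grid$max_features[i], ncol(features))
    mses <- vapply(seq_len(folds), function(f) {
      train <- fold_id != f
      fit <- randomForest::randomForest(
        x = features[train, , drop = FALSE], y = response[train],
        ntree = nt, mtry = mf)
      pred <- predict(fit, features[!train, , drop = FALSE])
      mean((pred - response[!train])^2)
    }, numeric(1))
    c(mse = mean(mses), se = sd(mses) / sqrt(folds))
  })
  cv <- cbind(grid, do.call(rbind, cv))
  best <- which.min(cv$mse)
  structure(list(n_trees = cv$n_trees[best],
                 max_features = cv$max_features[best],
                 cv = cv),
            class = "curp_cv")
}

#' Random-forest variable importance of the study parameters
#'
#' Fits a random-forest regressor of the response on the seven study
#' parameters and reports per-parameter relative importance, normalized to
#' sum to one with nonnegative entries.
#'
#' Two importance measures are provided: `"impurity"` (default) is the
#' total decrease in node impurity attributable to each predictor across
#' all trees; `"permutation_oob"` is the increase in out-of-bag MSE after
#' randomly permuting the predictor (negative raw values, which occur for
#' uninformative predictors, are floored at zero before normalization).
#'
#' @param features Data frame of the seven study parameters.
#' @param response Numeric response (typically [pca_first_component()]
#'   scores).
#' @param n_trees,max_features Forest hyperparameters; defaults are the
#'   published optimum from the 10-fold CV grid search.
#' @param method Importance measure.
#' @return A `curp_importance` data frame (`parameter`, `importance`),
#'   sorted descending, with attributes `method`, `n_trees`,
#'   `max_features`.
#' @export
variable_importance <- function(features, response, n_trees = 800,
                                max_features = 5,
                                method = c("impurity", "permutation_oob")) {
  method <- match.arg(method)
  if (!is.numeric(response) || any(!is.finite(response)))
    stop("response must be finite numeric", call. = FALSE)
  fit <- randomForest::randomForest(
    x = features, y = response, ntree = n_trees,
    mtry = min(max_features, ncol(features)),
    importance = method == "permutation_oob")
  raw <- if (method == "impurity") {
    fit$importance[, "IncNodePurity"]
  } else {
    pmax(randomForest::importance(fit, type = 1, scale = FALSE)[, 1], 0)
  }
  if (sum(raw) <= 0)
    stop("all importances are zero; nothing to normalize", call. = FALSE)
  imp <- raw / sum(raw)
  out <- data.frame(parameter = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "n_trees") <- n_trees
  attr(out, "max_features") <- max_features
  class(out) <- c("curp_importance", "data.frame")
  out
}

#' Full screening analysis: PCA response plus RF importance
#'
#' Convenience wrapper running [build_feature_table()],
#' [pca_first_component()], and [variable_importance()] in sequence.
#'
#' @inheritParams build_feature_table
#' @inheritParams variable_importance
#' @return A `curp_importance` data frame.
#' @export
importance_from_batch <- function(design, traces, burn_in_frac = 0.2,
                                  rows = "experiment", thin = 1L,
                                  n_trees = 800, max_features = 5,
                                  method = "impurity") {
  ft <- build_feature_table(design, traces, burn_in_frac = burn_in_frac,
                            rows = rows, thin = thin)
  pc1 <- pca_first_component(ft)
  variable_importance(ft[, PARAM_COLS], as.numeric(pc1),
                      n_trees = n_trees, max_features = max_features,
                      method = method)
}
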