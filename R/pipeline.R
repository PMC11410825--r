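# End-to-end orchestration: split -> features -> train both models ->
# MAPE fusion -> AISSO weight tuning -> metrics. All fitted artifacts
# (AC scaler, LCA index, min-max stats, model weights, fusion weights) are
# computed from the training and validation splits only; test labels touch
# nothing but the final metric computation.

#' Pipeline configuration
#'
#' @param lp Learning percentage: share of pairs used for training
#'   (60, 70, 80 or 90 in the usual experimental grid).
#' @param val_frac Fraction of the held-out remainder used for validation
#'   (the rest is the test split).
#' @param G Maximum auto-covariance gap.
#' @param rho,e0 Cubic-map parameters for the semantic-similarity weights.
#' @param symmetric_denominator Passed to [improved_semantic_similarity].
#' @param invert_weights Passed to [fusion_weights].
#' @param threshold Classification threshold on the fused score.
#' @param mrnn,dbn,aisso Named lists of overrides for [train_mrnn],
#'   [train_dbn_predict] and [aisso_config].
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(lp = 60, val_frac = 0.5, G = 2L,
                            rho = 2.59, e0 = 0.7,
                            symmetric_denominator = FALSE,
                            invert_weights = FALSE, threshold = 0.5,
                            mrnn = list(), dbn = list(), aisso = list(),
                            seed = 1L) {
  stopifnot(lp > 0, lp < 100, val_frac > 0, val_frac < 1)
  structure(list(lp = lp, val_frac = val_frac, G = G, rho = rho, e0 = e0,
                 symmetric_denominator = symmetric_denominator,
                 invert_weights = invert_weights, threshold = threshold,
                 mrnn = mrnn, dbn = dbn, aisso = aisso, seed = seed),
            class = "pipeline_config")
}

#' Stratified train/validation/test split of a pair list
#'
#' Within each label class, `lp` percent of the pairs go to training; the
#' remainder is split `val_frac` / `1 - val_frac` into validation and test.
#'
#' @param pairs Pair data.frame.
#' @param lp Learning percentage.
#' @param val_frac Validation share of the remainder.
#' @param seed RNG seed.
#' @return List of three pair data.frames: `train`, `val`, `test`.
#' @export
split_pairs <- function(pairs, lp = 60, val_frac = 0.5, seed = 1L) {
  set.seed(seed)
  idx_train <- idx_val <- idx_test <- integer(0)
  for (lab in unique(pairs$label)) {
    idx <- which(pairs$label == lab)
    idx <- idx[sample.int(length(idx))]
    n_tr <- round(lp / 100 * length(idx))
    rest <- idx[-seq_len(n_tr)]
    n_val <- round(val_frac * length(rest))
    idx_train <- c(idx_train, idx[seq_len(n_tr)])
    idx_val <- c(idx_val, rest[seq_len(n_val)])
    idx_test <- c(idx_test, rest[-seq_len(n_val)])
  }
  out <- list(train = pairs[sort(idx_train), , drop = FALSE],
              val = pairs[sort(idx_val), , drop = FALSE],
              test = pairs[sort(idx_test), , drop = FALSE])
  if (any(vapply(out, nrow, 0L) == 0L)) stop2("empty split; increase the pair count")
  out
}

fit_minmax <- function(X) {
  mn <- apply(X, 2L, min)
  mx <- apply(X, 2L, max)
  span <- mx - mn
  span[span <= .Machine$double.eps] <- 1
  list(min = mn, span = span)
}

apply_minmax <- function(X, mm) {
  clamp(sweep(sweep(X, 2L, mm$min), 2L, mm$span, "/"), 0, 1)
}

normalize_weights <- function(w) {
  s <- sum(w)
  if (!is.finite(s) || s < 1e-12) c(0.5, 0.5) else w / s
}

#' Fit the pair feature extractor on training pairs
#'
#' Computes raw auto-covariances for every protein, fits the AC scaler on
#' the proteins appearing in training pairs only, builds the LCA cluster
#' index from the training pairs, caches per-protein cluster term vectors,
#' and prepares per-namespace cubic-map weights for the semantic feature.
#'
#' @param data List with `proteins`, `dag` and `annotations`.
#' @param train_pairs Training pair data.frame.
#' @param config A [pipeline_config].
#' @param scales Scale table (default: bundled).
#' @return A `feature_extractor` object.
#' @export
fit_feature_extractor <- function(data, train_pairs, config = pipeline_config(),
                                  scales = load_scale_table()) {
  ac_raw <- ac_features(data$proteins, scales, config$G)
  train_prot <- unique(c(train_pairs$id_u, train_pairs$id_v))
  scaler <- fit_ac_scaler(ac_raw[train_prot, , drop = FALSE])
  ac_scaled <- apply_ac_scaler(ac_raw, scaler)
  rownames(ac_scaled) <- rownames(ac_raw)

  index <- suppressWarnings(build_lca_index(data$dag, train_pairs, data$annotations))
  tv <- lapply(data$proteins$id, function(p) {
    term_vector(index, data$dag, annotation_terms(data$annotations, p))
  })
  names(tv) <- data$proteins$id

  ns_order <- sort(names(data$dag$roots))
  omegas <- lapply(ns_order, function(ns) {
    m_ns <- sum(index$anchor_ns == ns)
    cubic_map_weights(config$rho, config$e0, m_ns)
  })
  names(omegas) <- ns_order

  structure(list(scales = scales, G = config$G, scaler = scaler,
                 ac_scaled = ac_scaled, index = index, tv = tv,
                 ns_order = ns_order, omegas = omegas,
                 rho = config$rho, e0 = config$e0,
                 symmetric_denominator = config$symmetric_denominator),
            class = "feature_extractor")
}

#' Build the pair feature matrix
#'
#' Concatenates, per pair: the two scaled AC vectors (canonical order), the
#' GO cluster feature vector, and one semantic-similarity scalar per
#' namespace.
#'
#' @param fx A `feature_extractor` from [fit_feature_extractor].
#' @param pairs Pair data.frame.
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(fx, pairs) {
  m <- fx$index$m
  ns_mask <- lapply(fx$ns_order, function(ns) fx$index$anchor_ns == ns)
  names(ns_mask) <- fx$ns_order
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    u <- pairs$id_u[i]; v <- pairs$id_v[i]
    ac <- pair_feature(fx$ac_scaled[u, ], fx$ac_scaled[v, ])
    gu <- fx$tv[[u]]; gv <- fx$tv[[v]]
    go <- gu + gv
    names(go) <- paste0("go.", fx$index$anchors)
    sem <- vapply(fx$ns_order, function(ns) {
      msk <- ns_mask[[ns]]
      if (!any(msk)) return(0)
      improved_semantic_similarity(gu[msk], gv[msk], fx$omegas[[ns]],
                                   fx$symmetric_denominator)
    }, 0)
    names(sem) <- paste0("sem.", fx$ns_order)
    c(ac, go, sem)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the full prediction stack on train and validation splits
#'
#' Feature extractor and min-max scaling fitted on training pairs; both
#' classifiers trained on the training split; MAPE fusion weights computed
#' on the validation split; AISSO tunes the fusion weights against the
#' validation mean squared error, seeded with the MAPE weights. No test
#' labels are used anywhere.
#'
#' @param data List with `proteins`, `dag` and `annotations`.
#' @param train_pairs,val_pairs Pair data.frames.
#' @param config A [pipeline_config].
#' @return A `ppi_model` with every fitted artifact.
#' @export
pipeline_fit <- function(data, train_pairs, val_pairs,
                         config = pipeline_config()) {
  fx <- fit_feature_extractor(data, train_pairs, config)
  Xtr_raw <- pair_features(fx, train_pairs)
  mm <- fit_minmax(Xtr_raw)
  Xtr <- apply_minmax(Xtr_raw, mm)
  Xval <- apply_minmax(pair_features(fx, val_pairs), mm)
  ytr <- train_pairs$label
  yval <- val_pairs$label

  mrnn <- train_mrnn(Xtr, ytr,
                     utils::modifyList(list(seed = config$seed + 1L), config$mrnn))
  dbn <- train_dbn_predict(Xtr, ytr,
                           utils::modifyList(list(seed = config$seed + 2L), config$dbn))
  vs1 <- mrnn_predict(mrnn$params, Xval)
  vs2 <- dbn_predict(dbn, Xval)
  fus <- fuse_models(yval, vs1, vs2, invert_weights = config$invert_weights)

  objective <- function(w) {
    wn <- normalize_weights(w)
    mean((yval - (wn[1] * vs1 + wn[2] * vs2))^2)
  }
  acfg <- do.call(aisso_config,
                  utils::modifyList(list(nd = 2L, seed = config$seed + 3L),
                                    config$aisso))
  opt <- aisso_optimize(objective, acfg, seed_solution = c(fus$w1, fus$w2))
  w_final <- normalize_weights(opt$best_par)

  structure(list(fx = fx, minmax = mm, mrnn = mrnn, dbn = dbn,
                 fusion = fus, objective = objective, aisso = opt,
                 w_final = w_final, config = config,
                 val_scores = list(mrnn = vs1, dbn = vs2), val_labels = yval),
            class = "ppi_model")
}

#' Score pairs with a fitted prediction stack
#'
#' @param model A `ppi_model` from [pipeline_fit].
#' @param data The data list the model was fitted on.
#' @param pairs Pair data.frame to score.
#' @return List with component scores `mrnn`, `dbn` and the `fused` score.
#' @export
pipeline_predict <- function(model, data, pairs) {
  X <- apply_minmax(pair_features(model$fx, pairs), model$minmax)
  s1 <- mrnn_predict(model$mrnn$params, X)
  s2 <- dbn_predict(model$dbn, X)
  list(mrnn = s1, dbn = s2,
       fused = fuse_scores(s1, s2, model$w_final[1], model$w_final[2]))
}

#' Run the full prediction pipeline
#'
#' Splits the pairs by learning percentage (stratified by label), fits the
#' whole stack on train/validation, and reports metrics on the held-out test
#' split.
#'
#' @param data List with `proteins`, `dag`, `annotations`; `NULL` generates
#'   a synthetic universe from `synth`.
#' @param pairs Labeled pair data.frame; `NULL` generates synthetic pairs.
#' @param config A [pipeline_config].
#' @param synth A [synth_config] used when `data` is `NULL`.
#' @return List with `metrics` (regression metrics plus `accuracy` on the
#'   test split), the fitted `model`, the `splits` and the test `scores`.
#' @export
run_pipeline <- function(data = NULL, pairs = NULL,
                         config = pipeline_config(),
                         synth = synth_config()) {
  if (is.null(data)) {
    data <- generate_universe(synth)
    pairs <- generate_pairs(data, synth)
  }
  if (is.null(pairs)) stop2("pairs must be supplied with external data")
  splits <- split_pairs(pairs, config$lp, config$val_frac, config$seed)
  model <- pipeline_fit(data, splits$train, splits$val, config)
  pred <- pipeline_predict(model, data, splits$test)
  ytest <- splits$test$label
  metrics <- suppressWarnings(regression_metrics(ytest, pred$fused))
  metrics$accuracy <- classification_accuracy(ytest, pred$fused, config$threshold)
  list(metrics = metrics, model = model, splits = splits, scores = pred)
}

#' Repeat the AISSO stage and summarize final objective values
#'
#' Re-runs the weight optimization of a fitted stack `R` times with distinct
#' seeds and summarizes the final validation objective values.
#'
#' @param model A `ppi_model` from [pipeline_fit] (or the `model` element of
#'   [run_pipeline] output).
#' @param R Number of repeats.
#' @param seeds Optional integer vector of length `R`.
#' @return List with the per-run `values` and `stats`
#'   (best/worst/mean/median/std, see [run_statistics]).
#' @export
run_pipeline_stats <- function(model, R = 10L, seeds = NULL) {
  if (R < 1L) stop2("R must be >= 1")
  if (is.null(seeds)) seeds <- model$config$seed + 100L + seq_len(R)
  stopifnot(length(seeds) == R)
  base <- utils::modifyList(list(nd = 2L), model$config$aisso)
  values <- vapply(seeds, function(s) {
    acfg <- do.call(aisso_config, utils::modifyList(base, list(seed = s)))
    aisso_optimize(model$objective, acfg,
                   seed_solution = c(model$fusion$w1, model$fusion$w2))$best_value
  }, 0)
  list(values = values, stats = run_statistics(values))
}
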