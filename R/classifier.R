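# Boosted decision-stump ensemble with tiered-agreement output.
#
# Discrete AdaBoost over axis-aligned stumps is used as a transparent,
# fully deterministic analogue of the toxin-like ranking ensemble: each
# member is an AdaBoost classifier; member agreement (votes) maps onto the
# four confidence tiers N < P1 < P2 < P3.

TIER_LEVELS <- c("N", "P1", "P2", "P3")

check_training_input <- function(features, labels) {
  if (!is.matrix(features) || !is.numeric(features)) {
    stop("'features' must be a numeric matrix")
  }
  if (is.null(colnames(features))) stop("'features' must have column names")
  if (anyNA(features) || any(!is.finite(features))) {
    stop("non-finite values in feature matrix")
  }
  if (length(labels) != nrow(features)) {
    stop("'labels' must have one entry per feature row")
  }
  if (!all(labels %in% c(-1, 1))) stop("labels must be coded -1/+1")
  if (length(unique(labels)) < 2L) {
    stop("training requires at least one positive and one negative example")
  }
}

# Best stump over all features for weighted labels. A stump predicts
# `polarity` when x > threshold and `-polarity` otherwise; thresholds are
# midpoints of consecutive distinct sorted feature values. Ties are broken
# by lowest feature index, then lowest threshold, then polarity +1.
best_stump <- function(features, labels, w) {
  best <- NULL
  best_err <- Inf
  for (j in seq_len(ncol(features))) {
    xj <- features[, j]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- labels[ord]
    ws <- w[ord]
    cut <- which(diff(xs) > 0)
    if (!length(cut)) next
    thr <- (xs[cut] + xs[cut + 1L]) / 2
    cum_pos <- cumsum(ws * (ys == 1))
    cum_neg <- cumsum(ws * (ys == -1))
    tot <- cum_pos[length(cum_pos)] + cum_neg[length(cum_neg)]
    # polarity +1: predict +1 above the threshold
    err_plus <- cum_pos[cut] + (cum_neg[length(cum_neg)] - cum_neg[cut])
    err_minus <- tot - err_plus
    jmin <- min(err_plus, err_minus)
    if (jmin < best_err) {
      ip <- which(err_plus == jmin)[1]
      im <- which(err_minus == jmin)[1]
      if (!is.na(ip) && (is.na(im) || ip <= im)) {
        best <- list(index = j, threshold = thr[ip], polarity = 1)
      } else {
        best <- list(index = j, threshold = thr[im], polarity = -1)
      }
      best_err <- jmin
    }
  }
  if (is.null(best)) stop("all features are constant; cannot fit a stump")
  best$feature <- colnames(features)[best$index]
  best
}

stump_predict <- function(features, index, threshold, polarity) {
  ifelse(features[, index] > threshold, polarity, -polarity)
}

#' Train one boosted-stump member classifier
#'
#' Discrete AdaBoost: `T` rounds of weighted stump fitting. Each round picks
#' the (feature, threshold, polarity) minimising the weighted 0/1 error over
#' thresholds at midpoints of sorted distinct feature values; the stump weight
#' is `alpha = 0.5 * log((1 - eps) / eps)` with `eps` clamped to
#' `[1e-10, 1 - 1e-10]`; example weights are multiplied by `exp(-alpha * y * h)`
#' and renormalised. Training is deterministic given the data.
#'
#' @param features numeric matrix (rows = examples, named columns).
#' @param labels numeric vector of -1/+1 labels.
#' @param T number of boosting rounds.
#' @return A member classifier: list with `stumps` (data frame of feature,
#'   threshold, polarity, alpha) and `train_error` (ensemble 0/1 training
#'   error after each round).
#' @export
train_member <- function(features, labels, T = 50L) {
  check_training_input(features, labels)
  if (T < 1) stop("'T' must be >= 1")
  n <- nrow(features)
  w <- rep(1 / n, n)
  stumps <- vector("list", T)
  margin <- numeric(n)
  train_error <- numeric(T)
  for (t in seq_len(T)) {
    s <- best_stump(features, labels, w)
    h <- stump_predict(features, s$index, s$threshold, s$polarity)
    eps <- sum(w[h != labels])
    eps <- min(max(eps, 1e-10), 1 - 1e-10)
    alpha <- 0.5 * log((1 - eps) / eps)
    w <- w * exp(-alpha * labels * h)
    w <- w / sum(w)
    s$alpha <- alpha
    stumps[[t]] <- s
    margin <- margin + alpha * h
    train_error[t] <- mean(sign(margin) != labels)
  }
  list(
    stumps = data.frame(
      feature = vapply(stumps, `[[`, character(1), "feature"),
      threshold = vapply(stumps, `[[`, numeric(1), "threshold"),
      polarity = vapply(stumps, `[[`, numeric(1), "polarity"),
      alpha = vapply(stumps, `[[`, numeric(1), "alpha"),
      stringsAsFactors = FALSE
    ),
    train_error = train_error
  )
}

member_margins <- function(member, features) {
  st <- member$stumps
  idx <- match(st$feature, colnames(features))
  m <- numeric(nrow(features))
  for (t in seq_len(nrow(st))) {
    m <- m + st$alpha[t] * stump_predict(features, idx[t], st$threshold[t], st$polarity[t])
  }
  m
}

#' Train the tiered ensemble
#'
#' Trains `M` AdaBoost members, each on a balanced bootstrap resample
#' (sampling with replacement `min(n_pos, n_neg)` examples from each class)
#' drawn with seeds `seed, seed + 1, ..., seed + M - 1`. The result is fully
#' determined by (data, T, M, seed).
#'
#' @param features numeric matrix (rows = examples, named columns).
#' @param labels numeric vector of -1/+1 labels.
#' @param T boosting rounds per member.
#' @param M number of ensemble members.
#' @param seed integer base seed for the bootstrap resamples.
#' @param tier_fractions named vector `c(p1 = , p2 = )` of member-vote
#'   fractions delimiting the P1 and P2 tiers (P3 requires unanimity).
#' @return A model object (list) with `members`, `feature_names`,
#'   `feature_version`, `tier_fractions` and `training_meta`.
#' @export
train_ensemble <- function(features, labels, T = 50L, M = 9L, seed = 1L,
                           tier_fractions = c(p1 = 0.5, p2 = 0.75)) {
  check_training_input(features, labels)
  if (M < 1) stop("'M' must be >= 1")
  pos <- which(labels == 1)
  neg <- which(labels == -1)
  n_each <- min(length(pos), length(neg))
  members <- vector("list", M)
  for (m in seq_len(M)) {
    set.seed(seed + m - 1L)
    idx <- c(
      sample(pos, n_each, replace = TRUE),
      sample(neg, n_each, replace = TRUE)
    )
    members[[m]] <- train_member(features[idx, , drop = FALSE], labels[idx], T = T)
  }
  list(
    format = "tolipscan-model",
    version = "1",
    feature_names = colnames(features),
    feature_version = FEATURE_CATALOGUE_VERSION,
    tier_fractions = as.list(tier_fractions),
    members = members,
    training_meta = list(
      n_pos = length(pos), n_neg = length(neg),
      n_each = n_each, T = T, M = M, seed = seed
    )
  )
}

tier_from_votes <- function(votes, M, tier_fractions) {
  thr_p2 <- ceiling(tier_fractions$p2 * M)
  thr_p1 <- ceiling(tier_fractions$p1 * M)
  ifelse(votes == M, "P3",
    ifelse(votes >= thr_p2, "P2",
      ifelse(votes >= thr_p1, "P1", "N")
    )
  )
}

#' Predict confidence tiers for a feature matrix
#'
#' Each member casts a vote when its signed margin is positive; the score is
#' the mean signed margin across members. Tiers: unanimous votes give P3,
#' at least `ceiling(p2 * M)` votes give P2, at least `ceiling(p1 * M)` give
#' P1, anything less is N (defaults 0.75 and 0.5).
#'
#' @param model a model from [train_ensemble()] or [read_model()].
#' @param features numeric matrix whose column names equal the model's
#'   `feature_names` (in order).
#' @return Data frame with columns `record_id`, `score`, `votes`, `tier`.
#' @export
predict_tiers <- function(model, features) {
  if (!identical(as.character(colnames(features)), as.character(model$feature_names))) {
    stop("feature names of the input do not match the model's feature_names")
  }
  M <- length(model$members)
  margins <- vapply(model$members, member_margins, numeric(nrow(features)),
                    features = features)
  margins <- matrix(margins, nrow = nrow(features), ncol = M)
  votes <- rowSums(margins > 0)
  data.frame(
    record_id = if (!is.null(rownames(features))) rownames(features) else
      as.character(seq_len(nrow(features))),
    score = rowMeans(margins),
    votes = as.integer(votes),
    tier = tier_from_votes(votes, M, model$tier_fractions),
    stringsAsFactors = FALSE
  )
}

#' Assemble a labelled training set from records
#'
#' @param records a protein record table containing every listed id.
#' @param positive_ids,negative_ids disjoint character vectors of record ids.
#' @param window polarity-profile window width.
#' @return List with `features` (matrix, positives first in the given order)
#'   and `labels` (+1/-1).
#' @export
build_training_set <- function(records, positive_ids, negative_ids, window = 5L) {
  if (length(intersect(positive_ids, negative_ids))) {
    stop("positive and negative id sets overlap")
  }
  if (length(positive_ids) == 0L || length(negative_ids) == 0L) {
    stop("both id sets must be non-empty")
  }
  ids <- c(positive_ids, negative_ids)
  missing <- setdiff(ids, records$id)
  if (length(missing)) {
    stop("ids absent from records: ", paste(missing, collapse = ", "))
  }
  sel <- records[match(ids, records$id), , drop = FALSE]
  list(
    features = feature_matrix(sel, window = window),
    labels = c(rep(1, length(positive_ids)), rep(-1, length(negative_ids)))
  )
}

#' Serialize a model to versioned JSON
#'
#' Full double precision is kept so that a written model reloads to
#' bit-identical predictions.
#'
#' @param model a model from [train_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  # 17 significant digits: doubles reload bit-exactly
  jsonlite::write_json(model, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @return `read_model` returns the model object.
#' @export
read_model <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(m$format, "tolipscan-model")) {
    stop("not a tolipscan model file: ", path)
  }
  m$feature_names <- unlist(m$feature_names)
  m$members <- lapply(m$members, function(mem) {
    st <- mem$stumps
    list(
      stumps = data.frame(
        feature = vapply(st, function(s) s$feature, character(1)),
        threshold = vapply(st, function(s) as.numeric(s$threshold), numeric(1)),
        polarity = vapply(st, function(s) as.numeric(s$polarity), numeric(1)),
        alpha = vapply(st, function(s) as.numeric(s$alpha), numeric(1)),
        stringsAsFactors = FALSE
      ),
      train_error = as.numeric(unlist(mem$train_error))
    )
  })
  m
}
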