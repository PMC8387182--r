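# Naive Bayes diagnosis with genetic-algorithm feature selection for tabular
# patient records with categorical features and a class label.

#' Fitness mapping
#'
#' `1 / (1 + exp(a))` in its printed (decreasing) orientation; with
#' `printed = FALSE` the conventional increasing sigmoid `1 / (1 + exp(-a))`
#' is used instead.
#'
#' @param a numeric score.
#' @param printed use the decreasing orientation (default TRUE).
#' @return value in `(0, 1)`.
#' @export
fitness_sigmoid <- function(a, printed = TRUE) {
  if (printed) 1 / (1 + exp(a)) else 1 / (1 + exp(-a))
}

#' Expected copy numbers for roulette selection
#'
#' Allocates `N` reproduction slots proportionally to fitness,
#' `e_x = N f_x / sum(f)`, rounding to integers by the largest-remainder rule
#' so the counts always sum to `N`.
#'
#' @param fitness_values positive fitness per individual.
#' @param N population size to allocate.
#' @return integer vector of copy counts summing to `N`.
#' @export
expected_copies <- function(fitness_values, N) {
  f <- as.numeric(fitness_values)
  if (any(f < 0) || sum(f) <= 0)
    config_error("fitness values must be non-negative with a positive sum")
  e <- N * f / sum(f)
  base <- floor(e)
  rem <- e - base
  short <- N - sum(base)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Joint probability of two events
#'
#' `P(M and N) = P(N | M) P(M)`; under independence this equals `P(N) P(M)`.
#'
#' @param p_n_given_m conditional probability `P(N | M)`.
#' @param p_m marginal probability `P(M)`.
#' @return the joint probability.
#' @export
joint_probability <- function(p_n_given_m, p_m) {
  if (any(c(p_n_given_m, p_m) < 0) || any(c(p_n_given_m, p_m) > 1))
    config_error("probabilities must lie in [0, 1]")
  p_n_given_m * p_m
}

#' Posteriors by the Bayes formula
#'
#' `P(N_j | M) = P(M | N_j) P(N_j) / sum_k P(M | N_k) P(N_k)`.
#'
#' @param likelihoods `P(M | N_j)` per hypothesis.
#' @param priors `P(N_j)`, summing to 1.
#' @return normalized posterior vector.
#' @export
bayes_posterior <- function(likelihoods, priors) {
  if (length(likelihoods) != length(priors))
    config_error("likelihoods and priors differ in length")
  num <- as.numeric(likelihoods) * as.numeric(priors)
  tot <- sum(num)
  if (tot <= 0) numeric_error("total probability is zero")
  num / tot
}

check_record_table <- function(table, class_col) {
  if (!is.data.frame(table)) config_error("records must be a data.frame")
  if (!class_col %in% names(table))
    config_error("class column '%s' not found", class_col)
  if (anyNA(table[[class_col]])) config_error("missing class labels")
  features <- setdiff(names(table), class_col)
  if (length(features) == 0) config_error("no feature columns")
  features
}

#' Fit a naive Bayes model
#'
#' Class priors and per-feature conditional tables estimated by additive
#' (Laplace) smoothing: `P(Y_k = v | C_j)` is the smoothed frequency of value
#' `v` among class-`j` records, the smoothing constant spread over the
#' feature's arity.
#'
#' @param table data.frame of categorical features plus a class column.
#' @param class_col name of the class column (default `"class"`).
#' @param smoothing additive smoothing constant (default 1; 0 reproduces raw
#'   frequencies and can yield zero probabilities on unseen values).
#' @return object of class `nb_model`: `priors`, `conditionals` (one
#'   class x value matrix per feature), `levels`, `smoothing`.
#' @export
nb_fit <- function(table, class_col = "class", smoothing = 1) {
  features <- check_record_table(table, class_col)
  cls <- factor(table[[class_col]])
  classes <- levels(cls)
  priors <- as.numeric(table(cls)) / length(cls)
  names(priors) <- classes
  conditionals <- list()
  lvls <- list()
  for (f in features) {
    x <- factor(table[[f]])
    lvls[[f]] <- levels(x)
    counts <- table(cls, x)  # classes x values
    cond <- (counts + smoothing) /
      (rowSums(counts) + smoothing * ncol(counts))
    conditionals[[f]] <- as.matrix(cond)
  }
  structure(list(priors = priors, conditionals = conditionals,
                 levels = lvls, classes = classes, smoothing = smoothing,
                 class_col = class_col),
            class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> %d classes (%s), %d features, smoothing %g\n",
              length(x$classes), paste(x$classes, collapse = ", "),
              length(x$conditionals), x$smoothing))
  invisible(x)
}

#' Classify a record with a naive Bayes model
#'
#' Scores each class by `P(C_j) prod_k P(Y_k | C_j)` over the features present
#' in the record and returns the arg-max class together with the normalized
#' posteriors.
#'
#' @param model an [nb_fit()] model.
#' @param record one-row data.frame or named list/vector of feature values.
#' @return list with `class` and `posteriors`.
#' @export
nb_predict <- function(model, record) {
  stopifnot(inherits(model, "nb_model"))
  record <- as.list(record)
  scores <- model$priors
  for (f in names(model$conditionals)) {
    if (is.null(record[[f]]) || is.na(record[[f]])) next
    v <- as.character(record[[f]])
    cond <- model$conditionals[[f]]
    if (!v %in% colnames(cond)) {
      if (model$smoothing == 0) {
        warning(sprintf("unseen value '%s' for feature '%s' with smoothing 0",
                        v, f))
        scores <- scores * 0
        next
      }
      # unseen value: uniform smoothed mass over an extra pseudo-level
      scores <- scores * (model$smoothing /
        (model$smoothing * (ncol(cond) + 1)))
      next
    }
    scores <- scores * cond[, v]
  }
  tot <- sum(scores)
  post <- if (tot > 0) scores / tot else rep(1 / length(scores), length(scores))
  names(post) <- model$classes
  list(class = model$classes[which.max(post)], posteriors = post)
}

nb_cv_accuracy <- function(table, class_col, mask, folds = 5L, smoothing = 1) {
  features <- setdiff(names(table), class_col)
  kept <- features[as.logical(mask)]
  n <- nrow(table)
  fold_id <- rep_len(seq_len(folds), n)
  correct <- 0L
  for (k in seq_len(folds)) {
    tr <- table[fold_id != k, c(kept, class_col), drop = FALSE]
    te <- table[fold_id == k, , drop = FALSE]
    if (length(unique(tr[[class_col]])) < 2) next
    m <- nb_fit(tr, class_col, smoothing)
    for (i in seq_len(nrow(te))) {
      pred <- nb_predict(m, te[i, kept, drop = FALSE])
      if (pred$class == as.character(te[[class_col]][i])) correct <- correct + 1L
    }
  }
  correct / n
}

#' Genetic-algorithm feature selection for naive Bayes
#'
#' Evolves binary feature masks: selection by [expected_copies()] of the
#' fitness values, one-point crossover, per-bit mutation, and elitism (the
#' best chromosome survives unchanged). A chromosome's raw score is the
#' cross-validated naive Bayes accuracy on its masked features; the score is
#' mapped through [fitness_sigmoid()] with the configured orientation
#' (`"conventional"` by default, so higher accuracy means higher fitness; the
#' printed decreasing form is available but inverts the selection pressure).
#'
#' @param table data.frame of categorical features plus a class column.
#' @param class_col name of the class column.
#' @param pop_size population size (default 30).
#' @param generations number of generations (default 50).
#' @param crossover_prob,mutation_prob one-point crossover probability and
#'   per-bit mutation rate.
#' @param folds cross-validation folds for the fitness evaluation.
#' @param smoothing Laplace constant passed to [nb_fit()].
#' @param orientation `"conventional"` or `"printed"` sigmoid orientation.
#' @param seed integer seed.
#' @return object of class `ga_result`: `mask` (best chromosome), `features`
#'   (selected names), `fitness`, `accuracy`, and `trace` (best-so-far fitness
#'   per generation).
#' @export
ga_select_features <- function(table, class_col = "class", pop_size = 30L,
                               generations = 50L, crossover_prob = 0.8,
                               mutation_prob = 0.02, folds = 5L,
                               smoothing = 1,
                               orientation = c("conventional", "printed"),
                               seed = NULL) {
  orientation <- match.arg(orientation)
  features <- check_record_table(table, class_col)
  nf <- length(features)
  printed <- orientation == "printed"
  cache <- new.env(parent = emptyenv())
  score_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    if (!is.null(cache[[key]])) return(cache[[key]])
    acc <- nb_cv_accuracy(table, class_col, mask, folds, smoothing)
    fit <- fitness_sigmoid(acc, printed = printed)
    cache[[key]] <- list(fitness = fit, accuracy = acc)
    cache[[key]]
  }
  repair <- function(mask) {
    if (sum(mask) == 0) mask[sample.int(nf, 1)] <- 1L
    mask
  }
  with_local_seed(seed, {
    pop <- lapply(seq_len(pop_size), function(i)
      repair(as.integer(stats::runif(nf) < 0.5)))
    trace <- numeric(generations)
    best <- NULL
    for (gen in seq_len(generations)) {
      scored <- lapply(pop, score_mask)
      fits <- vapply(scored, `[[`, 0, "fitness")
      gen_best <- which.max(fits)
      if (is.null(best) || fits[gen_best] > best$fitness) {
        best <- list(mask = pop[[gen_best]], fitness = fits[gen_best],
                     accuracy = scored[[gen_best]]$accuracy)
      }
      trace[gen] <- best$fitness
      copies <- expected_copies(fits, pop_size)
      pool <- pop[rep(seq_along(pop), copies)]
      pool <- pool[sample.int(length(pool))]
      nxt <- list(best$mask)  # elitism
      while (length(nxt) < pop_size) {
        a <- pool[[sample.int(length(pool), 1)]]
        b <- pool[[sample.int(length(pool), 1)]]
        if (stats::runif(1) < crossover_prob && nf > 1) {
          cut <- sample.int(nf - 1, 1)
          child <- c(a[seq_len(cut)], b[(cut + 1):nf])
        } else {
          child <- a
        }
        flip <- stats::runif(nf) < mutation_prob
        child[flip] <- 1L - child[flip]
        nxt[[length(nxt) + 1L]] <- repair(child)
      }
      pop <- nxt
    }
    structure(list(mask = best$mask, features = features[best$mask == 1L],
                   fitness = best$fitness, accuracy = best$accuracy,
                   trace = trace, orientation = orientation),
              class = "ga_result")
  })
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> selected {%s}, CV accuracy %.3f, fitness %.4f\n",
              paste(x$features, collapse = ", "), x$accuracy, x$fitness))
  invisible(x)
}

#' Sample synthetic diagnosis records from a known naive Bayes model
#'
#' Draws the class from `priors`, then each feature independently from its
#' class-conditional table -- so the conditional-independence assumption holds
#' by construction and the generating parameters are recoverable.
#'
#' @param n number of records.
#' @param priors named class prior vector.
#' @param conditionals list (per feature) of class x value probability
#'   matrices with row names matching the classes.
#' @param seed integer seed.
#' @return data.frame of factor features plus a `class` column.
#' @export
synth_records <- function(n, priors, conditionals, seed = NULL) {
  classes <- names(priors)
  if (is.null(classes)) config_error("priors must be named by class")
  with_local_seed(seed, {
    cls <- sample(classes, n, replace = TRUE, prob = priors)
    out <- list()
    for (f in names(conditionals)) {
      tab <- conditionals[[f]]
      vals <- colnames(tab)
      out[[f]] <- vapply(cls, function(cj)
        sample(vals, 1, prob = tab[cj, ]), "")
    }
    out$class <- cls
    data.frame(lapply(out, factor))
  })
}
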