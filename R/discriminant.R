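# Forward stepwise linear discriminant analysis with Wilks' Lambda entry,
# canonical discriminant functions, structure matrix and leave-one-out
# classification. SSCP notation: W = pooled within-group sums of squares and
# cross-products, T = total SSCP, Lambda(S) = det(W_S) / det(T_S).

# listwise-complete numeric matrix + group factor from a measurement table
.design <- function(data, variables) {
  stopifnot(is.data.frame(data), "species" %in% names(data),
            all(variables %in% names(data)))
  X <- as.matrix(data[, variables, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- stats::complete.cases(X) & !is.na(data$species)
  X <- X[keep, , drop = FALSE]
  g <- factor(as.character(data$species)[keep])
  if (nlevels(g) < 2) stop("need at least 2 species", call. = FALSE)
  if (any(table(g) < 1)) stop("empty group", call. = FALSE)
  list(X = X, g = g, ids = data$specimen_id[keep] %||% which(keep))
}

.sscp <- function(X, g) {
  grand <- colMeans(X)
  Tc <- sweep(X, 2, grand)
  Tm <- crossprod(Tc)
  W <- matrix(0, ncol(X), ncol(X), dimnames = dimnames(Tm))
  for (lv in levels(g)) {
    Xg <- X[g == lv, , drop = FALSE]
    Wc <- sweep(Xg, 2, colMeans(Xg))
    W <- W + crossprod(Wc)
  }
  list(W = W, T = Tm, B = Tm - W, grand = grand)
}

.wilks <- function(sscp, idx) {
  if (!length(idx)) return(1)
  dw <- det(sscp$W[idx, idx, drop = FALSE])
  dt <- det(sscp$T[idx, idx, drop = FALSE])
  if (!is.finite(dw) || !is.finite(dt) || dt <= 0) return(NA_real_)
  dw / dt
}

#' Univariate tests of equality of group means
#'
#' For each variable, the univariate Wilks' Lambda (within over total sum of
#' squares) and its F transform `F = ((1 - Lambda)/Lambda) * ((N - k)/(k - 1))`
#' with (k - 1, N - k) degrees of freedom, on the listwise-complete rows --
#' the screening table conventionally printed alongside a discriminant
#' analysis. Rows are ordered by decreasing F.
#'
#' @param data Measurement data.frame with a `species` column.
#' @param variables Candidate variables; defaults to those of
#'   [hook_variables()] present in `data`.
#' @return Data.frame: variable, wilks_lambda, F, df1, df2, p.
#' @export
equality_of_group_means <- function(data, variables = NULL) {
  variables <- variables %||% intersect(hook_variables(), names(data))
  d <- .design(data, variables)
  s <- .sscp(d$X, d$g)
  N <- nrow(d$X); k <- nlevels(d$g)
  df1 <- k - 1; df2 <- N - k
  out <- lapply(seq_along(variables), function(j) {
    sst <- s$T[j, j]
    if (sst <= 0) {
      warning(sprintf("variable %s has zero total variance; Lambda undefined",
                      variables[j]))
      return(data.frame(variable = variables[j], wilks_lambda = NA_real_,
                        F = NA_real_, df1 = df1, df2 = df2, p = NA_real_))
    }
    lam <- s$W[j, j] / sst
    Fv <- (1 - lam) / lam * (df2 / df1)
    data.frame(variable = variables[j], wilks_lambda = lam, F = Fv,
               df1 = df1, df2 = df2,
               p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$F), ]
  rownames(out) <- NULL
  out
}

#' Forward stepwise variable selection by Wilks' Lambda
#'
#' At each step the candidate variable minimizing the overall Wilks' Lambda
#' enters, provided its F-to-enter -- computed from the partial-Lambda ratio
#' with (k - 1, N - k - p) degrees of freedom, p the number already entered --
#' reaches `f_enter`; after each entry, entered variables whose F-to-remove
#' falls below `f_remove` leave. The procedure stops when no entry or removal
#' qualifies. With no variables entered, the entry F reduces to the
#' univariate F of [equality_of_group_means()]. Candidates whose addition
#' makes the within-group SSCP singular are skipped with a logged warning.
#'
#' @param data Measurement data.frame with a `species` column.
#' @param variables Candidate variables.
#' @param f_enter,f_remove Partial-F thresholds (defaults 3.84 / 2.71).
#' @return List with `selected` (ordered by entry) and `log` (data.frame:
#'   step, action, variable, lambda, F, df1, df2).
#' @export
stepwise_select <- function(data, variables = NULL, f_enter = 3.84,
                            f_remove = 2.71) {
  variables <- variables %||% intersect(hook_variables(), names(data))
  if (length(variables) < 2) {
    stop("need at least 2 candidate variables", call. = FALSE)
  }
  d <- .design(data, variables)
  s <- .sscp(d$X, d$g)
  N <- nrow(d$X); k <- nlevels(d$g)
  selected <- integer(0)
  log <- list()
  step <- 0L
  lambda_cur <- 1

  partial_F <- function(lam_ratio, q) {
    # q = variables in the smaller model
    (1 - lam_ratio) / lam_ratio * ((N - k - q) / (k - 1))
  }

  repeat {
    q <- length(selected)
    if (N - k - q < 1) break
    cand <- setdiff(seq_along(variables), selected)
    if (!length(cand)) break
    lam_new <- vapply(cand, function(j) .wilks(s, c(selected, j)), numeric(1))
    ratio <- lam_new / lambda_cur
    bad <- !is.finite(ratio) | ratio <= 0 | ratio > 1 + 1e-8
    if (any(bad)) {
      for (j in cand[bad]) {
        log[[length(log) + 1L]] <- data.frame(
          step = step + 1L, action = "skipped", variable = variables[j],
          lambda = NA_real_, F = NA_real_, df1 = k - 1, df2 = N - k - q,
          stringsAsFactors = FALSE)
        warning(sprintf("candidate %s skipped: singular within-group SSCP",
                        variables[j]))
      }
    }
    ok <- which(!bad)
    if (!length(ok)) break
    Fs <- partial_F(pmin(ratio[ok], 1), q)
    best <- ok[which.min(lam_new[ok])]
    Fbest <- partial_F(min(ratio[best], 1), q)
    if (Fbest < f_enter) break
    step <- step + 1L
    selected <- c(selected, cand[best])
    lambda_cur <- lam_new[best]
    log[[length(log) + 1L]] <- data.frame(
      step = step, action = "entered", variable = variables[cand[best]],
      lambda = lambda_cur, F = Fbest, df1 = k - 1, df2 = N - k - q,
      stringsAsFactors = FALSE)

    # removal phase
    repeat {
      p <- length(selected)
      if (p <= 1) break
      lam_without <- vapply(selected, function(j) {
        .wilks(s, setdiff(selected, j))
      }, numeric(1))
      ratio_r <- lambda_cur / lam_without
      Fr <- partial_F(pmin(pmax(ratio_r, .Machine$double.xmin), 1), p - 1)
      worst <- which.max(ratio_r) # largest ratio = least contribution
      if (!is.finite(Fr[worst]) || Fr[worst] >= f_remove) break
      step <- step + 1L
      removed <- selected[worst]
      selected <- selected[-worst]
      lambda_cur <- .wilks(s, selected)
      log[[length(log) + 1L]] <- data.frame(
        step = step, action = "removed", variable = variables[removed],
        lambda = lambda_cur, F = Fr[worst], df1 = k - 1, df2 = N - k - p + 1,
        stringsAsFactors = FALSE)
    }
    if (step > 4 * length(variables)) break # cycling guard
  }
  list(selected = variables[selected],
       log = if (length(log)) do.call(rbind, log) else
         data.frame(step = integer(0), action = character(0),
                    variable = character(0), lambda = numeric(0),
                    F = numeric(0), df1 = integer(0), df2 = integer(0)))
}

#' Fit canonical discriminant functions
#'
#' Canonical functions are the eigenvectors of `solve(W) %*% B` (W, B the
#' pooled within- and between-group SSCP of the selected variables), ordered
#' by eigenvalue and scaled so canonical scores have pooled within-group
#' variance 1. Also computes group centroids in canonical space, the pooled
#' within-group covariance, and the structure matrix: pooled within-group
#' correlations of every candidate variable (entered or not) with each
#' canonical function.
#'
#' @param data Measurement data.frame with a `species` column.
#' @param selected Selected (entered) variables, non-empty.
#' @param priors Named prior probabilities per species, `"equal"` (default)
#'   or `"proportional"`, or a numeric vector summing to 1.
#' @param candidates All candidate variables for the structure matrix;
#'   defaults to those of [hook_variables()] present in `data`.
#' @return A `discriminant_model` list.
#' @export
fit_canonical <- function(data, selected, priors = "equal",
                          candidates = NULL) {
  if (!length(selected)) stop("no variables selected", call. = FALSE)
  candidates <- candidates %||% intersect(hook_variables(), names(data))
  candidates <- union(candidates, selected)
  d <- .design(data, candidates)
  X <- d$X[, selected, drop = FALSE]
  g <- d$g
  N <- nrow(X); k <- nlevels(g); p <- ncol(X)
  s <- .sscp(X, g)
  if (N - k < p) stop("too few specimens for the selected set", call. = FALSE)
  Sw <- s$W / (N - k)
  qW <- tryCatch(solve(s$W), error = function(e) NULL)
  if (is.null(qW)) {
    stop("singular pooled within-group SSCP for variables: ",
         paste(selected, collapse = ", "), call. = FALSE)
  }
  m <- min(k - 1, p)
  e <- eigen(qW %*% s$B)
  ord <- order(-Re(e$values))[seq_len(m)]
  V <- Re(e$vectors[, ord, drop = FALSE])
  ev <- Re(e$values[ord])
  # scale: pooled within-group variance of each score = 1
  for (j in seq_len(m)) {
    sc <- sqrt(drop(t(V[, j]) %*% Sw %*% V[, j]))
    V[, j] <- V[, j] / sc
    big <- which.max(abs(V[, j]))
    if (V[big, j] < 0) V[, j] <- -V[, j] # deterministic sign
  }
  dimnames(V) <- list(selected, paste0("function", seq_len(m)))

  grand <- s$grand
  scores <- sweep(X, 2, grand) %*% V
  centroids <- apply(scores, 2, function(col) tapply(col, g, mean))
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(levels(g), colnames(V)))

  # priors
  if (is.character(priors)) {
    priors <- switch(match.arg(priors, c("equal", "proportional")),
                     equal = stats::setNames(rep(1 / k, k), levels(g)),
                     proportional = table(g) / N)
    priors <- stats::setNames(as.numeric(priors), levels(g))
  } else {
    stopifnot(length(priors) == k, abs(sum(priors) - 1) < 1e-8)
    if (is.null(names(priors))) names(priors) <- levels(g)
    priors <- priors[levels(g)]
  }

  # structure matrix over all candidates: pooled within-group correlations
  Xa <- d$X
  struct <- matrix(NA_real_, ncol(Xa), m,
                   dimnames = list(candidates, colnames(V)))
  for (v in seq_len(ncol(Xa))) {
    for (j in seq_len(m)) {
      cw <- vw <- sw <- 0
      for (lv in levels(g)) {
        xi <- Xa[g == lv, v] - mean(Xa[g == lv, v])
        si <- scores[g == lv, j] - mean(scores[g == lv, j])
        cw <- cw + sum(xi * si)
        vw <- vw + sum(xi^2)
        sw <- sw + sum(si^2)
      }
      struct[v, j] <- cw / sqrt(vw * sw)
    }
  }

  group_means <- do.call(rbind, lapply(levels(g), function(lv) {
    colMeans(X[g == lv, , drop = FALSE])
  }))
  rownames(group_means) <- levels(g)

  structure(list(variables = selected, coefficients = V,
                 grand_mean = grand[selected], eigenvalues = ev,
                 n_functions = m, centroids = centroids,
                 group_means = group_means, pooled_cov = Sw,
                 priors = priors, structure_matrix = struct,
                 counts = table(g), levels = levels(g)),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("<discriminant_model: %d group(s), %d canonical function(s)>\n",
              length(x$levels), x$n_functions))
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify specimens with a discriminant model
#'
#' Assigns each specimen to the group with smallest Mahalanobis distance to
#' the group mean in the selected-variable space (pooled within-group
#' covariance), penalized by `-2 log(prior)`.
#'
#' @param model A [fit_canonical()] model.
#' @param newdata Measurement data.frame containing the model variables.
#' @return Factor of predicted species.
#' @export
predict_discriminant <- function(model, newdata) {
  X <- as.matrix(newdata[, model$variables, drop = FALSE])
  storage.mode(X) <- "double"
  d2 <- vapply(model$levels, function(lv) {
    stats::mahalanobis(X, model$group_means[lv, ], model$pooled_cov) -
      2 * log(model$priors[[lv]])
  }, numeric(nrow(X)))
  d2 <- matrix(d2, nrow = nrow(X))
  factor(model$levels[max.col(-d2, ties.method = "first")],
         levels = model$levels)
}

#' Original and leave-one-out classification tables
#'
#' Original (resubstitution) classification uses the full-data model;
#' cross-validated classification refits the group means and pooled
#' covariance on each n - 1 subset while keeping the selected variable set
#' fixed, and classifies the held-out specimen. Folds that would leave a
#' group with fewer than 2 members are skipped with a warning and flagged.
#'
#' @param data Measurement data.frame with a `species` column.
#' @param selected Selected variables (fixed across folds).
#' @param priors As in [fit_canonical()].
#' @return A `classification_result` list: `original` and `cv` factors,
#'   count and percentage tables for both, overall percent correct, and
#'   canonical scores per specimen.
#' @export
classify_loo <- function(data, selected, priors = "equal") {
  d <- .design(data, selected)
  full <- fit_canonical(data, selected, priors = priors,
                        candidates = selected)
  df_used <- data.frame(d$X, check.names = FALSE)
  original <- predict_discriminant(full, df_used)
  n <- nrow(d$X)
  cv <- factor(rep(NA_character_, n), levels = full$levels)
  for (i in seq_len(n)) {
    sub <- data.frame(species = as.character(d$g[-i]),
                      d$X[-i, , drop = FALSE], check.names = FALSE)
    if (min(table(sub$species)) < 2) {
      warning(sprintf("fold %d skipped: a group would drop below 2 members",
                      i))
      next
    }
    mi <- tryCatch(fit_canonical(sub, selected, priors = priors,
                                 candidates = selected),
                   error = function(e) {
                     warning(sprintf("fold %d skipped: %s", i,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(mi)) next
    cv[i] <- as.character(predict_discriminant(mi, df_used[i, , drop = FALSE]))
  }
  truth <- factor(as.character(d$g), levels = full$levels)
  counts_orig <- table(truth, original)
  counts_cv <- table(truth, cv, useNA = "no")
  pct <- function(tab) {
    sweep(tab, 1, pmax(rowSums(tab), 1), "/") * 100
  }
  overall <- function(pred) {
    ok <- !is.na(pred)
    100 * sum(pred[ok] == truth[ok]) / sum(ok)
  }
  scores <- sweep(d$X[, full$variables, drop = FALSE], 2, full$grand_mean) %*%
    full$coefficients
  structure(list(original = original, cv = cv, truth = truth,
                 counts = list(original = counts_orig, cv = counts_cv),
                 percent = list(original = pct(counts_orig),
                                cv = pct(counts_cv)),
                 overall = list(original = overall(original),
                                cv = overall(cv)),
                 scores = data.frame(specimen_id = d$ids,
                                     species = as.character(d$g), scores,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE),
                 model = full),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Original: %.2f%% correct; cross-validated: %.2f%% correct\n",
              x$overall$original, x$overall$cv))
  cat("\nOriginal counts:\n"); print(x$counts$original)
  cat("\nCross-validated counts:\n"); print(x$counts$cv)
  invisible(x)
}

#' Full stepwise discriminant pipeline
#'
#' Forward stepwise selection, canonical fit with structure matrix, and
#' original + leave-one-out classification, in one call.
#'
#' @inheritParams stepwise_select
#' @inheritParams fit_canonical
#' @return List: `selection` (from [stepwise_select()]), `model`,
#'   `classification` (a [classify_loo()] result), `equality`
#'   (the [equality_of_group_means()] table).
#' @export
#' @examples
#' d <- generate_measurements(diplozoid_presets(), seed = 1)
#' res <- discriminant_analysis(d)
#' res$classification$overall
discriminant_analysis <- function(data, variables = NULL, f_enter = 3.84,
                                  f_remove = 2.71, priors = "equal") {
  variables <- variables %||% intersect(hook_variables(), names(data))
  sel <- stepwise_select(data, variables, f_enter = f_enter,
                         f_remove = f_remove)
  if (!length(sel$selected)) {
    stop("no variable met the entry criterion", call. = FALSE)
  }
  model <- fit_canonical(data, sel$selected, priors = priors,
                         candidates = variables)
  cls <- classify_loo(data, sel$selected, priors = priors)
  list(selection = sel, model = model, classification = cls,
       equality = equality_of_group_means(data, variables))
}
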