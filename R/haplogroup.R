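#' Train a haplogroup classifier (regularized LDA)
#'
#' Linear discriminant analysis on numeric-encoded genotype calls at a
#' small probe panel, used to assign mitochondrial (5 classes) or
#' Y-chromosome (6 classes) haplogroups. With a handful of probes and
#' near-constant within-class genotypes the pooled within-class covariance
#' is singular, so it is always shrunk toward a diagonal target:
#' `S* = (1 - lambda) S + lambda * mean(diag(S)) I`, with a small ridge
#' floor to guarantee positive definiteness.
#'
#' @param x Numeric matrix, samples x probes (genotype dosages; NAs
#'   allowed and imputed to the column mean for training).
#' @param labels Class labels, one per row of `x`.
#' @param probes Probe names (default: column names of `x`).
#' @param lambda Shrinkage weight in `[0, 1]` (default 0.5).
#' @param ridge Diagonal floor added to the shrunk covariance.
#' @param priors Class prior probabilities (default: uniform — training-set
#'   class sizes reflect panel design, not population frequencies).
#' @return An object of class `haplogroup_model`.
#' @export
train_haplogroup_classifier <- function(x, labels, probes = colnames(x),
                                        lambda = 0.5, ridge = 1e-3,
                                        priors = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), lambda >= 0, lambda <= 1)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes to train")
  if (min(table(labels)) < 1L) stop("every class needs a training sample")
  if (is.null(probes)) probes <- paste0("p", seq_len(ncol(x)))
  colnames(x) <- probes
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
  }
  p <- ncol(x)
  means <- t(vapply(classes, function(k) colMeans(x[labels == k, , drop = FALSE]),
                    numeric(p)))
  S <- matrix(0, p, p)
  for (k in classes) {
    xk <- x[labels == k, , drop = FALSE]
    if (nrow(xk) > 1L) S <- S + crossprod(sweep(xk, 2, colMeans(xk)))
  }
  dof <- max(nrow(x) - length(classes), 1L)
  S <- S / dof
  target <- mean(diag(S))
  if (!is.finite(target) || target <= 0) target <- 1
  Sreg <- (1 - lambda) * S + lambda * target * diag(p)
  diag(Sreg) <- diag(Sreg) + ridge
  if (is.null(priors)) priors <- rep(1 / length(classes), length(classes))
  structure(list(classes = classes, means = means, cov = Sreg,
                 priors = stats::setNames(priors, classes), probes = probes,
                 lambda = lambda),
            class = "haplogroup_model")
}

#' @export
print.haplogroup_model <- function(x, ...) {
  cat("<haplogroup_model> ", length(x$classes), " classes {",
      paste(x$classes, collapse = ", "), "} on ", length(x$probes),
      " probes\n", sep = "")
  invisible(x)
}

#' Assign a haplogroup to one or more samples
#'
#' Gaussian discriminant scores with the model's shared (regularized)
#' covariance; missing probes are tolerated by restricting the score to the
#' observed dimensions, provided at least half the model's probes are
#' present. Posteriors come from a log-sum-exp softmax over the class
#' scores.
#'
#' @param model A `haplogroup_model`.
#' @param x Numeric vector of probe dosages (named by probe), or a matrix
#'   samples x probes.
#' @param min_posterior Posterior below which the call is flagged
#'   low-confidence (default 0.8).
#' @return data.frame with `label`, `posterior`, `low_confidence`.
#' @export
assign_haplogroup <- function(model, x, min_posterior = 0.8) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  x <- as.matrix(x)
  if (!is.null(colnames(x))) {
    missing_probes <- setdiff(model$probes, colnames(x))
    x2 <- matrix(NA_real_, nrow(x), length(model$probes),
                 dimnames = list(rownames(x), model$probes))
    x2[, intersect(model$probes, colnames(x))] <-
      x[, intersect(model$probes, colnames(x)), drop = FALSE]
    x <- x2
  } else if (ncol(x) != length(model$probes)) {
    stop("unnamed input must cover all ", length(model$probes), " probes")
  }
  K <- length(model$classes)
  out <- data.frame(label = character(nrow(x)), posterior = numeric(nrow(x)),
                    low_confidence = logical(nrow(x)))
  for (i in seq_len(nrow(x))) {
    obs <- which(!is.na(x[i, ]))
    if (length(obs) < length(model$probes) / 2)
      stop("sample ", i, " covers fewer than half the model probes")
    Sinv <- solve(model$cov[obs, obs, drop = FALSE])
    xi <- x[i, obs]
    scores <- vapply(seq_len(K), function(k) {
      mu <- model$means[k, obs]
      d <- xi - mu
      -0.5 * drop(d %*% Sinv %*% d) + log(model$priors[k])
    }, 0)
    post <- exp(scores - max(scores))
    post <- post / sum(post)
    j <- which.max(post)
    out$label[i] <- model$classes[j]
    out$posterior[i] <- post[j]
    out$low_confidence[i] <- post[j] < min_posterior
  }
  out
}
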