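# ROC analysis and logistic-regression biomarker panels. The ROC machinery
# delegates to pROC (AUC, DeLong-type confidence interval, curve
# coordinates), the field-standard implementation; the panel fit is an
# ordinary maximum-likelihood logistic regression with block entry of all
# features.

#' ROC curve and AUC for a single score
#'
#' Computes the ROC curve of \code{score} against a binary \code{label},
#' the area under the curve (equivalent to the Mann-Whitney rank statistic,
#' ties counted one half) and an asymptotic DeLong confidence interval.
#' Higher scores are taken to indicate the positive class.
#'
#' @param score numeric vector.
#' @param label binary labels (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @param conf_level confidence level for the AUC interval.
#' @param ci_method "delong" (asymptotic, default) or "bootstrap".
#' @return a list of class \code{roc_result}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, and \code{curve} — a data frame of (fpr, tpr) points
#'   from (0, 0) to (1, 1).
#' @export
roc_auc <- function(score, label, conf_level = 0.95,
                    ci_method = c("delong", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  lab <- as_binary_label(label)
  if (length(unique(lab)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = lab, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  # pROC emits advisory warnings (e.g. for degenerate AUC == 1 intervals)
  ci <- suppressWarnings(
    pROC::ci.auc(r, conf.level = conf_level,
                 method = if (ci_method == "delong") "delong" else "bootstrap"))
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = as.numeric(ci[1]), ci_high = as.numeric(ci[3]),
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC = %.3f (%.3f-%.3f)\n", x$auc, x$ci_low, x$ci_high))
  invisible(x)
}

as_binary_label <- function(label) {
  if (is.logical(label)) return(as.integer(label))
  if (is.factor(label)) {
    if (nlevels(label) != 2) stop("label must have exactly two levels")
    return(as.integer(label == levels(label)[2]))
  }
  u <- sort(unique(label))
  if (length(u) > 2) stop("label must be binary")
  as.integer(label == u[length(u)])
}

#' Logistic-regression biomarker panel
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome on all
#' supplied features entered as one block (no variable selection), and
#' scores the in-sample predicted probabilities by ROC analysis. Because the
#' predicted probability is a monotone function of the linear predictor, the
#' panel AUC is well defined even under complete separation; separation is
#' reported via the \code{separation} flag.
#'
#' @param features numeric matrix or data frame, samples x features.
#' @param label binary outcome per sample.
#' @param conf_level confidence level for the panel AUC interval.
#' @return a list of class \code{panel_model}: \code{coefficients},
#'   \code{intercept}, \code{predicted_prob}, \code{separation}, and
#'   \code{roc} (a \code{roc_result}).
#' @export
logistic_panel <- function(features, label, conf_level = 0.95) {
  features <- as.data.frame(features)
  if (is.null(names(features)) || any(names(features) == ""))
    names(features) <- paste0("feature", seq_along(features))
  lab <- as_binary_label(label)
  if (length(unique(lab)) < 2) stop("both classes must be present")
  dat <- cbind(.outcome = lab, features)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.outcome ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  prob <- stats::fitted(fit)
  # squeeze into the open interval so downstream probability contracts hold
  eps <- .Machine$double.eps
  prob <- pmin(pmax(prob, eps), 1 - eps)
  structure(list(feature_names = names(features),
                 coefficients = stats::coef(fit)[-1],
                 intercept = stats::coef(fit)[1],
                 predicted_prob = prob,
                 separation = separation,
                 roc = roc_auc(prob, lab, conf_level = conf_level)),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic biomarker panel:", paste(x$feature_names, collapse = " + "),
      "\n")
  if (x$separation) cat("(note: complete separation detected)\n")
  print(x$roc)
  invisible(x)
}
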