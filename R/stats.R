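#' One-sample Kolmogorov-Smirnov normality screen
#'
#' KS distance of the sample against a normal distribution with the sample's
#' own mean and SD, with the asymptotic p-value — the classical "KS Z"
#' normality screen (no Lilliefors correction for estimated parameters, so
#' the p-value is conservative).
#'
#' @param values numeric vector, `n >= 5`.
#' @return list `statistic` (D), `p_value`.
#' @export
ks_one_sample_normal <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 5L) {
    stop("need at least 5 values")
  }
  s <- stats::sd(values)
  if (s == 0) {
    stop("zero variance sample")
  }
  res <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over pooled points of the absolute ECDF difference;
#' the p-value is the asymptotic two-sided one (appropriate at the n ~ 10^3
#' per group this pipeline produces).
#'
#' @param x,y numeric samples, both non-empty.
#' @return list `statistic` (D), `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("empty sample")
  }
  res <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' ROC AUC with Hanley-McNeil standard error
#'
#' AUC via the Mann-Whitney identity: the fraction of (positive, negative)
#' pairs with positive > negative, ties counted half. The treated
#' (mesenchymal-shifted) group is the positive class and scores are used
#' as-is — no direction flipping, so orientation-dependent descriptors sit
#' near 0.5 by construction. SE by Hanley & McNeil's formula with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`.
#'
#' @param pos,neg numeric descriptor values for the positive (treated) and
#'   negative (untreated) group.
#' @param descriptor optional descriptor name carried in the result.
#' @return object of class `roc_result`: `descriptor`, `auc`, `se`, `n_pos`,
#'   `n_neg`, `direction` (always `"as_is"`).
#' @export
roc_auc <- function(pos, neg, descriptor = NA_character_) {
  np <- length(pos)
  nn <- length(neg)
  if (np == 0L || nn == 0L) {
    stop("both groups must be non-empty")
  }
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (np - 1) * (q1 - auc^2) +
        (nn - 1) * (q2 - auc^2)) / (np * nn)
  structure(list(descriptor = descriptor,
                 auc = auc,
                 se = sqrt(max(v, 0)),
                 n_pos = np,
                 n_neg = nn,
                 direction = "as_is"),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %s: AUC %.4f (SE %.4f), n+ %d / n- %d\n",
              x$descriptor, x$auc, x$se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two AUCs
#'
#' Two-sided z-test `z = (auc_a - auc_b) / sqrt(se_a^2 + se_b^2)` with a
#' normal p-value. The correlation between AUCs computed on the same cells is
#' ignored (independence approximation), which makes the test conservative
#' for positively correlated descriptors.
#'
#' @param a,b [roc_auc()] results.
#' @return list `statistic` (z), `p_value`.
#' @export
compare_aucs <- function(a, b) {
  if (a$n_pos != b$n_pos || a$n_neg != b$n_neg) {
    warning("AUCs come from different sample sizes; ",
            "correlation between them is ignored")
  }
  z <- (a$auc - b$auc) / sqrt(a$se^2 + b$se^2)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Stats-stage configuration
#'
#' @param alpha significance threshold (default 0.05).
#' @param positive_group group label treated as the positive class.
#' @return list of class `stats_config`.
#' @export
stats_config <- function(alpha = 0.05, positive_group = "treated") {
  structure(list(alpha = alpha, positive_group = positive_group),
            class = "stats_config")
}

#' Rank descriptors by ROC AUC
#'
#' For every descriptor column: the two-sample KS comparison between groups
#' and the AUC with its SE, sorted by AUC descending (ties broken stably by
#' descriptor name); plus the upper-triangle matrix of pairwise AUC
#' comparison p-values in ranked order. No multiple-testing correction is
#' applied.
#'
#' @param features feature table (`data.frame` with `group_label` and
#'   descriptor columns).
#' @param descriptors descriptor columns to rank; default all present from
#'   `feature_names()`.
#' @param config a [stats_config()].
#' @return list of class `rank_report`: `ranking` (`data.frame` with
#'   `descriptor`, `auc`, `se`, `ks_D`, `ks_p`, `rank`), `pairwise_p`
#'   (matrix, upper triangle), `alpha`, `n_pos`, `n_neg`.
#' @export
rank_parameters <- function(features, descriptors = NULL,
                            config = stats_config()) {
  if (is.null(descriptors)) {
    descriptors <- intersect(feature_names(), names(features))
  }
  if (length(descriptors) < 1L) {
    stop("no descriptor columns found")
  }
  is_pos <- features$group_label == config$positive_group
  if (!any(is_pos) || all(is_pos)) {
    stop("need both a positive ('", config$positive_group,
         "') and a negative group")
  }
  rocs <- list()
  rows <- lapply(descriptors, function(d) {
    pos <- features[[d]][is_pos]
    neg <- features[[d]][!is_pos]
    ks <- ks_two_sample(pos, neg)
    rr <- roc_auc(pos, neg, descriptor = d)
    rocs[[d]] <<- rr
    data.frame(descriptor = d, auc = rr$auc, se = rr$se,
               ks_D = ks$statistic, ks_p = ks$p_value,
               stringsAsFactors = FALSE)
  })
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$auc, ranking$descriptor)
  ranking <- ranking[ord, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  k <- nrow(ranking)
  pw <- matrix(NA_real_, k, k,
               dimnames = list(ranking$descriptor, ranking$descriptor))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        pw[i, j] <- compare_aucs(rocs[[ranking$descriptor[i]]],
                                 rocs[[ranking$descriptor[j]]])$p_value
      }
    }
  }
  structure(list(ranking = ranking,
                 pairwise_p = pw,
                 alpha = config$alpha,
                 n_pos = sum(is_pos),
                 n_neg = sum(!is_pos)),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  cat(sprintf("Descriptor ranking by ROC AUC (positive n = %d, negative n = %d)\n",
              x$n_pos, x$n_neg))
  df <- x$ranking
  cat(sprintf("%4s %-20s %8s %8s %10s\n",
              "rank", "descriptor", "AUC", "SE", "KS p"))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("%4d %-20s %8.4f %8.4f %10.3g\n", df$rank[i],
                df$descriptor[i], df$auc[i], df$se[i], df$ks_p[i]))
  }
  cat("No multiple-testing correction applied.\n")
  invisible(x)
}
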