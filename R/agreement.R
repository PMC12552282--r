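#' Agreement weights for ordered rating categories
#'
#' Weight matrix used by the chance-corrected agreement coefficient.
#' `"linear"` (default) sets `w[k, l] = 1 - |k - l| / (K - 1)` from the
#' category ranks, `"quadratic"` squares the rank distance, `"identity"`
#' scores only exact matches (reducing AC2 to AC1).
#'
#' @param n_categories number of ordered categories K (>= 2).
#' @param type weighting family.
#' @return K x K symmetric weight matrix with unit diagonal.
#' @export
agreement_weights <- function(n_categories,
                              type = c("linear", "quadratic", "identity")) {
  type <- match.arg(type)
  K <- as.integer(n_categories)
  if (K < 2L) stop("need at least 2 categories", call. = FALSE)
  d <- abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1L)
  switch(type,
         linear = 1 - d,
         quadratic = 1 - d^2,
         identity = diag(K) * 1)
}

#' @noRd
as_ratings_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    ln <- tolower(names(scores))
    if (all(c("item_id", "rater_id", "score") %in% ln)) {
      names(scores) <- ln
      scores <- stats::xtabs(score ~ item_id + rater_id, scores,
                             addNA = FALSE) /
        stats::xtabs(~ item_id + rater_id, scores)
      scores <- matrix(as.numeric(scores), nrow(scores),
                       dimnames = dimnames(scores))
      scores[is.nan(scores)] <- NA
    } else {
      scores <- as.matrix(scores)
    }
  }
  if (!is.matrix(scores)) stop("`scores` must be an items x raters matrix ",
                               "or a long data frame", call. = FALSE)
  storage.mode(scores) <- "double"
  scores
}

#' Gwet's AC2 chance-corrected interrater agreement
#'
#' Computes Gwet's AC2 agreement coefficient for ordinal ratings from
#' multiple raters, `AC2 = (Pa - Pe) / (1 - Pe)`, where the weighted
#' observed agreement `Pa` averages, per item, the weighted concordance
#' over all rater pairs, and the chance agreement
#' `Pe = Tw / (q (q - 1)) * sum(pi_k (1 - pi_k))` uses the overall
#' category propensities `pi_k` and the total weight `Tw`. Missing cells
#' are handled by pairwise deletion within item; items rated by fewer than
#' two raters contribute to the propensities only. The variance follows
#' Gwet's item-level linearization and the confidence interval is the
#' normal approximation `AC2 +/- z * SE`, truncated to [-1, 1].
#'
#' If a single category is used by every rater on every item the
#' coefficient is 1 by convention and the result is flagged degenerate
#' (zero variance).
#'
#' @param scores items x raters matrix of ordinal scores (NAs allowed),
#'   or a long data frame with columns `item_id`, `rater_id`, `score`.
#' @param weights weighting family passed to [agreement_weights()], or a
#'   full weight matrix.
#' @param categories ordered vector of all rating categories; defaults to
#'   the sorted unique observed scores.
#' @param conf_level confidence level (default 0.95).
#' @return An object of class `gwet_ac2` with elements `coefficient`,
#'   `se`, `ci_low`, `ci_high`, `benchmark`, `pa`, `pe`, `n_items`,
#'   `n_raters`, `categories` and `degenerate`.
#' @examples
#' scores <- cbind(r1 = c(1, 2, 3, 4, 5), r2 = c(1, 2, 3, 4, 4),
#'                 r3 = c(1, 2, 3, 5, 5))
#' gwet_ac2(scores, categories = 1:5)
#' @export
gwet_ac2 <- function(scores, weights = "linear", categories = NULL,
                     conf_level = 0.95) {
  scores <- as_ratings_matrix(scores)
  if (nrow(scores) < 2L) stop("need at least 2 items", call. = FALSE)
  if (ncol(scores) < 2L) stop("need at least 2 raters", call. = FALSE)
  obs <- scores[!is.na(scores)]
  if (!length(obs)) stop("no ratings", call. = FALSE)
  if (is.null(categories)) categories <- sort(unique(obs))
  if (any(!obs %in% categories))
    stop("scores outside the declared categories", call. = FALSE)
  K <- length(categories)
  n_raters <- ncol(scores)

  # r_ik: number of raters placing item i in category k
  r <- vapply(categories,
              function(k) rowSums(scores == k, na.rm = TRUE),
              numeric(nrow(scores)))
  r <- matrix(r, nrow = nrow(scores))
  ri <- rowSums(r)
  r <- r[ri >= 1, , drop = FALSE]
  ri <- ri[ri >= 1]
  n <- nrow(r)
  if (!any(ri >= 2L))
    stop("every item needs at least 2 raters for agreement", call. = FALSE)

  used <- colSums(r) > 0
  if (sum(used) == 1L) {
    out <- list(coefficient = 1, se = 0, ci_low = 1, ci_high = 1,
                benchmark = "excellent", pa = 1, pe = 0,
                n_items = n, n_raters = n_raters,
                categories = categories, weights = "degenerate",
                degenerate = TRUE, conf_level = conf_level)
    class(out) <- "gwet_ac2"
    return(out)
  }

  if (is.character(weights)) {
    wname <- weights
    w <- agreement_weights(K, weights)
  } else {
    w <- as.matrix(weights)
    wname <- "custom"
    stopifnot(identical(dim(w), c(K, K)))
  }

  est <- gwet_ac2_core(r, ri, w)
  se <- sqrt(est$variance)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- list(coefficient = est$ac2, se = se,
              ci_low = max(-1, est$ac2 - z * se),
              ci_high = min(1, est$ac2 + z * se),
              benchmark = benchmark_agreement(max(-1, min(1, est$ac2))),
              pa = est$pa, pe = est$pe,
              n_items = n, n_raters = n_raters,
              categories = categories, weights = wname,
              degenerate = FALSE, conf_level = conf_level)
  class(out) <- "gwet_ac2"
  out
}

# Core estimator on the item x category count matrix.
#' @noRd
gwet_ac2_core <- function(r, ri, w) {
  n <- nrow(r); K <- ncol(r)
  two <- ri >= 2
  n2 <- sum(two)
  rstar <- r %*% w
  sum_q <- rowSums(r * (rstar - 1))
  den <- ri * (ri - 1)
  den[!two] <- 1
  pa_i <- sum_q / den
  pa_i[!two] <- 0
  pa <- sum(pa_i[two]) / n2
  pik <- colMeans(r / ri)
  Tw <- sum(w)
  pe <- Tw / (K * (K - 1)) * sum(pik * (1 - pik))
  if (1 - pe < .Machine$double.eps)
    return(list(ac2 = if (pa >= 1) 1 else NaN, pa = pa, pe = pe,
                variance = 0))
  ac2 <- (pa - pe) / (1 - pe)
  # Gwet's item-level linearization (infinite-population version)
  pe_r2 <- pe * as.numeric(two)
  ac2_i <- (n / n2) * (pa_i - pe_r2) / (1 - pe)
  pe_i <- Tw / (K * (K - 1)) * as.numeric(r %*% (1 - pik)) / ri
  ac2_ix <- ac2_i - 2 * (1 - ac2) * (pe_i - pe) / (1 - pe)
  variance <- if (n > 1) sum((ac2_ix - ac2)^2) / (n * (n - 1)) else 0
  list(ac2 = ac2, pa = pa, pe = pe, variance = variance)
}

#' Fleiss-style benchmark label for an agreement coefficient
#'
#' Labels an agreement coefficient: below 0.40 is poor, 0.40 to 0.75
#' (inclusive) is good, above 0.75 is excellent.
#'
#' @param ac2 agreement coefficient in [-1, 1].
#' @return `"poor"`, `"good"` or `"excellent"`.
#' @export
benchmark_agreement <- function(ac2) {
  if (!is.numeric(ac2) || any(!is.finite(ac2)) ||
      any(ac2 < -1) || any(ac2 > 1))
    stop("agreement coefficient must lie in [-1, 1]", call. = FALSE)
  ifelse(ac2 < 0.40, "poor", ifelse(ac2 <= 0.75, "good", "excellent"))
}

#' @export
print.gwet_ac2 <- function(x, digits = 3, ...) {
  cat("Gwet's AC2 interrater agreement\n")
  cat(sprintf("  AC2 = %.*f  %.0f%% CI [%.*f, %.*f]  (%s)\n",
              digits, x$coefficient, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high, x$benchmark))
  cat(sprintf("  Pa = %.*f, Pe = %.*f; %d items, %d raters, %d categories, %s weights\n",
              digits, x$pa, digits, x$pe, x$n_items, x$n_raters,
              length(x$categories), x$weights))
  if (isTRUE(x$degenerate))
    cat("  note: single category used throughout; variance degenerate\n")
  invisible(x)
}

#' @export
confint.gwet_ac2 <- function(object, parm, level = NULL, ...) {
  if (!is.null(level) && level != object$conf_level)
    stop("interval was built at conf_level = ", object$conf_level,
         call. = FALSE)
  m <- matrix(c(object$ci_low, object$ci_high), 1,
              dimnames = list("ac2", c("lower", "upper")))
  m
}

#' Read a multi-rater ratings table from CSV
#'
#' Accepts either a long table with columns `item_id`, `rater_id`,
#' `score`, or a wide items x raters table (first column taken as item id
#' if non-numeric).
#'
#' @param path CSV path.
#' @return Numeric items x raters matrix (NAs for missing cells).
#' @examples
#' ratings <- system.file("extdata", "example_ratings.csv", package = "ctiq")
#' gwet_ac2(read_ratings(ratings), categories = 1:5)
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop("ratings CSV not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ln <- tolower(names(df))
  if (all(c("item_id", "rater_id", "score") %in% ln)) {
    names(df) <- ln
    return(as_ratings_matrix(df[c("item_id", "rater_id", "score")]))
  }
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[-1L]
    m <- as.matrix(df)
    rownames(m) <- rn
  } else m <- as.matrix(df)
  storage.mode(m) <- "double"
  m
}
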