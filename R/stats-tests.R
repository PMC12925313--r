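#' Permutation test on the difference of group medians
#'
#' Two-sided independent-samples permutation test using the difference in
#' medians (group A minus group B) as test statistic. Group labels are
#' permuted preserving group sizes. When the number of distinct regroupings
#' \eqn{C(n_a + n_b, n_a)} does not exceed \code{n_permutations} (and
#' \code{method = "auto"}), all regroupings are enumerated and the p-value
#' is the exact fraction reaching the observed absolute statistic.
#' Otherwise random relabelings are sampled and the add-one estimator
#' \eqn{(b + 1)/(n + 1)} is used, which never returns zero.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param n_permutations Number of random relabelings in sampled mode, and
#'   the enumeration budget for exact mode. Default 100000.
#' @param seed Integer seed making sampled mode reproducible; \code{NULL}
#'   leaves the RNG state alone.
#' @param method \code{"auto"} (default), \code{"exact"} or
#'   \code{"sampled"}.
#' @return List of class \code{permutation_result}:
#'   \code{statistic_observed}, \code{p_value}, \code{n_permutations}
#'   (relabelings actually evaluated), \code{seed}, \code{exact}, plus the
#'   group medians and sizes.
#' @export
permutation_test_median_diff <- function(group_a, group_b,
                                         n_permutations = 100000,
                                         seed = NULL,
                                         method = c("auto", "exact",
                                                    "sampled")) {
  method <- match.arg(method)
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups must have at least 2 values")
  }
  stopifnot(n_permutations >= 1)
  n_a <- length(group_a); n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  observed <- stats::median(group_a) - stats::median(group_b)
  obs_abs <- abs(observed)
  n_comb <- choose(n_a + n_b, n_a)
  exact <- switch(method,
                  auto = n_comb <= n_permutations,
                  exact = TRUE,
                  sampled = FALSE)
  eps <- 1e-12 * (1 + obs_abs)
  if (exact) {
    idx_all <- utils::combn(n_a + n_b, n_a)
    stats_all <- apply(idx_all, 2, function(idx) {
      stats::median(pooled[idx]) - stats::median(pooled[-idx])
    })
    hits <- sum(abs(stats_all) >= obs_abs - eps)
    p <- hits / ncol(idx_all)
    n_used <- ncol(idx_all)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- .perm_count_median_diff(pooled, n_a, obs_abs,
                                    as.integer(n_permutations))
    p <- (hits + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(
    statistic_observed = observed,
    p_value = p,
    n_permutations = n_used,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    exact = exact,
    median_a = stats::median(group_a), median_b = stats::median(group_b),
    n_a = n_a, n_b = n_b
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (difference of medians, two-sided)\n  observed: %.6g (medians %.6g vs %.6g; n = %d vs %d)\n  p = %.6g  [%s, %d relabelings]\n",
    x$statistic_observed, x$median_a, x$median_b, x$n_a, x$n_b, x$p_value,
    if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

#' Compare core vs accessory groups of per-unit values
#'
#' Splits values by their core/accessory label and runs
#' [permutation_test_median_diff()] with group A = core and group B =
#' accessory, attaching the group medians and interquartile ranges.
#'
#' @param values Named numeric vector (names are unit ids), or a two-column
#'   data frame (id, value).
#' @param labels Data frame whose first column holds unit ids and whose
#'   \code{label} column is \code{core}/\code{accessory} (other labels are
#'   dropped).
#' @inheritParams permutation_test_median_diff
#' @return A \code{permutation_result} with an added \code{groups} summary
#'   data frame.
#' @export
compare_groups <- function(values, labels, n_permutations = 100000,
                           seed = NULL,
                           method = c("auto", "exact", "sampled")) {
  if (is.data.frame(values)) {
    values <- stats::setNames(values[[2]], values[[1]])
  }
  lab <- labels$label[match(names(values), labels[[1]])]
  if (any(is.na(lab))) {
    stop("id(s) without a label: ",
         paste(names(values)[is.na(lab)], collapse = ", "))
  }
  core <- values[lab == "core"]
  acc <- values[lab == "accessory"]
  if (length(core) < 2 || length(acc) < 2) {
    stop("each of the core and accessory groups needs at least 2 members")
  }
  res <- permutation_test_median_diff(core, acc, n_permutations, seed,
                                      method)
  qc <- median_iqr(core); qa <- median_iqr(acc)
  res$groups <- data.frame(
    label = c("core", "accessory"), n = c(length(core), length(acc)),
    q1 = c(qc[["q1"]], qa[["q1"]]),
    median = c(qc[["median"]], qa[["median"]]),
    q3 = c(qc[["q3"]], qa[["q3"]]), stringsAsFactors = FALSE)
  res
}

#' Test kingdom-wide prevalence of core vs accessory sugars
#'
#' Compares the prevalence of each nucleotide-sugar across the bacterial
#' kingdom (an external survey table) between the sugars called core and
#' accessory in the genome set under study.
#'
#' @param records Data frame with columns \code{sugar_id} and
#'   \code{kingdom_prevalence} (fractions in [0, 1]).
#' @param labels Sugar labels from [classify_sugar_prevalence()].
#' @inheritParams permutation_test_median_diff
#' @return A \code{permutation_result} (see [compare_groups()]).
#' @export
kingdom_prevalence_test <- function(records, labels, n_permutations = 100000,
                                    seed = NULL,
                                    method = c("auto", "exact", "sampled")) {
  lab <- labels[labels$label %in% c("core", "accessory"), , drop = FALSE]
  miss <- setdiff(lab[[1]], records$sugar_id)
  if (length(miss)) {
    stop("no kingdom-prevalence record for sugar(s): ",
         paste(miss, collapse = ", "))
  }
  vals <- stats::setNames(
    records$kingdom_prevalence[match(lab[[1]], records$sugar_id)], lab[[1]])
  compare_groups(vals, lab, n_permutations, seed, method)
}
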