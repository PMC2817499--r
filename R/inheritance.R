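#' Mendelian class expectations for a spot locus
#'
#' Each parental allele either produces the landmark spot or not. Gametes
#' carry either allele with probability 1/2; progeny classes are mapped
#' from the count of spot-producing alleles: 0 -> `absent`, 1 -> `half`,
#' 2 -> `full` (the half-intensity class is the RLGS heterozygote
#' signature).
#'
#' @param parent1 Logical length-2 vector: does each allele of the (first)
#'   parent produce the spot?
#' @param parent2 Second parent for an outcross; for `cross_type = "self"`
#'   it must be NULL or identical to `parent1`.
#' @param cross_type `"outcross_F1"` or `"self"`.
#' @return Named numeric vector of class probabilities (zero-probability
#'   classes dropped), summing to 1.
#' @examples
#' mendelian_expectation(c(TRUE, FALSE), c(FALSE, FALSE), "outcross_F1")
#' mendelian_expectation(c(TRUE, FALSE), cross_type = "self")
#' @export
mendelian_expectation <- function(parent1, parent2 = NULL,
                                  cross_type = c("outcross_F1", "self")) {
  cross_type <- match.arg(cross_type)
  parent1 <- as.logical(parent1)
  stopifnot(length(parent1) == 2L, !anyNA(parent1))
  if (cross_type == "self") {
    if (!is.null(parent2) && !identical(as.logical(parent2), parent1))
      stop("selfing takes a single parent; two distinct parents were given")
    parent2 <- parent1
  } else {
    if (is.null(parent2)) stop("an outcross needs two parents")
    parent2 <- as.logical(parent2)
    stopifnot(length(parent2) == 2L, !anyNA(parent2))
  }
  counts <- as.vector(outer(as.integer(parent1), as.integer(parent2), "+"))
  cls <- factor(c("absent", "half", "full")[counts + 1L],
                levels = c("absent", "half", "full"))
  p <- table(cls) / 4
  p <- stats::setNames(as.numeric(p), names(p))
  p[p > 0]
}

multinom_logprob <- function(x, prob) {
  lgamma(sum(x) + 1) - sum(lgamma(x + 1)) +
    sum(ifelse(x > 0, x * log(prob), 0))
}

# All k-part compositions of n, as a matrix with one row per outcome.
enumerate_counts <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- list()
  for (first in 0:n) {
    rest <- enumerate_counts(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' Exact multinomial goodness-of-fit test
#'
#' Two-sided exact test by the minimum-likelihood rule: the p-value sums
#' the probabilities of all outcomes no more probable than the observed
#' one (up to a 1e-7 relative tolerance for floating-point ties). Full
#' enumeration for `sum(x) <= enum_max`; larger panels fall back to Monte
#' Carlo sampling with a fixed seed, reported in the result.
#'
#' @param x Integer vector of observed class counts.
#' @param prob Numeric vector of expected class probabilities (normalised
#'   internally).
#' @param enum_max Largest total count for full enumeration.
#' @param n_mc Number of Monte Carlo draws beyond `enum_max`.
#' @param mc_seed Seed for the Monte Carlo branch.
#' @return List with `p_value`, `method`
#'   (`"exact_multinomial"`/`"monte_carlo_multinomial"`) and, for Monte
#'   Carlo, `seed`.
#' @export
exact_multinomial_test <- function(x, prob, enum_max = 20L, n_mc = 1e5,
                                   mc_seed = 1L) {
  x <- as.integer(x)
  stopifnot(length(x) == length(prob), all(x >= 0), all(prob >= 0))
  n <- sum(x)
  if (n < 1L) stop("the test needs at least one observation")
  prob <- prob / sum(prob)
  lp_obs <- multinom_logprob(x, prob)
  thr <- lp_obs + log1p(1e-7)
  if (n <= enum_max) {
    cm <- enumerate_counts(n, length(x))
    lp <- apply(cm, 1L, multinom_logprob, prob = prob)
    p <- sum(exp(lp[lp <= thr]))
    list(p_value = min(p, 1), method = "exact_multinomial")
  } else {
    draws <- with_seed(mc_seed, stats::rmultinom(n_mc, n, prob))
    lterm <- ifelse(prob > 0, log(prob), 0)   # zero-prob classes never drawn
    lp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) +
      colSums(draws * lterm)
    p <- (1 + sum(lp <= thr)) / (n_mc + 1)
    list(p_value = min(p, 1), method = "monte_carlo_multinomial",
         seed = mc_seed)
  }
}

#' Exact segregation test of observed class counts
#'
#' Two classes: two-sided exact binomial (minimum-likelihood rule, as in
#' `stats::binom.test`). Three or more classes: exact multinomial via
#' [exact_multinomial_test()].
#'
#' @param observed Named integer vector of class counts.
#' @param expected Class probabilities, aligned with `observed` (by name if
#'   both are named).
#' @param ... Passed to [exact_multinomial_test()].
#' @return List with `p_value`, `method` and the aligned inputs.
#' @examples
#' segregation_test(c(present = 5, absent = 4), c(present = .5, absent = .5))
#' @export
segregation_test <- function(observed, expected, ...) {
  observed <- round(observed)
  if (!is.null(names(observed)) && !is.null(names(expected))) {
    if (!setequal(names(observed), names(expected)))
      stop("observed and expected classes disagree: ",
           paste(names(observed), collapse = "/"), " vs ",
           paste(names(expected), collapse = "/"))
    expected <- expected[names(observed)]
  }
  stopifnot(length(observed) == length(expected), length(observed) >= 1L)
  n <- sum(observed)
  if (n < 1L) stop("segregation test needs at least one classified individual")
  expected <- expected / sum(expected)
  if (length(observed) == 1L) {
    # a single possible class: every panel matches the expectation
    res <- list(p_value = 1, method = "degenerate_single_class")
  } else if (length(observed) == 2L) {
    res <- list(p_value = stats::binom.test(observed[[1L]], n,
                                            expected[[1L]])$p.value,
                method = "exact_binomial")
  } else {
    res <- exact_multinomial_test(observed, expected, ...)
  }
  res$observed <- observed
  res$expected <- expected
  res
}

#' Segregation testing and non-Mendelian flagging across loci
#'
#' For every locus, builds observed class counts from per-individual
#' intensity classes, derives the Mendelian expectation from the parental
#' spot genotypes, runs the exact test, applies multiplicity correction
#' across loci, and flags loci whose adjusted p-value falls below `alpha`.
#' Individuals classified `other` are excluded from the test and counted
#' in the `n_other` QC column. The canonical flagged case is a selfed
#' panel from a heterozygous parent in which every individual is
#' half-intensity.
#'
#' @param classes Data frame with columns `locus` and `class` (one row per
#'   individual per locus; classes over `absent`/`half`/`full`/`other`), or
#'   a bare character vector of classes for a single locus `"focal"`.
#' @param parent1,parent2,cross_type Parental spot genotypes per
#'   [mendelian_expectation()]; `parent1`/`parent2` may also be named lists
#'   keyed by locus.
#' @param alpha Significance level applied to adjusted p-values.
#' @param correction Multiplicity correction method (see
#'   [stats::p.adjust()]); default Benjamini-Hochberg.
#' @param ... Passed to [segregation_test()].
#' @return Data frame with one row per locus: counts per class, expected
#'   probabilities, test name, `p_value`, `p_adj` and `verdict`
#'   (`mendelian_consistent` / `non_mendelian_flag`).
#' @export
flag_non_mendelian <- function(classes, parent1, parent2 = NULL,
                               cross_type = c("self", "outcross_F1"),
                               alpha = 0.05, correction = "BH", ...) {
  cross_type <- match.arg(cross_type)
  if (is.character(classes) && is.null(dim(classes)))
    classes <- data.frame(locus = "focal", class = classes,
                          stringsAsFactors = FALSE)
  stopifnot(is.data.frame(classes), all(c("locus", "class") %in% names(classes)))
  loci <- unique(classes$locus)
  geno_for <- function(geno, locus) {
    if (is.list(geno)) geno[[locus]] else geno
  }
  rows <- lapply(loci, function(locus) {
    cls <- classes$class[classes$locus == locus]
    n_other <- sum(cls == "other")
    cls <- cls[cls != "other"]
    expected <- mendelian_expectation(geno_for(parent1, locus),
                                      if (is.null(parent2)) NULL
                                      else geno_for(parent2, locus),
                                      cross_type)
    universe <- union(names(expected),
                      intersect(c("absent", "half", "full"), unique(cls)))
    universe <- intersect(c("absent", "half", "full"), universe)
    obs <- stats::setNames(
      vapply(universe, function(k) sum(cls == k), 0L), universe)
    exp_full <- stats::setNames(rep(0, length(universe)), universe)
    exp_full[names(expected)] <- expected
    tst <- segregation_test(obs, exp_full, ...)
    count_of <- function(k) if (k %in% universe) obs[[k]] else 0L
    expct_of <- function(k) if (k %in% universe) exp_full[[k]] else 0
    data.frame(locus = locus, n = sum(obs), n_other = n_other,
               count_absent = count_of("absent"),
               count_half = count_of("half"),
               count_full = count_of("full"),
               expected_absent = expct_of("absent"),
               expected_half = expct_of("half"),
               expected_full = expct_of("full"),
               test = tst$method, p_value = tst$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_value, method = correction)
  res$verdict <- ifelse(res$p_adj < alpha,
                        "non_mendelian_flag", "mendelian_consistent")
  rownames(res) <- NULL
  res
}
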