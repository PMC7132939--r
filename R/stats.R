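#' Maximum-likelihood log-normal fit of object volumes
#'
#' Fits a log-normal size distribution by maximum likelihood on the
#' natural logs: \eqn{\hat\mu} is the mean of \eqn{\ln v} and
#' \eqn{\hat\sigma} the root mean squared deviation (divisor n). Reports
#' the maximised log-likelihood and a Kolmogorov-Smirnov goodness-of-fit
#' summary against the fitted CDF (the p-value is the usual approximation
#' and is conservative-to-liberal when parameters are estimated from the
#' same data — treat it as a descriptive summary). A moment-matching
#' alternative (solving the log-normal mean/variance equations) is
#' available via \code{method}.
#'
#' @param volumes positive numeric vector (\eqn{\mu m^3}), length >= 3.
#' @param method \code{"mle"} (default) or \code{"moments"}.
#' @return a [LognormalFit].
#' @examples
#' set.seed(1)
#' fitLognormal(rlnorm(500, -5.1375, 0.9173))
#' @export
fitLognormal <- function(volumes, method = c("mle", "moments")) {
  method <- match.arg(method)
  v <- as.numeric(volumes)
  if (length(v) < 3L) stop("at least 3 volumes are required")
  if (anyNA(v) || any(v <= 0)) stop("all volumes must be positive")
  lg <- log(v)
  n <- length(v)
  if (method == "mle") {
    mu <- mean(lg)
    sigma <- sqrt(mean((lg - mu)^2))
  } else {
    m <- mean(v)
    s2 <- stats::var(v)
    sigma <- sqrt(log(1 + s2 / m^2))
    mu <- log(m) - sigma^2 / 2
  }
  ll <- sum(stats::dlnorm(v, meanlog = mu, sdlog = sigma, log = TRUE))
  if (sigma > 0) {
    ks <- suppressWarnings(stats::ks.test(v, stats::plnorm, meanlog = mu,
                                          sdlog = sigma))
    ksD <- unname(ks$statistic)
    ksP <- ks$p.value
  } else {
    ksD <- NA_real_
    ksP <- NA_real_
  }
  new("LognormalFit", mu = mu, sigma = sigma, n = as.integer(n),
      logLik = ll, ksStatistic = ksD, ksPValue = ksP)
}

#' Compartment concentration ratio
#'
#' Ratio between the percentage of objects found in a compartment and the
#' volume fraction (as a percentage of the reference space) occupied by
#' that compartment. A ratio above 1 means the objects are relatively
#' more concentrated in that compartment than its share of tissue volume
#' would predict.
#'
#' @param pctObjects percentage of objects in the compartment.
#' @param volumeFraction percentage of reference volume occupied by the
#'   compartment (must be positive).
#' @param compartment optional compartment name(s) carried through.
#' @return data.frame with columns \code{compartment}, \code{pct_mvbs},
#'   \code{volume_fraction}, \code{ratio}.
#' @examples
#' concentrationRatio(c(39.14, 42.70), c(38.50, 38.69),
#'                    c("dendrite", "nonsynaptic"))
#' @export
concentrationRatio <- function(pctObjects, volumeFraction,
                               compartment = NULL) {
  if (any(!is.finite(volumeFraction)) || any(volumeFraction <= 0))
    stop("volume fractions must be positive")
  if (length(pctObjects) != length(volumeFraction))
    stop("lengths of 'pctObjects' and 'volumeFraction' differ")
  if (is.null(compartment))
    compartment <- paste0("compartment_", seq_along(pctObjects))
  data.frame(compartment = compartment,
             pct_mvbs = pctObjects,
             volume_fraction = volumeFraction,
             ratio = pctObjects / volumeFraction,
             stringsAsFactors = FALSE)
}

#' Chi-squared test of compartment occupancy
#'
#' Goodness-of-fit form: observed per-compartment counts are compared to
#' the counts expected if objects were distributed in proportion to the
#' compartments' volume fractions (\code{expected_i = total * vf_i}, df =
#' c - 1). Independence form: pass a counts matrix (e.g. layer x
#' compartment) and omit \code{volumeFractions} to get the standard r x c
#' test (df = (r-1)(c-1), no continuity correction).
#'
#' @param observed integer counts: a vector (goodness of fit) or matrix
#'   (independence).
#' @param volumeFractions compartment volume fractions summing to 1
#'   (renormalized with a warning otherwise); ignored for the
#'   independence form.
#' @return a [ContingencyResult].
#' @examples
#' compartmentChiSquare(c(633, 257, 37, 691),
#'                      c(0.3850, 0.1711, 0.0570, 0.3869))
#' @export
compartmentChiSquare <- function(observed, volumeFractions = NULL) {
  if (is.matrix(observed) && is.null(volumeFractions)) {
    if (any(observed < 0)) stop("counts must be nonnegative")
    ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
    if (any(ht$expected == 0)) stop("expected cell count of zero")
    return(new("ContingencyResult", observed = observed,
               expected = ht$expected,
               statistic = unname(ht$statistic), df = unname(ht$parameter),
               pValue = ht$p.value, method = "independence"))
  }
  obs <- as.numeric(observed)
  total <- sum(obs)
  if (total <= 0) stop("total count must be positive")
  vf <- as.numeric(volumeFractions)
  if (length(vf) != length(obs))
    stop("one volume fraction per compartment is required")
  if (any(vf < 0)) stop("volume fractions must be nonnegative")
  if (abs(sum(vf) - 1) > 1e-9) {
    warning("volume fractions do not sum to 1; renormalizing")
    vf <- vf / sum(vf)
  }
  expected <- total * vf
  if (any(expected == 0)) stop("expected cell count of zero")
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  new("ContingencyResult", observed = obs, expected = expected,
      statistic = stat, df = df, pValue = p, method = "goodness_of_fit")
}

# Dunn's post-hoc z statistics on Kruskal-Wallis ranks, with tie
# correction; adjusted by Holm's method by default
.dunnTest <- function(values, groups, adjust = "holm") {
  N <- length(values)
  rk <- rank(values)
  meanRank <- tapply(rk, groups, mean)
  nG <- tapply(rk, groups, length)
  ties <- table(rk)
  tieSum <- sum(ties^3 - ties)
  sigma2 <- N * (N + 1) / 12 - tieSum / (12 * (N - 1))
  levs <- names(meanRank)
  pairs <- utils::combn(levs, 2)
  res <- apply(pairs, 2L, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt(sigma2 * (1 / nG[[i]] + 1 / nG[[j]]))
    z <- (meanRank[[i]] - meanRank[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = res["z", ], p = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Nonparametric group comparison
#'
#' Two-group design: Mann-Whitney (Wilcoxon rank-sum) test. k-group
#' design: Kruskal-Wallis test followed by Dunn's post-hoc pairwise
#' comparisons on the shared ranks, with Holm multiplicity adjustment by
#' default. Both use the large-sample approximations with tie
#' correction.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length as \code{values}.
#' @param design \code{"auto"} (from the number of groups),
#'   \code{"two_group"} or \code{"k_group"}.
#' @param adjust p-adjustment method for the Dunn comparisons (any method
#'   of [stats::p.adjust()]).
#' @return list with \code{method}, \code{statistic}, \code{p.value} and,
#'   for k groups, \code{posthoc} (data.frame of pairwise Dunn results).
#' @examples
#' groupCompare(c(rnorm(10), rnorm(10, 2)), rep(c("a", "b"), each = 10))
#' @export
groupCompare <- function(values, groups,
                         design = c("auto", "two_group", "k_group"),
                         adjust = "holm") {
  design <- match.arg(design)
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  counts <- table(groups)
  if (any(counts == 0L)) stop("every group must be nonempty")
  k <- length(counts)
  if (design == "auto") design <- if (k == 2L) "two_group" else "k_group"
  if (design == "two_group") {
    if (k != 2L) stop("two_group design requires exactly 2 groups")
    levs <- names(counts)
    ht <- suppressWarnings(
      stats::wilcox.test(values[groups == levs[1]],
                         values[groups == levs[2]], exact = FALSE,
                         correct = FALSE))
    list(method = "mann_whitney", statistic = unname(ht$statistic),
         p.value = ht$p.value)
  } else {
    if (k < 2L) stop("k_group design requires at least 2 groups")
    ht <- stats::kruskal.test(values, factor(groups))
    list(method = "kruskal_wallis", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p.value = ht$p.value,
         posthoc = .dunnTest(values, groups, adjust = adjust))
  }
}

#' Per-layer compartment summary table
#'
#' Summarises a catalog the way study tables report it: per cortical
#' layer (plus the pooled "I-VI" row), the percentage of objects in each
#' compartment with the standard error over that layer's stacks, or the
#' mean object volume per compartment with its standard error over
#' objects.
#'
#' @param catalog an [MVBCatalog].
#' @param what \code{"percent"} (compartment percentages, sem over
#'   stacks) or \code{"volume"} (mean volume in \eqn{10^{-3} \mu m^3},
#'   sem over objects).
#' @return data.frame with a \code{layer} column and
#'   \code{mean}/\code{sem} column pairs per compartment.
#' @export
layerCompartmentSummary <- function(catalog, what = c("percent", "volume")) {
  what <- match.arg(what)
  tab <- mvbTable(catalog)
  layers <- unique(tab$layer)
  rows <- lapply(c(as.list(layers), list(layers)), function(ls) {
    sub <- tab[tab$layer %in% ls, , drop = FALSE]
    lab <- if (length(ls) > 1L) "I-VI" else ls
    out <- list(layer = lab)
    for (cmp in .COMPARTMENTS) {
      if (what == "percent") {
        perStack <- vapply(split(sub, sub$stack_id), function(st)
          100 * mean(st$compartment == cmp), numeric(1))
        m <- mean(perStack)
        s <- if (length(perStack) > 1L)
          stats::sd(perStack) / sqrt(length(perStack)) else NA_real_
      } else {
        v <- 1000 * sub$volume_um3[sub$compartment == cmp]
        m <- if (length(v)) mean(v) else NA_real_
        s <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
      }
      out[[paste0(cmp, "_mean")]] <- round(m, 2)
      out[[paste0(cmp, "_sem")]] <- round(s, 2)
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
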