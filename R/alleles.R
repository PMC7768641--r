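# Allele peak calling: per-read copy-count estimates are clustered into one
# or two Gaussian modes; the mode means, rounded to integers, are the
# sample's alleles at the locus.

round_half_up <- function(x) floor(x + 0.5)

# 1D Gaussian mixture fit with deterministic initialisation.
# k = 1: closed-form MLE. k = 2: EM initialised at the 25th/75th percentiles
# of x, equal weights, common initial sd; iteration cap and tolerance fixed
# for reproducibility. Component sds are floored at 0.25 (half the integer
# grid spacing) so point masses keep a finite likelihood.
fit_normal_mixture <- function(x, k, max_iter = 200L, tol = 1e-4) {
  n <- length(x)
  sd_floor <- 0.25
  if (k == 1L) {
    mu <- mean(x)
    sigma <- max(sqrt(mean((x - mu)^2)), sd_floor)
    ll <- sum(stats::dnorm(x, mu, sigma, log = TRUE))
    return(list(k = 1L, mu = mu, sigma = sigma, lambda = 1,
                loglik = ll, bic = -2 * ll + 2 * log(n),
                assign = rep(1L, n)))
  }
  mu <- unname(stats::quantile(x, c(0.25, 0.75), type = 7))
  sigma <- rep(max(sqrt(mean((x - mean(x))^2)), sd_floor), 2L)
  lambda <- c(0.5, 0.5)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
    d2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    sigma <- pmax(c(sqrt(sum(r1 * (x - mu[1])^2) / n1),
                    sqrt(sum((1 - r1) * (x - mu[2])^2) / n2)), sd_floor)
    lambda <- c(n1, n2) / n
    ll <- sum(log(lambda[1] * stats::dnorm(x, mu[1], sigma[1]) +
                  lambda[2] * stats::dnorm(x, mu[2], sigma[2])))
    if (is.finite(ll) && abs(ll - ll_old) < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  r1 <- lambda[1] * stats::dnorm(x, mu[1], sigma[1])
  r2 <- lambda[2] * stats::dnorm(x, mu[2], sigma[2])
  list(k = 2L, mu = mu, sigma = sigma, lambda = lambda,
       loglik = ll_old, bic = -2 * ll_old + 5 * log(n),
       assign = ifelse(r1 >= r2, 1L, 2L))
}

#' Call one or two alleles from per-read copy counts
#'
#' Fits a 1-component and (for diploid samples) a 2-component Gaussian
#' mixture to the spanning-read copy-count estimates, selects between them
#' by BIC, and reports the component means rounded to the nearest integer
#' (ties round half up) as the sample's alleles. A 2-component fit whose
#' rounded means coincide collapses to a homozygous call reported twice.
#' With fewer than `min_reads` observations a distinct no-call is returned.
#'
#' @param copy_counts Numeric vector of per-read copy-count estimates from
#'   spanning reads at one locus of one sample.
#' @param ploidy 1 (haploid: one allele) or 2 (diploid).
#' @param min_reads Minimum number of spanning reads required to call.
#' @param sample_id,locus Optional identifiers carried into the result.
#' @return An object of class `allele_call`: a list with `status`
#'   (`"called"` or `"no_call"`), `alleles` (sorted integer vector, length
#'   `ploidy` when called), `support` (reads backing each allele; for a
#'   collapsed homozygote all support is recorded on the first copy) and
#'   `n_reads`.
#' @examples
#' call_alleles(c(rep(14, 10), rep(77, 10)), ploidy = 2)$alleles  # 14 77
#' @export
call_alleles <- function(copy_counts, ploidy = 2L, min_reads = 5L,
                         sample_id = NA_character_, locus = NULL) {
  if (!ploidy %in% c(1L, 2L)) stop("ploidy must be 1 or 2")
  if (min_reads < 1L) stop("min_reads must be >= 1")
  x <- sort(as.numeric(copy_counts))  # sorting makes the fit permutation-invariant
  n <- length(x)
  res <- list(sample_id = sample_id, locus = locus, ploidy = as.integer(ploidy),
              n_reads = n)
  if (n < min_reads) {
    res$status <- "no_call"
    res$alleles <- integer(0)
    res$support <- integer(0)
    return(structure(res, class = "allele_call"))
  }
  fit1 <- fit_normal_mixture(x, 1L)
  fit <- fit1
  if (ploidy == 2L && length(unique(x)) > 1L) {
    fit2 <- fit_normal_mixture(x, 2L)
    if (is.finite(fit2$bic) && fit2$bic < fit1$bic) fit <- fit2
  }
  if (fit$k == 2L) {
    a <- as.integer(round_half_up(fit$mu))
    sup <- tabulate(fit$assign, nbins = 2L)
    ord <- order(a)
    a <- a[ord]; sup <- sup[ord]
    if (a[1] == a[2]) {  # collapse to homozygote
      alleles <- c(a[1], a[1])
      support <- c(n, 0L)
    } else {
      alleles <- a
      support <- sup
    }
  } else {
    a <- as.integer(round_half_up(fit$mu))
    alleles <- if (ploidy == 2L) c(a, a) else a
    support <- if (ploidy == 2L) c(n, 0L) else n
  }
  res$status <- "called"
  res$alleles <- alleles
  res$support <- as.integer(support)
  res$fit <- fit[c("k", "mu", "sigma", "lambda", "bic")]
  structure(res, class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  if (x$status == "no_call") {
    cat(sprintf("allele call: NO CALL (%d spanning reads)\n", x$n_reads))
  } else {
    cat(sprintf("allele call: [%s] from %d spanning reads (support %s)\n",
                paste(x$alleles, collapse = ", "), x$n_reads,
                paste(x$support, collapse = "/")))
  }
  invisible(x)
}
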