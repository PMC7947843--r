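#' Nucleotide substitution model
#'
#' Time-reversible DNA substitution models used throughout the gene-tree
#' engine.  The rate matrix is scaled so that the mean substitution rate at
#' stationarity equals 1, i.e. branch lengths are expected substitutions per
#' site.  Optional among-site rate variation uses a discrete gamma with
#' `ncat` equal-probability categories (category means, normalized to mean 1).
#'
#' @param name one of `"JC69"`, `"HKY85"`, `"GTR"`.
#' @param freqs base frequencies (A, C, G, T); must be positive, summing to 1.
#'   Forced to 1/4 each under JC69.
#' @param kappa transition/transversion rate ratio (HKY85).
#' @param rates six GTR exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (GT is conventionally fixed to 1 when estimated).
#' @param alpha gamma shape; `NULL` means rate homogeneity.
#' @param ncat number of discrete gamma categories.
#' @return an object of class `subst_model`.
#' @export
subst_model <- function(name = c("GTR", "HKY85", "JC69"), freqs = rep(0.25, 4),
                        kappa = 2, rates = rep(1, 6), alpha = NULL, ncat = 4L) {
  name <- match.arg(name)
  if (name == "JC69") freqs <- rep(0.25, 4)
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4 || any(freqs <= 0))
    stop("subst_model: freqs must be 4 positive numbers")
  freqs <- freqs / sum(freqs)
  if (!is.null(alpha) && (!is.finite(alpha) || alpha <= 0))
    stop("subst_model: alpha must be positive")
  structure(list(name = name, freqs = freqs, kappa = kappa,
                 rates = as.numeric(rates), alpha = alpha, ncat = as.integer(ncat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  g <- if (is.null(x$alpha)) "" else sprintf("+G%d (alpha=%.3g)", x$ncat, x$alpha)
  cat(sprintf("<subst_model> %s%s freqs=%s\n", x$name, g,
              paste(sprintf("%.3f", x$freqs), collapse = "/")))
  invisible(x)
}

# rate matrix Q (mean rate 1) for a subst_model
.model_Q <- function(model) {
  pi <- model$freqs
  s <- switch(model$name,
    JC69  = rep(1, 6),
    HKY85 = c(1, model$kappa, 1, 1, model$kappa, 1),
    GTR   = model$rates)
  Q <- matrix(0, 4, 4)
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (k in 1:6) {
    i <- idx[k, 1]; j <- idx[k, 2]
    Q[i, j] <- s[k] * pi[j]
    Q[j, i] <- s[k] * pi[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# eigen-decomposition of a reversible Q via symmetrization:
# Q = U diag(lambda) Uinv with real lambda
.model_eigen <- function(model) {
  Q <- .model_Q(model)
  pi <- model$freqs
  D <- sqrt(pi)
  B <- diag(D) %*% Q %*% diag(1 / D)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / D) %*% e$vectors
  Uinv <- t(e$vectors) %*% diag(D)
  list(U = U, Uinv = Uinv, lambda = e$values, pi = pi)
}

# discrete gamma category rates (category means, mean 1) -- Yang (1994) style
.gamma_rates <- function(alpha, ncat) {
  if (is.null(alpha)) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
  r <- ncat * diff(stats::pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r) * 1  # guard against numeric drift; already mean ~1
}

#' Compress an alignment into unique site patterns
#'
#' @param locus a [locus_aln()].
#' @return a list with `patterns` (taxa x n_patterns character matrix),
#'   `weights` (pattern multiplicities, summing to the site count) and
#'   `index` (per-site pattern index, so `patterns[, index]` reconstructs the
#'   alignment).
#' @export
compress_patterns <- function(locus) {
  seq <- locus$seq
  key <- apply(seq, 2, paste, collapse = "")
  u <- !duplicated(key)
  index <- match(key, key[u])
  list(patterns = seq[, u, drop = FALSE],
       weights = as.numeric(tabulate(index, nbins = sum(u))),
       index = index)
}

# empirical base frequencies (floored away from zero)
.empirical_freqs <- function(seq) {
  counts <- c(sum(seq == "A"), sum(seq == "C"), sum(seq == "G"), sum(seq == "T"))
  if (sum(counts) == 0) return(rep(0.25, 4))
  f <- counts / sum(counts)
  f <- pmax(f, 1e-4)
  f / sum(f)
}

# build one engine block from (patterns, weights) in the tip order of `tips`
.make_block <- function(patterns, weights, model, tips, rmult = 1) {
  if (!all(tips %in% rownames(patterns)))
    stop("engine block: tree tips missing from alignment: ",
         paste(setdiff(tips, rownames(patterns)), collapse = ", "))
  eg <- .model_eigen(model)
  list(tipstate = .encode_masks(patterns[tips, , drop = FALSE]),
       weights = weights,
       U = eg$U, Uinv = eg$Uinv, lambda = eg$lambda, pi = eg$pi,
       rates = .gamma_rates(model$alpha, model$ncat),
       rmult = rmult)
}
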