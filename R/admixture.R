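# Haploid ancestry mixture model fitted by EM.  Each taxon t carries
# admixture proportions q_t (over K components) and each component k carries
# per-site allele frequencies f_ks; a 0/1 genotype at site s has
# P(g_ts = 1) = sum_k q_tk f_ks.  This is the maximum-likelihood clustering
# model of ADMIXTURE specialized to haploid binary data.

#' Fit a K-component ancestry mixture to a binary genotype matrix
#'
#' Maximizes sum over taxa and sites of
#' `log(sum_k q_tk * f_ks^g * (1-f_ks)^(1-g))` by EM, from `n_restarts`
#' random initializations, returning the best fit.  The log-likelihood is
#' non-decreasing across iterations by construction.  Component labels are
#' canonicalized so component 1 is the majority component of `ref_taxon`.
#'
#' @param g Binary matrix, taxa x sites, with taxon rownames.
#' @param K Number of ancestry components (1 <= K < n taxa).
#' @param n_restarts Random restarts (best kept).
#' @param seed Integer seed.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @param ref_taxon Taxon anchoring the component order (default first row).
#' @return Object of class `ancestry_fit`: list with `Q` (taxa x K mixture
#'   proportions, rows sum to 1), `F` (K x sites allele frequencies),
#'   `loglik`, `loglik_trace`, `K`.
#' @export
admixture_em <- function(g, K, n_restarts = 10L, seed = 1L, tol = 1e-6,
                         max_iter = 2000L, ref_taxon = rownames(g)[1L]) {
  g <- as.matrix(g)
  storage.mode(g) <- "double"
  Tn <- nrow(g); S <- ncol(g)
  if (K < 1L || K >= Tn) stop("K must satisfy 1 <= K < n_taxa")
  stopifnot(all(g %in% c(0, 1)))
  set.seed(seed)
  eps <- 1e-9

  run_once <- function() {
    Q <- matrix(runif(Tn * K), Tn, K)
    Q <- Q / rowSums(Q)
    Fm <- matrix(runif(K * S, 0.05, 0.95), K, S)
    trace <- numeric(0L)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      # likelihood of each site's genotype under each component: T x S per k
      # responsibilities r_tsk computed without materializing T x S x K
      num <- vector("list", K)
      denom <- matrix(0, Tn, S)
      for (k in seq_len(K)) {
        pk <- matrix(Fm[k, ], Tn, S, byrow = TRUE)
        lk <- g * pk + (1 - g) * (1 - pk)
        num[[k]] <- Q[, k] * lk
        denom <- denom + num[[k]]
      }
      ll <- sum(log(pmax(denom, eps)))
      trace <- c(trace, ll)
      Qn <- matrix(0, Tn, K)
      Fn <- matrix(0, K, S)
      for (k in seq_len(K)) {
        r <- num[[k]] / pmax(denom, eps)
        Qn[, k] <- rowSums(r) / S
        Fn[k, ] <- colSums(r * g) / pmax(colSums(r), eps)
      }
      Q <- Qn / rowSums(Qn)
      Fm <- pmin(pmax(Fn, eps), 1 - eps)
      if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
      ll_old <- ll
    }
    list(Q = Q, F = Fm, loglik = trace[length(trace)], loglik_trace = trace)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- run_once()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- rownames(g)
  # canonical component order: ref taxon's dominant component first
  if (!is.null(ref_taxon) && ref_taxon %in% rownames(g) && K > 1L) {
    ord <- order(best$Q[ref_taxon, ], decreasing = TRUE)
    best$Q <- best$Q[, ord, drop = FALSE]
    best$F <- best$F[ord, , drop = FALSE]
  }
  colnames(best$Q) <- paste0("C", seq_len(K))
  rownames(best$F) <- paste0("C", seq_len(K))
  structure(c(best, list(K = K)), class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  cat("Haploid ancestry mixture fit: K =", x$K,
      "; log-likelihood =", format(x$loglik, digits = 8), "\n")
  cat("Mixture proportions (head):\n")
  print(utils::head(round(x$Q, 3)))
  invisible(x)
}
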