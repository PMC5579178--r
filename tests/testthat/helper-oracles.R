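# Independent resampling oracle for the paired DeLong test: a studentized
# sign-flip permutation test.  Under the null that the two scores are
# exchangeable within subject, randomly swapping (a_i, b_i) leaves the
# joint distribution unchanged; the studentized AUC difference is
# recomputed for every resample (the DeLong covariance re-estimated per
# permutation), and the p-value is the fraction of resamples at least as
# extreme as the observed statistic.  Vectorized over resamples with
# data.table::frankv using per-column value offsets so midrank ties are
# preserved within each column.
perm_delong_p <- function(labels, a, b, B = 1e5, chunk = 1e4) {
  n <- length(labels)
  pos <- which(labels)
  neg <- which(!labels)
  m <- length(pos)
  nn <- length(neg)
  off <- (max(abs(c(a, b))) + 1) * 4
  ranks_cols <- function(M) {
    k <- ncol(M)
    nr <- nrow(M)
    v <- as.vector(M) + rep.int((seq_len(k) - 1) * off, rep.int(nr, k))
    matrix(data.table::frankv(v, ties.method = "average"), nr, k) -
      rep((seq_len(k) - 1) * nr, each = nr)
  }
  placements <- function(M) {
    R <- ranks_cols(M)
    list(v10 = (R[pos, , drop = FALSE] -
                  ranks_cols(M[pos, , drop = FALSE])) / nn,
         v01 = 1 - (R[neg, , drop = FALSE] -
                      ranks_cols(M[neg, , drop = FALSE])) / m)
  }
  zstat <- function(pa, pb) {
    aa <- colMeans(pa$v10)
    ab <- colMeans(pb$v10)
    s10aa <- (colSums(pa$v10^2) - m * aa^2) / (m - 1)
    s10bb <- (colSums(pb$v10^2) - m * ab^2) / (m - 1)
    s10ab <- (colSums(pa$v10 * pb$v10) - m * aa * ab) / (m - 1)
    s01aa <- (colSums(pa$v01^2) - nn * aa^2) / (nn - 1)
    s01bb <- (colSums(pb$v01^2) - nn * ab^2) / (nn - 1)
    s01ab <- (colSums(pa$v01 * pb$v01) - nn * aa * ab) / (nn - 1)
    vd <- (s10aa + s10bb - 2 * s10ab) / m + (s01aa + s01bb - 2 * s01ab) / nn
    d <- aa - ab
    ifelse(vd > 0, d / sqrt(vd), ifelse(abs(d) < 1e-12, 0, Inf))
  }
  z_obs <- delong_test(labels, a, b)$z
  count <- 0
  done <- 0
  while (done < B) {
    k <- min(chunk, B - done)
    swap <- matrix(runif(n * k) < 0.5, n, k)
    A <- matrix(a, n, k)
    Bm <- matrix(b, n, k)
    z <- zstat(placements(ifelse(swap, Bm, A)),
               placements(ifelse(swap, A, Bm)))
    count <- count + sum(abs(z) >= abs(z_obs) - 1e-12)
    done <- done + k
  }
  count / B
}

# Participant-level AUC of one system under one size definition.
participant_auc <- function(cohort, system, defn, seed = 1L, coeffs = NULL) {
  sel <- select_dominant(cohort, score_cohort(cohort, system, defn, coeffs),
                         seed)
  auc(sel$has_cancer, sel$rank)
}
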