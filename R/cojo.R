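## Conditional-and-joint (COJO) refinement of association peaks from
## summary statistics plus an individual-level LD reference. Joint least
## squares uses the reference genotype cross-products; the phenotypic sum of
## squares is imputed from each candidate's marginal effect, standard error
## and genotype variance (median across candidates), the standard
## summary-statistic construction.

#' Conditional-and-joint selection of independently associated SNPs
#'
#' Candidates are scan records with marginal `p < p_entry`. In stepwise
#' mode, selection starts from the smallest marginal p-value; at each step
#' the conditional p-value of every remaining candidate given the selected
#' set is computed by joint least squares on the LD-reference genotypes,
#' any candidate with `r^2 >` `r2_cap` to a selected SNP has its
#' conditional p-value set to 1, and the smallest conditional-p candidate
#' is added while it is below `p_sig`. The final report keeps SNPs whose
#' joint and marginal p-values are both below `p_sig`. In `"cond"` mode a
#' single joint fit of all (collinearity-pruned) candidates is performed
#' instead.
#'
#' @param records association records ([mlma_scan()] output)
#' @param ld_source [genotype_matrix()] covering all candidate SNPs (the LD
#'   reference)
#' @param p_entry marginal p-value cut for candidacy
#' @param p_sig conditional/joint significance threshold
#' @param r2_cap collinearity cap: conditional p of candidates exceeding
#'   this `r^2` with a selected SNP is set to 1
#' @param mode `"stepwise"` (default) or `"cond"`
#' @return data.frame of selected SNPs: `id`, `chrom`, `pos`, `b_marginal`,
#'   `p_marginal`, `b_joint`, `se_joint`, `p_joint`, `cond_p` (conditional
#'   p-value at the selection step), `step`; attribute `collinear_dropped`
#'   lists candidates whose conditional p was forced to 1. Zero rows when
#'   there are no candidates.
#' @export
cojo_select <- function(records, ld_source, p_entry = 1e-5, p_sig = 5e-8,
                        r2_cap = 0.9, mode = c("stepwise", "cond")) {
  mode <- match.arg(mode)
  empty <- data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), b_marginal = numeric(0),
                      p_marginal = numeric(0), b_joint = numeric(0),
                      se_joint = numeric(0), p_joint = numeric(0),
                      cond_p = numeric(0), step = integer(0))
  cand <- records[records$p < p_entry & !records$monomorphic, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  ## deterministic order regardless of input record order
  cand <- cand[order(cand$p, cand$chrom, cand$pos), , drop = FALSE]
  key <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")
  idx <- match(key(cand), key(ld_source$map))
  if (anyNA(idx)) stopf("LD reference does not cover all candidate SNPs")
  Xc <- scale(ld_source$X[, idx, drop = FALSE], center = TRUE, scale = FALSE)
  n <- nrow(Xc)
  k <- ncol(Xc)
  d <- colSums(Xc^2)
  R2 <- cor(Xc)^2
  ## implied phenotypic sum of squares (median across candidates)
  yty <- median(d * cand$b^2 + d * cand$se^2 * (n - 2))

  joint_fit <- function(set) {
    B <- crossprod(Xc[, set, drop = FALSE])
    rhs <- d[set] * cand$b[set]
    ch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), rhs))
    df <- n - length(set) - 1
    s2 <- max(yty - sum(beta * rhs), 1e-12) / df
    Binv <- chol2inv(ch)
    se <- sqrt(s2 * diag(Binv))
    pj <- pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
    list(beta = beta, se = se, p = pj)
  }

  dropped <- integer(0)
  if (mode == "stepwise") {
    S <- 1L                      # smallest marginal p
    cond_p <- cand$p[1]; step_of <- 1L
    repeat {
      rem <- setdiff(seq_len(k), S)
      if (!length(rem)) break
      cp <- rep(1, length(rem))
      for (i in seq_along(rem)) {
        ci <- rem[i]
        if (max(R2[ci, S]) > r2_cap) { cp[i] <- 1; next }
        fit <- joint_fit(c(S, ci))
        if (is.null(fit)) { cp[i] <- 1; next }   # rank-deficient with ci
        cp[i] <- fit$p[length(fit$p)]
      }
      dropped <- union(dropped, rem[cp == 1 &
                                      apply(R2[rem, S, drop = FALSE], 1, max) > r2_cap])
      best <- which.min(cp)
      if (cp[best] >= p_sig) break
      S <- c(S, rem[best])
      cond_p <- c(cond_p, cp[best]); step_of <- c(step_of, length(S))
    }
  } else {
    ## single conditional pass: greedy r^2 pruning in p order, one joint fit
    S <- integer(0)
    for (ci in seq_len(k)) {
      if (length(S) && max(R2[ci, S]) > r2_cap) { dropped <- c(dropped, ci); next }
      S <- c(S, ci)
    }
    cond_p <- rep(NA_real_, length(S)); step_of <- seq_along(S)
  }

  fit <- joint_fit(S)
  while (is.null(fit) && length(S) > 1) {    # rank-deficient selected set
    warnf("rank-deficient selected set; dropping most recent addition")
    S <- S[-length(S)]; cond_p <- cond_p[-length(cond_p)]
    step_of <- step_of[-length(step_of)]
    fit <- joint_fit(S)
  }
  if (mode == "cond") cond_p <- fit$p
  out <- data.frame(id = cand$id[S], chrom = cand$chrom[S], pos = cand$pos[S],
                    b_marginal = cand$b[S], p_marginal = cand$p[S],
                    b_joint = fit$beta, se_joint = fit$se, p_joint = fit$p,
                    cond_p = cond_p, step = step_of,
                    stringsAsFactors = FALSE)
  keep <- out$p_joint < p_sig & out$p_marginal < p_sig
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "collinear_dropped") <- cand$id[unique(dropped)]
  out
}
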