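## Restricted maximum likelihood for the single-GRM model
##   y = X beta + g + e,  g ~ N(0, A sg2),  e ~ N(0, I se2)
## by average-information updates with an EM-like fallback, all in the
## eigenbasis of A where V = A sg2 + I se2 is diagonal. Fixed effects are
## projected out exactly (REML), default intercept only.

## Workspace: precomputed rotations shared by greml / mlma / blup.
vc_workspace <- function(y, spec, X) {
  U <- spec$U
  list(spec = spec, X = X, y = y,
       ystar = crossprod(U, y), Xstar = crossprod(U, X),
       yy = sum(y^2), XtX = crossprod(X), Xty = crossprod(X, y),
       q = ncol(X))
}

## All V^-1 quadratic forms for one (sg2, se2) point.
vc_terms <- function(ws, sg2, se2) {
  sp <- ws$spec
  v <- sg2 * sp$d + se2
  extra <- sp$N - sp$r        # multiplicity of the zero-eigenvalue block
  ys <- ws$ystar; Xs <- ws$Xstar
  XViX <- crossprod(Xs, Xs / v) + (ws$XtX - crossprod(Xs)) / se2
  XViy <- crossprod(Xs, ys / v) + (ws$Xty - crossprod(Xs, ys)) / se2
  yViy <- sum(ys^2 / v) + (ws$yy - sum(ys^2)) / se2
  M <- solve(XViX)
  alpha <- M %*% XViy
  yPy <- as.numeric(yViy - crossprod(XViy, alpha))
  logdetV <- sum(log(v)) + extra * log(se2)
  ll <- -0.5 * (logdetV + determinant(XViX, logarithm = TRUE)$modulus + yPy)
  list(v = v, extra = extra, M = M, alpha = alpha, yPy = yPy, ll = as.numeric(ll))
}

## Apply V^-1 and P to N-vectors via the spectrum.
vinv_apply <- function(ws, v, se2, z) {
  zs <- crossprod(ws$spec$U, z)
  z / se2 + ws$spec$U %*% (zs * (1 / v - 1 / se2))
}
p_apply <- function(ws, tm, se2, z) {
  Viz <- vinv_apply(ws, tm$v, se2, z)
  ViX <- vinv_apply(ws, tm$v, se2, ws$X)
  Viz - ViX %*% (tm$M %*% crossprod(ws$X, Viz))
}

#' GREML variance components for the generation proxy
#'
#' Estimates `sigma_g^2` and `sigma_e^2` of the mixed model
#' `y = X beta + g + e` with `g ~ N(0, A sigma_g^2)` by restricted maximum
#' likelihood. Updates are average-information steps with step-halving and
#' an EM-like fallback; components are kept non-negative by boundary
#' projection. PVE = `sigma_g^2 / (sigma_g^2 + sigma_e^2)`; standard errors
#' come from the inverse average-information matrix, the PVE standard error
#' by the delta method.
#'
#' @param y a [make_generation_proxy()] object or numeric vector
#' @param K a `grm`, `grm_spectrum`, or [genotype_matrix()] (the latter is
#'   converted via [grm_spectrum()])
#' @param covariates optional numeric matrix of fixed-effect covariates
#'   (an intercept is always included)
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood
#' @param max_iter iteration cap
#' @return object of class `varcomp`: `sigma_g2`, `sigma_e2`, `pve`, their
#'   standard errors, `loglik`, `iterations`, `converged`, `degenerate`
#'   (TRUE when A is numerically proportional to I so only the total
#'   variance is identifiable), `boundary`
#' @export
greml <- function(y, K, covariates = NULL, tol = 1e-6, max_iter = 100L) {
  if (inherits(y, "generation_proxy")) y <- y$y
  y <- as.numeric(y)
  spec <- grm_spectrum(K)
  N <- spec$N
  if (length(y) != N) stopf("length(y) != GRM dimension")
  if (N < 30) stopf("GREML needs N >= 30 samples")
  X <- cbind(`(Intercept)` = rep(1, N))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ws <- vc_workspace(y, spec, X)

  vary <- var(y)
  degenerate <- sd(spec$d) < 1e-8 * max(mean(spec$d), 1)
  sg2 <- se2 <- vary / 2
  floor_v <- 1e-8 * vary
  boundary <- FALSE

  tm <- vc_terms(ws, sg2, se2)
  ll <- tm$ll
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    ## score vector
    Py <- p_apply(ws, tm, se2, y)
    APy <- spec$U %*% (spec$d * crossprod(spec$U, Py))
    yPAPy <- sum(Py * APy)
    yPPy <- sum(Py^2)
    trViA <- sum(spec$d / tm$v)
    trVi <- sum(1 / tm$v) + tm$extra / se2
    Xs <- ws$Xstar
    XViAViX <- crossprod(Xs, Xs * (spec$d / tm$v^2))
    XViViX <- crossprod(Xs, Xs / tm$v^2) + (ws$XtX - crossprod(Xs)) / se2^2
    trPA <- trViA - sum(diag(tm$M %*% XViAViX))
    trPI <- trVi - sum(diag(tm$M %*% XViViX))
    score <- -0.5 * c(trPA - yPAPy, trPI - yPPy)
    ## average-information matrix
    PAPy <- p_apply(ws, tm, se2, APy)
    PPy <- p_apply(ws, tm, se2, Py)
    AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                         sum(APy * PPy), sum(Py * PPy)), 2, 2)
    step <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step)))
      step <- c(sg2^2 / (N - ws$q) * (yPAPy - trPA),
                se2^2 / (N - ws$q) * (yPPy - trPI))  # EM-like fallback
    ## step-halving with EM fallback on likelihood decrease
    ok <- FALSE
    for (half in 0:8) {
      cand <- c(sg2, se2) + step / 2^half
      cand <- pmax(cand, floor_v)
      tm2 <- tryCatch(vc_terms(ws, cand[1], cand[2]), error = function(e) NULL)
      if (!is.null(tm2) && is.finite(tm2$ll) && tm2$ll >= ll - 1e-10) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      cand <- pmax(c(sg2 + sg2^2 / (N - ws$q) * (yPAPy - trPA),
                     se2 + se2^2 / (N - ws$q) * (yPPy - trPI)), floor_v)
      tm2 <- vc_terms(ws, cand[1], cand[2])
    }
    dll <- tm2$ll - ll
    sg2 <- cand[1]; se2 <- cand[2]; tm <- tm2; ll <- tm2$ll
    if (abs(dll) < tol) { converged <- TRUE; break }
  }
  boundary <- sg2 <= floor_v * 1.01 || se2 <= floor_v * 1.01

  ## SEs from the AI matrix at the optimum
  Py <- p_apply(ws, tm, se2, y)
  APy <- spec$U %*% (spec$d * crossprod(spec$U, Py))
  PAPy <- p_apply(ws, tm, se2, APy)
  PPy <- p_apply(ws, tm, se2, Py)
  AI <- 0.5 * matrix(c(sum(APy * PAPy), sum(APy * PPy),
                       sum(APy * PPy), sum(Py * PPy)), 2, 2)
  V <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  tot <- sg2 + se2
  h <- c(se2, -sg2) / tot^2
  pve_se <- sqrt(max(0, as.numeric(t(h) %*% V %*% h)))
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, pve = sg2 / tot,
                 se_g2 = sqrt(max(0, V[1, 1])), se_e2 = sqrt(max(0, V[2, 2])),
                 pve_se = pve_se, loglik = ll, iterations = it,
                 converged = converged, degenerate = degenerate,
                 boundary = boundary),
            class = "varcomp")
}

#' @exportS3Method base::print
print.varcomp <- function(x, ...) {
  cat(sprintf(paste0("<varcomp> sigma_g2=%.4g (SE %.3g), sigma_e2=%.4g (SE %.3g)\n",
                     "  PVE=%.4f (SE %.4f), loglik=%.3f, %d iter, converged=%s%s\n"),
              x$sigma_g2, x$se_g2, x$sigma_e2, x$se_e2, x$pve, x$pve_se,
              x$loglik, x$iterations, x$converged,
              if (x$degenerate) " [degenerate: A ~ I]" else ""))
  invisible(x)
}

#' BLUP polygenic values and residuals
#'
#' Given converged variance components, predicts each sample's polygenic
#' value `a_hat = sigma_g^2 A V^-1 (y - X beta_hat)` and residual
#' `e_hat = y - X beta_hat - a_hat`, with `beta_hat` by generalized least
#' squares. The identity `y = X beta_hat + a_hat + e_hat` holds exactly.
#'
#' @inheritParams greml
#' @param vc a converged [greml()] result
#' @return list: `a_hat`, `e_hat`, `beta_hat`, `fitted`
#' @export
blup_predict <- function(y, K, vc, covariates = NULL) {
  if (inherits(y, "generation_proxy")) y <- y$y
  y <- as.numeric(y)
  if (!isTRUE(vc$converged)) stopf("variance components did not converge")
  spec <- grm_spectrum(K)
  X <- cbind(`(Intercept)` = rep(1, spec$N))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ws <- vc_workspace(y, spec, X)
  tm <- vc_terms(ws, vc$sigma_g2, vc$sigma_e2)
  r <- y - as.numeric(X %*% tm$alpha)
  Vir <- vinv_apply(ws, tm$v, vc$sigma_e2, r)
  a_hat <- vc$sigma_g2 * (spec$U %*% (spec$d * crossprod(spec$U, Vir)))
  a_hat <- as.numeric(a_hat)
  e_hat <- r - a_hat
  list(a_hat = a_hat, e_hat = e_hat, beta_hat = as.numeric(tm$alpha),
       fitted = as.numeric(X %*% tm$alpha) + a_hat)
}
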