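# Per-residue Lipari-Szabo model-free fitting with F-test model selection.
#
# Candidate models (tau_m held fixed):
#   M1: S2 only            (2 residual dof with 3 observables)
#   M2: S2 + tau_e         (1 dof)
#   M3: S2 + Rex           (1 dof)
# Each model's chi2 = sum(((obs - calc)/err)^2) is minimized by a
# deterministic coarse grid followed by bounded local refinement; the
# simplest model not rejected against its extensions by an F-test at
# `alpha` is selected.

mf_chi2 <- function(s2, tau_e, rex, tau_m, consts, obs) {
  fr <- forward_rates(s2, tau_e, rex, tau_m, consts)
  ((fr$r1 - obs$r1) / obs$r1_err)^2 +
    ((fr$r2 - obs$r2) / obs$r2_err)^2 +
    ((fr$noe - obs$noe) / obs$noe_err)^2
}

mf_fit_model <- function(model, obs, tau_m, consts,
                         s2_grid = seq(0, 1, by = 0.01),
                         te_grid = c(0, exp(seq(log(1), log(1000),
                                                length.out = 25))),
                         rex_grid = seq(0, 15, by = 0.25)) {
  if (model == "M1") {
    chi <- mf_chi2(s2_grid, 0, 0, tau_m, consts, obs)
    s2_0 <- s2_grid[which.min(chi)]
    opt <- stats::optimize(function(s2) mf_chi2(s2, 0, 0, tau_m, consts, obs),
                           interval = c(max(0, s2_0 - 0.02),
                                        min(1, s2_0 + 0.02)), tol = 1e-12)
    return(list(model = "M1", s2 = opt$minimum, tau_e = 0, rex = 0,
                chi2 = opt$objective, dof = 2L, converged = TRUE))
  }
  if (model == "M2") {
    g <- expand.grid(s2 = s2_grid, te = te_grid)
    chi <- mf_chi2(g$s2, g$te, 0, tau_m, consts, obs)
    start <- g[which.min(chi), ]
    raw_fn <- function(p) mf_chi2(p[1], p[2], 0, tau_m, consts, obs)
    lower <- c(0, 0); upper <- c(1, 5000)
    par0 <- c(start$s2, start$te)
  } else {
    g <- expand.grid(s2 = s2_grid, rex = rex_grid)
    chi <- mf_chi2(g$s2, 0, g$rex, tau_m, consts, obs)
    start <- g[which.min(chi), ]
    raw_fn <- function(p) mf_chi2(p[1], 0, p[2], tau_m, consts, obs)
    lower <- c(0, 0); upper <- c(1, 100)
    par0 <- c(start$s2, start[[2]])
  }
  # evaluate at the clamped point plus a smooth penalty on the excursion,
  # so finite-difference gradients at the box boundary stay well-behaved
  fn <- function(p) {
    pc <- pmin(pmax(p, lower), upper)
    raw_fn(pc) + 1e6 * sum((p - pc)^2)
  }
  opt <- stats::optim(par0, fn, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 10, maxit = 500))
  # Nelder-Mead polish for extra precision
  nm <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 2000))
  if (nm$value <= opt$value) opt <- nm
  opt$par <- pmin(pmax(opt$par, lower), upper)
  converged <- is.finite(opt$value) &&
    (is.null(opt$convergence) || opt$convergence %in% c(0L, 1L))
  if (model == "M2")
    list(model = "M2", s2 = opt$par[1], tau_e = opt$par[2], rex = 0,
         chi2 = opt$value, dof = 1L, converged = converged)
  else
    list(model = "M3", s2 = opt$par[1], tau_e = 0, rex = opt$par[2],
         chi2 = opt$value, dof = 1L, converged = converged)
}

# F-test p-value for nested models (chi2_1/dof1 simpler, chi2_2/dof2 richer).
mf_ftest <- function(chi2_1, dof1, chi2_2, dof2, eps = 1e-12) {
  if (chi2_1 <= eps) return(1)      # simpler model already perfect
  if (chi2_2 <= eps) return(0)      # extension perfect, simpler is not
  f <- ((chi2_1 - chi2_2) / (dof1 - dof2)) / (chi2_2 / dof2)
  if (f <= 0) return(1)
  stats::pf(f, dof1 - dof2, dof2, lower.tail = FALSE)
}

#' Fit model-free parameters for one residue
#'
#' Fits the candidate Lipari-Szabo models to one (R1, R2, NOE) triple at
#' fixed overall tumbling time and selects a model by the classical
#' two-stage protocol: the one-parameter model M1 (S2 only) is retained
#' only when its chi2 passes a goodness-of-fit test at level `alpha` and
#' no two-parameter extension (M2: S2 + tau_e, or M3: S2 + Rex) improves
#' it significantly by an F-test at `alpha`; otherwise the best-fitting
#' extension is selected (the F-significant one when there is one).
#'
#' @param obs one-row data frame (or list) with `r1`, `r1_err`, `r2`,
#'   `r2_err`, `noe`, `noe_err`; all errors must be > 0.
#' @param tau_m overall tumbling time, ns.
#' @param consts a [spin_constants()] object.
#' @param models candidate subset of `c("M1", "M2", "M3")`.
#' @param alpha F-test significance level (default 0.05).
#' @return list of class `"modelfree_result"`: `model`, `s2`, `tau_e`
#'   (ps), `rex` (s-1), `chi2`, `dof`, `converged`, plus the per-model
#'   chi2 table in `candidates`.
#' @export
fit_modelfree <- function(obs, tau_m, consts = spin_constants(),
                          models = c("M1", "M2", "M3"), alpha = 0.05) {
  models <- match.arg(models, c("M1", "M2", "M3"), several.ok = TRUE)
  if (any(unlist(obs[c("r1_err", "r2_err", "noe_err")]) <= 0))
    stop_invalid("all observable errors must be > 0")
  fits <- lapply(models, mf_fit_model, obs = obs, tau_m = tau_m,
                 consts = consts)
  names(fits) <- models
  pick <- if ("M1" %in% models && length(models) > 1) {
    exts <- setdiff(models, "M1")
    # two-stage selection: keep M1 only if it both fits adequately
    # (chi2 goodness-of-fit) and no extension improves it significantly
    # (F-test); otherwise take the best-fitting extension
    p_adequate <- stats::pchisq(fits$M1$chi2, fits$M1$dof,
                                lower.tail = FALSE)
    pvals <- vapply(exts, function(m)
      mf_ftest(fits$M1$chi2, fits$M1$dof, fits[[m]]$chi2, fits[[m]]$dof),
      numeric(1))
    sig <- exts[pvals <= alpha]
    if (p_adequate > alpha && !length(sig)) "M1"
    else {
      cand <- if (length(sig)) sig else exts
      cand[which.min(vapply(cand, function(m) fits[[m]]$chi2, numeric(1)))]
    }
  } else {
    models[which.min(vapply(fits, `[[`, numeric(1), "chi2"))]
  }
  out <- fits[[pick]]
  out$candidates <- data.frame(
    model = models,
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    dof = vapply(fits, `[[`, integer(1), "dof"),
    row.names = NULL)
  out$alpha <- alpha
  class(out) <- "modelfree_result"
  out
}

#' @export
print.modelfree_result <- function(x, ...) {
  cat(sprintf("%s: S2 = %.3f, tau_e = %.1f ps, Rex = %.2f s-1, chi2 = %.3g (%d dof)\n",
              x$model, x$s2, x$tau_e, x$rex, x$chi2, x$dof))
  invisible(x)
}
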