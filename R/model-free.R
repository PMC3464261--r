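#' Fit the Lipari-Szabo model-free model to a rates table
#'
#' The central fitting routine: takes per-residue (R1, R2, NOE) values
#' with errors, estimates the overall rotational correlation time from
#' the R2/R1 ratio of the rigid subset (unless supplied), and fits each
#' residue's model-free parameters with F-test model selection
#' (see [fit_modelfree()]).
#'
#' Residues reported with a zero (or missing) error receive a nominal
#' weight of `min_rel_err` times the observable, flagged in the output;
#' chi2 values are then only comparative.
#'
#' @param rates a `"rates_table"` (see [extract_rates()]) or data frame
#'   with columns `residue_index`, `r1`, `r1_err`, `r2`, `r2_err`, `noe`,
#'   `noe_err`.
#' @param tau_m `"auto"` (default) to estimate the grand average from the
#'   data, or a fixed value in ns.
#' @param consts a [spin_constants()] object.
#' @param models candidate subset of `c("M1", "M2", "M3")`.
#' @param alpha F-test significance level.
#' @param per_residue_tau_m logical; fit each included residue at its own
#'   apparent tau_m instead of the grand average (excluded residues still
#'   use the average).
#' @param min_rel_err relative error floor substituted for non-positive
#'   reported errors.
#' @param ... arguments passed to [select_tumbling_subset()] (e.g.
#'   `noe_min`, `n_sd`).
#' @return An object of class `"model_free"`; see
#'   [summary.model_free()], [coef.model_free()], [predict.model_free()],
#'   [residuals.model_free()], [plot.model_free()] and
#'   [simulate.model_free()].
#' @examples
#' ds <- generate_dataset(generate_profile(12, seed = 1), seed = 2)
#' rt <- extract_rates(ds, n_mc = 50, seed = 3)
#' fit <- model_free(rt)
#' coef(fit)
#' @export
model_free <- function(rates, tau_m = "auto", consts = spin_constants(),
                       models = c("M1", "M2", "M3"), alpha = 0.05,
                       per_residue_tau_m = FALSE, min_rel_err = 0.02,
                       ...) {
  rates <- as.data.frame(rates)
  need <- c("residue_index", "r1", "r1_err", "r2", "r2_err", "noe",
            "noe_err")
  if (!all(need %in% names(rates)))
    stop_invalid("'rates' must have columns ", paste(need, collapse = ", "))
  floored <- FALSE
  for (v in c("r1", "r2", "noe")) {
    ev <- paste0(v, "_err")
    bad <- !is.finite(rates[[ev]]) | rates[[ev]] <= 0
    if (any(bad)) {
      floored <- TRUE
      # rates get a relative floor; the NOE, a ratio that passes through
      # zero, gets an absolute one
      rates[[ev]][bad] <- if (v == "noe") min_rel_err
                          else pmax(min_rel_err * abs(rates[[v]][bad]), 1e-6)
    }
  }
  tumbling <- NULL
  if (identical(tau_m, "auto") || per_residue_tau_m) {
    tumbling <- select_tumbling_subset(rates, consts = consts, ...)
  }
  tau_used <- if (identical(tau_m, "auto")) tumbling$average_tau_m
              else as.numeric(tau_m)
  fits <- lapply(seq_len(nrow(rates)), function(i) {
    tm_i <- tau_used
    if (per_residue_tau_m) {
      key <- as.character(rates$residue_index[i])
      if (key %in% names(tumbling$per_residue_tau_m))
        tm_i <- tumbling$per_residue_tau_m[[key]]
    }
    fit <- fit_modelfree(rates[i, ], tm_i, consts, models, alpha)
    fit$tau_m <- tm_i
    fit
  })
  results <- data.frame(
    residue_index = rates$residue_index,
    model = vapply(fits, `[[`, character(1), "model"),
    s2 = vapply(fits, `[[`, numeric(1), "s2"),
    tau_e = vapply(fits, `[[`, numeric(1), "tau_e"),
    rex = vapply(fits, `[[`, numeric(1), "rex"),
    chi2 = vapply(fits, `[[`, numeric(1), "chi2"),
    dof = vapply(fits, `[[`, integer(1), "dof"),
    tau_m = vapply(fits, `[[`, numeric(1), "tau_m"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  structure(list(results = results, tau_m = tau_used,
                 tumbling = tumbling, data = rates, consts = consts,
                 models = models, alpha = alpha,
                 error_floored = floored,
                 call = match.call()),
            class = "model_free")
}

#' @export
print.model_free <- function(x, ...) {
  cat("Lipari-Szabo model-free fit\n")
  cat(sprintf("  %d residues, tau_m = %.3f ns (%s)\n",
              nrow(x$results), x$tau_m,
              if (is.null(x$tumbling)) "fixed" else
                sprintf("mean of %d rigid residues",
                        length(x$tumbling$included))))
  tab <- table(x$results$model)
  cat("  selected models:",
      paste(sprintf("%s x %d", names(tab), tab), collapse = ", "), "\n")
  if (isTRUE(x$error_floored))
    cat("  note: zero reported errors replaced by a nominal floor\n")
  invisible(x)
}

#' Summary of a model-free fit
#'
#' @param object a `"model_free"` fit.
#' @param ... unused.
#' @return a `"summary.model_free"` list with the tumbling estimate,
#'   model counts, and per-class S2 statistics.
#' @export
summary.model_free <- function(object, ...) {
  r <- object$results
  out <- list(tau_m = object$tau_m, n = nrow(r),
              model_counts = table(r$model),
              s2_mean = mean(r$s2), s2_range = range(r$s2),
              n_rex = sum(r$rex > 0),
              mean_rex = if (any(r$rex > 0)) mean(r$rex[r$rex > 0]) else 0,
              chi2_total = sum(r$chi2),
              tumbling = object$tumbling, alpha = object$alpha)
  class(out) <- "summary.model_free"
  out
}

#' @export
print.summary.model_free <- function(x, ...) {
  cat("Model-free analysis summary\n")
  cat(sprintf("  residues            : %d\n", x$n))
  cat(sprintf("  tau_m               : %.3f ns\n", x$tau_m))
  cat(sprintf("  mean S2             : %.3f (range %.3f-%.3f)\n",
              x$s2_mean, x$s2_range[1], x$s2_range[2]))
  cat(sprintf("  residues with Rex   : %d (mean %.2f s-1)\n",
              x$n_rex, x$mean_rex))
  cat("  model counts        :",
      paste(sprintf("%s=%d", names(x$model_counts), x$model_counts),
            collapse = " "), "\n")
  cat(sprintf("  total chi2          : %.4g\n", x$chi2_total))
  invisible(x)
}

#' Extract model-free coefficients
#'
#' @param object a `"model_free"` fit.
#' @param ... unused.
#' @return numeric matrix (one row per residue) with columns `s2`,
#'   `tau_e` (ps) and `rex` (s-1), rownames = residue indices.
#' @export
coef.model_free <- function(object, ...) {
  m <- as.matrix(object$results[, c("s2", "tau_e", "rex")])
  rownames(m) <- object$results$residue_index
  m
}

#' Back-calculated relaxation observables of a model-free fit
#'
#' @param object a `"model_free"` fit.
#' @param newdata optional data frame of parameters (`s2`, `tau_e`,
#'   `rex`, optionally `tau_m`) to forward-model instead of the fitted
#'   ones.
#' @param ... unused.
#' @return data frame with `residue_index` (for fitted parameters),
#'   `r1`, `r2`, `noe`.
#' @export
predict.model_free <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    r <- object$results
    out <- forward_rates(r$s2, r$tau_e, r$rex, r$tau_m, object$consts)
    cbind(residue_index = r$residue_index, out)
  } else {
    tm <- newdata$tau_m %||% object$tau_m
    forward_rates(newdata$s2, newdata$tau_e %||% 0, newdata$rex %||% 0,
                  tm, object$consts)
  }
}

#' @export
fitted.model_free <- function(object, ...) predict(object)

#' Residuals of a model-free fit
#'
#' @param object a `"model_free"` fit.
#' @param type `"standardized"` (divided by the observable errors; these
#'   are the chi2 contributions) or `"raw"`.
#' @param ... unused.
#' @return data frame with `residue_index`, `r1`, `r2`, `noe` residuals.
#' @export
residuals.model_free <- function(object,
                                 type = c("standardized", "raw"), ...) {
  type <- match.arg(type)
  calc <- predict(object)
  d <- object$data
  out <- data.frame(residue_index = d$residue_index,
                    r1 = d$r1 - calc$r1,
                    r2 = d$r2 - calc$r2,
                    noe = d$noe - calc$noe)
  if (type == "standardized") {
    out$r1 <- out$r1 / d$r1_err
    out$r2 <- out$r2 / d$r2_err
    out$noe <- out$noe / d$noe_err
  }
  out
}

#' Plot a model-free fit
#'
#' Three stacked per-residue panels in the conventional layout: order
#' parameter S2, internal correlation time tau_e, and exchange
#' contribution Rex.
#'
#' @param x a `"model_free"` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.model_free <- function(x, ...) {
  r <- x$results
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1), mgp = c(2, 0.6, 0))
  on.exit(graphics::par(old))
  graphics::plot(r$residue_index, r$s2, type = "h", ylim = c(0, 1),
                 xlab = "", ylab = expression(S^2), ...)
  graphics::abline(h = 0.8, lty = 3)
  graphics::plot(r$residue_index, r$tau_e, type = "h",
                 xlab = "", ylab = expression(tau[e] ~ "(ps)"))
  graphics::plot(r$residue_index, r$rex, type = "h",
                 xlab = "residue", ylab = expression(R[ex] ~ (s^-1)))
  invisible(x)
}

#' Simulate rate tables from a fitted model
#'
#' Draws new (R1, R2, NOE) tables from the fitted parameters, adding
#' Gaussian noise with the observed per-residue errors.
#'
#' @param object a `"model_free"` fit.
#' @param nsim number of simulated tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` rates tables.
#' @export
simulate.model_free <- function(object, nsim = 1, seed = NULL, ...) {
  calc <- predict(object)
  d <- object$data
  with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      out <- data.frame(
        residue_index = d$residue_index,
        r1 = stats::rnorm(nrow(d), calc$r1, d$r1_err),
        r1_err = d$r1_err,
        r2 = stats::rnorm(nrow(d), calc$r2, d$r2_err),
        r2_err = d$r2_err,
        noe = stats::rnorm(nrow(d), calc$noe, d$noe_err),
        noe_err = d$noe_err)
      class(out) <- c("rates_table", "data.frame")
      out
    })
  })
}
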