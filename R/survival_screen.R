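#' Assign samples to lower / upper expression quartile groups
#'
#' The lower group contains samples whose expression is at or below the
#' first quartile, the upper group samples at or above the third quartile
#' (quartiles by the linear-interpolation quantile definition); the middle
#' half is excluded.  With the default inclusive tie rule, ties straddling
#' a boundary all enter the boundary group, so group sizes may exceed n/4.
#'
#' @param expr Named numeric vector of per-sample expression values; at
#'   least 8 non-missing values are required.
#' @param ties "inclusive" (<= Q1 / >= Q3, default) or "strict"
#'   (< Q1 / > Q3).
#' @return Character vector (named like `expr`) with values
#'   "lower_quartile", "upper_quartile", "excluded" (missing input stays
#'   `NA`).
#' @export
quartile_groups <- function(expr, ties = c("inclusive", "strict")) {
  ties <- match.arg(ties)
  ok <- !is.na(expr)
  if (sum(ok) < 8) stop("need at least 8 samples with non-missing expression")
  q <- stats::quantile(expr[ok], c(0.25, 0.75), type = 7, names = FALSE)
  if (q[1] == q[2]) {
    stop("first and third quartiles coincide; groups undefined")
  }
  grp <- rep(NA_character_, length(expr))
  if (ties == "inclusive") {
    grp[ok & expr <= q[1]] <- "lower_quartile"
    grp[ok & expr >= q[2]] <- "upper_quartile"
  } else {
    grp[ok & expr < q[1]] <- "lower_quartile"
    grp[ok & expr > q[2]] <- "upper_quartile"
  }
  grp[ok & is.na(grp)] <- "excluded"
  names(grp) <- names(expr)
  grp
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = progression, 0 = censored).
#' @return A `km_curve` data frame: time, n_risk, n_event, n_censor, surv
#'   (survival probability after each distinct time).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative follow-up time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Two-group log-rank test
#'
#' @param time,event Survival data.
#' @param group Group labels (two or more levels).
#' @return List: statistic (chi-squared), df, p.value.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least two groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd_$n) - 1
  list(statistic = unname(sd_$chisq), df = df,
       p.value = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Screen genes for quartile-stratified survival association
#'
#' For each gene, tumors are split into lower- and upper-quartile
#' expression groups ([quartile_groups()]) and compared by a two-group
#' log-rank test on time to (biochemical) progression.  Benjamini-Hochberg
#' FDR is applied across the genes actually tested within the cohort;
#' genes whose quartile split is undefined are reported with `NA` and enter
#' neither the numerator nor the denominator of the correction.
#'
#' @param expr Genes x samples expression matrix.
#' @param clinical Data frame with `sample`, `time`, `event` columns
#'   (tumors only, or with a `type` column from which tumors are taken).
#' @param genes Genes to screen (default: all matrix rows).
#' @return A `survival_screen` data frame: gene, statistic, p, fdr.
#' @export
logrank_screen <- function(expr, clinical, genes = rownames(expr)) {
  stopifnot(all(c("sample", "time", "event") %in% names(clinical)))
  if ("type" %in% names(clinical)) {
    clinical <- clinical[clinical$type == "tumor", , drop = FALSE]
  }
  clinical <- clinical[!is.na(clinical$time) & !is.na(clinical$event), ,
                       drop = FALSE]
  samp <- intersect(clinical$sample, colnames(expr))
  clinical <- clinical[match(samp, clinical$sample), , drop = FALSE]
  if (!all(genes %in% rownames(expr))) {
    stop("screened genes missing from the expression matrix")
  }
  res <- lapply(genes, function(g) {
    out <- tryCatch({
      grp <- quartile_groups(expr[g, samp])
      keep <- grp %in% c("lower_quartile", "upper_quartile")
      lr <- logrank_test(clinical$time[keep], clinical$event[keep],
                         grp[keep])
      c(lr$statistic, lr$p.value)
    }, error = function(e) c(NA_real_, NA_real_))
    data.frame(gene = g, statistic = out[1], p = out[2],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (all(is.na(res$p))) stop("no usable genes in the survival screen")
  res$fdr <- NA_real_
  ok <- !is.na(res$p)
  res$fdr[ok] <- stats::p.adjust(res$p[ok], method = "BH")
  class(res) <- c("survival_screen", class(res))
  res
}

#' Plot Kaplan-Meier step curves for quartile groups of one gene
#'
#' @param expr Named per-sample expression vector.
#' @param time,event Survival data aligned with `expr`.
#' @param main Plot title.
#' @export
plot_km_quartiles <- function(expr, time, event, main = "") {
  grp <- quartile_groups(expr)
  keep <- grp %in% c("lower_quartile", "upper_quartile")
  fit <- survival::survfit(survival::Surv(time[keep], event[keep]) ~
                             grp[keep])
  graphics::plot(fit, col = c("firebrick", "navy"), lwd = 2,
                 xlab = "time", ylab = "progression-free fraction",
                 main = main)
  graphics::legend("bottomleft", legend = c("lower quartile",
                                            "upper quartile"),
                   col = c("firebrick", "navy"), lwd = 2, bty = "n")
  invisible(fit)
}
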