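# Factorial models for per-sample responses, FDR control, and assembly of
# the final report tables.

#' Two-factor model with sequential tests
#'
#' Fits \code{response ~ assemblage + area + assemblage:area}. Gaussian
#' responses use least squares with sequential (Type-I) F-tests; species
#' richness uses a log-link Poisson GLM with sequential likelihood-ratio
#' chi-squared tests.
#'
#' @param response numeric vector, one value per sample.
#' @param meta per-sample metadata with \code{assemblage} and \code{area}.
#' @param family \code{"gaussian_ols"} or \code{"poisson_glm"}.
#' @return data.frame per term (assemblage, area, interaction): statistic
#'   and p-value.
#' @export
fit_factorial <- function(response, meta,
                          family = c("gaussian_ols", "poisson_glm")) {
  family <- match.arg(family)
  for (f in c("assemblage", "area")) {
    if (length(unique(meta[[f]])) < 2L) {
      stop("factor ", f, " needs at least 2 levels")
    }
  }
  dat <- data.frame(y = response,
                    assemblage = factor(meta$assemblage),
                    area = factor(meta$area))
  if (stats::sd(response) <= 1e-10 * (abs(mean(response)) + 1)) {
    # constant response: no term can explain anything
    return(data.frame(term = c("assemblage", "area", "interaction"),
                      statistic = 0, p = 1))
  }
  if (family == "poisson_glm") {
    if (any(dat$y != round(dat$y))) {
      stop("Poisson family requires integer counts")
    }
    fit <- stats::glm(y ~ assemblage * area, data = dat, family = "poisson")
    an <- stats::anova(fit, test = "LRT")
    out <- data.frame(term = rownames(an)[-1L],
                      statistic = an$Deviance[-1L],
                      p = an$`Pr(>Chi)`[-1L])
    explained <- an$Deviance[-1L]
    total <- an$`Resid. Dev`[1L]
  } else {
    fit <- stats::lm(y ~ assemblage * area, data = dat)
    an <- stats::anova(fit)
    n_terms <- nrow(an) - 1L
    out <- data.frame(term = rownames(an)[seq_len(n_terms)],
                      statistic = an$`F value`[seq_len(n_terms)],
                      p = an$`Pr(>F)`[seq_len(n_terms)])
    explained <- an$`Sum Sq`[seq_len(n_terms)]
    total <- sum(an$`Sum Sq`)
  }
  out$term <- sub("assemblage:area", "interaction", out$term)
  # a term explaining (numerically) zero variation carries no evidence;
  # guards exact-fit cases where both term and residual SS are rounding
  # dust and the F ratio is meaningless
  zero <- is.nan(out$p) | explained <= 1e-12 * max(total, 1e-300)
  out$p[zero] <- 1
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment via [stats::p.adjust()].
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  stats::p.adjust(p, method = "BH")
}

#' Assemble the per-trait and per-index report tables
#'
#' Builds one tidy table per community-weighted-mean trait and per
#' diversity index, each with the factorial model results attached, and a
#' run manifest. The BH family is all per-term p-values within one table
#' family (all CWM traits together; all diversity indices together).
#'
#' @param cwm_table output of [cwm()].
#' @param index_table data.frame of per-sample diversity indices with the
#'   same metadata columns (\code{sample_id}, \code{assemblage},
#'   \code{area}); the \code{richness} column, when present, is modelled
#'   with the Poisson family.
#' @param config the [analysis_config()] used for the run.
#' @return list with \code{trait_models}, \code{index_models} (model
#'   tables with raw and BH-adjusted p-values), \code{cwm} and
#'   \code{indices} (the input tables), and \code{manifest}.
#' @export
build_report <- function(cwm_table, index_table,
                         config = analysis_config()) {
  if (is.null(cwm_table) || is.null(index_table)) {
    stop("missing upstream output: ",
         if (is.null(cwm_table)) "cwm" else "indices")
  }
  meta_cols <- c("sample_id", "assemblage", "area")
  model_family <- function(tab) {
    responses <- setdiff(names(tab), meta_cols)
    res <- do.call(rbind, lapply(responses, function(v) {
      fam <- if (v == "richness") "poisson_glm" else "gaussian_ols"
      m <- fit_factorial(tab[[v]], tab, family = fam)
      cbind(response = v, m, family = fam)
    }))
    res$p_adj <- bh_adjust(res$p)
    res
  }
  list(trait_models = model_family(cwm_table),
       index_models = model_family(index_table),
       cwm = cwm_table, indices = index_table,
       manifest = list(config = unclass(config),
                       r_version = R.version.string,
                       package_version =
                         as.character(utils::packageVersion("traitvolume")),
                       timestamp = format(Sys.time(), tz = "UTC")))
}
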