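# Site-by-intervention statistics: long-format cohort assembly, mixed /
# fixed two-way model with interaction, Bonferroni per-site post hoc, and
# the simulated-change power analysis.

cohortMeasures <- function() {
  c("ct_ar", "ma_ar", "tt_ar", "cs_th", "i_min", "i_max", "pmi",
    "feret_max", "feret_min", "eccentricity", "dev_x", "dev_y")
}

#' Assemble the long-format cohort table from bone profiles
#'
#' One row per (mouse, limb, site, measure); values from breached sites
#' stay in the table as missing so the models drop that site's row, not
#' the mouse.
#'
#' @param profiles list of \linkS4class{BoneProfile} objects, one per bone.
#' @param metadata data.frame with one row per profile and columns
#'   \code{mouse_id}, \code{limb} ("left"/"right"), \code{group}.
#' @param measures measure columns to extract (default all standard ones).
#' @return long-format data.frame (mouse_id, limb, group, site_pct,
#'   measure_name, value).
#' @export
buildCohortTable <- function(profiles, metadata,
                             measures = cohortMeasures()) {
  stopifnot(length(profiles) == nrow(metadata),
            all(c("mouse_id", "limb", "group") %in% names(metadata)))
  key <- paste(metadata$mouse_id, metadata$limb)
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, limb) combinations in metadata")
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    d <- profileData(profiles[[i]])
    measures_i <- intersect(measures, names(d))
    long <- do.call(rbind, lapply(measures_i, function(m) {
      data.frame(mouse_id = metadata$mouse_id[i], limb = metadata$limb[i],
                 group = metadata$group[i], site_pct = d$site_pct,
                 measure_name = m, value = d[[m]])
    }))
    out[[i]] <- long
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

anovaP <- function(tab, term) {
  rn <- rownames(tab)
  pcol <- grep("^Pr\\(", colnames(tab), value = TRUE)[1L]
  hit <- which(rn == term)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(tab[hit[1L], pcol])
}

#' Fit the site-by-intervention model for one measure
#'
#' Fits \code{value ~ site + group + site:group} with bone site as a fixed
#' categorical factor, the intervention as a fixed effect and their
#' interaction (site-specific vs uniform response). With
#' \code{paired = TRUE} (left/right limbs from the same mice) a random
#' intercept per mouse is added and the model is estimated by REML with
#' lme4; otherwise an ordinary two-way fixed-effects model is used.
#' Overall intervention and interaction significance come from type-III
#' Wald tests (sum-to-zero contrasts); per-site intervention contrasts are
#' computed from the fixed-effect coefficients and their covariance.
#' Rows with missing values are dropped listwise within site. A singular
#' random-effect fit falls back to the fixed-effects model with a warning.
#'
#' @param table long-format cohort table (see
#'   \code{\link{buildCohortTable}}).
#' @param measure measure name to analyze.
#' @param paired include the random mouse intercept.
#' @return A \linkS4class{SiteModelResult} with raw per-site p-values;
#'   apply \code{\link{bonferroniPosthoc}} for the corrected site map.
#' @export
fitSiteModel <- function(table, measure, paired = FALSE) {
  d <- table[table$measure_name == measure & !is.na(table$value), ,
             drop = FALSE]
  if (nrow(d) == 0L) stop(sprintf("no data for measure '%s'", measure))
  d$site <- factor(d$site_pct)
  d$group <- factor(d$group)
  if (nlevels(d$group) < 2L) stop("need at least two groups")
  if (nlevels(d$site) < 2L) stop("need at least two sites")
  if ("control" %in% levels(d$group))
    d$group <- stats::relevel(d$group, "control")
  perGroup <- tapply(d$mouse_id, d$group, function(x) length(unique(x)))
  if (any(perGroup < 2L)) stop("need at least two subjects per group")
  ctr <- list(site = "contr.sum", group = "contr.sum")
  usedModel <- if (paired) "mixed" else "fixed"
  mod <- NULL
  if (paired) {
    mod <- tryCatch(
      lme4::lmer(value ~ site * group + (1 | mouse_id), data = d,
                 REML = TRUE, contrasts = ctr),
      error = function(e) stop("mixed model failed to converge: ",
                               conditionMessage(e), call. = FALSE))
    if (lme4::isSingular(mod)) {
      warning("singular random-effect fit; falling back to the ",
              "fixed-effects model")
      usedModel <- "fixed"
      mod <- NULL
    }
  }
  if (is.null(mod))
    mod <- stats::lm(value ~ site * group, data = d, contrasts = ctr)
  a3 <- car::Anova(mod, type = 3)
  overallP <- anovaP(a3, "group")
  interP <- anovaP(a3, "site:group")
  # per-site group contrast from the coefficient vector and covariance
  beta <- if (usedModel == "mixed") lme4::fixef(mod) else stats::coef(mod)
  V <- as.matrix(stats::vcov(mod))
  ok <- !is.na(beta)
  siteLevels <- levels(d$site)
  nd <- data.frame(site = factor(rep(siteLevels, 2L), levels = siteLevels),
                   group = factor(rep(levels(d$group),
                                      each = length(siteLevels)),
                                  levels = levels(d$group)))
  mm <- stats::model.matrix(~ site * group, nd, contrasts.arg = ctr)
  n <- length(siteLevels)
  L <- mm[(n + 1L):(2L * n), , drop = FALSE] - mm[1:n, , drop = FALSE]
  L <- L[, ok, drop = FALSE]
  est <- drop(L %*% beta[ok])
  se <- sqrt(rowSums((L %*% V[ok, ok]) * L))
  stat <- est / se
  rawP <- if (usedModel == "mixed") 2 * stats::pnorm(-abs(stat))
          else 2 * stats::pt(-abs(stat), stats::df.residual(mod))
  perSite <- data.frame(site_pct = as.numeric(siteLevels),
                        estimate = est, se = se, raw_p = rawP,
                        bonferroni_p = NA_real_, significant = NA)
  new("SiteModelResult", overallP = overallP, interactionP = interP,
      perSite = perSite, nSitesTested = length(siteLevels),
      meta = list(model = usedModel,
                  randomEffect = if (usedModel == "mixed") "mouse_id" else
                    "none",
                  method = if (usedModel == "mixed")
                    "REML, type-III Wald chi-square" else
                    "OLS, type-III F",
                  measure = measure, nObs = nrow(d)))
}

#' Bonferroni per-site post hoc correction
#'
#' Multiplies each per-site raw p-value by the number of sites tested
#' (capped at 1) and flags the sites significant at \code{alpha}. Following
#' the gated procedure, the per-site map is only reported when the overall
#' intervention effect is itself significant; otherwise the significance
#' flags are NA (not applicable).
#'
#' @param result a \linkS4class{SiteModelResult}.
#' @param alpha significance level (default 0.05).
#' @param gate require overall significance before reporting site flags.
#' @return the updated \linkS4class{SiteModelResult}.
#' @examples
#' # raw p = 0.0001 over 81 sites -> corrected 0.0081, significant
#' @export
bonferroniPosthoc <- function(result, alpha = 0.05, gate = TRUE) {
  stopifnot(is(result, "SiteModelResult"))
  ps <- result@perSite
  ps$bonferroni_p <- pmin(1, ps$raw_p * result@nSitesTested)
  if (gate && (is.na(result@overallP) || result@overallP >= alpha)) {
    ps$significant <- NA
  } else {
    ps$significant <- ps$bonferroni_p < alpha
  }
  result@perSite <- ps
  result
}

#' Simulated-intervention power analysis
#'
#' Replays the simulated-change design: per replicate, sample
#' \code{nPerGroup} control mice, duplicate their profiles multiplied by
#' \code{1 + effect} at every site as the "intervention" limb of the same
#' mice, and analyze with the mixed model (random mouse intercept) plus
#' Bonferroni post hoc. Reports the median overall intervention p-value
#' and the mean fraction of Bonferroni-significant sites across
#' replicates.
#'
#' @param table long-format cohort table of control bones (rows with
#'   group == "control" are used).
#' @param effect fractional change applied at all sites (default +10%).
#' @param nPerGroup mice sampled per replicate.
#' @param nReps number of replicates.
#' @param seed RNG seed (required; all sampling is seeded).
#' @param measure measure to analyze.
#' @param alpha significance level.
#' @return list with \code{medianOverallP},
#'   \code{meanFractionSitesSignificant} and the per-replicate vectors
#'   \code{overallP}, \code{fractionSites}.
#' @export
powerSimulation <- function(table, effect = 0.10, nPerGroup = 4L,
                            nReps = 100L, seed, measure = "ct_ar",
                            alpha = 0.05) {
  if (missing(seed)) stop("seed is required")
  ctrl <- table[table$group == "control" & table$measure_name == measure, ,
                drop = FALSE]
  mice <- unique(ctrl$mouse_id)
  if (nPerGroup > length(mice))
    stop(sprintf("nPerGroup = %d exceeds the %d available control mice",
                 nPerGroup, length(mice)))
  withLocalSeed(seed, {
    pvals <- numeric(nReps)
    fracSig <- numeric(nReps)
    for (r in seq_len(nReps)) {
      take <- sample(mice, nPerGroup)
      ctrlR <- ctrl[ctrl$mouse_id %in% take, , drop = FALSE]
      ctrlR$limb <- "left"
      intR <- ctrlR
      intR$limb <- "right"
      intR$group <- "intervention"
      intR$value <- intR$value * (1 + effect)
      fit <- suppressWarnings(
        fitSiteModel(rbind(ctrlR, intR), measure, paired = TRUE))
      fit <- bonferroniPosthoc(fit, alpha = alpha)
      pvals[r] <- overallP(fit)
      sig <- perSiteResults(fit)$significant
      fracSig[r] <- if (all(is.na(sig))) 0 else mean(sig, na.rm = TRUE)
    }
    list(medianOverallP = stats::median(pvals),
         meanFractionSitesSignificant = mean(fracSig),
         overallP = pvals, fractionSites = fracSig)
  })
}
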