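# Mixed-effects models linking coupling and behavioral synchrony:
# model ladder with nested comparisons, simple slopes, real-vs-pseudo
# contrasts.

#' Merge coupling records with synchrony summaries
#'
#' Joins per-(dyad, condition, group) coupling records to the behavioral
#' synchrony table, for the brain-behavior models.
#'
#' @param coupling Data frame from [roi_pair_coupling()] /
#'   [pseudo_coupling()] (between scope).
#' @param sync Data frame of [total_sync()] summaries.
#' @return Merged data frame with factors set.
#' @export
merge_coupling_sync <- function(coupling, sync) {
  df <- merge(coupling, sync,
              by.x = c("unit_id", "condition", "group"),
              by.y = c("dyad_id", "condition", "group"))
  df$dyad_id <- df$unit_id
  prepare_model_data(df)
}

prepare_model_data <- function(data) {
  for (col in c("condition", "roi_pair", "group", "dyad_id"))
    if (!is.null(data[[col]])) data[[col]] <- factor(data[[col]])
  data
}

ladder_formula <- function(dependent, fixed, depth, random) {
  rhs <- if (depth <= 1) paste(fixed, collapse = " + ")
         else sprintf("(%s)^%d", paste(fixed, collapse = " + "), depth)
  stats::as.formula(sprintf("%s ~ %s + (1 | %s)", dependent, rhs, random))
}

#' Fit a ladder of nested mixed-effects models
#'
#' Fits models of increasing interaction depth (main effects, + two-way,
#' + three-way, up to `max_depth`) with a random intercept per grouping
#' unit, by REML via `lmerTest`. Successive models are compared by
#' likelihood-ratio chi-squared tests on ML refits (`anova`), with df equal
#' to the parameter-count difference; the deepest model that improves
#' significantly on its predecessor is flagged as selected. A Type II Wald
#' chi-squared table (`car::Anova`) and partial eta-squared effect sizes
#' (from Satterthwaite F tests) are reported for the selected model.
#'
#' @param data Data frame of merged records (one row per unit x cell).
#' @param dependent Response column (e.g. `"wtc_z"` or `"total_sync"`).
#' @param fixed Character vector of fixed-effect columns (factors and/or
#'   the continuous coupling value).
#' @param random Grouping column for the random intercept (default
#'   `"dyad_id"`).
#' @param max_depth Maximum interaction depth (capped at the number of
#'   fixed factors).
#' @param alpha Selection level for the ladder comparisons (default 0.05).
#' @return A `model_ladder` list: `fits`, `comparisons` (Chisq, df, p per
#'   step), `selected` (index), `selected_fit`, `wald` (Type II table),
#'   `effect_sizes`, `singular` (per model), `formulas`.
#' @export
fit_model_ladder <- function(data, dependent, fixed,
                             random = "dyad_id", max_depth = 3,
                             alpha = 0.05) {
  data <- prepare_model_data(data)
  if (anyNA(data[[dependent]])) stop("missing dependent values; apply outlier exclusion first")
  for (f in fixed) {
    if (is.factor(data[[f]]) && nlevels(droplevels(data[[f]])) < 2)
      stop("fixed factor ", f, " needs >= 2 levels")
  }
  if (any(duplicated(data[, c(random, intersect(fixed, names(data))), drop = FALSE])))
    warning("duplicate rows per unit and cell: estimates unchanged but precision inflated")
  max_depth <- min(max_depth, length(fixed))
  fits <- list()
  formulas <- list()
  singular <- logical(0)
  for (d in seq_len(max_depth)) {
    fo <- ladder_formula(dependent, fixed, d, random)
    fit <- suppressMessages(lmerTest::lmer(fo, data = data))
    formulas[[d]] <- fo
    fits[[d]] <- fit
    singular[d] <- lme4::isSingular(fit)
  }
  comparisons <- NULL
  selected <- 1L
  if (length(fits) > 1) {
    rows <- list()
    for (d in 2:length(fits)) {
      a <- suppressMessages(stats::anova(fits[[d - 1]], fits[[d]]))
      chisq <- a$Chisq[2]
      df <- a$Df[2]
      p <- a$`Pr(>Chisq)`[2]
      rows[[d - 1]] <- data.frame(step = sprintf("depth %d vs %d", d - 1, d),
                                  chisq = chisq, df = df, p = p)
      if (!is.na(p) && p < alpha && selected == d - 1L) selected <- d
    }
    comparisons <- do.call(rbind, rows)
  }
  sel_fit <- fits[[selected]]
  wald <- tryCatch(car::Anova(sel_fit, type = 2), error = function(e) NULL)
  efs <- tryCatch({
    at <- stats::anova(sel_fit)   # lmerTest Satterthwaite F table
    data.frame(term = rownames(at),
               F = at$`F value`,
               df1 = at$NumDF, df2 = at$DenDF,
               p = at$`Pr(>F)`,
               eta2_partial = at$`F value` * at$NumDF /
                 (at$`F value` * at$NumDF + at$DenDF))
  }, error = function(e) NULL)
  structure(list(fits = fits, formulas = formulas, data = data,
                 comparisons = comparisons, selected = selected,
                 selected_fit = sel_fit, wald = wald,
                 effect_sizes = efs, singular = singular,
                 dependent = dependent, fixed = fixed, random = random,
                 meta = list(
                   estimation = "REML; ladder comparison by LRT chi-squared on ML refits",
                   df_method = "Satterthwaite")),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat("Mixed-model ladder:", x$dependent, "~",
      paste(x$fixed, collapse = " * "), "+ (1 |", x$random, ")\n")
  if (!is.null(x$comparisons)) print(x$comparisons, row.names = FALSE)
  cat("Selected: depth", x$selected,
      if (any(x$singular)) "(some fits singular)\n" else "\n")
  invisible(x)
}

#' Per-cell simple slopes of the coupling predictor
#'
#' Marginal slope of the dependent variable on the continuous coupling
#' value within each condition x ROI-pair cell (estimate, SE, df, t, p),
#' via `emmeans::emtrends` on the selected model.
#'
#' @param ladder A `model_ladder` (or a fitted `lmerMod`).
#' @param var Continuous predictor (default `"wtc_z"`).
#' @param by Cell factors (default condition and ROI pair).
#' @param data The model data (needed for the per-cell observation check).
#' @return Data frame: one row per cell with `estimate`, `SE`, `df`,
#'   `t`, `p`.
#' @export
simple_slopes <- function(ladder, var = "wtc_z",
                          by = c("condition", "roi_pair"), data = NULL) {
  fit <- if (inherits(ladder, "model_ladder")) ladder$selected_fit else ladder
  if (inherits(ladder, "model_ladder") && is.null(data)) data <- ladder$data
  if (!var %in% all.vars(stats::formula(fit)))
    stop("selected model does not include ", var)
  if (is.null(data)) stop("model data required")
  counts <- stats::aggregate(data[[var]], by = data[by], FUN = length)
  if (any(counts$x < 3))
    stop("cell with fewer than 3 observations")
  spec <- stats::as.formula(paste("~", paste(by, collapse = " * ")))
  tr <- emmeans::emtrends(fit, spec, var = var, data = data,
                          lmer.df = "satterthwaite")
  s <- as.data.frame(summary(tr, infer = c(FALSE, TRUE)))
  names(s)[names(s) == paste0(var, ".trend")] <- "estimate"
  names(s)[names(s) == "t.ratio"] <- "t"
  names(s)[names(s) == "p.value"] <- "p"
  s
}

#' Real-versus-pseudo contrasts per cell
#'
#' Model-based contrast of the real and pseudo group means within each
#' condition x ROI-pair cell, with Bonferroni adjustment across cells by
#' default.
#'
#' @param data Model data containing a `group` factor with both levels.
#' @param dependent Response column (default `"wtc_z"`).
#' @param by Cell factors.
#' @param random Random-intercept grouping column.
#' @param adjust `"bonferroni"` (across all cells) or `"none"`.
#' @return Data frame: per cell `estimate` (real - pseudo), `SE`, `df`,
#'   `t`, `p` (unadjusted), `p_adj`.
#' @export
real_vs_pseudo_contrast <- function(data, dependent = "wtc_z",
                                    by = c("condition", "roi_pair"),
                                    random = "dyad_id",
                                    adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  data <- prepare_model_data(data)
  if (nlevels(droplevels(data$group)) < 2)
    stop("both real and pseudo groups required")
  if (length(unique(data[[random]])) < 2)
    stop("contrast requires more than one grouping unit")
  fo <- stats::as.formula(sprintf(
    "%s ~ group * %s + (1 | %s)", dependent,
    paste(by, collapse = " * "), random))
  fit <- suppressMessages(lmerTest::lmer(fo, data = data))
  em <- emmeans::emmeans(fit, stats::as.formula(
    paste("~ group |", paste(by, collapse = " * "))),
    data = data, lmer.df = "satterthwaite")
  ct <- as.data.frame(summary(emmeans::contrast(em, "revpairwise"),
                              adjust = "none"))
  names(ct)[names(ct) == "t.ratio"] <- "t"
  names(ct)[names(ct) == "p.value"] <- "p"
  ct$p_adj <- if (adjust == "bonferroni")
    stats::p.adjust(ct$p, method = "bonferroni") else ct$p
  ct
}
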