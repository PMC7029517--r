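default_covariates <- function() c("age", "sex", "mfwd", "apoe_e4")

# Map user-facing covariate names to modeling-frame columns (0/1 indicators
# per the coding convention: race 0 = caucasian reference, 1 = african
# american; sex indicator = female; diagnosis as dummies with NC reference).
covariate_column <- function(x) {
  ifelse(x == "sex", "sex_female", ifelse(x == "race", "race_aa", x))
}

# Add indicator columns used by every model.
modeling_frame <- function(data) {
  dplyr::mutate(
    data,
    race_aa = as.integer(.data$race == "african_american"),
    sex_female = as.integer(.data$sex == "female")
  )
}

# Pretty term labels for reported results; interactions are reported
# race-first regardless of the ordering model.matrix chose.
clean_term <- function(term) {
  term <- sub("^\\(Intercept\\)$", "intercept", term)
  term <- vapply(strsplit(term, ":", fixed = TRUE), function(parts) {
    if (length(parts) == 2L && parts[2L] == "race_aa") parts <- rev(parts)
    paste(parts, collapse = ":")
  }, character(1))
  term <- gsub("race_aa", "race", term, fixed = TRUE)
  term <- gsub("sex_female", "sex", term, fixed = TRUE)
  term
}

# Locate a (possibly interaction) term among model.matrix column names,
# ignoring the ordering of interaction components.
match_term <- function(term_names, focal) {
  key <- function(x) vapply(strsplit(x, ":", fixed = TRUE),
                            function(p) paste(sort(p), collapse = ":"),
                            character(1))
  match(key(focal), key(term_names))
}

apply_subset <- function(data, subset, abeta_cutoff) {
  subset <- match.arg(subset, c("all", "controls_only", "amyloid_positive"))
  out <- switch(subset,
    all = data,
    controls_only = dplyr::filter(data, .data$diagnosis == "NC"),
    amyloid_positive = abeta_gate(data, abeta_cutoff)
  )
  if (nrow(out) == 0L) abort(paste0("empty subset: ", subset))
  out
}

#' Amyloid-positivity gate
#'
#' Retains subjects whose CSF Abeta42 is strictly below the cutoff
#' (default 192 pg/mL, the threshold for cerebral amyloid deposition);
#' a value of exactly 192 is excluded.
#'
#' @param subjects tibble with an `abeta42` column.
#' @param cutoff_pg_ml strict upper bound in pg/mL.
#' @return the gated subject tibble.
#' @export
abeta_gate <- function(subjects, cutoff_pg_ml = 192) {
  if (!"abeta42" %in% names(subjects) || anyNA(subjects$abeta42)) {
    abort("abeta42 must be recorded for all subjects")
  }
  dplyr::filter(subjects, .data$abeta42 < cutoff_pg_ml)
}

# Right-hand-side terms for a model spec; focal term last so scans can
# index it positionally after model.matrix.
model_terms <- function(biomarker, interaction, covariates, extra_covariates) {
  if (interaction && is.null(biomarker)) {
    abort("an interaction model requires a biomarker")
  }
  covs <- covariate_column(c(covariates, extra_covariates))
  bm <- if (is.null(biomarker)) NULL else biomarker_column[[biomarker]]
  rhs <- c(covs, bm, "race_aa",
           if (interaction) paste0("race_aa:", bm))
  unique(rhs)
}

# Shared OLS core: y (vector or matrix) on design X; Wald t CIs.
ols_terms <- function(X, y, conf_level = 0.95) {
  n <- nrow(X); p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):p]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  y <- as.matrix(y)
  beta <- qr.coef(qrx, y)
  res <- qr.resid(qrx, y)
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qrx))
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  list(estimate = beta, std.error = se, statistic = tstat, p.value = pval,
       conf.low = beta - tcrit * se, conf.high = beta + tcrit * se,
       df = df, sigma2 = sigma2, term = colnames(X))
}

#' Fit the moderation model for one node pair
#'
#' Ordinary least squares of a node pair's connectivity on race, an
#' optional biomarker, their interaction, and covariates (default: age,
#' sex, mean framewise displacement, APOE e4 carrier status), with
#' listwise deletion of subjects missing any model variable. Wald 95%
#' confidence intervals use the t distribution on the residual degrees of
#' freedom. Race is coded 0 = Caucasian (reference), 1 = African American,
#' so the race coefficient is the African-American offset; biomarkers enter
#' on their raw scale (Z units for cognition, pg/mL for CSF markers).
#'
#' @param data tibble of subjects joined with their connectivity columns
#'   (pair keys as produced by [simulate_connectivity()]).
#' @param pair node-pair key, e.g. `"PCU-vlTC"`.
#' @param biomarker `"cognition"`, `"abeta42"`, `"ttau"`, or `NULL` for a
#'   race-only contrast.
#' @param interaction include the race x biomarker term?
#' @param subset `"all"`, `"controls_only"`, or `"amyloid_positive"`
#'   (CSF Abeta42 < `abeta_cutoff`).
#' @param covariates,extra_covariates covariate names; `sex` and `race` are
#'   translated to their 0/1 indicators.
#' @param fisher analyze Fisher-z transformed connectivity (atanh) instead
#'   of raw correlations.
#' @param conf_level confidence level for the Wald intervals.
#' @param abeta_cutoff gate threshold in pg/mL.
#' @param map subsystem map (for the pair's block label).
#' @return a `pair_model` object; `tidy()` returns the per-term table
#'   (term, estimate, conf.low, conf.high, p.value), `glance()` the fit
#'   summary.
#' @export
fit_pair_model <- function(data, pair, biomarker = NULL, interaction = FALSE,
                           subset = "all", covariates = default_covariates(),
                           extra_covariates = NULL, fisher = FALSE,
                           conf_level = 0.95, abeta_cutoff = 192,
                           map = dmn_nodes()) {
  pair <- normalize_pair_key(pair, map)
  if (!pair %in% names(data)) abort(paste0("no connectivity column for pair ", pair))
  if (!is.null(biomarker)) {
    biomarker <- match.arg(biomarker, biomarker_levels)
  }
  data <- apply_subset(data, subset, abeta_cutoff)
  if (dplyr::n_distinct(data$race) < 2L) {
    abort("both races must be represented in the modeled subset")
  }
  frame <- modeling_frame(data)
  rhs <- model_terms(biomarker, interaction, covariates, extra_covariates)
  vars <- unique(c(pair, all.vars(reformulate(rhs))))
  frame <- frame[complete.cases(frame[, vars]), , drop = FALSE]
  n_used <- nrow(frame)
  X <- model.matrix(reformulate(rhs), frame)
  if (n_used <= ncol(X) + 2L) abort("too few complete observations for the design")
  y <- frame[[pair]]
  if (var(y) == 0) abort(paste0("undefined model: zero outcome variance for pair ", pair))
  if (fisher) y <- fisher_z(y)
  fit <- ols_terms(X, y, conf_level)
  terms_tbl <- tibble::tibble(
    term = clean_term(fit$term),
    estimate = unname(fit$estimate[, 1L]),
    std.error = unname(fit$std.error[, 1L]),
    statistic = unname(fit$statistic[, 1L]),
    p.value = unname(fit$p.value[, 1L]),
    conf.low = unname(fit$conf.low[, 1L]),
    conf.high = unname(fit$conf.high[, 1L])
  )
  structure(list(
    pair = pair,
    block = dmn_node_pairs(map)$block[dmn_node_pairs(map)$pair == pair],
    terms = terms_tbl,
    n_used = n_used,
    df_residual = fit$df,
    sigma = sqrt(fit$sigma2[[1L]]),
    r_squared = 1 - fit$sigma2[[1L]] * fit$df / sum((y - mean(y))^2),
    spec = list(biomarker = biomarker, interaction = interaction,
                subset = subset, covariates = covariates,
                extra_covariates = extra_covariates, fisher = fisher)
  ), class = "pair_model")
}

# Internal multi-outcome scan: one QR, all pairs at once. Pairs whose
# outcome is missing or degenerate are marked failed rather than fatal.
scan_engine <- function(data, map, biomarker, interaction, covariates,
                        extra_covariates, fisher, conf_level, focal) {
  pairs <- dmn_node_pairs(map)
  missing_cols <- setdiff(pairs$pair, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("connectivity columns missing for ",
                 length(missing_cols), " pair(s)"))
  }
  frame <- modeling_frame(data)
  rhs <- model_terms(biomarker, interaction, covariates, extra_covariates)
  pred_vars <- all.vars(reformulate(rhs))
  frame <- frame[complete.cases(frame[, pred_vars]), , drop = FALSE]
  X <- model.matrix(reformulate(rhs), frame)
  Y <- as.matrix(frame[, pairs$pair])
  ok <- apply(Y, 2L, function(y) !anyNA(y) && var(y) > 0)
  if (fisher) Y[, ok] <- fisher_z(Y[, ok, drop = FALSE])
  fit <- ols_terms(X, Y[, ok, drop = FALSE], conf_level)
  focal_idx <- match_term(fit$term, focal)
  if (is.na(focal_idx)) abort(paste0("focal term not in design: ", focal))
  res <- tibble::tibble(
    pair = pairs$pair, block = pairs$block, n_used = nrow(frame),
    estimate = NA_real_, std.error = NA_real_, statistic = NA_real_,
    conf.low = NA_real_, conf.high = NA_real_, p.value = NA_real_
  )
  res$estimate[ok] <- fit$estimate[focal_idx, ]
  res$std.error[ok] <- fit$std.error[focal_idx, ]
  res$statistic[ok] <- fit$statistic[focal_idx, ]
  res$conf.low[ok] <- fit$conf.low[focal_idx, ]
  res$conf.high[ok] <- fit$conf.high[focal_idx, ]
  res$p.value[ok] <- fit$p.value[focal_idx, ]
  terms_long <- purrr::map_dfr(seq_along(fit$term), function(j) {
    tibble::tibble(pair = pairs$pair[ok], block = pairs$block[ok],
                   term = clean_term(fit$term[j]),
                   estimate = fit$estimate[j, ],
                   conf.low = fit$conf.low[j, ],
                   conf.high = fit$conf.high[j, ],
                   p.value = fit$p.value[j, ])
  })
  list(results = res, terms = terms_long, failed = pairs$pair[!ok],
       n_used = nrow(frame))
}

attach_corrections <- function(results, q, lambda) {
  ok <- !is.na(results$p.value)
  results$bh_adjusted <- NA_real_
  results$bh_rejected <- NA
  results$storey_q <- NA_real_
  pi0 <- NA_real_
  if (any(ok)) {
    bh <- bh_stepup(results$p.value[ok], q)
    sq <- storey_q(results$p.value[ok], lambda)
    results$bh_adjusted[ok] <- bh$bh_adjusted
    results$bh_rejected[ok] <- bh$bh_rejected
    results$storey_q[ok] <- sq$storey_q
    pi0 <- attr(sq, "pi0")
  }
  list(results = results, pi0 = pi0)
}

#' Race x biomarker interaction scan over all node pairs
#'
#' Fits the moderation model of [fit_pair_model()] (with the interaction
#' term) to every enumerated node pair, collects the interaction term's
#' coefficient, confidence interval and unadjusted p-value per pair, and
#' attaches Benjamini-Hochberg (FDR `q`, default 10%) and Storey q-value
#' corrections computed within the scan's p-values. A pair whose outcome is
#' degenerate is marked failed and excluded from correction, not fatal.
#'
#' @inheritParams fit_pair_model
#' @param q Benjamini-Hochberg FDR level.
#' @param lambda Storey pi0 tuning parameter.
#' @return a `dmn_scan` object: `$results` (per-pair interaction row with
#'   corrections), `$terms` (all model terms, long), `$failed`, `$pi0`,
#'   plus the scan metadata. `tidy()` returns `$results`.
#' @export
interaction_scan <- function(data, biomarker, subset = "all",
                             covariates = default_covariates(),
                             extra_covariates = NULL, fisher = FALSE,
                             q = 0.10, lambda = 0.5, conf_level = 0.95,
                             abeta_cutoff = 192, map = dmn_nodes()) {
  biomarker <- match.arg(biomarker, biomarker_levels)
  data <- apply_subset(data, subset, abeta_cutoff)
  focal <- paste0("race_aa:", biomarker_column[[biomarker]])
  eng <- scan_engine(data, map, biomarker, TRUE, covariates,
                     extra_covariates, fisher, conf_level, focal)
  corr <- attach_corrections(eng$results, q, lambda)
  structure(list(
    results = corr$results, terms = eng$terms, failed = eng$failed,
    pi0 = corr$pi0, biomarker = biomarker, subset = subset,
    term = paste0("race:", biomarker_column[[biomarker]]),
    n_used = eng$n_used, q = q, lambda = lambda, fisher = fisher
  ), class = "dmn_scan")
}

#' Baseline race contrasts among cognitively normal subjects
#'
#' One race-contrast model per node pair restricted to controls, adjusting
#' for age, sex and APOE e4 carrier status; results are sorted by
#' unadjusted p-value and carry the same multiple-testing columns as
#' [interaction_scan()].
#'
#' @inheritParams interaction_scan
#' @export
baseline_contrast <- function(data, covariates = c("age", "sex", "apoe_e4"),
                              fisher = FALSE, q = 0.10, lambda = 0.5,
                              conf_level = 0.95, map = dmn_nodes()) {
  data <- apply_subset(data, "controls_only", 192)
  if (dplyr::n_distinct(data$race) < 2L) {
    abort("baseline contrast requires both races among controls")
  }
  eng <- scan_engine(data, map, NULL, FALSE, covariates, NULL,
                     fisher, conf_level, focal = "race_aa")
  corr <- attach_corrections(eng$results, q, lambda)
  res <- dplyr::arrange(corr$results, .data$p.value)
  structure(list(
    results = res, terms = eng$terms, failed = eng$failed,
    pi0 = corr$pi0, biomarker = NULL, subset = "controls_only",
    term = "race", n_used = eng$n_used, q = q, lambda = lambda,
    fisher = fisher
  ), class = "dmn_scan")
}

#' Run the three biomarker scans of the moderation analysis
#'
#' Convenience wrapper for the standard design: cognition and Abeta42
#' interactions in all subjects, t-Tau interactions only in the
#' amyloid-positive subset (Abeta42 < 192 pg/mL).
#'
#' @inheritParams interaction_scan
#' @return named list of three `dmn_scan` objects
#'   (`cognition`, `abeta42`, `ttau`).
#' @export
scan_all_biomarkers <- function(data, covariates = default_covariates(),
                                extra_covariates = NULL, fisher = FALSE,
                                q = 0.10, lambda = 0.5, abeta_cutoff = 192,
                                map = dmn_nodes()) {
  list(
    cognition = interaction_scan(data, "cognition", "all", covariates,
                                 extra_covariates, fisher, q, lambda,
                                 abeta_cutoff = abeta_cutoff, map = map),
    abeta42 = interaction_scan(data, "abeta42", "all", covariates,
                               extra_covariates, fisher, q, lambda,
                               abeta_cutoff = abeta_cutoff, map = map),
    ttau = interaction_scan(data, "ttau", "amyloid_positive", covariates,
                            extra_covariates, fisher, q, lambda,
                            abeta_cutoff = abeta_cutoff, map = map)
  )
}

#' Benjamini-Hochberg step-up correction
#'
#' Classic step-up control of the false discovery rate: sort p ascending,
#' find the largest k with `p_(k) <= k q / m`, reject hypotheses 1..k.
#' Adjusted p-values follow the min-forward cumulative rule (capped at 1);
#' rejection at level `q` is equivalent to `bh_adjusted <= q`.
#'
#' @param p p-values in (0, 1].
#' @param q FDR level, default 0.10.
#' @return tibble with `p`, `bh_adjusted`, `bh_rejected`, in input order.
#' @export
bh_stepup <- function(p, q = 0.10) {
  check_pvalues(p)
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, bh_adjusted = adj, bh_rejected = adj <= q)
}

#' Storey q-values with fixed-lambda pi0 estimate
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))` and computes
#' `q_(i) = min_(j >= i) pi0 m p_(j) / j` on the sorted scale, mapped back
#' to input order. With `pi0` forced to 1 this reduces exactly to the
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in (0, 1].
#' @param lambda tuning parameter in (0, 1), default 0.5 (a fixed lambda is
#'   used because spline pi0 estimators are unstable at m = 55).
#' @return tibble with `p` and `storey_q`; the pi0 estimate is attached as
#'   attribute `"pi0"`.
#' @export
storey_q <- function(p, lambda = 0.5) {
  check_pvalues(p)
  if (lambda <= 0 || lambda >= 1) abort("lambda must lie in (0, 1)")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  o <- order(p)
  q_sorted <- rev(cummin(rev(pi0 * m * p[o] / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  structure(tibble::tibble(p = p, storey_q = out), pi0 = pi0)
}

check_pvalues <- function(p) {
  if (length(p) == 0L || anyNA(p) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  invisible(p)
}

#' Subsystem-mean connectivity ANCOVA
#'
#' Tests whether race influences the mean inter-subsystem connectivity of a
#' block (per-subject average of its node-pair entries), adjusting for
#' diagnosis, age and sex. The race effect is the type-II F test (the
#' race term dropped from the full main-effects model).
#'
#' @param data subjects joined with connectivity columns.
#' @param block inter-subsystem block label (`"dm_midline"`,
#'   `"mtl_midline"` or `"dm_mtl"`).
#' @param map subsystem map.
#' @return one-row tibble: `block`, `statistic` (F), `df`, `df_residual`,
#'   `p.value`, `n`.
#' @export
subsystem_ancova <- function(data, block = "dm_midline", map = dmn_nodes()) {
  blocks <- list(dm_midline = c("midline_core", "dorsomedial"),
                 mtl_midline = c("midline_core", "medial_temporal"),
                 dm_mtl = c("dorsomedial", "medial_temporal"))
  if (!block %in% names(blocks)) abort("unknown inter-subsystem block")
  if (dplyr::n_distinct(data$race) < 2L || dplyr::n_distinct(data$diagnosis) < 2L) {
    abort("degenerate design: need both races and at least two diagnoses")
  }
  if (any(tapply(data$diagnosis, data$race, dplyr::n_distinct) < 2L)) {
    abort("degenerate design: a race stratum carries a single diagnosis")
  }
  ab <- blocks[[block]]
  frame <- modeling_frame(data)
  frame$mean_conn <- mean_subsystem_connectivity(data, ab[1L], ab[2L], map)
  fit <- lm(mean_conn ~ race_aa + diagnosis + age + sex_female,
            data = frame)
  dr <- drop1(fit, scope = ~race_aa, test = "F")
  tibble::tibble(
    block = block,
    statistic = dr[["F value"]][2L],
    df = dr$Df[2L],
    df_residual = fit$df.residual,
    p.value = dr[["Pr(>F)"]][2L],
    n = nrow(frame)
  )
}
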