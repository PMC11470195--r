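#' Length-based age classification rules
#'
#' Young-of-year are fish below `yoy_max_mm`; the 1-2 year bin upper edge
#' depends on the sampling year (growth varied between years); fish up to
#' `two_three_max_mm` are 2-3 years old, and longer fish are adults. Lengths
#' falling in configured gaps (90-100 mm and, for the wide-bin year, the
#' 270/271 mm boundary) are resolved by the gap policy; the default assigns
#' them to the nearer bin edge.
#'
#' @param yoy_max_mm upper length of young-of-year (exclusive), default 90.
#' @param one_two_min_mm lower length of the 1-2YO bin, default 100.
#' @param one_two_max_mm named numeric: upper 1-2YO edge per sampling year
#'   (default 210 for 2020, 180 for 2021-2023).
#' @param two_three_max_mm upper 2-3YO edge, default 270.
#' @param adult_min_mm adults are fish above this length, default 271.
#' @param gap_policy `"nearest"` (assign to the nearer edge) or `"na"`
#'   (leave gap lengths unassigned).
#' @return list of class `age_rules`.
#' @export
age_rules <- function(yoy_max_mm = 90, one_two_min_mm = 100,
                      one_two_max_mm = c("2020" = 210, "2021" = 180,
                                         "2022" = 180, "2023" = 180),
                      two_three_max_mm = 270, adult_min_mm = 271,
                      gap_policy = c("nearest", "na")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(yoy_max_mm < one_two_min_mm,
            all(one_two_max_mm > one_two_min_mm),
            all(one_two_max_mm <= two_three_max_mm),
            two_three_max_mm <= adult_min_mm)
  structure(list(yoy_max_mm = yoy_max_mm, one_two_min_mm = one_two_min_mm,
                 one_two_max_mm = one_two_max_mm,
                 two_three_max_mm = two_three_max_mm,
                 adult_min_mm = adult_min_mm, gap_policy = gap_policy),
            class = "age_rules")
}

#' Assign an age class from length at capture
#'
#' @param length_mm total length in mm (> 0); vectorised.
#' @param sampling_year year of capture (selects the year-specific 1-2YO
#'   edge; years without an explicit rule use the narrow post-2020 bins).
#' @param rules an [age_rules()].
#' @return character vector: `"YOY"`, `"1-2YO"`, `"2-3YO"` or `"adult"`.
#' @export
assign_age <- function(length_mm, sampling_year, rules = age_rules()) {
  if (any(length_mm <= 0, na.rm = TRUE)) stop("length_mm must be positive")
  n <- max(length(length_mm), length(sampling_year))
  length_mm <- rep_len(length_mm, n)
  sampling_year <- rep_len(sampling_year, n)
  yr <- as.character(sampling_year)
  upper12 <- ifelse(yr %in% names(rules$one_two_max_mm),
                    rules$one_two_max_mm[yr], 180)
  out <- rep(NA_character_, n)
  out[length_mm < rules$yoy_max_mm] <- "YOY"
  in12 <- length_mm >= rules$one_two_min_mm & length_mm <= upper12
  out[in12] <- "1-2YO"
  in23 <- length_mm > upper12 & length_mm <= rules$two_three_max_mm
  out[in23] <- "2-3YO"
  out[length_mm >= rules$adult_min_mm] <- "adult"
  gap <- is.na(out) & !is.na(length_mm)
  if (any(gap)) {
    if (rules$gap_policy == "nearest") {
      # lower gap (yoy_max, one_two_min): split at the midpoint
      lower <- gap & length_mm < rules$one_two_min_mm
      mid <- (rules$yoy_max_mm + rules$one_two_min_mm) / 2
      out[lower & length_mm < mid] <- "YOY"
      out[lower & length_mm >= mid] <- "1-2YO"
      # upper gap (two_three_max, adult_min): likewise
      upper <- gap & length_mm > rules$two_three_max_mm
      mid2 <- (rules$two_three_max_mm + rules$adult_min_mm) / 2
      out[upper & length_mm <= mid2] <- "2-3YO"
      out[upper & length_mm > mid2] <- "adult"
    }
  }
  out
}

#' Assign a birth-year cohort from age class and capture date
#'
#' Birth year is the capture year minus the class age (0 for YOY, 1 for
#' 1-2YO, 2 for 2-3YO), minus one more when the capture month precedes the
#' spawning month — a fish caught before the spawning season belongs to the
#' previous year's cohort. Adults are pooled into the `"adult"` group.
#'
#' @param age_class from [assign_age()].
#' @param capture_year integer year of capture.
#' @param capture_month optional month; missing months are treated as
#'   post-spawning.
#' @param spawning_month month the spawning season starts (default 11,
#'   austral spring).
#' @return character vector: birth year or `"adult"`.
#' @export
assign_cohort <- function(age_class, capture_year, capture_month = NULL,
                          spawning_month = 11L) {
  n <- max(length(age_class), length(capture_year))
  age_class <- rep_len(age_class, n)
  capture_year <- rep_len(capture_year, n)
  k <- c("YOY" = 0L, "1-2YO" = 1L, "2-3YO" = 2L)[age_class]
  out <- rep(NA_character_, n)
  adult <- !is.na(age_class) & age_class == "adult"
  out[adult] <- "adult"
  ok <- !is.na(k)
  birth <- capture_year - k
  if (!is.null(capture_month)) {
    capture_month <- rep_len(capture_month, n)
    pre <- !is.na(capture_month) & capture_month < spawning_month
    birth[pre] <- birth[pre] - 1L
  }
  out[ok] <- as.character(birth[ok])
  out
}

#' Fit a Gompertz growth model
#'
#' Nonlinear least squares of L(t) = b1 * exp(-b2 * exp(-b3 * t)) on
#' length-at-age data, from the stated initial values. Residuals (observed -
#' fitted) are the size-at-age residuals used as a growth-rate proxy in
#' fitness models.
#'
#' @param lengths_mm observed total lengths (mm).
#' @param ages_years ages (years); class midpoints when exact ages are
#'   unknown.
#' @param init named or positional start values `c(b1, b2, b3)`.
#' @return list of class `growth_model`: `b1`, `b2`, `b3`, `fitted`,
#'   `residuals`, `converged`, `fit` (the nls object).
#' @export
fit_gompertz <- function(lengths_mm, ages_years, init = c(200, 0.5, 0.3)) {
  ok <- !is.na(lengths_mm) & !is.na(ages_years)
  if (sum(ok) < 4 || length(unique(ages_years[ok])) < 2)
    stop("need >= 4 points spanning >= 2 distinct ages")
  dat <- data.frame(L = lengths_mm[ok], t = ages_years[ok])
  fit <- tryCatch(
    minpack.lm::nlsLM(L ~ b1 * exp(-b2 * exp(-b3 * t)), data = dat,
                      start = list(b1 = init[1], b2 = init[2], b3 = init[3]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    stop("Gompertz fit did not converge: ", conditionMessage(fit))
  cf <- stats::coef(fit)
  if (cf["b1"] <= 0 || cf["b3"] <= 0)
    warning("degenerate Gompertz fit (non-positive b1 or b3)")
  res <- rep(NA_real_, length(lengths_mm))
  res[ok] <- dat$L - stats::fitted(fit)
  structure(list(b1 = unname(cf["b1"]), b2 = unname(cf["b2"]),
                 b3 = unname(cf["b3"]),
                 fitted = stats::fitted(fit), residuals = res,
                 converged = fit$convInfo$isConv %||% TRUE, fit = fit),
            class = "growth_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the Gompertz curve
#' @param t age (years).
#' @param b1,b2,b3 parameters.
#' @return predicted length (mm).
#' @export
gompertz_length <- function(t, b1, b2, b3) b1 * exp(-b2 * exp(-b3 * t))

#' Model ladder for growth residuals and inbreeding depression
#'
#' Fits the nested linear models site; cohort; site + cohort; site + cohort +
#' interaction on size-at-age residuals, compares them with F-tests, then adds
#' individual heterozygosity (PHt) to the best structural model. A
#' significant PHt term (positive slope) is the inbreeding-depression signal.
#'
#' @param residuals size-at-age residuals per individual.
#' @param site,cohort factors per individual.
#' @param pht individual heterozygosity per individual.
#' @param alpha significance level for the ladder decisions (default 0.05).
#' @return list: `ladder` (data.frame: model, df, adj_r2, F, p vs previous
#'   accepted model), `best` (label), `pht_test` (list: estimate, p_value,
#'   significant), `fits`.
#' @export
growth_model_ladder <- function(residuals, site, cohort, pht, alpha = 0.05) {
  dat <- data.frame(y = residuals, site = factor(site),
                    cohort = factor(cohort), pht = pht)
  dat <- dat[stats::complete.cases(dat[, c("y", "site", "cohort")]), ]
  if (nlevels(droplevels(dat$site)) < 2 || nlevels(droplevels(dat$cohort)) < 2)
    stop("need >= 2 sites and >= 2 cohorts")
  dat$site <- droplevels(dat$site); dat$cohort <- droplevels(dat$cohort)
  if (stats::var(dat$y) == 0) {
    # constant response: no variance to attribute, no inbreeding signal
    ladder <- data.frame(model = c("site", "cohort", "site+cohort"),
                         df = NA_real_, adj_r2 = 0, p_vs_previous = NA_real_)
    return(list(ladder = ladder, best = "site",
                pht_test = list(estimate = 0, p_value = 1, significant = FALSE),
                fits = list()))
  }
  fits <- list(site = stats::lm(y ~ site, dat),
               cohort = stats::lm(y ~ cohort, dat),
               `site+cohort` = stats::lm(y ~ site + cohort, dat))
  has_int <- !any(table(dat$site, dat$cohort) == 0)
  if (has_int) {
    fits$`site*cohort` <- stats::lm(y ~ site * cohort, dat)
  } else {
    message("empty site-by-cohort cells; interaction model skipped")
  }
  adj <- vapply(fits, function(m) summary(m)$adj.r.squared, numeric(1))
  dfm <- vapply(fits, function(m) length(stats::coef(m)) - 1, numeric(1))
  # ladder: single predictors -> additive -> interaction
  best <- if (adj[["site"]] >= adj[["cohort"]]) "site" else "cohort"
  p_add <- stats::anova(fits[[best]], fits[["site+cohort"]])$`Pr(>F)`[2]
  if (!is.na(p_add) && p_add < alpha) best <- "site+cohort"
  p_int <- NA_real_
  if (has_int && best == "site+cohort") {
    p_int <- stats::anova(fits[["site+cohort"]], fits[["site*cohort"]])$`Pr(>F)`[2]
    if (!is.na(p_int) && p_int < alpha) best <- "site*cohort"
  }
  ladder <- data.frame(model = names(fits), df = dfm, adj_r2 = adj,
                       row.names = NULL)
  ladder$p_vs_previous <- NA_real_
  ladder$p_vs_previous[ladder$model == "site+cohort"] <- p_add
  if (has_int) ladder$p_vs_previous[ladder$model == "site*cohort"] <- p_int
  # inbreeding-depression step: add PHt to the best structural model
  datp <- dat[!is.na(dat$pht), ]
  base_form <- switch(best, site = y ~ site, cohort = y ~ cohort,
                      `site+cohort` = y ~ site + cohort,
                      `site*cohort` = y ~ site * cohort)
  m_base <- stats::lm(base_form, datp)
  m_pht <- stats::update(m_base, . ~ . + pht)
  p_pht <- stats::anova(m_base, m_pht)$`Pr(>F)`[2]
  est <- stats::coef(m_pht)[["pht"]]
  list(ladder = ladder, best = best,
       pht_test = list(estimate = est, p_value = p_pht,
                       significant = !is.na(p_pht) && p_pht < alpha),
       fits = fits)
}
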