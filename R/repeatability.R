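#' Variance components of the run-by-feed replicated design
#'
#' Two-way random model with interaction,
#' `y_rfk = mu + run_r + feed_f + (run:feed)_rf + e_rfk`, fitted either by
#' the expected-mean-squares (EMS) method-of-moments on the balanced ANOVA
#' (`method = "anova_ems"`) or by restricted maximum likelihood
#' (`method = "reml"`). For balanced data the REML solution is obtained by
#' maximizing the closed-form stratum likelihood of the four mean squares
#' (it coincides with the EMS solution whenever all EMS estimates are
#' non-negative); unbalanced data are handed to [lme4::lmer()]. Negative
#' method-of-moments components are truncated to 0 and flagged.
#'
#' EMS solution for `r` runs, `f` feeds, `n` replicates per cell:
#' `sigma2_e = MS_within`; `sigma2_RF = (MS_RF - MS_within) / n`;
#' `sigma2_R = (MS_R - MS_RF) / (n f)`; `sigma2_F = (MS_F - MS_RF) / (n r)`.
#'
#' @param data data.frame with columns `run`, `feed`, `value` (one row per
#'   bottle measurement).
#' @param method `"reml"` (default) or `"anova_ems"`.
#' @return Object of class `variance_components`: `sigma2_run`,
#'   `sigma2_feed`, `sigma2_run_feed`, `sigma2_error`, `method`,
#'   `truncated` (named logical), `n_reps`, and for the EMS method `raw`,
#'   the untruncated moment estimates (the unbiased estimator, useful for
#'   aggregation across datasets).
#' @examples
#' d <- expand.grid(run = 1:2, feed = c("a", "b"), rep = 1:2)
#' d$value <- rep(c(10, 12), each = 4)[order(rep(1:4, 2))]
#' @export
estimate_variance_components <- function(data,
                                         method = c("reml", "anova_ems")) {
  method <- match.arg(method)
  stopifnot(all(c("run", "feed", "value") %in% names(data)))
  data$run <- factor(data$run)
  data$feed <- factor(data$feed)
  r <- nlevels(data$run)
  f <- nlevels(data$feed)
  if (r < 2 || f < 2)
    stop("need at least 2 runs and 2 feeds to separate variance components")
  cells <- table(data$run, data$feed)
  balanced <- length(unique(as.vector(cells))) == 1 && all(cells > 0)
  n <- if (balanced) unique(as.vector(cells)) else NA
  if (all(cells <= 1))
    stop("a single replicate per cell: residual variance is inestimable")

  if (method == "anova_ems") {
    if (!balanced)
      stop("anova_ems requires a balanced design; use method = \"reml\"")
    if (n < 2)
      stop("anova_ems needs >= 2 replicates per cell")
    return(ems_components(data, r, f, n))
  }

  if (balanced && n >= 2) {
    reml_balanced(data, r, f, n)
  } else {
    reml_lme4(data)
  }
}

# strata mean squares from the balanced two-way ANOVA
anova_strata <- function(data) {
  fit <- stats::aov(value ~ run * feed, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  list(ms = stats::setNames(tab[["Mean Sq"]], rn),
       ss = stats::setNames(tab[["Sum Sq"]], rn),
       df = stats::setNames(tab[["Df"]], rn))
}

ems_components <- function(data, r, f, n) {
  st <- anova_strata(data)
  ms <- st$ms
  raw <- c(sigma2_error = unname(ms[["Residuals"]]),
           sigma2_run_feed = (ms[["run:feed"]] - ms[["Residuals"]]) / n,
           sigma2_run = (ms[["run"]] - ms[["run:feed"]]) / (n * f),
           sigma2_feed = (ms[["feed"]] - ms[["run:feed"]]) / (n * r))
  # snap floating-point residue to an exact zero before flagging
  raw[abs(raw) < 1e-9 * max(1, abs(raw))] <- 0
  truncated <- raw < 0
  if (any(truncated))
    warning("negative variance component estimate(s) truncated to 0: ",
            paste(names(raw)[truncated], collapse = ", "))
  est <- pmax(raw, 0)
  # raw moment estimates kept as a diagnostic: they are the unbiased
  # estimator, truncation being a per-dataset reporting convention
  structure(list(sigma2_run = est[["sigma2_run"]],
                 sigma2_feed = est[["sigma2_feed"]],
                 sigma2_run_feed = est[["sigma2_run_feed"]],
                 sigma2_error = est[["sigma2_error"]],
                 method = "anova_ems", truncated = truncated, n_reps = n,
                 raw = raw),
            class = "variance_components")
}

# REML for the balanced case via the stratum (mean-squares) restricted
# likelihood: -2 lR = sum_s df_s log(gamma_s) + SS_s / gamma_s, with
# gamma_e = s2e, gamma_RF = s2e + n s2RF, gamma_R = gamma_RF + n f s2R,
# gamma_F = gamma_RF + n r s2F. Interior maximum: gamma_s = MS_s, i.e. the
# EMS solution; boundary cases are solved numerically.
reml_balanced <- function(data, r, f, n) {
  st <- anova_strata(data)
  ss <- st$ss; df <- st$df
  ems <- suppressWarnings(ems_components(data, r, f, n))
  interior <- !any(ems$truncated)
  if (interior) {
    out <- ems
    out$method <- "reml"
    return(out)
  }
  negll <- function(theta) {           # theta = (s2e, s2RF, s2R, s2F) >= 0
    ge <- theta[1]
    grf <- theta[1] + n * theta[2]
    gr <- grf + n * f * theta[3]
    gf <- grf + n * r * theta[4]
    if (ge <= 0) return(1e12)
    df[["Residuals"]] * log(ge) + ss[["Residuals"]] / ge +
      df[["run:feed"]] * log(grf) + ss[["run:feed"]] / grf +
      df[["run"]] * log(gr) + ss[["run"]] / gr +
      df[["feed"]] * log(gf) + ss[["feed"]] / gf
  }
  start <- c(max(ems$sigma2_error, 1e-8), ems$sigma2_run_feed,
             ems$sigma2_run, ems$sigma2_feed)
  opt <- stats::optim(start, negll, method = "L-BFGS-B",
                      lower = c(1e-10, 0, 0, 0),
                      control = list(maxit = 500, factr = 1e4))
  est <- pmax(opt$par, 0)
  structure(list(sigma2_run = est[3], sigma2_feed = est[4],
                 sigma2_run_feed = est[2], sigma2_error = est[1],
                 method = "reml", truncated = ems$truncated, n_reps = n),
            class = "variance_components")
}

reml_lme4 <- function(data) {
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ 1 + (1 | run) + (1 | feed) + (1 | run:feed),
               data = data, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  pick <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  structure(list(sigma2_run = pick("run"), sigma2_feed = pick("feed"),
                 sigma2_run_feed = pick("run:feed"),
                 sigma2_error = pick("Residual"),
                 method = "reml",
                 truncated = c(sigma2_error = FALSE, sigma2_run_feed = FALSE,
                               sigma2_run = FALSE, sigma2_feed = FALSE),
                 n_reps = NA),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> (%s) run %.4g, feed %.4g, run:feed %.4g, error %.4g\n",
    x$method, x$sigma2_run, x$sigma2_feed, x$sigma2_run_feed,
    x$sigma2_error))
  invisible(x)
}

#' Repeatability limit
#'
#' `RT = 2 sqrt(2 sigma2_e)`: the absolute difference below which two
#' same-condition measurements are expected to fall with roughly 95 percent
#' confidence (the classical repeatability limit with 1.96 rounded to 2).
#'
#' @param vc A `variance_components` (or a bare residual variance).
#' @return RT in the endpoint's units (mL/g DM here).
#' @examples
#' repeatability_rt(list(sigma2_error = 2))  # 4
#' @export
repeatability_rt <- function(vc) {
  s2e <- if (is.list(vc)) vc$sigma2_error else vc
  if (s2e < 0) stop("residual variance must be non-negative")
  2 * sqrt(2 * s2e)
}

#' Coefficient of repeatability
#'
#' `RT% = 100 (s2_R + s2_F + s2_RF) / (s2_R + s2_F + s2_RF + s2_e)` — the
#' share of total variance not attributable to residual error.
#'
#' @param vc A `variance_components`.
#' @return Percentage in `[0, 100]`.
#' @export
repeatability_pct <- function(vc) {
  between <- vc$sigma2_run + vc$sigma2_feed + vc$sigma2_run_feed
  total <- between + vc$sigma2_error
  if (total <= 0)
    stop("all variance components are zero: RT% is undefined")
  100 * between / total
}

#' Percent difference between measurement techniques
#'
#' @param automated,manual Mean GP of each technique (same endpoint/unit).
#' @return `100 * (automated - manual) / manual`.
#' @examples
#' technique_pct_diff(145, 130)  # 11.5
#' @export
technique_pct_diff <- function(automated, manual) {
  100 * (automated - manual) / manual
}

#' Per-bottle endpoint values from a gas-production table
#'
#' @param gp_table Blank-corrected GP table (feed bottles only are kept).
#' @param endpoints Incubation hours; each must be present in every
#'   bottle's time grid.
#' @return Long data.frame `bottle_id`, `run`, `technique`, `feed_id`,
#'   `replicate`, `endpoint_h`, `value` (mL/g DM).
#' @export
endpoint_values <- function(gp_table, endpoints = c(6, 12, 24, 48)) {
  feed <- gp_table[gp_table$feed_id != "blank", ]
  ids <- unique(feed$bottle_id)
  out <- lapply(ids, function(id) {
    d <- feed[feed$bottle_id == id, ]
    d <- d[order(d$time_h), ]
    idx <- match(round(endpoints, 9), round(d$time_h, 9))
    if (anyNA(idx))
      stop("endpoint(s) ", paste(endpoints[is.na(idx)], collapse = ", "),
           " h not on the time grid of bottle ", id)
    data.frame(bottle_id = id, run = d$run_id[1], technique = d$technique[1],
               feed_id = d$feed_id[1], replicate = d$replicate[1],
               endpoint_h = endpoints, value = d$gp_mL_per_g[idx])
  })
  do.call(rbind, out)
}

#' Technique and feed summary of endpoint gas production
#'
#' Per-technique means, per-feed means, per-cell (technique-by-feed) means
#' and the automated-vs-manual percent difference at each endpoint. In the
#' full design each technique-by-feed mean averages 8 bottles and each
#' feed mean (within technique) 8; feed means pooled over techniques
#' average 16, while the tabulated per-technique feed means follow the
#' reporting convention of 12-observation means when 2 runs x 6 feeds are
#' summarized per technique with 4 replicates averaged across runs.
#'
#' @param gp_table Blank-corrected GP table.
#' @param endpoints Hours to summarize (default 6, 12, 24, 48).
#' @return List `technique_means`, `feed_means` (per technique),
#'   `cell_means`, `pct_diff` (per endpoint), `values` (the bottle-level
#'   endpoint table).
#' @export
technique_feed_means <- function(gp_table, endpoints = c(6, 12, 24, 48)) {
  ev <- endpoint_values(gp_table, endpoints)
  techs <- unique(ev$technique)
  if (!all(c("automated", "manual") %in% techs))
    stop("missing technique level: need both 'automated' and 'manual'")
  technique_means <- stats::aggregate(value ~ technique + endpoint_h,
                                      data = ev, FUN = mean)
  feed_means <- stats::aggregate(value ~ technique + feed_id + endpoint_h,
                                 data = ev, FUN = mean)
  cell_means <- stats::aggregate(
    value ~ technique + run + feed_id + endpoint_h, data = ev, FUN = mean)
  pct <- vapply(endpoints, function(e) {
    a <- technique_means$value[technique_means$technique == "automated" &
                                 technique_means$endpoint_h == e]
    m <- technique_means$value[technique_means$technique == "manual" &
                                 technique_means$endpoint_h == e]
    technique_pct_diff(a, m)
  }, numeric(1))
  list(technique_means = technique_means, feed_means = feed_means,
       cell_means = cell_means,
       pct_diff = stats::setNames(pct, paste0("GP_", endpoints)),
       values = ev)
}

#' Repeatability report per technique and endpoint
#'
#' Estimates the run/feed/run-by-feed/error variance components of the
#' endpoint values within each technique and derives RT and RT%.
#'
#' @param gp_table Blank-corrected GP table.
#' @param endpoints Hours to analyze.
#' @param method Passed to [estimate_variance_components()].
#' @return data.frame `technique`, `endpoint_h`, `sigma2_run`,
#'   `sigma2_feed`, `sigma2_run_feed`, `sigma2_error`, `RT`, `RT_pct`.
#' @export
repeatability_report <- function(gp_table, endpoints = c(6, 12, 24, 48),
                                 method = "reml") {
  ev <- endpoint_values(gp_table, endpoints)
  out <- list()
  for (tech in unique(ev$technique)) {
    for (e in endpoints) {
      d <- ev[ev$technique == tech & ev$endpoint_h == e, ]
      vc <- estimate_variance_components(
        data.frame(run = d$run, feed = d$feed_id, value = d$value),
        method = method)
      out[[length(out) + 1L]] <- data.frame(
        technique = tech, endpoint_h = e,
        sigma2_run = vc$sigma2_run, sigma2_feed = vc$sigma2_feed,
        sigma2_run_feed = vc$sigma2_run_feed,
        sigma2_error = vc$sigma2_error,
        RT = repeatability_rt(vc), RT_pct = repeatability_pct(vc))
    }
  }
  do.call(rbind, out)
}
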